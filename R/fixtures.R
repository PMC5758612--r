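#' Packaged individual threshold tables
#'
#' Loads the packaged contrast-threshold data: the baseline-experiment table
#' (10 participants -- 5 macular-degeneration observers testing at their
#' preferred retinal locus and 5 age- and eccentricity-matched controls --
#' by 2 orientations by 4 separations, 80 Michelson thresholds) and the
#' training-experiment table of threshold differences after 12 sessions of
#' collinear training (the 7 trained participants, 56 difference cells),
#' plus participant metadata. Files are checksum-verified against the
#' transcription, and numeric values are returned alongside their exact
#' printed string form so transcription fidelity can be asserted at the
#' string level.
#'
#' @return A `fixture_set`: list with `table2` (threshold table with extra
#'   column `threshold_string`), `table3` (columns `participant`, `group`,
#'   `orientation`, `separation`, `delta`, `delta_string`) and
#'   `participants` (columns `participant`, `group`, `trained`).
#' @export
#' @examples
#' fx <- load_fixtures()
#' subset(fx$table2, participant == "AMD1" & orientation == "collinear")
load_fixtures <- function() {
  paths <- c(table2 = "table2_exp1_thresholds.csv",
             table3 = "table3_exp2_training_deltas.csv",
             participants = "participants.csv")
  md5 <- c(table2 = "64a1be9eeb9cf6e0a103ab24c673f2f6",
           table3 = "90d17f36b792e39ef2bbbcdfdb79bda5",
           participants = "4196481ce6452182cb09b56589dd27b5")
  full <- vapply(paths, function(p)
    system.file("extdata", p, package = "latmask", mustWork = TRUE), "")
  got <- unname(tools::md5sum(full))
  if (!identical(got, unname(md5)))
    stop("packaged fixture checksum mismatch: ",
         paste(names(paths)[got != md5], collapse = ", "), call. = FALSE)

  t2 <- utils::read.csv(full[["table2"]], colClasses = "character")
  t2$threshold_string <- t2$threshold
  t2$threshold <- as.numeric(t2$threshold)
  t2$separation <- as.numeric(t2$separation)
  validate_threshold_table(t2)
  if (nrow(t2) != 80) stop("baseline table must have 80 cells", call. = FALSE)

  t3 <- utils::read.csv(full[["table3"]], colClasses = "character")
  t3$delta_string <- t3$delta
  t3$delta <- as.numeric(t3$delta)
  t3$separation <- as.numeric(t3$separation)
  if (nrow(t3) != 56) stop("training table must have 56 cells", call. = FALSE)

  meta <- utils::read.csv(full[["participants"]],
                          colClasses = c("character", "character", "logical"))
  if (!all(t3$participant %in% t2$participant))
    stop("trained participant missing from the baseline table", call. = FALSE)

  structure(list(table2 = t2, table3 = t3, participants = meta),
            class = "fixture_set")
}

#' Read and write threshold tables
#'
#' Threshold tables travel as plain CSV (comma separator, dot decimal,
#' header `participant,group,phase,orientation,separation,threshold`).
#'
#' @param path File path.
#' @return `read_threshold_table()`: a validated threshold table.
#' @export
read_threshold_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$separation <- as.numeric(tab$separation)
  validate_threshold_table(tab)
  tab
}

#' @rdname read_threshold_table
#' @param table Threshold table to write.
#' @export
write_threshold_table <- function(table, path) {
  validate_threshold_table(table)
  utils::write.csv(table[c("participant", "group", "phase", "orientation",
                           "separation", "threshold")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
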