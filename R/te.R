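#' Threshold elevation: the collinear/orthogonal log threshold ratio
#'
#' For each (participant, phase, separation) cell with both a collinear and
#' an orthogonal threshold, computes
#' \deqn{TE = \log_{10}(CT_{collinear} / CT_{orthogonal})}
#' Positive TE is collinear inhibition (the flankers raise the detection
#' threshold), negative TE is facilitation. No imputation is performed: a
#' cell missing either member of the pair is an error.
#'
#' @param table Threshold table: data frame with columns `participant`,
#'   `group`, `phase`, `orientation` (`collinear`/`orthogonal`),
#'   `separation`, `threshold` (Michelson, in (0, 1]).
#' @return Data frame with columns `participant`, `group`, `phase`,
#'   `separation`, `te` (log10 units), one row per matched pair.
#' @export
#' @examples
#' tab <- data.frame(participant = "P1", group = "control", phase = "pre",
#'                   orientation = c("collinear", "orthogonal"),
#'                   separation = 3, threshold = c(0.2, 0.1))
#' compute_te(tab)$te  # log10(2)
compute_te <- function(table) {
  validate_threshold_table(table)
  key <- c("participant", "group", "phase", "separation")
  col <- table[table$orientation == "collinear", c(key, "threshold")]
  ort <- table[table$orientation == "orthogonal", c(key, "threshold")]
  merged <- merge(col, ort, by = key, suffixes = c("_col", "_ort"),
                  all = TRUE)
  missing <- is.na(merged$threshold_col) | is.na(merged$threshold_ort)
  if (any(missing)) {
    bad <- merged[missing, key]
    stop("unpaired collinear/orthogonal cell(s): ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  out <- merged[key]
  out$te <- log10(merged$threshold_col / merged$threshold_ort)
  out <- out[order(out$participant, out$phase, out$separation), ]
  rownames(out) <- NULL
  out
}

validate_threshold_table <- function(table) {
  needed <- c("participant", "group", "phase", "orientation", "separation",
              "threshold")
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("threshold table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(table$orientation %in% c("collinear", "orthogonal")))
    stop("orientation must be 'collinear' or 'orthogonal'", call. = FALSE)
  if (any(table$threshold <= 0 | table$threshold > 1))
    stop("thresholds must be Michelson values in (0, 1]", call. = FALSE)
  key <- interaction(table$participant, table$phase, table$orientation,
                     table$separation, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (participant, phase, orientation, separation) rows",
         call. = FALSE)
  invisible(table)
}

#' Group summary of threshold-elevation values
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and count
#' of TE for one group at one separation (optionally one phase).
#'
#' @param te Output of [compute_te()].
#' @param group Group label to summarise.
#' @param separation Separation in lambda units.
#' @param phase Optional phase filter (`"pre"`/`"post"`).
#' @return List with `mean`, `sd`, `n`.
#' @export
group_te_summary <- function(te, group, separation, phase = NULL) {
  sel <- te$group == group & te$separation == separation
  if (!is.null(phase)) sel <- sel & te$phase == phase
  vals <- te$te[sel]
  if (length(vals) < 2)
    stop("fewer than 2 observations: SD undefined", call. = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}
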