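# odd-sized display so the centre falls on a pixel
small_geom <- display_geometry(width_px = 257, height_px = 257,
                               arcmin_per_pixel = 2.14,
                               mean_luminance = 47.6)

test_that("zero contrast renders a uniform field at mean luminance", {
  img <- render_gabor(0, sf = 1, orientation = 0, sigma = 0.5,
                      geometry = small_geom)
  expect_true(all(img$luminance == 47.6))
})

test_that("the Gabor equation evaluates in closed form at the envelope centre", {
  img <- render_gabor(0.5, sf = 1, orientation = 0, sigma = 0.5, phase = 0,
                      geometry = small_geom)
  ctr <- img$element_centers["target", ]
  expect_equal(img$luminance[ctr[1], ctr[2]], 47.6 * 1.5, tolerance = 1e-12)
  # one envelope sigma along the modulation axis: L = Lm (1 + c e^-1/2 cos(2 pi f x))
  px_per_deg <- 60 / 2.14
  x_deg <- round(0.5 * px_per_deg) / px_per_deg    # nearest-pixel offset
  expected <- 47.6 * (1 + 0.5 * exp(-x_deg^2 / (2 * 0.5^2)) * cos(2 * pi * x_deg))
  expect_equal(img$luminance[ctr[1], ctr[2] + round(0.5 * px_per_deg)],
               expected, tolerance = 1e-12)
})

test_that("rendered Michelson contrast equals nominal contrast within 1%", {
  for (c_nom in c(0.05, 0.217, 0.5, 1)) {
    img <- render_gabor(c_nom, sf = 1, orientation = 0, sigma = 0.5,
                        geometry = small_geom)
    expect_equal(measure_michelson(img), c_nom, tolerance = 0.01)
  }
})

test_that("triplet geometry: separation maps to rounded pixel offsets, linearly", {
  cfg3 <- stimulus_config(3, "collinear", geometry = small_geom)
  img3 <- render_triplet(cfg3)
  ctrs <- img3$element_centers
  offset3 <- ctrs["flanker_below", "row"] - ctrs["target", "row"]
  expect_identical(offset3, round(3 * 60 / 2.14))   # 84 px
  expect_identical(ctrs["target", "row"] - ctrs["flanker_above", "row"], offset3)

  geom_big <- display_geometry(1025, 1025, 2.14, 47.6)
  img6 <- render_triplet(stimulus_config(6, "collinear", geometry = geom_big))
  offset6 <- img6$element_centers["flanker_below", "row"] -
    img6$element_centers["target", "row"]
  expect_identical(offset6, round(6 * 60 / 2.14))
  expect_equal(offset6 / (6 * 60 / 2.14), offset3 / (3 * 60 / 2.14),
               tolerance = 0.02)
})

test_that("collinear flankers share the target orientation, orthogonal are rotated 90 deg", {
  col <- render_triplet(stimulus_config(3, "collinear", flanker_contrast = 0.6,
                                        geometry = small_geom))
  ort <- render_triplet(stimulus_config(3, "orthogonal", flanker_contrast = 0.6,
                                        geometry = small_geom))
  fc <- col$element_centers["flanker_above", ]
  # collinear (vertical stripes): luminance varies along columns at the
  # flanker centre row, is pure envelope along rows at the centre column
  row_prof <- col$luminance[fc[1], fc[2] + (-5:5)]
  col_prof <- col$luminance[fc[1] + (-5:5), fc[2]]
  expect_gt(max(abs(diff(sign(diff(row_prof))))), 0)   # oscillates
  expect_true(all(diff(col_prof[1:6]) > -1e-9))        # monotone envelope rise
  # orthogonal: the two axes swap roles
  row_prof_o <- ort$luminance[fc[1], fc[2] + (-5:5)]
  col_prof_o <- ort$luminance[fc[1] + (-5:5), fc[2]]
  expect_gt(max(abs(diff(sign(diff(col_prof_o))))), 0)
  expect_true(all(diff(row_prof_o[1:6]) > -1e-9))
})

test_that("vertical-axis cosine-phase triplet is left-right mirror symmetric", {
  img <- render_triplet(stimulus_config(3, "collinear", geometry = small_geom))
  expect_equal(img$luminance, img$luminance[, rev(seq_len(ncol(img$luminance)))],
               tolerance = 1e-12)
  imgo <- render_triplet(stimulus_config(4, "orthogonal", geometry = small_geom))
  expect_equal(imgo$luminance, imgo$luminance[, rev(seq_len(ncol(imgo$luminance)))],
               tolerance = 1e-12)
})

test_that("degenerate geometry is rejected with informative errors", {
  expect_error(stimulus_config(0, "collinear"), "positive")
  expect_error(stimulus_config(3, "collinear", target_contrast = 0), "0, 1")
  expect_error(stimulus_config(3, "collinear", target_contrast = 1.2), "0, 1")
  expect_error(render_gabor(0.5, sf = -1), "positive")
  expect_error(render_gabor(0.5, sf = 1, sigma = 0), "positive")
  tiny <- display_geometry(65, 65, 2.14, 47.6)
  expect_error(render_triplet(stimulus_config(8, "collinear", geometry = tiny)),
               "separation 8")
})

test_that("image export writes PNG and plain-text matrices", {
  img <- render_gabor(0.5, sf = 1, orientation = 0, sigma = 0.5,
                      geometry = display_geometry(65, 65, 2.14, 47.6))
  png_path <- tempfile(fileext = ".png")
  txt_path <- tempfile(fileext = ".txt")
  write_stimulus_png(img, png_path)
  write_stimulus_matrix(img, txt_path)
  expect_true(file.exists(png_path))
  back <- as.matrix(read.table(txt_path))
  dimnames(back) <- NULL
  expect_equal(back, img$luminance, tolerance = 1e-6)
  decoded <- png::readPNG(png_path)
  # mean luminance maps to mid-gray
  expect_equal(decoded[1, 1], 0.5, tolerance = 1 / 255)
})
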