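test_that("default grid covers the mid-IR window with 826 points", {
  g <- wn_grid()
  expect_equal(g$n_points, 826L)
  expect_equal(g$wavenumbers[1], 700)
  expect_equal(g$wavenumbers[826], 4000)
  expect_equal(unique(diff(g$wavenumbers)), 4)
  expect_error(wn_grid(4000, 700), class = "spectranet_config_error")
  expect_error(wn_grid(700, 4000, -4), class = "spectranet_config_error")
})

test_that("spectra tables reject mismatched axes and duplicate replicates", {
  g <- tiny_grid(4)
  expect_error(
    spectra_tbl("s1", 1L, "AS", matrix(1, 1, 5), g),
    class = "spectranet_axis_error"
  )
  expect_error(
    spectra_tbl(c("s1", "s1"), c(1L, 1L), c("AS", "AS"), matrix(1, 2, 4), g),
    class = "spectranet_label_error"
  )
  expect_error(
    spectra_tbl("s1", 1L, "XX", matrix(1, 1, 4), g, class_names = c("AS", "RA")),
    class = "spectranet_label_error"
  )
})

test_that("replicate averaging is the pointwise mean and is idempotent", {
  ds <- toy_dataset()
  avg <- average_replicates(ds)
  expect_equal(nrow(avg), 3L)
  # constant replicates 1, 2, 3 average to 2
  expect_equal(unname(absorbance_matrix(avg)[1, ]), rep(2, 4))
  # single replicate passes through unchanged
  expect_equal(unname(absorbance_matrix(avg)[2, ]), c(0, 2, 4, 6))
  expect_equal(as.character(avg$class_label), c("AS", "RA", "HC"))
  # idempotence
  again <- average_replicates(avg)
  expect_equal(absorbance_matrix(again), absorbance_matrix(avg))
  expect_equal(again$sample_id, avg$sample_id)
})

test_that("conflicting labels within a sample are rejected", {
  g <- tiny_grid(4)
  ds <- spectra_tbl(c("s1", "s1"), c(1L, 2L), c("AS", "RA"),
                    matrix(1, 2, 4), g, class_names = c("AS", "RA"))
  expect_error(average_replicates(ds), class = "spectranet_label_error")
})

test_that("normalisation maps spectra as documented", {
  g <- tiny_grid(3)
  ds <- spectra_tbl(c("a", "b"), c(1L, 1L), c("AS", "AS"),
                    rbind(c(0, 2, 4), c(3, 4, 0)), g)
  expect_identical(normalize_spectra(ds, "none"), ds)
  mm <- absorbance_matrix(normalize_spectra(ds, "minmax"))
  expect_equal(unname(mm[1, ]), c(0, 0.5, 1))
  vec <- absorbance_matrix(normalize_spectra(ds, "vector"))
  expect_equal(unname(vec[2, ]), c(0.6, 0.8, 0)) # 3-4-5 triangle
  flat <- spectra_tbl("c", 1L, "AS", matrix(5, 1, 3), g)
  expect_warning(out <- normalize_spectra(flat, "minmax"))
  expect_equal(unname(absorbance_matrix(out)[1, ]), c(0, 0, 0))
})

test_that("csv round trips preserve absorbance and labels", {
  ds <- generate_spectra(small_synth())
  for (fmt in c("csv_wide", "csv_long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_spectra(ds, f, fmt)
    back <- read_spectra(f, fmt, class_names = class_names(ds))
    rel <- abs(absorbance_matrix(back) - absorbance_matrix(ds)) /
      (abs(absorbance_matrix(ds)) + 1e-12)
    expect_lt(max(rel), 1e-9)
    expect_identical(as.character(back$class_label), as.character(ds$class_label))
    expect_identical(back$sample_id, ds$sample_id)
    expect_equal(spectra_grid(back)$n_points, spectra_grid(ds)$n_points)
  }
})

test_that("empty dataset round-trips through csv_wide as a header-only file", {
  g <- tiny_grid(5)
  empty <- spectra_tbl(character(0), integer(0), character(0),
                       matrix(numeric(0), 0, 5), g, class_names = "AS")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(empty, f, "csv_wide")
  expect_length(readLines(f), 1L)
  back <- read_spectra(f, "csv_wide")
  expect_equal(nrow(back), 0L)
})

test_that("csv_wide rows shorter than the declared axis are an axis error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(c("sample_id", "replicate_id", "class_label", 700 + 4 * 0:3), collapse = ","),
    "s1,1,AS,0.1,0.2,0.3" # 3 values for a 4-point axis
  ), f)
  expect_error(read_spectra(f, "csv_wide"), class = "spectranet_axis_error")
})

test_that("non-numeric absorbance is a parse error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(c("sample_id", "replicate_id", "class_label", 700 + 4 * 0:2), collapse = ","),
    "s1,1,AS,0.1,oops,0.3"
  ), f)
  expect_error(read_spectra(f, "csv_wide"), class = "spectranet_parse_error")
})

test_that("descending axes are reversed on read, never mirrored silently", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(c("sample_id", "replicate_id", "class_label", c(712, 708, 704, 700)),
          collapse = ","),
    "s1,1,AS,4,3,2,1"
  ), f)
  expect_message(ds <- read_spectra(f, "csv_wide"), "descending")
  expect_equal(spectra_grid(ds)$wavenumbers, c(700, 704, 708, 712))
  expect_equal(unname(absorbance_matrix(ds)[1, ]), c(1, 2, 3, 4))
})

test_that("jcampdx reader honours YFACTOR and NPOINTS", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=toy", "##XUNITS=1/CM", "##FIRSTX=100", "##LASTX=108",
               "##XFACTOR=1", "##YFACTOR=0.5", "##NPOINTS=5",
               "##XYDATA=(X++(Y..Y))", "100 2 4 6 8 10", "##END="), f)
  ds <- read_spectra(f, "jcampdx")
  # raw ordinate 2 times YFACTOR 0.5 = 1, and so on
  expect_equal(unname(absorbance_matrix(ds)[1, ]), c(1, 2, 3, 4, 5))
  # NPOINTS disagreement is an axis error
  writeLines(c("##TITLE=toy", "##FIRSTX=100", "##LASTX=108", "##YFACTOR=1",
               "##NPOINTS=6", "##XYDATA=(X++(Y..Y))", "100 2 4 6 8 10",
               "##END="), f)
  expect_error(read_spectra(f, "jcampdx"), class = "spectranet_axis_error")
  # unsupported data form is rejected
  writeLines(c("##TITLE=toy", "##NPOINTS=2", "##XYDATA=(XY..XY)",
               "100,1 104,2", "##END="), f)
  expect_error(read_spectra(f, "jcampdx"), class = "spectranet_parse_error")
})

test_that("jcampdx single-spectrum round trip is exact to 1e-9", {
  g <- tiny_grid(7)
  one <- spectra_tbl("s9", 1L, "OA",
                     matrix(c(0.11, 0.25, 1.5, 0.033, 1.2, 0, 0.7), 1), g,
                     class_names = c("OA"))
  f <- withr::local_tempfile(fileext = ".jdx")
  write_spectra(one, f, "jcampdx")
  back <- read_spectra(f, "jcampdx")
  expect_lt(max(abs(absorbance_matrix(back) - absorbance_matrix(one))), 1e-9)
  expect_equal(as.character(back$class_label), "OA")
  # multi-spectrum tables cannot be written to this format
  two <- generate_spectra(small_synth(n = 1L, reps = 2L))
  expect_error(write_spectra(two, f, "jcampdx"), class = "spectranet_io_error")
})

test_that("class mean spectra and envelopes are pointwise statistics", {
  g <- tiny_grid(2)
  ds <- spectra_tbl(c("a", "b", "c"), rep(1L, 3), c("AS", "AS", "RA"),
                    rbind(c(0, 0), c(2, 2), c(1, 3)), g,
                    class_names = c("AS", "RA"))
  ms <- mean_spectrum_by_class(ds)
  as_rows <- ms[ms$class_label == "AS", ]
  expect_equal(as_rows$mean, c(1, 1))
  expect_equal(as_rows$lower, c(0, 0))
  expect_equal(as_rows$upper, c(2, 2))
  ra_rows <- ms[ms$class_label == "RA", ]
  expect_equal(ra_rows$upper - ra_rows$lower, c(0, 0)) # single spectrum
  # a class declared but absent is an error naming it
  ds2 <- spectra_tbl("a", 1L, "AS", matrix(1, 1, 2), g,
                     class_names = c("AS", "RA"))
  expect_error(mean_spectrum_by_class(ds2), "RA",
               class = "spectranet_data_error")
})

test_that("4-class synthetic mean spectra have full grid length per class", {
  ds <- average_replicates(generate_spectra(small_synth()))
  ms <- mean_spectrum_by_class(ds)
  expect_equal(nrow(ms), 4L * 826L)
  expect_setequal(unique(as.character(ms$class_label)), c("AS", "RA", "OA", "HC"))
})
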