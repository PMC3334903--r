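test_that("well labels are canonical and round-trip", {
  expect_length(well_labels(), 96)
  expect_false(anyDuplicated(well_labels()) > 0)
  pw <- parse_well(well_labels())
  expect_identical(well_label(pw$row, pw$column), well_labels())
  expect_identical(parse_well("a1")$label, "A01")
  expect_error(parse_well("I01"), "invalid well")
  expect_error(parse_well("A13"), "invalid well|1..12")
  expect_error(well_label("A", 0), "1..12")
})

test_that("pm_curve validates its invariants", {
  expect_error(pm_curve(c(0, 1, 1, 2), 1:4), "strictly increasing")
  expect_error(pm_curve(0:3, c(1, 2, Inf, 4)), "finite")
  expect_error(pm_curve(0:2, 1:3, well = "Z9"), "invalid well")
  cv <- pm_curve(c(0, 1, NA, 3, 4), c(1, 2, 3, NA, 5))
  expect_length(cv$times, 3)          # pairwise NA dropping
  expect_false(cv$fittable)           # < 4 remaining points
})

test_that("plate CSV round-trips through the OmniLog dialect", {
  pl <- simulate_experiment(pm_design(strains = "s1"), seed = 11)[[1]]
  tf <- tempfile(fileext = ".csv")
  write_omnilog_csv(pl, tf)
  got <- read_omnilog_csv(tf)
  expect_length(got, 1)
  pl2 <- got[[1]]
  expect_identical(pl2$plate_id, pl$plate_id)
  expect_equal(pl2$times, pl$times)
  expect_length(pl2$curves, 96)
  expect_equal(vapply(pl2$curves, function(cv) cv$values, pl2$times * 0 + 1),
               vapply(pl$curves, function(cv) cv$values, pl$times * 0 + 1),
               tolerance = 1e-9)
})

test_that("partial plates and malformed headers are reported", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("Hour,A01,A02,A03", "0,1,2,3", "1,2,3,4", "2,3,4,5", "3,4,5,6"),
             tf)
  pl <- read_omnilog_csv(tf)[[1]]
  expect_length(pl$curves, 3)
  expect_length(pl$missing_wells, 93)

  writeLines(c("Hour,A01,XX9", "0,1,2", "1,2,3"), tf)
  expect_error(read_omnilog_csv(tf), "XX9")
  writeLines(c("Wrong,A01", "0,1", "1,2"), tf)
  expect_error(read_omnilog_csv(tf), "time column")
  writeLines(c("Hour,A01", "0,1", "2,2", "1,3", "3,4"), tf)
  expect_error(read_omnilog_csv(tf), "strictly increasing")
})

test_that("parameter tables have the fixed layout and round-trip bytewise", {
  cvs <- lapply(1:2, function(i)
    simulate_curve(shape_spec("logistic", noise_sd = 2), seed = i,
                   well = c("A01", "A02")[i]))
  fits <- lapply(cvs, pm_fit, method = "spline")
  tab <- parameter_table(fits)
  expect_identical(ncol(tab), 18L)
  expect_identical(nrow(tab), 2L)

  tf <- tempfile(); tf2 <- tempfile()
  write_parameter_table(tab, tf)
  back <- read_parameter_table(tf)
  expect_equal(back$A, tab$A, tolerance = 1e-9)
  write_parameter_table(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))

  # empty table -> header only
  tf3 <- tempfile()
  write_parameter_table(tab[0, ], tf3)
  expect_identical(length(readLines(tf3)), 1L)

  # mixed CI levels refuse to serialise
  ci1 <- bootstrap_cis(cvs[[1]], B = 5, seed = 1, level = 0.95)
  ci2 <- bootstrap_cis(cvs[[2]], B = 5, seed = 1, level = 0.90)
  expect_error(parameter_table(fits, cis = list(ci1, ci2)), "mixed CI levels")
})

test_that("control-well subtraction is available but leaves raw data default", {
  pl <- simulate_experiment(pm_design(strains = "s1"), seed = 3)[[1]]
  sub <- subtract_control(pl)
  expect_equal(sub$curves[["A01"]]$values, rep(0, length(pl$times)))
  expect_equal(sub$curves[["B05"]]$values,
               pl$curves[["B05"]]$values - pl$curves[["A01"]]$values)
  expect_error(subtract_control(pm_plate(pl$curves["B05"])), "not present")
})

test_that("artifact flagging matches a brute-force scanner", {
  # clean monotone curve
  expect_identical(nrow(flag_curve_artifacts(pm_curve(0:10, (0:10)^2))), 0L)

  # constructed spike
  y <- c(0, 2, 4, 60, 6, 8, 10)
  rep <- flag_curve_artifacts(pm_curve(0:6, y), drop_tol = 10)
  expect_true("transient-spike" %in% rep$kind)
  spike <- rep[rep$kind == "transient-spike", ]
  expect_identical(spike$from, 4L)
  expect_equal(spike$magnitude, 54)

  set.seed(42)
  for (rep_i in 1:40) {
    n <- sample(5:50, 1)
    y <- cumsum(stats::rnorm(n, 0.5, 4))
    tol <- stats::runif(1, 1, 10)
    got <- flag_curve_artifacts(pm_curve(seq_len(n), y), drop_tol = tol)
    want <- oracle_artifacts(y, tol)
    expect_identical(got$from[got$kind == "transient-spike"],
                     as.integer(want$spikes))
    gd <- got[got$kind == "non-monotone-drop", ]
    expect_identical(nrow(gd), length(want$drops))
    for (k in seq_along(want$drops)) {
      expect_identical(c(gd$from[k], gd$to[k]),
                       as.integer(want$drops[[k]][1:2]))
      expect_equal(gd$magnitude[k], want$drops[[k]][3])
    }
  }
})
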