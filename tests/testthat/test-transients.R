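test_that("write/read round trip preserves every field", {
  exp <- fixture_experiment()
  sub <- dplyr::filter(exp$transients, rcr_percent %in% c(0, 50),
                       replicate == 1L, clock_time == 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transients(sub, path)
  back <- read_transients(path)
  expect_equal(nrow(back), nrow(sub))
  expect_equal(back$time_s, sub$time_s, tolerance = 1e-12)
  expect_equal(back$fluorescence, sub$fluorescence, tolerance = 1e-12)
  expect_equal(back$plant_id, sub$plant_id)
  expect_equal(back$rcr_percent, sub$rcr_percent)
  expect_equal(back$clock_time, sub$clock_time)
})

test_that("a valid 70-point log-spaced file loads as one transient", {
  tr <- as_transient(log_grid(70), analytic_curve(log_grid(70)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transients(tr, path)
  back <- read_transients(path)
  expect_equal(nrow(back), 70)
})

test_that("validation rejects malformed curves with a named record", {
  grid <- log_grid(45)
  good <- as_transient(grid, analytic_curve(grid))

  bad <- good
  bad$time_s[10:11] <- bad$time_s[11:10]  # decreasing step
  bad <- bad[order(seq_len(nrow(bad))), ]
  expect_error(validate_transients(bad), class = "ojipr_validation_error")
  expect_error(validate_transients(bad), "non-monotone")
  expect_error(validate_transients(bad), "P1")

  late <- as_transient(log_grid(45, t_min = 1e-04),
                       analytic_curve(log_grid(45, t_min = 1e-04)))
  expect_error(validate_transients(late), "20")

  short <- as_transient(log_grid(45, t_max = 0.1),
                        analytic_curve(log_grid(45, t_max = 0.1)))
  expect_error(validate_transients(short), class = "ojipr_validation_error")

  neg <- good
  neg$fluorescence[3] <- -1
  expect_error(validate_transients(neg), "negative")

  few <- good[1:30, ]
  expect_error(validate_transients(few), "40")

  expect_error(read_transients(withr::local_tempfile()), "not found")
})

test_that("reading a file without required columns is a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(a = 1, b = 2), path)
  expect_error(read_transients(path), class = "ojipr_format_error")
})

test_that("duplicate averaging is the pointwise mean and checks grids", {
  grid <- log_grid(50)
  f <- analytic_curve(grid)
  t1 <- as_transient(grid, f, measurement_index = 1L)
  t2 <- as_transient(grid, f, measurement_index = 2L)

  # identical duplicates: output equals the input curve
  avg <- average_duplicates(dplyr::bind_rows(t1, t2))
  expect_equal(avg$fluorescence, f)
  expect_false("measurement_index" %in% names(avg))

  # linearity: mean of a and 3a is 2a
  t3 <- as_transient(grid, 3 * f, measurement_index = 2L)
  avg <- average_duplicates(dplyr::bind_rows(t1, t3))
  expect_equal(avg$fluorescence, 2 * f)

  # two generator draws against an independent pointwise computation
  exp1 <- generate_experiment(generator_config(seed = 1))
  one_leaf <- dplyr::filter(exp1$transients, plant_id == "RCR000_P1",
                            day == "2023-07-24", clock_time == 9)
  expected <- (one_leaf$fluorescence[one_leaf$measurement_index == 1] +
                 one_leaf$fluorescence[one_leaf$measurement_index == 2]) / 2
  avg <- average_duplicates(one_leaf)
  expect_equal(avg$fluorescence, expected)

  # mismatched grids: explicit error, no silent resampling
  t4 <- as_transient(grid * 1.01, f, measurement_index = 2L)
  expect_error(average_duplicates(dplyr::bind_rows(t1, t4)),
               class = "ojipr_grid_mismatch")
})

test_that("cardinal points are exact on grid-coincident samples", {
  cp <- extract_cardinal_points(worked_curve())
  expect_equal(cp$F0, 500)
  expect_equal(cp$F300, 900)
  expect_equal(cp$FJ, 1500)
  expect_equal(cp$FI, 2200)
  expect_equal(cp$Fm, 2500)
  expect_equal(cp$t_Fm, 1)
  expect_false(cp$is_flat)
})

test_that("a constant curve is flagged flat with equal cardinal points", {
  tr <- as_transient(log_grid(50), rep(1000, 50))
  cp <- extract_cardinal_points(tr)
  expect_true(cp$is_flat)
  expect_equal(cp$F0, 1000)
  expect_equal(cp$FJ, 1000)
  expect_equal(cp$FI, 1000)
  expect_equal(cp$Fm, 1000)
})

test_that("cardinal extraction matches the analytic phase model within 0.1 %", {
  grid <- log_grid(70)
  cp <- extract_cardinal_points(as_transient(grid, analytic_curve(grid)))
  marks <- c(2e-05, 3e-04, 2e-03, 3e-02)
  truth <- analytic_curve(marks)
  expect_lt(max(rel_err(c(cp$F0, cp$F300, cp$FJ, cp$FI), truth)), 0.001)
  expect_lt(rel_err(cp$Fm, analytic_curve(1)), 0.001)
})

test_that("cardinal points scale linearly with a fluorescence rescaling", {
  grid <- log_grid(60)
  f <- analytic_curve(grid)
  cp1 <- extract_cardinal_points(as_transient(grid, f))
  cp2 <- extract_cardinal_points(as_transient(grid, 3.7 * f))
  for (col in c("F0", "F300", "FJ", "FI", "Fm")) {
    expect_equal(cp2[[col]], 3.7 * cp1[[col]], tolerance = 1e-12)
  }
  expect_equal(cp2$is_flat, cp1$is_flat)
})

test_that("interpolated F300 lies between its bracketing samples", {
  for (seed in 1:20) {
    set.seed(seed)
    grid <- log_grid(41 + seed)
    f <- analytic_curve(grid) * exp(rnorm(length(grid), 0, 0.05))
    cp <- extract_cardinal_points(as_transient(grid, f))
    lo <- max(which(grid <= 3e-04)); hi <- min(which(grid >= 3e-04))
    expect_gte(cp$F300, min(f[lo], f[hi]))
    expect_lte(cp$F300, max(f[lo], f[hi]))
  }
})

test_that("a time mark outside the sampled range errors", {
  expect_error(cardinal_points(c(1e-04, 1e-02, 1), c(1, 2, 3)),
               class = "ojipr_out_of_range")
})

test_that("relative variable fluorescence is the (F-F0)/(Fm-F0) normalisation", {
  grid <- log_grid(70)
  tr <- as_transient(grid, analytic_curve(grid))
  v <- relative_variable_fluorescence(tr)
  cp <- extract_cardinal_points(tr)
  # pointwise independent recomputation
  expect_equal(v$V, (tr$fluorescence - cp$F0) / (cp$Fm - cp$F0))
  expect_equal(v$V[1], 0)
  expect_equal(max(v$V), 1)
  # V at 2 ms equals the VJ reported by the JIP engine
  jip <- compute_jip(tr)
  v2ms <- approx(log10(grid), v$V, xout = log10(2e-03))$y
  expect_equal(v2ms, jip$VJ, tolerance = 1e-10)

  # step curve: V jumps from 0 to 1
  fstep <- c(rep(500, 69), 2500)
  vs <- relative_variable_fluorescence(as_transient(grid, fstep))
  expect_equal(sort(unique(round(vs$V, 10))), c(0, 1))

  # flat curve: degenerate
  expect_error(
    relative_variable_fluorescence(as_transient(grid, rep(800, 70))),
    class = "ojipr_degenerate_curve")
})
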