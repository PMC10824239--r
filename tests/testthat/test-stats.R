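test_that("cutting angles map exactly to the printed design ratios", {
  expect_equal(angle_to_rcr(c(36, 72, 108, 180, 270)),
               c(10, 20, 30, 50, 75))
  expect_equal(angle_to_rcr(0), 0)
  expect_equal(angle_to_rcr(360), 100)
  expect_error(angle_to_rcr(-1), class = "ojipr_domain_error")
  expect_error(angle_to_rcr(400), class = "ojipr_domain_error")
})

test_that("tier mapping follows the four-level star convention", {
  p <- c(0.5, 0.05, 0.049, 0.005, 0.0049, 5e-04, 4.9e-04, 1e-04, 9e-05, 0)
  expect_equal(as.character(tier_from_p(p)),
               c("ns", "ns", "*", "*", "**", "**", "***", "***",
                 "****", "****"))
  expect_true(is.ordered(tier_from_p(p)))
})

make_groups <- function(means, n = 6, sd = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    rcr_percent = rep(as.numeric(names(means)), each = n),
    value = rnorm(n * length(means), rep(means, each = n), sd))
}

test_that("identical groups with identical values are ns everywhere", {
  d <- tibble::tibble(rcr_percent = rep(c(0, 50), each = 5),
                      value = rep(7, 10))
  cmp <- suppressWarnings(compare_to_control(d, value))
  td <- tidy(cmp)
  expect_equal(as.character(td$tier[!td$is_control]), "ns")
})

test_that("one-comparison Dunnett reduces to the pooled two-sample t-test", {
  d <- make_groups(c(`0` = 10, `50` = 11), n = 8, seed = 4)
  cmp <- tidy(compare_to_control(d, value))
  tt <- t.test(value ~ rcr_percent, data = d, var.equal = TRUE)
  expect_equal(cmp$p_adj[cmp$group == "50"], tt$p.value, tolerance = 1e-05)
  expect_equal(cmp$p_raw[cmp$group == "50"], tt$p.value, tolerance = 1e-05)
})

test_that("adjusted p-values are bracketed by raw and Bonferroni", {
  for (seed in 1:5) {
    d <- make_groups(c(`0` = 10, `10` = 10, `30` = 10.5, `50` = 12,
                       `75` = 9, `100` = 13), n = 5, seed = seed)
    td <- tidy(suppressWarnings(compare_to_control(d, value)))
    td <- dplyr::filter(td, !is_control)
    k <- nrow(td)
    expect_true(all(td$p_adj >= td$p_raw - 1e-10))
    expect_true(all(td$p_adj <= pmin(1, k * td$p_raw) + 1e-03))
  }
})

test_that("results are invariant to row permutation", {
  d <- make_groups(c(`0` = 5, `25` = 6, `50` = 8), n = 7, seed = 11)
  set.seed(2)
  cmp1 <- tidy(compare_to_control(d, value))
  cmp2 <- tidy(compare_to_control(d[sample(nrow(d)), ], value))
  expect_equal(cmp1, cmp2)
})

test_that("flagged-missing observations are excluded and counted; empty groups are not testable", {
  d <- make_groups(c(`0` = 10, `50` = 12, `75` = 14), n = 6, seed = 9)
  d$value[d$rcr_percent == 75] <- NA          # group entirely missing
  d$value[which(d$rcr_percent == 50)[1]] <- NA  # one stray missing value
  cmp <- compare_to_control(d, value)
  td <- tidy(cmp)
  expect_false(td$testable[td$group == "75"])
  expect_true(is.na(td$p_adj[td$group == "75"]))
  expect_true(td$testable[td$group == "50"])
  expect_lt(td$p_adj[td$group == "50"], 0.05)
  expect_equal(glance(cmp)$n_excluded, 7)
  expect_equal(td$n[td$group == "50"], 5)
})

test_that("strong variance heterogeneity triggers a warning", {
  set.seed(3)
  d <- tibble::tibble(
    rcr_percent = rep(c(0, 100), each = 10),
    value = c(rnorm(10, 10, 0.1), rnorm(10, 10, 3)))
  expect_warning(compare_to_control(d, value), "variance")
})

test_that("stratified comparisons are computed per stratum", {
  d <- dplyr::bind_rows(
    dplyr::mutate(make_groups(c(`0` = 10, `50` = 10), n = 6, seed = 1),
                  clock_time = 9),
    dplyr::mutate(make_groups(c(`0` = 10, `50` = 16), n = 6, seed = 2),
                  clock_time = 13))
  td <- tidy(compare_to_control(d, value, stratify_by = clock_time))
  expect_equal(sort(unique(td$stratum)), c(9, 13))
  t9 <- td$tier[td$group == "50" & td$stratum == 9]
  t13 <- td$tier[td$group == "50" & td$stratum == 13]
  expect_equal(as.character(t9), "ns")
  expect_true(t13 > "ns")
})

test_that("step intensity tables pass cardinal intensities through", {
  wc <- worked_curve()
  expect_equal(step_intensity_table(wc, "O")$intensity, 500)
  expect_equal(step_intensity_table(wc, "J")$intensity, 1500)
  expect_equal(step_intensity_table(wc, "I")$intensity, 2200)
  expect_equal(step_intensity_table(wc, "P")$intensity, 2500)
  expect_error(step_intensity_table(wc, "Q"), class = "ojipr_domain_error")

  leaves <- average_duplicates(fixture_experiment()$transients)
  tab <- step_intensity_table(leaves, "P")
  expect_equal(nrow(tab), 210)  # one row per averaged leaf measurement
  expect_true(all(c("rcr_percent", "clock_time", "intensity") %in%
                    names(tab)))
})

fake_results <- function(tiers_by_group, params = c("Fm", "Fv_over_Fm",
                                                    "PI_abs"),
                         stratum = "pooled") {
  tidyr::expand_grid(parameter = params,
                     group = names(tiers_by_group)) |>
    dplyr::mutate(
      stratum = stratum,
      tier = factor(tiers_by_group[group],
                    levels = c("ns", "*", "**", "***", "****"),
                    ordered = TRUE),
      is_control = FALSE)
}

test_that("threshold detection applies the persistence rule", {
  all_ns <- fake_results(c(`10` = "ns", `20` = "ns", `30` = "ns",
                           `50` = "ns", `75` = "ns", `100` = "ns"))
  expect_true(is.na(detect_threshold_rcr(all_ns)))

  only_100 <- fake_results(c(`10` = "ns", `20` = "ns", `30` = "ns",
                             `50` = "ns", `75` = "ns", `100` = "**"))
  expect_equal(detect_threshold_rcr(only_100), 100)

  onset_50 <- fake_results(c(`10` = "ns", `20` = "ns", `30` = "ns",
                             `50` = "*", `75` = "****", `100` = "****"))
  expect_equal(detect_threshold_rcr(onset_50), 50)

  # non-monotone: significant at 30, gap at 50 -> persistence answer 75
  gap <- fake_results(c(`10` = "ns", `20` = "ns", `30` = "**",
                        `50` = "ns", `75` = "*", `100` = "*"))
  expect_warning(thr <- detect_threshold_rcr(gap), "non-monotone")
  expect_equal(thr, 75)

  # stratified: earliest persistent change across strata wins
  strat <- dplyr::bind_rows(
    fake_results(c(`50` = "ns", `75` = "*", `100` = "*"), stratum = 17),
    fake_results(c(`50` = "*", `75` = "*", `100` = "*"), stratum = 9))
  expect_equal(detect_threshold_rcr(strat), 50)

  expect_error(detect_threshold_rcr(all_ns, params = c("Fm", "nope")),
               "nope")
})

test_that("compare_parameters binds tidy rows across parameters", {
  jip <- fixture_jip()
  res <- suppressWarnings(
    compare_parameters(jip, c("Fm", "Fv_over_Fm")))
  expect_equal(sort(unique(res$parameter)), c("Fm", "Fv_over_Fm"))
  expect_equal(nrow(res), 2 * 7)
})
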