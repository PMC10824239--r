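#' Convert a root-cutting angle to a root-cutting ratio
#'
#' The graded stress is applied by severing the root circle over a fixed
#' angle; the root cutting ratio (RCR) is that angle as a fraction of the
#' full circle, `angle/360 * 100` percent.  The experimental design uses
#' 36, 72, 108, 180 and 270 degrees (10, 20, 30, 50 and 75 %) plus full
#' removal (100 %).
#'
#' @param angle_deg Cutting angle(s) in degrees, in `[0, 360]`.
#' @return RCR in percent.
#' @export
angle_to_rcr <- function(angle_deg) {
  if (any(!is.finite(angle_deg) | angle_deg < 0 | angle_deg > 360)) {
    abort("cutting angle must lie in [0, 360] degrees",
          class = "ojipr_domain_error")
  }
  angle_deg / 360 * 100
}

#' Map p-values to significance tiers
#'
#' Four-level star convention: `ns` for p >= 0.05, `*` for p < 0.05,
#' `**` for p < 0.005, `***` for p < 0.0005, `****` for p < 0.0001.
#'
#' @param p Numeric vector of (adjusted) p-values.
#' @return An ordered factor with levels `ns < * < ** < *** < ****`.
#' @export
tier_from_p <- function(p) {
  cut(p, breaks = c(-Inf, 1e-04, 5e-04, 5e-03, 5e-02, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE) |>
    factor(levels = c("ns", "*", "**", "***", "****"), ordered = TRUE)
}

#' Compare treatment groups to a control (ANOVA + Dunnett)
#'
#' One-way ANOVA across groups followed by Dunnett's many-to-one
#' multiple-comparison procedure against the control group (two-sided,
#' single-step multivariate-t adjustment), optionally stratified, with the
#' four-tier significance convention of [tier_from_p()].  Flagged-missing
#' observations (`NA`) are excluded and counted; a group left with fewer
#' than two observations in a stratum is reported as not testable while the
#' remaining groups proceed.  A warning is emitted when the largest
#' group variance exceeds the smallest more than fourfold, since the
#' classical procedure assumes homogeneous variances.
#'
#' @param data A tibble of leaf-level values.
#' @param value Column (tidy-eval) holding the response.
#' @param group Column holding the group label (default `rcr_percent`).
#' @param control_label Label of the control group (default `0`).
#' @param stratify_by Optional column to stratify by (e.g. `clock_time`);
#'   `NULL` pools everything.
#' @param parameter Optional name recorded in the result (defaults to the
#'   value column's name).
#' @return An object of class `ojip_comparison`; see
#'   [tidy.ojip_comparison()] and [glance.ojip_comparison()].
#' @export
compare_to_control <- function(data, value, group = rcr_percent,
                               control_label = 0, stratify_by = NULL,
                               parameter = NULL) {
  val <- enquo(value); grp <- enquo(group); strat <- enquo(stratify_by)
  parameter <- parameter %||% as_name(val)
  has_strata <- !rlang::quo_is_null(strat)

  d <- tibble(
    value = dplyr::pull(data, !!val),
    group = dplyr::pull(data, !!grp),
    stratum = if (has_strata) dplyr::pull(data, !!strat) else "pooled")
  n_excluded <- sum(is.na(d$value))
  if (!control_label %in% d$group) {
    abort(sprintf("control group '%s' not present", control_label))
  }
  # group levels are fixed before flag-exclusion so all-missing groups
  # still appear in the output as not testable
  treated <- sort(unique(d$group[d$group != control_label]))
  d <- filter(d, !is.na(.data$value))
  d$group <- factor(d$group, levels = c(control_label, treated))

  res <- list(); anv <- list()
  for (s in sort(unique(d$stratum))) {
    ds <- filter(d, .data$stratum == s)
    counts <- table(ds$group)
    testable <- names(counts)[counts >= 2]
    not_testable <- setdiff(levels(d$group), testable)
    ds_t <- filter(ds, .data$group %in% testable) |>
      mutate(group = droplevels(.data$group))
    if (length(testable) < 2 || !as.character(control_label) %in% testable) {
      abort(sprintf(
        "stratum '%s': need the control and at least one treated group with >= 2 observations", s))
    }
    vars <- tapply(ds_t$value, ds_t$group, var)
    vars <- vars[!is.na(vars) & vars > 0]
    if (length(vars) > 1 && max(vars) / min(vars) > 4) {
      warn(sprintf(
        "stratum '%s', %s: group variances differ more than fourfold (ratio %.1f); Dunnett assumes homogeneous variances",
        s, parameter, max(vars) / min(vars)))
    }
    fit <- aov(value ~ group, data = ds_t)
    av <- summary(fit)[[1]]
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    p_adj <- with_fixed_rng(summary(gl)$test$pvalues)
    p_raw <- with_fixed_rng(
      summary(gl, test = multcomp::adjusted("none"))$test$pvalues)
    est <- stats::coef(gl)
    # degenerate case: zero residual variance and equal means gives 0/0
    # t statistics; a zero difference is evidence of no difference
    p_adj[is.nan(p_adj) & abs(est) < 1e-12] <- 1
    p_raw[is.nan(p_raw) & abs(est) < 1e-12] <- 1
    cmp_groups <- sub("^(.*) - .*$", "\\1", names(est))

    means <- ds |>
      group_by(.data$group) |>
      summarise(n = n(), mean = mean(.data$value),
                se = sd(.data$value) / sqrt(n()), .groups = "drop")
    row <- tibble(group = cmp_groups,
                  estimate = as.numeric(est),
                  p_raw = as.numeric(p_raw),
                  p_adj = pmin(1, as.numeric(p_adj)))
    out <- tibble(group = levels(d$group)) |>
      left_join(row, by = "group") |>
      left_join(mutate(means, group = as.character(.data$group)),
                by = "group") |>
      mutate(parameter = parameter, stratum = s,
             tier = tier_from_p(.data$p_adj),
             testable = !(.data$group %in% not_testable),
             is_control = .data$group == as.character(control_label),
             .before = 1)
    res[[length(res) + 1]] <- out
    anv[[length(anv) + 1]] <- tibble(
      parameter = parameter, stratum = s,
      df_between = av$Df[1], df_within = av$Df[2],
      anova_F = av$`F value`[1], anova_p = av$`Pr(>F)`[1],
      n_obs = nrow(ds_t), n_excluded = n_excluded)
  }
  structure(
    list(result = bind_rows(res), anova = bind_rows(anv),
         parameter = parameter, control_label = control_label,
         stratified = has_strata),
    class = "ojip_comparison")
}

#' @export
print.ojip_comparison <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one comparison vs control '%s' — %s\n",
              x$control_label, x$parameter))
  print(x$result, n = 30)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x An `ojip_comparison` object.
#' @param ... Unused.
#' @return A tibble with one row per (parameter, stratum, group): group
#'   mean, standard error, n, mean difference to control, raw and adjusted
#'   p-value, significance tier.
#' @method tidy ojip_comparison
#' @export
tidy.ojip_comparison <- function(x, ...) x$result

#' One-row-per-stratum summary of a group comparison
#'
#' @param x An `ojip_comparison` object.
#' @param ... Unused.
#' @return A tibble of ANOVA F statistics, p-values and observation counts.
#' @method glance ojip_comparison
#' @export
glance.ojip_comparison <- function(x, ...) x$anova

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method autoplot ojip_comparison
#' @export
autoplot.ojip_comparison <- function(object, ...) {
  d <- object$result |>
    mutate(group = factor(.data$group, levels = unique(.data$group)),
           label = ifelse(.data$is_control, "",
                          ifelse(is.na(.data$tier), "·",
                                 as.character(.data$tier))))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + 1.5 * .data$se,
                                    label = .data$label), vjust = -0.3) +
    ggplot2::labs(x = "group (RCR %)", y = object$parameter) +
    ggplot2::theme_minimal()
  if (object$stratified) p <- p + ggplot2::facet_wrap(~stratum)
  p
}

#' Compare several JIP parameters to the control at once
#'
#' Runs [compare_to_control()] for each named parameter column and binds
#' the tidy results; the usual input to [detect_threshold_rcr()].
#'
#' @param data A JIP parameter tibble (one row per leaf), e.g. from
#'   [compute_jip()].
#' @param params Character vector of parameter column names.
#' @inheritParams compare_to_control
#' @return A tibble of tidy comparison rows for all parameters.
#' @export
compare_parameters <- function(data, params, group = rcr_percent,
                               control_label = 0, stratify_by = NULL) {
  grp <- enquo(group); strat <- enquo(stratify_by)
  purrr::map(params, function(p) {
    tidy(compare_to_control(
      data, value = !!rlang::sym(p), group = !!grp,
      control_label = control_label, stratify_by = !!strat,
      parameter = p))
  }) |>
    bind_rows()
}

#' Per-leaf intensity of one OJIP step
#'
#' Extracts the fluorescence intensity of a named cardinal step (O, J, I or
#' P, i.e. F0, FJ, FI or Fm) for every leaf, labelled with the design
#' columns — the input for step-wise group comparisons.
#'
#' @param transients A leaf-level transient tibble.
#' @param step One of `"O"`, `"J"`, `"I"`, `"P"`.
#' @param eps_flat See [cardinal_points()].
#' @return A tibble with the design labels and an `intensity` column.
#' @export
step_intensity_table <- function(transients, step, eps_flat = 0.05) {
  col <- switch(step, O = "F0", J = "FJ", I = "FI", P = "Fm",
                abort(sprintf("unknown OJIP step '%s' (use O, J, I or P)", step),
                      class = "ojipr_domain_error"))
  extract_cardinal_points(transients, eps_flat = eps_flat) |>
    mutate(step = step, intensity = .data[[col]]) |>
    select(-all_of(c("F0", "F300", "FJ", "FI", "Fm", "t_Fm", "is_flat")))
}

#' Detect the stress-ratio threshold along the treatment gradient
#'
#' Given Dunnett comparison results for a core set of parameters across the
#' ordered RCR groups, finds the smallest RCR level at which every core
#' parameter is significant (tier `*` or beyond) both there and at every
#' larger level (persistence rule).  With stratified results (e.g. per
#' clock time) the persistence rule is applied within each stratum and the
#' smallest per-stratum threshold is returned — the earliest ratio at which
#' any measurement window shows a persistent change in the whole core set;
#' this keeps strata with strong variance heterogeneity (midday flattening)
#' or late-day recovery from masking a clear morning signal.  Returns `NA`
#' when no level qualifies anywhere.  A non-monotone significance pattern
#' (a significant level below a non-significant one) still yields the
#' persistence-rule answer but emits a warning.
#'
#' @param results A tidy comparison tibble (from [compare_parameters()] or
#'   `tidy()` of [compare_to_control()]).
#' @param params Core parameter set; default `c("Fm", "Fv_over_Fm",
#'   "PI_abs")`.
#' @return The threshold RCR in percent, or `NA_real_`.
#' @export
detect_threshold_rcr <- function(results,
                                 params = c("Fm", "Fv_over_Fm", "PI_abs")) {
  d <- results |>
    filter(.data$parameter %in% params, !.data$is_control)
  missing <- setdiff(params, unique(d$parameter))
  if (length(missing) > 0) {
    abort(paste0("no comparison results for parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  one_stratum <- function(ds) {
    sig <- ds |>
      mutate(sig = !is.na(.data$tier) & .data$tier > "ns",
             group = as.numeric(.data$group)) |>
      group_by(.data$group) |>
      summarise(all_sig = all(.data$sig), .groups = "drop") |>
      arrange(.data$group)
    persists <- rev(cumprod(rev(sig$all_sig))) > 0
    if (any(sig$all_sig & !persists)) {
      warn("non-monotone significance pattern along the RCR gradient; reporting the persistence-rule threshold")
    }
    if (!any(persists)) NA_real_ else sig$group[which(persists)[1]]
  }
  per_stratum <- d |>
    group_by(.data$stratum) |>
    dplyr::group_map(~one_stratum(.x))
  thresholds <- unlist(per_stratum)
  if (all(is.na(thresholds))) NA_real_ else min(thresholds, na.rm = TRUE)
}
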