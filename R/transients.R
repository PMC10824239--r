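#' Read OJIP transients from a long-format CSV file
#'
#' Reads a table of fast chlorophyll-a fluorescence induction curves in the
#' package's CSV dialect: one row per sampled time point, columns
#' `plant_id`, `rcr_percent`, `replicate`, `day`, `clock_time`,
#' `measurement_index`, `time_s`, `fluorescence` (UTF-8, header row, `.`
#' decimal separator).  Every curve is validated on load, see
#' [validate_transients()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per (curve, time point), ordered by curve
#'   and time.
#' @seealso [write_transients()], [extract_cardinal_points()]
#' @export
read_transients <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  spec <- readr::cols(
    plant_id = readr::col_character(),
    rcr_percent = readr::col_double(),
    replicate = readr::col_integer(),
    day = readr::col_character(),
    clock_time = readr::col_double(),
    measurement_index = readr::col_integer(),
    time_s = readr::col_double(),
    fluorescence = readr::col_double()
  )
  x <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE))
  missing <- setdiff(names(spec$cols), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ojipr_format_error")
  }
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed rows in ", path, " at line(s) ",
      paste(utils::head(probs$row, 10) + 1L, collapse = ", "),
      if (nrow(probs) > 10) " ..." else ""),
      class = "ojipr_format_error")
  }
  validate_transients(as_tibble(x))
}

#' Write OJIP transients to CSV
#'
#' Inverse of [read_transients()]; full double precision is preserved so a
#' write/read round trip reproduces the series to text-representation
#' precision.
#'
#' @param transients A transient tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transients <- function(transients, path) {
  readr::write_csv(transients, path, progress = FALSE)
  invisible(path)
}

#' Validate a table of OJIP transients
#'
#' Enforces the invariants every induction curve must satisfy before
#' analysis: strictly increasing time with the first sample at or before
#' 20 microseconds and the last at or after 0.3 s (so all cardinal marks are
#' inside the sampled range), finite non-negative fluorescence, and at least
#' 40 samples per curve.  Violations raise an error naming the offending
#' curve.
#'
#' @param transients A transient tibble (see [read_transients()] for
#'   columns).
#' @return The input, ordered by curve and time, invisibly classed as
#'   validated.
#' @export
validate_transients <- function(transients) {
  need <- c(.CURVE_KEYS, "time_s", "fluorescence")
  missing <- setdiff(need, names(transients))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ojipr_format_error")
  }
  # monotonicity is judged in file order: a curve whose samples arrive out
  # of time order is rejected, not silently re-sorted
  bad <- transients |>
    group_by(across(all_of(.CURVE_KEYS))) |>
    summarise(
      non_monotone = any(diff(.data$time_s) <= 0),
      starts_late = min(.data$time_s) > 2e-05,
      ends_early = max(.data$time_s) < 0.3,
      bad_values = any(!is.finite(.data$fluorescence) |
                         .data$fluorescence < 0),
      too_short = n() < 40,
      .groups = "drop") |>
    filter(.data$non_monotone | .data$starts_late | .data$ends_early |
             .data$bad_values | .data$too_short)
  if (nrow(bad) > 0) {
    rec <- bad[1, ]
    why <- c(
      "non-monotone time"[rec$non_monotone],
      "first sample after 20 µs"[rec$starts_late],
      "last sample before 0.3 s"[rec$ends_early],
      "non-finite or negative fluorescence"[rec$bad_values],
      "fewer than 40 samples"[rec$too_short])
    abort(sprintf(
      "invalid transient (plant %s, day %s, %s:00, measurement %s): %s%s",
      rec$plant_id, rec$day, rec$clock_time, rec$measurement_index,
      paste(why, collapse = "; "),
      if (nrow(bad) > 1) sprintf(" (and %d further curves)", nrow(bad) - 1)
      else ""),
      class = "ojipr_validation_error")
  }
  arrange(transients, across(all_of(.CURVE_KEYS)), .data$time_s)
}

#' Average duplicate measurements of each leaf
#'
#' Each leaf is measured more than once in quick succession; the recorded
#' value for a leaf is the pointwise arithmetic mean of its raw curves,
#' taken before any parameter is computed.  All measurements of one leaf
#' must share the same time grid (relative tolerance 1 ppm); nothing is
#' resampled silently.
#'
#' @param transients A transient tibble containing a `measurement_index`
#'   column.
#' @return A leaf-level transient tibble; `measurement_index` is dropped.
#' @export
average_duplicates <- function(transients) {
  transients <- transients |>
    arrange(across(all_of(.CURVE_KEYS)), .data$time_s)
  meta <- intersect(c(.META_COLS), names(transients))
  out <- transients |>
    group_by(across(all_of(setdiff(meta, "measurement_index")))) |>
    dplyr::group_modify(function(d, key) {
      curves <- split(d, d$measurement_index)
      ref <- curves[[1]]$time_s
      for (cv in curves) {
        if (length(cv$time_s) != length(ref) ||
            any(abs(cv$time_s - ref) > 1e-06 * pmax(abs(ref), 1e-300))) {
          abort(sprintf(
            "time grids of duplicate measurements differ (plant %s, day %s, %s:00)",
            key$plant_id, key$day, key$clock_time),
            class = "ojipr_grid_mismatch")
        }
      }
      tibble(
        time_s = ref,
        fluorescence = rowMeans(vapply(curves, function(cv) cv$fluorescence,
                                       numeric(length(ref)))))
    }) |>
    ungroup()
  out
}

#' Cardinal fluorescence points of one curve
#'
#' Low-level worker behind [extract_cardinal_points()]: given one sampled
#' curve, returns the fluorescence at the 20 microsecond (O), 300 microsecond,
#' 2 ms (J) and 30 ms (I) marks by interpolation linear in log10(time)
#' (exact sample values where a mark coincides with a grid point), the
#' curve maximum Fm (the P step) with its time, and the flat-curve flag
#' `is_flat`, true when the variable fluorescence Fm - F0 is below
#' `eps_flat * F0`.
#'
#' @param time_s,fluorescence Numeric vectors of one curve.
#' @param eps_flat Relative variable-fluorescence threshold below which a
#'   curve is considered flat (degenerate). Default 0.05.
#' @return A one-row tibble with columns `F0`, `F300`, `FJ`, `FI`, `Fm`,
#'   `t_Fm`, `is_flat`.
#' @export
cardinal_points <- function(time_s, fluorescence, eps_flat = 0.05) {
  marks <- interp_log_time(time_s, fluorescence, .OJIP_MARKS)
  i_max <- which.max(fluorescence)
  fm <- fluorescence[i_max]
  tibble(
    F0 = marks[[1]], F300 = marks[[2]], FJ = marks[[3]], FI = marks[[4]],
    Fm = fm, t_Fm = time_s[i_max],
    is_flat = (fm - marks[[1]]) < eps_flat * marks[[1]])
}

#' Extract cardinal points for every curve in a transient table
#'
#' @param transients A (typically leaf-level, duplicate-averaged) transient
#'   tibble.
#' @param eps_flat See [cardinal_points()].
#' @return A tibble with one row per curve: the design labels plus `F0`,
#'   `F300`, `FJ`, `FI`, `Fm`, `t_Fm`, `is_flat`.
#' @export
extract_cardinal_points <- function(transients, eps_flat = 0.05) {
  keys <- intersect(c(.META_COLS, "measurement_index"), names(transients))
  split_curves(transients, keys, function(tt, ff) {
    marks <- interp_log_time(tt, ff, .OJIP_MARKS)
    i <- which.max(ff)
    c(marks, Fm = ff[i], t_Fm = tt[i])
  }, c("F0", "F300", "FJ", "FI", "Fm", "t_Fm")) |>
    mutate(is_flat = (.data$Fm - .data$F0) < eps_flat * .data$F0)
}

# apply a scalar-vector-returning worker to every curve; returns the key
# tibble with the worker's outputs as columns (fast path shared by the
# extraction and JIP pipelines)
split_curves <- function(transients, keys, fn, out_names) {
  transients <- transients |>
    arrange(across(all_of(keys)), .data$time_s)
  g <- group_by(transients, across(all_of(keys)))
  info <- dplyr::group_data(g)
  tt <- transients$time_s
  ff <- transients$fluorescence
  vals <- vapply(info$.rows, function(ix) fn(tt[ix], ff[ix]),
                 numeric(length(out_names)))
  out <- info[setdiff(names(info), ".rows")]
  out[out_names] <- as_tibble(t(vals), .name_repair = "minimal") |>
    setNames(out_names)
  as_tibble(out)
}

#' Relative variable fluorescence V(t)
#'
#' Double normalisation of the induction curve between its O and P levels,
#' `V(t) = (F(t) - F0) / (Fm - F0)`, so that `V = 0` at the 20 microsecond
#' mark and `V = 1` at the curve maximum.  `V` at 2 ms is the JIP-test
#' parameter VJ.
#'
#' @param transients A transient tibble.
#' @param eps_flat See [cardinal_points()].
#' @return The input with an added `V` column.
#' @export
relative_variable_fluorescence <- function(transients, eps_flat = 0.05) {
  keys <- intersect(c(.META_COLS, "measurement_index"), names(transients))
  cp <- extract_cardinal_points(transients, eps_flat = eps_flat)
  if (any(cp$is_flat)) {
    abort("relative variable fluorescence is undefined for a flat curve (Fm ≈ F0)",
          class = "ojipr_degenerate_curve")
  }
  transients |>
    left_join(select(cp, all_of(keys), "F0", "Fm"), by = keys) |>
    mutate(V = (.data$fluorescence - .data$F0) / (.data$Fm - .data$F0)) |>
    select(-"F0", -"Fm")
}

#' Plot OJIP transients on a logarithmic time axis
#'
#' @param transients A transient tibble.
#' @param colour Column (tidy-eval) used for the colour aesthetic; defaults
#'   to the root-cutting-ratio group.
#' @return A ggplot object.
#' @export
plot_transients <- function(transients, colour = rcr_percent) {
  col <- enquo(colour)
  keys <- intersect(c(.CURVE_KEYS), names(transients))
  transients |>
    mutate(.curve = interaction(!!!rlang::syms(keys), drop = TRUE)) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$time_s, y = .data$fluorescence,
      group = .data$.curve, colour = factor(!!col))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "fluorescence (counts)",
                  colour = as_name(col)) +
    ggplot2::theme_minimal()
}
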