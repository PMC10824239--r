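#' Per-group phenomenological energy pipeline models
#'
#' Summarises the membrane-level (per excited cross-section, CS0 = O-step)
#' energy fluxes of each treatment group into the classic pipeline diagram
#' quantities: group means of absorption (`ABS_per_CS0`), trapping
#' (`TR0_per_CS0`), electron transport (`ET0_per_CS0`) and dissipation
#' (`DI0_per_CS0`), plus the active reaction-centre fraction — the group's
#' mean `RC_per_CS0` referenced to the control group's and clipped to
#' `[0, 1]` — discretised into `n_circles` display circles (open = active,
#' filled = inactive).  Aggregation is the arithmetic mean over non-flagged
#' leaf-level records, pooling replicates, days and clock times unless the
#' input was filtered beforehand; parameters are averaged, never curves.
#'
#' @param jip A JIP parameter tibble ([compute_jip()] output or the
#'   generator's truth table).
#' @param control_label Label of the control group (default `0`).
#' @param n_circles Number of reaction-centre display circles (default 12).
#' @param group Column (tidy-eval) holding the group label.
#' @return A tibble of class `ojip_pipeline`, one row per group, with
#'   columns `group`, `n`, the four flux means, `rc_per_cs0`,
#'   `rc_active_fraction`, `n_circles_total`, `n_circles_active`, and
#'   `available` (FALSE when every record of a group was flagged).
#' @export
build_pipeline_models <- function(jip, control_label = 0, n_circles = 12,
                                  group = rcr_percent) {
  if (n_circles < 1) abort("n_circles must be >= 1")
  grp <- enquo(group)
  d <- jip |>
    mutate(.group = dplyr::pull(jip, !!grp)) |>
    filter(!.data$flat, !.data$vj_degenerate,
           !is.na(.data$ABS_per_CS0), !is.na(.data$RC_per_CS0))
  if (!control_label %in% d$.group) {
    abort(sprintf(
      "control group '%s' has no usable (non-flagged) records", control_label))
  }
  all_groups <- sort(unique(dplyr::pull(jip, !!grp)))
  means <- d |>
    group_by(group = .data$.group) |>
    summarise(n = n(),
              abs_cs0 = mean(.data$ABS_per_CS0),
              tr0_cs0 = mean(.data$TR0_per_CS0),
              et0_cs0 = mean(.data$ET0_per_CS0),
              di0_cs0 = mean(.data$DI0_per_CS0),
              rc_per_cs0 = mean(.data$RC_per_CS0),
              .groups = "drop")
  rc_control <- means$rc_per_cs0[means$group == control_label]
  out <- tibble(group = all_groups) |>
    left_join(means, by = "group") |>
    mutate(
      available = !is.na(.data$abs_cs0),
      n = ifelse(is.na(.data$n), 0L, .data$n),
      rc_active_fraction = pmin(1, pmax(0, .data$rc_per_cs0 / rc_control)),
      n_circles_total = as.integer(n_circles),
      n_circles_active = as.integer(round_half_up(
        .data$rc_active_fraction * n_circles)))
  structure(out, class = c("ojip_pipeline", class(out)),
            control_label = control_label)
}

#' @method tidy ojip_pipeline
#' @export
tidy.ojip_pipeline <- function(x, ...) as_tibble(x)

#' @method autoplot ojip_pipeline
#' @export
autoplot.ojip_pipeline <- function(object, ...) {
  d <- as_tibble(object) |>
    filter(.data$available) |>
    tidyr::pivot_longer(all_of(c("abs_cs0", "tr0_cs0", "et0_cs0",
                                 "di0_cs0")),
                        names_to = "flux", values_to = "value") |>
    mutate(flux = factor(.data$flux,
                         levels = c("abs_cs0", "tr0_cs0", "et0_cs0",
                                    "di0_cs0"),
                         labels = c("ABS/CS0", "TR0/CS0", "ET0/CS0",
                                    "DI0/CS0")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flux, y = .data$value,
                                  fill = .data$flux)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~group, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "flux per CS0 (counts)") +
    ggplot2::theme_minimal()
}

# fixed-format number for byte-stable SVG output
svg_num <- function(x) sprintf("%.4f", x)

render_one_panel <- function(m, x0, y0, w, h, max_flux) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add('<text x="%s" y="%s" font-size="14" font-family="sans-serif">RCR %s%%</text>',
      svg_num(x0 + w / 2 - 30), svg_num(y0 + 16), format(m$group))
  if (!m$available) {
    add('<text x="%s" y="%s" font-size="12" font-family="sans-serif" fill="red">fluxes unavailable (all records flagged)</text>',
        svg_num(x0 + 10), svg_num(y0 + h / 2))
    return(lines)
  }
  fluxes <- c(ABS = m$abs_cs0, TR0 = m$tr0_cs0, ET0 = m$et0_cs0,
              DI0 = m$di0_cs0)
  max_width <- 40
  y_arrow <- y0 + 40
  xs <- x0 + 10 + (seq_along(fluxes) - 1) * (w - 20) / length(fluxes)
  for (i in seq_along(fluxes)) {
    wd <- max_width * fluxes[i] / max_flux
    # arrow = shaft rect (height encodes flux width) + triangular head
    add('<rect class="arrow-%s" x="%s" y="%s" width="%s" height="%s" fill="steelblue"/>',
        tolower(names(fluxes)[i]), svg_num(xs[i]),
        svg_num(y_arrow - wd / 2), svg_num(40), svg_num(wd))
    add('<polygon points="%s,%s %s,%s %s,%s" fill="steelblue"/>',
        svg_num(xs[i] + 40), svg_num(y_arrow - wd / 2 - 4),
        svg_num(xs[i] + 48), svg_num(y_arrow),
        svg_num(xs[i] + 40), svg_num(y_arrow + wd / 2 + 4))
    add('<text x="%s" y="%s" font-size="10" font-family="sans-serif">%s %s</text>',
        svg_num(xs[i]), svg_num(y_arrow + max_width / 2 + 18),
        names(fluxes)[i], svg_num(fluxes[i]))
  }
  # reaction-centre circles: open = active, filled = inactive
  y_circ <- y0 + h - 22
  r <- 6
  for (j in seq_len(m$n_circles_total)) {
    cx <- x0 + 10 + r + (j - 1) * (2.2 * r)
    filled <- j > m$n_circles_active
    add('<circle cx="%s" cy="%s" r="%s" stroke="black" fill="%s"/>',
        svg_num(cx), svg_num(y_circ), svg_num(r),
        if (filled) "black" else "white")
  }
  lines
}

#' Render energy pipeline models as an SVG figure
#'
#' Writes a deterministic vector figure (plain-text SVG; identical models
#' give byte-identical files): one panel per group, arrows whose widths are
#' proportional to the four per-CS0 fluxes normalised by the control
#' group's ABS/CS0 (the control ABS arrow has the configured maximum
#' width), and a row of open/filled circles for active/inactive reaction
#' centres.  Groups whose fluxes are unavailable get a placeholder panel
#' with a warning annotation.
#'
#' @param models An `ojip_pipeline` tibble from [build_pipeline_models()].
#' @param out Output file path (`.svg`).
#' @return `out`, invisibly.
#' @export
render_pipeline <- function(models, out) {
  control_label <- attr(models, "control_label")
  ctl <- models[models$group == control_label, ]
  max_flux <- ctl$abs_cs0
  if (!isTRUE(ctl$available) || !is.finite(max_flux)) {
    warn("control fluxes unavailable; normalising by the largest available flux")
    max_flux <- max(models$abs_cs0, na.rm = TRUE)
  }
  panel_w <- 260; panel_h <- 140; ncol <- 2
  nrow_p <- ceiling(nrow(models) / ncol)
  width <- ncol * panel_w; height <- nrow_p * panel_h
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height))
  for (i in seq_len(nrow(models))) {
    x0 <- ((i - 1) %% ncol) * panel_w
    y0 <- ((i - 1) %/% ncol) * panel_h
    lines <- c(lines, render_one_panel(models[i, ], x0, y0,
                                       panel_w, panel_h, max_flux))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, out, useBytes = TRUE)
  invisible(out)
}
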