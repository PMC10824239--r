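#' JIP-test parameters from cardinal fluorescence points
#'
#' Vectorised evaluation of the JIP-test parameter system from the cardinal
#' points of a dark-adapted induction curve:
#' \describe{
#'   \item{basic}{`Fv = Fm - F0`, `Fv_over_Fm = Fv/Fm` (maximum quantum
#'     yield of primary PSII photochemistry, phi_P0), `Fv_over_F0`}
#'   \item{kinetic}{`VJ = (FJ - F0)/(Fm - F0)` (relative variable
#'     fluorescence at 2 ms), `M0 = 4 (F300 - F0)/(Fm - F0)` (approximated
#'     initial slope of the relative rise)}
#'   \item{specific fluxes, per active reaction centre}{`TR0_per_RC =
#'     M0/VJ`, `ET0_per_RC = (M0/VJ)(1 - VJ)`, `ABS_per_RC =
#'     (M0/VJ)/(1 - F0/Fm)`, `DI0_per_RC = ABS_per_RC - TR0_per_RC`}
#'   \item{yields}{`TR0_per_ABS = 1 - F0/Fm`, `ET0_per_TR0 = 1 - VJ`
#'     (psi_0), `ET0_per_ABS` = their product}
#'   \item{performance index}{`PI_abs = (RC/ABS) * [phi_P0/(1 - phi_P0)] *
#'     [psi_0/(1 - psi_0)]` with `RC/ABS = 1/ABS_per_RC`}
#'   \item{phenomenological fluxes, per excited cross-section at the O
#'     step}{`ABS_per_CS0 = F0`, `TR0_per_CS0 = phi_P0 * F0`,
#'     `ET0_per_CS0 = phi_E0 * F0`, `DI0_per_CS0 = F0 - TR0_per_CS0`;
#'     reaction-centre densities `RC_per_CS0 = F0/ABS_per_RC`,
#'     `RC_per_CSm = Fm/ABS_per_RC`}
#' }
#'
#' Degenerate inputs are flagged, never propagated as infinities: a flat
#' curve (`Fm - F0 < eps_flat * F0`) keeps only `F0`, `Fm`, `Fv` and flags
#' everything else missing; a curve whose J step carries no usable kinetic
#' signal (`VJ <= 0`, `VJ >= 1`, or `M0 <= 0`, which arises on noisy
#' near-flat curves) keeps the basic and yield quantities but flags the
#' per-RC fluxes, and `PI_abs` is undefined whenever `psi_0` is 0 or 1.
#' In the limit `VJ = 1` the finite values `TR0_per_RC = M0`,
#' `ET0_per_RC = 0` are reported.
#'
#' @param F0,F300,FJ,FI,Fm Numeric vectors of cardinal fluorescence values
#'   (counts): at 20 us, 300 us, 2 ms, 30 ms, and the curve maximum.
#' @param Sm Optional normalized complementary area (ms), carried through;
#'   see [compute_sm()].
#' @param eps_flat Flat-curve threshold, see [cardinal_points()].
#' @return A tibble with one row per input curve holding all parameters
#'   plus logical flags `flat` and `vj_degenerate`.
#' @export
jip_parameters <- function(F0, F300, FJ, FI, Fm, Sm = NA_real_,
                           eps_flat = 0.05) {
  fv <- Fm - F0
  flat <- fv < eps_flat * F0
  vj <- (FJ - F0) / fv
  m0 <- 4 * (F300 - F0) / fv
  vj_degenerate <- !flat & (vj <= 0 | vj >= 1 | m0 <= 0)
  phi_p0 <- fv / Fm
  psi_0 <- 1 - vj
  phi_e0 <- phi_p0 * psi_0

  tr0_rc <- ifelse(vj >= 1, m0, m0 / vj)
  et0_rc <- ifelse(vj >= 1, 0, tr0_rc * (1 - vj))
  abs_rc <- tr0_rc / phi_p0
  di0_rc <- abs_rc - tr0_rc
  pi_abs <- (1 / abs_rc) * (phi_p0 / (1 - phi_p0)) * (psi_0 / (1 - psi_0))
  pi_abs[psi_0 <= 0 | psi_0 >= 1 | phi_p0 >= 1] <- NA_real_

  out <- tibble(
    F0 = F0, Fm = Fm, Fv = fv,
    Fv_over_Fm = phi_p0, Fv_over_F0 = fv / F0,
    VJ = vj, M0 = m0, Sm = Sm,
    TR0_per_RC = tr0_rc, ET0_per_RC = et0_rc,
    ABS_per_RC = abs_rc, DI0_per_RC = di0_rc,
    TR0_per_ABS = phi_p0, ET0_per_TR0 = psi_0, ET0_per_ABS = phi_e0,
    PI_abs = pi_abs,
    ABS_per_CS0 = F0,
    TR0_per_CS0 = phi_p0 * F0,
    ET0_per_CS0 = phi_e0 * F0,
    DI0_per_CS0 = F0 - phi_p0 * F0,
    RC_per_CS0 = F0 / abs_rc,
    RC_per_CSm = Fm / abs_rc,
    flat = flat, vj_degenerate = vj_degenerate)

  # per-RC fluxes need a usable J-step signal
  rc_cols <- c("TR0_per_RC", "ET0_per_RC", "ABS_per_RC", "DI0_per_RC",
               "PI_abs", "RC_per_CS0", "RC_per_CSm")
  out[out$vj_degenerate & out$VJ < 1, rc_cols] <- NA_real_
  # a flat curve carries no kinetic information at all
  ratio_cols <- setdiff(names(out), c("F0", "Fm", "Fv", "flat",
                                      "vj_degenerate", "ABS_per_CS0"))
  out[out$flat, ratio_cols] <- NA_real_
  out
}

#' Normalized total complementary area above the induction curve
#'
#' `Sm = integral from the 20 us mark to t(Fm) of (Fm - F(t)) dt / (Fm - F0)`,
#' a proxy for the size of the electron-acceptor pool that must be filled
#' before fluorescence reaches its maximum.  The integral is evaluated with
#' the trapezoidal rule on the sampled grid in linear time (the 20 us
#' endpoint is interpolated in log-time when it is not a grid point) and
#' reported in milliseconds, the field's customary unit: for a
#' single-exponential rise with time constant tau, Sm equals tau.
#'
#' @param time_s,fluorescence One sampled curve.
#' @param eps_flat Flat-curve threshold; for a flat curve the normalisation
#'   is ill-posed and an error is raised.
#' @return Sm in milliseconds (scalar).
#' @export
compute_sm <- function(time_s, fluorescence, eps_flat = 0.05) {
  t0 <- .OJIP_MARKS[["F0"]]
  f0 <- interp_log_time(time_s, fluorescence, t0)
  i_max <- which.max(fluorescence)
  fm <- fluorescence[i_max]
  if ((fm - f0) < eps_flat * f0) {
    abort("Sm is undefined for a flat curve (Fm ≈ F0)",
          class = "ojipr_degenerate_curve")
  }
  keep <- time_s > t0 & time_s <= time_s[i_max]
  tt <- c(t0, time_s[keep])
  ff <- c(f0, fluorescence[keep])
  area <- sum(diff(tt) * (2 * fm - ff[-1] - ff[-length(ff)])) / 2
  1000 * area / (fm - f0)
}

#' Compute the full JIP-test parameter record for every curve
#'
#' Convenience pipeline: cardinal-point extraction, complementary-area
#' integration and [jip_parameters()] for each curve of a (leaf-level)
#' transient table.
#'
#' @param transients A transient tibble, normally after
#'   [average_duplicates()].
#' @param eps_flat Flat-curve threshold, see [cardinal_points()].
#' @return A tibble with one row per curve: design labels, cardinal points,
#'   and every JIP parameter with its flags.
#' @export
compute_jip <- function(transients, eps_flat = 0.05) {
  keys <- intersect(c(.META_COLS, "measurement_index"), names(transients))
  cp <- split_curves(transients, keys, function(tt, ff) {
    marks <- interp_log_time(tt, ff, .OJIP_MARKS)
    i <- which.max(ff)
    flat <- (ff[i] - marks[[1]]) < eps_flat * marks[[1]]
    sm <- if (flat) NA_real_ else compute_sm(tt, ff, eps_flat = eps_flat)
    c(marks, Fm = ff[i], t_Fm = tt[i], Sm = sm)
  }, c("F0", "F300", "FJ", "FI", "Fm", "t_Fm", "Sm"))
  dplyr::bind_cols(
    select(cp, -all_of(c("F0", "Fm", "Sm"))),
    jip_parameters(cp$F0, cp$F300, cp$FJ, cp$FI, cp$Fm, Sm = cp$Sm,
                   eps_flat = eps_flat))
}

#' Write a JIP parameter table to TSV
#'
#' One row per leaf-level curve, tab-separated, `NA` for flagged-missing
#' values.
#'
#' @param jip A tibble from [compute_jip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jip <- function(jip, path) {
  readr::write_tsv(jip, path, na = "NA", progress = FALSE)
  invisible(path)
}
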