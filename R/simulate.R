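#' Configuration of the synthetic OJIP experiment generator
#'
#' Builds the full configuration for [generate_experiment()].  The
#' generator emulates a graded root-cutting stress experiment on
#' dark-adapted leaves: 7 root-cutting-ratio (RCR) groups (control plus
#' 10/20/30/50/75/100 %), 3 replicate plants per group, curves recorded at
#' five clock times (9:00 to 17:00) on two days, each leaf measured twice.
#'
#' Each noise-free curve follows a logistic-mixture rise in log time,
#' `F(t) = F0_base * (1 + A * S(t))` with
#' `S(t) = sum_k w_k * [s((log10 t - log10 tau_k)/sigma_k) - s_k(20 us)]`,
#' `s` the standard logistic, and one component per OJIP phase
#' (O-J, J-I, I-P; `tau` of 0.4, 8 and 80 ms).  Anchoring each component at
#' the 20 microsecond mark makes `F(20 us) = F0_base` exactly, so stress
#' acting on the amplitude `A` never moves F0 — mirroring the observation
#' that the O step is far more stable than the J/I/P steps.  The control
#' amplitude is solved so that dark-adapted Fv/Fm hits `fvfm_target`.
#'
#' Stress phenomenology (all multiplicative on `A`):
#' \itemize{
#'   \item amplitude depression `d(r)` per RCR group (zero below the
#'     configured onset, strong at 50 % and above);
#'   \item diurnal modulation with a midday minimum;
#'   \item near-complete flattening of midday curves for the 75 and 100 %
#'     groups (and partial flattening at 50 %), the "almost horizontal"
#'     curve regime;
#'   \item a late-afternoon (17:00) recovery factor shrinking the
#'     depression for the 50 and 75 % groups but not for 100 %;
#'   \item at 100 % RCR the O-J weight is inflated, raising VJ.
#' }
#' Noise: per-point multiplicative lognormal (`sigma_noise`), plus small
#' lognormal per-plant and per-day amplitude effects.  All randomness is
#' driven by `seed` through per-curve substreams hashed from the design
#' labels, so subsetting the design leaves individual curves unchanged.
#'
#' @param seed Integer root seed.
#' @param ... Named overrides of any default listed below (unknown names
#'   are an error).
#' @return A list of class `ojip_generator_config`.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # experimental design
    groups = c(0, 10, 20, 30, 50, 75, 100),
    cutting_angles = c(NA, 36, 72, 108, 180, 270, NA),
    replicates = 3L,
    clock_times = c(9, 11, 13, 15, 17),
    days = c("2023-07-24", "2023-07-31"),
    n_measurements = 2L,
    # sampling grid
    n_points = 70L, t_min = 2e-05, t_max = 1,
    # phase model
    f0_base = 500, fvfm_target = 0.82,
    tau = c(oj = 4e-04, ji = 8e-03, ip = 8e-02),
    sigma_log = c(oj = 0.22, ji = 0.25, ip = 0.25),
    weights = c(oj = 0.5, ji = 0.3, ip = 0.2),
    # stress response
    depression = c(`0` = 0, `10` = 0, `20` = 0, `30` = 0,
                   `50` = 0.25, `75` = 0.45, `100` = 0.65),
    w_oj_inflated = 0.7,
    diurnal = c(`9` = 1, `11` = 0.98, `13` = 0.94, `15` = 0.96, `17` = 1),
    flatten = list(`50` = list(clocks = c(13, 15), mult = 0.6),
                   `75` = list(clocks = c(13, 15), mult = 0.008),
                   `100` = list(clocks = c(13, 15, 17), mult = 0.008)),
    recovery_17 = c(`50` = 0.2, `75` = 0.6, `100` = 1),
    # noise
    sigma_noise = 0.03, sigma_plant = 0.01, sigma_day = 0.01)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown generator option(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ojipr_config_error")
  }
  cfg <- modifyList(cfg, dots)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  w <- cfg$weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-08) {
    abort("phase weights must be non-negative and sum to 1",
          class = "ojipr_config_error")
  }
  if (any(diff(cfg$tau) <= 0)) {
    abort("phase time constants must be strictly ordered tau_OJ < tau_JI < tau_IP",
          class = "ojipr_config_error")
  }
  if (cfg$t_min > 2e-05 || cfg$t_max < 0.3 || cfg$n_points < 40) {
    abort("sampling grid must span [<=20 us, >=0.3 s] with at least 40 points",
          class = "ojipr_config_error")
  }
  if (!0 %in% cfg$groups) {
    abort("the design needs a control group (RCR 0)",
          class = "ojipr_config_error")
  }
  structure(cfg, class = "ojip_generator_config")
}

logistic <- function(x) 1 / (1 + exp(-x))

# anchored logistic-mixture shape S(t) in [0, ~1); weights may be the
# VJ-inflated variant used at 100 % RCR
phase_shape <- function(t, cfg, weights = cfg$weights) {
  anchor <- 2e-05
  s <- 0
  for (k in seq_along(cfg$tau)) {
    s <- s + weights[k] *
      (logistic((log10(t) - log10(cfg$tau[k])) / cfg$sigma_log[k]) -
         logistic((log10(anchor) - log10(cfg$tau[k])) / cfg$sigma_log[k]))
  }
  unname(s)
}

inflated_weights <- function(cfg) {
  w <- cfg$weights
  rest <- 1 - cfg$w_oj_inflated
  c(cfg$w_oj_inflated, w[-1] * rest / sum(w[-1]))
}

# control amplitude solving Fv/Fm = target:  v = A*Smax/(1 + A*Smax)
control_amplitude <- function(cfg) {
  smax <- phase_shape(cfg$t_max, cfg)
  v <- cfg$fvfm_target
  v / ((1 - v) * smax)
}

# deterministic amplitude multiplier for one (group, clock): depression,
# diurnal cycle, midday flattening, 17:00 recovery
amplitude_factor <- function(group, clock, cfg) {
  g <- as.character(group)
  d <- unname(cfg$depression[g])
  if (is.na(d)) d <- 0
  if (clock == 17 && g %in% names(cfg$recovery_17)) {
    d <- d * unname(cfg$recovery_17[g])
  }
  f <- 1
  fl <- cfg$flatten[[g]]
  if (!is.null(fl) && clock %in% fl$clocks) f <- fl$mult
  list(factor = (1 - d) * unname(cfg$diurnal[as.character(clock)]) * f,
       effect_depression = d, effect_flat = 1 - f)
}

time_grid <- function(cfg) {
  10^seq(log10(cfg$t_min), log10(cfg$t_max), length.out = cfg$n_points)
}

# noise-free cardinal points and JIP parameters for one (group, clock)
truth_record <- function(group, clock, cfg, a0) {
  af <- amplitude_factor(group, clock, cfg)
  w <- if (group == 100) inflated_weights(cfg) else cfg$weights
  a <- a0 * af$factor
  marks <- c(.OJIP_MARKS, Fm = cfg$t_max)
  f <- setNames(cfg$f0_base * (1 + a * phase_shape(marks, cfg, weights = w)),
                names(marks))
  flat <- (f[["Fm"]] - f[["F0"]]) < 0.05 * f[["F0"]]
  sm <- NA_real_
  if (!flat) {
    tt <- 10^seq(log10(cfg$t_min), log10(cfg$t_max), length.out = 3000)
    sm <- compute_sm(tt, cfg$f0_base * (1 + a * phase_shape(tt, cfg, weights = w)))
  }
  dplyr::bind_cols(
    tibble(effect_depression = af$effect_depression,
           effect_flat = af$effect_flat),
    jip_parameters(f[["F0"]], f[["F300"]], f[["FJ"]], f[["FI"]], f[["Fm"]],
                   Sm = sm))
}

#' Generate a full synthetic root-cutting experiment
#'
#' Produces the complete measured data set of the emulated design — every
#' RCR group, replicate plant, clock time, day and duplicate measurement
#' (7 x 3 x 5 x 2 x 2 = 420 curves at the defaults) — together with the
#' noise-free ground truth per leaf.
#'
#' @param cfg A configuration from [generator_config()].
#' @return A list of class `ojip_experiment` with elements
#'   \describe{
#'     \item{transients}{long tibble of sampled curves, the
#'       [read_transients()] dialect}
#'     \item{truth}{one row per leaf: design labels, the stress effects
#'       actually applied (`effect_depression`, `effect_flat`), and the
#'       noise-free cardinal points and JIP parameters}
#'     \item{config}{the configuration used}
#'   }
#' @export
generate_experiment <- function(cfg = generator_config()) {
  cfg <- validate_generator_config(cfg)
  a0 <- control_amplitude(cfg)
  grid <- time_grid(cfg)
  shape_normal <- phase_shape(grid, cfg)
  shape_inflated <- phase_shape(grid, cfg, weights = inflated_weights(cfg))

  design <- tidyr::expand_grid(
    rcr_percent = cfg$groups,
    replicate = seq_len(cfg$replicates),
    day = cfg$days,
    clock_time = cfg$clock_times,
    measurement_index = seq_len(cfg$n_measurements)) |>
    mutate(plant_id = sprintf("RCR%03d_P%d", .data$rcr_percent,
                              .data$replicate))

  n <- cfg$n_points
  curves <- purrr::pmap(design, function(rcr_percent, replicate, day,
                                         clock_time, measurement_index,
                                         plant_id) {
    af <- amplitude_factor(rcr_percent, clock_time, cfg)
    set.seed(label_seed(c("plant", plant_id), cfg$seed))
    z_plant <- rnorm(1)
    set.seed(label_seed(c("day", day), cfg$seed))
    z_day <- rnorm(1)
    a <- a0 * af$factor *
      exp(cfg$sigma_plant * z_plant + cfg$sigma_day * z_day)
    shape <- if (rcr_percent == 100) shape_inflated else shape_normal
    set.seed(label_seed(c(plant_id, day, clock_time, measurement_index),
                        cfg$seed))
    noise <- exp(rnorm(n, 0, cfg$sigma_noise))
    cfg$f0_base * (1 + a * shape) * noise
  })

  transients <- design[rep(seq_len(nrow(design)), each = n), ] |>
    mutate(time_s = rep(grid, times = nrow(design)),
           fluorescence = unlist(curves)) |>
    select(all_of(c("plant_id", "rcr_percent", "replicate", "day",
                    "clock_time", "measurement_index", "time_s",
                    "fluorescence")))

  truth <- design |>
    distinct(.data$rcr_percent, .data$clock_time) |>
    mutate(rec = purrr::map2(.data$rcr_percent, .data$clock_time,
                             truth_record, cfg = cfg, a0 = a0)) |>
    tidyr::unnest("rec")
  truth <- design |>
    distinct(across(all_of(c("plant_id", "rcr_percent", "replicate",
                             "day", "clock_time")))) |>
    left_join(truth, by = c("rcr_percent", "clock_time"))

  structure(list(transients = transients, truth = truth, config = cfg),
            class = "ojip_experiment")
}

#' Generate a null experiment (no stress effects)
#'
#' Same design labels and noise model as [generate_experiment()] but with
#' every stress effect switched off: no amplitude depression, no midday
#' flattening, no VJ inflation.  All groups are draws from the control
#' distribution — the calibration input for the Dunnett machinery.
#'
#' @inheritParams generate_experiment
#' @return As [generate_experiment()]; the truth table's effect columns are
#'   all zero.
#' @export
generate_null_experiment <- function(cfg = generator_config()) {
  cfg <- validate_generator_config(cfg)
  cfg$depression[] <- 0
  cfg$flatten <- list()
  cfg$recovery_17[] <- 1
  cfg$w_oj_inflated <- cfg$weights[[1]]
  generate_experiment(cfg)
}

#' @export
print.ojip_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic OJIP experiment: %d curves (%d leaves), %d groups, seed %d\n",
    nrow(dplyr::distinct(x$transients,
                         across(all_of(.CURVE_KEYS)))),
    nrow(x$truth), length(x$config$groups), x$config$seed))
  invisible(x)
}
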