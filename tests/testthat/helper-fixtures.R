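# Shared fixtures, built in code at test time.

# the hand-checked cardinal-point example used throughout:
# F0 = 500, F300 = 900, FJ = 1500, FI = 2200, Fm = 2500
worked_curve <- function() {
  tibble::tibble(
    plant_id = "P1", rcr_percent = 0, replicate = 1L, day = "d1",
    clock_time = 9, measurement_index = 1L,
    time_s = c(2e-05, 3e-04, 2e-03, 3e-02, 1),
    fluorescence = c(500, 900, 1500, 2200, 2500))
}

# analytic logistic-mixture rise in log time (the generator's phase model,
# written out independently so it can serve as a closed-form oracle)
analytic_curve <- function(t, f0 = 500, a = 4.5,
                           tau = c(4e-04, 8e-03, 8e-02),
                           sig = c(0.22, 0.25, 0.25),
                           w = c(0.5, 0.3, 0.2)) {
  s <- function(x) 1 / (1 + exp(-x))
  shape <- Reduce(`+`, lapply(seq_along(tau), function(k) {
    w[k] * (s((log10(t) - log10(tau[k])) / sig[k]) -
              s((log10(2e-05) - log10(tau[k])) / sig[k]))
  }))
  f0 * (1 + a * shape)
}

# wrap a bare (time, fluorescence) series in the transient-table dialect
as_transient <- function(time_s, fluorescence, plant_id = "P1",
                         rcr_percent = 0, replicate = 1L, day = "d1",
                         clock_time = 9, measurement_index = 1L) {
  tibble::tibble(plant_id = plant_id, rcr_percent = rcr_percent,
                 replicate = replicate, day = day, clock_time = clock_time,
                 measurement_index = measurement_index,
                 time_s = time_s, fluorescence = fluorescence)
}

log_grid <- function(n = 70, t_min = 2e-05, t_max = 1) {
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

# one default synthetic experiment, generated once per test run
fixture_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_experiment(generator_config(seed = 42))
    cache
  }
})

fixture_jip <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- compute_jip(average_duplicates(fixture_experiment()$transients))
    }
    cache
  }
})

# random valid cardinal-point sets: F0 < F300 < FJ < FI < Fm with
# non-degenerate VJ
random_cardinal_points <- function(n, seed = 1) {
  set.seed(seed)
  F0 <- runif(n, 200, 1000)
  Fm <- F0 * (1 + runif(n, 0.5, 6))
  VJ <- runif(n, 0.05, 0.95)
  FJ <- F0 + VJ * (Fm - F0)
  F300 <- F0 + runif(n, 0.05, 0.95) * (FJ - F0)
  FI <- FJ + runif(n) * (Fm - FJ)
  tibble::tibble(F0 = F0, F300 = F300, FJ = FJ, FI = FI, Fm = Fm)
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
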