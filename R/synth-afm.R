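#' Synthetic AFM force-curve specification
#'
#' Emulates a parallel-plate compression experiment: near-zero baseline
#' before contact, a force peak at cell compression, exponential
#' relaxation to a plateau, and an optional drug-response transient added
#' after the drug time.
#'
#' @param baseline_nN pre-contact force.
#' @param peak_nN force peak at compression.
#' @param plateau_nN relaxed plateau force (> 0).
#' @param relax_tau_s relaxation time constant.
#' @param compression_start_s time of compression.
#' @param drug_time_s drug addition time (`NA` for none); must fall after
#'   the relaxation window.
#' @param drug_fn `NULL`, or a function of time-since-drug (s) returning a
#'   multiplicative force factor (1 = no effect); see
#'   [drug_transient()].
#' @param duration_s total duration.
#' @param rate_hz sampling rate.
#' @param noise_sd_nN additive Gaussian noise SD.
#' @param z_um cantilever height during compression.
#' @return object of class `force_curve_scene`.
#' @export
force_curve_scene <- function(baseline_nN = 0.1, peak_nN = 20,
                              plateau_nN = 12, relax_tau_s = 5,
                              compression_start_s = 5,
                              drug_time_s = NA, drug_fn = NULL,
                              duration_s = 120, rate_hz = 10,
                              noise_sd_nN = 0, z_um = 8) {
  assert_positive(plateau_nN, "plateau_nN")
  assert_positive(rate_hz, "rate_hz")
  if (!is.na(drug_time_s)) {
    abort_if(drug_time_s <= compression_start_s + 5 * relax_tau_s,
             "drug_time_s must fall after the relaxation window")
  }
  structure(as.list(environment()), class = "force_curve_scene")
}

#' Multiplicative drug transients
#'
#' `drug_transient(rise, final, tau_s)` rises instantaneously by `rise`
#' (fractional, e.g. 0.3 = +30%) and then decays exponentially toward
#' `1 + final`; the low-dose signature is a transient rise followed by a
#' decay below baseline, the high-dose signature an immediate monotone
#' drop (`rise = 0`, `final < 0`).
#'
#' @param rise initial fractional rise.
#' @param final asymptotic fractional change.
#' @param tau_s decay time constant.
#' @return function of time-since-drug returning a force factor.
#' @export
drug_transient <- function(rise = 0.3, final = -0.5, tau_s = 60) {
  force(rise); force(final); force(tau_s)
  function(dt) 1 + final + (rise - final) * exp(-dt / tau_s)
}

#' Generate a synthetic AFM force curve
#'
#' @param spec a [force_curve_scene()].
#' @param seed integer seed.
#' @return tibble `time_s`, `force_nN`, `z_um` with attribute `truth`.
#' @export
gen_force_curve <- function(spec, seed) {
  stopifnot(inherits(spec, "force_curve_scene"))
  set.seed(seed)
  t <- seq(0, spec$duration_s, by = 1 / spec$rate_hz)
  f <- rep(spec$baseline_nN, length(t))
  after <- t >= spec$compression_start_s
  f[after] <- spec$plateau_nN + (spec$peak_nN - spec$plateau_nN) *
    exp(-(t[after] - spec$compression_start_s) / spec$relax_tau_s)
  if (!is.na(spec$drug_time_s) && !is.null(spec$drug_fn)) {
    post <- t >= spec$drug_time_s
    f[post] <- f[post] * spec$drug_fn(t[post] - spec$drug_time_s)
  }
  if (spec$noise_sd_nN > 0) f <- f + stats::rnorm(length(t), 0, spec$noise_sd_nN)
  out <- tibble::tibble(time_s = t, force_nN = f,
                        z_um = ifelse(after, spec$z_um, spec$z_um + 10))
  attr(out, "truth") <- unclass(spec)
  out
}
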