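#' Simulate diffusion-model trials
#'
#' Euler-Maruyama simulation of the full diffusion model. Per trial, drift is
#' drawn Normal(`v`, `sv`), the start point Uniform over
#' `z_rel +/- sz_rel / 2` (scaled by `a`), and the non-decision time Uniform
#' over `ter +/- ster / 2`; evidence is then updated by
#' `v_trial * dt + s * sqrt(dt) * N(0, 1)` until it crosses 0 or `a`, or the
#' censoring bound is reached. Each trial uses its own RNG substream derived
#' from the seed, so a given trial sees the same noise sequence at every
#' candidate threshold (common random numbers).
#'
#' @param params a [ddm_params()] object.
#' @param config a [sim_config()] object.
#' @return A data frame with one row per trial: `boundary` ("upper", "lower",
#'   or `NA` when timed out), `decision_time` (s), `rt` (decision time plus
#'   the trial's sampled non-decision time, s), and `timed_out`.
#' @examples
#' sim <- simulate_trials(ddm_params(v = 1, a = 1), sim_config(n_trials = 100))
#' mean(sim$boundary == "upper", na.rm = TRUE)
#' @export
simulate_trials <- function(params, config = sim_config()) {
  stopifnot(inherits(params, "ddm_params"), inherits(config, "sim_config"))
  validate_ddm_params(params)
  res <- .cpp_simulate_trials(params$v, params$a, params$z_rel, params$ter,
                              params$sv, params$sz_rel, params$ster, params$s,
                              config$dt, config$max_decision_time,
                              config$n_trials, config$seed)
  data.frame(
    boundary = c("lower", "upper")[res$boundary + 1L],
    decision_time = res$decision_time,
    rt = res$rt,
    timed_out = res$timed_out,
    stringsAsFactors = FALSE
  )
}

#' Closed-form choice probability of the simple diffusion model
#'
#' Probability that a diffusion process with constant drift `v`, boundary
#' separation `a`, relative start `z_rel` and diffusion coefficient `s` is
#' absorbed at the upper boundary:
#' `(1 - exp(-2 v a z_rel / s^2)) / (1 - exp(-2 v a / s^2))`,
#' with the continuous `v -> 0` limit (`z_rel`) handled explicitly.
#'
#' @param v drift rate; @param a boundary separation, > 0;
#' @param z_rel relative start in (0, 1); @param s diffusion coefficient.
#' @return Upper-boundary absorption probability (vectorized over inputs).
#' @export
closed_form_pc <- function(v, a, z_rel = 0.5, s = 1) {
  if (any(a <= 0)) stop("'a' must be > 0", call. = FALSE)
  if (any(z_rel <= 0 | z_rel >= 1)) stop("'z_rel' must be in (0, 1)", call. = FALSE)
  x <- 2 * v * a / s^2
  out <- ifelse(abs(x) < 1e-9, z_rel, expm1(-x * z_rel) / expm1(-x))
  as.numeric(out)
}

#' Closed-form mean decision time of the simple diffusion model
#'
#' Unconditional mean first-passage time of the two-boundary diffusion with
#' constant drift: `-z/v + (a/v) * (1 - exp(-2 v z / s^2)) / (1 - exp(-2 v a / s^2))`
#' with `z = z_rel * a`. For `z_rel = 0.5` this reduces to
#' `(a / (2 v)) * tanh(a v / (2 s^2))`; the `v -> 0` limit is
#' `z * (a - z) / s^2`.
#'
#' @inheritParams closed_form_pc
#' @return Mean decision time in seconds (vectorized over inputs).
#' @export
closed_form_mean_dt <- function(v, a, z_rel = 0.5, s = 1) {
  if (any(a <= 0)) stop("'a' must be > 0", call. = FALSE)
  if (any(z_rel <= 0 | z_rel >= 1)) stop("'z_rel' must be in (0, 1)", call. = FALSE)
  z <- z_rel * a
  x <- 2 * v * a / s^2
  small <- abs(x) < 1e-6
  out <- numeric(length(x))
  lim <- z * (a - z) / s^2
  gen <- (a / v) * expm1(-2 * v * z / s^2) / expm1(-x) - z / v
  out <- ifelse(small, lim, gen)
  as.numeric(out)
}

#' Log density of the Wiener first-passage time
#'
#' Log of the first-passage-time density of the simple (no between-trial
#' variability) diffusion model at decision time `t` and the given boundary,
#' computed with the small-time / large-time series representations and an
#' accuracy-based switch (truncation tolerance 1e-7).
#'
#' @param t decision time(s) in seconds, > 0 (non-decision time already
#'   subtracted).
#' @param boundary "upper" or "lower" (length 1 or `length(t)`).
#' @inheritParams closed_form_pc
#' @return Log density, vectorized over `t`.
#' @export
wfpt_log_density <- function(t, boundary, v, a, z_rel = 0.5, s = 1) {
  if (any(t <= 0)) stop("'t' must be > 0", call. = FALSE)
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  up <- boundary == "upper"
  if (!all(boundary %in% c("upper", "lower")))
    stop("'boundary' must be \"upper\" or \"lower\"", call. = FALSE)
  .cpp_wfpt_logpdf(t, up, v, a, z_rel, s)
}

#' Log-likelihood of choice-RT data under the full diffusion model
#'
#' Per observation, the Wiener first-passage-time density is integrated over
#' the three between-trial variability distributions: analytically over the
#' Gaussian drift distribution, and by fixed-order Gauss-Legendre quadrature
#' over the uniform start-point and non-decision-time distributions.
#' Observations with zero density make the result `-Inf`.
#'
#' @param data a data frame with columns `rt` (s) and `boundary` ("upper" /
#'   "lower"); a `correct` logical column is accepted in place of `boundary`
#'   (correct = upper, the accuracy-coded convention).
#' @param params a [ddm_params()] object.
#' @param n_sz_nodes,n_ster_nodes quadrature orders for the start-point and
#'   non-decision-time integrals.
#' @return The summed log-likelihood (scalar).
#' @export
full_ddm_log_likelihood <- function(data, params, n_sz_nodes = 7,
                                    n_ster_nodes = 9) {
  if (NROW(data) == 0) stop("'data' must be non-empty", call. = FALSE)
  stopifnot(inherits(params, "ddm_params"))
  validate_ddm_params(params)
  up <- if ("boundary" %in% names(data)) data$boundary == "upper"
        else as.logical(data$correct)
  gw <- gl_nodes(n_sz_nodes)
  gt <- gl_nodes(n_ster_nodes)
  .cpp_full_ddm_loglik(data$rt, up, params$v, params$a, params$z_rel,
                       params$ter, params$sv, params$sz_rel, params$ster,
                       params$s, gw$x, gw$w, gt$x, gt$w)
}

# density (not log) of the full DDM at rt, vectorized; used by quadrature
# checks and by the density/CDF agreement tests
full_ddm_density <- function(rt, boundary, params, n_sz_nodes = 7,
                             n_ster_nodes = 9) {
  vapply(seq_along(rt), function(i) {
    ll <- full_ddm_log_likelihood(
      data.frame(rt = rt[i],
                 boundary = if (length(boundary) > 1) boundary[i] else boundary),
      params, n_sz_nodes, n_ster_nodes)
    exp(ll)
  }, numeric(1))
}
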