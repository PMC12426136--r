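#' Reward rate from summary statistics
#'
#' The reward-rate objective: accuracy divided by the average time spent per
#' trial,
#' `RR = PC / (MRT + ITI + FDT + (1 - PC) * ET)`,
#' where `PC` is the proportion correct, `MRT` the summary response time
#' (mean when computed from simulation; tabulated group summaries typically
#' report the median), and the timing constants come from the task.
#'
#' @param pc proportion correct in `[0, 1]`.
#' @param mrt summary response time in seconds, > 0.
#' @param timing a [timing_config()] object.
#' @return Reward rate in correct responses per second (vectorized).
#' @examples
#' reward_rate_from_summary(0.794, 0.760, timing_config(et = 1.0))
#' @export
reward_rate_from_summary <- function(pc, mrt, timing = timing_config()) {
  stopifnot(inherits(timing, "timing_config"))
  if (any(pc < 0 | pc > 1)) stop("'pc' must lie in [0, 1]", call. = FALSE)
  if (any(mrt <= 0)) stop("'mrt' must be > 0", call. = FALSE)
  denom <- mrt + timing$iti + timing$fdt + (1 - pc) * timing$et
  if (any(denom <= 0)) stop("reward-rate denominator must be > 0", call. = FALSE)
  pc / denom
}

#' Expected reward rate of a candidate threshold, by simulation
#'
#' Simulates trials at the candidate threshold in `params$a`, computes the
#' accuracy and mean response time (decision time plus non-decision time) and
#' applies the reward-rate formula. Timed-out trials are, by default, counted
#' as errors with decision time equal to the censoring bound
#' (`timeout_as_error = FALSE` drops them instead). Reproducible given
#' `config$seed`.
#'
#' @param params a [ddm_params()] object (its `a` is the candidate threshold).
#' @param timing a [timing_config()] object.
#' @param config a [sim_config()] object.
#' @param timeout_as_error how censored trials enter the reward rate.
#' @return Reward rate (1/s).
#' @export
expected_rr_of_threshold <- function(params, timing = timing_config(),
                                     config = sim_config(),
                                     timeout_as_error = TRUE) {
  stopifnot(inherits(params, "ddm_params"))
  validate_ddm_params(params)
  as.numeric(.cpp_rr_curve_sim(params$a, params$v, params$z_rel, params$ter,
                               params$sv, params$sz_rel, params$ster, params$s,
                               config$dt, config$max_decision_time,
                               config$n_trials, config$seed,
                               timing$iti, timing$fdt, timing$et,
                               timeout_as_error))
}

#' Closed-form reward-rate curve of the simple diffusion model
#'
#' Evaluates the reward rate at each candidate threshold from the closed-form
#' choice probability and mean decision time (no between-trial variability).
#' This is the oracle path against which the simulation-based search is
#' validated.
#'
#' @param grid ascending candidate thresholds.
#' @param v,z_rel,ter,s simple diffusion-model parameters.
#' @param timing a [timing_config()] object.
#' @return Numeric vector of reward rates along `grid`.
#' @export
rr_curve_closed_form <- function(grid, v, z_rel = 0.5, ter = 0.3,
                                 timing = timing_config(), s = 1) {
  pc <- closed_form_pc(v, grid, z_rel, s)
  mrt <- closed_form_mean_dt(v, grid, z_rel, s) + ter
  pc / (mrt + timing$iti + timing$fdt + (1 - pc) * timing$et)
}

#' Reward-rate-maximising threshold
#'
#' Grid search for the threshold that maximises reward rate given the other
#' diffusion parameters and the task timing. The default grid spans 0.01 to 4
#' in steps of 0.01. `method = "simulation"` evaluates every grid value by
#' simulation with common random numbers across grid points (the same trial
#' re-uses its noise stream at every candidate threshold, de-noising the
#' argmax); `method = "closed_form"` uses the exact simple-model curve and
#' requires all between-trial variabilities to be zero. Ties resolve to the
#' smallest threshold.
#'
#' @param params a [ddm_params()] object; its `a` is ignored.
#' @param timing a [timing_config()] object.
#' @param grid ascending candidate thresholds.
#' @param config a [sim_config()] object (simulation method).
#' @param method "simulation" or "closed_form".
#' @param timeout_as_error see [expected_rr_of_threshold()].
#' @return An `optimal_threshold_result`: list with `grid`, `rr_curve`,
#'   `a_star` (argmax threshold) and `rr_star` (maximum reward rate).
#' @examples
#' optimal_threshold(ddm_params(v = 1, ter = 0.3), method = "closed_form")$a_star
#' @export
optimal_threshold <- function(params, timing = timing_config(),
                              grid = seq(0.01, 4, by = 0.01),
                              config = sim_config(),
                              method = c("simulation", "closed_form"),
                              timeout_as_error = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(params, "ddm_params"))
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be non-empty and strictly ascending", call. = FALSE)
  if (method == "closed_form") {
    if (params$sv > 0 || params$sz_rel > 0 || params$ster > 0)
      stop("closed-form method requires sv = sz_rel = ster = 0", call. = FALSE)
    rr <- rr_curve_closed_form(grid, params$v, params$z_rel, params$ter,
                               timing, params$s)
  } else {
    rr <- as.numeric(.cpp_rr_curve_sim(grid, params$v, params$z_rel,
                                       params$ter, params$sv, params$sz_rel,
                                       params$ster, params$s, config$dt,
                                       config$max_decision_time,
                                       config$n_trials, config$seed,
                                       timing$iti, timing$fdt, timing$et,
                                       timeout_as_error))
  }
  if (!any(is.finite(rr) & rr > 0))
    stop("reward-rate curve is degenerate (all zero or non-finite)",
         call. = FALSE)
  i <- which.max(rr)  # first maximum = smallest threshold on ties
  structure(list(grid = grid, rr_curve = rr, a_star = grid[i], rr_star = rr[i],
                 method = method),
            class = "optimal_threshold_result")
}

#' @export
print.optimal_threshold_result <- function(x, ...) {
  cat(sprintf("Optimal threshold a* = %.3f (RR* = %.4f /s, %s method, %d grid points)\n",
              x$a_star, x$rr_star, x$method, length(x$grid)))
  invisible(x)
}

#' Export a reward-rate curve as CSV
#'
#' @param result an `optimal_threshold_result`.
#' @param path output file.
#' @export
write_rr_curve <- function(result, path) {
  stopifnot(inherits(result, "optimal_threshold_result"))
  write.csv(data.frame(threshold = result$grid, rr = result$rr_curve),
            path, row.names = FALSE)
  invisible(path)
}

#' Optimal-threshold distribution from posterior draws
#'
#' Maps each group-level posterior draw of the diffusion parameters through
#' the optimal-threshold search, forming the optimal-threshold "posterior"
#' used for the qualitative optimality bands.
#'
#' @param group_samples data frame (or list of equal-length vectors) with
#'   columns `v`, `z_rel`, `ter` and optionally `sv`, `sz_rel`, `ster`.
#' @inheritParams optimal_threshold
#' @return Numeric vector of optimal thresholds, one per draw.
#' @export
optimal_posterior_distribution <- function(group_samples,
                                           timing = timing_config(),
                                           grid = seq(0.01, 4, by = 0.01),
                                           config = sim_config(),
                                           method = c("closed_form", "simulation")) {
  method <- match.arg(method)
  if (is.list(group_samples) && !is.data.frame(group_samples)) {
    lens <- lengths(group_samples)
    if (length(unique(lens[lens > 1])) > 1)
      stop("sample arrays must have equal length", call. = FALSE)
  }
  gs <- as.data.frame(group_samples)
  need <- c("v", "z_rel", "ter")
  if (!all(need %in% names(gs)))
    stop("'group_samples' needs columns v, z_rel, ter", call. = FALSE)
  getcol <- function(nm) if (nm %in% names(gs)) gs[[nm]] else rep(0, nrow(gs))
  sv <- getcol("sv"); sz <- getcol("sz_rel"); ster <- getcol("ster")
  vapply(seq_len(nrow(gs)), function(i) {
    p <- ddm_params(v = gs$v[i], a = 1, z_rel = gs$z_rel[i], ter = gs$ter[i],
                    sv = sv[i], sz_rel = sz[i], ster = ster[i])
    optimal_threshold(p, timing, grid, config, method)$a_star
  }, numeric(1))
}

#' Nested quantile bands of a sample
#'
#' Empirical quantiles at 10/20/40/60/80/90% (linear-interpolation definition,
#' R type 7), the band structure used to display the optimal-threshold
#' distribution.
#'
#' @param samples numeric vector with at least 10 values.
#' @param probs quantile probabilities.
#' @return Named numeric vector of quantiles, nondecreasing.
#' @export
band_quantiles <- function(samples, probs = c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9)) {
  if (length(samples) < 10)
    stop("at least 10 samples are required", call. = FALSE)
  quantile(samples, probs = probs, names = TRUE, type = 7)
}
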