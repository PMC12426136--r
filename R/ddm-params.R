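#' Full diffusion-model parameter set
#'
#' Bundles one decision-maker's diffusion parameters: drift rate `v`
#' (evidence/s), boundary separation `a` (evidence units), relative starting
#' point `z_rel` (absolute start is `z_rel * a`), non-decision time `ter`
#' (s), and the between-trial variabilities of the full model: drift SD `sv`,
#' starting-point range `sz_rel` (as a fraction of `a`), and non-decision-time
#' range `ster` (s). The within-trial diffusion coefficient `s` is a scaling
#' constant, fixed at 1 throughout the package; the alternative 0.1 convention
#' only rescales `v`, `a` and `sv` by 10.
#'
#' @param v drift rate (evidence/s).
#' @param a boundary separation, > 0.
#' @param z_rel relative starting point in (0, 1); 0.5 is unbiased.
#' @param ter non-decision time in seconds; must satisfy `ter >= ster / 2`.
#' @param sv between-trial drift-rate SD, >= 0 (drift drawn Normal(`v`, `sv`)).
#' @param sz_rel between-trial starting-point range as a fraction of `a`,
#'   >= 0 (start drawn Uniform over `z_rel +/- sz_rel / 2`);
#'   `z_rel +/- sz_rel / 2` must stay inside (0, 1).
#' @param ster between-trial non-decision-time range in seconds, >= 0
#'   (drawn Uniform over `ter +/- ster / 2`).
#' @param s within-trial diffusion coefficient, > 0.
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' p <- ddm_params(v = 1.2, a = 1.5, ter = 0.3)
#' @export
ddm_params <- function(v, a = 1, z_rel = 0.5, ter = 0.3,
                       sv = 0, sz_rel = 0, ster = 0, s = 1) {
  p <- list(v = v, a = a, z_rel = z_rel, ter = ter,
            sv = sv, sz_rel = sz_rel, ster = ster, s = s)
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}

validate_ddm_params <- function(p) {
  with(p, {
    if (!is.finite(a) || a <= 0) stop("'a' must be > 0", call. = FALSE)
    if (z_rel <= 0 || z_rel >= 1) stop("'z_rel' must lie in (0, 1)", call. = FALSE)
    if (sv < 0 || sz_rel < 0 || ster < 0)
      stop("variability parameters must be >= 0", call. = FALSE)
    if (ter < ster / 2) stop("'ter' must be >= ster / 2", call. = FALSE)
    if (z_rel - sz_rel / 2 <= 0 || z_rel + sz_rel / 2 >= 1)
      stop("'z_rel' +/- 'sz_rel'/2 must stay inside (0, 1)", call. = FALSE)
    if (s <= 0) stop("'s' must be > 0", call. = FALSE)
  })
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Diffusion-model parameters:\n")
  cat(sprintf("  v = %.4g, a = %.4g, z_rel = %.4g, ter = %.4g s\n",
              x$v, x$a, x$z_rel, x$ter))
  cat(sprintf("  sv = %.4g, sz_rel = %.4g, ster = %.4g s  (s = %.3g)\n",
              x$sv, x$sz_rel, x$ster, x$s))
  invisible(x)
}

#' Simulation configuration
#'
#' Settings for the Euler-Maruyama trial simulator. The defaults (10-ms step,
#' 10-s censoring bound, 2000 trials per evaluation) are the settings used for
#' the simulation-based reward-rate grid search; validation against the
#' closed-form solutions uses a 1-ms step.
#'
#' @param dt Euler step in seconds, > 0.
#' @param max_decision_time censoring bound in seconds; trials still running
#'   at this point are flagged timed out.
#' @param n_trials trials per evaluation, >= 1.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.010, max_decision_time = 10, n_trials = 2000,
                       seed = 1) {
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (max_decision_time <= dt)
    stop("'max_decision_time' must exceed 'dt'", call. = FALSE)
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  structure(list(dt = dt, max_decision_time = max_decision_time,
                 n_trials = as.integer(n_trials), seed = seed),
            class = "sim_config")
}

#' Task timing configuration
#'
#' The dead-time constants of the task that enter the reward-rate
#' denominator: inter-trial interval `iti`, feedback display time `fdt`, and
#' the additional error timeout `et` (incorrect feedback shown `et` seconds
#' longer than correct feedback). Defaults reflect a task with a 500-ms
#' "Correct" message, a 1500-ms "Incorrect" message and a 500-ms inter-trial
#' interval. Responses faster than `anticipatory_cutoff` trigger a "Too Fast!"
#' message and an `anticipatory_timeout` pause; the anticipatory timeout is
#' deliberately not part of the reward-rate denominator.
#'
#' @param iti inter-trial interval (s).
#' @param fdt feedback display time (s).
#' @param et additional timeout for error responses (s); 0 when correct and
#'   incorrect feedback last equally long.
#' @param anticipatory_cutoff responses faster than this are anticipatory (s).
#' @param anticipatory_timeout pause after an anticipatory response (s).
#' @return An object of class `timing_config`.
#' @export
timing_config <- function(iti = 0.5, fdt = 0.5, et = 1.0,
                          anticipatory_cutoff = 0.250,
                          anticipatory_timeout = 1.5) {
  vals <- c(iti, fdt, et, anticipatory_cutoff, anticipatory_timeout)
  if (any(vals < 0)) stop("timing constants must be >= 0", call. = FALSE)
  structure(list(iti = iti, fdt = fdt, et = et,
                 anticipatory_cutoff = anticipatory_cutoff,
                 anticipatory_timeout = anticipatory_timeout),
            class = "timing_config")
}
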