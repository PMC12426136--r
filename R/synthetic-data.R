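# Synthetic fixed-time / fixed-trial experiments with known ground truth.
# The generator emulates the structure of a blocked 2AFC random-dot-motion
# study: 20 blocks, either 60 s per block (fixed time) or 40 trials per block
# (fixed trial), per-participant diffusion parameters drawn from group-level
# distributions, and thresholds optionally declining geometrically across
# blocks toward an asymptote (toward each participant's own optimal threshold
# when the asymptote is left unset), emulating decision-makers moving closer
# to optimality over blocks.

#' Group specification for the synthetic generator
#'
#' Group-level means and SDs for each diffusion parameter, plus the block
#' trajectory of the threshold. Participant parameters are drawn from normals
#' truncated to the valid parameter region. The threshold mean for block b is
#' `asymptote + (initial - asymptote) * (1 - decay)^(b - 1)`; with
#' `threshold_asymptote = NULL` the asymptote is the participant's own
#' reward-rate-optimal threshold plus `c_asymptote` (so `c_asymptote` is the
#' group's generating distance from optimality). Defaults emulate a
#' random-dot-motion cohort with accuracy near 0.8 and median RT near 0.8 s.
#'
#' @param label group label.
#' @param n_participants number of participants.
#' @param v_mean,v_sd drift-rate distribution.
#' @param z_rel_mean,z_rel_sd starting-point distribution.
#' @param ter_mean,ter_sd non-decision-time distribution (s).
#' @param sv_mean,sv_sd,sz_rel_mean,sz_rel_sd,ster_mean,ster_sd between-trial
#'   variability distributions (all zero by default: simple diffusion model).
#' @param threshold_initial block-1 threshold mean.
#' @param threshold_asymptote late-block threshold mean; `NULL` = each
#'   participant's optimal threshold plus `c_asymptote`.
#' @param threshold_decay geometric approach rate per block in `[0, 1)`;
#'   0 keeps the threshold constant at `threshold_initial`.
#' @param c_asymptote generating distance from optimality at the asymptote
#'   (used when `threshold_asymptote` is `NULL`).
#' @param a_sd between-participant SD of a constant threshold offset.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, n_participants = 25,
                       v_mean = 1.1, v_sd = 0.25,
                       z_rel_mean = 0.5, z_rel_sd = 0,
                       ter_mean = 0.35, ter_sd = 0.05,
                       sv_mean = 0, sv_sd = 0,
                       sz_rel_mean = 0, sz_rel_sd = 0,
                       ster_mean = 0, ster_sd = 0,
                       threshold_initial = 1.4,
                       threshold_asymptote = NULL,
                       threshold_decay = 0.15,
                       c_asymptote = 0.3,
                       a_sd = 0.15) {
  if (any(c(v_sd, z_rel_sd, ter_sd, sv_sd, sz_rel_sd, ster_sd, a_sd) < 0))
    stop("SDs must be >= 0", call. = FALSE)
  if (!is.null(threshold_asymptote) && threshold_asymptote <= 0)
    stop("threshold asymptote must be > 0", call. = FALSE)
  if (threshold_decay < 0 || threshold_decay >= 1)
    stop("'threshold_decay' must be in [0, 1)", call. = FALSE)
  structure(list(label = label, n_participants = n_participants,
                 v_mean = v_mean, v_sd = v_sd,
                 z_rel_mean = z_rel_mean, z_rel_sd = z_rel_sd,
                 ter_mean = ter_mean, ter_sd = ter_sd,
                 sv_mean = sv_mean, sv_sd = sv_sd,
                 sz_rel_mean = sz_rel_mean, sz_rel_sd = sz_rel_sd,
                 ster_mean = ster_mean, ster_sd = ster_sd,
                 threshold_initial = threshold_initial,
                 threshold_asymptote = threshold_asymptote,
                 threshold_decay = threshold_decay,
                 c_asymptote = c_asymptote, a_sd = a_sd),
            class = "group_spec")
}

#' Experiment design
#'
#' @param design_type "fixed_time" (60-s blocks, trial count varies) or
#'   "fixed_trial" (40-trial blocks, duration varies).
#' @param n_blocks number of blocks.
#' @param block_budget seconds per block (fixed time) or trials per block
#'   (fixed trial); `NULL` gives 60 s / 40 trials.
#' @param timing a [timing_config()].
#' @param sim a [sim_config()] used for trial generation (1-ms Euler step by
#'   default, for near-exact trial generation).
#' @param contaminant_rate probability that a trial is replaced by an
#'   anticipatory response (uniform RT below the anticipatory cutoff); off by
#'   default.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(design_type = c("fixed_trial", "fixed_time"),
                              n_blocks = 20, block_budget = NULL,
                              timing = timing_config(),
                              sim = sim_config(dt = 0.001),
                              contaminant_rate = 0) {
  design_type <- match.arg(design_type)
  if (is.null(block_budget))
    block_budget <- if (design_type == "fixed_time") 60 else 40
  if (block_budget <= 0 || n_blocks < 1)
    stop("budgets must be positive and n_blocks >= 1", call. = FALSE)
  structure(list(design_type = design_type, n_blocks = as.integer(n_blocks),
                 block_budget = block_budget, timing = timing, sim = sim,
                 contaminant_rate = contaminant_rate),
            class = "experiment_design")
}

rtnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate draw outside truncation bounds", call. = FALSE)
    return(rep(mean, n))
  }
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-10)
    stop("truncation region has (near-)zero mass; check the group spec",
         call. = FALSE)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Draw participant parameter sets from a group specification
#'
#' Draws each participant's diffusion parameters from truncated normals
#' respecting the parameter invariants, and computes each participant's true
#' reward-rate-optimal threshold (the ground truth for recovery tests).
#'
#' @param spec a [group_spec()].
#' @param seed integer seed.
#' @param timing a [timing_config()] (for the optimal-threshold computation).
#' @param grid threshold search grid.
#' @param b_method "closed_form" (exact; requires the spec's variabilities to
#'   be zero) or "simulation".
#' @param b_config a [sim_config()] for simulation-based optimal thresholds.
#' @return Data frame with one row per participant: parameters, the constant
#'   threshold offset `a_offset`, and `b_opt` (the participant's optimal
#'   threshold).
#' @export
sample_participants <- function(spec, seed = 1, timing = timing_config(),
                                grid = seq(0.01, 4, by = 0.01),
                                b_method = NULL, b_config = sim_config()) {
  stopifnot(inherits(spec, "group_spec"))
  set.seed(derive_seed(seed, 1))
  n <- spec$n_participants
  v <- rtnorm1(n, spec$v_mean, spec$v_sd, lower = 0.05)
  z <- rtnorm1(n, spec$z_rel_mean, spec$z_rel_sd, lower = 0.05, upper = 0.95)
  ter <- rtnorm1(n, spec$ter_mean, spec$ter_sd, lower = 0.05)
  sv <- rtnorm1(n, spec$sv_mean, spec$sv_sd, lower = 0)
  sz <- rtnorm1(n, spec$sz_rel_mean, spec$sz_rel_sd, lower = 0)
  sz <- pmin(sz, 2 * pmin(z, 1 - z) - 1e-3)
  sz[sz < 0] <- 0
  ster <- rtnorm1(n, spec$ster_mean, spec$ster_sd, lower = 0)
  ster <- pmin(ster, 2 * ter - 1e-3)
  a_off <- rnorm(n, 0, spec$a_sd)
  if (is.null(b_method))
    b_method <- if (all(c(sv, sz, ster) == 0)) "closed_form" else "simulation"
  cache <- make_b_cache()
  b_opt <- vapply(seq_len(n), function(i) {
    b_optimal(v[i], z[i], ter[i], sv[i], sz[i], ster[i], timing, grid,
              b_config, b_method, cache)
  }, numeric(1))
  data.frame(
    participant = sprintf("%s_p%02d", spec$label, seq_len(n)),
    group = spec$label, v = v, z_rel = z, ter = ter,
    sv = sv, sz_rel = sz, ster = ster,
    a_offset = a_off, b_opt = b_opt,
    stringsAsFactors = FALSE
  )
}

# threshold mean for each block given the spec and a participant's optimum
block_thresholds <- function(spec, n_blocks, b_opt, a_offset) {
  asym <- if (is.null(spec$threshold_asymptote)) b_opt + spec$c_asymptote
          else spec$threshold_asymptote
  b <- seq_len(n_blocks)
  a <- asym + (spec$threshold_initial - asym) * (1 - spec$threshold_decay)^(b - 1)
  pmax(a + a_offset, 0.05)
}

# simulate one batch of trials and dress them as trial records
sim_trial_records <- function(pars, design, n, seed) {
  p <- ddm_params(v = pars$v, a = pars$a, z_rel = pars$z_rel, ter = pars$ter,
                  sv = pars$sv, sz_rel = pars$sz_rel, ster = pars$ster)
  cfg <- design$sim
  raw <- .cpp_simulate_trials(p$v, p$a, p$z_rel, p$ter, p$sv, p$sz_rel,
                              p$ster, p$s, cfg$dt, cfg$max_decision_time,
                              n, seed)
  correct <- !is.na(raw$boundary) & raw$boundary == 1L
  rt <- raw$rt
  set.seed(derive_seed(seed, 7))
  if (design$contaminant_rate > 0) {
    contam <- runif(n) < design$contaminant_rate
    rt[contam] <- runif(sum(contam), 0.05, design$timing$anticipatory_cutoff)
    correct[contam] <- runif(sum(contam)) < 0.5
  }
  # stimulus direction balanced within the batch, order shuffled
  stim <- sample(rep(c("left", "right"), length.out = n))
  choice <- ifelse(correct, stim, ifelse(stim == "left", "right", "left"))
  data.frame(rt = rt, correct = correct, choice = choice,
             stringsAsFactors = FALSE)
}

#' Simulate one fixed-trial block
#'
#' Exactly `design$block_budget` trials (default 40), completed at the
#' participant's own pace. Correctness is defined against a planted stimulus
#' direction, balanced within the block in shuffled order.
#'
#' @param pars one row of [sample_participants()] output (or any list with
#'   `v`, `z_rel`, `ter`, `sv`, `sz_rel`, `ster`) plus the block threshold
#'   `a`.
#' @param design an [experiment_design()].
#' @param block block index.
#' @param seed integer seed.
#' @return Data frame of trial records (`block`, `rt`, `correct`, `choice`).
#' @export
simulate_fixed_trial_block <- function(pars, design, block, seed = 1) {
  n <- design$block_budget
  rec <- sim_trial_records(pars, design, n, derive_seed(seed, block))
  cbind(data.frame(block = block), rec)
}

#' Simulate one fixed-time block
#'
#' Trials accumulate while the block's time budget (default 60 s) has not
#' been exhausted by the per-trial wall time
#' `rt + fdt + iti + et * (1 - correct)` (anticipatory trials instead incur
#' the anticipatory timeout). The trial in progress when the budget expires
#' is completed, so at least one trial is always produced.
#'
#' @inheritParams simulate_fixed_trial_block
#' @return Data frame of trial records.
#' @export
simulate_fixed_time_block <- function(pars, design, block, seed = 1) {
  tmg <- design$timing
  # upper bound on how many trials can start within the budget
  n_max <- ceiling(design$block_budget / (tmg$fdt + tmg$iti)) + 2L
  rec <- sim_trial_records(pars, design, n_max, derive_seed(seed, block))
  anticip <- rec$rt < tmg$anticipatory_cutoff
  wall <- ifelse(anticip,
                 rec$rt + tmg$anticipatory_timeout + tmg$iti,
                 rec$rt + tmg$fdt + tmg$iti + tmg$et * (1 - rec$correct))
  started_at <- c(0, cumsum(wall)[-length(wall)])
  keep <- started_at < design$block_budget
  keep[1] <- TRUE
  rec <- rec[keep, , drop = FALSE]
  cbind(data.frame(block = block), rec)
}

#' Generate a complete synthetic experiment
#'
#' Draws participants for each group, simulates every block under the group's
#' design, and returns the concatenated trial table (in the trial CSV schema)
#' together with the generating ground truth: per-participant parameters,
#' per-block threshold means, and each participant's true optimal threshold.
#'
#' @param specs list of [group_spec()] objects (labels must be unique).
#' @param design an [experiment_design()], or a list of one design per group.
#' @param seed integer seed; the same seed reproduces the experiment exactly.
#' @return List with `trials` (data frame) and `ground_truth` (list with
#'   `participants`, `block_thresholds`, `design`).
#' @export
generate_experiment <- function(specs, design = experiment_design(), seed = 1) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  if (length(specs) < 1) stop("at least one group is required", call. = FALSE)
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("group labels must be unique", call. = FALSE)
  designs <- if (inherits(design, "experiment_design"))
    rep(list(design), length(specs)) else design
  stopifnot(length(designs) == length(specs))
  all_trials <- list(); all_parts <- list(); all_blocks <- list()
  for (g in seq_along(specs)) {
    spec <- specs[[g]]; des <- designs[[g]]
    parts <- sample_participants(spec, derive_seed(seed, g),
                                 timing = des$timing)
    all_parts[[g]] <- parts
    for (i in seq_len(nrow(parts))) {
      a_blocks <- block_thresholds(spec, des$n_blocks, parts$b_opt[i],
                                   parts$a_offset[i])
      all_blocks[[parts$participant[i]]] <- a_blocks
      recs <- lapply(seq_len(des$n_blocks), function(b) {
        pars <- c(as.list(parts[i, ]), list(a = a_blocks[b]))
        bseed <- derive_seed(seed, g, i, b)
        if (des$design_type == "fixed_trial")
          simulate_fixed_trial_block(pars, des, b, bseed)
        else simulate_fixed_time_block(pars, des, b, bseed)
      })
      rec <- do.call(rbind, recs)
      rec <- cbind(data.frame(participant = parts$participant[i],
                              group = spec$label,
                              stringsAsFactors = FALSE), rec)
      all_trials[[parts$participant[i]]] <- rec
    }
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  trials <- trials[, c("participant", "group", "block", "rt", "correct", "choice")]
  list(trials = trials,
       ground_truth = list(participants = do.call(rbind, all_parts),
                           block_thresholds = all_blocks,
                           design = designs))
}

#' Write the ground truth of a synthetic experiment as JSON
#'
#' @param experiment output of [generate_experiment()].
#' @param path output file.
#' @export
write_ground_truth <- function(experiment, path) {
  gt <- experiment$ground_truth
  jsonlite::write_json(
    list(participants = gt$participants,
         block_thresholds = gt$block_thresholds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
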