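# End-to-end orchestration: simulate -> preprocess -> fit the qualitative
# (block-by-block threshold) and quantitative (difference-from-optimality)
# models -> Bayes-factor tables and optimality-band summaries. Configuration
# is a YAML file or an equivalent named list; the exported functions are the
# entry points, so every stage is scriptable.

#' Read a pipeline configuration
#'
#' The configuration is YAML with optional sections `timing` (arguments of
#' [timing_config()]), `sim` ([sim_config()]), `sampler` ([sampler_config()]),
#' and top-level fields `model` ("block_threshold" or "difference"),
#' `delta_c_prior`, `block_window` (default `c(11, 20)`), `scale`
#' ("reduced" or "full"), `seed`, and `out_dir`.
#'
#' @param path YAML file path, or a named list already in this shape.
#' @return A `pipeline_config` list with all defaults filled in.
#' @export
pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else if (is.character(path)) yaml::read_yaml(path)
         else path
  cfg <- list(
    timing = do.call(timing_config, raw$timing %||% list()),
    sim = do.call(sim_config, raw$sim %||% list()),
    sampler = do.call(sampler_config, raw$sampler %||% list()),
    model = raw$model %||% "difference",
    delta_c_prior = raw$delta_c_prior %||% "normal",
    block_window = unlist(raw$block_window %||% c(11, 20)),
    scale = raw$scale %||% "reduced",
    seed = raw$seed %||% 1,
    out_dir = raw$out_dir %||% NULL
  )
  if (cfg$scale == "reduced") {
    # reduced-scale preset: the default test path
    cfg$sampler$n_iter <- min(cfg$sampler$n_iter, 800L)
    cfg$sampler$burn_in <- min(cfg$sampler$burn_in, 300L)
  }
  if (length(cfg$block_window) != 2 || cfg$block_window[1] > cfg$block_window[2])
    stop("'block_window' must be c(first, last)", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Qualitative optimality assessment
#'
#' For each group: fits the block-varying-threshold model, summarises the
#' group-level threshold posterior per block (median and 95% interval), and
#' builds the optimal-threshold "posterior" by mapping every group-level
#' posterior draw of (v, ter) -- with the starting point at its fixed 0.5 --
#' through the optimal-threshold search, summarised as 10/20/40/60/80/90%
#' bands. Thresholds above the band indicate decision-makers more cautious
#' than reward-rate optimality.
#'
#' @param trials filtered trial data frame (may contain several groups).
#' @param timing a [timing_config()].
#' @param sampler a [sampler_config()].
#' @param variant model variant, see [block_threshold_model()].
#' @param hyper a [hyperprior_config()].
#' @param grid threshold search grid for the optimal band.
#' @param n_band_draws cap on posterior draws mapped through the
#'   optimal-threshold search.
#' @param drop_block1 drop block 1 from the summary (its estimates reflect
#'   initial task adaptation)? Included by default.
#' @param out_dir if non-NULL, write per-group CSV summaries here.
#' @return List (one element per group) with `block_summary` (data frame),
#'   `optimal_band` (quantiles), `diagnostics`, and the fit; class
#'   `qualitative_result`.
#' @export
run_qualitative <- function(trials, timing = timing_config(),
                            sampler = sampler_config(),
                            variant = "simple",
                            hyper = hyperprior_config(),
                            grid = seq(0.01, 4, by = 0.01),
                            n_band_draws = 1000,
                            drop_block1 = FALSE,
                            out_dir = NULL) {
  groups <- unique(trials$group)
  out <- lapply(groups, function(g) {
    dat <- trials[trials$group == g, , drop = FALSE]
    model <- block_threshold_model(dat, timing = timing, variant = variant,
                                   hyper = hyper)
    fit <- fit_hierarchical(model, sampler)
    B <- model$n_blocks
    blocks <- model$blocks
    if (drop_block1 && B > 1) blocks_use <- seq_len(B)[-1] else blocks_use <- seq_len(B)
    bs <- do.call(rbind, lapply(blocks_use, function(b) {
      dr <- extract_param(fit, paste0("mu_a_b", b))
      data.frame(block = blocks[b], median = median(dr),
                 q2.5 = quantile(dr, 0.025), q97.5 = quantile(dr, 0.975))
    }))
    rownames(bs) <- NULL
    mu_v <- extract_param(fit, "mu_v")
    mu_ter <- extract_param(fit, "mu_ter")
    idx <- if (length(mu_v) > n_band_draws)
      round(seq(1, length(mu_v), length.out = n_band_draws)) else seq_along(mu_v)
    opt <- optimal_posterior_distribution(
      data.frame(v = mu_v[idx], z_rel = 0.5, ter = mu_ter[idx]),
      timing = timing, grid = grid, method = "closed_form")
    dg <- diagnostics(fit, params = paste0("mu_a_b", seq_len(B)))
    res <- list(group = g, block_summary = bs,
                optimal_band = band_quantiles(opt),
                optimal_draws = opt,
                diagnostics = dg,
                converged = all(is.finite(dg$rhat) & dg$rhat <= 1.1),
                fit = fit)
    if (!res$converged)
      warning(sprintf("group %s: split-R-hat above 1.1 for some block thresholds", g),
              call. = FALSE)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(bs, file.path(out_dir, paste0("blocks_", g, ".csv")),
                row.names = FALSE)
      write.csv(data.frame(quantile = names(res$optimal_band),
                           value = as.numeric(res$optimal_band)),
                file.path(out_dir, paste0("optimal_band_", g, ".csv")),
                row.names = FALSE)
    }
    res
  })
  names(out) <- groups
  structure(out, class = "qualitative_result")
}

#' Quantitative optimality comparison of two groups
#'
#' Fits the difference-from-optimality model three times -- once per prior on
#' the group difference `delta_c` (normal, positive truncation, negative
#' truncation) -- and assembles the seven-column Bayes-factor summary:
#' effect-vs-null from the normal-prior fit, the two directional Bayes
#' factors (with adjusted variants) from the truncated fits, and the
#' transitive A-vs-B ratios. `delta_c > 0` means group A (the first group in
#' `groups`) is closer to optimality.
#'
#' @param trials filtered trial data frame containing the two groups, already
#'   restricted to the analysis block window.
#' @param groups character vector of the two group labels (A first).
#' @param timing a [timing_config()].
#' @param sampler a [sampler_config()].
#' @param variant model variant, see [difference_model()].
#' @param hyper a [hyperprior_config()].
#' @param min_group_size refuse to fit smaller groups.
#' @param b_method optimal-threshold path for `b_i`.
#' @param out_dir if non-NULL, write the Bayes-factor table (CSV and JSON)
#'   here.
#' @return List with `bfs` (a [bayes_factor_set()]), `delta_c_samples` per
#'   prior variant, `fits`, and `diagnostics`; class `quantitative_result`.
#' @export
run_quantitative <- function(trials, groups = NULL,
                             timing = timing_config(),
                             sampler = sampler_config(),
                             variant = "simple",
                             hyper = hyperprior_config(),
                             min_group_size = 5,
                             b_method = "closed_form",
                             out_dir = NULL) {
  if (is.null(groups)) groups <- unique(trials$group)
  if (length(groups) != 2)
    stop("exactly two groups are required", call. = FALSE)
  trials <- trials[trials$group %in% groups, , drop = FALSE]
  trials$group <- factor(trials$group, levels = groups)
  sizes <- tapply(trials$participant, trials$group,
                  function(x) length(unique(x)))
  if (any(sizes < min_group_size))
    stop(sprintf("each group needs at least %d participants (got %s)",
                 min_group_size, paste(sizes, collapse = ", ")), call. = FALSE)
  trials$group <- as.character(trials$group)
  # refit under each delta_c prior, as in separate directional models
  variants <- c("normal", "positive", "negative")
  fits <- list(); draws <- list()
  for (vr in variants) {
    model <- difference_model(trials, timing = timing, variant = variant,
                              delta_c_prior = vr, hyper = hyper,
                              b_method = b_method)
    # keep group A = groups[1]
    if (!identical(model$groups, groups))
      model$group_index <- vapply(model$participants,
                                  function(p) match(p$group, groups), integer(1))
    model$groups <- groups
    fits[[vr]] <- fit_hierarchical(model, sampler)
    draws[[vr]] <- extract_param(fits[[vr]], "delta_c")
  }
  sdv <- hyper$delta_c_sd
  pr_n <- function(x) delta_c_prior_logpdf("normal", x, sdv)
  pr_p <- function(x) delta_c_prior_logpdf("positive", x, sdv)
  pr_m <- function(x) delta_c_prior_logpdf("negative", x, sdv)
  bfs <- bayes_factor_set(
    effect_vs_null = savage_dickey_bf(draws$normal, pr_n),
    a_vs_null = savage_dickey_bf(draws$positive, pr_p, truncation = "positive"),
    a_vs_null_adj = adjusted_bf(draws$positive, pr_p, truncation = "positive",
                                prior_sd = sdv),
    b_vs_null = savage_dickey_bf(draws$negative, pr_m, truncation = "negative"),
    b_vs_null_adj = adjusted_bf(draws$negative, pr_m, truncation = "negative",
                                prior_sd = sdv),
    group_a = groups[1], group_b = groups[2])
  dg <- lapply(fits, function(f)
    diagnostics(f, params = intersect(c("m_c", "delta_c", "mu_v", "mu_ter"),
                                      f$param_names)))
  res <- structure(list(bfs = bfs, delta_c_samples = draws, fits = fits,
                        diagnostics = dg, groups = groups),
                   class = "quantitative_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- as.data.frame(bfs)
    write.csv(tab, file.path(out_dir, "bayes_factors.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(tab), file.path(out_dir, "bayes_factors.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.quantitative_result <- function(x, ...) {
  print(x$bfs)
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Convenience orchestration: generate (or read) data, filter trials and
#' exclude participants, then run the configured analysis and write its
#' outputs under `out_dir`.
#'
#' @param config a [pipeline_config()] (or path / list accepted by it).
#' @param trials optional trial data frame or CSV path; when NULL a
#'   two-group synthetic experiment is generated from `specs`.
#' @param specs list of [group_spec()] used when generating.
#' @param design an [experiment_design()] used when generating.
#' @return The analysis result (`qualitative_result` or
#'   `quantitative_result`), with the preprocessed trials attached as
#'   `attr(, "trials")`.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         specs = NULL, design = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(design))
    design <- experiment_design(timing = config$timing)
  if (is.null(trials)) {
    if (is.null(specs))
      specs <- list(group_spec("None-Trial", n_participants = 8),
                    group_spec("RR-Trial", n_participants = 8))
    trials <- generate_experiment(specs, design, seed = config$seed)$trials
  } else if (is.character(trials)) {
    trials <- read_trials(trials)
  }
  trials <- filter_trials(trials)
  summ <- participant_summaries(trials)
  keep <- exclude_participants(summ, design$design_type)
  trials <- trials[trials$participant %in% keep$participant, , drop = FALSE]
  res <- if (config$model == "block_threshold") {
    run_qualitative(trials, timing = config$timing, sampler = config$sampler,
                    out_dir = config$out_dir)
  } else {
    win <- config$block_window
    dat <- trials[trials$block >= win[1] & trials$block <= win[2], , drop = FALSE]
    run_quantitative(dat, timing = config$timing, sampler = config$sampler,
                     out_dir = config$out_dir)
  }
  attr(res, "trials") <- trials
  res
}

#' Plot a qualitative optimality comparison
#'
#' Block-by-block posterior threshold medians with 95% intervals over the
#' optimal-threshold quantile bands (base graphics).
#'
#' @param x one group's element of a [run_qualitative()] result.
#' @param main plot title.
#' @export
plot_qualitative_group <- function(x, main = x$group) {
  bs <- x$block_summary; band <- x$optimal_band
  ylim <- range(c(bs$q2.5, bs$q97.5, band))
  plot(bs$block, bs$median, ylim = ylim, pch = 19,
       xlab = "Block", ylab = "Threshold (a)", main = main)
  shades <- c("#1b7837", "#5aae61", "#a6dba0")
  bands <- rbind(c(1, 6), c(2, 5), c(3, 4))
  for (k in 1:3) {
    polygon(c(min(bs$block), max(bs$block), max(bs$block), min(bs$block)),
            c(rep(band[bands[k, 1]], 2), rep(band[bands[k, 2]], 2)),
            col = grDevices::adjustcolor(shades[k], 0.35), border = NA)
  }
  segments(bs$block, bs$q2.5, bs$block, bs$q97.5)
  points(bs$block, bs$median, pch = 19)
  invisible(x)
}
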