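# Hierarchical model families for threshold-optimality analysis:
#  - block-varying-threshold model ("qualitative"): per-participant diffusion
#    parameters constant over blocks, threshold free per block, block-specific
#    group-level threshold distributions (independent across blocks)
#  - difference-from-optimality model ("quantitative"): each participant's
#    threshold is materialized as a_i = b_i + c_i where b_i is the
#    reward-rate-optimal threshold given their other parameters and c_i the
#    distance from optimality; two-group fits place group c-means at
#    m -/+ delta_c / 2, with delta_c > 0 meaning group A (the first group) is
#    closer to optimality.

# log density of a (truncated) normal, normalized on [lower, upper]
dtnorm_log <- function(x, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd <= 0)) return(rep(-Inf, length(x)))
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  out <- dnorm(x, mean, sd, log = TRUE) - log(z)
  out[x < lower | x > upper] <- -Inf
  out
}

#' Prior log density of the group difference-from-optimality parameter
#'
#' The three prior variants for the between-group difference `delta_c`:
#' `"normal"` (effect in either direction), `"positive"` (normal truncated to
#' `delta_c > 0`: group A closer to optimality), `"negative"` (truncated to
#' `delta_c < 0`: group B closer to optimality). Truncated variants are
#' half-normals, renormalized to integrate to 1 on their half-line.
#'
#' @param variant "normal", "positive" or "negative".
#' @param value evaluation point(s).
#' @param scale prior SD, > 0.
#' @return Log density, vectorized over `value`.
#' @export
delta_c_prior_logpdf <- function(variant = c("normal", "positive", "negative"),
                                 value, scale = 0.5) {
  variant <- match.arg(variant)
  if (scale <= 0) stop("'scale' must be > 0", call. = FALSE)
  switch(variant,
    normal = dnorm(value, 0, scale, log = TRUE),
    positive = ifelse(value > 0, log(2) + dnorm(value, 0, scale, log = TRUE), -Inf),
    negative = ifelse(value < 0, log(2) + dnorm(value, 0, scale, log = TRUE), -Inf)
  )
}

#' Hyperprior configuration
#'
#' Weakly informative hyperpriors for the group-level means and SDs,
#' centred on values typical for random-dot-motion tasks (drift around 1.5,
#' non-decision time around 0.3 s, thresholds around 1.5). Group means use
#' truncated normals on their natural support; group SDs use half-normals.
#' All entries are `c(location, scale)` pairs.
#'
#' @param mu_v,mu_ter,mu_a,mu_c means' hyperpriors (`mu_c` applies to the
#'   distance-from-optimality mean, untruncated).
#' @param sigma_v,sigma_ter,sigma_a,sigma_c half-normal scales for group SDs.
#' @param mu_sv,sigma_sv,mu_sz,sigma_sz,mu_ster,sigma_ster variability
#'   hyperpriors (full variant only).
#' @param delta_c_sd prior SD of the between-group difference `delta_c`.
#' @return A named list of class `hyperprior_config`.
#' @export
hyperprior_config <- function(mu_v = c(1.5, 1.0), sigma_v = c(0, 0.5),
                              mu_ter = c(0.3, 0.3), sigma_ter = c(0, 0.2),
                              mu_a = c(1.5, 1.0), sigma_a = c(0, 0.5),
                              mu_c = c(0.5, 1.0), sigma_c = c(0, 0.5),
                              mu_sv = c(0.5, 0.5), sigma_sv = c(0, 0.3),
                              mu_sz = c(0.2, 0.2), sigma_sz = c(0, 0.2),
                              mu_ster = c(0.1, 0.1), sigma_ster = c(0, 0.1),
                              delta_c_sd = 0.5) {
  structure(list(mu_v = mu_v, sigma_v = sigma_v, mu_ter = mu_ter,
                 sigma_ter = sigma_ter, mu_a = mu_a, sigma_a = sigma_a,
                 mu_c = mu_c, sigma_c = sigma_c, mu_sv = mu_sv,
                 sigma_sv = sigma_sv, mu_sz = mu_sz, sigma_sz = sigma_sz,
                 mu_ster = mu_ster, sigma_ster = sigma_ster,
                 delta_c_sd = delta_c_sd),
            class = "hyperprior_config")
}

# ---- optimal-threshold memoisation -----------------------------------------

#' Create a cache for memoised optimal thresholds
#' @return An environment used as a hash map.
#' @export
make_b_cache <- function() new.env(parent = emptyenv(), hash = TRUE)

# optimal threshold for one parameter set, memoised on values quantized to
# `quantize`; closed form for the no-variability case, otherwise simulation
# (coarse grid then local refinement, common random numbers throughout)
b_optimal <- function(v, z_rel, ter, sv = 0, sz_rel = 0, ster = 0,
                      timing, grid, config,
                      method = c("closed_form", "simulation"),
                      cache = NULL, quantize = 0.01) {
  method <- match.arg(method)
  q <- function(x) round(x / quantize) * quantize
  vq <- q(v); tq <- max(q(ter), quantize)
  key <- sprintf("%s|%.4f|%.4f|%.4f|%.4f|%.4f|%.4f",
                 method, vq, z_rel, tq, q(sv), q(sz_rel), q(ster))
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  if (method == "closed_form") {
    rr <- rr_curve_closed_form(grid, vq, z_rel, tq, timing)
    val <- grid[which.max(rr)]
  } else {
    p0 <- ddm_params(v = vq, a = 1, z_rel = z_rel, ter = tq, sv = q(sv),
                     sz_rel = q(sz_rel), ster = q(ster))
    coarse <- grid[seq(1, length(grid), by = max(1L, round(0.05 / diff(grid[1:2]))))]
    oc <- optimal_threshold(p0, timing, coarse, config, method = "simulation")
    lo <- max(min(grid), oc$a_star - 0.05); hi <- min(max(grid), oc$a_star + 0.05)
    fine <- grid[grid >= lo & grid <= hi]
    val <- optimal_threshold(p0, timing, fine, config, method = "simulation")$a_star
  }
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Materialize thresholds in the difference-from-optimality model
#'
#' Converts a difference-model state into per-participant thresholds:
#' `a_i = b_i + c_i`, where `b_i` is the reward-rate-optimal threshold for
#' participant i's current non-threshold parameters. Optimal thresholds are
#' memoised on parameter values quantized to `quantize` (so two participants
#' with identical non-threshold parameters share one computation); pass
#' `quantize` close to 0 and `cache = NULL` for the full per-evaluation
#' recomputation.
#'
#' @param state data frame with columns `v`, `ter`, `c`, and optionally
#'   `z_rel` (default 0.5), `sv`, `sz_rel`, `ster`.
#' @param timing a [timing_config()] object.
#' @param grid threshold search grid.
#' @param config a [sim_config()] (simulation method only).
#' @param method "closed_form" (no-variability exact path) or "simulation".
#' @param cache a [make_b_cache()] environment, or NULL for no memoisation.
#' @param quantize quantization step for the memoisation key.
#' @return Numeric vector of thresholds `a_i` (may be non-positive if `c_i`
#'   is low enough; the model log-posterior treats those states as invalid).
#' @export
materialize_thresholds <- function(state, timing = timing_config(),
                                   grid = seq(0.01, 4, by = 0.01),
                                   config = sim_config(),
                                   method = c("closed_form", "simulation"),
                                   cache = NULL, quantize = 0.01) {
  method <- match.arg(method)
  st <- as.data.frame(state)
  z <- if ("z_rel" %in% names(st)) st$z_rel else rep(0.5, nrow(st))
  gc0 <- function(nm) if (nm %in% names(st)) st[[nm]] else rep(0, nrow(st))
  sv <- gc0("sv"); sz <- gc0("sz_rel"); ster <- gc0("ster")
  b <- vapply(seq_len(nrow(st)), function(i) {
    b_optimal(st$v[i], z[i], st$ter[i], sv[i], sz[i], ster[i],
              timing, grid, config, method, cache, quantize)
  }, numeric(1))
  b + st$c
}

# ---- model constructors ----------------------------------------------------

prep_participants <- function(data) {
  need <- c("participant", "rt")
  if (!all(need %in% names(data)))
    stop("data needs at least participant and rt columns", call. = FALSE)
  upper <- if ("boundary" %in% names(data)) data$boundary == "upper"
           else as.logical(data$correct)
  data$.upper <- upper
  sp <- split(data, data$participant)
  lapply(sp, function(d) {
    list(id = as.character(d$participant[1]),
         group = if ("group" %in% names(d)) as.character(d$group[1]) else "all",
         rt = d$rt, upper = d$.upper,
         block = if ("block" %in% names(d)) as.integer(d$block) else rep(1L, nrow(d)))
  })
}

theta_names_for <- function(type, variant, n_blocks = NULL) {
  base <- switch(type, difference = c("v", "ter", "c"),
                 block_threshold = c("v", "ter"))
  if (variant == "full") base <- c(base, "sv", "sz_rel", "ster")
  if (type == "block_threshold") base <- c(base, paste0("a_b", seq_len(n_blocks)))
  base
}

#' Difference-from-optimality hierarchical model
#'
#' Builds the quantitative model: per participant, diffusion parameters plus
#' a distance-from-optimality `c_i`; the participant's threshold is
#' materialized as `b_i + c_i` with `b_i` their optimal threshold. With two
#' groups, group c-means are `m - delta_c/2` (group A, first level of
#' `group`) and `m + delta_c/2` (group B), so `delta_c > 0` means group A is
#' closer to optimality; `delta_c` gets one of the three priors of
#' [delta_c_prior_logpdf()]. The starting point is fixed at `z_rel = 0.5`
#' (accuracy coding).
#'
#' @param data trial data frame (`participant`, `group`, `rt`, `correct`),
#'   already filtered and restricted to the analysis block window.
#' @param timing a [timing_config()] object.
#' @param variant "simple" (v, ter, c per participant) or "full" (adds sv,
#'   sz_rel, ster).
#' @param delta_c_prior prior variant for `delta_c` (two-group data only).
#' @param hyper a [hyperprior_config()].
#' @param b_method optimal-threshold path for `b_i`; "closed_form" is exact
#'   for the simple variant, "simulation" is the general path.
#' @param grid threshold search grid.
#' @param b_config a [sim_config()] for simulation-based `b_i`.
#' @param quantize memoisation quantization for `b_i`.
#' @return An object of class `rrddm_model`.
#' @export
difference_model <- function(data, timing = timing_config(),
                             variant = c("simple", "full"),
                             delta_c_prior = c("normal", "positive", "negative"),
                             hyper = hyperprior_config(),
                             b_method = c("closed_form", "simulation"),
                             grid = seq(0.01, 4, by = 0.01),
                             b_config = sim_config(),
                             quantize = 0.01) {
  variant <- match.arg(variant)
  delta_c_prior <- match.arg(delta_c_prior)
  b_method <- match.arg(b_method)
  if (variant == "simple" && b_method == "simulation")
    warning("simulation-based b_i with the simple variant; closed form is exact and faster")
  if (variant == "full" && b_method == "closed_form")
    stop("the full variant requires simulation-based b_i", call. = FALSE)
  parts <- prep_participants(data)
  groups <- unique(vapply(parts, `[[`, character(1), "group"))
  if (length(groups) > 2) stop("at most two groups are supported", call. = FALSE)
  model <- structure(list(
    type = "difference", variant = variant,
    participants = parts, groups = groups,
    group_index = vapply(parts, function(p) match(p$group, groups), integer(1)),
    theta_names = theta_names_for("difference", variant),
    timing = timing, hyper = hyper, delta_c_prior = delta_c_prior,
    b_method = b_method, grid = grid, b_config = b_config,
    quantize = quantize, b_cache = make_b_cache()
  ), class = "rrddm_model")
  model$phi_names <- phi_names_for(model)
  model
}

#' Block-varying-threshold hierarchical model
#'
#' Builds the qualitative model: per participant, diffusion parameters
#' constant over blocks plus one threshold per block; thresholds follow
#' block-specific group-level distributions, independent across blocks.
#' Starting point fixed at `z_rel = 0.5`.
#'
#' @inheritParams difference_model
#' @param data trial data frame for a single group (`participant`, `block`,
#'   `rt`, `correct`).
#' @return An object of class `rrddm_model`.
#' @export
block_threshold_model <- function(data, timing = timing_config(),
                                  variant = c("simple", "full"),
                                  hyper = hyperprior_config()) {
  variant <- match.arg(variant)
  parts <- prep_participants(data)
  blocks <- sort(unique(unlist(lapply(parts, `[[`, "block"))))
  # renumber blocks 1..B in the order observed
  parts <- lapply(parts, function(p) {
    p$block <- match(p$block, blocks); p
  })
  model <- structure(list(
    type = "block_threshold", variant = variant,
    participants = parts, groups = "all",
    group_index = rep(1L, length(parts)),
    blocks = blocks, n_blocks = length(blocks),
    theta_names = theta_names_for("block_threshold", variant, length(blocks)),
    timing = timing, hyper = hyper
  ), class = "rrddm_model")
  model$phi_names <- phi_names_for(model)
  model
}

phi_names_for <- function(model) {
  h <- switch(model$variant,
              simple = c("mu_v", "sigma_v", "mu_ter", "sigma_ter"),
              full = c("mu_v", "sigma_v", "mu_ter", "sigma_ter",
                       "mu_sv", "sigma_sv", "mu_sz", "sigma_sz",
                       "mu_ster", "sigma_ster"))
  if (model$type == "difference") {
    if (length(model$groups) == 2) c(h, "m_c", "delta_c", "sigma_c")
    else c(h, "mu_c", "sigma_c")
  } else {
    c(h, paste0("mu_a_b", seq_len(model$n_blocks)),
      paste0("sigma_a_b", seq_len(model$n_blocks)))
  }
}

#' @export
print.rrddm_model <- function(x, ...) {
  cat(sprintf("Hierarchical %s model (%s variant): %d participants, %d group(s)\n",
              gsub("_", "-", x$type), x$variant, length(x$participants),
              length(x$groups)))
  if (x$type == "difference" && length(x$groups) == 2)
    cat(sprintf("  delta_c prior: %s (SD %.3g); groups A=%s, B=%s\n",
                x$delta_c_prior, x$hyper$delta_c_sd, x$groups[1], x$groups[2]))
  cat(sprintf("  per-individual parameters: %s\n",
              paste(x$theta_names, collapse = ", ")))
  invisible(x)
}

# ---- posterior components --------------------------------------------------

# per-trial threshold vector (or scalar) for participant j given theta
participant_a <- function(model, j, theta) {
  if (model$type == "difference") {
    b <- b_optimal(theta[["v"]], 0.5, theta[["ter"]],
                   if (model$variant == "full") theta[["sv"]] else 0,
                   if (model$variant == "full") theta[["sz_rel"]] else 0,
                   if (model$variant == "full") theta[["ster"]] else 0,
                   model$timing, model$grid, model$b_config,
                   model$b_method, model$b_cache, model$quantize)
    b + theta[["c"]]
  } else {
    ab <- theta[paste0("a_b", seq_len(model$n_blocks))]
    unname(ab[model$participants[[j]]$block])
  }
}

theta_ddm_valid <- function(model, theta, a) {
  v <- theta[["v"]]; ter <- theta[["ter"]]
  sv <- if (model$variant == "full") theta[["sv"]] else 0
  sz <- if (model$variant == "full") theta[["sz_rel"]] else 0
  ster <- if (model$variant == "full") theta[["ster"]] else 0
  all(a > 0) && ter > 0 && ter >= ster / 2 && sv >= 0 && sz >= 0 &&
    ster >= 0 && (0.5 - sz / 2) > 0 && (0.5 + sz / 2) < 1
}

# log-likelihood of participant j at individual parameter vector theta
participant_loglik <- function(model, j, theta) {
  a <- participant_a(model, j, theta)
  if (!theta_ddm_valid(model, theta, a)) return(-Inf)
  part <- model$participants[[j]]
  sv <- if (model$variant == "full") theta[["sv"]] else 0
  sz <- if (model$variant == "full") theta[["sz_rel"]] else 0
  ster <- if (model$variant == "full") theta[["ster"]] else 0
  gw <- gl_nodes(7); gt <- gl_nodes(9)
  .cpp_full_ddm_loglik(part$rt, part$upper, theta[["v"]], a, 0.5,
                       theta[["ter"]], sv, sz, ster, 1,
                       gw$x, gw$w, gt$x, gt$w)
}

# group-level log density of theta given phi, for participant in group g
group_logpdf <- function(model, theta, phi, g) {
  lp <- dtnorm_log(theta[["v"]], phi[["mu_v"]], phi[["sigma_v"]], lower = 0) +
        dtnorm_log(theta[["ter"]], phi[["mu_ter"]], phi[["sigma_ter"]], lower = 0)
  if (model$variant == "full") {
    lp <- lp +
      dtnorm_log(theta[["sv"]], phi[["mu_sv"]], phi[["sigma_sv"]], lower = 0) +
      dtnorm_log(theta[["sz_rel"]], phi[["mu_sz"]], phi[["sigma_sz"]],
                 lower = 0, upper = 1) +
      dtnorm_log(theta[["ster"]], phi[["mu_ster"]], phi[["sigma_ster"]], lower = 0)
  }
  if (model$type == "difference") {
    mu_c <- if (length(model$groups) == 2) {
      if (g == 1) phi[["m_c"]] - phi[["delta_c"]] / 2
      else phi[["m_c"]] + phi[["delta_c"]] / 2
    } else phi[["mu_c"]]
    lp <- lp + dnorm(theta[["c"]], mu_c, phi[["sigma_c"]], log = TRUE)
  } else {
    for (b in seq_len(model$n_blocks)) {
      lp <- lp + dtnorm_log(theta[[paste0("a_b", b)]],
                            phi[[paste0("mu_a_b", b)]],
                            phi[[paste0("sigma_a_b", b)]], lower = 0)
    }
  }
  as.numeric(lp)
}

hyper_logpdf <- function(model, phi) {
  h <- model$hyper
  lp <- dtnorm_log(phi[["mu_v"]], h$mu_v[1], h$mu_v[2], lower = 0) +
        dtnorm_log(phi[["sigma_v"]], h$sigma_v[1], h$sigma_v[2], lower = 0) +
        dtnorm_log(phi[["mu_ter"]], h$mu_ter[1], h$mu_ter[2], lower = 0) +
        dtnorm_log(phi[["sigma_ter"]], h$sigma_ter[1], h$sigma_ter[2], lower = 0)
  if (model$variant == "full") {
    lp <- lp +
      dtnorm_log(phi[["mu_sv"]], h$mu_sv[1], h$mu_sv[2], lower = 0) +
      dtnorm_log(phi[["sigma_sv"]], h$sigma_sv[1], h$sigma_sv[2], lower = 0) +
      dtnorm_log(phi[["mu_sz"]], h$mu_sz[1], h$mu_sz[2], lower = 0, upper = 1) +
      dtnorm_log(phi[["sigma_sz"]], h$sigma_sz[1], h$sigma_sz[2], lower = 0) +
      dtnorm_log(phi[["mu_ster"]], h$mu_ster[1], h$mu_ster[2], lower = 0) +
      dtnorm_log(phi[["sigma_ster"]], h$sigma_ster[1], h$sigma_ster[2], lower = 0)
  }
  if (model$type == "difference") {
    if (length(model$groups) == 2) {
      lp <- lp + dnorm(phi[["m_c"]], h$mu_c[1], h$mu_c[2], log = TRUE) +
        delta_c_prior_logpdf(model$delta_c_prior, phi[["delta_c"]],
                             h$delta_c_sd) +
        dtnorm_log(phi[["sigma_c"]], h$sigma_c[1], h$sigma_c[2], lower = 0)
    } else {
      lp <- lp + dnorm(phi[["mu_c"]], h$mu_c[1], h$mu_c[2], log = TRUE) +
        dtnorm_log(phi[["sigma_c"]], h$sigma_c[1], h$sigma_c[2], lower = 0)
    }
  } else {
    for (b in seq_len(model$n_blocks)) {
      lp <- lp + dtnorm_log(phi[[paste0("mu_a_b", b)]], h$mu_a[1], h$mu_a[2],
                            lower = 0) +
        dtnorm_log(phi[[paste0("sigma_a_b", b)]], h$sigma_a[1], h$sigma_a[2],
                   lower = 0)
    }
  }
  as.numeric(lp)
}

#' Hierarchical log posterior
#'
#' Sum of (i) each participant's full-diffusion log-likelihood (with the
#' difference model's threshold materialized as `b_i + c_i`), (ii) the
#' group-level log densities of the individual parameters, and (iii) the
#' hyperprior log densities of the group-level parameters. States violating
#' any invariant (non-positive thresholds or SDs, non-decision time
#' inconsistencies) have log posterior `-Inf`.
#'
#' @param model an `rrddm_model` from [difference_model()] or
#'   [block_threshold_model()].
#' @param state list with `theta` (participants x parameters matrix, columns
#'   named as `model$theta_names`, rows in participant order) and `phi`
#'   (named numeric vector of group-level parameters).
#' @return Scalar log posterior.
#' @export
log_posterior <- function(model, state) {
  stopifnot(inherits(model, "rrddm_model"))
  theta <- state$theta; phi <- state$phi
  if (is.null(dim(theta)) || ncol(theta) != length(model$theta_names) ||
      nrow(theta) != length(model$participants))
    stop("'state$theta' dimensions do not match the model", call. = FALSE)
  if (length(phi) != length(model$phi_names))
    stop("'state$phi' length does not match the model", call. = FALSE)
  if (is.null(colnames(theta))) colnames(theta) <- model$theta_names
  if (is.null(names(phi))) names(phi) <- model$phi_names
  total <- hyper_logpdf(model, phi)
  if (!is.finite(total)) return(-Inf)
  for (j in seq_along(model$participants)) {
    th <- theta[j, ]
    lp <- group_logpdf(model, th, phi, model$group_index[j])
    if (!is.finite(lp)) return(-Inf)
    ll <- participant_loglik(model, j, th)
    if (!is.finite(ll)) return(-Inf)
    total <- total + lp + ll
  }
  total
}
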