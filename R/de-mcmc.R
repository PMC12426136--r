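# Differential-evolution MCMC: population MCMC whose proposals are scaled
# differences between other chains' current states plus small uniform jitter.
# A generic sampler (run_demcmc) handles arbitrary targets; fit_hierarchical
# runs the blocked scheme for the hierarchical models (per-participant blocks
# in ascending participant order, then the group-level block), with optional
# migration during burn-in.

#' Sampler configuration
#'
#' Defaults follow common DE-MCMC practice: 3k chains where k is the number
#' of free parameters per individual, 4000 iterations with the first 1000
#' discarded as burn-in, difference-vector scale `gamma = 2.38 / sqrt(2 d)`
#' for a d-dimensional block, uniform jitter of half-width 0.001, and
#' migration (cyclic state exchange among a random chain subset) with
#' probability 0.1 per iteration during burn-in only.
#'
#' @param chains number of chains; `NULL` means
#'   `chains_per_param_multiplier * k` (at least 4).
#' @param chains_per_param_multiplier chains per free individual parameter.
#' @param n_iter total iterations (stored, including burn-in).
#' @param burn_in iterations discarded by downstream consumers, < `n_iter`.
#' @param gamma difference-vector scale; `NULL` means `2.38 / sqrt(2 d)`.
#' @param jitter half-width of the uniform proposal noise.
#' @param migration_prob per-iteration migration probability during burn-in.
#' @param seed integer seed; identical seeds give identical samples.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = NULL, chains_per_param_multiplier = 3,
                           n_iter = 4000, burn_in = 1000, gamma = NULL,
                           jitter = 0.001, migration_prob = 0.1, seed = 1) {
  if (burn_in >= n_iter) stop("'burn_in' must be < 'n_iter'", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  structure(list(chains = chains,
                 chains_per_param_multiplier = chains_per_param_multiplier,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 gamma = gamma, jitter = jitter,
                 migration_prob = migration_prob, seed = seed),
            class = "sampler_config")
}

#' Differential-evolution crossover proposal
#'
#' `proposal = theta_i + gamma * (theta_m - theta_n) + Uniform(-jitter, jitter)`
#' per coordinate, where m and n index two other chains. The proposal is
#' symmetric in the Metropolis sense, so the acceptance ratio is the
#' posterior ratio alone.
#'
#' @param theta_i current state of the updating chain.
#' @param theta_m,theta_n current states of two distinct other chains.
#' @param gamma difference-vector scale.
#' @param jitter uniform noise half-width.
#' @return Proposal vector, same length as `theta_i`.
#' @export
crossover_propose <- function(theta_i, theta_m, theta_n, gamma, jitter) {
  if (identical(theta_m, theta_i) && identical(theta_n, theta_i))
    stop("donor chains must be distinct from the updating chain", call. = FALSE)
  theta_i + gamma * (theta_m - theta_n) +
    runif(length(theta_i), -jitter, jitter)
}

# two distinct donor indices from 1..C excluding i
sample_donors <- function(C, i) {
  pool <- seq_len(C)[-i]
  pool[sample.int(C - 1L, 2L)]
}

new_posterior_samples <- function(samples, burn_in, accept_rate, config,
                                  extra = list()) {
  structure(c(list(samples = samples, burn_in = burn_in,
                   param_names = dimnames(samples)[[3]],
                   accept_rate = accept_rate, config = config), extra),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("Posterior samples: %d chains x %d iterations x %d parameters (burn-in %d)\n",
              d[1], d[2], d[3], x$burn_in))
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%s %.2f", names(x$accept_rate),
                            unlist(x$accept_rate)), collapse = ", ")))
  invisible(x)
}

#' Stack posterior draws into a matrix
#'
#' @param x a `posterior_samples` object.
#' @param include_burnin keep the burn-in iterations?
#' @param ... unused.
#' @return Matrix with one column per parameter, chains stacked.
#' @export
as.matrix.posterior_samples <- function(x, include_burnin = FALSE, ...) {
  it <- if (include_burnin) seq_len(dim(x$samples)[2])
        else seq.int(x$burn_in + 1L, dim(x$samples)[2])
  s <- x$samples[, it, , drop = FALSE]
  out <- apply(s, 3, function(m) as.vector(t(m)))
  colnames(out) <- x$param_names
  out
}

#' Extract post-burn-in draws of one parameter
#'
#' @param x a `posterior_samples` object.
#' @param name parameter name.
#' @param include_burnin keep the burn-in iterations?
#' @return Numeric vector (all chains stacked).
#' @export
extract_param <- function(x, name, include_burnin = FALSE) {
  if (!name %in% x$param_names) stop("unknown parameter: ", name, call. = FALSE)
  as.matrix(x, include_burnin = include_burnin)[, name]
}

check_lp <- function(lp, state) {
  if (is.nan(lp))
    stop("log posterior returned NaN at state: ",
         paste(sprintf("%.6g", state), collapse = ", "), call. = FALSE)
  lp
}

#' Run DE-MCMC on an arbitrary log posterior
#'
#' Plain (unblocked) differential-evolution MCMC: each chain in turn proposes
#' a crossover move built from two other chains' current states and accepts
#' it by the Metropolis rule. Migration (a cyclic exchange of states among a
#' random subset of chains, each move Metropolis-accepted) runs with the
#' configured probability during burn-in.
#'
#' @param log_posterior_fn function mapping a parameter vector to a log
#'   density (up to a constant).
#' @param init chains x parameters matrix of starting states; every row must
#'   have finite log posterior.
#' @param config a [sampler_config()].
#' @return A `posterior_samples` object.
#' @examples
#' lp <- function(th) dnorm(th, log = TRUE)
#' fit <- run_demcmc(lp, matrix(rnorm(6), 6, 1),
#'                   sampler_config(n_iter = 500, burn_in = 100))
#' @export
run_demcmc <- function(log_posterior_fn, init, config = sampler_config()) {
  init <- as.matrix(init)
  C <- nrow(init); d <- ncol(init)
  if (C < 4) stop("at least 4 chains are required", call. = FALSE)
  set.seed(config$seed)
  gamma <- if (is.null(config$gamma)) 2.38 / sqrt(2 * d) else config$gamma
  jit <- config$jitter
  cur <- init
  lp <- apply(init, 1, function(th) check_lp(log_posterior_fn(th), th))
  if (any(!is.finite(lp)))
    stop("initial states must have finite log posterior", call. = FALSE)
  n_iter <- config$n_iter
  pn <- colnames(init)
  if (is.null(pn)) pn <- paste0("par", seq_len(d))
  samples <- array(NA_real_, c(C, n_iter, d), dimnames = list(NULL, NULL, pn))
  acc <- 0L; att <- 0L
  for (it in seq_len(n_iter)) {
    for (i in seq_len(C)) {
      mn <- sample_donors(C, i)
      prop <- cur[i, ] + gamma * (cur[mn[1], ] - cur[mn[2], ]) +
        runif(d, -jit, jit)
      lpp <- check_lp(log_posterior_fn(prop), prop)
      att <- att + 1L
      if (is.finite(lpp) && log(runif(1)) < lpp - lp[i]) {
        cur[i, ] <- prop; lp[i] <- lpp; acc <- acc + 1L
      }
    }
    if (it <= config$burn_in && runif(1) < config$migration_prob) {
      k <- sample.int(C, sample(2:C, 1))
      from <- c(k[-1], k[1])  # cyclic donor
      for (idx in seq_along(k)) {
        i <- k[idx]; j <- from[idx]
        if (log(runif(1)) < lp[j] - lp[i]) {
          cur[i, ] <- cur[j, ]; lp[i] <- lp[j]
        }
      }
    }
    samples[, it, ] <- cur
  }
  new_posterior_samples(samples, config$burn_in,
                        list(overall = acc / att), config)
}

# ---- hierarchical blocked sampler ------------------------------------------

init_hierarchical_state <- function(model) {
  P <- length(model$participants)
  h <- model$hyper
  rpos <- function(m, s) abs(rnorm(1, m, s)) + 1e-3
  phi <- c(mu_v = rpos(1.2, 0.3), sigma_v = runif(1, 0.15, 0.5),
           mu_ter = rpos(0.3, 0.05), sigma_ter = runif(1, 0.03, 0.12))
  if (model$variant == "full") {
    phi <- c(phi, mu_sv = runif(1, 0.3, 0.8), sigma_sv = runif(1, 0.1, 0.3),
             mu_sz = runif(1, 0.05, 0.2), sigma_sz = runif(1, 0.03, 0.1),
             mu_ster = runif(1, 0.03, 0.12), sigma_ster = runif(1, 0.02, 0.06))
  }
  if (model$type == "difference") {
    if (length(model$groups) == 2) {
      d0 <- switch(model$delta_c_prior,
                   normal = runif(1, -0.2, 0.2),
                   positive = runif(1, 0.02, 0.3),
                   negative = runif(1, -0.3, -0.02))
      phi <- c(phi, m_c = runif(1, 0.2, 0.9), delta_c = d0,
               sigma_c = runif(1, 0.1, 0.4))
    } else {
      phi <- c(phi, mu_c = runif(1, 0.2, 0.9), sigma_c = runif(1, 0.1, 0.4))
    }
  } else {
    B <- model$n_blocks
    phi <- c(phi, setNames(runif(B, 0.9, 2.0), paste0("mu_a_b", seq_len(B))),
             setNames(runif(B, 0.1, 0.4), paste0("sigma_a_b", seq_len(B))))
  }
  phi <- phi[phi_names_for(model)]
  theta <- matrix(NA_real_, P, length(model$theta_names),
                  dimnames = list(NULL, model$theta_names))
  for (j in seq_len(P)) {
    part <- model$participants[[j]]
    th <- c(v = rpos(phi[["mu_v"]], 0.25),
            ter = runif(1, 0.4, 0.7) * min(part$rt))
    if (model$variant == "full") {
      tv <- th[["ter"]]
      th <- c(th, sv = runif(1, 0.2, 0.8), sz_rel = runif(1, 0.02, 0.2),
              ster = runif(1, 0.01, min(0.1, 1.8 * tv)))
    }
    if (model$type == "difference") {
      th <- c(th, c = runif(1, 0.2, 1.0))
    } else {
      th <- c(th, setNames(runif(model$n_blocks, 0.8, 1.8),
                           paste0("a_b", seq_len(model$n_blocks))))
    }
    theta[j, ] <- th[model$theta_names]
  }
  list(theta = theta, phi = phi)
}

#' Fit a hierarchical model with blocked DE-MCMC
#'
#' Runs DE-MCMC on a [difference_model()] or [block_threshold_model()]:
#' each iteration updates per-participant parameter blocks (participants in
#' ascending order) and then the group-level block, each with its own
#' crossover proposal and Metropolis acceptance; migration runs during
#' burn-in with the configured probability. Per-participant likelihoods are
#' cached so each update evaluates one likelihood.
#'
#' @param model an `rrddm_model`.
#' @param config a [sampler_config()]; `chains = NULL` gives
#'   `3 k` chains for `k` free per-individual parameters.
#' @param store_theta keep individual-level draws (group-level draws are
#'   always stored)?
#' @return A `posterior_samples` object; individual parameters are named
#'   `"<par>[<participant>]"`. Carries the model as `$model`.
#' @export
fit_hierarchical <- function(model, config = sampler_config(),
                             store_theta = FALSE) {
  stopifnot(inherits(model, "rrddm_model"))
  set.seed(config$seed)
  P <- length(model$participants)
  p <- length(model$theta_names)
  q <- length(model$phi_names)
  C <- if (!is.null(config$chains)) config$chains
       else max(4L, config$chains_per_param_multiplier * p)
  gamma_t <- if (is.null(config$gamma)) 2.38 / sqrt(2 * p) else config$gamma
  gamma_q <- if (is.null(config$gamma)) 2.38 / sqrt(2 * q) else config$gamma
  jit <- config$jitter
  grp <- model$group_index
  tn <- model$theta_names; qn <- model$phi_names

  ll_fun <- function(j, th) { names(th) <- tn; participant_loglik(model, j, th) }
  gd_fun <- function(th, phiv, g) {
    names(th) <- tn; names(phiv) <- qn; group_logpdf(model, th, phiv, g)
  }
  hy_fun <- function(phiv) { names(phiv) <- qn; hyper_logpdf(model, phiv) }

  theta <- array(NA_real_, c(C, P, p))
  phi <- matrix(NA_real_, C, q)
  ll <- matrix(-Inf, C, P); gd <- matrix(-Inf, C, P); hy <- rep(-Inf, C)
  for (i in seq_len(C)) {
    ok <- FALSE
    for (try in 1:200) {
      st <- init_hierarchical_state(model)
      h0 <- hy_fun(st$phi)
      if (!is.finite(h0)) next
      g0 <- vapply(seq_len(P), function(j) gd_fun(st$theta[j, ], st$phi, grp[j]),
                   numeric(1))
      if (any(!is.finite(g0))) next
      l0 <- vapply(seq_len(P), function(j) ll_fun(j, st$theta[j, ]), numeric(1))
      if (any(!is.finite(l0))) next
      theta[i, , ] <- st$theta; phi[i, ] <- st$phi
      ll[i, ] <- l0; gd[i, ] <- g0; hy[i] <- h0
      ok <- TRUE; break
    }
    if (!ok) stop("could not find a finite-posterior initial state", call. = FALSE)
  }

  n_iter <- config$n_iter
  par_names <- c(qn, if (store_theta)
    as.vector(t(outer(vapply(model$participants, `[[`, character(1), "id"), tn,
                      function(id, par) paste0(par, "[", id, "]")))))
  K <- length(par_names)
  samples <- array(NA_real_, c(C, n_iter, K),
                   dimnames = list(NULL, NULL, par_names))
  acc_t <- 0L; att_t <- 0L; acc_q <- 0L; att_q <- 0L
  for (it in seq_len(n_iter)) {
    for (i in seq_len(C)) {
      for (j in seq_len(P)) {
        mn <- sample_donors(C, i)
        prop <- theta[i, j, ] + gamma_t * (theta[mn[1], j, ] - theta[mn[2], j, ]) +
          runif(p, -jit, jit)
        g1 <- gd_fun(prop, phi[i, ], grp[j])
        l1 <- if (is.finite(g1)) ll_fun(j, prop) else -Inf
        att_t <- att_t + 1L
        if (is.finite(g1 + l1) &&
            log(runif(1)) < (g1 + l1) - (gd[i, j] + ll[i, j])) {
          theta[i, j, ] <- prop; gd[i, j] <- g1; ll[i, j] <- l1
          acc_t <- acc_t + 1L
        }
      }
      mn <- sample_donors(C, i)
      propq <- phi[i, ] + gamma_q * (phi[mn[1], ] - phi[mn[2], ]) +
        runif(q, -jit, jit)
      h1 <- hy_fun(propq)
      att_q <- att_q + 1L
      if (is.finite(h1)) {
        g1s <- vapply(seq_len(P), function(j) gd_fun(theta[i, j, ], propq, grp[j]),
                      numeric(1))
        tot1 <- h1 + sum(g1s)
        if (is.finite(tot1) &&
            log(runif(1)) < tot1 - (hy[i] + sum(gd[i, ]))) {
          phi[i, ] <- propq; gd[i, ] <- g1s; hy[i] <- h1
          acc_q <- acc_q + 1L
        }
      }
    }
    if (it <= config$burn_in && runif(1) < config$migration_prob) {
      tot <- hy + rowSums(gd) + rowSums(ll)
      k <- sample.int(C, sample(2:C, 1))
      from <- c(k[-1], k[1])
      for (idx in seq_along(k)) {
        i <- k[idx]; j2 <- from[idx]
        if (log(runif(1)) < tot[j2] - tot[i]) {
          theta[i, , ] <- theta[j2, , ]; phi[i, ] <- phi[j2, ]
          ll[i, ] <- ll[j2, ]; gd[i, ] <- gd[j2, ]; hy[i] <- hy[j2]
          tot[i] <- tot[j2]
        }
      }
    }
    samples[, it, seq_len(q)] <- phi
    if (store_theta)
      samples[, it, (q + 1):K] <- matrix(aperm(theta, c(1, 3, 2)), C, P * p)
  }
  new_posterior_samples(samples, config$burn_in,
                        list(participant_blocks = acc_t / att_t,
                             group_block = acc_q / att_q),
                        config, extra = list(model = model, n_chains = C))
}

# ---- convergence diagnostics -----------------------------------------------

split_rhat_one <- function(mat) {
  # mat: chains x iterations (post burn-in)
  n <- ncol(mat)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  seqs <- rbind(mat[, seq_len(half), drop = FALSE],
                mat[, (n - half + 1):n, drop = FALSE])
  m <- nrow(seqs)
  means <- rowMeans(seqs)
  vars <- apply(seqs, 1, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((half - 1) / half * W + B / half) / W)
}

ess_one <- function(mat) {
  # combined-chain effective sample size via Geyer initial positive sequence
  C <- nrow(mat); n <- ncol(mat)
  if (n < 4) return(NA_real_)
  vars <- apply(mat, 1, var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- n * var(rowMeans(mat))
  var_plus <- (n - 1) / n * W + ifelse(C > 1, B / n, 0)
  max_lag <- min(n - 2, 500)
  acovs <- vapply(seq_len(C), function(i) {
    a <- acf(mat[i, ], lag.max = max_lag, plot = FALSE, type = "covariance")
    as.vector(a$acf)
  }, numeric(max_lag + 1))
  mean_acov <- rowMeans(acovs)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  min(C * n / tau, C * n)
}

#' Convergence diagnostics
#'
#' Split-R-hat (each chain split in half) and effective sample size per
#' parameter, computed on the post-burn-in draws. Parameters with
#' R-hat above 1.1 trigger a warning.
#'
#' @param x a `posterior_samples` object with at least 2 chains.
#' @param params parameter names (default: all).
#' @return Data frame with `param`, `rhat`, `ess`.
#' @export
diagnostics <- function(x, params = NULL) {
  stopifnot(inherits(x, "posterior_samples"))
  if (dim(x$samples)[1] < 2)
    stop("diagnostics need at least 2 chains", call. = FALSE)
  if (is.null(params)) params <- x$param_names
  it <- seq.int(x$burn_in + 1L, dim(x$samples)[2])
  out <- do.call(rbind, lapply(params, function(pn) {
    k <- match(pn, x$param_names)
    mat <- x$samples[, it, k, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = dim(x$samples)[1])
    data.frame(param = pn, rhat = split_rhat_one(mat), ess = ess_one(mat),
               stringsAsFactors = FALSE)
  }))
  bad <- out$param[is.finite(out$rhat) & out$rhat > 1.1]
  if (length(bad))
    warning("split-R-hat above 1.1 for: ", paste(bad, collapse = ", "),
            call. = FALSE)
  out
}
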