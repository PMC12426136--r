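# Hierarchical model construction: priors, threshold materialization,
# log-posterior composition.

test_that("delta_c priors are proper and truncate correctly", {
  # truncated density doubles the untruncated one on its half-line
  expect_equal(delta_c_prior_logpdf("positive", 0.3, 0.5),
               log(2) + dnorm(0.3, 0, 0.5, log = TRUE))
  expect_identical(delta_c_prior_logpdf("positive", -0.1, 0.5), -Inf)
  expect_identical(delta_c_prior_logpdf("negative", 0.1, 0.5), -Inf)
  for (vr in c("normal", "positive", "negative")) {
    total <- integrate(function(x) exp(delta_c_prior_logpdf(vr, x, 0.5)),
                       -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(delta_c_prior_logpdf("flat", 0, 0.5))
  expect_error(delta_c_prior_logpdf("normal", 0, -1), "scale")
})

test_that("thresholds materialize as optimal-plus-distance with working memoisation", {
  st <- data.frame(v = c(1.2, 1.2, 0.9), ter = c(0.3, 0.3, 0.35),
                   c = c(0, 0.5, -0.2))
  tm <- timing_config()
  cache <- make_b_cache()
  a <- materialize_thresholds(st, tm, cache = cache)
  b1 <- optimal_threshold(ddm_params(v = 1.2, ter = 0.3), tm,
                          method = "closed_form")$a_star
  expect_equal(a[1], b1)            # c = 0 lands exactly on the optimum
  expect_equal(a[2], b1 + 0.5)      # identical non-threshold params share b
  expect_equal(length(ls(cache)), 2)  # two unique quantized keys
  # cached quantized path vs unquantized recomputation
  st2 <- data.frame(v = 1.213, ter = 0.296, c = 0)
  a_q <- materialize_thresholds(st2, tm, cache = make_b_cache(), quantize = 0.01)
  a_full <- materialize_thresholds(st2, tm, cache = NULL, quantize = 1e-9)
  expect_lt(abs(a_q - a_full), 0.05)
})

test_that("log posterior decomposes into likelihood, group, and hyper terms", {
  set.seed(20)
  exp1 <- generate_experiment(
    list(group_spec("A", n_participants = 3, threshold_decay = 0),
         group_spec("B", n_participants = 3, threshold_decay = 0)),
    experiment_design("fixed_trial", n_blocks = 1, block_budget = 30), seed = 4)
  trials <- filter_trials(exp1$trials)
  model <- difference_model(trials)
  P <- length(model$participants)
  theta <- matrix(rep(c(1.1, 0.25, 0.4), each = P), P,
                  dimnames = list(NULL, model$theta_names))
  phi <- setNames(c(1.2, 0.3, 0.3, 0.05, 0.4, 0.1, 0.3), model$phi_names)
  lp <- log_posterior(model, list(theta = theta, phi = phi))
  # independent recomposition from the exported pieces
  tm <- model$timing
  b <- materialize_thresholds(data.frame(v = theta[, "v"], ter = theta[, "ter"],
                                         c = theta[, "c"]), tm)
  ll <- sum(vapply(seq_len(P), function(j) {
    pt <- model$participants[[j]]
    full_ddm_log_likelihood(data.frame(rt = pt$rt, boundary = ifelse(pt$upper, "upper", "lower")),
                            ddm_params(v = 1.1, a = b[j], z_rel = 0.5, ter = 0.25))
  }, numeric(1)))
  gd <- sum(vapply(seq_len(P), function(j)
    rrddm:::group_logpdf(model, theta[j, ], phi, model$group_index[j]),
    numeric(1)))
  hy <- rrddm:::hyper_logpdf(model, phi)
  expect_equal(lp, ll + gd + hy, tolerance = 1e-8)
})

test_that("invariant violations drive the log posterior to -Inf", {
  exp1 <- generate_experiment(
    list(group_spec("A", n_participants = 2, threshold_decay = 0)),
    experiment_design("fixed_trial", n_blocks = 1, block_budget = 20), seed = 5)
  model <- difference_model(filter_trials(exp1$trials))
  P <- length(model$participants)
  theta <- matrix(rep(c(1.1, 0.25, 0.4), each = P), P,
                  dimnames = list(NULL, model$theta_names))
  phi <- setNames(c(1.2, 0.3, 0.3, 0.05, 0.4, 0.3), model$phi_names)
  expect_true(is.finite(log_posterior(model, list(theta = theta, phi = phi))))
  # c so negative that a_i = b_i + c_i <= 0
  theta_bad <- theta; theta_bad[1, "c"] <- -5
  expect_identical(log_posterior(model, list(theta = theta_bad, phi = phi)), -Inf)
  # non-positive group SD
  phi_bad <- phi; phi_bad["sigma_v"] <- -0.1
  expect_identical(log_posterior(model, list(theta = theta, phi = phi_bad)), -Inf)
  # dimension mismatch is an input error
  expect_error(log_posterior(model, list(theta = theta[, 1:2], phi = phi)),
               "dimensions")
})

test_that("degenerate hierarchy reduces to likelihood plus a constant", {
  exp1 <- generate_experiment(
    list(group_spec("A", n_participants = 1, threshold_decay = 0)),
    experiment_design("fixed_trial", n_blocks = 1, block_budget = 40), seed = 6)
  model <- difference_model(filter_trials(exp1$trials))
  phi <- setNames(c(1.2, 0.3, 0.3, 0.05, 0.4, 0.3), model$phi_names)
  th1 <- matrix(c(1.1, 0.25, 0.4), 1, dimnames = list(NULL, model$theta_names))
  th2 <- matrix(c(1.3, 0.28, 0.2), 1, dimnames = list(NULL, model$theta_names))
  lik <- function(th) {
    pt <- model$participants[[1]]
    b <- materialize_thresholds(data.frame(v = th[1], ter = th[2], c = th[3]),
                                model$timing)
    full_ddm_log_likelihood(
      data.frame(rt = pt$rt, boundary = ifelse(pt$upper, "upper", "lower")),
      ddm_params(v = th[1], a = b, z_rel = 0.5, ter = th[2]))
  }
  # with phi held fixed, posterior differences equal likelihood differences
  # plus group-density differences (the hierarchy's only theta-dependence)
  d_post <- log_posterior(model, list(theta = th1, phi = phi)) -
    log_posterior(model, list(theta = th2, phi = phi))
  d_ll <- lik(th1[1, ]) - lik(th2[1, ])
  d_gd <- rrddm:::group_logpdf(model, th1[1, ], phi, 1) -
    rrddm:::group_logpdf(model, th2[1, ], phi, 1)
  expect_equal(d_post, d_ll + d_gd, tolerance = 1e-8)
})

test_that("posterior is invariant to participant relabelling", {
  exp1 <- generate_experiment(
    list(group_spec("A", n_participants = 4, threshold_decay = 0)),
    experiment_design("fixed_trial", n_blocks = 1, block_budget = 20), seed = 7)
  trials <- filter_trials(exp1$trials)
  model <- difference_model(trials)
  P <- length(model$participants)
  set.seed(30)
  theta <- cbind(v = runif(P, 0.9, 1.3), ter = runif(P, 0.2, 0.3),
                 c = runif(P, 0.2, 0.6))
  phi <- setNames(c(1.2, 0.3, 0.3, 0.05, 0.4, 0.3), model$phi_names)
  lp1 <- log_posterior(model, list(theta = theta, phi = phi))
  # relabel: permute participants (and their thetas) together
  perm <- c(3, 1, 4, 2)
  trials2 <- trials
  relabel <- setNames(paste0("q", seq_len(P)), unique(trials$participant)[perm])
  trials2$participant <- relabel[trials2$participant]
  model2 <- difference_model(trials2)
  ord2 <- match(vapply(model2$participants, `[[`, character(1), "id"),
                paste0("q", seq_len(P)))
  theta2 <- theta[perm, , drop = FALSE][ord2, , drop = FALSE]
  lp2 <- log_posterior(model2, list(theta = theta2, phi = phi))
  expect_equal(lp1, lp2, tolerance = 1e-10)
})

test_that("block-threshold model exposes per-block group distributions", {
  exp1 <- generate_experiment(
    list(group_spec("A", n_participants = 3, threshold_decay = 0)),
    experiment_design("fixed_trial", n_blocks = 3, block_budget = 10), seed = 9)
  model <- block_threshold_model(filter_trials(exp1$trials))
  expect_equal(model$n_blocks, 3)
  expect_true(all(c("a_b1", "a_b2", "a_b3") %in% model$theta_names))
  expect_true(all(c("mu_a_b3", "sigma_a_b3") %in% model$phi_names))
  P <- length(model$participants)
  theta <- matrix(rep(c(1.1, 0.25, 1.2, 1.1, 1.0), each = P), P,
                  dimnames = list(NULL, model$theta_names))
  phi <- setNames(c(1.2, 0.3, 0.3, 0.05, rep(1.2, 3), rep(0.2, 3)),
                  model$phi_names)
  expect_true(is.finite(log_posterior(model, list(theta = theta, phi = phi))))
  theta_bad <- theta; theta_bad[2, "a_b2"] <- -0.5
  expect_identical(log_posterior(model, list(theta = theta_bad, phi = phi)), -Inf)
})

test_that("full-variant models and simulation-based optima are usable", {
  # simulation path of the optimal threshold agrees with closed form when
  # the variabilities are zero (coarse scan plus local refinement)
  tm <- timing_config()
  cache <- make_b_cache()
  b_sim <- rrddm:::b_optimal(1.2, 0.5, 0.3, 0, 0, 0, tm,
                             seq(0.01, 4, by = 0.01),
                             sim_config(n_trials = 2000, seed = 3),
                             method = "simulation", cache = cache)
  b_cf <- rrddm:::b_optimal(1.2, 0.5, 0.3, 0, 0, 0, tm,
                            seq(0.01, 4, by = 0.01), sim_config(),
                            method = "closed_form", cache = NULL)
  expect_lt(abs(b_sim - b_cf), 0.3)
  # full-variant difference model: finite log posterior through the
  # simulation-based b_i path
  e <- generate_experiment(
    list(group_spec("A", n_participants = 2, sv_mean = 0.6,
                    ster_mean = 0.1, threshold_decay = 0)),
    experiment_design("fixed_trial", n_blocks = 1), seed = 15)
  tr <- filter_trials(e$trials)
  m <- difference_model(tr, variant = "full", b_method = "simulation",
                        grid = seq(0.05, 3, by = 0.05),
                        b_config = sim_config(n_trials = 300, seed = 4))
  theta <- matrix(rep(c(1.1, 0.3, 0.4, 0.5, 0.1, 0.08), each = 2), 2,
                  dimnames = list(NULL, m$theta_names))
  phi <- setNames(c(1.2, 0.3, 0.3, 0.05, 0.5, 0.2, 0.1, 0.05, 0.08, 0.04,
                    0.4, 0.3), m$phi_names)
  expect_true(is.finite(log_posterior(m, list(theta = theta, phi = phi))))
  # closed-form b_i is refused when variabilities are free
  expect_error(difference_model(tr, variant = "full",
                                b_method = "closed_form"), "simulation")
  expect_error(optimal_threshold(ddm_params(v = 1, sv = 0.5),
                                 method = "closed_form"), "sv")
})
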