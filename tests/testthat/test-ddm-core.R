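# Simulator, closed-form oracles, and first-passage-time density machinery.

test_that("parameter and config invariants are enforced", {
  expect_error(ddm_params(v = 1, a = 0), "'a'")
  expect_error(ddm_params(v = 1, a = 1, z_rel = 1), "z_rel")
  expect_error(ddm_params(v = 1, a = 1, ter = 0.05, ster = 0.2), "ter")
  expect_error(ddm_params(v = 1, a = 1, z_rel = 0.5, sz_rel = 1.0), "z_rel")
  expect_error(ddm_params(v = 1, a = 1, sv = -1), "variability")
  expect_error(sim_config(dt = 0.02, max_decision_time = 0.01), "max_decision_time")
  expect_error(sim_config(dt = 0), "dt")
})

test_that("closed-form choice probability matches hand-computed values", {
  # 1 / (1 + exp(-1)), evaluated independently
  expect_equal(closed_form_pc(1, 1, 0.5, 1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(closed_form_pc(0, 1.7, 0.37), 0.37)       # drift-free limit
  expect_equal(closed_form_pc(1e-12, 2, 0.5), 0.5)       # continuity at v = 0
  expect_error(closed_form_pc(1, -1, 0.5), "'a'")
})

test_that("choice probability obeys reflection symmetry", {
  set.seed(11)
  for (i in 1:25) {
    v <- rnorm(1); a <- runif(1, 0.2, 3); z <- runif(1, 0.05, 0.95)
    expect_equal(closed_form_pc(v, a, z) + closed_form_pc(-v, a, 1 - z), 1,
                 tolerance = 1e-10)
  }
})

test_that("closed-form mean decision time matches hand-computed values", {
  expect_equal(closed_form_mean_dt(1, 1, 0.5, 1), 0.5 * tanh(0.5),
               tolerance = 1e-12)
  expect_equal(closed_form_mean_dt(1e-9, 1, 0.5, 1), 0.25, tolerance = 1e-6)
  # general-z drift-free limit: z (a - z) / s^2
  expect_equal(closed_form_mean_dt(1e-10, 2, 0.3), 0.6 * 1.4, tolerance = 1e-5)
})

test_that("overwhelming drift sends every finished trial to the upper boundary", {
  sim <- simulate_trials(ddm_params(v = 100, a = 1, ter = 0.2),
                         sim_config(n_trials = 500, seed = 5))
  done <- sim[!sim$timed_out, ]
  expect_true(all(done$boundary == "upper"))
  expect_true(all(done$rt >= done$decision_time))
})

test_that("zero drift splits boundaries near 50/50", {
  sim <- simulate_trials(ddm_params(v = 0, a = 1, ter = 0.2),
                         sim_config(n_trials = 10000, seed = 7))
  p <- mean(sim$boundary == "upper", na.rm = TRUE)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("simulated choice probability and mean DT converge to closed form as dt shrinks", {
  p <- ddm_params(v = 1, a = 1, z_rel = 0.5, ter = 0)
  pc_true <- closed_form_pc(1, 1, 0.5)
  dt_true <- closed_form_mean_dt(1, 1, 0.5)
  bias_pc <- bias_dt <- numeric(2)
  for (k in 1:2) {
    dtv <- c(0.01, 0.001)[k]
    sim <- simulate_trials(p, sim_config(dt = dtv, n_trials = 50000, seed = 21))
    bias_pc[k] <- abs(mean(sim$boundary == "upper", na.rm = TRUE) - pc_true)
    bias_dt[k] <- abs(mean(sim$decision_time) - dt_true)
  }
  expect_lt(bias_pc[2], bias_pc[1] + 3 * sqrt(0.25 / 50000))
  expect_lt(bias_dt[2], bias_dt[1])
  # at dt = 1 ms the upper-boundary proportion is within 3 binomial SEs
  expect_lt(bias_pc[2], 3 * sqrt(pc_true * (1 - pc_true) / 50000))
})

test_that("identical seeds reproduce trials bit-for-bit; different seeds do not", {
  p <- ddm_params(v = 1.2, a = 1.3, ter = 0.3, sv = 0.6, sz_rel = 0.1, ster = 0.1)
  s1 <- simulate_trials(p, sim_config(n_trials = 200, seed = 99))
  s2 <- simulate_trials(p, sim_config(n_trials = 200, seed = 99))
  s3 <- simulate_trials(p, sim_config(n_trials = 200, seed = 100))
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("Wiener density integrates to 1 and to the closed-form choice probability", {
  for (p in simple_param_grid()) {
    fu <- function(t) exp(wfpt_log_density(t, "upper", p$v, p$a, p$z_rel, p$s))
    fl <- function(t) exp(wfpt_log_density(t, "lower", p$v, p$a, p$z_rel, p$s))
    up <- integrate(fu, 1e-9, 20, rel.tol = 1e-9)$value
    lo <- integrate(fl, 1e-9, 20, rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, closed_form_pc(p$v, p$a, p$z_rel, p$s), tolerance = 1e-4)
  }
  expect_error(wfpt_log_density(-0.1, "upper", 1, 1), "'t'")
})

test_that("simulated RTs match the Wiener density (KS distance and histogram)", {
  p <- ddm_params(v = 1.2, a = 1.2, z_rel = 0.5, ter = 0)
  sim <- simulate_trials(p, sim_config(dt = 0.001, n_trials = 50000, seed = 13))
  up <- sim[!sim$timed_out & sim$boundary == "upper", "decision_time"]
  pc <- closed_form_pc(p$v, p$a, p$z_rel)
  # conditional CDF of upper-boundary decision times via quadrature
  f <- function(t) exp(wfpt_log_density(t, "upper", p$v, p$a, p$z_rel))
  ts <- sort(up)
  qs <- seq(0.05, 0.95, by = 0.05)
  emp_q <- quantile(up, qs)
  cdf_at <- vapply(emp_q, function(q)
    integrate(f, 1e-9, q, rel.tol = 1e-8)$value / pc, numeric(1))
  expect_lt(max(abs(cdf_at - qs)), 0.02)
  # bin-mass agreement on 10 equal-probability bins: each empirical decile
  # bin should hold the model-implied mass within Monte-Carlo error
  br <- quantile(up, seq(0, 1, by = 0.1))
  counts <- hist(up, breaks = br, plot = FALSE)$counts
  model_mass <- vapply(seq_len(10), function(k)
    integrate(f, br[k], br[k + 1], rel.tol = 1e-8)$value / pc, numeric(1))
  expect_lt(max(abs(counts / length(up) - model_mass)), 0.01)
})

test_that("full-DDM likelihood reduces exactly to the Wiener density without variabilities", {
  d <- data.frame(rt = c(0.45, 0.62, 0.80, 1.30),
                  boundary = c("upper", "lower", "upper", "upper"))
  p <- ddm_params(v = 1.1, a = 1.3, z_rel = 0.45, ter = 0.30)
  ll <- full_ddm_log_likelihood(d, p)
  ref <- sum(wfpt_log_density(d$rt - p$ter, d$boundary, p$v, p$a, p$z_rel))
  expect_equal(ll, ref, tolerance = 1e-12)
  expect_error(full_ddm_log_likelihood(d[0, ], p), "non-empty")
})

test_that("full-DDM density integrates to 1 for variability parameter sets", {
  for (p in full_param_grid()) {
    f <- function(t) rrddm:::full_ddm_density(t, "upper", p) +
      rrddm:::full_ddm_density(t, "lower", p)
    lo <- p$ter - p$ster / 2 + 1e-9
    total <- integrate(f, lo, 30, rel.tol = 1e-7)$value
    expect_equal(total, 1, tolerance = 1e-3)
  }
})

test_that("likelihood prefers the generating drift over shifted drifts", {
  p <- ddm_params(v = 1.2, a = 1.2, ter = 0.3)
  wins <- 0
  for (r in 1:20) {
    sim <- simulate_trials(p, sim_config(dt = 0.005, n_trials = 1000,
                                         seed = 4000 + r))
    d <- data.frame(rt = sim$rt[!sim$timed_out],
                    boundary = sim$boundary[!sim$timed_out])
    ll0 <- full_ddm_log_likelihood(d, p)
    llm <- full_ddm_log_likelihood(d, ddm_params(v = 0.6, a = 1.2, ter = 0.3))
    llp <- full_ddm_log_likelihood(d, ddm_params(v = 1.8, a = 1.2, ter = 0.3))
    if (ll0 > llm && ll0 > llp) wins <- wins + 1
  }
  expect_gte(wins, 19)
})
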