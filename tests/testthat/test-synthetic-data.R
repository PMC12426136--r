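# Synthetic-experiment generator: participant sampling, block simulation,
# design budgets, ground truth, and downstream consistency.

test_that("participant draws respect the spec and its degenerate limits", {
  sp0 <- group_spec("G", n_participants = 6, v_sd = 0, ter_sd = 0, a_sd = 0)
  d0 <- sample_participants(sp0, seed = 1)
  expect_true(all(d0$v == d0$v[1]) && all(d0$ter == d0$ter[1]))
  expect_equal(d0$v[1], 1.1)
  sp <- group_spec("G", n_participants = 10000, v_sd = 0.25, ter_sd = 0.05)
  d <- sample_participants(sp, seed = 2)
  # truncation at 0.05 barely bites at these means: 3-SE law-of-large-numbers
  expect_lt(abs(mean(d$v) - 1.1), 3 * 0.25 / sqrt(10000) + 0.005)
  expect_lt(abs(mean(d$ter) - 0.35), 3 * 0.05 / sqrt(10000) + 0.002)
  # every draw satisfies the diffusion-parameter invariants
  expect_true(all(d$v > 0 & d$ter > 0 & d$z_rel > 0 & d$z_rel < 1))
  expect_true(all(d$sv >= 0 & d$sz_rel >= 0 & d$ster >= 0))
  expect_true(all(d$ter >= d$ster / 2))
  expect_true(all(d$b_opt > 0))
  # infeasible truncation is an error
  expect_error(sample_participants(group_spec("G", 2, v_mean = -50, v_sd = 1),
                                   seed = 1), "mass")
})

test_that("fixed-trial blocks contain exactly the budgeted trials", {
  des <- experiment_design("fixed_trial", n_blocks = 2)
  pars <- list(v = 1.1, z_rel = 0.5, ter = 0.35, sv = 0, sz_rel = 0, ster = 0,
               a = 1.4)
  b <- simulate_fixed_trial_block(pars, des, block = 1, seed = 11)
  expect_equal(nrow(b), 40)
  expect_true(all(b$block == 1))
  expect_setequal(unique(b$choice), c("left", "right"))
  expect_equal(sum(b$choice == "left") + sum(b$choice == "right"), 40)
  # huge drift: essentially perfect accuracy
  fast <- simulate_fixed_trial_block(c(pars[names(pars) != "v"], v = 40),
                                     des, 1, seed = 12)
  expect_gt(mean(fast$correct), 0.97)
})

test_that("declining threshold trajectories show up as declining RTs", {
  sp <- group_spec("G", n_participants = 6, threshold_initial = 2.2,
                   threshold_asymptote = 0.9, threshold_decay = 0.35,
                   a_sd = 0)
  exp1 <- generate_experiment(list(sp),
                              experiment_design("fixed_trial", n_blocks = 8),
                              seed = 21)
  mrt <- tapply(exp1$trials$rt, exp1$trials$block, mean)
  expect_gt(mrt[1], mrt[8])
  expect_lt(cor(as.numeric(names(mrt)), mrt), -0.8)
})

test_that("fixed-time blocks respect the time budget", {
  tmg <- timing_config(iti = 0.5, fdt = 0.5, et = 1.0)
  des <- experiment_design("fixed_time", n_blocks = 1, timing = tmg)
  # near-deterministic 2.0-s wall time: v huge makes rt ~ ter = 1.0 exactly,
  # all correct, so wall = 1.0 + 0.5 + 0.5 = 2.0 and 30 trials fit
  pars <- list(v = 500, z_rel = 0.5, ter = 1.0, sv = 0, sz_rel = 0, ster = 0,
               a = 0.5)
  b <- simulate_fixed_time_block(pars, des, 1, seed = 31)
  expect_equal(nrow(b), 30)
  # Wald-style check: expected count ~ budget / E[wall time]
  pars2 <- list(v = 1.1, z_rel = 0.5, ter = 0.35, sv = 0, sz_rel = 0,
                ster = 0, a = 1.4)
  counts <- vapply(1:200, function(s)
    nrow(simulate_fixed_time_block(pars2, des, 1, seed = s)), numeric(1))
  pc <- closed_form_pc(1.1, 1.4, 0.5)
  wall <- closed_form_mean_dt(1.1, 1.4, 0.5) + 0.35 + 1.0 + (1 - pc) * 1.0
  expected <- 60 / wall
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(200) + 1)
  # slower parameter set yields fewer trials on paired seeds
  slow <- vapply(1:50, function(s)
    nrow(simulate_fixed_time_block(c(pars2[names(pars2) != "a"], a = 2.8),
                                   des, 1, seed = s)), numeric(1))
  expect_lt(mean(slow), mean(counts[1:50]))
})

test_that("experiments regenerate byte-identically and round-trip cleanly", {
  specs <- list(group_spec("A", n_participants = 3),
                group_spec("B", n_participants = 3))
  des <- experiment_design("fixed_trial", n_blocks = 2)
  e1 <- generate_experiment(specs, des, seed = 41)
  e2 <- generate_experiment(specs, des, seed = 41)
  f1 <- tempfile(); f2 <- tempfile()
  write_trials(e1$trials, f1); write_trials(e2$trials, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_experiment(list(group_spec("A", 2), group_spec("A", 2)),
                                   des, seed = 1), "unique")
  # default healthy cohort: no exclusions downstream
  tr <- filter_trials(e1$trials)
  kept <- exclude_participants(participant_summaries(tr), "fixed_trial")
  expect_equal(nrow(kept), 6)
  expect_equal(nrow(attr(kept, "excluded")), 0)
})

test_that("planted low-accuracy participants are exactly the ones excluded", {
  specs <- list(group_spec("good", n_participants = 4),
                group_spec("bad", n_participants = 3, v_mean = 0.06,
                           v_sd = 0, threshold_initial = 0.4,
                           threshold_decay = 0, a_sd = 0))
  e <- generate_experiment(specs, experiment_design("fixed_trial", n_blocks = 4),
                           seed = 51)
  tr <- filter_trials(e$trials)
  kept <- exclude_participants(participant_summaries(tr), "fixed_trial")
  excl <- attr(kept, "excluded")$participant
  expect_setequal(excl, paste0("bad_p0", 1:3))
})

test_that("generated data are internally consistent with the reward-rate formula", {
  e <- generate_experiment(list(group_spec("A", n_participants = 4)),
                           experiment_design("fixed_trial", n_blocks = 3),
                           seed = 61)
  tm <- timing_config()
  s <- summarize_group(filter_trials(e$trials), tm)
  expect_equal(s$rr, reward_rate_from_summary(s$pc, s$mrt, tm), tolerance = 1e-12)
})

test_that("ground truth serializes to JSON", {
  e <- generate_experiment(list(group_spec("A", n_participants = 2)),
                           experiment_design("fixed_trial", n_blocks = 2),
                           seed = 71)
  f <- tempfile(fileext = ".json")
  write_ground_truth(e, f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(gt$participants), 2)
  expect_equal(gt$participants$v, e$ground_truth$participants$v,
               tolerance = 1e-12)
})
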