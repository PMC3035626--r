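# Model trials with a known pattern inventory on a hand-made "map".
fake_map <- function(mv) {
  structure(list(model_vectors = mv, N = NA_integer_, n = ncol(mv),
                 config = NULL),
            class = "som_map")
}

fake_mt <- function(pattern_ids, stimulus, mv, dt_ms = 1) {
  structure(list(pattern_ids = pattern_ids,
                 trial_id = seq_along(pattern_ids),
                 stimulus = stimulus,
                 n_samples = length(pattern_ids[[1]]),
                 dt_ms = dt_ms, map = fake_map(mv)),
            class = "model_trials")
}

test_that("half-splits are disjoint, exhaustive and seeded", {
  ds <- random_dataset(61, n_units = 2, n_trials = 20, TD = 100,
                       stimuli = c("a", "b"))
  plan <- split_half(ds, seed = 3)
  for (j in c("a", "b")) {
    expect_length(plan[[j]]$train, 5)     # 10 trials per stimulus
    expect_length(plan[[j]]$test, 5)
    expect_length(intersect(plan[[j]]$train, plan[[j]]$test), 0)
  }
  expect_identical(split_half(ds, seed = 3), split_half(ds, seed = 3))
  # odd trial count: extra trial goes to train
  ds5 <- random_dataset(62, n_units = 2, n_trials = 5, TD = 100,
                        stimuli = "a")
  p5 <- split_half(ds5, seed = 1)
  expect_length(p5$a$train, 3)
  expect_length(p5$a$test, 2)
  # different seeds give different plans essentially always
  plans <- vapply(1:50, function(s) {
    p <- split_half(ds, seed = s)
    paste(c(p$a$train, "|", p$b$train), collapse = ",")
  }, character(1))
  expect_gt(length(unique(plans)), 48)
})

test_that("mean-rate classifier follows the rate-vector arithmetic", {
  # 1 unit, 2 stimuli, TD = 2 s; train rates 5 Hz vs 20 Hz
  mk <- function(id, stim, n_spikes)
    spike_trial(id, stim, list(seq(0, 1999, length.out = n_spikes)))
  trials <- list(
    mk(1, "s1", 10), mk(2, "s1", 10),     # 5 Hz
    mk(3, "s2", 40), mk(4, "s2", 40),     # 20 Hz
    mk(5, "s1", 36), mk(6, "s2", 36)      # test trials at 18 Hz
  )
  ds <- spike_dataset(trials, 1, c("s1", "s2"), 2000)
  plan <- structure(list(s1 = list(train = c(1L, 2L), test = 5L),
                         s2 = list(train = c(3L, 4L), test = 6L)),
                    class = "split_plan")
  res <- mean_rate_classify(ds, plan)
  # both test trials at 18 Hz sit nearest the 20 Hz model
  expect_equal(res$predicted, c("s2", "s2"))
  expect_equal(res$stimulus, c("s1", "s2"))
  # MR entry check via the public API: 100 spikes over 10 train trials of
  # TD = 2 s -> 5 Hz
  ds10 <- spike_dataset(lapply(1:10, function(k) mk(k, "s1", 10)),
                        1, "s1", 2000)
  expect_equal(unname(rowSums(spike_count_matrix(ds10))), rep(10, 10))
  expect_equal(sum(spike_count_matrix(ds10)) / (2 * 10), 5)
})

test_that("identical test and model rate vectors decode with distance 0", {
  mk <- function(id, stim, n_spikes)
    spike_trial(id, stim, list(seq(0, 999, length.out = n_spikes)))
  ds <- spike_dataset(list(mk(1, "s1", 8), mk(2, "s1", 8),
                           mk(3, "s2", 30), mk(4, "s2", 30),
                           mk(5, "s1", 8)),
                      1, c("s1", "s2"), 1000)
  plan <- structure(list(s1 = list(train = c(1L, 2L), test = 5L),
                         s2 = list(train = c(3L, 4L), test = integer(0))),
                    class = "split_plan")
  expect_equal(mean_rate_classify(ds, plan)$predicted, "s1")
})

test_that("specificity classifier scores are count-weighted specificities", {
  mv <- diag(2)
  # train: pattern 0 exclusive to s1, pattern 1 exclusive to s2
  mt <- fake_mt(list(rep(0L, 10), rep(1L, 10),
                     c(rep(0L, 4), rep(1L, 6)),   # test: r = (4, 6)
                     rep(0L, 10)),                # test: only s1's pattern
                c("s1", "s2", "s1", "s2"), mv)
  plan <- structure(list(s1 = list(train = 1L, test = 3L),
                         s2 = list(train = 2L, test = 4L)),
                    class = "split_plan")
  res <- specificity_classify(mt, plan)
  # trial 3: scores (4, 6) -> s2; trial 4: pattern exclusive to s1 -> s1
  expect_equal(res$predicted[res$trial_id == 3], "s2")
  expect_equal(res$predicted[res$trial_id == 4], "s1")
})

test_that("uniform specificities tie and resolve to the first stimulus", {
  mv <- diag(2)
  mt <- fake_mt(list(rep(0L, 10), rep(0L, 10), rep(0L, 10)),
                c("s1", "s2", "s1"), mv)
  plan <- structure(list(s1 = list(train = 1L, test = 3L),
                         s2 = list(train = 2L, test = integer(0))),
                    class = "split_plan")
  expect_equal(specificity_classify(mt, plan)$predicted, "s1")
})

test_that("trajectories average model vectors over windows", {
  mv <- rbind(c(0, 2), c(4, 0))
  # constant sequence -> every window equals that pattern's model vector
  tr <- build_trajectory(rep(0L, 12), fake_map(mv), tau_bins = 4)
  expect_equal(nrow(tr), 3)
  expect_true(all(apply(tr, 1, function(r) all(r == c(0, 2)))))
  # equal counts of both patterns in one window -> mean (2, 1)
  tr2 <- build_trajectory(c(0L, 1L, 0L, 1L), fake_map(mv), tau_bins = 4)
  expect_equal(unname(tr2[1, ]), c(2, 1))
  # window counts: 1200 samples, 20-bin windows -> 60; trailing partial drop
  expect_equal(nrow(build_trajectory(rep(0L, 1200), fake_map(mv), 20)), 60)
  expect_equal(nrow(build_trajectory(rep(0L, 130), fake_map(mv), 20)), 6)
  expect_error(build_trajectory(rep(0L, 10), fake_map(mv), 11), "exceeds")
})

test_that("sliding windows follow the requested step", {
  mv <- rbind(c(0, 2), c(4, 0))
  tr <- build_trajectory(rep(0L, 100), fake_map(mv), tau_bins = 20,
                         step_bins = 5)
  expect_equal(nrow(tr), 17)               # (100 - 20)/5 + 1
  expect_equal(attr(tr, "time_ms")[1:2], c(10, 15))
})

test_that("model trajectories are window-wise means of train trajectories", {
  set.seed(71)
  mv <- matrix(runif(12), 4, 3)
  ids <- replicate(6, sample(0:3, 40, replace = TRUE), simplify = FALSE)
  trajs <- lapply(ids, build_trajectory, map = fake_map(mv), tau_bins = 8)
  labels <- rep(c("a", "b"), each = 3)
  mod <- model_trajectories(trajs, labels)
  # naive per-window loop oracle
  for (j in c("a", "b")) {
    sel <- which(labels == j)
    for (w in 1:5) {
      oracle <- colMeans(do.call(rbind, lapply(trajs[sel],
                                               function(t) t[w, ])))
      expect_equal(mod$MT[[j]][w, ], oracle)
    }
  }
  # single train trial: model equals the trajectory
  mod1 <- model_trajectories(trajs[1], "a")
  expect_equal(mod1$MT$a, trajs[[1]], ignore_attr = TRUE)
  expect_error(model_trajectories(list(trajs[[1]], trajs[[2]][1:2, ]),
                                  c("a", "a")), "mismatch")
})

test_that("trajectory distances match the brute-force window loop", {
  set.seed(73)
  mv <- matrix(runif(12), 4, 3)
  ids <- replicate(5, sample(0:3, 30, replace = TRUE), simplify = FALSE)
  trajs <- lapply(ids, build_trajectory, map = fake_map(mv), tau_bins = 6)
  mod <- model_trajectories(trajs[1:4], c("a", "a", "b", "b"))
  pred <- trajectory_classify(trajs[5], mod)
  D <- attr(pred, "distances")
  for (j in 1:2) {
    oracle <- 0
    for (w in 1:5)
      oracle <- oracle + sqrt(sum((trajs[[5]][w, ] -
                                     mod$MT[[j]][w, ])^2))
    expect_equal(D[1, j], oracle)
  }
  # exact-model test trajectory decodes to its stimulus with distance 0
  pred_a <- trajectory_classify(list(mod$MT$a), mod)
  expect_equal(as.character(pred_a), "a")
  expect_equal(attr(pred_a, "distances")[1, 1], 0)
  # 1-window, 1-D hand case: MVA = 3 vs models 1 and 4
  mod1 <- structure(list(MT = list(s1 = matrix(1), s2 = matrix(4)),
                         stimulus_set = c("s1", "s2"), Nw = 1,
                         time_ms = 0.5),
                    class = "trajectory_model")
  p <- trajectory_classify(list(matrix(3)), mod1)
  expect_equal(as.character(p), "s2")
  expect_equal(attr(p, "distances")[1, ], c(2, 1))
})

test_that("the harness is at chance for degenerate and shuffled problems", {
  # a constant-pattern dataset carries no information: all classifiers
  # must sit at chance on balanced splits up to split noise
  mv <- diag(2)
  set.seed(83)
  ds <- random_dataset(83, n_units = 2, n_trials = 24, TD = 200,
                       rate_hz = 30, stimuli = c("a", "b", "c", "d"))
  mt <- fake_mt(replicate(24, rep(0L, 200), simplify = FALSE),
                trial_labels(ds), mv)
  perf <- run_performance(ds, mt, classifiers = "specificity",
                          n_splits = 60, seed = 5)
  # constant patterns -> all scores tie -> always "a" -> exactly 1/s
  expect_equal(perf$performance$mean, 0.25, tolerance = 1e-12)
  expect_equal(perf$performance$chance, 0.25)
})

test_that("an oracle-separable dataset is decoded perfectly by all three", {
  # each stimulus drives a disjoint unit set at high rate
  set.seed(91)
  n_per <- 6
  trials <- list()
  for (j in 1:3) for (r in 1:n_per) {
    spikes <- lapply(1:6, function(u) {
      if ((u - 1) %/% 2 + 1 == j) sort(runif(60, 0, 400)) else numeric(0)
    })
    trials[[length(trials) + 1]] <-
      spike_trial(length(trials) + 1, paste0("s", j), spikes)
  }
  ds <- spike_dataset(trials, 6, c("s1", "s2", "s3"), 400)
  pp <- pattern_pipeline(ds, tau_ms = 20, som_config(N = 4, M = 20000,
                                                     seed = 7))
  perf <- run_performance(ds, pp$model_trials,
                          classifiers = c("rate", "specificity",
                                          "trajectory"),
                          tau_bins = 20, n_splits = 20, seed = 11)
  expect_equal(unname(perf$performance$mean), rep(1, 3))
})

test_that("per-split mean stays within the binomial SE of the expectation", {
  # degenerate always-"a" decoding has per-split expectation 1/s exactly;
  # the mean over splits must agree to machine precision, and a noisy
  # specificity problem must stay within ~3 binomial SEs of 1/2
  set.seed(93)
  ds <- random_dataset(93, n_units = 2, n_trials = 30, TD = 150,
                       rate_hz = 40, stimuli = c("a", "b"))
  mt <- fake_mt(replicate(30, sample(0:9, 150, replace = TRUE),
                          simplify = FALSE),
                trial_labels(ds), diag(2)[c(1, 1), ])
  perf <- run_performance(ds, mt, classifiers = "specificity",
                          n_splits = 80, seed = 17)
  # splits reuse the same 30 trials, so the effective sample size for the
  # split-averaged mean is the trial count, not splits x test trials
  se_eff <- sqrt(0.5 * 0.5 / 30)
  expect_lt(abs(perf$performance$mean - 0.5), 3 * se_eff)
})

test_that("time-resolved distances equal the per-trial per-stimulus loop", {
  set.seed(101)
  mv <- matrix(runif(12), 4, 3)
  ids <- replicate(7, sample(0:3, 60, replace = TRUE), simplify = FALSE)
  trajs <- lapply(ids, build_trajectory, map = fake_map(mv),
                  tau_bins = 10, step_bins = 5)
  mod <- model_trajectories(trajs[1:4], c("a", "a", "b", "b"))
  d <- time_resolved_distances(trajs[5:7], mod, ts = "a")
  Nw <- mod$Nw
  for (w in c(1, 4, Nw)) {
    dT_o <- sapply(5:7, function(l)
      sqrt(sum((trajs[[l]][w, ] - mod$MT$a[w, ])^2)))
    dO_o <- sapply(5:7, function(l)
      sqrt(sum((trajs[[l]][w, ] - mod$MT$b[w, ])^2)))
    expect_equal(d$d_true[w], mean(dT_o))
    expect_equal(d$d_other[w], mean(dO_o))
    expect_equal(d$sd_true[w], sd(dT_o))
    expect_equal(d$sd_other[w], sd(dO_o))
  }
  # trajectories identical to every model -> all distances 0
  same <- structure(list(MT = list(a = trajs[[1]], b = trajs[[1]]),
                         stimulus_set = c("a", "b"), Nw = Nw,
                         time_ms = mod$time_ms),
                    class = "trajectory_model")
  d0 <- time_resolved_distances(list(trajs[[1]], trajs[[1]]), same, "a")
  expect_true(all(d0$d_true == 0 & d0$d_other == 0))
})

test_that("Cohen's d timecourse follows the pooled-SD formula and flips sign", {
  expect_equal(cohens_d_timecourse(1, 1, 0.5, 0.5), 0)
  expect_equal(cohens_d_timecourse(1, 1 + sqrt((0.3^2 + 0.4^2) / 2),
                                   0.3, 0.4), 1)
  # oracle on arrays
  set.seed(103)
  dT <- runif(10); dO <- runif(10); sT <- runif(10); sO <- runif(10)
  expect_equal(cohens_d_timecourse(dT, dO, sT, sO),
               (dO - dT) / sqrt((sT^2 + sO^2) / 2))
  # relabeling to a wrong stimulus flips the sign
  expect_equal(cohens_d_timecourse(dO, dT, sO, sT),
               -cohens_d_timecourse(dT, dO, sT, sO))
  # degenerate zeros
  expect_equal(cohens_d_timecourse(2, 2, 0, 0), 0)
  expect_error(cohens_d_timecourse(1, 2, -0.1, 0.5), ">= 0")
})

test_that("effect-size timecourse separates structured stimuli", {
  # two stimuli driving disjoint unit pairs -> positive Cohen's d
  set.seed(107)
  trials <- list()
  for (j in 1:2) for (r in 1:8) {
    spikes <- lapply(1:4, function(u) {
      if ((u - 1) %/% 2 + 1 == j) sort(runif(40, 0, 300)) else numeric(0)
    })
    trials[[length(trials) + 1]] <-
      spike_trial(length(trials) + 1, paste0("s", j), spikes)
  }
  ds <- spike_dataset(trials, 4, c("s1", "s2"), 300)
  pp <- pattern_pipeline(ds, 20, som_config(N = 3, M = 10000, seed = 3))
  es <- effect_size_timecourse(pp$model_trials, tau_bins = 20,
                               step_bins = 5, seed = 9)
  expect_true(all(c("stimulus", "time_ms", "cohens_d") %in% names(es)))
  expect_gt(mean(es$cohens_d), 1)
})

test_that("one-sample Z-test matches hand arithmetic and the null", {
  # hand case: n = 100, mean 1, mu0 = 0, sd = sqrt(100/99)
  x <- c(rep(0, 50), rep(2, 50))
  z <- one_sample_z(x, 0)
  expect_equal(z$z, 10 * sqrt(99 / 100))    # = 9.94987...
  expect_lt(z$p, 1e-20)
  # mean equal to mu0 -> z = 0, p = 1
  z0 <- one_sample_z(c(-1, 1), 0)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  # p approximately uniform under the null
  set.seed(109)
  ps <- replicate(400, one_sample_z(rnorm(50, 5, 2), 5)$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_error(one_sample_z(c(1, 1), 1), "zero standard deviation")
  expect_error(one_sample_z(1, 0), "at least 2")
})
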