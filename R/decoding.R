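#' Random half-split of trials into train and test sets
#'
#' Independently for each stimulus, trials are split uniformly at random
#' into disjoint train/test halves; with an odd trial count the extra trial
#' goes to the training set.
#'
#' @param ds a [spike_dataset()] (every stimulus needs `>= 2` trials).
#' @param seed integer seed.
#' @return An object of class `split_plan`: named list (per stimulus) of
#'   `train`/`test` trial-id vectors, plus attribute `seed`.
#' @export
split_half <- function(ds, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  labs <- trial_labels(ds)
  ids <- vapply(ds$trials, function(tr) tr$trial_id, integer(1))
  plan <- lapply(ds$stimulus_set, function(j) {
    tj <- ids[labs == j]
    if (length(tj) < 2) stop("stimulus '", j, "' has fewer than 2 trials")
    n_train <- ceiling(length(tj) / 2)
    train <- sort(sample(tj, n_train))
    list(train = train, test = sort(setdiff(tj, train)))
  })
  names(plan) <- ds$stimulus_set
  structure(plan, class = "split_plan", seed = as.integer(seed))
}

plan_ids <- function(plan, which) {
  sort(unlist(lapply(plan, `[[`, which), use.names = FALSE))
}

#' Mean-rate classifier
#'
#' Computes per-stimulus model rate vectors from the training trials
#' (`MR_j(i)` = total spike count of unit `i` over train trials of `j`,
#' divided by trial duration in seconds times the number of train trials),
#' then assigns every test trial to the stimulus whose model rate vector is
#' closest in Euclidean distance to the trial's own rate vector. Distance
#' ties go to the lowest stimulus index.
#'
#' @param ds a [spike_dataset()].
#' @param plan a [split_half()] plan.
#' @return data.frame with columns `trial_id`, `stimulus` (true) and
#'   `predicted`.
#' @export
mean_rate_classify <- function(ds, plan) {
  RV <- rate_vectors(ds)
  ids <- vapply(ds$trials, function(tr) tr$trial_id, integer(1))
  MR <- t(vapply(names(plan), function(j) {
    tr_rows <- match(plan[[j]]$train, ids)
    if (!length(tr_rows)) stop("empty training set for stimulus ", j)
    colMeans(RV[tr_rows, , drop = FALSE])
  }, numeric(ds$n)))
  dim(MR) <- c(length(plan), ds$n)
  test_ids <- plan_ids(plan, "test")
  rows <- match(test_ids, ids)
  pred <- vapply(rows, function(r) {
    d2 <- rowSums(sweep(MR, 2, RV[r, ])^2)
    which.min(d2)                           # ties -> lowest stimulus index
  }, integer(1))
  data.frame(trial_id = test_ids,
             stimulus = trial_labels(ds)[rows],
             predicted = names(plan)[pred],
             stringsAsFactors = FALSE)
}

# Per-trial mean firing-rate vectors in Hz (trials x units).
rate_vectors <- function(ds) {
  spike_count_matrix(ds) / (ds$trial_duration_ms / 1000)
}

#' Specificity classifier
#'
#' Pattern specificities are computed on the training trials only; each
#' test trial `l` then receives a score per stimulus,
#' `SCORE_l(j) = sum_p r_l(p) * SP_p(j)` over the patterns `p` expressed in
#' the trial (patterns unseen in training contribute 0), and is assigned to
#' the highest-scoring stimulus. Pattern position within the trial is
#' ignored. Ties go to the lowest stimulus index.
#'
#' @param model_trials a [assign_patterns()] result.
#' @param plan a [split_half()] plan whose stimuli match the model trials.
#' @return data.frame with `trial_id`, `stimulus`, `predicted`.
#' @export
specificity_classify <- function(model_trials, plan) {
  C <- pattern_count_matrix(model_trials)
  specificity_classify_counts(C, model_trials$trial_id,
                              model_trials$stimulus, plan)
}

# Trials x observed-patterns occurrence-count matrix.
pattern_count_matrix <- function(model_trials) {
  patterns <- sort(unique(unlist(model_trials$pattern_ids)))
  C <- t(vapply(model_trials$pattern_ids, function(ids)
    tabulate(match(ids, patterns), nbins = length(patterns)),
    integer(length(patterns))))
  dim(C) <- c(length(model_trials$pattern_ids), length(patterns))
  colnames(C) <- patterns
  C
}

specificity_classify_counts <- function(C, trial_id, stimulus, plan) {
  stimuli <- names(plan)
  train_rows <- match(plan_ids(plan, "train"), trial_id)
  lab_train <- factor(stimulus[train_rows], levels = stimuli)
  r_train <- rowsum(C[train_rows, , drop = FALSE], lab_train)  # s x patterns
  tot <- colSums(r_train)
  SP <- matrix(0, ncol(C), length(stimuli))
  seen <- tot > 0
  SP[seen, ] <- t(r_train[, seen, drop = FALSE]) / tot[seen]
  test_rows <- match(plan_ids(plan, "test"), trial_id)
  score <- C[test_rows, , drop = FALSE] %*% SP
  pred <- max.col(score, ties.method = "first")
  data.frame(trial_id = trial_id[test_rows],
             stimulus = stimulus[test_rows],
             predicted = stimuli[pred],
             stringsAsFactors = FALSE)
}

#' Trajectory of a model trial in pattern space
#'
#' Segments a trial's pattern-id sequence into windows of `tau_bins`
#' samples (by default non-overlapping; `step_bins` < `tau_bins` yields
#' overlapping, slid windows) and averages the model vectors of the
#' patterns within each window. A trailing partial window is dropped.
#'
#' @param pattern_ids integer vector of 0-based pattern ids for one trial.
#' @param map the `som_map` (or `kmeans_model`) that produced the ids.
#' @param tau_bins window size in samples (`>= 1`, at most the sequence
#'   length); the classifier convention sets it equal to the integration
#'   constant in samples.
#' @param step_bins window step in samples (default `tau_bins`).
#' @return Matrix `Nw x n` of window-averaged model vectors, with attribute
#'   `time_ms` giving each window's center (assuming 1 sample = 1 ms unless
#'   scaled by the caller).
#' @export
build_trajectory <- function(pattern_ids, map, tau_bins,
                             step_bins = tau_bins) {
  K <- length(pattern_ids)
  if (tau_bins < 1 || step_bins < 1) stop("window and step must be >= 1")
  if (tau_bins > K) stop("tau_bins exceeds number of samples")
  mv <- model_vector_matrix(map)
  V <- mv[pattern_ids + 1L, , drop = FALSE]
  cs <- rbind(0, apply(V, 2, cumsum))
  starts <- seq(1L, K - tau_bins + 1L, by = step_bins)
  MVA <- (cs[starts + tau_bins, , drop = FALSE] -
            cs[starts, , drop = FALSE]) / tau_bins
  attr(MVA, "time_ms") <- (starts - 1) + tau_bins / 2
  MVA
}

trial_trajectories <- function(model_trials, tau_bins,
                               step_bins = tau_bins) {
  lapply(model_trials$pattern_ids, build_trajectory,
         map = model_trials$map, tau_bins = tau_bins,
         step_bins = step_bins)
}

#' Per-stimulus model trajectories
#'
#' Averages, window by window, the trajectories of the training trials of
#' each stimulus.
#'
#' @param trajectories list of `Nw x n` trajectory matrices (all sharing
#'   `Nw`), e.g. from [build_trajectory()].
#' @param labels stimulus label per trajectory.
#' @param stimulus_set ordered stimulus labels.
#' @return An object of class `trajectory_model`: list with `MT` (named
#'   list of `Nw x n` matrices), `stimulus_set`, `Nw`, `time_ms`.
#' @export
model_trajectories <- function(trajectories, labels,
                               stimulus_set = unique(labels)) {
  Nw <- unique(vapply(trajectories, nrow, integer(1)))
  if (length(Nw) != 1) stop("trajectories have mismatched window counts")
  MT <- lapply(stimulus_set, function(j) {
    sel <- which(labels == j)
    if (!length(sel)) stop("no trajectories for stimulus ", j)
    Reduce(`+`, trajectories[sel]) / length(sel)
  })
  names(MT) <- stimulus_set
  structure(list(MT = MT, stimulus_set = stimulus_set, Nw = Nw,
                 time_ms = attr(trajectories[[1]], "time_ms")),
            class = "trajectory_model")
}

#' Trajectory classifier
#'
#' Each test trajectory accumulates, over all windows, the Euclidean
#' distance to each stimulus's model trajectory,
#' `DT_l(j) = sum_w ||MVA_l(w) - MT_j(w)||`, and is assigned to the
#' stimulus with the smallest total distance (ties to the lowest stimulus
#' index). Sensitive to both pattern identity and stimulus-locked position.
#'
#' @param trajectories list of test-trial trajectories (`Nw x n`, matching
#'   the model).
#' @param model a [model_trajectories()] object.
#' @return Character vector of predicted stimulus labels, plus attribute
#'   `distances` (trials x stimuli matrix of `DT`).
#' @export
trajectory_classify <- function(trajectories, model) {
  D <- t(vapply(trajectories, function(tr) {
    if (nrow(tr) != model$Nw) stop("window count mismatch")
    vapply(model$MT, function(mt)
      sum(sqrt(rowSums((tr - mt)^2))), numeric(1))
  }, numeric(length(model$MT))))
  dim(D) <- c(length(trajectories), length(model$MT))
  pred <- model$stimulus_set[max.col(-D, ties.method = "first")]
  attr(pred, "distances") <- D
  pred
}

#' Repeated half-split decoding performance
#'
#' Runs the requested classifiers over `n_splits` independent random
#' half-splits (distinct derived seeds) of the trials and reports, per
#' classifier, the mean and SD of the fraction of correctly classified test
#' trials, together with the chance level `1/s`. All classifiers share the
#' same split plans, so paired comparisons across classifiers are exact.
#'
#' @param ds a [spike_dataset()].
#' @param model_trials a [assign_patterns()] result for the same dataset;
#'   required by the `"specificity"` and `"trajectory"` classifiers.
#' @param classifiers subset of `c("rate", "specificity", "trajectory")`.
#' @param tau_bins trajectory window size in samples (required when
#'   `"trajectory"` is requested; convention: the integration constant in
#'   samples).
#' @param step_bins trajectory window step (default non-overlapping).
#' @param n_splits number of half-splits (the reference analysis uses
#'   1000; reduce for quick runs).
#' @param seed integer seed; split `i` uses `seed + i`.
#' @return An object of class `performance_result`: list with `performance`
#'   (data.frame `classifier`, `mean`, `sd`, `chance`, `n_splits`) and
#'   `per_split` (splits x classifiers matrix).
#' @export
run_performance <- function(ds, model_trials = NULL,
                            classifiers = c("rate", "specificity",
                                            "trajectory"),
                            tau_bins = NULL, step_bins = NULL,
                            n_splits = 100, seed = 1L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (any(classifiers != "rate") && is.null(model_trials))
    stop("model_trials required for pattern-based classifiers")
  if ("trajectory" %in% classifiers && is.null(tau_bins))
    stop("tau_bins required for the trajectory classifier")
  if (n_splits < 1) stop("n_splits must be >= 1")

  labs <- trial_labels(ds)
  ids <- vapply(ds$trials, function(tr) tr$trial_id, integer(1))
  RV <- if ("rate" %in% classifiers) rate_vectors(ds)
  C <- if ("specificity" %in% classifiers)
    pattern_count_matrix(model_trials)
  trajs <- if ("trajectory" %in% classifiers)
    trial_trajectories(model_trials, tau_bins,
                       step_bins %||% tau_bins)

  perf <- matrix(NA_real_, n_splits, length(classifiers),
                 dimnames = list(NULL, classifiers))
  for (i in seq_len(n_splits)) {
    plan <- split_half(ds, seed = as.integer(seed) + i)
    test_rows <- match(plan_ids(plan, "test"), ids)
    truth <- labs[test_rows]
    for (cl in classifiers) {
      pred <- switch(cl,
        rate = {
          res <- mean_rate_classify(ds, plan)
          res$predicted
        },
        specificity = {
          res <- specificity_classify_counts(C, ids, labs, plan)
          res$predicted
        },
        trajectory = {
          train_rows <- match(plan_ids(plan, "train"), ids)
          mt <- model_trajectories(trajs[train_rows], labs[train_rows],
                                   ds$stimulus_set)
          as.character(trajectory_classify(trajs[test_rows], mt))
        })
      perf[i, cl] <- mean(pred == truth)
    }
  }
  structure(
    list(performance = data.frame(
           classifier = classifiers,
           mean = colMeans(perf),
           sd = apply(perf, 2, stats::sd),
           chance = 1 / length(ds$stimulus_set),
           n_splits = n_splits,
           row.names = NULL,
           stringsAsFactors = FALSE),
         per_split = perf),
    class = "performance_result")
}

#' @export
print.performance_result <- function(x, ...) {
  cat("<performance_result> fraction correct over",
      x$performance$n_splits[1], "half-splits (chance",
      signif(x$performance$chance[1], 3), ")\n")
  print(x$performance, digits = 3)
  invisible(x)
}

#' Time-resolved distances of test trajectories to model trajectories
#'
#' For the test trials of one stimulus `ts`, computes at each window center
#' `t` the mean (over trials) Euclidean distance to the model trajectory of
#' the true stimulus, `d_T(t)`, and the mean distance to the models of the
#' other `s - 1` stimuli, `d_O(t)` (averaged over other stimuli within each
#' trial, then over trials). SDs are taken over test trials (for `d_O`,
#' over the per-trial means). Build the trajectories with a window step of
#' at most 5 samples for good temporal resolution.
#'
#' @param trajectories list of test-trial trajectories of stimulus `ts`.
#' @param model a [model_trajectories()] over the full stimulus set.
#' @param ts the true stimulus label.
#' @return data.frame with columns `time_ms`, `d_true`, `d_other`,
#'   `sd_true`, `sd_other`.
#' @export
time_resolved_distances <- function(trajectories, model, ts) {
  if (length(model$MT) < 2) stop("need at least 2 stimuli")
  if (!ts %in% model$stimulus_set) stop("unknown stimulus: ", ts)
  others <- setdiff(model$stimulus_set, ts)
  dT <- vapply(trajectories, function(tr)
    sqrt(rowSums((tr - model$MT[[ts]])^2)), numeric(model$Nw))
  dO <- vapply(trajectories, function(tr) {
    per_j <- vapply(others, function(j)
      sqrt(rowSums((tr - model$MT[[j]])^2)), numeric(model$Nw))
    rowMeans(rbind(per_j))
  }, numeric(model$Nw))
  dT <- rbind(dT); dO <- rbind(dO)
  data.frame(
    time_ms = model$time_ms,
    d_true = rowMeans(dT),
    d_other = rowMeans(dO),
    sd_true = apply(dT, 1, stats::sd),
    sd_other = apply(dO, 1, stats::sd)
  )
}

#' Time-resolved Cohen's d effect size
#'
#' Standardized separation between the distance of a test trial to other
#' stimuli's models and to its own stimulus's model:
#' `d(t) = (d_O(t) - d_T(t)) / sqrt((sd_T(t)^2 + sd_O(t)^2) / 2)`.
#' Positive values mean the trial is reliably closer to its true model at
#' that moment; the measure is a per-time-point signal-to-noise ratio of
#' stimulus discrimination. Where both SDs are 0 and the means agree, the
#' effect size is defined as 0.
#'
#' @param d_true,d_other mean distance timecourses.
#' @param sd_true,sd_other their SDs over test trials (`>= 0`).
#' @return Numeric vector of Cohen's d values.
#' @export
cohens_d_timecourse <- function(d_true, d_other, sd_true, sd_other) {
  if (any(sd_true < 0 | sd_other < 0)) stop("SDs must be >= 0")
  pooled <- sqrt((sd_true^2 + sd_other^2) / 2)
  d <- (d_other - d_true) / pooled
  # degenerate windows: variability at round-off scale carries no signal,
  # so an effectively-zero pooled SD with agreeing means defines d = 0
  tol <- 1e-9 * pmax(abs(d_true), abs(d_other), 1)
  degen <- pooled < tol
  d[degen & abs(d_other - d_true) < tol] <- 0
  d[degen & (d_other - d_true) >= tol] <- Inf
  d[degen & (d_true - d_other) >= tol] <- -Inf
  d
}

#' One-split effect-size timecourses for every stimulus
#'
#' Convenience wrapper: half-splits the trials once, fits model
#' trajectories on the training half with sliding windows, and returns the
#' time-resolved distances and Cohen's d for the test trials of each
#' stimulus.
#'
#' @param model_trials a [assign_patterns()] result.
#' @param tau_bins window size in samples.
#' @param step_bins window step in samples (default 5, the maximum step
#'   used for time-resolved analysis).
#' @param seed split seed.
#' @return data.frame with columns `stimulus`, `time_ms`, `d_true`,
#'   `d_other`, `sd_true`, `sd_other`, `cohens_d`.
#' @export
effect_size_timecourse <- function(model_trials, tau_bins, step_bins = 5,
                                   seed = 1L) {
  stimulus_set <- unique(model_trials$stimulus)
  labs <- model_trials$stimulus
  ids <- model_trials$trial_id
  plan <- local({
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    pl <- lapply(stimulus_set, function(j) {
      tj <- ids[labs == j]
      train <- sort(sample(tj, ceiling(length(tj) / 2)))
      list(train = train, test = sort(setdiff(tj, train)))
    })
    names(pl) <- stimulus_set
    structure(pl, class = "split_plan", seed = as.integer(seed))
  })
  trajs <- trial_trajectories(model_trials, tau_bins, step_bins)
  train_rows <- match(plan_ids(plan, "train"), ids)
  mt <- model_trajectories(trajs[train_rows], labs[train_rows], stimulus_set)
  out <- lapply(stimulus_set, function(ts) {
    test_rows <- match(plan[[ts]]$test, ids)
    d <- time_resolved_distances(trajs[test_rows], mt, ts)
    d$cohens_d <- cohens_d_timecourse(d$d_true, d$d_other,
                                      d$sd_true, d$sd_other)
    cbind(stimulus = ts, d, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$time_ms <- res$time_ms * model_trials$dt_ms
  res
}

#' One-sample location Z-test
#'
#' `z = (mean(values) - mu0) / (sd(values) / sqrt(n))`, two-sided p from
#' the standard normal. Used to test whether per-jitter average
#' performances differ from the unjittered baseline.
#'
#' @param values numeric sample (`n >= 2`, non-zero SD).
#' @param mu0 null location.
#' @return List with `z`, `p`, `n`, `mean`, `sd`.
#' @export
one_sample_z <- function(values, mu0) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation")
  z <- (mean(values) - mu0) / (s / sqrt(n))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n = n,
       mean = mean(values), sd = s)
}
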