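#' Pattern specificity over a stimulus set
#'
#' For every pattern `p` expressed in the model trials, counts its
#' occurrences `r_p(j)` in all trials belonging to each stimulus `j` (each
#' 1 ms sample of a model trial is one occurrence of its pattern) and
#' normalizes per pattern:
#' \deqn{SP_p(j) = r_p(j) / \sum_c r_p(c).}
#' Specificity lies in `[0, 1]` — 0 when the pattern never occurs for the
#' stimulus, 1 when it occurs only for it — and sums to exactly 1 across the
#' stimulus set for every observed pattern. Patterns with zero total
#' occurrences get no row.
#'
#' @param model_trials a [assign_patterns()] result.
#' @param labels stimulus label per trial (default taken from
#'   `model_trials`); every trial must be labeled.
#' @param stimulus_set ordered stimulus labels (default: unique labels in
#'   order of appearance).
#' @return An object of class `specificity_table`: list with `counts`
#'   (patterns x stimuli integer matrix, rownames = 0-based pattern ids),
#'   `specificity` (same shape, rows summing to 1), `stimulus_set`, `s`,
#'   `patterns`.
#' @export
pattern_specificity <- function(model_trials, labels = model_trials$stimulus,
                                stimulus_set = unique(labels)) {
  if (length(labels) != length(model_trials$pattern_ids))
    stop("need one label per trial")
  if (anyNA(labels)) stop("unlabeled trial")
  lab <- factor(labels, levels = stimulus_set)
  if (anyNA(lab)) stop("trial label outside stimulus_set")
  patterns <- sort(unique(unlist(model_trials$pattern_ids)))
  counts <- matrix(0L, length(patterns), length(stimulus_set),
                   dimnames = list(patterns, stimulus_set))
  for (k in seq_along(model_trials$pattern_ids)) {
    tb <- tabulate(
      match(model_trials$pattern_ids[[k]], patterns),
      nbins = length(patterns)
    )
    counts[, as.integer(lab[k])] <- counts[, as.integer(lab[k])] + tb
  }
  specificity_from_counts(counts, stimulus_set = stimulus_set)
}

#' Specificity table from an occurrence-count matrix
#'
#' Row-normalizes a patterns-x-stimuli occurrence table into specificities;
#' rows with zero total count are dropped (their specificity is undefined).
#'
#' @param counts non-negative matrix of occurrence counts, one row per
#'   pattern, one column per stimulus.
#' @param stimulus_set stimulus labels (default: column names or indices).
#' @return A `specificity_table` (see [pattern_specificity()]).
#' @export
specificity_from_counts <- function(counts, stimulus_set = NULL) {
  counts <- rbind(counts)
  if (any(counts < 0)) stop("occurrence counts must be non-negative")
  if (is.null(stimulus_set))
    stimulus_set <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  colnames(counts) <- stimulus_set
  if (is.null(rownames(counts)))
    rownames(counts) <- as.character(seq_len(nrow(counts)) - 1L)
  tot <- rowSums(counts)
  keep <- tot > 0
  counts <- counts[keep, , drop = FALSE]
  sp <- counts / rowSums(counts)
  structure(list(counts = counts, specificity = sp,
                 stimulus_set = stimulus_set, s = length(stimulus_set),
                 patterns = as.integer(rownames(counts))),
            class = "specificity_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.specificity_table <- function(x, ...) {
  cat("<specificity_table> ", nrow(x$counts), " observed patterns x ",
      x$s, " stimuli (chance 1/s = ", signif(1 / x$s, 3), ")\n", sep = "")
  invisible(x)
}

#' Tidy data.frame view of a specificity table
#' @param x a `specificity_table`.
#' @param ... unused.
#' @return data.frame with columns `pattern_id`, `stimulus`, `count`,
#'   `specificity`.
#' @export
as.data.frame.specificity_table <- function(x, ...) {
  data.frame(
    pattern_id = rep(x$patterns, times = x$s),
    stimulus = rep(x$stimulus_set, each = nrow(x$counts)),
    count = as.vector(x$counts),
    specificity = as.vector(x$specificity),
    stringsAsFactors = FALSE
  )
}

#' Specificity-thresholded pattern sequences
#'
#' For the trials of one stimulus, keeps only samples whose pattern has
#' specificity strictly above `threshold` for that stimulus; all other
#' samples are masked with `NA`. Lowering the threshold reveals gradually
#' more (less specific) patterns.
#'
#' @param model_trials a [assign_patterns()] result.
#' @param table a [pattern_specificity()] table.
#' @param stimulus stimulus label (must be in the table's stimulus set).
#' @param threshold specificity threshold in `[0, 1)`; e.g. 0.25 isolates
#'   patterns carrying most stimulus information.
#' @return List (one element per trial of `stimulus`) of integer pattern-id
#'   sequences with masked samples set to `NA`; names are trial ids.
#' @export
threshold_sequences <- function(model_trials, table, stimulus, threshold) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  j <- match(stimulus, table$stimulus_set)
  if (is.na(j)) stop("unknown stimulus: ", stimulus)
  sp_j <- table$specificity[, j]
  sel <- which(model_trials$stimulus == stimulus)
  out <- lapply(sel, function(k) {
    ids <- model_trials$pattern_ids[[k]]
    sp <- sp_j[match(as.character(ids), rownames(table$specificity))]
    sp[is.na(sp)] <- 0
    ids[sp <= threshold] <- NA_integer_
    ids
  })
  names(out) <- model_trials$trial_id[sel]
  out
}

#' Pattern-triggered spike-raster histogram (PTSRH)
#'
#' For each occurrence of a pattern at time `t_i`, binarizes each unit's
#' spikes (1 = at least one spike, 0 = none) in 1 ms bins over the window
#' `(t_i - window_ms, t_i]` and sums the binary rasters element-wise across
#' occurrences. Reveals which neurons (and how reliably) fire in the window
#' leading into a pattern, and whether those spikes ride on bursts.
#'
#' @param ds a [spike_dataset()].
#' @param occurrences data.frame with columns `trial_id` and `time_ms`.
#' @param window_ms window length in ms (default 30).
#' @return Integer matrix, units x `window_ms` bins; column `m` covers
#'   `(t_i - window_ms + m - 1, t_i - window_ms + m]` (last column ends at
#'   the occurrence). Each entry is at most the number of occurrences.
#' @export
ptsr_histogram <- function(ds, occurrences, window_ms = 30) {
  if (window_ms <= 0) stop("window_ms must be > 0")
  w <- as.integer(ceiling(window_ms))
  H <- matrix(0L, ds$n, w)
  if (!nrow(occurrences)) return(H)
  tid <- vapply(ds$trials, function(tr) tr$trial_id, integer(1))
  for (r in seq_len(nrow(occurrences))) {
    k <- match(occurrences$trial_id[r], tid)
    if (is.na(k)) stop("unknown trial_id: ", occurrences$trial_id[r])
    t_i <- occurrences$time_ms[r]
    if (t_i < 0 || t_i > ds$trial_duration_ms)
      stop("occurrence time outside trial bounds: ", t_i)
    for (u in seq_len(ds$n)) {
      s <- ds$trials[[k]]$spikes[[u]]
      s <- s[s > t_i - w & s <= t_i]
      if (!length(s)) next
      bins <- unique(ceiling(s - t_i + w))
      bins <- bins[bins >= 1 & bins <= w]
      H[u, bins] <- H[u, bins] + 1L
    }
  }
  H
}

#' First-occurrence times of a pattern and their min-max range
#'
#' For every trial of a stimulus containing the pattern, finds the earliest
#' sample time at which it occurs. The min-max range across trials measures
#' the stimulus-locking precision of the pattern.
#'
#' @param model_trials a [assign_patterns()] result.
#' @param pattern 0-based pattern id.
#' @param stimulus stimulus label.
#' @return List with `times` (named by trial id, ms), `range_ms`
#'   (max - min), `n_trials` (trials containing the pattern) and
#'   `n_total_trials` (trials of the stimulus).
#' @export
first_occurrence_jitter <- function(model_trials, pattern, stimulus) {
  sel <- which(model_trials$stimulus == stimulus)
  if (!length(sel)) stop("unknown stimulus: ", stimulus)
  dt <- model_trials$dt_ms
  times <- vapply(sel, function(k) {
    i <- match(pattern, model_trials$pattern_ids[[k]])
    if (is.na(i)) NA_real_ else (i - 1) * dt
  }, numeric(1))
  names(times) <- model_trials$trial_id[sel]
  times <- times[!is.na(times)]
  if (!length(times))
    stop("pattern ", pattern, " absent from all trials of ", stimulus)
  list(times = times, range_ms = max(times) - min(times),
       n_trials = length(times), n_total_trials = length(sel))
}

#' All occurrence times of a pattern as a trial/time table
#'
#' Convenience extractor feeding [ptsr_histogram()].
#'
#' @inheritParams first_occurrence_jitter
#' @param stimulus optional stimulus label restricting the trials.
#' @return data.frame with columns `trial_id`, `time_ms`.
#' @export
pattern_occurrences <- function(model_trials, pattern, stimulus = NULL) {
  sel <- seq_along(model_trials$pattern_ids)
  if (!is.null(stimulus)) sel <- which(model_trials$stimulus == stimulus)
  dt <- model_trials$dt_ms
  out <- lapply(sel, function(k) {
    i <- which(model_trials$pattern_ids[[k]] == pattern)
    if (!length(i)) return(NULL)
    data.frame(trial_id = model_trials$trial_id[k], time_ms = (i - 1) * dt)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(trial_id = integer(), time_ms = numeric())
  out
}
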