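#' Construct a spike dataset
#'
#' Container for simultaneously recorded spike trains organised by trial.
#' Each trial holds one sorted spike-time vector (in ms) per unit, a stimulus
#' label drawn from `stimulus_set`, and all trials share the duration
#' `trial_duration_ms`.
#'
#' @param trials list of trials as returned by [spike_trial()].
#' @param n_units number of simultaneously recorded units.
#' @param stimulus_set ordered character vector of stimulus labels.
#' @param trial_duration_ms positive trial duration in ms; every spike time
#'   must lie in `[0, trial_duration_ms)`.
#' @param epochs optional data.frame annotating stimulus epochs
#'   (columns `epoch`, `start_ms`, `end_ms`).
#'
#' @return An object of class `spike_dataset` with elements `trials`, `n`,
#'   `units` (integer ids `0:(n-1)`), `stimulus_set`, `trial_duration_ms`,
#'   `epochs`.
#' @export
spike_dataset <- function(trials, n_units, stimulus_set, trial_duration_ms,
                          epochs = NULL) {
  stopifnot(is.list(trials), n_units >= 1, trial_duration_ms > 0)
  stimulus_set <- as.character(stimulus_set)
  ds <- structure(
    list(
      trials = trials,
      n = as.integer(n_units),
      units = 0:(n_units - 1L),
      stimulus_set = stimulus_set,
      trial_duration_ms = as.numeric(trial_duration_ms),
      epochs = epochs
    ),
    class = "spike_dataset"
  )
  validate_spike_dataset(ds)
  ds
}

#' Construct a single trial
#'
#' @param trial_id integer trial identifier.
#' @param stimulus stimulus label.
#' @param spikes list of length `n` of numeric spike-time vectors (ms);
#'   unsorted input is sorted.
#' @return A list of class `spike_trial`.
#' @export
spike_trial <- function(trial_id, stimulus, spikes) {
  spikes <- lapply(spikes, function(x) sort(as.numeric(x)))
  structure(
    list(trial_id = as.integer(trial_id), stimulus = as.character(stimulus),
         spikes = spikes),
    class = "spike_trial"
  )
}

validate_spike_dataset <- function(ds) {
  TD <- ds$trial_duration_ms
  for (tr in ds$trials) {
    if (!tr$stimulus %in% ds$stimulus_set)
      stop("trial ", tr$trial_id, ": stimulus '", tr$stimulus,
           "' not in stimulus_set")
    if (length(tr$spikes) != ds$n)
      stop("trial ", tr$trial_id, ": expected ", ds$n, " unit spike lists")
    for (u in seq_along(tr$spikes)) {
      s <- tr$spikes[[u]]
      if (length(s) == 0) next
      if (is.unsorted(s))
        stop("trial ", tr$trial_id, ", unit ", u - 1, ": spike times unsorted")
      if (s[1] < 0 || s[length(s)] >= TD)
        stop("trial ", tr$trial_id, ", unit ", u - 1,
             ": spike time outside [0, TD)")
    }
  }
  invisible(ds)
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset> ", x$n, " units, ", length(x$trials), " trials, ",
      length(x$stimulus_set), " stimuli, TD = ", x$trial_duration_ms,
      " ms\n", sep = "")
  cat("  total spikes:", total_spike_count(x), "\n")
  invisible(x)
}

#' Stimulus label of every trial
#' @param ds a [spike_dataset()].
#' @return Character vector, one label per trial.
#' @export
trial_labels <- function(ds) {
  vapply(ds$trials, function(tr) tr$stimulus, character(1))
}

#' Trial counts per stimulus
#' @param ds a [spike_dataset()].
#' @return Named integer vector over `stimulus_set`.
#' @export
trials_per_stimulus <- function(ds) {
  lab <- factor(trial_labels(ds), levels = ds$stimulus_set)
  table(lab)
}

total_spike_count <- function(ds) {
  sum(vapply(ds$trials,
             function(tr) sum(lengths(tr$spikes)), numeric(1)))
}

#' Per-trial, per-unit spike counts
#' @param ds a [spike_dataset()].
#' @return Integer matrix, trials x units.
#' @export
spike_count_matrix <- function(ds) {
  m <- t(vapply(ds$trials, function(tr) lengths(tr$spikes),
                integer(ds$n)))
  dim(m) <- c(length(ds$trials), ds$n)
  m
}

#' Read a spike dataset from CSV + YAML metadata
#'
#' The CSV must have columns `trial_id,stimulus,unit,time_ms` (one spike per
#' row; rows may be unordered). The metadata sidecar is YAML with fields
#' `n`, `trial_duration_ms`, `stimulus_set`, `trials` (a list of
#' `trial_id`/`stimulus` entries so that spike-free trials survive the
#' round trip) and optionally `epochs`.
#'
#' @param path path to the spike CSV.
#' @param meta_path path to the YAML sidecar; defaults to `path` with its
#'   extension replaced by `.yaml`.
#' @return A [spike_dataset()].
#' @export
read_spikes <- function(path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- paste0(sub("\\.[^.]*$", "", path), ".yaml")
  meta <- yaml::read_yaml(meta_path)
  for (f in c("n", "trial_duration_ms", "stimulus_set", "trials"))
    if (is.null(meta[[f]])) stop("metadata missing field '", f, "'")
  n <- as.integer(meta$n)
  TD <- as.numeric(meta$trial_duration_ms)

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "stimulus", "unit", "time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spike file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$time_ms >= TD | df$time_ms < 0)
  if (length(bad))
    stop("spike time out of [0, TD) at row ", bad[1],
         " (time_ms = ", df$time_ms[bad[1]], ")")
  if (nrow(df) && (any(df$unit < 0) || any(df$unit >= n)))
    stop("unit id outside 0..n-1")

  trial_meta <- meta$trials
  trials <- lapply(trial_meta, function(tm) {
    tid <- as.integer(tm$trial_id)
    sub <- df[df$trial_id == tid, , drop = FALSE]
    spikes <- lapply(0:(n - 1L), function(u) {
      sort(sub$time_ms[sub$unit == u])
    })
    spike_trial(tid, tm$stimulus, spikes)
  })
  epochs <- if (!is.null(meta$epochs)) {
    do.call(rbind, lapply(meta$epochs, as.data.frame))
  } else NULL
  spike_dataset(trials, n, meta$stimulus_set, TD, epochs = epochs)
}

#' Write a spike dataset to CSV + YAML metadata
#'
#' Inverse of [read_spikes()]; `read_spikes(write_spikes(ds, ...))`
#' reproduces the dataset.
#'
#' @param ds a [spike_dataset()].
#' @param path output CSV path.
#' @param meta_path YAML sidecar path (default: `path` with `.yaml`).
#' @return Invisibly, `path`.
#' @export
write_spikes <- function(ds, path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- paste0(sub("\\.[^.]*$", "", path), ".yaml")
  rows <- lapply(ds$trials, function(tr) {
    per_unit <- lapply(seq_along(tr$spikes), function(u) {
      s <- tr$spikes[[u]]
      if (!length(s)) return(NULL)
      data.frame(trial_id = tr$trial_id, stimulus = tr$stimulus,
                 unit = u - 1L, time_ms = s)
    })
    do.call(rbind, per_unit)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(trial_id = integer(), stimulus = character(),
                     unit = integer(), time_ms = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)

  meta <- list(
    n = ds$n,
    trial_duration_ms = ds$trial_duration_ms,
    stimulus_set = as.list(ds$stimulus_set),
    trials = lapply(ds$trials, function(tr)
      list(trial_id = tr$trial_id, stimulus = tr$stimulus))
  )
  if (!is.null(ds$epochs)) {
    meta$epochs <- lapply(seq_len(nrow(ds$epochs)), function(i)
      as.list(ds$epochs[i, , drop = FALSE]))
  }
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}
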