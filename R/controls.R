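#' Jitter every spike independently with Gaussian noise
#'
#' Each spike time is displaced by an independent draw from
#' `N(0, sd_ms^2)`. Displaced spikes that leave `[0, TD)` are reflected back
#' at the boundaries, which preserves spike counts and local density.
#' Per-(trial, unit) spike counts are always preserved; trains are re-sorted.
#'
#' @param ds a [spike_dataset()].
#' @param sd_ms jitter standard deviation in ms (`>= 0`; `0` returns the
#'   dataset unchanged).
#' @param seed integer seed; one RNG stream per (dataset, seed) call.
#' @return A jittered [spike_dataset()].
#' @export
jitter_spikes <- function(ds, sd_ms, seed = 1L) {
  if (sd_ms < 0) stop("sd_ms must be >= 0")
  if (sd_ms == 0) return(ds)
  TD <- ds$trial_duration_ms
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  trials <- lapply(ds$trials, function(tr) {
    tr$spikes <- lapply(tr$spikes, function(s) {
      if (!length(s)) return(s)
      t2 <- s + stats::rnorm(length(s), 0, sd_ms)
      sort(reflect_into(t2, TD))
    })
    tr
  })
  ds$trials <- trials
  ds
}

# Fold times into [0, TD) by reflecting at 0 and TD (period 2*TD).
reflect_into <- function(t, TD) {
  m <- t %% (2 * TD)      # R's %% is non-negative for positive modulus
  out <- ifelse(m < TD, m, 2 * TD - m)
  # exact-boundary hit (probability ~0 with continuous noise)
  out[out >= TD] <- TD * (1 - .Machine$double.eps)
  out
}

#' Shuffle fixed windows of the time axis within each trial
#'
#' The trial is cut into consecutive windows of `window_ms`; windows are
#' permuted independently per trial by a uniform random permutation, and
#' spikes move rigidly with their window. If `window_ms` does not divide the
#' trial duration, the trailing partial window stays in place. Spike counts
#' are preserved.
#'
#' @param ds a [spike_dataset()].
#' @param window_ms window length in ms (`> 0`; the paper-style control uses
#'   20 ms).
#' @param seed integer seed; each trial uses its own derived stream so
#'   trials are permuted independently and reproducibly.
#' @param perm_fun optional function `(n_windows) -> permutation`, replacing
#'   the random permutation (used for deterministic checks, e.g. identity).
#' @return A shuffled [spike_dataset()].
#' @export
shuffle_windows <- function(ds, window_ms = 20, seed = 1L, perm_fun = NULL) {
  if (window_ms <= 0) stop("window_ms must be > 0")
  TD <- ds$trial_duration_ms
  nw <- floor(TD / window_ms)
  if (nw < 2 && is.null(perm_fun)) return(ds)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  for (k in seq_along(ds$trials)) {
    if (is.null(perm_fun)) {
      set.seed(as.integer(seed) + k)
      perm <- sample.int(nw)
    } else {
      perm <- perm_fun(nw)
    }
    # new_start[w] = start of the slot that original window w is moved to
    new_start <- (match(seq_len(nw), perm) - 1) * window_ms
    ds$trials[[k]]$spikes <- lapply(ds$trials[[k]]$spikes, function(s) {
      if (!length(s)) return(s)
      w <- floor(s / window_ms) + 1      # 1-based original window index
      keep <- w > nw                     # trailing partial window: in place
      s2 <- s
      idx <- !keep
      s2[idx] <- s[idx] - (w[idx] - 1) * window_ms + new_start[w[idx]]
      sort(s2)
    })
  }
  ds
}

#' Remove bursts, keeping the first spike of each burst
#'
#' A burst is a maximal run of spikes of one unit in one trial whose
#' consecutive inter-spike intervals, measured on the original train, are all
#' below `isi_threshold_ms`. Only the first spike of every burst (including
#' singleton "bursts") is kept. The operation is idempotent and never
#' increases spike counts.
#'
#' @param ds a [spike_dataset()].
#' @param isi_threshold_ms burst ISI threshold in ms (default 8).
#' @return A [spike_dataset()] with burst spikes removed.
#' @export
remove_bursts <- function(ds, isi_threshold_ms = 8) {
  if (isi_threshold_ms <= 0) stop("isi_threshold_ms must be > 0")
  ds$trials <- lapply(ds$trials, function(tr) {
    tr$spikes <- lapply(tr$spikes, function(s) {
      if (length(s) <= 1) return(s)
      s[c(TRUE, diff(s) >= isi_threshold_ms)]
    })
    tr
  })
  ds
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
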