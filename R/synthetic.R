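#' @keywords internal
# Derived integer sub-seed, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) + 7919 * as.numeric(k)) %% 2147483646) + 1L
}

# Inhomogeneous Poisson spikes by thinning against a 1 ms rate grid (Hz).
# Uses the current RNG stream.
poisson_from_grid <- function(rate_hz, TD) {
  rmax <- max(rate_hz)
  if (rmax <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rmax * TD / 1000)
  if (n_cand == 0) return(numeric(0))
  t_cand <- stats::runif(n_cand, 0, TD)
  r_at <- rate_hz[pmin(floor(t_cand) + 1L, length(rate_hz))]
  sort(t_cand[stats::runif(n_cand) * rmax < r_at])
}

# Replace single spikes by doublets/triplets with short ISIs (3-6 ms).
add_bursts <- function(times, burst_prob, TD, isi_range = c(3, 6)) {
  if (!length(times) || burst_prob <= 0) return(times)
  burst <- stats::runif(length(times)) < burst_prob
  if (!any(burst)) return(times)
  extras <- lapply(times[burst], function(t0) {
    k <- sample(1:2, 1)                    # doublet or triplet
    isis <- stats::runif(k, isi_range[1], isi_range[2])
    t0 + cumsum(isis)
  })
  out <- sort(c(times, unlist(extras)))
  out[out < TD]
}

# Smooth Gaussian rate bump added in place onto a 1 ms grid.
add_bump <- function(rate_hz, center_ms, amp_hz, sd_ms) {
  K <- length(rate_hz)
  lo <- max(1L, floor(center_ms - 4 * sd_ms) + 1L)
  hi <- min(K, ceiling(center_ms + 4 * sd_ms) + 1L)
  if (lo > hi) return(rate_hz)
  t <- (lo:hi) - 1
  rate_hz[lo:hi] <- rate_hz[lo:hi] +
    amp_hz * exp(-((t - center_ms)^2) / (2 * sd_ms^2))
  rate_hz
}

#' Synthetic drifting-grating-like dataset
#'
#' Inhomogeneous-Poisson spike trains emulating responses to sinusoidal
#' gratings drifting in `n_stimuli` equally spaced directions. Each trial
#' has a spontaneous epoch at baseline rate, a stimulus epoch in which unit
#' `i`'s rate is `baseline + gain_i(j) * (1 + sin(2 pi f t + phi_i))` with a
#' von-Mises-shaped direction-tuning gain, and a short OFF epoch at
#' baseline. The default temporal frequency 0.8333 Hz corresponds to a
#' 2 deg/s drift over 2.4 deg grating cycles.
#'
#' @param n_units number of units (default 26).
#' @param n_stimuli number of drift directions (default 12, 30 deg apart).
#' @param n_trials trials per stimulus (default 20).
#' @param TD trial duration in ms (default 4800).
#' @param seed master seed; all randomness derives from it.
#' @param baseline_hz spontaneous rate (default 5 Hz).
#' @param peak_gain_hz tuning gain at the preferred direction (default
#'   15 Hz; 0 makes all stimuli statistically identical).
#' @param kappa von Mises concentration of the direction tuning (default 2).
#' @param temporal_freq_hz drift temporal frequency (default 2/2.4 Hz).
#' @param spont_ms,off_ms spontaneous and OFF epoch durations (defaults
#'   1000 and 300 ms; the stimulus epoch fills the remainder).
#' @param burst_prob probability that a spike is expanded into a
#'   doublet/triplet with 3-6 ms ISIs (default 0.15).
#' @return A [spike_dataset()] with epoch annotations and a `ground_truth`
#'   attribute (tuning parameters and per-stimulus rate grids).
#' @export
gen_grating_like <- function(n_units = 26, n_stimuli = 12, n_trials = 20,
                             TD = 4800, seed = 1L, baseline_hz = 5,
                             peak_gain_hz = 15, kappa = 2,
                             temporal_freq_hz = 2 / 2.4,
                             spont_ms = 1000, off_ms = 300,
                             burst_prob = 0.15) {
  if (n_units < 2) stop("need at least 2 units")
  if (n_stimuli < 1 || n_trials < 1) stop("invalid counts")
  if (spont_ms + off_ms >= TD) stop("epochs exceed trial duration")
  stim_on <- spont_ms
  stim_off <- TD - off_ms

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(seed, 0))
  pref <- stats::runif(n_units, 0, 2 * pi)
  phase <- stats::runif(n_units, 0, 2 * pi)
  theta <- (seq_len(n_stimuli) - 1) * 2 * pi / n_stimuli
  gains <- outer(pref, theta, function(p, th)
    peak_gain_hz * exp(kappa * (cos(th - p) - 1)))

  stimulus_set <- sprintf("dir%03d", round(theta * 180 / pi))
  tgrid <- 0:(ceiling(TD) - 1)
  in_stim <- tgrid >= stim_on & tgrid < stim_off
  rate_grids <- lapply(seq_len(n_stimuli), function(j) {
    vapply(seq_len(n_units), function(i) {
      r <- rep(baseline_hz, length(tgrid))
      mod <- 1 + sin(2 * pi * temporal_freq_hz * (tgrid - stim_on) / 1000 +
                       phase[i])
      r[in_stim] <- baseline_hz + gains[i, j] * mod[in_stim]
      r
    }, numeric(length(tgrid)))
  })

  order_labels <- rep(seq_len(n_stimuli), each = n_trials)
  set.seed(derive_seed(seed, 1))
  order_labels <- sample(order_labels)      # randomized presentation order
  trials <- vector("list", length(order_labels))
  for (k in seq_along(order_labels)) {
    j <- order_labels[k]
    set.seed(derive_seed(seed, 100 + k))
    spikes <- lapply(seq_len(n_units), function(i) {
      s <- poisson_from_grid(rate_grids[[j]][, i], TD)
      add_bursts(s, burst_prob, TD)
    })
    trials[[k]] <- spike_trial(k, stimulus_set[j], spikes)
  }
  epochs <- data.frame(
    epoch = c("spontaneous", "stimulus", "off"),
    start_ms = c(0, stim_on, stim_off),
    end_ms = c(stim_on, stim_off, TD)
  )
  ds <- spike_dataset(trials, n_units, stimulus_set, TD, epochs = epochs)
  attr(ds, "ground_truth") <- list(
    type = "grating", pref_dir = pref, phase = phase, gains_hz = gains,
    baseline_hz = baseline_hz, temporal_freq_hz = temporal_freq_hz,
    rate_grids = rate_grids, epochs = epochs, burst_prob = burst_prob
  )
  ds
}

#' Synthetic flashed-letter-sequence dataset
#'
#' Emulates trials in which a sequence of items (letters) is flashed
#' briefly: each item drives, in a letter-specific unit subset, a transient
#' onset response (Gaussian rate bump with per-unit latency drawn in
#' `onset_latency_ms`, width ~`onset_width_ms`) and a sustained offset
#' response starting `offset_latency_ms` after flash offset; elsewhere
#' units fire background Poisson spikes. Per-trial latency jitter of SD
#' `locking_jitter_sd` is shared by all units within a trial and item,
#' emulating imperfect stimulus locking.
#'
#' @param n_units number of units (default 20).
#' @param sequences list of character vectors, one per stimulus, giving the
#'   item flashed at each onset (defaults to three 3-letter sequences
#'   sharing their letter inventory pairwise).
#' @param n_trials trials per stimulus (default 50).
#' @param TD trial duration in ms (default 1200).
#' @param seed master seed.
#' @param onsets item onset times in ms (default 500, 700, 900).
#' @param flash_ms flash duration (default 100; inter-item interval is
#'   whatever the onsets leave).
#' @param background_hz background rate (default 3 Hz).
#' @param onset_gain_hz peak onset bump rate (default 120 Hz).
#' @param onset_width_ms approximate onset bump width; the Gaussian SD is
#'   half of it (default 10).
#' @param onset_latency_ms per-unit onset latency range (default
#'   `c(30, 40)`).
#' @param offset_gain_hz sustained offset-response rate (default 25 Hz).
#' @param offset_latency_ms offset-response latency after flash offset
#'   (default 70).
#' @param offset_dur_ms offset-response duration (default 80).
#' @param locking_jitter_sd per-trial, per-item latency jitter SD in ms
#'   (default 3).
#' @param onset_reliability either a fraction in `(0, 1]` (per-trial
#'   response probability) or an integer `>= 1` (exact number of responding
#'   trials per stimulus and item). Default 1 (every trial responds).
#' @param units_per_letter size of each letter's unit subset (default
#'   `max(2, round(n_units / 3))`); subsets are drawn independently, so
#'   they may overlap.
#' @param burst_prob doublet/triplet probability (default 0.1).
#' @return A [spike_dataset()] with epoch annotations and a `ground_truth`
#'   attribute including per-(trial, item) response indicators and jitters.
#' @export
gen_flash_sequence_like <- function(n_units = 20,
                                    sequences = list(c("A", "B", "C"),
                                                     c("A", "D", "C"),
                                                     c("D", "B", "C")),
                                    n_trials = 50, TD = 1200, seed = 1L,
                                    onsets = c(500, 700, 900),
                                    flash_ms = 100, background_hz = 3,
                                    onset_gain_hz = 120,
                                    onset_width_ms = 10,
                                    onset_latency_ms = c(30, 40),
                                    offset_gain_hz = 25,
                                    offset_latency_ms = 70,
                                    offset_dur_ms = 80,
                                    locking_jitter_sd = 3,
                                    onset_reliability = 1,
                                    units_per_letter = max(2, round(n_units / 3)),
                                    burst_prob = 0.1) {
  if (n_units < 2) stop("need at least 2 units")
  n_slots <- length(onsets)
  if (any(vapply(sequences, length, integer(1)) != n_slots))
    stop("every sequence must have one item per onset")
  if (any(diff(onsets) < flash_ms))
    stop("overlapping items: onsets closer than flash duration")
  n_stimuli <- length(sequences)
  stimulus_set <- vapply(sequences, paste, character(1), collapse = "-")
  letters_used <- sort(unique(unlist(sequences)))

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(seed, 0))
  letter_units <- lapply(letters_used, function(L)
    sort(sample.int(n_units, units_per_letter)))
  names(letter_units) <- letters_used
  unit_latency <- stats::runif(n_units, onset_latency_ms[1],
                               onset_latency_ms[2])

  # trial metadata: response indicators and per-(trial, item) jitter
  total_trials <- n_stimuli * n_trials
  events <- expand.grid(rep_idx = seq_len(n_trials),
                        stimulus_idx = seq_len(n_stimuli),
                        slot = seq_len(n_slots))
  if (onset_reliability >= 1 && onset_reliability == round(onset_reliability) &&
      onset_reliability != 1) {
    k_resp <- as.integer(onset_reliability)
    if (k_resp > n_trials) stop("onset_reliability exceeds n_trials")
    events$responded <- FALSE
    for (j in seq_len(n_stimuli)) for (m in seq_len(n_slots)) {
      resp <- sample.int(n_trials, k_resp)
      sel <- events$stimulus_idx == j & events$slot == m
      events$responded[sel][resp] <- TRUE
    }
  } else {
    events$responded <- stats::runif(nrow(events)) < onset_reliability
  }
  events$jitter_ms <- stats::rnorm(nrow(events), 0, locking_jitter_sd)

  set.seed(derive_seed(seed, 1))
  order_idx <- sample(rep(seq_len(n_stimuli), each = n_trials))
  rep_counter <- integer(n_stimuli)
  trials <- vector("list", total_trials)
  events$trial_id <- NA_integer_
  tlen <- as.integer(ceiling(TD))
  for (k in seq_len(total_trials)) {
    j <- order_idx[k]
    rep_counter[j] <- rep_counter[j] + 1L
    ev_rows <- which(events$stimulus_idx == j &
                       events$rep_idx == rep_counter[j])
    events$trial_id[ev_rows] <- k
    # per-unit rate grids for this trial
    rate <- matrix(background_hz, tlen, n_units)
    for (m in seq_len(n_slots)) {
      ev <- events[ev_rows[events$slot[ev_rows] == m], ]
      if (!ev$responded) next
      L <- sequences[[j]][m]
      uu <- letter_units[[L]]
      for (u in uu) {
        center <- onsets[m] + unit_latency[u] + ev$jitter_ms
        rate[, u] <- add_bump(rate[, u], center, onset_gain_hz,
                              onset_width_ms / 2)
        # sustained offset response
        o0 <- onsets[m] + flash_ms + offset_latency_ms + ev$jitter_ms
        lo <- max(1L, floor(o0) + 1L)
        hi <- min(tlen, ceiling(o0 + offset_dur_ms))
        if (lo <= hi) rate[lo:hi, u] <- rate[lo:hi, u] + offset_gain_hz
      }
    }
    set.seed(derive_seed(seed, 100 + k))
    spikes <- lapply(seq_len(n_units), function(u) {
      s <- poisson_from_grid(rate[, u], TD)
      add_bursts(s, burst_prob, TD)
    })
    trials[[k]] <- spike_trial(k, stimulus_set[j], spikes)
  }

  epochs <- data.frame(
    epoch = paste0("item", seq_len(n_slots)),
    start_ms = onsets, end_ms = onsets + flash_ms
  )
  ds <- spike_dataset(trials, n_units, stimulus_set, TD, epochs = epochs)
  attr(ds, "ground_truth") <- list(
    type = "flash", sequences = sequences, letters = letters_used,
    letter_units = letter_units, unit_latency_ms = unit_latency,
    onsets_ms = onsets, flash_ms = flash_ms,
    offset_latency_ms = offset_latency_ms,
    locking_jitter_sd = locking_jitter_sd,
    events = events[, c("trial_id", "stimulus_idx", "slot", "responded",
                        "jitter_ms")]
  )
  ds
}

#' Synthetic movie-like dataset with slow and fast epochs
#'
#' Concatenates epochs with smooth low-frequency rate modulation ("slow
#' camera movement") and epochs with trains of sharp population transients
#' ("fast movement"). Each stimulus has its own fixed random profile; the
#' epoch layout is shared, enabling slow- vs fast-segment analyses.
#'
#' @param n_units number of units (default 22).
#' @param n_stimuli number of movie stimuli (default 3).
#' @param n_trials trials per stimulus (default 20).
#' @param TD trial duration in ms (default 4000).
#' @param seed master seed.
#' @param slow_epochs,fast_epochs lists of `c(start, end)` ms intervals;
#'   together they must tile `[0, TD)` without overlap (defaults: slow
#'   first half, fast second half).
#' @param baseline_hz background rate (default 3 Hz).
#' @param slow_amp_hz amplitude of the slow modulation (default 12 Hz).
#' @param slow_freq_range_hz frequency range of the slow sinusoids
#'   (default 0.3-1.2 Hz).
#' @param event_rate_hz rate of fast transient events within fast epochs
#'   (default 3 per second).
#' @param event_gain_hz peak rate of a transient bump (default 90 Hz).
#' @param event_width_ms transient bump width (Gaussian SD = half; default
#'   10).
#' @param locking_jitter_sd per-trial jitter SD of fast events (default 3).
#' @param burst_prob doublet/triplet probability (default 0.1).
#' @param units_per_event units participating in each fast event (default
#'   `max(2, round(n_units / 3))`).
#' @return A [spike_dataset()] with epoch annotations and a `ground_truth`
#'   attribute.
#' @export
gen_movie_like <- function(n_units = 22, n_stimuli = 3, n_trials = 20,
                           TD = 4000, seed = 1L,
                           slow_epochs = list(c(0, TD / 2)),
                           fast_epochs = list(c(TD / 2, TD)),
                           baseline_hz = 3, slow_amp_hz = 12,
                           slow_freq_range_hz = c(0.3, 1.2),
                           event_rate_hz = 3, event_gain_hz = 90,
                           event_width_ms = 10, locking_jitter_sd = 3,
                           burst_prob = 0.1,
                           units_per_event = max(2, round(n_units / 3))) {
  if (n_units < 2) stop("need at least 2 units")
  eps <- c(lapply(slow_epochs, c), lapply(fast_epochs, c))
  kind <- c(rep("slow", length(slow_epochs)), rep("fast", length(fast_epochs)))
  o <- order(vapply(eps, `[`, numeric(1), 1))
  eps <- eps[o]; kind <- kind[o]
  bounds <- do.call(rbind, eps)
  if (nrow(bounds) > 1 && any(bounds[-1, 1] < bounds[-nrow(bounds), 2]))
    stop("epoch overlap")
  if (bounds[1, 1] != 0 || bounds[nrow(bounds), 2] != TD ||
      (nrow(bounds) > 1 &&
         any(bounds[-1, 1] != bounds[-nrow(bounds), 2])))
    stop("epochs must tile [0, TD)")

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(seed, 0))
  tlen <- as.integer(ceiling(TD))
  tgrid <- 0:(tlen - 1)
  stimulus_set <- sprintf("movie%d", seq_len(n_stimuli))

  # per-stimulus fixed profiles
  profiles <- lapply(seq_len(n_stimuli), function(j) {
    freqs <- matrix(stats::runif(2 * n_units, slow_freq_range_hz[1],
                                 slow_freq_range_hz[2]), 2, n_units)
    phases <- matrix(stats::runif(2 * n_units, 0, 2 * pi), 2, n_units)
    ev <- list()
    for (e in which(kind == "fast")) {
      n_ev <- stats::rpois(1, event_rate_hz * diff(bounds[e, ]) / 1000)
      if (n_ev == 0) next
      times <- sort(stats::runif(n_ev, bounds[e, 1], bounds[e, 2]))
      ev[[length(ev) + 1]] <- data.frame(
        time_ms = times,
        id = seq_along(times) + 1000 * e
      )
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(time_ms = numeric(), id = integer())
    event_units <- lapply(seq_len(nrow(events)), function(r)
      sort(sample.int(n_units, units_per_event)))
    list(freqs = freqs, phases = phases, events = events,
         event_units = event_units)
  })

  # stimulus-locked (jitter-free) rate grids
  base_grids <- lapply(seq_len(n_stimuli), function(j) {
    pr <- profiles[[j]]
    rate <- matrix(baseline_hz, tlen, n_units)
    for (e in which(kind == "slow")) {
      sel <- tgrid >= bounds[e, 1] & tgrid < bounds[e, 2]
      for (u in seq_len(n_units)) {
        mod <- (1 + sin(2 * pi * pr$freqs[1, u] * tgrid / 1000 +
                          pr$phases[1, u])) / 2 +
               (1 + sin(2 * pi * pr$freqs[2, u] * tgrid / 1000 +
                          pr$phases[2, u])) / 2
        rate[sel, u] <- baseline_hz + slow_amp_hz * mod[sel] / 2
      }
    }
    rate
  })

  set.seed(derive_seed(seed, 1))
  order_idx <- sample(rep(seq_len(n_stimuli), each = n_trials))
  trials <- vector("list", length(order_idx))
  for (k in seq_along(order_idx)) {
    j <- order_idx[k]
    pr <- profiles[[j]]
    set.seed(derive_seed(seed, 100 + k))
    rate <- base_grids[[j]]
    if (nrow(pr$events)) {
      jit <- stats::rnorm(nrow(pr$events), 0, locking_jitter_sd)
      for (r in seq_len(nrow(pr$events))) {
        for (u in pr$event_units[[r]]) {
          rate[, u] <- add_bump(rate[, u], pr$events$time_ms[r] + jit[r],
                                event_gain_hz, event_width_ms / 2)
        }
      }
    }
    spikes <- lapply(seq_len(n_units), function(u) {
      s <- poisson_from_grid(rate[, u], TD)
      add_bursts(s, burst_prob, TD)
    })
    trials[[k]] <- spike_trial(k, stimulus_set[j], spikes)
  }

  epochs <- data.frame(epoch = kind, start_ms = bounds[, 1],
                       end_ms = bounds[, 2])
  ds <- spike_dataset(trials, n_units, stimulus_set, TD, epochs = epochs)
  attr(ds, "ground_truth") <- list(
    type = "movie", profiles = profiles, epochs = epochs,
    baseline_hz = baseline_hz
  )
  ds
}
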