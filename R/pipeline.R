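#' Analysis configuration
#'
#' Bundles the knobs of the end-to-end pipeline: the set of integration
#' time constants, the sampling step, the SOM configuration, the
#' classifiers, the number of half-splits, and the control settings.
#'
#' @param taus_ms integration time constants to sweep (default
#'   `c(1, 5, 10, 20, 50, 100, 500)` ms).
#' @param dt_ms sampling step (default 1 ms).
#' @param som a [som_config()].
#' @param classifiers classifiers to run.
#' @param n_splits half-splits per condition (reference: 1000).
#' @param jitter_sds_ms jitter control SDs (default 10, 20, 50, 100 ms).
#' @param shuffle_window_ms window-shuffle control window (default 20 ms).
#' @param burst_threshold_ms burst-removal ISI threshold (default 8 ms).
#' @param seed master seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(taus_ms = c(1, 5, 10, 20, 50, 100, 500),
                            dt_ms = 1, som = som_config(),
                            classifiers = c("rate", "specificity",
                                            "trajectory"),
                            n_splits = 100,
                            jitter_sds_ms = c(10, 20, 50, 100),
                            shuffle_window_ms = 20,
                            burst_threshold_ms = 8, seed = 1L) {
  stopifnot(all(taus_ms > 0), dt_ms > 0, n_splits >= 1)
  structure(list(taus_ms = taus_ms, dt_ms = dt_ms, som = som,
                 classifiers = classifiers, n_splits = n_splits,
                 jitter_sds_ms = jitter_sds_ms,
                 shuffle_window_ms = shuffle_window_ms,
                 burst_threshold_ms = burst_threshold_ms,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Activation -> map -> model trials for one time constant
#'
#' Runs the pattern-detection chain at a single integration constant:
#' exponential convolution and sampling, SOM training (fresh map per call,
#' seeded), and BMU assignment of every sample.
#'
#' @param ds a [spike_dataset()].
#' @param tau_ms integration time constant (ms).
#' @param som a [som_config()]; its seed is combined with `tau_ms` so each
#'   time constant trains its own map deterministically.
#' @param dt_ms sampling step (ms).
#' @return List with `avs` (activity vectors), `map` (trained SOM) and
#'   `model_trials`.
#' @export
pattern_pipeline <- function(ds, tau_ms, som = som_config(), dt_ms = 1) {
  avs <- build_activity_vectors(ds, tau_ms, dt_ms)
  som$seed <- derive_seed(som$seed, round(tau_ms * 10))
  map <- train_som(avs, som)
  mt <- assign_patterns(map, avs)
  list(avs = avs, map = map, model_trials = mt)
}

#' Full multi-timescale decoding analysis
#'
#' For each requested integration constant: builds activity vectors,
#' trains a fresh Kohonen map, constructs model trials, and evaluates the
#' requested classifiers under repeated half-split cross-validation.
#' Optional control conditions rerun the whole chain (map retraining
#' included) on manipulated spike data: window-shuffled, jittered and/or
#' burst-free.
#'
#' @param ds a [spike_dataset()].
#' @param config an [analysis_config()].
#' @param conditions character subset of
#'   `c("original", "shuffled", "jittered", "deburst")`.
#' @param verbose print per-stage progress.
#' @return data.frame with one row per (condition, tau, classifier):
#'   columns `condition`, `jitter_sd`, `tau_ms`, `classifier`, `mean`,
#'   `sd`, `chance`, `n_splits`.
#' @export
run_timescale_analysis <- function(ds, config = analysis_config(),
                                   conditions = "original",
                                   verbose = FALSE) {
  datasets <- list()
  for (cond in conditions) {
    switch(cond,
      original = { datasets[["original"]] <- ds },
      shuffled = {
        datasets[["shuffled"]] <-
          shuffle_windows(ds, config$shuffle_window_ms,
                          seed = derive_seed(config$seed, 11))
      },
      jittered = {
        for (sdj in config$jitter_sds_ms)
          datasets[[paste0("jittered_", sdj)]] <-
            jitter_spikes(ds, sdj, seed = derive_seed(config$seed, 13 + sdj))
      },
      deburst = {
        datasets[["deburst"]] <- remove_bursts(ds, config$burst_threshold_ms)
      },
      stop("unknown condition: ", cond))
  }

  rows <- list()
  for (nm in names(datasets)) {
    dsc <- datasets[[nm]]
    for (tau in config$taus_ms) {
      if (verbose)
        message(sprintf("[%s] tau = %g ms: activation + map + decoding",
                        nm, tau))
      pp <- pattern_pipeline(dsc, tau, config$som, config$dt_ms)
      perf <- run_performance(
        dsc, pp$model_trials, classifiers = config$classifiers,
        tau_bins = max(1L, round(tau / config$dt_ms)),
        n_splits = config$n_splits,
        seed = derive_seed(config$seed, 1000 + round(tau))
      )
      p <- perf$performance
      p$condition <- sub("_[0-9]+$", "", nm)
      p$jitter_sd <- ifelse(grepl("^jittered_", nm),
                            as.numeric(sub("^jittered_", "", nm)), NA)
      p$tau_ms <- tau
      rows[[length(rows) + 1]] <- p
    }
  }
  out <- do.call(rbind, rows)
  out[, c("condition", "jitter_sd", "tau_ms", "classifier", "mean", "sd",
          "chance", "n_splits")]
}

#' Simulate a dataset and write it to disk
#'
#' Runs one of the synthetic generators and writes the spike CSV, the YAML
#' metadata sidecar, and a ground-truth JSON next to it.
#'
#' @param type one of `"grating"`, `"flash"`, `"movie"`.
#' @param path output CSV path (sidecars derive from it).
#' @param seed master seed.
#' @param ... forwarded to the generator.
#' @return Invisibly, the generated [spike_dataset()].
#' @export
simulate_dataset <- function(type = c("grating", "flash", "movie"), path,
                             seed = 1L, ...) {
  type <- match.arg(type)
  ds <- switch(type,
    grating = gen_grating_like(seed = seed, ...),
    flash = gen_flash_sequence_like(seed = seed, ...),
    movie = gen_movie_like(seed = seed, ...))
  write_spikes(ds, path)
  gt <- attr(ds, "ground_truth")
  gt$rate_grids <- NULL                      # keep the sidecar small
  gt$profiles <- NULL
  gt_path <- paste0(sub("\\.[^.]*$", "", path), "_ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(ds)
}

#' Plot color sequences of model trials
#'
#' One horizontal line per trial of each stimulus; each 1 ms sample is
#' colored by the lattice position of its pattern, so stretches of similar
#' color mark stereotypically repeating patterns.
#'
#' @param model_trials a [assign_patterns()] result from a `som_map`.
#' @param stimuli stimuli to show (default all).
#' @param downsample_ms plot resolution in ms (default 4) to keep figures
#'   light.
#' @return A ggplot object.
#' @export
plot_color_sequences <- function(model_trials, stimuli = NULL,
                                 downsample_ms = 4) {
  if (!inherits(model_trials$map, "som_map"))
    stop("color sequences need a lattice-ordered (SOM) map")
  N <- model_trials$map$N
  stimuli <- stimuli %||% unique(model_trials$stimulus)
  sel <- which(model_trials$stimulus %in% stimuli)
  step <- max(1L, round(downsample_ms / model_trials$dt_ms))
  dat <- do.call(rbind, lapply(sel, function(k) {
    ids <- model_trials$pattern_ids[[k]]
    at <- seq(1L, length(ids), by = step)
    pos <- lattice_position(ids[at], N)
    col <- pattern_color(pos, N)
    data.frame(stimulus = model_trials$stimulus[k],
               trial = model_trials$trial_id[k],
               time_ms = (at - 1) * model_trials$dt_ms,
               color = grDevices::rgb(col[, 1], col[, 2], col[, 3]))
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = time_ms,
                                    y = factor(trial))) +
    ggplot2::geom_tile(ggplot2::aes(fill = color),
                       width = step * model_trials$dt_ms) +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_grid(rows = ggplot2::vars(stimulus),
                        scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "trial") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot decoding performance against the integration constant
#'
#' @param results a [run_timescale_analysis()] data.frame.
#' @return A ggplot object with one line per classifier (faceted by
#'   condition when several are present) and a dashed chance line.
#' @export
plot_performance <- function(results) {
  g <- ggplot2::ggplot(results,
    ggplot2::aes(x = tau_ms, y = mean,
                 color = classifier, group = classifier)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd,
                                        ymax = mean + sd),
                           width = 0.05) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = chance),
                        linetype = "dashed", color = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "integration constant tau (ms)",
                  y = "fraction correct") +
    ggplot2::theme_minimal()
  if (length(unique(results$condition)) > 1)
    g <- g + ggplot2::facet_wrap(ggplot2::vars(condition))
  g
}

#' Plot effect-size timecourses
#'
#' @param es an [effect_size_timecourse()] data.frame (optionally row-bound
#'   over several `tau_ms` values in a `tau_ms` column).
#' @return A ggplot object of Cohen's d over time, faceted by stimulus.
#' @export
plot_effect_size <- function(es) {
  g <- ggplot2::ggplot(es, ggplot2::aes(x = time_ms,
                                        y = cohens_d))
  if ("tau_ms" %in% names(es))
    g <- g + ggplot2::geom_line(ggplot2::aes(color = factor(tau_ms)))
  else g <- g + ggplot2::geom_line()
  g + ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                          color = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(stimulus)) +
    ggplot2::labs(x = "time (ms)", y = "Cohen's d",
                  color = "tau (ms)") +
    ggplot2::theme_minimal()
}
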