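#' Spike experiment container
#'
#' Spike times from a loose cell-attached recording of a spontaneously
#' active neuron, with the agonist application epoch marked. Epoch windows
#' used by the metrics (baseline; early agonist, 1-2 min after onset; late
#' agonist, at 5 min) are arguments of the metric functions so they stay
#' reproducible and adjustable.
#'
#' @param spike_times strictly increasing spike times in seconds from the
#'   start of the record.
#' @param agonist_onset_s time of agonist arrival (s); the baseline epoch is
#'   `[baseline_start_s, agonist_onset_s)`.
#' @param duration_s total record duration (s).
#' @param baseline_start_s start of the usable baseline (default 0).
#' @param sampling_rate_hz acquisition rate for raw traces (10 kHz typical).
#' @param cell_id,label free-text identifiers (e.g. cell and agonist).
#' @return Object of class `spike_experiment`.
#' @export
spike_experiment <- function(spike_times, agonist_onset_s, duration_s,
                             baseline_start_s = 0, sampling_rate_hz = 1e4,
                             cell_id = "cell", label = "") {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike_times must be strictly increasing")
  if (length(spike_times) && (spike_times[1L] < 0 ||
                              spike_times[length(spike_times)] > duration_s))
    stop("spike_times must lie within [0, duration_s]")
  if (!(baseline_start_s >= 0 && baseline_start_s < agonist_onset_s &&
        agonist_onset_s < duration_s))
    stop("need baseline_start_s < agonist_onset_s < duration_s")
  structure(list(spike_times = spike_times,
                 agonist_onset_s = agonist_onset_s,
                 duration_s = duration_s,
                 baseline_start_s = baseline_start_s,
                 sampling_rate_hz = sampling_rate_hz,
                 cell_id = as.character(cell_id), label = as.character(label)),
            class = "spike_experiment")
}

#' @export
print.spike_experiment <- function(x, ...) {
  cat(sprintf("spike_experiment '%s'%s: %d spikes over %.0f s, agonist at %.0f s\n",
              x$cell_id, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$spike_times), x$duration_s, x$agonist_onset_s))
  invisible(x)
}

#' Threshold spike detection on an extracellular trace
#'
#' Events are excursions beyond `threshold_sd` times the robust noise SD
#' (median absolute deviation about the trace median, so large spikes do not
#' inflate the noise estimate). Each suprathreshold run is reduced to its
#' extremum sample; events closer than `refractory_ms` to the previous
#' accepted event are suppressed. Both polarities are detected by default.
#'
#' @param trace numeric vector of finite samples.
#' @param sampling_rate_hz samples per second.
#' @param threshold_sd threshold in noise-SD multiples (> 0).
#' @param refractory_ms dead time after each accepted event (ms).
#' @param polarity `"both"`, `"negative"` or `"positive"`.
#' @return Spike times in seconds (sample `i` maps to `(i - 1) / rate`).
#'   A flat trace yields an empty result with a warning.
#' @export
detect_spikes <- function(trace, sampling_rate_hz, threshold_sd = 4,
                          refractory_ms = 2,
                          polarity = c("both", "negative", "positive")) {
  polarity <- match.arg(polarity)
  if (any(!is.finite(trace))) stop("trace must be finite")
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  noise_sd <- stats::mad(trace)
  if (noise_sd == 0) {
    warning("flat trace: noise SD is zero, no spikes detected")
    return(numeric(0))
  }
  dev <- trace - median(trace)
  mag <- switch(polarity, both = abs(dev), negative = -dev, positive = dev)
  over <- mag > threshold_sd * noise_sd
  if (!any(over)) return(numeric(0))
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- mapply(function(s, e) s - 1L + which.max(mag[s:e]),
                starts[runs$values], ends[runs$values])
  idx <- sort(idx)
  refr <- refractory_ms / 1000 * sampling_rate_hz
  keep <- idx[1L]
  last <- idx[1L]
  for (i in idx[-1L]) {
    if (i - last > refr) { keep <- c(keep, i); last <- i }
  }
  (keep - 1L) / sampling_rate_hz
}

#' Binned spike counts (firing-rate time course)
#'
#' Counts over half-open bins `[k*b, (k+1)*b)`; a spike exactly on a bin
#' edge belongs to the later bin. Counts sum to the number of spikes within
#' the covered span.
#'
#' @param spike_times spike times in seconds.
#' @param bin_seconds bin width (default 15 s, the usual time-course
#'   binning for these recordings).
#' @param t_max span to cover (default: up to the last spike).
#' @return Data frame with `bin_start`, `bin_end`, `count`, `rate_hz`.
#' @export
bin_rates <- function(spike_times, bin_seconds = 15, t_max = NULL) {
  if (bin_seconds <= 0) stop("bin_seconds must be > 0")
  if (is.null(t_max)) t_max <- if (length(spike_times)) max(spike_times) else 0
  n_bins <- max(1L, ceiling((t_max + .Machine$double.eps) / bin_seconds))
  idx <- floor(spike_times / bin_seconds) + 1L
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_seconds,
             bin_end = seq_len(n_bins) * bin_seconds,
             count = counts, rate_hz = counts / bin_seconds)
}

# firing rate over [a, b) in absolute record time
.window_rate <- function(exp, a, b) {
  sum(exp$spike_times >= a & exp$spike_times < b) / (b - a)
}

#' Baseline firing rate
#'
#' @param exp a [spike_experiment()].
#' @return Rate (Hz) over `[baseline_start_s, agonist_onset_s)`.
#' @export
baseline_rate <- function(exp) {
  stopifnot(inherits(exp, "spike_experiment"))
  .window_rate(exp, exp$baseline_start_s, exp$agonist_onset_s)
}

#' Percent inhibition of spontaneous firing
#'
#' `100 * (1 - rate_window / rate_baseline)`, clamped to `[0, 100]`.
#' The default window, 1-2 min after agonist onset, captures the maximal
#' effect. A rebound above baseline reports 0 with attribute
#' `rebound = TRUE`. Cells need a baseline of at least 60 s of firing;
#' a silent baseline is an error (such cells are excluded from analysis).
#'
#' @param exp a [spike_experiment()].
#' @param window_s measurement window in seconds relative to agonist onset
#'   (half-open).
#' @return Percent inhibition in `[0, 100]`.
#' @examples
#' ex <- spike_experiment(c(seq(0.5, 59.5, 1), 61.4, 63.4), 60, 180)
#' percent_inhibition(ex)
#' @export
percent_inhibition <- function(exp, window_s = c(60, 120)) {
  stopifnot(inherits(exp, "spike_experiment"), length(window_s) == 2L,
            window_s[2L] > window_s[1L])
  if (exp$agonist_onset_s - exp$baseline_start_s < 60)
    stop("baseline epoch shorter than 60 s")
  if (exp$agonist_onset_s + window_s[2L] > exp$duration_s)
    stop("record ends before the measurement window")
  rb <- baseline_rate(exp)
  if (rb == 0) stop("zero baseline rate: cell excluded (no steady firing)")
  rw <- .window_rate(exp, exp$agonist_onset_s + window_s[1L],
                     exp$agonist_onset_s + window_s[2L])
  raw <- 100 * (1 - rw / rb)
  structure(min(100, max(0, raw)), rebound = raw < 0)
}

#' Percent desensitization of the firing inhibition
#'
#' Decline of the agonist effect during continued application: the
#' difference between the percent inhibition in the early window (default
#' 1-2 min after onset, the maximal effect) and at 5 min (default window
#' 4.5-5 min), clamped to `[0, 100]`. With `normalized = TRUE` the
#' difference is instead expressed relative to the early (maximal)
#' inhibition; the raw difference is the default reading.
#'
#' @inheritParams percent_inhibition
#' @param early_window_s,late_window_s windows (s, relative to onset).
#' @param normalized rescale by the early inhibition (default `FALSE`).
#' @return Percent desensitization in `[0, 100]`, with attributes
#'   `inhibition_early` and `inhibition_late`.
#' @export
percent_desensitization <- function(exp, early_window_s = c(60, 120),
                                    late_window_s = c(270, 300),
                                    normalized = FALSE) {
  stopifnot(inherits(exp, "spike_experiment"))
  if (exp$agonist_onset_s + late_window_s[2L] > exp$duration_s)
    stop("agonist epoch shorter than ", late_window_s[2L] / 60,
         " min: desensitization not defined")
  early <- percent_inhibition(exp, early_window_s)
  late <- percent_inhibition(exp, late_window_s)
  d <- as.numeric(early) - as.numeric(late)
  if (normalized) {
    if (early == 0) stop("no early inhibition: normalized desensitization undefined")
    d <- 100 * d / as.numeric(early)
  }
  structure(min(100, max(0, d)),
            inhibition_early = as.numeric(early),
            inhibition_late = as.numeric(late))
}
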