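#' Construct a voltage-clamp trace record
#'
#' Container for repeated current traces recorded at a fixed sampling rate
#' around a stimulation time. Currents are in pA at a +10 mV holding
#' potential, where IPSCs appear as positive (outward) deflections.
#'
#' @param samples Time x trials numeric matrix (pA).
#' @param sample_rate Samples per second (default 10 kHz).
#' @param stim_time Stimulation time in seconds from trace start; at least
#'   1 s of pre-stimulus baseline must be available.
#' @param holding Holding potential in mV.
#' @return A `trace_record`.
#' @export
trace_record <- function(samples, sample_rate = 1e4, stim_time,
                         holding = 10) {
  if (is.vector(samples)) samples <- matrix(samples)
  stopifnot(is.matrix(samples), sample_rate > 0, stim_time > 0)
  if (stim_time < 1) stop("need at least 1 s of pre-stimulus baseline")
  structure(list(samples = samples, sample_rate = sample_rate,
                 stim_time = stim_time, holding = holding,
                 n_trials = ncol(samples)),
            class = "trace_record")
}

# time axis in seconds, aligned to trace start
.trace_times <- function(trace) {
  (seq_len(nrow(trace$samples)) - 1L) / trace$sample_rate
}

#' Detect the presence of an evoked IPSC
#'
#' Averages the trials, takes baseline mean and s.d. over the second before
#' stimulation, subtracts the baseline mean, and reports an IPSC as present
#' iff a contiguous excursion above 3 s.d. lasts longer than 10 ms within
#' the 500 ms window after stimulation.
#'
#' @param trace A [trace_record()] covering `[stim - 1 s, stim + 0.5 s]`.
#' @param sd_mult Threshold multiplier (default 3).
#' @param min_dur_s Minimum supra-threshold duration in seconds (default
#'   0.010, applied strictly: runs must exceed it).
#' @param window_s Post-stimulus search window in seconds.
#' @return List with `present`, `baseline_mean`, `baseline_sd`, and
#'   `longest_run_ms`.
#' @export
detect_ipsc <- function(trace, sd_mult = 3, min_dur_s = 0.010,
                        window_s = 0.5) {
  stopifnot(inherits(trace, "trace_record"))
  t <- .trace_times(trace)
  if (max(t) < trace$stim_time + window_s) {
    stop("trace must extend ", window_s, " s beyond stimulation")
  }
  avg <- rowMeans(trace$samples)
  base <- avg[t >= trace$stim_time - 1 & t < trace$stim_time]
  if (length(base) < trace$sample_rate * 0.99) {
    stop("insufficient pre-stimulus baseline")
  }
  m <- mean(base)
  s <- stats::sd(base)
  x <- avg - m
  post <- x[t >= trace$stim_time & t <= trace$stim_time + window_s]
  runs <- rle(post > sd_mult * s)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(present = longest / trace$sample_rate > min_dur_s,
       baseline_mean = m, baseline_sd = s,
       longest_run_ms = 1000 * longest / trace$sample_rate)
}

#' Early/late peak amplitudes and charge transfer
#'
#' Splits the baseline-subtracted average trace into an early (0-250 ms) and
#' a late (250-1500 ms) post-stimulus phase. Peaks are the maxima of the
#' positive-going current per phase (the early phase excludes the sample at
#' exactly 250 ms); charges are trapezoidal integrals (pA x s = pC) over
#' closed windows sharing the 250 ms sample, so that early + late equals the
#' integral over the full 0-1500 ms window.
#'
#' @param trace A [trace_record()] covering `stim + 1.5 s`.
#' @param early_s,late_s Phase boundaries in seconds post-stimulus.
#' @return List with `early_peak`, `late_peak` (pA), `early_charge`,
#'   `late_charge` (pC), and `early_fraction` (`NA` when total charge is 0).
#' @export
phase_metrics <- function(trace, early_s = 0.25, late_s = 1.5) {
  stopifnot(inherits(trace, "trace_record"))
  t <- .trace_times(trace)
  if (max(t) < trace$stim_time + late_s) {
    stop("trace must extend ", late_s, " s beyond stimulation")
  }
  avg <- rowMeans(trace$samples)
  base <- avg[t >= trace$stim_time - 1 & t < trace$stim_time]
  if (length(base) < trace$sample_rate * 0.99) {
    stop("insufficient pre-stimulus baseline")
  }
  x <- avg - mean(base)
  rel <- t - trace$stim_time
  early_open <- rel >= 0 & rel < early_s
  early_closed <- rel >= 0 & rel <= early_s
  late_closed <- rel >= early_s & rel <= late_s
  early_peak <- max(0, x[early_open])
  late_peak <- max(0, x[late_closed])
  early_charge <- pracma::trapz(t[early_closed], x[early_closed])
  late_charge <- pracma::trapz(t[late_closed], x[late_closed])
  total <- early_charge + late_charge
  list(early_peak = early_peak, late_peak = late_peak,
       early_charge = early_charge, late_charge = late_charge,
       early_fraction = if (total == 0) NA_real_ else early_charge / total)
}

#' Construct an FI-curve pair
#'
#' Firing rate versus injected current with and without photostimulation of
#' a neighboring glomerulus. Rates at each step are the averages of the two
#' repeated FI curves measured per cell.
#'
#' @param current_steps Strictly increasing current amplitudes (pA).
#' @param rate_off,rate_on Rates per step (Hz) without / with
#'   photostimulation.
#' @param step_duration Step length in seconds.
#' @param analysis_window Spike-count window in seconds.
#' @return An `fi_curve_pair`.
#' @export
fi_curve_pair <- function(current_steps, rate_off, rate_on,
                          step_duration = 0.5, analysis_window = 0.5) {
  stopifnot(length(current_steps) == length(rate_off),
            length(rate_off) == length(rate_on),
            all(diff(current_steps) > 0),
            all(rate_off >= 0), all(rate_on >= 0))
  structure(list(current_steps = current_steps, rate_off = rate_off,
                 rate_on = rate_on, step_duration = step_duration,
                 analysis_window = analysis_window),
            class = "fi_curve_pair")
}

#' Effective activity range of lateral inhibition
#'
#' A current step is "affected" when photostimulation decreases the firing
#' rate by strictly more than 10% (`(off - on)/off > threshold`, requiring
#' `off > 0`). Lateral inhibition is significant for the cell iff some run
#' of at least 2 consecutive affected steps exists. The reported bounds are
#' the light-off rates at the first and last step of the union of qualifying
#' runs (single isolated affected steps do not qualify and do not move the
#' bounds).
#'
#' @param fi An [fi_curve_pair()] with >= 2 steps.
#' @param threshold Fractional decrease defining an affected step.
#' @param min_run Minimum consecutive affected steps for significance.
#' @return List with `affected_steps` (indices), `significant`,
#'   `lower_bound`, `upper_bound` (Hz; `NA` when not significant).
#' @export
effective_range <- function(fi, threshold = 0.10, min_run = 2L) {
  stopifnot(inherits(fi, "fi_curve_pair"))
  if (length(fi$current_steps) < 2L) stop("need at least 2 current steps")
  if (all(fi$rate_off == 0)) {
    stop("effective range undefined: cell never fires without stimulation")
  }
  dec <- ifelse(fi$rate_off > 0,
                (fi$rate_off - fi$rate_on) / fi$rate_off, 0)
  affected <- dec > threshold
  runs <- rle(affected)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  qual <- which(runs$values & runs$lengths >= min_run)
  if (!length(qual)) {
    return(list(affected_steps = which(affected), significant = FALSE,
                lower_bound = NA_real_, upper_bound = NA_real_))
  }
  first <- starts[qual[1L]]
  last <- ends[qual[length(qual)]]
  list(affected_steps = which(affected), significant = TRUE,
       lower_bound = fi$rate_off[first], upper_bound = fi$rate_off[last])
}

#' Generate a synthetic IPSC trace with known ground truth
#'
#' Builds `n_trials` current traces of Gaussian baseline noise with
#' exponential-decay IPSC-like events (instantaneous rise, positive-going)
#' injected at fixed latencies after the stimulation time. Used to validate
#' [detect_ipsc()] and [phase_metrics()] against ground truth.
#'
#' @param events Data frame with columns `onset` (s after stimulation),
#'   `amplitude` (pA), `tau_decay` (s). May have zero rows.
#' @param noise_sd Baseline noise s.d. in pA.
#' @param n_trials Trials to average (default 5).
#' @param sample_rate Hz.
#' @param pre_s,post_s Seconds of trace before/after stimulation.
#' @param seed Integer seed.
#' @return A [trace_record()] with the generating `events` attached as
#'   `attr(, "truth")`.
#' @export
generate_ipsc_trace <- function(events = data.frame(onset = 0.02,
                                                    amplitude = 20,
                                                    tau_decay = 0.05),
                                noise_sd = 2, n_trials = 5L,
                                sample_rate = 1e4, pre_s = 1, post_s = 1.5,
                                seed = 1L) {
  stopifnot(all(c("onset", "amplitude", "tau_decay") %in% names(events)) ||
              nrow(events) == 0L)
  n <- as.integer(round((pre_s + post_s) * sample_rate)) + 1L
  t <- (seq_len(n) - 1L) / sample_rate
  stim <- pre_s
  signal <- numeric(n)
  for (i in seq_len(nrow(events))) {
    t0 <- stim + events$onset[i]
    after <- t >= t0
    signal[after] <- signal[after] +
      events$amplitude[i] * exp(-(t[after] - t0) / events$tau_decay[i])
  }
  set.seed(child_seed(seed, "ipsc-trace"))
  noise <- matrix(stats::rnorm(n * n_trials, 0, noise_sd), n, n_trials)
  rec <- trace_record(signal + noise, sample_rate = sample_rate,
                      stim_time = stim)
  attr(rec, "truth") <- events
  rec
}

#' Generate a synthetic FI-curve pair with known ground truth
#'
#' The light-off curve rises linearly over the current steps; a contiguous
#' block of steps has its light-on rate reduced by `decrease_frac`. Each of
#' the two simulated FI-curve repeats receives independent Gaussian rate
#' noise before averaging, mirroring the averaging applied to recorded
#' cells.
#'
#' @param current_steps Injected currents (pA).
#' @param max_rate Light-off rate at the largest step (Hz).
#' @param affected_steps Integer indices of truly inhibited steps.
#' @param decrease_frac True fractional rate decrease on those steps.
#' @param noise_sd Per-repeat rate noise s.d. (Hz).
#' @param seed Integer seed.
#' @return An [fi_curve_pair()] with `attr(, "truth")` holding the affected
#'   indices and the true off-rate bounds.
#' @export
generate_fi_pair <- function(current_steps = seq(50, 500, by = 50),
                             max_rate = 80, affected_steps = 2:4,
                             decrease_frac = 0.15, noise_sd = 0.5,
                             seed = 1L) {
  k <- length(current_steps)
  stopifnot(all(affected_steps %in% seq_len(k)))
  off_true <- max_rate * seq_len(k) / k
  on_true <- off_true
  on_true[affected_steps] <- off_true[affected_steps] * (1 - decrease_frac)
  set.seed(child_seed(seed, "fi-pair"))
  off <- pmax(0, colMeans(matrix(stats::rnorm(2L * k, rep(off_true, each = 2L),
                                              noise_sd), 2L, k)))
  on <- pmax(0, colMeans(matrix(stats::rnorm(2L * k, rep(on_true, each = 2L),
                                             noise_sd), 2L, k)))
  fi <- fi_curve_pair(current_steps, off, on)
  attr(fi, "truth") <- list(affected_steps = affected_steps,
                            lower_bound = off_true[min(affected_steps)],
                            upper_bound = off_true[max(affected_steps)],
                            decrease_frac = decrease_frac)
  fi
}

#' Generate a synthetic electrophysiology fixture
#'
#' Dispatcher over the two fixture generators.
#'
#' @param kind `"ipsc_trace"` or `"fi_pair"`.
#' @param params Named list of arguments passed to the generator.
#' @param seed Integer seed.
#' @return A [trace_record()] or [fi_curve_pair()] with ground truth in
#'   `attr(, "truth")`.
#' @export
generate_fixture <- function(kind = c("ipsc_trace", "fi_pair"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  fn <- if (kind == "ipsc_trace") generate_ipsc_trace else generate_fi_pair
  do.call(fn, c(params, list(seed = seed)))
}
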