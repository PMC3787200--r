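## ephys_analysis: sliding-template synaptic-current detection, kinetics,
## frequency statistics, reversal-potential regression, KS comparison.

#' Construct a current trace
#'
#' @param samples numeric vector of membrane current in pA.
#' @param sampling_rate_hz sampling frequency in Hz (typically 5–10 kHz
#'   for whole-cell synaptic-current recordings).
#' @param holding_potential_mv holding potential in mV (optional; inward
#'   glutamatergic currents dominate near −60 mV, outward GABA/glycinergic
#'   currents near 0 mV).
#' @param filter_hz low-pass filter corner recorded with the data
#'   (metadata only).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate_hz,
                          holding_potential_mv = NA_real_,
                          filter_hz = NA_real_) {
  sl_assert(is.numeric(samples) && all(is.finite(samples)), "InvalidTrace",
            "samples must be finite numerics")
  sl_assert(is.numeric(sampling_rate_hz) && sampling_rate_hz > 0,
            "InvalidTrace", "sampling_rate_hz must be > 0")
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 holding_potential_mv = holding_potential_mv,
                 filter_hz = filter_hz),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace: %d samples @ %g Hz (%.2f s), Vhold %s mV\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz,
              format(x$holding_potential_mv)))
  invisible(x)
}

#' Read a current trace from columnar text
#'
#' Accepts two-column text (time_s, current_pA; the sampling rate is
#' inferred from the time column) or single-column current with an
#' explicit `sampling_rate_hz`.
#'
#' @param path text file (whitespace- or comma-separated; `#` comments).
#' @param sampling_rate_hz required for single-column files.
#' @param holding_potential_mv,filter_hz metadata, see [current_trace()].
#' @return A `current_trace`.
#' @export
read_trace <- function(path, sampling_rate_hz = NULL,
                       holding_potential_mv = NA_real_,
                       filter_hz = NA_real_) {
  sl_assert(file.exists(path), "IOFailure", "file not found: '%s'", path)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      sep = if (any(grepl(",", readLines(path, n = 5)))) ","
                            else ""),
    error = function(e) e)
  sl_assert(!inherits(df, "error"), "IOFailure", "cannot parse '%s'", path)
  if (ncol(df) >= 2) {
    dt <- diff(df[[1]])
    sl_assert(all(dt > 0), "InvalidTrace", "time column must increase")
    current_trace(df[[2]], 1 / median(dt), holding_potential_mv, filter_hz)
  } else {
    sl_assert(!is.null(sampling_rate_hz), "InvalidTrace",
              "single-column trace needs an explicit sampling_rate_hz")
    current_trace(df[[1]], sampling_rate_hz, holding_potential_mv,
                  filter_hz)
  }
}

#' Difference-of-exponentials synaptic event template
#'
#' `w(t) = exp(-t/decay) - exp(-t/rise)`, peak-normalized to 1. Default
#' kinetics follow typical whole-cell recordings: fast EPSC-like events
#' (rise ~1 ms, decay ~10 ms) for inward searches; slower IPSC-like events
#' (rise ~2.5 ms, decay ~25 ms) for outward searches.
#'
#' @param rise_ms,decay_ms time constants in ms (`decay_ms > rise_ms`).
#' @param length_ms template duration in ms (default: rise + 4 * decay).
#'   Length trades kinetic specificity against detector dead time:
#'   detections closer than one template length are merged, so at high
#'   event rates a short template (a few ms, just covering the peak)
#'   recovers rates with far less loss.
#' @param sampling_rate_hz sampling frequency the template is realized at.
#' @return Numeric vector, unit peak.
#' @export
event_template <- function(rise_ms, decay_ms, length_ms = NULL,
                           sampling_rate_hz = 10000) {
  sl_assert(rise_ms > 0 && decay_ms > rise_ms, "InvalidParams",
            "need 0 < rise_ms < decay_ms")
  if (is.null(length_ms)) length_ms <- rise_ms + 4 * decay_ms
  t_ms <- seq(0, length_ms, by = 1000 / sampling_rate_hz)
  w <- exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms)
  w / max(w)
}

empty_event_list <- function(polarity, criterion_threshold, m, fs) {
  ev <- data.frame(onset_s = numeric(0), amplitude_pa = numeric(0),
                   criterion = numeric(0), polarity = character(0))
  attr(ev, "params") <- list(polarity = polarity,
                             criterion_threshold = criterion_threshold,
                             template_length = m, sampling_rate_hz = fs)
  class(ev) <- c("event_list", "data.frame")
  ev
}

#' Detect synaptic events with the optimally scaled sliding template
#'
#' At every offset the template is fit to the data window by least squares
#' in scale and baseline offset; the detection criterion is the fitted
#' scale divided by the standard error of the fit
#' (`sqrt(SSE / (N - 1))`). The criterion is invariant to gain and offset
#' changes of the recording. Local criterion maxima at or above the
#' threshold become events; detections closer than one template length
#' keep only the higher criterion.
#'
#' @param trace a [current_trace()].
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param template numeric template (unit positive peak), or `NULL` for
#'   the polarity-matched default [event_template()].
#' @param criterion_threshold detection threshold (default 3, standard for
#'   this detector; recorded in the result).
#' @param refine_kinetics also fit per-event 10–90% rise and decay tau via
#'   [event_kinetics()] (default `TRUE`).
#' @return data.frame of class `event_list`: `onset_s`, `amplitude_pa`
#'   (signed), `criterion`, `polarity`, and when refined `rise_10_90_ms`,
#'   `decay_tau_ms`. Attribute `params` records the settings.
#' @export
detect_events <- function(trace, polarity = c("inward", "outward"),
                          template = NULL, criterion_threshold = 3,
                          refine_kinetics = TRUE) {
  polarity <- match.arg(polarity)
  fs <- trace$sampling_rate_hz
  if (is.null(template)) {
    template <- if (polarity == "inward")
      event_template(1, 10, sampling_rate_hz = fs)
    else event_template(2.5, 25, sampling_rate_hz = fs)
  }
  y <- trace$samples
  if (polarity == "inward") y <- -y   # work with positive-going events
  n <- length(y); m <- length(template)
  sl_assert(m < n, "TemplateTooLong",
            "template (%d samples) must be shorter than the trace (%d)",
            m, n)
  w <- template
  sw <- sum(w); sw2 <- sum(w * w)
  nw <- n - m + 1L
  # running sums over each window via cumulative sums
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y * y))
  sy <- cy[(m + 1):(n + 1)] - cy[1:nw]
  sy2 <- cy2[(m + 1):(n + 1)] - cy2[1:nw]
  # sliding dot product sum(w * window) at every offset
  # (convolve type "filter" correlates directly, no kernel reversal)
  swy <- as.numeric(stats::convolve(y, w, type = "filter"))
  denom <- sw2 - sw * sw / m
  s <- (swy - sw * sy / m) / denom          # optimal scale
  off <- (sy - s * sw) / m                  # optimal offset
  sse <- pmax(sy2 + s * s * sw2 + m * off * off -
                2 * (s * swy + off * sy - s * off * sw), 0)
  se <- sqrt(sse / (m - 1))
  # floors proportional to the trace range keep the criterion finite and
  # exactly gain/offset-invariant while suppressing float-roundoff
  # "perfect fits" in event-free stretches
  span <- diff(range(y))
  if (span == 0) return(empty_event_list(polarity, criterion_threshold, m, fs))
  crit <- ifelse(s > 1e-6 * span, s / pmax(se, 1e-9 * span), 0)
  # local maxima of the criterion above threshold
  cand <- which(crit >= criterion_threshold)
  cand <- cand[crit[cand] >= c(-Inf, crit)[cand] &
                 crit[cand] >= c(crit, -Inf)[cand + 1L]]
  # resolve overlaps: greedy by criterion within one template length
  if (length(cand) > 1) {
    ord <- cand[order(-crit[cand])]
    taken <- logical(0); kept <- integer(0)
    for (i in ord) {
      if (!any(abs(kept - i) < m)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  sgn <- if (polarity == "inward") -1 else 1
  ev <- data.frame(onset_s = (cand - 1) / fs,
                   amplitude_pa = sgn * s[cand],
                   criterion = crit[cand],
                   polarity = polarity)
  if (isTRUE(refine_kinetics) && nrow(ev) > 0) {
    ev$rise_10_90_ms <- NA_real_
    ev$decay_tau_ms <- NA_real_
    kin_len <- max(m, round(0.04 * fs))  # >= 40 ms so decay fits converge
    for (i in seq_len(nrow(ev))) {
      seg <- trace$samples[cand[i]:min(n, cand[i] + kin_len - 1L)]
      kin <- tryCatch(event_kinetics(seg, fs, polarity),
                      error = function(e) NULL)
      if (!is.null(kin)) {
        ev$rise_10_90_ms[i] <- kin$rise_10_90_ms
        ev$decay_tau_ms[i] <- kin$decay_tau_ms
        ev$amplitude_pa[i] <- kin$amplitude_pa
      }
    }
  }
  attr(ev, "params") <- list(polarity = polarity,
                             criterion_threshold = criterion_threshold,
                             template_length = m,
                             sampling_rate_hz = fs)
  class(ev) <- c("event_list", "data.frame")
  ev
}

#' Kinetics of a single synaptic event
#'
#' The segment should start at (or just before) event onset and contain one
#' event. Baseline is the mean of the first samples before the rise; the
#' 10–90% rise time is obtained by linear interpolation of the threshold
#' crossings, and the decay time constant by a single-exponential least
#' squares fit from the peak towards baseline.
#'
#' @param segment numeric current segment (pA).
#' @param sampling_rate_hz sampling frequency (Hz).
#' @param polarity `"inward"` or `"outward"`.
#' @param baseline_samples samples averaged for the baseline (default:
#'   1 ms worth, at least 1).
#' @return List: `rise_10_90_ms`, `decay_tau_ms`, `amplitude_pa` (signed).
#' @export
event_kinetics <- function(segment, sampling_rate_hz,
                           polarity = c("inward", "outward"),
                           baseline_samples = NULL) {
  polarity <- match.arg(polarity)
  y <- as.numeric(segment)
  if (polarity == "inward") y <- -y
  n <- length(y)
  sl_assert(n >= 5, "NoPeakFound", "segment too short")
  if (is.null(baseline_samples))
    baseline_samples <- max(1L, round(sampling_rate_hz / 1000))
  k <- min(baseline_samples, n)
  # baseline = quieter of the segment's two ends, so segments that start
  # right at the peak (no pre-onset samples) still reference correctly
  base <- min(mean(y[seq_len(k)]), mean(y[(n - k + 1L):n]))
  ipk <- which.max(y)
  amp <- y[ipk] - base
  sl_assert(is.finite(amp) && amp > 0 && amp > 1e-9 * max(abs(y), 1),
            "NoPeakFound", "no peak above baseline in segment")
  dt_ms <- 1000 / sampling_rate_hz
  th10 <- base + 0.1 * amp; th90 <- base + 0.9 * amp
  cross_time <- function(th) {
    # last upward crossing before the peak, linearly interpolated
    below <- which(y[1:ipk] < th)
    if (length(below) == 0) return(0)
    i <- max(below)
    if (i == ipk) return((i - 1) * dt_ms)
    frac <- (th - y[i]) / (y[i + 1] - y[i])
    (i - 1 + frac) * dt_ms
  }
  rise <- cross_time(th90) - cross_time(th10)
  # decay: single-exponential-plus-offset fit towards baseline.  Start
  # once the signal has fallen to 90% of the peak: for rise-decay
  # waveforms the residual rising component distorts the first post-peak
  # samples.  The fitted offset re-estimates the baseline, which also
  # corrects the amplitude when the segment carries no quiet stretch.
  i90 <- which(y[ipk:n] - base <= 0.9 * amp)
  istart <- ipk + (if (length(i90)) i90[1] - 1L else 0L)
  if (istart >= n - 2L) istart <- ipk
  yd <- y[istart:n] - base
  td <- (seq_along(yd) - 1) * dt_ms
  pos <- yd > 0.02 * amp
  sl_assert(sum(pos) >= 3, "NoPeakFound", "decay too short to fit")
  fit0 <- lm(log(yd[pos]) ~ td[pos])
  tau0 <- -1 / coef(fit0)[2]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(td) / 3
  yraw <- y[istart:n]
  fit <- tryCatch(
    suppressWarnings(nls(yraw ~ A * exp(-td / tau) + C,
                         start = list(A = amp, tau = tau0, C = base),
                         control = list(warnOnly = TRUE))),
    error = function(e) NULL)
  tau <- tau0
  if (!is.null(fit) && is.finite(coef(fit)[["tau"]]) &&
        coef(fit)[["tau"]] > 0) {
    tau <- coef(fit)[["tau"]]
    base <- coef(fit)[["C"]]
    amp <- y[ipk] - base
    sl_assert(amp > 0, "NoPeakFound", "no peak above fitted baseline")
    th10 <- base + 0.1 * amp; th90 <- base + 0.9 * amp
    rise <- cross_time(th90) - cross_time(th10)
  }
  list(rise_10_90_ms = max(rise, dt_ms / 100),
       decay_tau_ms = tau,
       amplitude_pa = if (polarity == "inward") -amp else amp)
}

#' Ratio of two event frequencies
#'
#' `rate_a / rate_b`, rounded half-up to two decimals — e.g. the
#' EPSC:IPSC frequency ratio comparing inward-event rate at −60 mV with
#' outward-event rate at 0 mV.
#'
#' @param rate_a_hz,rate_b_hz event rates in Hz; `rate_b_hz` must be > 0.
#' @return Ratio, two decimals.
#' @export
frequency_ratio <- function(rate_a_hz, rate_b_hz) {
  sl_assert(is.numeric(rate_b_hz) && rate_b_hz > 0, "ZeroDenominator",
            "rate_b_hz must be > 0")
  round_half_up(rate_a_hz / rate_b_hz, 2)
}

#' Reversal potential from an I–V relationship
#'
#' Ordinary least squares of mean event amplitude on holding potential;
#' the reversal potential is the x-intercept `-intercept/slope`, with a
#' 95% confidence interval by the delta method on the slope/intercept
#' covariance.
#'
#' @param points data.frame with columns `holding_potential_mv` and
#'   `mean_amplitude_pa` (at least 3 rows, at least 2 distinct
#'   potentials).
#' @return List: `e_rev_mv`, `ci95_mv` (length-2), `slope_pa_per_mv`,
#'   `intercept_pa`, `fit` (the `lm` object).
#' @export
reversal_potential <- function(points) {
  sl_assert(is.data.frame(points) &&
              all(c("holding_potential_mv", "mean_amplitude_pa") %in%
                    names(points)), "InvalidParams",
            "points needs holding_potential_mv and mean_amplitude_pa")
  sl_assert(nrow(points) >= 3, "DegenerateDesign",
            "need at least 3 I-V points")
  v <- points$holding_potential_mv
  sl_assert(length(unique(v)) >= 2, "DegenerateDesign",
            "all holding potentials are equal")
  fit <- lm(mean_amplitude_pa ~ holding_potential_mv, data = points)
  b <- coef(fit)
  sl_assert(abs(b[2]) > .Machine$double.eps, "DegenerateDesign",
            "zero slope: no reversal in range")
  e_rev <- -b[1] / b[2]
  # vcov warns on numerically perfect fits; the zero-width CI is correct
  V <- suppressWarnings(vcov(fit))
  # delta method: g = -b0/b1, grad = (-1/b1, b0/b1^2)
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(max(0, t(grad) %*% V %*% grad))
  tq <- qt(0.975, df = fit$df.residual)
  list(e_rev_mv = unname(e_rev),
       ci95_mv = unname(c(e_rev - tq * se, e_rev + tq * se)),
       slope_pa_per_mv = unname(b[2]), intercept_pa = unname(b[1]),
       fit = fit)
}

#' Two-sample Kolmogorov–Smirnov comparison
#'
#' Compares two cumulative frequency distributions (e.g. amplitude or
#' inter-event-interval distributions of inward vs outward currents):
#' D is the maximum absolute difference between the empirical CDFs, with
#' the asymptotic two-sided p value.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return List: `D`, `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  sl_assert(length(sample_a) > 0 && length(sample_b) > 0, "EmptySample",
            "both samples must be non-empty")
  kt <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Write detected events to CSV
#' @param events an `event_list` from [detect_events()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  ok <- tryCatch({ write.csv(as.data.frame(events), path,
                             row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  sl_assert(ok, "IOFailure", "cannot write events to '%s'", path)
  invisible(path)
}
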