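fs <- 10000

inject <- function(n, onsets_s, amp, template) {
  y <- numeric(n)
  for (o in onsets_s) {
    s <- round(o * fs) + 1L
    e <- min(n, s + length(template) - 1L)
    y[s:e] <- y[s:e] + amp * template[seq_len(e - s + 1L)]
  }
  y
}

test_that("noiseless template events are detected at exact onsets", {
  tpl <- event_template(1, 10, sampling_rate_hz = fs)
  onsets <- c(0.1, 0.35, 0.52, 0.8, 1.0, 1.2, 1.5, 1.7)
  y <- inject(2 * fs, onsets, -30, tpl)
  ev <- detect_events(current_trace(y, fs, -60), "inward",
                      criterion_threshold = 3)
  expect_equal(nrow(ev), length(onsets))
  expect_equal(ev$onset_s, onsets, tolerance = 1 / fs / 10)
  expect_equal(ev$amplitude_pa, rep(-30, length(onsets)), tolerance = 0.02)
  expect_true(all(ev$polarity == "inward"))
})

test_that("a flat trace contains no events", {
  expect_equal(nrow(detect_events(current_trace(rep(5, 5000), fs),
                                  "inward")), 0)
  expect_equal(nrow(detect_events(current_trace(rep(0, 5000), fs),
                                  "outward")), 0)
})

test_that("the detection criterion is invariant under gain and offset", {
  set.seed(61)
  tpl <- event_template(1, 10, sampling_rate_hz = fs)
  y <- inject(fs, c(0.2, 0.6), -25, tpl) + rnorm(fs, sd = 2)
  e1 <- detect_events(current_trace(y, fs), "inward",
                      refine_kinetics = FALSE)
  e2 <- detect_events(current_trace(3.7 * y + 12, fs), "inward",
                      refine_kinetics = FALSE)
  expect_identical(e1$onset_s, e2$onset_s)
  expect_equal(e2$criterion, e1$criterion, tolerance = 1e-6)
})

test_that("template too long for the trace is an error", {
  tpl <- event_template(1, 10, sampling_rate_hz = fs)
  expect_error(detect_events(current_trace(rep(0, 100), fs), "inward",
                             template = tpl),
               class = "TemplateTooLong")
})

test_that("a seeded Poisson train is recovered within Poisson error", {
  sim <- generate_current_trace(60, rate_inward_hz = 10, noise_sd_pa = 2,
                                seed = 7)
  short_tpl <- event_template(1, 10, length_ms = 5, sampling_rate_hz = fs)
  ev <- detect_events(sim$trace, "inward", template = short_tpl,
                      criterion_threshold = 3, refine_kinetics = FALSE)
  n_true <- nrow(sim$events)
  expect_lt(abs(nrow(ev) - n_true), 2 * sqrt(n_true))
  # long-trace rate convergence: within 15% of the generating 10 Hz
  expect_lt(abs(nrow(ev) / 60 - 10) / 10, 0.15)
})

test_that("difference-of-exponential kinetics are recovered within 5%", {
  rise_tau <- 1.5; decay_tau <- 12
  tpl <- event_template(rise_tau, decay_tau, length_ms = 80,
                        sampling_rate_hz = fs)
  kin <- event_kinetics(-40 * tpl, fs, "inward")
  # closed-form 10-90% rise from the continuous waveform by root finding
  raw <- function(u) exp(-u / decay_tau) - exp(-u / rise_tau)
  tpk <- log(decay_tau / rise_tau) / (1 / rise_tau - 1 / decay_tau)
  w <- function(t) raw(t) / raw(tpk)
  t10 <- uniroot(function(t) w(t) - 0.1, c(0, tpk))$root
  t90 <- uniroot(function(t) w(t) - 0.9, c(0, tpk))$root
  expect_equal(kin$rise_10_90_ms, t90 - t10, tolerance = 0.05)
  expect_equal(kin$decay_tau_ms, decay_tau, tolerance = 0.05)
  expect_equal(kin$amplitude_pa, -40, tolerance = 0.02)
})

test_that("a step-to-exponential decay recovers its time constant exactly", {
  t_ms <- (0:999) / fs * 1000
  seg <- 35 * exp(-t_ms / 13.1)
  kin <- event_kinetics(seg, fs, "outward")
  expect_equal(kin$decay_tau_ms, 13.1, tolerance = 0.1 / 13.1)
  expect_error(event_kinetics(rep(2, 500), fs, "inward"),
               class = "NoPeakFound")
})

test_that("frequency ratios round half-up to two decimals", {
  expect_identical(frequency_ratio(9.8, 5.3), 1.85)  # EPSC:IPSC rates
  expect_identical(frequency_ratio(4.4, 4.4), 1)
  expect_identical(frequency_ratio(100 / 10, 50 / 10), 2)
  expect_error(frequency_ratio(1, 0), class = "ZeroDenominator")
})

test_that("reversal potential is exact on noiseless linear I-V data", {
  pts <- data.frame(holding_potential_mv = c(-80, -60, -40, -20, 0, 20))
  pts$mean_amplitude_pa <- 1 * (pts$holding_potential_mv + 56)
  rv <- reversal_potential(pts)
  expect_equal(rv$e_rev_mv, -56)
  expect_lt(diff(rv$ci95_mv), 1e-6)
  expect_error(reversal_potential(pts[1:2, ]), class = "DegenerateDesign")
  same_v <- data.frame(holding_potential_mv = rep(-60, 4),
                       mean_amplitude_pa = 1:4)
  expect_error(reversal_potential(same_v), class = "DegenerateDesign")
})

test_that("noisy I-V regression covers the generating reversal", {
  set.seed(63)
  true_erev <- -4
  pts <- data.frame(holding_potential_mv = c(-60, -40, -20, 0, 20, 40))
  pts$mean_amplitude_pa <- 0.8 * (pts$holding_potential_mv - true_erev) +
    rnorm(6, sd = 1.5)
  rv <- reversal_potential(pts)
  expect_gt(true_erev, rv$ci95_mv[1])
  expect_lt(true_erev, rv$ci95_mv[2])
})

test_that("KS statistics match the brute-force ECDF maximum", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_compare(1:5, 11:15)$D, 1)
  a <- c(0.2, 0.7, 1.3, 2.2, 2.9, 4.1)
  b <- c(0.5, 0.9, 1.1, 3.3, 3.4)
  expect_equal(ks_compare(a, b)$D, brute_force_ks_D(a, b))
  expect_error(ks_compare(numeric(0), 1:3), class = "EmptySample")
})

test_that("traces roundtrip through columnar text", {
  sim <- generate_current_trace(0.5, rate_inward_hz = 5, seed = 3)
  p2 <- tempfile(fileext = ".txt")
  n <- length(sim$trace$samples)
  write.table(data.frame(t = (0:(n - 1)) / fs, i = sim$trace$samples),
              p2, row.names = FALSE, col.names = FALSE)
  tr2 <- read_trace(p2)
  expect_equal(tr2$sampling_rate_hz, fs, tolerance = 1e-6)
  expect_equal(tr2$samples, sim$trace$samples, tolerance = 1e-6)
  p1 <- tempfile(fileext = ".txt")
  writeLines(as.character(sim$trace$samples), p1)
  expect_error(read_trace(p1), class = "InvalidTrace")
  tr1 <- read_trace(p1, sampling_rate_hz = fs)
  expect_equal(tr1$samples, sim$trace$samples, tolerance = 1e-6)
})
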