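# helper: a spike record over a toy model with chosen spike times
record_for <- function(circ, times_list, t_end) {
  rec <- cxsim:::new_spike_record(circ$neurons$id,
                                  rep(list(numeric()), nrow(circ$neurons)),
                                  t_end)
  for (nm in names(times_list)) rec$times[[nm]] <- times_list[[nm]]
  rec
}

test_that("the wedge-rate estimator reproduces its closed-form kernel", {
  toy <- toy_core(4)
  circ <- toy$circuit
  eb <- circ$neurons$id[circ$neurons$cell_class == "EB-LAL-PB"]
  rec <- record_for(circ, setNames(list(1.0), eb[1]), t_end = 4)
  wr <- wedge_rates(rec, circ, list(kernel_tau = 0.7215, sample_dt = 0.0001))
  # a single spike at t = 1: r(t) = exp(-(t-1)/0.7215) for t >= 1, 0 before
  i0 <- which.min(abs(wr$time - 0.9))
  expect_equal(unname(wr$rates[i0, 1]), 0)
  i1 <- which.min(abs(wr$time - 1.7215))
  expect_equal(unname(wr$rates[i1, 1]), exp(-1), tolerance = 1e-3)
  i2 <- which.min(abs(wr$time - 1.0))
  expect_equal(unname(wr$rates[i2, 1]), 1, tolerance = 1e-3)
  # kernel area over the recorded window: tau * (1 - exp(-T/tau))
  area <- 0.7215 * (1 - exp(-3 / 0.7215))
  expect_equal(unname(sum(wr$rates[, 1]) * 0.0001), area, tolerance = 1e-3)
})

test_that("identical trains on both neurons of a wedge leave the mean unchanged", {
  cfg <- default_config("B")
  cfg$counts[["EB-LAL-PB"]] <- 2L
  circ2 <- build_model_B(make_topology(), cfg)
  eb0 <- circ2$neurons$id[circ2$neurons$cell_class == "EB-LAL-PB" &
                            circ2$neurons$wedge == 0L]
  spk <- c(0.5, 1.1, 2.0)
  rec_both <- record_for(circ2, setNames(list(spk, spk), eb0), 3)
  cfg1 <- default_config("B")
  circ1 <- build_model_B(make_topology(), cfg1)
  eb1 <- circ1$neurons$id[circ1$neurons$cell_class == "EB-LAL-PB" &
                            circ1$neurons$wedge == 0L]
  rec_one <- record_for(circ1, setNames(list(spk), eb1), 3)
  r_both <- wedge_rates(rec_both, circ2)
  r_one <- wedge_rates(rec_one, circ1)
  expect_equal(r_both$rates[, 1], r_one$rates[, 1], tolerance = 1e-12)
})

test_that("rate traces shift exactly with a global time shift", {
  toy <- toy_core(4)
  circ <- toy$circuit
  eb <- circ$neurons$id[circ$neurons$cell_class == "EB-LAL-PB"]
  spk <- c(0.3, 0.9, 1.4)
  p <- list(kernel_tau = 0.7215, sample_dt = 0.01)
  rA <- wedge_rates(record_for(circ, setNames(list(spk), eb[2]), 3), circ, p)
  rB <- wedge_rates(record_for(circ, setNames(list(spk + 1), eb[2]), 4),
                    circ, p)
  i <- seq_len(length(rA$time) - 100)
  expect_equal(rB$rates[i + 100, 2], rA$rates[i, 2], tolerance = 1e-9)
})

test_that("only EB-LAL-PB spikes enter the estimator", {
  toy <- toy_core(4)
  circ <- toy$circuit
  pb <- circ$neurons$id[circ$neurons$cell_class == "PB-EB-LAL"]
  rec <- record_for(circ, setNames(list(c(0.5, 1)), pb[1]), 2)
  wr <- wedge_rates(rec, circ)
  expect_true(all(wr$rates == 0))
})

test_that("bump metrics: one-hot, uniform, and rotation cases", {
  toy <- toy_core(16)
  circ <- toy$circuit
  eb <- circ$neurons$id[circ$neurons$cell_class == "EB-LAL-PB"]
  # steady train in wedge 2 only -> single bump at its centre
  rec <- record_for(circ, setNames(list(seq(0.05, 2, by = 0.02)), eb[3]), 2)
  wr <- wedge_rates(rec, circ)
  bm <- bump_metrics(wr)
  late <- bm$time > 1
  expect_true(all(bm$n_bumps[late] == 1))
  expect_equal(stats::median(bm$peak_angle[late]),
               wedge_centers(circ$topology)[3], tolerance = 1)
  # all-zero profile: explicit undefined sentinel
  rec0 <- record_for(circ, list(), 1)
  bm0 <- bump_metrics(wedge_rates(rec0, circ))
  expect_true(all(!bm0$defined))
  expect_true(all(is.na(bm0$peak_angle)))
})

test_that("uniform profiles have zero vector strength and no defined peak", {
  r <- structure(list(time = 0.5, rates = matrix(3, 1, 16),
                      wedge = 0:15,
                      wedge_centers = seq(11.25, 348.75, by = 22.5),
                      n_per_wedge = rep(1L, 16), kernel_tau = 0.7215),
                 class = "cx_wedge_rates")
  bm <- bump_metrics(r)
  expect_equal(bm$vector_strength, 0, tolerance = 1e-12)
  expect_false(bm$defined)
  expect_equal(bm$n_bumps, 0L)
})

test_that("wrapped-Gaussian profile width matches 2.355 sigma", {
  theta <- seq(11.25, 348.75, by = 22.5)
  for (sig in c(30, 45)) {
    prof <- exp(-0.5 * (cxsim:::circ_diff_deg(theta, 180) / sig)^2)
    r <- structure(list(time = 0, rates = matrix(prof, 1),
                        wedge = 0:15, wedge_centers = theta,
                        n_per_wedge = rep(1L, 16), kernel_tau = 0.7215),
                   class = "cx_wedge_rates")
    bm <- bump_metrics(r)
    expect_equal(bm$n_bumps, 1L)
    expect_equal(bm$peak_angle, 180, tolerance = 1e-6)
    expect_equal(bm$width, 2.355 * sig, tolerance = 0.05 * 2.355 * sig)
  }
})

test_that("permuting wedge labels rotates the decoded angle", {
  theta <- seq(11.25, 348.75, by = 22.5)
  prof <- exp(-0.5 * (cxsim:::circ_diff_deg(theta, 100) / 40)^2)
  mk <- function(p) structure(
    list(time = 0, rates = matrix(p, 1), wedge = 0:15,
         wedge_centers = theta, n_per_wedge = rep(1L, 16),
         kernel_tau = 0.7215), class = "cx_wedge_rates")
  b0 <- bump_metrics(mk(prof))
  for (k in c(1, 5)) {
    bk <- bump_metrics(mk(prof[((0:15 - k) %% 16) + 1]))
    expect_equal((bk$peak_angle - b0$peak_angle) %% 360, (k * 22.5) %% 360,
                 tolerance = 1e-6)
  }
})

test_that("two separated blobs count as two bumps", {
  theta <- seq(11.25, 348.75, by = 22.5)
  prof <- exp(-0.5 * (cxsim:::circ_diff_deg(theta, 60) / 25)^2) +
    0.8 * exp(-0.5 * (cxsim:::circ_diff_deg(theta, 240) / 25)^2)
  r <- structure(list(time = 0, rates = matrix(prof, 1), wedge = 0:15,
                      wedge_centers = theta, n_per_wedge = rep(1L, 16),
                      kernel_tau = 0.7215), class = "cx_wedge_rates")
  expect_equal(bump_metrics(r)$n_bumps, 2L)
})

test_that("tracking error measures circular distance with offset correction", {
  pr <- make_usecase4_protocol()
  tgrid <- seq(2, 29, by = 0.1)
  bar <- bar_azimuth(pr, tgrid)
  mk_metrics <- function(peak) {
    structure(data.frame(time = tgrid, peak_angle = peak %% 360,
                         amplitude = 1, width = 45, n_bumps = 1L,
                         vector_strength = 0.9, defined = TRUE),
              class = c("cx_bump_metrics", "data.frame"))
  }
  # perfect tracking
  e0 <- tracking_error(mk_metrics(bar), pr, offset_correction = FALSE)
  expect_true(all(abs(e0$error_deg) < 1e-9))
  # antipodal: maximal circular distance
  e180 <- tracking_error(mk_metrics(bar + 180), pr, offset_correction = FALSE)
  expect_true(all(abs(e180$error_deg - 180) < 1e-9))
  # constant 30-degree offset removed by correction
  e30 <- tracking_error(mk_metrics(bar + 30), pr, offset_correction = TRUE,
                        window = c(2, 29))
  expect_true(all(abs(e30$error_deg) < 1e-6))
})

test_that("persistence verdicts follow the amplitude-ratio contract", {
  theta <- seq(11.25, 348.75, by = 22.5)
  tgrid <- seq(0, 36, by = 0.01)
  prof <- exp(-0.5 * (cxsim:::circ_diff_deg(theta, 90) / 30)^2)
  mk <- function(amp_t) structure(
    list(time = tgrid, rates = outer(amp_t, prof), wedge = 0:15,
         wedge_centers = theta, n_per_wedge = rep(1L, 16),
         kernel_tau = 0.7215), class = "cx_wedge_rates")
  # frozen after t_off: ratio 1, verdict true
  p1 <- persistence(mk(rep(10, length(tgrid))), t_off = 33)
  expect_true(p1$verdict)
  expect_equal(p1$ratio, 1, tolerance = 1e-9)
  # zero after t_off: ratio 0, verdict false
  amp <- ifelse(tgrid < 33, 10, 0)
  p0 <- persistence(mk(amp), t_off = 33)
  expect_false(p0$verdict)
  expect_equal(p0$ratio, 0, tolerance = 1e-9)
  # exponential decay: ratio matches the analytic window average
  tau <- 0.8
  amp_e <- ifelse(tgrid < 33, 10, 10 * exp(-(tgrid - 33) / tau))
  pe <- persistence(mk(amp_e), t_off = 33, horizon = 1.5)
  h <- 1.5
  ratio_exact <- tau * (exp(-h / (2 * tau)) - exp(-h / tau)) / (h / 2)
  expect_equal(pe$ratio, ratio_exact, tolerance = 1e-3)
  # horizon beyond the trace errors
  expect_error(persistence(mk(rep(1, length(tgrid))), t_off = 35.5,
                           horizon = 1.5), "horizon")
})
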