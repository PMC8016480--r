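test_that("the comparison protocol has the printed schedule", {
  pr <- make_usecase4_protocol()
  expect_equal(pr$duration, 35)
  roles <- vapply(pr$bars, function(b) b$role, character(1))
  expect_setequal(roles, c("moving", "static"))
  mv <- pr$bars[[which(roles == "moving")]]
  st <- pr$bars[[which(roles == "static")]]
  # static bar fixed at 60 degrees, strictly dimmer than the moving bar
  expect_equal(st$azimuth_fun(c(0, 10, 20)), rep(60, 3))
  expect_lt(st$brightness, mv$brightness)
  # moving bar stationary during the first second
  expect_equal(mv$azimuth_fun(c(0, 0.5, 0.99)), rep(0, 3))
  expect_false(mv$azimuth_fun(5) == 0)
  # moving bar gone after 30 s, static after 33 s, darkness after
  expect_true(all(render(pr, 31) == render(pr, 31) * (render(pr, 31) > 0)))
  f34 <- render(pr, 34)
  expect_true(all(f34 == 0))
  expect_error(render(pr, 36), "duration")
})

test_that("protocol configuration errors are rejected", {
  expect_error(make_usecase4_protocol(list(moving_brightness = 1.2)),
               "brightness")
  expect_error(make_usecase4_protocol(list(duration = -1)), "duration|t_off")
})

test_that("rendering is geometric: bands, wrap-around, max combination", {
  b1 <- bar_spec(function(t) rep(10, length(t)), width = 22.5,
                 brightness = 1, t_on = 0, t_off = 1)
  pr <- stimulus_protocol(list(b1), duration = 1)
  f <- render(pr, 0.5)
  az <- attr(f, "az_centers")
  on <- f[, 1] > 0
  expect_true(all(circ_dist_deg(az[on], 10) <= 11.25 + 1))
  expect_equal(sum(on), 22L, tolerance = 1)
  # empty protocol renders zeros
  f0 <- render(stimulus_protocol(list(), duration = 1), 0.3)
  expect_true(all(f0 == 0))
  # overlapping bars combine by max
  b2 <- bar_spec(function(t) rep(15, length(t)), 22.5, 0.5, 0, 1)
  prm <- stimulus_protocol(list(b1, b2), duration = 1)
  fm <- render(prm, 0.5)
  expect_equal(max(fm), 1)
  ov <- circ_dist_deg(az, 15) < 5
  expect_true(all(fm[ov, 1] == 1))
})

test_that("receptive-field filtering is area-normalized", {
  pr <- stimulus_protocol(list(bar_spec(function(t) rep(180, length(t)),
                                        359.9, 1, 0, 1)), duration = 1)
  full <- render(pr, 0.5)
  expect_equal(rf_filter(full, rf_rect(90, 22.5)), 1, tolerance = 1e-6)
  expect_equal(rf_filter(full, rf_gauss(90, 9)), 1, tolerance = 1e-6)
  dark <- render(stimulus_protocol(list(), duration = 1), 0.5)
  expect_equal(rf_filter(dark, rf_rect(0, 22.5)), 0)
  expect_equal(rf_filter(dark, rf_gauss(120, 9)), 0)
})

test_that("a centred 20-degree bar drives a 22.5-degree field at 20/22.5", {
  pr <- stimulus_protocol(list(bar_spec(function(t) rep(101.25, length(t)),
                                        20, 1, 0, 1)), duration = 1)
  f <- render(pr, 0.5)
  # grid quadrature approximates the overlap fraction at its 1-deg resolution
  expect_equal(rf_filter(f, rf_rect(101.25, 22.5)), 20 / 22.5,
               tolerance = 0.05)
  # the closed-form drive hits it exactly
  d <- cxsim:::rf_drive(pr, rf_rect(101.25, 22.5), 0.5)
  expect_equal(d, 20 / 22.5, tolerance = 1e-9)
})

test_that("closed-form drives agree with grid rendering plus rf_filter", {
  pr <- make_usecase4_protocol()
  for (tt in c(0.5, 5.2, 17.9, 31.0, 34.0)) {
    f <- render(pr, tt)
    for (rf in list(rf_rect(56.25, 22.5), rf_rect(190, 20),
                    rf_gauss(60, 9), rf_gauss(321, 9))) {
      expect_lt(abs(cxsim:::rf_drive(pr, rf, tt) - rf_filter(f, rf)), 0.02)
    }
  }
})

test_that("model B encoder: background, calibration, and linearity", {
  b <- build_model_B(make_topology())
  dt <- 1e-3
  # darkness: background rate everywhere
  dark <- stimulus_protocol(list(), duration = 0.1)
  drv <- encode_model_B(b, dark, dt = dt)
  expect_true(all(drv$values == 5))
  # calibration bar centred on a wedge: stimulus-driven component 120 Hz
  ctr <- wedge_centers(b$topology)[3]
  cal <- stimulus_protocol(list(bar_spec(function(t) rep(ctr, length(t)),
                                         20, 1, 0, 0.1)), duration = 0.1)
  drv_cal <- encode_model_B(b, cal, dt = dt)
  w2 <- drv_cal$ids[b$neurons$wedge[match(drv_cal$ids, b$neurons$id)] == 2L]
  expect_equal(max(drv_cal$values[, drv_cal$ids %in% w2]) - 5, 120,
               tolerance = 1e-9)
  # homogeneity of degree one in brightness
  half <- stimulus_protocol(list(bar_spec(function(t) rep(ctr, length(t)),
                                          20, 0.5, 0, 0.1)), duration = 0.1)
  drv_half <- encode_model_B(b, half, dt = dt)
  expect_equal(max(drv_half$values[, drv_cal$ids %in% w2]) - 5, 60,
               tolerance = 1e-9)
  # bounded
  expect_true(all(drv_cal$values >= 0 & drv_cal$values <= 125))
})

test_that("model B encoder is translation-equivariant across wedges", {
  b <- build_model_B(make_topology())
  dt <- 1e-3
  mk <- function(az) stimulus_protocol(list(bar_spec(
    function(t) rep(az, length(t)), 20, 1, 0, 0.05)), duration = 0.05)
  d0 <- encode_model_B(b, mk(10), dt = dt)
  d1 <- encode_model_B(b, mk(10 + 22.5), dt = dt)
  w <- b$neurons$wedge[match(d0$ids, b$neurons$id)]
  r0 <- d0$values[1, order(w)]
  r1 <- d1$values[1, order(w)]
  expect_equal(r1, r0[c(16, 1:15)], tolerance = 1e-9)
})

test_that("model C encoder routes wedge drive to the glomerulus pair", {
  cc <- build_model_C(make_topology())
  dt <- 1e-3
  ctr <- wedge_centers(cc$topology)[5]
  pr <- stimulus_protocol(list(bar_spec(function(t) rep(ctr, length(t)),
                                        22.5, 1, 0, 0.05)), duration = 0.05)
  drv <- encode_model_C(cc, pr, dt = dt)
  # disabled PB-EB-NO neurons receive no input channels
  cls <- cc$neurons$cell_class[match(drv$ids, cc$neurons$id)]
  expect_false(any(cls == "PB-EB-NO"))
  # a wedge-covering max-brightness bar gives 50 Hz at the mapped pair
  pair <- cc$topology$wedge_to_glom_pair[5, ]
  glom <- cc$neurons$glom[match(drv$ids, cc$neurons$id)]
  expect_equal(max(drv$values[, glom %in% pair]), 50, tolerance = 1)
  # darkness: zero, no background
  dark <- stimulus_protocol(list(), duration = 0.05)
  expect_true(all(encode_model_C(cc, dark, dt = dt)$values == 0))
})

test_that("model A encoder injects RF-filtered currents and skips disabled", {
  a <- build_model_A(make_topology())
  dt <- 1e-3
  dark <- stimulus_protocol(list(), duration = 0.05)
  d0 <- encode_model_A(a, dark, dt = dt)
  expect_true(all(d0$values == 0))
  # full-field light: every PB current equals the gain
  full <- stimulus_protocol(list(bar_spec(function(t) rep(180, length(t)),
                                          359.9, 1, 0, 0.05)), duration = 0.05)
  d1 <- encode_model_A(a, full, dt = dt)
  cls <- a$neurons$cell_class[match(d1$ids, a$neurons$id)]
  gain <- a$config$encoder$gain_pb
  expect_equal(unname(d1$values[1, cls != "Ring"]),
               rep(gain, sum(cls != "Ring")), tolerance = 0.01)
  # a localized bar drives only neurons whose RF overlaps it
  loc <- stimulus_protocol(list(bar_spec(function(t) rep(0, length(t)),
                                         20, 1, 0, 0.05)), duration = 0.05)
  d2 <- encode_model_A(a, loc, dt = dt)
  glom <- a$neurons$glom[match(d2$ids, a$neurons$id)]
  far <- which(cls != "Ring" &
                 circ_dist_deg(a$topology$glom_centers[
                   match(glom, a$topology$glom_ids)], 0) > 40)
  expect_true(all(d2$values[, far] == 0))
  # silenced neurons are excluded from the drive
  a_sil <- silence(a, "PB-EB-NO")
  d3 <- encode_model_A(a_sil, loc, dt = dt)
  cls3 <- a_sil$neurons$cell_class[match(d3$ids, a_sil$neurons$id)]
  expect_false(any(cls3 == "PB-EB-NO"))
})

test_that("Poisson sampling is seed-deterministic and statistically sound", {
  ids <- c("x", "y")
  dt <- 1e-4
  drv <- cxsim:::new_input_drive("poisson", dt, ids,
                                 matrix(100, 20000, 2), NULL)
  s1 <- sample_poisson(drv, seed = 3)
  s2 <- sample_poisson(drv, seed = 3)
  expect_identical(s1$steps, s2$steps)
  s3 <- sample_poisson(drv, seed = 4)
  expect_false(identical(s1$steps, s3$steps))
  # expected count 100 Hz * 2 s = 200, sd ~ 14
  for (k in 1:2) {
    expect_lt(abs(length(s1$steps[[k]]) - 200), 3 * sqrt(200))
  }
  # zero rate emits nothing; dt * rate >= 1 is rejected
  drv0 <- cxsim:::new_input_drive("poisson", dt, "x",
                                  matrix(0, 100, 1), NULL)
  expect_equal(length(sample_poisson(drv0, 1)$steps[[1]]), 0L)
  bad <- cxsim:::new_input_drive("poisson", 0.1, "x",
                                 matrix(100, 10, 1), NULL)
  expect_error(sample_poisson(bad, 1), "dt")
})
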