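test_that("IR signal nulls at TI = T1 log(2) and saturates at long TI", {
  sched <- IRSchedule(c(1000 * log(2), 10000), inversion_efficiency = 1)
  s <- simulateIRSignal(1000, sched)
  expect_equal(s[1], 0, tolerance = 1e-12)
  expect_equal(s[2], 1, tolerance = 1e-4)
})

test_that("IR signal equals the closed-form recovery curve", {
  sched <- defaultIRSchedule(n = 7, t1_max = 1500)
  ti <- inversionTimes(sched)
  s <- simulateIRSignal(447.37, sched, M0 = 2.5)
  expect_equal(s, 2.5 * (1 - 2 * exp(-ti / 447.37)), tolerance = 1e-14)
  # partial inversion
  sched2 <- IRSchedule(ti, inversion_efficiency = 0.9)
  s2 <- simulateIRSignal(447.37, sched2)
  expect_equal(s2, 1 - 1.8 * exp(-ti / 447.37), tolerance = 1e-14)
  expect_error(simulateIRSignal(447.37, sched, noise_sd = -0.1), ">= 0")
})

test_that("T1 fitting recovers noise-free inputs to high precision", {
  sched <- defaultIRSchedule()
  for (t1 in c(150, 447.37, 2897, 4250)) {
    s <- simulateIRSignal(t1, sched)
    expect_equal(fitT1IR(s, sched), t1, tolerance = 1e-6)
  }
  full <- fitT1IR(simulateIRSignal(1000, sched, M0 = 3), sched, full = TRUE)
  expect_equal(full$M0, 3, tolerance = 1e-6)
  expect_equal(full$beta, 1, tolerance = 1e-6)
})

test_that("T1 and T2 fits are invariant to overall signal scale", {
  ir <- defaultIRSchedule()
  cp <- CPMGSchedule(2, 500)
  s_ir <- simulateIRSignal(800, ir, noise_sd = 0.01, seed = 3)
  s_t2 <- simulateCPMG(250, cp, noise_sd = 0.005, seed = 4)
  t1_ref <- fitT1IR(s_ir, ir)
  t2_ref <- fitT2Mono(s_t2, echoTimes(cp))
  for (k in c(2.5, 1e6, 1e-3)) {
    expect_equal(fitT1IR(k * s_ir, ir), t1_ref, tolerance = 1e-8)
    expect_equal(fitT2Mono(k * s_t2, echoTimes(cp)), t2_ref,
                 tolerance = 1e-8)
  }
})

test_that("constant signals raise a fit-failure error", {
  sched <- defaultIRSchedule()
  expect_error(fitT1IR(rep(0.7, 7), sched), "no decay")
  expect_error(fitT2Mono(rep(1, 10), 1:10), "no decay")
})

test_that("noisy T1 estimates are unbiased to better than 0.5%", {
  sched <- defaultIRSchedule(n = 7, t1_max = 1500)
  set.seed(21)
  est <- vapply(1:500, function(i)
    fitT1IR(simulateIRSignal(1000, sched, noise_sd = 0.01), sched),
    numeric(1))
  expect_lt(abs(mean(est) - 1000) / 1000, 0.005)
})

test_that("CPMG decay hits the 1/e point and the zero-decay limit", {
  cp <- CPMGSchedule(946, 8)
  s <- simulateCPMG(946, cp, M0 = 2)
  expect_equal(s[1], 2 / exp(1), tolerance = 1e-12)
  # first echo tends to M0 as the echo spacing vanishes
  cp0 <- CPMGSchedule(1e-6, 8)
  expect_equal(simulateCPMG(500, cp0)[1], 1, tolerance = 1e-8)
  # full curve equals the direct formula, monotone non-increasing
  cp2 <- CPMGSchedule(1.5, 64)
  s2 <- simulateCPMG(310, cp2, M0 = 1.2)
  expect_equal(s2, 1.2 * exp(-echoTimes(cp2) / 310), tolerance = 1e-14)
  expect_true(all(diff(s2) <= 0))
})

test_that("T2 fitting is exact noise-free and matches the two-point closed form", {
  cp <- CPMGSchedule(2, 1000)
  s <- simulateCPMG(2760, cp)
  expect_equal(fitT2Mono(s, echoTimes(cp)), 2760, tolerance = 1e-6)
  # two echoes: closed-form solution T2 = (t2 - t1) / log(s1/s2)
  tpts <- c(30, 140)
  amps <- exp(-tpts / 210)
  expect_equal(fitT2Mono(amps, tpts), (140 - 30) / log(amps[1] / amps[2]),
               tolerance = 1e-10)
})

test_that("non-positive amplitudes trigger the nonlinear T2 fallback", {
  tpts <- seq(5, 400, by = 5)
  amps <- exp(-tpts / 120)
  amps[length(amps)] <- -1e-4  # a noisy late echo below zero
  fit <- fitT2Mono(amps, tpts, full = TRUE)
  expect_identical(fit$mode, "nonlinear")
  expect_equal(fit$T2, 120, tolerance = 0.01)
})

test_that("noisy T2 estimates are nearly unbiased at 0.5% noise", {
  cp <- CPMGSchedule(1, 1000)
  set.seed(33)
  est <- vapply(1:300, function(i)
    fitT2Mono(simulateCPMG(250, cp, noise_sd = 0.005), echoTimes(cp)),
    numeric(1))
  expect_lt(abs(mean(est) - 250) / 250, 0.01)
})

test_that("relaxometry study averages repeats and reduces variance", {
  ir <- defaultIRSchedule(n = 7, t1_max = 1500)
  cp <- CPMGSchedule(1, 1000)
  samples <- data.frame(sample_id = c("a", "b"), T1 = c(800, 1200),
                        T2 = c(150, 400))
  # noise-free: identity
  st <- runRelaxometryStudy(samples, ir, cp)
  expect_equal(st$T1_ms, samples$T1, tolerance = 1e-6)
  expect_equal(st$T2_ms, samples$T2, tolerance = 1e-6)
  expect_error(runRelaxometryStudy(samples[0, ], ir, cp), "non-empty")
  # averaging repeats shrinks the spread of the per-sample estimate
  one <- data.frame(sample_id = "a", T1 = 800, T2 = 150,
                    t1_repeats = 1, t2_repeats = 1)
  three <- data.frame(sample_id = "a", T1 = 800, T2 = 150,
                      t1_repeats = 3, t2_repeats = 3)
  set.seed(9)
  single <- vapply(1:40, function(i)
    runRelaxometryStudy(one, ir, cp, noise_sd = 0.02)$T1_ms, numeric(1))
  averaged <- vapply(1:40, function(i)
    runRelaxometryStudy(three, ir, cp, noise_sd = 0.02)$T1_ms, numeric(1))
  expect_lt(sd(averaged), sd(single))
})

test_that("study failures carry the sample id", {
  ir <- IRSchedule(c(1, 2, 3))  # hopelessly short for T1 = 1e6
  cp <- CPMGSchedule(1, 1000)
  bad <- data.frame(sample_id = "vial_9", T1 = 1000, T2 = 1e-9)
  expect_error(
    runRelaxometryStudy(bad, defaultIRSchedule(), cp, noise_sd = 0),
    "vial_9")
})

test_that("noise-free 60 MHz replication recovers unit slopes", {
  # calibrate relaxivities from the single-agent series, measure all 17
  # samples, invert, and regress estimated on true concentration
  ir <- defaultIRSchedule(n = 7, t1_max = 4500)
  cp <- CPMGSchedule(1, 1000)
  tab <- defaultPhantomTable()
  tt <- forwardRelaxation(water60, gd60, mn60, tab$gd_mM, tab$mn_mM)
  st <- runRelaxometryStudy(
    data.frame(sample_id = tab$vial_id, T1 = tt$T1, T2 = tt$T2), ir, cp)
  bl <- BaselineRelaxation(st$T1_ms[17], st$T2_ms[17])
  gd_fit <- AgentRelaxivity("Gd",
    fitSlope(fitRelaxivity(tab$gd_mM[1:5], 1 / st$T1_ms[1:5])),
    fitSlope(fitRelaxivity(tab$gd_mM[1:5], 1 / st$T2_ms[1:5])))
  mn_fit <- AgentRelaxivity("Mn",
    fitSlope(fitRelaxivity(tab$mn_mM[6:10], 1 / st$T1_ms[6:10])),
    fitSlope(fitRelaxivity(tab$mn_mM[6:10], 1 / st$T2_ms[6:10])))
  est <- invertDualAgent(bl, gd_fit, mn_fit, st$T1_ms, st$T2_ms)
  cal_gd <- calibrationReport(tab$gd_mM, est$concA)
  cal_mn <- calibrationReport(tab$mn_mM, est$concB)
  expect_lt(abs(fitSlope(cal_gd) - 1), 1e-6)
  expect_lt(abs(fitSlope(cal_mn) - 1), 1e-6)
  expect_gt(fitRSquared(cal_gd), 0.999999)
  expect_gt(fitRSquared(cal_mn), 0.999999)
})
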