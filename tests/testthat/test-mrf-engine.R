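test_that("default schedule is deterministic and respects its envelope", {
  s1 <- makeDefaultSchedule(n = 3000, seed = 4)
  s2 <- makeDefaultSchedule(n = 3000, seed = 4)
  expect_identical(flipAngles(s1), flipAngles(s2))
  expect_identical(repetitionTimes(s1), repetitionTimes(s2))
  s3 <- makeDefaultSchedule(n = 3000, seed = 5)
  expect_false(identical(flipAngles(s1), flipAngles(s3)))
  expect_gte(mean(repetitionTimes(s1)), 12)
  expect_lte(max(repetitionTimes(s1)), 15)
  expect_lte(max(flipAngles(s1)), 75)
  expect_gte(min(flipAngles(s1)), 0)
  # total acquisition of the 3000-point schedule is tens of seconds
  dur_s <- (sum(repetitionTimes(s1)) + inversionTime(s1)) / 1000
  expect_gt(dur_s, 30)
  expect_lt(dur_s, 60)
  # degenerate length-1 schedule is valid
  expect_s4_class(makeDefaultSchedule(n = 1, seed = 1), "MRFSchedule")
})

test_that("grid axes expand with shared boundaries counted once", {
  ax <- expandGridAxes(defaultDictionaryGrid())
  # independent enumeration of the printed segment lists
  t1_oracle <- unique(c(seq(10, 100, 10), seq(100, 1000, 20),
                        seq(1000, 2000, 40), seq(2000, 4500, 100)))
  t2_oracle <- unique(c(seq(2, 100, 2), seq(100, 150, 5), seq(160, 300, 10),
                        seq(300, 800, 50), seq(800, 1600, 100),
                        seq(1600, 3000, 200)))
  expect_identical(ax$T1, sort(t1_oracle))
  expect_identical(ax$T2, sort(t2_oracle))
  expect_length(ax$T1, 105L)
  expect_length(ax$T2, 100L)
})

test_that("grid expansion filters T2 > T1 pairs and orders by T1 then T2", {
  pairs <- expandDictionaryGrid(defaultDictionaryGrid())
  expect_true(all(pairs$T2 <= pairs$T1))
  expect_true(!is.unsorted(pairs$T1))
  # unfiltered expansion is the full Cartesian product
  nofilter <- expandDictionaryGrid(defaultDictionaryGrid(t2_le_t1 = FALSE))
  expect_identical(nrow(nofilter), 105L * 100L)
  # filtered count agrees with a brute-force pair count
  ax <- expandGridAxes(defaultDictionaryGrid())
  expect_identical(nrow(pairs),
                   sum(outer(ax$T1, ax$T2, ">=")))
  # single-point segment expands to one value
  g1 <- DictionaryGrid(list(c(10, 10, 10)), list(c(5, 5, 5)))
  expect_identical(expandDictionaryGrid(g1),
                   data.frame(T1 = 10, T2 = 5))
})

test_that("FISP signal vanishes without excitation or transverse lifetime", {
  sched <- small_schedule()
  expect_true(all(simulateFISP(1000, 100,
    MRFSchedule(rep(0, 50), rep(12, 50))) == 0))
  expect_lt(max(Mod(simulateFISP(1000, 0.01, sched))), 1e-8)
  expect_warning(simulateFISP(100, 200, sched), "unphysical")
  expect_error(simulateFISP(-5, 100, sched), "> 0")
})

test_that("EPG simulation agrees with the isochromat Bloch oracle", {
  set.seed(2024)
  for (i in 1:5) {
    n <- sample(50:150, 1)
    T1 <- exp(runif(1, log(100), log(3000)))
    T2 <- exp(runif(1, log(20), log(min(T1, 1500))))
    sch <- makeDefaultSchedule(n = n, seed = sample.int(1e6, 1))
    e <- simulateFISP(T1, T2, sch, kmax = n)
    b <- bloch_fisp(T1, T2, flipAngles(sch), repetitionTimes(sch),
                    inversionTime(sch), echoTime(sch))
    expect_lt(rel_rms(e, b), 0.01)
  }
})

test_that("EPG truncation at the default order is innocuous", {
  sch <- makeDefaultSchedule(n = 500, seed = 8)
  full <- simulateFISP(1000, 100, sch, kmax = 500)
  trunc <- simulateFISP(1000, 100, sch, kmax = 50)
  expect_lt(rel_rms(trunc, full), 1e-3)
})

test_that("dictionary atoms are unit norm, ordered, and bit-reproducible", {
  g <- DictionaryGrid(list(c(200, 400, 200)), list(c(50, 100, 50)))
  sched <- small_schedule()
  d <- buildDictionary(g, sched)
  expect_identical(dictSize(d), 4L)
  expect_equal(rowSums(Mod(dictAtoms(d))^2), rep(1, 4), tolerance = 1e-12)
  lk <- dictLookup(d)
  expect_true(!is.unsorted(lk$T1))
  expect_true(all(tapply(lk$T2, lk$T1, function(x) !is.unsorted(x))))
  d2 <- buildDictionary(g, sched)
  expect_identical(dictAtoms(d), dictAtoms(d2))
  # a schedule with no excitation yields zero-norm atoms -> error
  expect_error(
    buildDictionary(g, MRFSchedule(rep(0, 20), rep(12, 20))),
    "zero-norm")
})

test_that("atoms match themselves with coefficient 1, invariant to scale and phase", {
  d <- small_dictionary()
  lk <- dictLookup(d)
  set.seed(3)
  idx <- sample(dictSize(d), 25)
  m <- matchFingerprints(dictAtoms(d)[idx, ], d)
  expect_identical(m$T1, lk$T1[idx])
  expect_identical(m$T2, lk$T2[idx])
  expect_equal(m$match, rep(1, 25), tolerance = 1e-10)
  # positive scaling changes only the scale column
  m2 <- matchFingerprints(2.5 * dictAtoms(d)[idx, ], d)
  expect_identical(m2[c("T1", "T2")], m[c("T1", "T2")])
  expect_equal(m2$match, m$match, tolerance = 1e-12)
  expect_equal(m2$scale, 2.5 * m$scale, tolerance = 1e-12)
  # a global phase changes nothing observable
  m3 <- matchFingerprints(exp(0.7i) * dictAtoms(d)[idx, ], d)
  expect_identical(m3[c("T1", "T2")], m[c("T1", "T2")])
  expect_equal(m3$scale, m$scale, tolerance = 1e-12)
})

test_that("zero-norm signals are flagged as background, not errors", {
  d <- small_dictionary()
  m <- matchFingerprints(rep(0 + 0i, ncol(dictAtoms(d))), d)
  expect_true(m$no_signal)
  expect_identical(m$T1, 0)
  expect_identical(m$scale, 0)
  expect_error(matchFingerprints(rep(1 + 0i, 5), d), "does not match")
})

test_that("matching survives noise at SNR 30 on the full dictionary", {
  d <- default_dictionary()
  lk <- dictLookup(d)
  i0 <- which(lk$T1 == 800 & lk$T2 == 80)
  atom <- dictAtoms(d)[i0, ]
  n <- length(atom)
  ntrial <- 1000
  # SNR 30: total complex noise sd = peak amplitude / 30
  sdv <- max(Mod(atom)) / 30 / sqrt(2)
  set.seed(42)
  sig <- matrix(atom, ntrial, n, byrow = TRUE) +
    matrix(complex(real = rnorm(ntrial * n, sd = sdv),
                   imaginary = rnorm(ntrial * n, sd = sdv)), ntrial, n)
  m <- matchFingerprints(sig, d)
  expect_gte(mean(m$T1 == 800 & m$T2 == 80), 0.99)
})

test_that("off-grid truths match within one grid step across the hull", {
  d <- default_dictionary()
  sch <- default_schedule()
  ax <- expandGridAxes(defaultDictionaryGrid())
  set.seed(7)
  nd <- 200
  T1t <- runif(nd, 15, 4400)
  T2t <- vapply(T1t, function(t1) runif(1, 2.5, min(t1, 2900)), numeric(1))
  sigs <- t(vapply(seq_len(nd),
                   function(i) simulateFISP(T1t[i], T2t[i], sch),
                   complex(scheduleLength(sch))))
  m <- matchFingerprints(sigs, d)
  ok <- within_one_step(T1t, m$T1, ax$T1) & within_one_step(T2t, m$T2, ax$T2)
  expect_gte(mean(ok), 0.95)
})

test_that("matchMap reproduces a known atom pattern and flags background", {
  d <- small_dictionary()
  lk <- dictLookup(d)
  nt <- ncol(dictAtoms(d))
  arr <- array(0 + 0i, dim = c(4, 4, nt))
  pick <- matrix(c(3, 17, 40, 9), 2, 2)
  for (r in 1:2) for (c in 1:2)
    arr[r, c, ] <- dictAtoms(d)[pick[r, c], ]
  maps <- matchMap(arr, d)
  for (r in 1:2) for (c in 1:2) {
    expect_identical(t1Map(maps)[r, c], lk$T1[pick[r, c]])
    expect_identical(t2Map(maps)[r, c], lk$T2[pick[r, c]])
  }
  expect_true(all(noSignalMask(maps)[3:4, ]))
  expect_true(all(t1Map(maps)[3:4, ] == 0))
  # all-zero series -> all background
  maps0 <- matchMap(array(0 + 0i, dim = c(2, 2, nt)), d)
  expect_true(all(noSignalMask(maps0)))
  expect_error(matchMap(arr, d, mask = matrix(TRUE, 3, 3)), "mask")
})
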