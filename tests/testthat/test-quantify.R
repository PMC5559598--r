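test_that("baseline-valued maps invert to all-zero concentration maps", {
  t1m <- matrix(2897, 8, 8)
  t2m <- matrix(946, 8, 8)
  cm <- concentrationMaps(t1m, t2m, water3t, gd3t_mrf, mn3t_mrf)
  expect_true(all(agentMap(cm, 1) == 0))
  expect_true(all(agentMap(cm, 2) == 0))
  expect_error(concentrationMaps(t1m, matrix(946, 4, 4), water3t,
                                 gd3t_mrf, mn3t_mrf), "dimensions")
})

test_that("per-vial means from noise-free forward-model maps equal the truth", {
  spec <- defaultPhantomSpec(image_shape = c(64, 64), radius_px = 4)
  tm <- renderTruthMaps(spec)
  bl <- phantomBaseline(spec)
  tt <- forwardRelaxation(bl, gd3t_mrf, mn3t_mrf,
                          as.vector(truthGd(tm)), as.vector(truthMn(tm)))
  t1m <- matrix(tt$T1, 64, 64)
  t2m <- matrix(tt$T2, 64, 64)
  cm <- concentrationMaps(t1m, t2m, bl, gd3t_mrf, mn3t_mrf)
  roi <- roiStats(cm, truthLabels(tm))
  v <- vialTable(spec)
  ord <- match(roi$vial_id, v$vial_id)
  expect_equal(roi$meanA, v$gd_mM[ord], tolerance = 1e-10)
  expect_equal(roi$meanB, v$mn_mM[ord], tolerance = 1e-10)
  expect_true(all(roi$sdA < 1e-12))
})

test_that("noisy water maps give near-zero means with both signs unless clamped", {
  set.seed(12)
  n <- 40
  # perturb the water relaxation rates slightly
  t1m <- matrix(1 / (1 / 2897 + rnorm(n * n, sd = 2e-6)), n, n)
  t2m <- matrix(1 / (1 / 946 + rnorm(n * n, sd = 2e-6)), n, n)
  cm <- concentrationMaps(t1m, t2m, water3t, gd3t_mrf, mn3t_mrf)
  expect_true(any(agentMap(cm, 1) < 0) && any(agentMap(cm, 1) > 0))
  expect_lt(abs(mean(agentMap(cm, 1))), 5e-4)
  expect_lt(abs(mean(agentMap(cm, 2))), 5e-4)
  # clamping only affects negative pixels
  cc <- concentrationMaps(t1m, t2m, water3t, gd3t_mrf, mn3t_mrf, clamp = TRUE)
  expect_true(all(agentMap(cc, 1) >= 0))
  pos <- agentMap(cm, 1) >= 0
  expect_identical(agentMap(cc, 1)[pos], agentMap(cm, 1)[pos])
  expect_true(all(agentMap(cc, 1)[!pos] == 0))
})

test_that("no-signal pixels propagate as flagged zeros", {
  t1m <- matrix(c(0, 2897, 500, 300), 2, 2)
  t2m <- matrix(c(0, 946, 200, 100), 2, 2)
  cm <- concentrationMaps(t1m, t2m, water3t, gd3t_mrf, mn3t_mrf)
  expect_true(cm@noSignal[1, 1])
  expect_identical(agentMap(cm, 1)[1, 1], 0)
  roi <- roiStats(cm, matrix(1L, 2, 2))
  expect_identical(roi$n_pixels, 3L)  # the flagged pixel is excluded
})

test_that("ROI statistics match uniform values and a two-pass oracle", {
  vals <- matrix(0, 6, 6)
  labels <- matrix(0L, 6, 6)
  labels[1:2, 1:2] <- 1L; vals[1:2, 1:2] <- 0.3
  set.seed(4)
  labels[4:6, 4:6] <- 2L; vals[4:6, 4:6] <- rnorm(9, 0.1, 0.05)
  cm <- new("ConcentrationMaps", mapA = vals, mapB = vals * 2,
            clamped = FALSE, noSignal = matrix(FALSE, 6, 6),
            agentNames = c("Gd", "Mn"), provenance = list())
  roi <- roiStats(cm, labels)
  expect_identical(roi$meanA[roi$vial_id == 1], 0.3)
  expect_identical(roi$sdA[roi$vial_id == 1], 0)
  expect_equal(roi$sdA[roi$vial_id == 2], sd_two_pass(vals[4:6, 4:6]),
               tolerance = 1e-14)
  # union of two equal-size ROIs averages their means
  merged <- labels
  merged[merged == 2L] <- 1L
  vals2 <- vals; vals2[3, 3] <- 99  # unlabelled, must not count
  cm2 <- new("ConcentrationMaps", mapA = vals2, mapB = vals2,
             clamped = FALSE, noSignal = matrix(FALSE, 6, 6),
             agentNames = c("Gd", "Mn"), provenance = list())
  roi4 <- roiStats(cm2, labels)
  w <- roi4$n_pixels / sum(roi4$n_pixels)
  roiu <- roiStats(cm2, merged)
  expect_equal(roiu$meanA, sum(w * roi4$meanA), tolerance = 1e-14)
})

test_that("calibration report recovers exact and scaled relationships", {
  truth <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  fit <- calibrationReport(truth, truth)
  expect_equal(fitSlope(fit), 1, tolerance = 1e-12)
  expect_equal(fitIntercept(fit), 0, tolerance = 1e-12)
  expect_equal(fitRSquared(fit), 1, tolerance = 1e-12)
  expect_equal(fitSlope(calibrationReport(truth, 2 * truth)), 2,
               tolerance = 1e-12)
  expect_error(calibrationReport(truth[1:2], truth[1:2]), "3 points")
  expect_error(calibrationReport(rep(0.1, 5), truth), "degenerate")
})

test_that("vial comparison matches the closed-form t statistic", {
  mk <- function(a1, b1) {
    r <- data.frame(vial_id = c(1L, 2L), n_pixels = 10L,
                    meanA = c(a1, b1), sdA = 0.01,
                    meanB = c(a1 * 2, b1 * 2), sdB = 0.01)
    attr(r, "agents") <- c("Gd", "Mn")
    r
  }
  # identical per-repeat means across vials: t = 0, p = 1
  reps <- lapply(c(0.1, 0.2, 0.3), function(x) mk(x, x))
  same <- compareVials(reps, 1, 2)
  expect_equal(same$t, c(0, 0), tolerance = 1e-14)
  expect_equal(same$p, c(1, 1), tolerance = 1e-14)
  # textbook two-sample data
  x <- c(0.11, 0.13, 0.12, 0.10); y <- c(0.16, 0.18, 0.17, 0.19)
  reps2 <- lapply(1:4, function(i) mk(x[i], y[i]))
  out <- compareVials(reps2, 1, 2)
  expect_equal(out$t[1], t_two_sample(x, y), tolerance = 1e-12)
  expect_equal(out$df[1], 6)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(out$p[1], tt$p.value, tolerance = 1e-12)
  expect_error(compareVials(reps2[1], 1, 2), ">= 2")
})

test_that("adjacent mixture vials separate significantly over 12 repeats", {
  spec <- defaultPhantomSpec(image_shape = c(64, 64), radius_px = 4)
  sched <- default_schedule()
  d <- default_dictionary()
  reps <- repeatStudy(spec, sched, noise_sd = 0.01, n_repeats = 12, seed = 3)
  rois <- lapply(reps, function(s) {
    maps <- matchMap(s, d)
    lab <- truthLabels(seriesTruth(s))
    wpx <- which(lab == 17L & !noSignalMask(maps))
    bl <- BaselineRelaxation(mean(t1Map(maps)[wpx]), mean(t2Map(maps)[wpx]))
    cm <- concentrationMaps(maps, baseline = bl, agentA = gd3t_mrf,
                            agentB = mn3t_mrf)
    roiStats(cm, lab)
  })
  for (pair in list(c(11, 12), c(12, 13), c(14, 15))) {
    out <- compareVials(rois, pair[1], pair[2])
    expect_true(all(out$p < 0.05))
  }
})

test_that("the pipeline runs end to end, writes artifacts, and is reproducible", {
  out1 <- file.path(tempdir(), "dcmrf_run1")
  out2 <- file.path(tempdir(), "dcmrf_run2")
  cfg <- list(out_dir = out1, seed = 3L, image_shape = c(48L, 48L),
              radius_px = 3, noise_sd = 0.005, n_repeats = 2L,
              schedule = list(n = 300, baseline_tr = 12, seed = 11),
              grid_scale = 3L, write_nifti = TRUE)
  res <- runPipeline(cfg)
  files <- c("phantom_spec.csv", "schedule.json", "grid.json",
             "dictionary.rds", "roi_report.csv", "calibration_report.csv",
             "run_log.json", "t1_map.nii.gz", "conc_A.nii.gz")
  expect_true(all(file.exists(file.path(out1, files))))
  expect_identical(nrow(res$roi), 17L)
  expect_true(all(c("Gd", "Mn") %in% res$log$calibration$agent))
  # identical config -> identical report values
  cfg$out_dir <- out2
  res2 <- runPipeline(cfg)
  expect_identical(res$roi, res2$roi)
  expect_equal(fitSlope(res$calibration$A), fitSlope(res2$calibration$A),
               tolerance = 0)
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("the pipeline quantifies external T1/T2 maps without simulation", {
  out <- file.path(tempdir(), "dcmrf_ext")
  dir.create(out, showWarnings = FALSE)
  spec <- defaultPhantomSpec(image_shape = c(48, 48), radius_px = 3)
  tm <- renderTruthMaps(spec)
  bl <- phantomBaseline(spec)
  tt <- forwardRelaxation(bl, phantomAgents(spec)$A, phantomAgents(spec)$B,
                          as.vector(truthGd(tm)), as.vector(truthMn(tm)))
  writeMapNifti(matrix(tt$T1, 48, 48), file.path(out, "t1.nii.gz"))
  writeMapNifti(matrix(tt$T2, 48, 48), file.path(out, "t2.nii.gz"))
  writeMapNifti(truthLabels(tm) + 0, file.path(out, "labels.nii.gz"))
  res <- runPipeline(list(
    out_dir = out, t1_nifti = file.path(out, "t1.nii.gz"),
    t2_nifti = file.path(out, "t2.nii.gz"),
    labels_nifti = file.path(out, "labels.nii.gz"),
    baseline = c(baseT1(bl), baseT2(bl))))
  v <- vialTable(spec)
  ord <- match(res$roi$vial_id, v$vial_id)
  expect_equal(res$roi$meanA, v$gd_mM[ord], tolerance = 1e-6)
  expect_equal(res$roi$meanB, v$mn_mM[ord], tolerance = 1e-6)
  unlink(out, recursive = TRUE)
})
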