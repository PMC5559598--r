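# Shared fixtures: the reference Gd/Mn parameter sets and small schedules.

water60 <- BaselineRelaxation(4250, 2760)
water3t <- BaselineRelaxation(2897, 946)
gd60 <- AgentRelaxivity("Gd", 0.0040, 0.0048)
mn60 <- AgentRelaxivity("Mn", 0.0054, 0.0652)
gd3t_mrf <- AgentRelaxivity("Gd", 0.0056, 0.0076)
mn3t_mrf <- AgentRelaxivity("Mn", 0.0067, 0.1144)

# small dictionary fixture: coarse grid + short schedule, built lazily
# and shared across test files (deterministic, so safe to cache)
.cache <- new.env(parent = emptyenv())

small_schedule <- function(n = 400) {
  key <- paste0("sched", n)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- makeDefaultSchedule(n = n, seed = 11)
  .cache[[key]]
}

small_dictionary <- function() {
  if (is.null(.cache$small_dict))
    .cache$small_dict <- buildDictionary(defaultDictionaryGrid(scale = 6L),
                                         small_schedule())
  .cache$small_dict
}

# full default dictionary (3000-point schedule, full grid); built once
default_schedule <- function() {
  if (is.null(.cache$def_sched))
    .cache$def_sched <- makeDefaultSchedule(n = 3000, seed = 1)
  .cache$def_sched
}

default_dictionary <- function() {
  if (is.null(.cache$def_dict))
    .cache$def_dict <- buildDictionary(defaultDictionaryGrid(),
                                       default_schedule())
  .cache$def_dict
}

# end-to-end phantom replication (matched maps -> concentration maps ->
# per-vial calibration), shared by several acceptance checks
phantom_replication <- function(noise_sd) {
  key <- paste0("e2e", noise_sd)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  spec <- defaultPhantomSpec()
  dict <- default_dictionary()
  ser <- simulateMRFSeries(spec, default_schedule(), noise_sd = noise_sd,
                           seed = 7)
  maps <- matchMap(ser, dict)
  lab <- truthLabels(seriesTruth(ser))
  wpx <- which(lab == 17L & !noSignalMask(maps))
  bl <- BaselineRelaxation(mean(t1Map(maps)[wpx]), mean(t2Map(maps)[wpx]))
  ag <- phantomAgents(spec)
  cmaps <- concentrationMaps(maps, baseline = bl, agentA = ag$A,
                             agentB = ag$B)
  roi <- roiStats(cmaps, lab)
  tab <- vialTable(spec)
  ord <- match(roi$vial_id, tab$vial_id)
  res <- list(roi = roi, truth = tab[ord, ],
              gd = calibrationReport(tab$gd_mM[ord], roi$meanA),
              mn = calibrationReport(tab$mn_mM[ord], roi$meanB))
  .cache[[key]] <- res
  res
}
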