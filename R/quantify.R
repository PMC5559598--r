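## Pipeline head: concentration maps from T1/T2 maps, ROI statistics,
## calibration reporting and significance testing.

#' Pixelwise dual-agent concentration maps
#'
#' Applies \code{\link{invertDualAgent}} to every foreground pixel of a
#' pair of co-registered T1/T2 maps. Background / no-signal pixels
#' propagate as 0 and stay flagged. Negative estimates (possible with
#' noisy inputs) are returned raw unless \code{clamp = TRUE}, which sets
#' them to 0 (useful for map export; keep clamping off for unbiased ROI
#' statistics).
#'
#' @param t1_map,t2_map numeric matrices of matched relaxation times, ms
#'   (same dimensions). An \code{\link{MRFMaps}} object can be given as
#'   \code{t1_map}, in which case its T1/T2/no-signal content is used.
#' @param baseline \code{\link{BaselineRelaxation}} of the same modality
#'   as the maps (e.g. the matched water-vial values for MRF maps).
#' @param agentA,agentB \code{\link{AgentRelaxivity}} pair.
#' @param clamp clamp negative concentrations to zero?
#' @param no_signal optional logical matrix flagging background pixels;
#'   pixels with non-positive T1 or T2 are always treated as background.
#' @param det_tol singularity threshold, passed to
#'   \code{\link{invertDualAgent}}.
#' @return a \code{\link{ConcentrationMaps}} object.
#' @export
concentrationMaps <- function(t1_map, t2_map = NULL, baseline, agentA, agentB,
                              clamp = FALSE, no_signal = NULL,
                              det_tol = 1e-12) {
  if (is(t1_map, "MRFMaps")) {
    if (is.null(no_signal)) no_signal <- t1_map@noSignal
    t2_map <- t1_map@t2
    t1_map <- t1_map@t1
  }
  if (!is.matrix(t1_map) || !is.matrix(t2_map) ||
      !identical(dim(t1_map), dim(t2_map)))
    stop("'t1_map' and 't2_map' must be matrices of identical dimensions")
  if (is.null(no_signal)) no_signal <- matrix(FALSE, nrow(t1_map), ncol(t1_map))
  if (!identical(dim(no_signal), dim(t1_map)))
    stop("'no_signal' dimensions do not match the maps")
  no_signal <- no_signal | t1_map <= 0 | t2_map <= 0
  mapA <- mapB <- matrix(0, nrow(t1_map), ncol(t1_map))
  fg <- which(!no_signal)
  if (length(fg)) {
    conc <- invertDualAgent(baseline, agentA, agentB,
                            t1_map[fg], t2_map[fg], det_tol = det_tol)
    mapA[fg] <- conc$concA
    mapB[fg] <- conc$concB
  }
  if (clamp) {
    mapA[mapA < 0] <- 0
    mapB[mapB < 0] <- 0
  }
  new("ConcentrationMaps", mapA = mapA, mapB = mapB, clamped = isTRUE(clamp),
      noSignal = no_signal, agentNames = c(agentA@name, agentB@name),
      provenance = list(baseline = c(T1 = baseline@T1, T2 = baseline@T2),
                        r1 = c(agentA@r1, agentB@r1),
                        r2 = c(agentA@r2, agentB@r2),
                        det_tol = det_tol,
                        params_hash = rlang::hash(list(
                          baseline@T1, baseline@T2, agentA@r1, agentA@r2,
                          agentB@r1, agentB@r2))))
}

#' ROI statistics of concentration maps
#'
#' Per-label mean, standard deviation and pixel count of both agent
#' maps, excluding no-signal pixels. Labels with no valid pixel are
#' omitted from the report (not an error).
#'
#' @param maps a \code{\link{ConcentrationMaps}} object.
#' @param labels integer label matrix (0 = background), e.g.
#'   \code{truthLabels(renderTruthMaps(spec))}.
#' @return data.frame with columns \code{vial_id}, \code{n_pixels},
#'   \code{meanA}, \code{sdA}, \code{meanB}, \code{sdB} (agent A = Gd
#'   role, agent B = Mn role; see \code{attr(, "agents")}).
#' @export
roiStats <- function(maps, labels) {
  stopifnot(is(maps, "ConcentrationMaps"))
  if (!identical(dim(labels), dim(maps@mapA)))
    stop("'labels' dimensions do not match the maps")
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  rows <- lapply(ids, function(id) {
    px <- which(labels == id & !maps@noSignal)
    if (!length(px)) return(NULL)
    data.frame(vial_id = id, n_pixels = length(px),
               meanA = mean(maps@mapA[px]),
               sdA = if (length(px) > 1) sd(maps@mapA[px]) else NA_real_,
               meanB = mean(maps@mapB[px]),
               sdB = if (length(px) > 1) sd(maps@mapB[px]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(vial_id = integer(), n_pixels = integer(),
                      meanA = numeric(), sdA = numeric(),
                      meanB = numeric(), sdB = numeric())
  attr(out, "agents") <- maps@agentNames
  out
}

#' Estimated-versus-true calibration report
#'
#' OLS regression of estimated on true concentration with Pearson
#' correlation statistics; an unbiased method gives slope near 1 and
#' intercept near 0.
#'
#' @param true_conc known concentrations, mM (n >= 3).
#' @param est_conc estimated concentrations, mM (same length).
#' @return a \code{\link{CalibrationFit}} (slope, intercept, R^2,
#'   two-tailed p, n).
#' @export
calibrationReport <- function(true_conc, est_conc) {
  if (length(true_conc) != length(est_conc))
    stop("'true_conc' and 'est_conc' must have equal length")
  if (length(true_conc) < 3L) stop("at least 3 points are required")
  if (sd(true_conc) == 0 || sd(est_conc) == 0)
    stop("degenerate variance: concentrations do not vary")
  fitRelaxivity(true_conc, est_conc)
}

#' Compare two vials across repeated scans
#'
#' Unpaired two-tailed Student's t-test (equal-variance by default;
#' Welch optional) on the per-repeat ROI means of two vials, one test
#' per agent.
#'
#' @param reports list of ROI reports (one per repeat), as returned by
#'   \code{\link{roiStats}}.
#' @param vial_a,vial_b vial ids to compare (each needs >= 2 repeats).
#' @param welch use the Welch (unequal-variance) form?
#' @return data.frame with columns \code{agent}, \code{t}, \code{df},
#'   \code{p}.
#' @export
compareVials <- function(reports, vial_a, vial_b, welch = FALSE) {
  stopifnot(is.list(reports), length(reports) >= 2L)
  pull <- function(id, col) {
    v <- vapply(reports, function(rep) {
      row <- rep[rep$vial_id == id, ]
      if (nrow(row) != 1L) NA_real_ else row[[col]]
    }, numeric(1))
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop("vial ", id, " needs at least 2 repeats with valid pixels")
    v
  }
  agents <- attr(reports[[1]], "agents")
  if (is.null(agents)) agents <- c("A", "B")
  res <- lapply(c(meanA = "meanA", meanB = "meanB"), function(col) {
    tt <- t.test(pull(vial_a, col), pull(vial_b, col),
                 var.equal = !welch)
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  })
  data.frame(agent = agents, t = c(res$meanA["t"], res$meanB["t"]),
             df = c(res$meanA["df"], res$meanB["df"]),
             p = c(res$meanA["p"], res$meanB["p"]), row.names = NULL)
}
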