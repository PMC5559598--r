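## Digital vial-phantom generator: the synthetic-data module that stands
## in for the 17-vial Gd/Mn phantom study.

#' Default 17-vial concentration table
#'
#' The representative dual-agent phantom: 5 Gd-only vials spanning
#' 0.05-0.5 mM (serial-dilution style), 5 Mn-only vials spanning
#' 0.0125-0.2 mM (two-fold dilutions), 6 mixtures with Gd from 0.025 to
#' 0.355 mM and Mn from 0.00625 to 0.15 mM (evenly spaced, endpoints
#' exact), and one deionized-water vial. The exact mixture compositions
#' of the original physical phantom are not published; this table is a
#' representative stand-in hitting the stated range endpoints. Supply
#' your own table to \code{\link{PhantomSpec}} to model a specific
#' phantom.
#'
#' @return data.frame with columns \code{vial_id}, \code{gd_mM},
#'   \code{mn_mM} (17 rows).
#' @examples
#' tab <- defaultPhantomTable()
#' sum(tab$gd_mM == 0 & tab$mn_mM == 0)  # one water vial
#' @export
defaultPhantomTable <- function() {
  mix_gd <- seq(0.025, 0.355, length.out = 6)
  mix_mn <- seq(0.00625, 0.15, length.out = 6)
  data.frame(
    vial_id = 1:17,
    gd_mM = c(0.05, 0.1, 0.2, 0.35, 0.5, rep(0, 5), mix_gd, 0),
    mn_mM = c(rep(0, 5), 0.0125, 0.025, 0.05, 0.1, 0.2, mix_mn, 0))
}

#' Default digital phantom
#'
#' Lays the \code{\link{defaultPhantomTable}} vials out in the four-row
#' arrangement of the physical phantom (bottom row Gd-only, third row
#' Mn-only, top two rows mixtures, water in the top row), on a
#' \code{image_shape} image with circular vials.
#'
#' @param image_shape integer (rows, cols); default 128 x 128, a
#'   desk-scale stand-in for a full-resolution scan matrix.
#' @param radius_px vial radius in pixels.
#' @param vials concentration table (columns \code{vial_id},
#'   \code{gd_mM}, \code{mn_mM}); defaults to
#'   \code{\link{defaultPhantomTable}}. Must have 17 rows for the
#'   default layout.
#' @param baseline solvent \code{\link{BaselineRelaxation}}; default the
#'   3 T water baseline.
#' @param agentA,agentB \code{\link{AgentRelaxivity}} pair; default the
#'   3 T MRF Gd/Mn reference relaxivities.
#' @return a \code{\link{PhantomSpec}}.
#' @export
defaultPhantomSpec <- function(image_shape = c(128, 128), radius_px = 9,
                               vials = defaultPhantomTable(),
                               baseline = referenceBaseline("3T"),
                               agentA = referenceRelaxivities("Gd", "3T_MRF"),
                               agentB = referenceRelaxivities("Mn", "3T_MRF")) {
  if (nrow(vials) != 17L)
    stop("the default layout expects 17 vials; build a PhantomSpec directly ",
         "for other designs")
  sx <- image_shape[2] / 128; sy <- image_shape[1] / 128
  cols5 <- c(16, 40, 64, 88, 112)
  rows4 <- c(18, 48, 78, 108)
  geom <- rbind(
    data.frame(vial_id = 1:5,   cx_px = cols5,      cy_px = rows4[4]),  # Gd-only, bottom
    data.frame(vial_id = 6:10,  cx_px = cols5,      cy_px = rows4[3]),  # Mn-only, 3rd row
    data.frame(vial_id = 11:13, cx_px = cols5[1:3], cy_px = rows4[2]),  # mixtures
    data.frame(vial_id = 14:16, cx_px = cols5[1:3], cy_px = rows4[1]),  # mixtures
    data.frame(vial_id = 17,    cx_px = cols5[5],   cy_px = rows4[1]))  # water
  geom$cx_px <- geom$cx_px * sx
  geom$cy_px <- geom$cy_px * sy
  geom$radius_px <- radius_px
  v <- merge(vials, geom, by = "vial_id")
  v <- v[order(v$vial_id), ]
  PhantomSpec(image_shape, v, baseline, agentA, agentB)
}

#' Render ground-truth maps from a phantom spec
#'
#' Rasterizes the vials: a pixel belongs to a vial iff the distance from
#' its center to the vial center is at most the vial radius. The
#' per-agent maps carry the vial concentrations; the label map carries
#' the vial ids (0 = background).
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @return a \code{\link{TruthMaps}} object.
#' @export
renderTruthMaps <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  nr <- spec@imageShape[1]; nc <- spec@imageShape[2]
  gd <- mn <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  v <- spec@vials
  for (i in seq_len(nrow(v))) {
    inside <- (rr - v$cy_px[i])^2 + (cc - v$cx_px[i])^2 <= v$radius_px[i]^2
    gd[inside] <- v$gd_mM[i]
    mn[inside] <- v$mn_mM[i]
    labels[inside] <- as.integer(v$vial_id[i])
  }
  new("TruthMaps", gd = gd, mn = mn, labels = labels)
}

#' Simulate an MRF acquisition of a digital phantom
#'
#' Renders the phantom's ground-truth maps, computes each vial's
#' post-contrast (T1, T2) with \code{\link{forwardRelaxation}},
#' simulates the FISP-MRF signal evolution of every vial with
#' \code{\link{simulateFISP}}, assigns it to the vial's pixels, and adds
#' stationary complex Gaussian noise with per-channel standard deviation
#' \code{noise_sd} times the maximum noise-free signal amplitude.
#' Background pixels carry no signal; set
#' \code{include_background = TRUE} to store them too (zero + noise),
#' at a substantial memory cost for large images.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @param sched an \code{\link{MRFSchedule}}.
#' @param noise_sd noise level as a fraction of the maximum signal
#'   amplitude (default 0.01, a realistic in-vitro level).
#' @param seed integer seed; output is bit-reproducible given
#'   (spec, sched, noise_sd, seed).
#' @param include_background store background pixels as zero + noise?
#' @param kmax EPG truncation order.
#' @return an \code{\link{MRFSeries}}.
#' @export
simulateMRFSeries <- function(spec, sched, noise_sd = 0.01, seed = 1,
                              include_background = FALSE, kmax = 50L) {
  stopifnot(is(spec, "PhantomSpec"), is(sched, "MRFSchedule"))
  if (!.scalar_ok(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  truth <- renderTruthMaps(spec)
  v <- spec@vials
  tt <- forwardRelaxation(spec@baseline, spec@agentA, spec@agentB,
                          v$gd_mM, v$mn_mM)
  sigs <- tryCatch(
    epg_fisp_batch_cpp(tt$T1, tt$T2, sched@flipAngles * pi / 180,
                       sched@repetitionTimes, sched@inversionTime,
                       sched@echoTime, sched@inversionEfficiency,
                       as.integer(kmax), normalize = FALSE),
    error = function(e) stop("FISP simulation failed for a vial: ",
                             conditionMessage(e)))
  maxamp <- max(Mod(sigs))
  lab <- truth@labels
  pix <- if (include_background) seq_len(length(lab)) else which(lab != 0L)
  nt <- scheduleLength(sched)
  signals <- matrix(0 + 0i, length(pix), nt)
  for (i in seq_len(nrow(v))) {
    rows <- which(lab[pix] == as.integer(v$vial_id[i]))
    if (length(rows))
      signals[rows, ] <- matrix(sigs[i, ], length(rows), nt, byrow = TRUE)
  }
  if (noise_sd > 0) {
    sdv <- noise_sd * maxamp
    signals <- signals + with_seed(seed, {
      n <- length(signals)
      matrix(complex(real = rnorm(n, sd = sdv), imaginary = rnorm(n, sd = sdv)),
             nrow(signals), nt)
    })
  }
  new("MRFSeries", imageShape = spec@imageShape, pixelIndex = as.integer(pix),
      signals = signals, truth = truth,
      scheduleHash = scheduleFingerprint(sched),
      noiseSd = as.numeric(noise_sd), seed = as.integer(seed))
}

#' Simulate a repeated MRF study
#'
#' Simulates \code{n_repeats} independent acquisitions of the same
#' phantom with independent noise draws and, by default, a small random
#' integer translation of all vials per repeat (the repositioning
#' model).
#'
#' @inheritParams simulateMRFSeries
#' @param n_repeats number of repeats (>= 1).
#' @param reposition apply a random global translation per repeat?
#' @param max_shift_px maximum translation per axis, pixels.
#' @return list of \code{\link{MRFSeries}}, one per repeat.
#' @export
repeatStudy <- function(spec, sched, noise_sd = 0.01, n_repeats = 12,
                        seed = 1, reposition = TRUE, max_shift_px = 2,
                        kmax = 50L) {
  stopifnot(n_repeats >= 1)
  if (n_repeats == 1L && !reposition)
    return(list(simulateMRFSeries(spec, sched, noise_sd = noise_sd,
                                  seed = seed, kmax = kmax)))
  seeds <- with_seed(seed, sample.int(2^31 - 2, n_repeats + 1))
  shifts <- with_seed(seeds[n_repeats + 1], {
    if (reposition)
      matrix(sample(seq(-max_shift_px, max_shift_px),
                    2 * n_repeats, replace = TRUE), n_repeats, 2)
    else matrix(0L, n_repeats, 2)
  })
  lapply(seq_len(n_repeats), function(r) {
    sp <- spec
    if (any(shifts[r, ] != 0)) {
      v <- sp@vials
      v$cx_px <- v$cx_px + shifts[r, 1]
      v$cy_px <- v$cy_px + shifts[r, 2]
      sp <- PhantomSpec(sp@imageShape, v, sp@baseline, sp@agentA, sp@agentB)
    }
    simulateMRFSeries(sp, sched, noise_sd = noise_sd, seed = seeds[r],
                      kmax = kmax)
  })
}
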