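## FISP-MRF signal engine: acquisition schedule construction, dictionary
## grid expansion, EPG simulation, dictionary building, and
## inner-product matching.

#' Default FISP-MRF acquisition schedule
#'
#' Constructs a deterministic pseudo-random MRF schedule with the usual
#' a-priori flip-angle and TR variation: flip angles follow repeating
#' half-sinusoid lobes with alternating pseudo-random peak amplitudes
#' (max 75 degrees), and each TR is the baseline plus a smooth positive
#' perturbation of at most \code{tr_jitter} ms. The construction is a
#' documented default behind a schedule-config interface; any published
#' waveform can be loaded from JSON with \code{\link{readSchedule}}
#' instead.
#'
#' @param n number of excitations (default 3000).
#' @param baseline_tr baseline repetition time, ms (default 12).
#' @param seed integer seed; the schedule is fully determined by it.
#' @param inversion_time inversion-preparation delay, ms (default 21).
#' @param echo_time echo time, ms (default 2).
#' @param lobe_length excitations per flip-angle lobe.
#' @param fa_range peak flip-angle range, degrees (max <= 75).
#' @param tr_jitter maximum TR perturbation, ms.
#' @return an \code{\link{MRFSchedule}}.
#' @examples
#' sched <- makeDefaultSchedule(n = 100, seed = 1)
#' mean(repetitionTimes(sched))  # >= 12 ms
#' @export
makeDefaultSchedule <- function(n = 3000, baseline_tr = 12, seed = 1,
                                inversion_time = 21, echo_time = 2,
                                lobe_length = 250, fa_range = c(30, 75),
                                tr_jitter = 3) {
  stopifnot(n >= 1, baseline_tr > 0, tr_jitter >= 0)
  if (max(fa_range) > 75) stop("peak flip angles are capped at 75 degrees")
  with_seed(seed, {
    n_lobes <- ceiling(n / lobe_length)
    peaks <- runif(n_lobes, fa_range[1], fa_range[2])
    ## alternate high and low lobes for T1/T2 sensitivity variation
    if (n_lobes >= 2L) {
      even <- seq(2L, n_lobes, by = 2L)
      peaks[even] <- peaks[even] * runif(length(even), 0.4, 0.7)
    }
    k <- seq_len(n) - 1L
    lobe <- k %/% lobe_length + 1L
    pos <- k %% lobe_length + 1L
    fa <- peaks[lobe] * sin(pi * pos / (lobe_length + 1))
    ## smooth positive TR perturbation in [0, tr_jitter]
    u <- runif(n + 20L)
    sm <- stats::filter(u, rep(1 / 21, 21), sides = 2)
    sm <- sm[11:(10 + n)]
    rng <- range(sm)
    pert <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) * tr_jitter
            else rep(0, n)
    MRFSchedule(flip_angles = fa, repetition_times = baseline_tr + pert,
                inversion_time = inversion_time, echo_time = echo_time)
  })
}

#' Default dictionary grid
#'
#' The piecewise-uniform (T1, T2) dictionary grid used for matching:
#' T1 10-100 ms step 10, 100-1000 step 20, 1000-2000 step 40,
#' 2000-4500 step 100; T2 2-100 step 2, 100-150 step 5, 160-300 step
#' 10, 300-800 step 50, 800-1600 step 100, 1600-3000 step 200. This
#' expands to 105 distinct T1 and 100 distinct T2 values; pairs with
#' T2 > T1 are dropped by default.
#'
#' @param t2_le_t1 drop pairs with T2 > T1 (default TRUE).
#' @param scale integer coarsening factor for desk-scale work: every
#'   \code{scale}-th value of each axis is kept (1 = full grid).
#' @return a \code{\link{DictionaryGrid}} (for \code{scale} = 1) or the
#'   coarsened \code{\link{DictionaryGrid}} rebuilt from explicit values.
#' @export
defaultDictionaryGrid <- function(t2_le_t1 = TRUE, scale = 1L) {
  g <- DictionaryGrid(
    t1_segments = list(c(10, 100, 10), c(100, 1000, 20),
                       c(1000, 2000, 40), c(2000, 4500, 100)),
    t2_segments = list(c(2, 100, 2), c(100, 150, 5), c(160, 300, 10),
                       c(300, 800, 50), c(800, 1600, 100),
                       c(1600, 3000, 200)),
    t2_le_t1 = t2_le_t1)
  if (scale <= 1L) return(g)
  ax <- expandGridAxes(g)
  keep <- function(v) v[seq(1, length(v), by = scale)]
  DictionaryGrid(t1_segments = cbind(keep(ax$T1), keep(ax$T1), 1),
                 t2_segments = cbind(keep(ax$T2), keep(ax$T2), 1),
                 t2_le_t1 = t2_le_t1)
}

#' @rdname expandDictionaryGrid
#' @export
expandGridAxes <- function(grid) {
  stopifnot(is(grid, "DictionaryGrid"))
  vals <- function(seg) {
    v <- unlist(lapply(seq_len(nrow(seg)), function(i)
      seq(seg[i, 1], seg[i, 2], by = seg[i, 3])))
    sort(unique(round(v, 9)))
  }
  list(T1 = vals(grid@t1Segments), T2 = vals(grid@t2Segments))
}

#' Expand a dictionary grid to (T1, T2) pairs
#'
#' Expands each axis's segments (counting shared segment boundaries
#' once), forms all Cartesian pairs, and removes pairs with T2 > T1
#' when the grid's filter flag is set (such pairs are unphysical for
#' the aqueous solutions modelled here). Pairs are ordered by T1
#' ascending, then T2 ascending.
#'
#' @param grid a \code{\link{DictionaryGrid}}.
#' @return data.frame with columns \code{T1}, \code{T2} (ms).
#' @export
expandDictionaryGrid <- function(grid) {
  ax <- expandGridAxes(grid)
  pairs <- expand.grid(T2 = ax$T2, T1 = ax$T1)[, c("T1", "T2")]
  if (grid@t2LeT1) pairs <- pairs[pairs$T2 <= pairs$T1, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("grid expansion is empty")
  rownames(pairs) <- NULL
  pairs
}

#' Simulate a FISP-MRF signal evolution
#'
#' Extended-phase-graph simulation of an inversion-prepared FISP
#' acquisition: the longitudinal state is inverted (efficiency from the
#' schedule, default ideal), relaxes during the inversion time, then per
#' TR the magnetization is rotated by the flip angle about a fixed axis,
#' relaxes with E1 = exp(-dt/T1) and E2 = exp(-dt/T2) split before and
#' after the echo, and receives one unit of gradient dephasing
#' (unbalanced FISP gradient, no RF spoiling). The recorded sample is
#' the F0 configuration at the echo time after each pulse.
#'
#' @param T1,T2 relaxation times, ms (> 0).
#' @param sched an \code{\link{MRFSchedule}}.
#' @param kmax number of configuration orders retained (default 50,
#'   ample for these schedules; increase for very long T2).
#' @return complex vector of length \code{scheduleLength(sched)}.
#' @export
simulateFISP <- function(T1, T2, sched, kmax = 50L) {
  stopifnot(is(sched, "MRFSchedule"))
  if (!.scalar_ok(T1) || !.scalar_ok(T2) || T1 <= 0 || T2 <= 0)
    stop("'T1' and 'T2' must be finite and > 0")
  if (T2 > T1)
    warning("T2 > T1 is unphysical for these solutions; simulating anyway")
  epg_fisp_cpp(T1, T2, sched@flipAngles * pi / 180, sched@repetitionTimes,
               sched@inversionTime, sched@echoTime,
               sched@inversionEfficiency, as.integer(kmax))
}

#' Build an MRF dictionary
#'
#' Simulates one signal evolution per retained (T1, T2) grid pair and
#' stores them unit-normalized, ordered by T1 then T2 ascending. The
#' build is deterministic; atoms with numerically zero norm abort with
#' the offending pair reported.
#'
#' @param grid a \code{\link{DictionaryGrid}}.
#' @param sched an \code{\link{MRFSchedule}}.
#' @param kmax configuration orders retained by the EPG recursion.
#' @return an \code{\link{MRFDictionary}}.
#' @examples
#' g <- DictionaryGrid(list(c(100, 200, 100)), list(c(50, 100, 50)))
#' d <- buildDictionary(g, makeDefaultSchedule(n = 60, seed = 1))
#' dictSize(d)
#' @export
buildDictionary <- function(grid, sched, kmax = 50L) {
  stopifnot(is(grid, "DictionaryGrid"), is(sched, "MRFSchedule"))
  lookup <- expandDictionaryGrid(grid)
  raw <- epg_fisp_batch_cpp(lookup$T1, lookup$T2,
                            sched@flipAngles * pi / 180,
                            sched@repetitionTimes, sched@inversionTime,
                            sched@echoTime, sched@inversionEfficiency,
                            as.integer(kmax), normalize = FALSE)
  nrm <- sqrt(rowSums(Re(raw)^2 + Im(raw)^2))
  bad <- which(nrm < .Machine$double.eps * ncol(raw))
  if (length(bad))
    stop("zero-norm dictionary atoms at (T1, T2) = ",
         paste(sprintf("(%g, %g)", lookup$T1[bad], lookup$T2[bad]),
               collapse = ", "))
  new("MRFDictionary", atoms = raw / nrm, lookup = lookup,
      scheduleHash = scheduleFingerprint(sched), schedule = sched,
      grid = grid)
}

## Inner-product scores of raw signals (timepoints x nsig) against all
## atoms, computed blockwise: returns list(idx, score_norm, score_raw).
.match_scores <- function(signals, dict, block = 1024L) {
  atoms <- dict@atoms
  nsig <- ncol(signals)
  idx <- integer(nsig); raw <- numeric(nsig); nrm_ip <- numeric(nsig)
  snorm <- sqrt(colSums(Re(signals)^2 + Im(signals)^2))
  for (s0 in seq(1L, nsig, by = block)) {
    s1 <- min(s0 + block - 1L, nsig)
    sc <- Mod(Conj(atoms) %*% signals[, s0:s1, drop = FALSE])  # entries x blk
    b <- max.col(t(sc), ties.method = "first")
    idx[s0:s1] <- b
    raw[s0:s1] <- sc[cbind(b, seq_along(b))]
  }
  ok <- snorm > 0
  nrm_ip[ok] <- raw[ok] / snorm[ok]
  list(idx = idx, match = pmin(nrm_ip, 1), scale = raw, no_signal = !ok)
}

#' Match signals against an MRF dictionary
#'
#' Vector-based inner-product matching: each signal is assigned the
#' (T1, T2) of the atom maximizing the magnitude of the complex inner
#' product with the unit-normalized signal. Ties break deterministically
#' toward the lowest atom index (atoms are ordered by T1, then T2,
#' ascending). A zero-norm signal is flagged as no-signal (background),
#' not an error. Matching is invariant to global positive scaling and
#' global phase of the signal.
#'
#' @param signals a complex (or numeric) vector, or a matrix with one
#'   signal per row (columns = timepoints).
#' @param dict an \code{\link{MRFDictionary}} whose atoms have the same
#'   number of timepoints.
#' @return data.frame with columns \code{T1}, \code{T2},
#'   \code{match} (|normalized inner product|, in [0, 1]), \code{scale}
#'   (|<atom, raw signal>|) and \code{no_signal}.
#' @export
matchFingerprints <- function(signals, dict) {
  stopifnot(is(dict, "MRFDictionary"))
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != ncol(dict@atoms))
    stop("signal length (", ncol(signals), ") does not match the ",
         "dictionary timepoints (", ncol(dict@atoms), ")")
  sig <- t(signals)
  if (!is.complex(sig)) sig <- sig + 0i
  sc <- .match_scores(sig, dict)
  out <- data.frame(T1 = dict@lookup$T1[sc$idx],
                    T2 = dict@lookup$T2[sc$idx],
                    match = sc$match, scale = sc$scale,
                    no_signal = sc$no_signal)
  out$T1[sc$no_signal] <- 0
  out$T2[sc$no_signal] <- 0
  out$match[sc$no_signal] <- 0
  out$scale[sc$no_signal] <- 0
  out
}

#' Pixelwise dictionary matching of an image series
#'
#' Applies \code{\link{matchFingerprints}} to every stored pixel of an
#' \code{\link{MRFSeries}} (or to every pixel of a rows x cols x time
#' array) and assembles T1, T2, match-coefficient and scale maps.
#' Pixels without signal (background, or zero-norm series) are set to 0
#' and flagged in the no-signal map.
#'
#' @param series an \code{\link{MRFSeries}} or a 3-D array
#'   (rows, cols, time).
#' @param dict an \code{\link{MRFDictionary}}.
#' @param mask optional logical matrix; pixels outside it are treated
#'   as background.
#' @return an \code{\link{MRFMaps}} object.
#' @export
matchMap <- function(series, dict, mask = NULL) {
  stopifnot(is(dict, "MRFDictionary"))
  if (is(series, "MRFSeries")) {
    shape <- series@imageShape
    pix <- series@pixelIndex
    sig <- series@signals
  } else if (is.array(series) && length(dim(series)) == 3L) {
    shape <- dim(series)[1:2]
    pix <- seq_len(prod(shape))
    sig <- matrix(series, nrow = prod(shape))
    if (!is.complex(sig)) sig <- sig + 0i
  } else stop("'series' must be an MRFSeries or a 3-D array")
  if (!is.null(mask)) {
    if (!identical(dim(mask), as.integer(shape)) &&
        !identical(dim(mask), shape))
      stop("mask dimensions do not match the series")
    keep <- mask[pix]
    pix <- pix[keep]
    sig <- sig[keep, , drop = FALSE]
  }
  blank <- matrix(0, shape[1], shape[2])
  maps <- list(t1 = blank, t2 = blank, match = blank, scale = blank,
               noSignal = matrix(TRUE, shape[1], shape[2]))
  if (length(pix)) {
    m <- matchFingerprints(sig, dict)
    maps$t1[pix] <- m$T1
    maps$t2[pix] <- m$T2
    maps$match[pix] <- m$match
    maps$scale[pix] <- m$scale
    maps$noSignal[pix] <- m$no_signal
  }
  new("MRFMaps", t1 = maps$t1, t2 = maps$t2, match = maps$match,
      scale = maps$scale, noSignal = maps$noSignal)
}
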