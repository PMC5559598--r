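## S4 classes for the DC-MRF toolkit. All relaxation times are ms, rates
## ms^-1, relaxivities mM^-1 ms^-1, concentrations mM.

.scalar_ok <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

## ---------------------------------------------------------------- agents --

#' Contrast-agent relaxivity pair
#'
#' An \code{AgentRelaxivity} holds the longitudinal (\code{r1}) and
#' transverse (\code{r2}) relaxivities of one paramagnetic contrast agent,
#' i.e. the per-mM increase of R1 = 1/T1 and R2 = 1/T2 it causes.
#'
#' @slot name single character label (e.g. \code{"Gd"}).
#' @slot r1 longitudinal relaxivity, mM^-1 ms^-1; must be finite and > 0.
#' @slot r2 transverse relaxivity, mM^-1 ms^-1; must be finite and > 0.
#'
#' @examples
#' gd <- AgentRelaxivity("Gd", r1 = 0.0040, r2 = 0.0048)
#' r1(gd)
#' @export
setClass("AgentRelaxivity",
  representation(name = "character", r1 = "numeric", r2 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name))
      msg <- c(msg, "'name' must be a single non-NA string")
    if (!.scalar_ok(object@r1) || object@r1 <= 0)
      msg <- c(msg, "'r1' must be a single finite positive number")
    if (!.scalar_ok(object@r2) || object@r2 <= 0)
      msg <- c(msg, "'r2' must be a single finite positive number")
    if (length(msg)) msg else TRUE
  })

#' @param name single character label.
#' @param r1,r2 relaxivities in mM^-1 ms^-1.
#' @rdname AgentRelaxivity-class
#' @export
AgentRelaxivity <- function(name, r1, r2) {
  new("AgentRelaxivity", name = as.character(name),
      r1 = as.numeric(r1), r2 = as.numeric(r2))
}

#' @rdname AgentRelaxivity-class
#' @param x an \code{AgentRelaxivity}.
#' @export
r1 <- function(x) x@r1

#' @rdname AgentRelaxivity-class
#' @export
r2 <- function(x) x@r2

#' @rdname AgentRelaxivity-class
#' @export
agentName <- function(x) x@name

setMethod("show", "AgentRelaxivity", function(object) {
  cat(sprintf("AgentRelaxivity '%s': r1 = %.4g, r2 = %.4g mM^-1 ms^-1\n",
              object@name, object@r1, object@r2))
})

## -------------------------------------------------------------- baseline --

#' Pre-contrast relaxation times
#'
#' Baseline (pre-contrast) T1 and T2 of the solvent or tissue, in ms.
#'
#' @slot T1 pre-contrast T1, ms.
#' @slot T2 pre-contrast T2, ms.
#'
#' @examples
#' water60 <- BaselineRelaxation(4250, 2760)
#' @export
setClass("BaselineRelaxation",
  representation(T1 = "numeric", T2 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalar_ok(object@T1) || object@T1 <= 0)
      msg <- c(msg, "'T1' must be a single finite positive number (ms)")
    if (!.scalar_ok(object@T2) || object@T2 <= 0)
      msg <- c(msg, "'T2' must be a single finite positive number (ms)")
    if (length(msg)) msg else TRUE
  })

#' @param T1,T2 pre-contrast relaxation times, ms.
#' @rdname BaselineRelaxation-class
#' @export
BaselineRelaxation <- function(T1, T2) {
  new("BaselineRelaxation", T1 = as.numeric(T1), T2 = as.numeric(T2))
}

#' @rdname BaselineRelaxation-class
#' @param x a \code{BaselineRelaxation}.
#' @export
baseT1 <- function(x) x@T1

#' @rdname BaselineRelaxation-class
#' @export
baseT2 <- function(x) x@T2

setMethod("show", "BaselineRelaxation", function(object) {
  cat(sprintf("BaselineRelaxation: T1_0 = %.6g ms, T2_0 = %.6g ms\n",
              object@T1, object@T2))
})

## ---------------------------------------------------------- calibration --

#' Linear calibration fit
#'
#' Result of an ordinary least-squares fit of a relaxation rate (or an
#' estimated concentration) against known concentration.
#'
#' @slot slope fitted slope (relaxivity when fitting rates, mM^-1 ms^-1).
#' @slot intercept fitted intercept.
#' @slot rSquared squared Pearson correlation, in [0, 1] (NA for a
#'   degenerate flat response).
#' @slot pValue two-tailed p-value from the t statistic of the
#'   correlation with n - 2 degrees of freedom (NA when n < 3).
#' @slot n number of points fitted.
#' @export
setClass("CalibrationFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", pValue = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
      msg <- c(msg, "'rSquared' must lie in [0, 1]")
    if (object@n < 2L) msg <- c(msg, "'n' must be >= 2")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit (n = %d): slope = %.6g, intercept = %.6g, R^2 = %.6g, p = %.3g\n",
    object@n, object@slope, object@intercept, object@rSquared, object@pValue))
})

#' @rdname CalibrationFit-class
#' @param x a \code{CalibrationFit}.
#' @export
fitSlope <- function(x) x@slope

#' @rdname CalibrationFit-class
#' @export
fitIntercept <- function(x) x@intercept

#' @rdname CalibrationFit-class
#' @export
fitRSquared <- function(x) x@rSquared

#' @rdname CalibrationFit-class
#' @export
fitPValue <- function(x) x@pValue

## ----------------------------------------------------------- relaxometry --

#' Inversion-recovery schedule
#'
#' Inversion times for an inversion-recovery spin-echo T1 measurement.
#'
#' @slot inversionTimes strictly increasing inversion times, ms.
#' @slot inversionEfficiency fraction of ideal inversion achieved, in (0, 1].
#' @export
setClass("IRSchedule",
  representation(inversionTimes = "numeric", inversionEfficiency = "numeric"),
  validity = function(object) {
    ti <- object@inversionTimes
    msg <- character()
    if (length(ti) < 1L || any(!is.finite(ti)) || any(ti <= 0))
      msg <- c(msg, "'inversionTimes' must be finite and > 0")
    if (length(ti) > 1L && any(diff(ti) <= 0))
      msg <- c(msg, "'inversionTimes' must be strictly increasing")
    b <- object@inversionEfficiency
    if (!.scalar_ok(b) || b <= 0 || b > 1)
      msg <- c(msg, "'inversionEfficiency' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' @param inversion_times strictly increasing inversion times, ms.
#' @param inversion_efficiency inversion efficiency in (0, 1]; 1 = ideal
#'   180 degree inversion.
#' @rdname IRSchedule-class
#' @export
IRSchedule <- function(inversion_times, inversion_efficiency = 1) {
  new("IRSchedule", inversionTimes = as.numeric(inversion_times),
      inversionEfficiency = as.numeric(inversion_efficiency))
}

#' Default inversion-recovery schedule
#'
#' Log-spaced inversion times between \code{ti_min} and
#' \code{3 * t1_max}, mirroring a relaxometer protocol with a small
#' number of inversion times spanning the expected T1 range.
#'
#' @param n number of inversion times (default 7).
#' @param t1_max largest T1 expected in the samples, ms.
#' @param ti_min shortest inversion time, ms.
#' @param inversion_efficiency passed to \code{\link{IRSchedule}}.
#' @return an \code{IRSchedule}.
#' @export
defaultIRSchedule <- function(n = 7, t1_max = 4500, ti_min = 50,
                              inversion_efficiency = 1) {
  IRSchedule(exp(seq(log(ti_min), log(3 * t1_max), length.out = n)),
             inversion_efficiency)
}

#' @rdname IRSchedule-class
#' @param x an \code{IRSchedule}.
#' @export
inversionTimes <- function(x) x@inversionTimes

setMethod("show", "IRSchedule", function(object) {
  cat(sprintf("IRSchedule: %d inversion times, %.3g-%.3g ms (efficiency %.3g)\n",
              length(object@inversionTimes), min(object@inversionTimes),
              max(object@inversionTimes), object@inversionEfficiency))
})

#' CPMG echo-train schedule
#'
#' @slot echoSpacing spacing between echoes, ms.
#' @slot nEchoes number of echoes (>= 8 for a relaxometer echo train).
#' @export
setClass("CPMGSchedule",
  representation(echoSpacing = "numeric", nEchoes = "integer"),
  validity = function(object) {
    msg <- character()
    if (!.scalar_ok(object@echoSpacing) || object@echoSpacing <= 0)
      msg <- c(msg, "'echoSpacing' must be finite and > 0")
    if (object@nEchoes < 8L)
      msg <- c(msg, "'nEchoes' must be >= 8")
    if (length(msg)) msg else TRUE
  })

#' @param echo_spacing echo spacing, ms.
#' @param n_echoes number of echoes.
#' @rdname CPMGSchedule-class
#' @export
CPMGSchedule <- function(echo_spacing = 1, n_echoes = 1000) {
  new("CPMGSchedule", echoSpacing = as.numeric(echo_spacing),
      nEchoes = as.integer(n_echoes))
}

#' @rdname CPMGSchedule-class
#' @param x a \code{CPMGSchedule}.
#' @export
echoTimes <- function(x) seq_len(x@nEchoes) * x@echoSpacing

setMethod("show", "CPMGSchedule", function(object) {
  cat(sprintf("CPMGSchedule: %d echoes, spacing %.3g ms\n",
              object@nEchoes, object@echoSpacing))
})

## ------------------------------------------------------------------- MRF --

#' MRF acquisition schedule
#'
#' Per-excitation flip angles and repetition times of a FISP-MRF
#' acquisition, plus the inversion-preparation delay and echo time.
#'
#' @slot flipAngles flip angle per excitation, degrees.
#' @slot repetitionTimes repetition time per excitation, ms.
#' @slot inversionTime delay between the inversion pulse and the first
#'   excitation, ms.
#' @slot echoTime time from excitation to the sampled echo, ms; must be
#'   smaller than every TR.
#' @slot inversionEfficiency efficiency of the inversion pulse, (0, 1].
#' @export
setClass("MRFSchedule",
  representation(flipAngles = "numeric", repetitionTimes = "numeric",
                 inversionTime = "numeric", echoTime = "numeric",
                 inversionEfficiency = "numeric"),
  validity = function(object) {
    fa <- object@flipAngles; tr <- object@repetitionTimes
    msg <- character()
    if (length(fa) < 1L) msg <- c(msg, "schedule must have length >= 1")
    if (length(fa) != length(tr))
      msg <- c(msg, "'flipAngles' and 'repetitionTimes' must have equal length")
    if (any(!is.finite(fa)) || any(fa < 0) || any(fa > 180))
      msg <- c(msg, "'flipAngles' must be finite, in [0, 180] degrees")
    if (any(!is.finite(tr)) || any(tr <= 0))
      msg <- c(msg, "'repetitionTimes' must be finite and > 0")
    if (!.scalar_ok(object@inversionTime) || object@inversionTime < 0)
      msg <- c(msg, "'inversionTime' must be >= 0")
    if (!.scalar_ok(object@echoTime) || object@echoTime < 0 ||
        (length(tr) && object@echoTime >= min(tr)))
      msg <- c(msg, "'echoTime' must satisfy 0 <= echoTime < min(TR)")
    b <- object@inversionEfficiency
    if (!.scalar_ok(b) || b <= 0 || b > 1)
      msg <- c(msg, "'inversionEfficiency' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' @param flip_angles flip angles, degrees.
#' @param repetition_times repetition times, ms.
#' @param inversion_time inversion-preparation delay, ms.
#' @param echo_time echo time, ms.
#' @param inversion_efficiency inversion efficiency in (0, 1].
#' @rdname MRFSchedule-class
#' @export
MRFSchedule <- function(flip_angles, repetition_times, inversion_time = 21,
                        echo_time = 2, inversion_efficiency = 1) {
  new("MRFSchedule", flipAngles = as.numeric(flip_angles),
      repetitionTimes = as.numeric(repetition_times),
      inversionTime = as.numeric(inversion_time),
      echoTime = as.numeric(echo_time),
      inversionEfficiency = as.numeric(inversion_efficiency))
}

#' @rdname MRFSchedule-class
#' @param x an \code{MRFSchedule}.
#' @export
flipAngles <- function(x) x@flipAngles

#' @rdname MRFSchedule-class
#' @export
repetitionTimes <- function(x) x@repetitionTimes

#' @rdname MRFSchedule-class
#' @export
inversionTime <- function(x) x@inversionTime

#' @rdname MRFSchedule-class
#' @export
echoTime <- function(x) x@echoTime

#' @rdname MRFSchedule-class
#' @export
scheduleLength <- function(x) length(x@flipAngles)

#' @rdname MRFSchedule-class
#' @export
scheduleFingerprint <- function(x) {
  rlang::hash(list(x@flipAngles, x@repetitionTimes, x@inversionTime,
                   x@echoTime, x@inversionEfficiency))
}

setMethod("show", "MRFSchedule", function(object) {
  cat(sprintf(
    "MRFSchedule: %d excitations, FA %.3g-%.3g deg, TR %.4g-%.4g ms, TI %.3g ms, TE %.3g ms\n",
    length(object@flipAngles), min(object@flipAngles), max(object@flipAngles),
    min(object@repetitionTimes), max(object@repetitionTimes),
    object@inversionTime, object@echoTime))
})

#' Dictionary grid specification
#'
#' Piecewise-uniform T1 and T2 axes for the MRF dictionary. Each segment
#' is (start, stop, step) in ms; segment boundaries shared by adjacent
#' segments are counted once on expansion.
#'
#' @slot t1Segments numeric matrix, one row per segment, columns
#'   start/stop/step (ms).
#' @slot t2Segments same layout for the T2 axis.
#' @slot t2LeT1 if TRUE (default), grid pairs with T2 > T1 are dropped.
#' @export
setClass("DictionaryGrid",
  representation(t1Segments = "matrix", t2Segments = "matrix",
                 t2LeT1 = "logical"),
  validity = function(object) {
    chk <- function(m, lab) {
      if (!is.numeric(m) || ncol(m) != 3L || nrow(m) < 1L)
        return(sprintf("'%s' must be a numeric matrix with columns start, stop, step", lab))
      if (any(!is.finite(m))) return(sprintf("'%s' must be finite", lab))
      if (any(m[, 1] <= 0) || any(m[, 2] < m[, 1]) || any(m[, 3] <= 0))
        return(sprintf("'%s' segments need 0 < start <= stop and step > 0", lab))
      if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2]))
        return(sprintf("'%s' segments must be increasing and non-overlapping", lab))
      NULL
    }
    msg <- c(chk(object@t1Segments, "t1Segments"),
             chk(object@t2Segments, "t2Segments"))
    if (length(object@t2LeT1) != 1L || is.na(object@t2LeT1))
      msg <- c(msg, "'t2LeT1' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
  })

#' @param t1_segments,t2_segments matrix (or list of length-3 vectors)
#'   of (start, stop, step) segments, ms.
#' @param t2_le_t1 drop pairs with T2 > T1?
#' @rdname DictionaryGrid-class
#' @export
DictionaryGrid <- function(t1_segments, t2_segments, t2_le_t1 = TRUE) {
  as_seg <- function(s) {
    if (is.list(s)) s <- do.call(rbind, s)
    s <- matrix(as.numeric(s), ncol = 3L,
                dimnames = list(NULL, c("start", "stop", "step")))
    s
  }
  new("DictionaryGrid", t1Segments = as_seg(t1_segments),
      t2Segments = as_seg(t2_segments), t2LeT1 = isTRUE(t2_le_t1))
}

setMethod("show", "DictionaryGrid", function(object) {
  ax <- expandGridAxes(object)
  cat(sprintf("DictionaryGrid: %d T1 values (%g-%g ms), %d T2 values (%g-%g ms), T2<=T1 filter %s\n",
              length(ax$T1), min(ax$T1), max(ax$T1),
              length(ax$T2), min(ax$T2), max(ax$T2),
              if (object@t2LeT1) "on" else "off"))
})

#' MRF dictionary
#'
#' Unit-norm simulated signal evolutions indexed by (T1, T2). Atoms are
#' stored one per row, ordered by T1 ascending then T2 ascending; this
#' ordering defines the deterministic tie-break used by matching.
#'
#' @slot atoms complex matrix, entries x timepoints, each row unit
#'   Euclidean norm.
#' @slot lookup data.frame with columns \code{T1}, \code{T2} (ms), one
#'   row per atom.
#' @slot scheduleHash hash of the generating \code{MRFSchedule}.
#' @slot schedule the generating \code{MRFSchedule}.
#' @slot grid the generating \code{DictionaryGrid}.
#' @export
setClass("MRFDictionary",
  representation(atoms = "matrix", lookup = "data.frame",
                 scheduleHash = "character", schedule = "MRFSchedule",
                 grid = "DictionaryGrid"),
  validity = function(object) {
    msg <- character()
    if (!is.complex(object@atoms))
      msg <- c(msg, "'atoms' must be a complex matrix")
    if (nrow(object@atoms) != nrow(object@lookup))
      msg <- c(msg, "one lookup row per atom required")
    if (!all(c("T1", "T2") %in% names(object@lookup)))
      msg <- c(msg, "'lookup' needs columns T1 and T2")
    if (anyDuplicated(object@lookup[c("T1", "T2")]))
      msg <- c(msg, "lookup (T1, T2) pairs must be unique")
    if (length(msg)) msg else TRUE
  })

#' @rdname MRFDictionary-class
#' @param x an \code{MRFDictionary}.
#' @export
dictAtoms <- function(x) x@atoms

#' @rdname MRFDictionary-class
#' @export
dictLookup <- function(x) x@lookup

#' @rdname MRFDictionary-class
#' @export
dictSize <- function(x) nrow(x@atoms)

setMethod("show", "MRFDictionary", function(object) {
  cat(sprintf("MRFDictionary: %d atoms x %d timepoints (schedule %s)\n",
              nrow(object@atoms), ncol(object@atoms),
              substr(object@scheduleHash, 1, 8)))
})

## --------------------------------------------------------------- phantom --

#' Digital vial phantom specification
#'
#' Geometry and ground-truth agent concentrations of a digital phantom:
#' circular vials on an image grid, each carrying a (Gd-role, Mn-role)
#' concentration pair, plus the solvent baseline and the two agents'
#' relaxivities.
#'
#' @slot imageShape integer (rows, cols) in pixels.
#' @slot vials data.frame with columns \code{vial_id}, \code{gd_mM},
#'   \code{mn_mM}, \code{cx_px}, \code{cy_px}, \code{radius_px}.
#'   \code{cx_px} is the column coordinate, \code{cy_px} the row.
#' @slot baseline \code{BaselineRelaxation} of the solvent.
#' @slot agentA,agentB \code{AgentRelaxivity} of the two agents
#'   (A = Gd role, B = Mn role).
#' @export
setClass("PhantomSpec",
  representation(imageShape = "integer", vials = "data.frame",
                 baseline = "BaselineRelaxation",
                 agentA = "AgentRelaxivity", agentB = "AgentRelaxivity"),
  validity = function(object) {
    msg <- character()
    v <- object@vials
    need <- c("vial_id", "gd_mM", "mn_mM", "cx_px", "cy_px", "radius_px")
    if (!all(need %in% names(v)))
      return(paste("vials table needs columns:", paste(need, collapse = ", ")))
    if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
      msg <- c(msg, "'imageShape' must be two positive integers")
    if (nrow(v)) {
      if (any(!is.finite(v$gd_mM)) || any(!is.finite(v$mn_mM)) ||
          any(v$gd_mM < 0) || any(v$mn_mM < 0))
        msg <- c(msg, "vial concentrations must be finite and >= 0")
      if (any(v$radius_px <= 0))
        msg <- c(msg, "vial radii must be > 0")
      if (anyDuplicated(v$vial_id))
        msg <- c(msg, "vial_id values must be unique")
      if (any(v$cx_px - v$radius_px < 0.5) ||
          any(v$cx_px + v$radius_px > object@imageShape[2] + 0.5) ||
          any(v$cy_px - v$radius_px < 0.5) ||
          any(v$cy_px + v$radius_px > object@imageShape[1] + 0.5))
        msg <- c(msg, "vials must lie inside the image bounds")
      if (nrow(v) > 1L) {
        d <- as.matrix(stats::dist(v[, c("cx_px", "cy_px")]))
        rs <- outer(v$radius_px, v$radius_px, "+")
        diag(d) <- Inf
        if (any(d < rs)) msg <- c(msg, "vials must not overlap")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' @param image_shape integer (rows, cols).
#' @param vials vial table (see slot description).
#' @param baseline a \code{BaselineRelaxation}.
#' @param agentA,agentB \code{AgentRelaxivity} objects.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(image_shape, vials, baseline, agentA, agentB) {
  new("PhantomSpec", imageShape = as.integer(image_shape),
      vials = as.data.frame(vials), baseline = baseline,
      agentA = agentA, agentB = agentB)
}

#' @rdname PhantomSpec-class
#' @param x a \code{PhantomSpec}.
#' @export
vialTable <- function(x) x@vials

#' @rdname PhantomSpec-class
#' @export
imageShape <- function(x) x@imageShape

#' @rdname PhantomSpec-class
#' @export
phantomBaseline <- function(x) x@baseline

#' @rdname PhantomSpec-class
#' @export
phantomAgents <- function(x) list(A = x@agentA, B = x@agentB)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d vials on a %dx%d image (agents %s/%s)\n",
              nrow(object@vials), object@imageShape[1], object@imageShape[2],
              object@agentA@name, object@agentB@name))
})

#' Ground-truth concentration maps
#'
#' Pixelwise ground truth rendered from a \code{PhantomSpec}: per-agent
#' concentration maps and an integer ROI label map (0 = background,
#' otherwise the vial_id).
#'
#' @slot gd concentration map of agent A (Gd role), mM.
#' @slot mn concentration map of agent B (Mn role), mM.
#' @slot labels integer label matrix.
#' @export
setClass("TruthMaps",
  representation(gd = "matrix", mn = "matrix", labels = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@gd), dim(object@mn)) ||
        !identical(dim(object@gd), dim(object@labels)))
      return("all maps must share the same dimensions")
    if (any(object@gd[object@labels == 0L] != 0) ||
        any(object@mn[object@labels == 0L] != 0))
      return("maps must be zero outside labelled vials")
    TRUE
  })

#' @rdname TruthMaps-class
#' @param x a \code{TruthMaps}.
#' @export
truthGd <- function(x) x@gd

#' @rdname TruthMaps-class
#' @export
truthMn <- function(x) x@mn

#' @rdname TruthMaps-class
#' @export
truthLabels <- function(x) x@labels

setMethod("show", "TruthMaps", function(object) {
  cat(sprintf("TruthMaps: %dx%d, %d labelled vials\n",
              nrow(object@gd), ncol(object@gd),
              length(setdiff(unique(as.vector(object@labels)), 0L))))
})

#' Simulated MRF pixel series
#'
#' Per-pixel complex MRF signal evolutions for the foreground (vial)
#' pixels of a phantom. Background pixels carry no signal and are not
#' stored unless the series was simulated with
#' \code{include_background = TRUE}.
#'
#' @slot imageShape integer (rows, cols).
#' @slot pixelIndex linear (column-major) indices of the stored pixels.
#' @slot signals complex matrix, stored pixels x timepoints.
#' @slot truth the \code{TruthMaps} the series was rendered from.
#' @slot scheduleHash hash of the generating schedule.
#' @slot noiseSd complex-noise standard deviation as a fraction of the
#'   maximum noise-free signal amplitude.
#' @slot seed RNG seed used.
#' @export
setClass("MRFSeries",
  representation(imageShape = "integer", pixelIndex = "integer",
                 signals = "matrix", truth = "TruthMaps",
                 scheduleHash = "character", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.complex(object@signals))
      msg <- c(msg, "'signals' must be complex")
    if (nrow(object@signals) != length(object@pixelIndex))
      msg <- c(msg, "one signal row per stored pixel required")
    npix <- prod(object@imageShape)
    if (length(object@pixelIndex) &&
        (min(object@pixelIndex) < 1L || max(object@pixelIndex) > npix))
      msg <- c(msg, "'pixelIndex' out of image bounds")
    if (length(msg)) msg else TRUE
  })

#' @rdname MRFSeries-class
#' @param x an \code{MRFSeries}.
#' @export
seriesSignals <- function(x) x@signals

#' @rdname MRFSeries-class
#' @export
seriesTruth <- function(x) x@truth

setMethod("show", "MRFSeries", function(object) {
  cat(sprintf("MRFSeries: %dx%d image, %d stored pixels x %d timepoints (noise sd %.3g)\n",
              object@imageShape[1], object@imageShape[2],
              nrow(object@signals), ncol(object@signals), object@noiseSd))
})

## ------------------------------------------------------------------ maps --

#' Matched parameter maps
#'
#' Pixelwise T1/T2 maps produced by dictionary matching, together with
#' the match coefficient, the proton-density-like scale, and a
#' no-signal (background) flag per pixel.
#'
#' @slot t1,t2 matched relaxation-time maps, ms (0 where no signal).
#' @slot match absolute normalized inner product of the winning atom.
#' @slot scale \code{|<atom, raw signal>|}, arbitrary units.
#' @slot noSignal logical matrix, TRUE where the pixel had no signal.
#' @export
setClass("MRFMaps",
  representation(t1 = "matrix", t2 = "matrix", match = "matrix",
                 scale = "matrix", noSignal = "matrix"),
  validity = function(object) {
    dims <- lapply(list(object@t1, object@t2, object@match,
                        object@scale, object@noSignal), dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
      return("all map slots must share dimensions")
    TRUE
  })

#' @rdname MRFMaps-class
#' @param x an \code{MRFMaps}.
#' @export
t1Map <- function(x) x@t1

#' @rdname MRFMaps-class
#' @export
t2Map <- function(x) x@t2

#' @rdname MRFMaps-class
#' @export
noSignalMask <- function(x) x@noSignal

setMethod("show", "MRFMaps", function(object) {
  cat(sprintf("MRFMaps: %dx%d (%d no-signal pixels)\n",
              nrow(object@t1), ncol(object@t1), sum(object@noSignal)))
})

#' Per-agent concentration maps
#'
#' Output of the pixelwise dual-agent inversion: one concentration map
#' per agent, with provenance and an optional non-negativity clamp.
#'
#' @slot mapA concentration of agent A (Gd role), mM.
#' @slot mapB concentration of agent B (Mn role), mM.
#' @slot clamped TRUE if negative pixels were clamped to zero.
#' @slot noSignal logical matrix of background pixels (set to 0).
#' @slot agentNames character(2), names of agents A and B.
#' @slot provenance list of parameter hashes and inputs.
#' @export
setClass("ConcentrationMaps",
  representation(mapA = "matrix", mapB = "matrix", clamped = "logical",
                 noSignal = "matrix", agentNames = "character",
                 provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@mapA), dim(object@mapB)) ||
        !identical(dim(object@mapA), dim(object@noSignal)))
      msg <- c(msg, "maps must share dimensions")
    if (isTRUE(object@clamped) &&
        (min(object@mapA) < 0 || min(object@mapB) < 0))
      msg <- c(msg, "clamped maps must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @rdname ConcentrationMaps-class
#' @param x a \code{ConcentrationMaps}.
#' @param agent 1, 2, or an agent name.
#' @export
agentMap <- function(x, agent = 1L) {
  if (is.character(agent)) agent <- match(agent, x@agentNames)
  if (is.na(agent) || !agent %in% 1:2) stop("unknown agent")
  if (agent == 1L) x@mapA else x@mapB
}

setMethod("show", "ConcentrationMaps", function(object) {
  cat(sprintf("ConcentrationMaps (%s/%s): %dx%d, clamped = %s\n",
              object@agentNames[1], object@agentNames[2],
              nrow(object@mapA), ncol(object@mapA), object@clamped))
})
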