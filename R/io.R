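## Plain-text and NIfTI I/O: schedules and grids as JSON, phantom specs
## and reports as CSV (+ JSON header), maps and series as NIfTI,
## dictionaries as RDS with a JSON sidecar.

#' @rdname scheduleIO
#' @export
writeSchedule <- function(sched, path) {
  stopifnot(is(sched, "MRFSchedule"))
  jsonlite::write_json(list(
    flip_angles_deg = sched@flipAngles,
    repetition_times_ms = sched@repetitionTimes,
    inversion_time_ms = sched@inversionTime,
    echo_time_ms = sched@echoTime,
    inversion_efficiency = sched@inversionEfficiency),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read and write MRF schedules as JSON
#'
#' @param sched an \code{\link{MRFSchedule}}.
#' @param path file path.
#' @return \code{readSchedule} returns an \code{\link{MRFSchedule}}.
#' @rdname scheduleIO
#' @export
readSchedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  MRFSchedule(x$flip_angles_deg, x$repetition_times_ms,
              x$inversion_time_ms, x$echo_time_ms,
              x$inversion_efficiency)
}

#' @rdname gridIO
#' @export
writeDictionaryGrid <- function(grid, path) {
  stopifnot(is(grid, "DictionaryGrid"))
  seg <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  jsonlite::write_json(list(t1_segments = seg(grid@t1Segments),
                            t2_segments = seg(grid@t2Segments),
                            t2_le_t1 = grid@t2LeT1),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read and write dictionary grids as JSON
#'
#' @param grid a \code{\link{DictionaryGrid}}.
#' @param path file path.
#' @return \code{readDictionaryGrid} returns a
#'   \code{\link{DictionaryGrid}}.
#' @rdname gridIO
#' @export
readDictionaryGrid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  DictionaryGrid(x$t1_segments, x$t2_segments, x$t2_le_t1)
}

#' @rdname phantomIO
#' @export
writePhantomSpec <- function(spec, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(is(spec, "PhantomSpec"))
  write.csv(spec@vials[, c("vial_id", "gd_mM", "mn_mM",
                           "cx_px", "cy_px", "radius_px")],
            csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    image_shape = spec@imageShape,
    baseline = list(T1_ms = spec@baseline@T1, T2_ms = spec@baseline@T2),
    agents = list(
      A = list(name = spec@agentA@name, r1 = spec@agentA@r1,
               r2 = spec@agentA@r2),
      B = list(name = spec@agentB@name, r1 = spec@agentB@r1,
               r2 = spec@agentB@r2))),
    json_path, digits = I(17), auto_unbox = TRUE)
  invisible(csv_path)
}

#' Read and write phantom specifications
#'
#' The vial table (\code{vial_id, gd_mM, mn_mM, cx_px, cy_px,
#' radius_px}) is stored as CSV; image shape, baseline and agent
#' relaxivities go in a JSON header next to it.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @param csv_path path of the vial-table CSV.
#' @param json_path path of the JSON header (defaults to the CSV path
#'   with extension \code{.json}).
#' @return \code{readPhantomSpec} returns a \code{\link{PhantomSpec}}.
#' @rdname phantomIO
#' @export
readPhantomSpec <- function(csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  v <- read.csv(csv_path)
  h <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  PhantomSpec(h$image_shape, v,
              BaselineRelaxation(h$baseline$T1_ms, h$baseline$T2_ms),
              AgentRelaxivity(h$agents$A$name, h$agents$A$r1, h$agents$A$r2),
              AgentRelaxivity(h$agents$B$name, h$agents$B$r1, h$agents$B$r2))
}

#' Read a calibration series CSV
#'
#' Expects columns \code{concentration_mM}, \code{R1_per_ms},
#' \code{R2_per_ms}.
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @examples
#' # synthetic noise-free Gd series at the 60 MHz parameters
#' p <- system.file("extdata", "synthetic_gd_60mhz_calibration.csv",
#'                  package = "dcmrf")
#' calibrateAgent(readCalibrationSeries(p), agent = "Gd")
#' @export
readCalibrationSeries <- function(path) {
  x <- read.csv(path)
  need <- c("concentration_mM", "R1_per_ms", "R2_per_ms")
  if (!all(need %in% names(x)))
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "))
  x
}

#' Fit both relaxivities of one agent from a calibration series
#'
#' @param series data.frame as returned by
#'   \code{\link{readCalibrationSeries}}.
#' @param agent agent label for the report.
#' @return data.frame with columns \code{agent}, \code{rate},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p},
#'   \code{n} (one row for R1, one for R2).
#' @export
calibrateAgent <- function(series, agent = "agent") {
  row <- function(rate, fit)
    data.frame(agent = agent, rate = rate, slope = fit@slope,
               intercept = fit@intercept, r_squared = fit@rSquared,
               p = fit@pValue, n = fit@n)
  rbind(row("R1", fitRelaxivity(series$concentration_mM, series$R1_per_ms)),
        row("R2", fitRelaxivity(series$concentration_mM, series$R2_per_ms)))
}

## ------------------------------------------------------------------ NIfTI --

#' @rdname niftiIO
#' @export
writeMapNifti <- function(map, path, pixdim_mm = c(1, 1)) {
  if (is(map, "ConcentrationMaps"))
    stop("write each agent map separately via agentMap()")
  arr <- array(as.numeric(map), dim = c(dim(map), 1L))
  img <- RNifti::asNifti(arr, pixdim = c(pixdim_mm, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write maps and series as NIfTI
#'
#' Maps are written as single-slice 3-D volumes; an MRF pixel series is
#' written as a 4-D volume (x, y, 1, time). Complex series are exported
#' as magnitude by default, or as a real/imaginary file pair with
#' \code{magnitude_only = FALSE} (suffixes \code{_real}/\code{_imag}).
#'
#' @param map numeric matrix (or \code{\link{MRFMaps}} slot content).
#' @param series an \code{\link{MRFSeries}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param pixdim_mm pixel size, mm.
#' @param magnitude_only export \code{Mod(signal)} only?
#' @return the path(s) written, invisibly; \code{readMapNifti} returns a
#'   matrix.
#' @rdname niftiIO
#' @export
readMapNifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
  arr
}

#' @rdname niftiIO
#' @export
writeSeriesNifti <- function(series, path, magnitude_only = TRUE,
                             pixdim_mm = c(1, 1)) {
  stopifnot(is(series, "MRFSeries"))
  shape <- series@imageShape
  nt <- ncol(series@signals)
  fill <- function(values) {
    arr <- array(0, dim = c(shape[1], shape[2], 1L, nt))
    flat <- matrix(0, prod(shape), nt)
    flat[series@pixelIndex, ] <- values
    arr[, , 1L, ] <- array(flat, dim = c(shape[1], shape[2], nt))
    RNifti::asNifti(arr, pixdim = c(pixdim_mm, 1, 1))
  }
  if (magnitude_only) {
    RNifti::writeNifti(fill(Mod(series@signals)), path)
    return(invisible(path))
  }
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- substr(path, nchar(stem) + 1L, nchar(path))
  paths <- paste0(stem, c("_real", "_imag"), ext)
  RNifti::writeNifti(fill(Re(series@signals)), paths[1])
  RNifti::writeNifti(fill(Im(series@signals)), paths[2])
  invisible(paths)
}

## ------------------------------------------------------------- dictionary --

#' @rdname dictionaryIO
#' @export
saveDictionary <- function(dict, path,
                           json_path = sub("\\.rds$", ".json", path)) {
  stopifnot(is(dict, "MRFDictionary"))
  saveRDS(dict, path)
  jsonlite::write_json(list(
    n_atoms = nrow(dict@atoms), n_timepoints = ncol(dict@atoms),
    schedule_hash = dict@scheduleHash,
    t1_range_ms = range(dict@lookup$T1),
    t2_range_ms = range(dict@lookup$T2)),
    json_path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Persist and reload an MRF dictionary
#'
#' The dictionary (atoms, lookup, schedule, grid) is stored as an RDS
#' file with a small JSON sidecar describing its provenance.
#'
#' @param dict an \code{\link{MRFDictionary}}.
#' @param path RDS path.
#' @param json_path sidecar path (defaults to \code{path} with
#'   extension \code{.json}).
#' @return \code{loadDictionary} returns the \code{\link{MRFDictionary}}.
#' @rdname dictionaryIO
#' @export
loadDictionary <- function(path) {
  dict <- readRDS(path)
  if (!is(dict, "MRFDictionary")) stop("not an MRFDictionary file")
  validObject(dict)
  dict
}
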