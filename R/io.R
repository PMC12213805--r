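#' Write a flow study to NIfTI files
#'
#' Serialises a `flow_study` as four 4D NIfTI volumes (magnitude plus the
#' three velocity components, cardiac frames along the fourth axis) and a
#' JSON sidecar carrying timing, VENC and grid metadata.
#'
#' @param study a `flow_study`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory path, invisibly.
#' @export
write_study_nifti <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- c(list(mag = study$magnitude), study$velocity)
  for (nm in names(vols)) {
    img <- RNifti::asNifti(vols[[nm]],
                           pixdim = c(study$spacing, 1))
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm)))
  }
  meta <- list(frame_times = study$frame_times, period = study$period,
               venc = study$venc, spacing = study$spacing,
               origin = study$origin)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a flow study written by [write_study_nifti()]
#'
#' @param dir directory containing the NIfTI series and JSON sidecar.
#' @param prefix file-name prefix used at write time.
#' @return a `flow_study`.
#' @export
read_study_nifti <- function(dir, prefix = "study") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  grab <- function(nm) {
    arr <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm)))
    array(as.numeric(arr), dim = dim(arr))
  }
  structure(
    list(magnitude = grab("mag"),
         velocity = list(vx = grab("vx"), vy = grab("vy"), vz = grab("vz")),
         spacing = meta$spacing, origin = meta$origin,
         frame_times = meta$frame_times, period = meta$period,
         venc = meta$venc, meta = list()),
    class = "flow_study"
  )
}

#' Export a labelled geometry as legacy VTK image data
#'
#' Writes the vessel mask and region labels as an ASCII `STRUCTURED_POINTS`
#' dataset readable by ParaView and similar tools.  (Written directly: the
#' legacy VTK format is a simple text layout.)
#'
#' @param geometry a `vessel_geometry`.
#' @param path output `.vtk` file path.
#' @return the path, invisibly.
#' @export
write_geometry_vtk <- function(geometry, path) {
  d <- dim(geometry$mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "pahemo vessel geometry", "ASCII", "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %g %g %g", geometry$origin[1], geometry$origin[2],
            geometry$origin[3]),
    sprintf("SPACING %g %g %g", geometry$spacing[1], geometry$spacing[2],
            geometry$spacing[3]),
    sprintf("POINT_DATA %d", prod(d)),
    "SCALARS region int 1", "LOOKUP_TABLE default"
  ), con)
  writeLines(paste(as.integer(geometry$labels), collapse = " "), con)
  invisible(path)
}

#' Write Windkessel parameters to JSON
#'
#' Serialises a named list of per-branch [windkessel_params()] (SI units) to
#' a JSON file keyed by branch, and reads them back.
#'
#' @param params named list of [windkessel_params()].
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_windkessel_json <- function(params, path) {
  jsonlite::write_json(
    lapply(params, function(p) p[c("r1", "r2", "c", "distal_pressure")]),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_windkessel_json
#' @export
read_windkessel_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) {
    windkessel_params(p$r1, p$r2, p$c, p$distal_pressure)
  })
}

#' Write a flow waveform to CSV
#'
#' Two-column CSV (`time`, `flow`) with the period recorded in a comment
#' header line.
#'
#' @param waveform a [flow_waveform()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%.12g", wf_period(waveform)), con)
  write.csv(as.data.frame(waveform[, c("time", "flow")]), con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  first <- readLines(path, n = 1L)
  period <- as.numeric(sub("# period_s=", "", first, fixed = TRUE))
  df <- read.csv(path, comment.char = "#")
  flow_waveform(df$time, df$flow, period)
}
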