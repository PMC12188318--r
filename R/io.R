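# Plain-text interchange: ASCII PLY point clouds and JSON geometry sidecars.

#' Write a point cloud as ASCII PLY
#'
#' @param cloud N x 3 matrix (mm).
#' @param path output file.
#' @export
write_ply <- function(cloud, path) {
  stop_if_not_matrix3(cloud, "cloud")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(cloud)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(cloud, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' Read an ASCII PLY point cloud
#'
#' Supports the vertex x/y/z layout written by [write_ply()].
#'
#' @param path PLY file.
#' @return N x 3 matrix.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("not an ASCII PLY file")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  start <- which(lines == "end_header")[1]
  dat <- utils::read.table(text = lines[start + seq_len(nv)])
  as.matrix(dat[, 1:3])
}

#' Save / load a cone-beam geometry as JSON
#' @param geom a [cone_beam_geometry()].
#' @param path JSON file.
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  cone_beam_geometry(g$gantry_angle_deg, g$sad, g$sdd, g$detector_cols,
                     g$detector_rows, g$pixel_pitch_mm)
}

#' Write a projection as a plain-text matrix (TSV)
#' @param proj rows x cols matrix.
#' @param path output file.
#' @export
write_projection <- function(proj, path) {
  utils::write.table(proj, path, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t"))
}
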