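# Volume and dataset I/O. Velocity volumes travel as NIfTI (the standard
# medical-imaging container; x, y, z, [time,] component) with a JSON
# sidecar for acquisition metadata; single frames can be exported as ASCII
# VTI for inspection in ParaView-style viewers.

#' Write a velocity volume as NIfTI plus JSON sidecar
#'
#' @param velocity Array `[x, y, z, 3]` (one frame) or `[x, y, z, t, 3]`.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param spacing Voxel size in mm.
#' @param meta Named list of extra metadata stored in the sidecar (e.g.
#'   `venc`, `snr_db`, `times`).
#' @return `path`, invisibly.
#' @export
write_velocity_nifti <- function(velocity, path, spacing = 1, meta = list()) {
  img <- RNifti::asNifti(velocity)
  RNifti::writeNifti(img, path)
  meta$spacing_mm <- spacing
  meta$dim <- dim(velocity)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a velocity volume written by [write_velocity_nifti()]
#'
#' @param path NIfTI path.
#' @return List with `velocity` (array) and `meta` (sidecar list, or empty
#'   when no sidecar exists).
#' @export
read_velocity_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr)[setdiff(names(attributes(arr)), "dim")] <- NULL
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list()
  list(velocity = arr, meta = meta)
}

#' Export one frame as an ASCII VTK ImageData (.vti) file
#'
#' Writes velocity (3-component), speed and optionally the fluid mask as
#' point data on the uniform grid, for rendering jets and stitched
#' predictions in ParaView-style viewers.
#'
#' @param velocity Array `[x, y, z, 3]` in m/s.
#' @param path Output `.vti` path.
#' @param spacing Voxel size in mm.
#' @param mask Optional logical fluid mask.
#' @return `path`, invisibly.
#' @export
write_vti <- function(velocity, path, spacing = 1, mask = NULL) {
  d <- dim(velocity)[1:3]
  con <- file(path, "w")
  on.exit(close(con))
  ext <- sprintf("0 %d 0 %d 0 %d", d[1] - 1, d[2] - 1, d[3] - 1)
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<VTKFile type=\"ImageData\" version=\"0.1\" byte_order=\"LittleEndian\">",
    sprintf("  <ImageData WholeExtent=\"%s\" Origin=\"0 0 0\" Spacing=\"%g %g %g\">",
            ext, spacing, spacing, spacing),
    sprintf("    <Piece Extent=\"%s\">", ext),
    "      <PointData Vectors=\"velocity\">"), con)
  vec <- cbind(as.vector(velocity[, , , 1]), as.vector(velocity[, , , 2]),
               as.vector(velocity[, , , 3]))
  writeLines(sprintf(
    "        <DataArray type=\"Float32\" Name=\"velocity\" NumberOfComponents=\"3\" format=\"ascii\">"),
    con)
  writeLines(paste(apply(vec, 1, paste, collapse = " "), collapse = " "), con)
  writeLines("        </DataArray>", con)
  writeLines(
    "        <DataArray type=\"Float32\" Name=\"speed\" format=\"ascii\">",
    con)
  writeLines(paste(sqrt(rowSums(vec^2)), collapse = " "), con)
  writeLines("        </DataArray>", con)
  if (!is.null(mask)) {
    writeLines(
      "        <DataArray type=\"UInt8\" Name=\"mask\" format=\"ascii\">",
      con)
    writeLines(paste(as.integer(as.vector(mask)), collapse = " "), con)
    writeLines("        </DataArray>", con)
  }
  writeLines(c("      </PointData>", "      <CellData/>", "    </Piece>",
               "  </ImageData>", "</VTKFile>"), con)
  invisible(path)
}

#' Write / read the geometry catalogue as plain-text CSV
#'
#' @param cat20 A data frame as returned by [geometry_catalogue()].
#' @param path CSV path.
#' @return `path` / the catalogue data frame.
#' @export
write_geometry_csv <- function(cat20, path) {
  write.csv(cat20, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Save / load a network checkpoint
#'
#' Checkpoints carry the architecture spec, all parameters and the
#' initialisation seed.
#'
#' @param model An `sr_network`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` / the restored `sr_network`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sr_network"))
  saveRDS(list(spec = model$spec, params = model$params, seed = model$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  model <- build_network(x$spec, seed = x$seed)
  model$params <- x$params
  model
}
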