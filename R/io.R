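# NIfTI input/output (RNifti) for quantitative maps and intermediates.

#' Write a volume to NIfTI
#'
#' @param volume Numeric array \code{[nx, ny, nz]}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param voxel_mm Isotropic voxel size stored in the header.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_mm = 1) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_mm, length(dim(volume)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path File path.
#' @return Numeric array with attribute \code{"voxel_mm"}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Round-trip a volume through NIfTI
#'
#' Writes and re-reads a volume, checking that the data array is preserved
#' bit-exactly and the voxel size within 1e-6. Malformed files raise a parse
#' error naming the file.
#'
#' @param volume Numeric array.
#' @param path File path (defaults to a tempfile).
#' @param voxel_mm Voxel size to store.
#' @return The re-read volume.
#' @export
io_roundtrip <- function(volume, path = tempfile(fileext = ".nii.gz"), voxel_mm = 1) {
  write_volume(volume, path, voxel_mm)
  back <- tryCatch(read_volume(path),
                   error = function(e) stop(sprintf("failed to parse '%s': %s",
                                                    path, conditionMessage(e)),
                                            call. = FALSE))
  stop_if(!identical(dim(back), dim(volume)), "round-trip changed the volume shape")
  stop_if(!isTRUE(all.equal(as.vector(back), as.vector(volume), tolerance = 0)),
          "round-trip changed the data array")
  back
}

#' Write the quantitative maps of a matched set
#'
#' Emits \code{t1.nii.gz}, \code{r1.nii.gz}, \code{pd.nii.gz},
#' \code{corr.nii.gz} (and \code{t2.nii.gz}) under a prefix.
#'
#' @param mapset An \code{mrf_mapset}.
#' @param out_prefix Directory/prefix for the outputs.
#' @param voxel_mm Voxel size.
#' @return Named vector of paths, invisibly.
#' @export
write_mapset <- function(mapset, out_prefix, voxel_mm = 1) {
  dir.create(dirname(file.path(out_prefix, "x")), recursive = TRUE, showWarnings = FALSE)
  r1 <- r1_map(mapset$t1_map)
  r1[!is.finite(r1)] <- 0
  paths <- c(t1 = file.path(out_prefix, "t1.nii.gz"),
             t2 = file.path(out_prefix, "t2.nii.gz"),
             pd = file.path(out_prefix, "pd.nii.gz"),
             r1 = file.path(out_prefix, "r1.nii.gz"),
             corr = file.path(out_prefix, "corr.nii.gz"))
  write_volume(mapset$t1_map, paths["t1"], voxel_mm)
  write_volume(mapset$t2_map, paths["t2"], voxel_mm)
  write_volume(mapset$pd_map, paths["pd"], voxel_mm)
  write_volume(unclass(r1), paths["r1"], voxel_mm)
  write_volume(mapset$match_corr_map, paths["corr"], voxel_mm)
  invisible(paths)
}
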