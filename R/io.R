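## Volume and table I/O. Volumes are NIfTI-1 via RNifti with a shared
## diagonal affine from the voxel size; tables are TSV at full precision.

#' Write a 3-D/4-D array as NIfTI-1
#'
#' @param vol Numeric/integer/logical array.
#' @param path Output path (".nii" or ".nii.gz").
#' @param voxdim_mm Voxel size per spatial axis in mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, voxdim_mm = 0.8) {
  voxdim_mm <- rep(voxdim_mm, length.out = 3)
  v <- vol
  if (is.logical(v)) v <- array(as.integer(v), dim(vol))
  img <- RNifti::asNifti(v, reference = NULL)
  RNifti::pixdim(img) <- voxdim_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return Array with a `voxdim` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxdim") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write a data frame as TSV (full precision)
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#' @param path TSV file.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE)
}

#' Check that two volumes share a grid
#' @param a,b Arrays (with optional `voxdim` attributes).
#' @param names_ab Labels used in the error message.
#' @export
check_same_grid <- function(a, b, names_ab = c("a", "b")) {
  if (!identical(dim(a)[1:3], dim(b)[1:3]))
    stop("grid mismatch between ", names_ab[1], " ",
         paste(dim(a)[1:3], collapse = "x"), " and ", names_ab[2], " ",
         paste(dim(b)[1:3], collapse = "x"))
  va <- attr(a, "voxdim"); vb <- attr(b, "voxdim")
  if (!is.null(va) && !is.null(vb) && any(abs(va - vb) > 1e-6))
    stop("voxel-size mismatch between ", names_ab[1], " and ", names_ab[2])
  invisible(TRUE)
}
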