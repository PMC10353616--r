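#' Read a NIfTI-1 volume
#'
#' 4D files become a [bold_run()] (TR taken from the header's fourth
#' pixdim, or from `tr_s` with a warning when the header carries none);
#' 3D files become a [scalar_map()]. Plain and gzipped files are both
#' accepted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param expect `"run"` (4D required), `"map"` (3D required) or
#'   `"any"`.
#' @param tr_s Fallback repetition time (s) when the header has none.
#' @param mask Optional binary 3D array attached to a returned run/map.
#' @return A [bold_run()] or [scalar_map()].
#' @export
read_volume <- function(path, expect = c("any", "run", "map"), tr_s = NULL,
                        mask = NULL) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  if (nd == 4L) {
    if (expect == "map")
      stop("expected a 3D map but ", path, " is 4D")
    tr <- RNifti::niftiHeader(path)$pixdim[5]  # raw header value
    if (!is.finite(tr) || tr <= 0) {
      if (is.null(tr_s))
        stop("no TR in header of ", path, " and no `tr_s` fallback given")
      warning("TR missing from header of ", path, "; using tr_s = ", tr_s)
      tr <- tr_s
    }
    bold_run(array(as.numeric(img), dim = dim(img)), tr_s = tr,
             affine = affine, mask = mask)
  } else if (nd == 3L) {
    if (expect == "run")
      stop("expected a 4D run but ", path, " is 3D")
    v <- array(as.numeric(img), dim = dim(img))
    if (is.null(mask)) mask <- array(1, dim = dim(v))
    scalar_map(v, mask, affine)
  } else stop(path, " has unsupported dimensionality ", nd)
}

#' Write a run or map as NIfTI-1
#'
#' Writes the data with the object's affine as both sform and qform
#' (RAS+), and (for runs) the TR in the fourth pixdim.
#'
#' @param x A [bold_run()] or [scalar_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "bold_run")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(affine_voxel_sizes(x$affine), x$tr_s)
  } else if (inherits(x, "scalar_map")) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- affine_voxel_sizes(x$affine)
  } else stop("`x` must be a bold_run or scalar_map")
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::qform(img) <- structure(x$affine, code = 2L)
  ok <- try(RNifti::writeNifti(img, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path TSV file with a header row; lines starting `#` are
#'   comments.
#' @return Data frame.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a tab-separated table with a comment header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param comments Character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
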