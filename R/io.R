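#' Export image maps as NIfTI
#'
#' Thin wrapper over the RNifti package (suggested dependency) for writing
#' magnitude maps; complex images are written as magnitude/phase pairs.
#'
#' @param img Numeric or complex matrix (or 3D array).
#' @param path Output path (`.nii` / `.nii.gz`); complex input writes
#'   `<path>_mag` and `<path>_phase`.
#' @param pixdim Voxel size(s) in mm (default 1).
#' @return The path(s) written, invisibly.
#' @export
export_nifti <- function(img, path, pixdim = 1) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("export_nifti requires the RNifti package")
  wr <- function(x, p) {
    im <- RNifti::asNifti(x)
    RNifti::pixdim(im) <- rep(pixdim, length.out = length(dim(x)))
    RNifti::writeNifti(im, p)
    p
  }
  if (is.complex(img)) {
    root <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- substr(path, nchar(root) + 1, nchar(path))
    invisible(c(wr(abs(img), paste0(root, "_mag", ext)),
                wr(Arg(img), paste0(root, "_phase", ext))))
  } else invisible(wr(img, path))
}
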