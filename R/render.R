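#' Render an RGB brightfield field from stain concentration maps
#'
#' Beer-Lambert forward model: per pixel and channel,
#' `I_c = (I0_c + 1) * 10^(-sum_s conc_s * M[s, c]) - 1`, plus optional
#' additive Gaussian noise, clipped to `[0, 255]`. This is the exact inverse
#' of [rgb_to_od()] followed by [deconvolve()], so noiseless rendered fields
#' round-trip through deconvolution to machine precision.
#'
#' @param conc named list of H x W concentration matrices (names must be
#'   stains of `basis`; missing stains are treated as zero) or an
#'   H x W x 3 array in basis stain order.
#' @param basis a [stain_basis()].
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (8-bit scale).
#' @param seed optional integer seed making the noise reproducible.
#' @return H x W x 3 numeric intensity array in `[0, 255]` (continuous;
#'   quantisation to 8 bits happens when the field is written to disk).
#' @examples
#' b <- he_basis()
#' img <- render_field(list(hematoxylin = matrix(0.3, 8, 8)), b)
#' @export
render_field <- function(conc, basis, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(basis, "stain_basis"))
  if (is.list(conc) && !is.array(conc)) {
    nm <- names(conc)
    if (is.null(nm) || !all(nm %in% basis$stains))
      stop("concentration maps must be named after basis stains: ",
           paste(basis$stains, collapse = ", "))
    dims <- lapply(conc, dim)
    ref <- dims[[1]]
    for (i in seq_along(conc)) {
      if (!identical(dims[[i]], ref))
        stop(sprintf("concentration map '%s' has shape %s, expected %s",
                     nm[i], paste(dims[[i]], collapse = "x"),
                     paste(ref, collapse = "x")))
      if (any(conc[[i]] < 0))
        stop(sprintf("concentration map '%s' contains negative values", nm[i]))
    }
    a <- array(0, dim = c(ref, 3))
    for (i in seq_along(conc)) a[, , match(nm[i], basis$stains)] <- conc[[i]]
    conc <- a
  }
  if (length(dim(conc)) != 3 || dim(conc)[3] != 3)
    stop("conc must be a named list of matrices or an H x W x 3 array")
  d <- dim(conc)
  od <- matrix(conc, ncol = 3) %*% basis$M     # N x 3 channel OD
  img <- array(0, dim = d)
  for (c in 1:3) {
    img[, , c] <- (basis$I0[c] + 1) * 10^(-matrix(od[, c], d[1], d[2])) - 1
  }
  if (noise_sd > 0) {
    addnoise <- function() img + array(rnorm(prod(d), sd = noise_sd), dim = d)
    img <- if (is.null(seed)) addnoise() else withr::with_seed(seed, addnoise())
  }
  clip(img, 0, 255)
}

#' Write a field to disk as 8-bit TIFF or PNG
#'
#' Intensities are rounded to integers (8-bit quantisation) at write time.
#'
#' @param img H x W x 3 intensity array in `[0, 255]`.
#' @param path output path; format from extension unless given.
#' @param format `"tiff"` or `"png"` (default: from file extension).
#' @return `path`, invisibly.
#' @export
write_field <- function(img, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff" else if (ext == "png") "png"
              else stop("cannot infer image format from extension: ", ext)
  }
  q <- clip(round(img), 0, 255) / 255
  if (format == "tiff") tiff::writeTIFF(q, path, bits.per.sample = 8L)
  else png::writePNG(q, path)
  invisible(path)
}

#' Read an 8-bit RGB field from TIFF or PNG
#'
#' @param path image path.
#' @return H x W x 3 numeric array on the 0..255 intensity scale.
#' @export
read_field <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  a * 255
}
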