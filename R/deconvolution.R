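#' Convert an RGB micrograph to optical density
#'
#' Per channel, `OD_c = -log10((I_c + 1) / (I0_c + 1))`, clipped to
#' `[0, od_cap]`. The +1 offset inside the logarithm avoids `log(0)` for
#' fully absorbing 8-bit pixels without a special case; background pixels
#' (`I = I0`) map exactly to OD 0 and the transform is monotone decreasing
#' in intensity.
#'
#' @param img H x W x 3 numeric array, 8-bit intensity scale (0..255).
#' @param I0 background intensity per channel (length 1 or 3).
#' @param od_cap maximum OD retained.
#' @return H x W x 3 array of optical densities in `[0, od_cap]`.
#' @export
rgb_to_od <- function(img, I0 = c(255, 255, 255), od_cap = 3) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("input must be a 3-channel (H x W x 3) image array")
  if (any(I0 <= 0)) stop("background intensity I0 must be positive")
  I0 <- rep_len(I0, 3)
  od <- img
  for (c in 1:3) od[, , c] <- -log10((img[, , c] + 1) / (I0[c] + 1))
  clip(od, 0, od_cap)
}

#' Unmix an optical-density field into per-stain concentrations
#'
#' Solves, per pixel, the 3x3 linear system `OD = t(M) %*% conc` for the
#' stain concentrations, where the rows of `M` are the basis stain vectors.
#' Negative concentrations (pixels outside the stain simplex, e.g. noise)
#' are clamped to zero only when `clamp_negatives = TRUE`; whether clamping
#' was applied is recorded in the `"clamped"` attribute.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param basis a [stain_basis()].
#' @param clamp_negatives clamp negative concentrations to 0.
#' @return H x W x 3 array of concentrations, third dimension named by stain.
#' @export
deconvolve <- function(od, basis, clamp_negatives = FALSE) {
  stopifnot(inherits(basis, "stain_basis"))
  if (length(dim(od)) != 3 || dim(od)[3] != 3)
    stop("OD field must be an H x W x 3 array")
  Minv <- solve(basis$M)
  d <- dim(od)
  odm <- matrix(od, ncol = 3)          # N x 3, columns = channels
  conc <- odm %*% Minv                  # OD = C %*% M  =>  C = OD %*% M^-1
  clamped <- FALSE
  if (clamp_negatives && any(conc < 0)) {
    conc[conc < 0] <- 0
    clamped <- TRUE
  }
  out <- array(conc, dim = d, dimnames = list(NULL, NULL, basis$stains))
  attr(out, "clamped") <- clamped
  out
}

## Otsu's threshold from a histogram: maximise between-class variance over
## all bin cut points; returns the boundary between the arg-max bin and the
## next one.
otsu_from_counts <- function(counts, mids) {
  stopifnot(length(counts) == length(mids), length(counts) >= 2)
  tot <- sum(counts)
  if (tot == 0) stop("empty histogram")
  p <- counts / tot
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  sb <- sb[-length(sb)]
  ## ties (flat plateau between well-separated modes): take the middle cut
  ks <- which(sb >= max(sb) - 1e-12 * max(max(sb), 1))
  k <- ks[ceiling(length(ks) / 2)]
  (mids[k] + mids[k + 1]) / 2
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based Otsu threshold (maximal between-class variance) on
#' `n_bins` equal-width bins spanning `range` (defaults to the data range).
#'
#' @param values numeric vector.
#' @param n_bins number of histogram bins.
#' @param range length-2 numeric; values outside are clipped into it.
#' @return The threshold value.
#' @export
otsu_threshold <- function(values, n_bins = 256, range = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to threshold")
  if (is.null(range)) range <- base::range(values)
  if (diff(range) == 0) return(range[1])
  v <- clip(values, range[1], range[2])
  br <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  otsu_from_counts(counts, mids)
}

#' Threshold one stain channel of a concentration field
#'
#' Produces a binary mask of pixels whose concentration in the selected
#' stain channel is at or above the threshold. With `method = "otsu"` the
#' threshold is computed from the channel's histogram, restricted to
#' `tissue` when a tissue mask is supplied; with `method = "fixed"` the
#' supplied `fixed_value` is used.
#'
#' @param conc concentration array from [deconvolve()].
#' @param stain stain name or index of the channel to threshold.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold for `method = "fixed"`.
#' @param tissue optional logical matrix restricting the Otsu histogram.
#' @param n_bins histogram bins for Otsu.
#' @return Logical H x W mask with the threshold in attribute `"threshold"`.
#' @export
threshold_channel <- function(conc, stain, method = c("otsu", "fixed"),
                              fixed_value = NULL, tissue = NULL, n_bins = 256) {
  method <- match.arg(method)
  ch <- if (is.character(stain)) {
    if (!stain %in% dimnames(conc)[[3]]) stop("unknown stain: ", stain)
    conc[, , stain]
  } else conc[, , stain]
  thr <- if (method == "fixed") {
    if (is.null(fixed_value)) stop("method = 'fixed' requires fixed_value")
    fixed_value
  } else {
    vals <- if (!is.null(tissue)) ch[tissue] else as.vector(ch)
    otsu_threshold(pmax(vals, 0), n_bins = n_bins)
  }
  mask <- ch >= thr
  attr(mask, "threshold") <- thr
  mask
}

## Class means either side of a threshold, from a histogram.
class_contrast <- function(counts, mids, thr) {
  lo <- mids < thr
  n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
  if (n0 == 0 || n1 == 0) return(0)
  m0 <- sum(counts[lo] * mids[lo]) / n0
  m1 <- sum(counts[!lo] * mids[!lo]) / n1
  m1 - m0
}

## Otsu with a unimodality guard for chromogen channels. Otsu always splits
## a histogram, even a unimodal one (e.g. a field with no positive staining,
## or one that is entirely positive), so the split is only trusted when the
## two classes differ by at least `min_contrast` OD-equivalents; otherwise
## the fixed `floor` decides whether the single mode is positive.
guarded_otsu <- function(counts, mids, min_contrast = 0.2, floor = 0.15) {
  thr <- otsu_from_counts(counts, mids)
  if (class_contrast(counts, mids, thr) < min_contrast) floor else thr
}

## Pooled histogram counts of one stain channel across a batch of fields,
## used for the shared-Otsu threshold ("uniformly applied" thresholds).
pooled_otsu <- function(channels, tissues = NULL, n_bins = 512, range = c(0, 3)) {
  counts <- integer(n_bins)
  br <- seq(range[1], range[2], length.out = n_bins + 1)
  for (i in seq_along(channels)) {
    v <- channels[[i]]
    if (!is.null(tissues)) v <- v[tissues[[i]]]
    v <- clip(pmax(as.vector(v), 0), range[1], range[2])
    bin <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), n_bins)
    counts <- counts + tabulate(bin, nbins = n_bins)
  }
  mids <- (br[-1] + br[-length(br)]) / 2
  guarded_otsu(counts, mids)
}
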