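#' Construct a stain basis for color deconvolution
#'
#' A stain basis holds three unit-norm optical-density (OD) stain vectors
#' (rows of a 3x3 matrix, channel order R, G, B), the background intensity
#' `I0` per channel, and the OD cap applied when converting images to OD.
#' Brightfield stains mix additively in OD space (Beer-Lambert law), so a
#' pixel's OD vector is the concentration-weighted sum of the stain vectors
#' and deconvolution is the inverse of that 3x3 linear system.
#'
#' @param vectors 3x3 numeric matrix, one stain per row (R, G, B components).
#'   Rows are normalised to unit Euclidean norm.
#' @param stains character vector of three stain names (row names).
#' @param I0 background (unstained) intensity per channel, 8-bit scale.
#' @param od_cap maximum optical density retained; transmission below
#'   `10^-od_cap` is treated as saturated.
#' @return An object of class `stain_basis`.
#' @examples
#' b <- he_basis()
#' b$M
#' @export
stain_basis <- function(vectors, stains = rownames(vectors),
                        I0 = c(255, 255, 255), od_cap = 3) {
  M <- as.matrix(vectors)
  if (!all(dim(M) == c(3, 3))) stop("stain basis must be a 3x3 matrix (stains x RGB)")
  if (any(M < 0)) stop("stain vectors must be non-negative in OD space")
  if (any(I0 <= 0)) stop("background intensity I0 must be positive")
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) stop("stain vectors must be non-zero")
  M <- M / nrm
  if (is.null(stains)) stains <- paste0("stain", 1:3)
  rownames(M) <- stains
  colnames(M) <- c("R", "G", "B")
  sv <- svd(M)$d
  cn <- if (sv[3] <= sv[1] * .Machine$double.eps) Inf else sv[1] / sv[3]
  if (!is.finite(cn) || cn > 1e6) {
    stop(sprintf("stain basis is singular or ill-conditioned (condition number %.3g)", cn))
  }
  structure(list(M = M, stains = stains, I0 = rep_len(I0, 3), od_cap = od_cap,
                 condition_number = cn),
            class = "stain_basis")
}

#' @export
print.stain_basis <- function(x, ...) {
  cat("Stain basis (", paste(x$stains, collapse = ", "), ")\n", sep = "")
  print(round(x$M, 4))
  cat("I0 =", paste(x$I0, collapse = ", "),
      " od_cap =", x$od_cap,
      " condition number =", signif(x$condition_number, 4), "\n")
  invisible(x)
}

## Residual third stain vector: cross product of the two named vectors,
## negatives clamped to zero, renormalised (Ruifrok & Johnston's convention
## for two-stain slides).
residual_vector <- function(v1, v2) {
  v <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  v <- pmax(v, 0)
  if (all(v == 0)) stop("named stain vectors are collinear; no residual direction")
  v / sqrt(sum(v^2))
}

RUIFROK <- list(
  hematoxylin = c(0.650, 0.704, 0.286),
  eosin       = c(0.072, 0.990, 0.105),
  dab         = c(0.268, 0.570, 0.776)
)

#' Standard hematoxylin / eosin stain basis
#'
#' Ruifrok-Johnston published OD vectors for hematoxylin and eosin, with the
#' third vector the (clamped) orthogonal residual used for two-stain slides.
#'
#' @inheritParams stain_basis
#' @return A `stain_basis` with stains `hematoxylin`, `eosin`, `residual`.
#' @export
he_basis <- function(I0 = c(255, 255, 255), od_cap = 3) {
  h <- RUIFROK$hematoxylin / sqrt(sum(RUIFROK$hematoxylin^2))
  e <- RUIFROK$eosin / sqrt(sum(RUIFROK$eosin^2))
  stain_basis(rbind(h, e, residual_vector(h, e)),
              stains = c("hematoxylin", "eosin", "residual"),
              I0 = I0, od_cap = od_cap)
}

#' Standard hematoxylin / DAB stain basis
#'
#' Ruifrok-Johnston OD vectors for hematoxylin and the DAB chromogen, third
#' vector the clamped orthogonal residual.
#'
#' @inheritParams stain_basis
#' @return A `stain_basis` with stains `hematoxylin`, `dab`, `residual`.
#' @export
hdab_basis <- function(I0 = c(255, 255, 255), od_cap = 3) {
  h <- RUIFROK$hematoxylin / sqrt(sum(RUIFROK$hematoxylin^2))
  d <- RUIFROK$dab / sqrt(sum(RUIFROK$dab^2))
  stain_basis(rbind(h, d, residual_vector(h, d)),
              stains = c("hematoxylin", "dab", "residual"),
              I0 = I0, od_cap = od_cap)
}
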