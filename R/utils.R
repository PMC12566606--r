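#' @importFrom stats rnorm sd
NULL

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-field random seed from a base seed
#'
#' Mixes a base seed with group and field indices so that a whole group set is
#' reproducible from a single integer without storing one seed per field.
#' The result is kept inside the 32-bit signed integer range.
#'
#' @param base_seed integer base seed.
#' @param group_index 1-based group index.
#' @param field_index 1-based field index within the group.
#' @return A single integer seed.
#' @export
field_seed <- function(base_seed, group_index = 1L, field_index = 1L) {
  s <- (as.numeric(base_seed) + 7919 * as.numeric(group_index) +
          104729 * as.numeric(field_index)) %% 2147483647
  as.integer(s)
}

## Pixels of a rasterized disk, restricted to the image frame.
## Returns linear indices into an H x W matrix plus the distance of each
## pixel centre to the disk centre (used for anti-aliased rims).
disk_pixels <- function(cy, cx, r, H, W, extra = 0) {
  rr <- r + extra
  y0 <- max(1L, floor(cy - rr)); y1 <- min(H, ceiling(cy + rr))
  x0 <- max(1L, floor(cx - rr)); x1 <- min(W, ceiling(cx + rr))
  if (y0 > y1 || x0 > x1) return(list(idx = integer(0), d = numeric(0)))
  ys <- y0:y1; xs <- x0:x1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  keep <- d2 <= rr^2
  idx <- as.integer(outer(ys, (xs - 1L) * H, "+"))[keep]
  list(idx = idx, d = sqrt(d2[keep]))
}

## Smooth Gaussian random field, rescaled to unit standard deviation.
smooth_noise <- function(H, W, sigma = 8) {
  m <- EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = sigma)
  s <- sd(m)
  if (s == 0) return(m)
  (m - mean(m)) / s
}

#' Label connected components of a binary mask
#'
#' 8-connected labelling built on EBImage's 4-connected \code{bwlabel}:
#' diagonally adjacent 4-connected labels are merged by union-find.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4 || n <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # down-left diagonal
  p <- rbind(cbind(as.vector(a1), as.vector(b1)),
             cbind(as.vector(a2), as.vector(b2)))
  p <- p[p[, 1] > 0 & p[, 2] > 0 & p[, 1] != p[, 2], , drop = FALSE]
  if (nrow(p) == 0) return(lab)
  p <- unique(p)
  parent <- seq_len(n)
  findroot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(p))) {
    ra <- findroot(p[k, 1]); rb <- findroot(p[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), findroot, integer(1))
  newid <- match(root, sort(unique(root)))
  pos <- lab > 0
  lab[pos] <- newid[lab[pos]]
  lab
}

gcd2 <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

## Chain-code perimeter with the Proffitt-Rosen corrected step weights
## (0.948 for axial steps, 1.340 for diagonal steps), which debias the
## systematic over-estimation of naive 8-connected chain length.
chain_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(4 * 0.948 * sqrt(max(n, 1)))
  d <- pts - pts[c(2:n, 1), , drop = FALSE]
  diagonal <- abs(d[, 1]) == 1 & abs(d[, 2]) == 1
  sum(ifelse(diagonal, 1.340, 0.948))
}

## Solidity = pixel area / convex-hull area. The hull area in pixel units is
## obtained from the shoelace area of the hull polygon of boundary pixel
## centres plus the Pick's-theorem correction A + B/2 + 1, i.e. the number of
## lattice points covered by the hull.
component_solidity <- function(pts, area_px) {
  if (nrow(pts) < 3) return(1)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  A <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  dx <- abs(diff(c(x, x[1]))); dy <- abs(diff(c(y, y[1])))
  B <- sum(mapply(function(a, b) if (a == 0 && b == 0) 0 else gcd2(max(a, b), min(a, b)),
                  dx, dy))
  hull_px <- A + B / 2 + 1
  min(1, area_px / max(hull_px, 1))
}

## Gradient magnitude of a matrix by central differences (replicated borders).
gradient_magnitude <- function(g) {
  H <- nrow(g); W <- ncol(g)
  gx <- (g[, c(2:W, W), drop = FALSE] - g[, c(1, 1:(W - 1)), drop = FALSE]) / 2
  gy <- (g[c(2:H, H), , drop = FALSE] - g[c(1, 1:(H - 1)), , drop = FALSE]) / 2
  sqrt(gx^2 + gy^2)
}

#' Shape descriptors of labelled components
#'
#' Computes, per labelled component: centroid, pixel area, chain-code
#' perimeter, circularity (4*pi*A/P^2), convex solidity, and optionally the
#' mean intensity-gradient magnitude along the component boundary.
#'
#' @param lab integer label matrix (from [label_components()]).
#' @param intensity optional matrix (e.g. grayscale image) from which the mean
#'   boundary gradient is measured.
#' @param pixel_size pixel edge length in micrometres; used for `area_um2`.
#' @return data.frame with one row per component.
#' @export
component_features <- function(lab, intensity = NULL, pixel_size = NA_real_) {
  n <- max(lab)
  empty <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_px = numeric(0), area_um2 = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      solidity = numeric(0), border_gradient = numeric(0))
  if (n == 0) return(empty)
  idx <- which(lab > 0)
  lb <- lab[idx]
  H <- nrow(lab)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(lb, nbins = n)
  cy <- tapply(rows, lb, mean)
  cx <- tapply(cols, lb, mean)
  contours <- EBImage::ocontour(lab)
  gm <- if (!is.null(intensity)) gradient_magnitude(intensity) else NULL
  per <- numeric(n); sol <- numeric(n); grad <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pts <- contours[[i]]
    per[i] <- chain_perimeter(pts)
    sol[i] <- component_solidity(pts, area[i])
    if (!is.null(gm)) {
      ii <- pts[, 1] + 1L + pts[, 2] * H   # ocontour coords are 0-based (row, col)
      grad[i] <- mean(gm[ii])
    }
  }
  circ <- pmin(4 * pi * area / pmax(per, 1e-9)^2, 1.2)
  data.frame(label = seq_len(n), x = as.numeric(cx), y = as.numeric(cy),
             area_px = as.numeric(area),
             area_um2 = as.numeric(area) * pixel_size^2,
             perimeter = per, circularity = circ, solidity = sol,
             border_gradient = grad)
}

## Drop labelled components smaller than min_px; returns the pruned mask.
remove_small_components <- function(mask, min_px, connectivity = 8) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- sizes >= min_px
  out <- mask
  out[lab > 0] <- keep[lab[lab > 0]]
  out
}
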