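# Shared fixture builders: small fields keep unit tests fast; acceptance
# tests use the full 512 x 512 study geometry.

small_he_params <- function(...) {
  args <- utils::modifyList(
    list(width = 256, height = 256, n_droplets = 6, n_rbc_blobs = 4,
         droplet_radius = c(4, 12), rbc_radius = c(5, 10)),
    list(...))
  do.call(scene_params, args)
}

small_ihc_params <- function(target = 0.3, ...) {
  args <- utils::modifyList(
    list(width = 256, height = 256, target_dab_fraction = target),
    list(...))
  do.call(scene_params, args)
}

# Uniform "tissue" concentration maps with white disks (droplets) or DAB
# blobs painted at given centres; used to build hand-constructed scenes
# independent of the stochastic generator.
flat_he_scene <- function(H, W, disks = NULL, rim = 1, eosin = 0.3, hema = 0.22,
                          noise_sd = 0) {
  eos <- matrix(eosin, H, W)
  hem <- matrix(hema, H, W)
  if (!is.null(disks)) {
    for (i in seq_len(nrow(disks))) {
      cy <- disks$y[i]; cx <- disks$x[i]; r <- disks$r[i]
      ys <- pmax(1, floor(cy - r - rim)):pmin(H, ceiling(cy + r + rim))
      xs <- pmax(1, floor(cx - r - rim)):pmin(W, ceiling(cx + r + rim))
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
      s <- pmin(pmax((d - r) / rim, 0), 1)
      eos[ys, xs] <- eos[ys, xs] * s
      hem[ys, xs] <- hem[ys, xs] * s
    }
  }
  render_field(list(hematoxylin = hem, eosin = eos), he_basis(),
               noise_sd = noise_sd)
}

flat_ihc_scene <- function(H, W, blobs = NULL, hema = 0.45, dab_conc = 0.7,
                           noise_sd = 0) {
  hem <- matrix(hema, H, W)
  dab <- matrix(0, H, W)
  if (!is.null(blobs)) {
    for (i in seq_len(nrow(blobs))) {
      cy <- blobs$y[i]; cx <- blobs$x[i]; r <- blobs$r[i]
      ys <- pmax(1, floor(cy - r)):pmin(H, ceiling(cy + r))
      xs <- pmax(1, floor(cx - r)):pmin(W, ceiling(cx + r))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      dab[ys, xs][d2 <= r^2] <- dab_conc
    }
  }
  render_field(list(hematoxylin = hem, dab = dab), hdab_basis(),
               noise_sd = noise_sd)
}

# Brute-force Otsu oracle: exhaustively test every histogram cut and pick
# the one maximising between-class variance, computed from first principles.
otsu_bruteforce <- function(values, n_bins = 256, range = base::range(values)) {
  br <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(values, br, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  sb <- rep(-Inf, n_bins - 1)
  for (k in 1:(n_bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    sb[k] <- (n0 / (n0 + n1)) * (n1 / (n0 + n1)) * (m0 - m1)^2
  }
  # same tie-break convention as the implementation: middle of a flat plateau
  ks <- which(sb >= max(sb) - 1e-12 * max(max(sb), 1))
  best_k <- ks[ceiling(length(ks) / 2)]
  (mids[best_k] + mids[best_k + 1]) / 2
}
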