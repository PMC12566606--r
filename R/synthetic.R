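#' Scene parameters for the synthetic histology generator
#'
#' Bundles the controllable properties of a simulated 40x brightfield field:
#' geometry, object counts and radii, stain intensities, the target
#' DAB-positive fraction of tissue for IHC fields, and sensor noise.
#' Defaults emulate a 512 x 512 px field at 0.25 um/px with moderate object
#' densities; all values are overridable.
#'
#' @param width,height field size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param n_droplets number of lipid vacuoles (H&E fields).
#' @param droplet_radius length-2 range of droplet radii, px.
#' @param droplet_rim width (px) of the anti-aliased droplet rim drawn just
#'   outside the nominal radius, giving the sharply defined border.
#' @param n_rbc_blobs number of RBC (erythrocyte) clusters.
#' @param rbc_radius length-2 range of RBC blob radii, px.
#' @param target_dab_fraction desired DAB-positive fraction of tissue for
#'   IHC fields, in `[0, 1]`.
#' @param dab_blob_radius length-2 range of DAB blob radii, px.
#' @param noise_sd additive Gaussian intensity noise sd (8-bit scale).
#' @param background background (unstained) intensity per channel.
#' @param eosin_bg,eosin_texture_sd mean and texture sd of the eosin
#'   concentration of H&E parenchyma (OD-equivalent units).
#' @param hema_bg,hema_texture_sd mean and texture sd of the hematoxylin
#'   concentration of H&E parenchyma.
#' @param rbc_eosin eosin concentration inside RBC blobs.
#' @param ihc_hema,ihc_hema_texture_sd hematoxylin counterstain mean and
#'   texture sd on IHC tissue.
#' @param dab_conc DAB concentration painted on positive pixels.
#' @param n_tissue_blobs number of overlapping disks whose union forms the
#'   IHC tissue region.
#' @param tissue_blob_radius length-2 radius range of tissue disks; default
#'   `c(0.10, 0.20) * min(width, height)`.
#' @param max_attempts rejection-sampling attempts per object before the
#'   generator gives up with an error.
#' @return An object of class `scene_params` (a validated list).
#' @export
scene_params <- function(width = 512, height = 512, pixel_size = 0.25,
                         n_droplets = 12, droplet_radius = c(4, 18),
                         droplet_rim = 1.0,
                         n_rbc_blobs = 8, rbc_radius = c(5, 12),
                         target_dab_fraction = 0,
                         dab_blob_radius = c(4, 14),
                         noise_sd = 3, background = c(255, 255, 255),
                         eosin_bg = 0.30, eosin_texture_sd = 0.05,
                         hema_bg = 0.22, hema_texture_sd = 0.04,
                         rbc_eosin = 1.10,
                         ihc_hema = 0.45, ihc_hema_texture_sd = 0.05,
                         dab_conc = 0.70,
                         n_tissue_blobs = 25, tissue_blob_radius = NULL,
                         max_attempts = 1000) {
  if (is.null(tissue_blob_radius))
    tissue_blob_radius <- c(0.10, 0.20) * min(width, height)
  p <- list(width = as.integer(width), height = as.integer(height),
            pixel_size = pixel_size,
            n_droplets = as.integer(n_droplets),
            droplet_radius = droplet_radius, droplet_rim = droplet_rim,
            n_rbc_blobs = as.integer(n_rbc_blobs), rbc_radius = rbc_radius,
            target_dab_fraction = target_dab_fraction,
            dab_blob_radius = dab_blob_radius,
            noise_sd = noise_sd, background = rep_len(background, 3),
            eosin_bg = eosin_bg, eosin_texture_sd = eosin_texture_sd,
            hema_bg = hema_bg, hema_texture_sd = hema_texture_sd,
            rbc_eosin = rbc_eosin,
            ihc_hema = ihc_hema, ihc_hema_texture_sd = ihc_hema_texture_sd,
            dab_conc = dab_conc,
            n_tissue_blobs = as.integer(n_tissue_blobs),
            tissue_blob_radius = tissue_blob_radius,
            max_attempts = as.integer(max_attempts))
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  stopifnot(p$width > 0, p$height > 0, p$pixel_size > 0)
  if (p$n_droplets < 0 || p$n_rbc_blobs < 0 || p$n_tissue_blobs < 0)
    stop("object counts must be non-negative")
  for (nm in c("droplet_radius", "rbc_radius", "dab_blob_radius",
               "tissue_blob_radius")) {
    r <- p[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop(nm, " must be a positive increasing length-2 range")
  }
  if (p$target_dab_fraction < 0 || p$target_dab_fraction > 1)
    stop("target_dab_fraction must be in [0, 1]")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(p$background < 1 | p$background > 255))
    stop("background intensity must be in [1, 255]")
  invisible(p)
}

## Rejection-sampled, mutually non-overlapping disk placement. Returns a
## data.frame(y, x, r). `margin` is added to every pairwise clearance and to
## the distance from the field border.
place_disks <- function(existing, n, radius_range, H, W, margin, max_attempts,
                        what = "object") {
  placed <- existing
  for (k in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      lim <- r + margin
      if (2 * lim >= min(H, W)) next
      cy <- stats::runif(1, lim, H - lim)
      cx <- stats::runif(1, lim, W - lim)
      if (nrow(placed) > 0) {
        dd <- sqrt((placed$y - cy)^2 + (placed$x - cx)^2)
        if (any(dd < placed$r + r + margin)) next
      }
      placed <- rbind(placed, data.frame(y = cy, x = cx, r = r))
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(paste0("could not place %s %d of %d after %d attempts; ",
                          "the field is too crowded for the requested count ",
                          "and radius range"), what, k, n, max_attempts))
  }
  placed
}

#' Generate a synthetic H&E liver field with ground truth
#'
#' Renders eosinophilic parenchyma (mixed hematoxylin + eosin with smooth
#' texture), round unstained lipid vacuoles with a sharp 1 px rim, and
#' strongly eosinophilic RBC blobs. All objects are placed by rejection
#' sampling with mutual clearance, so droplet, rim, and RBC masks are
#' pairwise disjoint, and every placed object is recorded in the returned
#' ground truth. Deterministic given `(params, seed)`.
#'
#' @param params a [scene_params()].
#' @param seed integer seed.
#' @return list with `image` (H x W x 3 intensity array) and `truth`, a
#'   `ground_truth` list holding `rbc_mask`, `droplet_mask`, `droplet_list`
#'   and `rbc_list` (data.frames x, y, r), `dab_mask`, `tissue_mask`,
#'   `true_dab_fraction`, and `seed`.
#' @export
generate_he_field <- function(params = scene_params(), seed = 1L) {
  validate_scene_params(params)
  withr::with_seed(as.integer(seed), {
    H <- params$height; W <- params$width
    eos <- clip(params$eosin_bg + params$eosin_texture_sd * smooth_noise(H, W),
                0.12, 0.50)
    hem <- clip(params$hema_bg + params$hema_texture_sd * smooth_noise(H, W),
                0.08, 0.40)
    rim <- params$droplet_rim
    disks <- place_disks(data.frame(y = numeric(0), x = numeric(0), r = numeric(0)),
                         params$n_droplets, params$droplet_radius, H, W,
                         margin = rim + 2, max_attempts = params$max_attempts,
                         what = "droplet")
    nd <- nrow(disks)
    disks <- place_disks(disks, params$n_rbc_blobs, params$rbc_radius, H, W,
                         margin = rim + 2, max_attempts = params$max_attempts,
                         what = "RBC blob")
    disks$type <- c(rep("droplet", nd), rep("rbc", nrow(disks) - nd))
    droplet_mask <- matrix(FALSE, H, W)
    rbc_mask <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(disks))) {
      d <- disks[i, ]
      if (d$type == "droplet") {
        px <- disk_pixels(d$y, d$x, d$r, H, W, extra = rim)
        s <- clip((px$d - d$r) / rim, 0, 1)   # 0 inside, ramps to 1 outside
        eos[px$idx] <- eos[px$idx] * s
        hem[px$idx] <- hem[px$idx] * s
        droplet_mask[px$idx[px$d <= d$r]] <- TRUE
      } else {
        px <- disk_pixels(d$y, d$x, d$r, H, W)
        eos[px$idx] <- params$rbc_eosin
        rbc_mask[px$idx] <- TRUE
      }
    }
    basis <- he_basis(I0 = params$background)
    img <- render_field(list(hematoxylin = hem, eosin = eos), basis,
                        noise_sd = params$noise_sd)
    dl <- disks[disks$type == "droplet", c("x", "y", "r")]
    rl <- disks[disks$type == "rbc", c("x", "y", "r")]
    rownames(dl) <- rownames(rl) <- NULL
    truth <- structure(list(
      rbc_mask = rbc_mask, droplet_mask = droplet_mask,
      droplet_list = dl, rbc_list = rl,
      dab_mask = matrix(FALSE, H, W),
      tissue_mask = !droplet_mask,
      true_dab_fraction = NA_real_,
      seed = as.integer(seed)), class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Generate a synthetic DAB/hematoxylin IHC field with ground truth
#'
#' Draws an irregular tissue region (union of random disks), paints a
#' hematoxylin counterstain with smooth texture on all tissue, then paints
#' clustered DAB blobs on tissue until the DAB-positive pixel count equals
#' `round(target_dab_fraction * tissue_px)` exactly (the last blob is
#' truncated to its pixels nearest the blob centre, and any remaining
#' deficit is filled by growing the positive region along its boundary).
#' The realised fraction therefore matches the target to within one pixel.
#' Deterministic given `(params, seed)`.
#'
#' @inheritParams generate_he_field
#' @return list with `image` and `truth` (see [generate_he_field()]);
#'   `truth$true_dab_fraction` is the realised `|dab| / |tissue|`.
#' @export
generate_ihc_field <- function(params = scene_params(), seed = 1L) {
  validate_scene_params(params)
  withr::with_seed(as.integer(seed), {
    H <- params$height; W <- params$width
    tissue <- matrix(FALSE, H, W)
    for (i in seq_len(params$n_tissue_blobs)) {
      r <- stats::runif(1, params$tissue_blob_radius[1], params$tissue_blob_radius[2])
      cy <- stats::runif(1, 0.18 * H, 0.82 * H)
      cx <- stats::runif(1, 0.18 * W, 0.82 * W)
      tissue[disk_pixels(cy, cx, r, H, W)$idx] <- TRUE
    }
    tissue_px <- sum(tissue)
    if (tissue_px == 0) stop("no tissue generated; increase n_tissue_blobs")
    f <- params$target_dab_fraction
    target_px <- round(f * tissue_px)
    dab <- matrix(FALSE, H, W)
    if (target_px >= tissue_px) {
      dab <- tissue
    } else if (target_px > 0) {
      tissue_idx <- which(tissue)
      dab_px <- 0L
      rmin <- params$dab_blob_radius[1]
      iter <- 0L
      while (dab_px < target_px && (target_px - dab_px) >= pi * rmin^2 / 2) {
        iter <- iter + 1L
        if (iter > 50000L)
          stop("target_dab_fraction unreachable with the configured blob sizes")
        ctr <- tissue_idx[sample.int(length(tissue_idx), 1)]
        cy <- ((ctr - 1L) %% H) + 1L
        cx <- ((ctr - 1L) %/% H) + 1L
        r <- stats::runif(1, rmin, params$dab_blob_radius[2])
        px <- disk_pixels(cy, cx, r, H, W)
        new <- px$idx[tissue[px$idx] & !dab[px$idx]]
        if (length(new) == 0) next
        room <- target_px - dab_px
        if (length(new) > room) {
          dnew <- px$d[tissue[px$idx] & !dab[px$idx]]
          new <- new[order(dnew)][seq_len(room)]
        }
        dab[new] <- TRUE
        dab_px <- dab_px + length(new)
      }
      ## exact top-up: grow along the boundary of the existing positive region
      while (dab_px < target_px) {
        if (dab_px == 0) {           # fraction below half a minimal blob
          ctr <- tissue_idx[sample.int(length(tissue_idx), 1)]
          cy <- ((ctr - 1L) %% H) + 1L; cx <- ((ctr - 1L) %/% H) + 1L
          px <- disk_pixels(cy, cx, max(2, sqrt(target_px / pi)), H, W)
          new <- px$idx[tissue[px$idx]]
          new <- new[order(px$d[tissue[px$idx]])][seq_len(min(length(new), target_px))]
        } else {
          ring <- EBImage::dilate(dab * 1, EBImage::makeBrush(3, "box")) > 0
          cand <- which(ring & tissue & !dab)
          if (length(cand) == 0) break
          take <- min(target_px - dab_px, length(cand))
          new <- if (take < length(cand)) sample(cand, take) else cand
        }
        dab[new] <- TRUE
        dab_px <- dab_px + length(new)
      }
    }
    hem <- matrix(0, H, W)
    hem[tissue] <- clip(params$ihc_hema +
                          params$ihc_hema_texture_sd * smooth_noise(H, W),
                        0.25, 0.70)[tissue]
    dabmap <- matrix(0, H, W)
    dabmap[dab] <- params$dab_conc
    basis <- hdab_basis(I0 = params$background)
    img <- render_field(list(hematoxylin = hem, dab = dabmap), basis,
                        noise_sd = params$noise_sd)
    truth <- structure(list(
      rbc_mask = matrix(FALSE, H, W),
      droplet_mask = matrix(FALSE, H, W),
      droplet_list = data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
      rbc_list = data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
      dab_mask = dab, tissue_mask = tissue,
      true_dab_fraction = sum(dab) / tissue_px,
      seed = as.integer(seed)), class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Generate a multi-group set of synthetic fields on disk
#'
#' Writes one image file per field (8-bit TIFF by default) plus a
#' `ground_truth.csv` audit table. Per-field seeds are derived from
#' `base_seed` with [field_seed()], so the whole set is reproducible from a
#' single integer.
#'
#' @param group_spec named list mapping group label to its [scene_params()].
#' @param n_fields number of fields per group.
#' @param base_seed integer base seed.
#' @param out_dir output directory (created if needed).
#' @param modality `"ihc"` or `"he"`.
#' @param format `"tiff"` or `"png"`.
#' @param animals_per_group fields are assigned to this many animal ids per
#'   group, round-robin, to support nested (per-animal) summaries.
#' @return Invisibly, the ground-truth data.frame (one row per field, with
#'   columns group, animal, field_id, file, seed, n_droplets, rbc_px,
#'   droplet_px, tissue_px, dab_px, true_dab_fraction).
#' @export
generate_group_set <- function(group_spec, n_fields, base_seed, out_dir,
                               modality = c("ihc", "he"),
                               format = c("tiff", "png"),
                               animals_per_group = 5) {
  modality <- match.arg(modality)
  format <- match.arg(format)
  stopifnot(n_fields >= 1, length(group_spec) >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  ext <- if (format == "tiff") "tif" else "png"
  rows <- list()
  for (g in seq_along(group_spec)) {
    gname <- names(group_spec)[g]
    params <- group_spec[[g]]
    for (i in seq_len(n_fields)) {
      s <- field_seed(base_seed, g, i)
      fld <- if (modality == "ihc") generate_ihc_field(params, s)
             else generate_he_field(params, s)
      file <- file.path(out_dir, sprintf("%s_%03d.%s", gname, i, ext))
      write_field(fld$image, file, format)
      tr <- fld$truth
      rows[[length(rows) + 1]] <- data.frame(
        group = gname,
        animal = ((i - 1) %% animals_per_group) + 1,
        field_id = sprintf("%s_%03d", gname, i),
        file = basename(file), seed = s,
        n_droplets = nrow(tr$droplet_list),
        rbc_px = sum(tr$rbc_mask), droplet_px = sum(tr$droplet_mask),
        tissue_px = sum(tr$tissue_mask), dab_px = sum(tr$dab_mask),
        true_dab_fraction = tr$true_dab_fraction)
    }
  }
  gt <- do.call(rbind, rows)
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(gt)
}
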