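#' Segment red blood cells in an H&E field
#'
#' RBCs are identified by their characteristic intense eosin staining: a
#' pixel is called RBC when its eosin concentration (after color
#' deconvolution) is at least `eosin_min` AND its red/green intensity ratio
#' is at least `ratio_min`; connected specks smaller than `min_rbc_px` are
#' removed. The area is reported both as raw pixels and as a percentage of
#' total image area.
#'
#' @param img H x W x 3 intensity array (0..255).
#' @param basis stain basis, default [he_basis()].
#' @param eosin_min minimum eosin concentration (OD-equivalent units).
#' @param ratio_min minimum (R+1)/(G+1) intensity ratio.
#' @param min_rbc_px minimum connected-component size kept, px.
#' @param pixel_size um/px for the um^2 area.
#' @return list with `mask` (logical), `rbc_area_px`, `rbc_area_um2`,
#'   `rbc_area_pct` (% of image area).
#' @export
segment_rbc <- function(img, basis = he_basis(), eosin_min = 0.7,
                        ratio_min = 2.5, min_rbc_px = 20, pixel_size = 0.25) {
  od <- rgb_to_od(img, I0 = basis$I0, od_cap = basis$od_cap)
  conc <- deconvolve(od, basis)
  eos <- conc[, , "eosin"]
  ratio <- (img[, , 1] + 1) / (img[, , 2] + 1)
  mask <- eos >= eosin_min & ratio >= ratio_min
  mask <- remove_small_components(mask, min_rbc_px)
  a <- sum(mask)
  list(mask = mask, rbc_area_px = a, rbc_area_um2 = a * pixel_size^2,
       rbc_area_pct = 100 * a / (nrow(mask) * ncol(mask)))
}

#' Detect lipid droplets (fat vacuoles) in an H&E field
#'
#' Candidate vacuoles are connected components (8-connectivity) of the
#' near-white mask (all three channels at or above `white_frac * I0`),
#' hole-filled before measurement, then filtered by four uniformly applied
#' criteria: minimum area, minimum circularity (4*pi*A/P^2), minimum convex
#' solidity, and minimum mean intensity-gradient along the border (the
#' "sharply defined border" requirement that separates vacuoles from pale
#' or torn regions).
#'
#' @param img H x W x 3 intensity array (0..255).
#' @param white_frac fraction of `I0` above which a channel counts as
#'   unstained.
#' @param min_area minimum component area, px^2.
#' @param circularity_min minimum circularity.
#' @param solidity_min minimum solidity.
#' @param border_gradient_min minimum mean border gradient, intensity/px.
#' @param I0 background intensity per channel.
#' @param pixel_size um/px.
#' @return data.frame of droplet records (label, x, y, area_px, area_um2,
#'   perimeter, circularity, solidity, border_gradient), one row per
#'   accepted droplet; zero rows is a valid result. The pre-filter candidate
#'   mask is attached as attribute `"white_mask"`.
#' @export
detect_droplets <- function(img, white_frac = 0.85, min_area = 30,
                            circularity_min = 0.6, solidity_min = 0.85,
                            border_gradient_min = 8,
                            I0 = c(255, 255, 255), pixel_size = 0.25) {
  stopifnot(min_area > 0, circularity_min > 0, solidity_min > 0,
            border_gradient_min >= 0)
  I0 <- rep_len(I0, 3)
  white <- img[, , 1] >= white_frac * I0[1] &
           img[, , 2] >= white_frac * I0[2] &
           img[, , 3] >= white_frac * I0[3]
  out <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                    area_px = numeric(0), area_um2 = numeric(0),
                    perimeter = numeric(0), circularity = numeric(0),
                    solidity = numeric(0), border_gradient = numeric(0))
  if (any(white)) {
    lab <- label_components(white, 8)
    lab <- EBImage::fillHull(lab)
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    feats <- component_features(lab, intensity = gray, pixel_size = pixel_size)
    keep <- feats$area_px >= min_area &
            feats$circularity >= circularity_min &
            feats$solidity >= solidity_min &
            feats$border_gradient >= border_gradient_min
    out <- feats[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "white_mask") <- white
  out
}

#' Quantify one H&E field: RBC area, fat droplet count and area
#'
#' Composes [segment_rbc()] and [detect_droplets()]. Fat droplet area is the
#' cumulative cross-sectional area of accepted droplets normalised to total
#' image area (not tissue area), matching the H&E morphometry convention;
#' RBC area is likewise a percentage of image area.
#'
#' @param img H x W x 3 intensity array.
#' @param field_id identifier copied into the output row.
#' @param rbc named list of overrides for [segment_rbc()] parameters.
#' @param droplets named list of overrides for [detect_droplets()] parameters.
#' @param pixel_size um/px.
#' @param basis stain basis for the RBC eosin channel.
#' @return one-row data.frame (field_id, rbc_area_pct, rbc_area_px,
#'   fat_count, fat_area_pct, fat_area_px, tissue_area_px) with the droplet
#'   records as attribute `"droplets"` and the RBC mask as `"rbc_mask"`.
#' @export
quantify_he_field <- function(img, field_id = "field", rbc = list(),
                              droplets = list(), pixel_size = 0.25,
                              basis = he_basis()) {
  rb <- do.call(segment_rbc, c(list(img = img, basis = basis,
                                    pixel_size = pixel_size), rbc))
  dr <- do.call(detect_droplets, c(list(img = img, I0 = basis$I0,
                                        pixel_size = pixel_size), droplets))
  H <- dim(img)[1]; W <- dim(img)[2]
  fat_px <- sum(dr$area_px)
  res <- data.frame(field_id = field_id,
                    rbc_area_pct = rb$rbc_area_pct,
                    rbc_area_px = rb$rbc_area_px,
                    fat_count = nrow(dr),
                    fat_area_pct = 100 * fat_px / (H * W),
                    fat_area_px = fat_px,
                    tissue_area_px = H * W - sum(attr(dr, "white_mask")))
  attr(res, "droplets") <- dr
  attr(res, "rbc_mask") <- rb$mask
  res
}

#' Quantify a batch of H&E fields
#'
#' @param fields either a character vector of image file paths or a named
#'   list of in-memory H x W x 3 arrays.
#' @param ... passed on to [quantify_he_field()].
#' @return data.frame with one row per field.
#' @export
quantify_he_batch <- function(fields, ...) {
  ids <- if (is.character(fields)) tools::file_path_sans_ext(basename(fields))
         else if (!is.null(names(fields))) names(fields)
         else sprintf("field_%03d", seq_along(fields))
  rows <- lapply(seq_along(fields), function(i) {
    img <- if (is.character(fields)) read_field(fields[[i]]) else fields[[i]]
    quantify_he_field(img, field_id = ids[i], ...)
  })
  do.call(rbind, rows)
}
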