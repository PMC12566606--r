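#' Delimit the tissue region of a brightfield field
#'
#' Tissue is wherever total optical density (sum over channels) reaches
#' `od_min`; the raw mask is regularised by morphological closing and
#' removal of small components, which fills pinholes and discards dust.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param od_min minimum summed OD for a tissue pixel.
#' @param close_radius radius (px) of the disc brush used for closing.
#' @param min_size minimum component size kept, px^2.
#' @return Logical H x W tissue mask.
#' @export
tissue_mask <- function(od, od_min = 0.15, close_radius = 2, min_size = 100) {
  m <- (od[, , 1] + od[, , 2] + od[, , 3]) >= od_min
  if (any(m) && close_radius > 0) {
    m <- EBImage::closing(m * 1, EBImage::makeBrush(2 * close_radius + 1, "disc")) > 0
  }
  remove_small_components(m, min_size)
}

## Artifact rejection on a positive mask: components below min_area are
## always removed (specks); components are also removed when they are both
## larger than max_area AND rounder than circularity_max, the signature of
## bubbles and precipitate rather than genuine immunostaining (true positive
## regions at high stain fractions form large but irregular clusters).
filter_artifacts <- function(pos, min_area, max_area, circularity_max) {
  n_rejected <- 0L
  if (!any(pos)) return(list(mask = pos, n_rejected = 0L))
  lab <- label_components(pos, 8)
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  drop <- sizes < min_area
  big <- which(sizes > max_area & !drop)
  if (length(big)) {
    feats <- component_features(lab)
    drop[big] <- feats$circularity[big] > circularity_max
  }
  n_rejected <- sum(drop)
  out <- pos
  out[lab > 0] <- !drop[lab[lab > 0]]
  list(mask = out, n_rejected = as.integer(n_rejected))
}

#' Quantify DAB-positive area in one IHC field
#'
#' Isolates the DAB chromogen channel by color deconvolution, thresholds it
#' (Otsu within tissue by default, or a fixed/shared threshold), rejects
#' artifacts by size and shape, and reports the percentage of positive
#' pixels over the tissue area:
#' `dab_pos_pct = 100 * |positive & tissue| / |tissue|`.
#'
#' @param img H x W x 3 intensity array (0..255).
#' @param basis stain basis, default [hdab_basis()].
#' @param threshold list: `method` `"otsu"` or `"fixed"`, and `value` for
#'   fixed thresholds (e.g. a shared-Otsu value pooled across a batch).
#' @param artifact list of filter settings: `min_area` (px^2),
#'   `max_area_frac` (fraction of tissue area above which a component is a
#'   bubble candidate), `circularity_max` (bubble roundness cut).
#' @param od_min,close_radius,min_size passed to [tissue_mask()].
#' @param field_id identifier copied into the output row.
#' @return one-row data.frame (field_id, dab_pos_pct, tissue_area_px,
#'   dab_area_px, n_rejected_artifacts, threshold) with the positive mask
#'   as attribute `"dab_mask"` and the tissue mask as `"tissue_mask"`.
#' @export
quantify_ihc_field <- function(img, basis = hdab_basis(),
                               threshold = list(method = "otsu", value = NULL),
                               artifact = list(min_area = 20,
                                               max_area_frac = 0.05,
                                               circularity_max = 0.95),
                               od_min = 0.15, close_radius = 2, min_size = 100,
                               field_id = "field") {
  od <- rgb_to_od(img, I0 = basis$I0, od_cap = basis$od_cap)
  tis <- tissue_mask(od, od_min = od_min, close_radius = close_radius,
                     min_size = min_size)
  if (!any(tis))
    stop("empty tissue mask for field '", field_id,
         "': DAB-positive percentage is undefined")
  conc <- deconvolve(od, basis, clamp_negatives = TRUE)
  dab <- pmax(conc[, , "dab"], 0)
  thr <- if (identical(threshold$method, "fixed") || !is.null(threshold$value)) {
    if (is.null(threshold$value)) stop("fixed threshold requires a value")
    threshold$value
  } else {
    # per-field Otsu with the unimodality guard (a field with no staining, or
    # one stained throughout, has no bimodal histogram for Otsu to split)
    br <- seq(0, basis$od_cap, length.out = 257)
    v <- clip(dab[tis], 0, basis$od_cap)
    bin <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), 256L)
    guarded_otsu(tabulate(bin, nbins = 256), (br[-1] + br[-257]) / 2)
  }
  pos <- dab >= thr & tis
  flt <- filter_artifacts(pos,
                          min_area = artifact$min_area,
                          max_area = artifact$max_area_frac * sum(tis),
                          circularity_max = artifact$circularity_max)
  dab_px <- sum(flt$mask & tis)
  res <- data.frame(field_id = field_id,
                    dab_pos_pct = 100 * dab_px / sum(tis),
                    tissue_area_px = sum(tis), dab_area_px = dab_px,
                    n_rejected_artifacts = flt$n_rejected,
                    threshold = thr)
  attr(res, "dab_mask") <- flt$mask
  attr(res, "tissue_mask") <- tis
  res
}

#' Quantify a batch of IHC fields with a uniformly applied threshold
#'
#' With `threshold_mode = "shared-otsu"` (the default) the DAB histograms of
#' all fields, restricted to their tissue masks, are pooled and a single
#' Otsu threshold is applied to every field — one threshold uniformly
#' applied across samples. `"otsu"` thresholds each field independently;
#' `"fixed"` applies `fixed_value` everywhere.
#'
#' @param fields character vector of image paths or a named list of
#'   H x W x 3 arrays.
#' @param basis stain basis.
#' @param threshold_mode `"shared-otsu"`, `"otsu"`, or `"fixed"`.
#' @param fixed_value threshold for `"fixed"`.
#' @param ... passed to [quantify_ihc_field()] (artifact filters, tissue
#'   mask settings).
#' @return data.frame with one row per field; the applied threshold is in
#'   column `threshold`.
#' @export
quantify_ihc_batch <- function(fields, basis = hdab_basis(),
                               threshold_mode = c("shared-otsu", "otsu", "fixed"),
                               fixed_value = NULL, ...) {
  threshold_mode <- match.arg(threshold_mode)
  ids <- if (is.character(fields)) tools::file_path_sans_ext(basename(fields))
         else if (!is.null(names(fields))) names(fields)
         else sprintf("field_%03d", seq_along(fields))
  get_img <- function(i) if (is.character(fields)) read_field(fields[[i]]) else fields[[i]]
  thr_list <- switch(threshold_mode,
    "fixed" = {
      if (is.null(fixed_value)) stop("threshold_mode 'fixed' requires fixed_value")
      list(method = "fixed", value = fixed_value)
    },
    "otsu" = list(method = "otsu", value = NULL),
    "shared-otsu" = {
      channels <- vector("list", length(fields))
      tissues <- vector("list", length(fields))
      for (i in seq_along(fields)) {
        img <- get_img(i)
        od <- rgb_to_od(img, I0 = basis$I0, od_cap = basis$od_cap)
        tissues[[i]] <- tissue_mask(od)
        conc <- deconvolve(od, basis, clamp_negatives = TRUE)
        channels[[i]] <- conc[, , "dab"]
      }
      shared <- pooled_otsu(channels, tissues, range = c(0, basis$od_cap))
      list(method = "fixed", value = shared)
    })
  rows <- lapply(seq_along(fields), function(i) {
    quantify_ihc_field(get_img(i), basis = basis, threshold = thr_list,
                       field_id = ids[i], ...)
  })
  do.call(rbind, rows)
}

#' Summarise per-field IHC measurements per group
#'
#' Two-stage (nested) aggregation matching the study design of several
#' fields imaged per animal and several animals per treatment group: fields
#' are first averaged within animal, then the group mean and sample SD
#' (n - 1 denominator) are taken across animal means, so animals — not
#' fields — are the unit of replication. `pool_fields = TRUE` instead pools
#' all fields of a group directly.
#'
#' @param data data.frame with at least the group, animal and value columns.
#' @param value,group,animal column names.
#' @param pool_fields pool fields across animals instead of nesting.
#' @return data.frame (group, n, mean, sd, n1_flag): `n` is the number of
#'   animals (or fields when pooling); groups with a single replicate get
#'   `sd = 0` and `n1_flag = TRUE`.
#' @export
summarize_group_ihc <- function(data, value = "dab_pos_pct", group = "group",
                                animal = "animal", pool_fields = FALSE) {
  stopifnot(all(c(value, group) %in% names(data)))
  if (!pool_fields && !animal %in% names(data))
    stop("animal column '", animal, "' not found; use pool_fields = TRUE to pool")
  if (nrow(data) == 0) stop("no rows to summarise")
  if (pool_fields) {
    unit <- data[[value]]
    ug <- as.character(data[[group]])
  } else {
    am <- stats::aggregate(data[[value]],
                           by = list(group = data[[group]], animal = data[[animal]]),
                           FUN = mean)
    unit <- am$x
    ug <- as.character(am$group)
  }
  agg <- data.frame(group = sort(unique(as.character(ug))))
  agg$n <- as.integer(table(ug)[agg$group])
  agg$mean <- as.numeric(tapply(unit, ug, mean)[agg$group])
  sds <- tapply(unit, ug, stats::sd)[agg$group]
  agg$n1_flag <- agg$n == 1
  agg$sd <- ifelse(agg$n1_flag, 0, as.numeric(sds))
  agg[, c("group", "n", "mean", "sd", "n1_flag")]
}
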