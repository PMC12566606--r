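test_that("tissue delimitation recovers the generator's tissue region", {
  # pure background -> empty; fully stained -> full
  b <- hdab_basis()
  bg <- render_field(list(hematoxylin = matrix(0, 64, 64)), b)
  expect_equal(sum(tissue_mask(rgb_to_od(bg, b$I0))), 0)
  full <- render_field(list(hematoxylin = matrix(0.45, 64, 64)), b)
  expect_equal(sum(tissue_mask(rgb_to_od(full, b$I0))), 64 * 64)

  # synthetic field: Jaccard overlap with ground truth >= 0.98
  f <- generate_ihc_field(scene_params(512, 512, target_dab_fraction = 0.3),
                          seed = 14)
  tis <- tissue_mask(rgb_to_od(f$image, b$I0, b$od_cap))
  jac <- sum(tis & f$truth$tissue_mask) / sum(tis | f$truth$tissue_mask)
  expect_gte(jac, 0.98)
})

test_that("DAB positive-area percentage recovers the generator's truth", {
  # saturation points: target 0 -> 0 %, target 1 -> 100 % (+/- 0.5 pp)
  f0 <- generate_ihc_field(small_ihc_params(0), seed = 3)
  expect_equal(quantify_ihc_field(f0$image)$dab_pos_pct, 0, tolerance = 0.5)
  f1 <- generate_ihc_field(small_ihc_params(1), seed = 3)
  expect_equal(quantify_ihc_field(f1$image)$dab_pos_pct, 100, tolerance = 0.5)

  # mid-range field at the 0.361 fraction: recovered within 1 pp
  f <- generate_ihc_field(scene_params(512, 512, target_dab_fraction = 0.361),
                          seed = 15)
  q <- quantify_ihc_field(f$image)
  expect_lt(abs(q$dab_pos_pct - 100 * f$truth$true_dab_fraction), 1.0)
  expect_lte(q$dab_area_px, q$tissue_area_px)

  # empty tissue is an explicit error, not a silent zero
  b <- hdab_basis()
  bg <- render_field(list(hematoxylin = matrix(0, 64, 64)), b)
  expect_error(quantify_ihc_field(bg), "empty tissue")
})

test_that("dab_pos_pct is invariant to rotation and flip, monotone in added blobs", {
  f <- generate_ihc_field(small_ihc_params(0.25), seed = 16)
  q0 <- quantify_ihc_field(f$image)$dab_pos_pct
  rot90 <- function(a) {
    out <- array(0, dim = c(dim(a)[2], dim(a)[1], 3))
    for (c in 1:3) out[, , c] <- t(a[dim(a)[1]:1, , c])
    out
  }
  flip <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
  expect_equal(quantify_ihc_field(rot90(f$image))$dab_pos_pct, q0, tolerance = 1e-10)
  expect_equal(quantify_ihc_field(flip(f$image))$dab_pos_pct, q0, tolerance = 1e-10)

  # painting additional DAB blobs inside tissue never decreases the metric
  # (fixed threshold isolates the mask logic from Otsu's histogram shift)
  b3 <- data.frame(x = c(60, 120, 180), y = c(60, 120, 60), r = c(15, 18, 12))
  b5 <- rbind(b3, data.frame(x = c(60, 180), y = c(180, 180), r = c(14, 16)))
  thr <- list(method = "fixed", value = 0.35)
  p3 <- quantify_ihc_field(flat_ihc_scene(240, 240, b3), threshold = thr)$dab_pos_pct
  p5 <- quantify_ihc_field(flat_ihc_scene(240, 240, b5), threshold = thr)$dab_pos_pct
  expect_gt(p5, p3)
})

test_that("artifact filters reject specks and large perfect-disk bubbles", {
  # genuine blobs + sub-minimum specks: specks rejected and counted
  blobs <- data.frame(x = c(60, 150), y = c(60, 150), r = c(15, 18))
  specks <- data.frame(x = c(200, 30, 110), y = c(40, 200, 200), r = rep(1.8, 3))
  img <- flat_ihc_scene(240, 240, rbind(blobs, specks))
  q <- quantify_ihc_field(img, threshold = list(method = "fixed", value = 0.35))
  expect_equal(q$n_rejected_artifacts, 3)

  # a huge, nearly perfectly circular positive disk (> max_area_frac of
  # tissue and circularity > 0.95) is rejected as a bubble; the equally
  # large but irregular merged cluster is kept
  bubble <- data.frame(x = 120, y = 120, r = 60)
  qb <- quantify_ihc_field(flat_ihc_scene(240, 240, bubble),
                           threshold = list(method = "fixed", value = 0.35))
  expect_equal(qb$n_rejected_artifacts, 1)
  expect_equal(qb$dab_area_px, 0)

  cluster <- data.frame(x = c(100, 130, 120, 95, 145), y = c(100, 100, 130, 130, 125),
                        r = c(25, 22, 24, 18, 20))
  qc <- quantify_ihc_field(flat_ihc_scene(240, 240, cluster),
                           threshold = list(method = "fixed", value = 0.35))
  expect_equal(qc$n_rejected_artifacts, 0)
  expect_gt(qc$dab_area_px, pi * 25^2)
})

test_that("shared-Otsu batch thresholding applies one threshold uniformly", {
  flds <- list(a = generate_ihc_field(small_ihc_params(0.15), 21)$image,
               b = generate_ihc_field(small_ihc_params(0.45), 22)$image)
  q <- quantify_ihc_batch(flds, threshold_mode = "shared-otsu")
  expect_equal(length(unique(q$threshold)), 1)
  expect_lt(abs(q$dab_pos_pct[1] - 15), 1.0)
  expect_lt(abs(q$dab_pos_pct[2] - 45), 1.0)
  qf <- quantify_ihc_batch(flds, threshold_mode = "fixed", fixed_value = 0.35)
  expect_equal(unique(qf$threshold), 0.35)
  expect_error(quantify_ihc_batch(flds, threshold_mode = "fixed"), "fixed_value")
})

test_that("group summaries nest fields within animals", {
  # one animal, one field: SD reported as 0 with the n = 1 flag
  d1 <- data.frame(group = "g", animal = 1, dab_pos_pct = 40)
  s1 <- summarize_group_ihc(d1)
  expect_equal(s1$mean, 40)
  expect_equal(s1$sd, 0)
  expect_true(s1$n1_flag)

  # five animals at 30, 32, 34, 36, 38 % (two fields each, averaging to
  # those values): group mean 34, sample SD sqrt(10)
  d5 <- data.frame(group = "g", animal = rep(1:5, each = 2),
                   dab_pos_pct = c(29, 31, 31, 33, 33, 35, 35, 37, 37, 39))
  s5 <- summarize_group_ihc(d5)
  expect_equal(s5$n, 5)
  expect_equal(s5$mean, 34)
  expect_equal(s5$sd, sqrt(10), tolerance = 1e-12)

  # permuting row order leaves the summary unchanged
  perm <- d5[sample(nrow(d5)), ]
  expect_equal(summarize_group_ihc(perm), s5)

  # pooling fields uses fields as units
  sp <- summarize_group_ihc(d5, pool_fields = TRUE)
  expect_equal(sp$n, 10)
  expect_equal(sp$mean, 34)

  expect_error(summarize_group_ihc(d5[0, ]), "no rows")
})
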