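test_that("render_field reproduces the Beer-Lambert forward model", {
  b <- he_basis()
  # empty scene: every pixel equals the background intensity exactly
  img <- render_field(list(hematoxylin = matrix(0, 4, 4)), b, noise_sd = 0)
  expect_equal(as.vector(img), rep(255, 48))

  # one concentration unit of a pure-red-absorbing stain: one decade of
  # attenuation in R, the inverse of the OD transform: (I0+1)/10 - 1
  bi <- stain_basis(diag(3), stains = c("r", "g", "b"))
  img1 <- render_field(list(r = matrix(1, 2, 2)), bi, noise_sd = 0)
  expect_equal(img1[1, 1, ], c((255 + 1) / 10 - 1, 255, 255), tolerance = 1e-9)

  # shape mismatch is rejected naming the offending map
  expect_error(render_field(list(hematoxylin = matrix(0, 4, 4),
                                 eosin = matrix(0, 5, 4)), b),
               "'eosin'.*5x4")
  expect_error(render_field(list(bogus = matrix(0, 2, 2)), b), "named after")

  # noise is reproducible under a seed
  n1 <- render_field(list(hematoxylin = matrix(0.2, 8, 8)), b, noise_sd = 3, seed = 5)
  n2 <- render_field(list(hematoxylin = matrix(0.2, 8, 8)), b, noise_sd = 3, seed = 5)
  expect_identical(n1, n2)
})

test_that("render -> deconvolve round-trip recovers concentrations to 1e-6", {
  for (basis in list(he_basis(), hdab_basis())) {
    set.seed(9)
    c1 <- matrix(runif(48 * 48, 0, 1.2), 48)
    c2 <- matrix(runif(48 * 48, 0, 1.2), 48)
    maps <- list(c1, c2)
    names(maps) <- basis$stains[1:2]
    img <- render_field(maps, basis, noise_sd = 0)
    conc <- deconvolve(rgb_to_od(img, basis$I0, basis$od_cap), basis)
    expect_lt(max(abs(conc[, , 1] - c1)), 1e-6)
    expect_lt(max(abs(conc[, , 2] - c2)), 1e-6)
    expect_lt(max(abs(conc[, , 3])), 1e-6)
  }
})

test_that("H&E generator bookkeeping matches its ground truth", {
  # no objects -> empty masks
  f0 <- generate_he_field(small_he_params(n_droplets = 0, n_rbc_blobs = 0), seed = 2)
  expect_equal(sum(f0$truth$droplet_mask), 0)
  expect_equal(sum(f0$truth$rbc_mask), 0)

  # requested droplet count is recorded exactly
  f7 <- generate_he_field(small_he_params(n_droplets = 7, n_rbc_blobs = 0), seed = 3)
  expect_equal(nrow(f7$truth$droplet_list), 7)

  # rasterized disk areas: mask pixel count within rasterization error
  # (<= perimeter in px) of the analytic area, per field
  dl <- f7$truth$droplet_list
  expect_lt(abs(sum(f7$truth$droplet_mask) - sum(pi * dl$r^2)),
            sum(2 * pi * dl$r))

  # RBC blobs are disjoint disks: the summed pixel counts of independently
  # rasterized placed disks equal the mask pixel count exactly
  f3 <- generate_he_field(small_he_params(n_droplets = 0, n_rbc_blobs = 3), seed = 4)
  rl <- f3$truth$rbc_list
  per_disk <- vapply(seq_len(nrow(rl)), function(i) {
    sum(outer((1:256 - rl$y[i])^2, (1:256 - rl$x[i])^2, "+") <= rl$r[i]^2)
  }, numeric(1))
  expect_equal(sum(f3$truth$rbc_mask), sum(per_disk))

  # masks are pairwise disjoint and dab is empty on H&E fields
  f <- generate_he_field(small_he_params(), seed = 5)
  expect_equal(sum(f$truth$droplet_mask & f$truth$rbc_mask), 0)
  expect_equal(sum(f$truth$dab_mask), 0)

  # determinism
  g1 <- generate_he_field(small_he_params(), seed = 11)
  g2 <- generate_he_field(small_he_params(), seed = 11)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$truth$droplet_list, g2$truth$droplet_list)

  # impossible packing errors out naming the crowding
  expect_error(generate_he_field(scene_params(width = 64, height = 64,
                                              n_droplets = 200,
                                              droplet_radius = c(10, 12)),
                                 seed = 1),
               "too crowded")
})

test_that("IHC generator hits the target DAB fraction and its invariants", {
  # target 0 -> empty; target 1 -> dab equals tissue
  f0 <- generate_ihc_field(small_ihc_params(0), seed = 2)
  expect_equal(sum(f0$truth$dab_mask), 0)
  f1 <- generate_ihc_field(small_ihc_params(1), seed = 2)
  expect_identical(f1$truth$dab_mask, f1$truth$tissue_mask)

  # target 0.361 on a 512x512 field: realized fraction within +/- 0.5 pp
  f <- generate_ihc_field(scene_params(512, 512, target_dab_fraction = 0.361),
                          seed = 7)
  expect_gte(f$truth$true_dab_fraction, 0.356)
  expect_lte(f$truth$true_dab_fraction, 0.366)

  # dab_mask is a subset of tissue_mask
  expect_equal(sum(f$truth$dab_mask & !f$truth$tissue_mask), 0)

  # determinism
  h1 <- generate_ihc_field(small_ihc_params(0.25), seed = 9)
  h2 <- generate_ihc_field(small_ihc_params(0.25), seed = 9)
  expect_identical(h1$image, h2$image)
  expect_identical(h1$truth$dab_mask, h2$truth$dab_mask)
})

test_that("group sets are written completely and reproducibly", {
  spec <- list(a = small_ihc_params(0.20), b = small_ihc_params(0.40))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gt1 <- generate_group_set(spec, n_fields = 3, base_seed = 21, out_dir = d1)
  gt2 <- generate_group_set(spec, n_fields = 3, base_seed = 21, out_dir = d2)

  expect_equal(nrow(gt1), 6)
  expect_equal(length(list.files(d1, pattern = "\\.tif$")), 6)
  expect_true(file.exists(file.path(d1, "ground_truth.csv")))

  # same base seed -> byte-identical images
  for (f in gt1$file) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }

  # per-group mean of realized fractions matches the configured targets
  m <- tapply(gt1$true_dab_fraction, gt1$group, mean)
  expect_lt(abs(m[["a"]] - 0.20), 0.005)
  expect_lt(abs(m[["b"]] - 0.40), 0.005)
})
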