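anova_fixture <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                            value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  # SSB = 6, MSB = 3, SSW = 6, MSW = 1 -> F = 3 on (2, 6)
  a <- one_way_anova(anova_fixture)
  expect_equal(a$F, 3)
  expect_equal(unname(a$df), c(2, 6))
  expect_equal(a$p, pf(3, 2, 6, lower.tail = FALSE))

  # order invariance
  perm <- anova_fixture[sample(nrow(anova_fixture)), ]
  expect_equal(one_way_anova(perm)$F, 3)

  # two groups with the same value sets: equal means -> F = 0, p = 1
  d0 <- data.frame(group = rep(c("a", "b"), each = 3), value = rep(1:3, 2))
  a0 <- one_way_anova(d0)
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  # agreement with the base-R fit on an irregular unbalanced fixture
  set.seed(31)
  d <- data.frame(group = rep(c("x", "y", "z"), times = c(4, 6, 5)),
                  value = rnorm(15, rep(c(0, 1, 3), times = c(4, 6, 5))))
  a2 <- one_way_anova(d)
  ref <- summary(stats::aov(value ~ group, data = d))[[1]]
  expect_equal(a2$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(a2$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # degenerate and error cases
  dg <- data.frame(group = rep(c("a", "b"), each = 2), value = c(1, 1, 2, 2))
  ad <- one_way_anova(dg)
  expect_true(ad$degenerate)
  expect_equal(ad$F, Inf)
  expect_equal(ad$p, 0)
  expect_error(one_way_anova(data.frame(group = c("a", "a", "b", "b"),
                                        value = rep(5, 4))), "no variance")
  expect_error(one_way_anova(data.frame(group = "a", value = 1:3)), "2 groups")
})

test_that("ANOVA F equals the two-sample t^2 when k = 2", {
  set.seed(7)
  d <- data.frame(group = rep(c("a", "b"), each = 8), value = rnorm(16, rep(c(0, 1), each = 8)))
  a <- one_way_anova(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  # and the Tukey pair p equals the t-test p via q = |t| * sqrt(2)
  tk <- tukey_hsd(d)
  expect_equal(tk$q, abs(unname(tt$statistic)) * sqrt(2), tolerance = 1e-10)
  # ptukey is numerically integrated; agreement to ~1e-6 is its precision
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey HSD agrees with stats::TukeyHSD and is scale invariant", {
  set.seed(12)
  d <- data.frame(group = rep(c("a", "b", "c", "d"), each = 5),
                  value = rnorm(20, rep(c(0, 0.5, 1, 3), each = 5)))
  tk <- tukey_hsd(d)
  ref <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)

  # all group means equal -> every adjusted p = 1
  d0 <- data.frame(group = rep(c("a", "b", "c"), each = 3), value = rep(1:3, 3))
  expect_true(all(abs(tukey_hsd(d0)$p_adj - 1) < 1e-6))

  # doubling values (a unit change) leaves q and p unchanged
  d2 <- d; d2$value <- d$value * 2
  tk2 <- tukey_hsd(d2)
  expect_equal(tk2$q, tk$q, tolerance = 1e-10)
  expect_equal(tk2$p_adj, tk$p_adj, tolerance = 1e-10)
  expect_equal(tk2$diff, tk$diff * 2, tolerance = 1e-10)

  # unbalanced groups use the Tukey-Kramer standard error
  du <- data.frame(group = rep(c("a", "b"), times = c(3, 6)),
                   value = c(1, 2, 3, 4, 5, 6, 5, 4, 6))
  tku <- tukey_hsd(du)
  msw <- attr(tku, "anova")$ms_within
  expect_equal(tku$se, sqrt(msw * (1 / 3 + 1 / 6) / 2), tolerance = 1e-12)
})

test_that("metric panels are compared per metric with failures skipped", {
  set.seed(5)
  d <- data.frame(group = rep(c("SD", "LKE", "HKE"), each = 10),
                  globulin = rnorm(30, rep(c(3.1, 2.8, 2.4), each = 10), 0.15),
                  creatinine = rnorm(30, rep(c(0.45, 0.62, 0.64), each = 10), 0.05),
                  flat = rep(1, 30))
  res <- compare_all_metrics(d, c("globulin", "creatinine", "flat", "absent"))
  expect_equal(sort(unique(res$metric)), c("creatinine", "globulin"))
  expect_equal(nrow(res), 2 * choose(3, 2))
  expect_setequal(attr(res, "skipped"), c("flat", "absent"))

  # a 5-SD group shift at n = 10 is flagged significant
  shift <- res[res$metric == "globulin" & res$group_a == "HKE" &
               res$group_b == "SD", ]
  expect_true(shift$significant)

  # empty metric list -> empty result, no error
  e <- compare_all_metrics(d, character(0))
  expect_equal(nrow(e), 0)
})

test_that("a full blood-chemistry panel yields one row per metric per pair", {
  biomarkers <- c("glucose", "albumin", "globulin", "creatinine", "BUN", "ALT",
                  "ALP", "bilirubin", "sodium", "potassium", "chloride")
  set.seed(77)
  d <- data.frame(group = rep(c("SD", "LKE", "HKE"), each = 10))
  for (b in biomarkers) d[[b]] <- rnorm(30, 10, 2)
  res <- compare_all_metrics(d, biomarkers)
  expect_equal(nrow(res), length(biomarkers) * choose(3, 2))
  expect_equal(length(attr(res, "skipped")), 0)
})
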