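test_that("area histograms count half-open bins with a sub-threshold tally", {
  h <- histogram_areas(records_from_areas(c(0.5, 1.5, 1.7, 2.5)), 1:5)
  expect_equal(h$counts, c(2L, 1L, 0L, 0L, 0L))
  expect_equal(h$sub_threshold, 1L)
  expect_equal(h$total_count, 3L)
  h0 <- histogram_areas(records_from_areas(numeric(0)), 1:5)
  expect_true(all(h0$counts == 0))
  expect_error(histogram_areas(records_from_areas(1), c(2, 2, 3)),
               "increasing")
  # edge cases: values on edges fall in the right-hand bin; open last bin
  h2 <- histogram_areas(records_from_areas(c(1, 2, 5, 100)), 1:5)
  expect_equal(h2$counts, c(1L, 1L, 0L, 0L, 2L))
})

test_that("histogram counts match analytic log-normal bin probabilities", {
  set.seed(42)
  n <- 1000; mu <- log(2); s <- 0.5
  areas <- rlnorm(n, mu, s)
  h <- histogram_areas(records_from_areas(areas), 1:5)
  edges <- c(1:5, Inf)
  for (i in 1:5) {
    p <- plnorm(edges[i + 1], mu, s) - plnorm(edges[i], mu, s)
    expect_lt(abs(h$counts[i] - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("only accepted records are counted", {
  recs <- data.frame(area_um2 = c(1.5, 1.6, 2.5),
                     accepted = c(TRUE, FALSE, TRUE))
  h <- histogram_areas(recs, 1:5)
  expect_equal(h$counts, c(1L, 1L, 0L, 0L, 0L))
})

test_that("ROI mean intensity is the arithmetic mean over ROI pixels", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 10; m[2, 2] <- 20; m[3, 3] <- 30
  roi <- matrix(FALSE, 4, 4); roi[cbind(1:3, 1:3)] <- TRUE
  expect_equal(mean_intensity(new_plane(m, 1), roi), 20)
  expect_equal(mean_intensity(new_plane(matrix(7.5, 9, 9), 1)), 7.5)
  expect_error(mean_intensity(new_plane(m, 1), matrix(FALSE, 4, 4)), "empty")
})

test_that("zero-noise field mean equals background plus object flux", {
  spec <- clean_spec(seed = 19)
  f <- generate_plane(spec)
  lm <- f$truth$label_map; nuc <- f$truth$nucleus_mask
  analytic <- spec$background_level +
    (sum(nuc) * spec$nucleus_intensity +
       sum(lm > 0) * spec$condensate_peak_intensity) / length(lm)
  expect_equal(mean_intensity(f$plane), analytic, tolerance = 1e-6)
})

test_that("pooled t matches the hand formula and quadrature of the density", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  # hand computation: mean diff -3, pooled sd 1, se sqrt(2/3)
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0213, tolerance = 1e-2)
  # identical groups
  t0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  # reported p equals 2 * upper-tail quadrature of the t density
  q <- 2 * integrate(function(x) dt(x, tt$df), abs(tt$t), Inf)$value
  expect_equal(tt$p, q, tolerance = 1e-8)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})

test_that("Welch option reproduces the unequal-variance test", {
  a <- c(1, 2, 3, 8); b <- c(4, 5, 6)
  got <- two_sample_t(a, b, welch = TRUE)
  ref <- t.test(a, b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
})

test_that("Holm-Sidak adjustment matches its step-down definition", {
  expect_equal(holm_sidak_adjust(0.03), 0.03)
  got <- holm_sidak_adjust(c(0.01, 0.02, 0.20))
  expect_equal(got, c(1 - (1 - 0.01)^3, 1 - (1 - 0.02)^2, 0.20),
               tolerance = 1e-12)
  expect_equal(round(got, 6), c(0.029701, 0.039600, 0.200000))
  expect_equal(holm_sidak_adjust(rep(0.04, 5)), rep(1 - 0.96^5, 5))
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Holm-Sidak is order-invariant, monotone, and never below raw", {
  set.seed(3)
  for (m in c(2, 5, 20)) {
    p <- runif(m)
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p))
    perm <- sample(m)
    expect_equal(holm_sidak_adjust(p[perm]), adj[perm])
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("group comparison tests subject-level counts per bin", {
  mk <- function(areas, subject, group) {
    histogram_areas(records_from_areas(areas), 1:5,
                    subject_id = subject, group = group)
  }
  ha <- lapply(1:3, function(i) mk(c(1.5, 2.5, 3.5), paste0("a", i), "WT"))
  hb <- lapply(1:3, function(i) mk(c(1.5, 2.5, 3.5), paste0("b", i), "cKO"))
  cmp <- compare_groups(c(ha, hb))
  expect_true(all(cmp$per_bin$t == 0))
  expect_true(all(cmp$per_bin$p_adj == 1))
  expect_equal(cmp$total$t, 0)
  expect_equal(cmp$n_per_group, c(3L, 3L))
  expect_true(all(cmp$per_bin$p_adj >= cmp$per_bin$p_raw))
  # count conservation from histograms into the comparison means
  expect_equal(sum(cmp$per_bin$mean_a), cmp$total$mean_a)
  expect_error(compare_groups(ha), "two group")
  expect_error(compare_groups(c(ha[1], hb[1], ha[2], hb[2])[1:3]))
})

test_that("a shifted group is detected in the expected bins", {
  set.seed(11)
  mk <- function(n_obj, mu, subject, group) {
    histogram_areas(records_from_areas(rlnorm(n_obj, mu, 0.5)), 1:5,
                    subject_id = subject, group = group)
  }
  ha <- lapply(1:12, function(i) mk(rpois(1, 50), log(2), paste0("a", i), "WT"))
  hb <- lapply(1:12, function(i) mk(rpois(1, 70), log(2) * 0.7,
                                    paste0("b", i), "cKO"))
  cmp <- compare_groups(c(ha, hb))
  expect_lt(cmp$per_bin$p_adj[1], 0.05)   # [1,2) bin gains condensates
  expect_lt(cmp$total$p, 0.05)
  expect_gt(cmp$total$mean_b, cmp$total$mean_a)
})
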