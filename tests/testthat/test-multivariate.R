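toy_metrics <- function() {
  set.seed(42)
  data.frame(specimen = paste0("sp", 1:8),
             BV = rnorm(8, 10), TV = rnorm(8, 20),
             Rmin = c(rnorm(4, 0.05, 0.02), rnorm(4, 0.6, 0.05)),
             Cg = runif(8, 0.5, 0.9))
}

test_that("feature assembly joins, drops sparse columns, imputes with flags", {
  m1 <- toy_metrics()
  m2 <- data.frame(specimen = paste0("sp", 1:8), Ani.M = runif(8, 0.2, 0.8))
  grp <- setNames(rep(c("terrestrial", "aquatic"), each = 4), m1$specimen)
  ft <- assemble_features(list(m1, m2), grp)
  expect_equal(nrow(ft$data), 8L)
  expect_true("Ani.M" %in% names(ft$data))
  # a column missing for most specimens is dropped with a warning
  m3 <- m2; m3$mostly_na <- c(1, rep(NA, 7))
  expect_warning(ft2 <- assemble_features(list(m1, m3), grp), "missing")
  expect_false("mostly_na" %in% names(ft2$data))
  # one missing cell: column-mean imputation, flagged
  m4 <- m1; m4$BV[3] <- NA
  ft3 <- assemble_features(list(m4), grp)
  expect_equal(ft3$data$BV[3], mean(m1$BV[-3]))
  expect_true(ft3$imputed[3, "BV"])
  # duplicate identifiers error
  dup <- rbind(m1, m1[1, ])
  expect_error(assemble_features(list(dup), grp), "[Dd]uplicate")
})

test_that("correlation PCA: trace, rank-1 case, sign convention, scores", {
  ft <- assemble_features(list(toy_metrics()),
                          setNames(rep(c("terrestrial", "aquatic"), each = 4),
                                   paste0("sp", 1:8)))
  p <- pca_correlation(ft)
  expect_equal(sum(p$eigenvalues), ncol(ft$data), tolerance = 1e-9)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
  # loadings orthonormal, scores centred, data reconstructed exactly
  expect_equal(crossprod(p$loadings), diag(ncol(ft$data)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(p$scores))), 1e-9)
  z <- scale(as.matrix(ft$data))
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(z[, ]),
               tolerance = 1e-9)
  # sign convention: dominant loading of each component is positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # two perfectly correlated variables: PC1 explains everything
  two <- data.frame(a = 1:6, b = 2 * (1:6) + 3)
  p2 <- pca_correlation(two)
  expect_equal(p2$explained_variance[1], 1, tolerance = 1e-9)
  # zero-variance columns are dropped with a warning
  expect_warning(pca_correlation(data.frame(a = 1:5, b = 5:1, c = rep(1, 5))),
                 "zero-variance")
  # affine rescaling of raw columns leaves the correlation PCA unchanged
  resc <- as.data.frame(ft$data)
  resc$BV <- 100 * resc$BV - 7
  p3 <- pca_correlation(resc)
  expect_equal(abs(p3$scores), abs(p$scores), tolerance = 1e-8)
})

test_that("planted group separation appears on PC1", {
  set.seed(13)
  n <- 10
  grp <- rep(c("terrestrial", "aquatic"), each = n)
  sep <- c(rnorm(n, -3), rnorm(n, 3))
  tab <- data.frame(specimen = paste0("s", 1:(2 * n)),
                    v1 = sep + rnorm(2 * n, 0, 0.3),
                    v2 = sep + rnorm(2 * n, 0, 0.3),
                    v3 = rnorm(2 * n))
  ft <- assemble_features(list(tab), setNames(grp, tab$specimen))
  p <- pca_correlation(ft)
  s1 <- p$scores[grp == "terrestrial", 1]
  s2 <- p$scores[grp == "aquatic", 1]
  pooled <- sqrt((var(s1) + var(s2)) / 2)
  expect_gt(abs(mean(s1) - mean(s2)), 2 * pooled)
})

test_that("group overlap reports axis-range intersections", {
  scores <- rbind(matrix(c(0, 0, 1, 1, 0.5, 0.5), 3, 2),      # A
                  matrix(c(0.8, 1.8, 0.9, 2.0, 1.0, 2.2), 3, 2),  # B overlaps A
                  matrix(c(5, 6, 5.5, 5, 6, 5.5), 3, 2))      # C separate
  res <- structure(list(scores = scores,
                        group = rep(c("A", "B", "C"), each = 3)),
                   class = "pca_result")
  ov <- group_overlap(res, axes = c(1, 2))
  get <- function(a, b) ov[ov$group_a == a & ov$group_b == b |
                             ov$group_a == b & ov$group_b == a, ]
  expect_true(get("A", "B")$overlap_both)
  expect_false(get("A", "C")$overlap_both)
  expect_false(get("B", "C")$overlap_both)
  # identical groups overlap; singletons are flagged
  res2 <- structure(list(scores = scores[c(1:3, 1:3, 7), ],
                         group = c(rep("A", 3), rep("B", 3), "C")),
                    class = "pca_result")
  ov2 <- group_overlap(res2, axes = c(1, 2))
  expect_true(ov2[ov2$group_a == "A" & ov2$group_b == "B", "overlap_both"])
  expect_true(any(ov2$singleton_b[ov2$group_b == "C"]))
})
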