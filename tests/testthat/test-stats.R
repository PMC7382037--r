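test_that("Pearson screen matches the reference implementation", {
  set.seed(7)
  m <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  m$d <- 2 * m$a + rnorm(30, sd = 0.3)
  out <- pearson_screen(m)
  for (i in seq_len(nrow(out))) {
    ref <- stats::cor.test(m[[out$feature_a[i]]], m[[out$feature_b[i]]])
    expect_equal(out$r[i], unname(ref$estimate), tolerance = 1e-8)
    expect_equal(out$p[i], ref$p.value, tolerance = 1e-8)
  }
  # perfect correlation
  perf <- pearson_screen(data.frame(x = 1:10, y = 2 * (1:10)))
  expect_equal(perf$r, 1, tolerance = 1e-12)
  expect_lt(perf$p, 1e-12)
  # zero-variance feature reported as NA, not an error
  zv <- pearson_screen(data.frame(x = 1:10, y = rep(1, 10)))
  expect_true(is.na(zv$r))
  # affine invariance (sign follows slope)
  m2 <- data.frame(x = rnorm(20)); m2$y <- rnorm(20)
  r1 <- pearson_screen(m2)$r
  m3 <- data.frame(x = 5 - 3 * m2$x, y = m2$y)
  expect_equal(pearson_screen(m3)$r, -r1, tolerance = 1e-12)
})

test_that("group t test matches stats::t.test in both variance modes", {
  set.seed(11)
  m <- data.frame(v = c(rnorm(8, 1), rnorm(20)))
  ph <- rep(c("Bacteroidota", "other"), c(8, 20))
  res <- group_t_test(m, "v", ph, "Bacteroidota")
  ref <- stats::t.test(m$v[ph == "Bacteroidota"], m$v[ph != "Bacteroidota"],
                       var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  resw <- group_t_test(m, "v", ph, "Bacteroidota", welch = TRUE)
  refw <- stats::t.test(m$v[ph == "Bacteroidota"], m$v[ph != "Bacteroidota"])
  expect_equal(resw$p, refw$p.value, tolerance = 1e-8)

  # identical groups: p about 1
  m0 <- data.frame(v = rep(c(1, 2, 1, 2), 4))
  expect_gt(group_t_test(m0, "v", rep(c("g", "g", "r", "r"), 4), "g")$p,
            0.99)
  # one-row group violates the precondition
  expect_error(group_t_test(m, "v", rep(c("g", "r"), c(1, 27)), "g"),
               "at least two")
})

test_that("planted group effects are detected with adequate power", {
  # delta = 3 SD, n = 20 vs 100: significant in nearly every replicate
  set.seed(33)
  hits <- vapply(1:100, function(i) {
    m <- data.frame(v = c(rnorm(20, 3), rnorm(100)))
    group_t_test(m, "v", rep(c("g", "r"), c(20, 100)), "g")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null simulations show the nominal type-I error rate", {
  set.seed(55)
  p_t <- vapply(1:400, function(i) {
    m <- data.frame(v = rnorm(40))
    group_t_test(m, "v", rep(c("g", "r"), 20), "g")$p
  }, numeric(1))
  expect_gt(mean(p_t < 0.05), 0.02)
  expect_lt(mean(p_t < 0.05), 0.09)
  # permutation-style null for the correlation p-values: roughly uniform
  p_r <- vapply(1:400, function(i) {
    pearson_screen(data.frame(x = rnorm(15), y = rnorm(15)))$p
  }, numeric(1))
  expect_gt(mean(p_r < 0.05), 0.02)
  expect_lt(mean(p_r < 0.05), 0.09)
  expect_true(all(p_r >= 0 & p_r <= 1))
})

test_that("PCA ordination matches a direct eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  res <- pca_ordinate(x, scale. = TRUE)
  xs <- scale(x, center = TRUE, scale = TRUE)
  ei <- eigen(stats::cov(xs), symmetric = TRUE)
  scores <- xs %*% ei$vectors
  for (j in 1:2) {
    k <- which.max(abs(ei$vectors[, j]))
    if (ei$vectors[k, j] < 0) scores[, j] <- -scores[, j]
  }
  expect_equal(unname(res$scores), unname(scores[, 1:2]), tolerance = 1e-8)
  expect_equal(res$var_explained, ei$values / sum(ei$values),
               tolerance = 1e-8)

  # row-order invariance under the fixed sign convention
  perm <- sample(10)
  res2 <- pca_ordinate(x[perm, ], scale. = TRUE)
  expect_equal(unname(res2$scores), unname(res$scores[perm, ]),
               tolerance = 1e-8)

  # two perfectly correlated features: PC1 explains everything
  y <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  resy <- pca_ordinate(y, scale. = TRUE)
  expect_equal(resy$var_explained[1], 1, tolerance = 1e-12)

  # normal-theory ellipses returned per phylum with >= 3 rows
  ph <- rep(c("A", "B"), 5)
  rese <- pca_ordinate(x, phylum_col = ph)
  expect_named(rese$ellipses, c("A", "B"))
  expect_length(rese$ellipses$A$radii, 2)
})

test_that("planted niche structure separates in ordination space", {
  com <- generate_community(community_spec(seed = 7))
  res <- suppressWarnings(suppressMessages(run_all(com)))
  scores <- res$stats$pca$scores
  cl <- res$capacity$cluster$cluster_id
  hydro <- cl %in% c("hyd1", "hyd2", "ht", "residual")
  syntroph <- cl %in% c("syn_fo", "syn_o2", "diet")
  s1 <- scores[, 1]
  # silhouette-style check on PC1: groups are internally closer than
  # they are to each other
  intra <- mean(stats::dist(s1[hydro])) + mean(stats::dist(s1[syntroph]))
  inter <- abs(mean(s1[hydro]) - mean(s1[syntroph]))
  expect_gt(inter, intra / 2)
})

test_that("function frequency screen flags exclusive functions only", {
  pres <- cbind(everywhere = rep(1, 12),
                exclusive = rep(c(1, 0), c(5, 7)),
                noise = rep(c(1, 0, 1, 0), 3))
  group <- rep(c(TRUE, FALSE), c(5, 7))
  out <- function_frequency_screen(pres, group)
  expect_false(out$enriched[out$fn == "everywhere"])
  expect_true(out$enriched[out$fn == "exclusive"])
  outf <- function_frequency_screen(pres, group, method = "fisher")
  expect_true(outf$enriched[outf$fn == "exclusive"])

  # i.i.d. Bernoulli null: about 5% false positives
  set.seed(77)
  null_mat <- matrix(rbinom(24 * 300, 1, 0.5), 24, 300,
                     dimnames = list(NULL, paste0("fn", 1:300)))
  g0 <- rep(c(TRUE, FALSE), 12)
  out0 <- function_frequency_screen(null_mat, g0)
  fp <- mean(out0$p < 0.05, na.rm = TRUE)
  expect_gt(fp, 0.015)
  expect_lt(fp, 0.10)
})
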