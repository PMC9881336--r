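blobs_7d <- function(centers_sd, n_each = 15, seed = 1) {
  set.seed(seed)
  k <- nrow(centers_sd)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_each * 7, mean = rep(centers_sd[i, ], each = n_each)),
           n_each, 7)
  }))
  colnames(x) <- METRIC_COLUMNS
  x
}

test_that("z-scoring matches the sample-sd convention and is idempotent", {
  tab <- tibble::tibble(sla = c(1, 2, 3), dlsta = c(2, 2.5, 3))
  out <- zscore_scale(tab, c("sla", "dlsta"))
  expect_equal(out$scaled$sla, c(-1, 0, 1))
  expect_equal(out$params$mean, c(2, 2.5))
  again <- zscore_scale(out$scaled, c("sla", "dlsta"))
  expect_equal(again$scaled$sla, out$scaled$sla, tolerance = 1e-12)
  expect_error(zscore_scale(tibble::tibble(sla = c(1, 1, 1))), "zero-variance")
  expect_error(zscore_scale(tibble::tibble(sla = c(1, NA, 3))), "missing")
})

test_that("silhouette selection finds the constructed number of blobs", {
  two <- blobs_7d(rbind(rep(0, 7), rep(6 / sqrt(7), 7)), seed = 21)
  sel2 <- select_k_silhouette(two, k_range = 2:6, seed = 1)
  expect_equal(sel2$chosen_k, 2)
  three <- blobs_7d(rbind(rep(0, 7), rep(6 / sqrt(7), 7),
                          c(rep(6 / sqrt(7), 3), rep(-6 / sqrt(7), 4))), seed = 22)
  sel3 <- select_k_silhouette(three, k_range = 2:6, seed = 1)
  expect_equal(sel3$chosen_k, 3)
})

test_that("k-means separates distant pairs, is deterministic, and rejects degenerate input", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  fit <- kmeans_fit(x, 2, seed = 3)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_true(fit$labels[1] != fit$labels[3])

  y <- matrix(stats::rnorm(40 * 3), 40, 3)
  f1 <- kmeans_fit(y, 3, seed = 9)
  f2 <- kmeans_fit(y, 3, seed = 9)
  expect_identical(f1$labels, f2$labels)

  dup <- matrix(1, 5, 2)
  expect_error(kmeans_fit(dup, 2, seed = 1), "empty")
})

test_that("cluster labels are canonicalized by decreasing size", {
  x <- rbind(matrix(stats::rnorm(30 * 2, 0, 0.2), 30, 2),
             matrix(stats::rnorm(10 * 2, 8, 0.2), 10, 2))
  fit <- kmeans_fit(x, 2, seed = 5)
  expect_equal(unname(fit$labels[1]), 1)   # bigger cluster labelled 1
  expect_equal(unname(fit$labels[40]), 2)
})

test_that("the sum-of-squares decomposition matches the toy configuration and the identity", {
  x <- rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2))
  ss <- cluster_ss(x, c(1, 1, 2, 2))
  expect_equal(ss$wss_total, 4)
  expect_equal(unname(ss$wss), c(2, 2))
  expect_equal(ss$bss, 16)
  expect_equal(ss$tss, ss$wss_total + ss$bss)

  # singleton clusters have zero within sum of squares
  one <- cluster_ss(x, 1:4)
  expect_equal(unname(one$wss), rep(0, 4))

  set.seed(31)
  r <- matrix(stats::rnorm(60 * 5), 60, 5)
  lab <- kmeans_fit(r, 4, seed = 2)$labels
  ssr <- cluster_ss(r, lab)
  expect_equal(ssr$wss_total + ssr$bss, ssr$tss, tolerance = 1e-8)
})

test_that("permutation importance singles out the informative metric", {
  set.seed(41)
  n <- 60
  x <- matrix(stats::rnorm(n * 7), n, 7)
  colnames(x) <- METRIC_COLUMNS
  labels <- ifelse(x[, 1] > 0, 1, 2)
  x[, 1] <- x[, 1] + ifelse(labels == 1, 1.5, -1.5)
  imp <- rf_importance(x, labels, n_trees = 300, seed = 7)
  expect_equal(imp$metric[1], "sla")
  noise <- imp$importance[imp$metric != "sla"]
  expect_true(all(abs(noise) <= 0.02))
  expect_error(rf_importance(x, rep(1, n)), "2 clusters")
})

test_that("correlated informative clones share positive importance", {
  set.seed(43)
  n <- 80
  base <- stats::rnorm(n)
  labels <- ifelse(base + stats::rnorm(n, 0, 0.3) > 0, 1, 2)
  x <- cbind(base, base + stats::rnorm(n, 0, 0.05),
             matrix(stats::rnorm(n * 5), n, 5))
  colnames(x) <- METRIC_COLUMNS
  imp <- rf_importance(x, labels, n_trees = 300, seed = 7)
  expect_gt(imp$importance[imp$metric == "sla"], 0.01)
  expect_gt(imp$importance[imp$metric == "dlsta"], 0.01)
})

test_that("PCA projection explains all variance for one-directional data", {
  set.seed(51)
  dir <- stats::rnorm(7); dir <- dir / sqrt(sum(dir^2))
  x <- outer(stats::rnorm(25), dir)
  colnames(x) <- METRIC_COLUMNS
  p <- pca_project(x)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-10)
  # loadings are orthonormal (isometry of the projection)
  expect_equal(t(p$loadings) %*% p$loadings, diag(7), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
})

test_that("condition comparison counts switchers through centroid matching", {
  m <- tibble::tibble(participant_id = sprintf("P%02d", 1:20))
  set.seed(61)
  base <- rbind(matrix(stats::rnorm(10 * 7, 0, 0.4), 10, 7),
                matrix(stats::rnorm(10 * 7, 3, 0.4), 10, 7))
  colnames(base) <- METRIC_COLUMNS
  ma <- dplyr::bind_cols(m, tibble::as_tibble(base))
  ca <- cluster_gait(ma, k = 2, seed = 1, n_trees = 50)
  cb <- cluster_gait(ma, k = 2, seed = 99, n_trees = 50)
  cmp_same <- compare_conditions(ca, cb)
  expect_equal(cmp_same$n_switched, 0)

  # move exactly one participant across the boundary in condition B
  shifted <- base
  shifted[3, ] <- shifted[3, ] + 3
  mb <- dplyr::bind_cols(m, tibble::as_tibble(shifted))
  cb2 <- cluster_gait(mb, k = 2, seed = 2, n_trees = 50)
  cmp <- compare_conditions(ca, cb2)
  expect_equal(cmp$n_switched, 1)
  expect_equal(cmp$switchers, "P03")
})

test_that("clinical contrasts reproduce the exact Mann-Whitney enumeration", {
  meta <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6), group = "stroke",
    le_fugl_meyer = 1:6
  )
  labels <- stats::setNames(c(1, 1, 1, 2, 2, 2), meta$participant_id)
  out <- clinical_contrast(labels, meta)
  expect_equal(out$u, 0)
  expect_equal(out$p_value, 0.1)
  expect_true(out$exact)

  sym <- tibble::tibble(participant_id = sprintf("P%d", 1:4), group = "stroke",
                        le_fugl_meyer = c(1, 4, 2, 3))
  lab2 <- stats::setNames(c(1, 1, 2, 2), sym$participant_id)
  out2 <- clinical_contrast(lab2, sym)
  expect_equal(out2$p_value, 1)
  expect_error(clinical_contrast(lab2, dplyr::mutate(sym, le_fugl_meyer = 5)),
               "identical")
})

test_that("the authored adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(71)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- a
    flip <- sample(40, 8)
    b[flip] <- sample(1:3, 8, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("the full clustering pipeline is deterministic and excludes incomplete rows", {
  coh <- cohort_metrics(generate_cohort(c(stroke = 8, neurotypical = 8),
                                        profiles = contrast_profiles(), seed = 13))
  ss <- dplyr::filter(coh, speed_condition == "self_selected")
  ss$hip_hike_deg[ss$participant_id == "N02"] <- NA
  a <- cluster_gait(ss, seed = 5, n_trees = 100)
  b <- cluster_gait(ss, seed = 5, n_trees = 100)
  expect_identical(tidy(a), tidy(b))
  expect_equal(a$excluded, "N02")
  expect_false("N02" %in% names(a$labels))
  # row order does not change the statistics
  c2 <- cluster_gait(ss[sample(nrow(ss)), ], seed = 5, n_trees = 100)
  expect_equal(glance(c2)$bss, glance(a)$bss, tolerance = 1e-9)
  expect_equal(sort(names(a$labels)), sort(names(c2$labels)))
})

test_that("plot builders return ggplot objects", {
  coh <- cohort_metrics(generate_cohort(c(stroke = 6, neurotypical = 6),
                                        profiles = contrast_profiles(), seed = 19))
  expect_s3_class(plot_metric_speed(coh, "sla"), "ggplot")
  ss <- dplyr::filter(coh, speed_condition == "self_selected")
  cl <- cluster_gait(ss, k = 2, seed = 4, n_trees = 50)
  expect_s3_class(autoplot(cl), "ggplot")
  expect_s3_class(plot_importance(cl), "ggplot")
})
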