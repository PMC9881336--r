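#' Z-score scale a metrics matrix
#'
#' Scales each metric column to mean 0, sample standard deviation 1
#' (n - 1 denominator), as required before distance-based clustering of
#' metrics with heterogeneous units. Scaling is done independently within
#' each speed condition by the pipeline. Participants with any missing
#' metric must be excluded beforehand.
#'
#' @param table Tibble or data frame whose `columns` are the metrics; other
#'   columns are carried through unchanged.
#' @param columns Metric columns to scale (default the standard seven).
#' @return List with `scaled` (the table with scaled metric columns) and
#'   `params` (tibble of per-metric `mean` and `sd`).
#' @export
zscore_scale <- function(table, columns = METRIC_COLUMNS) {
  columns <- intersect(columns, names(table))
  if (nrow(table) < 2) stop("need at least 2 rows to scale")
  if (any(is.na(table[, columns]))) {
    stop("missing metric values: exclude incomplete participants before scaling")
  }
  params <- purrr::map_dfr(columns, function(cl) {
    v <- table[[cl]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", cl)
    tibble::tibble(metric = cl, mean = mean(v), sd = s)
  })
  scaled <- table
  for (i in seq_along(columns)) {
    scaled[[columns[i]]] <- (table[[columns[i]]] - params$mean[i]) / params$sd[i]
  }
  list(scaled = scaled, params = params)
}

# numeric matrix of the metric columns
metric_matrix <- function(table, columns = METRIC_COLUMNS) {
  columns <- intersect(columns, names(table))
  as.matrix(table[, columns])
}

#' k-means with k-means++ initialization and restarts
#'
#' Lloyd's algorithm seeded with k-means++ starts, best of `n_init`
#' restarts by total within-cluster sum of squares; deterministic for a
#' given seed. Cluster labels are canonicalized by decreasing cluster size
#' (ties broken by the first principal coordinate of the centroid).
#'
#' @param x Numeric matrix (rows = participants, columns = scaled metrics)
#'   or a table containing the metric columns.
#' @param k Number of clusters (`k < nrow(x)`).
#' @param seed Integer seed.
#' @param n_init Number of restarts.
#' @return List with `labels` (integer vector), `centroids` (k x p matrix)
#'   and `tot_withinss`.
#' @export
kmeans_fit <- function(x, k, seed = 1, n_init = 25) {
  x <- metric_matrix_or_matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of rows")
  if (nrow(unique(x)) < k) {
    stop("fewer than k distinct points: k-means would produce empty clusters")
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_init(x, k)
    km <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) best <- km
  }
  if (is.null(best)) stop("k-means failed to produce a valid clustering")
  canonicalize_clusters(best$cluster, best$centers, best$tot.withinss)
}

metric_matrix_or_matrix <- function(x) {
  if (is.matrix(x)) x else metric_matrix(x)
}

# k-means++ seeding (squared-distance-proportional sampling)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
    nd <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

canonicalize_clusters <- function(labels, centers, tot_withinss) {
  sizes <- tabulate(labels, nbins = nrow(centers))
  ord <- order(-sizes, centers[, 1])
  relabel <- match(seq_len(nrow(centers)), ord)
  list(labels = relabel[labels], centroids = centers[ord, , drop = FALSE],
       tot_withinss = tot_withinss)
}

#' Within/between sum-of-squares decomposition of a clustering
#'
#' `WSS_c` is the summed squared distance of each member to its centroid
#' (between-subjects variability within the cluster); `BSS` is the
#' size-weighted squared distance of the centroids from the grand mean
#' (distance between clusters). `sum(WSS) + BSS` equals the total sum of
#' squares about the grand mean.
#'
#' @param x Matrix or metrics table in the space the clustering was run in.
#' @param labels Integer cluster labels.
#' @return List with `wss` (per cluster), `wss_total`, `bss`, `tss`.
#' @export
cluster_ss <- function(x, labels) {
  x <- metric_matrix_or_matrix(x)
  stopifnot(nrow(x) == length(labels))
  if (any(tabulate(labels, nbins = max(labels)) == 0)) {
    stop("every cluster must be nonempty")
  }
  grand <- colMeans(x)
  ks <- sort(unique(labels))
  wss <- vapply(ks, function(k) {
    xi <- x[labels == k, , drop = FALSE]
    ctr <- colMeans(xi)
    sum(sweep(xi, 2, ctr)^2)
  }, numeric(1))
  bss <- sum(vapply(ks, function(k) {
    xi <- x[labels == k, , drop = FALSE]
    nrow(xi) * sum((colMeans(xi) - grand)^2)
  }, numeric(1)))
  list(wss = stats::setNames(wss, ks), wss_total = sum(wss), bss = bss,
       tss = sum(sweep(x, 2, grand)^2))
}

#' Choose the number of clusters by the silhouette method
#'
#' Runs [kmeans_fit()] for each candidate k and computes the mean
#' silhouette width (Euclidean distance); the chosen k maximizes it, ties
#' broken toward the smaller k.
#'
#' @param x Scaled metrics matrix or table.
#' @param k_range Candidate numbers of clusters.
#' @param seed Integer seed.
#' @param n_init Restarts per k.
#' @return List with `chosen_k` and `silhouette_by_k` (named numeric).
#' @export
select_k_silhouette <- function(x, k_range = 2:8, seed = 1, n_init = 25) {
  x <- metric_matrix_or_matrix(x)
  if (nrow(x) <= max(k_range)) stop("need more rows than max(k_range)")
  dmat <- stats::dist(x)
  sil <- vapply(k_range, function(k) {
    fit <- kmeans_fit(x, k, seed = seed + k, n_init = n_init)
    mean(cluster::silhouette(fit$labels, dmat)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  chosen <- k_range[which.max(sil)]
  list(chosen_k = chosen, silhouette_by_k = sil)
}

#' Random-forest permutation importance of the metrics for cluster labels
#'
#' Trains a random-forest classifier of the cluster assignment from the
#' scaled metrics and reports each metric's mean decrease in out-of-bag
#' accuracy under permutation of that metric (unscaled raw importance);
#' higher values mean the metric mattered more for the clustering.
#'
#' @param x Scaled metrics matrix or table.
#' @param labels Cluster labels.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return Tibble with `metric`, `importance`, sorted decreasing.
#' @export
rf_importance <- function(x, labels, n_trees = 500, seed = 1) {
  x <- metric_matrix_or_matrix(x)
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  if (any(table(labels) < 3)) stop("every cluster needs at least 3 members")
  set.seed(seed)
  fit <- randomForest::randomForest(x, factor(labels), ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)
  tibble::tibble(metric = rownames(imp), importance = imp[, 1]) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Project scaled metrics onto the first two principal components
#'
#' SVD-based PCA for visualization only (clustering always runs in the
#' full scaled space). The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x Scaled metrics matrix or table.
#' @return List with `scores` (n x 2 matrix, PC1/PC2), `explained_variance`
#'   (proportion per component, all components) and `loadings`.
#' @export
pca_project <- function(x) {
  x <- metric_matrix_or_matrix(x)
  if (nrow(x) <= 2) stop("need more than 2 rows for a PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  list(scores = scores[, 1:2, drop = FALSE],
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       loadings = rot)
}

#' Cluster overall gait behavior at one speed condition
#'
#' The full per-condition pipeline: exclude participants with any missing
#' metric, z-score scale within the condition, choose k by silhouette
#' (unless given), k-means with restarts, sum-of-squares decomposition,
#' random-forest permutation importance, and a PCA projection for
#' plotting.
#'
#' @param metrics Tibble with `participant_id` and the seven metric
#'   columns, one row per participant (one speed condition).
#' @param k Number of clusters, or `NULL` to select by silhouette.
#' @param k_range Candidate k values for the silhouette method.
#' @param seed Integer seed governing initialization and the forest.
#' @param n_init k-means restarts.
#' @param n_trees Random-forest size.
#' @param condition Optional condition label stored in the result.
#' @return An object of class `gait_clusters`.
#' @export
cluster_gait <- function(metrics, k = NULL, k_range = 2:8, seed = 1,
                         n_init = 25, n_trees = 500, condition = NA_character_) {
  cols <- intersect(METRIC_COLUMNS, names(metrics))
  complete <- stats::complete.cases(metrics[, cols])
  excluded <- metrics$participant_id[!complete]
  dat <- metrics[complete, ]
  if (nrow(dat) < 3) stop("fewer than 3 participants with complete metrics")
  sc <- zscore_scale(dat, cols)
  x <- metric_matrix(sc$scaled, cols)
  rownames(x) <- dat$participant_id

  sil <- NULL
  if (is.null(k)) {
    sil <- select_k_silhouette(x, k_range = k_range, seed = seed, n_init = n_init)
    k <- sil$chosen_k
  }
  fit <- kmeans_fit(x, k, seed = seed, n_init = n_init)
  ss <- cluster_ss(x, fit$labels)
  imp <- tryCatch(rf_importance(x, fit$labels, n_trees = n_trees, seed = seed),
                  error = function(e) {
                    warning("variable importance skipped: ", conditionMessage(e))
                    NULL
                  })
  pca <- pca_project(x)

  structure(list(
    condition = condition, chosen_k = k,
    labels = stats::setNames(fit$labels, dat$participant_id),
    centroids = fit$centroids,
    wss = ss$wss, wss_total = ss$wss_total, bss = ss$bss, tss = ss$tss,
    silhouette_by_k = sil$silhouette_by_k,
    importance = imp,
    pca_scores = pca$scores, pca_explained = pca$explained_variance,
    scaling_params = sc$params,
    scaled = x,
    data = dat, excluded = excluded, seed = seed
  ), class = "gait_clusters")
}

#' @export
print.gait_clusters <- function(x, ...) {
  cat(sprintf("<gait_clusters>%s k = %d, n = %d participants\n",
              if (!is.na(x$condition)) paste0(" [", x$condition, "]") else "",
              x$chosen_k, length(x$labels)))
  cat("  sizes:", paste(table(x$labels), collapse = ", "), "\n")
  cat(sprintf("  WSS = %s (total %.1f), BSS = %.1f, TSS = %.1f\n",
              paste(sprintf("%.1f", x$wss), collapse = "/"),
              x$wss_total, x$bss, x$tss))
  if (!is.null(x$importance)) {
    cat("  importance ranking:", paste(x$importance$metric, collapse = " > "), "\n")
  }
  if (length(x$excluded) > 0) {
    cat("  excluded (missing metrics):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare cluster assignments between two speed conditions
#'
#' Matches cluster identities across conditions by nearest centroids in
#' scaled space (k-means labels are arbitrary), restricts to the common
#' participants, and reports who switched clusters and how the
#' within/between sum-of-squares changed.
#'
#' @param result_a,result_b `gait_clusters` objects (e.g. self-selected
#'   and fastest speed).
#' @return List with `assignments` (tibble: participant, label in each
#'   condition after matching, `switched`), `n_switched`, `wss_change`,
#'   `bss_change`.
#' @export
compare_conditions <- function(result_a, result_b) {
  common <- intersect(names(result_a$labels), names(result_b$labels))
  if (length(common) < length(result_a$labels) ||
      length(common) < length(result_b$labels)) {
    warning("participant sets differ; restricting the comparison to the ",
            length(common), " common participants")
  }
  # match B's clusters to A's by centroid proximity (greedy on the
  # distance matrix; exact for the k = 2 case of interest)
  ka <- nrow(result_a$centroids); kb <- nrow(result_b$centroids)
  dmat <- outer(seq_len(kb), seq_len(ka), Vectorize(function(i, j) {
    sum((result_b$centroids[i, ] - result_a$centroids[j, ])^2)
  }))
  map <- rep(NA_integer_, kb)
  free_b <- seq_len(kb); free_a <- seq_len(ka)
  while (length(free_b) > 0 && length(free_a) > 0) {
    sub <- dmat[free_b, free_a, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    map[free_b[ij[1]]] <- free_a[ij[2]]
    free_b <- free_b[-ij[1]]; free_a <- free_a[-ij[2]]
  }
  map[is.na(map)] <- setdiff(seq_len(max(ka, kb)), map)[seq_len(sum(is.na(map)))]

  la <- result_a$labels[common]
  lb <- map[result_b$labels[common]]
  assignments <- tibble::tibble(
    participant_id = common, cluster_a = unname(la), cluster_b = unname(lb),
    switched = la != lb
  )
  list(
    assignments = assignments,
    n_switched = sum(assignments$switched),
    switchers = assignments$participant_id[assignments$switched],
    wss_change = stats::setNames(
      result_b$wss[map] - result_a$wss, paste0("cluster_", seq_along(result_a$wss))),
    bss_change = result_b$bss - result_a$bss,
    bss = c(a = result_a$bss, b = result_b$bss)
  )
}

#' Contrast a clinical measure between clusters (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test of a clinical variable (Lower-Extremity
#' Fugl-Meyer score or gait speed) between the members of two clusters,
#' by default restricted to participants post-stroke. The exact null
#' distribution is enumerated when the combined sample is small (n <= 20)
#' and tie-free; otherwise the normal approximation with tie correction is
#' used.
#'
#' @param result A `gait_clusters` object (k = 2).
#' @param meta Tibble with `participant_id`, `group` and the clinical
#'   variable.
#' @param variable Column name, e.g. `"le_fugl_meyer"` or `"speed"`.
#' @param stroke_only Restrict to stroke participants (default `TRUE`).
#' @return List with `u`, `p_value`, `n`, `medians`, `exact`.
#' @export
clinical_contrast <- function(result, meta, variable = "le_fugl_meyer",
                              stroke_only = TRUE) {
  labels <- if (inherits(result, "gait_clusters")) result$labels else result
  meta <- meta[!duplicated(meta$participant_id), ]
  meta <- meta[meta$participant_id %in% names(labels), ]
  if (stroke_only) meta <- meta[meta$group == "stroke", ]
  v <- meta[[variable]]
  cl <- unname(labels[meta$participant_id])
  ok <- !is.na(v) & !is.na(cl)
  v <- v[ok]; cl <- cl[ok]
  ks <- sort(unique(cl))
  if (length(ks) != 2) stop("clinical_contrast requires exactly 2 nonempty clusters")
  x <- v[cl == ks[1]]; y <- v[cl == ks[2]]
  if (length(unique(c(x, y))) == 1) stop("all values identical; no contrast possible")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
  list(
    u = unname(wt$statistic), p_value = wt$p.value,
    n = c(length(x), length(y)),
    medians = c(stats::median(x), stats::median(y)),
    exact = exact
  )
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions (1 = identical,
#' ~0 = random); used to compare recovered clusters with known group
#' membership in simulation studies.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
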