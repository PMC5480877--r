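# Unsupervised validation: hierarchical clustering of the feature matrix
# on correlation distance and silhouette-based cluster comparison.

#' Z-scale the columns of a feature matrix
#'
#' Per feature column: `(x - mean) / sd` (sample SD).  A zero-variance
#' column carries no information and is set to all zeros (logged).
#'
#' @param x numeric matrix (rows = objects, columns = features).
#' @return matrix of the same shape.
#' @export
zscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_input("z-scaling needs >= 2 rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    rs_msg("zero-variance feature column(s) set to 0: ",
           paste(colnames(x)[flat] %||% which(flat), collapse = ", "))
    sdv[flat] <- 1
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z[, flat] <- 0
  z
}

#' Correlation distance between two vectors
#'
#' `(1 - Pearson r) / 2`: 0 for perfectly correlated profiles, 0.5 for
#' uncorrelated, 1 for perfectly anti-correlated.  Invariant to positive
#' affine rescaling of either vector.  A zero-variance vector has no
#' defined correlation; r is treated as 0 (distance 0.5, logged).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return distance in \[0, 1\].
#' @export
corr_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_input("vectors must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rs_msg("zero-variance vector in corr_distance; distance set to 0.5")
    return(0.5)
  }
  (1 - stats::cor(x, y)) / 2
}

# Pairwise (1-r)/2 distances between the ROWS of x, as a "dist".
# Zero-variance rows get r = 0 against everything (distance 0.5).
corr_dist_matrix <- function(x) {
  x <- as.matrix(x)
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- 0
  d <- (1 - r) / 2
  diag(d) <- 0
  stats::as.dist(d)
}

# Silhouette widths per object: s = (B - A) / max(A, B), A the average
# distance to the object's own cluster, B the minimal average distance to
# another cluster.  Singletons and A = B = 0 give s = 0.
silhouette_widths <- function(d, labels) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(length(labels) == n)
  labs <- unique(labels)
  if (length(labs) < 2) stop_input("silhouette needs >= 2 clusters")
  idx <- lapply(labs, function(g) which(labels == g))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    own_idx <- setdiff(idx[[match(own, labs)]], i)
    if (!length(own_idx)) { s[i] <- 0; next }  # singleton convention
    A <- mean(dm[i, own_idx])
    B <- min(vapply(labs[labs != own], function(g) {
      mean(dm[i, idx[[match(g, labs)]]])
    }, 0))
    s[i] <- if (max(A, B) == 0) 0 else (B - A) / max(A, B)
  }
  names(s) <- rownames(dm) %||% as.character(seq_len(n))
  s
}

#' Silhouette coefficients for a clustering
#'
#' Per object, `s = (B - A) / max(A, B)` where A is the average distance
#' from the object to every other object of its own cluster and B the
#' minimal average distance to the objects of another cluster.  Objects in
#' singleton clusters, and degenerate objects with A = B = 0, get s = 0.
#' An average above 0.5 indicates reasonable partitioning; below 0.2, no
#' cluster structure.
#'
#' @param d a `dist` (or square distance matrix).
#' @param labels cluster labels, one per object; at least two distinct.
#' @return list with `widths` (named per-object silhouettes in \[-1, 1\])
#'   and `average_sc`.
#' @export
silhouette_sc <- function(d, labels) {
  w <- silhouette_widths(d, labels)
  list(widths = w, average_sc = mean(w))
}

#' Hierarchical clustering of TSS chromatin signatures
#'
#' Agglomerative clustering with unweighted average linkage on
#' `(1 - correlation)/2` distances between (by default z-scaled) feature
#' profiles, cut to `k` clusters.  With `k = 2` this is the partition that
#' separates rod from common TSS.
#'
#' @param x a SummarizedExperiment from [build_feature_matrix()] (the
#'   `"cpm"` assay is used) or a numeric matrix (rows = TSS).
#' @param k number of clusters (default 2).
#' @param scale z-scale feature columns before computing distances
#'   (default TRUE; clustering raw counts would be dominated by the
#'   highest-magnitude assay).
#' @return object of class `tss_clusters`: list with `labels` (named
#'   cluster indices), `hclust` (the merge tree; `$merge`/`$height` give
#'   the merge history), `sil` (per-object silhouettes), `average_sc`,
#'   and `dist`.
#' @export
cluster_tss <- function(x, k = 2, scale = TRUE) {
  m <- if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "cpm")
  } else {
    as.matrix(x)
  }
  if (k < 1 || k > nrow(m)) stop_input("k out of range")
  z <- if (scale) zscale(m) else m
  d <- corr_dist_matrix(z)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(m) %||% as.character(seq_len(nrow(m)))
  sil <- if (k >= 2) silhouette_sc(d, labels) else
    list(widths = stats::setNames(rep(NA_real_, nrow(m)), names(labels)),
         average_sc = NA_real_)
  structure(list(labels = labels, hclust = hc, sil = sil$widths,
                 average_sc = sil$average_sc, dist = d, k = k),
            class = "tss_clusters")
}

#' @export
print.tss_clusters <- function(x, ...) {
  cat(sprintf("<tss_clusters> %d objects, k = %d, average SC = %.3f\n",
              length(x$labels), x$k, x$average_sc))
  print(table(x$labels))
  invisible(x)
}

#' Silhouette separation between two predefined sets
#'
#' Treats `set_a` and `set_b` as the two clusters and computes the average
#' silhouette coefficient on correlation distances of (by default
#' z-scaled) features -- the statistic used to ask whether two groups of
#' TSS form separate clusters (e.g. known rod vs common) or one cluster
#' (e.g. known vs newly predicted rod).
#'
#' @param x SummarizedExperiment or matrix as in [cluster_tss()].
#' @param set_a,set_b disjoint non-empty vectors of row identifiers.
#' @param scale z-scale before distances (default TRUE).
#' @return the average silhouette coefficient.
#' @export
between_set_sc <- function(x, set_a, set_b, scale = TRUE) {
  m <- if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "cpm")
  } else {
    as.matrix(x)
  }
  if (!length(set_a) || !length(set_b)) stop_input("empty set")
  if (length(intersect(set_a, set_b))) stop_input("sets overlap")
  miss <- setdiff(c(set_a, set_b), rownames(m))
  if (length(miss)) {
    stop_input("unknown ids: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  sub <- m[c(set_a, set_b), , drop = FALSE]
  z <- if (scale) zscale(sub) else sub
  d <- corr_dist_matrix(z)
  labels <- rep(c("a", "b"), c(length(set_a), length(set_b)))
  silhouette_sc(d, labels)$average_sc
}
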