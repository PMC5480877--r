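# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (per-bp loops, double loops, pairwise recomputation)
# and never share code with the implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

make_track <- function(chrom, start, end, score, assay = "H3K4me2",
                       timepoint = "PN1", library_size = NULL) {
  gr <- GRanges(chrom, IRanges(start + 1L, end), score = score)
  quiet(signal_track(assay, timepoint, gr, library_size))
}

# per-entry overlap-count oracle: each entry overlapping [ws, we) (0-based
# half-open) contributes its score once
oracle_count <- function(chrom, start, end, score, wchrom, ws, we) {
  total <- 0
  for (i in seq_along(start)) {
    if (chrom[i] == wchrom && start[i] < we && end[i] > ws) {
      total <- total + score[i]
    }
  }
  total
}

# per-bp oracle for basepair-weighted aggregation
oracle_weighted <- function(chrom, start, end, score, wchrom, ws, we) {
  total <- 0
  for (i in seq_along(start)) {
    if (chrom[i] != wchrom) next
    for (bp in seq(start[i], end[i] - 1)) {
      if (bp >= ws && bp < we) total <- total + score[i]
    }
  }
  total
}

# naive silhouette: direct double loop over the distance matrix
oracle_silhouette <- function(dmat, labels) {
  n <- nrow(dmat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- same[same != i]
    if (length(same) == 0) { s[i] <- 0; next }
    A <- sum(dmat[i, same]) / length(same)
    B <- Inf
    for (g in unique(labels)) {
      if (g == labels[i]) next
      other <- which(labels == g)
      B <- min(B, sum(dmat[i, other]) / length(other))
    }
    s[i] <- if (max(A, B) == 0) 0 else (B - A) / max(A, B)
  }
  s
}

# exhaustive average-linkage: recompute every cluster-pair average of the
# ORIGINAL pairwise distances at each step; returns sorted merge heights
oracle_average_linkage_heights <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dd <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# interval-union oracle: merge 0-based half-open intervals on one chrom
oracle_union_count <- function(start, end, max_gap = 0) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  n_sites <- 1
  cur_end <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_end + max_gap) n_sites <- n_sites + 1
    cur_end <- max(cur_end, end[i])
  }
  n_sites
}

# one shared default simulation per test run (the generator is fast but
# the feature/cluster stages are reused by several files)
sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(sim_cache$sim)) {
    sim_cache$sim <- simulate_dataset(sim_config(seed = 1),
                                      dir = file.path(tempdir(), "rodsig_sim1"))
    sim_cache$se <- quiet(build_feature_matrix(
      sim_cache$sim$tss, sim_cache$sim$tracks,
      chrom_sizes = sim_cache$sim$chrom_sizes))
  }
  list(sim = sim_cache$sim, se = sim_cache$se)
}
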