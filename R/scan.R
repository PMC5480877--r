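# Genome-wide discovery of loci bearing the rod-TSS chromatin signature
# outside annotated TSS, with genomic-context annotation.

#' Tile a genome into overlapping windows
#'
#' Half-open tiles of `window` bp every `step` bp per chromosome; the last
#' tile is clipped at the chromosome end.  The union of tiles covers the
#' whole chromosome.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window tile width in bp (default 2000, matching a +/- 1000 bp
#'   feature window around the tile midpoint).
#' @param step tile spacing in bp (default 500); `window >= step > 0`.
#' @return GRanges of tiles.
#' @export
tile_genome <- function(chrom_sizes, window = 2000, step = 500) {
  stopifnot(window >= step, step > 0)
  parts <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- if (len <= window) 0 else seq(0, len - window + step, by = step)
    data.frame(chrom = ch, start = starts, end = pmin(starts + window, len))
  })
  d <- do.call(rbind, parts)
  gr0(d$chrom, d$start, d$end)
}

#' Class centroids and feature scaler from a classified training set
#'
#' Z-scales the training feature matrix and averages the scaled profiles
#' of each class; scan tiles are later scaled with the same training
#' means/SDs before comparison.  The centroids inherit the clustering
#' geometry that the silhouette analysis validates.
#'
#' @param se SummarizedExperiment from [build_feature_matrix()].
#' @param labels vector of class labels (`"rod"` / `"common"`), named by
#'   tss_id or in row order.
#' @return object of class `signature_centroids`: list with `rod`,
#'   `common` (mean z-profiles), `center`, `scale` (training
#'   column means/SDs).
#' @export
class_centroids <- function(se, labels) {
  m <- SummarizedExperiment::assay(se, "cpm")
  if (!is.null(names(labels))) labels <- labels[rownames(m)]
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m), all(c("rod", "common") %in% labels))
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  structure(list(rod = colMeans(z[labels == "rod", , drop = FALSE]),
                 common = colMeans(z[labels == "common", , drop = FALSE]),
                 center = mu, scale = sdv),
            class = "signature_centroids")
}

# correlation distance of each row of z to a centroid vector
row_corr_dist <- function(z, centroid) {
  n <- ncol(z)
  zr <- z - rowMeans(z)
  denom <- sqrt(rowSums(zr^2))
  cc <- centroid - mean(centroid)
  cden <- sqrt(sum(cc^2))
  r <- as.vector(zr %*% cc) / (denom * cden)
  r[!is.finite(r)] <- 0  # flat profile or flat centroid: treat r as 0
  (1 - r) / 2
}

#' Score candidate windows for the rod-TSS signature
#'
#' Two selectable scoring paths:
#' * `"centroid"`: a window passes when its z-scaled profile (training
#'   scaler) is strictly closer in correlation distance to the rod
#'   centroid than to the common centroid; score = d(common) - d(rod).
#' * `"rule"`: a window passes when [classify_rod_signature()] calls it
#'   rod; score = number of satisfied signature criteria (0-6: k4 ratio
#'   gate, RD1 depletion, DHS increase, CRX, NRL, PolII increase).
#'
#' @param fm list with `raw` and `cpm` feature matrices for the windows
#'   (as produced internally by the scan; see [scan_genome()]).
#' @param path `"centroid"` or `"rule"`.
#' @param centroids [class_centroids()] (required for the centroid path).
#' @param thresholds [rod_thresholds()] (used by the rule path).
#' @return data.frame `passes` (logical), `score` (numeric).
#' @export
score_windows <- function(fm, path = c("centroid", "rule"), centroids = NULL,
                          thresholds = rod_thresholds()) {
  path <- match.arg(path)
  if (path == "centroid") {
    if (is.null(centroids)) stop_input("centroid path needs centroids")
    z <- sweep(sweep(fm$cpm, 2, centroids$center, "-"), 2,
               centroids$scale, "/")
    d_rod <- row_corr_dist(z, centroids$rod)
    d_common <- row_corr_dist(z, centroids$common)
    # a flat raw profile (e.g. an all-zero tile) carries no evidence and
    # never passes, even though scaling would lend it a shape
    flat <- apply(fm$cpm, 1, stats::sd) == 0
    data.frame(passes = d_rod < d_common & !flat,
               score = ifelse(flat, 0, d_common - d_rod))
  } else {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = fm$raw, cpm = fm$cpm))
    st <- derive_stats(se, thresholds, preset = "fixed")
    cls <- classify_rod_signature(st, thresholds)
    crit <- cbind(st$k4_ratio >= thresholds$k4_ratio_min,
                  st$k4_rd1_depleted,
                  st$dhs_group %in% c("up", "strong"),
                  st$crx_bound, st$nrl_bound, st$polii_group != "none")
    data.frame(passes = cls$class == "rod", score = rowSums(crit))
  }
}

#' Merge passing tiles into sites
#'
#' Overlapping or near-adjacent (gap <= `max_gap`) passing tiles are
#' merged into one site whose score is the maximum member score.
#'
#' @param tiles GRanges of passing tiles, sorted.
#' @param scores numeric scores, one per tile.
#' @param max_gap maximum gap in bp to bridge (default 0: merge only
#'   overlapping/abutting tiles).
#' @return GRanges of merged sites with a `score` column.
#' @export
merge_hits <- function(tiles, scores = rep(0, length(tiles)), max_gap = 0) {
  if (!length(tiles)) {
    out <- GenomicRanges::GRanges()
    out$score <- numeric(0)
    return(out)
  }
  red <- GenomicRanges::reduce(tiles, min.gapwidth = max_gap + 1L,
                               ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(tiles, red, ignore.strand = TRUE)
  red$score <- vapply(seq_along(red), function(j) {
    max(scores[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]])
  }, 0)
  red
}

#' Annotate the genomic context of sites
#'
#' Assigns each site exactly one category by its midpoint with precedence
#' promoter > TES > exon > intron > intergenic: `promoter` when the
#' midpoint lies within `promoter_halfwidth` of any annotated TSS, `TES`
#' analogously for transcript ends, `exon`/`intron` by position within
#' gene bodies, `intergenic` otherwise.  Also reports the nearest gene.
#'
#' @param sites GRanges of sites.
#' @param gene_models a [read_gene_models()] object.
#' @param known_tss data.frame with `chrom` and `position` (0-based);
#'   defaults to the gene models' TSS.
#' @param promoter_halfwidth,tes_halfwidth bp half-widths (default 1000).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `context` (factor promoter/TES/exon/intron/intergenic),
#'   `nearest_gene`.
#' @export
annotate_context <- function(sites, gene_models, known_tss = NULL,
                             promoter_halfwidth = 1000,
                             tes_halfwidth = 1000) {
  stopifnot(methods::is(gene_models, "gene_models"))
  known_tss <- known_tss %||% gene_models$tss
  n <- length(sites)
  mid <- start0(sites) + (end0(sites) - start0(sites)) %/% 2L
  midgr <- gr0(as.character(GenomicRanges::seqnames(sites)), mid, mid + 1L)
  tssgr <- gr0(known_tss$chrom,
               pmax(known_tss$position - promoter_halfwidth, 0),
               known_tss$position + promoter_halfwidth + 1L)
  g <- gene_models$genes
  tesgr <- gr0(g$chrom, pmax(g$tes - tes_halfwidth, 0),
               g$tes + tes_halfwidth + 1L)
  bodygr <- gr0(g$chrom, g$tx_start, g$tx_end)
  in_prom <- GenomicRanges::countOverlaps(midgr, tssgr) > 0
  in_tes <- GenomicRanges::countOverlaps(midgr, tesgr) > 0
  in_exon <- if (length(gene_models$exons)) {
    GenomicRanges::countOverlaps(midgr, gene_models$exons,
                                 ignore.strand = TRUE) > 0
  } else rep(FALSE, n)
  in_body <- GenomicRanges::countOverlaps(midgr, bodygr) > 0
  context <- rep("intergenic", n)
  context[in_body] <- "intron"
  context[in_exon] <- "exon"
  context[in_tes] <- "TES"
  context[in_prom] <- "promoter"
  nearest_gene <- rep(NA_character_, n)
  if (nrow(g) && n) {
    dn <- GenomicRanges::distanceToNearest(midgr, bodygr, ignore.strand = TRUE)
    nearest_gene[S4Vectors::queryHits(dn)] <-
      g$gene_id[S4Vectors::subjectHits(dn)]
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
             start = start0(sites), end = end0(sites),
             context = factor(context, levels = c("promoter", "TES", "exon",
                                                  "intron", "intergenic")),
             nearest_gene = nearest_gene,
             stringsAsFactors = FALSE)
}

#' Summarize scan hits by genomic context
#'
#' @param hits data.frame with a `context` column ([scan_genome()] /
#'   [annotate_context()] output); must be non-empty.
#' @return data.frame `group`, `count`, `percent` (rounded half away from
#'   zero; sums to 100 within rounding).
#' @export
summarize_contexts <- function(hits) {
  if (!nrow(hits)) stop_input("no hits to summarize")
  group_summary(hits$context)
}

#' Scan a genome for rod-TSS-signature loci
#'
#' Tiles the genome, evaluates the 13-feature chromatin signature in a
#' +/- `halfwidth` window around every tile midpoint, scores tiles by the
#' selected path, merges passing tiles into sites, and annotates their
#' genomic context.  By default, tiles whose midpoint falls within
#' `exclude_halfwidth` of an annotated TSS are excluded so the scan
#' reports unannotated loci only; set `exclude_tss = FALSE` to keep them
#' (annotated rod TSS are then themselves recovered as hits).
#'
#' @param tracks list of [signal_track()] covering all 13 features.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param gene_models a [read_gene_models()] object.
#' @param path `"centroid"` (default) or `"rule"`; see [score_windows()].
#' @param centroids [class_centroids()] from the classified training TSS
#'   (required for the centroid path).
#' @param thresholds [rod_thresholds()] for the rule path.
#' @param known_tss data.frame (`chrom`, `position`) of annotated TSS;
#'   defaults to the gene models' TSS.
#' @param exclude_tss drop tiles near annotated TSS (default TRUE).
#' @param exclude_halfwidth exclusion half-width in bp (default 1000).
#' @param window,step tiling parameters (see [tile_genome()]).
#' @param halfwidth feature window half-width around tile midpoints.
#' @param max_gap merge gap in bp (see [merge_hits()]).
#' @return data.frame of scan hits: `chrom`, `start`, `end` (0-based
#'   half-open merged site), `score`, `context`, `nearest_gene`.
#' @export
scan_genome <- function(tracks, chrom_sizes, gene_models,
                        path = c("centroid", "rule"), centroids = NULL,
                        thresholds = rod_thresholds(), known_tss = NULL,
                        exclude_tss = TRUE, exclude_halfwidth = 1000,
                        window = 2000, step = 500, halfwidth = 1000,
                        max_gap = 0) {
  path <- match.arg(path)
  known_tss <- known_tss %||% gene_models$tss
  tiles <- tile_genome(chrom_sizes, window, step)
  mid <- start0(tiles) + (end0(tiles) - start0(tiles)) %/% 2L
  wins <- gr0(as.character(GenomicRanges::seqnames(tiles)),
              pmax(mid - halfwidth, 0),
              pmin(mid + halfwidth, chrom_sizes[
                as.character(GenomicRanges::seqnames(tiles))]))
  if (exclude_tss && nrow(known_tss)) {
    # a candidate locus must be signal-independent of annotated promoters:
    # drop tiles whose *feature window* touches an annotated TSS window
    tssgr <- gr0(known_tss$chrom,
                 pmax(known_tss$position - exclude_halfwidth, 0),
                 known_tss$position + exclude_halfwidth + 1L)
    keep <- GenomicRanges::countOverlaps(wins, tssgr,
                                         ignore.strand = TRUE) == 0
    tiles <- tiles[keep]
    wins <- wins[keep]
  }
  fm <- window_feature_matrix(wins, tracks)
  sc <- score_windows(fm, path, centroids, thresholds)
  hits <- merge_hits(tiles[sc$passes], sc$score[sc$passes], max_gap)
  ann <- annotate_context(hits, gene_models, known_tss)
  ann$score <- hits$score
  ann[, c("chrom", "start", "end", "score", "context", "nearest_gene")]
}

#' Write scan hits as a UCSC-loadable BED6 file
#'
#' Scores are rescaled to 0-1000.
#'
#' @param hits scan-hit data.frame from [scan_genome()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scan_bed <- function(hits, path) {
  if (nrow(hits)) {
    rng <- range(hits$score)
    s1000 <- if (diff(rng) == 0) rep(1000, nrow(hits)) else
      round((hits$score - rng[1]) / diff(rng) * 1000)
    gr <- gr0(hits$chrom, hits$start, hits$end)
    gr$name <- sprintf("site_%03d", seq_len(nrow(hits)))
    gr$score <- s1000
  } else {
    gr <- GenomicRanges::GRanges()
  }
  write_bed(gr, path)
}
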