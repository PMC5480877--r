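# End-to-end orchestration: read inputs, extract features, derive stats,
# classify, cluster, scan, and write a deterministic report bundle.

#' Orient cluster indices into rod / common classes
#'
#' The two clusters of an unsupervised partition carry arbitrary indices;
#' the rod cluster is identified as the one with the higher mean H3K4me2
#' PN15/PN1 developmental ratio.
#'
#' @param labels named cluster indices (from [cluster_tss()]).
#' @param k4_ratio per-object H3K4me2 PN15/PN1 ratios, named or in the
#'   same order as `labels`.
#' @return named factor with levels rod, common.
#' @export
orient_clusters <- function(labels, k4_ratio) {
  if (!is.null(names(k4_ratio))) k4_ratio <- k4_ratio[names(labels)]
  stopifnot(length(labels) == length(k4_ratio))
  means <- tapply(k4_ratio, labels, mean)
  rod_cluster <- names(means)[which.max(means)]
  stats::setNames(factor(ifelse(as.character(labels) == rod_cluster,
                                "rod", "common"),
                         levels = c("rod", "common")),
                  names(labels))
}

read_track_manifest <- function(manifest, base_dir = dirname(manifest)) {
  d <- utils::read.table(manifest, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("assay", "timepoint", "file")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_input("track manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  lapply(seq_len(nrow(d)), function(i) {
    p <- d$file[i]
    if (!file.exists(p)) p <- file.path(base_dir, d$file[i])
    if (!file.exists(p)) stop_input("track file not found: ", d$file[i])
    read_track_bedgraph(p, d$assay[i], d$timepoint[i],
                        library_size = d$library_size[i] %||% NULL)
  })
}

#' Run the full TSS-signature pipeline
#'
#' Reads a dataset directory (`tss.bed`, `tracks.tsv` manifest,
#' `genes.gtf`, `chrom.sizes` -- the layout written by
#' [simulate_dataset()]), builds the 13-feature matrix, derives the
#' signature statistics, classifies every TSS by rule and by 2-cluster
#' average-linkage clustering, summarizes marker groups per class, scans
#' the genome for unannotated rod-signature loci, and writes a
#' deterministic report bundle to `outdir`:
#' `features.tsv` (features + derived stats + both classifications),
#' `clusters.tsv` (cluster index, class, silhouette),
#' `group_summary.tsv` (per-class marker bookkeeping),
#' `scan_sites.bed` / `scan_sites.tsv`, and `run_log.txt`.
#' Rerunning with identical inputs reproduces the bundle byte for byte.
#'
#' @param input_dir dataset directory.
#' @param outdir output directory (created if needed).
#' @param threshold_preset `"data"` recomputes the PolII/DHS cutoffs from
#'   the input TSS set as mean + 2 SD; `"fixed"` uses the reference
#'   values 182 / 1.35 (see [derive_stats()]).
#' @param scan_path `"centroid"` or `"rule"` (see [scan_genome()]).
#' @param thresholds base [rod_thresholds()].
#' @param halfwidth,window,step,max_gap analysis and scan geometry.
#' @return (invisibly) list: `se`, `stats`, `rule_class`, `clusters`,
#'   `cluster_class`, `centroids`, `hits`, `group_summary`, `files`.
#' @export
run_pipeline <- function(input_dir, outdir,
                         threshold_preset = c("data", "fixed"),
                         scan_path = c("centroid", "rule"),
                         thresholds = rod_thresholds(),
                         halfwidth = 1000, window = 2000, step = 500,
                         max_gap = 0) {
  threshold_preset <- match.arg(threshold_preset)
  scan_path <- match.arg(scan_path)
  paths <- file.path(input_dir, c("tss.bed", "tracks.tsv", "genes.gtf",
                                  "chrom.sizes"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_input("input stage: missing file(s): ",
               paste(basename(missing), collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  tss <- read_tss_bed(paths[1])
  tracks <- read_track_manifest(paths[2], input_dir)
  models <- read_gene_models(paths[3])
  chrom_sizes <- read_chrom_sizes(paths[4])

  se <- build_feature_matrix(tss, tracks, halfwidth = halfwidth,
                             chrom_sizes = chrom_sizes)
  st <- derive_stats(se, thresholds, preset = threshold_preset)
  th_used <- attr(st, "thresholds")
  rule <- classify_rod_signature(st, th_used)

  cl <- cluster_tss(se, k = 2)
  k4 <- stats::setNames(st$k4_ratio, st$tss_id)
  cl_class <- orient_clusters(cl$labels, k4)
  # the scan searches for the signature, so the centroids are trained on
  # the rule-based signature classes (both classes must be represented)
  centroid_labels <- stats::setNames(as.character(rule$class), rule$tss_id)
  if (length(unique(centroid_labels)) < 2) {
    centroid_labels <- stats::setNames(as.character(cl_class), names(cl_class))
  }
  centroids <- class_centroids(se, centroid_labels)

  hits <- scan_genome(tracks, chrom_sizes, models, path = scan_path,
                      centroids = centroids, thresholds = th_used,
                      known_tss = data.frame(chrom = tss$chrom,
                                             position = tss$position),
                      window = window, step = step, halfwidth = halfwidth,
                      max_gap = max_gap)

  marker <- function(cls) {
    rows <- as.character(cl_class[st$tss_id]) == cls
    rbind(
      cbind(class = cls, marker = "CRX",
            group_summary(ifelse(st$crx_bound[rows], "bound", "unbound"))),
      cbind(class = cls, marker = "NRL",
            group_summary(ifelse(st$nrl_bound[rows], "bound", "unbound"))),
      cbind(class = cls, marker = "DHS",
            group_summary(st$dhs_group[rows])),
      cbind(class = cls, marker = "PolII",
            group_summary(st$polii_group[rows]))
    )
  }
  gs <- rbind(marker("rod"), marker("common"))

  f_features <- file.path(outdir, "features.tsv")
  extra <- cbind(st[, setdiff(names(st), "tss_id")],
                 rule_class = as.character(rule$class),
                 confidence = rule$confidence,
                 cluster = unname(cl$labels[st$tss_id]),
                 cluster_class = as.character(cl_class[st$tss_id]))
  write_feature_tsv(se, f_features, extra = extra)
  f_clusters <- file.path(outdir, "clusters.tsv")
  utils::write.table(
    data.frame(tss_id = names(cl$labels), cluster = unname(cl$labels),
               class = as.character(cl_class),
               silhouette = unname(cl$sil), stringsAsFactors = FALSE),
    f_clusters, sep = "\t", quote = FALSE, row.names = FALSE)
  f_groups <- file.path(outdir, "group_summary.tsv")
  utils::write.table(gs, f_groups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_bed <- file.path(outdir, "scan_sites.bed")
  write_scan_bed(hits, f_bed)
  f_scan <- file.path(outdir, "scan_sites.tsv")
  utils::write.table(hits, f_scan, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_log <- file.path(outdir, "run_log.txt")
  writeLines(c(
    sprintf("rodsig %s", as.character(utils::packageVersion("rodsig"))),
    sprintf("input_dir: %s", normalizePath(input_dir)),
    sprintf("threshold_preset: %s", threshold_preset),
    sprintf("t_polii: %.6g (%s)", th_used$t_polii, threshold_preset),
    sprintf("t_dhs_strong: %.6g (%s)", th_used$t_dhs_strong,
            threshold_preset),
    sprintf("k4_ratio_min: %.6g", th_used$k4_ratio_min),
    sprintf("pseudocount: %.6g", th_used$pseudocount),
    sprintf("scan_path: %s", scan_path),
    sprintf("n_tss: %d  n_rule_rod: %d  n_cluster_rod: %d  n_scan_sites: %d",
            nrow(tss), sum(rule$class == "rod"),
            sum(cl_class == "rod"), nrow(hits)),
    sprintf("average_sc: %.4f", cl$average_sc)
  ), f_log)

  invisible(list(se = se, stats = st, rule_class = rule, clusters = cl,
                 cluster_class = cl_class, centroids = centroids,
                 hits = hits, group_summary = gs, thresholds = th_used,
                 files = c(features = f_features, clusters = f_clusters,
                           groups = f_groups, scan_bed = f_bed,
                           scan_tsv = f_scan, log = f_log)))
}

#' Reported-percentage bookkeeping table
#'
#' Applies the [summarize_groups()] count/percent rule to a list of
#' (numerator, denominator) pairs -- the arithmetic behind every reported
#' "n of N (x%)" figure.
#'
#' @param numerator,denominator integer vectors (recycled names allowed);
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param label optional character labels per pair.
#' @return data.frame `label`, `numerator`, `denominator`, `percent`.
#' @export
#' @examples
#' worked_example_report(c(72, 2), c(107, 11))  # 67%, 18%
worked_example_report <- function(numerator, denominator, label = NULL) {
  stopifnot(length(numerator) == length(denominator))
  if (any(denominator <= 0)) stop_input("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator)) {
    stop_input("numerator out of range")
  }
  pct <- vapply(seq_along(numerator), function(i) {
    labels <- rep(c("yes", "no"),
                  c(numerator[i], denominator[i] - numerator[i]))
    summarize_groups(labels, "yes")[["percent"]]
  }, 0)
  data.frame(label = label %||% sprintf("pair%d", seq_along(numerator)),
             numerator = numerator, denominator = denominator,
             percent = pct, stringsAsFactors = FALSE)
}
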