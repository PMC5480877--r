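# Synthetic TSS annotations, gene models and assay x timepoint tracks with
# the statistical structure the analysis assumes, plus ground-truth labels.
# The generator emulates the shape of the real inputs -- per-TSS window
# counts with class-dependent developmental ratios, bimodal TF binding,
# DHS/PolII developmental changes -- not read-level data.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis was developed under:
#' 72 single-TSS genes (all rod), 27 two-TSS and 8 three-TSS genes with
#' exactly one rod TSS each (107 genes, 150 TSS, 107 rod / 43 common);
#' rod H3K4me2 PN15/PN1 ratios lognormal with mean 10.1, common with mean
#' 2.6, the reported +/- 2.1 and +/- 0.5 being standard errors over 41 and
#' 37 TSS so the per-TSS lognormal SD is `sem * sqrt(n_ref)`; CRX bound in
#' 73% of rod and 8% of common TSS, NRL in 56% / 3%, bound TF counts at
#' least `bound_reads_min` (the bimodality gap) and unbound exactly 0;
#' DHS and PolII developmental-group proportions per class as reported;
#' and 20 planted non-TSS loci carrying the rod profile at intronic and
#' intergenic positions.  Counts are negative-binomial noised with
#' dispersion `nb_size`.
#'
#' @param seed integer seed driving all randomness.
#' @param n_genes_single,n_genes_two_tss,n_genes_three_tss gene counts.
#' @param rod_k4,common_k4 lists `list(center, sem, n_ref)` for the class
#'   H3K4me2 PN15/PN1 ratio law.
#' @param p_crx,p_nrl named vectors `c(rod=, common=)` of binding
#'   probabilities.
#' @param bound_reads_min minimum reads at a bound TSS (default 300).
#' @param tf_extra_mu mean extra reads above the minimum at bound TSS.
#' @param polii_props,dhs_props per-class developmental-group proportion
#'   lists (`rod`, `common`).
#' @param n_planted_sites planted non-TSS rod-signature loci (default 20).
#' @param mark_coherence Gaussian-copula correlation in \[0, 1\] coupling a
#'   locus's marks through one latent "signature strength": chromatin
#'   marks at a developmentally activated promoter are co-regulated, so a
#'   TSS with a strong H3K4me2 rise tends to also gain DHS, PolII and TF
#'   binding.  The coupling leaves every marginal law (ratio
#'   distributions, binding probabilities, group proportions) unchanged;
#'   0 gives independent marks.
#' @param nb_size negative-binomial size (dispersion) for counts.
#' @param k4_base,dhs_base,polii_base per-class baseline (early-timepoint)
#'   signal levels.  Rod promoters are essentially silent early in
#'   development -- low H3K4me2 and little hypersensitivity in the newborn
#'   retina, both developing postnatally -- while common promoters are
#'   active at all ages, so the rod baselines sit well below the common
#'   ones.
#' @param gene_length,gene_spacing gene body length and intergenic gap, bp.
#' @param library_size library size recorded for every track (tracks are
#'   emitted on a common per-million-like scale).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes_single = 72,
                       n_genes_two_tss = 27,
                       n_genes_three_tss = 8,
                       rod_k4 = list(center = 10.1, sem = 2.1, n_ref = 41),
                       common_k4 = list(center = 2.6, sem = 0.5, n_ref = 37),
                       p_crx = c(rod = 0.73, common = 0.08),
                       p_nrl = c(rod = 0.56, common = 0.03),
                       bound_reads_min = 300,
                       tf_extra_mu = 150,
                       polii_props = list(
                         rod = c(none = 37, low = 41, high = 35) / 113,
                         common = c(none = 28, low = 7, high = 2) / 37),
                       dhs_props = list(
                         rod = c(down = 7, up = 8, strong = 98) / 113,
                         common = c(down = 27, up = 5, strong = 5) / 37),
                       n_planted_sites = 20,
                       mark_coherence = 0.7,
                       nb_size = 10,
                       k4_base = c(rod = 10, common = 80),
                       dhs_base = c(rod = 150, common = 1500),
                       polii_base = 25,
                       gene_length = 10000,
                       gene_spacing = 12000,
                       library_size = 1e6) {
  stopifnot(n_genes_single >= 0, n_genes_two_tss >= 0, n_genes_three_tss >= 0,
            all(c(p_crx, p_nrl) >= 0), all(c(p_crx, p_nrl) <= 1),
            rod_k4$center > 0, common_k4$center > 0,
            bound_reads_min > 0, n_planted_sites >= 0, nb_size > 0,
            gene_length > 8000, gene_spacing > 4000, library_size > 0)
  structure(as.list(environment()), class = "sim_config")
}

# lognormal meanlog/sdlog with mean `center` and SD `sem * sqrt(n_ref)`
lnorm_params <- function(law) {
  cv <- (law$sem * sqrt(law$n_ref)) / law$center
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(law$center) - sdlog^2 / 2, sdlog = sdlog)
}

# split an integer count over three sub-intervals of the window
split3 <- function(v) {
  a <- floor(v * 0.25)
  cbind(a, v - 2 * a, a)
}

# three count entries per center: [c-600,c-200), [c-200,c+200), [c+200,c+600)
count_entries <- function(chrom, center, values) {
  sp <- split3(values)
  keep <- rep(seq_along(center), 3)
  starts <- c(center - 600L, center - 200L, center + 200L)
  ends <- starts + 400L
  score <- c(sp[, 1], sp[, 2], sp[, 3])
  ok <- score > 0
  data.frame(chrom = rep(chrom, 3)[ok], start = starts[ok], end = ends[ok],
             score = score[ok], stringsAsFactors = FALSE)
}

# one 500 bp entry whose bp x score aggregate equals `values`
weighted_entries <- function(chrom, center, values) {
  ok <- values > 0
  data.frame(chrom = chrom[ok], start = center[ok] - 250L,
             end = center[ok] + 250L, score = values[ok] / 500,
             stringsAsFactors = FALSE)
}

# quantile-couple a uniform to ordered group proportions (higher u =
# stronger group)
group_from_u <- function(u, props) {
  cum <- cumsum(props)
  names(props)[findInterval(u, cum[-length(cum)]) + 1L]
}

# class-conditional feature draws for n loci; returns a matrix of the 13
# feature target values (count scale; DHS on the weighted scale), with the
# drawn ratio law and DHS group attached for signature screening.  One
# latent N(0,1) "signature strength" per locus couples the marks through
# a Gaussian copula with correlation `mark_coherence`; each mark's
# marginal law is untouched.
draw_profiles_once <- function(n, class, cfg) {
  nb <- function(mu) stats::rnbinom(n, size = cfg$nb_size, mu = pmax(mu, 0.01))
  rho <- cfg$mark_coherence %||% 0.7
  strength <- stats::rnorm(n)
  latent <- function() {
    stats::pnorm(rho * strength + sqrt(1 - rho^2) * stats::rnorm(n))
  }
  law <- lnorm_params(if (class == "rod") cfg$rod_k4 else cfg$common_k4)
  base <- nb(cfg$k4_base[[class]]) + 1
  r <- stats::qlnorm(latent(), law$meanlog, law$sdlog)
  k4_pn1 <- base
  k4_pn15 <- nb(base * r)
  k4_pn7 <- nb(base * sqrt(r))
  k4_e17 <- nb(base * if (class == "rod") 0.4 else 0.9)
  k4_rd1 <- if (class == "rod") nb(base) else nb(base * r)
  dhs_group <- group_from_u(latent(), cfg$dhs_props[[class]])
  dhs_ratio <- numeric(n)
  dhs_ratio[dhs_group == "down"] <- runif(sum(dhs_group == "down"), 0.3, 0.9)
  dhs_ratio[dhs_group == "up"] <- runif(sum(dhs_group == "up"), 1.02, 1.33)
  ns <- sum(dhs_group == "strong")
  dhs_ratio[dhs_group == "strong"] <- 1.45 + stats::rlnorm(ns, log(2), 0.5)
  dhs_1d <- stats::rgamma(n, shape = 4, scale = cfg$dhs_base[[class]] / 4)
  dhs_8w <- dhs_1d * dhs_ratio
  dhs_1w <- dhs_1d * sqrt(dhs_ratio)
  polii_group <- group_from_u(latent(), cfg$polii_props[[class]])
  polii_pn2 <- nb(cfg$polii_base)
  delta <- numeric(n)
  delta[polii_group == "none"] <- -stats::rnbinom(sum(polii_group == "none"),
                                                  size = cfg$nb_size, mu = 5)
  delta[polii_group == "low"] <- floor(runif(sum(polii_group == "low"),
                                             1, 181))
  delta[polii_group == "high"] <- 183 + stats::rnbinom(
    sum(polii_group == "high"), size = cfg$nb_size, mu = 150)
  polii_pn25 <- pmax(polii_pn2 + delta, 0)
  tf_draw <- function(p) {
    bound <- latent() > 1 - p
    ifelse(bound, cfg$bound_reads_min +
             stats::rnbinom(n, size = cfg$nb_size, mu = cfg$tf_extra_mu), 0)
  }
  crx_total <- tf_draw(cfg$p_crx[[class]])
  crx_s1 <- stats::rbinom(n, crx_total, 0.5)
  crx_s2 <- crx_total - crx_s1
  nrl <- tf_draw(cfg$p_nrl[[class]])
  mat <- cbind(H3K4me2_E17 = k4_e17, H3K4me2_PN1 = k4_pn1,
               H3K4me2_PN7 = k4_pn7, H3K4me2_PN15 = k4_pn15,
               H3K4me2_RD1 = k4_rd1,
               DHS_1D = dhs_1d, DHS_1W = dhs_1w, DHS_8W = dhs_8w,
               PolII_PN2 = polii_pn2, PolII_PN25 = polii_pn25,
               CRX_S1 = crx_s1, CRX_S2 = crx_s2, NRL = nrl)
  list(mat = mat, has_signature = r >= 3 & dhs_group != "down")
}

# `signature_only = TRUE` redraws loci until every profile actually bears
# the rod signature (clear H3K4me2 developmental gain, no DHS loss):
# planted scan sites emulate loci that *exhibit* the signature, whereas a
# class cohort keeps its faithful marginal tails.
draw_profiles <- function(n, class, cfg, signature_only = FALSE) {
  d <- draw_profiles_once(n, class, cfg)
  mat <- d$mat
  if (signature_only) {
    ok <- d$has_signature
    while (any(!ok)) {
      idx <- which(!ok)
      nd <- draw_profiles_once(length(idx), class, cfg)
      mat[idx, ] <- nd$mat
      ok[idx] <- nd$has_signature
    }
  }
  mat
}

#' Generate a synthetic TSS/chromatin dataset with ground truth
#'
#' Lays out genes on two synthetic chromosomes, assigns one rod TSS per
#' gene (single-TSS genes are rod; multi-TSS genes get exactly one rod and
#' the rest common), draws the 13 chromatin features from the
#' class-conditional laws of [sim_config()], plants `n_planted_sites`
#' rod-profile loci at intronic and intergenic positions, and writes
#' everything as plain-text files: `tss.bed`, `genes.gtf`, `chrom.sizes`,
#' one bedGraph per assay x timepoint under `tracks/`, a `tracks.tsv`
#' manifest (assay, timepoint, file, library_size), and truth tables
#' `truth_tss.tsv` / `truth_sites.tsv`.  The same seed yields
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) a list: `config`, `dir`, `files` (named paths),
#'   `tss` (data.frame with `known_class`), `tracks` (named list of
#'   [signal_track()]), `chrom_sizes`, `truth` (list `tss`, `sites`).
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("rodsig_")) {
  stopifnot(methods::is(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)

  n_genes <- cfg$n_genes_single + cfg$n_genes_two_tss + cfg$n_genes_three_tss
  if (n_genes < 1) stop_input("no genes requested")
  n_tss_per_gene <- rep(c(1L, 2L, 3L),
                        c(cfg$n_genes_single, cfg$n_genes_two_tss,
                          cfg$n_genes_three_tss))
  pitch <- as.integer(cfg$gene_length + cfg$gene_spacing)
  n_chr1 <- ceiling(n_genes / 2)
  gene_chr <- rep(c("chr1", "chr2"), c(n_chr1, n_genes - n_chr1))
  gene_idx_on_chr <- c(seq_len(n_chr1), seq_len(n_genes - n_chr1))
  tx_start <- 6000L + (gene_idx_on_chr - 1L) * pitch
  chrom_sizes <- c(
    chr1 = 6000L + n_chr1 * pitch + 6000L,
    chr2 = 6000L + max(n_genes - n_chr1, 1L) * pitch + 6000L
  )
  gene_id <- sprintf("G%03d", seq_len(n_genes))

  # TSS layout: isoform starts 0 / 3000 / 6000 bp into the gene body
  rel <- list(`1` = 0L, `2` = c(0L, 3000L), `3` = c(0L, 3000L, 6000L))
  tss <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    k <- n_tss_per_gene[i]
    data.frame(gene_id = gene_id[i], chrom = gene_chr[i],
               position = tx_start[i] + rel[[as.character(k)]],
               isoform = seq_len(k), stringsAsFactors = FALSE)
  }))
  tss$tss_id <- sprintf("%s.T%d", tss$gene_id, tss$isoform)
  tss$strand <- "+"
  tss$n_tss_in_gene <- n_tss_per_gene[match(tss$gene_id, gene_id)]
  # exactly one rod TSS per gene; the single TSS of single-TSS genes is rod
  tss$known_class <- "common"
  for (g in gene_id) {
    rows <- which(tss$gene_id == g)
    rod_row <- if (length(rows) == 1) rows else rows[sample.int(length(rows), 1)]
    tss$known_class[rod_row] <- "rod"
  }

  # planted non-TSS rod-signature loci: alternate intron (2.5 kb into a
  # single-TSS gene body) and intergenic (mid-gap downstream of a gene)
  n_sites <- cfg$n_planted_sites
  sites <- NULL
  if (n_sites > 0) {
    n_intron <- ceiling(n_sites / 2)
    n_inter <- n_sites - n_intron
    single_genes <- which(n_tss_per_gene == 1)
    if (length(single_genes) < n_intron || n_genes < n_inter) {
      stop_input("genome too small for requested planted sites")
    }
    host_intron <- sort(sample(single_genes, n_intron))
    host_inter <- sort(sample(seq_len(n_genes), n_inter))
    center <- c(tx_start[host_intron] + 2500L,
                tx_start[host_inter] + as.integer(cfg$gene_length) +
                  as.integer(cfg$gene_spacing / 2))
    sites <- data.frame(
      site_id = sprintf("S%02d", seq_len(n_sites)),
      chrom = c(gene_chr[host_intron], gene_chr[host_inter]),
      center = center,
      start = center - 600L, end = center + 600L,
      context = rep(c("intron", "intergenic"), c(n_intron, n_inter)),
      stringsAsFactors = FALSE
    )
  }

  # class-conditional feature draws
  feat <- matrix(0, nrow(tss), 13,
                 dimnames = list(tss$tss_id, signature_features()$feature))
  for (cls in c("rod", "common")) {
    rows <- tss$known_class == cls
    if (any(rows)) feat[rows, ] <- draw_profiles(sum(rows), cls, cfg)
  }
  site_feat <- NULL
  if (n_sites > 0) {
    site_feat <- draw_profiles(n_sites, "rod", cfg, signature_only = TRUE)
    rownames(site_feat) <- sites$site_id
  }

  # assemble per-feature tracks
  fdef <- signature_features()
  centers <- c(tss$position, if (n_sites > 0) sites$center)
  chroms <- c(tss$chrom, if (n_sites > 0) sites$chrom)
  allfeat <- rbind(feat, site_feat)
  tracks <- list()
  track_files <- character()
  for (j in seq_len(nrow(fdef))) {
    fn <- fdef$feature[j]
    vals <- allfeat[, fn]
    ent <- if (fdef$aggregation[j] == "weighted") {
      weighted_entries(chroms, centers, vals)
    } else {
      count_entries(chroms, as.integer(centers), round(vals))
    }
    ent <- ent[order(ent$chrom, ent$start, ent$end), , drop = FALSE]
    path <- file.path(dir, "tracks", paste0(fn, ".bedGraph"))
    writeLines(sprintf("%s\t%d\t%d\t%s", ent$chrom, ent$start, ent$end,
                       formatC(ent$score, format = "fg", digits = 6,
                               width = 1)), path)
    track_files[fn] <- path
    gr <- gr0(ent$chrom, ent$start, ent$end, score = ent$score)
    tracks[[fn]] <- signal_track(fdef$assay[j], fdef$timepoint[j], gr,
                                 library_size = cfg$library_size)
  }

  # annotation files
  tss_bed <- file.path(dir, "tss.bed")
  o <- order(tss$chrom, tss$position)
  writeLines(sprintf("%s\t%d\t%d\t%s|%s\t0\t+", tss$chrom[o], tss$position[o],
                     tss$position[o] + 1L, tss$gene_id[o], tss$tss_id[o]),
             tss_bed)
  gtf <- file.path(dir, "genes.gtf")
  writeLines(make_gtf_lines(gene_id, gene_chr, tx_start, n_tss_per_gene,
                            rel, cfg$gene_length), gtf)
  cs <- file.path(dir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", names(chrom_sizes), chrom_sizes), cs)
  manifest <- file.path(dir, "tracks.tsv")
  utils::write.table(
    data.frame(assay = fdef$assay, timepoint = fdef$timepoint,
               feature = fdef$feature,
               file = file.path("tracks", paste0(fdef$feature, ".bedGraph")),
               library_size = cfg$library_size, stringsAsFactors = FALSE),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_tss <- file.path(dir, "truth_tss.tsv")
  utils::write.table(tss[, c("tss_id", "gene_id", "chrom", "position",
                             "known_class")],
                     truth_tss, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_sites <- file.path(dir, "truth_sites.tsv")
  if (n_sites > 0) {
    utils::write.table(sites[, c("site_id", "chrom", "start", "end",
                                 "context")],
                       truth_sites, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(data.frame(site_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  context = character()),
                       truth_sites, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  out_tss <- tss[, c("tss_id", "gene_id", "chrom", "position", "strand",
                     "n_tss_in_gene", "known_class")]
  rownames(out_tss) <- NULL
  invisible(list(
    config = cfg, dir = dir,
    files = c(tss = tss_bed, gtf = gtf, chrom_sizes = cs,
              manifest = manifest, truth_tss = truth_tss,
              truth_sites = truth_sites, track_files),
    tss = out_tss, tracks = tracks, chrom_sizes = chrom_sizes,
    truth = list(tss = out_tss[, c("tss_id", "gene_id", "known_class")],
                 sites = sites)
  ))
}

# GTF lines for the synthetic gene models: per isoform a transcript plus
# its exon chain (first exon at the isoform start, then the shared exons)
make_gtf_lines <- function(gene_id, gene_chr, tx_start, n_tss, rel,
                           gene_length) {
  lines <- character()
  gene_length <- as.integer(gene_length)
  shared <- matrix(as.integer(rbind(c(4000L, 4400L), c(9400L, 10000L)) *
                                (gene_length / 10000)), ncol = 2)
  for (i in seq_along(gene_id)) {
    for (k in seq_len(n_tss[i])) {
      r <- rel[[as.character(n_tss[i])]][k]
      txid <- sprintf("%s.T%d", gene_id[i], k)
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gene_id[i], txid)
      exon_start <- as.integer(c(r, shared[shared[, 1] >= r + 600L, 1]))
      exon_end <- as.integer(c(r + 600L, shared[shared[, 1] >= r + 600L, 2]))
      lines <- c(lines,
        sprintf("%s\trodsig_sim\ttranscript\t%d\t%d\t.\t+\t.\t%s",
                gene_chr[i], tx_start[i] + r + 1L,
                tx_start[i] + gene_length, attrs),
        sprintf("%s\trodsig_sim\texon\t%d\t%d\t.\t+\t.\t%s",
                gene_chr[i], tx_start[i] + exon_start + 1L,
                tx_start[i] + exon_end, attrs))
    }
  }
  lines
}

#' Compare predictions against generator ground truth
#'
#' Two modes.  Label mode (`predicted` has `tss_id`/`class` or is a named
#' vector): accuracy over all truth TSS, recall of the rod class, and the
#' false-discovery fraction among predicted rod.  Site mode (`predicted`
#' has `chrom`/`start`/`end`): recall = fraction of truth sites overlapped
#' by at least 1 bp, fdr = fraction of predicted sites overlapping no
#' truth site; accuracy is `NA` (no per-object identity).
#'
#' @param predicted predictions (see above).
#' @param truth the matching element of `simulate_dataset()$truth`
#'   (`$tss` or `$sites`).
#' @return list `accuracy`, `recall`, `fdr` (each in \[0, 1\] or NA).
#' @export
truth_compare <- function(predicted, truth) {
  if (is.data.frame(predicted) && all(c("chrom", "start", "end") %in%
                                      names(predicted))) {
    if (!is.data.frame(truth) || !all(c("chrom", "start", "end") %in%
                                      names(truth))) {
      stop_input("site predictions need a site truth table")
    }
    if (!nrow(truth)) stop_input("empty site truth table")
    tg <- gr0(truth$chrom, truth$start, truth$end)
    if (!nrow(predicted)) {
      return(list(accuracy = NA_real_, recall = 0, fdr = NA_real_))
    }
    pg <- gr0(predicted$chrom, predicted$start, predicted$end)
    recall <- mean(GenomicRanges::countOverlaps(tg, pg) > 0)
    fdr <- mean(GenomicRanges::countOverlaps(pg, tg) == 0)
    return(list(accuracy = NA_real_, recall = recall, fdr = fdr))
  }
  if (is.data.frame(predicted)) {
    pred <- stats::setNames(as.character(predicted$class), predicted$tss_id)
  } else {
    pred <- stats::setNames(as.character(predicted), names(predicted))
  }
  unknown <- setdiff(names(pred), truth$tss_id)
  if (length(unknown)) {
    stop_input("unknown ids: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  tr <- stats::setNames(truth$known_class %||% truth$class, truth$tss_id)
  common_ids <- intersect(truth$tss_id, names(pred))
  if (!length(common_ids)) stop_input("no overlapping ids")
  p <- pred[common_ids]; t <- tr[common_ids]
  list(accuracy = mean(p == t),
       recall = if (any(t == "rod")) mean(p[t == "rod"] == "rod") else NA_real_,
       fdr = if (any(p == "rod")) mean(t[p == "rod"] != "rod") else NA_real_)
}
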