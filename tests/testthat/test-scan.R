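# Genome tiling, signature scoring, hit merging and context annotation.

scan_setup <- function() {
  s <- default_sim()
  if (is.null(sim_cache$scan)) {
    st <- quiet(derive_stats(s$se, preset = "fixed"))
    rule <- classify_rod_signature(st)
    sim_cache$scan <- list(
      st = st, rule = rule,
      gm = read_gene_models(s$sim$files[["gtf"]]),
      cen = class_centroids(s$se, setNames(as.character(rule$class),
                                           rule$tss_id)),
      ktss = data.frame(chrom = s$sim$tss$chrom,
                        position = s$sim$tss$position))
  }
  c(s, sim_cache$scan)
}

test_that("tile_genome emits clipped, covering, half-open tiles", {
  tiles <- tile_genome(c(chrA = 5000), window = 2000, step = 500)
  expect_equal(length(tiles), 8)
  expect_equal(GenomicRanges::start(tiles)[1] - 1L, 0L)
  expect_equal(GenomicRanges::end(tiles)[1], 2000L)
  expect_equal(GenomicRanges::start(tiles)[8] - 1L, 3500L)
  expect_equal(GenomicRanges::end(tiles)[8], 5000L)
  # a chromosome shorter than the window gives one clipped tile
  short <- tile_genome(c(chrB = 900), 2000, 500)
  expect_equal(length(short), 1)
  expect_equal(GenomicRanges::end(short), 900L)
  # the union of tiles covers the chromosome
  cov <- GenomicRanges::reduce(tiles)
  expect_equal(length(cov), 1)
  expect_equal(GenomicRanges::width(cov), 5000L)
  expect_error(tile_genome(c(chrA = 5000), window = 100, step = 500))
})

test_that("centroid scoring passes rod-profile windows and rejects
           degenerate ones", {
  ss <- scan_setup()
  m <- assay(ss$se, "cpm")
  truth <- setNames(ss$sim$truth$tss$known_class, ss$sim$truth$tss$tss_id)
  fm <- list(raw = m, cpm = m)
  sc <- score_windows(fm, path = "centroid", centroids = ss$cen)
  # strong separation: most rod TSS windows pass, most common do not
  expect_gt(mean(sc$passes[truth[rownames(m)] == "rod"]), 0.75)
  expect_lt(mean(sc$passes[truth[rownames(m)] == "common"]), 0.25)
  # an all-zero window never passes
  zero <- matrix(0, 2, 13, dimnames = list(NULL, colnames(m)))
  sc0 <- score_windows(list(raw = zero, cpm = zero), "centroid",
                       centroids = ss$cen)
  expect_false(any(sc0$passes))
  # a window equal to the common centroid profile fails
  common_prof <- ss$cen$common * ss$cen$scale + ss$cen$center
  mc <- rbind(common_prof, common_prof)
  colnames(mc) <- colnames(m)
  scc <- score_windows(list(raw = mc, cpm = mc), "centroid",
                       centroids = ss$cen)
  expect_false(any(scc$passes))
  expect_error(score_windows(fm, "centroid"), "centroids")
})

test_that("rule scoring counts satisfied criteria", {
  ss <- scan_setup()
  m <- assay(ss$se, "counts")
  sc <- quiet(score_windows(list(raw = m, cpm = assay(ss$se, "cpm")),
                            path = "rule"))
  expect_equal(sc$passes,
               as.character(ss$rule$class) == "rod", ignore_attr = TRUE)
  expect_true(all(sc$score >= 0 & sc$score <= 6))
  expect_true(all(sc$score[sc$passes] >= 3))
})

test_that("merge_hits unions overlapping tiles and keeps the best score", {
  t1 <- GRanges("chr1", IRanges(c(1, 501), c(2000, 2500)))
  merged <- merge_hits(t1, c(0.2, 0.7))
  expect_equal(length(merged), 1)
  expect_equal(GenomicRanges::start(merged) - 1L, 0L)
  expect_equal(GenomicRanges::end(merged), 2500L)
  expect_equal(merged$score, 0.7)
  # disjoint tiles 10 kb apart stay separate at max_gap 0
  t2 <- GRanges("chr1", IRanges(c(1, 12001), c(2000, 14000)))
  expect_equal(length(merge_hits(t2, c(1, 1))), 2)
  # bridged when the gap is allowed
  expect_equal(length(merge_hits(t2, c(1, 1), max_gap = 10000)), 1)
  # merged count equals a brute-force union oracle on random fixtures
  set.seed(13)
  for (i in 1:5) {
    n <- 60
    start <- sample(0:50000, n)
    tiles <- GRanges("chr1", IRanges(start + 1, start + 2000))
    expect_equal(length(merge_hits(tiles, rep(0, n))),
                 oracle_union_count(start, start + 2000))
  }
})

test_that("context annotation follows the precedence rules on constructed
           gene models", {
  gtf <- tempfile(fileext = ".gtf")
  attrs <- 'gene_id "GX"; transcript_id "GX.T1";'
  writeLines(c(
    sprintf("chr1\ttest\ttranscript\t5001\t15000\t.\t+\t.\t%s", attrs),
    sprintf("chr1\ttest\texon\t5001\t5600\t.\t+\t.\t%s", attrs),
    sprintf("chr1\ttest\texon\t9001\t9400\t.\t+\t.\t%s", attrs),
    sprintf("chr1\ttest\texon\t14401\t15000\t.\t+\t.\t%s", attrs)), gtf)
  gm <- read_gene_models(gtf)
  site <- function(s, e) rodsig:::gr0("chr1", s, e)
  ctx <- function(s, e) as.character(annotate_context(site(s, e), gm)$context)
  expect_equal(ctx(5200, 5400), "promoter")    # 300 bp from the TSS
  expect_equal(ctx(7000, 8000), "intron")      # inside body, no feature
  expect_equal(ctx(9100, 9300), "exon")        # midpoint inside exon 2
  expect_equal(ctx(14100, 14300), "TES")       # within 1000 bp of the end
  expect_equal(ctx(40000, 41000), "intergenic")
  # promoter wins over exon when both apply (midpoint in exon 1)
  expect_equal(ctx(5050, 5250), "promoter")
  ann <- annotate_context(site(7000, 8000), gm)
  expect_equal(ann$nearest_gene, "GX")
})

test_that("context summaries reproduce pie-chart bookkeeping", {
  hits <- data.frame(context = factor(rep(c("promoter", "exon", "TES",
                                            "intron", "intergenic"),
                                          c(132, 12, 12, 312, 132)),
                                      levels = c("promoter", "TES", "exon",
                                                 "intron", "intergenic")))
  gs <- summarize_contexts(hits)
  expect_equal(gs$percent[gs$group == "promoter"], 22)
  expect_equal(gs$percent[gs$group == "intron"], 52)
  expect_lte(abs(sum(gs$percent) - 100), 1)
  expect_error(summarize_contexts(hits[0, , drop = FALSE]), "no hits")
})

test_that("the genome scan recovers planted loci with matching contexts
           and is deterministic", {
  ss <- scan_setup()
  hits <- scan_genome(ss$sim$tracks, ss$sim$chrom_sizes, ss$gm,
                      centroids = ss$cen, known_tss = ss$ktss)
  tc <- truth_compare(hits, ss$sim$truth$sites)
  expect_gt(tc$recall, 0.75)
  expect_lt(tc$fdr, 0.1)
  # recovered sites carry the planted genomic context
  tg <- rodsig:::gr0(ss$sim$truth$sites$chrom, ss$sim$truth$sites$start,
                     ss$sim$truth$sites$end)
  pg <- rodsig:::gr0(hits$chrom, hits$start, hits$end)
  ov <- GenomicRanges::findOverlaps(tg, pg)
  expect_equal(as.character(hits$context[S4Vectors::subjectHits(ov)]),
               ss$sim$truth$sites$context[S4Vectors::queryHits(ov)])
  # deterministic
  hits2 <- scan_genome(ss$sim$tracks, ss$sim$chrom_sizes, ss$gm,
                       centroids = ss$cen, known_tss = ss$ktss)
  expect_identical(hits, hits2)
})

test_that("with annotated-TSS exclusion off the scan recognizes rod but
           not common promoters", {
  ss <- scan_setup()
  hits <- scan_genome(ss$sim$tracks, ss$sim$chrom_sizes, ss$gm,
                      centroids = ss$cen, known_tss = ss$ktss,
                      exclude_tss = FALSE)
  hg <- rodsig:::gr0(hits$chrom, hits$start, hits$end)
  truth <- ss$sim$truth$tss
  win <- function(cls) {
    t <- ss$sim$tss[ss$sim$tss$known_class == cls, ]
    rodsig:::gr0(t$chrom, pmax(t$position - 1000, 0), t$position + 1000)
  }
  rod_rec <- mean(GenomicRanges::countOverlaps(win("rod"), hg) > 0)
  com_rec <- mean(GenomicRanges::countOverlaps(win("common"), hg) > 0)
  expect_gt(rod_rec, 0.75)
  expect_lt(com_rec, 0.25)
  expect_gt(rod_rec - com_rec, 0.5)
})

test_that("scan hits export as valid UCSC-scaled BED", {
  ss <- scan_setup()
  hits <- scan_genome(ss$sim$tracks, ss$sim$chrom_sizes, ss$gm,
                      centroids = ss$cen, known_tss = ss$ktss)
  f <- tempfile(fileext = ".bed")
  write_scan_bed(hits, f)
  d <- read.table(f, sep = "\t")
  expect_equal(nrow(d), nrow(hits))
  expect_true(all(d$V5 >= 0 & d$V5 <= 1000))
})
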