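# Domain types and readers/writers for the standard formats the pipeline
# touches.  Coordinates follow the BED convention (0-based half-open) at
# every file boundary and in user-facing TSS positions; interval arithmetic
# is delegated to GenomicRanges internally.

#' The 13-feature chromatin signature
#'
#' Each TSS is characterized by 13 chromatin features: H3K4me2 occupancy at
#' five developmental points (E17, PN1, PN7, PN15 and in the rod-less RD1
#' mutant at PN30), DNase I hypersensitivity at three points (1D, 1W, 8W),
#' PolII occupancy at PN2 and PN25, CRX binding (two ChIP samples S1, S2)
#' and NRL binding (PN28).  Read-based assays are aggregated by counting
#' scored entries overlapping the TSS window; DHS is aggregated as
#' intersecting basepairs times entry score.
#'
#' @return A data.frame with one row per feature: `feature` (column name in
#'   the feature matrix), `assay`, `timepoint`, and `aggregation`
#'   (`"count"` or `"weighted"`).
#' @export
#' @examples
#' signature_features()
signature_features <- function() {
  data.frame(
    feature = c("H3K4me2_E17", "H3K4me2_PN1", "H3K4me2_PN7", "H3K4me2_PN15",
                "H3K4me2_RD1", "DHS_1D", "DHS_1W", "DHS_8W",
                "PolII_PN2", "PolII_PN25", "CRX_S1", "CRX_S2", "NRL"),
    assay = c(rep("H3K4me2", 5), rep("DHS", 3), rep("PolII", 2),
              rep("CRX", 2), "NRL"),
    timepoint = c("E17", "PN1", "PN7", "PN15", "RD1", "1D", "1W", "8W",
                  "PN2", "PN25", "S1", "S2", "PN28"),
    aggregation = c(rep("count", 5), rep("weighted", 3), rep("count", 5)),
    stringsAsFactors = FALSE
  )
}

#' Construct a signal track
#'
#' A signal track holds the scored genomic intervals of one assay at one
#' timepoint plus a library-size normalizer.  Entries are kept as-is
#' (overlaps are meaningful in peak/score files and all contribute to
#' aggregation) but stored sorted by (chrom, start).
#'
#' @param assay assay name, one of H3K4me2, CRX, NRL, PolII, DHS.
#' @param timepoint timepoint label (e.g. "E17", "PN1", "8W", "S1").
#' @param gr a [GenomicRanges::GRanges] with a numeric `score` column;
#'   scores must be non-negative.
#' @param library_size total read/score mass used for normalization;
#'   defaults to `sum(score * width)`.  Must be positive; an empty track
#'   falls back to 1 with a message.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(assay, timepoint, gr, library_size = NULL) {
  stopifnot(methods::is(gr, "GRanges"))
  if (is.null(gr$score)) gr$score <- rep(1, length(gr))
  if (any(gr$score < 0)) {
    stop_input("negative scores in ", assay, "@", timepoint, " track")
  }
  o <- order_gr(gr)
  if (is.unsorted(o)) {
    rs_msg("sorting unsorted track ", assay, "@", timepoint)
    gr <- gr[o]
  }
  if (is.null(library_size)) {
    library_size <- sum(gr$score * GenomicRanges::width(gr))
  }
  if (library_size <= 0) {
    rs_msg("track ", assay, "@", timepoint,
           " has zero score mass; library_size set to 1")
    library_size <- 1
  }
  structure(
    list(assay = assay, timepoint = timepoint, gr = gr,
         library_size = library_size),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s @ %s: %d entries, library size %.4g\n",
              x$assay, x$timepoint, length(x$gr), x$library_size))
  invisible(x)
}

check_fields <- function(path, min_fields) {
  nf <- utils::count.fields(path, comment.char = "#")
  if (length(nf) == 0) return(invisible(0L))
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stop_input(sprintf("%s: line %d has %d fields (need >= %d)",
                       path, bad[1], nf[bad[1]], min_fields))
  }
  invisible(length(nf))
}

#' Read TSS annotations from a BED6 file
#'
#' The BED name column must encode `gene_id|tss_id`.  Positions are kept
#' 0-based (the BED start of the single-bp TSS interval).  Because RefSeq
#' isoform starts are given at single-bp resolution, distinct TSS records of
#' one gene closer than `collapse_bp` would double-count one promoter; such
#' records are collapsed onto the first (logged).
#'
#' @param path BED6 file.
#' @param collapse_bp same-gene TSS closer than this many bp are collapsed
#'   into one record (default 50); set 0 to disable.
#' @return data.frame with columns `tss_id`, `gene_id`, `chrom`, `position`
#'   (0-based bp), `strand`, `n_tss_in_gene`.
#' @export
read_tss_bed <- function(path, collapse_bp = 50) {
  n <- check_fields(path, 6)
  empty <- data.frame(tss_id = character(), gene_id = character(),
                      chrom = character(), position = integer(),
                      strand = character(), n_tss_in_gene = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  d <- utils::read.table(path, sep = "", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "character", "character"))
  bad <- which(is.na(d$start) | is.na(d$end) | d$start < 0 | d$end <= d$start)
  if (length(bad)) {
    stop_input(sprintf("%s: line %d: invalid interval", path, bad[1]))
  }
  parts <- strsplit(d$name, "|", fixed = TRUE)
  badname <- which(lengths(parts) != 2)
  if (length(badname)) {
    stop_input(sprintf("%s: line %d: name '%s' is not gene_id|tss_id",
                       path, badname[1], d$name[badname[1]]))
  }
  badstrand <- which(!d$strand %in% c("+", "-", "."))
  if (length(badstrand)) {
    stop_input(sprintf("%s: line %d: bad strand '%s'", path,
                       badstrand[1], d$strand[badstrand[1]]))
  }
  out <- data.frame(
    tss_id = vapply(parts, `[`, "", 2),
    gene_id = vapply(parts, `[`, "", 1),
    chrom = d$chrom,
    position = d$start,
    strand = d$strand,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out$tss_id)
  if (any(dup)) {
    stop_input("duplicate tss_id: ", paste(unique(out$tss_id[dup]),
                                           collapse = ", "))
  }
  if (collapse_bp > 0 && nrow(out) > 1) {
    o <- order(out$gene_id, out$chrom, out$position)
    out <- out[o, , drop = FALSE]
    same_gene <- c(FALSE, out$gene_id[-1] == out$gene_id[-nrow(out)] &
                     out$chrom[-1] == out$chrom[-nrow(out)])
    too_close <- c(FALSE, diff(out$position) < collapse_bp) & same_gene
    if (any(too_close)) {
      rs_msg("collapsing ", sum(too_close), " TSS within ", collapse_bp,
             " bp of a same-gene neighbour: ",
             paste(out$tss_id[too_close], collapse = ", "))
      out <- out[!too_close, , drop = FALSE]
    }
  }
  out$n_tss_in_gene <- as.integer(table(out$gene_id)[out$gene_id])
  rownames(out) <- NULL
  out
}

#' Read a scored interval track (bedGraph or scored BED)
#'
#' Accepts 4-column bedGraph (`chrom start end score`) or BED5+ with the
#' score in column 5.  Entries are validated (non-negative scores), sorted
#' if needed (logged), and overlapping entries are retained as-is.
#'
#' @inheritParams signal_track
#' @param path input file.
#' @return a [signal_track()].
#' @export
read_track_bedgraph <- function(path, assay, timepoint, library_size = NULL) {
  nf <- utils::count.fields(path, comment.char = "#")
  if (length(nf) == 0) {
    return(signal_track(assay, timepoint,
                        GenomicRanges::GRanges(score = numeric()),
                        library_size))
  }
  bad <- which(nf < 4)
  if (length(bad)) {
    stop_input(sprintf("%s: line %d has %d fields (need 4 bedGraph or >=5 BED)",
                       path, bad[1], nf[bad[1]]))
  }
  d <- utils::read.table(path, sep = "", stringsAsFactors = FALSE,
                         fill = TRUE, header = FALSE)
  score <- if (max(nf) >= 5 && min(nf) >= 5) {
    suppressWarnings(as.numeric(d[[5]]))
  } else {
    suppressWarnings(as.numeric(d[[4]]))
  }
  if (anyNA(score)) {
    stop_input(sprintf("%s: line %d: non-numeric score", path,
                       which(is.na(score))[1]))
  }
  if (any(score < 0)) {
    stop_input(sprintf("%s: line %d: negative score", path,
                       which(score < 0)[1]))
  }
  badiv <- which(d[[2]] < 0 | d[[3]] <= d[[2]])
  if (length(badiv)) {
    stop_input(sprintf("%s: line %d: invalid interval", path, badiv[1]))
  }
  gr <- gr0(d[[1]], as.integer(d[[2]]), as.integer(d[[3]]), score = score)
  signal_track(assay, timepoint, gr, library_size)
}

#' Read a chromosome sizes file
#'
#' @param path two-column TSV (`chrom  length`).
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "", stringsAsFactors = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "integer"))
  if (any(d$size <= 0)) stop_input("non-positive chromosome size in ", path)
  stats::setNames(d$size, d$chrom)
}

#' Read gene models from a GTF file
#'
#' Gene models supply the genomic-context categories used when annotating
#' scan hits (promoter, exon, TES, intron, intergenic).  Transcript starts
#' define TSS positions, the far end of the gene its TES; exons of all
#' isoforms are unioned.
#'
#' @param path GTF file with `transcript` and `exon` features carrying
#'   `gene_id` attributes.
#' @return object of class `gene_models`: list with `genes` (data.frame:
#'   `gene_id`, `chrom`, `strand`, `tx_start`/`tx_end` 0-based half-open,
#'   `tes` 0-based bp), `exons` (GRanges with `gene_id`), and `tss`
#'   (data.frame: `gene_id`, `chrom`, `position` 0-based).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!length(gr)) stop_input("no features in ", path)
  tx <- gr[gr$type == "transcript"]
  ex <- gr[gr$type == "exon"]
  if (!length(tx)) stop_input("no transcript features in ", path)
  neg <- as.character(GenomicRanges::strand(tx)) == "-"
  tss_pos <- ifelse(neg, end0(tx) - 1L, start0(tx))
  tss <- unique(data.frame(gene_id = tx$gene_id,
                           chrom = as.character(GenomicRanges::seqnames(tx)),
                           position = tss_pos, stringsAsFactors = FALSE))
  spl <- split(seq_along(tx), tx$gene_id)
  genes <- do.call(rbind, lapply(names(spl), function(g) {
    i <- spl[[g]]
    s <- as.character(GenomicRanges::strand(tx[i][1]))
    lo <- min(start0(tx[i])); hi <- max(end0(tx[i]))
    data.frame(gene_id = g,
               chrom = as.character(GenomicRanges::seqnames(tx[i][1])),
               strand = s, tx_start = lo, tx_end = hi,
               tes = if (s == "-") lo else hi - 1L,
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chrom, genes$tx_start), , drop = FALSE]
  rownames(genes) <- NULL
  exons <- GenomicRanges::GRanges()
  if (length(ex)) {
    red <- lapply(split(ex, ex$gene_id), function(e) {
      r <- GenomicRanges::reduce(e, ignore.strand = TRUE)
      r$gene_id <- rep(e$gene_id[1], length(r))
      r
    })
    exons <- unlist(methods::as(red, "GRangesList"), use.names = FALSE)
    exons <- exons[order_gr(exons)]
  }
  structure(list(genes = genes, exons = exons,
                 tss = tss[order(tss$chrom, tss$position), , drop = FALSE]),
            class = "gene_models")
}

#' Write intervals to a BED6 file
#'
#' Output is deterministically ordered by (chrom, start, end) and written
#' in BED convention (0-based half-open), loadable in the UCSC genome
#' browser.  Reading a file written by this function and writing it again
#' is byte-stable.
#'
#' @param gr a GRanges; optional metadata columns `name` and `score` are
#'   used for BED columns 4-5.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  if (length(gr)) gr <- gr[order_gr(gr)]
  name <- if (!is.null(gr$name)) as.character(gr$name) else rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   start0(gr), end0(gr), name,
                   formatC(score, format = "fg", digits = 6, width = 1),
                   strand)
  writeLines(lines, path)
  invisible(path)
}
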