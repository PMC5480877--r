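# Aggregation of assay tracks in the TSS +/- halfwidth window and assembly
# of the 13-feature matrix.

#' Symmetric windows around TSS positions
#'
#' Builds the `position +/- halfwidth` analysis window (0-based half-open
#' `[position - halfwidth, position + halfwidth)`) for each TSS, clipped at
#' zero and at the chromosome end when sizes are supplied.  Windows are
#' symmetric about the TSS, so strand does not affect aggregation.
#'
#' @param tss data.frame as returned by [read_tss_bed()] (needs `chrom`,
#'   `position`, optionally `tss_id` used for names), or a single-row
#'   equivalent.
#' @param halfwidth window half-width in bp (default 1000).
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   given, positions beyond the chromosome end are an error and windows
#'   are clipped at the end.
#' @return GRanges of windows, named by `tss_id` when present.
#' @export
window_around_tss <- function(tss, halfwidth = 1000, chrom_sizes = NULL) {
  stopifnot(halfwidth > 0)
  if (any(tss$position < 0)) stop_input("negative TSS position")
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(tss$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop_input("chromosomes missing from sizes: ",
                 paste(unknown, collapse = ", "))
    }
    len <- chrom_sizes[tss$chrom]
    beyond <- which(tss$position >= len)
    if (length(beyond)) {
      stop_input("TSS position beyond chromosome end: ",
                 paste(tss$tss_id[beyond] %||% beyond, collapse = ", "))
    }
    end <- pmin(tss$position + halfwidth, len)
  } else {
    end <- tss$position + halfwidth
  }
  start <- pmax(tss$position - halfwidth, 0)
  w <- gr0(tss$chrom, start, end)
  if (!is.null(tss$tss_id)) names(w) <- tss$tss_id
  w
}

#' Aggregate a track over windows by entry counting
#'
#' Read-count semantics: every track entry overlapping a window contributes
#' its score once, regardless of how much of it lies inside the window.
#' Used for the read-based assays (H3K4me2, CRX, NRL, PolII).
#'
#' @param track a [signal_track()].
#' @param windows GRanges of analysis windows.
#' @return numeric vector, one non-negative total per window.
#' @export
aggregate_count <- function(track, windows) {
  stopifnot(methods::is(track, "signal_track"))
  out <- numeric(length(windows))
  if (!length(track$gr) || !length(windows)) return(out)
  ov <- GenomicRanges::findOverlaps(track$gr, windows, ignore.strand = TRUE)
  if (length(ov)) {
    s <- rowsum(track$gr$score[S4Vectors::queryHits(ov)],
                S4Vectors::subjectHits(ov))
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Aggregate a track over windows by basepair-weighted score
#'
#' Each entry contributes the number of basepairs it intersects with the
#' window times its score.  Used for DHS tracks.  Additive under window
#' splitting: the value on `[a,c)` equals the sum over `[a,b)` and `[b,c)`.
#'
#' @inheritParams aggregate_count
#' @return numeric vector, one non-negative total per window.
#' @export
aggregate_weighted <- function(track, windows) {
  stopifnot(methods::is(track, "signal_track"))
  out <- numeric(length(windows))
  if (!length(track$gr) || !length(windows)) return(out)
  ov <- GenomicRanges::findOverlaps(track$gr, windows, ignore.strand = TRUE)
  if (length(ov)) {
    inter <- GenomicRanges::pintersect(
      track$gr[S4Vectors::queryHits(ov)],
      windows[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE
    )
    contrib <- GenomicRanges::width(inter) *
      track$gr$score[S4Vectors::queryHits(ov)]
    s <- rowsum(contrib, S4Vectors::subjectHits(ov))
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Library-size normalization (counts per million by default)
#'
#' @param value raw aggregate value(s).
#' @param library_size positive library size.
#' @param scale scale factor (default 1e6).
#' @return `value * scale / library_size`.
#' @export
normalize_count <- function(value, library_size, scale = 1e6) {
  if (any(library_size <= 0)) stop_input("library_size must be positive")
  value * scale / library_size
}

# Raw and normalized feature matrices for arbitrary windows.
window_feature_matrix <- function(windows, tracks, scale = 1e6) {
  feat <- signature_features()
  key <- paste(feat$assay, feat$timepoint, sep = "@")
  have <- vapply(tracks, function(t) paste(t$assay, t$timepoint, sep = "@"), "")
  idx <- match(key, have)
  if (anyNA(idx)) {
    stop_input("missing required track(s): ",
               paste(key[is.na(idx)], collapse = ", "))
  }
  raw <- vapply(seq_len(nrow(feat)), function(j) {
    tr <- tracks[[idx[j]]]
    if (feat$aggregation[j] == "weighted") {
      aggregate_weighted(tr, windows)
    } else {
      aggregate_count(tr, windows)
    }
  }, numeric(length(windows)))
  raw <- matrix(raw, nrow = length(windows), ncol = nrow(feat),
                dimnames = list(names(windows), feat$feature))
  libs <- vapply(tracks[idx], `[[`, 1, "library_size")
  cpm <- sweep(raw, 2, libs / scale, "/")
  list(raw = raw, cpm = cpm, library_size = stats::setNames(libs, feat$feature))
}

#' Build the per-TSS 13-feature matrix
#'
#' Aggregates every required assay x timepoint track over each TSS window
#' and returns a [SummarizedExperiment::SummarizedExperiment] with TSS as
#' rows and the 13 signature features as columns, carrying a raw-aggregate
#' assay (`"counts"`) and a library-size-normalized assay (`"cpm"`,
#' counts per million).
#'
#' @param tss TSS data.frame from [read_tss_bed()].
#' @param tracks list of [signal_track()] covering all 13 assay x timepoint
#'   combinations of [signature_features()]; a missing combination is an
#'   error naming it.
#' @param halfwidth analysis window half-width in bp (default 1000).
#' @param chrom_sizes optional chromosome lengths for window clipping.
#' @param scale normalization scale (default 1e6).
#' @return SummarizedExperiment (rows = TSS with `rowData` from `tss`,
#'   columns = features with `colData` assay/timepoint/aggregation/
#'   library_size).
#' @export
build_feature_matrix <- function(tss, tracks, halfwidth = 1000,
                                 chrom_sizes = NULL, scale = 1e6) {
  windows <- window_around_tss(tss, halfwidth, chrom_sizes)
  fm <- window_feature_matrix(windows, tracks, scale)
  feat <- signature_features()
  feat$library_size <- unname(fm$library_size)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = fm$raw, cpm = fm$cpm),
    rowData = S4Vectors::DataFrame(tss, row.names = tss$tss_id),
    colData = S4Vectors::DataFrame(feat, row.names = feat$feature)
  )
}

#' Export a feature matrix (plus optional derived columns) as TSV
#'
#' @param se SummarizedExperiment from [build_feature_matrix()].
#' @param path output TSV path.
#' @param assay_name which assay to write (default `"cpm"`).
#' @param extra optional data.frame of extra columns (same row order).
#' @return the path, invisibly.
#' @export
write_feature_tsv <- function(se, path, assay_name = "cpm", extra = NULL) {
  m <- as.data.frame(SummarizedExperiment::assay(se, assay_name))
  out <- cbind(tss_id = rownames(m), m, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
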