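# Derived per-TSS statistics, thresholds, group classification and the
# bookkeeping summaries used throughout the analysis.

#' Binding call from aggregated ChIP reads
#'
#' CRX and NRL binding near TSS is clearly bimodal: unbound TSS have 0
#' reads in the window and bound TSS have several hundred.  Accordingly,
#' 0 reads is classified as no binding and everything above as positive
#' binding.  The call is monotone in the read count.
#'
#' @param reads non-negative read count(s).
#' @return logical vector, `TRUE` for bound.
#' @export
#' @examples
#' call_binding(c(0, 1, 350))
call_binding <- function(reads) {
  if (any(reads < 0)) stop_input("negative read count")
  reads > 0
}

#' Mean plus two sample standard deviations
#'
#' The threshold rule used for both the strong PolII up-regulation cutoff
#' (reference value 182) and the strong DHS increase cutoff (reference
#' value 1.35): both were derived from the data as mean + 2 SD.
#'
#' @param values numeric vector of at least 2 values.
#' @return `mean(values) + 2 * sd(values)`.
#' @export
mean_plus_2sd <- function(values) {
  if (length(values) < 2) stop_input("need at least 2 values")
  mean(values) + 2 * stats::sd(values)
}

#' Classification thresholds
#'
#' Bundles the cutoffs of the signature rules.  `t_polii` and
#' `t_dhs_strong` default to the reference values (182 and 1.35, each
#' mean + 2 SD in the mouse retina datasets the signature was developed
#' on); [derive_stats()] can instead recompute them from the input TSS set
#' with [mean_plus_2sd()].  `t_dhs_up = 1` separates developmental DHS
#' loss from gain and is fixed.  `k4_ratio_min` gates the rule-based rod
#' call on the H3K4me2 PN15/PN1 developmental ratio: the constitutive
#' class averages a ratio of 2.6 and the rod class 10.1, so the default
#' gate sits between them at 3.  `pseudocount` is added to both terms of
#' every developmental ratio so zero-coverage windows stay defined.
#'
#' @param t_polii strong PolII up-regulation cutoff on delta PolII.
#' @param t_dhs_strong strong DHS increase cutoff on the 8W/1D ratio.
#' @param k4_ratio_min rule-based rod gate on the H3K4me2 PN15/PN1 ratio.
#' @param pseudocount pseudocount for developmental ratios.
#' @return object of class `rod_thresholds` (a validated list, with
#'   `t_dhs_up` fixed at 1).
#' @export
rod_thresholds <- function(t_polii = 182, t_dhs_strong = 1.35,
                           k4_ratio_min = 3, pseudocount = 1) {
  stopifnot(t_polii > 0, t_dhs_strong > 1, k4_ratio_min > 0, pseudocount >= 0)
  structure(list(t_polii = t_polii, t_dhs_strong = t_dhs_strong,
                 t_dhs_up = 1, k4_ratio_min = k4_ratio_min,
                 pseudocount = pseudocount),
            class = "rod_thresholds")
}

#' Developmental ratio with pseudocount
#'
#' `(late + pseudocount) / (early + pseudocount)`; with the default
#' pseudocount 1, a window with no signal at either timepoint gets the
#' neutral ratio 1.
#'
#' @param late,early non-negative signal values.
#' @param pseudocount non-negative pseudocount.
#' @return numeric ratio(s).
#' @export
dev_ratio <- function(late, early, pseudocount = 1) {
  if (pseudocount < 0) stop_input("pseudocount must be >= 0")
  den <- early + pseudocount
  if (any(den == 0)) stop_input("zero denominator (early = 0, pseudocount = 0)")
  (late + pseudocount) / den
}

#' Classify developmental PolII change into none / low / high
#'
#' Partitions delta PolII (PN25 - PN2): no binding change or a decrease
#' (`delta <= 0`) is `none`; `0 < delta <= t_polii` is `low`
#' (up-regulated); `delta > t_polii` is `high` (strongly up-regulated).
#' The boundary value goes to the lower group so the three groups
#' partition the real line.
#'
#' @param delta numeric delta PolII value(s).
#' @param t_polii positive cutoff (reference value 182).
#' @return factor with levels none, low, high.
#' @export
classify_polii <- function(delta, t_polii = 182) {
  stopifnot(t_polii > 0)
  factor(ifelse(delta <= 0, "none", ifelse(delta <= t_polii, "low", "high")),
         levels = c("none", "low", "high"))
}

#' Classify developmental DHS change into down / up / strong
#'
#' Partitions the DHS 8W/1D ratio: `< 1` is `down` (hypersensitivity lost
#' during development), `1 <= ratio <= t_strong` is `up`, `> t_strong` is
#' `strong`.  The boundary value goes to the lower group.
#'
#' @param ratio positive DHS developmental ratio(s).
#' @param t_strong cutoff above 1 (reference value 1.35).
#' @return factor with levels down, up, strong.
#' @export
classify_dhs <- function(ratio, t_strong = 1.35) {
  stopifnot(t_strong > 1)
  if (any(ratio <= 0)) stop_input("DHS ratio must be positive")
  factor(ifelse(ratio < 1, "down", ifelse(ratio <= t_strong, "up", "strong")),
         levels = c("down", "up", "strong"))
}

#' Derive per-TSS signature statistics from the feature matrix
#'
#' Computes, for every TSS: the H3K4me2 PN15/PN1 developmental ratio (on
#' normalized values), whether H3K4me2 in the rod-less RD1 retina is
#' depleted below PN15, delta PolII (PN25 - PN2), the DHS 8W/1D ratio,
#' CRX binding (S1 + S2 reads) and NRL binding calls on raw counts, and
#' the PolII / DHS developmental groups.
#'
#' @param se SummarizedExperiment from [build_feature_matrix()].
#' @param thresholds a [rod_thresholds()].
#' @param preset `"fixed"` uses `thresholds` as given; `"data"` recomputes
#'   `t_polii` as mean + 2 SD of the positive delta PolII values and
#'   `t_dhs_strong` as mean + 2 SD of the DHS ratios of the input TSS set
#'   (falling back to the fixed value when fewer than 2 values are
#'   available or the recomputed cutoff is not > 1).
#' @return data.frame (one row per TSS): `tss_id`, `k4_ratio`,
#'   `k4_rd1_depleted`, `delta_polii`, `dhs_ratio`, `crx_reads`,
#'   `crx_bound`, `nrl_bound`, `polii_group`, `dhs_group`; the thresholds
#'   actually applied are attached as `attr(, "thresholds")`.
#' @export
derive_stats <- function(se, thresholds = rod_thresholds(),
                         preset = c("fixed", "data")) {
  preset <- match.arg(preset)
  stopifnot(methods::is(thresholds, "rod_thresholds"))
  raw <- SummarizedExperiment::assay(se, "counts")
  cpm <- SummarizedExperiment::assay(se, "cpm")
  pc <- thresholds$pseudocount
  k4_ratio <- dev_ratio(cpm[, "H3K4me2_PN15"], cpm[, "H3K4me2_PN1"], pc)
  delta_polii <- raw[, "PolII_PN25"] - raw[, "PolII_PN2"]
  dhs_ratio <- dev_ratio(raw[, "DHS_8W"], raw[, "DHS_1D"], pc)
  if (preset == "data") {
    pos <- delta_polii[delta_polii > 0]
    t_polii <- if (length(pos) >= 2) mean_plus_2sd(pos) else thresholds$t_polii
    t_dhs <- if (length(dhs_ratio) >= 2) mean_plus_2sd(dhs_ratio) else
      thresholds$t_dhs_strong
    if (!is.finite(t_dhs) || t_dhs <= 1) t_dhs <- thresholds$t_dhs_strong
    if (!is.finite(t_polii) || t_polii <= 0) t_polii <- thresholds$t_polii
    thresholds <- rod_thresholds(t_polii, t_dhs, thresholds$k4_ratio_min, pc)
  }
  out <- data.frame(
    tss_id = rownames(raw),
    k4_ratio = unname(k4_ratio),
    k4_rd1_depleted = unname(cpm[, "H3K4me2_RD1"] < cpm[, "H3K4me2_PN15"]),
    delta_polii = unname(delta_polii),
    dhs_ratio = unname(dhs_ratio),
    crx_reads = unname(raw[, "CRX_S1"] + raw[, "CRX_S2"]),
    stringsAsFactors = FALSE
  )
  out$crx_bound <- call_binding(out$crx_reads)
  out$nrl_bound <- call_binding(raw[, "NRL"])
  out$polii_group <- classify_polii(out$delta_polii, thresholds$t_polii)
  out$dhs_group <- classify_dhs(out$dhs_ratio, thresholds$t_dhs_strong)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}

#' Rule-based rod / common classification
#'
#' A TSS is called `rod` when it shows the defining combination: H3K4me2
#' accumulation during development (`k4_ratio >= k4_ratio_min`), less
#' H3K4me2 in the rod-less RD1 retina than at PN15, and a developmental
#' DHS increase (group `up` or `strong`).  CRX, NRL and PolII support the
#' call but are not required -- a sizeable minority of genuine rod TSS
#' lack CRX (~25%) or NRL (~44%) binding -- so they contribute to a
#' reported confidence score (fraction of the three supporting marks
#' present) rather than to the gate.
#'
#' @param stats data.frame from [derive_stats()].
#' @param thresholds a [rod_thresholds()]; defaults to the thresholds
#'   attached to `stats`.
#' @return data.frame: `tss_id`, `class` (factor rod/common),
#'   `confidence` in \[0, 1\].
#' @export
classify_rod_signature <- function(stats, thresholds = NULL) {
  thresholds <- thresholds %||% attr(stats, "thresholds") %||% rod_thresholds()
  need <- c("tss_id", "k4_ratio", "k4_rd1_depleted", "dhs_group",
            "crx_bound", "nrl_bound", "polii_group")
  miss <- setdiff(need, names(stats))
  if (length(miss)) {
    stop_input("missing derived statistics: ", paste(miss, collapse = ", "))
  }
  rod <- stats$k4_ratio >= thresholds$k4_ratio_min &
    stats$k4_rd1_depleted &
    stats$dhs_group %in% c("up", "strong")
  conf <- rowMeans(cbind(stats$crx_bound, stats$nrl_bound,
                         stats$polii_group != "none"))
  data.frame(tss_id = stats$tss_id,
             class = factor(ifelse(rod, "rod", "common"),
                            levels = c("rod", "common")),
             confidence = conf,
             stringsAsFactors = FALSE)
}

#' Count and rounded percentage of a category
#'
#' The bookkeeping primitive behind every reported "n (x%)" figure:
#' counts `of_interest` among `labels` and rounds the percentage to the
#' nearest integer, halves away from zero.
#'
#' @param labels non-empty vector of categorical labels.
#' @param of_interest the category to summarize.
#' @return named numeric `c(count, percent)`.
#' @export
#' @examples
#' summarize_groups(rep(c("bound", "unbound"), c(55, 17)), "bound")  # 55, 76
summarize_groups <- function(labels, of_interest) {
  if (!length(labels)) stop_input("empty label vector")
  n <- sum(labels == of_interest)
  c(count = n, percent = round_half_away(100 * n / length(labels)))
}

#' Full per-category count/percent table
#'
#' @param labels non-empty vector (or factor) of labels.
#' @return data.frame `group`, `count`, `percent`; percentages sum to
#'   100 within rounding.
#' @export
group_summary <- function(labels) {
  if (!length(labels)) stop_input("empty label vector")
  lev <- if (is.factor(labels)) levels(labels) else unique(labels)
  do.call(rbind, lapply(lev, function(g) {
    s <- summarize_groups(labels, g)
    data.frame(group = g, count = s[["count"]], percent = s[["percent"]],
               stringsAsFactors = FALSE)
  }))
}

#' Two-tailed unpaired Student's t-test between two groups
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return the two-tailed p-value; degenerate input (zero variance in both
#'   groups) returns 1 when the means are equal and 0 otherwise.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_input("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}
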