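# Two-condition (chemogenetic) comparison: which genetic interactions are
# aggravated (more negative) or alleviated (less negative) under the drug.

#' Call aggravated / alleviated interactions between two conditions
#'
#' For every pair scored and unflagged in both matrices,
#' `delta = S_drug - S_control`. A pair is `AGGRAVATED` when
#' `delta <= -min_delta` and the pair is significant in the drug condition;
#' `ALLEVIATED` when `delta >= +min_delta` and the pair is significant in the
#' control condition; otherwise `UNCHANGED`. Significance defaults to the
#' genome-wide Bonferroni threshold (`alpha / n tested pairs`): the delta of
#' an ordinary pair fluctuates on the same scale as the S score itself, so an
#' unadjusted gate would fill the call list with chance calls across
#' thousands of pairs.
#'
#' Pairs present in only one condition are never silently dropped; they are
#' returned in the `unpaired` attribute.
#'
#' @param m_ctrl,m_drug `interaction_matrix` objects with P filled, sharing
#'   (part of) a gene set.
#' @param min_delta Minimum |delta| for a call (default 2.0).
#' @param p_cut Significance gate; default `alpha / N` with `alpha = 0.05`.
#' @return Data frame of class `differential_calls`, sorted by `|delta|`
#'   descending: `pair`, `gene_a`, `gene_b`, `s_control`, `s_drug`, `delta`,
#'   `category`; attribute `unpaired` lists pairs scored in exactly one
#'   condition.
#' @export
compare_conditions <- function(m_ctrl, m_drug, min_delta = 2.0, p_cut = NULL) {
  shared <- intersect(m_ctrl$genes, m_drug$genes)
  if (length(shared) < 2L) stop("compare_conditions: disjoint gene sets")
  Sc <- usable_S(m_ctrl)[shared, shared]
  Sd <- usable_S(m_drug)[shared, shared]
  Pc <- m_ctrl$P[shared, shared]
  Pd <- m_drug$P[shared, shared]

  pr <- all_pairs(shared)
  idx <- cbind(match(pr$gene_a, shared), match(pr$gene_b, shared))
  pr$s_control <- Sc[idx]
  pr$s_drug <- Sd[idx]
  both <- is.finite(pr$s_control) & is.finite(pr$s_drug)
  one <- xor(is.finite(pr$s_control), is.finite(pr$s_drug))
  unpaired <- pr[one, c("pair", "gene_a", "gene_b", "s_control", "s_drug")]
  pr <- pr[both, , drop = FALSE]
  pr$delta <- pr$s_drug - pr$s_control
  if (is.null(p_cut)) p_cut <- 0.05 / max(nrow(pr), 1L)

  pc <- Pc[idx][both]
  pd <- Pd[idx][both]
  agg <- pr$delta <= -min_delta & is.finite(pd) & pd <= p_cut
  alle <- pr$delta >= min_delta & is.finite(pc) & pc <= p_cut
  pr$category <- ifelse(agg, "AGGRAVATED", ifelse(alle, "ALLEVIATED", "UNCHANGED"))
  pr <- pr[order(-abs(pr$delta)), , drop = FALSE]
  rownames(pr) <- NULL
  attr(pr, "unpaired") <- unpaired
  attr(pr, "p_cut") <- p_cut
  class(pr) <- c("differential_calls", "data.frame")
  emap_log("compare_conditions: %d shared pairs, %d aggravated, %d alleviated, %d unpaired",
           nrow(pr), sum(agg), sum(alle), nrow(unpaired))
  pr
}

#' Scan for one-direction-only significant pairs
#'
#' Flags pairs whose score is significant in exactly one of the reciprocal
#' directions while the other direction sits inside the null bulk (|z| below
#' the `p_cut`-equivalent bound of the robust-standardized directional
#' scores). Applied per condition; an excess in the drug condition (count
#' ratio > 1) is the signature of condition-specific directional noise.
#'
#' @param pairs_ctrl,pairs_drug `raw_score_pairs` for the two conditions.
#' @param p_cut Two-sided P bound defining the significance cut.
#' @return A list with `control` and `drug` (data frames of flagged pairs
#'   with their directional z scores) and `ratio` (drug count / control
#'   count; `NA` when the control count is 0).
#' @export
axis_artifact_scan <- function(pairs_ctrl, pairs_drug, p_cut = 0.005) {
  z_cut <- stats::qnorm(1 - p_cut / 2)
  scan_one <- function(pr) {
    s_all <- c(pr$s_qa, pr$s_aq)
    s_all <- s_all[is.finite(s_all)]
    med <- stats::median(s_all)
    sc <- stats::mad(s_all, constant = 1.4826)
    z_qa <- (pr$s_qa - med) / sc
    z_aq <- (pr$s_aq - med) / sc
    sig_qa <- is.finite(z_qa) & abs(z_qa) >= z_cut
    sig_aq <- is.finite(z_aq) & abs(z_aq) >= z_cut
    bulk_qa <- is.finite(z_qa) & abs(z_qa) < z_cut
    bulk_aq <- is.finite(z_aq) & abs(z_aq) < z_cut
    hit <- (sig_qa & bulk_aq) | (sig_aq & bulk_qa)
    out <- pr[hit, c("pair", "gene_a", "gene_b", "s_qa", "s_aq")]
    out$z_qa <- z_qa[hit]
    out$z_aq <- z_aq[hit]
    rownames(out) <- NULL
    out
  }
  ctrl <- scan_one(pairs_ctrl)
  drug <- scan_one(pairs_drug)
  ratio <- if (nrow(ctrl) > 0L) nrow(drug) / nrow(ctrl) else NA_real_
  emap_log("axis_artifact_scan: %d control, %d drug one-direction pairs",
           nrow(ctrl), nrow(drug), level = "debug")
  list(control = ctrl, drug = drug, ratio = ratio)
}
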