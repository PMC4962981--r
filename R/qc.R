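# Strain-level quality control: reciprocal concordance and noisy-strain
# removal. A strain measured as query and as array yields two independent
# scores per pair; systematic disagreement between the two directions is the
# working definition of a noisy strain here.

#' Reciprocal S-score concordance
#'
#' Pearson correlation of the unaveraged directional scores `s_qa` vs `s_aq`
#' over pairs scored in both directions, optionally restricted to significant
#' pairs (averaged P below `p_cut`).
#'
#' @param pairs A `raw_score_pairs` data frame.
#' @param significant_only Restrict to significant pairs.
#' @param p_cut P cutoff used with `significant_only`.
#' @param m `interaction_matrix` with P filled (required when
#'   `significant_only = TRUE`; supplies the averaged P per pair).
#' @return The correlation, or `NA` when fewer than 3 pairs qualify.
#' @export
reciprocal_concordance <- function(pairs, significant_only = FALSE,
                                   p_cut = 0.005, m = NULL) {
  ok <- is.finite(pairs$s_qa) & is.finite(pairs$s_aq)
  if (significant_only) {
    if (is.null(m)) stop("reciprocal_concordance: significant_only needs the matrix for P values")
    i <- match(pairs$gene_a, m$genes)
    j <- match(pairs$gene_b, m$genes)
    pv <- m$P[cbind(i, j)]
    ok <- ok & is.finite(pv) & pv < p_cut
  }
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(pairs$s_qa[ok], pairs$s_aq[ok])
}

#' Detect noisy strains by reciprocal discordance
#'
#' A strain's discordance is the median over its partners of
#' `|s_qa - s_aq|`. Strains whose discordance exceeds `k_noisy` times the
#' screen-wide median discordance are flagged; the screen-wide median is then
#' recomputed without the flagged strains and the rule applied once more (one
#' removal iteration, keeping the procedure deterministic and
#' order-independent).
#'
#' When the pairs carry variance-stabilized directional scores
#' (`s_qa_stab` / `s_aq_stab`, see [score_grid()]), the discordance is
#' computed on those: the modified t divides by the cross's own replicate
#' variance, which self-normalizes a noisy strain's scores and caps its
#' discordance near the screen median regardless of how noisy the strain is;
#' the stabilized scores scale linearly with strain noise so the
#' `k_noisy`-fold rule discriminates as intended.
#'
#' @param pairs A `raw_score_pairs` data frame.
#' @param k_noisy Multiplier on the screen-wide median discordance.
#' @return Character vector of flagged gene ids (with attribute
#'   `discordance`, the named per-strain discordances).
#' @export
detect_noisy_strains <- function(pairs, k_noisy = 3) {
  if (!is.null(pairs$s_qa_stab)) {
    x <- pairs$s_qa_stab
    y <- pairs$s_aq_stab
  } else {
    x <- pairs$s_qa
    y <- pairs$s_aq
  }
  ok <- is.finite(x) & is.finite(y)
  pr <- pairs[ok, , drop = FALSE]
  if (nrow(pr) == 0L)
    return(structure(character(), discordance = numeric()))
  d <- abs(x[ok] - y[ok])
  genes <- sort(unique(c(pr$gene_a, pr$gene_b)))
  disc <- vapply(genes, function(g) {
    stats::median(d[pr$gene_a == g | pr$gene_b == g])
  }, numeric(1))
  flagged <- names(disc)[disc > k_noisy * stats::median(disc)]
  rest <- disc[setdiff(names(disc), flagged)]
  if (length(rest) >= 1L) {
    more <- names(rest)[rest > k_noisy * stats::median(rest)]
    flagged <- union(flagged, more)
  }
  if (length(flagged))
    emap_log("detect_noisy_strains: flagged %d of %d strains",
             length(flagged), length(genes))
  structure(flagged, discordance = disc)
}

#' Flag pairs involving noisy strains
#'
#' Adds the `NOISY_STRAIN` flag to every cell involving a flagged strain so
#' downstream analyses exclude them; S values of unrelated pairs are
#' untouched.
#'
#' @param m An `interaction_matrix`.
#' @param strains Character vector of noisy gene ids.
#' @return The flagged matrix.
#' @export
flag_noisy_strains <- function(m, strains) {
  idx <- m$genes %in% strains
  if (!any(idx)) return(m)
  m$flags[idx, ] <- flag_add(m$flags[idx, ], "NOISY_STRAIN")
  m$flags[, idx] <- flag_add(m$flags[, idx], "NOISY_STRAIN")
  m
}

#' Concordance between two screens of the same gene set
#'
#' Pearson correlation of the symmetrized S scores over pairs finite and
#' unflagged in both matrices, reported for all shared pairs and for the
#' significant subset (P below `p_cut` in at least one screen).
#'
#' @param m1,m2 `interaction_matrix` objects.
#' @param p_cut P cutoff for the significant subset.
#' @return A list: `correlation`, `n_pairs`, `correlation_significant`,
#'   `n_significant`.
#' @export
replicate_concordance <- function(m1, m2, p_cut = 0.005) {
  shared <- intersect(m1$genes, m2$genes)
  if (length(shared) < 2L) stop("replicate_concordance: disjoint gene sets")
  S1 <- usable_S(m1)[shared, shared]
  S2 <- usable_S(m2)[shared, shared]
  P1 <- m1$P[shared, shared]
  P2 <- m2$P[shared, shared]
  ut <- upper.tri(S1)
  ok <- ut & is.finite(S1) & is.finite(S2)
  if (sum(ok) < 3L) stop("replicate_concordance: fewer than 3 shared scored pairs")
  sig <- ok & ((is.finite(P1) & P1 < p_cut) | (is.finite(P2) & P2 < p_cut))
  list(correlation = stats::cor(S1[ok], S2[ok]),
       n_pairs = sum(ok),
       correlation_significant = if (sum(sig) >= 3L)
         stats::cor(S1[sig], S2[sig]) else NA_real_,
       n_significant = sum(sig))
}

#' QC summary report
#'
#' Per-strain reciprocal discordance, noisy flags, and before/after
#' concordance; pair bookkeeping is conserved
#' (`pairs_in = pairs_out + pairs_dropped`).
#'
#' @param pairs A `raw_score_pairs` data frame.
#' @param m `interaction_matrix` with P values.
#' @param k_noisy Noisy-strain multiplier.
#' @param p_cut Significance cutoff for the significant-only concordance.
#' @return A list with `strains` (per-strain table), `noisy`, `concordance`
#'   (before/after, all/significant), and `pair_counts`.
#' @export
qc_report <- function(pairs, m, k_noisy = 3, p_cut = 0.005) {
  noisy <- detect_noisy_strains(pairs, k_noisy = k_noisy)
  disc <- attr(noisy, "discordance")
  strains <- data.frame(gene_id = names(disc), discordance = as.numeric(disc),
                        noisy = names(disc) %in% noisy,
                        stringsAsFactors = FALSE, row.names = NULL)
  keep <- !(pairs$gene_a %in% noisy | pairs$gene_b %in% noisy)
  conc <- list(
    all_before = reciprocal_concordance(pairs),
    all_after = reciprocal_concordance(pairs[keep, , drop = FALSE]),
    significant_before = reciprocal_concordance(pairs, TRUE, p_cut, m),
    significant_after = reciprocal_concordance(pairs[keep, , drop = FALSE],
                                               TRUE, p_cut, m))
  counts <- c(pairs_in = nrow(pairs), pairs_out = sum(keep),
              pairs_dropped = sum(!keep), strains_flagged = length(noisy))
  emap_log("qc_report: %d/%d pairs kept, %d strain(s) flagged",
           counts[["pairs_out"]], counts[["pairs_in"]],
           counts[["strains_flagged"]])
  list(strains = strains, noisy = noisy, concordance = conc,
       pair_counts = counts)
}
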