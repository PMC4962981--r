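# Profile correlations, significance classes, curve analytics, clustering.
#
# A gene's interaction profile is its vector of S scores against all other
# genes; profile correlation (Pearson) is the similarity currency of E-MAP
# analysis. Profiles exclude the mutual pair entry S[i,j] and all flagged
# cells so a single strong interaction cannot inflate its own correlation.

#' Pairwise interaction-profile correlations
#'
#' For genes i and j, the Pearson correlation of their S profiles over
#' partners `k` not in `{i, j}` with finite, unflagged values in both
#' profiles (pairwise-complete). P values come from the t transform with
#' `n_used - 2` degrees of freedom. Pairs with fewer than 3 shared partners
#' are missing.
#'
#' @param m An `interaction_matrix`.
#' @return A `correlation_matrix`.
#' @export
profile_correlations <- function(m) {
  S <- usable_S(m)
  n <- length(m$genes)
  r <- matrix(NA_real_, n, n)
  P <- matrix(NA_real_, n, n)
  nu <- matrix(NA_integer_, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- S[i, ]
    for (j in (i + 1L):n) {
      x <- xi
      y <- S[j, ]
      x[c(i, j)] <- NA
      y[c(i, j)] <- NA
      ok <- is.finite(x) & is.finite(y)
      k <- sum(ok)
      if (k < 3L) next
      rv <- suppressWarnings(stats::cor(x[ok], y[ok]))
      if (!is.finite(rv)) next  # zero-variance profile
      nu[i, j] <- nu[j, i] <- k
      r[i, j] <- r[j, i] <- rv
      P[i, j] <- P[j, i] <- corr_pvalue(rv, k)
    }
  }
  correlation_matrix(m$genes, r, P, nu)
}

# two-sided P for a Pearson correlation via the t transform
corr_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Classify pairs by joint S / correlation significance
#'
#' Every pair scored in both tables falls in exactly one category:
#' `S_ONLY` (significant S, non-significant correlation), `CORR_ONLY`,
#' `BOTH`, or `NEITHER`. Significance is `P <= p_s` for S scores and
#' `P <= p_corr` for correlations (boundary values significant).
#'
#' @param m An `interaction_matrix` with P filled.
#' @param c A `correlation_matrix`.
#' @param th An `emap_thresholds`.
#' @return Data frame with columns `pair`, `gene_a`, `gene_b`, `S`, `r`,
#'   `p_s`, `p_corr`, `category`; attribute `counts` tabulates the
#'   categories.
#' @export
classify_pairs <- function(m, c, th = emap_thresholds()) {
  stopifnot(identical(m$genes, c$genes))
  pr <- all_pairs(m$genes)
  i <- match(pr$gene_a, m$genes)
  j <- match(pr$gene_b, m$genes)
  idx <- cbind(i, j)
  pr$S <- usable_S(m)[idx]
  pr$r <- c$r[idx]
  pr$p_s <- m$P[idx]
  pr$p_corr <- c$P[idx]
  pr <- pr[is.finite(pr$S) & is.finite(pr$p_s) & is.finite(pr$p_corr), ,
           drop = FALSE]
  s_sig <- pr$p_s <= th$p_s
  c_sig <- pr$p_corr <= th$p_corr
  pr$category <- ifelse(s_sig & c_sig, "BOTH",
                 ifelse(s_sig, "S_ONLY",
                 ifelse(c_sig, "CORR_ONLY", "NEITHER")))
  rownames(pr) <- NULL
  counts <- table(factor(pr$category,
                         levels = c("S_ONLY", "CORR_ONLY", "BOTH", "NEITHER")))
  attr(pr, "counts") <- counts
  emap_log("classify_pairs: %d pairs (%s)", nrow(pr),
           paste(names(counts), as.integer(counts), sep = "=", collapse = ", "),
           level = "debug")
  pr
}

#' High-correlation pairs
#'
#' Pairs with `r` strictly greater than `cut`, sorted descending.
#'
#' @param c A `correlation_matrix`.
#' @param cut Correlation cutoff (strict `>`).
#' @return Data frame `pair`, `gene_a`, `gene_b`, `r`.
#' @export
high_correlation_pairs <- function(c, cut = 0.5) {
  pr <- all_pairs(c$genes)
  pr$r <- c$r[cbind(match(pr$gene_a, c$genes), match(pr$gene_b, c$genes))]
  pr <- pr[is.finite(pr$r) & pr$r > cut, , drop = FALSE]
  pr <- pr[order(-pr$r), , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

# qualifying pairs for the curve analytics: both r and significant S present
curve_pairs <- function(m, c, th) {
  pr <- classify_pairs(m, c, th)
  pr <- pr[is.finite(pr$r) & pr$p_s <= th$p_s & is.finite(pr$S), , drop = FALSE]
  pr[order(pr$r, pr$pair), , drop = FALSE]
}

window_index <- function(n, window, mode) {
  if (mode == "chunk") {
    split(seq_len(n), ceiling(seq_len(n) / window))
  } else {
    if (n < window) return(list(seq_len(n)))
    lapply(seq_len(n - window + 1L), function(s) s:(s + window - 1L))
  }
}

#' Mean significant S as a function of profile correlation
#'
#' Sorts pairs that have both a correlation and a significant S score by `r`
#' and summarizes consecutive windows of `th$window` pairs by their mean
#' correlation and mean S. Windows are non-overlapping by default
#' (`mode = "chunk"`); `mode = "rolling"` slides by one pair instead. A
#' trailing window shorter than `th$window` is kept and flagged `partial`.
#'
#' @param m An `interaction_matrix` with P filled.
#' @param c A `correlation_matrix`.
#' @param th An `emap_thresholds`.
#' @param mode `"chunk"` or `"rolling"`.
#' @return Data frame `mean_r`, `mean_S`, `n`, `partial`.
#' @export
s_vs_correlation_curve <- function(m, c, th = emap_thresholds(),
                                   mode = c("chunk", "rolling")) {
  mode <- match.arg(mode)
  pr <- curve_pairs(m, c, th)
  if (nrow(pr) == 0L)
    return(data.frame(mean_r = numeric(), mean_S = numeric(),
                      n = integer(), partial = logical()))
  win <- window_index(nrow(pr), th$window, mode)
  out <- do.call(rbind, lapply(win, function(w) {
    data.frame(mean_r = mean(pr$r[w]), mean_S = mean(pr$S[w]),
               n = length(w), partial = length(w) < th$window)
  }))
  rownames(out) <- NULL
  out
}

#' Positive/negative interaction ratio along the correlation axis
#'
#' Same windowing as [s_vs_correlation_curve()], but each window reports the
#' ratio of significantly positive to significantly negative S scores;
#' windows with no negative interaction get `NA` (never infinity).
#'
#' @inheritParams s_vs_correlation_curve
#' @return Data frame `mean_r`, `ratio`, `n_pos`, `n_neg`, `n`, `partial`.
#' @export
pos_neg_ratio_curve <- function(m, c, th = emap_thresholds(),
                                mode = c("chunk", "rolling")) {
  mode <- match.arg(mode)
  pr <- curve_pairs(m, c, th)
  if (nrow(pr) == 0L)
    return(data.frame(mean_r = numeric(), ratio = numeric(), n_pos = integer(),
                      n_neg = integer(), n = integer(), partial = logical()))
  win <- window_index(nrow(pr), th$window, mode)
  out <- do.call(rbind, lapply(win, function(w) {
    np <- sum(pr$S[w] > 0)
    nn <- sum(pr$S[w] < 0)
    data.frame(mean_r = mean(pr$r[w]),
               ratio = if (nn > 0L) np / nn else NA_real_,
               n_pos = np, n_neg = nn, n = length(w),
               partial = length(w) < th$window)
  }))
  rownames(out) <- NULL
  out
}

#' Average-linkage hierarchical clustering of interaction profiles
#'
#' Agglomerative clustering on the distance `1 - r` (missing correlations are
#' treated as `r = 0`). The gene order is made deterministic by sorting genes
#' lexicographically before clustering, so ties break on `gene_id`.
#'
#' @param c A `correlation_matrix`.
#' @return A list with `order` (leaf-ordered gene ids) and `tree` (an
#'   [stats::hclust] object).
#' @export
hierarchical_cluster <- function(c) {
  fin <- is.finite(c$r[upper.tri(c$r)])
  if (!any(fin)) stop("hierarchical_cluster: no finite correlations")
  if (length(c$genes) < 3L) stop("hierarchical_cluster: need >= 3 genes")
  ord <- order(c$genes)
  r <- c$r[ord, ord]
  r[!is.finite(r)] <- 0
  d <- stats::as.dist(1 - r)
  tree <- stats::hclust(d, method = "average")
  tree$labels <- c$genes[ord]
  list(order = tree$labels[tree$order], tree = tree)
}

#' Hyper-interacting genes
#'
#' Counts significant pairs per gene and flags genes whose count exceeds
#' `mean + k_sd * sd` of the per-gene counts *and* involves at least
#' `min_frac` of the gene's tested partners. The fraction floor targets the
#' hyper-interactor phenotype — interactions spread throughout the profile,
#' a substantial share of all partners — and keeps the rule quiet both on
#' screens where counts are low and near-Poisson (a pure mean + 2 SD rule
#' fires on chance alone there) and on genes whose interactions are
#' concentrated in one chromosomal region, which are the subject of the
#' region scan, not hyper-interactors.
#'
#' @param m An `interaction_matrix` with P filled.
#' @param th An `emap_thresholds` (supplies `p_s`).
#' @param k_sd SD multiplier (default 2).
#' @param min_frac Minimum fraction of tested partners (default 0.2).
#' @return Character vector of flagged gene ids with attribute `counts`
#'   (named per-gene significant-interaction counts).
#' @export
hyper_interactors <- function(m, th = emap_thresholds(), k_sd = 2,
                              min_frac = 0.2) {
  S <- usable_S(m)
  sig <- is.finite(S) & is.finite(m$P) & m$P <= th$p_s
  counts <- rowSums(sig)
  tested <- rowSums(is.finite(S) & is.finite(m$P))
  if (!length(counts) || all(tested == 0L))
    return(structure(character(), counts = counts))
  cut <- mean(counts) + k_sd * stats::sd(counts)
  frac <- ifelse(tested > 0L, counts / tested, 0)
  flagged <- names(counts)[counts > cut & frac >= min_frac]
  structure(flagged, counts = counts)
}

#' Interaction and correlation frequencies by functional class
#'
#' For each ordered pair of functional classes (A, B), the fraction of tested
#' A-B gene pairs with a significant interaction, and (when a correlation
#' matrix is supplied) with a high correlation (`r > th$corr_high`).
#' Unlabeled genes are grouped under `"unannotated"`.
#'
#' @param m An `interaction_matrix` with P filled.
#' @param loci A `gene_loci` table supplying `functional_class`.
#' @param th An `emap_thresholds`.
#' @param c Optional `correlation_matrix`.
#' @return A list with `interaction` (class x class frequency matrix),
#'   `tested` (pair counts), and `correlation` (or NULL).
#' @export
class_crosstab <- function(m, loci, th = emap_thresholds(), c = NULL) {
  cls <- loci$functional_class[match(m$genes, loci$gene_id)]
  cls[is.na(cls) | cls == ""] <- "unannotated"
  classes <- sort(unique(cls))
  S <- usable_S(m)
  tested <- is.finite(S) & is.finite(m$P)
  sig <- tested & m$P <= th$p_s
  agg <- function(mat) {
    out <- matrix(0, length(classes), length(classes),
                  dimnames = list(classes, classes))
    for (a in classes) for (b in classes) {
      sel <- mat[cls == a, cls == b, drop = FALSE]
      ut <- if (a == b) sum(sel[upper.tri(sel)]) else sum(sel)
      out[a, b] <- ut
    }
    out
  }
  n_test <- agg(tested)
  freq <- agg(sig) / n_test
  freq[n_test == 0] <- NA_real_
  corr_freq <- NULL
  if (!is.null(c)) {
    hi <- is.finite(c$r) & c$r > th$corr_high
    n_corr <- agg(is.finite(c$r) + 0)
    corr_freq <- agg(hi + 0) / n_corr
    corr_freq[n_corr == 0] <- NA_real_
  }
  list(interaction = freq, tested = n_test, correlation = corr_freq)
}

#' Overlap of pair sets (Venn regions)
#'
#' Counts, for every combination of membership among the named sets, how many
#' canonical pair keys fall in exactly that Venn region.
#'
#' @param tested_pairs Character vector of canonical pair keys (see
#'   [pair_key()]).
#' @param reference_sets Named list of character vectors of pair keys.
#' @return Data frame with one row per non-empty membership pattern:
#'   `region` (e.g. `"tested&krogan"`), `count`; plus attribute `sets`
#'   (per-set sizes).
#' @export
set_overlap <- function(tested_pairs, reference_sets = list()) {
  sets <- c(list(tested = unique(tested_pairs)),
            lapply(reference_sets, unique))
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("set_overlap: reference sets must be named")
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  region <- apply(memb, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- table(region)
  out <- data.frame(region = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "sets") <- vapply(sets, length, integer(1))
  out
}
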