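# Raw colony sizes -> symmetrized, significance-annotated S scores.
#
# The S score is the modified t-statistic of the E-MAP tradition: the
# deviation of a cross's mean colony size from the control expectation of its
# array gene, over the combination of the control spread and the (floored)
# replicate variance. Robust statistics (median / scaled MAD) are used for
# all control fits because true interactions contaminate means.

#' Normalize a colony-size grid
#'
#' Plate effects are removed by scaling every plate so its median colony size
#' equals the global median; plates with no usable sizes are left unscaled and
#' reported in the `unscaled_plates` attribute. Query-strain effects are then
#' removed by scaling every query row so its median equals the global median
#' (single-mutant fitness differences otherwise masquerade as interactions of
#' that query with every array). An optional polish step removes residual
#' row/column trends (e.g. plate-geometry gradients) by median polish in log
#' space. Sizes remain non-negative throughout.
#'
#' @param grid A `cross_grid`.
#' @param polish Logical; run the log-space median polish.
#' @param query_scale Logical; equalize query-row medians (default TRUE).
#' @return A normalized `cross_grid` with attributes `plate_factors` (named
#'   scale factors) and `unscaled_plates`.
#' @export
normalize_grid <- function(grid, polish = FALSE, query_scale = TRUE) {
  stopifnot(inherits(grid, "cross_grid"))
  sizes <- grid$sizes
  gm <- stats::median(sizes, na.rm = TRUE)
  if (!is.finite(gm) || gm <= 0) stop("normalize_grid: no usable colony sizes")

  plates <- unique(as.vector(grid$plate_of))
  plates <- plates[!is.na(plates)]
  factors <- stats::setNames(rep(NA_real_, length(plates)), plates)
  plate_rep <- array(rep(grid$plate_of, dim(sizes)[3]), dim = dim(sizes))
  for (p in plates) {
    sel <- plate_rep == p & !is.na(plate_rep)
    pm <- stats::median(sizes[sel], na.rm = TRUE)
    if (is.finite(pm) && pm > 0) {
      factors[[p]] <- gm / pm
      sizes[sel] <- sizes[sel] * (gm / pm)
    }
  }
  unscaled <- names(factors)[!is.finite(factors)]
  if (length(unscaled))
    emap_log("normalize_grid: %d plate(s) without usable sizes left unscaled",
             length(unscaled))

  if (query_scale) {
    for (q in seq_along(grid$queries)) {
      qm <- stats::median(sizes[q, , ], na.rm = TRUE)
      if (is.finite(qm) && qm > 0) sizes[q, , ] <- sizes[q, , ] * (gm / qm)
    }
  }

  if (polish) {
    lm_ <- log(pmax(cross_means(sizes), .Machine$double.xmin))
    mp <- stats::medpolish(lm_, eps = 1e-10, maxiter = 100L,
                           na.rm = TRUE, trace.iter = FALSE)
    adj <- exp(outer(mp$row, mp$col, `+`))
    for (r in seq_len(dim(sizes)[3])) sizes[, , r] <- sizes[, , r] / adj
  }

  out <- cross_grid(grid$condition, sizes, grid$plate_of)
  attr(out, "plate_factors") <- factors
  attr(out, "unscaled_plates") <- unscaled
  out
}

# per-cross replicate means, counts and variances from a 3-way sizes array
cross_means <- function(sizes) {
  R <- dim(sizes)[3]
  tot <- 0; nob <- 0
  for (r in seq_len(R)) {
    x <- sizes[, , r]
    ok <- !is.na(x)
    x[!ok] <- 0
    tot <- tot + x
    nob <- nob + ok
  }
  out <- tot / nob
  out[nob == 0L] <- NA_real_
  out
}

cross_stats <- function(sizes) {
  R <- dim(sizes)[3]
  tot <- 0; nob <- 0; ss <- 0
  for (r in seq_len(R)) {
    x <- sizes[, , r]
    ok <- !is.na(x)
    x[!ok] <- 0
    tot <- tot + x
    ss <- ss + x^2
    nob <- nob + ok
  }
  m <- tot / nob
  m[nob == 0L] <- NA_real_
  v <- (ss - nob * m^2) / (nob - 1L)
  v[nob < 2L] <- NA_real_
  v[v < 0] <- 0  # numerical guard
  list(mean = m, var = v, n = nob)
}

#' Fit per-array-gene control statistics
#'
#' For every array gene, the expected colony size is the median across queries
#' of that gene's per-cross mean sizes, and the spread is the scaled median
#' absolute deviation (consistent with a standard deviation). Spreads are
#' floored at the screen-wide median spread. The screen-wide median replicate
#' variance is also recorded (`variance_floor`, on the standard-deviation
#' scale): the observed variance of a quadruplicate has only 3 degrees of
#' freedom, so the S denominator moderates each cross's variance toward this
#' typical value (see [compute_s_score()]) — an unmoderated denominator gives
#' the score heavy t tails and defeats the normal reference of the empirical
#' null. Both quantities carry a small absolute backstop (`1e-6` times the
#' global median size) so the noise-free limit stays finite. Array genes with
#' fewer than `min_crosses` usable crosses are flagged missing.
#'
#' @param grid A normalized `cross_grid`.
#' @param n_ctrl_eff Effective control replicate count entering the S
#'   denominator (default: the grid's replicate count).
#' @param min_crosses Minimum usable crosses per array gene (default 4).
#' @return An object of class `control_stats`: a data frame with columns
#'   `array_gene`, `expected`, `spread` (floored), `n_ctrl`, `missing`, plus
#'   attribute `variance_floor` (the replicate-variance floor, on the
#'   standard-deviation scale).
#' @export
fit_control_stats <- function(grid, n_ctrl_eff = NULL, min_crosses = 4L) {
  stopifnot(inherits(grid, "cross_grid"))
  st <- cross_stats(grid$sizes)
  usable <- colSums(!is.na(st$mean))
  expected <- apply(st$mean, 2L, stats::median, na.rm = TRUE)
  spread <- apply(st$mean, 2L, robust_spread)
  missing <- usable < min_crosses
  expected[missing] <- NA_real_
  spread[missing] <- NA_real_
  gm <- stats::median(grid$sizes, na.rm = TRUE)
  spread_floor <- max(stats::median(spread, na.rm = TRUE), 1e-6 * gm,
                      na.rm = TRUE)
  spread <- pmax(spread, spread_floor)
  var_floor <- max(stats::median(st$var, na.rm = TRUE), (1e-6 * gm)^2,
                   na.rm = TRUE)
  if (is.null(n_ctrl_eff)) n_ctrl_eff <- dim(grid$sizes)[3]
  out <- data.frame(array_gene = grid$arrays, expected = expected,
                    spread = spread, n_ctrl = as.integer(n_ctrl_eff),
                    missing = missing, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "variance_floor") <- sqrt(var_floor)
  class(out) <- c("control_stats", "data.frame")
  if (any(missing))
    emap_log("fit_control_stats: %d array gene(s) with < %d usable crosses flagged missing",
             sum(missing), min_crosses)
  out
}

#' Compute one S score
#'
#' The modified t-statistic
#' `S = (mean(observed) - expected) / sqrt(spread^2 / n_ctrl_eff +
#' v_mod / n_obs)`, where the replicate variance is moderated toward the
#' screen-typical value:
#' `v_mod = ((n_obs - 1) * var(observed) + prior_df * variance_floor^2) /
#' (n_obs - 1 + prior_df)`. A quadruplicate's raw variance has 3 degrees of
#' freedom; borrowing `prior_df` pseudo-degrees from the screen-wide median
#' replicate variance stabilizes the denominator so the null score
#' distribution has near-normal tails while extreme crosses still widen
#' their own denominators. Negative S means the double mutant grew less than
#' expected (synthetic sick); positive S means it grew better (alleviation /
#' suppression). At least two observed replicates are required; otherwise
#' `NA` is returned.
#'
#' @param observed Numeric vector of replicate colony sizes (NA allowed).
#' @param ctrl A list (or one-row `control_stats` slice) with elements
#'   `expected`, `spread`, `n_ctrl` and `variance_floor`.
#' @param prior_df Pseudo-degrees of freedom of the variance moderation
#'   (default 6).
#' @return The S score (scalar).
#' @export
compute_s_score <- function(observed, ctrl, prior_df = 6) {
  obs <- observed[is.finite(observed)]
  n_obs <- length(obs)
  if (n_obs < 2L || !is.finite(ctrl$expected)) return(NA_real_)
  df <- n_obs - 1L
  v <- (df * stats::var(obs) + prior_df * ctrl$variance_floor^2) /
    (df + prior_df)
  (mean(obs) - ctrl$expected) /
    sqrt(ctrl$spread^2 / ctrl$n_ctrl + v / n_obs)
}

#' Score every cross of a grid (directional S scores)
#'
#' Vectorized application of [compute_s_score()] to every `[query x array]`
#' cell against the array gene's control statistics.
#'
#' @param grid A normalized `cross_grid`.
#' @param ctrl `control_stats` from [fit_control_stats()]; fitted on `grid`
#'   when omitted.
#' @param prior_df Variance-moderation pseudo-degrees of freedom (see
#'   [compute_s_score()]).
#' @return A list with `s` (query x array matrix of directional S scores),
#'   `s_stab` (variance-stabilized scores: same statistic with the screen-wide
#'   variance floor in place of the cross's own replicate variance, so a
#'   noisy strain's scores are not deflated by its own inflated variance —
#'   used for noisy-strain detection, never as the interaction score),
#'   `n_obs` (replicates used per cross) and `ctrl`.
#' @export
score_grid <- function(grid, ctrl = NULL, prior_df = 6) {
  if (is.null(ctrl)) ctrl <- fit_control_stats(grid)
  st <- cross_stats(grid$sizes)
  floor_v <- attr(ctrl, "variance_floor")
  df <- st$n - 1L
  v <- (df * st$var + prior_df * floor_v^2) / (df + prior_df)
  num <- st$mean - matrix(ctrl$expected, nrow(st$mean), ncol(st$mean),
                          byrow = TRUE)
  spread_term <- matrix(ctrl$spread^2 / ctrl$n_ctrl,
                        nrow(st$mean), ncol(st$mean), byrow = TRUE)
  s <- num / sqrt(spread_term + v / st$n)
  s_stab <- num / sqrt(spread_term + floor_v^2 / st$n)
  s[st$n < 2L] <- NA_real_
  s_stab[st$n < 2L] <- NA_real_
  dimnames(s) <- dimnames(s_stab) <- dimnames(grid$sizes)[1:2]
  list(s = s, s_stab = s_stab, n_obs = st$n, ctrl = ctrl)
}

#' Collect reciprocal raw score pairs
#'
#' Pairs up the directional scores of `[query A x array B]` and
#' `[query B x array A]` for every unordered pair present in a directional
#' score matrix (queries and arrays sharing the same gene set).
#'
#' @param s_dir Square directional score matrix from [score_grid()].
#' @param s_stab Optional matching matrix of variance-stabilized scores;
#'   carried along as `s_qa_stab` / `s_aq_stab` for noisy-strain detection.
#' @return Data frame of class `raw_score_pairs` with columns `pair`,
#'   `gene_a`, `gene_b`, `s_qa`, `s_aq` (NA when a direction is missing).
#' @export
raw_score_pairs <- function(s_dir, s_stab = NULL) {
  genes <- rownames(s_dir)
  if (!identical(genes, colnames(s_dir)))
    stop("raw_score_pairs: queries and arrays must be the same gene set")
  pr <- all_pairs(genes)
  i <- match(pr$gene_a, genes)
  j <- match(pr$gene_b, genes)
  pr$s_qa <- s_dir[cbind(i, j)]
  pr$s_aq <- s_dir[cbind(j, i)]
  if (!is.null(s_stab)) {
    pr$s_qa_stab <- s_stab[cbind(i, j)]
    pr$s_aq_stab <- s_stab[cbind(j, i)]
  }
  keep <- is.finite(pr$s_qa) | is.finite(pr$s_aq)
  pr <- pr[keep, , drop = FALSE]
  rownames(pr) <- NULL
  class(pr) <- c("raw_score_pairs", "data.frame")
  pr
}

#' Symmetrize reciprocal scores into an interaction matrix
#'
#' The S score of a pair is the mean of its available directions; pairs
#' scored in only one direction are flagged `ONE_DIRECTION_ONLY`.
#'
#' @param pairs A `raw_score_pairs` data frame.
#' @param genes Gene order for the matrix (default: genes seen in `pairs`).
#' @return An `interaction_matrix` (P values not yet filled; see
#'   [s_pvalues()]).
#' @export
symmetrize <- function(pairs, genes = NULL) {
  if (is.null(genes))
    genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  n <- length(genes)
  S <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  flags <- matrix("", n, n, dimnames = list(genes, genes))
  i <- match(pairs$gene_a, genes)
  j <- match(pairs$gene_b, genes)
  sval <- rowMeans(cbind(pairs$s_qa, pairs$s_aq), na.rm = TRUE)
  sval[!is.finite(sval)] <- NA_real_
  one_dir <- xor(is.finite(pairs$s_qa), is.finite(pairs$s_aq))
  S[cbind(i, j)] <- sval
  S[cbind(j, i)] <- sval
  od <- which(one_dir)
  flags[cbind(i[od], j[od])] <- "ONE_DIRECTION_ONLY"
  flags[cbind(j[od], i[od])] <- "ONE_DIRECTION_ONLY"
  interaction_matrix(genes, S, flags = flags)
}

#' Attach two-sided P values to an interaction matrix
#'
#' The default empirical null assumes the bulk of pairs are non-interacting:
#' the full S distribution is robust-standardized — centered at its median,
#' scaled by the central 80\% interquantile range calibrated to the normal
#' (`(q90 - q10) / (2 * qnorm(0.9))`, immune to tail contamination by up to
#' ~10\% true interactions and better tail-matched than the MAD for mildly
#' non-normal score distributions) — and evaluated against the standard
#' normal, two-sided. The permutation null
#' instead shuffles replicate measurements across crosses within each array
#' gene, re-scores, and uses the pooled permuted S values as the null
#' (recommended for small screens; requires the normalized grid).
#'
#' @param m An `interaction_matrix` with S filled.
#' @param method `"empirical"` or `"permute"`.
#' @param grid Normalized `cross_grid` (required for `"permute"`).
#' @param n_perm Number of permutations (default 2000).
#' @param seed Seed for the permutation null.
#' @return The matrix with `P` filled.
#' @export
s_pvalues <- function(m, method = c("empirical", "permute"),
                      grid = NULL, n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  S <- m$S
  fin <- is.finite(S)
  if (method == "empirical") {
    if (sum(fin[upper.tri(fin)]) < 50L)
      stop("s_pvalues: fewer than 50 finite S values; use method = \"permute\"")
    med <- stats::median(S[fin])
    sc <- diff(stats::quantile(S[fin], c(0.1, 0.9), names = FALSE)) /
      (2 * stats::qnorm(0.9))
    if (sc == 0)
      stop("s_pvalues: degenerate S distribution (zero robust scale)")
    z <- (S - med) / sc
    P <- 2 * stats::pnorm(-abs(z))
  } else {
    if (is.null(grid)) stop("s_pvalues: permutation null needs the grid")
    null_s <- permuted_null_scores(grid, n_perm = n_perm, seed = seed)
    null_abs <- sort(abs(null_s))
    cnt <- length(null_abs) - findInterval(abs(S) - 1e-12, null_abs)
    P <- matrix((cnt + 1) / (length(null_abs) + 1), nrow(S), ncol(S),
                dimnames = dimnames(S))
  }
  P[!fin] <- NA_real_
  m$P <- P
  m
}

permuted_null_scores <- function(grid, n_perm, seed) {
  set.seed(as.integer(seed))
  ctrl <- fit_control_stats(grid)
  out <- vector("list", n_perm)
  sz <- grid$sizes
  d <- dim(sz)
  for (b in seq_len(n_perm)) {
    perm <- sz
    for (a in seq_len(d[2])) {
      col <- sz[, a, , drop = FALSE]
      perm[, a, ] <- array(sample(col), dim = c(d[1], 1L, d[3]))
    }
    g2 <- grid
    g2$sizes <- perm
    out[[b]] <- as.vector(score_grid(g2, ctrl = ctrl)$s)
  }
  x <- unlist(out)
  x[is.finite(x)]
}

#' Bonferroni genome-wide significance threshold
#'
#' @param m An `interaction_matrix` with P filled (used to count tested
#'   pairs), or a number of tested pairs.
#' @param alpha Family-wise alpha (default 0.05).
#' @return The per-pair P threshold `alpha / N`, with attribute `n_tested`.
#' @export
bonferroni_cut <- function(m, alpha = 0.05) {
  n <- if (inherits(m, "interaction_matrix")) {
    sum(is.finite(m$P[upper.tri(m$P)]))
  } else as.integer(m)
  if (n <= 0L) stop("bonferroni_cut: no tested pairs")
  structure(alpha / n, n_tested = n)
}

#' Run the full raw-to-matrix scoring pipeline
#'
#' Normalizes the grid, fits control statistics, scores both directions of
#' every cross, symmetrizes, and attaches P values.
#'
#' @param grid A raw `cross_grid` with queries == arrays.
#' @param polish Passed to [normalize_grid()].
#' @param null P-value method, `"empirical"` (default) or `"permute"`.
#' @param pvalues Logical; skip the P-value step when FALSE (e.g. noise-free
#'   screens, whose degenerate S distribution has no empirical null).
#' @param n_perm,seed Permutation-null settings.
#' @return A list with `matrix` (`interaction_matrix` with P), `pairs`
#'   (`raw_score_pairs`), `ctrl` (`control_stats`), `grid` (normalized grid),
#'   and `s_dir` (directional score matrix).
#' @export
score_screen <- function(grid, polish = FALSE,
                         null = c("empirical", "permute"),
                         pvalues = TRUE, n_perm = 2000L, seed = 1L) {
  null <- match.arg(null)
  ng <- normalize_grid(grid, polish = polish)
  sg <- score_grid(ng)
  pairs <- raw_score_pairs(sg$s, sg$s_stab)
  m <- symmetrize(pairs, genes = rownames(sg$s))
  if (pvalues)
    m <- s_pvalues(m, method = null, grid = ng, n_perm = n_perm, seed = seed)
  emap_log("score_screen[%s]: %d genes, %d pairs scored",
           grid$condition, length(m$genes),
           sum(is.finite(m$S[upper.tri(m$S)])), level = "debug")
  list(matrix = m, pairs = pairs, ctrl = sg$ctrl, grid = ng, s_dir = sg$s)
}
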