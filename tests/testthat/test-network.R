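# Profile correlations, joint significance classes, curves, clustering,
# hyper-interactors, class cross-tabs and set overlaps.

oracle_profile_cor <- function(S, i, j) {
  x <- S[i, ]; y <- S[j, ]
  x[c(i, j)] <- NA; y[c(i, j)] <- NA
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  cor(x[ok], y[ok])
}

test_that("profile correlations exclude the mutual pair and match the oracle", {
  S <- random_S(20, seed = 21)
  m <- im_from_S(S)
  cm <- profile_correlations(m)
  for (i in c(1, 5, 12)) for (j in c(3, 9, 20)) {
    if (i == j) next
    expect_equal(cm$r[i, j], oracle_profile_cor(S, i, j), tolerance = 1e-12)
  }
  expect_identical(cm$r, t(cm$r))
  expect_true(all(cm$n_used[upper.tri(cm$n_used)] == 18))
  # a proportional profile gives r = 1 (built so the shared entries vanish)
  S2 <- S
  S2[2, ] <- 2 * S[1, ]; S2[, 2] <- 2 * S[, 1]
  S2[1, 2] <- S2[2, 1] <- S[1, 2]
  diag(S2) <- NA
  cm2 <- profile_correlations(im_from_S(S2))
  expect_equal(cm2$r[1, 2], 1.0)
  # r is invariant to the pair's own S value
  S3 <- S
  S3[1, 3] <- S3[3, 1] <- 50
  cm3 <- profile_correlations(im_from_S(S3))
  expect_equal(cm3$r[1, 3], cm$r[1, 3], tolerance = 1e-12)
  # a gene with an all-missing profile has only missing correlations
  S4 <- S
  S4[4, ] <- S4[, 4] <- NA
  cm4 <- profile_correlations(im_from_S(S4))
  expect_true(all(is.na(cm4$r[4, ])))
})

test_that("correlation P values follow the t transform", {
  S <- random_S(15, seed = 22)
  cm <- profile_correlations(im_from_S(S))
  r <- cm$r[2, 7]; n <- cm$n_used[2, 7]
  expect_equal(cm$P[2, 7],
               2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2),
               tolerance = 1e-12)
  # cross-check against the stats reference implementation
  x <- S[2, -c(2, 7)]; y <- S[7, -c(2, 7)]
  ok <- is.finite(x) & is.finite(y)
  expect_equal(cm$P[2, 7], cor.test(x[ok], y[ok])$p.value, tolerance = 1e-10)
})

test_that("pair classification partitions scored pairs at the stated cuts", {
  genes <- letters[1:4]
  S <- matrix(0, 4, 4, dimnames = list(genes, genes))
  S[1, 2] <- S[2, 1] <- -5
  P <- matrix(0.5, 4, 4, dimnames = list(genes, genes))
  P[1, 2] <- P[2, 1] <- 0.004          # significant S
  P[3, 4] <- P[4, 3] <- 0.005          # boundary: still significant (<=)
  m <- interaction_matrix(genes, S, P = P)
  r <- matrix(0.1, 4, 4); Pc <- matrix(0.2, 4, 4)
  Pc[3, 4] <- Pc[4, 3] <- 0.01         # significant correlation
  cm <- correlation_matrix(genes, r, Pc, matrix(10L, 4, 4))
  cl <- classify_pairs(m, cm)
  get <- function(a, b) cl$category[cl$pair == pair_key(a, b)]
  expect_equal(get("a", "b"), "S_ONLY")
  expect_equal(get("c", "d"), "BOTH")
  expect_equal(get("a", "c"), "NEITHER")
  # exactly one category per scored pair; counts sum to the total
  expect_equal(sum(attr(cl, "counts")), nrow(cl))
  expect_equal(nrow(cl), choose(4, 2))
})

test_that("high-correlation listing uses a strict inequality", {
  genes <- letters[1:4]
  r <- matrix(0, 4, 4)
  r[1, 2] <- r[2, 1] <- 0.51
  r[3, 4] <- r[4, 3] <- 0.5
  cm <- correlation_matrix(genes, r, matrix(0.5, 4, 4), matrix(10L, 4, 4))
  hi <- high_correlation_pairs(cm, 0.5)
  expect_equal(hi$pair, pair_key("a", "b"))   # 0.5 exactly is excluded
  empty <- correlation_matrix(genes, matrix(NA_real_, 4, 4),
                              matrix(NA_real_, 4, 4), matrix(NA_integer_, 4, 4))
  expect_equal(nrow(high_correlation_pairs(empty, 0.5)), 0L)
})

make_curve_input <- function(n_pairs, seed, s_const = NULL) {
  # build matrices with n_pairs significant pairs carrying known r and S
  set.seed(seed)
  n <- ceiling((1 + sqrt(1 + 8 * n_pairs)) / 2)
  stopifnot(choose(n, 2) >= n_pairs)
  genes <- sprintf("g%02d", 1:n)
  S <- matrix(0, n, n); P <- matrix(1, n, n)
  r <- matrix(NA_real_, n, n); nu <- matrix(NA_integer_, n, n)
  pr <- utils::combn(n, 2)[, 1:n_pairs, drop = FALSE]
  for (k in seq_len(n_pairs)) {
    i <- pr[1, k]; j <- pr[2, k]
    S[i, j] <- S[j, i] <- if (is.null(s_const)) rnorm(1, 0, 4) else s_const
    P[i, j] <- P[j, i] <- 0.001
    r[i, j] <- r[j, i] <- runif(1, -1, 1)
    nu[i, j] <- nu[j, i] <- 10L
  }
  dimnames(S) <- dimnames(P) <- dimnames(r) <- dimnames(nu) <-
    list(genes, genes)
  list(m = interaction_matrix(genes, S, P = P),
       c = correlation_matrix(genes, r, P * 0 + 0.5, nu))
}

test_that("curve windows chunk sorted pairs and match the sort-and-chunk oracle", {
  th <- emap_thresholds()
  inp <- make_curve_input(35, seed = 31)
  cv <- s_vs_correlation_curve(inp$m, inp$c, th)
  expect_equal(nrow(cv), 4L)               # 3 full windows + 1 partial of 5
  expect_equal(cv$n, c(10L, 10L, 10L, 5L))
  expect_equal(cv$partial, c(FALSE, FALSE, FALSE, TRUE))
  # oracle: sort by r, chunk, average
  idx <- which(upper.tri(inp$c$r) & is.finite(inp$c$r), arr.ind = TRUE)
  rv <- inp$c$r[idx]; sv <- inp$m$S[idx]
  o <- order(rv)
  chunks <- split(o, ceiling(seq_along(o) / 10))
  expect_equal(cv$mean_r, vapply(chunks, function(w) mean(rv[w]), 0),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(cv$mean_S, vapply(chunks, function(w) mean(sv[w]), 0),
               ignore_attr = TRUE, tolerance = 1e-12)
  # all-equal S gives a flat curve
  flat <- make_curve_input(20, seed = 32, s_const = -3)
  cvf <- s_vs_correlation_curve(flat$m, flat$c, th)
  expect_true(all(cvf$mean_S == -3))
  # rolling mode slides by one pair
  cvr <- s_vs_correlation_curve(inp$m, inp$c, th, mode = "rolling")
  expect_equal(nrow(cvr), 35L - 10L + 1L)
})

test_that("the positive/negative ratio handles empty denominators as missing", {
  th <- emap_thresholds()
  inp <- make_curve_input(10, seed = 33, s_const = 4)   # all positive
  pn <- pos_neg_ratio_curve(inp$m, inp$c, th)
  expect_true(is.na(pn$ratio))
  expect_equal(pn$n_pos, 10L)
  mixed <- make_curve_input(10, seed = 34)
  pnm <- pos_neg_ratio_curve(mixed$m, mixed$c, th)
  expect_equal(pnm$ratio, pnm$n_pos / pnm$n_neg)
})

test_that("curves are invariant to input gene order", {
  th <- emap_thresholds()
  fx <- suppressor_screen()
  m <- fx$scored$matrix
  cm <- profile_correlations(m)
  cv1 <- s_vs_correlation_curve(m, cm, th)
  set.seed(61)
  perm <- sample(length(m$genes))
  mp <- interaction_matrix(m$genes[perm], m$S[perm, perm], m$P[perm, perm],
                           m$flags[perm, perm])
  cmp <- correlation_matrix(cm$genes[perm], cm$r[perm, perm],
                            cm$P[perm, perm], cm$n_used[perm, perm])
  cv2 <- s_vs_correlation_curve(mp, cmp, th)
  expect_equal(cv1, cv2, tolerance = 1e-12)
})

test_that("hierarchical clustering separates planted blocks deterministically", {
  skip_if_not_installed("mclust")
  # two blocks of 6 genes with scaled-copy profiles over 40 partner genes
  set.seed(41)
  base1 <- rnorm(40); base2 <- rnorm(40)
  prof <- rbind(t(replicate(6, base1 * runif(1, 0.5, 2) + rnorm(40, 0, 0.1))),
                t(replicate(6, base2 * runif(1, 0.5, 2) + rnorm(40, 0, 0.1))))
  Sq <- matrix(0, 52, 52)
  Sq[1:12, 13:52] <- prof
  Sq <- Sq + t(Sq)
  genes <- sprintf("g%02d", 1:52)
  dimnames(Sq) <- list(genes, genes)
  cm_all <- profile_correlations(im_from_S(Sq))
  sub <- 1:12
  cm <- correlation_matrix(genes[sub], cm_all$r[sub, sub],
                           cm_all$P[sub, sub], cm_all$n_used[sub, sub])
  hc <- hierarchical_cluster(cm)
  k2 <- cutree(hc$tree, k = 2)[genes[sub]]
  truth <- rep(1:2, each = 6)
  expect_equal(mclust::adjustedRandIndex(k2, truth), 1.0)
  # near-identical profiles merge first, at distance near 0
  expect_lt(hc$tree$height[1], 0.1)
  # determinism
  hc2 <- hierarchical_cluster(cm)
  expect_identical(hc$order, hc2$order)
  # degenerate input
  empty <- correlation_matrix(genes[1:3], matrix(NA_real_, 3, 3),
                              matrix(NA_real_, 3, 3), matrix(NA_integer_, 3, 3))
  expect_error(hierarchical_cluster(empty), "no finite")
})

test_that("hyper-interactors are flagged for breadth, not chance counts", {
  # planted: one gene interacting with 30% of partners
  tr <- generate_truth(seed = 9, interaction_fraction = 0, n_suppressors = 0)
  hub <- tr$loci$gene_id[1]
  partners <- sample(tr$loci$gene_id[-1], round(0.3 * 119))
  tr$interactions <- setNames(runif(length(partners), -0.6, -0.4),
                              pair_key(hub, partners))
  m <- score_screen(simulate_colonies(tr, "control"))$matrix
  expect_identical(as.character(hyper_interactors(m)), hub)
  # uniform screens: empty in most seeds
  empty <- vapply(1:10, function(s) {
    tr0 <- generate_truth(seed = s + 600, n_suppressors = 0)
    m0 <- score_screen(simulate_colonies(tr0, "control"))$matrix
    length(hyper_interactors(m0)) == 0L
  }, logical(1))
  expect_gte(sum(empty), 9L)
  # empty matrix
  m_empty <- im_from_S(random_S(4, seed = 1) * NA_real_)
  expect_length(hyper_interactors(m_empty), 0L)
})

test_that("class cross-tabs report per-class-pair interaction frequencies", {
  genes <- letters[1:6]
  S <- matrix(0, 6, 6); P <- matrix(1, 6, 6)
  # significant pairs: a-b (within class X), d-e (within class Y)
  S[1, 2] <- S[2, 1] <- -5; P[1, 2] <- P[2, 1] <- 0.001
  S[4, 5] <- S[5, 4] <- -4; P[4, 5] <- P[5, 4] <- 0.001
  dimnames(S) <- dimnames(P) <- list(genes, genes)
  m <- interaction_matrix(genes, S, P = P)
  loci <- gene_loci(genes, rep("chr1", 6), (0:5) * 1e6, (0:5) * 1e6 + 1000,
                    functional_class = c("X", "X", "X", "Y", "Y", NA))
  ct <- class_crosstab(m, loci)
  expect_equal(ct$interaction["X", "X"], 1 / 3)  # 1 of 3 within-X pairs
  expect_equal(ct$interaction["Y", "Y"], 1)      # 1 of 1 within-Y pair
  expect_equal(ct$interaction["X", "Y"], 0)      # no cross-class interactions
  expect_true("unannotated" %in% rownames(ct$interaction))
  expect_equal(ct$tested["X", "Y"], 6)
})

test_that("set overlap counts Venn regions exactly", {
  a <- pair_key(c("a", "a", "b"), c("b", "c", "c"))
  # identical sets intersect fully
  ov <- set_overlap(a, list(ref = a))
  expect_equal(ov$count[ov$region == "tested&ref"], 3L)
  # disjoint sets have empty intersections
  b <- pair_key(c("x", "x"), c("y", "z"))
  ov2 <- set_overlap(a, list(ref = b))
  expect_true(!"tested&ref" %in% ov2$region)
  expect_equal(ov2$count[ov2$region == "tested"], 3L)
  expect_equal(ov2$count[ov2$region == "ref"], 2L)
  # random sets against a direct set-algebra oracle
  set.seed(51)
  for (k in 1:20) {
    u <- pair_key(sample(letters, 40, TRUE), sample(LETTERS, 40, TRUE))
    s1 <- sample(u, 15); s2 <- sample(u, 20)
    ov3 <- set_overlap(s1, list(r = s2))
    both <- length(intersect(unique(s1), unique(s2)))
    got <- ov3$count[ov3$region == "tested&r"]
    expect_equal(if (length(got)) got else 0L, both)
  }
})
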