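# Shared fixtures, built in code. All screens are small enough to simulate
# and score in well under a second; a few heavily reused ones are cached for
# the duration of the test run.

options(emapkit.verbose = "quiet")

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# noise-free, fitness-homogeneous screen with planted interactions: the exact
# limit in which every robust estimate is tie-exact
noise_free_screen <- function(seed = 42, n_genes = 60) {
  cached(sprintf("nf_%d_%d", seed, n_genes), {
    tr <- generate_truth(n_genes = n_genes, n_chromosomes = 3,
                         fitness_range = c(1, 1), interaction_fraction = 0.02,
                         n_suppressors = 0, noise_cv = 0, seed = seed)
    list(truth = tr,
         scored = score_screen(simulate_colonies(tr, "control"),
                               pvalues = FALSE))
  })
}

# the default planted-suppressor fixture (120 genes, one 10-gene region)
suppressor_screen <- function(seed = 11) {
  cached(sprintf("sup_%d", seed), {
    tr <- generate_truth(seed = seed)
    list(truth = tr,
         scored = score_screen(simulate_colonies(tr, "control")))
  })
}

# genes chromosomally linked to a planted suppressor locus (the true region)
planted_region <- function(truth) {
  sup <- truth$suppressors
  truth$loci$gene_id[truth$loci$chromosome == sup$chromosome[1] &
                     abs(truth$loci$start_bp - sup$position_bp[1]) <
                       truth$linkage_bp]
}

# a small interaction matrix built directly from an S matrix
im_from_S <- function(S, P = NULL) {
  interaction_matrix(rownames(S), S, P = P)
}

# deterministic symmetric S matrix with unit-scale noise, for constructed cases
random_S <- function(n, seed, genes = sprintf("g%02d", seq_len(n))) {
  set.seed(seed)
  S <- matrix(stats::rnorm(n * n), n, n, dimnames = list(genes, genes))
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- NA_real_
  S
}

# matrices whose significant pairs carry the given correlation and S vectors,
# for exercising the window-curve operations on known inputs
curve_fixture <- function(r_vals, s_vals) {
  npair <- length(r_vals)
  n <- ceiling((1 + sqrt(1 + 8 * npair)) / 2)
  genes <- sprintf("g%03d", seq_len(n))
  S <- matrix(0, n, n); P <- matrix(1, n, n)
  r <- matrix(NA_real_, n, n); nu <- matrix(NA_integer_, n, n)
  idx <- utils::combn(n, 2)[, seq_len(npair), drop = FALSE]
  for (k in seq_len(npair)) {
    i <- idx[1, k]; j <- idx[2, k]
    S[i, j] <- S[j, i] <- s_vals[k]
    P[i, j] <- P[j, i] <- 0.001
    r[i, j] <- r[j, i] <- r_vals[k]
    nu[i, j] <- nu[j, i] <- 10L
  }
  dimnames(S) <- dimnames(P) <- dimnames(r) <- dimnames(nu) <-
    list(genes, genes)
  list(m = interaction_matrix(genes, S, P = P),
       c = correlation_matrix(genes, r, P * 0 + 0.5, nu))
}

# straight-line brute-force oracle of the S statistic (kept independent of
# compute_s_score's implementation)
oracle_s <- function(obs, expected, spread, n_ctrl, vfloor, prior_df = 6) {
  obs <- obs[is.finite(obs)]
  n <- length(obs)
  v <- ((n - 1) * stats::var(obs) + prior_df * vfloor^2) / (n - 1 + prior_df)
  (mean(obs) - expected) / sqrt(spread^2 / n_ctrl + v / n)
}
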