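# Genome ordering, linkage masking, suppressor-region detection and the
# positional permutation null.

make_loci_line <- function(n, spacing = 20000L, chroms = 2L) {
  per <- ceiling(n / chroms)
  chrom <- rep(paste0("chr", seq_len(chroms)), each = per)[1:n]
  within <- ave(seq_len(n), chrom, FUN = seq_along)
  gene_loci(sprintf("g%02d", 1:n), chrom, (within - 1L) * spacing,
            (within - 1L) * spacing + 1500L)
}

test_that("genome ordering matches a lexicographic sort oracle", {
  loci <- make_loci_line(20)
  S <- random_S(20, seed = 81, genes = loci$gene_id)
  m0 <- im_from_S(S)
  # already ordered: identity
  expect_identical(order_by_genome(m0, loci)$genes, loci$gene_id)
  # reversed input: exact reversal back to genome order
  rev_ <- rev(seq_len(20))
  mr <- interaction_matrix(loci$gene_id[rev_], S[rev_, rev_])
  expect_identical(order_by_genome(mr, loci)$genes, loci$gene_id)
  # random permutation against an explicit sort oracle
  set.seed(82)
  perm <- sample(20)
  mp <- interaction_matrix(loci$gene_id[perm], S[perm, perm])
  mo <- order_by_genome(mp, loci)
  oracle <- loci$gene_id[order(match(loci$chromosome, unique(loci$chromosome)),
                               loci$start_bp)]
  expect_identical(mo$genes, oracle)
  expect_equal(mo$S, S[oracle, oracle])
  # gene without a locus errors
  expect_error(order_by_genome(m0, loci[-1, ]), "without locus")
})

test_that("linkage masking uses a strict 100 kb bound on the same chromosome", {
  loci <- gene_loci(c("A", "B", "C", "D"),
                    c("chr1", "chr1", "chr1", "chr2"),
                    c(0L, 99999L, 100000L, 0L),
                    c(1000L, 100999L, 101000L, 1000L))
  m <- im_from_S(random_S(4, seed = 83, genes = loci$gene_id))
  mm <- mask_linked_pairs(m, loci, 100000L)
  mk <- has_flag(mm, "MASKED_LINKED")
  expect_true(mk["A", "B"])    # 99,999 bp apart: masked
  expect_false(mk["A", "C"])   # exactly 100,000 bp: not masked
  expect_true(mk["B", "C"])    # 1 bp apart
  expect_false(mk["A", "D"])   # same coordinates, different chromosome
  expect_false(mk["C", "D"])
})

test_that("masking equals a brute-force all-pairs distance computation", {
  set.seed(84)
  for (k in 1:20) {
    n <- sample(5:15, 1)
    loci <- gene_loci(sprintf("g%02d", 1:n),
                      sample(paste0("chr", 1:3), n, TRUE),
                      st <- sample.int(400000L, n), st + 1000L)
    m <- im_from_S(random_S(n, seed = k, genes = loci$gene_id))
    lb <- sample(c(50000L, 100000L, 150000L), 1)
    mk <- has_flag(mask_linked_pairs(m, loci, lb), "MASKED_LINKED")
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expected <- loci$chromosome[i] == loci$chromosome[j] &&
        abs(loci$start_bp[i] - loci$start_bp[j]) < lb
      if (mk[i, j] != expected)
        fail(sprintf("mask mismatch at %d,%d (case %d)", i, j, k))
    }
  }
  succeed()
})

test_that("masked pairs drop out of significance counts and classifications", {
  fx <- suppressor_screen()
  th <- emap_thresholds()
  m <- mask_linked_pairs(fx$scored$matrix, fx$truth$loci, th$linkage_bp)
  cm <- profile_correlations(m)
  cl <- classify_pairs(m, cm, th)
  mk <- has_flag(m, "MASKED_LINKED")
  masked_keys <- all_pairs(m$genes)
  masked_keys <- masked_keys$pair[mk[cbind(match(masked_keys$gene_a, m$genes),
                                           match(masked_keys$gene_b, m$genes))]]
  expect_gt(length(masked_keys), 0L)
  expect_false(any(cl$pair %in% masked_keys))
  # hyper-interactor counting likewise ignores masked cells
  counts <- attr(hyper_interactors(m, th), "counts")
  expect_true(all(counts <= rowSums(!mk) - 1L))
})

test_that("an all-zero matrix produces no region calls", {
  loci <- make_loci_line(30)
  S <- matrix(0, 30, 30, dimnames = list(loci$gene_id, loci$gene_id))
  calls <- detect_regions(im_from_S(S), loci)
  expect_equal(nrow(calls), 0L)
})

test_that("run length gating follows region_min_run", {
  loci <- make_loci_line(30, chroms = 2L)   # chr1: g01..g15, chr2: g16..g30
  S <- matrix(0, 30, 30, dimnames = list(loci$gene_id, loci$gene_id))
  # distant gene g01 (chr1) interacts with 4 consecutive chr2 genes
  run <- sprintf("g%02d", 20:23)
  S["g01", run] <- S[run, "g01"] <- -5
  m <- im_from_S(S)
  expect_equal(nrow(detect_regions(m, loci,
                                   emap_thresholds(region_min_run = 5))), 0L)
  calls <- detect_regions(m, loci, emap_thresholds(region_min_run = 4))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$distant_gene, "g01")
  expect_equal(calls$member_genes, paste(run, collapse = ","))
  expect_equal(calls$run_length, 4L)
  expect_equal(calls$min_S, -5)
})

test_that("missing cells skip without breaking a run unless configured", {
  loci <- make_loci_line(30, chroms = 2L)
  S <- matrix(0, 30, 30, dimnames = list(loci$gene_id, loci$gene_id))
  run <- sprintf("g%02d", 20:25)
  S["g01", run] <- S[run, "g01"] <- -5
  S["g01", "g22"] <- S["g22", "g01"] <- NA   # failed cross inside the region
  m <- im_from_S(S)
  th <- emap_thresholds(region_min_run = 5)
  calls <- detect_regions(m, loci, th)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$run_length, 5L)         # 6 planted minus the missing one
  calls2 <- detect_regions(m, loci, th, missing_breaks_run = TRUE)
  expect_equal(nrow(calls2), 0L)             # split into runs of 2 and 3
})

test_that("runs inside the distant gene's own linkage neighborhood are discarded", {
  loci <- make_loci_line(30, chroms = 1L, spacing = 20000L)  # one chromosome
  genes <- loci$gene_id
  S <- matrix(0, 30, 30, dimnames = list(genes, genes))
  # g15 with a run right next to itself (within 100 kb): linkage, not signal
  near <- sprintf("g%02d", 16:20)
  S["g15", near] <- S[near, "g15"] <- -6
  # and a second run far away on the same chromosome (well outside 100 kb)
  far <- sprintf("g%02d", 26:30)
  S["g15", far] <- S[far, "g15"] <- -6
  m <- im_from_S(S)
  calls <- detect_regions(m, loci, emap_thresholds(region_min_run = 5))
  g15 <- calls[calls$distant_gene == "g15", ]
  expect_equal(nrow(g15), 1L)
  expect_equal(g15$member_genes, paste(far, collapse = ","))
})

test_that("the planted suppressor region is recovered exactly", {
  fx <- suppressor_screen()
  th <- emap_thresholds()
  m <- mask_linked_pairs(fx$scored$matrix, fx$truth$loci, th$linkage_bp)
  hyper <- hyper_interactors(m, th)
  calls <- detect_regions(m, fx$truth$loci, th, exclude_hyper = hyper)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$distant_gene, fx$truth$suppressors$carrier_query)
  planted <- planted_region(fx$truth)
  members <- strsplit(calls$member_genes, ",")[[1]]
  expect_lte(length(setdiff(planted, members)), 1L)
  expect_lte(length(setdiff(members, planted)), 1L)
  expect_lt(calls$median_S, th$region_s_cut)
  # exhaustive run-scan oracle over the carrier's profile
  carrier <- fx$truth$suppressors$carrier_query
  chr <- fx$truth$suppressors$chromosome
  on_ch <- fx$truth$loci$gene_id[fx$truth$loci$chromosome == chr]
  on_ch <- on_ch[order(fx$truth$loci$start_bp[match(on_ch, fx$truth$loci$gene_id)])]
  below <- m$S[carrier, on_ch] < th$region_s_cut
  runs <- rle(as.vector(below))
  best <- max(runs$lengths[runs$values])
  expect_equal(calls$run_length, best)
})

test_that("region detection is invariant to matrix row order", {
  fx <- suppressor_screen()
  th <- emap_thresholds()
  m <- mask_linked_pairs(fx$scored$matrix, fx$truth$loci, th$linkage_bp)
  set.seed(85)
  perm <- sample(length(m$genes))
  mp <- interaction_matrix(m$genes[perm], m$S[perm, perm], m$P[perm, perm],
                           m$flags[perm, perm])
  c1 <- detect_regions(m, fx$truth$loci, th)
  c2 <- detect_regions(mp, fx$truth$loci, th)
  expect_equal(c1, c2)
})

test_that("the positional permutation null is seeded and bounds real screens", {
  fx <- suppressor_screen()
  th <- emap_thresholds()
  m <- mask_linked_pairs(fx$scored$matrix, fx$truth$loci, th$linkage_bp)
  nr1 <- region_null_rate(m, fx$truth$loci, th, permutations = 25, seed = 9)
  nr2 <- region_null_rate(m, fx$truth$loci, th, permutations = 25, seed = 9)
  expect_identical(nr1$counts, nr2$counts)
  expect_error(region_null_rate(m, fx$truth$loci, th, permutations = 0),
               "permutations")
  # the planted screen's observed call count exceeds the positional null
  obs <- nrow(detect_regions(m, fx$truth$loci, th))
  expect_gt(obs, nr1$q95)
})

test_that("the genome heat map writes a faithful ordered TSV", {
  fx <- suppressor_screen()
  th <- emap_thresholds()
  m <- mask_linked_pairs(fx$scored$matrix, fx$truth$loci, th$linkage_bp)
  png_path <- file.path(withr::local_tempdir(), "heatmap.png")
  paths <- genome_heatmap(m, fx$truth$loci, png_path)
  expect_true(all(file.exists(paths)))
  back <- read_matrix(paths[["tsv"]])
  mo <- order_by_genome(m, fx$truth$loci)
  expect_identical(back$genes, mo$genes)
  expect_identical(back$S, mo$S)
  # masked cells form one diagonal block per chromosome, sized by the number
  # of screened genes on that chromosome
  mk <- has_flag(back, "MASKED_LINKED")
  chrom <- fx$truth$loci$chromosome[match(back$genes, fx$truth$loci$gene_id)]
  expect_false(any(mk[chrom == "chr1", chrom == "chr2"]))
  blk <- mk[chrom == "chr1", chrom == "chr1"]
  expect_equal(dim(blk), rep(sum(chrom == "chr1"), 2))
  expect_true(any(blk))
})
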