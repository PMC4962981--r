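#' Generate the ground truth of a synthetic E-MAP screen
#'
#' Lays screened genes out on chromosomes and plants every parameter the
#' analysis is meant to recover: single-mutant fitness, a sparse set of
#' genetic interactions (multiplicative deviations `epsilon` from the product
#' neutral model, negative = synthetic sick), condition-specific interaction
#' shifts applied only in the `"drug"` condition, noisy strains with inflated
#' replicate noise, per-plate scale factors, and query-borne suppressor
#' mutations that are lost whenever the partner gene is chromosomally linked
#' to the suppressor locus (selection for the array marker evicts the
#' suppressor).
#'
#' The defaults describe the package's reference screen: 120 genes on 4
#' chromosomes (30 genes per chromosome, one gene every 20 kb), quadruplicate
#' crosses, 2\% of pairs interacting (70\% negative), lognormal replicate
#' noise with a coefficient of variation of 0.15, and one suppressor whose
#' locus sits mid-chromosome between two genes so that exactly 10 genes fall
#' within the 100 kb linkage window.
#'
#' @param n_genes Number of screened genes (>= 4).
#' @param n_chromosomes Number of chromosomes (>= 1); genes are split evenly.
#' @param gene_spacing_bp Distance between consecutive gene starts.
#' @param gene_length_bp Gene length (end - start).
#' @param fitness_range Range for uniform single-mutant fitness draws; use
#'   `c(1, 1)` for a fitness-homogeneous screen (the exact noise-free limit).
#' @param interaction_fraction Fraction of unordered pairs with planted
#'   interactions.
#' @param prop_negative Proportion of planted interactions that are negative.
#' @param epsilon_neg_range,epsilon_pos_range Ranges for negative/positive
#'   interaction deviations.
#' @param n_drug_shifts Number of pairs with condition-specific shifts; half
#'   aggravating (negative `delta_epsilon` on otherwise neutral pairs), half
#'   alleviating (positive `delta_epsilon` on planted negative pairs).
#' @param drug_shift Absolute size of `delta_epsilon`.
#' @param n_noisy Number of noisy strains.
#' @param noisy_factor Replicate-noise inflation factor for noisy strains.
#' @param n_suppressors Number of suppressor-carrying strains.
#' @param rescue_factor Growth rescue factor of a suppressor (> 1).
#' @param noise_cv Replicate coefficient of variation (lognormal noise).
#' @param genes_per_plate Array genes per plate block; plates are unordered
#'   block pairs so reciprocal crosses share a plate.
#' @param plate_scale_sd Lognormal sd of per-plate scale factors (0 = none).
#' @param gradient Logical; plant a linear column gradient within each plate
#'   (a normalization stressor, off by default).
#' @param linkage_bp Linkage window used by the suppressor-loss mechanism.
#' @param seed Integer seed; the truth is deterministic given the seed.
#' @return An object of class `synthetic_truth`.
#' @export
generate_truth <- function(n_genes = 120L, n_chromosomes = 4L,
                           gene_spacing_bp = 20000L, gene_length_bp = 1500L,
                           fitness_range = c(0.7, 1),
                           interaction_fraction = 0.02,
                           prop_negative = 0.7,
                           epsilon_neg_range = c(-0.8, -0.3),
                           epsilon_pos_range = c(0.3, 0.6),
                           n_drug_shifts = 0L, drug_shift = 0.45,
                           n_noisy = 0L, noisy_factor = 5,
                           n_suppressors = 1L, rescue_factor = 2.5,
                           noise_cv = 0.15,
                           genes_per_plate = 30L, plate_scale_sd = 0.1,
                           gradient = FALSE,
                           linkage_bp = 100000L,
                           seed = 1L) {
  if (n_genes < 4L) stop("generate_truth: need at least 4 genes")
  if (n_chromosomes < 1L) stop("generate_truth: need at least 1 chromosome")
  if (n_suppressors > n_genes) stop("generate_truth: more suppressors than strains")
  if (n_noisy > n_genes) stop("generate_truth: more noisy strains than strains")
  if (rescue_factor <= 1) stop("generate_truth: rescue_factor must be > 1")
  if (noise_cv < 0) stop("generate_truth: noise_cv must be >= 0")
  set.seed(as.integer(seed))

  per_chrom <- ceiling(n_genes / n_chromosomes)
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), each = per_chrom)[seq_len(n_genes)]
  within <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- (within - 1L) * gene_spacing_bp
  gene_id <- sprintf("g%03d", seq_len(n_genes))
  loci <- gene_loci(gene_id, chrom, start, start + gene_length_bp,
                    functional_class = sample(c("transporter", "lipid biosynthesis",
                                                "cell wall", "unknown"),
                                              n_genes, replace = TRUE),
                    location_label = sample(c("ER", "PM", "mitochondria", "vacuole"),
                                            n_genes, replace = TRUE))

  fitness <- stats::runif(n_genes, fitness_range[1], fitness_range[2])
  names(fitness) <- gene_id

  pairs <- all_pairs(gene_id)
  n_int <- round(interaction_fraction * nrow(pairs))
  int_idx <- if (n_int > 0L) sample(nrow(pairs), n_int) else integer()
  neg <- stats::rbinom(n_int, 1L, prop_negative) == 1L
  eps <- numeric(n_int)
  eps[neg] <- stats::runif(sum(neg), epsilon_neg_range[1], epsilon_neg_range[2])
  eps[!neg] <- stats::runif(sum(!neg), epsilon_pos_range[1], epsilon_pos_range[2])
  interactions <- stats::setNames(eps, pairs$pair[int_idx])

  # condition-specific shifts: aggravating on neutral pairs, alleviating on
  # planted negative pairs (an existing sick interaction relieved on drug)
  drug_shifts <- numeric(0)
  if (n_drug_shifts > 0L) {
    n_agg <- ceiling(n_drug_shifts / 2)
    n_all <- n_drug_shifts - n_agg
    neutral <- setdiff(seq_len(nrow(pairs)), int_idx)
    neg_pairs <- names(interactions)[interactions < 0]
    if (length(neutral) < n_agg || length(neg_pairs) < n_all)
      stop("generate_truth: not enough pairs to host the requested drug shifts")
    agg <- pairs$pair[sample(neutral, n_agg)]
    all_ <- sample(neg_pairs, n_all)
    drug_shifts <- stats::setNames(c(rep(-drug_shift, n_agg), rep(drug_shift, n_all)),
                                   c(agg, all_))
  }

  noisy_strains <- if (n_noisy > 0L) sample(gene_id, n_noisy) else character()

  suppressors <- NULL
  if (n_suppressors > 0L) {
    if (n_chromosomes < 2L)
      stop("generate_truth: suppressors need >= 2 chromosomes (carrier and locus must be unlinked)")
    chroms <- unique(loci$chromosome)
    sup_list <- vector("list", n_suppressors)
    for (s in seq_len(n_suppressors)) {
      sup_chrom <- chroms[(s %% length(chroms)) + 1L]
      on_chrom <- loci[loci$chromosome == sup_chrom, ]
      mid <- floor(nrow(on_chrom) / 2)
      # midway between two gene starts, so the strict < linkage window holds a
      # symmetric block of genes on either side
      sup_pos <- on_chrom$start_bp[mid] + gene_spacing_bp %/% 2L
      carrier <- sample(loci$gene_id[loci$chromosome != sup_chrom], 1L)
      sup_list[[s]] <- data.frame(carrier_query = carrier,
                                  chromosome = sup_chrom,
                                  position_bp = sup_pos,
                                  rescue_factor = rescue_factor,
                                  stringsAsFactors = FALSE)
    }
    suppressors <- do.call(rbind, sup_list)
  }

  n_blocks <- ceiling(n_genes / genes_per_plate)
  block_pairs <- expand.grid(i = seq_len(n_blocks), j = seq_len(n_blocks))
  block_pairs <- block_pairs[block_pairs$i <= block_pairs$j, ]
  plate_ids <- sprintf("P%d.%d", block_pairs$i, block_pairs$j)
  plate_scales <- stats::setNames(
    if (plate_scale_sd > 0) stats::rlnorm(length(plate_ids), 0, plate_scale_sd)
    else rep(1, length(plate_ids)),
    plate_ids)

  structure(list(loci = loci, single_fitness = fitness,
                 interactions = interactions, drug_shifts = drug_shifts,
                 noisy_strains = noisy_strains, noisy_factor = noisy_factor,
                 suppressors = suppressors,
                 noise_cv = noise_cv, plate_scales = plate_scales,
                 genes_per_plate = as.integer(genes_per_plate),
                 gradient = isTRUE(gradient),
                 linkage_bp = as.integer(linkage_bp),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d genes / %d chromosomes, %d interactions, ",
                     "%d drug shifts, %d noisy strains, %d suppressors, cv %.3g, seed %d\n"),
              nrow(x$loci), length(unique(x$loci$chromosome)),
              length(x$interactions), length(x$drug_shifts),
              length(x$noisy_strains), NROW(x$suppressors),
              x$noise_cv, x$seed))
  invisible(x)
}

# plate id for query index qi and array index ai (unordered block pair)
plate_id_for <- function(qi, ai, genes_per_plate) {
  bq <- (qi - 1L) %/% genes_per_plate + 1L
  ba <- (ai - 1L) %/% genes_per_plate + 1L
  sprintf("P%d.%d", pmin(bq, ba), pmax(bq, ba))
}

#' Simulate a replicate colony-size grid from planted truth
#'
#' Expected size of the cross `[query q x array a]` is
#' `plate_scale * f_q * f_a * (1 + epsilon_qa (+ delta_epsilon_qa on drug))`,
#' multiplied by the suppressor `rescue_factor` whenever the strain of `q` (or
#' `a`) carries a suppressor and the partner gene does *not* lie within
#' `linkage_bp` of the suppressor locus on the same chromosome: a linked array
#' marker evicts the suppressor during selection, and suppressor loss is
#' deterministic inside the window. Replicates are drawn lognormally around
#' the expectation with coefficient of variation `noise_cv` (inflated by
#' `noisy_factor` for noisy strains); `noise_cv = 0` returns the expectation
#' exactly. Queries and arrays are the full gene set, so the grid contains
#' both `[q x a]` and `[a x q]` crosses with independent noise.
#'
#' @param truth A `synthetic_truth`.
#' @param condition `"control"` or `"drug"`.
#' @param replicates Replicates per cross (default 4, quadruplicate crosses).
#' @param seed Seed for the noise draws; defaults to a condition-specific
#'   offset of `truth$seed` so the two conditions get independent noise.
#' @return A `cross_grid`.
#' @export
simulate_colonies <- function(truth, condition = c("control", "drug"),
                              replicates = 4L, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  condition <- match.arg(condition)
  if (is.null(seed))
    seed <- truth$seed + if (condition == "drug") 200003L else 100003L
  set.seed(as.integer(seed))

  genes <- truth$loci$gene_id
  n <- length(genes)
  f <- truth$single_fitness[genes]

  eps <- matrix(0, n, n, dimnames = list(genes, genes))
  assign_pairs <- function(m, shifts) {
    if (!length(shifts)) return(m)
    gg <- do.call(rbind, strsplit(names(shifts), "|", fixed = TRUE))
    i <- match(gg[, 1], genes); j <- match(gg[, 2], genes)
    m[cbind(i, j)] <- m[cbind(i, j)] + shifts
    m[cbind(j, i)] <- m[cbind(j, i)] + shifts
    m
  }
  eps <- assign_pairs(eps, truth$interactions)
  if (condition == "drug") eps <- assign_pairs(eps, truth$drug_shifts)

  expect <- outer(f, f) * (1 + eps)

  # suppressor rescue, lost where the partner is linked to the suppressor locus
  if (NROW(truth$suppressors)) {
    for (s in seq_len(nrow(truth$suppressors))) {
      sp <- truth$suppressors[s, ]
      linked <- truth$loci$chromosome == sp$chromosome &
        abs(truth$loci$start_bp - sp$position_bp) < truth$linkage_bp
      ci <- match(sp$carrier_query, genes)
      expect[ci, !linked] <- expect[ci, !linked] * sp$rescue_factor
      expect[!linked, ci] <- expect[!linked, ci] * sp$rescue_factor
    }
  }

  qi <- rep(seq_len(n), times = n)
  ai <- rep(seq_len(n), each = n)
  plate_of <- matrix(plate_id_for(qi, ai, truth$genes_per_plate), n, n,
                     dimnames = list(genes, genes))
  expect <- expect * matrix(truth$plate_scales[plate_of], n, n)

  if (truth$gradient) {
    pos <- (seq_len(n) - 1L) %% truth$genes_per_plate + 1L
    gsz <- pmin(truth$genes_per_plate, n)
    grad <- 1 + 0.3 * (pos - (gsz + 1) / 2) / gsz
    expect <- sweep(expect, 2L, grad, `*`)
  }

  cv <- matrix(truth$noise_cv, n, n)
  if (length(truth$noisy_strains)) {
    ni <- match(truth$noisy_strains, genes)
    cv[ni, ] <- cv[ni, ] * truth$noisy_factor
    cv[, ni] <- pmax(cv[, ni], truth$noise_cv * truth$noisy_factor)
  }

  sizes <- array(NA_real_, c(n, n, replicates), dimnames = list(genes, genes, NULL))
  for (r in seq_len(replicates)) {
    if (truth$noise_cv == 0) {
      sizes[, , r] <- expect
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      draw <- stats::rlnorm(n * n, meanlog = log(expect) - sdlog^2 / 2,
                            sdlog = as.vector(sdlog))
      sizes[, , r] <- matrix(draw, n, n)
    }
  }
  g <- cross_grid(condition, sizes, plate_of, loci = truth$loci)
  emap_log("simulate_colonies[%s]: %d x %d x %d grid (seed %d)",
           condition, n, n, replicates, seed, level = "debug")
  g
}

#' Write a simulated screen to disk
#'
#' Writes the control and drug colony grids, the locus table and a plain-text
#' truth summary (planted interactions, shifts, noisy strains, suppressors).
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @param replicates Replicates per cross.
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(truth, dir, replicates = 4L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    loci = file.path(dir, "loci.bed"),
    control = file.path(dir, "colonies_control.tsv"),
    drug = file.path(dir, "colonies_drug.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_locus_table(truth$loci, paths[["loci"]])
  write_cross_grid(simulate_colonies(truth, "control", replicates), paths[["control"]])
  write_cross_grid(simulate_colonies(truth, "drug", replicates), paths[["drug"]])
  rows <- character()
  if (length(truth$interactions))
    rows <- c(rows, sprintf("interaction\t%s\t%.17g", names(truth$interactions),
                            truth$interactions))
  if (length(truth$drug_shifts))
    rows <- c(rows, sprintf("drug_shift\t%s\t%.17g", names(truth$drug_shifts),
                            truth$drug_shifts))
  if (length(truth$noisy_strains))
    rows <- c(rows, sprintf("noisy_strain\t%s\tNA", truth$noisy_strains))
  if (NROW(truth$suppressors))
    rows <- c(rows, sprintf("suppressor\t%s\t%s:%d:x%.3g",
                            truth$suppressors$carrier_query,
                            truth$suppressors$chromosome,
                            truth$suppressors$position_bp,
                            truth$suppressors$rescue_factor))
  writeLines(c("record\tkey\tvalue", rows), paths[["truth"]])
  invisible(paths)
}
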