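# Genome-order analytics: linkage masking, genome-ordered heat maps, and the
# scan for chromosomal regions that uniformly interact with one distant gene.
#
# Double mutants of two genes close on the same chromosome are depleted by
# meiotic linkage, not genetic interaction, so linked pairs are masked. A
# contiguous run of genes all strongly interacting with the same distant gene
# is instead the signature of an undeclared suppressor mutation carried by
# the distant gene's strain and lost wherever the selected partner marker is
# linked to the suppressor locus.

gene_genome_order <- function(genes, loci, chrom_order = NULL) {
  i <- match(genes, loci$gene_id)
  if (anyNA(i))
    stop("gene(s) without locus: ", paste(genes[is.na(i)], collapse = ", "))
  chroms <- chrom_order %||% unique(loci$chromosome)
  ci <- match(loci$chromosome[i], chroms)
  if (anyNA(ci)) stop("chromosome(s) missing from chromosome order")
  order(ci, loci$start_bp[i], genes)
}

#' Reorder an interaction matrix in genome order
#'
#' Genes are sorted by chromosome (in the order given, or the order of first
#' appearance in the locus table) and by `start_bp` within each chromosome;
#' rows and columns are permuted consistently.
#'
#' @param m An `interaction_matrix`.
#' @param loci A `gene_loci` table covering every matrix gene.
#' @param chrom_order Optional character vector fixing the chromosome order.
#' @return The reordered `interaction_matrix`.
#' @export
order_by_genome <- function(m, loci, chrom_order = NULL) {
  ord <- gene_genome_order(m$genes, loci, chrom_order)
  interaction_matrix(m$genes[ord], m$S[ord, ord], m$P[ord, ord],
                     m$flags[ord, ord])
}

#' Mask chromosomally linked pairs
#'
#' Pairs on the same chromosome whose `start_bp` positions are closer than
#' `linkage_bp` (strict `<`) are flagged `MASKED_LINKED` and excluded from
#' significance counts, profile correlations and region calls. Pairs on
#' different chromosomes are never masked.
#'
#' @param m An `interaction_matrix`.
#' @param loci A `gene_loci` table.
#' @param linkage_bp Masking distance in base pairs.
#' @return The flagged matrix.
#' @export
mask_linked_pairs <- function(m, loci, linkage_bp = 100000L) {
  i <- match(m$genes, loci$gene_id)
  if (anyNA(i))
    stop("mask_linked_pairs: gene(s) without locus: ",
         paste(m$genes[is.na(i)], collapse = ", "))
  chrom <- loci$chromosome[i]
  start <- loci$start_bp[i]
  same <- outer(chrom, chrom, `==`)
  near <- abs(outer(start, start, `-`)) < linkage_bp
  mask <- same & near
  diag(mask) <- FALSE
  m$flags[mask] <- flag_add(m$flags[mask], "MASKED_LINKED")
  emap_log("mask_linked_pairs: %d pairs masked (< %d bp)",
           sum(mask[upper.tri(mask)]), as.integer(linkage_bp))
  m
}

#' Detect chromosomal regions uniformly interacting with one distant gene
#'
#' For every gene `g` (outside `exclude_hyper`), each chromosome is traversed
#' in genome order over the genes with finite, unmasked `S[g, .]`; maximal
#' runs of consecutive genes all scoring below `th$region_s_cut` are
#' collected and reported when at least `th$region_min_run` genes long.
#' Missing cells are skipped without breaking a run by default (a failed
#' cross should not split a real region; set `missing_breaks_run = TRUE` to
#' change that); masked linked cells are likewise skipped. Runs that touch
#' `g`'s own linkage neighborhood (within `th$linkage_bp` of `g` on its own
#' chromosome) are discarded — they reflect linkage, not a transferred
#' suppressor. Calls are sorted by run length (descending), then minimum S
#' (ascending), then gene id.
#'
#' @param m An `interaction_matrix` (any row order; genome order is
#'   re-derived internally).
#' @param loci A `gene_loci` table.
#' @param th An `emap_thresholds` (uses `region_s_cut`, `region_min_run`,
#'   `linkage_bp`).
#' @param exclude_hyper Gene ids never considered as the distant gene
#'   (hyper-interactors; see [hyper_interactors()]).
#' @param missing_breaks_run Logical (default FALSE).
#' @return Data frame of class `region_calls`: `distant_gene`, `chromosome`,
#'   `region_start_bp`, `region_end_bp`, `member_genes` (comma-separated),
#'   `run_length`, `n_below_cut`, `min_S`, `median_S`.
#' @export
detect_regions <- function(m, loci, th = emap_thresholds(),
                           exclude_hyper = character(),
                           missing_breaks_run = FALSE) {
  ord <- gene_genome_order(m$genes, loci)
  genes <- m$genes[ord]
  S <- usable_S(m)[ord, ord]
  masked <- has_flag(m, "MASKED_LINKED")[ord, ord]
  li <- match(genes, loci$gene_id)
  chrom <- loci$chromosome[li]
  start <- loci$start_bp[li]
  end <- loci$end_bp[li]

  calls <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    if (g %in% exclude_hyper) next
    for (ch in unique(chrom)) {
      on_ch <- which(chrom == ch & genes != g)
      if (!length(on_ch)) next
      run <- integer()
      flush <- function(run) {
        if (length(run) < th$region_min_run) return(NULL)
        r_start <- min(start[run]); r_end <- max(end[run])
        # a run touching g's own linkage neighborhood is linkage, not signal
        if (chrom[gi] == ch &&
            start[gi] >= r_start - th$linkage_bp &&
            start[gi] <= r_end + th$linkage_bp) return(NULL)
        sv <- S[gi, run]
        data.frame(distant_gene = g, chromosome = ch,
                   region_start_bp = r_start, region_end_bp = r_end,
                   member_genes = paste(genes[run], collapse = ","),
                   run_length = length(run), n_below_cut = length(run),
                   min_S = min(sv), median_S = stats::median(sv),
                   stringsAsFactors = FALSE)
      }
      for (k in on_ch) {
        v <- S[gi, k]
        if (masked[gi, k] || (is.na(v) && !missing_breaks_run)) next
        if (is.finite(v) && v < th$region_s_cut) {
          run <- c(run, k)
        } else {
          calls[[length(calls) + 1L]] <- flush(run)
          run <- integer()
        }
      }
      calls[[length(calls) + 1L]] <- flush(run)
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(distant_gene = character(), chromosome = character(),
                      region_start_bp = integer(), region_end_bp = integer(),
                      member_genes = character(), run_length = integer(),
                      n_below_cut = integer(), min_S = numeric(),
                      median_S = numeric(), stringsAsFactors = FALSE)
  out <- out[order(-out$run_length, out$min_S, out$distant_gene,
                   out$chromosome, out$region_start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_calls", "data.frame")
  emap_log("detect_regions: %d call(s)", nrow(out))
  out
}

#' Positional permutation null for region calls
#'
#' Permutes the gene-to-locus assignment, re-runs [detect_regions()] and
#' reports the distribution of call counts, so an observed call count can be
#' judged against positional chance.
#'
#' @param m An `interaction_matrix`.
#' @param loci A `gene_loci` table.
#' @param th An `emap_thresholds`.
#' @param permutations Number of permutations (default 200).
#' @param seed Seed for the permutations.
#' @param exclude_hyper Passed through to [detect_regions()].
#' @return A list with `mean`, `q95` and `counts` (per-permutation call
#'   counts).
#' @export
region_null_rate <- function(m, loci, th = emap_thresholds(),
                             permutations = 200L, seed = 1L,
                             exclude_hyper = character()) {
  if (permutations < 1L) stop("region_null_rate: permutations must be >= 1")
  set.seed(as.integer(seed))
  sub <- loci[match(m$genes, loci$gene_id), , drop = FALSE]
  counts <- integer(permutations)
  for (b in seq_len(permutations)) {
    perm <- sub
    perm$gene_id <- sample(perm$gene_id)
    class(perm) <- class(loci)
    counts[b] <- nrow(detect_regions(m, perm, th,
                                     exclude_hyper = exclude_hyper))
  }
  list(mean = mean(counts),
       q95 = stats::quantile(counts, 0.95, names = FALSE, type = 1L),
       counts = counts)
}

#' Genome-ordered heat map
#'
#' Writes the genome-ordered S matrix (and its flags sidecar) as TSV and
#' renders a PNG heat map on a blue-white-yellow diverging scale with
#' masked-linked cells in grey — in a screen masked at < 100 kb those grey
#' cells form one diagonal block per chromosome, each sized by the number of
#' screened genes on that chromosome — and chromosome boundaries drawn.
#'
#' @param m An `interaction_matrix` (reordered internally).
#' @param loci A `gene_loci` table.
#' @param path Output path for the PNG; the TSV is written alongside with
#'   extension `.tsv`.
#' @param s_sat |S| value at which the color scale saturates.
#' @return Invisibly, a named vector of the files written.
#' @export
genome_heatmap <- function(m, loci, path, s_sat = 6) {
  mo <- order_by_genome(m, loci)
  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  write_matrix(mo, tsv)
  n <- length(mo$genes)
  vals <- pmax(pmin(mo$S, s_sat), -s_sat)
  masked <- has_flag(mo, "MASKED_LINKED")
  vals[masked] <- NA_real_
  chrom <- loci$chromosome[match(mo$genes, loci$gene_id)]
  bounds <- which(diff(as.integer(factor(chrom, levels = unique(chrom)))) != 0)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#FFD92F"))(101)
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1, 1, 2, 1))
  z <- t(vals[n:1, , drop = FALSE])
  graphics::image(seq_len(n), seq_len(n), z, zlim = c(-s_sat, s_sat),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("genome-ordered S scores (%d genes)", n))
  na_cells <- which(is.na(z), arr.ind = TRUE)
  if (nrow(na_cells))
    graphics::points(na_cells[, 1], na_cells[, 2], pch = 15, cex = 0.4,
                     col = "grey60")
  for (b in bounds) {
    graphics::abline(v = b + 0.5, col = "grey30")
    graphics::abline(h = n - b + 0.5, col = "grey30")
  }
  invisible(c(png = path, tsv = tsv))
}
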