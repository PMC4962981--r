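#' Gene locus tables
#'
#' A locus table maps every screened gene to its chromosomal position and,
#' optionally, to a functional class and a subcellular location label.
#' Coordinates are 0-based half-open (BED convention); the representative
#' position of a gene for all distance computations is `start_bp`.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chromosome Character vector of chromosome labels.
#' @param start_bp,end_bp Integer coordinates, `0 <= start_bp < end_bp`.
#' @param functional_class Optional character vector (NA allowed).
#' @param location_label Optional character vector (NA allowed; multi-label
#'   entries are comma-separated).
#' @return A data frame of class `gene_loci`.
#' @export
gene_loci <- function(gene_id, chromosome, start_bp, end_bp,
                      functional_class = NA_character_,
                      location_label = NA_character_) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chromosome = as.character(chromosome),
                   start_bp = as.integer(start_bp),
                   end_bp = as.integer(end_bp),
                   functional_class = as.character(functional_class),
                   location_label = as.character(location_label),
                   stringsAsFactors = FALSE)
  validate_loci(df)
}

validate_loci <- function(df) {
  if (anyNA(df$gene_id) || any(df$gene_id == ""))
    stop("locus table: empty gene_id")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("locus table: duplicated gene_id(s): ",
         paste(unique(dup), collapse = ", "))
  if (anyNA(df$start_bp) || anyNA(df$end_bp))
    stop("locus table: non-integer coordinates")
  if (any(df$start_bp < 0L))
    stop("locus table: start_bp must be >= 0")
  bad <- which(df$end_bp <= df$start_bp)
  if (length(bad))
    stop("locus table: end_bp <= start_bp for gene(s): ",
         paste(df$gene_id[bad], collapse = ", "))
  class(df) <- c("gene_loci", "data.frame")
  df
}

#' Read a BED-like locus table
#'
#' Expects tab-separated columns `chromosome, start, end, gene_id` with
#' optional fifth (`functional_class`) and sixth (`location_label`) columns.
#' Lines starting with `#` (and an optional `chromosome`-led header line) are
#' skipped. Duplicate gene ids and inverted intervals are rejected.
#'
#' @param path Path to the file.
#' @return A `gene_loci` data frame.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("locus table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (any(keep)) {
    first <- which(keep)[1L]
    if (grepl("^chrom", lines[[first]], ignore.case = TRUE))
      keep[first] <- FALSE
  }
  rows <- vector("list", sum(keep))
  n <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stop(sprintf("locus table parse error at line %d: expected >= 4 tab-separated columns", i))
    st <- suppressWarnings(as.integer(f[[2]]))
    en <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(st) || is.na(en))
      stop(sprintf("locus table parse error at line %d: non-integer coordinates", i))
    n <- n + 1L
    rows[[n]] <- data.frame(
      gene_id = f[[4]], chromosome = f[[1]], start_bp = st, end_bp = en,
      functional_class = if (length(f) >= 5L && nzchar(f[[5]])) f[[5]] else NA_character_,
      location_label = if (length(f) >= 6L && nzchar(f[[6]])) f[[6]] else NA_character_,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[seq_len(n)])
  if (is.null(df)) stop("locus table is empty: ", path)
  out <- validate_loci(df)
  emap_log("read_locus_table: %d loci on %d chromosome(s) from %s",
           nrow(out), length(unique(out$chromosome)), path, level = "debug")
  out
}

#' Write a locus table in the BED-like format read by [read_locus_table()]
#'
#' @param loci A `gene_loci` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_locus_table <- function(loci, path) {
  stopifnot(inherits(loci, "gene_loci"))
  fmt <- function(x) ifelse(is.na(x), "", x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   loci$chromosome, loci$start_bp, loci$end_bp, loci$gene_id,
                   fmt(loci$functional_class), fmt(loci$location_label))
  writeLines(lines, path)
  invisible(path)
}
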