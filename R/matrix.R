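#' Interaction and correlation matrices
#'
#' An interaction matrix holds, for one screen condition, the symmetrized
#' S score of every gene pair together with its two-sided P value and a set of
#' status flags per cell (`MASKED_LINKED`, `NOISY_STRAIN`, `MISSING`,
#' `ONE_DIRECTION_ONLY`). The diagonal is always missing. A correlation matrix
#' has the same shape with Pearson profile correlations `r`, their P values
#' and the profile length `n_used` per pair.
#'
#' @param genes Ordered character vector of gene ids.
#' @param S Symmetric numeric matrix of S scores (NA allowed).
#' @param P Symmetric numeric matrix of two-sided P values (NA where S is NA).
#' @param flags Symmetric character matrix of `;`-separated flag sets
#'   (`""` = no flag). Defaults to no flags (with `MISSING` on NA cells).
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(genes, S, P = NULL, flags = NULL) {
  genes <- as.character(genes)
  n <- length(genes)
  stopifnot(is.matrix(S), nrow(S) == n, ncol(S) == n)
  dimnames(S) <- list(genes, genes)
  asym <- abs(S - t(S))
  if (any(asym > 1e-8, na.rm = TRUE))
    stop("interaction_matrix: S is not symmetric")
  diag(S) <- NA_real_
  if (is.null(P)) P <- matrix(NA_real_, n, n)
  dimnames(P) <- list(genes, genes)
  diag(P) <- NA_real_
  if (is.null(flags)) flags <- matrix("", n, n)
  dimnames(flags) <- list(genes, genes)
  flags[is.na(S)] <- flag_add(flags[is.na(S)], "MISSING")
  diag(flags) <- "MISSING"
  structure(list(genes = genes, S = S, P = P, flags = flags),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  sc <- sum(is.finite(x$S[upper.tri(x$S)]))
  cat(sprintf("interaction_matrix: %d genes, %d/%d pairs scored\n",
              length(x$genes), sc, choose(length(x$genes), 2)))
  invisible(x)
}

#' @rdname interaction_matrix
#' @param r Symmetric numeric matrix of Pearson correlations.
#' @param n_used Symmetric integer matrix of profile lengths.
#' @return `correlation_matrix()`: an object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(genes, r, P, n_used) {
  genes <- as.character(genes)
  n <- length(genes)
  stopifnot(is.matrix(r), nrow(r) == n, ncol(r) == n)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation_matrix: |r| > 1")
  dimnames(r) <- dimnames(P) <- dimnames(n_used) <- list(genes, genes)
  diag(r) <- NA_real_; diag(P) <- NA_real_; diag(n_used) <- NA_integer_
  structure(list(genes = genes, r = r, P = P, n_used = n_used),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d genes, %d/%d pairs with r\n",
              length(x$genes), sum(is.finite(x$r[upper.tri(x$r)])),
              choose(length(x$genes), 2)))
  invisible(x)
}

# --- flag helpers -----------------------------------------------------------

flag_add <- function(flags, flag) {
  has <- flag_has(flags, flag)
  out <- ifelse(flags == "", flag, paste(flags, flag, sep = ";"))
  out[has] <- flags[has]
  out
}

flag_has <- function(flags, flag) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Test cells of an interaction matrix for a status flag
#'
#' @param m An `interaction_matrix`.
#' @param flag Flag name, e.g. `"MASKED_LINKED"`.
#' @return Logical matrix of the same shape as `m$S`.
#' @export
has_flag <- function(m, flag) {
  out <- matrix(flag_has(m$flags, flag), nrow(m$flags), ncol(m$flags),
                dimnames = dimnames(m$flags))
  out
}

# S values usable for downstream analysis: finite and not excluded by QC/mask
usable_S <- function(m) {
  S <- m$S
  bad <- has_flag(m, "MASKED_LINKED") | has_flag(m, "NOISY_STRAIN")
  S[bad] <- NA_real_
  S
}

# --- I/O --------------------------------------------------------------------

#' Write a matrix as square TSV (with a flags sidecar)
#'
#' Writes gene ids as the first row and column and `NA` for missing values at
#' full double precision, so a write/read round trip is bit exact. For
#' interaction matrices a sidecar `<path basename>.flags.tsv` holds the flag
#' sets; for correlation matrices the `r` table is written.
#'
#' @param m An `interaction_matrix` or `correlation_matrix`.
#' @param path Output path for the value TSV.
#' @return Invisibly, the paths written (value file, and flags file if any).
#' @export
write_matrix <- function(m, path) {
  if (inherits(m, "interaction_matrix")) {
    vals <- m$S
  } else if (inherits(m, "correlation_matrix")) {
    vals <- m$r
  } else stop("write_matrix: unsupported object")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("gene_id", m$genes), collapse = "\t"), con)
  body <- format_full(vals)
  writeLines(paste(m$genes, apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  paths <- path
  if (inherits(m, "interaction_matrix")) {
    fpath <- paste0(tools::file_path_sans_ext(path), ".flags.tsv")
    fcon <- file(fpath, "w")
    on.exit(close(fcon), add = TRUE)
    writeLines(paste(c("gene_id", m$genes), collapse = "\t"), fcon)
    fl <- m$flags
    fl[fl == ""] <- "."
    writeLines(paste(m$genes, apply(fl, 1L, paste, collapse = "\t"),
                     sep = "\t"), fcon)
    paths <- c(paths, fpath)
  }
  invisible(paths)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path Path of the value TSV; a `.flags.tsv` sidecar is picked up
#'   automatically when present.
#' @return An `interaction_matrix` (without P values; recompute with
#'   [s_pvalues()] if needed).
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE, colClasses = "character")
  genes <- rownames(tab)
  if (!identical(colnames(tab), genes))
    stop("matrix file: row and column gene ids differ")
  S <- matrix(as.numeric(as.matrix(tab)), nrow(tab), ncol(tab),
              dimnames = list(genes, genes))
  fpath <- paste0(tools::file_path_sans_ext(path), ".flags.tsv")
  flags <- NULL
  if (file.exists(fpath)) {
    ftab <- utils::read.delim(fpath, header = TRUE, sep = "\t", row.names = 1L,
                              check.names = FALSE, colClasses = "character")
    flags <- as.matrix(ftab)
    flags[flags == "."] <- ""
    dimnames(flags) <- list(genes, genes)
  }
  interaction_matrix(genes, S, flags = flags)
}
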