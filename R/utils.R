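# Internal helpers shared across modules.

#' Canonical unordered pair keys
#'
#' Builds the canonical string key `"A|B"` (lexicographically sorted) used to
#' identify an unordered gene pair throughout the package.
#'
#' @param a,b Character vectors of gene ids (recycled to common length).
#' @return Character vector of keys.
#' @export
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- b < a
  key <- paste(a, b, sep = "|")
  key[swap] <- paste(b[swap], a[swap], sep = "|")
  key
}

#' Enumerate all unordered gene pairs
#'
#' @param genes Character vector of unique gene ids.
#' @return Data frame with columns `gene_a`, `gene_b`, `pair` (canonical key);
#'   one row per unordered pair, `choose(n, 2)` rows in total.
#' @export
all_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene ids must be unique")
  n <- length(genes)
  if (n < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      pair = character(), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  a <- genes[idx[1L, ]]
  b <- genes[idx[2L, ]]
  data.frame(gene_a = a, gene_b = b, pair = pair_key(a, b),
             stringsAsFactors = FALSE)
}

# Scaled MAD (consistent with sd under normality); returns 0 for all-equal x.
robust_spread <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::mad(x, constant = 1.4826)
}

# format a numeric matrix at full double precision for bit-exact round trips
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  dim(out) <- dim(x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
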