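#' Replicate colony-size grids
#'
#' A cross grid holds the replicate colony sizes of all `[query x array]`
#' crosses of one screen condition as a 3-way array
#' `[query, array, replicate]`, together with the plate each cross was grown
#' on. Missing crosses are `NA`; sizes are non-negative.
#'
#' @param condition Condition tag, `"control"` or `"drug"`.
#' @param sizes Numeric 3-way array `[query, array, replicate]` with dimnames
#'   on the first two margins giving the gene ids.
#' @param plate_of Character matrix `[query, array]` of plate identifiers.
#' @param loci Optional `gene_loci` table; when given, every query and array
#'   gene id must resolve against it (fail-fast, no silent drops).
#' @return An object of class `cross_grid`.
#' @export
cross_grid <- function(condition, sizes, plate_of, loci = NULL) {
  condition <- match.arg(condition, c("control", "drug"))
  stopifnot(is.array(sizes), length(dim(sizes)) == 3L)
  queries <- dimnames(sizes)[[1]]
  arrays <- dimnames(sizes)[[2]]
  if (is.null(queries) || is.null(arrays))
    stop("cross_grid: 'sizes' needs gene ids as dimnames on margins 1 and 2")
  if (any(sizes < 0, na.rm = TRUE))
    stop("cross_grid: negative colony sizes")
  stopifnot(is.matrix(plate_of),
            nrow(plate_of) == length(queries),
            ncol(plate_of) == length(arrays))
  dimnames(plate_of) <- list(queries, arrays)
  if (!is.null(loci)) {
    unknown <- setdiff(union(queries, arrays), loci$gene_id)
    if (length(unknown))
      stop("cross_grid: gene id(s) absent from locus table: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(condition = condition, queries = queries, arrays = arrays,
                 sizes = sizes, plate_of = plate_of),
            class = "cross_grid")
}

#' @export
print.cross_grid <- function(x, ...) {
  cat(sprintf("cross_grid [%s]: %d queries x %d arrays x %d replicates (%d plates, %.1f%% missing)\n",
              x$condition, length(x$queries), length(x$arrays),
              dim(x$sizes)[3], length(unique(as.vector(x$plate_of))),
              100 * mean(is.na(x$sizes))))
  invisible(x)
}

#' Read a long-format colony-size table
#'
#' Expects a tab-separated file with header
#' `query_id  array_id  replicate  size  plate_id`, one measurement per row.
#' Crosses absent from the file are marked missing. Negative sizes and
#' replicate indices outside `1..replicates` are rejected.
#'
#' @param path Path to the file.
#' @param condition Condition tag for the grid.
#' @param replicates Declared replicate count per cross (default 4,
#'   quadruplicate crosses).
#' @param loci Optional `gene_loci` table for id validation.
#' @return A `cross_grid`.
#' @export
read_cross_grid <- function(path, condition, replicates = 4L, loci = NULL) {
  if (!file.exists(path)) stop("colony table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "numeric", "character"))
  need <- c("query_id", "array_id", "replicate", "size", "plate_id")
  if (!all(need %in% names(df)))
    stop("colony table must have columns: ", paste(need, collapse = ", "))
  if (any(df$size < 0, na.rm = TRUE))
    stop("colony table: negative size value(s)")
  if (any(is.na(df$replicate)) ||
      any(df$replicate < 1L | df$replicate > replicates))
    stop("colony table: replicate index outside 1..", replicates)
  queries <- sort(unique(df$query_id))
  arrays <- sort(unique(df$array_id))
  sizes <- array(NA_real_,
                 dim = c(length(queries), length(arrays), replicates),
                 dimnames = list(queries, arrays, NULL))
  qi <- match(df$query_id, queries)
  ai <- match(df$array_id, arrays)
  sizes[cbind(qi, ai, df$replicate)] <- df$size
  plate_of <- matrix(NA_character_, length(queries), length(arrays),
                     dimnames = list(queries, arrays))
  plate_of[cbind(qi, ai)] <- df$plate_id
  g <- cross_grid(condition, sizes, plate_of, loci = loci)
  emap_log("read_cross_grid[%s]: %d x %d grid, %d measurements from %s",
           condition, length(queries), length(arrays), nrow(df), path,
           level = "debug")
  g
}

#' Write a cross grid in the long format read by [read_cross_grid()]
#'
#' @param grid A `cross_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cross_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cross_grid"))
  d <- dim(grid$sizes)
  idx <- which(!is.na(grid$sizes), arr.ind = TRUE)
  df <- data.frame(query_id = grid$queries[idx[, 1]],
                   array_id = grid$arrays[idx[, 2]],
                   replicate = idx[, 3],
                   size = sprintf("%.17g", grid$sizes[idx]),
                   plate_id = grid$plate_of[idx[, 1:2, drop = FALSE]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$query_id, df$array_id, df$replicate), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
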