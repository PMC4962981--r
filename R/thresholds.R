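#' Analysis thresholds
#'
#' Bundles every tunable cutoff of the pipeline with its default. Defaults
#' follow the screen conventions used throughout the package: unadjusted
#' P <= 0.005 for S-score significance and P <= 0.05 for profile-correlation
#' significance, a Bonferroni family alpha of 0.05, a high-correlation cutoff
#' of r > 0.5 (strict), a curve knee reference at r = 0.4, windows of 10 pairs
#' for the correlation curves, 100 kb linkage masking (strict `<`), and region
#' calls requiring runs of at least 5 consecutive genes with S < -3.
#'
#' @param p_s Unadjusted P cutoff for S-score significance.
#' @param p_corr Unadjusted P cutoff for correlation significance.
#' @param bonferroni_alpha Family-wise alpha for the Bonferroni reference line.
#' @param corr_high High-correlation cutoff (strict `>`).
#' @param corr_knee Correlation value where the S-vs-correlation curves turn.
#' @param window Number of pairs per window in the curve summaries.
#' @param linkage_bp Linkage masking distance in base pairs (strict `<`).
#' @param region_s_cut S-score cutoff (negative) for region membership.
#' @param region_min_run Minimum run length for a region call.
#' @return An object of class `emap_thresholds` (a validated named list).
#' @export
emap_thresholds <- function(p_s = 0.005, p_corr = 0.05,
                            bonferroni_alpha = 0.05,
                            corr_high = 0.5, corr_knee = 0.4,
                            window = 10L, linkage_bp = 100000L,
                            region_s_cut = -3, region_min_run = 5L) {
  th <- list(p_s = as.numeric(p_s), p_corr = as.numeric(p_corr),
             bonferroni_alpha = as.numeric(bonferroni_alpha),
             corr_high = as.numeric(corr_high),
             corr_knee = as.numeric(corr_knee),
             window = as.integer(window),
             linkage_bp = as.integer(linkage_bp),
             region_s_cut = as.numeric(region_s_cut),
             region_min_run = as.integer(region_min_run))
  for (f in c("p_s", "p_corr", "bonferroni_alpha")) {
    v <- th[[f]]
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop(sprintf("'%s' must lie strictly between 0 and 1", f))
  }
  if (th$window < 2L) stop("'window' must be >= 2")
  if (th$linkage_bp <= 0L) stop("'linkage_bp' must be positive")
  if (!is.finite(th$region_s_cut) || th$region_s_cut >= 0)
    stop("'region_s_cut' must be negative")
  if (th$region_min_run < 2L) stop("'region_min_run' must be >= 2")
  class(th) <- "emap_thresholds"
  th
}

#' @export
print.emap_thresholds <- function(x, ...) {
  cat("E-MAP analysis thresholds:\n")
  for (f in names(x)) cat(sprintf("  %-17s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read a flat key/value configuration file
#'
#' Parses a minimal TOML-style configuration: one `key = value` assignment per
#' line, `#` comments, quoted strings, numbers and `true`/`false` booleans.
#' `[section]` headers are accepted and ignored (keys must be unique across the
#' whole file). Keys matching [emap_thresholds()] fields override the defaults;
#' all other keys are returned untouched so simulation settings can share the
#' same file.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `thresholds` (an `emap_thresholds` object) and
#'   `extra` (named list of remaining keys).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vals <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "" || grepl("^\\[.*\\]$", line)) next
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3L)
      stop(sprintf("config parse error at line %d: '%s'", i, lines[[i]]))
    key <- m[[2]]
    raw <- trimws(m[[3]])
    if (key %in% names(vals))
      stop(sprintf("duplicate config key '%s' at line %d", key, i))
    vals[[key]] <- parse_config_value(raw, i)
  }
  th_fields <- names(formals(emap_thresholds))
  th_args <- vals[intersect(names(vals), th_fields)]
  th <- do.call(emap_thresholds, th_args)
  list(thresholds = th, extra = vals[setdiff(names(vals), th_fields)])
}

parse_config_value <- function(raw, lineno) {
  if (grepl('^".*"$', raw) || grepl("^'.*'$", raw))
    return(substr(raw, 2L, nchar(raw) - 1L))
  if (raw %in% c("true", "false")) return(raw == "true")
  num <- suppressWarnings(as.numeric(raw))
  if (!is.na(num)) return(num)
  stop(sprintf("config parse error at line %d: cannot interpret '%s'",
               lineno, raw))
}
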