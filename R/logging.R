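# Minimal leveled logging to standard error.
#
# Every pipeline stage reports its in/out counts through emap_log() so a run
# leaves an auditable trail (strains removed, pairs masked, calls made).
# Verbosity is controlled with options(emapkit.verbose = ...): "quiet",
# "info" (default) or "debug".

.log_levels <- c(quiet = 0L, info = 1L, debug = 2L)

#' Log a message to standard error
#'
#' @param ... Passed to [sprintf()] (first argument is the format string).
#' @param level `"info"` or `"debug"`.
#' @return Invisibly, the formatted message.
#' @export
emap_log <- function(..., level = "info") {
  opt <- getOption("emapkit.verbose", "info")
  want <- .log_levels[[match.arg(opt, names(.log_levels))]]
  lev <- .log_levels[[match.arg(level, c("info", "debug"))]]
  msg <- sprintf(...)
  if (lev <= want && want > 0L) {
    message(sprintf("[%s] %s %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    toupper(level), msg))
  }
  invisible(msg)
}
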