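# Session logging and small shared helpers.

.fragmentREnv <- new.env(parent = emptyenv())

#' Session log file
#'
#' One timestamped plain-text log file is written per session; messages at
#' INFO level and above are appended. The default location is under
#' \code{tempdir()}.
#'
#' @param path set the log file path; with no argument, returns the
#'   current path (creating the default lazily).
#' @return The log file path, invisibly when setting.
#' @export
fragmentLogFile <- function(path) {
  if (!missing(path)) {
    .fragmentREnv$logfile <- path
    return(invisible(path))
  }
  if (is.null(.fragmentREnv$logfile)) {
    .fragmentREnv$logfile <- file.path(
      tempdir(), format(Sys.time(), "fragmentR_%Y%m%d_%H%M%S.log"))
  }
  .fragmentREnv$logfile
}

logMsg <- function(level, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...))
  try(cat(line, "\n", sep = "", file = fragmentLogFile(), append = TRUE),
      silent = TRUE)
  invisible(line)
}

logInfo <- function(...) logMsg("INFO", ...)
logWarn <- function(...) logMsg("WARN", ...)

formatSettingValue <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  as.character(v)
}

# Run a function with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, fun) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}
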