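# Orchestration: single-algorithm runs and pipelines over molecule sets
# with deterministic contiguous-chunk parallelism, aggregation of
# per-molecule fragment lists into frequency records, settings
# persistence, and histogram data extraction.

.processOne <- function(frag, mol) {
  sf <- shouldFilter(frag, mol)
  if (isTRUE(sf$filter)) {
    return(list(status = "FILTERED", reason = sf$reason, fragments = NULL))
  }
  pp <- preprocessMolecule(frag, mol)
  if (!isTRUE(pp$ok)) {
    return(list(status = "FILTERED", reason = pp$reason, fragments = NULL))
  }
  res <- tryCatch(
    list(status = if (isTRUE(pp$changed)) "PREPROCESSED" else "OK",
         reason = pp$reason,
         fragments = fragmentMolecule(frag, pp$mol)),
    error = function(e) list(status = "FAILED",
                             reason = conditionMessage(e), fragments = NULL))
  res
}

# one molecule through an ordered list of fragmenter stages; fragments a
# later stage filters (or cannot process) pass through unchanged
.processPipelineOne <- function(frags, mol) {
  first <- .processOne(frags[[1]], mol)
  if (is.null(first$fragments)) return(first)
  units <- first$fragments
  if (length(frags) > 1L) {
    for (stage in frags[-1]) {
      nxt <- character(0)
      for (u in units) {
        m <- tryCatch(parseSmiles(u), error = function(e) NULL)
        if (is.null(m)) {
          logInfo("pipeline: fragment '", u, "' not parseable by next stage; passed through")
          nxt <- c(nxt, u)
          next
        }
        r <- .processOne(stage, m)
        if (is.null(r$fragments)) {
          logInfo("pipeline: fragment '", u, "' ", tolower(r$status),
                  " by stage '", fragmenterId(stage), "'; passed through")
          nxt <- c(nxt, u)
        } else {
          nxt <- c(nxt, r$fragments)
        }
      }
      units <- nxt
    }
  }
  list(status = first$status, reason = first$reason, fragments = units)
}

# contiguous chunking: output independent of thread count
.chunkIndices <- function(n, nThreads) {
  k <- max(1L, min(nThreads, n))
  sizes <- diff(round(seq(0, n, length.out = k + 1L)))
  split(seq_len(n), rep(seq_len(k), sizes))
}

.runEngine <- function(mols, worker, nThreads) {
  n <- length(mols@molecules)
  if (n == 0L) stop("no input molecules", call. = FALSE)
  chunks <- .chunkIndices(n, nThreads)
  doChunk <- function(idx) lapply(idx, function(i) worker(mols@molecules[[i]]))
  results <- if (length(chunks) > 1L) {
    parallel::mclapply(chunks, doChunk, mc.cores = length(chunks))
  } else {
    lapply(chunks, doChunk)
  }
  unlist(results, recursive = FALSE, use.names = FALSE)
}

.collectRun <- function(mols, results, stages, snapshot, runName, seed) {
  r <- mols@records
  status <- data.frame(
    record_id = r$record_id, name = r$name,
    canonical_smiles = r$canonical_smiles,
    status = vapply(results, `[[`, "", "status"),
    reason = vapply(results, function(x)
      if (is.null(x$reason)) NA_character_ else as.character(x$reason)[1],
      character(1)),
    stringsAsFactors = FALSE)
  items <- list()
  for (i in seq_along(results)) {
    fr <- results[[i]]$fragments
    if (is.null(fr) || length(fr) == 0L) next
    tab <- table(fr)
    items[[length(items) + 1L]] <- data.frame(
      record_id = r$record_id[i],
      fragment_smiles = names(tab),
      count = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  items <- if (length(items) > 0L) do.call(rbind, items)
           else data.frame(record_id = integer(0),
                           fragment_smiles = character(0),
                           count = integer(0), stringsAsFactors = FALSE)
  rownames(items) <- NULL
  frags <- aggregateFragments(items, status, seed)
  if (nrow(frags) == 0L)
    warning("run '", runName, "' produced no fragments", call. = FALSE)
  new("FragmentationRun", runName = runName, stages = stages,
      settingsSnapshot = snapshot, status = status, items = items,
      fragments = frags, seed = as.integer(seed))
}

#' Aggregate per-molecule fragment lists into fragment records
#'
#' Groups by canonical SMILES; \code{frequency} is the total occurrence
#' count over all molecules, \code{molecule_frequency} the number of
#' distinct molecules containing the fragment. The sample parent is drawn
#' from the containing molecules by a seeded generator. Sorted by
#' descending frequency, ties by canonical SMILES ascending.
#'
#' @param items data.frame with \code{record_id}, \code{fragment_smiles},
#'   \code{count}.
#' @param status per-molecule status table (for parent names).
#' @param seed integer seed for sample-parent selection.
#' @return the aggregated fragment data.frame.
#' @export
aggregateFragments <- function(items, status, seed = 0L) {
  if (nrow(items) == 0L) {
    return(data.frame(fragment_smiles = character(0), frequency = integer(0),
                      molecule_frequency = integer(0),
                      sample_parent_id = integer(0),
                      sample_parent_name = character(0),
                      stringsAsFactors = FALSE))
  }
  freq <- tapply(items$count, items$fragment_smiles, sum)
  mfreq <- tapply(items$record_id, items$fragment_smiles,
                  function(x) length(unique(x)))
  keys <- sort(names(freq))
  df <- data.frame(fragment_smiles = keys,
                   frequency = as.integer(freq[keys]),
                   molecule_frequency = as.integer(mfreq[keys]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$fragment_smiles), , drop = FALSE]
  rownames(df) <- NULL
  parents <- withSeed(seed, function() {
    vapply(df$fragment_smiles, function(k) {
      ids <- sort(unique(items$record_id[items$fragment_smiles == k]))
      if (length(ids) == 1L) ids else sample(ids, 1L)
    }, integer(1), USE.NAMES = FALSE)
  })
  df$sample_parent_id <- parents
  df$sample_parent_name <- status$name[match(parents, status$record_id)]
  df
}

#' Run a single fragmentation algorithm over a molecule set
#'
#' Molecules are partitioned into contiguous chunks, processed
#' independently and recombined in input order, so results are identical
#' for any thread count. Per-molecule failures are isolated (status
#' \code{FAILED}, logged); a run in which every molecule is filtered
#' completes with an empty fragment list and a warning.
#'
#' @param mols a \linkS4class{MoleculeSet}.
#' @param fragmenter a \linkS4class{Fragmenter} (or a registry id string).
#' @param nThreads number of worker threads (>= 1).
#' @param seed integer seed for sample-parent selection.
#' @param runName run label, unique per session.
#' @return A \linkS4class{FragmentationRun}.
#' @examples
#' \dontrun{
#' set <- readSmilesFile("molecules.smi")
#' run <- runSingle(set, "ertl-fg")
#' fragmentRecords(run)
#' }
#' @export
runSingle <- function(mols, fragmenter, nThreads = 1L, seed = 0L,
                      runName = NULL) {
  if (is.character(fragmenter)) fragmenter <- makeFragmenter(fragmenter)
  stopifnot(nThreads >= 1L)
  if (is.null(runName)) runName <- fragmenterId(fragmenter)
  logInfo("runSingle: '", runName, "' on ", length(mols@molecules),
          " molecules, ", nThreads, " thread(s)")
  results <- .runEngine(mols, function(m) .processOne(fragmenter, m), nThreads)
  stages <- list(list(id = fragmenterId(fragmenter),
                      settings = fragmenter@settings))
  snapshot <- stats::setNames(list(fragmenter@settings), fragmenterId(fragmenter))
  .collectRun(mols, results, stages, snapshot, runName, seed)
}

#' Run a fragmentation pipeline over a molecule set
#'
#' Stage 1 consumes the input molecules; each later stage consumes every
#' fragment emitted by the previous stage. Fragments a stage filters (or
#' cannot parse) pass through unchanged with a logged note. Final
#' fragments are aggregated against the ORIGINAL input molecules:
#' \code{molecule_frequency} counts distinct imported molecules.
#'
#' @param mols a \linkS4class{MoleculeSet}.
#' @param pipeline a list of stages, each \code{list(id =, settings =)},
#'   or a character vector of fragmenter ids.
#' @inheritParams runSingle
#' @return A \linkS4class{FragmentationRun}.
#' @export
runPipeline <- function(mols, pipeline, nThreads = 1L, seed = 0L,
                        runName = "pipeline") {
  if (is.character(pipeline))
    pipeline <- lapply(pipeline, function(id) list(id = id, settings = list()))
  stopifnot(length(pipeline) >= 1L)
  frags <- lapply(pipeline, function(st) {
    makeFragmenter(st$id, if (is.null(st$settings)) list() else st$settings)
  })
  logInfo("runPipeline: '", runName, "' with ", length(frags), " stage(s) on ",
          length(mols@molecules), " molecules")
  results <- .runEngine(mols, function(m) .processPipelineOne(frags, m),
                        nThreads)
  stages <- lapply(frags, function(f)
    list(id = fragmenterId(f), settings = f@settings))
  snapshot <- stats::setNames(lapply(frags, function(f) f@settings),
                              vapply(frags, fragmenterId, character(1)))
  .collectRun(mols, results, stages, snapshot, runName, seed)
}

#' Persist fragmenter settings to a line-based text file
#'
#' Writes \code{key=value} lines (booleans as \code{true}/\code{false});
#' \code{#} lines are comments. \code{loadSettings} reads such a file
#' back, validating each value against the fragmenter's descriptors:
#' invalid values and unknown keys warn and are ignored, so a partial or
#' damaged file degrades to defaults.
#'
#' @param fragmenter a \linkS4class{Fragmenter}.
#' @param path settings file path (default \code{<id>.settings}).
#' @return \code{persistSettings}: the path, invisibly.
#' @export
persistSettings <- function(fragmenter, path = NULL) {
  if (is.null(path)) path <- paste0(fragmenterId(fragmenter), ".settings")
  s <- fragmenter@settings
  lines <- c(paste0("# ", fragmenterId(fragmenter), " settings"),
             vapply(names(s), function(k)
               paste0(k, "=", formatSettingValue(s[[k]])), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname persistSettings
#' @return \code{loadSettings}: the fragmenter with settings replaced by
#'   the validated file contents.
#' @export
loadSettings <- function(fragmenter, path) {
  if (!file.exists(path)) {
    warning("settings file not found: ", path, "; keeping defaults",
            call. = FALSE)
    return(fragmenter)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L) {
      warning("malformed settings line ignored: '", ln, "'", call. = FALSE)
      next
    }
    overrides[[trimws(substr(ln, 1, eq - 1L))]] <-
      trimws(substr(ln, eq + 1L, nchar(ln)))
  }
  fragmenter@settings <- applySettings(settingDescriptors(fragmenter),
                                       fragmenter@settings, overrides,
                                       strict = FALSE)
  fragmenter
}

#' Histogram data for the most frequent fragments
#'
#' @param run a \linkS4class{FragmentationRun} with fragments.
#' @param topN number of fragments to return (>= 1); values above the
#'   number of fragments return all of them.
#' @param by count to rank by: total \code{"frequency"} or
#'   \code{"molecule_frequency"}.
#' @return data.frame with \code{fragment_smiles} and \code{count},
#'   sorted descending by the chosen measure.
#' @export
histogramData <- function(run, topN = 10L,
                          by = c("frequency", "molecule_frequency")) {
  by <- match.arg(by)
  stopifnot(topN >= 1L)
  f <- fragmentRecords(run)
  if (nrow(f) == 0L) stop("run has no fragments", call. = FALSE)
  ord <- order(-f[[by]], f$fragment_smiles)
  f <- f[ord, , drop = FALSE]
  n <- min(topN, nrow(f))
  data.frame(fragment_smiles = f$fragment_smiles[seq_len(n)],
             count = f[[by]][seq_len(n)],
             stringsAsFactors = FALSE)
}
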