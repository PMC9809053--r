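# The plugin contract: typed settings with validation, the fragmenter
# registry, and default filter/preprocess behaviour shared by all
# algorithms.

#' Construct a SettingDescriptor
#'
#' @param key setting name (unique within one fragmenter).
#' @param valueType one of BOOLEAN, INTEGER, FLOAT, STRING, ENUM.
#' @param default default value of that type.
#' @param allowed allowed values (ENUM only).
#' @param description one-line help text.
#' @return A \linkS4class{SettingDescriptor}.
#' @export
settingDescriptor <- function(key, valueType, default, allowed = list(),
                              description = "") {
  new("SettingDescriptor", key = key, valueType = valueType,
      default = default, allowed = as.list(allowed),
      description = description)
}

# Parse/validate one value against a descriptor. Accepts native values
# and their string forms (settings files, --set flags). Returns the
# coerced value or signals via the `invalid` handler.
coerceSetting <- function(desc, value) {
  vt <- desc@valueType
  bad <- function() stop("invalid value for setting '", desc@key, "': ",
                         paste(value, collapse = " "), call. = FALSE)
  if (vt == "BOOLEAN") {
    if (is.logical(value) && length(value) == 1L && !is.na(value)) return(value)
    if (is.character(value) && tolower(value) %in% c("true", "false"))
      return(tolower(value) == "true")
    bad()
  } else if (vt == "INTEGER") {
    v <- suppressWarnings(as.numeric(value))
    if (length(v) == 1L && !is.na(v) && v == round(v)) return(as.integer(v))
    bad()
  } else if (vt == "FLOAT") {
    v <- suppressWarnings(as.numeric(value))
    if (length(v) == 1L && !is.na(v)) return(v)
    bad()
  } else if (vt == "STRING") {
    if (is.character(value) && length(value) == 1L) return(value)
    bad()
  } else if (vt == "ENUM") {
    if (is.character(value) && length(value) == 1L &&
        value %in% unlist(desc@allowed)) return(value)
    bad()
  }
  bad()
}

# Merge overrides into current settings. strict: unknown key or invalid
# value is an error (construction, --set). lenient: warn and keep the
# current value (settings-file loading).
applySettings <- function(descriptors, current, overrides, strict = TRUE) {
  out <- current
  for (k in names(overrides)) {
    d <- descriptors[[k]]
    if (is.null(d)) {
      if (strict) stop("unknown setting key: '", k, "'", call. = FALSE)
      warning("ignoring unknown setting key: '", k, "'", call. = FALSE)
      logWarn("settings: unknown key '", k, "' ignored")
      next
    }
    v <- tryCatch(coerceSetting(d, overrides[[k]]), error = function(e) e)
    if (inherits(v, "error")) {
      if (strict) stop(conditionMessage(v), call. = FALSE)
      warning(conditionMessage(v), "; keeping current value", call. = FALSE)
      logWarn("settings: ", conditionMessage(v), "; keeping current value")
      next
    }
    out[[k]] <- v
  }
  out
}

defaultSettings <- function(descriptors) {
  lapply(descriptors, function(d) d@default)
}

#' Registered fragmentation algorithms
#'
#' @return character vector of registry identifiers.
#' @export
registeredFragmenters <- function() c("ertl-fg", "sugar-removal", "scaffold")

#' Construct a fragmenter by identifier
#'
#' Creates a fragmentation algorithm instance with default settings,
#' optionally overridden. Overrides are validated against the
#' algorithm's \linkS4class{SettingDescriptor}s; unknown keys or
#' type-invalid values are an error.
#'
#' @param id one of \code{registeredFragmenters()}.
#' @param settings named list (or named character vector) of overrides.
#' @return A \linkS4class{Fragmenter} subclass instance.
#' @examples
#' \dontrun{
#' makeFragmenter("ertl-fg", list(environment_mode = "full"))
#' }
#' @export
makeFragmenter <- function(id, settings = list()) {
  cls <- switch(id,
    "ertl-fg" = "ErtlFragmenter",
    "sugar-removal" = "SugarRemovalFragmenter",
    "scaffold" = "ScaffoldFragmenter",
    stop("unknown fragmenter id: '", id, "'; registered: ",
         paste(registeredFragmenters(), collapse = ", "), call. = FALSE))
  f <- new(cls, settings = list())
  f@settings <- defaultSettings(settingDescriptors(f))
  if (length(settings) > 0L) {
    f@settings <- applySettings(settingDescriptors(f), f@settings,
                                as.list(settings), strict = TRUE)
  }
  f
}

# ---- default contract behaviour ----

#' @rdname shouldFilter
#' @export
setMethod("shouldFilter", "Fragmenter", function(x, mol) {
  list(filter = FALSE, reason = NA_character_)
})

#' @rdname preprocessMolecule
#' @export
setMethod("preprocessMolecule", "Fragmenter", function(x, mol) {
  list(mol = mol, ok = TRUE, changed = FALSE, reason = NA_character_)
})
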