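# Internal helpers shared across modules.

# log(1 + exp(x)) without overflow for large x.
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 30
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Coerce an engraftment status column to 0/1 (1 = engrafter).
as_binary_status <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) abort("Numeric status must contain only 0 and 1.")
    return(as.integer(x))
  }
  if (is.character(x) || is.factor(x)) {
    x <- tolower(as.character(x))
    ok <- x %in% c("engrafter", "nonengrafter", "e", "ne")
    if (!all(ok)) {
      abort("Character status must be 'engrafter'/'nonengrafter' (or 'E'/'NE').")
    }
    return(as.integer(x %in% c("engrafter", "e")))
  }
  abort("Unsupported status encoding.")
}
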