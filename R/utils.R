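# Internal helpers shared across modules.

# Abort unless `x` is a data frame containing all of `cols`.
check_columns <- function(x, cols, what = "input") {
  if (!is.data.frame(x)) {
    abort(paste0(what, " must be a data frame"))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Numeric (non-metadata) columns of a counts-style table.
sample_columns <- function(x, meta_cols) {
  setdiff(names(x), meta_cols)
}

# Evaluate `expr` under `seed` when non-NULL, without touching the
# caller's RNG state; otherwise evaluate as-is.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), force(expr))
  }
}

# Derive a per-stage seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

# Strand/orientation helpers. Orientations are axis-relative: "forward"
# points toward increasing coordinates.
flip_orientation <- function(orientation) {
  out <- ifelse(orientation == "forward", "reverse",
    ifelse(orientation == "reverse", "forward", NA_character_)
  )
  if (anyNA(out)) {
    abort("orientation must be 'forward' or 'reverse'")
  }
  out
}
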