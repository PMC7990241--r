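# internal helpers shared across modules

MISSING_TOKENS <- c("", "na", "nan")

#' @noRd
is_missing_token <- function(x) {
  tolower(trimws(x)) %in% MISSING_TOKENS
}

# Parse measurement text: missing tokens -> NA; anything else must be numeric.
# Returns list(values = numeric, bad = logical flag per cell for non-numeric text).
#' @noRd
parse_measurement_text <- function(x) {
  miss <- is_missing_token(x)
  val <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(val)
  val[miss] <- NA_real_
  list(values = val, bad = bad)
}

#' @noRd
abort_mp <- function(msg, class = "metabopipe_error") {
  rlang::abort(msg, class = c(class, "metabopipe_error"))
}

#' @noRd
as_measurement_matrix <- function(measurements) {
  m <- as.matrix(as.data.frame(measurements))
  if (!is.numeric(m)) {
    abort_mp("measurement table contains non-numeric columns")
  }
  m
}

# Derive a reproducible 32-bit sub-seed from a base seed and an index so that
# per-column / per-stage draws are independent of how many other draws happen.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483587) + 1L
}

#' @noRd
with_seed_mp <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
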