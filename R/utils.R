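# Internal helpers: validation, seeded evaluation, stable id hashing.

stopf <- function(fmt, ..., class = "neoresponse_error") {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, len = NULL) {
  if (!is.numeric(x)) stopf("`%s` must be numeric", name)
  if (!is.null(len) && length(x) != len) {
    stopf("`%s` must have length %d", name, len)
  }
  bad <- !is.na(x) & (x < lower | x > upper)
  if (any(bad)) {
    stopf("`%s` must lie in [%s, %s] (got %s)", name,
          format(lower), format(upper), format(x[which(bad)[1]]))
  }
  if (!allow_na && anyNA(x)) stopf("`%s` must not contain NA", name)
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generator internals never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  code
}

# 32-bit FNV-1a hash of a string, folded into [0, 2^31 - 1].
# Used to derive stable per-patient RNG substreams from the cohort seed, so
# that any subset of patients is reproducible independently of cohort order.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

derive_seed <- function(base_seed, key) {
  as.integer((as.numeric(base_seed) + stable_hash(as.character(key))) %% (2^31 - 1))
}

# FNV-1a hash of arbitrary text, reported as 8 hex digits (config fingerprint
# in pipeline reports).
text_fingerprint <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(paste(txt, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
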