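# Internal helpers: seed streams, hashing, rounding conventions.

# Derive a reproducible child seed for a named pipeline stage.  All
# randomness in the package flows from one top-level seed through this
# function, so runs are reproducible stage by stage.  Result stays inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- fnv1a32(paste0("kmsacost:", stage, ":", format(seed, scientific = FALSE)))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a hash of a character string, returned as a double in
# [0, 2^32).  Used for config fingerprints in manifests; avoids a
# dependency on a dedicated digest package.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - 2147483648 * (h >= 2147483648)), b)
    if (h < 0) h <- h + 4294967296
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# Round half away from zero (printed-percentage convention); R's round()
# is round-half-even which would turn 52.5 into 52.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Age in completed years at a reference date
#'
#' The exact-matching age key: completed years between birth and the
#' index/reference date.
#'
#' @param birth,at `Date` vectors.
#' @return integer years.
#' @export
completed_years <- function(birth, at) {
  as.integer(floor(as.numeric(at - birth) / 365.25))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s: probabilities must lie in [0, 1]", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s: probabilities must sum to 1 (got %.12f)", what, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}
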