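# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 32-bit FNV-1a hash of a character string
#'
#' Used for stable, reference-free SNP names and config fingerprints.
#' Implemented with split-limb arithmetic so every step is exact in doubles
#' (R has no native unsigned 32-bit integers).
#'
#' @param x a single character string.
#' @return a double in `[0, 2^32)`.
#' @keywords internal
#' @noRd
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte: b < 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * 16777619 mod 2^32, exact via 16-bit limbs
    hl <- h %% 65536
    hh <- (h - hl) / 65536
    h <- (hl * 16777619 + ((hh * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Counter/name-based derivation: adding a stage never perturbs the seeds of
#' other stages, and grids parallelize reproducibly.
#'
#' @param seed master seed (integer-valued scalar).
#' @param key character label (stage name, repetition counter, ...).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- fnv1a32(paste0(format(seed, scientific = FALSE), "/", key))
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Discretize continuous genotype estimates to the closer value in {0,1,2}
#'
#' Ties (exactly 0.5 or 1.5) round toward the heterozygote class 1, which
#' absorbs three of the five tetraploid dosage classes and is therefore the
#' maximum-prior call.
#'
#' @param x numeric vector or matrix of genotype estimates.
#' @return the input with non-missing values replaced by 0, 1 or 2.
#' @export
discretize_geno <- function(x) {
  out <- x
  v <- !is.na(x)
  out[v] <- ifelse(x[v] < 0.5, 0, ifelse(x[v] <= 1.5, 1, 2))
  out
}

# Resolve a rate/depth law argument: scalar, vector or function(k).
resolve_law <- function(law, k, what = "rate") {
  if (is.function(law)) {
    out <- law(k)
  } else if (is.numeric(law)) {
    out <- rep_len(law, k)
  } else {
    stop(what, " law must be numeric or a function(k)")
  }
  if (length(out) != k) stop(what, " law returned wrong length")
  out
}

# Sample from an inverse-Gaussian(mu, lambda) distribution
# (Michael-Schucany-Haas transformation); used by the Bayesian Lasso.
rinvgauss1 <- function(mu, lambda) {
  nu <- stats::rnorm(1L)
  z <- nu * nu
  x <- mu + mu * mu * z / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * z + mu * mu * z * z)
  if (x <= 0) x <- .Machine$double.eps
  if (stats::runif(1L) <= mu / (mu + x)) x else mu * mu / x
}
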