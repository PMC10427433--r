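#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic operations in the package draw their randomness from one
#' integer master seed through this counter-based splitting scheme, so each
#' module can be regenerated independently of the order in which modules run.
#'
#' @param seed Master integer seed.
#' @param index Non-negative integer stream counter (one per consumer).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # affine hop in 31-bit space; constants are odd primes so distinct indices
  # cannot collide for small seeds
  as.integer((abs(seed) * 48271 + index * 16807 + 12345) %% 2147483647)
}

#' Area under the ROC curve for a score against binary labels
#'
#' Rank-sum (Mann-Whitney) formulation; higher scores are expected for
#' positives. Ties handled by midranks.
#'
#' @param score Numeric vector.
#' @param positive Logical vector, same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative labels")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Jaccard index of two sets
#' @param a,b Vectors treated as sets.
#' @return `|a ∩ b| / |a ∪ b|` (1 when both empty).
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Winsorize a numeric vector at empirical quantiles
#'
#' Values below the lower quantile are replaced with it, values above the
#' upper quantile with that. Missing values are kept missing.
#'
#' @param x Numeric vector.
#' @param probs Two probabilities (lower, upper).
#' @return Winsorized vector.
#' @export
winsorize <- function(x, probs = c(0.05, 0.95)) {
  stopifnot(length(probs) == 2L, probs[1] <= probs[2])
  q <- stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
  pmin(pmax(x, q[1]), q[2])
}

#' Signed cube root
#' @param x Numeric vector.
#' @return `sign(x) * |x|^(1/3)`.
#' @export
cube_root <- function(x) sign(x) * abs(x)^(1 / 3)

# stable short hash of an R object (used to stamp outputs with their config)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
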