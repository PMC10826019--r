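# Internal helpers shared across modules.

# Deterministic substream seed derived from a global seed and a stream name,
# so that changing one pipeline stage does not perturb the draws of another.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% 1000000007
  as.integer((as.numeric(seed) %% 65536 * 32749 + h) %% 2147483647)
}

# Full-precision decimal text for doubles ("%.17g" round-trips exactly).
num_text <- function(x) sprintf("%.17g", x)

# Benjamini-Hochberg step-up adjustment (input order preserved).
#
# Thin validating wrapper over stats::p.adjust; exposed because every stage
# of the pipeline gates on BH-adjusted values.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; the order of the input vector is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Intersect two gene sets
#'
#' Exact, case-sensitive intersection after whitespace stripping; the order
#' of the first argument is preserved.
#'
#' @param a,b Character vectors of gene identifiers.
#' @return Character vector `a` \eqn{\cap} `b`.
#' @export
intersect_sets <- function(a, b) {
  a <- unique(trimws(as.character(a)))
  b <- unique(trimws(as.character(b)))
  a[a %in% b]
}
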