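#' @useDynLib lowcovcall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize rbinom rpois runif setNames median cor predict
#' @importFrom utils read.table write.table
NULL

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_prob <- function(x, name, max = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > max)
    stop_invalid("`%s` must be a probability in [0, %g]", name, max)
  as.numeric(x)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Each pipeline stage draws its randomness under a seed deterministically
#' derived from the master seed and the stage name, so stages can be re-run
#' in isolation with identical results.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

## phred-scale a likelihood vector/matrix: round(-10 log10 L), min-normalised,
## capped at 255 (VCF PL convention). L = 0 maps to the cap.
phred_scale <- function(lik) {
  pl <- -10 * log10(lik)
  pl[!is.finite(pl)] <- Inf
  if (is.matrix(lik)) pl <- pl - apply(pl, 1L, min) else pl <- pl - min(pl)
  pl <- round(pl)
  pl[pl > 255] <- 255
  pl
}

## argmax over the columns of an n x 3 matrix with ties broken toward the
## lowest dosage (reference-first, as real callers do)
argmax_genotype <- function(m) {
  max.col(m, ties.method = "first")
}
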