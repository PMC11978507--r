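#' Method-of-moments signal normalization (iteration 1)
#'
#' Computes the linear transform of the event current means `E` whose image
#' has exactly the same population mean and sd as the reference k-mer model
#' means `K` covered by the basecalled alignment:
#' `scale = sd(K)/sd(E)`, `shift = mean(K) - scale * mean(E)`.
#'
#' @param event_means event current means (>= 2 values, non-constant).
#' @param ref_kmer_means model means of the covered reference positions, one
#'   entry per covered position (occurrence-weighted).
#' @return list with `scale`, `shift`, `iteration = 1`.
#' @export
mom_normalize <- function(event_means, ref_kmer_means) {
  if (length(event_means) < 2 || length(ref_kmer_means) < 2)
    stop("need at least 2 events and 2 reference k-mers")
  se <- pop_sd(event_means)
  if (se == 0) stop("degenerate signal: zero variance in event means")
  scale <- pop_sd(ref_kmer_means) / se
  shift <- mean(ref_kmer_means) - scale * mean(event_means)
  list(scale = scale, shift = shift, iteration = 1L)
}

#' Regression signal normalization (iteration 2)
#'
#' Ordinary least squares of the model means on the observed per-position
#' current means (each reference position contributes one pair regardless of
#' dwell time): `scale` is the slope and `shift` the intercept. Falls back to
#' the identity (i.e. keeps the iteration-1 transform) with a warning when
#' the observed values are constant.
#'
#' @param observed per-reference-position mean of all raw samples aligned to
#'   the position, in current normalized units.
#' @param model_means corresponding model means.
#' @return list with `scale`, `shift`, `iteration = 2`.
#' @export
regression_normalize <- function(observed, model_means) {
  ok <- is.finite(observed) & is.finite(model_means)
  observed <- observed[ok]; model_means <- model_means[ok]
  if (length(observed) < 3)
    stop("need at least 3 aligned (observed, model) pairs")
  vx <- stats::var(observed)
  if (vx == 0) {
    warning("constant observed currents; falling back to iteration-1 transform")
    return(list(scale = 1, shift = 0, iteration = 2L))
  }
  scale <- stats::cov(observed, model_means) / vx
  shift <- mean(model_means) - scale * mean(observed)
  list(scale = scale, shift = shift, iteration = 2L)
}

# compose two linear transforms: apply a first, then b
compose_norm <- function(a, b) {
  list(scale = b$scale * a$scale, shift = b$scale * a$shift + b$shift,
       iteration = max(a$iteration, b$iteration))
}
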