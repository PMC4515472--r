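#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median rnorm rpois rnbinom rbinom runif lm coef
#'   pchisq pt t.test wilcox.test p.adjust logLik sd setNames complete.cases
#' @importFrom utils head read.csv write.csv
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state afterwards.
# Every generator routes its randomness through this so that scenes, spectra and
# tables are pure functions of (params, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Otsu threshold on an arbitrary-range numeric vector: exhaustive search over
# `nbins` histogram cut points for the split maximising between-class variance.
# Returns a threshold on the original intensity scale.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bc <- (mu_t * w - mu)^2 / (w * (1 - w))
  bc[!is.finite(bc)] <- -Inf
  k <- which.max(bc[-nbins])
  (mids[k] + mids[k + 1]) / 2
}
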