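#' @importFrom stats aggregate as.dist cor dist hclust cutree median
#'   quantile rnorm runif rnbinom nlminb optimize pchisq qchisq sd setNames
#'   var lm.fit poly
#' @importFrom utils read.delim write.table head
NULL

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' A single master seed deterministically yields independent per-stage and
#' per-chemical seeds by hashing the label strings into the integer range.
#'
#' @param seed master seed (integer).
#' @param ... character labels (stage name, chemical id, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
subSeed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  m <- 2147480009 # prime below 2^31
  h <- as.double(seed %% m)
  for (code in utf8ToInt(labels)) h <- (h * 131 + code) %% m
  as.integer(h %% (m - 1L) + 1L)
}

#' Gini coefficient of a nonnegative vector
#'
#' Computed from the mean absolute difference, without the small-sample
#' `n/(n-1)` correction. Used as a per-sample signal-concentration QC metric
#' on probe counts.
#'
#' @param x nonnegative numeric vector (per-probe counts of one sample).
#' @return Gini coefficient in `[0, 1]`.
#' @export
giniCoefficient <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  n <- length(x)
  if (n == 0L || mean(x) == 0) return(0)
  xs <- sort(x)
  # mean absolute difference via the sorted-order identity
  g <- 2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
  max(0, g)
}

## Weighted pool-adjacent-violators (nondecreasing isotonic regression).
## Returns the fitted values in the input order.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 1L) return(y)
  nb <- n
  bval <- y
  bw <- w
  bsize <- rep(1L, n)
  i <- 1L
  while (i < nb) {
    if (bval[i] > bval[i + 1L] + 0) {
      # merge blocks i and i+1
      tw <- bw[i] + bw[i + 1L]
      bval[i] <- (bval[i] * bw[i] + bval[i + 1L] * bw[i + 1L]) / tw
      bw[i] <- tw
      bsize[i] <- bsize[i] + bsize[i + 1L]
      bval <- bval[-(i + 1L)]
      bw <- bw[-(i + 1L)]
      bsize <- bsize[-(i + 1L)]
      nb <- nb - 1L
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  rep(bval[seq_len(nb)], bsize[seq_len(nb)])
}

## Tukey fence bounds at k * IQR beyond the quartiles (type-7 quantiles).
tukeyFence <- function(x, k = 3) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

## Percentile interval of a draw vector (2.5/97.5 at level 0.95, type 7).
percentileCi <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  quantile(x, c(a, 1 - a), type = 7, names = FALSE, na.rm = TRUE)
}

## stop() with a consistent prefix-free message assembled via sprintf
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
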