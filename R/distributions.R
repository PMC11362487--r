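#' Inverse-logit link
#'
#' \code{exp(x)/(1+exp(x))}, computed overflow-safely for any finite x.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
inverse_logit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

#' Logit link
#' @param p Values in (0, 1).
#' @return Real values.
#' @export
logit <- function(p) log(p) - log1p(-p)

#' Beta-proportion log-density
#'
#' The beta distribution parameterized by its mean \code{mu} and
#' dispersion (precision) \code{M}, with shape parameters
#' \code{a = mu * M} and \code{b = (1 - mu) * M}. Larger M concentrates
#' the distribution around mu.
#'
#' @param y Outcome values strictly inside (0, 1). Exact 0/1 are an
#'   error: apply [transform_bounds()] first.
#' @param mu Mean in (0, 1).
#' @param M Dispersion > 0.
#' @return Log-density, vectorized over the longest argument.
#' @export
betaprop_logpdf <- function(y, mu, M) {
  if (any(y <= 0 | y >= 1)) {
    stop("betaprop_logpdf() requires 0 < y < 1; apply transform_bounds() to boundary values")
  }
  stopifnot(all(mu > 0 & mu < 1), all(M > 0))
  lgamma(M) - lgamma(mu * M) - lgamma((1 - mu) * M) +
    (mu * M - 1) * log(y) + ((1 - mu) * M - 1) * log1p(-y)
}

#' Random beta-proportion draws
#' @inheritParams betaprop_logpdf
#' @param n Number of draws.
#' @return Draws strictly in (0, 1).
#' @export
rbetaprop <- function(n, mu, M) {
  stopifnot(all(mu > 0 & mu < 1), all(M > 0))
  stats::rbeta(n, mu * M, (1 - mu) * M)
}

#' Compress boundary values into the open unit interval
#'
#' Entropy scores can be exactly 0 (perfect agreement) or 1 (all
#' transcriptions distinct), which a beta likelihood cannot support.
#' The default compression \code{y' = (y * (n - 1) + 0.5) / n}
#' (Smithson & Verkuilen) maps [0, 1] into (0, 1) while leaving 0.5
#' fixed; it is applied identically to the outcome of every model so
#' that information criteria remain comparable across families. An
#' epsilon clamp is available as an alternative.
#'
#' @param y Values in [0, 1].
#' @param n Sample size used by the compression (number of
#'   observations).
#' @param method \code{"compress"} (default) or \code{"clamp"}.
#' @param eps Clamp width when \code{method = "clamp"}.
#' @return Values strictly in (0, 1).
#' @export
transform_bounds <- function(y, n, method = c("compress", "clamp"),
                             eps = 1e-6) {
  method <- match.arg(method)
  if (any(y < 0 | y > 1)) stop("transform_bounds() requires values in [0, 1]")
  if (method == "compress") {
    stopifnot(n >= 2)
    (y * (n - 1) + 0.5) / n
  } else {
    pmin(pmax(y, eps), 1 - eps)
  }
}

#' Invert the boundary compression
#' @inheritParams transform_bounds
#' @param y_t Compressed values.
#' @return Original values in [0, 1].
#' @export
inverse_transform_bounds <- function(y_t, n) (y_t * n - 0.5) / (n - 1)

# Truncated-normal draws by rejection; bounds are a few SDs from the
# mean everywhere this is used, so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Stable log(sum(exp(x))) and log(mean(exp(x))).
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))
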