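# Chain-quality diagnostics: rank-normalized split R-hat and
# autocorrelation-based effective sample size (Vehtari et al. 2021
# variants of the classic Gelman-Rubin / Geyer estimators).

# iterations x chains -> split-halves matrix (iterations/2 x 2*chains).
split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- n %/% 2L
  if (h < 1L) stop("need at least 2 iterations per chain to split")
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1L):n, , drop = FALSE])
}

# Pooled rank-normalization (fractional offset 3/8).
rank_normalize <- function(x) {
  d <- dim(x)
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  dim(z) <- d
  z
}

rhat_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Potential scale reduction factor (R-hat)
#'
#' Rank-normalized split R-hat: the maximum of the split-R-hat of the
#' rank-normalized draws (bulk) and of the rank-normalized folded draws
#' (tails). Values above 1.05 indicate chains that have not mixed. The
#' plain Gelman-Rubin split statistic is available with
#' \code{rank_normalized = FALSE}.
#'
#' @param x Matrix of draws for one parameter, iterations x chains
#'   (at least 2 chains, 4 iterations).
#' @param rank_normalized Use the rank-normalized variant (default).
#' @return The R-hat statistic; \code{NaN} for degenerate (constant)
#'   draws.
#' @export
rhat <- function(x, rank_normalized = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("rhat() needs at least 2 chains")
  if (nrow(x) < 4L) stop("rhat() needs at least 4 iterations per chain")
  if (stats::sd(x) == 0 || !all(is.finite(x))) return(NaN)
  xs <- split_chains(x)
  if (!rank_normalized) return(rhat_basic(xs))
  bulk <- rhat_basic(rank_normalize(xs))
  folded <- rhat_basic(rank_normalize(abs(xs - stats::median(x))))
  max(bulk, folded)
}

# Per-chain autocovariance (biased, lags 0..n-1) via FFT.
autocov_fft <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  np <- 2L * 2L^ceiling(log2(n))
  f <- stats::fft(c(v, rep(0, np - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / np
  ac / n  # biased estimate
}

# Combined-chain ESS with Geyer's initial positive sequence and
# initial monotone sequence corrections.
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (stats::sd(x) == 0 || !all(is.finite(x))) return(NaN)
  ac <- vapply(seq_len(m), function(c) autocov_fft(x[, c]), numeric(n))
  chain_var <- ac[1L, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(colMeans(x))
  if (var_plus == 0) return(NaN)
  acm <- rowMeans(ac)  # lag t is element t+1
  rho <- numeric(n)
  rho[1L] <- 1
  rho[2L] <- 1 - (mean_var - acm[2L]) / var_plus
  even <- 1; odd <- rho[2L]
  t <- 1L
  # initial positive sequence: keep adjacent pairs while their sum > 0
  while (t < n - 3L && (even + odd) > 0) {
    even <- 1 - (mean_var - acm[t + 2L]) / var_plus
    odd <- 1 - (mean_var - acm[t + 3L]) / var_plus
    if ((even + odd) >= 0) {
      rho[t + 2L] <- even
      rho[t + 3L] <- odd
    }
    t <- t + 2L
  }
  max_t <- t - 2L
  if (even > 0) rho[max_t + 2L] <- even
  # initial monotone sequence: pair sums nonincreasing
  t <- 1L
  while (t <= max_t - 2L) {
    if (rho[t + 2L] + rho[t + 3L] > rho[t] + rho[t + 1L]) {
      rho[t + 2L] <- (rho[t] + rho[t + 1L]) / 2
      rho[t + 3L] <- rho[t + 2L]
    }
    t <- t + 2L
  }
  total <- m * n
  tau_hat <- -1 + 2 * sum(rho[seq_len(max_t + 1L)]) + rho[max_t + 2L]
  tau_hat <- max(tau_hat, 1 / log10(total))
  total / tau_hat
}

#' Effective sample size
#'
#' Autocorrelation-based ESS on split chains with Geyer's initial
#' positive-sequence truncation. The default (bulk) variant
#' rank-normalizes the draws first; \code{type = "tail"} returns the
#' minimum ESS of the 5\% and 95\% exceedance indicators. Estimates
#' exceeding the total draw count (antithetic chains) are capped at the
#' total and flagged via the \code{"capped"} attribute.
#'
#' @param x Matrix of draws, iterations x chains.
#' @param type \code{"bulk"}, \code{"tail"} or \code{"mean"} (no rank
#'   normalization).
#' @return ESS (\code{NaN} for degenerate draws), with attribute
#'   \code{capped}.
#' @export
ess <- function(x, type = c("bulk", "tail", "mean")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("ess() needs at least 2 chains")
  if (nrow(x) < 4L) stop("ess() needs at least 4 iterations per chain")
  total <- length(x)
  raw <- switch(type,
    bulk = ess_basic(rank_normalize(split_chains(x))),
    mean = ess_basic(split_chains(x)),
    tail = {
      qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
      min(ess_basic(split_chains(1 * (x <= qs[1]))),
          ess_basic(split_chains(1 * (x <= qs[2]))))
    })
  if (is.nan(raw)) return(structure(NaN, capped = FALSE))
  structure(min(raw, total), capped = raw > total)
}

#' Diagnostics report for a fit
#'
#' One row per monitored parameter: rank-normalized split R-hat, bulk
#' and tail ESS, and flags. The convergence flag follows the 1.05
#' R-hat cutoff.
#'
#' @param fit An \code{si_fit}, or a draws array
#'   \code{[iteration, chain, parameter]}.
#' @param params Optional character subset of parameter names.
#' @param rhat_cutoff Flag threshold, default 1.05.
#' @return A \code{diagnostics_report} data.frame with columns
#'   \code{parameter, rhat, ess_bulk, ess_tail, flag, degenerate},
#'   and attribute \code{n_flagged}.
#' @export
diagnose <- function(fit, params = NULL, rhat_cutoff = 1.05) {
  draws <- if (inherits(fit, "si_fit")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3L)
  all_pars <- dimnames(draws)[[3]]
  if (is.null(params)) params <- all_pars
  params <- intersect(params, all_pars)
  rows <- lapply(params, function(p) {
    x <- draws[, , p]
    r <- rhat(x)
    eb <- ess(x, "bulk")
    et <- ess(x, "tail")
    data.frame(parameter = p, rhat = as.numeric(r),
               ess_bulk = as.numeric(eb), ess_tail = as.numeric(et),
               flag = is.nan(r) || r > rhat_cutoff,
               degenerate = is.nan(r))
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(0), rhat = numeric(0),
               ess_bulk = numeric(0), ess_tail = numeric(0),
               flag = logical(0), degenerate = logical(0))
  attr(rep, "n_flagged") <- sum(rep$flag)
  class(rep) <- c("diagnostics_report", "data.frame")
  rep
}

#' Write a diagnostics report to CSV
#'
#' @param report A [diagnose()] result.
#' @param path Output CSV path.
#' @return The number of flagged parameters, invisibly (the pipeline's
#'   gating status: nonzero means convergence problems).
#' @export
write_diagnostics <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(attr(report, "n_flagged"))
}

#' Plot data for chain-quality graphics
#'
#' Emits the underlying data of the standard convergence graphics
#' (trace, rank histogram, autocorrelation, density) as tidy data
#' frames, keeping plotting itself out of the core.
#'
#' @param fit An \code{si_fit} or draws array.
#' @param parameter Parameter name.
#' @param type One of \code{"trace"}, \code{"rank"}, \code{"acf"},
#'   \code{"density"}.
#' @param bins Rank-histogram bin count.
#' @param lag_max Maximum ACF lag.
#' @return A tidy data.frame.
#' @export
plot_data <- function(fit, parameter, type = c("trace", "rank", "acf", "density"),
                      bins = 20L, lag_max = 50L) {
  type <- match.arg(type)
  draws <- if (inherits(fit, "si_fit")) fit$draws else fit
  x <- draws[, , parameter, drop = FALSE][, , 1L]
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  switch(type,
    trace = data.frame(iteration = rep(seq_len(n), m),
                       chain = rep(seq_len(m), each = n),
                       value = as.vector(x)),
    rank = {
      r <- matrix(rank(as.vector(x), ties.method = "average"), n, m)
      brk <- seq(0, length(x), length.out = bins + 1L)
      do.call(rbind, lapply(seq_len(m), function(c) {
        h <- graphics::hist(r[, c], breaks = brk, plot = FALSE)
        data.frame(chain = c, bin = seq_len(bins), count = h$counts)
      }))
    },
    acf = do.call(rbind, lapply(seq_len(m), function(c) {
      a <- stats::acf(x[, c], lag.max = min(lag_max, n - 1L), plot = FALSE)
      data.frame(chain = c, lag = as.vector(a$lag), acf = as.vector(a$acf))
    })),
    density = do.call(rbind, lapply(seq_len(m), function(c) {
      d <- stats::density(x[, c])
      data.frame(chain = c, x = d$x, y = d$y)
    })))
}
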