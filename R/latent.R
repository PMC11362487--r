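# Latent potential-intelligibility posteriors, rankings, contrasts and
# highest posterior density intervals.

#' Highest posterior density interval
#'
#' The shortest interval containing \code{prob} posterior mass,
#' computed by sliding a window of \code{ceiling(prob * n)} samples
#' over the sorted draws (assumes a unimodal posterior).
#'
#' @param samples Numeric draws (50 or more recommended).
#' @param prob Interval mass in (0, 1), default 0.95.
#' @return Named vector \code{c(lower, upper)}.
#' @export
hpdi <- function(samples, prob = 0.95) {
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    stop("prob must be in (0, 1)")
  }
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2L) stop("hpdi() needs at least 2 finite samples")
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Extract speakers' latent potential intelligibility
#'
#' Assembles each speaker's latent potential intelligibility draw by
#' draw from the structural components of a beta-proportion GLLAMM fit:
#' \deqn{SI_i = \alpha + \alpha_{HS[i]} + \beta_{A,HS[i]} (A_i - \bar A)
#'   + e_i + u_i,}
#' with fixed-effect terms included as the model variant specifies and
#' \eqn{u_i} the average of the speaker's sentence effects. Block
#' effects are not part of the latent trait. Speakers are ranked by
#' posterior mean, most intelligible first, ties broken by speaker id.
#'
#' @param fit An \code{si_fit} for a beta-family model.
#' @param prob HPDI mass for the summary.
#' @return A \code{latent_posterior} list with \code{draws} (retained
#'   draws x speakers, columns named by speaker label) and
#'   \code{summary} (speaker, mean, hpdi_lo, hpdi_hi, rank).
#' @export
extract_si <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "si_fit"))
  if (fit$spec$family != "beta") {
    stop("latent potential intelligibility is defined by the structural ",
         "model of the beta-proportion GLLAMM; model ", fit$spec$model_id,
         " is a normal LMM")
  }
  D <- draws_matrix(fit)
  idx <- fit$index
  I <- idx$n_speakers
  si <- matrix(D[, "alpha"], nrow(D), I)
  if (fit$spec$fixed_effects != "intercept_only") {
    aHS <- D[, par_cols(fit, "alpha_HS"), drop = FALSE]
    si <- si + aHS[, idx$g, drop = FALSE]
    if (fit$spec$fixed_effects == "group_intercepts_plus_common_slope") {
      si <- si + outer(D[, "beta_A"], idx$agec)
    } else {
      si <- si + D[, par_cols(fit, "beta_A_HS"), drop = FALSE][, idx$g, drop = FALSE] *
        matrix(idx$agec, nrow(D), I, byrow = TRUE)
    }
  }
  si <- si + D[, par_cols(fit, "e"), drop = FALSE]
  U <- D[, par_cols(fit, "u"), drop = FALSE]
  for (i in seq_len(I)) {
    cols <- which(idx$sent_speaker == i)
    si[, i] <- si[, i] + rowMeans(U[, cols, drop = FALSE])
  }
  colnames(si) <- as.character(idx$spk_levels)
  mean_si <- colMeans(si)
  his <- apply(si, 2L, hpdi, prob = prob)
  ord <- order(-mean_si, idx$spk_levels)
  rk <- integer(I); rk[ord] <- seq_len(I)
  structure(list(draws = si,
                 summary = data.frame(speaker = idx$spk_levels,
                                      mean = mean_si,
                                      hpdi_lo = his[1L, ],
                                      hpdi_hi = his[2L, ],
                                      rank = rk,
                                      row.names = NULL)),
            class = "latent_posterior")
}

#' @export
print.latent_posterior <- function(x, ...) {
  cat(sprintf("<latent_posterior: %d speakers, %d draws>\n",
              ncol(x$draws), nrow(x$draws)))
  print(utils::head(x$summary[order(x$summary$rank), ], 5L))
  invisible(x)
}

new_contrast <- function(label, draws, prob) {
  h <- hpdi(draws, prob)
  structure(list(label = label, draws = draws, mean = mean(draws),
                 hpdi = h, significant = h[["lower"]] > 0 || h[["upper"]] < 0),
            class = "si_contrast")
}

#' @export
print.si_contrast <- function(x, ...) {
  cat(sprintf("<contrast %s: mean %.3f, 95%% HPDI [%.3f, %.3f]%s>\n",
              x$label, x$mean, x$hpdi[["lower"]], x$hpdi[["upper"]],
              if (x$significant) ", HPDI excludes 0" else ""))
  invisible(x)
}

#' Contrast two speakers' latent intelligibility
#'
#' The posterior of \code{SI_i - SI_j}; "significant" means the HPDI
#' excludes zero (an interval-exclusion criterion, not a frequentist
#' test).
#'
#' @param lp A [extract_si()] result.
#' @param i,j Speaker labels (as in the data's \code{speaker} column).
#' @param prob HPDI mass.
#' @return An \code{si_contrast}.
#' @export
speaker_contrast <- function(lp, i, j, prob = 0.95) {
  stopifnot(inherits(lp, "latent_posterior"))
  ci <- as.character(i); cj <- as.character(j)
  if (!all(c(ci, cj) %in% colnames(lp$draws))) {
    stop("unknown speaker id(s): ", ci, ", ", cj)
  }
  new_contrast(sprintf("SI[%s] - SI[%s]", ci, cj),
               lp$draws[, ci] - lp$draws[, cj], prob)
}

#' Group-level fixed-effect contrasts
#'
#' The HI/CI minus NH contrasts of the group intercepts
#' (\code{alpha_HS[2] - alpha_HS[1]}) and, for group-slope variants,
#' the age slopes (\code{beta_A_HS[2] - beta_A_HS[1]}), computed on the
#' draw scale.
#'
#' @param fit An \code{si_fit} whose model includes group intercepts.
#' @param prob HPDI mass.
#' @return Named list of \code{si_contrast} objects.
#' @export
group_contrasts <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "si_fit"))
  if (fit$spec$fixed_effects == "intercept_only") {
    stop("model ", fit$spec$model_id,
         " has no group parameters; no group contrast is defined")
  }
  D <- draws_matrix(fit)
  aHS <- D[, par_cols(fit, "alpha_HS"), drop = FALSE]
  out <- list(alpha_HS = new_contrast("alpha_HS[2] - alpha_HS[1]",
                                      aHS[, 2L] - aHS[, 1L], prob))
  if (fit$spec$fixed_effects == "group_intercepts_plus_group_slopes") {
    b <- D[, par_cols(fit, "beta_A_HS"), drop = FALSE]
    out$beta_A_HS <- new_contrast("beta_A_HS[2] - beta_A_HS[1]",
                                  b[, 2L] - b[, 1L], prob)
  }
  out
}

#' Speaker-ranking table
#'
#' @param lp A [extract_si()] result.
#' @return The summary data.frame ordered by rank (most intelligible
#'   first).
#' @export
rank_speakers <- function(lp) {
  stopifnot(inherits(lp, "latent_posterior"))
  s <- lp$summary[order(lp$summary$rank), ]
  rownames(s) <- NULL
  s
}
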