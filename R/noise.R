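#' Replicate residuals of a peak table
#'
#' For each (cell, concentration) group with at least 2 retained replicates,
#' the residual of a replicate is its log response minus the group mean:
#' e_ik(c_j) = r_ijk - (1/K) sum_k r_ijk, with K the post-QC replicate
#' count of that group. Groups with fewer than 2 retained replicates are
#' excluded with a warning. Within every group the residuals sum to zero by
#' construction.
#'
#' @param peaks peak table (rows flagged \code{artifact_removed} are ignored).
#' @return data.frame: cell_id, concentration_nM, replicate, pulse_index,
#'   residual, K (group size).
#' @export
compute_residuals <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    stop("compute_residuals: empty peak table")
  }
  keep <- peaks$qc_flag != "artifact_removed"
  peaks <- peaks[keep, , drop = FALSE]
  grp <- interaction(peaks$cell_id, peaks$concentration_nM, drop = TRUE)
  pieces <- split(peaks, grp)
  small <- vapply(pieces, nrow, integer(1)) < 2
  if (any(small)) {
    warning("compute_residuals: ", sum(small),
            " group(s) with < 2 replicates excluded")
    pieces <- pieces[!small]
  }
  if (length(pieces) == 0) stop("compute_residuals: no group with K >= 2")
  out <- lapply(pieces, function(g) {
    data.frame(cell_id = g$cell_id,
               concentration_nM = g$concentration_nM,
               replicate = g$replicate,
               pulse_index = g$pulse_index,
               residual = g$peak_log_response - mean(g$peak_log_response),
               K = nrow(g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cell_id, out$pulse_index), , drop = FALSE]
}

#' Fit the per-concentration scaled-t noise model
#'
#' Pools residuals across cells for each concentration (the noise
#' distribution is shared across cells and specific to each input) and fits
#' (sigma_j, nu_j) by maximum likelihood.
#'
#' @param residuals data.frame from \code{compute_residuals}, or a peak
#'   table (residuals are computed first).
#' @param nu_bounds degrees-of-freedom bounds.
#' @param min_n minimum pooled residuals per concentration.
#' @return data.frame: concentration_nM, sigma, nu, loglik, n.
#' @export
fit_noise_model <- function(residuals, nu_bounds = c(0.5, 200), min_n = 50) {
  if (!"residual" %in% names(residuals)) {
    residuals <- compute_residuals(residuals)
  }
  concs <- sort(unique(residuals$concentration_nM))
  rows <- lapply(concs, function(cj) {
    e <- residuals$residual[residuals$concentration_nM == cj]
    fit <- fit_scaled_t(e, nu_bounds = nu_bounds, min_n = min_n)
    data.frame(concentration_nM = cj, sigma = fit$sigma, nu = fit$nu,
               loglik = fit$loglik, n = fit$n)
  })
  do.call(rbind, rows)
}

#' Noise-fit diagnostics
#'
#' Per concentration: residual skewness and excess kurtosis, a
#' quantile-quantile table of empirical vs fitted scaled-t quantiles, and
#' the log-likelihood of the scaled-t fit against a zero-mean Gaussian MLE
#' fit (positive delta favours the heavy-tailed model).
#'
#' @param residuals data.frame from \code{compute_residuals}.
#' @param params data.frame from \code{fit_noise_model}.
#' @param probs quantile probabilities for the QQ table.
#' @return named list of per-concentration diagnostic lists.
#' @export
diagnose_fit <- function(residuals, params,
                         probs = c(0.01, 0.05, 0.1, 0.25, 0.5,
                                   0.75, 0.9, 0.95, 0.99)) {
  out <- lapply(seq_len(nrow(params)), function(j) {
    cj <- params$concentration_nM[j]
    e <- residuals$residual[residuals$concentration_nM == cj]
    n <- length(e)
    m2 <- mean(e^2)
    skew <- mean(e^3) / m2^1.5
    exkurt <- mean(e^4) / m2^2 - 3
    sd_hat <- sqrt(m2)                  # Gaussian MLE around the known 0 mean
    ll_gauss <- sum(stats::dnorm(e, 0, sd_hat, log = TRUE))
    ll_t <- scaled_t_loglik(e, params$sigma[j], params$nu[j])
    qq <- data.frame(prob = probs,
                     empirical = stats::quantile(e, probs, names = FALSE),
                     fitted = qscaled_t(probs, params$sigma[j], params$nu[j]))
    list(concentration_nM = cj, n = n, skewness = skew,
         excess_kurtosis = exkurt, loglik_t = ll_t,
         loglik_gaussian = ll_gauss, loglik_delta = ll_t - ll_gauss,
         qq = qq)
  })
  names(out) <- paste0("c", params$concentration_nM)
  out
}
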