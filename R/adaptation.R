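#' Reproducibility of consecutive responses
#'
#' Pools, across cells, all within-cell pairs of consecutive responses
#' (pulse n, pulse n + 1) at a fixed concentration, and reports their
#' Pearson correlation, the ordinary least-squares slope of the (n+1)th on
#' the nth response, and a two-sided test of slope = 1. The regression runs
#' on the linear response scale (peak heights, exp of the stored log
#' responses): under a constant multiplicative per-pulse decay d the
#' noise-free slope equals d, so a slope below one indicates dampening with
#' repeated stimulation.
#'
#' @param peaks peak table from a constant-concentration repeated
#'   stimulation (or any table; pairs are formed within cell and
#'   concentration in pulse order).
#' @return list: r, slope, intercept, p_slope_eq_1, n_pairs.
#' @export
consecutive_correlation <- function(peaks) {
  peaks <- peaks[peaks$qc_flag != "artifact_removed", , drop = FALSE]
  grp <- interaction(peaks$cell_id, peaks$concentration_nM, drop = TRUE)
  pairs <- lapply(split(peaks, grp), function(g) {
    g <- g[order(g$pulse_index), , drop = FALSE]
    consec <- which(diff(g$pulse_index) == 1)
    if (length(consec) == 0) return(NULL)
    data.frame(x = exp(g$peak_log_response[consec]),
               y = exp(g$peak_log_response[consec + 1]))
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) < 3) {
    stop("consecutive_correlation: fewer than 3 consecutive pairs")
  }
  fit <- stats::lm(y ~ x, data = pairs)
  b <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  tstat <- (b - 1) / se
  list(r = stats::cor(pairs$x, pairs$y),
       slope = b,
       intercept = stats::coef(fit)[["(Intercept)"]],
       p_slope_eq_1 = 2 * stats::pt(-abs(tstat), df = fit$df.residual),
       n_pairs = nrow(pairs))
}

#' Per-pulse desensitization from log-space regression
#'
#' Regresses the log response on the global pulse index with a fixed
#' intercept per cell (cells differ in response strength), and converts the
#' common slope beta into a per-pulse fractional decay 1 - exp(beta) with a
#' 95% confidence interval, plus the implied drop over 20 pulses
#' 1 - exp(20 beta). With per-cell intercepts the estimate is immune to
#' between-cell strength differences. \code{per_cell_intercepts = FALSE}
#' pools all cells around a single intercept.
#'
#' @param peaks peak table (constant concentration, >= 5 pulses per cell).
#' @param per_cell_intercepts logical.
#' @return list of class \code{adaptation_fit}: decay_percent and its CI,
#'   drop_20_pulses_percent, slope_log (beta), p value, n_obs, n_cells.
#' @export
fit_decay <- function(peaks, per_cell_intercepts = TRUE) {
  peaks <- peaks[peaks$qc_flag != "artifact_removed", , drop = FALSE]
  if (length(unique(peaks$pulse_index)) < 2) {
    stop("fit_decay: need responses at more than one pulse index")
  }
  d <- data.frame(y = peaks$peak_log_response,
                  pulse = peaks$pulse_index,
                  cell = factor(peaks$cell_id))
  fit <- if (per_cell_intercepts && nlevels(d$cell) > 1) {
    stats::lm(y ~ 0 + cell + pulse, data = d)
  } else {
    stats::lm(y ~ pulse, data = d)
  }
  beta <- stats::coef(fit)[["pulse"]]
  se <- sqrt(stats::vcov(fit)["pulse", "pulse"])
  crit <- stats::qt(0.975, df = fit$df.residual)
  ci_beta <- c(beta - crit * se, beta + crit * se)
  tstat <- beta / se
  structure(
    list(slope_log = beta,
         decay_percent = 100 * (1 - exp(beta)),
         decay_ci_percent = 100 * (1 - exp(rev(ci_beta))),
         drop_20_pulses_percent = 100 * (1 - exp(20 * beta)),
         p_value = 2 * stats::pt(-abs(tstat), df = fit$df.residual),
         n_obs = nrow(d),
         n_cells = nlevels(d$cell)),
    class = "adaptation_fit")
}

#' Median-residual adaptation correction
#'
#' For each pulse number, computes the median across cells of the replicate
#' residual at that pulse and subtracts it from every log response at that
#' pulse. This removes the systematic pulse-order trend (desensitization)
#' while leaving cell-specific mean responses untouched; applied twice it
#' is a no-op up to numerical tolerance. Pulse numbers with fewer than 3
#' residuals are left uncorrected with a warning.
#'
#' The correction applied at each pulse is the per-pulse median centred
#' within its concentration block (the medians of a block are shifted to
#' average zero there), so group means — and hence the dose-response
#' profiles — are preserved exactly and the correction is idempotent; only
#' the pulse-order trend within blocks is removed.
#'
#' @param peaks peak table.
#' @return peak table with corrected \code{peak_log_response}; the applied
#'   per-pulse corrections are attached as attribute \code{corrections}.
#' @export
adaptation_correct <- function(peaks) {
  res <- compute_residuals(peaks)
  med <- stats::aggregate(residual ~ pulse_index, data = res,
                          FUN = stats::median)
  cnt <- stats::aggregate(residual ~ pulse_index, data = res, FUN = length)
  med$n <- cnt$residual
  thin <- med$n < 3
  if (any(thin)) {
    warning("adaptation_correct: pulse(s) ",
            paste(med$pulse_index[thin], collapse = ", "),
            " have < 3 residuals; left uncorrected")
    med$residual[thin] <- 0
  }
  pc <- unique(peaks[, c("pulse_index", "concentration_nM")])
  med$concentration_nM <-
    pc$concentration_nM[match(med$pulse_index, pc$pulse_index)]
  for (cj in unique(med$concentration_nM)) {
    sel <- med$concentration_nM == cj & !thin
    if (any(sel)) med$residual[sel] <- med$residual[sel] -
        mean(med$residual[sel])
  }
  shift <- med$residual[match(peaks$pulse_index, med$pulse_index)]
  shift[is.na(shift)] <- 0
  out <- peaks
  out$peak_log_response <- peaks$peak_log_response - shift
  attr(out, "corrections") <- med
  out
}
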