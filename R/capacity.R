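#' Stimulus design
#'
#' The input alphabet of the channel: the ordered agonist concentrations,
#' the number of replicate pulses per concentration, and the pulse timing.
#' Defaults are the repeated-stimulation protocol used throughout the
#' package: 7 acetylcholine concentrations from 100 nM to 10 uM, each pulsed
#' 5 times for 10 s with a 110 s inter-pulse rinse, in ascending order.
#'
#' @param concentrations_nM strictly increasing positive concentrations.
#' @param n_replicates pulses per concentration (K).
#' @param pulse_duration_s stimulation length per pulse.
#' @param gap_s inter-pulse gap.
#' @param rise_time_s time from pulse onset to peak calcium.
#' @param t0_s onset of the first pulse in the recording.
#' @return object of class \code{stimulus_design}.
#' @export
stimulus_design <- function(concentrations_nM = c(100, 250, 500, 750,
                                                  1500, 3000, 10000),
                            n_replicates = 5,
                            pulse_duration_s = 10,
                            gap_s = 110,
                            rise_time_s = 8,
                            t0_s = 50) {
  # single-concentration designs are allowed for repeated-stimulation
  # (adaptation) experiments; capacity estimation itself requires >= 2
  stopifnot(length(concentrations_nM) >= 1,
            all(concentrations_nM > 0),
            all(diff(concentrations_nM) > 0),
            n_replicates >= 1,
            pulse_duration_s > 0, gap_s > 0, rise_time_s > 0, t0_s >= 0)
  n_pulses <- length(concentrations_nM) * n_replicates
  onsets <- t0_s + (seq_len(n_pulses) - 1) * (pulse_duration_s + gap_s)
  structure(
    list(concentrations_nM = concentrations_nM,
         n_replicates = n_replicates,
         pulse_duration_s = pulse_duration_s,
         gap_s = gap_s,
         rise_time_s = rise_time_s,
         t0_s = t0_s,
         n_pulses = n_pulses,
         onsets_s = onsets,
         # concentration index and replicate for each global pulse:
         # all K replicates of c1, then c2, ... (ascending schedule)
         pulse_conc_index = rep(seq_along(concentrations_nM),
                                each = n_replicates),
         pulse_replicate = rep(seq_len(n_replicates),
                               times = length(concentrations_nM))),
    class = "stimulus_design")
}

#' Discrete-input, continuous-output channel model
#'
#' Builds the conditional output distributions P(r | c) of an additive-noise
#' channel whose input support is a finite set of concentrations and whose
#' output, the log peak response, is the input-specific mean plus scaled-t
#' noise. The continuous output axis is discretized on a uniform quadrature
#' grid spanning every conditional's mean plus/minus 8 times its 99.9%
#' scaled-t quantile; the grid densifies automatically so that its spacing
#' does not exceed a quarter of the smallest scale, which keeps narrow
#' conditionals resolved.
#'
#' @param mu per-support-point mean log response.
#' @param sigma per-support-point scaled-t scale (recycled).
#' @param nu per-support-point degrees of freedom (recycled).
#' @param support optional labels for the support points (e.g. nM).
#' @param grid_size minimum number of output grid points.
#' @param max_grid_size cap on automatic densification.
#' @return object of class \code{channel_model}: the normalized conditional
#'   pmf matrix \code{W} (rows = inputs), the grid, and the parameters.
#' @export
channel_model <- function(mu, sigma, nu, support = NULL,
                          grid_size = 2001, max_grid_size = 200000) {
  n <- length(mu)
  stopifnot(n >= 2, all(is.finite(mu)))
  sigma <- rep_len(sigma, n)
  nu <- rep_len(nu, n)
  stopifnot(all(sigma > 0), all(nu > 0))
  tail_q <- sigma * stats::qt(0.999, df = nu)
  lo <- min(mu - 8 * tail_q)
  hi <- max(mu + 8 * tail_q)
  span <- hi - lo
  g <- max(grid_size, ceiling(span / (min(sigma) / 4)) + 1)
  if (g > max_grid_size) g <- max_grid_size
  grid <- seq(lo, hi, length.out = g)
  h <- grid[2] - grid[1]
  dens <- vapply(seq_len(n),
                 function(j) dscaled_t(grid - mu[j], sigma[j], nu[j]),
                 numeric(g))
  dens <- t(dens)                      # n x g
  mass <- (rowSums(dens) - 0.5 * (dens[, 1] + dens[, g])) * h
  if (any(mass < 0.999)) {
    stop("channel_model: output grid too narrow (conditional mass ",
         format(min(mass)), " < 0.999)")
  }
  W <- dens * h
  W <- W / rowSums(W)
  structure(
    list(W = W, grid = grid, h = h, mu = mu, sigma = sigma, nu = nu,
         support = if (is.null(support)) seq_len(n) else support),
    class = "channel_model")
}

#' Mutual information of a channel at a given input distribution
#'
#' Computes, by deterministic quadrature on the model's output grid,
#' \deqn{I = \sum_j P(c_j) \int P(r|c_j)
#'   \log_2 \frac{P(r|c_j)}{\sum_l P(r|c_l) P(c_l)} \, dr.}
#'
#' @param model a \code{channel_model}.
#' @param p input distribution over the model support (sums to 1).
#' @return mutual information in bits (non-negative).
#' @export
mutual_information <- function(model, p) {
  W <- model$W
  stopifnot(length(p) == nrow(W), all(p >= 0))
  stopifnot(abs(sum(p) - 1) < 1e-9)
  q <- as.vector(crossprod(W, p))      # output marginal
  pos <- W > 0 & rep(q > 0, each = nrow(W))
  lr <- matrix(0, nrow(W), ncol(W))
  lr[pos] <- log(W[pos] / (matrix(q, nrow(W), ncol(W), byrow = TRUE)[pos]))
  I <- sum(p * rowSums(W * lr)) / log(2)
  max(I, 0)
}

#' Capacity-achieving input distribution (Blahut-Arimoto)
#'
#' Maximizes mutual information over input distributions on the model's
#' support by Blahut-Arimoto alternating maximization on the discretized
#' output. Iterations stop when the capacity bound gap
#' (max_j D_j - I, in bits) falls below \code{tol} or after
#' \code{max_iter} iterations. The objective is non-decreasing and the
#' returned value is at least the mutual information of the uniform input.
#'
#' On fine input supports the capacity-achieving distribution concentrates
#' on a few points and plain Blahut-Arimoto closes its optimality gap only
#' sublinearly. Two standard refinements are used, neither affecting what
#' is certified: the multiplicative update is overrelaxed,
#' p <- p exp(gamma D) with an adaptive exponent that falls back to the
#' plain update whenever the objective would decrease (the accepted
#' objective sequence stays non-decreasing), and iteration runs on an
#' active set of inputs whose weight has not decayed to numerical zero,
#' with periodic Kuhn-Tucker checks over the full support that re-admit any
#' violating input. Convergence is declared only on the full-support gap,
#' which is a valid optimality certificate for the returned distribution
#' whatever path produced it.
#'
#' @param model a \code{channel_model}.
#' @param tol convergence gap in bits.
#' @param max_iter iteration cap.
#' @param trace logical; if TRUE, return the per-iteration objective.
#' @param check_every full-support gap check interval (iterations).
#' @param prune active-set weight floor, relative to the largest weight.
#' @return list: \code{p} (optimal input distribution), \code{bits}
#'   (capacity estimate), \code{iterations}, \code{gap_bits},
#'   \code{converged}, and optionally \code{objective_trace}.
#' @export
optimize_input_distribution <- function(model, tol = 1e-4, max_iter = 5000,
                                        trace = FALSE, check_every = 100L,
                                        prune = 1e-14) {
  W <- model$W
  n <- nrow(W)
  logW <- matrix(0, n, ncol(W))
  posW <- W > 0
  logW[posW] <- log(W[posW])
  WlogW <- rowSums(W * logW)           # sum_r W log W, per input
  ltol <- tol * log(2)                 # gap tolerance in nats

  p <- rep(1 / n, n)
  obj <- if (trace) numeric(0) else NULL
  it <- 0L
  active <- seq_len(n)
  I <- 0
  gap_full <- Inf
  repeat {
    Wa <- W[active, , drop = FALSE]
    WlogWa <- WlogW[active]
    pa <- p[active]
    pa <- pa / sum(pa)
    inner_gap <- Inf
    gamma <- 1
    I_prev <- -Inf
    pa_prev <- pa
    D_prev <- NULL
    for (k in seq_len(check_every)) {
      it <- it + 1L
      q <- as.vector(crossprod(Wa, pa))
      logq <- ifelse(q > 0, log(q), 0) # q=0 columns have W=0 for all inputs
      D <- WlogWa - as.vector(Wa %*% logq)   # KL(W_j || q), nats
      I <- sum(pa * D)
      if (I < I_prev - 1e-13 && !is.null(D_prev)) {
        # overrelaxed step overshot: back off and retry from the last accept
        gamma <- max(1, gamma / 4)
        pa <- pa_prev
        D <- D_prev
        I <- I_prev
      } else {
        gamma <- min(gamma * 1.15, 64)
        if (trace) obj <- c(obj, I / log(2))
      }
      inner_gap <- max(D) - I
      if (inner_gap < 0.5 * ltol || it >= max_iter) break
      pa_prev <- pa
      D_prev <- D
      I_prev <- I
      lw <- log(pa) + gamma * D
      lw <- lw - max(lw)
      pa <- exp(lw)
      pa <- pa / sum(pa)
    }
    p <- numeric(n)
    p[active] <- pa
    # Kuhn-Tucker check over the full support
    qf <- as.vector(crossprod(W, p))
    logqf <- ifelse(qf > 0, log(qf), 0)
    Df <- WlogW - as.vector(W %*% logqf)
    gap_full <- (max(Df) - I) / log(2)
    if (gap_full < tol || it >= max_iter) break
    viol <- which(Df > I + 0.25 * ltol)
    keep <- active[pa > prune * max(pa)]
    newactive <- sort(unique(c(keep, viol)))
    if (length(newactive) < 2) newactive <- sort(unique(c(newactive,
                                                          which.max(Df))))
    # seed re-admitted inputs with a small weight
    newp <- p[newactive]
    newp[newp == 0] <- 1e-3 * max(newp)
    p <- numeric(n)
    p[newactive] <- newp / sum(newp)
    active <- newactive
  }
  out <- list(p = p, bits = I / log(2), iterations = it,
              gap_bits = gap_full, converged = gap_full < tol)
  if (!out$converged) {
    warning("Blahut-Arimoto did not reach gap < ", tol, " bits in ",
            max_iter, " iterations (last gap ", format(gap_full), ")")
  }
  if (trace) out$objective_trace <- obj
  out
}

#' Per-cell dose-response profile
#'
#' Group-mean log responses per tested concentration for one cell, computed
#' from retained (non-artifact) peak table rows.
#'
#' @param peaks peak table rows for a single cell.
#' @return data.frame: concentration_nM, mu (mean log response), K (count).
#' @export
cell_response_profile <- function(peaks) {
  peaks <- peaks[peaks$qc_flag != "artifact_removed", , drop = FALSE]
  if (nrow(peaks) == 0) stop("cell_response_profile: no retained peaks")
  agg <- stats::aggregate(peak_log_response ~ concentration_nM, data = peaks,
                          FUN = mean)
  cnt <- stats::aggregate(peak_log_response ~ concentration_nM, data = peaks,
                          FUN = length)
  out <- data.frame(concentration_nM = agg$concentration_nM,
                    mu = agg$peak_log_response,
                    K = cnt$peak_log_response)
  out[order(out$concentration_nM), , drop = FALSE]
}

#' Interpolated channel model over a continuous concentration axis
#'
#' Builds a fine input support on the log10-concentration axis spanning the
#' tested range and interpolates the cell mean mu(c) and the noise
#' parameters sigma(c), nu(c) piecewise-linearly in log10 c between the
#' tested knots. The support is the union of a uniform M-point grid and the
#' tested concentrations themselves, so knot values are reproduced exactly
#' and the tested support is a subset of the interpolated support. No
#' extrapolation outside the tested range.
#'
#' @param design a \code{stimulus_design} (or vector of tested nM).
#' @param noise data.frame with concentration_nM, sigma, nu at the knots.
#' @param profile data.frame with concentration_nM, mu at the knots.
#' @param M nominal grid size (>= number of tested concentrations).
#' @param grid_size output quadrature size passed to \code{channel_model}.
#' @return a \code{channel_model} whose support is the concentration grid (nM).
#' @export
interpolate_params <- function(design, noise, profile, M = 101,
                               grid_size = 2001) {
  concs <- if (inherits(design, "stimulus_design")) {
    design$concentrations_nM
  } else design
  concs <- concs[concs %in% intersect(noise$concentration_nM,
                                      profile$concentration_nM)]
  if (M < length(concs)) {
    stop("interpolate_params: M must be >= number of tested concentrations")
  }
  if (length(concs) < 2) {
    stop("interpolate_params: need >= 2 concentrations with noise and profile")
  }
  lc <- log10(concs)
  grid_lc <- sort(unique(c(seq(min(lc), max(lc), length.out = M), lc)))
  key <- function(df, col) df[[col]][match(concs, df$concentration_nM)]
  mu_g <- stats::approx(lc, key(profile, "mu"), xout = grid_lc)$y
  sg_g <- stats::approx(lc, key(noise, "sigma"), xout = grid_lc)$y
  nu_g <- stats::approx(lc, key(noise, "nu"), xout = grid_lc)$y
  channel_model(mu_g, sg_g, nu_g, support = 10^grid_lc,
                grid_size = grid_size)
}

#' Per-cell channel capacity estimate
#'
#' Estimates a cell's channel capacity from its peak table rows and the
#' shared noise model. \code{mode = "lower_bound"} restricts the input
#' support to the tested concentrations (a lower bound on the capacity);
#' \code{mode = "interpolated"} optimizes over a fine concentration grid
#' with piecewise-linearly interpolated parameters; \code{mode = "both"}
#' returns both.
#'
#' @param peaks peak table rows for one cell.
#' @param noise data.frame concentration_nM, sigma, nu.
#' @param design a \code{stimulus_design}.
#' @param mode one of "lower_bound", "interpolated", "both".
#' @param M interpolation grid size.
#' @param tol Blahut-Arimoto gap tolerance (bits).
#' @return one-row data.frame: cell_id, lower_bound_bits, interpolated_bits,
#'   ec50_nM, n_concentrations, converged; with attribute
#'   \code{input_distributions}.
#' @export
estimate_cell_capacity <- function(peaks, noise, design,
                                   mode = c("both", "lower_bound",
                                            "interpolated"),
                                   M = 101, tol = 1e-4) {
  mode <- match.arg(mode)
  cell <- unique(peaks$cell_id)
  stopifnot(length(cell) == 1)
  prof <- cell_response_profile(peaks)
  prof <- prof[prof$concentration_nM %in% design$concentrations_nM, ,
               drop = FALSE]
  if (nrow(prof) < 2) {
    stop("estimate_cell_capacity: cell ", cell,
         " has < 2 concentrations with retained replicates")
  }
  missing_noise <- setdiff(prof$concentration_nM, noise$concentration_nM)
  if (length(missing_noise) > 0) {
    stop("estimate_cell_capacity: no noise parameters for concentration(s) ",
         paste(missing_noise, collapse = ", "))
  }
  idx <- match(prof$concentration_nM, noise$concentration_nM)
  lb <- ib <- NA_real_
  conv <- TRUE
  pd <- list()
  if (mode %in% c("both", "lower_bound")) {
    m <- channel_model(prof$mu, noise$sigma[idx], noise$nu[idx],
                       support = prof$concentration_nM)
    o <- optimize_input_distribution(m, tol = tol)
    lb <- o$bits
    conv <- conv && o$converged
    pd$lower_bound <- data.frame(concentration_nM = m$support, p = o$p)
  }
  if (mode %in% c("both", "interpolated")) {
    m <- interpolate_params(design,
                            noise[idx, c("concentration_nM", "sigma", "nu")],
                            prof, M = M)
    o <- optimize_input_distribution(m, tol = tol)
    ib <- o$bits
    conv <- conv && o$converged
    pd$interpolated <- data.frame(concentration_nM = m$support, p = o$p)
  }
  ec50 <- tryCatch(estimate_ec50(prof), error = function(e) NA_real_)
  out <- data.frame(cell_id = cell,
                    lower_bound_bits = lb,
                    interpolated_bits = ib,
                    ec50_nM = ec50,
                    n_concentrations = nrow(prof),
                    converged = conv)
  attr(out, "input_distributions") <- pd
  out
}

#' Capacity estimates for every cell in a peak table
#'
#' @param peaks full peak table.
#' @param noise noise parameter table.
#' @param design a \code{stimulus_design}.
#' @param ... passed to \code{estimate_cell_capacity}.
#' @return data.frame, one row per estimable cell; cells that cannot be
#'   estimated are dropped with a warning.
#' @export
estimate_population_capacity <- function(peaks, noise, design, ...) {
  cells <- sort(unique(peaks$cell_id))
  rows <- lapply(cells, function(cl) {
    tryCatch(
      estimate_cell_capacity(peaks[peaks$cell_id == cl, , drop = FALSE],
                             noise, design, ...),
      error = function(e) {
        warning("cell ", cl, " skipped: ", conditionMessage(e))
        NULL
      })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no cell could be estimated")
  do.call(rbind, rows)
}

#' Half-maximal effective concentration of a dose-response profile
#'
#' EC50 is the concentration at which the normalized response
#' (mu - min mu) / (max mu - min mu) first crosses 0.5, found by
#' piecewise-linear interpolation on the log10-concentration axis.
#'
#' @param profile data.frame with concentration_nM and mu (>= 3 rows).
#' @return EC50 in nM; error if the profile is flat or never crosses 0.5.
#' @export
estimate_ec50 <- function(profile) {
  stopifnot(nrow(profile) >= 3)
  mu <- profile$mu
  rng <- max(mu) - min(mu)
  if (rng <= 0) stop("estimate_ec50: flat profile, EC50 undefined")
  f <- (mu - min(mu)) / rng
  lc <- log10(profile$concentration_nM)
  for (i in seq_len(length(f) - 1)) {
    if (f[i] < 0.5 && f[i + 1] >= 0.5) {
      w <- (0.5 - f[i]) / (f[i + 1] - f[i])
      return(10^(lc[i] + w * (lc[i + 1] - lc[i])))
    }
    if (i == 1 && f[1] >= 0.5) return(10^lc[1])
  }
  stop("estimate_ec50: profile never crosses half-maximum")
}

#' Population summary of capacity estimates
#'
#' @param estimates data.frame from \code{estimate_population_capacity}.
#' @param bin_width histogram bin width in bits.
#' @return list: per-mode mean, sd (0 with an n=1 flag for a single cell),
#'   histogram bin counts, n, and the per-cell table.
#' @export
summarize_population <- function(estimates, bin_width = 0.1) {
  stopifnot(nrow(estimates) >= 1)
  one <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return(NULL)
    brk <- seq(0, ceiling(max(x) / bin_width) * bin_width + bin_width,
               by = bin_width)
    hh <- graphics::hist(x, breaks = brk, plot = FALSE)
    list(mean = mean(x),
         sd = if (length(x) > 1) stats::sd(x) else 0,
         n = length(x),
         single_cell = length(x) == 1,
         hist_breaks = hh$breaks,
         hist_counts = hh$counts)
  }
  list(lower_bound = one(estimates$lower_bound_bits),
       interpolated = one(estimates$interpolated_bits),
       n_cells = nrow(estimates),
       per_cell = estimates)
}
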