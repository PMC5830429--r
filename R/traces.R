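#' Remove the slowly rising background from a ratio trace
#'
#' The recording background rises over the experiment; it is estimated as a
#' smoothed rolling minimum with a window longer than one pulse period (so
#' each window contains inter-pulse baseline samples), subtracted, and the
#' result recentred on its 20th percentile so inter-pulse intervals sit at
#' about zero.
#'
#' @param ratio numeric ratio trace, uniformly sampled.
#' @param window_frames odd window length in frames; must exceed one pulse
#'   period and be at most the trace length.
#' @return background-corrected trace, same length.
#' @export
remove_background <- function(ratio, window_frames = 181) {
  n <- length(ratio)
  stopifnot(all(is.finite(ratio)))
  if (window_frames >= n) {
    stop("remove_background: window (", window_frames,
         ") not shorter than trace (", n, ")")
  }
  if (window_frames %% 2 == 0) window_frames <- window_frames + 1
  bmin <- zoo::rollapply(ratio, window_frames, min, align = "center",
                         partial = TRUE)
  sm <- zoo::rollapply(bmin, window_frames, mean, align = "center",
                       partial = TRUE)
  corrected <- ratio - sm
  corrected - stats::quantile(corrected, 0.2, names = FALSE)
}

# local maxima that are the strict max of a centred window and exceed thr
.local_maxima <- function(x, half_width = 15, thr = 0) {
  n <- length(x)
  idx <- which(x > thr)
  idx <- idx[idx > 1 & idx < n]
  keep <- vapply(idx, function(i) {
    lo <- max(1, i - half_width)
    hi <- min(n, i + half_width)
    x[i] >= max(x[lo:hi]) && x[i] > x[i - 1]
  }, logical(1))
  idx[keep]
}

#' Detect the expected pulse peaks on a corrected trace
#'
#' Searches the background-corrected trace for the x = N * K peaks expected
#' from the stimulation schedule. Prominent maxima (above
#' \code{prominence_mads} times the trace MAD) anchor a time alignment: the
#' median offset between their times and the template (the scheduled peak
#' times, or a representative cell's detected peak times) is applied to the
#' template, and every pulse's height is read as the local maximum of the
#' corrected trace in a window around its projected time. Pulses without an
#' independently detected prominent peak — typically the early
#' low-concentration ones near background — are flagged \code{extrapolated}.
#'
#' @param time_s time vector (uniform 1 s spacing, within 1%).
#' @param ratio background-corrected ratio trace.
#' @param design a \code{stimulus_design}.
#' @param reference_times optional template peak times (one per pulse) from
#'   a representative trace; defaults to the scheduled onset + rise time.
#' @param prominence_mads detection threshold in trace MADs.
#' @param window_s half-width of the height-extraction window.
#' @return data.frame: pulse_index, time_s, height, detected (logical),
#'   qc_flag ("ok" or "extrapolated"); exactly one row per expected pulse.
#' @export
detect_peaks <- function(time_s, ratio, design, reference_times = NULL,
                         prominence_mads = 6, window_s = 12) {
  stopifnot(length(time_s) == length(ratio))
  dt <- diff(time_s)
  if (any(abs(dt - stats::median(dt)) > 0.01 * stats::median(dt))) {
    stop("detect_peaks: non-uniform sampling")
  }
  x <- design$n_pulses
  expected <- if (is.null(reference_times)) {
    design$onsets_s + design$rise_time_s
  } else reference_times
  stopifnot(length(expected) == x)
  # noise scale from the baseline-dominated lower half of the corrected
  # trace; the whole-trace MAD is inflated by the transients themselves
  lower <- ratio[ratio <= stats::median(ratio)]
  thr <- prominence_mads * max(stats::mad(lower, center = 0), 1e-12)
  step <- stats::median(dt)
  hw <- max(3L, as.integer(round(window_s / step)))
  prom <- .local_maxima(ratio, half_width = hw, thr = thr)
  if (length(prom) < 2) {
    stop("detect_peaks: fewer than 2 prominent peaks; template unanchorable")
  }
  prom_t <- time_s[prom]
  # assign each prominent peak to its nearest expected pulse
  near <- vapply(prom_t, function(tp) which.min(abs(expected - tp)),
                 integer(1))
  offset <- stats::median(prom_t - expected[near])
  projected <- expected + offset
  rec <- lapply(seq_len(x), function(p) {
    sel <- which(abs(time_s - projected[p]) <= window_s)
    if (length(sel) == 0) {
      stop("detect_peaks: projected pulse ", p, " outside the trace")
    }
    hit <- prom[near == p & abs(prom_t - projected[p]) <= window_s]
    if (length(hit) > 0) {
      i <- hit[which.max(ratio[hit])]
      data.frame(pulse_index = p, time_s = time_s[i], height = ratio[i],
                 detected = TRUE, qc_flag = "ok",
                 stringsAsFactors = FALSE)
    } else {
      # no independent detection: place the peak at the projected time and
      # read the height as the local maximum of the window around it
      data.frame(pulse_index = p, time_s = projected[p],
                 height = max(ratio[sel]),
                 detected = FALSE, qc_flag = "extrapolated",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rec)
}

#' Select the most representative trace of an experiment
#'
#' Automated surrogate for the manual choice of an alignment template:
#' among cells with at least half the expected pulses independently
#' detectable, returns the one maximizing the count of detected prominent
#' peaks, breaking ties by higher median peak height and then by lowest
#' cell id.
#'
#' @param traces data.frame time_s, cell_id, ratio (background-corrected).
#' @param design a \code{stimulus_design}.
#' @param ... passed to \code{detect_peaks}.
#' @return the selected cell_id.
#' @export
select_reference_trace <- function(traces, design, ...) {
  cells <- sort(unique(traces$cell_id))
  score <- lapply(cells, function(cl) {
    tr <- traces[traces$cell_id == cl, , drop = FALSE]
    pk <- tryCatch(detect_peaks(tr$time_s, tr$ratio, design, ...),
                   error = function(e) NULL)
    if (is.null(pk)) return(c(n = 0, med = -Inf))
    c(n = sum(pk$detected),
      med = stats::median(pk$height[pk$detected]))
  })
  n_det <- vapply(score, `[[`, numeric(1), "n")
  med_h <- vapply(score, `[[`, numeric(1), "med")
  ok <- n_det >= design$n_pulses / 2
  if (!any(ok)) {
    stop("select_reference_trace: no trace with >= ", design$n_pulses / 2,
         " independently detectable peaks; supply a reference cell manually")
  }
  ord <- order(-n_det, -med_h, cells)
  ord <- ord[ok[ord]]
  cells[ord[1]]
}

#' Flag artifact peaks and build the log-scale peak table
#'
#' Within each (cell, concentration) group of at least 3 peaks, entries
#' whose log height deviates from the group median by more than
#' \code{mad_threshold} times the group MAD are flagged
#' \code{artifact_removed} (the manual artifact-by-eye step, made
#' reproducible). Heights are converted to the natural log of the
#' baseline-subtracted peak height, floored at \code{floor_frac} of the
#' cell's maximum corrected amplitude so the log is always defined (such
#' entries keep the \code{extrapolated} flag).
#'
#' @param peaks data.frame with cell_id, concentration_nM, replicate,
#'   pulse_index, height, qc_flag.
#' @param mad_threshold outlier threshold in group MADs.
#' @param floor_frac height floor as a fraction of the cell's max height.
#' @return peak table: cell_id, concentration_nM, replicate, pulse_index,
#'   peak_log_response, qc_flag.
#' @export
remove_artifacts <- function(peaks, mad_threshold = 5, floor_frac = 1e-3) {
  stopifnot(all(c("cell_id", "concentration_nM", "replicate", "pulse_index",
                  "height") %in% names(peaks)))
  if (is.null(peaks$qc_flag)) peaks$qc_flag <- "ok"
  out <- lapply(split(peaks, peaks$cell_id), function(pc) {
    eps <- floor_frac * max(pc$height, na.rm = TRUE)
    if (!is.finite(eps) || eps <= 0) eps <- floor_frac
    floored <- pc$height < eps
    pc$peak_log_response <- log(pmax(pc$height, eps))
    pc$qc_flag[floored & pc$qc_flag == "ok"] <- "extrapolated"
    for (grp in split(seq_len(nrow(pc)), pc$concentration_nM)) {
      if (length(grp) < 3) next
      lr <- pc$peak_log_response[grp]
      dev <- abs(lr - stats::median(lr))
      cut <- mad_threshold * stats::mad(lr)
      if (cut > 0) {
        bad <- grp[dev > cut]
        pc$qc_flag[bad] <- "artifact_removed"
        if (length(bad) == length(grp)) {
          warning("remove_artifacts: all replicates removed for cell ",
                  pc$cell_id[1], " at ", pc$concentration_nM[grp[1]], " nM")
        }
      }
    }
    pc
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("cell_id", "concentration_nM", "replicate", "pulse_index",
          "peak_log_response", "qc_flag")]
}

#' Extract a peak table from a set of raw traces
#'
#' Full trace-processing stage: background removal per cell, automatic
#' reference-trace selection (unless given), template-aligned peak
#' detection, and artifact flagging with log conversion. Cells whose peaks
#' cannot be anchored are dropped with a warning.
#'
#' @param traces data.frame time_s, cell_id, ratio (raw).
#' @param design a \code{stimulus_design}.
#' @param reference_cell optional cell_id to use as the alignment template.
#' @param window_frames background window, frames.
#' @param mad_threshold artifact threshold.
#' @param ... passed to \code{detect_peaks}.
#' @return peak table as from \code{remove_artifacts}.
#' @export
extract_peak_table <- function(traces, design, reference_cell = NULL,
                               window_frames = 181, mad_threshold = 5, ...) {
  cells <- sort(unique(traces$cell_id))
  corr <- lapply(cells, function(cl) {
    tr <- traces[traces$cell_id == cl, , drop = FALSE]
    tr <- tr[order(tr$time_s), , drop = FALSE]
    tr$ratio <- remove_background(tr$ratio, window_frames)
    tr
  })
  corr_df <- do.call(rbind, corr)
  if (is.null(reference_cell)) {
    reference_cell <- select_reference_trace(corr_df, design, ...)
  }
  ref <- corr_df[corr_df$cell_id == reference_cell, , drop = FALSE]
  ref_pk <- detect_peaks(ref$time_s, ref$ratio, design, ...)
  ref_times <- ref_pk$time_s
  raw <- lapply(corr, function(tr) {
    cl <- tr$cell_id[1]
    pk <- tryCatch(
      detect_peaks(tr$time_s, tr$ratio, design, reference_times = ref_times,
                   ...),
      error = function(e) {
        warning("cell ", cl, " dropped: ", conditionMessage(e))
        NULL
      })
    if (is.null(pk)) return(NULL)
    data.frame(cell_id = cl,
               concentration_nM =
                 design$concentrations_nM[design$pulse_conc_index],
               replicate = design$pulse_replicate,
               pulse_index = pk$pulse_index,
               height = pk$height,
               qc_flag = pk$qc_flag,
               stringsAsFactors = FALSE)
  })
  raw <- raw[!vapply(raw, is.null, logical(1))]
  if (length(raw) == 0) stop("extract_peak_table: no cell could be processed")
  remove_artifacts(do.call(rbind, raw), mad_threshold = mad_threshold)
}
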