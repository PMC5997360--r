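# Period, peak time, phase and amplitude extraction.
#
# Phase convention: peak time relative to lights-on (t = 0 of the analysis
# window), multiplied by 2*pi and divided by the period; radians in
# [0, 2*pi).

#' Locate local maxima of a sampled profile with quadratic refinement
#'
#' Internal helper: local-maximum bracketing on a uniform grid followed by
#' a parabola through the three bracketing points.
#' @noRd
refine_peaks <- function(times, values) {
  n <- length(values)
  idx <- which(values[2:(n - 1)] > values[1:(n - 2)] &
                 values[2:(n - 1)] >= values[3:n]) + 1L
  if (!length(idx)) return(numeric(0))
  vapply(idx, function(i) {
    y1 <- values[i - 1]; y2 <- values[i]; y3 <- values[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    times[i] + delta * (times[2] - times[1])
  }, numeric(1))
}

#' Estimate the oscillation period of a trajectory
#'
#' Mean successive peak-to-peak interval over the analysis window, with
#' peaks located on the dense output and refined quadratically.
#'
#' @param traj `dde_traj`.
#' @param gene variable name or index (default: first variable).
#' @param dt sampling interval for peak bracketing (hours).
#' @return period in hours.
#' @export
estimate_period <- function(traj, gene = 1, dt = 0.05) {
  stopifnot(inherits(traj, "dde_traj"))
  times <- seq(traj$window_start, traj$t_end, by = dt)
  v <- dde_evaluate(traj, times)[, gene]
  peaks <- refine_peaks(times, v)
  if (length(peaks) < 2)
    stop("no sustained oscillation: fewer than 2 peaks in analysis window")
  mean(diff(peaks))
}

#' Estimate phase, peak time and amplitude
#'
#' For a trajectory, the first peak of the dense output after the analysis
#' window start; for replicate time-course data (a data frame with columns
#' `time_h`, `replicate`, `value`, optionally pre-filtered to one
#' gene/tissue), the peak of the replicate-mean profile with quadratic
#' interpolation across the three nearest time points (circular in the
#' cycle).
#'
#' @param x `dde_traj` or data.frame of one gene's replicate measurements.
#' @param gene variable name (trajectory input only).
#' @param period oscillation period in hours; defaults to
#'   [estimate_period()] for trajectories and 24 for data.
#' @param flat_eps amplitude below which the phase is declared undefined.
#' @return object of class `phase_estimate`: `gene`, `period`, `peak_time`
#'   (hours after lights-on, modulo period), `phase` (radians in
#'   `[0, 2*pi)`), `amplitude` (peak minus trough), `flag` (`"ok"` or
#'   `"undefined"`).
#' @export
estimate_phase <- function(x, gene = 1, period = NULL, flat_eps = 1e-3) {
  if (inherits(x, "dde_traj")) {
    if (is.null(period)) period <- estimate_period(x, gene)
    times <- seq(x$window_start, min(x$t_end, x$window_start + 2 * period),
                 by = 0.05)
    v <- dde_evaluate(x, times)[, gene]
    cyc <- times - x$window_start
    peaks <- refine_peaks(times, v)
    amp <- max(v[cyc <= period]) - min(v[cyc <= period])
    gene_lab <- if (is.character(gene)) gene else x$varnames[gene]
    if (amp < flat_eps || !length(peaks)) {
      warning("flat profile: phase undefined for ", gene_lab)
      return(new_phase_estimate(gene_lab, period, NA_real_, NA_real_, amp,
                                "undefined"))
    }
    peak_time <- (peaks[1] - x$window_start) %% period
  } else {
    df <- as.data.frame(x)
    need <- c("time_h", "replicate", "value")
    if (!all(need %in% names(df)))
      stop("data input needs columns: ", paste(need, collapse = ", "))
    if (is.null(period)) period <- 24
    prof <- tapply(df$value, df$time_h, mean)
    tt <- as.numeric(names(prof))
    vv <- as.numeric(prof)
    gene_lab <- if ("gene" %in% names(df)) as.character(df$gene[1]) else
      as.character(gene)
    amp <- max(vv) - min(vv)
    if (amp < flat_eps) {
      warning("flat profile: phase undefined for ", gene_lab)
      return(new_phase_estimate(gene_lab, period, NA_real_, NA_real_, amp,
                                "undefined"))
    }
    i <- which.max(vv)
    n <- length(vv)
    # three nearest points, circular in the cycle
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    tm <- tt[im]; tp <- tt[ip]
    if (i == 1) tm <- tm - period
    if (i == n) tp <- tp + period
    y1 <- vv[im]; y2 <- vv[i]; y3 <- vv[ip]
    # parabola through three (possibly unevenly spaced) points
    t1 <- tm - tt[i]; t3 <- tp - tt[i]
    denom <- t1 * t3 * (t1 - t3)
    a <- (t3 * (y1 - y2) - t1 * (y3 - y2)) / denom
    b <- (t1^2 * (y3 - y2) - t3^2 * (y1 - y2)) / denom
    delta <- if (a < 0) -b / (2 * a) else 0
    delta <- max(min(delta, max(t3, 0)), min(t1, 0))
    peak_time <- (tt[i] + delta) %% period
  }
  phase <- (2 * pi * peak_time / period) %% (2 * pi)
  new_phase_estimate(gene_lab, period, peak_time, phase, amp, "ok")
}

new_phase_estimate <- function(gene, period, peak_time, phase, amplitude,
                               flag) {
  structure(list(gene = gene, period = period, peak_time = peak_time,
                 phase = phase, amplitude = amplitude, flag = flag),
            class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat(sprintf(
    "phase estimate [%s]: period %.3g h, peak %.3g h, phase %.3g rad, amplitude %.3g (%s)\n",
    x$gene, x$period, x$peak_time, x$phase, x$amplitude, x$flag))
  invisible(x)
}

#' Circular phase difference
#'
#' Difference `a - b` wrapped to `(-pi, pi]`; exactly antiphase profiles
#' map to `+pi` (documented tie-break).  A positive value means `a` peaks
#' later in phase than `b` by less than half a cycle.
#'
#' @param phi_a,phi_b phases in radians (any real; reduced modulo 2*pi).
#' @return radians in `(-pi, pi]`.
#' @export
phase_difference <- function(phi_a, phi_b) {
  d <- (phi_a - phi_b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Tabulate phases of all variables of a trajectory
#'
#' @param traj `dde_traj`.
#' @param tissue optional tissue label for the report.
#' @return data.frame: gene, tissue, period_h, peak_time_h, phase_rad,
#'   amplitude.
#' @export
phase_report <- function(traj, tissue = traj$tissue) {
  rows <- lapply(traj$varnames, function(g) {
    pe <- estimate_phase(traj, g)
    data.frame(gene = g, tissue = if (is.null(tissue)) NA_character_ else
      tissue, period_h = pe$period, peak_time_h = pe$peak_time,
      phase_rad = pe$phase, amplitude = pe$amplitude,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
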