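# Harmonic stiffness of interface angles from equilibrium fluctuations:
# kappa = kB T / sigma^2, with sigma^2 the variance of the angle (radians)
# over the equilibrated window, pooled across runs.

#' Restrict an angle series to its equilibrated window
#'
#' Keeps the frames after a time cutoff. The analysis convention is to use
#' the second half of each run (a 500 ns cutoff for microsecond runs);
#' with `t_cut_ns = NULL` the cutoff is half the series time span, which
#' scales the same rule to shorter synthetic runs.
#'
#' @param series an `interface_angle_series` (any data.frame with a
#'   `time_ns` column).
#' @param t_cut_ns cutoff time, ns; frames with `time_ns > t_cut_ns` are
#'   kept. `NULL` = half the span; 0 returns the series unchanged.
#' @return the windowed series.
#' @export
equilibrated_window <- function(series, t_cut_ns = NULL) {
  if (nrow(series) == 0) stop("window error: empty series")
  if (is.null(t_cut_ns))
    t_cut_ns <- min(series$time_ns) + diff(range(series$time_ns)) / 2
  if (t_cut_ns > max(series$time_ns))
    stop("window error: cutoff ", t_cut_ns, " ns at or beyond the final frame")
  if (t_cut_ns <= min(series$time_ns) && t_cut_ns <= 0) return(series)
  out <- series[series$time_ns > t_cut_ns, , drop = FALSE]
  if (nrow(out) == 0) stop("window error: no frames after cutoff")
  out
}

#' Unwrap a circular angle series around its mean branch
#'
#' Shifts angles reported in (-180, 180] by +-360 degrees so a series
#' fluctuating across the branch cut becomes continuous; fluctuations are
#' assumed small relative to the full circle.
#'
#' @param angles_deg numeric vector of angles, degrees.
#' @return unwrapped angles, degrees.
#' @export
unwrap_angles <- function(angles_deg) {
  if (length(angles_deg) < 2) return(angles_deg)
  # circular mean as the branch center
  mu <- rad2deg(atan2(mean(sin(deg2rad(angles_deg))), mean(cos(deg2rad(angles_deg)))))
  d <- (angles_deg - mu + 180) %% 360 - 180
  mu + d
}

#' Pooled variance of angle series across runs
#'
#' Concatenates the (windowed) samples of one conformational angle over
#' runs and computes the variance about the pooled mean, in rad^2. The
#' standard error is a block bootstrap over runs.
#'
#' @param series_list list of numeric vectors (angles in degrees), one per
#'   run; a single vector is accepted.
#' @param n_boot bootstrap resamples for the SE (default 1000; 0 skips it).
#' @param seed RNG seed for the bootstrap.
#' @param per_run if TRUE, fluctuations are taken about each run's own
#'   mean before pooling (default FALSE: pooled mean).
#' @return list with `variance` (rad^2), `se` (rad^2, NA if `n_boot` = 0 or
#'   a single run), `n` (pooled sample size), `n_runs`.
#' @details The variance uses the 1/n (population / ensemble-average)
#'   normalization, so pooling a run with a copy of itself reproduces the
#'   single-run variance exactly.
#' @export
pooled_variance <- function(series_list, n_boot = 1000, seed = 1L,
                            per_run = FALSE) {
  if (is.numeric(series_list)) series_list <- list(series_list)
  runs <- lapply(series_list, function(x) deg2rad(unwrap_angles(as.numeric(x))))
  if (per_run) runs <- lapply(runs, function(x) x - mean(x))
  pop_var <- function(x) mean((x - mean(x))^2)
  pooled <- unlist(runs, use.names = FALSE)
  n <- length(pooled)
  if (n < 2) stop("pooled variance needs at least 2 samples")
  v <- pop_var(pooled)

  se <- NA_real_
  if (n_boot > 0 && length(runs) > 1) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vb <- vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(length(runs), length(runs), replace = TRUE)
      pop_var(unlist(runs[pick], use.names = FALSE))
    }, numeric(1))
    se <- stats::sd(vb)
  }
  list(variance = v, se = se, n = n, n_runs = length(runs))
}

#' Harmonic stiffness from an angular variance (equipartition)
#'
#' kappa = kB T / sigma^2. With sigma^2 in rad^2, kappa in thermal units
#' kBT/rad^2 is numerically 1/sigma^2; the Joule value kB T / sigma^2 is
#' also reported.
#'
#' @param sigma2 variance of the angle, rad^2 (> 0).
#' @param temperature_K temperature (default 300 K).
#' @param se_sigma2 optional standard error of `sigma2`; propagated to
#'   kappa by first-order error propagation.
#' @param label,kind optional interface label and angle kind ("bend" or
#'   "twist") carried into the report.
#' @return list of class `stiffness_report`: `kappa_kBT` (kBT/rad^2),
#'   `kappa_J` (J/rad^2), `kappa_se_kBT`, `sigma2`, `temperature_K`,
#'   `method` = "equipartition".
#' @export
harmonic_stiffness <- function(sigma2, temperature_K = 300, se_sigma2 = NA,
                               label = NULL, kind = NULL) {
  if (!is.finite(sigma2) || sigma2 < 0) stop("variance must be finite and >= 0")
  if (sigma2 == 0) stop("infinite stiffness: zero angular variance")
  kappa <- 1 / sigma2
  structure(list(label = label, kind = kind,
                 sigma2 = sigma2,
                 temperature_K = temperature_K,
                 kappa_kBT = kappa,
                 kappa_J = .kB * temperature_K / sigma2,
                 kappa_se_kBT = if (is.na(se_sigma2)) NA_real_ else se_sigma2 / sigma2^2,
                 method = "equipartition"),
            class = "stiffness_report")
}

#' @export
print.stiffness_report <- function(x, ...) {
  cat(sprintf("stiffness_report%s%s: kappa = %.4g kBT/rad^2 (sigma^2 = %.3g rad^2%s)\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              if (!is.null(x$kind)) paste0(" ", x$kind) else "",
              x$kappa_kBT, x$sigma2,
              if (is.na(x$kappa_se_kBT)) "" else sprintf(", se %.3g kBT/rad^2", x$kappa_se_kBT)))
  invisible(x)
}

#' Block convergence diagnostics for an angle series
#'
#' Splits the (already windowed) series into equal-duration blocks and
#' summarizes each: the standard stationarity check of splitting the
#' equilibrated window into four 125-ns-style segments. The drift statistic
#' is max |block mean - global mean| / pooled SD.
#'
#' @param angles_deg numeric vector of angles, degrees (one run, windowed).
#' @param n_blocks number of equal blocks (default 4).
#' @return list with `blocks` (data.frame: block, n, mean, var, q25,
#'   median, q75) and `drift_statistic`.
#' @export
convergence_report <- function(angles_deg, n_blocks = 4L) {
  x <- as.numeric(angles_deg)
  n <- length(x)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  edges <- floor(seq(0, n, length.out = n_blocks + 1))
  blk <- lapply(seq_len(n_blocks), function(b) x[(edges[b] + 1):edges[b + 1]])
  blocks <- data.frame(
    block = seq_len(n_blocks),
    n = vapply(blk, length, integer(1)),
    mean = vapply(blk, mean, numeric(1)),
    var = vapply(blk, stats::var, numeric(1)),
    q25 = vapply(blk, function(v) unname(stats::quantile(v, 0.25)), numeric(1)),
    median = vapply(blk, stats::median, numeric(1)),
    q75 = vapply(blk, function(v) unname(stats::quantile(v, 0.75)), numeric(1)))
  drift <- max(abs(blocks$mean - mean(x))) / stats::sd(x)
  list(blocks = blocks, drift_statistic = drift)
}
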