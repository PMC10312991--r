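# Four-parameter logistic dose-response fitting, the secondary-screen
# activity rule, and artifact flagging.

#' Four-parameter logistic function
#'
#' `bottom + (top - bottom) / (1 + (x/ec50)^hill)`: equals `top` at dose 0
#' and `bottom` at saturating dose when `hill > 0`.
#'
#' @param x dose (uM).
#' @param top,bottom,ec50,hill curve parameters.
#' @return response.
#' @export
fourpl <- function(x, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + (x / ec50)^hill)
}

#' Fit a 4PL dose-response curve
#'
#' Bounded least squares on log10 dose via L-BFGS-B over (top, bottom,
#' log10 EC50, hill), initialized from the data extremes and the half-range
#' crossing, with a small multistart over Hill slopes. EC50 is constrained
#' to [min_dose/10, max_dose*10]. A flat series (response range below
#' `flat_tol`) or an optimizer failure yields `converged = FALSE` with
#' diagnostics rather than an error.
#'
#' @param series data.frame with columns `dose_um` and the response column
#'   (a `dose_series` works directly).
#' @param response response column name (default `"ratio"`).
#' @param flat_tol minimal response range treated as a real curve.
#' @return list of class `fourpl_fit`: top, bottom, ec50, hill, rss,
#'   converged, n, response.
#' @export
fit_4pl <- function(series, response = "ratio", flat_tol = 1e-8) {
  x <- series$dose_um; y <- series[[response]]
  ok <- is.finite(x) & is.finite(y) & x > 0
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4)
    stop_tgn("tgn_config_error", "4PL fit needs >= 4 distinct doses")
  dm <- sort(unique(x))
  ymean <- vapply(dm, function(d) mean(y[x == d]), numeric(1))
  out <- list(top = NA_real_, bottom = NA_real_, ec50 = NA_real_,
              hill = NA_real_, rss = NA_real_, converged = FALSE,
              n = length(y), response = response)
  class(out) <- "fourpl_fit"
  if (diff(range(ymean)) < flat_tol) {
    out$top <- out$bottom <- mean(y)
    out$rss <- sum((y - mean(y))^2)
    return(out)
  }
  lo_e <- log10(min(dm) / 10); hi_e <- log10(max(dm) * 10)
  top0 <- mean(ymean[seq_len(min(2, length(ymean)))])
  bot0 <- mean(ymean[(length(ymean) - min(1, length(ymean) - 1)):length(ymean)])
  # half-range crossing as the EC50 guess
  half <- (top0 + bot0) / 2
  cross <- which(diff(sign(ymean - half)) != 0)
  e0 <- if (length(cross)) log10(sqrt(dm[cross[1]] * dm[cross[1] + 1]))
        else mean(c(lo_e, hi_e))
  e0 <- min(max(e0, lo_e), hi_e)
  obj <- function(p) {
    pred <- p[2] + (p[1] - p[2]) / (1 + 10^(p[4] * (log10(x) - p[3])))
    sum((y - pred)^2)
  }
  span <- diff(range(y)) + 1e-12
  lower <- c(min(y) - 2 * span, min(y) - 2 * span, lo_e, -10)
  upper <- c(max(y) + 2 * span, max(y) + 2 * span, hi_e, 10)
  best <- NULL
  for (h0 in c(1, 1.5, 0.5, 3)) {
    fit <- tryCatch(
      stats::optim(c(top0, bot0, e0, h0), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(out)
  p <- best$par
  out$top <- p[1]; out$bottom <- p[2]; out$ec50 <- 10^p[3]; out$hill <- p[4]
  out$rss <- best$value
  out$converged <- best$convergence == 0 &&
    abs(p[1] - p[2]) > max(flat_tol, 1e-6 * span) &&
    p[3] > lo_e + 1e-6 && p[3] < hi_e - 1e-6
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> top %.4g bottom %.4g EC50 %.4g uM hill %.3g (rss %.3g, %s)\n",
    x$top, x$bottom, x$ec50, x$hill, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Secondary-screen activity call
#'
#' Active if and only if there are at least `min_doses` doses at which BOTH
#' replicates reduce the metric by at least |z_threshold| SD and the dose is
#' not toxicity-flagged.
#'
#' @param series data.frame with columns `dose_um`, `replicate`, `z_ratio`,
#'   and logical `toxic` (per row; a dose is toxic when any replicate is).
#' @param z_threshold activity threshold on the z-score (default -3).
#' @param min_doses minimum number of qualifying doses (default 2).
#' @return list: active (logical), supporting_doses (uM vector).
#' @export
call_secondary_active <- function(series, z_threshold = -3, min_doses = 2) {
  reps <- table(series$dose_um)
  if (any(reps != 2))
    stop_tgn("tgn_config_error",
             "secondary activity rule expects exactly 2 replicates per dose")
  doses <- sort(unique(series$dose_um))
  tox <- if ("toxic" %in% names(series)) series$toxic else FALSE
  qual <- vapply(doses, function(d) {
    rows <- series$dose_um == d
    all(series$z_ratio[rows] <= z_threshold) && !any(tox[rows] %in% TRUE)
  }, logical(1))
  list(active = sum(qual) >= min_doses, supporting_doses = doses[qual])
}

#' Flag autofluorescence / imaging-artifact compounds
#'
#' A compound is flagged when its cargo-channel background, z-scored against
#' the vehicle-well background distribution, exceeds `z_max` at two or more
#' doses, or when background increases monotonically with dose (Spearman
#' rho > `rho_max`).
#'
#' @param series data.frame with columns `dose_um` and `background` for one
#'   compound (replicates averaged per dose internally).
#' @param vehicle_bg background intensities of vehicle/control wells (>= 2).
#' @param z_max,rho_max rule thresholds.
#' @return list: flagged (logical), n_high_doses, spearman_rho.
#' @export
flag_artifact_wells <- function(series, vehicle_bg, z_max = 3,
                                rho_max = 0.9) {
  stopifnot(length(vehicle_bg) >= 2)
  doses <- sort(unique(series$dose_um))
  bg <- vapply(doses, function(d) mean(series$background[series$dose_um == d]),
               numeric(1))
  z <- (bg - mean(vehicle_bg)) / stats::sd(vehicle_bg)
  rho <- if (length(doses) >= 3) stats::cor(doses, bg, method = "spearman")
         else 0
  n_high <- sum(z > z_max)
  list(flagged = n_high >= 2 || (is.finite(rho) && rho > rho_max),
       n_high_doses = n_high, spearman_rho = rho)
}

#' Summarize EC50s over converged fits
#'
#' Median and IQR (type-7 linear-interpolation quartiles) of the converged
#' EC50s; non-converged fits are listed separately.
#'
#' @param fits list of `fourpl_fit` objects (optionally named by compound).
#' @return list: median_um, iqr_um, n_converged, table (data.frame with
#'   compound, ec50, converged).
#' @export
ec50_summary <- function(fits) {
  nm <- names(fits) %||% as.character(seq_along(fits))
  tab <- data.frame(
    compound = nm,
    ec50 = vapply(fits, function(f) f$ec50, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  ec <- tab$ec50[tab$converged]
  if (!length(ec))
    stop_tgn("tgn_empty_summary", "no converged fits to summarize")
  q <- stats::quantile(ec, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median_um = q[2], iqr_um = q[3] - q[1], n_converged = length(ec),
       table = tab)
}
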