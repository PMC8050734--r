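#' Wrap hours into [0, tau)
#'
#' @param x numeric hours.
#' @param tau period length in hours.
#' @return `x` reduced modulo `tau` into `[0, tau)`.
#' @keywords internal
wrap_hours <- function(x, tau = 24) {
  ((x %% tau) + tau) %% tau
}

#' Wrap an hour difference into (-tau/2, tau/2]
#'
#' Antiphase differences (exactly tau/2 apart) are reported as +tau/2.
#'
#' @inheritParams wrap_hours
#' @keywords internal
wrap_signed <- function(x, tau = 24) {
  w <- wrap_hours(x, tau)
  ifelse(w > tau / 2, w - tau, w)
}

#' Single-condition cosinor fit
#'
#' Least-squares fit of \eqn{y = M + \beta_1 \cos(\omega t) + \beta_2
#' \sin(\omega t)} with \eqn{\omega = 2\pi/\tau}. Amplitude is
#' \eqn{A = \sqrt{\beta_1^2 + \beta_2^2}} and the acrophase (time of fitted
#' peak) is \eqn{\phi = \mathrm{atan2}(\beta_2, \beta_1)/\omega} wrapped into
#' `[0, tau)`. The p-value is the F-test of \eqn{\beta_1 = \beta_2 = 0}.
#'
#' Pairs with missing `y` are dropped; at least 3 distinct timepoints must
#' remain. A constant series returns amplitude 0 and p = 1.
#'
#' @param y numeric abundances (replicates as independent observations).
#' @param t zeitgeber times in hours, same length as `y`.
#' @param tau period in hours (> 0).
#' @return One-row data frame with columns `mesor`, `amplitude`, `acrophase`,
#'   `tau`, `p_value`, `n_used`, plus internal columns `beta_cos`, `beta_sin`,
#'   `rss`, `sst`.
#' @export
#' @examples
#' t <- rep(c(2, 6, 10, 14, 18, 22), each = 4)
#' y <- 10 + 2 * cos(2 * pi * (t - 6) / 24)
#' fit_cosinor(y, t, tau = 24)
fit_cosinor <- function(y, t, tau = 24) {
  stopifnot(length(y) == length(t))
  if (!is.finite(tau) || tau <= 0) stop("tau must be a positive number")
  keep <- is.finite(y)
  y <- y[keep]
  t <- t[keep]
  if (length(unique(t)) < 3) {
    stop("fewer than 3 distinct timepoints with non-missing values")
  }
  n <- length(y)
  w <- 2 * pi / tau
  X <- cbind(1, cos(w * t), sin(w * t))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    return(data.frame(
      mesor = y[1], amplitude = 0, acrophase = 0, tau = tau,
      p_value = 1, n_used = n, beta_cos = 0, beta_sin = 0,
      rss = 0, sst = 0
    ))
  }
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  A <- sqrt(b[2]^2 + b[3]^2)
  phi <- wrap_hours(atan2(b[3], b[2]) / w, tau)
  df2 <- n - 3
  if (df2 <= 0) stop("not enough observations for the cosinor F-test")
  p <- if (rss <= sst * 1e-14) {
    0
  } else {
    stats::pf(((sst - rss) / 2) / (rss / df2), 2, df2, lower.tail = FALSE)
  }
  data.frame(
    mesor = unname(b[1]), amplitude = unname(A), acrophase = unname(phi),
    tau = tau, p_value = unname(p), n_used = n,
    beta_cos = unname(b[2]), beta_sin = unname(b[3]), rss = rss, sst = sst
  )
}

#' Free-running period scan
#'
#' Fits a cosinor at every period on a grid (default 20-28 h in 0.1-h steps,
#' the usual scan for constant-light designs) and returns the fit at the
#' residual-sum-of-squares minimum. Because the period is selected over the
#' grid, the reported `p_value` is Bonferroni-corrected by the grid size and
#' the row carries `grid_selected = TRUE`; the uncorrected single-period
#' p-value is kept in `p_single`. The scan p-value is therefore never smaller
#' than the p-value of a fit at a prespecified period.
#'
#' @inheritParams fit_cosinor
#' @param tau_range length-2 numeric, period scan bounds in hours.
#' @param step grid resolution in hours.
#' @return One-row data frame as [fit_cosinor()] plus `p_single`,
#'   `n_grid`, `grid_selected`.
#' @export
scan_period <- function(y, t, tau_range = c(20, 28), step = 0.1) {
  stopifnot(length(tau_range) == 2, tau_range[1] <= tau_range[2], step > 0)
  span <- diff(range(t)) + modal_spacing(t)
  if (tau_range[1] <= 0 || tau_range[2] > 2 * span) {
    stop("tau_range must lie within (0, 2 * sampling span]")
  }
  grid <- seq(tau_range[1], tau_range[2], by = step)
  if (length(grid) == 0) stop("empty period grid")
  fits <- lapply(grid, function(tau) fit_cosinor(y, t, tau))
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  best <- fits[[which.min(rss)]]
  best$p_single <- best$p_value
  best$p_value <- min(1, best$p_value * length(grid))
  best$n_grid <- length(grid)
  best$grid_selected <- TRUE
  best
}

#' Modal spacing between consecutive distinct timepoints
#' @keywords internal
modal_spacing <- function(t) {
  ts <- sort(unique(t))
  if (length(ts) < 2) return(0)
  d <- diff(ts)
  as.numeric(names(sort(table(d), decreasing = TRUE))[1])
}
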