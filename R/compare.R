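#' Compare rhythm parameters between two conditions for one feature
#'
#' Joint nonlinear least-squares fit of
#' \deqn{y = (M_A + \Delta M x) + (A_A + \Delta A x)
#'   \cos(2\pi (t - \phi_A - \Delta\phi x)/\tau)}
#' with condition indicator \eqn{x} (0 for A, 1 for B), in the style of
#' CircaCompare. Wald tests on \eqn{\Delta M}, \eqn{\Delta A} and
#' \eqn{\Delta\phi} come from the asymptotic covariance of the fit. The fit
#' is initialized at the exact optimum implied by the two per-condition
#' linear cosinor fits (the joint objective separates by condition), so
#' convergence is immediate in regular cases; on failure up to
#' `max_restarts` deterministic phase-jittered restarts are tried and an
#' unconverged row is flagged (`converged = FALSE`), never dropped.
#'
#' The phase difference is reported wrapped into \eqn{(-\tau/2, \tau/2]};
#' exact antiphase is reported as \eqn{+\tau/2}. All differences are
#' condition B minus condition A. When the joint fit has (numerically) zero
#' residual variance, Wald standard errors vanish; a zero estimate is then
#' assigned p = 1 and a nonzero one p = 0.
#'
#' @param y_a,y_b abundances in condition A and B.
#' @param t_a,t_b zeitgeber times matching `y_a`, `y_b` (if `t_b` is missing,
#'   `t_a` is recycled for both).
#' @param tau shared period in hours.
#' @param max_restarts restarts with jittered initial phase difference.
#' @return One-row data frame: per-condition `mesor/amplitude/acrophase`,
#'   differences `d_mesor`, `d_amplitude`, `d_phase` with standard errors and
#'   Wald p-values, `tau`, `n`, `converged`.
#' @export
compare_rhythms <- function(y_a, y_b, t_a, t_b = NULL, tau = 24,
                            max_restarts = 5) {
  if (is.null(t_b)) t_b <- t_a
  stopifnot(length(y_a) == length(t_a), length(y_b) == length(t_b))
  fa <- fit_cosinor(y_a, t_a, tau)
  fb <- fit_cosinor(y_b, t_b, tau)
  dat <- data.frame(
    y = c(y_a, y_b), t = c(t_a, t_b),
    x = rep(c(0, 1), c(length(y_a), length(y_b)))
  )
  dat <- dat[is.finite(dat$y), ]
  n <- nrow(dat)
  dphi0 <- wrap_signed(fb$acrophase - fa$acrophase, tau)
  start0 <- list(
    MA = fa$mesor, dM = fb$mesor - fa$mesor,
    AA = fa$amplitude, dA = fb$amplitude - fa$amplitude,
    phiA = fa$acrophase, dphi = dphi0
  )
  jitters <- c(0, 2, -2, 4, -4, 6)[seq_len(max_restarts + 1)]
  fit <- NULL
  for (jt in jitters) {
    st <- start0
    st$dphi <- dphi0 + jt
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ (MA + dM * x) + (AA + dA * x) *
          cos(2 * pi * (t - phiA - dphi * x) / tau),
        data = dat, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  out <- data.frame(
    mesor_a = fa$mesor, mesor_b = fb$mesor,
    amplitude_a = fa$amplitude, amplitude_b = fb$amplitude,
    acrophase_a = fa$acrophase, acrophase_b = fb$acrophase,
    d_mesor = fb$mesor - fa$mesor,
    d_amplitude = fb$amplitude - fa$amplitude,
    d_phase = dphi0,
    se_mesor = NA_real_, se_amplitude = NA_real_, se_phase = NA_real_,
    p_mesor = NA_real_, p_amplitude = NA_real_, p_phase = NA_real_,
    tau = tau, n = n, converged = FALSE, method = "none",
    stringsAsFactors = FALSE
  )
  sm <- if (!is.null(fit)) tryCatch(summary(fit), error = function(e) NULL)
  if (is.null(sm)) {
    ## the joint objective separates by condition, so the two linear cosinor
    ## fits are the exact optimum; Wald errors come from the delta method on
    ## their coefficients with a pooled residual variance (identical to the
    ## asymptotic covariance of the joint fit). Used when the nls wrapper
    ## cannot build its model object (e.g. exactly duplicated series).
    lin <- .compare_wald_linear(y_a, y_b, t_a, t_b, tau, fa, fb)
    if (is.null(lin)) {
      return(out)
    }
    out[names(lin)] <- lin
    out$converged <- TRUE
    out$method <- "linear_delta"
    return(out)
  }
  cf <- sm$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  dfres <- n - 6
  wald_p <- function(e, s) {
    if (!is.finite(s) || s < 1e-10 * max(1, abs(e))) {
      return(if (abs(e) < 1e-8) 1 else 0)
    }
    2 * stats::pt(abs(e / s), df = dfres, lower.tail = FALSE)
  }
  out$d_mesor <- est["dM"]
  out$d_amplitude <- est["dA"]
  out$d_phase <- wrap_signed(est["dphi"], tau)
  out$se_mesor <- se["dM"]
  out$se_amplitude <- se["dA"]
  out$se_phase <- se["dphi"]
  out$p_mesor <- wald_p(est["dM"], se["dM"])
  out$p_amplitude <- wald_p(est["dA"], se["dA"])
  out$p_phase <- wald_p(est["dphi"], se["dphi"])
  out$converged <- TRUE
  out$method <- "nls"
  rownames(out) <- NULL
  out
}

## Exact Wald statistics for the joint two-condition cosinor from the two
## per-condition linear fits (delta method, pooled residual variance).
.compare_wald_linear <- function(y_a, y_b, t_a, t_b, tau, fa, fb) {
  w <- 2 * pi / tau
  block <- function(y, t) {
    keep <- is.finite(y)
    y <- y[keep]
    t <- t[keep]
    X <- cbind(1, cos(w * t), sin(w * t))
    XtXi <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (is.null(XtXi)) return(NULL)
    b <- drop(XtXi %*% crossprod(X, y))
    rss <- sum((y - drop(X %*% b))^2)
    list(b = b, XtXi = XtXi, rss = rss, n = length(y))
  }
  ba <- block(y_a, t_a)
  bb <- block(y_b, t_b)
  if (is.null(ba) || is.null(bb)) return(NULL)
  dfres <- ba$n + bb$n - 6
  if (dfres <= 0) return(NULL)
  s2 <- (ba$rss + bb$rss) / dfres
  stats_for <- function(bl) {
    b <- bl$b
    V <- s2 * bl$XtXi
    A2 <- b[2]^2 + b[3]^2
    A <- sqrt(A2)
    gA <- if (A > 0) c(0, b[2] / A, b[3] / A) else c(0, 1, 0)
    gP <- if (A2 > 0) c(0, -b[3] / A2, b[2] / A2) * tau / (2 * pi) else c(0, 0, 0)
    list(
      var_M = V[1, 1],
      var_A = drop(t(gA) %*% V %*% gA),
      var_P = drop(t(gP) %*% V %*% gP)
    )
  }
  sa <- stats_for(ba)
  sb <- stats_for(bb)
  wald <- function(est, se) {
    if (!is.finite(se) || se < 1e-10 * max(1, abs(est))) {
      return(if (abs(est) < 1e-8) 1 else 0)
    }
    2 * stats::pt(abs(est / se), df = dfres, lower.tail = FALSE)
  }
  dM <- fb$mesor - fa$mesor
  dA <- fb$amplitude - fa$amplitude
  dP <- wrap_signed(fb$acrophase - fa$acrophase, tau)
  seM <- sqrt(sa$var_M + sb$var_M)
  seA <- sqrt(sa$var_A + sb$var_A)
  seP <- sqrt(sa$var_P + sb$var_P)
  list(
    d_mesor = dM, d_amplitude = dA, d_phase = dP,
    se_mesor = seM, se_amplitude = seA, se_phase = seP,
    p_mesor = wald(dM, seM), p_amplitude = wald(dA, seA),
    p_phase = wald(dP, seP)
  )
}

#' Batch two-condition rhythm comparison
#'
#' Runs [compare_rhythms()] on every requested feature of a matrix.
#'
#' @param mat feature x sample matrix with rownames.
#' @param design sample design table matching the matrix columns.
#' @param condition_a,condition_b condition labels (differences are B - A).
#' @param features feature ids (default: all rows).
#' @param tau shared period in hours.
#' @return data frame with one row per feature (`feature_id` first column).
#' @export
compare_rhythms_batch <- function(mat, design, condition_a, condition_b,
                                  features = rownames(mat), tau = 24) {
  stopifnot(
    condition_a %in% design$condition,
    condition_b %in% design$condition
  )
  sa <- design$condition == condition_a
  sb <- design$condition == condition_b
  rows <- lapply(features, function(f) {
    r <- compare_rhythms(mat[f, sa], mat[f, sb],
      design$zt[sa], design$zt[sb],
      tau = tau
    )
    cbind(feature_id = f, r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pointwise two-sample t-tests per timepoint with Bonferroni correction
#'
#' Welch two-sample t-test comparing the two conditions at each timepoint of
#' each feature. The multiple-testing family is the set of timepoints within
#' a feature: with m timepoints, a timepoint is flagged significant when
#' p < alpha / m. Timepoints with fewer than 2 replicates in either group are
#' flagged untestable.
#'
#' @param mat_a,mat_b feature x sample matrices (same features, one
#'   condition each).
#' @param zt_a,zt_b zeitgeber times of the columns; the two grids must agree.
#' @param alpha familywise error level.
#' @return long data frame: `feature_id`, `zt`, group means, `t_stat`, `df`,
#'   `p_value`, `p_threshold` (= alpha/m), `significant`, `untestable`.
#' @export
pointwise_tests <- function(mat_a, mat_b, zt_a, zt_b, alpha = 0.05) {
  stopifnot(
    ncol(mat_a) == length(zt_a), ncol(mat_b) == length(zt_b),
    identical(rownames(mat_a), rownames(mat_b))
  )
  grid <- sort(unique(zt_a))
  if (!identical(grid, sort(unique(zt_b)))) {
    stop("the two conditions must share the same timepoint grid")
  }
  m <- length(grid)
  thr <- alpha / m
  res <- lapply(grid, function(z) {
    A <- mat_a[, zt_a == z, drop = FALSE]
    B <- mat_b[, zt_b == z, drop = FALSE]
    na <- rowSums(is.finite(A))
    nb <- rowSums(is.finite(B))
    ma <- rowMeans(A, na.rm = TRUE)
    mb <- rowMeans(B, na.rm = TRUE)
    va <- apply(A, 1, stats::var, na.rm = TRUE)
    vb <- apply(B, 1, stats::var, na.rm = TRUE)
    sa2 <- va / na
    sb2 <- vb / nb
    tt <- (mb - ma) / sqrt(sa2 + sb2)
    df <- (sa2 + sb2)^2 / (sa2^2 / (na - 1) + sb2^2 / (nb - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    unt <- na < 2 | nb < 2
    p[unt] <- NA
    tt[unt] <- NA
    df[unt] <- NA
    data.frame(
      feature_id = rownames(mat_a), zt = z,
      mean_a = ma, mean_b = mb, t_stat = tt, df = df, p_value = p,
      p_threshold = thr, significant = !is.na(p) & p < thr,
      untestable = unt, stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, res)
  out[order(out$feature_id, out$zt), ]
}

#' Z-scored timepoint-mean profiles for heatmaps
#'
#' Per feature and condition, replicate abundances are averaged per timepoint
#' and the resulting 24-h mean profile is standardized to mean 0 and sd 1
#' ("Z score of the mean"). Constant profiles are returned as all zeros with
#' `constant = TRUE`. The z-profile is invariant to positive affine
#' transformations of the input.
#'
#' @param mat feature x sample matrix with rownames.
#' @param design sample design table matching the columns.
#' @param conditions conditions to include (default: all in the design).
#' @return long data frame: `feature_id`, `condition`, `zt`, `mean_value`,
#'   `z`, `constant`.
#' @export
zscore_profiles <- function(mat, design, conditions = unique(design$condition)) {
  out <- lapply(conditions, function(cond) {
    sel <- design$condition == cond
    zt <- sort(unique(design$zt[sel]))
    if (length(zt) < 2) stop("need at least 2 timepoints per condition")
    mm <- vapply(zt, function(z) {
      rowMeans(mat[, sel & design$zt == z, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(mat)))
    mm <- matrix(mm, nrow = nrow(mat))
    mu <- rowMeans(mm)
    sd <- apply(mm, 1, stats::sd)
    const <- sd == 0 | !is.finite(sd)
    Z <- (mm - mu) / ifelse(const, 1, sd)
    Z[const, ] <- 0
    data.frame(
      feature_id = rep(rownames(mat), times = length(zt)),
      condition = cond,
      zt = rep(zt, each = nrow(mat)),
      mean_value = as.vector(mm),
      z = as.vector(Z),
      constant = rep(const, times = length(zt)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
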