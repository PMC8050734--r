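#' Kuiper test for circular uniformity or a circular two-sample difference
#'
#' The Kuiper statistic \eqn{V = D^+ + D^-} is the rotation-invariant
#' circular analogue of Kolmogorov-Smirnov. Against the uniform reference the
#' p-value uses the asymptotic Kuiper series with Stephens' finite-sample
#' modification; against a background sample the two-sample V is computed on
#' the pooled empirical CDFs and the p-value comes from seeded label
#' permutations.
#'
#' @param angles numeric radians (at least 3).
#' @param background optional numeric radians; if supplied, a two-sample
#'   test of `angles` vs `background` is run by permutation.
#' @param n_perm permutations for the two-sample test (>= 100).
#' @param seed integer seed for the permutation test.
#' @return list: `statistic` (V), `p_value`, `n`, `method`.
#' @export
kuiper_test <- function(angles, background = NULL, n_perm = 10000,
                        seed = 1) {
  if (length(angles) < 3) stop("need at least 3 angles")
  if (is.null(background)) {
    u <- sort((angles %% (2 * pi)) / (2 * pi))
    n <- length(u)
    i <- seq_len(n)
    V <- max(i / n - u) + max(u - (i - 1) / n)
    lam <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
    j <- 1:100
    p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
    p <- min(1, max(0, p))
    return(list(statistic = V, p_value = p, n = n, method = "uniform"))
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  V <- .kuiper_two(angles, background)
  pool <- c(angles, background)
  k <- length(angles)
  b <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(r) {
      idx <- sample.int(length(pool), k)
      .kuiper_two(pool[idx], pool[-idx]) >= V
    }, logical(1)))
  })
  list(
    statistic = V, p_value = (b + 1) / (n_perm + 1),
    n = length(angles), method = "two_sample_permutation"
  )
}

## Two-sample Kuiper V on the pooled sample (ties aggregated).
.kuiper_two <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v <- c(x %% (2 * pi), y %% (2 * pi))
  e <- c(rep(1 / n1, n1), rep(-1 / n2, n2))
  o <- order(v)
  v <- v[o]
  cum <- cumsum(e[o])
  ## at tied pooled values only the last cumulative value is a valid CDF diff
  last <- c(v[-1] != v[-length(v)], TRUE)
  d <- cum[last]
  max(c(0, d)) - min(c(0, d))
}

#' Convert phase-shift hours to angles in radians
#' @keywords internal
.shift_to_angle <- function(shift, period = 24) {
  2 * pi * shift / period
}

#' Circular mean direction in hours
#' @keywords internal
.circular_mean_hours <- function(angles, period = 24) {
  wrap_hours(atan2(mean(sin(angles)), mean(cos(angles))) * period / (2 * pi),
    period
  )
}

#' Mean resultant length of a set of angles
#' @keywords internal
.resultant_length <- function(angles) {
  sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
}

#' Phase set enrichment analysis on circular phase shifts
#'
#' For each gene set (intersected with the shift universe and kept if at
#' least `min_size` members remain), tests whether the members' phase-shift
#' angles are distributed differently from the background of all non-member
#' shifts, using the two-sample Kuiper statistic with a seeded permutation
#' p-value. The set's "magnitude" — its temporal cohesiveness — is the
#' circular mean resultant length R of the member angles (1 when all member
#' shifts coincide, near 0 when they are spread uniformly), and the circular
#' mean shift locates the set on the 0-24 h circle. BH q-values are computed
#' across all tested sets.
#'
#' Shifts (hours) are mapped to angles by \eqn{\theta = 2\pi \cdot
#' \mathrm{shift} / \mathrm{period}}. With `reference = "uniform"` the
#' one-sample Kuiper test against the uniform circle is used instead of the
#' non-member background.
#'
#' @param records data frame with `feature_id` and the shift column.
#' @param gene_sets a [read_gmt()] collection (named list with `members`).
#' @param min_size minimum members after intersection with the universe.
#' @param n_perm permutations (>= 100) for the background reference.
#' @param seed integer seed.
#' @param shift_col column of `records` holding shifts in hours.
#' @param period hours per full turn of the shift circle.
#' @param reference `"background"` (non-members, default) or `"uniform"`.
#' @return data frame: `set_name`, `n_members_used`, `kuiper_V`, `magnitude`,
#'   `circular_mean_shift`, `p_value`, `q_value`.
#' @export
psea <- function(records, gene_sets, min_size = 5, n_perm = 10000, seed = 1,
                 shift_col = "folded_shift", period = 24,
                 reference = c("background", "uniform")) {
  reference <- match.arg(reference)
  if (is.null(records) || nrow(records) == 0) stop("empty shift universe")
  if (n_perm < 100) stop("n_perm must be at least 100")
  shifts <- stats::setNames(records[[shift_col]], records$feature_id)
  members_of <- lapply(gene_sets, function(s) {
    intersect(s$members, names(shifts))
  })
  keep <- vapply(members_of, length, integer(1)) >= min_size
  rows <- lapply(which(keep), function(k) {
    mem <- members_of[[k]]
    th <- .shift_to_angle(shifts[mem], period)
    bg <- .shift_to_angle(shifts[setdiff(names(shifts), mem)], period)
    kt <- if (reference == "background" && length(bg) >= 3) {
      kuiper_test(th, background = bg, n_perm = n_perm, seed = seed + k)
    } else {
      kuiper_test(th)
    }
    data.frame(
      set_name = names(gene_sets)[k],
      n_members_used = length(mem),
      kuiper_V = kt$statistic,
      magnitude = .resultant_length(th),
      circular_mean_shift = .circular_mean_hours(th, period),
      p_value = kt$p_value,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    return(data.frame(
      set_name = character(), n_members_used = integer(),
      kuiper_V = numeric(), magnitude = numeric(),
      circular_mean_shift = numeric(), p_value = numeric(),
      q_value = numeric(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Gene-set overrepresentation by the one-sided Fisher exact test
#'
#' For each target set, forms the 2x2 table of the query against the set
#' within the universe and computes the one-sided (greater) Fisher exact
#' p-value via the hypergeometric tail, the sample odds ratio (zero cells
#' give 0 or Inf unless `haldane = TRUE`, which adds 0.5 to every cell), and
#' BH q-values across sets.
#'
#' @param query character vector of feature ids; must be a subset of
#'   `universe`.
#' @param target_sets a [read_gmt()] collection (named list with `members`).
#' @param universe character vector of feature ids.
#' @param haldane use the Haldane-Anscombe 0.5 correction for the odds ratio.
#' @return data frame: `set_name`, `overlap_k`, `set_size_K`, `query_size_n`,
#'   `universe_size_N`, `odds_ratio`, `p_value`, `q_value`.
#' @export
overrepresentation <- function(query, target_sets, universe,
                               haldane = FALSE) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop(
      "query features absent from the universe: ",
      paste(utils::head(setdiff(query, universe), 5), collapse = ", ")
    )
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(target_sets), function(nm) {
    set <- intersect(target_sets[[nm]]$members, universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k
    b <- K - k
    cc <- n - k
    d <- N - K - n + k
    or <- if (haldane) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else if (a == 0) {
      0
    } else if (b == 0 || cc == 0) {
      Inf
    } else {
      (a * d) / (b * cc)
    }
    data.frame(
      set_name = nm, overlap_k = k, set_size_K = K, query_size_n = n,
      universe_size_N = N, odds_ratio = or, p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
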