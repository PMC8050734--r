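#' Fold a signed phase shift onto the 0 to tau/2 window
#'
#' Because rhythms are circular, a phase advance of d hours is the same
#' displacement as a phase delay of tau - d hours; the folded shift is the
#' absolute circular distance, \eqn{\min(m, \tau - m)} with
#' \eqn{m = |d| \bmod \tau}. For tau = 24 a shift of +14 h folds to 10 h
#' (24 - 14 = 10) and the folded window is 0-12 h.
#'
#' @param delta signed phase shift(s) in hours (finite; NA passes through).
#' @param tau period in hours (> 0).
#' @return folded shift(s) in `[0, tau/2]`.
#' @export
#' @examples
#' fold_phase_shift(14) # 10
#' fold_phase_shift(c(0, 12, -14, 20, 26)) # 0 12 10 4 2
fold_phase_shift <- function(delta, tau = 24) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop("tau must be a single positive number")
  }
  if (any(is.infinite(delta))) stop("delta must be finite")
  m <- abs(delta) %% tau
  pmin(m, tau - m)
}

#' Classify a folded phase shift into an entrainment class
#'
#' Bins follow the resolution of a 4-h sampling grid: folded shifts in
#' [0, 4] h are phase-locked, (4, 8) h intermediate, and [8, 12] h
#' phase-inverted. The boundary values 4 and 8 belong to the closed outer
#' bins, matching the printed interval notation "0-4 h" and "8-12 h".
#'
#' @param folded folded shift(s) in hours, within `[0, 12]`.
#' @return character vector in
#'   `c("phase_locked", "intermediate", "phase_inverted")`.
#' @export
classify_shift <- function(folded) {
  bad <- !is.na(folded) & (folded < 0 | folded > 12)
  if (any(bad)) {
    stop("folded shift outside [0, 12]: ", paste(folded[bad], collapse = ", "))
  }
  ifelse(is.na(folded), NA_character_,
    ifelse(folded <= 4, "phase_locked",
      ifelse(folded >= 8, "phase_inverted", "intermediate")
    )
  )
}

#' Dual-oscillating features and per-condition sets
#'
#' Features rhythmic (BH q below the threshold) in both conditions define
#' the universe for phase-shift analysis; the single-condition sets are also
#' returned for Venn-style summaries.
#'
#' @param fits_a,fits_b [detect_rhythms()] tables over the same feature
#'   universe.
#' @param q_threshold BH q-value threshold.
#' @return list with `dual`, `a_only`, `b_only` (feature id vectors),
#'   `rhythmic_a`, `rhythmic_b`, and `n_universe`.
#' @export
dual_oscillating <- function(fits_a, fits_b, q_threshold = 0.05) {
  if (!setequal(fits_a$feature_id, fits_b$feature_id)) {
    stop("the two fit tables cover different feature universes")
  }
  ra <- fits_a$feature_id[!is.na(fits_a$q_value) & fits_a$q_value < q_threshold]
  rb <- fits_b$feature_id[!is.na(fits_b$q_value) & fits_b$q_value < q_threshold]
  list(
    dual = intersect(ra, rb),
    a_only = setdiff(ra, rb),
    b_only = setdiff(rb, ra),
    rhythmic_a = ra, rhythmic_b = rb,
    n_universe = length(unique(fits_a$feature_id))
  )
}

#' Build phase-shift records for dual-oscillating features
#'
#' The signed shift (condition B minus A, hours, wrapped into (-12, 12]) is
#' taken from the converged joint fit when available, else from the
#' difference of the per-condition cosinor acrophases; the provenance is
#' recorded per feature. Folding and classification follow
#' [fold_phase_shift()] and [classify_shift()].
#'
#' @param comparisons [compare_rhythms_batch()] table.
#' @param dual feature ids to include (the dual-oscillating set).
#' @param tau period in hours.
#' @return data frame: `feature_id`, `signed_shift`, `folded_shift`,
#'   `entrainment_class`, `shift_source`.
#' @export
phase_shift_records <- function(comparisons, dual = comparisons$feature_id,
                                tau = 24) {
  cmp <- comparisons[comparisons$feature_id %in% dual, , drop = FALSE]
  from_fit <- cmp$converged
  signed <- ifelse(from_fit, cmp$d_phase,
    wrap_signed(cmp$acrophase_b - cmp$acrophase_a, tau)
  )
  folded <- fold_phase_shift(signed, tau)
  data.frame(
    feature_id = cmp$feature_id,
    signed_shift = signed,
    folded_shift = folded,
    entrainment_class = classify_shift(folded),
    shift_source = ifelse(from_fit, "joint_fit", "acrophase_diff"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Summarize entrainment classes and the folded-shift histogram
#'
#' @param records [phase_shift_records()] table.
#' @return list of class `entrainment_summary`: `n_dual`, per-class `counts`
#'   and `percentages` (2 decimals), and `histogram` (1-h bins `[0,1)` ...
#'   `[11,12]`, the last bin closed). An empty record set returns the
#'   explicit empty sentinel (`n_dual = 0`, `empty = TRUE`).
#' @export
entrainment_summary <- function(records) {
  classes <- c("phase_locked", "intermediate", "phase_inverted")
  if (is.null(records) || nrow(records) == 0) {
    return(structure(
      list(
        n_dual = 0L, empty = TRUE,
        counts = stats::setNames(rep(0L, 3), classes),
        percentages = stats::setNames(rep(NA_real_, 3), classes),
        histogram = data.frame(
          bin_lo = 0:11, bin_hi = 1:12, count = rep(0L, 12)
        )
      ),
      class = "entrainment_summary"
    ))
  }
  cls <- factor(records$entrainment_class, levels = classes)
  counts <- table(cls)
  n <- nrow(records)
  bin <- pmin(floor(records$folded_shift), 11) # last bin [11, 12] closed
  hist <- data.frame(
    bin_lo = 0:11, bin_hi = 1:12,
    count = as.integer(tabulate(bin + 1, nbins = 12))
  )
  structure(
    list(
      n_dual = n, empty = FALSE,
      counts = stats::setNames(as.integer(counts), classes),
      percentages = stats::setNames(
        round(100 * as.integer(counts) / n, 2), classes
      ),
      histogram = hist
    ),
    class = "entrainment_summary"
  )
}

#' @export
print.entrainment_summary <- function(x, ...) {
  if (x$empty) {
    cat("Entrainment summary: no dual-oscillating features\n")
    return(invisible(x))
  }
  cat("Entrainment summary over", x$n_dual, "dual-oscillating features\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-15s %6d (%6.2f%%)\n", k, x$counts[[k]], x$percentages[[k]]))
  }
  invisible(x)
}

#' Integrate phase-shifted gene sets across datasets
#'
#' For each named dataset (feature id -> folded shift among its
#' dual-oscillating features), takes the set with folded shift strictly
#' greater than `threshold` hours (default 4 h, the relaxed criterion for
#' calling a transcript phase-shifted), reports its fraction of the
#' dual-oscillating features as the dataset's degree of phase entrainment,
#' and tabulates pairwise overlaps between the phase-shifted sets.
#'
#' @param shift_tables named list; each element either a data frame with
#'   columns `feature_id` and `folded_shift` or a named numeric vector of
#'   folded shifts.
#' @param threshold strict lower bound in hours for calling a shift.
#' @return list: `per_dataset` (data frame with `dataset`, `n_dual`,
#'   `n_shifted`, `pct_shifted`), `shifted_sets`, `overlap_counts` (matrix),
#'   `overlap_fraction` (overlap / row dataset's shifted-set size).
#' @export
cross_dataset_integration <- function(shift_tables, threshold = 4) {
  nm <- names(shift_tables)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("shift_tables must have unique non-empty names")
  }
  sets <- lapply(shift_tables, function(tb) {
    if (is.data.frame(tb)) {
      stats::setNames(tb$folded_shift, tb$feature_id)
    } else {
      tb
    }
  })
  shifted <- lapply(sets, function(s) names(s)[s > threshold])
  per <- data.frame(
    dataset = nm,
    n_dual = vapply(sets, length, integer(1)),
    n_shifted = vapply(shifted, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per$pct_shifted <- round(100 * per$n_shifted / per$n_dual, 2)
  k <- length(nm)
  oc <- matrix(0L, k, k, dimnames = list(nm, nm))
  of <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ov <- length(intersect(shifted[[i]], shifted[[j]]))
      oc[i, j] <- ov
      of[i, j] <- if (length(shifted[[i]]) > 0) ov / length(shifted[[i]]) else NA
    }
  }
  list(
    per_dataset = per, shifted_sets = shifted,
    overlap_counts = oc, overlap_fraction = of
  )
}

#' Condition-licensed 12-h oscillators
#'
#' Features rhythmic at tau = 12 h (BH q below threshold) in exactly one
#' condition — oscillations "licensed" by that feeding regimen.
#'
#' @param fits12_a,fits12_b [detect_ultradian()] tables over the same
#'   feature universe.
#' @param q_threshold BH q-value threshold.
#' @return named list of feature id vectors, one per licensing condition,
#'   plus `both` (rhythmic in both, excluded from the licensed sets).
#' @export
licensed_oscillators <- function(fits12_a, fits12_b, q_threshold = 0.05) {
  if (!setequal(fits12_a$feature_id, fits12_b$feature_id)) {
    stop("the two fit tables cover different feature universes")
  }
  ra <- fits12_a$feature_id[
    !is.na(fits12_a$q_value) & fits12_a$q_value < q_threshold
  ]
  rb <- fits12_b$feature_id[
    !is.na(fits12_b$q_value) & fits12_b$q_value < q_threshold
  ]
  ca <- unique(fits12_a$condition)[1]
  cb <- unique(fits12_b$condition)[1]
  out <- list(setdiff(ra, rb), setdiff(rb, ra), intersect(ra, rb))
  names(out) <- c(ca, cb, "both")
  out
}

#' End-to-end entrainment pipeline on one dataset
#'
#' Convenience wrapper running detection in both conditions, the dual-
#' oscillating intersection, the per-feature joint comparison, phase-shift
#' folding/classification, and the class summary.
#'
#' @param mat feature x sample matrix.
#' @param design matching sample design table.
#' @param condition_a,condition_b condition labels (shifts are B - A).
#' @param tau period in hours.
#' @param q_threshold BH q threshold for rhythmicity.
#' @return list: `fits_a`, `fits_b`, `dual`, `comparisons`, `records`,
#'   `summary`.
#' @export
entrainment_pipeline <- function(mat, design, condition_a, condition_b,
                                 tau = 24, q_threshold = 0.05) {
  fits_a <- detect_rhythms(mat, design, condition_a, tau = tau,
    q_threshold = q_threshold
  )
  fits_b <- detect_rhythms(mat, design, condition_b, tau = tau,
    q_threshold = q_threshold
  )
  dual <- dual_oscillating(fits_a, fits_b, q_threshold)
  comparisons <- if (length(dual$dual) > 0) {
    compare_rhythms_batch(mat, design, condition_a, condition_b,
      features = dual$dual, tau = tau
    )
  } else {
    NULL
  }
  records <- if (!is.null(comparisons)) {
    phase_shift_records(comparisons, tau = tau)
  } else {
    NULL
  }
  list(
    fits_a = fits_a, fits_b = fits_b, dual = dual,
    comparisons = comparisons, records = records,
    summary = entrainment_summary(records)
  )
}
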