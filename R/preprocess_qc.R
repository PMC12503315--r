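#' Baseline (offset) correction
#'
#' Shifts a trace by the mean of its pre-stimulus baseline so that the
#' average pre-stimulus level is zero: the mean of the last 40 (scotopic) or
#' 20 (photopic) pre-stimulus samples is subtracted from every sample.
#' Idempotent.
#'
#' @param x An `erg_trace` or `erg_cohort`.
#' @param ... Unused.
#' @return The corrected object, same class as `x`.
#' @export
baseline_correct <- function(x, ...) UseMethod("baseline_correct")

# shared worker on a raw sample vector
.correct_samples <- function(samples, n_pre_avail, condition) {
  n_pre <- .baseline_n[[condition]]
  if (n_pre_avail < n_pre)
    stop("insufficient pre-stimulus samples for ", condition,
         " baseline correction (", n_pre_avail, " < ", n_pre, ")", call. = FALSE)
  idx <- (n_pre_avail - n_pre + 1L):n_pre_avail
  samples - mean(samples[idx])
}

#' @rdname baseline_correct
#' @export
baseline_correct.erg_trace <- function(x, ...) {
  x$samples <- .correct_samples(x$samples, x$n_pre, x$condition)
  x
}

#' @rdname baseline_correct
#' @export
baseline_correct.erg_cohort <- function(x, ...) {
  tr <- copy(x$traces)
  n_pre <- round(tr$t0_offset_s * tr$sample_rate_hz)
  tr[, samples := Map(.correct_samples, samples, n_pre, condition)]
  x$traces <- tr
  x
}

#' Inter-trial consistency (MAD) score
#'
#' At each time point the mean absolute deviation of the trial voltages about
#' their cross-trial mean is computed; the score is the sum over all time
#' points (units: uV times samples). Identical trials score 0; inconsistent,
#' artifact-laden recordings score high. Order-invariant.
#'
#' @param trials A list of two or more baseline-corrected `erg_trace` objects
#'   (same mouse/eye/condition), or plain numeric vectors of equal length.
#' @return Numeric scalar score (>= 0).
#' @export
trial_mad_score <- function(trials) {
  vecs <- lapply(trials, function(t) if (inherits(t, "erg_trace")) t$samples else t)
  if (length(vecs) < 2) stop("at least 2 trials are required", call. = FALSE)
  len <- lengths(vecs)
  if (length(unique(len)) != 1)
    stop("alignment error: trials have unequal lengths", call. = FALSE)
  m <- do.call(rbind, vecs)
  sum(colMeans(abs(sweep(m, 2, colMeans(m)))))
}

#' MAD consistency QC over a cohort
#'
#' Computes a [trial_mad_score()] per (mouse, eye, condition); the cutoff for
#' each condition is the empirical `quantile` (default upper 1%) of all that
#' condition's scores, pooled across eyes. A mouse is flagged for a condition
#' if either eye's score exceeds the cutoff; its data for that condition are
#' excluded downstream (the other condition is unaffected).
#'
#' @param cohort A baseline-corrected `erg_cohort`.
#' @param quantile Empirical quantile used as cutoff (default 0.99).
#' @return List with `scores` (mouse_id, eye, condition, score, cutoff,
#'   flagged), `cutoffs`, and `flags` (mouse_id, stage = "mad", condition,
#'   detail).
#' @export
mad_qc <- function(cohort, quantile = 0.99) {
  stopifnot(inherits(cohort, "erg_cohort"), quantile > 0, quantile < 1)
  scores <- cohort$traces[, .(score = trial_mad_score(samples)),
                          by = .(mouse_id, eye, condition)]
  for (cond in unique(scores$condition)) {
    n <- sum(scores$condition == cond)
    if (n < 100)
      warning("fewer than 100 MAD scores for ", cond,
              " (", n, "): quantile cutoff is unstable", call. = FALSE)
  }
  cutoffs <- scores[, .(cutoff = stats::quantile(score, quantile, names = FALSE)),
                    by = condition]
  scores <- cutoffs[scores, on = "condition"]
  scores[, flagged := score > cutoff]
  flags <- scores[flagged == TRUE,
                  .(detail = sprintf("MAD score %.3g > cutoff %.3g (%s eye)",
                                     max(score), cutoff[1],
                                     paste(eye, collapse = "/"))),
                  by = .(mouse_id, condition)]
  flags <- flags[, .(mouse_id, stage = "mad", condition, detail)]
  list(scores = scores[, .(mouse_id, eye, condition, score, cutoff, flagged)],
       cutoffs = cutoffs, flags = flags)
}

#' Average repeated trials into one waveform
#'
#' Pointwise arithmetic mean of two or more (or identity on one)
#' baseline-corrected, QC-passing trials.
#'
#' @param trials Non-empty list of `erg_trace` objects of equal length.
#' @return An `erg_trace` with `trial = NA` and a `trial_count` field.
#' @export
average_trials <- function(trials) {
  if (length(trials) == 0) stop("empty trial list", call. = FALSE)
  stopifnot(all(vapply(trials, inherits, TRUE, "erg_trace")))
  len <- lengths(lapply(trials, `[[`, "samples"))
  if (length(unique(len)) != 1)
    stop("alignment error: trials have unequal lengths", call. = FALSE)
  avg <- trials[[1]]
  avg$samples <- colMeans(do.call(rbind, lapply(trials, `[[`, "samples")))
  avg$trial <- NA_integer_
  avg$trial_count <- length(trials)
  avg
}

#' Wildtype-referenced extreme-value QC
#'
#' For each parameter and eye, limits are the wildtype control mean plus or
#' minus `sd_mult` wildtype standard deviations (n-1 denominator). The limits
#' are applied to the entire dataset (wildtype and mutant alike); any mouse
#' with a value outside the closed interval is flagged for that condition.
#' Limits depend only on wildtype values, so mutant data never move them.
#'
#' @param amplitudes Long amplitude table: `mouse_id`, `eye`, `condition`,
#'   `parameter`, `amplitude_uV`.
#' @param sessions Session table (for `strain_id`).
#' @param sd_mult SD multiplier (default 3).
#' @param control_strain Wildtype sentinel strain id.
#' @return List with `flags` (mouse_id, stage = "extreme", condition, detail)
#'   and `limits` (condition, parameter, eye, lower, upper).
#' @export
extreme_value_qc <- function(amplitudes, sessions, sd_mult = 3,
                             control_strain = "C57BL/6NJ") {
  amplitudes <- as.data.table(amplitudes)
  sessions <- as.data.table(sessions)
  wt_ids <- sessions[strain_id == control_strain, mouse_id]
  wt <- amplitudes[mouse_id %in% wt_ids & is.finite(amplitude_uV)]
  if (nrow(wt) == 0)
    stop("configuration error: no wildtype values to form limits", call. = FALSE)
  limits <- wt[, {
    if (.N < 2)
      stop("configuration error: fewer than 2 wildtype values for ",
           condition[1], " ", parameter[1], " (", eye[1], " eye)", call. = FALSE)
    .(lower = mean(amplitude_uV) - sd_mult * sd(amplitude_uV),
      upper = mean(amplitude_uV) + sd_mult * sd(amplitude_uV))
  }, by = .(condition, parameter, eye)]
  merged <- limits[amplitudes, on = c("condition", "parameter", "eye")]
  out <- merged[is.finite(amplitude_uV) & !is.na(lower) &
                  (amplitude_uV < lower | amplitude_uV > upper)]
  flags <- out[, .(detail = paste(sprintf("%s %s (%s eye) = %.3g outside [%.3g, %.3g]",
                                          condition, parameter, eye,
                                          amplitude_uV, lower, upper),
                                  collapse = "; ")),
               by = .(mouse_id, condition)]
  flags <- flags[, .(mouse_id, stage = "extreme", condition, detail)]
  list(flags = flags, limits = limits)
}

#' Strain sample-size gate
#'
#' Counts QC-passing mice per strain and condition (sexes combined) and
#' reports which strains reach the inclusion threshold (default n >= 5).
#'
#' @param sessions Session table.
#' @param qc_flags Combined QC flag table (`mouse_id`, `condition`); flagged
#'   (mouse, condition) pairs do not count for that condition. Flags with
#'   `condition = NA` (metadata issues) exclude the mouse from both conditions.
#' @param amplitudes Optional amplitude table; if supplied, only mice with at
#'   least one extracted amplitude in a condition count for it.
#' @param min_n Minimum passing mice per strain and condition (default 5).
#' @param control_strain Wildtype sentinel; excluded from the gate listing.
#' @return data.table: `strain_id`, `condition`, `n_pass`, `eligible`.
#' @export
sample_size_gate <- function(sessions, qc_flags = NULL, amplitudes = NULL,
                             min_n = 5, control_strain = "C57BL/6NJ") {
  sessions <- as.data.table(sessions)
  strains <- setdiff(unique(sessions$strain_id), control_strain)
  grid <- CJ(strain_id = strains, condition = .erg_conditions)
  count_one <- function(st, cond) {
    ids <- sessions[strain_id == st, unique(mouse_id)]
    if (!is.null(amplitudes)) {
      amp <- as.data.table(amplitudes)
      ids <- intersect(ids, amp[condition == cond & is.finite(amplitude_uV),
                                unique(mouse_id)])
    }
    if (!is.null(qc_flags) && nrow(qc_flags)) {
      fl <- as.data.table(qc_flags)
      bad <- fl[is.na(condition) | condition == cond, unique(mouse_id)]
      ids <- setdiff(ids, bad)
    }
    length(ids)
  }
  grid[, n_pass := mapply(count_one, strain_id, condition)]
  grid[, eligible := n_pass >= min_n]
  grid[]
}
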