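#' Construct a single ERG trace
#'
#' An `erg_trace` holds one uniformly sampled voltage series for one
#' mouse/eye/condition/trial, in microvolts, with the stimulus at t = 0.
#' Samples recorded before the stimulus (the pre-stimulus baseline) are the
#' first `round(t0_offset * sample_rate)` samples.
#'
#' @param mouse_id Opaque mouse identifier.
#' @param eye `"L"` or `"R"`.
#' @param condition `"scotopic"` or `"photopic"`.
#' @param trial Trial index (integer >= 1), or `NA` for an averaged trace.
#' @param samples Numeric vector of voltages in microvolts.
#' @param sample_rate Sampling rate in Hz (default 2000).
#' @param t0_offset Seconds of pre-stimulus recording included (default 0.02 s
#'   scotopic, 0.01 s photopic).
#' @return An object of class `erg_trace`.
#' @export
erg_trace <- function(mouse_id, eye, condition, trial, samples,
                      sample_rate = 2000,
                      t0_offset = if (condition == "scotopic") 0.02 else 0.01) {
  condition <- match.arg(condition, .erg_conditions)
  eye <- match.arg(eye, c("L", "R"))
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  n_pre <- round(t0_offset * sample_rate)
  if (length(samples) <= .baseline_n[[condition]])
    stop("sample count must exceed the pre-stimulus baseline count (",
         .baseline_n[[condition]], ") for ", condition, " traces",
         call. = FALSE)
  structure(
    list(mouse_id = as.character(mouse_id), eye = eye, condition = condition,
         trial = trial, sample_rate = sample_rate, t0_offset = t0_offset,
         samples = as.numeric(samples), n_pre = as.integer(n_pre)),
    class = "erg_trace")
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf("<erg_trace> %s %s eye, %s, trial %s: %d samples @ %g Hz (%.0f ms pre-stimulus)\n",
              x$mouse_id, x$eye, x$condition, format(x$trial),
              length(x$samples), x$sample_rate, x$t0_offset * 1000))
  invisible(x)
}

#' Sample times of a trace in milliseconds post-stimulus
#'
#' @param trace An `erg_trace`.
#' @return Numeric vector, same length as `trace$samples`; the first
#'   post-stimulus sample has time 0.
#' @export
trace_times_ms <- function(trace) {
  (seq_along(trace$samples) - 1L - trace$n_pre) * 1000 / trace$sample_rate
}

#' Construct an ERG cohort
#'
#' A cohort bundles a session (metadata) table and a trace table with
#' referential keys. Construction checks column presence and value domains;
#' use [validate_cohort()] for the per-mouse QC report and [read_cohort()]
#' for strict integrity checks on ingest.
#'
#' @param sessions data.frame with columns `mouse_id`, `strain_id`, `zygosity`
#'   (`homozygous`/`heterozygous`/`wildtype`), `sex` (`M`/`F`), `test_date`
#'   (Date or ISO-8601 string), `batch_id`.
#' @param traces data.frame with columns `mouse_id`, `eye` (`L`/`R`),
#'   `condition`, `trial`, `sample_rate_hz`, `t0_offset_s` and a list column
#'   `samples` of numeric vectors (microvolts).
#' @param provenance Free-text provenance string.
#' @return An object of class `erg_cohort`.
#' @export
erg_cohort <- function(sessions, traces, provenance = "") {
  sessions <- as.data.table(sessions)
  traces <- as.data.table(traces)
  req_s <- c("mouse_id", "strain_id", "zygosity", "sex", "test_date", "batch_id")
  req_t <- c("mouse_id", "eye", "condition", "trial", "sample_rate_hz",
             "t0_offset_s", "samples")
  miss <- setdiff(req_s, names(sessions))
  if (length(miss)) stop("session table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(req_t, names(traces))
  if (length(miss)) stop("trace table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sessions[, mouse_id := as.character(mouse_id)]
  sessions[, test_date := as.Date(test_date)]
  traces[, mouse_id := as.character(mouse_id)]
  structure(list(sessions = sessions[], traces = traces[],
                 provenance = provenance),
            class = "erg_cohort")
}

#' @export
print.erg_cohort <- function(x, ...) {
  cat(sprintf("<erg_cohort> %d mice (%d strains), %d traces\n",
              nrow(x$sessions), length(unique(x$sessions$strain_id)),
              nrow(x$traces)))
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# one trace row -> erg_trace object
.row_trace <- function(tr, i) {
  erg_trace(tr$mouse_id[i], tr$eye[i], tr$condition[i], tr$trial[i],
            tr$samples[[i]], tr$sample_rate_hz[i], tr$t0_offset_s[i])
}

#' Read a cohort from delimited trace and session tables
#'
#' The canonical storage dialect is a long-format delimited table, one row per
#' trace, with the voltage series packed into a single `samples` column as
#' `;`-separated decimal microvolts. See [write_cohort()] for the writer.
#'
#' @param trace_path,session_path Paths to the trace and session tables.
#' @param dialect Storage dialect; only `"csv"` is implemented.
#' @return An `erg_cohort`.
#' @export
read_cohort <- function(trace_path, session_path, dialect = "csv") {
  dialect <- match.arg(dialect, "csv")
  if (!file.exists(trace_path)) stop("trace file not found: ", trace_path, call. = FALSE)
  if (!file.exists(session_path)) stop("session file not found: ", session_path, call. = FALSE)
  sessions <- fread(session_path, colClasses = list(character = "mouse_id"))
  traces <- fread(trace_path, colClasses = list(character = c("mouse_id", "samples")))
  req_t <- c("mouse_id", "eye", "condition", "trial", "sample_rate_hz",
             "t0_offset_s", "samples")
  miss <- setdiff(req_t, names(traces))
  if (length(miss)) stop("trace file missing required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  req_s <- c("mouse_id", "strain_id", "zygosity", "sex", "test_date", "batch_id")
  miss <- setdiff(req_s, names(sessions))
  if (length(miss)) stop("session file missing required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  traces[, samples := lapply(samples, function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))]
  unknown <- setdiff(traces$mouse_id, sessions$mouse_id)
  if (length(unknown))
    stop("integrity error: trace(s) reference unknown mouse id(s): ",
         paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)
  if (any(!is.finite(traces$sample_rate_hz)) || any(traces$sample_rate_hz <= 0))
    stop("sampling error: non-positive sample rate", call. = FALSE)
  rate_by_cond <- traces[, uniqueN(sample_rate_hz), by = condition]
  if (any(rate_by_cond$V1 > 1))
    stop("sampling error: non-uniform sample rate within condition ",
         paste(rate_by_cond[V1 > 1, condition], collapse = ", "), call. = FALSE)
  cohort <- erg_cohort(sessions, traces,
                       provenance = paste0("read_cohort:", basename(trace_path)))
  dup <- cohort$traces[, .N, by = .(mouse_id, eye, condition, trial)][N > 1L]
  if (nrow(dup))
    stop("integrity error: duplicate (mouse, eye, condition, trial) keys for ",
         paste(unique(dup$mouse_id), collapse = ", "), call. = FALSE)
  cohort
}

#' Write a cohort to delimited trace and session tables
#'
#' Samples are serialized at fixed 1e-6 microvolt precision so that
#' `read_cohort(write_cohort(x))` round-trips within that tolerance.
#'
#' @param cohort An `erg_cohort`.
#' @param trace_path,session_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, trace_path, session_path) {
  stopifnot(inherits(cohort, "erg_cohort"))
  for (p in c(trace_path, session_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) stop("I/O error: directory does not exist: ", d, call. = FALSE)
  }
  out <- copy(cohort$traces)
  out[, samples := vapply(samples, function(s)
    paste(formatC(s, format = "f", digits = 6), collapse = ";"), character(1))]
  fwrite(out, trace_path)
  fwrite(cohort$sessions, session_path)
  invisible(c(trace_path, session_path))
}

#' Validate a cohort and report per-mouse issues
#'
#' Report-only mirror of the screen's first (generic) QC step: mice with
#' unresolved metadata issues, incomplete trial sets, or sampling violations
#' are listed so downstream stages can exclude them. The cohort itself is
#' never modified.
#'
#' @param cohort An `erg_cohort`.
#' @return data.table with columns `mouse_id`, `stage` (always `"metadata"`),
#'   `condition` (or `NA` for cohort-level issues), `detail`. Zero rows for a
#'   clean cohort.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "erg_cohort"))
  issues <- list()
  add <- function(mouse, cond, detail)
    data.table(mouse_id = mouse, stage = "metadata",
               condition = if (is.null(cond)) NA_character_ else cond,
               detail = detail)

  dup <- cohort$sessions[, .N, by = mouse_id][N > 1L, mouse_id]
  if (length(dup)) issues <- c(issues, list(add(dup, NULL, "duplicate id")))

  bad_sex <- cohort$sessions[!sex %in% c("M", "F"), mouse_id]
  if (length(bad_sex)) issues <- c(issues, list(add(bad_sex, NULL, "invalid sex")))
  bad_zyg <- cohort$sessions[!zygosity %in% c("homozygous", "heterozygous", "wildtype"),
                             mouse_id]
  if (length(bad_zyg)) issues <- c(issues, list(add(bad_zyg, NULL, "invalid zygosity")))
  bad_date <- cohort$sessions[is.na(test_date), mouse_id]
  if (length(bad_date)) issues <- c(issues, list(add(bad_date, NULL, "missing test date")))

  unknown <- setdiff(cohort$traces$mouse_id, cohort$sessions$mouse_id)
  if (length(unknown))
    issues <- c(issues, list(add(unknown, NULL, "trace without session")))

  tr <- cohort$traces
  if (nrow(tr)) {
    counts <- tr[, .(n_trials = .N), by = .(mouse_id, eye, condition)]
    counts[, n_expected := .expected_trials[condition]]
    inc <- counts[n_trials != n_expected]
    if (nrow(inc))
      issues <- c(issues, list(inc[, .(mouse_id, stage = "metadata", condition,
                                       detail = sprintf("incomplete trials (%s eye: %d of %d)",
                                                        eye, n_trials, n_expected))]))
    # sampling violations: rate, finiteness, pre-stimulus depth, epoch span
    for (i in seq_len(nrow(tr))) {
      cond <- tr$condition[i]
      s <- tr$samples[[i]]
      rate <- tr$sample_rate_hz[i]
      n_pre <- round(tr$t0_offset_s[i] * rate)
      bad <- NULL
      if (!is.finite(rate) || rate <= 0) bad <- "non-positive sample rate"
      else if (any(!is.finite(s))) bad <- "non-finite samples"
      else if (n_pre < .baseline_n[[cond]])
        bad <- sprintf("insufficient pre-stimulus samples (%d < %d)",
                       n_pre, .baseline_n[[cond]])
      else {
        span <- (length(s) - 1 - n_pre) * 1000 / rate
        if (span < .epoch_ms[[cond]][2])
          bad <- sprintf("epoch too short (%.0f < %.0f ms)", span, .epoch_ms[[cond]][2])
      }
      if (!is.null(bad))
        issues <- c(issues, list(add(tr$mouse_id[i], cond, paste0("sampling: ", bad))))
    }
  }
  if (!length(issues))
    return(data.table(mouse_id = character(), stage = character(),
                      condition = character(), detail = character()))
  unique(rbindlist(issues, use.names = TRUE))
}
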