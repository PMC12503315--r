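#' Component measurement windows
#'
#' Closed search intervals, in milliseconds post-stimulus, within which each
#' ERG component's landmark is sought on the averaged waveform. The defaults
#' are consistent with standard mouse ERG timing and the display epochs used
#' for this protocol (a/b within ~200 ms; c and FO-like within the 5 s
#' scotopic epoch; photopic response within ~100 ms). The FO-like window
#' starts dynamically at the c-wave peak time, so only its end is configured.
#'
#' @param scotopic,photopic Named lists of `c(start_ms, end_ms)` intervals
#'   overriding the defaults (components `a`, `b`, `c`, `fo` for scotopic;
#'   `a`, `b` for photopic).
#' @return Object of class `component_windows`.
#' @export
component_windows <- function(scotopic = list(), photopic = list()) {
  w <- list(
    scotopic = list(a = c(3, 60), b = c(15, 250), c = c(400, 3500),
                    fo = c(NA, 5000)),
    photopic = list(a = c(3, 30), b = c(15, 100)))
  w$scotopic <- modifyList(w$scotopic, scotopic)
  w$photopic <- modifyList(w$photopic, photopic)
  for (cond in names(w)) for (comp in names(w[[cond]])) {
    iv <- w[[cond]][[comp]]
    if (length(iv) != 2 || (!is.na(iv[1]) && iv[1] >= iv[2]))
      stop("invalid window for ", cond, " ", comp, call. = FALSE)
  }
  if (w$scotopic$a[2] > w$scotopic$b[2] || w$scotopic$c[1] <= w$scotopic$b[1])
    stop("scotopic windows must be ordered a before b, b before c", call. = FALSE)
  structure(w, class = "component_windows")
}

# earliest-tie argmin/argmax on a closed index set
.arg_extreme <- function(s, idx, find_max) {
  v <- s[idx]
  idx[if (find_max) which.max(v) else which.min(v)]
}

#' Extract ERG component amplitudes from an averaged waveform
#'
#' Measurement conventions (baseline is 0 after [baseline_correct()]):
#' * a-wave: baseline to the most negative trough in the a-window, reported
#'   as a non-negative magnitude (0 if the trace never goes negative there);
#' * b-wave: a-wave trough to the highest peak in the b-window at times
#'   strictly after the trough;
#' * scotopic c-wave: baseline to the highest peak in the c-window after the
#'   b-wave peak;
#' * scotopic FO-like wave: c-wave peak down to the deepest trough between
#'   the c-peak and the end of the epoch, as a non-negative magnitude.
#'
#' Extrema are located on the raw averaged samples (no extra smoothing; the
#' acquisition bandpass already limits noise), ties broken to the earliest
#' time point. A component whose search window is empty after the landmark
#' ordering constraints is recorded as missing (`NA`) rather than an error.
#'
#' @param avg_trace A baseline-corrected, averaged `erg_trace`.
#' @param windows A [component_windows()] object.
#' @return Object of class `component_amplitudes`: list with `amplitude_uV`
#'   and `landmark_ms`, both named by component, plus `condition`, `mouse_id`,
#'   `eye`.
#' @export
extract_components <- function(avg_trace, windows = component_windows()) {
  stopifnot(inherits(avg_trace, "erg_trace"),
            inherits(windows, "component_windows"))
  cond <- avg_trace$condition
  s <- avg_trace$samples
  t_ms <- trace_times_ms(avg_trace)
  w <- windows[[cond]]
  comps <- .components[[cond]]
  amp <- setNames(rep(NA_real_, length(comps)), comps)
  lmk <- setNames(rep(NA_real_, length(comps)), comps)

  in_win <- function(lo, hi, after = -Inf) which(t_ms >= lo & t_ms <= hi & t_ms > after)

  ia <- in_win(w$a[1], w$a[2])
  if (length(ia)) {
    i <- .arg_extreme(s, ia, find_max = FALSE)
    lmk["a"] <- t_ms[i]
    amp["a"] <- max(0, -s[i])
    trough_val <- s[i]
    ib <- in_win(w$b[1], w$b[2], after = lmk["a"])
    if (length(ib)) {
      j <- .arg_extreme(s, ib, find_max = TRUE)
      lmk["b"] <- t_ms[j]
      amp["b"] <- s[j] - trough_val
    }
  }
  if (cond == "scotopic" && is.finite(lmk["b"])) {
    ic <- in_win(w$c[1], w$c[2], after = lmk["b"])
    if (length(ic)) {
      k <- .arg_extreme(s, ic, find_max = TRUE)
      lmk["c"] <- t_ms[k]
      amp["c"] <- s[k]
      ifo <- in_win(lmk["c"], w$fo[2], after = lmk["c"])
      if (length(ifo)) {
        m <- .arg_extreme(s, ifo, find_max = FALSE)
        lmk["fo"] <- t_ms[m]
        amp["fo"] <- s[k] - s[m]
      }
    }
  }
  structure(list(mouse_id = avg_trace$mouse_id, eye = avg_trace$eye,
                 condition = cond, amplitude_uV = amp, landmark_ms = lmk),
            class = "component_amplitudes")
}

#' @export
print.component_amplitudes <- function(x, ...) {
  cat(sprintf("<component_amplitudes> %s %s eye, %s\n", x$mouse_id, x$eye,
              x$condition))
  print(data.frame(component = names(x$amplitude_uV),
                   amplitude_uV = unname(x$amplitude_uV),
                   landmark_ms = unname(x$landmark_ms)), row.names = FALSE)
  invisible(x)
}

#' Landmark (latency) times of the ERG components
#'
#' Returns the landmark times already located by [extract_components()].
#' Latencies are provided for completeness only; the screen's statistics use
#' amplitudes.
#'
#' @inheritParams extract_components
#' @return data.table: `mouse_id`, `eye`, `condition`, `parameter`,
#'   `landmark_ms`.
#' @export
measure_latencies <- function(avg_trace, windows = component_windows()) {
  x <- extract_components(avg_trace, windows)
  data.table(mouse_id = x$mouse_id, eye = x$eye, condition = x$condition,
             parameter = names(x$landmark_ms),
             landmark_ms = unname(x$landmark_ms))
}

# long amplitude table from a component_amplitudes object
.amplitudes_long <- function(x) {
  data.table(mouse_id = x$mouse_id, eye = x$eye, condition = x$condition,
             parameter = names(x$amplitude_uV),
             amplitude_uV = unname(x$amplitude_uV),
             landmark_ms = unname(x$landmark_ms))
}

#' Average trials and extract component amplitudes for a whole cohort
#'
#' Convenience wrapper: for every (mouse, eye, condition) not excluded by
#' `qc_flags`, averages the trials and extracts component amplitudes.
#'
#' @param cohort A baseline-corrected `erg_cohort`.
#' @param windows A [component_windows()] object.
#' @param qc_flags Optional flag table (`mouse_id`, `condition`); flagged
#'   pairs are skipped (NA condition excludes the mouse everywhere).
#' @return Long data.table: `mouse_id`, `eye`, `condition`, `parameter`,
#'   `amplitude_uV`, `landmark_ms`.
#' @export
extract_cohort_components <- function(cohort, windows = component_windows(),
                                      qc_flags = NULL) {
  stopifnot(inherits(cohort, "erg_cohort"))
  tr <- cohort$traces
  if (!is.null(qc_flags) && nrow(qc_flags)) {
    fl <- as.data.table(qc_flags)
    drop_all <- fl[is.na(condition), unique(mouse_id)]
    tr <- tr[!mouse_id %in% drop_all]
    fl2 <- unique(fl[!is.na(condition), .(mouse_id, condition)])
    tr <- tr[!fl2, on = c("mouse_id", "condition")]
  }
  if (nrow(tr) == 0)
    return(data.table(mouse_id = character(), eye = character(),
                      condition = character(), parameter = character(),
                      amplitude_uV = numeric(), landmark_ms = numeric()))
  keys <- unique(tr[, .(mouse_id, eye, condition)])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- tr[keys[i], on = c("mouse_id", "eye", "condition")]
    trials <- lapply(seq_len(nrow(sub)), function(j) .row_trace(sub, j))
    out[[i]] <- .amplitudes_long(extract_components(average_trials(trials), windows))
  }
  rbindlist(out)
}
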