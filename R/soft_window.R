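#' Soft temporal window shape
#'
#' A flat-top symmetric bump centred on each mutant test date. For a single
#' centre `c`, the weight at time `t` (distance `d = |t - c|` in days) is the
#' product of a rising and a falling logistic,
#'
#'   `w(d) = plogis(3k (1 + d/l)) * plogis(3k (1 - d/l))`
#'
#' which is ~1 for `d << l`, 0.5 at the half-width `d = l`, and decays to 0
#' for `d >> l` with edge sharpness controlled by `k`. Multiple centres are
#' aggregated by pointwise maximum, so cohorts tested far apart produce a
#' broad or multimodal window.
#'
#' @param k Dimensionless edge sharpness (> 0).
#' @param l Half-width in days (> 0).
#' @param centers Mutant test dates (`Date` or numeric days).
#' @return Object of class `window_shape`.
#' @export
window_shape <- function(k, l, centers) {
  if (length(centers) == 0)
    stop("configuration error: empty centers", call. = FALSE)
  stopifnot(is.numeric(k), k > 0, is.numeric(l), l > 0)
  structure(list(k = k, l = l, centers = as.numeric(centers)),
            class = "window_shape")
}

#' Evaluate the soft-window weight function
#'
#' @param t Dates (or numeric days) at which to evaluate.
#' @param shape A [window_shape()].
#' @return Numeric weights in `[0, 1]`, one per element of `t`.
#' @export
weight_function <- function(t, shape) {
  stopifnot(inherits(shape, "window_shape"))
  tn <- as.numeric(t)
  d <- vapply(tn, function(x) min(abs(x - shape$centers)), numeric(1))
  z <- 3 * shape$k
  plogis(z * (1 + d / shape$l)) * plogis(z * (1 - d / shape$l))
}

#' Optimize the soft window for one strain-by-parameter comparison
#'
#' Exhaustive grid search over candidate `(l, k)` pairs: among candidates
#' whose effective control size (sum of weights) is at least
#' `max(min_effective_n, number of mutant dates)`, the pair minimizing the
#' weighted variance of the control values is selected (ties broken to the
#' smaller `l`, then smaller `k`, via the deterministic grid order). If no
#' candidate satisfies the constraint, all-ones weights are returned with a
#' warning (equivalent to an unwindowed comparison).
#'
#' @param control_dates Test dates of the wildtype control mice.
#' @param mutant_dates Test dates of the mutant mice (the window centres are
#'   the unique dates).
#' @param values Per-control parameter values (same order as
#'   `control_dates`); only their weighted variance enters the objective.
#' @param grid data.frame of candidate `l` (days) and `k` values. Default:
#'   `l` in 7, 14, 28, 56, 112, 224, 448 crossed with `k` in 1, 2, 5, 10.
#' @param min_effective_n Minimum effective control size (default 20).
#' @return Object of class `control_weights`: `weights` (one per control, in
#'   `[0,1]`), `effective_n`, `k`, `l`, `shape`, `fallback`.
#' @export
optimize_window <- function(control_dates, mutant_dates, values,
                            grid = NULL, min_effective_n = 20) {
  stopifnot(length(control_dates) == length(values), length(mutant_dates) >= 1)
  if (is.null(grid))
    grid <- CJ(l = c(7, 14, 28, 56, 112, 224, 448), k = c(1, 2, 5, 10))
  grid <- as.data.table(grid)
  setorder(grid, l, k)
  centers <- unique(as.numeric(mutant_dates))
  need <- max(min_effective_n, length(mutant_dates))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    sh <- window_shape(grid$k[i], grid$l[i], centers)
    w <- weight_function(control_dates, sh)
    en <- sum(w)
    if (en < need || en <= 1) next
    wm <- sum(w * values) / en
    obj <- sum(w * (values - wm)^2) / (en - 1)
    if (is.null(best) || obj < best$obj)
      best <- list(obj = obj, w = w, en = en, k = grid$k[i], l = grid$l[i],
                   shape = sh)
  }
  if (is.null(best)) {
    warning("soft-window constraint unsatisfiable on grid; ",
            "falling back to all-ones weights", call. = FALSE)
    sh <- window_shape(max(grid$k), max(grid$l), centers)
    return(structure(list(weights = rep(1, length(control_dates)),
                          effective_n = length(control_dates),
                          k = NA_real_, l = NA_real_, shape = sh,
                          fallback = TRUE),
                     class = "control_weights"))
  }
  structure(list(weights = best$w, effective_n = best$en, k = best$k,
                 l = best$l, shape = best$shape, fallback = FALSE),
            class = "control_weights")
}

#' @export
print.control_weights <- function(x, ...) {
  cat(sprintf("<control_weights> %d controls, effective n = %.1f, k = %s, l = %s%s\n",
              length(x$weights), x$effective_n, format(x$k), format(x$l),
              if (x$fallback) " (fallback: all-ones)" else ""))
  invisible(x)
}
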