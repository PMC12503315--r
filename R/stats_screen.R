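# Weighted least squares with effective-sample-size degrees of freedom.
# df = sum(weights) - ncol(X), so fractional control weights do not inflate
# the nominal sample size. With unit weights this reproduces classical OLS
# (and the one-way ANOVA F test, since F = t^2 for a single contrast).
.wls <- function(y, X, w) {
  stopifnot(length(y) == nrow(X), length(w) == length(y), all(w >= 0))
  XtW <- t(X * w)
  xtx <- XtW %*% X
  if (abs(det(xtx)) < 1e-12 * prod(pmax(diag(xtx), 1)))
    stop("fit error: singular design", call. = FALSE)
  beta <- solve(xtx, XtW %*% y)
  r <- y - X %*% beta
  rss <- sum(w * r^2)
  df <- sum(w) - ncol(X)
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- unname(sqrt(sigma2 * diag(solve(xtx))))
  tval <- as.numeric(beta) / se
  p <- 2 * pt(-abs(tval), df)
  list(beta = as.numeric(beta), se = se, t = tval, p = p, df = df, rss = rss)
}

#' Weighted genotype fit for one eye of one strain-by-parameter comparison
#'
#' Weighted least squares of the amplitude on a 0/1 genotype indicator
#' (wildtype reference, mutant weights all 1): `Y = B0 + B1 * genotype`.
#' `B0` is the weighted wildtype mean and the effect size is the percentage
#' change from wildtype, `100 * B1 / B0`. The p-value is the t test of `B1`
#' with degrees of freedom based on the effective sample size (sum of
#' weights) minus 2.
#'
#' @param values Amplitudes (uV).
#' @param genotype Integer vector, 0 = wildtype, 1 = mutant.
#' @param weights Per-observation weights in `[0, 1]` (mutants conventionally
#'   1). Default all ones.
#' @return Object of class `genotype_fit`: `B0`, `B1`, `p`, `effect_pct`,
#'   `n_mutant`, `effective_n_control`, `se`, `t`, `df`.
#' @export
weighted_genotype_fit <- function(values, genotype, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(genotype))
  genotype <- as.integer(genotype)
  if (!all(genotype %in% c(0L, 1L)))
    stop("genotype must be coded 0 (wildtype) / 1 (mutant)", call. = FALSE)
  if (length(unique(genotype)) < 2)
    stop("fit error: need both genotype levels", call. = FALSE)
  keep <- is.finite(values) & weights > 0
  v <- values[keep]; g <- genotype[keep]; w <- weights[keep]
  if (length(unique(g)) < 2)
    stop("fit error: need both genotype levels with positive weight", call. = FALSE)
  f <- .wls(v, cbind(`(Intercept)` = 1, genotype = g), w)
  B0 <- f$beta[1]; B1 <- f$beta[2]
  effect <- if (B0 == 0) {
    warning("B0 = 0: effect percentage undefined", call. = FALSE)
    NA_real_
  } else 100 * B1 / B0
  structure(list(B0 = B0, B1 = B1, p = f$p[2], effect_pct = effect,
                 n_mutant = sum(g == 1L),
                 effective_n_control = sum(w[g == 0L]),
                 se = f$se[2], t = f$t[2], df = f$df),
            class = "genotype_fit")
}

#' @export
print.genotype_fit <- function(x, ...) {
  cat(sprintf("<genotype_fit> B0 = %.4g, B1 = %.4g, effect = %.2f%%, p = %.3g (df = %.1f)\n",
              x$B0, x$B1, x$effect_pct, x$p, x$df))
  cat(sprintf("  n mutant = %d, effective n control = %.1f\n",
              x$n_mutant, x$effective_n_control))
  invisible(x)
}

#' Combine both eyes of a strain-by-parameter comparison
#'
#' Fits each eye separately, then pools the left- and right-eye observations
#' (each mouse contributing up to two observations) into one weighted fit —
#' the plainest reading of "data combined between the two eyes". The
#' mean-effect percentage is the arithmetic mean of the two per-eye effect
#' percentages.
#'
#' @param left,right Per-eye data: each a list with elements `values`,
#'   `genotype`, and optionally `weights`.
#' @return Object of class `strain_fit`: `left`, `right`, `combined`
#'   ([weighted_genotype_fit()] objects) and `mean_effect_pct`.
#' @export
combine_eyes <- function(left, right) {
  as_eye <- function(e) {
    stopifnot(is.list(e), !is.null(e$values), !is.null(e$genotype))
    if (is.null(e$weights)) e$weights <- rep(1, length(e$values))
    e
  }
  left <- as_eye(left); right <- as_eye(right)
  fit_l <- weighted_genotype_fit(left$values, left$genotype, left$weights)
  fit_r <- weighted_genotype_fit(right$values, right$genotype, right$weights)
  fit_c <- weighted_genotype_fit(c(left$values, right$values),
                                 c(left$genotype, right$genotype),
                                 c(left$weights, right$weights))
  structure(list(left = fit_l, right = fit_r, combined = fit_c,
                 mean_effect_pct = mean(c(fit_l$effect_pct, fit_r$effect_pct))),
            class = "strain_fit")
}

#' Call concordant hits from per-strain results
#'
#' A strain-by-parameter result is a hit iff `p_left <= p_eye`,
#' `p_right <= p_eye` and `p_combined <= p_comb` (defaults 0.01, 0.01 and
#' 0.0001). Results significant in the combined analysis but with one eye
#' above the per-eye threshold are labelled `non_concordant` and are not
#' hits; everything else is `ns`. Direction is the sign of the mean-effect
#' percentage.
#'
#' @param results data.table with columns `strain_id`, `condition`,
#'   `parameter`, `p_left`, `p_right`, `p_combined`, `mean_effect_pct`.
#' @param p_eye Per-eye significance threshold (default 0.01).
#' @param p_comb Combined-eyes threshold (default 0.0001).
#' @return List: `calls` (input plus `is_hit`, `direction`, `label`),
#'   `by_parameter` (hit counts per condition and parameter), `by_strain`
#'   (strain-level screen verdicts: a strain is a screen hit if any parameter
#'   is a hit).
#' @export
call_strain_hits <- function(results, p_eye = 0.01, p_comb = 1e-4) {
  calls <- as.data.table(results)
  req <- c("strain_id", "condition", "parameter", "p_left", "p_right",
           "p_combined", "mean_effect_pct")
  miss <- setdiff(req, names(calls))
  if (length(miss)) stop("results missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  calls <- copy(calls)
  calls[, is_hit := !is.na(p_left) & !is.na(p_right) & !is.na(p_combined) &
          p_left <= p_eye & p_right <= p_eye & p_combined <= p_comb]
  calls[, direction := fifelse(is.na(mean_effect_pct), NA_character_,
                               fifelse(mean_effect_pct >= 0, "increase", "decrease"))]
  calls[, label := fifelse(is_hit, "hit",
                           fifelse(!is.na(p_combined) & p_combined <= p_comb,
                                   "non_concordant", "ns"))]
  by_parameter <- calls[, .(n_tested = .N, n_hits = sum(is_hit)),
                        by = .(condition, parameter)]
  by_strain <- calls[, .(any_hit = any(is_hit),
                         hit_parameters = paste(
                           paste(condition[is_hit], parameter[is_hit], sep = "_"),
                           collapse = ",")),
                     by = strain_id]
  list(calls = calls[], by_parameter = by_parameter[], by_strain = by_strain[])
}

# Welch's unequal-variance t statistic; handles the degenerate
# zero-variance cases stats::t.test refuses (identical constant groups ->
# t = 0, p = 1).
.welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  delta <- mean(x) - mean(y)
  if (se2 == 0) {
    if (delta == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(delta) * Inf, df = n1 + n2 - 2, p = 0))
  }
  tval <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Sexual-dimorphism assessment of the wildtype control population
#'
#' Welch's unequal-variance t-test of male vs female wildtype amplitudes,
#' per parameter and eye (6 parameters x 2 eyes = 12 tests), with a
#' Bonferroni-corrected significance threshold (default 0.004, i.e., 0.05
#' over 12 tests).
#'
#' @param amplitudes Long amplitude table (see [extract_cohort_components()]).
#' @param sessions Session table (for `strain_id` and `sex`).
#' @param alpha Significance threshold after correction (default 0.004).
#' @param control_strain Wildtype sentinel strain id.
#' @return data.table: `condition`, `parameter`, `eye`, `n_male`, `n_female`,
#'   `mean_male`, `mean_female`, `t`, `p`, `significant`. Tests with fewer
#'   than 2 values in a sex are skipped with a warning.
#' @export
welch_dimorphism <- function(amplitudes, sessions, alpha = 0.004,
                             control_strain = "C57BL/6NJ") {
  amplitudes <- as.data.table(amplitudes)
  sessions <- as.data.table(sessions)
  wt <- sessions[strain_id == control_strain, .(mouse_id, sex)]
  dat <- wt[amplitudes, on = "mouse_id", nomatch = NULL]
  dat <- dat[is.finite(amplitude_uV)]
  out <- dat[, {
    xm <- amplitude_uV[sex == "M"]; xf <- amplitude_uV[sex == "F"]
    if (length(xm) < 2 || length(xf) < 2) {
      warning("dimorphism test skipped for ", condition[1], " ", parameter[1],
              " (", eye[1], " eye): a sex has < 2 values", call. = FALSE)
      .(n_male = length(xm), n_female = length(xf),
        mean_male = mean(xm), mean_female = mean(xf),
        t = NA_real_, p = NA_real_)
    } else {
      wt_ <- .welch(xm, xf)
      .(n_male = length(xm), n_female = length(xf),
        mean_male = mean(xm), mean_female = mean(xf),
        t = wt_$t, p = wt_$p)
    }
  }, by = .(condition, parameter, eye)]
  out[, significant := !is.na(p) & p <= alpha]
  out[]
}

#' Sex-by-genotype interaction fit for one eye (or pooled eyes)
#'
#' Weighted model `Y = B0 + B_sex + B_geno + B_int * sex * genotype`; returns
#' the interaction term's coefficient and p-value (effective-sample-size
#' degrees of freedom, as in [weighted_genotype_fit()]).
#'
#' @param values Amplitudes.
#' @param genotype 0/1 genotype indicator.
#' @param sex Factor or character (`M`/`F`) or 0/1 indicator.
#' @param weights Per-observation weights (default all ones).
#' @return List: `B_int`, `p`, `df`.
#' @export
interaction_fit <- function(values, genotype, sex, weights = rep(1, length(values))) {
  sx <- if (is.numeric(sex)) sex else as.integer(sex == "M")
  g <- as.integer(genotype)
  keep <- is.finite(values) & weights > 0
  X <- cbind(1, sx, g, sx * g)[keep, , drop = FALSE]
  f <- .wls(values[keep], X, weights[keep])
  list(B_int = f$beta[4], p = f$p[4], df = f$df)
}

#' Sex-by-genotype interaction screen
#'
#' For each strain with at least `min_per_sex` QC-passing mutants of each sex,
#' fits the sex-by-genotype interaction per eye and for the pooled eyes, and
#' applies the same concordance rule to the interaction term (per-eye
#' `p <= p_eye`, combined `p <= p_comb`).
#'
#' @param amplitudes Long amplitude table.
#' @param sessions Session table.
#' @param weights Optional data.table (`strain_id`, `condition`, `parameter`,
#'   `eye`, `mouse_id`, `weight`) of control weights; default all ones.
#' @param min_per_sex Minimum mutants per sex per strain (default 4).
#' @param p_eye,p_comb Significance thresholds (defaults 0.01, 0.0001).
#' @param control_strain Wildtype sentinel strain id.
#' @return data.table: `strain_id`, `condition`, `parameter`, `n_male`,
#'   `n_female`, `p_left`, `p_right`, `p_combined`, `significant`, `skipped`.
#' @export
interaction_screen <- function(amplitudes, sessions, weights = NULL,
                               min_per_sex = 4, p_eye = 0.01, p_comb = 1e-4,
                               control_strain = "C57BL/6NJ") {
  amplitudes <- as.data.table(amplitudes)
  sessions <- as.data.table(sessions)
  strains <- setdiff(unique(sessions$strain_id), control_strain)
  rows <- list()
  for (st in strains) {
    mut <- sessions[strain_id == st]
    n_m <- sum(mut$sex == "M"); n_f <- sum(mut$sex == "F")
    pars <- unique(amplitudes[, .(condition, parameter)])
    if (n_m < min_per_sex || n_f < min_per_sex) {
      rows[[length(rows) + 1L]] <- data.table(
        strain_id = st, condition = pars$condition, parameter = pars$parameter,
        n_male = n_m, n_female = n_f, p_left = NA_real_, p_right = NA_real_,
        p_combined = NA_real_, significant = FALSE, skipped = TRUE)
      next
    }
    ids <- c(sessions[strain_id == control_strain, mouse_id], mut$mouse_id)
    dat <- amplitudes[mouse_id %in% ids]
    dat <- sessions[, .(mouse_id, strain_id, sex)][dat, on = "mouse_id"]
    dat[, genotype := as.integer(strain_id == st)]
    for (pi in seq_len(nrow(pars))) {
      sub <- dat[condition == pars$condition[pi] & parameter == pars$parameter[pi] &
                   is.finite(amplitude_uV)]
      if (!is.null(weights)) {
        wtab <- as.data.table(weights)[strain_id == st &
                                         condition == pars$condition[pi] &
                                         parameter == pars$parameter[pi]]
        sub <- merge(sub, wtab[, .(mouse_id, eye, weight)],
                     by = c("mouse_id", "eye"), all.x = TRUE)
        sub[is.na(weight) | genotype == 1L, weight := 1]
      } else sub[, weight := 1]
      fit_eye <- function(e) {
        d <- sub[eye == e]
        if (nrow(d) < 8 || length(unique(d$genotype)) < 2 ||
            length(unique(d$sex)) < 2) return(NA_real_)
        tryCatch(interaction_fit(d$amplitude_uV, d$genotype, d$sex, d$weight)$p,
                 error = function(e) NA_real_)
      }
      pl <- fit_eye("L"); pr <- fit_eye("R")
      pc <- if (is.na(pl) || is.na(pr)) NA_real_ else
        tryCatch(interaction_fit(sub$amplitude_uV, sub$genotype, sub$sex,
                                 sub$weight)$p,
                 error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.table(
        strain_id = st, condition = pars$condition[pi],
        parameter = pars$parameter[pi], n_male = n_m, n_female = n_f,
        p_left = pl, p_right = pr, p_combined = pc,
        significant = !is.na(pl) && !is.na(pr) && !is.na(pc) &&
          pl <= p_eye && pr <= p_eye && pc <= p_comb,
        skipped = FALSE)
    }
  }
  rbindlist(rows)
}
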