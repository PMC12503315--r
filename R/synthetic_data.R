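#' Default waveform kernel parameters
#'
#' Each component is a smooth, polarity-signed lobe: Gaussian lobes for the
#' a-, b-, FO-like and photopic waves, and a slow gamma-like lobe for the
#' c-wave (zero for t <= 0, peaking at its latency). Amplitudes are kernel
#' magnitudes in microvolts; because lobes overlap, the *measured* component
#' amplitudes (per the trough/peak conventions of [extract_components()])
#' differ from the kernel amplitudes — [template_extrema()] is the oracle for
#' the measured values. Magnitudes are generator choices typical of mouse ERG
#' at these stimulus strengths, not values taken from any dataset.
#'
#' @param condition `"scotopic"` or `"photopic"`.
#' @return Named list of per-component kernel parameter lists
#'   (`amp`, `lat_ms`, `width_ms`, `kernel`, `polarity`, `shape`).
#' @export
waveform_params <- function(condition = c("scotopic", "photopic")) {
  condition <- match.arg(condition)
  if (condition == "scotopic") {
    list(
      a  = list(amp = 200, lat_ms = 16,   width_ms = 5,   kernel = "gauss", polarity = -1),
      b  = list(amp = 400, lat_ms = 80,   width_ms = 20,  kernel = "gauss", polarity = +1),
      c  = list(amp = 150, lat_ms = 1200, shape = 4,      kernel = "gamma", polarity = +1),
      fo = list(amp = 120, lat_ms = 3800, width_ms = 400, kernel = "gauss", polarity = -1))
  } else {
    list(
      a = list(amp = 15, lat_ms = 12, width_ms = 3,  kernel = "gauss", polarity = -1),
      b = list(amp = 90, lat_ms = 50, width_ms = 10, kernel = "gauss", polarity = +1))
  }
}

# one kernel lobe evaluated at t (ms)
.kernel_lobe <- function(p, t_ms) {
  if (p$kernel == "gauss") {
    p$polarity * p$amp * exp(-(t_ms - p$lat_ms)^2 / (2 * p$width_ms^2))
  } else { # gamma-like: 0 for t <= 0, unit peak at lat_ms
    v <- numeric(length(t_ms))
    pos <- t_ms > 0
    x <- t_ms[pos] / p$lat_ms
    v[pos] <- p$polarity * p$amp * x^p$shape * exp(p$shape * (1 - x))
    v
  }
}

#' Evaluate the noiseless waveform template
#'
#' Sum of the polarity-signed component kernels at the requested times.
#'
#' @param params Kernel parameters, as from [waveform_params()].
#' @param condition `"scotopic"` or `"photopic"` (used only for validation).
#' @param t_ms Times in milliseconds post-stimulus (may be negative).
#' @return Numeric vector of voltages (uV).
#' @export
waveform_template <- function(params, condition, t_ms) {
  stopifnot(is.list(params))
  Reduce(`+`, lapply(params, .kernel_lobe, t_ms = t_ms))
}

#' Analytic extrema oracle for the waveform template
#'
#' Applies the measurement conventions of [extract_components()] to the
#' *continuous* template via numerical optimization of the closed-form kernel
#' sum (independent of any sampled trace), yielding the measured component
#' amplitudes and landmark times the extraction should recover.
#'
#' @inheritParams waveform_template
#' @param windows A [component_windows()] object.
#' @return List with `amplitude_uV` and `landmark_ms`, named by component.
#' @export
template_extrema <- function(params, condition, windows = component_windows()) {
  f <- function(t) waveform_template(params, condition, t)
  w <- windows[[condition]]
  comps <- .components[[condition]]
  amp <- setNames(rep(NA_real_, length(comps)), comps)
  lmk <- setNames(rep(NA_real_, length(comps)), comps)
  opt <- function(lo, hi, maximum) optimize(f, c(lo, hi), maximum = maximum,
                                            tol = 1e-6)
  oa <- opt(w$a[1], w$a[2], maximum = FALSE)
  lmk["a"] <- oa$minimum; amp["a"] <- max(0, -oa$objective)
  ob <- opt(max(w$b[1], lmk["a"]), w$b[2], maximum = TRUE)
  lmk["b"] <- ob$maximum; amp["b"] <- ob$objective - oa$objective
  if (condition == "scotopic") {
    oc <- opt(max(w$c[1], lmk["b"]), w$c[2], maximum = TRUE)
    lmk["c"] <- oc$maximum; amp["c"] <- oc$objective
    ofo <- opt(lmk["c"], w$fo[2], maximum = FALSE)
    lmk["fo"] <- ofo$minimum; amp["fo"] <- oc$objective - ofo$objective
  }
  list(amplitude_uV = amp, landmark_ms = lmk)
}

#' Describe one mutant strain for the simulator
#'
#' @param strain_id Strain identifier.
#' @param n_male,n_female Mutant mice per sex (default 4 + 4).
#' @param zygosity `"homozygous"` or `"heterozygous"`.
#' @param weeks Integer week indices of the strain's test batches (mice are
#'   assigned to batches round-robin).
#' @param effects Named numeric vector of multiplicative component effects,
#'   names of the form `condition_component` (e.g.
#'   `c(scotopic_a = -0.43)` scales the scotopic a-kernel by 0.57).
#' @return A `strain_spec` list.
#' @export
strain_spec <- function(strain_id, n_male = 4, n_female = 4,
                        zygosity = "homozygous", weeks = 1L, effects = numeric()) {
  stopifnot(n_male + n_female >= 1, length(weeks) >= 1)
  ok <- unlist(lapply(.erg_conditions,
                      function(cd) paste(cd, .components[[cd]], sep = "_")))
  bad <- setdiff(names(effects), ok)
  if (length(bad)) stop("unknown effect name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(strain_id = strain_id, n_male = n_male, n_female = n_female,
                 zygosity = zygosity, weeks = as.integer(weeks),
                 effects = effects),
            class = "strain_spec")
}

#' Simulation configuration
#'
#' The stated world of the synthetic screen: weekly wildtype cohorts of
#' 5 males + 5 females, mutant strains tested in 1-6 batches, 3 scotopic
#' trials and 20 photopic sweeps per eye at 2000 Hz, slow drift across the
#' acquisition window, occasional artifact trials and gross whole-mouse
#' outliers. Noise defaults (between-mouse CV 0.06, between-eye CV 0.24,
#' trial noise 5 uV) reflect an inbred, age-matched control line in which
#' per-eye technical variation dominates biological between-animal variation;
#' see the methods vignette.
#'
#' @param n_weeks Number of weekly wildtype cohorts.
#' @param wt_per_week Named vector `c(male =, female =)` of wildtype mice per
#'   week (default 5 + 5).
#' @param strains List of [strain_spec()] objects (may be empty).
#' @param start_date First test date.
#' @param week_spacing_days Days between consecutive weekly cohorts
#'   (default 7; larger values stretch the acquisition window).
#' @param mouse_cv Between-mouse lognormal coefficient of variation.
#' @param eye_cv Between-eye (within mouse and condition) lognormal CV.
#' @param trial_sd_uV Additive per-sample trial noise SD (uV).
#' @param baseline_drift_uV_per_year Constant offset drift (removed by
#'   baseline correction).
#' @param gain_drift_per_year Multiplicative amplitude drift per year (what
#'   the soft window must absorb).
#' @param artifact_rate Per-trial probability of high-variance corruption.
#' @param artifact_sd_uV SD of the injected artifact noise.
#' @param outlier_rate Per-mouse probability of a gross amplitude-scaling
#'   outlier.
#' @param outlier_sd_range Outlier magnitude in units of the total amplitude
#'   SD (default 4-8).
#' @param conditions Conditions to simulate.
#' @param scotopic_params,photopic_params Kernel parameter sets.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_weeks = 4,
                       wt_per_week = c(male = 5, female = 5),
                       strains = list(),
                       start_date = as.Date("2019-01-07"),
                       week_spacing_days = 7,
                       mouse_cv = 0.06,
                       eye_cv = 0.24,
                       trial_sd_uV = 5,
                       baseline_drift_uV_per_year = 50,
                       gain_drift_per_year = 0.05,
                       artifact_rate = 0.005,
                       artifact_sd_uV = 200,
                       outlier_rate = 0.01,
                       outlier_sd_range = c(4, 8),
                       conditions = .erg_conditions,
                       scotopic_params = waveform_params("scotopic"),
                       photopic_params = waveform_params("photopic"),
                       seed = 1L) {
  if (n_weeks < 1) stop("configuration error: n_weeks must be >= 1", call. = FALSE)
  if (artifact_rate < 0 || artifact_rate > 1 || outlier_rate < 0 || outlier_rate > 1)
    stop("configuration error: rates must lie in [0, 1]", call. = FALSE)
  if (length(strains))
    stopifnot(all(vapply(strains, inherits, TRUE, "strain_spec")))
  for (st in strains)
    if (any(st$weeks > n_weeks))
      stop("configuration error: strain ", st$strain_id,
           " assigned to week beyond n_weeks", call. = FALSE)
  structure(list(
    n_weeks = as.integer(n_weeks), wt_per_week = wt_per_week,
    strains = strains, start_date = as.Date(start_date),
    week_spacing_days = week_spacing_days, mouse_cv = mouse_cv,
    eye_cv = eye_cv, trial_sd_uV = trial_sd_uV,
    baseline_drift_uV_per_year = baseline_drift_uV_per_year,
    gain_drift_per_year = gain_drift_per_year, artifact_rate = artifact_rate,
    artifact_sd_uV = artifact_sd_uV, outlier_rate = outlier_rate,
    outlier_sd_range = outlier_sd_range, conditions = conditions,
    scotopic_params = scotopic_params, photopic_params = photopic_params,
    seed = as.integer(seed)), class = "sim_config")
}

# sample times (ms) for one condition at 2000 Hz
.sim_times_ms <- function(condition) {
  if (condition == "scotopic") seq(-20, 5000, by = 0.5) else seq(-10, 100, by = 0.5)
}

#' Generate a synthetic ERG cohort with ground truth
#'
#' Deterministic for a fixed seed. Strain effects are applied
#' multiplicatively to the component kernel amplitudes; gain drift scales all
#' amplitudes as a linear function of test date; offset drift shifts whole
#' traces (and is exactly removed by baseline correction); artifacts corrupt
#' single trials with high-variance noise; gross outliers rescale all of a
#' mouse's amplitudes far outside the wildtype range.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (an [erg_cohort()]) and `truth`
#'   (`effects`, `artifacts`, `outliers` tables; never read by the pipeline).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  week_date <- function(w) cfg$start_date + (w - 1L) * cfg$week_spacing_days

  sess <- list()
  for (w in seq_len(cfg$n_weeks)) {
    n_m <- cfg$wt_per_week[["male"]]; n_f <- cfg$wt_per_week[["female"]]
    if (n_m + n_f == 0) next
    sess[[length(sess) + 1L]] <- data.table(
      mouse_id = sprintf("WT_w%02d_%s%d", w, rep(c("m", "f"), c(n_m, n_f)),
                         c(seq_len(n_m), seq_len(n_f))),
      strain_id = "C57BL/6NJ", zygosity = "wildtype",
      sex = rep(c("M", "F"), c(n_m, n_f)),
      test_date = week_date(w),
      batch_id = sprintf("w%02d", w))
  }
  for (st in cfg$strains) {
    n <- st$n_male + st$n_female
    sexes <- rep(c("M", "F"), c(st$n_male, st$n_female))
    wk <- st$weeks[((seq_len(n) - 1L) %% length(st$weeks)) + 1L]
    sess[[length(sess) + 1L]] <- data.table(
      mouse_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", st$strain_id),
                         seq_len(n)),
      strain_id = st$strain_id, zygosity = st$zygosity, sex = sexes,
      test_date = week_date(wk), batch_id = sprintf("w%02d", wk))
  }
  sessions <- rbindlist(sess)

  # effect lookup: strain -> condition_component -> multiplicative delta
  eff_of <- function(strain, cond, comp) {
    for (st in cfg$strains)
      if (st$strain_id == strain) {
        nm <- paste(cond, comp, sep = "_")
        return(if (nm %in% names(st$effects)) st$effects[[nm]] else 0)
      }
    0
  }

  params <- list(scotopic = cfg$scotopic_params, photopic = cfg$photopic_params)
  t_ms <- lapply(setNames(nm = cfg$conditions), .sim_times_ms)
  years <- as.numeric(sessions$test_date - cfg$start_date) / 365.25

  total_cv <- sqrt(cfg$mouse_cv^2 + cfg$eye_cv^2)
  trace_rows <- list()
  artifacts <- list()
  outliers <- list()

  for (i in seq_len(nrow(sessions))) {
    mid <- sessions$mouse_id[i]
    strain <- sessions$strain_id[i]
    mouse_scale <- exp(rnorm(1, 0, cfg$mouse_cv))
    is_outlier <- runif(1) < cfg$outlier_rate
    out_gain <- 1
    if (is_outlier) {
      s <- runif(1, cfg$outlier_sd_range[1], cfg$outlier_sd_range[2])
      out_gain <- max(0.05, 1 + sample(c(-1, 1), 1) * s * total_cv)
      outliers[[length(outliers) + 1L]] <- data.table(mouse_id = mid, gain = out_gain)
    }
    gain_t <- 1 + cfg$gain_drift_per_year * years[i]
    offset <- cfg$baseline_drift_uV_per_year * years[i]
    for (cond in cfg$conditions) {
      n_trials <- .expected_trials[[cond]]
      tt <- t_ms[[cond]]
      for (e in c("R", "L")) {
        eye_scale <- exp(rnorm(1, 0, cfg$eye_cv))
        p <- params[[cond]]
        for (comp in names(p))
          p[[comp]]$amp <- p[[comp]]$amp * (1 + eff_of(strain, cond, comp)) *
            mouse_scale * eye_scale * gain_t * out_gain
        base <- waveform_template(p, cond, tt) + offset
        noise <- matrix(rnorm(n_trials * length(tt), 0, cfg$trial_sd_uV),
                        nrow = n_trials)
        corrupt <- runif(n_trials) < cfg$artifact_rate
        for (k in which(corrupt)) {
          noise[k, ] <- noise[k, ] + rnorm(length(tt), 0, cfg$artifact_sd_uV)
          artifacts[[length(artifacts) + 1L]] <-
            data.table(mouse_id = mid, eye = e, condition = cond, trial = k)
        }
        trace_rows[[length(trace_rows) + 1L]] <- data.table(
          mouse_id = mid, eye = e, condition = cond, trial = seq_len(n_trials),
          sample_rate_hz = 2000,
          t0_offset_s = if (cond == "scotopic") 0.02 else 0.01,
          samples = lapply(seq_len(n_trials), function(k) base + noise[k, ]))
      }
    }
  }

  effects <- rbindlist(c(list(data.table(strain_id = character(),
                                         condition = character(),
                                         parameter = character(),
                                         effect = numeric())),
                         lapply(cfg$strains, function(st) {
    grid <- rbindlist(lapply(cfg$conditions, function(cd)
      data.table(strain_id = st$strain_id, condition = cd,
                 parameter = .components[[cd]])))
    grid[, effect := mapply(eff_of, strain_id, condition, parameter)]
    grid
  })))

  cohort <- erg_cohort(sessions, rbindlist(trace_rows),
                       provenance = sprintf("generate_cohort(seed=%d)", cfg$seed))
  truth <- list(
    effects = effects,
    artifacts = if (length(artifacts)) rbindlist(artifacts) else
      data.table(mouse_id = character(), eye = character(),
                 condition = character(), trial = integer()),
    outliers = if (length(outliers)) rbindlist(outliers) else
      data.table(mouse_id = character(), gain = numeric()))
  list(cohort = cohort, truth = truth)
}

#' Named fixture cohorts for tests and examples
#'
#' Small (<= 60 mice), byte-stable cohorts with documented ground truth:
#' * `"tiny-clean"`: 20 wildtype + 6 mutants, no effects, no corruption — the
#'   screen should call 0 hits;
#' * `"one-hit"`: adds one strain with a planted -50% scotopic a-kernel
#'   effect — exactly that strain/parameter should be called;
#' * `"drifted"`: cohorts spread over ~3 years with strong gain drift —
#'   exercises the soft window;
#' * `"dimorphic"`: one strain with a male-only -75% scotopic a shift —
#'   exercises the sex-by-genotype interaction screen.
#'
#' @param name Preset id.
#' @param seed Seed override (default: preset-specific fixed seed).
#' @return List with `cohort` and `truth`, as from [generate_cohort()].
#' @export
make_fixture <- function(name = c("tiny-clean", "one-hit", "drifted", "dimorphic"),
                         seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    "tiny-clean" = sim_config(
      n_weeks = 2,
      strains = list(strain_spec("Nullx", 3, 3, weeks = 1:2)),
      baseline_drift_uV_per_year = 0, gain_drift_per_year = 0,
      artifact_rate = 0, outlier_rate = 0, seed = 101L),
    "one-hit" = sim_config(
      n_weeks = 4,
      strains = list(strain_spec("Nullx", 4, 4, weeks = 1:2),
                     strain_spec("Hitx", 5, 5, weeks = 2:3,
                                 effects = c(scotopic_a = -0.5))),
      baseline_drift_uV_per_year = 0, gain_drift_per_year = 0,
      artifact_rate = 0, outlier_rate = 0, seed = 102L),
    "drifted" = sim_config(
      n_weeks = 5, week_spacing_days = 200,
      strains = list(strain_spec("Latex", 4, 4, weeks = 5,
                                 effects = c(scotopic_a = -0.4))),
      gain_drift_per_year = 0.15, artifact_rate = 0, outlier_rate = 0,
      seed = 103L),
    "dimorphic" = sim_config(
      n_weeks = 4,
      strains = list(strain_spec("Dimox", 8, 8, weeks = 1:3)),
      baseline_drift_uV_per_year = 0, gain_drift_per_year = 0,
      artifact_rate = 0, outlier_rate = 0, seed = 104L))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- generate_cohort(cfg)
  if (name == "dimorphic") {
    # male-only -75% scotopic a-kernel shift, applied post hoc so females are null
    male_ids <- out$cohort$sessions[strain_id == "Dimox" & sex == "M", mouse_id]
    tr <- out$cohort$traces
    idx <- which(tr$mouse_id %in% male_ids & tr$condition == "scotopic")
    p0 <- cfg$scotopic_params$a
    for (i in idx) {
      tt <- .sim_times_ms("scotopic")
      tr$samples[[i]] <- tr$samples[[i]] + (-0.75) * .kernel_lobe(p0, tt)
    }
    out$cohort$traces <- tr
    out$truth$effects <- data.table(
      strain_id = "Dimox", condition = "scotopic", parameter = "a",
      effect = -0.75, note = "males only")
  }
  out
}

#' Amplitude-level strain simulator
#'
#' Simulates extracted component amplitudes directly — the amplitude-level
#' marginal of the waveform model — for statistical studies (effect recovery,
#' null screens, drift robustness) where generating full traces would be
#' wasteful. Each mouse gets a shared lognormal scale (`mouse_cv`), each eye
#' an independent lognormal scale (`eye_cv`), plus additive measurement noise
#' (`meas_sd`, the residual of trial averaging); a multiplicative genotype
#' `effect` applies to mutants, and an optional linear drift in uV/year
#' applies to all mice by test date.
#'
#' @param n_control,n_mutant Group sizes (mice).
#' @param effect Multiplicative effect for mutants (e.g. -0.43).
#' @param mu Baseline mean amplitude (uV).
#' @param mouse_cv,eye_cv Lognormal CVs (defaults as in [sim_config()]).
#' @param meas_sd Additive per-eye measurement noise SD (uV; default 3,
#'   the approximate residual after averaging 3 scotopic trials).
#' @param control_dates,mutant_dates Optional test dates (required if
#'   `drift_uV_per_year` is nonzero or weights are to be optimized).
#' @param drift_uV_per_year Linear amplitude drift applied by date.
#' @param sex_effect Optional multiplicative effect applied only to male
#'   mutants (for dimorphism studies); sexes are assigned half and half.
#' @return data.table: `mouse_id`, `genotype` (0/1), `sex`, `date`, `eye`,
#'   `value`.
#' @export
simulate_amplitudes <- function(n_control, n_mutant, effect = 0, mu = 150,
                                mouse_cv = 0.06, eye_cv = 0.24, meas_sd = 3,
                                control_dates = NULL, mutant_dates = NULL,
                                drift_uV_per_year = 0, sex_effect = NULL) {
  n <- n_control + n_mutant
  genotype <- rep(c(0L, 1L), c(n_control, n_mutant))
  sex <- c(rep(c("F", "M"), length.out = n_control),
           rep(c("F", "M"), length.out = n_mutant))
  if (is.null(control_dates)) control_dates <- rep(0, n_control)
  if (is.null(mutant_dates)) mutant_dates <- rep(0, n_mutant)
  dates <- c(as.numeric(control_dates), as.numeric(mutant_dates))
  stopifnot(length(dates) == n)
  mult <- ifelse(genotype == 1L, 1 + effect, 1)
  if (!is.null(sex_effect))
    mult <- mult * ifelse(genotype == 1L & sex == "M", 1 + sex_effect, 1)
  m <- exp(rnorm(n, 0, mouse_cv))
  drift <- drift_uV_per_year * (dates - min(dates)) / 365.25
  one_eye <- function(e) data.table(
    mouse_id = sprintf("m%04d", seq_len(n)), genotype = genotype, sex = sex,
    date = dates, eye = e,
    value = mu * mult * m * exp(rnorm(n, 0, eye_cv)) + drift +
      rnorm(n, 0, meas_sd))
  rbind(one_eye("L"), one_eye("R"))
}
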