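test_that("baseline_correct zeroes the pre-stimulus mean and is idempotent", {
  # constant +12 uV offset: every sample shifts by -12
  tr <- erg_trace("m1", "L", "scotopic", 1L, rep(12, 10041))
  out <- baseline_correct(tr)
  expect_equal(out$samples, rep(0, 10041))

  # already-zero baseline: unchanged
  z <- erg_trace("m1", "L", "scotopic", 1L, c(rep(0, 40), rnorm(10001)))
  expect_equal(baseline_correct(z)$samples[1:40], rep(0, 40))

  # ramp pre-stimulus: shift equals the independently computed mean
  ramp <- c(1:40, rep(5, 10001))
  m <- mean(1:40)
  out2 <- baseline_correct(erg_trace("m2", "R", "scotopic", 1L, ramp))
  expect_equal(out2$samples, ramp - m)
  expect_lt(abs(mean(out2$samples[1:40])), 1e-9)

  # idempotent
  expect_equal(baseline_correct(out2)$samples, out2$samples)

  # insufficient pre-stimulus samples
  short <- erg_trace("m3", "L", "scotopic", 1L, rep(0, 10041),
                     t0_offset = 0.01)
  expect_error(baseline_correct(short), "insufficient pre-stimulus")
})

test_that("trial_mad_score matches hand and brute-force oracles", {
  expect_equal(trial_mad_score(list(rep(1, 50), rep(1, 50), rep(1, 50))), 0)

  # two trials differing by 1 uV everywhere: deviations +/-0.5 -> N * 0.5
  n <- 240
  expect_equal(trial_mad_score(list(rep(0, n), rep(1, n))), n * 0.5)

  # brute-force loop oracle on noisy trials
  set.seed(42)
  trials <- replicate(3, rnorm(100), simplify = FALSE)
  brute <- 0
  for (j in 1:100) {
    v <- vapply(trials, `[`, numeric(1), j)
    brute <- brute + mean(abs(v - mean(v)))
  }
  expect_equal(trial_mad_score(trials), brute)

  # order invariance and common-constant invariance
  expect_equal(trial_mad_score(rev(trials)), trial_mad_score(trials))
  shifted <- lapply(trials, `+`, 7)
  expect_equal(trial_mad_score(shifted), trial_mad_score(trials))

  expect_error(trial_mad_score(list(rnorm(5))), "2 trials")
  expect_error(trial_mad_score(list(rnorm(5), rnorm(6))), "alignment")
})

test_that("mad_qc flags planted inconsistent trials and nothing on identical data", {
  co <- flat_cohort(4)
  out <- suppressWarnings(mad_qc(co))
  expect_equal(nrow(out$flags), 0)
  expect_true(all(out$scores$score == 0))

  # corrupt one scotopic trial of m3's right eye
  co2 <- flat_cohort(4)
  i <- which(co2$traces$mouse_id == "m3" & co2$traces$eye == "R" &
               co2$traces$condition == "scotopic" & co2$traces$trial == 2L)
  set.seed(1)
  co2$traces$samples[[i]] <- co2$traces$samples[[i]] + rnorm(10041, 0, 200)
  out2 <- suppressWarnings(mad_qc(co2))
  expect_equal(out2$flags$mouse_id, "m3")
  expect_equal(out2$flags$condition, "scotopic")
  w <- testthat::capture_warnings(mad_qc(co2))
  expect_true(any(grepl("fewer than 100", w)))
})

test_that("average_trials is the pointwise mean", {
  tr1 <- erg_trace("m1", "L", "scotopic", 1L, rep(2, 10041))
  expect_equal(average_trials(list(tr1))$samples, tr1$samples)

  v <- rnorm(10041)
  up <- erg_trace("m1", "L", "scotopic", 1L, v)
  dn <- erg_trace("m1", "L", "scotopic", 2L, -v)
  expect_equal(average_trials(list(up, dn))$samples, rep(0, 10041))

  set.seed(3)
  mats <- replicate(3, rnorm(10041), simplify = FALSE)
  trs <- lapply(1:3, function(i) erg_trace("m1", "L", "scotopic", i, mats[[i]]))
  avg <- average_trials(trs)
  for (j in c(1, 500, 4000, 9000, 10041))
    expect_equal(avg$samples[j], mean(c(mats[[1]][j], mats[[2]][j], mats[[3]][j])))
  expect_equal(avg$trial_count, 3)
  expect_error(average_trials(list()), "empty")
})

amp_row <- function(mouse, eye, value, param = "a", cond = "scotopic")
  data.table::data.table(mouse_id = mouse, eye = eye, condition = cond,
                         parameter = param, amplitude_uV = value,
                         landmark_ms = 15)

test_that("extreme_value_qc applies wildtype-only closed limits", {
  sessions <- data.table::data.table(
    mouse_id = c(sprintf("wt%d", 1:5), "mut1", "mut2"),
    strain_id = c(rep("C57BL/6NJ", 5), "Mutx", "Mutx"),
    zygosity = c(rep("wildtype", 5), "homozygous", "homozygous"),
    sex = "M", test_date = as.Date("2020-01-06"), batch_id = "w01")

  # degenerate SD 0: any deviating mutant is flagged, equal one is not
  amps <- rbind(amp_row(sprintf("wt%d", 1:5), "L", 100),
                amp_row("mut1", "L", 100.1), amp_row("mut2", "L", 100))
  out <- extreme_value_qc(amps, sessions)
  expect_equal(out$flags$mouse_id, "mut1")

  # boundary value exactly at mean + 3 SD passes (closed interval)
  wt_vals <- c(90, 95, 100, 105, 110)
  lim <- mean(wt_vals) + 3 * sd(wt_vals)
  amps2 <- rbind(amp_row(sprintf("wt%d", 1:5), "L", wt_vals),
                 amp_row("mut1", "L", lim),
                 amp_row("mut2", "L", lim + 1e-6))
  out2 <- extreme_value_qc(amps2, sessions)
  expect_equal(out2$flags$mouse_id, "mut2")

  # limits depend only on wildtype values
  amps3 <- data.table::copy(amps2)
  amps3[mouse_id == "mut2", amplitude_uV := 1e6]
  expect_equal(extreme_value_qc(amps3, sessions)$limits, out2$limits)

  # < 2 wildtype values -> configuration error
  expect_error(extreme_value_qc(amp_row(c("wt1", "mut1"), "L", c(1, 2)),
                                sessions), "configuration error")
})

test_that("extreme_value_qc recovers planted gross outliers exactly", {
  set.seed(11)
  n_wt <- 60; n_mut <- 40
  sessions <- data.table::data.table(
    mouse_id = c(sprintf("wt%02d", 1:n_wt), sprintf("mu%02d", 1:n_mut)),
    strain_id = rep(c("C57BL/6NJ", "Mutx"), c(n_wt, n_mut)),
    zygosity = rep(c("wildtype", "homozygous"), c(n_wt, n_mut)),
    sex = "F", test_date = as.Date("2020-01-06"), batch_id = "w01")
  vals <- rnorm(n_wt + n_mut, 200, 20)
  planted <- c("mu01", "mu07", "wt03", "mu22", "wt41")
  ids <- sessions$mouse_id
  vals[ids %in% planted] <- 200 + sample(c(-1, 1), 5, TRUE) * 6 * 20
  out <- extreme_value_qc(amp_row(ids, "L", vals), sessions)
  expect_setequal(out$flags$mouse_id, planted)
})

test_that("sample_size_gate applies the n >= 5 threshold per condition", {
  sessions <- data.table::data.table(
    mouse_id = sprintf("m%02d", 1:6), strain_id = "Mutx",
    zygosity = "homozygous", sex = "M",
    test_date = as.Date("2020-01-06"), batch_id = "w01")
  # 6 scotopic-passing, 4 photopic-passing (2 flagged photopic)
  flags <- data.table::data.table(
    mouse_id = c("m01", "m02"), stage = "mad", condition = "photopic",
    detail = "")
  gate <- sample_size_gate(sessions, flags)
  expect_true(gate[condition == "scotopic", eligible])
  expect_false(gate[condition == "photopic", eligible])
  expect_equal(gate[condition == "photopic", n_pass], 4)

  # exactly 5 passing -> eligible
  gate2 <- sample_size_gate(sessions[1:5], NULL)
  expect_true(all(gate2$eligible))

  # 0 passing -> ineligible everywhere
  flags3 <- data.table::data.table(mouse_id = sessions$mouse_id, stage = "mad",
                                   condition = NA_character_, detail = "")
  gate3 <- sample_size_gate(sessions, flags3)
  expect_false(any(gate3$eligible))
})
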