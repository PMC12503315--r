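# shared fixture cache so expensive cohorts are generated once per test run
.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function(name) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- make_fixture(name)
  .fx_cache[[name]]
}

screen_fixture <- function(name) {
  key <- paste0("screen_", name)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- suppressWarnings(
      run_screen(get_fixture(name)$cohort, verbose = FALSE))
  .fx_cache[[key]]
}

# hand-built scotopic trace: given values at specified times (ms), zero
# elsewhere, 2000 Hz, 20 ms pre-stimulus
spike_trace <- function(spikes_ms, spikes_uV, condition = "scotopic",
                        mouse_id = "m1", eye = "L", trial = 1L) {
  t_ms <- if (condition == "scotopic") seq(-20, 5000, by = 0.5) else seq(-10, 100, by = 0.5)
  s <- numeric(length(t_ms))
  for (i in seq_along(spikes_ms)) {
    # narrow triangular bump so the extremum sits exactly at the spike time
    s <- s + spikes_uV[i] * pmax(0, 1 - abs(t_ms - spikes_ms[i]) / 2)
  }
  erg_trace(mouse_id, eye, condition, trial, s)
}

# minimal complete cohort built by hand: n mice, all-zero traces
flat_cohort <- function(n_mice = 2, strains = rep("C57BL/6NJ", n_mice),
                        level = 0) {
  sessions <- data.table::data.table(
    mouse_id = sprintf("m%d", seq_len(n_mice)), strain_id = strains,
    zygosity = ifelse(strains == "C57BL/6NJ", "wildtype", "homozygous"),
    sex = rep(c("M", "F"), length.out = n_mice),
    test_date = as.Date("2020-01-06"), batch_id = "w01")
  rows <- list()
  for (m in sessions$mouse_id) for (e in c("L", "R")) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      mouse_id = m, eye = e, condition = "scotopic", trial = 1:3,
      sample_rate_hz = 2000, t0_offset_s = 0.02,
      samples = replicate(3, rep(level, 10041), simplify = FALSE))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      mouse_id = m, eye = e, condition = "photopic", trial = 1:20,
      sample_rate_hz = 2000, t0_offset_s = 0.01,
      samples = replicate(20, rep(level, 221), simplify = FALSE))
  }
  erg_cohort(sessions, data.table::rbindlist(rows), provenance = "helper")
}

expect_flagged <- function(flags, mouse, cond) {
  testthat::expect_true(any(flags$mouse_id == mouse & flags$condition == cond))
}
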