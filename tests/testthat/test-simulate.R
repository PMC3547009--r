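# The synthetic-EEG generator: component injection, noise statistics,
# cohort structure and artifact injection.

small_block <- function(n_trials = 12, n_deviants = 0, seed = 1) {
  generate_block(n_trials, n_deviants, 5, 11, seed = seed,
                 block = list(syllable = "fu", contrast = "T1/T6",
                              deviant_tone = "T6"))
}

test_that("zero noise and no components give an all-zero recording", {
  rec <- simulate_block(small_block(), noise = noise_spec(0), seed = 1)
  expect_true(all(rec$data == 0))
  expect_equal(rec$rate, 500)
  expect_true(all(diff(rec$events$sample) == 600))
})

test_that("identical seeds reproduce identical recordings", {
  sq <- small_block(12, 1, seed = 3)
  a <- simulate_block(sq, effects = list(component_spec("MMN", -1)),
                      noise = noise_spec(2), seed = 7)
  b <- simulate_block(sq, effects = list(component_spec("MMN", -1)),
                      noise = noise_spec(2), seed = 7)
  expect_identical(a$data, b$data)
  c <- simulate_block(sq, effects = list(component_spec("MMN", -1)),
                      noise = noise_spec(2), seed = 8)
  expect_false(identical(c$data, a$data))
})

test_that("topographies are FCz-maximal with weight 1 in the analysis reference", {
  m <- build_paper_montage()
  spec <- component_spec("MMN", -1)
  w <- component_topography(spec, m)
  eff <- w - mean(w[m$mastoids])
  expect_equal(unname(eff["FCz"]), 1)
  expect_equal(unname(which.max(eff)), match("FCz", m$labels))
  expect_true(all(w[m$mastoids] < 0))
})

test_that("noise-free injected MMN is recovered exactly at the divergence-locked latency", {
  sq <- generate_block(seed = 2, block = list(syllable = "fu",
                                              contrast = "T1/T6",
                                              deviant_tone = "T6"))
  rec <- simulate_block(sq, effects = list(component_spec("MMN", -1,
                                                          peak_latency_ms = 132)),
                        noise = noise_spec(0), seed = 1)
  ep <- epoch_recording(rec)
  ep <- baseline_correct(ep)
  ep <- rereference_mastoids(ep)
  srt <- sort_trials(sq)
  w <- build_difference_waves(ep, srt)
  wave <- w$true$data["FCz", ]
  i <- which.min(wave)
  ## divergence 100 ms for T1/T6, so the trough sits at 232 ms post onset
  expect_equal(ep$times_ms[i], 232)
  expect_equal(min(wave), -1, tolerance = 0.05)
  ## the dummy wave is flat until the upcoming deviant's tail leaks in
  expect_lt(max(abs(w$dummy$data["FCz", ep$times_ms <= 700])), 1e-9)

  ## sharper oracle: the wave equals the injected band-limited template
  ## (baseline-shifted) wherever no neighbouring trial's component leaks in
  wf <- mmnpipe:::.component_waveform(component_spec("MMN", -1,
                                                     peak_latency_ms = 132),
                                      500)
  tmpl <- numeric(length(ep$times_ms))
  centre_ms <- 100 + 132
  pos <- round((ep$times_ms - centre_ms) * 500 / 1000)
  hit <- match(pos, wf$offsets)
  tmpl[!is.na(hit)] <- wf$values[hit[!is.na(hit)]]
  expected <- tmpl - mean(tmpl[ep$times_ms < 0])
  sel <- ep$times_ms <= 700
  expect_equal(wave[sel], expected[sel], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("standard-average variance follows the sigma^2/n closed form", {
  sq <- small_block(20, 0)
  sigma <- 5
  vals <- matrix(NA_real_, 200, 3)
  for (k in 1:200) {
    rec <- simulate_block(sq, noise = noise_spec(sigma), seed = 1000 + k)
    ep <- epoch_recording(rec)
    avg <- rowMeans(ep$data, dims = 2)
    vals[k, ] <- c(avg["FCz", 100], avg["Pz", 500], avg["C3", 800])
  }
  v <- apply(vals, 2, stats::var)
  expect_true(all(abs(v - sigma^2 / 20) / (sigma^2 / 20) < 0.30))
  expect_lt(abs(mean(v) - sigma^2 / 20) / (sigma^2 / 20), 0.15)
})

test_that("cohorts carry two labelled groups with per-participant jitter", {
  plan <- build_experiment(1, seed = 1, n_trials = 14, n_deviants = 1)
  coh <- simulate_cohort(20, plan, noise = noise_spec(1), seed = 5)
  expect_equal(nrow(coh$participants), 40)
  expect_equal(as.integer(table(coh$participants$group)), c(20L, 20L))
  expect_gt(stats::sd(coh$participants$latency_shift_ms), 5)
  ## deterministic rebuild
  coh2 <- simulate_cohort(20, plan, noise = noise_spec(1), seed = 5)
  expect_identical(coh$participants, coh2$participants)
})

test_that("group-specific effects land only in the specified group", {
  plan <- build_experiment(1, seed = 2, n_trials = 16, n_deviants = 1)
  tbl <- default_effect_table()
  tbl$components <- lapply(seq_len(nrow(tbl)), function(i) {
    if (tbl$group[i] == "control" && tbl$syllable[i] == "fu" &&
        tbl$contrast[i] == "T1/T6")
      list(component_spec("P3a", 2)) else list()
  })
  coh <- simulate_cohort(1, plan, effect_table = tbl,
                         noise = noise_spec(0), seed = 3,
                         latency_jitter_sd_ms = 0,
                         amplitude_jitter_frac = 0, obligatory = list())
  rec_ctl <- realize_recording(coh, "S01", 1)
  rec_dis <- realize_recording(coh, "S02", 1)
  expect_identical(coh$participants$group, c("control", "dissociation"))
  expect_gt(max(abs(rec_ctl$data)), 0.5)
  expect_equal(max(abs(rec_dis$data)), 0)
})

test_that("zero-effect zero-noise cohorts produce all-zero data", {
  plan <- build_experiment(1, seed = 2, n_trials = 14, n_deviants = 1)
  tbl <- default_effect_table()
  tbl$components <- lapply(seq_len(nrow(tbl)), function(i) list())
  coh <- simulate_cohort(1, plan, effect_table = tbl,
                         noise = noise_spec(0), seed = 3, obligatory = list())
  expect_true(all(realize_recording(coh, 1, 1)$data == 0))
})

test_that("artifact injection is honest about what it wrote", {
  sq <- small_block(15, 0)
  rec <- simulate_block(sq, noise = noise_spec(1), seed = 4)
  same <- inject_artifacts(rec, c(blink = 0, drift = 0, extreme = 0),
                           seed = 1)
  expect_identical(same$recording$data, rec$data)
  expect_equal(nrow(same$log), 0)

  art <- inject_artifacts(rec, c(blink = 0, drift = 0, extreme = 1),
                          seed = 2)
  expect_equal(nrow(art$log), 15)
  ## every epoch now fails the ±300 µV rule on unfiltered data
  ep <- epoch_recording(art$recording)
  res <- reject_artifacts(ep, rules = list(extreme_uv = 300, abs_uv = NULL,
                                           trend_uv = NULL,
                                           improbable_sd = NULL,
                                           kurtosis_sd = NULL))
  expect_equal(res$report$per_rule[["extreme"]], 15)

  ## a single extreme excursion takes out exactly that epoch
  one <- rec
  one$data["Cz", rec$events$sample[7] + 50:75] <- 400
  ep1 <- epoch_recording(one)
  r1 <- reject_artifacts(ep1, rules = list(extreme_uv = 300, abs_uv = NULL,
                                           trend_uv = NULL,
                                           improbable_sd = NULL,
                                           kurtosis_sd = NULL))
  expect_identical(which(!ep1$trial_index %in% r1$epochs$trial_index), 7L)
})

test_that("blink artifacts land on frontal channels at the stated rate", {
  sq <- small_block(40, 0)
  rec <- simulate_block(sq, noise = noise_spec(0), seed = 4)
  art <- inject_artifacts(rec, c(blink = 0.5, drift = 0, extreme = 0),
                          seed = 9)
  expect_gt(nrow(art$log), 8)
  expect_lt(nrow(art$log), 32)
  expect_true(all(art$log$type == "blink"))
  expect_gt(max(abs(art$recording$data["FPz", ])), 100)
  expect_equal(max(abs(art$recording$data["Pz", ])), 0)
})
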