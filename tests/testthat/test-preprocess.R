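# Filtering, epoching, baseline, re-referencing and the rejection rules.

tiny_recording <- function(nch = 4, ns = 4000, rate = 500, sd = 1,
                           seed = 1, labels = c("FCz", "Cz", "M1", "M2")) {
  set.seed(seed)
  data <- matrix(stats::rnorm(nch * ns, sd = sd), nch,
                 dimnames = list(labels, NULL))
  ev <- data.frame(sample = c(600, 1800, 3000),
                   label = c("standard", "standard", "deviant"),
                   stimulus_id = "fu6", stringsAsFactors = FALSE)
  new_recording(data, rate, ev, build_paper_montage())
}

test_that("the bandpass is zero-phase with the specified gain bounds", {
  t <- (1:5000) / 500
  mk <- function(v) new_recording(matrix(v, 1, dimnames = list("FCz", NULL)),
                                  500, data.frame(sample = integer(0),
                                                  label = character(0),
                                                  stimulus_id = character(0)),
                                  build_paper_montage())
  z <- bandpass(mk(rep(0, 5000)))
  expect_true(all(z$data == 0))
  g10 <- bandpass(mk(sin(2 * pi * 10 * t)))
  expect_gte(max(abs(g10$data[1, 2000:3000])), 0.95)
  expect_lte(max(abs(g10$data[1, 2000:3000])), 1.05)
  g50 <- bandpass(mk(sin(2 * pi * 50 * t)))
  expect_lte(max(abs(g50$data[1, 2000:3000])), 0.1)
  ## zero phase: a symmetric pulse keeps its centre of mass
  pulse <- exp(-((1:5000) - 2500)^2 / (2 * 15^2))
  fp <- bandpass(mk(pulse))$data[1, ]
  expect_equal(which.max(fp), 2500, tolerance = 1)
  expect_error(bandpass(mk(pulse), 20, 1), "invalid band edges")
  expect_error(bandpass(mk(pulse), 0, 20), "invalid band edges")
})

test_that("epoching is exact index arithmetic with boundary logging", {
  rec <- tiny_recording()
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data), c(4, 900, 3))
  expect_equal(range(ep$times_ms), c(-800, 998))
  ## the sample at time 0 is the recording sample at the event
  i0 <- which(ep$times_ms == 0)
  for (j in 1:3)
    expect_equal(ep$data[, i0, j], rec$data[, rec$events$sample[j]],
                 ignore_attr = TRUE)
  expect_equal(ep$data[, 1, 2], rec$data[, 1800 - 0.8 * 500],
               ignore_attr = TRUE)
  ## an event 100 ms from the start cannot host an 800 ms baseline
  rec2 <- rec
  rec2$events <- rbind(data.frame(sample = 50, label = "standard",
                                  stimulus_id = "fu6"), rec$events)
  expect_warning(ep2 <- epoch_recording(rec2), "skipped")
  expect_equal(dim(ep2$data)[3], 3)
  expect_equal(ep2$log$n_skipped, 1)
  expect_identical(ep2$trial_index, 2:4)
})

test_that("baseline correction zeroes the pre-stimulus mean and shifts bumps rigidly", {
  rec <- tiny_recording()
  ep <- epoch_recording(rec)
  ## constant offset vanishes entirely
  cp <- ep
  cp$data[] <- 3.25
  bc <- baseline_correct(cp)
  expect_true(all(abs(bc$data) < 1e-12))
  ## generic epochs: baseline means are 0 within 1e-9
  b2 <- baseline_correct(ep)
  pre <- b2$times_ms < 0
  expect_lt(max(abs(apply(b2$data[, pre, , drop = FALSE], c(1, 3), mean))),
            1e-9)
  ## a post-stimulus bump is preserved, shifted by minus the baseline mean
  one <- ep
  one$data[] <- 0
  bump <- exp(-(one$times_ms - 300)^2 / (2 * 40^2))
  one$data[1, , 1] <- 2 + bump          # offset 2, bump on top
  b3 <- baseline_correct(one)
  expect_equal(b3$data[1, , 1], bump - mean(bump[pre]) +
                 2 - 2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mean-mastoid re-referencing is the stated algebra", {
  rec <- tiny_recording()
  ep <- baseline_correct(epoch_recording(rec))
  rr <- rereference_mastoids(ep)
  ## explicit algebra on the pre-transform signals
  expect_equal(rr$data["FCz", , ],
               ep$data["FCz", , ] - (ep$data["M1", , ] + ep$data["M2", , ]) / 2,
               tolerance = 1e-12)
  ## transformed mastoids average to zero pointwise
  expect_lt(max(abs(rr$data["M1", , ] + rr$data["M2", , ])), 1e-12)
  ## identical signal on all channels cancels completely
  same <- ep
  same$data[] <- rep(ep$data[1, , ], each = 4)
  expect_true(all(abs(rereference_mastoids(same)$data) < 1e-12))
  ## opposite-sign mastoid weights boost the fronto-central signal
  topo <- ep
  topo$data[] <- 0
  topo$data["FCz", , ] <- 1
  topo$data["M1", , ] <- -0.2
  topo$data["M2", , ] <- -0.2
  expect_equal(max(rereference_mastoids(topo)$data["FCz", , ]), 1.2)
  ## a montage without mastoid channels errors
  noM <- epoch_recording(tiny_recording(labels = c("FCz", "Cz", "F3", "F4")))
  noM <- baseline_correct(noM)
  expect_error(rereference_mastoids(noM), "missing mastoid")
})

test_that("each rejection rule fires on its constructed violation and only then", {
  set.seed(8)
  nt <- 450
  d <- array(stats::rnorm(3 * nt * 40, sd = 1), c(3, nt, 40),
             dimnames = list(c("FCz", "Cz", "Pz"), NULL, NULL))
  ep <- make_epochs(d, pre_ms = 100)
  clean <- reject_artifacts(ep)
  expect_equal(clean$report$n_removed, 0)
  expect_equal(clean$report$pct_removed, 0)

  ## 150 µV excursion -> 100 µV rule but not the ±300 µV extreme rule
  d2 <- d; d2[2, 200:210, 5] <- 150
  r2 <- reject_artifacts(make_epochs(d2, pre_ms = 100))
  expect_equal(unname(r2$report$per_rule["amplitude"]), 1)
  expect_false(5 %in% r2$epochs$trial_index)
  r2e <- reject_artifacts(make_epochs(d2, pre_ms = 100,
                                      stages = c("filter", "epoch")),
                          rules = list(extreme_uv = 300, abs_uv = NULL,
                                       trend_uv = NULL, improbable_sd = NULL,
                                       kurtosis_sd = NULL))
  expect_equal(unname(r2e$report$per_rule["extreme"]), 0)

  ## linear ramp spanning 100 µV fails the 75 µV trend rule; 60 µV passes
  ramp <- seq(-50, 50, length.out = nt)
  d3 <- d; d3[1, , 7] <- d3[1, , 7] + ramp
  fit <- stats::lm(d3[1, , 7] ~ seq_len(nt))       # least-squares oracle
  expect_gt(abs(stats::coef(fit)[2]) * (nt - 1), 75)
  r3 <- reject_artifacts(make_epochs(d3, pre_ms = 100))
  expect_gte(unname(r3$report$per_rule["trend"]), 1)
  expect_false(7 %in% r3$epochs$trial_index)
  d4 <- d; d4[1, , 7] <- d4[1, , 7] + 0.6 * ramp
  r4 <- reject_artifacts(make_epochs(d4, pre_ms = 100),
                         rules = list(extreme_uv = NULL, abs_uv = NULL,
                                      trend_uv = 75, improbable_sd = NULL,
                                      kurtosis_sd = NULL))
  expect_equal(unname(r4$report$per_rule["trend"]), 0)

  ## improbable data: one wild sample far beyond 5 across-trial SDs
  d5 <- d; d5[3, 111, 9] <- 30
  r5 <- reject_artifacts(make_epochs(d5, pre_ms = 100),
                         rules = list(extreme_uv = NULL, abs_uv = NULL,
                                      trend_uv = NULL, improbable_sd = 5,
                                      kurtosis_sd = NULL))
  expect_true(9 %in% which(!ep$trial_index %in% r5$epochs$trial_index))

  ## abnormal distribution: heavy spike train inflates kurtosis
  d6 <- d
  d6[2, seq(10, nt, by = 45), 11] <- 12
  r6 <- reject_artifacts(make_epochs(d6, pre_ms = 100),
                         rules = list(extreme_uv = NULL, abs_uv = NULL,
                                      trend_uv = NULL, improbable_sd = NULL,
                                      kurtosis_sd = 5))
  expect_true(11 %in% which(!ep$trial_index %in% r6$epochs$trial_index))
})

test_that("drop = FALSE flags survivors without copying the array", {
  set.seed(9)
  d <- array(stats::rnorm(3 * 200 * 12), c(3, 200, 12),
             dimnames = list(c("FCz", "Cz", "Pz"), NULL, NULL))
  d[1, 50, 4] <- 200
  epA <- reject_artifacts(make_epochs(d, pre_ms = 100))$epochs
  epB <- reject_artifacts(make_epochs(d, pre_ms = 100), drop = FALSE)$epochs
  expect_identical(epB$surviving, epA$trial_index)
  expect_equal(dim(epB$data)[3], 12)
  expect_equal(dim(epA$data)[3], length(epA$surviving))
})

test_that("the stage-state flag enforces the pipeline order", {
  rec <- tiny_recording()
  ep <- epoch_recording(rec)
  expect_error(rereference_mastoids(ep), "requires stage 'baseline'")
  expect_error(reject_artifacts(ep, rules = rejection_rules()),
               "requires stage 'rereference'")
  expect_error(baseline_correct(structure(list(stages = character(0)),
                                          class = "mmn_epochs")),
               "requires stage 'epoch'")
})

test_that("the ICA hook passes through by default and applies a supplied cleaner", {
  rec <- tiny_recording()
  ep <- epoch_recording(rec)
  h <- ica_hook(ep)
  expect_identical(h$data, ep$data)
  expect_true("ica" %in% h$stages)
  h2 <- ica_hook(ep, function(arr, e) arr * 0)
  expect_true(all(h2$data == 0))
})

test_that("preprocess_recording equals the composed stage functions", {
  rec <- tiny_recording(nch = 64, ns = 4000, sd = 2, seed = 3,
                        labels = build_paper_montage()$labels)
  a <- preprocess_recording(rec)
  f <- bandpass(rec)
  e <- epoch_recording(f)
  e <- reject_artifacts(e, rules = list(extreme_uv = 300, abs_uv = NULL,
                                        trend_uv = NULL, improbable_sd = NULL,
                                        kurtosis_sd = NULL))$epochs
  e <- ica_hook(e)
  e <- baseline_correct(e)
  e <- rereference_mastoids(e)
  e <- reject_artifacts(e)$epochs
  expect_equal(a$data, e$data, tolerance = 1e-12)
  expect_identical(a$surviving, e$surviving)
  expect_setequal(a$stages, c("filter", "epoch", "extreme_scan", "ica",
                              "baseline", "rereference", "reject"))
})
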