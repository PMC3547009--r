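# Synthetic multi-channel EEG recordings of the oddball experiment: the
# stand-in for the study's unavailable raw data.
#
# ERP components are modelled as band-limited Gaussian pulses: a Gaussian
# envelope conditioned once on the 1-20 Hz analysis band and renormalised to
# unit peak. (A raw Gaussian keeps a sizable fraction of its peak below
# 1 Hz; no high-passed acquisition/analysis chain could then reproduce its
# nominal amplitude, so nominal amplitudes are defined in the band the
# pipeline analyses.) Topographies are spherical caps decaying with angular
# distance from a fronto-central maximum, with opposite-sign mastoid lobes;
# weights are normalised so that after mean-mastoid re-referencing the
# component's value at its topographic maximum equals `amplitude_uv`.

#' Specify an ERP component to inject
#'
#' @param kind "MMN", "P3a", "N1" or "P2". MMN and P3a are deviant-only
#'   components, time-locked to the block's divergence point; N1/P2 are
#'   obligatory components time-locked to stimulus onset and injected into
#'   every trial (so they cancel in difference waves).
#' @param amplitude_uv signed peak amplitude (µV) at the topography maximum
#'   in the mean-mastoid reference; MMN must be negative, P3a positive.
#' @param peak_latency_ms peak time in ms, post-divergence for MMN/P3a,
#'   post-stimulus-onset for obligatory components.
#' @param width_ms Gaussian envelope SD (> 0).
#' @param center channel of the topographic maximum.
#' @param spread angular SD (radians) of the spherical-cap topography.
#' @param mastoid_weight raw opposite-sign weight at M1/M2 (mean-mastoid
#'   re-referencing then boosts the fronto-central value, as for real MMN
#'   topographies).
#' @return A \code{component_spec} list.
#' @export
component_spec <- function(kind = c("MMN", "P3a", "N1", "P2"),
                           amplitude_uv,
                           peak_latency_ms = switch(kind, MMN = 132,
                                                    P3a = 202, N1 = 100,
                                                    P2 = 200),
                           width_ms = switch(kind, MMN = 50, P3a = 60, 40),
                           center = "FCz", spread = 0.9,
                           mastoid_weight = -0.15) {
  kind <- match.arg(kind)
  stopifnot(width_ms > 0)
  if (kind == "MMN" && amplitude_uv > 0)
    stop("MMN polarity must be negative at fronto-central sites")
  if (kind == "P3a" && amplitude_uv < 0)
    stop("P3a polarity must be positive at fronto-central sites")
  structure(list(kind = kind, amplitude_uv = amplitude_uv,
                 peak_latency_ms = peak_latency_ms, width_ms = width_ms,
                 center = center, spread = spread,
                 mastoid_weight = mastoid_weight,
                 locked_to = if (kind %in% c("MMN", "P3a")) "divergence"
                 else "onset"),
            class = "component_spec")
}

#' Per-channel topography weights of a component
#'
#' Spherical-cap decay from the component's centre channel, opposite-sign
#' lobes at the mastoids, scaled so the centre-channel weight equals 1
#' after mean-mastoid re-referencing.
#'
#' @param spec a \code{component_spec}.
#' @param montage an \code{mmn_montage}.
#' @return Named numeric vector over the montage channels.
#' @export
component_topography <- function(spec, montage) {
  pos <- montage$positions
  ctr <- pos[spec$center, ]
  ang <- angular_distance(pos, ctr)
  w <- exp(-ang^2 / (2 * spec$spread^2))
  w[match(montage$mastoids, montage$labels)] <- spec$mastoid_weight
  eff <- w[match(spec$center, montage$labels)] -
    mean(w[match(montage$mastoids, montage$labels)])
  w <- w / eff
  stats::setNames(w, montage$labels)
}

## Band-limited unit-peak waveform of a component on the recording grid.
## Returned as (offsets in samples relative to the locking event, values).
.component_waveform <- function(spec, rate, band = c(1, 20)) {
  dt <- 1000 / rate
  half <- round(1500 / dt)            # ±1.5 s support: holds filter ringing
  offs <- seq(-half, half)
  g <- exp(-(offs * dt)^2 / (2 * spec$width_ms^2))
  filt <- design_bandpass(rate, band[1], band[2])
  ## condition on the analysis band over a long zero-padded window
  gf <- .apply_bandpass(matrix(g, 1), filt)[1, ]
  gf <- gf / gf[half + 1]             # renormalise to unit peak at centre
  keep <- abs(offs * dt) <= 700       # crop to the part that matters
  list(offsets = offs[keep], values = gf[keep] * spec$amplitude_uv)
}

#' Background-noise specification
#'
#' @param sd_uv standard deviation of the stationary zero-mean background
#'   noise per channel and sample, µV.
#' @param spectrum "white" or "one_over_f".
#' @param alpha_amplitude_uv amplitude of an optional 10 Hz rhythm.
#' @param artifact_rates named per-trial probabilities (blink, drift,
#'   extreme) used by \code{\link{inject_artifacts}}.
#' @return A \code{noise_spec} list.
#' @export
noise_spec <- function(sd_uv = 10, spectrum = c("white", "one_over_f"),
                       alpha_amplitude_uv = 0,
                       artifact_rates = c(blink = 0, drift = 0, extreme = 0)) {
  spectrum <- match.arg(spectrum)
  stopifnot(sd_uv >= 0, all(artifact_rates >= 0 & artifact_rates <= 1))
  structure(list(sd_uv = sd_uv, spectrum = spectrum,
                 alpha_amplitude_uv = alpha_amplitude_uv,
                 artifact_rates = artifact_rates), class = "noise_spec")
}

.background_noise <- function(nch, ns, rate, noise) {
  if (noise$sd_uv <= 0) {
    x <- matrix(0, nch, ns)
  } else if (noise$spectrum == "white") {
    x <- stats::rnorm(nch * ns, sd = noise$sd_uv)
    dim(x) <- c(nch, ns)
  } else {
    ## 1/f amplitude shaping in the frequency domain, unit-variance rescale
    x <- matrix(stats::rnorm(nch * ns), nch, ns)
    f <- seq(0, rate, length.out = ns + 1)[seq_len(ns)]
    f <- pmin(f, rate - f)
    scale <- 1 / sqrt(pmax(f, 1))     # flat below 1 Hz
    x <- t(apply(x, 1, function(ch) {
      y <- Re(stats::fft(stats::fft(ch) * scale, inverse = TRUE)) / ns
      y / stats::sd(y)
    })) * noise$sd_uv
  }
  if (noise$alpha_amplitude_uv > 0) {
    tsec <- seq_len(ns) / rate
    ph <- stats::runif(nch, 0, 2 * pi)
    x <- x + noise$alpha_amplitude_uv *
      sin(outer(ph, 2 * pi * 10 * tsec, "+"))
  }
  x
}

#' Simulate one continuous oddball block recording
#'
#' Produces a vertex-referenced 64-channel recording at 500 Hz: stationary
#' zero-mean background noise, obligatory components (N1/P2) on every trial,
#' and deviant components (MMN/P3a) on deviant trials, time-locked to the
#' block's divergence point. The recording starts 1 s before the first
#' stimulus and ends 1 s after the last trial's offset.
#'
#' @param seq a valid \code{trial_sequence} with a block descriptor.
#' @param effects list of \code{component_spec}s for deviant trials (may be
#'   empty).
#' @param noise a \code{noise_spec}.
#' @param montage an \code{mmn_montage}.
#' @param seed integer seed; identical seeds give identical recordings.
#' @param rate sampling rate (500 Hz).
#' @param obligatory list of \code{component_spec}s injected into all
#'   trials.
#' @return An \code{mmn_recording}.
#' @export
simulate_block <- function(seq, effects = list(), noise = noise_spec(),
                           montage = build_paper_montage(), seed = 1L,
                           rate = 500, obligatory = list()) {
  stopifnot(inherits(seq, "trial_sequence"))
  bad <- validate_sequence(seq)
  if (length(bad)) stop("invalid trial sequence: ", bad[1])
  if (!is.null(seq$block)) {
    div_ms <- contrast_divergence(seq$block$syllable, seq$block$contrast,
                                  rate)
  } else {
    div_ms <- 0
  }
  set.seed(as.integer(seed))
  pad <- as.integer(rate)              # 1 s before first / after last trial
  onset_samples <- pad + 1L + as.integer(round(seq$onsets_ms * rate / 1000))
  ns <- max(onset_samples) + round(1.2 * rate) + pad
  nch <- length(montage$labels)
  data <- .background_noise(nch, ns, rate, noise)
  rownames(data) <- montage$labels
  ## accumulate each component's time course once, then add all topographies
  ## with a single matrix product
  specs <- c(lapply(obligatory, function(s) list(spec = s, deviant = FALSE)),
             lapply(effects, function(s) list(spec = s, deviant = TRUE)))
  if (length(specs)) {
    topo_mat <- matrix(0, nch, length(specs))
    course <- matrix(0, length(specs), ns)
    for (k in seq_along(specs)) {
      spec <- specs[[k]]$spec
      wf <- .component_waveform(spec, rate)
      topo_mat[, k] <- component_topography(spec, montage)
      lock_ms <- if (spec$locked_to == "divergence") div_ms else 0
      centre <- onset_samples + round((lock_ms + spec$peak_latency_ms) *
                                        rate / 1000)
      if (specs[[k]]$deviant) centre <- centre[seq$labels == "deviant"]
      for (s in centre) {
        cols <- s + wf$offsets
        ok <- cols >= 1 & cols <= ns
        course[k, cols[ok]] <- course[k, cols[ok]] + wf$values[ok]
      }
    }
    data <- cpp_add_outer(data, topo_mat, course)   # in place: data is owned
  }
  events <- data.frame(sample = onset_samples, label = seq$labels,
                       stimulus_id = seq$stimulus_ids %||%
                         rep(NA_character_, length(seq$labels)),
                       stringsAsFactors = FALSE)
  new_recording(data, rate, events, montage,
                meta = list(block = seq$block, divergence_ms = div_ms,
                            seed = seed))
}

#' Default obligatory (N1/P2) components
#'
#' Injected identically into standards and deviants so they cancel in
#' difference waves.
#' @return List of two \code{component_spec}s.
#' @export
default_obligatory <- function() {
  list(component_spec("N1", amplitude_uv = -0.8, peak_latency_ms = 100,
                      center = "Cz"),
       component_spec("P2", amplitude_uv = 0.6, peak_latency_ms = 200,
                      center = "Cz"))
}

#' Default effect table reproducing the study's qualitative result pattern
#'
#' Control group: MMN and P3a for the lexical T1/T6 contrast, weak MMN for
#' nonlexical T1/T6 and lexical T4/T6, nothing for nonlexical T4/T6.
#' Dissociation group: MMN for lexical T1/T6 only (zero MMN for its T4/T6
#' deviants).
#'
#' @param strong_mmn,weak_mmn,p3a default amplitudes (µV).
#' @return Data frame with columns group, syllable, contrast and a
#'   list-column \code{components}.
#' @export
default_effect_table <- function(strong_mmn = -1, weak_mmn = -0.4, p3a = 1) {
  rows <- list(
    list(group = "control", syllable = "fu", contrast = "T1/T6",
         components = list(component_spec("MMN", strong_mmn),
                           component_spec("P3a", p3a))),
    list(group = "control", syllable = "fu", contrast = "T4/T6",
         components = list(component_spec("MMN", weak_mmn,
                                          peak_latency_ms = 136))),
    list(group = "control", syllable = "lu", contrast = "T1/T6",
         components = list(component_spec("MMN", weak_mmn))),
    list(group = "control", syllable = "lu", contrast = "T4/T6",
         components = list()),
    list(group = "dissociation", syllable = "fu", contrast = "T1/T6",
         components = list(component_spec("MMN", strong_mmn))),
    list(group = "dissociation", syllable = "fu", contrast = "T4/T6",
         components = list()),
    list(group = "dissociation", syllable = "lu", contrast = "T1/T6",
         components = list()),
    list(group = "dissociation", syllable = "lu", contrast = "T4/T6",
         components = list())
  )
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(group = r$group, syllable = r$syllable,
               contrast = r$contrast, stringsAsFactors = FALSE)))
  df$components <- lapply(rows, `[[`, "components")
  df
}

.effects_for <- function(effect_table, group, syllable, contrast) {
  i <- which(effect_table$group == group &
               effect_table$syllable == syllable &
               effect_table$contrast == contrast)
  if (length(i) == 0) return(list())
  effect_table$components[[i[1]]]
}

#' Simulate a cohort of participants
#'
#' Two groups of simulated participants, each with per-participant latency
#' and amplitude jitter applied to every deviant component. Recordings are
#' not materialised by default (a full cohort would not fit in memory);
#' instead the returned object carries the per-participant realisations and
#' \code{\link{realize_recording}} produces any participant x block
#' recording on demand, reproducibly.
#'
#' @param n_per_group participants per group (>= 1).
#' @param plan an \code{experiment_plan}.
#' @param effect_table see \code{\link{default_effect_table}}.
#' @param noise a \code{noise_spec}.
#' @param seed master seed.
#' @param groups group labels.
#' @param latency_jitter_sd_ms SD of the per-participant latency shift
#'   (25 ms, matching the order of magnitude of published between-subject
#'   latency dispersion).
#' @param amplitude_jitter_frac SD of the per-participant multiplicative
#'   amplitude factor (0.1).
#' @param obligatory obligatory components, all trials.
#' @return An \code{mmn_cohort}: participant table (id, group, jitters,
#'   seed) plus the simulation ingredients.
#' @export
simulate_cohort <- function(n_per_group, plan,
                            effect_table = default_effect_table(),
                            noise = noise_spec(), seed = 1L,
                            groups = c("control", "dissociation"),
                            latency_jitter_sd_ms = 25,
                            amplitude_jitter_frac = 0.1,
                            obligatory = default_obligatory()) {
  stopifnot(n_per_group >= 1)
  set.seed(as.integer(seed))
  n <- n_per_group * length(groups)
  participants <- data.frame(
    id = sprintf("S%02d", seq_len(n)),
    group = rep(groups, each = n_per_group),
    latency_shift_ms = stats::rnorm(n, 0, latency_jitter_sd_ms),
    amplitude_factor = pmax(stats::rnorm(n, 1, amplitude_jitter_frac), 0),
    seed = vapply(seq_len(n), function(i) child_seed(seed, i), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(participants = participants, plan = plan,
                 effect_table = effect_table, noise = noise,
                 obligatory = obligatory, seed = seed),
            class = "mmn_cohort")
}

#' @export
print.mmn_cohort <- function(x, ...) {
  cat(sprintf("<mmn_cohort> %d participants (%s), %d blocks planned\n",
              nrow(x$participants),
              paste(table(x$participants$group), collapse = "+"),
              length(x$plan$blocks)))
  invisible(x)
}

#' Materialise one participant x block recording of a cohort
#'
#' @param cohort an \code{mmn_cohort}.
#' @param participant participant id or row index.
#' @param block index into the cohort's experiment plan, or a
#'   \code{trial_sequence}.
#' @param montage montage (default: the paper template).
#' @param rate sampling rate.
#' @return An \code{mmn_recording} with the participant's jittered effects.
#' @export
realize_recording <- function(cohort, participant, block,
                              montage = build_paper_montage(), rate = 500) {
  p <- if (is.character(participant))
    cohort$participants[cohort$participants$id == participant, ]
  else cohort$participants[participant, , drop = FALSE]
  stopifnot(nrow(p) == 1)
  seq <- if (inherits(block, "trial_sequence")) block else
    cohort$plan$blocks[[block]]
  effects <- .effects_for(cohort$effect_table, p$group, seq$block$syllable,
                          seq$block$contrast)
  effects <- lapply(effects, function(spec) {
    spec$peak_latency_ms <- spec$peak_latency_ms + p$latency_shift_ms
    spec$amplitude_uv <- spec$amplitude_uv * p$amplitude_factor
    spec
  })
  blk_id <- if (inherits(block, "trial_sequence")) 0L else block
  simulate_block(seq, effects = effects, noise = cohort$noise,
                 montage = montage,
                 seed = child_seed(p$seed, blk_id), rate = rate,
                 obligatory = cohort$obligatory)
}

#' Inject blink, drift and extreme-amplitude artifacts
#'
#' Trials are selected independently with the spec's per-trial
#' probabilities. Blinks are 150 ms Gaussian deflections on frontal
#' channels; drifts are linear ramps spanning \code{drift_span_uv} across
#' the epoch window; extreme artifacts are rectangular excursions exceeding
#' the ±300 µV rule.
#'
#' @param recording an \code{mmn_recording}.
#' @param rates named per-trial probabilities (blink, drift, extreme).
#' @param seed integer seed.
#' @param blink_uv,drift_span_uv,extreme_uv artifact magnitudes.
#' @return List with the modified \code{recording} and an injection
#'   \code{log} data.frame (trial, type, amplitude).
#' @export
inject_artifacts <- function(recording,
                             rates = c(blink = 0, drift = 0, extreme = 0),
                             seed = 1L, blink_uv = 150, drift_span_uv = 100,
                             extreme_uv = 400) {
  stopifnot(all(rates >= 0 & rates <= 1))
  set.seed(as.integer(seed))
  ev <- recording$events
  rate <- recording$rate
  labs <- rownames(recording$data)
  frontal <- intersect(c("FP1", "FPz", "FP2", "AF3", "AF4"), labs)
  npre <- round(0.8 * rate); npost <- rate
  log <- list()
  for (i in seq_len(nrow(ev))) {
    s <- ev$sample[i]
    win <- (s - npre):(s + npost - 1)
    win <- win[win >= 1 & win <= ncol(recording$data)]
    if (stats::runif(1) < (rates["blink"] %||% 0)) {
      t0 <- sample(win, 1)
      offs <- round(-0.15 * rate):round(0.15 * rate)
      cols <- t0 + offs
      okc <- cols >= 1 & cols <= ncol(recording$data)
      bump <- blink_uv * exp(-(offs * 1000 / rate)^2 / (2 * 50^2))
      recording$data[frontal, cols[okc]] <-
        recording$data[frontal, cols[okc]] +
        matrix(bump[okc], length(frontal), sum(okc), byrow = TRUE)
      log[[length(log) + 1]] <- data.frame(trial = i, type = "blink",
                                           amplitude = blink_uv)
    }
    if (stats::runif(1) < (rates["drift"] %||% 0)) {
      ch <- sample(setdiff(labs, recording$montage$mastoids), 1)
      ramp <- seq(-drift_span_uv / 2, drift_span_uv / 2,
                  length.out = length(win))
      recording$data[ch, win] <- recording$data[ch, win] + ramp
      log[[length(log) + 1]] <- data.frame(trial = i, type = "drift",
                                           amplitude = drift_span_uv)
    }
    if (stats::runif(1) < (rates["extreme"] %||% 0)) {
      ch <- sample(setdiff(labs, recording$montage$mastoids), 1)
      t0 <- sample(win[win <= max(win) - round(0.05 * rate)], 1)
      cols <- t0:(t0 + round(0.05 * rate))
      recording$data[ch, cols] <- recording$data[ch, cols] + extreme_uv
      log[[length(log) + 1]] <- data.frame(trial = i, type = "extreme",
                                           amplitude = extreme_uv)
    }
  }
  list(recording = recording,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(trial = integer(0), type = character(0),
                    amplitude = numeric(0)))
}
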