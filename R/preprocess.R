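# The preprocessing chain: bandpass filtering, epoching, baseline
# correction, mean-mastoid re-referencing, and the four artifact-rejection
# rules. Stages must run in the fixed order
#   filter -> epoch -> [ICA hook] -> baseline -> re-reference -> reject
# which is enforced by a stage-state flag carried on the recording/epoch
# objects. The heavy inner loops (IIR filtering, epoch cutting, scan
# statistics) are implemented in C++; the exported functions are thin,
# composable wrappers around them.

#' Construct a continuous multi-channel recording
#'
#' @param data channels x samples matrix in microvolts; rownames are channel
#'   labels.
#' @param rate sampling rate in Hz.
#' @param events data.frame with columns \code{sample} (1-based, strictly
#'   increasing), \code{label} ("standard"/"deviant"), \code{stimulus_id}.
#' @param montage the \code{mmn_montage} the channels belong to.
#' @param reference label of the online reference.
#' @param meta optional list of block metadata (condition, divergence, seed).
#' @return An object of class \code{mmn_recording}.
#' @export
new_recording <- function(data, rate, events, montage, reference = "Cz",
                          meta = list()) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  if (nrow(events) > 0) {
    stopifnot(all(diff(events$sample) > 0))
  }
  structure(list(data = data, rate = rate, events = events,
                 montage = montage, reference = reference,
                 stages = character(0), meta = meta),
            class = "mmn_recording")
}

#' @export
print.mmn_recording <- function(x, ...) {
  cat(sprintf(
    "<mmn_recording> %d channels x %d samples @ %g Hz, %d events [%s]\n",
    nrow(x$data), ncol(x$data), x$rate, nrow(x$events),
    if (length(x$stages)) paste(x$stages, collapse = ",") else "raw"))
  invisible(x)
}

## Filter design: zero-phase Butterworth, high-pass order 2 + low-pass
## order 4, each applied forward-backward. The half-filters are kept at
## orders where the transfer-function form is numerically well conditioned
## at EEG band edges.
design_bandpass <- function(rate, low_hz = 1, high_hz = 20) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2))
    stop(sprintf("invalid band edges: need 0 < low (%g) < high (%g) < rate/2 (%g)",
                 low_hz, high_hz, rate / 2))
  list(hp = signal::butter(2, low_hz / (rate / 2), type = "high"),
       lp = signal::butter(4, high_hz / (rate / 2), type = "low"),
       rate = rate)
}

## zero-phase application to rows of a matrix (odd-reflection padding)
.apply_bandpass <- function(x, filt, npad = 3 * filt$rate) {
  out <- cpp_filtfilt_rows(x, filt$hp$b, filt$hp$a, filt$lp$b, filt$lp$a,
                           as.integer(npad))
  rownames(out) <- rownames(x)
  out
}

#' Zero-phase bandpass filter of a continuous recording
#'
#' 1-20 Hz by default, applied forward-backward (no group delay). Passband
#' gain at 10 Hz is within 5% of unity and a 50 Hz component is attenuated
#' by more than 20 dB.
#'
#' @param recording an \code{mmn_recording}.
#' @param low_hz,high_hz band edges in Hz, \code{0 < low < high < rate/2}.
#' @return The filtered recording, with stage flag "filter" set.
#' @export
bandpass <- function(recording, low_hz = 1, high_hz = 20) {
  stopifnot(inherits(recording, "mmn_recording"))
  filt <- design_bandpass(recording$rate, low_hz, high_hz)
  out <- recording
  out$data <- .apply_bandpass(recording$data, filt)
  out$stages <- union(recording$stages, "filter")
  out$meta$band <- c(low_hz, high_hz)
  out
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Each event yields one epoch of \code{pre_ms + post_ms} (default 1800 ms:
#' an 800 ms pre-stimulus interval and 1000 ms post-stimulus). The sample at
#' time 0 is the recording sample at the event. Events whose window falls
#' outside the recording are skipped and counted in the log.
#'
#' @param recording an \code{mmn_recording} (normally already filtered).
#' @param events optional events data.frame (default: the recording's own).
#' @param pre_ms,post_ms window extent around stimulus onset, ms.
#' @return An \code{mmn_epochs} object: list with \code{data} (channels x
#'   time x trials), \code{times_ms} (-pre .. +post), \code{labels},
#'   \code{stimulus_ids}, \code{trial_index} (position in the event list),
#'   \code{rate}, \code{montage}, \code{stages}, \code{log}.
#' @export
epoch_recording <- function(recording, events = recording$events,
                            pre_ms = 800, post_ms = 1000) {
  stopifnot(inherits(recording, "mmn_recording"))
  rate <- recording$rate
  npre <- round(pre_ms * rate / 1000)
  npost <- round(post_ms * rate / 1000)
  nt <- npre + npost
  ns <- ncol(recording$data)
  ok <- events$sample - npre >= 1 & events$sample + npost - 1 <= ns
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(sprintf("%d event(s) too close to the recording edge; skipped",
                    n_skipped))
  ev <- events[ok, , drop = FALSE]
  dat <- cpp_epoch_build(recording$data, as.integer(ev$sample), npre, npost)
  dimnames(dat) <- list(rownames(recording$data), NULL, NULL)
  structure(list(
    data = dat,
    times_ms = seq(-npre, npost - 1L) * 1000 / rate,
    labels = ev$label,
    stimulus_ids = ev$stimulus_id,
    trial_index = which(ok),
    rate = rate,
    montage = recording$montage,
    meta = recording$meta,
    stages = union(recording$stages, "epoch"),
    log = list(n_events = nrow(events), n_epochs = nrow(ev),
               n_skipped = n_skipped)
  ), class = "mmn_epochs")
}

#' @export
print.mmn_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mmn_epochs> %d ch x %d samples x %d trials @ %g Hz [%s]\n",
              d[1], d[2], d[3], x$rate, paste(x$stages, collapse = ",")))
  invisible(x)
}

.require_stage <- function(epochs, stage, op) {
  if (!stage %in% epochs$stages)
    stop(sprintf("%s requires stage '%s' to have run first (stages so far: %s)",
                 op, stage, paste(epochs$stages, collapse = ", ")))
}

#' ICA hook
#'
#' Pass-through hook for an external Independent Component Analysis
#' implementation. The pipeline never reimplements ICA; supply \code{fun} to
#' call one (it receives and must return the channels x time x trials
#' array). With \code{fun = NULL} (the default, appropriate for synthetic
#' data) the epochs pass through unchanged apart from the stage flag.
#'
#' @param epochs an \code{mmn_epochs}.
#' @param fun NULL or function(array, epochs) -> array.
#' @return The (possibly cleaned) epochs with stage flag "ica".
#' @export
ica_hook <- function(epochs, fun = NULL) {
  .require_stage(epochs, "epoch", "ica_hook")
  if (!is.null(fun)) epochs$data <- fun(epochs$data, epochs)
  epochs$stages <- union(epochs$stages, "ica")
  epochs
}

.mastoid_idx <- function(epochs, montage) {
  m <- montage$mastoids
  i <- match(m, dimnames(epochs$data)[[1]])
  if (anyNA(i))
    stop("missing mastoid channel(s): ",
         paste(m[is.na(i)], collapse = ", "))
  i
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and trial, the mean over the pre-stimulus interval
#' (times < 0), so the baseline mean becomes exactly zero.
#'
#' @param epochs an \code{mmn_epochs}.
#' @return Corrected epochs with stage flag "baseline".
#' @export
baseline_correct <- function(epochs) {
  .require_stage(epochs, "epoch", "baseline_correct")
  npre <- sum(epochs$times_ms < 0)
  if (npre == 0) stop("epochs carry no pre-stimulus samples")
  d <- dim(epochs$data)
  epochs$data <- cpp_baseline_reref(epochs$data + 0, d[1], d[2], d[3],
                                    npre, 0L, 0L, TRUE, FALSE)
  epochs$stages <- union(epochs$stages, "baseline")
  epochs
}

#' Re-reference epochs to the mean of the mastoids
#'
#' Every channel x becomes x - (M1 + M2)/2, computed from the pre-transform
#' signals; afterwards the mean of the transformed mastoids is identically
#' zero.
#'
#' @param epochs a baseline-corrected \code{mmn_epochs}.
#' @param montage montage supplying the mastoid labels.
#' @return Re-referenced epochs with stage flag "rereference".
#' @export
rereference_mastoids <- function(epochs, montage = epochs$montage) {
  .require_stage(epochs, "baseline", "rereference_mastoids")
  mi <- .mastoid_idx(epochs, montage)
  d <- dim(epochs$data)
  epochs$data <- cpp_baseline_reref(epochs$data + 0, d[1], d[2], d[3],
                                    0L, mi[1] - 1L, mi[2] - 1L, FALSE, TRUE)
  epochs$reference <- "mean-mastoids"
  epochs$stages <- union(epochs$stages, "rereference")
  epochs
}

#' Artifact-rejection rule set
#'
#' @param extreme_uv absolute-amplitude bound of the pre-ICA extreme-trial
#'   scan (±300 µV).
#' @param abs_uv absolute-amplitude bound of the final scan (100 µV).
#' @param trend_uv maximal least-squares linear trend across the epoch
#'   (|slope| x epoch duration), 75 µV.
#' @param improbable_sd per-sample deviation bound in units of the
#'   across-trial SD at the same channel and latency (5 SD).
#' @param kurtosis_sd bound on the across-trial z-score of per-epoch
#'   (log-)kurtosis (5 SD).
#' @return A list of thresholds; set an element to NULL to disable the rule.
#' @export
rejection_rules <- function(extreme_uv = 300, abs_uv = 100, trend_uv = 75,
                            improbable_sd = 5, kurtosis_sd = 5) {
  list(extreme_uv = extreme_uv, abs_uv = abs_uv, trend_uv = trend_uv,
       improbable_sd = improbable_sd, kurtosis_sd = kurtosis_sd)
}

#' Scan epochs for artifacts and drop offending trials
#'
#' A trial is removed if any enabled rule fires on any analysis channel
#' (scalp channels; mastoids are not scanned). Rules: absolute amplitude
#' (±300 µV extreme scan, 100 µV final scan), least-squares linear trend
#' greater than 75 µV across the epoch, improbable data beyond 5
#' across-trial SDs at the same channel and latency, and abnormal
#' distributions whose per-epoch kurtosis sits beyond 5 SD of the
#' across-trial kurtosis distribution (z-scored on the log scale, since the
#' sampling distribution of kurtosis is strongly right-skewed).
#'
#' @param epochs an \code{mmn_epochs}.
#' @param rules a \code{\link{rejection_rules}} list. The ±300 µV extreme
#'   scan may run any time after epoching; the remaining rules require
#'   re-referenced data.
#' @param channels channels to scan (default: the montage's analysis
#'   channels present in the data).
#' @param drop if TRUE (default) offending trials are removed from the
#'   returned epochs; if FALSE the data are kept intact and only the
#'   \code{surviving} index (original trial numbering) is recorded, which
#'   avoids copying large arrays in pipeline use.
#' @return List with \code{epochs} (survivors; rejection info appended to
#'   the log; element \code{surviving} lists the surviving original trial
#'   indices) and \code{report}: per-rule counts, total removed, percentage.
#' @export
reject_artifacts <- function(epochs, rules = rejection_rules(),
                             channels = NULL, drop = TRUE) {
  .require_stage(epochs, "epoch", "reject_artifacts")
  full_scan <- !is.null(rules$abs_uv) || !is.null(rules$trend_uv) ||
    !is.null(rules$improbable_sd) || !is.null(rules$kurtosis_sd)
  if (full_scan) .require_stage(epochs, "rereference", "reject_artifacts")
  labs <- dimnames(epochs$data)[[1]]
  channels <- channels %||% intersect(epochs$montage$analysis_labels, labs)
  ci <- match(channels, labs)
  d <- dim(epochs$data)
  ntr <- d[3]
  st <- cpp_artifact_scan(epochs$data, d[1], d[2], d[3], as.integer(ci),
                          full_scan,
                          if (full_scan && !is.null(rules$improbable_sd))
                            rules$improbable_sd else -1)
  fired <- list()
  if (!is.null(rules$extreme_uv))
    fired$extreme <- colSums(st$absmax > rules$extreme_uv) > 0
  if (!is.null(rules$abs_uv))
    fired$amplitude <- colSums(st$absmax > rules$abs_uv) > 0
  if (!is.null(rules$trend_uv))
    fired$trend <- colSums(st$span > rules$trend_uv) > 0
  if (!is.null(rules$improbable_sd) && ntr >= 3)
    fired$improbable <- as.logical(st$improbable)
  if (!is.null(rules$kurtosis_sd) && ntr >= 3) {
    lk <- log(pmax(st$kurt, 1e-12))
    km <- rowMeans(lk)
    ks <- sqrt(pmax(rowSums((lk - km)^2), 0) / (ntr - 1))
    ks[ks == 0] <- Inf
    fired$kurtosis <- colSums(abs(lk - km) / ks > rules$kurtosis_sd) > 0
  }
  fired <- lapply(fired, function(f) { f[is.na(f)] <- FALSE; f })
  any_fired <- Reduce(`|`, fired, rep(FALSE, ntr))
  keep <- !any_fired
  report <- list(per_rule = vapply(fired, sum, integer(1)),
                 n_trials = ntr, n_removed = sum(any_fired),
                 pct_removed = 100 * sum(any_fired) / max(ntr, 1),
                 channels_scanned = channels)
  out <- epochs
  if (drop) {
    if (!all(keep)) out$data <- epochs$data[, , keep, drop = FALSE]
    out$labels <- epochs$labels[keep]
    out$stimulus_ids <- epochs$stimulus_ids[keep]
    out$trial_index <- epochs$trial_index[keep]
  }
  out$surviving <- epochs$trial_index[keep]
  out$stages <- union(epochs$stages, if (full_scan) "reject" else
    "extreme_scan")
  out$log[[if (full_scan) "rejection" else "extreme_scan"]] <- report
  list(epochs = out, report = report)
}

#' Write / read epochs as a JSON header plus raw array
#'
#' The header (\code{<path>.json}) documents shape (channels, samples,
#' trials), sampling rate, time axis, channel labels, trial labels and the
#' stage flags; the array itself is stored as little-endian float64 in
#' channel-fastest order at \code{<path>}.
#'
#' @param epochs an \code{mmn_epochs}.
#' @param path path of the raw array file.
#' @rdname epochs_io
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  hdr <- list(n_channels = d[1], n_samples = d[2], n_trials = d[3],
              rate = epochs$rate, times_ms = epochs$times_ms,
              channels = dimnames(epochs$data)[[1]],
              labels = epochs$labels,
              stimulus_ids = epochs$stimulus_ids,
              trial_index = epochs$trial_index,
              stages = epochs$stages,
              dtype = "float64-little", order = "channel,time,trial")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @param montage montage to attach on read.
#' @rdname epochs_io
#' @export
read_epochs <- function(path, montage = build_paper_montage()) {
  hdr <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- hdr$n_channels * hdr$n_samples * hdr$n_trials
  con <- file(path, "rb")
  on.exit(close(con))
  data <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  dim(data) <- c(hdr$n_channels, hdr$n_samples, hdr$n_trials)
  dimnames(data) <- list(hdr$channels, NULL, NULL)
  structure(list(data = data, times_ms = hdr$times_ms,
                 labels = hdr$labels, stimulus_ids = hdr$stimulus_ids,
                 trial_index = hdr$trial_index, rate = hdr$rate,
                 montage = montage, meta = list(), stages = hdr$stages,
                 log = list()), class = "mmn_epochs")
}

#' Run the full preprocessing chain on a continuous recording
#'
#' filter -> epoch -> extreme-trial scan (±300 µV) -> ICA hook -> baseline ->
#' mean-mastoid re-reference -> remaining rejection rules, in the fixed
#' order. Identical to composing the exported stage functions; the
#' baseline/re-reference pair is fused into one in-place pass for speed.
#'
#' @param recording an \code{mmn_recording}.
#' @param low_hz,high_hz filter band (1-20 Hz).
#' @param pre_ms,post_ms epoch window (800/1000 ms).
#' @param rules rejection thresholds, see \code{\link{rejection_rules}}.
#' @param ica optional ICA function passed to \code{\link{ica_hook}}.
#' @param drop_rejected if FALSE, rejected trials of the final scan are
#'   flagged via the \code{surviving} index instead of being copied out of
#'   the array (see \code{\link{reject_artifacts}}).
#' @return The surviving \code{mmn_epochs} (rejection reports in the log).
#' @export
preprocess_recording <- function(recording, low_hz = 1, high_hz = 20,
                                 pre_ms = 800, post_ms = 1000,
                                 rules = rejection_rules(), ica = NULL,
                                 drop_rejected = TRUE) {
  rec <- bandpass(recording, low_hz, high_hz)
  ep <- epoch_recording(rec, pre_ms = pre_ms, post_ms = post_ms)
  pre <- reject_artifacts(ep, rules = list(extreme_uv = rules$extreme_uv,
                                           abs_uv = NULL, trend_uv = NULL,
                                           improbable_sd = NULL,
                                           kurtosis_sd = NULL))
  ep <- ica_hook(pre$epochs, ica)
  ## fused baseline + re-reference (the array is owned here, so in place)
  npre <- sum(ep$times_ms < 0)
  mi <- .mastoid_idx(ep, ep$montage)
  d <- dim(ep$data)
  ep$data <- cpp_baseline_reref(ep$data, d[1], d[2], d[3], npre,
                                mi[1] - 1L, mi[2] - 1L, TRUE, TRUE)
  ep$reference <- "mean-mastoids"
  ep$stages <- union(ep$stages, c("baseline", "rereference"))
  post <- reject_artifacts(ep, rules = list(extreme_uv = NULL,
                                            abs_uv = rules$abs_uv,
                                            trend_uv = rules$trend_uv,
                                            improbable_sd = rules$improbable_sd,
                                            kurtosis_sd = rules$kurtosis_sd),
                           drop = drop_rejected)
  post$epochs
}
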