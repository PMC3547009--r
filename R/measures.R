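# Trial sorting, true and dummy difference waves, MMN/P3a measurement.
#
# Surviving trials are sorted into (i) deviants, (ii) the standard
# immediately before each deviant, and (iii) the standard preceding each
# standard-before-a-deviant; a triplet is formed only when all three members
# survived rejection. avg(i) - avg(ii) is the true difference wave,
# avg(ii) - avg(iii) the dummy wave. MMN is the most negative peak at FCz in
# the 100-250 ms window post-divergence point; P3a the most positive peak
# after the individual MMN peak. Mean amplitudes are 100 ms window averages
# of (true - dummy).

#' Sort surviving trials into deviant / pre-deviant / pre-pre-deviant
#'
#' @param seq the block's \code{trial_sequence}.
#' @param surviving indices (into the original trial order) of trials that
#'   survived artifact rejection.
#' @return A \code{sorted_trials} list with index vectors \code{deviant},
#'   \code{std_before}, \code{std_before_that} (equal lengths, presentation
#'   order neighbours), and counts.
#' @export
sort_trials <- function(seq, surviving = seq_along(seq$labels)) {
  lab <- seq$labels
  dev <- which(lab == "deviant")
  dev <- dev[dev >= 3]
  ok <- dev %in% surviving & (dev - 1) %in% surviving &
    (dev - 2) %in% surviving &
    lab[dev - 1] == "standard" & lab[dev - 2] == "standard"
  dev <- dev[ok]
  structure(list(deviant = dev, std_before = dev - 1L,
                 std_before_that = dev - 2L,
                 n_triplets = length(dev),
                 n_deviants_total = sum(lab == "deviant")),
            class = "sorted_trials")
}

#' Build true and dummy difference waves from epochs
#'
#' @param epochs post-rejection \code{mmn_epochs} of one block.
#' @param sorted a \code{sorted_trials} for the same block (indices refer to
#'   the original trial order; the epochs' \code{trial_index} maps them).
#' @return List with \code{true} and \code{dummy}, each a
#'   \code{difference_wave}: channels x time matrix plus metadata
#'   (\code{kind}, \code{n_triplets}, \code{divergence_ms},
#'   \code{times_ms}).
#' @export
build_difference_waves <- function(epochs, sorted) {
  if (sorted$n_triplets < 1)
    stop("no surviving deviant triplets; cannot form difference waves")
  d <- dim(epochs$data)
  avg <- function(orig) {
    idx <- match(orig, epochs$trial_index)
    if (anyNA(idx)) stop("sorted trial indices missing from epochs")
    m <- cpp_trial_mean(epochs$data, d[1], d[2], d[3], as.integer(idx))
    rownames(m) <- dimnames(epochs$data)[[1]]
    m
  }
  a_i <- avg(sorted$deviant)
  a_ii <- avg(sorted$std_before)
  a_iii <- avg(sorted$std_before_that)
  mk <- function(kind, m) structure(
    list(kind = kind, data = m, times_ms = epochs$times_ms,
         rate = epochs$rate, n_triplets = sorted$n_triplets,
         divergence_ms = epochs$meta$divergence_ms %||% 0,
         block = epochs$meta$block), class = "difference_wave")
  list(true = mk("true", a_i - a_ii), dummy = mk("dummy", a_ii - a_iii))
}

#' @export
print.difference_wave <- function(x, ...) {
  cat(sprintf("<difference_wave> %s: %d ch x %d samples, %d triplets, divergence %g ms\n",
              x$kind, nrow(x$data), ncol(x$data), x$n_triplets,
              x$divergence_ms))
  invisible(x)
}

#' @export
plot.difference_wave <- function(x, channel = "FCz", ...) {
  graphics::plot(x$times_ms, x$data[channel, ], type = "l",
                 xlab = "time from stimulus onset (ms)",
                 ylab = sprintf("%s amplitude (uV)", channel),
                 main = sprintf("%s difference wave", x$kind), ...)
  graphics::abline(v = x$divergence_ms, lty = 2)
  invisible(x)
}

.peak_pick <- function(x, times, decreasing) {
  i <- if (decreasing) which.max(x) else which.min(x)  # earliest on ties
  list(i = i, boundary = i == 1L || i == length(x))
}

#' Measure the MMN on a difference wave
#'
#' Latency is the most negative sample at the given channel within the
#' search window post-divergence point (earliest sample on ties); a peak
#' sitting on a window edge is flagged, not rejected.
#'
#' @param wave a \code{difference_wave} (normally the true wave).
#' @param channel measurement electrode (FCz).
#' @param window_ms search window in ms post-divergence point (100-250).
#' @return A \code{component_measure}: list with \code{component},
#'   \code{peak_latency_ms} (post-divergence), \code{peak_amplitude_uv},
#'   \code{flags}.
#' @export
measure_mmn <- function(wave, channel = "FCz", window_ms = c(100, 250)) {
  div <- wave$divergence_ms
  t_abs <- div + window_ms
  sel <- wave$times_ms >= t_abs[1] & wave$times_ms <= t_abs[2]
  if (!any(sel)) stop("MMN search window lies outside the epoch")
  x <- wave$data[channel, sel]
  tms <- wave$times_ms[sel]
  p <- .peak_pick(-x, tms, decreasing = TRUE)
  structure(list(component = "MMN",
                 peak_latency_ms = tms[p$i] - div,
                 peak_amplitude_uv = x[p$i],
                 channel = channel,
                 flags = if (p$boundary) "boundary_peak" else character(0)),
            class = "component_measure")
}

#' Measure the P3a following an individual MMN peak
#'
#' The most positive sample strictly after the MMN peak (earliest on ties).
#' If the wave never goes positive there, the least-negative sample is
#' returned with a low-confidence flag so cohort tables stay rectangular.
#'
#' @param wave a \code{difference_wave}.
#' @param mmn the \code{component_measure} of this wave's MMN.
#' @param channel measurement electrode.
#' @return A \code{component_measure} for the P3a.
#' @export
measure_p3a <- function(wave, mmn, channel = "FCz") {
  div <- wave$divergence_ms
  sel <- wave$times_ms > div + mmn$peak_latency_ms
  if (!any(sel)) stop("no samples after the MMN peak to search for P3a")
  x <- wave$data[channel, sel]
  tms <- wave$times_ms[sel]
  p <- .peak_pick(x, tms, decreasing = TRUE)
  flags <- character(0)
  if (x[p$i] <= 0) flags <- c(flags, "low_confidence")
  if (p$boundary) flags <- c(flags, "boundary_peak")
  structure(list(component = "P3a",
                 peak_latency_ms = tms[p$i] - div,
                 peak_amplitude_uv = x[p$i],
                 channel = channel, flags = flags),
            class = "component_measure")
}

#' @export
print.component_measure <- function(x, ...) {
  cat(sprintf("<%s> peak %.2f uV at %g ms post-divergence%s\n", x$component,
              x$peak_amplitude_uv, x$peak_latency_ms,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Windowed mean amplitude of (true - dummy)
#'
#' Average over a window (100 ms by default) centred on a component peak,
#' post-divergence point, of the true minus the dummy difference wave.
#'
#' @param true_wave,dummy_wave \code{difference_wave}s of one condition.
#' @param center_ms window centre in ms post-divergence (e.g. the grand
#'   average peaks 132/136 ms for MMN, 202 ms for P3a).
#' @param width_ms window width (100 ms).
#' @param channel measurement electrode.
#' @return Mean amplitude in µV.
#' @export
mean_amplitude <- function(true_wave, dummy_wave, center_ms, width_ms = 100,
                           channel = "FCz") {
  stopifnot(identical(true_wave$times_ms, dummy_wave$times_ms))
  div <- true_wave$divergence_ms
  lo <- div + center_ms - width_ms / 2
  hi <- div + center_ms + width_ms / 2
  sel <- true_wave$times_ms >= lo & true_wave$times_ms <= hi
  if (!any(sel) || lo < min(true_wave$times_ms) ||
      hi > max(true_wave$times_ms))
    stop("amplitude window overflows the epoch")
  mean(true_wave$data[channel, sel] - dummy_wave$data[channel, sel])
}

## Grand-average window centres (ms post-divergence) used for cohort tables:
## MMN 132 ms (T1/T6 conditions), 136 ms (fu T4/T6), P3a 202 ms.
WINDOW_CENTERS <- c(mmn = 132, mmn_fu_t4t6 = 136, p3a = 202)

#' Per-participant measures table for one condition
#'
#' @param waves result of \code{\link{build_difference_waves}}.
#' @param participant,group,condition identifiers copied into the rows.
#' @param centers named window centres (ms post-divergence) for the mean
#'   amplitudes; \code{NULL} recomputes them from this wave's own peaks.
#' @param channel measurement electrode.
#' @return Tidy data.frame: participant, group, condition, component,
#'   peak_latency_ms, peak_amplitude_uv, mean_amplitude_uv, flags.
#' @export
measure_condition <- function(waves, participant = NA, group = NA,
                              condition = NA, centers = NULL,
                              channel = "FCz") {
  mmn <- measure_mmn(waves$true, channel = channel)
  p3a <- measure_p3a(waves$true, mmn, channel = channel)
  c_mmn <- if (is.null(centers)) mmn$peak_latency_ms else centers[["mmn"]]
  c_p3a <- if (is.null(centers)) p3a$peak_latency_ms else centers[["p3a"]]
  amp <- function(centre) mean_amplitude(waves$true, waves$dummy, centre,
                                         channel = channel)
  data.frame(
    participant = participant, group = group, condition = condition,
    component = c("MMN", "P3a"),
    peak_latency_ms = c(mmn$peak_latency_ms, p3a$peak_latency_ms),
    peak_amplitude_uv = c(mmn$peak_amplitude_uv, p3a$peak_amplitude_uv),
    mean_amplitude_uv = c(amp(c_mmn), amp(c_p3a)),
    flags = c(paste(mmn$flags, collapse = ";"),
              paste(p3a$flags, collapse = ";")),
    stringsAsFactors = FALSE)
}
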