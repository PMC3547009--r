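# Schematic pitch contours of the tone/syllable conditions and divergence
# points between condition pairs.
#
# All syllables share a 100 ms unvoiced onset (F0 = 0) and a 300 ms vowel.
# T1 is level-high and T6 level-low; their contours first differ at vowel
# onset (100 ms post-stimulus onset). T4 equals T6 sample-for-sample before
# the pair's divergence point (200 ms for fu, 180 ms for lu) and then follows
# a linear segment whose endpoint is solved so that the vowel-mean F0 matches
# the configured per-condition mean. The segment is anchored one sample
# period before the divergence point, so the first sample at which the two
# contours differ is exactly the divergence time.

## per-condition vowel-mean F0 (Hz) and T4/T6 divergence points (ms)
F0_DEFAULTS <- list(
  fu = c(T1 = 254.9, T4 = 178.6, T6 = 170.9),
  lu = c(T1 = 284.7, T4 = 180.2, T6 = 184.3)
)
T4_DIVERGENCE_MS <- c(fu = 200, lu = 180)
ONSET_DUR_MS <- 100
VOWEL_DUR_MS <- 300

#' Synthesize a schematic pitch contour
#'
#' @param syllable "fu" (lexical) or "lu" (nonlexical).
#' @param tone "T1", "T4" or "T6".
#' @param sampling_rate samples per second of the F0 track (default 500).
#' @param f0_params named list like \code{F0_DEFAULTS}: per-syllable named
#'   vectors of vowel-mean F0 in Hz.
#' @param t4_divergence_ms per-syllable T4/T6 divergence points (ms
#'   post-stimulus onset).
#' @return A \code{pitch_contour}: list with \code{syllable}, \code{tone},
#'   \code{times_ms}, \code{f0_hz}, \code{onset_dur_ms}, \code{vowel_dur_ms}.
#'   The vowel-segment mean of \code{f0_hz} equals the configured mean.
#' @examples
#' mean(vowel_f0(synthesize_contour("fu", "T1")))  # 254.9
#' @export
synthesize_contour <- function(syllable, tone, sampling_rate = 500,
                               f0_params = F0_DEFAULTS,
                               t4_divergence_ms = T4_DIVERGENCE_MS) {
  if (!syllable %in% names(f0_params))
    stop("unknown syllable: ", syllable)
  if (!tone %in% names(f0_params[[syllable]]))
    stop("unknown tone: ", tone)
  dt <- 1000 / sampling_rate
  n <- round((ONSET_DUR_MS + VOWEL_DUR_MS) * sampling_rate / 1000)
  times <- seq(0, by = dt, length.out = n)
  vowel <- times >= ONSET_DUR_MS
  total_ms <- ONSET_DUR_MS + VOWEL_DUR_MS
  means <- f0_params[[syllable]]
  f0 <- numeric(n)
  if (tone %in% c("T1", "T6")) {
    f0[vowel] <- means[[tone]]
  } else {
    m6 <- means[["T6"]]
    target <- means[["T4"]]
    d <- t4_divergence_ms[[syllable]]
    post <- vowel & times >= d
    ## linear segment through anchor (d - dt, m6); endpoint e at total_ms
    ## solved so the discrete vowel mean equals `target`
    u <- (times[post] - d + dt) / (total_ms - d + dt)
    e <- m6 + (target - m6) * sum(vowel) / sum(u)
    f0[vowel] <- m6
    f0[post] <- m6 + (e - m6) * u
  }
  structure(list(syllable = syllable, tone = tone, times_ms = times,
                 f0_hz = f0, onset_dur_ms = ONSET_DUR_MS,
                 vowel_dur_ms = VOWEL_DUR_MS, rate = sampling_rate),
            class = "pitch_contour")
}

#' Vowel-segment F0 samples of a contour
#' @param contour a \code{pitch_contour}.
#' @return Numeric vector of F0 over the voiced (vowel) segment.
#' @export
vowel_f0 <- function(contour) {
  contour$f0_hz[contour$times_ms >= contour$onset_dur_ms]
}

#' @export
print.pitch_contour <- function(x, ...) {
  cat(sprintf("<pitch_contour> %s %s: %d samples @ %g Hz, vowel mean %.1f Hz\n",
              x$syllable, x$tone, length(x$f0_hz), x$rate,
              mean(vowel_f0(x))))
  invisible(x)
}

#' @export
plot.pitch_contour <- function(x, ...) {
  graphics::plot(x$times_ms, x$f0_hz, type = "l", xlab = "time (ms)",
                 ylab = "F0 (Hz)",
                 main = paste(x$syllable, x$tone), ...)
  invisible(x)
}

.check_grids <- function(a, b) {
  if (a$syllable != b$syllable)
    stop("contours belong to different syllables: ", a$syllable, " vs ",
         b$syllable)
  if (length(a$times_ms) != length(b$times_ms) ||
      any(abs(a$times_ms - b$times_ms) > 1e-9))
    stop("contours are sampled on mismatched time grids")
}

#' Divergence point between two pitch contours
#'
#' The earliest time at which the absolute F0 difference exceeds
#' \code{tol_hz} and stays above it for the remainder of the syllable.
#'
#' @param a,b \code{pitch_contour}s on the same syllable and time grid.
#' @param tol_hz difference tolerance in Hz (0 for noise-free synthetic
#'   contours).
#' @return Time in ms post-stimulus onset, or \code{NA} if the contours
#'   never (persistently) differ.
#' @examples
#' divergence_point(synthesize_contour("fu", "T4"),
#'                  synthesize_contour("fu", "T6"))  # 200
#' @export
divergence_point <- function(a, b, tol_hz = 0) {
  .check_grids(a, b)
  over <- abs(a$f0_hz - b$f0_hz) > tol_hz
  if (!any(over)) return(NA_real_)
  below <- which(!over)
  first <- if (length(below) == 0) 1L else max(below) + 1L
  if (first > length(over)) return(NA_real_)
  a$times_ms[first]
}

#' Vowel-mean F0 difference between two contours
#'
#' Mean F0 of \code{a} over the vowel segment minus that of \code{b}.
#'
#' @inheritParams divergence_point
#' @return Difference in Hz.
#' @export
mean_f0_difference <- function(a, b) {
  .check_grids(a, b)
  mean(vowel_f0(a)) - mean(vowel_f0(b))
}

#' Divergence point of a block's tonal contrast
#'
#' Synthesizes the two contours of the contrast and runs the divergence
#' detector; T1/T6 diverges at vowel onset (100 ms), T4/T6 at 200 ms (fu)
#' or 180 ms (lu).
#'
#' @param syllable "fu" or "lu".
#' @param contrast "T1/T6" or "T4/T6".
#' @param sampling_rate F0 track rate, Hz.
#' @return Time in ms post-stimulus onset.
#' @export
contrast_divergence <- function(syllable, contrast, sampling_rate = 500) {
  tones <- strsplit(contrast, "/", fixed = TRUE)[[1]]
  divergence_point(synthesize_contour(syllable, tones[1], sampling_rate),
                   synthesize_contour(syllable, tones[2], sampling_rate))
}

#' Export a pitch contour as two-column CSV (time_ms, f0_hz)
#' @param contour a \code{pitch_contour}.
#' @param path file path.
#' @export
write_contour <- function(contour, path) {
  utils::write.csv(data.frame(time_ms = contour$times_ms,
                              f0_hz = contour$f0_hz),
                   path, row.names = FALSE)
  invisible(path)
}
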