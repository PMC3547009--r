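# Oddball trial sequences and the 8-block experiment layout.
#
# A block is a constrained randomized sequence of standards and deviants:
# under the study defaults 535 trials of which 80 are deviants, a minimum of
# five and a maximum of 11 standards between consecutive deviants, at least
# two leading standards (so every deviant later contributes a full
# deviant / standard-before-deviant / standard-before-that triplet), an
# unconstrained trailing run, and a constant 1200 ms onset-to-onset interval
# (400 ms syllable + 800 ms inter-stimulus interval).

DESIGN_DEFAULTS <- list(n_trials = 535L, n_deviants = 80L, min_gap = 5L,
                        max_gap = 11L, soa_ms = 1200, syllable_ms = 400,
                        isi_ms = 800, lead_min = 2L)

#' Is an oddball block design feasible?
#'
#' TRUE iff at least one label sequence exists with \code{n_deviants}
#' deviants among \code{n_trials} trials, runs of standards between
#' consecutive deviants within \code{[min_gap, max_gap]}, and at least two
#' leading standards before the first deviant.
#'
#' @param n_trials,n_deviants,min_gap,max_gap nonnegative integer counts.
#' @return logical.
#' @examples
#' is_feasible(535, 80, 5, 11)   # the study's block parameters
#' is_feasible(6, 2, 5, 11)      # too few standards
#' @export
is_feasible <- function(n_trials, n_deviants, min_gap, max_gap) {
  stopifnot(n_trials >= 0, n_deviants >= 0, min_gap >= 0,
            max_gap >= min_gap)
  if (n_deviants > n_trials) return(FALSE)
  if (n_deviants == 0) return(TRUE)
  n_std <- n_trials - n_deviants
  n_std >= DESIGN_DEFAULTS$lead_min + (n_deviants - 1) * min_gap
}

## Composition counts: number of ways d gaps in [min_gap, max_gap] sum to s,
## as a double vector indexed by s = 0..smax. Used both by the sampler and by
## the exhaustive-enumeration oracle in the tests.
.gap_count_table <- function(d, min_gap, max_gap, smax) {
  counts <- matrix(0, nrow = d + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  w <- max_gap - min_gap
  for (k in seq_len(d)) {
    prev <- counts[k, ]
    cur <- numeric(smax + 1L)
    for (g in min_gap:max_gap) {
      if (g <= smax)
        cur[(g + 1L):(smax + 1L)] <- cur[(g + 1L):(smax + 1L)] +
          prev[1L:(smax - g + 1L)]
    }
    counts[k + 1L, ] <- cur
  }
  counts
}

#' Generate one oddball block
#'
#' Draws uniformly from the set of all label sequences satisfying the design
#' constraints (deviant count, inter-deviant gap bounds, leading-standard
#' minimum of two, unconstrained trailing run). Sampling is exact: a
#' dynamic-programming table of constrained gap compositions is used to draw
#' the gap vector sequentially, then the leading run is drawn uniformly over
#' its feasible range and the trailing run absorbs the remainder.
#'
#' @param n_trials,n_deviants,min_gap,max_gap design counts; see
#'   \code{\link{is_feasible}}.
#' @param seed integer seed; identical seeds reproduce identical sequences.
#' @param block optional block descriptor, a list with \code{syllable}
#'   ("fu" lexical / "lu" nonlexical), \code{contrast} ("T1/T6" or "T4/T6"),
#'   and \code{deviant_tone}. Stimulus identities are derived from it.
#' @param soa_ms onset-to-onset interval (default 1200 ms).
#' @return A \code{trial_sequence}: list with \code{labels}
#'   ("standard"/"deviant"), \code{stimulus_ids}, \code{onsets_ms},
#'   \code{block}, and the design parameters.
#' @export
generate_block <- function(n_trials = DESIGN_DEFAULTS$n_trials,
                           n_deviants = DESIGN_DEFAULTS$n_deviants,
                           min_gap = DESIGN_DEFAULTS$min_gap,
                           max_gap = DESIGN_DEFAULTS$max_gap,
                           seed = 1L,
                           block = NULL,
                           soa_ms = DESIGN_DEFAULTS$soa_ms) {
  if (!is_feasible(n_trials, n_deviants, min_gap, max_gap)) {
    n_std <- n_trials - n_deviants
    need <- DESIGN_DEFAULTS$lead_min + max(n_deviants - 1, 0) * min_gap
    stop(sprintf(paste0("infeasible design: %d standards cannot supply a ",
                        "%d-trial leading run plus %d inter-deviant runs of ",
                        "at least %d (needs >= %d standards)"),
                 n_std, DESIGN_DEFAULTS$lead_min,
                 max(n_deviants - 1, 0), min_gap, need))
  }
  set.seed(as.integer(seed))
  labels <- rep("standard", n_trials)
  if (n_deviants >= 1L) {
    n_std <- n_trials - n_deviants
    lead_min <- DESIGN_DEFAULTS$lead_min
    d <- n_deviants - 1L                      # number of inter-deviant gaps
    budget <- n_std - lead_min                # standards available to gaps + extras
    if (d == 0L) {
      s <- 0L
    } else {
      tab <- .gap_count_table(d, min_gap, max_gap, budget)
      ## weight each total gap sum s by the number of (lead, trail) splits of
      ## the remainder: lead in [lead_min, lead_min + budget - s]
      s_range <- 0:budget
      w <- tab[d + 1L, ] * (budget - s_range + 1)
      s <- s_range[sample.int(length(s_range), 1L, prob = w)]
    }
    ## sequential conditional draw of each gap
    gaps <- integer(d)
    rem <- s
    if (d > 0L) {
      tab <- .gap_count_table(d, min_gap, max_gap, s)
      for (k in seq_len(d)) {
        left <- d - k                          # gaps remaining after this one
        gvals <- min_gap:max_gap
        pr <- vapply(gvals, function(g) {
          r <- rem - g
          if (r < 0) return(0)
          tab[left + 1L, r + 1L]
        }, numeric(1))
        g <- gvals[sample.int(length(gvals), 1L, prob = pr)]
        gaps[k] <- g
        rem <- rem - g
      }
    }
    extra <- budget - s                        # split between lead and trail
    lead <- lead_min + sample.int(extra + 1L, 1L) - 1L
    pos <- lead + 1L + cumsum(c(0L, gaps + 1L))
    labels[pos] <- "deviant"
  }
  stim <- NULL
  if (!is.null(block)) {
    tones <- strsplit(block$contrast, "/", fixed = TRUE)[[1]]
    std_tone <- setdiff(tones, block$deviant_tone)
    stopifnot(length(std_tone) == 1L)
    stim <- ifelse(labels == "deviant",
                   paste0(block$syllable, sub("T", "", block$deviant_tone)),
                   paste0(block$syllable, sub("T", "", std_tone)))
  }
  structure(list(
    labels = labels,
    stimulus_ids = stim,
    onsets_ms = seq(0, by = soa_ms, length.out = n_trials),
    block = block,
    params = list(n_trials = n_trials, n_deviants = n_deviants,
                  min_gap = min_gap, max_gap = max_gap, soa_ms = soa_ms,
                  lead_min = DESIGN_DEFAULTS$lead_min, seed = seed)
  ), class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  b <- if (is.null(x$block)) "unlabelled block" else
    sprintf("%s %s, deviant %s", x$block$syllable, x$block$contrast,
            x$block$deviant_tone)
  cat(sprintf("<trial_sequence> %s: %d trials, %d deviants, SOA %g ms\n",
              b, length(x$labels), sum(x$labels == "deviant"),
              x$params$soa_ms))
  invisible(x)
}

#' Validate a trial sequence against design parameters
#'
#' @param seq a \code{trial_sequence}.
#' @param n_trials,n_deviants,min_gap,max_gap,soa_ms expected design values
#'   (default: the sequence's own parameters).
#' @return A character vector of violations; empty iff the sequence is valid.
#' @export
validate_sequence <- function(seq,
                              n_trials = seq$params$n_trials,
                              n_deviants = seq$params$n_deviants,
                              min_gap = seq$params$min_gap,
                              max_gap = seq$params$max_gap,
                              soa_ms = seq$params$soa_ms) {
  viol <- character(0)
  lab <- seq$labels
  if (length(lab) != n_trials)
    viol <- c(viol, sprintf("trial count %d != expected %d",
                            length(lab), n_trials))
  ndev <- sum(lab == "deviant")
  if (ndev != n_deviants)
    viol <- c(viol, sprintf("deviant count %d != expected %d",
                            ndev, n_deviants))
  dev_pos <- which(lab == "deviant")
  if (length(dev_pos) >= 2) {
    gaps <- diff(dev_pos) - 1L
    bad <- which(gaps < min_gap | gaps > max_gap)
    for (i in bad)
      viol <- c(viol, sprintf(
        "run of %d standards between deviants at trials %d and %d outside [%d, %d]",
        gaps[i], dev_pos[i], dev_pos[i + 1L], min_gap, max_gap))
  }
  if (length(dev_pos) >= 1 && dev_pos[1] - 1L < DESIGN_DEFAULTS$lead_min)
    viol <- c(viol, sprintf("leading run of %d standards < minimum %d",
                            dev_pos[1] - 1L, DESIGN_DEFAULTS$lead_min))
  on <- seq$onsets_ms
  if (length(on) >= 2 && any(abs(diff(on) - soa_ms) > 1e-9))
    viol <- c(viol, sprintf("onsets are not an arithmetic sequence with step %g ms",
                            soa_ms))
  viol
}

#' Build the eight-block experiment plan
#'
#' The blocks realize the 2 x 2 x 2 factorial: syllable type (lexical
#' \emph{fu} vs nonlexical \emph{lu}) x tonal contrast (T1/T6 vs T4/T6) x
#' which member of the contrast is the deviant. Within each contrast the
#' lexical blocks precede the nonlexical ones and consecutive blocks of the
#' same syllable/contrast swap the deviant and standard roles. Four
#' rotations (contrast order x role order) are cycled across participants.
#'
#' @param rotation_id integer in 1..4.
#' @param seed integer; each block gets a distinct child seed.
#' @param n_trials,n_deviants,min_gap,max_gap design counts per block.
#' @return An \code{experiment_plan}: list of 8 \code{trial_sequence}s plus
#'   the rotation id.
#' @export
build_experiment <- function(rotation_id = 1L, seed = 1L,
                             n_trials = DESIGN_DEFAULTS$n_trials,
                             n_deviants = DESIGN_DEFAULTS$n_deviants,
                             min_gap = DESIGN_DEFAULTS$min_gap,
                             max_gap = DESIGN_DEFAULTS$max_gap) {
  if (!rotation_id %in% 1:4)
    stop("unknown rotation_id (must be 1, 2, 3 or 4): ", rotation_id)
  contrast_order <- if (rotation_id %in% c(1L, 2L))
    c("T1/T6", "T4/T6") else c("T4/T6", "T1/T6")
  t6_first <- rotation_id %in% c(1L, 3L)
  blocks <- list()
  k <- 0L
  for (contrast in contrast_order) {
    tones <- strsplit(contrast, "/", fixed = TRUE)[[1]]
    other <- setdiff(tones, "T6")
    roles <- if (t6_first) c("T6", other) else c(other, "T6")
    for (syllable in c("fu", "lu")) {        # lexical before nonlexical
      for (dev in roles) {
        k <- k + 1L
        blk <- list(syllable = syllable, contrast = contrast,
                    deviant_tone = dev,
                    block_id = sprintf("%s_%s_dev%s", syllable,
                                       gsub("/", "", contrast), dev))
        blocks[[k]] <- generate_block(n_trials, n_deviants, min_gap, max_gap,
                                      seed = child_seed(seed, k),
                                      block = blk)
      }
    }
  }
  structure(list(blocks = blocks, rotation_id = rotation_id, seed = seed),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> rotation %d, %d blocks:\n", x$rotation_id,
              length(x$blocks)))
  for (b in x$blocks) cat("  ", b$block$block_id, "\n", sep = "")
  invisible(x)
}

#' Export / import a trial sequence as tab-separated text
#'
#' Columns: trial, label, stimulus_id, onset_ms. The block descriptor and
#' design parameters travel in a JSON sidecar line prefixed with '#'.
#'
#' @param seq a \code{trial_sequence}.
#' @param path file path.
#' @rdname sequence_io
#' @export
write_sequence <- function(seq, path) {
  meta <- jsonlite::toJSON(list(block = seq$block, params = seq$params),
                           auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  df <- data.frame(trial = seq_along(seq$labels), label = seq$labels,
                   stimulus_id = seq$stimulus_ids %||% NA,
                   onset_ms = seq$onsets_ms)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_sequence <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(list(labels = df$label,
                 stimulus_ids = if (all(is.na(df$stimulus_id))) NULL else
                   df$stimulus_id,
                 onsets_ms = df$onset_ms,
                 block = meta$block, params = meta$params),
            class = "trial_sequence")
}
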