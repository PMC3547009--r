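# Nonparametric cluster-based permutation test over channels x time,
# comparing true vs dummy difference waves across participants.
#
# Pointwise paired t-statistics are thresholded at the two-tailed p < .05
# critical value; supra-threshold points are joined into clusters by spatial
# (channel-neighbourhood) and temporal (±1 sample) adjacency, separately for
# positive and negative t. Each cluster's mass is the sum of its member
# t-values (sum-T). Null distributions of the extreme positive and negative
# masses are built from random per-participant condition exchanges
# (sign flips of true - dummy); a cluster is significant when its mass falls
# in the outer 2.5th percentile of the matching distribution.

.stack_diffs <- function(true_waves, dummy_waves) {
  stopifnot(length(true_waves) == length(dummy_waves),
            length(true_waves) >= 2)
  d1 <- true_waves[[1]]$data
  chn <- rownames(d1)
  nt <- ncol(d1)
  n <- length(true_waves)
  D <- matrix(0, n, length(d1))
  for (i in seq_len(n)) {
    ti <- true_waves[[i]]$data
    di <- dummy_waves[[i]]$data
    stopifnot(identical(dim(ti), dim(d1)), identical(rownames(ti), chn),
              identical(dim(di), dim(d1)))
    D[i, ] <- as.vector(ti - di)
  }
  list(D = D, channels = chn, n_time = nt,
       times_ms = true_waves[[1]]$times_ms,
       divergence_ms = true_waves[[1]]$divergence_ms %||% 0)
}

#' Pointwise paired t-map of true vs dummy difference waves
#'
#' @param true_waves,dummy_waves lists (one element per participant) of
#'   \code{difference_wave}s on identical channel/time grids.
#' @param alpha two-tailed cluster-forming alpha (0.05).
#' @return A \code{tmap}: list with \code{t} (channels x time),
#'   \code{df} (participants - 1), \code{threshold_t}, \code{channels},
#'   \code{times_ms}.
#' @export
pointwise_t <- function(true_waves, dummy_waves, alpha = 0.05) {
  if (length(true_waves) < 2)
    stop("need at least 2 participants for a paired t-map")
  s <- .stack_diffs(true_waves, dummy_waves)
  n <- nrow(s$D)
  m <- colMeans(s$D)
  v <- (colSums(s$D^2) - n * m^2) / (n - 1)
  t <- ifelse(v > 0, m / sqrt(v / n), 0)
  structure(list(
    t = matrix(t, nrow = length(s$channels),
               dimnames = list(s$channels, NULL)),
    df = n - 1L,
    threshold_t = stats::qt(1 - alpha / 2, df = n - 1),
    alpha = alpha,
    channels = s$channels, times_ms = s$times_ms,
    divergence_ms = s$divergence_ms), class = "tmap")
}

.neighbor_index_list <- function(adjacency, channels) {
  lapply(channels, function(ch) {
    nb <- adjacency$neighbors[[ch]] %||% character(0)
    match(intersect(nb, channels), channels)
  })
}

#' Form spatio-temporal clusters from a thresholded t-map
#'
#' Connected components of supra-threshold points under (channel, sample)
#' adjacency: ±1 sample at the same channel, neighbouring channels at the
#' same sample (no diagonal links). Positive and negative t are clustered
#' separately.
#'
#' @param tmap a \code{\link{pointwise_t}} result.
#' @param adjacency an \code{mmn_adjacency} covering the tmap's channels.
#' @param threshold cluster-forming |t| threshold (default: the tmap's).
#' @return List of \code{cluster_result}s, each with \code{members}
#'   (data.frame channel/sample/time_ms), \code{mass} (sum-T), \code{sign},
#'   \code{time_range_ms}, \code{channels}; p-values unset.
#' @export
form_clusters <- function(tmap, adjacency, threshold = tmap$threshold_t) {
  chn <- tmap$channels
  if (!all(chn %in% adjacency$labels))
    stop("adjacency does not cover t-map channels: ",
         paste(setdiff(chn, adjacency$labels), collapse = ", "))
  nbr <- .neighbor_index_list(adjacency, chn)
  out <- list()
  for (sign in c(1L, -1L)) {
    lab <- cpp_label_clusters(tmap$t, threshold, nbr, sign)
    k <- length(lab$masses)
    if (k == 0) next
    for (j in seq_len(k)) {
      idx <- which(lab$labels == j, arr.ind = TRUE)
      members <- data.frame(channel = chn[idx[, 1]], sample = idx[, 2],
                            time_ms = tmap$times_ms[idx[, 2]],
                            t = tmap$t[idx], stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- structure(list(
        members = members,
        mass = lab$masses[j],
        sign = if (sign > 0) "positive" else "negative",
        time_range_ms = range(members$time_ms),
        channels = sort(unique(members$channel)),
        p_value = NA_real_, significant = NA), class = "cluster_result")
    }
  }
  out[order(-abs(vapply(out, `[[`, numeric(1), "mass")))]
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster> %s, sum-T %.2f, %d points, %g-%g ms, %d channels%s\n",
    x$sign, x$mass, nrow(x$members), x$time_range_ms[1], x$time_range_ms[2],
    length(x$channels),
    if (is.na(x$p_value)) "" else sprintf(", p = %.4g%s", x$p_value,
                                          if (isTRUE(x$significant)) " *"
                                          else "")))
  invisible(x)
}

#' Permutation scheme for the cluster test
#'
#' @param n_permutations number of random partitions (study default 10000).
#' @param seed integer seed for the random sign flips.
#' @param exhaustive if TRUE and 2^n <= n_permutations, all 2^n sign
#'   assignments are enumerated instead of sampled.
#' @param tail_p per-tail significance level (2.5th percentile).
#' @param alpha two-tailed cluster-forming alpha.
#' @return A \code{permutation_scheme} list.
#' @export
permutation_scheme <- function(n_permutations = 10000, seed = 1L,
                               exhaustive = FALSE, tail_p = 0.025,
                               alpha = 0.05) {
  structure(list(n_permutations = n_permutations, seed = seed,
                 exhaustive = exhaustive, tail_p = tail_p, alpha = alpha),
            class = "permutation_scheme")
}

#' Cluster-based permutation test of true vs dummy difference waves
#'
#' @param true_waves,dummy_waves per-participant \code{difference_wave}
#'   lists.
#' @param adjacency channel adjacency graph.
#' @param scheme a \code{\link{permutation_scheme}}.
#' @return A \code{cluster_test}: list with \code{clusters} (each carrying
#'   its permutation p-value and significance at the per-tail level),
#'   \code{tmap}, \code{null_pos}/\code{null_neg} distributions,
#'   \code{scheme}, \code{exhaustive} flag.
#' @export
cluster_permutation_test <- function(true_waves, dummy_waves, adjacency,
                                     scheme = permutation_scheme()) {
  tm <- pointwise_t(true_waves, dummy_waves, alpha = scheme$alpha)
  s <- .stack_diffs(true_waves, dummy_waves)
  n <- nrow(s$D)
  clusters <- form_clusters(tm, adjacency)
  exhaustive <- isTRUE(scheme$exhaustive) && 2^n <= scheme$n_permutations
  if (exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    flips <- t(flips)
    storage.mode(flips) <- "integer"
  } else {
    set.seed(as.integer(scheme$seed))
    flips <- matrix(sample(c(-1L, 1L), n * scheme$n_permutations,
                           replace = TRUE), nrow = n)
  }
  nbr <- .neighbor_index_list(adjacency, tm$channels)
  ss <- colSums(s$D^2)
  tD <- t(s$D)
  nperm_total <- ncol(flips)
  chunk <- max(1L, floor(2e7 / nrow(tD)))    # bound the P x chunk buffer
  null_pos <- numeric(nperm_total)
  null_neg <- numeric(nperm_total)
  at <- 1L
  while (at <= nperm_total) {
    hi <- min(at + chunk - 1L, nperm_total)
    M <- tD %*% flips[, at:hi, drop = FALSE] / n
    extremes <- cpp_perm_extreme_mass(M, ss, n, tm$threshold_t, nbr,
                                      length(tm$channels), s$n_time)
    null_pos[at:hi] <- extremes[, 1]
    null_neg[at:hi] <- extremes[, 2]
    at <- hi + 1L
  }
  nperm <- ncol(flips)
  for (j in seq_along(clusters)) {
    cl <- clusters[[j]]
    if (exhaustive) {
      p <- if (cl$sign == "positive") mean(null_pos >= cl$mass) else
        mean(null_neg <= cl$mass)
    } else {
      p <- if (cl$sign == "positive")
        (1 + sum(null_pos >= cl$mass)) / (nperm + 1)
      else (1 + sum(null_neg <= cl$mass)) / (nperm + 1)
    }
    clusters[[j]]$p_value <- p
    clusters[[j]]$significant <- p <= scheme$tail_p
  }
  structure(list(clusters = clusters, tmap = tm, n_participants = n,
                 null_pos = null_pos, null_neg = null_neg,
                 scheme = scheme, exhaustive = exhaustive),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "Cluster-based permutation test: n = %d participants, %s partitions\n",
    x$n_participants,
    if (x$exhaustive) sprintf("all %d", length(x$null_pos)) else
      format(length(x$null_pos), big.mark = ",")))
  cat(sprintf("cluster-forming |t| > %.3f (two-tailed p < %g, df = %d)\n",
              x$tmap$threshold_t, x$tmap$alpha, x$tmap$df))
  if (length(x$clusters) == 0) {
    cat("no supra-threshold clusters\n")
  } else {
    for (cl in x$clusters) print(cl)
  }
  invisible(x)
}

#' @export
summary.cluster_test <- function(object, ...) {
  if (length(object$clusters) == 0)
    return(data.frame(sign = character(0), mass = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      t_start_ms = numeric(0), t_end_ms = numeric(0),
                      n_channels = integer(0), n_points = integer(0)))
  do.call(rbind, lapply(object$clusters, function(cl) data.frame(
    sign = cl$sign, mass = cl$mass, p_value = cl$p_value,
    significant = cl$significant,
    t_start_ms = cl$time_range_ms[1], t_end_ms = cl$time_range_ms[2],
    n_channels = length(cl$channels), n_points = nrow(cl$members),
    stringsAsFactors = FALSE)))
}

#' Export cluster-test results
#'
#' JSON carries the full member lists; the CSV is the flat summary table.
#'
#' @param test a \code{cluster_test}.
#' @param json_path,csv_path output paths (NULL to skip either).
#' @export
write_cluster_results <- function(test, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- lapply(test$clusters, function(cl) list(
      sign = cl$sign, mass = cl$mass, p_value = cl$p_value,
      significant = cl$significant, time_range_ms = cl$time_range_ms,
      channels = cl$channels,
      members = cl$members[, c("channel", "sample", "time_ms", "t")]))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(summary(test), csv_path, row.names = FALSE)
  invisible(test)
}

#' Empirical type-I error of the cluster test under a null simulation
#'
#' Generates datasets with no deviant-specific effect (by default,
#' independent Gaussian per-participant true/dummy noise waves on a reduced
#' channels x time grid), runs the permutation test on each, and reports the
#' fraction with at least one significant cluster in either tail.
#'
#' @param n_datasets number of null datasets.
#' @param n_participants participants per dataset.
#' @param adjacency channel adjacency; the grid uses its channels.
#' @param n_time time samples per wave.
#' @param noise_sd SD of the null waves.
#' @param scheme reduced \code{\link{permutation_scheme}} (e.g. 200
#'   permutations).
#' @param seed master seed.
#' @param generator optional function(n_participants, n_channels, n_time)
#'   returning list(true = , dummy = ) wave lists, to plug in other null
#'   simulations.
#' @return List with \code{rate}, \code{n_significant}, \code{n_datasets},
#'   and the per-dataset logical vector.
#' @export
type1_calibration <- function(n_datasets, n_participants, adjacency,
                              n_time = 250, noise_sd = 1,
                              scheme = permutation_scheme(200),
                              seed = 1L, generator = NULL) {
  chn <- adjacency$labels
  nch <- length(chn)
  mkwave <- function(m) structure(
    list(kind = "sim", data = m,
         times_ms = seq_len(ncol(m)), rate = NA, divergence_ms = 0),
    class = "difference_wave")
  hits <- logical(n_datasets)
  for (k in seq_len(n_datasets)) {
    set.seed(child_seed(seed, k))
    if (is.null(generator)) {
      tw <- lapply(seq_len(n_participants), function(i) {
        m <- matrix(stats::rnorm(nch * n_time, sd = noise_sd), nch,
                    dimnames = list(chn, NULL))
        mkwave(m)
      })
      dw <- lapply(seq_len(n_participants), function(i) {
        m <- matrix(stats::rnorm(nch * n_time, sd = noise_sd), nch,
                    dimnames = list(chn, NULL))
        mkwave(m)
      })
    } else {
      g <- generator(n_participants, nch, n_time)
      tw <- g$true; dw <- g$dummy
    }
    sch <- scheme
    sch$seed <- child_seed(seed, n_datasets + k)
    res <- cluster_permutation_test(tw, dw, adjacency, sch)
    hits[k] <- any(vapply(res$clusters, `[[`, logical(1), "significant"))
  }
  list(rate = mean(hits), n_significant = sum(hits),
       n_datasets = n_datasets, hits = hits)
}
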