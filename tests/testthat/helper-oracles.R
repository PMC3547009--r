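# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (brute force / enumeration / graph search)
# and never share code with the implementation they check.

## Brute-force spatio-temporal clustering of a thresholded t-map via igraph
## connected components on an explicitly constructed point graph.
oracle_clusters <- function(tmap, neighbors, threshold) {
  C <- nrow(tmap); Tn <- ncol(tmap)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tmap > threshold, arr.ind = TRUE)
    if (nrow(supra) == 0) next
    id <- function(c, t) paste(c, t, sep = "_")
    nodes <- id(supra[, 1], supra[, 2])
    keep <- matrix(FALSE, C, Tn)
    keep[supra] <- TRUE
    edges <- character(0)
    for (r in seq_len(nrow(supra))) {
      c0 <- supra[r, 1]; t0 <- supra[r, 2]
      if (t0 < Tn && keep[c0, t0 + 1])
        edges <- c(edges, id(c0, t0), id(c0, t0 + 1))
      for (cn in neighbors[[c0]])
        if (keep[cn, t0]) edges <- c(edges, id(c0, t0), id(cn, t0))
    }
    g <- igraph::graph_from_data_frame(
      d = if (length(edges)) as.data.frame(matrix(edges, ncol = 2,
                                                  byrow = TRUE)) else
        data.frame(from = character(0), to = character(0)),
      vertices = data.frame(name = nodes), directed = FALSE)
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      mem <- names(comp$membership)[comp$membership == k]
      parts <- do.call(rbind, strsplit(mem, "_"))
      idx <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
      out[[length(out) + 1]] <- list(sign = sgn, n = nrow(idx),
                                     mass = sum(tmap[idx]))
    }
  }
  out
}

## random neighbour structure for small synthetic grids (symmetric)
random_neighbors <- function(n_channels, p = 0.3) {
  nb <- vector("list", n_channels)
  for (a in seq_len(n_channels - 1)) for (b in (a + 1):n_channels) {
    if (stats::runif(1) < p) {
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  lapply(nb, function(v) as.integer(sort(unique(v))))
}

## wrap a channels x time matrix as a difference_wave
as_wave <- function(m, divergence_ms = 0, times_ms = NULL, kind = "true") {
  structure(list(kind = kind, data = m,
                 times_ms = times_ms %||% (seq_len(ncol(m)) - 1),
                 rate = NA, n_triplets = NA,
                 divergence_ms = divergence_ms),
            class = "difference_wave")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## exhaustive enumeration of valid oddball label vectors (tiny designs):
## gaps in [min_gap, max_gap], >= 2 leading standards, free trailing run
oracle_enumerate_sequences <- function(n_trials, n_deviants, min_gap,
                                       max_gap) {
  res <- list()
  recurse <- function(labels, n_dev_left, last_dev) {
    pos <- length(labels)
    if (pos == n_trials) {
      if (n_dev_left == 0) res[[length(res) + 1]] <<- labels
      return(invisible())
    }
    ## place standard
    recurse(c(labels, "standard"), n_dev_left, last_dev)
    ## place deviant
    if (n_dev_left > 0) {
      nxt <- pos + 1
      ok <- if (is.na(last_dev)) nxt >= 3 else {
        gap <- nxt - last_dev - 1
        gap >= min_gap && gap <= max_gap
      }
      if (ok) recurse(c(labels, "deviant"), n_dev_left - 1, nxt)
    }
  }
  recurse(character(0), n_deviants, NA)
  res
}

## adjacency object over an explicit neighbour-index list
grid_adjacency <- function(neighbors, labels = sprintf("ch%d",
                                                       seq_along(neighbors))) {
  nb <- lapply(neighbors, function(v) labels[v])
  names(nb) <- labels
  edges <- do.call(rbind, lapply(seq_along(neighbors), function(a) {
    b <- neighbors[[a]]
    b <- b[b > a]
    if (length(b)) cbind(labels[a], labels[b]) else NULL
  }))
  structure(list(labels = labels,
                 edges = edges %||% matrix(character(0), ncol = 2),
                 neighbors = nb, radius = NA), class = "mmn_adjacency")
}

## small synthetic epochs object for rule-level tests
make_epochs <- function(data, rate = 500, pre_ms = 100,
                        labels = rep("standard", dim(data)[3]),
                        montage = NULL,
                        stages = c("filter", "epoch", "ica", "baseline",
                                   "rereference")) {
  if (is.null(montage)) {
    labs <- dimnames(data)[[1]]
    montage <- structure(list(labels = labs,
                              positions = NULL, reference = "Cz",
                              mastoids = intersect(c("M1", "M2"), labs),
                              analysis_labels = setdiff(labs,
                                                        c("M1", "M2"))),
                         class = "mmn_montage")
  }
  npre <- round(pre_ms * rate / 1000)
  structure(list(data = data,
                 times_ms = (seq_len(dim(data)[2]) - npre - 1) * 1000 / rate,
                 labels = labels,
                 stimulus_ids = rep(NA_character_, dim(data)[3]),
                 trial_index = seq_len(dim(data)[3]),
                 rate = rate, montage = montage, meta = list(),
                 stages = stages, log = list()),
            class = "mmn_epochs")
}

## montage whose electrodes sit at chosen unit vectors
make_montage <- function(positions, labels = rownames(positions),
                         mastoids = character(0)) {
  structure(list(labels = labels, positions = positions,
                 reference = "Cz", mastoids = mastoids,
                 analysis_labels = setdiff(labels, mastoids)),
            class = "mmn_montage")
}
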