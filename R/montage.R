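# 64-channel extended 10-20 montage and the channel-adjacency graph used for
# spatial clustering.
#
# Positions live on the unit sphere (dimensionless). Convention: x = right,
# y = anterior, z = up. Scalp electrodes are placed by the standard 10-20/10-10
# arc construction: midline and ear-to-ear arcs in 18-degree steps, the outer
# ring at 72 degrees polar angle, and intermediate rows by great-circle
# interpolation between the ring electrode and the corresponding midline
# electrode. M1/M2 (mastoids) and CB1/CB2 sit at nominal inferior positions.

## (polar angle from vertex, azimuth from anterior midline; negative = left)
.sph_point <- function(polar_deg, az_deg) {
  p <- polar_deg * pi / 180
  a <- az_deg * pi / 180
  c(sin(p) * sin(a), sin(p) * cos(a), cos(p))
}

.montage_positions <- function() {
  pos <- list()
  ## midline, 18-degree steps along nasion-inion arc
  mid <- c(FPz = 72, Fz = 36, FCz = 18, Cz = 0, CPz = -18, Pz = -36,
           POz = -54, Oz = -72)
  for (lab in names(mid)) {
    ang <- mid[[lab]]
    pos[[lab]] <- .sph_point(abs(ang), if (ang >= 0) 0 else 180)
  }
  ## outer ring at polar 72, azimuth steps of 18 from FPz leftward;
  ## right-hemisphere labels mirror in x
  ring_left <- c(FP1 = -18, AF7 = -36, F7 = -54, FT7 = -72, T7 = -90,
                 TP7 = -108, P7 = -126, PO7 = -144, O1 = -162)
  for (lab in names(ring_left)) pos[[lab]] <- .sph_point(72, ring_left[[lab]])
  ## virtual points used only for interpolation
  AFz <- .sph_point(54, 0)
  ## rows: great-circle interpolation ring -> midline
  row_fill <- function(from, to, labels) {
    n <- length(labels) + 1L
    for (i in seq_along(labels)) {
      pos[[labels[i]]] <<- slerp(pos[[from]] %||% from, pos[[to]] %||% to,
                                 i / n)
    }
  }
  pos[["AF3"]] <- slerp(pos[["AF7"]], AFz, 0.5)
  row_fill("F7", "Fz", c("F5", "F3", "F1"))
  row_fill("FT7", "FCz", c("FC5", "FC3", "FC1"))
  row_fill("T7", "Cz", c("C5", "C3", "C1"))
  row_fill("TP7", "CPz", c("CP5", "CP3", "CP1"))
  row_fill("P7", "Pz", c("P5", "P3", "P1"))
  row_fill("PO7", "POz", c("PO5", "PO3"))
  ## inferior electrodes (nominal cap positions)
  pos[["M1"]] <- unit(.sph_point(108, -100))
  pos[["CB1"]] <- unit(.sph_point(90, -150))
  ## mirror all left-hemisphere electrodes to the right
  mirror <- c(FP1 = "FP2", AF7 = "AF8", AF3 = "AF4", F7 = "F8", F5 = "F6",
              F3 = "F4", F1 = "F2", FT7 = "FT8", FC5 = "FC6", FC3 = "FC4",
              FC1 = "FC2", T7 = "T8", C5 = "C6", C3 = "C4", C1 = "C2",
              TP7 = "TP8", CP5 = "CP6", CP3 = "CP4", CP1 = "CP2", P7 = "P8",
              P5 = "P6", P3 = "P4", P1 = "P2", PO7 = "PO8", PO5 = "PO6",
              PO3 = "PO4", O1 = "O2", M1 = "M2", CB1 = "CB2")
  for (lab in names(mirror)) {
    p <- pos[[lab]]
    pos[[mirror[[lab]]]] <- c(-p[1], p[2], p[3])
  }
  pos[["AF7"]] <- NULL; pos[["AF8"]] <- NULL  # not part of the 64-channel cap
  mat <- do.call(rbind, pos)
  mat / sqrt(rowSums(mat^2))
}

## channel order of the 64-channel cap
.montage_labels <- c(
  "FP1", "FPz", "FP2", "AF3", "AF4",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "M1", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "M2",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
  "CB1", "O1", "Oz", "O2", "CB2")

#' Build the 64-channel extended 10-20 template montage
#'
#' Returns the montage of the standard 64-channel cap: the 62 labels printed
#' in typical extended 10-20 layouts plus AF3/AF4, with FCz, the mastoids
#' M1/M2 and the cerebellar sites CB1/CB2 included. Positions are template
#' spherical coordinates on the unit sphere; the online reference is the
#' vertex (Cz).
#'
#' @return An object of class \code{mmn_montage}: list with \code{labels},
#'   \code{positions} (64 x 3 unit vectors), \code{reference},
#'   \code{mastoids}, and \code{analysis_labels} (scalp channels entering
#'   artifact scans and clustering; mastoids excluded).
#' @examples
#' m <- build_paper_montage()
#' nrow(m$positions)
#' @export
build_paper_montage <- function() {
  pos_all <- .montage_positions()
  stopifnot(all(.montage_labels %in% rownames(pos_all)))
  pos <- pos_all[.montage_labels, , drop = FALSE]
  structure(list(
    labels = .montage_labels,
    positions = pos,
    reference = "Cz",
    mastoids = c("M1", "M2"),
    analysis_labels = setdiff(.montage_labels, c("M1", "M2"))
  ), class = "mmn_montage")
}

#' @export
print.mmn_montage <- function(x, ...) {
  cat("<mmn_montage> ", length(x$labels), " channels, reference ",
      x$reference, ", mastoids ", paste(x$mastoids, collapse = "/"), "\n",
      sep = "")
  invisible(x)
}

## Default angular-distance threshold (radians) for the neighbourhood graph.
## Chosen once so that the template montage has a median neighbour count of
## 4-8 (FieldTrip-like template behaviour); exposed in the config.
DEFAULT_ADJACENCY_RADIUS <- 0.42

#' Channel adjacency from angular distance
#'
#' Two channels are neighbours when the great-circle distance between their
#' template positions is at most \code{max_angular_distance} radians. The
#' resulting graph drives the spatial part of spatio-temporal clustering.
#'
#' @param montage an \code{mmn_montage}.
#' @param max_angular_distance neighbourhood radius in radians (> 0).
#' @param channels optional subset of labels to build the graph on (defaults
#'   to the montage's analysis channels).
#' @return An object of class \code{mmn_adjacency}: list with \code{labels},
#'   \code{edges} (2-column character matrix, each unordered pair once) and
#'   \code{neighbors} (named list of character vectors).
#' @export
build_adjacency <- function(montage,
                            max_angular_distance = DEFAULT_ADJACENCY_RADIUS,
                            channels = montage$analysis_labels) {
  stopifnot(inherits(montage, "mmn_montage"),
            is.numeric(max_angular_distance), max_angular_distance > 0)
  channels <- channels %||% montage$labels
  if (length(channels) == 0)
    stop("montage has no channels to build adjacency from")
  if (!all(channels %in% montage$labels))
    stop("unknown channel labels: ",
         paste(setdiff(channels, montage$labels), collapse = ", "))
  pos <- montage$positions[channels, , drop = FALSE]
  n <- length(channels)
  edges <- matrix(character(0), ncol = 2)
  if (n >= 2) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- acos(pmin(pmax(rowSums(pos[ij[, 1], , drop = FALSE] *
                                  pos[ij[, 2], , drop = FALSE]), -1), 1))
    keep <- d <= max_angular_distance
    edges <- cbind(channels[ij[keep, 1]], channels[ij[keep, 2]])
  }
  nb <- stats::setNames(lapply(channels, function(ch) {
    sort(unique(c(edges[edges[, 1] == ch, 2], edges[edges[, 2] == ch, 1])))
  }), channels)
  structure(list(labels = channels, edges = edges, neighbors = nb,
                 radius = max_angular_distance),
            class = "mmn_adjacency")
}

#' @export
print.mmn_adjacency <- function(x, ...) {
  cat("<mmn_adjacency> ", length(x$labels), " channels, ", nrow(x$edges),
      " edges, median neighbours ",
      stats::median(lengths(x$neighbors)), "\n", sep = "")
  invisible(x)
}

#' Read / write a montage as a plain-text table
#'
#' Four tab-separated columns: label, x, y, z.
#'
#' @param montage an \code{mmn_montage}.
#' @param path file path.
#' @rdname montage_io
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   x = montage$positions[, 1],
                   y = montage$positions[, 2],
                   z = montage$positions[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param reference,mastoids metadata not stored in the table.
#' @rdname montage_io
#' @export
read_montage <- function(path, reference = "Cz", mastoids = c("M1", "M2")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
  if (anyDuplicated(df$label)) stop("duplicate electrode labels in ", path)
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$label
  nrm <- sqrt(rowSums(pos^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("electrode positions must have unit norm (tolerance 1e-6)")
  structure(list(labels = df$label, positions = pos, reference = reference,
                 mastoids = mastoids,
                 analysis_labels = setdiff(df$label, mastoids)),
            class = "mmn_montage")
}

#' Export an adjacency graph as an edge-list text file
#'
#' @param adjacency an \code{mmn_adjacency}.
#' @param path file path; two tab-separated label columns, one row per edge.
#' @export
write_adjacency <- function(adjacency, path) {
  utils::write.table(as.data.frame(adjacency$edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("a", "b"))
  invisible(path)
}
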