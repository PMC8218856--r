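#' @useDynLib erppipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Spherical-head construction of the extended 10-20 layout.
#
# Anchors are placed exactly: the outer ring sits at 72 deg inclination from
# the vertex in 18-deg azimuth steps; midline electrodes step along the
# sagittal arc in 18-deg increments; the central coronal row steps from Cz
# towards T7/T8. Interior rows (F, FC, CP, P, AF, PO) are obtained by
# great-circle interpolation between their midline anchor and the
# corresponding ring electrode, which is how the 10-10 subdivisions are
# defined. Azimuth convention: 0 = nasion, positive clockwise (right).
.ring_az <- c(
  FP1 = -18, FP2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
  FT7 = -72, FT8 = 72, T7 = -90, T8 = 90, TP7 = -108, TP8 = 108,
  P7 = -126, P8 = 126, PO7 = -144, PO8 = 144, O1 = -162, O2 = 162, OZ = 180
)

.sph2cart <- function(incl_deg, az_deg, radius) {
  incl <- incl_deg * pi / 180
  az <- az_deg * pi / 180
  radius * c(sin(incl) * sin(az), sin(incl) * cos(az), cos(incl))
}

.slerp <- function(p, q, f) {
  # great-circle interpolation between two points on the same sphere
  r <- sqrt(sum(p^2))
  u <- p / r
  v <- q / r
  omega <- acos(pmin(1, pmax(-1, sum(u * v))))
  w <- (sin((1 - f) * omega) * u + sin(f * omega) * v) / sin(omega)
  w * r
}

.montage_positions <- function(radius_cm = 8.5) {
  pos <- list()
  for (lab in names(.ring_az)) {
    pos[[lab]] <- .sph2cart(72, .ring_az[[lab]], radius_cm)
  }
  midline <- c(AFZ = 54, FZ = 36, FCZ = 18, CZ = 0, CPZ = -18, PZ = -36,
               POZ = -54)
  for (lab in names(midline)) {
    incl <- abs(midline[[lab]])
    az <- if (midline[[lab]] >= 0) 0 else 180
    pos[[lab]] <- .sph2cart(incl, az, radius_cm)
  }
  # central coronal row: Cz -> T7/T8 in 18-deg steps
  for (k in 1:3) {
    pos[[paste0("C", 2 * k - 1)]] <- .sph2cart(18 * k, -90, radius_cm)
    pos[[paste0("C", 2 * k)]] <- .sph2cart(18 * k, 90, radius_cm)
  }
  # interior rows: fractions along midline-anchor -> ring-anchor arcs
  rows <- list(
    F  = list(mid = "FZ",  left = "F7",  right = "F8",
              left_labs = c("F1", "F3", "F5"), right_labs = c("F2", "F4", "F6"),
              fr = c(0.25, 0.5, 0.75)),
    FC = list(mid = "FCZ", left = "FT7", right = "FT8",
              left_labs = c("FC1", "FC3", "FC5"), right_labs = c("FC2", "FC4", "FC6"),
              fr = c(0.25, 0.5, 0.75)),
    CP = list(mid = "CPZ", left = "TP7", right = "TP8",
              left_labs = c("CP1", "CP3", "CP5"), right_labs = c("CP2", "CP4", "CP6"),
              fr = c(0.25, 0.5, 0.75)),
    P  = list(mid = "PZ",  left = "P7",  right = "P8",
              left_labs = c("P1", "P3", "P5"), right_labs = c("P2", "P4", "P6"),
              fr = c(0.25, 0.5, 0.75)),
    AF = list(mid = "AFZ", left = "AF7", right = "AF8",
              left_labs = "AF3", right_labs = "AF4", fr = 0.5),
    PO = list(mid = "POZ", left = "PO7", right = "PO8",
              left_labs = "PO3", right_labs = "PO4", fr = 0.5)
  )
  for (rw in rows) {
    for (i in seq_along(rw$fr)) {
      pos[[rw$left_labs[i]]] <- .slerp(pos[[rw$mid]], pos[[rw$left]], rw$fr[i])
      pos[[rw$right_labs[i]]] <- .slerp(pos[[rw$mid]], pos[[rw$right]], rw$fr[i])
    }
  }
  # inferior temporal pair completing the 62-channel cap
  pos[["FT9"]] <- .sph2cart(90, -72, radius_cm)
  pos[["FT10"]] <- .sph2cart(90, 72, radius_cm)
  # earlobe reference electrodes, below the ear canal
  pos[["A1"]] <- .sph2cart(112, -92, radius_cm)
  pos[["A2"]] <- .sph2cart(112, 92, radius_cm)
  pos
}

.scalp_order <- c(
  "FP1", "FP2",
  "AF7", "AF3", "AFZ", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT9", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8", "FT10",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POZ", "PO4", "PO8",
  "O1", "OZ", "O2"
)

#' Build the 62-channel extended 10-20 montage
#'
#' Constructs electrode positions on a spherical head model for a 62-channel
#' cap (extended 10-20 layout) plus two earlobe reference electrodes, and a
#' spatial adjacency relation used for spatio-temporal clustering. Channels
#' are adjacent when their 3D inter-electrode distance is below
#' `adjacency_cm` (earlobes never take part in scalp adjacency).
#'
#' @param radius_cm head sphere radius in centimetres.
#' @param adjacency_cm neighbourhood distance threshold in centimetres.
#' @return An object of class `montage`: list with `labels` (64 channel
#'   names, scalp first, then `A1`, `A2`), `scalp` (the 62 scalp labels),
#'   `positions` (64 x 3 matrix, cm), and `adjacency` (62 x 62 logical
#'   matrix over scalp channels, symmetric, irreflexive).
#' @examples
#' m <- make_montage()
#' sum(m$adjacency["PZ", ])   # neighbours of PZ
#' @export
make_montage <- function(radius_cm = 8.5, adjacency_cm = 4) {
  stopifnot(radius_cm > 0, adjacency_cm > 0)
  pos <- .montage_positions(radius_cm)
  labels <- c(.scalp_order, "A1", "A2")
  stopifnot(!anyDuplicated(labels), all(labels %in% names(pos)))
  P <- t(vapply(labels, function(l) pos[[l]], numeric(3)))
  colnames(P) <- c("x", "y", "z")
  D <- as.matrix(stats::dist(P[.scalp_order, , drop = FALSE]))
  adj <- D < adjacency_cm
  diag(adj) <- FALSE
  structure(list(labels = labels, scalp = .scalp_order, positions = P,
                 adjacency = adj, radius_cm = radius_cm,
                 adjacency_cm = adjacency_cm),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("montage: %d scalp channels + %d reference, adjacency < %g cm\n",
              length(x$scalp), length(x$labels) - length(x$scalp),
              x$adjacency_cm))
  cat(sprintf("mean neighbours per scalp channel: %.1f\n",
              mean(rowSums(x$adjacency))))
  invisible(x)
}

#' Inter-electrode distances of a montage
#'
#' @param m a `montage`.
#' @return symmetric matrix of 3D distances (cm) over all channels.
#' @export
montage_distances <- function(m) {
  as.matrix(stats::dist(m$positions))
}

# adjacency as a 0-based neighbour index list for the C++ kernels
.adjacency_list0 <- function(adjacency) {
  if (is.null(adjacency) || nrow(adjacency) == 0) return(list())
  lapply(seq_len(nrow(adjacency)), function(i) which(adjacency[i, ]) - 1L)
}
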