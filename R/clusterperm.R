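#' Paired t map over channels and samples
#'
#' One-sample t statistic (df = n - 1) on the within-subject differences
#' A - B at every (channel, sample) point.
#'
#' @param condA,condB lists of per-subject `evoked` objects (same subjects,
#'   same order, same geometry).
#' @return list of class `stat_map`: `values` (channels x samples t),
#'   `channels`, `fs`, `t0`, `n`.
#' @export
paired_t_map <- function(condA, condB) {
  n <- length(condA)
  if (n < 2 || length(condB) != n) stop("need >= 2 paired subjects")
  ref <- condA[[1]]
  diffs <- lapply(seq_len(n), function(i) {
    if (!identical(condA[[i]]$channels, ref$channels) ||
        !identical(condB[[i]]$channels, ref$channels))
      stop("mismatched geometry between conditions/subjects")
    condA[[i]]$data - condB[[i]]$data
  })
  D <- vapply(diffs, as.vector, numeric(length(ref$data)))  # points x n
  m <- rowMeans(D)
  sd <- sqrt(rowSums((D - m)^2) / (n - 1))
  t <- ifelse(sd > 0, m / (sd / sqrt(n)), 0)
  structure(list(values = matrix(t, nrow(ref$data), ncol(ref$data),
                                 dimnames = list(ref$channels, NULL)),
                 channels = ref$channels, fs = ref$fs, t0 = ref$t0, n = n),
            class = "stat_map")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For each point and sign, integrates `extent(h)^E * h^H * dh` over
#' thresholds `0 < h <= |t|` (Riemann sum with step `dh`), where the extent
#' is the size of the spatio-temporal connected component containing the
#' point at height `h`. Negative values are enhanced on the negated map and
#' re-signed, so the output is a signed enhancement map.
#'
#' @param map a `stat_map` (or plain channels x samples matrix).
#' @param adjacency channels x channels logical matrix; an empty/NULL
#'   adjacency clusters along time only (with a warning when there are
#'   several channels).
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param dh integration step; default `max(|t|) / n_steps`.
#' @param n_steps number of Riemann steps when `dh` is NULL.
#' @return enhanced map of the same shape/class as the input.
#' @export
tfce_enhance <- function(map, adjacency = NULL, E = 0.5, H = 2, dh = NULL,
                         n_steps = 100) {
  v <- if (inherits(map, "stat_map")) map$values else map
  stopifnot(is.matrix(v))
  if (!is.null(dh) && dh <= 0) stop("dh must be > 0")
  if (is.null(adjacency) || length(adjacency) == 0 || !any(adjacency)) {
    if (nrow(v) > 1)
      warning("empty spatial adjacency: clustering along time only")
    adjacency <- matrix(FALSE, nrow(v), nrow(v))
  }
  adj0 <- .adjacency_list0(adjacency)
  enh <- tfce_cpp(v, adj0, E, H, if (is.null(dh)) -1 else dh, n_steps)
  dimnames(enh) <- dimnames(v)
  if (inherits(map, "stat_map")) {
    map$values <- enh
    map
  } else enh
}

#' Spatio-temporal connected components of a boolean mask
#'
#' Two points are connected iff they share a channel and are temporal
#' neighbours (`|s1 - s2| = 1`) or share a sample and are spatially
#' adjacent channels.
#'
#' @param mask logical channels x samples matrix.
#' @param adjacency channels x channels logical matrix.
#' @return list of components, each an integer matrix with columns
#'   `channel`, `sample` (1-based indices).
#' @export
spatiotemporal_components <- function(mask, adjacency) {
  stopifnot(is.matrix(mask))
  if (is.null(adjacency)) adjacency <- matrix(FALSE, nrow(mask), nrow(mask))
  stopifnot(nrow(adjacency) == nrow(mask))
  lab <- label_components_cpp(mask, .adjacency_list0(adjacency))
  k <- max(lab)
  lapply(seq_len(k), function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    colnames(w) <- c("channel", "sample")
    w
  })
}

# core sign-flip permutation engine on a points x subjects difference matrix
.signflip_null <- function(D, n_perm, stat_fun, exact = FALSE) {
  n <- ncol(D)
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(signs)
  } else {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  ss <- rowSums(D^2)
  vapply(seq_len(n_perm), function(p) {
    m <- as.vector(D %*% signs[p, ]) / n
    s2 <- (ss - n * m^2) / (n - 1)
    t <- ifelse(s2 > 1e-24, m / sqrt(s2 / n), 0)
    stat_fun(t)
  }, numeric(1))
}

#' Cluster-based permutation test for a paired contrast
#'
#' Computes the observed paired t map, enhances it (TFCE by default, or
#' classical cluster mass at a fixed cluster-forming threshold), and builds
#' the permutation null by random sign flips of the per-subject difference
#' maps (exchangeability under the paired null). For each permutation the
#' maximum absolute enhanced statistic is recorded (max-statistic correction
#' over space and time); the Monte Carlo p-value at each point (TFCE) or for
#' each cluster (mass) is `(1 + #[perm max >= observed]) / (n_perm + 1)`.
#' When `2^n <= n_perm` all sign assignments are enumerated instead and the
#' p-value denominator is `2^n`.
#'
#' @param condA,condB lists of per-subject `evoked` objects.
#' @param adjacency channels x channels logical matrix.
#' @param n_perm number of random sign flips (default 1000).
#' @param alpha significance level for reporting clusters.
#' @param method "tfce" or "mass".
#' @param E,H,dh,n_steps TFCE parameters (see [tfce_enhance()]).
#' @param mass_threshold cluster-forming |t| threshold for method "mass";
#'   default the two-sided 0.05 t quantile.
#' @param seed optional RNG seed for reproducibility.
#' @return list of class `cluster_result`: `p` (channels x samples Monte
#'   Carlo p map), `observed` (enhanced map), `tmap`, `clusters`
#'   (data.frame: sign, channels involved, time range in ms, mass, p),
#'   `sig_mask`, `n_perm`, `method`, `alpha`.
#' @export
permutation_test <- function(condA, condB, adjacency, n_perm = 1000,
                             alpha = 0.05, method = c("tfce", "mass"),
                             E = 0.5, H = 2, dh = NULL, n_steps = 100,
                             mass_threshold = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value scale")
  tmap <- paired_t_map(condA, condB)
  n <- tmap$n
  exact <- 2^n <= n_perm
  v <- tmap$values
  nch <- nrow(v)
  if (is.null(adjacency)) adjacency <- matrix(FALSE, nch, nch)
  adj0 <- .adjacency_list0(adjacency)

  ref <- condA[[1]]
  D <- vapply(seq_len(n), function(i)
    as.vector(condA[[i]]$data - condB[[i]]$data), numeric(length(v)))

  if (method == "tfce") {
    step <- if (is.null(dh)) max(abs(v)) / n_steps else dh
    if (!is.finite(step) || step <= 0) step <- 1   # all-zero observed map
    obs <- tfce_cpp(v, adj0, E, H, step, n_steps)
    stat_fun <- function(t)
      max(abs(tfce_cpp(matrix(t, nch), adj0, E, H, step, n_steps)))
    null_max <- .signflip_null(D, n_perm, stat_fun, exact)
    denom <- if (exact) 2^n else n_perm + 1
    num <- if (exact) 0 else 1
    p <- matrix(vapply(abs(obs), function(o)
      (num + sum(null_max >= o - 1e-12)) / denom, numeric(1)), nch)
    sig <- p < alpha & abs(obs) > 0
    clusters <- .describe_clusters(sig, obs, p, adjacency, tmap)
  } else {
    thr <- mass_threshold %||% stats::qt(0.975, n - 1)
    mass_stat <- function(t) {
      m <- 0
      for (sgn in c(1, -1)) {
        lab <- label_components_cpp(matrix(sgn * t > thr, nch), adj0)
        if (max(lab) > 0)
          m <- max(m, max(abs(tapply(t[lab > 0], lab[lab > 0], sum))))
      }
      m
    }
    obs <- v
    null_max <- .signflip_null(D, n_perm, mass_stat, exact)
    denom <- if (exact) 2^n else n_perm + 1
    num <- if (exact) 0 else 1
    p <- matrix(1, nch, ncol(v))
    sig <- matrix(FALSE, nch, ncol(v))
    rows <- list()
    for (sgn in c(1, -1)) {
      comps <- spatiotemporal_components(sgn * v > thr, adjacency)
      for (cmp in comps) {
        mass <- sum(v[cmp])
        pc <- (num + sum(null_max >= abs(mass) - 1e-12)) / denom
        p[cmp] <- pmin(p[cmp], pc)
        if (pc < alpha) sig[cmp] <- TRUE
        rows[[length(rows) + 1]] <- .cluster_row(cmp, sgn, mass, pc, tmap)
      }
    }
    clusters <- if (length(rows)) do.call(rbind, rows) else .empty_clusters()
  }
  dimnames(p) <- dimnames(v)
  structure(list(p = p, observed = obs, tmap = tmap, clusters = clusters,
                 sig_mask = sig, n_perm = if (exact) 2^n else n_perm,
                 exact = exact, method = method, alpha = alpha),
            class = "cluster_result")
}

.cluster_row <- function(cmp, sgn, mass, pc, tmap) {
  tt <- tmap$t0 + (cmp[, "sample"] - 1) * 1000 / tmap$fs
  data.frame(sign = if (sgn > 0) "positive" else "negative",
             n_points = nrow(cmp),
             channels = paste(sort(unique(tmap$channels[cmp[, "channel"]])),
                              collapse = "/"),
             start_ms = min(tt), end_ms = max(tt), mass = mass, p = pc)
}

.empty_clusters <- function()
  data.frame(sign = character(), n_points = integer(), channels = character(),
             start_ms = numeric(), end_ms = numeric(), mass = numeric(),
             p = numeric())

# significant-point components summarised per sign (TFCE reporting)
.describe_clusters <- function(sig, enh, p, adjacency, tmap) {
  rows <- list()
  for (sgn in c(1, -1)) {
    comps <- spatiotemporal_components(sig & (sgn * enh > 0), adjacency)
    for (cmp in comps)
      rows[[length(rows) + 1]] <-
        .cluster_row(cmp, sgn, sum(enh[cmp]), min(p[cmp]), tmap)
  }
  if (length(rows)) do.call(rbind, rows) else .empty_clusters()
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster permutation test (%s, %d permutations%s), alpha = %g\n",
              x$method, x$n_perm, if (x$exact) ", exact" else "", x$alpha))
  if (nrow(x$clusters) == 0) cat("no clusters\n") else print(x$clusters)
  invisible(x)
}

#' Serialize a cluster result to JSON
#'
#' @param x a `cluster_result`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(x, path) {
  jsonlite::write_json(
    list(method = x$method, n_perm = x$n_perm, alpha = x$alpha,
         clusters = x$clusters,
         n_significant_points = sum(x$sig_mask)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
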