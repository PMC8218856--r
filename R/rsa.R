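RSA_ITEMS <- c("self_A", "fearful_A", "happy_A", "neutral_A",
               "self_B", "fearful_B", "happy_B", "neutral_B")

#' Split-half condition patterns
#'
#' Randomly partitions each condition's trials into two disjoint,
#' near-equal pools and averages each pool, yielding 8 channel-pattern time
#' series (2 pools x 4 conditions) per subject. The partition is
#' reproducible from the seed.
#'
#' @param e a preprocessed [epochs()] object.
#' @param seed RNG seed for the partition.
#' @return array 8 x channels x samples, item order
#'   `self_A, fearful_A, happy_A, neutral_A, self_B, ..., neutral_B`, with
#'   attribute `pools` (list of trial indices).
#' @export
split_half_evokeds <- function(e, seed = 1) {
  set.seed(seed)
  d <- dim(e$data)
  out <- array(NA_real_, c(8, d[2], d[3]),
               dimnames = list(RSA_ITEMS, e$channels, NULL))
  pools <- list()
  for (ci in seq_along(CONDITIONS)) {
    cond <- CONDITIONS[ci]
    idx <- which(e$conditions == cond)
    if (length(idx) < 2) stop("condition '", cond, "' has fewer than 2 trials")
    idx <- sample(idx)
    half <- floor(length(idx) / 2)
    a <- idx[seq_len(half)]
    b <- idx[(half + 1):length(idx)]
    out[ci, , ] <- colMeans(e$data[a, , , drop = FALSE], dims = 1)
    out[ci + 4, , ] <- colMeans(e$data[b, , , drop = FALSE], dims = 1)
    pools[[cond]] <- list(A = sort(a), B = sort(b))
  }
  attr(out, "pools") <- pools
  attr(out, "fs") <- e$fs
  attr(out, "t0") <- e$t0
  out
}

#' Time-resolved 8 x 8 Euclidean distance matrices
#'
#' At every time point, the Euclidean distance over channel space between
#' each pair of the 8 split-half condition patterns.
#'
#' @param patterns 8 x channels x samples array from [split_half_evokeds()].
#' @param fs,t0 sampling metadata (taken from `patterns` attributes if
#'   present).
#' @return object of class `rdm_series`: `distances` (samples x 8 x 8 array,
#'   each slice symmetric with zero diagonal), `items`, `fs`, `t0`.
#' @export
rdm_series <- function(patterns, fs = NULL, t0 = NULL) {
  stopifnot(length(dim(patterns)) == 3, dim(patterns)[1] == 8)
  ns <- dim(patterns)[3]
  D <- array(0, c(ns, 8, 8), dimnames = list(NULL, RSA_ITEMS, RSA_ITEMS))
  for (s in seq_len(ns)) {
    D[s, , ] <- as.matrix(stats::dist(patterns[, , s]))
  }
  structure(list(distances = D, items = RSA_ITEMS,
                 fs = fs %||% attr(patterns, "fs"),
                 t0 = t0 %||% attr(patterns, "t0")),
            class = "rdm_series")
}

#' Model template set for the template regression
#'
#' Three binary 8 x 8 model matrices over the split-half item order: an
#' off-diagonal entry is 0 ("similar") when both items belong to the
#' model's similar-set or both to its complement, 1 ("dissimilar")
#' otherwise; same-condition cross-pool pairs are always similar; the
#' diagonal is 0. Similar-sets: \{self, fearful\} (self+fear model),
#' \{self, happy\} (self+happy model), \{self\} (self-only model).
#' Each template is then z-scored.
#'
#' With `vectorization = "offdiag"` (default) templates are z-scored over
#' the 56 off-diagonal entries and the regression intercept is a constant;
#' with `"full64"` they are z-scored over all 64 entries and the intercept
#' is the 8 x 8 identity.
#'
#' @param vectorization "offdiag" or "full64".
#' @return object of class `template_set`: `raw` (list of 3 binary
#'   matrices), `X` (design matrix: intercept + 3 z-scored template
#'   columns), `mask` (logical 8 x 8 of vectorized cells), `vectorization`.
#' @export
build_templates <- function(vectorization = c("offdiag", "full64")) {
  vectorization <- match.arg(vectorization)
  cond_of <- sub("_[AB]$", "", RSA_ITEMS)
  sets <- list(self_fear = c("self", "fearful"),
               self_happy = c("self", "happy"),
               self_only = "self")
  raw <- lapply(sets, function(set) {
    M <- matrix(0, 8, 8, dimnames = list(RSA_ITEMS, RSA_ITEMS))
    for (i in 1:8) for (j in 1:8) {
      if (i == j || cond_of[i] == cond_of[j]) next
      M[i, j] <- as.numeric(xor(cond_of[i] %in% set, cond_of[j] %in% set))
    }
    M
  })
  mask <- if (vectorization == "full64") matrix(TRUE, 8, 8) else
    !diag(8) > 0
  z <- function(M) {
    v <- M[mask]
    (v - mean(v)) / stats::sd(v)
  }
  intercept <- if (vectorization == "full64") as.numeric(diag(8)[mask]) else
    rep(1, sum(mask))
  X <- cbind(intercept = intercept,
             self_fear = z(raw$self_fear),
             self_happy = z(raw$self_happy),
             self_only = z(raw$self_only))
  if (qr(X)$rank < ncol(X)) stop("template design is rank deficient")
  structure(list(raw = raw, X = X, mask = mask,
                 vectorization = vectorization),
            class = "template_set")
}

#' Template regression of an RDM series
#'
#' Per time point, ordinary least squares of the vectorized distance matrix
#' on the intercept and the three z-scored model templates:
#' `D = b0 + sum_n b_n template_n + e`.
#'
#' @param rdm an `rdm_series`.
#' @param templates a [build_templates()] set.
#' @return object of class `beta_series` (single subject): `betas`
#'   (samples x 4: intercept, self_fear, self_happy, self_only),
#'   `residual_var` (per time point), `fs`, `t0`, `smoothed = FALSE`.
#' @export
regress_templates <- function(rdm, templates = build_templates()) {
  D <- rdm$distances
  ns <- dim(D)[1]
  mask <- templates$mask
  Y <- t(vapply(seq_len(ns), function(s) D[s, , ][mask],
                numeric(sum(mask))))          # ns x cells
  X <- templates$X
  fit <- lm.fit(X, t(Y))
  B <- t(fit$coefficients)                    # ns x 4
  colnames(B) <- colnames(X)
  res <- t(fit$residuals)                     # ns x cells
  rv <- rowSums(res^2) / (ncol(Y) - ncol(X))
  structure(list(betas = B, residual_var = rv, fs = rdm$fs, t0 = rdm$t0,
                 smoothed = FALSE, vectorization = templates$vectorization),
            class = "beta_series")
}

#' Gaussian temporal smoothing of beta series
#'
#' Convolution of each regressor's beta time course with a unit-mass
#' Gaussian kernel (`width_ms` is the kernel FWHM, so
#' `sigma = width_ms / (2 sqrt(2 log 2))`), with reflective edge padding.
#'
#' @param b a `beta_series`.
#' @param width_ms kernel FWHM in ms (default 32).
#' @return smoothed `beta_series`.
#' @export
smooth_betas <- function(b, width_ms = 32) {
  stopifnot(width_ms > 0)
  sigma <- width_ms / (2 * sqrt(2 * log(2))) / 1000 * b$fs  # samples
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  b$betas <- apply(b$betas, 2, .reflect_convolve, kernel = k)
  b$smoothed <- TRUE
  b$smooth_fwhm_ms <- width_ms
  b
}

.reflect_convolve <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  n <- length(x)
  pad <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  stats::convolve(pad, rev(kernel), type = "filter")
}

#' Group-level temporal cluster test on a template's betas
#'
#' One-sample t across subjects at every time point on the chosen
#' regressor's (smoothed) beta, enhanced with temporal-only TFCE, with a
#' sign-flip permutation null and max-statistic correction, exactly as in
#' [permutation_test()]. Clusters are reported with their time range and
#' sign (positive/negative predictor).
#'
#' @param betas list of per-subject `beta_series`.
#' @param regressor column name or index (e.g. "self_only").
#' @param n_perm,alpha,E,H,dh,n_steps,seed as in [permutation_test()].
#' @return a `cluster_result` (1 "channel" x samples geometry).
#' @export
group_beta_cluster_test <- function(betas, regressor, n_perm = 1000,
                                    alpha = 0.05, E = 0.5, H = 2, dh = NULL,
                                    n_steps = 100, seed = NULL) {
  if (length(betas) < 2) stop("need >= 2 subjects")
  mat <- vapply(betas, function(b) b$betas[, regressor],
                numeric(nrow(betas[[1]]$betas)))   # samples x subjects
  sds <- apply(mat, 1, stats::sd)
  if (all(sds < 1e-12) && any(abs(rowMeans(mat)) > 1e-12))
    stop("degenerate beta series: zero variance across subjects")
  fs <- betas[[1]]$fs
  t0 <- betas[[1]]$t0
  evA <- lapply(seq_along(betas), function(i) structure(
    list(data = matrix(mat[, i], 1), condition = "beta", n_trials = 1,
         fs = fs, t0 = t0, channels = "beta"), class = "evoked"))
  ev0 <- lapply(evA, function(ev) { ev$data[] <- 0; ev })
  permutation_test(evA, ev0, adjacency = matrix(FALSE, 1, 1),
                   n_perm = n_perm, alpha = alpha, method = "tfce",
                   E = E, H = H, dh = dh, n_steps = n_steps, seed = seed)
}

#' End-to-end RSA for one subject
#'
#' Split-half pooling, RDM series, template regression and smoothing.
#'
#' @param e preprocessed [epochs()].
#' @param templates a [build_templates()] set.
#' @param seed split seed.
#' @param width_ms smoothing FWHM (ms).
#' @param n_splits number of independent random splits to average the RDM
#'   series over (default 1, the single-split analysis).
#' @return a `beta_series`.
#' @export
subject_rsa <- function(e, templates = build_templates(), seed = 1,
                        width_ms = 32, n_splits = 1) {
  acc <- NULL
  for (k in seq_len(n_splits)) {
    pat <- split_half_evokeds(e, seed = seed + (k - 1) * 101)
    rdm <- rdm_series(pat)
    acc <- if (is.null(acc)) rdm$distances else acc + rdm$distances
  }
  rdm <- structure(list(distances = acc / n_splits, items = RSA_ITEMS,
                        fs = e$fs, t0 = e$t0), class = "rdm_series")
  smooth_betas(regress_templates(rdm, templates), width_ms)
}
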