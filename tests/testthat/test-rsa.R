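test_that("split-half pooling partitions every condition into disjoint halves", {
  sim <- simulate_subject(tiny_cfg(n_trials = 9), 1)
  pat <- split_half_evokeds(sim$epochs, seed = 3)
  expect_identical(dim(pat)[1], 8L)
  pools <- attr(pat, "pools")
  for (cond in names(pools)) {
    a <- pools[[cond]]$A
    b <- pools[[cond]]$B
    expect_length(intersect(a, b), 0)
    expect_setequal(c(a, b), which(sim$epochs$conditions == cond))
    expect_lte(abs(length(a) - length(b)), 1)
  }
  # reproducible from the seed
  expect_identical(pat, split_half_evokeds(sim$epochs, seed = 3))
  # noiseless data: both pools equal the condition template
  s0 <- simulate_subject(noiseless_cfg(), 1)
  p0 <- split_half_evokeds(s0$epochs, seed = 1)
  expect_equal(p0["self_A", , ], p0["self_B", , ], tolerance = 1e-12)
  e1 <- s0$epochs
  e1$conditions[which(e1$conditions == "self")[-1]] <- "purge"
  expect_error(split_half_evokeds(e1, 1), "fewer than 2")
})

test_that("RDM series are Euclidean, symmetric and correctly shaped", {
  sim <- simulate_subject(tiny_cfg(), 1)
  pat <- split_half_evokeds(sim$epochs, seed = 2)
  rdm <- rdm_series(pat)
  ns <- dim(sim$epochs$data)[3]
  expect_identical(dim(rdm$distances), c(ns, 8L, 8L))
  s <- rdm$distances[100, , ]
  expect_equal(s, t(s))
  expect_true(all(diag(s) == 0))
  expect_true(all(s >= 0))
  # triangle inequality on random triples
  for (r in 1:20) {
    ijk <- sample(8, 3)
    expect_lte(s[ijk[1], ijk[2]],
               s[ijk[1], ijk[3]] + s[ijk[3], ijk[2]] + 1e-9)
  }
  # 3-4-5 identity
  pat2 <- array(0, c(8, 2, 1))
  pat2[2, , 1] <- c(3, 4)
  rdm2 <- rdm_series(pat2, fs = 500, t0 = 0)
  expect_equal(rdm2$distances[1, 1, 2], 5)
  # duplicated patterns are indiscernible
  pat2[3, , 1] <- pat2[2, , 1]
  expect_equal(rdm_series(pat2, 500, 0)$distances[1, 2, 3], 0)
})

test_that("model templates encode the hypothesised similarity structures", {
  tm <- build_templates()
  raw <- tm$raw
  expect_equal(raw$self_only["self_A", "fearful_B"], 1)
  expect_equal(raw$self_only["fearful_A", "happy_B"], 0)
  expect_equal(raw$self_only["self_A", "self_B"], 0)
  expect_equal(raw$self_fear["self_A", "fearful_A"], 0)
  expect_equal(raw$self_fear["self_A", "neutral_B"], 1)
  expect_equal(raw$self_fear["happy_A", "neutral_B"], 0)
  expect_equal(raw$self_happy["self_B", "happy_A"], 0)
  expect_equal(raw$self_happy["fearful_A", "self_B"], 1)
  for (M in raw) expect_equal(M, t(M))
  # z-scoring over the vectorized cells used in the regression
  for (k in 2:4) {
    expect_equal(mean(tm$X[, k]), 0, tolerance = 1e-12)
    expect_equal(sd(tm$X[, k]), 1, tolerance = 1e-12)
  }
  t64 <- build_templates("full64")
  expect_identical(nrow(t64$X), 64L)
  expect_equal(t64$X[, 1], as.numeric(diag(8)))
  expect_identical(nrow(tm$X), 56L)
  expect_equal(tm$X[, 1], rep(1, 56))
})

test_that("template regression equals the normal-equations oracle", {
  set.seed(31)
  for (mode in c("offdiag", "full64")) {
    tm <- build_templates(mode)
    ns <- 40
    D <- array(0, c(ns, 8, 8))
    for (s in 1:ns) {
      M <- matrix(rnorm(64), 8)
      M <- abs(M + t(M)); diag(M) <- 0
      D[s, , ] <- M
    }
    rdm <- structure(list(distances = D, items = dimnames(D)[[2]],
                          fs = 500, t0 = 0), class = "rdm_series")
    b <- regress_templates(rdm, tm)
    X <- tm$X
    pinv <- solve(t(X) %*% X) %*% t(X)
    for (s in c(1, 17, 40)) {
      expect_equal(unname(b$betas[s, ]),
                   as.vector(pinv %*% D[s, , ][tm$mask]), tolerance = 1e-8)
    }
    # scale equivariance
    rdm2 <- rdm; rdm2$distances <- 3 * rdm$distances
    expect_equal(regress_templates(rdm2, tm)$betas, 3 * b$betas,
                 tolerance = 1e-9)
  }
  # exact recovery when the distance matrix is built from the design
  t64 <- build_templates("full64")
  z3 <- matrix(0, 8, 8); z3[t64$mask] <- t64$X[, "self_only"]
  D <- array(0, c(2, 8, 8)); D[1, , ] <- 2 * z3; D[2, , ] <- diag(8)
  rdm <- structure(list(distances = D, items = NULL,
                        fs = 500, t0 = 0), class = "rdm_series")
  b <- regress_templates(rdm, t64)
  expect_equal(unname(b$betas[1, ]), c(0, 0, 0, 2), tolerance = 1e-10)
  expect_equal(unname(b$betas[2, ]), c(1, 0, 0, 0), tolerance = 1e-10)
})

test_that("Gaussian beta smoothing is unit-mass with reflective edges", {
  b <- structure(list(betas = matrix(1, 100, 4,
                                     dimnames = list(NULL, c("intercept",
                                                             "self_fear",
                                                             "self_happy",
                                                             "self_only"))),
                      residual_var = rep(0, 100), fs = 500, t0 = 0,
                      smoothed = FALSE), class = "beta_series")
  s <- smooth_betas(b)
  expect_equal(s$betas, b$betas, tolerance = 1e-12)   # constants unchanged
  # unit impulse integrates to one
  b2 <- b; b2$betas[, ] <- 0; b2$betas[50, ] <- 1
  s2 <- smooth_betas(b2)
  expect_equal(colSums(s2$betas), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # direct convolution oracle in the interior
  set.seed(40)
  b3 <- b; b3$betas[, 2] <- rnorm(100)
  s3 <- smooth_betas(b3, width_ms = 32)
  sigma <- 32 / (2 * sqrt(2 * log(2))) / 1000 * 500
  half <- ceiling(4 * sigma)
  k <- dnorm(-half:half, sd = sigma); k <- k / sum(k)
  for (i in c(40, 60)) {
    expect_equal(unname(s3$betas[i, 2]),
                 sum(b3$betas[i + (-half:half), 2] * rev(k)), tolerance = 1e-9)
  }
})

test_that("group beta cluster tests find planted signs and reject degenerate input", {
  set.seed(41)
  mkb <- function(x) structure(list(
    betas = cbind(intercept = 0, self_fear = 0, self_happy = 0, self_only = x),
    residual_var = rep(0, length(x)), fs = 500, t0 = 0, smoothed = TRUE),
    class = "beta_series")
  n <- 12
  betas <- lapply(1:n, function(i) {
    x <- rnorm(120, sd = 0.5)
    x[40:80] <- x[40:80] + 2
    mkb(x)
  })
  cr <- group_beta_cluster_test(betas, "self_only", n_perm = 300, seed = 6)
  expect_true(any(cr$clusters$sign == "positive"))
  expect_gte(min(cr$clusters$start_ms[cr$clusters$sign == "positive"]), 0)
  # duplicated single subject: zero between-subject variance
  dup <- lapply(1:5, function(i) mkb(rep(1, 120)))
  expect_error(group_beta_cluster_test(dup, "self_only"), "degenerate")
})
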