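mk_ev <- function(data, channels = paste0("Ch", seq_len(nrow(data)))) {
  structure(list(data = data, condition = "x", n_trials = 1, fs = 500,
                 t0 = 0, channels = channels), class = "evoked")
}
chain_adj <- function(n) {
  a <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- TRUE
  a
}

test_that("paired t maps match the element-wise oracle and closed forms", {
  set.seed(5)
  n <- 8
  A <- lapply(1:n, function(i) mk_ev(matrix(rnorm(40), 4)))
  B <- lapply(1:n, function(i) mk_ev(matrix(rnorm(40), 4)))
  tm <- paired_t_map(A, B)
  for (p in sample(40, 5)) {
    d <- vapply(1:n, function(i) A[[i]]$data[p] - B[[i]]$data[p], numeric(1))
    expect_equal(tm$values[p], unname(t.test(d)$statistic), tolerance = 1e-10)
  }
  # A == B gives t = 0 everywhere
  expect_true(all(paired_t_map(A, A)$values == 0))
  # constant difference d with subject s.d. s: t = d / (s / sqrt(n))
  base <- matrix(0, 4, 10)
  offs <- c(1, 2, 3, 4, 5, 6)
  A2 <- lapply(offs, function(o) mk_ev(base + 2 + (o - mean(offs))))
  B2 <- lapply(offs, function(o) mk_ev(base + (o - mean(offs)) * 0))
  # differences: 2 + centered offsets, sd = sd(offs)
  tm2 <- paired_t_map(A2, B2)
  expect_equal(unname(tm2$values[1, 1]), 2 / (sd(offs) / sqrt(6)),
               tolerance = 1e-10)
  expect_error(paired_t_map(A[1], B[1]), ">= 2")
})

test_that("TFCE matches the brute-force threshold sweep", {
  set.seed(6)
  adj <- chain_adj(6)
  for (r in 1:3) {
    v <- matrix(rnorm(6 * 20), 6, 20)
    dh <- max(abs(v)) / 200
    expect_equal(tfce_enhance(v, adj, dh = dh), oracle_tfce(v, adj, dh = dh),
                 tolerance = 1e-10)
  }
  # the worked single-channel example
  v <- matrix(c(0, 2, 2, 2, 0), 1)
  got <- tfce_enhance(v, matrix(FALSE, 1, 1), dh = 0.01)
  orc <- oracle_tfce(v, matrix(FALSE, 1, 1), dh = 0.01)
  expect_equal(got, orc, tolerance = 1e-12)
  expect_equal(got[1, 2], sum(3^0.5 * seq(0.01, 2, by = 0.01)^2 * 0.01))
  # all-zero map stays zero; doubling never decreases enhancement
  expect_true(all(tfce_enhance(matrix(0, 3, 5), chain_adj(3)) == 0))
  v <- matrix(rnorm(60), 6)
  e1 <- abs(tfce_enhance(v, adj, dh = 0.01))
  e2 <- abs(tfce_enhance(2 * v, adj, dh = 0.01))
  expect_true(all(e2 >= e1 - 1e-9))
  # isolated point: analytic integral h^H over 0..v is v^3/3
  v <- matrix(c(0, 0, 1.5, 0, 0), 1)
  got <- tfce_enhance(v, matrix(FALSE, 1, 1), dh = 1.5 / 2000)[3]
  expect_equal(got, 1.5^3 / 3, tolerance = 0.01 * 1.5^3 / 3)
})

test_that("spatio-temporal components match a flood-fill oracle", {
  adj <- chain_adj(6)
  # two non-adjacent channels at the same sample: two components
  mask <- matrix(FALSE, 6, 4)
  mask[1, 2] <- mask[4, 2] <- TRUE
  expect_length(spatiotemporal_components(mask, adj), 2)
  # one channel, samples 3..10: one component of size 8
  mask <- matrix(FALSE, 1, 12)
  mask[1, 3:10] <- TRUE
  comps <- spatiotemporal_components(mask, matrix(FALSE, 1, 1))
  expect_length(comps, 1)
  expect_identical(nrow(comps[[1]]), 8L)
  # random masks agree with the oracle
  set.seed(10)
  for (r in 1:5) {
    mask <- matrix(runif(6 * 20) < 0.4, 6, 20)
    comps <- spatiotemporal_components(mask, adj)
    lab <- oracle_components(mask, adj)
    expect_identical(length(comps), max(lab))
    sizes <- sort(vapply(comps, nrow, integer(1)))
    expect_identical(sizes, sort(unname(as.integer(table(lab[lab > 0])))))
  }
})

test_that("the permutation test is null-safe, quantized and sign-antisymmetric", {
  set.seed(11)
  n <- 10
  A <- lapply(1:n, function(i) mk_ev(matrix(rnorm(5 * 30), 5)))
  # identical conditions: zero observed statistic, nothing significant
  r0 <- permutation_test(A, A, chain_adj(5), n_perm = 200, seed = 1)
  expect_true(all(r0$observed == 0))
  expect_identical(nrow(r0$clusters), 0L)
  # strong effect: p bounded below by 1/(n_perm + 1)
  B <- lapply(A, function(ev) { ev$data <- ev$data - 3; ev })
  r1 <- permutation_test(A, B, chain_adj(5), n_perm = 200, seed = 2)
  expect_equal(min(r1$p), 1 / 201)
  expect_true(nrow(r1$clusters) > 0)
  # swapping conditions mirrors the result at the same seed
  r2 <- permutation_test(B, A, chain_adj(5), n_perm = 200, seed = 2)
  expect_equal(r2$observed, -r1$observed, tolerance = 1e-9)
  expect_equal(r2$p, r1$p)
  expect_true(all(r2$clusters$sign == "negative"))
  # small samples switch to exact enumeration over 2^n sign patterns
  A6 <- A[1:6]
  B6 <- B[1:6]
  r3 <- permutation_test(A6, B6, chain_adj(5), n_perm = 200, seed = 3)
  expect_true(r3$exact)
  expect_identical(r3$n_perm, 64)
  expect_true(all(abs(r3$p * 64 - round(r3$p * 64)) < 1e-9))
  expect_warning(permutation_test(A, B, chain_adj(5), n_perm = 50, seed = 4),
                 "coarse")
})

test_that("fixed-threshold cluster mass agrees with a direct implementation", {
  set.seed(14)
  n <- 9
  A <- lapply(1:n, function(i) mk_ev(matrix(rnorm(4 * 25), 4) +
                                       0.8 * (row(matrix(0, 4, 25)) == 2)))
  B <- lapply(1:n, function(i) mk_ev(matrix(rnorm(4 * 25), 4)))
  adj <- chain_adj(4)
  thr <- qt(0.975, n - 1)
  r <- permutation_test(A, B, adj, n_perm = 300, method = "mass",
                        mass_threshold = thr, seed = 5)
  # clusters recomputed independently from the t map
  tm <- paired_t_map(A, B)$values
  for (sgn in c(1, -1)) {
    lab <- oracle_components(sgn * tm > thr, adj)
    if (max(lab) == 0) next
    masses <- sort(abs(vapply(seq_len(max(lab)), function(k)
      sum(tm[lab == k]), numeric(1))))
    got <- sort(abs(r$clusters$mass[r$clusters$sign ==
                                      ifelse(sgn > 0, "positive", "negative")]))
    expect_equal(got, masses, tolerance = 1e-9)
  }
})
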