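mk_epochs <- function(data, fs = 500, t0 = -200, channels = NULL) {
  d <- dim(data)
  epochs(data, fs = fs, t0 = t0,
         conditions = rep("self", d[1]),
         channels = channels %||% paste0("Ch", seq_len(d[2])))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("earlobe re-referencing subtracts the linked-ear average", {
  d <- array(rnorm(2 * 4 * 100), c(2, 4, 100))
  d[, 3, ] <- 2   # A1
  d[, 4, ] <- 4   # A2
  e <- mk_epochs(d, channels = c("CZ", "PZ", "A1", "A2"))
  r <- rereference_earlobes(e)
  expect_equal(r$data[, 1, ], d[, 1, ] - 3)
  expect_equal(r$data[, 3, ] + r$data[, 4, ],
               array(0, c(2, 100)), tolerance = 1e-12)
  # zero reference leaves data unchanged
  d0 <- d; d0[, 3:4, ] <- 0
  e0 <- mk_epochs(d0, channels = c("CZ", "PZ", "A1", "A2"))
  expect_equal(rereference_earlobes(e0)$data[, 1:2, ], d0[, 1:2, ])
  expect_error(rereference_earlobes(e, left = "XX"), "XX")
})

test_that("zero-phase filtering notches 50 Hz and keeps the pass band", {
  fs <- 500; n <- 1000
  tt <- (0:(n - 1)) / fs
  x50 <- sin(2 * pi * 50 * tt)
  x10 <- sin(2 * pi * 10 * tt)
  d <- array(0, c(1, 2, n))
  d[1, 1, ] <- x50
  d[1, 2, ] <- x10
  e <- filter_epochs(mk_epochs(d, t0 = 0))
  mid <- 200:800
  att50 <- 20 * log10(max(abs(e$data[1, 1, mid])) / max(abs(x50[mid])))
  expect_lt(att50, -20)
  att10 <- 20 * log10(max(abs(e$data[1, 2, mid])) / max(abs(x10[mid])))
  expect_gt(att10, -1)
  # all-zero input stays zero
  z <- filter_epochs(mk_epochs(array(0, c(1, 1, 500)), t0 = 0))
  expect_equal(max(abs(z$data)), 0)
})

test_that("band-pass concentrates white-noise power below 30 Hz", {
  set.seed(3)
  n <- 2000
  d <- array(rnorm(n), c(1, 1, n))
  e <- filter_epochs(mk_epochs(d, t0 = 0))
  x <- e$data[1, 1, ]
  # periodogram oracle via plain FFT
  P <- Mod(fft(x))^2
  f <- (0:(n - 1)) * 500 / n
  inband <- sum(P[f > 0.5 & f < 30])
  outband <- sum(P[f > 35 & f < 250])
  expect_gt(inband / (inband + outband), 0.95)
  expect_error(filter_epochs(mk_epochs(d, t0 = 0), band = c(1, 300)), "Nyquist|inside")
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  d <- array(7, c(2, 3, 851))
  e <- baseline_correct(mk_epochs(d))
  expect_equal(max(abs(e$data)), 0)
  set.seed(1)
  d <- array(rnorm(2 * 3 * 851, mean = 1.5), c(2, 3, 851))
  e <- baseline_correct(mk_epochs(d))
  idx <- which(epoch_times(e) <= 0)
  expect_lt(max(abs(rowMeans(e$data[, , idx], dims = 2))), 1e-9)
  e2 <- baseline_correct(e)
  expect_equal(e2$data, e$data, tolerance = 1e-12)
  expect_error(baseline_correct(mk_epochs(d), c(2000, 2100)), "no samples")
})

test_that("artefact rules fire exactly as specified", {
  ns <- 500
  smooth <- 5 * sin(2 * pi * 3 * (0:(ns - 1)) / 500)   # 10 uV range, lively
  d <- array(rep(smooth, each = 4), c(4, 1, ns))
  d[2, 1, 250:ns] <- d[2, 1, 250:ns] + 60      # single 60 uV step
  d[3, 1, ] <- 0.01 * sin(2 * pi * 3 * (0:(ns - 1)) / 500)  # flat
  d[4, 1, ] <- d[4, 1, ] + 150 * sin(pi * (0:(ns - 1)) / ns) # >200 uV range? no: 150
  d[4, 1, 100] <- d[4, 1, 100] + 0  # keep
  e <- mk_epochs(d, t0 = 0)
  rej <- reject_artefacts(e)
  expect_true(rej$report$kept[1])
  expect_identical(rej$report$rule_violated[2], "step")
  expect_identical(rej$report$rule_violated[3], "activity")
  expect_true(rej$report$kept[4])   # 160 uV total range is permitted
  # brute-force oracle over random trials
  set.seed(8)
  d <- array(rnorm(6 * 2 * 300, sd = 20), c(6, 2, 300))
  e <- mk_epochs(d, t0 = 0)
  rej <- reject_artefacts(e)
  win <- 51
  for (tr in 1:6) {
    viol_step <- any(abs(apply(d[tr, , ], 1, diff)) > 50)
    viol_range <- any(apply(d[tr, , ], 1, function(x) diff(range(x))) > 200)
    viol_act <- FALSE
    for (ch in 1:2) for (s in 1:(300 - win + 1)) {
      w <- d[tr, ch, s:(s + win - 1)]
      if (diff(range(w)) < 0.5) viol_act <- TRUE
    }
    expect_identical(rej$report$kept[tr], !(viol_step || viol_range || viol_act))
  }
})

test_that("segmentation follows the inclusive-endpoint convention", {
  set.seed(2)
  cont <- matrix(rnorm(3 * 5000), 3)
  ev <- seq(600, by = 45, length.out = 72)
  e <- segment_epochs(cont, ev, c(-200, 1500), 500)
  expect_identical(dim(e$data), c(72L, 3L, 851L))
  expect_equal(e$t0, -200)
  expect_equal(e$data[1, , 101], cont[, ev[1]])   # sample at t = 0
  e1 <- segment_epochs(cont, 100, c(0, 0), 500)
  expect_identical(dim(e1$data)[3], 1L)
  expect_equal(e1$data[1, , 1], cont[, 100])
  expect_error(segment_epochs(cont, c(50, 4990), c(-200, 1500), 500),
               "event 1")
})

test_that("operations preserve ordering and append history", {
  sim <- simulate_subject(tiny_cfg(), 1)
  e <- preprocess_epochs(sim$epochs)
  ops <- vapply(e$history, `[[`, "", "op")
  expect_identical(ops, c("simulate", "rereference_earlobes", "filter_epochs",
                          "ica_ocular_correction", "baseline_correct",
                          "reject_artefacts"))
  expect_identical(e$channels, setdiff(sim$epochs$channels, c("A1", "A2")))
})
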