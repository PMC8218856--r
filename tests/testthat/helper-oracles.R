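# Independent oracles used across test files. These deliberately use naive
# direct computation (flood fill, explicit Riemann sums, enumeration,
# alternative integral forms) rather than the package's algorithms.

# plain-R flood fill over the spatio-temporal grid
oracle_components <- function(mask, adj) {
  nch <- nrow(mask); ns <- ncol(mask)
  lab <- matrix(0L, nch, ns); nxt <- 0L
  for (p in which(mask)) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      ch <- (q - 1) %% nch + 1; t <- (q - 1) %/% nch + 1
      nb <- integer()
      if (t > 1) nb <- c(nb, q - nch)
      if (t < ns) nb <- c(nb, q + nch)
      nb <- c(nb, (t - 1) * nch + which(adj[ch, ]))
      for (r in nb) if (mask[r] && lab[r] == 0L) { lab[r] <- nxt; queue <- c(queue, r) }
    }
  }
  lab
}

# brute-force TFCE: explicit threshold sweep with igraph component labelling
oracle_tfce <- function(v, adj, E = 0.5, H = 2, dh) {
  nch <- nrow(v); ns <- ncol(v); n <- nch * ns
  idx_ch <- function(p) (p - 1) %% nch + 1
  idx_t <- function(p) (p - 1) %/% nch + 1
  edges <- c()
  for (p in seq_len(n)) {
    t <- idx_t(p); ch <- idx_ch(p)
    if (t < ns) edges <- c(edges, p, p + nch)
    for (q in which(adj[ch, ])) if (q > ch) edges <- c(edges, p, (t - 1) * nch + q)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  out <- matrix(0, nch, ns)
  for (sgn in c(1, -1)) {
    x <- pmax(sgn * v, 0)
    if (max(x) <= 0) next
    for (h in seq(dh, max(x), by = dh)) {
      active <- which(x >= h)
      if (!length(active)) next
      sg <- igraph::induced_subgraph(g, active)
      cmp <- igraph::components(sg)
      ext <- cmp$csize[cmp$membership]
      out[active] <- out[active] + sgn * ext^E * h^H * dh
    }
  }
  out
}

# Rouder's g-mixture integral form of the JZS Bayes factor (independent of
# the package's noncentral-t route)
oracle_bf10_g <- function(t, n, r = 0.707) {
  nu <- n - 1
  num <- stats::integrate(function(g)
    (1 + n * g)^(-1/2) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1/2) * r * g^(-3/2) * exp(-r^2 / (2 * g)),
    0, Inf, rel.tol = 1e-10)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

# exact two-sided signed-rank p by enumerating all sign assignments
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
  list(v = v_obs, p_two = p, p_ge = mean(vs >= v_obs))
}

# Friedman statistic from its textbook mid-rank definition with the
# general tie-robust denominator
oracle_friedman_stat <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  (k - 1) * sum((colSums(r) - n * (k + 1) / 2)^2) /
    sum((r - (k + 1) / 2)^2)
}

# small default simulation configs for fast unit tests
tiny_channels <- function() reduced_channel_set()[1:12]

tiny_cfg <- function(..., n_trials = 8, rng_seed = 42,
                     epoch_window = c(-100, 400)) {
  sim_config(n_subjects = 3, n_trials = n_trials, channels = tiny_channels(),
             epoch_window = epoch_window, rng_seed = rng_seed, ...)
}

noiseless_cfg <- function(...) {
  sim_config(n_subjects = 2, n_trials = 4, channels = reduced_channel_set(),
             pink_sd = 0, white_sd = 0, alpha_amp = 0,
             p3_subject_sd = 0, lpp_subject_sd = 0,
             p3_cond_sd = 0, lpp_cond_sd = 0, artefact_rate = 0,
             rng_seed = 7, ...)
}
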