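#' Normality-gated test routing
#'
#' Shapiro-Wilk per condition column; the omnibus test is routed to the
#' nonparametric Friedman test as soon as any condition deviates from
#' normality (p < alpha), otherwise to repeated-measures ANOVA. A constant
#' column is degenerate and counts as a deviation.
#'
#' @param values subjects x conditions matrix.
#' @param alpha normality test level.
#' @return list with `route` ("anova" or "friedman") and `shapiro_p`
#'   (per-condition p-values; NA for degenerate columns).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3)
  p <- apply(values, 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  })
  deviates <- is.na(p) | p < alpha
  list(route = if (any(deviates)) "friedman" else "anova", shapiro_p = p)
}

# Greenhouse-Geisser epsilon from the sample covariance of the k conditions
.gg_epsilon <- function(values) {
  k <- ncol(values)
  S <- stats::cov(values)
  C <- diag(k) - matrix(1 / k, k, k)
  St <- C %*% S %*% C
  tr <- sum(diag(St))
  eps <- tr^2 / ((k - 1) * sum(St^2))
  min(1, max(1 / (k - 1), eps))
}

#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Classical within-subject decomposition: `SS_total = SS_subject +
#' SS_condition + SS_error`. The Greenhouse-Geisser epsilon correction is
#' always applied to the degrees of freedom (numerator df > 1), and partial
#' eta squared is reported as `SS_condition / (SS_condition + SS_error)`.
#'
#' @param values complete subjects x conditions matrix (no missing cells).
#' @return list of class `stat_result`: statistic `F`, uncorrected and
#'   corrected dfs, `epsilon`, p-values (uncorrected and GG-corrected,
#'   `p` = corrected), `eta_sq_partial`, and the SS terms.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not supported")
  n <- nrow(values)
  k <- ncol(values)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(values)
  ss_subject <- k * sum((rowMeans(values) - grand)^2)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_error <- ss_total - ss_subject - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_error <- ss_error / df2
  f <- if (ms_error > 0) ms_cond / ms_error else ifelse(ms_cond > 0, Inf, 0)
  eps <- .gg_epsilon(values)
  p_unc <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(test = "rm_anova", statistic = f,
                 df = c(df1, df2), df_corrected = c(df1 * eps, df2 * eps),
                 epsilon = eps, p_uncorrected = p_unc, p = p_gg,
                 eta_sq_partial = ss_cond / (ss_cond + ss_error),
                 ss = c(subject = ss_subject, condition = ss_cond,
                        error = ss_error),
                 correction = "greenhouse-geisser"),
            class = "stat_result")
}

#' Friedman rank test for a complete within-subject design
#'
#' @param values complete subjects x conditions matrix; rows are ranked with
#'   mid-ranks for ties.
#' @return `stat_result` with the chi-squared statistic, `df = k - 1`, p.
#' @export
friedman_rank_test <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 conditions")
  if (anyNA(values)) stop("missing cells are not supported")
  ft <- stats::friedman.test(values)
  stat <- unname(ft$statistic)
  pval <- ft$p.value
  if (!is.finite(stat)) {   # all ranks tied in every row: no evidence
    stat <- 0
    pval <- 1
  }
  structure(list(test = "friedman", statistic = stat,
                 df = unname(ft$parameter), p = pval,
                 correction = "none"),
            class = "stat_result")
}

# signed-rank statistic, Z and p for paired samples
.wilcoxon_signed_rank <- function(x, y, exact_max_n = 25) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, z = 0, p = 1, n = 0, warning = "all differences zero"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  mu <- n * (n + 1) / 4
  tie_table <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_table^3 - tie_table) / 48
  z <- if (sigma2 > 0) (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2) else 0
  if (n <= exact_max_n && !ties) {
    p <- stats::psignrank(min(v, n * (n + 1) / 2 - v), n) * 2
    p <- min(1, p)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = v, z = z, p = p, n = n, warning = NULL)
}

#' Pairwise Wilcoxon signed-rank post hocs with Bonferroni correction
#'
#' Exact two-sided p-values (signed-rank distribution) for n <= 25 without
#' ties, otherwise a normal approximation with continuity and tie
#' correction. The Bonferroni-adjusted significance threshold
#' `family_alpha / n_comparisons` is reported alongside each comparison,
#' together with the paired JZS Bayes factor.
#'
#' @param values subjects x conditions matrix.
#' @param comparisons list of label pairs; default all pairs of columns.
#' @param family_alpha family-wise level.
#' @param bf include `bf10` per comparison (see [bf10_paired_t()]).
#' @return data.frame: pair, V, Z, p, bonferroni threshold, significant,
#'   bf10.
#' @export
wilcoxon_posthocs <- function(values, comparisons = NULL, family_alpha = 0.05,
                              bf = TRUE) {
  values <- as.matrix(values)
  if (is.null(comparisons)) {
    cn <- colnames(values) %||% paste0("c", seq_len(ncol(values)))
    colnames(values) <- cn
    comparisons <- utils::combn(cn, 2, simplify = FALSE)
  }
  thr <- family_alpha / length(comparisons)
  rows <- lapply(comparisons, function(pr) {
    x <- values[, pr[1]]
    y <- values[, pr[2]]
    w <- .wilcoxon_signed_rank(x, y)
    if (!is.null(w$warning)) warning(pr[1], " vs ", pr[2], ": ", w$warning)
    b <- if (bf && stats::sd(x - y) > 0) bf10_paired_t(x, y) else NA_real_
    data.frame(a = pr[1], b = pr[2], V = w$statistic, Z = w$z, p = w$p,
               bonferroni_threshold = thr, significant = w$p < thr,
               bf10 = b)
  })
  do.call(rbind, rows)
}

#' JZS Bayes factor for a paired t contrast
#'
#' Default Bayes factor with a zero-centred Cauchy prior on the
#' standardized effect size delta: `BF10 = integral of
#' f(t | df, ncp = delta sqrt(n)) Cauchy(delta; 0, scale) d delta` divided
#' by `f(t | df, ncp = 0)`, evaluated by adaptive quadrature over the
#' noncentral-t likelihood.
#'
#' @param x,y paired samples (or `y = NULL` to test `x` against zero).
#' @param cauchy_scale prior scale (default 0.707, the "medium" prior).
#' @return BF10 (evidence for a nonzero effect over the null).
#' @export
bf10_paired_t <- function(x, y = NULL, cauchy_scale = 0.707) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  stopifnot(n >= 2)
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of differences")
  t <- mean(d) / (sdd / sqrt(n))
  bf10_from_t(t, n, cauchy_scale)
}

#' JZS Bayes factor from a t statistic
#'
#' @param t observed paired/one-sample t statistic.
#' @param n sample size (df = n - 1).
#' @param cauchy_scale Cauchy prior scale.
#' @return BF10.
#' @export
bf10_from_t <- function(t, n, cauchy_scale = 0.707) {
  nu <- n - 1
  like <- function(delta)
    suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, cauchy_scale)
  m1 <- suppressWarnings(stats::integrate(like, -Inf, Inf, rel.tol = 1e-8,
                                          stop.on.error = FALSE)$value)
  m0 <- stats::dt(t, df = nu)
  m1 / m0
}

#' Behavioural reaction-time analysis
#'
#' Keeps responded trials with RT in the analysis window, computes
#' per-subject per-condition medians, excludes subjects whose median
#' exceeds the group mean + 3 s.d. in every condition, routes the omnibus
#' test through [normality_gate()] and runs pairwise post hocs with Bayes
#' factors.
#'
#' @param rt data.frame with subject, trial, condition, rt_ms, responded.
#' @param window ms pair of analysable RTs.
#' @param alpha significance level.
#' @param outlier_sd outlier cut in group s.d. units.
#' @return list: `medians` (subject x condition matrix after exclusions),
#'   `excluded_subjects`, `route`, `omnibus` (`stat_result`), `posthocs`
#'   (data.frame with Wilcoxon and paired-t p-values and BF10),
#'   `condition_means` (group mean of medians).
#' @export
analyze_rts <- function(rt, window = c(100, 1000), alpha = 0.05,
                        outlier_sd = 3) {
  ok <- rt$responded & rt$rt_ms >= window[1] & rt$rt_ms <= window[2]
  rt <- rt[ok, , drop = FALSE]
  subjects <- sort(unique(rt$subject))
  med <- matrix(NA_real_, length(subjects), 4,
                dimnames = list(subjects, CONDITIONS))
  for (i in seq_along(subjects)) {
    for (cond in CONDITIONS) {
      v <- rt$rt_ms[rt$subject == subjects[i] & rt$condition == cond]
      if (length(v)) med[i, cond] <- stats::median(v)
    }
  }
  incomplete <- apply(med, 1, anyNA)
  if (any(incomplete)) {
    warning("subject(s) without valid trials in some condition excluded: ",
            paste(subjects[incomplete], collapse = ", "))
    med <- med[!incomplete, , drop = FALSE]
    subjects <- subjects[!incomplete]
  }
  cut <- colMeans(med) + outlier_sd * apply(med, 2, stats::sd)
  outlier <- apply(med, 1, function(r) all(r > cut))
  excluded <- subjects[outlier]
  if (length(excluded)) {
    med <- med[!outlier, , drop = FALSE]
  }
  gate <- normality_gate(med, alpha)
  omnibus <- if (gate$route == "anova") rm_anova(med) else friedman_rank_test(med)
  post <- wilcoxon_posthocs(med, family_alpha = alpha)
  # paired-t p for reference alongside the nonparametric post hocs
  post$p_t <- vapply(seq_len(nrow(post)), function(i)
    stats::t.test(med[, post$a[i]], med[, post$b[i]], paired = TRUE)$p.value,
    numeric(1))
  list(medians = med, excluded_subjects = excluded, route = gate$route,
       shapiro_p = gate$shapiro_p, omnibus = omnibus, posthocs = post,
       condition_means = colMeans(med))
}

#' @export
print.stat_result <- function(x, ...) {
  if (x$test == "rm_anova") {
    cat(sprintf("rm-ANOVA: F(%g, %g) = %.3f, GG eps = %.3f, p(GG) = %.4g, partial eta^2 = %.3f\n",
                x$df[1], x$df[2], x$statistic, x$epsilon, x$p, x$eta_sq_partial))
  } else {
    cat(sprintf("%s: chi^2(%g) = %.3f, p = %.4g\n", x$test, x$df,
                x$statistic, x$p))
  }
  invisible(x)
}
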