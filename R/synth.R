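CONDITIONS <- c("self", "fearful", "happy", "neutral")

#' Simulation configuration for a four-condition face-detection EEG study
#'
#' Defaults emulate the design of the emulated study: 30 subjects, 72 trials
#' per condition, 62-channel extended 10-20 cap sampled at 500 Hz, epochs
#' from -200 to 1500 ms, condition-specific P3 (centro-parietal, Gaussian
#' time course) and LPP (fronto-central, sustained plateau) amplitudes,
#' spatially correlated 1/f background noise, 10 Hz alpha, occasional
#' threshold-violating artefacts, and condition-specific reaction-time
#' medians. Planted P3/LPP amplitudes are defined as the pooled window-mean
#' amplitude they produce (pool and window given below), so the generator is
#' calibrated in the same units the analysis reports.
#'
#' Between-subject amplitude structure has two levels: a common per-subject
#' offset (`p3_subject_sd`, `lpp_subject_sd`, shared by all conditions, sets
#' the between-subject spread of amplitudes) and a subject-by-condition
#' jitter (`p3_cond_sd`, `lpp_cond_sd`) that determines the error variance
#' of within-subject comparisons. Defaults are calibrated to the
#' between-subject s.d. and the within-subject error variance implied by the
#' group statistics the design emulates.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per condition.
#' @param fs sampling rate, Hz.
#' @param epoch_window epoch start/end in ms, endpoints inclusive.
#' @param cond_p3_amp named vector, planted P3 pooled-window amplitude per
#'   condition (microvolts; pool PZ/CPZ/CP2/P2, window 250-500 ms).
#' @param cond_lpp_amp named vector, planted LPP pooled-window amplitude per
#'   condition (microvolts; pool FCZ/FC2/C2, window 650-900 ms).
#' @param p3_latency_ms,p3_sigma_ms Gaussian P3 bump timing.
#' @param lpp_window_ms extent of the LPP plateau (raised-cosine edges).
#' @param seed_electrodes list of component -> seed electrode labels for the
#'   spatial weighting.
#' @param spatial_falloff_cm Gaussian spatial spread (cm) of component
#'   topographies around their seeds.
#' @param pink_sd,pink_exponent,white_sd,alpha_amp noise model: per-channel
#'   s.d. of the spatially correlated 1/f^exponent background, white sensor
#'   noise s.d., and 10 Hz alpha amplitude (all microvolts).
#' @param n_noise_sources number of shared spatial sources mixed into the
#'   pink background.
#' @param p3_subject_sd,lpp_subject_sd between-subject s.d. of the common
#'   amplitude offset (microvolts).
#' @param p3_cond_sd,lpp_cond_sd s.d. of the subject-by-condition amplitude
#'   jitter (microvolts).
#' @param self_topo_shift_cm displacement (cm, towards the right) of the
#'   self condition's P3/LPP topography centre; 0 keeps all conditions on a
#'   common topography. Used for representational analyses in which the
#'   self condition carries a distinct spatial pattern.
#' @param emo_topo_shift_cm displacement magnitude (cm) of the fearful and
#'   happy topography centres, directed opposite to the self displacement
#'   (and slightly apart from each other), so that the self pattern is
#'   farther from the emotional patterns than from the neutral one.
#' @param artefact_rate fraction of trials receiving an injected artefact
#'   (voltage jump, extreme range, or flat channel).
#' @param rt_median_ms named vector of condition reaction-time medians (ms).
#' @param rt_subject_sd between-subject s.d. of the RT shift (ms).
#' @param rt_trial_sigma lognormal trial-level spread of RTs.
#' @param response_rate probability a trial has a recorded response.
#' @param channels optional subset of scalp channel labels to simulate
#'   (plus earlobes); NULL = full 62-channel cap.
#' @param rng_seed integer master seed; all randomness derives from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = 30, n_trials = 72, fs = 500,
                       epoch_window = c(-200, 1500),
                       cond_p3_amp = c(self = 7.771, fearful = 5.103,
                                       happy = 4.811, neutral = 5.300),
                       cond_lpp_amp = c(self = 16.789, fearful = 9.078,
                                        happy = 9.010, neutral = 8.759),
                       p3_latency_ms = 350, p3_sigma_ms = 60,
                       lpp_window_ms = c(600, 1250),
                       seed_electrodes = list(P3 = c("PZ", "CPZ"), LPP = "FCZ"),
                       spatial_falloff_cm = 3.5,
                       pink_sd = 4, pink_exponent = 1, white_sd = 1.5,
                       alpha_amp = 1.5, n_noise_sources = 8,
                       p3_subject_sd = 2.4, lpp_subject_sd = 7.4,
                       p3_cond_sd = 1.31, lpp_cond_sd = 3.0,
                       self_topo_shift_cm = 0,
                       emo_topo_shift_cm = 0,
                       artefact_rate = 0.03,
                       rt_median_ms = c(self = 244.925, fearful = 248.754,
                                        happy = 249.268, neutral = 247.652),
                       rt_subject_sd = 24.5, rt_trial_sigma = 0.1,
                       response_rate = 0.995,
                       channels = NULL, rng_seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (nm in c("cond_p3_amp", "cond_lpp_amp", "rt_median_ms")) {
    v <- cfg[[nm]]
    if (!setequal(names(v), CONDITIONS) || length(v) != 4)
      stop("configuration error: `", nm, "` must cover exactly conditions {",
           paste(CONDITIONS, collapse = ", "), "}")
    if (!all(is.finite(v))) stop("configuration error: `", nm, "` must be finite")
  }
  stopifnot(cfg$n_trials >= 1, cfg$fs > 0,
            length(cfg$epoch_window) == 2,
            cfg$epoch_window[1] < cfg$epoch_window[2],
            cfg$artefact_rate >= 0, cfg$artefact_rate < 1)
  invisible(cfg)
}

#' Number of samples per epoch implied by a window and sampling rate
#'
#' Endpoints are inclusive: `round((t1 - t0) / 1000 * fs) + 1`.
#' @param window ms pair. @param fs Hz.
#' @return integer sample count.
#' @export
epoch_sample_count <- function(window, fs) {
  as.integer(round((window[2] - window[1]) / 1000 * fs) + 1)
}

# Keep only the given scalp channels (plus earlobes) of a montage.
#' Subset a montage to a set of scalp channels
#' @param m a `montage`. @param scalp_labels scalp channels to keep.
#' @return a reduced `montage` (earlobes always retained).
#' @export
subset_montage <- function(m, scalp_labels) {
  stopifnot(all(scalp_labels %in% m$scalp))
  keep <- m$scalp[m$scalp %in% scalp_labels]  # preserve cap order
  labels <- c(keep, "A1", "A2")
  m$labels <- labels
  m$scalp <- keep
  m$positions <- m$positions[labels, , drop = FALSE]
  m$adjacency <- m$adjacency[keep, keep, drop = FALSE]
  m
}

# Gaussian spatial profile around seed electrodes (min distance to any seed),
# optionally displaced by a 3D shift vector (cm) for topography shifts.
.spatial_weights <- function(m, seeds, falloff_cm, shift_cm = c(0, 0, 0)) {
  stopifnot(all(seeds %in% rownames(m$positions)))
  shift_cm <- rep_len(shift_cm, 3)
  P <- m$positions[m$scalp, , drop = FALSE]
  if (!length(seeds))
    return(stats::setNames(rep(0, nrow(P)), m$scalp))
  S <- m$positions[seeds, , drop = FALSE]
  if (any(shift_cm != 0)) S <- sweep(S, 2, shift_cm, `+`)
  d2 <- vapply(seq_len(nrow(S)), function(i)
    rowSums(sweep(P, 2, S[i, ])^2), numeric(nrow(P)))
  dmin2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
  w <- exp(-dmin2 / (2 * falloff_cm^2))
  names(w) <- m$scalp
  w
}

# time profiles on [0,1]
.gauss_profile <- function(tt, mu, sigma) {
  p <- exp(-(tt - mu)^2 / (2 * sigma^2))
  p[tt < 0] <- 0   # components are post-stimulus
  p
}

.plateau_profile <- function(tt, on, off, ramp = 100) {
  p <- numeric(length(tt))
  p[tt >= on + ramp & tt <= off - ramp] <- 1
  ris <- tt >= on & tt < on + ramp
  p[ris] <- 0.5 * (1 - cos(pi * (tt[ris] - on) / ramp))
  fal <- tt > off - ramp & tt <= off
  p[fal] <- 0.5 * (1 - cos(pi * (off - tt[fal]) / ramp))
  p
}

# Evoked templates for one subject: list per condition of channels x samples
# matrices (scalp channels then earlobes). Amplitudes are calibrated so that
# the pooled window mean of each component equals `amp` exactly.
.condition_templates <- function(cfg, m, p3_amp, lpp_amp) {
  tt <- cfg$epoch_window[1] + (seq_len(epoch_sample_count(cfg$epoch_window, cfg$fs)) - 1) *
    1000 / cfg$fs
  nch <- length(m$scalp)

  shifts <- list(
    self = c(cfg$self_topo_shift_cm, 0, 0),
    fearful = cfg$emo_topo_shift_cm * c(-1, 0.5, 0),
    happy = cfg$emo_topo_shift_cm * c(-1, -0.5, 0),
    neutral = c(0, 0, 0))
  w_p3 <- list()
  w_lpp <- list()
  for (cond in CONDITIONS) {
    w_p3[[cond]] <- .spatial_weights(m, cfg$seed_electrodes$P3,
                                     cfg$spatial_falloff_cm, shifts[[cond]])
    w_lpp[[cond]] <- .spatial_weights(m, cfg$seed_electrodes$LPP,
                                      cfg$spatial_falloff_cm, shifts[[cond]])
  }
  prof_p3 <- .gauss_profile(tt, cfg$p3_latency_ms, cfg$p3_sigma_ms)
  prof_lpp <- .plateau_profile(tt, cfg$lpp_window_ms[1], cfg$lpp_window_ms[2])

  # shared early visual complex (identical across conditions)
  w_p1 <- .spatial_weights(m, intersect(c("POZ", "O1", "O2", "OZ"), m$scalp),
                           cfg$spatial_falloff_cm)
  w_n170 <- .spatial_weights(m, intersect(c("PO7", "PO8", "P7", "P8"), m$scalp),
                             cfg$spatial_falloff_cm)
  if (!length(w_p1)) w_p1 <- rep(0, nch)
  if (!length(w_n170)) w_n170 <- rep(0, nch)
  common <- 3.0 * outer(w_p1, .gauss_profile(tt, 100, 14)) -
    4.0 * outer(w_n170, .gauss_profile(tt, 170, 16)) +
    2.0 * outer(w_p1, .gauss_profile(tt, 230, 20))

  p3_pool <- intersect(c("PZ", "CPZ", "CP2", "P2"), m$scalp)
  lpp_pool <- intersect(c("FCZ", "FC2", "C2"), m$scalp)
  if (!length(p3_pool) || !length(lpp_pool))
    stop("simulated montage must contain the P3 and LPP pool electrodes")
  i_p3w <- which(tt >= 250 & tt <= 500)
  i_lppw <- which(tt >= 650 & tt <= 900)

  out <- list()
  for (cond in CONDITIONS) {
    # calibration: pooled window mean of the component = planted amplitude;
    # when the calibration window lies outside a (shortened) epoch the
    # component is scaled by its pooled peak instead
    g_p3 <- mean(w_p3[[cond]][p3_pool]) *
      (if (length(i_p3w)) mean(prof_p3[i_p3w]) else max(prof_p3, 1e-12))
    g_lpp <- mean(w_lpp[[cond]][lpp_pool]) *
      (if (length(i_lppw)) mean(prof_lpp[i_lppw]) else max(prof_lpp, 1e-12))
    tpl <- common +
      (p3_amp[[cond]] / g_p3) * outer(w_p3[[cond]], prof_p3) +
      (lpp_amp[[cond]] / g_lpp) * outer(w_lpp[[cond]], prof_lpp)
    # earlobes pick up an attenuated common scalp signal
    ear <- matrix(rep(0.1 * colMeans(tpl), 2), nrow = 2, byrow = TRUE)
    out[[cond]] <- rbind(tpl, ear)
  }
  out
}

# 1/f^(alpha) noise columns: n x m matrix, unit variance per column
.pink_noise <- function(n, m, exponent) {
  if (m == 0) return(matrix(0, n, 0))
  nf <- floor(n / 2)
  f <- c(1e-12, seq_len(n - 1))
  f[f > nf] <- n - f[f > nf]          # two-sided frequency index
  w <- matrix(stats::rnorm(n * m), n, m)
  W <- stats::mvfft(w)
  sc <- f^(-exponent / 2)
  sc[1] <- 0                          # remove DC
  W <- W * sc
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  x
}

.subject_seed <- function(rng_seed, subject_id) {
  # integer hash (splitmix-style) so related master seeds / subject ids give
  # unrelated streams; Mersenne-Twister's first draws correlate across
  # arithmetically related seeds otherwise
  x <- (rng_seed * 2654435761 + subject_id * 40503 + 12345) %% 2147483629
  x <- (x * 48271) %% 2147483629
  x <- (x * 69621) %% 2147483629
  as.integer(x)
}

#' Simulate one subject's epoched EEG and reaction times
#'
#' Per condition, generates `n_trials` epochs as the condition's evoked
#' template (shared visual complex + condition-scaled P3 bump + LPP plateau,
#' with subject-level amplitude offsets drawn once per subject) plus
#' spatially correlated pink noise, white sensor noise and posterior alpha.
#' A configured fraction of trials receives an injected artefact that
#' violates one of the rejection thresholds. Reaction times follow a shifted
#' lognormal with condition-specific medians. Fully reproducible from the
#' configuration seed.
#'
#' @param cfg a [sim_config()].
#' @param subject_id integer subject index (1-based).
#' @param montage optional pre-built montage (built/subset from `cfg` if NULL).
#' @return list with `epochs` (an [epochs()] object including earlobe
#'   channels), `rt` (data.frame subject/trial/condition/rt_ms/responded),
#'   and `artefacts` (data.frame trial/type of injected artefacts).
#' @export
simulate_subject <- function(cfg, subject_id, montage = NULL) {
  validate_sim_config(cfg)
  if (is.null(montage)) {
    montage <- make_montage()
    if (!is.null(cfg$channels)) montage <- subset_montage(montage, cfg$channels)
  }
  set.seed(.subject_seed(cfg$rng_seed, subject_id))
  invisible(stats::runif(97))  # burn-in past the generator's seeding regime

  ns <- epoch_sample_count(cfg$epoch_window, cfg$fs)
  nch_s <- length(montage$scalp)
  nch <- nch_s + 2
  ntr_c <- cfg$n_trials
  ntr <- 4L * ntr_c
  tt <- cfg$epoch_window[1] + (seq_len(ns) - 1) * 1000 / cfg$fs

  # subject-level amplitude structure
  p3_off <- stats::rnorm(1, 0, cfg$p3_subject_sd)
  lpp_off <- stats::rnorm(1, 0, cfg$lpp_subject_sd)
  p3_amp <- cfg$cond_p3_amp + p3_off + stats::rnorm(4, 0, cfg$p3_cond_sd)
  lpp_amp <- cfg$cond_lpp_amp + lpp_off + stats::rnorm(4, 0, cfg$lpp_cond_sd)
  names(p3_amp) <- names(cfg$cond_p3_amp)
  names(lpp_amp) <- names(cfg$cond_lpp_amp)
  tpl <- .condition_templates(cfg, montage, p3_amp, lpp_amp)

  # shared spatial sources for the pink background
  K <- cfg$n_noise_sources
  src <- sample(montage$scalp, K, replace = K > nch_s)
  W <- vapply(src, function(s)
    .spatial_weights(montage, s, 2 * cfg$spatial_falloff_cm), numeric(nch_s))
  W <- rbind(W, matrix(0.05, 2, K))               # weak earlobe pickup
  W <- W / sqrt(rowSums(W^2))                     # unit pink variance per channel

  w_alpha <- .spatial_weights(montage, intersect(c("OZ", "POZ", "O1", "O2"),
                                                 montage$scalp), 4)
  if (!length(w_alpha)) w_alpha <- rep(0, nch_s)
  w_alpha <- c(w_alpha, 0, 0)

  conditions <- sample(rep(CONDITIONS, each = ntr_c))
  data <- array(0, c(ntr, nch, ns))
  S_all <- .pink_noise(ns, ntr * K, cfg$pink_exponent)    # one bulk FFT pass
  phases <- stats::runif(ntr, 0, 2 * pi)
  aamps <- cfg$alpha_amp * stats::runif(ntr, 0.5, 1.5)
  for (tr in seq_len(ntr)) {
    S <- S_all[, (tr - 1) * K + seq_len(K), drop = FALSE] # ns x K
    pink <- tcrossprod(S, W) * cfg$pink_sd                # ns x nch
    white <- matrix(stats::rnorm(ns * nch, 0, cfg$white_sd), ns, nch)
    white[, nch - 1:0] <- white[, nch - 1:0] * 1.5        # earlobes noisier
    alpha <- outer(sin(2 * pi * 10 * tt / 1000 + phases[tr]) * aamps[tr],
                   w_alpha)
    data[tr, , ] <- tpl[[conditions[tr]]] + t(pink + white + alpha)
  }

  # injected artefacts
  art <- data.frame(trial = integer(), type = character())
  n_art <- stats::rbinom(1, ntr, cfg$artefact_rate)
  if (n_art > 0) {
    trs <- sample(ntr, n_art)
    types <- sample(c("jump", "range", "flat"), n_art, replace = TRUE)
    for (i in seq_len(n_art)) {
      tr <- trs[i]
      ch <- sample(nch_s, 1)
      if (types[i] == "jump") {
        at <- sample(seq(10, ns - 10), 1)
        data[tr, ch, at:ns] <- data[tr, ch, at:ns] +
          sample(c(-1, 1), 1) * stats::runif(1, 70, 120)
      } else if (types[i] == "range") {
        data[tr, ch, ] <- data[tr, ch, ] +
          sin(pi * seq(0, 1, length.out = ns)) * stats::runif(1, 230, 320)
      } else {
        data[tr, ch, ] <- stats::rnorm(1, 0, 5) + stats::rnorm(ns, 0, 0.05)
      }
    }
    art <- data.frame(trial = trs, type = types)
  }

  e <- epochs(data, fs = cfg$fs, t0 = cfg$epoch_window[1],
              conditions = conditions, channels = montage$labels,
              subject_id = subject_id,
              history = list(list(op = "simulate",
                                  params = list(seed = .subject_seed(cfg$rng_seed, subject_id)))))

  rt <- simulate_rts(cfg, subject_id, conditions)
  list(epochs = e, rt = rt, artefacts = art)
}

#' Simulate reaction times for one subject
#'
#' Shifted-lognormal model: `rt = (median_c + subject_shift) * exp(sigma z)`
#' so the per-subject, per-condition median equals the planted condition
#' median plus a subject-level random shift.
#'
#' @param cfg a [sim_config()].
#' @param subject_id subject index (used only for labelling; the RNG state
#'   is taken as-is so this can be called inside [simulate_subject()]).
#' @param conditions per-trial condition labels.
#' @return data.frame with subject, trial, condition, rt_ms, responded.
#' @export
simulate_rts <- function(cfg, subject_id, conditions) {
  shift <- stats::rnorm(1, 0, cfg$rt_subject_sd)
  med <- cfg$rt_median_ms[conditions] + shift
  rt <- med * exp(stats::rnorm(length(conditions), 0, cfg$rt_trial_sigma))
  data.frame(subject = subject_id, trial = seq_along(conditions),
             condition = conditions, rt_ms = as.numeric(rt),
             responded = stats::runif(length(conditions)) < cfg$response_rate)
}

#' Simulate a full multi-subject study
#'
#' Subjects are independent, each with a seed derived from the master seed.
#' With `dir` given, each subject is written to the on-disk epoch container
#' (`sub-<id>.bin/.json`) and the pooled RT table to `rt.csv`; otherwise
#' everything is returned in memory.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @return list with `subjects` (list of [simulate_subject()] results, or
#'   file stems when `dir` is given), `rt` (pooled RT table), `montage`.
#' @export
simulate_study <- function(cfg, dir = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  montage <- make_montage()
  if (!is.null(cfg$channels)) montage <- subset_montage(montage, cfg$channels)
  subjects <- vector("list", cfg$n_subjects)
  rts <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    sim <- simulate_subject(cfg, s, montage)
    rts[[s]] <- sim$rt
    if (!is.null(dir)) {
      stem <- file.path(dir, sprintf("sub-%02d", s))
      ok <- tryCatch(write_epochs(sim$epochs, stem), error = function(e)
        stop("failed to write epochs to ", stem, ": ", conditionMessage(e)))
      subjects[[s]] <- stem
    } else {
      subjects[[s]] <- sim
    }
  }
  rt <- do.call(rbind, rts)
  if (!is.null(dir))
    utils::write.csv(rt, file.path(dir, "rt.csv"), row.names = FALSE)
  list(subjects = subjects, rt = rt, montage = montage, config = cfg)
}

#' Reduced scalp subset for desk-scale analyses
#'
#' A 21-channel subset of the cap covering the centro-parietal P3 pool, the
#' fronto-central LPP pool and a posterior/temporal periphery, used by the
#' replicate-based validation studies to keep runtimes at desk scale while
#' preserving the spatial structure the analyses rely on.
#'
#' @return character vector of scalp channel labels.
#' @export
reduced_channel_set <- function() {
  c("PZ", "CPZ", "CP2", "P2", "P1", "CP1", "POZ", "FCZ", "FC2", "C2",
    "CZ", "FZ", "O1", "OZ", "O2", "PO7", "PO8", "C1", "FC1", "P3", "CP3")
}

#' Null-study configuration (no condition effects)
#'
#' All four conditions share identical planted amplitudes and no
#' subject-by-condition amplitude jitter, so any between-condition
#' difference is pure noise: the configuration under which cluster tests
#' must reject at their nominal rate. Geometry is reduced (short epochs,
#' small channel subset) because false-positive calibration does not depend
#' on it.
#'
#' @param n_subjects,n_trials,rng_seed study size and seed.
#' @param channels scalp subset.
#' @param epoch_window ms pair.
#' @return a [sim_config()].
#' @export
sim_config_null <- function(n_subjects = 20, n_trials = 8, rng_seed = 1,
                            channels = reduced_channel_set()[1:12],
                            epoch_window = c(-100, 200)) {
  eq <- function(v) c(self = v, fearful = v, happy = v, neutral = v)
  sim_config(n_subjects = n_subjects, n_trials = n_trials,
             epoch_window = epoch_window,
             cond_p3_amp = eq(5.746), cond_lpp_amp = eq(10.909),
             p3_cond_sd = 0, lpp_cond_sd = 0,
             artefact_rate = 0, channels = channels, rng_seed = rng_seed)
}

#' Self-distinct topography configuration
#'
#' All conditions share identical component amplitudes (the grand means of
#' the default amplitude maps) and no subject-by-condition jitter; the self
#' condition's topography centre is displaced, and the two emotional
#' conditions are displaced by a smaller amount in roughly the opposite
#' direction. The representational structure this plants -- the self
#' pattern distinct from all others, and more distant from the emotional
#' patterns than from the neutral one -- is the structure under which the
#' self-only template is a positive predictor and the self+fear /
#' self+happy templates are negative predictors of the distance series.
#'
#' @param n_subjects,n_trials,rng_seed study size and seed.
#' @param channels scalp subset.
#' @param self_shift_cm,emo_shift_cm displacement magnitudes.
#' @return a [sim_config()].
#' @export
sim_config_self_distinct <- function(n_subjects = 20, n_trials = 16,
                                     rng_seed = 1,
                                     channels = reduced_channel_set(),
                                     self_shift_cm = 2, emo_shift_cm = 0.7) {
  eq <- function(v) c(self = v, fearful = v, happy = v, neutral = v)
  sim_config(n_subjects = n_subjects, n_trials = n_trials,
             cond_p3_amp = eq(5.746), cond_lpp_amp = eq(10.909),
             p3_cond_sd = 0, lpp_cond_sd = 0,
             self_topo_shift_cm = self_shift_cm,
             emo_topo_shift_cm = emo_shift_cm,
             channels = channels, rng_seed = rng_seed)
}
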