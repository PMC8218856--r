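#' Pipeline configuration
#'
#' Bundles and validates the parameters of every stage. Can be loaded from
#' a YAML or JSON file via [read_pipeline_config()]; every stage's
#' parameters are serialized into the run's provenance log.
#'
#' @param sim a [sim_config()].
#' @param rules a [rejection_rules()].
#' @param components a [component_windows()] list.
#' @param alpha significance level for all frequentist tests.
#' @param cauchy_scale JZS prior scale.
#' @param n_perm permutations for cluster tests.
#' @param tfce list of TFCE parameters `E`, `H`, `n_steps`.
#' @param cluster_method "tfce" or "mass".
#' @param rsa list: `width_ms`, `n_splits`, `vectorization`.
#' @param seed master seed for analysis-stage randomness (splits,
#'   permutations).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), rules = rejection_rules(),
                            components = component_windows(),
                            alpha = 0.05, cauchy_scale = 0.707,
                            n_perm = 1000,
                            tfce = list(E = 0.5, H = 2, n_steps = 100),
                            cluster_method = "tfce",
                            rsa = list(width_ms = 32, n_splits = 1,
                                       vectorization = "offdiag"),
                            seed = 1) {
  stopifnot(alpha > 0, alpha < 1, cauchy_scale > 0, n_perm >= 1,
            cluster_method %in% c("tfce", "mass"),
            rsa$vectorization %in% c("offdiag", "full64"))
  validate_sim_config(sim)
  structure(list(sim = sim, rules = rules, components = components,
                 alpha = alpha, cauchy_scale = cauchy_scale, n_perm = n_perm,
                 tfce = tfce, cluster_method = cluster_method, rsa = rsa,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar overrides in the file replace the package defaults; unknown keys
#' are an error (schema validation before any stage runs).
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("sim", "rules", "components", "alpha", "cauchy_scale", "n_perm",
             "tfce", "cluster_method", "rsa", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$rules)) args$rules <- do.call(rejection_rules, raw$rules)
  if (!is.null(raw$components))
    args$components <- do.call(component_windows, raw$components)
  for (key in c("alpha", "cauchy_scale", "n_perm", "cluster_method", "seed"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  for (key in c("tfce", "rsa"))
    if (!is.null(raw[[key]])) args[[key]] <- utils::modifyList(
      formals(pipeline_config)[[key]] |> eval(), raw[[key]])
  do.call(pipeline_config, args)
}

#' Run the full simulated-study analysis pipeline
#'
#' Simulate -> preprocess -> component amplitude table + univariate
#' statistics -> paired cluster-permutation contrasts (self vs fearful /
#' happy / neutral) -> RSA template regression with group cluster tests ->
#' behavioural RT analysis. All result tables are written to `out_dir`
#' (CSV/JSON, keys sorted by subject) along with a provenance log, and
#' returned invisibly.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("erp", "stats", "cluster", "rsa", "behaviour")` to run after
#'   simulation + preprocessing.
#' @return list with `amplitudes`, `erp_stats`, `clusters`, `rsa`,
#'   `behaviour`, `rejections`, `provenance` (invisible).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir,
                         stages = c("erp", "stats", "cluster", "rsa",
                                    "behaviour")) {
  t_start <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .stage_msg <- function(...) message(sprintf("[%s] %s",
                                              format(Sys.time(), "%H:%M:%S"),
                                              sprintf(...)))
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    .stage_msg("stage %s ...", name)
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .stage_msg("stage %s done (%.1f s)", name,
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
    r
  }

  study <- run_stage("simulate", simulate_study(cfg$sim))
  amp <- run_stage("preprocess+erp",
                   study_amplitudes(study, cfg$components, cfg$rules))
  out <- list(amplitudes = amp$table, rejections = amp$rejections)
  utils::write.csv(amp$table[order(amp$table$subject, amp$table$condition), ],
                   file.path(out_dir, "amplitude_table.csv"), row.names = FALSE)
  utils::write.csv(amp$rejections, file.path(out_dir, "rejection_report.csv"),
                   row.names = FALSE)

  if ("stats" %in% stages) {
    out$erp_stats <- run_stage("stats", {
      res <- list()
      for (comp in names(cfg$components)) {
        m <- amplitude_matrix(amp$table, comp)
        gate <- normality_gate(m, cfg$alpha)
        omni <- if (gate$route == "anova") rm_anova(m) else friedman_rank_test(m)
        post <- wilcoxon_posthocs(m, family_alpha = cfg$alpha)
        res[[comp]] <- list(route = gate$route, omnibus = omni, posthocs = post)
      }
      res
    })
    stats_rows <- do.call(rbind, lapply(names(out$erp_stats), function(comp) {
      ph <- out$erp_stats[[comp]]$posthocs
      ph$component <- comp
      ph
    }))
    utils::write.csv(stats_rows, file.path(out_dir, "erp_posthocs.csv"),
                     row.names = FALSE)
  }

  if ("cluster" %in% stages) {
    out$clusters <- run_stage("cluster", {
      evs <- amp$evokeds
      adj <- study$montage$adjacency
      res <- list()
      for (other in c("fearful", "happy", "neutral")) {
        a <- lapply(evs, `[[`, "self")
        b <- lapply(evs, `[[`, other)
        keep <- !vapply(a, is.null, TRUE) & !vapply(b, is.null, TRUE)
        cr <- permutation_test(a[keep], b[keep], adj, n_perm = cfg$n_perm,
                               alpha = cfg$alpha, method = cfg$cluster_method,
                               E = cfg$tfce$E, H = cfg$tfce$H,
                               n_steps = cfg$tfce$n_steps,
                               seed = cfg$seed + match(other, CONDITIONS))
        write_cluster_result(cr, file.path(out_dir,
                                           paste0("cluster_self_vs_", other, ".json")))
        res[[paste0("self_vs_", other)]] <- cr
      }
      res
    })
  }

  if ("rsa" %in% stages) {
    out$rsa <- run_stage("rsa", {
      tmpl <- build_templates(cfg$rsa$vectorization)
      betas <- list()
      for (s in seq_along(amp$evokeds)) {
        sub <- study$subjects[[s]]
        e <- if (is.character(sub)) read_epochs(sub) else sub$epochs
        e <- preprocess_epochs(e, rules = cfg$rules)
        betas[[s]] <- subject_rsa(e, tmpl, seed = cfg$seed + s,
                                  width_ms = cfg$rsa$width_ms,
                                  n_splits = cfg$rsa$n_splits)
      }
      tests <- list()
      rows <- list()
      for (reg in c("self_fear", "self_happy", "self_only")) {
        cr <- group_beta_cluster_test(betas, reg, n_perm = cfg$n_perm,
                                      alpha = cfg$alpha,
                                      seed = cfg$seed + 100 + nchar(reg))
        tests[[reg]] <- cr
        if (nrow(cr$clusters)) {
          cl <- cr$clusters
          cl$model <- reg
          rows[[reg]] <- cl
        }
      }
      tbl <- if (length(rows)) do.call(rbind, rows) else .empty_clusters()
      utils::write.csv(tbl, file.path(out_dir, "rsa_clusters.csv"),
                       row.names = FALSE)
      list(betas = betas, tests = tests, clusters = tbl)
    })
  }

  if ("behaviour" %in% stages) {
    out$behaviour <- run_stage("behaviour", analyze_rts(study$rt,
                                                        alpha = cfg$alpha))
    utils::write.csv(data.frame(condition = names(out$behaviour$condition_means),
                                mean_median_rt_ms = out$behaviour$condition_means),
                     file.path(out_dir, "rt_medians.csv"), row.names = FALSE)
  }

  out$provenance <- list(
    config = rapply(unclass(cfg), unclass, how = "replace"),
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("erppipe")),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(out$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out)
}

#' Subject x condition amplitude matrix for one component
#'
#' @param table amplitude table from [build_amplitude_table()].
#' @param component component name.
#' @return subjects x 4 matrix (condition columns in canonical order).
#' @export
amplitude_matrix <- function(table, component) {
  tb <- table[table$component == component, ]
  subjects <- sort(unique(tb$subject))
  m <- matrix(NA_real_, length(subjects), 4,
              dimnames = list(subjects, CONDITIONS))
  for (i in seq_len(nrow(tb)))
    m[as.character(tb$subject[i]), tb$condition[i]] <- tb$amplitude_uv[i]
  m
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header (INI format), the `.vmrk` marker file and the
#' binary `.eeg` data file (multiplexed `IEEE_FLOAT_32` or `INT_16` with
#' per-channel resolution). Read-only support for the common vendor layout.
#'
#' @param vhdr path to the header file.
#' @return list: `data` (channels x samples matrix, microvolts), `fs`,
#'   `channels`, `events` (data.frame type/description/sample).
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) stop("header file not found: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("header field missing: ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  datafile <- file.path(dirname(vhdr), get_field("DataFile"))
  markerfile <- file.path(dirname(vhdr), get_field("MarkerFile"))
  fmt <- get_field("DataFormat")
  if (toupper(fmt) != "BINARY") stop("unsupported DataFormat: ", fmt)
  orient <- get_field("DataOrientation")
  if (toupper(orient) != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", orient)
  nch <- as.integer(get_field("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_field("SamplingInterval"))
  binfmt <- toupper(get_field("BinaryFormat"))

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != nch)
    stop("header inconsistent: NumberOfChannels=", nch, " but ",
         length(ch_lines), " channel entries")
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))

  if (!file.exists(datafile)) stop("data file not found: ", datafile)
  sz <- file.info(datafile)$size
  con <- file(datafile, "rb")
  on.exit(close(con), add = TRUE)
  if (binfmt == "IEEE_FLOAT_32") {
    n <- sz / 4
    x <- readBin(con, "double", n = n, size = 4, endian = "little")
  } else if (binfmt == "INT_16") {
    n <- sz / 2
    x <- readBin(con, "integer", n = n, size = 2, signed = TRUE,
                 endian = "little")
  } else stop("unsupported BinaryFormat: ", binfmt)
  ns <- length(x) %/% nch
  data <- matrix(x[seq_len(ns * nch)], nrow = nch) * res
  rownames(data) <- labels

  if (!file.exists(markerfile)) stop("marker file not found: ", markerfile)
  mk <- grep("^Mk[0-9]+=", readLines(markerfile, warn = FALSE), value = TRUE)
  mparts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  events <- data.frame(
    type = vapply(mparts, `[`, "", 1),
    description = vapply(mparts, `[`, "", 2),
    sample = as.integer(vapply(mparts, `[`, "", 3)))
  list(data = data, fs = fs, channels = labels, events = events)
}
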