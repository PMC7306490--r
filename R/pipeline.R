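# End-to-end orchestration: simulate -> preprocess -> metrics ->
# group statistics -> clustering.

#' The canonical 11 site pairs
#'
#' Three homologous (symmetric) pairs, four finger-toe pairs and four
#' ear-finger pairs, in the order used by the multiple-comparison
#' table.
#' @return data.frame with columns `a`, `b`.
#' @export
default_pairs <- function() {
  p <- rbind(c("LE", "RE"), c("LF", "RF"), c("LT", "RT"),
             c("LF", "LT"), c("RF", "LT"), c("LF", "RT"), c("RF", "RT"),
             c("LE", "LF"), c("RE", "LF"), c("LE", "RF"), c("RE", "RF"))
  data.frame(a = p[, 1], b = p[, 2], stringsAsFactors = FALSE)
}

#' Assemble the full pipeline configuration
#'
#' All defaults reproduce the acquisition and analysis settings of the
#' study design: 31.25 Hz sampling, 0.01-0.15 Hz sLFO band, 300 s / 30 s
#' moving windows, +/- 20 s lag search, MCCC significance threshold
#' 0.3, fuzzifier b = 2.
#'
#' @param ... overrides for any top-level element.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs = 31.25,
    band = c(0.01, 0.15),
    filter_order = 4,
    scheme = window_scheme(300, 30),
    max_lag = 20,
    mccc_threshold = 0.3,
    optics = optics_constants(),
    preprocess = list(spike = TRUE, wavelet = TRUE, z_thresh = 5, guard = 3L,
                      levels = 6L, k_thresh = 3.3, artifact_domain = "hemo"),
    psd = list(segment_s = 100, overlap = 0.5),
    pairs = default_pairs(),
    summary = "median",
    features = list(mccc_pairs = "LE-RE",
                    delay_pairs = c("LF-LT", "RF-LT", "LF-RT", "RF-RT")),
    fcm = list(b = 2, epsilon = 1e-5, max_iter = 300, n_restarts = 10),
    bh_dialect = "plain",
    vascular = vascular_config(),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_param("unknown config element(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# FNV-1a over the YAML serialization: a short stable fingerprint so
# every emitted table can be traced to the configuration that made it.
config_hash <- function(config) {
  txt <- yaml::as.yaml(lapply(config, function(el)
    if (is.function(el)) "function" else el))
  h <- 0
  for (byte in utf8ToInt(txt)) h <- (h * 31 + byte) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate a cohort under a pipeline configuration
#'
#' Wraps [simulate_cohort()] with the configuration's vascular model,
#' optics and seed, and writes a provenance record (`provenance.yaml`:
#' configuration echo, hash, seed, package version) beside the
#' recordings.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param n_healthy,n_stroke subject counts (default 25 each).
#' @param duration recording length in seconds.
#' @return the written [cohort_manifest()].
#' @export
run_simulate <- function(config = pipeline_config(), out_dir,
                         n_healthy = 25, n_stroke = 25, duration = 600) {
  man <- simulate_cohort(n_healthy, n_stroke, out_dir,
                         cfg = config$vascular, duration = duration,
                         fs = config$fs, optics = config$optics,
                         seed = config$seed)
  yaml::write_yaml(list(config_hash = config_hash(config),
                        seed = config$seed,
                        n_healthy = n_healthy, n_stroke = n_stroke,
                        duration = duration, fs = config$fs,
                        package_version = as.character(utils::packageVersion("slfomark"))),
                   file.path(out_dir, "provenance.yaml"))
  man
}

# Preprocess all sites of one recording; returns named list of sLFO
# Delta[HbO] series.
preprocess_recording <- function(rec, config) {
  pp <- config$preprocess
  setNames(lapply(rec$sites, function(s) {
    h <- preprocess_site(rec$intensity[[s]][, "660"], rec$intensity[[s]][, "920"],
                         fs = rec$fs, optics = config$optics, site = s,
                         spike = pp$spike, wavelet = pp$wavelet,
                         z_thresh = pp$z_thresh, guard = pp$guard,
                         levels = pp$levels, k_thresh = pp$k_thresh,
                         band = config$band, order = config$filter_order,
                         artifact_domain = pp$artifact_domain)
    h$hbo
  }), rec$sites)
}

# Metrics for all configured pairs of one subject's sLFO signals.
subject_pair_metrics <- function(slfo, fs, config) {
  pairs <- config$pairs
  lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    if (!(a %in% names(slfo)) || !(b %in% names(slfo))) return(NULL)
    pair_metrics(slfo[[a]], slfo[[b]], fs, scheme = config$scheme,
                 max_lag = config$max_lag,
                 mccc_threshold = config$mccc_threshold,
                 pair = c(a, b), summary = config$summary)
  })
}

#' Cluster biomarker features and evaluate discrimination
#'
#' Fits a two-cluster fuzzy c-means model to the given feature columns,
#' identifies the stroke-like cluster from the center geometry -- the
#' center with the lower feature mean when `stroke_like = "low"` (MCCC
#' features: lesions reduce symmetric correlation) or the higher mean
#' when `"high"` (absolute-delay features: lesions add delay) -- so the
#' clustering itself stays unsupervised, and scores each subject by its
#' membership in that cluster. When group labels are supplied the score
#' is evaluated by [roc_auc()].
#'
#' @param features numeric matrix/data.frame of the selected feature
#'   columns (rows = subjects, non-finite rows dropped).
#' @param labels optional group labels for ROC evaluation.
#' @param stroke_like `"low"` or `"high"`: which center is stroke-like.
#' @param config a [pipeline_config()] (FCM settings and seed).
#' @param k number of clusters (default 2).
#' @return list: `model`, `kept` (row indices used), `score`
#'   (stroke-like membership), `hard_label` (`"stroke-like"` /
#'   `"healthy-like"`), `roc` (NULL without labels).
#' @export
fcm_classify <- function(features, labels = NULL,
                         stroke_like = c("low", "high"),
                         config = pipeline_config(), k = 2) {
  stroke_like <- match.arg(stroke_like)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  kept <- which(apply(x, 1, function(r) all(is.finite(r))))
  x <- x[kept, , drop = FALSE]
  fc <- config$fcm
  model <- fcm_fit(x, k = k, b = fc$b, epsilon = fc$epsilon,
                   max_iter = fc$max_iter, n_restarts = fc$n_restarts,
                   seed = child_seed(config$seed, 97))
  center_level <- rowMeans(model$centers)
  stroke_cluster <- if (stroke_like == "low") which.min(center_level)
                    else which.max(center_level)
  score <- model$memberships[, stroke_cluster]
  roc <- if (!is.null(labels) && k == 2) {
    l <- labels[kept]
    if (length(unique(l[!is.na(l)])) == 2) roc_auc(score, l) else NULL
  }
  list(model = model, kept = kept, score = score,
       hard_label = ifelse(max.col(model$memberships) == stroke_cluster,
                           "stroke-like", "healthy-like"),
       stroke_cluster = stroke_cluster, roc = roc)
}

#' Run the full analysis over a cohort
#'
#' For every manifest entry: read the recording, preprocess all sites
#' to sLFO Delta\[HbO\], compute windowed MCCC/delay metrics for the
#' configured site pairs and the Welch spectral profile per site. Then,
#' when both groups are present: rank-sum comparisons of the per-pair
#' MCCC and delay summaries with BH adjustment (one family per metric
#' type), and fuzzy c-means classification of the configured feature
#' sets with ROC evaluation. Per-subject failures are logged and
#' skipped; the run fails only if no subject succeeds.
#'
#' @param config a [pipeline_config()].
#' @param manifest a `cohort_manifest` or path to a manifest file.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as CSV together with a configuration echo.
#' @return list with `window_metrics`, `subject_summary`,
#'   `spectral_summary`, `features`, `comparisons`, `fcm_mccc`,
#'   `fcm_delay`, `failed_subjects`, `config_hash`.
#' @export
run_analyze <- function(config = pipeline_config(), manifest, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "cohort_manifest"))
  entries <- manifest$entries
  if (!nrow(entries)) stop_param("empty manifest")
  win_rows <- list(); sum_rows <- list(); psd_rows <- list()
  failed <- character(0)
  for (i in seq_len(nrow(entries))) {
    id <- entries$subject_id[i]
    res <- tryCatch({
      rec <- read_recording(entries$file[i])
      slfo <- preprocess_recording(rec, config)
      pms <- subject_pair_metrics(slfo, rec$fs, config)
      pms <- pms[!vapply(pms, is.null, TRUE)]
      wr <- do.call(rbind, lapply(pms, function(pm)
        cbind(subject = id, group = entries$group[i],
              pair = paste(pm$pair, collapse = "-"), pm$windows)))
      sr <- do.call(rbind, lapply(pms, function(pm)
        data.frame(subject = id, group = entries$group[i],
                   pair = paste(pm$pair, collapse = "-"),
                   mccc_summary = pm$mccc_summary,
                   delay_summary = pm$delay_summary,
                   abs_delay_variance = pm$abs_delay_variance,
                   n_significant = pm$n_significant,
                   stringsAsFactors = FALSE)))
      pr <- do.call(rbind, lapply(names(slfo), function(s) {
        prof <- compute_psd(slfo[[s]], rec$fs,
                            segment_s = config$psd$segment_s,
                            overlap = config$psd$overlap, band = config$band)
        data.frame(subject = id, group = entries$group[i], site = s,
                   spectral_width = spectral_width(prof),
                   peak_freq = prof$freqs[which.max(prof$psd)],
                   stringsAsFactors = FALSE)
      }))
      list(wr = wr, sr = sr, pr = pr)
    }, error = function(e) {
      message(sprintf("subject %s failed: %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, id) else {
      win_rows[[id]] <- res$wr; sum_rows[[id]] <- res$sr; psd_rows[[id]] <- res$pr
    }
  }
  if (!length(sum_rows)) stop_param("all subjects failed")
  window_metrics <- do.call(rbind, win_rows)
  subject_summary <- do.call(rbind, sum_rows)
  spectral_summary <- do.call(rbind, psd_rows)
  rownames(window_metrics) <- rownames(subject_summary) <-
    rownames(spectral_summary) <- NULL

  # wide per-subject feature table: one MCCC and one delay column per pair
  subjects <- unique(subject_summary$subject)
  feat <- data.frame(subject = subjects,
                     group = entries$group[match(subjects, entries$subject_id)],
                     stringsAsFactors = FALSE)
  for (p in unique(subject_summary$pair)) {
    sel <- subject_summary[subject_summary$pair == p, ]
    m <- match(subjects, sel$subject)
    feat[[paste0("mccc_", p)]] <- sel$mccc_summary[m]
    feat[[paste0("delay_", p)]] <- sel$delay_summary[m]
  }

  comparisons <- NULL; fcm_mccc <- NULL; fcm_delay <- NULL
  two_groups <- all(table(factor(feat$group, c("healthy", "stroke"))) >= 2)
  if (two_groups) {
    pair_names <- unique(subject_summary$pair)
    cm <- compare_groups(feat, feat$group,
                         columns = paste0("mccc_", pair_names),
                         dialect = config$bh_dialect)
    cd <- compare_groups(feat, feat$group,
                         columns = paste0("delay_", pair_names),
                         dialect = config$bh_dialect)
    comparisons <- data.frame(
      pair = pair_names,
      mccc_p = cm$p_value, mccc_adjusted_p = cm$adjusted_p, mccc_tier = cm$tier,
      delay_p = cd$p_value, delay_adjusted_p = cd$adjusted_p,
      delay_tier = cd$tier, stringsAsFactors = FALSE)
    fcm_mccc <- fcm_classify(
      feat[paste0("mccc_", config$features$mccc_pairs)],
      labels = feat$group, stroke_like = "low", config = config)
    delay_cols <- paste0("delay_", config$features$delay_pairs)
    fcm_delay <- fcm_classify(
      feat[delay_cols], labels = feat$group, stroke_like = "high",
      config = config)
  }

  out <- list(window_metrics = window_metrics,
              subject_summary = subject_summary,
              spectral_summary = spectral_summary,
              features = feat, comparisons = comparisons,
              fcm_mccc = fcm_mccc, fcm_delay = fcm_delay,
              failed_subjects = failed, config_hash = config_hash(config))
  if (!is.null(out_dir)) write_analysis(out, config, out_dir)
  out
}

write_analysis <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    df <- cbind(df, config_hash = out$config_hash)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(out$window_metrics, "window_metrics.csv")
  wcsv(out$subject_summary, "subject_summary.csv")
  wcsv(out$spectral_summary, "spectral_summary.csv")
  wcsv(out$features, "features.csv")
  wcsv(out$comparisons, "comparisons.csv")
  for (nm in c("fcm_mccc", "fcm_delay")) {
    fc <- out[[nm]]
    if (is.null(fc)) next
    wcsv(data.frame(subject = out$features$subject[fc$kept],
                    group = out$features$group[fc$kept],
                    score = fc$score, hard_label = fc$hard_label),
         paste0(nm, "_memberships.csv"))
    if (!is.null(fc$roc)) {
      wcsv(fc$roc$curve, paste0(nm, "_roc.csv"))
    }
  }
  cfg_echo <- lapply(config, function(el) {
    if (is.function(el)) return("function")
    if (inherits(el, "optics_constants"))
      return(list(dpf = as.list(el$dpf),
                  extinction = apply(el$extinction, 1, as.list, simplify = FALSE),
                  separation = el$separation))
    if (is.data.frame(el)) return(lapply(el, as.vector))
    if (is.list(el)) return(lapply(el, function(x) if (is.function(x)) "function" else x))
    el
  })
  yaml::write_yaml(c(list(config_hash = out$config_hash), cfg_echo),
                   file.path(out_dir, "config_echo.yaml"))
  invisible(NULL)
}

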