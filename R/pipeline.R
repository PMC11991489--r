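# End-to-end orchestration over a dataset directory laid out as
# subject/condition/state.edf (as written by gen_study). Stage artifacts are
# plain files (CSV/JSON; epoch blocks as RDS working files) so every stage
# can be run, inspected and re-run independently.

read_index <- function(dataset_dir) {
  idx_path <- file.path(dataset_dir, "index.csv")
  if (file.exists(idx_path)) {
    idx <- utils::read.csv(idx_path, stringsAsFactors = FALSE)
    idx$path <- file.path(dataset_dir, idx$subject, idx$condition,
                          paste0(idx$state, ".edf"))
  } else {
    files <- list.files(dataset_dir, pattern = "\\.edf$", recursive = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no EDF recordings under ", dataset_dir)
    parts <- strsplit(sub(paste0("^", dataset_dir, "/?"), "", files), "/")
    idx <- do.call(rbind, lapply(seq_along(files), function(i) data.frame(
      subject = parts[[i]][1], condition = parts[[i]][2],
      state = sub("\\.edf$", "", parts[[i]][3]), path = files[i],
      stringsAsFactors = FALSE)))
  }
  missing <- !file.exists(idx$path)
  if (any(missing))
    stop("missing recordings: ", paste(idx$path[missing], collapse = ", "))
  idx
}

rec_id <- function(row) paste(row$subject, row$condition, row$state, sep = "_")

stage_report <- function(stage, inputs, outputs, params, t0,
                         warnings = character()) {
  list(stage = stage, inputs = inputs, outputs = outputs, params = params,
       warnings = warnings,
       elapsed_s = round(as.numeric(Sys.time()) - t0, 2))
}

#' Preprocess every recording of a dataset
#'
#' Runs the EEG and EMG cleaning chains on each recording and stores the
#' epoch blocks and cleaned continuous signals as per-recording RDS working
#' files under `out_dir/preprocessed`.
#'
#' @param dataset_dir dataset root (subject/condition/state.edf).
#' @param out_dir pipeline output directory.
#' @param config configuration list, see [default_config()].
#' @return a stage report list.
#' @export
pipeline_preprocess <- function(dataset_dir, out_dir,
                                config = default_config()) {
  t0 <- as.numeric(Sys.time())
  idx <- read_index(dataset_dir)
  pdir <- file.path(out_dir, "preprocessed")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  outs <- character()
  for (i in seq_len(nrow(idx))) {
    rec <- read_recording(idx$path[i])
    eeg <- preprocess_eeg(rec, config)
    emg <- preprocess_emg(rec, config)
    out <- file.path(pdir, paste0(rec_id(idx[i, ]), ".rds"))
    saveRDS(list(eeg = eeg, emg = emg, meta = rec$meta), out)
    outs <- c(outs, out)
  }
  utils::write.csv(idx[, c("subject", "condition", "state")],
                   file.path(pdir, "index.csv"), row.names = FALSE)
  stage_report("preprocess", idx$path, outs,
               config[c("eeg_band", "notches", "target_rate",
                        "epoch_length")], t0)
}

preprocessed_index <- function(out_dir) {
  pdir <- file.path(out_dir, "preprocessed")
  idx <- utils::read.csv(file.path(pdir, "index.csv"),
                         stringsAsFactors = FALSE)
  idx$path <- file.path(pdir, paste0(idx$subject, "_", idx$condition, "_",
                                     idx$state, ".rds"))
  idx
}

#' EMG fatigue feature stage
#'
#' Per-epoch RMS/MPF/MF in the configured sub-bands for every contraction
#' recording; written to `emg_features.csv` (plus subject-level means in
#' `emg_features_subject.csv`).
#'
#' @inheritParams pipeline_preprocess
#' @return a stage report list.
#' @export
pipeline_emg <- function(dataset_dir, out_dir, config = default_config()) {
  t0 <- as.numeric(Sys.time())
  idx <- preprocessed_index(out_dir)
  idx <- idx[idx$state != "rest", ]
  rows <- list()
  for (i in seq_len(nrow(idx))) {
    pp <- readRDS(idx$path[i])
    rows[[i]] <- emg_feature_table(pp$emg$epochs, config$emg_sub_bands,
                                   config)
  }
  tab <- do.call(rbind, rows)
  out1 <- file.path(out_dir, "emg_features.csv")
  utils::write.csv(tab, out1, row.names = FALSE)
  agg <- stats::aggregate(cbind(rms, mpf, mf) ~ subject + condition +
                            state + band, data = tab, FUN = mean)
  out2 <- file.path(out_dir, "emg_features_subject.csv")
  utils::write.csv(agg, out2, row.names = FALSE)
  stage_report("emg_features", idx$path, c(out1, out2),
               config["emg_sub_bands"], t0)
}

#' PLV connectivity stage
#'
#' ROI-level PLV matrix per recording and band, written as one CSV per
#' (recording, band) under `out_dir/plv/<band>/`.
#'
#' @inheritParams pipeline_preprocess
#' @param bands character vector of band names to compute (default
#'   `"alpha"`).
#' @param roi_map ROI map, see [default_roi_map()].
#' @return a stage report list.
#' @export
pipeline_plv <- function(dataset_dir, out_dir, config = default_config(),
                         bands = "alpha", roi_map = default_roi_map()) {
  t0 <- as.numeric(Sys.time())
  idx <- preprocessed_index(out_dir)
  outs <- character()
  for (bn in bands) {
    bdir <- file.path(out_dir, "plv", bn)
    dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(idx))) {
      pp <- readRDS(idx$path[i])
      pm <- plv_matrix(pp$eeg$epochs, roi_map, config$bands[[bn]],
                       order = config$filter_order)
      out <- file.path(bdir, paste0(rec_id(idx[i, ]), ".csv"))
      utils::write.csv(data.frame(roi = pm$rois, pm$plv,
                                  check.names = FALSE),
                       out, row.names = FALSE)
      outs <- c(outs, out)
    }
  }
  stage_report("plv", idx$path, outs, list(bands = bands), t0)
}

read_plv_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(tab[, -1])
  dimnames(M) <- list(tab$roi, tab$roi)
  M
}

#' Graph-metric stage
#'
#' Small-world and efficiency metrics over the sparsity grid for every PLV
#' matrix produced by [pipeline_plv()]; long CSV `graph_metrics.csv`.
#'
#' @inheritParams pipeline_plv
#' @param n_random null-ensemble size per sparsity level (default from
#'   config).
#' @return a stage report list.
#' @export
pipeline_graph <- function(dataset_dir, out_dir, config = default_config(),
                           bands = "alpha", n_random = config$n_random) {
  t0 <- as.numeric(Sys.time())
  rows <- list()
  ins <- character()
  for (bn in bands) {
    bdir <- file.path(out_dir, "plv", bn)
    for (f in list.files(bdir, pattern = "\\.csv$", full.names = TRUE)) {
      M <- read_plv_csv(f)
      met <- metrics_over_sparsity(M, config$sparsity, n_random,
                                   seed = substream_seed(config$seed,
                                                         basename(f)))
      met$recording <- sub("\\.csv$", "", basename(f))
      met$band <- bn
      rows[[length(rows) + 1]] <- met
      ins <- c(ins, f)
    }
  }
  out <- file.path(out_dir, "graph_metrics.csv")
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
  stage_report("graph_metrics", ins, out,
               list(sparsity = config$sparsity, n_random = n_random), t0)
}

load_plv_stack <- function(out_dir, band, condition, state) {
  bdir <- file.path(out_dir, "plv", band)
  files <- list.files(bdir, pattern = paste0("_", condition, "_", state,
                                             "\\.csv$"),
                      full.names = TRUE)
  if (!length(files)) stop("no PLV matrices for ", condition, "/", state)
  subjects <- sub("_.*$", "", basename(files))
  files <- files[order(subjects)]
  mats <- lapply(files, read_plv_csv)
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)),
               dimnames = c(dimnames(mats[[1]]), list(sort(subjects))))
  arr
}

#' NBS contrast stage
#'
#' Paired network-based-statistic contrast of PLV matrices between the two
#' sleep conditions within a state; result serialized as JSON.
#'
#' @inheritParams pipeline_plv
#' @param band band name (default `"alpha"`).
#' @param state motor state to contrast (default `"rest"`).
#' @param n_perm permutations (default from config).
#' @return a stage report list (with the `mb_nbs` result attached as
#'   `$result`).
#' @export
pipeline_nbs <- function(dataset_dir, out_dir, config = default_config(),
                         band = "alpha", state = "rest",
                         n_perm = config$n_perm) {
  t0 <- as.numeric(Sys.time())
  A <- load_plv_stack(out_dir, band, "good", state)
  B <- load_plv_stack(out_dir, band, "poor", state)
  res <- nbs_paired(A, B, config$edge_alpha, config$comp_alpha, n_perm,
                    seed = substream_seed(config$seed, "nbs"))
  out <- file.path(out_dir, sprintf("nbs_%s_%s.json", band, state))
  jsonlite::write_json(
    list(band = band, state = state, n_perm = n_perm,
         components = lapply(seq_along(res$components), function(i)
           list(edges = res$components[[i]],
                extent = nrow(res$components[[i]]),
                p = res$component_p[i])),
         significant = res$significant),
    out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rep <- stage_report("nbs", file.path(out_dir, "plv", band), out,
                      list(band = band, state = state, n_perm = n_perm), t0)
  rep$result <- res
  rep
}

#' MVAR/PDC stage
#'
#' For every contraction recording, fits one MVAR (BIC order selection) to
#' the cleaned continuous C3, C4 and EMG channels over the configured
#' segment and computes band-averaged PDC for beta, gamma1 and gamma2;
#' written to `pdc_band.csv`.
#'
#' @inheritParams pipeline_preprocess
#' @return a stage report list.
#' @export
pipeline_pdc <- function(dataset_dir, out_dir, config = default_config()) {
  t0 <- as.numeric(Sys.time())
  idx <- preprocessed_index(out_dir)
  idx <- idx[idx$state != "rest", ]
  rows <- list()
  warns <- character()
  for (i in seq_len(nrow(idx))) {
    pp <- readRDS(idx$path[i])
    eeg <- pp$eeg$continuous
    emg <- pp$emg$continuous
    n <- min(ncol(eeg$data), ncol(emg$data),
             round(config$pdc_segment * eeg$rate))
    ic <- match(config$pdc_channels, eeg$labels)
    if (anyNA(ic)) stop("PDC channels missing from EEG")
    joint <- recording(
      rbind(eeg$data[ic, seq_len(n), drop = FALSE],
            emg$data[1, seq_len(n), drop = FALSE]),
      eeg$rate, c(config$pdc_channels, "EMG"),
      kinds = c(rep("EEG", length(ic)), "EMG"), meta = pp$meta)
    model <- withCallingHandlers(
      fit_mvar(joint, max_order = config$pdc_max_order),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    spec <- pdc(model, variant = config$pdc_variant)
    for (bn in c("beta", "gamma1", "gamma2")) {
      bp <- band_pdc(spec, config$bands[[bn]])
      bp$subject <- idx$subject[i]
      bp$condition <- idx$condition[i]
      bp$state <- idx$state[i]
      bp$band <- bn
      bp$order <- model$order
      rows[[length(rows) + 1]] <- bp
    }
  }
  out <- file.path(out_dir, "pdc_band.csv")
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
  stage_report("pdc", idx$path, out,
               config[c("pdc_segment", "pdc_variant", "pdc_channels")],
               t0, warns)
}

#' Condition contrast stage
#'
#' Paired sleep-condition contrasts of (i) subject-level EMG features per
#' band and state (Wilcoxon signed rank), and (ii) band PDC per directed
#' pair and state (paired t with BH-FDR across the family). Written to
#' `emg_contrasts.csv` and `pdc_contrasts.csv`.
#'
#' @inheritParams pipeline_preprocess
#' @return a stage report list (with both tables attached).
#' @export
pipeline_contrasts <- function(dataset_dir, out_dir,
                               config = default_config()) {
  t0 <- as.numeric(Sys.time())
  emg <- utils::read.csv(file.path(out_dir, "emg_features_subject.csv"),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (st in unique(emg$state)) for (bn in unique(emg$band)) {
    for (feat in c("rms", "mpf", "mf")) {
      a <- emg[emg$state == st & emg$band == bn & emg$condition == "good", ]
      b <- emg[emg$state == st & emg$band == bn & emg$condition == "poor", ]
      a <- a[order(a$subject), ]
      b <- b[order(b$subject), ]
      if (!nrow(a) || !identical(a$subject, b$subject)) next
      res <- wilcoxon_signed(a[[feat]], b[[feat]])
      rows[[length(rows) + 1]] <- data.frame(
        state = st, band = bn, feature = feat, statistic = res$statistic,
        p = res$p,
        direction = if (mean(b[[feat]] - a[[feat]]) >= 0) "increase"
                    else "decrease",  # poor relative to good
        stringsAsFactors = FALSE)
    }
  }
  emg_con <- do.call(rbind, rows)
  emg_con$q_significant <- fdr_bh(emg_con$p, config$fdr_q)
  out1 <- file.path(out_dir, "emg_contrasts.csv")
  utils::write.csv(emg_con, out1, row.names = FALSE)

  pdc_tab <- utils::read.csv(file.path(out_dir, "pdc_band.csv"),
                             stringsAsFactors = FALSE)
  pdc_rows <- list()
  for (st in unique(pdc_tab$state)) {
    a <- pdc_tab[pdc_tab$state == st & pdc_tab$condition == "poor", ]
    b <- pdc_tab[pdc_tab$state == st & pdc_tab$condition == "good", ]
    con <- pdc_contrast(a, b, q = config$fdr_q)
    con$state <- st
    pdc_rows[[length(pdc_rows) + 1]] <- con
  }
  pdc_con <- do.call(rbind, pdc_rows)
  out2 <- file.path(out_dir, "pdc_contrasts.csv")
  utils::write.csv(pdc_con, out2, row.names = FALSE)
  rep <- stage_report("contrasts",
                      file.path(out_dir, c("emg_features_subject.csv",
                                           "pdc_band.csv")),
                      c(out1, out2), list(fdr_q = config$fdr_q), t0)
  rep$emg <- emg_con
  rep$pdc <- pdc_con
  rep
}

#' Run the full pipeline over a dataset
#'
#' preprocess -> EMG features -> PLV -> graph metrics -> NBS -> PDC ->
#' contrasts, with one stage report each and a combined `summary.json`.
#' Any stage failure halts the pipeline; completed stage outputs are
#' retained.
#'
#' @param dataset_dir dataset root (e.g. from [gen_study()]).
#' @param out_dir output directory for all stage artifacts.
#' @param config configuration list, see [default_config()].
#' @param bands PLV band names (default `"alpha"`).
#' @param n_random,n_perm ensemble sizes (default from config).
#' @return list of stage reports, invisibly.
#' @export
run_pipeline <- function(dataset_dir, out_dir, config = default_config(),
                         bands = "alpha", n_random = config$n_random,
                         n_perm = config$n_perm) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  reports$preprocess <- pipeline_preprocess(dataset_dir, out_dir, config)
  reports$emg <- pipeline_emg(dataset_dir, out_dir, config)
  reports$plv <- pipeline_plv(dataset_dir, out_dir, config, bands)
  reports$graph <- pipeline_graph(dataset_dir, out_dir, config, bands,
                                  n_random)
  reports$nbs <- pipeline_nbs(dataset_dir, out_dir, config, bands[1],
                              "rest", n_perm)
  reports$pdc <- pipeline_pdc(dataset_dir, out_dir, config)
  reports$contrasts <- pipeline_contrasts(dataset_dir, out_dir, config)
  summ <- lapply(reports, function(r)
    r[c("stage", "outputs", "elapsed_s", "warnings")])
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(reports)
}
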