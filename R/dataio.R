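#' Read a recording from disk
#'
#' Dispatches on format: EDF (16-bit, with optional JSON sidecar for kinds
#' and metadata) or CSV (channels as rows, header row of labels) with a
#' mandatory JSON sidecar carrying at least the sampling rate.
#'
#' @param path file path (`.edf` or `.csv`).
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @return an `mb_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(read_edf(path))
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(tab[[1]])
  data <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(data) <- NULL
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("CSV recordings need a JSON sidecar with the sampling rate: ", side)
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(sc$rate)) stop("sidecar lacks 'rate'")
  recording(data, sc$rate, labels, kinds = sc$kinds,
            meta = if (is.null(sc$meta)) list() else as.list(sc$meta))
}

#' Write a recording to disk
#'
#' EDF stores values with 16-bit quantization over a symmetric physical
#' range; CSV is exact (full double precision). Both write a JSON sidecar.
#'
#' @param rec an `mb_recording`.
#' @param path output path.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  validate_recording(rec)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(write_edf(rec, path))
  # %.17g preserves doubles exactly through the text round trip
  vals <- matrix(sprintf("%.17g", rec$data), nrow(rec$data))
  tab <- data.frame(channel = rec$labels, vals, check.names = FALSE)
  names(tab) <- c("channel", paste0("s", seq_len(ncol(rec$data))))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(rate = rec$rate, labels = rec$labels, kinds = rec$kinds,
         meta = rec$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default run configuration
#'
#' Defaults reproduce the study settings: 2 s epochs, EEG band 1-100 Hz with
#' 48-52 and 98-102 Hz notches, resampling to 500 Hz, mastoid (M1/M2)
#' re-reference, EMG band 20-150 Hz, PLV sparsity grid 0.22-0.29 in steps of
#' 0.01 with 1000 random null networks, 2000 NBS permutations at edge and
#' component alpha 0.05, and a 180 s PDC segment over C3/C4 + EMG.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    epoch_length = 2,
    eeg_band = c(1, 100),
    notches = list(c(48, 52), c(98, 102)),
    target_rate = 500,
    ref_labels = c("M1", "M2"),
    emg_band = c(20, 150),
    emg_sub_bands = list(low = c(20, 100), high = c(100, 150)),
    filter_order = 4,
    reject_abs_uV = 150,
    reject_z_max = 5,
    bands = list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                 beta = c(13, 30), gamma1 = c(30, 60), gamma2 = c(60, 100)),
    sparsity = seq(0.22, 0.29, by = 0.01),
    n_random = 1000,
    n_perm = 2000,
    edge_alpha = 0.05,
    comp_alpha = 0.05,
    fdr_q = 0.05,
    pdc_segment = 180,
    pdc_variant = "paper_H",
    pdc_max_order = 20,
    pdc_channels = c("C3", "C4"),
    welch_win = 1,
    welch_overlap = 0.5,
    seed = 1L,
    out_dir = "mbconn_out"
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Unset keys are filled with [default_config()] values; unknown keys are
#' kept (and reported by [validate_config()]).
#'
#' @param path config file (`.yaml`/`.yml`/`.json`), or `NULL` for defaults.
#' @return named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(user)) {
    for (k in names(user)) {
      v <- user[[k]]
      if (k %in% c("notches", "emg_sub_bands", "bands") && !is.list(v))
        v <- as.list(as.data.frame(v))
      cfg[[k]] <- v
    }
  }
  viol <- validate_config(cfg)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  cfg
}

#' Validate a run configuration
#'
#' Total: every malformed value yields a named violation string, never an
#' error.
#'
#' @param cfg config list as from [load_config()].
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(cfg) {
  v <- character()
  chk_band <- function(b, name) {
    if (!is.numeric(b) || length(b) != 2 || !all(is.finite(b)))
      return(sprintf("%s: must be two finite numbers", name))
    if (b[1] >= b[2]) return(sprintf("%s: lo (%g) >= hi (%g)", name, b[1], b[2]))
    character()
  }
  num_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      sprintf("%s: must be a single positive number", name) else character()
  }
  v <- c(v, num_pos(cfg$epoch_length, "epoch_length"),
         num_pos(cfg$target_rate, "target_rate"),
         num_pos(cfg$n_random, "n_random"),
         num_pos(cfg$n_perm, "n_perm"),
         chk_band(cfg$eeg_band, "eeg_band"),
         chk_band(cfg$emg_band, "emg_band"))
  for (i in seq_along(cfg$notches))
    v <- c(v, chk_band(cfg$notches[[i]], paste0("notches[", i, "]")))
  for (nm in names(cfg$bands))
    v <- c(v, chk_band(cfg$bands[[nm]], paste0("bands$", nm)))
  if (!is.numeric(cfg$sparsity) || !length(cfg$sparsity) ||
      any(!is.finite(cfg$sparsity)) ||
      any(cfg$sparsity <= 0 | cfg$sparsity >= 1))
    v <- c(v, "sparsity: all levels must lie in (0, 1)")
  for (a in c("edge_alpha", "comp_alpha", "fdr_q")) {
    if (!is.numeric(cfg[[a]]) || length(cfg[[a]]) != 1 ||
        !is.finite(cfg[[a]]) || cfg[[a]] <= 0 || cfg[[a]] >= 1)
      v <- c(v, sprintf("%s: must lie in (0, 1)", a))
  }
  if (!is.null(cfg$pdc_variant) &&
      !cfg$pdc_variant %in% c("paper_H", "standard_Abar"))
    v <- c(v, "pdc_variant: must be 'paper_H' or 'standard_Abar'")
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    v <- c(v, paste0("unknown key: ", unknown))
  v
}
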