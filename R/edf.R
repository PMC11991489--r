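# Minimal EDF (European Data Format, 16-bit) reader/writer.
# Scope: continuous recordings, one common sampling rate, physical unit uV.
# Channel kinds and study metadata travel in a JSON sidecar (<path>.json);
# without a sidecar, kinds are guessed from the labels.

edf_pad <- function(x, n) {
  x <- substr(x, 1, n)
  paste0(x, strrep(" ", n - nchar(x)))
}

edf_header_num <- function(x, n) edf_pad(format(x, scientific = FALSE, trim = TRUE), n)

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' covering the data; the quantization step is `(2*max|x|)/65535` microvolts.
#' Data are laid out in 1-second records when the sample count is a whole
#' number of seconds, otherwise in a single record.
#'
#' @param rec an `mb_recording`; data must be finite.
#' @param path output file path.
#' @param sidecar write a JSON sidecar with kinds and metadata (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, sidecar = TRUE) {
  validate_recording(rec)
  n_ch <- nrow(rec$data)
  n_s <- ncol(rec$data)
  if (abs(rec$rate - round(rec$rate)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  rate <- round(rec$rate)
  if (n_s %% rate == 0) {
    spr <- rate
    n_rec <- n_s %/% rate
    rec_dur <- 1
  } else {
    spr <- n_s
    n_rec <- 1
    rec_dur <- n_s / rate
  }
  pmax_ <- max(abs(rec$data), 1e-6)
  phys_min <- -pmax_
  phys_max <- pmax_
  dig_min <- -32768
  dig_max <- 32767
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((rec$data - phys_min) / scale) + dig_min
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    "01.01.26", "00.00.00",
    edf_header_num(256 * (n_ch + 1), 8), edf_pad("", 44),
    edf_header_num(n_rec, 8), edf_header_num(rec_dur, 8),
    edf_header_num(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, n) writeChar(paste(vapply(vals, edf_pad, "", n = n),
                                             collapse = ""), con, eos = NULL)
  field(rec$labels, 16)
  field(rep("", n_ch), 80)                      # transducer
  field(rep("uV", n_ch), 8)                     # physical dimension
  field(rep(format(phys_min, scientific = FALSE), n_ch), 8)
  field(rep(format(phys_max, scientific = FALSE), n_ch), 8)
  field(rep(format(dig_min), n_ch), 8)
  field(rep(format(dig_max), n_ch), 8)
  field(rep("", n_ch), 80)                      # prefiltering
  field(rep(format(spr), n_ch), 8)
  field(rep("", n_ch), 32)                      # reserved
  # data records: per record, each channel's samples contiguously, int16 LE
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  if (sidecar) {
    jsonlite::write_json(
      list(rate = rec$rate, labels = rec$labels, kinds = rec$kinds,
           meta = rec$meta),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' All signals must share one sampling rate. If `<path>.json` exists it
#' supplies channel kinds and metadata; otherwise kinds are guessed from the
#' labels.
#'
#' @param path EDF file path.
#' @return an `mb_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                         # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || n_ch < 1) stop("malformed EDF header")
  fields <- function(n) vapply(seq_len(n_ch), function(i) rd(n), "")
  labels <- fields(16)
  fields(80)
  fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1)
    stop("EDF reader supports a single common sampling rate only")
  spr <- spr[1]
  if (anyDuplicated(labels))
    stop("duplicate channel labels in EDF header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rate <- spr / rec_dur
  out <- matrix(0, n_ch, n_rec * spr)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = n_ch * spr, size = 2,
                   endian = "little")
    out[, ((r - 1) * spr + 1):(r * spr)] <-
      t(matrix(raw, nrow = spr, ncol = n_ch))
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(n_ch))
    out[i, ] <- (out[i, ] - dig_min[i]) * scale[i] + phys_min[i]
  side <- paste0(path, ".json")
  kinds <- NULL
  meta <- list()
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(sc$kinds)) kinds <- sc$kinds
    if (!is.null(sc$meta)) meta <- as.list(sc$meta)
    if (!is.null(sc$rate)) rate <- sc$rate
  }
  recording(out, rate, labels, kinds, meta)
}
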