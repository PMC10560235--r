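#' Continuous multichannel recording
#'
#' Container for a continuous recording: channels x time sample matrix,
#' sampling rate, unique channel labels and an optional channel -> ROI map.
#'
#' @param samples numeric matrix, channels x time (signal units, e.g. uV).
#' @param fs sampling rate in Hz.
#' @param labels channel labels.
#' @param roi_map optional named character vector or list mapping channel
#'   label -> ROI label.
#' @param units signal units string.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, labels = NULL, roi_map = NULL,
                      units = "uV") {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stopf("fs must be a positive scalar")
  }
  if (!all(is.finite(samples))) stopf("samples must be finite")
  labels <- labels %||% paste0("ch", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples)) stopf("labels length mismatch")
  if (anyDuplicated(labels)) stopf("channel labels must be unique")
  if (!is.null(roi_map)) {
    roi_map <- unlist(roi_map)
    unknown <- setdiff(names(roi_map), labels)
    if (length(unknown)) {
      stopf("roi_map refers to unknown channels: %s",
            paste(unknown, collapse = ", "))
    }
  }
  structure(list(samples = samples, fs = fs, labels = labels,
                 roi_map = roi_map, units = units),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.3f s, %s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$units))
  invisible(x)
}

#' Read and write recordings (native container or EDF)
#'
#' The package's native container (`format = "rds"`) stores the recording
#' schema (`data`, `fs`, `labels`, `roi_map`, `units`) via R serialization
#' and round-trips bit-exactly. `format = "edf"` reads/writes European Data
#' Format files (16-bit samples with per-signal physical/digital scaling per
#' the EDF specification); EDF round trips are exact up to the 16-bit
#' amplitude quantization, and the signal length must be an integer number
#' of 1-second data records.
#'
#' @param path file path.
#' @param format `"rds"` or `"edf"`; for reading, inferred from the file
#'   extension when omitted.
#' @param rec a [recording()].
#' @return `read_recording` returns a [recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||%
    (if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "rds")
  switch(format,
    rds = {
      obj <- readRDS(path)
      if (!is.list(obj) || !all(c("data", "fs", "labels") %in% names(obj))) {
        stopf("not a native recording container: %s", path)
      }
      recording(obj$data, fs = obj$fs, labels = obj$labels,
                roi_map = obj$roi_map, units = obj$units %||% "uV")
    },
    edf = read_edf(path),
    stopf("unknown format '%s'", format))
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "recording"))
  format <- format %||%
    (if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "rds")
  switch(format,
    rds = saveRDS(list(data = rec$samples, fs = rec$fs, labels = rec$labels,
                       roi_map = rec$roi_map, units = rec$units),
                  path, version = 2),
    edf = write_edf(rec, path),
    stopf("unknown format '%s'", format))
  invisible(path)
}

## ---- EDF (European Data Format), 16-bit continuous recordings ----------

## format a number into at most 8 ASCII characters, EDF header style
edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  formatC(signif(x, 2), format = "e", digits = 1)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  N <- ncol(rec$samples)
  spr <- as.integer(round(rec$fs))  # samples per 1 s record
  if (abs(rec$fs - spr) > 1e-9) stopf("EDF writer requires an integer fs")
  if (N %% spr != 0) {
    stopf("EDF writer requires a whole number of 1 s records (%d samples at fs = %d); trim or pad first",
          N, spr)
  }
  nrec <- N %/% spr
  pmin <- apply(rec$samples, 1, min)
  pmax <- apply(rec$samples, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  ## the header stores physical ranges as 8-char ASCII; digitize against the
  ## values as written so read-back scaling matches exactly
  pmin_s <- vapply(pmin, edf_num8, "")
  pmax_s <- vapply(pmax, edf_num8, "")
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep(rec$units, ns), 8)                 # physical dimension
  field(pmin_s, 8)
  field(pmax_s, 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                       # reserved
  gain <- (pmax - pmin) / (dmax - dmin)
  dig <- round((rec$samples - pmin) / gain + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(nrec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < width) {
      stopf("malformed EDF header in %s: truncated at offset %s", path,
            seek(con))
    }
    trimws(raw)
  }
  version <- rd(8)
  if (version != "0") stopf("malformed EDF header in %s: bad version field at offset 0", path)
  rd(80); rd(80); rd(8); rd(8)
  nbytes_hdr <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("malformed EDF header in %s: bad signal count at offset 252", path)
  if (nbytes_hdr != 256 + 256 * ns) {
    stopf("malformed EDF header in %s: header size %d does not match %d signals",
          path, nbytes_hdr, ns)
  }
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80)
  units <- fields(8)
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L) {
    stopf("EDF reader supports a single sampling rate; found %s",
          paste(unique(spr), collapse = ", "))
  }
  n_per_rec <- sum(spr)
  vals <- readBin(con, integer(), n = nrec * n_per_rec, size = 2,
                  signed = TRUE, endian = "little")
  if (length(vals) != nrec * n_per_rec) {
    stopf("truncated EDF data in %s: expected %d samples, found %d",
          path, nrec * n_per_rec, length(vals))
  }
  samples <- matrix(0, ns, nrec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    block <- matrix(vals[(r - 1L) * n_per_rec + seq_len(n_per_rec)],
                    nrow = spr[1], ncol = ns)
    samples[, (r - 1L) * spr[1] + seq_len(spr[1])] <-
      t(block) * gain + (pmin - dmin * gain)
  }
  fs <- spr[1] / dur
  recording(samples, fs = fs, labels = labels, units = unique(units)[1])
}

## ---- events and ROI maps ------------------------------------------------

#' Read and write event tables (TSV)
#'
#' Events follow a BIDS-events-like layout with columns `onset_s`,
#' `duration_s` and any trial annotation columns (`trial_class`,
#' `word_pair`, `bias`, `vot_step`, `congruency`, `phase`).
#'
#' @param events data frame with at least `onset_s` and `duration_s`.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  if (!all(c("onset_s", "duration_s") %in% names(events))) {
    stopf("events must have onset_s and duration_s columns")
  }
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE)
}

#' Read and write channel -> ROI maps (JSON)
#'
#' @param roi_map named character vector or list `{channel: roi}`.
#' @param path file path.
#' @export
write_roi_map <- function(roi_map, path) {
  jsonlite::write_json(as.list(unlist(roi_map)), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_map
#' @export
read_roi_map <- function(path) {
  unlist(jsonlite::read_json(path))
}
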