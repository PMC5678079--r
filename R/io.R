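#' Read a raw EEG recording from disk
#'
#' Dispatches on format: BrainVision header files (`.vhdr`, with their
#' `.eeg`/`.vmrk` companions) or EDF/EDF+ files (`.edf`). Data are returned
#' in microvolts with 0-based event sample indices.
#'
#' @param path file path (`.vhdr` or `.edf`; `"auto"` dispatches on the
#'   extension).
#' @param format `"auto"`, `"brainvision"` or `"edf"`.
#' @param require_events error if no events are present? Default `TRUE`
#'   (an un-annotated recording cannot be epoched).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf"),
                           require_events = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      vhdr = "brainvision",
      edf = "edf",
      stop("unknown recording format for extension '.", ext,
           "' (expected .vhdr or .edf)", call. = FALSE))
  }
  rec <- switch(format,
    brainvision = read_brainvision(path),
    edf = read_edf(path))
  if (require_events && nrow(rec$events) == 0L) {
    stop("no events: the recording has no stimulation-onset markers", call. = FALSE)
  }
  rec
}

# ---- BrainVision (.vhdr / .eeg / .vmrk) -------------------------------------

parse_ini <- function(lines) {
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "[")) {
      section <- gsub("\\[|\\]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr` (text header), `<base>.eeg` (multiplexed binary,
#' IEEE float 32) and `<base>.vmrk` (markers). Each event becomes a
#' `Stimulus` marker with description `S<label>` at its 1-based sample
#' position.
#'
#' @param rec an [eeg_recording()].
#' @param path output `.vhdr` path (companions are placed alongside).
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (tolower(tools::file_ext(path)) != "vhdr") path <- paste0(path, ".vhdr")
  base <- sub("\\.vhdr$", "", basename(path), ignore.case = TRUE)
  dir <- dirname(path)
  eeg_file <- file.path(dir, paste0(base, ".eeg"))
  vmrk_file <- file.path(dir, paste0(base, ".vmrk"))
  m <- nrow(rec$data)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", m),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$rate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(m), rec$channel_names))
  writeLines(hdr, path, useBytes = TRUE)

  con <- file(eeg_file, "wb")
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  close(con)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(rec$events)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%d,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$label, rec$events$sample + 1L))
  }
  writeLines(mk, vmrk_file, useBytes = TRUE)
  invisible(path)
}

read_brainvision <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ini <- parse_ini(readLines(path, warn = FALSE, encoding = "UTF-8"))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chi <- ini[["Channel Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", path, call. = FALSE)
  if (!identical(toupper(ci$DataFormat), "BINARY") ||
      !identical(toupper(ci$DataOrientation), "MULTIPLEXED")) {
    stop("only BINARY/MULTIPLEXED BrainVision data are supported", call. = FALSE)
  }
  m <- as.integer(ci$NumberOfChannels)
  rate <- 1e6 / as.numeric(ci$SamplingInterval)
  ch <- vapply(seq_len(m), function(i) {
    spec <- chi[[paste0("Ch", i)]]
    if (is.null(spec)) stop("channel Ch", i, " missing from header", call. = FALSE)
    strsplit(spec, ",", fixed = TRUE)[[1]][1]
  }, character(1))
  res <- vapply(seq_len(m), function(i) {
    parts <- strsplit(chi[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    if (length(parts) >= 3L && nzchar(parts[3])) as.numeric(parts[3]) else 1
  }, numeric(1))

  dir <- dirname(path)
  eeg_file <- file.path(dir, ci$DataFile)
  fmt <- toupper(bi$BinaryFormat %||% "IEEE_FLOAT_32")
  nbytes <- file.size(eeg_file)
  con <- file(eeg_file, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, numeric(), n = nbytes %/% 4L, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(con, integer(), n = nbytes %/% 2L, size = 2L, signed = TRUE,
                   endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  n_samp <- length(raw) %/% m
  if (n_samp * m != length(raw)) {
    stop(sprintf("data size inconsistent with %d channels", m), call. = FALSE)
  }
  data <- matrix(raw, nrow = m, ncol = n_samp)   # multiplexed: channels fast
  if (fmt == "INT_16") data <- data * res

  events <- data.frame(sample = integer(), label = integer())
  vmrk_file <- file.path(dir, ci$MarkerFile %||% "")
  if (nzchar(ci$MarkerFile %||% "") && file.exists(vmrk_file)) {
    mki <- parse_ini(readLines(vmrk_file, warn = FALSE, encoding = "UTF-8"))
    mks <- mki[["Marker Infos"]] %||% list()
    rows <- lapply(mks, function(spec) {
      parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
      if (length(parts) < 3L || trimws(parts[1]) != "Stimulus") return(NULL)
      lab <- suppressWarnings(as.integer(gsub("[^0-9]", "", parts[2])))
      data.frame(sample = as.integer(parts[3]) - 1L, label = lab)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) events <- do.call(rbind, rows)
  }
  eeg_recording(data, rate, ch, events)
}

# ---- EDF / EDF+ -------------------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(format(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as an EDF+ file
#'
#' 16-bit EDF+C with one-second data records and an `EDF Annotations`
#' stream carrying one time-stamped annotation per event (text = the target
#' id). The recording is zero-padded to a whole number of records; each
#' channel is scaled to its own physical range.
#'
#' @param rec an [eeg_recording()].
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- nrow(rec$data)
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  rate <- as.integer(round(rate))
  n_rec <- as.integer(ceiling(ncol(rec$data) / rate))
  data <- matrix(0, nrow = m, ncol = n_rec * rate)
  data[, seq_len(ncol(rec$data))] <- rec$data

  phys_max <- apply(data, 1L, function(x) max(abs(x), 1e-6))
  dig_max <- 32767
  gain <- phys_max / dig_max
  digital <- round(sweep(data, 1L, gain, "/"))

  # annotation stream (raw bytes: TALs use \x14 separators and \x00
  # terminators, which cannot live in R character strings)
  SEP <- as.raw(0x14); NUL <- as.raw(0x00)
  ann_per_rec <- lapply(seq_len(n_rec) - 1L, function(r) {
    tal <- c(charToRaw(sprintf("+%d", r)), SEP, SEP)
    ev <- rec$events[rec$events$sample %/% rate == r, , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      tal <- c(tal, NUL, charToRaw(sprintf("+%.6f", ev$sample[j] / rate)), SEP,
               charToRaw(as.character(ev$label[j])), SEP)
    }
    c(tal, NUL)
  })
  ann_bytes <- max(vapply(ann_per_rec, length, integer(1))) + 2L
  ann_samples <- as.integer(ceiling(ann_bytes / 2))

  ns <- m + 1L
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8L); wr("X X X X", 80L); wr("Startdate 01-JAN-2026 X X X", 80L)
  wr("01.01.26", 8L); wr("00.00.00", 8L)
  wr(header_bytes, 8L); wr("EDF+C", 44L); wr(n_rec, 8L); wr("1", 8L); wr(ns, 4L)
  labels <- c(rec$channel_names, "EDF Annotations")
  for (lab in labels) wr(lab, 16L)
  for (i in seq_len(ns)) wr("", 80L)                     # transducer
  for (i in seq_len(ns)) wr(if (i <= m) "uV" else "", 8L)
  for (i in seq_len(ns)) wr(if (i <= m) sprintf("%.6g", -phys_max[i]) else "-1", 8L)
  for (i in seq_len(ns)) wr(if (i <= m) sprintf("%.6g", phys_max[i]) else "1", 8L)
  for (i in seq_len(ns)) wr("-32768", 8L)
  for (i in seq_len(ns)) wr("32767", 8L)
  for (i in seq_len(ns)) wr("", 80L)                     # prefiltering
  for (i in seq_len(ns)) wr(if (i <= m) rate else ann_samples, 8L)
  for (i in seq_len(ns)) wr("", 32L)                     # reserved

  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * rate + seq_len(rate)
    for (i in seq_len(m)) {
      writeBin(as.integer(digital[i, idx]), con, size = 2L, endian = "little")
    }
    payload <- ann_per_rec[[r]]
    payload <- c(payload, raw(2L * ann_samples - length(payload)))
    writeBin(payload, con)
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(rd(8L)); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  for (i in seq_len(ns)) rd(80L)
  for (i in seq_len(ns)) rd(8L)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  for (i in seq_len(ns)) rd(80L)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), integer(1))
  for (i in seq_len(ns)) rd(32L)

  is_ann <- labels == "EDF Annotations"
  sig <- which(!is_ann)
  m <- length(sig)
  if (length(unique(spr[sig])) != 1L) {
    stop("EDF signals with differing sampling rates are not supported", call. = FALSE)
  }
  rate <- spr[sig[1]] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min

  data <- matrix(0, nrow = m, ncol = n_rec * spr[sig[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        bytes <- readBin(con, "raw", n = 2L * spr[i])
        ann_text <- c(ann_text, rawToChar(bytes[bytes != as.raw(0)]))
      } else {
        v <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
        j <- match(i, sig)
        data[j, (r - 1L) * spr[i] + seq_len(spr[i])] <- gain[i] * v + offset[i]
      }
    }
  }

  events <- data.frame(sample = integer(), label = integer())
  if (length(ann_text)) {
    tals <- strsplit(paste(ann_text, collapse = ""), "\x14\x14", fixed = TRUE)[[1]]
    rows <- lapply(tals, function(chunk) {
      # events appear as "+<onset>\x14<text>" pairs after record-start stamps
      parts <- strsplit(chunk, "\x14", fixed = TRUE)[[1]]
      out <- list()
      k <- 1L
      while (k + 1L <= length(parts)) {
        onset <- suppressWarnings(as.numeric(sub("^\\+", "", parts[k])))
        lab <- suppressWarnings(as.integer(gsub("[^0-9]", "", parts[k + 1L])))
        if (!is.na(onset) && !is.na(lab)) {
          out[[length(out) + 1L]] <- data.frame(
            sample = as.integer(round(onset * rate)), label = lab)
        }
        k <- k + 2L
      }
      if (length(out)) do.call(rbind, out) else NULL
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) events <- unique(do.call(rbind, rows))
  }
  eeg_recording(data, rate, labels[sig], events)
}

# ---- epoch / model containers ----------------------------------------------

#' Persist an epoch set or trained model
#'
#' R-native serialisation with a schema field; the companion loaders check
#' the class and schema on the way back in.
#'
#' @param x an [epoch_set()] or `cvep_model`.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_cvep <- function(x, path) {
  stopifnot(inherits(x, "epoch_set") || inherits(x, "cvep_model"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_cvep
#' @export
load_cvep <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!(inherits(x, "epoch_set") || inherits(x, "cvep_model"))) {
    stop("not a saved epoch set or model: ", path, call. = FALSE)
  }
  x
}
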