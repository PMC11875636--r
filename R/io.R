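#' Portable on-disk epoch store
#'
#' An epoch store is a pair of files sharing a stem: `<stem>.json`, a JSON
#' manifest (subject id, sampling rate, channel names, time grid, label
#' codes, baseline window, array dims and an md5 provenance hash of the
#' payload), and `<stem>.bin`, a little-endian float64 payload holding the
#' `trials x channels x samples` array followed by the label vector.
#' Round-trips are bit-exact; [read_epochs()] validates the manifest
#' against the payload (dims and hash) before accepting it.
#'
#' @param epochs a [epochs_set()].
#' @param stem path stem (without extension); the directory must exist.
#' @return invisibly, a list with the two paths and the payload hash.
#' @export
write_epochs <- function(epochs, stem) {
  bin <- paste0(stem, ".bin")
  man <- paste0(stem, ".json")
  d <- dim(epochs$data)
  con <- file(bin, "wb")
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  writeBin(as.numeric(epochs$labels), con, size = 8, endian = "little")
  close(con)
  hash <- unname(tools::md5sum(bin))
  jsonlite::write_json(list(
    format = "bandfocus-epochs-v1",
    subject_id = epochs$subject_id,
    sampling_rate = epochs$sampling_rate,
    channel_names = epochs$channel_names,
    t_start = epochs$times[1],
    n_times = length(epochs$times),
    label_codes = list(natural = 0, supernumerary = 1),
    baseline_window = epochs$baseline_window,
    dims = d,
    payload_md5 = hash), man, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = man, payload = bin, payload_md5 = hash))
}

#' @rdname write_epochs
#' @param stem_or_manifest stem or path to the `.json` manifest.
#' @return `read_epochs` returns the [epochs_set()].
#' @export
read_epochs <- function(stem_or_manifest) {
  man <- if (grepl("\\.json$", stem_or_manifest)) stem_or_manifest
         else paste0(stem_or_manifest, ".json")
  m <- jsonlite::read_json(man, simplifyVector = TRUE)
  bin <- sub("\\.json$", ".bin", man)
  if (!file.exists(bin)) stop("payload missing: ", bin)
  d <- as.integer(m$dims)
  if (length(d) != 3 || length(m$channel_names) != d[2] || m$n_times != d[3])
    stop("corrupt manifest: dims inconsistent with metadata")
  n_expected <- prod(d) + d[1]
  if (file.size(bin) != 8 * n_expected)
    stop("corrupt store: payload size does not match manifest dims")
  if (!identical(unname(tools::md5sum(bin)), m$payload_md5))
    stop("corrupt store: payload hash mismatch")
  con <- file(bin, "rb")
  raw <- readBin(con, "numeric", n = n_expected, size = 8, endian = "little")
  close(con)
  times <- m$t_start + (seq_len(d[3]) - 1) / m$sampling_rate
  epochs_set(m$subject_id, array(raw[seq_len(prod(d))], d),
             m$sampling_rate, m$channel_names, times,
             as.integer(raw[prod(d) + seq_len(d[1])]),
             as.numeric(m$baseline_window))
}

# --- minimal EDF+ writer/reader (continuous recording, 1-s records) -------

.pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf("%-*s", width, s)
}

#' Write a continuous multichannel recording to EDF+
#'
#' Minimal EDF+ writer used for fixtures and interchange: one-second data
#' records, 16-bit samples with per-file physical scaling, and an
#' `EDF Annotations` signal carrying the event markers.
#'
#' @param data `channels x samples` numeric matrix.
#' @param fs sampling rate (samples per one-second record).
#' @param channel_names channel labels.
#' @param events `data.frame(onset, text)` with onsets in seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, fs, channel_names, events, path) {
  ns <- nrow(data)
  n_rec <- ceiling(ncol(data) / fs)
  if (ncol(data) < n_rec * fs)
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))
  pmax_ <- max(abs(data), 1e-6)
  dig <- round(data / pmax_ * 32767)
  ann_len <- 60L  # 2-byte samples per record for the annotation signal
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad_field("0", 8), .pad_field("X X X X", 80), .pad_field("Startdate X X X X", 80),
    .pad_field("01.01.00", 8), .pad_field("00.00.00", 8),
    .pad_field((ns + 2) * 256, 8), .pad_field("EDF+C", 44),
    .pad_field(n_rec, 8), .pad_field(1, 8), .pad_field(ns + 1, 4))
  writeChar(hdr, con, eos = NULL)
  lab <- c(channel_names, "EDF Annotations")
  field <- function(vals, w) writeChar(paste0(vapply(vals, .pad_field, "", w),
                                              collapse = ""), con, eos = NULL)
  field(lab, 16)
  field(rep("", ns + 1), 80)
  field(c(rep("uV", ns), ""), 8)
  field(c(rep(sprintf("%.6g", -pmax_), ns), -1), 8)
  field(c(rep(sprintf("%.6g", pmax_), ns), 1), 8)
  field(c(rep(-32768, ns), -32768), 8)
  field(c(rep(32767, ns), 32767), 8)
  field(rep("", ns + 1), 80)
  field(c(rep(fs, ns), ann_len), 8)
  field(rep("", ns + 1), 32)
  for (r in seq_len(n_rec) - 1L) {
    sl <- r * fs + seq_len(fs)
    writeBin(as.integer(t(dig[, sl, drop = FALSE])), con, size = 2,
             endian = "little")
    tal <- sprintf("+%g\x14\x14", r)
    ev <- events[events$onset >= r & events$onset < r + 1, , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      tal <- paste0(tal, sprintf("+%g\x14%s\x14", ev$onset[i], ev$text[i]))
    raw_tal <- charToRaw(tal)
    raw_tal <- c(raw_tal, raw(2 * ann_len - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  ann_ix <- which(labs == "EDF Annotations")
  sig_ix <- setdiff(seq_len(ns), ann_ix)
  data <- lapply(sig_ix, function(i) numeric(0))
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (i %in% ann_ix) {
        raw_tal <- readBin(con, "raw", n = 2 * spr[i])
        ann_text <- c(ann_text, rawToChar(raw_tal[raw_tal != as.raw(0)]))
      } else {
        v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
        j <- match(i, sig_ix)
        g <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
        data[[j]] <- c(data[[j]], pmin_[i] + (v - dmin[i]) * g)
      }
    }
  }
  # parse TALs: "+onset(\x15dur)?\x14text\x14"
  events <- data.frame(onset = numeric(0), text = character(0))
  for (tal in unlist(strsplit(paste(ann_text, collapse = ""), "\x14\\+",
                              fixed = FALSE))) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2) next
    onset <- suppressWarnings(as.numeric(sub("^\\+", "", strsplit(parts[1], "\x15")[[1]][1])))
    txt <- parts[2]
    if (!is.na(onset) && nzchar(txt))
      events <- rbind(events, data.frame(onset = onset, text = txt))
  }
  fs <- spr[sig_ix[1]] / rec_dur
  list(data = do.call(rbind, data), fs = fs, channel_names = labs[sig_ix],
       events = events)
}

# --- minimal BrainVision writer/reader ------------------------------------

#' Write a continuous recording in BrainVision format
#'
#' Minimal writer (multiplexed IEEE float32 `.eeg`, `.vhdr` header,
#' `.vmrk` markers) used for fixtures and interchange.
#'
#' @inheritParams write_edf
#' @param stem path stem; `.vhdr`, `.vmrk`, `.eeg` are created.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(data, fs, channel_names, events, stem) {
  base <- basename(stem)
  vhdr <- paste0(stem, ".vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(data)),
    sprintf("SamplingInterval=%g", 1e6 / fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nrow(data)), channel_names)), vhdr)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(events)), events$text,
            round(events$onset * fs) + 1L)), paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}

.bv_get <- function(lines, key) {
  ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
  sub(paste0("^", key, "="), "", ln)
}

.read_brainvision <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nch <- as.integer(.bv_get(lines, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(.bv_get(lines, "SamplingInterval"))
  if (!identical(.bv_get(lines, "BinaryFormat"), "IEEE_FLOAT_32"))
    stop("unsupported BrainVision binary format")
  chl <- grep("^Ch[0-9]+=", lines, value = TRUE)
  channel_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", chl), ","),
                          `[[`, "", 1)
  eeg <- file.path(dirname(path), .bv_get(lines, "DataFile"))
  vmrk <- file.path(dirname(path), .bv_get(lines, "MarkerFile"))
  n <- file.size(eeg) / 4
  con <- file(eeg, "rb")
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  data <- matrix(v, nch)                      # multiplexed: channels fast
  mk <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  events <- data.frame(
    onset = (as.numeric(vapply(parts, `[[`, "", 3)) - 1) / fs,
    text = vapply(parts, `[[`, "", 2))
  list(data = data, fs = fs, channel_names = channel_names, events = events)
}

#' Epoch a continuous external recording (EDF / BrainVision)
#'
#' Reads a continuous recording with event markers, validates the channel
#' labels against a montage, and cuts fixed-length epochs around the
#' markers of the two motor-imagery conditions. Markers too close to the
#' recording edges are dropped with a warning.
#'
#' @param path file path (`.edf`, or BrainVision `.vhdr`).
#' @param format `"edf"` or `"brainvision"`; inferred from the extension
#'   by default.
#' @param montage a [montage()] the channel labels must belong to.
#' @param window `c(start, end)` epoch window in seconds around each
#'   marker (cue at 0).
#' @param label_map named integer vector mapping marker text to condition
#'   codes 0/1 (default `c(NT = 0, ST = 1)`).
#' @param subject_id id for the resulting epochs (default: file stem).
#' @return a [epochs_set()].
#' @export
read_external <- function(path, format = c("auto", "edf", "brainvision"),
                          montage = make_default_montage(),
                          window = c(-1, 4), label_map = c(NT = 0L, ST = 1L),
                          subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "brainvision"
  rec <- if (format == "edf") .read_edf(path) else .read_brainvision(path)
  unknown <- setdiff(rec$channel_names, montage$channel_names)
  if (length(unknown))
    stop("unknown channel label(s) not in montage: ",
         paste(unknown, collapse = ", "))
  # map channels onto montage order (restricted to channels present)
  keep <- montage$channel_names[montage$channel_names %in% rec$channel_names]
  data <- rec$data[match(keep, rec$channel_names), , drop = FALSE]
  ev <- rec$events[rec$events$text %in% names(label_map), , drop = FALSE]
  if (!nrow(ev))
    stop("no event markers matching conditions (",
         paste(names(label_map), collapse = ", "), ") found in ", path)
  fs <- rec$fs
  n <- ncol(data)
  len <- round((window[2] - window[1]) * fs)
  epochs <- list(); labels <- integer(0); dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    s0 <- round(ev$onset[i] * fs) + round(window[1] * fs) + 1L
    if (s0 < 1 || s0 + len - 1 > n) { dropped <- dropped + 1L; next }
    epochs[[length(epochs) + 1L]] <- data[, s0:(s0 + len - 1L), drop = FALSE]
    labels <- c(labels, label_map[[ev$text[i]]])
  }
  if (dropped)
    warning(sprintf("%d marker(s) too close to the recording edge: dropped", dropped))
  if (!length(epochs)) stop("no complete epochs could be extracted")
  arr <- aperm(array(unlist(epochs), c(length(keep), len, length(epochs))),
               c(3, 1, 2))
  times <- window[1] + (seq_len(len) - 1) / fs
  epochs_set(subject_id %||% sub("\\.[^.]+$", "", basename(path)),
             arr, fs, keep, times, labels,
             baseline_window = c(window[1], min(0, window[2])))
}
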