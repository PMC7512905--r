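# Trial interchange: EDF (one file per trial, 16-bit, single data record)
# and plain delimited text (time x channels with a header row), plus a
# delimited manifest mapping files to subject/condition labels.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write one trial as an EDF file
#'
#' Minimal EDF (16-bit, little-endian) writer: eight signals, one data
#' record holding the whole trial, physical range taken from each channel's
#' observed min/max. Subject and condition are stored in the patient and
#' recording identification fields.
#'
#' @param trial An [eeg_trial].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_edf <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  ns <- nrow(trial$samples)
  n <- ncol(trial$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("subject ", trial$subject_id), 80),
    edf_pad(paste0("condition ", trial$condition), 80),
    edf_pad("01.01.01", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(1, 8), edf_num(n / trial$fs, 8), edf_pad(ns, 4))
  phys_min <- apply(trial$samples, 1, min)
  phys_max <- apply(trial$samples, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  sig <- function(values, width) {
    paste(vapply(values, edf_pad, character(1), width = width), collapse = "")
  }
  signum <- function(values, width) {
    paste(vapply(values, edf_num, character(1), width = width), collapse = "")
  }
  header <- paste0(
    header,
    sig(trial$channels, 16),
    sig(rep("", ns), 80),
    sig(rep("uV", ns), 8),
    signum(phys_min, 8), signum(phys_max, 8),
    sig(rep("-32768", ns), 8), sig(rep("32767", ns), 8),
    sig(rep("", ns), 80),
    sig(rep(n, ns), 8),
    sig(rep("", ns), 32))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  for (ch in seq_len(ns)) {
    dig <- round((trial$samples[ch, ] - phys_min[ch]) / (phys_max[ch] - phys_min[ch]) *
                   65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read one trial from an EDF file
#'
#' Counterpart of [write_trial_edf()]; values are recovered within the
#' 16-bit quantization of the stored physical range. Subject and condition
#' default to the identification fields but can be overridden (e.g. from a
#' manifest).
#'
#' @param path EDF file path.
#' @param subject_id,condition Optional label overrides.
#' @return An [eeg_trial].
#' @export
read_trial_edf <- function(path, subject_id = NULL, condition = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_edf_field(con, 8)                       # version
  patient <- read_edf_field(con, 80)
  recording <- read_edf_field(con, 80)
  read_edf_field(con, 8); read_edf_field(con, 8)
  read_edf_field(con, 8); read_edf_field(con, 44)
  n_records <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  labels <- vapply(seq_len(ns), function(i) read_edf_field(con, 16),
                   character(1))
  for (i in seq_len(ns)) read_edf_field(con, 80)
  for (i in seq_len(ns)) read_edf_field(con, 8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8)),
                 numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8)),
                 numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8)),
                 numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(read_edf_field(con, 8)),
                 numeric(1))
  for (i in seq_len(ns)) read_edf_field(con, 80)
  spr <- vapply(seq_len(ns), function(i) as.integer(read_edf_field(con, 8)),
                integer(1))
  for (i in seq_len(ns)) read_edf_field(con, 32)
  samples <- matrix(0, nrow = ns, ncol = spr[1] * n_records)
  for (rec in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      cols <- (rec - 1) * spr[ch] + seq_len(spr[ch])
      samples[ch, cols] <- pmin[ch] + (dig - dmin[ch]) /
        (dmax[ch] - dmin[ch]) * (pmax[ch] - pmin[ch])
    }
  }
  fs <- spr[1] / rec_dur
  if (is.null(subject_id)) subject_id <- sub("^subject ", "", patient)
  if (is.null(condition)) condition <- sub("^condition ", "", recording)
  validate_channels(labels, path)
  eeg_trial(samples[match(eeg_channels(), labels), , drop = FALSE], fs,
            subject_id, condition)
}

validate_channels <- function(labels, path) {
  if (!setequal(labels, eeg_channels()) ||
      length(labels) != length(eeg_channels())) {
    stop(sprintf("channel-set mismatch in %s: got [%s], expected [%s]",
                 path, paste(labels, collapse = ", "),
                 paste(eeg_channels(), collapse = ", ")), call. = FALSE)
  }
}

#' Write one trial as delimited text
#'
#' Tab-separated, time x channels, header row of channel labels.
#'
#' @inheritParams write_trial_edf
#' @export
write_trial_delim <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  df <- as.data.frame(t(trial$samples))
  names(df) <- trial$channels
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_delim
#' @param subject_id,condition Trial labels (delimited files carry none).
#' @param fs Sampling rate in Hz.
#' @export
read_trial_delim <- function(path, subject_id, condition, fs = 500) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  validate_channels(names(df), path)
  eeg_trial(t(as.matrix(df[, eeg_channels()])), fs, subject_id, condition)
}

#' Write a dataset of trials plus a manifest
#'
#' One file per trial (`<subject>_<condition>.<ext>`) and a tab-separated
#' `manifest.tsv` with columns `file`, `subject`, `condition`, `fs`.
#'
#' @param trials A trial table.
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"delim"`.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(trials, dir, format = c("edf", "delim")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(trials), "trial" %in% names(trials))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") "edf" else "tsv"
  files <- sprintf("%s_%s.%s", trials$subject, trials$condition, ext)
  for (i in seq_len(nrow(trials))) {
    path <- file.path(dir, files[i])
    if (format == "edf") write_trial_edf(trials$trial[[i]], path)
    else write_trial_delim(trials$trial[[i]], path)
  }
  manifest <- data.frame(file = files, subject = trials$subject,
                         condition = as.character(trials$condition),
                         fs = trials$fs)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Load a dataset of trials from a directory
#'
#' Reads `manifest.tsv` from `dir`, loads each trial file (EDF or delimited
#' by extension), normalizes condition labels case-insensitively and channel
#' order to the canonical montage, and validates a consistent sampling rate.
#'
#' @param dir Directory containing `manifest.tsv` and the trial files.
#' @return A trial table.
#' @export
read_trials <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) {
    stop("no manifest.tsv in ", dir, call. = FALSE)
  }
  manifest <- read.table(mpath, header = TRUE, sep = "\t",
                         colClasses = c(file = "character",
                                        subject = "character"))
  if (!all(c("file", "subject", "condition") %in% names(manifest))) {
    stop("manifest must have columns file, subject, condition", call. = FALSE)
  }
  trials <- purrr::pmap(manifest, function(file, subject, condition,
                                           fs = 500, ...) {
    path <- file.path(dir, file)
    if (grepl("\\.edf$", file, ignore.case = TRUE)) {
      read_trial_edf(path, subject_id = subject, condition = condition)
    } else {
      read_trial_delim(path, subject_id = subject, condition = condition,
                       fs = fs)
    }
  })
  tbl <- trial_table(trials)
  if (length(unique(tbl$fs)) != 1L) {
    stop("inconsistent sampling rates across trials: ",
         paste(unique(tbl$fs), collapse = ", "), call. = FALSE)
  }
  tbl
}
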