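# Minimal RIFF/WAV reader and writer. Mono, IEEE float32 (written) or
# PCM16/float32 (read). No installed R package covers WAV in this stack.

write_wav <- function(x, path, fs_hz) {
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    stop("not a WAV file: ", path, call. = FALSE)
  fmt <- NULL; samples <- NULL; fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, 2, endian = "little")
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16L))
      attr(fmt, "bits") <- bits
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      bits <- attr(fmt, "bits")
      if (fmt == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", sz / 4L, 4, endian = "little")
      } else if (fmt == 1L && bits == 16L) {
        samples <- readBin(con, "integer", sz / 2L, 2, signed = TRUE,
                           endian = "little") / 32768
      } else stop("unsupported WAV encoding", call. = FALSE)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(samples)) stop("truncated WAV file: ", path, call. = FALSE)
  list(samples = samples, fs_hz = fs)
}

# Minimal WFDB-style record (format 16, interleaved int16 .dat + text .hea).
write_wfdb <- function(signals, path_base, fs_hz, descriptions = names(signals)) {
  nsig <- length(signals)
  n <- length(signals[[1]])
  gains <- vapply(signals, function(x) {
    m <- max(abs(x)); if (m == 0) 1 else 32000 / m
  }, numeric(1))
  dig <- mapply(function(x, g) as.integer(round(x * g)), signals, gains,
                SIMPLIFY = FALSE)
  rec <- basename(path_base)
  hea <- c(sprintf("%s %d %g %d", rec, nsig, fs_hz, n),
           vapply(seq_len(nsig), function(j)
             sprintf("%s.dat 16 %.6f 16 0 0 0 0 %s", rec, gains[j],
                     descriptions[j]), character(1)))
  writeLines(hea, paste0(path_base, ".hea"))
  inter <- integer(nsig * n)
  for (j in seq_len(nsig)) inter[seq(j, by = nsig, length.out = n)] <- dig[[j]]
  con <- file(paste0(path_base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path_base)
}

read_wfdb <- function(path_hea) {
  lines <- readLines(path_hea)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig_lines <- lines[2:(1 + nsig)]
  gains <- numeric(nsig); descs <- character(nsig)
  for (j in seq_len(nsig)) {
    f <- strsplit(trimws(sig_lines[j]), "\\s+")[[1]]
    if (f[2] != "16") stop("only WFDB format 16 supported", call. = FALSE)
    gains[j] <- as.numeric(f[3])
    descs[j] <- if (length(f) >= 9) f[9] else sprintf("sig%d", j)
  }
  dat <- sub("\\.hea$", ".dat", path_hea)
  con <- file(dat, "rb")
  on.exit(close(con))
  inter <- readBin(con, "integer", nsig * n, 2, signed = TRUE, endian = "little")
  if (length(inter) < nsig * n) stop("truncated WFDB .dat file", call. = FALSE)
  sigs <- lapply(seq_len(nsig), function(j)
    inter[seq(j, by = nsig, length.out = n)] / gains[j])
  names(sigs) <- descs
  list(signals = sigs, fs_hz = fs, descriptions = descs)
}

#' Read a paired PCG + ECG recording
#'
#' Supported sources: a CSV file with columns `t,pcg,ecg` (sampling rate
#' inferred from the median time step) or `pcg,ecg` plus an explicit
#' `fs_hz`; a WFDB-style record (`.hea` + format-16 `.dat`) with a PCG and
#' an ECG signal; or a pair of WAV files (`path` = PCG, `ecg_path` = ECG).
#' The method is ECG-referenced: a source without an ECG channel is an
#' error.
#'
#' @param path Path to the CSV, `.hea`, or PCG `.wav` file.
#' @param ecg_path ECG `.wav` path when `path` is a WAV file.
#' @param fs_hz Sampling rate override (required for headerless CSV without
#'   a time column; must agree with file headers when both are present).
#' @param label Identifier; defaults to the file name.
#' @return A [pcg_recording()].
#' @export
read_recording <- function(path, ecg_path = NULL, fs_hz = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  label <- label %||% sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!"ecg" %in% names(df))
      stop("ECG required: the method is ECG-referenced and '", path,
           "' has no 'ecg' column", call. = FALSE)
    if (!"pcg" %in% names(df)) stop("no 'pcg' column in ", path, call. = FALSE)
    if ("t" %in% names(df)) {
      fs_file <- 1 / stats::median(diff(df$t))
      if (!is.null(fs_hz) && abs(fs_file - fs_hz) > 0.01 * fs_hz)
        message("declared fs (", fs_hz, " Hz) disagrees with time column (",
                round(fs_file, 2), " Hz); using the time column")
      fs_hz <- fs_file
    }
    if (is.null(fs_hz)) stop("fs_hz required for CSV without a time column",
                             call. = FALSE)
    return(pcg_recording(df$pcg, df$ecg, fs_hz, label = label))
  }
  if (ext == "hea") {
    w <- read_wfdb(path)
    nm <- tolower(w$descriptions)
    i_pcg <- which(grepl("pcg|phono", nm))[1]
    i_ecg <- which(grepl("ecg|ekg", nm))[1]
    if (is.na(i_ecg))
      stop("ECG required: no ECG signal in WFDB record ", path, call. = FALSE)
    if (is.na(i_pcg)) i_pcg <- setdiff(seq_along(nm), i_ecg)[1]
    return(pcg_recording(w$signals[[i_pcg]], w$signals[[i_ecg]], w$fs_hz,
                         label = label))
  }
  if (ext == "wav") {
    if (is.null(ecg_path))
      stop("ECG required: provide ecg_path alongside the PCG WAV",
           call. = FALSE)
    p <- read_wav(path)
    e <- read_wav(ecg_path)
    if (p$fs_hz != e$fs_hz) {
      # resample the lower-rate channel by linear interpolation
      message("PCG and ECG sampling rates disagree; resampling to ",
              max(p$fs_hz, e$fs_hz), " Hz")
      if (p$fs_hz < e$fs_hz) p <- resample_to(p, e$fs_hz) else e <- resample_to(e, p$fs_hz)
    }
    n <- min(length(p$samples), length(e$samples))
    return(pcg_recording(p$samples[1:n], e$samples[1:n], p$fs_hz, label = label))
  }
  stop("unsupported format: .", ext, call. = FALSE)
}

resample_to <- function(w, fs_new) {
  n_new <- round(length(w$samples) * fs_new / w$fs_hz)
  t_old <- (seq_along(w$samples) - 1) / w$fs_hz
  t_new <- (seq_len(n_new) - 1) / fs_new
  list(samples = stats::approx(t_old, w$samples, xout = t_new, rule = 2)$y,
       fs_hz = fs_new)
}

#' Write a recording to disk
#'
#' CSV writes a single `t,pcg,ecg` table; WAV writes a pair of float32 mono
#' files (`<name>_pcg.wav`, `<name>_ecg.wav`); WFDB writes `<name>.hea` +
#' format-16 `<name>.dat` with signals described as PCG and ECG. Synthetic
#' ground truth, when present, goes to a `<name>_truth.json` sidecar.
#'
#' @param recording A [pcg_recording()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @param format One of `"csv"`, `"wav"`, `"wfdb"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_recording <- function(recording, dir, name = recording$label,
                            format = c("csv", "wav", "wfdb")) {
  format <- match.arg(format)
  stopifnot(is_pcg_recording(recording))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (format == "csv") {
    f <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(
      data.frame(t = (seq_along(recording$pcg) - 1) / recording$fs_hz,
                 pcg = recording$pcg, ecg = recording$ecg),
      f, row.names = FALSE)
    files <- f
  } else if (format == "wav") {
    f1 <- file.path(dir, paste0(name, "_pcg.wav"))
    f2 <- file.path(dir, paste0(name, "_ecg.wav"))
    write_wav(recording$pcg, f1, recording$fs_hz)
    write_wav(recording$ecg, f2, recording$fs_hz)
    files <- c(f1, f2)
  } else {
    base <- file.path(dir, name)
    write_wfdb(list(PCG = recording$pcg, ECG = recording$ecg), base,
               recording$fs_hz)
    files <- paste0(base, c(".hea", ".dat"))
  }
  if (!is.null(recording$ground_truth)) {
    gt <- recording$ground_truth
    gt$component_specs <- lapply(gt$component_specs, unclass)
    gt$latencies_ms <- as.data.frame(gt$latencies_ms)
    fj <- file.path(dir, paste0(name, "_truth.json"))
    jsonlite::write_json(gt, fj, auto_unbox = TRUE, digits = NA)
    files <- c(files, fj)
  }
  invisible(files)
}

#' Write pipeline result tables
#'
#' Writes whichever result tables are supplied as CSV (missing values as
#' empty cells, the not-available convention) and a combined JSON (missing
#' values as `null`). Empty tables produce headers-only files.
#'
#' @param results Named list of data frames; conventional names are
#'   `beat_snr`, `subject_thresholds`, `threshold_vs_uncertainty`,
#'   `validation`.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  fj <- file.path(dir, "results.json")
  jsonlite::write_json(results, fj, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(c(files, fj))
}
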