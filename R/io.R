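# Recording, schedule and configuration I/O, plus the config-driven
# pipeline driver.
#
# Delimited-text dialect: a header line `# fs=<Hz>`, a tab-separated channel
# label row, then one row per sample (lossless, inspectable fixtures). EDF
# (European Data Format) is read and written directly in base R: the format
# is a fixed-layout ASCII header plus 16-bit little-endian data records with
# a per-signal physical/digital linear mapping. No installed R package
# handles EDF, so the codec lives here with round-trip tests.

#' Write a recording to delimited text
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) == 0L) stop("refusing to write a 0-sample recording.",
                                 call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Expects the dialect written by [write_recording_text()]: `# fs=<Hz>`
#' header, a label row, tab-separated samples in columns per channel.
#'
#' @param path input file path.
#' @return An [eeg_recording()].
#' @export
read_recording_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*fs=([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2L) {
    stop("missing sampling-rate field: first line must be '# fs=<Hz>'.",
         call. = FALSE)
  }
  fs <- as.numeric(m[2])
  labels <- strsplit(readLines(path, n = 2L)[2], "\t", fixed = TRUE)[[1]]
  tab <- utils::read.table(path, sep = "\t", skip = 2L,
                           colClasses = "numeric")
  if (ncol(tab) != length(labels)) {
    stop("ragged channels: label row and data columns disagree.",
         call. = FALSE)
  }
  m <- t(as.matrix(tab))
  dimnames(m) <- NULL
  eeg_recording(m, fs, labels)
}

#' Read a recording (format by extension)
#'
#' Dispatches on file extension: `.edf` via [read_edf()], anything else via
#' [read_recording_text()].
#' @param path input file path.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
  else read_recording_text(path)
}

#' Write a recording (format by extension)
#' @param rec an [eeg_recording()].
#' @param path output path; `.edf` selects EDF, anything else text.
#' @param ... forwarded to [write_edf()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, ...) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) write_edf(rec, path, ...)
  else write_recording_text(rec, path)
}

# --- EDF codec --------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write a recording as EDF
#'
#' European Data Format: 256-byte main header, 256 bytes per signal, then
#' 1-second data records of 16-bit little-endian integers mapped linearly
#' from the declared physical range. Samples outside `physical_range` are an
#' error, never silently clipped. The recording is truncated to a whole
#' number of 1-second records (EDF records are fixed-duration).
#'
#' @param rec an [eeg_recording()] with integer `fs`.
#' @param path output path.
#' @param physical_range symmetric physical range in microvolts declared in
#'   the header. Default `c(-1000, 1000)`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_range = c(-1000, 1000)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) == 0L) stop("refusing to write a 0-sample recording.",
                                 call. = FALSE)
  if (rec$fs != round(rec$fs)) {
    stop("EDF writing requires an integer sampling rate.", call. = FALSE)
  }
  if (min(rec$data) < physical_range[1] || max(rec$data) > physical_range[2]) {
    stop(sprintf("samples outside the declared physical range [%g, %g] uV; widen `physical_range`.",
                 physical_range[1], physical_range[2]), call. = FALSE)
  }
  ns <- n_channels(rec)
  spr <- as.integer(rec$fs)                    # samples per record per signal
  n_rec <- n_samples(rec) %/% spr
  if (n_rec == 0L) stop("recording shorter than one 1-second EDF record.",
                        call. = FALSE)
  dmin <- -32768; dmax <- 32767
  gain <- (dmax - dmin) / (physical_range[2] - physical_range[1])
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("EEG electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(rep(format(physical_range[1]), ns), 8)
  field(rep(format(physical_range[2]), ns), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, idx] - physical_range[1]) * gain + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads the fixed-layout header and 16-bit data records, applying each
#' signal's physical/digital mapping; requires all signals to share one
#' sampling rate.
#'
#' @param path input file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header length (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L) {
    stop("mixed per-signal sampling rates are not supported.", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
      data[ch, (r - 1L) * spr[ch] + seq_len(spr[ch])] <- phys
    }
  }
  eeg_recording(data, fs, labels)
}

# --- schedules and config ---------------------------------------------------

#' Write an event schedule as TSV
#' @param schedule schedule tibble (`onset_s`, `label`, `sequence`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  schedule <- validate_schedule(schedule)
  utils::write.table(schedule[, c("onset_s", "label", "sequence")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event schedule from TSV
#' @param path input path.
#' @return A schedule tibble.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_schedule(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Run a configured analysis pipeline
#'
#' Config-driven front end over the simulation and analysis chains. The
#' config is a named list (or path to a YAML file) with a `paradigm` field
#' (`"assr"`, `"erp"` or `"comfort"`), a `seed`, and per-paradigm settings;
#' unspecified settings fall back to the documented defaults. Given the same
#' config and seed the outputs are identical. The returned provenance record
#' (config hash + seed + package version) suffices to regenerate them.
#'
#' @param config named list or YAML file path.
#' @return A list with `results` (paradigm-specific tibbles), `log`
#'   (character vector of stage messages), and `provenance`.
#' @export
#' @examples
#' out <- run_pipeline(list(paradigm = "assr", seed = 3,
#'                          assr = list(duration_s = 100)))
#' out$results$snr
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  paradigm <- config$paradigm
  if (is.null(paradigm) || !paradigm %in% c("assr", "erp", "comfort")) {
    stop("config must name a paradigm: 'assr', 'erp' or 'comfort'.",
         call. = FALSE)
  }
  seed <- config$seed
  if (is.null(seed) && paradigm != "comfort") {
    stop("config must provide a `seed` for stochastic paradigms.", call. = FALSE)
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  results <- switch(
    paradigm,
    assr = {
      p <- utils::modifyList(
        list(fm = 41, amplitude_uv = 1, duration_s = 100, fs = 1000,
             n_channels = 3L, points_per_epoch = 1000L,
             harmonic_amplitudes = numeric(0)),
        config$assr %||% list())
      note("simulating ASSR recording: fs=%g, fm=%g, %g s", p$fs, p$fm,
           p$duration_s)
      rec <- simulate_assr_recording(
        fm = p$fm, amplitude_uv = p$amplitude_uv,
        harmonic_amplitudes = p$harmonic_amplitudes,
        duration_s = p$duration_s, fs = p$fs, n_channels = p$n_channels,
        seed = seed)
      out <- run_assr(rec, fm = p$fm, points_per_epoch = p$points_per_epoch)
      note("sweeps averaged; SNR at %g Hz: %s dB", p$fm,
           paste(sprintf("%.2f", out$snr$snr_db), collapse = ", "))
      out
    },
    erp = {
      p <- utils::modifyList(list(n_participants = 8L),
                             config$erp %||% list())
      sc <- do.call(default_scenario, config$scenario %||% list())
      note("simulating %d participants, %d sequences each",
           p$n_participants, sc$n_sequences)
      study <- run_erp_study(p$n_participants, sc, seed = seed)
      rej <- purrr::map_dbl(study$participants, function(x) {
        if (is.null(x$rejection_report)) NA_real_
        else attr(x$rejection_report, "rejected_fraction_pct")
      })
      note("rejected fractions (%%): %s",
           paste(sprintf("%.1f", rej), collapse = ", "))
      note("P300: %.2f uV at %.0f ms (N = %d)",
           study$p300$amplitude_uv, study$p300$latency_ms,
           study$result$n_participants)
      list(p300 = study$p300,
           grand_average = study$result$grand_average,
           difference = study$result$difference,
           n_participants = study$result$n_participants)
    },
    comfort = {
      path <- config$comfort$responses
      if (is.null(path)) stop("comfort config needs `responses` (TSV path).",
                              call. = FALSE)
      sheet <- utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
      scores <- score_comfort_sheet(sheet)
      devices <- sort(unique(scores$device))
      if (length(devices) != 2L) {
        stop("comfort comparison needs exactly 2 devices.", call. = FALSE)
      }
      a <- scores$comfort_index[scores$device == devices[1]]
      b <- scores$comfort_index[scores$device == devices[2]]
      note("scored %d responses across devices %s", nrow(scores),
           paste(devices, collapse = " vs "))
      list(scores = scores,
           tests = dplyr::bind_rows(
             noninferiority_t_test(a, b, direction = "noninferiority"),
             noninferiority_t_test(a, b, direction = "nonsuperiority"),
             unpaired_t_test(a, b)))
    })
  provenance <- list(
    config_hash = config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("earpipe")))
  list(results = results, log = log, provenance = provenance)
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
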