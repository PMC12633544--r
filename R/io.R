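#' Read a single-channel biosignal
#'
#' Supported formats: European Data Format (EDF, one channel read from the
#' file; physical dimensions uV, mV and V are converted to microvolts) and
#' two-column delimited text (`time_s`, `value_uv`). Delimited input must
#' be uniformly sampled: a timestamp gap or jitter beyond 1 ppm of the
#' sampling interval is rejected.
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"`; guessed from the extension by
#'   default.
#' @param t0 wall-clock start override; for EDF the header start time is
#'   used when `NULL`.
#' @param channel channel index for EDF files.
#' @return a [raw_signal()].
#' @export
read_signal <- function(path, format = NULL, t0 = NULL, channel = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||%
    (if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited")
  if (format == "edf") return(read_edf(path, channel = channel, t0 = t0))
  d <- read.table(path, header = TRUE, sep = "\t")
  if (ncol(d) < 2L) stop("delimited signal needs columns time_s, value_uv")
  tt <- d[[1L]]; v <- d[[2L]]
  if (length(tt) < 2L) stop("signal too short to verify uniform sampling")
  dt <- diff(tt)
  if (any(abs(dt - dt[1L]) > 1e-6 * dt[1L])) {
    k <- which(abs(dt - dt[1L]) > 1e-6 * dt[1L])[1L]
    stop(sprintf("non-uniform timestamps: interval at row %d is %.6g s (expected %.6g s)",
                 k + 1L, dt[k], dt[1L]))
  }
  raw_signal(v, fs = 1 / dt[1L], t0 = t0 %||% format_clock(tt[1L]))
}

#' Write a single-channel biosignal
#'
#' @param x a [raw_signal()].
#' @param path output path.
#' @param format `"edf"` (16-bit, values round-trip within the EDF
#'   quantisation of the physical range) or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "raw_signal"))
  format <- format %||%
    (if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited")
  if (format == "edf") return(write_edf(x, path))
  t0s <- parse_clock(x$t0)
  d <- data.frame(time_s = t0s + (seq_along(x$samples) - 1) / x$fs,
                  value_uv = x$samples)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal single-channel EDF support ------------------------------------
# EDF is a fixed-layout format: a 256-byte global header, 256 bytes per
# signal header, then 16-bit little-endian data records. No R package for it
# is available here, so the subset needed for round-tripping device signals
# is implemented directly.

pad_field <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  sprintf(paste0("%-", n, "s"), s)
}

write_edf <- function(x, path, label = "chan1", dim = "uV") {
  fs <- x$fs
  spr <- round(fs)            # one-second data records
  if (abs(spr - fs) > 1e-9) stop("EDF writer requires an integer sampling rate")
  n <- length(x$samples)
  nrec <- ceiling(n / spr)
  v <- c(x$samples, numeric(nrec * spr - n))
  pmax_ <- max(abs(v), 1)
  dig <- as.integer(round(v / pmax_ * 32767))
  t0s <- parse_clock(x$t0)
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("Startdate X", 80),
    pad_field("01.01.00", 8),
    pad_field(gsub(":", ".", format_clock(t0s)), 8),
    pad_field(256 + 256, 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field("1", 4),
    # per-signal header fields
    pad_field(label, 16), pad_field("", 80), pad_field(dim, 8),
    pad_field(sprintf("%g", -pmax_), 8), pad_field(sprintf("%g", pmax_), 8),
    pad_field("-32767", 8), pad_field("32767", 8), pad_field("", 80),
    pad_field(spr, 8), pad_field("", 32))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path, channel = 1L, t0 = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8)
  start_time <- gsub("\\.", ":", trimws(rd(8)))
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < channel) stop("EDF file truncated or channel missing")
  fields <- list(label = 16, transducer = 80, dim = 8, pmin = 8, pmax = 8,
                 dmin = 8, dmax = 8, prefilter = 80, spr = 8, reserved = 32)
  hdr <- lapply(fields, function(w) vapply(seq_len(ns), function(i) rd(w), ""))
  spr <- as.integer(hdr$spr)
  pmin <- as.numeric(hdr$pmin); pmax_ <- as.numeric(hdr$pmax)
  dmin <- as.numeric(hdr$dmin); dmax <- as.numeric(hdr$dmax)
  dim_ <- trimws(hdr$dim)
  total_rec <- sum(spr)
  out <- numeric(0)
  raw_all <- readBin(con, "integer", n = nrec * total_rec, size = 2L,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < nrec * total_rec) stop("EDF file truncated")
  offs <- c(0L, cumsum(spr))
  ch <- unlist(lapply(seq_len(nrec) - 1L, function(r) {
    raw_all[(r * total_rec + offs[channel] + 1L):(r * total_rec + offs[channel + 1L])]
  }))
  scale <- (pmax_[channel] - pmin[channel]) / (dmax[channel] - dmin[channel])
  v <- (ch - dmin[channel]) * scale + pmin[channel]
  mult <- switch(tolower(dim_[channel]), "uv" = 1, "\u00b5v" = 1,
                 "mv" = 1e3, "v" = 1e6, NULL)
  if (is.null(mult)) stop("EDF physical dimension '", dim_[channel],
                          "' is not convertible to microvolts")
  fs <- spr[channel] / rec_dur
  raw_signal(v * mult, fs = fs, t0 = t0 %||% start_time)
}

#' Read / write event annotations
#'
#' Delimited text with columns `onset_s`, `offset_s`, `label`.
#'
#' @param path file path.
#' @return data frame of annotations.
#' @export
read_annotations <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s", "label") %in% names(d))) {
    stop("annotations need columns onset_s, offset_s, label")
  }
  if (any(d$onset_s >= d$offset_s)) stop("annotation onsets must precede offsets")
  d
}

#' @rdname read_annotations
#' @param ann data frame with `onset_s`, `offset_s`, `label`.
#' @export
write_annotations <- function(ann, path) {
  write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- device configuration documents ----------------------------------------

config_schema <- list(
  top = c("version", "seed", "profiles", "schedule", "recorder", "scenario"),
  profile = c("id", "chain", "classifier", "policy", "sense_contacts",
              "stim_contacts"),
  chain = c("band_lo_hz", "band_hi_hz", "offset_cutoff_hz", "ema_tau_s",
            "bp_order", "quant_uv"),
  classifier = c("threshold_uv", "debounce_s", "source"),
  policy = c("baseline_ma", "active_ma", "freq_hz", "pw_us",
             "ramp_ma_per_pulse", "baseline_freq_hz", "sham"),
  recorder = c("buffer_bytes", "bytes_per_sample", "fs_base", "decimation"),
  scenario = c("name", "time_scale", "artefact_gain_uv_per_ma", "biphasic")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key '%s' in %s", unknown[1L], where), call. = FALSE)
  }
}

#' Serialise profiles and schedule to a device configuration document
#'
#' The configuration document is a version-tagged YAML file holding the
#' profiles (at most two in strict device parity), the 48 slot ids, the
#' recorder configuration and an optional scenario block. [read_config()]
#' validates the schema (unknown keys are rejected) and the pair
#' round-trips losslessly.
#'
#' @param schedule a [device_schedule()].
#' @param recorder optional [loop_recorder_config()].
#' @param seed integer seed recorded in the document.
#' @param scenario optional named list (`name`, `time_scale`,
#'   `artefact_gain_uv_per_ma`, `biphasic`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(schedule, path, recorder = NULL, seed = 1L,
                         scenario = NULL) {
  stopifnot(inherits(schedule, "device_schedule"))
  doc <- list(
    version = 1L, seed = as.integer(seed),
    profiles = lapply(unname(schedule$profiles), function(p) {
      list(id = p$id,
           chain = unclass(p$chain),
           classifier = unclass(p$classifier),
           policy = unclass(p$policy),
           sense_contacts = p$sense_contacts,
           stim_contacts = p$stim_contacts)
    }),
    schedule = list(slots = schedule$slots))
  if (!is.null(recorder)) doc$recorder <- unclass(recorder)
  if (!is.null(scenario)) doc$scenario <- scenario
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read and validate a device configuration document
#'
#' @param path path to a YAML configuration written by [write_config()].
#' @param research allow more than two profiles.
#' @return list with `schedule` (a [device_schedule()]), `recorder`
#'   (a [loop_recorder_config()] or `NULL`), `seed` and `scenario`.
#' @export
read_config <- function(path, research = FALSE) {
  if (!file.exists(path)) stop("config not found: ", path)
  doc <- yaml::read_yaml(path)
  check_keys(doc, config_schema$top, "document")
  if (is.null(doc$version)) stop("config lacks a version tag")
  if (is.null(doc$profiles) || !length(doc$profiles)) {
    stop("config defines no profiles (schema path: profiles)")
  }
  profiles <- list()
  for (pl in doc$profiles) {
    check_keys(pl, config_schema$profile, paste0("profiles/", pl$id %||% "?"))
    check_keys(pl$chain, config_schema$chain, "chain")
    check_keys(pl$classifier, config_schema$classifier, "classifier")
    check_keys(pl$policy, config_schema$policy, "policy")
    ch <- do.call(chain_config, pl$chain[setdiff(names(pl$chain), "bp_order")])
    clf <- do.call(classifier_config, pl$classifier)
    pol <- do.call(stim_policy, pl$policy)
    profiles[[pl$id]] <- stim_profile(pl$id, ch, clf, pol,
                                      pl$sense_contacts %||% c(1L, 2L),
                                      pl$stim_contacts %||% c(3L, 4L))
  }
  slots <- doc$schedule$slots
  sched <- device_schedule(slots, profiles, research = research)
  rec <- if (!is.null(doc$recorder)) {
    check_keys(doc$recorder, config_schema$recorder, "recorder")
    do.call(loop_recorder_config, doc$recorder)
  }
  if (!is.null(doc$scenario)) {
    check_keys(doc$scenario, config_schema$scenario, "scenario")
  }
  list(schedule = sched, recorder = rec, seed = doc$seed %||% 1L,
       scenario = doc$scenario)
}

#' Export a tuning result as a device configuration
#'
#' Writes the tuned chain and classifier as a complete single-profile
#' configuration document ready for [read_config()].
#'
#' @param result a `tune_result` from [tune()].
#' @param path output path.
#' @param policy a [stim_policy()] to embed.
#' @return `path`, invisibly.
#' @export
write_tuned_config <- function(result, path, policy = stim_policy()) {
  stopifnot(inherits(result, "tune_result"))
  p <- stim_profile("A", result$chain, result$classifier, policy)
  write_config(device_schedule(rep("A", 48), list(A = p)), path,
               seed = result$seed)
}

#' Write a run manifest
#'
#' Every command-line run records a manifest tying outputs to their
#' provenance: package version, seed, MD5 of the configuration and of each
#' input file, and the list of outputs. Re-running with the same manifest
#' inputs reproduces deterministic outputs byte-identically.
#'
#' @param path manifest output path (JSON).
#' @param seed seed used for the run.
#' @param config_path optional configuration file.
#' @param inputs character vector of input file paths.
#' @param outputs character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config_path = NULL,
                           inputs = character(0), outputs = character(0)) {
  md5 <- function(f) unname(tools::md5sum(f))
  man <- list(
    package = "rheostim",
    version = as.character(utils::packageVersion("rheostim")),
    seed = seed,
    config = if (!is.null(config_path))
      list(path = config_path, md5 = md5(config_path)),
    inputs = lapply(inputs, function(f) list(path = f, md5 = md5(f))),
    outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a device log
#'
#' Writes the session summary (crossing counts, transitions, warnings) as
#' JSON, plus delimited-text traces for the amplitude and envelope and the
#' recorder snapshot when present.
#'
#' @param log a `device_log`.
#' @param prefix output path prefix; files `<prefix>_log.json`,
#'   `<prefix>_amplitude.tsv`, `<prefix>_envelope.tsv` (and
#'   `<prefix>_recorder.tsv`) are written.
#' @return character vector of written paths, invisibly.
#' @export
write_device_log <- function(log, prefix) {
  stopifnot(inherits(log, "device_log"))
  paths <- character(0)
  js <- list(t0 = log$t0, fs = log$fs, time_scale = log$time_scale,
             n_samples = length(log$amplitude_ma),
             total_crossings = sum(log$crossings_per_slot),
             crossings_per_slot = log$crossings_per_slot,
             transitions = log$transitions,
             warnings = log$warnings)
  p <- paste0(prefix, "_log.json")
  jsonlite::write_json(js, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  tt <- (seq_along(log$amplitude_ma) - 1) / log$fs
  p <- paste0(prefix, "_amplitude.tsv")
  write.table(data.frame(time_s = tt, amplitude_ma = log$amplitude_ma), p,
              sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_envelope.tsv")
  write.table(data.frame(time_s = tt, envelope_uv = log$envelope$values), p,
              sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(log$recorder)) {
    per <- storage_period_s(log$recorder$cfg)
    vals <- log$recorder$values
    p <- paste0(prefix, "_recorder.tsv")
    write.table(data.frame(slot_time_s = (seq_along(vals) - 1) * per,
                           stored_uv = vals), p,
                sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
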