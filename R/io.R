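# Readers and writers: flat little-endian int16 binary per channel with a
# JSON metadata sidecar, CSV tables, and JSON session configs.

#' Write a recording as flat binary + JSON sidecar
#'
#' Each channel (LFP then accelerometer) is written as little-endian int16
#' in `<stem>_<channel>.bin` after scaling by a per-file `scale` factor
#' chosen so the maximum absolute sample maps to 32000 counts; the sidecar
#' `<stem>.json` records `fs`, channel order, per-channel scale
#' (a.u. per count) and epoch marks.
#'
#' @param rec An `lfp_recording`.
#' @param stem Output path stem (directories must exist).
#' @return Invisibly, the sidecar path.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "lfp_recording"))
  chans <- list()
  mats <- rbind(rec$lfp, rec$acc)
  labels <- c(rownames(rec$lfp), paste0("acc_", rownames(rec$acc)))
  for (i in seq_along(labels)) {
    v <- mats[i, ]
    peak <- max(abs(v), 1e-12)
    scale <- peak / 32000
    path <- paste0(stem, "_", labels[i], ".bin")
    con <- file(path, "wb")
    writeBin(as.integer(round(v / scale)), con, size = 2, endian = "little")
    close(con)
    chans[[labels[i]]] <- list(file = basename(path), scale = scale)
  }
  sidecar <- paste0(stem, ".json")
  meta <- list(fs = rec$fs, channels = names(chans),
               channel_meta = chans, epoch_marks = rec$epoch_marks,
               n_samples = ncol(rec$lfp))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a recording written by [write_recording()]
#'
#' @param sidecar Path to the JSON sidecar.
#' @return An `lfp_recording` (LFP channels and any `acc_*` channels are
#'   split back apart; `config` holds the sidecar path).
#' @export
read_recording <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  n <- meta$n_samples
  read_ch <- function(name) {
    cm <- meta$channel_meta[[name]]
    con <- file(file.path(dir, cm$file), "rb")
    v <- readBin(con, "integer", n = n, size = 2, endian = "little")
    close(con)
    v * cm$scale
  }
  labels <- meta$channels
  acc_labels <- grep("^acc_", labels, value = TRUE)
  lfp_labels <- setdiff(labels, acc_labels)
  lfp <- do.call(rbind, lapply(lfp_labels, read_ch))
  rownames(lfp) <- lfp_labels
  acc <- if (length(acc_labels)) {
    a <- do.call(rbind, lapply(acc_labels, read_ch))
    rownames(a) <- sub("^acc_", "", acc_labels)
    a
  } else NULL
  epochs <- lapply(meta$epoch_marks, as.numeric)
  structure(list(lfp = lfp, acc = acc, fs = meta$fs,
                 channel_labels = lfp_labels, epoch_marks = epochs,
                 config = sidecar),
            class = "lfp_recording")
}

#' Write a session configuration as JSON
#'
#' @param cfg A [session_config()].
#' @param path Output path.
#' @export
write_session_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "session_config"))
  out <- unclass(cfg)
  # named vectors must become JSON objects, not bare arrays
  out$band_amplitudes <- as.list(out$band_amplitudes)
  out$condition_multipliers <- as.list(out$condition_multipliers)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session configuration from JSON
#'
#' @param path JSON path written by [write_session_config()].
#' @return A `session_config`.
#' @export
read_session_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- session_config(
    duration_s = raw$duration_s, fs_lfp = raw$fs_lfp, fs_raw = raw$fs_raw,
    band_amplitudes = unlist(raw$band_amplitudes),
    one_over_f_exponent = raw$one_over_f_exponent, noise_sd = raw$noise_sd,
    pac_specs = raw$pac_specs,
    condition_multipliers = unlist(raw$condition_multipliers),
    interregion_lag_ms = raw$interregion_lag_ms,
    interregion_band = raw$interregion_band,
    interregion_gain = raw$interregion_gain,
    common_source_gain = raw$common_source_gain,
    condition = raw$condition,
    injection_s = raw$injection_s,
    synth_raw = isTRUE(raw$synth_raw),
    seed = raw$seed
  )
  cfg
}
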