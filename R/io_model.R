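# Core data model: recordings, spike-train sets, stimulation protocols,
# epoching.  Conventions used throughout the package: time in seconds
# (float), sample indices 0-based in files / 1-based inside R, intervals
# half-open [start, end).

REGIONS <- c("MS", "HP")
LAYERS <- c("oriens", "pyramidale", "radiatum", "unknown")

#' Construct a multichannel LFP recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channels data.frame with columns `id` (unique integer),
#'   `region` ("MS"/"HP"), `shank` (integer >= 0), `depth_index`
#'   (integer >= 0, 0 = most dorsal contact) and optionally `layer`.
#' @param session_id character label.
#' @return a `recording` object.
#' @export
recording <- function(data, rate, channels, session_id = "session") {
  data <- as.matrix(data)
  stopifnot(is.numeric(rate), rate > 0, nrow(data) == nrow(channels))
  if (!all(c("id", "region", "shank", "depth_index") %in% names(channels)))
    stop("channel metadata must have id, region, shank, depth_index")
  if (anyDuplicated(channels$id)) stop("channel ids must be unique")
  if (!all(channels$region %in% REGIONS)) stop("region must be MS or HP")
  if (is.null(channels$layer)) channels$layer <- "unknown"
  if (!all(channels$layer %in% LAYERS)) stop("unknown layer label")
  if (!all(is.finite(data))) stop("recording data must be finite")
  structure(list(data = data, rate = rate, channels = channels,
                 session_id = session_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              x$session_id, nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate))
  invisible(x)
}

#' Write a recording as interleaved int16 binary plus JSON sidecar
#'
#' The binary holds channel-interleaved little-endian int16 samples
#' (`value_uv = raw * scale_uv_per_bit`); the sidecar holds
#' `n_channels`, `rate_hz`, `dtype`, `scale_uv_per_bit`, `session_id`
#' and the channel metadata table.
#'
#' @param rec a [recording()].
#' @param binary_path output `.dat` path.
#' @param sidecar_path output `.json` path.
#' @param scale microvolts per bit (default 0.195).
#' @export
write_recording <- function(rec, binary_path, sidecar_path, scale = 0.195) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) == 0) stop("schema error: empty channel list")
  raw <- round(rec$data / scale)
  if (any(raw > 32767 | raw < -32768))
    stop("range error: values overflow int16 at this scale")
  con <- file(binary_path, "wb")
  on.exit(close(con))
  writeBin(as.integer(raw), con, size = 2L, endian = "little")
  meta <- list(
    n_channels = nrow(rec$data),
    rate_hz = rec$rate,
    dtype = "int16",
    scale_uv_per_bit = scale,
    session_id = rec$session_id,
    channels = rec$channels
  )
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a recording from interleaved int16 binary plus JSON sidecar
#'
#' @param binary_path `.dat` path.
#' @param sidecar_path `.json` path (see [write_recording()] schema).
#' @return a [recording()].
#' @export
read_recording <- function(binary_path, sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("n_channels", "rate_hz", "dtype", "scale_uv_per_bit", "channels")
  if (!all(need %in% names(meta)))
    stop("schema error: sidecar missing keys: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  if (!identical(meta$dtype, "int16")) stop("schema error: dtype must be int16")
  nch <- as.integer(meta$n_channels)
  sz <- file.info(binary_path)$size
  if (is.na(sz) || sz %% (2L * nch) != 0)
    stop("malformed file: size not divisible by 2 * n_channels")
  nsamp <- as.integer(sz / (2L * nch))
  con <- file(binary_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nch * nsamp, size = 2L,
                 endian = "little", signed = TRUE)
  data <- matrix(raw * meta$scale_uv_per_bit, nrow = nch)
  recording(data, meta$rate_hz, as.data.frame(meta$channels),
            session_id = if (is.null(meta$session_id)) "session" else meta$session_id)
}

#' Construct a spike-train set
#'
#' @param units list of lists, each with `unit_id` (character), `region`
#'   ("MS"/"HP") and `times` (ascending numeric seconds).
#' @return a `spike_train_set` object.
#' @export
spike_train_set <- function(units) {
  for (u in units) {
    stopifnot(!is.null(u$unit_id), u$region %in% REGIONS)
    if (length(u$times) && (is.unsorted(u$times, strictly = TRUE) || any(u$times < 0)))
      stop("spike times must be strictly ascending and non-negative")
  }
  names(units) <- vapply(units, function(u) as.character(u$unit_id), character(1))
  structure(list(units = units), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- vapply(x$units, function(u) length(u$times), integer(1))
  cat(sprintf("<spike_train_set: %d units, %d spikes>\n", length(ns), sum(ns)))
  invisible(x)
}

#' Read spike times from CSV (columns unit_id, region, time_s)
#'
#' Rows may arrive in any order; per-unit times are sorted.  Duplicate
#' timestamps within a unit are collapsed with a warning; an unknown
#' region is a schema error.
#'
#' @param csv_path input path.
#' @return a [spike_train_set()].
#' @export
read_spikes <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "region", "time_s") %in% names(df)))
    stop("schema error: need columns unit_id, region, time_s")
  if (!all(df$region %in% REGIONS)) stop("schema error: unknown region")
  units <- lapply(split(df, df$unit_id), function(g) {
    tt <- sort(g$time_s)
    if (anyDuplicated(tt)) {
      warning("duplicate timestamps collapsed for unit ", g$unit_id[1])
      tt <- unique(tt)
    }
    list(unit_id = as.character(g$unit_id[1]), region = g$region[1], times = tt)
  })
  spike_train_set(unname(units))
}

#' Write a spike-train set to CSV
#'
#' @param spikes a [spike_train_set()].
#' @param csv_path output path.
#' @export
write_spikes <- function(spikes, csv_path) {
  rows <- do.call(rbind, lapply(spikes$units, function(u) {
    if (!length(u$times)) return(NULL)
    data.frame(unit_id = u$unit_id, region = u$region, time_s = u$times)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  invisible(NULL)
}

#' Construct a stimulation protocol
#'
#' @param onsets ascending pulse onset times in seconds.
#' @param pulse_duration pulse length in seconds (default 5).
#' @param period pulse period in seconds (default 20).
#' @param session_length session length in seconds (default 600).
#' @return a `stim_protocol` object.
#' @export
stim_protocol <- function(onsets, pulse_duration = 5, period = 20,
                          session_length = 600) {
  stopifnot(!is.unsorted(onsets), pulse_duration > 0)
  if (any(onsets + pulse_duration > session_length + 1e-9))
    stop("pulse extends past session end")
  if (length(onsets) > 1 && any(diff(onsets) < pulse_duration - 1e-9))
    stop("pulses overlap")
  structure(list(onsets = as.numeric(onsets), pulse_duration = pulse_duration,
                 period = period, session_length = session_length),
            class = "stim_protocol")
}

#' Default 10-minute protocol: 5 s on every 20 s (15 s off - 5 s on)
#'
#' @param session_length seconds (default 600).
#' @param pulse_duration seconds (default 5).
#' @param period seconds (default 20).
#' @return a [stim_protocol()] with onsets 15, 35, ...
#' @export
default_protocol <- function(session_length = 600, pulse_duration = 5,
                             period = 20) {
  onsets <- seq(period - pulse_duration, session_length - pulse_duration,
                by = period)
  stim_protocol(onsets, pulse_duration, period, session_length)
}

#' Read / write a protocol CSV (columns onset_s, duration_s)
#' @param csv_path path.
#' @param session_length session length in seconds for validation.
#' @return a [stim_protocol()].
#' @export
read_protocol <- function(csv_path, session_length = 600) {
  df <- utils::read.csv(csv_path)
  if (!all(c("onset_s", "duration_s") %in% names(df)))
    stop("schema error: need columns onset_s, duration_s")
  stim_protocol(sort(df$onset_s), pulse_duration = df$duration_s[1],
                period = if (nrow(df) > 1) stats::median(diff(sort(df$onset_s))) else 20,
                session_length = session_length)
}

#' @rdname read_protocol
#' @param protocol a [stim_protocol()].
#' @export
write_protocol <- function(protocol, csv_path) {
  utils::write.csv(
    data.frame(onset_s = protocol$onsets,
               duration_s = protocol$pulse_duration),
    csv_path, row.names = FALSE)
  invisible(NULL)
}

#' Build on / pre-pulse-off epochs from a protocol
#'
#' For each pulse onset t: `on = [t, t + d)` and `off_pre = [t - d, t)`
#' where `d` is the pulse duration (the off epoch is the matched window
#' immediately preceding the pulse, not the full inter-pulse gap).
#' Pairs whose off window would start before the session (or overlap the
#' previous pulse) are dropped; on epochs are clipped to the session.
#'
#' @param protocol a [stim_protocol()].
#' @param off_duration length of the pre-pulse off window (defaults to
#'   the pulse duration so pairs are matched).
#' @return data.frame with `start`, `end`, `label` ("on"/"off_pre") and
#'   `trial` index; intervals half-open.
#' @export
epochs_from_protocol <- function(protocol, off_duration = NULL) {
  d <- protocol$pulse_duration
  if (is.null(off_duration)) off_duration <- d
  out <- NULL
  trial <- 0L
  prev_end <- -Inf
  for (t in protocol$onsets) {
    off_start <- t - off_duration
    if (off_start < 0 || off_start < prev_end) { prev_end <- t + d; next }
    trial <- trial + 1L
    out <- rbind(out,
                 data.frame(start = off_start, end = t, label = "off_pre", trial = trial),
                 data.frame(start = t, end = min(t + d, protocol$session_length),
                            label = "on", trial = trial))
    prev_end <- t + d
  }
  out
}

# Internal: spikes falling in a set of half-open intervals; returns count
# and total interval duration.
count_in_epochs <- function(times, epochs) {
  cnt <- 0L
  for (i in seq_len(nrow(epochs)))
    cnt <- cnt + sum(times >= epochs$start[i] & times < epochs$end[i])
  list(count = cnt, duration = sum(epochs$end - epochs$start))
}
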