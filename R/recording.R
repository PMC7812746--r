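#' Multichannel recording container
#'
#' Continuous multichannel signal with sampling rate and per-channel depth
#' and area metadata. This is the package's "LFP" object: rows are time
#' samples, columns are channels. Channels within an area are numbered from
#' superficial to deep; by convention channel 3 of a 14-channel probe proxies
#' the supragranular layers and channel 10 the subgranular layers.
#'
#' @param signal Numeric matrix, time x channel.
#' @param fs Sampling rate in Hz.
#' @param depth_um Numeric vector of channel depths in micrometres.
#' @param area Character vector naming the area of each channel.
#'
#' @return An object of class `mc_recording` with elements `signal`, `fs`
#'   and `channels` (a data.frame with `channel`, `depth_um`, `area`).
#' @export
#' @examples
#' rec <- mc_recording(matrix(rnorm(200), 100, 2), fs = 100,
#'                     depth_um = c(100, 200), area = c("S1", "S1"))
#' dim(rec$signal)
mc_recording <- function(signal, fs, depth_um = NULL, area = NULL) {
  signal <- as.matrix(signal)
  ct_assert(is.numeric(signal), "signal must be numeric")
  ct_assert(is_scalar_num(fs) && fs > 0, "fs must be a positive number")
  nch <- ncol(signal)
  if (is.null(depth_um)) depth_um <- seq_len(nch) * 100
  if (is.null(area)) area <- rep("area1", nch)
  ct_assert(length(depth_um) == nch, "depth_um must have one entry per channel")
  ct_assert(length(area) == nch, "area must have one entry per channel")
  structure(
    list(
      signal = signal,
      fs = fs,
      channels = data.frame(
        channel = seq_len(nch),
        depth_um = as.numeric(depth_um),
        area = as.character(area),
        stringsAsFactors = FALSE
      )
    ),
    class = "mc_recording"
  )
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf(
    "<mc_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
    nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs
  ))
  for (a in unique(x$channels$area)) {
    idx <- x$channels$area == a
    cat(sprintf("  area %s: channels %s, depths %g-%g um\n", a,
                paste(range(x$channels$channel[idx]), collapse = "-"),
                min(x$channels$depth_um[idx]), max(x$channels$depth_um[idx])))
  }
  invisible(x)
}

# Channel indices belonging to one area, in depth order.
area_channels <- function(rec, area) {
  idx <- which(rec$channels$area == area)
  ct_assert(length(idx) > 0, "unknown area '%s'", area)
  idx[order(rec$channels$depth_um[idx])]
}

#' Event table
#'
#' @param onset_s Numeric vector of stimulus onsets in seconds.
#' @param condition Character vector of condition labels (recycled).
#'
#' @return A data.frame with columns `onset_s` and `condition`.
#' @export
event_table <- function(onset_s, condition = "stim") {
  ct_assert(is.numeric(onset_s) && all(is.finite(onset_s)),
            "onset_s must be finite numeric")
  data.frame(
    onset_s = as.numeric(onset_s),
    condition = rep_len(as.character(condition), length(onset_s)),
    stringsAsFactors = FALSE
  )
}

# ---- container I/O ---------------------------------------------------------
# Layout: a directory holding
#   signal.tsv  -- tab-separated time x channel matrix, no header,
#                  doubles printed with "%.17g" so round-trips are bit-exact
#   meta.json   -- {sampling_rate, channel_depth_um, area}
#   events.tsv  -- optional sidecar: onset_s <TAB> condition, with header

#' Write / read the shared recording container
#'
#' `write_recording()` stores an [mc_recording] (and optionally its event
#' table) in a plain-text container directory; `read_recording()` loads it
#' back. Doubles are serialized with 17 significant digits, so a write/read
#' cycle reproduces the signal bit-exactly.
#'
#' @param rec An [mc_recording].
#' @param path Container directory (created if needed).
#' @param events Optional event table written as `events.tsv`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the [mc_recording], with the event table attached as
#'   `attr(rec, "events")` when present.
#' @export
write_recording <- function(rec, path, events = NULL) {
  ct_assert(inherits(rec, "mc_recording"), "rec must be an mc_recording")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  txt <- matrix(sprintf("%.17g", rec$signal), nrow = nrow(rec$signal))
  data.table::fwrite(data.table::as.data.table(txt),
                     file.path(path, "signal.tsv"),
                     sep = "\t", col.names = FALSE, quote = FALSE)
  meta <- list(
    sampling_rate = rec$fs,
    channel_depth_um = rec$channels$depth_um,
    area = rec$channels$area
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(events)) write_events(events, file.path(path, "events.tsv"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  sig_path <- file.path(path, "signal.tsv")
  ct_assert(file.exists(meta_path), "container %s is missing meta.json", path)
  ct_assert(file.exists(sig_path), "container %s is missing signal.tsv", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("sampling_rate", "channel_depth_um", "area")) {
    if (is.null(meta[[field]])) {
      ct_stop("container %s: required metadata field '%s' is missing",
              path, field)
    }
  }
  sig <- as.matrix(data.table::fread(sig_path, sep = "\t", header = FALSE))
  dimnames(sig) <- NULL
  rec <- mc_recording(sig, fs = as.numeric(meta$sampling_rate),
                      depth_um = meta$channel_depth_um, area = meta$area)
  ev_path <- file.path(path, "events.tsv")
  if (file.exists(ev_path)) attr(rec, "events") <- read_events(ev_path)
  rec
}

#' Read / write TSV event tables
#'
#' Events are stored as a two-column TSV (`onset_s`, `condition`) with a
#' header row. Malformed rows abort the load with the offending line number.
#'
#' @param path TSV file path.
#' @param events Event table as produced by [event_table()].
#' @return `read_events()` returns the event data.frame.
#' @export
read_events <- function(path) {
  ct_assert(file.exists(path), "event file %s does not exist", path)
  lines <- readLines(path)
  ct_assert(length(lines) >= 1, "event file %s is empty", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ct_assert(identical(header, c("onset_s", "condition")),
            "event file %s: expected header 'onset_s<TAB>condition'", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  onset <- numeric(length(parts))
  cond <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    val <- suppressWarnings(as.numeric(p[1]))
    if (length(p) != 2L || is.na(val)) {
      ct_stop("event file %s: malformed row at line %d: '%s'",
              path, i + 1L, body[i])
    }
    onset[i] <- val
    cond[i] <- p[2]
  }
  event_table(onset, cond)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  ct_assert(is.data.frame(events) &&
              all(c("onset_s", "condition") %in% names(events)),
            "events must have columns onset_s and condition")
  lines <- c(
    "onset_s\tcondition",
    sprintf("%.17g\t%s", events$onset_s, events$condition)
  )
  writeLines(lines, path)
  invisible(path)
}
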