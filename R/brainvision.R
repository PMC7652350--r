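#' Read a BrainVision recording (.vhdr / .vmrk / .eeg)
#'
#' Parses the INI-style header, the marker file and the binary data file of
#' the BrainVision Core format. Binary formats `IEEE_FLOAT_32` and `INT_16`
#' (scaled by the per-channel resolution) and both `MULTIPLEXED` and
#' `VECTORIZED` orientations are supported. Values are returned in uV.
#'
#' @param header_path path to the `.vhdr` header file.
#' @param channel channel label to extract (default `"Pz"`), or `NULL` for
#'   all channels.
#' @return a list with `data` (numeric vector for one channel, or a
#'   samples-by-channels matrix), `channels`, `sample_rate` (Hz), and
#'   `markers` (tibble with `type`, `description`, `sample` — 1-based — and
#'   `time_ms` = `sample * 1000 / sample_rate`).
#' @seealso [write_brainvision()]
#' @export
read_brainvision <- function(header_path, channel = "Pz") {
  if (!file.exists(header_path)) abort(paste("no such file:", header_path))
  hdr <- parse_ini(readLines(header_path, warn = FALSE))
  common <- hdr[["Common Infos"]]
  if (is.null(common)) abort("header has no [Common Infos] section")

  dir <- dirname(header_path)
  data_path <- file.path(dir, common[["DataFile"]])
  marker_path <- if (!is.null(common[["MarkerFile"]])) {
    file.path(dir, common[["MarkerFile"]])
  }
  if (!file.exists(data_path)) {
    abort(paste("companion data file missing:", data_path))
  }
  if (!is.null(marker_path) && !file.exists(marker_path)) {
    abort(paste("companion marker file missing:", marker_path))
  }

  n_chan <- as.integer(common[["NumberOfChannels"]])
  samp_int_us <- as.numeric(common[["SamplingInterval"]])
  sample_rate <- 1e6 / samp_int_us
  orientation <- toupper(common[["DataOrientation"]] %||% "MULTIPLEXED")

  chans <- hdr[["Channel Infos"]]
  ch <- purrr::map(chans[order(as.integer(sub("^Ch", "", names(chans))))],
                   ~ strsplit(.x, ",")[[1]])
  ch_names <- unname(purrr::map_chr(ch, 1))
  resolution <- purrr::map_dbl(ch, function(f) {
    r <- if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else NA
    if (is.na(r)) 1 else r
  })

  fmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  raw <- switch(fmt,
    IEEE_FLOAT_32 = readBin(data_path, "double", size = 4,
                            n = file.size(data_path) / 4, endian = "little"),
    INT_16 = readBin(data_path, "integer", size = 2,
                     n = file.size(data_path) / 2, endian = "little"),
    abort(paste("unknown BinaryFormat field:", fmt))
  )
  n_samp <- length(raw) %/% n_chan
  mat <- if (orientation == "MULTIPLEXED") {
    t(matrix(raw[seq_len(n_samp * n_chan)], n_chan, n_samp))
  } else if (orientation == "VECTORIZED") {
    matrix(raw[seq_len(n_samp * n_chan)], n_samp, n_chan)
  } else {
    abort(paste("unknown DataOrientation:", orientation))
  }
  mat <- sweep(mat, 2, resolution, `*`)
  colnames(mat) <- ch_names

  markers <- read_vmrk(marker_path, sample_rate)

  data <- if (is.null(channel)) mat else {
    if (!channel %in% ch_names) {
      abort(sprintf("channel '%s' not found (have: %s)", channel,
                    paste(ch_names, collapse = ", ")))
    }
    unname(mat[, channel])
  }
  list(data = data, channels = ch_names, sample_rate = sample_rate,
       markers = markers)
}

read_vmrk <- function(marker_path, sample_rate) {
  if (is.null(marker_path) || is.na(marker_path) ||
      !file.exists(marker_path)) {
    return(tibble(type = character(), description = character(),
                  sample = integer(), time_ms = numeric()))
  }
  ini <- parse_ini(readLines(marker_path, warn = FALSE))
  mk <- ini[["Marker Infos"]]
  if (is.null(mk) || !length(mk)) {
    return(tibble(type = character(), description = character(),
                  sample = integer(), time_ms = numeric()))
  }
  mk <- mk[order(as.integer(sub("^Mk", "", names(mk))))]
  fields <- unname(purrr::map(mk, ~ strsplit(.x, ",")[[1]]))
  tibble(
    type = purrr::map_chr(fields, 1),
    description = purrr::map_chr(fields, ~ if (length(.x) > 1) .x[2] else ""),
    sample = purrr::map_int(fields, ~ as.integer(.x[3]))
  ) |>
    mutate(time_ms = .data$sample * 1000 / sample_rate)
}

# Minimal INI parser: returns a named list of sections, each a named list of
# key=value strings. Values may themselves contain commas.
parse_ini <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (!is.null(section) && grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      out[[section]][[key]] <- trimws(substr(ln, eq + 1, nchar(ln)))
    }
  }
  out
}

#' Write a BrainVision recording
#'
#' Writes the `.vhdr`/`.vmrk`/`.eeg` triplet for a single- or multi-channel
#' continuous recording; mainly used to build fixtures and to export
#' simulated data for external tools.
#'
#' @param data numeric vector (one channel) or samples-by-channels matrix,
#'   in uV.
#' @param stem path stem; `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` are
#'   created.
#' @param sample_rate sampling rate in Hz.
#' @param channels channel labels.
#' @param markers optional data frame with columns `type`, `description`,
#'   `sample` (1-based).
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(data, stem, sample_rate = 500,
                              channels = "Pz", markers = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  stopifnot(ncol(data) == length(channels))
  base <- basename(stem)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ncol(data)),
    paste0("SamplingInterval=", format(1e6 / sample_rate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(channels), channels)
  )
  writeLines(hdr, paste0(stem, ".vhdr"))

  mk_lines <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]"
  )
  if (!is.null(markers) && nrow(markers)) {
    mk_lines <- c(mk_lines, sprintf(
      "Mk%d=%s,%s,%d,1,0", seq_len(nrow(markers)),
      markers$type, markers$description %||% "", markers$sample
    ))
  }
  writeLines(mk_lines, paste0(stem, ".vmrk"))

  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(data)), con, size = 4, endian = "little")
  invisible(paste0(stem, ".vhdr"))
}
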