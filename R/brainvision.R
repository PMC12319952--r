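#' Read and write BrainVision recordings
#'
#' Minimal support for the BrainVision triplet: a `.vhdr` text header, a
#' `.vmrk` marker file, and a binary `.eeg` data file
#' (IEEE float32, multiplexed channel order — the actiCHamp default).
#' Markers named `cue` / `target` round-trip into the record's `events`
#' table.
#'
#' @param record An `eeg_record`.
#' @param basepath Output path without extension; the three files are
#'   written next to each other.
#' @return `write_brainvision()` returns the `.vhdr` path invisibly;
#'   `read_brainvision()` returns an `eeg_record` (with an empty
#'   schedule).
#' @export
write_brainvision <- function(record, basepath) {
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  n_ch <- nrow(record$data)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / record$srate, digits = 12)),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), record$channel_names)
  )
  writeLines(header, vhdr)
  pos <- round(record$events$onset * record$srate) + 1L
  markers <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_along(pos) + 1L,
            record$events$event, pos)
  )
  writeLines(markers, paste0(basepath, ".vmrk"))
  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(record$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

bv_section <- function(lines, name) {
  starts <- grep("^\\[", lines)
  i <- grep(paste0("^\\[", name, "\\]$"), lines)
  if (length(i) == 0) return(character())
  nxt <- starts[starts > i]
  end <- if (length(nxt)) nxt[1] - 1 else length(lines)
  lines[(i + 1):end]
}

bv_keyvals <- function(section) {
  kv <- section[grepl("=", section, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(vals, keys)
}

#' @rdname write_brainvision
#' @param vhdr_path Path to the `.vhdr` header file.
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  common <- bv_keyvals(bv_section(lines, "Common Infos"))
  binary <- bv_keyvals(bv_section(lines, "Binary Infos"))
  if (!identical(unname(common["DataFormat"]), "BINARY") ||
      !identical(unname(common["DataOrientation"]), "MULTIPLEXED") ||
      !identical(unname(binary["BinaryFormat"]), "IEEE_FLOAT_32")) {
    abort("Only BINARY multiplexed IEEE_FLOAT_32 recordings are supported.",
          class = "attnpipe_config_error")
  }
  n_ch <- as.integer(common["NumberOfChannels"])
  srate <- 1e6 / as.numeric(common["SamplingInterval"])
  ch_info <- bv_keyvals(bv_section(lines, "Channel Infos"))
  channels <- vapply(strsplit(unname(ch_info), ",", fixed = TRUE),
                     `[[`, character(1), 1)
  dirn <- dirname(vhdr_path)
  eeg_path <- file.path(dirn, common["DataFile"])
  n_bytes <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_data <- readBin(con, "numeric", n = n_bytes / 4, size = 4,
                      endian = "little")
  data <- matrix(raw_data, nrow = n_ch)
  rownames(data) <- channels

  events <- tibble(trial = integer(), event = character(),
                   onset = numeric())
  vmrk_path <- file.path(dirn, common["MarkerFile"])
  if (file.exists(vmrk_path)) {
    mk <- bv_keyvals(bv_section(readLines(vmrk_path, warn = FALSE),
                                "Marker Infos"))
    parts <- strsplit(unname(mk), ",", fixed = TRUE)
    keep <- vapply(parts, function(p) p[1] == "Stimulus", logical(1))
    if (any(keep)) {
      desc <- vapply(parts[keep], `[[`, character(1), 2)
      pos <- as.integer(vapply(parts[keep], `[[`, character(1), 3))
      events <- tibble(trial = NA_integer_, event = desc,
                       onset = (pos - 1) / srate)
      events <- events |>
        dplyr::group_by(.data$event) |>
        dplyr::mutate(trial = dplyr::row_number()) |>
        dplyr::ungroup()
    }
  }
  structure(
    list(data = data, srate = srate, channel_names = channels,
         events = events, schedule = tibble(trial = integer())),
    class = "eeg_record"
  )
}
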