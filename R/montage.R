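#' Channel montages and the posterior electrode cluster
#'
#' The standard 64-channel actiCAP layout (10-20 names, including the
#' TP9/TP10 mastoid-approximating reference sites), and the cluster of 17
#' posterior electrodes over which ERPs, alpha power and decoding features
#' are computed.
#'
#' @format `posterior_17` is a character vector of 17 electrode names;
#'   `montage_64()` returns all 64 names in recording order.
#' @export
posterior_17 <- c(
  "Pz", "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
  "POz", "PO3", "PO4", "PO7", "PO8", "Oz", "O1", "O2"
)

#' @rdname posterior_17
#' @export
montage_64 <- function() {
  c(
    "Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9",
    "CP5", "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8",
    "TP10", "CP6", "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4",
    "F8", "Fp2", "AF7", "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1",
    "C5", "TP7", "CP3", "P1", "P5", "PO7", "PO3", "POz", "PO8", "PO4",
    "P6", "P2", "CPz", "CP4", "TP8", "C6", "C2", "FC4", "FT8", "F6",
    "AF8", "AF4", "F2", "Iz"
  )
}

#' @rdname posterior_17
#' @param name `"full64"` for the complete cap, `"posterior19"` for the
#'   desk-scale montage holding only the 17 posterior channels plus the
#'   TP9/TP10 references.
#' @export
montage <- function(name = c("full64", "posterior19")) {
  name <- match.arg(name)
  switch(name,
    full64 = montage_64(),
    posterior19 = c("TP9", "TP10", posterior_17)
  )
}

#' Seven-color palette of the detection task
#'
#' Colors are abstract labels; rendering and isoluminance calibration are
#' out of scope.
#' @export
color_palette <- function() {
  c("red", "green", "blue", "yellow", "pink", "orange", "cyan")
}

# Accept either a montage name or an explicit channel vector.
resolve_montage <- function(x) {
  if (length(x) > 1) as.character(x) else montage(x)
}

frontal_channels <- function(channels) {
  channels[grepl("^(Fp|AF|F|FT|FC)", channels) & !grepl("^FCz$", channels)]
}
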