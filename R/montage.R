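#' @title EEG montage and channel adjacency
#' @description An idealized 2-D layout for the standard 64-channel 10-20 /
#'   10-10 electrode set, and the neighbor structure derived from it. The
#'   coordinates place the electrode rows (Fp, AF, F, FC/FT, C/T, CP/TP, P,
#'   PO, O) on evenly spaced grid lines and number the lateral positions
#'   symmetrically, which preserves the topology that cluster formation
#'   needs; they are a synthetic layout, not digitized positions.
#' @name montage
NULL

.montage_channels_64 <- c(
  "Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2"
)

#' Channels used for the centroparietal P300 mean amplitude
#'
#' The default 24-channel centroparietal set over which target-evoked P300
#' mean amplitudes are extracted.
#' @return character vector of channel names
#' @export
p300_channel_set <- function() {
  c("C3", "CP5", "CP1", "Pz", "P3", "P4", "P8", "CP6", "CP2", "C4",
    "C1", "C5", "CP3", "P1", "P5", "PO7", "PO3", "PO4", "P6", "P2",
    "CPz", "CP4", "C2", "Cz")
}

#' Standard montage with idealized 2-D coordinates
#'
#' @param channels channel names to include (default: the full 64-channel
#'   set); names must follow 10-20 / 10-10 conventions (ring prefix plus
#'   `z` or a lateral number)
#' @return data.frame with `channel`, `x`, `y` (head units, left negative,
#'   front positive)
#' @export
standard_montage <- function(channels = .montage_channels_64) {
  ring_y <- c(Fp = 0.8, AF = 0.6, F = 0.4, FC = 0.2, FT = 0.2,
              C = 0, T = 0, CP = -0.2, TP = -0.2, P = -0.4,
              PO = -0.6, O = -0.8, I = -1.0)
  parse_one <- function(ch) {
    m <- regmatches(ch, regexec("^([A-Za-z]+?)(z|[0-9]+)$", ch))[[1]]
    if (length(m) != 3) stop("unrecognized channel name: ", ch)
    ring <- m[2]; pos <- m[3]
    # T7/T8 and TP/FT lateral channels live on the C-family rows
    ring_key <- switch(ring, T = "T", Fp = "Fp", ring)
    if (!ring_key %in% names(ring_y)) stop("unknown electrode ring: ", ring)
    y <- ring_y[[ring_key]]
    if (pos == "z") {
      x <- 0
    } else {
      i <- as.integer(pos)
      side <- if (i %% 2 == 1) -1 else 1
      x <- side * 0.2 * ceiling(i / 2)
    }
    c(x = x, y = y)
  }
  xy <- t(vapply(channels, parse_one, c(x = 0, y = 0)))
  data.frame(channel = channels, x = xy[, "x"], y = xy[, "y"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Channel adjacency from montage coordinates
#'
#' Two channels are neighbors when their planar distance does not exceed
#' `cutoff`. The default cutoff of 0.3 links each interior electrode of the
#' idealized grid (spacing 0.2) to its 4 rectilinear and 4 diagonal
#' neighbors, giving a median neighbor count in the 4-8 range.
#'
#' @param montage data.frame from [standard_montage()]
#' @param cutoff neighbor distance cutoff in head units
#' @return symmetric logical matrix (no self-neighbors) with channel
#'   dimnames
#' @export
channel_adjacency <- function(montage, cutoff = 0.3) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$channel, montage$channel)
  adj
}
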