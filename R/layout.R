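#' Canonical 22-channel bipolar longitudinal montage
#'
#' The fixed, ordered list of bipolar derivations used throughout the package.
#' It is the 22-channel subset common to all CHB-MIT-style pediatric recordings:
#' left and right temporal and parasagittal chains, the midline chain, and the
#' inferior temporal chain through FT9/FT10. Note that `T7-P7` and `P7-T7` are
#' both present (as in the source montage); their derivation midpoints coincide.
#'
#' @return Character vector of 22 channel names.
#' @export
canonical_channels <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ",
    "P7-T7", "T7-FT9", "FT9-FT10", "FT10-T8")
}

# 2-D head-schematic coordinates (unitless, nose up) for the 10-20 electrodes
# appearing in the canonical montage. Outer ring at radius 1, inner positions
# at radius 0.5, FT9/FT10 on the inferior 10% ring (radius 1.2).
electrode_positions <- function() {
  deg <- function(a) a * pi / 180
  ring <- function(angle, r) c(r * cos(deg(angle)), r * sin(deg(angle)))
  pos <- rbind(
    FP1 = ring(108, 1), FP2 = ring(72, 1),
    F7  = ring(144, 1), F8  = ring(36, 1),
    T7  = ring(180, 1), T8  = ring(0, 1),
    P7  = ring(216, 1), P8  = ring(-36, 1),
    O1  = ring(252, 1), O2  = ring(-72, 1),
    F3  = ring(135, 0.5), F4 = ring(45, 0.5),
    C3  = ring(180, 0.5), C4 = ring(0, 0.5),
    P3  = ring(225, 0.5), P4 = ring(-45, 0.5),
    FZ  = c(0, 0.5), CZ = c(0, 0), PZ = c(0, -0.5),
    FT9 = ring(162, 1.2), FT10 = ring(18, 1.2)
  )
  colnames(pos) <- c("x", "y")
  pos
}

#' Electrode layout for a bipolar montage
#'
#' Computes one 2-D coordinate per bipolar derivation as the midpoint of the two
#' 10-20 electrode positions forming the pair (e.g. the coordinate of `FP1-F3`
#' is the midpoint of FP1 and F3). Coordinates live on a unitless head-schematic
#' plane (top view, nose up) and feed the spatial-distance graph.
#'
#' @param channels Character vector of `ELEC1-ELEC2` derivation names.
#'   Defaults to [canonical_channels()].
#' @return A list of class `electrode_layout` with `names` and a matrix
#'   `coords` (one row per derivation, columns `x`, `y`).
#' @examples
#' lay <- electrode_layout()
#' head(lay$coords)
#' @export
electrode_layout <- function(channels = canonical_channels()) {
  pos <- electrode_positions()
  coords <- t(vapply(channels, function(ch) {
    parts <- strsplit(ch, "-", fixed = TRUE)[[1L]]
    abort_if(length(parts) != 2L, "channel name not a bipolar pair: ", ch)
    abort_if(!all(parts %in% rownames(pos)),
             "unknown electrode(s) in ", ch, ": ",
             paste(setdiff(parts, rownames(pos)), collapse = ", "))
    (pos[parts[1L], ] + pos[parts[2L], ]) / 2
  }, numeric(2)))
  colnames(coords) <- c("x", "y")
  structure(list(names = channels, coords = coords), class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> ", length(x$names), " bipolar derivations\n", sep = "")
  invisible(x)
}

#' Read or write an electrode layout as CSV
#'
#' Plain CSV with columns `name`, `x`, `y`.
#'
#' @param layout An `electrode_layout`.
#' @param path File path.
#' @return `read_layout_csv()` returns an `electrode_layout`;
#'   `write_layout_csv()` returns `path` invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  df <- data.frame(name = layout$names,
                   x = layout$coords[, "x"], y = layout$coords[, "y"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- as.matrix(df[, c("x", "y")])
  rownames(coords) <- df$name
  structure(list(names = df$name, coords = coords), class = "electrode_layout")
}
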