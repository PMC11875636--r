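#' Electrode montage with 2-D head-model positions and named ROIs
#'
#' A montage couples an ordered set of channel labels with positions in a
#' unit-disc head model (nose towards +y, right ear towards +x) and a set of
#' named regions of interest (electrode subsets). Positions are a flat polar
#' projection of the 10-10 spherical layout: the vertex maps to the origin
#' and the head circumference to radius one.
#'
#' @param channel_names character vector of unique channel labels.
#' @param positions numeric matrix, one row per channel, columns `x`, `y`;
#'   all rows must lie inside the closed unit disc.
#' @param rois named list of character vectors; every entry must be a subset
#'   of `channel_names`.
#' @return An object of class `bfn_montage`.
#' @seealso [make_default_montage()]
#' @export
montage <- function(channel_names, positions, rois = list()) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop_config("montage channel names must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channel_names) || ncol(positions) != 2)
    stop_config("positions must be a %d x 2 matrix", length(channel_names))
  if (any(sqrt(rowSums(positions^2)) > 1 + 1e-9))
    stop_config("all positions must lie within the closed unit disc")
  for (nm in names(rois)) {
    missing <- setdiff(rois[[nm]], channel_names)
    if (length(missing))
      stop_config("ROI '%s' contains unknown channels: %s", nm,
                  paste(missing, collapse = ", "))
  }
  dimnames(positions) <- list(channel_names, c("x", "y"))
  structure(list(channel_names = channel_names, positions = positions,
                 rois = rois),
            class = "bfn_montage")
}

#' @export
print.bfn_montage <- function(x, ...) {
  cat(sprintf("<bfn_montage> %d channels, %d ROI(s)\n",
              length(x$channel_names), length(x$rois)))
  for (nm in names(x$rois))
    cat(sprintf("  %s: %s\n", nm, paste(x$rois[[nm]], collapse = " ")))
  invisible(x)
}

# 10-10 grid bookkeeping: sagittal row index (front positive, vertex row 0)
# and lateral index (z = 0, odd numbers increase towards the ears).
.bfn_rows <- list(
  Fp = 4L, AF = 3L, F = 2L, FC = 1L, C = 0L, CP = -1L, P = -2L, PO = -3L,
  O = -4L
)

.bfn_chan_table <- function() {
  rows <- list(
    Fp = c("Fp1", "Fpz", "Fp2"),
    AF = c("AF7", "AF3", "AFz", "AF4", "AF8"),
    F  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    FC = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    C  = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    CP = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    P  = c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"),
    PO = c("PO7", "PO3", "POz", "PO4", "PO8"),
    O  = c("O1", "Oz", "O2", "Iz")
  )
  out <- list()
  for (row in names(rows)) {
    labs <- rows[[row]]
    for (lab in labs) {
      num <- sub("^[A-Za-z]+?(?=[0-9]*$)", "", lab, perl = TRUE)
      midline <- num == "" || grepl("z$", lab)
      lat <- if (midline) 0L else as.integer(num)
      side <- if (midline) 0L else if (lat %% 2 == 1) -1L else 1L
      lat_steps <- if (side == 0L) 0L else as.integer(ceiling(lat / 2))
      sag <- if (lab == "Iz") -5L else .bfn_rows[[row]]
      # outer temporal/parietal chain sits one lateral step further out
      out[[lab]] <- c(sag = sag, lat = side * lat_steps)
    }
  }
  out
}

#' Default 64-channel 10-10 montage with frontal ROIs
#'
#' Builds the montage used throughout the package: 64 channels of the
#' extended 10-10 system projected onto the unit disc, with the two frontal
#' regions of interest used in the natural- vs supernumerary-thumb analyses:
#' right = AF8, F6, F8, FC6, C6 and left = AF7, F5, F7, FC5, C5.
#'
#' @return A [montage()] object with ROIs `"right_frontal"` and
#'   `"left_frontal"` (10 channels in total).
#' @examples
#' m <- make_default_montage()
#' m$rois$right_frontal
#' @export
make_default_montage <- function() {
  tab <- .bfn_chan_table()
  names_ <- names(tab)
  pos <- t(vapply(tab, function(ij) {
    sag <- ij[["sag"]]; lat <- ij[["lat"]]
    # polar angle from the vertex: 18 degrees per 10% step, capped at the
    # circumference; azimuth measured from the nose, positive to the right
    theta <- min(18 * sqrt(sag^2 + lat^2), 90)
    r <- theta / 90
    az <- atan2(lat, sag)
    c(x = r * sin(az), y = r * cos(az))
  }, numeric(2)))
  montage(names_, pos,
          rois = list(
            right_frontal = c("AF8", "F6", "F8", "FC6", "C6"),
            left_frontal  = c("AF7", "F5", "F7", "FC5", "C5")
          ))
}

#' ROI channel labels of a montage
#'
#' @param montage a [montage()] object.
#' @param which ROI names to collect; defaults to all.
#' @return character vector of channel labels (order: as listed per ROI).
#' @export
roi_channels <- function(montage, which = names(montage$rois)) {
  unique(unlist(montage$rois[which], use.names = FALSE))
}
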