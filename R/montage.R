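#' Standard 31-channel 10-20 montage
#'
#' Builds the 31-channel active-electrode montage used throughout the
#' package: channel names, unit-sphere electrode positions, the left/right
#' mirror-pair map, and the frontal and parietal pair sets used for the
#' coronal-plane asymmetry contrast.
#'
#' Positions derive from the classical BESA spherical angles for the 10-20
#' system, converted to Cartesian coordinates on the unit sphere with +x
#' through the nasion, +y through the left ear and +z through the vertex.
#' Odd-numbered labels sit over the left hemisphere and mirror their
#' even-numbered counterparts (F3-F4, T7-T8, ...); midline `z` channels are
#' unpaired.
#'
#' Note: some published channel selections mention FC9/FC10, which do not
#' exist in this 31-channel montage; only the 31 listed channels are carried.
#'
#' @return An object of class `eeg_montage`: a list with `channels`
#'   (character), `positions` (31 x 3 matrix of unit vectors), `pairs`
#'   (data.frame with columns `left`, `right`), `mirror` (named character
#'   vector mapping each lateral channel to its mirror), `frontal_pairs`,
#'   `parietal_pairs` (character vectors of `"L-R"` pair labels) and
#'   `region_match` (data.frame matching each frontal pair to its parietal
#'   counterpart across the coronal plane).
#' @examples
#' m <- standard_montage()
#' m$frontal_pairs
#' @export
standard_montage <- function() {
  # BESA spherical angles (theta, phi) in degrees for the 31 channels.
  besa <- matrix(c(
    -92, -72,  # FP1
     92,  90,  # FPz
     92,  72,  # FP2
    -92, -36,  # F7
    -60, -51,  # F3
     46,  90,  # Fz
     60,  51,  # F4
     92,  36,  # F8
    -72, -21,  # FC5
    -32, -45,  # FC1
     23,  90,  # FCz
     32,  45,  # FC2
     72,  21,  # FC6
    -92,   0,  # T7
    -45,   0,  # C3
      0,   0,  # Cz
     45,   0,  # C4
    -72,  21,  # CP5
     92,   0,  # T8
    -32,  45,  # CP1
     23, -90,  # CPz
     32, -45,  # CP2
     72, -21,  # CP6
    -92,  36,  # P7
    -60,  51,  # P3
     46, -90,  # Pz
     60, -51,  # P4
     92, -36,  # P8
    -92,  72,  # O1
     92, -90,  # Oz
     92, -72   # O2
  ), ncol = 2, byrow = TRUE)
  channels <- c("FP1", "FPz", "FP2", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FCz", "FC2", "FC6", "T7", "C3", "Cz", "C4",
                "CP5", "T8", "CP1", "CPz", "CP2", "CP6", "P7", "P3", "Pz",
                "P4", "P8", "O1", "Oz", "O2")
  th <- besa[, 1] * pi / 180
  ph <- besa[, 2] * pi / 180
  # theta: inclination from the vertex, signed left (-) / right (+);
  # phi rotates the horizontal component from the ear axis toward the nose.
  s <- ifelse(th < 0, -1, 1)
  x <- sin(abs(th)) * sin(ph * s)
  y <- -s * sin(abs(th)) * cos(ph * s)
  z <- cos(abs(th))
  pos <- cbind(x, y, z)
  pos <- pos / sqrt(rowSums(pos^2))
  rownames(pos) <- channels
  colnames(pos) <- c("x", "y", "z")

  left  <- c("FP1", "F7", "F3", "FC5", "FC1", "T7", "C3", "CP5", "CP1",
             "P7", "P3", "O1")
  right <- c("FP2", "F8", "F4", "FC6", "FC2", "T8", "C4", "CP6", "CP2",
             "P8", "P4", "O2")
  pairs <- data.frame(left = left, right = right, stringsAsFactors = FALSE)
  mirror <- stats::setNames(c(right, left), c(left, right))

  frontal  <- c("F7-F8", "FC5-FC6", "F3-F4", "FC1-FC2")
  parietal <- c("P7-P8", "CP5-CP6", "P3-P4", "CP1-CP2")

  structure(list(
    channels = channels,
    positions = pos,
    pairs = pairs,
    mirror = mirror,
    frontal_pairs = frontal,
    parietal_pairs = parietal,
    region_match = data.frame(frontal = frontal, parietal = parietal,
                              stringsAsFactors = FALSE)
  ), class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channels), " channels, ",
      nrow(x$pairs), " bilateral pairs\n", sep = "")
  invisible(x)
}

pair_label <- function(left, right) paste0(left, "-", right)

# Split a "L-R" pair label into its channel names.
split_pair <- function(label) strsplit(label, "-", fixed = TRUE)[[1]]
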