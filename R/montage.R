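#' Standard wireless-cap montage
#'
#' Channel labels of the 26-electrode 10/20 cap used for dyadic recordings:
#' 24 signal channels, online reference FCz, ground AFz. The signal channels
#' are the ones carried in the data matrices.
#'
#' @format Character vector of 24 channel labels.
#' @export
wbw_montage <- c(
  "Fp1", "Fp2", "F7", "Fz", "F8", "FC1", "FC2", "C3", "Cz", "C4",
  "T7", "T8", "TP9", "TP10", "CP5", "CP1", "CPz", "CP2", "CP6",
  "P3", "Pz", "P4", "O1", "O2"
)

## inclination from vertex (deg) and azimuth from nasion, clockwise to the
## right (deg), on a unit sphere head model
.wbw_angles <- matrix(c(
  92, -18,    # Fp1
  92,  18,    # Fp2
  92, -54,    # F7
  46,   0,    # Fz
  92,  54,    # F8
  32, -45,    # FC1
  32,  45,    # FC2
  46, -90,    # C3
  0,    0,    # Cz
  46,  90,    # C4
  92, -90,    # T7
  92,  90,    # T8
  108, -108,  # TP9
  108,  108,  # TP10
  71, -111,   # CP5
  32, -135,   # CP1
  23,  180,   # CPz
  32,  135,   # CP2
  71,  111,   # CP6
  60, -141,   # P3
  46,  180,   # Pz
  60,  141,   # P4
  92, -162,   # O1
  92,  162    # O2
), ncol = 2, byrow = TRUE,
dimnames = list(wbw_montage, c("incl", "azim")))

#' Unit-sphere electrode positions
#'
#' Cartesian coordinates (x right, y anterior, z superior) of the montage
#' electrodes on a unit-sphere head model, for spherical-spline interpolation
#' and for constructing smooth synthetic scalp topographies.
#'
#' @param labels Channel labels; must be a subset of [wbw_montage].
#' @return Numeric matrix (channels x 3) with rownames.
#' @export
montage_positions <- function(labels = wbw_montage) {
  unknown <- setdiff(labels, rownames(.wbw_angles))
  if (length(unknown)) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  a <- .wbw_angles[labels, , drop = FALSE] * pi / 180
  cbind(
    x = sin(a[, "incl"]) * sin(a[, "azim"]),
    y = sin(a[, "incl"]) * cos(a[, "azim"]),
    z = cos(a[, "incl"])
  ) |> (\(m) { rownames(m) <- labels; m })()
}

#' Smooth scalp topography weights centred on an electrode
#'
#' Gaussian falloff in chord distance on the unit sphere; weight is 1 at the
#' centre electrode. Used by the simulator to spread component amplitudes
#' over the scalp.
#'
#' @param center Channel label at which the weight is 1.
#' @param spread Gaussian width in chord-distance units (sphere radius 1).
#' @param labels Channel labels.
#' @return Named numeric vector of weights in (0, 1].
#' @export
topography_weights <- function(center, spread = 0.9, labels = wbw_montage) {
  pos <- montage_positions(labels)
  ctr <- montage_positions(center)
  d <- sqrt(rowSums((pos - matrix(ctr, nrow(pos), 3, byrow = TRUE))^2))
  w <- exp(-d^2 / (2 * spread^2))
  names(w) <- labels
  w
}
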