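#' Standard 30-channel 10-20 montage
#'
#' Idealized spherical-head positions for the 30-electrode extended 10-20
#' montage used throughout the package. Electrodes sit on a unit sphere;
#' positions are parameterized by inclination from the vertex (Cz) and
#' azimuth measured from the right-ear axis (nose = +y, left ear = -x).
#'
#' @return A data.frame with columns `name`, `x`, `y`, `z` (unit-sphere
#'   Cartesian coordinates, head radius 1).
#' @examples
#' m <- standard_montage()
#' stopifnot(nrow(m) == 30, all(abs(m$x^2 + m$y^2 + m$z^2 - 1) < 1e-12))
#' @export
standard_montage <- function() {
  # name, inclination from vertex (deg), azimuth from right ear (deg)
  tab <- matrix(c(
    "FP1", 92, 108,  "FP2", 92,  72,
    "F7",  92, 144,  "F3",  62, 129,  "Fz",  46,  90,  "F4",  62,  51,  "F8",  92, 36,
    "FC5", 71, 158,  "FC1", 32, 135,  "FC2", 32,  45,  "FC6", 71,  22,
    "C3",  46, 180,  "Cz",   0,   0,  "C4",  46,   0,
    "CP5", 71, -158, "CP1", 32, -135, "CP2", 32, -45,  "CP6", 71, -22,
    "P7",  92, -144, "P3",  62, -129, "Pz",  46, -90,  "P4",  62, -51,  "P8", 92, -36,
    "PO7", 92, -126, "PO3", 78, -112, "POz", 69, -90,  "PO4", 78, -68,  "PO8", 92, -54,
    "O1",  92, -108, "O2",  92, -72
  ), ncol = 3, byrow = TRUE)
  inc <- as.numeric(tab[, 2]) * pi / 180
  azi <- as.numeric(tab[, 3]) * pi / 180
  data.frame(
    name = tab[, 1],
    x = sin(inc) * cos(azi),
    y = sin(inc) * sin(azi),
    z = cos(inc),
    stringsAsFactors = FALSE
  )
}

#' Posterior electrode clusters
#'
#' The three posterior electrode sets used for cluster-averaged ERP
#' statistics: the whole posterior cluster and its left/right halves.
#'
#' @return Named list of character vectors `posterior`, `left`, `right`.
#' @export
electrode_clusters <- function() {
  list(
    posterior = c("P3", "P4", "P7", "P8", "PO3", "PO4", "PO7", "PO8", "O1", "O2"),
    left      = c("P3", "P7", "PO3", "PO7", "O1"),
    right     = c("P4", "P8", "PO4", "PO8", "O2")
  )
}

#' Gaussian topography weights around a peak electrode
#'
#' Channel weights that fall off as a Gaussian of the great-circle angular
#' distance from a peak electrode. Used to give synthetic ERP components a
#' smooth focal scalp distribution; the peak channel has weight 1.
#'
#' @param peak Name of the peak electrode.
#' @param sigma_deg Angular standard deviation of the fall-off, degrees.
#' @param montage Montage data.frame as from [standard_montage()].
#' @return Named numeric vector of weights in (0, 1], one per montage channel.
#' @export
topo_weights <- function(peak, sigma_deg = 30, montage = standard_montage()) {
  i <- match(peak, montage$name)
  if (is.na(i)) stop("unknown peak electrode: ", peak)
  p <- c(montage$x[i], montage$y[i], montage$z[i])
  cosang <- pmin(pmax(as.matrix(montage[, c("x", "y", "z")]) %*% p, -1), 1)
  ang <- acos(cosang) * 180 / pi
  w <- exp(-(ang / sigma_deg)^2 / 2)
  stats::setNames(as.numeric(w), montage$name)
}

angular_cosines <- function(pos_a, pos_b) {
  # pos: n x 3 matrices of unit vectors
  pmin(pmax(pos_a %*% t(pos_b), -1), 1)
}
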