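# Idealized spherical electrode montage (extended 10/20 system).

# Standard 64-channel actiCAP label set.
acticap64_labels <- c(
  "Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9",
  "CP5", "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8",
  "TP10", "CP6", "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4",
  "F8", "Fp2", "AF7", "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1",
  "C5", "TP7", "CP3", "P1", "P5", "PO7", "PO3", "POz", "PO4", "PO8",
  "P6", "P2", "CPz", "CP4", "TP8", "C6", "C2", "FC4", "FT8", "F6",
  "F2", "AF8", "AF4", "Iz"
)

# Reduced 32-channel option retaining both analysis ROIs (P2/P4/PO4 and
# Fz/FC1/FC2) plus an even scalp coverage; used for scaled simulations.
acticap32_labels <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
  "FC6", "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6",
  "P7", "P3", "Pz", "P2", "P4", "P8", "PO3", "POz", "PO4", "O1",
  "Oz", "O2"
)

# Spherical linear interpolation between two unit vectors.
slerp <- function(u, v, f) {
  w <- acos(max(-1, min(1, sum(u * v))))
  if (w < 1e-12) return(u)
  (sin((1 - f) * w) * u + sin(f * w) * v) / sin(w)
}

sph_to_xyz <- function(theta, phi) {
  # theta: polar angle from vertex (deg); phi: azimuth (deg, 0 = right ear
  # direction, 90 = nasion, counterclockwise seen from above).
  t <- deg2rad(theta); p <- deg2rad(phi)
  c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

xyz_to_sph <- function(v) {
  c(theta = rad2deg(acos(max(-1, min(1, v[3])))),
    phi = rad2deg(atan2(v[2], v[1])) %% 360)
}

# Build the idealized position table for the extended 10/20 system.
# Construction: the outer 10% ring (Fpz..Oz through T7/T8) lies at polar
# angle 72 deg with azimuths on an 18 deg grid; midline electrodes step 18 deg
# along the sagittal arc; lateral electrodes are slerped between their row's
# midline and ring electrode at fractions 1/4 (x1), 1/2 (x3), 3/4 (x5);
# the 9/10 electrodes (FT9 etc.) sit 18 deg below their ring neighbours.
build_1020_positions <- function() {
  pos <- list()
  put <- function(label, theta, phi) pos[[label]] <<- sph_to_xyz(theta, phi)

  # Outer ring, left side then right mirror (azimuth measured from +x = right).
  ring_left <- c(Fpz = 90, Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162, T7 = 180,
                 TP7 = 198, P7 = 216, PO7 = 234, O1 = 252, Oz = 270)
  for (nm in names(ring_left)) put(nm, 72, ring_left[[nm]])
  mirror <- c(Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8", T7 = "T8",
              TP7 = "TP8", P7 = "P8", PO7 = "PO8", O1 = "O2")
  for (nm in names(mirror)) put(mirror[[nm]], 72, (180 - ring_left[[nm]]) %% 360)

  # Midline sagittal arc (18 deg steps from the vertex).
  mid <- list(AFz = c(54, 90), Fz = c(36, 90), FCz = c(18, 90), Cz = c(0, 90),
              CPz = c(18, 270), Pz = c(36, 270), POz = c(54, 270))
  for (nm in names(mid)) put(nm, mid[[nm]][1], mid[[nm]][2])

  # Below-ring electrodes.
  put("Iz", 90, 270)
  put("FT9", 90, 162); put("FT10", 90, 18)
  put("TP9", 90, 198); put("TP10", 90, 342)

  # Lateral rows: slerp midline -> ring at 1/4, 1/2, 3/4.
  rows <- list(
    AF = list(mid = "AFz", ringL = "AF7", ringR = "AF8",
              L = c(AF3 = 0.5), R = c(AF4 = 0.5)),
    F  = list(mid = "Fz", ringL = "F7", ringR = "F8",
              L = c(F1 = 0.25, F3 = 0.5, F5 = 0.75),
              R = c(F2 = 0.25, F4 = 0.5, F6 = 0.75)),
    FC = list(mid = "FCz", ringL = "FT7", ringR = "FT8",
              L = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75),
              R = c(FC2 = 0.25, FC4 = 0.5, FC6 = 0.75)),
    C  = list(mid = "Cz", ringL = "T7", ringR = "T8",
              L = c(C1 = 0.25, C3 = 0.5, C5 = 0.75),
              R = c(C2 = 0.25, C4 = 0.5, C6 = 0.75)),
    CP = list(mid = "CPz", ringL = "TP7", ringR = "TP8",
              L = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75),
              R = c(CP2 = 0.25, CP4 = 0.5, CP6 = 0.75)),
    P  = list(mid = "Pz", ringL = "P7", ringR = "P8",
              L = c(P1 = 0.25, P3 = 0.5, P5 = 0.75),
              R = c(P2 = 0.25, P4 = 0.5, P6 = 0.75)),
    PO = list(mid = "POz", ringL = "PO7", ringR = "PO8",
              L = c(PO3 = 0.5), R = c(PO4 = 0.5))
  )
  for (row in rows) {
    for (side in c("L", "R")) {
      ring <- pos[[if (side == "L") row$ringL else row$ringR]]
      fr <- row[[side]]
      for (nm in names(fr)) pos[[nm]] <- slerp(pos[[row$mid]], ring, fr[[nm]])
    }
  }
  pos
}

#' Idealized spherical montage for the 64-channel actiCAP layout
#'
#' Electrode positions on a unit sphere following the extended 10/20 system:
#' the outer 10% ring at 72 degrees polar angle, midline electrodes on an
#' 18 degree sagittal grid, and intermediate electrodes placed by great-circle
#' interpolation. These are idealized template coordinates, not per-subject
#' digitizations.
#'
#' @param channels Number of channels: 64 (full cap) or 32 (reduced option
#'   retaining both analysis ROIs).
#' @param head_radius Scalp sphere radius in cm used by the surface Laplacian.
#' @return An object of class `eeg_montage`: a `data.frame` with columns
#'   `label`, `theta` (polar angle from vertex, degrees), `phi` (azimuth,
#'   degrees, 0 = right preauricular direction, 90 = nasion), `x`, `y`, `z`
#'   (unit-sphere Cartesian), with attribute `head_radius`.
#' @examples
#' mon <- acticap_montage()
#' subset(mon, label %in% c("PO4", "Fz"))
#' @export
acticap_montage <- function(channels = 64, head_radius = 10) {
  channels <- match.arg(as.character(channels), c("64", "32"))
  labels <- if (channels == "64") acticap64_labels else acticap32_labels
  pos <- build_1020_positions()
  xyz <- t(vapply(labels, function(l) pos[[l]], numeric(3)))
  sph <- t(apply(xyz, 1, xyz_to_sph))
  mon <- data.frame(label = labels, theta = sph[, 1], phi = sph[, 2],
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  rownames(mon) <- NULL
  attr(mon, "head_radius") <- head_radius
  class(mon) <- c("eeg_montage", "data.frame")
  mon
}

#' Construct a montage from spherical coordinates
#'
#' @param label Channel labels (unique).
#' @param theta Polar angles from the vertex (degrees).
#' @param phi Azimuths (degrees; 0 = right preauricular direction,
#'   90 = nasion, counterclockwise from above).
#' @param head_radius Scalp sphere radius (cm).
#' @return An `eeg_montage` object (see [acticap_montage()]).
#' @export
make_montage <- function(label, theta, phi, head_radius = 10) {
  if (anyDuplicated(label)) stop("montage labels must be unique", call. = FALSE)
  xyz <- t(mapply(sph_to_xyz, theta, phi))
  mon <- data.frame(label = as.character(label), theta = theta, phi = phi,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  attr(mon, "head_radius") <- head_radius
  class(mon) <- c("eeg_montage", "data.frame")
  mon
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("EEG montage: %d channels on a unit sphere (head radius %g cm)\n",
              nrow(x), attr(x, "head_radius")))
  invisible(x)
}

montage_xyz <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}

# Great-circle (cosine) distances between montage electrodes and a unit vector.
montage_cos_to <- function(montage, v) {
  as.vector(montage_xyz(montage) %*% (v / sqrt(sum(v^2))))
}

# Smooth scalp topography peaked at the mean direction of `center_labels`.
gaussian_topography <- function(montage, center_labels, fwhm = 50) {
  xyz <- montage_xyz(montage)
  idx <- match(center_labels, montage$label)
  if (anyNA(idx)) stop("topography center labels missing from montage", call. = FALSE)
  ctr <- colMeans(xyz[idx, , drop = FALSE])
  ctr <- ctr / sqrt(sum(ctr^2))
  ang <- rad2deg(acos(pmax(-1, pmin(1, as.vector(xyz %*% ctr)))))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-0.5 * (ang / sigma)^2)
  names(w) <- montage$label
  w
}

#' Read / write a montage table
#'
#' Delimited table with columns `label`, `theta`, `phi` (degrees, conventions
#' as in [acticap_montage()]).
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @param head_radius Head radius to attach when reading.
#' @return `read_montage` returns an `eeg_montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(montage[, c("label", "theta", "phi")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path, head_radius = 10) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  make_montage(tab$label, tab$theta, tab$phi, head_radius = head_radius)
}
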