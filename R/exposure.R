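# Solvent accessibility: Shrake-Rupley SASA, relative SASA against
# theoretical maxima, per-state ensemble summaries, and detection of
# residues whose exposure status changes between conformational states.

#' Construct a structure frame
#'
#' A minimal coordinates-plus-annotation container: one row per atom with a
#' van der Waals radius, a residue index in the same 1-based numbering as
#' mutation strings, and a residue type (1-letter code).
#'
#' @param coords n x 3 coordinate matrix, Angstroms.
#' @param radius Per-atom van der Waals radius (Angstroms), or a single
#'   value recycled; defaults to element lookup via `element`.
#' @param residue_index Integer residue id per atom (non-decreasing within
#'   a chain).
#' @param residue_type One-letter residue code per atom (or per residue).
#' @param element Optional element symbol per atom for radius lookup.
#' @return An object of class `structure_frame`.
#' @export
structure_frame <- function(coords, radius = NULL, residue_index,
                            residue_type = NULL, element = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(residue_index))
  if (is.null(radius)) {
    if (is.null(element)) stop("supply radius or element")
    tab <- vdw_radii()
    radius <- unname(tab[element])
    radius[is.na(radius)] <- 1.70
  }
  radius <- rep_len(radius, nrow(coords))
  if (any(radius <= 0)) stop("radii must be positive")
  if (!is.null(residue_type) && length(residue_type) != nrow(coords))
    residue_type <- residue_type[match(residue_index, unique(residue_index))]
  structure(list(coords = coords, radius = radius,
                 residue_index = as.integer(residue_index),
                 residue_type = residue_type),
            class = "structure_frame")
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Places `n_sphere_points` evenly distributed test points (deterministic
#' golden-section spiral) on each atom's solvent-expanded sphere
#' (radius + probe) and counts the points not occluded by any neighboring
#' expanded sphere; the accessible fraction times the expanded-sphere area
#' gives the atomic SASA, summed per residue.
#'
#' @param frame A [structure_frame()].
#' @param probe Probe radius, Angstroms (water = 1.4).
#' @param n_sphere_points Test points per atom (>= 92).
#' @return Named numeric vector of per-residue SASA, Angstrom^2, ordered by
#'   residue index.
#' @export
shrake_rupley_sasa <- function(frame, probe = 1.4, n_sphere_points = 960) {
  stopifnot(inherits(frame, "structure_frame"), n_sphere_points >= 92)
  xyz <- frame$coords
  rr <- frame$radius + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  if (any(d2[upper.tri(d2)] == 0))
    warning("overlapping identical atoms; SASA computed as-is")
  area <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (rr[i] + rr)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    test <- sweep(pts * rr[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dx <- test[, 1] - xyz[j, 1]
      dy <- test[, 2] - xyz[j, 2]
      dz <- test[, 3] - xyz[j, 3]
      acc <- acc & (dx * dx + dy * dy + dz * dz >= rr[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rr[i]^2 * sum(acc) / n_sphere_points
  }
  out <- tapply(area, frame$residue_index, sum)
  out[order(as.integer(names(out)))]
}

#' Relative solvent accessibility and exposure classification
#'
#' `rASA = SASA / SASA_max` with per-residue theoretical maxima (Tien et
#' al. by default) and the inclusive exposure rule `exposed iff
#' rASA >= threshold` (default 0.25). Values slightly above 1 are legal
#' (extended conformations can exceed the theoretical maxima) and flagged,
#' not rejected.
#'
#' @param sasa Per-residue SASA, Angstrom^2.
#' @param sequence One-letter residue codes, same length as `sasa`.
#' @param max_table Named maximum-SASA table; defaults to [tien_max_sasa()].
#' @param threshold Exposure threshold on rASA.
#' @return Data frame with `residue`, `type`, `sasa`, `rasa`, `exposed`.
#' @export
rasa_profile <- function(sasa, sequence, max_table = tien_max_sasa(),
                         threshold = 0.25) {
  if (length(sasa) != length(sequence))
    stop("sequence length does not match SASA vector")
  mx <- max_table[sequence]
  if (anyNA(mx))
    stop("no SASA_max for residue(s): ",
         paste(unique(sequence[is.na(mx)]), collapse = ", "),
         " (supply a custom max_table)")
  rasa <- unname(sasa / mx)
  data.frame(residue = seq_along(sasa), type = sequence,
             sasa = unname(sasa), rasa = rasa,
             exposed = rasa >= threshold)
}

#' Ensemble-mean relative accessibility per residue
#'
#' Computes the per-frame rASA profile for every frame of a state ensemble
#' and averages it (mode `"mean"`), optionally also reporting the fraction
#' of frames in which each residue is exposed (mode `"fraction"` thresholds
#' per frame instead of thresholding the mean).
#'
#' @param frames List of [structure_frame()]s (one conformational state).
#' @param sequence One-letter codes per residue.
#' @param max_table,threshold,probe,n_sphere_points See
#'   [rasa_profile()] / [shrake_rupley_sasa()].
#' @param mode `"mean"` (average rASA, then threshold) or `"fraction"`
#'   (exposed in >= 50 % of frames).
#' @return Data frame with `residue`, `mean_rasa`, `frac_exposed`,
#'   `exposed`.
#' @export
state_exposure_summary <- function(frames, sequence,
                                   max_table = tien_max_sasa(),
                                   threshold = 0.25, probe = 1.4,
                                   n_sphere_points = 960,
                                   mode = c("mean", "fraction")) {
  mode <- match.arg(mode)
  stopifnot(length(frames) >= 1)
  profs <- vapply(frames, function(fr)
    rasa_profile(shrake_rupley_sasa(fr, probe, n_sphere_points),
                 sequence, max_table, threshold)$rasa,
    numeric(length(sequence)))
  profs <- matrix(profs, nrow = length(sequence))
  mean_rasa <- rowMeans(profs)
  frac <- rowMeans(profs >= threshold)
  exposed <- if (mode == "mean") mean_rasa >= threshold else frac >= 0.5
  data.frame(residue = seq_along(sequence), mean_rasa = mean_rasa,
             frac_exposed = frac, exposed = exposed)
}

#' Residues changing exposure status between two states
#'
#' `newly_exposed` holds residues buried in the native profile
#' (rASA < threshold) and exposed in the comparison profile
#' (rASA >= threshold); `newly_buried` is the reverse. This is the
#' native-to-intermediate threshold-crossing analysis used to locate
#' unfolding-exposed regions.
#'
#' @param native,other Equal-length per-residue mean rASA vectors.
#' @param threshold Exposure threshold (default 0.25).
#' @return An `exposure_change` list with integer sets `newly_exposed` and
#'   `newly_buried` (disjoint by construction).
#' @export
exposure_change <- function(native, other, threshold = 0.25) {
  if (length(native) != length(other))
    stop("profiles have different lengths")
  structure(list(
    newly_exposed = which(native < threshold & other >= threshold),
    newly_buried = which(other < threshold & native >= threshold)),
    class = "exposure_change")
}
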