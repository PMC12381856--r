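# Physical constants and bundled reference tables.

R_GAS <- 8.314            # J mol-1 K-1
PLANCK <- 6.62607015e-34  # J s
BOLTZMANN <- 1.380649e-23 # J K-1

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Theoretical maximum solvent-accessible surface areas
#'
#' Per-residue theoretical maximum SASA values (Tien et al. 2013,
#' PLoS ONE 8:e80635), in square Angstroms, used as the denominator of the
#' relative solvent accessibility rASA = SASA / SASA_max.
#'
#' @return Named numeric vector over the 20 standard one-letter residue codes.
#' @export
tien_max_sasa <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
}

#' Bundled hydrophobicity scales
#'
#' Two classical per-residue hydrophobicity scales used for surface
#' hydrophobicity accounting: Kyte-Doolittle (1982) and the Eisenberg
#' consensus scale (1984). Values are on the scales' native units; callers
#' min-max normalize before summing (see
#' [surface_hydrophobicity_change()]).
#'
#' @param name `"kyte_doolittle"` or `"eisenberg"`.
#' @return Named numeric vector over the 20 standard residues.
#' @export
hydrophobicity_scale <- function(name = c("kyte_doolittle", "eisenberg")) {
  name <- match.arg(name)
  switch(name,
    kyte_doolittle = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
    eisenberg = c(
      A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
      E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
      M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
      Y = 0.26, V = 1.08))
}

#' Van der Waals radii by element
#'
#' Bondi (1964) van der Waals radii in Angstroms for the elements common in
#' protein structures; unlisted elements fall back to 1.70 (carbon).
#'
#' @return Named numeric vector.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

# Evenly distributed unit sphere points (deterministic golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
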