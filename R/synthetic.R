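# Synthetic-data generators. Every input class the pipeline consumes can be
# generated with known ground truth, so each analysis stage is testable as a
# round trip. All generators are bit-reproducible given (parameters, seed)
# and store their ground truth alongside the data.

#' Default ground-truth kinetic parameters for simulations
#'
#' Chosen once so that simulated DSC peaks fall near 330-340 K with
#' scan-rate shifts of 1-3 K across 0.5-2 K/min — the qualitative signature
#' of kinetically controlled dehalogenase unfolding — with all heat
#' assigned to the first step (the constraint that fits such data best).
#'
#' @return A [kinetic_params()] object.
#' @export
default_truth_params <- function() {
  kinetic_params(ea1 = 400, tstar1 = 337, ea2 = 300, tstar2 = 342,
                 dh1 = 450, dh2 = 0)
}

default_spectro_baselines <- function(technique) {
  switch(technique,
    DSF_BCM = matrix(c(330, 0.01, 345, 0.02, 350, 0.03), 3, 2, byrow = TRUE),
    CD = matrix(c(-20, 0.01, -10, 0.02, -2, 0.01), 3, 2, byrow = TRUE),
    ISOTHERMAL = matrix(c(1, 0, 0.45, 0, 0.05, 0), 3, 2, byrow = TRUE),
    stop("no default baselines for ", technique))
}

#' Simulate multi-technique, multi-scan-rate melt curves
#'
#' Forward-models each technique over [propagate_scan()] fractions
#' ([dsc_signal()] for DSC, [spectro_signal()] otherwise) and adds i.i.d.
#' Gaussian noise scaled to the curve amplitude. The default scan-rate set
#' is 0.5, 1 and 2 K/min.
#'
#' @param truth Ground-truth [kinetic_params()].
#' @param scan_rates Scan rates, K/min.
#' @param techniques Subset of `"DSC"`, `"DSF_BCM"`, `"CD"`.
#' @param noise_sd Noise standard deviation as a fraction of each curve's
#'   amplitude.
#' @param seed RNG seed.
#' @param t_range Scan window, K.
#' @param n_points Points per curve.
#' @return List of [experiment_curve()]s with attributes `truth` and
#'   `seed`.
#' @export
gen_thermal_datasets <- function(truth = default_truth_params(),
                                 scan_rates = c(0.5, 1, 2),
                                 techniques = c("DSC", "DSF_BCM", "CD"),
                                 noise_sd = 0.02, seed = 1,
                                 t_range = c(293.15, 368.15),
                                 n_points = 151) {
  stopifnot(all(scan_rates > 0))
  techniques <- match.arg(techniques, c("DSC", "DSF_BCM", "CD"),
                          several.ok = TRUE)
  with_seed(seed, {
    curves <- list()
    for (tech in techniques) for (v in scan_rates) {
      fr <- propagate_scan(truth, t_range[1], t_range[2], v,
                           n_grid = n_points)
      base <- if (tech == "DSC") NULL else default_spectro_baselines(tech)
      y <- if (tech == "DSC") dsc_signal(truth, fr, v)
           else spectro_signal(fr, base)
      amp <- max(diff(range(y)), .Machine$double.eps)
      y <- y + stats::rnorm(length(y), 0, noise_sd * amp)
      curves[[length(curves) + 1]] <-
        experiment_curve(tech, fr$grid, y, scan_rate = v,
                         baseline_params = base)
    }
    structure(curves, truth = truth, seed = seed, noise_sd = noise_sd)
  })
}

#' Simulate isothermal unfolding traces
#'
#' Spectroscopic-type signals over the analytic [propagate_isothermal()]
#' fractions at a set of hold temperatures spanning the unfolding range
#' (default 323.15-353.15 K, i.e. 50-80 degrees Celsius), plus Gaussian
#' noise.
#'
#' @param truth Ground-truth [kinetic_params()].
#' @param temps Hold temperatures, K (within 273-380 K).
#' @param duration Trace length(s), min; recycled along `temps`. The
#'   default durations are rate-matched to the default hold temperatures —
#'   hours at the low end, a one-minute temperature-jump-style acquisition
#'   at the high end — so each trace actually resolves its kinetics.
#' @param n_points Points per trace.
#' @param noise_sd Fraction-of-amplitude noise level.
#' @param seed RNG seed.
#' @return List of `ISOTHERMAL` [experiment_curve()]s with attribute
#'   `truth`.
#' @export
gen_isothermal_traces <- function(truth = default_truth_params(),
                                  temps = c(323.15, 338.15, 353.15),
                                  duration = c(240, 60, 1), n_points = 121,
                                  noise_sd = 0.02, seed = 1) {
  stopifnot(all(temps >= 273 & temps <= 380))
  duration <- rep_len(duration, length(temps))
  base <- default_spectro_baselines("ISOTHERMAL")
  with_seed(seed, {
    curves <- Map(function(tt, dur) {
      times <- seq(0, dur, length.out = n_points)
      fr <- propagate_isothermal(truth, tt, times)
      y <- spectro_signal(fr, base)
      amp <- max(diff(range(y)), .Machine$double.eps)
      y <- y + stats::rnorm(length(y), 0, noise_sd * amp)
      experiment_curve("ISOTHERMAL", times, y, hold_temperature = tt,
                       baseline_params = base)
    }, temps, duration)
    structure(curves, truth = truth, seed = seed, noise_sd = noise_sd)
  })
}

#' Simulate hidden-Markov RMSD feature series with known macrostates
#'
#' Samples macrostate trajectories from a row-stochastic transition matrix
#' (initial states drawn from its stationary distribution) and emits
#' Gaussian RMSD values per state.
#'
#' @param macro_T Row-stochastic macrostate transition matrix.
#' @param emissions Matrix with one row per state: columns (mean, sd) in
#'   Angstroms; means must be distinct.
#' @param n_traj,n_frames Number and length of trajectories.
#' @param seed RNG seed.
#' @return List: `series` (a `feature_series`), `labels` (per-trajectory
#'   true macrostate vectors), `macro_T`, `stationary`.
#' @export
gen_markov_feature_series <- function(macro_T, emissions, n_traj = 1,
                                      n_frames = 1000, seed = 1) {
  macro_T <- as.matrix(macro_T)
  if (max(abs(rowSums(macro_T) - 1)) > 1e-8)
    stop("macro_T must be row-stochastic")
  if (anyDuplicated(emissions[, 1])) stop("emission means must be distinct")
  n_state <- nrow(macro_T)
  e <- eigen(t(macro_T))
  pi_ <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_ <- abs(pi_) / sum(abs(pi_))
  with_seed(seed, {
    labels <- lapply(seq_len(n_traj), function(i) {
      s <- integer(n_frames)
      s[1] <- sample.int(n_state, 1, prob = pi_)
      for (t in seq_len(n_frames - 1))
        s[t + 1] <- sample.int(n_state, 1, prob = macro_T[s[t], ])
      s
    })
    series <- lapply(labels, function(s)
      stats::rnorm(length(s), emissions[s, 1], emissions[s, 2]))
    list(series = structure(series, frame_interval_ns = 1,
                            residue_range = c(12, 285),
                            class = "feature_series"),
         labels = labels, macro_T = macro_T, stationary = pi_)
  })
}

#' Generate a toy coordinate ensemble with planted exposure changes
#'
#' One-bead-per-residue conformers on a compact cubic-lattice blob. In the
#' compact state the planted patch residues are the innermost beads
#' (sequestered behind a shell of neighbors); in the opened state they are
#' translated far outside the blob, mimicking local unfolding. Gaussian
#' coordinate jitter distinguishes frames. The planted patch is the ground
#' truth `newly_exposed` set for [exposure_change()].
#'
#' @param n_residues Number of beads (>= 10).
#' @param n_patch Number of planted core residues that unbury.
#' @param jitter_sd Per-axis coordinate jitter, Angstroms.
#' @param n_frames Frames per state.
#' @param seed RNG seed.
#' @param bead_radius Bead van der Waals radius, Angstroms.
#' @param spacing Lattice spacing, Angstroms.
#' @return List: `compact` and `open` (lists of [structure_frame()]s),
#'   `newly_exposed` (planted residue indices), `sequence` (all `"A"` by
#'   bead-radius convention), `max_table` (isolated-bead SASA maxima for
#'   rASA on the toy geometry).
#' @export
gen_toy_ensemble <- function(n_residues = 60, n_patch = 4, jitter_sd = 0.1,
                             n_frames = 10, seed = 1, bead_radius = 3.0,
                             spacing = 4.5) {
  stopifnot(n_residues >= 10, n_patch >= 1, n_patch < n_residues / 2)
  g <- 6L # grid half-width; plenty for the sizes used here
  ax <- seq(-g, g) * spacing
  lattice <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  lattice <- lattice[order(rowSums(lattice^2)), ]
  if (nrow(lattice) < n_residues) stop("lattice too small for n_residues")
  coords <- lattice[seq_len(n_residues), ]
  # patch = innermost beads; remaining beads keep the blob closed around them
  patch <- seq_len(n_patch)
  open_coords <- coords
  rmax <- sqrt(max(rowSums(coords^2)))
  open_coords[patch, ] <- cbind(rmax + 20 + seq_len(n_patch) * 4 * bead_radius,
                                0, 0)
  mk_frames <- function(base) lapply(seq_len(n_frames), function(i)
    structure_frame(base + matrix(stats::rnorm(length(base), 0, jitter_sd),
                                  ncol = 3),
                    radius = bead_radius,
                    residue_index = seq_len(n_residues)))
  with_seed(seed, {
    compact <- mk_frames(coords)
    open <- mk_frames(open_coords)
    iso <- 4 * pi * (bead_radius + 1.4)^2
    list(compact = compact, open = open, newly_exposed = patch,
         sequence = rep("A", n_residues),
         max_table = c(A = iso))
  })
}

#' Generate an aggregation profile, sequence and mutation strings with
#' planted APRs
#'
#' Background scores are drawn well below the APR threshold and planted
#' ranges well above it, so [segment_aprs()] recovers the plant exactly.
#' Optionally emits mutation strings guaranteed to validate against the
#' generated sequence.
#'
#' @param n_residues Sequence length.
#' @param planted_aprs List of length-2 integer ranges (start, end).
#' @param apr_score,background Mean scores inside/outside planted ranges.
#' @param n_mutations Number of mutation tokens to generate (0 for none).
#' @param seed RNG seed.
#' @return List: `profile` (numeric scores), `sequence` (1-letter vector),
#'   `planted` (list of ranges, merged if overlapping), `mutation_string`.
#' @export
gen_profiles_and_sequences <- function(n_residues = 300,
                                       planted_aprs = list(c(160, 185),
                                                           c(260, 280)),
                                       apr_score = 0.6, background = 0.1,
                                       n_mutations = 0, seed = 1) {
  ranges <- lapply(planted_aprs, function(r) sort(as.integer(r[1:2])))
  if (any(unlist(ranges) > n_residues) || any(unlist(ranges) < 1))
    stop("planted range outside the sequence")
  mask <- rep(FALSE, n_residues)
  merged_warn <- FALSE
  for (r in ranges) {
    if (any(mask[r[1]:r[2]])) merged_warn <- TRUE
    mask[r[1]:r[2]] <- TRUE
  }
  if (merged_warn) warning("overlapping planted ranges merged")
  r2 <- rle(mask)
  ends <- cumsum(r2$lengths); starts <- ends - r2$lengths + 1
  planted <- Map(c, starts[r2$values], ends[r2$values])
  with_seed(seed, {
    profile <- ifelse(mask,
                      apr_score + stats::runif(n_residues, -0.1, 0.1),
                      background + stats::runif(n_residues, -0.05, 0.05))
    sequence <- sample(AMINO_ACIDS, n_residues, replace = TRUE)
    mutation_string <- ""
    if (n_mutations > 0) {
      pos <- sort(sample.int(n_residues, n_mutations))
      muts <- vapply(pos, function(p)
        sample(setdiff(AMINO_ACIDS, sequence[p]), 1), character(1))
      mutation_string <- paste(sprintf("%s%d%s", sequence[pos], pos, muts),
                               collapse = " + ")
    }
    list(profile = profile, sequence = sequence, planted = planted,
         mutation_string = mutation_string)
  })
}
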