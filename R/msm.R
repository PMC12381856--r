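# Markov state modeling of unfolding trajectories from a 1-D C-alpha RMSD
# feature: Kabsch superposition, microstate clustering, MSM estimation,
# PCCA-style coarse graining into folded / intermediate / unfolded
# macrostates, and per-state structural statistics.

#' Optimal (Kabsch) superposition of one coordinate set onto another
#'
#' Least-squares rigid-body superposition via singular value decomposition
#' of the covariance matrix, with the determinant correction that excludes
#' improper rotations.
#'
#' @param frame,reference n x 3 coordinate matrices with matching rows.
#' @return List with `coords` (superposed frame) and `rmsd` (Angstroms).
#' @export
kabsch_superpose <- function(frame, reference) {
  stopifnot(is.matrix(frame), is.matrix(reference),
            ncol(frame) == 3, ncol(reference) == 3)
  if (nrow(frame) != nrow(reference))
    stop("atom-count mismatch: frame has ", nrow(frame),
         " atoms, reference ", nrow(reference))
  fc <- scale(frame, scale = FALSE)
  rc <- scale(reference, scale = FALSE)
  s <- svd(crossprod(fc, rc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- fc %*% rot
  aligned <- sweep(aligned, 2, attr(rc, "scaled:center"), "+")
  list(coords = aligned,
       rmsd = sqrt(mean(rowSums((aligned - reference)^2))))
}

#' C-alpha RMSD feature series against a reference structure
#'
#' Superposes each frame onto the reference (rotation + translation,
#' least squares) over the selected atoms before computing the RMSD, so the
#' result is invariant to rigid motion of the frames. The default residue
#' range 12-285 excludes the flexible termini of the dehalogenase fold.
#'
#' @param trajectories A list of trajectories; each trajectory is a list of
#'   n x 3 coordinate matrices (or a single such list for one trajectory).
#' @param reference n x 3 reference coordinates.
#' @param selection Optional row (atom) indices used for superposition and
#'   RMSD, e.g. the C-alpha atoms of residues 12-285.
#' @param frame_interval_ns Time between frames, ns (metadata).
#' @param residue_range Length-2 residue range recorded as metadata.
#' @return A `feature_series` object: list of numeric RMSD vectors
#'   (Angstroms), one per trajectory.
#' @export
kabsch_rmsd_series <- function(trajectories, reference, selection = NULL,
                               frame_interval_ns = 1,
                               residue_range = c(12, 285)) {
  if (is.matrix(trajectories[[1]])) trajectories <- list(trajectories)
  ref <- if (is.null(selection)) reference else reference[selection, , drop = FALSE]
  series <- lapply(trajectories, function(traj)
    vapply(traj, function(fr) {
      f <- if (is.null(selection)) fr else fr[selection, , drop = FALSE]
      kabsch_superpose(f, ref)$rmsd
    }, numeric(1)))
  structure(series, frame_interval_ns = frame_interval_ns,
            residue_range = residue_range, class = "feature_series")
}

#' Cluster a 1-D feature series into microstates
#'
#' k-means in one dimension, deterministic given the seed. Cluster indices
#' are relabeled so centers are ascending, which makes microstate 1 the
#' most native-like.
#'
#' @param series A `feature_series` (or list of numeric vectors).
#' @param k Number of microstates.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return A `microstate_model`: `centers` (ascending), `assignments`
#'   (per-trajectory integer vectors), `k`, `wcss` (within-cluster SSQ).
#' @export
cluster_features <- function(series, k, seed = 1, nstart = 10) {
  vals <- unlist(series, use.names = FALSE)
  if (k > length(vals)) stop("k exceeds the number of frames")
  # Hartigan-Wong; its Quick-TRANSfer warning on duplicate-dense 1-D data
  # signals early stopping of a refinement stage, not an invalid result
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(vals, centers = k, nstart = nstart, iter.max = 200)))
  ord <- order(km$centers)
  relabel <- match(seq_len(k), ord)
  assign_flat <- relabel[km$cluster]
  lens <- vapply(series, length, integer(1))
  idx <- cumsum(c(0, lens))
  assignments <- lapply(seq_along(series), function(i)
    assign_flat[(idx[i] + 1):idx[i + 1]])
  structure(list(centers = sort(as.vector(km$centers)),
                 assignments = assignments, k = k,
                 wcss = km$tot.withinss),
            class = "microstate_model")
}

# Normalize assignments input to a list of integer vectors.
as_assignment_list <- function(assignments) {
  if (inherits(assignments, "microstate_model")) return(assignments$assignments)
  if (!is.list(assignments)) list(as.integer(assignments))
  else lapply(assignments, as.integer)
}

#' Estimate a Markov state model from discrete assignments
#'
#' Sliding-window transition counts at the given lag (trajectory boundaries
#' respected), restricted to the largest strongly connected set of states,
#' row-normalized. The stationary distribution is the leading left
#' eigenvector. The default estimator is non-reversible; `reversible = TRUE`
#' symmetrizes the count matrix (a detailed-balance-enforcing variant).
#'
#' @param assignments A `microstate_model`, an integer vector, or a list of
#'   per-trajectory integer vectors.
#' @param lag Lag time in frames (>= 1).
#' @param reversible Symmetrize counts before normalizing.
#' @return An `msm` object: `transition_matrix`, `stationary`, `states`
#'   (original labels of the retained strongly connected states), `counts`,
#'   `lag`.
#' @export
build_msm <- function(assignments, lag = 1, reversible = FALSE) {
  stopifnot(lag >= 1)
  trajs <- as_assignment_list(assignments)
  states <- sort(unique(unlist(trajs)))
  n <- length(states)
  C <- matrix(0, n, n, dimnames = list(states, states))
  for (tr in trajs) {
    m <- match(tr, states)
    if (length(m) > lag) {
      from <- m[seq_len(length(m) - lag)]
      to <- m[-seq_len(lag)]
      tab <- table(factor(from, levels = seq_len(n)),
                   factor(to, levels = seq_len(n)))
      C <- C + unclass(tab)
    }
  }
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  largest <- which(comp$membership == which.max(comp$csize))
  if (length(largest) < 2)
    stop("disconnected data: fewer than 2 strongly connected states")
  C <- C[largest, largest, drop = FALSE]
  states <- states[largest]
  if (reversible) C <- (C + t(C)) / 2
  P <- C / rowSums(C)
  e <- eigen(t(P))
  i1 <- which.min(abs(e$values - 1))
  pi_ <- Re(e$vectors[, i1])
  pi_ <- abs(pi_) / sum(abs(pi_))
  structure(list(transition_matrix = P, stationary = pi_, states = states,
                 counts = C, lag = lag, reversible = reversible),
            class = "msm")
}

#' Coarse-grain an MSM into labeled macrostates
#'
#' PCCA-style spectral grouping: microstates are embedded in the top
#' `n_macro` right eigenvectors of the transition matrix and grouped by
#' seeded k-means. Macrostates are labeled by their stationary-weighted
#' mean feature value (folded = lowest mean RMSD, unfolded = highest). With
#' `n_macro = 4` the two middle states are merged into a single
#' intermediate, so the output always has the three states
#' folded / intermediate / unfolded.
#'
#' @param msm An [build_msm()] result.
#' @param n_macro 3 or 4 metastable sets to resolve before merging.
#' @param micro_means Feature (mean RMSD, Angstrom) per microstate, named or
#'   ordered by the original microstate labels in `msm$states`.
#' @param seed Seed for the spectral k-means.
#' @return A `macrostate_model`: `macro_of_micro` (1 = folded, 2 =
#'   intermediate, 3 = unfolded per retained microstate), `labels`,
#'   `mean_rmsd`, `populations`, `transition_matrix` (flux-aggregated),
#'   `flags`.
#' @export
coarse_grain_label <- function(msm, n_macro = 3, micro_means, seed = 1) {
  stopifnot(inherits(msm, "msm"), n_macro %in% c(3, 4))
  P <- msm$transition_matrix
  if (nrow(P) < n_macro) stop("fewer connected microstates than macrostates")
  means <- if (!is.null(names(micro_means)))
    micro_means[as.character(msm$states)] else micro_means[msm$states]
  e <- eigen(P)
  ord <- order(-Mod(e$values))
  flags <- character(0)
  lam <- Mod(e$values[ord])
  if (nrow(P) > n_macro && abs(lam[n_macro] - lam[n_macro + 1]) < 1e-10)
    flags <- c(flags, "degenerate_spectral_gap") # tie broken by index order
  emb <- Re(e$vectors[, ord[seq_len(n_macro)], drop = FALSE])
  emb <- scale(emb, center = FALSE,
               scale = apply(abs(emb), 2, max) + 1e-300)
  km <- with_seed(seed, stats::kmeans(emb, centers = n_macro, nstart = 25,
                                      iter.max = 200))
  grp <- km$cluster
  pi_ <- msm$stationary
  gmean <- vapply(seq_len(n_macro), function(g)
    sum(pi_[grp == g] * means[grp == g]) / sum(pi_[grp == g]), numeric(1))
  grp <- match(grp, order(gmean))          # 1 = lowest mean RMSD
  if (n_macro == 4) grp[grp == 3] <- 2     # merge the two middle states
  grp[grp == 4] <- 3
  labels <- c("folded", "intermediate", "unfolded")
  mean_rmsd <- vapply(1:3, function(g)
    sum(pi_[grp == g] * means[grp == g]) / sum(pi_[grp == g]), numeric(1))
  pops <- vapply(1:3, function(g) sum(pi_[grp == g]), numeric(1))
  Tm <- matrix(0, 3, 3, dimnames = list(labels, labels))
  for (a in 1:3) for (b in 1:3)
    Tm[a, b] <- sum(pi_[grp == a] * P[grp == a, grp == b, drop = FALSE]) /
      sum(pi_[grp == a])
  structure(list(macro_of_micro = stats::setNames(grp, msm$states),
                 labels = labels, mean_rmsd = stats::setNames(mean_rmsd, labels),
                 populations = stats::setNames(pops, labels),
                 transition_matrix = Tm, n_macro_requested = n_macro,
                 flags = flags),
            class = "macrostate_model")
}

#' Map per-frame microstate assignments to macrostate labels
#'
#' @param model A [coarse_grain_label()] result.
#' @param assignments Microstate assignments (vector, list, or
#'   `microstate_model`). Frames in microstates dropped from the connected
#'   set get `NA`.
#' @return Integer vector/list of macrostates (1 folded, 2 intermediate,
#'   3 unfolded), same shape as the input.
#' @export
assign_macrostates <- function(model, assignments) {
  trajs <- as_assignment_list(assignments)
  map <- model$macro_of_micro
  out <- lapply(trajs, function(tr) unname(map[as.character(tr)]))
  if (length(out) == 1) out[[1]] else out
}

#' Chapman-Kolmogorov test of Markovianity
#'
#' For each factor f, compares the transition matrix estimated directly at
#' lag `f * lag` with the f-th power of the matrix estimated at `lag`
#' (max-norm deviation over the common state set), alongside a
#' 3-standard-error binomial sampling bound. Both compared matrices are
#' estimates: the bound combines the binomial error of the long-lag matrix
#' with the error of the short-lag matrix propagated through the f-th
#' power, giving `3 sqrt((1 + f) p (1 - p) / n)` at worst-case `p = 1/2`
#' over the row counts of the longer lag.
#'
#' @param assignments Discrete state assignments (vector or list).
#' @param lag Base lag, frames.
#' @param factors Integer multipliers (>= 1).
#' @return Data frame with columns `factor`, `deviation`, `sampling_bound`.
#' @export
ck_test <- function(assignments, lag, factors = c(2, 3, 5)) {
  stopifnot(all(factors >= 1))
  trajs <- as_assignment_list(assignments)
  n_frames <- sum(vapply(trajs, length, integer(1)))
  if (n_frames <= lag * max(factors))
    stop("insufficient frames for lag * max(factor)")
  m1 <- build_msm(trajs, lag = lag)
  out <- lapply(factors, function(f) {
    mf <- build_msm(trajs, lag = lag * f)
    common <- intersect(m1$states, mf$states)
    i1 <- match(common, m1$states); i2 <- match(common, mf$states)
    Ppow <- diag(length(m1$states))
    for (i in seq_len(f)) Ppow <- Ppow %*% m1$transition_matrix
    dev <- max(abs(mf$transition_matrix[i2, i2] - Ppow[i1, i1]))
    rows <- rowSums(mf$counts)[i2]
    bound <- max(3 * sqrt((1 + f) * 0.25 / pmax(rows, 1)))
    data.frame(factor = f, deviation = dev, sampling_bound = bound)
  })
  do.call(rbind, out)
}

#' Per-residue B-factors of a conformational state ensemble
#'
#' Frames are superposed onto the state-mean structure (two-pass: align to
#' the first frame, form the mean, re-align to the mean), then
#' `B_atom = (8 pi^2 / 3) <|r - <r>|^2>` and the residue B-factor is the
#' mean over its backbone atoms.
#'
#' @param frames List of n x 3 coordinate matrices (one state's ensemble).
#' @param residue_index Integer residue id per atom (length n).
#' @param atom_select Optional logical/integer selection of backbone atoms
#'   (C, C-alpha, N, O) among the n atoms; default uses all atoms given.
#' @return Named numeric vector of per-residue B-factors, Angstrom^2 (with
#'   attribute `flag = "degenerate"` for a single-frame state).
#' @export
per_residue_bfactors <- function(frames, residue_index, atom_select = NULL) {
  stopifnot(length(frames) >= 1)
  if (!is.null(atom_select)) {
    frames <- lapply(frames, function(f) f[atom_select, , drop = FALSE])
    residue_index <- residue_index[atom_select]
  }
  if (length(frames) == 1) {
    b <- tapply(rep(0, nrow(frames[[1]])), residue_index, mean)
    warning("single-frame state: zero fluctuation (degenerate)")
    return(structure(b, flag = "degenerate"))
  }
  aligned <- lapply(frames, function(f) kabsch_superpose(f, frames[[1]])$coords)
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(frames, function(f) kabsch_superpose(f, mean_str)$coords)
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  msf <- Reduce(`+`, lapply(aligned, function(f)
    rowSums((f - mean_str)^2))) / length(aligned)
  b_atom <- (8 * pi^2 / 3) * msf
  tapply(b_atom, residue_index, mean)
}

#' Sample representative frames of a state
#'
#' Uniform sampling without replacement, reproducible per seed; if `n` is at
#' least the state size, all frames are returned in index order.
#'
#' @param assignments Integer state assignment per frame (vector or list,
#'   concatenated in order).
#' @param state State whose frames to sample.
#' @param n Number of frames.
#' @param seed RNG seed.
#' @return Sorted integer frame indices (into the concatenated assignment).
#' @export
sample_state_frames <- function(assignments, state, n, seed = 1) {
  flat <- unlist(as_assignment_list(assignments), use.names = FALSE)
  idx <- which(flat == state)
  if (!length(idx)) stop("state ", state, " is empty")
  if (n >= length(idx)) return(idx)
  sort(with_seed(seed, sample(idx, n)))
}
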