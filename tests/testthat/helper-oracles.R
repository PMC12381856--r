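# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: brute-force integration, dynamic programming,
# grid-plus-polish search, and closed forms.

# Explicit-Euler integration of the scan ODE at a fixed fine step.
euler_scan_oracle <- function(params, t0, t1, v, h = 1e-3) {
  k <- function(ea, tstar, tt) exp((ea * 1000 / 8.314) * (1 / tstar - 1 / tt))
  n <- ceiling((t1 - t0) / h)
  grid <- t0 + h * (0:n)
  out <- matrix(0, n + 1, 3)
  out[1, ] <- c(1, 0, 0)
  xn <- 1; xi <- 0
  k2_zero <- is.infinite(params$tstar2)
  for (s in seq_len(n)) {
    tt <- grid[s]
    k1 <- k(params$ea1, params$tstar1, tt)
    k2 <- if (k2_zero) 0 else k(params$ea2, params$tstar2, tt)
    xn_new <- xn - h * k1 * xn / v
    xi <- xi + h * (k1 * xn - k2 * xi) / v
    xn <- xn_new
    out[s + 1, ] <- c(xn, xi, 1 - xn - xi)
  }
  list(grid = grid, fractions = out)
}

# Exact 1-D k-means by dynamic programming (O(k n^2) with prefix sums).
dp_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # cost of one cluster over x[i..j]
  cost <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- cost(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    best <- Inf
    for (i in m:j) {
      c_ <- D[m - 1, i - 1] + cost(i, j)
      if (c_ < best) best <- c_
    }
    D[m, j] <- best
  }
  D[k, n]
}

# Brute-force minimum RMSD over rotations: quaternion grid then local polish
# (independent of the SVD-based Kabsch implementation).
bruteforce_min_rmsd <- function(frame, reference) {
  fc <- scale(frame, scale = FALSE)
  rc <- scale(reference, scale = FALSE)
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((fc %*% t(R) - rc)^2)))
  }
  grid <- as.matrix(expand.grid(w = seq(-1, 1, length.out = 7),
                                x = seq(-1, 1, length.out = 7),
                                y = seq(-1, 1, length.out = 7),
                                z = seq(-1, 1, length.out = 7)))
  grid <- grid[rowSums(grid^2) > 1e-6, ]
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt2 <- stats::optim(opt$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
  min(opt$value, opt2$value)
}

# Closed-form accessible area of two intersecting solvent-expanded spheres
# of equal expanded radius R with center distance d: each sphere loses the
# spherical cap beyond the mid-plane.
two_sphere_accessible_area <- function(radius, probe, d) {
  R <- radius + probe
  full <- 4 * pi * R^2
  cap <- 2 * pi * R * (R - d / 2)
  c(per_atom = full - cap, total = 2 * (full - cap))
}

# Small random rigid structure for superposition tests.
random_structure <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 5), ncol = 3)
}

rotation_matrix_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
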