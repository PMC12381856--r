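# Global fitting of multi-technique thermal denaturation data to the
# three-state irreversible model.
#
# The model separates into nonlinear parameters (Ea1, Tstar1, Ea2, Tstar2),
# which shape the state fractions, and linear parameters (dHcal1, dHcal2 and
# the per-dataset baselines), which scale them. The fit exploits this by
# variable projection: for every trial of the nonlinear quadruple the linear
# coefficients are solved exactly by weighted linear least squares, and only
# the four nonlinear parameters are handed to the bounded Levenberg-Marquardt
# optimizer, restarted from a Latin-hypercube set of initial points.

fit_datasets_check <- function(datasets) {
  ok <- vapply(datasets, inherits, logical(1), "experiment_curve")
  if (!all(ok)) stop("all datasets must be experiment_curve objects")
  keep <- vapply(datasets, function(d) d$technique != "SLS", logical(1))
  if (!all(keep))
    warning("SLS curves report aggregation, not unfolding; dropped from the fit")
  datasets[keep]
}

# Per-dataset inverse-variance weights so techniques with different units
# contribute comparably. Scans: variance of residuals around a linear trend
# through the leading (pre-transition) points. Isothermal traces have no
# pre-transition region (the signal decays from t = 0), so their noise is
# estimated from lag-1 successive differences, which a smooth signal
# contributes little to. Both are floored at 0.1 % of the signal amplitude
# so noiseless data cannot produce infinite weights.
dataset_weights <- function(datasets, scheme) {
  vapply(datasets, function(d) {
    amp <- max(diff(range(d$y)), 1e-12)
    if (scheme == "uniform") return(1 / amp^2)
    v <- if (d$technique == "ISOTHERMAL") {
      mean(diff(d$y, differences = 2)^2) / 6
    } else {
      nb <- max(5L, floor(length(d$x) * 0.15))
      xs <- d$x[seq_len(nb)]; ys <- d$y[seq_len(nb)]
      mean(stats::lm.fit(cbind(1, xs), ys)$residuals^2)
    }
    1 / max(v, (1e-3 * amp)^2)
  }, numeric(1))
}

# Fractions of states for every dataset at the current nonlinear parameters.
fit_fractions <- function(theta, datasets, max_step) {
  p <- kinetic_params(theta[1], theta[2], theta[3], theta[4])
  lapply(datasets, function(d) {
    if (d$technique == "ISOTHERMAL")
      propagate_isothermal(p, d$hold_temperature, d$x)
    else propagate_scan(p, v = d$scan_rate, grid = d$x, max_step = max_step)
  })
}

# Weighted design matrix over all datasets. Columns: global dh1 and/or dh2
# (feeding DSC curves only), then a 6-column per-state linear-baseline block
# per spectroscopic/isothermal dataset.
fit_design <- function(theta, datasets, fracs, free_dh, tref) {
  p <- kinetic_params(theta[1], theta[2], theta[3], theta[4])
  nrow_d <- vapply(datasets, function(d) length(d$x), integer(1))
  off <- c(0L, cumsum(nrow_d))
  blk_w <- vapply(datasets, function(d)
    switch(d$technique, DSC = 0L, ISOTHERMAL = 3L, 6L), integer(1))
  X <- matrix(0, sum(nrow_d), length(free_dh) + sum(blk_w))
  cn <- free_dh
  col_base <- length(free_dh)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]; fr <- fracs[[i]]; rows <- (off[i] + 1):off[i + 1]
    if (d$technique == "DSC") {
      if ("dh1" %in% free_dh)
        X[rows, match("dh1", free_dh)] <-
          rate_constant(p, 1, d$x) * fr$xN / d$scan_rate
      if ("dh2" %in% free_dh)
        X[rows, match("dh2", free_dh)] <-
          rate_constant(p, 2, d$x) * fr$xI / d$scan_rate
    } else if (d$technique == "ISOTHERMAL") {
      # constant per-state signal at fixed temperature: intercepts only
      # (time-slope baselines are near-collinear with the kinetics and
      # destroy the identifiability of the second step)
      X[rows, col_base + 1:3] <- cbind(fr$xN, fr$xI, fr$xD)
      cn <- c(cn, paste0("ds", i, "_", c("aN", "aI", "aD")))
      col_base <- col_base + 3L
    } else {
      dx <- d$x - tref
      blk <- cbind(fr$xN, fr$xN * dx, fr$xI, fr$xI * dx, fr$xD, fr$xD * dx)
      X[rows, col_base + 1:6] <- blk
      cn <- c(cn, paste0("ds", i, "_", c("aN", "bN", "aI", "bI", "aD", "bD")))
      col_base <- col_base + 6L
    }
  }
  colnames(X) <- cn
  X
}

# Projected weighted residuals: solve the linear coefficients by (rank-aware)
# least squares, enforcing dh >= 0 by dropping a negative enthalpy column.
fit_residuals <- function(theta, datasets, w, free_dh, tref, max_step,
                          return_fit = FALSE) {
  fracs <- fit_fractions(theta, datasets, max_step)
  X <- fit_design(theta, datasets, fracs, free_dh, tref)
  y <- unlist(lapply(datasets, `[[`, "y"), use.names = FALSE)
  sw <- sqrt(rep(w, vapply(datasets, function(d) length(d$x), integer(1))))
  solve_ls <- function(Xs) {
    beta <- stats::lm.fit(Xs * sw, y * sw)$coefficients
    beta[is.na(beta)] <- 0
    stats::setNames(beta, colnames(Xs))
  }
  beta <- solve_ls(X)
  neg <- intersect(names(beta)[beta < 0], c("dh1", "dh2"))
  if (length(neg)) { # non-negativity of enthalpies via column dropping
    keep <- setdiff(colnames(X), neg)
    beta_k <- solve_ls(X[, keep, drop = FALSE])
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    beta[keep] <- beta_k
  }
  res <- (y - as.vector(X %*% beta)) * sw
  if (!return_fit) return(res)
  list(residuals = res, beta = beta, X = X, sw = sw, y = y, fracs = fracs)
}

#' Global fit of thermal unfolding data to the three-state irreversible model
#'
#' Fits DSC, spectroscopic melt curves (two or more scan rates) and optional
#' isothermal traces simultaneously. Kinetic parameters are shared across
#' all datasets; baselines are per dataset. Following the model-selection
#' protocol for kinetically controlled unfolding, the calorimetric enthalpy
#' of one of the two steps can be fixed to zero (`"fix_dh1"`/`"fix_dh2"`),
#' or both constraints tried and the lower-residual fit kept (`"auto"`).
#'
#' @param datasets List of [experiment_curve()] objects (SLS curves are
#'   dropped with a warning).
#' @param init Optional [kinetic_params()] starting point, always included
#'   among the optimization starts.
#' @param constraint `"auto"`, `"fix_dh1"`, `"fix_dh2"` or `"none"`.
#' @param weights `"invvar"` (per-dataset inverse variance of pre-transition
#'   residuals, so techniques with different units contribute comparably) or
#'   `"uniform"` (amplitude-normalized).
#' @param n_starts Number of Latin-hypercube starting points.
#' @param seed Seed for the Latin-hypercube start design.
#' @param lower,upper Bounds on (Ea1 kJ/mol, Tstar1 K, Ea2 kJ/mol, Tstar2 K).
#' @param tref Baseline reference temperature, K.
#' @param max_step Propagator internal step, K.
#' @return An object of class `fit_result`: `params` ([kinetic_params()]
#'   with fitted enthalpies), `baselines` (per-dataset coefficients), `rss`
#'   (weighted residual sum of squares), `stderr` (per-parameter standard
#'   errors from the Jacobian, `NA` if rank-deficient), `constraint_used`,
#'   `converged` and `flags`.
#' @export
global_fit <- function(datasets, init = NULL,
                       constraint = c("auto", "fix_dh1", "fix_dh2", "none"),
                       weights = c("invvar", "uniform"),
                       n_starts = 20, seed = 1,
                       lower = c(80, 300, 80, 300),
                       upper = c(800, 380, 800, 380),
                       tref = 298.15, max_step = 0.05) {
  constraint <- match.arg(constraint)
  weights <- match.arg(weights)
  datasets <- fit_datasets_check(datasets)
  flags <- character(0)
  rates <- unlist(lapply(datasets, `[[`, "scan_rate"))
  if (length(unique(rates)) < 2) {
    warning("fewer than 2 distinct scan rates: kinetic parameters are ",
            "poorly identifiable; fit proceeds, flagged")
    flags <- c(flags, "identifiability")
  }
  if (constraint == "auto") {
    f1 <- global_fit(datasets, init, "fix_dh1", weights, n_starts, seed,
                     lower, upper, tref, max_step)
    f2 <- global_fit(datasets, init, "fix_dh2", weights, n_starts, seed,
                     lower, upper, tref, max_step)
    best <- if (f1$rss <= f2$rss) f1 else f2
    best$model_selection <- c(fix_dh1 = f1$rss, fix_dh2 = f2$rss)
    return(best)
  }
  free_dh <- switch(constraint, fix_dh1 = "dh2", fix_dh2 = "dh1",
                    none = c("dh1", "dh2"))
  w <- dataset_weights(datasets, weights)

  starts <- with_seed(seed, lhs::randomLHS(n_starts, 4))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  if (!is.null(init)) {
    stopifnot(inherits(init, "kinetic_params"))
    starts <- rbind(c(init$ea1, init$tstar1, init$ea2, init$tstar2), starts)
  }

  obj <- function(th) fit_residuals(th, datasets, w, free_dh, tref, max_step)
  n_res <- sum(vapply(datasets, function(d) length(d$x), integer(1)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = obj,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-11, ptol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) { # ties broken by first index
      best <- list(fit = fit, rss = rss, start = s)
    }
    # an essentially exact fit cannot be improved by further restarts
    if (best$rss < 1e-10 * n_res) break
  }
  if (is.null(best)) stop("all optimization starts failed")
  converged <- best$fit$info %in% 1:4
  if (!converged) flags <- c(flags, "non_convergence")

  th <- best$fit$par
  full <- fit_residuals(th, datasets, w, free_dh, tref, max_step,
                        return_fit = TRUE)
  beta <- full$beta
  dh1 <- if ("dh1" %in% names(beta)) max(0, beta[["dh1"]]) else 0
  dh2 <- if ("dh2" %in% names(beta)) max(0, beta[["dh2"]]) else 0
  params <- kinetic_params(th[1], th[2], th[3], th[4], dh1, dh2)

  # standard errors: Jacobian = [numeric d(res)/d(theta) | weighted design]
  Jnl <- vapply(1:4, function(j) {
    h <- max(1e-6 * abs(th[j]), 1e-6)
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (obj(tp) - obj(tm)) / (2 * h)
  }, numeric(length(full$residuals)))
  J <- cbind(Jnl, -full$X * full$sw)
  p_all <- ncol(J); n_all <- nrow(J)
  stderr <- rep(NA_real_, p_all)
  if (qr(J)$rank == p_all && n_all > p_all) {
    sigma2 <- best$rss / (n_all - p_all)
    covm <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
    if (!is.null(covm)) stderr <- sqrt(pmax(0, diag(covm)))
    else flags <- c(flags, "jacobian_rank_deficient")
  } else flags <- c(flags, "jacobian_rank_deficient")
  names(stderr) <- c("ea1", "tstar1", "ea2", "tstar2", colnames(full$X))

  base_names <- grep("^ds", names(beta), value = TRUE)
  structure(list(params = params,
                 baselines = beta[base_names],
                 rss = best$rss, stderr = stderr,
                 constraint_used = constraint, converged = converged,
                 n_datasets = length(datasets),
                 n_scan_rates = length(unique(rates)),
                 weights = w, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> constraint=%s, weighted rss=%.6g, converged=%s\n",
              x$constraint_used, x$rss, x$converged))
  print(x$params)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
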