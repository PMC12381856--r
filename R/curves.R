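# Experiment curve container, curve-level descriptors and delimited-text IO.

CURVE_TECHNIQUES <- c("DSC", "DSF_BCM", "CD", "SLS", "ISOTHERMAL")

#' One technique's thermal-scan or isothermal trace
#'
#' @param technique One of `"DSC"`, `"DSF_BCM"`, `"CD"`, `"SLS"`
#'   (temperature scans; `x` in K) or `"ISOTHERMAL"` (`x` in minutes).
#' @param x Strictly increasing axis: temperature (K) for scans, time (min)
#'   for isothermal traces.
#' @param y Signal: kJ mol^-1 K^-1 (DSC), nm (DSF barycentric mean), mdeg
#'   (CD), counts (SLS), arbitrary (isothermal).
#' @param scan_rate Scan rate, K/min (scans only).
#' @param hold_temperature Hold temperature, K (isothermal only).
#' @param baseline_params Optional 3 x 2 matrix of per-state linear baseline
#'   coefficients (rows N, I, D) for spectroscopic techniques.
#' @return An object of class `experiment_curve`.
#' @export
experiment_curve <- function(technique, x, y, scan_rate = NULL,
                             hold_temperature = NULL, baseline_params = NULL) {
  technique <- match.arg(technique, CURVE_TECHNIQUES)
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (technique == "ISOTHERMAL") {
    if (is.null(hold_temperature)) stop("isothermal curves need hold_temperature (K)")
    scan_rate <- NULL
  } else {
    if (is.null(scan_rate)) stop(technique, " curves need scan_rate (K/min)")
    hold_temperature <- NULL
  }
  structure(list(technique = technique, x = x, y = y, scan_rate = scan_rate,
                 hold_temperature = hold_temperature,
                 baseline_params = baseline_params),
            class = "experiment_curve")
}

#' @export
print.experiment_curve <- function(x, ...) {
  rate <- if (!is.null(x$scan_rate)) sprintf("scan %.2g K/min", x$scan_rate)
          else sprintf("hold %.2f K", x$hold_temperature)
  cat(sprintf("<experiment_curve> %s, %d points, %s, x in [%.4g, %.4g]\n",
              x$technique, length(x$x), rate, min(x$x), max(x$x)))
  invisible(x)
}

#' Barycentric mean of a fluorescence spectrum
#'
#' `BCM = sum(lambda I) / sum(I)`, the intensity-weighted mean emission
#' wavelength used as the nanoDSF unfolding coordinate.
#'
#' @param wavelengths Wavelengths, nm.
#' @param intensities Non-negative intensities, not all zero.
#' @return Barycentric mean, nm.
#' @export
bcm_from_spectrum <- function(wavelengths, intensities) {
  stopifnot(length(wavelengths) == length(intensities))
  if (any(intensities < 0)) stop("intensities must be non-negative")
  s <- sum(intensities)
  if (s == 0) stop("barycentric mean undefined for an all-zero spectrum")
  sum(wavelengths * intensities) / s
}

#' Mean residue ellipticity from observed ellipticity
#'
#' `MRE = theta_obs * Mw * 100 / (n * c * l)`, the factor 100 arising from
#' the conversion of the molecular weight to mg/dmol.
#'
#' @param theta_obs Measured ellipticity, degrees.
#' @param mw Molecular weight, g/mol.
#' @param n_residues Number of amino acids.
#' @param conc Protein concentration, mg/mL.
#' @param path Cell path length, cm.
#' @return Mean residue ellipticity.
#' @export
mre_convert <- function(theta_obs, mw, n_residues, conc, path) {
  if (any(c(mw, n_residues, conc, path) <= 0))
    stop("mw, n_residues, conc and path must all be positive")
  theta_obs * mw * 100 / (n_residues * conc * path)
}

#' Curve-level descriptors (Tm, Agg_max, onset temperature)
#'
#' * `tm_peak`: temperature of the curve maximum (DSC-style apparent Tm).
#' * `tm_midpoint`: midpoint of a fitted four-parameter logistic
#'   (sigmoid half-amplitude crossing); returns `NA` with a
#'   `"fit_failed"` flag attribute for non-sigmoidal curves.
#' * `agg_max`: maximum signal within `window` (default 293.15-353.15 K,
#'   the 20-80 degrees Celsius SLS window).
#' * `t_onset`: first x where y exceeds the pre-transition baseline mean by
#'   `k_sd` standard deviations (baseline = first `baseline_frac` of points).
#'
#' @param curve An [experiment_curve()].
#' @param metric One of `"tm_peak"`, `"tm_midpoint"`, `"agg_max"`, `"t_onset"`.
#' @param window Length-2 x-window for `agg_max`.
#' @param k_sd Onset threshold in baseline standard deviations.
#' @param baseline_frac Fraction of leading points treated as baseline.
#' @return Scalar in the units of `curve$x` (or `curve$y` for `agg_max`),
#'   possibly with a `flag` attribute.
#' @export
curve_metrics <- function(curve, metric = c("tm_peak", "tm_midpoint",
                                            "agg_max", "t_onset"),
                          window = c(293.15, 353.15), k_sd = 5,
                          baseline_frac = 0.15) {
  stopifnot(inherits(curve, "experiment_curve"))
  metric <- match.arg(metric)
  x <- curve$x; y <- curve$y
  if (length(x) < 5) stop("curve must have at least 5 points")
  switch(metric,
    tm_peak = x[which.max(y)],
    agg_max = {
      sel <- x >= window[1] & x <= window[2]
      if (!any(sel)) stop("agg_max window contains no points")
      max(y[sel])
    },
    t_onset = {
      nb <- max(3L, floor(length(x) * baseline_frac))
      mu <- mean(y[seq_len(nb)]); sdv <- stats::sd(y[seq_len(nb)])
      hit <- which(y > mu + k_sd * sdv)
      hit <- hit[hit > nb]
      if (!length(hit)) structure(NA_real_, flag = "no_onset") else x[hit[1]]
    },
    tm_midpoint = {
      lo <- stats::median(y[seq_len(3)]); hi <- stats::median(y[length(y) - 2:0])
      xm0 <- x[which.min(abs(y - (lo + hi) / 2))]
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(y ~ a + (b - a) / (1 + exp((xm - x) / s)),
                     start = list(a = lo, b = hi, xm = xm0,
                                  s = diff(range(x)) / 20),
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE))),
        error = function(e) NULL)
      if (is.null(fit)) return(structure(NA_real_, flag = "fit_failed"))
      co <- stats::coef(fit)
      if (abs(co[["b"]] - co[["a"]]) < 1e-12)
        return(structure(NA_real_, flag = "fit_failed"))
      unname(co[["xm"]])
    })
}

#' Unfolding reversibility from first and reheat DSC scans
#'
#' `100 * integral(reheat) / integral(first)` by the trapezoid rule, the
#' fraction of refolded protein after heating just past the calorimetric
#' peak. Values above 100 are reported as-is with a `"clipped"` flag.
#'
#' @param first_scan,reheat_scan Baseline-subtracted DSC
#'   [experiment_curve()]s over the same temperature window.
#' @return Reversibility, percent.
#' @export
reversibility_ratio <- function(first_scan, reheat_scan) {
  stopifnot(inherits(first_scan, "experiment_curve"),
            inherits(reheat_scan, "experiment_curve"))
  trap <- function(cv) sum(diff(cv$x) * (head(cv$y, -1) + cv$y[-1]) / 2)
  a1 <- trap(first_scan)
  if (abs(a1) < .Machine$double.eps)
    stop("reversibility undefined: zero first-scan integral")
  r <- 100 * trap(reheat_scan) / a1
  if (r > 100) structure(r, flag = "clipped") else r
}

#' Correlate the SLS aggregation signal with modeled state fractions
#'
#' Min-max normalizes the SLS trace within `window`, propagates the kinetic
#' model at the SLS scan rate, and reports the Pearson correlation of the
#' normalized signal with each of xI, xD and xI + xD. The best-matching
#' species indicates whether aggregation tracks the intermediate or the
#' denatured state.
#'
#' @param params A [kinetic_params()] object.
#' @param v Scan rate of the SLS measurement, K/min.
#' @param sls An SLS [experiment_curve()].
#' @param window Length-2 temperature window covering the transition, K.
#' @return List with `correlations` (named: I, D, `I+D`) and `best_match`;
#'   a constant SLS window yields `NA` correlations and a `flag`.
#' @export
state_fraction_sls_correlation <- function(params, v, sls,
                                           window = range(sls$x)) {
  stopifnot(inherits(sls, "experiment_curve"))
  sel <- sls$x >= window[1] & sls$x <= window[2]
  xs <- sls$x[sel]; ys <- sls$y[sel]
  if (length(xs) < 3) stop("window contains fewer than 3 SLS points")
  if (diff(range(ys)) == 0)
    return(list(correlations = c(I = NA, D = NA, `I+D` = NA),
                best_match = NA_character_, flag = "constant_signal"))
  ys <- (ys - min(ys)) / diff(range(ys))
  fr <- propagate_scan(params, v = v, grid = xs)
  cors <- c(I = stats::cor(ys, fr$xI), D = stats::cor(ys, fr$xD),
            `I+D` = stats::cor(ys, fr$xI + fr$xD))
  list(correlations = cors,
       best_match = names(cors)[which.max(cors)])
}

#' Read and write experiment curves as annotated CSV
#'
#' Curves are stored as two-column CSV (`x`, `y`) preceded by comment
#' headers `#technique=`, and `#scan_rate_C_per_min=` or `#hold_T_C=`.
#' Temperatures are degrees Celsius in files and Kelvin in memory.
#'
#' @param path File path.
#' @return [read_curve()] returns an [experiment_curve()];
#'   [write_curve()] invisibly returns `path`.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) NULL else as.character(sub(".*=", "", m[1]))
  }
  technique <- meta("technique")
  if (is.null(technique)) stop("missing #technique= header in ", path)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (technique == "ISOTHERMAL") {
    experiment_curve(technique, df$x, df$y,
                     hold_temperature = as.numeric(meta("hold_T_C")) + 273.15)
  } else {
    experiment_curve(technique, df$x + 273.15, df$y,
                     scan_rate = as.numeric(meta("scan_rate_C_per_min")))
  }
}

#' @rdname read_curve
#' @param curve An [experiment_curve()] to write.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "experiment_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#technique=", curve$technique), con)
  if (curve$technique == "ISOTHERMAL") {
    writeLines(sprintf("#hold_T_C=%.10g", curve$hold_temperature - 273.15), con)
    x_out <- curve$x
  } else {
    writeLines(sprintf("#scan_rate_C_per_min=%.10g", curve$scan_rate), con)
    x_out <- curve$x - 273.15
  }
  utils::write.csv(data.frame(x = x_out, y = curve$y), con, row.names = FALSE)
  invisible(path)
}
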