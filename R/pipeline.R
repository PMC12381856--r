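# Pipeline orchestration: a single JSON configuration drives the stages
# simulate -> fit-unfolding -> msm -> exposure -> cryptic-apr -> mutations,
# with validated IO, defaulting recorded in a run manifest, and stage gating
# (stages run only when their inputs are available).

pipeline_defaults <- function() {
  list(seed = 1L, output_dir = "crypticfold_out",
       threshold = 0.25, apr_threshold = 0.25,
       min_apr_len = 1L, min_hits = 2L,
       constraint = "auto", n_starts = 20L,
       report_temps_C = c(40, 60, 80),
       lag = 10L, n_micro = 50L, n_macro = 3L)
}

#' Validate a pipeline configuration
#'
#' Reads a JSON configuration (or takes an equivalent list), fills in
#' defaults, and collects all validation errors instead of stopping at the
#' first. Referenced files must exist; thresholds must lie in [0, 1];
#' seeds must be integers.
#'
#' @param config Path to a JSON file or a named list.
#' @return A `pipeline_config` list with `$defaults_applied` recording every
#'   defaulted field. Throws a single error listing all problems if any.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  errors <- character(0)
  defaults <- pipeline_defaults()
  applied <- character(0)
  for (key in c("seed", "output_dir", "threshold", "apr_threshold",
                "min_apr_len", "min_hits", "constraint", "n_starts",
                "report_temps_C", "lag", "n_micro", "n_macro")) {
    if (is.null(config[[key]])) {
      config[[key]] <- defaults[[key]]
      applied <- c(applied, key)
    }
  }
  if (config$seed != round(config$seed))
    errors <- c(errors, "seed: must be an integer")
  for (key in c("threshold", "apr_threshold"))
    if (!is.numeric(config[[key]]) || config[[key]] < 0 || config[[key]] > 1)
      errors <- c(errors, paste0(key, ": must lie within [0, 1]"))
  if (!config$constraint %in% c("auto", "fix_dh1", "fix_dh2", "none"))
    errors <- c(errors, "constraint: must be auto/fix_dh1/fix_dh2/none")
  for (key in c("datasets", "profile", "native_rasa", "fasta", "exposed")) {
    paths <- config[[key]]
    if (is.character(paths))
      for (p in paths) if (!file.exists(p))
        errors <- c(errors, paste0(key, ": file not found: ", p))
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  config$defaults_applied <- applied
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the analysis pipeline from a validated configuration
#'
#' Stages are gated on their inputs: `simulate` (when `config$simulate` is
#' present) generates a full synthetic bundle; `fit_unfolding` runs when
#' curve datasets exist (from files or simulation); `msm` when a feature
#' series exists; `exposure` when state ensembles exist; `cryptic_apr` when
#' a score profile plus an exposed set exist; `mutations` when a mutation
#' string is given. All numeric outputs are deterministic given the config;
#' a JSON manifest beside the outputs records versions, seeds, input
#' digests and every applied default.
#'
#' @param config A [validate_config()] result (or something it accepts).
#' @return Invisibly, a list with `manifest` and per-stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  results <- list()
  manifest <- list(
    package = "crypticfold",
    version = as.character(utils::packageVersion("crypticfold")),
    r_version = as.character(getRversion()),
    seed = seed, defaults_applied = config$defaults_applied,
    stages = character(0), inputs = list())

  datasets <- NULL
  if (is.character(config$datasets)) {
    datasets <- lapply(config$datasets, read_curve)
    manifest$inputs$datasets <-
      as.list(tools::md5sum(config$datasets))
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    noise <- if (is.null(sim$noise_sd)) 0.02 else sim$noise_sd
    truth <- default_truth_params()
    scans <- gen_thermal_datasets(truth, noise_sd = noise, seed = seed)
    iso <- gen_isothermal_traces(truth, noise_sd = noise, seed = seed + 1)
    datasets <- c(scans, iso)
    results$simulate <- list(truth = unclass(truth))
    manifest$stages <- c(manifest$stages, "simulate")
  }

  if (!is.null(datasets)) {
    fit <- global_fit(datasets, constraint = config$constraint,
                      n_starts = config$n_starts, seed = seed)
    bar <- barrier_at(fit$params, config$report_temps_C + 273.15)
    results$fit_unfolding <- list(fit = fit, barriers = bar)
    fit_json <- list(params = unclass(fit$params), rss = fit$rss,
                     constraint_used = fit$constraint_used,
                     converged = fit$converged,
                     barriers = list(temperature_C = config$report_temps_C,
                                     dG1_kJ_mol = bar$dG1, dG2_kJ_mol = bar$dG2))
    jsonlite::write_json(fit_json, file.path(out_dir, "fit_unfolding.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages <- c(manifest$stages, "fit_unfolding")
  }

  if (!is.null(config$simulate) && isTRUE(config$simulate$msm)) {
    macro_T <- matrix(c(0.98, 0.02, 0.00,
                        0.01, 0.98, 0.01,
                        0.00, 0.02, 0.98), 3, 3, byrow = TRUE)
    emissions <- cbind(mean = c(2, 8, 14), sd = c(1, 1, 1))
    hm <- gen_markov_feature_series(macro_T, emissions, n_traj = 4,
                                    n_frames = 5000, seed = seed)
    micro <- cluster_features(hm$series, k = config$n_micro, seed = seed)
    msm <- build_msm(micro, lag = config$lag)
    means <- stats::setNames(micro$centers, seq_len(micro$k))
    macro <- coarse_grain_label(msm, config$n_macro, means, seed = seed)
    results$msm <- macro
    utils::write.csv(data.frame(state = macro$labels,
                                mean_rmsd_A = macro$mean_rmsd,
                                population = macro$populations),
                     file.path(out_dir, "msm_states.csv"), row.names = FALSE)
    manifest$stages <- c(manifest$stages, "msm")
  }

  exposed_set <- NULL
  native_rasa <- NULL
  if (!is.null(config$simulate) && isTRUE(config$simulate$exposure)) {
    toy <- gen_toy_ensemble(seed = seed)
    native <- state_exposure_summary(toy$compact, toy$sequence,
                                     max_table = toy$max_table,
                                     threshold = config$threshold)
    interm <- state_exposure_summary(toy$open, toy$sequence,
                                     max_table = toy$max_table,
                                     threshold = config$threshold)
    ch <- exposure_change(native$mean_rasa, interm$mean_rasa,
                          config$threshold)
    exposed_set <- ch$newly_exposed
    native_rasa <- native$mean_rasa
    results$exposure <- list(change = ch, native = native,
                             intermediate = interm)
    utils::write.csv(data.frame(residue = native$residue,
                                native_rasa = native$mean_rasa,
                                intermediate_rasa = interm$mean_rasa),
                     file.path(out_dir, "exposure.csv"), row.names = FALSE)
    manifest$stages <- c(manifest$stages, "exposure")
  }

  profile <- NULL
  if (is.character(config$profile)) {
    df <- utils::read.csv(config$profile)
    profile <- df$score[order(df$residue_index)]
    manifest$inputs$profile <- as.list(tools::md5sum(config$profile))
  }
  if (is.null(exposed_set) && !is.null(config$exposed)) {
    exposed_set <- if (is.character(config$exposed) &&
                       file.exists(config$exposed[1]))
      utils::read.csv(config$exposed)$residue else as.integer(config$exposed)
  }
  if (is.null(native_rasa) && is.character(config$native_rasa))
    native_rasa <- utils::read.csv(config$native_rasa)$rasa
  if (!is.null(profile) && !is.null(exposed_set)) {
    segs <- segment_aprs(profile, config$apr_threshold, config$min_apr_len)
    rep_ <- overlap_exposed_aprs(exposed_set, segs)
    cryptic <- if (!is.null(native_rasa))
      flag_cryptic_aprs(segs, exposed_set, native_rasa,
                        config$min_hits, config$threshold) else NULL
    results$cryptic_apr <- list(segments = segs, overlap = rep_,
                                cryptic = cryptic)
    jsonlite::write_json(
      list(n_newly_exposed = rep_$n_newly_exposed,
           n_newly_exposed_in_apr = rep_$n_newly_exposed_in_apr,
           fraction_pct = rep_$fraction,
           segments = as.data.frame(segs),
           cryptic = if (is.null(cryptic)) NULL else as.data.frame(cryptic)),
      file.path(out_dir, "cryptic_apr.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages <- c(manifest$stages, "cryptic_apr")
  }

  if (is.character(config$mutation_spec)) {
    seq_ <- if (is.character(config$fasta)) read_fasta(config$fasta) else NULL
    muts <- parse_mutations(config$mutation_spec, seq_)
    results$mutations <- muts
    if (!is.null(native_rasa))
      results$mutation_locations <-
        classify_mutation_locations(muts, native_rasa, config$threshold)
    manifest$stages <- c(manifest$stages, "mutations")
  }

  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results))
}

#' Read the first record of a FASTA file as a 1-letter vector
#'
#' @param path FASTA file path.
#' @return Character vector of residues.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readAAStringSet(path)
    return(strsplit(as.character(s[[1]]), "")[[1]])
  }
  lines <- readLines(path)
  strsplit(paste(lines[!grepl("^>", lines)], collapse = ""), "")[[1]]
}
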