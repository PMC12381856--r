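# Aggregation-prone-region analysis: mutation-string parsing, APR
# segmentation of per-residue aggregation-score profiles, overlap of
# unfolding-exposed residues with APRs (the cryptic-APR statistic), and
# mutation-level surface-hydrophobicity accounting.

#' Parse a mutation string
#'
#' Accepts strings such as `"E20S + F80R + C128F"`; tokens are separated by
#' `+` with optional whitespace, and stray internal spaces inside a token
#' (as in `"D166 K"`) are tolerated. When a sequence is supplied, every
#' wild-type letter is validated against it.
#'
#' @param spec Mutation string (empty string gives an empty list).
#' @param sequence Optional character vector of 1-letter codes (or a single
#'   string) for wild-type validation; positions are 1-based into it.
#' @return A data frame of class `mutation_list` with columns `wt`, `pos`,
#'   `mut`, in token order.
#' @export
parse_mutations <- function(spec, sequence = NULL) {
  if (!is.null(sequence) && length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  spec <- trimws(spec)
  if (identical(spec, "") || is.na(spec))
    return(structure(data.frame(wt = character(), pos = integer(),
                                mut = character()),
                     class = c("mutation_list", "data.frame")))
  tokens <- trimws(strsplit(spec, "+", fixed = TRUE)[[1]])
  parsed <- lapply(tokens, function(tok) {
    tok2 <- gsub("[[:space:]]", "", tok)
    m <- regmatches(tok2, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tok2))[[1]]
    if (length(m) != 4)
      stop("malformed mutation token: '", tok, "'")
    wt <- toupper(m[2]); mut <- toupper(m[4]); pos <- as.integer(m[3])
    if (!(wt %in% AMINO_ACIDS) || !(mut %in% AMINO_ACIDS))
      stop("unknown amino-acid letter in token '", tok, "'")
    list(wt = wt, pos = pos, mut = mut)
  })
  df <- data.frame(wt = vapply(parsed, `[[`, "", "wt"),
                   pos = vapply(parsed, `[[`, 1L, "pos"),
                   mut = vapply(parsed, `[[`, "", "mut"))
  if (!is.null(sequence)) {
    if (any(df$pos > length(sequence)))
      stop("mutation position ", df$pos[df$pos > length(sequence)][1],
           " outside the sequence (length ", length(sequence), ")")
    bad <- which(sequence[df$pos] != df$wt)
    if (length(bad))
      stop("wild-type mismatch at position ", df$pos[bad[1]], ": sequence has ",
           sequence[df$pos[bad[1]]], ", mutation string says ", df$wt[bad[1]])
  }
  structure(df, class = c("mutation_list", "data.frame"))
}

#' Canonical formatting of a mutation list
#'
#' @param mutations A `mutation_list`.
#' @return A single string `"E20S + F80R + ..."` that [parse_mutations()]
#'   round-trips.
#' @export
format_mutations <- function(mutations) {
  paste(sprintf("%s%d%s", mutations$wt, mutations$pos, mutations$mut),
        collapse = " + ")
}

#' Segment an aggregation-score profile into APRs
#'
#' Maximal runs of consecutive residues whose score strictly exceeds the
#' threshold (regions that do not exceed it are non-APR); runs shorter than
#' `min_length` are discarded.
#'
#' @param profile Per-residue aggregation scores (finite numerics).
#' @param threshold Score threshold (default 0.25).
#' @param min_length Minimum segment length.
#' @return Data frame of class `apr_segments` with `start`, `end` (1-based,
#'   inclusive), `peak`, `mean`, sorted by `start`.
#' @export
segment_aprs <- function(profile, threshold = 0.25, min_length = 1) {
  if (any(!is.finite(profile))) stop("scores must be finite")
  above <- profile > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_length
  seg <- data.frame(start = starts[keep], end = ends[keep])
  seg$peak <- mapply(function(s, e) max(profile[s:e]), seg$start, seg$end)
  seg$mean <- mapply(function(s, e) mean(profile[s:e]), seg$start, seg$end)
  structure(seg[order(seg$start), , drop = FALSE],
            class = c("apr_segments", "data.frame"))
}

apr_union <- function(segments) {
  if (!nrow(segments)) return(integer())
  unique(unlist(mapply(seq, segments$start, segments$end,
                       SIMPLIFY = FALSE)))
}

#' Overlap of unfolding-exposed residues with predicted APRs
#'
#' The headline cryptic-aggregation statistic: the percentage of newly
#' exposed residues that fall inside the union of APR segments.
#'
#' @param newly_exposed Integer residue set (e.g. from
#'   [exposure_change()]).
#' @param segments An [segment_aprs()] result.
#' @return List of class `overlap_report`: `n_newly_exposed`,
#'   `n_newly_exposed_in_apr`, `fraction` (percent; `NA` with flag
#'   `"undefined"` for an empty exposed set).
#' @export
overlap_exposed_aprs <- function(newly_exposed, segments) {
  newly_exposed <- unique(as.integer(newly_exposed))
  inside <- intersect(newly_exposed, apr_union(segments))
  frac <- if (!length(newly_exposed)) NA_real_
          else 100 * length(inside) / length(newly_exposed)
  structure(list(n_newly_exposed = length(newly_exposed),
                 n_newly_exposed_in_apr = length(inside),
                 fraction = frac,
                 flag = if (!length(newly_exposed)) "undefined" else NULL),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d / %d newly exposed residues in APRs (%s%%)\n",
              x$n_newly_exposed_in_apr, x$n_newly_exposed,
              if (is.na(x$fraction)) "NA" else sprintf("%.1f", x$fraction)))
  invisible(x)
}

#' Flag cryptic APRs
#'
#' An APR is cryptic when it is buried in the native state (the majority of
#' its residues have native rASA below the threshold) yet contains at least
#' `min_hits` residues that become exposed during unfolding — regions that
#' cannot drive aggregation from the native fold but can once partial
#' unfolding uncovers them.
#'
#' @param segments An [segment_aprs()] result.
#' @param newly_exposed Integer residue set from [exposure_change()].
#' @param native_rasa Per-residue native mean rASA.
#' @param min_hits Minimum newly exposed residues inside the segment.
#' @param threshold rASA burial threshold.
#' @return `segments` with added columns `n_hits`, `buried_majority`,
#'   `cryptic`, restricted to cryptic rows.
#' @export
flag_cryptic_aprs <- function(segments, newly_exposed, native_rasa,
                              min_hits = 2, threshold = 0.25) {
  if (!nrow(segments)) {
    segments$n_hits <- integer(); segments$buried_majority <- logical()
    segments$cryptic <- logical()
    return(segments)
  }
  segments$n_hits <- mapply(function(s, e)
    sum(newly_exposed >= s & newly_exposed <= e),
    segments$start, segments$end)
  segments$buried_majority <- mapply(function(s, e)
    mean(native_rasa[s:e] < threshold) > 0.5,
    segments$start, segments$end)
  segments$cryptic <- segments$n_hits >= min_hits & segments$buried_majority
  segments[segments$cryptic, , drop = FALSE]
}

#' Classify mutation sites as surface or buried
#'
#' A mutation is on the surface when the wild-type structure's native rASA
#' at its position is at least the threshold.
#'
#' @param mutations A `mutation_list`.
#' @param native_rasa Per-residue native rASA profile.
#' @param threshold rASA exposure threshold.
#' @return List with per-mutation `location` (`"surface"`/`"buried"`),
#'   `n_surface`, `n_buried`, `n_total`.
#' @export
classify_mutation_locations <- function(mutations, native_rasa,
                                        threshold = 0.25) {
  if (nrow(mutations) && any(mutations$pos > length(native_rasa)))
    stop("mutation position outside the rASA profile")
  loc <- ifelse(native_rasa[mutations$pos] >= threshold, "surface", "buried")
  list(location = stats::setNames(
         loc, sprintf("%s%d%s", mutations$wt, mutations$pos, mutations$mut)),
       n_surface = sum(loc == "surface"), n_buried = sum(loc == "buried"),
       n_total = length(loc))
}

#' Surface hydrophobicity change caused by a mutation set
#'
#' Sums a min-max-normalized hydrophobicity value over all surface residues
#' (native rASA >= threshold) for the wild-type sequence and for the mutant
#' sequence (residue identities substituted; exposure status held fixed at
#' the wild-type structure), and reports the percent change
#' `100 (H_mut - H_wt) / H_wt`.
#'
#' @param sequence Wild-type sequence (1-letter vector or single string).
#' @param mutations A `mutation_list`.
#' @param native_rasa Per-residue native rASA profile.
#' @param scale Scale name understood by [hydrophobicity_scale()], or a
#'   named numeric vector over the 20 residues.
#' @param threshold rASA exposure threshold.
#' @return List: `percent_change`, `h_wt`, `h_mut`, `scale`.
#' @export
surface_hydrophobicity_change <- function(sequence, mutations, native_rasa,
                                          scale = "kyte_doolittle",
                                          threshold = 0.25) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  scale_name <- if (is.character(scale)) scale else "custom"
  sc <- if (is.character(scale)) hydrophobicity_scale(scale) else scale
  if (!all(AMINO_ACIDS %in% names(sc)))
    stop("scale must provide a value for all 20 residues")
  sc <- (sc - min(sc)) / (max(sc) - min(sc))
  surface <- which(native_rasa >= threshold)
  mut_seq <- sequence
  mut_seq[mutations$pos] <- mutations$mut
  bad <- setdiff(unique(c(sequence[surface], mut_seq[surface])), names(sc))
  if (length(bad)) stop("unknown residue letter: ", paste(bad, collapse = ","))
  h_wt <- sum(sc[sequence[surface]])
  h_mut <- sum(sc[mut_seq[surface]])
  list(percent_change = 100 * (h_mut - h_wt) / h_wt,
       h_wt = h_wt, h_mut = h_mut, scale = scale_name)
}
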