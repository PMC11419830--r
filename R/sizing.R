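#' Size the repeat interval of one spanning molecule
#'
#' The observed distance is measured in the molecule frame between the site
#' paired to the upstream marker and the downstream representative: the site
#' paired to the downstream marker, the site paired to its companion, or —
#' when both resolved — the mean of the two molecule positions (mirroring
#' the averaged reference position used in the corrected reference
#' distance). The expansion size is the observed distance minus the locus's
#' corrected reference distance; because the reference's own repeat units
#' were already subtracted, it equals the molecule's full repeat-tract
#' length in bp (negative values arise from sizing noise on short alleles
#' and are retained).
#'
#' @param alignment An `ogm_alignment` whose pairs include the locus
#'   markers (a member of a spanning set).
#' @param mol The corresponding `ogm_molecule`.
#' @param locus An `ogm_locus`.
#' @return A one-row data frame: `molecule_id`, `observed_distance`,
#'   `expansion_size`, `repeat_estimate` (= expansion / unit length),
#'   `downstream_rep`.
#' @export
size_molecule <- function(alignment, mol, locus) {
  stopifnot(inherits(alignment, "ogm_alignment"),
            inherits(mol, "ogm_molecule"), inherits(locus, "ogm_locus"))
  pr <- alignment$pairs
  q_at <- function(id) {
    k <- match(id, pr$ref_id)
    if (is.na(k)) NA_real_ else mol$positions[pr$qry_site[k]]
  }
  q_up <- q_at(locus$upstream[["id"]])
  q_dn <- q_at(locus$downstream[["id"]])
  q_cp <- if (is.null(locus$companion)) NA_real_ else q_at(locus$companion[["id"]])
  if (is.na(q_up) || (is.na(q_dn) && is.na(q_cp)))
    stop("alignment does not cover both locus markers; ",
         "run select_spanning() first")
  rep_pos <- mean(c(q_dn, q_cp), na.rm = TRUE)
  if (isTRUE(all.equal(q_up, rep_pos)))
    stop("upstream and downstream markers paired to the same molecule site")
  observed <- abs(rep_pos - q_up)
  expansion <- observed - locus$corrected_ref_distance
  data.frame(molecule_id = alignment$molecule_id,
             observed_distance = observed,
             expansion_size = expansion,
             repeat_estimate = expansion / locus$repeat_unit_len,
             downstream_rep = if (!is.na(q_dn) && !is.na(q_cp)) "both"
               else if (!is.na(q_dn)) "downstream" else "companion")
}

#' Size all molecules of a spanning set
#'
#' @param spanning An `ogm_spanning_set` from [select_spanning()].
#' @param molecules The molecule list the alignments refer to.
#' @return Data frame of per-molecule size calls (see [size_molecule()]).
#' @export
size_spanning <- function(spanning, molecules) {
  stopifnot(inherits(spanning, "ogm_spanning_set"))
  locus <- attr(spanning, "locus")
  by_id <- list()
  for (m in molecules) by_id[[as.character(m$molecule_id)]] <- m
  rows <- lapply(spanning, function(a) {
    mol <- by_id[[as.character(a$molecule_id)]]
    if (is.null(mol)) stop("molecule ", a$molecule_id, " not supplied")
    size_molecule(a, mol, locus)
  })
  if (length(rows) == 0)
    return(data.frame(molecule_id = integer(0), observed_distance = numeric(0),
                      expansion_size = numeric(0), repeat_estimate = numeric(0),
                      downstream_rep = character(0)))
  do.call(rbind, rows)
}

#' Convert an expansion size in bp to a repeat count
#'
#' @param size_bp Expansion size(s) in bp.
#' @param unit Repeat unit length in bp (> 0; 3 for CTG).
#' @param mode `"exact"` (real-valued), `"floor"`, or `"nearest_hundred"`
#'   (the reporting convention for large expansions, e.g. 16,803 bp ->
#'   ~5600 repeats).
#' @return Repeat count(s).
#' @export
to_repeats <- function(size_bp, unit = 3,
                       mode = c("exact", "floor", "nearest_hundred")) {
  stopifnot(unit > 0)
  mode <- match.arg(mode)
  r <- size_bp / unit
  switch(mode,
         exact = r,
         floor = floor(r),
         nearest_hundred = round_half_up(r / 100) * 100)
}

#' Bin expansion sizes into a fixed-width histogram
#'
#' Half-open bins `[k*w, (k+1)*w)`; negative sizes fall in negative-k bins.
#' Counts conserve the number of calls.
#'
#' @param sizes Numeric expansion sizes in bp (or a size-call data frame
#'   with an `expansion_size` column).
#' @param bin_width Bin width in bp (> 0; default 200, the reporting
#'   convention).
#' @return Data frame `bin_start`, `bin_mid`, `count`, covering the
#'   occupied range contiguously; zero rows for empty input.
#' @export
histogram_sizes <- function(sizes, bin_width = 200) {
  stopifnot(bin_width > 0)
  if (is.data.frame(sizes)) sizes <- sizes$expansion_size
  if (length(sizes) == 0)
    return(data.frame(bin_start = numeric(0), bin_mid = numeric(0),
                      count = integer(0)))
  k <- floor(sizes / bin_width)
  rng <- seq(min(k), max(k))
  cnt <- tabulate(match(k, rng), nbins = length(rng))
  data.frame(bin_start = rng * bin_width,
             bin_mid = rng * bin_width + bin_width / 2,
             count = as.integer(cnt))
}

#' Per-sample molecule summary
#'
#' Mean and maximum expansion size over all spanning molecules — both
#' alleles pooled, unphased — plus the 200 bp histogram and the fraction of
#' molecules above the expanded-molecule threshold (>2000 bp by default, a
#' descriptive classifier: such molecules are observed exclusively in
#' expansion-positive affected tissue).
#'
#' Single non-clustering molecules far outside the allele clusters are a
#' known artifact of misaligning long repetitive regions with sparse
#' labels; they are retained by default (filtering would bias means), but
#' an optional cluster-support filter can drop molecules whose histogram
#' bin holds fewer than `min_cluster_support` molecules.
#'
#' @param calls Size-call data frame from [size_spanning()].
#' @param sample_id,tissue Sample metadata.
#' @param expanded_threshold Expanded-molecule cutoff in bp.
#' @param bin_width Histogram bin width in bp.
#' @param min_cluster_support If > 0, drop molecules whose support bin
#'   holds fewer than this many molecules (default 0 = keep everything).
#' @param cluster_bin_width Width of the support bins used by the filter
#'   (defaults to `bin_width`; a wider window suits broad mosaic clusters).
#' @return An `ogm_sample_summary`: list with `sample_id`, `tissue`,
#'   `n_molecules`, `mean_size`, `max_size`, `histogram`,
#'   `expanded_fraction` and `expanded_threshold`. With zero calls the mean
#'   and max are `NA` and the summary is flagged (`empty = TRUE`).
#' @export
summarize_sample <- function(calls, sample_id = "sample", tissue = NA_character_,
                             expanded_threshold = 2000, bin_width = 200,
                             min_cluster_support = 0,
                             cluster_bin_width = bin_width) {
  sz <- calls$expansion_size
  if (min_cluster_support > 0 && length(sz) > 0) {
    bin <- floor(sz / cluster_bin_width)
    support <- ave(bin, bin, FUN = length)
    sz <- sz[support >= min_cluster_support]
  }
  n <- length(sz)
  structure(list(
    sample_id = sample_id, tissue = tissue, n_molecules = n,
    mean_size = if (n > 0) mean(sz) else NA_real_,
    max_size = if (n > 0) max(sz) else NA_real_,
    histogram = histogram_sizes(sz, bin_width),
    expanded_fraction = if (n > 0) mean(sz > expanded_threshold) else NA_real_,
    expanded_threshold = expanded_threshold,
    empty = n == 0),
    class = "ogm_sample_summary")
}

#' @export
print.ogm_sample_summary <- function(x, ...) {
  cat(sprintf("ogm_sample_summary '%s'%s\n", x$sample_id,
              if (is.na(x$tissue)) "" else paste0(" (", x$tissue, ")")))
  if (x$empty) {
    cat("  no spanning molecules\n")
    return(invisible(x))
  }
  cat(sprintf("  molecules %d; mean %s bp; max %s bp; fraction > %d bp: %.3f\n",
              x$n_molecules, format(round(x$mean_size), big.mark = ","),
              format(round(x$max_size), big.mark = ","),
              x$expanded_threshold, x$expanded_fraction))
  invisible(x)
}

#' Summary table across samples (per-sample reporting columns)
#'
#' @param summaries List of `ogm_sample_summary`.
#' @return Data frame with `sample_id`, `tissue`, `n_molecules`,
#'   `mean_size` (0-decimal bp), `max_size`, `expanded_fraction`.
#' @export
summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(sample_id = s$sample_id, tissue = s$tissue,
               n_molecules = s$n_molecules,
               mean_size = round(s$mean_size),
               max_size = round(s$max_size),
               expanded_fraction = s$expanded_fraction)))
}

#' Run the full sizing pipeline on a simulation
#'
#' Convenience end-to-end wrapper: align every simulated molecule to the
#' region map (with the locus interval declared size-cost free), select
#' spanning molecules, and size them.
#'
#' @param sim An `ogm_simulation`.
#' @param penalties Base alignment penalties; the locus free gap is filled
#'   in from the simulation's region.
#' @param sample_id,tissue,expanded_threshold Passed to
#'   [summarize_sample()].
#' @return List with `alignments`, `spanning`, `calls`, `summary`.
#' @export
size_pipeline <- function(sim, penalties = align_penalties(),
                          sample_id = "sample", tissue = NULL,
                          expanded_threshold = 2000, min_cluster_support = 0) {
  stopifnot(inherits(sim, "ogm_simulation"))
  region <- sim$region
  penalties$free_gap <- c(region$locus$upstream[["position"]],
                          region$locus$downstream[["position"]])
  aln <- align_molecules(sim$molecules, region$map, penalties)
  sp <- select_spanning(aln, region$locus)
  calls <- size_spanning(sp, sim$molecules)
  list(alignments = aln, spanning = sp, calls = calls,
       summary = summarize_sample(calls, sample_id,
                                  tissue = if (is.null(tissue)) sim$profile else tissue,
                                  expanded_threshold = expanded_threshold,
                                  min_cluster_support = min_cluster_support))
}
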