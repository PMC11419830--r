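#' Build a reference label map from explicit positions
#'
#' A reference label map is the in-silico "digestion" of a contig: the ordered
#' genomic positions at which the labelling enzyme's recognition motif occurs.
#' All downstream sizing is done on inter-label distances, never on sequence.
#'
#' @param contig_name Contig identifier (e.g. `"chr18"`).
#' @param contig_length Contig length in bp.
#' @param positions Integer vector of 1-based label positions, strictly
#'   increasing.
#' @param label_ids Optional integer ids; default `seq_along(positions)`.
#'   Ids must be unique and ordered by position (Bionano convention: SiteID
#'   increases along the contig).
#' @return An object of class `ogm_labelmap`: a list with `contig_name`,
#'   `contig_length` and a data frame `labels` (columns `label_id`,
#'   `position`).
#' @export
label_map <- function(contig_name, contig_length, positions,
                      label_ids = seq_along(positions)) {
  positions <- as.numeric(positions)
  if (length(positions) > 0) {
    if (any(diff(positions) <= 0))
      stop("label positions must be strictly increasing")
    if (positions[1] < 1 || positions[length(positions)] > contig_length)
      stop("label positions must lie in [1, contig_length]")
  }
  if (anyDuplicated(label_ids))
    stop("label_ids must be unique")
  if (is.unsorted(label_ids, strictly = TRUE))
    stop("label_ids must be ordered by position")
  structure(
    list(contig_name = as.character(contig_name),
         contig_length = as.numeric(contig_length),
         labels = data.frame(label_id = as.integer(label_ids),
                             position = positions)),
    class = "ogm_labelmap")
}

#' @export
print.ogm_labelmap <- function(x, ...) {
  cat(sprintf("ogm_labelmap: %s (%s bp), %d label sites\n",
              x$contig_name, format(x$contig_length, big.mark = ","),
              nrow(x$labels)))
  if (nrow(x$labels) > 0) {
    dens <- nrow(x$labels) / x$contig_length * 1e5
    cat(sprintf("  density %.1f labels/100 kb; first %s, last %s\n", dens,
                format(x$labels$position[1], big.mark = ","),
                format(x$labels$position[nrow(x$labels)], big.mark = ",")))
  }
  invisible(x)
}

#' In-silico digestion: scan a sequence for label motif sites
#'
#' Finds every occurrence of the recognition motif on the forward strand and
#' of its reverse complement (a site is labelled regardless of strand), with
#' duplicates collapsed. The default DLE-1 motif CTTAAG is its own reverse
#' complement, so a single scan covers both strands. Overlapping occurrences
#' are all reported.
#'
#' @param sequence Nucleotide sequence: a single character string over
#'   A/C/G/T/N, or a [Biostrings::DNAString].
#' @param motif Recognition motif (default `"CTTAAG"`, DLE-1); length >= 4,
#'   A/C/G/T only.
#' @param contig_name Name recorded in the returned map.
#' @return An `ogm_labelmap` with labels at every motif start position
#'   (1-based); an empty sequence yields an empty map.
#' @export
scan_labels <- function(sequence, motif = "CTTAAG", contig_name = "contig") {
  motif <- toupper(as.character(motif))
  if (nchar(motif) < 4) stop("motif length must be >= 4")
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A/C/G/T")
  if (is.character(sequence)) sequence <- Biostrings::DNAString(toupper(sequence))
  n <- length(sequence)
  if (n == 0) return(label_map(contig_name, 0, numeric(0)))
  fwd <- Biostrings::start(Biostrings::matchPattern(motif, sequence))
  rcm <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  if (rcm == motif) {
    pos <- fwd
  } else {
    rev <- Biostrings::start(Biostrings::matchPattern(rcm, sequence))
    pos <- sort(unique(c(fwd, rev)))
  }
  label_map(contig_name, n, pos)
}

#' Read a FASTA reference and digest one contig into a label map
#'
#' @param path FASTA file path.
#' @param motif Recognition motif passed to [scan_labels()].
#' @param contig Contig name to digest; default the first record.
#' @return An `ogm_labelmap`.
#' @export
read_fasta_labelmap <- function(path, motif = "CTTAAG", contig = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  i <- if (is.null(contig)) 1L else match(contig, nm)
  if (is.na(i)) stop("contig not found: ", contig)
  scan_labels(seqs[[i]], motif, contig_name = nm[i])
}

round_half_up <- function(x) floor(x + 0.5)

#' Merge sub-resolution label sites into effective positions
#'
#' Two recognition sites closer than the imaging resolution (~1 kb) are seen
#' as a single fluorescent spot, so the reference must be collapsed the same
#' way before comparison: consecutive labels whose gap is at most
#' `resolution_limit` are merged into one effective site at the (half-up
#' rounded) mean of their positions. Merging is greedy left-to-right on
#' consecutive gaps; a merged site is only re-merged with the next label if
#' its mean position is itself within the limit (more than two labels
#' chaining triggers a warning, since the averaging correction is only
#' well-characterised for pairs).
#'
#' @param map An `ogm_labelmap`.
#' @param resolution_limit Merge distance in bp (> 0; default 1000).
#' @return A data frame with one row per effective site: `effective_position`
#'   and a list column `label_ids` of the member label ids.
#' @export
effective_positions <- function(map, resolution_limit = 1000) {
  stopifnot(inherits(map, "ogm_labelmap"), resolution_limit > 0)
  pos <- map$labels$position
  ids <- map$labels$label_id
  out_pos <- numeric(0)
  out_ids <- list()
  i <- 1
  while (i <= length(pos)) {
    cur_pos <- pos[i]
    cur_ids <- ids[i]
    j <- i + 1
    while (j <= length(pos) && (pos[j] - cur_pos) <= resolution_limit) {
      # mean of all members, so a merged pair only absorbs a third label when
      # its averaged position is still within the limit
      cur_ids <- c(cur_ids, ids[j])
      cur_pos <- round_half_up(mean(pos[ids %in% cur_ids]))
      j <- j + 1
    }
    if (length(cur_ids) > 2)
      warning(sprintf("%d labels chain within %d bp around position %s",
                      length(cur_ids), resolution_limit,
                      format(cur_pos, big.mark = ",")))
    out_pos <- c(out_pos, cur_pos)
    out_ids <- c(out_ids, list(cur_ids))
    i <- j
  }
  out <- data.frame(effective_position = out_pos)
  out$label_ids <- out_ids
  out
}

#' Define a repeat locus by its flanking label pair
#'
#' The locus is sized between an upstream marker and a downstream marker.
#' When a companion label sits within the imaging resolution of the
#' downstream marker, only one of the two is ever detected on a molecule
#' (randomly), so the reference distance must be taken to the *average* of
#' the two positions. Subtracting the repeat units already present in the
#' reference then yields a corrected reference distance such that a
#' molecule's inter-marker excess over it equals its full repeat-tract
#' length in bp.
#'
#' @param map An `ogm_labelmap` containing the marker labels.
#' @param upstream_id,downstream_id Label ids of the flanking markers
#'   (upstream must precede downstream).
#' @param ref_repeat_count Repeat units carried by the reference assembly
#'   between the markers (24 for CTG18.1 in hg38).
#' @param repeat_unit_len Repeat unit length in bp (3 for CTG).
#' @param resolution_limit Companion-detection distance in bp (default 1000).
#' @param name Locus name carried through reports.
#' @return An object of class `ogm_locus` with fields `upstream`,
#'   `downstream`, `companion` (or `NULL`), `ref_repeat_count`,
#'   `repeat_unit_len`, `resolution_limit`, and the derived distances
#'   `raw_distance` (downstream - upstream), `averaged_distance`
#'   (companion-averaged downstream - upstream) and `corrected_ref_distance`
#'   (averaged minus `ref_repeat_count * repeat_unit_len`).
#' @export
build_locus <- function(map, upstream_id, downstream_id,
                        ref_repeat_count = 24, repeat_unit_len = 3,
                        resolution_limit = 1000, name = "locus") {
  stopifnot(inherits(map, "ogm_labelmap"))
  lab <- map$labels
  iu <- match(upstream_id, lab$label_id)
  id <- match(downstream_id, lab$label_id)
  if (is.na(iu) || is.na(id))
    stop("marker label id not present in map")
  up_pos <- lab$position[iu]
  dn_pos <- lab$position[id]
  if (up_pos >= dn_pos) stop("upstream marker must precede downstream marker")
  # the averaging scheme assumes the upstream marker itself resolves cleanly
  near_up <- abs(lab$position - up_pos) <= resolution_limit & lab$label_id != upstream_id
  if (any(near_up))
    stop("upstream marker has a neighbouring label within the resolution ",
         "limit; the single-sided averaging correction does not cover this")
  companion <- NULL
  if (id < nrow(lab) && (lab$position[id + 1] - dn_pos) <= resolution_limit)
    companion <- c(id = lab$label_id[id + 1], position = lab$position[id + 1])
  eff_dn <- if (is.null(companion)) dn_pos else
    round_half_up((dn_pos + companion[["position"]]) / 2)
  raw <- dn_pos - up_pos
  avg <- eff_dn - up_pos
  corrected <- avg - ref_repeat_count * repeat_unit_len
  structure(
    list(name = name,
         contig = map$contig_name,
         upstream = c(id = lab$label_id[iu], position = up_pos),
         downstream = c(id = lab$label_id[id], position = dn_pos),
         companion = companion,
         ref_repeat_count = as.integer(ref_repeat_count),
         repeat_unit_len = as.integer(repeat_unit_len),
         resolution_limit = resolution_limit,
         raw_distance = raw,
         averaged_distance = avg,
         corrected_ref_distance = corrected),
    class = "ogm_locus")
}

#' @export
print.ogm_locus <- function(x, ...) {
  cat(sprintf("ogm_locus '%s' on %s\n", x$name, x$contig))
  cat(sprintf("  upstream marker %d @ %s; downstream %d @ %s%s\n",
              x$upstream[["id"]], format(x$upstream[["position"]], big.mark = ","),
              x$downstream[["id"]], format(x$downstream[["position"]], big.mark = ","),
              if (is.null(x$companion)) "" else
                sprintf("; companion %d @ %s", x$companion[["id"]],
                        format(x$companion[["position"]], big.mark = ","))))
  cat(sprintf("  raw %s bp; companion-averaged %s bp; corrected (- %d x %d bp) %s bp\n",
              format(x$raw_distance, big.mark = ","),
              format(x$averaged_distance, big.mark = ","),
              x$ref_repeat_count, x$repeat_unit_len,
              format(x$corrected_ref_distance, big.mark = ",")))
  invisible(x)
}

#' The CTG18.1 locus marker map (hg38)
#'
#' The three hg38 DLE-1 label sites flanking the CTG18.1 repeat in TCF4
#' intron 3: the upstream marker (site 10,414 of chr18, position 55,584,360),
#' the downstream marker (10,415 @ 55,594,648) and its sub-resolution
#' companion (10,416 @ 55,595,438).
#'
#' @return An `ogm_labelmap` for chr18 restricted to the three marker sites.
#' @export
ctg18_marker_map <- function() {
  label_map("chr18", 80373285,
            positions = c(55584360, 55594648, 55595438),
            label_ids = c(10414L, 10415L, 10416L))
}

#' The CTG18.1 locus definition (hg38)
#'
#' Convenience wrapper: [build_locus()] on [ctg18_marker_map()] with the
#' hg38 reference's 24 CTG units. Yields the 10,611 bp corrected reference
#' distance used for per-molecule expansion sizing.
#' @export
ctg18_locus <- function() {
  build_locus(ctg18_marker_map(), 10414L, 10415L,
              ref_repeat_count = 24, repeat_unit_len = 3, name = "CTG18.1")
}

#' Read locus definitions and scan settings from a YAML config
#'
#' The config carries `motif`, `resolution_limit` and a named `loci` table
#' (`upstream_id`, `downstream_id`, `ref_repeats`, `unit`).
#'
#' @param path YAML file.
#' @return A list with `motif`, `resolution_limit` and `loci`.
#' @export
read_locus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(motif = if (is.null(cfg$motif)) "CTTAAG" else cfg$motif,
       resolution_limit = if (is.null(cfg$resolution_limit)) 1000 else cfg$resolution_limit,
       loci = cfg$loci)
}
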