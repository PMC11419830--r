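#' Alignment penalty settings for the built-in label aligner
#'
#' The built-in aligner is a deliberately simplified stand-in for vendor
#' molecule-to-reference alignment, intended for synthetic molecules; real
#' data should come in as XMAP produced by the vendor pipeline. Scores:
#' each matched label pair earns `match_score`; skipped reference and
#' molecule labels between consecutive pairs cost `miss_ref` / `miss_qry`
#' each; each matched interval pays `size_cost * (ref_gap - qry_gap)^2`,
#' except intervals straddling `free_gap` (the declared repeat locus), which
#' are size-cost free so arbitrarily expanded molecules still align.
#'
#' @param match_score Reward per matched pair.
#' @param miss_ref,miss_qry Penalty per skipped label.
#' @param size_cost Penalty per bp^2 of interval-length mismatch.
#' @param free_gap Optional `c(lo, hi)` reference interval exempt from
#'   `size_cost`.
#' @param max_skip Maximum consecutive skipped labels considered per side.
#' @param min_flank Minimum matched pairs required on each side of
#'   `free_gap` (or in total, when no `free_gap` is declared).
#' @return A list of penalty settings.
#' @export
align_penalties <- function(match_score = 5, miss_ref = 3, miss_qry = 3,
                            size_cost = 1e-5, free_gap = NULL,
                            max_skip = 5, min_flank = 3) {
  list(match_score = match_score, miss_ref = miss_ref, miss_qry = miss_qry,
       size_cost = size_cost, free_gap = free_gap,
       max_skip = as.integer(max_skip), min_flank = as.integer(min_flank))
}

dp_call <- function(ref_pos, qry_pos, p) {
  free <- !is.null(p$free_gap)
  .dp_align(as.numeric(ref_pos), as.numeric(qry_pos),
            p$match_score, p$miss_ref, p$miss_qry, p$size_cost,
            if (free) p$free_gap[1] else 0, if (free) p$free_gap[2] else 0,
            free, p$max_skip)
}

#' Align one molecule to a reference label map
#'
#' Dynamic programme over monotone label pairings (see [align_penalties()]
#' for the objective). Both orientations are tried; the better-scoring one
#' is kept (ties go to `+`). Deterministic tie-breaking prefers more matched
#' pairs, then the leftmost reference placement.
#'
#' @param mol An `ogm_molecule` with at least 5 labels.
#' @param map An `ogm_labelmap`.
#' @param penalties See [align_penalties()].
#' @return An `ogm_alignment` (list with `molecule_id`, `contig`,
#'   `orientation`, `pairs` data frame of `ref_id`/`qry_site`, `score`,
#'   `confidence`), or `NULL` when the molecule has fewer than 5 labels or
#'   the flank-support requirement is not met.
#' @export
align_molecule <- function(mol, map, penalties = align_penalties()) {
  stopifnot(inherits(mol, "ogm_molecule"), inherits(map, "ogm_labelmap"))
  q <- mol$positions
  if (length(q) < 5) return(NULL)
  rp <- map$labels$position
  fwd <- dp_call(rp, q, penalties)
  rev_q <- sort(mol$length - q + 1)
  rev <- dp_call(rp, rev_q, penalties)
  if (rev$score > fwd$score + 1e-9) {
    hit <- rev; orient <- "-"
    qry_site <- length(q) - hit$qry_idx + 1L   # back to original site indices
  } else {
    hit <- fwd; orient <- "+"
    qry_site <- hit$qry_idx
  }
  ref_ids <- map$labels$label_id[hit$ref_idx]
  ref_pos <- rp[hit$ref_idx]
  p <- penalties
  if (!is.null(p$free_gap)) {
    if (sum(ref_pos <= p$free_gap[1]) < p$min_flank ||
        sum(ref_pos >= p$free_gap[2]) < p$min_flank) return(NULL)
  } else if (length(ref_ids) < p$min_flank) return(NULL)
  structure(list(molecule_id = mol$molecule_id,
                 contig = map$contig_name,
                 orientation = orient,
                 pairs = data.frame(ref_id = ref_ids, qry_site = qry_site),
                 score = hit$score,
                 confidence = hit$score),
            class = "ogm_alignment")
}

#' Align a list of molecules
#'
#' @param molecules List of `ogm_molecule`.
#' @param map Reference `ogm_labelmap`.
#' @param penalties See [align_penalties()].
#' @return List of `ogm_alignment` (rejected molecules omitted).
#' @export
align_molecules <- function(molecules, map, penalties = align_penalties()) {
  out <- lapply(molecules, align_molecule, map = map, penalties = penalties)
  out[!vapply(out, is.null, logical(1))]
}

#' Select locus-spanning molecules
#'
#' Keeps alignments whose matched pairs include the locus's upstream marker
#' and at least one of the downstream marker or its sub-resolution
#' companion; the retained representative(s) are recorded per alignment
#' (attribute `downstream_rep`: `"downstream"`, `"companion"` or `"both"`).
#'
#' @param alignments List of `ogm_alignment`.
#' @param locus An `ogm_locus`.
#' @return The spanning subset, with class `ogm_spanning_set` and the locus
#'   attached as attribute `locus`. Idempotent.
#' @export
select_spanning <- function(alignments, locus) {
  stopifnot(inherits(locus, "ogm_locus"))
  up <- locus$upstream[["id"]]; dn <- locus$downstream[["id"]]
  cp <- if (is.null(locus$companion)) NA_integer_ else locus$companion[["id"]]
  keep <- list()
  for (a in alignments) {
    ids <- a$pairs$ref_id
    has_dn <- dn %in% ids
    has_cp <- !is.na(cp) && cp %in% ids
    if ((up %in% ids) && (has_dn || has_cp)) {
      attr(a, "downstream_rep") <-
        if (has_dn && has_cp) "both" else if (has_dn) "downstream" else "companion"
      keep[[length(keep) + 1]] <- a
    }
  }
  structure(keep, class = "ogm_spanning_set", locus = locus)
}

# ---- XMAP 0.2 ------------------------------------------------------------

xmap_cols <- c("XmapEntryID", "QryContigID", "RefContigID", "QryStartPos",
               "QryEndPos", "RefStartPos", "RefEndPos", "Orientation",
               "Confidence", "HitEnum", "QryLen", "RefLen", "LabelChannel",
               "Alignment")

#' Read molecule-to-reference alignments from XMAP
#'
#' Parses the 14-column XMAP 0.2 table; the `Alignment` column's
#' `(refSiteID,qrySiteID)` pairs become the pair list, orientation from the
#' `Orientation` column, confidence from `Confidence`.
#'
#' @param path XMAP file.
#' @param contig_names Optional named vector mapping `RefContigID` to contig
#'   names.
#' @return List of `ogm_alignment`.
#' @export
read_xmap <- function(path, contig_names = NULL) {
  ver <- grep("^# XMAP File Version:", readLines(path, n = 20), value = TRUE)
  if (length(ver) == 1 && !grepl("0\\.2", ver))
    warning("unexpected XMAP version (", trimws(sub(".*:", "", ver)),
            "); attempting best-effort parse")
  df <- parse_bionano_table(path, c("QryContigID", "RefContigID",
                                    "Orientation", "Confidence", "Alignment"))
  lapply(seq_len(nrow(df)), function(k) {
    al <- df$Alignment[k]
    m <- regmatches(al, gregexpr("\\((\\d+),(\\d+)\\)", al))[[1]]
    if (length(m) == 0) stop("empty Alignment field in row ", k, " of ", path)
    parts <- do.call(rbind, strsplit(gsub("[()]", "", m), ",", fixed = TRUE))
    ref_id <- as.integer(parts[, 1]); qry_site <- as.integer(parts[, 2])
    ord <- order(ref_id)
    rcid <- df$RefContigID[k]
    structure(list(molecule_id = as.integer(as.numeric(df$QryContigID[k])),
                   contig = if (!is.null(contig_names) && rcid %in% names(contig_names))
                     unname(contig_names[rcid]) else rcid,
                   orientation = df$Orientation[k],
                   pairs = data.frame(ref_id = ref_id[ord],
                                      qry_site = qry_site[ord]),
                   score = as.numeric(df$Confidence[k]),
                   confidence = as.numeric(df$Confidence[k])),
              class = "ogm_alignment")
  })
}

#' Write alignments to XMAP
#'
#' @param alignments List of `ogm_alignment`.
#' @param path Output file.
#' @param map Optional reference `ogm_labelmap` used to fill ref positions.
#' @param molecules Optional list of `ogm_molecule` (by id) used to fill
#'   query positions and lengths.
#' @param ref_contig_id Numeric reference contig id to write (default 1).
#' @return `path`, invisibly.
#' @export
write_xmap <- function(alignments, path, map = NULL, molecules = NULL,
                       ref_contig_id = 1) {
  mol_by_id <- list()
  for (m in molecules) mol_by_id[[as.character(m$molecule_id)]] <- m
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# XMAP File Version:\t0.2",
               "# Label Channels:\t1",
               paste0("#h\t", paste(xmap_cols, collapse = "\t")),
               paste0("#f\t", paste(c("int", "int", "int", "float", "float",
                                      "float", "float", "string", "float",
                                      "string", "float", "float", "int",
                                      "string"), collapse = "\t"))), con)
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    pr <- a$pairs
    pair_str <- paste0(sprintf("(%d,%d)", pr$ref_id, pr$qry_site), collapse = "")
    mol <- mol_by_id[[as.character(a$molecule_id)]]
    qpos <- if (is.null(mol)) c(0, 0) else
      range(mol$positions[range(pr$qry_site)])
    rpos <- if (is.null(map)) c(0, 0) else
      range(map$labels$position[match(range(pr$ref_id), map$labels$label_id)])
    writeLines(sprintf("%d\t%d\t%d\t%.1f\t%.1f\t%.1f\t%.1f\t%s\t%.2f\t%s\t%.1f\t%.1f\t%d\t%s",
                       k, a$molecule_id, ref_contig_id,
                       qpos[1], qpos[2], rpos[1], rpos[2],
                       a$orientation, a$confidence,
                       paste0(nrow(pr), "M"),
                       if (is.null(mol)) 0 else mol$length,
                       if (is.null(map)) 0 else map$contig_length,
                       1L, pair_str), con)
  }
  invisible(path)
}
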