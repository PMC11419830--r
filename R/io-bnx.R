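# BNX 1.3: per-molecule records. A `0` line carries molecule metadata
# (channel, id, length, label count), the following `1` line carries the
# channel-1 label positions along the molecule, conventionally terminated by
# the molecule length. Optional QX quality lines are ignored on read.

#' Construct a single molecule
#'
#' @param molecule_id Integer id.
#' @param length Molecule length in bp.
#' @param positions Strictly increasing label offsets from the molecule
#'   start, each in (0, length].
#' @param origin Optional list(contig, start, strand) recording where a
#'   simulated molecule came from.
#' @param truth_repeats Optional ground-truth repeat count (simulation).
#' @return An object of class `ogm_molecule`.
#' @export
molecule <- function(molecule_id, length, positions, origin = NULL,
                     truth_repeats = NULL) {
  positions <- as.numeric(positions)
  if (length(positions) > 0) {
    if (any(diff(positions) <= 0))
      stop("label offsets must be strictly increasing")
    if (positions[1] <= 0 || positions[length(positions)] > length)
      stop("label offsets must lie in (0, length]")
  }
  structure(list(molecule_id = as.integer(molecule_id),
                 length = as.numeric(length),
                 positions = positions,
                 origin = origin,
                 truth_repeats = truth_repeats),
            class = "ogm_molecule")
}

#' Write molecules to a BNX 1.3 file
#'
#' @param molecules List of `ogm_molecule` objects (may be empty).
#' @param path Output file.
#' @return `path`, invisibly. Positions are written with one decimal;
#'   round-trip through [read_bnx()] is lossless at that precision.
#' @export
write_bnx <- function(molecules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# BNX File Version:\t1.3",
    "# Label Channels:\t1",
    "# Nickase Recognition Site 1:\tCTTAAG;green_01",
    sprintf("# Number of Molecules:\t%d", length(molecules)),
    "#0h\tLabelChannel\tMoleculeId\tLength\tNumberofLabels",
    "#0f\tint\tint\tfloat\tint",
    "#1h\tLabelChannel\tLabelPositions[N]",
    "#1f\tint\tfloat"), con)
  for (m in molecules) {
    writeLines(sprintf("0\t%d\t%.1f\t%d", m$molecule_id, m$length,
                       length(m$positions)), con)
    writeLines(paste(c("1", sprintf("%.1f", c(m$positions, m$length))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read molecules from a BNX file
#'
#' @param path BNX file.
#' @return List of `ogm_molecule`. QX quality lines are skipped; only
#'   channel-1 label lines are used.
#' @export
read_bnx <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# BNX File Version:", lines[1]))
    stop("malformed BNX header: expected '# BNX File Version:' on line 1, got: ",
         if (length(lines) == 0) "<empty file>" else lines[1])
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  mols <- list()
  i <- 1
  while (i <= length(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (f[1] != "0")
      stop("malformed BNX record: expected a '0' line, got: ", body[i])
    if (length(f) < 3)
      stop("malformed BNX '0' line (needs LabelChannel, MoleculeId, Length): ",
           body[i])
    id <- as.integer(f[2]); len <- as.numeric(f[3])
    pos <- numeric(0)
    i <- i + 1
    while (i <= length(body)) {
      g <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (g[1] == "0") break
      if (g[1] == "1") {
        v <- as.numeric(g[-1])
        # conventional trailing molecule-length sentinel
        if (length(v) > 0 && abs(v[length(v)] - len) < 1e-6)
          v <- v[-length(v)]
        pos <- v
      } # other channels / QX lines ignored
      i <- i + 1
    }
    mols[[length(mols) + 1]] <- molecule(id, len, pos)
  }
  mols
}
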