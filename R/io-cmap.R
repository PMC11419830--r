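# Bionano CMAP (version 0.2 dialect): tab-separated label-map table with
# columns CMapId, ContigLength, NumSites, SiteID, LabelChannel, Position.
# Positions travel as floats with one decimal, as written in the wild.

#' Write a label map to CMAP
#'
#' @param map An `ogm_labelmap`.
#' @param path Output file.
#' @param cmap_id Numeric contig id to write (CMAP keys contigs by number,
#'   not name); default 1.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(map, path, cmap_id = 1) {
  stopifnot(inherits(map, "ogm_labelmap"))
  n <- nrow(map$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# CMAP File Version:\t0.2",
    "# Label Channels:\t1",
    "# Nickase Recognition Site 1:\tCTTAAG",
    sprintf("# Number of Consensus Maps:\t1"),
    paste0("#h\t", paste(c("CMapId", "ContigLength", "NumSites", "SiteID",
                           "LabelChannel", "Position"), collapse = "\t")),
    paste0("#f\t", paste(c("int", "float", "int", "int", "int", "float"),
                         collapse = "\t"))), con)
  if (n > 0) {
    rows <- sprintf("%d\t%.1f\t%d\t%d\t%d\t%.1f",
                    cmap_id, map$contig_length, n,
                    map$labels$label_id, 1L, map$labels$position)
    writeLines(rows, con)
  }
  invisible(path)
}

parse_bionano_table <- function(path, required) {
  lines <- readLines(path)
  hdr <- grep("^#h\t", lines, value = TRUE)
  if (length(hdr) != 1)
    stop("missing #h column header line in ", path)
  cols <- strsplit(sub("^#h\t", "", hdr), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(required, cols)
  if (length(miss) > 0)
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < length(cols))
  if (length(bad) > 0)
    stop("malformed row ", bad[1], " in ", path)
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Read a CMAP label map
#'
#' @param path CMAP file.
#' @param cmap_id Contig id to extract; default the first in the file.
#' @param contig_name Name for the returned map; default `"cmap<ID>"`.
#' @return An `ogm_labelmap`. Only label channel 1 is kept; positions are
#'   rounded to integer bp.
#' @export
read_cmap <- function(path, cmap_id = NULL, contig_name = NULL) {
  ver <- grep("^# CMAP File Version:", readLines(path, n = 20), value = TRUE)
  if (length(ver) == 1 && !grepl("0\\.[12]", ver))
    warning("unexpected CMAP version (", trimws(sub(".*:", "", ver)),
            "); attempting best-effort parse")
  df <- parse_bionano_table(path, c("CMapId", "ContigLength", "NumSites",
                                    "SiteID", "LabelChannel", "Position"))
  if (nrow(df) == 0) stop("CMAP contains no label rows: ", path)
  ids <- as.numeric(df$CMapId)
  use <- if (is.null(cmap_id)) ids[1] else cmap_id
  df <- df[ids == use & as.integer(df$LabelChannel) == 1L, , drop = FALSE]
  if (nrow(df) == 0) stop("CMapId ", use, " (channel 1) not found in ", path)
  ord <- order(as.numeric(df$Position))
  df <- df[ord, , drop = FALSE]
  label_map(contig_name = if (is.null(contig_name)) paste0("cmap", use) else contig_name,
            contig_length = round(as.numeric(df$ContigLength[1])),
            positions = round(as.numeric(df$Position)),
            label_ids = as.integer(df$SiteID))
}
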