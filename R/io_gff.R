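#' Feature annotation table
#'
#' Constructs and validates the package's annotation data frame:
#' 1-based inclusive coordinates, `+`/`-` strand, and feature kind
#' collapsed to `CDS`, `tRNA`, `rRNA` or `other`.  Origin-spanning
#' features on a circular chromosome are rejected (start must not
#' exceed end).
#'
#' @param feature_id Unique feature identifiers.
#' @param gene_name Gene symbols (may repeat).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"other"`.
#' @param genome_length Optional genome length for bounds checking.
#' @return A `data.frame` of class `feature_annotation`, sorted by start.
#' @export
feature_annotation <- function(feature_id, gene_name, start, end, strand,
                               kind = "CDS", genome_length = NULL) {
  df <- data.frame(feature_id = as.character(feature_id),
                   gene_name = as.character(gene_name),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   kind = as.character(kind),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$feature_id))
    stop("feature_annotation: duplicate feature_id '",
         df$feature_id[duplicated(df$feature_id)][1L], "'")
  bad <- which(df$start < 1L | df$start > df$end)
  if (length(bad))
    stop(sprintf(
      "feature_annotation: start > end (or start < 1) for feature '%s' (%d..%d); origin-spanning features are not supported",
      df$feature_id[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]))
  if (!all(df$strand %in% c("+", "-")))
    stop("feature_annotation: strand must be '+' or '-'")
  if (!all(df$kind %in% c("CDS", "tRNA", "rRNA", "other")))
    stop("feature_annotation: kind must be CDS, tRNA, rRNA or other")
  if (!is.null(genome_length) && any(df$end > genome_length))
    stop("feature_annotation: feature end beyond genome length")
  df <- df[order(df$start, df$feature_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("feature_annotation", "data.frame")
  df
}

# pull `key=value` out of a GFF3 attribute string; NA when absent
gff_attr <- function(attr, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regexpr(pat, attr, perl = TRUE)
  out <- rep(NA_character_, length(attr))
  hit <- m > 0L
  out[hit] <- sub(pat, "\\1", regmatches(attr, m), perl = TRUE)
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Read a GFF3 annotation file
#'
#' Columns 4/5 are taken as 1-based inclusive.  The gene name is taken
#' from the attribute keys `gene`, then `Name`, then `ID`; the feature id
#' from `ID`, falling back to the gene name.  Feature ids must be unique.
#'
#' @param path Path to a GFF3 file.
#' @param genome_length Optional genome length for bounds checking.
#' @return A [feature_annotation()] data frame sorted by start.
#' @export
read_gff3 <- function(path, genome_length = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- ape::read.gff(path, GFF3 = TRUE)
  if (nrow(g) == 0L)
    return(feature_annotation(character(), character(), integer(),
                              integer(), character(), character()))
  bad <- which(g$start > g$end)
  if (length(bad))
    stop(sprintf("GFF3 format error: start > end (%d > %d) for feature on '%s'",
                 g$start[bad[1L]], g$end[bad[1L]], as.character(g$seqid[bad[1L]])))
  att <- as.character(g$attributes)
  gene <- gff_attr(att, "gene")
  name <- gff_attr(att, "Name")
  id <- gff_attr(att, "ID")
  gene_name <- ifelse(!is.na(gene), gene, ifelse(!is.na(name), name, id))
  feature_id <- ifelse(!is.na(id), id, gene_name)
  if (anyNA(feature_id))
    feature_id[is.na(feature_id)] <-
      paste0("feature_", which(is.na(feature_id)))
  if (anyDuplicated(feature_id))
    stop("GFF3 format error: duplicate feature ID '",
         feature_id[duplicated(feature_id)][1L], "'")
  type <- as.character(g$type)
  kind <- ifelse(type %in% c("CDS", "tRNA", "rRNA"), type, "other")
  feature_annotation(feature_id, gene_name, g$start, g$end,
                     as.character(g$strand), kind, genome_length)
}

#' Write an annotation table as GFF3
#'
#' @param features A [feature_annotation()] data frame.
#' @param seqid Sequence id for column 1.
#' @param path Output path.
#' @param source Value for GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, seqid, path, source = "bacpopscan") {
  hdr <- "##gff-version 3"
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   seqid, source, features$kind,
                   features$start, features$end, features$strand,
                   ifelse(features$kind == "CDS", "0", "."),
                   sprintf("ID=%s;gene=%s", features$feature_id,
                           features$gene_name))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
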