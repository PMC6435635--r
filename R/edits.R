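# Edit application, indel left-normalization, and coordinate liftover.
# An edit table has columns: kind ("snp", "del", "ins"), pos, ref, alt.
#   snp: pos is the substituted base, ref/alt single bases
#   del: ref is the deleted run starting at pos, alt == ""
#   ins: alt is inserted immediately BEFORE pos, ref == ""

validate_edits <- function(edits, seq = NULL) {
  if (is.null(edits) || nrow(edits) == 0L) return(invisible(edits))
  stopifnot(all(c("kind", "pos", "ref", "alt") %in% names(edits)))
  if (!all(edits$kind %in% c("snp", "del", "ins")))
    stop("edits: kind must be snp, del or ins")
  n <- if (is.null(seq)) Inf else nchar(seq)
  span_start <- edits$pos
  span_end <- ifelse(edits$kind == "del", edits$pos + nchar(edits$ref) - 1L,
                     ifelse(edits$kind == "snp", edits$pos,
                            edits$pos - 1L))  # ins occupies the junction
  if (any(span_start < 1L) || any(span_end > n))
    stop("edits: position outside the sequence")
  o <- order(span_start, span_end)
  ss <- span_start[o]; se <- span_end[o]; kk <- edits$kind[o]
  if (nrow(edits) > 1L) {
    prev_end <- se[-nrow(edits)]
    next_start <- ss[-1L]
    # insertions at the same junction as another edit's end are overlaps too
    if (any(next_start <= prev_end))
      stop("edits: overlapping edits at position ",
           next_start[which(next_start <= prev_end)[1L]])
  }
  if (!is.null(seq)) {
    for (i in which(edits$kind != "ins")) {
      l <- max(nchar(edits$ref[i]), 1L)
      have <- substr(seq, edits$pos[i], edits$pos[i] + l - 1L)
      if (have != edits$ref[i])
        stop(sprintf("edits: reference mismatch at %d (edit says '%s', sequence has '%s')",
                     edits$pos[i], edits$ref[i], have))
    }
  }
  invisible(edits)
}

#' Apply an edit set to a sequence
#'
#' Applies SNPs, deletions and insertions (given in the coordinates of
#' `seq`) and returns the edited sequence.  Edits must be
#' non-overlapping; they are applied right to left so coordinates never
#' shift underneath one another.
#'
#' @param seq A [genome_seq()] or nucleotide string.
#' @param edits Data frame with columns `kind` (`"snp"`, `"del"`,
#'   `"ins"`), `pos`, `ref`, `alt`; insertions are placed before `pos`.
#' @return The edited sequence as a string.
#' @export
apply_edits <- function(seq, edits) {
  s <- as_seq_string(seq)
  if (is.null(edits) || nrow(edits) == 0L) return(s)
  validate_edits(edits, s)
  # an insertion at the same position as another edit must be emitted first
  o <- order(edits$pos, edits$kind != "ins")
  edits <- edits[o, , drop = FALSE]
  pieces <- character(2L * nrow(edits) + 1L)
  cursor <- 1L
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    pieces[2L * i - 1L] <- substr(s, cursor, p - 1L)
    if (edits$kind[i] == "snp") {
      pieces[2L * i] <- edits$alt[i]
      cursor <- p + 1L
    } else if (edits$kind[i] == "del") {
      pieces[2L * i] <- ""
      cursor <- p + nchar(edits$ref[i])
    } else {
      pieces[2L * i] <- edits$alt[i]
      cursor <- p
    }
  }
  pieces[2L * nrow(edits) + 1L] <- substr(s, cursor, nchar(s))
  paste(pieces, collapse = "")
}

#' Left-normalize an indel against its reference
#'
#' Shifts a deletion/insertion to its leftmost equivalent placement
#' (the VCF-style canonical form): a deletion of `ref[p..p+L-1]` moves
#' left while `ref[p-1] == ref[p+L-1]`; an insertion before `p` moves
#' left while `ref[p-1]` equals the last inserted base (rotating the
#' inserted sequence).
#'
#' @param seq Reference [genome_seq()] or string.
#' @param pos 1-based position (first deleted base, or insertion point).
#' @param ref Deleted run (`""` for insertions).
#' @param alt Inserted sequence (`""` for deletions).
#' @return A list with normalized `pos`, `ref`, `alt` and the shift
#'   applied.
#' @export
left_normalize_indel <- function(seq, pos, ref, alt) {
  s <- as_seq_string(seq)
  shift <- 0L
  if (nchar(ref) > 0L && nchar(alt) == 0L) {          # deletion
    l <- nchar(ref)
    while (pos > 1L &&
           substr(s, pos - 1L, pos - 1L) == substr(s, pos + l - 1L, pos + l - 1L)) {
      pos <- pos - 1L; shift <- shift + 1L
    }
    ref <- substr(s, pos, pos + l - 1L)
  } else if (nchar(alt) > 0L && nchar(ref) == 0L) {   # insertion
    l <- nchar(alt)
    while (pos > 1L &&
           substr(s, pos - 1L, pos - 1L) == substr(alt, l, l)) {
      alt <- paste0(substr(alt, l, l), substr(alt, 1L, l - 1L))
      pos <- pos - 1L; shift <- shift + 1L
    }
  } else stop("left_normalize_indel: exactly one of ref/alt must be empty")
  list(pos = pos, ref = ref, alt = alt, shift = shift)
}

#' Lift reference positions through an edit set
#'
#' Maps 1-based reference coordinates to the coordinates of the edited
#' (query) sequence.  Positions inside a deletion map to `NA`.
#'
#' @param pos Integer vector of reference positions.
#' @param edits Edit table as in [apply_edits()].
#' @return Integer vector of query positions (`NA` for deleted sites).
#' @export
lift_position <- function(pos, edits) {
  out <- as.integer(pos)
  if (is.null(edits) || nrow(edits) == 0L) return(out)
  shift <- rep(0L, length(pos))
  for (i in seq_len(nrow(edits))) {
    k <- edits$kind[i]; p <- edits$pos[i]
    if (k == "del") {
      l <- nchar(edits$ref[i])
      out[pos >= p & pos <= p + l - 1L] <- NA_integer_
      shift[pos > p + l - 1L] <- shift[pos > p + l - 1L] - l
    } else if (k == "ins") {
      l <- nchar(edits$alt[i])
      shift[pos >= p] <- shift[pos >= p] + l
    }
  }
  out + shift
}

#' Lift a feature annotation through an edit set
#'
#' Features whose span is wholly or partly deleted are dropped (their
#' ids are returned in the `dropped` attribute).
#'
#' @param features A [feature_annotation()] data frame in reference
#'   coordinates.
#' @param edits Edit table as in [apply_edits()].
#' @return The lifted [feature_annotation()] in query coordinates.
#' @export
lift_annotation <- function(features, edits) {
  ns <- lift_position(features$start, edits)
  ne <- lift_position(features$end, edits)
  keep <- !is.na(ns) & !is.na(ne)
  out <- feature_annotation(features$feature_id[keep],
                            features$gene_name[keep],
                            ns[keep], ne[keep],
                            features$strand[keep], features$kind[keep])
  attr(out, "dropped") <- features$feature_id[!keep]
  out
}
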