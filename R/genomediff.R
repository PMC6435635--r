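# Collinear whole-genome comparison: unique-k-mer anchors, collinear
# chaining, base-level alignment of small inter-anchor gaps, and
# classification of large gaps as deleted/inserted segments.

# exact base-4 encoding of all k-mers as doubles (4^k < 2^53 for k <= 26);
# windows containing N give NA
kmer_codes <- function(chars, k) {
  codes <- match(chars, c("A", "C", "G", "T")) - 1
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  for (j in 0:(k - 1L)) out <- out * 4 + codes[(1L + j):(n + j)]
  out
}

unique_kmer_positions <- function(codes) {
  dup <- duplicated(codes) | duplicated(codes, fromLast = TRUE)
  which(!dup & !is.na(codes))
}

#' Find exact-match anchors between two genomes
#'
#' Anchors are maximal exact matches seeded at k-mers that occur exactly
#' once in each sequence.  Co-diagonal seed runs are merged, each run is
#' extended outwards to mismatch, and overlapping anchors (in either
#' coordinate) are resolved by trimming so the result is a
#' non-overlapping list sorted by reference position.
#'
#' @param ref,qry [genome_seq()] objects or nucleotide strings.
#' @param k K-mer seed length (at least 15; default 21).
#' @return A data frame `ref_start, qry_start, length` (1-based).
#' @export
find_anchors <- function(ref, qry, k = 21L) {
  if (k < 15L) stop("find_anchors: k must be >= 15")
  rs <- as_seq_string(ref); qs <- as_seq_string(qry)
  rc <- strsplit(rs, "")[[1]]; qc <- strsplit(qs, "")[[1]]
  cr <- kmer_codes(rc, k); cq <- kmer_codes(qc, k)
  ur <- unique_kmer_positions(cr); uq <- unique_kmer_positions(cq)
  m <- match(cr[ur], cq[uq])
  hit <- !is.na(m)
  i <- ur[hit]; j <- uq[m[hit]]
  if (length(i) == 0L)
    return(data.frame(ref_start = integer(0), qry_start = integer(0),
                      length = integer(0)))
  diag <- j - i
  o <- order(diag, i)
  i <- i[o]; j <- j[o]; diag <- diag[o]
  new_run <- c(TRUE, diff(diag) != 0L | diff(i) != 1L)
  run <- cumsum(new_run)
  first <- !duplicated(run)
  len <- as.integer(tabulate(run)) + k - 1L
  a <- data.frame(ref_start = i[first], qry_start = j[first], length = len)
  # maximal extension to the first mismatching base on either side
  rraw <- charToRaw(rs); qraw <- charToRaw(qs)
  nr <- length(rraw); nq <- length(qraw)
  for (t in seq_len(nrow(a))) {
    s1 <- a$ref_start[t]; s2 <- a$qry_start[t]; l <- a$length[t]
    while (s1 > 1L && s2 > 1L && rraw[s1 - 1L] == qraw[s2 - 1L]) {
      s1 <- s1 - 1L; s2 <- s2 - 1L; l <- l + 1L
    }
    while (s1 + l <= nr && s2 + l <= nq && rraw[s1 + l] == qraw[s2 + l]) {
      l <- l + 1L
    }
    a$ref_start[t] <- s1; a$qry_start[t] <- s2; a$length[t] <- l
  }
  # merge same-diagonal anchors that now coincide or overlap
  a <- unique(a)
  dg <- a$qry_start - a$ref_start
  o <- order(dg, a$ref_start)
  a <- a[o, , drop = FALSE]; dg <- dg[o]
  keep <- logical(nrow(a))
  last <- 0L
  for (t in seq_len(nrow(a))) {
    if (last > 0L && dg[t] == dg[last] &&
        a$ref_start[t] <= a$ref_start[last] + a$length[last]) {
      new_end <- max(a$ref_start[last] + a$length[last],
                     a$ref_start[t] + a$length[t])
      a$length[last] <- new_end - a$ref_start[last]
    } else {
      keep[t] <- TRUE
      last <- t
    }
  }
  a <- a[keep, , drop = FALSE]
  # resolve residual overlaps (different diagonals) by front-trimming in
  # reference order; trimming an exact match keeps it an exact match
  a <- a[order(a$ref_start, a$qry_start), , drop = FALSE]
  out <- list()
  prev_re <- 0L; prev_qe <- 0L
  for (t in seq_len(nrow(a))) {
    s1 <- a$ref_start[t]; s2 <- a$qry_start[t]; l <- a$length[t]
    cut <- max(prev_re - s1 + 1L, prev_qe - s2 + 1L, 0L)
    s1 <- s1 + cut; s2 <- s2 + cut; l <- l - cut
    if (l >= 1L) {
      out[[length(out) + 1L]] <- c(s1, s2, l)
      prev_re <- s1 + l - 1L; prev_qe <- s2 + l - 1L
    }
  }
  a <- as.data.frame(do.call(rbind, out))
  names(a) <- c("ref_start", "qry_start", "length")
  rownames(a) <- NULL
  a
}

#' Select the best collinear chain of anchors
#'
#' Maximum-coverage chain that is strictly increasing in both
#' coordinates (weighted longest-increasing-subsequence on anchor
#' lengths); score ties are broken towards the chain using the anchor
#' with the smaller reference position.
#'
#' @param anchors Data frame `ref_start, qry_start, length`.
#' @return The chained subset, sorted by `ref_start`.
#' @export
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(anchors)
  a <- anchors[order(anchors$ref_start, anchors$qry_start), , drop = FALSE]
  re <- a$ref_start + a$length - 1L
  qe <- a$qry_start + a$length - 1L
  score <- as.numeric(a$length)
  prev <- rep(NA_integer_, n)
  for (t in seq_len(n)) {
    for (u in seq_len(t - 1L)) {
      if (re[u] < a$ref_start[t] && qe[u] < a$qry_start[t]) {
        cand <- score[u] + a$length[t]
        if (cand > score[t]) { score[t] <- cand; prev[t] <- u }
      }
    }
  }
  best <- which(score == max(score))[1L]
  chain <- integer(0)
  t <- best
  while (!is.na(t)) { chain <- c(t, chain); t <- prev[t] }
  out <- a[chain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

consensus_variant_frame <- function() {
  data.frame(kind = character(0), ref_pos = integer(0), qry_pos = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             length_delta = integer(0), stringsAsFactors = FALSE)
}

# SNPs and indels from one aligned gap; offsets are the last ref/qry
# positions before the gap
extract_gap_variants <- function(ref_chunk, qry_chunk, ref_off, qry_off) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qry_chunk),
    subject = Biostrings::DNAString(ref_chunk),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_at <- cumsum(ra != "-")
  qry_at <- cumsum(qa != "-")
  vars <- list()
  mism <- which(ra != "-" & qa != "-" & ra != qa)
  if (length(mism))
    vars$snp <- data.frame(kind = "SNP",
                           ref_pos = ref_off + ref_at[mism],
                           qry_pos = qry_off + qry_at[mism],
                           ref_allele = ra[mism], alt_allele = qa[mism],
                           length_delta = 0L, stringsAsFactors = FALSE)
  gap_runs <- function(is_gap) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  dr <- gap_runs(qa == "-")          # qry gap = deletion from reference
  if (nrow(dr))
    vars$del <- data.frame(
      kind = "DIP",
      ref_pos = ref_off + ref_at[dr[, 1L]],
      qry_pos = qry_off + qry_at[dr[, 1L]] + 1L,
      ref_allele = vapply(seq_len(nrow(dr)), function(x)
        paste(ra[dr[x, 1L]:dr[x, 2L]], collapse = ""), ""),
      alt_allele = "", stringsAsFactors = FALSE)
  ir <- gap_runs(ra == "-")          # ref gap = insertion in query
  if (nrow(ir))
    vars$ins <- data.frame(
      kind = "DIP",
      ref_pos = ref_off + ref_at[ir[, 1L]] + 1L,
      qry_pos = qry_off + qry_at[ir[, 1L]],
      ref_allele = "",
      alt_allele = vapply(seq_len(nrow(ir)), function(x)
        paste(qa[ir[x, 1L]:ir[x, 2L]], collapse = ""), ""),
      stringsAsFactors = FALSE)
  out <- do.call(rbind, vars)
  if (is.null(out)) return(consensus_variant_frame())
  if (!is.null(vars$del))
    out$length_delta[out$kind == "DIP" & out$alt_allele == ""] <-
      -nchar(out$ref_allele[out$kind == "DIP" & out$alt_allele == ""])
  if (!is.null(vars$ins))
    out$length_delta[out$kind == "DIP" & out$ref_allele == ""] <-
      nchar(out$alt_allele[out$kind == "DIP" & out$ref_allele == ""])
  out$length_delta[out$kind == "SNP"] <- 0L
  out
}

#' Compare two collinear genomes
#'
#' Chains unique-k-mer anchors, closes small inter-anchor gaps by global
#' alignment (match +1, mismatch −1, gap open −2, gap extend −1), and
#' classifies large reference-only gaps as deleted segments and large
#' query-only gaps as inserted segments.  SNPs are per-position (a run
#' of n adjacent mismatches is n SNPs); DIPs are left-normalized against
#' the reference; any indel of at least `min_segment_len` is reported as
#' a segment, never as a DIP, so the two counts are disjoint.  Applying
#' all reported variants and segments to the reference reconstructs the
#' query exactly.
#'
#' @param ref,qry Reference and query [genome_seq()] objects (same
#'   origin convention; rotation is not searched).
#' @param config A [run_config()] supplying `anchor_k`, `band` and
#'   `min_segment_len`.
#' @return A list of class `genome_diff`: `variants` (SNP/DIP data
#'   frame with both coordinate systems), `deleted_segments`
#'   (`ref_start, ref_end, length`), `inserted_segments` (`ref_pos,
#'   qry_start, qry_end, length, seq`), and `chain` (the anchor chain).
#' @export
diff_genomes <- function(ref, qry, config = run_config()) {
  rs <- as_seq_string(ref); qs <- as_seq_string(qry)
  anchors <- find_anchors(rs, qs, config$anchor_k)
  if (nrow(anchors) == 0L)
    stop("diff_genomes: no anchors found; the inputs do not look like collinear homologs")
  chain <- chain_anchors(anchors)
  band <- config$band
  msl <- config$min_segment_len
  nr <- nchar(rs); nq <- nchar(qs)
  bounds <- rbind(
    cbind(ref_end = c(0L, chain$ref_start + chain$length - 1L),
          qry_end = c(0L, chain$qry_start + chain$length - 1L),
          ref_next = c(chain$ref_start, nr + 1L),
          qry_next = c(chain$qry_start, nq + 1L)))
  vars <- list(); dels <- list(); inss <- list()
  for (g in seq_len(nrow(bounds))) {
    r0 <- bounds[g, "ref_end"]; q0 <- bounds[g, "qry_end"]
    r1 <- bounds[g, "ref_next"]; q1 <- bounds[g, "qry_next"]
    lr <- r1 - r0 - 1L; lq <- q1 - q0 - 1L
    if (lr <= 0L && lq <= 0L) next
    if (lr > 0L && lq == 0L) {
      if (lr >= msl) {
        dels[[length(dels) + 1L]] <- data.frame(
          ref_start = r0 + 1L, ref_end = r1 - 1L, length = lr)
      } else {
        vars[[length(vars) + 1L]] <- data.frame(
          kind = "DIP", ref_pos = r0 + 1L, qry_pos = q0 + 1L,
          ref_allele = substr(rs, r0 + 1L, r1 - 1L), alt_allele = "",
          length_delta = -lr, stringsAsFactors = FALSE)
      }
    } else if (lq > 0L && lr == 0L) {
      if (lq >= msl) {
        inss[[length(inss) + 1L]] <- data.frame(
          ref_pos = r0 + 1L, qry_start = q0 + 1L, qry_end = q1 - 1L,
          length = lq, seq = substr(qs, q0 + 1L, q1 - 1L),
          stringsAsFactors = FALSE)
      } else {
        vars[[length(vars) + 1L]] <- data.frame(
          kind = "DIP", ref_pos = r0 + 1L, qry_pos = q0 + 1L,
          ref_allele = "", alt_allele = substr(qs, q0 + 1L, q1 - 1L),
          length_delta = lq, stringsAsFactors = FALSE)
      }
    } else if (min(lr, lq) <= band && max(lr, lq) <= max(band, 10L * msl)) {
      gv <- extract_gap_variants(substr(rs, r0 + 1L, r1 - 1L),
                                 substr(qs, q0 + 1L, q1 - 1L), r0, q0)
      big_del <- gv$kind == "DIP" & gv$length_delta <= -msl
      big_ins <- gv$kind == "DIP" & gv$length_delta >= msl
      if (any(big_del))
        dels[[length(dels) + 1L]] <- data.frame(
          ref_start = gv$ref_pos[big_del],
          ref_end = gv$ref_pos[big_del] - gv$length_delta[big_del] - 1L,
          length = -gv$length_delta[big_del])
      if (any(big_ins))
        inss[[length(inss) + 1L]] <- data.frame(
          ref_pos = gv$ref_pos[big_ins], qry_start = gv$qry_pos[big_ins],
          qry_end = gv$qry_pos[big_ins] + gv$length_delta[big_ins] - 1L,
          length = gv$length_delta[big_ins],
          seq = gv$alt_allele[big_ins], stringsAsFactors = FALSE)
      gv <- gv[!(big_del | big_ins), , drop = FALSE]
      if (nrow(gv)) vars[[length(vars) + 1L]] <- gv
    } else {
      # both sides large: substitution-level detail is not recoverable,
      # report the replacement as one deleted plus one inserted segment
      dels[[length(dels) + 1L]] <- data.frame(
        ref_start = r0 + 1L, ref_end = r1 - 1L, length = lr)
      inss[[length(inss) + 1L]] <- data.frame(
        ref_pos = r0 + 1L, qry_start = q0 + 1L, qry_end = q1 - 1L,
        length = lq, seq = substr(qs, q0 + 1L, q1 - 1L),
        stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(vars)) do.call(rbind, vars) else consensus_variant_frame()
  if (nrow(variants)) {
    dip <- which(variants$kind == "DIP")
    for (i in dip) {
      nn <- left_normalize_indel(rs, variants$ref_pos[i],
                                 variants$ref_allele[i],
                                 variants$alt_allele[i])
      variants$qry_pos[i] <- variants$qry_pos[i] - nn$shift
      variants$ref_pos[i] <- nn$pos
      variants$ref_allele[i] <- nn$ref
      variants$alt_allele[i] <- nn$alt
    }
    variants <- variants[order(variants$ref_pos, variants$qry_pos), ,
                         drop = FALSE]
    rownames(variants) <- NULL
  }
  deleted <- if (length(dels)) do.call(rbind, dels) else
    data.frame(ref_start = integer(0), ref_end = integer(0),
               length = integer(0))
  inserted <- if (length(inss)) do.call(rbind, inss) else
    data.frame(ref_pos = integer(0), qry_start = integer(0),
               qry_end = integer(0), length = integer(0),
               seq = character(0), stringsAsFactors = FALSE)
  rownames(deleted) <- NULL; rownames(inserted) <- NULL
  structure(list(variants = variants, deleted_segments = deleted,
                 inserted_segments = inserted, chain = chain),
            class = "genome_diff")
}

#' @export
print.genome_diff <- function(x, ...) {
  cat(sprintf(
    "<genome_diff> %d SNPs, %d DIPs, %d deleted segment(s), %d inserted segment(s)\n",
    sum(x$variants$kind == "SNP"), sum(x$variants$kind == "DIP"),
    nrow(x$deleted_segments), nrow(x$inserted_segments)))
  invisible(x)
}

#' Convert a genome diff to an edit table
#'
#' Expresses a [diff_genomes()] result as the edit set (in reference
#' coordinates) accepted by [apply_edits()] and [lift_position()];
#' applying it to the reference reconstructs the query.
#'
#' @param diff A `genome_diff`.
#' @param ref The reference [genome_seq()] or string (needed to spell
#'   out the content of deleted segments).
#' @return An edit data frame (`kind, pos, ref, alt`).
#' @export
edits_from_diff <- function(diff, ref) {
  rs <- as_seq_string(ref)
  v <- diff$variants
  rows <- list()
  if (nrow(v))
    rows$v <- data.frame(
      kind = ifelse(v$kind == "SNP", "snp",
                    ifelse(v$alt_allele == "", "del", "ins")),
      pos = v$ref_pos, ref = v$ref_allele, alt = v$alt_allele,
      stringsAsFactors = FALSE)
  d <- diff$deleted_segments
  if (nrow(d))
    rows$d <- data.frame(kind = "del", pos = d$ref_start,
                         ref = substring(rs, d$ref_start, d$ref_end),
                         alt = "", stringsAsFactors = FALSE)
  i <- diff$inserted_segments
  if (nrow(i))
    rows$i <- data.frame(kind = "ins", pos = i$ref_pos, ref = "",
                         alt = i$seq, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(kind = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Classify the presence of a reference region in a query genome
#'
#' Reports the fraction of a reference interval covered by chained
#' anchors against the query: `intact` when at least 99% is covered,
#' `absent` below 5%, `partial` otherwise.
#'
#' @param region Length-2 integer vector `c(start, end)` in reference
#'   coordinates.
#' @param ref,qry [genome_seq()] objects.
#' @param config A [run_config()].
#' @return A list: `classification`, `fraction`, `covered_bp`,
#'   `region_length`.
#' @export
locate_region <- function(region, ref, qry, config = run_config()) {
  stopifnot(length(region) == 2L, region[1L] <= region[2L])
  chain <- chain_anchors(find_anchors(as_seq_string(ref),
                                      as_seq_string(qry), config$anchor_k))
  s <- region[1L]; e <- region[2L]
  covered <- 0L
  if (nrow(chain)) {
    a_s <- pmax(chain$ref_start, s)
    a_e <- pmin(chain$ref_start + chain$length - 1L, e)
    covered <- sum(pmax(a_e - a_s + 1L, 0L))
  }
  len <- e - s + 1L
  frac <- covered / len
  cls <- if (frac >= 0.99) "intact" else if (frac < 0.05) "absent" else "partial"
  list(classification = cls, fraction = frac, covered_bp = covered,
       region_length = len)
}
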