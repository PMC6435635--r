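# Multi-sensitivity scanning of pileups for sub-consensus variants, and
# consensus calling.  The threshold comparison is inclusive (>=): a
# variant at exactly the tier frequency is reported.

# consensus base index per site among A/C/G/T/del, ties resolved in
# favour of the reference allele (and otherwise by A<C<G<T<del order)
consensus_call <- function(p) {
  m <- cbind(A = p$A, C = p$C, G = p$G, T = p$T, del = p$del)
  mx <- pmax(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L])
  ref_idx <- match(p$ref_base, c("A", "C", "G", "T"))
  ref_count <- m[cbind(seq_len(nrow(m)), ref_idx)]
  call <- max.col(m, ties.method = "first")
  call[ref_count == mx] <- ref_idx[ref_count == mx]
  colnames(m)[call]
}

pop_variant_frame <- function(pos = integer(0), ref_allele = character(0),
                              alt_allele = character(0),
                              frequency = numeric(0), depth = integer(0),
                              tiers = character(0)) {
  df <- data.frame(pos = as.integer(pos), ref_allele = ref_allele,
                   alt_allele = alt_allele, frequency = frequency,
                   depth = as.integer(depth), tiers = tiers,
                   stringsAsFactors = FALSE)
  class(df) <- c("pop_variants", "data.frame")
  df
}

tier_label <- function(freq, tiers) {
  vapply(freq, function(f) paste(tiers[tiers <= f], collapse = ","), "")
}

#' Scan pileups for sub-consensus variants at one sensitivity tier
#'
#' Reports, per site with depth at least `min_depth`, every
#' non-reference allele whose read frequency is at least `tier`
#' (multiallelic sites yield one record per allele).  Deletion and
#' insertion evidence is reported under the same rule, with
#' `alt_allele` `"-"` (deletion of the site) or `"+SEQ"` (insertion
#' after the site).  The consensus allele itself — the majority call,
#' ties resolved towards the reference — is never reported as a
#' population variant, nor is the reference allele; insertions
#' supported by a read majority are treated as consensus likewise.
#'
#' @param pileups A `site_pileup` data frame.
#' @param tier Frequency threshold in `(0, 1]`.
#' @param min_depth Minimum depth for a site to be scanned.
#' @param tiers_config Optional full tier vector used to label each
#'   variant with every configured tier at which it would be reported;
#'   defaults to just `tier`.
#' @return A `pop_variants` data frame: `pos, ref_allele, alt_allele,
#'   frequency, depth, tiers`, sorted by position.
#' @export
scan_sites <- function(pileups, tier, min_depth = 10L, tiers_config = NULL) {
  stopifnot(tier > 0, tier <= 1)
  if (is.null(tiers_config)) tiers_config <- tier
  if (is.null(pileups) || nrow(pileups) == 0L) return(pop_variant_frame())
  p <- pileups[pileups$depth >= max(min_depth, 1L), , drop = FALSE]
  if (nrow(p) == 0L) return(pop_variant_frame())
  cons <- consensus_call(p)
  out <- vector("list", 6L)
  bases <- c("A", "C", "G", "T")
  for (b in bases) {
    f <- p[[b]] / p$depth
    sel <- which(p$ref_base != b & cons != b & f >= tier)
    out[[match(b, bases)]] <- if (length(sel))
      pop_variant_frame(p$pos[sel], p$ref_base[sel], b, f[sel],
                        p$depth[sel], tier_label(f[sel], tiers_config))
  }
  fdel <- p$del / p$depth
  sel <- which(cons != "del" & fdel >= tier)
  out[[5L]] <- if (length(sel))
    pop_variant_frame(p$pos[sel], p$ref_base[sel], "-", fdel[sel],
                      p$depth[sel], tier_label(fdel[sel], tiers_config))
  with_ins <- which(!is.na(p$ins) & p$ins != "." & nzchar(p$ins))
  if (length(with_ins)) {
    ins_rows <- lapply(with_ins, function(i) {
      cts <- parse_ins(p$ins[i])
      f <- cts / p$depth[i]
      keep <- f >= tier & f <= 0.5
      if (!any(keep)) return(NULL)
      pop_variant_frame(rep(p$pos[i], sum(keep)),
                        rep(p$ref_base[i], sum(keep)),
                        paste0("+", names(cts)[keep]), unname(f[keep]),
                        rep(p$depth[i], sum(keep)),
                        tier_label(unname(f[keep]), tiers_config))
    })
    out[[6L]] <- do.call(rbind, ins_rows)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) return(pop_variant_frame())
  res <- res[order(res$pos, res$alt_allele), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan pileups across all configured sensitivity tiers
#'
#' Equivalent to the union of per-tier scans: one record per
#' (site, alternate allele) pair with its full tier set (every
#' configured tier at or below the observed frequency).
#'
#' @param pileups A `site_pileup` data frame.
#' @param config A [run_config()] supplying `sensitivity_tiers` and
#'   `min_depth`.
#' @return A `pop_variants` data frame.
#' @export
scan_all_tiers <- function(pileups, config = run_config()) {
  tiers <- config$sensitivity_tiers
  scan_sites(pileups, tier = min(tiers), min_depth = config$min_depth,
             tiers_config = tiers)
}

#' Call the consensus sequence from pileups
#'
#' Per covered site the consensus allele is the count argmax (ties
#' resolved in favour of the reference allele).  Sites the pileup does
#' not cover, or covers with zero depth, are emitted as `N` and
#' reported as undetermined spans.  Majority deletions remove the site
#' from the consensus; majority insertions (insertion frequency above
#' 0.5) are inserted after it — both are reported as differences with
#' reference and query coordinates.
#'
#' @param pileups A `site_pileup` data frame.
#' @param reference The reference [genome_seq()] the pileup positions
#'   refer to.
#' @return A list: `consensus` ([genome_seq()]), `differences` (data
#'   frame `kind, ref_pos, qry_pos, ref_allele, alt_allele`), and
#'   `n_spans` (data frame `start, end` of undetermined runs).
#' @export
call_consensus <- function(pileups, reference) {
  n <- seq_length(reference)
  refc <- strsplit(reference$seq, "")[[1]]
  out <- refc
  covered <- rep(FALSE, n)
  diffs <- list()
  ins_after <- rep("", n)
  if (!is.null(pileups) && nrow(pileups) > 0L) {
    p <- pileups[pileups$depth > 0L & pileups$pos >= 1L & pileups$pos <= n, ,
                 drop = FALSE]
    covered[p$pos] <- TRUE
    cons <- consensus_call(p)
    snp <- which(cons != "del" & cons != p$ref_base)
    if (length(snp))
      diffs$snp <- data.frame(kind = "SNP", ref_pos = p$pos[snp],
                              ref_allele = p$ref_base[snp],
                              alt_allele = cons[snp], stringsAsFactors = FALSE)
    del <- which(cons == "del")
    if (length(del))
      diffs$del <- data.frame(kind = "DIP", ref_pos = p$pos[del],
                              ref_allele = p$ref_base[del],
                              alt_allele = "", stringsAsFactors = FALSE)
    out[p$pos] <- ifelse(cons == "del", "", cons)
    with_ins <- which(!is.na(p$ins) & p$ins != "." & nzchar(p$ins))
    for (i in with_ins) {
      cts <- parse_ins(p$ins[i])
      f <- cts / p$depth[i]
      j <- which(f > 0.5)
      if (length(j)) {
        ins_after[p$pos[i]] <- names(cts)[j[1L]]
        diffs$ins <- rbind(diffs$ins, data.frame(
          kind = "DIP", ref_pos = p$pos[i] + 1L, ref_allele = "",
          alt_allele = names(cts)[j[1L]], stringsAsFactors = FALSE))
      }
    }
  }
  out[!covered] <- "N"
  spans <- integer(0)
  r <- rle(!covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  n_spans <- data.frame(start = starts[r$values], end = ends[r$values])
  # query coordinates: cumulative length of emitted consensus text
  widths <- nchar(out) + nchar(ins_after)
  qry_at <- cumsum(widths) - widths + 1L
  dd <- do.call(rbind, diffs)
  if (is.null(dd)) {
    dd <- data.frame(kind = character(0), ref_pos = integer(0),
                     qry_pos = integer(0), ref_allele = character(0),
                     alt_allele = character(0), stringsAsFactors = FALSE)
  } else {
    dd$qry_pos <- qry_at[pmin(dd$ref_pos, n)]
    dd <- dd[order(dd$ref_pos), c("kind", "ref_pos", "qry_pos",
                                  "ref_allele", "alt_allele")]
    rownames(dd) <- NULL
  }
  seq_out <- paste(paste0(out, ins_after), collapse = "")
  list(consensus = genome_seq(paste0(reference$id, "_consensus"), seq_out,
                              reference$circular),
       differences = dd, n_spans = n_spans)
}
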