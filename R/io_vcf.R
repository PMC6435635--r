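#' Write variants to a VCF v4.2 file
#'
#' Accepts either population variants (from [scan_sites()] /
#' [scan_all_tiers()]; columns `pos, ref_allele, alt_allele, frequency,
#' depth, tiers`) or consensus variants (from [diff_genomes()]; columns
#' `kind, ref_pos, qry_pos, ref_allele, alt_allele`).  Indels are
#' emitted with the preceding reference base as anchor per the VCF
#' convention (the following base if the event touches position 1).
#' Population records carry `AF` and `TIERS` INFO keys plus `DP`;
#' consensus records omit `AF` and carry `TYPE` and `QPOS` instead.
#'
#' @param variants A variant data frame (may have zero rows).
#' @param ref The reference [genome_seq()] the positions refer to
#'   (needed for indel anchor bases; its id becomes the CHROM column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, ref, path) {
  stopifnot(inherits(ref, "genome_seq"))
  n_ref <- nchar(ref$seq)
  is_pop <- "frequency" %in% names(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$id, n_ref),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele read frequency\">",
    "##INFO=<ID=TIERS,Number=.,Type=Float,Description=\"Sensitivity tiers at which the variant is reported\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Consensus variant kind (SNP or DIP)\">",
    "##INFO=<ID=QPOS,Number=1,Type=Integer,Description=\"Query-genome coordinate of the variant\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  rows <- character(0)
  if (!is.null(variants) && nrow(variants) > 0L) {
    rows <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      if (is_pop) {
        pos <- v$pos
        if (pos < 1L || pos > n_ref)
          stop("write_vcf: position ", pos, " outside reference ", ref$id)
        if (v$alt_allele == "-") {                      # deletion of this base
          a <- vcf_anchor_indel(ref$seq, pos, del = substr(ref$seq, pos, pos),
                                ins = "")
        } else if (startsWith(v$alt_allele, "+")) {     # insertion after pos
          a <- vcf_anchor_indel(ref$seq, pos + 1L, del = "",
                                ins = sub("^\\+", "", v$alt_allele))
        } else {
          a <- list(pos = pos, ref = v$ref_allele, alt = v$alt_allele)
        }
        info <- sprintf("DP=%d;AF=%s;TIERS=%s", as.integer(v$depth),
                        format(v$frequency, trim = TRUE), v$tiers)
      } else {
        pos <- v$ref_pos
        if (pos < 1L || pos > n_ref + 1L)
          stop("write_vcf: position ", pos, " outside reference ", ref$id)
        if (v$kind == "SNP") {
          a <- list(pos = pos, ref = v$ref_allele, alt = v$alt_allele)
        } else {
          a <- vcf_anchor_indel(ref$seq, pos, del = v$ref_allele,
                                ins = v$alt_allele)
        }
        info <- sprintf("TYPE=%s;QPOS=%d", v$kind, as.integer(v$qry_pos))
      }
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", ref$id, a$pos, a$ref, a$alt, info)
    }, "")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# VCF-style anchoring for an indel at reference position `pos`:
# `del` is the deleted reference run starting at pos ("" for pure
# insertion before pos), `ins` the inserted sequence.
vcf_anchor_indel <- function(refseq, pos, del, ins) {
  l_del <- nchar(del)
  if (pos > 1L) {
    anchor <- substr(refseq, pos - 1L, pos - 1L)
    list(pos = pos - 1L,
         ref = paste0(anchor, del),
         alt = paste0(anchor, ins))
  } else {
    # event at position 1: anchor on the base following the event
    nxt <- substr(refseq, l_del + 1L, l_del + 1L)
    list(pos = 1L,
         ref = paste0(del, nxt),
         alt = paste0(ins, nxt))
  }
}
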