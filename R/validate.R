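#' Full strain-vs-reference validation report
#'
#' Runs the complete consensus-comparison pipeline on a strain genome
#' against an annotated reference genome and itemises everything the
#' comparison yields: SNP and DIP totals, deleted-segment coordinates,
#' the intergenic / synonymous / amino-acid-changing split of the SNPs,
#' genome length and GC content of the strain, the strain-side length
#' of a named gene (e.g. the frameshift-restored *sfp*), and calls
#' lying within `boundary_pad` of a deleted-segment edge (reported
#' separately, since different tools disagree on those).  Works on any
#' FASTA + GFF3 pair with a shared origin convention, e.g. downloaded
#' GenBank-derived records or the package's own simulated scenario.
#'
#' @param ref,qry Reference and query (strain) [genome_seq()] objects,
#'   or paths to single-record FASTA files.
#' @param annotations Reference [feature_annotation()] or a GFF3 path.
#' @param config A [run_config()].
#' @param gene_of_interest Gene name whose strain-side CDS length is
#'   extracted (default `"sfp"`); skipped when absent.
#' @param region Optional `c(start, end)` reference interval classified
#'   by [locate_region()].
#' @param boundary_pad Distance (bp) from a segment edge within which a
#'   call counts as boundary-adjacent.
#' @return A list of class `validation_report`.
#' @export
reference_validation_report <- function(ref, qry, annotations,
                                        config = run_config(),
                                        gene_of_interest = "sfp",
                                        region = NULL,
                                        boundary_pad = 100L) {
  if (is.character(ref)) ref <- read_fasta(ref)[[1L]]
  if (is.character(qry)) qry <- read_fasta(qry)[[1L]]
  if (is.character(annotations)) annotations <- read_gff3(annotations)
  d <- diff_genomes(ref, qry, config)
  v <- d$variants
  snps <- v[v$kind == "SNP", , drop = FALSE]
  dips <- v[v$kind == "DIP", , drop = FALSE]
  eff <- annotate_variants(snps, annotations, ref)
  sev <- most_severe_effect(eff)
  n_aa <- sum(sev$category %in% c("missense", "stop_gain", "stop_loss"))
  n_syn <- sum(sev$category == "synonymous")
  n_inter <- sum(sev$category == "intergenic")
  dip_alloc <- allocate_dips(
    data.frame(pos = dips$ref_pos, ref = dips$ref_allele,
               alt = dips$alt_allele, stringsAsFactors = FALSE),
    annotations)
  segs <- d$deleted_segments
  near <- logical(nrow(v))
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs)))
      near <- near |
        (abs(v$ref_pos - segs$ref_start[i]) <= boundary_pad) |
        (abs(v$ref_pos - segs$ref_end[i]) <= boundary_pad)
  }
  gene_len <- NA_integer_
  goi <- annotations[annotations$gene_name == gene_of_interest, , drop = FALSE]
  if (nrow(goi) == 1L) {
    ed <- edits_from_diff(d, ref)
    qs <- lift_position(goi$start, ed)
    qe <- lift_position(goi$end, ed)
    if (!is.na(qs) && !is.na(qe)) gene_len <- qe - qs + 1L
  }
  region_report <- if (!is.null(region))
    locate_region(region, ref, qry, config) else NULL
  structure(list(
    n_snps = nrow(snps), n_dips = nrow(dips),
    deleted_segments = segs, inserted_segments = d$inserted_segments,
    first_deleted_segment_start = if (nrow(segs)) min(segs$ref_start)
                                  else NA_integer_,
    snp_intergenic = n_inter, snp_synonymous = n_syn,
    snp_aa_changing = n_aa,
    dips_in_gene = dip_alloc$in_gene,
    dips_intergenic = dip_alloc$intergenic,
    qry_length = seq_length(qry), qry_gc = gc_content(qry),
    gene_of_interest = gene_of_interest,
    gene_of_interest_qry_len = gene_len,
    boundary_adjacent = v[near, , drop = FALSE],
    region = region_report,
    variants = v), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  query genome: %s bp, GC %.1f%%\n",
              format(x$qry_length, big.mark = ","), x$qry_gc))
  cat(sprintf("  SNPs: %d (intergenic %d, synonymous %d, aa-changing %d)\n",
              x$n_snps, x$snp_intergenic, x$snp_synonymous,
              x$snp_aa_changing))
  cat(sprintf("  DIPs: %d (in genes %d, intergenic %d)\n",
              x$n_dips, x$dips_in_gene, x$dips_intergenic))
  if (nrow(x$deleted_segments))
    cat(sprintf("  deleted segments: %s\n",
                paste(sprintf("%d-%d", x$deleted_segments$ref_start,
                              x$deleted_segments$ref_end),
                      collapse = ", ")))
  if (!is.na(x$gene_of_interest_qry_len))
    cat(sprintf("  %s length in query: %d bp\n", x$gene_of_interest,
                x$gene_of_interest_qry_len))
  cat(sprintf("  boundary-adjacent calls: %d\n",
              nrow(x$boundary_adjacent)))
  invisible(x)
}
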