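# Codon-level consequence annotation of SNPs and DIPs against a CDS
# annotation, including frameshift/ORF-restoration analysis and
# amino-acid property-transition classification.

# Property classes.  Charge: acidic {D,E}, basic {K,R,H}, all others
# neutral.  Size: the common small/large split — small
# {G,A,S,C,T,P,N,D,V}, large the remaining eleven residues.  These two
# tables are the load-bearing interpretive choice of the whole
# property-transition classification and are pinned here.
AA_ACIDIC <- c("D", "E")
AA_BASIC <- c("K", "R", "H")
AA_SMALL <- c("G", "A", "S", "C", "T", "P", "N", "D", "V")
AA_ALL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_LARGE <- setdiff(AA_ALL, AA_SMALL)

charge_class <- function(aa1) {
  ifelse(aa1 %in% AA_ACIDIC, "acidic",
         ifelse(aa1 %in% AA_BASIC, "basic", "neutral"))
}

size_class <- function(aa1) ifelse(aa1 %in% AA_SMALL, "small", "large")

# severity order used when one variant hits several overlapping genes
EFFECT_SEVERITY <- c(frameshift = 7, stop_gain = 6, stop_loss = 5,
                     missense = 4, inframe_indel = 3, synonymous = 2,
                     intergenic = 1)

#' Classify the physico-chemical transition of an amino-acid change
#'
#' Charge transitions (acidic/basic/neutral) take precedence over size
#' transitions (small/large); a change to a stop codon is a
#' `truncation`; `none` when neither class changes.
#'
#' @param aa_from,aa_to Amino acids, one- or three-letter (`"*"` for
#'   stop).
#' @return One of `neutral_to_basic`, `basic_to_neutral`,
#'   `neutral_to_acidic`, `acidic_to_neutral`, `acidic_to_basic`,
#'   `basic_to_acidic`, `small_to_large`, `large_to_small`,
#'   `truncation`, `none`.
#' @examples
#' classify_property_transition("Asn", "Lys")  # neutral_to_basic
#' classify_property_transition("Arg", "Ser")  # basic_to_neutral
#' classify_property_transition("Leu", "Ile")  # none
#' @export
classify_property_transition <- function(aa_from, aa_to) {
  f <- aa_one_letter(aa_from); t <- aa_one_letter(aa_to)
  if (t == "*") return("truncation")
  if (f == "*") return("none")
  cf <- charge_class(f); ct <- charge_class(t)
  if (cf != ct) return(paste0(cf, "_to_", ct))
  if (size_class(f) != size_class(t))
    return(paste0(size_class(f), "_to_", size_class(t)))
  "none"
}

variant_effect_row <- function(pos, gene = NA_character_,
                               gene_name = NA_character_,
                               category, codon_index = NA_integer_,
                               aa_change = NA_character_,
                               property_transition = "none",
                               spans_boundary = FALSE) {
  data.frame(pos = as.integer(pos), gene = gene, gene_name = gene_name,
             category = category, codon_index = as.integer(codon_index),
             aa_change = aa_change,
             property_transition = property_transition,
             spans_boundary = spans_boundary, stringsAsFactors = FALSE)
}

#' Annotate a single-nucleotide variant against the annotation
#'
#' Maps the position to its codon and residue index (strand-aware: on
#' `-` strand genes the codon is read from the reverse complement), and
#' classifies the change.  A SNP inside several overlapping CDS features
#' yields one row per feature; outside any CDS it is `intergenic`.
#'
#' @param pos 1-based genome position.
#' @param ref,alt Reference and alternate base (genome / plus strand).
#' @param annotations A [feature_annotation()] data frame.
#' @param genome The [genome_seq()] the coordinates refer to.
#' @return A data frame with columns `pos, gene, gene_name, category,
#'   codon_index, aa_change, property_transition, spans_boundary`.
#' @export
annotate_snp <- function(pos, ref, alt, annotations, genome) {
  gseq <- as_seq_string(genome)
  have <- substr(gseq, pos, pos)
  if (have != ref)
    stop(sprintf(
      "annotate_snp: reference allele mismatch at %d (variant says %s, genome has %s)",
      pos, ref, have))
  hits <- annotations[annotations$kind == "CDS" &
                        annotations$start <= pos & annotations$end >= pos, ,
                      drop = FALSE]
  if (nrow(hits) == 0L)
    return(variant_effect_row(pos, category = "intergenic"))
  out <- lapply(seq_len(nrow(hits)), function(i) {
    ft <- hits[i, ]
    cd <- codon_at(genome, ft, pos)
    alt_in_cds <- if (ft$strand == "-") comp_base(alt) else alt
    alt_codon <- cd$codon
    substr(alt_codon, cd$within + 1L, cd$within + 1L) <- alt_in_cds
    ref_aa <- translate_codons(cd$codon, init = cd$index == 1L)
    alt_aa <- translate_codons(alt_codon, init = cd$index == 1L)
    category <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gain"
      else if (ref_aa == "*") "stop_loss"
      else "missense"
    aa_change <- if (category %in% c("missense", "stop_gain", "stop_loss"))
      paste0(aa_three_letter(ref_aa), cd$index, aa_three_letter(alt_aa))
    else NA_character_
    pt <- if (category == "missense")
      classify_property_transition(ref_aa, alt_aa)
    else if (category == "stop_gain") "truncation" else "none"
    variant_effect_row(pos, ft$feature_id, ft$gene_name, category,
                       cd$index, aa_change, pt)
  })
  do.call(rbind, out)
}

#' Annotate a deletion-insertion polymorphism
#'
#' For a DIP inside a CDS the alternative gene is built by applying the
#' indel and both versions are translated to their first stop.  A length
#' change divisible by 3 is an `inframe_indel`; otherwise a
#' `frameshift`, with the ORF comparison classifying it as
#' `frame_restoring` (the reference frame carries an internal stop and
#' the shifted frame reads through to the full expected length),
#' `truncated` (the shifted frame stops earlier than the reference
#' product), or `frame_disrupting`.  In-frame indels are classified
#' `unchanged` / `truncated` / `extended` by product length.  A DIP
#' spanning a CDS boundary is annotated against each overlapped feature
#' and flagged.
#'
#' @param pos 1-based position: first deleted base for a deletion, or
#'   the base before which the insertion occurs.
#' @param ref Deleted reference run (`""` for an insertion).
#' @param alt Inserted sequence (`""` for a deletion).
#' @inheritParams annotate_snp
#' @return A list with `effects` (a data frame as in [annotate_snp()],
#'   category `inframe_indel`, `frameshift` or `intergenic`) and `orf`
#'   (a data frame with `gene, ref_protein_len, alt_protein_len,
#'   classification`, or `NULL` for intergenic DIPs).
#' @export
analyze_dip <- function(pos, ref, alt, annotations, genome) {
  gseq <- as_seq_string(genome)
  l_ref <- nchar(ref); l_alt <- nchar(alt)
  if ((l_ref == 0L) == (l_alt == 0L))
    stop("analyze_dip: exactly one of ref/alt must be empty after normalization")
  if (l_ref > 0L && substr(gseq, pos, pos + l_ref - 1L) != ref)
    stop("analyze_dip: reference run mismatch at ", pos)
  delta <- l_alt - l_ref
  # genomic footprint used for the overlap rule: every deleted base for a
  # deletion; the insertion point (strictly inside a gene) for an insertion
  if (l_ref > 0L) {
    cds_hit <- annotations$kind == "CDS" &
      annotations$start <= pos + l_ref - 1L & annotations$end >= pos
  } else {
    cds_hit <- annotations$kind == "CDS" &
      annotations$start < pos & annotations$end >= pos
  }
  hits <- annotations[cds_hit, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(list(effects = variant_effect_row(pos, category = "intergenic"),
                orf = NULL))
  mutated <- apply_edits(gseq, data.frame(
    kind = if (l_ref > 0L) "del" else "ins", pos = pos, ref = ref,
    alt = alt, stringsAsFactors = FALSE))
  eff <- vector("list", nrow(hits)); orf <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ft <- hits[i, ]
    inside <- if (l_ref > 0L)
      pos >= ft$start && (pos + l_ref - 1L) <= ft$end else TRUE
    # feature coordinates in the mutated genome: events inside the gene
    # shift its end by delta; the gene body before `pos` is unchanged
    new_end <- ft$end + if (pos <= ft$end) delta else 0L
    alt_cds <- substr(mutated, ft$start, new_end)
    if (ft$strand == "-") alt_cds <- revcomp(alt_cds)
    ref_tr <- translate_cds(cds_sequence(genome, ft))
    alt_tr <- translate_cds(alt_cds)
    category <- if (delta %% 3L == 0L) "inframe_indel" else "frameshift"
    classification <- if (category == "frameshift") {
      if (ref_tr$internal_stop && alt_tr$length == alt_tr$expected_length)
        "frame_restoring"
      else if (alt_tr$length < ref_tr$length) "truncated"
      else "frame_disrupting"
    } else {
      if (alt_tr$length == ref_tr$length) "unchanged"
      else if (alt_tr$length < ref_tr$length) "truncated"
      else "extended"
    }
    eff[[i]] <- variant_effect_row(pos, ft$feature_id, ft$gene_name,
                                   category, spans_boundary = !inside)
    orf[[i]] <- data.frame(gene = ft$feature_id,
                           ref_protein_len = ref_tr$length,
                           alt_protein_len = alt_tr$length,
                           classification = classification,
                           stringsAsFactors = FALSE)
  }
  list(effects = do.call(rbind, eff), orf = do.call(rbind, orf))
}

#' Allocate DIPs to structural genes vs intergenic space
#'
#' A DIP is in-gene iff any deleted base overlaps a CDS, or, for an
#' insertion, the insertion point lies strictly inside a CDS.
#'
#' @param dips Data frame with columns `pos`, `ref`, `alt` (one side
#'   empty, as in [analyze_dip()]).
#' @param annotations A [feature_annotation()] data frame.
#' @return A list with integer counts `in_gene` and `intergenic` and a
#'   logical vector `in_gene_flags` parallel to `dips`.
#' @export
allocate_dips <- function(dips, annotations) {
  cds <- annotations[annotations$kind == "CDS", , drop = FALSE]
  flags <- vapply(seq_len(nrow(dips)), function(i) {
    pos <- dips$pos[i]; l_ref <- nchar(dips$ref[i])
    if (l_ref > 0L)
      any(cds$start <= pos + l_ref - 1L & cds$end >= pos)
    else
      any(cds$start < pos & cds$end >= pos)
  }, logical(1))
  list(in_gene = sum(flags), intergenic = sum(!flags),
       in_gene_flags = flags)
}

#' Annotate a set of variants
#'
#' Dispatches each variant to [annotate_snp()] or [analyze_dip()].
#' Accepts population variants (`pos/ref_allele/alt_allele`, indels as
#' `"-"` or `"+SEQ"`) or consensus variants (`kind/ref_pos/ref_allele/
#' alt_allele`).
#'
#' @param variants A variant data frame.
#' @inheritParams annotate_snp
#' @return A data frame of effect rows with a `variant_id` column
#'   (row index into `variants`); one row per overlapped feature.
#' @export
annotate_variants <- function(variants, annotations, genome) {
  if (is.null(variants) || nrow(variants) == 0L)
    return(cbind(variant_id = integer(0),
                 variant_effect_row(integer(0), category = character(0))))
  pop <- "frequency" %in% names(variants)
  out <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (pop) {
      if (v$alt_allele == "-") {
        e <- analyze_dip(v$pos, v$ref_allele, "", annotations, genome)$effects
      } else if (startsWith(v$alt_allele, "+")) {
        e <- analyze_dip(v$pos + 1L, "", sub("^\\+", "", v$alt_allele),
                         annotations, genome)$effects
      } else {
        e <- annotate_snp(v$pos, v$ref_allele, v$alt_allele, annotations,
                          genome)
      }
    } else {
      if (v$kind == "SNP") {
        e <- annotate_snp(v$ref_pos, v$ref_allele, v$alt_allele,
                          annotations, genome)
      } else {
        e <- analyze_dip(v$ref_pos, v$ref_allele, v$alt_allele,
                         annotations, genome)$effects
      }
    }
    cbind(variant_id = i, e)
  })
  do.call(rbind, out)
}

#' Most severe effect per variant
#'
#' For summaries, keeps one row per variant: the most severe category
#' across overlapping genes (frameshift > stop_gain > stop_loss >
#' missense > inframe_indel > synonymous > intergenic).
#'
#' @param effects Output of [annotate_variants()].
#' @return A data frame with one row per `variant_id`.
#' @export
most_severe_effect <- function(effects) {
  if (nrow(effects) == 0L) return(effects)
  sev <- EFFECT_SEVERITY[effects$category]
  keep <- unlist(lapply(split(seq_len(nrow(effects)), effects$variant_id),
                        function(idx) idx[which.max(sev[idx])]))
  out <- effects[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
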