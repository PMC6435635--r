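# The default simulation scenario: a 1 Mb reference/strain pair
# emulating a sequenced biocontrol culture — 106 consensus SNPs
# (18 intergenic, 46 synonymous, 42 amino-acid-changing), 23 small DIPs
# (9 in structural genes, among them the frame-restoring single-base
# deletion in the sfp-like pseudogene at 407,533), three multi-kilobase
# deletions at the literal prophage-region coordinates
# 529,444-536,858 / 536,946-548,309 / 548,412-549,854 (87 bp and 102 bp
# retained islands), and population pileups whose sub-consensus SNPs
# concentrate in five designated hotspot genes.

SCENARIO_DELETIONS <- data.frame(
  start = c(529444L, 536946L, 548412L),
  end = c(536858L, 548309L, 549854L))

SCENARIO_HOTSPOTS <- c("yqcG", "cwlA", "yobL", "yqxH", "xlyB")

scenario_gene_plans <- function(sfp_seq) {
  plans <- list()
  bg_starts <- seq(20000L, by = 9000L, length.out = 25L)
  for (i in seq_along(bg_starts))
    plans[[length(plans) + 1L]] <- gene_spec(
      sprintf("bg%02d", i), bg_starts[i], n_res = 300L,
      strand = if (i %% 2L) "+" else "-")
  yq <- yqcg_gene_plan(301000L)
  plans[[length(plans) + 1L]] <- yq$spec
  plans[[length(plans) + 1L]] <- gene_spec("cwlA", 320000L, n_res = 268L)
  plans[[length(plans) + 1L]] <- gene_spec("yobL", 340000L, n_res = 300L,
                                           strand = "-")
  plans[[length(plans) + 1L]] <- gene_spec("yqxH", 360000L, n_res = 200L)
  plans[[length(plans) + 1L]] <- gene_spec("xlyB", 380000L, n_res = 234L,
                                           strand = "-")
  plans[[length(plans) + 1L]] <- gene_spec("sfp", 407200L, seq = sfp_seq)
  plans[[length(plans) + 1L]] <- gene_spec("phg1", 530000L, n_res = 300L)
  plans[[length(plans) + 1L]] <- gene_spec("phg2", 540000L, n_res = 300L,
                                           strand = "-")
  plans[[length(plans) + 1L]] <- gene_spec("phg3", 548500L, n_res = 180L)
  post_starts <- seq(600000L, by = 15000L, length.out = 10L)
  for (i in seq_along(post_starts))
    plans[[length(plans) + 1L]] <- gene_spec(
      sprintf("pg%02d", i), post_starts[i], n_res = 300L,
      strand = if (i %% 2L) "+" else "-")
  list(plans = plans, yq_panel = yq$panel)
}

# pick a single-nucleotide change of the requested consequence class
# inside a CDS feature (strand-aware genome coordinates)
plant_cds_snp <- function(genome, feature, category) {
  cds <- cds_sequence(genome, feature)
  cods <- split_codons(cds)
  nc <- length(cods)
  for (attempt in 1:300) {
    idx <- sample(2:(nc - 1L), 1L)
    codon <- cods[idx]
    aa <- translate_codons(codon, init = FALSE)
    if (aa == "*") next
    cand <- list()
    for (w in 1:3) {
      for (b in setdiff(SIM_BASES, substr(codon, w, w))) {
        alt_codon <- codon
        substr(alt_codon, w, w) <- b
        alt_aa <- translate_codons(alt_codon, init = FALSE)
        got <- if (alt_aa == aa) "synonymous"
               else if (alt_aa == "*") "stop_gain" else "missense"
        if (got == category)
          cand[[length(cand) + 1L]] <- c(w = w, b = b)
      }
    }
    if (!length(cand)) next
    ch <- cand[[sample(length(cand), 1L)]]
    w <- as.integer(ch["w"]); b <- ch["b"]
    if (feature$strand == "+") {
      pos <- feature$start + (idx - 1L) * 3L + w - 1L
      ref <- substr(codon, w, w); alt <- b
    } else {
      pos <- feature$end - ((idx - 1L) * 3L + w - 1L)
      ref <- comp_base(substr(codon, w, w)); alt <- comp_base(b)
    }
    return(list(pos = pos, ref = ref, alt = alt, codon_index = idx))
  }
  stop("could not plant a ", category, " SNP in ", feature$feature_id)
}

# ensure the flanks of a large deletion cannot extend into it (exact
# segment-coordinate recovery): force ref[end] != ref[start-1] and
# ref[start] != ref[end+1]; both changed bases lie inside the deletion
disambiguate_segment_bounds <- function(chars, segments) {
  for (i in seq_len(nrow(segments))) {
    s <- segments$start[i]; e <- segments$end[i]
    if (chars[e] == chars[s - 1L])
      chars[e] <- setdiff(SIM_BASES, chars[s - 1L])[1L]
    if (chars[s] == chars[e + 1L])
      chars[s] <- setdiff(SIM_BASES, chars[e + 1L])[1L]
  }
  chars
}

#' Simulate the full culture-emulation scenario
#'
#' Builds a reference genome and annotation, derives the strain genome
#' by applying the planted consensus edits, lifts the annotation into
#' strain coordinates, and generates population pileups over the strain
#' with the designated hotspot structure.  Defaults encode the emulated
#' conditions: 1 Mb genome at 43.6% GC, 106 consensus SNPs split
#' 18 intergenic / 46 synonymous / 42 amino-acid-changing, 23 DIPs
#' (9 in genes, including the frame-restoring sfp deletion at 407,533),
#' the three deletions at 529,444-536,858, 536,946-548,309 and
#' 548,412-549,854, mean coverage 78, and five hotspot genes whose
#' low-tier SNP counts are 37 (yqcG: 17 panel + 20 silent), 9 (cwlA),
#' 5 (yobL), 4 (yqxH) and 3 (xlyB).
#'
#' @param seed Integer seed driving every random choice.
#' @param length Genome length (>= 800 kb so the deletion region fits
#'   with margin).
#' @param mean_depth Mean pileup coverage.
#' @param error_rate Sequencing error rate for binomial pileups.
#' @param pileup_mode `"binomial"` (sequencing-like noise) or `"exact"`.
#' @return A list: `reference`, `ref_annotation`, `strain`,
#'   `strain_annotation`, `pileups`, `edits` (the applied consensus
#'   edit table) and `truth` (planted population variants, consensus
#'   SNPs with categories, DIPs with in-gene flags, deleted segments,
#'   hotspot gene ids, rates).
#' @export
simulate_scenario <- function(seed = 1L, length = 1000000L,
                              mean_depth = 78, error_rate = 0.005,
                              pileup_mode = c("binomial", "exact")) {
  pileup_mode <- match.arg(pileup_mode)
  length <- as.integer(length)
  if (length < 800000L)
    stop("simulate_scenario: the scenario layout needs at least 800 kb")
  set.seed(as.integer(seed))
  sfp <- make_frameshift_gene()
  gp <- scenario_gene_plans(sfp$seq)
  ref <- simulate_reference(seed, length, gp$plans)
  chars <- strsplit(ref$genome$seq, "")[[1]]
  chars <- disambiguate_segment_bounds(chars, SCENARIO_DELETIONS)
  reference <- genome_seq(ref$genome$id, paste(chars, collapse = ""))
  ann <- ref$annotation

  set.seed(as.integer(seed) + 1L)
  used <- c(407533L)          # sfp deletion position is fixed
  far <- function(p, gap) all(abs(used - p) >= gap)
  in_del_buffer <- function(p)
    any(p >= SCENARIO_DELETIONS$start - 200L &
        p <= SCENARIO_DELETIONS$end + 200L)

  coding_genes <- ann[grepl("^(bg|pg)", ann$feature_id), , drop = FALSE]
  plant_many <- function(category, n) {
    out <- vector("list", n)
    got <- 0L
    while (got < n) {
      ft <- coding_genes[sample(nrow(coding_genes), 1L), ]
      p <- plant_cds_snp(reference, ft, category)
      if (!far(p$pos, 40L)) next
      got <- got + 1L
      used <<- c(used, p$pos)
      out[[got]] <- data.frame(kind = "snp", pos = p$pos, ref = p$ref,
                               alt = p$alt, category = category,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  snps <- rbind(plant_many("synonymous", 46L),
                plant_many("missense", 40L),
                plant_many("stop_gain", 2L))
  # intergenic SNPs: outside every feature (5 bp pad) and the deletions
  is_intergenic <- function(p)
    !any(ann$start - 5L <= p & ann$end + 5L >= p) && !in_del_buffer(p)
  got <- 0L
  while (got < 18L) {
    p <- sample(1000:(length - 1000L), 1L)
    if (!is_intergenic(p) || !far(p, 40L)) next
    got <- got + 1L
    used <- c(used, p)
    snps <- rbind(snps, data.frame(
      kind = "snp", pos = p, ref = substr(reference$seq, p, p),
      alt = sample(setdiff(SIM_BASES, substr(reference$seq, p, p)), 1L),
      category = "intergenic", stringsAsFactors = FALSE))
  }

  # 23 DIPs: the sfp frame-restoring deletion + 8 more in genes + 14
  # intergenic, lengths 1-6, stored left-normalized
  dips <- data.frame(kind = "del", pos = 407533L, ref = sfp$del_base,
                     alt = "", in_gene = TRUE, stringsAsFactors = FALSE)
  plant_dip <- function(in_gene) {
    repeat {
      if (in_gene) {
        ft <- coding_genes[sample(nrow(coding_genes), 1L), ]
        p <- sample((ft$start + 10L):(ft$end - 20L), 1L)
      } else {
        p <- sample(1000:(length - 1000L), 1L)
        if (!is_intergenic(p)) next
      }
      if (!far(p, 200L)) next
      l <- sample(1:6, 1L)
      if (sample(c(TRUE, FALSE), 1L)) {
        nn <- left_normalize_indel(reference$seq, p,
                                   substr(reference$seq, p, p + l - 1L), "")
      } else {
        nn <- left_normalize_indel(reference$seq, p, "",
                                   paste(sample(SIM_BASES, l, TRUE),
                                         collapse = ""))
      }
      if (!far(nn$pos, 200L)) next
      if (in_gene &&
          !(nn$pos >= ft$start + 5L && nn$pos + l <= ft$end - 5L)) next
      used <<- c(used, nn$pos)
      return(data.frame(kind = if (nchar(nn$ref)) "del" else "ins",
                        pos = nn$pos, ref = nn$ref, alt = nn$alt,
                        in_gene = in_gene, stringsAsFactors = FALSE))
    }
  }
  for (i in 1:8) dips <- rbind(dips, plant_dip(TRUE))
  for (i in 1:14) dips <- rbind(dips, plant_dip(FALSE))

  seg_edits <- data.frame(
    kind = "del", pos = SCENARIO_DELETIONS$start,
    ref = substring(reference$seq, SCENARIO_DELETIONS$start,
                    SCENARIO_DELETIONS$end),
    alt = "", stringsAsFactors = FALSE)
  edits <- rbind(snps[, c("kind", "pos", "ref", "alt")],
                 dips[, c("kind", "pos", "ref", "alt")], seg_edits)
  edits <- edits[order(edits$pos), ]
  rownames(edits) <- NULL
  strain <- derive_strain(reference, edits, id = "synthetic_strain")
  strain_ann <- lift_annotation(ann, edits)

  # population variants over the strain: hotspot structure
  set.seed(as.integer(seed) + 2L)
  ga <- function(id) strain_ann[strain_ann$feature_id == id, ]
  yq <- ga("yqcG")
  pv <- panel_population_variants(yq$start, yq$end, yq$strand, gp$yq_panel)
  pv <- rbind(pv, synonymous_population_variants(
    strain, yq, 20L, gp$yq_panel$residue, freq = 0.5))
  plant_gene_snps <- function(id, k, freq = 0.10) {
    ft <- ga(id)
    pos <- sort(sample((ft$start + 3L):(ft$end - 3L), k))
    refb <- substring(strain$seq, pos, pos)
    altb <- vapply(refb, function(b) sample(setdiff(SIM_BASES, b), 1L), "")
    data.frame(pos = pos, ref = refb, alt = unname(altb), freq = freq,
               label = id, stringsAsFactors = FALSE)
  }
  pv <- rbind(pv, plant_gene_snps("cwlA", 9L), plant_gene_snps("yobL", 5L),
              plant_gene_snps("yqxH", 4L), plant_gene_snps("xlyB", 3L))
  # background singletons: one low-tier SNP in each of 10 ordinary genes
  # and 5 intergenic sites, so no non-hotspot feature reaches 2 SNPs
  bg_ids <- sample(strain_ann$feature_id[grepl("^(bg|pg)",
                                               strain_ann$feature_id)], 10L)
  for (id in bg_ids) pv <- rbind(pv, plant_gene_snps(id, 1L))
  n_strain <- seq_length(strain)
  got <- 0L
  while (got < 5L) {
    p <- sample(1000:(n_strain - 1000L), 1L)
    if (any(strain_ann$start - 5L <= p & strain_ann$end + 5L >= p)) next
    if (any(abs(pv$pos - p) < 10L)) next
    b <- substr(strain$seq, p, p)
    pv <- rbind(pv, data.frame(pos = p, ref = b,
                               alt = sample(setdiff(SIM_BASES, b), 1L),
                               freq = 0.10, label = "intergenic",
                               stringsAsFactors = FALSE))
    got <- got + 1L
  }
  pv <- pv[order(pv$pos), ]
  rownames(pv) <- NULL
  pileups <- simulate_pileups(strain, pv, mean_depth = mean_depth,
                              error_rate = error_rate, mode = pileup_mode,
                              seed = as.integer(seed) + 3L)
  truth <- list(
    planted_population_variants = pv,
    planted_consensus_snps = snps,
    planted_dips = dips,
    deleted_segments = cbind(SCENARIO_DELETIONS,
                             length = SCENARIO_DELETIONS$end -
                               SCENARIO_DELETIONS$start + 1L),
    hotspot_gene_ids = SCENARIO_HOTSPOTS,
    sfp_deleted_base = sfp$del_base,
    error_rate = error_rate, mean_depth = mean_depth)
  list(reference = reference, ref_annotation = ann, strain = strain,
       strain_annotation = strain_ann, pileups = pileups, edits = edits,
       truth = truth, seed = as.integer(seed), length = length)
}

#' Write a simulated scenario to disk
#'
#' Emits the reference and strain FASTA, both GFF3 annotations, the
#' pileup TSV, the truth tables as JSON, and the resolved run
#' configuration YAML.
#'
#' @param scn Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(scn$reference, file.path(dir, "reference.fasta"))
  write_fasta(scn$strain, file.path(dir, "strain.fasta"))
  write_gff3(scn$ref_annotation, scn$reference$id,
             file.path(dir, "reference.gff3"))
  write_gff3(scn$strain_annotation, scn$strain$id,
             file.path(dir, "strain.gff3"))
  write_pileup_tsv(scn$pileups, file.path(dir, "pileups.tsv"))
  jsonlite::write_json(scn$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_run_config(run_config(seed = scn$seed,
                              mean_depth = scn$truth$mean_depth,
                              error_rate = scn$truth$error_rate),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
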