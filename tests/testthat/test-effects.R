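# Consequence annotation: codon mapping, property transitions,
# frameshift/ORF analysis, DIP allocation.

# genome with one plus-strand CDS whose codons we control
make_codon_genome <- function(codons) {
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  g <- paste0(random_seq(100, seed = 77), cds, random_seq(100))
  list(genome = genome_seq("t", g),
       annotation = feature_annotation("g1", "g1", 101L,
                                       100L + nchar(cds), "+", "CDS"))
}

test_that("SNP annotation maps codons and residues on the plus strand", {
  codons <- rep("GCT", 200)
  codons[146] <- "TGC"    # residue 147 (after the initiator Met)
  codons[99] <- "TGG"     # residue 100
  fx <- make_codon_genome(codons)
  st <- 101L

  # TGC -> TAC at residue 147: missense Cys147Tyr
  p <- st + 146L * 3L + 1L       # second base of codon 147
  e <- annotate_snp(p, "G", "A", fx$annotation, fx$genome)
  expect_equal(e$category, "missense")
  expect_equal(e$aa_change, "Cys147Tyr")
  expect_equal(e$codon_index, 147L)

  # TGG -> TGA at residue 100: stop gain Trp100*
  p <- st + 99L * 3L + 2L
  e <- annotate_snp(p, "G", "A", fx$annotation, fx$genome)
  expect_equal(e$category, "stop_gain")
  expect_equal(e$aa_change, "Trp100*")
  expect_equal(e$property_transition, "truncation")

  # GCT -> GCC: synonymous, no aa_change label
  p <- st + 10L * 3L + 2L
  e <- annotate_snp(p, "T", "C", fx$annotation, fx$genome)
  expect_equal(e$category, "synonymous")
  expect_true(is.na(e$aa_change))

  # outside any feature: intergenic
  e <- annotate_snp(5L, substr(fx$genome$seq, 5, 5), "A", fx$annotation,
                    fx$genome)
  expect_equal(e$category, "intergenic")

  # disagreement with the genome is a consistency error
  expect_error(annotate_snp(p, "A", "C", fx$annotation, fx$genome),
               "mismatch")
})

test_that("minus-strand annotation equals the plus-strand mirror", {
  for (seed in 1:5) {
    fw <- random_gene_genome(60, "+", seed = seed)
    # mirror construction: reverse-complement the whole genome; the gene
    # sits at mirrored coordinates on the minus strand
    n <- seq_length(fw$genome)
    rc <- genome_seq("rc", revcomp(fw$genome$seq))
    ann_rc <- feature_annotation("g1", "g1", n - fw$annotation$end + 1L,
                                 n - fw$annotation$start + 1L, "-", "CDS")
    set.seed(seed + 500)
    pos <- sample((fw$annotation$start + 3L):(fw$annotation$end - 3L), 5L)
    for (p in pos) {
      b <- substr(fw$genome$seq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      e1 <- annotate_snp(p, b, alt, fw$annotation, fw$genome)
      p2 <- n - p + 1L
      e2 <- annotate_snp(p2, chartr("ACGT", "TGCA", b),
                         chartr("ACGT", "TGCA", alt), ann_rc, rc)
      expect_equal(e1$category, e2$category)
      expect_equal(e1$aa_change, e2$aa_change)
      expect_equal(e1$codon_index, e2$codon_index)
    }
  }
})

test_that("property transitions follow charge-over-size precedence", {
  cases <- list(
    c("Asn", "Lys", "neutral_to_basic"),
    c("Arg", "Ser", "basic_to_neutral"),
    c("Ala", "Glu", "neutral_to_acidic"),
    c("Asp", "Gly", "acidic_to_neutral"),
    c("Leu", "Ile", "none"),              # same charge, same size class
    c("Gly", "Arg", "neutral_to_basic"),  # charge change wins over size
    c("Gly", "Leu", "small_to_large"),
    c("Trp", "Ala", "large_to_small"),
    c("Lys", "*", "truncation"))
  for (cs in cases)
    expect_equal(classify_property_transition(cs[1], cs[2]), cs[3],
                 info = paste(cs[1], "->", cs[2]))
})

test_that("annotation agrees with the full-translation oracle", {
  n_checked <- 0L
  for (seed in 1:20) {
    fx <- random_gene_genome(sample(30:120, 1), sample(c("+", "-"), 1),
                             seed = seed)
    ft <- fx$annotation[1, ]
    set.seed(seed + 900)
    for (rep in 1:5) {
      p <- sample((ft$start + 3L):(ft$end - 3L), 1L)
      b <- substr(fx$genome$seq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      got <- annotate_snp(p, b, alt, fx$annotation, fx$genome)
      want <- oracle_snp_effect(fx$genome$seq, ft, p, b, alt)
      expect_equal(got$category, want$category,
                   info = sprintf("seed %d pos %d", seed, p))
      expect_equal(got$aa_change, want$aa_change)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 100L)
})

test_that("in-frame and frameshifting DIPs are classified by ORF outcome", {
  fx <- random_gene_genome(80, "+", seed = 3)
  ft <- fx$annotation[1, ]
  # 3-bp deletion mid-CDS, codon-aligned: in-frame, one residue shorter
  p <- ft$start + 30L
  res <- analyze_dip(p, substr(fx$genome$seq, p, p + 2L), "",
                     fx$annotation, fx$genome)
  expect_equal(res$effects$category, "inframe_indel")
  expect_equal(res$orf$ref_protein_len - res$orf$alt_protein_len, 1L)
  expect_equal(res$orf$classification, "truncated")

  # 1-bp insertion: frameshift; oracle = translating the mutated gene
  p <- ft$start + 31L
  res <- analyze_dip(p, "", "A", fx$annotation, fx$genome)
  expect_equal(res$effects$category, "frameshift")
  mut <- apply_edits(fx$genome, data.frame(kind = "ins", pos = p,
                                           ref = "", alt = "A"))
  aa <- oracle_translate(substr(mut, ft$start, ft$end + 1L))
  stop_at <- which(aa == "*")[1]
  oracle_len <- if (is.na(stop_at)) length(aa) else stop_at - 1L
  expect_equal(res$orf$alt_protein_len, oracle_len)
  expect_equal(res$orf$classification,
               if (oracle_len < res$orf$ref_protein_len) "truncated"
               else "frame_disrupting")

  # intergenic DIP
  res <- analyze_dip(5L, substr(fx$genome$seq, 5L, 5L), "",
                     fx$annotation, fx$genome)
  expect_equal(res$effects$category, "intergenic")
  expect_null(res$orf)
})

test_that("the sfp-like single-base deletion is frame-restoring", {
  scn <- get_scenario()
  dip <- scn$truth$planted_dips[1, ]
  expect_equal(dip$pos, 407533L)
  res <- analyze_dip(dip$pos, dip$ref, dip$alt, scn$ref_annotation,
                     scn$reference)
  expect_equal(res$effects$gene, "sfp")
  expect_equal(res$effects$category, "frameshift")
  expect_equal(res$orf$classification, "frame_restoring")
  expect_equal(res$orf$alt_protein_len, 224L)   # (675 / 3) - 1 residues
  expect_lt(res$orf$ref_protein_len, 224L)
})

test_that("DIP allocation matches a brute-force interval check", {
  ann <- feature_annotation(c("a", "b"), c("a", "b"), c(100L, 300L),
                            c(200L, 380L), c("+", "-"), "CDS")
  # strictly between genes
  d1 <- data.frame(pos = 250L, ref = "AA", alt = "")
  expect_equal(allocate_dips(d1, ann)$intergenic, 1L)
  # overlapping a CDS by exactly one base
  d2 <- data.frame(pos = 99L, ref = "AA", alt = "")
  expect_equal(allocate_dips(d2, ann)$in_gene, 1L)
  # insertion at a gene's first position is outside (before the gene)
  d3 <- data.frame(pos = 100L, ref = "", alt = "TT")
  expect_equal(allocate_dips(d3, ann)$intergenic, 1L)

  set.seed(8)
  dips <- data.frame(pos = sample(1:500, 40),
                     ref = ifelse(runif(40) < 0.5, "AAA", ""),
                     alt = "", stringsAsFactors = FALSE)
  dips$alt[dips$ref == ""] <- "GG"
  got <- allocate_dips(dips, ann)
  want <- vapply(seq_len(nrow(dips)), function(i) {
    if (nchar(dips$ref[i]) > 0) {
      span <- dips$pos[i]:(dips$pos[i] + nchar(dips$ref[i]) - 1L)
      any(vapply(span, function(s) any(ann$start <= s & ann$end >= s),
                 TRUE))
    } else {
      any(ann$start < dips$pos[i] & ann$end >= dips$pos[i])
    }
  }, TRUE)
  expect_equal(got$in_gene_flags, want)
  expect_equal(got$in_gene + got$intergenic, 40L)
})

test_that("every SNP receives exactly one category (partition)", {
  scn <- get_scenario()
  snps <- scn$truth$planted_consensus_snps
  eff <- annotate_variants(
    data.frame(kind = "SNP", ref_pos = snps$pos, qry_pos = NA,
               ref_allele = snps$ref, alt_allele = snps$alt,
               stringsAsFactors = FALSE),
    scn$ref_annotation, scn$reference)
  sev <- most_severe_effect(eff)
  expect_equal(nrow(sev), nrow(snps))
  aa <- sum(sev$category %in% c("missense", "stop_gain", "stop_loss"))
  syn <- sum(sev$category == "synonymous")
  inter <- sum(sev$category == "intergenic")
  expect_equal(aa + syn + inter, nrow(snps))
  expect_equal(sev$category[sev$category != "intergenic"],
               snps$category[snps$category != "intergenic"])
})
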