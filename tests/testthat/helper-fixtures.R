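# Shared fixtures (built once per run) and independent brute-force
# oracles used by the property tests.

.fixture_cache <- new.env(parent = emptyenv())

get_scenario <- function() {
  if (is.null(.fixture_cache$scn))
    .fixture_cache$scn <- simulate_scenario(seed = 1)
  .fixture_cache$scn
}

get_scenario_diff <- function() {
  if (is.null(.fixture_cache$diff)) {
    scn <- get_scenario()
    .fixture_cache$diff <- diff_genomes(scn$reference, scn$strain)
  }
  .fixture_cache$diff
}

get_yqcg_fixture <- function() {
  if (is.null(.fixture_cache$yq))
    .fixture_cache$yq <- build_yqcg_fixture(seed = 1)
  .fixture_cache$yq
}

get_scenario_exact_pileups <- function() {
  if (is.null(.fixture_cache$px)) {
    scn <- get_scenario()
    .fixture_cache$px <- simulate_pileups(
      scn$strain, scn$truth$planted_population_variants,
      mean_depth = 78, mode = "exact")
  }
  .fixture_cache$px
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_pileups <- function(n_sites, seed, lambda = 10) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  pileup_table(seq_len(n_sites), ref,
               A = rpois(n_sites, lambda), C = rpois(n_sites, lambda),
               G = rpois(n_sites, lambda), T = rpois(n_sites, lambda),
               del = rpois(n_sites, 2))
}

# --- independent per-site scan oracle (plain loop over the definition)
brute_scan <- function(p, tier, min_depth = 10) {
  rows <- list()
  for (i in seq_len(nrow(p))) {
    if (p$depth[i] < min_depth) next
    counts <- c(A = p$A[i], C = p$C[i], G = p$G[i], T = p$T[i],
                del = p$del[i])
    cons <- names(counts)[which.max(counts)]
    if (counts[[p$ref_base[i]]] == max(counts)) cons <- p$ref_base[i]
    for (b in c("A", "C", "G", "T")) {
      f <- counts[[b]] / p$depth[i]
      if (b != p$ref_base[i] && b != cons && f >= tier)
        rows[[length(rows) + 1L]] <-
          data.frame(pos = p$pos[i], alt = b, freq = f)
    }
    fdel <- counts[["del"]] / p$depth[i]
    if (cons != "del" && fdel >= tier)
      rows[[length(rows) + 1L]] <-
        data.frame(pos = p$pos[i], alt = "-", freq = fdel)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(pos = integer(0), alt = character(0),
                               freq = numeric(0))
  else out[order(out$pos, out$alt), , drop = FALSE]
}

# --- exhaustive best-chain oracle for small anchor sets
brute_chain_score <- function(a) {
  n <- nrow(a)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx)) next
    o <- idx[order(a$ref_start[idx])]
    re <- a$ref_start[o] + a$length[o] - 1L
    qe <- a$qry_start[o] + a$length[o] - 1L
    ok <- TRUE
    if (length(o) > 1L)
      ok <- all(a$ref_start[o][-1L] > re[-length(o)]) &&
        all(a$qry_start[o][-1L] > qe[-length(o)])
    if (ok) best <- max(best, sum(a$length[o]))
  }
  best
}

# --- full-translation oracle for SNP consequences (independent of the
# codon-local annotation path: mutates the genome, re-extracts and
# re-translates the whole CDS with Biostrings, and diffs the proteins)
oracle_translate <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)), if.fuzzy.codon = "X"))
  strsplit(aa, "")[[1]]
}

oracle_snp_effect <- function(genome_str, ft, pos, ref, alt) {
  extract <- function(g) {
    s <- substr(g, ft$start, ft$end)
    if (ft$strand == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    s
  }
  stopifnot(substr(genome_str, pos, pos) == ref)
  g2 <- paste0(substr(genome_str, 1L, pos - 1L), alt,
               substr(genome_str, pos + 1L, nchar(genome_str)))
  a1 <- oracle_translate(extract(genome_str))
  a2 <- oracle_translate(extract(g2))
  d <- which(a1 != a2)
  if (!length(d)) return(list(category = "synonymous",
                              aa_change = NA_character_))
  i <- d[1L]
  three <- function(x) if (x == "*") "*" else
    unname(Biostrings::AMINO_ACID_CODE[x])
  cat <- if (a2[i] == "*") "stop_gain" else if (a1[i] == "*") "stop_loss"
         else "missense"
  list(category = cat,
       aa_change = paste0(three(a1[i]), i, three(a2[i])))
}

# random CDS (ATG start, TAA stop, no pinned content) planted in a
# random genome; returns genome string + single-row annotation
random_gene_genome <- function(n_codons, strand, seed) {
  set.seed(seed)
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(nonstop, n_codons - 1L, replace = TRUE),
                             collapse = ""), "TAA")
  flank1 <- random_seq(300)
  flank2 <- random_seq(300)
  body <- if (strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  else cds
  g <- paste0(flank1, body, flank2)
  ann <- feature_annotation("g1", "g1", 301L, 300L + nchar(cds), strand,
                            "CDS")
  list(genome = genome_seq("t", g), annotation = ann, cds = cds)
}
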