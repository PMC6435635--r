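# Synthetic-data generator: reference genome + annotation, a derived
# strain genome (SNPs, small DIPs, large deletions), and population
# pileups with planted sub-consensus structure, plus the truth tables
# needed for recovery tests.

SIM_BASES <- c("A", "C", "G", "T")

random_codons <- function(n) {
  nonstop <- setdiff(names(genetic_code_table()), STOP_CODONS)
  sample(nonstop, n, replace = TRUE)
}

#' Specify one gene for the reference simulator
#'
#' A gene is realized as `ATG` + random non-stop codons + `TAA`, with
#' selected residues pinned to specific codons, or spliced verbatim
#' from `seq` (used e.g. for a pseudogene carrying a frameshift).
#'
#' @param name Feature id / gene name.
#' @param start 1-based genome start.
#' @param n_res Number of coding residues including the initiator Met
#'   (realized CDS length is `3 * n_res + 3` with the stop codon).
#' @param strand `"+"` or `"-"`.
#' @param codons Named list residue-index -> codon to pin.
#' @param seq Verbatim CDS sequence overriding the construction.
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(name, start, n_res = NULL, strand = "+",
                      codons = list(), seq = NULL) {
  if (is.null(seq) && is.null(n_res))
    stop("gene_spec: give either n_res or seq")
  structure(list(name = name, start = as.integer(start), n_res = n_res,
                 strand = strand, codons = codons, seq = seq),
            class = "gene_spec")
}

#' Simulate a reference genome with planted genes
#'
#' Draws a random background at the target GC composition and splices
#' in the genes of `gene_plan` (reverse-complemented for `-` strand
#' genes).  Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param length Genome length (bp).
#' @param gene_plan List of [gene_spec()] objects (non-overlapping).
#' @param gc Target GC fraction (default 0.436, a B. subtilis-like
#'   composition).
#' @param id Sequence id of the genome.
#' @return A list: `genome` ([genome_seq()]) and `annotation`
#'   ([feature_annotation()]).
#' @export
simulate_reference <- function(seed, length, gene_plan = list(),
                               gc = 0.436, id = "synthetic_ref") {
  set.seed(as.integer(seed))
  length <- as.integer(length)
  chars <- sample(SIM_BASES, length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  rows <- list()
  prev <- cbind(start = integer(0), end = integer(0))
  for (g in gene_plan) {
    s <- if (!is.null(g$seq)) toupper(g$seq) else {
      cods <- random_codons(g$n_res)
      cods[1L] <- "ATG"
      if (length(g$codons))
        cods[as.integer(names(g$codons))] <- unlist(g$codons)
      paste0(paste(cods, collapse = ""), "TAA")
    }
    gend <- g$start + nchar(s) - 1L
    if (gend > length || g$start < 1L)
      stop("simulate_reference: gene plan overflows genome length (",
           g$name, ")")
    if (nrow(prev) && any(g$start <= prev[, "end"] & gend >= prev[, "start"]))
      stop("simulate_reference: gene plan overlaps at ", g$name)
    prev <- rbind(prev, cbind(start = g$start, end = gend))
    spl <- if (g$strand == "-") revcomp(s) else s
    chars[g$start:gend] <- strsplit(spl, "")[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = g$name, gene_name = g$name, start = g$start,
      end = gend, strand = g$strand, kind = "CDS", stringsAsFactors = FALSE)
  }
  ann <- if (length(rows)) {
    r <- do.call(rbind, rows)
    feature_annotation(r$feature_id, r$gene_name, r$start, r$end, r$strand,
                       r$kind, length)
  } else {
    feature_annotation(character(0), character(0), integer(0), integer(0),
                       character(0), character(0))
  }
  list(genome = genome_seq(id, paste(chars, collapse = "")),
       annotation = ann)
}

#' The YqcG-toxin substitution panel
#'
#' The amino-acid substitutions segregating in the sequenced
#' hypermutating culture's *yqcG* gene, with the shallowest
#' sensitivity scan that still detects each (35%, 20% or 5%) and the
#' band frequency the simulator plants it at (0.50, 0.25 and 0.10
#' respectively, i.e. inside the frequency band each scan tier
#' implies).  The three tier sets are nested: 35% within 20% within 5%.
#'
#' @return A data frame: `residue, aa_from, aa_to, scan_tier,
#'   band_freq`.
#' @export
yqcg_substitution_panel <- function() {
  p <- data.frame(
    residue = c(15L, 18L, 28L, 84L, 89L, 98L, 101L, 104L, 122L, 128L,
                173L, 240L, 257L, 260L, 316L, 319L, 343L),
    aa_from = c("Lys", "Gln", "Val", "Phe", "Asn", "Thr", "Ala", "Leu",
                "Met", "Asp", "Gly", "Arg", "Ser", "Ala", "Ala", "Gly",
                "Lys"),
    aa_to = c("Asn", "Lys", "Ala", "Ile", "Ser", "Ser", "Glu", "Phe",
              "Ile", "Glu", "Ala", "Lys", "Thr", "Val", "Gly", "Val",
              "Gln"),
    scan_tier = c(0.05, 0.20, 0.35, 0.35, 0.35, 0.35, 0.05, 0.05, 0.05,
                  0.05, 0.05, 0.05, 0.20, 0.35, 0.20, 0.20, 0.20),
    stringsAsFactors = FALSE)
  p$band_freq <- c(`0.35` = 0.50, `0.2` = 0.25, `0.05` = 0.10)[
    as.character(p$scan_tier)]
  p
}

#' Gene plan realizing the YqcG substitution panel
#'
#' Builds a 531-residue toxin-like gene in which every panel
#' substitution is reachable by one nucleotide change: each constrained
#' residue gets a deterministic codon pair `(from, to)` differing at
#' exactly one position.
#'
#' @param start Genome start position for the gene.
#' @param name Gene name.
#' @param n_res Residue count (default 531, the toxin's length).
#' @param strand `"+"` or `"-"`.
#' @return A list: `spec` (a [gene_spec()]) and `panel` (the panel with
#'   `codon_from`, `codon_to` and `offset` columns added).
#' @export
yqcg_gene_plan <- function(start, name = "yqcG", n_res = 531L,
                           strand = "+") {
  panel <- yqcg_substitution_panel()
  pairs <- lapply(seq_len(nrow(panel)), function(i)
    codon_pair_for_change(panel$aa_from[i], panel$aa_to[i]))
  panel$codon_from <- vapply(pairs, `[[`, "", "from")
  panel$codon_to <- vapply(pairs, `[[`, "", "to")
  panel$offset <- vapply(pairs, `[[`, 0L, "offset")
  codons <- as.list(panel$codon_from)
  names(codons) <- panel$residue
  list(spec = gene_spec(name, start, n_res, strand, codons),
       panel = panel)
}

#' Population SNPs realizing a substitution panel
#'
#' Converts panel rows (residue/codon/offset, as from
#' [yqcg_gene_plan()]) into genome-coordinate population variants at
#' their band frequencies, strand-aware.
#'
#' @param gene_start,gene_end Gene coordinates.
#' @param strand Gene strand.
#' @param panel Panel with `codon_from`, `codon_to`, `offset`,
#'   `band_freq`.
#' @return Data frame `pos, ref, alt, freq, label`.
#' @export
panel_population_variants <- function(gene_start, gene_end, strand, panel) {
  w <- panel$offset
  ref_b <- substr(panel$codon_from, w + 1L, w + 1L)
  alt_b <- substr(panel$codon_to, w + 1L, w + 1L)
  if (strand == "+") {
    pos <- gene_start + (panel$residue - 1L) * 3L + w
  } else {
    pos <- gene_end - ((panel$residue - 1L) * 3L + w)
    ref_b <- comp_base(ref_b); alt_b <- comp_base(alt_b)
  }
  data.frame(pos = pos, ref = ref_b, alt = alt_b, freq = panel$band_freq,
             label = paste0(panel$aa_from, panel$residue, panel$aa_to),
             stringsAsFactors = FALSE)
}

# population SNPs at fourfold-degenerate third positions (silent)
synonymous_population_variants <- function(genome, feature, n,
                                           exclude_residues = integer(0),
                                           freq = 0.5) {
  fourfold <- c("GC", "GT", "GG", "CC", "CT", "TC", "AC", "CG")
  cds <- cds_sequence(genome, feature)
  cods <- split_codons(cds)
  cand <- setdiff(which(substr(cods, 1L, 2L) %in% fourfold),
                  c(1L, length(cods), exclude_residues))
  if (length(cand) < n)
    stop("not enough fourfold-degenerate codons to plant ", n,
         " synonymous variants")
  sel <- sort(sample(cand, n))
  third <- substr(cods[sel], 3L, 3L)
  alt_cds <- SIM_BASES[match(third, SIM_BASES) %% 4L + 1L]
  if (feature$strand == "+") {
    pos <- feature$start + (sel - 1L) * 3L + 2L
    ref_b <- third; alt_b <- alt_cds
  } else {
    pos <- feature$end - ((sel - 1L) * 3L + 2L)
    ref_b <- comp_base(third); alt_b <- comp_base(alt_cds)
  }
  data.frame(pos = pos, ref = ref_b, alt = alt_b, freq = freq,
             label = "synonymous", stringsAsFactors = FALSE)
}

# construct a pseudogene: a functional (n_res residue) CDS carrying one
# extra base at gene offset ins_offset, so that (a) the reference frame
# hits an internal stop and (b) deleting the extra base restores the
# full-length product; the extra base differs from its left neighbour,
# so the restoring deletion is already left-normalized
make_frameshift_gene <- function(n_res = 224L, ins_offset = 334L) {
  for (attempt in 1:100) {
    cods <- random_codons(n_res - 1L)
    cds <- paste0("ATG", paste(cods, collapse = ""), "TAA")
    left <- substr(cds, ins_offset - 1L, ins_offset - 1L)
    for (x in setdiff(SIM_BASES, left)) {
      g <- paste0(substr(cds, 1L, ins_offset - 1L), x,
                  substr(cds, ins_offset, nchar(cds)))
      tr <- translate_cds(g)
      if (tr$internal_stop && tr$length < n_res)
        return(list(seq = g, functional = cds, del_offset = ins_offset,
                    del_base = x))
    }
  }
  stop("could not construct a frameshifted pseudogene")
}

#' Apply consensus edits to derive a strain genome
#'
#' Applies consensus SNPs, small DIPs and large deletions (given in
#' reference coordinates, non-overlapping) right to left, yielding the
#' derived strain sequence; the new length is the reference length plus
#' the net indel balance minus deleted bases.
#'
#' @param reference A [genome_seq()].
#' @param edits Edit table as in [apply_edits()].
#' @param id Id for the derived genome.
#' @return A [genome_seq()].
#' @export
derive_strain <- function(reference, edits,
                          id = paste0(reference$id, "_derived")) {
  genome_seq(id, apply_edits(reference, edits), reference$circular)
}

#' Simulate per-site pileups over a genome
#'
#' In `exact` mode depth is constant at `round(mean_depth)` and the
#' planted alternate count is `round(freq * depth)`, with no noise —
#' integer-deterministic, for threshold tests.  In `binomial` mode
#' depth is Poisson(`mean_depth`), alternate counts are
#' Binomial(depth, freq), and sequencing errors move reads from the
#' reference base uniformly onto the other three bases at
#' `error_rate/3` each.
#'
#' @param strain The [genome_seq()] the pileup describes.
#' @param variants Planted sub-consensus variants: data frame
#'   `pos, ref, alt, freq` with `alt` a base, `"-"` (deletion of the
#'   site) or `"+SEQ"` (insertion after the site).  May be `NULL`.
#' @param mean_depth Mean coverage (default 78, the emulated culture depth).
#' @param error_rate Per-base error rate (binomial mode only).
#' @param mode `"binomial"` or `"exact"`.
#' @param seed Optional seed set before drawing.
#' @return A `site_pileup` data frame covering every position.
#' @export
simulate_pileups <- function(strain, variants = NULL, mean_depth = 78,
                             error_rate = 0.005,
                             mode = c("binomial", "exact"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- as_seq_string(strain)
  n <- nchar(s)
  refc <- strsplit(s, "")[[1]]
  base_idx <- match(refc, SIM_BASES)
  if (anyNA(base_idx))
    stop("simulate_pileups: genome contains N; pileups need resolved bases")
  depth <- if (mode == "exact") rep.int(as.integer(round(mean_depth)), n)
           else rpois(n, mean_depth)
  counts <- matrix(0L, nrow = n, ncol = 4L,
                   dimnames = list(NULL, SIM_BASES))
  counts[cbind(seq_len(n), base_idx)] <- depth
  if (mode == "binomial" && error_rate > 0) {
    err <- rbinom(n, depth, error_rate)
    counts[cbind(seq_len(n), base_idx)] <- depth - err
    others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                    c(1L, 2L, 3L))[base_idx, , drop = FALSE]
    e1 <- rbinom(n, err, 1 / 3)
    e2 <- rbinom(n, err - e1, 1 / 2)
    e3 <- err - e1 - e2
    idx <- cbind(seq_len(n), others[, 1L])
    counts[idx] <- counts[idx] + e1
    idx <- cbind(seq_len(n), others[, 2L])
    counts[idx] <- counts[idx] + e2
    idx <- cbind(seq_len(n), others[, 3L])
    counts[idx] <- counts[idx] + e3
  }
  del <- integer(n)
  ins <- rep(".", n)
  if (!is.null(variants) && nrow(variants) > 0L) {
    if (anyNA(variants$pos) || any(variants$pos < 1L) ||
        any(variants$pos > n))
      stop("simulate_pileups: variant planted at a deleted or out-of-range position")
    for (i in seq_len(nrow(variants))) {
      p <- variants$pos[i]
      if (!variants$alt[i] %in% c("-") && !startsWith(variants$alt[i], "+") &&
          variants$ref[i] != refc[p])
        stop("simulate_pileups: planted ref allele disagrees with genome at ", p)
      d <- depth[p]
      k <- if (mode == "exact") as.integer(round(variants$freq[i] * d))
           else rbinom(1L, d, variants$freq[i])
      if (startsWith(variants$alt[i], "+")) {
        ins[p] <- format_ins(stats::setNames(k, sub("^\\+", "",
                                                    variants$alt[i])))
        next
      }
      avail <- counts[p, base_idx[p]]
      k <- min(k, avail)
      counts[p, base_idx[p]] <- avail - k
      if (variants$alt[i] == "-") del[p] <- del[p] + k
      else counts[p, variants$alt[i]] <- counts[p, variants$alt[i]] + k
    }
  }
  pileup_table(seq_len(n), refc, counts[, "A"], counts[, "C"],
               counts[, "G"], counts[, "T"], del, ins)
}

#' Fixture: a hypermutating toxin gene with planted tier bands
#'
#' Builds a small genome containing the YqcG-like gene from
#' [yqcg_gene_plan()], plants the 17 panel substitutions at their band
#' frequencies plus `n_synonymous` silent SNPs at 0.50, and generates
#' exact-mode pileups — the deterministic input for tier-reconstruction
#' checks (a 35% scan then sees 25 SNPs in the gene, 5 of which change
#' the protein).
#'
#' @param seed Integer seed.
#' @param depth Constant exact-mode depth (default 100).
#' @param genome_length Fixture genome length.
#' @param gene_start Gene placement.
#' @param n_synonymous Number of silent high-frequency SNPs planted.
#' @return A list: `genome`, `annotation`, `truth` (planted variants),
#'   `pileups`, `panel`.
#' @export
build_yqcg_fixture <- function(seed = 1L, depth = 100L,
                               genome_length = 6000L, gene_start = 2001L,
                               n_synonymous = 20L) {
  plan <- yqcg_gene_plan(gene_start)
  ref <- simulate_reference(seed, genome_length, list(plan$spec))
  gene <- ref$annotation[ref$annotation$feature_id == "yqcG", ]
  pv <- panel_population_variants(gene$start, gene$end, gene$strand,
                                  plan$panel)
  set.seed(as.integer(seed) + 101L)
  sv <- synonymous_population_variants(ref$genome, gene, n_synonymous,
                                       plan$panel$residue, freq = 0.5)
  truth <- rbind(pv[, c("pos", "ref", "alt", "freq", "label")], sv)
  truth <- truth[order(truth$pos), ]
  rownames(truth) <- NULL
  pileups <- simulate_pileups(ref$genome, truth, mean_depth = depth,
                              error_rate = 0, mode = "exact")
  list(genome = ref$genome, annotation = ref$annotation, truth = truth,
       pileups = pileups, panel = plan$panel)
}
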