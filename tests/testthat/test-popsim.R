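# Synthetic-data generator: determinism, gene-plan constraints,
# composition, strain derivation, pileup models, truth recovery.

test_that("reference simulation is byte-deterministic for a fixed seed", {
  plan <- list(gene_spec("gA", 1001L, n_res = 50L),
               gene_spec("gB", 2001L, n_res = 40L, strand = "-"))
  r1 <- simulate_reference(7L, 5000L, plan)
  r2 <- simulate_reference(7L, 5000L, plan)
  expect_identical(r1$genome$seq, r2$genome$seq)
  expect_identical(as.data.frame(r1$annotation), as.data.frame(r2$annotation))
})

test_that("gene plans pin the requested codons", {
  plan <- yqcg_gene_plan(2001L)
  ref <- simulate_reference(3L, 6000L, list(plan$spec))
  gene <- ref$annotation[1, ]
  # residue 28 must be a valine codon (the Val28Ala substitution source)
  cod28 <- substr(ref$genome$seq, gene$start + 27L * 3L,
                  gene$start + 27L * 3L + 2L)
  expect_true(cod28 %in% c("GTT", "GTC", "GTA", "GTG"))
  # every panel substitution is one nucleotide away in the realized gene
  tr <- translate_cds(substr(ref$genome$seq, gene$start, gene$end))
  expect_equal(tr$length, 531L)
  expect_false(tr$internal_stop)
})

test_that("realized GC composition hits the target at scale", {
  ref <- simulate_reference(11L, 100000L, gc = 0.436)
  expect_lt(abs(gc_content(ref$genome) - 43.6), 0.5)
})

test_that("gene plans beyond the genome are rejected", {
  expect_error(simulate_reference(1L, 1000L,
                                  list(gene_spec("g", 900L, n_res = 50L))),
               "overflows")
})

test_that("strain derivation applies edits with exact length accounting", {
  ref <- genome_seq("r", random_seq(20000, seed = 5))
  big_del <- data.frame(kind = "del", pos = 5000L,
                        ref = substr(ref$seq, 5000L, 12414L), alt = "",
                        stringsAsFactors = FALSE)
  strain <- derive_strain(ref, big_del)
  expect_equal(seq_length(strain), 20000L - 7415L)

  expect_identical(derive_strain(ref, big_del[0, ])$seq, ref$seq)

  overlapping <- rbind(big_del,
                       data.frame(kind = "snp", pos = 6000L,
                                  ref = substr(ref$seq, 6000L, 6000L),
                                  alt = "A", stringsAsFactors = FALSE))
  expect_error(derive_strain(ref, overlapping), "overlap")

  wrong <- data.frame(kind = "snp", pos = 10L, ref = "A", alt = "C",
                      stringsAsFactors = FALSE)
  if (substr(ref$seq, 10L, 10L) == "A") wrong$ref <- "C"
  expect_error(derive_strain(ref, wrong), "mismatch")
})

test_that("the pseudogene construction carries a frame-restoring deletion", {
  scn <- get_scenario()
  sfp <- scn$ref_annotation[scn$ref_annotation$feature_id == "sfp", ]
  expect_equal(sfp$end - sfp$start + 1L, 676L)
  ref_tr <- translate_cds(substr(scn$reference$seq, sfp$start, sfp$end))
  expect_true(ref_tr$internal_stop)
  # the strain-side gene is 675 bp and translates to the full product
  sfp_q <- scn$strain_annotation[scn$strain_annotation$feature_id == "sfp", ]
  expect_equal(sfp_q$end - sfp_q$start + 1L, 675L)
  alt_tr <- translate_cds(substr(scn$strain$seq, sfp_q$start, sfp_q$end))
  expect_false(alt_tr$internal_stop)
  expect_equal(alt_tr$length, 224L)
})

test_that("exact-mode pileups are integer-deterministic", {
  g <- genome_seq("g", random_seq(200, seed = 9))
  p40 <- which(strsplit(g$seq, "")[[1]] == "A")[1]
  v <- data.frame(pos = p40, ref = "A", alt = "G", freq = 0.40,
                  stringsAsFactors = FALSE)
  px <- simulate_pileups(g, v, mean_depth = 100, mode = "exact")
  expect_true(all(px$depth == 100L))
  expect_equal(px$G[px$pos == p40], 40L)
  expect_equal(px$A[px$pos == p40], 60L)
  # no variant + zero error rate: every site is monoallelic
  px0 <- simulate_pileups(g, NULL, mean_depth = 50, error_rate = 0,
                          mode = "binomial", seed = 4)
  cnt <- as.matrix(px0[, c("A", "C", "G", "T")])
  expect_true(all(rowSums(cnt > 0L) == 1L))
})

test_that("binomial-mode frequencies concentrate around the planted value", {
  g <- genome_seq("g", paste(rep("A", 30), collapse = ""))
  v <- data.frame(pos = 1:30, ref = "A", alt = "G", freq = 0.40,
                  stringsAsFactors = FALSE)
  px <- simulate_pileups(g, v, mean_depth = 10000, error_rate = 0,
                         mode = "binomial", seed = 11)
  emp <- px$G / px$depth
  expect_true(all(abs(emp - 0.40) <= 0.015))   # 3-sigma binomial bound
})

test_that("variants planted at absent positions are rejected", {
  g <- genome_seq("g", random_seq(100, seed = 2))
  v <- data.frame(pos = NA_integer_, ref = "A", alt = "G", freq = 0.4)
  expect_error(simulate_pileups(g, v, mode = "exact"), "deleted")
  v2 <- data.frame(pos = 101L, ref = "A", alt = "G", freq = 0.4)
  expect_error(simulate_pileups(g, v2, mode = "exact"), "deleted|range")
})

test_that("exact-mode scans recover exactly the planted variants per tier", {
  fx <- get_yqcg_fixture()
  for (t in c(0.05, 0.20, 0.35)) {
    got <- scan_sites(fx$pileups, t)
    want <- fx$truth[fx$truth$freq >= t, ]
    expect_equal(got$pos, want$pos)
    expect_equal(got$alt_allele, want$alt)
    expect_equal(got$frequency, want$freq)
  }
})
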