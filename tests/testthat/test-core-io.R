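# Readers/writers: FASTA, GFF3, pileup TSV, VCF, YAML config.

test_that("FASTA reading normalizes case and RNA bases and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "acgu", "NNgt"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "g1")
  expect_equal(recs[[1]]$seq, "ACGTNNGT")

  seqs <- lapply(1:3, function(i)
    genome_seq(paste0("s", i), random_seq(257, seed = i)))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f2)
  back <- read_fasta(f2)
  expect_equal(lapply(back, `[[`, "seq"), lapply(seqs, `[[`, "seq"))
  expect_equal(vapply(back, `[[`, "", "id"), c("s1", "s2", "s3"))
})

test_that("FASTA format errors are specific", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("", "ACGT", ">g1", "ACGT"), f)
  expect_error(read_fasta(f), "line 2")

  writeLines(c(">g1", "ACXGT"), f)
  expect_error(read_fasta(f), "outside A/C/G/T/N")

  writeLines(c(">g1", "ACGT", ">g1", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">g1", "ACGT", ">empty"), f)
  expect_error(read_fasta(f), "no sequence")

  writeLines(character(0), f)
  expect_equal(read_fasta(f), list())
})

test_that("GFF3 reading applies gene/Name/ID precedence and validates", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t10\t18\t.\t+\t0\tID=cds1;gene=sfp",
    "chr\tsrc\tCDS\t30\t41\t.\t-\t0\tID=cds2;Name=yqcG",
    "chr\tsrc\ttRNA\t2\t5\t.\t+\t.\tID=trn1",
    "chr\tsrc\tregion\t1\t100\t.\t+\t.\tID=reg1"), f)
  ann <- read_gff3(f)
  expect_equal(nrow(ann), 4L)
  expect_equal(ann$start, sort(ann$start))            # sorted by start
  expect_equal(ann$gene_name[ann$feature_id == "cds1"], "sfp")
  expect_equal(ann$gene_name[ann$feature_id == "cds2"], "yqcG")
  expect_equal(ann$gene_name[ann$feature_id == "trn1"], "trn1")
  expect_equal(ann$kind[ann$feature_id == "reg1"], "other")
  expect_equal(ann$end[ann$feature_id == "cds1"] -
                 ann$start[ann$feature_id == "cds1"] + 1L, 9L)

  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t10\t18\t.\t+\t0\tID=a",
               "chr\tsrc\tCDS\t20\t28\t.\t+\t0\tID=a"), f)
  expect_error(read_gff3(f), "duplicate")

  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t18\t10\t.\t+\t0\tID=a"), f)
  expect_error(read_gff3(f), "start > end")
})

test_that("GFF3 writing round-trips an annotation table", {
  ann <- feature_annotation(c("a", "b"), c("geneA", "geneB"),
                            c(11L, 400L), c(100L, 952L), c("+", "-"),
                            c("CDS", "rRNA"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, "chr", f)
  back <- read_gff3(f)
  expect_equal(as.data.frame(back), as.data.frame(ann))
})

test_that("pileup TSV round-trips randomly generated tables", {
  set.seed(42)
  p <- random_pileups(1000, seed = 42)
  with_ins <- sample(1000, 60)
  p$ins[with_ins] <- vapply(with_ins, function(i)
    paste(sprintf("%s:%d",
                  vapply(1:2, function(j) random_seq(sample(1:4, 1)), ""),
                  sample(1:5, 2, replace = TRUE)), collapse = ";"), "")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pileup_tsv(p, f)
  back <- read_pileup_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(p))
})

test_that("pileup validation errors cite the offending position", {
  p <- pileup_table(c(5L, 9L), c("A", "G"), A = c(70L, 1L),
                    C = c(30L, 9L))
  expect_equal(p$depth, c(100L, 10L))
  p$depth[2] <- 99L
  expect_error(validate_pileup(p), "pos 9")
  p2 <- pileup_table(5L, "A", A = 10L)
  p2$C <- -1L
  expect_error(validate_pileup(p2), "pos 5")
  expect_error(pileup_table(1L, "N", A = 5L), "ref_base")
})

test_that("VCF emission anchors indels and carries the INFO keys", {
  ref <- genome_seq("chr", "ACGTACGTACGTACGTACGT")
  pop <- data.frame(pos = c(7L, 11L, 4L),
                    ref_allele = c("G", "T", "T"),
                    alt_allele = c("A", "-", "+CC"),
                    frequency = c(0.4, 0.1, 0.25), depth = 100L,
                    tiers = c("0.05,0.2,0.35", "0.05", "0.05,0.2"),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pop, ref, f)
  lines <- grep("^[^#]", readLines(f), value = TRUE)
  fields <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(fields[1, 2], "7")
  expect_equal(fields[1, 4], "G"); expect_equal(fields[1, 5], "A")
  # 1-bp deletion of pos 11 anchors at POS 10: REF two bases, ALT one
  expect_equal(fields[2, 2], "10")
  expect_equal(nchar(fields[2, 4]), 2L); expect_equal(nchar(fields[2, 5]), 1L)
  # insertion after pos 4 anchors at POS 4
  expect_equal(fields[3, 2], "4")
  expect_equal(fields[3, 5], paste0(fields[3, 4], "CC"))
  expect_true(all(grepl("AF=", fields[, 8])))
  expect_true(all(grepl("TIERS=", fields[, 8])))

  v <- vcfR::read.vcfR(f, verbose = FALSE)   # independent parser agrees
  expect_equal(as.integer(v@fix[, "POS"]), c(7L, 10L, 4L))
  expect_equal(unname(vcfR::extract.info(v, "AF")[1]), "0.4")

  write_vcf(pop[0, ], ref, f)                # empty set -> header only
  expect_length(grep("^[^#]", readLines(f)), 0L)
  expect_error(write_vcf(transform(pop, pos = 99L), ref, f), "outside")
})

test_that("run configuration validates and round-trips through YAML", {
  expect_error(run_config(sensitivity_tiers = c(0.2, 0.05)), "ascending")
  expect_error(run_config(sensitivity_tiers = c(0, 0.5)), "\\(0, 1\\]")
  expect_error(run_config(min_depth = 0), "min_depth")
  cfg <- run_config(seed = 99L, sensitivity_tiers = c(0.1, 0.5),
                    band = 2000L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_equal(back, cfg)
})
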