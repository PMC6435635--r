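# Anchoring, chaining, and collinear genome comparison.

test_that("anchors cover identical sequences and split at substitutions", {
  s <- random_seq(10000, seed = 21)
  a <- find_anchors(s, s)
  expect_equal(nrow(a), 1L)
  expect_equal(a$ref_start, 1L)
  expect_equal(a$length, 10000L)

  q <- s
  mid <- 5000L
  substr(q, mid, mid) <- if (substr(s, mid, mid) == "A") "C" else "A"
  a2 <- find_anchors(s, q)
  expect_equal(nrow(a2), 2L)
  expect_equal(a2$ref_start[1], 1L)
  expect_equal(a2$ref_start[1] + a2$length[1] - 1L, mid - 1L)
  expect_equal(a2$ref_start[2], mid + 1L)
})

test_that("the anchor chain skips a planted deletion exactly", {
  s <- random_seq(50000, seed = 22)
  q <- paste0(substr(s, 1, 19999), substr(s, 22000, 50000))  # 2 kb gone
  ch <- chain_anchors(find_anchors(s, q))
  expect_equal(nrow(ch), 2L)
  expect_equal(ch$ref_start[1] + ch$length[1] - 1L, 19999L)
  expect_equal(ch$ref_start[2], 22000L)
  expect_equal(ch$qry_start[2], 20000L)
})

test_that("chaining matches the exhaustive oracle and drops transpositions", {
  collinear <- data.frame(ref_start = c(1L, 200L, 500L),
                          qry_start = c(1L, 210L, 490L),
                          length = c(100L, 150L, 80L))
  expect_equal(nrow(chain_anchors(collinear)), 3L)

  transposed <- rbind(collinear,
                      data.frame(ref_start = 350L, qry_start = 5000L,
                                 length = 20L))
  expect_false(350L %in% chain_anchors(transposed)$ref_start)

  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(6:10, 1)
    a <- data.frame(ref_start = sample(1:2000, n),
                    qry_start = sample(1:2000, n),
                    length = sample(10:200, n, replace = TRUE))
    got <- chain_anchors(a)
    expect_equal(sum(got$length), brute_chain_score(a),
                 info = paste("seed", seed))
  }
})

test_that("identical genomes diff to nothing", {
  g <- genome_seq("g", random_seq(20000, seed = 23))
  d <- diff_genomes(g, g)
  expect_equal(nrow(d$variants), 0L)
  expect_equal(nrow(d$deleted_segments), 0L)
  expect_equal(nrow(d$inserted_segments), 0L)
})

test_that("unrelated sequences raise a collinearity error", {
  a <- genome_seq("a", random_seq(3000, seed = 24))
  b <- genome_seq("b", random_seq(3000, seed = 25))
  expect_error(diff_genomes(a, b), "collinear")
})

test_that("random edit sets round-trip through the diff", {
  for (seed in 1:4) {
    set.seed(seed * 100)
    ref <- genome_seq("r", random_seq(20000, seed = seed * 100 + 1))
    pos <- sort(sample(seq(500, 18000, by = 350), 12))
    edits <- do.call(rbind, lapply(seq_along(pos), function(i) {
      p <- pos[i]
      kind <- sample(c("snp", "del", "ins"), 1)
      if (kind == "snp") {
        b <- substr(ref$seq, p, p)
        data.frame(kind = "snp", pos = p, ref = b,
                   alt = sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   stringsAsFactors = FALSE)
      } else if (kind == "del") {
        l <- sample(1:8, 1)
        nn <- left_normalize_indel(ref$seq, p,
                                   substr(ref$seq, p, p + l - 1L), "")
        data.frame(kind = "del", pos = nn$pos, ref = nn$ref, alt = "",
                   stringsAsFactors = FALSE)
      } else {
        l <- sample(1:8, 1)
        nn <- left_normalize_indel(ref$seq, p, "",
                                   random_seq(l))
        data.frame(kind = "ins", pos = nn$pos, ref = "", alt = nn$alt,
                   stringsAsFactors = FALSE)
      }
    }))
    qry <- derive_strain(ref, edits)
    d <- diff_genomes(ref, qry)
    # byte-exact reconstruction from the emitted edits
    expect_identical(apply_edits(ref, edits_from_diff(d, ref)), qry$seq,
                     info = paste("seed", seed))
    # recovered set equals the planted left-normalized set
    got <- d$variants
    expect_equal(got$ref_pos, edits$pos)
    expect_equal(got$ref_allele, edits$ref)
    expect_equal(got$alt_allele, edits$alt)
  }
})

test_that("a long indel becomes a segment, never a DIP", {
  ref <- genome_seq("r", random_seq(30000, seed = 31))
  edits <- data.frame(kind = "del", pos = 10000L,
                      ref = substr(ref$seq, 10000L, 11199L), alt = "",
                      stringsAsFactors = FALSE)
  qry <- derive_strain(ref, edits)
  d <- diff_genomes(ref, qry)   # default min_segment_len 1000
  expect_equal(nrow(d$deleted_segments), 1L)
  expect_equal(d$deleted_segments$length, 1200L)
  expect_false(any(abs(d$variants$length_delta) >= 1000L))
  # below the threshold the same event is a DIP
  d2 <- diff_genomes(ref, qry, run_config(min_segment_len = 5000L))
  expect_equal(nrow(d2$deleted_segments), 0L)
  expect_equal(sum(d2$variants$kind == "DIP"), 1L)
})

test_that("the diff is symmetric under argument exchange", {
  ref <- genome_seq("r", random_seq(15000, seed = 41))
  edits <- data.frame(
    kind = c("snp", "del", "ins"),
    pos = c(3000L, 6000L, 9000L),
    ref = c(substr(ref$seq, 3000L, 3000L),
            substr(ref$seq, 6000L, 6004L), ""),
    alt = c(if (substr(ref$seq, 3000L, 3000L) == "A") "G" else "A",
            "", "TTACG"),
    stringsAsFactors = FALSE)
  edits <- do.call(rbind, lapply(seq_len(nrow(edits)), function(i) {
    e <- edits[i, ]
    if (e$kind == "snp") return(e)
    nn <- left_normalize_indel(ref$seq, e$pos, e$ref, e$alt)
    data.frame(kind = e$kind, pos = nn$pos, ref = nn$ref, alt = nn$alt,
               stringsAsFactors = FALSE)
  }))
  qry <- derive_strain(ref, edits)
  fwd <- diff_genomes(ref, qry)
  rev <- diff_genomes(qry, ref)
  expect_equal(sum(fwd$variants$kind == "SNP"),
               sum(rev$variants$kind == "SNP"))
  # alleles swap
  fs <- fwd$variants[fwd$variants$kind == "SNP", ]
  rs <- rev$variants[rev$variants$kind == "SNP", ]
  expect_equal(fs$ref_allele, rs$alt_allele)
  expect_equal(fs$alt_allele, rs$ref_allele)
  # deletions and insertions mirror
  fd <- fwd$variants[fwd$variants$alt_allele == "", ]
  ri <- rev$variants[rev$variants$ref_allele == "", ]
  expect_equal(fd$ref_allele, ri$alt_allele)
})

test_that("region presence classification spans intact to absent", {
  ref <- genome_seq("r", random_seq(30000, seed = 51))
  region <- c(10000L, 13999L)
  same <- locate_region(region, ref, ref)
  expect_equal(same$classification, "intact")
  expect_equal(same$fraction, 1.0)

  gone <- derive_strain(ref, data.frame(
    kind = "del", pos = 10000L, ref = substr(ref$seq, 10000L, 13999L),
    alt = "", stringsAsFactors = FALSE))
  lr <- locate_region(region, ref, gone)
  expect_equal(lr$classification, "absent")
  expect_lt(lr$fraction, 0.05)

  half <- derive_strain(ref, data.frame(
    kind = "del", pos = 10000L, ref = substr(ref$seq, 10000L, 11999L),
    alt = "", stringsAsFactors = FALSE))
  lh <- locate_region(region, ref, half)
  expect_equal(lh$classification, "partial")
  expect_equal(lh$fraction, 0.5, tolerance = 0.01)
})
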