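# Gene-level aggregation of population variants across sensitivity
# tiers, hotspot calling (>= 2 SNPs at the lowest tier), and
# within-gene positional statistics.

# assign each variant position to containing features (possibly
# several) or to the intergenic interval between feature-covered runs
assign_to_features <- function(pos, annotations) {
  n <- length(pos)
  if (nrow(annotations) == 0L) {
    return(data.frame(variant = seq_len(n), feature_id = "intergenic:1-end",
                      feature_start = 1L, stringsAsFactors = FALSE))
  }
  fr <- IRanges::IRanges(start = annotations$start, end = annotations$end)
  vr <- IRanges::IRanges(start = pos, width = 1L)
  ov <- IRanges::findOverlaps(vr, fr)
  hit <- data.frame(variant = S4Vectors::queryHits(ov),
                    feature_id = annotations$feature_id[
                      S4Vectors::subjectHits(ov)],
                    feature_start = annotations$start[
                      S4Vectors::subjectHits(ov)],
                    stringsAsFactors = FALSE)
  orphan <- setdiff(seq_len(n), unique(hit$variant))
  if (length(orphan)) {
    cov <- IRanges::reduce(fr)
    gaps <- IRanges::gaps(cov, start = 1L)
    gi <- IRanges::findOverlaps(IRanges::IRanges(pos[orphan], width = 1L),
                                gaps)
    gs <- IRanges::start(gaps)[S4Vectors::subjectHits(gi)]
    ge <- IRanges::end(gaps)[S4Vectors::subjectHits(gi)]
    lab <- sprintf("intergenic:%d-%d", gs, ge)
    # positions beyond the last feature fall outside gaps(,start=1)
    no_gap <- setdiff(seq_along(orphan), S4Vectors::queryHits(gi))
    hit2 <- data.frame(variant = orphan[S4Vectors::queryHits(gi)],
                       feature_id = lab, feature_start = gs,
                       stringsAsFactors = FALSE)
    if (length(no_gap)) {
      tail_start <- max(annotations$end) + 1L
      hit2 <- rbind(hit2, data.frame(
        variant = orphan[no_gap],
        feature_id = sprintf("intergenic:%d-end", tail_start),
        feature_start = tail_start, stringsAsFactors = FALSE))
    }
    hit <- rbind(hit, hit2)
  }
  hit[order(hit$variant), , drop = FALSE]
}

#' Aggregate population variants per gene / intergenic interval
#'
#' Assigns each variant to the feature containing it (once per feature
#' when genes overlap) or to its intergenic interval, counts variants
#' per sensitivity tier, and flags hypermutation hotspots: features
#' with at least two SNPs at the lowest-tier scan.  Only features with
#' at least one variant at the lowest tier are reported, sorted by
#' lowest-tier count (descending; ties by feature id).
#'
#' @param variants A `pop_variants` data frame (needs `pos` and
#'   `frequency`).
#' @param annotations A [feature_annotation()] data frame in the same
#'   coordinates as the variants.
#' @param tiers Sensitivity tiers (ascending).
#' @param effects Optional output of [annotate_variants()] on the same
#'   variant rows, used to add amino-acid-changing counts per tier.
#' @return A data frame of class `hotspot_report`: `feature_id`,
#'   one `count_<tier>` column per tier, `hotspot`, optional
#'   `aa_changing_<tier>` columns, and a `positions` list column of
#'   within-feature offsets (1-based from feature start).
#' @export
aggregate_hotspots <- function(variants, annotations,
                               tiers = c(0.05, 0.20, 0.35),
                               effects = NULL) {
  tiers <- sort(tiers)
  empty <- data.frame(feature_id = character(0), stringsAsFactors = FALSE)
  if (is.null(variants) || nrow(variants) == 0L) {
    for (t in tiers) empty[[paste0("count_", t)]] <- integer(0)
    empty$hotspot <- logical(0)
    class(empty) <- c("hotspot_report", "data.frame")
    return(empty)
  }
  asg <- assign_to_features(variants$pos, annotations)
  asg$freq <- variants$frequency[asg$variant]
  aa_flag <- NULL
  if (!is.null(effects)) {
    aa_ids <- unique(effects$variant_id[
      effects$category %in% c("missense", "stop_gain", "stop_loss")])
    aa_flag <- seq_len(nrow(variants)) %in% aa_ids
  }
  feats <- unique(asg[, c("feature_id", "feature_start")])
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    sub <- asg[asg$feature_id == feats$feature_id[i], , drop = FALSE]
    out <- data.frame(feature_id = feats$feature_id[i],
                      stringsAsFactors = FALSE)
    for (t in tiers)
      out[[paste0("count_", t)]] <- sum(sub$freq >= t)
    out$hotspot <- out[[paste0("count_", tiers[1L])]] >= 2L
    if (!is.null(aa_flag))
      for (t in tiers)
        out[[paste0("aa_changing_", t)]] <-
          sum(aa_flag[sub$variant] & sub$freq >= t)
    out$positions <- I(list(sort(
      variants$pos[sub$variant] - feats$feature_start[i] + 1L)))
    out
  })
  rep <- do.call(rbind, rows)
  low <- rep[[paste0("count_", tiers[1L])]]
  rep <- rep[low > 0L, , drop = FALSE]
  rep <- rep[order(-rep[[paste0("count_", tiers[1L])]], rep$feature_id), ,
             drop = FALSE]
  rownames(rep) <- NULL
  class(rep) <- c("hotspot_report", "data.frame")
  rep
}

#' Top-ranked hotspot features
#'
#' @param reports Output of [aggregate_hotspots()] (already sorted by
#'   lowest-tier count, ties by feature id).
#' @param n Number of features to return (the full list if fewer).
#' @return The first `n` report rows.
#' @export
rank_top <- function(reports, n) {
  utils::head(reports, n)
}

#' Positional distribution of variants within a gene
#'
#' Bins within-gene offsets and tests the bin counts against a uniform
#' position distribution by chi-square goodness of fit.  The test is an
#' addition of this package (the non-randomness of hotspot positions is
#' otherwise only a qualitative observation): to keep expected counts
#' at 5 or more, the test is run on at most `floor(n/5)` equal bins,
#' and declined entirely (statistic and p `NA`) when fewer than 3 such
#' bins are possible; the requested profile is emitted regardless.
#'
#' @param positions Within-gene offsets (1-based).
#' @param gene_length Gene length in bp.
#' @param n_bins Number of profile bins (>= 3; default 20).
#' @return A list: `profile` (data frame `bin, start, end, count`),
#'   `statistic`, `p_value`, `n_bins_tested`, `tested`.
#' @export
positional_profile <- function(positions, gene_length, n_bins = 20L) {
  if (n_bins < 3L) stop("positional_profile: n_bins must be >= 3")
  stopifnot(all(positions >= 1L), all(positions <= gene_length))
  bin_counts <- function(b) {
    w <- gene_length / b
    tabulate(pmin(ceiling(positions / w), b), b)
  }
  w <- gene_length / n_bins
  profile <- data.frame(bin = seq_len(n_bins),
                        start = floor((seq_len(n_bins) - 1L) * w) + 1L,
                        end = floor(seq_len(n_bins) * w),
                        count = bin_counts(n_bins))
  n <- length(positions)
  b_eff <- min(n_bins, n %/% 5L)
  if (b_eff < 3L)
    return(list(profile = profile, statistic = NA_real_,
                p_value = NA_real_, n_bins_tested = 0L, tested = FALSE))
  ct <- stats::chisq.test(bin_counts(b_eff))
  list(profile = profile, statistic = unname(ct$statistic),
       p_value = ct$p.value, n_bins_tested = b_eff, tested = TRUE)
}
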