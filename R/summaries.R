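# Closed-form summary statistics: biocontrol index with replicate
# statistics, average sequencing coverage, GC content.

# half-up decimal rounding (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Biocontrol index from paired colony radii
#'
#' `BCI = (C - T) / C * 100`, computed per replicate pair — `C` the
#' pathogen colony radius on the control plate, `T` the radius in
#' confrontation with the antagonist — then summarised as mean and
#' sample standard deviation (n − 1), both reported to 2 decimals
#' with the raw per-replicate values retained.
#'
#' @param control_radii,treatment_radii Equal-length positive numeric
#'   vectors (mm); treatment radii may be 0 (full inhibition).
#' @return A list: `mean`, `sd` (2-decimal percent), `values`
#'   (raw per-replicate BCI).
#' @examples
#' compute_bci(c(30, 30, 30), c(10, 10, 10))  # 66.67 +/- 0.00
#' @export
compute_bci <- function(control_radii, treatment_radii) {
  if (length(control_radii) != length(treatment_radii))
    stop("compute_bci: control and treatment radii must pair up (equal length)")
  if (length(control_radii) == 0L)
    stop("compute_bci: no replicates")
  if (any(control_radii <= 0))
    stop("compute_bci: control radii must be positive")
  if (any(treatment_radii < 0))
    stop("compute_bci: treatment radii must be non-negative")
  bci <- (control_radii - treatment_radii) / control_radii * 100
  s <- if (length(bci) > 1L) stats::sd(bci) else 0
  list(mean = round_half_up(mean(bci), 2L),
       sd = round_half_up(s, 2L),
       values = bci)
}

#' Average sequencing coverage
#'
#' `n_reads * read_len / genome_len`, truncated (not rounded) to two
#' decimals — the display convention that reproduces the coverage the
#' source platform reports for these read counts.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length (nt).
#' @param genome_len Genome length (bp).
#' @param allow_zero If `TRUE`, `n_reads = 0` yields 0 instead of an
#'   error.
#' @return Coverage, truncated to 2 decimals.
#' @examples
#' average_coverage(6531607, 50, 4195195)  # 77.84
#' @export
average_coverage <- function(n_reads, read_len, genome_len,
                             allow_zero = FALSE) {
  if (genome_len <= 0) stop("average_coverage: genome_len must be positive")
  if (read_len <= 0) stop("average_coverage: read_len must be positive")
  if (n_reads == 0 && allow_zero) return(0)
  if (n_reads <= 0) stop("average_coverage: n_reads must be positive")
  floor(n_reads * read_len / genome_len * 100) / 100
}

#' GC content of a sequence, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`, `N` bases excluded from both
#' numerator and denominator, rounded half-up to 1 decimal.
#'
#' @param x A [genome_seq()] or nucleotide string.
#' @return GC percentage (1 decimal).
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(x) {
  s <- as_seq_string(x)
  gc <- nchar(gsub("[^GC]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  if (acgt == 0L) stop("gc_content: no A/C/G/T bases in sequence")
  round_half_up(100 * gc / acgt, 1L)
}

#' @rdname gc_content
#' @export
at_content <- function(x) {
  s <- as_seq_string(x)
  at <- nchar(gsub("[^AT]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  if (acgt == 0L) stop("at_content: no A/C/G/T bases in sequence")
  round_half_up(100 * at / acgt, 1L)
}
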