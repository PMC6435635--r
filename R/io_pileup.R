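#' Per-site read pileup table
#'
#' The package's pileup container: one row per covered reference
#' position, with read counts per base, reads supporting a deletion of
#' the site, and insertion evidence anchored after the site.  The depth
#' column is always derived as `A + C + G + T + del` (insertions do not
#' add depth; they are carried by reads already counted at the site).
#'
#' @param pos 1-based reference positions.
#' @param ref_base Reference base per site (`A/C/G/T`).
#' @param A,C,G,T Non-negative read counts per base.
#' @param del Reads supporting a deletion of this site.
#' @param ins Insertion evidence: `"seq:count"` pairs joined by `";"`,
#'   or `"."` when none.
#' @return A `data.frame` of class `site_pileup` with a derived `depth`
#'   column.
#' @export
pileup_table <- function(pos, ref_base, A = 0L, C = 0L, G = 0L, T = 0L,
                         del = 0L, ins = ".") {
  n <- length(pos)
  df <- data.frame(pos = as.integer(pos),
                   ref_base = as.character(ref_base),
                   A = as.integer(rep_len(A, n)), C = as.integer(rep_len(C, n)),
                   G = as.integer(rep_len(G, n)), T = as.integer(rep_len(T, n)),
                   del = as.integer(rep_len(del, n)),
                   ins = as.character(rep_len(ins, n)),
                   stringsAsFactors = FALSE)
  df$depth <- df$A + df$C + df$G + df$T + df$del
  class(df) <- c("site_pileup", "data.frame")
  validate_pileup(df)
}

#' Validate a pileup table
#'
#' Checks column presence, non-negative counts, the base alphabet, and
#' the depth invariant `depth == A + C + G + T + del`.
#'
#' @param p A pileup `data.frame`.
#' @return `p`, invisibly classed as `site_pileup`.
#' @export
validate_pileup <- function(p) {
  need <- c("pos", "ref_base", "A", "C", "G", "T", "del", "ins", "depth")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("pileup validation error: missing column(s) ", paste(miss, collapse = ", "))
  cnt <- as.matrix(p[, c("A", "C", "G", "T", "del")])
  if (any(cnt < 0L)) {
    i <- which(rowSums(cnt < 0L) > 0L)[1L]
    stop("pileup validation error at pos ", p$pos[i], ": negative count")
  }
  bad_ref <- which(!p$ref_base %in% c("A", "C", "G", "T"))
  if (length(bad_ref))
    stop("pileup validation error at pos ", p$pos[bad_ref[1L]],
         ": ref_base must be one of A/C/G/T")
  ds <- rowSums(cnt)
  off <- which(p$depth != ds)
  if (length(off))
    stop("pileup validation error at pos ", p$pos[off[1L]],
         ": depth (", p$depth[off[1L]], ") != A+C+G+T+del (", ds[off[1L]], ")")
  if (!inherits(p, "site_pileup")) class(p) <- c("site_pileup", class(p))
  invisible(p)
}

#' Read / write the package pileup TSV
#'
#' The on-disk dialect has columns `pos, ref_base, A, C, G, T, DEL, INS`
#' (tab-separated, header line); `INS` holds semicolon-joined
#' `seq:count` pairs or `"."`.  Depth is derived on read, so a
#' depth-inconsistent file cannot exist; in-memory tables are still
#' checked by [validate_pileup()].  `write_pileup_tsv()` then
#' `read_pileup_tsv()` is an identity on valid tables.
#'
#' @param path Path to the TSV file.
#' @return For `read_pileup_tsv()`, a `site_pileup` data frame.
#' @export
read_pileup_tsv <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("ref_base", "INS")),
                          data.table = FALSE)
  need <- c("pos", "ref_base", "A", "C", "G", "T", "DEL", "INS")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("pileup format error: missing column(s) ", paste(miss, collapse = ", "))
  pileup_table(dt$pos, dt$ref_base, dt$A, dt$C, dt$G, dt$T, dt$DEL, dt$INS)
}

#' @rdname read_pileup_tsv
#' @param records A `site_pileup` data frame.
#' @export
write_pileup_tsv <- function(records, path) {
  validate_pileup(records)
  out <- data.frame(pos = records$pos, ref_base = records$ref_base,
                    A = records$A, C = records$C, G = records$G,
                    T = records$T, DEL = records$del, INS = records$ins,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# "seq:count;seq:count" -> named integer vector (empty for ".")
parse_ins <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(integer(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(x) as.integer(x[2]), 0L)
  names(counts) <- vapply(kv, `[[`, "", 1L)
  counts
}

format_ins <- function(counts) {
  if (length(counts) == 0L) return(".")
  paste(sprintf("%s:%d", names(counts), as.integer(counts)), collapse = ";")
}
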