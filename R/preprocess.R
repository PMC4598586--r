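#' Residual enzyme sequences and their bisulfite-converted forms
#'
#' The ligation design leaves short enzyme-derived residues at read 5' ends:
#' AGCTC for SacI and TAA for MseI. On bisulfite reads these residues appear
#' with any subset of C->T (or, on complement strands, G->A) conversions, so
#' all such deterministic variants are matched with zero mismatches.
#'
#' @param residues Character vector of unconverted residues.
#' @return Character vector of residue variants, longest first.
#' @export
enzyme_residues <- function(residues = c("AGCTC", "TAA")) {
  variants <- function(res, from, to) {
    idx <- which(strsplit(res, "")[[1]] == from)
    if (length(idx) == 0) return(res)
    combos <- unlist(lapply(0:length(idx), function(k) {
      utils::combn(idx, k, simplify = FALSE)
    }), recursive = FALSE)
    vapply(combos, function(ps) {
      ch <- strsplit(res, "")[[1]]
      ch[ps] <- to
      paste0(ch, collapse = "")
    }, character(1))
  }
  out <- unique(unlist(lapply(residues, function(r) {
    c(variants(r, "C", "T"), variants(r, "G", "A"))
  })))
  out[order(-nchar(out), out)]
}

trim_one_end <- function(seqs, quals, residues, keep_len) {
  n <- length(seqs)
  raw <- nchar(seqs) > keep_len          # already-trimmed reads pass through
  off <- integer(n)
  for (res in residues) {
    hit <- raw & off == 0L & startsWith(seqs, res)
    off[hit] <- nchar(res)
  }
  keep_to <- ifelse(raw, off + keep_len, nchar(seqs))
  list(seqs = substr(seqs, off + 1L, keep_to),
       quals = substr(quals, off + 1L, keep_to),
       trim5p = off)
}

#' Trim read pairs to the analysis span
#'
#' Removes the residual enzyme recognition sequence (or any of its bisulfite
#' conversions) from the 5' end of each mate when present, then truncates
#' both sequence and qualities to `keep_len` bases (the first 75 bp are
#' retained for analysis). Reads already at or below `keep_len` are left
#' unchanged, which makes trimming idempotent.
#'
#' @param reads Tibble with columns name, seq1, qual1, seq2, qual2.
#' @param residues Residue variants from [enzyme_residues()].
#' @param keep_len Bases to retain from the 5' end (default 75).
#' @return `reads` with trimmed seq/qual columns plus `trim1`/`trim2`, the
#'   number of residue bases removed from each mate's 5' end.
#' @export
trim_reads <- function(reads, residues = enzyme_residues(), keep_len = 75L) {
  stopifnot(all(c("seq1", "qual1", "seq2", "qual2") %in% names(reads)))
  if (any(nchar(reads$seq1) != nchar(reads$qual1)) ||
      any(nchar(reads$seq2) != nchar(reads$qual2))) {
    bad <- which(nchar(reads$seq1) != nchar(reads$qual1) |
                   nchar(reads$seq2) != nchar(reads$qual2))[1]
    stop("malformed read record at index ", bad,
         ": sequence/quality length mismatch", call. = FALSE)
  }
  t1 <- trim_one_end(reads$seq1, reads$qual1, residues, keep_len)
  t2 <- trim_one_end(reads$seq2, reads$qual2, residues, keep_len)
  out <- reads
  out$seq1 <- t1$seqs; out$qual1 <- t1$quals
  out$seq2 <- t2$seqs; out$qual2 <- t2$quals
  out$trim1 <- t1$trim5p
  out$trim2 <- t2$trim5p
  out
}

#' Quality-filter read pairs
#'
#' Discards a pair when either mate has strictly more than `max_low_frac` of
#' its bases below Phred `min_q` (the ">5% of bases with Q<30" rule); pairs
#' exactly at the boundary are retained. Retained pairs are unmodified, and
#' both mates of a failing pair are dropped together because downstream
#' alignment is paired.
#'
#' @param reads Tibble with columns name, seq1, qual1, seq2, qual2.
#' @param max_low_frac Maximum tolerated fraction of low-quality bases.
#' @param min_q Phred threshold defining a low-quality base.
#' @return List with `reads` (retained pairs) and `log` (tibble of input,
#'   discarded and retained pair counts).
#' @export
quality_filter <- function(reads, max_low_frac = 0.05, min_q = 30L) {
  low_frac <- function(quals) {
    vapply(quals, function(q) {
      v <- utf8ToInt(q) - 33L
      mean(v < min_q)
    }, numeric(1), USE.NAMES = FALSE)
  }
  bad <- low_frac(reads$qual1) > max_low_frac |
    low_frac(reads$qual2) > max_low_frac
  list(reads = reads[!bad, , drop = FALSE],
       log = tibble::tibble(input_pairs = nrow(reads),
                            discarded = sum(bad),
                            retained = sum(!bad)))
}
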