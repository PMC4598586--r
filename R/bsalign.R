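#' Build a converted-genome alignment index
#'
#' Holds the reference together with its two three-letter alphabets (C->T and
#' G->A), against which bisulfite reads are matched after the corresponding
#' read conversion. Seed lookup is exact k-mer matching over the converted
#' (or plain) genome; [index_lookup()] exposes it and returns exactly the
#' positions a brute-force scan would.
#'
#' @param ref Named character vector of chromosome sequences.
#' @param k Seed length (>= 10, default 20). Chromosomes shorter than `k` are
#'   excluded with a warning.
#' @return An object of class `bs_index`.
#' @export
build_bs_index <- function(ref, k = 20L) {
  stop_if_not_ref(ref)
  stopifnot(k >= 10)
  short <- nchar(ref) < k
  if (any(short)) {
    warning("excluding chromosome(s) shorter than k: ",
            paste(names(ref)[short], collapse = ", "))
    ref <- ref[!short]
  }
  structure(list(ref = ref,
                 spaces = list(plain = ref,
                               CT = chartr("C", "T", ref),
                               GA = chartr("G", "A", ref)),
                 chrom_lengths = chrom_lengths_of(ref),
                 k = as.integer(k)),
            class = "bs_index")
}

#' Exact k-mer lookup in an alignment index
#'
#' @param index A [build_bs_index()] index.
#' @param kmers Character vector of k-mers (all of length `index$k`).
#' @param space One of "plain", "CT", "GA".
#' @return Tibble with columns kmer_idx, chrom, pos (0-based start).
#' @export
index_lookup <- function(index, kmers, space = c("plain", "CT", "GA")) {
  space <- match.arg(space)
  stopifnot(all(nchar(kmers) == index$k))
  if (length(kmers) == 0) {
    return(tibble::tibble(kmer_idx = integer(), chrom = character(),
                          pos = integer()))
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  hits <- lapply(names(index$spaces[[space]]), function(chrom) {
    mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(
      index$spaces[[space]][[chrom]]))
    st <- Biostrings::startIndex(mi)
    ns <- lengths(st)
    tibble::tibble(kmer_idx = rep(seq_along(ns), ns),
                   chrom = chrom,
                   pos = unlist(st[ns > 0], use.names = FALSE) - 1L)
  })
  dplyr::bind_rows(hits)
}

# Transform a read into the matching space/orientation.
transform_read <- function(seqs, space, orient) {
  s <- if (orient == "rc") revcomp(seqs) else seqs
  switch(space, plain = s, CT = chartr("C", "T", s), GA = chartr("G", "A", s))
}

# Candidate alignments for one (mate, space, orient) combination: exact-seed
# hits at two read offsets, fully verified against the converted reference.
mate_candidates <- function(tr_seqs, index, space, max_mm) {
  k <- index$k
  lens <- nchar(tr_seqs)
  idx_ok <- which(lens >= k)
  if (length(idx_ok) == 0) {
    return(tibble::tibble(read_idx = integer(), chrom = character(),
                          pos = integer(), mm = integer()))
  }
  # Two seeds per read; disjoint whenever the read is >= 2k, which with a
  # 1-mismatch budget guarantees at least one exact seed (pigeonhole).
  off2 <- pmin(k, lens[idx_ok] - k)
  seeds <- tibble::tibble(
    read_idx = rep(idx_ok, 2L),
    offset = c(rep(0L, length(idx_ok)), off2),
    kmer = c(substr(tr_seqs[idx_ok], 1L, k),
             substr(tr_seqs[idx_ok], off2 + 1L, off2 + k)))
  seeds <- dplyr::distinct(seeds)
  hits <- index_lookup(index, seeds$kmer, space)
  if (nrow(hits) == 0) {
    return(tibble::tibble(read_idx = integer(), chrom = character(),
                          pos = integer(), mm = integer()))
  }
  cand <- tibble::tibble(read_idx = seeds$read_idx[hits$kmer_idx],
                         chrom = hits$chrom,
                         pos = hits$pos - seeds$offset[hits$kmer_idx])
  cand$len <- lens[cand$read_idx]
  cand <- cand[cand$pos >= 0 &
                 cand$pos + cand$len <= index$chrom_lengths[cand$chrom], ]
  cand <- dplyr::distinct(cand, .data$read_idx, .data$chrom, .data$pos,
                          .keep_all = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(read_idx = integer(), chrom = character(),
                          pos = integer(), mm = integer()))
  }
  ref_sub <- substring(index$spaces[[space]][cand$chrom],
                       cand$pos + 1L, cand$pos + cand$len)
  cand$mm <- str_mismatches(tr_seqs[cand$read_idx], ref_sub)
  cand[cand$mm <= max_mm, c("read_idx", "chrom", "pos", "len", "mm")]
}

align_core <- function(reads, index, templates, max_mm, max_insert) {
  n <- nrow(reads)
  empty <- tibble::tibble(name = character(), chrom = character(),
                          start1 = integer(), len1 = integer(),
                          orient1 = character(), start2 = integer(),
                          len2 = integer(), orient2 = character(),
                          bs_strand = character(), mm = integer())
  if (n == 0) {
    attr(empty, "counts") <- c(input = 0L, aligned = 0L, ambiguous = 0L,
                               unaligned = 0L)
    return(empty)
  }
  combos <- unique(do.call(rbind, lapply(templates, function(tp) {
    data.frame(mate = c(1L, 2L), space = tp$space,
               orient = c(tp$orient1, tp$orient2))
  })))
  cand_by <- list()
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    seqs <- if (cb$mate == 1L) reads$seq1 else reads$seq2
    tr <- transform_read(seqs, cb$space, cb$orient)
    cand_by[[paste(cb$mate, cb$space, cb$orient)]] <-
      mate_candidates(tr, index, cb$space, max_mm)
  }
  pair_cands <- lapply(templates, function(tp) {
    c1 <- cand_by[[paste(1L, tp$space, tp$orient1)]]
    c2 <- cand_by[[paste(2L, tp$space, tp$orient2)]]
    if (nrow(c1) == 0 || nrow(c2) == 0) return(NULL)
    j <- dplyr::inner_join(
      dplyr::rename(c1, pos1 = "pos", len1 = "len", mm1 = "mm"),
      dplyr::rename(c2, pos2 = "pos", len2 = "len", mm2 = "mm"),
      by = c("read_idx", "chrom"), relationship = "many-to-many")
    if (nrow(j) == 0) return(NULL)
    if (tp$r1_side == "left") {
      pL <- j$pos1; lenL <- j$len1; pR <- j$pos2; lenR <- j$len2
    } else {
      pL <- j$pos2; lenL <- j$len2; pR <- j$pos1; lenR <- j$len1
    }
    ins <- pR + lenR - pL
    ok <- pL <= pR & ins <= max_insert & ins >= pmax(lenL, lenR) &
      j$mm1 + j$mm2 <= max_mm
    j <- j[ok, ]
    if (nrow(j) == 0) return(NULL)
    tibble::tibble(read_idx = j$read_idx, chrom = j$chrom,
                   start1 = j$pos1, len1 = j$len1, orient1 = tp$orient1,
                   start2 = j$pos2, len2 = j$len2, orient2 = tp$orient2,
                   bs_strand = tp$name, mm = j$mm1 + j$mm2)
  })
  cands <- dplyr::bind_rows(pair_cands)
  if (nrow(cands) == 0) {
    attr(empty, "counts") <- c(input = n, aligned = 0L, ambiguous = 0L,
                               unaligned = n)
    return(empty)
  }
  cands <- dplyr::distinct(cands)
  best <- cands |>
    dplyr::group_by(.data$read_idx) |>
    dplyr::filter(.data$mm == min(.data$mm)) |>
    dplyr::mutate(n_best = dplyr::n()) |>
    dplyr::ungroup()
  uniq <- best[best$n_best == 1L, ]
  n_amb <- length(unique(best$read_idx[best$n_best > 1L]))
  out <- tibble::tibble(name = reads$name[uniq$read_idx],
                        chrom = uniq$chrom,
                        start1 = uniq$start1, len1 = uniq$len1,
                        orient1 = uniq$orient1,
                        start2 = uniq$start2, len2 = uniq$len2,
                        orient2 = uniq$orient2,
                        bs_strand = uniq$bs_strand, mm = uniq$mm)
  attr(out, "counts") <- c(input = n, aligned = nrow(out), ambiguous = n_amb,
                           unaligned = n - nrow(out) - n_amb)
  out
}

bs_templates <- list(
  list(name = "OT", space = "CT", orient1 = "fwd", orient2 = "rc",
       r1_side = "left"),
  list(name = "CTOT", space = "CT", orient1 = "rc", orient2 = "fwd",
       r1_side = "right"),
  list(name = "OB", space = "GA", orient1 = "rc", orient2 = "fwd",
       r1_side = "right"),
  list(name = "CTOB", space = "GA", orient1 = "fwd", orient2 = "rc",
       r1_side = "left"))

plain_templates <- list(
  list(name = "fwd", space = "plain", orient1 = "fwd", orient2 = "rc",
       r1_side = "left"),
  list(name = "rev", space = "plain", orient1 = "rc", orient2 = "fwd",
       r1_side = "right"))

#' Align bisulfite read pairs non-directionally
#'
#' Evaluates all four bisulfite-strand hypotheses (OT, OB, CTOT, CTOB) in
#' three-letter space: the read is C->T or G->A converted and matched against
#' the correspondingly converted reference, so converted cytosines are never
#' counted as mismatches. A pair aligns when both mates match in proper
#' orientation with a consistent insert (<= `max_insert`, the size-selection
#' upper bound) and at most `max_mm` total mismatches in converted space.
#' Only pairs with a strictly unique best-scoring location are reported;
#' ties are counted as ambiguous, mirroring the uniquely-mapped-reads rule.
#'
#' @param reads Trimmed, filtered read pairs (tibble name/seq1/qual1/...).
#' @param index A [build_bs_index()] index.
#' @param max_mm Maximum total mismatches per pair in converted space.
#' @param max_insert Maximum mate span in bp.
#' @return Alignment tibble (name, chrom, start1/len1/orient1, start2/len2/
#'   orient2, bs_strand, mm) with a `counts` attribute
#'   (input/aligned/ambiguous/unaligned).
#' @export
align_bs_reads <- function(reads, index, max_mm = 1L, max_insert = 500L) {
  align_core(reads, index, bs_templates, max_mm, max_insert)
}

#' Align plain (non-bisulfite) read pairs
#'
#' As [align_bs_reads()] but in the unconverted alphabet with the two genomic
#' strand hypotheses; used for ddRAD reads ahead of SNP calling.
#'
#' @inheritParams align_bs_reads
#' @return Alignment tibble with a `counts` attribute.
#' @export
align_plain_reads <- function(reads, index, max_mm = 1L, max_insert = 500L) {
  align_core(reads, index, plain_templates, max_mm, max_insert)
}
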