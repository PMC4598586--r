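#' Catalog cytosines and their sequence context
#'
#' Scans both strands of the reference and classifies every cytosine as CG,
#' CHG or CHH (H = A, C or T), the three contexts maintained by distinct
#' plant methylation pathways. Context is determined solely by the reference:
#' the base after the C decides CG, otherwise the base two positions on
#' decides CHG, else CHH. Cytosines whose context is undefined (within 2 bp
#' of a chromosome end, or followed by N) are excluded.
#'
#' @param ref Named character vector of chromosome sequences.
#' @param trinucleotide Include the strand-oriented trinucleotide column.
#' @return Tibble with columns chrom, pos (0-based), strand, context, and
#'   optionally tri.
#' @export
classify_cytosines <- function(ref, trinucleotide = FALSE) {
  stop_if_not_ref(ref)
  C <- as.raw(67); G <- as.raw(71); A <- as.raw(65); Tb <- as.raw(84)
  acgt <- as.raw(c(65, 67, 71, 84))
  out <- lapply(names(ref), function(chrom) {
    r <- charToRaw(ref[[chrom]])
    L <- length(r)
    # --- top strand: C at p (1-based index i), context from r[i+1], r[i+2]
    i <- which(r == C)
    i <- i[i <= L - 1L]
    nxt <- r[i + 1L]
    is_cg <- nxt == G
    # non-CG needs i+2 in range and H (A/C/T) at i+1
    ok_h <- nxt %in% c(A, C, Tb)
    i2ok <- i <= L - 2L
    nxt2 <- r[pmin(i + 2L, L)]
    is_chg <- !is_cg & ok_h & i2ok & nxt2 == G
    is_chh <- !is_cg & ok_h & i2ok & nxt2 %in% c(A, C, Tb)
    keep <- is_cg | is_chg | is_chh
    top <- tibble::tibble(
      chrom = chrom, pos = i[keep] - 1L, strand = "+",
      context = dplyr::case_when(is_cg[keep] ~ "CG",
                                 is_chg[keep] ~ "CHG",
                                 TRUE ~ "CHH"))
    if (trinucleotide) {
      p <- i[keep]
      top$tri <- substr(rep(ref[[chrom]], length(p)), p, pmin(p + 2L, L))
    }
    # --- bottom strand: C on bottom where top has G at p (index j);
    # bottom 5'->3' runs right-to-left, so context reads r[j-1], r[j-2]
    # (complemented): next base is G iff top[j-1] == C, H iff top[j-1] in
    # {A, G, T}.
    j <- which(r == G)
    j <- j[j >= 2L]
    prv <- r[j - 1L]
    b_cg <- prv == C
    ok_hb <- prv %in% c(A, G, Tb)
    j2ok <- j >= 3L
    prv2 <- r[pmax(j - 2L, 1L)]
    b_chg <- !b_cg & ok_hb & j2ok & prv2 == C
    b_chh <- !b_cg & ok_hb & j2ok & prv2 %in% c(A, G, Tb)
    keepb <- b_cg | b_chg | b_chh
    bot <- tibble::tibble(
      chrom = chrom, pos = j[keepb] - 1L, strand = "-",
      context = dplyr::case_when(b_cg[keepb] ~ "CG",
                                 b_chg[keepb] ~ "CHG",
                                 TRUE ~ "CHH"))
    if (trinucleotide) {
      p <- j[keepb]
      bot$tri <- revcomp(substr(rep(ref[[chrom]], length(p)),
                                pmax(p - 2L, 1L), p))
    }
    dplyr::bind_rows(top, bot)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$pos, .data$strand)
}

# Reverse a quality string.
rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Expand aligned mates into per-base records in top-strand orientation.
# Returns pair index, mate, chrom, informative strand, pos, base, q.
expand_alignments <- function(alignments, reads, informative = TRUE) {
  if (nrow(alignments) == 0) {
    return(tibble::tibble(pair = integer(), mate = integer(),
                          chrom = character(), strand = character(),
                          pos = integer(), base = character(), q = integer()))
  }
  al <- dplyr::inner_join(dplyr::mutate(alignments,
                                        pair = dplyr::row_number()),
                          reads[, c("name", "seq1", "qual1", "seq2", "qual2")],
                          by = "name")
  strand_of <- if (informative) {
    c(OT = "+", CTOT = "+", OB = "-", CTOB = "-")
  } else {
    c(fwd = "+", rev = "+")
  }
  per_mate <- lapply(1:2, function(m) {
    seqs <- al[[paste0("seq", m)]]
    quals <- al[[paste0("qual", m)]]
    orient <- al[[paste0("orient", m)]]
    starts <- al[[paste0("start", m)]]
    lens <- al[[paste0("len", m)]]
    rc <- orient == "rc"
    top <- seqs
    top[rc] <- revcomp(seqs[rc])
    qtop <- quals
    qtop[rc] <- rev_string(quals[rc])
    tibble::tibble(
      pair = rep(al$pair, lens),
      mate = m,
      chrom = rep(al$chrom, lens),
      strand = rep(unname(strand_of[al$bs_strand]), lens),
      pos = rep(starts, lens) + sequence(lens) - 1L,
      base = unlist(strsplit(top, ""), use.names = FALSE),
      q = unlist(lapply(qtop, utf8ToInt), use.names = FALSE) - 33L)
  })
  dplyr::bind_rows(per_mate)
}

#' Pile up methylation evidence over the cytosine catalog
#'
#' Projects uniquely aligned bisulfite pairs onto the cytosine catalog. Only
#' the informative strand of each alignment contributes (OT/CTOT report
#' top-strand cytosines, OB/CTOB bottom-strand). Where mates overlap, each
#' genomic position contributes at most once (read 1's base is taken). A
#' retained cytosine base calls methylated when it survived conversion (C on
#' the informative strand) and unmethylated when converted (read as T);
#' bases below `min_baseq` or that are neither state are skipped.
#'
#' @param alignments Alignment tibble from [align_bs_reads()].
#' @param reads The read pairs that were aligned.
#' @param catalog Cytosine catalog from [classify_cytosines()].
#' @param min_baseq Minimum Phred base quality (default 20).
#' @return Tibble chrom, pos, strand, context, meth, unmeth.
#' @export
pileup_methylation <- function(alignments, reads, catalog, min_baseq = 20L) {
  known <- unique(catalog$chrom)
  bad <- setdiff(unique(alignments$chrom), known)
  if (length(bad) > 0) {
    stop("alignment references unknown chromosome(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  long <- expand_alignments(alignments, reads, informative = TRUE)
  long <- long |>
    dplyr::arrange(.data$pair, .data$mate) |>
    dplyr::distinct(.data$pair, .data$chrom, .data$pos, .keep_all = TRUE) |>
    dplyr::filter(.data$q >= min_baseq)
  hits <- dplyr::inner_join(long, catalog,
                            by = c("chrom", "pos", "strand"))
  # informative base pairs: top-strand sites read C/T; bottom-strand sites
  # appear as G/A in top orientation
  keep <- (hits$strand == "+" & hits$base %in% c("C", "T")) |
    (hits$strand == "-" & hits$base %in% c("G", "A"))
  hits <- hits[keep, ]
  hits$is_meth <- hits$base %in% c("C", "G")
  hits |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$context) |>
    dplyr::summarise(meth = sum(.data$is_meth), unmeth = sum(!.data$is_meth),
                     .groups = "drop")
}

#' Call per-site methylation levels
#'
#' Emits only sites reaching the minimum depth; the level is the methylated
#' fraction of quality-passing, overlap-deduplicated informative bases.
#'
#' @param counts Per-site counts from [pileup_methylation()].
#' @param min_depth Minimum coverage for a call (default 10).
#' @return Tibble chrom, pos, strand, context, meth, unmeth, coverage, level.
#' @export
call_levels <- function(counts, min_depth = 10L) {
  counts |>
    dplyr::mutate(coverage = .data$meth + .data$unmeth) |>
    dplyr::filter(.data$coverage >= min_depth) |>
    dplyr::mutate(level = .data$meth / .data$coverage)
}

#' Call candidate SNPs from plain alignments
#'
#' Deliberately permissive SNP calling for masking: a position is a candidate
#' when at least `min_alt_count` bases with quality >= `min_baseq` differ
#' from the reference. The reported alternate is the majority non-reference
#' base (ties broken alphabetically).
#'
#' @param alignments Alignment tibble from [align_plain_reads()].
#' @param reads The ddRAD read pairs that were aligned.
#' @param ref Named character vector of chromosome sequences.
#' @param min_baseq Minimum Phred base quality (default 20).
#' @param min_alt_count Minimum high-quality non-reference bases (default 1).
#' @return Tibble chrom, pos, ref, alt (candidate variants).
#' @export
call_snps <- function(alignments, reads, ref, min_baseq = 20L,
                      min_alt_count = 1L) {
  long <- expand_alignments(alignments, reads, informative = FALSE)
  if (nrow(long) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()))
  }
  long <- long |>
    dplyr::arrange(.data$pair, .data$mate) |>
    dplyr::distinct(.data$pair, .data$chrom, .data$pos, .keep_all = TRUE) |>
    dplyr::filter(.data$q >= min_baseq)
  long$refbase <- unname(substring(ref[long$chrom], long$pos + 1L,
                                   long$pos + 1L))
  alt <- long[long$base != long$refbase, ]
  if (nrow(alt) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()))
  }
  alt |>
    dplyr::count(.data$chrom, .data$pos, .data$refbase, .data$base,
                 name = "n_alt") |>
    dplyr::group_by(.data$chrom, .data$pos, .data$refbase) |>
    dplyr::summarise(total_alt = sum(.data$n_alt),
                     alt = .data$base[order(-.data$n_alt, .data$base)][1],
                     .groups = "drop") |>
    dplyr::filter(.data$total_alt >= min_alt_count) |>
    dplyr::transmute(chrom = .data$chrom, pos = .data$pos,
                     ref = .data$refbase, alt = .data$alt)
}

#' Mask methylation sites disrupted by SNPs
#'
#' Removes a site when any candidate SNP falls in its context-defining
#' window: positions C..C+1 for CG and C..C+2 for CHG/CHH, oriented along
#' the site's strand. Reports how many sites were removed per context.
#'
#' @param calls Site calls from [call_levels()].
#' @param variants Candidate variants (tibble chrom, pos, ...).
#' @return List with `calls` (retained) and `masked` (per-context removals).
#' @export
mask_sites <- function(calls, variants) {
  if (nrow(variants) == 0 || nrow(calls) == 0) {
    masked <- tibble::tibble(context = c("CG", "CHG", "CHH"), n_masked = 0L)
    return(list(calls = calls, masked = masked))
  }
  w <- ifelse(calls$context == "CG", 1L, 2L)
  win_start <- ifelse(calls$strand == "+", calls$pos, calls$pos - w)
  win_end <- ifelse(calls$strand == "+", calls$pos + w, calls$pos)
  gr_win <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(win_start + 1L,
                                                    win_end + 1L))
  gr_var <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos + 1L,
                                                    width = 1L))
  hit <- IRanges::overlapsAny(gr_win, gr_var)
  masked <- calls[hit, ] |>
    dplyr::count(.data$context, name = "n_masked") |>
    tidyr::complete(context = c("CG", "CHG", "CHH"),
                    fill = list(n_masked = 0L))
  list(calls = calls[!hit, , drop = FALSE], masked = masked)
}
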