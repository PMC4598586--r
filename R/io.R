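# Standard-format readers and writers. Coordinates are 0-based half-open
# internally; BED stays 0-based, GFF3/SAM/VCF are 1-based on write.

#' Read and write FASTA
#'
#' @param ref Named character vector of chromosome sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(ref, path) {
  stop_if_not_ref(ref)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read and write paired FASTQ
#'
#' Pairs are written as `<prefix>_1.fastq.gz` / `<prefix>_2.fastq.gz`.
#'
#' @param reads Tibble with columns name, seq1, qual1, seq2, qual2.
#' @param prefix Output path prefix.
#' @return `read_fastq_pairs` returns the reads tibble.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  write_one <- function(seqs, quals, names, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names
    Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"),
                                format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  p1 <- paste0(prefix, "_1.fastq.gz")
  p2 <- paste0(prefix, "_2.fastq.gz")
  write_one(reads$seq1, reads$qual1, reads$name, p1)
  write_one(reads$seq2, reads$qual2, reads$name, p2)
  invisible(c(p1, p2))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(prefix) {
  read_one <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    tibble::tibble(name = names(x), seq = as.character(x),
                   qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  r1 <- read_one(paste0(prefix, "_1.fastq.gz"))
  r2 <- read_one(paste0(prefix, "_2.fastq.gz"))
  stopifnot(identical(r1$name, r2$name))
  tibble::tibble(name = r1$name, seq1 = r1$seq, qual1 = r1$qual,
                 seq2 = r2$seq, qual2 = r2$qual)
}

#' Read and write annotations as GFF3
#'
#' Features carry `subgenome` and `copy_class` attributes where labelled.
#' GFF3 is 1-based inclusive on disk; the in-memory annotation is 0-based
#' half-open.
#'
#' @param ann Annotation tibble.
#' @param path File path.
#' @return `read_gff3` returns an annotation tibble.
#' @export
write_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1L, ann$end),
                               strand = ann$strand)
  S4Vectors::mcols(gr)$type <- ann$type
  S4Vectors::mcols(gr)$ID <- ann$feature_id
  S4Vectors::mcols(gr)$gene_id <- ann$gene_id
  S4Vectors::mcols(gr)$subgenome <- ann$subgenome
  S4Vectors::mcols(gr)$copy_class <- ann$copy_class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    feature_id = as.character(mc$ID),
    gene_id = as.character(mc$gene_id),
    subgenome = as.character(mc$subgenome),
    copy_class = suppressWarnings(as.integer(mc$copy_class)))
}

#' Write fragments (or any intervals) as BED6
#'
#' Fragment names are `leftEnzyme_rightEnzyme`.
#'
#' @param fragments Fragment tibble from [double_digest()].
#' @param path File path.
#' @export
write_bed <- function(fragments, path) {
  nm <- if (all(c("left_enzyme", "right_enzyme") %in% names(fragments))) {
    paste0(fragments$left_enzyme, "_", fragments$right_enzyme)
  } else if ("feature_id" %in% names(fragments)) {
    fragments$feature_id
  } else "."
  strand <- if ("strand" %in% names(fragments)) fragments$strand else "+"
  readr::write_tsv(tibble::tibble(chrom = fragments$chrom,
                                  start = fragments$start,
                                  end = fragments$end,
                                  name = nm, score = 0L, strand = strand),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read and write minimal VCF
#'
#' Substitution-only site list with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO
#' columns (POS is 1-based on disk).
#'
#' @param variants Tibble chrom, pos (0-based), ref, alt.
#' @param path File path.
#' @return `read_vcf_min` returns a variants tibble.
#' @export
write_vcf_min <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       variants$chrom, variants$pos + 1L,
                       variants$ref, variants$alt), con)
  }
  invisible(path)
}

#' @rdname write_vcf_min
#' @export
read_vcf_min <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()))
  }
  f <- strsplit(lines, "\t")
  tibble::tibble(chrom = vapply(f, `[`, character(1), 1),
                 pos = as.integer(vapply(f, `[`, character(1), 2)) - 1L,
                 ref = vapply(f, `[`, character(1), 4),
                 alt = vapply(f, `[`, character(1), 5))
}

#' Read and write alignments as SAM
#'
#' Emits one record per mate with the standard mandatory fields plus `XB`
#' (bisulfite strand / template) and `XM` (pair mismatch count) tags.
#' `read_sam` reconstructs the package's alignment tibble from such a file.
#'
#' @param alignments Alignment tibble.
#' @param reads The read pairs that were aligned.
#' @param ref Named character vector (for the header).
#' @param path File path.
#' @return `read_sam` returns an alignment tibble.
#' @export
write_sam <- function(alignments, reads, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref))), con)
  if (nrow(alignments) > 0) {
    al <- dplyr::inner_join(alignments,
                            reads[, c("name", "seq1", "qual1", "seq2",
                                      "qual2")],
                            by = "name")
    for (m in 1:2) {
      rc <- al[[paste0("orient", m)]] == "rc"
      flag <- 1L + 2L + ifelse(m == 1, 64L, 128L) + ifelse(rc, 16L, 0L) +
        ifelse(al[[paste0("orient", ifelse(m == 1, 2, 1))]] == "rc", 32L, 0L)
      seqs <- al[[paste0("seq", m)]]
      quals <- al[[paste0("qual", m)]]
      seqs[rc] <- revcomp(seqs[rc])
      quals[rc] <- rev_string(quals[rc])
      writeLines(sprintf(
        "%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t0\t%s\t%s\tXB:Z:%s\tXM:i:%d",
        al$name, flag, al$chrom, al[[paste0("start", m)]] + 1L,
        al[[paste0("len", m)]],
        al[[paste0("start", ifelse(m == 1, 2, 1))]] + 1L,
        seqs, quals, al$bs_strand, al$mm), con)
    }
  }
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble::tibble(name = character(), chrom = character(),
                          start1 = integer(), len1 = integer(),
                          orient1 = character(), start2 = integer(),
                          len2 = integer(), orient2 = character(),
                          bs_strand = character(), mm = integer()))
  }
  f <- strsplit(lines, "\t")
  rec <- tibble::tibble(
    name = vapply(f, `[`, character(1), 1),
    flag = as.integer(vapply(f, `[`, character(1), 2)),
    chrom = vapply(f, `[`, character(1), 3),
    pos = as.integer(vapply(f, `[`, character(1), 4)) - 1L,
    len = nchar(vapply(f, `[`, character(1), 10)),
    bs_strand = sub("^XB:Z:", "", vapply(f, `[`, character(1), 12)),
    mm = as.integer(sub("^XM:i:", "", vapply(f, `[`, character(1), 13))))
  rec$mate <- ifelse(bitwAnd(rec$flag, 64L) > 0, 1L, 2L)
  rec$orient <- ifelse(bitwAnd(rec$flag, 16L) > 0, "rc", "fwd")
  wide <- tidyr::pivot_wider(rec[, c("name", "chrom", "bs_strand", "mm",
                                     "mate", "pos", "len", "orient")],
                             names_from = "mate",
                             values_from = c("pos", "len", "orient"))
  tibble::tibble(name = wide$name, chrom = wide$chrom,
                 start1 = wide$pos_1, len1 = wide$len_1,
                 orient1 = wide$orient_1, start2 = wide$pos_2,
                 len2 = wide$len_2, orient2 = wide$orient_2,
                 bs_strand = wide$bs_strand, mm = wide$mm)
}

#' Write site calls / truth tables as TSV
#'
#' @param x A tibble.
#' @param path File path.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Write per-context bedGraph of methylation levels
#'
#' One file per context: `<prefix>.<context>.bedGraph`.
#'
#' @param calls Site calls from [call_levels()].
#' @param prefix Output path prefix.
#' @export
write_bedgraph <- function(calls, prefix) {
  paths <- character(0)
  for (ctx in unique(calls$context)) {
    sub <- calls[calls$context == ctx, ]
    p <- sprintf("%s.%s.bedGraph", prefix, ctx)
    readr::write_tsv(tibble::tibble(chrom = sub$chrom, start = sub$pos,
                                    end = sub$pos + 1L, value = sub$level),
                     p, col_names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
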