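test_that("context classification follows the CG / CHG / CHH definition", {
  s1 <- classify_cytosines(c(x = "ACGT"))
  expect_equal(s1$context[s1$strand == "+" & s1$pos == 1], "CG")
  expect_equal(s1$context[s1$strand == "-" & s1$pos == 2], "CG")
  s2 <- classify_cytosines(c(x = "ACAGT"))
  expect_equal(s2$context[s2$strand == "+" & s2$pos == 1], "CHG")
  s3 <- classify_cytosines(c(x = "ACATT"))
  expect_equal(s3$context[s3$strand == "+" & s3$pos == 1], "CHH")
})

test_that("every classifiable cytosine gets exactly one context", {
  ref <- random_ref(2e4, seed = 100)
  sites <- classify_cytosines(ref)
  s <- ref[[1]]
  n_c <- sum(charToRaw(s) == charToRaw("C"))
  n_g <- sum(charToRaw(s) == charToRaw("G"))
  # at most 2 bp per strand per chromosome end can be unclassifiable
  expect_gte(nrow(sites), n_c + n_g - 4)
  expect_lte(nrow(sites), n_c + n_g)
  expect_false(any(duplicated(sites[, c("chrom", "pos", "strand")])))
  expect_setequal(unique(sites$context), c("CG", "CHG", "CHH"))
})

# Minimal hand-built alignment scenario: one OT pair on a known sequence.
tiny_scene <- function(seq, start1, len1, start2, len2, seq1, qual1,
                       seq2 = NULL, qual2 = NULL, bs = "OT") {
  if (is.null(seq2)) {
    seq2 <- revcomp(substr(seq, start2 + 1, start2 + len2))
    qual2 <- strrep("I", len2)
  }
  ref <- c(chr1 = seq)
  reads <- tibble::tibble(name = "p1", seq1 = seq1, qual1 = qual1,
                          seq2 = seq2, qual2 = qual2)
  aln <- tibble::tibble(name = "p1", chrom = "chr1",
                        start1 = start1, len1 = len1, orient1 = "fwd",
                        start2 = start2, len2 = len2, orient2 = "rc",
                        bs_strand = bs, mm = 0L)
  list(ref = ref, reads = reads, aln = aln,
       catalog = classify_cytosines(ref))
}

test_that("a single high-quality C at a CG site counts (1, 0)", {
  sc <- tiny_scene("TTACGTTTTTTTTTTTTTTT", 0L, 10L, 10L, 10L,
                   seq1 = "TTACGTTTTT", qual1 = strrep("I", 10))
  counts <- pileup_methylation(sc$aln, sc$reads, sc$catalog)
  cg <- counts[counts$pos == 3 & counts$strand == "+", ]
  expect_equal(cg$meth, 1L)
  expect_equal(cg$unmeth, 0L)
  # converted T at the same site counts (0, 1)
  sc2 <- tiny_scene("TTACGTTTTTTTTTTTTTTT", 0L, 10L, 10L, 10L,
                    seq1 = "TTATGTTTTT", qual1 = strrep("I", 10))
  counts2 <- pileup_methylation(sc2$aln, sc2$reads, sc2$catalog)
  cg2 <- counts2[counts2$pos == 3 & counts2$strand == "+", ]
  expect_equal(c(cg2$meth, cg2$unmeth), c(0L, 1L))
})

test_that("bases below Q20 contribute nothing", {
  q <- paste0("II", "2", strrep("I", 7))   # Q17 at offset 3 (the C)
  sc <- tiny_scene("TTACGTTTTTTTTTTTTTTT", 0L, 10L, 10L, 10L,
                   seq1 = "TTACGTTTTT", qual1 = paste0("III", "2",
                                                       strrep("I", 6)))
  counts <- pileup_methylation(sc$aln, sc$reads, sc$catalog)
  expect_equal(nrow(counts[counts$pos == 3 & counts$strand == "+", ]), 0L)
})

test_that("overlapping mates contribute once, preferring read 1", {
  # both mates fully overlap positions 0..9; read1 says C, read2 says T
  sc <- tiny_scene("TTACGTTTTTTTTTTTTTTT", 0L, 10L, 0L, 10L,
                   seq1 = "TTACGTTTTT", qual1 = strrep("I", 10),
                   seq2 = revcomp("TTATGTTTTT"), qual2 = strrep("I", 10))
  counts <- pileup_methylation(sc$aln, sc$reads, sc$catalog)
  cg <- counts[counts$pos == 3 & counts$strand == "+", ]
  expect_equal(cg$meth + cg$unmeth, 1L)
  expect_equal(cg$meth, 1L)   # read 1's C wins
})

test_that("an alignment on an unknown chromosome is an error", {
  sc <- tiny_scene("TTACGTTTTTTTTTTTTTTT", 0L, 10L, 10L, 10L,
                   seq1 = "TTACGTTTTT", qual1 = strrep("I", 10))
  bad <- sc$aln
  bad$chrom <- "chrMissing"
  expect_error(pileup_methylation(bad, sc$reads, sc$catalog),
               "unknown chromosome")
})

test_that("call_levels enforces the depth threshold and computes levels", {
  counts <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                           strand = "+", context = "CG",
                           meth = c(7L, 5L, 0L), unmeth = c(3L, 4L, 10L))
  calls <- call_levels(counts, min_depth = 10)
  expect_equal(nrow(calls), 2L)             # coverage 9 yields no call
  expect_equal(calls$level[calls$pos == 10], 0.7)
  expect_equal(calls$level[calls$pos == 30], 0)
  expect_equal(call_levels(counts, min_depth = 9)$coverage,
               c(10L, 9L, 10L))
})

test_that("pileup counts equal a brute-force per-read tally", {
  g <- small_genome(seed = 110, chrom_lengths = 3e4, n_genes = 10, n_tes = 6)
  truth <- generate_methylome(g$ref, g$ann, methylation_model(), seed = 111)
  fr <- select_representation(double_digest(g$ref),
                              digest_params(require_mixed_ends = FALSE))
  reads <- simulate_rrbs_reads(g$ref, truth, sim = clean_sim(3),
                               fragments = fr, seed = 112)
  tr <- trim_reads(reads)
  aln <- align_bs_reads(tr, build_bs_index(g$ref))
  catalog <- classify_cytosines(g$ref)
  counts <- pileup_methylation(aln, tr, catalog)

  # brute force: loop over alignment rows, walk each mate base by base
  tally <- new.env()
  al <- dplyr::inner_join(aln, tr, by = "name")
  for (i in seq_len(nrow(al))) {
    seen <- character(0)
    strand <- if (al$bs_strand[i] %in% c("OT", "CTOT")) "+" else "-"
    for (m in 1:2) {
      s <- al[[paste0("seq", m)]][i]
      q <- al[[paste0("qual", m)]][i]
      if (al[[paste0("orient", m)]][i] == "rc") {
        s <- revcomp(s)
        q <- intToUtf8(rev(utf8ToInt(q)))
      }
      st <- al[[paste0("start", m)]][i]
      for (o in seq_len(nchar(s))) {
        pos <- st + o - 1L
        keypos <- as.character(pos)
        if (keypos %in% seen) next
        seen <- c(seen, keypos)
        if (utf8ToInt(substr(q, o, o)) - 33L < 20L) next
        b <- substr(s, o, o)
        key <- paste(al$chrom[i], pos, strand)
        val <- if (strand == "+" && b == "C") "m"
               else if (strand == "+" && b == "T") "u"
               else if (strand == "-" && b == "G") "m"
               else if (strand == "-" && b == "A") "u"
               else NA
        if (is.na(val)) next
        cur <- mget(key, envir = tally, ifnotfound = list(c(0L, 0L)))[[1]]
        cur[if (val == "m") 1 else 2] <- cur[if (val == "m") 1 else 2] + 1L
        assign(key, cur, envir = tally)
      }
    }
  }
  keys <- paste(catalog$chrom, catalog$pos, catalog$strand)
  brute <- t(vapply(keys, function(k) {
    mget(k, envir = tally, ifnotfound = list(c(0L, 0L)))[[1]]
  }, integer(2)))
  nz <- rowSums(brute) > 0
  got <- dplyr::left_join(catalog, counts,
                          by = c("chrom", "pos", "strand", "context"))
  got$meth[is.na(got$meth)] <- 0L
  got$unmeth[is.na(got$unmeth)] <- 0L
  expect_equal(got$meth, unname(brute[, 1]))
  expect_equal(got$unmeth, unname(brute[, 2]))
  expect_gt(sum(nz), 100)
})

test_that("SNP calling recovers simulated variants perfectly on clean reads", {
  base <- random_ref(4e4, seed = 120)
  z <- apply_variants(base, 1e-3, seed = 121)
  fr <- select_representation(double_digest(z$ref),
                              digest_params(require_mixed_ends = FALSE))
  reads <- simulate_ddrad_reads(z$ref, sim = clean_sim(10), fragments = fr,
                                seed = 122)
  tr <- trim_reads(reads)
  aln <- align_plain_reads(tr, build_bs_index(base))
  snps <- call_snps(aln, tr, base)
  # which true variants are covered by at least one aligned base?
  long <- rrbsim:::expand_alignments(aln, tr, informative = FALSE)
  covered <- unique(paste(long$chrom, long$pos))
  truth_here <- z$variants[paste(z$variants$chrom, z$variants$pos) %in%
                             covered, ]
  got <- paste(snps$chrom, snps$pos)
  expect_setequal(got, paste(truth_here$chrom, truth_here$pos))
  j <- dplyr::inner_join(snps, z$variants, by = c("chrom", "pos"),
                         suffix = c("", ".true"))
  expect_equal(j$ref, j$ref.true)
  expect_equal(j$alt, j$alt.true)
})

test_that("masking removes exactly the sites whose context window holds a SNP", {
  calls <- tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L),
    strand = c("+", "+", "-", "+"),
    context = c("CG", "CHH", "CG", "CHH"),
    meth = 5L, unmeth = 5L, coverage = 10L, level = 0.5)
  variants <- tibble::tibble(chrom = "chr1",
                             pos = c(101L, 203L, 299L),
                             ref = "A", alt = "G")
  out <- mask_sites(calls, variants)
  # SNP at the G of the CG site (101) masks site 100;
  # SNP 3 bp downstream of the CHH site (203) leaves site 200 alone;
  # minus-strand CG at 300 has window 299..300, so 299 masks it
  expect_setequal(out$calls$pos, c(200L, 400L))
  expect_equal(out$masked$n_masked[out$masked$context == "CG"], 2L)
  expect_equal(out$masked$n_masked[out$masked$context == "CHH"], 0L)
  # no variants: calls unchanged
  none <- mask_sites(calls, variants[0, ])
  expect_identical(none$calls, calls)
})

test_that("incomplete conversion biases unmethylated sites by 1 - efficiency", {
  ref <- random_ref(1.5e5, seed = 130)
  fr <- select_representation(double_digest(ref),
                              digest_params(require_mixed_ends = FALSE))
  reads <- simulate_rrbs_reads(ref, flat_truth(ref, 0),
                               sim = clean_sim(15,
                                               conversion_efficiency = 0.99),
                               fragments = fr, seed = 131)
  tr <- trim_reads(reads)
  counts <- pileup_methylation(rrbsim:::provenance_alignments(tr), tr,
                               classify_cytosines(ref))
  n <- sum(counts$meth + counts$unmeth)
  frac <- sum(counts$meth) / n
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(frac - 0.01), 3 * se)
})
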