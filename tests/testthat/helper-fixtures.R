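# Shared fixtures: everything is generated in code at test time.

# Random i.i.d. genome as a named character vector.
random_ref <- function(lengths, seed = 1, gc = 0.5) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(lengths, function(L) {
    paste0(sample(names(probs), L, replace = TRUE, prob = probs),
           collapse = "")
  }, character(1))
  names(out) <- sprintf("chr%d", seq_along(lengths))
  out
}

# A small genome with annotation, suitable for fast end-to-end exercises.
small_genome <- function(seed = 1, chrom_lengths = 3e5, n_genes = 90,
                         n_tes = 60) {
  generate_genome(genome_spec(n_chromosomes = length(chrom_lengths),
                              chrom_lengths = chrom_lengths,
                              n_genes = n_genes, n_tes = n_tes, seed = seed))
}

# Error-free, uniform-quality simulation parameters.
clean_sim <- function(mean_coverage = 20, conversion_efficiency = 1) {
  read_sim_params(mean_coverage = mean_coverage,
                  conversion_efficiency = conversion_efficiency,
                  error_rate = 0, quality_probs = c("40" = 1))
}

# A single whole-chromosome fragment (for read-simulation tests that do not
# care about digestion).
whole_fragment <- function(ref) {
  tibble::tibble(chrom = names(ref), start = 0L, end = nchar(ref),
                 left_enzyme = "SacI", right_enzyme = "MseI",
                 length = nchar(ref))
}

# Constant-level truth over every cytosine of a genome.
flat_truth <- function(ref, level) {
  tr <- classify_cytosines(ref)
  tr$component <- "intergenic"
  tr$true_level <- level
  tr
}

# Brute-force double digest by regex scanning (independent oracle).
oracle_digest <- function(ref, enz_a = re_saci(), enz_b = re_msei()) {
  out <- lapply(names(ref), function(chrom) {
    s <- ref[[chrom]]
    L <- nchar(s)
    scan <- function(enz) {
      hits <- integer(0)
      for (p in seq_len(max(L - nchar(enz$site) + 1L, 0L))) {
        if (substr(s, p, p + nchar(enz$site) - 1L) == enz$site) {
          hits <- c(hits, p - 1L + enz$cut_offset)
        }
      }
      hits
    }
    ca <- scan(enz_a); cb <- scan(enz_b)
    cuts <- sort(unique(c(ca, cb)))
    cuts <- cuts[cuts > 0 & cuts < L]
    lab <- ifelse(cuts %in% ca, enz_a$name, enz_b$name)
    bounds <- c(0L, cuts, L)
    labs <- c("chrom_end", lab, "chrom_end")
    n <- length(bounds) - 1L
    tibble::tibble(chrom = chrom, start = bounds[seq_len(n)],
                   end = bounds[-1], left_enzyme = labs[seq_len(n)],
                   right_enzyme = labs[-1],
                   length = bounds[-1] - bounds[seq_len(n)])
  })
  dplyr::bind_rows(out)
}

# Parse provenance read names into a tibble.
parse_provenance <- function(names) {
  f <- strsplit(names, ":")
  tibble::tibble(chrom = vapply(f, `[`, character(1), 1),
                 start = as.integer(vapply(f, `[`, character(1), 2)),
                 end = as.integer(vapply(f, `[`, character(1), 3)),
                 bs = vapply(f, `[`, character(1), 5))
}

# Exhaustive alignment oracle built on Biostrings::matchPattern (a full scan
# with mismatches, independent of the package's seed-and-verify path).
oracle_align_pair <- function(seq1, seq2, ref, max_mm = 1, max_insert = 500,
                              bisulfite = TRUE) {
  spaces <- list(plain = ref, CT = chartr("C", "T", ref),
                 GA = chartr("G", "A", ref))
  templates <- if (bisulfite) {
    list(OT = list("CT", "fwd", "rc", "left"),
         CTOT = list("CT", "rc", "fwd", "right"),
         OB = list("GA", "rc", "fwd", "right"),
         CTOB = list("GA", "fwd", "rc", "left"))
  } else {
    list(fwd = list("plain", "fwd", "rc", "left"),
         rev = list("plain", "rc", "fwd", "right"))
  }
  tf <- function(s, space, orient) {
    if (orient == "rc") s <- revcomp(s)
    switch(space, plain = s, CT = chartr("C", "T", s),
           GA = chartr("G", "A", s))
  }
  scan <- function(s, space) {
    hits <- list()
    for (ch in names(ref)) {
      m <- Biostrings::matchPattern(s, spaces[[space]][[ch]],
                                    max.mismatch = max_mm)
      if (length(m) == 0) next
      st <- Biostrings::start(m)
      mm <- vapply(st, function(p) {
        sum(charToRaw(s) != charToRaw(substr(spaces[[space]][[ch]], p,
                                             p + nchar(s) - 1L)))
      }, integer(1))
      hits[[ch]] <- data.frame(chrom = ch, pos = st - 1L, mm = mm)
    }
    do.call(rbind, c(hits, list(data.frame(chrom = character(),
                                           pos = integer(),
                                           mm = integer()))))
  }
  cands <- list()
  for (tn in names(templates)) {
    tp <- templates[[tn]]
    h1 <- scan(tf(seq1, tp[[1]], tp[[2]]), tp[[1]])
    h2 <- scan(tf(seq2, tp[[1]], tp[[3]]), tp[[1]])
    if (nrow(h1) == 0 || nrow(h2) == 0) next
    for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
      if (h1$chrom[i] != h2$chrom[j]) next
      if (tp[[4]] == "left") {
        pL <- h1$pos[i]; pR <- h2$pos[j]; lenR <- nchar(seq2)
        lenL <- nchar(seq1)
      } else {
        pL <- h2$pos[j]; pR <- h1$pos[i]; lenR <- nchar(seq1)
        lenL <- nchar(seq2)
      }
      ins <- pR + lenR - pL
      if (pL > pR || ins > max_insert || ins < max(lenL, lenR)) next
      mm <- h1$mm[i] + h2$mm[j]
      if (mm > max_mm) next
      cands[[length(cands) + 1L]] <- data.frame(
        template = tn, chrom = h1$chrom[i], start1 = h1$pos[i],
        start2 = h2$pos[j], mm = mm)
    }
  }
  if (length(cands) == 0) return(NULL)
  all <- unique(do.call(rbind, cands))
  best <- all[all$mm == min(all$mm), , drop = FALSE]
  if (nrow(best) != 1) return("ambiguous")
  best
}

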