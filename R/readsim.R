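#' Read-simulation parameters
#'
#' Controls paired-end read simulation from size-selected fragments: raw read
#' length (PE100), per-fragment sampling depth, bisulfite conversion
#' efficiency, sequencing error, the per-base Phred quality distribution and
#' the bisulfite-strand mix. The default strand mix is non-directional: read
#' pairs are drawn uniformly from the four bisulfite strands (OT, OB, CTOT,
#' CTOB).
#'
#' @param read_length Raw read length in bp (default 100).
#' @param mean_coverage Target per-cytosine informative depth over captured
#'   sites. Bisulfite molecules report one strand only, so the simulator
#'   samples Poisson(2 x mean_coverage) pairs per fragment for bisulfite
#'   libraries and Poisson(mean_coverage) for plain (ddRAD) libraries.
#' @param conversion_efficiency Probability that an unmethylated cytosine is
#'   converted (read as T). Methylated cytosines are never converted.
#' @param error_rate Per-base substitution sequencing error probability.
#' @param quality_probs Named numeric: Phred values and their probabilities.
#' @param directionality Named numeric over OT/OB/CTOT/CTOB summing to 1.
#' @param seed Integer seed.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 100L,
                            mean_coverage = 20,
                            conversion_efficiency = 0.995,
                            error_rate = 0.001,
                            quality_probs = c("40" = 0.93, "37" = 0.03,
                                              "35" = 0.02, "32" = 0.01,
                                              "29" = 0.005, "25" = 0.003,
                                              "15" = 0.002),
                            directionality = c(OT = 0.25, OB = 0.25,
                                               CTOT = 0.25, CTOB = 0.25),
                            seed = NULL) {
  stopifnot(read_length > 0, mean_coverage > 0,
            conversion_efficiency >= 0, conversion_efficiency <= 1,
            error_rate >= 0, error_rate < 1,
            abs(sum(quality_probs) - 1) < 1e-8,
            all(names(directionality) %in% c("OT", "OB", "CTOT", "CTOB")),
            abs(sum(directionality) - 1) < 1e-8)
  structure(list(read_length = as.integer(read_length),
                 mean_coverage = mean_coverage,
                 conversion_efficiency = conversion_efficiency,
                 error_rate = error_rate,
                 quality_probs = quality_probs,
                 directionality = directionality,
                 seed = seed),
            class = "read_sim_params")
}

# Per-chromosome strand-indexed lookup of true levels (NA where no record).
truth_lookup <- function(ref, truth) {
  lk <- lapply(names(ref), function(chrom) {
    L <- nchar(ref[[chrom]])
    plus <- rep(NA_real_, L); minus <- rep(NA_real_, L)
    sub <- truth[truth$chrom == chrom, ]
    p <- sub$strand == "+"
    plus[sub$pos[p] + 1L] <- sub$true_level[p]
    minus[sub$pos[!p] + 1L] <- sub$true_level[!p]
    list(plus = plus, minus = minus)
  })
  names(lk) <- names(ref)
  lk
}

# Apply iid substitution errors and draw quality strings for a set of reads.
finish_reads <- function(seqs, sim) {
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, sim$error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1),
                      character(1))
    seqs[i] <- paste0(ch, collapse = "")
  }
  qv <- as.integer(names(sim$quality_probs))
  quals <- if (length(qv) == 1L) {
    vapply(lens, function(n) intToUtf8(rep(qv + 33L, n)), character(1))
  } else {
    vapply(lens, function(n) {
      intToUtf8(sample(qv, n, replace = TRUE, prob = sim$quality_probs) + 33L)
    }, character(1))
  }
  list(seqs = seqs, quals = quals)
}

simulate_reads_core <- function(ref, fragments, sim, truth = NULL,
                                bisulfite = TRUE, seed = NULL) {
  stop_if_not_ref(ref)
  rl <- sim$read_length
  lk <- if (bisulfite) truth_lookup(ref, truth)
  with_seed(seed, {
    short <- fragments$length < 30L
    n_short <- sum(short)
    frags <- fragments[!short, , drop = FALSE]
    recs <- vector("list", nrow(frags))
    for (fi in seq_len(nrow(frags))) {
      fr <- frags[fi, ]
      # a molecule reports cytosines on one strand only, so sampling twice the
      # target coverage in pairs yields ~mean_coverage informative depth per
      # cytosine (bisulfite); plain reads inform both strands
      m <- stats::rpois(1, if (bisulfite) 2 * sim$mean_coverage
                        else sim$mean_coverage)
      if (m == 0) next
      fseq <- substr(ref[[fr$chrom]], fr$start + 1L, fr$end)
      L <- nchar(fseq)
      fchars <- strsplit(fseq, "")[[1]]
      if (bisulfite) {
        bs <- sample(names(sim$directionality), m, replace = TRUE,
                     prob = sim$directionality)
        top_mol <- bs %in% c("OT", "CTOT")
        templates <- character(m)
        # top-strand cytosines (relevant to OT/CTOT molecules)
        cpos <- which(fchars == "C")
        lv_top <- lk[[fr$chrom]]$plus[fr$start + cpos]
        lv_top[is.na(lv_top)] <- 0       # SNP-created C: unmethylated
        # bottom-strand cytosines appear as G on the top strand
        gpos <- which(fchars == "G")
        lv_bot <- lk[[fr$chrom]]$minus[fr$start + gpos]
        lv_bot[is.na(lv_bot)] <- 0
        for (k in seq_len(m)) {
          ch <- fchars
          if (top_mol[k]) {
            if (length(cpos)) {
              meth <- stats::rbinom(length(cpos), 1L, lv_top) == 1L
              conv <- !meth & stats::runif(length(cpos)) < sim$conversion_efficiency
              ch[cpos[conv]] <- "T"
            }
            tmpl <- paste0(ch, collapse = "")
            templates[k] <- if (bs[k] == "OT") tmpl else revcomp(tmpl)
          } else {
            if (length(gpos)) {
              meth <- stats::rbinom(length(gpos), 1L, lv_bot) == 1L
              conv <- !meth & stats::runif(length(gpos)) < sim$conversion_efficiency
              ch[gpos[conv]] <- "A"     # bottom-strand C->T, top view G->A
            }
            tmpl <- paste0(ch, collapse = "")
            templates[k] <- if (bs[k] == "OB") revcomp(tmpl) else tmpl
          }
        }
      } else {
        bs <- sample(c("fwd", "rev"), m, replace = TRUE)
        templates <- ifelse(bs == "fwd", fseq, revcomp(fseq))
      }
      n1 <- pmin(rl, L)
      r1 <- substr(templates, 1L, n1)
      r2 <- revcomp(substr(templates, pmax(L - rl + 1L, 1L), L))
      recs[[fi]] <- tibble::tibble(
        name = sprintf("%s:%d:%d:+:%s:%d", fr$chrom, fr$start, fr$end, bs,
                       seq_len(m)),
        seq1 = r1, seq2 = r2)
    }
    reads <- dplyr::bind_rows(recs)
    if (nrow(reads) == 0) {
      reads <- tibble::tibble(name = character(), seq1 = character(),
                              seq2 = character())
    }
    f1 <- finish_reads(reads$seq1, sim)
    f2 <- finish_reads(reads$seq2, sim)
    out <- tibble::tibble(name = reads$name,
                          seq1 = f1$seqs, qual1 = f1$quals,
                          seq2 = f2$seqs, qual2 = f2$quals)
    attr(out, "skipped_short") <- n_short
    out
  })
}

#' Simulate non-directional bisulfite read pairs from a reduced representation
#'
#' For each selected fragment, samples Poisson(mean_coverage) molecules. Each
#' molecule draws its bisulfite strand from the directionality mix, then every
#' cytosine on the sequenced strand draws a binary methylation state once per
#' molecule with probability equal to its true level; unmethylated cytosines
#' are converted to T with the configured efficiency, methylated cytosines
#' are never converted. Sequencing errors and qualities are applied
#' afterwards. Reads are paired, taken from the fragment ends inward (raw
#' length 100, truncating at the fragment end), and read names encode the
#' ground-truth origin `chrom:start:end:strand:bs-strand:molecule` for
#' provenance-based testing. Fragments shorter than 30 bp are skipped; the
#' count is available as `attr(, "skipped_short")`.
#'
#' @param ref Sample genome (named character vector) the molecules derive
#'   from.
#' @param truth Ground-truth methylome tibble ([generate_methylome()]).
#' @param digest A [digest_params()] (used when `fragments` is NULL).
#' @param sim A [read_sim_params()].
#' @param enz_a,enz_b Restriction enzymes for the double digest.
#' @param fragments Optional pre-selected fragment tibble; when NULL the
#'   reduced representation is derived from `ref` via [double_digest()] and
#'   [select_representation()].
#' @param seed Integer seed (defaults to `sim$seed`).
#' @return Tibble with columns name, seq1, qual1, seq2, qual2.
#' @export
simulate_rrbs_reads <- function(ref, truth, digest = digest_params(),
                                sim = read_sim_params(),
                                enz_a = re_saci(), enz_b = re_msei(),
                                fragments = NULL, seed = sim$seed) {
  if (is.null(fragments)) {
    fragments <- select_representation(double_digest(ref, enz_a, enz_b), digest)
  }
  if (nrow(fragments) == 0) stop("representation set is empty", call. = FALSE)
  simulate_reads_core(ref, fragments, sim, truth = truth, bisulfite = TRUE,
                      seed = seed)
}

#' Simulate plain (non-bisulfite) ddRAD read pairs
#'
#' Identical sampling scheme to [simulate_rrbs_reads()] but without bisulfite
#' conversion; used to detect sample-versus-reference SNPs for masking.
#' Read names encode `chrom:start:end:strand:fwd|rev:molecule`.
#'
#' @inheritParams simulate_rrbs_reads
#' @return Tibble with columns name, seq1, qual1, seq2, qual2.
#' @export
simulate_ddrad_reads <- function(ref, digest = digest_params(),
                                 sim = read_sim_params(),
                                 enz_a = re_saci(), enz_b = re_msei(),
                                 fragments = NULL, seed = sim$seed) {
  if (is.null(fragments)) {
    fragments <- select_representation(double_digest(ref, enz_a, enz_b), digest)
  }
  if (nrow(fragments) == 0) stop("representation set is empty", call. = FALSE)
  simulate_reads_core(ref, fragments, sim, truth = NULL, bisulfite = FALSE,
                      seed = seed)
}
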