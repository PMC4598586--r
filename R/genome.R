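#' Specification of a synthetic genome
#'
#' Describes the synthetic multi-chromosome genome used throughout the
#' pipeline: overall base composition, gene and transposable-element (TE)
#' content, the fraction of TEs concentrated in a central "pericentromeric"
#' block, and densities for tandem/inverted repeat tracks. The synthetic
#' genome emulates the layout the analysis assumes for a mesohexaploid
#' crucifer: gene models with exon/intron structure carrying subgenome
#' (LF/MF1/MF2) and copy-number (1/2/3) labels, TE-dense pericentromeres,
#' and annotated repeat tracks.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths in bp (recycled
#'   to `n_chromosomes`).
#' @param gc_content Genome GC fraction in (0, 1).
#' @param n_genes,n_tes Total numbers of gene models and TE intervals.
#' @param te_pericentromeric_fraction Fraction of TEs placed inside the
#'   central pericentromeric block (the central 20% of each chromosome).
#' @param repeat_tracks List with `tandem_density` and `inverted_density`
#'   (expected repeat intervals per kb) and `mean_length` (bp).
#' @param exon_length_range,intron_length_range,te_length_range Sampling
#'   ranges (bp) for feature part lengths.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L,
                        chrom_lengths = 1e6,
                        gc_content = 0.42,
                        n_genes = 600L,
                        n_tes = 400L,
                        te_pericentromeric_fraction = 0.6,
                        repeat_tracks = list(tandem_density = 0.02,
                                             inverted_density = 0.01,
                                             mean_length = 300),
                        exon_length_range = c(120L, 400L),
                        intron_length_range = c(80L, 300L),
                        te_length_range = c(300L, 1500L),
                        seed = 1L) {
  chrom_lengths <- as.integer(rep_len(chrom_lengths, n_chromosomes))
  stopifnot(n_chromosomes >= 1, all(chrom_lengths > 0),
            gc_content > 0, gc_content < 1,
            n_genes >= 0, n_tes >= 0,
            te_pericentromeric_fraction >= 0, te_pericentromeric_fraction <= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_lengths = chrom_lengths,
                 gc_content = gc_content,
                 n_genes = as.integer(n_genes),
                 n_tes = as.integer(n_tes),
                 te_pericentromeric_fraction = te_pericentromeric_fraction,
                 repeat_tracks = repeat_tracks,
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 te_length_range = as.integer(te_length_range),
                 seed = seed),
            class = "genome_spec")
}

# Place features of given lengths without overlap inside [zone_start, zone_end).
# Returns 0-based starts, or errors when the packing is infeasible.
pack_intervals <- function(lengths, zone_start, zone_end) {
  if (length(lengths) == 0) return(integer(0))
  free <- (zone_end - zone_start) - sum(lengths)
  if (free < 0) {
    stop("infeasible packing: features exceed chromosome capacity", call. = FALSE)
  }
  # Random composition of the free space into (n + 1) gaps; flooring each gap
  # keeps features integer-aligned and strictly non-overlapping.
  n <- length(lengths)
  cuts <- sort(stats::runif(n, 0, 1))
  gaps <- floor(diff(c(0, cuts, 1)) * free)
  ord <- sample.int(n)                         # random feature order
  len_ord <- lengths[ord]
  starts <- zone_start + cumsum(gaps[seq_len(n)]) +
    c(0, cumsum(len_ord)[-n])
  out <- integer(n)
  out[ord] <- as.integer(starts)
  out
}

#' Generate a synthetic reference genome and annotation
#'
#' Draws chromosome sequences i.i.d. at the requested GC content and lays out
#' non-overlapping gene models (with exon/intron structure, strand, subgenome
#' and copy-number labels), TE intervals (a configurable fraction confined to
#' the central pericentromeric block), and tandem/inverted repeat tracks.
#' Genes are kept out of the pericentromeric block, mirroring the gene-poor,
#' TE-dense organisation of plant pericentromeres.
#'
#' All coordinates are 0-based half-open on the top strand.
#'
#' @param spec A [genome_spec()].
#' @return A list of class `rrbs_genome` with elements:
#'   `ref` (named character vector of chromosome sequences),
#'   `ann` (tibble of features: chrom, start, end, strand, type, feature_id,
#'   gene_id, subgenome, copy_class), and `peri` (tibble of the declared
#'   pericentromeric blocks).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    probs <- c(A = (1 - spec$gc_content) / 2, C = spec$gc_content / 2,
               G = spec$gc_content / 2, T = (1 - spec$gc_content) / 2)
    chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    ref <- vapply(spec$chrom_lengths, function(L) {
      paste0(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    names(ref) <- chroms

    # Apportion genes/TEs to chromosomes by length.
    w <- spec$chrom_lengths / sum(spec$chrom_lengths)
    gene_per <- as.integer(round(spec$n_genes * w))
    te_per <- as.integer(round(spec$n_tes * w))
    # fix rounding drift on the last chromosome
    gene_per[length(gene_per)] <- spec$n_genes - sum(gene_per[-length(gene_per)])
    te_per[length(te_per)] <- spec$n_tes - sum(te_per[-length(te_per)])

    ann_rows <- list()
    peri_rows <- list()
    gene_counter <- 0L
    te_counter <- 0L

    for (ci in seq_len(spec$n_chromosomes)) {
      L <- spec$chrom_lengths[ci]
      chrom <- chroms[ci]
      peri <- c(floor(0.4 * L), floor(0.6 * L))
      peri_rows[[ci]] <- tibble::tibble(chrom = chrom,
                                        start = peri[1], end = peri[2])

      ng <- gene_per[ci]
      # Gene structures: exon/intron part lengths per gene.
      gene_parts <- vector("list", ng)
      gene_len <- integer(ng)
      if (ng > 0) {
        n_ex <- sample(1:5, ng, replace = TRUE)
        for (g in seq_len(ng)) {
          ex <- sample(seq(spec$exon_length_range[1], spec$exon_length_range[2]),
                       n_ex[g], replace = TRUE)
          intr <- if (n_ex[g] > 1) {
            sample(seq(spec$intron_length_range[1], spec$intron_length_range[2]),
                   n_ex[g] - 1L, replace = TRUE)
          } else integer(0)
          gene_parts[[g]] <- list(exons = ex, introns = intr)
          gene_len[g] <- sum(ex) + sum(intr)
        }
      }

      nt <- te_per[ci]
      te_len <- if (nt > 0) {
        sample(seq(spec$te_length_range[1], spec$te_length_range[2]),
               nt, replace = TRUE)
      } else integer(0)
      n_peri <- round(nt * spec$te_pericentromeric_fraction)
      is_peri <- rep(FALSE, nt)
      if (nt > 0 && n_peri > 0) is_peri[sample.int(nt, n_peri)] <- TRUE

      # Pericentromeric TEs go in the central block; genes and the remaining
      # TEs are split greedily between the two chromosome arms (most free
      # space first), then packed without overlap within each arm.
      peri_starts <- pack_intervals(te_len[is_peri], peri[1], peri[2])
      arm_feats_len <- c(gene_len, te_len[!is_peri])
      free <- c(peri[1], L - peri[2])              # arm capacities
      if (sum(arm_feats_len) > 0.95 * sum(free)) {
        stop("infeasible packing: features exceed chromosome capacity",
             call. = FALSE)
      }
      arm_of <- integer(length(arm_feats_len))
      for (i in sample.int(max(length(arm_feats_len), 1L))[seq_along(arm_feats_len)]) {
        a <- which.max(free)
        arm_of[i] <- a
        free[a] <- free[a] - arm_feats_len[i]
      }
      arm_starts <- integer(length(arm_feats_len))
      arm_starts[arm_of == 1L] <- pack_intervals(arm_feats_len[arm_of == 1L],
                                                 0L, peri[1])
      arm_starts[arm_of == 2L] <- pack_intervals(arm_feats_len[arm_of == 2L],
                                                 peri[2], L)

      gene_starts <- arm_starts[seq_len(ng)]
      te_arm_starts <- arm_starts[setdiff(seq_along(arm_feats_len), seq_len(ng))]
      te_starts <- integer(nt)
      te_starts[is_peri] <- peri_starts
      te_starts[!is_peri] <- te_arm_starts

      if (ng > 0) {
        strands <- sample(c("+", "-"), ng, replace = TRUE)
        subg <- sample(c("LF", "MF1", "MF2"), ng, replace = TRUE)
        copyc <- sample(1:3, ng, replace = TRUE, prob = c(0.45, 0.35, 0.20))
        for (g in seq_len(ng)) {
          gene_counter <- gene_counter + 1L
          gid <- sprintf("gene%05d", gene_counter)
          parts <- gene_parts[[g]]
          gs <- gene_starts[g]
          ge <- gs + gene_len[g]
          # exon/intron layout left-to-right in genome coordinates
          seg_len <- as.vector(rbind(c(parts$exons, NA),
                                     c(parts$introns, NA, NA)))
          seg_len <- seg_len[!is.na(seg_len)][seq_len(2L * length(parts$exons) - 1L)]
          seg_type <- rep(c("exon", "intron"), length.out = length(seg_len))
          seg_start <- gs + c(0L, cumsum(seg_len)[-length(seg_len)])
          rows <- tibble::tibble(
            chrom = chrom, start = c(gs, seg_start),
            end = c(ge, seg_start + seg_len),
            strand = strands[g], type = c("gene", seg_type),
            feature_id = c(gid, sprintf("%s.%s%d", gid, substr(seg_type, 1, 1),
                                        seq_along(seg_type))),
            gene_id = gid, subgenome = subg[g], copy_class = copyc[g])
          ann_rows[[length(ann_rows) + 1L]] <- rows
        }
      }
      if (nt > 0) {
        for (t in seq_len(nt)) {
          te_counter <- te_counter + 1L
          ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
            chrom = chrom, start = te_starts[t], end = te_starts[t] + te_len[t],
            strand = sample(c("+", "-"), 1), type = "te",
            feature_id = sprintf("te%05d", te_counter),
            gene_id = NA_character_, subgenome = NA_character_,
            copy_class = NA_integer_)
        }
      }

      # Repeat tracks are annotation intervals (they may overlap anything).
      for (rt in c("tandem_repeat", "inverted_repeat")) {
        dens <- if (rt == "tandem_repeat") spec$repeat_tracks$tandem_density
                else spec$repeat_tracks$inverted_density
        n_rep <- stats::rpois(1, dens * L / 1000)
        if (n_rep > 0) {
          rl <- pmax(20L, stats::rpois(n_rep, spec$repeat_tracks$mean_length))
          rs <- sample.int(L - max(rl), n_rep, replace = TRUE) - 1L
          ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
            chrom = chrom, start = rs, end = pmin(rs + rl, L),
            strand = "+", type = rt,
            feature_id = sprintf("%s_%s_%d", rt, chrom, seq_len(n_rep)),
            gene_id = NA_character_, subgenome = NA_character_,
            copy_class = NA_integer_)
        }
      }
    }

    ann <- if (length(ann_rows)) {
      dplyr::arrange(dplyr::bind_rows(ann_rows), .data$chrom, .data$start)
    } else {
      tibble::tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), type = character(),
                     feature_id = character(), gene_id = character(),
                     subgenome = character(), copy_class = integer())
    }
    structure(list(ref = ref, ann = ann,
                   peri = dplyr::bind_rows(peri_rows), spec = spec),
              class = "rrbs_genome")
  })
}

#' @export
print.rrbs_genome <- function(x, ...) {
  cat(sprintf("<rrbs_genome> %d chromosome(s), %s bp total\n",
              length(x$ref), format(sum(nchar(x$ref)), big.mark = ",")))
  cat(sprintf("  genes: %d  TEs: %d  annotation rows: %d\n",
              sum(x$ann$type == "gene"), sum(x$ann$type == "te"), nrow(x$ann)))
  invisible(x)
}
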