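#' Ground-truth methylation model
#'
#' Maps genomic component x sequence context to a true methylation level
#' distribution. Components follow the genic/TE anatomy used throughout the
#' package: `te`, `exon`, `intron`, `promoter`, `flank` (1 kb gene flanks)
#' and `intergenic`. Default means reproduce the canonical plant ordering
#' (CG >= CHG >= CHH within each component; TE > intron > exon), with the TE,
#' intron and exon values at component means reported for mesohexaploid
#' crucifer genomes.
#'
#' Three distribution families are supported per (component, context) cell:
#' * `constant` - every site carries exactly the mean level (degenerate);
#' * `two_point` - sites are fully methylated with probability `mean`, else
#'   fully unmethylated (the bimodal pattern typical of plant CG);
#' * `beta` - levels drawn from Beta(mean * conc, (1 - mean) * conc).
#'
#' @param means Optional tibble with columns component, context, mean
#'   overriding the defaults (rows are matched by component + context).
#' @param cg_family,chg_family,chh_family Distribution family per context.
#' @param concentration Beta concentration parameter (mean-parameterised).
#' @param uniform Optional named numeric `c(CG=, CHG=, CHH=)`; when given,
#'   every component uses these means (handy for genome-wide calibrations).
#' @return Tibble of class `methylation_model` with columns component,
#'   context, mean, family, concentration.
#' @export
methylation_model <- function(means = NULL,
                              cg_family = "two_point",
                              chg_family = "beta",
                              chh_family = "beta",
                              concentration = 2,
                              uniform = NULL) {
  defaults <- tibble::tribble(
    ~component,   ~CG,   ~CHG,  ~CHH,
    "te",         0.880, 0.540, 0.177,
    "exon",       0.251, 0.088, 0.027,
    "intron",     0.544, 0.220, 0.059,
    "promoter",   0.270, 0.090, 0.030,
    "flank",      0.350, 0.120, 0.040,
    "intergenic", 0.450, 0.200, 0.060)
  tab <- tidyr::pivot_longer(defaults, -"component",
                             names_to = "context", values_to = "mean")
  if (!is.null(uniform)) {
    stopifnot(all(c("CG", "CHG", "CHH") %in% names(uniform)))
    tab$mean <- unname(uniform[tab$context])
  }
  if (!is.null(means)) {
    means <- tibble::as_tibble(means)
    tab <- dplyr::rows_update(tab, means[, c("component", "context", "mean")],
                              by = c("component", "context"))
  }
  fam <- c(CG = cg_family, CHG = chg_family, CHH = chh_family)
  tab$family <- unname(fam[tab$context])
  tab$concentration <- concentration
  stopifnot(all(tab$mean >= 0 & tab$mean <= 1),
            all(tab$family %in% c("constant", "two_point", "beta")))
  # within-component ordering CG >= CHG >= CHH
  wide <- tidyr::pivot_wider(tab[, 1:3], names_from = "context",
                             values_from = "mean")
  if (any(wide$CG < wide$CHG - 1e-12) || any(wide$CHG < wide$CHH - 1e-12)) {
    stop("methylation model must satisfy CG >= CHG >= CHH per component",
         call. = FALSE)
  }
  structure(tab, class = c("methylation_model", class(tab)))
}

# GRanges of each genomic component, in model priority order.
component_granges <- function(ann, chrom_lengths, promoter = 200L,
                              flank = 1000L, split_flanks = FALSE) {
  mk <- function(df) {
    if (nrow(df) == 0) {
      return(GenomicRanges::GRanges())
    }
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end))
  }
  genes <- dplyr::filter(ann, .data$type == "gene")
  L <- chrom_lengths[genes$chrom]
  plus <- genes$strand == "+"
  clip <- function(s, e) {
    tibble::tibble(chrom = genes$chrom,
                   start = pmax(pmin(s, L), 0L),
                   end = pmin(pmax(e, 0L), L))
  }
  prom <- clip(ifelse(plus, genes$start - promoter, genes$end),
               ifelse(plus, genes$start, genes$end + promoter))
  ups <- clip(ifelse(plus, genes$start - flank, genes$end),
              ifelse(plus, genes$start, genes$end + flank))
  dns <- clip(ifelse(plus, genes$end, genes$start - flank),
              ifelse(plus, genes$end + flank, genes$start))
  drop_empty <- function(df) df[df$end > df$start, , drop = FALSE]
  out <- list(
    te = mk(dplyr::filter(ann, .data$type == "te")),
    exon = mk(dplyr::filter(ann, .data$type == "exon")),
    intron = mk(dplyr::filter(ann, .data$type == "intron")),
    promoter = mk(drop_empty(prom)))
  if (split_flanks) {
    out$upstream <- mk(drop_empty(ups))
    out$downstream <- mk(drop_empty(dns))
  } else {
    out$flank <- mk(drop_empty(dplyr::bind_rows(ups, dns)))
  }
  out
}

# Assign each site the highest-priority component it overlaps
# (te > exon > intron > promoter > flank > intergenic).
assign_components <- function(sites, ann, chrom_lengths,
                              promoter = 200L, flank = 1000L) {
  comp <- rep("intergenic", nrow(sites))
  if (nrow(ann) == 0 || nrow(sites) == 0) return(comp)
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L, width = 1L))
  comps <- component_granges(ann, chrom_lengths, promoter, flank)
  for (nm in names(comps)) {
    if (length(comps[[nm]]) == 0) next
    hit <- IRanges::overlapsAny(gr_sites, comps[[nm]])
    comp[hit & comp == "intergenic"] <- nm
  }
  comp
}

#' Generate a ground-truth methylome
#'
#' Assigns every cytosine on both strands a true methylation level drawn from
#' the model cell for its (component, context), where the component is the
#' highest-priority annotated feature overlapping the site
#' (te > exon > intron > promoter > flank > intergenic).
#'
#' @param ref Named character vector of chromosome sequences.
#' @param ann Annotation tibble from [generate_genome()].
#' @param model A [methylation_model()].
#' @param seed Integer seed.
#' @param promoter,flank Component geometry in bp.
#' @return Tibble with columns chrom, pos, strand, context, component,
#'   true_level.
#' @export
generate_methylome <- function(ref, ann, model = methylation_model(),
                               seed = 1L, promoter = 200L, flank = 1000L) {
  stopifnot(inherits(model, "methylation_model"))
  sites <- classify_cytosines(ref)
  sites$component <- assign_components(sites, ann, chrom_lengths_of(ref),
                                       promoter, flank)
  key <- paste(sites$component, sites$context)
  mkey <- paste(model$component, model$context)
  idx <- match(key, mkey)
  if (anyNA(idx)) {
    stop("methylation model does not cover component/context: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  mu <- model$mean[idx]
  fam <- model$family[idx]
  conc <- model$concentration[idx]
  with_seed(seed, {
    lv <- mu
    tp <- fam == "two_point"
    if (any(tp)) lv[tp] <- as.numeric(stats::rbinom(sum(tp), 1L, mu[tp]))
    be <- fam == "beta" & mu > 0 & mu < 1
    if (any(be)) {
      lv[be] <- stats::rbeta(sum(be), mu[be] * conc[be],
                             (1 - mu[be]) * conc[be])
    }
    sites$true_level <- lv
    sites
  })
}

#' Introduce substitution variants into a reference genome
#'
#' Draws SNPs uniformly at the given per-base rate and applies them to the
#' reference, yielding the "sample" genome sequenced by the simulators and the
#' truth set of variants for masking experiments.
#'
#' @param ref Named character vector of chromosome sequences.
#' @param snp_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `ref` (mutated genome) and `variants` (tibble chrom,
#'   pos, ref, alt).
#' @export
apply_variants <- function(ref, snp_rate, seed = 1L) {
  stop_if_not_ref(ref)
  stopifnot(snp_rate >= 0, snp_rate < 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    res <- lapply(names(ref), function(chrom) {
      s <- ref[[chrom]]
      L <- nchar(s)
      n <- stats::rbinom(1, L, snp_rate)
      if (n == 0) {
        return(list(seq = s, var = NULL))
      }
      pos <- sort(sample.int(L, n)) # 1-based
      refb <- substring(s, pos, pos)
      altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1), character(1))
      r <- charToRaw(s)
      r[pos] <- charToRaw(paste0(altb, collapse = ""))
      list(seq = rawToChar(r),
           var = tibble::tibble(chrom = chrom, pos = pos - 1L,
                                ref = refb, alt = unname(altb)))
    })
    mut <- vapply(res, function(x) x$seq, character(1))
    names(mut) <- names(ref)
    vars <- dplyr::bind_rows(lapply(res, function(x) x$var))
    if (nrow(vars) == 0) {
      vars <- tibble::tibble(chrom = character(), pos = integer(),
                             ref = character(), alt = character())
    }
    list(ref = mut, variants = vars)
  })
}
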