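#' Expression model for synthetic RPKM tables
#'
#' Log-normal RPKM per gene with stratum-specific location (subgenome x
#' copy-class), a negative coupling to the gene's mean genic methylation, and
#' a common dispersion. Defaults encode the expression hierarchy expected in
#' a fractionated mesohexaploid: LF > MF2 > MF1 across subgenomes and
#' single-copy genes expressed lower than retained duplicates.
#'
#' @param subgenome_mu Named numeric, log-RPKM location per subgenome.
#' @param copy_offset Named numeric, additive log-RPKM offset per copy class
#'   ("1", "2", "3").
#' @param coupling Coefficient of (centred) genic methylation on log-RPKM;
#'   negative couples methylation to reduced transcription.
#' @param dispersion Log-scale standard deviation (> 0).
#' @param seed Integer seed.
#' @return An object of class `expression_model`.
#' @export
expression_model <- function(subgenome_mu = c(LF = log(12), MF1 = log(7),
                                              MF2 = log(9)),
                             copy_offset = c("1" = -0.4, "2" = 0.1,
                                             "3" = 0.3),
                             coupling = -2,
                             dispersion = 1.5,
                             seed = NULL) {
  stopifnot(dispersion > 0,
            all(c("LF", "MF1", "MF2") %in% names(subgenome_mu)),
            all(c("1", "2", "3") %in% names(copy_offset)))
  structure(list(subgenome_mu = subgenome_mu, copy_offset = copy_offset,
                 coupling = coupling, dispersion = dispersion, seed = seed),
            class = "expression_model")
}

#' Generate a synthetic expression table
#'
#' Draws one RPKM value per annotated gene from the expression model. The
#' expected log-RPKM is the gene's stratum location plus
#' `coupling * (genic methylation - genome mean genic methylation)`, where
#' genic methylation is the mean true CG level over the gene body; with a
#' negative coupling, transcription decreases with gene-body methylation.
#'
#' @param ann Annotation tibble with labelled genes.
#' @param truth Ground-truth methylome from [generate_methylome()].
#' @param model An [expression_model()].
#' @param seed Integer seed (defaults to `model$seed`).
#' @return Tibble gene_id, subgenome, copy_class, genic_meth, rpkm.
#' @export
generate_expression <- function(ann, truth, model = expression_model(),
                                seed = model$seed) {
  genes <- dplyr::filter(ann, .data$type == "gene")
  if (any(is.na(genes$subgenome)) || any(is.na(genes$copy_class))) {
    stop("every gene must carry subgenome and copy_class labels",
         call. = FALSE)
  }
  cg <- truth[truth$context == "CG", ]
  gr_s <- GenomicRanges::GRanges(cg$chrom,
                                 IRanges::IRanges(cg$pos + 1L, width = 1L))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  ov <- GenomicRanges::findOverlaps(gr_s, gr_g)
  gm <- tibble::tibble(gene = S4Vectors::subjectHits(ov),
                       level = cg$true_level[S4Vectors::queryHits(ov)]) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(genic_meth = mean(.data$level), .groups = "drop")
  genes$genic_meth <- 0
  genes$genic_meth[gm$gene] <- gm$genic_meth
  centred <- genes$genic_meth - mean(genes$genic_meth)
  mu <- model$subgenome_mu[genes$subgenome] +
    model$copy_offset[as.character(genes$copy_class)] +
    model$coupling * centred
  with_seed(seed, {
    rpkm <- if (model$dispersion > 1e-12) {
      exp(stats::rnorm(nrow(genes), mu, model$dispersion))
    } else {
      exp(mu)
    }
    tibble::tibble(gene_id = genes$gene_id,
                   subgenome = genes$subgenome,
                   copy_class = genes$copy_class,
                   genic_meth = genes$genic_meth,
                   rpkm = unname(rpkm))
  })
}
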