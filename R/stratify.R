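#' Pooled methylation by subgenome or copy-number stratum
#'
#' Pools methylated/unmethylated read counts per stratum (subgenome LF/MF1/
#' MF2 or copy class 1/2/3) for each gene-anatomy component and context.
#' Sites are attached to genes strand-awarely; `genic` pools exon and intron
#' evidence of the gene body. Genes lacking the stratifying label are
#' excluded (count in `attr(, "unlabelled_genes")`); empty strata are simply
#' absent.
#'
#' @param calls Site calls from [call_levels()].
#' @param ann Annotation tibble with subgenome/copy_class labels on genes.
#' @param key Stratifying label: "subgenome" or "copy_class".
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param promoter,flank Component geometry in bp.
#' @return Tibble of class `stratum_summary`: stratum, component, context,
#'   n_sites, meth, unmeth, mean (read-count pooled).
#' @export
stratum_means <- function(calls, ann, key = c("subgenome", "copy_class"),
                          chrom_lengths, promoter = 200L, flank = 1000L) {
  key <- match.arg(key)
  genes <- dplyr::filter(ann, .data$type == "gene")
  unlabelled <- sum(is.na(genes[[key]]))
  genes <- genes[!is.na(genes[[key]]), , drop = FALSE]
  parts <- dplyr::filter(ann, .data$type %in% c("exon", "intron"),
                         .data$gene_id %in% genes$gene_id)
  gr_s <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1L, width = 1L))
  strata <- sort(unique(genes[[key]]))
  rows <- lapply(strata, function(st) {
    g <- genes[genes[[key]] == st, , drop = FALSE]
    sub_ann <- dplyr::bind_rows(g, parts[parts$gene_id %in% g$gene_id, ])
    comps <- component_granges(sub_ann, chrom_lengths, promoter, flank,
                               split_flanks = TRUE)
    comps$te <- NULL
    # gene body = exon + intron pooled
    comps$genic <- GenomicRanges::GRanges(g$chrom,
                                          IRanges::IRanges(g$start + 1L,
                                                           g$end))
    per_comp <- lapply(names(comps), function(nm) {
      if (length(comps[[nm]]) == 0) return(NULL)
      hit <- IRanges::overlapsAny(gr_s, GenomicRanges::reduce(comps[[nm]]))
      sub <- calls[hit, ]
      if (nrow(sub) == 0) return(NULL)
      sub |>
        dplyr::group_by(.data$context) |>
        dplyr::summarise(n_sites = dplyr::n(), meth = sum(.data$meth),
                         unmeth = sum(.data$unmeth), .groups = "drop") |>
        dplyr::mutate(component = nm, .before = 1)
    })
    dplyr::bind_rows(per_comp) |>
      dplyr::mutate(stratum = as.character(st), .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(mean = .data$meth / (.data$meth + .data$unmeth))
  attr(out, "unlabelled_genes") <- unlabelled
  class(out) <- c("stratum_summary", class(out))
  out
}

#' Pairwise 2x2 chi-square comparison of pooled methylation
#'
#' One-degree-of-freedom chi-square on pooled (methylated, unmethylated)
#' read counts of two strata, without continuity correction:
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`. Significance uses the fixed critical
#' value 6.63 (the 0.99 quantile of the 1-df null, i.e. P < 0.01), matching
#' a fixed-threshold testing scheme with no multiplicity correction.
#' Vectorised over its arguments.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b Pooled read counts.
#' @param critical Critical value (default `qchisq(0.99, 1)`).
#' @return Tibble of class `meth_chisq`: statistic, df, p_value, significant,
#'   computable (FALSE when a marginal is zero).
#' @export
pairwise_chisq <- function(meth_a, unmeth_a, meth_b, unmeth_b,
                           critical = stats::qchisq(0.99, 1)) {
  a <- as.numeric(meth_a); b <- as.numeric(unmeth_a)
  c_ <- as.numeric(meth_b); d <- as.numeric(unmeth_b)
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  computable <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat <- ifelse(computable, n * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2),
                 NA_real_)
  out <- tibble::tibble(statistic = stat, df = 1L,
                        p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                        significant = !is.na(stat) & stat > critical,
                        computable = computable)
  class(out) <- c("meth_chisq", class(out))
  attr(out, "critical") <- critical
  out
}

#' All pairwise stratum comparisons for one component and context
#'
#' @param summary A [stratum_means()] table.
#' @param component,context Cell to compare across strata.
#' @param critical Chi-square critical value.
#' @return Tibble: stratum_a, stratum_b, mean_a, mean_b plus the
#'   [pairwise_chisq()] columns.
#' @export
stratum_tests <- function(summary, component = "genic", context = "CG",
                          critical = stats::qchisq(0.99, 1)) {
  cell <- summary[summary$component == component &
                    summary$context == context, ]
  if (nrow(cell) < 2) {
    stop("need at least two strata with data for component '", component,
         "', context '", context, "'", call. = FALSE)
  }
  pairs <- utils::combn(seq_len(nrow(cell)), 2)
  a <- cell[pairs[1, ], ]; b <- cell[pairs[2, ], ]
  res <- pairwise_chisq(a$meth, a$unmeth, b$meth, b$unmeth, critical)
  out <- dplyr::bind_cols(tibble::tibble(stratum_a = a$stratum,
                                         stratum_b = b$stratum,
                                         mean_a = a$mean, mean_b = b$mean),
                          res)
  class(out) <- c("meth_chisq", class(out))
  attr(out, "critical") <- critical
  out
}

#' Classify genes into expression classes
#'
#' RPKM <= `low_max` is low, `low_max` < RPKM <= `high_min` is medium,
#' RPKM > `high_min` is high (boundaries: 5 is low, 50 is medium, 50.01 is
#' high at the defaults).
#'
#' @param expression Tibble with columns gene_id, rpkm.
#' @param low_max,high_min Class boundaries (defaults 5 and 50).
#' @return `expression` with an added ordered factor column `class`.
#' @export
bin_expression <- function(expression, low_max = 5, high_min = 50) {
  if (any(expression$rpkm < 0)) {
    stop("negative RPKM values are not allowed", call. = FALSE)
  }
  cls <- ifelse(expression$rpkm <= low_max, "low",
                ifelse(expression$rpkm <= high_min, "medium", "high"))
  dplyr::mutate(expression,
                class = factor(cls, levels = c("low", "medium", "high"),
                               ordered = TRUE))
}

# chi-square on an s x 3 contingency table (no continuity correction)
chisq_table <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  if (any(e == 0)) return(NA_real_)
  sum((tab - e)^2 / e)
}

# Greedy compact-letter display: strata ordered by descending high fraction;
# a stratum joins the letter of the first earlier stratum it is not
# significantly different from, else opens a new letter.
assign_letters <- function(strata, sig_pairs) {
  letters_out <- character(length(strata))
  next_letter <- 1L
  for (i in seq_along(strata)) {
    joined <- FALSE
    for (j in seq_len(i - 1L)) {
      key <- paste(sort(c(strata[i], strata[j])), collapse = "|")
      if (!isTRUE(sig_pairs[[key]])) {
        letters_out[i] <- letters_out[j]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      letters_out[i] <- letters[next_letter]
      next_letter <- next_letter + 1L
    }
  }
  letters_out
}

#' Expression-class composition per stratum
#'
#' Cross-tabulates expression classes against a stratifying gene label,
#' reports class fractions per stratum, tests every stratum pair with a
#' 2-df chi-square on the 3-class count vectors, and assigns compact
#' significance letters (strata sharing a letter are not significantly
#' different; letters follow descending high-class fraction).
#'
#' @param classes Output of [bin_expression()].
#' @param ann Annotation tibble with gene labels.
#' @param key "subgenome" or "copy_class".
#' @param p_threshold Significance threshold for the pairwise tests
#'   (default 0.01).
#' @return List of class `expression_crosstab` with `table` (stratum, class,
#'   n, fraction, letter), `tests` (pairwise chi-square results).
#' @export
expression_crosstab <- function(classes, ann, key = c("subgenome",
                                                      "copy_class"),
                                p_threshold = 0.01) {
  key <- match.arg(key)
  genes <- dplyr::filter(ann, .data$type == "gene")
  df <- dplyr::inner_join(classes[, c("gene_id", "class")],
                          genes[, c("gene_id", key)], by = "gene_id")
  df <- df[!is.na(df[[key]]), ]
  df$stratum <- as.character(df[[key]])
  counts <- df |>
    dplyr::count(.data$stratum, .data$class, name = "n", .drop = FALSE) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(counts[, c("stratum", "class", "n")],
                             names_from = "class", values_from = "n",
                             values_fill = 0L)
  strata <- wide$stratum
  tests <- NULL
  sig_pairs <- list()
  if (length(strata) >= 2) {
    pr <- utils::combn(seq_along(strata), 2)
    tests <- dplyr::bind_rows(lapply(seq_len(ncol(pr)), function(i) {
      tab <- as.matrix(wide[pr[, i], c("low", "medium", "high")])
      stat <- chisq_table(tab)
      tibble::tibble(stratum_a = strata[pr[1, i]],
                     stratum_b = strata[pr[2, i]],
                     statistic = stat, df = 2L,
                     p_value = stats::pchisq(stat, 2, lower.tail = FALSE),
                     significant = !is.na(stat) &
                       stats::pchisq(stat, 2, lower.tail = FALSE) <
                       p_threshold)
    }))
    for (i in seq_len(ncol(pr))) {
      k <- paste(sort(strata[pr[, i]]), collapse = "|")
      sig_pairs[[k]] <- tests$significant[i]
    }
  }
  high_frac <- counts$fraction[counts$class == "high"][match(
    strata, counts$stratum[counts$class == "high"])]
  ord <- order(-high_frac, strata)
  lets <- assign_letters(strata[ord], sig_pairs)
  letter_map <- stats::setNames(lets, strata[ord])
  counts$letter <- unname(letter_map[counts$stratum])
  structure(list(table = counts, tests = tests),
            class = "expression_crosstab")
}

#' @export
print.expression_crosstab <- function(x, ...) {
  cat("<expression_crosstab>\n")
  print(x$table)
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' Mean genic methylation by expression class
#'
#' Pools genic (gene-body) methylation evidence per expression class and
#' context, and reports whether the class means decrease monotonically from
#' low to high expression — the signature of the negative coupling between
#' transcription and gene-body methylation.
#'
#' @param calls Site calls from [call_levels()].
#' @param ann Annotation tibble.
#' @param classes Output of [bin_expression()].
#' @return Tibble of class `meth_expression`: class, context, n_sites, meth,
#'   unmeth, mean; `attr(, "monotone_decreasing")` is a named logical per
#'   context.
#' @export
methylation_expression_association <- function(calls, ann, classes) {
  genes <- dplyr::filter(ann, .data$type == "gene")
  genes <- dplyr::inner_join(genes, classes[, c("gene_id", "class")],
                             by = "gene_id")
  gr_s <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1L, width = 1L))
  rows <- lapply(levels(classes$class), function(cl) {
    g <- genes[genes$class == cl, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start + 1L, g$end)))
    hit <- IRanges::overlapsAny(gr_s, gr)
    sub <- calls[hit, ]
    if (nrow(sub) == 0) return(NULL)
    sub |>
      dplyr::group_by(.data$context) |>
      dplyr::summarise(n_sites = dplyr::n(), meth = sum(.data$meth),
                       unmeth = sum(.data$unmeth), .groups = "drop") |>
      dplyr::mutate(class = cl, .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c("low", "medium", "high"),
                                 ordered = TRUE),
                  mean = .data$meth / (.data$meth + .data$unmeth)) |>
    dplyr::arrange(.data$context, .data$class)
  mono <- out |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(mono = all(diff(.data$mean) <= 0), .groups = "drop")
  attr(out, "monotone_decreasing") <- stats::setNames(mono$mono, mono$context)
  class(out) <- c("meth_expression", class(out))
  out
}
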