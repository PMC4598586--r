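test_that("the 2x2 chi-square matches the closed form and the fixed criterion", {
  same <- pairwise_chisq(50, 50, 50, 50)
  expect_equal(same$statistic, 0)
  expect_false(same$significant)
  diffd <- pairwise_chisq(70, 30, 50, 50)
  expect_equal(round(diffd$statistic, 2), 8.33)
  expect_true(diffd$significant)
  # the P < 0.01 criterion is the 0.99 quantile of the 1-df null
  expect_equal(round(stats::qchisq(0.99, 1), 2), 6.63)
  # zero marginal: not computable
  z <- pairwise_chisq(0, 0, 5, 5)
  expect_false(z$computable)
  expect_true(is.na(z$statistic))
})

test_that("the chi-square statistic agrees with stats::chisq.test on random tables", {
  set.seed(180)
  for (i in 1:100) {
    tab <- matrix(sample(1:500, 4, TRUE), 2)
    ours <- pairwise_chisq(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("tidy() and glance() expose the comparison results", {
  x <- pairwise_chisq(c(70, 50), c(30, 50), c(50, 50), c(50, 50))
  td <- tidy(x)
  expect_equal(nrow(td), 2L)
  expect_named(td, c("statistic", "df", "p.value", "significant",
                     "computable"))
  gl <- glance(x)
  expect_equal(gl$n_comparisons, 2L)
  expect_equal(gl$n_significant, 1L)
})

test_that("expression classes respect the RPKM boundaries exactly", {
  expr <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                         rpkm = c(0, 5, 5.5, 50, 50.01))
  cls <- bin_expression(expr)
  expect_equal(as.character(cls$class),
               c("low", "low", "medium", "medium", "high"))
  expect_error(bin_expression(tibble::tibble(gene_id = "g", rpkm = -1)),
               "negative RPKM")
})

mk_ann_genes <- function(n, key, values) {
  tibble::tibble(chrom = "chr1",
                 start = seq(0L, by = 2000L, length.out = n),
                 end = seq(0L, by = 2000L, length.out = n) + 1000L,
                 strand = "+", type = "gene",
                 feature_id = sprintf("g%04d", 1:n),
                 gene_id = sprintf("g%04d", 1:n),
                 subgenome = if (key == "subgenome") values else "LF",
                 copy_class = if (key == "copy_class") values else 1L)
}

test_that("identical class distributions share one letter; 7.3% is reported as such", {
  n <- 3000
  ann <- mk_ann_genes(n, "copy_class", rep(1:3, each = 1000))
  rpkm <- rep(c(rep(1, 500), rep(10, 427), rep(100, 73)), 3)
  cls <- bin_expression(tibble::tibble(gene_id = ann$gene_id, rpkm = rpkm))
  xt <- expression_crosstab(cls, ann, "copy_class")
  expect_true(all(xt$table$letter == "a"))
  high <- xt$table[xt$table$class == "high", ]
  expect_equal(high$fraction, rep(0.073, 3))
  expect_false(any(xt$tests$significant))
})

test_that("three mutually different strata earn letters a, b, c by high fraction", {
  n <- 3000
  ann <- mk_ann_genes(n, "subgenome", rep(c("LF", "MF1", "MF2"), each = 1000))
  mk_block <- function(n_low, n_med, n_high) {
    c(rep(1, n_low), rep(10, n_med), rep(100, n_high))
  }
  rpkm <- c(mk_block(200, 400, 400),    # LF: most high
            mk_block(700, 250, 50),     # MF1: least
            mk_block(450, 350, 200))    # MF2: middle
  cls <- bin_expression(tibble::tibble(gene_id = ann$gene_id, rpkm = rpkm))
  xt <- expression_crosstab(cls, ann, "subgenome")
  expect_true(all(xt$tests$significant))
  letter_of <- unique(xt$table[, c("stratum", "letter")])
  lk <- stats::setNames(letter_of$letter, letter_of$stratum)
  expect_equal(unname(lk[c("LF", "MF2", "MF1")]), c("a", "b", "c"))
})

test_that("stratum means reproduce component means for a single stratum", {
  g <- small_genome(seed = 190, chrom_lengths = 1e5, n_genes = 30, n_tes = 0)
  ann <- g$ann
  ann$subgenome[ann$type == "gene"] <- "LF"
  sites <- classify_cytosines(g$ref)
  calls <- sites
  set.seed(191)
  calls$meth <- stats::rbinom(nrow(calls), 10, 0.4)
  calls$unmeth <- 10L - calls$meth
  calls$coverage <- 10L
  calls$level <- calls$meth / 10
  sm <- stratum_means(calls, ann, "subgenome", chrom_lengths_of(g$ref))
  cm <- component_means(calls, ann, chrom_lengths_of(g$ref))
  for (comp in c("exon", "intron", "promoter", "upstream", "downstream")) {
    a <- sm[sm$component == comp & sm$context == "CG", ]
    b <- cm[cm$component == comp & cm$context == "CG", ]
    expect_equal(a$meth, b$meth)
    expect_equal(a$unmeth, b$unmeth)
  }
})

test_that("stratum pooled counts sum to the whole-genome pooled counts", {
  g <- small_genome(seed = 200, chrom_lengths = 2e5, n_genes = 60, n_tes = 0)
  sites <- classify_cytosines(g$ref)
  calls <- sites
  set.seed(201)
  calls$meth <- stats::rbinom(nrow(calls), 12, 0.3)
  calls$unmeth <- 12L - calls$meth
  calls$coverage <- 12L
  calls$level <- calls$meth / 12
  sm <- stratum_means(calls, g$ann, "subgenome", chrom_lengths_of(g$ref))
  ann_all <- g$ann
  ann_all$subgenome[ann_all$type == "gene"] <- "ALL"
  total <- stratum_means(calls, ann_all, "subgenome",
                         chrom_lengths_of(g$ref))
  # strata partition the genes, and gene bodies do not overlap, so pooled
  # genic counts must add up
  genic <- sm[sm$component == "genic", ] |>
    dplyr::group_by(context) |>
    dplyr::summarise(meth = sum(meth), unmeth = sum(unmeth))
  tot_genic <- total[total$component == "genic", ]
  expect_equal(genic$meth, tot_genic$meth)
  expect_equal(genic$unmeth, tot_genic$unmeth)
})

test_that("unlabelled genes are excluded and counted", {
  g <- small_genome(seed = 210, chrom_lengths = 1e5, n_genes = 20, n_tes = 0)
  ann <- g$ann
  drop <- ann$gene_id %in% ann$gene_id[ann$type == "gene"][1:5]
  ann$subgenome[drop] <- NA
  sites <- classify_cytosines(g$ref)
  calls <- sites
  calls$meth <- 5L; calls$unmeth <- 5L; calls$coverage <- 10L
  calls$level <- 0.5
  sm <- stratum_means(calls, ann, "subgenome", chrom_lengths_of(g$ref))
  expect_equal(attr(sm, "unlabelled_genes"), 5L)
})

test_that("injected subgenome ordering is recovered and tested as significant", {
  g <- small_genome(seed = 220, chrom_lengths = 4e5, n_genes = 120, n_tes = 0)
  genes <- g$ann[g$ann$type == "gene", ]
  offs <- c(LF = 0.30, MF1 = 0.38, MF2 = 0.34)
  sites <- classify_cytosines(g$ref)
  gr_s <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1, width = 1))
  lvl <- rep(NA_real_, nrow(sites))
  for (sg in names(offs)) {
    gg <- genes[genes$subgenome == sg, ]
    gr_g <- GenomicRanges::GRanges(gg$chrom,
                                   IRanges::IRanges(gg$start + 1, gg$end))
    lvl[IRanges::overlapsAny(gr_s, gr_g)] <- offs[sg]
  }
  keep <- !is.na(lvl)
  calls <- sites[keep, ]
  set.seed(221)
  calls$meth <- stats::rbinom(nrow(calls), 20, lvl[keep])
  calls$unmeth <- 20L - calls$meth
  calls$coverage <- 20L
  calls$level <- calls$meth / 20
  sm <- stratum_means(calls, g$ann, "subgenome", chrom_lengths_of(g$ref))
  genic <- sm[sm$component == "genic" & sm$context == "CG", ]
  expect_equal(genic$stratum[order(-genic$mean)], c("MF1", "MF2", "LF"))
  tst <- stratum_tests(sm, "genic", "CG")
  expect_true(all(tst$significant))
})

test_that("the association table is monotone given decreasing inputs and handles one class", {
  ann <- mk_ann_genes(30, "subgenome", "LF")
  sites <- tibble::tibble(chrom = "chr1",
                          pos = as.integer(seq(100, 59000, by = 200)),
                          strand = "+", context = "CG")
  gene_of <- findInterval(sites$pos, ann$start)
  lvl <- c(rep(0.8, 10), rep(0.5, 10), rep(0.2, 10))[gene_of]
  calls <- sites
  calls$meth <- as.integer(round(lvl * 10))
  calls$unmeth <- 10L - calls$meth
  calls$coverage <- 10L
  calls$level <- lvl
  classes <- bin_expression(tibble::tibble(
    gene_id = ann$gene_id,
    rpkm = c(rep(1, 10), rep(10, 10), rep(100, 10))))
  out <- methylation_expression_association(calls, ann, classes)
  expect_equal(as.character(out$class), c("low", "medium", "high"))
  expect_true(attr(out, "monotone_decreasing")[["CG"]])
  one <- methylation_expression_association(
    calls, ann, bin_expression(tibble::tibble(gene_id = ann$gene_id,
                                              rpkm = rep(1, 30))))
  expect_equal(nrow(one), 1L)
})
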