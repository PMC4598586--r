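mk_calls <- function(pos, level, chrom = "chr1", context = "CG",
                     strand = "+", coverage = 10L) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 context = context,
                 meth = as.integer(round(level * coverage)),
                 unmeth = as.integer(coverage - round(level * coverage)),
                 coverage = as.integer(coverage), level = level)
}

test_that("window means average site levels and honour window geometry", {
  calls <- mk_calls(c(1000L, 2000L), c(0.2, 0.4))
  w <- window_profile(calls, c(chr1 = 250000L))
  cg <- w[w$context == "CG" & w$n_sites > 0, ]
  expect_equal(cg$mean_level[cg$start == 0], 0.3)
  # empty windows report no sites and an undefined mean
  empty <- w[w$context == "CHH", ]
  expect_true(all(empty$n_sites == 0))
  expect_true(all(is.na(empty$mean_level)))
  # a site at 150 kb falls in both [0,200k) and [100k,300k)
  calls2 <- mk_calls(150000L, 1)
  w2 <- window_profile(calls2, c(chr1 = 300000L))
  hit <- w2[w2$context == "CG" & w2$n_sites > 0, ]
  expect_setequal(hit$start, c(0L, 100000L))
  # the last partial window is included
  expect_true(any(w2$end == 300000L))
})

test_that("non-overlapping windows pooled by site count give the genome mean", {
  set.seed(140)
  calls <- mk_calls(sort(sample(0:299999, 500)), stats::runif(500))
  w <- window_profile(calls, c(chr1 = 300000L), win = 50000L, step = 50000L)
  cg <- w[w$context == "CG" & w$n_sites > 0, ]
  pooled <- sum(cg$mean_level * cg$n_sites) / sum(cg$n_sites)
  expect_equal(pooled, mean(calls$level), tolerance = 1e-12)
})

test_that("window repeat totals clip annotation intervals to the window", {
  ann <- tibble::tibble(chrom = "chr1", start = 90000L, end = 110000L,
                        strand = "+", type = "tandem_repeat",
                        feature_id = "tr1", gene_id = NA_character_,
                        subgenome = NA_character_, copy_class = NA_integer_)
  w <- window_profile(mk_calls(1L, 0.5), c(chr1 = 200000L), ann = ann,
                      win = 100000L, step = 100000L)
  first <- unique(w$repeat_bases[w$start == 0])
  second <- unique(w$repeat_bases[w$start == 100000])
  expect_equal(first, 10000L)
  expect_equal(second, 10000L)
})

test_that("component means are strand-aware and cover the six components", {
  g <- small_genome(seed = 150)
  truth <- generate_methylome(g$ref, g$ann, methylation_model(), seed = 151)
  calls <- truth
  calls$meth <- 10L; calls$unmeth <- 0L; calls$coverage <- 10L
  calls$level <- 1
  cm <- component_means(calls, g$ann, chrom_lengths_of(g$ref))
  expect_setequal(unique(cm$component),
                  c("te", "exon", "intron", "promoter", "upstream",
                    "downstream"))
  expect_true(all(cm$mean_level == 1))
  expect_true(all(cm$pooled_level == 1))
})

test_that("a minus-strand gene's promoter sits above its TSS coordinate", {
  ann <- tibble::tibble(chrom = "chr1", start = 5000L, end = 6000L,
                        strand = "-", type = "gene", feature_id = "g1",
                        gene_id = "g1", subgenome = "LF", copy_class = 1L)
  # site 100 bp above the gene end (inside the minus-strand promoter)
  calls <- mk_calls(c(6100L, 4900L), c(1, 0))
  cm <- component_means(calls, ann, c(chr1 = 20000L))
  prom <- cm[cm$component == "promoter", ]
  expect_equal(prom$n_sites, 1L)
  expect_equal(prom$mean_level, 1)
  dn <- cm[cm$component == "downstream", ]
  expect_equal(dn$mean_level, 0)
})

test_that("metagene bins are exact for a 1-kb gene and form a partition", {
  feats <- tibble::tibble(chrom = "chr1", start = 2000L, end = 3000L,
                          strand = "+", type = "gene", feature_id = "g1",
                          gene_id = "g1", subgenome = "LF", copy_class = 1L)
  pos <- 2000:2999
  calls <- mk_calls(pos, rep(1, length(pos)))
  prof <- metagene_profile(calls, feats)
  body <- prof[prof$region == "body", ]
  expect_equal(nrow(body), 10L)
  expect_true(all(body$n_sites == 100L))  # exactly 100 bp per decile
  # partition: every body site lands in exactly one bin
  expect_equal(sum(body$n_sites), length(pos))
})

test_that("metagene profiles are flat under a uniform methylome and mirror strand", {
  g <- small_genome(seed = 160, chrom_lengths = 2e5, n_genes = 60, n_tes = 0)
  genes <- g$ann[g$ann$type == "gene", ]
  truth <- classify_cytosines(g$ref)
  calls <- truth
  calls$meth <- 8L; calls$unmeth <- 2L; calls$coverage <- 10L
  calls$level <- 0.8
  prof <- metagene_profile(calls, genes)
  expect_true(all(abs(prof$mean_level - 0.8) < 1e-12))
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  # flipping strands reverses bins but cannot change a flat profile
  prof2 <- metagene_profile(calls, flipped)
  expect_equal(dim(prof), dim(prof2))
  expect_true(all(abs(prof2$mean_level - 0.8) < 1e-12))
})

test_that("a TE-boundary step function shows up at the body edges", {
  ref <- random_ref(6e4, seed = 170)
  feats <- tibble::tibble(chrom = "chr1",
                          start = seq(5000L, 50000L, by = 5000L),
                          end = seq(5000L, 50000L, by = 5000L) + 2000L,
                          strand = "+", type = "te",
                          feature_id = sprintf("te%d", 1:10),
                          gene_id = NA_character_,
                          subgenome = NA_character_,
                          copy_class = NA_integer_)
  sites <- classify_cytosines(ref)
  inside <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(feats))) {
    inside <- inside | (sites$pos >= feats$start[i] &
                          sites$pos < feats$end[i])
  }
  calls <- sites
  calls$level <- ifelse(inside, 0.9, 0.1)
  calls$meth <- as.integer(calls$level * 10)
  calls$unmeth <- 10L - calls$meth
  calls$coverage <- 10L
  prof <- metagene_profile(calls, feats)
  body_cg <- prof[prof$region == "body" & prof$context == "CG", ]
  up_cg <- prof[prof$region == "upstream" & prof$context == "CG", ]
  expect_true(all(body_cg$mean_level > 0.85))
  expect_true(all(up_cg$mean_level < 0.15))
})

test_that("features shorter than the bin count are excluded and logged", {
  feats <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                          end = c(5L, 1100L), strand = "+", type = "gene",
                          feature_id = c("tiny", "ok"),
                          gene_id = c("tiny", "ok"),
                          subgenome = NA_character_, copy_class = NA_integer_)
  prof <- metagene_profile(mk_calls(500L, 0.5), feats)
  expect_equal(attr(prof, "excluded_short"), 1L)
})

test_that("level histogram separates exact zero and fills ten bins", {
  calls <- mk_calls(c(1L, 2L, 3L, 4L), c(0, 0.05, 0.95, 1),
                    coverage = c(20L, 20L, 20L, 20L))
  h <- level_histogram(calls)
  cg <- h[h$context == "CG", ]
  expect_equal(cg$n_sites[cg$bin == "0"], 1L)
  expect_equal(cg$n_sites[cg$bin == "(0,10]"], 1L)
  expect_equal(cg$n_sites[cg$bin == "(90,100]"], 2L)
  expect_equal(sum(cg$fraction), 1, tolerance = 1e-9)
  all_zero <- level_histogram(mk_calls(1:5, rep(0, 5)))
  z <- all_zero[all_zero$context == "CG", ]
  expect_equal(z$fraction[z$bin == "0"], 1)
})
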