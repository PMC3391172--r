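test_that("contingency test picks the right branch and edge cases", {
  r <- contingency_test(1, 1, 1, 1)
  expect_equal(r$test_used, "fisher")
  expect_equal(r$p_value, 1)

  # boundary of the sample-size rule
  expect_equal(contingency_test(1000, 1000, 1000, 1999)$test_used, "fisher")
  expect_equal(contingency_test(1000, 1000, 1000, 2000)$test_used,
               "chisq_yates")

  # zero margin: degenerate, p = 1
  z <- contingency_test(0, 0, 5, 7)
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)

  expect_error(contingency_test(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_test(1.5, 2, 3, 4), "non-negative")

  expect_equal(significance_stars(c(2e-4, 2e-3, 0.02, 0.2)),
               c("***", "**", "*", "ns"))
})

test_that("Fisher branch equals the hypergeometric enumeration oracle", {
  expect_equal(contingency_test(5, 15, 15, 5)$p_value,
               fisher_by_enumeration(5, 15, 15, 5), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:200) {
    t <- as.vector(rmultinom(1, sample(4:200, 1), runif(4) + 0.05))
    expect_equal(contingency_test(t[1], t[2], t[3], t[4])$p_value,
                 fisher_by_enumeration(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher branch matches stats::fisher.test's two-sided p", {
  set.seed(8)
  for (i in 1:100) {
    t <- as.vector(rmultinom(1, sample(6:400, 1), runif(4) + 0.05))
    expect_equal(contingency_test(t[1], t[2], t[3], t[4])$p_value,
                 fisher.test(matrix(t, 2))$p.value, tolerance = 1e-10)
  }
})

test_that("Yates branch equals the closed form and stats::chisq.test", {
  a <- 150; b <- 850; cc <- 1000; d <- 9000
  r <- contingency_test(a, b, cc, d)
  expect_equal(r$test_used, "chisq_yates")
  n <- a + b + cc + d
  stat <- n * max(0, abs(a * d - b * cc) - n / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(r$statistic, stat)
  expect_equal(r$p_value, pchisq(stat, 1, lower.tail = FALSE))
  ref <- suppressWarnings(
    chisq.test(matrix(c(a, b, cc, d), 2, byrow = TRUE), correct = TRUE))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)

  # a proportional table (ad = bc): the continuity correction clamps at 0
  r0 <- contingency_test(100, 900, 1000, 9000)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("normalized X frequency matches the direct formulas", {
  ids <- sprintf("g%03d", 1:700)
  ann <- make_annot(ids, n_x = 100)            # genome fraction 1/7
  nf <- normalized_x_frequency(ids[c(1:10, 101:190)], ann)  # k=10, n=100
  expect_equal(nf$genome_x_fraction, 1 / 7)
  expect_equal(nf$normalized_freq, 0.1 / (1 / 7))
  expect_equal(nf$se_norm, sqrt(0.1 * 0.9 / 100) / (1 / 7))
  expect_equal(unname(nf$band70),
               nf$normalized_freq + c(-1, 1) * nf$se_norm)
  expect_equal(unname(nf$band95),
               nf$normalized_freq + c(-2, 2) * nf$se_norm)
  expect_true(nf$band95[1] <= nf$band70[1] && nf$band70[2] <= nf$band95[2])

  # a set with exactly the genome fraction scores 1
  nf1 <- normalized_x_frequency(ids[c(1:2, 101:112)], ann)
  expect_equal(nf1$normalized_freq, 1)

  expect_error(suppressWarnings(normalized_x_frequency(c("zz"), ann)),
               "empty gene set")
})

test_that("null type-I error of the set-vs-rest contingency test is ~5%", {
  set.seed(23)
  ids <- sprintf("g%05d", 1:4000)
  ann <- make_annot(ids, n_x = round(4000 / 6))
  hits <- 0; n_rep <- 1000
  for (i in 1:n_rep) {
    set <- sample(ids, 150)
    in_set <- ann$gene_id %in% set
    is_x <- ann$linkage_class == "X"
    p <- contingency_test(sum(in_set & is_x), sum(in_set & !is_x),
                          sum(!in_set & is_x), sum(!in_set & !is_x))$p_value
    hits <- hits + (p < 0.05)
  }
  expect_equal(hits / n_rep, 0.05, tolerance = 0.02 / 0.05)
})

test_that("chromosomal enrichment recovers planted depletion and nulls", {
  set.seed(55)
  n <- 6000
  ids <- sprintf("g%05d", seq_len(n))
  # genome at X fraction 1/6; planted set with the X fraction halved
  ann <- make_annot(ids, n_x = 1000)
  x_ids <- ids[1:1000]; a_ids <- ids[1001:n]
  set_depleted <- c(sample(x_ids, 25), sample(a_ids, 275))  # phat = 1/12
  calls <- data.frame(gene_id = set_depleted, tissue = "testis",
                      min_ratio = 11, stringsAsFactors = FALSE)
  enr <- chromosomal_enrichment(calls, ann)
  row2 <- enr[enr$threshold == 2, ]
  expect_equal(row2$normalized_freq, 0.5, tolerance = 0.2)
  expect_lt(row2$p_value, 0.01)
  # nested thresholds reuse the same set here (all min_ratio = 11)
  expect_equal(enr$n, rep(300L, 3))

  # a uniform draw from the genome is near 1 and not significant
  set_null <- sample(ids, 300)
  calls0 <- data.frame(gene_id = set_null, tissue = "head",
                       min_ratio = 11, stringsAsFactors = FALSE)
  enr0 <- chromosomal_enrichment(calls0, ann)
  expect_equal(enr0$normalized_freq[1], 1, tolerance = 0.25)
  expect_gt(enr0$p_value[1], 0.05)

  # empty post-filter set emits an n = 0 row without a test
  calls_y <- data.frame(gene_id = "not_a_gene", tissue = "head",
                        min_ratio = 11, stringsAsFactors = FALSE)
  enr_y <- chromosomal_enrichment(calls_y, ann)
  expect_equal(enr_y$n, rep(0L, 3))
  expect_true(all(is.na(enr_y$p_value)))
})

test_that("excluding sex-biased genes is a no-op when none are biased", {
  set.seed(66)
  ids <- sprintf("g%04d", 1:2000)
  ann <- make_annot(ids, n_x = 333)
  calls <- data.frame(gene_id = sample(ids, 100), tissue = "head",
                      min_ratio = 6, stringsAsFactors = FALSE)
  sx <- sex_bias(rep(10, 2000), rep(10, 2000), gene_id = ids)
  a <- chromosomal_enrichment(calls, ann)
  b <- chromosomal_enrichment(calls, ann, exclude_sex_biased = TRUE,
                              sex_calls = sx)
  attr(a, "exclude_sex_biased") <- NULL
  attr(b, "exclude_sex_biased") <- NULL
  expect_identical(a, b)
})

test_that("testis-bias enrichment delegates to the generic 2x2 test", {
  set.seed(10)
  ids <- sprintf("g%04d", 1:3000)
  ann <- make_annot(ids, n_x = 500)
  # plant a 3x excess of testis-biased genes inside the set
  biased <- sample(ids, 600)
  t_ <- ifelse(ids %in% biased, 90, 10); o_ <- rep(10, 3000)
  sx <- sex_bias(t_, o_, gene_id = ids)
  set_ids <- c(sample(biased, 150), sample(setdiff(ids, biased), 100))
  calls <- data.frame(gene_id = set_ids, tissue = "midgut", min_ratio = 3,
                      stringsAsFactors = FALSE)
  tb <- testis_bias_enrichment(calls, sx, ann, thresholds = 2)
  expect_lt(tb$p_value, 1e-6)
  expect_equal(tb$testis_biased_in_set, 150)
  ref <- contingency_test(tb$testis_biased_in_set, tb$other_in_set,
                          tb$testis_biased_rest, tb$other_rest)
  expect_equal(tb$p_value, ref$p_value)
  expect_equal(tb$odds_ratio, ref$odds_ratio)

  # genome-matched composition is not significant
  set_m <- c(sample(biased, 30), sample(setdiff(ids, biased), 120))
  calls_m <- data.frame(gene_id = set_m, tissue = "midgut", min_ratio = 3,
                        stringsAsFactors = FALSE)
  expect_gt(testis_bias_enrichment(calls_m, sx, ann, thresholds = 2)$p_value,
            0.05)

  # the ovary contrast restricts the second margin to ovary-biased genes
  o2 <- o_; o2[1:300] <- 1000
  sx2 <- sex_bias(t_, o2, gene_id = ids)
  tb2 <- testis_bias_enrichment(calls, sx2, ann, thresholds = 2,
                                contrast = "ovary-biased")
  cls <- sx2$class[match(ids, sx2$gene_id)]
  expect_equal(tb2$testis_biased_rest + tb2$other_rest +
                 tb2$testis_biased_in_set + tb2$other_in_set,
               sum(cls != "unbiased"))
})
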