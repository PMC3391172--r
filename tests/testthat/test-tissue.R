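test_that("minimal tissue-to-tissue ratio follows the rule and floor", {
  # the documented midgut pattern: specific at >2 but not at >5
  r <- min_tissue_ratio(c(midgut = 629, testis = 196, ovary = 34), "midgut")
  expect_equal(r, 629 / 196)
  expect_true(r > 2 && r <= 5)

  expect_equal(min_tissue_ratio(c(a = 10, b = 10, c = 10), "a"), 1)

  # zero denominator floored at 1 before division
  expect_equal(min_tissue_ratio(c(a = 100, b = 0, c = 50), "a", floor = 1),
               2)
  expect_equal(min_tissue_ratio(c(a = 100, b = 0, c = 50), "a", floor = 25),
               2)

  # non-positive focal signal is never specific
  expect_equal(min_tissue_ratio(c(a = 0, b = 5), "a"), 0)
  expect_error(min_tissue_ratio(c(a = 1), "a"), "non-focal")
  expect_error(min_tissue_ratio(c(a = 1, b = 2), "z"), "not in panel")
})

test_that("ratio classification equals a brute-force gene x tissue loop", {
  set.seed(14)
  tissues <- c("midgut", "head", "salivary_gland", "ovary", "testis")
  sig <- matrix(rlnorm(40 * 5, log(50), 1), nrow = 40,
                dimnames = list(sprintf("g%02d", 1:40), tissues))
  panel <- make_panel(sig)
  calls <- classify_specific(panel, sex_tissues_in_panel = TRUE)
  # oracle: double loop, no shared code with the implementation
  for (g in rownames(sig)) for (tis in tissues) {
    others <- sig[g, setdiff(tissues, tis)]
    ratio <- min(sig[g, tis] / pmax(others, 1))
    hit <- calls$gene_id == g & calls$tissue == tis
    if (ratio > 2) {
      expect_true(any(hit))
      expect_equal(calls$min_ratio[hit], ratio)
      expect_equal(as.character(calls$threshold_class[hit]),
                   if (ratio > 10) ">10" else if (ratio > 5) ">5" else ">2")
    } else {
      expect_false(any(hit))
    }
  }
})

test_that("specific sets are nested across thresholds and a planted gene
           appears at every threshold it exceeds", {
  set.seed(9)
  tissues <- c("midgut", "head", "ovary", "testis")
  sig <- matrix(rlnorm(30 * 4, log(40), 0.4), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), tissues))
  sig["g05", "head"] <- 12 * max(sig["g05", c("midgut", "ovary", "testis")])
  panel <- make_panel(sig)
  calls <- classify_specific(panel, sex_tissues_in_panel = TRUE)
  sets <- lapply(c(2, 5, 10), function(t)
    calls$gene_id[calls$tissue == "head" & calls$min_ratio > t])
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(vapply(sets, function(s) "g05" %in% s, logical(1))))

  # a uniform panel yields no specific calls at all
  uni <- make_panel(matrix(10, 5, 4,
                           dimnames = list(paste0("g", 1:5), tissues)))
  expect_equal(nrow(classify_specific(uni)), 0)
})

test_that("sex tissues are excluded from denominators by default", {
  sig <- rbind(g1 = c(midgut = 629, head = 100, testis = 250, ovary = 34))
  panel <- make_panel(sig)
  # with testis in the denominator the gene is barely 2-fold specific ...
  with_sex <- classify_specific(panel, sex_tissues_in_panel = TRUE)
  expect_equal(with_sex$min_ratio[with_sex$tissue == "midgut"], 629 / 250)
  # ... by default it is scored against somatic tissues only
  default <- classify_specific(panel)
  expect_equal(default$min_ratio[default$tissue == "midgut"], 629 / 100)
  expect_equal(attr(default, "config")$sex_tissues_in_panel, FALSE)
})

test_that("sex-bias classes follow the ratio rule and partition the genes", {
  r <- sex_bias(c(196, 50, 10, 0, 0), c(34, 50, 30, 5, 0))
  expect_equal(as.character(r$class),
               c("testis-biased", "unbiased", "ovary-biased",
                 "ovary-biased", "unbiased"))
  expect_true(r$undefined_ratio[5])
  expect_equal(r$testis_ovary_ratio[1], 196 / 34)

  # at threshold 5 the first gene is still testis-biased (ratio ~5.76)
  expect_equal(as.character(sex_bias(196, 34, threshold = 5)$class),
               "testis-biased")

  # partition property on random signals
  set.seed(31)
  t_ <- rlnorm(500, 3, 1); o_ <- rlnorm(500, 3, 1)
  cls <- sex_bias(t_, o_)$class
  expect_equal(sum(table(cls)), 500)
  tb <- t_ / o_ > 2; ob <- o_ / t_ > 2
  expect_equal(as.vector(table(cls)[c("testis-biased", "ovary-biased")]),
               c(sum(tb), sum(ob)))
  expect_false(any(tb & ob))
})

test_that("presence/absence specificity is strict and single-tissue", {
  tissues <- c("head", "testis", "ovary")
  sig <- matrix(10, 3, 3, dimnames = list(paste0("g", 1:3), tissues))
  calls <- array(FALSE, c(3, 3, 4))
  calls[1, 2, ] <- TRUE                    # g1: testis 4/4, absent elsewhere
  calls[2, 2, ] <- TRUE; calls[2, 1, 1] <- TRUE   # g2: 1/4 in head too
  calls[3, 2, 1:3] <- TRUE                 # g3: only 3/4 in testis
  panel <- make_panel(sig, calls = calls)
  pa <- presence_absence_specific(panel)
  expect_equal(pa$gene_id, "g1")
  expect_equal(pa$tissue, "testis")
})

test_that("presence/absence classification equals the brute-force rule", {
  set.seed(77)
  tissues <- c("head", "midgut", "testis", "ovary")
  n <- 60
  sig <- matrix(10, n, 4, dimnames = list(sprintf("g%02d", 1:n), tissues))
  calls <- array(runif(n * 4 * 4) < 0.45, c(n, 4, 4))
  panel <- make_panel(sig, calls = calls)
  pa <- presence_absence_specific(panel)
  for (g in seq_len(n)) {
    hits <- character(0)
    for (ti in 1:4) {
      if (all(calls[g, ti, ]) &&
          all(!calls[g, setdiff(1:4, ti), ])) hits <- c(hits, tissues[ti])
    }
    got <- pa$tissue[pa$gene_id == sprintf("g%02d", g)]
    expect_equal(sort(got), sort(hits))
  }
  # each gene maps to at most one tissue
  expect_false(anyDuplicated(pa$gene_id) > 0)
})

test_that("the age filter keeps the requested class and flags gaps", {
  ann <- gene_annotation(paste0("g", 1:4), c("X", "2L", "3R", "4"),
                         age_class = c("old", "young", "old", NA))
  expect_warning(
    kept <- suppressMessages(filter_by_age(paste0("g", 1:4), ann)),
    "without age class")
  expect_equal(kept, c("g1", "g3"))
  expect_equal(suppressMessages(filter_by_age(character(0), ann)),
               character(0))
  df <- data.frame(gene_id = paste0("g", 1:3), tissue = "head",
                   min_ratio = NA_real_)
  expect_equal(suppressMessages(filter_by_age(df, ann))$gene_id,
               c("g1", "g3"))
})
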