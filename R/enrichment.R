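#' 2x2 contingency test with the sample-size selection rule
#'
#' Tests association in a 2x2 table `(a, b; c, d)` using the rule applied
#' throughout the enrichment analyses: a Fisher exact test when the total
#' sample size `N = a+b+c+d` is smaller than 5000 cases, otherwise a
#' chi-square test with Yates continuity correction.
#'
#' The two-sided Fisher p-value follows the probability-mass convention
#' of R's `fisher.test`: the sum, over all tables with the observed
#' margins, of hypergeometric probabilities not exceeding that of the
#' observed table (with a `1e-7` relative slack for ties). The Yates
#' statistic is the closed form
#' `N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 df.
#' A zero row or column margin makes the table degenerate: `p = 1` with a
#' flag. The odds ratio is the sample cross-product ratio `ad / bc`.
#'
#' @param a,b,c,d non-negative integer counts; `a` and `b` share the
#'   first row (e.g. X-linked / autosomal genes in the set), `c` and `d`
#'   the second (same split in the rest of the genome).
#' @param cutoff total-sample-size boundary between the two tests.
#' @return an object of class `"contingency_result"`: `counts` (2x2
#'   matrix), `total_n`, `test_used` (`"fisher"` or `"chisq_yates"`),
#'   `statistic` (Yates chi-square, `NA` for Fisher), `p_value`,
#'   `odds_ratio`, `significance` (`***`, `**`, `*`, `ns`), `degenerate`.
#' @examples
#' contingency_test(1, 1, 1, 1)      # balanced: Fisher p = 1
#' contingency_test(10, 90, 1000, 4000)
#' @export
contingency_test <- function(a, b, c, d, cutoff = 5000) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  # double arithmetic: margin products overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(set = c("in", "out"),
                                class = c("first", "second")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- (a * d) / (b * c)
  if (degenerate) {
    res <- list(test_used = if (n < cutoff) "fisher" else "chisq_yates",
                statistic = NA_real_, p_value = 1)
  } else if (n < cutoff) {
    res <- list(test_used = "fisher", statistic = NA_real_,
                p_value = .fisher_p(a, b, c, d))
  } else {
    m <- (a + b) * (c + d) * (a + c) * (b + d)
    stat <- n * max(0, abs(a * d - b * c) - n / 2)^2 / m
    res <- list(test_used = "chisq_yates", statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  structure(
    c(list(counts = tab, total_n = n, odds_ratio = or,
           significance = significance_stars(res$p_value),
           degenerate = degenerate), res),
    class = "contingency_result"
  )
}

# two-sided Fisher exact p for a 2x2 table, probability-mass convention
.fisher_p <- function(a, b, c, d) {
  m <- a + b            # first-row margin (draws)
  k <- a + c            # first-column margin (white balls)
  n2 <- b + d
  support <- max(0, m - n2):min(m, k)
  probs <- stats::dhyper(support, k, n2, m)
  p_obs <- stats::dhyper(a, k, n2, m)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Map a p-value to the study's significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise.
#'
#' @param p p-value(s).
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 contingency test (", x$test_used, ", N = ", x$total_n, ")\n",
      sep = "")
  print(x$counts)
  cat(sprintf("  odds ratio = %.3f   P = %.4g  %s%s\n", x$odds_ratio,
              x$p_value, x$significance,
              if (x$degenerate) "  (zero margin; degenerate)" else ""))
  invisible(x)
}

#' Normalized X-linked frequency of a gene set
#'
#' The fraction of a gene set on the X chromosome divided by the
#' genome-wide X fraction: 1.0 means the set is chromosomally random, and
#' values below/above 1 indicate X depletion/enrichment. The standard
#' error of the set's X fraction (binomial, with the genome fraction
#' treated as fixed) is divided by the genome fraction, giving bands at
#' one SE (roughly 70% coverage) and two SEs (roughly 95%).
#'
#' @param gene_set character vector of gene ids (non-empty).
#' @param annot annotation `data.frame`; the genome background is every
#'   annotated gene with `linkage_class` `"X"` or `"autosome"`.
#' @param universe optional character vector restricting the genome
#'   background (e.g. after removing sex-biased genes).
#' @return an object of class `"normalized_frequency"`: `n`, `x_in_set`,
#'   `genome_x_fraction`, `set_x_fraction`, `normalized_freq`, `se_norm`,
#'   `band70`, `band95`.
#' @examples
#' ann <- gene_annotation(sprintf("g%d", 1:700),
#'                        rep(c("X", "2L", "2R", "3L", "3R", "2L", "3R"), 100))
#' normalized_x_frequency(sprintf("g%d", 1:70), ann)
#' @export
normalized_x_frequency <- function(gene_set, annot, universe = NULL) {
  bg <- annot[annot$linkage_class %in% c("X", "autosome"), ]
  if (!is.null(universe)) bg <- bg[bg$gene_id %in% universe, ]
  if (!nrow(bg)) stop("empty genome background")
  p0 <- mean(bg$linkage_class == "X")
  lc <- bg$linkage_class[match(gene_set, bg$gene_id)]
  if (anyNA(lc)) {
    warning(sum(is.na(lc)), " set gene(s) outside background dropped")
    lc <- lc[!is.na(lc)]
  }
  n <- length(lc)
  if (n == 0) stop("empty gene set")
  k <- sum(lc == "X")
  phat <- k / n
  f <- phat / p0
  se <- sqrt(phat * (1 - phat) / n) / p0
  structure(
    list(n = n, x_in_set = k, genome_x_fraction = p0,
         set_x_fraction = phat, normalized_freq = f, se_norm = se,
         band70 = c(lower = f - se, upper = f + se),
         band95 = c(lower = f - 2 * se, upper = f + 2 * se)),
    class = "normalized_frequency"
  )
}

#' @export
print.normalized_frequency <- function(x, ...) {
  cat(sprintf(
    "Normalized X frequency: %.3f (set %d/%d X-linked; genome fraction %.3f)\n",
    x$normalized_freq, x$x_in_set, x$n, x$genome_x_fraction))
  cat(sprintf("  70%% band (1 SE): [%.3f, %.3f]   95%% band (2 SE): [%.3f, %.3f]\n",
              x$band70[1], x$band70[2], x$band95[1], x$band95[2]))
  invisible(x)
}

# set-vs-rest 2x2 on linkage: (X in set, A in set; X rest, A rest)
.linkage_table <- function(set_ids, bg) {
  in_set <- bg$gene_id %in% set_ids
  is_x <- bg$linkage_class == "X"
  c(a = sum(in_set & is_x), b = sum(in_set & !is_x),
    c = sum(!in_set & is_x), d = sum(!in_set & !is_x))
}

#' Chromosomal enrichment of tissue-specific gene sets
#'
#' For each tissue and fold threshold, tests whether the tissue-specific
#' set is depleted or enriched on the X chromosome relative to the rest
#' of the genome: a 2x2 contingency test of (X, autosome) x (in set,
#' rest of genome) via [contingency_test], plus the normalized X
#' frequency with SE bands via [normalized_x_frequency].
#'
#' With `exclude_sex_biased = TRUE`, genes classified testis- or
#' ovary-biased in `sex_calls` are removed from both the set and the
#' genome background before testing. This is the confound-removal step:
#' tissue-specific sets are generally contaminated with testis-biased
#' genes, which are themselves under-represented on the X, so an apparent
#' X depletion of a somatic tissue's specific genes can vanish once
#' sex-biased genes are excluded.
#'
#' @param calls a `"specificity_calls"` data frame (from
#'   [classify_specific] or [presence_absence_specific]).
#' @param annot annotation `data.frame`; the annotated genes with
#'   included linkage define the genome.
#' @param thresholds fold thresholds to report; ignored for call-based
#'   specificity (one row per tissue, threshold `NA`).
#' @param exclude_sex_biased remove sex-biased genes from set and
#'   background first.
#' @param sex_calls a `"sexbias_calls"` data frame; required when
#'   `exclude_sex_biased = TRUE`.
#' @param p_adjust add a Benjamini-Hochberg column (`p_bh`) across the
#'   reported rows; raw p-values and stars are reported either way.
#' @return a `data.frame`, one row per tissue x threshold: set size `n`,
#'   `x_in_set`, `normalized_freq`, `se_norm`, band bounds, `test_used`,
#'   `odds_ratio`, `p_value`, `significance`. Empty post-filter sets give
#'   a row with `n = 0` and no test.
#' @export
chromosomal_enrichment <- function(calls, annot, thresholds = c(2, 5, 10),
                                   exclude_sex_biased = FALSE,
                                   sex_calls = NULL, p_adjust = FALSE) {
  bg <- annot[annot$linkage_class %in% c("X", "autosome"), ]
  if (exclude_sex_biased) {
    if (is.null(sex_calls))
      stop("sex_calls required when exclude_sex_biased = TRUE")
    biased <- sex_calls$gene_id[sex_calls$class != "unbiased"]
    bg <- bg[!bg$gene_id %in% biased, ]
    calls <- calls[!calls$gene_id %in% biased, , drop = FALSE]
  }
  ratio_based <- !all(is.na(calls$min_ratio))
  thr_list <- if (ratio_based) sort(thresholds) else NA_real_
  rows <- list()
  for (tis in sort(unique(calls$tissue))) {
    for (thr in thr_list) {
      sel <- calls$tissue == tis
      if (!is.na(thr)) sel <- sel & calls$min_ratio > thr
      set_ids <- intersect(calls$gene_id[sel], bg$gene_id)
      if (!length(set_ids)) {
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tis, threshold = thr, n = 0L, x_in_set = NA_integer_,
          normalized_freq = NA_real_, se_norm = NA_real_,
          band70_lower = NA_real_, band70_upper = NA_real_,
          band95_lower = NA_real_, band95_upper = NA_real_,
          test_used = NA_character_, odds_ratio = NA_real_,
          p_value = NA_real_, significance = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      nf <- normalized_x_frequency(set_ids, bg)
      tb <- .linkage_table(set_ids, bg)
      ct <- contingency_test(tb["a"], tb["b"], tb["c"], tb["d"])
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tis, threshold = thr, n = nf$n, x_in_set = nf$x_in_set,
        normalized_freq = nf$normalized_freq, se_norm = nf$se_norm,
        band70_lower = nf$band70[1], band70_upper = nf$band70[2],
        band95_lower = nf$band95[1], band95_upper = nf$band95[2],
        test_used = ct$test_used, odds_ratio = ct$odds_ratio,
        p_value = ct$p_value, significance = ct$significance,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "exclude_sex_biased") <- exclude_sex_biased
  out
}

#' Testis-bias enrichment within tissue-specific sets
#'
#' Tests, per tissue and threshold, whether a tissue-specific set holds
#' an excess of testis-biased genes relative to the rest of the genome.
#' The default contrast compares testis-biased against all non-testis-
#' biased genes; `contrast = "ovary-biased"` restricts the second margin
#' to ovary-biased genes.
#'
#' @param calls a `"specificity_calls"` data frame.
#' @param sex_calls a `"sexbias_calls"` data frame covering the genome.
#' @param annot annotation `data.frame` defining the genome (linkage
#'   filter applied as elsewhere).
#' @param thresholds fold thresholds; ignored for call-based calls.
#' @param contrast `"non-testis-biased"` (default) or `"ovary-biased"`.
#' @return a `data.frame`, one row per tissue x threshold, with the 2x2
#'   counts and [contingency_test] results.
#' @export
testis_bias_enrichment <- function(calls, sex_calls, annot,
                                   thresholds = c(2, 5, 10),
                                   contrast = c("non-testis-biased",
                                                "ovary-biased")) {
  contrast <- match.arg(contrast)
  bg <- annot[annot$linkage_class %in% c("X", "autosome"), ]
  cls <- sex_calls$class[match(bg$gene_id, sex_calls$gene_id)]
  keep <- !is.na(cls)
  if (contrast == "ovary-biased") keep <- keep & cls != "unbiased"
  bg <- bg[keep, ]
  is_tb <- cls[keep] == "testis-biased"
  ratio_based <- !all(is.na(calls$min_ratio))
  thr_list <- if (ratio_based) sort(thresholds) else NA_real_
  rows <- list()
  for (tis in sort(unique(calls$tissue))) {
    for (thr in thr_list) {
      sel <- calls$tissue == tis
      if (!is.na(thr)) sel <- sel & calls$min_ratio > thr
      in_set <- bg$gene_id %in% calls$gene_id[sel]
      a <- sum(in_set & is_tb); b <- sum(in_set & !is_tb)
      cc <- sum(!in_set & is_tb); dd <- sum(!in_set & !is_tb)
      ct <- contingency_test(a, b, cc, dd)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tis, threshold = thr, n = a + b,
        testis_biased_in_set = a, other_in_set = b,
        testis_biased_rest = cc, other_rest = dd,
        test_used = ct$test_used, odds_ratio = ct$odds_ratio,
        p_value = ct$p_value, significance = ct$significance,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  out
}
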