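#' Minimal tissue-to-tissue signal ratio
#'
#' The specificity score of one gene for a focal tissue: the minimum over
#' all other panel tissues of the focal signal divided by that tissue's
#' signal. A gene is tissue-specific at fold `t` when this minimum
#' exceeds `t`, i.e. the focal signal is at least `t`-fold above every
#' other tissue.
#'
#' Denominator signals below `floor` are raised to `floor` before
#' division (atlas signals are non-negative means, and a zero denominator
#' would otherwise make any expressed gene infinitely specific). A focal
#' signal of zero or less scores 0, i.e. never specific.
#'
#' @param signals named numeric vector of one gene's mean signals,
#'   including the focal tissue.
#' @param focal_tissue name of the focal tissue.
#' @param floor denominator floor in signal units.
#' @return the minimal ratio (single number).
#' @examples
#' # the classic midgut-specific pattern: 629 vs 196 and 34
#' min_tissue_ratio(c(midgut = 629, testis = 196, ovary = 34), "midgut")
#' @export
min_tissue_ratio <- function(signals, focal_tissue, floor = 1) {
  if (!focal_tissue %in% names(signals))
    stop("focal tissue '", focal_tissue, "' not in panel")
  focal <- signals[[focal_tissue]]
  others <- signals[setdiff(names(signals), focal_tissue)]
  if (!length(others)) stop("need at least one non-focal tissue")
  if (focal <= 0) return(0)
  min(focal / pmax(others, floor))
}

#' Classify tissue-specific genes by signal ratio
#'
#' Scores every gene against every focal tissue by the minimal
#' tissue-to-tissue signal ratio and reports the genes exceeding the
#' smallest threshold, together with the largest threshold class each
#' reaches. The candidate sets are nested by construction:
#' specific at >10 implies >5 implies >2.
#'
#' By default the two sex tissues (testis, ovary) are excluded from the
#' denominator panel when scoring other tissues, so a gene may be, say,
#' midgut-specific while still expressed more in testis than in ovary;
#' this is what lets tissue-specific sets become contaminated with
#' testis-biased genes, the confound the enrichment layer removes. Set
#' `sex_tissues_in_panel = TRUE` to keep them in every denominator. The
#' choice is recorded in the result's `"config"` attribute.
#'
#' @param panel a [tissue_panel].
#' @param thresholds fold thresholds, default `c(2, 5, 10)`.
#' @param sex_tissues_in_panel keep testis/ovary in the denominator panel
#'   for non-sex focal tissues.
#' @param sex_tissues names of the sex tissues present in the panel.
#' @param floor denominator floor (see [min_tissue_ratio]).
#' @param focal_tissues tissues to score; defaults to all panel tissues.
#' @return a `data.frame` of class `"specificity_calls"` with columns
#'   `gene_id`, `tissue`, `min_ratio`, `threshold_class` (ordered factor
#'   over the thresholds); one row per (gene, tissue) exceeding the
#'   smallest threshold.
#' @export
classify_specific <- function(panel, thresholds = c(2, 5, 10),
                              sex_tissues_in_panel = FALSE,
                              sex_tissues = c("testis", "ovary"),
                              floor = 1, focal_tissues = panel$tissues) {
  stopifnot(inherits(panel, "tissue_panel"))
  thresholds <- sort(thresholds)
  sig <- panel$signals
  rows <- lapply(focal_tissues, function(ft) {
    denom_tissues <- setdiff(panel$tissues, ft)
    if (!sex_tissues_in_panel)
      denom_tissues <- setdiff(denom_tissues, setdiff(sex_tissues, ft))
    if (!length(denom_tissues))
      stop("no denominator tissues left for focal tissue '", ft, "'")
    denom <- pmax(sig[, denom_tissues, drop = FALSE], floor)
    ratio <- apply(sig[, ft] / denom, 1, min)
    ratio[sig[, ft] <= 0] <- 0
    hit <- ratio > thresholds[1]
    if (!any(hit)) return(NULL)
    data.frame(gene_id = panel$gene_ids[hit], tissue = ft,
               min_ratio = ratio[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), tissue = character(0),
                      min_ratio = numeric(0), stringsAsFactors = FALSE)
  lab <- paste0(">", thresholds)
  out$threshold_class <- factor(
    lab[findInterval(out$min_ratio, thresholds,
                     left.open = TRUE)],
    levels = lab, ordered = TRUE)
  rownames(out) <- NULL
  attr(out, "config") <- list(thresholds = thresholds,
                              sex_tissues_in_panel = sex_tissues_in_panel,
                              sex_tissues = sex_tissues, floor = floor)
  class(out) <- c("specificity_calls", "data.frame")
  out
}

#' Testis/ovary sex-bias classification
#'
#' A gene is testis-biased when its testis-to-ovary signal ratio exceeds
#' the fold threshold, ovary-biased when the ovary-to-testis ratio does,
#' and unbiased otherwise; the three classes are mutually exclusive for
#' any threshold >= 1. When both signals are zero the ratio is undefined
#' and the gene is classed unbiased with `undefined_ratio = TRUE`.
#'
#' @param testis_signal,ovary_signal numeric vectors of mean signals
#'   (non-negative), recycled to common length.
#' @param threshold fold cutoff; the study's default is 2 (5 and 10 are
#'   used for stricter sets).
#' @param gene_id optional gene keys for the output.
#' @return a `data.frame` of class `"sexbias_calls"` with columns
#'   `gene_id`, `testis_ovary_ratio`, `class` (factor: `testis-biased`,
#'   `ovary-biased`, `unbiased`), `undefined_ratio`.
#' @examples
#' sex_bias(196, 34)   # the CG7194-like pattern: testis-biased
#' @export
sex_bias <- function(testis_signal, ovary_signal, threshold = 2,
                     gene_id = NULL) {
  n <- max(length(testis_signal), length(ovary_signal))
  t_ <- rep_len(as.numeric(testis_signal), n)
  o_ <- rep_len(as.numeric(ovary_signal), n)
  if (any(t_ < 0, na.rm = TRUE) || any(o_ < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  if (threshold < 1) stop("threshold must be >= 1")
  ratio <- t_ / o_                      # Inf when ovary 0, NaN when both 0
  undef <- t_ == 0 & o_ == 0
  cls <- rep("unbiased", n)
  cls[!undef & ratio > threshold] <- "testis-biased"
  cls[!undef & o_ / t_ > threshold] <- "ovary-biased"
  out <- data.frame(
    gene_id = if (is.null(gene_id)) sprintf("gene%d", seq_len(n))
              else as.character(gene_id),
    testis_ovary_ratio = ratio,
    class = factor(cls, levels = c("testis-biased", "ovary-biased",
                                   "unbiased")),
    undefined_ratio = undef,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sexbias_calls", "data.frame")
  out
}

#' Sex-bias classification for a whole panel
#'
#' @param panel a [tissue_panel] containing `testis` and `ovary` columns.
#' @param threshold fold cutoff (see [sex_bias]).
#' @return a `"sexbias_calls"` data frame keyed by the panel's gene ids.
#' @export
sex_bias_panel <- function(panel, threshold = 2) {
  stopifnot(inherits(panel, "tissue_panel"))
  miss <- setdiff(c("testis", "ovary"), panel$tissues)
  if (length(miss))
    stop("panel lacks tissue(s): ", paste(miss, collapse = ", "))
  sex_bias(panel$signals[, "testis"], panel$signals[, "ovary"],
           threshold = threshold, gene_id = panel$gene_ids)
}

#' Tissue specificity from present/absent calls
#'
#' The strict call-based definition: a gene is specific to tissue T when
#' it is called present in all four replicate arrays of T and absent in
#' every replicate of every other tissue. Each gene can satisfy this for
#' at most one tissue. Genes with missing calls are skipped with a
#' warning.
#'
#' @param panel a [tissue_panel] with calls.
#' @return a `data.frame` of class `"specificity_calls"` with columns
#'   `gene_id`, `tissue` (and `min_ratio = NA`, for interface parity with
#'   [classify_specific]).
#' @export
presence_absence_specific <- function(panel) {
  stopifnot(inherits(panel, "tissue_panel"))
  if (is.null(panel$calls)) stop("panel has no present/absent calls")
  calls <- panel$calls
  bad <- apply(is.na(calls), 1, any)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing calls skipped")
    calls <- calls[!bad, , , drop = FALSE]
  }
  n_present <- apply(calls, c(1, 2), sum)      # genes x tissues, 0..4
  all_present <- n_present == 4
  # specific: exactly one tissue fully present, zero calls in all others
  full <- rowSums(all_present)
  any_other <- rowSums(n_present > 0)
  hit <- full == 1 & any_other == 1
  tissue <- panel$tissues[apply(all_present[hit, , drop = FALSE], 1,
                                which.max)]
  out <- data.frame(
    gene_id = rownames(calls)[hit],
    tissue = if (length(tissue)) tissue else character(0),
    min_ratio = rep(NA_real_, sum(hit)),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- list(method = "presence_absence")
  class(out) <- c("specificity_calls", "data.frame")
  out
}

#' Filter a gene set by gene age class
#'
#' Keeps only genes of the requested age class; the study restricts
#' call-based specificity analyses to old genes (origin predating the
#' Sophophora/Drosophila subgenus split) because young X-linked genes are
#' enriched for testis-biased expression and would confound chromosomal
#' contrasts. Genes without an age class are excluded with a warning.
#'
#' @param gene_set character vector of gene ids, or a
#'   `"specificity_calls"` data frame (filtered on its `gene_id` column).
#' @param annot annotation `data.frame` with `age_class`.
#' @param keep `"old"` (default) or `"young"`.
#' @return the filtered set, same shape as the input.
#' @export
filter_by_age <- function(gene_set, annot, keep = "old") {
  ids <- if (is.data.frame(gene_set)) gene_set$gene_id else gene_set
  age <- annot$age_class[match(ids, annot$gene_id)]
  if (anyNA(age) && length(ids))
    warning(sum(is.na(age)), " gene(s) without age class excluded")
  sel <- !is.na(age) & age == keep
  message("age filter (keep ", keep, "): ", sum(sel), " of ", length(ids),
          " gene(s) kept")
  if (is.data.frame(gene_set)) gene_set[sel, , drop = FALSE]
  else ids[sel]
}
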