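#' One-way random-effects variance decomposition of a stage
#'
#' Partitions the variability of a gene x replicate matrix into an
#' among-gene component (biological signal) and a within-gene,
#' among-replicate component (experimental error), by the sum-of-squares
#' method with genes as the random grouping factor:
#'
#' \deqn{SS_{within} = \sum_g \sum_r (y_{gr} - \bar y_g)^2, \quad
#'       SS_{among} = \sum_g n_g (\bar y_g - \bar y)^2}
#'
#' with mean squares `MS_within = SS_within / (N - G)` and
#' `MS_among = SS_among / (G - 1)`. The error variance component is
#' `MS_within`; the among-gene component is
#' `max(0, (MS_among - MS_within) / n0)`, where `n0` is the effective
#' group size (Sokal-Rohlf correction
#' `n0 = (N - sum(n_g^2)/N) / (G - 1)`, equal to the replicate count for
#' balanced data). The experimental-error fraction is
#' `100 * var_within / (var_within + var_among)` percent.
#'
#' @param stage a [stage_expression] object or numeric matrix (genes x
#'   replicates). `NA` cells are allowed in a bare matrix and produce an
#'   unbalanced decomposition; genes need at least one observation and the
#'   design at least one gene with two.
#' @return an object of class `"variance_components"` with fields
#'   `ss_among`, `ss_within`, `ms_among`, `ms_within`, `var_among`,
#'   `var_within`, `error_fraction` (percent), `n_genes`, `n_replicates`,
#'   `n0`, `stage`.
#' @examples
#' m <- rbind(g1 = c(1, 1), g2 = c(3, 3))
#' variance_components(m)$error_fraction  # no replicate noise -> 0
#' @export
variance_components <- function(stage) {
  label <- if (inherits(stage, "stage_expression")) stage$stage else NA_character_
  A <- if (inherits(stage, "stage_expression")) stage$A else as.matrix(stage)
  if (ncol(A) < 2) stop("within-gene sum of squares undefined for a single replicate")
  if (nrow(A) < 2) stop("need at least 2 genes")
  obs <- !is.na(A)
  n_g <- rowSums(obs)
  if (any(n_g == 0)) stop("gene(s) with no observations")
  N <- sum(n_g)
  G <- nrow(A)
  if (N - G < 1) stop("no within-gene degrees of freedom")
  gmean <- rowMeans(A, na.rm = TRUE)
  grand <- sum(A, na.rm = TRUE) / N
  ss_within <- sum((A - gmean)^2, na.rm = TRUE)
  ss_among <- sum(n_g * (gmean - grand)^2)
  ms_within <- ss_within / (N - G)
  ms_among <- ss_among / (G - 1)
  n0 <- (N - sum(n_g^2) / N) / (G - 1)
  var_within <- ms_within
  var_among <- max(0, (ms_among - ms_within) / n0)
  structure(
    list(stage = label,
         ss_among = ss_among, ss_within = ss_within,
         ms_among = ms_among, ms_within = ms_within,
         var_among = var_among, var_within = var_within,
         error_fraction = 100 * var_within / (var_within + var_among),
         n_genes = G, n_replicates = ncol(A), n0 = n0),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, digits = 3, ...) {
  cat("Variance decomposition",
      if (!is.na(x$stage)) paste0("(stage ", x$stage, ")"), "\n")
  cat(sprintf("  genes: %d   replicates: %d (n0 = %.3f)\n",
              x$n_genes, x$n_replicates, x$n0))
  cat(sprintf("  SS among: %.*g   SS within: %.*g\n",
              digits + 2, x$ss_among, digits + 2, x$ss_within))
  cat(sprintf("  var among genes: %.*g   var within replicates: %.*g\n",
              digits, x$var_among, digits, x$var_within))
  cat(sprintf("  experimental error: %.1f%% of total variance\n",
              x$error_fraction))
  invisible(x)
}

#' Variance decomposition for every stage
#'
#' @param stages a collection accepted by [correlation_summary()].
#' @return a `data.frame`, one row per stage, with the
#'   [variance_components] fields.
#' @export
variance_components_table <- function(stages) {
  stages <- .as_stage_list(stages)
  rows <- lapply(stages, function(s) {
    v <- variance_components(s)
    data.frame(stage = v$stage, n_genes = v$n_genes,
               n_replicates = v$n_replicates,
               ss_among = v$ss_among, ss_within = v$ss_within,
               var_among = v$var_among, var_within = v$var_within,
               error_fraction = v$error_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene standard deviations across replicates
#'
#' Sample SD (denominator `n - 1`) of each gene's replicate measurements;
#' the distribution of these SDs is the within-gene half of the SD-ratio
#' diagnostic.
#'
#' @param stage a [stage_expression] object or matrix.
#' @return named numeric vector of per-gene SDs.
#' @export
within_gene_sds <- function(stage) {
  A <- if (inherits(stage, "stage_expression")) stage$A else as.matrix(stage)
  if (ncol(A) < 2) stop("SD across replicates needs at least 2 replicates")
  apply(A, 1, stats::sd, na.rm = TRUE)
}

#' Among-gene vs within-replicate SD ratio
#'
#' Compares the standard deviation among genes (SD across genes of the
#' per-gene replicate means) to the mean of the per-gene SDs across
#' replicates. A ratio near 1 means gene-to-gene signal barely exceeds
#' measurement noise; two-fold expression differences (one log2 unit)
#' between chromosome classes are then difficult to detect from replicate
#' averages.
#'
#' Reported pooled over all genes and, when an annotation is supplied,
#' per linkage class (X vs autosome). Classes with fewer than 2 genes are
#' skipped with a warning. When the mean within-gene SD is zero the ratio
#' is infinite and flagged via the `degenerate` column.
#'
#' @param stage a [stage_expression] object.
#' @param annot optional annotation `data.frame` (see [gene_annotation]).
#' @return a `data.frame` of class `"sd_ratio"` with columns `stage`,
#'   `class` (`pooled`, `X`, `autosome`), `n_genes`, `among_gene_sd`,
#'   `mean_within_sd`, `ratio`, `degenerate`.
#' @export
sd_ratio <- function(stage, annot = NULL) {
  A <- if (inherits(stage, "stage_expression")) stage$A else as.matrix(stage)
  label <- if (inherits(stage, "stage_expression")) stage$stage else NA_character_
  means <- rowMeans(A, na.rm = TRUE)
  sds <- within_gene_sds(A)
  groups <- list(pooled = seq_along(means))
  if (!is.null(annot)) {
    lc <- annot$linkage_class[match(rownames(A), annot$gene_id)]
    for (cl in c("X", "autosome")) {
      ix <- which(!is.na(lc) & lc == cl)
      if (length(ix) < 2) {
        warning("linkage class '", cl, "' has <2 genes; skipped")
      } else groups[[cl]] <- ix
    }
  }
  rows <- lapply(names(groups), function(g) {
    ix <- groups[[g]]
    among <- stats::sd(means[ix])
    within <- mean(sds[ix])
    data.frame(stage = label, class = g, n_genes = length(ix),
               among_gene_sd = among, mean_within_sd = within,
               ratio = if (within > 0) among / within else Inf,
               degenerate = within == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sd_ratio", "data.frame")
  out
}
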