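#' Per-gene mean expression across replicates
#'
#' Each gene's expression value for chromosome-level contrasts is the
#' arithmetic mean of its replicate A-values.
#'
#' @param stage a [stage_expression] object or matrix.
#' @return named numeric vector of per-gene means.
#' @export
gene_means <- function(stage) {
  A <- if (inherits(stage, "stage_expression")) stage$A else as.matrix(stage)
  rowMeans(A, na.rm = TRUE)
}

#' X-versus-autosome expression contrast
#'
#' Two-sample t-test of equality of mean expression between X-linked and
#' autosomal genes, on per-gene replicate means. Under meiotic sex
#' chromosome inactivation the X class is expected to fall below the
#' autosomes as meiotic cells accumulate in later developmental stages.
#'
#' @param means named per-gene mean vector (names = gene ids), or a
#'   [stage_expression] object (means computed via [gene_means]).
#' @param annot annotation `data.frame`; genes with `linkage_class`
#'   `"excluded"` or missing from the annotation are dropped.
#' @param var_equal `FALSE` (default) for the Welch unequal-variance test,
#'   `TRUE` for Student's pooled-variance test.
#' @param alternative passed to [stats::t.test()]; two-sided by default.
#' @param stage_label optional label carried into the result.
#' @return an object of class `"chromosome_comparison"` with fields
#'   `stage`, `mean_X`, `mean_A`, `n_X`, `n_A`, `t_statistic`, `df`,
#'   `p_value`, `direction` (sign of `mean_X - mean_A`), `flagged`
#'   (degenerate variance).
#' @export
x_autosome_test <- function(means, annot, var_equal = FALSE,
                            alternative = "two.sided", stage_label = NULL) {
  if (inherits(means, "stage_expression")) {
    if (is.null(stage_label)) stage_label <- means$stage
    means <- gene_means(means)
  }
  if (is.null(names(means))) stop("means must be named by gene id")
  lc <- annot$linkage_class[match(names(means), annot$gene_id)]
  x <- means[!is.na(lc) & lc == "X"]
  a <- means[!is.na(lc) & lc == "autosome"]
  if (length(x) < 2 || length(a) < 2)
    stop("need at least 2 genes in each linkage class")
  flagged <- (stats::sd(x) == 0 && length(x) == 2) ||
             (stats::sd(a) == 0 && length(a) == 2)
  if (stats::sd(x) == 0 && stats::sd(a) == 0) {
    # t.test errors on doubly-constant data; report the degenerate answer
    tt <- list(statistic = c(t = if (mean(x) == mean(a)) 0 else Inf *
                               sign(mean(x) - mean(a))),
               parameter = c(df = length(x) + length(a) - 2),
               p.value = if (mean(x) == mean(a)) 1 else 0)
    flagged <- TRUE
  } else {
    tt <- stats::t.test(x, a, var.equal = var_equal,
                        alternative = alternative)
  }
  structure(
    list(stage = if (is.null(stage_label)) NA_character_ else stage_label,
         mean_X = mean(x), mean_A = mean(a),
         n_X = length(x), n_A = length(a),
         t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         direction = sign(mean(x) - mean(a)),
         var_equal = var_equal, alternative = alternative,
         flagged = flagged),
    class = "chromosome_comparison"
  )
}

#' @export
print.chromosome_comparison <- function(x, ...) {
  cat("X vs autosome expression",
      if (!is.na(x$stage)) paste0("(stage ", x$stage, ")"), "\n")
  cat(sprintf("  mean X: %.4f (n = %d)   mean autosome: %.4f (n = %d)\n",
              x$mean_X, x$n_X, x$mean_A, x$n_A))
  cat(sprintf("  %s t = %.3f, df = %.1f, P = %.3g  [X %s autosomes]%s\n",
              if (x$var_equal) "Student" else "Welch",
              x$t_statistic, x$df, x$p_value,
              if (x$direction < 0) "below" else if (x$direction > 0)
                "above" else "equal to",
              if (x$flagged) "  (degenerate variance, flagged)" else ""))
  invisible(x)
}

#' X-versus-autosome contrasts for every stage
#'
#' @param stages a collection accepted by [correlation_summary()].
#' @param annot annotation `data.frame`.
#' @param ... passed to [x_autosome_test()].
#' @return a `data.frame`, one row per stage.
#' @export
x_autosome_tests <- function(stages, annot, ...) {
  stages <- .as_stage_list(stages)
  rows <- lapply(stages, function(s) {
    r <- x_autosome_test(s, annot, ...)
    data.frame(stage = r$stage, mean_X = r$mean_X, mean_A = r$mean_A,
               n_X = r$n_X, n_A = r$n_A, t_statistic = r$t_statistic,
               p_value = r$p_value, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
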