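#' Pairwise replicate correlations within a stage
#'
#' Computes the Pearson product-moment correlation over genes for every
#' unordered pair of replicate columns. On log2 intensity data the
#' expected pairwise correlation is the intraclass ratio
#' `var_among / (var_among + var_within)`, which makes it a direct readout
#' of experimental error (see [variance_components]).
#'
#' Pairs involving a zero-variance (constant) replicate column have an
#' undefined correlation; they are dropped with a warning rather than set
#' to an arbitrary value.
#'
#' @param stage a [stage_expression] object (or bare matrix, genes x
#'   replicates).
#' @return named numeric vector, one entry per replicate pair
#'   (`C(n_replicates, 2)` entries when no column is constant).
#' @export
pairwise_correlations <- function(stage) {
  A <- if (inherits(stage, "stage_expression")) stage$A else as.matrix(stage)
  if (ncol(A) < 2) stop("need at least 2 replicate columns")
  if (nrow(A) < 3) stop("need at least 3 genes")
  sds <- apply(A, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant replicate column(s); their pairs dropped")
    A <- A[, !const, drop = FALSE]
    if (ncol(A) < 2) return(numeric(0))
  }
  cm <- stats::cor(A)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  out <- cm[upper.tri(cm)]
  names(out) <- paste0(colnames(A)[pairs[, "row"]], ":",
                       colnames(A)[pairs[, "col"]])
  out
}

#' Replicate-quality summary across stages
#'
#' Summarises the pairwise replicate correlations of each stage (min, Q1,
#' median, Q3, max) and pools them into an overall mean and global
#' minimum. A quality flag is raised when the pooled mean falls below
#' `threshold`; well-replicated array experiments typically show pairwise
#' correlations above 0.9, and the developing-testis data this package
#' targets averaged only about 0.7.
#'
#' @param stages a `stage_expression`, a list of them, or the result of
#'   [simulate_stage_set()].
#' @param threshold quality benchmark for the pooled mean correlation.
#' @return an object of class `"replicate_qc"`: per-stage quartile table,
#'   pooled mean (`overall_mean`), `global_min`, the per-stage correlation
#'   vectors, and the `low_quality` flag.
#' @export
correlation_summary <- function(stages, threshold = 0.9) {
  stages <- .as_stage_list(stages)
  cors <- lapply(stages, pairwise_correlations)
  qs <- t(vapply(cors, stats::quantile, numeric(5),
                 probs = c(0, 0.25, 0.5, 0.75, 1)))
  colnames(qs) <- c("min", "q1", "median", "q3", "max")
  per_stage <- data.frame(
    stage = vapply(stages, function(s) s$stage, character(1)),
    n_pairs = lengths(cors), qs,
    mean = vapply(cors, mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  pooled <- unlist(cors, use.names = FALSE)
  structure(
    list(per_stage = per_stage, correlations = cors,
         overall_mean = mean(pooled), global_min = min(pooled),
         threshold = threshold,
         low_quality = mean(pooled) < threshold),
    class = "replicate_qc"
  )
}

#' @export
print.replicate_qc <- function(x, digits = 3, ...) {
  cat("Replicate quality summary (", nrow(x$per_stage), " stage(s))\n",
      sep = "")
  print(cbind(x$per_stage[1:2],
              round(x$per_stage[-(1:2)], digits)), row.names = FALSE)
  cat(sprintf("Overall mean correlation: %.*f   global minimum: %.*f\n",
              digits, x$overall_mean, digits, x$global_min))
  if (x$low_quality)
    cat(sprintf(
      "FLAG: pooled mean below quality benchmark %.2f - high experimental error\n",
      x$threshold))
  invisible(x)
}

#' Box plot of per-stage replicate correlations
#'
#' @param x a `replicate_qc` object.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.replicate_qc <- function(x, ...) {
  graphics::boxplot(x$correlations, names = x$per_stage$stage,
                    ylab = "pairwise replicate correlation",
                    xlab = "developmental stage", ...)
  graphics::abline(h = x$overall_mean, col = "blue")
  graphics::abline(h = c(0.5, 1), lty = 2)
  invisible(x)
}

# normalise the stage-collection argument shared by several entry points
.as_stage_list <- function(stages) {
  if (inherits(stages, "stage_expression")) return(list(stages))
  if (inherits(stages, "stage_simulation")) return(stages$stages)
  if (is.list(stages) &&
      all(vapply(stages, inherits, logical(1), "stage_expression")))
    return(stages)
  stop("expected stage_expression object(s)")
}
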