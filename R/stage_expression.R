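#' Two-channel M/A transformation
#'
#' Converts normalized log2 red/green channel intensities into the
#' log-ratio and average-intensity coordinates used by all downstream
#' analyses: `M = R - G` (log fold change) and `A = (R + G) / 2` (average
#' log2 intensity). A missing value in either channel propagates to both
#' `M` and `A`; records with missing `A` are excluded from the statistical
#' analyses at load time.
#'
#' @param R,G numeric vectors of normalized log2 channel intensities;
#'   `NA` allowed.
#' @return a `data.frame` with columns `M` and `A`.
#' @seealso [ma_invert()] for the inverse transform.
#' @examples
#' ma_transform(R = c(5, 4, NA), G = c(5, 2, 3))
#' @export
ma_transform <- function(R, G) {
  for (ch in list(R = R, G = G)) {
    if (!is.numeric(ch)) {
      parsed <- suppressWarnings(as.numeric(ch))
      bad <- which(is.na(parsed) & !is.na(ch))
      stop("channel intensities must be numeric; offending row: ",
           if (length(bad)) bad[1] else "(non-numeric vector)")
    }
  }
  if (length(R) != length(G)) stop("R and G must have equal length")
  data.frame(M = R - G, A = (R + G) / 2)
}

#' Invert the M/A transformation
#'
#' Recovers the channel intensities: `R = A + M/2`, `G = A - M/2`.
#'
#' @param M log fold change.
#' @param A average log2 intensity.
#' @return a `data.frame` with columns `R` and `G`.
#' @export
ma_invert <- function(M, A) {
  data.frame(R = A + M / 2, G = A - M / 2)
}

#' Construct a stage expression set
#'
#' A stage expression set is the unit of the developmental analysis: a
#' gene x replicate matrix of A-values (average log2 intensities) for one
#' developmental stage. Rows with missing values are not allowed; the
#' loader drops them per stage before construction.
#'
#' @param A numeric matrix, genes in rows and replicates in columns.
#' @param stage stage label (see [STAGE_LABELS] for the canonical seven).
#' @param gene_ids row keys; defaults to `rownames(A)`.
#' @return an object of class `"stage_expression"`.
#' @export
stage_expression <- function(A, stage, gene_ids = rownames(A)) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (is.null(gene_ids)) stop("gene_ids required (or rownames on A)")
  if (length(gene_ids) != nrow(A))
    stop("gene_ids length does not match matrix rows")
  if (anyNA(A))
    stop("stage '", stage, "': missing A-values must be dropped before ",
         "construction (see read_stage_expression)")
  rownames(A) <- as.character(gene_ids)
  if (is.null(colnames(A)))
    colnames(A) <- sprintf("rep%02d", seq_len(ncol(A)))
  structure(
    list(stage = as.character(stage), A = A,
         gene_ids = rownames(A), n_replicates = ncol(A)),
    class = "stage_expression"
  )
}

#' @export
print.stage_expression <- function(x, ...) {
  cat("Stage expression set: stage", x$stage, "-",
      nrow(x$A), "genes x", x$n_replicates, "replicates\n")
  cat("A-value range:", sprintf("%.2f .. %.2f", min(x$A), max(x$A)), "\n")
  invisible(x)
}

#' @export
dim.stage_expression <- function(x) dim(x$A)

#' Read stage expression sets from a delimited table
#'
#' The canonical dialect is one row per gene per stage:
#' `gene_id`, `stage`, `rep01` ... `repNN` (A-values, log2). One
#' `stage_expression` object is built per stage; within a stage, any row
#' with a missing A-value is dropped (missingness is stage-wise, so a gene
#' dropped in one stage can remain in another). Dropped-row counts are
#' reported via `message()`.
#'
#' @param path file path.
#' @param annot optional annotation `data.frame`; when supplied, the gene
#'   keys must overlap it and genes absent from it are flagged (kept, with
#'   a message).
#' @param stages allowed stage labels; rows with other labels are a
#'   configuration error. `NULL` accepts any label.
#' @param sep field separator.
#' @return a named list of `stage_expression` objects, in order of first
#'   appearance.
#' @export
read_stage_expression <- function(path, annot = NULL, stages = STAGE_LABELS,
                                  sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "stage")
  if (length(setdiff(need, names(tab))))
    stop("expression file lacks gene_id/stage columns")
  rep_cols <- grep("^rep[0-9]+$", names(tab), value = TRUE)
  if (length(rep_cols) < 1) stop("no replicate columns (rep01, rep02, ...)")
  if (!is.null(stages)) {
    unknown <- setdiff(unique(tab$stage), stages)
    if (length(unknown))
      stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  }
  sets <- lapply(split(tab, factor(tab$stage, unique(tab$stage))), function(d) {
    A <- as.matrix(d[, rep_cols, drop = FALSE])
    keep <- stats::complete.cases(A)
    dropped <- sum(!keep)
    if (dropped > 0)
      message("stage ", d$stage[1], ": dropped ", dropped,
              " row(s) with missing A-values")
    if (!any(keep))
      stop("stage '", d$stage[1], "': all rows have missing A-values")
    stage_expression(A[keep, , drop = FALSE], stage = d$stage[1],
                     gene_ids = d$gene_id[keep])
  })
  if (!is.null(annot)) {
    all_ids <- unique(unlist(lapply(sets, `[[`, "gene_ids")))
    hit <- all_ids %in% annot$gene_id
    if (!any(hit))
      stop("no overlap between expression gene keys and annotation")
    if (!all(hit))
      message(sum(!hit), " gene(s) without annotation (kept, flagged)")
  }
  sets
}

#' Write stage expression sets to a delimited table
#'
#' Writes the dialect read by [read_stage_expression()].
#'
#' @param sets a `stage_expression` or list of them.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_stage_expression <- function(sets, path, sep = "\t") {
  if (inherits(sets, "stage_expression")) sets <- list(sets)
  nrep <- unique(vapply(sets, function(s) s$n_replicates, integer(1)))
  if (length(nrep) != 1)
    stop("all stages must share a replicate count in one file")
  rows <- lapply(sets, function(s) {
    d <- as.data.frame(s$A)
    names(d) <- sprintf("rep%02d", seq_len(ncol(d)))
    cbind(data.frame(gene_id = s$gene_ids, stage = s$stage,
                     stringsAsFactors = FALSE), d)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
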