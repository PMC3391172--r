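#' Construct a tissue expression panel
#'
#' A tissue panel holds, for each gene, the mean microarray signal per
#' panel tissue and (optionally) the four present/absent replicate calls
#' per tissue, in the style of an expression atlas such as FlyAtlas.
#'
#' @param signals numeric matrix of mean signals, genes in rows, tissues
#'   in columns (non-negative).
#' @param calls optional logical array `genes x tissues x 4` of
#'   present/absent calls (`TRUE` = present), dimnames aligned to
#'   `signals`; `NULL` when the panel carries signals only.
#' @param gene_ids row keys; defaults to `rownames(signals)`.
#' @return an object of class `"tissue_panel"`.
#' @export
tissue_panel <- function(signals, calls = NULL, gene_ids = rownames(signals)) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (is.null(colnames(signals))) stop("signals must have tissue column names")
  if (is.null(gene_ids)) stop("gene_ids required (or rownames on signals)")
  if (length(gene_ids) != nrow(signals))
    stop("gene_ids length does not match signal rows")
  if (any(signals < 0, na.rm = TRUE)) stop("signals must be non-negative")
  rownames(signals) <- as.character(gene_ids)
  if (!is.null(calls)) {
    if (!is.array(calls) || length(dim(calls)) != 3 || dim(calls)[3] != 4)
      stop("calls must be a genes x tissues x 4 array")
    if (!all(dim(calls)[1:2] == dim(signals)))
      stop("calls dimensions do not match signals")
    storage.mode(calls) <- "logical"
    dimnames(calls) <- list(rownames(signals), colnames(signals),
                            paste0("call", 1:4))
  }
  structure(
    list(gene_ids = rownames(signals), tissues = colnames(signals),
         signals = signals, calls = calls),
    class = "tissue_panel"
  )
}

#' @export
print.tissue_panel <- function(x, ...) {
  cat("Tissue panel:", length(x$gene_ids), "genes x",
      length(x$tissues), "tissues",
      if (is.null(x$calls)) "(signals only)\n" else "(signals + P/A calls)\n")
  cat("tissues:", paste(x$tissues, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tissue_panel <- function(x) dim(x$signals)

#' Subset a tissue panel by gene
#'
#' @param x a `tissue_panel`.
#' @param i gene indices or ids.
#' @param ... unused.
#' @return a `tissue_panel` restricted to the selected genes.
#' @export
`[.tissue_panel` <- function(x, i, ...) {
  tissue_panel(x$signals[i, , drop = FALSE],
               calls = if (!is.null(x$calls)) x$calls[i, , , drop = FALSE])
}

#' Read a tissue panel from a delimited table
#'
#' Expects columns `gene_id`, one `<tissue>_signal` per tissue, and — when
#' calls are present — `<tissue>_call1` .. `<tissue>_call4` holding `P`
#' (present) or `A` (absent). A tissue with some but not all four call
#' columns is a format error.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a `tissue_panel`.
#' @export
read_tissue_panel <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("tissue panel lacks gene_id column")
  sig_cols <- grep("_signal$", names(tab), value = TRUE)
  if (!length(sig_cols)) stop("no <tissue>_signal columns found")
  tissues <- sub("_signal$", "", sig_cols)
  signals <- as.matrix(tab[, sig_cols, drop = FALSE])
  colnames(signals) <- tissues
  rownames(signals) <- tab$gene_id
  call_cols <- grep("_call[1-4]$", names(tab), value = TRUE)
  calls <- NULL
  if (length(call_cols)) {
    calls <- array(NA, dim = c(nrow(tab), length(tissues), 4))
    for (ti in seq_along(tissues)) {
      want <- paste0(tissues[ti], "_call", 1:4)
      have <- intersect(want, names(tab))
      if (length(have) != 4)
        stop("tissue '", tissues[ti], "' has ", length(have),
             " call column(s); exactly 4 required")
      for (k in 1:4) calls[, ti, k] <- tab[[want[k]]] == "P"
    }
  }
  tissue_panel(signals, calls = calls, gene_ids = tab$gene_id)
}

#' Write a tissue panel to a delimited table
#'
#' Writes the dialect read by [read_tissue_panel()].
#'
#' @param panel a `tissue_panel`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_tissue_panel <- function(panel, path, sep = "\t") {
  out <- data.frame(gene_id = panel$gene_ids, stringsAsFactors = FALSE)
  for (ti in seq_along(panel$tissues)) {
    out[[paste0(panel$tissues[ti], "_signal")]] <- panel$signals[, ti]
    if (!is.null(panel$calls))
      for (k in 1:4)
        out[[paste0(panel$tissues[ti], "_call", k)]] <-
          ifelse(panel$calls[, ti, k], "P", "A")
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a gene-level tissue panel from probe-level tables
#'
#' Crosslinks probe-level signal (and optional call) tables to gene
#' annotation, applies the unique-alignment filter, and aggregates
#' multiple probes per gene: signals are averaged; present/absent calls
#' are taken from the probe with the highest overall mean signal (calls
#' are per-array booleans, so averaging is undefined).
#'
#' @param signal_table `data.frame` with a `probe_id` column and one
#'   `<tissue>_signal` column per tissue.
#' @param call_table optional `data.frame` with `probe_id` and
#'   `<tissue>_call1..4` columns (`P`/`A`); row set must cover
#'   `signal_table`.
#' @param probe_map `data.frame` mapping `probe_id` to `gene_id` and
#'   `unique_alignment` (logical).
#' @param keep_nonunique keep probes aligning to multiple genomic
#'   locations (default drops them).
#' @return a `tissue_panel` keyed by `gene_id`.
#' @export
load_tissue_panel <- function(signal_table, call_table = NULL, probe_map,
                              keep_nonunique = FALSE) {
  need <- c("probe_id", "gene_id", "unique_alignment")
  if (length(setdiff(need, names(probe_map))))
    stop("probe_map needs columns probe_id, gene_id, unique_alignment")
  if (!"probe_id" %in% names(signal_table))
    stop("signal_table lacks probe_id column")
  idx <- match(signal_table$probe_id, probe_map$probe_id)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " probe(s) without mapping dropped")
    signal_table <- signal_table[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  keep <- keep_nonunique | probe_map$unique_alignment[idx]
  message(sum(keep), " of ", length(keep), " probe(s) retained",
          if (!keep_nonunique) " after unique-alignment filter")
  signal_table <- signal_table[keep, , drop = FALSE]
  gene <- probe_map$gene_id[idx[keep]]

  sig_cols <- grep("_signal$", names(signal_table), value = TRUE)
  if (!length(sig_cols)) stop("no <tissue>_signal columns found")
  tissues <- sub("_signal$", "", sig_cols)
  sig <- as.matrix(signal_table[, sig_cols, drop = FALSE])

  gmeans <- rowsum(sig, gene) / as.vector(table(gene)[sort(unique(gene))])
  colnames(gmeans) <- tissues
  gene_ids <- rownames(gmeans)

  calls <- NULL
  if (!is.null(call_table)) {
    m <- match(signal_table$probe_id, call_table$probe_id)
    if (anyNA(m)) stop("call_table does not cover all retained probes")
    # representative probe per gene: the one with highest overall mean signal
    strength <- rowMeans(sig)
    rep_probe <- vapply(split(seq_along(gene), gene), function(ix)
      ix[which.max(strength[ix])], integer(1))[gene_ids]
    calls <- array(NA, dim = c(length(gene_ids), length(tissues), 4))
    for (ti in seq_along(tissues)) {
      want <- paste0(tissues[ti], "_call", 1:4)
      have <- intersect(want, names(call_table))
      if (length(have) != 4)
        stop("tissue '", tissues[ti], "' has ", length(have),
             " call column(s); exactly 4 required")
      for (k in 1:4)
        calls[, ti, k] <- call_table[[want[k]]][m[rep_probe]] == "P"
    }
  }
  tissue_panel(gmeans, calls = calls, gene_ids = gene_ids)
}
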