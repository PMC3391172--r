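#' Canonical developmental stage labels
#'
#' The seven developing-testis stages of the study design: feeding (F) and
#' wandering (W) larvae grown for 4, 5, 6, 7 or 10 days at 18 degrees C,
#' plus adults.
#'
#' @export
STAGE_LABELS <- c("4thF", "5thF", "6thF", "7thF", "7thW", "10thW", "Adult")

# chromosome arms that enter X-vs-autosome contrasts
.INCLUDED_ARMS <- c("X", "2L", "2R", "3L", "3R", "4")

#' Map chromosome arms to linkage classes
#'
#' Arm `X` maps to `"X"`; arms `2L`, `2R`, `3L`, `3R` and `4` map to
#' `"autosome"`; anything else (Y, heterochromatic scaffolds,
#' mitochondrial, unmapped) maps to `"excluded"` and is dropped from
#' linkage contrasts.
#'
#' @param chromosome character vector of arm labels.
#' @return character vector of `"X"`, `"autosome"` or `"excluded"`.
#' @examples
#' linkage_class(c("X", "2L", "4", "Y", "U"))
#' @export
linkage_class <- function(chromosome) {
  out <- ifelse(chromosome == "X", "X",
    ifelse(chromosome %in% .INCLUDED_ARMS, "autosome", "excluded"))
  out[is.na(chromosome)] <- "excluded"
  out
}

#' Assemble a gene annotation table
#'
#' Validates and normalises the three annotation fields used throughout the
#' pipeline: chromosome arm, gene age class and probe-alignment uniqueness.
#' A `linkage_class` column is derived from the arm.
#'
#' @param gene_id character vector of gene/transcript keys.
#' @param chromosome arm labels (`X`, `2L`, `2R`, `3L`, `3R`, `4`, or other).
#' @param age_class `"old"` (origin predating the Sophophora/Drosophila
#'   subgenus split) or `"young"`; may contain `NA`.
#' @param unique_alignment logical; `TRUE` when the probe aligns to a single
#'   genomic location.
#' @return a `data.frame` with columns `gene_id`, `chromosome`,
#'   `linkage_class`, `age_class`, `unique_alignment`.
#' @export
gene_annotation <- function(gene_id, chromosome,
                            age_class = NA_character_,
                            unique_alignment = TRUE) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicated gene_id in annotation: ",
         paste(utils::head(gene_id[duplicated(gene_id)], 3), collapse = ", "))
  age_class <- as.character(age_class)
  bad_age <- !is.na(age_class) & !age_class %in% c("old", "young")
  if (any(bad_age))
    stop("age_class must be 'old', 'young' or NA")
  data.frame(
    gene_id = gene_id,
    chromosome = as.character(chromosome),
    linkage_class = linkage_class(as.character(chromosome)),
    age_class = age_class,
    unique_alignment = as.logical(unique_alignment),
    stringsAsFactors = FALSE
  )
}

#' Read a gene annotation table from delimited text
#'
#' Expects columns `gene_id`, `chromosome` and optionally `age_class` and
#' `unique_alignment` (logical or 0/1).
#'
#' @param path file path.
#' @param sep field separator (tab by default).
#' @return a `data.frame` as from [gene_annotation()].
#' @export
read_annotation <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chromosome")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  gene_annotation(
    gene_id = tab$gene_id,
    chromosome = tab$chromosome,
    age_class = if ("age_class" %in% names(tab)) tab$age_class else NA,
    unique_alignment = if ("unique_alignment" %in% names(tab))
      as.logical(tab$unique_alignment) else TRUE
  )
}

#' Write a gene annotation table
#'
#' @param annot annotation `data.frame`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path, sep = "\t") {
  cols <- c("gene_id", "chromosome", "age_class", "unique_alignment")
  utils::write.table(annot[, intersect(cols, names(annot))], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# look up linkage for a set of genes; unannotated genes dropped with a warning
.set_linkage <- function(gene_set, annot) {
  idx <- match(gene_set, annot$gene_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " gene(s) not in annotation; dropped")
    idx <- idx[!is.na(idx)]
  }
  annot$linkage_class[idx]
}
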