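# per-stage experimental-error fractions used for the default time course
# (percent of total variance attributable to within-replicate error)
.DEFAULT_ERROR_PCT <- c("4thF" = 29.7, "5thF" = 33.3, "6thF" = 24.9,
                        "7thF" = 23.9, "7thW" = 26.5, "10thW" = 32.2,
                        "Adult" = 44.2)

#' Configuration for the developing-testis simulator
#'
#' Defaults reproduce the structure of the study's time course: 14,000
#' transcripts measured in 10 biological replicates over seven stages,
#' with among-gene variance 1.0 (log2 squared) and per-stage
#' within-replicate variance chosen so the experimental-error fraction
#' follows the 24-44% profile of the real data; the expected pairwise
#' replicate correlation is then `1 - error_fraction/100`, i.e. around
#' 0.7. X-linked genes (fraction 0.16 of the genome, the FlyBase
#' release-5-era share) receive an additive log2 shift per stage: zero in
#' the four early stages and -0.5 in the three late stages (wandering
#' larvae and adult), emulating meiotic X inactivation as meiotic cells
#' accumulate.
#'
#' @param n_genes number of genes (transcripts).
#' @param n_replicates replicates per stage.
#' @param stage_labels stage names.
#' @param gene_mean,var_among location and variance of the per-gene
#'   baseline distribution (log2 A-values).
#' @param var_within within-replicate error variance; scalar or one value
#'   per stage. The default converts the study-like error-percentage
#'   profile into variances given `var_among`.
#' @param x_fraction fraction of genes on the X chromosome.
#' @param x_shift additive log2 shift of X-linked gene means; scalar or
#'   one value per stage (negative = MSCI-like downshift).
#' @param young_fraction fraction of genes in the "young" age class.
#' @param seed integer seed; config + seed fully determine the output.
#' @return a list of class `"stage_sim_config"`.
#' @export
sim_stage_config <- function(n_genes = 14000, n_replicates = 10,
                             stage_labels = STAGE_LABELS,
                             gene_mean = 7, var_among = 1,
                             var_within = NULL,
                             x_fraction = 0.16,
                             x_shift = c(0, 0, 0, 0, -0.5, -0.5, -0.5),
                             young_fraction = 0.1, seed = 1L) {
  n_stages <- length(stage_labels)
  if (anyDuplicated(stage_labels)) stop("stage labels must be unique")
  if (is.null(var_within)) {
    err <- if (n_stages == length(.DEFAULT_ERROR_PCT))
      .DEFAULT_ERROR_PCT / 100 else rep(0.3, n_stages)
    var_within <- var_among * err / (1 - err)
  }
  var_within <- rep_len(var_within, n_stages)
  x_shift <- rep_len(x_shift, n_stages)
  if (var_among < 0 || any(var_within < 0))
    stop("variances must be non-negative")
  if (x_fraction < 0 || x_fraction > 1 ||
      young_fraction < 0 || young_fraction > 1)
    stop("fractions must lie in [0, 1]")
  structure(
    list(n_genes = n_genes, n_replicates = n_replicates,
         stage_labels = stage_labels, gene_mean = gene_mean,
         var_among = var_among, var_within = var_within,
         x_fraction = x_fraction, x_shift = x_shift,
         young_fraction = young_fraction, seed = as.integer(seed)),
    class = "stage_sim_config"
  )
}

# draw chromosome arms: X with prob x_fraction, autosomal arms otherwise
# (arm 4 rare, as in the real genome)
.draw_arms <- function(n, x_fraction) {
  auto <- c("2L", "2R", "3L", "3R", "4")
  auto_w <- c(0.24, 0.24, 0.24, 0.25, 0.03) * (1 - x_fraction)
  sample(c("X", auto), n, replace = TRUE, prob = c(x_fraction, auto_w))
}

#' Simulate a developing-testis replicate time course
#'
#' Generates one [stage_expression] matrix per stage under the additive
#' model `y_gsr = mu_g + shift_s * [g on X] + e_gsr`, with per-gene
#' baselines `mu_g ~ N(gene_mean, var_among)` shared across stages and
#' independent Gaussian replicate error `e ~ N(0, var_within[s])`. The
#' returned truth record stores every generating parameter and the
#' per-gene linkage, so downstream estimates (variance components,
#' replicate correlations, X-vs-autosome contrasts) can be checked
#' against known values.
#'
#' @param config a [sim_stage_config()]; identical config (including
#'   seed) gives bit-identical output.
#' @return a list of class `"stage_simulation"`: `stages` (named list of
#'   `stage_expression`), `annotation` (see [gene_annotation]), `truth`
#'   (config plus per-gene baseline means).
#' @export
simulate_stage_set <- function(config = sim_stage_config()) {
  stopifnot(inherits(config, "stage_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("CG%05d:1", seq_len(n))
  arms <- .draw_arms(n, config$x_fraction)
  age <- ifelse(stats::runif(n) < config$young_fraction, "young", "old")
  mu <- stats::rnorm(n, config$gene_mean, sqrt(config$var_among))
  on_x <- arms == "X"
  stages <- stats::setNames(vector("list", length(config$stage_labels)),
                            config$stage_labels)
  for (s in seq_along(config$stage_labels)) {
    mu_s <- mu + config$x_shift[s] * on_x
    Y <- mu_s + matrix(
      stats::rnorm(n * config$n_replicates, 0, sqrt(config$var_within[s])),
      nrow = n)
    stages[[s]] <- stage_expression(Y, stage = config$stage_labels[s],
                                    gene_ids = ids)
  }
  structure(
    list(stages = stages,
         annotation = gene_annotation(ids, arms, age_class = age),
         truth = c(unclass(config), list(gene_means = mu, on_x = on_x))),
    class = "stage_simulation"
  )
}

#' @export
print.stage_simulation <- function(x, ...) {
  cat("Simulated developing-testis time course:",
      x$truth$n_genes, "genes x", x$truth$n_replicates, "replicates x",
      length(x$stages), "stages\n")
  cat("stages:", paste(names(x$stages), collapse = ", "), "\n")
  cat("X fraction:", x$truth$x_fraction,
      "  X shifts:", paste(x$truth$x_shift, collapse = ", "), "\n")
  invisible(x)
}

#' Configuration for the tissue-panel simulator
#'
#' Defaults emulate a FlyAtlas-style adult panel: seven tissues
#' (including testis and ovary), log-normal background signals around 100
#' units, a planted tissue-specific fraction per tissue at 12-fold, and a
#' coupling probability with which a planted somatic-tissue-specific gene
#' is additionally testis-biased. Planted testis-specific (and, with
#' coupling, testis-biased) genes can be pushed toward the autosomes and
#' ovary-specific genes toward the X via odds multipliers on the X
#' probability, reproducing the chromosomal confound the enrichment layer
#' is designed to remove.
#'
#' @param n_genes number of genes.
#' @param tissues panel tissue names; must contain `testis` and `ovary`.
#' @param meanlog,sdlog_gene,sdlog_tissue log-normal signal model:
#'   per-gene size `exp(N(meanlog, sdlog_gene^2))`, per-tissue
#'   multiplicative noise `exp(N(0, sdlog_tissue^2))`.
#' @param specific_fraction fraction of genes planted as specific per
#'   tissue (disjoint across tissues).
#' @param specific_fold planted fold of the focal signal over the gene's
#'   maximum background signal; must exceed 1.
#' @param absent_fraction fraction of each planted specific set whose
#'   non-focal signals are suppressed below the call threshold (these
#'   genes are recoverable by the strict presence/absence definition).
#' @param sexbias_coupling probability that a planted somatic-tissue
#'   specific gene is additionally testis-biased (testis raised to 3-8x
#'   its ovary signal).
#' @param testis_x_odds,ovary_x_odds multipliers on the X-assignment odds
#'   for testis-linked genes (planted testis-specific and coupled
#'   testis-biased; < 1 depletes the X) and ovary-specific genes (> 1
#'   enriches the X).
#' @param x_fraction,young_fraction as in [sim_stage_config()].
#' @param call_threshold signal above which a replicate array calls the
#'   gene present.
#' @param call_flip_prob probability of flipping each of the 4 replicate
#'   calls (call noise).
#' @param seed integer seed.
#' @return a list of class `"panel_sim_config"`.
#' @export
sim_panel_config <- function(n_genes = 10000,
                             tissues = c("midgut", "malpighian_tubule",
                                         "accessory_gland",
                                         "salivary_gland", "head",
                                         "ovary", "testis"),
                             meanlog = log(100), sdlog_gene = 1,
                             sdlog_tissue = 0.5,
                             specific_fraction = 0.02,
                             specific_fold = 12,
                             absent_fraction = 0.25,
                             sexbias_coupling = 0.3,
                             testis_x_odds = 0.25, ovary_x_odds = 2.5,
                             x_fraction = 0.16, young_fraction = 0.1,
                             call_threshold = 50, call_flip_prob = 0.01,
                             seed = 1L) {
  if (!all(c("testis", "ovary") %in% tissues))
    stop("panel must contain testis and ovary")
  if (specific_fold <= 1) stop("specific_fold must exceed 1")
  if (specific_fraction * length(tissues) > 1)
    stop("planted fractions exceed the gene count")
  bad01 <- c(specific_fraction, absent_fraction, sexbias_coupling,
             x_fraction, young_fraction, call_flip_prob)
  if (any(bad01 < 0 | bad01 > 1)) stop("fractions must lie in [0, 1]")
  structure(
    list(n_genes = n_genes, tissues = tissues, meanlog = meanlog,
         sdlog_gene = sdlog_gene, sdlog_tissue = sdlog_tissue,
         specific_fraction = specific_fraction,
         specific_fold = specific_fold,
         absent_fraction = absent_fraction,
         sexbias_coupling = sexbias_coupling,
         testis_x_odds = testis_x_odds, ovary_x_odds = ovary_x_odds,
         x_fraction = x_fraction, young_fraction = young_fraction,
         call_threshold = call_threshold,
         call_flip_prob = call_flip_prob, seed = as.integer(seed)),
    class = "panel_sim_config"
  )
}

# biased X assignment: multiply the X odds by `odds`
.x_prob <- function(base, odds) {
  o <- base / (1 - base) * odds
  o / (1 + o)
}

#' Simulate a tissue expression panel with known ground truth
#'
#' Background genes receive exchangeable log-normal signals across all
#' tissues. Per tissue, a planted set of specific genes has its focal
#' signal raised to `specific_fold` times the gene's maximum background
#' signal; a subset of each planted set additionally has all non-focal
#' signals suppressed below the call threshold, making it recoverable by
#' the strict presence/absence definition. Planted genes specific to a
#' somatic tissue become testis-biased with probability
#' `sexbias_coupling` (testis signal raised to 3-8 times ovary, kept
#' below the focal signal). Chromosome assignments are drawn with the X
#' odds multiplied by `testis_x_odds` for testis-linked genes and
#' `ovary_x_odds` for ovary-specific genes. Present/absent calls arise
#' from thresholding the signal, with four per-tissue replicate calls and
#' independent flip noise.
#'
#' @param config a [sim_panel_config()].
#' @return a list of class `"panel_simulation"`: `panel` (a
#'   [tissue_panel]), `annotation`, and `truth` with the config and the
#'   planted gene lists (`specific` per tissue, `pa_specific` per tissue,
#'   `testis_biased`).
#' @export
simulate_tissue_panel <- function(config = sim_panel_config()) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  tissues <- config$tissues
  nt <- length(tissues)
  ids <- sprintf("CG%05d", seq_len(n))
  size <- stats::rnorm(n, config$meanlog, config$sdlog_gene)
  sig <- exp(size + matrix(stats::rnorm(n * nt, 0, config$sdlog_tissue),
                           nrow = n))
  dimnames(sig) <- list(ids, tissues)

  n_spec <- round(config$specific_fraction * n)
  planted <- stats::setNames(vector("list", nt), tissues)
  pa_planted <- stats::setNames(vector("list", nt), tissues)
  pool <- sample.int(n)                   # disjoint planted sets
  taken <- 0
  somatic <- setdiff(tissues, c("testis", "ovary"))
  for (ti in seq_len(nt)) {
    ix <- pool[taken + seq_len(n_spec)]
    taken <- taken + n_spec
    planted[[ti]] <- ids[ix]
    sig[ix, ti] <- config$specific_fold *
      apply(sig[ix, -ti, drop = FALSE], 1, max)
    n_pa <- round(config$absent_fraction * n_spec)
    pa_ix <- ix[seq_len(n_pa)]
    pa_planted[[ti]] <- ids[pa_ix]
    if (n_pa) {
      low <- matrix(stats::runif(n_pa * (nt - 1), 0,
                                 config$call_threshold / 4),
                    nrow = n_pa)
      sig[pa_ix, -ti] <- low
      sig[pa_ix, ti] <- pmax(sig[pa_ix, ti],
                             config$specific_fold * config$call_threshold)
    }
  }

  # testis-bias coupling for somatic planted genes
  coupled <- character(0)
  for (tis in somatic) {
    ix <- match(planted[[tis]], ids)
    ix <- ix[!ids[ix] %in% pa_planted[[tis]]]   # keep PA sets clean
    hit <- ix[stats::runif(length(ix)) < config$sexbias_coupling]
    if (length(hit)) {
      fold <- stats::runif(length(hit), 3, 8)
      tcol <- match("testis", tissues)
      ocol <- match("ovary", tissues)
      focal <- sig[cbind(hit, match(tis, tissues))]
      sig[hit, tcol] <- pmin(fold * sig[hit, ocol], 0.9 * focal)
      coupled <- c(coupled, ids[hit])
    }
  }
  # planted testis-specific genes are testis-biased by construction
  testis_biased_truth <- union(coupled, planted[["testis"]])

  # chromosome assignment with planted skews
  px <- rep(config$x_fraction, n)
  px[ids %in% testis_biased_truth] <-
    .x_prob(config$x_fraction, config$testis_x_odds)
  px[ids %in% c(planted[["testis"]], pa_planted[["testis"]])] <-
    .x_prob(config$x_fraction, config$testis_x_odds)
  px[ids %in% c(planted[["ovary"]], pa_planted[["ovary"]])] <-
    .x_prob(config$x_fraction, config$ovary_x_odds)
  on_x <- stats::runif(n) < px
  arms <- .draw_arms(n, config$x_fraction)  # arm labels for autosomes
  arms[on_x] <- "X"
  arms[!on_x & arms == "X"] <-
    sample(c("2L", "2R", "3L", "3R"), sum(!on_x & arms == "X"),
           replace = TRUE)
  age <- ifelse(stats::runif(n) < config$young_fraction, "young", "old")

  present <- sig > config$call_threshold
  calls <- array(rep(present, 4), dim = c(n, nt, 4))
  if (config$call_flip_prob > 0) {
    flip <- array(stats::runif(n * nt * 4) < config$call_flip_prob,
                  dim = c(n, nt, 4))
    calls <- xor(calls, flip)
  }

  panel <- tissue_panel(sig, calls = calls, gene_ids = ids)
  structure(
    list(panel = panel,
         annotation = gene_annotation(ids, arms, age_class = age),
         truth = c(unclass(config),
                   list(specific = planted, pa_specific = pa_planted,
                        testis_biased = testis_biased_truth))),
    class = "panel_simulation"
  )
}

#' @export
print.panel_simulation <- function(x, ...) {
  cat("Simulated tissue panel:", x$truth$n_genes, "genes x",
      length(x$truth$tissues), "tissues\n")
  cat("planted specific per tissue:",
      length(x$truth$specific[[1]]),
      "  (of which strict presence/absence:",
      length(x$truth$pa_specific[[1]]), ")\n")
  cat("testis-biased (planted + coupled):",
      length(x$truth$testis_biased), "\n")
  invisible(x)
}

#' Write a simulation to the canonical delimited files
#'
#' Serialises a [simulate_stage_set()] or [simulate_tissue_panel()]
#' result into the TSV dialects the loaders read, plus the annotation and
#' a truth table of planted labels.
#'
#' @param sim a `stage_simulation` or `panel_simulation`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  if (inherits(sim, "stage_simulation")) {
    write_stage_expression(sim$stages, file.path(dir, "expression.tsv"))
    truth <- data.frame(gene_id = sim$annotation$gene_id,
                        on_x = sim$truth$on_x,
                        baseline_mean = sim$truth$gene_means)
  } else if (inherits(sim, "panel_simulation")) {
    write_tissue_panel(sim$panel, file.path(dir, "panel.tsv"))
    truth <- data.frame(
      gene_id = sim$annotation$gene_id,
      specific_tissue = .planted_label(sim$annotation$gene_id,
                                       sim$truth$specific),
      pa_specific_tissue = .planted_label(sim$annotation$gene_id,
                                          sim$truth$pa_specific),
      testis_biased = sim$annotation$gene_id %in% sim$truth$testis_biased)
  } else stop("unknown simulation object")
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.planted_label <- function(ids, planted) {
  lab <- rep(NA_character_, length(ids))
  for (tis in names(planted)) lab[ids %in% planted[[tis]]] <- tis
  lab
}
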