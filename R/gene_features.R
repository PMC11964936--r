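#' Expression breadth of a gene
#'
#' The number of tissues in which a gene's replicate-mean expression is
#' strictly greater than `tpm_min` (default 3 TPM).
#'
#' @param tissue_means Named numeric vector of replicate-mean TPM per
#'   tissue.
#' @param tpm_min Threshold (strict >).
#' @return Integer in 0..n_tissues.
#' @export
expression_breadth <- function(tissue_means, tpm_min = 3) {
  sum(tissue_means > tpm_min)
}

#' Tau tissue-specificity index
#'
#' Yanai's tau on replicate-mean per-tissue expression:
#' `tau = sum_i(1 - x_i / max(x)) / (N - 1)`. Equals 1 when the gene is
#' expressed in a single tissue and 0 when expression is uniform across
#' tissues.
#'
#' @param tissue_means Named numeric vector (length >= 2).
#' @return Tau in \[0, 1\], or `NA_real_` for an all-zero gene (undefined).
#' @export
tau_specificity <- function(tissue_means) {
  n <- length(tissue_means)
  if (n < 2L) stop("tau requires >= 2 tissues", call. = FALSE)
  mx <- max(tissue_means)
  if (mx <= 0) return(NA_real_)
  sum(1 - tissue_means / mx) / (n - 1)
}

#' Call a gene tissue-specific
#'
#' A gene is specific to its highest-expressed tissue iff its tau exceeds
#' `tau_min` and the top tissue's replicate-mean expression exceeds
#' `tpm_min` (5 TPM). A tie at the maximum is ambiguous and yields no call.
#'
#' @param tissue_means Named numeric vector of per-tissue means.
#' @param tau_min Tau threshold (strict >, default 0.7).
#' @param tpm_min Expression threshold in the top tissue (strict >,
#'   default 5).
#' @return The tissue name, or `NA_character_` for no call.
#' @export
tissue_specific_call <- function(tissue_means, tau_min = 0.7, tpm_min = 5) {
  tau <- tau_specificity(tissue_means)
  if (is.na(tau) || tau <= tau_min) return(NA_character_)
  mx <- max(tissue_means)
  if (mx <= tpm_min) return(NA_character_)
  top <- names(tissue_means)[tissue_means == mx]
  if (length(top) != 1L) return(NA_character_)
  top
}

#' Functional status of a gene
#'
#' A gene is non-functional if it is annotated as a pseudogene or its
#' average expression — the mean over its per-tissue replicate means — is
#' below `tpm_min` (3 TPM).
#'
#' @param tissue_means Named numeric vector of per-tissue means.
#' @param pseudogene_flag Logical annotation flag.
#' @param tpm_min Threshold (strict <; default 3).
#' @return `TRUE` if functional.
#' @export
functional_status <- function(tissue_means, pseudogene_flag, tpm_min = 3) {
  !(isTRUE(pseudogene_flag) || mean(tissue_means) < tpm_min)
}

#' Positional duplication type of a gene pair
#'
#' From gene order alone: copies adjacent in gene index on the same
#' chromosome are tandem duplicates; copies up to `proximal_max_gap` genes
#' apart are proximal; everything else — including pairs on different
#' chromosomes — is dispersed. Pairs already labelled WGD or transposed by
#' upstream synteny tools should keep those labels; this classifier covers
#' the positional remainder.
#'
#' @param gene_a,gene_b Gene IDs.
#' @param models A `GeneModels` data.frame ([read_gene_models()]).
#' @param proximal_max_gap Maximum index distance for proximal (default 10).
#' @return One of `"tandem"`, `"proximal"`, `"dispersed"`.
#' @export
positional_dup_classify <- function(gene_a, gene_b, models,
                                    proximal_max_gap = 10) {
  ia <- match(gene_a, models$gene_id)
  ib <- match(gene_b, models$gene_id)
  if (is.na(ia)) stop("no gene model for ", gene_a, call. = FALSE)
  if (is.na(ib)) stop("no gene model for ", gene_b, call. = FALSE)
  if (models$chromosome[ia] != models$chromosome[ib]) return("dispersed")
  d <- abs(models$gene_index[ia] - models$gene_index[ib])
  if (d == 1L) return("tandem")
  if (d >= 2L && d <= proximal_max_gap) return("proximal")
  "dispersed"
}

#' Build the per-gene feature table for one species
#'
#' Combines expression breadth, tau, the tissue-specific call and the
#' functional-status call for every gene of a species.
#'
#' @param mean_expression Gene x tissue replicate-mean matrix
#'   ([average_replicates()]).
#' @param models Optional `GeneModels` supplying `pseudogene_flag` (genes
#'   absent from the models are treated as non-pseudogenes).
#' @param config A `RunConfig`.
#' @return data.frame with one row per gene: `gene_id`, `species`,
#'   `breadth`, `tau`, `tissue_specific_in`, `functional`.
#' @export
gene_feature_table <- function(mean_expression, models = NULL,
                               config = run_config()) {
  genes <- rownames(mean_expression)
  pseudo <- rep(FALSE, length(genes))
  if (!is.null(models)) {
    idx <- match(genes, models$gene_id)
    pseudo <- ifelse(is.na(idx), FALSE, models$pseudogene_flag[idx])
  }
  rows <- lapply(seq_along(genes), function(i) {
    tm <- mean_expression[i, ]
    data.frame(
      gene_id = genes[i],
      species = attr(mean_expression, "species") %||% NA_character_,
      breadth = expression_breadth(tm, config$breadth_tpm),
      tau = tau_specificity(tm),
      tissue_specific_in = tissue_specific_call(tm, config$tau_min,
                                                config$tissue_specific_tpm),
      functional = functional_status(tm, pseudo[i], config$functional_tpm),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
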