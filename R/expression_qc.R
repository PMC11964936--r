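#' Replicate-level quality control by Spearman correlation
#'
#' Within each (species, tissue) replicate set, computes the pairwise
#' Spearman correlation over genes and summarizes each sample by the mean of
#' its pairwise rho values. A sample is removed iff that mean is at or below
#' `min_rho` ("0.75 or below" is out). Groups with a single replicate pass
#' untouched; if every replicate of a group fails, the whole group is
#' dropped and flagged in the report. A constant expression column makes
#' Spearman undefined; such correlations are treated as 0 and the sample
#' flagged.
#'
#' The per-sample mean (rather than, say, the group minimum) isolates single
#' discordant samples inside larger replicate sets.
#'
#' @param dataset An `ExpressionDataset`.
#' @param min_rho Removal threshold; samples with mean pairwise rho
#'   `<= min_rho` are removed (default 0.75).
#' @return List with `dataset` (filtered) and `report`, a data.frame with
#'   one row per input sample: `sample_id`, `species`, `tissue`,
#'   `mean_rho`, `kept`, `reason`.
#' @export
replicate_qc <- function(dataset, min_rho = 0.75) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sheet <- dataset$sheet
  v <- dataset$values
  grp <- split(sheet$sample_id, paste(sheet$species, sheet$tissue, sep = "\r"))
  rows <- lapply(grp, function(ids) {
    meta <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
    if (length(ids) == 1L) {
      return(data.frame(sample_id = ids, species = meta$species,
                        tissue = meta$tissue, mean_rho = NA_real_,
                        kept = TRUE, reason = "single_replicate",
                        stringsAsFactors = FALSE))
    }
    sub <- v[, ids, drop = FALSE]
    rho <- suppressWarnings(stats::cor(sub, method = "spearman"))
    undef <- is.na(rho)
    rho[undef] <- 0
    diag(rho) <- NA
    mean_rho <- rowMeans(rho, na.rm = TRUE)
    flagged <- apply(undef, 1L, any)
    kept <- mean_rho > min_rho
    reason <- ifelse(kept, "pass",
                     sprintf("mean_spearman_%.3f_le_%.2f", mean_rho, min_rho))
    reason[!kept & flagged] <- paste0(reason[!kept & flagged],
                                      ";constant_vector")
    if (!any(kept)) reason[] <- paste0(reason, ";whole_group_dropped")
    data.frame(sample_id = ids, species = meta$species, tissue = meta$tissue,
               mean_rho = unname(mean_rho), kept = unname(kept),
               reason = reason, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report <- report[match(sheet$sample_id, report$sample_id), , drop = FALSE]
  rownames(report) <- NULL
  keep_ids <- report$sample_id[report$kept]
  if (length(keep_ids) == 0L) stop("replicate QC removed every sample",
                                   call. = FALSE)
  dropped_groups <- unique(paste(report$species, report$tissue)[
    !paste(report$species, report$tissue) %in%
      paste(report$species, report$tissue)[report$kept]])
  if (length(dropped_groups)) {
    message("replicate QC dropped whole group(s): ",
            paste(dropped_groups, collapse = "; "))
  }
  list(dataset = subset_dataset(dataset, samples = keep_ids), report = report)
}

#' Remove genes with zero expression in every sample
#'
#' @param dataset An `ExpressionDataset`.
#' @return The dataset restricted to genes with at least one positive value.
#' @export
drop_all_zero_genes <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  keep <- rownames(dataset$values)[rowSums(dataset$values > 0) > 0L]
  if (length(keep) == 0L) stop("no genes", call. = FALSE)
  subset_dataset(dataset, genes = keep)
}

#' Average expression over biological replicates
#'
#' Arithmetic mean of TPM over the replicates of each (tissue, gene) within
#' a single species, producing the gene x tissue matrix used by the dosage
#' test, expression breadth, tau and the functional-status call.
#'
#' @param dataset A single-species `ExpressionDataset` (post-QC).
#' @return Numeric matrix genes x tissues with attribute `species`.
#' @export
average_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sp <- unique(dataset$sheet$species)
  if (length(sp) != 1L) {
    stop("average_replicates expects a single species; use split_by_species()",
         call. = FALSE)
  }
  tissues <- unique(dataset$sheet$tissue)
  out <- vapply(tissues, function(tt) {
    ids <- dataset$sheet$sample_id[dataset$sheet$tissue == tt]
    rowMeans(dataset$values[, ids, drop = FALSE])
  }, numeric(nrow(dataset$values)))
  out <- matrix(out, nrow = nrow(dataset$values),
                dimnames = list(rownames(dataset$values), tissues))
  attr(out, "species") <- sp
  out
}

#' Replicate-mean expression for every species
#'
#' @param datasets Named list of single-species `ExpressionDataset`s.
#' @return Named list of gene x tissue matrices (see [average_replicates()]).
#' @export
mean_expression_by_species <- function(datasets) {
  lapply(datasets, average_replicates)
}

#' PCA of singleton-gene expression across species
#'
#' Singleton genes (orthogroups with exactly one gene in every analysed
#' species) are directly comparable across genomes, so stacking their
#' log2(TPM+1) profiles across species gives a matrix on which samples are
#' expected to cluster by tissue, not by species — the standard sanity check
#' on a multi-species expression resource. Features are singleton
#' orthogroups, observations are all samples of all species; features are
#' centred before PCA.
#'
#' As a quantitative stand-in for "samples cluster by tissue", the fraction
#' of samples whose nearest tissue centroid (Euclidean, in the retained
#' component space) is their own tissue is reported. If the matrix is
#' constant (zero total variance) the accuracy is defined as the
#' 1/n_tissues chance baseline.
#'
#' @param datasets Named list of single-species `ExpressionDataset`s.
#' @param orthogroups An `OrthogroupTable`.
#' @param n_components Number of principal components to retain (default 2).
#' @return List with `scores` (data.frame: sample_id, species, tissue,
#'   PC columns), `explained_variance` (proportion per retained PC),
#'   `tissue_accuracy`, and `n_singletons`.
#' @export
singleton_pca <- function(datasets, orthogroups, n_components = 2) {
  stopifnot(inherits(orthogroups, "OrthogroupTable"))
  species <- names(datasets)
  singles <- singleton_orthogroups(orthogroups, species)
  if (length(singles) < n_components) {
    stop("fewer singleton genes (", length(singles),
         ") than components (", n_components, ")", call. = FALSE)
  }
  sub <- orthogroups[orthogroups$orthogroup_id %in% singles &
                       orthogroups$species %in% species, , drop = FALSE]
  blocks <- lapply(species, function(sp) {
    map <- sub[sub$species == sp, , drop = FALSE]
    gene_of <- stats::setNames(map$gene_id, map$orthogroup_id)
    ds <- datasets[[sp]]
    miss <- setdiff(unname(gene_of), rownames(ds$values))
    if (length(miss)) stop("singleton gene absent from matrix: ", miss[1L],
                           call. = FALSE)
    m <- t(ds$values[gene_of[singles], , drop = FALSE])
    colnames(m) <- singles
    m
  })
  x <- log2(do.call(rbind, blocks) + 1)
  meta <- do.call(rbind, lapply(datasets, function(d)
    d$sheet[, c("sample_id", "species", "tissue")]))
  rownames(meta) <- NULL
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  tv <- sum(apply(x, 2L, stats::var))
  if (tv == 0) {
    scores <- matrix(0, nrow(x), n_components,
                     dimnames = list(NULL, paste0("PC", seq_len(n_components))))
    ev <- rep(0, n_components)
  } else {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
    scores <- p$x
    ev <- (p$sdev^2 / sum(p$sdev^2))[seq_len(ncol(scores))]
  }
  acc <- nearest_centroid_accuracy(scores, meta$tissue)
  list(scores = cbind(meta, as.data.frame(scores)),
       explained_variance = ev,
       tissue_accuracy = acc,
       n_singletons = length(singles))
}

#' Orthogroups with exactly one gene in every species
#'
#' @param orthogroups An `OrthogroupTable`.
#' @param species Character vector of species that must each contribute
#'   exactly one gene.
#' @return Character vector of orthogroup IDs.
#' @export
singleton_orthogroups <- function(orthogroups, species) {
  sub <- orthogroups[orthogroups$species %in% species, , drop = FALSE]
  cnt <- table(sub$orthogroup_id, sub$species)
  ok <- rownames(cnt)[rowSums(cnt == 1L) == length(species) &
                        rowSums(cnt) == length(species)]
  sort(ok)
}

nearest_centroid_accuracy <- function(scores, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (all(scores == 0) || nrow(scores) == 0L) return(1 / length(lev))
  cent <- t(vapply(lev, function(l)
    colMeans(scores[labels == l, , drop = FALSE]), numeric(ncol(scores))))
  d2 <- outer(rowSums(scores^2), rowSums(cent^2), "+") -
    2 * scores %*% t(cent)
  pred <- lev[max.col(-d2, ties.method = "first")]
  mean(pred == labels)
}

#' Summed paralogue-pair expression matrix (alternative PCA input)
#'
#' For orthogroups with exactly two copies in a species, the summed TPM of
#' the two copies per sample. Provided as the alternative, pair-dosage
#' reading of the cross-species PCA input; [singleton_pca()] is the primary
#' reading.
#'
#' @param dataset A single-species `ExpressionDataset`.
#' @param orthogroups An `OrthogroupTable`.
#' @return Matrix orthogroups x samples of summed pair expression.
#' @export
summed_pair_matrix <- function(dataset, orthogroups) {
  sp <- unique(dataset$sheet$species)
  stopifnot(length(sp) == 1L)
  cn <- species_copy_number(orthogroups, sp)
  ogs <- names(cn)[cn == 2L]
  sub <- orthogroups[orthogroups$species == sp &
                       orthogroups$orthogroup_id %in% ogs, , drop = FALSE]
  sub <- sub[sub$gene_id %in% rownames(dataset$values), , drop = FALSE]
  cnt <- table(sub$orthogroup_id)
  ogs <- names(cnt)[cnt == 2L]
  out <- t(vapply(ogs, function(og) {
    g <- sub$gene_id[sub$orthogroup_id == og]
    colSums(dataset$values[g, , drop = FALSE])
  }, numeric(ncol(dataset$values))))
  out
}
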