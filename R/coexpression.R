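#' Genes with greater-than-median expression in at least one sample
#'
#' The coexpression analysis is restricted to genes that exceed the
#' per-sample median expression in at least one sample of the species.
#' Medians are computed per sample over all genes present in the dataset at
#' the time of the call, and the comparison is strict: a gene sitting
#' exactly at the median in every sample is removed.
#'
#' @param dataset A single-species `ExpressionDataset`.
#' @return Character vector of retained gene IDs (in matrix order).
#' @export
median_expression_subset <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  med <- apply(v, 2L, stats::median)
  keep <- rowSums(v > rep(med, each = nrow(v))) > 0L
  rownames(v)[keep]
}

#' Build a per-species rank-standardized coexpression network
#'
#' The network is constructed from the Pearson correlation between all gene
#' pairs over all retained samples of the species (tissues pooled,
#' replicates included), then made comparable across genes by ranking:
#' \enumerate{
#'   \item correlate: Pearson r over samples; the diagonal is excluded;
#'   \item rank per gene: each gene's off-diagonal correlations are ranked
#'     ascending with average ranks for ties, so the most strongly
#'     co-expressed partner gets the largest rank; correlations undefined
#'     because a partner has zero variance are assigned the median rank of
#'     that gene's defined ranks;
#'   \item symmetrize: the two directed ranks of a pair are averaged;
#'   \item standardize: the whole matrix is divided by its maximum
#'     symmetrized rank, giving weights in \[0, 1\] with the single most
#'     co-expressed pair at exactly 1.
#' }
#'
#' Ranks are computed within the supplied gene subset (the
#' median-expression universe), so weights depend on that universe.
#'
#' @param dataset A single-species `ExpressionDataset` with >= 3 samples.
#' @param gene_subset Genes to include, typically
#'   [median_expression_subset()]; default uses all genes in the dataset.
#' @return A `CoexpressionNetwork`: list with `species`, `genes`, and
#'   `weights` (symmetric matrix, diagonal `NA`).
#' @export
build_network <- function(dataset, gene_subset = rownames(dataset$values)) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sp <- unique(dataset$sheet$species)
  if (length(sp) != 1L) stop("build_network expects a single species",
                             call. = FALSE)
  if (ncol(dataset$values) < 3L) {
    stop("insufficient samples for correlation (need >= 3, have ",
         ncol(dataset$values), ")", call. = FALSE)
  }
  gene_subset <- intersect(gene_subset, rownames(dataset$values))
  n <- length(gene_subset)
  if (n < 2L) stop("need >= 2 genes to build a network", call. = FALSE)
  x <- t(dataset$values[gene_subset, , drop = FALSE])
  cc <- suppressWarnings(stats::cor(x))
  diag(cc) <- NA
  rk <- rank_correlations(cc)
  rm(cc)
  rk <- (rk + t(rk)) / 2
  w <- rk / max(rk, na.rm = TRUE)
  structure(list(species = sp, genes = gene_subset, weights = w),
            class = "CoexpressionNetwork")
}

# Per-row ascending average ranks of off-diagonal correlations; NAs (beyond
# the diagonal) get the median of the row's defined ranks, or the middle of
# the rank range if no correlation in the row is defined. The diagonal stays
# NA. Ranking a full row with na.last = "keep" excludes the NA diagonal
# automatically, so ranks run over the n-1 off-diagonal entries.
rank_correlations <- function(cc) {
  n <- nrow(cc)
  rk <- matrix(NA_real_, n, n, dimnames = dimnames(cc))
  for (i in seq_len(n)) {
    r <- rank(cc[i, ], ties.method = "average", na.last = "keep")
    if (anyNA(r)) {
      med <- if (all(is.na(r))) n / 2 else stats::median(r, na.rm = TRUE)
      r[is.na(r)] <- med
    }
    r[i] <- NA
    rk[i, ] <- r
  }
  rk
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork (%s): %d genes\n", x$species,
              length(x$genes)))
  invisible(x)
}

#' Look up the coexpression weight of a gene pair
#'
#' @param network A `CoexpressionNetwork`.
#' @param gene_a,gene_b Gene IDs.
#' @return The symmetrized standardized weight in \[0, 1\], or `NA_real_` if
#'   either gene is absent from the network (it failed the median-expression
#'   subset) or the two genes are identical (diagonal excluded).
#' @export
pair_coexpression <- function(network, gene_a, gene_b) {
  stopifnot(inherits(network, "CoexpressionNetwork"))
  if (identical(gene_a, gene_b)) return(NA_real_)
  if (!(gene_a %in% network$genes) || !(gene_b %in% network$genes)) {
    return(NA_real_)
  }
  unname(network$weights[gene_a, gene_b])
}

#' Dump a network as a three-column edge table (upper triangle)
#'
#' @param network A `CoexpressionNetwork`.
#' @param path Output TSV path (use a `.gz` suffix for compression).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  w <- network$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  df <- data.frame(gene_a = network$genes[ut[, 1L]],
                   gene_b = network$genes[ut[, 2L]],
                   weight = w[ut], stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
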