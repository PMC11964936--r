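#' Construct an expression dataset
#'
#' An `ExpressionDataset` couples a non-negative TPM matrix (genes x samples)
#' with its sample sheet. It is the substrate of every downstream stage:
#' replicate QC, coexpression networks, fate classification and the
#' dosage-constraint test all consume (filtered versions of) this object.
#'
#' @param values Numeric matrix of TPM values, genes in rows, samples in
#'   columns; `rownames` are gene IDs, `colnames` sample IDs. All values must
#'   be finite and non-negative; absence is encoded as 0, never `NA`.
#' @param sheet A data.frame with columns `sample_id`, `species`, `tissue`,
#'   `replicate` and optionally `pct_uniquely_mapped` (percentage in
#'   \[0, 100\]). Every column of `values` must appear exactly once.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` and `sheet`.
#' @examples
#' m <- matrix(c(1, 0, 5, 2, 0, 7), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), species = "spA",
#'                     tissue = "apex", replicate = 1:2)
#' ds <- expression_dataset(m, sheet)
#' @export
expression_dataset <- function(values, sheet) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  obj <- structure(list(values = values, sheet = sheet),
                   class = "ExpressionDataset")
  validate_expression_dataset(obj)
}

validate_expression_dataset <- function(x) {
  v <- x$values
  sheet <- x$sheet
  if (is.null(rownames(v)) || nrow(v) == 0L) stop("no genes", call. = FALSE)
  if (is.null(colnames(v)) || ncol(v) == 0L) stop("no samples", call. = FALSE)
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup)) {
    stop("duplicate gene IDs: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    stop("expression values must be finite (encode absence as 0, not NA)",
         call. = FALSE)
  }
  if (any(v < 0)) {
    bad <- rownames(v)[which(rowSums(v < 0) > 0)[1L]]
    stop("negative expression values (gene ", bad, ")", call. = FALSE)
  }
  need <- c("sample_id", "species", "tissue", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1L], call. = FALSE)
  }
  key <- paste(sheet$species, sheet$tissue, sheet$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (species, tissue, replicate) in sheet: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  absent <- setdiff(colnames(v), sheet$sample_id)
  if (length(absent)) {
    stop("sample in matrix missing from sheet: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  # keep sheet rows aligned with, and restricted to, matrix columns
  x$sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  rownames(x$sheet) <- NULL
  x
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s species, %s tissues)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sheet$species)),
              length(unique(x$sheet$tissue))))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Subset an expression dataset by genes and/or samples
#'
#' @param dataset An `ExpressionDataset`.
#' @param genes Character vector of gene IDs to keep (default all).
#' @param samples Character vector of sample IDs to keep (default all).
#' @return A new `ExpressionDataset`.
#' @export
subset_dataset <- function(dataset, genes = NULL, samples = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("unknown gene: ", miss[1L], call. = FALSE)
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss)) stop("unknown sample: ", miss[1L], call. = FALSE)
    v <- v[, samples, drop = FALSE]
  }
  sheet <- dataset$sheet[dataset$sheet$sample_id %in% colnames(v), , drop = FALSE]
  expression_dataset(v, sheet)
}

#' Split a multi-species dataset into per-species datasets
#'
#' @param dataset An `ExpressionDataset` possibly containing several species.
#' @return Named list of single-species `ExpressionDataset` objects.
#' @export
split_by_species <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sp <- unique(dataset$sheet$species)
  out <- lapply(sp, function(s) {
    keep <- dataset$sheet$sample_id[dataset$sheet$species == s]
    subset_dataset(dataset, samples = keep)
  })
  names(out) <- sp
  out
}
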