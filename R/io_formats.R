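#' Read an expression matrix and its sample sheet
#'
#' Reads a tab-separated TPM matrix (first column gene IDs, header row of
#' sample IDs) together with a sample-sheet TSV (`sample_id`, `species`,
#' `tissue`, `replicate`, optional `pct_uniquely_mapped`). Samples whose
#' fraction of uniquely mapped reads is 50% or below are dropped with a
#' warning: the mapping-rate filter is an upstream alignment QC carried in
#' the sheet, and only samples with more than 50% uniquely mapped reads are
#' analysed.
#'
#' @param path Path to the expression matrix TSV.
#' @param sheet_path Path to the sample sheet TSV.
#' @param min_pct_mapped Retention threshold on `pct_uniquely_mapped`;
#'   samples at or below it are removed (default 50).
#' @return A validated [expression_dataset()].
#' @export
read_expression <- function(path, sheet_path, min_pct_mapped = 50) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression matrix needs >=1 sample column",
                           call. = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  sheet <- data.table::fread(sheet_path, sep = "\t", header = TRUE,
                             data.table = FALSE)
  if ("pct_uniquely_mapped" %in% names(sheet)) {
    pct <- sheet$pct_uniquely_mapped
    low <- !is.na(pct) & pct <= min_pct_mapped & sheet$sample_id %in% colnames(m)
    if (any(low)) {
      warning("dropping ", sum(low), " sample(s) with <=", min_pct_mapped,
              "% uniquely mapped reads: ",
              paste(sheet$sample_id[low], collapse = ", "), call. = FALSE)
      m <- m[, setdiff(colnames(m), sheet$sample_id[low]), drop = FALSE]
    }
  }
  expression_dataset(m, sheet[sheet$sample_id %in% colnames(m), , drop = FALSE])
}

#' Write an expression dataset to TSV
#'
#' Inverse of [read_expression()]; round-trips losslessly.
#'
#' @param dataset An `ExpressionDataset`.
#' @param path Output path for the matrix TSV.
#' @param sheet_path Optional output path for the sample sheet TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, sheet_path = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(gene_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(sheet_path)) write_tsv(dataset$sheet, sheet_path)
  invisible(path)
}

#' Read an orthogroup table
#'
#' Parses the OrthoFinder `Orthogroups.tsv` dialect: a header line starting
#' with `Orthogroup` followed by one column per species; cells are
#' comma+space-separated gene lists and an empty cell means the species has
#' no member. A gene listed under two orthogroups violates the partition
#' invariant and is a hard error.
#'
#' @param path Path to the TSV.
#' @return An `OrthogroupTable`: a data.frame with columns `orthogroup_id`,
#'   `species`, `gene_id` (one row per gene) carrying attribute `species`
#'   (the full species column set, including species with no genes left).
#' @export
read_orthogroups <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1L] != "Orthogroup") {
    stop("malformed orthogroup header: first column must be 'Orthogroup', got '",
         names(tab)[1L], "'", call. = FALSE)
  }
  if (ncol(tab) < 2L) stop("orthogroup table has no species columns", call. = FALSE)
  if (anyDuplicated(tab$Orthogroup)) {
    stop("duplicate orthogroup ID: ",
         tab$Orthogroup[duplicated(tab$Orthogroup)][1L], call. = FALSE)
  }
  species <- names(tab)[-1L]
  rows <- lapply(species, function(sp) {
    cells <- tab[[sp]]
    genes <- strsplit(cells, ", ", fixed = TRUE)
    n <- lengths(genes)
    has <- !is.na(cells) & nzchar(cells)
    data.frame(orthogroup_id = rep(tab$Orthogroup[has], n[has]),
               species = sp,
               gene_id = unlist(genes[has], use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  orthogroup_table(long, species = species)
}

#' Construct an orthogroup table from a long data.frame
#'
#' @param long data.frame with columns `orthogroup_id`, `species`, `gene_id`.
#' @param species Character vector of all species columns (defaults to those
#'   observed).
#' @return An `OrthogroupTable`.
#' @export
orthogroup_table <- function(long, species = sort(unique(long$species))) {
  long <- as.data.frame(long, stringsAsFactors = FALSE)
  stopifnot(all(c("orthogroup_id", "species", "gene_id") %in% names(long)))
  key <- paste(long$species, long$gene_id)
  if (anyDuplicated(key)) {
    bad <- long$gene_id[duplicated(key)][1L]
    stop("gene assigned to more than one orthogroup: ", bad, call. = FALSE)
  }
  long <- long[order(long$orthogroup_id, long$species, long$gene_id), ,
               drop = FALSE]
  rownames(long) <- NULL
  structure(long, species = species,
            class = c("OrthogroupTable", "data.frame"))
}

#' @export
print.OrthogroupTable <- function(x, ...) {
  cat(sprintf("OrthogroupTable: %d orthogroups, %d genes, %d species\n",
              length(unique(x$orthogroup_id)), nrow(x),
              length(attr(x, "species"))))
  invisible(x)
}

#' Write an orthogroup table in Orthogroups.tsv dialect
#'
#' @param og An `OrthogroupTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  stopifnot(inherits(og, "OrthogroupTable"))
  species <- attr(og, "species")
  ids <- sort(unique(og$orthogroup_id))
  out <- data.frame(Orthogroup = ids, stringsAsFactors = FALSE)
  for (sp in species) {
    sub <- og[og$species == sp, , drop = FALSE]
    lst <- split(sub$gene_id, factor(sub$orthogroup_id, levels = ids))
    out[[sp]] <- vapply(lst, function(g) paste(sort(g), collapse = ", "), "")
  }
  write_tsv(out, path)
  invisible(path)
}

#' Total gene count per orthogroup
#'
#' Family size of an orthogroup is the number of genes it contains summed
#' over all species.
#'
#' @param og An `OrthogroupTable`.
#' @return Named integer vector, names are orthogroup IDs.
#' @export
family_sizes <- function(og) {
  stopifnot(inherits(og, "OrthogroupTable"))
  tab <- table(og$orthogroup_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-orthogroup gene counts for one species
#' @param og An `OrthogroupTable`.
#' @param species Species name.
#' @return Named integer vector over orthogroups present in that species.
#' @export
species_copy_number <- function(og, species) {
  sub <- og[og$species == species, , drop = FALSE]
  tab <- table(sub$orthogroup_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read gene models from GFF3
#'
#' Imports `gene` (and `pseudogene`) features and assigns each gene a
#' 0-based `gene_index`: its rank along the chromosome by ascending start
#' coordinate, ties broken lexicographically by gene ID so indexing is
#' deterministic. The index, not base pairs, is the adjacency metric used
#' to call tandem/proximal/dispersed duplications. Strand is recorded but
#' ignored for ordering.
#'
#' @param gff3_path Path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `gene_index`, `pseudogene_flag`.
#' @export
read_gene_models <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "pseudogene")
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0L) stop("no gene features in ", gff3_path, call. = FALSE)
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  bad <- is.na(ids) | !nzchar(ids)
  if (any(bad)) {
    warning("skipping ", sum(bad), " gene feature(s) without an ID",
            call. = FALSE)
    gr <- gr[!bad]; type <- type[!bad]; ids <- ids[!bad]
  }
  pseudo <- type == "pseudogene"
  bt <- gr$biotype
  if (!is.null(bt)) pseudo <- pseudo | (!is.na(bt) & bt == "pseudogene")
  df <- data.frame(gene_id = as.character(ids),
                   chromosome = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   pseudogene_flag = pseudo,
                   stringsAsFactors = FALSE)
  gene_models(df)
}

#' Construct a gene-model table, assigning gene indices
#'
#' @param df data.frame with at least `gene_id`, `chromosome`, `start`,
#'   `end`; optional `strand` and `pseudogene_flag`.
#' @return data.frame of class `GeneModels` with `gene_index` filled in.
#' @export
gene_models <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$pseudogene_flag)) df$pseudogene_flag <- FALSE
  miss <- is.na(df$start) | is.na(df$end)
  if (any(miss)) {
    warning("skipping ", sum(miss), " gene(s) without coordinates: ",
            paste(utils::head(df$gene_id[miss], 3), collapse = ", "),
            call. = FALSE)
    df <- df[!miss, , drop = FALSE]
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene ID in gene models: ",
         df$gene_id[duplicated(df$gene_id)][1L], call. = FALSE)
  }
  stopifnot(all(df$start <= df$end))
  df <- df[order(df$chromosome, df$start, df$gene_id), , drop = FALSE]
  df$gene_index <- stats::ave(seq_len(nrow(df)), df$chromosome,
                              FUN = seq_along) - 1L
  rownames(df) <- NULL
  class(df) <- c("GeneModels", "data.frame")
  df
}

#' Write gene models as GFF3
#'
#' @param models A `GeneModels` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chromosome,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand)
  gr$type <- ifelse(models$pseudogene_flag, "pseudogene", "gene")
  gr$ID <- models$gene_id
  gr$source <- "parafates"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Deterministic TSV writer shared by every stage: fixed quoting/precision so
# equal inputs produce byte-identical files.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
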