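# Small in-code fixtures shared across test files.

make_dataset <- function(values, species = "spA",
                         tissues = NULL, replicates = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  ns <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", 1:ns)
  if (is.null(tissues)) tissues <- rep("apex", ns)
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_len(ns), tissues, FUN = seq_along)
  }
  sheet <- data.frame(sample_id = colnames(values), species = species,
                      tissue = tissues, replicate = replicates,
                      stringsAsFactors = FALSE)
  expression_dataset(values, sheet)
}

random_dataset <- function(n_genes, n_samples, species = "spA",
                           tissues = NULL, zero_frac = 0.1) {
  v <- matrix(2^stats::rnorm(n_genes * n_samples, 4, 2), n_genes)
  v[stats::runif(length(v)) < zero_frac] <- 0
  make_dataset(v, species = species, tissues = tissues)
}

# two replicate columns whose Spearman correlation is exactly 0.75:
# rank displacement vector d with sum(d^2) = 14 over n = 7 genes gives
# rho = 1 - 6*14 / (7 * 48) = 0.75
rho075_columns <- function() {
  x <- c(10, 20, 30, 40, 50, 60, 70)          # ranks 1..7
  y <- c(40, 10, 20, 30, 50, 70, 60)          # ranks 4 1 2 3 5 7 6
  stopifnot(abs(stats::cor(x, y, method = "spearman") - 0.75) < 1e-12)
  cbind(x, y)
}

# tiny simulated world reused by unit tests (seconds, not minutes)
tiny_sim <- function(seed = 5, ...) {
  simulate_expression(sim_config(
    n_species = 2, n_replicates = 2, n_singletons = 120,
    n_pairs_per_mode = 8, n_orthogroups_constrained = 10,
    n_orthogroups_drift = 4, n_tissue_specific = 4, n_pseudogenes = 3,
    seed = seed, ...))
}

run_pipeline <- function(sim) {
  qc <- lapply(sim$datasets, function(d)
    drop_all_zero_genes(replicate_qc(d)$dataset))
  nets <- lapply(qc, function(d)
    build_network(d, median_expression_subset(d)))
  list(sim = sim, datasets = qc, networks = nets)
}
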