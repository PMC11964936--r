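#' Orthogroups retained for a dosage comparison
#'
#' For one tissue and one species pair, an orthogroup enters the dosage test
#' iff it has exactly two copies in each of the two species and all four
#' genes have strictly positive replicate-mean expression in that tissue.
#'
#' @param tissue Tissue name.
#' @param species_a,species_b Species names.
#' @param mean_expression Named list of gene x tissue replicate-mean
#'   matrices ([mean_expression_by_species()]).
#' @param orthogroups An `OrthogroupTable`.
#' @param two_copy Optional precomputed per-species two-copy orthogroup
#'   lists (internal caching used by [dosage_test()]).
#' @return Character vector of orthogroup IDs.
#' @export
retained_orthogroups <- function(tissue, species_a, species_b,
                                 mean_expression, orthogroups,
                                 two_copy = NULL) {
  two_a <- two_copy[[species_a]] %||%
    two_copy_orthogroups(orthogroups, species_a)
  two_b <- two_copy[[species_b]] %||%
    two_copy_orthogroups(orthogroups, species_b)
  cand <- intersect(names(two_a), names(two_b))
  ta <- og_pair_totals(cand, two_a, mean_expression[[species_a]], tissue)
  tb <- og_pair_totals(cand, two_b, mean_expression[[species_b]], tissue)
  sort(cand[ta$all_positive & tb$all_positive])
}

two_copy_orthogroups <- function(orthogroups, species) {
  sub <- orthogroups[orthogroups$species == species, , drop = FALSE]
  grp <- split(sub$gene_id, sub$orthogroup_id)
  grp[lengths(grp) == 2L]
}

# summed replicate-mean expression of both copies per orthogroup, plus
# whether all copies are strictly positive; vectorized over orthogroups
og_pair_totals <- function(ogs, two_list, mexpr, tissue) {
  n <- length(ogs)
  if (n == 0L || is.null(mexpr) || !(tissue %in% colnames(mexpr))) {
    return(list(total = rep(NA_real_, n), all_positive = rep(FALSE, n)))
  }
  genes <- unlist(two_list[ogs], use.names = FALSE)
  vals <- mexpr[, tissue][match(genes, rownames(mexpr))]
  m <- matrix(vals, nrow = 2L)
  list(total = colSums(m),
       all_positive = colSums(!is.na(m) & m > 0) == 2L)
}

#' Cross-species dosage comparisons for one tissue and species pair
#'
#' For each retained orthogroup, sums the replicate-mean expression of the
#' two copies in each species, takes the log2 ratio of the two totals,
#' z-scores the ratios over all retained orthogroups of this comparison
#' (mean/sd centring by default, median/MAD if `config$robust_z`), and
#' converts each z to a two-sided standard-normal p value,
#' `p = 2 * (1 - pnorm(|z|))`. Log transformation symmetrizes the ratio so
#' swapping the species merely negates `log2_ratio` and `z`, leaving p
#' unchanged. If all ratios are identical (zero spread) every z is 0 and
#' every p is 1, with a warning.
#'
#' @param tissue Tissue name.
#' @param focal,other Species names (ordered: ratio is focal/other).
#' @param retained Orthogroup IDs from [retained_orthogroups()].
#' @param mean_expression Named list of gene x tissue mean matrices.
#' @param orthogroups An `OrthogroupTable`.
#' @param config A `RunConfig` (`min_orthogroups_per_comparison`,
#'   `robust_z`).
#' @param two_copy Optional precomputed per-species two-copy orthogroup
#'   lists (internal caching used by [dosage_test()]).
#' @return data.frame with one row per orthogroup: `tissue`, `focal`,
#'   `other`, `orthogroup_id`, `total_focal`, `total_other`, `log2_ratio`,
#'   `z`, `p`; zero rows (with a message) if fewer than the minimum number
#'   of orthogroups is retained.
#' @export
dosage_comparisons <- function(tissue, focal, other, retained,
                               mean_expression, orthogroups,
                               config = run_config(), two_copy = NULL) {
  empty <- data.frame(tissue = character(), focal = character(),
                      other = character(), orthogroup_id = character(),
                      total_focal = numeric(), total_other = numeric(),
                      log2_ratio = numeric(), z = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (length(retained) < config$min_orthogroups_per_comparison) {
    message(sprintf("skipping comparison %s vs %s in %s: %d < %d retained orthogroups",
                    focal, other, tissue, length(retained),
                    config$min_orthogroups_per_comparison))
    return(empty)
  }
  two_f <- two_copy[[focal]] %||% two_copy_orthogroups(orthogroups, focal)
  two_o <- two_copy[[other]] %||% two_copy_orthogroups(orthogroups, other)
  tf <- og_pair_totals(retained, two_f, mean_expression[[focal]], tissue)$total
  to <- og_pair_totals(retained, two_o, mean_expression[[other]], tissue)$total
  lr <- log2(tf / to)
  if (isTRUE(config$robust_z)) {
    ctr <- stats::median(lr)
    scl <- stats::mad(lr)
  } else {
    ctr <- mean(lr)
    scl <- stats::sd(lr)
  }
  if (!is.finite(scl) || scl == 0) {
    warning("zero spread of dosage ratios for ", focal, " vs ", other,
            " in ", tissue, "; all z set to 0", call. = FALSE)
    z <- rep(0, length(lr))
  } else {
    z <- (lr - ctr) / scl
  }
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(tissue = tissue, focal = focal, other = other,
             orthogroup_id = retained, total_focal = unname(tf),
             total_other = unname(to), log2_ratio = unname(lr),
             z = unname(z), p = unname(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort p ascending, set
#' `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1 and restore the original
#' order. Implemented directly because the adjustment is part of the
#' dosage-call contract; it is cross-checked against an independent oracle
#' in the test suite.
#'
#' @param p_values Numeric vector of p values in (0, 1\].
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Aggregate dosage comparisons into per-orthogroup calls
#'
#' For each (orthogroup, focal species, tissue), averages the p values over
#' all pairwise species comparisons in which that species is focal, applies
#' the Benjamini-Hochberg correction across orthogroups within each
#' (species, tissue), and calls an orthogroup dosage-unconstrained iff the
#' adjusted average p falls below `alpha` (and, when `config$z_min > 0`,
#' its largest |z| additionally reaches `z_min`). All other orthogroups are
#' assumed to evolve under constraint on total dosage.
#'
#' @param comparisons data.frame of pooled [dosage_comparisons()] rows
#'   (both orientations of every species pair).
#' @param config A `RunConfig` (`alpha`, `z_min`).
#' @return data.frame with one row per (orthogroup, species, tissue):
#'   `n_comparisons`, `mean_p`, `max_abs_z`, `adj_p`, `call`.
#' @export
aggregate_and_call <- function(comparisons, config = run_config()) {
  if (nrow(comparisons) == 0L) {
    return(data.frame(orthogroup_id = character(), species = character(),
                      tissue = character(), n_comparisons = integer(),
                      mean_p = numeric(), max_abs_z = numeric(),
                      adj_p = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(comparisons)
  agg <- dt[, list(n_comparisons = .N, mean_p = mean(p),
                   max_abs_z = max(abs(z))),
            by = list(orthogroup_id, species = focal, tissue)]
  agg[, adj_p := bh_adjust(mean_p), by = list(species, tissue)]
  agg[, call := ifelse(adj_p < config$alpha &
                         (config$z_min <= 0 | max_abs_z >= config$z_min),
                       "unconstrained", "constrained")]
  out <- as.data.frame(agg, stringsAsFactors = FALSE)
  out <- out[order(out$species, out$tissue, out$orthogroup_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full cross-species dosage-constraint test
#'
#' Enumerates every tissue shared by at least two species (tissues present
#' in fewer than two species are skipped automatically), builds both
#' orientations of each pairwise comparison, and aggregates into
#' per-(orthogroup, species, tissue) calls. A per-(orthogroup, species)
#' roll-up (`unconstrained` in any tissue implies `unconstrained`) is also
#' returned for convenience.
#'
#' @param mean_expression Named list of gene x tissue mean matrices.
#' @param orthogroups An `OrthogroupTable`.
#' @param config A `RunConfig`.
#' @return List with `comparisons`, `calls`, and `species_calls` (the
#'   any-tissue roll-up).
#' @export
dosage_test <- function(mean_expression, orthogroups,
                        config = run_config()) {
  species <- names(mean_expression)
  tissues_of <- lapply(mean_expression, colnames)
  all_tissues <- sort(unique(unlist(tissues_of)))
  two_copy <- lapply(stats::setNames(species, species), function(sp)
    two_copy_orthogroups(orthogroups, sp))
  comp <- list()
  for (tissue in all_tissues) {
    with_t <- species[vapply(tissues_of, function(tt) tissue %in% tt,
                             logical(1))]
    if (length(with_t) < 2L) next
    cmb <- utils::combn(sort(with_t), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      ret <- retained_orthogroups(tissue, a, b, mean_expression, orthogroups,
                                  two_copy)
      fwd <- dosage_comparisons(tissue, a, b, ret, mean_expression,
                                orthogroups, config, two_copy)
      if (nrow(fwd) == 0L) next
      rev <- fwd
      rev$focal <- fwd$other; rev$other <- fwd$focal
      rev$total_focal <- fwd$total_other; rev$total_other <- fwd$total_focal
      rev$log2_ratio <- -fwd$log2_ratio
      rev$z <- -fwd$z
      comp[[length(comp) + 1L]] <- rbind(fwd, rev)
    }
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    dosage_comparisons("", "", "", character(), mean_expression,
                       orthogroups, run_config(min_orthogroups_per_comparison = 2))
  calls <- aggregate_and_call(comparisons, config)
  species_calls <- if (nrow(calls)) {
    dt <- data.table::as.data.table(calls)
    sc <- dt[, list(call = if (any(call == "unconstrained"))
      "unconstrained" else "constrained",
      n_tissues = length(unique(tissue))),
      by = list(orthogroup_id, species)]
    as.data.frame(sc[order(species, orthogroup_id)], stringsAsFactors = FALSE)
  } else {
    data.frame(orthogroup_id = character(), species = character(),
               call = character(), n_tissues = integer(),
               stringsAsFactors = FALSE)
  }
  list(comparisons = comparisons, calls = calls,
       species_calls = species_calls)
}
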