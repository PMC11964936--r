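#' Enumerate within-species paralogue pairs from orthogroups
#'
#' All unordered combinations of genes of the same orthogroup within each
#' species become pair records; orthogroups with more than two copies in a
#' species contribute every combination.
#'
#' @param orthogroups An `OrthogroupTable`.
#' @param species Character vector of species to enumerate (default: all).
#' @param annotations Optional data.frame with columns `species`, `gene_a`,
#'   `gene_b` and any of `dup_type` (one of WGD, tandem, proximal,
#'   transposed, dispersed), `ka`, `ks`; merged onto pairs irrespective of
#'   gene order.
#' @return data.frame with columns `species`, `orthogroup_id`, `gene_a`,
#'   `gene_b` (sorted within pair), plus `dup_type`, `ka`, `ks` when
#'   annotations are given.
#' @export
paralogue_pairs <- function(orthogroups, species = NULL, annotations = NULL) {
  stopifnot(inherits(orthogroups, "OrthogroupTable"))
  sub <- orthogroups
  if (!is.null(species)) sub <- sub[sub$species %in% species, , drop = FALSE]
  key <- paste(sub$orthogroup_id, sub$species, sep = "\r")
  grp <- split(sub$gene_id, key)
  grp <- grp[lengths(grp) >= 2L]
  rows <- lapply(names(grp), function(k) {
    genes <- sort(grp[[k]])
    cmb <- utils::combn(genes, 2L)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(species = parts[2L], orthogroup_id = parts[1L],
               gene_a = cmb[1L, ], gene_b = cmb[2L, ],
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), orthogroup_id = character(),
               gene_a = character(), gene_b = character(),
               stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$species, pairs$orthogroup_id,
                       pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  if (!is.null(annotations)) {
    ann <- annotations
    k1 <- paste(ann$species, pmin(ann$gene_a, ann$gene_b),
                pmax(ann$gene_a, ann$gene_b))
    kp <- paste(pairs$species, pairs$gene_a, pairs$gene_b)
    idx <- match(kp, k1)
    for (col in intersect(c("dup_type", "ka", "ks"), names(ann))) {
      pairs[[col]] <- ann[[col]][idx]
    }
  }
  pairs
}

#' Pre-classification filter for a paralogue pair
#'
#' Reproduces the filtration funnel: a pair is `low_or_no_expression` if
#' either copy failed the greater-than-median expression subset;
#' `insufficient` if both copies pass but the pair has fewer than two
#' samples in which both are non-zero, or its network coexpression is
#' undefined; otherwise it is eligible for classification.
#'
#' @param gene_a,gene_b Gene IDs.
#' @param dataset The species' post-QC `ExpressionDataset`.
#' @param gene_subset Genes retained by [median_expression_subset()].
#' @param network Optional `CoexpressionNetwork` for the coexpression
#'   definedness check.
#' @return One of `"low_or_no_expression"`, `"insufficient"`, `"eligible"`.
#' @export
pair_filter <- function(gene_a, gene_b, dataset, gene_subset,
                        network = NULL) {
  if (!(gene_a %in% gene_subset) || !(gene_b %in% gene_subset)) {
    return("low_or_no_expression")
  }
  a <- dataset$values[gene_a, ]
  b <- dataset$values[gene_b, ]
  if (sum(a > 0 & b > 0) < 2L) return("insufficient")
  if (!is.null(network) &&
      is.na(pair_coexpression(network, gene_a, gene_b))) {
    return("insufficient")
  }
  "eligible"
}

#' Log2 fold-change statistics for a paralogue pair
#'
#' Over the samples in which both copies are non-zero (the log ratio is
#' undefined otherwise), computes `l_s = log2(a_s / b_s)` and summarizes
#' expression divergence by `mean_abs_l2fc = |mean(l)|` and `sd_l2fc`, the
#' sample standard deviation (n-1 denominator) of `l`. Both are invariant
#' to swapping the two copies.
#'
#' @param gene_a,gene_b Gene IDs.
#' @param dataset The species' `ExpressionDataset`.
#' @return List with `mean_abs_l2fc`, `sd_l2fc`, `n_samples_used`; the
#'   statistics are `NA` with `n_samples_used < 2` when fewer than two
#'   usable samples exist ("insufficient").
#' @export
fold_change_stats <- function(gene_a, gene_b, dataset) {
  a <- dataset$values[gene_a, ]
  b <- dataset$values[gene_b, ]
  use <- a > 0 & b > 0
  n <- sum(use)
  if (n < 2L) {
    return(list(mean_abs_l2fc = NA_real_, sd_l2fc = NA_real_,
                n_samples_used = n))
  }
  l <- log2(a[use] / b[use])
  list(mean_abs_l2fc = abs(mean(l)), sd_l2fc = stats::sd(l),
       n_samples_used = n)
}

#' Assign a paralogue pair to an expression-fate group
#'
#' The four groups partition pairs by their rank-standardized coexpression
#' and log2 fold-change statistics:
#' \describe{
#'   \item{I, dosage balanced}{coexpression > 0.9; mean < 1; s.d. < 1}
#'   \item{II, paralogue dominance}{coexpression > 0.9; mean >= 1; s.d. < 1}
#'   \item{III, specialized}{coexpression > 0.9; mean >= 1; s.d. >= 1}
#'   \item{IV, diverged}{coexpression < 0.5; mean >= 1; s.d. >= 1}
#' }
#' All inequalities are as stated (strict on coexpression, non-strict at 1
#' on the fold-change side for groups II-IV). Triples matching no rule —
#' e.g. coexpression in \[0.5, 0.9\], or low coexpression without fold
#' change — fall into the `threshold_gap` bucket with group `"none"`.
#'
#' @param coexpression Weight in \[0, 1\].
#' @param mean_abs_l2fc,sd_l2fc Fold-change statistics, see
#'   [fold_change_stats()].
#' @param config A `RunConfig` (thresholds `coexpr_high`, `coexpr_low`,
#'   `fc_mean`, `fc_sd`).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"none"`.
#' @export
classify_pair <- function(coexpression, mean_abs_l2fc, sd_l2fc,
                          config = run_config()) {
  if (is.na(coexpression) || is.na(mean_abs_l2fc) || is.na(sd_l2fc)) {
    return("none")
  }
  hi <- config$coexpr_high; lo <- config$coexpr_low
  fm <- config$fc_mean; fs <- config$fc_sd
  if (coexpression > hi) {
    if (mean_abs_l2fc < fm && sd_l2fc < fs) return("I")
    if (mean_abs_l2fc >= fm && sd_l2fc < fs) return("II")
    if (mean_abs_l2fc >= fm && sd_l2fc >= fs) return("III")
    return("none")  # mean < 1 with sd >= 1 under high coexpression
  }
  if (coexpression < lo && mean_abs_l2fc >= fm && sd_l2fc >= fs) return("IV")
  "none"
}

#' Classify all paralogue pairs and summarize the filtration funnel
#'
#' Runs the full per-pair pipeline: the low/insufficient filter, fold-change
#' statistics, network coexpression lookup and the group I-IV rules. Pairs
#' whose statistics are defined but match no rule are bucketed
#' `threshold_gap`. Buckets partition the input.
#'
#' @param pairs data.frame from [paralogue_pairs()].
#' @param datasets Named list of single-species post-QC `ExpressionDataset`s.
#' @param networks Named list of `CoexpressionNetwork`s per species; the
#'   network's gene set doubles as the median-expression subset.
#' @param config A `RunConfig`.
#' @return List with `records` (one row per pair: statistics, bucket,
#'   `group`) and `funnel` (list of per-bucket and per-group counts and
#'   fractions, including the share of classified pairs in groups I-III).
#' @export
classify_all <- function(pairs, datasets, networks, config = run_config()) {
  n <- nrow(pairs)
  coex <- mean_fc <- sd_fc <- rep(NA_real_, n)
  nsamp <- integer(n)
  bucket <- character(n)
  group <- rep("none", n)
  for (sp in unique(pairs$species)) {
    idx <- which(pairs$species == sp)
    ds <- datasets[[sp]]
    nw <- networks[[sp]]
    if (is.null(ds) || is.null(nw)) {
      stop("missing dataset or network for species ", sp, call. = FALSE)
    }
    ia <- match(pairs$gene_a[idx], rownames(ds$values))
    ib <- match(pairs$gene_b[idx], rownames(ds$values))
    if (anyNA(ia)) stop("gene absent from expression matrix: ",
                        pairs$gene_a[idx][which(is.na(ia))[1L]], call. = FALSE)
    if (anyNA(ib)) stop("gene absent from expression matrix: ",
                        pairs$gene_b[idx][which(is.na(ib))[1L]], call. = FALSE)
    va <- ds$values[ia, , drop = FALSE]
    vb <- ds$values[ib, , drop = FALSE]
    na_ <- match(pairs$gene_a[idx], nw$genes)
    nb_ <- match(pairs$gene_b[idx], nw$genes)
    in_subset <- !is.na(na_) & !is.na(nb_)
    nz <- (va > 0) & (vb > 0)
    n_used <- rowSums(nz)
    l2 <- log2(va / vb)
    l2[!nz] <- 0
    mean_l <- ifelse(n_used > 0, rowSums(l2) / n_used, NA_real_)
    ss <- rowSums(((l2 - mean_l) * nz)^2)
    sd_l <- ifelse(n_used >= 2, sqrt(ss / (n_used - 1)), NA_real_)
    w <- rep(NA_real_, length(idx))
    w[in_subset] <- nw$weights[cbind(na_[in_subset], nb_[in_subset])]
    bk <- ifelse(!in_subset, "low_or_no_expression",
                 ifelse(n_used < 2L | is.na(w), "insufficient", "eligible"))
    elig <- bk == "eligible"
    coex[idx] <- ifelse(elig, w, NA_real_)
    mean_fc[idx] <- ifelse(elig, abs(mean_l), NA_real_)
    sd_fc[idx] <- ifelse(elig, sd_l, NA_real_)
    nsamp[idx] <- ifelse(elig, n_used, 0L)
    g <- rep("none", length(idx))
    g[elig] <- vapply(which(elig), function(j)
      classify_pair(w[j], abs(mean_l[j]), sd_l[j], config), "")
    group[idx] <- g
    bucket[idx] <- ifelse(elig, ifelse(g == "none", "threshold_gap",
                                       "classified"), bk)
  }
  records <- cbind(pairs,
                   data.frame(coexpression = coex, mean_abs_l2fc = mean_fc,
                              sd_l2fc = sd_fc, n_samples_used = nsamp,
                              bucket = bucket, group = group,
                              stringsAsFactors = FALSE))
  list(records = records, funnel = funnel_summary(records))
}

funnel_summary <- function(records) {
  n <- nrow(records)
  buckets <- c("low_or_no_expression", "insufficient", "threshold_gap",
               "classified")
  bcount <- vapply(buckets, function(b) sum(records$bucket == b), 0L)
  groups <- c("I", "II", "III", "IV")
  gcount <- vapply(groups, function(g) sum(records$group == g), 0L)
  ncl <- bcount[["classified"]]
  list(n_pairs = n,
       bucket_counts = as.list(bcount),
       bucket_fractions = as.list(if (n) bcount / n else bcount * NA_real_),
       group_counts = as.list(gcount),
       group_fractions_of_classified =
         as.list(if (ncl) gcount / ncl else gcount * NA_real_),
       frac_classified_in_I_III =
         if (ncl) sum(gcount[c("I", "II", "III")]) / ncl else NA_real_)
}

#' Number of tissues in which both copies of a pair are expressed
#'
#' Intersects the expression breadths of the two copies: a tissue counts if
#' both genes exceed `breadth_tpm` replicate-mean TPM there. Ranges from 0
#' to the number of tissues.
#'
#' @param gene_a,gene_b Gene IDs.
#' @param mean_expression Gene x tissue replicate-mean matrix
#'   ([average_replicates()]).
#' @param breadth_tpm TPM threshold (strict >, default 3).
#' @return Integer count of shared expressed tissues.
#' @export
shared_expression_domains <- function(gene_a, gene_b, mean_expression,
                                      breadth_tpm = 3) {
  a <- mean_expression[gene_a, ]
  b <- mean_expression[gene_b, ]
  sum(a > breadth_tpm & b > breadth_tpm)
}

#' Stratify classified pairs by duplication origin within Ks windows
#'
#' Retains WGD pairs with Ks in the WGD window and tandem/proximal pairs in
#' the SSD window (closed intervals), then tabulates fate groups for WGD vs
#' SSD origin. Pairs without a Ks value are excluded from this summary only.
#'
#' @param records Classified pair records ([classify_all()]`$records`) with
#'   `dup_type` and `ks` columns.
#' @param config A `RunConfig` (`ks_wgd`, `ks_ssd` windows).
#' @return data.frame with columns `origin` (WGD/SSD), `group`, `n`.
#' @export
wgd_ssd_summary <- function(records, config = run_config()) {
  stopifnot(all(c("dup_type", "ks") %in% names(records)))
  r <- records[records$bucket == "classified" & !is.na(records$ks), ,
               drop = FALSE]
  wgd <- r$dup_type == "WGD" &
    r$ks >= config$ks_wgd[1L] & r$ks <= config$ks_wgd[2L]
  ssd <- r$dup_type %in% c("tandem", "proximal") &
    r$ks >= config$ks_ssd[1L] & r$ks <= config$ks_ssd[2L]
  out <- rbind(
    data.frame(origin = "WGD", group = r$group[which(wgd)],
               stringsAsFactors = FALSE),
    data.frame(origin = "SSD", group = r$group[which(ssd)],
               stringsAsFactors = FALSE))
  agg <- as.data.frame(table(origin = out$origin, group = out$group),
                       stringsAsFactors = FALSE)
  names(agg)[3L] <- "n"
  agg[order(agg$origin, agg$group), , drop = FALSE]
}
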