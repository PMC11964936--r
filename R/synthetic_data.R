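#' Simulation configuration
#'
#' Describes the synthetic multi-species, multi-tissue expression world the
#' generator emulates: a clade-scale RNA-seq resource with up to five
#' tissues and a few replicates per tissue, orthogroups containing
#' singletons and two-copy paralogue pairs, pairs planted in one of four
#' expression-fate modes, and orthogroup total dosage that is either
#' conserved across species or drifting. Expression is log-normal
#' throughout (positive values, multiplicative noise), matching the log2
#' fold-change analyses downstream.
#'
#' @param n_species Number of species (default 5).
#' @param tissues Tissue vocabulary (default the five profiled tissues:
#'   apex, cotyledon, hypocotyl, inflorescence, leaves).
#' @param n_replicates Biological replicates per (species, tissue)
#'   (default 3).
#' @param n_singletons Single-copy orthogroups shared by all species,
#'   emulating the genome background of mostly lower-expressed genes
#'   (default 2500, a slight majority of the gene population, as in real
#'   transcriptomes where most genes are expressed below the median of the
#'   genes under study).
#' @param n_pairs_per_mode Planted paralogue pairs per fate mode; a single
#'   number or a named vector over I-IV (default 200 each).
#' @param n_orthogroups_constrained,n_orthogroups_drift Additional two-copy
#'   orthogroups (equal-copy split) whose summed dosage is conserved across
#'   species, respectively escapes constraint in one randomly chosen
#'   species per orthogroup (defaults 100 and 25: most pairs evolve under
#'   dosage constraint).
#' @param dominance_delta Uniform log2 offset between copies in mode II
#'   (default 2).
#' @param specialization_delta_range Range (log2) from which the mode III/IV
#'   per-pair divergence targets are drawn uniformly; both the planted mean
#'   and planted spread of per-tissue offsets come from this range, so
#'   planted modes sit above the 1/1 classification thresholds and are
#'   recoverable by construction (default c(1.3, 2)).
#' @param drift_sd Log2 magnitude of the lineage-specific dosage multiplier
#'   of drift orthogroups (default 2: a 4-fold shift up or down in the
#'   drifted species).
#' @param noise_sd Log2 s.d. of multiplicative measurement noise per value
#'   (default 0.1).
#' @param replicate_sd Log2 s.d. of additional per-replicate biological
#'   noise per value (default 0.1).
#' @param base_expression_logmean,base_expression_logsd Log2 mean/s.d. of
#'   baseline gene expression (defaults 5 and 1, i.e. typically ~32 TPM).
#' @param tissue_sd Log2 s.d. of per-tissue expression deviations around a
#'   gene's baseline (default 3: expression varies strongly across organs,
#'   which both separates tissues in PCA and separates true coexpression
#'   partners from the background correlation noise floor).
#' @param n_tissue_specific Singleton genes planted as expressed in exactly
#'   one tissue (default 20).
#' @param n_pseudogenes Singleton genes planted as pseudogenes with trace
#'   expression (default 10).
#' @param seed Integer seed for the generator's RNG stream (default 1).
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_species = 5,
                       tissues = c("apex", "cotyledon", "hypocotyl",
                                   "inflorescence", "leaves"),
                       n_replicates = 3,
                       n_singletons = 2500,
                       n_pairs_per_mode = 200,
                       n_orthogroups_constrained = 100,
                       n_orthogroups_drift = 25,
                       dominance_delta = 2,
                       specialization_delta_range = c(1.3, 2),
                       drift_sd = 2,
                       noise_sd = 0.1,
                       replicate_sd = 0.1,
                       base_expression_logmean = 5,
                       base_expression_logsd = 1,
                       tissue_sd = 3,
                       n_tissue_specific = 20,
                       n_pseudogenes = 10,
                       seed = 1L) {
  if (length(n_pairs_per_mode) == 1L) {
    n_pairs_per_mode <- stats::setNames(rep(n_pairs_per_mode, 4L),
                                        c("I", "II", "III", "IV"))
  }
  stopifnot(all(c("I", "II", "III", "IV") %in% names(n_pairs_per_mode)))
  cfg <- list(n_species = as.integer(n_species), tissues = tissues,
              n_replicates = as.integer(n_replicates),
              n_singletons = as.integer(n_singletons),
              n_pairs_per_mode = n_pairs_per_mode[c("I", "II", "III", "IV")],
              n_orthogroups_constrained = as.integer(n_orthogroups_constrained),
              n_orthogroups_drift = as.integer(n_orthogroups_drift),
              dominance_delta = dominance_delta,
              specialization_delta_range = specialization_delta_range,
              drift_sd = drift_sd, noise_sd = noise_sd,
              replicate_sd = replicate_sd,
              base_expression_logmean = base_expression_logmean,
              base_expression_logsd = base_expression_logsd,
              tissue_sd = tissue_sd,
              n_tissue_specific = as.integer(n_tissue_specific),
              n_pseudogenes = as.integer(n_pseudogenes),
              seed = as.integer(seed))
  if (length(cfg$tissues) == 0L) stop("zero tissues", call. = FALSE)
  if (cfg$n_replicates < 1L) stop("zero replicates", call. = FALSE)
  counts <- c(cfg$n_species, cfg$n_singletons, cfg$n_pairs_per_mode,
              cfg$n_orthogroups_constrained, cfg$n_orthogroups_drift,
              cfg$n_tissue_specific, cfg$n_pseudogenes)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  sds <- c(cfg$drift_sd, cfg$noise_sd, cfg$replicate_sd,
           cfg$base_expression_logsd, cfg$tissue_sd)
  if (any(sds < 0)) stop("sds must be >= 0", call. = FALSE)
  structure(cfg, class = "SimConfig")
}

# center to sample mean 0 and, when possible, scale to sample sd 1
std0 <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Simulate a multi-species expression resource with planted truth
#'
#' Generates, for each species, a TPM matrix over tissues x replicates,
#' together with matching orthogroups, gene models on synthetic chromosomes
#' and a truth table of every planted label. All species share each
#' orthogroup's underlying tissue profile, so constrained orthogroups
#' conserve summed dosage across species up to noise, while each drift
#' orthogroup escapes the ancestral total in one randomly chosen species
#' via a fixed 2^drift_sd-fold multiplier on both copies.
#'
#' Per pair (log2 scale, per tissue): copy A carries the orthogroup profile;
#' mode I sets copy B equal to A; mode II offsets B by a uniform
#' `dominance_delta`; mode III offsets B per tissue by planted offsets whose
#' sample mean and spread are drawn above the classification thresholds;
#' mode IV gives B a profile anti-correlated with A (reciprocal tissue
#' usage) with a planted mean offset, so the planted group is recoverable
#' at default thresholds — a separability assumption, not a biological
#' claim. Replicate and measurement noise are multiplicative (log-normal)
#' per value. Pairs are laid out on synthetic chromosomes as tandem
#' (adjacent), proximal (2-10 genes apart) and dispersed
#' (different chromosomes) duplicates in a 1:1:2 rotation.
#'
#' @param config A [sim_config()].
#' @return List with `datasets` (named list of per-species
#'   `ExpressionDataset`s), `orthogroups` (`OrthogroupTable`),
#'   `gene_models` (named list of per-species `GeneModels`), `truth` (list
#'   of data.frames `pairs`, `dosage`, `genes`) and `config`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  tissues <- config$tissues
  nt <- length(tissues)
  species <- sprintf("sp%02d", seq_len(config$n_species))

  modes <- rep(c("I", "II", "III", "IV"), times = config$n_pairs_per_mode)
  regimes <- c(rep("constrained", config$n_orthogroups_constrained),
               rep("drift", config$n_orthogroups_drift))
  n_pair_og <- length(modes) + length(regimes)
  n_single <- config$n_singletons + config$n_tissue_specific +
    config$n_pseudogenes
  og_ids <- sprintf("OG%06d", seq_len(n_pair_og + n_single))
  pair_ogs <- og_ids[seq_len(n_pair_og)]
  single_ogs <- og_ids[n_pair_og + seq_len(n_single)]
  pair_mode <- c(modes, rep(NA_character_, length(regimes)))
  pair_regime <- c(rep("constrained", length(modes)), regimes)
  single_kind <- rep(c("regular", "tissue_specific", "pseudogene"),
                     times = c(config$n_singletons, config$n_tissue_specific,
                               config$n_pseudogenes))

  # orthogroup-level profiles, shared across species (log2)
  prof <- profile_pair_ogs(config, pair_mode, nt)
  sprof <- profile_single_ogs(config, single_kind, nt)

  # lineage-specific dosage drift: each drift orthogroup escapes the
  # ancestral total in exactly one randomly chosen species, where both
  # copies are shifted by +/- drift_sd log2 (a fixed-magnitude multiplier;
  # diffuse zero-mean drift would be partially indistinguishable from
  # constraint by construction)
  drift_shift <- matrix(0, n_pair_og, config$n_species,
                        dimnames = list(pair_ogs, species))
  is_drift <- which(pair_regime == "drift")
  if (length(is_drift) && config$n_species > 0L) {
    drifted_sp <- sample.int(config$n_species, length(is_drift),
                             replace = TRUE)
    sign <- sample(c(-1, 1), length(is_drift), replace = TRUE)
    drift_shift[cbind(is_drift, drifted_sp)] <- sign * config$drift_sd
  }

  layout <- pair_layout(pair_ogs)

  sheet_t <- rep(tissues, each = config$n_replicates)
  sheet_r <- rep(seq_len(config$n_replicates), times = nt)
  cell_sd <- sqrt(config$noise_sd^2 + config$replicate_sd^2)

  datasets <- list()
  models <- list()
  og_rows <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    gene_a <- paste0(sp, "_", pair_ogs, "_A")
    gene_b <- paste0(sp, "_", pair_ogs, "_B")
    gene_s <- paste0(sp, "_", single_ogs, "_S")
    genes <- c(gene_a, gene_b, gene_s)
    # expected log2 expression per gene x tissue
    lmat <- rbind(prof$a + drift_shift[, si],
                  prof$b + drift_shift[, si],
                  sprof)
    rownames(lmat) <- genes
    # deterministic per-species noise sub-stream
    set.seed((config$seed %% 1000003L) * 1000L + si)
    expand <- lmat[, rep(seq_len(nt), each = config$n_replicates),
                   drop = FALSE]
    if (cell_sd > 0) {
      expand <- expand + stats::rnorm(length(expand), 0, cell_sd)
    }
    tpm <- 2^expand
    colnames(tpm) <- paste(sp, sheet_t, paste0("r", sheet_r), sep = "_")
    sheet <- data.frame(sample_id = colnames(tpm), species = sp,
                        tissue = sheet_t, replicate = sheet_r,
                        pct_uniquely_mapped = 95,
                        stringsAsFactors = FALSE)
    datasets[[sp]] <- expression_dataset(tpm, sheet)
    models[[sp]] <- place_genes(sp, layout, gene_a, gene_b, gene_s,
                                gene_s[single_kind == "pseudogene"])
    og_rows[[sp]] <- data.frame(
      orthogroup_id = c(pair_ogs, pair_ogs, single_ogs),
      species = sp, gene_id = genes, stringsAsFactors = FALSE)
  }
  orthogroups <- orthogroup_table(do.call(rbind, og_rows), species = species)

  truth_pairs <- data.frame(orthogroup_id = pair_ogs, mode = pair_mode,
                            dup_type = layout$dup_type[pair_ogs],
                            stringsAsFactors = FALSE)
  truth_dosage <- expand.grid(orthogroup_id = pair_ogs, species = species,
                              stringsAsFactors = FALSE)
  truth_dosage$constraint <- ifelse(
    drift_shift[cbind(match(truth_dosage$orthogroup_id, pair_ogs),
                      match(truth_dosage$species, species))] != 0,
    "drift", "constrained")
  truth_genes <- do.call(rbind, lapply(species, function(sp) {
    data.frame(
      gene_id = paste0(sp, "_", single_ogs, "_S"),
      species = sp,
      planted_kind = single_kind,
      planted_tissue_specific = ifelse(single_kind == "tissue_specific",
                                       sprof_attr(sprof, "specific_tissue"),
                                       NA_character_),
      planted_functional = single_kind != "pseudogene",
      stringsAsFactors = FALSE)
  }))
  rownames(truth_genes) <- NULL

  list(datasets = datasets, orthogroups = orthogroups, gene_models = models,
       truth = list(pairs = truth_pairs, dosage = truth_dosage,
                    genes = truth_genes),
       config = config)
}

# log2 per-tissue profiles of both copies of every pair orthogroup
profile_pair_ogs <- function(config, pair_mode, nt) {
  n <- length(pair_mode)
  a <- b <- matrix(0, n, nt)
  rng <- config$specialization_delta_range
  for (i in seq_len(n)) {
    mu <- stats::rnorm(1, config$base_expression_logmean,
                       config$base_expression_logsd)
    dev <- stats::rnorm(nt, 0, config$tissue_sd)
    total <- mu + dev
    mode <- pair_mode[i]
    if (is.na(mode) || mode == "I") {
      a[i, ] <- total - 1
      b[i, ] <- total - 1
    } else if (mode == "II") {
      d <- config$dominance_delta
      a[i, ] <- total - log2(1 + 2^(-d))
      b[i, ] <- a[i, ] - d
    } else if (mode == "III") {
      # dampened copy: B follows A's tissue profile with compressed dynamic
      # range, so the pair stays monotonically related (high coexpression)
      # while the per-tissue offset has planted sample mean dm and spread ds
      dm <- stats::runif(1, rng[1L], rng[2L])
      ds <- stats::runif(1, rng[1L], rng[2L])
      dev_std <- std0(dev)
      total <- mu + config$tissue_sd * dev_std
      delta <- dm + ds * dev_std
      a[i, ] <- total - log2(1 + 2^(-delta))
      b[i, ] <- a[i, ] - delta
    } else { # IV: anti-correlated reciprocal tissue usage
      dm <- stats::runif(1, rng[1L], rng[2L])
      dev0 <- dev - mean(dev)
      eps <- std0(stats::rnorm(nt)) * config$tissue_sd / 4
      l <- dm + 2 * dev0 + (eps - mean(eps))
      a[i, ] <- total - 1
      b[i, ] <- a[i, ] - l
    }
    # planted pairs emulate pairs that survive the expression funnel: lift
    # the pair (both copies equally, preserving fold change, correlation
    # and cross-species dosage) until each copy peaks at or above the
    # baseline log-mean, which sits well clear of the per-sample median of
    # the genome background
    lift <- max(0, config$base_expression_logmean -
                  min(max(a[i, ]), max(b[i, ])))
    a[i, ] <- a[i, ] + lift
    b[i, ] <- b[i, ] + lift
  }
  list(a = a, b = b)
}

# log2 per-tissue profiles of singleton orthogroup genes
profile_single_ogs <- function(config, single_kind, nt) {
  n <- length(single_kind)
  out <- matrix(0, n, nt)
  specific <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mu <- stats::rnorm(1, config$base_expression_logmean,
                       config$base_expression_logsd)
    kind <- single_kind[i]
    if (kind == "regular") {
      # genome background: broadly spread and lower-expressed on average
      # than the retained, expressed paralogues under study; keeps the
      # per-sample median realistic for the greater-than-median subset
      mu_bg <- stats::rnorm(1, config$base_expression_logmean - 3, 2)
      out[i, ] <- mu_bg + stats::rnorm(nt, 0, config$tissue_sd)
    } else if (kind == "tissue_specific") {
      t_star <- sample.int(nt, 1L)
      out[i, ] <- -4
      out[i, t_star] <- max(mu, log2(5) + 2)  # well above the 5-TPM call
      specific[i] <- config$tissues[t_star]
    } else { # pseudogene: trace expression
      out[i, ] <- -3 + stats::rnorm(nt, 0, 0.2)
    }
  }
  attr(out, "specific_tissue") <- specific
  out
}

sprof_attr <- function(sprof, what) attr(sprof, what)

# chromosomal layout shared by all species: tandem blocks (adjacent),
# proximal blocks (index distance 2..10), dispersed across chromosomes
pair_layout <- function(pair_ogs) {
  n <- length(pair_ogs)
  dup_type <- rep(c("tandem", "proximal", "dispersed", "dispersed"),
                  length.out = n)
  names(dup_type) <- pair_ogs
  prox <- pair_ogs[dup_type == "proximal"]
  # group proximal pairs into blocks of g pairs (A1..Ag B1..Bg), so each
  # pair in a block of size g sits exactly g genes apart; g cycles 2..10
  blocks <- list()
  i <- 1L; g <- 2L
  while (i <= length(prox)) {
    take <- min(g, length(prox) - i + 1L)
    if (take == 1L) {
      # a lone trailing pair cannot form a block of >=2: pad with distance 2
      blocks[[length(blocks) + 1L]] <- list(ogs = prox[i], gap = 2L)
    } else {
      blocks[[length(blocks) + 1L]] <- list(ogs = prox[i:(i + take - 1L)],
                                            gap = take)
    }
    i <- i + take
    g <- if (g >= 10L) 2L else g + 1L
  }
  list(dup_type = dup_type, proximal_blocks = blocks)
}

place_genes <- function(sp, layout, gene_a, gene_b, gene_s,
                        pseudo_genes = character()) {
  dup <- layout$dup_type
  ogs <- names(dup)
  a_of <- stats::setNames(gene_a, ogs)
  b_of <- stats::setNames(gene_b, ogs)
  chr1 <- character()
  for (og in ogs[dup == "tandem"]) chr1 <- c(chr1, a_of[[og]], b_of[[og]])
  for (blk in layout$proximal_blocks) {
    if (length(blk$ogs) == 1L) {
      # single pair at distance 2: insert one singleton-slot placeholder later
      chr1 <- c(chr1, a_of[[blk$ogs]], paste0(sp, "_FILLER"), b_of[[blk$ogs]])
    } else {
      chr1 <- c(chr1, unname(a_of[blk$ogs]), unname(b_of[blk$ogs]))
    }
  }
  disp <- ogs[dup == "dispersed"]
  chr2 <- unname(a_of[disp])
  chr3 <- unname(b_of[disp])
  # singletons fill chromosome 1's tail (and replace the filler slot)
  singles <- gene_s
  fill <- which(chr1 == paste0(sp, "_FILLER"))
  if (length(fill)) {
    if (length(singles) == 0L) stop("need >=1 singleton as proximal filler",
                                    call. = FALSE)
    chr1[fill] <- singles[1L]
    singles <- singles[-1L]
  }
  chr1 <- c(chr1, singles)
  build <- function(chr, ids) {
    if (length(ids) == 0L) return(NULL)
    data.frame(gene_id = ids, chromosome = chr,
               start = seq_along(ids) * 10000L + 1L,
               end = seq_along(ids) * 10000L + 2001L,
               strand = "+", stringsAsFactors = FALSE)
  }
  df <- rbind(build(paste0(sp, "_chr1"), chr1),
              build(paste0(sp, "_chr2"), chr2),
              build(paste0(sp, "_chr3"), chr3))
  df$pseudogene_flag <- df$gene_id %in% pseudo_genes
  gene_models(df)
}

#' Summarize a truth table
#'
#' Independent recount of the planted labels: pairs per fate mode,
#' orthogroup x species constraint labels, and gene-level planted flags.
#'
#' @param truth The `truth` element of [simulate_expression()] output.
#' @return List with `mode_counts`, `constraint_counts` and `gene_counts`
#'   (named integer vectors).
#' @export
summarize_truth <- function(truth) {
  modes <- truth$pairs$mode[!is.na(truth$pairs$mode)]
  mode_counts <- vapply(c("I", "II", "III", "IV"),
                        function(m) sum(modes == m), 0L)
  cons <- truth$dosage$constraint
  constraint_counts <- vapply(c("constrained", "drift"),
                              function(x) sum(cons == x), 0L)
  kinds <- truth$genes$planted_kind
  gene_counts <- vapply(c("regular", "tissue_specific", "pseudogene"),
                        function(k) sum(kinds == k), 0L)
  list(mode_counts = mode_counts, constraint_counts = constraint_counts,
       gene_counts = gene_counts)
}
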