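#' Analysis run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults are the operating point of the published analysis workflow this
#' package implements:
#' \describe{
#'   \item{spearman_min}{replicate Spearman rho at or below which a sample is
#'     removed (0.75).}
#'   \item{coexpr_high, coexpr_low}{rank-standardized coexpression cut-offs
#'     separating correlated (groups I-III, > 0.9) from diverged
#'     (group IV, < 0.5) pairs.}
#'   \item{fc_mean, fc_sd}{log2 fold-change mean and s.d. thresholds (1, 1).}
#'   \item{breadth_tpm}{TPM above which a tissue counts towards expression
#'     breadth (3).}
#'   \item{tau_min, tissue_specific_tpm}{tau and TPM cut-offs for calling a
#'     gene tissue-specific (0.7, 5).}
#'   \item{functional_tpm}{mean TPM below which a non-pseudogene is still
#'     called non-functional (3).}
#'   \item{alpha}{BH-adjusted average-p threshold below which an orthogroup
#'     is called dosage-unconstrained (0.05).}
#'   \item{proximal_max_gap}{maximum gene-index distance for a proximal
#'     duplication (10); distance 1 is tandem.}
#'   \item{ks_wgd, ks_ssd}{closed Ks intervals retaining WGD
#'     (\[0.2, 2.5\]) and tandem/proximal (\[0.05, 2.5\]) pairs in the
#'     duplication-age-stratified summary.}
#'   \item{min_orthogroups_per_comparison}{minimum retained orthogroups for a
#'     (tissue, species pair) dosage comparison (3).}
#'   \item{z_min}{optional additional |z| cut-off for the dosage call; `0`
#'     (default) disables it and the call rests on the adjusted p alone.}
#'   \item{robust_z}{use median/MAD instead of mean/sd when z-scoring dosage
#'     ratios (default FALSE).}
#'   \item{sim_*}{sizes and noise level forwarded to [sim_config()] by the
#'     CLI `simulate` stage, so pipeline runs can be scaled.}
#' }
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    spearman_min = 0.75,
    coexpr_high = 0.9,
    coexpr_low = 0.5,
    fc_mean = 1,
    fc_sd = 1,
    breadth_tpm = 3,
    tau_min = 0.7,
    tissue_specific_tpm = 5,
    functional_tpm = 3,
    alpha = 0.05,
    proximal_max_gap = 10,
    ks_wgd = c(0.2, 2.5),
    ks_ssd = c(0.05, 2.5),
    min_orthogroups_per_comparison = 3,
    min_pct_mapped = 50,
    z_min = 0,
    robust_z = FALSE,
    sim_n_species = 5,
    sim_n_replicates = 3,
    sim_n_singletons = 2500,
    sim_n_pairs_per_mode = 200,
    sim_n_orthogroups_constrained = 100,
    sim_n_orthogroups_drift = 25,
    sim_n_tissue_specific = 20,
    sim_n_pseudogenes = 10,
    sim_noise_sd = 0.1,
    seed = 1L,
    out_dir = "."
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what, call. = FALSE)
  chk(cfg$spearman_min >= -1 && cfg$spearman_min <= 1, "spearman_min in [-1,1]")
  chk(cfg$coexpr_low <= cfg$coexpr_high, "coexpr_low <= coexpr_high")
  chk(cfg$coexpr_high <= 1 && cfg$coexpr_low >= 0, "coexpression cutoffs in [0,1]")
  chk(cfg$fc_mean >= 0 && cfg$fc_sd >= 0, "fold-change thresholds >= 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha in (0,1)")
  chk(cfg$proximal_max_gap >= 1, "proximal_max_gap >= 1")
  chk(length(cfg$ks_wgd) == 2 && length(cfg$ks_ssd) == 2, "Ks windows length 2")
  chk(cfg$min_orthogroups_per_comparison >= 2, "min orthogroups >= 2")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a flat key-value file
#'
#' Accepts a flat TOML-like `key = value` or YAML-like `key: value` file.
#' Array values use `[a, b]`; strings may be quoted; `#` starts a comment.
#' Keys absent from the file keep their defaults, so a partial file is a
#' valid override set. CLI flags override the file, the file overrides
#' defaults.
#'
#' @param path Path to the config file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
    out[[m[2L]]] <- parse_config_value(trimws(m[3L]))
  }
  do.call(run_config, out)
}

parse_config_value <- function(v) {
  if (grepl("^\\[.*\\]$", v)) {
    parts <- trimws(strsplit(substr(v, 2L, nchar(v) - 1L), ",")[[1L]])
    return(vapply(parts, function(p) parse_config_value(p), numeric(1),
                  USE.NAMES = FALSE))
  }
  if (grepl('^".*"$', v)) return(substr(v, 2L, nchar(v) - 1L))
  if (v %in% c("true", "TRUE", "True")) return(TRUE)
  if (v %in% c("false", "FALSE", "False")) return(FALSE)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Write a run configuration as a flat key = value file
#'
#' Round-trips losslessly through [read_run_config()].
#'
#' @param cfg A `RunConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- function(x) {
    if (is.character(x)) return(paste0('"', x, '"'))
    if (is.logical(x)) return(tolower(as.character(x)))
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (length(v) > 1L) {
      sprintf("%s = [%s]", k, paste(vapply(v, fmt, ""), collapse = ", "))
    } else {
      sprintf("%s = %s", k, fmt(v))
    }
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Stable hash of a config for the run summary (md5 of its serialized text).
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".cfg")
  on.exit(unlink(tf))
  write_run_config(cfg, tf)
  unname(tools::md5sum(tf))
}
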