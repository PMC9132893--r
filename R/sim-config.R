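#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort generator. The defaults
#' define the reference study conditions used throughout the test suite:
#' a 200-gene panel of compact 6-TM channel-like proteins, two cancer types
#' with 50 tumor / 50 normal samples each, 20 genes with a 3-fold mutation
#' rate multiplier inside TM intervals, a background rate of ~50 mutations
#' per gene, planted differential expression at |log2 effect| = 2, a
#' survival hazard multiplier of 2 for genetically altered patients, and
#' ten gene-drug pairs planted at Spearman rho 0.6 across 500 cell lines
#' with 10% missing IC50 values.
#'
#' @param seed integer; master seed. Each generator derives its own
#'   independent stream from `seed` plus a fixed op-specific offset, so
#'   adding a generator call never perturbs another's draws.
#' @param n_genes number of panel genes to simulate.
#' @param n_cancer_types number of cancer types.
#' @param n_tumor,n_normal tumor/normal samples per cancer type.
#' @param gene_length_range protein length range (residues), sampled
#'   uniformly.
#' @param n_tm_intervals,tm_interval_length TM annotation of each simulated
#'   gene: number of non-overlapping intervals (0-8) and their length.
#' @param background_mutation_rate somatic mutations per residue per cohort;
#'   a gene's expected non-TM mutation count is `rate * (L - L_TR)`.
#' @param tm_enrichment_genes character vector of genes whose TM intervals
#'   mutate at `tm_rate_multiplier` times the background rate. The default
#'   `NULL` resolves to the first `n_enriched_genes` simulated genes.
#' @param n_enriched_genes number of TM-enriched genes when
#'   `tm_enrichment_genes` is `NULL`.
#' @param tm_rate_multiplier dimensionless rate multiplier (>= 0) inside TM
#'   intervals of enriched genes.
#' @param p_deleterious_tm,p_deleterious_other probability that a mutation is
#'   SIFT-deleterious / PolyPhen-damaging, by region.
#' @param cadd_mean_tm,cadd_mean_other,cadd_sd CADD score distribution by
#'   region (normal, truncated at 0).
#' @param p_nonsynonymous,p_silent variant-class probabilities (remainder is
#'   class "other", which carries no protein position).
#' @param cnv_gain_prob,cnv_loss_prob per-gene per-sample probabilities of
#'   any gain (+1/+2) or any loss (-1/-2); one third of events are
#'   high-level (|value| = 2).
#' @param expr_mean_log2,expr_mean_sd,expr_sd log2-FPKM model: gene means
#'   are N(`expr_mean_log2`, `expr_mean_sd`), within-gene spread is
#'   N(0, `expr_sd`).
#' @param de_genes named numeric vector of planted tumor log2 effects
#'   (names are gene symbols); `NULL` resolves to 10 genes at +2 and 10 at
#'   -2 (after the TM-enriched block).
#' @param module_size,module_loading co-expression module planted for
#'   pathway-recovery tests: `module_size` genes share a latent factor with
#'   the module anchor gene at loading `module_loading`.
#' @param proliferation_gene symbol of the designated proliferation marker
#'   (its expression tracks a latent proliferation factor).
#' @param altered_fraction fraction of patients assigned `altered` status in
#'   the integrated cohort of [sim_cohort()]. The clinical arm receives its
#'   own planted label because a desk-scale cohort dense enough for the
#'   region-enrichment statistics saturates any alteration rule derived
#'   from its own mutations.
#' @param hazard_multiplier_altered hazard ratio of altered vs unaltered
#'   patients (> 0).
#' @param base_hazard baseline exponential event hazard per day.
#' @param censor_horizon independent censoring times are U(0, horizon) days.
#' @param hypoxia_shift,tmb_ratio,stage_odds_shift clinical covariate shifts
#'   for altered patients: additive shift of the (unit-variance) hypoxia
#'   score, multiplicative shift of the Poisson TMB mean, and
#'   proportional-odds multiplier for stage/grade. The magnitudes are
#'   placeholders (no published effect sizes exist for these contrasts).
#' @param tmb_mean Poisson mean of the drawn TMB covariate in unaltered
#'   patients.
#' @param n_drugs,n_cell_lines IC50 matrix dimensions.
#' @param planted_drug_pairs data.frame with columns `gene`, `drug`, `rho`
#'   (|rho| < 1): gene-drug pairs generated from a Gaussian copula at the
#'   stated Spearman rho; `NULL` resolves to 10 pairs at rho 0.6.
#' @param missing_fraction MCAR missing fraction of the IC50 matrix, in
#'   \[0, 0.3) by default so no drug trips the 30% removal filter unless
#'   requested per drug via `extra_missing_drugs`.
#' @param extra_missing_drugs named numeric vector: per-drug missing
#'   fractions overriding `missing_fraction` (may exceed 0.3 to exercise the
#'   removal filter).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_cancer_types = 2L,
                       n_tumor = 50L,
                       n_normal = 50L,
                       gene_length_range = c(500L, 900L),
                       n_tm_intervals = 7L,
                       tm_interval_length = 23L,
                       background_mutation_rate = 50 / 700,
                       tm_enrichment_genes = NULL,
                       n_enriched_genes = 20L,
                       tm_rate_multiplier = 3,
                       p_deleterious_tm = 0.5,
                       p_deleterious_other = 0.25,
                       cadd_mean_tm = 20,
                       cadd_mean_other = 15,
                       cadd_sd = 5,
                       p_nonsynonymous = 0.7,
                       p_silent = 0.25,
                       cnv_gain_prob = 0.15,
                       cnv_loss_prob = 0.15,
                       expr_mean_log2 = 3,
                       expr_mean_sd = 1.5,
                       expr_sd = 1,
                       de_genes = NULL,
                       module_size = 30L,
                       module_loading = 0.8,
                       proliferation_gene = "MKI67",
                       altered_fraction = 0.5,
                       hazard_multiplier_altered = 2,
                       base_hazard = 1 / 1000,
                       censor_horizon = 2000,
                       hypoxia_shift = 1,
                       tmb_ratio = 2,
                       tmb_mean = 10,
                       stage_odds_shift = 2,
                       n_drugs = 50L,
                       n_cell_lines = 500L,
                       planted_drug_pairs = NULL,
                       missing_fraction = 0.1,
                       extra_missing_drugs = NULL) {
  cfg <- as.list(environment())

  counts <- c("n_genes", "n_cancer_types", "n_tumor", "n_normal",
              "n_drugs", "n_cell_lines", "module_size")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1)
      stop("configuration error: ", nm, " must be a positive count")
  if (n_cell_lines < 10L)
    stop("configuration error: n_cell_lines must be >= 10")
  if (tm_rate_multiplier < 0)
    stop("configuration error: tm_rate_multiplier must be >= 0")
  if (background_mutation_rate < 0)
    stop("configuration error: background_mutation_rate must be >= 0")
  if (hazard_multiplier_altered <= 0)
    stop("configuration error: hazard_multiplier_altered must be > 0")
  if (expr_sd <= 0 || expr_mean_sd < 0)
    stop("configuration error: expression dispersion must be positive")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("configuration error: missing_fraction must be in [0, 1)")
  if (altered_fraction <= 0 || altered_fraction >= 1)
    stop("configuration error: altered_fraction must be in (0, 1)")
  if (cnv_gain_prob < 0 || cnv_loss_prob < 0 ||
      cnv_gain_prob > 1 || cnv_loss_prob > 1 ||
      cnv_gain_prob + cnv_loss_prob > 1)
    stop("configuration error: CNV gain/loss probabilities must lie in [0,1] and sum to <= 1")
  if (n_tm_intervals < 0L || n_tm_intervals > 8L)
    stop("configuration error: n_tm_intervals must be in 0..8")
  if (n_tm_intervals > 0 &&
      (n_tm_intervals * (tm_interval_length + 1)) > gene_length_range[1])
    stop("configuration error: requested TM intervals exceed protein length")
  if (!is.null(planted_drug_pairs)) {
    stopifnot(is.data.frame(planted_drug_pairs),
              all(c("gene", "drug", "rho") %in% names(planted_drug_pairs)))
    if (any(abs(planted_drug_pairs$rho) >= 1))
      stop("configuration error: |rho| of planted drug pairs must be < 1")
  }
  gene_names <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(cfg$tm_enrichment_genes))
    cfg$tm_enrichment_genes <- gene_names[seq_len(min(n_enriched_genes, n_genes))]
  if (is.null(cfg$de_genes)) {
    n_up <- min(10L, n_genes)
    idx_up <- seq_len(n_up) + min(n_enriched_genes, max(0L, n_genes - 20L))
    idx_up <- idx_up[idx_up <= n_genes]
    idx_dn <- idx_up + n_up
    idx_dn <- idx_dn[idx_dn <= n_genes]
    cfg$de_genes <- stats::setNames(
      c(rep(2, length(idx_up)), rep(-2, length(idx_dn))),
      gene_names[c(idx_up, idx_dn)])
  }
  cfg$gene_names <- gene_names
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (seed ", x$seed, "): ", x$n_genes, " genes, ",
      x$n_cancer_types, " cancer types x ", x$n_tumor, "T/", x$n_normal, "N, ",
      length(x$tm_enrichment_genes), " TM-enriched genes (x",
      x$tm_rate_multiplier, "), ", x$n_drugs, " drugs x ", x$n_cell_lines,
      " cell lines\n", sep = "")
  invisible(x)
}

# One pseudo-random stream per generator op: seed derived from the master
# seed plus an op offset, kept below 2^31. Restores the caller's RNG state.
with_op_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(((as.integer(seed) %% 1000003L) * 2039L + as.integer(offset)) %%
             2147483647L)
  force(code)
}

.op_offsets <- c(panel = 11L, mutations = 23L, cnv = 37L, expression = 41L,
                 clinical = 53L, drugs = 67L, sets = 79L, status = 83L)
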