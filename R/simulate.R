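#' Simulate a gene panel
#'
#' Generates a panel of channel-like proteins: lengths uniform over
#' `config$gene_length_range`, each annotated with `config$n_tm_intervals`
#' non-overlapping transmembrane intervals of `config$tm_interval_length`
#' residues, evenly spaced over the protein. Families are assigned
#' round-robin over six labels so family-level summaries are exercisable.
#'
#' @param config [sim_config()].
#' @return A [gene_panel].
#' @export
sim_gene_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_op_seed(config$seed, .op_offsets[["panel"]], {
    n <- config$n_genes
    len <- round(stats::runif(n, config$gene_length_range[1],
                              config$gene_length_range[2]))
    fams <- paste0("FAM", 1:6)
    genes <- data.frame(symbol = config$gene_names,
                        family = fams[(seq_len(n) - 1L) %% 6L + 1L],
                        length = len, stringsAsFactors = FALSE)
    iv <- NULL
    k <- config$n_tm_intervals
    if (k > 0L) {
      w <- config$tm_interval_length
      iv <- do.call(rbind, lapply(seq_len(n), function(i) {
        L <- len[i]
        # even placement with at least one residue between intervals
        starts <- round(seq(1, L - w + 1, length.out = k))
        data.frame(gene = genes$symbol[i], start = starts,
                   end = starts + w - 1L, stringsAsFactors = FALSE)
      }))
    }
    gene_panel(genes, iv)
  })
}

#' Simulate a somatic mutation table
#'
#' Per-gene mutation counts are Poisson with region-specific rates: the
#' background rate per residue outside TM intervals, and the background rate
#' times `config$tm_rate_multiplier` inside TM intervals of
#' `config$tm_enrichment_genes`. Positions are uniform within their region,
#' so for an enriched gene the expected TM fraction of mutations is
#' `m*f / (m*f + (1-f))` with `f = L_TR/L_g`. Each record carries a variant
#' class, SIFT/PolyPhen labels and a CADD score whose distributions may
#' differ by region; class "other" records (splice-like) carry no protein
#' position.
#'
#' @param panel [gene_panel].
#' @param config [sim_config()].
#' @return data.frame of class `mutation_table` with columns `sample`,
#'   `cancer_type`, `gene`, `protein_pos`, `variant_class`, `sift`,
#'   `polyphen`, `cadd`.
#' @export
sim_mutations <- function(panel, config) {
  stopifnot(inherits(panel, "gene_panel"), inherits(config, "sim_config"))
  if (any(panel$genes$length <= 0)) stop("generation error: zero-length protein")
  with_op_seed(config$seed, .op_offsets[["mutations"]], {
    g <- panel$genes
    rate <- config$background_mutation_rate
    mult <- ifelse(g$symbol %in% config$tm_enrichment_genes,
                   config$tm_rate_multiplier, 1)
    n_out <- stats::rpois(nrow(g), rate * (g$length - g$tm_length))
    n_in <- stats::rpois(nrow(g), rate * mult * g$tm_length)

    samples <- sim_sample_ids(config)
    tumor_ids <- samples$sample[samples$tumor]
    tumor_type <- stats::setNames(samples$cancer_type[samples$tumor], tumor_ids)

    recs <- lapply(seq_len(nrow(g)), function(i) {
      ni <- n_in[i]; no <- n_out[i]
      if (ni + no == 0L) return(NULL)
      pos <- c(sample_tm_positions(panel, g$symbol[i], ni),
               sample_non_tm_positions(panel, g$symbol[i], no))
      data.frame(gene = g$symbol[i], protein_pos = pos,
                 in_tm = rep(c(TRUE, FALSE), c(ni, no)),
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) {
      out <- data.frame(sample = character(), cancer_type = character(),
                        gene = character(), protein_pos = integer(),
                        variant_class = character(), sift = character(),
                        polyphen = character(), cadd = numeric(),
                        stringsAsFactors = FALSE)
      class(out) <- c("mutation_table", "data.frame")
      return(out)
    }
    m <- nrow(recs)
    recs$sample <- sample(tumor_ids, m, replace = TRUE)
    recs$cancer_type <- unname(tumor_type[recs$sample])
    u <- stats::runif(m)
    recs$variant_class <- ifelse(u < config$p_nonsynonymous, "nonsynonymous",
                          ifelse(u < config$p_nonsynonymous + config$p_silent,
                                 "silent", "other"))
    recs$protein_pos[recs$variant_class == "other"] <- NA_integer_
    p_del <- ifelse(recs$in_tm, config$p_deleterious_tm,
                    config$p_deleterious_other)
    del <- stats::runif(m) < p_del
    # SIFT and PolyPhen agree on most calls but not all
    recs$sift <- ifelse(del & stats::runif(m) < 0.9, "deleterious", "tolerated")
    recs$polyphen <- ifelse(del & stats::runif(m) < 0.9, "damaging", "benign")
    recs$sift[recs$variant_class != "nonsynonymous"] <- NA_character_
    recs$polyphen[recs$variant_class != "nonsynonymous"] <- NA_character_
    mu <- ifelse(recs$in_tm, config$cadd_mean_tm, config$cadd_mean_other)
    recs$cadd <- pmax(0, stats::rnorm(m, mu, config$cadd_sd))
    out <- recs[order(recs$gene, recs$sample),
                c("sample", "cancer_type", "gene", "protein_pos",
                  "variant_class", "sift", "polyphen", "cadd")]
    rownames(out) <- NULL
    class(out) <- c("mutation_table", "data.frame")
    out
  })
}

# Uniform positions inside / outside the merged TM intervals of a gene.
sample_tm_positions <- function(panel, gene, n) {
  if (n == 0L) return(integer())
  iv <- panel$tm_intervals[panel$tm_intervals$gene == gene, , drop = FALSE]
  res <- unlist(Map(seq.int, iv$start, iv$end))
  res[sample.int(length(res), n, replace = TRUE)]
}

sample_non_tm_positions <- function(panel, gene, n) {
  if (n == 0L) return(integer())
  L <- panel$genes$length[panel$genes$symbol == gene]
  iv <- panel$tm_intervals[panel$tm_intervals$gene == gene, , drop = FALSE]
  tm <- if (nrow(iv)) unlist(Map(seq.int, iv$start, iv$end)) else integer()
  res <- setdiff(seq_len(L), tm)
  res[sample.int(length(res), n, replace = TRUE)]
}

# Sample universe shared by the tumor-facing generators.
sim_sample_ids <- function(config) {
  types <- sprintf("CT%02d", seq_len(config$n_cancer_types))
  do.call(rbind, lapply(types, function(ct) {
    data.frame(
      sample = c(sprintf("%s_T%03d", ct, seq_len(config$n_tumor)),
                 sprintf("%s_N%03d", ct, seq_len(config$n_normal))),
      cancer_type = ct,
      tumor = rep(c(TRUE, FALSE), c(config$n_tumor, config$n_normal)),
      stringsAsFactors = FALSE)
  }))
}

#' Simulate a GISTIC-style thresholded CNV matrix
#'
#' Entries take values in \{-2, -1, 0, 1, 2\}: per gene and tumor sample a
#' gain occurs with probability `cnv_gain_prob` and a loss with
#' `cnv_loss_prob`; one third of events are high-level (|value| = 2).
#'
#' @inheritParams sim_mutations
#' @return [omics_matrix()] with role `"cnv"` (genes x tumor samples).
#' @export
sim_cnv <- function(panel, config) {
  stopifnot(inherits(panel, "gene_panel"), inherits(config, "sim_config"))
  with_op_seed(config$seed, .op_offsets[["cnv"]], {
    samples <- sim_sample_ids(config)
    samples <- samples[samples$tumor, , drop = FALSE]
    ng <- nrow(panel$genes); ns <- nrow(samples)
    pg <- config$cnv_gain_prob; pl <- config$cnv_loss_prob
    u <- stats::runif(ng * ns)
    v <- integer(ng * ns)
    v[u < pg] <- 1L
    v[u < pg / 3] <- 2L
    v[u > 1 - pl] <- -1L
    v[u > 1 - pl / 3] <- -2L
    m <- matrix(v, ng, ns,
                dimnames = list(panel$genes$symbol, samples$sample))
    omics_matrix(m, role = "cnv", col_data = samples)
  })
}

#' Simulate tumor/normal expression cohorts
#'
#' log2-FPKM is normal around per-gene means; `config$de_genes` are shifted
#' in tumors by their stated log2 effect. A co-expression module of
#' `module_size` genes (the module anchor is its first gene) shares a latent
#' factor at loading `module_loading`, making the module recoverable by
#' correlation-ranked GSEA. The designated proliferation marker
#' (`config$proliferation_gene`, added as an extra row) tracks a latent
#' proliferation factor.
#'
#' @inheritParams sim_mutations
#' @return [omics_matrix()] with role `"expression"` (FPKM scale, genes x
#'   samples) with column metadata `sample`, `cancer_type`, `tumor`; the
#'   planted module genes are in `attr(x, "module_genes")`.
#' @export
sim_expression <- function(panel, config) {
  stopifnot(inherits(panel, "gene_panel"), inherits(config, "sim_config"))
  with_op_seed(config$seed, .op_offsets[["expression"]], {
    samples <- sim_sample_ids(config)
    genes <- c(panel$genes$symbol, config$proliferation_gene)
    ng <- length(genes); ns <- nrow(samples)
    mu <- stats::setNames(
      stats::rnorm(ng, config$expr_mean_log2, config$expr_mean_sd), genes)
    # planted DE genes are clearly expressed at baseline: a +1 pseudocount
    # in downstream fold changes makes shifts on near-zero FPKM
    # unidentifiable, so the planted truth would otherwise be ill-defined
    de_named <- intersect(names(config$de_genes), genes)
    mu[de_named] <- pmax(mu[de_named], 2.5)
    x <- matrix(stats::rnorm(ng * ns, 0, config$expr_sd), ng, ns,
                dimnames = list(genes, samples$sample))

    # planted co-expression module (first module_size panel genes after the
    # DE block) on a latent factor; loadings shrink residual variance so
    # total variance stays at expr_sd^2
    n_mod <- min(config$module_size, nrow(panel$genes))
    start <- min(length(config$tm_enrichment_genes) +
                   length(config$de_genes) + 1L,
                 max(1L, nrow(panel$genes) - n_mod + 1L))
    module_genes <- panel$genes$symbol[seq(start, length.out = n_mod)]
    lam <- config$module_loading
    factor_mod <- stats::rnorm(ns, 0, config$expr_sd)
    x[module_genes, ] <- lam * matrix(factor_mod, n_mod, ns, byrow = TRUE) +
      sqrt(1 - lam^2) * x[module_genes, ]

    # proliferation factor drives the marker gene and, weakly, the module
    factor_prolif <- stats::rnorm(ns, 0, config$expr_sd)
    x[config$proliferation_gene, ] <-
      0.9 * factor_prolif + sqrt(1 - 0.81) * x[config$proliferation_gene, ]

    x <- x + mu
    de <- config$de_genes
    de <- de[names(de) %in% genes]
    if (length(de))
      x[names(de), samples$tumor] <- x[names(de), samples$tumor] + de

    fpkm <- 2^x
    out <- omics_matrix(fpkm, role = "expression", col_data = samples)
    attr(out, "module_genes") <- module_genes
    out
  })
}

#' Simulate a clinical table given alteration status
#'
#' Survival is exponential with hazard `base_hazard` for unaltered and
#' `base_hazard * hazard_multiplier_altered` for altered patients, censored
#' independently at U(0, `censor_horizon`) days. Hypoxia score (standard
#' normal), drawn TMB (Poisson) and ordinal stage/grade shift with
#' alteration status per the config.
#'
#' @param status named character vector, values `"altered"`/`"unaltered"`,
#'   names are patient ids.
#' @param config [sim_config()].
#' @return data.frame of class `clinical_table`.
#' @export
sim_clinical <- function(status, config) {
  stopifnot(inherits(config, "sim_config"), length(status) > 0,
            !is.null(names(status)))
  if (config$hazard_multiplier_altered <= 0)
    stop("configuration error: hazard multiplier must be > 0")
  with_op_seed(config$seed, .op_offsets[["clinical"]], {
    n <- length(status)
    alt <- status == "altered"
    haz <- config$base_hazard *
      ifelse(alt, config$hazard_multiplier_altered, 1)
    t_event <- stats::rexp(n, haz)
    t_cens <- stats::runif(n, 0, config$censor_horizon)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    # disease-free endpoint: same structure, faster clock
    t_event2 <- stats::rexp(n, 1.5 * haz)
    t_cens2 <- stats::runif(n, 0, config$censor_horizon)

    ord_probs <- function(shift, k) {
      # proportional-odds tilt of a uniform ordinal distribution
      cuts <- stats::qlogis(seq_len(k - 1) / k)
      p <- diff(c(0, stats::plogis(cuts - log(shift)), 1))
      p
    }
    draw_ord <- function(shifted, k) {
      p0 <- ord_probs(1, k); p1 <- ord_probs(config$stage_odds_shift, k)
      ifelse(shifted,
             sample.int(k, n, replace = TRUE, prob = p1),
             sample.int(k, n, replace = TRUE, prob = p0))[seq_len(n)]
    }
    stage <- ifelse(alt,
                    sample(1:4, n, TRUE, ord_probs(config$stage_odds_shift, 4)),
                    sample(1:4, n, TRUE, ord_probs(1, 4)))
    grade <- ifelse(alt,
                    sample(1:3, n, TRUE, ord_probs(config$stage_odds_shift, 3)),
                    sample(1:3, n, TRUE, ord_probs(1, 3)))
    out <- data.frame(
      patient_id = names(status),
      os_time = os_time,
      os_event = os_event,
      dfs_time = pmin(t_event2, t_cens2),
      dfs_event = as.integer(t_event2 <= t_cens2),
      stage = factor(stage, levels = 1:4, ordered = TRUE),
      grade = factor(grade, levels = 1:3, ordered = TRUE),
      sex = sample(c("female", "male"), n, replace = TRUE),
      ethnicity = sample(c("A", "B", "C"), n, replace = TRUE,
                         prob = c(0.6, 0.3, 0.1)),
      weight = stats::rnorm(n, 75, 12),
      hypoxia_score = stats::rnorm(n, ifelse(alt, config$hypoxia_shift, 0), 1),
      tmb = stats::rpois(n, config$tmb_mean *
                           ifelse(alt, config$tmb_ratio, 1)),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("clinical_table", "data.frame")
    out
  })
}

#' Simulate cell-line expression and drug IC50 matrices
#'
#' IC50 values are on the natural-log scale. Drugs belong to classes of ten
#' (drug-class latent factor per cell line, loading 0.7), emulating the
#' mechanism-level clustering of real drug panels; this is what makes
#' row-neighbour imputation informative. For each planted (gene, drug, rho)
#' triple the drug's IC50 is generated from a Gaussian copula with the
#' gene's expression at the stated Spearman rho (the normal correlation is
#' `2*sin(pi*rho/6)` so the rank correlation comes out at rho); gene-drug
#' pairs not planted are independent. Missing values are MCAR at
#' `missing_fraction`, overridable per drug via `extra_missing_drugs`.
#'
#' @inheritParams sim_mutations
#' @return list with elements `ic50` ([omics_matrix()], role `"ic50"`,
#'   drugs x cell lines) and `expression` (role `"expression"`, genes x
#'   cell lines).
#' @export
sim_drug_response <- function(panel, config) {
  stopifnot(inherits(panel, "gene_panel"), inherits(config, "sim_config"))
  if (config$n_cell_lines < 10L)
    stop("configuration error: need at least 10 cell lines")
  pairs <- config$planted_drug_pairs
  if (is.null(pairs)) {
    k <- min(10L, config$n_drugs, nrow(panel$genes))
    pairs <- data.frame(gene = panel$genes$symbol[seq_len(k)],
                        drug = sprintf("DRUG%02d", seq_len(k)),
                        rho = 0.6, stringsAsFactors = FALSE)
  }
  if (any(abs(pairs$rho) >= 1))
    stop("configuration error: |rho| must be < 1")
  with_op_seed(config$seed, .op_offsets[["drugs"]], {
    nl <- config$n_cell_lines
    lines <- sprintf("CL%04d", seq_len(nl))
    genes <- panel$genes$symbol
    drugs <- sprintf("DRUG%02d", seq_len(config$n_drugs))
    ez <- matrix(stats::rnorm(length(genes) * nl), length(genes), nl,
                 dimnames = list(genes, lines))
    # drug classes: blocks of 10 drugs share a per-cell-line class factor
    n_class <- ceiling(length(drugs) / 10)
    class_of <- rep(seq_len(n_class), each = 10)[seq_along(drugs)]
    cf <- matrix(stats::rnorm(n_class * nl), n_class, nl)
    lam <- 0.7
    iz <- lam * cf[class_of, , drop = FALSE] +
      sqrt(1 - lam^2) * matrix(stats::rnorm(length(drugs) * nl),
                               length(drugs), nl)
    dimnames(iz) <- list(drugs, lines)
    for (i in seq_len(nrow(pairs))) {
      g <- pairs$gene[i]; d <- pairs$drug[i]
      if (!g %in% genes || !d %in% drugs) next
      r <- 2 * sin(pi * pairs$rho[i] / 6)  # Pearson rho giving Spearman rho
      iz[d, ] <- r * ez[g, ] + sqrt(1 - r^2) * iz[d, ]
    }
    expr <- 2^(config$expr_mean_log2 + config$expr_sd * ez)
    ic50 <- 2 + 1.5 * iz  # natural-log IC50 scale
    miss <- matrix(stats::runif(length(drugs) * nl) < config$missing_fraction,
                   length(drugs), nl, dimnames = dimnames(iz))
    if (!is.null(config$extra_missing_drugs)) {
      for (d in names(config$extra_missing_drugs))
        miss[d, ] <- stats::runif(nl) < config$extra_missing_drugs[[d]]
    }
    ic50[miss] <- NA_real_
    meta <- data.frame(sample = lines, cancer_type = "CELLLINE",
                       tumor = TRUE, stringsAsFactors = FALSE)
    list(ic50 = omics_matrix(ic50, role = "ic50", col_data = meta),
         expression = omics_matrix(expr, role = "expression",
                                   col_data = meta))
  })
}

#' Simulate a gene set collection around a planted module
#'
#' Builds a small GMT-style collection: set `"PLANTED_MODULE"` contains the
#' co-expression module genes of [sim_expression()] and the remaining sets
#' are random draws from the panel, so exactly one set should be recovered
#' by the GSEA screen when anchored at a module gene.
#'
#' @param panel [gene_panel].
#' @param module_genes character vector (from
#'   `attr(sim_expression(...), "module_genes")`).
#' @param config [sim_config()].
#' @param n_sets total number of sets.
#' @param set_size size of the random sets.
#' @return named list of character vectors.
#' @export
sim_gene_sets <- function(panel, module_genes, config, n_sets = 10L,
                          set_size = 25L) {
  stopifnot(inherits(config, "sim_config"))
  with_op_seed(config$seed, .op_offsets[["sets"]], {
    sets <- list(PLANTED_MODULE = module_genes)
    for (i in seq_len(n_sets - 1L))
      sets[[sprintf("RANDOM_SET_%02d", i)]] <-
        sample(panel$genes$symbol, min(set_size, nrow(panel$genes)))
    sets
  })
}

#' Simulate a full cohort
#'
#' Runs every generator under one config. The clinical arm receives a
#' planted alteration label (`altered_fraction` of tumor patients): a
#' desk-scale cohort dense enough in mutations for the region-enrichment
#' statistics saturates any alteration rule computed from its own genetics,
#' so the planted label is what keeps the clinical contrasts recoverable.
#' All planted parameters are recorded in the `manifest` element so
#' recovery tests can compare estimates with truth.
#'
#' @param config [sim_config()].
#' @return list with elements `panel`, `mutations`, `cnv`, `expression`,
#'   `clinical`, `status`, `drug` (list `ic50`, `expression`), `gene_sets`,
#'   and `manifest` (named list of planted truths).
#' @export
sim_cohort <- function(config = sim_config()) {
  panel <- sim_gene_panel(config)
  muts <- sim_mutations(panel, config)
  cnv <- sim_cnv(panel, config)
  expr <- sim_expression(panel, config)
  patients <- colnames(cnv)
  status <- with_op_seed(config$seed, .op_offsets[["status"]],
    stats::setNames(ifelse(stats::runif(length(patients)) <
                             config$altered_fraction,
                           "altered", "unaltered"), patients))
  clinical <- sim_clinical(status, config)
  drug <- sim_drug_response(panel, config)
  gene_sets <- sim_gene_sets(panel, attr(expr, "module_genes"), config)
  manifest <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    altered_fraction = config$altered_fraction,
    tm_enrichment_genes = config$tm_enrichment_genes,
    tm_rate_multiplier = config$tm_rate_multiplier,
    de_genes = config$de_genes,
    module_genes = attr(expr, "module_genes"),
    module_anchor = attr(expr, "module_genes")[1],
    hazard_multiplier_altered = config$hazard_multiplier_altered,
    planted_drug_pairs = if (is.null(config$planted_drug_pairs)) {
      k <- min(10L, config$n_drugs, nrow(panel$genes))
      data.frame(gene = panel$genes$symbol[seq_len(k)],
                 drug = sprintf("DRUG%02d", seq_len(k)), rho = 0.6,
                 stringsAsFactors = FALSE)
    } else config$planted_drug_pairs,
    proliferation_gene = config$proliferation_gene)
  list(panel = panel, mutations = muts, cnv = cnv, expression = expr,
       clinical = clinical, status = status, drug = drug,
       gene_sets = gene_sets, manifest = manifest)
}
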