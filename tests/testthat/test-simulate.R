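test_that("generators are deterministic given the config seed", {
  cfg <- sim_config(seed = 9, n_genes = 20, n_tumor = 10, n_normal = 6,
                    n_cell_lines = 30, n_drugs = 8)
  a <- sim_cohort(cfg)
  b <- sim_cohort(cfg)
  expect_identical(a$mutations, b$mutations)
  expect_identical(unomx(a$cnv), unomx(b$cnv))
  expect_identical(unomx(a$expression), unomx(b$expression))
  expect_identical(a$clinical, b$clinical)
  expect_identical(unomx(a$drug$ic50), unomx(b$drug$ic50))
  # op streams are independent: changing drug dims leaves mutations alone
  cfg2 <- sim_config(seed = 9, n_genes = 20, n_tumor = 10, n_normal = 6,
                     n_cell_lines = 40, n_drugs = 8)
  expect_identical(a$mutations, sim_mutations(sim_gene_panel(cfg2), cfg2))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_genes = 0), "positive count")
  expect_error(sim_config(tm_rate_multiplier = -1), ">= 0")
  expect_error(sim_config(missing_fraction = 1), "missing_fraction")
  expect_error(sim_config(hazard_multiplier_altered = 0), "> 0")
  expect_error(sim_config(cnv_gain_prob = 0.7, cnv_loss_prob = 0.7), "CNV")
  expect_error(sim_config(n_cell_lines = 5), ">= 10")
  expect_error(
    sim_config(gene_length_range = c(100, 120), n_tm_intervals = 8,
               tm_interval_length = 23),
    "exceed protein length")
  expect_error(
    sim_config(planted_drug_pairs = data.frame(gene = "G001", drug = "D1",
                                               rho = 1)),
    "rho")
})

test_that("mutation generator matches the region mixture law", {
  # multiplier 1: pooled TM density ~ other density
  cfg <- sim_config(seed = 31, n_genes = 60, tm_rate_multiplier = 1,
                    background_mutation_rate = 0.6)
  panel <- sim_gene_panel(cfg)
  muts <- sim_mutations(panel, cfg)
  expect_gt(nrow(muts), 1e4)
  d <- mutation_density_by_region(muts, panel, per_gene = FALSE)
  expect_lt(abs(d$tm_density / d$other_density - 1), 0.05)

  # multiplier 3 on a gene with f = 0.2: expected TM fraction
  # 3*0.2 / (3*0.2 + 0.8) = 0.4286
  cfg3 <- sim_config(seed = 32, n_genes = 1, gene_length_range = c(500, 500),
                     n_tm_intervals = 5, tm_interval_length = 20,
                     tm_enrichment_genes = "G001", tm_rate_multiplier = 3,
                     background_mutation_rate = 2)
  p3 <- sim_gene_panel(cfg3)
  expect_equal(p3$genes$tm_length / p3$genes$length, 0.2)
  m3 <- sim_mutations(p3, cfg3)
  pos <- m3[!is.na(m3$protein_pos), ]
  frac <- mean(in_tm_region(p3, pos$gene, pos$protein_pos))
  expect_lt(abs(frac - 3 * 0.2 / (3 * 0.2 + 0.8)), 0.03)

  # zero rate: empty table
  cfg0 <- sim_config(seed = 33, n_genes = 5, background_mutation_rate = 0)
  expect_equal(nrow(sim_mutations(sim_gene_panel(cfg0), cfg0)), 0)
})

test_that("cnv generator hits configured marginal frequencies", {
  cfg <- sim_config(seed = 41, n_genes = 30, n_tumor = 500,
                    n_cancer_types = 2, cnv_gain_prob = 0.3,
                    cnv_loss_prob = 0.1)
  cnv <- sim_cnv(sim_gene_panel(cfg), cfg)
  x <- unomx(cnv)
  expect_true(all(x %in% -2:2))
  expect_equal(mean(x >= 1), 0.3, tolerance = 0.03)
  expect_equal(mean(x <= -1), 0.1, tolerance = 0.02)
  cfg0 <- sim_config(seed = 42, n_genes = 10, cnv_gain_prob = 0,
                     cnv_loss_prob = 0.2)
  expect_true(all(unomx(sim_cnv(sim_gene_panel(cfg0), cfg0)) <= 0))
})

test_that("expression generator recovers planted effects and modules", {
  cfg <- sim_config(seed = 51, n_genes = 120)
  panel <- sim_gene_panel(cfg)
  expr <- sim_expression(panel, cfg)
  meta <- omx_meta(expr)
  x <- log2(unomx(expr))
  de <- cfg$de_genes
  emp <- rowMeans(x[names(de), meta$tumor]) -
    rowMeans(x[names(de), !meta$tumor])
  expect_true(all(abs(emp - de) < 0.5))
  # unplanted genes have no shift
  other <- setdiff(panel$genes$symbol, names(de))[1:20]
  emp0 <- rowMeans(x[other, meta$tumor]) - rowMeans(x[other, !meta$tumor])
  expect_true(all(abs(emp0) < 0.6))
  # module genes are co-expressed: mean pairwise Spearman above 0.4
  mod <- attr(expr, "module_genes")
  rho <- cor(t(x[mod[1:10], ]), method = "spearman")
  expect_gt(mean(rho[upper.tri(rho)]), 0.4)
})

test_that("clinical generator encodes hazard and covariate shifts", {
  cfg <- sim_config(seed = 61, hazard_multiplier_altered = 2)
  status <- setNames(rep(c("altered", "unaltered"), each = 200),
                     sprintf("P%03d", 1:400))
  cl <- sim_clinical(status, cfg)
  fit <- hazard_ratio(factor(status[cl$patient_id], c("unaltered", "altered")),
                      cl$os_time, cl$os_event)
  expect_gt(fit$hr, 1.6)
  expect_lt(fit$hr, 2.5)
  # null configuration: no shifts anywhere
  cfg0 <- sim_config(seed = 62, hazard_multiplier_altered = 1,
                     hypoxia_shift = 0, tmb_ratio = 1, stage_odds_shift = 1)
  cl0 <- sim_clinical(status, cfg0)
  cmp <- compare_clinical_features(cl0, status)
  expect_true(all(cmp$adjusted_p[cmp$status == "tested"] > 0.05))
  # degenerate censoring: horizon so short that no events are observed
  cfgc <- sim_config(seed = 63, censor_horizon = 1e-6)
  clc <- sim_clinical(status, cfgc)
  expect_true(all(clc$os_event == 0))
  expect_error(logrank_test(clc$os_time, clc$os_event, status), "no events")
})

test_that("drug response generator plants copula correlations and MCAR", {
  cfg <- sim_config(seed = 71)
  panel <- sim_gene_panel(cfg)
  d <- sim_drug_response(panel, cfg)
  expect_equal(dim(unomx(d$ic50)), c(50L, 500L))
  expect_lt(abs(mean(is.na(unomx(d$ic50))) - 0.1), 0.01)
  rho <- cor(unomx(d$expression)["G001", ], unomx(d$ic50)["DRUG01", ],
             method = "spearman", use = "pairwise.complete.obs")
  expect_lt(abs(rho - 0.6), 0.1)
  # complete when missing_fraction = 0
  cfg0 <- sim_config(seed = 72, missing_fraction = 0)
  expect_equal(sum(is.na(unomx(sim_drug_response(panel, cfg0)$ic50))), 0)
  # per-drug overrides can exceed the removal filter
  cfg4 <- sim_config(seed = 73, extra_missing_drugs = c(DRUG05 = 0.4))
  ic <- unomx(sim_drug_response(panel, cfg4)$ic50)
  expect_gt(mean(is.na(ic["DRUG05", ])), 0.30)
})

test_that("cohort manifest records planted truths and matrices are NA-clean", {
  co <- cached_cohort()
  mf <- co$manifest
  expect_equal(mf$tm_rate_multiplier, 3)
  expect_length(mf$tm_enrichment_genes, 20)
  expect_equal(unname(mf$de_genes), rep(c(2, -2), each = 10))
  expect_equal(mf$hazard_multiplier_altered, 2)
  expect_equal(nrow(mf$planted_drug_pairs), 10)
  expect_false(anyNA(unomx(co$cnv)))
  expect_false(anyNA(unomx(co$expression)))
})
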