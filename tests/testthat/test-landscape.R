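test_that("mutation frequency is distinct mutated samples over cohort size", {
  p <- tiny_panel()
  m <- rbind(muts_at("GA", 1, 2, sample = "S1"),
             muts_at("GA", 0, 1, sample = "S2"))
  freq <- mutation_frequency_matrix(m, c(CT01 = 4), p)
  expect_equal(freq["GA", "CT01"], 0.5)  # 2 distinct samples of 4
  expect_equal(freq["GB", "CT01"], 0)
  one <- mutation_frequency_matrix(muts_at("GA", 1, 3, sample = "S1"),
                                   c(CT01 = 4), p)
  expect_equal(one["GA", "CT01"], 0.25)  # 1 of 4 despite 3 records
  empty <- m[0, ]
  expect_true(all(mutation_frequency_matrix(empty, c(CT01 = 4), p) == 0))
  expect_error(mutation_frequency_matrix(m, c(OTHER = 4), p),
               "absent from cohort_sizes")
})

test_that("TMB counts nonsynonymous records per sample, zero when absent", {
  m <- rbind(muts_at("GA", 1, 3, sample = "S1", class = "nonsynonymous"),
             muts_at("GA", 0, 2, sample = "S1", class = "silent"))
  tmb <- compute_tmb(m, c("S1", "S2"))
  expect_equal(unname(tmb["S1"]), 3)
  expect_equal(unname(tmb["S2"]), 0)
})

test_that("TM enrichment reproduces the binomial tail and ratio", {
  p <- tiny_panel()
  # N = 10, k = 5, p_ri = 0.2
  enr <- tm_region_enrichment(muts_at("GA", 5, 10), p)
  row <- enr[enr$gene == "GA", ]
  expect_equal(row$p_ri, 0.2)
  expect_equal(row$enrichment, 5 / (10 * 0.2))
  direct <- sum(choose(10, 5:10) * 0.2^(5:10) * 0.8^(10 - 5:10))
  expect_equal(row$p_value, direct, tolerance = 1e-10)
  expect_equal(round(row$p_value, 7), 0.0327935)
  # k = 0 gives tail probability 1
  enr0 <- tm_region_enrichment(muts_at("GA", 0, 7), p)
  expect_equal(enr0$p_value[enr0$gene == "GA"], 1)
  # saturated region: L_TR = L_g means p = 1, E = k/N, never enriched
  psat <- gene_panel(data.frame(symbol = "GS", family = "F", length = 50),
                     data.frame(gene = "GS", start = 1, end = 50))
  msat <- data.frame(sample = "S1", cancer_type = "CT01", gene = "GS",
                     protein_pos = c(3L, 10L, 40L),
                     variant_class = "nonsynonymous", sift = NA, polyphen = NA,
                     cadd = NA_real_)
  esat <- tm_region_enrichment(msat, psat)
  expect_equal(esat$p_value, 1)
  expect_equal(esat$enrichment, 1)
  expect_false(any(esat$enriched))
})

test_that("TM enrichment handles unscored genes and invalid positions", {
  p <- gene_panel(data.frame(symbol = c("G1", "G2"), family = "F",
                             length = c(100, 100)),
                  data.frame(gene = "G1", start = 1, end = 20))
  m <- data.frame(sample = "S", cancer_type = "CT", gene = c("G1", "G2"),
                  protein_pos = c(5L, 50L), variant_class = "nonsynonymous",
                  sift = NA, polyphen = NA, cadd = NA_real_)
  enr <- tm_region_enrichment(m, p)
  expect_true(enr$scored[enr$gene == "G1"])
  expect_false(enr$scored[enr$gene == "G2"])  # no TM annotation
  expect_true(is.na(enr$p_value[enr$gene == "G2"]))
  bad <- m; bad$protein_pos[1] <- 200L
  expect_error(tm_region_enrichment(bad, p), "outside")
})

test_that("enrichment ratio and p-value are monotone in k", {
  p <- tiny_panel()
  res <- lapply(0:10, function(k) {
    e <- tm_region_enrichment(muts_at("GA", k, 10), p)
    e[e$gene == "GA", ]
  })
  E <- vapply(res, `[[`, numeric(1), "enrichment")
  pv <- vapply(res, `[[`, numeric(1), "p_value")
  expect_true(all(diff(E) > 0))
  expect_true(all(diff(pv) < 0))
  # E = 1 exactly when k/N equals the TM fraction (k=2, N=10, f=0.2)
  expect_equal(E[3], 1)
})

test_that("region comparison is exact for small n and powered for shifts", {
  same <- region_value_compare(c(2, 5, 5, 9), c(9, 5, 2, 5))
  expect_equal(same$p_value, 1)
  expect_equal(same$method, "exact enumeration")
  sep <- region_value_compare(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$p_value, 2 / choose(6, 3))  # only the two extreme splits
  set.seed(1)
  big <- region_value_compare(rnorm(100, 3), rnorm(100, 0))
  expect_lt(big$p_value, 1e-6)
  expect_equal(big$method, "normal approximation")
  expect_gt(big$shift, 2.5)
  expect_error(region_value_compare(numeric(), 1:3), "at least one value")
})

test_that("exact rank-sum enumeration matches wilcox.test without ties", {
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    mine <- region_value_compare(a, b)$p_value
    ref <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("deleterious-region association builds the 2x2 and Fisher p", {
  p <- tiny_panel()
  res <- deleterious_region_association(muts_from_table(3, 0, 0, 3), p)
  expect_equal(res$p_value, 0.1, tolerance = 1e-10)
  expect_equal(as.integer(res$table), c(3L, 0L, 0L, 3L))
  bal <- deleterious_region_association(muts_from_table(5, 5, 5, 5), p)
  expect_equal(bal$p_value, 1)
  expect_equal(bal$odds_ratio, 1)
  # NA-labelled mutations are excluded from the table
  m <- muts_from_table(3, 0, 0, 3)
  extra <- muts_at("GA", 1, 2)  # NA sift/polyphen
  res2 <- deleterious_region_association(rbind(m, extra), p)
  expect_equal(sum(res2$table), 6)
  expect_equal(res2$n_excluded_na, 2)
  expect_error(deleterious_region_association(extra, p), "no mutation carries")
})

test_that("Fisher p equals hypergeometric enumeration for small tables", {
  p <- tiny_panel()
  hyper_p <- function(a, b, c, d) {
    # condition on margins; two-sided: sum of outcomes at most as probable
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(3)
  for (i in 1:12) {
    tab <- as.vector(rmultinom(1, sample(8:40, 1), c(.3, .2, .25, .25)))
    if (tab[1] + tab[2] == 0 || tab[3] + tab[4] == 0) next
    res <- deleterious_region_association(
      muts_from_table(tab[1], tab[2], tab[3], tab[4]), p)
    expect_equal(res$p_value, hyper_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
})

test_that("CNV frequencies threshold gains and losses correctly", {
  p <- tiny_panel()
  m <- matrix(c(2, 1, 0, -1,   0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("GA", "GB"), paste0("S", 1:4)))
  cnv <- omics_matrix(m, role = "cnv",
                      col_data = data.frame(sample = paste0("S", 1:4),
                                            cancer_type = "CT01"))
  f <- cnv_frequency_matrix(cnv, p)
  expect_equal(f$gain["GA", "CT01"], 0.5)
  expect_equal(f$loss["GA", "CT01"], 0.25)
  expect_equal(f$gain["GB", "CT01"], 0)
  expect_true(all(f$gain + f$loss <= 1))
  fh <- cnv_frequency_matrix(cnv, p, mode = "high")
  expect_equal(fh$gain["GA", "CT01"], 0.25)
  expect_equal(fh$loss["GA", "CT01"], 0)
  expect_error(omics_matrix(matrix(3, 1, 1, dimnames = list("GA", "S1")),
                            role = "cnv"), "-2..2")
})

test_that("CNV frequencies round-trip the generator probabilities", {
  cfg <- sim_config(seed = 87, n_genes = 20, n_tumor = 500,
                    cnv_gain_prob = 0.3, cnv_loss_prob = 0.15)
  panel <- sim_gene_panel(cfg)
  f <- cnv_frequency_matrix(sim_cnv(panel, cfg), panel)
  expect_equal(mean(f$gain), 0.3, tolerance = 0.03)
  expect_equal(mean(f$loss), 0.15, tolerance = 0.03)
})
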