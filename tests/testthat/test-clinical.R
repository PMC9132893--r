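test_that("alteration status applies the mutation-or-high-CNV rule", {
  p <- tiny_panel()
  m <- muts_at("GA", 1, 1, sample = "P1")
  cn <- matrix(c(0, 0, 0, 0, 2, -1), nrow = 2, byrow = TRUE,
               dimnames = list(c("GA", "GB"), c("P1", "P2", "P3")))
  cnv <- omics_matrix(cn, "cnv",
                      data.frame(sample = c("P1", "P2", "P3"),
                                 cancer_type = "CT"))
  st <- alteration_status(m, cnv, p, patients = c("P1", "P2", "P3", "P4"))
  expect_equal(unname(st), c("altered", "altered", "unaltered", "unaltered"))
  # silent mutations do not alter
  msil <- muts_at("GA", 1, 1, sample = "P3", class = "silent")
  st2 <- alteration_status(msil, NULL, p, patients = "P3")
  expect_equal(unname(st2), "unaltered")
  # relaxing the CNV rule can only grow the altered set
  st_any <- alteration_status(m, cnv, p, patients = c("P1", "P2", "P3", "P4"),
                              cnv_rule = "any")
  expect_true(all(st[st == "altered"] == st_any[st == "altered"]))
  expect_equal(unname(st_any["P3"]), "altered")  # -1 now counts
  expect_error(alteration_status(m, cnv, p, patients = character()),
               "empty patient universe")
})

test_that("clinical feature comparison picks tests by feature type", {
  co <- cached_cohort()
  cmp <- compare_clinical_features(co$clinical, co$status)
  expect_equal(cmp$test[cmp$feature == "weight"], "wilcoxon")
  expect_true(cmp$test[cmp$feature == "sex"] %in% c("chi-square", "fisher"))
  expect_equal(cmp$type[cmp$feature == "stage"], "ordinal")
  # planted shifts are detected
  expect_lt(cmp$adjusted_p[cmp$feature == "hypoxia_score"], 0.001)
  expect_lt(cmp$adjusted_p[cmp$feature == "tmb"], 0.001)
  # a sparse categorical feature takes the Fisher branch
  cl <- co$clinical
  cl$ethnicity <- c(rep("RARE", 3), rep("COMMON", nrow(cl) - 3))
  cmp2 <- compare_clinical_features(cl, co$status)
  expect_equal(cmp2$test[cmp2$feature == "ethnicity"], "fisher")
  # a missing feature is reported untested, not an error
  cl$weight <- NA_real_
  cmp3 <- compare_clinical_features(cl, co$status)
  expect_match(cmp3$status[cmp3$feature == "weight"], "untested")
})

test_that("log-rank test matches hand tabulation and survdiff", {
  # worked 6-patient instance: group A times 1,3,5 (all events),
  # group B times 2,4,6 (events at 2 and 4, censored at 6)
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 1, 1, 1, 0)
  group <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(time, event, group)
  # hand tabulation over event times 1..5:
  # t=1: n=6, n_A=3, d=1, d_A=1 -> E += 1/2, V += (1/2)(1/2)(5/5)
  # t=2: n=5, n_A=2, d=1, d_A=0 -> E += 2/5
  # t=3: n=4, n_A=2, d=1, d_A=1 -> E += 1/2
  # t=4: n=3, n_A=1, d=1, d_A=0 -> E += 1/3
  # t=5: n=2, n_A=1, d=1, d_A=1 -> E += 1/2
  O <- 3; E <- 1/2 + 2/5 + 1/2 + 1/3 + 1/2
  V <- (3/6)*(3/6) + (2/5)*(3/5) + (2/4)*(2/4) + (1/3)*(2/3) + (1/2)*(1/2)
  expect_equal(lr$observed, O)
  expect_equal(lr$expected, E, tolerance = 1e-12)
  expect_equal(lr$chi2, (O - E)^2 / V, tolerance = 1e-12)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-10)
  # identical groups: zero statistic
  lr0 <- logrank_test(c(time, time), c(event, event),
                      rep(c("A", "B"), each = 6))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(time, rep(0, 6), group), "no events")
  expect_error(logrank_test(time, event, c(1, 1, 2, 2, 3, 3)), "exactly 2")
})

test_that("log-rank is label-symmetric and agrees with survdiff broadly", {
  set.seed(19)
  for (i in 1:8) {
    n <- sample(20:80, 1)
    time <- rexp(n, 0.01)
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("x", "y"), n, replace = TRUE)
    if (sum(event) == 0 || length(unique(group)) < 2) next
    a <- logrank_test(time, event, group)
    b <- logrank_test(time, event, ifelse(group == "x", "y", "x"))
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(a$chi2, sd$chisq, tolerance = 1e-8)
  }
})

test_that("optimal cutpoint separates survival groups and honors minprop", {
  set.seed(23)
  # bimodal expression; high expressors die early
  x <- rep(c(1, 10), each = 20)
  time <- c(rexp(20, 0.001), rexp(20, 0.02))
  event <- rep(1, 40)
  oc <- optimal_cutpoint(x, time, event)
  expect_gt(oc$cutpoint, 1)
  expect_lt(oc$cutpoint, 10)
  expect_true(oc$selection_biased)
  # minprop: with n = 20 and minprop 0.1, groups of size < 2 never proposed
  x2 <- c(1, seq(2, 3, length.out = 18), 10)
  t2 <- rexp(20, 0.01); e2 <- rep(1, 20)
  oc2 <- optimal_cutpoint(x2, t2, e2, minprop = 0.1)
  expect_gte(sum(x2 <= oc2$cutpoint), 2)
  expect_gte(sum(x2 > oc2$cutpoint), 2)
  expect_error(optimal_cutpoint(rep(5, 20), t2, e2), "constant")
  expect_error(optimal_cutpoint(x2[1:8], t2[1:8], e2[1:8]), "at least 10")
})

test_that("cutpoint equals exhaustive survdiff scan", {
  set.seed(29)
  for (i in 1:6) {
    n <- sample(c(20, 50, 120, 200), 1)
    x <- rnorm(n)
    time <- rexp(n, 0.01 * exp(0.4 * (x > 0)))
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) next
    oc <- optimal_cutpoint(x, time, event)
    ref <- brute_cutpoint(x, time, event)
    expect_equal(oc$statistic^2, ref$chisq, tolerance = 1e-8)
    expect_equal(oc$cutpoint, ref$cutpoint, tolerance = 1e-8)
  }
})

test_that("hazard ratio classifies fits and applies the zero filter", {
  set.seed(31)
  n <- 400
  grp <- factor(rep(c("low", "high"), each = n / 2), c("low", "high"))
  time <- c(rexp(n / 2, 0.001), rexp(n / 2, 0.002))
  event <- rbinom(n, 1, 0.8)
  fit <- hazard_ratio(grp, time, event)
  expect_equal(fit$status, "ok")
  expect_gt(fit$hr, 1.5)
  expect_lt(fit$hr, 2.7)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_equal(fit$classification, "risky")
  # protective when the labels flip
  fit2 <- hazard_ratio(factor(grp, c("high", "low")), time, event)
  expect_equal(fit2$classification, "protective")
  expect_equal(fit2$hr, 1 / fit$hr, tolerance = 1e-6)
  # null: identical survival in both groups
  t0 <- rep(rexp(n / 2, 0.001), 2)
  e0 <- rep(rbinom(n / 2, 1, 0.8), 2)
  fit0 <- hazard_ratio(grp, t0, e0)
  expect_equal(fit0$classification, "ns")
  expect_true(fit0$ci_low < 1 && fit0$ci_high > 1)
  # zero-expression filter
  xz <- c(rep(0, 240), rexp(160, 1))
  fz <- hazard_ratio(xz, time, event)
  expect_match(fz$status, "zero-expression filter")
  expect_true(is.na(fz$hr))
})

test_that("hazard ratio and log-rank agree in direction on large cohorts", {
  co <- cached_cohort()
  grp <- factor(co$status[co$clinical$patient_id], c("unaltered", "altered"))
  fit <- hazard_ratio(grp, co$clinical$os_time, co$clinical$os_event)
  lr <- logrank_test(co$clinical$os_time, co$clinical$os_event, grp)
  expect_equal(fit$p_value, lr$p_value)
  expect_gt(fit$hr, 1.2)  # altered arm carries hazard multiplier 2
})

test_that("null cohorts keep the false-flag rate near nominal", {
  # 200 seeded replicates with no planted shifts: the pooled fraction of
  # feature tests at raw p < 0.05 stays at/below 0.075
  ps <- unlist(lapply(1:200, function(s) {
    cfg <- sim_config(seed = 10000 + s, hazard_multiplier_altered = 1,
                      hypoxia_shift = 0, tmb_ratio = 1, stage_odds_shift = 1)
    status <- setNames(rep(c("altered", "unaltered"), each = 30),
                       sprintf("P%03d", 1:60))
    cl <- sim_clinical(status, cfg)
    cmp <- compare_clinical_features(cl, status)
    cmp$p_value[cmp$status == "tested"]
  }))
  expect_lte(mean(ps < 0.05), 0.075)
})

test_that("survival screen emits one classified row per gene and cancer", {
  co <- cached_cohort()
  meta <- omx_meta(co$expression)
  texpr <- omics_matrix(unomx(co$expression)[1:15, meta$tumor],
                        "expression", meta[meta$tumor, ])
  scr <- survival_screen(texpr, co$clinical, co$panel)
  expect_equal(nrow(scr), 15 * length(unique(meta$cancer_type)))
  expect_true(all(scr$classification %in% c("risky", "protective", "ns")))
  ok <- scr$status == "ok"
  expect_true(all(scr$ci_low[ok] <= scr$hr[ok] &
                    scr$hr[ok] <= scr$ci_high[ok]))
})
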