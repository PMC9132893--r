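#' Genetic alteration status of patients
#'
#' A patient is `altered` when they carry at least one nonsynonymous
#' mutation in a panel gene, or a CNV event in a panel gene at the chosen
#' level: `cnv_rule = "high"` (default) counts only |value| = 2
#' (cBioPortal-style alteration semantics), `"any"` counts |value| >= 1.
#' The patient universe must be supplied explicitly so that patients with
#' no records are representable (they are `unaltered`).
#'
#' @param muts mutation table (may be `NULL`).
#' @param cnv [omics_matrix()] with role `"cnv"`, columns = patients (may be
#'   `NULL`).
#' @param panel [gene_panel].
#' @param patients character vector, the patient universe.
#' @param cnv_rule `"high"` or `"any"`.
#' @return named character vector over `patients` with values
#'   `"altered"` / `"unaltered"`.
#' @export
alteration_status <- function(muts, cnv, panel, patients,
                              cnv_rule = c("high", "any")) {
  cnv_rule <- match.arg(cnv_rule)
  stopifnot(inherits(panel, "gene_panel"))
  if (length(patients) == 0L) stop("input error: empty patient universe")
  altered <- character(0)
  if (!is.null(muts) && nrow(muts)) {
    m <- muts[muts$gene %in% panel$genes$symbol &
                muts$variant_class == "nonsynonymous", , drop = FALSE]
    altered <- unique(m$sample)
  }
  if (!is.null(cnv)) {
    x <- unomx(cnv)
    x <- x[intersect(rownames(x), panel$genes$symbol), , drop = FALSE]
    thr <- if (cnv_rule == "high") 2 else 1
    hit <- colnames(x)[colSums(abs(x) >= thr, na.rm = TRUE) > 0]
    altered <- union(altered, hit)
  }
  out <- ifelse(patients %in% altered, "altered", "unaltered")
  stats::setNames(out, patients)
}

#' Compare clinical features between altered and unaltered patients
#'
#' Categorical features (sex, ethnicity) are tested with the chi-square
#' test, falling back to Fisher's exact test when any expected cell count
#' is below 5; continuous features (weight, hypoxia score, TMB) with the
#' two-sided Wilcoxon rank-sum test; ordinal features (stage, grade) with
#' the rank-sum test on their ordinal codes. P-values are BH-adjusted
#' across the tested features. Features entirely missing are reported as
#' untested.
#'
#' @param clinical data.frame with `patient_id` and any of `sex`,
#'   `ethnicity`, `weight`, `hypoxia_score`, `tmb`, `stage`, `grade`.
#' @param status named character vector (`"altered"`/`"unaltered"`) covering
#'   `clinical$patient_id`.
#' @return data.frame `feature`, `type`, `test`, `p_value`, `adjusted_p`,
#'   `status`.
#' @export
compare_clinical_features <- function(clinical, status) {
  stopifnot(is.data.frame(clinical), "patient_id" %in% names(clinical))
  grp <- factor(status[clinical$patient_id], c("unaltered", "altered"))
  if (length(unique(stats::na.omit(grp))) < 2L)
    stop("input error: both alteration groups must be nonempty")
  spec <- list(sex = "categorical", ethnicity = "categorical",
               weight = "continuous", hypoxia_score = "continuous",
               tmb = "continuous", stage = "ordinal", grade = "ordinal")
  rows <- lapply(names(spec), function(f) {
    if (!f %in% names(clinical) || all(is.na(clinical[[f]])))
      return(data.frame(feature = f, type = spec[[f]], test = NA_character_,
                        p_value = NA_real_, status = "untested: missing",
                        stringsAsFactors = FALSE))
    v <- clinical[[f]]
    if (spec[[f]] == "categorical") {
      tab <- table(v, grp)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chi-square"
      }
    } else {
      num <- if (spec[[f]] == "ordinal") as.numeric(ordered(v)) else
        as.numeric(v)
      p <- suppressWarnings(stats::wilcox.test(
        num[grp == "altered"], num[grp == "unaltered"],
        exact = FALSE, correct = TRUE)$p.value)
      test <- "wilcoxon"
    }
    data.frame(feature = f, type = spec[[f]], test = test, p_value = p,
               status = "tested", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  tested <- out$status == "tested"
  out$adjusted_p[tested] <- stats::p.adjust(out$p_value[tested], "BH")
  out <- out[, c("feature", "type", "test", "p_value", "adjusted_p",
                 "status")]
  rownames(out) <- NULL
  out
}

# Two-group log-rank O-E-V tabulation over pooled event times.
logrank_oev <- function(time, event, g1) {
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  c(O = O, E = E, V = V)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled event times:
#' `chi2 = (O - E)^2 / V` referred to a chi-square distribution with one
#' degree of freedom, where O/E/V are the observed events, their
#' hypergeometric expectation and variance summed over event times.
#'
#' @param time nonnegative follow-up times.
#' @param event 0/1 event indicators (1 = event).
#' @param group vector with exactly two distinct values.
#' @return list `chi2`, `p_value`, `observed`, `expected` (both for the
#'   first group level).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("input error: negative times")
  if (!all(event %in% c(0, 1))) stop("input error: events must be 0/1")
  lev <- unique(group)
  if (length(lev) != 2L) stop("input error: exactly 2 groups required")
  if (sum(event) == 0L) stop("input error: no events (all censored)")
  s <- logrank_oev(time, event, group == lev[1])
  chi2 <- if (s["V"] > 0) unname((s["O"] - s["E"])^2 / s["V"]) else 0
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = unname(s["O"]), expected = unname(s["E"]))
}

#' Maximally selected survival cutpoint
#'
#' Scans every candidate cutpoint (midpoints between consecutive distinct
#' expression values) that leaves at least `minprop` of the patients in each
#' group, computes the standardized two-group log-rank statistic
#' `z = (O - E)/sqrt(V)` at each, and returns the cutpoint maximizing |z|
#' (the maximally selected rank statistic). Because the cutpoint is chosen
#' to maximize the statistic, a log-rank p-value computed on the resulting
#' groups is optimistically biased; downstream fits carry a
#' `selection_biased` flag.
#'
#' @param x numeric expression values (>= 10 patients, not constant).
#' @param time,event survival data aligned with `x`.
#' @param minprop minimum proportion of patients per group (default 0.1).
#' @return list `cutpoint`, `statistic` (max |z|), `groups` (factor
#'   `"low"`/`"high"`), `n_candidates`, `selection_biased = TRUE`.
#' @export
optimal_cutpoint <- function(x, time, event, minprop = 0.1) {
  stopifnot(length(x) == length(time), length(x) == length(event))
  n <- length(x)
  if (n < 10L) stop("input error: need at least 10 patients")
  if (length(unique(x)) < 2L) stop("input error: expression is constant")
  if (sum(event) == 0L) stop("input error: no events (all censored)")
  xs <- sort(unique(x))
  cand <- (xs[-length(xs)] + xs[-1]) / 2
  nmin <- max(1L, ceiling(minprop * n))
  keep <- vapply(cand, function(cp) {
    nl <- sum(x <= cp)
    nl >= nmin && (n - nl) >= nmin
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand))
    stop("input error: no cutpoint satisfies the minprop constraint")
  z <- vapply(cand, function(cp) {
    s <- logrank_oev(time, event, x <= cp)
    if (s["V"] <= 0) return(0)
    unname(abs(s["O"] - s["E"]) / sqrt(s["V"]))
  }, numeric(1))
  best <- which.max(z)
  cp <- cand[best]
  list(cutpoint = cp, statistic = z[best],
       groups = factor(ifelse(x <= cp, "low", "high"), c("low", "high")),
       n_candidates = length(cand), selection_biased = TRUE)
}

#' Univariate hazard ratio for an expression value or grouping
#'
#' For numeric input the patients are first dichotomized at the maximally
#' selected cutpoint ([optimal_cutpoint()]); genes whose expression is zero
#' in more than `zero_fraction_limit` of the patients are skipped rather
#' than fitted. The hazard ratio of the high- versus low-expression group
#' (or of the second versus first level of a supplied 2-level factor) comes
#' from a univariate Cox proportional-hazards fit (Efron tie handling) with
#' a Wald 95% confidence interval; the reported p-value is the log-rank
#' test p of the same grouping. Classification follows the screening rule:
#' `risky` when HR > 1 and p < `alpha`, `protective` when HR < 1 and
#' p < `alpha`, otherwise `ns`.
#'
#' @param x numeric expression vector, or a factor/character with exactly
#'   two levels.
#' @param time,event survival data aligned with `x`.
#' @param minprop passed to [optimal_cutpoint()] for numeric input.
#' @param zero_fraction_limit skip numeric input with more than this
#'   fraction of zeros (default 0.5).
#' @param alpha significance threshold of the classification (default 0.05).
#' @return data.frame (one row) with `hr`, `ci_low`, `ci_high`,
#'   `logrank_chi2`, `p_value`, `cutpoint`, `classification`, `status`,
#'   `selection_biased`. When the input is skipped or the fit fails, `hr`
#'   is `NA` and `status` says why.
#' @export
hazard_ratio <- function(x, time, event, minprop = 0.1,
                         zero_fraction_limit = 0.5, alpha = 0.05) {
  skip_row <- function(status) data.frame(
    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    logrank_chi2 = NA_real_, p_value = NA_real_, cutpoint = NA_real_,
    classification = "ns", status = status, selection_biased = NA,
    stringsAsFactors = FALSE)
  cutpoint <- NA_real_; biased <- FALSE
  if (is.numeric(x)) {
    if (mean(x == 0) > zero_fraction_limit)
      return(skip_row("skipped: zero-expression filter"))
    oc <- tryCatch(optimal_cutpoint(x, time, event, minprop = minprop),
                   error = function(e) e)
    if (inherits(oc, "error"))
      return(skip_row(paste0("skipped: ", conditionMessage(oc))))
    grp <- oc$groups
    cutpoint <- oc$cutpoint
    biased <- TRUE
  } else {
    grp <- factor(x)
    if (nlevels(grp) != 2L)
      stop("input error: grouping must have exactly 2 levels")
  }
  if (min(table(grp[event == 1])) < 1L)
    return(skip_row("skipped: a group has no events"))
  lr <- logrank_test(time, event, grp)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ grp, ties = "efron"),
    warning = function(w) w, error = function(e) e)
  if (inherits(fit, "warning") || inherits(fit, "error"))
    return(data.frame(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      logrank_chi2 = lr$chi2, p_value = lr$p_value,
                      cutpoint = cutpoint, classification = "ns",
                      status = paste0("flagged: ",
                                      conditionMessage(fit)),
                      selection_biased = biased, stringsAsFactors = FALSE))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  hr <- exp(beta)
  cls <- if (lr$p_value < alpha) {
    if (hr > 1) "risky" else if (hr < 1) "protective" else "ns"
  } else "ns"
  data.frame(hr = hr, ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             logrank_chi2 = lr$chi2, p_value = lr$p_value,
             cutpoint = cutpoint, classification = cls, status = "ok",
             selection_biased = biased, stringsAsFactors = FALSE)
}

#' Survival screen over panel genes
#'
#' Applies [hazard_ratio()] (cutpoint dichotomization of tumor expression,
#' Cox HR, log-rank p) to each panel gene within each cancer type.
#'
#' @param expr [omics_matrix()] role `"expression"`; tumor columns are
#'   matched to `clinical$patient_id`.
#' @param clinical clinical table with `patient_id`, and the endpoint
#'   columns.
#' @param panel [gene_panel].
#' @param endpoint `"os"` (overall survival, default) or `"dfs"`.
#' @param ... passed to [hazard_ratio()].
#' @return data.frame with one row per gene x cancer type.
#' @export
survival_screen <- function(expr, clinical, panel, endpoint = c("os", "dfs"),
                            ...) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical)))
    stop("input error: clinical table lacks ", tcol, "/", ecol)
  meta <- omx_meta(expr)
  x <- unomx(expr)
  ids <- intersect(colnames(x), clinical$patient_id)
  if (!length(ids)) stop("input error: no shared patients")
  cl <- clinical[match(ids, clinical$patient_id), ]
  meta <- meta[match(ids, meta$sample), , drop = FALSE]
  genes <- intersect(panel$genes$symbol, rownames(x))
  rows <- list()
  for (ct in unique(meta$cancer_type)) {
    sel <- meta$cancer_type == ct
    for (g in genes) {
      r <- hazard_ratio(x[g, ids[sel]], cl[[tcol]][sel], cl[[ecol]][sel], ...)
      r <- cbind(data.frame(gene = g, cancer_type = ct,
                            stringsAsFactors = FALSE), r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
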