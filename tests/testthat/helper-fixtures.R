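# Shared fixtures, built in code.

# Two-gene panel with known TM geometry: GA 100 aa with TM 1-20 (f = 0.2),
# GB 200 aa with TM 51-100 (f = 0.25).
tiny_panel <- function() {
  gene_panel(
    data.frame(symbol = c("GA", "GB"), family = c("F1", "F2"),
               length = c(100, 200)),
    data.frame(gene = c("GA", "GB"), start = c(1, 51), end = c(20, 100)))
}

# Mutation table with explicit positions/regions for one gene of
# tiny_panel(); k positions inside TM, N - k outside.
muts_at <- function(gene = "GA", k, n, sample = "S1", cancer = "CT01",
                    class = "nonsynonymous") {
  stopifnot(k <= n)
  tm_pos <- if (gene == "GA") 1:20 else 51:100
  other_pos <- if (gene == "GA") 21:100 else c(1:50, 101:200)
  pos <- c(rep(tm_pos, length.out = k),
           if (n > k) rep(other_pos, length.out = n - k))
  data.frame(sample = sample, cancer_type = cancer, gene = gene,
             protein_pos = as.integer(pos)[seq_len(n)], variant_class = class,
             sift = NA_character_, polyphen = NA_character_, cadd = NA_real_,
             stringsAsFactors = FALSE)
}

# Mutation table realizing a given region x deleterious 2x2 table on GA.
muts_from_table <- function(tm_del, tm_not, other_del, other_not) {
  mk <- function(n, in_tm, del) {
    if (n == 0) return(NULL)
    data.frame(sample = "S1", cancer_type = "CT01", gene = "GA",
               protein_pos = as.integer(rep(if (in_tm) 1:20 else 21:100,
                                            length.out = n)),
               variant_class = "nonsynonymous",
               sift = if (del) "deleterious" else "tolerated",
               polyphen = if (del) "damaging" else "benign",
               cadd = 10, stringsAsFactors = FALSE)
  }
  do.call(rbind, Filter(Negate(is.null),
                        list(mk(tm_del, TRUE, TRUE), mk(tm_not, TRUE, FALSE),
                             mk(other_del, FALSE, TRUE),
                             mk(other_not, FALSE, FALSE))))
}

# Default study-condition cohort, generated once per test run.
cached_cohort <- local({
  env <- new.env()
  function(seed = 421L) {
    key <- paste0("s", seed)
    if (is.null(env[[key]])) env[[key]] <- sim_cohort(sim_config(seed = seed))
    env[[key]]
  }
})

# Brute-force maximally selected cutpoint via survival::survdiff.
brute_cutpoint <- function(x, time, event, minprop = 0.1) {
  xs <- sort(unique(x))
  cand <- (xs[-length(xs)] + xs[-1]) / 2
  n <- length(x)
  nmin <- max(1, ceiling(minprop * n))
  best <- NULL
  for (cp in cand) {
    g <- x <= cp
    if (sum(g) < nmin || sum(!g) < nmin) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    if (is.null(best) || sd$chisq > best$chisq)
      best <- list(cutpoint = cp, chisq = sd$chisq)
  }
  best
}
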