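#' Pipeline configuration
#'
#' Validates input paths and thresholds for [run_pipeline()]. Only `panel`
#' is mandatory; stages whose inputs are absent are skipped (and logged) at
#' run time.
#'
#' @param panel path to the panel TSV (`symbol`, `family`, `length`).
#' @param tm_intervals optional TM interval TSV (`gene`, `start`, `end`).
#' @param mutations,cnv,cnv_meta,expression,expression_meta,clinical,status,gene_sets,ic50,cell_expression
#'   optional input paths (the file set written by [write_cohort()]).
#'   `status` is a patient alteration-status TSV (`patient_id`, `status`);
#'   when absent the status is derived from the genetic inputs via
#'   [alteration_status()].
#' @param outdir output directory.
#' @param seed integer seed used by the seeded stages (GSEA permutations).
#' @param e_threshold,p_threshold,tm_p_adjust TM-enrichment thresholds, see
#'   [tm_region_enrichment()].
#' @param min_normals,lfc_threshold,de_alpha differential expression
#'   settings, see [differential_expression()].
#' @param minprop,zero_fraction_limit survival settings, see
#'   [hazard_ratio()].
#' @param n_perm,min_overlap GSEA settings, see [gsea_screen()].
#' @param gsea_anchors anchors for the GSEA stage; default: panel genes
#'   capped at `max_anchors`.
#' @param max_anchors cap on the number of GSEA anchors (default 10).
#' @param na_limit,knn_k IC50 preprocessing, see [prepare_ic50()].
#' @param scc_threshold_drug |SCC| threshold of the drug screen
#'   (default 0.15).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel,
                            tm_intervals = NULL,
                            mutations = NULL,
                            cnv = NULL,
                            cnv_meta = NULL,
                            expression = NULL,
                            expression_meta = NULL,
                            clinical = NULL,
                            status = NULL,
                            gene_sets = NULL,
                            ic50 = NULL,
                            cell_expression = NULL,
                            outdir = "panelscan_out",
                            seed = 1L,
                            e_threshold = 1.3,
                            p_threshold = 0.05,
                            tm_p_adjust = "BH",
                            min_normals = 5L,
                            lfc_threshold = 1,
                            de_alpha = 0.05,
                            minprop = 0.1,
                            zero_fraction_limit = 0.5,
                            n_perm = 1000L,
                            min_overlap = 5L,
                            gsea_anchors = NULL,
                            max_anchors = 10L,
                            na_limit = 0.30,
                            knn_k = 5L,
                            scc_threshold_drug = 0.15) {
  cfg <- as.list(environment())
  path_fields <- c("panel", "tm_intervals", "mutations", "cnv", "cnv_meta",
                   "expression", "expression_meta", "clinical", "status",
                   "gene_sets", "ic50", "cell_expression")
  for (f in path_fields) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: ", f, " file not found: ", cfg[[f]])
  }
  stopifnot(e_threshold > 0, p_threshold > 0, p_threshold <= 1,
            minprop > 0, minprop < 0.5, na_limit >= 0, na_limit < 1,
            n_perm >= 1, scc_threshold_drug >= 0, scc_threshold_drug < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full panel analysis pipeline
#'
#' Executes the stages in order -- genomic landscape (mutation/CNV
#' frequencies, TMB, TM-region enrichment, deleterious-mutation
#' association), differential expression, clinical relevance (alteration
#' status, feature comparisons, per-gene survival screen), pathway GSEA,
#' and pharmacogenomics (IC50 filtering/imputation and the drug screen) --
#' skipping stages whose inputs are absent. One TSV is written per result
#' table, plus `run_manifest.txt` (config hash, seed, package version,
#' thresholds applied, stages run) and `run_log.txt`. Outputs are
#' deterministic given identical config and seed.
#'
#' @param config [pipeline_config()].
#' @param quiet suppress progress messages (default `FALSE`).
#' @return named list of result tables (also written under
#'   `config$outdir`), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  outputs <- list()
  emit <- function(name, df) {
    outputs[[name]] <<- df
    write_tsv(df, file.path(config$outdir, paste0(name, ".tsv")))
  }

  panel <- read_panel(config$panel, config$tm_intervals)
  note("panel: ", nrow(panel$genes), " genes, ",
       length(unique(panel$genes$family)), " families")

  muts <- if (!is.null(config$mutations)) read_mutations(config$mutations)
  cnv <- if (!is.null(config$cnv))
    read_omics(config$cnv, "cnv", config$cnv_meta)
  expr <- if (!is.null(config$expression))
    read_omics(config$expression, "expression", config$expression_meta)
  clinical <- if (!is.null(config$clinical)) read_clinical(config$clinical)

  # --- landscape ---------------------------------------------------------
  if (!is.null(muts)) {
    meta <- if (!is.null(cnv)) omx_meta(cnv) else NULL
    cohort_sizes <- if (!is.null(meta))
      table(meta$cancer_type) else table(unique(
        muts[, c("sample", "cancer_type")])$cancer_type)
    freq <- mutation_frequency_matrix(
      muts, stats::setNames(as.integer(cohort_sizes), names(cohort_sizes)),
      panel)
    emit("mutation_frequency",
         data.frame(gene = rownames(freq), freq, check.names = FALSE))
    samples <- if (!is.null(meta)) meta$sample else unique(muts$sample)
    tmb <- compute_tmb(muts, samples)
    emit("tmb", data.frame(sample = names(tmb), tmb = as.integer(tmb),
                           stringsAsFactors = FALSE))
    enr <- tm_region_enrichment(muts, panel,
                                e_threshold = config$e_threshold,
                                p_threshold = config$p_threshold,
                                p_adjust = config$tm_p_adjust)
    emit("tm_enrichment", enr)
    note("landscape: ", sum(enr$enriched), " genes enriched in TM regions (E > ",
         config$e_threshold, ", ", config$tm_p_adjust, " p < ",
         config$p_threshold, ")")
    assoc <- tryCatch(deleterious_region_association(muts, panel),
                      error = function(e) e)
    if (!inherits(assoc, "error")) {
      emit("deleterious_association",
           data.frame(region = rep(rownames(assoc$table), 2),
                      label = rep(colnames(assoc$table), each = 2),
                      count = as.integer(assoc$table),
                      p_value = assoc$p_value,
                      odds_ratio = assoc$odds_ratio))
    } else note("landscape: deleterious association skipped (",
                conditionMessage(assoc), ")")
  } else note("landscape: skipped (no mutation input)")

  if (!is.null(cnv)) {
    cf <- cnv_frequency_matrix(cnv, panel)
    emit("cnv_gain_frequency",
         data.frame(gene = rownames(cf$gain), cf$gain, check.names = FALSE))
    emit("cnv_loss_frequency",
         data.frame(gene = rownames(cf$loss), cf$loss, check.names = FALSE))
  } else note("cnv frequencies: skipped (no cnv input)")

  # --- differential expression ------------------------------------------
  if (!is.null(expr) && !is.null(omx_meta(expr)) &&
      "tumor" %in% names(omx_meta(expr))) {
    de <- differential_expression(expr, min_normals = config$min_normals,
                                  lfc_threshold = config$lfc_threshold,
                                  alpha = config$de_alpha)
    emit("differential_expression", de$results)
    if (nrow(de$skipped)) emit("de_skipped_cohorts", de$skipped)
    note("expression: ", sum(de$results$direction != "ns"),
         " DE gene-cancer pairs")
  } else note("expression: skipped (no expression input with tumor/normal metadata)")

  # --- clinical relevance ------------------------------------------------
  if (!is.null(clinical) &&
      (!is.null(config$status) || !is.null(muts) || !is.null(cnv))) {
    patients <- clinical$patient_id
    if (!is.null(config$status)) {
      st <- utils::read.delim(config$status, stringsAsFactors = FALSE)
      status <- stats::setNames(st$status, st$patient_id)[patients]
      note("clinical: using supplied alteration status")
    } else {
      status <- alteration_status(muts, cnv, panel, patients = patients)
      note("clinical: alteration status derived from genetic inputs")
    }
    emit("alteration_status",
         data.frame(patient_id = names(status), status = unname(status),
                    stringsAsFactors = FALSE))
    cmp <- tryCatch(compare_clinical_features(clinical, status),
                    error = function(e) e)
    if (!inherits(cmp, "error")) emit("clinical_comparisons", cmp)
    else note("clinical: feature comparisons skipped (",
              conditionMessage(cmp), ")")
    lr <- tryCatch(logrank_test(clinical$os_time, clinical$os_event,
                                status[clinical$patient_id]),
                   error = function(e) e)
    if (!inherits(lr, "error")) {
      grp_hr <- hazard_ratio(factor(status[clinical$patient_id],
                                    c("unaltered", "altered")),
                             clinical$os_time, clinical$os_event)
      emit("alteration_survival",
           cbind(data.frame(comparison = "altered_vs_unaltered"), grp_hr))
      note("clinical: altered-vs-unaltered HR ",
           round(grp_hr$hr, 3), ", log-rank p ",
           signif(grp_hr$p_value, 3))
    } else note("clinical: survival comparison skipped (",
                conditionMessage(lr), ")")
  } else note("clinical comparisons: skipped (missing clinical or genetic input)")

  if (!is.null(clinical) && !is.null(expr)) {
    tum <- omx_meta(expr)$tumor
    texpr <- omics_matrix(unomx(expr)[, tum, drop = FALSE],
                          role = "expression",
                          col_data = omx_meta(expr)[tum, , drop = FALSE])
    surv <- survival_screen(texpr, clinical, panel,
                            minprop = config$minprop,
                            zero_fraction_limit = config$zero_fraction_limit)
    emit("survival_screen", surv)
    note("clinical: ", sum(surv$classification == "risky"), " risky / ",
         sum(surv$classification == "protective"),
         " protective gene-cancer pairs")
  } else note("survival screen: skipped (missing clinical or expression input)")

  # --- pathways -----------------------------------------------------------
  if (!is.null(expr) && !is.null(config$gene_sets)) {
    sets <- read_gmt(config$gene_sets)
    anchors <- config$gsea_anchors
    if (is.null(anchors))
      anchors <- utils::head(intersect(panel$genes$symbol, rownames(expr)),
                             config$max_anchors)
    tum <- if (!is.null(omx_meta(expr)) && "tumor" %in% names(omx_meta(expr)))
      omx_meta(expr)$tumor else rep(TRUE, ncol(expr))
    gsea <- gsea_screen(unomx(expr)[, tum, drop = FALSE], anchors, sets,
                        n_perm = config$n_perm, seed = config$seed,
                        min_overlap = config$min_overlap)
    emit("gsea_screen", gsea)
    note("pathways: ", sum(gsea$adjusted_p < 0.05, na.rm = TRUE),
         " significant anchor-set pairs")
  } else note("pathways: skipped (missing expression or gene sets)")

  # --- pharmacogenomics ---------------------------------------------------
  if (!is.null(config$ic50) && !is.null(config$cell_expression)) {
    ic50 <- read_matrix_tsv(config$ic50)
    cexpr <- read_matrix_tsv(config$cell_expression)
    prep <- prepare_ic50(ic50, na_limit = config$na_limit, k = config$knn_k)
    if (nrow(prep$removed))
      emit("ic50_removed_drugs", prep$removed)
    note("pharmaco: removed ", nrow(prep$removed), " drugs, imputed ",
         prep$n_imputed, " values")
    pg <- intersect(panel$genes$symbol, rownames(cexpr))
    screen <- correlation_screen(cexpr[pg, , drop = FALSE], prep$matrix,
                                 scc_threshold = config$scc_threshold_drug)
    emit("drug_correlations", screen)
    note("pharmaco: ", sum(screen$significant, na.rm = TRUE),
         " significant gene-drug pairs (|SCC| > ",
         config$scc_threshold_drug, ")")
  } else note("pharmaco: skipped (missing ic50 or cell-line expression)")

  # --- manifest -----------------------------------------------------------
  cfg_flat <- config
  class(cfg_flat) <- "list"
  cfg_lines <- vapply(names(cfg_flat), function(k)
    paste0(k, "=", paste(format(cfg_flat[[k]], trim = TRUE),
                         collapse = ",")), character(1))
  cfg_file <- file.path(config$outdir, "run_config.txt")
  writeLines(cfg_lines, cfg_file)
  manifest <- c(
    list(package_version = as.character(utils::packageVersion("panelscan")),
         seed = config$seed,
         config_md5 = unname(tools::md5sum(cfg_file)),
         tables = paste(sort(names(outputs)), collapse = ","),
         coordinates = "protein residues, 1-based inclusive",
         frequencies = "proportions in [0,1]"))
  write_manifest(manifest, file.path(config$outdir, "run_manifest.txt"))
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(outputs)
}
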