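write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, DMP meta-analysis (sex, age, saDMP
#' classification, interaction scan), the saVMP variability analysis,
#' per-cohort epimutation and entropy profiling with their age/sex models,
#' and enrichment of the saDMP/snaDMP catalogs, writing one TSV per catalog
#' plus a JSON run summary to the configured output directory. The run is
#' deterministic given the config (the seed is set at entry).
#'
#' @param config A [run_config()].
#' @return Invisibly, the run-summary list (also written as
#'   `run_summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- stage("read", {
    list(
      datasets = lapply(config$dataset_paths, read_beta_matrix),
      sheets = lapply(config$sheet_paths, read_sample_sheet),
      annotation = read_annotation(config$annotation_path)
    )
  })

  datasets <- stage("preprocess", {
    filtered <- lapply(inputs$datasets, filter_probes, annotation = inputs$annotation)
    if (length(filtered) > 1L) intersect_common(filtered) else filtered
  })
  sheets <- inputs$sheets
  universe <- probe_ids(datasets[[1L]])

  dmp <- stage("dmp_meta", {
    sex_tabs <- mapply(function(ds, sh) {
      associate(residualize_for("sex-assoc", ds, sh), sh$sex)
    }, datasets, sheets, SIMPLIFY = FALSE)
    age_tabs <- mapply(function(ds, sh) {
      associate(residualize_for("age-assoc", ds, sh), sh$age)
    }, datasets, sheets, SIMPLIFY = FALSE)
    sdmp <- call_dmps(sex_tabs, config$sig_threshold)
    admp <- call_dmps(age_tabs, config$sig_threshold)
    catalog <- classify_sadmps(sdmp$set, admp$set, sdmp$meta, admp$meta)
    inter <- interaction_scan(datasets, sheets, config$sig_threshold)
    list(catalog = catalog, sdmp = sdmp$set, admp = admp$set, interaction = inter$set)
  })
  write_tsv(dmp$catalog, file.path(config$out_dir, "dmp_catalog.tsv"))
  write_tsv(data.frame(probe_id = dmp$interaction),
            file.path(config$out_dir, "interaction_probes.tsv"))

  vmp <- stage("vmp", {
    bp <- mapply(bp_scan, datasets, sheets, SIMPLIFY = FALSE)
    call_savmps(bp, config$sig_threshold, config$homosced_threshold)
  })
  write_tsv(vmp, file.path(config$out_dir, "vmp_catalog.tsv"))

  epi <- stage("epimutation", {
    lapply(seq_along(datasets), function(i) {
      prof <- detect_epimutations(datasets[[i]], k = config$iqr_multiplier)
      burden <- burden_model(prof, sheets[[i]])
      write_tsv(data.frame(sample_id = names(prof$counts), count = prof$counts),
                file.path(config$out_dir,
                          sprintf("epimutation_burden_%s.tsv", datasets[[i]]$cohort)))
      write_tsv(prof$flags,
                file.path(config$out_dir,
                          sprintf("epimutation_flags_%s.tsv", datasets[[i]]$cohort)))
      list(profile = prof, burden = burden)
    })
  })

  ent <- stage("entropy", {
    lapply(seq_along(datasets), function(i) {
      e <- shannon_entropy(adjusted_betas(datasets[[i]], sheets[[i]]))
      write_tsv(data.frame(sample_id = names(e), entropy = as.numeric(e)),
                file.path(config$out_dir,
                          sprintf("entropy_%s.tsv", datasets[[i]]$cohort)))
      list(entropy = e, model = entropy_age_model(e, sheets[[i]]))
    })
  })

  enr <- stage("enrichment", {
    sa <- dmp$catalog$probe_id[dmp$catalog$class == "saDMP"]
    sna <- dmp$catalog$probe_id[dmp$catalog$class == "snaDMP"]
    out <- list()
    if (length(sa)) {
      out$saDMP <- enrichment_report(sa, universe, inputs$annotation)
      write_tsv(out$saDMP, file.path(config$out_dir, "enrichment_saDMP.tsv"))
    }
    if (length(sna)) {
      out$snaDMP <- enrichment_report(sna, universe, inputs$annotation)
      write_tsv(out$snaDMP, file.path(config$out_dir, "enrichment_snaDMP.tsv"))
    }
    out
  })

  summary <- list(
    n_datasets = length(datasets),
    n_probes_common = length(universe),
    thresholds = list(significance = config$sig_threshold,
                      homoscedasticity = config$homosced_threshold,
                      iqr_multiplier = config$iqr_multiplier),
    seed = config$seed,
    counts = list(
      sDMP = length(dmp$sdmp),
      aDMP = length(dmp$admp),
      saDMP = sum(dmp$catalog$class == "saDMP"),
      snaDMP = sum(dmp$catalog$class == "snaDMP"),
      interaction = length(dmp$interaction),
      saVMP_female = sum(vmp$scenario == "female-specific"),
      saVMP_male = sum(vmp$scenario == "male-specific"),
      saVMP_opposite = sum(vmp$scenario == "opposite"),
      epimutations_per_cohort = vapply(epi, function(x) sum(x$profile$counts),
                                       numeric(1))
    ),
    entropy_age_slope = lapply(ent, function(x) x$model$per_sex$slope)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
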