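#' Filter probes against the annotation
#'
#' Removes sex-chromosome probes and blacklist-flagged probes (internal SNPs,
#' non-unique bisulfite mapping, off-target hybridization). Dataset probes
#' absent from the annotation are dropped with a logged count.
#'
#' @param dataset A `MethylationDataset`.
#' @param annotation A `ProbeAnnotation`.
#' @param max_missing Probes with more than this fraction of missing values
#'   are also dropped (default 0.05).
#' @return The filtered `MethylationDataset`, with attribute `removal_report`
#'   (a data frame of per-reason counts).
#' @export
filter_probes <- function(dataset, annotation, max_missing = 0.05) {
  stopifnot(inherits(dataset, "MethylationDataset"),
            inherits(annotation, "ProbeAnnotation"))
  probes <- probe_ids(dataset)
  ann <- annotation[match(probes, annotation$probe_id), ]
  unannotated <- is.na(ann$probe_id)
  if (any(unannotated)) {
    message(sum(unannotated), " probe(s) not in annotation; dropped")
  }
  sex_chr <- !unannotated & ann$chr %in% c("X", "Y")
  blacklisted <- !unannotated & ann$blacklist
  too_missing <- rowMeans(is.na(dataset$beta)) > max_missing
  keep <- !unannotated & !sex_chr & !blacklisted & !too_missing
  if (!any(keep)) stop("no probes left after filtering")
  report <- data.frame(
    reason = c("unannotated", "sex_chromosome", "blacklist", "missingness", "retained"),
    n = c(sum(unannotated), sum(sex_chr), sum(blacklisted & !sex_chr),
          sum(too_missing & !unannotated & !sex_chr & !blacklisted), sum(keep))
  )
  out <- methylation_dataset(dataset$beta[keep, , drop = FALSE], dataset$cohort)
  attr(out, "removal_report") <- report
  out
}

#' Restrict datasets to their common probes
#'
#' All datasets are cut down to the sorted intersection of their probe IDs,
#' in identical order, so that per-probe statistics line up across cohorts
#' for meta-analysis.
#'
#' @param datasets List of >= 2 `MethylationDataset`s.
#' @return List of restricted datasets, same length and order.
#' @export
intersect_common <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least 2 datasets to intersect")
  common <- Reduce(intersect, lapply(datasets, probe_ids))
  if (length(common) == 0L) stop("empty probe intersection across datasets")
  common <- sort(common)
  lapply(datasets, function(ds) {
    methylation_dataset(ds$beta[common, , drop = FALSE], ds$cohort)
  })
}

#' Residualize betas for one analysis axis
#'
#' Dispatches the covariate recipe of each axis before association testing:
#' the sex axis adjusts for age plus the five cell fractions, the age axis
#' for sex plus cell fractions, and the variability and entropy axes for
#' cell fractions only. The epimutation axis uses raw betas and has no
#' recipe here.
#'
#' @param axis One of `"sex-assoc"`, `"age-assoc"`, `"variability"`,
#'   `"entropy"`.
#' @param dataset A `MethylationDataset`.
#' @param sheet Matching `SampleSheet`.
#' @return Residual matrix from [regress_out()].
#' @export
residualize_for <- function(axis, dataset, sheet) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (!identical(colnames(dataset$beta), sheet$sample_id)) {
    stop("sample sheet not aligned with dataset columns")
  }
  cells <- sheet[, CELL_COLS]
  covs <- switch(axis,
    "sex-assoc" = cbind(age = sheet$age, cells),
    "age-assoc" = cbind(sex = sex_code(sheet$sex), cells),
    "variability" = cells,
    "entropy" = cells,
    stop("unknown axis: ", axis)
  )
  regress_out(dataset$beta, covs)
}
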