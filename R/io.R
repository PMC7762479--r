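# Cell-fraction columns required on every sample sheet (five-part whole-blood
# deconvolution: CD8 T, CD4 T, natural killer, B cells, granulocytes).
CELL_COLS <- c("CD8T", "CD4T", "NK", "Bcell", "Gran")

ISLAND_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")

#' Construct a methylation dataset
#'
#' A `MethylationDataset` is a probe-by-sample matrix of beta values (fraction
#' methylated, in \[0,1\]) for one cohort, with unique probe and sample IDs.
#'
#' @param beta Numeric matrix, probes in rows, samples in columns; `rownames`
#'   are probe IDs and `colnames` sample IDs. `NA` marks missing values.
#' @param cohort Single string naming the cohort.
#' @return An object of class `MethylationDataset`.
#' @export
methylation_dataset <- function(beta, cohort = "cohort") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix")
  }
  if (nrow(beta) == 0L || ncol(beta) == 0L) stop("empty beta matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) {
    stop("duplicate probe ID: ", rownames(beta)[duplicated(rownames(beta))][1L])
  }
  if (anyDuplicated(colnames(beta))) {
    stop("duplicate sample ID: ", colnames(beta)[duplicated(colnames(beta))][1L])
  }
  bad <- which(!is.na(beta) & (beta < -1e-9 | beta > 1 + 1e-9), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "beta value %.6g outside [0,1] at probe '%s', sample '%s'",
      beta[bad[1L, , drop = FALSE]],
      rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]]
    ))
  }
  structure(list(beta = beta, cohort = cohort), class = "MethylationDataset")
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat(sprintf(
    "MethylationDataset '%s': %d probes x %d samples (%d missing values)\n",
    x$cohort, nrow(x$beta), ncol(x$beta), sum(is.na(x$beta))
  ))
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) dim(x$beta)

#' Probe IDs of a dataset
#'
#' @param ds A `MethylationDataset`.
#' @return Character vector of probe IDs (the beta-matrix rownames).
#' @export
probe_ids <- function(ds) rownames(ds$beta)
sample_ids <- function(ds) colnames(ds$beta)

#' Read a beta-value matrix
#'
#' Reads a TSV or CSV file whose first column holds probe IDs and whose header
#' row holds sample IDs, into a [methylation_dataset()]. The delimiter is
#' taken from the file extension (`.csv` means comma, anything else tab);
#' gzip-compressed files are handled transparently.
#'
#' @param path Path to the file.
#' @param cohort Cohort label; default is the file name without extension.
#' @return A `MethylationDataset`.
#' @export
read_beta_matrix <- function(path, cohort = NULL) {
  if (is.null(cohort)) cohort <- sub("\\.(tsv|csv)(\\.gz)?$", "", basename(path))
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("beta matrix file needs a probe column and >=1 sample column")
  probes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in beta matrix body")
  rownames(m) <- probes
  methylation_dataset(m, cohort)
}

#' Write a beta-value matrix
#'
#' Inverse of [read_beta_matrix()]: probe IDs in the first column
#' (`probe_id`), one column per sample. Values are written in full precision
#' so that a read/write round trip is the identity.
#'
#' @param dataset A `MethylationDataset`.
#' @param path Output path (`.csv` for comma-separated, otherwise TSV;
#'   a `.gz` suffix gzips the output).
#' @export
write_beta_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- data.frame(probe_id = probe_ids(dataset),
                   dataset$beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet is a CSV with one row per sample and columns `sample_id`,
#' `age` (years), `sex` (`F` or `M`) and the five blood-cell fraction
#' estimates `CD8T`, `CD4T`, `NK`, `Bcell`, `Gran`. Cell fractions are
#' estimates and need not sum to one; a sum far from 1 is only warned about.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_sample_sheet(df)
}

#' Validate a data frame as a sample sheet
#' @param df Data frame with the sample-sheet columns.
#' @return The validated `SampleSheet`.
#' @export
as_sample_sheet <- function(df) {
  required <- c("sample_id", "age", "sex", CELL_COLS)
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("sample sheet missing column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  bad_sex <- setdiff(unique(as.character(df$sex)), c("F", "M"))
  if (length(bad_sex)) stop("unknown sex token: '", bad_sex[1L], "' (expected F or M)")
  if (any(df$age < 0, na.rm = TRUE)) stop("negative age in sample sheet")
  fr <- as.matrix(df[, CELL_COLS])
  if (any(fr < 0, na.rm = TRUE)) stop("negative cell fraction in sample sheet")
  tot <- rowSums(fr)
  if (any(abs(tot - 1) > 0.25, na.rm = TRUE)) {
    warning(sprintf("%d sample(s) have cell fractions summing far from 1 (estimates need not sum to 1)",
                    sum(abs(tot - 1) > 0.25, na.rm = TRUE)))
  }
  df$sex <- as.character(df$sex)
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Write a sample sheet
#' @param sheet A `SampleSheet`.
#' @param path Output CSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numeric sex coding used pipeline-wide
#'
#' Fixed convention: female = 0, male = 1, so a positive sex effect means
#' "hypermethylated in males".
#'
#' @param sex Character vector of `"F"`/`"M"`.
#' @return Numeric 0/1 vector.
#' @export
sex_code <- function(sex) {
  out <- ifelse(sex == "M", 1, ifelse(sex == "F", 0, NA_real_))
  if (anyNA(out)) stop("unknown sex token in sex_code()")
  out
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `chr` (1-22, X, Y), `pos` (1-based manifest
#' coordinate), `island_relation` (Island / N_Shore / S_Shore / N_Shelf /
#' S_Shelf / OpenSea), `genes` (semicolon-separated symbols, possibly empty),
#' and the 0/1 flags `blacklist` (SNP / cross-reactive / off-target),
#' `imprinted` and `hormone_gene`.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` of class `ProbeAnnotation`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "", na.strings = character())
  as_probe_annotation(df)
}

#' Validate a data frame as probe annotation
#' @param df Data frame with annotation columns.
#' @return The validated `ProbeAnnotation`.
#' @export
as_probe_annotation <- function(df) {
  required <- c("probe_id", "chr", "pos", "island_relation", "genes",
                "blacklist", "imprinted", "hormone_gene")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("annotation missing column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  bad <- setdiff(unique(df$island_relation), ISLAND_LEVELS)
  if (length(bad)) stop("unknown island relation: ", bad[1L])
  df$chr <- as.character(df$chr)
  df$blacklist <- as.logical(df$blacklist)
  df$imprinted <- as.logical(df$imprinted)
  df$hormone_gene <- as.logical(df$hormone_gene)
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' Write a probe annotation table
#' @param annotation A `ProbeAnnotation`.
#' @param path Output TSV path.
#' @export
write_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df$blacklist <- as.integer(df$blacklist)
  df$imprinted <- as.integer(df$imprinted)
  df$hormone_gene <- as.integer(df$hormone_gene)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the file paths and thresholds steering [run_pipeline()].
#'
#' @param dataset_paths Character vector of beta-matrix files, one per cohort.
#' @param sheet_paths Matching character vector of sample-sheet CSVs.
#' @param annotation_path Probe annotation TSV.
#' @param sig_threshold Significance threshold on the Bonferroni-corrected
#'   meta p-value (default 0.01).
#' @param homosced_threshold Corrected meta p above which the other sex is
#'   called homoscedastic in the saVMP scenarios (default 0.05).
#' @param iqr_multiplier Epimutation outlier multiplier k in
#'   Q1 - k*IQR / Q3 + k*IQR (default 3).
#' @param age_bins Age-class bin edges, strictly increasing; defaults to the
#'   classes 14-39, 40-59, 60-94.
#' @param seed Integer random seed.
#' @param out_dir Output directory for catalogs and the run summary.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(dataset_paths, sheet_paths, annotation_path,
                       sig_threshold = 0.01, homosced_threshold = 0.05,
                       iqr_multiplier = 3,
                       age_bins = c(14, 39, 59, 94),
                       seed = 1L, out_dir = "results") {
  if (length(dataset_paths) < 1L) stop("need at least one dataset")
  if (length(sheet_paths) != length(dataset_paths)) {
    stop("dataset_paths and sheet_paths lengths differ")
  }
  stopifnot(sig_threshold > 0, sig_threshold < 1,
            homosced_threshold > 0, homosced_threshold < 1,
            iqr_multiplier > 0)
  if (any(diff(age_bins) <= 0)) stop("age bin edges must be strictly increasing")
  structure(list(
    dataset_paths = dataset_paths, sheet_paths = sheet_paths,
    annotation_path = annotation_path,
    sig_threshold = sig_threshold, homosced_threshold = homosced_threshold,
    iqr_multiplier = iqr_multiplier, age_bins = age_bins,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Every field of [run_config()] can be given in a YAML file; omitted fields
#' take their defaults.
#'
#' @param path YAML file path.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}
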