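#' Per-probe association of residualized betas with sex or age
#'
#' Pearson correlation of every probe's (residualized) values with the
#' target, with a two-sided t-test p-value and a Benjamini-Hochberg column
#' over all probes of the dataset. A binary sex target (F/M coded 0/1) makes
#' this the point-biserial correlation. Missing values are excluded pairwise.
#'
#' @param residuals Probe-by-sample matrix (typically from
#'   [residualize_for()]).
#' @param target Per-sample numeric vector (age) or character `"F"`/`"M"`.
#' @return A data frame of class `AssocStat`: `probe_id`, `r`, `p`, `p_bh`,
#'   `sign`, `n`, `flagged` (zero-variance probes get r = NA, p = 1,
#'   sign = 0).
#' @export
associate <- function(residuals, target) {
  if (is.character(target) || is.factor(target)) target <- sex_code(as.character(target))
  stopifnot(is.matrix(residuals), length(target) == ncol(residuals))
  n <- rowSums(!is.na(residuals) & !is.na(matrix(target, nrow(residuals),
                                                 ncol(residuals), byrow = TRUE)))
  if (any(n < 3L)) stop("every probe needs >= 3 pairwise-complete samples")
  suppressWarnings(
    r <- as.vector(stats::cor(t(residuals), target, use = "pairwise.complete.obs"))
  )
  flagged <- !is.finite(r)
  r_safe <- ifelse(flagged, 0, pmin(pmax(r, -1), 1))
  tstat <- r_safe * sqrt((n - 2) / pmax(1 - r_safe^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[flagged] <- 1
  out <- data.frame(
    probe_id = rownames(residuals),
    r = ifelse(flagged, NA_real_, r_safe),
    p = p,
    p_bh = adjust_pvalues(p, "BH"),
    sign = ifelse(flagged, 0L, as.integer(sign(r_safe))),
    n = n,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
  class(out) <- c("AssocStat", "data.frame")
  out
}

check_universe <- function(tables) {
  ids <- lapply(tables, `[[`, "probe_id")
  if (!all(vapply(ids[-1L], identical, logical(1), ids[[1L]]))) {
    stop("probe universes differ across datasets")
  }
  ids[[1L]]
}

# Column `col` of each per-dataset table as a probes-by-datasets matrix,
# robust to a single-probe universe.
collect_col <- function(tables, col, m) {
  matrix(vapply(tables, function(t) as.numeric(t[[col]]), numeric(m)),
         nrow = m)
}

#' Call meta-significant probes on one axis
#'
#' Runs the signed sample-size-weighted meta-analysis over the per-dataset
#' association tables, corrects the meta p-value by Bonferroni over the
#' probe universe, and keeps probes that are both significant
#' (corrected meta p strictly below `threshold`) and direction-concordant
#' in every dataset. By default the per-dataset Benjamini-Hochberg-adjusted
#' p-values are combined, matching the published procedure; set
#' `use_bh = FALSE` to combine raw p-values instead.
#'
#' @param assoc_tables List of `AssocStat` tables (one per dataset, same
#'   probe universe).
#' @param threshold Significance threshold on the Bonferroni-corrected meta
#'   p (default 0.01).
#' @param use_bh Combine BH-adjusted per-dataset p-values (default `TRUE`).
#' @return A list: `set` (character vector of called probes) and `meta`
#'   (`MetaStat` with probe rownames).
#' @export
call_dmps <- function(assoc_tables, threshold = 0.01, use_bh = TRUE) {
  if (length(assoc_tables) < 2L) stop("need association tables from >= 2 datasets")
  universe <- check_universe(assoc_tables)
  pcol <- if (use_bh) "p_bh" else "p"
  pvals <- collect_col(assoc_tables, pcol, length(universe))
  signs <- collect_col(assoc_tables, "sign", length(universe))
  n <- vapply(assoc_tables, function(t) max(t$n), numeric(1))
  rownames(pvals) <- universe
  meta <- stouffer_meta(pvals, signs, n)
  set <- universe[meta$p_bonf < threshold & meta$concordant]
  list(set = set, meta = meta)
}

#' Classify saDMPs and snaDMPs
#'
#' Intersects the sex- and age-associated probe sets: probes in both are
#' saDMPs (sex- and age-associated differentially methylated positions),
#' sex-only probes are snaDMPs, age-only probes are labeled `aDMP-only`.
#' saDMPs get a quadrant from the two meta directions (positive sex effect
#' means hypermethylated in males; positive age effect means
#' hypermethylation with aging).
#'
#' @param sdmp_set,admp_set Probe ID vectors from [call_dmps()].
#' @param sex_meta,age_meta The corresponding `MetaStat` tables (probe
#'   rownames covering the universe).
#' @return A data frame of class `DMPCatalog`: `probe_id`, `class`
#'   (`saDMP` / `snaDMP` / `aDMP-only` / `none`), `quadrant`, and per-axis
#'   meta `z`, `p` and `p_bonf` columns.
#' @export
classify_sadmps <- function(sdmp_set, admp_set, sex_meta, age_meta) {
  universe <- rownames(sex_meta)
  if (!identical(universe, rownames(age_meta))) {
    stop("sex and age meta tables cover different universes")
  }
  if (!all(sdmp_set %in% universe) || !all(admp_set %in% universe)) {
    stop("called sets must be subsets of the universe")
  }
  cls <- rep("none", length(universe))
  cls[universe %in% admp_set] <- "aDMP-only"
  cls[universe %in% sdmp_set] <- "snaDMP"
  cls[universe %in% sdmp_set & universe %in% admp_set] <- "saDMP"
  sex_dir <- ifelse(sex_meta$z > 0, "M-hyper", "M-hypo")
  age_dir <- ifelse(age_meta$z > 0, "age-hyper", "age-hypo")
  quadrant <- ifelse(cls == "saDMP", paste(sex_dir, age_dir, sep = "/"), "n/a")
  out <- data.frame(
    probe_id = universe, class = cls, quadrant = quadrant,
    sex_z = sex_meta$z, sex_p = sex_meta$p, sex_p_bonf = sex_meta$p_bonf,
    age_z = age_meta$z, age_p = age_meta$p, age_p_bonf = age_meta$p_bonf,
    stringsAsFactors = FALSE
  )
  class(out) <- c("DMPCatalog", "data.frame")
  out
}

# Vectorized per-probe OLS of beta on a fixed design; returns the estimate,
# t-test p and sign of one coefficient for every probe.
fit_coefficient <- function(beta, X, term) {
  j <- match(term, colnames(X))
  if (is.na(j)) stop("term not in design: ", term)
  XtXi <- chol2inv(chol(crossprod(X)))
  A <- XtXi %*% t(X)                     # p x n
  complete <- rowSums(is.na(beta)) == 0L
  est <- se <- rep(NA_real_, nrow(beta))
  dfree <- rep(nrow(X) - ncol(X), nrow(beta))
  if (any(complete)) {
    B <- beta[complete, , drop = FALSE]
    C <- B %*% t(A)                      # probes x p
    R <- B - C %*% t(X)
    rss <- rowSums(R^2)
    s2 <- rss / (nrow(X) - ncol(X))
    est[complete] <- C[, j]
    se[complete] <- sqrt(s2 * XtXi[j, j])
  }
  for (i in which(!complete)) {
    ok <- !is.na(beta[i, ])
    if (sum(ok) <= ncol(X)) next
    f <- stats::lm.fit(X[ok, , drop = FALSE], beta[i, ok])
    s2 <- sum(f$residuals^2) / f$df.residual
    xi <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))
    est[i] <- f$coefficients[j]
    se[i] <- sqrt(s2 * xi[j, j])
    dfree[i] <- f$df.residual
  }
  tstat <- est / se
  p <- 2 * stats::pt(abs(tstat), df = dfree, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  data.frame(probe_id = rownames(beta), estimate = est,
             p = p, sign = as.integer(sign(ifelse(is.na(est), 0, est))),
             stringsAsFactors = FALSE)
}

#' Scan for age-by-sex interactions in methylation trajectories
#'
#' Per dataset and probe, fits
#' `beta ~ age + sex + age:sex + CD8T + CD4T + NK + Bcell + Gran` and takes
#' the interaction-term t-test p-value; the per-dataset p-values are
#' BH-adjusted, combined by signed sample-size-weighted meta-analysis using
#' the interaction-slope signs, Bonferroni-corrected over the universe, and
#' filtered for all-dataset sign concordance.
#'
#' @param datasets List of `MethylationDataset`s on a common probe universe.
#' @param sheets Parallel list of `SampleSheet`s.
#' @param threshold Corrected-meta-p threshold (default 0.01).
#' @return A list: `set` (called interaction probes) and `meta`
#'   (`MetaStat`).
#' @export
interaction_scan <- function(datasets, sheets, threshold = 0.01) {
  stopifnot(length(datasets) == length(sheets), length(datasets) >= 2L)
  tables <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]; sh <- sheets[[i]]
    if (!identical(colnames(ds$beta), sh$sample_id)) {
      stop("sample sheet not aligned with dataset ", i)
    }
    sexn <- sex_code(sh$sex)
    if (length(unique(sexn)) < 2L) stop("both sexes required in dataset ", i)
    X <- cbind(intercept = 1, age = sh$age, sex = sexn,
               age_sex = sh$age * sexn, as.matrix(sh[, CELL_COLS]))
    tab <- fit_coefficient(ds$beta, X, "age_sex")
    tab$p_bh <- adjust_pvalues(tab$p, "BH")
    tab$n <- nrow(sh)
    tables[[i]] <- tab
  }
  universe <- check_universe(tables)
  pvals <- collect_col(tables, "p_bh", length(universe))
  signs <- collect_col(tables, "sign", length(universe))
  rownames(pvals) <- universe
  meta <- stouffer_meta(pvals, signs,
                        vapply(tables, function(t) t$n[1L], numeric(1)))
  list(set = universe[meta$p_bonf < threshold & meta$concordant], meta = meta)
}
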