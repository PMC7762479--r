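#' Cell-composition-adjusted beta values
#'
#' Regresses the five blood-cell fractions out of the betas, then restores
#' each probe's mean: `beta_adj[i, j] = residual[i, j] + mean(beta[i, ])`,
#' so adjusted values stay on the beta scale. Values pushed outside
#' `[eps, 1 - eps]` by the adjustment are clipped, with the number of clipped
#' cells recorded.
#'
#' @param dataset A `MethylationDataset`.
#' @param sheet Matching `SampleSheet`.
#' @param eps Clipping margin keeping values strictly inside (0, 1)
#'   (default 1e-6).
#' @return A list of class `AdjustedBetaMatrix`: `beta_adj`, `probe_means`,
#'   `eps`, `n_clipped`.
#' @export
adjusted_betas <- function(dataset, sheet, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5)
  res <- residualize_for("entropy", dataset, sheet)
  pm <- rowMeans(dataset$beta, na.rm = TRUE)
  adj <- res + pm
  n_clipped <- sum(adj < eps | adj > 1 - eps, na.rm = TRUE)
  adj <- pmin(pmax(adj, eps), 1 - eps)
  structure(list(beta_adj = adj, probe_means = pm, eps = eps,
                 n_clipped = n_clipped),
            class = "AdjustedBetaMatrix")
}

#' Normalized Shannon entropy per subject
#'
#' For subject j over N probes,
#' `Entropy_j = 1 / (N * log(1/2)) * sum_i [b * log(b) + (1 - b) * log(1 - b)]`
#' with `b = beta_adj[i, j]` and natural logarithms. The normalization maps
#' entropy into \[0, 1\]: 1 when every site is half-methylated (maximal
#' disorder), approaching 0 for a fully determined methylome.
#'
#' @param adjusted An `AdjustedBetaMatrix`, or a bare numeric matrix with all
#'   values strictly inside (0, 1).
#' @return A named numeric vector of class `EntropyProfile`, one entropy per
#'   subject.
#' @export
shannon_entropy <- function(adjusted) {
  mat <- if (inherits(adjusted, "AdjustedBetaMatrix")) adjusted$beta_adj else adjusted
  stopifnot(is.matrix(mat))
  if (any(mat <= 0 | mat >= 1, na.rm = TRUE)) {
    stop("values must lie strictly inside (0,1); clip via adjusted_betas()")
  }
  h <- mat * log(mat) + (1 - mat) * log1p(-mat)
  n_used <- colSums(!is.na(h))
  ent <- colSums(h, na.rm = TRUE) / (n_used * log(0.5))
  structure(ent, class = "EntropyProfile")
}

#' Age and sex models of methylome entropy
#'
#' Per-sex OLS of entropy on age plus the pooled age-by-sex ANCOVA, the same
#' modeling used for epimutation burden.
#'
#' @param entropy An `EntropyProfile` (named by sample).
#' @param sheet Matching `SampleSheet`.
#' @return A list of class `EntropyModel`: `per_sex` (sex, slope, p, n) and
#'   `ancova`.
#' @export
entropy_age_model <- function(entropy, sheet) {
  e <- unclass(entropy)[sheet$sample_id]
  if (anyNA(e)) stop("sample sheet and entropy profile subjects differ")
  per_sex <- do.call(rbind, lapply(c("F", "M"), function(s) {
    idx <- sheet$sex == s
    fit <- summary(stats::lm(e[idx] ~ sheet$age[idx]))$coefficients
    data.frame(sex = s, slope = fit[2L, 1L], p = fit[2L, 4L], n = sum(idx),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sex = per_sex,
                 ancova = ancova_interaction(e, sheet$age, sheet$sex)),
            class = "EntropyModel")
}
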