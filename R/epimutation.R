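#' Interquartile-range outlier bounds for one probe
#'
#' Quartiles use linear interpolation between order statistics (R's default
#' quantile type 7); the convention is fixed because the flag set can change
#' with it. Bounds are `L = Q1 - k * IQR` and `U = Q3 + k * IQR`.
#'
#' @param x Numeric vector of beta values (>= 4 finite values).
#' @param k IQR multiplier (default 3).
#' @return A list of class `EpimutationBounds`: `q1`, `q3`, `iqr`, `lower`,
#'   `upper`, `k`.
#' @export
compute_bounds <- function(x, k = 3) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need >= 4 finite values to compute quartiles")
  if (k < 0) stop("IQR multiplier must be nonnegative")
  q <- stats::quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  structure(list(q1 = q[1L], q3 = q[2L], iqr = iqr,
                 lower = q[1L] - k * iqr, upper = q[2L] + k * iqr, k = k),
            class = "EpimutationBounds")
}

#' Detect epimutations in a dataset
#'
#' Flags every (probe, subject) cell whose beta value lies strictly outside
#' the probe's `Q1 - k IQR` / `Q3 + k IQR` bounds computed across the cohort;
#' values equal to a bound are not flagged. Invariant probes (IQR = 0) flag
#' any deviation from the constant; the optional `min_iqr` filter skips
#' probes with an IQR at or below it (default 0 = off, skipped probes are
#' counted in the result).
#'
#' @param dataset A `MethylationDataset`.
#' @param k IQR multiplier (default 3).
#' @param min_iqr Probes with `IQR <= min_iqr` are excluded from flagging
#'   when `min_iqr > 0`.
#' @return A list of class `EpimutationProfile`: `counts` (named per-subject
#'   integer vector), `flags` (data frame of `probe_id`, `sample_id`,
#'   `value`), `bounds` (per-probe data frame), `k`, and `n_skipped` probes.
#' @export
detect_epimutations <- function(dataset, k = 3, min_iqr = 0) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  beta <- dataset$beta
  qs <- apply(beta, 1L, stats::quantile, probs = c(0.25, 0.75),
              na.rm = TRUE, names = FALSE, type = 7)
  iqr <- qs[2L, ] - qs[1L, ]
  lower <- qs[1L, ] - k * iqr
  upper <- qs[2L, ] + k * iqr
  active <- if (min_iqr > 0) iqr > min_iqr else rep(TRUE, nrow(beta))
  out <- !is.na(beta) & (beta < lower | beta > upper) & active
  idx <- which(out, arr.ind = TRUE)
  flags <- data.frame(
    probe_id = rownames(beta)[idx[, 1L]],
    sample_id = colnames(beta)[idx[, 2L]],
    value = beta[idx],
    stringsAsFactors = FALSE
  )
  counts <- colSums(out)
  bounds <- data.frame(probe_id = rownames(beta), q1 = qs[1L, ], q3 = qs[2L, ],
                       iqr = iqr, lower = lower, upper = upper,
                       stringsAsFactors = FALSE)
  structure(list(counts = counts, flags = flags, bounds = bounds, k = k,
                 n_skipped = sum(!active)),
            class = "EpimutationProfile")
}

#' Age and sex models of epimutation burden
#'
#' Regresses `log10(count + 1)` on age separately in females and males
#' (reporting slope and slope p-value per sex), and fits the pooled ANCOVA
#' with an age-by-sex interaction to ask whether the age trend differs
#' between sexes.
#'
#' @param profile An `EpimutationProfile`.
#' @param sheet Matching `SampleSheet`.
#' @return A list of class `BurdenModel`: `per_sex` (data frame with sex,
#'   slope, p, n) and `ancova` ([ancova_interaction()] result on the
#'   log-counts).
#' @export
burden_model <- function(profile, sheet) {
  stopifnot(inherits(profile, "EpimutationProfile"))
  counts <- profile$counts[sheet$sample_id]
  if (anyNA(counts)) stop("sample sheet and profile subjects differ")
  if (all(counts == 0)) warning("all epimutation counts are zero")
  y <- log10(counts + 1)
  per_sex <- do.call(rbind, lapply(c("F", "M"), function(s) {
    idx <- sheet$sex == s
    fit <- summary(stats::lm(y[idx] ~ sheet$age[idx]))$coefficients
    data.frame(sex = s, slope = fit[2L, 1L], p = fit[2L, 4L], n = sum(idx),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sex = per_sex,
                 ancova = ancova_interaction(y, sheet$age, sheet$sex)),
            class = "BurdenModel")
}
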