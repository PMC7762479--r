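#' Simulation configuration for multi-cohort methylome data
#'
#' Describes a study of several whole-blood cohorts measured on a common
#' probe set, with the statistical structure the analysis axes assume: probes
#' carrying sex effects, age slopes and age-by-sex interactions on the beta
#' scale, sex-specific age-dependent residual variance, cell-composition
#' confounding with an age-trending granulocyte fraction, and rare
#' epimutations whose per-subject rate grows with age.
#'
#' @param cohort_sizes Integer vector, samples per cohort (default four
#'   cohorts of 500, split evenly between sexes).
#' @param age_ranges List of `c(min, max)` ages per cohort; defaults emulate
#'   cohorts of differing width spanning adolescence to the tenth decade.
#' @param n_probes Number of autosomal probes on the common array.
#' @param frac_sex,frac_age,frac_both,frac_interaction Fractions of probes
#'   carrying a sex effect only, an age slope only, both, or an age-by-sex
#'   interaction. Must be jointly feasible (sum < 1).
#' @param delta_sex Sex-effect size in beta units (male minus female;
#'   default 0.05).
#' @param age_slope Age slope magnitude in beta units per year (default
#'   0.001; sign randomized per probe so hyper- and hypomethylation both
#'   occur).
#' @param interaction_slope Male-minus-female difference in age slope for
#'   interaction probes, beta units per year.
#' @param frac_het_female,frac_het_male Fractions of probes with
#'   age-increasing residual variance in females only / males only. The
#'   male:female default ratio of 10 mirrors the strong male excess of
#'   variability remodeling seen in blood.
#' @param frac_het_opposite Fraction with variance increasing in one sex and
#'   decreasing in the other (default 0).
#' @param het_slope Relative growth of the noise SD per year of age for
#'   heteroscedastic probes (default 0.0125: SD doubles over 80 years).
#' @param epimut_base,epimut_age Log-linear epimutation rate parameters: a
#'   subject of age `t` receives `Poisson(exp(epimut_base + epimut_age * t))`
#'   injected epimutations.
#' @param noise_sd Baseline per-probe noise SD in beta units (default 0.03).
#' @param frac_cell_probes Fraction of probes whose methylation tracks the
#'   granulocyte fraction (cell-composition confounding).
#' @param cell_loading Beta-units change per unit granulocyte-fraction change
#'   at confounded probes.
#' @param cell_conc Dirichlet concentration parameters for the five cell
#'   fractions (CD8T, CD4T, NK, Bcell, Gran); defaults give typical
#'   whole-blood proportions.
#' @param cell_age_trend Per-year log-scale growth of the granulocyte
#'   concentration parameter, producing the age-related granulocyte shift
#'   that makes cell composition a confounder (default 0.005).
#' @param seed Integer seed; all draws are reproducible given it.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(cohort_sizes = c(500L, 500L, 500L, 500L),
                       age_ranges = list(c(19, 101), c(14, 94),
                                         c(30, 85), c(40, 80)),
                       n_probes = 5000L,
                       frac_sex = 0.04, frac_age = 0.04, frac_both = 0.04,
                       frac_interaction = 0.004,
                       delta_sex = 0.05, age_slope = 0.001,
                       interaction_slope = 0.002,
                       frac_het_female = 0.002, frac_het_male = 0.02,
                       frac_het_opposite = 0,
                       het_slope = 0.0125,
                       epimut_base = -1, epimut_age = 0.02,
                       noise_sd = 0.03,
                       frac_cell_probes = 0.02, cell_loading = 0.2,
                       cell_conc = c(CD8T = 5, CD4T = 10, NK = 4,
                                     Bcell = 3, Gran = 42),
                       cell_age_trend = 0.005,
                       seed = 1L) {
  age_ranges <- if (is.list(age_ranges)) age_ranges else list(age_ranges)
  if (length(age_ranges) == 1L) age_ranges <- rep(age_ranges, length(cohort_sizes))
  if (length(age_ranges) != length(cohort_sizes)) {
    stop("age_ranges must match cohort_sizes")
  }
  fr <- c(frac_sex, frac_age, frac_both, frac_interaction,
          frac_het_female, frac_het_male, frac_het_opposite, frac_cell_probes)
  if (any(fr < 0 | fr > 1)) stop("probe fractions must lie in [0,1]")
  if (frac_sex + frac_age + frac_both + frac_interaction + frac_cell_probes > 1) {
    stop("mean-effect probe fractions jointly infeasible (sum > 1)")
  }
  if (frac_het_female + frac_het_male + frac_het_opposite > 1) {
    stop("heteroscedasticity fractions jointly infeasible")
  }
  if (any(cohort_sizes < 4L)) stop("each cohort needs >= 2 samples per sex")
  if (noise_sd <= 0) stop("noise scale must be positive")
  structure(list(
    cohort_sizes = as.integer(cohort_sizes), age_ranges = age_ranges,
    n_probes = as.integer(n_probes),
    frac_sex = frac_sex, frac_age = frac_age, frac_both = frac_both,
    frac_interaction = frac_interaction,
    delta_sex = delta_sex, age_slope = age_slope,
    interaction_slope = interaction_slope,
    frac_het_female = frac_het_female, frac_het_male = frac_het_male,
    frac_het_opposite = frac_het_opposite, het_slope = het_slope,
    epimut_base = epimut_base, epimut_age = epimut_age,
    noise_sd = noise_sd,
    frac_cell_probes = frac_cell_probes, cell_loading = cell_loading,
    cell_conc = cell_conc, cell_age_trend = cell_age_trend,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

#' Ground-truth probe table for a simulation
#'
#' Probe identities, baseline means and effect assignments are shared across
#' all cohorts of a study (they model one array design), so they are drawn
#' once from the configuration seed. Mean-effect roles (sex / age / both /
#' interaction / cell-confounded) are mutually exclusive; heteroscedasticity
#' scenarios (none / female / male / opposite) are assigned independently
#' among effect-free probes so variance calls are not confounded with mean
#' effects.
#'
#' @param config A `SimConfig`.
#' @return A data frame of class `SyntheticTruth` with one row per probe:
#'   `probe_id`, `baseline`, `sex_effect`, `age_slope_f`, `age_slope_m`,
#'   `interaction` flag, `het_scenario`, `var_slope_f`, `var_slope_m`
#'   (relative SD growth per year), and `cell_loading`.
#' @export
probe_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  np <- config$n_probes
  probe_id <- sprintf("cg%06d", seq_len(np))

  # Bimodal baseline: unmethylated and methylated modes plus an intermediate
  # component. Effect probes are drawn from the intermediate band so that
  # mean shifts stay feasible inside (0,1).
  comp <- sample(c("lo", "hi", "mid"), np, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  baseline <- numeric(np)
  baseline[comp == "lo"] <- pmin(pmax(stats::rnorm(sum(comp == "lo"), 0.10, 0.03), 0.02), 0.25)
  baseline[comp == "hi"] <- pmin(pmax(stats::rnorm(sum(comp == "hi"), 0.90, 0.03), 0.75), 0.98)
  baseline[comp == "mid"] <- stats::runif(sum(comp == "mid"), 0.30, 0.70)

  n_sex <- round(config$frac_sex * np)
  n_age <- round(config$frac_age * np)
  n_both <- round(config$frac_both * np)
  n_int <- round(config$frac_interaction * np)
  n_cell <- round(config$frac_cell_probes * np)
  role <- rep("none", np)
  idx <- sample.int(np, n_sex + n_age + n_both + n_int + n_cell)
  role[idx] <- rep(c("sex", "age", "both", "interaction", "cell"),
                   c(n_sex, n_age, n_both, n_int, n_cell))
  # effect probes get mid-range baselines so additive shifts remain feasible
  baseline[role != "none"] <- stats::runif(sum(role != "none"), 0.30, 0.70)

  sex_effect <- ifelse(role %in% c("sex", "both"),
                       config$delta_sex * sample(c(-1, 1), np, replace = TRUE), 0)
  # Age slopes drift toward intermediate methylation (hypermethylation at
  # low-methylated probes and vice versa), the direction of epigenetic drift;
  # with mid-range effect baselines this still yields a near-even
  # hyper/hypo split. Interaction probes keep a random direction.
  slope_sign <- ifelse(baseline < 0.5, 1, -1)
  slope_sign[role == "interaction"] <- sample(c(-1, 1), sum(role == "interaction"),
                                              replace = TRUE)
  age_common <- ifelse(role %in% c("age", "both"),
                       config$age_slope * slope_sign, 0)
  age_slope_f <- age_common
  age_slope_m <- age_common
  is_int <- role == "interaction"
  age_slope_m[is_int] <- age_slope_m[is_int] +
    config$interaction_slope * slope_sign[is_int]

  free <- which(role == "none")
  n_hf <- round(config$frac_het_female * np)
  n_hm <- round(config$frac_het_male * np)
  n_ho <- round(config$frac_het_opposite * np)
  if (n_hf + n_hm + n_ho > length(free)) {
    stop("not enough effect-free probes for the heteroscedasticity scenarios")
  }
  het_scenario <- rep("none", np)
  hidx <- sample(free, n_hf + n_hm + n_ho)
  het_scenario[hidx] <- rep(c("female", "male", "opposite"), c(n_hf, n_hm, n_ho))
  var_slope_f <- ifelse(het_scenario %in% c("female", "opposite"), config$het_slope, 0)
  var_slope_m <- ifelse(het_scenario == "male", config$het_slope,
                        ifelse(het_scenario == "opposite", -config$het_slope / 2, 0))

  cell_loading <- ifelse(role == "cell",
                         config$cell_loading * sample(c(-1, 1), np, replace = TRUE), 0)

  out <- data.frame(
    probe_id = probe_id, baseline = baseline, role = role,
    sex_effect = sex_effect,
    age_slope_f = age_slope_f, age_slope_m = age_slope_m,
    interaction = is_int,
    het_scenario = het_scenario,
    var_slope_f = var_slope_f, var_slope_m = var_slope_m,
    cell_loading = cell_loading,
    stringsAsFactors = FALSE
  )
  class(out) <- c("SyntheticTruth", "data.frame")
  out
}

# Dirichlet draw via independent gammas; rows are samples.
rdirichlet <- function(n, alpha_matrix) {
  g <- matrix(stats::rgamma(n * ncol(alpha_matrix), shape = alpha_matrix),
              nrow = n)
  g / rowSums(g)
}

#' Simulate one cohort
#'
#' Draws one cohort's beta matrix, sample sheet and ground truth from a
#' shared probe truth table. Per-sample means are
#' `baseline + sex_effect * sex + age_slope_sex * (age - midpoint) +
#' cell_loading * (Gran - E[Gran])`; Gaussian noise has SD
#' `noise_sd * (1 + var_slope_sex * (age - age_min))` and the result is
#' clipped to \[0.001, 0.999\].
#'
#' @param config A `SimConfig`.
#' @param cohort Cohort index (1-based).
#' @param truth Optional precomputed [probe_truth()]; computed from
#'   `config` if omitted (it must be shared when simulating several cohorts).
#' @return A list with elements `dataset` (`MethylationDataset`), `sheet`
#'   (`SampleSheet`, carrying noisy cell-fraction estimates), `truth` (the
#'   probe truth, unchanged) and `true_cells` (matrix of true fractions).
#' @export
simulate_cohort <- function(config, cohort = 1L, truth = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(truth)) truth <- probe_truth(config)
  n <- config$cohort_sizes[cohort]
  rng <- config$age_ranges[[cohort]]
  set.seed(config$seed + 7919L * cohort)

  age <- round(stats::runif(n, rng[1L], rng[2L]), 1)
  sex <- rep(c("F", "M"), length.out = n)[sample.int(n)]
  # guarantee >= 2 per sex
  if (sum(sex == "F") < 2L) sex[1:2] <- "F"
  if (sum(sex == "M") < 2L) sex[1:2] <- "M"
  sexn <- sex_code(sex)

  alpha <- matrix(config$cell_conc, nrow = n, ncol = 5L, byrow = TRUE)
  alpha[, 5L] <- alpha[, 5L] * exp(config$cell_age_trend * (age - 50))
  fr <- rdirichlet(n, alpha)
  colnames(fr) <- CELL_COLS
  # The sheet carries deconvolution *estimates*: true fractions plus a small
  # estimation error, so they need not sum to one (as with real references).
  est <- pmax(fr + stats::rnorm(length(fr), sd = 0.005), 0)
  colnames(est) <- CELL_COLS
  gran_ref <- config$cell_conc[5L] / sum(config$cell_conc)

  mid <- mean(rng)
  np <- config$n_probes
  slope <- outer(truth$age_slope_f, 1 - sexn) + outer(truth$age_slope_m, sexn)
  mu <- truth$baseline +
    outer(truth$sex_effect, sexn) +
    slope * matrix(age - mid, np, n, byrow = TRUE) +
    outer(truth$cell_loading, fr[, "Gran"] - gran_ref)

  infeasible <- rowSums(mu > 0.999 | mu < 0.001) == n
  if (any(infeasible)) {
    stop("infeasible effect: probe ", truth$probe_id[which(infeasible)[1L]],
         " has mean outside (0,1) at every age")
  }

  vslope <- outer(truth$var_slope_f, 1 - sexn) + outer(truth$var_slope_m, sexn)
  sd_mat <- config$noise_sd *
    pmax(0.2, 1 + vslope * matrix(age - rng[1L], np, n, byrow = TRUE))
  beta <- mu + stats::rnorm(np * n, sd = sd_mat)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  rownames(beta) <- truth$probe_id
  colnames(beta) <- sprintf("C%d_S%03d", cohort, seq_len(n))

  sheet <- as_sample_sheet(data.frame(
    sample_id = colnames(beta), age = age, sex = sex, est,
    stringsAsFactors = FALSE
  ))
  rownames(fr) <- colnames(beta)
  list(dataset = methylation_dataset(beta, sprintf("cohort%d", cohort)),
       sheet = sheet, truth = truth, true_cells = fr)
}

#' Simulate a full multi-cohort study
#'
#' @param config A `SimConfig`.
#' @param inject Also inject epimutations at the configured rates.
#' @return A list with `datasets`, `sheets`, `true_cells` (parallel lists),
#'   the shared probe `truth`, and when `inject = TRUE` a list
#'   `epimutations` of injected-flag data frames per cohort.
#' @export
simulate_study <- function(config, inject = FALSE) {
  truth <- probe_truth(config)
  k <- length(config$cohort_sizes)
  datasets <- vector("list", k)
  sheets <- vector("list", k)
  cells <- vector("list", k)
  flags <- if (inject) vector("list", k) else NULL
  for (i in seq_len(k)) {
    sim <- simulate_cohort(config, i, truth)
    cells[[i]] <- sim$true_cells
    if (inject) {
      set.seed(config$seed + 104729L * i)
      inj <- inject_epimutations(sim$dataset, sim$sheet,
                                 base = config$epimut_base,
                                 age_coef = config$epimut_age)
      sim$dataset <- inj$dataset
      flags[[i]] <- inj$flags
    }
    datasets[[i]] <- sim$dataset
    sheets[[i]] <- sim$sheet
  }
  out <- list(datasets = datasets, sheets = sheets, true_cells = cells,
              truth = truth)
  if (inject) out$epimutations <- flags
  out
}

#' Inject rare epimutations into a clean dataset
#'
#' Each subject of age `t` receives `Poisson(exp(base + age_coef * t))`
#' epimutations, each placed at a uniformly chosen probe strictly outside the
#' clean data's `Q1 - 3 IQR` / `Q3 + 3 IQR` bounds for that probe (with a
#' safety margin so the flags stay detectable after the bounds are recomputed
#' on the contaminated data). Probes whose bounds leave no room inside
#' \[0.001, 0.999\] are resampled and counted.
#'
#' @param dataset Clean `MethylationDataset`.
#' @param sheet Matching `SampleSheet`.
#' @param base,age_coef Log-linear rate parameters.
#' @param k IQR multiplier defining the outlier bounds (default 3).
#' @return A list: `dataset` (contaminated copy), `flags` (data frame of
#'   injected `probe_id`, `sample_id`, `value`), and `n_resampled` (probes
#'   skipped as infeasible).
#' @export
inject_epimutations <- function(dataset, sheet, base = -1, age_coef = 0.02,
                                k = 3) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  beta <- dataset$beta
  stopifnot(identical(colnames(beta), sheet$sample_id))
  lambda <- exp(base + age_coef * sheet$age)
  counts <- stats::rpois(length(lambda), lambda)
  flags <- list()
  n_resampled <- 0L
  if (sum(counts) > 0L) {
    qs <- apply(beta, 1L, stats::quantile, probs = c(0.25, 0.75),
                na.rm = TRUE, names = FALSE)
    iqr <- qs[2L, ] - qs[1L, ]
    lower <- qs[1L, ] - k * iqr
    upper <- qs[2L, ] + k * iqr
    margin <- pmax(0.5 * iqr, 0.02)
    for (j in which(counts > 0L)) {
      placed <- 0L
      used <- integer(0)
      tries <- 0L
      while (placed < counts[j] && tries < 50L * counts[j]) {
        tries <- tries + 1L
        i <- sample.int(nrow(beta), 1L)
        if (i %in% used) next
        up_ok <- upper[i] + margin[i] <= 0.999
        lo_ok <- lower[i] - margin[i] >= 0.001
        if (!up_ok && !lo_ok) { n_resampled <- n_resampled + 1L; next }
        side <- if (up_ok && lo_ok) sample(c("up", "lo"), 1L) else if (up_ok) "up" else "lo"
        val <- if (side == "up") {
          min(0.999, upper[i] + margin[i] + abs(stats::rnorm(1, 0, 0.01)))
        } else {
          max(0.001, lower[i] - margin[i] - abs(stats::rnorm(1, 0, 0.01)))
        }
        beta[i, j] <- val
        used <- c(used, i)
        placed <- placed + 1L
        flags[[length(flags) + 1L]] <- data.frame(
          probe_id = rownames(beta)[i], sample_id = colnames(beta)[j],
          value = val, stringsAsFactors = FALSE)
      }
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(probe_id = character(), sample_id = character(),
               value = numeric(), stringsAsFactors = FALSE)
  list(dataset = methylation_dataset(beta, dataset$cohort),
       flags = flags, n_resampled = n_resampled)
}

#' Synthetic probe annotation for a simulated study
#'
#' Draws a plausible annotation table for a set of simulated probes:
#' autosomal/sex-chromosome assignment, CpG-island relation, a sparse
#' gene map over an artificial gene pool, and the blacklist, imprinted and
#' hormone-gene flags used by filtering and enrichment.
#'
#' @param probe_ids Character vector of probe IDs (typically
#'   `truth$probe_id` from [simulate_study()]).
#' @param seed Integer seed; the table is deterministic given
#'   (`probe_ids`, `seed`).
#' @param frac_sex_chr,frac_blacklist,frac_imprinted,frac_hormone Expected
#'   fractions of probes on sex chromosomes, blacklist-flagged, in imprinted
#'   regions, and mapped to a hormone-pathway gene.
#' @return A `ProbeAnnotation`.
#' @export
simulate_annotation <- function(probe_ids, seed = 1L, frac_sex_chr = 0.03,
                                frac_blacklist = 0.05, frac_imprinted = 0.02,
                                frac_hormone = 0.03) {
  set.seed(seed)
  np <- length(probe_ids)
  chr <- sample(as.character(1:22), np, replace = TRUE)
  sexp <- stats::runif(np) < frac_sex_chr
  chr[sexp] <- sample(c("X", "Y"), sum(sexp), replace = TRUE, prob = c(0.9, 0.1))
  island <- sample(ISLAND_LEVELS, np, replace = TRUE,
                   prob = c(0.31, 0.12, 0.11, 0.05, 0.05, 0.36))
  genes <- character(np)
  pool <- sprintf("GENE%04d", seq_len(max(50L, np %/% 10L)))
  n_genes <- sample(0:2, np, replace = TRUE, prob = c(0.25, 0.6, 0.15))
  has <- n_genes > 0
  genes[has] <- vapply(n_genes[has], function(k) {
    paste(sample(pool, k), collapse = ";")
  }, character(1))
  hormone_pool <- sample(pool, max(1L, round(length(pool) * 0.05)))
  hormone <- vapply(strsplit(genes, ";", fixed = TRUE),
                    function(g) any(g %in% hormone_pool), logical(1))
  # top up to the expected hormone fraction with direct flags
  extra <- stats::runif(np) < frac_hormone
  as_probe_annotation(data.frame(
    probe_id = probe_ids,
    chr = chr,
    pos = cumsum(sample.int(5000L, np, replace = TRUE)),
    island_relation = island,
    genes = genes,
    blacklist = stats::runif(np) < frac_blacklist,
    imprinted = stats::runif(np) < frac_imprinted,
    hormone_gene = hormone | extra,
    stringsAsFactors = FALSE
  ))
}
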