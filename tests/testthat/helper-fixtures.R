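# Small fixture builders shared across test files. Everything is generated in
# code so the suite has no binary or stored data.

make_beta <- function(nprobe, nsample, seed = 1, prefix = "cg") {
  set.seed(seed)
  m <- matrix(runif(nprobe * nsample, 0.05, 0.95), nprobe, nsample,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(nprobe)),
                              sprintf("S%03d", seq_len(nsample))))
  methylation_dataset(m, "test")
}

make_sheet <- function(n, seed = 1, age = NULL, sex = NULL) {
  set.seed(seed)
  if (is.null(age)) age <- round(runif(n, 20, 90), 1)
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  fr <- matrix(rgamma(n * 5, shape = rep(c(5, 10, 4, 3, 42), each = n)), n, 5)
  fr <- fr / rowSums(fr) + rnorm(n * 5, sd = 0.004)
  fr <- pmax(fr, 0)
  colnames(fr) <- c("CD8T", "CD4T", "NK", "Bcell", "Gran")
  as_sample_sheet(data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                             age = age, sex = sex, fr,
                             stringsAsFactors = FALSE))
}

make_annotation <- function(probe_ids, chr = "1",
                            island = "OpenSea", genes = "",
                            blacklist = FALSE, imprinted = FALSE,
                            hormone = FALSE) {
  n <- length(probe_ids)
  as_probe_annotation(data.frame(
    probe_id = probe_ids,
    chr = rep_len(chr, n),
    pos = seq_len(n) * 1000L,
    island_relation = rep_len(island, n),
    genes = rep_len(genes, n),
    blacklist = rep_len(blacklist, n),
    imprinted = rep_len(imprinted, n),
    hormone_gene = rep_len(hormone, n),
    stringsAsFactors = FALSE
  ))
}

# A small but complete simulated study used by several files.
small_config <- function(seed = 11, ...) {
  sim_config(cohort_sizes = c(80L, 80L),
             age_ranges = list(c(20, 90), c(25, 85)),
             n_probes = 300L, seed = seed, ...)
}
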