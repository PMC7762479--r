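# Map a category name to a per-probe logical over an annotation slice.
category_membership <- function(ann, category) {
  if (category %in% c("imprinted", "hormone_gene", "blacklist")) {
    return(ann[[category]])
  }
  rel <- ann$island_relation
  switch(category,
    Shore = rel %in% c("N_Shore", "S_Shore"),
    Shelf = rel %in% c("N_Shelf", "S_Shelf"),
    {
      if (!category %in% ISLAND_LEVELS) stop("unknown category: ", category)
      rel == category
    }
  )
}

#' Probe-level category enrichment
#'
#' Fisher test of a probe catalog (foreground) against the analysis
#' background for membership in an annotation category. Island-relation
#' categories may be a single level or the pooled `"Shore"` / `"Shelf"`;
#' the flag columns `"imprinted"`, `"hormone_gene"` work directly.
#'
#' @param foreground Character vector of probe IDs (must be a subset of
#'   `background`).
#' @param background Character vector of probe IDs — the probes surviving
#'   preprocessing.
#' @param annotation A `ProbeAnnotation` covering the background.
#' @param category Category name (see Details).
#' @return A list of class `EnrichmentEntry`: the `ContingencyResult`,
#'   `level = "probe"`, `category`, and foreground/background sizes.
#' @export
probe_enrichment <- function(foreground, background, annotation, category) {
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background")
  }
  ann <- annotation[match(background, annotation$probe_id), ]
  if (anyNA(ann$probe_id)) stop("background probes missing from annotation")
  inc <- category_membership(ann, category)
  fg <- background %in% foreground
  test <- fisher_2x2(sum(fg & inc), sum(fg & !inc),
                     sum(!fg & inc), sum(!fg & !inc))
  structure(list(test = test, level = "probe", category = category,
                 n_foreground = sum(fg), n_background = length(background)),
            class = "EnrichmentEntry")
}

probe_genes <- function(annotation, probes) {
  g <- annotation$genes[match(probes, annotation$probe_id)]
  g <- unlist(strsplit(g[!is.na(g) & nzchar(g)], ";", fixed = TRUE))
  unique(g)
}

#' Gene-level enrichment in a gene list
#'
#' Maps foreground and background probe sets to gene-symbol sets (a probe
#' annotated to several genes counts toward each) and Fisher-tests
#' membership in the supplied gene list (e.g. sex-hormone-related or
#' imprinted genes).
#'
#' @param foreground,background Probe ID vectors, foreground a subset.
#' @param annotation A `ProbeAnnotation` with semicolon-separated `genes`.
#' @param gene_list Character vector of gene symbols.
#' @return A list of class `EnrichmentEntry` with `level = "gene"` and the
#'   gene-set sizes.
#' @export
gene_enrichment <- function(foreground, background, annotation, gene_list) {
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background")
  }
  fg_genes <- probe_genes(annotation, foreground)
  bg_genes <- probe_genes(annotation, background)
  if (length(bg_genes) == 0L) stop("empty gene universe")
  inc <- bg_genes %in% gene_list
  fg <- bg_genes %in% fg_genes
  test <- fisher_2x2(sum(fg & inc), sum(fg & !inc),
                     sum(!fg & inc), sum(!fg & !inc))
  structure(list(test = test, level = "gene", category = "gene_list",
                 n_foreground = length(fg_genes), n_background = length(bg_genes)),
            class = "EnrichmentEntry")
}

#' Standard enrichment report for a probe catalog
#'
#' Runs [probe_enrichment()] over the island-relation zones (Island, pooled
#' Shore, pooled Shelf, OpenSea) plus the imprinted-region and
#' hormone-gene flags, returning one row per category.
#'
#' @param foreground,background Probe ID vectors.
#' @param annotation A `ProbeAnnotation`.
#' @return A data frame of class `EnrichmentReport`: category, level, counts,
#'   odds ratio and p per row.
#' @export
enrichment_report <- function(foreground, background, annotation) {
  cats <- c("Island", "Shore", "Shelf", "OpenSea", "imprinted", "hormone_gene")
  rows <- lapply(cats, function(cat) {
    e <- probe_enrichment(foreground, background, annotation, cat)
    data.frame(category = cat, level = e$level,
               fg_in = e$test$table[1L, 1L], fg_out = e$test$table[1L, 2L],
               bg_in = e$test$table[2L, 1L], bg_out = e$test$table[2L, 2L],
               odds_ratio = e$test$odds_ratio, p = e$test$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("EnrichmentReport", "data.frame")
  out
}
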