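#' Row-centered overexpression values
#'
#' Converts a gene-level group-median table into tumor/tissue-dependent
#' overexpression values: each row has its across-group mean subtracted, so a
#' positive value means the gene's median expression in that group is higher
#' than in the other groups of the same dataset. Human datasets typically
#' contrast the SHH group against the other medulloblastoma subgroups; mouse
#' datasets additionally carry healthy-cerebellum controls in the row mean —
#' both fall out of whichever group columns the dataset has.
#'
#' @param table Gene-level tibble from [group_medians()] /
#'   [collapse_to_genes_max_mean()] with >= 2 group columns.
#' @return Tibble of the same shape; attribute `mode = "row_centered"`.
#' @export
center_rows <- function(table) {
  grp <- median_table_groups(table)
  if (length(grp) < 2L) abort("need >= 2 group columns to row-center")
  m <- as.matrix(table[, grp, drop = FALSE])
  m <- m - rowMeans(m)
  out <- dplyr::bind_cols(tibble(feature = table$feature), as_tibble(m))
  for (a in c("dataset_id", "species", "feature_level")) {
    attr(out, a) <- attr(table, a)
  }
  attr(out, "mode") <- "row_centered"
  out
}

#' Cerebellum-normalized overexpression values
#'
#' The robustness-check variant: instead of row-centering, the healthy
#' cerebellum control median is subtracted from every group's median, so the
#' control column is identically zero and every other value is expression
#' relative to normal cerebellum.
#'
#' @param table Gene-level tibble from [group_medians()].
#' @param control_group Label of the cerebellum control column (matched
#'   case-insensitively).
#' @return Tibble of the same shape; attributes `mode =
#'   "cerebellum_normalized"` and `control_group`.
#' @export
cerebellum_normalize <- function(table, control_group = "cerebellum") {
  grp <- median_table_groups(table)
  ctrl <- match_group(control_group, grp, "control group")
  m <- as.matrix(table[, grp, drop = FALSE])
  m <- m - m[, ctrl]
  out <- dplyr::bind_cols(tibble(feature = table$feature), as_tibble(m))
  for (a in c("dataset_id", "species", "feature_level")) {
    attr(out, a) <- attr(table, a)
  }
  attr(out, "mode") <- "cerebellum_normalized"
  attr(out, "control_group") <- ctrl
  out
}

#' Quantile-rank genes by overexpression in a target group
#'
#' Orders genes ascending by their overexpression value in `target_group` and
#' maps the 1-based rank r (ties receiving their average rank) to
#' (r - 1) / (n - 1), so ranks span exactly \[0, 1\]: the most overexpressed
#' gene gets 1, the least 0.
#'
#' @param table Overexpression tibble from [center_rows()] or
#'   [cerebellum_normalize()] with >= 2 genes.
#' @param target_group Group column to rank by (matched case-insensitively,
#'   so `"SHH"` finds a mouse `"Shh"` column).
#' @return Tibble with columns `gene`, `qrank`; attributes `dataset_id`,
#'   `species`, `target_group`.
#' @export
quantile_rank <- function(table, target_group = "SHH") {
  grp <- median_table_groups(table)
  tg <- match_group(target_group, grp, "target group")
  v <- table[[tg]]
  n <- length(v)
  if (n < 2L) abort("need >= 2 genes to rank")
  out <- tibble(
    gene = table$feature,
    qrank = (rank(v, ties.method = "average") - 1) / (n - 1)
  )
  attr(out, "dataset_id") <- attr(table, "dataset_id")
  attr(out, "species") <- attr(table, "species")
  attr(out, "target_group") <- tg
  out
}

# translate a rank vector's gene symbols to canonical (human-side) symbols
canonicalize_genes <- function(genes, species, homolog_map) {
  if (species == "human") {
    toupper(genes)
  } else {
    key <- setNames(homolog_map$human, tolower(homolog_map$mouse))
    unname(key[tolower(genes)])
  }
}

#' Average quantile ranks across the datasets of one species
#'
#' Unweighted per-gene mean of quantile ranks over the datasets in which the
#' gene is present (partial averaging: a gene absent from some datasets keeps
#' the mean over those it appears in, with the count recorded). Gene keys are
#' canonicalized to the human-side symbol of the homolog pair; mouse genes
#' without a homolog partner are dropped.
#'
#' @param rank_vectors List of tibbles from [quantile_rank()].
#' @param species `"human"` or `"mouse"`: which datasets to average.
#' @param homolog_map Tibble from [read_homolog_map()].
#' @return Tibble with columns `gene`, `mean_rank`, `n_datasets`.
#' @export
average_ranks_by_species <- function(rank_vectors, species, homolog_map) {
  species <- match.arg(species, c("human", "mouse"))
  keep <- purrr::keep(rank_vectors, ~ identical(attr(.x, "species"), species))
  if (!length(keep)) abort(sprintf("no rank vectors of species '%s'", species))
  purrr::map_dfr(keep, function(rv) {
    tibble(gene = canonicalize_genes(rv$gene, species, homolog_map),
           qrank = rv$qrank)
  }) %>%
    filter(!is.na(.data$gene)) %>%
    group_by(.data$gene) %>%
    summarise(mean_rank = mean(.data$qrank), n_datasets = dplyr::n(),
              .groups = "drop")
}

#' Human-minus-mouse rank differences with specificity labels
#'
#' Joins the species mean-rank tables over resolvable homolog pairs and
#' computes `diff = human_mean_rank - mouse_mean_rank`, sorted descending: the
#' top of the table holds genes highly ranked in human SHH tumors but lowly in
#' mouse models. A specificity label operationalizes "closer to 1 / closer to
#' 0": `human_specific` when the human rank is at least `high` and the mouse
#' rank at most `low`; `mouse_specific` symmetric; `shared` when both ranks
#' are at least `high`; `neither` otherwise.
#'
#' @param human_means,mouse_means Tibbles from [average_ranks_by_species()].
#' @param high,low Rank cutoffs (defaults 0.8 / 0.2).
#' @return Tibble with columns `gene`, `human_mean_rank`, `mouse_mean_rank`,
#'   `n_human_datasets`, `n_mouse_datasets`, `diff`, `label`, sorted by
#'   descending `diff`.
#' @export
rank_difference <- function(human_means, mouse_means, high = 0.8, low = 0.2) {
  joined <- dplyr::inner_join(
    rename(human_means, human_mean_rank = "mean_rank",
           n_human_datasets = "n_datasets"),
    rename(mouse_means, mouse_mean_rank = "mean_rank",
           n_mouse_datasets = "n_datasets"),
    by = "gene")
  if (nrow(joined) == 0L) {
    abort("no gene is present in datasets of both species")
  }
  joined %>%
    mutate(
      diff = .data$human_mean_rank - .data$mouse_mean_rank,
      label = dplyr::case_when(
        human_mean_rank >= high & mouse_mean_rank <= low ~ "human_specific",
        mouse_mean_rank >= high & human_mean_rank <= low ~ "mouse_specific",
        human_mean_rank >= high & mouse_mean_rank >= high ~ "shared",
        TRUE ~ "neither"
      )
    ) %>%
    arrange(desc(.data$diff))
}
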