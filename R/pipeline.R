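#' Run the cross-species ranking pipeline end-to-end
#'
#' Orchestrates every stage on a set of datasets and writes a deterministic
#' result bundle: per-dataset overexpression tables and rank vectors, species
#' mean-rank tables, the human-minus-mouse rank-difference table with
#' specificity labels, the dataset correlogram, preranked GSEA results for
#' both enrichment directions, concordance against a coexpression rank table
#' when one is supplied, plot-ready TSVs (rank "boxplot" long table; gene-set
#' median summaries), and a JSON run manifest recording seed and parameters.
#' Any stage failure aborts with a stage-named message and removes the
#' partially written output directory.
#'
#' @param config Either a path to a YAML file or a list with entries:
#'   `datasets` (list; each either an [expression_dataset()] or a list with
#'   `path`, `annotation_path`, `dataset_id`, `species` and optionally
#'   `annotation_file` mapping probesets to genes), `mode` (`"row_centered"`
#'   default or `"cerebellum_normalized"`), `control_group` (default
#'   `"cerebellum"`), `target_group` (default `"SHH"`), `homolog_map` (path,
#'   tibble, or `NULL` for the case-convention map), `gmt` (path or gene-set
#'   tibble, optional), `coexpression` (path or tibble gene/qrank, optional),
#'   `normalize` (`"none"` default or `"invariant_set"`), `gsea` (list:
#'   `min_size`, `max_size`, `n_perm`, `weight`), `seed` (integer), `out_dir`.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the in-memory results (`rank_diff`,
#'   `correlogram`, `gsea`, `concordance_*`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir %||% abort("no output directory given")
  seed <- as.integer(config$seed %||% 1L)
  mode <- config$mode %||% "row_centered"
  target_group <- config$target_group %||% "SHH"
  control_group <- config$control_group %||% "cerebellum"
  gsea_par <- utils::modifyList(
    list(min_size = 15, max_size = 500, n_perm = 1000, weight = 1),
    config$gsea %||% list())

  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(stage, e) {
    if (created) unlink(out_dir, recursive = TRUE)
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) on_fail(name, e))
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  datasets <- stage("ingest", lapply(config$datasets, load_dataset_entry))
  species <- vapply(datasets, function(d) d$species, "")
  if (!all(c("human", "mouse") %in% species)) {
    on_fail("diff", simpleError(
      ">= 1 dataset per species is required for the rank-difference stage"))
  }

  if (identical(config$normalize %||% "none", "invariant_set")) {
    datasets <- stage("normalize", lapply(datasets, invariant_set_normalize))
  }

  over <- stage("overexpression", lapply(datasets, function(d) {
    gm <- group_medians(d)
    if (d$feature_level == "probeset") {
      gm <- collapse_to_genes_max_mean(gm, d$probe_annotation)
    }
    if (mode == "cerebellum_normalized" &&
        any(tolower(median_table_groups(gm)) == tolower(control_group))) {
      cerebellum_normalize(gm, control_group)
    } else {
      center_rows(gm)
    }
  }))

  homolog_map <- stage("homologs", {
    hm <- config$homolog_map
    if (is.data.frame(hm)) {
      hm
    } else if (is.character(hm)) {
      read_homolog_map(hm)
    } else {
      read_homolog_map(
        mouse_genes = unique(unlist(lapply(
          over[species == "mouse"], function(t) t$feature))),
        human_genes = unique(unlist(lapply(
          over[species == "human"], function(t) t$feature))))
    }
  })

  ranks <- stage("rank", lapply(over, quantile_rank,
                                target_group = target_group))
  human_means <- stage("average_human",
                       average_ranks_by_species(ranks, "human", homolog_map))
  mouse_means <- stage("average_mouse",
                       average_ranks_by_species(ranks, "mouse", homolog_map))
  rank_diff <- stage("diff", rank_difference(human_means, mouse_means))
  corr <- stage("correlogram",
                dataset_correlogram(over, homolog_map, target_group,
                                    on_ranks = isTRUE(config$on_ranks)))

  gsea_res <- NULL
  if (!is.null(config$gmt)) {
    sets <- if (is.data.frame(config$gmt)) config$gmt else read_gmt(config$gmt)
    gsea_res <- stage("gsea", run_gsea(
      ranked_list(rank_diff), sets,
      min_size = gsea_par$min_size, max_size = gsea_par$max_size,
      n_perm = gsea_par$n_perm, weight = gsea_par$weight, seed = seed))
  }

  conc_h <- conc_m <- NULL
  if (!is.null(config$coexpression)) {
    cx <- config$coexpression
    if (is.character(cx)) {
      cx <- read.delim(cx, stringsAsFactors = FALSE)
    }
    conc_h <- stage("concordance_human", rank_concordance(cx, human_means))
    conc_m <- stage("concordance_mouse", rank_concordance(cx, mouse_means))
  }

  manifest <- list(
    package = "crossmb",
    version = as.character(utils::packageVersion("crossmb")),
    seed = seed, mode = mode, target_group = target_group,
    normalize = config$normalize %||% "none", gsea = gsea_par,
    datasets = lapply(datasets, function(d) list(
      dataset_id = d$dataset_id, species = d$species,
      n_features = nrow(d$matrix), n_samples = ncol(d$matrix))),
    stages = c("ingest", "overexpression", "homologs", "rank", "diff",
               "correlogram",
               if (!is.null(gsea_res)) "gsea",
               if (!is.null(conc_h)) c("concordance_human",
                                       "concordance_mouse"))
  )

  stage("write", {
    for (i in seq_along(over)) {
      id <- attr(over[[i]], "dataset_id")
      write_results(over[[i]],
                    file.path(out_dir, sprintf("overexpression_%s.tsv", id)))
      write_results(ranks[[i]],
                    file.path(out_dir, sprintf("ranks_%s.tsv", id)))
    }
    write_results(human_means, file.path(out_dir, "mean_ranks_human.tsv"))
    write_results(mouse_means, file.path(out_dir, "mean_ranks_mouse.tsv"))
    write_results(rank_diff, file.path(out_dir, "rank_diff.tsv"))
    write_results(tidy(corr), file.path(out_dir, "correlogram.tsv"))
    write_results(rank_boxplot_data(ranks, homolog_map),
                  file.path(out_dir, "rank_boxplot.tsv"))
    if (!is.null(gsea_res)) {
      for (dirn in c("positive", "negative")) {
        tab <- filter(gsea_res, .data$direction == dirn)
        if (nrow(tab)) {
          write_results(select(tab, -"leading_edge") %>%
                          mutate(leading_edge = vapply(
                            tab$leading_edge, paste, "", collapse = ",")),
                        file.path(out_dir, sprintf("gsea_%s.tsv", dirn)))
        }
      }
      write_results(gene_set_summary(over, gsea_res, homolog_map,
                                     target_group),
                    file.path(out_dir, "gene_set_summary.tsv"))
    }
    if (!is.null(conc_h)) {
      write_results(bind_rows(
        mutate(glance(conc_h), species = "human"),
        mutate(glance(conc_m), species = "mouse")),
        file.path(out_dir, "concordance.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(
    datasets = datasets, overexpression = over, ranks = ranks,
    human_means = human_means, mouse_means = mouse_means,
    rank_diff = rank_diff, correlogram = corr, gsea = gsea_res,
    concordance_human = conc_h, concordance_mouse = conc_m,
    manifest = manifest))
}

load_dataset_entry <- function(entry) {
  if (inherits(entry, "expr_dataset")) return(entry)
  ann <- NULL
  if (!is.null(entry$annotation_file)) {
    df <- read_two_column_tsv(entry$annotation_file, c("probeset", "gene"))
    ann <- setNames(df$gene, df$probeset)
  }
  read_expression_matrix(entry$path, entry$annotation_path,
                         entry$dataset_id, entry$species,
                         feature_level = entry$feature_level %||%
                           if (is.null(ann)) "gene" else "probeset",
                         probe_annotation = ann)
}

# long table backing the per-gene rank boxplots: one row per
# (gene, dataset), canonical human-side symbols
rank_boxplot_data <- function(ranks, homolog_map) {
  purrr::map_dfr(ranks, function(rv) {
    tibble(gene = canonicalize_genes(rv$gene, attr(rv, "species"),
                                     homolog_map),
           dataset_id = attr(rv, "dataset_id"),
           species = attr(rv, "species"),
           qrank = rv$qrank)
  }) %>% filter(!is.na(.data$gene))
}

# per gene set x species: median overexpression of member genes — the
# summary behind the gene-set-wise panels of the robustness check
gene_set_summary <- function(over, gsea_res, homolog_map, target_group) {
  purrr::map_dfr(seq_len(nrow(gsea_res)), function(i) {
    members <- toupper(unlist(gsea_res$leading_edge[i]))
    purrr::map_dfr(over, function(t) {
      tg <- match_group(target_group, median_table_groups(t))
      g <- canonicalize_genes(t$feature, attr(t, "species"), homolog_map)
      v <- t[[tg]][!is.na(g) & g %in% members]
      tibble(set_name = gsea_res$set_name[i],
             dataset_id = attr(t, "dataset_id"),
             species = attr(t, "species"),
             n_genes = length(v),
             median_overexpression = if (length(v)) median(v) else NA_real_)
    })
  })
}

#' Write a synthetic suite to disk
#'
#' Materializes a [generate_suite()] result as the plain-text files the
#' ingestion layer reads: per-dataset expression and annotation TSVs, a
#' probeset-to-gene annotation TSV, the homolog map, the truth table, the
#' coexpression rank table, and a GMT collection with the planted sets.
#'
#' @param config A [synthetic_config()], or a path to a YAML file of
#'   [synthetic_config()] arguments.
#' @param out_dir Output directory (created if needed).
#' @param n_random_sets Random background sets in the GMT (default 50).
#' @return Invisibly, the generated suite with an added `paths` element.
#' @export
simulate_command <- function(config = synthetic_config(), out_dir,
                             n_random_sets = 50) {
  if (is.character(config) && length(config) == 1L) {
    config <- do.call(synthetic_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "synthetic_config"))
  suite <- generate_suite(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (d in suite$datasets) {
    paths[[d$dataset_id]] <- list(
      path = file.path(out_dir, sprintf("expr_%s.tsv", d$dataset_id)),
      annotation_path = file.path(out_dir,
                                  sprintf("groups_%s.tsv", d$dataset_id)),
      annotation_file = file.path(out_dir,
                                  sprintf("probes_%s.tsv", d$dataset_id)),
      dataset_id = d$dataset_id, species = d$species,
      feature_level = "probeset")
    write_expression_matrix(d, paths[[d$dataset_id]]$path,
                            paths[[d$dataset_id]]$annotation_path)
    utils::write.table(
      data.frame(probeset = names(d$probe_annotation),
                 gene = unname(d$probe_annotation)),
      paths[[d$dataset_id]]$annotation_file,
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(suite$homolog_map,
                     file.path(out_dir, "homolog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(suite$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(suite$coexpression,
                     file.path(out_dir, "coexpression_ranks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gmt <- generate_gmt_with_planted_sets(suite$truth,
                                        n_random_sets = n_random_sets,
                                        seed = config$seed)
  write_gmt(gmt, file.path(out_dir, "gene_sets.gmt"))
  suite$paths <- paths
  invisible(suite)
}
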