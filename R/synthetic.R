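#' Configuration for the synthetic multi-dataset generator
#'
#' Defines the study conditions the generator emulates: a panel of mouse
#' Shh-MB model datasets with healthy-cerebellum controls and human MB cohort
#' datasets whose controls are the other molecular subgroups, on a log2
#' additive scale with planted cross-species structure. Defaults: 2000 genes,
#' 3 datasets per species, 50-gene planted sets (shared hedgehog targets up
#' in the SHH group of both species; human-specific up only in human SHH;
#' mouse-specific up only in mouse Shh), a 1.5 log2 group effect, residual
#' noise sd 0.8 log2 units, human cohorts of 20 samples per subgroup and
#' mouse panels of 10 per group — magnitudes typical of published MB
#' expression panels.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_mouse_datasets,n_human_datasets Datasets per species (default 3).
#' @param mouse_groups,human_groups Named integer vectors of samples per
#'   group. Defaults `c(Shh = 10, cerebellum = 10)` and
#'   `c(SHH = 20, Group3 = 20, Group4 = 20)`.
#' @param probes_per_gene Integer vector of possible probeset counts per gene,
#'   sampled uniformly (default 1:3).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression
#'   distribution (defaults 7, 1.5).
#' @param noise_sd Per-sample residual sd in log2 units (default 0.8).
#' @param batch_shift_sd Per-array additive offset sd (default 0.3); exercises
#'   between-array normalization.
#' @param probe_offset_sd Probe-specific additive offset sd (default 0.3).
#' @param shared_set_size,human_specific_set_size,mouse_specific_set_size
#'   Planted set sizes (defaults 50 each).
#' @param effect_log2 Planted group effect in log2 units (default 1.5).
#' @param coexpr_jitter Sd of the noise added to the Gli1-coexpression scores
#'   before ranking (default 0.5).
#' @param seed Integer seed (default 1).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_mouse_datasets = 3, n_human_datasets = 3,
                             mouse_groups = c(Shh = 10, cerebellum = 10),
                             human_groups = c(SHH = 20, Group3 = 20,
                                              Group4 = 20),
                             probes_per_gene = 1:3,
                             baseline_mean = 7, baseline_sd = 1.5,
                             noise_sd = 0.8, batch_shift_sd = 0.3,
                             probe_offset_sd = 0.3,
                             shared_set_size = 50,
                             human_specific_set_size = 50,
                             mouse_specific_set_size = 50,
                             effect_log2 = 1.5,
                             coexpr_jitter = 0.5,
                             seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_mouse_datasets = as.integer(n_mouse_datasets),
    n_human_datasets = as.integer(n_human_datasets),
    mouse_groups = mouse_groups, human_groups = human_groups,
    probes_per_gene = as.integer(probes_per_gene),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
    probe_offset_sd = probe_offset_sd,
    shared_set_size = as.integer(shared_set_size),
    human_specific_set_size = as.integer(human_specific_set_size),
    mouse_specific_set_size = as.integer(mouse_specific_set_size),
    effect_log2 = effect_log2, coexpr_jitter = coexpr_jitter,
    seed = as.integer(seed)
  )
  planted <- cfg$shared_set_size + cfg$human_specific_set_size +
    cfg$mouse_specific_set_size
  if (planted > cfg$n_genes) abort("planted set sizes exceed n_genes")
  if (cfg$baseline_sd <= 0 || cfg$noise_sd <= 0) abort("sds must be > 0")
  if (any(cfg$mouse_groups < 1) || any(cfg$human_groups < 1)) {
    abort("every group needs >= 1 sample")
  }
  if (!"Shh" %in% names(cfg$mouse_groups) ||
      !"SHH" %in% names(cfg$human_groups)) {
    abort("mouse groups must include 'Shh' and human groups 'SHH'")
  }
  structure(cfg, class = "synthetic_config")
}

# title-case mouse symbol roots; human symbols are their uppercase forms
synth_symbols <- function(n) sprintf("Sgene%04d", seq_len(n))

#' Generate a synthetic cross-species expression suite
#'
#' Simulates the full input panel: per gene a baseline log2 expression shared
#' across datasets, per array an additive batch shift, per sample Gaussian
#' noise, and planted group effects — shared hedgehog-target genes are up by
#' `effect_log2` in the SHH group of every dataset of both species,
#' human-specific genes only in human SHH, mouse-specific genes only in mouse
#' Shh. Probesets (1-3 per gene) share the gene value plus a probe-specific
#' offset. Mouse datasets use title-case symbols, human datasets the
#' uppercase forms of the same roots, linked by the case-convention homolog
#' map. A Gli1-coexpression rank table is emitted with the shared-target
#' genes at the top (jittered).
#'
#' @param config A [synthetic_config()].
#' @return List with elements `datasets` (list of probeset-level
#'   [expression_dataset()]s with probe annotations), `homolog_map`,
#'   `truth` (tibble: `gene` = human-side symbol, `membership`,
#'   `effect_log2`), `coexpression` (tibble: `gene`, `qrank`, mouse-cased
#'   symbols), `config`.
#' @export
generate_suite <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_suite_impl(config))
}

generate_suite_impl <- function(cfg) {
  n <- cfg$n_genes
  mouse_sym <- synth_symbols(n)
  human_sym <- toupper(mouse_sym)

  membership <- rep("background", n)
  idx <- sample.int(n, cfg$shared_set_size + cfg$human_specific_set_size +
                      cfg$mouse_specific_set_size)
  i_shared <- idx[seq_len(cfg$shared_set_size)]
  i_human <- idx[cfg$shared_set_size + seq_len(cfg$human_specific_set_size)]
  i_mouse <- idx[cfg$shared_set_size + cfg$human_specific_set_size +
                   seq_len(cfg$mouse_specific_set_size)]
  membership[i_shared] <- "shared_target"
  membership[i_human] <- "human_specific"
  membership[i_mouse] <- "mouse_specific"

  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)

  make_dataset <- function(species, d) {
    groups <- if (species == "mouse") cfg$mouse_groups else cfg$human_groups
    syms <- if (species == "mouse") mouse_sym else human_sym
    target <- if (species == "mouse") "Shh" else "SHH"
    effect <- numeric(n)
    up <- if (species == "mouse") c(i_shared, i_mouse) else c(i_shared, i_human)
    effect[up] <- cfg$effect_log2

    # probe structure is drawn from a fixed stream so that changing the
    # config seed changes values but never matrix shapes
    n_probes <- withr::with_seed(
      1815L, sample(cfg$probes_per_gene, n, replace = TRUE))
    probe_gene <- rep(seq_len(n), n_probes)
    probe_ids <- sprintf("p%05d_at", seq_along(probe_gene))
    probe_off <- rnorm(length(probe_gene), 0, cfg$probe_offset_sd)

    sample_groups <- rep(names(groups), groups)
    sample_ids <- sprintf("%s_%s_s%02d",
                          paste0(substr(species, 1, 2), d),
                          sample_groups, seq_along(sample_groups))
    batch <- rnorm(length(sample_ids), 0, cfg$batch_shift_sd)

    gene_mu <- outer(baseline, rep(1, length(sample_ids)))
    shh_cols <- sample_groups == target
    gene_mu[, shh_cols] <- gene_mu[, shh_cols] + effect
    mat <- gene_mu[probe_gene, , drop = FALSE] + probe_off +
      rep(batch, each = length(probe_gene)) +
      matrix(rnorm(length(probe_gene) * length(sample_ids), 0, cfg$noise_sd),
             length(probe_gene))
    dimnames(mat) <- list(probe_ids, sample_ids)
    expression_dataset(
      mat, setNames(sample_groups, sample_ids), species,
      dataset_id = sprintf("%s%d", species, d),
      feature_level = "probeset",
      probe_annotation = setNames(syms[probe_gene], probe_ids))
  }

  datasets <- c(
    lapply(seq_len(cfg$n_mouse_datasets), function(d) make_dataset("mouse", d)),
    lapply(seq_len(cfg$n_human_datasets), function(d) make_dataset("human", d))
  )

  homolog_map <- tibble(mouse = mouse_sym, human = human_sym)
  truth <- tibble(gene = human_sym, membership = membership,
                  effect_log2 = ifelse(membership == "background", 0,
                                       cfg$effect_log2))

  # Gli1-coexpression ranks: shared targets score high, everything else null
  coexpr_score <- ifelse(membership == "shared_target", 2, 0) +
    rnorm(n, 0, max(cfg$coexpr_jitter, 1e-9))
  coexpression <- tibble(
    gene = mouse_sym,
    qrank = (rank(coexpr_score, ties.method = "average") - 1) / (n - 1))

  list(datasets = datasets, homolog_map = homolog_map, truth = truth,
       coexpression = coexpression, config = cfg)
}

#' Gene-set collection with the planted sets embedded
#'
#' Emits one gene set per planted category (`PLANTED_SHARED_TARGET`,
#' `PLANTED_HUMAN_SPECIFIC`, `PLANTED_MOUSE_SPECIFIC`) plus `n_random_sets`
#' background sets drawn uniformly from all genes — the stand-in for a
#' hallmark/curated collection when validating the enrichment stage.
#'
#' @param truth Truth tibble from [generate_suite()].
#' @param n_random_sets Number of random background sets (default 50).
#' @param set_size_range Length-2 integer range of random-set sizes
#'   (default c(15, 100)).
#' @param seed Integer seed.
#' @return Gene-set tibble (as from [read_gmt()]).
#' @export
generate_gmt_with_planted_sets <- function(truth, n_random_sets = 50,
                                           set_size_range = c(15, 100),
                                           seed = 1) {
  if (max(set_size_range) > nrow(truth)) {
    abort("set size range exceeds gene count")
  }
  planted <- split(truth$gene, truth$membership)
  planted <- planted[setdiff(names(planted), "background")]
  nm_map <- c(shared_target = "PLANTED_SHARED_TARGET",
              human_specific = "PLANTED_HUMAN_SPECIFIC",
              mouse_specific = "PLANTED_MOUSE_SPECIFIC")
  sets <- tibble(
    name = unname(nm_map[names(planted)]),
    description = sprintf("planted %s genes", names(planted)),
    genes = unname(planted)
  )
  rand <- withr::with_seed(seed, {
    lapply(seq_len(n_random_sets), function(i) {
      k <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
      sample(truth$gene, k)
    })
  })
  bind_rows(sets, tibble(
    name = sprintf("RANDOM_SET_%03d", seq_len(n_random_sets)),
    description = "random background set",
    genes = rand
  ))
}
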