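#' Rank-invariant-set between-array normalization
#'
#' Renormalizes each array against a reference by fitting a monotone mapping
#' through its rank-invariant features. For an array/reference pair, the
#' invariant set is found iteratively: starting from all features, features
#' whose proportion rank difference — |rank in array − rank in reference|
#' divided by the current set size — is below `prop_threshold` are retained,
#' ranks are recomputed within the retained set, and the process repeats until
#' the set stabilizes (at most `max_iter` rounds). A running-median smooth
#' (window `window` invariant points, shrunk to an odd size if the set is
#' small) through the (array, reference) value pairs of the invariant set is
#' then applied to all features by linear interpolation; values outside the
#' invariant range are mapped by the nearest smooth point. The reference array
#' is left unchanged.
#'
#' @param dataset An [expression_dataset()] with at least 2 samples.
#' @param reference A sample id, or `"pseudo-median"` (default) for the
#'   synthetic array of per-feature median values.
#' @param prop_threshold Proportion-rank-difference cutoff defining the
#'   invariant set (default 0.05).
#' @param max_iter Maximum refinement iterations (default 30).
#' @param window Running-median window in invariant points (default 51).
#' @return The dataset with every non-reference array monotonically
#'   transformed onto the reference scale.
#' @export
invariant_set_normalize <- function(dataset, reference = "pseudo-median",
                                    prop_threshold = 0.05, max_iter = 30,
                                    window = 51) {
  stopifnot(inherits(dataset, "expr_dataset"))
  mat <- dataset$matrix
  if (ncol(mat) < 2L) abort("need >= 2 samples to normalize")
  if (identical(reference, "pseudo-median")) {
    ref <- apply(mat, 1L, median)
  } else {
    if (!reference %in% colnames(mat)) {
      abort(sprintf("reference sample '%s' not in dataset", reference))
    }
    ref <- mat[, reference]
  }
  out <- mat
  for (j in seq_len(ncol(mat))) {
    if (!identical(reference, "pseudo-median") &&
        colnames(mat)[j] == reference) next
    out[, j] <- normalize_one_array(mat[, j], ref, prop_threshold, max_iter,
                                    window)
  }
  dataset$matrix <- out
  dataset
}

normalize_one_array <- function(x, ref, prop_threshold, max_iter, window) {
  n <- length(x)
  keep <- seq_len(n)
  for (it in seq_len(max_iter)) {
    rx <- rank(x[keep], ties.method = "average")
    rr <- rank(ref[keep], ties.method = "average")
    prd <- abs(rx - rr) / length(keep)
    new_keep <- keep[prd < prop_threshold]
    if (length(new_keep) == length(keep)) break
    keep <- new_keep
    if (length(keep) < 20L) break
  }
  if (length(keep) < 20L) {
    abort(paste0("fewer than 20 rank-invariant features found; ",
                 "increase `prop_threshold`"))
  }
  ord <- order(x[keep])
  xi <- x[keep][ord]
  yi <- ref[keep][ord]
  k <- min(window, length(xi))
  if (k %% 2L == 0L) k <- k - 1L
  # endrule "keep": the raw invariant pairs anchor the mapping at the ends,
  # so a clean monotone distortion is recovered exactly over the full range
  ys <- if (k >= 3L) runmed(yi, k, endrule = "keep") else yi
  # collapse duplicated x positions so approx() has strictly ordered knots
  ux <- !duplicated(xi)
  if (sum(ux) < 2L) return(rep(mean(ys), n))
  approx(xi[ux], ys[ux], xout = x, rule = 2, ties = "ordered")$y
}

#' Per-group median expression table
#'
#' For every feature, the median log2 expression over the samples of each
#' group — the per-dataset summary all downstream overexpression scoring is
#' built on. Single-sample groups yield that sample's value.
#'
#' @param dataset An [expression_dataset()].
#' @return Tibble with a `feature` column and one numeric column per group
#'   label; attributes `dataset_id`, `species`, `feature_level` carry through.
#' @export
group_medians <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  groups <- dataset$sample_groups
  labels <- unique(unname(groups))
  empty <- labels[!labels %in% groups[colnames(dataset$matrix)]]
  if (length(empty)) {
    abort(sprintf("group(s) with no samples: %s", paste(empty, collapse = ", ")))
  }
  med <- vapply(labels, function(g) {
    cols <- names(groups)[groups == g]
    m <- dataset$matrix[, cols, drop = FALSE]
    apply(m, 1L, median)
  }, numeric(nrow(dataset$matrix)))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1L, dimnames = list(rownames(dataset$matrix), labels))
  out <- as_tibble(med)
  out <- dplyr::bind_cols(tibble(feature = rownames(dataset$matrix)), out)
  attr(out, "dataset_id") <- dataset$dataset_id
  attr(out, "species") <- dataset$species
  attr(out, "feature_level") <- dataset$feature_level
  out
}

median_table_groups <- function(table) setdiff(names(table), "feature")

#' Collapse a probeset-level median table to gene level (max-mean)
#'
#' For each gene the retained row is the probeset whose mean across the
#' table's group columns is maximal (ties broken by lexicographically
#' smallest probeset id). Unannotated probesets (absent from `annotation`, or
#' mapped to the empty string) are dropped.
#'
#' @param table Probeset-level tibble from [group_medians()].
#' @param annotation Named character vector probeset id -> gene symbol.
#' @return Gene-level tibble (`feature` column holds gene symbols), attribute
#'   `feature_level = "gene"`; attribute `chosen_probe` records the selected
#'   probeset per gene.
#' @export
collapse_to_genes_max_mean <- function(table, annotation) {
  grp <- median_table_groups(table)
  ann <- annotation[nzchar(annotation)]
  hit <- table$feature %in% names(ann)
  if (!any(hit)) abort("no probeset in the table is covered by the annotation")
  sub <- table[hit, , drop = FALSE]
  genes <- unname(ann[sub$feature])
  means <- rowMeans(as.matrix(sub[, grp, drop = FALSE]))
  # deterministic argmax: order by gene, then -mean, then probeset id
  ord <- order(genes, -means, sub$feature)
  first <- ord[!duplicated(genes[ord])]
  out <- sub[first, , drop = FALSE]
  chosen <- out$feature
  out$feature <- genes[first]
  out <- arrange(out, .data$feature)
  attr(out, "dataset_id") <- attr(table, "dataset_id")
  attr(out, "species") <- attr(table, "species")
  attr(out, "feature_level") <- "gene"
  attr(out, "chosen_probe") <- setNames(chosen[order(genes[first])], out$feature)
  out
}

#' Sample-level expression of a gene's most expressed probeset
#'
#' For single-gene plots: returns the sample-level expression row of the
#' probeset with the highest mean log2 expression among those annotated to
#' `gene` (ties broken by probeset id).
#'
#' @param dataset A probeset-level [expression_dataset()].
#' @param gene Gene symbol (matched case-insensitively).
#' @param annotation Named character vector probeset id -> gene symbol;
#'   defaults to the dataset's own `probe_annotation`.
#' @return Tibble with columns `sample_id`, `group`, `value`; attributes
#'   `gene` and `probeset`.
#' @export
select_max_mean_probe <- function(dataset, gene, annotation = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (is.null(annotation)) annotation <- dataset$probe_annotation
  if (is.null(annotation)) abort("no probe annotation available")
  probes <- names(annotation)[tolower(annotation) == tolower(gene)]
  probes <- intersect(probes, rownames(dataset$matrix))
  if (!length(probes)) {
    abort(sprintf("gene '%s' has no annotated probeset in the dataset", gene))
  }
  means <- rowMeans(dataset$matrix[probes, , drop = FALSE])
  best <- probes[order(-means, probes)][1L]
  out <- tibble(
    sample_id = colnames(dataset$matrix),
    group = unname(dataset$sample_groups[colnames(dataset$matrix)]),
    value = unname(dataset$matrix[best, ])
  )
  attr(out, "gene") <- gene
  attr(out, "probeset") <- best
  out
}
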