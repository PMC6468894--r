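#' Assemble an expression dataset
#'
#' Bundles a log2 expression matrix (features x samples) with its sample-to-
#' group annotation, species tag and dataset id into the container the rest of
#' the pipeline consumes. Features are microarray probesets or gene symbols;
#' groups are tumor/tissue labels such as `"SHH"`, `"Group3"` or
#' `"cerebellum"`.
#'
#' @param matrix Numeric matrix, rows = feature ids (unique, non-empty),
#'   columns = sample ids (unique). Values on the log2 scale.
#' @param sample_groups Named character vector or two-column data frame
#'   (`sample_id`, `group`) mapping every matrix column to a group label.
#' @param species `"human"` or `"mouse"`.
#' @param dataset_id Short identifier used in result tables.
#' @param feature_level `"probeset"` or `"gene"`.
#' @param probe_annotation Optional named character vector mapping probeset id
#'   to gene symbol (empty string = unannotated). Must be absent when
#'   `feature_level = "gene"`.
#' @return An object of class `expr_dataset`: a list with elements `matrix`,
#'   `sample_groups` (named character vector), `species`, `dataset_id`,
#'   `feature_level`, `probe_annotation`, `n_dropped_na` (rows removed because
#'   of missing values).
#' @export
#' @examples
#' m <- matrix(rnorm(12, 7), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c(s1 = "SHH", s2 = "SHH", s3 = "Group3",
#'   s4 = "Group3"), "human", "toy", feature_level = "gene")
#' ds
expression_dataset <- function(matrix, sample_groups, species, dataset_id,
                               feature_level = c("probeset", "gene"),
                               probe_annotation = NULL) {
  feature_level <- match.arg(feature_level)
  species <- match.arg(species, c("human", "mouse"))
  if (is.data.frame(sample_groups)) {
    stopifnot(ncol(sample_groups) >= 2)
    sample_groups <- setNames(as.character(sample_groups[[2]]),
                              as.character(sample_groups[[1]]))
  }
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix")
  }
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    abort(sprintf("dataset '%s': empty expression matrix", dataset_id))
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort("`matrix` needs feature rownames and sample colnames")
  }
  dup <- rownames(matrix)[duplicated(rownames(matrix))]
  if (length(dup)) {
    abort(sprintf("dataset '%s': duplicate feature ids: %s", dataset_id,
                  paste(unique(head(dup, 5)), collapse = ", ")))
  }
  if (anyDuplicated(colnames(matrix))) {
    abort(sprintf("dataset '%s': duplicate sample ids", dataset_id))
  }
  missing_ann <- setdiff(colnames(matrix), names(sample_groups))
  if (length(missing_ann)) {
    abort(sprintf(
      "dataset '%s': samples without a group label: %s", dataset_id,
      paste(missing_ann, collapse = ", ")))
  }
  n_dropped <- 0L
  if (anyNA(matrix)) {
    keep <- stats::complete.cases(matrix)
    n_dropped <- sum(!keep)
    inform(sprintf("dataset '%s': dropped %d row(s) with missing values",
                   dataset_id, n_dropped))
    matrix <- matrix[keep, , drop = FALSE]
    if (nrow(matrix) == 0L) {
      abort(sprintf("dataset '%s': all rows had missing values", dataset_id))
    }
  }
  if (feature_level == "gene" && !is.null(probe_annotation)) {
    abort("gene-level datasets carry no probe annotation")
  }
  structure(
    list(
      matrix = matrix,
      sample_groups = sample_groups[colnames(matrix)],
      species = species,
      dataset_id = as.character(dataset_id),
      feature_level = feature_level,
      probe_annotation = probe_annotation,
      n_dropped_na = n_dropped
    ),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset '%s'> %s, %s-level: %d features x %d samples\n",
    x$dataset_id, x$species, x$feature_level, nrow(x$matrix), ncol(x$matrix)))
  tab <- table(x$sample_groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$matrix)

#' Sample groups of a dataset as a tibble
#'
#' @param dataset An [expression_dataset()].
#' @return Tibble with columns `sample_id`, `group`.
#' @export
sample_groups <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  tibble(sample_id = names(dataset$sample_groups),
         group = unname(dataset$sample_groups))
}

# case-insensitive resolution of a group label against a dataset/table's
# group set; the SHH/Shh capitalization difference between species is the
# reason this exists
match_group <- function(target, groups, what = "group") {
  if (target %in% groups) return(target)
  hit <- groups[tolower(groups) == tolower(target)]
  hit <- unique(hit)
  if (length(hit) == 1L) return(hit)
  abort(sprintf("%s '%s' not found among: %s", what, target,
                paste(unique(groups), collapse = ", ")))
}
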