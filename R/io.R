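#' Read an expression matrix with its sample annotation
#'
#' Ingests a tab-separated expression table (first column feature ids, header
#' row sample ids — the layout of a GEO series-matrix expression block saved
#' as plain TSV) together with a two-column sample annotation TSV
#' (`sample_id`, `group`). Values that look linear rather than log2 (matrix
#' maximum above `log_threshold`) are transformed with `log2(x + 1)`; log2
#' microarray intensities rarely exceed ~16 while linear intensities always
#' do, so the detection is idempotent. Rows containing missing values are
#' dropped and counted.
#'
#' @param path Expression matrix TSV.
#' @param annotation_path Sample annotation TSV (two columns, with or without
#'   a header).
#' @param dataset_id,species Passed to [expression_dataset()].
#' @param feature_level `"probeset"` (default) or `"gene"`.
#' @param probe_annotation Optional named character vector probeset -> symbol.
#' @param log_threshold Matrix maximum above which values are treated as
#'   linear intensities. Default 50.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, annotation_path, dataset_id, species,
                                   feature_level = "probeset",
                                   probe_annotation = NULL,
                                   log_threshold = 50) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) abort(sprintf("'%s': expected features + >=1 sample", path))
  features <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- features

  ann <- read_two_column_tsv(annotation_path, c("sample_id", "group"))
  groups <- setNames(ann$group, ann$sample_id)

  if (max(mat, na.rm = TRUE) > log_threshold) {
    inform(sprintf(
      "dataset '%s': values look linear (max %.3g > %g); applying log2(x + 1)",
      dataset_id, max(mat, na.rm = TRUE), log_threshold))
    mat <- log2(mat + 1)
  }
  expression_dataset(mat, groups, species, dataset_id,
                     feature_level = feature_level,
                     probe_annotation = probe_annotation)
}

# two-column TSV reader tolerating an optional header row equal to `cols`
read_two_column_tsv <- function(path, cols) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("'%s': empty file", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    abort(sprintf("'%s': line %d is not two tab-separated fields", path, bad[1L]))
  }
  df <- tibble(!!cols[1] := vapply(parts, `[[`, "", 1L),
               !!cols[2] := vapply(parts, `[[`, "", 2L))
  if (identical(unname(tolower(unlist(df[1L, ]))), tolower(cols))) {
    df <- df[-1L, ]
  }
  df
}

#' Write an expression dataset back to disk
#'
#' Inverse of [read_expression_matrix()]: writes the matrix TSV (feature ids
#' in the first column, named like `feature_level`) and the two-column sample
#' annotation TSV. Round-trips values at full precision.
#'
#' @param dataset An [expression_dataset()].
#' @param path,annotation_path Output file paths.
#' @return `dataset`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path, annotation_path) {
  stopifnot(inherits(dataset, "expr_dataset"))
  df <- data.frame(feature = rownames(dataset$matrix), dataset$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- dataset$feature_level
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(dataset$sample_groups),
               group = unname(dataset$sample_groups)),
    annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Read a GMT gene-set collection
#'
#' Parses the Broad GMT dialect: one set per line,
#' `name TAB description TAB member TAB member ...`. Member symbols are
#' uppercased and deduplicated within a set.
#'
#' @param path GMT file.
#' @return Tibble with columns `name`, `description` and list-column `genes`
#'   (character vectors of unique uppercase symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort(sprintf("'%s': line %d has fewer than 3 tab-separated fields",
                  path, bad[1L]))
  }
  nm <- vapply(parts, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    abort(sprintf("'%s': duplicate gene-set name(s): %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  tibble(
    name = nm,
    description = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) {
      g <- unique(toupper(p[-(1:2)]))
      g[nzchar(g)]
    })
  )
}

#' Write a gene-set collection as GMT
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output file.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(c("name", "description", "genes") %in% names(sets)))
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

#' Convert a gene-set tibble to a named list
#'
#' @param sets Tibble from [read_gmt()].
#' @return Named list of character vectors.
#' @export
gene_set_list <- function(sets) setNames(sets$genes, sets$name)

#' Read or construct a mouse-human homolog symbol map
#'
#' With a path, reads a two-column TSV (`mouse`, `human`); many-to-many
#' entries are resolved per `resolution` (the default `one_to_one_only` drops
#' every symbol involved in an ambiguity and reports the count). Without a
#' path, builds the case-convention map — mouse title-case symbols paired with
#' their uppercase human form (e.g. Gpr153/GPR153) — from the supplied symbol
#' universes.
#'
#' @param path Homolog map TSV, or `NULL` for the case-convention default.
#' @param mouse_genes,human_genes Symbol universes used when `path` is `NULL`.
#' @param resolution `"one_to_one_only"` (drop ambiguous symbols) or
#'   `"first"` (keep the first occurrence of each symbol).
#' @return Tibble with columns `mouse`, `human`; attribute `n_ambiguous`
#'   counts pairs removed by resolution.
#' @export
read_homolog_map <- function(path = NULL, mouse_genes = NULL,
                             human_genes = NULL,
                             resolution = c("one_to_one_only", "first")) {
  resolution <- match.arg(resolution)
  if (is.null(path)) {
    if (is.null(mouse_genes) || is.null(human_genes)) {
      abort("without `path`, supply `mouse_genes` and `human_genes`")
    }
    hu <- unique(human_genes)
    mo <- unique(mouse_genes)
    pairs <- tibble(mouse = mo, human = toupper(mo)) %>%
      filter(.data$human %in% toupper(hu))
    # report symbols under the human-side casing actually present
    hu_by_upper <- setNames(hu, toupper(hu))
    pairs$human <- unname(hu_by_upper[pairs$human])
  } else {
    pairs <- read_two_column_tsv(path, c("mouse", "human"))
  }
  pairs <- dplyr::distinct(pairs)
  amb <- unique(c(
    pairs$mouse[duplicated(pairs$mouse) | duplicated(pairs$mouse, fromLast = TRUE)],
    pairs$human[duplicated(pairs$human) | duplicated(pairs$human, fromLast = TRUE)]
  ))
  n_amb <- 0L
  if (length(amb)) {
    before <- nrow(pairs)
    if (resolution == "one_to_one_only") {
      pairs <- pairs[!(pairs$mouse %in% amb) & !(pairs$human %in% amb), ,
                     drop = FALSE]
    } else {
      pairs <- pairs[!duplicated(pairs$mouse) & !duplicated(pairs$human), ,
                     drop = FALSE]
    }
    n_amb <- before - nrow(pairs)
    inform(sprintf("homolog map: removed %d ambiguous pair(s)", n_amb))
  }
  structure(as_tibble(pairs), n_ambiguous = n_amb)
}

#' Write a result table as TSV
#'
#' Writes any pipeline result table tab-separated with a header, in a
#' deterministic row order: GSEA results sort by FWER p then descending
#' absolute NES, rank-difference tables by descending `diff`, everything else
#' by its first column.
#'
#' @param table Non-empty data frame.
#' @param path Output file.
#' @return `table` (sorted as written), invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("`table` must be a non-empty data frame")
  }
  if (all(c("fwer_p", "nes") %in% names(table))) {
    table <- arrange(table, .data$fwer_p, desc(abs(.data$nes)))
  } else if ("diff" %in% names(table)) {
    table <- arrange(table, desc(.data$diff))
  } else {
    table <- arrange(table, table[[1L]])
  }
  flat <- as.data.frame(lapply(table, function(col) {
    if (is.list(col)) vapply(col, paste, "", collapse = ",") else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}
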