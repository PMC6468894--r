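#' Pairwise dataset correlogram of SHH overexpression values
#'
#' Pearson correlation of target-group overexpression values between every
#' pair of datasets, over the genes the pair shares (mouse symbols mapped to
#' their human homolog first; intersection is pairwise-complete, so each cell
#' may use a different gene set, whose size is reported). With `on_ranks =
#' TRUE` the correlation is computed on quantile ranks of the values instead.
#'
#' @param tables List of overexpression tibbles ([center_rows()] /
#'   [cerebellum_normalize()]), length >= 2.
#' @param homolog_map Tibble from [read_homolog_map()].
#' @param target_group Column to correlate (matched case-insensitively per
#'   table). Default `"SHH"`.
#' @param on_ranks Correlate quantile ranks instead of values. Default FALSE.
#' @return Object of class `crossmb_correlogram`: list with `r` and `n`
#'   (symmetric matrices, dataset ids as dimnames), `species` (named vector),
#'   `on_ranks`.
#' @export
dataset_correlogram <- function(tables, homolog_map, target_group = "SHH",
                                on_ranks = FALSE) {
  if (length(tables) < 2L) abort("need >= 2 overexpression tables")
  ids <- vapply(tables, function(t) attr(t, "dataset_id"), "")
  spp <- vapply(tables, function(t) attr(t, "species"), "")
  vecs <- lapply(tables, function(t) {
    tg <- match_group(target_group, median_table_groups(t), "target group")
    g <- canonicalize_genes(t$feature, attr(t, "species"), homolog_map)
    v <- t[[tg]]
    keep <- !is.na(g) & !duplicated(g)
    v <- v[keep]
    if (on_ranks) v <- (rank(v, ties.method = "average") - 1) / (length(v) - 1)
    setNames(v, g[keep])
  })
  k <- length(vecs)
  r <- diag(1, k); n <- matrix(0L, k, k)
  dimnames(r) <- dimnames(n) <- list(ids, ids)
  diag(n) <- vapply(vecs, length, 0L)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    shared <- intersect(names(vecs[[i]]), names(vecs[[j]]))
    if (length(shared) < 3L) {
      abort(sprintf("datasets '%s' and '%s' share fewer than 3 genes",
                    ids[i], ids[j]))
    }
    r[i, j] <- r[j, i] <- cor(vecs[[i]][shared], vecs[[j]][shared])
    n[i, j] <- n[j, i] <- length(shared)
  }
  structure(list(r = r, n = n, species = setNames(spp, ids),
                 on_ranks = on_ranks),
            class = "crossmb_correlogram")
}

#' @export
print.crossmb_correlogram <- function(x, ...) {
  cat(sprintf("<crossmb_correlogram> %d datasets (%s)\n", nrow(x$r),
              if (x$on_ranks) "on ranks" else "on values"))
  print(round(x$r, 3))
  invisible(x)
}

#' Tidy a correlogram into one row per dataset pair
#'
#' @param x A `crossmb_correlogram`.
#' @param ... Unused.
#' @return Tibble with columns `dataset_a`, `dataset_b`, `species_a`,
#'   `species_b`, `comparison` (`within_human` / `within_mouse` /
#'   `between_species`), `r`, `n` — upper triangle only.
#' @export
tidy.crossmb_correlogram <- function(x, ...) {
  ids <- rownames(x$r)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    dataset_a = ids[pairs[, 1L]],
    dataset_b = ids[pairs[, 2L]],
    species_a = unname(x$species[ids[pairs[, 1L]]]),
    species_b = unname(x$species[ids[pairs[, 2L]]]),
    r = x$r[pairs],
    n = as.integer(x$n[pairs])
  ) %>%
    mutate(comparison = dplyr::case_when(
      species_a == species_b & species_a == "human" ~ "within_human",
      species_a == species_b ~ "within_mouse",
      TRUE ~ "between_species"
    )) %>%
    select("dataset_a", "dataset_b", "species_a", "species_b", "comparison",
           "r", "n")
}

#' Within- versus between-species correlation summary
#'
#' @param x A `crossmb_correlogram`.
#' @param ... Unused.
#' @return One-row tibble: `mean_within_species_r`, `mean_between_species_r`,
#'   `within_minus_between`, `n_pairs`.
#' @export
glance.crossmb_correlogram <- function(x, ...) {
  td <- tidy(x)
  within <- td$r[td$comparison != "between_species"]
  between <- td$r[td$comparison == "between_species"]
  tibble(
    mean_within_species_r = mean(within),
    mean_between_species_r = mean(between),
    within_minus_between = mean(within) - mean(between),
    n_pairs = nrow(td)
  )
}

#' Plot a dataset correlogram
#'
#' Heat-tile plot of the pairwise Pearson correlations, datasets ordered
#' mouse-first then human, correlation printed in each tile.
#'
#' @param object A `crossmb_correlogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossmb_correlogram <- function(object, ...) {
  ids <- names(sort(object$species))
  df <- as_tibble(as.data.frame(as.table(object$r[ids, ids])),
                  .name_repair = ~ c("dataset_a", "dataset_b", "r"))
  ggplot2::ggplot(df, ggplot2::aes(.data$dataset_a, .data$dataset_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
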