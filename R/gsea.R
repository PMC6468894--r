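#' Build a ranked gene list
#'
#' Sorts scores (e.g. human-minus-mouse rank differences) descending, with
#' ties broken by gene symbol sort so the ordering is deterministic across
#' platforms. Duplicate genes are an error.
#'
#' @param scores Named numeric vector (gene -> score) or a data frame with a
#'   gene column and a score column (a [rank_difference()] table works: `diff`
#'   is the score).
#' @return Named numeric vector sorted descending, class `crossmb_ranked`.
#' @export
ranked_list <- function(scores) {
  if (is.data.frame(scores)) {
    score_col <- intersect(c("diff", "score"), names(scores))
    if (!length(score_col)) abort("data frame needs a `diff` or `score` column")
    scores <- setNames(scores[[score_col[1L]]], scores$gene)
  }
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    abort("scores must be named by gene")
  }
  names(scores) <- toupper(names(scores))
  if (anyDuplicated(names(scores))) abort("duplicate genes in ranked list")
  ord <- order(-scores, names(scores), method = "radix")
  structure(scores[ord], class = "crossmb_ranked")
}

# core running-sum statistic, computed only at hit positions.
# pos: sorted indices of the set's genes in the ranked list; w: |score|^weight
# at those positions. Hits increment by w/sum(w); each miss decrements by
# 1/(N - k). Extrema of the running sum occur right after a hit (candidate
# max) or right before one (candidate min).
es_core <- function(pos, w, n_total) {
  k <- length(pos)
  sw <- sum(w)
  w <- if (sw == 0) rep(1 / k, k) else w / sw
  miss_dec <- 1 / (n_total - k)
  cum_hit <- cumsum(w)
  misses_before <- pos - seq_len(k)          # misses strictly before hit i
  at_hit <- cum_hit - misses_before * miss_dec
  before_hit <- c(0, cum_hit[-k]) - misses_before * miss_dec
  hi <- max(at_hit)
  lo <- min(c(before_hit, cum_hit[k] - (n_total - k) * miss_dec))
  # positive extreme wins a tie; the tolerance absorbs accumulation error
  if (hi >= -lo - 1e-12) hi else lo
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list top to bottom: genes in the set (hits) increment the
#' running sum by |score|^`weight` normalized over the set's hits; every
#' other gene decrements it by 1 / (N - N_hits). The enrichment score (ES) is
#' the running-sum value of maximal absolute deviation from zero, signed; the
#' leading edge is the set's genes at or before the extremum (positive ES) or
#' at and after it (negative ES). At `weight = 0` the ES is the signed
#' two-sample Kolmogorov-Smirnov D statistic between hit and miss positions.
#'
#' @param list A [ranked_list()].
#' @param set Character vector of gene symbols (a row of [read_gmt()] via its
#'   `genes` list-column, or any symbol set).
#' @param weight Exponent on |score| for hit increments (default 1).
#' @return List with `es`, `running_sum` (full-length numeric, for plotting),
#'   `leading_edge` (character), `set_size_used`.
#' @export
enrichment_score <- function(list, set, weight = 1) {
  stopifnot(inherits(list, "crossmb_ranked"), weight >= 0)
  genes <- names(list)
  n <- length(genes)
  pos <- sort(which(genes %in% toupper(set)))
  k <- length(pos)
  if (k == 0L) abort("set has no gene in the ranked list")
  if (k == n) abort("set contains every listed gene; miss decrement undefined")
  w <- abs(unname(list))[pos]^weight
  es <- es_core(pos, w, n)

  # full running sum for plots / leading edge
  inc <- numeric(n)
  sw <- sum(abs(unname(list))[pos]^weight)
  inc[pos] <- if (sw == 0) 1 / k else abs(unname(list))[pos]^weight / sw
  inc[-pos] <- -1 / (n - k)
  rs <- cumsum(inc)
  if (es >= 0) {
    peak <- which.max(rs)
    le <- genes[pos[pos <= peak]]
  } else {
    # extremum of the minimum is just before the following hit; the running
    # sum minimum index locates it
    trough <- which.min(rs)
    le <- genes[pos[pos > trough]]
  }
  list(es = es, running_sum = rs, leading_edge = le, set_size_used = k)
}

#' Permutation null sample of enrichment scores
#'
#' Samples `n_perm` uniformly random gene sets of size `set_size` from the
#' ranked list and returns their enrichment scores — the standard preranked
#' null (no phenotype labels exist for a preranked analysis).
#'
#' @param list A [ranked_list()].
#' @param set_size Size of the random sets (0 < size < list length).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; identical seeds give identical samples.
#' @param weight Exponent as in [enrichment_score()].
#' @return Numeric vector of `n_perm` null ES values.
#' @export
permutation_null <- function(list, set_size, n_perm, seed, weight = 1) {
  stopifnot(inherits(list, "crossmb_ranked"))
  n <- length(list)
  if (set_size <= 0L || set_size >= n) abort("set_size must be in (0, n)")
  if (n_perm < 100L) abort("n_perm must be >= 100")
  absw <- abs(unname(list))^weight
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(n, set_size))
      es_core(pos, absw[pos], n)
    }, 0)
  })
}

#' Normalize enrichment scores and compute permutation FWER
#'
#' NES = ES divided by the absolute mean of the same-sign null ES of that set
#' (positive and negative nulls normalized separately, keeping the sign).
#' Nominal p is the fraction of same-sign null ES at least as extreme as the
#' observed. The FWER p-value is the fraction of permutations in which the
#' most extreme same-sign null NES over the whole family meets or exceeds the
#' observed NES, among permutations contributing at least one same-sign
#' value (for any realistic family that is every permutation; for a family
#' of one set it makes the FWER p equal the nominal p on the NES scale).
#' p-values of exactly 0 mean "< 1/n_perm".
#'
#' @param observed Tibble with columns `set_name`, `es`, `set_size_used`,
#'   `leading_edge` (list-column) — one row per set.
#' @param nulls Matrix of null ES, `n_perm` rows x one column per set (same
#'   order as `observed`).
#' @return Tibble of GSEA results: `set_name`, `set_size_used`, `es`, `nes`,
#'   `nominal_p`, `fwer_p`, `direction`, `leading_edge`; sets whose ES sign
#'   has no same-sign nulls get `NA` NES and are excluded from the FWER
#'   family (with a message).
#' @export
normalize_and_fwer <- function(observed, nulls) {
  stopifnot(nrow(observed) == ncol(nulls))
  n_sets <- nrow(observed)
  n_perm <- nrow(nulls)

  pos_mean <- apply(nulls, 2L, function(v) mean(v[v > 0]))
  neg_mean <- apply(nulls, 2L, function(v) mean(v[v < 0]))

  es <- observed$es
  denom <- ifelse(es >= 0, pos_mean, abs(neg_mean))
  nes <- es / denom
  bad <- !is.finite(nes)
  if (any(bad)) {
    inform(sprintf("%d set(s) had no same-sign null ES; NES undefined, excluded from FWER",
                   sum(bad)))
  }

  nominal_p <- vapply(seq_len(n_sets), function(j) {
    v <- nulls[, j]
    if (es[j] >= 0) {
      same <- v[v >= 0]
      if (!length(same)) return(NA_real_)
      mean(same >= es[j])
    } else {
      same <- v[v <= 0]
      if (!length(same)) return(NA_real_)
      mean(same <= es[j])
    }
  }, 0)

  # per-permutation null NES, normalized by each set's own same-sign mean
  pos_nes <- sweep(nulls, 2L, pos_mean, "/")
  pos_nes[nulls <= 0 | !is.finite(pos_nes)] <- NA_real_
  neg_nes <- sweep(nulls, 2L, abs(neg_mean), "/")
  neg_nes[nulls >= 0 | !is.finite(neg_nes)] <- NA_real_
  fam <- which(!bad)
  max_pos <- apply(pos_nes[, fam, drop = FALSE], 1L, function(v)
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  min_neg <- apply(neg_nes[, fam, drop = FALSE], 1L, function(v)
    if (all(is.na(v))) Inf else min(v, na.rm = TRUE))

  fwer_p <- vapply(seq_len(n_sets), function(j) {
    if (bad[j]) return(NA_real_)
    if (es[j] >= 0) {
      valid <- is.finite(max_pos)
      mean(max_pos[valid] >= nes[j])
    } else {
      valid <- is.finite(min_neg)
      mean(min_neg[valid] <= nes[j])
    }
  }, 0)

  tibble(
    set_name = observed$set_name,
    set_size_used = observed$set_size_used,
    es = es,
    nes = nes,
    nominal_p = nominal_p,
    fwer_p = fwer_p,
    direction = ifelse(es >= 0, "positive", "negative"),
    leading_edge = observed$leading_edge
  )
}

#' Preranked gene-set enrichment analysis
#'
#' Runs the full preranked GSEA over a collection: filters sets to those with
#' `min_size <= |set ∩ list| <= max_size`, computes each observed ES, draws a
#' shared permutation null (one random same-size gene set per set per
#' permutation), normalizes to NES, and reports nominal and family-wise error
#' rate p-values for both enrichment directions — positive ES flags
#' human-specific gene sets, negative ES mouse-specific ones, when the scores
#' are human-minus-mouse rank differences.
#'
#' @param list A [ranked_list()] (or names scores coercible by
#'   [ranked_list()]).
#' @param sets Gene-set tibble from [read_gmt()] (columns `name`, `genes`).
#' @param min_size,max_size Membership-in-list size filter (defaults 15/500).
#' @param n_perm Permutations (default 1000).
#' @param weight ES exponent (default 1).
#' @param seed Integer seed for the permutation null.
#' @return Tibble as from [normalize_and_fwer()], sorted by `fwer_p` then
#'   descending |NES|; attribute `n_filtered` counts sets removed by the size
#'   filter.
#' @export
run_gsea <- function(list, sets, min_size = 15, max_size = 500,
                     n_perm = 1000, weight = 1, seed = 1) {
  if (!inherits(list, "crossmb_ranked")) list <- ranked_list(list)
  genes <- names(list)
  sizes <- vapply(sets$genes, function(g) sum(genes %in% toupper(g)), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) abort("no gene set survives the size filter")
  if (any(!keep)) {
    inform(sprintf("%d set(s) outside size range [%d, %d] skipped",
                   sum(!keep), min_size, max_size))
  }
  surv <- sets[keep, , drop = FALSE]
  obs <- purrr::map(surv$genes, ~ enrichment_score(list, .x, weight))
  observed <- tibble(
    set_name = surv$name,
    es = vapply(obs, `[[`, 0, "es"),
    set_size_used = vapply(obs, `[[`, 0L, "set_size_used"),
    leading_edge = lapply(obs, `[[`, "leading_edge")
  )

  n <- length(list)
  absw <- abs(unname(list))^weight
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      vapply(observed$set_size_used, function(k) {
        pos <- sort(sample.int(n, k))
        es_core(pos, absw[pos], n)
      }, 0)
    }, numeric(nrow(observed)))
  })
  nulls <- t(matrix(nulls, nrow = nrow(observed)))

  res <- normalize_and_fwer(observed, nulls)
  res <- arrange(res, .data$fwer_p, desc(abs(.data$nes)))
  attr(res, "n_filtered") <- sum(!keep)
  attr(res, "n_perm") <- n_perm
  res
}

#' Plot a running-sum enrichment curve
#'
#' @param list A [ranked_list()].
#' @param set Character vector of gene symbols.
#' @param weight ES exponent (default 1).
#' @return A ggplot object: the running sum with hit positions as a rug.
#' @export
plot_running_sum <- function(list, set, weight = 1) {
  es <- enrichment_score(list, set, weight)
  df <- tibble(position = seq_along(es$running_sum),
               running_sum = es$running_sum)
  hits <- tibble(position = which(names(list) %in% toupper(set)))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line(color = "#2166AC") +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = .data$position),
                      inherit.aes = FALSE, sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(x = "rank in ordered list", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", es$es)) +
    ggplot2::theme_minimal()
}
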