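#' Rank concordance between two gene rankings
#'
#' Ordinary least-squares regression of one quantile-rank vector on another
#' over their shared genes — used to ask whether genes highly ranked by
#' SHH-tumor overexpression are also highly ranked by coexpression with mouse
#' Gli1. Reports the rank R², slope, and the two-sided p-value for zero
#' slope.
#'
#' @param rank_a,rank_b Either named numeric vectors (gene -> rank) or
#'   two-column data frames (gene, rank). `rank_b` is regressed on `rank_a`.
#'   Genes are matched case-insensitively.
#' @return Object of class `crossmb_concordance` wrapping the `lm` fit, with
#'   fields `r_squared`, `slope`, `p_value`, `n`.
#' @export
rank_concordance <- function(rank_a, rank_b) {
  a <- as_rank_vector(rank_a)
  b <- as_rank_vector(rank_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) abort("fewer than 3 shared genes")
  fit <- lm(b ~ a, data = list(a = unname(a[shared]), b = unname(b[shared])))
  sm <- summary(fit)
  structure(
    list(
      r_squared = sm$r.squared,
      slope = unname(stats::coef(fit)[2L]),
      p_value = unname(sm$coefficients[2L, 4L]),
      n = length(shared),
      fit = fit
    ),
    class = "crossmb_concordance"
  )
}

as_rank_vector <- function(x) {
  if (is.data.frame(x)) {
    rank_col <- intersect(c("qrank", "rank", "mean_rank"), names(x))
    if (!length(rank_col)) rank_col <- names(x)[2L]
    gene_col <- if ("gene" %in% names(x)) "gene" else names(x)[1L]
    x <- setNames(x[[rank_col[1L]]], x[[gene_col]])
  }
  if (is.null(names(x))) abort("ranks must be named by gene")
  names(x) <- toupper(names(x))
  x[!duplicated(names(x))]
}

#' @export
print.crossmb_concordance <- function(x, ...) {
  cat(sprintf(
    "<rank concordance> R^2 = %.4f, slope = %.3f, p = %.3g, n = %d\n",
    x$r_squared, x$slope, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.crossmb_concordance <- function(x, ...) {
  tibble(term = c("(Intercept)", "rank_a"),
         estimate = unname(stats::coef(x$fit)),
         std.error = summary(x$fit)$coefficients[, 2L],
         p.value = summary(x$fit)$coefficients[, 4L])
}

#' @export
glance.crossmb_concordance <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, p_value = x$p_value,
         n = x$n)
}

#' Scatter plot of a rank-concordance fit
#'
#' @param object A `crossmb_concordance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossmb_concordance <- function(object, ...) {
  df <- tibble(a = object$fit$model$a, b = object$fit$model$b)
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#B2182B") +
    ggplot2::labs(
      x = "rank A", y = "rank B",
      subtitle = sprintf("R² = %.3f, p = %.2g, n = %d",
                         object$r_squared, object$p_value, object$n)) +
    ggplot2::theme_minimal()
}
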