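cortest_result <- function(statistic, df, p, kind, estimate = NA_real_,
                           n = NA_integer_) {
  tibble::tibble(kind = kind, estimate = estimate, statistic = statistic,
                 df = df, p.value = p, n = n)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided test of the difference in means without assuming equal
#' variances, with Welch-Satterthwaite degrees of freedom. Delegates to
#' [stats::t.test()].
#'
#' @param a,b numeric vectors, each of length >= 2; at least one with
#'   positive variance.
#' @return a one-row tibble: `kind`, `estimate` (mean difference a - b),
#'   `statistic` (t), `df`, `p.value`, `n`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) rlang::abort("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    rlang::abort("both groups have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  cortest_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                 "welch_t", estimate = mean(a) - mean(b),
                 n = length(a) + length(b))
}

#' Pearson correlation with t-based significance
#'
#' Significance of r is evaluated with `t = r * sqrt((n - 2) / (1 - r^2))` on
#' n - 2 degrees of freedom, two-sided ([stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return a one-row tibble: `kind`, `estimate` (r), `statistic` (t), `df`,
#'   `p.value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  cortest_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
                 "pearson", estimate = unname(ct$estimate), n = length(x))
}

#' Spearman rank correlation with t-approximation significance
#'
#' rho is the Pearson correlation of mid-ranks (ties get the average rank);
#' its significance uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom,
#' two-sided.
#'
#' @inheritParams pearson_cor
#' @return a one-row tibble as for [pearson_cor()] with `kind = "spearman"`.
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0; tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  cortest_result(tstat, n - 2, p, "spearman", estimate = rho, n = n)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (length(x) < 3) rlang::abort("at least 3 pairs are required")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::abort("constant vector: correlation undefined")
  }
  invisible(TRUE)
}

#' Assign pLDDT confidence categories
#'
#' The three-way banding used when relating confidence to flexibility:
#' high (score >= 98.5), medium (96.0 <= score < 98.5), low (score < 96.0).
#'
#' @param scores numeric pLDDT values (0-100).
#' @param high_min,low_max band edges.
#' @return factor with levels `high`, `medium`, `low`.
#' @export
score_categories <- function(scores, high_min = 98.5, low_max = 96.0) {
  factor(
    ifelse(scores >= high_min, "high",
           ifelse(scores >= low_max, "medium", "low")),
    levels = c("high", "medium", "low")
  )
}

#' Relate model confidence to crystallographic flexibility
#'
#' Joins a pLDDT profile of a predicted model with the B-factor profile of a
#' crystal structure on shared residues, then reports the Spearman rank
#' correlation between confidence and B-factor (expected negative: low
#' confidence marks flexible regions), the Pearson correlation between
#' per-residue expected position error and B-factor when a PAE matrix is
#' supplied, the per-residue confidence category, and per-category B-factor
#' summaries.
#'
#' @param plddt a `residue_profile` of pLDDT values (see [extract_profile()]).
#' @param bfac a `residue_profile` of B-factors.
#' @param pae optional n x n PAE matrix (see [read_pae()]), indexed in the
#'   order of the `plddt` profile; reduced per residue before correlating.
#' @param pae_reduce `"row"` (mean of the residue's row, default), `"col"`,
#'   or `"sym"` (mean of row and column means).
#' @param high_min,low_max category band edges (see [score_categories()]).
#' @return a list of class `confidence_report`: `data` (per-residue tibble),
#'   `spearman` (pLDDT vs B), `pearson_pae` (PAE vs B, or `NULL`),
#'   `by_category` (per-category B summaries).
#' @export
confidence_vs_flexibility <- function(plddt, bfac, pae = NULL,
                                      pae_reduce = c("row", "col", "sym"),
                                      high_min = 98.5, low_max = 96.0) {
  pae_reduce <- match.arg(pae_reduce)
  pl <- tibble::as_tibble(plddt)
  if (!is.null(pae)) {
    if (nrow(pae) != nrow(pl)) {
      rlang::abort("PAE size does not match the pLDDT profile")
    }
    pl$pae <- switch(pae_reduce,
      row = rowMeans(pae),
      col = colMeans(pae),
      sym = (rowMeans(pae) + colMeans(pae)) / 2
    )
  }
  data <- dplyr::inner_join(
    pl |> dplyr::rename(plddt = "value"),
    tibble::as_tibble(bfac) |> dplyr::select("residue_id", bfactor = "value"),
    by = "residue_id"
  )
  if (nrow(data) < 3) rlang::abort("fewer than 3 shared residues")
  data$category <- score_categories(data$plddt, high_min, low_max)

  by_category <- data |>
    dplyr::group_by(.data$category, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_bfactor = mean(.data$bfactor),
      median_bfactor = stats::median(.data$bfactor),
      .groups = "drop"
    )

  structure(
    list(
      data = data,
      spearman = spearman_cor(data$plddt, data$bfactor),
      pearson_pae = if (!is.null(pae)) pearson_cor(data$pae, data$bfactor),
      by_category = by_category
    ),
    class = "confidence_report"
  )
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report> %d residues; spearman(pLDDT, B) = %.3f (p = %.3g)\n",
              nrow(x$data), x$spearman$estimate, x$spearman$p.value))
  if (!is.null(x$pearson_pae)) {
    cat(sprintf("  pearson(PAE, B) = %.3f (p = %.3g)\n",
                x$pearson_pae$estimate, x$pearson_pae$p.value))
  }
  print(x$by_category)
  invisible(x)
}

#' @export
tidy.confidence_report <- function(x, ...) x$data

#' @export
glance.confidence_report <- function(x, ...) {
  tibble::tibble(
    spearman_rho = x$spearman$estimate,
    spearman_p = x$spearman$p.value,
    pearson_pae_r = if (is.null(x$pearson_pae)) NA_real_ else x$pearson_pae$estimate,
    pearson_pae_p = if (is.null(x$pearson_pae)) NA_real_ else x$pearson_pae$p.value,
    n = nrow(x$data)
  )
}

#' @export
autoplot.confidence_report <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$plddt, y = .data$bfactor,
                               colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pLDDT", y = expression(B-factor ~ (ring(A)^2))) +
    ggplot2::theme_minimal()
}
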