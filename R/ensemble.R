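#' Pairwise dissimilarity over a structure ensemble
#'
#' Computes every pairwise dissimilarity (superposition RMSD or IRDM metric)
#' over an ensemble. By default all comparisons are restricted to the
#' ensemble-wide common residue set so the matrix is coherent for clustering;
#' `common = "pairwise"` instead uses the residues shared by each pair.
#'
#' @param structures a list of [structure_model()] objects; names become the
#'   labels (unnamed lists use the structures' `id` attributes).
#' @param metric_kind `"rmsd"` or `"irdm"`.
#' @param level comparison level (IRDM is defined on C-alpha only).
#' @param common `"ensemble"` (default) or `"pairwise"` residue selection.
#' @return an object of class `dissimilarity_matrix`: list with `values`
#'   (m x m symmetric matrix, zero diagonal, angstroms), `labels`,
#'   `metric_kind`, `level`.
#' @export
pairwise_dissimilarity <- function(structures,
                                   metric_kind = c("rmsd", "irdm"),
                                   level = c("calpha", "mainchain", "allatom"),
                                   common = c("ensemble", "pairwise")) {
  metric_kind <- match.arg(metric_kind)
  level <- match.arg(level)
  common <- match.arg(common)
  if (metric_kind == "irdm") level <- "calpha"
  m <- length(structures)
  if (m < 2) rlang::abort("at least 2 structures are required")
  labels <- names(structures) %||%
    vapply(structures, function(s) attr(s, "id"), "")
  if (is.null(names(structures))) names(structures) <- labels

  common_ids <- NULL
  if (common == "ensemble") {
    id_sets <- lapply(structures, function(s) residues_with_level(s, level)$residue_id)
    common_ids <- Reduce(intersect, id_sets)
    if (length(common_ids) == 0) rlang::abort("no common residues across the ensemble")
  }

  values <- matrix(0, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- structures[[i]]; b <- structures[[j]]
      map <- build_correspondence(a, b, level)
      if (!is.null(common_ids)) {
        map <- map[map$id_a %in% common_ids, ]
        attr(map, "level") <- level
        class(map) <- c("correspondence_map", class(tibble::tibble()))
        if (nrow(map) == 0) rlang::abort("no common residues across the ensemble")
      }
      v <- if (metric_kind == "rmsd") {
        rmsd_structures(a, b, map)
      } else {
        irdm_compare(distance_matrix(a, map$id_a),
                     distance_matrix(b, map$id_b))$metric
      }
      values[i, j] <- values[j, i] <- v
    }
  }
  structure(
    list(values = values, labels = labels, metric_kind = metric_kind,
         level = level, n_residues = length(common_ids %||% NA_integer_)),
    class = "dissimilarity_matrix"
  )
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d structures, %s/%s\n",
              length(x$labels), x$metric_kind, x$level))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
tidy.dissimilarity_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    item1 = x$labels[idx[, 1]],
    item2 = x$labels[idx[, 2]],
    distance = x$values[idx]
  )
}

#' @export
autoplot.dissimilarity_matrix <- function(object, ...) {
  m <- length(object$labels)
  df <- tidyr::expand_grid(col = seq_len(m), row = seq_len(m))
  df$value <- as.vector(object$values)  # column-major: row varies fastest
  df$item1 <- object$labels[df$row]
  df$item2 <- object$labels[df$col]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$item2, levels = object$labels),
    y = factor(.data$item1, levels = rev(object$labels)),
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = sprintf("%s (Å)", object$metric_kind)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Hierarchical clustering of a structure ensemble
#'
#' Agglomerative clustering on a dissimilarity matrix. Average linkage
#' (UPGMA) is the default; merge heights are in the units of the metric
#' (angstroms).
#'
#' @param d a `dissimilarity_matrix`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an object of class `structure_dendrogram` wrapping the
#'   [stats::hclust()] result (`$hclust`), with `labels`, `linkage` and
#'   `metric_kind`.
#' @export
hcluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dissimilarity_matrix")) {
    if (is.matrix(d)) {
      if (!isSymmetric(unname(d), tol = 1e-8)) rlang::abort("dissimilarity matrix must be symmetric")
      d <- structure(list(values = d,
                          labels = rownames(d) %||% as.character(seq_len(nrow(d))),
                          metric_kind = "unknown", level = "unknown"),
                     class = "dissimilarity_matrix")
    } else rlang::abort("d must be a dissimilarity_matrix or symmetric matrix")
  }
  if (!isSymmetric(unname(d$values), tol = 1e-8)) {
    rlang::abort("dissimilarity matrix must be symmetric")
  }
  hc <- stats::hclust(stats::as.dist(d$values), method = linkage)
  structure(list(hclust = hc, labels = d$labels, linkage = linkage,
                 metric_kind = d$metric_kind),
            class = "structure_dendrogram")
}

#' @export
print.structure_dendrogram <- function(x, ...) {
  cat(sprintf("<structure_dendrogram> %d leaves, %s linkage on %s\n",
              length(x$labels), x$linkage, x$metric_kind))
  invisible(x)
}

#' Cut a structure dendrogram into clusters
#'
#' @param tree a `structure_dendrogram`.
#' @param height cut height in the metric's units (angstroms).
#' @return a tibble with `label` and integer `cluster`.
#' @export
cut_clusters <- function(tree, height) {
  k <- stats::cutree(tree$hclust, h = height)
  tibble::tibble(label = names(k), cluster = unname(k))
}

#' Export a dendrogram as Newick
#'
#' @param tree a `structure_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}

#' Compare predicted-vs-crystal and crystal-vs-crystal dissimilarities
#'
#' Splits a dissimilarity matrix into the m values between one designated
#' member (typically the predicted model) and every other member, and the
#' m(m-1)/2 values among the remaining members, then tests the group means by
#' Welch's t-test.
#'
#' @param d a `dissimilarity_matrix`.
#' @param member label of the designated member.
#' @return a list of class `group_comparison`: `groups` tibble (group, n,
#'   median, mean, sd), `test` (a `cortest_result` tibble from [welch_t()]),
#'   `values` (long tibble of all values with their group).
#' @export
group_comparison <- function(d, member) {
  if (!member %in% d$labels) rlang::abort(paste0("unknown label: ", member))
  i <- match(member, d$labels)
  vs_member <- d$values[i, -i]
  rest <- d$values[-i, -i, drop = FALSE]
  among_rest <- rest[upper.tri(rest)]
  if (length(vs_member) < 2 || length(among_rest) < 2) {
    rlang::abort("both groups need at least 2 values")
  }
  values <- dplyr::bind_rows(
    tibble::tibble(group = paste0(member, "_vs_rest"), value = as.numeric(vs_member)),
    tibble::tibble(group = "rest_vs_rest", value = as.numeric(among_rest))
  )
  groups <- values |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    )
  structure(list(groups = groups,
                 test = welch_t(vs_member, among_rest),
                 values = values),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$groups)
  cat(sprintf("Welch t = %.3f, df = %.2f, p = %.3g\n",
              x$test$statistic, x$test$df, x$test$p.value))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$groups

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$test$statistic, df = x$test$df,
                 p.value = x$test$p.value)
}

#' Test whether an ensemble member is a clustering outlier
#'
#' Cuts the dendrogram at the given height and reports whether the member is
#' alone in its cluster (the null hypothesis of the validation design: a
#' predicted model that were an outlier group would form its own cluster,
#' separate from the crystal structures).
#'
#' @param tree a `structure_dendrogram`.
#' @param member leaf label.
#' @param height cut height (angstroms).
#' @return list with `is_singleton` (logical) and `cluster_members`
#'   (character, co-members including `member`).
#' @export
outlier_test <- function(tree, member, height) {
  if (!member %in% tree$labels) rlang::abort(paste0("unknown label: ", member))
  part <- cut_clusters(tree, height)
  cl <- part$cluster[part$label == member]
  members <- part$label[part$cluster == cl]
  list(is_singleton = length(members) == 1, cluster_members = members)
}

#' Correlation between crystal resolution and deviation from a reference
#'
#' For each crystal structure with a recorded resolution, computes its RMSD
#' to a designated reference structure (excluded from the x/y pairs) and
#' reports the Pearson correlation between resolution and RMSD.
#'
#' @param structures list of crystal [structure_model()]s with `resolution`
#'   attributes.
#' @param reference a [structure_model()] (typically the highest-resolution
#'   member).
#' @param level comparison level.
#' @return a list of class `resolution_correlation`: `data` tibble (label,
#'   resolution, rmsd) and `test` (Pearson `cortest_result`).
#' @export
resolution_correlation <- function(structures, reference,
                                   level = c("calpha", "mainchain", "allatom")) {
  level <- match.arg(level)
  ref_id <- attr(reference, "id")
  labels <- names(structures) %||%
    vapply(structures, function(s) attr(s, "id"), "")
  keep <- labels != ref_id
  structures <- structures[keep]; labels <- labels[keep]
  res <- vapply(structures, function(s) attr(s, "resolution") %||% NA_real_,
                numeric(1))
  ok <- is.finite(res)
  if (sum(ok) < 3) rlang::abort("at least 3 structures with resolution are required")
  structures <- structures[ok]; labels <- labels[ok]; res <- res[ok]
  rmsd <- vapply(structures, function(s) rmsd_structures(s, reference, level = level),
                 numeric(1))
  data <- tibble::tibble(label = labels, resolution = res, rmsd = rmsd)
  structure(list(data = data, test = pearson_cor(res, rmsd)),
            class = "resolution_correlation")
}

#' @export
print.resolution_correlation <- function(x, ...) {
  cat(sprintf("<resolution_correlation> cc = %.3f, p = %.3g over %d structures\n",
              x$test$estimate, x$test$p.value, nrow(x$data)))
  invisible(x)
}

#' @export
tidy.resolution_correlation <- function(x, ...) x$data

#' @export
glance.resolution_correlation <- function(x, ...) x$test

#' @export
autoplot.resolution_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$resolution, y = .data$rmsd)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "resolution (Å)", y = "RMSD to reference (Å)") +
    ggplot2::theme_minimal()
}
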