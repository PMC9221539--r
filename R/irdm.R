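#' Inter-residue distance map (IRDM) of a structure
#'
#' The IRDM of a structure with n residues is the n x n matrix of Euclidean
#' distances between C-alpha atoms. It re-indexes each residue by its
#' distances to all residues, so it is invariant under translation, rotation
#' and reflection of the structure.
#'
#' @param s a [structure_model()].
#' @param ids optional character vector of `residue_id`s
#'   (`chain:resno:icode`, `.` for no insertion code) selecting and ordering
#'   the residues; default all residues with a C-alpha, structure order.
#' @return an object of class `irdm_matrix`: list with `d` (n x n matrix,
#'   angstroms), `residue_ids` and `n`.
#' @export
distance_matrix <- function(s, ids = NULL) {
  ca <- dplyr::filter(tibble::as_tibble(s), .data$elety == "CA") |>
    dplyr::mutate(rid = residue_key(.data$chain, .data$resno, .data$icode))
  if (is.null(ids)) {
    ids <- ca$rid
  } else {
    missing <- setdiff(ids, ca$rid)
    if (length(missing)) {
      rlang::abort(paste0("residues without C-alpha in selection: ",
                          paste(utils::head(missing, 5), collapse = ", "),
                          if (length(missing) > 5) " ..."))
    }
  }
  xyz <- as.matrix(ca[match(ids, ca$rid), c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- NULL
  structure(list(d = d, residue_ids = ids, n = length(ids)),
            class = "irdm_matrix")
}

#' @export
print.irdm_matrix <- function(x, ...) {
  cat(sprintf("<irdm_matrix> %d x %d C-alpha distance map\n", x$n, x$n))
  invisible(x)
}

#' Compare two inter-residue distance maps
#'
#' For aligned maps `d1`, `d2`, each residue i carries the row-difference
#' norm e_i = sqrt(sum_j (d1\[i,j\] - d2\[i,j\])^2): the Euclidean distance
#' between the two re-indexed representations of residue i. The overall
#' dissimilarity is the root mean square of the e_i,
#' `metric = sqrt(mean(e_i^2))`, which equals the Frobenius norm of
#' (d1 - d2) divided by sqrt(n); the element-wise map of absolute differences
#' is returned for heatmap display. All values are in angstroms. Because
#' distance maps are chirality-blind, the metric is zero between a structure
#' and its mirror image.
#'
#' @param d1,d2 `irdm_matrix` objects of equal size with aligned residues
#'   (built on a shared correspondence).
#' @return an object of class `irdm_comparison`: `metric` (angstroms),
#'   `row_profile` (a `residue_profile` tibble of e_i), `diff_map`
#'   (n x n matrix of absolute differences), `n`.
#' @export
irdm_compare <- function(d1, d2) {
  if (!inherits(d1, "irdm_matrix") || !inherits(d2, "irdm_matrix")) {
    rlang::abort("inputs must be irdm_matrix objects")
  }
  if (d1$n != d2$n) rlang::abort("distance maps have different sizes")
  delta <- d1$d - d2$d
  e <- sqrt(rowSums(delta^2))
  metric <- sqrt(mean(e^2))
  parts <- strsplit(d1$residue_ids, ":", fixed = TRUE)
  prof <- tibble::tibble(
    residue_id = d1$residue_ids,
    chain = vapply(parts, `[`, "", 1),
    resno = suppressWarnings(as.integer(vapply(parts, `[`, "", 2))),
    icode = ifelse(vapply(parts, `[`, "", 3) == ".", "",
                   vapply(parts, `[`, "", 3)),
    value = e
  )
  prof <- structure(prof, class = c("residue_profile", class(prof)),
                    label = "irdm_row_distance")
  structure(
    list(metric = metric, row_profile = prof, diff_map = abs(delta), n = d1$n,
         residue_ids = d1$residue_ids),
    class = "irdm_comparison"
  )
}

#' @export
print.irdm_comparison <- function(x, ...) {
  cat(sprintf("<irdm_comparison> metric = %.4f A over %d residues\n",
              x$metric, x$n))
  invisible(x)
}

#' @export
tidy.irdm_comparison <- function(x, ...) {
  tibble::as_tibble(x$row_profile)
}

#' @export
glance.irdm_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, n = x$n,
                 max_row_distance = max(x$row_profile$value))
}

#' IRDM dissimilarity between two structures
#'
#' Convenience wrapper: builds a C-alpha correspondence, computes both
#' distance maps on the common residues and returns the comparison.
#'
#' @param a,b [structure_model()] objects.
#' @param map optional precomputed correspondence map (C-alpha level).
#' @return an `irdm_comparison`.
#' @export
irdm_structures <- function(a, b, map = NULL) {
  if (is.null(map)) map <- build_correspondence(a, b, "calpha")
  irdm_compare(distance_matrix(a, map$id_a), distance_matrix(b, map$id_b))
}

#' Heatmap of an IRDM difference map
#'
#' @param object an `irdm_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.irdm_comparison <- function(object, ...) {
  df <- tidyr::expand_grid(j = seq_len(object$n), i = seq_len(object$n))
  df$delta <- as.vector(object$diff_map)  # column-major: i varies fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$delta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|Δd| (Å)") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "residue j", y = "residue i") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.residue_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$resno, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue number", y = attr(object, "label")) +
    ggplot2::theme_minimal()
}
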