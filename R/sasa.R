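# Bondi-style van der Waals radii (angstroms) by element symbol
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
  H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  ZN = 1.39, FE = 1.40, MG = 1.73, MN = 1.40, CA = 2.31, "NA" = 2.27, K = 2.75
)

# Deterministic quasi-uniform points on the unit sphere (golden spiral);
# no randomness, so SASA values are reproducible bit-for-bit.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere is inflated by the probe radius and covered with a
#' deterministic golden-spiral point set; a point is accessible when it lies
#' outside every neighbouring atom's inflated sphere. The accessible fraction
#' times the inflated-sphere area gives the per-atom SASA.
#'
#' @param s a [structure_model()] (or a data frame with `element`, `x`, `y`,
#'   `z` columns); heavy atoms only are expected.
#' @param probe probe radius in angstroms (water: 1.4).
#' @param n_points sphere sample count per atom.
#' @return an object of class `sasa_result`: `per_atom` (tibble with the atom
#'   columns plus `radius` and `area`), `total` (square angstroms), `probe`,
#'   `n_points`.
#' @export
shrake_rupley <- function(s, probe = 1.4, n_points = 960) {
  at <- tibble::as_tibble(s)
  if (nrow(at) == 0) rlang::abort("no atoms")
  unknown <- setdiff(unique(at$element), names(VDW_RADII))
  if (length(unknown)) {
    rlang::abort(paste0("no van der Waals radius for element(s): ",
                        paste(unknown, collapse = ", ")))
  }
  r <- unname(VDW_RADII[at$element]) + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)

  # neighbour lists from the pairwise distance matrix (inflated spheres touch)
  dmat <- as.matrix(stats::dist(xyz))
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < r[i] + r & seq_len(n) != i)
    p_i <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      occluded <- rep(FALSE, n_points)
      for (j in nb) {
        dx <- p_i[, 1] - xyz[j, 1]
        dy <- p_i[, 2] - xyz[j, 2]
        dz <- p_i[, 3] - xyz[j, 3]
        occluded <- occluded | (dx * dx + dy * dy + dz * dz < r[j]^2)
        if (all(occluded)) break
      }
      acc <- sum(!occluded)
    } else {
      acc <- n_points
    }
    area[i] <- acc / n_points * 4 * pi * r[i]^2
  }
  at$radius <- r - probe
  at$area <- area
  structure(list(per_atom = at, total = sum(area), probe = probe,
                 n_points = n_points, radii_set = "bondi"),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total = %.1f A^2 over %d atoms (probe %.1f, %d points)\n",
              x$total, nrow(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' @export
tidy.sasa_result <- function(x, ...) x$per_atom

#' @export
glance.sasa_result <- function(x, ...) {
  tibble::tibble(total = x$total, n_atoms = nrow(x$per_atom),
                 probe = x$probe, n_points = x$n_points)
}

#' Solvent-accessible surface area buried between two residue groups
#'
#' The buried interface area is `SASA(A alone) + SASA(B alone) -
#' SASA(A and B together)`. Atoms outside the two groups are excluded from
#' all three computations, so the value reflects the pairwise interface
#' between the groups themselves; pass `context = TRUE` to keep the rest of
#' the structure present in every computation instead.
#'
#' @param s a [structure_model()].
#' @param group_a,group_b disjoint character vectors of `residue_id`s
#'   (`chain:resno:icode`, `.` for no insertion code).
#' @param probe probe radius (angstroms).
#' @param n_points sphere sample count.
#' @param context keep atoms outside the groups in all three computations.
#' @return a list of class `buried_area`: `buried` (square angstroms),
#'   `sasa_a`, `sasa_b`, `sasa_ab` totals, plus the call parameters.
#' @export
buried_interface_area <- function(s, group_a, group_b, probe = 1.4,
                                  n_points = 960, context = FALSE) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    rlang::abort("both groups must be nonempty")
  }
  if (length(intersect(group_a, group_b))) {
    rlang::abort("groups must be disjoint")
  }
  at <- tibble::as_tibble(s) |>
    dplyr::mutate(rid = residue_key(.data$chain, .data$resno, .data$icode))
  missing <- setdiff(c(group_a, group_b), at$rid)
  if (length(missing)) {
    rlang::abort(paste0("residue id(s) not in structure: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  in_a <- at$rid %in% group_a
  in_b <- at$rid %in% group_b
  base <- if (context) rep(TRUE, nrow(at)) else (in_a | in_b)
  total <- function(sel) shrake_rupley(at[sel, ], probe, n_points)$total
  sasa_a <- total(base & !in_b)
  sasa_b <- total(base & !in_a)
  sasa_ab <- total(base)
  structure(
    list(buried = sasa_a + sasa_b - sasa_ab,
         sasa_a = sasa_a, sasa_b = sasa_b, sasa_ab = sasa_ab,
         probe = probe, n_points = n_points, context = context),
    class = "buried_area"
  )
}

#' @export
print.buried_area <- function(x, ...) {
  cat(sprintf(
    "<buried_area> %.1f A^2 buried (A alone %.1f + B alone %.1f - together %.1f)\n",
    x$buried, x$sasa_a, x$sasa_b, x$sasa_ab))
  invisible(x)
}

#' @export
glance.buried_area <- function(x, ...) {
  tibble::tibble(buried = x$buried, sasa_a = x$sasa_a, sasa_b = x$sasa_b,
                 sasa_ab = x$sasa_ab, probe = x$probe, n_points = x$n_points)
}
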