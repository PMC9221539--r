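#' Ideal alpha-helical C-alpha trace
#'
#' Places n C-alpha atoms on the canonical helix: rise 1.5 angstroms per
#' residue, 100 degrees rotation per residue, radius 2.3 angstroms. This
#' yields the familiar ~3.8 angstrom consecutive C-alpha spacing and ~6.2
#' angstrom i, i+4 contacts.
#'
#' @param n number of residues (>= 4).
#' @param chain chain identifier.
#' @param id structure id.
#' @return a [structure_model()] with one CA atom per residue (ALA).
#' @export
build_helix <- function(n, chain = "A", id = "helix") {
  if (n < 4) rlang::abort("a helix needs at least 4 residues")
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  structure_model(
    tibble::tibble(
      chain = chain, resno = seq_len(n), icode = "", resid = "ALA",
      elety = "CA", element = "C",
      x = 2.3 * cos(theta), y = 2.3 * sin(theta), z = 1.5 * i,
      occupancy = 1, b = 0, altloc = ""
    ),
    id = id, source = "crystal"
  )
}

#' Self-avoiding random-coil C-alpha trace
#'
#' A seeded random walk with fixed 3.8 angstrom steps and a mild
#' direction-persistence bias; adequate geometry for metric tests, not a
#' physical backbone.
#'
#' @param n residues.
#' @param chain,id as in [build_helix()].
#' @return a [structure_model()].
#' @export
build_coil <- function(n, chain = "A", id = "coil") {
  if (n < 2) rlang::abort("need at least 2 residues")
  xyz <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    step <- dir + stats::rnorm(3, sd = 0.6)
    dir <- step / sqrt(sum(step^2))
    xyz[i, ] <- xyz[i - 1, ] + 3.8 * dir
  }
  structure_model(
    tibble::tibble(
      chain = chain, resno = seq_len(n), icode = "", resid = "ALA",
      elety = "CA", element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b = 0, altloc = ""
    ),
    id = id, source = "crystal"
  )
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  r <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

#' Apply a rigid motion to a structure
#'
#' @param s a [structure_model()].
#' @param rotation 3 x 3 proper rotation (default: seeded random).
#' @param translation length-3 vector (angstroms).
#' @return the transformed structure.
#' @export
rigid_transform <- function(s, rotation = NULL, translation = c(0, 0, 0)) {
  rotation <- rotation %||% random_rotation()
  xyz <- as.matrix(tibble::as_tibble(s)[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  out <- tibble::as_tibble(s)
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  structure_model(out, id = attr(s, "id"), source = attr(s, "source"),
                  resolution = attr(s, "resolution"),
                  space_group = attr(s, "space_group"))
}

#' Mirror a structure (improper transform)
#'
#' Negates the x coordinate: useful for demonstrating that distance-map
#' metrics are chirality-blind while superposition RMSD is not.
#'
#' @param s a [structure_model()].
#' @return the mirrored structure.
#' @export
mirror_structure <- function(s) {
  out <- tibble::as_tibble(s)
  out$x <- -out$x
  structure_model(out, id = attr(s, "id"), source = attr(s, "source"))
}

default_plddt_rule <- function(sigma) {
  pmin(pmax(100 - 40 * sigma / (max(sigma) + 1e-9), 50), 100)
}

#' Generate a synthetic structure ensemble with known ground truth
#'
#' Emulates the variability of a crystal-structure ensemble (different
#' crystallization conditions / lattices) by adding iid Gaussian noise to a
#' base C-alpha geometry: each member is the base plus a per-residue,
#' per-coordinate displacement of standard deviation sigma_i, optionally
#' followed by a random rigid motion. Ground-truth tracks follow the
#' crystallographic relations: B_i = 8 pi^2 sigma_i^2, and pLDDT_i is a
#' monotone decreasing map of sigma_i into \[50, 100\]. Under iid noise the
#' expected member-vs-base superposition RMSD is about sqrt(3) * sigma.
#'
#' @param n_residues residues in the base geometry.
#' @param n_members ensemble members.
#' @param sigma per-coordinate noise s.d. in angstroms: a scalar, a length
#'   `n_residues` vector, or a length `n_members` list/vector giving one
#'   scalar per member (planted groups).
#' @param geometry `"ideal_helix"`, `"random_coil"` or `"mixed"` (helix with
#'   a coil tail).
#' @param rigid_motions apply a random rigid motion to each member.
#' @param group_offset optional numeric vector (one value per member) of a
#'   hinge-like conformational change: the second half of the chain is
#'   shifted by this many angstroms along x *before* noise and rigid motion.
#'   Unlike a whole-body shift (which superposition removes), this changes
#'   the shape, so members sharing an offset form a planted cluster.
#' @param include_predicted also emit an unperturbed member with
#'   `source = "predicted"` whose B column carries the pLDDT track.
#' @param seed integer seed; identical arguments and seed give identical
#'   output.
#' @return list of class `synthetic_ensemble`: `structures` (named list;
#'   members `m1..mk` and optionally `pred`), `base` (the unperturbed
#'   geometry), `truth` (tibble: `resno`, `sigma`, `bfactor`, `plddt`),
#'   `member_sigma` (scalar sigma per member).
#' @export
make_ensemble <- function(n_residues = 100, n_members = 5, sigma = 0.3,
                          geometry = c("ideal_helix", "random_coil", "mixed"),
                          rigid_motions = TRUE, group_offset = NULL,
                          include_predicted = FALSE, seed = 1L) {
  geometry <- match.arg(geometry)
  if (any(unlist(sigma) < 0)) rlang::abort("sigma must be >= 0")
  set.seed(seed)

  base <- switch(geometry,
    ideal_helix = build_helix(n_residues, id = "base"),
    random_coil = build_coil(n_residues, id = "base"),
    mixed = {
      h <- build_helix(ceiling(n_residues / 2), id = "base")
      cl <- build_coil(n_residues - ceiling(n_residues / 2), id = "tail")
      ct <- tibble::as_tibble(cl)
      hend <- tibble::as_tibble(h)[nrow(tibble::as_tibble(h)), c("x", "y", "z")]
      ct$x <- ct$x + hend$x + 3.8; ct$y <- ct$y + hend$y; ct$z <- ct$z + hend$z
      ct$resno <- ct$resno + ceiling(n_residues / 2)
      structure_model(dplyr::bind_rows(tibble::as_tibble(h), ct),
                      id = "base", source = "crystal")
    }
  )

  per_member <- is.list(sigma) || length(sigma) == n_members
  sigma_profile <- function(k) {
    sg <- if (per_member) rep_len(unlist(sigma)[k], n_residues)
          else rep_len(sigma, n_residues)
    sg
  }
  member_sigma <- vapply(seq_len(n_members),
                         function(k) mean(sigma_profile(k)), numeric(1))

  xyz0 <- as.matrix(tibble::as_tibble(base)[, c("x", "y", "z")])
  structures <- list()
  for (k in seq_len(n_members)) {
    sg <- sigma_profile(k)
    noise <- matrix(stats::rnorm(3 * n_residues, sd = rep(sg, 3)),
                    n_residues, 3)
    xyz <- xyz0 + noise
    if (!is.null(group_offset) && group_offset[k] != 0) {
      hinge <- xyz0[, 3] > stats::median(xyz0[, 3])
      xyz[hinge, 1] <- xyz[hinge, 1] + group_offset[k]
    }
    at <- tibble::as_tibble(base)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at$b <- 8 * pi^2 * sg^2
    m <- structure_model(at, id = paste0("m", k), source = "crystal")
    if (rigid_motions) {
      m <- rigid_transform(m, random_rotation(),
                           stats::rnorm(3, sd = 10))
    }
    structures[[paste0("m", k)]] <- m
  }

  truth_sigma <- if (per_member) rep(mean(member_sigma), n_residues)
                 else rep_len(sigma, n_residues)
  truth <- tibble::tibble(
    resno = seq_len(n_residues),
    sigma = truth_sigma,
    bfactor = 8 * pi^2 * truth_sigma^2,
    plddt = default_plddt_rule(truth_sigma)
  )

  if (include_predicted) {
    at <- tibble::as_tibble(base)
    at$b <- truth$plddt
    structures[["pred"]] <- structure_model(at, id = "pred", source = "predicted")
  }

  structure(
    list(structures = structures, base = base, truth = truth,
         member_sigma = member_sigma, seed = seed, geometry = geometry),
    class = "synthetic_ensemble"
  )
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf("<synthetic_ensemble> %d members x %d residues (%s), seed %d\n",
              length(x$structures), nrow(x$truth), x$geometry, x$seed))
  invisible(x)
}

#' Write a synthetic ensemble to PDB files plus a ground-truth TSV
#'
#' @param ens a `synthetic_ensemble`.
#' @param dir output directory (created if needed).
#' @return tibble of written paths, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(ens$structures, function(s, nm) {
    p <- file.path(dir, paste0(nm, ".pdb"))
    write_structure(s, p)
    p
  })
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(ens$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tibble::tibble(name = c(names(paths), "truth"),
                           path = c(unname(paths), truth_path)))
}
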