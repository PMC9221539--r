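# Shared fixtures and independent oracles, all built in code.

toy_structure <- function(xyz, chain = "A", resid = "ALA", elety = "CA",
                          element = "C", b = 0, id = "toy",
                          source = "crystal", resno = NULL) {
  xyz <- as.matrix(xyz)
  structure_model(
    tibble::tibble(
      chain = chain, resno = resno %||% seq_len(nrow(xyz)), icode = "",
      resid = resid, elety = elety, element = element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b = b, altloc = ""
    ),
    id = id, source = source
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coords_of <- function(s) as.matrix(tibble::as_tibble(s)[, c("x", "y", "z")])

# Independent RMSD oracle: brute-force minimization over a quaternion grid
# (seeded uniform sample with staged refinement), using the trace identity
# rmsd^2 = (|p0|^2 + |q0|^2 - 2 tr(R H)) / n -- no SVD anywhere.
quat_to_rotvec <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

grid_rmsd <- function(p, q, n_coarse = 200000, n_refine = 50000) {
  p0 <- sweep(p, 2, colMeans(p)); q0 <- sweep(q, 2, colMeans(q))
  h <- crossprod(q0, p0)
  hv <- as.vector(t(h))
  sp <- sum(p0^2); sq <- sum(q0^2); n <- nrow(p)
  set.seed(42)
  qs <- matrix(stats::rnorm(4 * n_coarse), ncol = 4)
  qs <- qs / sqrt(rowSums(qs^2))
  best <- qs[which.max(quat_to_rotvec(qs) %*% hv), ]
  for (scale in c(0.05, 0.005, 5e-4, 5e-5)) {
    cand <- matrix(stats::rnorm(4 * n_refine, sd = scale), ncol = 4)
    cand <- sweep(cand, 2, best, "+")
    cand <- cand / sqrt(rowSums(cand^2))
    cand <- rbind(best, cand)
    best <- cand[which.max(quat_to_rotvec(cand) %*% hv), ]
  }
  tr <- as.numeric(quat_to_rotvec(matrix(best, 1)) %*% hv)
  sqrt(max((sp + sq - 2 * tr) / n, 0))
}

# Brute-force PROSITE checker: tests the pattern element list window by
# window, no regular expressions.
brute_scan <- function(pattern, sq) {
  pat <- sub("\\.$", "", trimws(pattern))
  elements <- strsplit(pat, "-", fixed = TRUE)[[1]]
  make_matcher <- function(el) {
    if (el %in% c("x", "X")) {
      function(ch) TRUE
    } else if (startsWith(el, "[")) {
      allowed <- strsplit(substr(el, 2, nchar(el) - 1), "")[[1]]
      function(ch) ch %in% allowed
    } else if (startsWith(el, "{")) {
      banned <- strsplit(substr(el, 2, nchar(el) - 1), "")[[1]]
      function(ch) !(ch %in% banned)
    } else {
      function(ch) ch == el
    }
  }
  expanded <- list()
  for (el in elements) {
    m <- regmatches(el, regexec("^(.*)\\((\\d+)(,(\\d+))?\\)$", el))[[1]]
    reps <- 1L
    if (length(m)) {
      stopifnot(!nzchar(m[5]))  # brute oracle handles fixed repeats only
      el <- m[2]; reps <- as.integer(m[3])
    }
    matcher <- make_matcher(el)
    for (r in seq_len(reps)) expanded[[length(expanded) + 1]] <- matcher
  }
  L <- length(expanded)
  chars <- strsplit(toupper(sq), "")[[1]]
  hits <- integer(0)
  for (start in seq_len(max(length(chars) - L + 1, 0))) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!expanded[[k]](chars[start + k - 1])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

# Minimal fixed-column PDB text for a 3-residue C-alpha trace (b = 20), with
# header metadata, written at test time.
write_mini_pdb <- function(path, altloc_block = FALSE) {
  lines <- c(
    "HEADER    TEST PROTEIN                            01-JAN-20   XXXX",
    "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.",
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 21 21 21    4"
  )
  atom_line <- function(serial, name, alt, resno, x, y, z, occ, b) {
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, name, alt, "ALA", "A", resno, x, y, z, occ, b)
  }
  if (altloc_block) {
    lines <- c(lines,
      atom_line(1, "CA", "A", 1, 0, 0, 0, 0.60, 20),
      atom_line(2, "CA", "B", 1, 5, 0, 0, 0.40, 20),
      atom_line(3, "CA", " ", 2, 3.8, 0, 0, 1, 20),
      atom_line(4, "CA", " ", 3, 7.6, 0, 0, 1, 20))
  } else {
    lines <- c(lines,
      atom_line(1, "CA", " ", 1, 0, 0, 0, 1, 20),
      atom_line(2, "CA", " ", 2, 3.8, 0, 0, 1, 20),
      atom_line(3, "CA", " ", 3, 7.6, 0, 0, 1, 20))
  }
  writeLines(c(lines, "END"), path)
  path
}

# The same 3-residue content as an mmCIF atom_site loop.
write_mini_cif <- function(path) {
  writeLines(c(
    "data_mini",
    "_refine.ls_d_res_high  1.50",
    "_symmetry.space_group_name_H-M  'P 21 21 21'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 20.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . ALA A 1 2 ? 3.800 0.000 0.000 1.00 20.00 ? 2 ALA A CA 1",
    "ATOM 3 C CA . ALA A 1 3 ? 7.600 0.000 0.000 1.00 20.00 ? 3 ALA A CA 1"
  ), path)
  path
}

# PAE JSON writers for the two public AlphaFold DB dialects.
write_pae_dialect_a <- function(path, mat) {
  n <- nrow(mat)
  idx <- expand.grid(r2 = seq_len(n), r1 = seq_len(n))  # r2 varies fastest
  obj <- list(list(
    residue1 = idx$r1, residue2 = idx$r2,
    distance = mat[cbind(idx$r1, idx$r2)],
    max_predicted_aligned_error = max(mat)
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

write_pae_dialect_b <- function(path, mat) {
  obj <- list(list(
    predicted_aligned_error = apply(mat, 1, identity, simplify = FALSE),
    max_predicted_aligned_error = max(mat)
  ))
  obj[[1]]$predicted_aligned_error <- lapply(seq_len(nrow(mat)),
                                             function(i) mat[i, ])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}
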