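#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

#' Construct a structure model from an atom table
#'
#' The central container of the package: a tibble with one row per atom and a
#' `structure_model` class carrying structure-level metadata as attributes.
#' Columns: `chain`, `resno`, `icode`, `resid` (3-letter residue name),
#' `elety` (atom name), `element`, `x`, `y`, `z`, `occupancy`, `b`
#' (crystallographic B-factor in squared angstroms, or pLDDT on 0-100 for
#' predicted models) and `altloc`.
#'
#' @param atoms data frame with the columns above (missing `icode`,
#'   `occupancy`, `altloc`, `element` are filled with defaults).
#' @param id structure identifier string.
#' @param source `"crystal"` or `"predicted"`.
#' @param resolution resolution in angstroms, or `NA` (predicted models carry
#'   none).
#' @param space_group space-group symbol, or `NA`.
#' @return a `structure_model` tibble.
#' @export
structure_model <- function(atoms, id = "model", source = c("crystal", "predicted"),
                            resolution = NA_real_, space_group = NA_character_) {
  source <- match.arg(source)
  atoms <- as_tibble(atoms)
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$elety)
  }
  needed <- c("chain", "resno", "icode", "resid", "elety", "element",
              "x", "y", "z", "occupancy", "b", "altloc")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  atoms <- atoms[needed]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  atoms <- arrange(atoms, .data$chain, .data$resno, .data$icode)
  if (source == "predicted") {
    resolution <- NA_real_
    space_group <- NA_character_
  }
  structure(atoms,
    class = c("structure_model", class(atoms)),
    id = id, source = source,
    resolution = resolution, space_group = space_group
  )
}

guess_element <- function(elety) {
  e <- sub("^[0-9']*", "", elety)
  two <- toupper(substr(e, 1, 2))
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &
           nchar(elety) == 4, # 4-char names start in col 13; 2-letter elements
         two, toupper(substr(e, 1, 1)))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %s (%s)%s%s: %d atoms, %d residues\n",
    attr(x, "id"), attr(x, "source"),
    if (is.na(attr(x, "resolution"))) "" else sprintf(", %.2f A", attr(x, "resolution")),
    if (is.na(attr(x, "space_group"))) "" else sprintf(", %s", attr(x, "space_group")),
    nrow(x), nrow(residues(x))
  ))
  NextMethod()
}

#' Residue table of a structure
#'
#' @param s a `structure_model`.
#' @return tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `resid`, and a unique `residue_id` string `chain:resno:icode`.
#' @export
residues <- function(s) {
  distinct(as_tibble(s), .data$chain, .data$resno, .data$icode, .data$resid) |>
    mutate(residue_id = residue_key(.data$chain, .data$resno, .data$icode))
}

residue_key <- function(chain, resno, icode) {
  paste(chain, resno, ifelse(is.na(icode) | icode == "", ".", icode), sep = ":")
}

#' Read a coordinate file into a structure model
#'
#' Reads PDB (fixed-column) or mmCIF files via bio3d, keeping model 1 only.
#' Hydrogens, waters and hetero residues are dropped; when an atom has several
#' alternate locations the highest-occupancy conformer is kept (ties broken by
#' file order). Resolution and space group are parsed from the header when
#' present.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param source `"crystal"`, `"predicted"`, or `"auto"`: with `"auto"` a file
#'   without a recorded resolution whose B-factor column lies in \[0, 100\] is
#'   taken as a predicted model (the AlphaFold DB convention stores pLDDT
#'   there).
#' @param id identifier for the structure (default: file name without
#'   extension).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source = c("auto", "crystal", "predicted"),
                           id = NULL) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) abort(paste0("cannot parse ", path, " as ", format, ": ",
                                     conditionMessage(e)))
  )
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) abort(paste0("empty model in ", path))

  at <- at |>
    mutate(
      element = ifelse(is.na(.data$elesy) | .data$elesy == "",
                       guess_element(.data$elety), toupper(.data$elesy)),
      alt = ifelse(is.na(.data$alt), "", .data$alt),
      insert = ifelse(is.na(.data$insert), "", .data$insert),
      o = ifelse(is.na(.data$o), 1, .data$o)
    ) |>
    filter(.data$type == "ATOM",
           .data$element != "H", .data$element != "D",
           !.data$resid %in% c("HOH", "WAT", "DOD"),
           .data$resid %in% STANDARD_AA)
  if (nrow(at) == 0) abort(paste0("no protein atoms in ", path))

  # altloc policy: keep the highest-occupancy conformer, ties -> first in file
  at <- at |>
    mutate(.row = seq_len(n())) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(desc(.data$o), .data$.row, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$.row)

  meta <- read_structure_header(path, format)
  if (source == "auto") {
    source <- if (is.na(meta$resolution) &&
                  all(at$b >= 0 & at$b <= 100, na.rm = TRUE)) "predicted" else "crystal"
  }
  structure_model(
    tibble(
      chain = at$chain, resno = at$resno, icode = at$insert, resid = at$resid,
      elety = at$elety, element = at$element,
      x = at$x, y = at$y, z = at$z,
      occupancy = at$o, b = at$b, altloc = at$alt
    ),
    id = id %||% sub("\\.[^.]*$", "", basename(path)),
    source = source,
    resolution = meta$resolution, space_group = meta$space_group
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_structure_header <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  resolution <- NA_real_
  space_group <- NA_character_
  if (format == "pdb") {
    rl <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(rl)) {
      m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
      if (length(m)) resolution <- as.numeric(m)
    }
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr) && nchar(cr[1]) >= 56) {
      sg <- trimws(substr(cr[1], 56, 66))
      if (nzchar(sg)) space_group <- sg
    }
  } else {
    for (key in c("_refine.ls_d_res_high", "_reflns.d_resolution_high")) {
      rl <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
      if (length(rl)) {
        v <- suppressWarnings(as.numeric(trimws(sub(key, "", rl[1], fixed = TRUE))))
        if (is.finite(v)) { resolution <- v; break }
      }
    }
    sl <- grep("^_symmetry\\.space_group_name_H-M\\s", lines, value = TRUE)
    if (length(sl)) {
      sg <- gsub("['\"]", "", trimws(sub("^\\S+\\s+", "", sl[1])))
      if (nzchar(sg)) space_group <- sg
    }
  }
  list(resolution = resolution, space_group = space_group)
}

#' Write a structure model to a PDB file
#'
#' Coordinates are written in the fixed-column PDB convention (3 decimals);
#' crystal metadata is not re-emitted beyond a resolution REMARK when present.
#'
#' @param s a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  xyz <- as.vector(t(as.matrix(as_tibble(s)[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = s$resno, resid = s$resid, chain = s$chain,
    insert = ifelse(s$icode == "", "", s$icode),
    elety = s$elety, o = s$occupancy, b = s$b,
    elesy = s$element
  )
  if (!is.na(attr(s, "resolution"))) {
    lines <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                         attr(s, "resolution")), lines), path)
  }
  invisible(path)
}

level_atoms <- function(level) {
  switch(level,
    calpha = "CA",
    mainchain = c("N", "CA", "C", "O"),
    allatom = NULL,
    abort(paste0("unknown level: ", level))
  )
}

#' Establish residue correspondence between two structures
#'
#' Residues are matched by author numbering `(chain, resno, icode)`; this is
#' the convention under which AlphaFold DB models (UniProt numbering) line up
#' with PDB author numbering. Pairs are restricted to residues that carry all
#' atoms the comparison level demands (for `allatom`, at least one heavy atom
#' name in common). Residue-name mismatches (e.g. crystal-construct mutations)
#' are retained but flagged in the `name_mismatch` column.
#'
#' @param a,b [structure_model()] objects.
#' @param level `"calpha"`, `"mainchain"` or `"allatom"`.
#' @param chain_map optional named character vector mapping chains of `a` to
#'   chains of `b`, e.g. `c(A = "B")`.
#' @return a tibble of class `correspondence_map` with columns `id_a`, `id_b`,
#'   `resid_a`, `resid_b`, `name_mismatch`, ordered as in `a`, and a `level`
#'   attribute.
#' @export
build_correspondence <- function(a, b, level = c("calpha", "mainchain", "allatom"),
                                 chain_map = NULL) {
  level <- match.arg(level)
  ra <- residues_with_level(a, level)
  rb <- residues_with_level(b, level)
  if (!is.null(chain_map)) {
    ra <- mutate(ra, match_chain = dplyr::coalesce(
      unname(chain_map[.data$chain]), .data$chain))
  } else {
    ra <- mutate(ra, match_chain = .data$chain)
  }
  pairs <- inner_join(
    ra |> select(chain_a = "chain", "match_chain", resno_a = "resno",
                 icode_a = "icode", resid_a = "resid", id_a = "residue_id"),
    rb |> select(match_chain = "chain", resno_b = "resno",
                 icode_b = "icode", resid_b = "resid", id_b = "residue_id"),
    by = c("match_chain" = "match_chain", "resno_a" = "resno_b",
           "icode_a" = "icode_b")
  )
  if (nrow(pairs) == 0) abort("no common residues")
  pairs <- pairs |>
    transmute(.data$id_a, .data$id_b, .data$resid_a, .data$resid_b,
              name_mismatch = .data$resid_a != .data$resid_b)
  if (any(pairs$name_mismatch)) {
    warn(sprintf("%d residue-name mismatch(es) retained (e.g. %s vs %s)",
                 sum(pairs$name_mismatch),
                 pairs$resid_a[pairs$name_mismatch][1],
                 pairs$resid_b[pairs$name_mismatch][1]))
  }
  structure(pairs, class = c("correspondence_map", class(pairs)), level = level)
}

residues_with_level <- function(s, level) {
  need <- level_atoms(level)
  res <- residues(s)
  if (is.null(need)) return(res)  # allatom: common names handled at stacking
  have <- as_tibble(s) |>
    filter(.data$elety %in% need) |>
    group_by(.data$chain, .data$resno, .data$icode) |>
    summarise(n_have = dplyr::n_distinct(.data$elety), .groups = "drop") |>
    filter(.data$n_have == length(need))
  semi_join(res, have, by = c("chain", "resno", "icode"))
}

# Stack paired coordinates of two structures at the map's level.
# Returns N x 3 matrices p, q in map order, plus per-row residue index (into
# the map) for per-residue reductions. For allatom, heavy atoms common by
# name within each residue pair are used.
matched_coords <- function(a, b, map) {
  level <- attr(map, "level")
  need <- level_atoms(level)
  ta <- as_tibble(a) |>
    mutate(rid = residue_key(.data$chain, .data$resno, .data$icode))
  tb <- as_tibble(b) |>
    mutate(rid = residue_key(.data$chain, .data$resno, .data$icode))
  if (!is.null(need)) {
    ta <- filter(ta, .data$elety %in% need)
    tb <- filter(tb, .data$elety %in% need)
  }
  key <- tibble(id_a = map$id_a, id_b = map$id_b, residue_index = seq_len(nrow(map)))
  joined <- key |>
    inner_join(ta |> select(id_a = "rid", "elety", xa = "x", ya = "y", za = "z"),
               by = "id_a", relationship = "many-to-many") |>
    inner_join(tb |> select(id_b = "rid", "elety", xb = "x", yb = "y", zb = "z"),
               by = c("id_b", "elety")) |>
    arrange(.data$residue_index, .data$elety)
  if (nrow(joined) == 0) abort("no common atoms at this level")
  list(
    p = as.matrix(joined[, c("xa", "ya", "za")]),
    q = as.matrix(joined[, c("xb", "yb", "zb")]),
    residue_index = joined$residue_index,
    atom_name = joined$elety
  )
}

#' Extract a per-residue scalar profile from the B-factor column
#'
#' The per-residue value is the temperature factor of the C-alpha atom: the
#' crystallographic B-factor for crystal structures, or the pLDDT confidence
#' score for predicted models (stored in the B-factor column by convention).
#'
#' @param s a [structure_model()].
#' @param what `"bfactor"` or `"plddt"`. For `"plddt"` values must lie in
#'   \[0, 100\]; supplying a crystal structure whose B-factors happen to fall
#'   in that range is accepted and is the caller's responsibility.
#' @return a tibble of class `residue_profile`: `residue_id`, `chain`,
#'   `resno`, `icode`, `value`, with a `label` attribute.
#' @export
extract_profile <- function(s, what = c("bfactor", "plddt")) {
  what <- match.arg(what)
  res <- residues(s)
  ca <- as_tibble(s) |> filter(.data$elety == "CA")
  prof <- left_join(res, ca |> select("chain", "resno", "icode", value = "b"),
                    by = c("chain", "resno", "icode"))
  if (anyNA(prof$value)) {
    warn(sprintf("%d residue(s) without C-alpha skipped", sum(is.na(prof$value))))
    prof <- filter(prof, !is.na(.data$value))
  }
  if (what == "plddt" && (any(prof$value < 0) || any(prof$value > 100))) {
    abort("B-factor column outside [0, 100]: not a pLDDT-annotated model")
  }
  out <- prof |> select("residue_id", "chain", "resno", "icode", "value")
  structure(out, class = c("residue_profile", class(out)), label = what)
}

#' Write a residue profile as two-column TSV
#'
#' @param profile a `residue_profile` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(residue = profile$residue_id, value = profile$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read an AlphaFold predicted-aligned-error (PAE) matrix from JSON
#'
#' Both public AlphaFold DB dialects are supported: the flat paired-index form
#' (`residue1`/`residue2`/`distance` arrays) and the nested row-list form
#' (`predicted_aligned_error`). Entries are in angstroms; the matrix need not
#' be symmetric.
#'
#' @param path JSON file path.
#' @return an n x n numeric matrix.
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  # AF DB files wrap the payload in a one-element array
  if (is.null(names(js)) && length(js) >= 1 && is.list(js[[1]])) js <- js[[1]]
  if (!is.null(js[["predicted_aligned_error"]])) {
    rows <- js[["predicted_aligned_error"]]
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) abort("ragged PAE rows")
    pae <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
    if (nrow(pae) != ncol(pae)) abort("PAE matrix is not square")
  } else if (!is.null(js[["residue1"]])) {
    r1 <- unlist(js[["residue1"]]); r2 <- unlist(js[["residue2"]])
    d <- as.numeric(unlist(js[["distance"]]))
    if (length(r1) != length(r2) || length(r1) != length(d)) {
      abort("inconsistent lengths in paired-index PAE file")
    }
    n <- max(r1, r2)
    if (length(d) != n * n) abort("paired-index PAE does not fill a square matrix")
    pae <- matrix(NA_real_, n, n)
    pae[cbind(r1, r2)] <- d
    if (anyNA(pae)) abort("paired-index PAE leaves missing entries")
  } else {
    abort("unrecognized PAE JSON dialect")
  }
  storage.mode(pae) <- "double"
  if (any(pae < 0)) abort("negative PAE entries")
  unname(pae)
}
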