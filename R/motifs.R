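#' Convert a PROSITE-syntax pattern to a regular expression
#'
#' Supports the core PROSITE syntax: single residue letters, `x` for any
#' residue, `[ABC]` alternatives, `{ABC}` exclusions, element repetition
#' `(n)` or `(n,m)`, `<` (N-terminal anchor) and `>` (C-terminal anchor),
#' with elements separated by `-` and an optional trailing `.`.
#'
#' @param pattern PROSITE pattern string, e.g. `"P-x-L-x-P"`.
#' @return a single regular expression string.
#' @export
prosite_to_regex <- function(pattern) {
  pat <- sub("\\.$", "", trimws(pattern))
  if (!nzchar(pat)) rlang::abort("empty pattern")
  anchored_start <- startsWith(pat, "<")
  anchored_end <- endsWith(pat, ">")
  if (anchored_start) pat <- substr(pat, 2, nchar(pat))
  if (anchored_end) pat <- substr(pat, 1, nchar(pat) - 1)
  elements <- strsplit(pat, "-", fixed = TRUE)[[1]]
  out <- character(length(elements))
  for (k in seq_along(elements)) {
    el <- elements[k]
    if (!nzchar(el)) {
      rlang::abort(sprintf("malformed pattern: empty element %d in '%s'", k, pattern))
    }
    rep_suffix <- ""
    m <- regmatches(el, regexec("^(.*)\\((\\d+)(,(\\d+))?\\)$", el))[[1]]
    if (length(m)) {
      el <- m[2]
      rep_suffix <- if (nzchar(m[5])) sprintf("{%s,%s}", m[3], m[5])
                    else sprintf("{%s}", m[3])
    }
    body <- if (el == "x" || el == "X") {
      "[A-Z]"
    } else if (grepl("^\\[[A-Z]+\\]$", el)) {
      el
    } else if (grepl("^\\{[A-Z]+\\}$", el)) {
      paste0("[^", substr(el, 2, nchar(el) - 1), "]")
    } else if (grepl("^[A-Z]$", el)) {
      el
    } else {
      rlang::abort(sprintf("malformed pattern element %d: '%s' in '%s'",
                           k, elements[k], pattern))
    }
    out[k] <- paste0(body, rep_suffix)
  }
  paste0(if (anchored_start) "^", paste(out, collapse = ""),
         if (anchored_end) "$")
}

#' Scan sequences for a PROSITE-style motif
#'
#' Every start position is tested independently, so overlapping occurrences
#' are all reported (e.g. `P-x-L-x-P` matches `PALAPALAP` at positions 1 and
#' 5).
#'
#' @param pattern PROSITE pattern string (see [prosite_to_regex()]).
#' @param sequences a path to a FASTA file, a named character vector of
#'   protein sequences, or a `Biostrings::AAStringSet`.
#' @return tibble of class `motif_hits` with `sequence_id`, `start` (1-based)
#'   and `match` (the matched substring).
#' @export
scan_pattern <- function(pattern, sequences) {
  rx <- prosite_to_regex(pattern)
  seqs <- as_sequence_vector(sequences)
  hits <- purrr::imap(seqs, function(sq, id) {
    sq <- toupper(sq)
    # lookahead makes overlapping matches visible; capture recovers the text
    m <- gregexpr(paste0("(?=(", rx, "))"), sq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1]
    tibble::tibble(
      sequence_id = id,
      start = starts,
      match = substring(sq, starts, starts + lens - 1)
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble::tibble(sequence_id = character(), start = integer(),
                          match = character())
  }
  structure(out, class = c("motif_hits", class(out)), pattern = pattern)
}

as_sequence_vector <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    ss <- Biostrings::readAAStringSet(sequences)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (methods::is(sequences, "XStringSet")) {
    out <- as.character(sequences)
    names(out) <- sub("\\s.*$", "", names(sequences))
    return(out)
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- paste0("seq", seq_along(sequences))
    }
    return(sequences)
  }
  rlang::abort("sequences must be a FASTA path, character vector, or AAStringSet")
}

#' Motif fold enrichment against a sequence background
#'
#' Fold enrichment is the ratio of the average number of matches per protein
#' in the query list to the average number of random matches per sequence in
#' the background. Significance uses a Poisson count test: under the null the
#' total number of matches in `n_proteins` sequences is Poisson with mean
#' `lambda = n_proteins * background_rate`, and `p = P(X >= n_hits)` (upper
#' tail). With several motifs tested together, supply vectors and the
#' Benjamini-Hochberg procedure controls the FDR across them.
#'
#' The background defaults describe a PROSITE-style random-match estimate for
#' the P-x-L-x-P motif: 10318 expected matches in a background of about
#' 100000 sequences. Background counts are match counts, not
#' sequences-with-a-match.
#'
#' @param n_hits observed match count(s) in the query list (vectorized over
#'   motifs).
#' @param n_proteins number of query proteins.
#' @param background_matches expected random match count(s) in the background.
#' @param background_size number of background sequences.
#' @param motif optional motif label(s).
#' @return tibble of class `enrichment_result` with one row per motif:
#'   `motif`, `n_hits`, `n_proteins`, `observed_rate`, `background_matches`,
#'   `background_size`, `background_rate`, `fold`, `lambda`, `p.value`,
#'   `fdr`.
#' @export
motif_enrichment <- function(n_hits, n_proteins,
                             background_matches = 10318,
                             background_size = 100000,
                             motif = NULL) {
  if (any(n_hits < 0) || any(background_matches < 0)) {
    rlang::abort("counts must be non-negative")
  }
  if (n_proteins < 1 || background_size < 1) {
    rlang::abort("n_proteins and background_size must be >= 1")
  }
  k <- length(n_hits)
  background_matches <- rep_len(background_matches, k)
  background_rate <- background_matches / background_size
  if (any(background_rate == 0)) rlang::abort("zero background rate")
  observed_rate <- n_hits / n_proteins
  lambda <- n_proteins * background_rate
  p <- stats::ppois(n_hits - 1, lambda, lower.tail = FALSE)
  out <- tibble::tibble(
    motif = motif %||% paste0("motif", seq_len(k)),
    n_hits = n_hits,
    n_proteins = n_proteins,
    observed_rate = observed_rate,
    background_matches = background_matches,
    background_size = background_size,
    background_rate = background_rate,
    fold = observed_rate / background_rate,
    lambda = lambda,
    p.value = p,
    fdr = stats::p.adjust(p, method = "BH")
  )
  structure(out, class = c("enrichment_result", class(out)))
}

#' Scan a FASTA list and test motif enrichment in one call
#'
#' @param pattern PROSITE pattern string.
#' @param sequences as in [scan_pattern()].
#' @inheritParams motif_enrichment
#' @return list with `hits` (a `motif_hits` tibble) and `enrichment` (a
#'   one-row `enrichment_result`).
#' @export
scan_and_enrich <- function(pattern, sequences,
                            background_matches = 10318,
                            background_size = 100000) {
  seqs <- as_sequence_vector(sequences)
  hits <- scan_pattern(pattern, seqs)
  enr <- motif_enrichment(nrow(hits), length(seqs),
                          background_matches, background_size,
                          motif = pattern)
  list(hits = hits, enrichment = enr)
}
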