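# Proteome scanning: lysine-centered 7-mer enumeration, additive PSSM
# scoring, ranking/thresholding, and peptide-variant rank prediction.

#' Read a protein FASTA into a tibble
#'
#' Reads plain or gzipped FASTA via Biostrings. UniProt-style headers
#' (`sp|ACC|NAME ...` / `tr|ACC|NAME ...`) yield the accession as
#' `protein_id`; otherwise the first whitespace-delimited header token is used.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `protein_id`, `sequence` (uppercase),
#'   `description`.
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  first_tok <- sub("\\s.*$", "", headers)
  uni <- regmatches(first_tok, regexec("^(?:sp|tr)\\|([^|]+)\\|", first_tok))
  ids <- ifelse(vapply(uni, length, 1L) == 2L,
                vapply(uni, function(x) if (length(x) == 2) x[2] else NA_character_, ""),
                first_tok)
  tibble::tibble(protein_id = ids,
                 sequence = unname(toupper(as.character(seqs))),
                 description = headers)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Tibble with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_proteome_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$protein_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

as_proteins <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(read_proteome(x))
  if (methods::is(x, "AAStringSet")) {
    return(tibble::tibble(protein_id = names(x), sequence = as.character(x)))
  }
  if (is.data.frame(x)) {
    if (!all(c("protein_id", "sequence") %in% names(x))) {
      abort_invalid("proteins need 'protein_id' and 'sequence' columns")
    }
    return(tibble::as_tibble(x))
  }
  abort_invalid("proteins must be a FASTA path, an AAStringSet, or a data frame")
}

standard_7mer_regex <- function() "^[ACDEFGHIKLMNPQRSTVWY]{7}$"

#' Enumerate lysine-centered 7-mers
#'
#' One candidate motif per lysine carrying a full +/-3-residue context:
#' lysines within three residues of either terminus are skipped (the library
#' holds only complete 7-mers, so the scoring matrix has no terminus model).
#' Motifs containing a non-standard letter (B, J, O, U, X, Z) are dropped and
#' counted in the `skipped_nonstandard` attribute.
#'
#' @param proteins A FASTA path, `AAStringSet`, or tibble with `protein_id`
#'   and `sequence` columns (uppercase).
#' @return Tibble with columns `protein_id`, `center_pos` (1-based position of
#'   the central K), `motif` (the 7-mer); attribute `skipped_nonstandard`
#'   counts dropped motifs.
#' @export
#' @examples
#' extract_kmers(tibble::tibble(protein_id = "p", sequence = "ARTKQTARK"))
#' # one motif ARTKQTA at center_pos 4; K9 lacks C-terminal context
extract_kmers <- function(proteins) {
  proteins <- as_proteins(proteins)
  per <- purrr::map2(proteins$protein_id, proteins$sequence, function(id, seq) {
    n <- nchar(seq)
    if (n < 7L) return(NULL)
    ks <- gregexpr("K", seq, fixed = TRUE)[[1]]
    ks <- ks[ks >= 4L & ks <= n - 3L]
    if (length(ks) == 0 || ks[1] == -1L) return(NULL)
    tibble::tibble(protein_id = id, center_pos = as.integer(ks),
                   motif = substring(seq, ks - 3L, ks + 3L))
  })
  out <- dplyr::bind_rows(per)
  if (nrow(out) == 0) {
    out <- tibble::tibble(protein_id = character(), center_pos = integer(),
                          motif = character())
  }
  ok <- grepl(standard_7mer_regex(), out$motif)
  res <- out[ok, ]
  attr(res, "skipped_nonstandard") <- sum(!ok)
  res
}

# lookup matrix: rows = standard residues present, cols = the 6 positions
pssm_lookup <- function(matrix) {
  std <- dplyr::filter(matrix, !.data$phospho)
  wide <- tidyr::pivot_wider(std, id_cols = "residue",
                             names_from = "position", values_from = "score")
  m <- as.matrix(wide[, as.character(kopl_positions())])
  rownames(m) <- wide$residue
  m
}

check_scoring_matrix <- function(matrix) {
  if (!inherits(matrix, "kopl_matrix")) abort_invalid("expected a kopl_matrix PSSM")
  if (matrix_mode(matrix) != "global") {
    abort_invalid("scoring requires a globally normalized matrix; position-normalized matrices are for per-position display only")
  }
  if (!is_transformed(matrix)) {
    abort_invalid("scoring requires the log-transformed matrix (run log_transform() first)")
  }
  invisible(matrix)
}

# core additive scorer; returns NA for motifs touching a residue with no
# matrix row when unmatched = "skip", or treats such cells as 0 when "zero"
score_7mers <- function(motifs, M, unmatched = c("skip", "zero")) {
  unmatched <- match.arg(unmatched)
  if (length(motifs) == 0) return(numeric(0))
  ch <- matrix(unlist(strsplit(motifs, "", fixed = TRUE), use.names = FALSE),
               nrow = length(motifs), byrow = TRUE)
  flank_cols <- c(1L, 2L, 3L, 5L, 6L, 7L)
  total <- numeric(length(motifs))
  missing_row <- logical(length(motifs))
  for (j in seq_along(flank_cols)) {
    rid <- match(ch[, flank_cols[j]], rownames(M))
    v <- M[cbind(rid, j)]
    missing_row <- missing_row | is.na(rid)
    v[is.na(v)] <- 0
    total <- total + v
  }
  if (unmatched == "skip") total[missing_row] <- NA_real_
  total
}

check_7mers <- function(motifs) {
  bad <- nchar(motifs) != 7L | substr(motifs, 4L, 4L) != "K" |
    !grepl(standard_7mer_regex(), motifs)
  if (any(bad)) {
    abort_invalid(paste0("not valid lysine-centered 7-mers: ",
                         paste(unique(utils::head(motifs[bad], 5)), collapse = ", ")))
  }
  invisible(motifs)
}

#' Score lysine-centered 7-mer peptides with a PSSM
#'
#' The score of a motif is the sum over its six flanking positions of the
#' matrix entry for the residue observed there; the central lysine, fixed in
#' every library sequence, contributes nothing. With a globally normalized,
#' ln(1+x)-transformed matrix each cell lies in \[0, ln 2\], so scores lie in
#' \[0, 6 ln 2 ~ 4.159\]. A flank residue with no matrix row (cysteine under
#' the default 19-letter fixed alphabet) makes the motif unscorable under the
#' default `"skip"` policy (score `NA`, with a warning); `"zero"` imputes 0
#' for the missing cell instead.
#'
#' @param peptides Character vector of 7-mers, or a data frame with a
#'   `peptide` or `motif` column.
#' @param matrix A transformed, global-mode `kopl_matrix`.
#' @param unmatched `"skip"` (default) or `"zero"`.
#' @return Tibble with columns `peptide`, `score`.
#' @export
score_peptides <- function(peptides, matrix, unmatched = c("skip", "zero")) {
  unmatched <- match.arg(unmatched)
  if (is.data.frame(peptides)) {
    col <- intersect(c("peptide", "motif"), names(peptides))[1]
    if (is.na(col)) abort_invalid("peptide data frame needs a 'peptide' or 'motif' column")
    peptides <- peptides[[col]]
  }
  check_scoring_matrix(matrix)
  check_7mers(peptides)
  M <- pssm_lookup(matrix)
  s <- score_7mers(peptides, M, unmatched)
  if (anyNA(s)) {
    warn(sprintf("%d peptide(s) contain a residue with no matrix row and were left unscored",
                 sum(is.na(s))))
  }
  tibble::tibble(peptide = peptides, score = s)
}

new_candidates <- function(tbl, log) {
  out <- tibble::new_tibble(tbl, class = "kopl_candidates")
  attr(out, "scan_log") <- log
  out
}

#' @export
print.kopl_candidates <- function(x, ...) {
  lg <- scan_log(x)
  if (!is.null(lg)) {
    cat(sprintf("<kopl candidates: %d rows; %d proteins, %d sites scored, %d skipped>\n",
                nrow(x), lg$proteins_read, lg$sites_scored,
                lg$skipped_nonstandard + lg$skipped_unscored))
  }
  NextMethod()
}

#' Run log of a proteome scan
#'
#' @param table A `kopl_candidates` table from [scan_proteome()].
#' @return Named list: proteins read, K sites with full context, sites scored,
#'   motifs skipped for non-standard letters or unscorable residues.
#' @export
scan_log <- function(table) attr(table, "scan_log")

#' Scan a proteome for candidate methylation substrates
#'
#' Extracts every lysine-centered 7-mer, scores each with the PSSM, and
#' tabulates candidates. By default identical 7-mers are collapsed to one row
#' ("motif" mode) carrying every site bearing that sequence; `"site"` mode
#' keeps one row per site. Rows are ordered by score descending with
#' alphabetical motif tie-break; `rank` is dense and 1-based; `percentile` is
#' 100 x the fraction of rows scoring at or below the row (100 = top score).
#' A run log (proteins read, sites found, motifs skipped) goes to standard
#' error and is attached as the `scan_log` attribute.
#'
#' @param proteins FASTA path, `AAStringSet`, or tibble with `protein_id`,
#'   `sequence`.
#' @param matrix Transformed, global-mode `kopl_matrix`.
#' @param collapse `"motif"` (default: dedupe identical 7-mers) or `"site"`.
#' @param unmatched Policy for residues without a matrix row; see
#'   [score_peptides()].
#' @param quiet Suppress the run-log message.
#' @return A `kopl_candidates` tibble. Motif mode: `motif`, `score`, `rank`,
#'   `percentile`, `n_sites`, `sites` (semicolon-joined `protein:pos`). Site
#'   mode: `protein_id`, `center_pos`, `motif`, `score`, `rank`, `percentile`.
#' @export
scan_proteome <- function(proteins, matrix, collapse = c("motif", "site"),
                          unmatched = c("skip", "zero"), quiet = FALSE) {
  collapse <- match.arg(collapse)
  unmatched <- match.arg(unmatched)
  proteins <- as_proteins(proteins)
  check_scoring_matrix(matrix)
  kmers <- extract_kmers(proteins)
  skipped_ns <- attr(kmers, "skipped_nonstandard")
  M <- pssm_lookup(matrix)
  kmers$score <- score_7mers(kmers$motif, M, unmatched)
  skipped_un <- sum(is.na(kmers$score))
  scored <- dplyr::filter(kmers, !is.na(.data$score))
  log <- list(proteins_read = nrow(proteins),
              k_sites_full_context = nrow(kmers) + skipped_ns,
              sites_scored = nrow(scored),
              skipped_nonstandard = skipped_ns,
              skipped_unscored = skipped_un)
  if (!quiet) {
    message(sprintf(
      "scan: %d protein(s), %d K site(s) with full context, %d scored, %d skipped (non-standard: %d, unscorable: %d)",
      log$proteins_read, log$k_sites_full_context, log$sites_scored,
      skipped_ns + skipped_un, skipped_ns, skipped_un))
  }
  if (nrow(scored) == 0) {
    warn("no scoreable lysine-centered 7-mers found; returning an empty table")
    empty <- if (collapse == "motif") {
      tibble::tibble(motif = character(), score = numeric(), rank = integer(),
                     percentile = numeric(), n_sites = integer(), sites = character())
    } else {
      tibble::tibble(protein_id = character(), center_pos = integer(),
                     motif = character(), score = numeric(), rank = integer(),
                     percentile = numeric())
    }
    return(new_candidates(empty, log))
  }
  if (collapse == "motif") {
    tbl <- scored |>
      dplyr::arrange(.data$protein_id, .data$center_pos) |>
      dplyr::group_by(.data$motif, .data$score) |>
      dplyr::summarise(
        n_sites = dplyr::n(),
        sites = paste(.data$protein_id, .data$center_pos, sep = ":", collapse = ";"),
        .groups = "drop")
  } else {
    tbl <- dplyr::select(scored, "protein_id", "center_pos", "motif", "score")
  }
  tbl <- tbl |>
    dplyr::arrange(dplyr::desc(.data$score), .data$motif) |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$score)),
                  percentile = 100 * dplyr::cume_dist(.data$score),
                  .after = "score")
  new_candidates(tbl, log)
}

#' Keep the top fraction of ranked candidates
#'
#' Count mode (default) keeps the top `ceiling(top_fraction * n)` rows of the
#' deterministically ordered table — the rule behind "top 15% of all
#' lysine-centered 7-mer motifs". Equal-score blocks straddling the cutoff are
#' resolved by the table's alphabetical tie-break. Score-range mode instead
#' keeps rows with `score >= max - top_fraction * (max - min)`, i.e. the top
#' fraction of the score range. Percentiles are those computed on the full
#' table before cutting.
#'
#' @param table A `kopl_candidates` table.
#' @param top_fraction Fraction in (0, 1].
#' @param mode `"count"` or `"score_range"`.
#' @return The thresholded `kopl_candidates` tibble.
#' @export
top_candidates <- function(table, top_fraction = 0.15, mode = c("count", "score_range")) {
  mode <- match.arg(mode)
  if (!is.numeric(top_fraction) || length(top_fraction) != 1 ||
      is.na(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    abort_invalid("top_fraction must be a single number in (0, 1]")
  }
  key <- if ("motif" %in% names(table)) "motif" else "protein_id"
  ord <- dplyr::arrange(table, dplyr::desc(.data$score), .data[[key]])
  kept <- if (mode == "count") {
    utils::head(ord, ceiling(top_fraction * nrow(ord)))
  } else {
    if (nrow(ord) == 0) ord else {
      cut <- max(ord$score) - top_fraction * (max(ord$score) - min(ord$score))
      dplyr::filter(ord, .data$score >= cut)
    }
  }
  new_candidates(kept, scan_log(table))
}

#' Predict the activity ordering of peptide variants
#'
#' Scores a base lysine-centered 7-mer with each candidate residue substituted
#' at one flanking position and returns the variants sorted by score
#' descending. Because scoring is additive, the score difference between two
#' substitutions equals the difference of the two matrix entries at that
#' position, so the returned order is exactly the matrix's ordering of those
#' residues. The central lysine (P0) is immutable.
#'
#' @param matrix Transformed, global-mode `kopl_matrix`.
#' @param base A valid lysine-centered 7-mer.
#' @param position Flanking position (integer or `"P-1"` label).
#' @param residues Residues to substitute (must have matrix rows).
#' @return Tibble with columns `residue`, `peptide`, `score`, sorted by score
#'   descending (alphabetical on exact ties).
#' @export
#' @examples
#' # with any matrix ranking I > V > L > T at P-1 the returned order is I,V,L,T
predict_variant_order <- function(matrix, base, position, residues) {
  if (is.character(position)) position <- parse_position(position)
  check_position(position)
  check_scoring_matrix(matrix)
  check_7mers(base)
  if (length(base) != 1) abort_invalid("base must be a single 7-mer")
  M <- pssm_lookup(matrix)
  if (any(!residues %in% rownames(M))) {
    abort_invalid(paste0("residue(s) with no matrix row: ",
                         paste(setdiff(residues, rownames(M)), collapse = ", ")))
  }
  variants <- vapply(residues, function(r) {
    v <- base
    substr(v, position + 4L, position + 4L) <- r
    v
  }, "")
  s <- score_7mers(variants, M, unmatched = "skip")
  tibble::tibble(residue = residues, peptide = unname(variants), score = s) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$residue)
}
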