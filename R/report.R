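# Candidate curation: join scan results with user-supplied annotations,
# declarative flag filters, and candidate-table I/O.

#' Annotate scan candidates with per-protein attributes
#'
#' Left-joins user-supplied annotations (tissue expression, pathway links,
#' domain membership, ...) onto each candidate site by `protein_id`. Site-mode
#' tables gain the annotation columns directly. Motif-mode tables, whose rows
#' may carry several sites, gain per-row aggregates: logical flags become
#' `any()` over the row's sites, other columns the `";"`-joined unique values.
#' Scores, ranks and row counts never change; unmatched sites carry empty
#' annotations.
#'
#' @param table A `kopl_candidates` table.
#' @param annotations Data frame with `protein_id` plus free attribute
#'   columns; `protein_id` must be unique. May be empty or `NULL` (no-op).
#' @return The table with annotation columns appended.
#' @export
annotate_candidates <- function(table, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) return(table)
  if (!"protein_id" %in% names(annotations)) {
    abort_invalid("annotations need a 'protein_id' column")
  }
  if (anyDuplicated(annotations$protein_id)) {
    abort_invalid(paste0("duplicated protein_id in annotations: ",
                         paste(unique(annotations$protein_id[duplicated(annotations$protein_id)]),
                               collapse = ", ")))
  }
  annotations <- tibble::as_tibble(annotations)
  log <- scan_log(table)
  if ("protein_id" %in% names(table)) {
    out <- dplyr::left_join(tibble::as_tibble(table), annotations, by = "protein_id")
    return(new_candidates(out, log))
  }
  if (!"sites" %in% names(table)) {
    abort_invalid("candidate table has neither 'protein_id' nor 'sites'")
  }
  attr_cols <- setdiff(names(annotations), "protein_id")
  per_row <- table$sites |>
    strsplit(";", fixed = TRUE) |>
    purrr::map(function(s) {
      ids <- sub(":[0-9]+$", "", s)
      hits <- annotations[match(ids, annotations$protein_id), attr_cols, drop = FALSE]
      purrr::imap(hits, function(v, nm) {
        if (is.logical(v)) any(v, na.rm = TRUE)
        else {
          u <- unique(v[!is.na(v) & v != ""])
          if (length(u) == 0) NA_character_ else paste(u, collapse = ";")
        }
      }) |> tibble::as_tibble()
    }) |>
    dplyr::bind_rows()
  out <- dplyr::bind_cols(tibble::as_tibble(table), per_row)
  new_candidates(out, log)
}

#' Filter candidates on required annotation flags
#'
#' Keeps rows for which every named flag column is `TRUE` (`NA` counts as
#' `FALSE`): a declarative stand-in for manual curation criteria such as
#' expression in the target tissue or the site lying in an annotated domain.
#' A pure subset: rows are returned unchanged.
#'
#' @param table An annotated `kopl_candidates` table.
#' @param require Character vector of flag column names.
#' @return The filtered table.
#' @export
filter_candidates <- function(table, require) {
  missing <- setdiff(require, names(table))
  if (length(missing) > 0) {
    abort_invalid(paste0("unknown flag column(s): ", paste(missing, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(table))
  for (f in require) keep <- keep & !is.na(table[[f]]) & table[[f]] == TRUE
  new_candidates(table[keep, ], scan_log(table))
}

#' Write / read a candidate table as TSV
#'
#' Lossless round-trip of all columns (numbers are written with full
#' precision). Reading restores the `kopl_candidates` class and checks the
#' core columns are present.
#'
#' @param table A `kopl_candidates` table.
#' @param path File path.
#' @return `write_candidates()`: the path, invisibly; `read_candidates()`:
#'   the table.
#' @export
write_candidates <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  tbl <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_invalid(paste0("cannot parse candidate file: ", conditionMessage(e)))
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort_invalid(sprintf("malformed candidate file at line %d: %s",
                          prob$row[1], prob$expected[1]))
  }
  need <- c("score", "rank", "percentile")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort_invalid(paste0("candidate file is missing column(s): ",
                         paste(missing, collapse = ", ")))
  }
  if (!any(c("motif", "protein_id") %in% names(tbl))) {
    abort_invalid("candidate file needs a 'motif' or 'protein_id' column")
  }
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  new_candidates(tibble::as_tibble(tbl), NULL)
}
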