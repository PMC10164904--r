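# tidy()/glance() methods for the package's result objects.

#' Tidy a selectivity matrix
#'
#' @param x A `kopl_matrix`.
#' @param ... Unused.
#' @return A plain tibble: `position`, `position_label`, `residue`, `phospho`,
#'   `score`.
#' @method tidy kopl_matrix
#' @export
tidy.kopl_matrix <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(position_label = position_label(.data$position), .after = "position")
}

#' @rdname tidy.kopl_matrix
#' @return `glance()`: a one-row tibble with the mode, transform state, grid
#'   dimensions and entry range.
#' @method glance kopl_matrix
#' @export
glance.kopl_matrix <- function(x, ...) {
  std <- dplyr::filter(tibble::as_tibble(x), !.data$phospho)
  tibble::tibble(
    mode = matrix_mode(x),
    transformed = is_transformed(x),
    n_positions = dplyr::n_distinct(std$position),
    n_residues = dplyr::n_distinct(std$residue),
    n_phospho_rows = sum(x$phospho),
    min_score = min(std$score),
    max_score = max(std$score)
  )
}

#' Tidy a recovery report
#'
#' @param x A `kopl_recovery` from [recovery_report()].
#' @param ... Unused.
#' @return `tidy()`: the per-position tibble; `glance()`: a one-row overall
#'   summary.
#' @method tidy kopl_recovery
#' @export
tidy.kopl_recovery <- function(x, ...) x$per_position

#' @rdname tidy.kopl_recovery
#' @method glance kopl_recovery
#' @export
glance.kopl_recovery <- function(x, ...) {
  tibble::tibble(
    overall_spearman = x$overall_spearman,
    overall_concordance = x$overall_concordance,
    overall_applicable = x$overall_applicable,
    top_cell_match = x$top_cell_match,
    n_cells = x$n_cells
  )
}

#' Tidy a candidate table
#'
#' @param x A `kopl_candidates`.
#' @param ... Unused.
#' @return `tidy()`: the table as a plain tibble; `glance()`: a one-row
#'   summary with row count, score range and the scan run log counts.
#' @method tidy kopl_candidates
#' @export
tidy.kopl_candidates <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.kopl_candidates
#' @method glance kopl_candidates
#' @export
glance.kopl_candidates <- function(x, ...) {
  lg <- scan_log(x)
  tibble::tibble(
    n_rows = nrow(x),
    min_score = if (nrow(x)) min(x$score) else NA_real_,
    max_score = if (nrow(x)) max(x$score) else NA_real_,
    proteins_read = lg$proteins_read %||% NA_integer_,
    sites_scored = lg$sites_scored %||% NA_integer_,
    skipped = if (is.null(lg)) NA_integer_ else lg$skipped_nonstandard + lg$skipped_unscored
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
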