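# Screen processing: replicate cpm -> mean signal -> normalized (and
# log-transformed) selectivity matrix, plus the high/medium/low
# validation-set selection rule.

#' Read a raw K-OPL screen table
#'
#' Expects a CSV/TSV with a `set_id` column and one or more replicate columns
#' (`rep1`, `rep2`, ...). Ragged rows are permitted: a blank cell means the
#' replicate was not measured (e.g. a set measured in duplicate among
#' triplicates). Phospho-residue sets (lowercase `s`/`t`/`y` codes) are parsed
#' and carried along.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A long tibble with columns `set_id`, `position`, `residue`,
#'   `phospho`, `replicate`, `cpm` (one row per measured replicate).
#' @export
read_screen <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!"set_id" %in% names(raw)) abort_invalid("screen file must have a 'set_id' column")
  rep_cols <- setdiff(names(raw), "set_id")
  if (length(rep_cols) == 0) abort_invalid("screen file must have at least one replicate column")
  if (anyDuplicated(raw$set_id)) {
    abort_invalid(paste0("duplicated set_id row(s): ",
                         paste(unique(raw$set_id[duplicated(raw$set_id)]), collapse = ", ")))
  }
  long <- raw |>
    dplyr::mutate(dplyr::across(dplyr::all_of(rep_cols), as.numeric)) |>
    tidyr::pivot_longer(dplyr::all_of(rep_cols), names_to = "replicate", values_to = "cpm") |>
    dplyr::filter(!is.na(.data$cpm)) |>
    dplyr::mutate(replicate = match(.data$replicate, rep_cols))
  as_screen_records(long)
}

# normalize a records table: ensure set_id/cpm, derive position/residue/phospho
as_screen_records <- function(records) {
  if (!all(c("set_id", "cpm") %in% names(records))) {
    abort_invalid("screen records need 'set_id' and 'cpm' columns")
  }
  if (any(records$cpm < 0)) abort_invalid("cpm values must be non-negative")
  parsed <- parse_set_id(unique(records$set_id))
  records |>
    dplyr::select(-dplyr::any_of(c("position", "residue", "phospho"))) |>
    dplyr::left_join(parsed, by = "set_id") |>
    dplyr::arrange(.data$position, .data$residue) |>
    tibble::as_tibble()
}

#' Average replicate measurements per library set
#'
#' Arithmetic mean of the replicate cpm values of each set. Replicate counts
#' may differ between sets (screens occasionally carry a duplicate cell among
#' triplicates); each set needs at least one value. Completeness is checked
#' against the library grid: every (position, residue) cell of `sets` must be
#' covered exactly once. Phospho-residue rows are exempt from the completeness
#' check and pass through.
#'
#' @param records Long tibble with columns `set_id`, `cpm` (one row per
#'   replicate), e.g. from [read_screen()] or [simulate_screen()].
#' @param sets Library definition, default [kopl_sets()].
#' @return A tibble with columns `set_id`, `position`, `residue`, `phospho`,
#'   `mean_cpm`, `n_replicates`, covering the full grid.
#' @export
#' @examples
#' rec <- tibble::tibble(set_id = "P-1:I", cpm = c(100, 110, 120))
#' average_replicates(rec, sets = kopl_sets("I"))$mean_cpm # 110 (and an error
#' # would name any uncovered cell of a fuller grid)
average_replicates <- function(records, sets = kopl_sets()) {
  records <- as_screen_records(records)
  means <- records |>
    dplyr::group_by(.data$set_id, .data$position, .data$residue, .data$phospho) |>
    dplyr::summarise(mean_cpm = mean(.data$cpm), n_replicates = dplyr::n(), .groups = "drop")
  std <- dplyr::filter(means, !.data$phospho)
  missing <- setdiff(sets$set_id, std$set_id)
  if (length(missing) > 0) {
    abort_invalid(paste0("screen is missing library grid cell(s): ",
                         paste(missing, collapse = ", ")))
  }
  extra <- setdiff(std$set_id, sets$set_id)
  if (length(extra) > 0) {
    abort_invalid(paste0("screen has set(s) outside the library grid: ",
                         paste(extra, collapse = ", ")))
  }
  dplyr::arrange(means, .data$phospho, .data$position, .data$residue)
}

new_kopl_matrix <- function(entries, mode, transformed) {
  out <- tibble::new_tibble(entries, class = "kopl_matrix")
  attr(out, "kopl_mode") <- mode
  attr(out, "kopl_transformed") <- transformed
  out
}

#' @export
print.kopl_matrix <- function(x, ...) {
  cat(sprintf("<kopl selectivity matrix: mode=%s, %s>\n",
              matrix_mode(x), if (is_transformed(x)) "ln(1+x) transformed" else "untransformed"))
  NextMethod()
}

#' Mode and transform state of a selectivity matrix
#'
#' @param matrix A `kopl_matrix` from [normalize_screen()].
#' @return `matrix_mode()`: `"global"` or `"position"`; `is_transformed()`:
#'   logical.
#' @export
matrix_mode <- function(matrix) attr(matrix, "kopl_mode")

#' @rdname matrix_mode
#' @export
is_transformed <- function(matrix) isTRUE(attr(matrix, "kopl_transformed"))

#' Normalize mean screen signal into a selectivity matrix
#'
#' Global mode divides every cell by the single highest mean cpm in the table —
#' the normalization used to build the scanning PSSM. Position mode divides the
#' cells of each flanking position by that position's maximum — the
#' normalization of per-position selectivity heatmaps. Both preserve the rank
#' order of signal within any position; entries land in \[0, 1\].
#'
#' @param signal Mean-signal tibble from [average_replicates()] (columns
#'   `position`, `residue`, `mean_cpm`; `phospho` optional).
#' @param mode `"global"` or `"position"`.
#' @return A `kopl_matrix`: tibble with columns `position`, `residue`,
#'   `phospho`, `score`, carrying the mode and (un)transformed state.
#' @export
normalize_screen <- function(signal, mode = c("global", "position")) {
  mode <- match.arg(mode)
  if (!all(c("position", "residue", "mean_cpm") %in% names(signal))) {
    abort_invalid("signal needs columns position, residue, mean_cpm")
  }
  if (any(signal$mean_cpm < 0)) abort_invalid("mean cpm must be non-negative")
  if (!"phospho" %in% names(signal)) signal$phospho <- FALSE
  entries <- signal |>
    dplyr::select("position", "residue", "phospho", "mean_cpm")
  if (mode == "global") {
    mx <- max(entries$mean_cpm)
    if (mx <= 0) abort_degenerate("all-zero signal table cannot be normalized")
    entries <- dplyr::mutate(entries, score = .data$mean_cpm / mx)
  } else {
    entries <- entries |>
      dplyr::group_by(.data$position) |>
      dplyr::mutate(score = {
        mx <- max(.data$mean_cpm)
        if (mx <= 0) abort_degenerate(
          paste0("all-zero signal at position ", position_label(.data$position[1])))
        .data$mean_cpm / mx
      }) |>
      dplyr::ungroup()
  }
  entries <- entries |>
    dplyr::select(-"mean_cpm") |>
    dplyr::arrange(.data$phospho, .data$position, .data$residue)
  new_kopl_matrix(entries, mode, transformed = FALSE)
}

#' Log-transform a normalized selectivity matrix
#'
#' Adds a pseudocount of 1 to each normalized entry and takes the natural log:
#' x -> ln(1 + x). Applied after normalization (never to raw cpm), it maps
#' \[0, 1\] to \[0, ln 2\] strictly monotonically, so every ordering is
#' preserved while compressing the dynamic range the additive PSSM sums over.
#'
#' @param matrix An untransformed `kopl_matrix`.
#' @return The matrix with transformed entries and the transformed flag set.
#' @export
log_transform <- function(matrix) {
  if (!inherits(matrix, "kopl_matrix")) abort_invalid("expected a kopl_matrix")
  if (is_transformed(matrix)) abort_state("matrix is already log-transformed")
  if (any(matrix$score < 0 | matrix$score > 1 + 1e-12)) {
    abort_invalid("untransformed entries must lie in [0, 1]")
  }
  out <- dplyr::mutate(matrix, score = log1p(.data$score))
  new_kopl_matrix(out, matrix_mode(matrix), transformed = TRUE)
}

#' Select high/medium/low validation sets at a position
#'
#' Implements the rule used to pick sets for orthogonal confirmation assays:
#' at a given flanking position, the set with the highest mean signal is the
#' high group; the set with approximately half the high signal (closest to
#' high/2) is the medium group; the set with signal nearest the background is
#' the low group. Background defaults to the minimum mean signal at that
#' position. Ties break alphabetically by residue. Phospho rows are excluded.
#'
#' @param signal Mean-signal tibble from [average_replicates()].
#' @param position Flanking position (integer or `"P-1"`-style label).
#' @param background Numeric background cpm, or `"auto"` (position minimum).
#' @return One-row tibble: `position`, `high`, `medium`, `low` (set ids), the
#'   corresponding mean cpms, `background_cpm`, and a `degenerate` flag set
#'   when the three choices collapse onto fewer than three distinct sets.
#' @export
select_validation_sets <- function(signal, position, background = "auto") {
  if (is.character(position)) position <- parse_position(position)
  check_position(position)
  if (!"phospho" %in% names(signal)) signal$phospho <- FALSE
  at <- signal |>
    dplyr::filter(.data$position == !!position, !.data$phospho) |>
    dplyr::arrange(.data$residue)
  if (nrow(at) < 3) {
    abort_invalid(sprintf("need at least 3 sets at %s, found %d",
                          position_label(position), nrow(at)))
  }
  if (identical(background, "auto")) background <- min(at$mean_cpm)
  if (!is.numeric(background) || length(background) != 1) {
    abort_invalid("background must be a single number or \"auto\"")
  }
  pick <- function(target) at$residue[which.min(abs(at$mean_cpm - target))]
  high_res <- at$residue[which.max(at$mean_cpm)] # which.max: first = alphabetical
  high_cpm <- at$mean_cpm[at$residue == high_res]
  medium_res <- pick(high_cpm / 2)
  low_res <- pick(background)
  cpm_of <- function(r) at$mean_cpm[at$residue == r]
  tibble::tibble(
    position = as.integer(position),
    high = kopl_set_id(position, high_res),
    medium = kopl_set_id(position, medium_res),
    low = kopl_set_id(position, low_res),
    high_cpm = high_cpm,
    medium_cpm = cpm_of(medium_res),
    low_cpm = cpm_of(low_res),
    background_cpm = background,
    degenerate = length(unique(c(high_res, medium_res, low_res))) < 3
  )
}

#' Write / read a selectivity matrix as TSV
#'
#' Rows are residues (phospho rows last, lowercase), columns the six flanking
#' positions P-3..P+3; two header comment lines record the normalization mode
#' and transform state. Values are written with 15 significant digits so a
#' read-back reproduces entries well below 1e-12 relative error.
#'
#' @param matrix A `kopl_matrix`.
#' @param path Output/input file path.
#' @return `write_selectivity_matrix()`: the path, invisibly;
#'   `read_selectivity_matrix()`: the `kopl_matrix`.
#' @export
write_selectivity_matrix <- function(matrix, path) {
  if (!inherits(matrix, "kopl_matrix")) abort_invalid("expected a kopl_matrix")
  wide <- matrix |>
    dplyr::mutate(col = position_label(.data$position)) |>
    dplyr::arrange(.data$phospho, .data$residue) |>
    tidyr::pivot_wider(id_cols = "residue", names_from = "col", values_from = "score")
  cols <- position_label(kopl_positions())
  wide <- wide[, c("residue", intersect(cols, names(wide)))]
  hdr <- c(sprintf("# mode: %s", matrix_mode(matrix)),
           sprintf("# transformed: %s", is_transformed(matrix)))
  body <- vapply(seq_len(nrow(wide)), function(i) {
    paste(c(wide$residue[i],
            sprintf("%.15g", as.numeric(wide[i, -1]))), collapse = "\t")
  }, "")
  writeLines(c(hdr, paste(c("residue", names(wide)[-1]), collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_selectivity_matrix
#' @export
read_selectivity_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  mode <- sub("^# mode: *", "", grep("^# mode:", hdr, value = TRUE))
  transformed <- as.logical(sub("^# transformed: *", "",
                                grep("^# transformed:", hdr, value = TRUE)))
  if (length(mode) != 1 || length(transformed) != 1 || is.na(transformed)) {
    abort_invalid("matrix file is missing '# mode:' / '# transformed:' header lines")
  }
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  entries <- wide |>
    tidyr::pivot_longer(-"residue", names_to = "col", values_to = "score") |>
    dplyr::filter(!is.na(.data$score)) |> # phospho rows may not cover every position
    dplyr::mutate(position = parse_position(.data$col),
                  phospho = .data$residue %in% phospho_codes()) |>
    dplyr::select("position", "residue", "phospho", "score") |>
    dplyr::arrange(.data$phospho, .data$position, .data$residue)
  new_kopl_matrix(entries, mode, transformed)
}
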