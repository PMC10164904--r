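# Combinatorial structure of the K-OPL: alphabets, positions, set ids,
# enumeration, membership and sequence-space size.

#' Amino-acid alphabets used by the library
#'
#' `aa_alphabet()` returns the 20 standard single-letter amino-acid codes
#' (alphabetical). `fixed_alphabet()` returns the default 19-letter alphabet of
#' residues fixed one-per-set in the library: the 20 standard residues minus
#' cysteine, the conventional exclusion in synthesized peptide libraries (its
#' thiol cross-links during synthesis and assay). Six flanking positions times
#' 19 fixed residues gives the 114 sets of the screen; the degenerate positions
#' use all 20 residues, giving 20^6 = 64 million distinct 7-mers per library.
#'
#' @return Character vector of single-letter codes.
#' @export
#' @examples
#' length(aa_alphabet())   # 20
#' length(fixed_alphabet()) # 19, no "C"
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
fixed_alphabet <- function() setdiff(aa_alphabet(), "C")

# phospho-residue codes: lowercase s/t/y mark phosphorylated Ser/Thr/Tyr sets
phospho_codes <- function() c("s", "t", "y")

#' Flanking positions of the library
#'
#' Positions relative to the central lysine (P0), in the P-notation used for
#' oriented peptide libraries: -3, -2, -1, +1, +2, +3. P0 itself is always
#' lysine and is never a set's variable position.
#'
#' @return Integer vector of the six flanking positions.
#' @export
kopl_positions <- function() c(-3L, -2L, -1L, 1L, 2L, 3L)

#' Format and parse P-notation position labels
#'
#' @param position Integer vector of flanking positions (non-zero, |p| <= 3).
#' @param label Character vector like `"P-1"`, `"P+2"`.
#' @return `position_label()`: character labels; `parse_position()`: integers.
#' @export
#' @examples
#' position_label(c(-3, 1)) # "P-3" "P+1"
#' parse_position("P-1")    # -1
position_label <- function(position) {
  check_position(position)
  sprintf("P%+d", as.integer(position))
}

#' @rdname position_label
#' @export
parse_position <- function(label) {
  m <- regmatches(label, regexec("^P([+-][1-3])$", label))
  bad <- vapply(m, length, 1L) != 2L
  if (any(bad)) {
    abort_invalid(paste0("invalid position label(s): ",
                         paste(label[bad], collapse = ", "),
                         " (expected P-3..P-1, P+1..P+3)"))
  }
  as.integer(vapply(m, `[[`, "", 2L))
}

check_position <- function(position) {
  p <- suppressWarnings(as.integer(position))
  if (any(is.na(p)) || any(p == 0L) || any(abs(p) > 3L)) {
    abort_invalid("positions must be integers in {-3,-2,-1,+1,+2,+3}; P0 is the fixed central lysine")
  }
  invisible(p)
}

check_alphabet <- function(alphabet, what = "alphabet") {
  if (length(alphabet) == 0) abort_invalid(paste0(what, " must be non-empty"))
  if (any(nchar(alphabet) != 1L) || any(!alphabet %in% LETTERS)) {
    abort_invalid(paste0(what, " must contain single uppercase letters"))
  }
  if (anyDuplicated(alphabet)) abort_invalid(paste0(what, " must not contain duplicates"))
  invisible(alphabet)
}

#' Canonical K-OPL set identifiers
#'
#' A set is identified as `"P{signed position}:{residue}"`, e.g. `"P-1:I"` for
#' the set with isoleucine fixed one position N-terminal of the central lysine.
#' Lowercase `s`, `t`, `y` residues denote phosphorylated Ser/Thr/Tyr sets.
#'
#' @param position Integer flanking position(s).
#' @param residue Single-letter fixed residue(s).
#' @param set_id Character vector of set ids to parse.
#' @return `kopl_set_id()`: character ids. `parse_set_id()`: a tibble with
#'   columns `set_id`, `position`, `residue`, `phospho`.
#' @export
#' @examples
#' kopl_set_id(-1, "I")      # "P-1:I"
#' parse_set_id("P+2:M")
kopl_set_id <- function(position, residue) {
  paste0(position_label(position), ":", residue)
}

#' @rdname kopl_set_id
#' @export
parse_set_id <- function(set_id) {
  m <- regmatches(set_id, regexec("^P([+-][1-3]):([A-Za-z])$", set_id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort_invalid(paste0("malformed set id(s): ", paste(set_id[bad], collapse = ", ")))
  }
  residue <- vapply(m, `[[`, "", 3L)
  phospho <- residue %in% phospho_codes()
  if (any(!phospho & !residue %in% aa_alphabet())) {
    abort_invalid(paste0("unknown residue code in set id(s): ",
                         paste(set_id[!phospho & !residue %in% aa_alphabet()], collapse = ", ")))
  }
  tibble::tibble(
    set_id = set_id,
    position = as.integer(vapply(m, `[[`, "", 2L)),
    residue = residue,
    phospho = phospho
  )
}

#' Enumerate the sets of a K-OPL
#'
#' One set per (flanking position, fixed residue) pair: six positions times the
#' fixed-residue alphabet. With the default 19-letter alphabet this is the
#' 114-set library of a standard K-OPL screen.
#'
#' @param fixed Character vector of fixed residues (default [fixed_alphabet()]).
#' @return A tibble with columns `set_id`, `position`, `fixed_residue`, ordered
#'   by position ascending then residue alphabetical.
#' @export
#' @examples
#' nrow(kopl_sets())        # 114
#' kopl_sets("A")$set_id    # "P-3:A" ... "P+3:A"
kopl_sets <- function(fixed = fixed_alphabet()) {
  check_alphabet(fixed, "fixed-residue alphabet")
  grid <- tidyr::expand_grid(position = kopl_positions(), fixed_residue = sort(fixed))
  dplyr::mutate(grid,
                set_id = kopl_set_id(.data$position, .data$fixed_residue),
                .before = 1)
}

#' Test membership of a peptide in a K-OPL set
#'
#' A lysine-centered 7-mer belongs to the set `P{p}:{r}` when its central
#' (4th) residue is K and the residue at flanking position `p` is `r`.
#'
#' @param sequence Character vector of 7-letter uppercase peptides.
#' @param set_id Canonical set id (length 1), e.g. `"P-1:I"`.
#' @return Logical vector, one element per sequence.
#' @export
#' @examples
#' in_kopl_set("RRIKKVK", "P-1:I") # TRUE
#' in_kopl_set("RRIKKVK", "P-1:L") # FALSE
in_kopl_set <- function(sequence, set_id) {
  if (length(set_id) != 1L) abort_invalid("set_id must be a single id")
  set <- parse_set_id(set_id)
  if (any(nchar(sequence) != 7L)) {
    abort_invalid("sequences must be exactly 7 letters (K-centered 7-mers)")
  }
  if (any(sequence != toupper(sequence))) {
    abort_invalid("sequences must be uppercase")
  }
  substr(sequence, 4L, 4L) == "K" &
    substr(sequence, set$position + 4L, set$position + 4L) == set$residue
}

#' Size of the sequence space queried by the library
#'
#' The number of distinct 7-mers with a fixed central lysine and six degenerate
#' flanking positions: |alphabet|^6. For the 20-letter standard alphabet this
#' is 64,000,000 — the sequence space a full K-OPL screen interrogates.
#'
#' @param degenerate Character vector: the alphabet of the degenerate
#'   positions (default [aa_alphabet()], 20 letters).
#' @return A number.
#' @export
#' @examples
#' sequence_space_size()       # 64e6
#' sequence_space_size("A")    # 1
sequence_space_size <- function(degenerate = aa_alphabet()) {
  check_alphabet(degenerate, "degenerate alphabet")
  length(degenerate)^6
}
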