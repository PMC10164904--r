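# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-position loops, data-frame lookups) so they share no
# code path with the implementation they check.

# score one 7-mer by looking each flank residue up in the long-format matrix
naive_score <- function(motif, mat_long) {
  total <- 0
  for (p in c(-3, -2, -1, 1, 2, 3)) {
    r <- substr(motif, p + 4, p + 4)
    hit <- mat_long$score[mat_long$position == p & mat_long$residue == r &
                            !mat_long$phospho]
    if (length(hit) == 0) return(NA_real_)
    total <- total + hit
  }
  total
}

# enumerate and score every eligible lysine-centered 7-mer by sliding window
naive_scan <- function(proteins, mat_long) {
  rows <- list()
  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$sequence[i]
    n <- nchar(seq)
    if (n < 7) next
    for (cp in 4:(n - 3)) {
      if (substr(seq, cp, cp) != "K") next
      motif <- substr(seq, cp - 3, cp + 3)
      if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]{7}$", motif)) next
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = proteins$protein_id[i], center_pos = cp, motif = motif,
        score = naive_score(motif, mat_long))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(protein_id = character(), center_pos = integer(),
                      motif = character(), score = numeric()))
  }
  do.call(rbind, rows)
}

# random mean-signal table over the full default grid
random_signal <- function(seed, max_cpm = 10000) {
  withr::with_seed(seed, {
    grid <- kopl_sets()
    tibble::tibble(set_id = grid$set_id, position = grid$position,
                   residue = grid$fixed_residue, phospho = FALSE,
                   mean_cpm = runif(nrow(grid), 0, max_cpm))
  })
}

# random transformed global matrix via the pipeline
random_matrix <- function(seed) {
  random_signal(seed) |> normalize_screen("global") |> log_transform()
}

# random lysine-centered 7-mers over an alphabet
random_7mers <- function(n, seed, alphabet = aa_alphabet()) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      flank <- sample(alphabet, 6, replace = TRUE)
      paste(c(flank[1:3], "K", flank[4:6]), collapse = "")
    }, "")
  })
}

# random proteins as a tibble
random_proteins <- function(n, len_range, seed) {
  withr::with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    tibble::tibble(
      protein_id = sprintf("RP%03d", seq_len(n)),
      sequence = vapply(lens, function(l) {
        paste(sample(aa_alphabet(), l, replace = TRUE), collapse = "")
      }, ""))
  })
}

# screen records with given per-set cpm vectors on a small custom grid
records_from_list <- function(cpms) {
  tibble::tibble(set_id = rep(names(cpms), lengths(cpms)),
                 cpm = unlist(cpms, use.names = FALSE))
}
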