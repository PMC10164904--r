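# helper: matrix with a single non-zero cell at (P-1, I) = ln 2, zero elsewhere
single_cell_matrix <- function() {
  sig <- dplyr::mutate(random_signal(1), mean_cpm = 0)
  sig$mean_cpm[sig$position == -1 & sig$residue == "I"] <- 1000
  log_transform(normalize_screen(sig, "global"))
}

uniform_matrix <- function() {
  sig <- dplyr::mutate(random_signal(1), mean_cpm = 500)
  log_transform(normalize_screen(sig, "global"))
}

test_that("k-mer extraction keeps only lysines with full flanking context", {
  one <- extract_kmers(tibble::tibble(protein_id = "p", sequence = "RRIKKVK"))
  expect_equal(one$center_pos, 4L)
  expect_equal(one$motif, "RRIKKVK") # Ks at 5 and 7 lack context
  expect_equal(nrow(extract_kmers(tibble::tibble(protein_id = "p", sequence = "AAAAAAA"))), 0)
  h3 <- extract_kmers(tibble::tibble(protein_id = "H3", sequence = "ARTKQTARK"))
  expect_equal(h3$motif, "ARTKQTA")
  expect_equal(h3$center_pos, 4L)
  expect_equal(nrow(extract_kmers(tibble::tibble(protein_id = "p", sequence = ""))), 0)
  # non-standard letters are skipped and counted
  x <- extract_kmers(tibble::tibble(protein_id = "p", sequence = "AAXKAAAKAAA"))
  expect_equal(x$motif, "AAAKAAA")
  expect_equal(attr(x, "skipped_nonstandard"), 1)
})

test_that("extraction matches a sliding-window oracle on random proteins", {
  prot <- random_proteins(30, c(7, 60), seed = 5)
  got <- extract_kmers(prot)
  ora <- naive_scan(prot, tibble::as_tibble(uniform_matrix()))
  expect_equal(got$protein_id, ora$protein_id)
  expect_equal(got$center_pos, ora$center_pos)
  expect_equal(got$motif, ora$motif)
})

test_that("motif scores are additive sums of matrix cells with known bounds", {
  u <- uniform_matrix() # every cell ln 2
  s <- score_peptides(c("RRIKKVK", "ARTKQTA"), u)
  expect_equal(s$score, rep(6 * log(2), 2))
  sc <- single_cell_matrix()
  expect_equal(score_peptides("RRIKKVK", sc)$score, log(2))
  expect_equal(score_peptides("RRLKKVK", sc)$score, 0)
  expect_error(score_peptides("RRIKKV", sc), class = "koplr_invalid_input")
  expect_error(score_peptides("RRIRKVK", sc), class = "koplr_invalid_input")
})

test_that("scoring agrees with the brute-force oracle on random matrices", {
  m <- random_matrix(17)
  motifs <- random_7mers(100, seed = 18, alphabet = fixed_alphabet())
  got <- score_peptides(motifs, m)$score
  expected <- vapply(motifs, naive_score, 0, mat_long = tibble::as_tibble(m))
  expect_equal(got, unname(expected))
})

test_that("residues without a matrix row follow the skip or impute-zero policy", {
  m <- random_matrix(2) # 19 rows, no C
  expect_warning(s <- score_peptides("ACAKAAA", m), "unscored")
  expect_true(is.na(s$score))
  z <- score_peptides("ACAKAAA", m, unmatched = "zero")
  a <- score_peptides("AAAKAAA", m)$score
  mt <- tibble::as_tibble(m)
  expect_equal(z$score, a - mt$score[mt$position == -2 & mt$residue == "A"])
})

test_that("scoring refuses untransformed or position-normalized matrices", {
  sig <- random_signal(6)
  expect_error(score_peptides("AAAKAAA", normalize_screen(sig, "global")),
               class = "koplr_invalid_input")
  expect_error(score_peptides("AAAKAAA", log_transform(normalize_screen(sig, "position"))),
               class = "koplr_invalid_input")
})

test_that("proteome scan collapses identical motifs and carries all sites", {
  prot <- tibble::tibble(protein_id = c("A1", "B2"),
                         sequence = c("GGGRRIKKVKGGG", "TTRRIKKVKTT"))
  ct <- scan_proteome(prot, single_cell_matrix(), quiet = TRUE)
  row <- ct[ct$motif == "RRIKKVK", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$n_sites, 2)
  expect_equal(row$score, log(2))
  expect_match(row$sites, "A1:7;B2:6")
  expect_equal(row$rank, 1L)
  expect_equal(row$percentile, 100)
  # per-site mode keeps one row per site
  cs <- scan_proteome(prot, single_cell_matrix(), collapse = "site", quiet = TRUE)
  expect_equal(sum(cs$motif == "RRIKKVK"), 2)
})

test_that("scan equals the naive oracle and conserves site counts", {
  prot <- random_proteins(5, c(40, 50), seed = 41)
  m <- random_matrix(42)
  ct <- scan_proteome(prot, m, quiet = TRUE)
  ora <- naive_scan(prot, tibble::as_tibble(m))
  ora_ok <- ora[!is.na(ora$score), ]
  expect_equal(nrow(ct), length(unique(ora_ok$motif)))
  expect_equal(sort(ct$motif), sort(unique(ora_ok$motif)))
  expect_equal(sum(ct$n_sites), nrow(ora_ok))
  lg <- scan_log(ct)
  expect_equal(lg$sites_scored, nrow(ora_ok))
  expect_equal(lg$skipped_unscored, sum(is.na(ora$score)))
  # scores match per motif
  idx <- match(ct$motif, ora_ok$motif)
  expect_equal(ct$score, ora_ok$score[idx])
})

test_that("scan output is deterministic and ordered score-desc then motif-asc", {
  prot <- random_proteins(10, c(30, 60), seed = 77)
  m <- random_matrix(78)
  a <- scan_proteome(prot, m, quiet = TRUE)
  b <- scan_proteome(prot, m, quiet = TRUE)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(all(diff(a$score) <= 0))
  expect_true(all(a$score >= 0 & a$score <= 6 * log(2) + 1e-12))
  ties <- split(a$motif, a$score)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), TRUE)))
})

test_that("an empty or K-free proteome yields an empty table with a warning", {
  prot <- tibble::tibble(protein_id = "p", sequence = "AAAAAAAAAA")
  expect_warning(ct <- scan_proteome(prot, uniform_matrix(), quiet = TRUE))
  expect_equal(nrow(ct), 0)
  expect_s3_class(ct, "kopl_candidates")
})

test_that("top-fraction thresholding uses the ceiling rule and tie-breaks", {
  prot <- random_proteins(20, c(50, 80), seed = 90)
  m <- random_matrix(91)
  ct <- scan_proteome(prot, m, quiet = TRUE)
  n <- nrow(ct)
  expect_gt(n, 10)
  expect_equal(nrow(top_candidates(ct, 0.2)), ceiling(0.2 * n))
  expect_equal(nrow(top_candidates(head(ct, 10), 0.2)), 2)
  expect_equal(nrow(top_candidates(head(ct, 7), 0.15)), 2) # ceil(1.05)
  expect_error(top_candidates(ct, 0), class = "koplr_invalid_input")
  expect_error(top_candidates(ct, 1.1), class = "koplr_invalid_input")
  # percentiles come from the full table, not the cut
  kept <- top_candidates(ct, 0.1)
  expect_equal(kept$percentile, ct$percentile[seq_len(nrow(kept))])
  # equal-score block straddling the cutoff: alphabetical selection, exact count
  block <- ct
  block$score <- rep(1, n)
  got <- top_candidates(block, 0.5)
  expect_equal(nrow(got), ceiling(0.5 * n))
  expect_equal(got$motif, sort(block$motif)[seq_len(nrow(got))])
})

test_that("score-range thresholding keeps the top fraction of the score span", {
  prot <- random_proteins(20, c(50, 80), seed = 13)
  m <- random_matrix(14)
  ct <- scan_proteome(prot, m, quiet = TRUE)
  kept <- top_candidates(ct, 0.15, mode = "score_range")
  cut <- max(ct$score) - 0.15 * (max(ct$score) - min(ct$score))
  expect_equal(sort(kept$motif), sort(ct$motif[ct$score >= cut]))
})

test_that("variant ordering mirrors the matrix entries and is additive", {
  m <- random_matrix(23)
  mt <- tibble::as_tibble(m)
  out <- predict_variant_order(m, "ARTKQTA", "P-1", c("I", "V", "L", "T"))
  entries <- mt[mt$position == -1 & mt$residue %in% c("I", "V", "L", "T"), ]
  expect_equal(out$residue, entries$residue[order(-entries$score)])
  # identity substitution leaves the score unchanged
  base_score <- score_peptides("ARTKQTA", m)$score
  expect_equal(out$score[out$residue == "T"], base_score)
  # additivity: delta score equals the matrix-entry difference (50 random cases)
  withr::with_seed(99, {
    for (i in 1:50) {
      base <- random_7mers(1, seed = sample.int(1e6, 1), alphabet = fixed_alphabet())
      pos <- sample(kopl_positions(), 1)
      new <- sample(fixed_alphabet(), 1)
      old <- substr(base, pos + 4, pos + 4)
      v <- predict_variant_order(m, base, pos, new)
      delta <- mt$score[mt$position == pos & mt$residue == new] -
        mt$score[mt$position == pos & mt$residue == old]
      expect_equal(v$score - score_peptides(base, m)$score, delta)
    }
  })
  expect_error(predict_variant_order(m, "ARTKQTA", 0, "I"), class = "koplr_invalid_input")
  expect_error(predict_variant_order(m, "ARTKQTA", -1, "C"), class = "koplr_invalid_input")
})

test_that("FASTA round-trips and UniProt accessions are extracted", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P12345|TEST_HUMAN Some protein", "MARTKQTARKSTGGKAPRKQLA",
               ">plainheader with description", "GGVKKPHRYRPGTVALREIRRYQK"), path)
  prot <- read_proteome(path)
  expect_equal(prot$protein_id, c("P12345", "plainheader"))
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(prot, path2)
  back <- read_proteome(path2)
  expect_equal(back$sequence, prot$sequence)
  expect_equal(back$protein_id, prot$protein_id)
})
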