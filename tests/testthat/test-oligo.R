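test_that("central SRE segments reconstruct with symmetric numbering", {
  seg16 <- build_sre_segment(16)
  expect_equal(paste(seg16$bases, collapse = ""), "TGTCCATATTAGGACA")
  expect_equal(seg16$positions, c(-8:-1, 1:8))

  expect_equal(paste(build_sre_segment(12)$bases, collapse = ""),
               "TCCATATTAGGA")
  expect_equal(paste(build_sre_segment(20)$bases, collapse = ""),
               "GATGTCCATATTAGGACATC")

  expect_error(build_sre_segment(13), "supported lengths")
  expect_error(build_sre_segment(28), "flank sequence unavailable")
})

test_that("position labels map to array indices and back", {
  seg <- build_sre_segment(16)
  # index = position + N/2 for negative, position + N/2 - 1 for positive
  expect_equal(position_to_index(seg, -8), 1L)
  expect_equal(position_to_index(seg, -1), 8L)
  expect_equal(position_to_index(seg, 1), 9L)
  expect_equal(position_to_index(seg, 8), 16L)
  expect_equal(index_to_position(seg, position_to_index(seg, -3)), -3L)
  expect_error(position_to_index(seg, 0), "not present")
  expect_error(oligo_sequence("ACGT", positions = c(-1, 0, 1, 2)),
               "position 0")
})

test_that("hairpin enumeration pairs outside-in and stops at first mismatch", {
  seg16 <- build_sre_segment(16)
  hp <- enumerate_hairpin_fold(seg16)
  expect_equal(hp$n_wc, 5L)
  expect_equal(sort(hp$loop_positions), c(-3, -2, -1, 1, 2, 3))
  expect_equal(pair_labels(seg16, hp),
               c("AT_8", "CG_7", "AT_6", "GC_5", "GC_4"))
  expect_equal(hp$molecularity, 1L)

  expect_equal(enumerate_hairpin_fold(build_sre_segment(12))$n_wc, 3L)

  # no complementary ends: everything is loop
  polya <- oligo_sequence("AAAAAAAAAA")
  hp0 <- enumerate_hairpin_fold(polya, min_loop = 3)
  expect_equal(hp0$n_wc, 0L)
  expect_equal(length(hp0$loop_positions), 10L)

  expect_error(enumerate_hairpin_fold(oligo_sequence("ACGT")), "shorter")
})

test_that("hairpin stem counts match the melting-study lengths", {
  expected <- c(`12` = 3L, `14` = 4L, `16` = 5L, `18` = 6L, `20` = 7L)
  for (N in names(expected))
    expect_equal(enumerate_hairpin_fold(build_sre_segment(as.integer(N)))$n_wc,
                 expected[[N]], info = paste("N =", N))
})

test_that("hairpin stem never exceeds the geometric bound", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(seq(8, 30, by = 2), 1)
    s <- oligo_sequence(sample(c("A", "C", "G", "T"), n, replace = TRUE))
    hp <- enumerate_hairpin_fold(s, min_loop = 3)
    expect_lte(hp$n_wc, floor((n - 3) / 2))
  }
})

test_that("homoduplex enumeration flags the central mismatches", {
  du <- enumerate_homoduplex_fold(build_sre_segment(16))
  expect_equal(du$n_wc, 12L)
  expect_equal(nrow(du$pairs), 16L)
  expect_equal(sort(du$pairs$position_a[!du$pairs$is_wc]), c(-3, -2, 2, 3))
  expect_equal(du$molecularity, 2L)

  # perfect palindrome control and a no-pair homopolymer
  expect_equal(enumerate_homoduplex_fold(oligo_sequence("CTGACGTCAG"))$n_wc,
               10L)
  expect_equal(enumerate_homoduplex_fold(oligo_sequence("AAAA"))$n_wc, 0L)
})

test_that("homoduplex pairing is symmetric", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:24, 1)
    s <- oligo_sequence(sample(c("A", "C", "G", "T"), n, replace = TRUE))
    du <- enumerate_homoduplex_fold(s)
    # pair (i, n+1-i) WC iff pair (n+1-i, i) WC
    expect_equal(du$pairs$is_wc, rev(du$pairs$is_wc))
  }
})

test_that("single-strand masses follow the Oligo Calc convention", {
  expect_equal(molecular_weight(build_sre_segment(16)), 4880.26,
               tolerance = 1e-9)
  expect_equal(round(molecular_weight(build_sre_segment(16))), 4880)
  expect_equal(round(molecular_weight(build_sre_segment(20))), 6116)
  expect_equal(molecular_weight(oligo_sequence("A")), 251.25,
               tolerance = 1e-9)
  # the 12-mer computes to 3644.46 (a printed table rounds it to 3645;
  # the formula value is authoritative here)
  expect_equal(molecular_weight(build_sre_segment(12)), 3644.46,
               tolerance = 1e-9)
  expect_error(molecular_weight(oligo_sequence("")), "empty")
})

test_that("mass is additive up to one condensation constant", {
  set.seed(11)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(2:12, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(2:12, 1),
                      replace = TRUE), collapse = "")
    expect_equal(molecular_weight(oligo_sequence(paste0(a, b))),
                 molecular_weight(oligo_sequence(a)) +
                   molecular_weight(oligo_sequence(b)) + 61.96,
                 tolerance = 1e-9)
  }
})

test_that("FASTA and fold-report round trips", {
  seg <- build_sre_segment(16)
  fa <- tempfile(fileext = ".fasta")
  write_fasta_oligos(seg, fa)
  back <- read_fasta_oligos(fa)
  expect_equal(back[[1]]$bases, seg$bases)
  expect_equal(back[[1]]$name, "SREseg16")

  tsv <- tempfile(fileext = ".tsv")
  write_fold_report(enumerate_homoduplex_fold(seg), tsv)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$is_wc), 12)
})
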