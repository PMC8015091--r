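test_that("count_kmers enumerates overlapping windows and skips invalid ones", {
  counts <- count_kmers(genome_sequence("ACGT", "g"), 2)
  expect_equal(counts[["AC"]], 1L)
  expect_equal(counts[["CG"]], 1L)
  expect_equal(counts[["GT"]], 1L)
  expect_equal(sum(counts), 3L)

  # N yields no valid window at all
  expect_equal(sum(count_kmers(genome_sequence("N", "g"), 1)), 0L)
  # windows containing N are skipped entirely, not partially
  expect_equal(sum(count_kmers(genome_sequence("ACNGT", "g"), 2)), 2L)

  # windows never span record boundaries
  split2 <- count_kmers(genome_sequence(c("AC", "GT"), "g"), 2)
  expect_equal(split2[["AC"]], 1L)
  expect_equal(split2[["GT"]], 1L)
  expect_equal(split2[["CG"]], 0L)

  expect_error(genome_sequence("", "g"), "invalid-input")
  expect_error(genome_sequence(character(0), "g"), "invalid-input")
  expect_error(count_kmers(genome_sequence("ACGT", "g"), 0), "invalid-parameter")
  expect_error(count_kmers(genome_sequence("ACG", "g"), 4), "invalid-input")
})

test_that("counting matches the naive offset-scan oracle", {
  cases <- list()
  for (i in 1:16) {
    len <- c(100, 250, 500, 1000, 2500, 5000, 10000)[1 + (i %% 7)]
    cases[[i]] <- random_dna(len, seed = 100 + i, n_prob = ifelse(i %% 3 == 0, 0.02, 0))
  }
  # multi-record genomes
  cases[[17]] <- c(random_dna(300, 201), random_dna(150, 202))
  cases[[18]] <- c(random_dna(80, 203, n_prob = 0.05), random_dna(120, 204))
  cases[[19]] <- c("ACGTN", "NNACGT", "TTTT")
  cases[[20]] <- random_dna(10000, 205, n_prob = 0.01)

  for (ci in seq_along(cases)) {
    g <- genome_sequence(cases[[ci]], paste0("case", ci))
    for (k in 1:4) {
      got <- count_kmers(g, k)
      want <- naive_count_kmers(g$records, k)
      expect_identical(as.integer(got), unname(as.integer(want)),
                       info = sprintf("case %d, k = %d", ci, k))
    }
  }
})

test_that("expected counts follow the prefix*suffix/middle rule", {
  g <- genome_sequence("AAAA", "toy")
  o2 <- count_kmers(g, 2)
  o1 <- count_kmers(g, 1)
  expect_equal(o2[["AA"]], 3L)
  expect_equal(o1[["A"]], 4L)
  e <- expected_counts(o2, o1, 3)
  expect_equal(e[["AAA"]], 3 * 3 / 4)
  # zero numerator (prefix or suffix unseen) and zero middle both give E = 0
  expect_equal(e[["AAC"]], 0)
  expect_equal(e[["CCC"]], 0)
  expect_true(all(e >= 0) && all(is.finite(e)))

  expect_error(expected_counts(o1, o2, 3), "invalid-parameter")
  expect_error(expected_counts(o2, o1, 2), "invalid-parameter")
})

test_that("expected approximates observed on an i.i.d. uniform sequence", {
  g <- genome_sequence(random_dna(500000, seed = 7), "iid")
  o <- count_kmers(g, 4)
  e <- expected_counts(count_kmers(g, 3), count_kmers(g, 2), 4)
  rel <- abs(as.numeric(o) - as.numeric(e)) / as.numeric(e)
  expect_lt(median(rel), 0.05)
  expect_lt(max(rel), 0.25)
})

test_that("scores obey the (O-E)/(O+E) identities and bounds", {
  o <- make_counts(c(5, 0, 3, 0), 1)
  e <- make_expected(c(5, 2, 0, 0), 1)
  s <- score_signature(o, e)
  expect_equal(as.numeric(s), c(0, -1, 1, 0))  # O=E, O=0<E, E=0<O, O=E=0
  expect_equal(s[["C"]], -1)

  # hand arithmetic: O=2, E=2.25
  s2 <- score_signature(make_counts(c(2, 0, 0, 0), 1),
                        make_expected(c(2.25, 0, 0, 0), 1))
  expect_equal(s2[["A"]], -0.25 / 4.25)

  # monotone in O with E > 0 fixed; always within [-1, 1]
  os <- 0:20
  ss <- vapply(os, function(oo) {
    score_signature(make_counts(c(oo, 0, 0, 0), 1),
                    make_expected(c(4, 0, 0, 0), 1))[["A"]]
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
  expect_true(all(ss >= -1 & ss <= 1))

  expect_error(score_signature(make_counts(rep(1, 16), 2), e), "invalid-parameter")
})

test_that("whole-genome signature composes the stages (worked micro-example)", {
  s <- wgks_signature(genome_sequence("AAAA", "toy"), k = 3)
  expect_length(s, 64)
  expect_equal(s[["AAA"]], (2 - 2.25) / (2 + 2.25))
  expect_equal(unname(s[names(s) != "AAA"]), rep(0, 63))

  # a word with O = 0 but E > 0 scores exactly -1:
  # "AATAA" gives O(AA)=2, O(A)=4 so E(AAA)=1 while AAA never occurs
  s2 <- wgks_signature(genome_sequence("AATAA", "toy2"), k = 3)
  expect_equal(s2[["AAA"]], -1)
})

test_that("signature order is lexicographic with base-4 ranks (A=0..T=3)", {
  words <- kmer_words(3)
  expect_equal(words[1], "AAA")
  expect_equal(words[64], "TTT")
  expect_false(is.unsorted(words))
  encode <- function(w) {
    digits <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T")) - 1
    sum(digits * 4^(rev(seq_along(digits)) - 1))
  }
  for (w in c("AAA", "ACG", "TGA", "CTT", "TTT"))
    expect_equal(words[encode(w) + 1], w)
  s <- wgks_signature(genome_sequence(random_dna(2000, 11), "g"), k = 3)
  expect_identical(names(s), words)
})

test_that("duplication of records leaves every score unchanged", {
  g <- genome_sequence(c(random_dna(3000, 21), random_dna(1500, 22)), "g")
  gg <- genome_sequence(c(g$records, g$records), "g2")
  for (k in c(3, 5)) {
    s1 <- wgks_signature(g, k)
    s2 <- wgks_signature(gg, k)
    expect_lt(max(abs(as.numeric(s1) - as.numeric(s2))), 1e-12)
  }
})

test_that("canonical mode folds each word with its reverse complement", {
  g <- genome_sequence("ACGTT", "g")
  cc <- count_kmers(g, 2, canonical = TRUE)
  # windows AC,CG,GT,TT -> canonical AC,CG,AC,AA
  expect_equal(cc[["AC"]], 2L)
  expect_equal(cc[["AA"]], 1L)
  expect_equal(cc[["CG"]], 1L)
  expect_equal(sum(cc), 4L)
})

test_that("the memory guard rejects oversized k", {
  expect_error(kmer_words(13), "memory guard")
  expect_error(wgks_signature(genome_sequence("ACGT", "g"), 13), "memory guard")
})
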