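test_that("hand-computable k-mer cases come out exactly", {
  f <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(f[["AA"]]), 1.0)
  expect_equal(sum(f), 1.0)
  f2 <- kmer_frequencies("ACDA", 2)
  expect_equal(unname(f2[c("AC", "CD", "DA")]), rep(1 / 3, 3))
  expect_equal(sum(f2 > 0), 3L)
  # windows containing X drop out of numerator and denominator
  f3 <- kmer_frequencies("ACXDA", 2)
  expect_equal(unname(f3[c("AC", "DA")]), c(0.5, 0.5))
  expect_warning(f4 <- kmer_frequencies("A", 2), "shorter")
  expect_true(all(f4 == 0))
})

test_that("k-mer blocks have the documented dimensionality", {
  expect_length(kmer_frequencies("ACDEFG", 2), 400L)
  expect_length(kmer_frequencies("ACDEFG", 3), 8000L)
  alph <- side_chain_alphabet()
  expect_length(kmer_frequencies("ACDEFG", 2, alph), 49L)
  expect_length(kmer_frequencies("ACDEFG", 3, alph), 343L)
  expect_length(kmer_frequencies("ACDEFG", 4, alph), 2401L)
})

test_that("k-mer frequencies agree with a naive dictionary oracle", {
  withr::local_seed(101)
  alph <- side_chain_alphabet()
  for (i in 1:25) {
    s <- random_aa_seq(sample(5:50, 1))
    for (k in 2:4) {
      impl_aa <- kmer_frequencies(s, k)
      oracle_aa <- naive_kmer_freq(s, k, virann::AA_LETTERS)
      expect_equal(impl_aa[names(oracle_aa)], oracle_aa,
                   tolerance = 1e-12)
      s_sc <- translate_side_chain(s, alph)
      impl_sc <- kmer_frequencies(s_sc, k, alph)
      oracle_sc <- naive_kmer_freq(s_sc, k, alph$symbols)
      expect_equal(impl_sc[names(oracle_sc)], oracle_sc, tolerance = 1e-12)
    }
  }
})

test_that("side-chain translation maps groups and preserves length", {
  alph <- side_chain_alphabet()
  expect_equal(translate_side_chain("AAAA", alph),
               strrep(alph$groups[["A"]], 4))
  kr <- translate_side_chain("KR", alph)
  expect_equal(substr(kr, 1, 1), substr(kr, 2, 2))
  expect_error(translate_side_chain("MK-L", alph), "position 3")
  # translating first or mapping windows is equivalent: frequencies on the
  # translated string sum to 1 like any other alphabet
  s <- random_aa_seq(40)
  expect_equal(sum(kmer_frequencies(translate_side_chain(s, alph), 3, alph)), 1)
  # and translation before or inside kmer_frequencies is the same thing
  expect_equal(kmer_frequencies(s, 3, alph),
               kmer_frequencies(translate_side_chain(s, alph), 3, alph))
})

test_that("a 7-group alphabet is required and the mapping is total", {
  alph <- side_chain_alphabet()
  expect_length(alph$symbols, 7L)
  expect_setequal(names(alph$groups), virann::AA_LETTERS)
  bad <- stats::setNames(rep("1", 20), virann::AA_LETTERS)
  expect_error(side_chain_alphabet(bad), "7 distinct")
})

test_that("physicochemical descriptors match reference values", {
  x <- compute_extra_features("MKVLAEDFWYCCH")
  expect_equal(unname(x[["aromaticity"]]), 3 / 13, tolerance = 1e-12)
  expect_equal(unname(x[["length"]]), 13)
  # frozen Biopython ProtParam reference values for this sequence
  expect_equal(unname(x[["instability_index"]]), 36.7923076923077,
               tolerance = 1e-9)
  expect_equal(unname(x[["molecular_weight"]]), 1644.9335, tolerance = 1e-6)
  expect_equal(unname(x[["gravy"]]), 0.2461538461538461, tolerance = 1e-9)
  expect_equal(unname(x[["extinction_reduced"]]), 5500 + 1490)
  expect_equal(unname(x[["extinction_cystines"]]), 5500 + 1490 + 125)
  y <- compute_extra_features("GAVLIMKRHDESTNQFWYCP")
  expect_equal(unname(y[["instability_index"]]), 35.39, tolerance = 1e-9)
  expect_equal(unname(y[["molecular_weight"]]), 2395.7134, tolerance = 1e-6)
})

test_that("extinction and aromaticity edge cases follow the formulas", {
  x <- compute_extra_features("AAAA")
  expect_equal(unname(x[["aromaticity"]]), 0)
  expect_equal(unname(x[["extinction_reduced"]]), 0)
  expect_equal(unname(x[["extinction_cystines"]]), 0)
  expect_equal(unname(compute_extra_features("FWY")[["aromaticity"]]), 1)
  # a single cysteine cannot form a bridge
  expect_equal(unname(compute_extra_features("CAAA")[["extinction_cystines"]]), 0)
  g <- compute_extra_features("G")
  expect_equal(unname(g[["molecular_weight"]]), 75.0666, tolerance = 1e-6)
  expect_error(compute_extra_features(""), "empty")
})

test_that("isoelectric point matches a brute-force charge grid scan", {
  # independent oracle: same documented EMBOSS pKa constants, independent
  # grid-scan code path
  grid_pi <- function(seq) {
    letters <- strsplit(seq, "")[[1]]
    cn <- table(factor(letters, levels = virann::AA_LETTERS))
    pka_pos <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
    pka_neg <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
    n_pos <- c(Nterm = 1, K = cn[["K"]], R = cn[["R"]], H = cn[["H"]])
    n_neg <- c(Cterm = 1, D = cn[["D"]], E = cn[["E"]], C = cn[["C"]],
               Y = cn[["Y"]])
    grid <- seq(0, 14, by = 5e-4)
    charge <- vapply(grid, function(ph) {
      sum(n_pos / (1 + 10^(ph - pka_pos))) -
        sum(n_neg / (1 + 10^(pka_neg - ph)))
    }, numeric(1))
    grid[which.min(abs(charge))]
  }
  withr::local_seed(7)
  for (s in c("DDDD", "KKKK", "MKVLAEDFWYCCH", random_aa_seq(60))) {
    expect_equal(unname(compute_extra_features(s)[["isoelectric_point"]]),
                 grid_pi(s), tolerance = 0.005)
  }
  expect_lt(compute_extra_features("DDDD")[["isoelectric_point"]],
            compute_extra_features("KKKK")[["isoelectric_point"]])
})

test_that("all 12 feature models have the printed dimensions", {
  expected <- c(di_sc = 49, di_sc_p = 57, tri_sc = 343, tri_sc_p = 351,
                tetra_sc = 2401, tetra_sc_p = 2409, di = 400, di_p = 408,
                tri = 8000, tri_p = 8008, tetra_sc_tri_p = 10409,
                all = 11201)
  for (m in model_names()) {
    sch <- feature_schema(m)
    expect_equal(sch$total_dim, unname(expected[[m]]), info = m)
    expect_length(sch$feature_names, sch$total_dim)
    expect_equal(sum(sch$blocks$dim), sch$total_dim, info = m)
  }
  expect_error(feature_schema("pentamer"), "valid models")
})

test_that("extracted matrices follow the schema and k-mer blocks sum to 1", {
  withr::local_seed(5)
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = replicate(3, random_aa_seq(60)))
  m <- extract_features(recs, "all")
  expect_equal(dim(m), c(3L, 11201L))
  expect_equal(rownames(m), recs$id)
  sch <- attr(m, "schema")
  offset <- 0
  for (i in seq_len(nrow(sch$blocks))) {
    idx <- offset + seq_len(sch$blocks$dim[i])
    if (sch$blocks$kind[i] != "extra") {
      expect_equal(unname(rowSums(m[, idx])), rep(1, 3), tolerance = 1e-9)
      expect_true(all(m[, idx] >= 0 & m[, idx] <= 1))
    }
    offset <- offset + sch$blocks$dim[i]
  }
  m2 <- extract_features(recs, "tetra_sc_tri_p")
  expect_equal(ncol(m2), 10409L)
})
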