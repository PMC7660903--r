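test_that("pairwise identity behaves like a global-alignment fraction", {
  expect_equal(pairwise_identity("MKVLAE", "MKVLAE"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("MKVL", "MKIL"), 0.75)
  # symmetric
  withr::local_seed(2)
  a <- random_aa_seq(50); b <- random_aa_seq(40)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
               tolerance = 1e-12)
})

test_that("the compiled aligner reproduces the reference aligner exactly", {
  # independent oracle: Biostrings Needleman-Wunsch under the same scoring
  withr::local_seed(3)
  mat <- diag(1, 21)
  dimnames(mat) <- list(c(virann::AA_LETTERS, "X"),
                        c(virann::AA_LETTERS, "X"))
  mat["X", "X"] <- 0
  for (i in 1:15) {
    a <- random_aa_seq(sample(20:120, 1))
    b <- random_aa_seq(sample(20:120, 1))
    ali <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(b), a, substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5, type = "global")
    ref <- Biostrings::nmatch(ali) /
      nchar(as.character(Biostrings::alignedPattern(ali)))
    expect_equal(pairwise_identity(a, b), ref, tolerance = 1e-12)
  }
})

test_that("the identity matrix matches direct pairwise computation", {
  withr::local_seed(4)
  seqs <- c(replicate(6, random_aa_seq(60)))
  m <- identity_matrix(seqs)
  expect_equal(diag(m), rep(1, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], pairwise_identity(seqs[i], seqs[j]),
                 tolerance = 1e-12)
  }
  # pruned entries are upper bounds, never underestimates
  m_pruned <- identity_matrix(seqs, at_least = 0.4)
  expect_true(all(m_pruned >= m - 1e-12))
})

test_that("greedy clustering recovers planted families", {
  # two families at ~90% within, far apart between
  withr::local_seed(9)
  corpus <- suppressWarnings(generate_corpus(synthetic_config(
    n_classes = 2, families_per_class = 2, members_per_family = 6,
    length_range = c(80, 120), rng_seed = 9,
    class_names = c("Portal", "others")
  )))
  recs <- corpus$records[corpus$records$label == "Portal", ]
  cl <- greedy_cluster(recs, 0.40)
  expect_equal(length(unique(cl$representative)), 2L)
  fam <- sub("_m\\d+$", "", cl$id)
  expect_equal(length(unique(paste(fam, cl$representative))), 2L)
  # representative is the longest member (ties by id)
  for (r in unique(cl$representative)) {
    members <- cl[cl$representative == r, ]
    expect_equal(max(nchar(members$sequence)),
                 nchar(members$sequence[members$id == r]))
  }
})

test_that("clustering degenerate cases: identical set and threshold 1", {
  same <- tibble::tibble(id = paste0("s", 1:5), sequence = rep("MKVLAEMKVL", 5))
  cl <- greedy_cluster(same, 0.40)
  expect_equal(length(unique(cl$representative)), 1L)
  withr::local_seed(13)
  distinct <- tibble::tibble(id = paste0("d", 1:6),
                             sequence = replicate(6, random_aa_seq(40)))
  cl2 <- greedy_cluster(distinct, 1.0)
  expect_equal(length(unique(cl2$representative)), 6L)
})

test_that("representative partitioning is balanced and seeded", {
  reps22 <- paste0("r", 1:22)
  p <- partition_representatives(reps22, split_config(), seed = 5)
  expect_true(all(table(p$set) == 2L))
  reps23 <- paste0("r", 1:23)
  p2 <- partition_representatives(reps23, split_config(), seed = 5)
  expect_setequal(as.integer(table(p2$set)), c(2L, 3L))
  expect_equal(sum(table(p2$set) == 3L), 1L)
  p3 <- partition_representatives(reps23, split_config(), seed = 5)
  expect_equal(p2, p3)
  expect_warning(partition_representatives(paste0("r", 1:4), split_config(),
                                           seed = 1), "empty")
})

test_that("expansion carries members with their representative", {
  clusters <- tibble::tibble(
    id = c("r1", "m1", "m2", "r2"),
    sequence = c("AAAA", "AAAC", "AACA", "WWWW"),
    representative = c("r1", "r1", "r1", "r2")
  )
  partition <- tibble::tibble(representative = c("r1", "r2"),
                              set = c("3D", "TEST"))
  ex <- expand_partition(clusters, partition, split_config())
  expect_equal(nrow(ex), 4L)
  expect_true(all(ex$set[ex$representative == "r1"] == "3D"))
  unexp <- expand_partition(clusters, partition,
                            split_config(expand = FALSE))
  expect_equal(sort(unexp$id), c("r1", "r2"))
})

test_that("exact deduplication keeps the earliest set and counts removals", {
  assignment <- tibble::tibble(
    id = c("a", "b", "c", "d", "e", "f"),
    sequence = c("MMMM", "MMMM", "KKKK", "KKKK", "WWWW", "WWWW"),
    set = c("2D", "1D", "1D", "TEST", "5D", "5D")
  )
  expect_message(out <- dedup_exact(assignment, split_config()), "3 exact")
  expect_equal(nrow(out), 3L)
  expect_true(all(c("b", "c") %in% out$id))  # 1D beats 2D and TEST
  expect_equal(out$id[out$sequence == "WWWW"], "e")  # id order within a set
})

test_that("background purging removes homologs of class sequences", {
  withr::local_seed(21)
  cls <- tibble::tibble(id = "c1", sequence = random_aa_seq(80))
  near_copy <- cls$sequence
  substr(near_copy, 1, 8) <- "WWWWWWWW"
  others <- tibble::tibble(
    id = c("o1", "o2", "o3"),
    sequence = c(cls$sequence,      # identical -> removed
                 near_copy,          # ~90% identical -> removed
                 random_aa_seq(80))  # unrelated -> retained
  )
  expect_message(kept <- purge_cross_homologs(others, cls, 0.60), "removed")
  expect_equal(kept$id, "o3")
  expect_equal(purge_cross_homologs(others, cls[0, ], 0.60), others)
})

test_that("the full split keeps homologous sequences inside one set", {
  sp <- tiny_split()
  a <- sp$assignment
  # disjoint cover of retained sequences
  expect_equal(anyDuplicated(a$id), 0L)
  expect_true(all(a$set %in% split_set_names_for_tests()))
  # all members of a cluster share one set
  expect_true(all(tapply(a$set, a$representative,
                         function(s) length(unique(s))) == 1L))
  # the central guarantee, checked exhaustively
  expect_equal(count_cross_set_homologs(sp), 0L)
})

test_that("split audit counts are monotone and the split is deterministic", {
  sp <- tiny_split()
  expect_true(all(sp$audit$clusters_at_threshold <= sp$audit$after_expansion))
  expect_true(all(sp$audit$after_expansion <= sp$audit$raw))
  expect_true(all(sp$audit$after_dedup <= sp$audit$after_expansion))
  sp2 <- suppressWarnings(suppressMessages(
    build_split(tiny_corpus()$records, split_config(rng_seed = 3),
                classes = unique(tiny_corpus()$records$label))
  ))
  expect_equal(sp$assignment, sp2$assignment)
  # unexpanded baseline keeps exactly the representatives, same sets
  sp_unexp <- suppressWarnings(suppressMessages(
    build_split(tiny_corpus()$records,
                split_config(rng_seed = 3, expand = FALSE),
                classes = unique(tiny_corpus()$records$label))
  ))
  expect_true(all(sp_unexp$assignment$id == sp_unexp$assignment$representative))
  both <- dplyr::inner_join(
    sp$assignment[sp$assignment$id == sp$assignment$representative, ],
    sp_unexp$assignment, by = "id"
  )
  expect_equal(both$set.x, both$set.y)
})

test_that("a class with zero sequences is a named error", {
  recs <- tiny_corpus()$records
  expect_error(
    suppressWarnings(build_split(recs, split_config(),
                                 classes = c(unique(recs$label), "Collar"))),
    "Collar")
})

test_that("split manifests round-trip through TSV", {
  sp <- tiny_split()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(sp, tf)
  man <- read_split_manifest(tf)
  expect_equal(nrow(man), nrow(sp$assignment))
  expect_named(man, c("id", "class", "cluster_rep", "set"))
  expect_equal(man$set, sp$assignment$set)
})
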