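# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 4-class corpus with clear family structure (80 sequences)
tiny_corpus <- function() {
  memo("tiny_corpus", suppressWarnings(generate_corpus(synthetic_config(
    n_classes = 4, families_per_class = 4, members_per_family = 5,
    length_range = c(80, 150), rng_seed = 3,
    class_names = c("Major capsid", "Portal", "Major tail", "others")
  ))))
}

tiny_split <- function() {
  memo("tiny_split", suppressWarnings(suppressMessages(
    build_split(tiny_corpus()$records, split_config(rng_seed = 3),
                classes = unique(tiny_corpus()$records$label))
  )))
}

# 3-class corpus plus a hand-dealt 10-fold split (homology layout is not the
# point here; family-blocked round-robin keeps folds balanced)
ensemble_fixture <- function() {
  memo("ensemble_fixture", {
    corpus <- suppressWarnings(generate_corpus(synthetic_config(
      n_classes = 3, families_per_class = 5, members_per_family = 8,
      length_range = c(70, 120), rng_seed = 11,
      class_names = c("Major capsid", "Portal", "others")
    )))
    recs <- corpus$records
    sets <- split_set_names_for_tests()
    fam <- sub("_m\\d+$", "", recs$id)
    fam_set <- stats::setNames(rep_len(sets, length(unique(fam))),
                               sample(unique(fam)))
    assignment <- tibble::tibble(
      id = recs$id, sequence = recs$sequence, label = recs$label,
      representative = fam, set = unname(fam_set[fam])
    )
    split <- structure(list(assignment = assignment,
                            config = split_config(rng_seed = 11)),
                       class = "split_assignment")
    list(corpus = corpus, split = split,
         classes = c("Major capsid", "Portal", "others"))
  })
}

split_set_names_for_tests <- function() c(paste0(1:10, "D"), "TEST")

small_mlp_config <- function(n_features, n_classes, seed = 1) {
  mlp_config(n_features = n_features, n_classes = n_classes,
             hidden_width = 24, max_epochs = 60, batch_size = 64,
             rng_seed = seed)
}

trained_tiny_ensemble <- function() {
  memo("trained_tiny_ensemble", {
    fx <- ensemble_fixture()
    withr::with_seed(11, suppressWarnings(cross_validate(
      fx$corpus$records, fx$split, "di_sc_p",
      small_mlp_config(feature_schema("di_sc_p")$total_dim, 3),
      classes = fx$classes
    )))
  })
}

# naive dictionary-count oracle for k-mer frequencies
naive_kmer_freq <- function(sequence, k, letters_set) {
  n <- nchar(sequence)
  nm_grid <- do.call(expand.grid,
                     c(rep(list(letters_set), k),
                       list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  nm <- sort(do.call(paste0, nm_grid))
  counts <- stats::setNames(numeric(length(nm)), nm)
  if (n < k) return(counts)
  windows <- substring(sequence, 1:(n - k + 1), k:n)
  valid <- windows %in% nm
  if (!any(valid)) return(counts)
  tab <- table(windows[valid])
  counts[names(tab)] <- as.numeric(tab)
  counts / sum(counts)
}

random_aa_seq <- function(len) {
  paste(sample(virann::AA_LETTERS, len, replace = TRUE), collapse = "")
}
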