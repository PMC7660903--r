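# Synthetic protein corpora with controlled homology structure.
#
# Each class holds several families; a family is an ancestor sequence plus
# mutated copies. Within-family identity is controlled by the substitution
# rate, between-family identity is capped by rejection sampling, and class
# identity is carried by a compositional tilt (class-preferred residues are
# enriched), i.e. exactly the kind of signal composition-based classifiers
# can detect. The background class "others" samples from the untilted
# profile. The generator emits standard record tibbles (and FASTA/TSV via
# seqio), so every pipeline stage is testable offline.

# background residue profile: rounded UniProt-like average frequencies
BACKGROUND_PROFILE <- c(
  A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039, G = 0.071,
  H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.040,
  P = 0.047, Q = 0.039, R = 0.055, S = 0.066, T = 0.053, V = 0.069,
  W = 0.011, Y = 0.029
)

#' Synthetic corpus configuration
#'
#' Defaults describe a corpus that exercises the full pipeline: 11 classes
#' (the last is the background "others"), 6 families of 6 members each,
#' within-family identity 0.90 — far above the 0.40 clustering threshold —
#' and between-family ancestor identity capped at 0.25 — far below it, so
#' the split's no-cross-set-homologs guarantee is exactly testable. The
#' class signal is a Dirichlet-style tilt: each non-background class enriches
#' 4 preferred residues by `exp(class_bias_strength)` (about 2.7-fold at the
#' default 1.0).
#'
#' @param n_classes Number of classes including the background (default 11).
#' @param families_per_class Families per class (default 6).
#' @param members_per_family Sequences per family (default 6).
#' @param length_range Ancestor length range in residues (default 80-600).
#' @param within_family_identity Target member-to-ancestor identity
#'   (default 0.90); the substitution rate is its complement.
#' @param between_family_identity_max Cap on ancestor pairwise identity
#'   (default 0.25), enforced by rejection sampling.
#' @param class_bias_strength Log-enrichment of class-preferred residues
#'   (default 1.0; 0 removes all class signal — the negative control).
#' @param indel_rate Per-site single-residue indel rate (default 0.01), kept
#'   low so alignment identity tracks substitution identity.
#' @param rng_seed Seed; corpora are byte-identical for a fixed seed.
#' @param class_names Optional class names (last one is the background);
#'   defaults to [class_list()] when `n_classes` is 11.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 11, families_per_class = 6,
                             members_per_family = 6,
                             length_range = c(80, 600),
                             within_family_identity = 0.90,
                             between_family_identity_max = 0.25,
                             class_bias_strength = 1.0, indel_rate = 0.01,
                             rng_seed = 1, class_names = NULL) {
  stopifnot(n_classes >= 2, families_per_class >= 1,
            members_per_family >= 1, length_range[1] >= 2,
            within_family_identity > 0, within_family_identity <= 1,
            between_family_identity_max > 0,
            class_bias_strength >= 0, indel_rate >= 0)
  if (is.null(class_names)) {
    class_names <- if (n_classes == 11) {
      class_list()
    } else {
      c(paste0("class", seq_len(n_classes - 1)), "others")
    }
  }
  stopifnot(length(class_names) == n_classes)
  structure(list(n_classes = as.integer(n_classes),
                 families_per_class = as.integer(families_per_class),
                 members_per_family = as.integer(members_per_family),
                 length_range = as.integer(length_range),
                 within_family_identity = within_family_identity,
                 between_family_identity_max = between_family_identity_max,
                 class_bias_strength = class_bias_strength,
                 indel_rate = indel_rate, rng_seed = as.integer(rng_seed),
                 class_names = class_names),
            class = "synthetic_config")
}

sample_profile_seq <- function(len, profile) {
  paste(sample(AA_LETTERS, len, replace = TRUE, prob = profile),
        collapse = "")
}

mutate_sequence <- function(sequence, sub_rate, indel_rate, profile) {
  letters <- strsplit(sequence, "")[[1]]
  n <- length(letters)
  n_sub <- stats::rbinom(1, n, sub_rate)
  if (n_sub > 0) {
    pos <- sample.int(n, n_sub)
    for (p in pos) {
      choices <- setdiff(AA_LETTERS, letters[p])
      letters[p] <- sample(choices, 1,
                           prob = profile[choices] / sum(profile[choices]))
    }
  }
  n_indel <- stats::rbinom(1, n, indel_rate)
  for (i in seq_len(n_indel)) {
    if (length(letters) <= 2) break
    p <- sample.int(length(letters), 1)
    if (stats::runif(1) < 0.5) {
      letters <- letters[-p]
    } else {
      letters <- append(letters,
                        sample(AA_LETTERS, 1, prob = BACKGROUND_PROFILE), p)
    }
  }
  paste(letters, collapse = "")
}

#' Generate a labeled synthetic corpus
#'
#' See [synthetic_config()] for the generative model. Family ancestors are
#' resampled (up to 50 attempts each) until their identity to every
#' previously accepted ancestor is at or below the configured cap.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (tibble `id`, `description`, `sequence`,
#'   `label`), `truth` (tibble `id`, `label`) and `config`.
#' @examples
#' corpus <- generate_corpus(synthetic_config(
#'   n_classes = 3, families_per_class = 2, members_per_family = 3,
#'   length_range = c(60, 90), rng_seed = 42))
#' dplyr::count(corpus$records, label)
#' @export
generate_corpus <- function(config = synthetic_config()) {
  set.seed(config$rng_seed)
  profiles <- lapply(seq_len(config$n_classes), function(ci) {
    prof <- BACKGROUND_PROFILE
    if (ci < config$n_classes && config$class_bias_strength > 0) {
      preferred <- sample(AA_LETTERS, 4)
      prof[preferred] <- prof[preferred] * exp(config$class_bias_strength)
    }
    prof / sum(prof)
  })
  sub_rate <- 1 - config$within_family_identity
  accepted_ancestors <- character(0)
  rows <- list()
  for (ci in seq_len(config$n_classes)) {
    cls <- config$class_names[ci]
    cls_tag <- gsub("[^A-Za-z0-9]+", "", cls)
    for (fi in seq_len(config$families_per_class)) {
      len <- sample(seq(config$length_range[1], config$length_range[2]), 1)
      anc <- NULL
      for (try in 1:50) {
        cand <- sample_profile_seq(len, profiles[[ci]])
        ok <- length(accepted_ancestors) == 0 ||
          all(identity_to_set(cand, accepted_ancestors) <=
                config$between_family_identity_max)
        if (ok) { anc <- cand; break }
      }
      if (is.null(anc)) {
        stop("could not sample a sufficiently divergent ancestor for class '",
             cls, "' family ", fi,
             "; try longer sequences or fewer families")
      }
      accepted_ancestors <- c(accepted_ancestors, anc)
      seqs <- c(anc, vapply(seq_len(config$members_per_family - 1),
                            function(m) mutate_sequence(anc, sub_rate,
                                                        config$indel_rate,
                                                        profiles[[ci]]),
                            character(1)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sprintf("%s_f%02d_m%02d", cls_tag, fi,
                     seq_len(config$members_per_family)),
        description = paste("synthetic", cls, "family", fi),
        sequence = seqs, label = cls
      )
    }
  }
  records <- dplyr::bind_rows(rows)
  list(records = records,
       truth = records[, c("id", "label")], config = config)
}

#' A tiny worked fixture with frozen expectations
#'
#' A deterministic corpus of under 60 sequences (3 classes, 2 families
#' each, with 5 planted exact-duplicate pairs) whose greedy clustering at
#' 40% identity was computed once with the brute-force all-pairs oracle and
#' frozen in `inst/extdata/worked_fixture_clusters.tsv`. Also carries a
#' hand-planted 15-item prediction/truth pattern (3-class confusion matrix
#' with rows (5,0,0), (1,4,0), (0,2,3)) whose metrics are hand-countable:
#' precisions 5/6, 4/6, 1; recalls 1, 0.8, 0.6; accuracy 12/15.
#'
#' @return List with `records`, `expected_clusters` (tibble `id`,
#'   `representative`), `planted_predictions`, `planted_truth`,
#'   `planted_classes`.
#' @export
generate_worked_fixture <- function() {
  corpus <- generate_corpus(synthetic_config(
    n_classes = 3, families_per_class = 2, members_per_family = 8,
    length_range = c(60, 90), rng_seed = 20260101 %% 2^31,
    class_names = c("Major capsid", "Portal", "others")
  ))
  records <- corpus$records
  # plant 5 exact duplicates: copies of the first member of 5 families
  dup_src <- records[!duplicated(paste(records$label,
                                       sub("_m.*$", "", records$id))), ]
  dup_src <- utils::head(dup_src, 5)
  dups <- tibble::tibble(
    id = paste0(dup_src$id, "_dup"),
    description = paste(dup_src$description, "(exact duplicate)"),
    sequence = dup_src$sequence, label = dup_src$label
  )
  records <- dplyr::bind_rows(records, dups)

  path <- system.file("extdata", "worked_fixture_clusters.tsv",
                      package = "virann")
  expected <- if (nzchar(path)) {
    readr::read_tsv(path, col_types = "cc", progress = FALSE)
  }

  cl3 <- c("A", "B", "C")
  planted_truth <- rep(cl3, times = c(5, 5, 5))
  planted_pred <- c(rep("A", 5),              # class A: all correct
                    "A", rep("B", 4),         # class B: one leaks to A
                    rep("B", 2), rep("C", 3)) # class C: two leak to B
  ids <- sprintf("q%02d", seq_along(planted_truth))
  list(records = records, expected_clusters = expected,
       planted_predictions = tibble::tibble(
         id = ids, predicted_class = planted_pred,
         escore = rep(10, length(ids))),
       planted_truth = tibble::tibble(id = ids, label = planted_truth),
       planted_classes = cl3)
}
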