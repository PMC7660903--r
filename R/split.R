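# Homology-aware cluster-expansion split.
#
# The pipeline that keeps homologous proteins out of different sets while
# retaining all sequence diversity: per class, greedy-cluster at 40%
# identity, deal cluster representatives into 11 subsets (10 cross-
# validation sets plus TEST), expand each representative back to its full
# cluster inside its subset, merge the classes set-wise, remove exact
# duplicates, and (beforehand) purge background sequences with >= 60%
# identity to any class sequence.

SET_NAMES <- c(paste0(1:10, "D"), "TEST")

#' Split configuration
#'
#' @param cluster_identity Identity threshold for within-class clustering
#'   (default 0.40).
#' @param purge_identity Threshold for cross-database purging of background
#'   sequences (default 0.60).
#' @param n_validation_sets Number of cross-validation sets (default 10; the
#'   split always adds one TEST set).
#' @param rng_seed Seed driving the partition shuffle.
#' @param expand Expand representatives back to full clusters (default
#'   `TRUE`); `FALSE` keeps representatives only (the unexpanded baseline).
#' @return Object of class `split_config`.
#' @export
split_config <- function(cluster_identity = 0.40, purge_identity = 0.60,
                         n_validation_sets = 10, rng_seed = 1,
                         expand = TRUE) {
  stopifnot(purge_identity > 0, purge_identity <= 1,
            cluster_identity > 0, cluster_identity <= 1,
            n_validation_sets >= 1)
  structure(list(cluster_identity = cluster_identity,
                 purge_identity = purge_identity,
                 n_validation_sets = as.integer(n_validation_sets),
                 rng_seed = as.integer(rng_seed), expand = isTRUE(expand)),
            class = "split_config")
}

split_set_names <- function(config) {
  c(paste0(seq_len(config$n_validation_sets), "D"), "TEST")
}

#' Greedy incremental clustering at an identity threshold
#'
#' CD-HIT-style: sequences are sorted by decreasing length (ties by id);
#' each sequence joins the first existing cluster whose representative it
#' matches at `>= threshold` global-alignment identity, otherwise it founds
#' a new cluster. Representatives are therefore the longest members. A
#' letter-multiset upper bound prunes alignments that cannot reach the
#' threshold.
#'
#' @param records Record tibble (columns `id`, `sequence`), typically all of
#'   one class.
#' @param threshold Identity threshold in (0, 1].
#' @return Tibble `id`, `sequence`, `representative` (the representative's
#'   id; representatives map to themselves), in clustering order.
#' @export
greedy_cluster <- function(records, threshold) {
  stopifnot(threshold > 0, threshold <= 1, nrow(records) > 0)
  ord <- order(-nchar(records$sequence), records$id)
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  cnt <- letter_count_matrix(seqs)
  lens <- nchar(seqs)
  rep_idx <- integer(0)              # indices (into ord) of representatives
  assignment <- character(length(ids))
  for (i in seq_along(ids)) {
    joined <- NA_character_
    if (length(rep_idx) > 0) {
      bound <- colSums(pmin(t(cnt[rep_idx, , drop = FALSE]), cnt[i, ])) /
        pmax(lens[rep_idx], lens[i])
      cand <- rep_idx[bound >= threshold]
      if (length(cand) > 0) {
        idv <- identity_to_set(seqs[i], seqs[cand])
        hit <- which(idv >= threshold)
        if (length(hit) > 0) joined <- ids[cand[hit[1]]]
      }
    }
    if (is.na(joined)) {
      rep_idx <- c(rep_idx, i)
      joined <- ids[i]
    }
    assignment[i] <- joined
  }
  tibble::tibble(id = ids, sequence = seqs, representative = assignment)
}

#' Partition cluster representatives into the split sets
#'
#' Representatives are shuffled with the seeded generator and dealt
#' round-robin, so per-class set sizes (counted in clusters) differ by at
#' most one.
#'
#' @param representatives Character vector of representative ids (one per
#'   cluster).
#' @param config A [split_config()].
#' @param seed Optional seed set locally before the shuffle; by default the
#'   current RNG stream is used (as inside [build_split()], which seeds once
#'   from `config$rng_seed`).
#' @return Tibble `representative`, `set`.
#' @export
partition_representatives <- function(representatives, config = split_config(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # deal into a shuffled set order so classes with fewer clusters than sets
  # still spread over random sets rather than always filling 1D..nD
  sets <- sample(split_set_names(config))
  n <- length(representatives)
  if (n < length(sets)) {
    warning("only ", n, " cluster(s) for ", length(sets),
            " sets; some sets will be empty for this class")
  }
  shuffled <- representatives[sample.int(n)]
  tibble::tibble(representative = shuffled,
                 set = rep_len(sets, n))
}

#' Expand a representative partition to all cluster members
#'
#' Every member inherits the set of its cluster's representative. With
#' `expand = FALSE` in the configuration, only the representatives are
#' retained (the unexpanded baseline split).
#'
#' @param clusters Tibble from [greedy_cluster()].
#' @param partition Tibble from [partition_representatives()].
#' @param config A [split_config()].
#' @return Tibble `id`, `sequence`, `representative`, `set`.
#' @export
expand_partition <- function(clusters, partition, config = split_config()) {
  out <- dplyr::inner_join(clusters, partition, by = "representative")
  if (!config$expand) out <- dplyr::filter(out, .data$id == .data$representative)
  out
}

#' Remove exact duplicate sequences across a split
#'
#' Among byte-identical sequences, the survivor is the first by (set order,
#' id order); all others are dropped wherever they occur. The number of
#' removals is reported in a message.
#'
#' @param assignment Tibble with columns `id`, `sequence`, `set` (and any
#'   others, preserved).
#' @param config A [split_config()] (defines set order).
#' @return Deduplicated tibble.
#' @export
dedup_exact <- function(assignment, config = split_config()) {
  set_rank <- match(assignment$set, split_set_names(config))
  ord <- order(set_rank, assignment$id)
  keep_first <- !duplicated(assignment$sequence[ord])
  removed <- sum(!keep_first)
  if (removed > 0) message(removed, " exact duplicate sequence(s) removed")
  assignment[ord[keep_first], , drop = FALSE]
}

#' Purge background sequences homologous to class sequences
#'
#' Co-clusters the background ("others") records together with all class
#' records at `threshold` and drops every background record whose cluster
#' contains any class record.
#'
#' @param others Record tibble of background sequences.
#' @param classes_records Record tibble of all class sequences.
#' @param threshold Identity threshold (default 0.60).
#' @return The retained subset of `others`.
#' @export
purge_cross_homologs <- function(others, classes_records, threshold = 0.60) {
  if (nrow(classes_records) == 0 || nrow(others) == 0) return(others)
  combined <- tibble::tibble(
    id = c(paste0("O::", others$id), paste0("C::", classes_records$id)),
    sequence = c(others$sequence, classes_records$sequence)
  )
  cl <- greedy_cluster(combined, threshold)
  cl$is_class <- startsWith(cl$id, "C::")
  tainted <- unique(cl$representative[cl$is_class])
  keep_ids <- sub("^O::", "", cl$id[!cl$is_class & !(cl$representative %in% tainted)])
  n_removed <- nrow(others) - length(keep_ids)
  if (n_removed > 0) {
    message(n_removed, " background sequence(s) removed as homologous to a class sequence")
  }
  others[others$id %in% keep_ids, , drop = FALSE]
}

#' Build the full homology-aware split
#'
#' Runs the whole pipeline: purge the background class against the labeled
#' classes, then per class cluster / partition / expand, merge all classes
#' set-wise, and remove exact duplicates. Returns the assignment with an
#' audit table of per-class counts at each stage (raw, clusters at the 40%
#' threshold, after expansion and 100% deduplication).
#'
#' @param records Labeled record tibble (columns `id`, `sequence`, `label`);
#'   the background class is recognized by the label `"others"`.
#' @param config A [split_config()].
#' @param classes Class names expected in `label`; a class with zero records
#'   is an error naming it.
#' @return Object of class `split_assignment`: list with `assignment`
#'   (tibble `id`, `sequence`, `label`, `representative`, `set`), `audit`
#'   (per-class stage counts), `config`.
#' @examples
#' \donttest{
#' corpus <- generate_corpus(synthetic_config(n_classes = 3,
#'   families_per_class = 12, members_per_family = 2, rng_seed = 7))
#' sp <- build_split(corpus$records, split_config(rng_seed = 7),
#'                   classes = unique(corpus$records$label))
#' table(sp$assignment$set)
#' }
#' @export
build_split <- function(records, config = split_config(),
                        classes = class_list()) {
  stopifnot(all(c("id", "sequence", "label") %in% names(records)))
  if (anyNA(records$label)) stop("all records must be labeled to build a split")
  missing_cls <- setdiff(classes, unique(records$label))
  if (length(missing_cls) > 0) {
    stop("class with zero sequences: ", paste(missing_cls, collapse = ", "))
  }
  has_others <- "others" %in% classes
  if (has_others) {
    others <- records[records$label == "others", , drop = FALSE]
    class_recs <- records[records$label != "others", , drop = FALSE]
    others <- purge_cross_homologs(others, class_recs, config$purge_identity)
    records <- dplyr::bind_rows(class_recs, others)
  }
  set.seed(config$rng_seed)
  pieces <- list(); audit <- list()
  for (cls in classes) {
    recs <- records[records$label == cls, , drop = FALSE]
    if (nrow(recs) == 0) stop("class with zero sequences after purging: ", cls)
    cl <- greedy_cluster(recs, config$cluster_identity)
    reps <- unique(cl$representative)
    part <- partition_representatives(reps, config)
    exp <- expand_partition(cl, part, config)
    exp$label <- cls
    pieces[[cls]] <- exp
    audit[[cls]] <- tibble::tibble(
      class = cls, raw = nrow(recs), clusters_at_threshold = length(reps),
      after_expansion = nrow(exp)
    )
  }
  merged <- dplyr::bind_rows(pieces)
  merged <- dedup_exact(merged, config)
  audit <- dplyr::bind_rows(audit)
  dedup_counts <- dplyr::count(merged, .data$label, name = "after_dedup")
  audit <- dplyr::left_join(audit, dedup_counts,
                            by = c(class = "label"))
  structure(list(
    assignment = tibble::as_tibble(merged[, c("id", "sequence", "label",
                                              "representative", "set")]),
    audit = audit, config = config
  ), class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>", nrow(x$assignment), "sequences in",
      length(unique(x$assignment$set)), "sets\n")
  print(table(x$assignment$set)[split_set_names(x$config)])
  invisible(x)
}

#' Write / read a split manifest
#'
#' The manifest is a TSV `id, class, cluster_rep, set` with a header row.
#'
#' @param split A `split_assignment`.
#' @param path Output path.
#' @return `path` invisibly (write); tibble (read).
#' @export
write_split_manifest <- function(split, path) {
  man <- split$assignment[, c("id", "label", "representative", "set")]
  names(man) <- c("id", "class", "cluster_rep", "set")
  readr::write_tsv(man, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Count cross-set homologous pairs
#'
#' The split's central guarantee: no two sequences in different sets share
#' `>= threshold` identity. This audit counts violating pairs exhaustively
#' (with exact upper-bound pruning), for use on corpora of moderate size.
#'
#' @param split A `split_assignment`.
#' @param threshold Identity threshold; defaults to the split's clustering
#'   threshold.
#' @return Number of cross-set pairs at or above the threshold.
#' @export
count_cross_set_homologs <- function(split,
                                     threshold = split$config$cluster_identity) {
  a <- split$assignment
  m <- identity_matrix(a$sequence, at_least = threshold)
  cross <- outer(a$set, a$set, `!=`)
  sum(m[upper.tri(m)] >= threshold & cross[upper.tri(cross)])
}
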