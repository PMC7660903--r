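# Ensemble scoring, calibration and evaluation.
#
# The ensemble score of a query is the per-class sum of the softmax outputs
# of the ten cross-validation networks, so scores range from 0 to the member
# count (10) and sum to the member count over the classes. The query is
# assigned the arg-max class; an optional abstention threshold marks
# low-scoring queries "not classified". Confidence calibration turns a
# (class, score) pair into the fraction of TEST queries predicted as that
# class at that score or higher that were correct.

#' Sum member softmax outputs into ensemble scores
#'
#' @param member_softmax Array `members x sequences x classes` from
#'   [predict_members()]; every member/sequence row must sum to 1.
#' @param n_members Expected member count (default: first dimension).
#' @return Matrix `sequences x classes`; each row sums to the member count.
#' @export
ensemble_score <- function(member_softmax, n_members = NULL) {
  stopifnot(length(dim(member_softmax)) == 3)
  if (!is.null(n_members) && dim(member_softmax)[1] != n_members) {
    stop("expected ", n_members, " members, got ", dim(member_softmax)[1])
  }
  row_sums <- apply(member_softmax, c(1, 2), sum)
  if (any(abs(row_sums - 1) > 1e-5)) {
    stop("member softmax rows must sum to 1")
  }
  apply(member_softmax, c(2, 3), sum)
}

#' Classify ensemble scores
#'
#' Arg-max over classes with a deterministic tie-break (the earlier class in
#' the class-list column order wins). With `abstain_threshold` set, queries
#' whose top score falls below it are labeled `"not classified"`.
#'
#' @param scores Matrix `sequences x classes` from [ensemble_score()]
#'   (column names are the class list).
#' @param abstain_threshold Optional minimum top score.
#' @return Tibble `predicted_class`, `escore` (score of the predicted class,
#'   reported even when abstaining).
#' @export
classify_scores <- function(scores, abstain_threshold = NULL) {
  top_idx <- apply(scores, 1, which.max)
  top_score <- scores[cbind(seq_len(nrow(scores)), top_idx)]
  pred <- colnames(scores)[top_idx]
  if (!is.null(abstain_threshold)) {
    pred[top_score < abstain_threshold] <- "not classified"
  }
  tibble::tibble(predicted_class = pred, escore = top_score)
}

#' Score protein records with a trained ensemble
#'
#' Extracts features under the ensemble's schema, runs all members, sums
#' softmax outputs and classifies. When the ensemble carries a calibrated
#' confidence table, each prediction also gets its confidence.
#'
#' @param ensemble A `virion_ensemble`.
#' @param records Record tibble (columns `id`, `sequence`).
#' @param abstain_threshold Optional minimum top score (see
#'   [classify_scores()]).
#' @param features Optional precomputed feature matrix.
#' @return Tibble: `id`, `predicted_class`, `escore`, `confidence` (NA
#'   without calibration), then one `score_<class>` column per class.
#' @export
score_proteins <- function(ensemble, records, abstain_threshold = NULL,
                           features = NULL) {
  if (is.null(features)) features <- extract_features(records, ensemble$schema)
  arr <- predict_members(ensemble, features)
  scores <- ensemble_score(arr)
  cls <- classify_scores(scores, abstain_threshold)
  conf <- rep(NA_real_, nrow(records))
  if (!is.null(ensemble$confidence)) {
    conf <- confidence_lookup(ensemble$confidence, cls$predicted_class,
                              cls$escore)
  }
  score_cols <- tibble::as_tibble(scores)
  names(score_cols) <- paste0("score_", gsub("[^A-Za-z0-9]+", "_",
                                             colnames(scores)))
  dplyr::bind_cols(
    tibble::tibble(id = records$id, predicted_class = cls$predicted_class,
                   escore = cls$escore, confidence = conf),
    score_cols
  )
}

#' @export
predict.virion_ensemble <- function(object, records,
                                    abstain_threshold = NULL, ...) {
  score_proteins(object, records, abstain_threshold = abstain_threshold)
}

# per-class precision/recall/F1 plus macro, weighted and accuracy
classification_metrics <- function(pred, truth, classes) {
  per_class <- lapply(classes, function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble::tibble(class = cls, precision = precision, recall = recall,
                   f1 = f1, support = tp + fn)
  })
  per_class <- dplyr::bind_rows(per_class)
  present <- per_class$support > 0
  macro <- tibble::tibble(
    precision = mean(per_class$precision[present]),
    recall = mean(per_class$recall[present]),
    f1 = mean(per_class$f1[present])
  )
  w <- per_class$support / sum(per_class$support)
  weighted <- tibble::tibble(
    precision = sum(w * per_class$precision),
    recall = sum(w * per_class$recall),
    f1 = sum(w * per_class$f1)
  )
  list(per_class = per_class, macro = macro, weighted = weighted,
       accuracy = mean(pred == truth))
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param pred,truth Character vectors of predicted and true classes.
#' @param classes Class list fixing row/column order; predictions outside it
#'   (e.g. `"not classified"`) get their own column.
#' @param normalize Row-normalize so every row sums to 1 (rows with zero
#'   support stay zero).
#' @return Numeric matrix.
#' @export
confusion_matrix <- function(pred, truth, classes = sort(unique(truth)),
                             normalize = FALSE) {
  pred_levels <- c(classes, setdiff(unique(pred), classes))
  m <- table(factor(truth, levels = classes),
             factor(pred, levels = pred_levels))
  m <- unclass(m)
  dimnames(m) <- list(truth = rownames(m), predicted = colnames(m))
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  m
}

#' Build the per-class score-to-confidence table
#'
#' For every class and score threshold `s`, the confidence is the fraction
#' of TEST queries predicted as that class with ensemble score `>= s` that
#' were correctly classified. The threshold grid is 0 to the member count in
#' steps of 0.1 plus all observed scores; thresholds above a class's highest
#' observed score carry the last defined value forward and are flagged
#' `sparse`. At the minimal threshold the confidence equals the class's
#' precision on the TEST set.
#'
#' @param predictions Prediction tibble from [score_proteins()] (columns
#'   `id`, `predicted_class`, `escore`).
#' @param truth Tibble `id`, `label` (or named character vector keyed by id).
#' @param classes Class list; a class never predicted gets an all-sparse row
#'   set.
#' @param n_members Score ceiling (default 10).
#' @return Tibble of class `confidence_table`: `class`, `threshold`,
#'   `confidence`, `n_predicted`, `sparse`.
#' @export
build_confidence_table <- function(predictions, truth,
                                   classes = class_list(), n_members = 10) {
  truth_vec <- truth_as_vector(truth)
  missing_ids <- setdiff(predictions$id, names(truth_vec))
  if (length(missing_ids) > 0) {
    stop("no truth label for id(s): ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  true_class <- truth_vec[predictions$id]
  grid <- sort(unique(c(seq(0, n_members, by = 0.1),
                        round(predictions$escore, 10))))
  rows <- lapply(classes, function(cls) {
    sel <- predictions$predicted_class == cls
    sc <- predictions$escore[sel]
    ok <- true_class[sel] == cls
    conf <- rep(NA_real_, length(grid))
    n_pred <- integer(length(grid))
    for (i in seq_along(grid)) {
      at <- sc >= grid[i]
      n_pred[i] <- sum(at)
      if (n_pred[i] > 0) conf[i] <- sum(ok & at) / n_pred[i]
    }
    sparse <- n_pred == 0
    # carry the nearest lower defined value into empty bins
    filled <- conf
    last <- NA_real_
    for (i in seq_along(filled)) {
      if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
    }
    tibble::tibble(class = cls, threshold = grid, confidence = filled,
                   n_predicted = n_pred, sparse = sparse)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("confidence_table", class(out))
  out
}

truth_as_vector <- function(truth) {
  if (is.data.frame(truth)) {
    lab_col <- intersect(c("label", "class"), names(truth))[1]
    stats::setNames(truth[[lab_col]], truth$id)
  } else {
    truth
  }
}

#' Look up calibrated confidences
#'
#' For each (class, score) pair returns the confidence at the largest
#' tabulated threshold not exceeding the score. Classes absent from the
#' table (including `"not classified"`) give `NA`.
#'
#' @param table A `confidence_table`.
#' @param class Character vector of predicted classes.
#' @param score Numeric vector of ensemble scores.
#' @return Numeric vector of confidences in `[0, 1]` (or `NA`).
#' @export
confidence_lookup <- function(table, class, score) {
  vapply(seq_along(class), function(i) {
    rows <- table[table$class == class[i] & table$threshold <= score[i] &
                    !is.na(table$confidence), ]
    if (nrow(rows) == 0) return(NA_real_)
    rows$confidence[which.max(rows$threshold)]
  }, numeric(1))
}

#' Attach a calibrated confidence table to an ensemble
#'
#' Scores the TEST-set records and builds the confidence table from them.
#'
#' @param ensemble A `virion_ensemble`.
#' @param records Labeled record tibble covering the TEST set.
#' @param split The `split_assignment` that trained the ensemble.
#' @return The ensemble with `$confidence` set.
#' @export
calibrate_confidence <- function(ensemble, records, split) {
  test_ids <- split$assignment$id[split$assignment$set == "TEST"]
  test_recs <- records[records$id %in% test_ids, , drop = FALSE]
  if (nrow(test_recs) == 0) stop("split has no TEST sequences")
  preds <- score_proteins(ensemble, test_recs)
  ensemble$confidence <- build_confidence_table(
    preds, stats::setNames(test_recs$label, test_recs$id),
    classes = ensemble$classes, n_members = length(ensemble$members)
  )
  ensemble
}

#' Evaluate predictions at one or more score cutoffs
#'
#' At cutoff 0 all queries count. At cutoff `s`, queries with top score
#' below `s` are excluded entirely ("not classified") and the retained
#' fraction is reported. ROC curves are computed once on the full set,
#' one-vs-rest per class, with `score/n_members` as the graded statistic.
#'
#' @param predictions Prediction tibble from [score_proteins()] (per-class
#'   `score_*` columns required for ROC; ROC is skipped without them).
#' @param truth Tibble `id`, `label` or named vector keyed by id.
#' @param score_cutoffs Numeric cutoffs (default 0).
#' @param classes Class list.
#' @param n_members Score ceiling (default 10).
#' @return Object of class `virann_metrics`: `per_class` (tibble over
#'   cutoffs), `summary` (accuracy, macro/weighted averages, retained
#'   fraction per cutoff), `confusion` (list of matrices keyed by cutoff),
#'   `roc` (tibble `class`, `auc`, `curve`).
#' @export
evaluate_predictions <- function(predictions, truth, score_cutoffs = 0,
                                 classes = class_list(), n_members = 10) {
  truth_vec <- truth_as_vector(truth)
  true_class <- truth_vec[predictions$id]
  if (anyNA(true_class)) stop("missing truth label for some predictions")
  per_class <- list(); summary <- list(); confusion <- list()
  for (s in score_cutoffs) {
    keep <- predictions$escore >= s
    key <- format(s)
    if (!any(keep)) {
      warning("no predictions retained at cutoff ", s)
      summary[[key]] <- tibble::tibble(
        cutoff = s, n_retained = 0L, retained_fraction = 0,
        accuracy = NA_real_, macro_precision = NA_real_,
        macro_recall = NA_real_, macro_f1 = NA_real_,
        weighted_precision = NA_real_, weighted_recall = NA_real_,
        weighted_f1 = NA_real_
      )
      next
    }
    m <- classification_metrics(predictions$predicted_class[keep],
                                true_class[keep], classes)
    per_class[[key]] <- dplyr::mutate(m$per_class, cutoff = s, .before = 1)
    summary[[key]] <- tibble::tibble(
      cutoff = s, n_retained = sum(keep),
      retained_fraction = mean(keep), accuracy = m$accuracy,
      macro_precision = m$macro$precision, macro_recall = m$macro$recall,
      macro_f1 = m$macro$f1,
      weighted_precision = m$weighted$precision,
      weighted_recall = m$weighted$recall, weighted_f1 = m$weighted$f1
    )
    confusion[[key]] <- confusion_matrix(predictions$predicted_class[keep],
                                         true_class[keep], classes)
  }
  roc <- compute_roc(predictions, true_class, classes, n_members)
  structure(list(per_class = dplyr::bind_rows(per_class),
                 summary = dplyr::bind_rows(summary),
                 confusion = confusion, roc = roc,
                 classes = classes),
            class = "virann_metrics")
}

compute_roc <- function(predictions, true_class, classes, n_members) {
  score_cols <- paste0("score_", gsub("[^A-Za-z0-9]+", "_", classes))
  if (!all(score_cols %in% names(predictions))) return(NULL)
  rows <- lapply(seq_along(classes), function(i) {
    response <- as.integer(true_class == classes[i])
    if (length(unique(response)) < 2) {
      return(tibble::tibble(class = classes[i], auc = NA_real_,
                            curve = list(NULL)))
    }
    r <- pROC::roc(response, predictions[[score_cols[i]]] / n_members,
                   quiet = TRUE, direction = "<", levels = c(0, 1))
    curve <- tibble::tibble(fpr = 1 - r$specificities,
                            tpr = r$sensitivities)
    tibble::tibble(class = classes[i], auc = as.numeric(pROC::auc(r)),
                   curve = list(curve))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.virann_metrics <- function(x, ...) {
  cat("<virann_metrics>\n")
  print(x$summary)
  invisible(x)
}

#' Per-class metrics of an evaluation
#' @param x A `virann_metrics` object.
#' @param ... Unused.
#' @return Tibble `cutoff`, `class`, `precision`, `recall`, `f1`, `support`.
#' @method tidy virann_metrics
#' @export
tidy.virann_metrics <- function(x, ...) x$per_class

#' Per-cutoff summary of an evaluation
#' @param x A `virann_metrics` object.
#' @param ... Unused.
#' @return Tibble with accuracy, macro and weighted averages per cutoff.
#' @method glance virann_metrics
#' @export
glance.virann_metrics <- function(x, ...) x$summary

#' Write predictions / metrics to disk
#'
#' @param predictions Prediction tibble.
#' @param path CSV output path.
#' @return `path` invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_csv(predictions, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @param metrics A `virann_metrics`.
#' @param prefix Output prefix; writes `<prefix>_per_class.csv`,
#'   `<prefix>_summary.csv`, `<prefix>_confusion_<cutoff>.csv` and
#'   `<prefix>_metrics.json`.
#' @export
write_metrics <- function(metrics, prefix) {
  readr::write_csv(metrics$per_class, paste0(prefix, "_per_class.csv"),
                   progress = FALSE)
  readr::write_csv(metrics$summary, paste0(prefix, "_summary.csv"),
                   progress = FALSE)
  for (key in names(metrics$confusion)) {
    m <- metrics$confusion[[key]]
    df <- cbind(tibble::tibble(truth = rownames(m)),
                tibble::as_tibble(m))
    readr::write_csv(df, paste0(prefix, "_confusion_", key, ".csv"),
                     progress = FALSE)
  }
  payload <- list(summary = metrics$summary,
                  per_class = metrics$per_class)
  if (!is.null(metrics$roc)) {
    payload$roc_auc <- metrics$roc[, c("class", "auc")]
  }
  jsonlite::write_json(payload, paste0(prefix, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(prefix)
}
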