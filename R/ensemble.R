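# The ten-member ensemble trained by 10-fold cross-validation.
#
# Fold i uses set "iD" for validation and the other nine cross-validation
# sets for training; TEST is never touched during training or
# standardization. Every fold fits its own z-score standardizer on its
# training split (k-mer frequencies and physicochemical extras live on very
# different scales), and trains one network with class weights inversely
# proportional to class counts.

#' Class weights inversely proportional to class counts
#'
#' `w_c = N / (K * n_c)`, normalized so that equally sized classes all get
#' weight 1; invariant under rescaling all counts.
#'
#' @param counts Named positive per-class training counts.
#' @return Named numeric weights.
#' @examples
#' class_weights(c(a = 100, b = 50))  # 0.75, 1.5
#' @export
class_weights <- function(counts) {
  if (any(counts < 1)) {
    stop("zero-count class: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  sum(counts) / (length(counts) * counts)
}

fit_standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2, std$center), 2, std$scale, "/")
}

#' Train one cross-validation fold
#'
#' Fits the standardizer on the training matrix only, applies it to both
#' matrices, and trains one network (see [mlp_train()]).
#'
#' @param x_train,x_val Raw feature matrices.
#' @param y_train,y_val Factors over the class list.
#' @param config An [mlp_config()].
#' @param weights Optional named per-class weights (default
#'   [class_weights()] of the training counts).
#' @return Object of class `fold_model`: the trained network plus
#'   `standardizer` and `classes`.
#' @export
train_fold <- function(x_train, y_train, x_val, y_val, config,
                       weights = NULL) {
  stopifnot(is.factor(y_train), is.factor(y_val),
            identical(levels(y_train), levels(y_val)))
  classes <- levels(y_train)
  if (is.null(weights)) {
    weights <- class_weights(table(y_train))
  }
  std <- fit_standardizer(x_train)
  net <- mlp_train(apply_standardizer(std, x_train), as.integer(y_train),
                   apply_standardizer(std, x_val), as.integer(y_val),
                   config, class_weights = as.numeric(weights[classes]))
  structure(c(net, list(standardizer = std, classes = classes)),
            class = "fold_model")
}

predict_fold <- function(fold, x) {
  P <- mlp_predict(fold, apply_standardizer(fold$standardizer, x))
  colnames(P) <- fold$classes
  P
}

#' Train the full ensemble by 10-fold cross-validation
#'
#' For each cross-validation set `iD` trains one network with `iD` as the
#' validation set and the remaining sets as training data. TEST-set
#' sequences are excluded from every fold. Per-fold seeds are fanned out
#' deterministically from `config$rng_seed`.
#'
#' @param records Labeled record tibble (columns `id`, `sequence`, `label`).
#' @param split A `split_assignment` from [build_split()] covering the
#'   record ids.
#' @param schema A [feature_schema()] or model name.
#' @param config An [mlp_config()] (its `n_features`/`n_classes` are
#'   overridden by the schema and class list), or `NULL` for defaults.
#' @param classes Class list (defines output order).
#' @param features Optional precomputed feature matrix (rownames = ids) to
#'   avoid re-extraction.
#' @return Object of class `virion_ensemble`: `members` (list of
#'   `fold_model`), `schema`, `classes`, `fold_metrics` (per-fold validation
#'   accuracy and weighted F1), `confidence` (NULL until
#'   [calibrate_confidence()]).
#' @export
cross_validate <- function(records, split, schema, config = NULL,
                           classes = class_list(), features = NULL) {
  if (is.character(schema)) schema <- feature_schema(schema)
  assignment <- split$assignment
  cv_sets <- setdiff(split_set_names(split$config), "TEST")
  missing_sets <- setdiff(cv_sets, unique(assignment$set))
  if (length(missing_sets) > 0) {
    stop("split is missing set(s): ", paste(missing_sets, collapse = ", "))
  }
  work <- dplyr::inner_join(
    assignment[assignment$set %in% cv_sets, c("id", "set")],
    records[, c("id", "sequence", "label")], by = "id"
  )
  if (anyNA(work$label)) stop("unlabeled records in cross-validation sets")
  if (is.null(features)) {
    features <- extract_features(work, schema)
  } else {
    features <- features[work$id, , drop = FALSE]
  }
  y <- factor(work$label, levels = classes)
  if (anyNA(y)) stop("labels outside the class list")
  if (is.null(config)) {
    config <- mlp_config(n_features = schema$total_dim,
                         n_classes = length(classes))
  }
  config$n_features <- schema$total_dim
  config$n_classes <- length(classes)
  set.seed(config$rng_seed)
  fold_seeds <- sample.int(.Machine$integer.max, length(cv_sets))

  members <- vector("list", length(cv_sets))
  metrics <- vector("list", length(cv_sets))
  for (i in seq_along(cv_sets)) {
    val_idx <- work$set == cv_sets[i]
    cfg_i <- config
    cfg_i$rng_seed <- fold_seeds[i]
    fold <- train_fold(features[!val_idx, , drop = FALSE], y[!val_idx],
                       features[val_idx, , drop = FALSE], y[val_idx], cfg_i)
    fold$fold_index <- i
    members[[i]] <- fold
    P <- predict_fold(fold, features[val_idx, , drop = FALSE])
    pred <- classes[apply(P, 1, which.max)]
    m <- classification_metrics(pred, as.character(y[val_idx]), classes)
    best_ep <- fold$best_epoch
    stop_ep <- fold$stopped_epoch
    metrics[[i]] <- tibble::tibble(
      fold = i, validation_set = cv_sets[i], n_validation = sum(val_idx),
      accuracy = m$accuracy, weighted_f1 = m$weighted$f1,
      macro_f1 = m$macro$f1, best_epoch = best_ep, stopped_epoch = stop_ep
    )
  }
  structure(list(members = members, schema = schema, classes = classes,
                 fold_metrics = dplyr::bind_rows(metrics),
                 config = config, confidence = NULL),
            class = "virion_ensemble")
}

#' @export
print.virion_ensemble <- function(x, ...) {
  cat("<virion_ensemble>", length(x$members), "members,",
      x$schema$model_name, "features (", x$schema$total_dim, "),",
      length(x$classes), "classes\n")
  cat("mean validation accuracy:",
      round(mean(x$fold_metrics$accuracy), 3), "\n")
  if (!is.null(x$confidence)) cat("confidence table attached\n")
  invisible(x)
}

#' Per-member softmax predictions
#'
#' @param ensemble A `virion_ensemble`.
#' @param x Raw feature matrix conforming to the ensemble's schema.
#' @return Array `members x sequences x classes`; every member/sequence row
#'   sums to 1.
#' @export
predict_members <- function(ensemble, x) {
  if (ncol(x) != ensemble$schema$total_dim) {
    stop("feature matrix has ", ncol(x), " columns; schema '",
         ensemble$schema$model_name, "' expects ", ensemble$schema$total_dim)
  }
  out <- array(0, dim = c(length(ensemble$members), nrow(x),
                          length(ensemble$classes)),
               dimnames = list(NULL, rownames(x), ensemble$classes))
  for (m in seq_along(ensemble$members)) {
    out[m, , ] <- predict_fold(ensemble$members[[m]], x)
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold validation metrics of an ensemble
#'
#' @param x A `virion_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per fold (validation accuracy, weighted and
#'   macro F1, best/stopped epochs).
#' @method tidy virion_ensemble
#' @export
tidy.virion_ensemble <- function(x, ...) x$fold_metrics

#' One-row ensemble summary
#'
#' Mean validation weighted F1 and accuracy across the 10 folds with
#' t-based 95% confidence half-widths (n = number of folds).
#'
#' @param x A `virion_ensemble`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance virion_ensemble
#' @export
glance.virion_ensemble <- function(x, ...) {
  fm <- x$fold_metrics
  ci_half <- function(v) {
    if (length(v) < 2) return(NA_real_)
    stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
  }
  tibble::tibble(
    n_members = length(x$members),
    model = x$schema$model_name,
    n_features = x$schema$total_dim,
    n_classes = length(x$classes),
    mean_val_accuracy = mean(fm$accuracy),
    ci95_val_accuracy = ci_half(fm$accuracy),
    mean_val_weighted_f1 = mean(fm$weighted_f1),
    ci95_val_weighted_f1 = ci_half(fm$weighted_f1)
  )
}

#' Save / load an ensemble bundle
#'
#' The bundle is a directory holding `schema.json` (model name, class list,
#' side-chain grouping, training configuration), `fold_metrics.csv`,
#' `training_log.csv`, one `member_XX.rds` per fold (weights plus
#' standardizer) and, when calibrated, `confidence.csv`.
#'
#' @param ensemble A `virion_ensemble`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` invisibly (save); a `virion_ensemble` (load).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    model_name = ensemble$schema$model_name,
    classes = ensemble$classes,
    side_chain_groups = as.list(ensemble$schema$sc_alphabet$groups),
    config = unclass(ensemble$config),
    n_members = length(ensemble$members)
  )
  jsonlite::write_json(meta, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(ensemble$fold_metrics, file.path(dir, "fold_metrics.csv"),
                   progress = FALSE)
  logs <- dplyr::bind_rows(lapply(seq_along(ensemble$members), function(i) {
    dplyr::mutate(ensemble$members[[i]]$training_log, fold = i,
                  .before = 1)
  }))
  readr::write_csv(logs, file.path(dir, "training_log.csv"), progress = FALSE)
  for (i in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[i]],
            file.path(dir, sprintf("member_%02d.rds", i)))
  }
  if (!is.null(ensemble$confidence)) {
    readr::write_csv(ensemble$confidence, file.path(dir, "confidence.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "schema.json"),
                              simplifyVector = TRUE)
  groups <- unlist(meta$side_chain_groups)
  schema <- feature_schema(meta$model_name, side_chain_alphabet(groups))
  member_files <- sort(list.files(dir, pattern = "^member_\\d+\\.rds$",
                                  full.names = TRUE))
  members <- lapply(member_files, readRDS)
  config <- meta$config
  class(config) <- "mlp_config"
  conf_path <- file.path(dir, "confidence.csv")
  confidence <- if (file.exists(conf_path)) {
    structure(readr::read_csv(conf_path, show_col_types = FALSE,
                              progress = FALSE),
              class = c("confidence_table", "tbl_df", "tbl", "data.frame"))
  }
  fm <- readr::read_csv(file.path(dir, "fold_metrics.csv"),
                        show_col_types = FALSE, progress = FALSE)
  structure(list(members = members, schema = schema,
                 classes = meta$classes, fold_metrics = fm, config = config,
                 confidence = confidence),
            class = "virion_ensemble")
}
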