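make_member_array <- function(rows_list) {
  # rows_list: list over members of n x K matrices
  arr <- array(0, dim = c(length(rows_list), nrow(rows_list[[1]]),
                          ncol(rows_list[[1]])),
               dimnames = list(NULL, rownames(rows_list[[1]]),
                               colnames(rows_list[[1]])))
  for (m in seq_along(rows_list)) arr[m, , ] <- rows_list[[m]]
  arr
}

test_that("ensemble scores are summed softmax and conserve the member count", {
  K <- 11
  onehot <- matrix(0, 1, K, dimnames = list("q", class_list()))
  onehot[1, "Portal"] <- 1
  arr <- make_member_array(rep(list(onehot), 10))
  sc <- ensemble_score(arr)
  expect_equal(unname(sc[1, "Portal"]), 10)
  expect_equal(sum(sc), 10)
  unif <- matrix(1 / K, 1, K, dimnames = list("q", class_list()))
  sc2 <- ensemble_score(make_member_array(rep(list(unif), 10)))
  expect_equal(unname(sc2[1, ]), rep(10 / K, K))
  withr::local_seed(51)
  rand <- lapply(1:10, function(i) {
    z <- matrix(stats::rexp(3 * K), 3, K,
                dimnames = list(paste0("q", 1:3), class_list()))
    z / rowSums(z)
  })
  sc3 <- ensemble_score(make_member_array(rand))
  expect_equal(unname(rowSums(sc3)), rep(10, 3), tolerance = 1e-9)
  expect_true(all(sc3 >= 0 & sc3 <= 10))
  bad <- make_member_array(rand)
  bad[1, 1, ] <- bad[1, 1, ] * 2
  expect_error(ensemble_score(bad), "sum to 1")
  expect_error(ensemble_score(make_member_array(rand[1:3]), n_members = 10),
               "expected 10")
})

test_that("classification is arg-max with deterministic ties and abstention", {
  sc <- matrix(c(1, 6, 3, 2, 3.1, 4.9), 2, 3, byrow = TRUE,
               dimnames = list(NULL, c("Major capsid", "Portal", "others")))
  out <- classify_scores(sc)
  expect_equal(out$predicted_class, c("Portal", "others"))
  expect_equal(out$escore, c(6, 4.9))
  # the documented abstention cutoff: top score below 5 is not classified
  out5 <- classify_scores(sc, abstain_threshold = 5)
  expect_equal(out5$predicted_class, c("Portal", "not classified"))
  tie <- matrix(c(4, 4, 2), 1, 3,
                dimnames = list(NULL, c("Major capsid", "Portal", "others")))
  expect_equal(classify_scores(tie)$predicted_class, "Major capsid")
})

test_that("the confidence table matches hand enumeration on six items", {
  preds <- tibble::tibble(
    id = paste0("t", 1:6),
    predicted_class = c("A", "A", "A", "A", "B", "B"),
    escore = c(9, 7, 5, 3, 8, 4)
  )
  truth <- c(t1 = "A", t2 = "A", t3 = "B", t4 = "A", t5 = "B", t6 = "A")
  tab <- build_confidence_table(preds, truth, classes = c("A", "B"),
                                n_members = 10)
  conf_at <- function(cls, s) {
    rows <- tab[tab$class == cls & tab$threshold <= s & !is.na(tab$confidence), ]
    rows$confidence[which.max(rows$threshold)]
  }
  # class A predictions by descending score: 9(T), 7(T), 5(F), 3(T)
  expect_equal(conf_at("A", 0), 3 / 4)   # precision of A
  expect_equal(conf_at("A", 4), 2 / 3)
  expect_equal(conf_at("A", 6), 1)
  # class B: 8(T), 4(F)
  expect_equal(conf_at("B", 0), 1 / 2)
  expect_equal(conf_at("B", 5), 1)
  # above the top observed score the value is carried forward, flagged sparse
  top <- tab[tab$class == "A" & tab$threshold > 9, ]
  expect_true(all(top$sparse))
  expect_true(all(top$confidence == 1))
})

test_that("all-correct predictions give confidence 1 everywhere defined", {
  preds <- tibble::tibble(id = paste0("t", 1:4),
                          predicted_class = c("A", "A", "B", "B"),
                          escore = c(2, 8, 5, 9))
  truth <- stats::setNames(c("A", "A", "B", "B"), preds$id)
  tab <- build_confidence_table(preds, truth, classes = c("A", "B"))
  expect_true(all(tab$confidence[!is.na(tab$confidence)] == 1))
})

test_that("corrupting one correct high score never raises confidence below it", {
  withr::local_seed(53)
  n <- 40
  preds <- tibble::tibble(
    id = paste0("q", 1:n),
    predicted_class = sample(c("A", "B"), n, TRUE),
    escore = round(stats::runif(n, 1, 10), 2)
  )
  truth <- stats::setNames(
    ifelse(stats::runif(n) < 0.8, preds$predicted_class,
           ifelse(preds$predicted_class == "A", "B", "A")), preds$id)
  tab <- build_confidence_table(preds, truth, classes = c("A", "B"))
  # corrupt the highest-scoring correct A prediction
  cand <- which(preds$predicted_class == "A" & truth[preds$id] == "A")
  victim <- cand[which.max(preds$escore[cand])]
  truth2 <- truth
  truth2[preds$id[victim]] <- "B"
  tab2 <- build_confidence_table(preds, truth2, classes = c("A", "B"))
  below <- tab$class == "A" & tab$threshold <= preds$escore[victim] &
    !is.na(tab$confidence) & !is.na(tab2$confidence)
  expect_true(all(tab2$confidence[below] <= tab$confidence[below] + 1e-12))
})

test_that("the toy confusion matrix yields the hand-computed metrics", {
  fx <- generate_worked_fixture()
  preds <- fx$planted_predictions
  truth <- fx$planted_truth
  met <- evaluate_predictions(preds, truth, classes = fx$planted_classes)
  pc <- met$per_class
  expect_equal(pc$precision, c(5 / 6, 4 / 6, 1))
  expect_equal(pc$recall, c(1, 0.8, 0.6))
  expect_equal(pc$support, c(5L, 5L, 5L))
  expect_equal(met$summary$accuracy, 12 / 15)
  cm <- met$confusion[["0"]]
  expect_equal(unname(cm[, fx$planted_classes]),
               matrix(c(5, 0, 0, 1, 4, 0, 0, 2, 3), 3, byrow = TRUE))
  # accuracy equals the weighted average recall
  expect_equal(met$summary$weighted_recall, met$summary$accuracy)
  # F1 is the harmonic mean of precision and recall
  expect_equal(pc$f1, 2 * pc$precision * pc$recall /
                 (pc$precision + pc$recall))
})

test_that("metrics agree with an independent confusion-table oracle", {
  oracle_metrics <- function(pred, truth, classes) {
    cm <- table(factor(truth, classes), factor(pred, classes))
    tp <- diag(cm)
    prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
    rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    support <- rowSums(cm)
    list(precision = unname(prec), recall = unname(rec), f1 = unname(f1),
         accuracy = sum(tp) / sum(cm),
         weighted_f1 = sum(f1 * support / sum(support)))
  }
  withr::local_seed(57)
  classes <- c("A", "B", "C", "D")
  for (i in 1:50) {
    n <- sample(20:60, 1)
    truth <- sample(classes, n, TRUE)
    pred <- ifelse(stats::runif(n) < 0.6, truth, sample(classes, n, TRUE))
    ids <- paste0("x", seq_len(n))
    met <- evaluate_predictions(
      tibble::tibble(id = ids, predicted_class = pred, escore = 10),
      stats::setNames(truth, ids), classes = classes)
    ora <- oracle_metrics(pred, truth, classes)
    expect_equal(met$per_class$precision, ora$precision, tolerance = 1e-12)
    expect_equal(met$per_class$recall, ora$recall, tolerance = 1e-12)
    expect_equal(met$per_class$f1, ora$f1, tolerance = 1e-12)
    expect_equal(met$summary$accuracy, ora$accuracy, tolerance = 1e-12)
    expect_equal(met$summary$weighted_f1, ora$weighted_f1, tolerance = 1e-12)
  }
})

test_that("score cutoffs shrink the retained set monotonically", {
  withr::local_seed(59)
  n <- 100
  preds <- tibble::tibble(
    id = paste0("q", 1:n),
    predicted_class = sample(c("A", "B"), n, TRUE),
    escore = stats::runif(n, 0, 10)
  )
  truth <- stats::setNames(sample(c("A", "B"), n, TRUE), preds$id)
  met <- evaluate_predictions(preds, truth, score_cutoffs = c(0, 2, 5, 8),
                              classes = c("A", "B"))
  rf <- met$summary$retained_fraction
  expect_equal(rf[1], 1)
  expect_true(all(diff(rf) <= 0))
  expect_warning(
    evaluate_predictions(preds, truth, score_cutoffs = 11,
                         classes = c("A", "B")),
    "no predictions retained")
})

test_that("one-vs-rest ROC areas separate signal from noise", {
  withr::local_seed(61)
  n <- 200
  truth_a <- c(rep("A", n / 2), rep("B", n / 2))
  ids <- paste0("r", 1:n)
  # informative score for A, pure noise for B
  score_a <- c(stats::rnorm(n / 2, 7, 1.5), stats::rnorm(n / 2, 3, 1.5))
  score_a <- pmin(pmax(score_a, 0), 10)
  preds <- tibble::tibble(
    id = ids,
    predicted_class = ifelse(score_a >= 5, "A", "B"),
    escore = pmax(score_a, 10 - score_a),
    score_A = score_a, score_B = 10 - score_a
  )
  met <- evaluate_predictions(preds, stats::setNames(truth_a, ids),
                              classes = c("A", "B"))
  expect_gt(met$roc$auc[met$roc$class == "A"], 0.9)
  # class-B score is the mirror image, so its AUC matches by symmetry
  expect_equal(met$roc$auc[met$roc$class == "B"],
               met$roc$auc[met$roc$class == "A"], tolerance = 1e-9)
})

test_that("calibrated lookups attach per-prediction confidences", {
  preds <- tibble::tibble(
    id = paste0("t", 1:6),
    predicted_class = c("A", "A", "A", "A", "B", "B"),
    escore = c(9, 7, 5, 3, 8, 4)
  )
  truth <- c(t1 = "A", t2 = "A", t3 = "B", t4 = "A", t5 = "B", t6 = "A")
  tab <- build_confidence_table(preds, truth, classes = c("A", "B"))
  looked <- confidence_lookup(tab, c("A", "B", "not classified"),
                              c(7, 8, 9))
  expect_equal(looked[1:2], c(1, 1))
  expect_true(is.na(looked[3]))
})
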