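# Biomarker-panel evaluation with standard classifiers under stratified
# k-fold cross-validation. The classifiers themselves come from their
# standard implementations (randomForest, rpart, glm, e1071, nnet); the
# harness, fold logic and metric definitions live here. Features are
# log10-transformed and z-scaled with training-fold statistics only, so
# no information leaks from held-out samples.

.classifier_roster <- c("random_forest", "decision_tree", "logistic",
                        "naive_bayes", "mlp")

# fit one classifier and return held-out scores for the positive class
.fit_score <- function(algorithm, xtr, ytr, xte) {
  pos <- levels(ytr)[2L]
  switch(algorithm,
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 200)
      stats::predict(fit, xte, type = "prob")[, pos]
    },
    decision_tree = {
      df <- data.frame(y = ytr, xtr, check.names = TRUE)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      nd <- data.frame(xte, check.names = TRUE)
      stats::predict(fit, nd, type = "prob")[, pos]
    },
    logistic = {
      # ridge-penalized logistic: stays well-posed on wide panels (p > n);
      # a single-feature panel is well-posed and uses plain glm
      if (ncol(xtr) >= 2L) {
        fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                              lambda = 0.01, standardize = FALSE)
        drop(stats::predict(fit, xte, type = "response"))
      } else {
        df <- data.frame(y = ytr, xtr, check.names = TRUE)
        fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                           family = stats::binomial()))
        nd <- data.frame(xte, check.names = TRUE)
        suppressWarnings(stats::predict(fit, nd, type = "response"))
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte, type = "raw")[, pos]
    },
    mlp = {
      capture <- utils::capture.output(
        fit <- nnet::nnet(xtr, stats::model.matrix(~ ytr - 1)[, 2L],
                          size = 5, decay = 0.1, maxit = 200, trace = FALSE,
                          MaxNWts = 100000)
      )
      drop(stats::predict(fit, xte))
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

# weighted (class-prevalence) precision/recall plus true specificity
.weighted_metrics <- function(truth, predicted) {
  lv <- levels(truth)
  n <- length(truth)
  prec <- rec <- spec <- numeric(length(lv))
  wt <- numeric(length(lv))
  for (i in seq_along(lv)) {
    cl <- lv[i]
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- sum(predicted != cl & truth != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
    wt[i] <- sum(truth == cl) / n
  }
  list(weighted_precision = sum(wt * prec),
       weighted_recall = sum(wt * rec),
       weighted_true_specificity = sum(wt * spec))
}

#' Evaluate a biomarker panel with one classifier
#'
#' Stratified k-fold cross-validation of a classifier restricted to the
#' panel features. Out-of-fold class scores are pooled across folds; the
#' ROC area is computed from the pooled scores, and weighted precision
#' (reported in the field as "specificity") and weighted recall
#' ("sensitivity") from the pooled predicted classes, weighting per-class
#' values by class prevalence. Feature transformation (log10 and
#' z-scaling) is fitted inside each training fold.
#'
#' @param table experimental-only [feature_table()] containing the panel
#'   columns.
#' @param class_labels 2-level class vector aligned to rows.
#' @param panel character vector of component/metabolite ids to use.
#' @param algorithm one of `"random_forest"`, `"decision_tree"`,
#'   `"logistic"`, `"naive_bayes"`, `"mlp"`.
#' @param n_folds folds (default 10).
#' @param seed integer seed for the fold draw (and any stochastic
#'   learner).
#' @param folds optional explicit per-sample fold assignment (overrides
#'   the seeded stratified draw).
#' @return A list of class `classifier_report`: algorithm, panel size,
#'   `weighted_precision`, `weighted_recall`, `weighted_true_specificity`,
#'   `roc_area`, per-sample out-of-fold `scores` and `predicted`, `folds`,
#'   `seed`.
#' @export
evaluate_panel <- function(table, class_labels, panel, algorithm,
                           n_folds = 10L, seed = 1L, folds = NULL) {
  algorithm <- match.arg(algorithm, .classifier_roster)
  if (length(panel) == 0L) {
    stop("evaluate_panel: panel is empty", call. = FALSE)
  }
  missing_feat <- setdiff(panel, table$components$component_id)
  if (length(missing_feat) > 0L) {
    stop("evaluate_panel: panel features missing from table: ",
         paste(utils::head(missing_feat, 5L), collapse = ", "), call. = FALSE)
  }
  x <- table$intensity[, panel, drop = FALSE]
  if (any(x <= 0)) {
    stop("evaluate_panel: intensities must be positive for the log ",
         "transform", call. = FALSE)
  }
  x <- log10(x)
  y <- factor(class_labels)
  if (nlevels(y) != 2L) {
    stop("evaluate_panel: exactly 2 classes required", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(folds)) folds <- stratified_folds(y, n_folds, seed = NULL)
  scores <- numeric(length(y))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    scl <- scale_center(x[tr, , drop = FALSE], "uv")
    xtr <- scl$x
    xte <- apply_scaling(x[!tr, , drop = FALSE], scl)
    scores[!tr] <- .fit_score(algorithm, xtr, y[tr], xte)
  }
  predicted <- factor(ifelse(scores >= 0.5, levels(y)[2L], levels(y)[1L]),
                      levels = levels(y))
  met <- .weighted_metrics(y, predicted)
  roc <- pROC::roc(response = y, predictor = scores, levels = levels(y),
                   direction = "<", quiet = TRUE)
  structure(c(list(algorithm = algorithm, panel = panel,
                   n_features = length(panel), n_folds = n_folds,
                   seed = seed, roc_area = as.numeric(pROC::auc(roc)),
                   scores = scores, predicted = predicted, truth = y,
                   folds = folds),
              met),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("classifier_report: %s on %d feature(s), %d-fold CV\n",
                     "  weighted precision %.3f  weighted recall %.3f  ",
                     "ROC area %.3f\n"),
              x$algorithm, x$n_features, x$n_folds,
              x$weighted_precision, x$weighted_recall, x$roc_area))
  invisible(x)
}

#' Summarize classifier reports into an algorithms x datasets x panels grid
#'
#' @param reports a list of entries, each a list with `dataset`, `panel_name`
#'   and `report` (a `classifier_report`); the shape produced by the
#'   pipeline's classification stage.
#' @return A `data.frame` grid of class `classifier_grid` with one row per
#'   (algorithm, dataset, panel) and the metric triplet; attribute
#'   `"best_panel"` flags the best panel (highest ROC area) per dataset.
#' @export
summarize_reports <- function(reports) {
  if (length(reports) == 0L) {
    out <- data.frame(algorithm = character(), dataset = character(),
                      panel = character(), weighted_precision = numeric(),
                      weighted_recall = numeric(),
                      weighted_true_specificity = numeric(),
                      roc_area = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("classifier_grid", "data.frame")
    return(out)
  }
  rows <- lapply(reports, function(e) {
    data.frame(algorithm = e$report$algorithm, dataset = e$dataset,
               panel = e$panel_name,
               weighted_precision = e$report$weighted_precision,
               weighted_recall = e$report$weighted_recall,
               weighted_true_specificity = e$report$weighted_true_specificity,
               roc_area = e$report$roc_area, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- do.call(rbind, lapply(split(out, out$dataset), function(d) {
    agg <- tapply(d$roc_area, d$panel, mean)
    data.frame(dataset = d$dataset[1L],
               best_panel = names(agg)[which.max(agg)],
               mean_roc = max(agg), stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL
  attr(out, "best_panel") <- best
  class(out) <- c("classifier_grid", "data.frame")
  out
}
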