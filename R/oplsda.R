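# Orthogonal projections to latent structures discriminant analysis
# (OPLS-DA) for a binary class, with one predictive component. The
# orthogonal filter iteratively extracts directions of X variation
# uncorrelated with the class vector before the single predictive
# component is taken from the deflated matrix. With n_orth = 0 the model
# is exactly single-component PLS1. All steps are closed-form per
# component (single-response NIPALS needs no iteration).

# encode a 2-level class as a +/-1 response; levels sorted for stability
.encode_class <- function(class_labels) {
  f <- factor(class_labels)
  lv <- levels(f)
  if (length(lv) != 2L) {
    stop("OPLS-DA requires exactly 2 classes; got ", length(lv), call. = FALSE)
  }
  if (any(table(f) < 2L)) {
    stop("OPLS-DA requires at least 2 samples per class", call. = FALSE)
  }
  list(y = ifelse(f == lv[2L], 1, -1), levels = lv)
}

# core fit on an already scaled X and centered y
.opls_core <- function(X, y, n_orth) {
  n <- nrow(X); p <- ncol(X)
  if (n_orth + 1L >= min(n, p)) {
    stop("n_orth (", n_orth, ") must be below the rank of the matrix",
         call. = FALSE)
  }
  ssx_total <- sum(X^2)
  W_o <- matrix(0, p, 0L); P_o <- matrix(0, p, 0L); T_o <- matrix(0, n, 0L)
  Xd <- X
  for (k in seq_len(n_orth)) {
    w <- crossprod(Xd, y)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) stop("degenerate class covariance during orthogonal ",
                         "extraction", call. = FALSE)
    w <- w / wn
    t <- Xd %*% w
    pvec <- crossprod(Xd, t) / sum(t^2)
    w_orth <- pvec - c(crossprod(w, pvec)) * w
    won <- sqrt(sum(w_orth^2))
    if (won < 1e-10) {
      stop("n_orth (", n_orth, ") is at or above the rank of the ",
           "class-orthogonal variation", call. = FALSE)
    }
    w_orth <- w_orth / won
    t_orth <- Xd %*% w_orth
    p_orth <- crossprod(Xd, t_orth) / sum(t_orth^2)
    Xd <- Xd - tcrossprod(t_orth, p_orth)
    W_o <- cbind(W_o, w_orth); P_o <- cbind(P_o, p_orth)
    T_o <- cbind(T_o, t_orth)
  }
  w <- crossprod(Xd, y)
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12) stop("degenerate class covariance in predictive component",
                       call. = FALSE)
  w <- w / wn
  t_p <- Xd %*% w
  p_p <- crossprod(Xd, t_p) / sum(t_p^2)
  q <- sum(y * t_p) / sum(t_p^2)
  r2y <- 1 - sum((y - q * t_p)^2) / sum(y^2)
  modeled <- sum(t_p^2) * sum(p_p^2)
  if (ncol(T_o) > 0L) {
    modeled <- modeled + sum(colSums(T_o^2) * colSums(P_o^2))
  }
  list(w = drop(w), p_p = drop(p_p), q = q, t_p = drop(t_p),
       W_o = W_o, P_o = P_o, T_o = T_o,
       r2y = r2y, r2x = modeled / ssx_total, n_orth = n_orth)
}

# project new scaled rows through the orthogonal filter, return t_p / yhat
.opls_core_predict <- function(core, Xnew) {
  X <- Xnew
  for (k in seq_len(core$n_orth)) {
    t_o <- X %*% core$W_o[, k]
    X <- X - tcrossprod(t_o, core$P_o[, k])
  }
  t_p <- drop(X %*% core$w)
  list(t_p = t_p, yhat = core$q * t_p)
}

#' Fit an OPLS-DA model
#'
#' Extracts `n_orth` orthogonal components (structured X variation
#' uncorrelated with the class) followed by a single predictive component.
#' The matrix is centered/scaled internally via [scale_center()] and the
#' scaling parameters are stored for prediction.
#'
#' @param x numeric matrix (samples x components), raw or normalized scale.
#' @param class_labels a 2-level factor/character/logical vector.
#' @param n_orth number of orthogonal components (0 gives exactly
#'   single-component PLS1).
#' @param scale scaling method passed to [scale_center()] (default `"uv"`).
#' @return An object of class `oplsda`: predictive scores `t_p`, unit-norm
#'   predictive weights `w`, loadings `p_p`, regression scalar `q`,
#'   orthogonal scores/weights/loadings, `r2x`, `r2y`, the class encoding
#'   and the scaling parameters.
#' @export
fit_oplsda <- function(x, class_labels, n_orth = 0L,
                       scale = c("uv", "pareto", "none")) {
  x <- as.matrix(x)
  enc <- .encode_class(class_labels)
  scaling <- scale_center(x, match.arg(scale))
  y_center <- mean(enc$y)
  core <- .opls_core(scaling$x, enc$y - y_center, n_orth)
  structure(c(core,
              list(scaling = scaling, class_levels = enc$levels,
                   y_center = y_center,
                   component_ids = colnames(scaling$x))),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive + ", x$n_orth, " orthogonal component(s)\n",
      sep = "")
  cat(sprintf("  classes: %s vs %s\n", x$class_levels[1L], x$class_levels[2L]))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f\n", x$r2x, x$r2y))
  invisible(x)
}

#' Predict from an OPLS-DA model
#'
#' @param object an [fit_oplsda()] model.
#' @param newdata raw matrix with the training columns.
#' @param ... unused.
#' @return A list: `t_p` (predictive scores), `y_hat` (numeric response on
#'   the centered +/-1 scale plus the training class-vector mean), and
#'   `class` (predicted labels).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$scaling$orig_names)) {
    newdata <- newdata[, object$scaling$orig_names, drop = FALSE]
  }
  Xs <- apply_scaling(newdata, object$scaling)
  pr <- .opls_core_predict(object, Xs)
  yhat <- pr$yhat + object$y_center
  cls <- ifelse(yhat >= 0, object$class_levels[2L], object$class_levels[1L])
  list(t_p = pr$t_p, y_hat = yhat, class = cls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `n_folds` folds, drawing proportionally
#' within each class so every fold preserves the class balance.
#'
#' @param class_labels class vector.
#' @param n_folds number of folds.
#' @param seed optional integer seed.
#' @return An integer fold index per sample.
#' @export
stratified_folds <- function(class_labels, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- factor(class_labels)
  if (any(table(f) < 2L)) {
    stop("stratified_folds: each class needs at least 2 samples", call. = FALSE)
  }
  fold <- integer(length(f))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated predictive ability Q2
#'
#' Stratified k-fold cross-validation of the class vector:
#' `Q2 = 1 - PRESS / SS`, with PRESS the sum of squared held-out
#' prediction errors and SS the total centered sum of squares of the
#' class vector. Centering and scaling are re-estimated inside each
#' training fold.
#'
#' @param x raw matrix (samples x components).
#' @param class_labels 2-level class vector.
#' @param n_orth orthogonal components of the model.
#' @param n_folds folds (default 7, stratified by class).
#' @param seed integer seed for the fold draw.
#' @param scale scaling method.
#' @param folds optional explicit per-sample fold assignment (overrides
#'   the seeded stratified draw).
#' @return An object of class `opls_cv`: `q2`, `press`, `ss`, `n`,
#'   `n_orth`, `n_folds`, `folds`, and the pooled out-of-fold numeric
#'   predictions `y_hat`.
#' @export
cross_validated_q2 <- function(x, class_labels, n_orth = 0L, n_folds = 7L,
                               seed = NULL, scale = "uv", folds = NULL) {
  x <- as.matrix(x)
  enc <- .encode_class(class_labels)
  if (n_folds < 2L) stop("cross_validated_q2: n_folds must be >= 2",
                         call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(class_labels, n_folds, seed)
  yhat <- numeric(length(enc$y))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    scaling <- scale_center(x[tr, , drop = FALSE], scale)
    y_center <- mean(enc$y[tr])
    core <- .opls_core(scaling$x, enc$y[tr] - y_center, n_orth)
    Xte <- apply_scaling(x[!tr, , drop = FALSE], scaling)
    yhat[!tr] <- .opls_core_predict(core, Xte)$yhat + y_center
  }
  press <- sum((enc$y - yhat)^2)
  ss <- sum((enc$y - mean(enc$y))^2)
  structure(list(q2 = 1 - press / ss, press = press, ss = ss,
                 n = length(enc$y), n_orth = n_orth, n_folds = n_folds,
                 folds = folds, y_hat = yhat),
            class = "opls_cv")
}

#' CV-ANOVA significance of a cross-validated latent-variable model
#'
#' F-test comparing the cross-validated predictive residuals against the
#' total class-vector variation:
#' `F = ((SS - PRESS) / d1) / (PRESS / d2)` with `d1 = A` (the number of
#' model components, orthogonal plus predictive) and `d2 = n - A - 1`.
#' When PRESS >= SS the model shows no predictive improvement and p = 1.
#'
#' @param cv an `opls_cv` object from [cross_validated_q2()].
#' @return The p-value from the F distribution, with attributes `F`,
#'   `df1`, `df2`.
#' @export
cv_anova <- function(cv) {
  stopifnot(inherits(cv, "opls_cv"))
  a <- cv$n_orth + 1L
  d2 <- cv$n - a - 1L
  if (d2 < 1L) stop("cv_anova: too few samples for the F test", call. = FALSE)
  if (cv$press >= cv$ss) {
    p <- 1
    fstat <- 0
  } else {
    fstat <- ((cv$ss - cv$press) / a) / (cv$press / d2)
    p <- stats::pf(fstat, a, d2, lower.tail = FALSE)
  }
  structure(p, F = fstat, df1 = a, df2 = d2)
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model on random permutations of the class labels and
#' compares the permuted R2Y/Q2 with the observed values. The empirical
#' p-value is `(1 + #\{permuted Q2 >= observed Q2\}) / (n_permutations + 1)`.
#' The test passes when p <= 0.05 and every permuted R2Y falls below the
#' observed R2Y.
#'
#' @param x raw matrix.
#' @param class_labels 2-level class vector.
#' @param n_orth orthogonal components.
#' @param n_permutations number of label permutations (>= 20, default 100).
#' @param seed integer seed.
#' @param n_folds folds for the Q2 of each permutation.
#' @param scale scaling method.
#' @return A list of class `opls_permutation`: `observed` (r2y, q2),
#'   `permuted` (data.frame of r2y, q2), `p_value`, `pass`,
#'   `n_permutations`.
#' @export
permutation_test <- function(x, class_labels, n_orth = 0L,
                             n_permutations = 100L, seed = NULL,
                             n_folds = 7L, scale = "uv") {
  if (n_permutations < 20L) {
    stop("permutation_test: n_permutations must be >= 20", call. = FALSE)
  }
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  obs_fit <- fit_oplsda(x, class_labels, n_orth, scale)
  obs_cv <- cross_validated_q2(x, class_labels, n_orth, n_folds,
                               seed = NULL, scale = scale)
  perm <- matrix(NA_real_, n_permutations, 2L,
                 dimnames = list(NULL, c("r2y", "q2")))
  for (b in seq_len(n_permutations)) {
    yp <- sample(class_labels)
    fitp <- fit_oplsda(x, yp, n_orth, scale)
    cvp <- cross_validated_q2(x, yp, n_orth, n_folds, seed = NULL,
                              scale = scale)
    perm[b, ] <- c(fitp$r2y, cvp$q2)
  }
  p <- (1 + sum(perm[, "q2"] >= obs_cv$q2)) / (n_permutations + 1)
  structure(list(observed = list(r2y = obs_fit$r2y, q2 = obs_cv$q2),
                 permuted = as.data.frame(perm),
                 p_value = p,
                 pass = (p <= 0.05) && all(perm[, "r2y"] < obs_fit$r2y),
                 n_permutations = n_permutations),
            class = "opls_permutation")
}

#' Choose the number of orthogonal components
#'
#' Adds orthogonal components while the cross-validated Q2 improves by
#' more than `improvement` (default 0.01), up to `max_orth`.
#'
#' @param x raw matrix.
#' @param class_labels 2-level class vector.
#' @param max_orth maximum orthogonal components tried (default 5).
#' @param improvement minimum Q2 gain to accept one more component.
#' @param n_folds,seed,scale forwarded to [cross_validated_q2()].
#' @return A list: `n_orth` (chosen), `q2` (at the chosen size),
#'   `q2_path` (Q2 for 0..tried components).
#' @export
select_n_orth <- function(x, class_labels, max_orth = 5L, improvement = 0.01,
                          n_folds = 7L, seed = NULL, scale = "uv") {
  x <- as.matrix(x)
  max_orth <- min(max_orth, min(dim(x)) - 2L)
  path <- cross_validated_q2(x, class_labels, 0L, n_folds, seed, scale)$q2
  best <- 0L
  while (best < max_orth) {
    q2_next <- tryCatch(
      cross_validated_q2(x, class_labels, best + 1L, n_folds, seed = NULL,
                         scale = scale)$q2,
      error = function(e) NA_real_)
    if (is.na(q2_next) || q2_next - path[length(path)] <= improvement) {
      path <- c(path, q2_next)
      break
    }
    path <- c(path, q2_next)
    best <- best + 1L
  }
  list(n_orth = best, q2 = path[best + 1L], q2_path = path)
}

#' Full validation report for an OPLS-DA model
#'
#' Bundles the three model-quality criteria: cross-validated Q2 > 0.5,
#' CV-ANOVA p < 0.05, and a passing permutation test (all three must hold
#' for a `"good"` verdict).
#'
#' @param x raw matrix.
#' @param class_labels 2-level class vector.
#' @param n_orth orthogonal components.
#' @param n_folds,n_permutations,seed,scale forwarded to the component
#'   tests.
#' @return A list of class `validation_report`: `r2x`, `r2y`, `q2`,
#'   `cv_anova_p`, `permutation`, `verdict` (`"good"`/`"poor"`).
#' @export
validate_oplsda <- function(x, class_labels, n_orth = 0L, n_folds = 7L,
                            n_permutations = 100L, seed = NULL,
                            scale = "uv") {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_oplsda(x, class_labels, n_orth, scale)
  cv <- cross_validated_q2(x, class_labels, n_orth, n_folds, seed = NULL,
                           scale = scale)
  p_cv <- cv_anova(cv)
  perm <- permutation_test(x, class_labels, n_orth, n_permutations,
                           seed = NULL, n_folds = n_folds, scale = scale)
  verdict <- if (cv$q2 > 0.5 && as.numeric(p_cv) < 0.05 && perm$pass) {
    "good"
  } else {
    "poor"
  }
  structure(list(r2x = fit$r2x, r2y = fit$r2y, q2 = cv$q2,
                 cv_anova_p = as.numeric(p_cv), permutation = perm,
                 verdict = verdict),
            class = "validation_report")
}

#' Variable importance in projection (VIP)
#'
#' For the single predictive component the VIP of component i reduces to
#' `sqrt(p) * |w_i| / ||w||`; the mean squared VIP over components is 1.
#'
#' @param model an [fit_oplsda()] model.
#' @return A `data.frame` (`component_id`, `vip`, `rank`) sorted by the
#'   original column order, with rank 1 for the largest VIP.
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  w <- model$w
  vip <- sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
  data.frame(component_id = model$component_ids %||% seq_along(w),
             vip = vip,
             rank = rank(-vip, ties.method = "min"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' S-plot coordinates
#'
#' Covariance and Pearson correlation between the predictive scores and
#' every (scaled) component column of the training matrix; together they
#' form the S-plot used to assess biomarker reliability.
#'
#' @param model an [fit_oplsda()] model.
#' @param x the raw training matrix the model was fitted on.
#' @return A `data.frame` (`component_id`, `covariance`, `correlation`,
#'   `zero_variance`); zero-variance columns are reported with
#'   correlation 0 and flagged.
#' @export
splot_coordinates <- function(model, x) {
  stopifnot(inherits(model, "oplsda"))
  Xs <- apply_scaling(as.matrix(x), model$scaling)
  t_p <- model$t_p
  n <- nrow(Xs)
  tc <- t_p - mean(t_p)
  Xc <- sweep(Xs, 2L, colMeans(Xs), "-")
  covv <- drop(crossprod(Xc, tc)) / (n - 1)
  sds <- sqrt(colSums(Xc^2) / (n - 1))
  zero <- sds < 1e-12
  corr <- numeric(length(covv))
  corr[!zero] <- covv[!zero] / (sds[!zero] * stats::sd(t_p))
  data.frame(component_id = model$component_ids %||% seq_along(covv),
             covariance = covv, correlation = corr, zero_variance = zero,
             stringsAsFactors = FALSE, row.names = NULL)
}
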