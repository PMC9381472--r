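# Ridge-penalized logistic regression by Newton iteration.
# Objective: sum_i -[y log p + (1-y) log(1-p)] + ||beta||^2 / (2C), intercept
# unpenalized. C follows the "larger = weaker penalty" convention.
.ridge_logistic <- function(x, y, penalty_c = 1, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  xa <- cbind(`(intercept)` = 1, x)
  p <- ncol(xa)
  lambda <- c(0, rep(1 / penalty_c, p - 1L))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(xa %*% beta)
    mu <- plogis(eta)
    grad <- as.vector(crossprod(xa, mu - y)) + lambda * beta
    if (max(abs(grad)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    hess <- crossprod(xa, xa * w) + diag(lambda, p)
    beta <- beta - solve(hess, grad)
  }
  names(beta) <- colnames(xa)
  beta
}

#' Fit a (ridge-penalized) logistic lateralization model
#'
#' Binary logistic regression of side-of-onset on asymmetry-index features.
#' The default fit is penalized maximum likelihood with an L2 ridge on the
#' slope coefficients (strength `1 / penalty_c`, intercept unpenalized):
#' with two dozen subjects and near-separable features the unpenalized
#' likelihood diverges, and the mild default penalty (`penalty_c = 1`)
#' stabilises it. `penalized = FALSE` gives plain maximum likelihood via
#' [stats::glm()]. Features are used as given (asymmetry indices are already
#' on a z-derived scale); set `standardize = TRUE` to z-score them first.
#'
#' @param data data frame holding the feature columns and the label column.
#' @param features character, names of numeric feature columns.
#' @param label_col name of the class column; default `"laterality"`.
#' @param positive level coded 1 (default `"L"`: left-sided disease is the
#'   positive class).
#' @param penalty_c inverse penalty strength; larger is weaker.
#' @param penalized use the ridge fit (default) or plain ML.
#' @param standardize z-score features before fitting.
#'
#' @return Object of class `logistic_fit` with elements `coefficients`,
#'   `features`, `positive`, and the scaling used.
#' @export
fit_logistic <- function(data, features, label_col = "laterality",
                         positive = "L", penalty_c = 1, penalized = TRUE,
                         standardize = FALSE) {
  miss <- setdiff(c(features, label_col), names(data))
  if (length(miss)) abort(paste("Missing columns:", paste(miss, collapse = ", ")))
  x <- as.matrix(data[features])
  if (any(!is.finite(x))) abort("Features contain missing or non-finite values.")
  y <- as.integer(data[[label_col]] == positive)
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present to fit a classifier.")
  }
  center <- rep(0, ncol(x))
  scale_ <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  beta <- if (penalized) {
    .ridge_logistic(x, y, penalty_c = penalty_c)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial())
    )
    stats::setNames(fit$coefficients, c("(intercept)", colnames(x)))
  }
  structure(
    list(
      coefficients = beta, features = features, positive = positive,
      center = center, scale = scale_, penalty_c = penalty_c,
      penalized = penalized
    ),
    class = "logistic_fit"
  )
}

#' Predicted class-1 probabilities from a logistic fit
#'
#' @param object A [fit_logistic()] result.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.vector(plogis(cbind(1, x) %*% object$coefficients))
}

#' Leave-one-out cross-validated probabilities
#'
#' For each subject, refits the logistic model on the remaining n - 1 and
#' records the held-out subject's predicted probability of the positive
#' class; output order matches input order. Errors, naming the held-out
#' subject, if any training fold collapses to a single class.
#'
#' @inheritParams fit_logistic
#' @param ... passed on to [fit_logistic()].
#' @return Numeric vector of held-out probabilities, one per row of `data`.
#' @export
loocv_probabilities <- function(data, features, label_col = "laterality",
                                positive = "L", ...) {
  n <- nrow(data)
  if (n < 3L) abort("LOOCV needs at least 3 subjects.")
  ids <- if ("subject_id" %in% names(data)) data$subject_id else as.character(seq_len(n))
  y <- data[[label_col]] == positive
  probs <- numeric(n)
  for (i in seq_len(n)) {
    if (length(unique(y[-i])) < 2L) {
      abort(sprintf(
        "LOOCV fold holding out subject %s has a single-class training set.",
        ids[i]
      ))
    }
    fit <- fit_logistic(data[-i, , drop = FALSE], features, label_col,
                        positive, ...)
    probs[i] <- predict(fit, data[i, , drop = FALSE])
  }
  probs
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' receives a higher score than a randomly chosen negative, ties counted
#' one-half; identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param probabilities numeric scores.
#' @param labels 0/1 (or logical) true classes; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (length(probabilities) != length(labels)) abort("Length mismatch.")
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0) abort("Both classes must be present to compute AUC.")
  r <- rank(probabilities)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered from the
#'   (0, 0) to the (1, 1) corner.
#' @export
roc_points <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("Both classes must be present.")
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(th, function(t) {
    call_pos <- probabilities >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(call_pos & labels == 0L) / n0,
      tpr = sum(call_pos & labels == 1L) / n1
    )
  })
  dplyr::distinct(pts, .data$fpr, .data$tpr, .keep_all = TRUE)
}

#' Mean squared error between labels and predicted probabilities
#'
#' The Brier-type prediction error: mean over subjects of
#' `(label - probability)^2`; lower is better.
#'
#' @inheritParams roc_auc
#' @return Single numeric value.
#' @export
probability_mse <- function(probabilities, labels) {
  if (length(probabilities) == 0L) abort("Empty input.")
  if (length(probabilities) != length(labels)) abort("Length mismatch.")
  mean((as.numeric(labels) - probabilities)^2)
}

#' Lateralization accuracy summary
#'
#' @param calls character vector of predicted sides (`"L"`/`"R"`, or
#'   `"undetermined"`, which never matches and so counts as incorrect).
#' @param truth character vector of true sides, same length.
#' @return Tibble with `n_correct`, `n_total`, `percent` (two decimals).
#' @export
accuracy_summary <- function(calls, truth) {
  if (length(calls) != length(truth)) abort("`calls` and `truth` length mismatch.")
  n_correct <- sum(calls == truth, na.rm = TRUE)
  n_total <- length(truth)
  tibble::tibble(
    n_correct = n_correct,
    n_total = n_total,
    percent = round(100 * n_correct / n_total, 2)
  )
}

#' Leave-one-out logistic lateralization of a cohort
#'
#' The package's classifier driver: runs [loocv_probabilities()] on the given
#' asymmetry-index features, makes hard side calls at the 0.5 threshold
#' (exact ties are `"undetermined"` and count as incorrect), and summarises
#' performance as the AUC of the pooled held-out probabilities, the
#' probability mean squared error, the accuracy, and the ROC curve.
#'
#' @inheritParams fit_logistic
#' @param model_name label for reporting, e.g. `"T2"`, `"PET"`, `"T2+PET"`.
#' @param threshold hard-call probability threshold.
#' @param ... passed to [fit_logistic()] via [loocv_probabilities()].
#'
#' @return Object of class `lateralization_result`: a list with `model_name`,
#'   `subjects` (per-subject tibble: id, truth, LOOCV probability, call,
#'   correctness), `auc`, `mse`, `accuracy` (tibble), `roc` (tibble) and
#'   `confusion` counts.
#' @export
lateralize <- function(data, features, label_col = "laterality",
                       positive = "L", model_name = paste(features, collapse = "+"),
                       threshold = 0.5, ...) {
  probs <- loocv_probabilities(data, features, label_col, positive, ...)
  truth <- as.character(data[[label_col]])
  y <- as.integer(truth == positive)
  negative <- setdiff(unique(truth), positive)
  if (length(negative) != 1L) abort("Exactly two classes are required.")
  call <- dplyr::case_when(
    probs > threshold ~ positive,
    probs < threshold ~ negative,
    TRUE ~ "undetermined"
  )
  ids <- if ("subject_id" %in% names(data)) data$subject_id else as.character(seq_along(probs))
  subjects <- tibble::tibble(
    subject_id = ids, truth = truth, label = y,
    probability = probs, call = call, correct = call == truth
  )
  structure(
    list(
      model_name = model_name,
      features = features,
      positive = positive,
      subjects = subjects,
      auc = roc_auc(probs, y),
      mse = probability_mse(probs, y),
      accuracy = accuracy_summary(call, truth),
      roc = roc_points(probs, y),
      confusion = c(
        tp = sum(call == positive & truth == positive),
        fp = sum(call == positive & truth != positive),
        tn = sum(call == negative & truth != positive),
        fn = sum(call == negative & truth == positive),
        undetermined = sum(call == "undetermined")
      )
    ),
    class = "lateralization_result"
  )
}

#' @export
print.lateralization_result <- function(x, ...) {
  cat(sprintf(
    "<lateralization_result [%s]> n = %d, AUC = %.3f, MSE = %.3f, accuracy = %.2f%% (%d/%d)\n",
    x$model_name, nrow(x$subjects), x$auc, x$mse,
    x$accuracy$percent, x$accuracy$n_correct, x$accuracy$n_total
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-subject tidy view of a lateralization result
#'
#' @param x A [lateralize()] result.
#' @param ... unused.
#' @return Tibble, one row per subject.
#' @method tidy lateralization_result
#' @export
tidy.lateralization_result <- function(x, ...) x$subjects

#' One-row performance summary of a lateralization result
#'
#' @param x A [lateralize()] result.
#' @param ... unused.
#' @return Tibble with `model`, `n`, `auc`, `mse`, `n_correct`,
#'   `accuracy_percent`.
#' @method glance lateralization_result
#' @export
glance.lateralization_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    n = nrow(x$subjects),
    auc = x$auc,
    mse = x$mse,
    n_correct = x$accuracy$n_correct,
    accuracy_percent = x$accuracy$percent
  )
}

#' ROC curve plot of one or more lateralization results
#'
#' @param object A [lateralize()] result.
#' @param ... further `lateralization_result` objects to overlay.
#' @return A ggplot.
#' @method autoplot lateralization_result
#' @export
autoplot.lateralization_result <- function(object, ...) {
  extra <- purrr::keep(list(...), inherits, "lateralization_result")
  results <- c(list(object), extra)
  df <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(r$roc,
      model = sprintf("%s (AUC %.3f)", r$model_name, r$auc)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      colour = NULL, title = "LOOCV lateralization ROC"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
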