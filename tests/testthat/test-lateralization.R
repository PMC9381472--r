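make_cohort <- function(n1 = 8, n0 = 8, sep = 2, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n1 + n0)),
    ai = c(rnorm(n1, sep / 2), rnorm(n0, -sep / 2)),
    laterality = rep(c("L", "R"), c(n1, n0))
  ))
}

test_that("separable data is classified on the correct side of 0.5", {
  d <- tibble::tibble(
    ai = c(2, 3, 2.5, -2, -3, -2.5),
    laterality = rep(c("L", "R"), each = 3)
  )
  fit <- fit_logistic(d, "ai")
  p <- predict(fit, d)
  expect_true(all(p[1:3] > 0.5) && all(p[4:6] < 0.5))
})

test_that("an uninformative feature yields prevalence probabilities", {
  d <- tibble::tibble(ai = rep(1.3, 10),
                      laterality = rep(c("L", "R"), c(6, 4)))
  fit <- fit_logistic(d, "ai")
  expect_lt(abs(fit$coefficients[["ai"]]), 1e-6)
  expect_equal(unique(round(predict(fit, d), 6)), 0.6)
})

test_that("single-class input cannot be fit", {
  d <- tibble::tibble(ai = rnorm(5), laterality = rep("L", 5))
  expect_error(fit_logistic(d, "ai"), "[Bb]oth classes")
  expect_error(fit_logistic(tibble::tibble(a = 1), "missing_col"), "Missing")
})

test_that("generating coefficients are recovered from large samples", {
  withr::local_seed(77)
  n <- 10000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.5 + 1.2 * x1 - 0.8 * x2
  y <- rbinom(n, 1, plogis(eta))
  d <- tibble::tibble(x1 = x1, x2 = x2,
                      laterality = ifelse(y == 1, "L", "R"))
  fit <- fit_logistic(d, c("x1", "x2"))
  expect_lt(abs(fit$coefficients[["x1"]] - 1.2) / 1.2, 0.05)
  expect_lt(abs(fit$coefficients[["x2"]] + 0.8) / 0.8, 0.05)

  # the ridge fit approaches plain ML when the penalty is negligible
  ml <- fit_logistic(d, c("x1", "x2"), penalized = FALSE)
  expect_equal(unname(fit$coefficients), unname(ml$coefficients),
               tolerance = 0.01)
})

test_that("LOOCV probabilities respect order and fold-collapse contracts", {
  d <- tibble::tibble(ai = c(5, 4, -5, -4),
                      laterality = c("L", "L", "R", "R"))
  p <- loocv_probabilities(d, "ai")
  expect_true(all(p[1:2] > 0.5) && all(p[3:4] < 0.5))

  perm <- c(3, 1, 4, 2)
  expect_equal(loocv_probabilities(d[perm, ], "ai"), p[perm])

  bad <- tibble::tibble(subject_id = c("a", "b", "c"),
                        ai = c(1, -1, -2),
                        laterality = c("L", "R", "R"))
  expect_error(loocv_probabilities(bad, "ai"), "subject a")
})

test_that("AUC matches the exhaustive pairwise oracle on small instances", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.4, 0.4), c(1, 0)), 0.5)
  withr::local_seed(91)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)  # coarse grid to exercise tie handling
    expect_equal(roc_auc(scores, labels), oracle_auc_pairwise(scores, labels))
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "[Bb]oth classes")
})

test_that("AUC is invariant under feature negation with label swap", {
  withr::local_seed(15)
  scores <- runif(30)
  labels <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(roc_auc(scores, labels), roc_auc(-scores, 1 - labels))
})

test_that("empirical AUC of two Gaussian classes matches the closed form", {
  withr::local_seed(33)
  n <- 100000
  mu_diff <- 1.49
  s1 <- 0.81; s0 <- 1.28
  scores <- c(rnorm(n, mu_diff, s1), rnorm(n, 0, s0))
  labels <- rep(1:0, each = n)
  expected <- pnorm(mu_diff / sqrt(s1^2 + s0^2))
  expect_lt(abs(roc_auc(scores, labels) - expected), 0.01)
})

test_that("probability MSE follows its definition", {
  expect_equal(probability_mse(c(1, 0), c(1, 0)), 0)
  expect_equal(probability_mse(c(0.5, 0.5), c(1, 0)), 0.25)
  expect_equal(probability_mse(c(0.9, 0.6, 0.2), c(1, 1, 0)), 0.07)
  expect_error(probability_mse(numeric(0), numeric(0)), "Empty")
  # constant-prevalence predictor scores prevalence * (1 - prevalence)
  labels <- rep(c(1, 0), c(6, 4))
  expect_equal(probability_mse(rep(0.6, 10), labels), 0.6 * 0.4)
})

test_that("accuracy summaries round to two decimals", {
  expect_equal(accuracy_summary(rep("L", 46),
                                rep(c("L", "R"), c(44, 2)))$percent, 95.65)
  acc <- accuracy_summary(rep("L", 46), rep(c("L", "R"), c(39, 7)))
  expect_equal(acc$percent, 84.78)
  expect_equal(round(acc$percent, 1), 84.8)
  expect_equal(accuracy_summary(rep("L", 5), rep("R", 5))$percent, 0)
  expect_error(accuracy_summary("L", c("L", "R")), "length")
})

test_that("the lateralization driver assembles a coherent result", {
  d <- make_cohort(n1 = 10, n0 = 8, sep = 2.5, seed = 10)
  res <- lateralize(d, "ai", model_name = "T2")
  expect_s3_class(res, "lateralization_result")
  expect_equal(nrow(res$subjects), 18)
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_equal(res$mse, probability_mse(res$subjects$probability,
                                        res$subjects$label))
  expect_equal(sum(res$confusion[c("tp", "fp", "tn", "fn", "undetermined")]), 18)

  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$auc, res$auc)
  expect_identical(tidy(res), res$subjects)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("mirroring the cohort flips every lateralization call", {
  d <- make_cohort(n1 = 9, n0 = 7, sep = 1.5, seed = 12)
  res <- lateralize(d, "ai")
  mirrored <- dplyr::mutate(d, ai = -ai,
                            laterality = ifelse(laterality == "L", "R", "L"))
  res_m <- lateralize(mirrored, "ai")
  expect_equal(res_m$subjects$probability, 1 - res$subjects$probability,
               tolerance = 1e-8)
  flip <- c(L = "R", R = "L", undetermined = "undetermined")
  expect_equal(unname(flip[res$subjects$call]), res_m$subjects$call)
  expect_equal(res_m$auc, res$auc, tolerance = 1e-10)
})

test_that("AUC agrees with the pROC reference implementation", {
  withr::local_seed(27)
  for (rep in 1:5) {
    n <- 40
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.45, 0.55))
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})
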