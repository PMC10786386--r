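referral_rows <- function() {
  # patient R1: referral at interaction 3 of 4; R2: referral at the first
  # assessment (step 2); N1: never referred
  list(
    mini_row("R1", "10:00", "Triage Nurse; Patient", "EDIS",
             "Referral to Emergency Medical"),
    mini_row("R1", "10:20", "Nurse; Patient"),
    mini_row("R1", "10:40", "Registrar", "Patient File",
             "Referral to Emergency Psychiatry"),
    mini_row("R1", "11:00", "Psychiatric Liaison Nurse; Patient"),
    mini_row("R2", "12:00", "Triage Nurse; Patient", "EDIS",
             "Referral to Emergency Medical"),
    mini_row("R2", "12:30", "Consultant; Patient", "",
             "Referral to Emergency Psychiatry"),
    mini_row("N1", "14:00", "Triage Nurse; Patient", "EDIS",
             "Referral to Emergency Medical"),
    mini_row("N1", "14:10", "Nurse; Patient")
  )
}

test_that("state vectors follow the node-then-upper-triangle layout", {
  v <- vectorize_state(list(nodes = c("a", "b"), edges = rbind(c("a", "b"))),
                       node_order = c("a", "b", "c"))
  expect_equal(unname(v), c(1, 1, 0, 1, 0, 0))
  expect_equal(names(v), c("a", "b", "c", "a|b", "a|c", "b|c"))

  empty <- vectorize_state(list(nodes = character(0), edges = NULL),
                           node_order = c("a", "b", "c"))
  expect_equal(unname(empty), rep(0, 6))

  long <- vectorize_state(list(nodes = "n01", edges = NULL),
                          node_order = sprintf("n%02d", 1:30))
  expect_length(long, 30 + 435)

  expect_error(
    vectorize_state(list(nodes = "zz", edges = NULL), node_order = c("a")),
    "outside the universe")
})

test_that("dynamic states stop at the referral point and label it", {
  log <- mini_log(referral_rows())
  expect_message(ds <- build_dynamic_states(log), "1 patient")
  expect_equal(nrow(ds$x), 5)  # 3 states for R1, 2 for R2; N1 dropped
  expect_equal(ds$y[ds$patient == "R1"], c(0L, 0L, 1L))
  expect_equal(ds$y[ds$patient == "R2"], c(0L, 1L))
  # exactly one positive per referred patient
  expect_true(all(tapply(ds$y, ds$patient, sum) == 1))
  # monotone growth: bitwise X_t <= X_{t+1}
  for (p in unique(ds$patient)) {
    xs <- ds$x[ds$patient == p, , drop = FALSE]
    if (nrow(xs) > 1) {
      expect_true(all(diff(xs) >= 0))
    }
  }
  # the trigger edge appears only in the final (positive) state of R1
  expect_equal(unname(ds$x[ds$patient == "R1", "Patient File|Registrar"]),
               c(0, 0, 1))
})

test_that("a referral at the first interaction yields one positive state", {
  rows <- list(mini_row("A", "10:00", "Consultant; Patient", "",
                        "Referral to Emergency Psychiatry"),
               mini_row("B", "10:00", "Consultant; Patient", "",
                        "Referral to Emergency Psychiatry"),
               mini_row("B", "10:30", "Nurse; Patient"))
  # B's post-referral interaction is discarded; universe shared
  ds <- build_dynamic_states(mini_log(rows))
  expect_equal(nrow(ds$x), 2)
  expect_equal(ds$y, c(1L, 1L))
})

test_that("Bernoulli NB reproduces the closed-form micro example", {
  x <- matrix(c(1, 1, 0, 0, 1), ncol = 1)
  y <- c(1, 1, 0, 0, 0)
  fit <- fit_bernoulli_nb(x, y)
  expect_equal(unname(fit$prob1[1, "1"]), 3 / 4)
  expect_equal(unname(fit$prob1[1, "0"]), 2 / 5)
  post <- predict(fit, matrix(1, 1, 1), type = "posterior")
  # 0.4 * 0.75 vs 0.6 * 0.4
  expect_equal(unname(post[1, "1"]), 0.3 / (0.3 + 0.24))
  expect_equal(predict(fit, matrix(c(1, 0), 2, 1)), c(1L, 0L))

  # a feature absent from one class is smoothed, never zero
  x2 <- cbind(x, 0)
  fit2 <- fit_bernoulli_nb(x2, y)
  expect_equal(unname(fit2$prob1[2, "1"]), 1 / 4)
  expect_true(all(fit2$prob1 > 0 & fit2$prob1 < 1))

  expect_error(fit_bernoulli_nb(x, rep(1, 5)), "single class")
})

test_that("posterior ties are broken toward no-referral", {
  x <- matrix(1, 4, 1)
  y <- c(0, 0, 1, 1)
  fit <- fit_bernoulli_nb(x, y)
  expect_equal(predict(fit, matrix(1, 1, 1)), 0L)
})

test_that("NB posteriors agree with brute-force Bayes products", {
  set.seed(71)
  for (rep in 1:10) {
    nf <- sample(2:6, 1)
    n <- 30
    x <- matrix(rbinom(n * nf, 1, runif(nf)), n, nf, byrow = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    fit <- fit_bernoulli_nb(x, y)
    xnew <- matrix(rbinom(5 * nf, 1, 0.5), 5, nf)
    expect_equal(unname(predict(fit, xnew, type = "posterior")),
                 unname(bf_nb_posterior(x, y, xnew)), tolerance = 1e-12)
  }
})

test_that("NB matches an independent reference implementation", {
  set.seed(72)
  nf <- 4
  x <- matrix(rbinom(200, 1, 0.4), 50, nf)
  y <- rbinom(50, 1, 0.5)
  fit <- fit_bernoulli_nb(x, y)
  df <- as.data.frame(lapply(as.data.frame(x), factor, levels = c(0, 1)))
  ref <- e1071::naiveBayes(df, factor(y, levels = c(0, 1)), laplace = 1)
  post_ref <- predict(ref, df, type = "raw")
  post <- predict(fit, x, type = "posterior")
  expect_equal(unname(post[, "1"]), unname(post_ref[, 2]), tolerance = 1e-9)
})

test_that("balanced accuracy implements the sensitivity/specificity mean", {
  expect_equal(balanced_accuracy(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(balanced_accuracy(rep(0, 6), c(1, 1, 0, 0, 0, 0)), 0.5)
  # TP=1, FN=1, TN=2, FP=0
  expect_equal(balanced_accuracy(c(1, 0, 0, 0), c(1, 1, 0, 0)), 0.75)
  expect_error(balanced_accuracy(c(1, 0), c(1, 1)), "single class")
})

test_that("grouped splits keep whole patients together and are reproducible", {
  log <- mini_log(referral_rows())
  ds <- suppressMessages(build_dynamic_states(log))
  # replicate to 10 patients for a meaningful 80:20 split
  big <- ds
  big$x <- do.call(rbind, replicate(5, ds$x, simplify = FALSE))
  big$y <- rep(ds$y, 5)
  big$patient <- paste0(rep(ds$patient, 5), rep(1:5, each = length(ds$y)))
  set.seed(42)
  splits <- grouped_resample_splits(big, n_splits = 50)
  for (sp in splits) {
    expect_length(intersect(big$patient[sp$train], big$patient[sp$test]), 0)
    expect_length(unique(big$patient[sp$test]), 2)
    expect_equal(sort(unique(big$y[sp$test])), c(0L, 1L))
  }
  set.seed(42)
  splits2 <- grouped_resample_splits(big, n_splits = 50)
  expect_identical(splits, splits2)
})

test_that("oversampling balances the training classes by duplication", {
  set.seed(3)
  x <- matrix(rbinom(60, 1, 0.5), 20, 3)
  y <- c(rep(0, 16), rep(1, 4))
  os <- oversample_minority(x, y)
  expect_equal(sum(os$y == 0), sum(os$y == 1))
  # added rows are copies of minority rows
  extra <- os$x[21:nrow(os$x), , drop = FALSE]
  pool <- x[y == 1, , drop = FALSE]
  for (r in seq_len(nrow(extra))) {
    expect_true(any(apply(pool, 1, identical, y = extra[r, ])))
  }
})

test_that("features constant across the data have exactly zero importance", {
  log <- mini_log(referral_rows())
  ds <- suppressMessages(build_dynamic_states(log))
  big <- ds
  big$x <- do.call(rbind, replicate(5, ds$x, simplify = FALSE))
  big$y <- rep(ds$y, 5)
  big$patient <- paste0(rep(ds$patient, 5), rep(1:5, each = length(ds$y)))
  rep_out <- permutation_importance(big, n_splits = 40, seed = 1)
  # "Patient" is in every state: permutation cannot change anything
  row <- rep_out$importance[rep_out$importance$feature == "Patient", ]
  expect_equal(row$mean_importance, 0)
  expect_equal(row$lower95, 0)
  expect_equal(row$upper95, 0)
  expect_equal(rep_out$n_splits, 40)
  expect_length(rep_out$baseline, 40)
  expect_true(all(rep_out$baseline >= 0 & rep_out$baseline <= 1))
})
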