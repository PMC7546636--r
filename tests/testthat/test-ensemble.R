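toy_features <- function(n = 40, seed = 5) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject = rep(sprintf("s%02d", 1:(n / 4)), each = 4),
      segment = rep(1:4, n / 4),
      label = rep(c("C", "DM"), each = n / 2),
      k = c(runif(n / 2, 0.1, 1.2), runif(n / 2, -0.8, -0.1)),
      sigma = c(runif(n / 2, 1e-4, 3e-3), runif(n / 2, 0.1, 0.9))
    )
  })
}

test_that("base learners separate a linearly separable set deterministically", {
  d <- toy_features()
  bl <- fit_base_learners(d, config = ensemble_config(), seed = 1)
  P <- predict_learners(bl, d)
  expect_equal(dim(P), c(40, 3))
  expect_true(all(P >= 0 & P <= 1))
  y <- as.integer(d$label == "DM")
  expect_equal(as.integer(P[, "boost"] >= 0.5), y)   # training accuracy 1

  bl2 <- fit_base_learners(d, config = ensemble_config(), seed = 1)
  expect_identical(predict_learners(bl2, d), P)

  expect_error(fit_base_learners(d[d$label == "DM", ]),
               class = "rubeoscan_error_fit")
})

test_that("named configurations pin the tuned hyperparameters", {
  ref <- ensemble_config()
  expect_equal(ref$n_learners, 10)
  expect_equal(ref$learning_rate, 0.469)
  expect_equal(ref$max_splits, 38)
  expect_equal(ref$rus_max_splits, 39)
  alt <- ensemble_config(variant = "learners52")
  expect_equal(alt$n_learners, 52)
  expect_equal(alt$learning_rate, 0.107)
})

test_that("RUSBoost undersampling balances classes reproducibly", {
  y <- c(rep(1, 20), rep(0, 10))
  idx <- rubeoscan:::rus_index(y, seed = 3)
  expect_equal(sum(y[idx] == 1), 10)
  expect_equal(sum(y[idx] == 0), 10)
  expect_identical(idx, rubeoscan:::rus_index(y, seed = 3))
})

test_that("COWE weights solve the simplex MSE problem", {
  withr::local_seed(8)
  y <- rep(c(0, 1), each = 50)
  perfect <- y
  coin <- runif(100)
  w <- cowe_weights(rbind(perfect, coin), y)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= -1e-12))
  expect_lt(abs(w[1] - 1), 0.05)

  expect_equal(as.numeric(cowe_weights(matrix(perfect, 1), y)), 1)

  # identical learners tie-break to uniform
  w2 <- cowe_weights(rbind(coin, coin), y)
  expect_equal(as.numeric(w2), c(0.5, 0.5))

  expect_error(cowe_weights(rbind(perfect, coin), rep(1, 100)),
               class = "rubeoscan_error_fit")
})

test_that("projected-gradient COWE matches the grid oracle beyond 3 learners", {
  withr::local_seed(9)
  y <- rep(c(0, 1), each = 60)
  P <- cbind(
    0.8 * y + 0.1,                      # good
    runif(120),                         # noise
    0.6 * y + 0.2 + 0.1 * runif(120),   # decent
    1 - y                               # adversarial
  )
  w4 <- cowe_weights(P, y)
  expect_equal(attr(w4, "solver"), "projected_gradient")
  expect_equal(sum(w4), 1, tolerance = 1e-9)
  mse <- function(w) mean((as.numeric(P %*% w) - y)^2)
  # optimal CV-MSE no worse than any vertex (single learner), within tol
  vertex_best <- min(vapply(1:4, function(i) mse(diag(4)[i, ]), numeric(1)))
  expect_lte(mse(as.numeric(w4)), vertex_best + 1e-6)
  # and no worse than a coarse random-simplex search
  rand <- matrix(rexp(4 * 2000), ncol = 4)
  rand <- rand / rowSums(rand)
  expect_lte(mse(as.numeric(w4)), min(apply(rand, 1, mse)) + 1e-4)
})

test_that("classification applies the score >= 0.5 -> DM rule", {
  d <- toy_features()
  model <- fit_cowe(d, config = ensemble_config(), seed = 2)
  expect_equal(sum(model$weights), 1, tolerance = 1e-9)
  pred <- classify_segment(model, d)
  expect_equal(pred$label, ifelse(pred$score >= 0.5, "DM", "C"))
  # control-like and diabetic-like reference points
  ref <- tibble::tibble(k = c(0.0869, -0.378), sigma = c(0.0001, 0.156))
  expect_equal(classify_segment(model, ref)$label, c("C", "DM"))
  expect_error(classify_segment(list(), ref), class = "rubeoscan_error_state")
})

test_that("majority voting follows the 4-of-6 rule with ties undecided", {
  expect_equal(majority_vote(c("DM", "DM", "DM", "DM", "C", "C"))$final, "DM")
  expect_equal(majority_vote(c("DM", "DM", "DM", "C", "C", "C"))$final,
               "undecided")
  expect_equal(majority_vote(c("C", "C", "C", "C", "C", "DM"))$final, "C")
  expect_equal(majority_vote(c("DM", "DM", "C"))$final, "DM")  # strict majority
  expect_equal(majority_vote(c("DM", "C"))$final, "undecided")
  expect_equal(majority_vote("DM")$final, "DM")
  expect_error(majority_vote(character(0)), class = "rubeoscan_error_input")
  expect_error(majority_vote(c("DM", "x")), class = "rubeoscan_error_input")
})

test_that("flipping one vote toward a class never moves the decision away", {
  rank_for <- function(final) switch(final, C = -1, undecided = 0, DM = 1)
  for (n in c(3, 6)) {
    combos <- expand.grid(rep(list(c("C", "DM")), n), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      v <- unlist(combos[i, ])
      base <- rank_for(majority_vote(v)$final)
      for (j in which(v == "C")) {
        v2 <- v
        v2[j] <- "DM"
        expect_gte(rank_for(majority_vote(v2)$final), base)
      }
    }
  }
})

test_that("subject-level LOO-XV yields one fold per subject and clean metrics", {
  tails <- small_clean_tails()          # 10 subjects, clean separation
  loo <- loo_xv(tails, config = ensemble_config(), seed = 4)
  expect_equal(nrow(loo$decisions), 10)
  expect_equal(loo$metrics$sensitivity, 100)
  expect_equal(loo$metrics$specificity, 100)
  expect_equal(loo$metrics$undecided, 0)
  expect_gte(loo$metrics$auc, 0.99)
  expect_equal(nrow(tidy(loo)), 10)
  expect_equal(glance(loo)$accuracy, 100)

  expect_error(loo_xv(tails[tails$group == "DM", ]),
               class = "rubeoscan_error_input")
})

test_that("the unsupervised sgn(k) rule reproduces per-group recall from counts", {
  # 18 DM subjects (15 negative-k, 3 positive-k), 9 C (7 positive, 2 negative)
  mk <- function(gname, n, k_sign) {
    tibble::tibble(
      subject = rep(sprintf("%s%02d", gname, seq_len(n)), each = 6),
      group = gname, segment = rep(1:6, n),
      k = rep(k_sign, each = 6) * 0.4
    )
  }
  tf <- dplyr::bind_rows(
    mk("DM", 18, c(rep(-1, 15), rep(1, 3))),
    mk("C", 9, c(rep(1, 7), rep(-1, 2)))
  )
  res <- unsupervised_sgn_classifier(tf)
  expect_equal(res$metrics$sensitivity, 100 * 15 / 18, tolerance = 1e-9)
  expect_equal(res$metrics$specificity, 100 * 7 / 9, tolerance = 1e-9)
  expect_error(unsupervised_sgn_classifier(tf[, c("subject", "segment")]),
               class = "rubeoscan_error_input")
})
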