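# Segment-level classification from (k, sigma) tail features with a
# cross-validated optimal weighted ensemble (COWE) of base learners,
# subject-level leave-one-out cross-validation, and majority-vote fusion
# over video segments. Class convention: C = 0, DM = 1; a weighted score
# >= 0.5 predicts DM.

#' Ensemble configuration
#'
#' The reference configuration pins the boosted-tree hyperparameters to
#' the tuned values (10 shallow trees, learning rate 0.469, at most 38
#' splits per tree) so runs are reproducible; `variant = "learners52"`
#' selects the alternative tuned point (52 learners, learning rate
#' 0.107). With `imbalance = "rus"` the majority class is randomly
#' undersampled before boosting (RUSBoost-style; at most 39 splits),
#' which matters when one class is twice the size of the other.
#'
#' @param variant `"reference"` or `"learners52"`.
#' @param n_learners Number of boosting rounds.
#' @param learning_rate Boosting shrinkage.
#' @param max_splits Maximum internal splits per tree.
#' @param imbalance `"none"` or `"rus"` (random undersampling of the
#'   majority class).
#' @param rus_max_splits Maximum splits when `imbalance = "rus"`.
#' @param learners Character vector of base learners to combine:
#'   any of `"boost"`, `"lda"`, `"logit"`.
#' @param inner_folds Folds of the internal cross-validation that
#'   produces out-of-fold scores for the COWE weight fit (default 5).
#' @param features Feature columns used for classification; default
#'   `c("k", "sigma")`. Extras (`gamma`, `beta`, `theta`) can be added.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(variant = c("reference", "learners52"),
                            n_learners = NULL, learning_rate = NULL,
                            max_splits = 38, imbalance = c("none", "rus"),
                            rus_max_splits = 39,
                            learners = c("boost", "lda", "logit"),
                            inner_folds = 5, features = c("k", "sigma")) {
  variant <- match.arg(variant)
  imbalance <- match.arg(imbalance)
  defaults <- switch(variant,
    reference = list(n_learners = 10, learning_rate = 0.469),
    learners52 = list(n_learners = 52, learning_rate = 0.107)
  )
  n_learners <- n_learners %||% defaults$n_learners
  learning_rate <- learning_rate %||% defaults$learning_rate
  check_number(n_learners, "n_learners", lower = 1, integerish = TRUE)
  check_number(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  check_number(max_splits, "max_splits", lower = 1, integerish = TRUE)
  learners <- match.arg(learners, c("boost", "lda", "logit"),
                        several.ok = TRUE)
  structure(
    list(variant = variant, n_learners = n_learners,
         learning_rate = learning_rate, max_splits = max_splits,
         imbalance = imbalance, rus_max_splits = rus_max_splits,
         learners = learners, inner_folds = inner_folds,
         features = features),
    class = "ensemble_config"
  )
}

as_label01 <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    as.integer(as.character(labels) == "DM")
  } else {
    as.integer(labels)
  }
}

feature_matrix <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop_rube(paste0("Missing feature columns: ",
                     paste(missing, collapse = ", ")), "input")
  }
  as.matrix(data[, features, drop = FALSE])
}

rus_index <- function(y, seed) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(seq_along(y))
  maj <- if (n1 > n0) 1L else 0L
  keep_min <- which(y != maj)
  maj_idx <- which(y == maj)
  keep_maj <- with_seed_(seed, sample(maj_idx, length(keep_min)))
  sort(c(keep_min, keep_maj))
}

fit_one_learner <- function(kind, X, y, config, seed) {
  switch(kind,
    boost = {
      if (config$imbalance == "rus") {
        idx <- rus_index(y, seed)
        X <- X[idx, , drop = FALSE]
        y <- y[idx]
        leaves <- config$rus_max_splits + 1
      } else {
        leaves <- config$max_splits + 1
      }
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      with_seed_(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = config$learning_rate,
                      max_depth = 0, tree_method = "hist",
                      grow_policy = "lossguide", max_leaves = leaves,
                      nthread = 1, seed = seed %% 2147483647),
        data = dtrain, nrounds = config$n_learners, verbose = 0
      ))
    },
    lda = MASS::lda(X, grouping = factor(y, levels = c(0, 1))),
    logit = {
      df <- as.data.frame(X)
      df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    stop_rube(paste0("Unknown base learner: ", kind), "config")
  )
}

predict_one_learner <- function(kind, fit, X) {
  switch(kind,
    boost = as.numeric(predict(fit, xgboost::xgb.DMatrix(X, nthread = 1))),
    lda = as.numeric(predict(fit, X)$posterior[, "1"]),
    logit = {
      p <- suppressWarnings(
        as.numeric(predict(fit, as.data.frame(X), type = "response"))
      )
      p
    }
  )
}

#' Fit the base learners of the ensemble
#'
#' Fits every base learner in the configuration on the training features:
#' gradient-boosted shallow decision trees (the reference learner), linear
#' discriminant analysis, and logistic regression. Class-1 (DM)
#' probability scores of the learners are what COWE combines.
#'
#' @param data Data frame of segment features (and optionally a `label`
#'   column).
#' @param labels Class labels (`"C"`/`"DM"`, factor, or 0/1); taken from
#'   `data$label` when NULL.
#' @param config An [ensemble_config()].
#' @param seed Integer seed (reproducible fits).
#' @return A list of class `base_learners`.
#' @export
fit_base_learners <- function(data, labels = NULL,
                              config = ensemble_config(), seed = 1) {
  y <- as_label01(labels %||% data$label)
  if (length(unique(y)) < 2) {
    stop_rube("Training data must contain both classes.", "fit")
  }
  X <- feature_matrix(data, config$features)
  fits <- purrr::imap(
    rlang::set_names(config$learners),
    function(kind, nm) fit_one_learner(kind, X, y, config,
                                       derive_seed(seed, nm))
  )
  structure(list(fits = fits, kinds = config$learners, config = config,
                 seed = seed),
            class = "base_learners")
}

#' Score matrix of the base learners
#'
#' @param learners A `base_learners` object.
#' @param data New data with the configured feature columns.
#' @return A samples x learners matrix of class-1 (DM) probabilities.
#' @export
predict_learners <- function(learners, data) {
  stopifnot(inherits(learners, "base_learners"))
  X <- feature_matrix(data, learners$config$features)
  out <- vapply(
    seq_along(learners$kinds),
    function(i) predict_one_learner(learners$kinds[i], learners$fits[[i]], X),
    numeric(nrow(X))
  )
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- learners$kinds
  out
}

project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

#' Cross-validated optimal ensemble weights (COWE)
#'
#' Finds simplex weights (w_i >= 0, sum w_i = 1) over base-learner scores
#' that minimise the cross-validated mean squared prediction error of the
#' weighted score against the 0/1 labels. The scores should be
#' out-of-fold class-1 probabilities; the objective averages the fold
#' MSEs. With up to 3 learners the simplex is searched exhaustively on a
#' 0.01 grid; otherwise projected-gradient descent with multistart is
#' used. Near-ties (within 1e-9 of the optimum) are broken toward the
#' uniform weighting, so identical learners share weight equally.
#'
#' @param base_predictions Learners x samples matrix of class-1
#'   probability scores (a samples x learners matrix is accepted and
#'   transposed, detected from the label length).
#' @param labels 0/1 (or `"C"`/`"DM"`) labels per sample.
#' @param folds Number of folds or a fold-assignment vector used to
#'   average the MSE; default 5.
#' @return Named numeric weight vector with attributes `cv_mse` and
#'   `solver`.
#' @export
cowe_weights <- function(base_predictions, labels, folds = 5) {
  y <- as_label01(labels)
  if (length(unique(y)) < 2) {
    stop_rube("Labels must contain both classes.", "fit")
  }
  P <- as.matrix(base_predictions)
  if (nrow(P) != length(y) && ncol(P) == length(y)) P <- t(P)
  if (nrow(P) != length(y)) {
    stop_rube("Prediction matrix does not match the number of labels.", "input")
  }
  L <- ncol(P)
  fold_id <- if (length(folds) == length(y)) {
    as.integer(folds)
  } else {
    rep_len(seq_len(folds), length(y))
  }
  fold_mse <- function(w) {
    r <- as.numeric(P %*% w) - y
    mean(tapply(r^2, fold_id, mean))
  }
  if (L == 1) {
    w <- 1
  } else if (L <= 3) {
    grid <- seq(0, 1, by = 0.01)
    ws <- if (L == 2) {
      cbind(grid, 1 - grid)
    } else {
      g <- expand.grid(w1 = grid, w2 = grid)
      g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
      cbind(g$w1, g$w2, pmax(1 - g$w1 - g$w2, 0))
    }
    vals <- apply(ws, 1, fold_mse)
    near <- which(vals <= min(vals) + 1e-9)
    uni <- rep(1 / L, L)
    dist_uni <- apply(ws[near, , drop = FALSE], 1, function(w) sum((w - uni)^2))
    w <- ws[near[which.min(dist_uni)], ]
  } else {
    lip <- 2 * max(eigen(crossprod(P) / nrow(P), symmetric = TRUE,
                         only.values = TRUE)$values)
    starts <- rbind(diag(L), matrix(1 / L, 1, L),
                    with_seed_(7L, matrix(stats::runif(5 * L), 5, L)))
    starts <- t(apply(starts, 1, function(s) project_simplex(s / max(sum(s), 1e-9))))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      w <- starts[i, ]
      for (it in 1:500) {
        grad <- 2 * as.numeric(crossprod(P, as.numeric(P %*% w) - y)) / nrow(P)
        w_new <- project_simplex(w - grad / lip)
        if (sum(abs(w_new - w)) < 1e-12) break
        w <- w_new
      }
      v <- fold_mse(w)
      if (is.null(best) || v < best$v - 1e-12) best <- list(w = w, v = v)
    }
    w <- best$w
  }
  w <- as.numeric(w)
  names(w) <- colnames(P) %||% paste0("learner", seq_len(L))
  attr(w, "cv_mse") <- fold_mse(w)
  attr(w, "solver") <- if (L <= 3) "simplex_grid" else "projected_gradient"
  w
}

#' Fit a full COWE ensemble
#'
#' Fits the base learners on all training rows, produces out-of-fold
#' class-1 scores via seeded stratified internal cross-validation, and
#' optimises the COWE simplex weights on those scores.
#'
#' @inheritParams fit_base_learners
#' @return A list of class `cowe_ensemble` with `learners`, `weights`,
#'   `cv_mse`, `oof` (out-of-fold score matrix), `config`, `seed`.
#' @export
fit_cowe <- function(data, labels = NULL, config = ensemble_config(),
                     seed = 1) {
  y <- as_label01(labels %||% data$label)
  if (length(unique(y)) < 2) {
    stop_rube("Training data must contain both classes.", "fit")
  }
  n <- length(y)
  k <- min(config$inner_folds, min(table(y)))
  fold_id <- integer(n)
  for (cls in unique(y)) {  # stratified, seeded
    idx <- which(y == cls)
    fold_id[idx] <- with_seed_(
      derive_seed(seed, paste0("folds", cls)),
      sample(rep_len(seq_len(k), length(idx)))
    )
  }
  oof <- matrix(NA_real_, n, length(config$learners),
                dimnames = list(NULL, config$learners))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2) next
    bl <- fit_base_learners(data[tr, , drop = FALSE], y[tr], config,
                            derive_seed(seed, paste0("inner", f)))
    oof[!tr, ] <- predict_learners(bl, data[!tr, , drop = FALSE])
  }
  keep <- stats::complete.cases(oof)
  w <- cowe_weights(oof[keep, , drop = FALSE], y[keep], folds = fold_id[keep])
  learners <- fit_base_learners(data, y, config, seed)
  structure(
    list(learners = learners, weights = w, cv_mse = attr(w, "cv_mse"),
         oof = oof, config = config, seed = seed),
    class = "cowe_ensemble"
  )
}

#' Classify segments with a fitted COWE ensemble
#'
#' @param model A `cowe_ensemble` from [fit_cowe()].
#' @param features Data frame with the configured feature columns.
#' @return A tibble with `score` (weighted DM probability in `[0, 1]`)
#'   and `label` (`"DM"` when score >= 0.5, else `"C"`).
#' @export
classify_segment <- function(model, features) {
  if (!inherits(model, "cowe_ensemble")) {
    stop_rube("`model` must be a fitted `cowe_ensemble`.", "state")
  }
  Pm <- predict_learners(model$learners, features)
  score <- as.numeric(Pm %*% model$weights)
  tibble(score = score, label = ifelse(score >= 0.5, "DM", "C"))
}

#' Majority-vote fusion of segment labels
#'
#' A subject's final label is the class holding at least 4 of the 6
#' segment votes; with fewer segments aggregated, a strict majority
#' decides; an exact tie is `"undecided"`.
#'
#' @param segment_labels Character/factor vector of `"C"`/`"DM"` votes
#'   (1 to 6 entries).
#' @return A one-row tibble with `votes_dm`, `votes_c`, `n_segments`,
#'   `final`.
#' @export
#' @examples
#' majority_vote(c("DM", "DM", "DM", "DM", "C", "C"))$final   # "DM"
#' majority_vote(c("DM", "DM", "DM", "C", "C", "C"))$final    # "undecided"
majority_vote <- function(segment_labels) {
  v <- as.character(segment_labels)
  if (length(v) == 0) stop_rube("No segment labels to fuse.", "input")
  if (!all(v %in% c("C", "DM"))) {
    stop_rube("Segment labels must be \"C\" or \"DM\".", "input")
  }
  n <- length(v)
  votes_dm <- sum(v == "DM")
  votes_c <- n - votes_dm
  final <- if (votes_dm > n / 2) "DM" else if (votes_c > n / 2) "C" else "undecided"
  tibble(votes_dm = votes_dm, votes_c = votes_c, n_segments = n, final = final)
}

# Rank-based AUC of pooled segment scores (Mann-Whitney form).
pooled_auc <- function(scores, truth01) {
  r <- rank(scores)
  n1 <- sum(truth01 == 1)
  n0 <- sum(truth01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[truth01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

subject_metrics <- function(decisions) {
  truth <- as.character(decisions$group)
  pred <- decisions$final
  tp <- sum(truth == "DM" & pred == "DM")
  tn <- sum(truth == "C" & pred == "C")
  n_dm <- sum(truth == "DM")
  n_c <- sum(truth == "C")
  tibble(
    n_subjects = nrow(decisions),
    tp = tp, fn = n_dm - tp, tn = tn, fp = n_c - tn,
    undecided = sum(pred == "undecided"),
    accuracy = 100 * (tp + tn) / nrow(decisions),
    sensitivity = 100 * tp / n_dm,     # DM recall; undecided counts against
    specificity = 100 * tn / n_c       # C recall
  )
}

#' Subject-level leave-one-out cross-validation
#'
#' One fold per subject: all segments of the held-out subject are removed
#' from training (asserted — leakage is an internal error), a COWE
#' ensemble is fitted on the rest, the held-out segments are scored, and
#' the subject's label is fused by majority vote. Reports per-subject
#' decisions, pooled segment predictions, and subject- and segment-level
#' metrics (sensitivity = DM recall, specificity = C recall, in percent;
#' undecided subjects count against both).
#'
#' @param cohort Data frame of segment features with columns `subject`,
#'   `segment`, `label` (or `group`), and the configured features.
#' @param config An [ensemble_config()].
#' @param seed Integer seed.
#' @return A list of class `loo_result` with `decisions`,
#'   `segment_predictions`, `metrics`, `config`, `seed`.
#' @export
loo_xv <- function(cohort, config = ensemble_config(), seed = 1) {
  cohort <- as_tibble(cohort)
  if (!"label" %in% names(cohort) && "group" %in% names(cohort)) {
    cohort$label <- as.character(cohort$group)
  }
  y <- as_label01(cohort$label)
  subj_tab <- dplyr::distinct(cohort, .data$subject, .data$label)
  class_tab <- table(subj_tab$label)
  if (length(class_tab) < 2 || min(class_tab) < 2) {
    stop_rube("At least 2 subjects per class are required.", "input")
  }
  subjects <- subj_tab$subject
  seg_preds <- purrr::map(subjects, function(s) {
    tr <- cohort$subject != s
    if (any(cohort$subject[!tr] %in% cohort$subject[tr])) {
      abort("Leakage: held-out subject present in the training fold.",
            class = "rubeoscan_internal_error")
    }
    model <- fit_cowe(cohort[tr, , drop = FALSE], config = config,
                      seed = derive_seed(seed, s))
    pred <- classify_segment(model, cohort[!tr, , drop = FALSE])
    tibble(
      subject = cohort$subject[!tr], segment = cohort$segment[!tr],
      truth = as.character(cohort$label[!tr]),
      score = pred$score, predicted = pred$label
    )
  }) |> purrr::list_rbind()
  decisions <- seg_preds |>
    dplyr::group_by(.data$subject) |>
    dplyr::reframe(group = .data$truth[1], majority_vote(.data$predicted))
  metrics <- subject_metrics(decisions)
  seg_truth01 <- as_label01(seg_preds$truth)
  seg_pred01 <- as_label01(seg_preds$predicted)
  metrics$segment_accuracy <- 100 * mean(seg_pred01 == seg_truth01)
  metrics$segment_sensitivity <-
    100 * sum(seg_pred01 == 1 & seg_truth01 == 1) / sum(seg_truth01 == 1)
  metrics$segment_specificity <-
    100 * sum(seg_pred01 == 0 & seg_truth01 == 0) / sum(seg_truth01 == 0)
  metrics$auc <- pooled_auc(seg_preds$score, seg_truth01)
  structure(
    list(decisions = decisions, segment_predictions = seg_preds,
         metrics = metrics, config = config, seed = seed),
    class = "loo_result"
  )
}

#' Unsupervised sgn(k) subject classifier
#'
#' Classifies each segment by the sign of its fitted Pareto tail index
#' (k >= 0 is the scale-free control signature, k < 0 the random DM
#' signature) and fuses segments with the same majority-vote rule. No
#' training is involved.
#'
#' @param tail_features Data frame with columns `subject`, `segment`, and
#'   `k` (or `verdict`), plus optionally `group` for metrics.
#' @return A list of class `sgn_result` with `decisions` and (when true
#'   groups are present) `metrics`.
#' @export
unsupervised_sgn_classifier <- function(tail_features) {
  tf <- as_tibble(tail_features)
  if (!"verdict" %in% names(tf)) {
    if (!"k" %in% names(tf)) {
      stop_rube("Need a `k` or `verdict` column for every segment.", "input")
    }
    if (any(!is.finite(tf$k))) {
      stop_rube("Missing tail fits: non-finite `k` present.", "input")
    }
    tf$verdict <- ifelse(tf$k >= 0, "SOC_powerlaw", "TW_random")
  }
  tf$seg_label <- ifelse(tf$verdict == "SOC_powerlaw", "C", "DM")
  decisions <- tf |>
    dplyr::group_by(.data$subject) |>
    dplyr::reframe(
      group = if ("group" %in% names(tf)) as.character(.data$group[1]) else NA,
      majority_vote(.data$seg_label)
    )
  metrics <- if ("group" %in% names(tf)) subject_metrics(decisions) else NULL
  structure(list(decisions = decisions, metrics = metrics),
            class = "sgn_result")
}
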