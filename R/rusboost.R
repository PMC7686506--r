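#' Build classification datasets from the cohort table
#'
#' Produces the tumor-grade task (LGG / HGG / MET, from the patient
#' diagnosis) and the tissue-type task (REA / INF / NEC / TUM, from
#' histology). Non-pathological (NPL) rows are removed from both tasks
#' because only two such samples exist. Each observation is one sampled
#' pixel with its colocalized NADH/PPIX lifetime pair; the feature set is
#' chosen through the model formula (`label ~ tau_ppix_ns` for PPIX-only,
#' `label ~ tau_nadh_ns + tau_ppix_ns` for the combined classifier).
#'
#' @param cohort_table a [build_cohort_table()] result
#' @return list with data.frames `grade` and `tissue`, each holding
#'   `label` (factor), `tau_nadh_ns`, `tau_ppix_ns`, `sample_id`,
#'   `patient_id`
#' @export
build_datasets <- function(cohort_table) {
  tab <- cohort_table[cohort_table$tissue != "NPL", ]
  mk <- function(labels, levels_) {
    d <- data.frame(label = factor(labels, levels = levels_),
                    tau_nadh_ns = tab$tau_nadh_ns,
                    tau_ppix_ns = tab$tau_ppix_ns,
                    sample_id = tab$sample_id,
                    patient_id = tab$patient_id,
                    stringsAsFactors = FALSE)
    cnt <- table(d$label)
    if (any(cnt == 0))
      stop("empty class: ", paste(names(cnt)[cnt == 0], collapse = ", "))
    d
  }
  list(grade = mk(tab$grade, c("LGG", "HGG", "MET")),
       tissue = mk(tab$tissue, c("REA", "INF", "NEC", "TUM")))
}

#' Classifier configuration
#'
#' Hyperparameters of the RUS-boosted tree ensemble. Defaults mirror the
#' common RUSBoost configuration: 30 shallow trees, learning rate 0.1, and
#' per-iteration undersampling of every non-minority class to the minority
#' class size.
#'
#' @param n_learners number of boosting iterations
#' @param learning_rate shrinkage applied to the weight update, in (0, 1]
#' @param max_tree_splits cap on decision splits per tree (implemented as
#'   the corresponding depth limit of a binary CART tree)
#' @param undersample_ratio target size of each class per iteration as a
#'   multiple of the minority-class size
#' @param n_folds cross-validation folds
#' @param seed RNG seed
#' @return object of class `classifier_config`
#' @export
classifier_config <- function(n_learners = 30L, learning_rate = 0.1,
                              max_tree_splits = 20L, undersample_ratio = 1.0,
                              n_folds = 5L, seed = 1L) {
  stopifnot(n_learners >= 1L, n_folds >= 2L,
            learning_rate > 0, learning_rate <= 1, undersample_ratio > 0)
  structure(list(n_learners = as.integer(n_learners),
                 learning_rate = learning_rate,
                 max_tree_splits = as.integer(max_tree_splits),
                 undersample_ratio = undersample_ratio,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "classifier_config")
}

# class-probability matrix (n x K, columns in `classes` order) from a tree
tree_probs <- function(tree, data, classes) {
  p <- predict(tree, newdata = data, type = "prob")
  out <- matrix(0, nrow(data), length(classes),
                dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

#' RUS-boosted decision trees
#'
#' Boosted ensemble of depth-limited CART trees for imbalanced multi-class
#' problems, following the AdaBoost.M2 pseudo-loss formulation with random
#' under-sampling (RUS): at each iteration every non-minority class is
#' randomly undersampled (respecting the current observation weights) to
#' `undersample_ratio` times the minority-class size before the weak
#' learner is fitted, so minority classes keep influencing every learner.
#' Iterations whose pseudo-loss reaches 0.5 are discarded and the weights
#' reset (standard safeguard). Trees vote with weight `log(1/beta_t)` on
#' their class-probability outputs.
#'
#' @param formula model formula, e.g. `label ~ tau_nadh_ns + tau_ppix_ns`
#' @param data data.frame holding the response factor and features
#' @param config a [classifier_config()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @return object of class `rusboost`: `trees`, `log_inv_beta` vote
#'   weights, `classes`, `formula`, `config`, `n_discarded`
#' @export
rusboost <- function(formula, data, config = classifier_config(),
                     seed = config$seed) {
  stopifnot(inherits(config, "classifier_config"))
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  classes <- levels(y)
  K <- length(classes)
  if (K < 2L) stop("need at least two classes")
  m <- length(y)
  depth <- max(1L, floor(log2(config$max_tree_splits + 1)))
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, xval = 0,
                               minsplit = 20, minbucket = 7)
  with_seed(seed, function() {
    # mislabel weight distribution D(i, y), zero on the true label
    D <- matrix(1 / (m * (K - 1)), m, K, dimnames = list(NULL, classes))
    D[cbind(seq_len(m), as.integer(y))] <- 0
    trees <- list()
    log_inv_beta <- numeric(0)
    n_discarded <- 0L
    t <- 0L
    max_attempts <- 3L * config$n_learners
    attempts <- 0L
    while (t < config$n_learners && attempts < max_attempts) {
      attempts <- attempts + 1L
      w_obs <- rowSums(D)
      # random undersampling: cap each class at ratio x minority size,
      # drawing within class proportionally to current weights
      cls_n <- table(y)
      target <- max(1L, ceiling(config$undersample_ratio * min(cls_n)))
      keep <- unlist(lapply(classes, function(cl) {
        idx <- which(y == cl)
        if (length(idx) <= target) return(idx)
        pr <- w_obs[idx]
        if (sum(pr) <= 0) pr <- rep(1, length(idx))
        sample(idx, target, prob = pr)
      }), use.names = FALSE)
      sub <- mf[keep, , drop = FALSE]
      wts <- w_obs[keep]
      if (sum(wts) <= 0) wts <- rep(1, length(keep))
      wts <- wts / mean(wts)
      # do.call forces the weights vector into the call: rpart resolves
      # `weights` by non-standard evaluation and would not see a local
      tree <- do.call(rpart::rpart,
                      list(formula = formula, data = sub, weights = wts,
                           method = "class", control = ctrl))
      h <- tree_probs(tree, mf, classes)
      h_true <- h[cbind(seq_len(m), as.integer(y))]
      # AdaBoost.M2 pseudo-loss over the mislabel distribution
      eps <- 0.5 * sum(D * (1 - h_true + h))
      if (eps >= 0.5) {
        n_discarded <- n_discarded + 1L
        D <- matrix(1 / (m * (K - 1)), m, K, dimnames = list(NULL, classes))
        D[cbind(seq_len(m), as.integer(y))] <- 0
        next
      }
      eps <- max(eps, 1e-10)
      beta <- eps / (1 - eps)
      expo <- config$learning_rate * 0.5 * (1 + h_true - h)
      D <- D * beta^expo
      D[cbind(seq_len(m), as.integer(y))] <- 0
      D <- D / sum(D)
      t <- t + 1L
      trees[[t]] <- tree
      log_inv_beta[t] <- log(1 / beta)
    }
    if (t == 0L) stop("boosting failed: every iteration had pseudo-loss >= 0.5")
    structure(list(trees = trees, log_inv_beta = log_inv_beta,
                   classes = classes, formula = formula, config = config,
                   n_discarded = n_discarded),
              class = "rusboost")
  })
}

#' @export
print.rusboost <- function(x, ...) {
  cat(sprintf("RUS-boosted trees: %d learners, %d classes (%s)\n",
              length(x$trees), length(x$classes),
              paste(x$classes, collapse = ", ")))
  if (x$n_discarded > 0)
    cat(sprintf("  (%d iterations discarded for pseudo-loss >= 0.5)\n",
                x$n_discarded))
  invisible(x)
}

#' Predict from a RUS-boosted ensemble
#'
#' @param object a [rusboost()] model
#' @param newdata data.frame of features
#' @param type `"class"` for labels, `"prob"` for normalized vote scores
#' @param ... unused
#' @return factor of predicted labels, or a matrix of class scores
#' @export
predict.rusboost <- function(object, newdata,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  score <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (t in seq_along(object$trees))
    score <- score +
      object$log_inv_beta[t] * tree_probs(object$trees[[t]], newdata,
                                          object$classes)
  if (type == "prob") return(score / pmax(rowSums(score), .Machine$double.eps))
  factor(object$classes[max.col(score, ties.method = "first")],
         levels = object$classes)
}

#' Cross-validated RUSBoost evaluation
#'
#' Fivefold (by default) cross-validation with folds drawn uniformly over
#' observations, deliberately ignoring the patient/sample grouping
#' ("patient-unspecific" partition — prone to optimism since pixels of one
#' sample land in both train and test, but the alternative leaves the
#' smallest classes nearly empty). Set `group_by_patient = TRUE` for the
#' grouped alternative. Reports the pooled confusion matrix, row-normalized
#' rates in percent, and observation-level overall accuracy.
#'
#' @param formula model formula selecting the feature set
#' @param data dataset from [build_datasets()]
#' @param config a [classifier_config()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @param group_by_patient if `TRUE`, folds are drawn over patients
#' @return object of class `rusboost_cv`: `accuracy`, `confusion` counts,
#'   `confusion_rate` (row %), `fold` assignments, `per_fold_accuracy`
#' @export
cross_validate <- function(formula, data, config = classifier_config(),
                           seed = config$seed, group_by_patient = FALSE) {
  y <- model.response(model.frame(formula, data))
  y <- droplevels(factor(y))
  n <- length(y)
  k <- config$n_folds
  fold <- with_seed(mix_seed(seed, 101L), function() {
    if (group_by_patient) {
      pats <- unique(data$patient_id)
      pf <- sample(rep(seq_len(k), length.out = length(pats)))
      pf[match(data$patient_id, pats)]
    } else {
      f <- sample(rep(seq_len(k), length.out = n))
      tries <- 0L
      # every fold's training part must contain every class
      while (tries < 20L &&
             any(vapply(seq_len(k), function(j)
               nlevels(droplevels(y[f != j])) < nlevels(y), TRUE))) {
        f <- unsplit(lapply(split(seq_len(n), y), function(idx)
          sample(rep(seq_len(k), length.out = length(idx)))), y)
        tries <- tries + 1L
      }
      f
    }
  })
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (j in seq_len(k)) {
    fit <- rusboost(formula, data[fold != j, , drop = FALSE], config,
                    seed = mix_seed(seed, j))
    pred[fold == j] <- predict(fit, data[fold == j, , drop = FALSE])
  }
  confusion <- table(true = y, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  rate <- sweep(confusion, 1, pmax(rowSums(confusion), 1), "/") * 100
  per_fold <- vapply(seq_len(k), function(j)
    mean(pred[fold == j] == y[fold == j]), 0)
  structure(list(accuracy = acc, confusion = confusion,
                 confusion_rate = rate, fold = fold,
                 per_fold_accuracy = per_fold, n = n,
                 formula = formula, config = config, seed = seed),
            class = "rusboost_cv")
}

#' @export
print.rusboost_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV of RUS-boosted trees on %d observations\n",
              x$config$n_folds, x$n))
  cat(sprintf("Overall accuracy: %.1f%%\n", 100 * x$accuracy))
  cat("Row-normalized confusion (%):\n")
  print(round(x$confusion_rate, 1))
  invisible(x)
}
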