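## Pathway scoring: feature construction (chassis taxon, pathway Gibbs
## energy, fraction-of-reaction target flux, aggregated reaction
## fingerprints, enzyme-availability scores), a gradient-boosted global
## classifier with stratified cross-validation, the non-learned direct score,
## and top-k recovery of reference pathways.

#' Build the feature vector of a pathway
#'
#' Pathway-level features (chassis taxonomy id, pathway Gibbs energy, target
#' flux) are joined with order-free aggregates of the reaction-level features:
#' elementwise sum of the reaction fingerprints, mean enzyme-availability
#' (rule) score, sum of reaction Gibbs energies, and the reaction count.
#' Missing Gibbs energy or flux is imputed with 0 and flagged in a dedicated
#' binary feature, so pathways with unresolved species remain scoreable.
#'
#' @param p an `rp_pathway` whose properties have been populated (see
#'   [annotate_thermo()] and [fraction_of_reaction_fba()]).
#' @param chassis an `rp_chassis` (supplies the taxonomy id).
#' @param nbits fingerprint width.
#' @return named numeric vector of length `nbits + 8`.
#' @export
build_features <- function(p, chassis, nbits = FP_BITS) {
  dg <- p$properties$pathway_dg
  flux <- p$properties$target_flux
  fp <- integer(nbits)
  rdg <- 0
  avail <- numeric(0)
  for (r in p$reactions) {
    fp <- fp + reaction_fingerprint(r, p$species, nbits = nbits)
    if (!is.null(r$dg_prime)) rdg <- rdg + r$dg_prime
    avail <- c(avail, r$rule_score %||% NA_real_)
  }
  availability_mean <- mean(avail, na.rm = TRUE)
  if (!is.finite(availability_mean)) availability_mean <- 0
  out <- c(
    taxon_id = as.numeric(chassis$taxon_id),
    pathway_dg = dg %||% 0,
    dg_missing = as.numeric(is.null(dg)),
    target_flux = flux %||% 0,
    flux_missing = as.numeric(is.null(flux)),
    availability_mean = availability_mean,
    reaction_dg_sum = rdg,
    n_reactions = length(p$reactions),
    stats::setNames(as.numeric(fp), sprintf("fp%d", seq_len(nbits) - 1L))
  )
  out
}

#' Assemble a feature matrix for a pathway collection
#'
#' @param pathways list of `rp_pathway`.
#' @param chassis an `rp_chassis` shared by the collection.
#' @param nbits fingerprint width.
#' @return numeric matrix, one row per pathway (row names = pathway ids).
#' @export
feature_matrix <- function(pathways, chassis, nbits = FP_BITS) {
  rows <- lapply(pathways, build_features, chassis = chassis, nbits = nbits)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(pathways, `[[`, character(1), "id")
  m
}

stratified_folds <- function(y, nfolds, seed) {
  folds <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

#' Train the gradient-boosted global classifier
#'
#' Binary gradient-boosted tree classifier (XGBoost) over pathway feature
#' vectors, with maximum tree depth 1000 and shrinkage (learning rate) 0.3;
#' remaining hyperparameters stay at library defaults. Performance is
#' estimated by stratified 4-fold cross-validation: overall accuracy and
#' false-positive rate at the 0.5 probability threshold.
#'
#' @param x numeric feature matrix (rows = pathways).
#' @param y binary labels (0/1 or logical), both classes required.
#' @param nfolds number of CV folds (default 4).
#' @param seed seed for the fold assignment (default 42).
#' @param nrounds boosting rounds (default 100).
#' @param max_depth,eta tree depth and shrinkage.
#' @param threshold probability cut for the CV metrics.
#' @return list of class `rp_classifier` with `model` (trained on all data),
#'   `cv` (`accuracy`, `fpr`, per-fold accuracies) and the settings.
#' @export
train_global_classifier <- function(x, y, nfolds = 4L, seed = 42L,
                                    nrounds = 100L, max_depth = 1000L,
                                    eta = 0.3, threshold = 0.5) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) {
    stop("training needs both a positive and a negative class")
  }
  x <- as.matrix(x)
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, nthread = 1)

  folds <- stratified_folds(y, nfolds, seed)
  pred <- rep(NA_real_, length(y))
  fold_acc <- numeric(nfolds)
  for (k in seq_len(nfolds)) {
    tr <- folds != k
    dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = nrounds, verbose = 0)
    pred[!tr] <- stats::predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
    fold_acc[k] <- mean((pred[!tr] > threshold) == (y[!tr] == 1))
  }
  hard <- pred > threshold
  accuracy <- mean(hard == (y == 1))
  negatives <- y == 0
  fpr <- if (any(negatives)) mean(hard[negatives]) else NA_real_

  final <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = nrounds, verbose = 0)
  structure(
    list(model = final,
         cv = list(accuracy = accuracy, fpr = fpr, fold_accuracy = fold_acc,
                   prediction = pred),
         feature_names = colnames(x), threshold = threshold,
         nfolds = nfolds, seed = seed),
    class = "rp_classifier")
}

#' Global (machine-learned) pathway score
#'
#' Positive-class probability of a pathway under a trained classifier.
#'
#' @param classifier an `rp_classifier` from [train_global_classifier()].
#' @param features a feature vector from [build_features()], or a matrix of
#'   them (one row per pathway).
#' @return numeric vector of scores in \[0, 1\].
#' @export
global_score <- function(classifier, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  if (ncol(features) != length(classifier$feature_names)) {
    stop(sprintf("feature dimensionality mismatch: got %d, model expects %d",
                 ncol(features), length(classifier$feature_names)))
  }
  stats::predict(classifier$model, xgboost::xgb.DMatrix(as.matrix(features)))
}

minmax <- function(v) {
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps^0.5) return(rep(0.5, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Direct (non-learned) pathway score
#'
#' Sum of four criteria computed across a candidate set sharing one (target,
#' chassis) pair: the inverse pathway length, the min-max normalized negated
#' pathway Gibbs energy (favoring strongly negative values), the min-max
#' normalized mean enzyme-availability score, and the min-max normalized
#' target flux. When a criterion is constant across the set its normalized
#' value is 0.5 for every candidate.
#'
#' @param candidates non-empty list of `rp_pathway` with populated
#'   properties (`pathway_dg`, `target_flux`) and rule scores.
#' @return data frame with one row per candidate: `pathway_id`, the four
#'   components (`inv_length`, `neg_norm_dg`, `norm_availability`,
#'   `norm_flux`) and their sum `value`.
#' @export
direct_score <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  n_rxn <- vapply(candidates, function(p) length(p$reactions), numeric(1))
  dg <- vapply(candidates, function(p) p$properties$pathway_dg %||% 0, numeric(1))
  flux <- vapply(candidates, function(p) p$properties$target_flux %||% 0, numeric(1))
  avail <- vapply(candidates, function(p) {
    v <- vapply(p$reactions, function(r) r$rule_score %||% NA_real_, numeric(1))
    m <- mean(v, na.rm = TRUE)
    if (is.finite(m)) m else 0
  }, numeric(1))
  comp <- data.frame(
    pathway_id = vapply(candidates, `[[`, character(1), "id"),
    inv_length = 1 / n_rxn,
    neg_norm_dg = minmax(-dg),
    norm_availability = minmax(avail),
    norm_flux = minmax(flux),
    stringsAsFactors = FALSE)
  comp$value <- comp$inv_length + comp$neg_norm_dg + comp$norm_availability +
    comp$norm_flux
  comp
}

#' Top-k recovery of reference pathways
#'
#' For every (target, chassis) group containing at least one reference
#' pathway, the group counts as recovered when a reference's score ranks
#' among the k highest distinct score values of the group (ties share a
#' rank). Returns the fraction of recovered groups.
#'
#' @param scored data frame with columns `group`, `score`, `is_reference`.
#' @param k rank cutoff (>= 1).
#' @return fraction in \[0, 1\].
#' @export
topk_recovery <- function(scored, k) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  stopifnot(all(c("group", "score", "is_reference") %in% names(scored)))
  groups <- split(scored, scored$group)
  with_ref <- Filter(function(g) any(g$is_reference), groups)
  if (!length(with_ref)) return(NA_real_)
  recovered <- vapply(with_ref, function(g) {
    distinct <- sort(unique(g$score), decreasing = TRUE)
    cutoff <- distinct[min(k, length(distinct))]
    any(g$score[g$is_reference] >= cutoff)
  }, logical(1))
  mean(recovered)
}
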