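make_scored_collection <- function(n = 60, seed = 21, effect = 3,
                                   pos_frac = 0.095) {
  ch <- make_toy_chassis(5, seed = 1)
  pw <- make_pathway_set(n, ch, seed = seed, positive_fraction = pos_frac,
                         effect_size = effect, n_reactions_range = c(2, 4))
  list(ch = ch, pw = pw)
}

test_that("feature vectors are deterministic and order-free", {
  s <- make_scored_collection(4)
  p <- s$pw$pathways[[1]]
  f1 <- build_features(p, s$ch)
  f2 <- build_features(p, s$ch)
  expect_identical(f1, f2)
  expect_length(f1, 4096 + 8)
  # permuting the reaction list leaves the vector unchanged
  p_perm <- p
  perm <- rev(seq_along(p$reactions))
  p_perm$reactions <- p$reactions[perm]
  p_perm$groups$rp_pathway <- names(p_perm$reactions)
  expect_identical(build_features(p_perm, s$ch), f1)
  # single-reaction pathway: availability equals that reaction's rule score
  single <- pathway_record(
    "one",
    reactions = list(reaction_record("r", c(A = 1), c(T = 1),
                                     rule_score = 0.61)),
    target_id = "T",
    species = list(species_record("A", smiles = "CCO"),
                   species_record("T", smiles = "CCC")))
  expect_equal(unname(build_features(single, s$ch)["availability_mean"]), 0.61)
})

test_that("missing energies and fluxes are imputed with an explicit flag", {
  s <- make_scored_collection(2)
  p <- s$pw$pathways[[1]]
  p$properties$pathway_dg <- NULL
  p$properties$target_flux <- NULL
  f <- build_features(p, s$ch)
  expect_equal(unname(f["pathway_dg"]), 0)
  expect_equal(unname(f["dg_missing"]), 1)
  expect_equal(unname(f["target_flux"]), 0)
  expect_equal(unname(f["flux_missing"]), 1)
})

test_that("the classifier separates planted classes and collapses under shuffling", {
  s <- make_scored_collection(200, seed = 31, effect = 3)
  X <- feature_matrix(s$pw$pathways, s$ch)
  clf <- train_global_classifier(X, s$pw$labels)
  expect_gte(clf$cv$accuracy, 0.95)
  expect_lte(clf$cv$fpr, 0.10)
  # label shuffling: accuracy within +-0.05 of the majority-class rate
  set.seed(17)
  y_shuf <- sample(s$pw$labels)
  clf0 <- train_global_classifier(X, y_shuf)
  majority <- max(mean(y_shuf), 1 - mean(y_shuf))
  expect_lt(abs(clf0$cv$accuracy - majority), 0.05)
  # single-class input is a training error
  expect_error(train_global_classifier(X, rep(TRUE, nrow(X))), "class")
})

test_that("cross-validated accuracy grows with the planted effect size", {
  accs <- vapply(c(0, 1.5, 3), function(eff) {
    s <- make_scored_collection(150, seed = 41, effect = eff)
    X <- feature_matrix(s$pw$pathways, s$ch)
    train_global_classifier(X, s$pw$labels)$cv$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
  expect_gt(accs[3], accs[1])
})

test_that("global scores are deterministic probabilities", {
  s <- make_scored_collection(80, seed = 51, effect = 3)
  X <- feature_matrix(s$pw$pathways, s$ch)
  clf <- train_global_classifier(X, s$pw$labels)
  sc <- global_score(clf, X)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(sc, global_score(clf, X))
  # a training positive from the separable set scores above the threshold
  pos <- which(s$pw$labels)[1]
  expect_gt(global_score(clf, X[pos, , drop = FALSE]), 0.5)
  # dimensionality mismatches are refused
  expect_error(global_score(clf, X[, 1:10]), "mismatch")
})

test_that("direct scores match hand arithmetic on a two-candidate set", {
  mk <- function(id, n, dg, flux, avail) {
    rx <- lapply(seq_len(n), function(j) {
      reaction_record(sprintf("%s_r%d", id, j),
                      stats::setNames(1, if (j == 1) "A" else sprintf("I%d", j - 1)),
                      stats::setNames(1, if (j == n) "T" else sprintf("I%d", j)),
                      rule_score = avail)
    })
    ids <- unique(unlist(lapply(rx, function(r) c(names(r$reactants), names(r$products)))))
    pathway_record(id, rx, "T", lapply(ids, species_record),
                   properties = list(pathway_dg = dg, target_flux = flux))
  }
  a <- mk("a", 2, -50, 4, 0.9)
  b <- mk("b", 4, -10, 1, 0.3)
  got <- direct_score(list(a, b))
  # candidate a: shorter, more negative dG, higher availability, higher flux
  expect_equal(got$inv_length, c(1 / 2, 1 / 4))
  expect_equal(got$neg_norm_dg, c(1, 0))
  expect_equal(got$norm_availability, c(1, 0))
  expect_equal(got$norm_flux, c(1, 0))
  expect_equal(got$value, c(3.5, 0.25))
  # identical candidates score identically, with constant axes at 0.5
  same <- direct_score(list(a, a))
  expect_equal(same$value[1], same$value[2])
  # strict dominance implies a strictly maximal score
  expect_gt(got$value[1], got$value[2])
})

test_that("direct scores are invariant to affine rescaling of raw fluxes", {
  s <- make_scored_collection(10, seed = 61)
  base <- direct_score(s$pw$pathways)
  rescaled <- lapply(s$pw$pathways, function(p) {
    p$properties$target_flux <- 100 + 7 * p$properties$target_flux
    p
  })
  got <- direct_score(rescaled)
  expect_equal(got$norm_flux, base$norm_flux, tolerance = 1e-12)
})

test_that("top-k recovery ranks by distinct scores and is monotone in k", {
  scored <- data.frame(
    group = rep(c("g1", "g2"), each = 4),
    score = c(0.9, 0.8, 0.8, 0.1,   0.5, 0.4, 0.3, 0.2),
    is_reference = c(FALSE, FALSE, TRUE, FALSE,
                     FALSE, FALSE, FALSE, TRUE))
  # g1 reference shares the second-highest distinct score -> in top 2
  expect_equal(topk_recovery(scored, 1), 0)
  expect_equal(topk_recovery(scored, 2), 0.5)
  expect_equal(topk_recovery(scored, 4), 1)
  # k at least the group size always recovers present references
  expect_equal(topk_recovery(scored, 10), 1)
  # unique maximum recovered at k = 1
  top <- data.frame(group = "g", score = c(1, 0.2, 0.1),
                    is_reference = c(TRUE, FALSE, FALSE))
  expect_equal(topk_recovery(top, 1), 1)
  # monotone over a seeded random instance
  set.seed(5)
  rnd <- data.frame(group = rep(letters[1:6], each = 10),
                    score = round(stats::runif(60), 2),
                    is_reference = as.logical(stats::rbinom(60, 1, 0.15)))
  recov <- vapply(1:10, function(k) topk_recovery(rnd, k), numeric(1))
  expect_true(all(diff(recov) >= 0))
  expect_error(topk_recovery(rnd, 0), "k")
})
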