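test_that("completion creates one reaction per (rule, template) pair with cofactors", {
  fx <- make_rule_db(n_rules = 1, templates_per_rule = 2, seed = 1)
  t1 <- fx$master$transformations[[1]]
  done <- complete_transformation(t1, fx$db)
  expect_length(done, 2)
  # template 2 re-adds a cofactor pair with template stoichiometry
  r2 <- done[[2]]
  expect_true("CFA_1" %in% names(r2$reactants))
  expect_true("CFB_1" %in% names(r2$products))
  expect_equal(unname(r2$reactants[["CFA_1"]]), 1)
  # rule provenance is populated
  expect_identical(r2$rule_id, "RR_1")
  expect_identical(r2$template_id, "TPL_1_2")
  expect_true(r2$rule_score >= 0 && r2$rule_score <= 1)
  # the transformation's own species are retained
  expect_true(all(names(t1$lhs) %in% names(r2$reactants)))
  expect_true(all(names(t1$rhs) %in% names(r2$products)))
})

test_that("unknown rule ids raise a lookup error naming the id", {
  fx <- make_rule_db(n_rules = 1, templates_per_rule = 1, seed = 1)
  t_bad <- transformation("Tx", lhs = c(M0 = 1), rhs = c(M1 = 1),
                          rule_ids = "RR_MISSING")
  expect_error(complete_transformation(t_bad, fx$db), "RR_MISSING")
})

test_that("enumeration takes the Cartesian product of the per-transformation forks", {
  fx <- make_rule_db(n_rules = 2, templates_per_rule = c(2, 3), seed = 1)
  got <- enumerate_pathways(fx$master, fx$db, species = fx$species)
  expect_length(got, 6)
  # single alternative everywhere -> exactly one pathway, equal to completion
  fx1 <- make_rule_db(n_rules = 1, templates_per_rule = 1, seed = 2)
  got1 <- enumerate_pathways(fx1$master, fx1$db, species = fx1$species)
  expect_length(got1, 1)
  done <- complete_transformation(fx1$master$transformations[[1]], fx1$db)
  expect_identical(got1[[1]]$reactions[[1]]$reactants, done[[1]]$reactants)
  expect_identical(got1[[1]]$reactions[[1]]$products, done[[1]]$products)
})

test_that("two rules sharing a template collapse to one fork", {
  fx <- make_rule_db(n_rules = 2, templates_per_rule = c(2, 3), seed = 1,
                     share_template = TRUE)
  # transformation 1 has 3 raw alternatives, but one duplicates another
  got <- enumerate_pathways(fx$master, fx$db, species = fx$species)
  oracle <- brute_force_enumeration(fx$master, fx$db, fx$species)
  expect_length(got, length(oracle))
  expect_length(got, 6)
})

test_that("enumeration matches the brute-force oracle and is order-invariant", {
  for (seed in 1:4) {
    n_t <- 1 + seed %% 3
    tpr <- 1 + (seq_len(n_t) + seed) %% 3
    fx <- make_rule_db(n_rules = n_t, templates_per_rule = tpr, seed = seed,
                       share_template = seed %% 2 == 0)
    got <- enumerate_pathways(fx$master, fx$db, species = fx$species)
    oracle <- brute_force_enumeration(fx$master, fx$db, fx$species)
    expect_length(got, length(oracle))
    # upper bound: product of alternative counts
    n_alts <- vapply(fx$master$transformations, function(t) {
      sum(vapply(t$rule_ids, function(r) length(fx$db[[r]]), integer(1)))
    }, numeric(1))
    expect_lte(length(got), prod(n_alts))
    # every output pathway produces the target
    for (p in got) {
      produced <- unlist(lapply(p$reactions, function(r) names(r$products)))
      expect_true(fx$master$target_id %in% produced)
    }
    # listing order of rules within a transformation must not matter
    m_rev <- fx$master
    m_rev$transformations <- lapply(m_rev$transformations, function(t) {
      t$rule_ids <- rev(t$rule_ids)
      t
    })
    got_rev <- enumerate_pathways(m_rev, fx$db, species = fx$species)
    sig_set <- function(ps) {
      sort(vapply(ps, function(p) {
        paste(sort(vapply(p$reactions, pathranker:::reaction_signature,
                          character(1), species = p$species)), collapse = "||")
      }, character(1)))
    }
    expect_identical(sig_set(got), sig_set(got_rev))
  }
})

test_that("the keep-top cut ranks by mean rule score with lexicographic ties", {
  fx <- make_rule_db(n_rules = 2, templates_per_rule = c(2, 3), seed = 3)
  all6 <- enumerate_pathways(fx$master, fx$db, species = fx$species)
  top2 <- enumerate_pathways(fx$master, fx$db, species = fx$species, keep_top = 2)
  expect_length(top2, 2)
  mean_score <- function(p) mean(vapply(p$reactions, function(r) r$rule_score,
                                        numeric(1)))
  kept <- vapply(top2, mean_score, numeric(1))
  dropped <- vapply(all6, mean_score, numeric(1))
  expect_gte(min(kept), sort(dropped, decreasing = TRUE)[2] - 1e-12)
})

test_that("rule databases round-trip through the TSV dialect", {
  fx <- make_rule_db(n_rules = 2, templates_per_rule = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rule_db(fx$db, path)
  again <- read_rule_db(path)
  expect_identical(names(again), names(fx$db))
  expect_equal(again$RR_1[[2]]$lhs, fx$db$RR_1[[2]]$lhs)
  expect_equal(again$RR_1[[2]]$rule_score, fx$db$RR_1[[2]]$rule_score)
  # malformed equations and out-of-range scores are rejected
  expect_error(parse_equation("A -> B"), "<=>")
  bad <- data.frame(rule_id = "r", template_id = "t", equation = "1 A <=> 1 B",
                    direction = "forward", rule_score = 1.2)
  expect_error(read_rule_db(bad), "0, 1")
})
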