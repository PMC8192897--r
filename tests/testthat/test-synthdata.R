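test_that("generation is deterministic given the seed and loads strictly", {
  cfg <- school_sim_config(n_students = 40, seed = 123)
  a <- generate_school(cfg)
  b <- generate_school(cfg)
  expect_identical(a$network$adj, b$network$adj)
  expect_identical(a$network$aff, b$network$aff)
  expect_identical(a$attrs, b$attrs)

  dir <- withr::local_tempdir()
  write_generated_school(a, dir, "sch")
  back <- read_school(file.path(dir, "sch_arcs.csv"),
                      file.path(dir, "sch_affiliations.csv"),
                      file.path(dir, "sch_attributes.csv"), strict = TRUE)
  expect_equal(sum(back$network$adj), sum(a$network$adj))
  prov <- jsonlite::read_json(file.path(dir, "sch_provenance.json"))
  expect_equal(prov$seed, 123)
  expect_equal(prov$n_students, 40)
})

test_that("generated schools respect cap and structural-zero constraints", {
  for (seed in c(1, 2, 3)) {
    g <- generate_school(school_sim_config(n_students = 60, seed = seed))
    validate_network(g$network)
    out_deg <- rowSums(g$network$adj)
    expect_true(all(out_deg[g$network$respondent] <= 6))
    expect_true(all(out_deg[!g$network$respondent] == 0))
    # continuous attributes blank exactly for non-respondents
    expect_true(all(is.na(g$attrs$knowledge[!g$attrs$respondent])))
    expect_true(all(!is.na(g$attrs$knowledge[g$attrs$respondent])))
  }
})

test_that("peer-supporter share matches the selection-and-uptake process", {
  # invite top 25% of 200 (= 50), keep each w.p. 0.52: mean 26 PS (13%);
  # the seed-averaged count must sit inside the binomial 99% interval
  counts <- vapply(1:10, function(s)
    sum(generate_school(school_sim_config(n_students = 200,
                                          seed = 500 + s))$attrs$ps),
    numeric(1))
  half_width <- 2.576 * sqrt(50 * 0.52 * 0.48) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 26), half_width)
})

test_that("affiliation alignment raises the cross-level arc statistic", {
  spec <- model_spec(list(effect_term("ArcA"), effect_term("TXAXarc")))
  mean_txax <- function(alignment) {
    mean(vapply(1:20, function(s) {
      g <- generate_school(school_sim_config(
        n_students = 80, affiliation_alignment = alignment,
        seed = 900 + s))
      if (length(g$network$groups) == 0) return(0)
      unname(graph_statistics(g$network, g$attrs, spec)["Cross-level arc [TXAXarc]"])
    }, numeric(1)))
  }
  expect_gt(mean_txax(10), mean_txax(1))
})

test_that("gender homophily strength orders the interaction statistic", {
  spec <- model_spec(list(effect_term("ArcA"),
                          effect_term("Interaction", "gender")))
  mean_gi <- function(odds) {
    mean(vapply(1:20, function(s) {
      g <- generate_school(school_sim_config(
        n_students = 80, gender_match_odds = odds, seed = 700 + s))
      unname(graph_statistics(g$network, g$attrs,
                              spec)["Gender-Interaction"])
    }, numeric(1)))
  }
  m <- c(mean_gi(1), mean_gi(3), mean_gi(9))
  expect_true(all(diff(m) > 0))
})

test_that("model-based generation hits closed-form densities", {
  skel <- generate_school(school_sim_config(n_students = 20, seed = 55))
  spec <- model_spec(list(effect_term("ArcA")), condition_max_out = FALSE)
  nfree <- nrow(free_tie_variables(skel$network))
  # theta = 0: density ~ 1/2 of the free tie space
  n0 <- generate_from_model(skel$network, skel$attrs, 0, spec,
                            sampler_config(seed = 77, start = "empty"))
  expect_lt(abs(sum(n0$adj) / nfree - 0.5), 0.12)
  # theta = -3: expected density 1/(1+e^3) ~ 0.047
  n3 <- generate_from_model(skel$network, skel$attrs, -3, spec,
                            sampler_config(seed = 78, start = "empty"))
  expect_lt(sum(n3$adj) / nfree, 0.1)
  # determinism
  n3b <- generate_from_model(skel$network, skel$attrs, -3, spec,
                             sampler_config(seed = 78, start = "empty"))
  expect_identical(n3$adj, n3b$adj)
})

test_that("infeasible configurations are rejected", {
  expect_error(school_sim_config(n_students = 1, seed = 1))
  expect_error(school_sim_config(nomination_cap = 0, seed = 1))
  expect_error(school_sim_config(response_rate = 1.5, seed = 1))
  expect_error(school_sim_config(n_students = 10), "seed")
})
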