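# Graph statistics on the worked 3-student fixture (arcs 1->2, 2->1, 2->3;
# groups g1 = {1,2}, g2 = {2,3}; lambda = 2).  Expected values are frozen
# from hand enumeration of the closed forms.

test_that("all statistic families reproduce the hand-computed fixture", {
  g3 <- g3_fixture()
  z <- graph_statistics(g3$net, g3$attrs, all16_spec())
  expect_equal(unname(z[c("Density [ArcA]", "Reciprocity [ReciprocityA]")]),
               c(3, 1))
  # in-degrees all <= 1 contribute 0; only node 2 (out-degree 2) gives
  # 4 * ((1/2)^2 + 2/2 - 1) = 1
  expect_equal(unname(z[c("Popularity spread [AinSA]",
                          "Activity spread [AoutSA]")]), c(0, 1))
  # no arc has a completing two-path; the only two-path is 1->2->3 so the
  # ordered pair (1,3) contributes 2 * (1 - 1/2) = 1
  expect_equal(unname(z[c("Path closure [ATA-T]",
                          "Multiple 2-paths [A2PA-T]")]), c(0, 1))
  # x = (1,2,4) over arcs: senders 1+2+2, receivers 2+1+4, |diff| 1+1+2
  expect_equal(unname(z[c("Knowledge-Sender", "Knowledge-Receiver",
                          "Norms-Difference")]), c(5, 7, 4))
  # b = (1,0,1): no arc joins two 1-coded students
  expect_equal(unname(z["Gender-Interaction"]), 0)
  # dX = (1,2,1): sum din*dX = 4, sum dout*dX = 5; every arc shares exactly
  # one group; L3XAX = (1*2-1)+(2*1-1)+(2*1-1) = 3
  expect_equal(unname(z[c("Indegree [In2StarAX]", "Outdegree [Out2StarAX]",
                          "Cross-level arc [TXAXarc]",
                          "Cross-level 3-paths [L3XAX]")]), c(4, 5, 3, 3))
  # PS-talking products: ps*talk = (1,0,4); arcs weight senders (1,0,0) and
  # receivers (0,1,4)
  expect_equal(unname(z[c("PS Talking-Sender", "PS Talking-Receiver")]),
               c(1, 5))
})

test_that("every statistic vanishes on an arcless network", {
  g3 <- g3_fixture()
  empty <- mergm_network(g3$net$students, g3$net$groups,
                         aff = g3$net$aff)
  expect_true(all(graph_statistics(empty, g3$attrs, all16_spec()) == 0))
})

test_that("alternating star statistics match the alternating-series oracle", {
  spec <- function(l) model_spec(list(
    effect_term("ArcA"), effect_term("AinSA", lambda = l),
    effect_term("AoutSA", lambda = l)), condition_max_out = FALSE)
  set.seed(202)
  for (lambda in c(1.5, 2, 3)) {
    for (rep in 1:5) {
      rn <- random_multilevel(n = 10, p_resp = 1)
      z <- graph_statistics(rn$net, rn$attrs, spec(lambda))
      expect_equal(unname(z["Popularity spread [AinSA]"]),
                   alt_star_series(colSums(rn$net$adj), lambda),
                   tolerance = 1e-10)
      expect_equal(unname(z["Activity spread [AoutSA]"]),
                   alt_star_series(rowSums(rn$net$adj), lambda),
                   tolerance = 1e-10)
    }
  }
})

test_that("statistics are invariant under roster relabelling", {
  set.seed(303)
  for (rep in 1:5) {
    rn <- random_multilevel(n = 8)
    perm <- sample(8)
    net2 <- mergm_network(rn$net$students[perm], rn$net$groups,
                          rn$net$adj[perm, perm],
                          rn$net$aff[perm, , drop = FALSE],
                          rn$net$respondent[perm],
                          max_out = rn$net$max_out)
    attrs2 <- rn$attrs[perm, ]
    expect_equal(graph_statistics(net2, attrs2, all16_spec()),
                 graph_statistics(rn$net, rn$attrs, all16_spec()))
  }
})

test_that("change statistics handle first arcs and reciprocation", {
  g3 <- g3_fixture()
  empty <- mergm_network(g3$net$students, g3$net$groups, aff = g3$net$aff)
  d <- change_statistics(empty, g3$attrs, all16_spec(), 1, 2)
  expect_equal(unname(d["Density [ArcA]"]), 1)
  expect_equal(unname(d["Reciprocity [ReciprocityA]"]), 0)
  expect_equal(unname(d["Path closure [ATA-T]"]), 0)

  # 2->1 reciprocates the existing 1->2
  no21 <- g3$net; no21$adj["2", "1"] <- 0L
  d2 <- change_statistics(no21, g3$attrs, all16_spec(), 2, 1)
  expect_equal(unname(d2["Reciprocity [ReciprocityA]"]), 1)
  # change statistics are defined as on-minus-off regardless of state
  d3 <- change_statistics(g3$net, g3$attrs, all16_spec(), 2, 1)
  expect_equal(d2, d3)
})

test_that("dyad-level terms have background-independent change statistics", {
  linear <- c("Density [ArcA]", "Knowledge-Sender", "Knowledge-Receiver",
              "Gender-Interaction", "Norms-Difference", "PS Talking-Sender",
              "PS Talking-Receiver", "Indegree [In2StarAX]",
              "Outdegree [Out2StarAX]", "Cross-level arc [TXAXarc]",
              "Cross-level 3-paths [L3XAX]")
  set.seed(404)
  base <- random_multilevel(n = 7, p_resp = 1)
  for (rep in 1:5) {
    other <- random_multilevel(n = 7, p_resp = 1)
    net2 <- base$net; net2$adj <- other$net$adj   # same rosters/affiliations
    d1 <- change_statistics(base$net, base$attrs, all16_spec(), 1, 2)
    d2 <- change_statistics(net2, base$attrs, all16_spec(), 1, 2)
    expect_equal(d1[linear], d2[linear])
  }
})

test_that("term construction validates attributes and lambda", {
  expect_error(effect_term("Interaction", "knowledge"), "binary")
  expect_error(effect_term("Difference", "gender"), "continuous")
  expect_error(effect_term("Sender"), "requires an attribute")
  expect_error(effect_term("ArcA", "gender"), "does not take")
  expect_error(effect_term("AinSA", lambda = 0.5), "lambda")
  expect_error(effect_term("NoSuch"), "unknown")
  expect_error(model_spec(list(effect_term("ReciprocityA"))), "ArcA")
  expect_error(model_spec(list(effect_term("ArcA"), effect_term("ArcA"))),
               "duplicate")
  g3 <- g3_fixture()
  expect_error(change_statistics(g3$net, g3$attrs, all16_spec(), 1, 1),
               "free tie set")
  bad <- g3$net; bad$respondent[3] <- FALSE; bad$adj["3", ] <- 0L
  expect_error(change_statistics(bad, g3$attrs, all16_spec(), 3, 1),
               "free tie set")
})

test_that("model specifications round-trip through YAML", {
  spec <- school_model_spec(lambda = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(effect_labels(back), effect_labels(spec))
  expect_equal(back$terms[[3]]$lambda, 3)
  expect_true(back$condition_max_out)

  shipped <- read_model_spec(system.file("extdata", "default_school_model.yaml",
                                         package = "mergm"))
  expect_equal(effect_labels(shipped), effect_labels(school_model_spec()))
  expect_length(shipped$terms, 26)
})

test_that("the default school model tags every effect to one component", {
  spec <- school_model_spec()
  comp <- effect_components(spec)
  expect_length(comp, 26)
  expect_equal(sum(comp == "structural controls"), 6)
  expect_equal(sum(comp == "implementation fidelity"), 4)
  expect_equal(sum(comp == "mechanisms of impact"), 4)   # PS S/R + PS-talking
  expect_equal(sum(comp == "context"), 12)
})

test_that("missing attributes resolve by mean/zero imputation", {
  attrs <- data.frame(student = c("a", "b", "c"),
                      respondent = c(TRUE, TRUE, FALSE),
                      gender = c(1, NA, 0), ps = c(NA, 1, 0),
                      knowledge = c(2, 4, NA), norms = c(1, 1, NA),
                      talking = c(0, 2, NA))
  cv <- resolve_covariates(attrs)
  expect_equal(unname(cv[, "gender"]), c(1, 0, 0))       # binary -> 0
  expect_equal(unname(cv[, "knowledge"]), c(2, 4, 3))    # respondent mean
  cvz <- resolve_covariates(attrs, impute_continuous = "zero")
  expect_equal(unname(cvz[, "knowledge"]), c(2, 4, 0))
})
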