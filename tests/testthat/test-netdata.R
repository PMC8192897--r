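test_that("loading from records builds validated structures", {
  empty <- load_multilevel_network(
    data.frame(sender = character(), receiver = character()),
    data.frame(student = character(), group = character()),
    data.frame(student = character(), respondent = logical(),
               gender = numeric(), ps = numeric(), knowledge = numeric(),
               norms = numeric(), talking = numeric()))
  expect_equal(length(empty$network$students), 0)
  expect_equal(network_summary(empty$network)$arcs, 0)
  expect_true(is.na(network_summary(empty$network)$density))

  attrs <- data.frame(student = c("a", "b", "c"), respondent = TRUE,
                      gender = c(1, 0, 1), ps = 0, knowledge = 1,
                      norms = 1, talking = 1)
  got <- load_multilevel_network(
    data.frame(sender = c("a", "b", "b"), receiver = c("b", "a", "c")),
    data.frame(student = c("a", "b", "b", "c"),
               group = c("g1", "g1", "g2", "g2")),
    attrs)
  expect_equal(sum(got$network$adj), 3)
  expect_equal(sum(got$network$aff), 4)
  expect_equal(got$network$groups, c("g1", "g2"))
})

test_that("structural-zero and cap rules are enforced in strict mode", {
  attrs <- data.frame(student = c("a", "b", "c", "d"),
                      respondent = c(TRUE, TRUE, TRUE, FALSE),
                      gender = 0, ps = 0, knowledge = 1, norms = 1,
                      talking = 1)
  arcs_bad <- data.frame(sender = "d", receiver = "a")
  affs <- data.frame(student = character(), group = character())
  expect_error(load_multilevel_network(arcs_bad, affs, attrs),
               "structural-zero")
  expect_warning(
    ok <- load_multilevel_network(arcs_bad, affs, attrs, strict = FALSE),
    "structural-zero")
  expect_equal(sum(ok$network$adj), 0)

  expect_error(load_multilevel_network(
    data.frame(sender = "a", receiver = "a"), affs, attrs), "self-arc")
  expect_error(load_multilevel_network(
    data.frame(sender = "a", receiver = "zz"), affs, attrs), "unknown")

  many <- data.frame(sender = "a", receiver = c("b", "c", "d"))
  expect_error(load_multilevel_network(many, affs, attrs, max_out = 2),
               "nomination cap")
  expect_warning(
    capped <- load_multilevel_network(many, affs, attrs, max_out = 2,
                                      strict = FALSE),
    "nomination cap")
  expect_equal(sum(capped$network$adj), 2)
})

test_that("duplicate records collapse to binary ties with a warning", {
  attrs <- data.frame(student = c("a", "b"), respondent = TRUE, gender = 0,
                      ps = 0, knowledge = 1, norms = 1, talking = 1)
  expect_warning(
    got <- load_multilevel_network(
      data.frame(sender = c("a", "a"), receiver = c("b", "b")),
      data.frame(student = character(), group = character()), attrs),
    "duplicate arc")
  expect_equal(sum(got$network$adj), 1)
  expect_warning(
    got2 <- load_multilevel_network(
      data.frame(sender = character(), receiver = character()),
      data.frame(student = c("a", "a"), group = c("g1", "g1")), attrs),
    "duplicate affiliation")
  expect_equal(sum(got2$network$aff), 1)
})

test_that("free tie variables are the respondent-sender ordered pairs", {
  all10 <- mergm_network(sprintf("s%d", 1:10))
  expect_equal(nrow(free_tie_variables(all10)), 90)   # n(n-1), full response

  part <- mergm_network(c("a", "b", "c"),
                        respondent = c(TRUE, TRUE, FALSE))
  ftv <- free_tie_variables(part)
  expect_equal(nrow(ftv), 4)
  expect_false(any(ftv[, "sender"] == 3))

  expect_equal(nrow(free_tie_variables(mergm_network("solo"))), 0)

  # size identity Sum_respondents (n - 1) on random inputs
  set.seed(11)
  for (rep in 1:20) {
    rn <- random_multilevel(n = sample(2:12, 1), p_resp = runif(1))
    ftv <- free_tie_variables(rn$net)
    expect_equal(nrow(ftv),
                 sum(rn$net$respondent) * (length(rn$net$students) - 1))
    expect_true(all(rn$net$respondent[ftv[, "sender"]]))
  }
})

test_that("summary reports counts, density and response proportion", {
  g3 <- g3_fixture()
  s <- network_summary(g3$net, g3$attrs)
  expect_equal(s$arcs, 3)
  expect_equal(s$density, 0.5)          # 3 of 6 free tie variables

  roster <- mergm_network(sprintf("s%d", 1:100),
                          respondent = rep(c(TRUE, FALSE), c(79, 21)))
  expect_equal(network_summary(roster)$response_proportion, 0.79)
})

test_that("write/read round-trips the canonicalised records", {
  gen <- generate_school(school_sim_config(n_students = 25, seed = 42))
  dir <- withr::local_tempdir()
  write_school(gen$network, gen$attrs, dir, "rt")
  back <- read_school(file.path(dir, "rt_arcs.csv"),
                      file.path(dir, "rt_affiliations.csv"),
                      file.path(dir, "rt_attributes.csv"))
  expect_equal(back$network$adj, gen$network$adj)
  expect_equal(back$network$aff[, sort(colnames(gen$network$aff))],
               gen$network$aff[, sort(colnames(gen$network$aff))])
  expect_equal(back$network$respondent, gen$network$respondent)
  expect_equal(back$attrs$knowledge, gen$attrs$knowledge)
  # writing the re-read data reproduces the files byte-for-byte
  dir2 <- withr::local_tempdir()
  write_school(back$network, back$attrs, dir2, "rt")
  for (f in c("rt_arcs.csv", "rt_affiliations.csv", "rt_attributes.csv"))
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)))
})

test_that("interchange matrices are written in roster order", {
  g3 <- g3_fixture()
  dir <- withr::local_tempdir()
  write_matrices(g3$net, file.path(dir, "adj.txt"), file.path(dir, "aff.txt"))
  adj <- as.matrix(read.table(file.path(dir, "adj.txt")))
  expect_equal(unname(adj), unname(g3$net$adj))
})
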