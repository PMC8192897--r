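## Synthetic school-network generator.
##
## Stands in for undeposited survey data: emulates a year group of students
## who nominate up to six close friends, a peer-supporter (PS) selection
## taking the most-nominated quarter of the year group with partial uptake,
## PS-created online groups whose membership aligns with offline
## friendship, and partial survey response with non-respondents' outgoing
## ties structurally absent.

#' Configuration of the synthetic school generator
#'
#' Defaults encode the study conditions being emulated: a year group of 130
#' students, 79% survey response, a nomination cap of six, the top 25% of
#' the year group invited as peer supporters with 52% uptake (about 13%
#' of the year group becoming PS), and one online group per PS whose
#' membership is strongly enriched among the PS's friends.  Attribute
#' scales (a 0-12 knowledge score, 1-5 norms adherence, 0-5 talking
#' frequency) are plausible survey scales, not published distributions.
#'
#' @param n_students year-group size.
#' @param response_rate proportion completing the survey.
#' @param male_proportion probability of `gender = 1`.
#' @param nomination_cap maximum nominations per respondent.
#' @param mean_out_degree target mean number of nominations per student
#'   before non-response deletion.
#' @param ps_top_fraction fraction of the year group invited to the PS role
#'   (most-nominated first).
#' @param ps_uptake probability an invited student takes the role.
#' @param groups_per_ps online groups opened per PS.
#' @param affiliation_alignment multiplier on the group-joining probability
#'   when an arc (either direction) links a student to the group's PS.
#' @param baseline_join_prob group-joining probability without such an arc.
#' @param attr_means,attr_sds means and standard deviations of the
#'   knowledge, norms and talking scores.
#' @param attr_cor common pairwise correlation of the three scores.
#' @param gender_match_odds odds multiplier for same-gender nominations.
#' @param reciprocity_bonus log-odds bonus for reciprocating an incoming
#'   arc.
#' @param transitivity_bonus log-odds bonus when a two-path already links
#'   sender to receiver.
#' @param attr_distance_decay log-odds penalty per standardised unit of
#'   total attribute distance.
#' @param seed integer seed; mandatory.
#' @return an object of class `school_sim_config` (a plain list, JSON
#'   serialisable for provenance records).
#' @export
school_sim_config <- function(n_students = 130, response_rate = 0.79,
                              male_proportion = 0.45, nomination_cap = 6,
                              mean_out_degree = 3.5,
                              ps_top_fraction = 0.25, ps_uptake = 0.52,
                              groups_per_ps = 1,
                              affiliation_alignment = 10,
                              baseline_join_prob = 0.03,
                              attr_means = c(knowledge = 7, norms = 3.5,
                                             talking = 2.5),
                              attr_sds = c(knowledge = 2, norms = 0.8,
                                           talking = 1.2),
                              attr_cor = 0.3,
                              gender_match_odds = 3,
                              reciprocity_bonus = 1.5,
                              transitivity_bonus = 1,
                              attr_distance_decay = 0.25,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_students >= 2, nomination_cap >= 1,
            response_rate >= 0, response_rate <= 1,
            male_proportion >= 0, male_proportion <= 1,
            ps_top_fraction >= 0, ps_top_fraction <= 1,
            ps_uptake >= 0, ps_uptake <= 1,
            baseline_join_prob >= 0, baseline_join_prob <= 1,
            affiliation_alignment > 0, groups_per_ps >= 0,
            mean_out_degree > 0)
  structure(as.list(environment()), class = "school_sim_config")
}

#' Generate one synthetic school
#'
#' Pipeline: (1) draw attributes (Bernoulli gender; correlated Gaussian
#' knowledge/norms/talking scores); (2) grow the friendship network by
#' sequential arc proposals whose receiver odds are boosted by reciprocity,
#' an existing two-path (transitivity), gender match and attribute
#' similarity, respecting the nomination cap; (3) select peer supporters by
#' in-degree-plus-noise nomination scores, inviting the top
#' `ps_top_fraction` and retaining each with probability `ps_uptake`;
#' (4) open `groups_per_ps` online groups per PS, which every student joins
#' with the baseline probability, multiplied by `affiliation_alignment`
#' when an arc links them to the PS; (5) mark `1 - response_rate` of
#' students as non-respondents, deleting their outgoing (but not incoming)
#' arcs and blanking their continuous attributes.  Deterministic given the
#' seed.
#'
#' @param config a [school_sim_config()].
#' @return list with elements `network` ([mergm_network()]), `attrs`
#'   (attribute data frame) and `config`.
#' @export
generate_school <- function(config) {
  stopifnot(inherits(config, "school_sim_config"))
  set.seed(config$seed)
  n <- config$n_students
  students <- sprintf("s%03d", seq_len(n))

  ## attributes
  gender <- stats::rbinom(n, 1, config$male_proportion)
  R <- matrix(config$attr_cor, 3, 3); diag(R) <- 1
  zc <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(R)
  cont <- sweep(sweep(zc, 2, config$attr_sds, "*"), 2, config$attr_means, "+")
  colnames(cont) <- c("knowledge", "norms", "talking")
  sdist <- as.matrix(stats::dist(sweep(cont, 2, config$attr_sds, "/"),
                                 method = "manhattan"))

  ## friendship growth
  adj <- matrix(0L, n, n)
  cap <- config$nomination_cap
  n_arcs <- round(config$mean_out_degree * n)
  same_gender <- outer(gender, gender, "==")
  for (a in seq_len(n_arcs)) {
    elig <- which(rowSums(adj) < cap)
    if (!length(elig)) break
    i <- if (length(elig) == 1) elig else sample(elig, 1)
    cand <- which(adj[i, ] == 0L)
    cand <- cand[cand != i]
    if (!length(cand)) next
    two_path <- (adj[i, , drop = FALSE] %*% adj)[1, cand] > 0
    lw <- config$reciprocity_bonus * adj[cand, i] +
      config$transitivity_bonus * two_path +
      log(config$gender_match_odds) * same_gender[i, cand] -
      config$attr_distance_decay * sdist[i, cand]
    j <- if (length(cand) == 1) cand else
      sample(cand, 1, prob = exp(lw - max(lw)))
    adj[i, j] <- 1L
  }

  ## peer-supporter selection from nomination popularity
  score <- colSums(adj) + stats::rnorm(n)
  invited <- order(score, decreasing = TRUE)[seq_len(round(config$ps_top_fraction * n))]
  ps <- rep(0L, n)
  ps[invited[stats::runif(length(invited)) < config$ps_uptake]] <- 1L

  ## online groups opened by PS; membership aligned with friendship
  ps_idx <- which(ps == 1L)
  groups <- character(0)
  aff <- matrix(0L, n, 0)
  for (s in ps_idx) {
    for (g in seq_len(config$groups_per_ps)) {
      gname <- sprintf("g_%s_%d", students[s], g)
      linked <- adj[s, ] == 1L | adj[, s] == 1L
      pj <- pmin(1, config$baseline_join_prob *
                   ifelse(linked, config$affiliation_alignment, 1))
      member <- as.integer(stats::runif(n) < pj)
      member[s] <- 1L
      aff <- cbind(aff, member)
      groups <- c(groups, gname)
    }
  }

  ## non-response: outgoing arcs deleted, incoming retained
  respondent <- rep(TRUE, n)
  n_nonresp <- round((1 - config$response_rate) * n)
  if (n_nonresp > 0) {
    nonresp <- sample.int(n, n_nonresp)
    respondent[nonresp] <- FALSE
    adj[nonresp, ] <- 0L
  }

  attrs <- data.frame(student = students, respondent = respondent,
                      gender = gender, ps = ps,
                      knowledge = cont[, "knowledge"],
                      norms = cont[, "norms"],
                      talking = cont[, "talking"])
  attrs[!respondent, c("knowledge", "norms", "talking")] <- NA
  net <- mergm_network(students, groups, adj, aff, respondent,
                       max_out = cap)
  list(network = net, attrs = attrs, config = config)
}

#' Draw one network from a MERGM over a fixed skeleton
#'
#' Model-based generator for recovery studies: keeps the skeleton's roster,
#' affiliations, respondent flags and attributes, and returns a single
#' network drawn from the model at `theta` after burn-in.
#'
#' @param net skeleton [mergm_network()] (its arcs only matter when the
#'   sampler starts from the observed state).
#' @param attrs attribute data frame (or `NULL`).
#' @param theta parameter vector.
#' @param spec a [model_spec()].
#' @param config a [sampler_config()]; `n_samples` is forced to 1.
#' @return a [mergm_network()].
#' @export
generate_from_model <- function(net, attrs, theta, spec, config) {
  config$n_samples <- 1L
  config$retain_networks <- FALSE
  batch <- simulate_mergm(net, attrs, theta, spec, config)
  batch$final_network
}

#' Write a generated school plus its provenance record
#'
#' Emits the three delimited files of the data model and a JSON provenance
#' record of the generator configuration (including the seed).
#'
#' @param school result of [generate_school()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_generated_school <- function(school, dir, prefix = "school") {
  paths <- write_school(school$network, school$attrs, dir, prefix)
  prov <- file.path(dir, paste0(prefix, "_provenance.json"))
  jsonlite::write_json(unclass(school$config), prov, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, prov))
}
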