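# Shared fixtures: a 3-student worked example with known statistic values,
# random multilevel networks, and the full 16-family model specification.

g3_fixture <- function() {
  net <- mergm_network(
    c("1", "2", "3"), c("g1", "g2"),
    adj = matrix(c(0, 1, 0,
                   1, 0, 1,
                   0, 0, 0), 3, 3, byrow = TRUE),
    aff = matrix(c(1, 0,
                   1, 1,
                   0, 1), 3, 2, byrow = TRUE))
  attrs <- data.frame(student = c("1", "2", "3"), respondent = TRUE,
                      gender = c(1, 0, 1), ps = c(1, 0, 1),
                      knowledge = c(1, 2, 4), norms = c(1, 2, 4),
                      talking = c(1, 2, 4))
  list(net = net, attrs = attrs)
}

# all sixteen effect families, attribute slots filled with the standard
# covariates
all16_spec <- function(lambda = 2, condition_max_out = FALSE) {
  model_spec(c(
    lapply(c("ArcA", "ReciprocityA"), effect_term),
    lapply(c("AinSA", "AoutSA", "ATA-T", "A2PA-T"), effect_term,
           lambda = lambda),
    list(effect_term("Sender", "knowledge"),
         effect_term("Receiver", "knowledge"),
         effect_term("Interaction", "gender"),
         effect_term("Difference", "norms"),
         effect_term("PSTalkingSender"),
         effect_term("PSTalkingReceiver"),
         effect_term("In2StarAX"), effect_term("Out2StarAX"),
         effect_term("TXAXarc"), effect_term("L3XAX"))),
    condition_max_out = condition_max_out)
}

# random multilevel network + attributes; uses the current RNG stream
random_multilevel <- function(n = 6, n_groups = 2, p_arc = 0.3,
                              p_aff = 0.4, p_resp = 0.8) {
  students <- sprintf("r%02d", seq_len(n))
  respondent <- stats::runif(n) < p_resp
  if (!any(respondent)) respondent[1] <- TRUE
  adj <- matrix(as.integer(stats::runif(n * n) < p_arc), n, n)
  diag(adj) <- 0L
  adj[!respondent, ] <- 0L
  aff <- matrix(as.integer(stats::runif(n * n_groups) < p_aff), n, n_groups)
  attrs <- data.frame(student = students, respondent = respondent,
                      gender = stats::rbinom(n, 1, 0.5),
                      ps = stats::rbinom(n, 1, 0.2),
                      knowledge = stats::rnorm(n, 7, 2),
                      norms = stats::rnorm(n, 3.5, 1),
                      talking = stats::rnorm(n, 2.5, 1))
  attrs[!respondent, c("knowledge", "norms", "talking")] <- NA
  net <- mergm_network(students, sprintf("g%d", seq_len(n_groups)),
                       adj, aff, respondent, max_out = n)
  list(net = net, attrs = attrs)
}

# independent oracle for the alternating star statistics: the explicit
# alternating series sum_k (-1)^k S_k / lambda^(k-2) over star counts
# S_k = sum_i choose(d_i, k)
alt_star_series <- function(degrees, lambda) {
  kmax <- max(degrees, 2)
  s <- 0
  for (k in 2:kmax)
    s <- s + (-1)^k * sum(choose(degrees, k)) / lambda^(k - 2)
  s
}
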