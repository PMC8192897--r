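#' Sampler configuration
#'
#' Settings for Metropolis-Hastings simulation of friendship networks from a
#' MERGM.  Defaults scale with the size of the free tie space: burn-in
#' 50 x |free set| single-dyad toggle steps and thinning 10 x |free set|
#' between retained samples.
#'
#' @param n_samples number of retained samples.
#' @param burn_in steps before the first retained sample (`NULL`: 50 x
#'   |free set|).
#' @param thinning steps between retained samples (`NULL`: 10 x |free set|).
#' @param seed integer seed; mandatory, there is no implicit entropy.
#' @param respect_max_out enforce the nomination cap by rejecting proposals
#'   that would exceed it (default `NULL`: inherit the model
#'   specification's `condition_max_out` flag).
#' @param retain_networks keep the sampled networks (needed for auxiliary
#'   goodness-of-fit statistics).
#' @param start `"observed"` (default) or `"empty"` starting state.
#' @param track_states accumulate visit counts of every network state,
#'   encoded as a bitmask over the free dyads (exact-distribution checks;
#'   only for tiny tie spaces).
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 100, burn_in = NULL, thinning = NULL,
                           seed, respect_max_out = NULL,
                           retain_networks = FALSE, start = c("observed", "empty"),
                           track_states = FALSE) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  start <- match.arg(start)
  if (n_samples < 1) stop("n_samples must be positive")
  if (!is.null(burn_in) && burn_in < 0) stop("burn_in must be non-negative")
  if (!is.null(thinning) && thinning < 1) stop("thinning must be positive")
  structure(list(n_samples = as.integer(n_samples), burn_in = burn_in,
                 thinning = thinning, seed = as.integer(seed),
                 respect_max_out = respect_max_out,
                 retain_networks = retain_networks, start = start,
                 track_states = track_states),
            class = "sampler_config")
}

## low-level chain advance shared by the sampler and the estimator;
## assumes the RNG state is already set by the caller
.mh <- function(net, built, adj, z, theta, burnin, thin, nsamp,
                respect_cap, retain = FALSE, track = FALSE) {
  .cpp_mh_run(adj, built$free - 1L, theta, built$codes, built$lambdas,
              built$covs, built$dx, built$smat,
              net$max_out, respect_cap, z,
              as.integer(burnin), as.integer(thin), as.integer(nsamp),
              retain, track)
}

## networks from an unconditioned run live in the uncapped tie space, so the
## returned objects carry an unbinding cap
.net_with_adj <- function(net, adj, capped = TRUE) {
  dimnames(adj) <- dimnames(net$adj)
  net$adj <- adj
  if (!capped) net$max_out <- max(net$max_out, length(net$students) - 1L)
  validate_network(net)
  net
}

#' Simulate networks from a MERGM
#'
#' Metropolis-Hastings on the constrained tie space: a free dyad is drawn
#' uniformly, its toggle accepted with probability min(1, exp(theta . dz)).
#' Proposals that would push a respondent past the nomination cap are
#' rejected when conditioning is on, so the chain never leaves the
#' constrained space; structural zeros can never be proposed at all.
#' Statistics are accumulated incrementally from change statistics and
#' cross-checked against a full recount at the end of the run (and on the
#' first and last retained network when networks are kept).
#'
#' @param net a [mergm_network()] supplying rosters, affiliations and
#'   respondent flags (and the starting state when `start = "observed"`).
#' @param attrs attribute data frame (or `NULL` for attribute-free models).
#' @param theta parameter vector aligned with `spec`.
#' @param spec a [model_spec()].
#' @param config a [sampler_config()].
#' @return an object of class `sample_batch`: `stats` (n_samples x n_terms
#'   matrix), `acceptance_rate`, `final_network`, optionally `networks` and
#'   state-visit counts `visits`.
#' @export
simulate_mergm <- function(net, attrs, theta, spec, config) {
  stopifnot(inherits(config, "sampler_config"))
  built <- .spec_build(net, attrs, spec)
  if (length(theta) != length(spec$terms))
    stop("theta/spec length mismatch")
  nfree <- nrow(built$free)
  if (nfree == 0) stop("empty free tie space")
  burnin <- config$burn_in %||% (50L * nfree)
  thin <- config$thinning %||% (10L * nfree)
  cap_on <- config$respect_max_out %||% spec$condition_max_out

  start_net <- if (config$start == "empty")
    .net_with_adj(net, matrix(0L, nrow(net$adj), ncol(net$adj))) else net
  z0 <- unname(graph_statistics(start_net, attrs, spec))

  set.seed(config$seed)
  res <- .mh(net, built, start_net$adj, z0, theta, burnin, thin,
             config$n_samples, cap_on,
             retain = config$retain_networks, track = config$track_states)

  final_net <- .net_with_adj(net, res$adj, capped = cap_on)
  # incremental/recount cross-check on the final state
  z_final <- unname(graph_statistics(final_net, attrs, spec))
  if (max(abs(z_final - res$z)) > 1e-6 * max(1, max(abs(z_final))))
    stop("internal error: incremental statistics diverged from recount")

  batch <- list(stats = res$stats, acceptance_rate = res$acceptance_rate,
                final_network = final_net, theta = theta, spec = spec,
                burn_in = burnin, thinning = thin, seed = config$seed)
  colnames(batch$stats) <- effect_labels(spec)
  if (config$retain_networks) {
    batch$networks <- lapply(res$networks, function(el) {
      adj <- matrix(0L, nrow(net$adj), ncol(net$adj))
      if (nrow(el) > 0) adj[el] <- 1L
      .net_with_adj(net, adj, capped = cap_on)
    })
    for (k in unique(c(1L, length(batch$networks)))) {
      zk <- unname(graph_statistics(batch$networks[[k]], attrs, spec))
      if (max(abs(zk - res$stats[k, ])) > 1e-6 * max(1, max(abs(zk))))
        stop("internal error: retained-sample statistics diverged from recount")
    }
  }
  if (config$track_states) {
    batch$visits <- res$visits
    batch$free_dyads <- built$free
  }
  class(batch) <- "sample_batch"
  batch
}

#' Advance a network by Metropolis-Hastings steps
#'
#' Low-level single-chain update used in tests and diagnostics: runs
#' `n_steps` toggle proposals from the supplied state and returns the new
#' state.  One step is one proposal.
#'
#' @inheritParams simulate_mergm
#' @param n_steps number of proposals.
#' @param seed integer seed.
#' @param respect_max_out enforce the nomination cap (default: the
#'   specification's conditioning flag).
#' @return list with `network`, `z` (statistics of the new state) and
#'   `acceptance_rate`.
#' @export
metropolis_update <- function(net, attrs, theta, spec, n_steps = 1L, seed,
                              respect_max_out = spec$condition_max_out) {
  built <- .spec_build(net, attrs, spec)
  if (length(theta) != length(spec$terms))
    stop("theta/spec length mismatch")
  z0 <- unname(graph_statistics(net, attrs, spec))
  set.seed(seed)
  res <- .mh(net, built, net$adj, z0, theta, burnin = 0L,
             thin = as.integer(n_steps), nsamp = 1L,
             respect_cap = respect_max_out)
  list(network = .net_with_adj(net, res$adj, capped = respect_max_out),
       z = res$z,
       acceptance_rate = res$acceptance_rate)
}

#' Export a statistic trace as delimited text
#'
#' Writes the retained statistic vectors of a batch, one row per sample,
#' for external convergence diagnostics.
#'
#' @param batch a `sample_batch`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace <- function(batch, path) {
  utils::write.csv(as.data.frame(batch$stats), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("MERGM sample batch: %d samples, acceptance rate %.3f\n",
              nrow(x$stats), x$acceptance_rate))
  cat("statistic means:\n")
  print(round(colMeans(x$stats), 3))
  invisible(x)
}
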