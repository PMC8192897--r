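#' Estimation configuration
#'
#' Settings for the three-phase stochastic-approximation maximum-likelihood
#' estimator.  Chain lengths scale with the size of the free tie space
#' |F|: phase 1 burns 20|F| steps and draws `phase1_n` samples 2|F| apart;
#' each phase-2 Robbins-Monro iteration advances the chain |F| steps; phase
#' 3 burns 10|F| steps and draws `phase3_n` samples `phase3_thin` x |F|
#' apart.  The gain sequence halves across sub-phases of geometrically
#' growing length (`subphase_base` x 2^(k-1) iterations in sub-phase k).
#'
#' @param phase1_n phase-1 sample size (scaling estimate).
#' @param subphases number of Robbins-Monro sub-phases.
#' @param subphase_base iterations in the first sub-phase.
#' @param gain initial gain a0; sub-phase k uses a0 / 2^(k-1).
#' @param phase3_n phase-3 sample size (convergence check and standard
#'   errors).
#' @param phase3_thin thinning of phase 3 in units of |F| steps.
#' @param conv_threshold convergence bound on the absolute t-ratios
#'   (default 0.1, the conventional criterion for this model family).
#' @param max_rounds maximum estimation rounds; after a non-converged phase
#'   3 the parameter takes a Newton step using the phase-3 covariance and
#'   phase 3 is re-run.
#' @param max_step per-component clamp on one Robbins-Monro update.
#' @param seed integer seed; mandatory.
#' @return an object of class `estimation_config`.
#' @export
estimation_config <- function(phase1_n = 100, subphases = 5,
                              subphase_base = 40, gain = 0.1,
                              phase3_n = 1000, phase3_thin = 5,
                              conv_threshold = 0.1, max_rounds = 4,
                              max_step = 0.5, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(phase1_n > 0, subphases > 0, subphase_base > 0, gain > 0,
            phase3_n > 1, phase3_thin > 0, conv_threshold > 0,
            max_rounds > 0)
  structure(as.list(environment()), class = "estimation_config")
}

#' Significance rule for fitted parameters
#'
#' A parameter is flagged significant when the ratio of its absolute value
#' to its estimated standard error strictly exceeds 2 (two-sided, so large
#' negative estimates are significant too).
#'
#' @param theta parameter vector.
#' @param se standard errors (must be positive).
#' @return logical vector.
#' @export
significance <- function(theta, se) {
  if (length(theta) != length(se)) stop("length mismatch")
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
  abs(theta) / se > 2
}

#' Standard errors from the simulated-statistic covariance
#'
#' At the MLE the covariance of the sufficient statistics is the Fisher
#' information, so the standard errors are the square roots of the diagonal
#' of its inverse.  A near-singular covariance falls back to the
#' Moore-Penrose pseudo-inverse with a warning.
#'
#' @param stat_cov symmetric covariance matrix of simulated statistics.
#' @return numeric vector of standard errors; attribute `pseudo_inverse`
#'   is `TRUE` when the fallback was taken.
#' @export
standard_errors <- function(stat_cov) {
  if (!is.matrix(stat_cov) || nrow(stat_cov) != ncol(stat_cov))
    stop("covariance must be a square matrix")
  pseudo <- FALSE
  inv <- tryCatch({
    if (rcond(stat_cov) < 1e-12) stop("near-singular")
    solve(stat_cov)
  }, error = function(e) {
    pseudo <<- TRUE
    warning("near-singular statistic covariance; using pseudo-inverse")
    MASS::ginv(stat_cov)
  })
  se <- sqrt(pmax(diag(inv), 0))
  attr(se, "pseudo_inverse") <- pseudo
  se
}

## pre-fit guards -------------------------------------------------------------

.check_boundary <- function(z_obs, spec, nfree, X) {
  labs <- effect_labels(spec)
  for (k in seq_along(spec$terms)) {
    nm <- spec$terms[[k]]$name
    if (nm == "ArcA" && (z_obs[k] <= 0 || z_obs[k] >= nfree))
      stop("observed density at its boundary (", z_obs[k], " of ", nfree,
           " ties): the MLE does not exist; remove the data or the model")
    # non-negative count statistics observed at their minimum of zero
    nonneg <- all(X[, k] >= 0) && any(X[, k] > 0)
    if (nm != "ArcA" && nonneg && z_obs[k] == 0)
      stop("observed statistic '", labs[k], "' is at its boundary (zero): ",
           "the MLE diverges; consider removing this term")
  }
  invisible(NULL)
}

.check_collinear <- function(X, spec) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    stop("collinear effect terms on the observed network: ",
         paste(effect_labels(spec)[dep], collapse = ", "))
  }
  invisible(NULL)
}

#' Fit a MERGM by MCMC maximum likelihood
#'
#' Three-phase stochastic approximation (Robbins-Monro):
#'
#' 1. *Phase 1* simulates briefly at the starting value (logit of the
#'    observed density for the arc term, zero elsewhere) and estimates a
#'    diagonal scaling from the statistic variances.
#' 2. *Phase 2* runs `subphases` Robbins-Monro sub-phases with halving
#'    gains, updating theta <- theta - a_k D^-1 (z_sim - z_obs) after each
#'    short chain advance.
#' 3. *Phase 3* draws a large sample at the candidate estimate, computes
#'    convergence t-ratios (mean(z_sim) - z_obs) / sd(z_sim), declares
#'    convergence when all |t| fall below the threshold, and derives
#'    standard errors from the inverse covariance of the simulated
#'    statistics.  While not converged (up to `max_rounds`), the estimate
#'    takes a Newton step using the phase-3 covariance and phase 3 is
#'    repeated.
#'
#' Degenerate simulation (statistics collapsing onto a constant, e.g. an
#' empty or full graph) and observed statistics at their extremes are
#' reported as diagnostic errors rather than returned as estimates.
#'
#' @param net a [mergm_network()] (the observed network).
#' @param attrs attribute data frame (or `NULL`).
#' @param spec a [model_spec()]; its `condition_max_out` flag decides
#'   whether the sample space is conditioned on the nomination cap.
#' @param config an [estimation_config()].
#' @return an object of class `mergm_fit` with elements `theta`, `se`,
#'   `conv_t`, `significant`, `stat_cov`, `z_obs`, `converged`,
#'   `phase3_stats` and `diagnostics`.
#' @export
fit_mergm <- function(net, attrs, spec, config) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "estimation_config"))
  built <- .spec_build(net, attrs, spec)
  p <- length(spec$terms)
  nfree <- nrow(built$free)
  if (nfree == 0) stop("empty free tie space")
  z_obs <- unname(graph_statistics(net, attrs, spec))

  set.seed(config$seed)
  probe <- built$free
  if (nrow(probe) > 1000)
    probe <- probe[sample.int(nrow(probe), 1000), , drop = FALSE]
  X <- dyad_design_matrix(net, attrs, spec, dyads = probe)$X
  .check_boundary(z_obs, spec, nfree, X)
  .check_collinear(X, spec)

  dens <- sum(net$adj) / nfree
  theta <- numeric(p)
  arc_k <- which(vapply(spec$terms, `[[`, character(1), "name") == "ArcA")
  theta[arc_k] <- stats::qlogis(dens)

  cap <- spec$condition_max_out
  adj <- net$adj
  z <- z_obs
  accepts <- numeric(0)

  advance <- function(burnin, thin, nsamp) {
    res <- .mh(net, built, adj, z, theta, burnin, thin, nsamp, cap)
    adj <<- res$adj; z <<- res$z
    accepts <<- c(accepts, res$acceptance_rate)
    res$stats
  }

  ## Phase 1: diagonal scaling
  s1 <- advance(20L * nfree, 2L * nfree, config$phase1_n)
  D <- apply(s1, 2, stats::var)
  if (any(D < 1e-12))
    stop("degenerate simulation in phase 1: statistic(s) ",
         paste(effect_labels(spec)[D < 1e-12], collapse = ", "),
         " do not vary; the model cannot be identified at the start value")
  ## Phase 2: Robbins-Monro sub-phases
  for (sub in seq_len(config$subphases)) {
    a <- config$gain / 2^(sub - 1)
    for (it in seq_len(config$subphase_base * 2^(sub - 1))) {
      zs <- advance(0L, nfree, 1L)[1, ]
      step <- a * (zs - z_obs) / D
      step <- pmin(pmax(step, -config$max_step), config$max_step)
      theta <- theta - step
    }
  }

  ## Phase 3 (repeated with Newton polish until converged)
  converged <- FALSE
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    s3 <- advance(10L * nfree, as.integer(config$phase3_thin * nfree),
                  config$phase3_n)
    zbar <- colMeans(s3)
    sdv <- apply(s3, 2, stats::sd)
    if (any(sdv < 1e-12))
      stop("degenerate simulation in phase 3: statistic(s) ",
           paste(effect_labels(spec)[sdv < 1e-12], collapse = ", "),
           " collapsed onto a constant")
    S <- stats::cov(s3)
    conv_t <- (zbar - z_obs) / sdv
    if (max(abs(conv_t)) < config$conv_threshold) { converged <- TRUE; break }
    if (rounds >= config$max_rounds) break
    ridge <- diag(1e-8 * diag(S), nrow = nrow(S))
    theta <- theta - drop(solve(S + ridge, zbar - z_obs))
  }

  se <- standard_errors(S)
  labs <- effect_labels(spec)
  names(theta) <- names(se) <- names(conv_t) <- labs
  dimnames(S) <- list(labs, labs)
  colnames(s3) <- labs
  fit <- list(theta = theta, se = as.numeric(se), conv_t = conv_t,
              significant = significance(theta, as.numeric(se)),
              stat_cov = S, z_obs = stats::setNames(z_obs, labs),
              converged = converged, spec = spec, phase3_stats = s3,
              diagnostics = list(rounds = rounds, seed = config$seed,
                                 free_tie_variables = nfree,
                                 acceptance_rates = accepts,
                                 pseudo_inverse = isTRUE(attr(se, "pseudo_inverse")),
                                 config = config))
  names(fit$se) <- labs
  class(fit) <- "mergm_fit"
  fit
}

#' @export
print.mergm_fit <- function(x, ...) {
  cat(sprintf("MERGM fit (%s; max |conv t| = %.3f)\n",
              if (x$converged) "converged" else "NOT converged",
              max(abs(x$conv_t))))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Tabulate a fit in reporting form
#'
#' @param x a `mergm_fit`.
#' @param ... unused.
#' @return data frame with columns `effect`, `parameter`, `stderr`,
#'   `significant` (asterisk marking).
#' @export
as.data.frame.mergm_fit <- function(x, ...) {
  data.frame(effect = names(x$theta),
             parameter = unname(x$theta),
             stderr = unname(x$se),
             significant = ifelse(x$significant, "*", ""),
             row.names = NULL)
}
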