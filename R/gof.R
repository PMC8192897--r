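## Goodness-of-fit: simulate at the fitted parameters and compare observed
## vs simulated distributions of the fitted statistics and of auxiliary
## descriptors that are not part of the model.

## shared t-ratio kernel: (observed - simulated mean) / simulated sd;
## 0 when the distribution is degenerate at the observed value, +/-Inf when
## degenerate elsewhere
.t_ratio <- function(obs, mn, sdv) {
  ifelse(sdv > 0, (obs - mn) / sdv,
         ifelse(obs == mn, 0, sign(obs - mn) * Inf))
}

#' Auxiliary descriptive statistics of a friendship network
#'
#' The default goodness-of-fit panel beyond the fitted statistics: standard
#' deviation and skewness of the in- and out-degree distributions, global
#' transitivity (fraction of directed two-paths that are closed by an arc),
#' isolate count and mutual-dyad count.
#'
#' @param net a [mergm_network()].
#' @return named numeric vector.
#' @export
auxiliary_statistics <- function(net) {
  y <- net$adj
  din <- colSums(y); dout <- rowSums(y)
  skew <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(0)
    mean((v - mean(v))^3) / s^3
  }
  TP <- y %*% y
  two_paths <- sum(TP) - sum(diag(TP))
  c(in_degree_sd = stats::sd(din),
    in_degree_skew = skew(din),
    out_degree_sd = stats::sd(dout),
    out_degree_skew = skew(dout),
    transitivity = if (two_paths > 0) sum(y * TP) / two_paths else 0,
    isolates = sum(din + dout == 0),
    mutual_dyads = sum(y * t(y)) / 2)
}

#' Goodness-of-fit of a fitted MERGM
#'
#' Simulates networks at the fitted parameters and reports, for every
#' fitted statistic and every auxiliary descriptor, the observed value, the
#' simulated mean and standard deviation, and the t-ratio
#' (observed - mean) / sd.  Fitted statistics were matched during
#' estimation, so adequacy demands |t| < 0.1 for them; auxiliary statistics
#' are adequate at |t| < 2.  Only converged fits are accepted.
#'
#' @param net the observed [mergm_network()].
#' @param attrs attribute data frame (or `NULL`).
#' @param fit a converged `mergm_fit`.
#' @param config a [sampler_config()]; `retain_networks` is forced on since
#'   auxiliary statistics need the sampled networks.  Ignored when
#'   `use_phase3 = TRUE`.
#' @param aux include the auxiliary panel (default `TRUE`).
#' @param use_phase3 reuse the estimator's stored phase-3 sample instead of
#'   simulating afresh (fitted statistics only); the resulting t-ratios
#'   then agree with the estimator's convergence t-ratios by construction.
#' @return an object of class `mergm_gof`: a data frame with columns
#'   `statistic`, `observed`, `sim_mean`, `sim_sd`, `t`, `fitted`,
#'   `adequate`.
#' @export
goodness_of_fit <- function(net, attrs, fit, config = NULL, aux = TRUE,
                            use_phase3 = FALSE) {
  stopifnot(inherits(fit, "mergm_fit"))
  if (!fit$converged)
    stop("goodness-of-fit refused: the fit did not converge")
  spec <- fit$spec
  z_obs <- fit$z_obs

  if (use_phase3) {
    stats_mat <- fit$phase3_stats
    aux_obs <- aux_mat <- NULL
  } else {
    if (is.null(config)) stop("a sampler_config is required")
    config$retain_networks <- aux
    batch <- simulate_mergm(net, attrs, fit$theta, spec, config)
    stats_mat <- batch$stats
    if (aux) {
      aux_obs <- auxiliary_statistics(net)
      aux_mat <- t(vapply(batch$networks, auxiliary_statistics,
                          numeric(length(aux_obs))))
    } else aux_obs <- aux_mat <- NULL
  }

  mn <- colMeans(stats_mat)
  sdv <- apply(stats_mat, 2, stats::sd)
  tv <- .t_ratio(z_obs, mn, sdv)
  out <- data.frame(statistic = names(z_obs), observed = unname(z_obs),
                    sim_mean = unname(mn), sim_sd = unname(sdv),
                    t = unname(tv), fitted = TRUE,
                    adequate = abs(unname(tv)) < 0.1, row.names = NULL)
  if (!is.null(aux_mat)) {
    mn2 <- colMeans(aux_mat)
    sd2 <- apply(aux_mat, 2, stats::sd)
    tv2 <- .t_ratio(aux_obs, mn2, sd2)
    out <- rbind(out, data.frame(
      statistic = names(aux_obs), observed = unname(aux_obs),
      sim_mean = unname(mn2), sim_sd = unname(sd2), t = unname(tv2),
      fitted = FALSE, adequate = abs(unname(tv2)) < 2, row.names = NULL))
  }
  class(out) <- c("mergm_gof", "data.frame")
  out
}

#' @export
print.mergm_gof <- function(x, ...) {
  cat("MERGM goodness-of-fit",
      if (all(x$adequate)) "(all statistics adequate)" else
        "(INADEQUATE statistics present)", "\n")
  df <- as.data.frame(x)
  df$observed <- round(df$observed, 3)
  df$sim_mean <- round(df$sim_mean, 3)
  df$sim_sd <- round(df$sim_sd, 3)
  df$t <- round(df$t, 3)
  df$adequate <- ifelse(df$adequate, "yes", "NO")
  print(df, row.names = FALSE)
  invisible(x)
}
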