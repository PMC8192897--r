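## Study orchestration: per-school fits, goodness-of-fit, and a multi-school
## report in the conventional layout (schools as column pairs, effects as
## rows grouped by family, asterisks marking significance).

#' Fit a MERGM study across schools
#'
#' Fits each school independently (estimates for networks of different
#' sizes are not comparable, so there is deliberately no pooled layer),
#' runs goodness-of-fit on converged fits, and collects everything in a
#' study report.  A failure in one school (degeneracy, boundary, ...) is
#' recorded as that school's diagnostic and does not abort the others.
#'
#' @param schools named list; each element either a
#'   [school_sim_config()] (the school is generated) or a list with
#'   elements `network` and `attrs`.
#' @param spec a [model_spec()] shared by all schools.
#' @param seed master seed; per-school seeds are derived from it.
#' @param est named list of [estimation_config()] overrides (e.g.
#'   `list(phase3_n = 500)`).
#' @param gof logical, run goodness-of-fit (default `TRUE`);
#'   or a named list of [sampler_config()] overrides.
#' @return an object of class `study_report`.
#' @export
run_study <- function(schools, spec, seed, est = list(), gof = TRUE) {
  if (length(schools) == 0) stop("no schools configured")
  if (is.null(names(schools)))
    names(schools) <- paste0("School", seq_along(schools))
  out <- vector("list", length(schools))
  names(out) <- names(schools)
  for (k in seq_along(schools)) {
    sc <- schools[[k]]
    school_seed <- (seed + 1000L * k) %% .Machine$integer.max
    rec <- list(name = names(schools)[k])
    res <- tryCatch({
      if (inherits(sc, "school_sim_config")) sc <- generate_school(sc)
      net <- sc$network; attrs <- sc$attrs
      rec$summary <- network_summary(net, attrs)
      ec <- do.call(estimation_config, c(est, list(seed = school_seed)))
      rec$fit <- fit_mergm(net, attrs, spec, ec)
      if (!isFALSE(gof)) {
        gc_over <- if (is.list(gof)) gof else list()
        gcfg <- do.call(sampler_config,
                        c(gc_over, list(seed = school_seed + 1L)))
        rec$gof <- goodness_of_fit(net, attrs, rec$fit, config = gcfg)
      }
      rec
    }, error = function(e) { rec$error <- conditionMessage(e); rec })
    out[[k]] <- res
  }
  structure(list(schools = out, spec = spec, seed = seed,
                 components = stats::setNames(effect_components(spec),
                                              effect_labels(spec))),
            class = "study_report")
}

#' Render a study report as a plain-text table
#'
#' Schools appear as column pairs (Parameter, Stderr) in input order;
#' effects as rows grouped under Structural / Actor-relation / Cross-level
#' headings; estimates are printed to three decimals with an asterisk
#' appended when |parameter| / stderr > 2.  Schools whose fit failed are
#' shown with their diagnostic below the table.
#'
#' @param report a `study_report`.
#' @return a single character string (the table text).
#' @export
render_table <- function(report) {
  spec <- report$spec
  labs <- effect_labels(spec)
  grp <- vapply(spec$terms, function(t)
    .effect_families$group[.effect_families$name == t$name], character(1))
  headings <- c(structural = "Structural effects",
                `actor-relation` = "Actor-relation interaction effects",
                `cross-level` = "Cross-level effects")
  snames <- vapply(report$schools, `[[`, character(1), "name")
  wl <- max(nchar(c(labs, "Effects")), 0) + 2
  fmt_num <- function(v) formatC(v, format = "f", digits = 3)

  header1 <- paste0(formatC("", width = wl),
                    paste(formatC(snames, width = 19), collapse = " "))
  header2 <- paste0(formatC("Effects", width = wl, flag = "-"),
                    paste(rep(paste(formatC("Parameter", width = 10),
                                    formatC("Stderr", width = 8)),
                              length(snames)), collapse = " "))
  lines <- c(header1, header2)
  for (g in c("structural", "actor-relation", "cross-level")) {
    rows <- which(grp == g)
    if (!length(rows)) next
    lines <- c(lines, headings[[g]])
    for (r in rows) {
      cells <- vapply(report$schools, function(s) {
        if (is.null(s$fit)) return(paste(formatC("-", width = 10),
                                         formatC("", width = 8)))
        star <- if (s$fit$significant[r]) " *" else ""
        paste0(formatC(fmt_num(s$fit$theta[r]), width = 10),
               " ", formatC(fmt_num(s$fit$se[r]), width = 8), star)
      }, character(1))
      lines <- c(lines, paste0(formatC(labs[r], width = wl, flag = "-"),
                               paste(cells, collapse = " ")))
    }
  }
  failed <- Filter(function(s) !is.null(s$error), report$schools)
  if (length(failed))
    lines <- c(lines, "",
               vapply(failed, function(s)
                 paste0(s$name, ": fit failed - ", s$error), character(1)))
  paste(lines, collapse = "\n")
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_table(x), "\n")
  conv <- vapply(x$schools, function(s)
    !is.null(s$fit) && s$fit$converged, logical(1))
  cat(sprintf("\n%d/%d school fits converged\n", sum(conv), length(conv)))
  invisible(x)
}

#' Serialise a fit in reporting form to a delimited file
#'
#' Columns `effect`, `parameter`, `stderr`, `significant` (asterisk), plus
#' the process-evaluation component tag of each effect.
#'
#' @param fit a `mergm_fit`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fit <- function(fit, path) {
  df <- as.data.frame(fit)
  df$component <- effect_components(fit$spec)
  df$conv_t <- unname(fit$conv_t)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
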