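#!/usr/bin/env Rscript
# Assemble the multi-school report: effects as rows grouped by family,
# schools as (Parameter, Stderr) column pairs, asterisks for |theta|/SE > 2,
# plus a summary of what each effect block says about the three
# process-evaluation components (implementation fidelity, mechanisms of
# impact, context).

library(mergm)

fit_dir <- file.path("results", "fits")
spec <- read_model_spec(file.path(fit_dir, "analysis_model.yaml"))
fits <- list.files(fit_dir, pattern = "_fit\\.csv$")
stopifnot(length(fits) > 0)

schools <- lapply(fits, function(f) {
  est <- read.csv(file.path(fit_dir, f))
  fit <- structure(list(theta = setNames(est$parameter, est$effect),
                        se = est$stderr,
                        significant = est$significant == "*",
                        spec = spec, converged = TRUE),
                   class = "mergm_fit")
  list(name = sub("_fit\\.csv$", "", f), fit = fit)
})
report <- structure(list(schools = schools, spec = spec, seed = NA),
                    class = "study_report")
txt <- render_table(report)
cat(txt, "\n\n")

comp <- effect_components(spec)
labs <- effect_labels(spec)
cat("Process-evaluation reading of significant effects:\n")
for (cc in unique(comp)) {
  cat("\n*", cc, "*\n")
  for (k in which(comp == cc)) {
    marks <- vapply(schools, function(s)
      if (s$fit$significant[k]) "*" else ".", character(1))
    cat(sprintf("  %-30s %s\n", labs[k], paste(marks, collapse = " ")))
  }
}

dir.create("results", showWarnings = FALSE)
writeLines(txt, file.path("results", "report.txt"))
cat("\nReport written to results/report.txt\n")
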