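## Effect catalogue -----------------------------------------------------------
##
## Sixteen effect families: six structural (arc, reciprocity, alternating
## in/out-stars, alternating path closure, alternating multiple two-paths),
## six actor-relation templates (sender, receiver, binary interaction,
## continuous absolute difference, and the PS-by-talking sender/receiver
## products), and four cross-level statistics over the fixed affiliations.

.effect_families <- data.frame(
  name = c("ArcA", "ReciprocityA", "AinSA", "AoutSA", "ATA-T", "A2PA-T",
           "Sender", "Receiver", "Interaction", "Difference",
           "PSTalkingSender", "PSTalkingReceiver",
           "In2StarAX", "Out2StarAX", "TXAXarc", "L3XAX"),
  code = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 6L, 7L,
           10L, 11L, 12L, 13L),
  needs_attr = c(rep(FALSE, 6), rep(TRUE, 4), FALSE, FALSE, rep(FALSE, 4)),
  alternating = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, rep(FALSE, 10)),
  group = c(rep("structural", 6), rep("actor-relation", 6),
            rep("cross-level", 4)),
  stringsAsFactors = FALSE)

.binary_attrs <- c("gender", "ps")
.continuous_attrs <- c("knowledge", "norms", "talking")

#' Define one effect term
#'
#' @param name effect family name; one of `ArcA`, `ReciprocityA`, `AinSA`,
#'   `AoutSA`, `ATA-T`, `A2PA-T`, `Sender`, `Receiver`, `Interaction`,
#'   `Difference`, `PSTalkingSender`, `PSTalkingReceiver`, `In2StarAX`,
#'   `Out2StarAX`, `TXAXarc`, `L3XAX`.
#' @param attribute covariate name for the actor-relation templates
#'   (`Sender`/`Receiver` take any attribute, `Interaction` a binary one,
#'   `Difference` a continuous one); must be absent for all other families.
#' @param lambda smoothing constant (>= 1) for the alternating statistics;
#'   default 2, the conventional value of the estimation-software family
#'   this model catalogue mirrors.  Ignored by non-alternating terms.
#' @return an object of class `effect_term`.
#' @export
effect_term <- function(name, attribute = NULL, lambda = 2) {
  fam <- .effect_families[.effect_families$name == name, ]
  if (nrow(fam) != 1) stop("unknown effect family: ", name)
  if (fam$needs_attr && is.null(attribute))
    stop("effect ", name, " requires an attribute")
  if (!fam$needs_attr && !is.null(attribute))
    stop("effect ", name, " does not take an attribute")
  if (name == "Interaction" && !attribute %in% .binary_attrs)
    stop("Interaction is defined for binary attributes only")
  if (name == "Difference" && !attribute %in% .continuous_attrs)
    stop("Difference is defined for continuous attributes only")
  if (lambda < 1) stop("lambda must be >= 1")
  structure(list(name = name, attribute = attribute, lambda = lambda),
            class = "effect_term")
}

#' Assemble a model specification
#'
#' @param terms list of [effect_term()]s; `(name, attribute)` pairs must be
#'   unique and the arc (density) term `ArcA` must be present.
#' @param condition_max_out logical; condition the model's sample space on
#'   the respondent nomination cap (default `TRUE`, matching a survey that
#'   asks for up to six friends).
#' @param center logical; center continuous covariates at the respondent
#'   mean before use (default `FALSE`: raw scales).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(terms, condition_max_out = TRUE, center = FALSE) {
  if (inherits(terms, "effect_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, logical(1), "effect_term")))
  keys <- vapply(terms, function(t)
    paste(t$name, t$attribute %||% "", sep = ":"), character(1))
  if (anyDuplicated(keys)) stop("duplicate (name, attribute) effect terms")
  if (!"ArcA" %in% vapply(terms, `[[`, character(1), "name"))
    stop("a model must contain the density term ArcA")
  structure(list(terms = terms, condition_max_out = condition_max_out,
                 center = center),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The default 26-effect school model
#'
#' The shipped per-school specification: six structural effects, the full
#' sender/receiver/interaction-or-difference block for gender, peer-supporter
#' status, knowledge, norms and talking, the PS-by-talking sender and
#' receiver products, and the four cross-level effects.
#'
#' @param lambda smoothing constant for the alternating terms (default 2).
#' @inheritParams model_spec
#' @return a [model_spec()] with 26 terms.
#' @export
school_model_spec <- function(lambda = 2, condition_max_out = TRUE) {
  terms <- c(
    lapply(c("ArcA", "ReciprocityA"), effect_term),
    lapply(c("AinSA", "AoutSA", "ATA-T", "A2PA-T"), effect_term,
           lambda = lambda),
    lapply(c("Sender", "Receiver", "Interaction"), effect_term,
           attribute = "gender"),
    lapply(c("Sender", "Receiver"), effect_term, attribute = "ps"),
    unlist(lapply(c("knowledge", "norms", "talking"), function(a)
      lapply(c("Sender", "Receiver", "Difference"), effect_term,
             attribute = a)), recursive = FALSE),
    lapply(c("PSTalkingSender", "PSTalkingReceiver"), effect_term),
    lapply(c("In2StarAX", "Out2StarAX", "TXAXarc", "L3XAX"), effect_term))
  model_spec(terms, condition_max_out = condition_max_out)
}

#' Human-readable effect labels
#'
#' Reporting labels in the conventional style of multilevel-ERGM software
#' output: structural and cross-level effects carry their parameter name in
#' brackets (e.g. `Density [ArcA]`), actor-relation effects are
#' `Attribute-Template` (e.g. `Gender-Sender`, `Talking-Difference`).
#'
#' @param spec a [model_spec()].
#' @return character vector of labels, one per term.
#' @export
effect_labels <- function(spec) {
  pretty <- c(gender = "Gender", ps = "PS", knowledge = "Knowledge",
              norms = "Norms", talking = "Talking")
  fixed <- c("ArcA" = "Density [ArcA]",
             "ReciprocityA" = "Reciprocity [ReciprocityA]",
             "AinSA" = "Popularity spread [AinSA]",
             "AoutSA" = "Activity spread [AoutSA]",
             "ATA-T" = "Path closure [ATA-T]",
             "A2PA-T" = "Multiple 2-paths [A2PA-T]",
             "PSTalkingSender" = "PS Talking-Sender",
             "PSTalkingReceiver" = "PS Talking-Receiver",
             "In2StarAX" = "Indegree [In2StarAX]",
             "Out2StarAX" = "Outdegree [Out2StarAX]",
             "TXAXarc" = "Cross-level arc [TXAXarc]",
             "L3XAX" = "Cross-level 3-paths [L3XAX]")
  vapply(spec$terms, function(t) {
    if (t$name %in% names(fixed)) return(unname(fixed[t$name]))
    paste0(pretty[t$attribute], "-", t$name)
  }, character(1))
}

#' Effect-to-process-evaluation component tags
#'
#' Tags every term of a specification with the process-evaluation component
#' its estimate speaks to: cross-level effects measure implementation
#' fidelity of the online-group delivery, peer-supporter actor effects the
#' mechanisms of impact, the remaining attribute effects the relational
#' context, and the purely structural effects serve as structural controls.
#'
#' @param spec a [model_spec()].
#' @return character vector, one tag per term.
#' @export
effect_components <- function(spec) {
  vapply(spec$terms, function(t) {
    fam <- .effect_families[.effect_families$name == t$name, ]
    if (fam$group == "cross-level") return("implementation fidelity")
    if (fam$group == "structural") return("structural controls")
    if (t$name %in% c("PSTalkingSender", "PSTalkingReceiver") ||
        identical(t$attribute, "ps")) return("mechanisms of impact")
    "context"
  }, character(1))
}

## Covariate resolution -------------------------------------------------------

#' Resolve modelling covariates from the attribute table
#'
#' Missing attribute values (non-respondents and item non-response) are
#' resolved before any statistic is computed: continuous attributes are
#' imputed at the respondent mean (or zero), binary attributes at zero.
#' This keeps every arc's contribution defined while centring the influence
#' of missing actors.  The policy is logged via `message()` when imputation
#' actually occurs.
#'
#' @param attrs attribute data frame (see [load_multilevel_network()]).
#' @param center center continuous covariates at the respondent mean.
#' @param impute_continuous `"mean"` (default) or `"zero"`.
#' @param quiet suppress the imputation message.
#' @return numeric matrix, one column per attribute, no missing values.
#' @export
resolve_covariates <- function(attrs, center = FALSE,
                               impute_continuous = c("mean", "zero"),
                               quiet = TRUE) {
  impute_continuous <- match.arg(impute_continuous)
  resp <- as.logical(attrs$respondent)
  out <- matrix(0, nrow(attrs), 0)
  for (v in c(.binary_attrs, .continuous_attrs)) {
    x <- as.numeric(attrs[[v]])
    nmiss <- sum(is.na(x))
    if (v %in% .binary_attrs) {
      x[is.na(x)] <- 0
    } else {
      fill <- if (impute_continuous == "mean")
        mean(x[resp], na.rm = TRUE) else 0
      if (is.nan(fill)) fill <- 0
      x[is.na(x)] <- fill
      if (center) x <- x - mean(x[resp])
    }
    if (nmiss > 0 && !quiet)
      message("imputed ", nmiss, " missing value(s) of '", v, "'")
    out <- cbind(out, x)
  }
  colnames(out) <- c(.binary_attrs, .continuous_attrs)
  rownames(out) <- attrs$student
  out
}

## internal: everything the C++ core needs, precomputed once per model
.spec_build <- function(net, attrs, spec) {
  validate_network(net)
  p <- length(spec$terms)
  n <- length(net$students)
  codes <- integer(p)
  lambdas <- numeric(p)
  covs <- matrix(0, n, p)
  needs <- any(vapply(spec$terms, function(t)
    !is.null(t$attribute) ||
      t$name %in% c("PSTalkingSender", "PSTalkingReceiver"), logical(1)))
  cv <- NULL
  if (needs) {
    if (is.null(attrs)) stop("attribute table required by the model terms")
    if (!identical(as.character(attrs$student), net$students))
      stop("attribute rows must match the student roster")
    cv <- resolve_covariates(attrs, center = spec$center)
  }
  for (k in seq_len(p)) {
    t <- spec$terms[[k]]
    fam <- .effect_families[.effect_families$name == t$name, ]
    codes[k] <- fam$code
    lambdas[k] <- if (fam$alternating) t$lambda else 2
    if (!is.null(t$attribute)) {
      if (!t$attribute %in% colnames(cv))
        stop("attribute absent from table: ", t$attribute)
      covs[, k] <- cv[, t$attribute]
    } else if (t$name %in% c("PSTalkingSender", "PSTalkingReceiver")) {
      covs[, k] <- cv[, "ps"] * cv[, "talking"]
    }
  }
  dx <- if (length(net$groups) > 0) rowSums(net$aff) else rep(0, n)
  smat <- if (length(net$groups) > 0) net$aff %*% t(net$aff)
          else matrix(0, n, n)
  free <- free_tie_variables(net)
  list(codes = codes, lambdas = lambdas, covs = covs,
       dx = as.numeric(dx), smat = smat, free = free)
}

## Graph statistics (reference implementation) --------------------------------

#' Graph statistics of a multilevel network
#'
#' Computes the sufficient statistics z(y) for every term of a model
#' specification, by direct (vectorised) evaluation of the closed forms:
#'
#' * `ArcA` = number of arcs; `ReciprocityA` = number of mutual dyads;
#' * `AinSA` = lambda^2 * sum_i \[(1-1/lambda)^din_i + din_i/lambda - 1\]
#'   (alternating in-star; `AoutSA` analogous on out-degrees);
#' * `ATA-T` = lambda * sum over arcs (i,j) of \[1 - (1-1/lambda)^TP(i,j)\]
#'   where TP(i,j) counts directed two-paths i->k->j (alternating path
#'   closure); `A2PA-T` sums the same kernel over all ordered pairs
#'   (alternating multiple two-paths);
#' * actor-relation terms are attribute-weighted arc counts (sender x_i,
#'   receiver x_j, binary product, absolute difference, PS-talking
#'   products);
#' * cross-level terms weight degrees and arcs by group-affiliation counts
#'   and shared-group counts.
#'
#' This is the recount oracle the incremental change statistics are checked
#' against; it is independent of the sampler's bookkeeping.
#'
#' @param net a [mergm_network()].
#' @param attrs attribute data frame (required when the model has
#'   actor-relation terms).
#' @param spec a [model_spec()].
#' @return named numeric vector aligned with the specification's terms.
#' @export
graph_statistics <- function(net, attrs, spec) {
  built <- .spec_build(net, attrs, spec)
  y <- net$adj
  n <- nrow(y)
  din <- colSums(y); dout <- rowSums(y)
  dx <- built$dx; smat <- built$smat
  TP <- NULL
  z <- numeric(length(spec$terms))
  for (k in seq_along(spec$terms)) {
    tm <- spec$terms[[k]]
    lam <- built$lambdas[k]
    r <- 1 - 1 / lam
    x <- built$covs[, k]
    z[k] <- switch(tm$name,
      "ArcA" = sum(y),
      "ReciprocityA" = sum(y * t(y)) / 2,
      "AinSA" = lam^2 * sum(r^din + din / lam - 1),
      "AoutSA" = lam^2 * sum(r^dout + dout / lam - 1),
      "ATA-T" = {
        if (is.null(TP)) TP <- y %*% y
        lam * sum(y * (1 - r^TP))
      },
      "A2PA-T" = {
        if (is.null(TP)) TP <- y %*% y
        k1 <- 1 - r^TP
        lam * (sum(k1) - sum(diag(k1)))
      },
      "Sender" = sum(dout * x),
      "Receiver" = sum(din * x),
      "Interaction" = as.numeric(x %*% y %*% x),
      "Difference" = sum(y * abs(outer(x, x, "-"))),
      "PSTalkingSender" = sum(dout * x),
      "PSTalkingReceiver" = sum(din * x),
      "In2StarAX" = sum(din * dx),
      "Out2StarAX" = sum(dout * dx),
      "TXAXarc" = sum(y * smat),
      "L3XAX" = sum(y * (outer(dx, dx) - smat)),
      stop("unknown term"))
  }
  names(z) <- effect_labels(spec)
  z
}

#' Change statistics for one tie variable
#'
#' The vector z(y with y_ij = 1) - z(y with y_ij = 0), holding every other
#' tie fixed, computed incrementally (the same code path the sampler uses).
#' Equals the full-recount difference exactly.
#'
#' @param net a [mergm_network()].
#' @param attrs attribute data frame (or `NULL`).
#' @param spec a [model_spec()].
#' @param sender,receiver roster positions (1-based integers) or student
#'   identifiers; the dyad must lie in the free tie set.
#' @return named numeric vector of per-term changes.
#' @export
change_statistics <- function(net, attrs, spec, sender, receiver) {
  built <- .spec_build(net, attrs, spec)
  i <- if (is.character(sender)) match(sender, net$students) else as.integer(sender)
  j <- if (is.character(receiver)) match(receiver, net$students) else as.integer(receiver)
  if (is.na(i) || is.na(j) || i == j || i < 1 || j < 1 ||
      i > length(net$students) || j > length(net$students) ||
      !net$respondent[i])
    stop("dyad outside the free tie set")
  d <- .cpp_change_stats(net$adj, i - 1L, j - 1L, built$codes, built$lambdas,
                         built$covs, built$dx, built$smat)
  names(d) <- effect_labels(spec)
  d
}

#' Dyad-level design matrix of change statistics
#'
#' One row per free tie variable, giving the change statistics of that dyad
#' evaluated on the observed network with the dyad itself set absent.  For a
#' dyad-independent model this is the exact logistic-regression design of
#' the tie variables; it also drives the pre-fit collinearity guard.
#'
#' @inheritParams change_statistics
#' @param dyads optional integer matrix of (sender, receiver) rows to
#'   restrict to (default: the full free set).
#' @return list with `X` (matrix of change statistics), `y` (observed tie
#'   indicators) and `dyads`.
#' @export
dyad_design_matrix <- function(net, attrs, spec, dyads = NULL) {
  built <- .spec_build(net, attrs, spec)
  if (is.null(dyads)) dyads <- built$free
  X <- matrix(0, nrow(dyads), length(spec$terms))
  yv <- numeric(nrow(dyads))
  for (r in seq_len(nrow(dyads))) {
    i <- dyads[r, 1]; j <- dyads[r, 2]
    X[r, ] <- .cpp_change_stats(net$adj, i - 1L, j - 1L, built$codes,
                                built$lambdas, built$covs, built$dx,
                                built$smat)
    yv[r] <- net$adj[i, j]
  }
  colnames(X) <- effect_labels(spec)
  list(X = X, y = yv, dyads = dyads)
}

## Serialisation --------------------------------------------------------------

#' Write / read a model specification as a YAML config
#'
#' The config lists `condition_max_out`, `center` and one `{name,
#' attribute, lambda}` entry per term.  The shipped default config
#' (`system.file("extdata", "default_school_model.yaml", package = "mergm")`)
#' reproduces the 26-effect school model of [school_model_spec()].
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `write_model_spec()`: the path, invisibly; `read_model_spec()`:
#'   a [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  obj <- list(
    condition_max_out = spec$condition_max_out,
    center = spec$center,
    terms = lapply(spec$terms, function(t)
      c(list(name = t$name),
        if (!is.null(t$attribute)) list(attribute = t$attribute),
        list(lambda = t$lambda))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  terms <- lapply(obj$terms, function(t)
    effect_term(t$name, attribute = t$attribute, lambda = t$lambda %||% 2))
  model_spec(terms,
             condition_max_out = isTRUE(obj$condition_max_out),
             center = isTRUE(obj$center))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("MERGM specification:", length(x$terms), "effects",
      if (x$condition_max_out) "(conditioned on the nomination cap)" else "",
      "\n")
  lab <- effect_labels(x)
  comp <- effect_components(x)
  for (k in seq_along(lab))
    cat(sprintf("  %-30s %s\n", lab[k], comp[k]))
  invisible(x)
}
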