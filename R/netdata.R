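#' Construct a multilevel school network
#'
#' A multilevel network couples a directed friendship network over students
#' (level A) with a fixed, undirected bipartite affiliation network between
#' students and online groups (level B).  Friendship arcs are the modelled
#' tie variables; affiliations are exogenous predictors.  Two structural
#' rules of the survey design are enforced as invariants:
#'
#' * an arc can only be sent by a respondent (ties from students who did not
#'   complete the survey are structurally impossible, i.e. fixed zeros);
#' * a respondent names at most `max_out` friends (the nomination cap).
#'
#' @param students character vector of unique student identifiers (the
#'   roster; includes non-respondents who were nominated by others).
#' @param groups character vector of unique group identifiers (may be empty).
#' @param adj n-by-n 0/1 integer matrix of friendship arcs, `adj[i, j] = 1`
#'   when `i` nominates `j`; the diagonal must be zero.
#' @param aff n-by-m 0/1 integer matrix of student-group affiliations.
#' @param respondent logical vector, `TRUE` for students who completed the
#'   survey.
#' @param max_out nomination cap for respondents (default 6).
#' @return an object of class `mergm_network`.
#' @seealso [load_multilevel_network()], [free_tie_variables()]
#' @export
mergm_network <- function(students, groups = character(), adj = NULL,
                          aff = NULL, respondent = NULL, max_out = 6L) {
  students <- as.character(students)
  groups <- as.character(groups)
  n <- length(students)
  m <- length(groups)
  if (anyDuplicated(students)) stop("duplicate student identifiers in roster")
  if (m > 0 && anyDuplicated(groups)) stop("duplicate group identifiers")
  if (is.null(adj)) adj <- matrix(0L, n, n)
  if (is.null(aff)) aff <- matrix(0L, n, m)
  if (is.null(respondent)) respondent <- rep(TRUE, n)
  adj <- matrix(as.integer(adj), n, n)
  aff <- matrix(as.integer(aff), n, max(m, 0L))
  dimnames(adj) <- list(students, students)
  if (m > 0) dimnames(aff) <- list(students, groups)
  net <- structure(
    list(students = students, groups = groups, adj = adj, aff = aff,
         respondent = as.logical(respondent), max_out = as.integer(max_out)),
    class = "mergm_network")
  validate_network(net)
  net
}

#' Validate the structural invariants of a multilevel network
#'
#' Checks the no-self-arc rule, binary coding, the structural-zero rule
#' (every arc's sender is a respondent) and the respondent out-degree cap.
#' Used internally after every operation that produces networks, and by the
#' test suite as a global conservation check on sampled and generated
#' networks.
#'
#' @param net a [mergm_network()].
#' @return `net`, invisibly; errors describe the violated rule.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "mergm_network"))
  n <- length(net$students)
  if (!all(dim(net$adj) == c(n, n))) stop("adjacency dimension mismatch")
  if (nrow(net$aff) != n) stop("affiliation dimension mismatch")
  if (length(net$respondent) != n) stop("respondent flag length mismatch")
  if (any(is.na(net$adj)) || !all(net$adj %in% c(0L, 1L)))
    stop("adjacency must be 0/1")
  if (!all(net$aff %in% c(0L, 1L))) stop("affiliations must be 0/1")
  if (n > 0 && any(diag(net$adj) != 0L)) stop("self-arcs are not allowed")
  if (n > 0) {
    sender_nonresp <- rowSums(net$adj) > 0 & !net$respondent
    if (any(sender_nonresp))
      stop("structural-zero rule violated: arcs sent by non-respondent(s) ",
           paste(net$students[sender_nonresp], collapse = ", "),
           " (ties from non-respondents are structurally impossible)")
    over <- rowSums(net$adj) > net$max_out
    if (any(over))
      stop("respondent out-degree exceeds the nomination cap (max_out = ",
           net$max_out, ") for ", paste(net$students[over], collapse = ", "))
  }
  invisible(net)
}

#' Assemble a multilevel network and attribute table from records
#'
#' Builds the validated data pair from in-memory records (data frames), the
#' form in which delimited files arrive.  Duplicate arc or affiliation
#' records collapse to a single binary tie with a warning.  In strict mode
#' (the default) an arc whose sender is flagged non-respondent, or a
#' respondent with more than `max_out` nominations, is an error; in
#' non-strict mode the offending records are dropped with a warning, which
#' accommodates messy survey exports.
#'
#' @param arc_records data frame with columns `sender`, `receiver`.
#' @param affiliation_records data frame with columns `student`, `group`.
#' @param attribute_records data frame with columns `student`, `respondent`,
#'   `gender`, `ps`, `knowledge`, `norms`, `talking`; its `student` column
#'   defines the roster and its order.  Empty cells are missing values.
#' @param max_out nomination cap (default 6).
#' @param strict logical; treat structural violations as errors (default
#'   `TRUE`).
#' @return list with elements `network` ([mergm_network()]) and `attrs`
#'   (the attribute data frame, keyed by `student`).
#' @export
load_multilevel_network <- function(arc_records, affiliation_records,
                                    attribute_records, max_out = 6L,
                                    strict = TRUE) {
  attrs <- as.data.frame(attribute_records)
  needed <- c("student", "respondent", "gender", "ps",
              "knowledge", "norms", "talking")
  missing_cols <- setdiff(needed, names(attrs))
  if (length(missing_cols))
    stop("attribute table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  attrs$student <- as.character(attrs$student)
  if (anyDuplicated(attrs$student)) stop("duplicate students in attributes")
  students <- attrs$student
  respondent <- as.logical(attrs$respondent)
  for (v in c("gender", "ps")) {
    bad <- !(attrs[[v]] %in% c(0, 1) | is.na(attrs[[v]]))
    if (any(bad)) stop("binary attribute '", v, "' must be 0/1 or missing")
  }
  for (v in c("knowledge", "norms", "talking")) {
    if (any(is.infinite(attrs[[v]])))
      stop("continuous attribute '", v, "' must be finite when present")
  }

  arcs <- as.data.frame(arc_records)
  if (nrow(arcs) > 0) {
    arcs$sender <- as.character(arcs$sender)
    arcs$receiver <- as.character(arcs$receiver)
    unknown <- setdiff(c(arcs$sender, arcs$receiver), students)
    if (length(unknown))
      stop("unknown student identifier(s) in arcs: ",
           paste(unknown, collapse = ", "))
    if (any(arcs$sender == arcs$receiver))
      stop("self-arcs are not allowed")
    dup <- duplicated(arcs[c("sender", "receiver")])
    if (any(dup)) {
      warning(sum(dup), " duplicate arc record(s) collapsed to binary ties")
      arcs <- arcs[!dup, , drop = FALSE]
    }
    nonresp_send <- !respondent[match(arcs$sender, students)]
    if (any(nonresp_send)) {
      msg <- paste0(sum(nonresp_send), " arc(s) sent by non-respondents ",
                    "violate the structural-zero rule (ties from ",
                    "non-respondents are structurally impossible)")
      if (strict) stop(msg) else {
        warning(msg, "; records dropped")
        arcs <- arcs[!nonresp_send, , drop = FALSE]
      }
    }
  }

  affs <- as.data.frame(affiliation_records)
  groups <- character()
  if (nrow(affs) > 0) {
    affs$student <- as.character(affs$student)
    affs$group <- as.character(affs$group)
    unknown <- setdiff(affs$student, students)
    if (length(unknown))
      stop("unknown student identifier(s) in affiliations: ",
           paste(unknown, collapse = ", "))
    dup <- duplicated(affs[c("student", "group")])
    if (any(dup)) {
      warning(sum(dup), " duplicate affiliation record(s) collapsed")
      affs <- affs[!dup, , drop = FALSE]
    }
    groups <- unique(affs$group)
  }

  n <- length(students)
  adj <- matrix(0L, n, n, dimnames = list(students, students))
  if (nrow(arcs) > 0)
    adj[cbind(match(arcs$sender, students), match(arcs$receiver, students))] <- 1L
  over <- rowSums(adj) > max_out
  if (any(over)) {
    msg <- paste0("respondent out-degree exceeds the nomination cap for ",
                  paste(students[over], collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; surplus nominations dropped (arbitrary order)")
    for (i in which(over)) {
      keep <- which(adj[i, ] == 1L)[seq_len(max_out)]
      adj[i, ] <- 0L
      adj[i, keep] <- 1L
    }
  }
  aff <- matrix(0L, n, length(groups), dimnames = list(students, groups))
  if (nrow(affs) > 0)
    aff[cbind(match(affs$student, students), match(affs$group, groups))] <- 1L

  net <- mergm_network(students, groups, adj, aff, respondent, max_out)
  list(network = net, attrs = attrs)
}

#' Read one school's delimited files
#'
#' Reads the three per-school files — arc list (`sender,receiver`),
#' affiliation list (`student,group`) and attribute table
#' (`student,respondent,gender,ps,knowledge,norms,talking`) — and assembles
#' them through [load_multilevel_network()].
#'
#' @param arcs_file,affiliations_file,attributes_file file paths.
#' @inheritParams load_multilevel_network
#' @return as [load_multilevel_network()].
#' @export
read_school <- function(arcs_file, affiliations_file, attributes_file,
                        max_out = 6L, strict = TRUE) {
  arcs <- utils::read.csv(arcs_file, colClasses = "character")
  affs <- utils::read.csv(affiliations_file, colClasses = "character")
  attrs <- utils::read.csv(attributes_file)
  load_multilevel_network(arcs, affs, attrs, max_out = max_out,
                          strict = strict)
}

#' Write one school's delimited files
#'
#' Emits the canonical three-file representation (arcs, affiliations,
#' attributes) so that `read_school()` round-trips to the identical
#' canonicalised records: arcs in roster order (sender-major), affiliations
#' in roster-by-group order.
#'
#' @param net a [mergm_network()].
#' @param attrs the attribute data frame.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix, e.g. `"school1"`.
#' @return invisibly, the three file paths written.
#' @export
write_school <- function(net, attrs, dir, prefix = "school") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(net$students)
  if (n > 0 && sum(net$adj) > 0) {
    ij <- which(net$adj == 1L, arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    arcs <- data.frame(sender = net$students[ij[, 1]],
                       receiver = net$students[ij[, 2]])
  } else {
    arcs <- data.frame(sender = character(), receiver = character())
  }
  affs <- data.frame(student = character(), group = character())
  if (length(net$groups) > 0 && sum(net$aff) > 0) {
    ig <- which(net$aff == 1L, arr.ind = TRUE)
    ig <- ig[order(ig[, 1], ig[, 2]), , drop = FALSE]
    affs <- data.frame(student = net$students[ig[, 1]],
                       group = net$groups[ig[, 2]])
  }
  paths <- file.path(dir, paste0(prefix, c("_arcs.csv", "_affiliations.csv",
                                           "_attributes.csv")))
  utils::write.csv(arcs, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(affs, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(attrs, paths[3], row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}

#' Enumerate the free (modelled) tie variables
#'
#' The modelled tie variables are exactly the ordered pairs `(i, j)`,
#' `i != j`, whose sender `i` is a respondent; all other ordered pairs are
#' structural zeros fixed at 0.  With full response this is the classical
#' n(n-1) dyad count.  Pairs are returned in deterministic sender-major
#' roster order.
#'
#' @param net a [mergm_network()].
#' @return integer matrix with columns `sender`, `receiver` (roster
#'   positions, 1-based) and one row per free tie variable.
#' @export
free_tie_variables <- function(net) {
  validate_network(net)
  n <- length(net$students)
  senders <- which(net$respondent)
  if (n < 2 || length(senders) == 0)
    return(matrix(integer(), 0, 2,
                  dimnames = list(NULL, c("sender", "receiver"))))
  out <- cbind(sender = rep(senders, each = n - 1L),
               receiver = unlist(lapply(senders, function(i) setdiff(seq_len(n), i))))
  rownames(out) <- NULL
  out
}

#' Summarise a school's network and attributes
#'
#' Counts of students, respondents, arcs, groups and affiliations, density
#' over the free tie variables, the response proportion, and respondent
#' means of the individual covariates.  Density of an empty tie space is
#' reported as `NA` by convention.
#'
#' @param net a [mergm_network()].
#' @param attrs attribute data frame (optional; attribute means omitted
#'   when absent).
#' @return a list of class `mergm_summary`.
#' @export
network_summary <- function(net, attrs = NULL) {
  validate_network(net)
  n <- length(net$students)
  nfree <- nrow(free_tie_variables(net))
  arcs <- sum(net$adj)
  out <- list(
    students = n,
    respondents = sum(net$respondent),
    arcs = arcs,
    groups = length(net$groups),
    affiliations = sum(net$aff),
    free_tie_variables = nfree,
    density = if (nfree > 0) arcs / nfree else NA_real_,
    response_proportion = if (n > 0) mean(net$respondent) else NA_real_)
  if (!is.null(attrs)) {
    resp <- as.logical(attrs$respondent)
    out$attribute_means <- vapply(
      c("gender", "ps", "knowledge", "norms", "talking"),
      function(v) mean(attrs[[v]][resp], na.rm = TRUE), numeric(1))
  }
  class(out) <- "mergm_summary"
  out
}

#' @export
print.mergm_summary <- function(x, ...) {
  cat(sprintf(
    "Multilevel school network: %d students (%d respondents, %.0f%% response)\n",
    x$students, x$respondents, 100 * x$response_proportion))
  cat(sprintf("  %d arcs over %d free tie variables (density %.3f)\n",
              x$arcs, x$free_tie_variables, x$density))
  cat(sprintf("  %d groups, %d affiliations\n", x$groups, x$affiliations))
  if (!is.null(x$attribute_means)) {
    cat("  respondent attribute means:\n")
    print(round(x$attribute_means, 3))
  }
  invisible(x)
}

#' Write adjacency and incidence matrices for interchange
#'
#' Optional writer emitting the square friendship adjacency matrix and the
#' student-by-group incidence matrix as whitespace-delimited text in roster
#' order, the exchange format of existing ERGM estimation tools.
#'
#' @param net a [mergm_network()].
#' @param adj_file,aff_file output paths (`NULL` to skip one of them).
#' @return invisibly, the paths written.
#' @export
write_matrices <- function(net, adj_file = NULL, aff_file = NULL) {
  validate_network(net)
  if (!is.null(adj_file))
    utils::write.table(net$adj, adj_file, row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(aff_file))
    utils::write.table(net$aff, aff_file, row.names = FALSE,
                       col.names = FALSE)
  invisible(c(adj_file, aff_file))
}
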