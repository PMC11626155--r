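## ---------------------------------------------------------------------------
## Hierarchical haplotype calling from (possibly partial) genotypes
## ---------------------------------------------------------------------------

# Normalize a genotype call vector to a named integer vector with values
# 0 (ancestral), 1 (derived), NA (untested). Accepts numeric or the
# character states "ancestral"/"derived"/"missing".
normalize_calls <- function(calls) {
  if (is.list(calls)) calls <- unlist(calls)
  nm <- names(calls)
  if (is.null(nm)) stop("genotype calls must be named by variant id",
                        call. = FALSE)
  if (is.character(calls)) {
    out <- ifelse(calls %in% c("derived", "1"), 1L,
                  ifelse(calls %in% c("ancestral", "0"), 0L, NA_integer_))
  } else {
    out <- as.integer(calls)
    if (any(!out %in% c(0L, 1L) & !is.na(out))) {
      stop("genotype states must be 0, 1 or NA", call. = FALSE)
    }
  }
  stats::setNames(out, nm)
}

msy_condition <- function(class, message, ...) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = NULL, ...))
}

# Edge state given the tested variants on it: "derived" if any derived call
# (intra-edge disagreement flagged upstream), "ancestral" if tested and all
# ancestral, "untested" otherwise (includes variant-free junction edges).
edge_states <- function(tree, calls) {
  nodes <- setdiff(bt_nodes(tree), tree$root)
  vapply(nodes, function(nd) {
    v <- tree$edge_variants[[nd]]
    st <- calls[v[v %in% names(calls)]]
    st <- st[!is.na(st)]
    if (!length(st)) return("untested")
    if (any(st == 1L)) "derived" else "ancestral"
  }, character(1))
}

#' Call a sample's haplotype by hierarchical descent
#'
#' Emulates successive backbone genotyping: the call is the deepest node whose
#' root path is supported by the tested variants. An untested variant that
#' lies between two tested-derived variants on one path is bracketed, i.e.
#' treated as derived — this is what lets a skip-ahead test series (e.g. a
#' Crown variant followed directly by a deep terminal variant) yield a
#' terminal call. A tested-ancestral edge blocks descent through it.
#'
#' Status is `terminal` at a terminal HT; at an internal node it is
#' `inner_confirmed` when every child edge was tested (and found ancestral)
#' and `inner_unresolved` when at least one child edge is untested. Both
#' internal statuses display with the field's `"*"` suffix (`label`).
#'
#' Off-path derived variants are tolerated one at a time (kept in
#' `conflicts`, with a warning); two or more — or a support tie between
#' disjoint candidate paths — raise an ambiguous-call error carrying the
#' candidate paths. A sample with no tested variant raises a no-call error.
#'
#' @param calls named vector of variant states (0/1/NA, or
#'   `"ancestral"`/`"derived"`/`"missing"`), names = panel variant ids.
#' @param tree a `backbone_tree` with placed variants.
#' @param sample sample id used in the returned assignment.
#' @return an object of class `ht_assignment`: fields `sample`, `node`,
#'   `status`, `label`, `conflicts`, `tested_path`, `n_tested`.
#' @export
call_haplotype <- function(calls, tree, sample = "sample") {
  calls <- normalize_calls(calls)
  placed <- unlist(tree$edge_variants, use.names = FALSE)
  unknown <- setdiff(names(calls), if (is.null(tree$panel)) placed else
    tree$panel$id)
  if (length(unknown)) {
    stop("calls reference variants outside the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tested <- calls[!is.na(calls)]
  if (!length(tested)) {
    stop(msy_condition("msy_no_call",
                       sprintf("sample '%s': no tested variants", sample)))
  }
  es <- edge_states(tree, tested)
  derived_edges <- names(es)[es == "derived"]
  DV <- names(tested)[tested == 1L]

  # candidate nodes: bottom ends of derived edges whose root path has no
  # tested-ancestral edge above them
  path_clean <- function(nd) {
    above <- setdiff(bt_path(tree, nd), tree$root)
    !any(es[above] == "ancestral")
  }
  cand <- derived_edges[vapply(derived_edges, path_clean, logical(1))]
  # maximal candidates (drop any candidate that is an ancestor of another)
  if (length(cand) > 1L) {
    keep <- vapply(cand, function(nd) {
      !any(vapply(setdiff(cand, nd), function(other)
        nd %in% bt_path(tree, other)[-length(bt_path(tree, other))],
        logical(1)))
    }, logical(1))
    cand <- cand[keep]
  }

  if (!length(cand)) {
    node <- tree$root
    conflicts <- sort(DV)   # any derived call is off-path at the root
  } else if (length(cand) == 1L) {
    node <- cand
    conflicts <- sort(setdiff(DV, bt_path_variants(tree, node)))
  } else {
    support <- vapply(cand, function(nd)
      sum(DV %in% bt_path_variants(tree, nd)), integer(1))
    best <- cand[support == max(support)]
    if (length(best) > 1L) {
      stop(msy_condition(
        "msy_ambiguous_call",
        sprintf("sample '%s': tied support between disjoint paths (%s)",
                sample, paste(sort(best), collapse = ", ")),
        candidates = lapply(sort(best), bt_path, tree = tree)))
    }
    node <- best
    conflicts <- sort(setdiff(DV, bt_path_variants(tree, node)))
  }

  if (length(conflicts) >= 2L) {
    stop(msy_condition(
      "msy_ambiguous_call",
      sprintf("sample '%s': %d off-path derived variants (%s)",
              sample, length(conflicts), paste(conflicts, collapse = ", ")),
      candidates = c(list(bt_path(tree, node)),
                     lapply(cand, bt_path, tree = tree))))
  }
  if (length(conflicts) == 1L) {
    warning(sprintf("sample '%s': off-path derived variant %s kept as conflict",
                    sample, conflicts), call. = FALSE)
  }

  kids <- tree$children[[node]]
  if (!length(kids)) {
    status <- "terminal"
  } else {
    kid_states <- es[kids]
    status <- if (all(kid_states == "ancestral")) "inner_confirmed"
              else "inner_unresolved"
  }
  structure(
    list(sample = sample, node = node, status = status,
         label = if (status == "terminal") node else paste0(node, "*"),
         conflicts = conflicts,
         tested_path = sort(intersect(DV, bt_path_variants(tree, node))),
         n_tested = length(tested)),
    class = "ht_assignment")
}

#' @export
print.ht_assignment <- function(x, ...) {
  cat(sprintf("%s -> %s [%s]%s\n", x$sample, x$label, x$status,
              if (length(x$conflicts))
                paste0(" conflicts: ", paste(x$conflicts, collapse = ","))
              else ""))
  invisible(x)
}

#' Call haplotypes for a cohort
#'
#' Vectorized [call_haplotype()]; per-sample failures (no-call, ambiguous
#' call) are captured into the `ok`/`note` columns instead of aborting the
#' batch. Output is independent of input order (each sample is called in
#' isolation); rows follow the input order.
#'
#' @param genotypes matrix (samples x variants, 0/1/NA) or named list of call
#'   vectors.
#' @param tree a `backbone_tree`.
#' @return `data.frame` of class `ht_assignments` with columns `sample`,
#'   `node`, `label`, `status`, `conflicts` (";"-joined), `n_tested`, `ok`,
#'   `note`.
#' @export
batch_call <- function(genotypes, tree) {
  if (is.matrix(genotypes) || is.data.frame(genotypes)) {
    M <- as.matrix(genotypes)
    ids <- rownames(M)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(M)))
    genotypes <- stats::setNames(
      lapply(seq_len(nrow(M)), function(i) M[i, ]), ids)
  }
  ids <- names(genotypes)
  if (is.null(ids)) ids <- paste0("s", seq_along(genotypes))
  rows <- lapply(seq_along(genotypes), function(i) {
    a <- withCallingHandlers(
      tryCatch(call_haplotype(genotypes[[i]], tree, sample = ids[[i]]),
               error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning"))
    if (inherits(a, "ht_assignment")) {
      data.frame(sample = a$sample, node = a$node, label = a$label,
                 status = a$status,
                 conflicts = paste(a$conflicts, collapse = ";"),
                 n_tested = a$n_tested, ok = TRUE, note = "",
                 stringsAsFactors = FALSE)
    } else {
      cls <- if (inherits(a, "msy_no_call")) "no_call"
             else if (inherits(a, "msy_ambiguous_call")) "ambiguous"
             else "error"
      data.frame(sample = ids[[i]], node = NA_character_,
                 label = NA_character_, status = cls, conflicts = "",
                 n_tested = NA_integer_, ok = FALSE,
                 note = conditionMessage(a), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ht_assignments", "data.frame")
  out
}

#' Frequency-aware test plan for successive genotyping
#'
#' Given the current (consistent) partial genotype, returns the untested
#' edge variants below the current node, ordered so that branches leading to
#' high prior-mass haplotypes are assayed first (the field practice of
#' testing a breed's common haplotypes first). Within the plan the order is
#' depth-first: a branch's own variants precede its subtree, branches are
#' ranked by descending subtree prior mass, ties broken by variant id.
#' Subtrees with zero prior mass are omitted when a prior is supplied; pass a
#' uniform prior to enumerate everything.
#'
#' @param tree a `backbone_tree`.
#' @param current named call vector (may be empty) — the tests done so far.
#' @param prior named numeric, haplotype (node) name -> prior mass; `NULL`
#'   for uniform over terminal HTs.
#' @return list with `node` (current consistent node) and `plan` (ordered
#'   character vector of variant ids; empty at a terminal).
#' @export
plan_tests <- function(tree, current = NULL, prior = NULL) {
  if (is.null(prior)) {
    tips <- bt_tips(tree)
    prior <- stats::setNames(rep(1 / length(tips), length(tips)), tips)
  }
  if (any(prior < 0)) stop("prior masses must be >= 0", call. = FALSE)
  bad <- setdiff(names(prior), bt_nodes(tree))
  if (length(bad)) {
    stop("prior references unknown node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  current <- if (is.null(current) || !length(current)) {
    stats::setNames(integer(0), character(0))
  } else normalize_calls(current)
  tested_ids <- names(current)[!is.na(current)]
  node <- if (length(tested_ids)) {
    call_haplotype(current, tree, sample = "plan")$node
  } else tree$root

  mass <- function(nd) {
    d <- bt_descendants(tree, nd)
    sum(prior[names(prior) %in% d])
  }
  rec <- function(nd) {
    kids <- tree$children[[nd]]
    if (!length(kids)) return(character(0))
    masses <- vapply(kids, mass, numeric(1))
    first_v <- vapply(kids, function(k) {
      v <- sort(tree$edge_variants[[k]])
      if (length(v)) v[1L] else paste0("~", k)   # junctions sort last
    }, character(1))
    kids <- kids[order(-masses, first_v)]
    out <- character(0)
    for (k in kids) {
      if (mass(k) <= 0) next
      v <- sort(setdiff(tree$edge_variants[[k]], tested_ids))
      out <- c(out, v, rec(k))
    }
    out
  }
  list(node = node, plan = rec(node))
}

#' Impute untested alleles from a haplotype assignment
#'
#' Fills the full panel-ordered 0/1 vector for a sample: variants on the
#' root path of the assigned node are set derived (1), all off-path variants
#' ancestral (0). Tested states are never overwritten; a tested-derived
#' off-path variant stays 1 and is flagged via the `"conflict_variants"`
#' attribute. Idempotent: imputing an already complete vector returns it
#' unchanged.
#'
#' @param a an `ht_assignment` (or a node name).
#' @param tree a `backbone_tree`.
#' @param calls optional named call vector of the tested states (0/1/NA).
#' @return named integer 0/1 vector over the placed panel variants, in panel
#'   order.
#' @export
impute_alleles <- function(a, tree, calls = NULL) {
  node <- if (inherits(a, "ht_assignment")) a$node else as.character(a)
  stopifnot(node %in% bt_nodes(tree))
  ids <- if (!is.null(tree$panel)) {
    tree$panel$id[tree$panel$placed]
  } else unlist(tree$edge_variants, use.names = FALSE)
  vec <- stats::setNames(rep(0L, length(ids)), ids)
  vec[intersect(bt_path_variants(tree, node), ids)] <- 1L
  conflicts <- character(0)
  if (!is.null(calls)) {
    calls <- normalize_calls(calls)
    tested <- calls[!is.na(calls) & names(calls) %in% ids]
    conflicts <- names(tested)[tested == 1L & vec[names(tested)] == 0L]
    vec[names(tested)] <- tested
  }
  attr(vec, "conflict_variants") <- conflicts
  vec
}

#' Encode a cohort's assignments as a 0/1 variant matrix
#'
#' One row per sample, columns in panel order; untested path variants are
#' imputed derived, off-path variants ancestral ([impute_alleles()]).
#' Re-calling the encoded matrix with [batch_call()] reproduces the
#' assignments (node and label).
#'
#' @param assignments an `ht_assignments` data.frame from [batch_call()] (or
#'   list of `ht_assignment`).
#' @param tree a `backbone_tree`.
#' @param genotypes optional original genotypes (matrix or named list) whose
#'   tested states take precedence over imputation.
#' @return integer matrix, samples x placed panel variants.
#' @export
encode_matrix <- function(assignments, tree, genotypes = NULL) {
  if (inherits(assignments, "ht_assignments") || is.data.frame(assignments)) {
    df <- assignments[assignments$ok, , drop = FALSE]
    samples <- df$sample
    nodes <- df$node
  } else {
    samples <- vapply(assignments, `[[`, character(1), "sample")
    nodes <- vapply(assignments, `[[`, character(1), "node")
  }
  ids <- if (!is.null(tree$panel)) tree$panel$id[tree$panel$placed] else
    unlist(tree$edge_variants, use.names = FALSE)
  if (is.matrix(genotypes) || is.data.frame(genotypes)) {
    G <- as.matrix(genotypes)
    genotypes <- stats::setNames(
      lapply(seq_len(nrow(G)), function(i) G[i, ]), rownames(G))
  }
  M <- matrix(0L, nrow = length(samples), ncol = length(ids),
              dimnames = list(samples, ids))
  for (i in seq_along(samples)) {
    cl <- if (!is.null(genotypes)) genotypes[[samples[i]]] else NULL
    M[i, ] <- impute_alleles(nodes[i], tree, calls = cl)[ids]
  }
  M
}
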