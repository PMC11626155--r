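#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## backbone_tree: rooted haplotype tree with variant-annotated edges
## ---------------------------------------------------------------------------

#' Construct a backbone tree object
#'
#' A `backbone_tree` is a rooted tree of named haplotype nodes. Every non-root
#' node owns the edge above it; haplotype-determining variants are attached to
#' that edge. Terminal nodes are named haplotypes (HTs); internal nodes are
#' branching points to which samples may be allocated as `"*HT"` calls.
#'
#' @param parent named character vector mapping each node to its parent; the
#'   root maps to `NA`.
#' @param children named list mapping each node to its (ordered) children.
#' @param edge_variants named list mapping each non-root node to the character
#'   vector of variant ids on the edge above it (may be empty for junction
#'   nodes).
#' @param panel variant panel `data.frame` as returned by
#'   [parse_variant_panel()], or `NULL`.
#' @param crown_root name of the node rooting the Crown haplogroup, or `NA`.
#' @param edge_length optional named numeric of branch lengths (years) for the
#'   edge above each non-root node.
#'
#' @return an object of class `backbone_tree`.
#' @export
backbone_tree <- function(parent, children, edge_variants = list(),
                          panel = NULL, crown_root = NA_character_,
                          edge_length = NULL) {
  nodes <- names(parent)
  if (is.null(nodes) || anyDuplicated(nodes)) {
    stop("node names must be present and unique", call. = FALSE)
  }
  root <- nodes[is.na(parent)]
  if (length(root) != 1L) {
    stop("tree must have exactly one root", call. = FALSE)
  }
  for (nd in setdiff(nodes, root)) {
    if (!parent[[nd]] %in% nodes) {
      stop(sprintf("parent of '%s' is not a node", nd), call. = FALSE)
    }
  }
  # connectivity + acyclicity: every node reaches root in <= n steps
  n <- length(nodes)
  for (nd in nodes) {
    cur <- nd
    steps <- 0L
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in parent map", call. = FALSE)
    }
    if (cur != root) stop("tree is not connected", call. = FALSE)
  }
  children <- children[intersect(nodes, names(children))]
  for (nd in nodes) if (is.null(children[[nd]])) children[[nd]] <- character(0)
  ev <- edge_variants
  for (nd in nodes) if (is.null(ev[[nd]])) ev[[nd]] <- character(0)
  if (length(ev[[root]])) {
    stop("root must not carry defining variants", call. = FALSE)
  }
  # canonical storage order: preorder from the root (children order kept)
  pre <- character(0)
  stack <- root
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    pre <- c(pre, cur)
    stack <- c(as.character(children[[cur]]), stack)
  }
  if (length(pre) != n) stop("tree is not connected", call. = FALSE)
  children <- lapply(children, as.character)
  tree <- structure(
    list(root = root, parent = parent[pre], children = children[pre],
         edge_variants = ev[pre], panel = panel,
         crown_root = crown_root,
         edge_length = if (is.null(edge_length)) NULL else
           edge_length[setdiff(pre, root)]),
    class = "backbone_tree"
  )
  if (!is.na(crown_root) && !crown_root %in% nodes) {
    stop(sprintf("crown_root '%s' is not a node", crown_root), call. = FALSE)
  }
  tree
}

#' @export
print.backbone_tree <- function(x, ...) {
  cat(sprintf("backbone_tree: %d nodes (%d terminal), root '%s'\n",
              length(bt_nodes(x)), length(bt_tips(x)), x$root))
  if (!is.na(x$crown_root)) cat(sprintf("  crown root: '%s'\n", x$crown_root))
  nv <- sum(lengths(x$edge_variants))
  cat(sprintf("  %d placed variant(s) on edges\n", nv))
  invisible(x)
}

#' Nodes, tips and structure accessors
#'
#' @param tree a `backbone_tree`.
#' @return `bt_nodes()`: all node names; `bt_tips()`: terminal node names;
#'   `bt_internal()`: internal node names.
#' @export
bt_nodes <- function(tree) names(tree$parent)

#' @rdname bt_nodes
#' @export
bt_tips <- function(tree) {
  names(tree$children)[lengths(tree$children) == 0L]
}

#' @rdname bt_nodes
#' @export
bt_internal <- function(tree) setdiff(bt_nodes(tree), bt_tips(tree))

#' Root-to-node path
#'
#' @param tree a `backbone_tree`.
#' @param node node name.
#' @return character vector of node names from root to `node` inclusive.
#' @export
bt_path <- function(tree, node) {
  stopifnot(node %in% bt_nodes(tree))
  path <- character(0)
  cur <- node
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$parent[[cur]]
  }
  path
}

#' Variants on the root-to-node path
#'
#' The defining variants of every edge between the root and `node`.
#'
#' @inheritParams bt_path
#' @return character vector of variant ids (possibly empty).
#' @export
bt_path_variants <- function(tree, node) {
  path <- bt_path(tree, node)
  unlist(tree$edge_variants[setdiff(path, tree$root)], use.names = FALSE)
}

#' Descendants of a node (self included)
#'
#' @inheritParams bt_path
#' @return character vector of node names in preorder.
#' @export
bt_descendants <- function(tree, node) {
  out <- character(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, cur)
    stack <- c(tree$children[[cur]], stack)
  }
  out
}

#' @rdname bt_descendants
#' @export
bt_subtree_tips <- function(tree, node) {
  intersect(bt_descendants(tree, node), bt_tips(tree))
}

bt_preorder <- function(tree) bt_descendants(tree, tree$root)

#' Is a node inside the Crown haplogroup?
#'
#' @inheritParams bt_path
#' @return logical; `FALSE` everywhere when no crown root is set.
#' @export
bt_in_crown <- function(tree, node) {
  if (is.na(tree$crown_root)) return(rep(FALSE, length(node)))
  crown <- bt_descendants(tree, tree$crown_root)
  node %in% crown
}

## ---------------------------------------------------------------------------
## Variant panel
## ---------------------------------------------------------------------------

#' Parse a haplotype-determining variant panel
#'
#' The panel lists the key variants of the genotyping backbone: marker id,
#' marker class (SNP, indel or microsatellite), ancestral allele, derived
#' allele set and the backbone edge (named by its child node) that the derived
#' allele defines. Multi-allelic derived sets (the microsatellite case) are
#' written `"a|b"`.
#'
#' @param x path to a CSV with header `id,marker_class,ancestral,derived,edge`,
#'   or a `data.frame` with those columns.
#' @return a `data.frame` with columns `id`, `marker_class`, `ancestral`,
#'   `derived` (`"|"`-joined set) and `edge` (`NA` when unplaced), plus a
#'   logical `placed` column. Unplaced variants trigger a warning.
#' @export
parse_variant_panel <- function(x) {
  tab <- if (is.character(x)) {
    utils::read.csv(x, colClasses = "character")
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  required <- c("id", "marker_class", "ancestral", "derived", "edge")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("panel missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("empty variant panel", call. = FALSE)
    out <- tab[required]
    out$placed <- logical(0)
    return(out)
  }
  tab <- tab[required]
  for (cc in required) tab[[cc]] <- as.character(tab[[cc]])
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup)) {
    stop("duplicate variant id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(tab$marker_class),
                       c("SNP", "indel", "microsatellite"))
  if (length(bad_class)) {
    stop("unknown marker_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  derived_sets <- strsplit(tab$derived, "|", fixed = TRUE)
  if (any(lengths(derived_sets) == 0L)) {
    stop("every variant needs a non-empty derived allele set", call. = FALSE)
  }
  clash <- mapply(function(a, d) a %in% d, tab$ancestral, derived_sets)
  if (any(clash)) {
    stop("ancestral allele inside derived set for: ",
         paste(tab$id[clash], collapse = ", "), call. = FALSE)
  }
  tab$edge[!nzchar(tab$edge)] <- NA_character_
  tab$placed <- !is.na(tab$edge)
  if (any(!tab$placed)) {
    warning("unplaced variant(s): ", paste(tab$id[!tab$placed], collapse = ", "),
            call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

## ---------------------------------------------------------------------------
## Newick import/export
## ---------------------------------------------------------------------------

#' Parse a labelled Newick backbone and attach its variant panel
#'
#' Internal node labels are mandatory (samples are allocated to branching
#' points, so every node must be addressable). Branch lengths are accepted and
#' stored but play no role in calling. Placed panel variants are attached to
#' the edge above the node their `edge` column names.
#'
#' @param newick Newick string or path to a Newick file.
#' @param panel variant panel (`data.frame` from [parse_variant_panel()]), or
#'   `NULL` for a bare topology.
#' @param crown_root optional Crown root node name.
#' @return a `backbone_tree`. Panel variants referencing no tree node raise an
#'   error; placed variants not referenced by the tree are impossible by
#'   construction (each names its edge), but unplaced ones are kept in the
#'   panel and reported by [validate_backbone()].
#' @export
parse_backbone <- function(newick, panel = NULL, crown_root = NA_character_) {
  txt <- newick
  if (length(txt) == 1L && !grepl(";", txt, fixed = TRUE) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: empty tree", call. = FALSE)
  if (is.null(phy$node.label) || any(!nzchar(phy$node.label)) ||
      anyNA(phy$node.label)) {
    stop("all internal nodes must be labelled", call. = FALSE)
  }
  labels <- c(phy$tip.label, phy$node.label)
  dup <- unique(labels[duplicated(labels)])
  if (length(dup)) {
    stop("duplicate node label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  parent <- stats::setNames(rep(NA_character_, length(labels)), labels)
  children <- stats::setNames(vector("list", length(labels)), labels)
  for (nd in labels) children[[nd]] <- character(0)
  for (i in seq_len(nrow(phy$edge))) {
    p <- labels[phy$edge[i, 1L]]
    ch <- labels[phy$edge[i, 2L]]
    parent[[ch]] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  edge_length <- NULL
  if (!is.null(phy$edge.length)) {
    edge_length <- stats::setNames(phy$edge.length, labels[phy$edge[, 2L]])
  }
  ev <- stats::setNames(rep(list(character(0)), length(labels)), labels)
  if (!is.null(panel) && nrow(panel)) {
    placed <- panel[panel$placed, , drop = FALSE]
    missing_edge <- setdiff(unique(placed$edge), labels)
    if (length(missing_edge)) {
      stop("panel variant(s) reference missing node(s): ",
           paste(missing_edge, collapse = ", "), call. = FALSE)
    }
    root <- labels[is.na(parent)]
    if (any(placed$edge == root)) {
      stop("variants cannot be placed on the root: ",
           paste(placed$id[placed$edge == root], collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(nrow(placed))) {
      nd <- placed$edge[i]
      ev[[nd]] <- c(ev[[nd]], placed$id[i])
    }
  }
  backbone_tree(parent, children, ev, panel = panel,
                crown_root = crown_root, edge_length = edge_length)
}

#' Serialize a backbone tree to Newick
#'
#' Internal labels are always written; branch lengths only when stored and
#' `branch_lengths = TRUE`. Labels containing Newick metacharacters are
#' single-quoted.
#'
#' @param tree a `backbone_tree`.
#' @param branch_lengths write stored edge lengths?
#' @return a single Newick string terminated by `";"`.
#' @export
serialize_backbone <- function(tree, branch_lengths = FALSE) {
  quote_label <- function(x) {
    if (grepl("[\\s(),:;'\\[\\]]", x, perl = TRUE)) {
      paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
    } else x
  }
  bl <- function(nd) {
    if (branch_lengths && !is.null(tree$edge_length) &&
        !is.na(tree$edge_length[nd])) {
      sprintf(":%.10g", unname(tree$edge_length[nd]))
    } else ""
  }
  rec <- function(nd) {
    kids <- tree$children[[nd]]
    if (!length(kids)) return(paste0(quote_label(nd), bl(nd)))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
           quote_label(nd), bl(nd))
  }
  paste0(rec(tree$root), ";")
}

## ---------------------------------------------------------------------------
## Perfect phylogeny from a binary matrix
## ---------------------------------------------------------------------------

# Pairs of distinct columns violating rooted compatibility: with 0 the known
# ancestral state the all-zero root haplotype is implicit, so two columns are
# incompatible iff gametes 01, 10 and 11 all occur among the samples.
incompatible_pairs <- function(M) {
  m <- ncol(M)
  if (m < 2L) return(matrix(integer(0), ncol = 2L))
  ov <- crossprod(M)            # |i & j|
  cnt <- diag(ov)
  bad <- which(ov > 0 & ov < matrix(cnt, m, m) &
                 ov < matrix(cnt, m, m, byrow = TRUE), arr.ind = TRUE)
  bad[bad[, 1L] < bad[, 2L], , drop = FALSE]
}

#' Build a haplotype tree from a binary sample-by-variant matrix
#'
#' Constructs the (unique up to junctions) rooted perfect phylogeny implied by
#' a complete 0/1 genotype matrix under infinite sites: every variant labels
#' exactly one edge and every sample's derived-variant set equals the variants
#' on its root-to-leaf path. Variants with identical presence columns collapse
#' onto one edge. Internal nodes are synthesized as `"N<k>"` in deterministic
#' preorder; leaves keep the sample names.
#'
#' Incompatible variant pairs (both derived states observed together and
#' apart) abort with an error listing the offending pairs, unless
#' `drop_recurrent = TRUE`, in which case columns are removed greedily (the
#' column in the most conflicts first, ties broken lexicographically by
#' variant id) and reported via the `"dropped_variants"` attribute and a
#' warning.
#'
#' @param M numeric/integer matrix with entries 0/1, rownames = sample ids,
#'   colnames = variant ids; no missing values.
#' @param drop_recurrent drop conflicting columns instead of failing?
#' @return a `backbone_tree` whose tips are the samples; attribute
#'   `"dropped_variants"` lists removed column ids (empty if none).
#' @export
build_tree_from_matrix <- function(M, drop_recurrent = FALSE) {
  M <- as.matrix(M)
  if (anyNA(M) || !all(M %in% c(0, 1))) {
    stop("matrix entries must be 0/1 with no missing values", call. = FALSE)
  }
  if (is.null(rownames(M))) rownames(M) <- paste0("s", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("v", seq_len(ncol(M)))
  storage.mode(M) <- "integer"

  # collapse identical columns; keys are the presence patterns
  keys <- apply(M, 2L, paste, collapse = "")
  groups <- split(colnames(M), keys)
  # drop all-zero columns (uninformative, belong to no edge)
  zero_key <- paste(rep.int(0L, nrow(M)), collapse = "")
  uninformative <- groups[[zero_key]]
  groups[[zero_key]] <- NULL
  rep_ids <- vapply(groups, function(g) sort(g)[1L], character(1))
  D <- M[, rep_ids, drop = FALSE]    # one column per distinct pattern

  dropped <- character(0)
  repeat {
    bad <- incompatible_pairs(D)
    if (!nrow(bad)) break
    if (!drop_recurrent) {
      pairs <- apply(bad, 1L, function(ij) {
        paste(sort(c(colnames(D)[ij[1L]], colnames(D)[ij[2L]])),
              collapse = " ~ ")
      })
      stop("incompatible variant pair(s): ", paste(unique(pairs), collapse = "; "),
           call. = FALSE)
    }
    conflicts <- tabulate(c(bad[, 1L], bad[, 2L]), nbins = ncol(D))
    worst <- which(conflicts == max(conflicts))
    worst <- worst[order(colnames(D)[worst])][1L]
    key_worst <- paste(D[, worst], collapse = "")
    dropped <- c(dropped, groups[[key_worst]])
    groups[[key_worst]] <- NULL
    D <- D[, -worst, drop = FALSE]
  }
  if (length(dropped)) {
    warning("dropped recurrent/conflicting variant column(s): ",
            paste(sort(dropped), collapse = ", "), call. = FALSE)
  }

  samples <- rownames(M)
  n <- nrow(M)
  m <- ncol(D)
  sizes <- colSums(D)
  # clusters sorted by decreasing size, ties by representative variant id
  ord <- order(-sizes, colnames(D))
  D <- D[, ord, drop = FALSE]
  sizes <- sizes[ord]

  parent <- c(stats::setNames(NA_character_, ".root"))
  children <- list(".root" = character(0))
  ev <- list(".root" = character(0))
  cluster_node <- character(m)          # node owning each cluster
  cluster_sets <- lapply(seq_len(m), function(j) which(D[, j] == 1L))

  node_id <- 0L
  for (j in seq_len(m)) {
    node_id <- node_id + 1L
    nm <- paste0(".c", node_id)
    # parent = smallest previously placed cluster strictly containing this one
    par <- ".root"
    best <- n + 1L
    set_j <- cluster_sets[[j]]
    if (j > 1L) {
      for (k in seq_len(j - 1L)) {
        if (sizes[k] > sizes[j] && sizes[k] < best &&
            all(set_j %in% cluster_sets[[k]])) {
          par <- cluster_node[k]
          best <- sizes[k]
        }
      }
    }
    cluster_node[j] <- nm
    parent[nm] <- par
    children[[par]] <- c(children[[par]], nm)
    children[[nm]] <- character(0)
    key_j <- paste(D[, j], collapse = "")
    ev[[nm]] <- sort(groups[[key_j]])
  }

  # attach each sample as a leaf under its smallest containing cluster
  for (i in seq_len(n)) {
    host <- ".root"
    best <- n + 1L
    for (j in seq_len(m)) {
      if (D[i, j] == 1L && sizes[j] < best) {
        host <- cluster_node[j]
        best <- sizes[j]
      }
    }
    s <- samples[i]
    parent[s] <- host
    children[[host]] <- c(children[[host]], s)
    children[[s]] <- character(0)
    ev[[s]] <- character(0)
  }

  # order children deterministically: internal clusters first (by size desc,
  # then name), then sample leaves alphabetically
  internal_set <- c(".root", cluster_node)
  csize <- stats::setNames(c(n, sizes), internal_set)
  for (nd in internal_set) {
    kids <- children[[nd]]
    ints <- kids[kids %in% internal_set]
    lvs <- sort(setdiff(kids, ints))
    ints <- ints[order(-csize[ints], ints)]
    children[[nd]] <- c(ints, lvs)
  }

  # rename internal nodes N<k> in deterministic preorder
  pre <- character(0)
  stack <- ".root"
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    pre <- c(pre, cur)
    stack <- c(children[[cur]], stack)
  }
  pre_int <- pre[pre %in% internal_set]
  new_names <- stats::setNames(paste0("N", seq_along(pre_int) - 1L), pre_int)
  new_names[".root"] <- "N0"
  rename <- function(x) {
    i <- x %in% names(new_names)
    x[i] <- new_names[x[i]]
    x
  }
  all_nodes <- names(parent)
  parent2 <- stats::setNames(rename(unname(parent)), rename(all_nodes))
  children2 <- stats::setNames(lapply(children, rename), rename(names(children)))
  ev2 <- stats::setNames(ev, rename(names(ev)))

  # panel for the variants actually placed
  edge_of <- stats::setNames(rep(NA_character_, ncol(M)), colnames(M))
  for (nd in names(ev2)) for (v in ev2[[nd]]) edge_of[v] <- nd
  panel <- data.frame(
    id = colnames(M), marker_class = "SNP",
    ancestral = "0", derived = "1",
    edge = unname(edge_of[colnames(M)]),
    placed = !is.na(edge_of[colnames(M)]),
    stringsAsFactors = FALSE
  )
  panel <- panel[!panel$id %in% dropped, , drop = FALSE]
  rownames(panel) <- NULL

  out <- backbone_tree(parent2, children2, ev2, panel = panel)
  attr(out, "dropped_variants") <- sort(dropped)
  attr(out, "uninformative_variants") <-
    sort(if (is.null(uninformative)) character(0) else uninformative)
  out
}

## ---------------------------------------------------------------------------
## sHG condensation
## ---------------------------------------------------------------------------

#' Condense haplotypes into sub-haplogroups (sHGs)
#'
#' sHGs are whole subtrees of the backbone used as coarse reporting units.
#' Each sHG is named by its subtree root; all terminal HTs inside the subtree
#' map to its label.
#'
#' @param tree a `backbone_tree`.
#' @param shg_table `data.frame` with columns `node` (subtree root in the
#'   tree) and `shg` (label); or a named character vector `node -> shg`.
#' @return list with `map` (named character, terminal HT -> sHG label),
#'   `n_shg` (distinct labels used) and `unassigned` (terminal HTs under no
#'   sHG root).
#' @export
condense_shg <- function(tree, shg_table) {
  if (!is.data.frame(shg_table)) {
    shg_table <- data.frame(node = names(shg_table),
                            shg = unname(shg_table),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("node", "shg") %in% names(shg_table)))
  missing_nodes <- setdiff(shg_table$node, bt_nodes(tree))
  if (length(missing_nodes)) {
    stop("sHG root(s) not in tree: ", paste(missing_nodes, collapse = ", "),
         call. = FALSE)
  }
  # nesting check: no sHG root may be an ancestor of another
  desc <- lapply(shg_table$node, bt_descendants, tree = tree)
  for (i in seq_along(desc)) {
    nested <- shg_table$node[-i][shg_table$node[-i] %in% desc[[i]]]
    if (length(nested)) {
      stop(sprintf("sHG root '%s' contains other sHG root(s): %s",
                   shg_table$node[i], paste(nested, collapse = ", ")),
           call. = FALSE)
    }
  }
  map <- character(0)
  for (i in seq_along(desc)) {
    tips <- intersect(desc[[i]], bt_tips(tree))
    map[tips] <- shg_table$shg[i]
  }
  unassigned <- setdiff(bt_tips(tree), names(map))
  list(map = map, n_shg = length(unique(shg_table$shg)),
       unassigned = unassigned)
}

## ---------------------------------------------------------------------------
## Structural validation report
## ---------------------------------------------------------------------------

#' Structural report on a backbone tree
#'
#' Counts terminal and inner nodes inside and outside the Crown subtree,
#' lists unplaced panel variants and junction nodes (non-root internal or
#' terminal nodes whose edge carries no defining variant).
#'
#' @param tree a `backbone_tree`.
#' @param file optional path; when given the report is also written as JSON.
#' @return a list report (class `backbone_report`).
#' @export
validate_backbone <- function(tree, file = NULL) {
  tips <- bt_tips(tree)
  inner <- setdiff(bt_internal(tree), tree$root)
  crown_nodes <- if (is.na(tree$crown_root)) character(0) else
    bt_descendants(tree, tree$crown_root)
  non_root <- setdiff(bt_nodes(tree), tree$root)
  junction <- non_root[lengths(tree$edge_variants[non_root]) == 0L]
  unplaced <- character(0)
  if (!is.null(tree$panel) && nrow(tree$panel)) {
    unplaced <- tree$panel$id[!tree$panel$placed]
  }
  report <- list(
    n_nodes = length(bt_nodes(tree)),
    crown_root = tree$crown_root,
    crown_terminal = sum(tips %in% crown_nodes),
    crown_inner = sum(inner %in% crown_nodes),
    noncrown_terminal = sum(!tips %in% crown_nodes),
    noncrown_inner = sum(!inner %in% crown_nodes),
    junction_nodes = junction,
    unplaced_variants = unplaced
  )
  class(report) <- "backbone_report"
  if (!is.null(file)) {
    jsonlite::write_json(unclass(report), file, auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  report
}

#' @export
print.backbone_report <- function(x, ...) {
  cat("backbone report\n")
  cat(sprintf("  Crown:     %d terminal, %d inner\n",
              x$crown_terminal, x$crown_inner))
  cat(sprintf("  non-Crown: %d terminal, %d inner (root excluded)\n",
              x$noncrown_terminal, x$noncrown_inner))
  if (length(x$junction_nodes)) {
    cat("  junction nodes:", paste(x$junction_nodes, collapse = ", "), "\n")
  }
  if (length(x$unplaced_variants)) {
    cat("  unplaced variants:", paste(x$unplaced_variants, collapse = ", "), "\n")
  }
  invisible(x)
}
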