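# Shared fixtures and independent oracles (all built in code, no stored data).

# Toy Crown-style backbone: root -> {daC (Crown), NC}; Crown splits into an
# Arabian-like path (Ao -> aA1a) and a T-like clade (T1 -> {T1a, T1b}).
toy_panel <- function() {
  parse_variant_panel(data.frame(
    id = c("rAX", "rW", "rY", "vT", "vT1a", "vT1b", "vNC"),
    marker_class = "SNP", ancestral = "A", derived = "G",
    edge = c("daC", "Ao", "aA1a", "T1", "T1a", "T1b", "NC"),
    stringsAsFactors = FALSE))
}

toy_tree <- function() {
  parse_backbone("(((aA1a)Ao,(T1a,T1b)T1)daC,(NCx)NC)root;",
                 toy_panel(), crown_root = "daC")
}

# NB: NCx hangs under NC on a junction edge (no defining variant).

# ---- independent oracles ---------------------------------------------------

# Rooted-compatibility scan: with 0 the known ancestral state, a variant pair
# is tree-incompatible iff the gametes 01, 10 and 11 all occur. O(m^2)
# exhaustive, written without reference to the builder's internals.
oracle_incompatible_pairs <- function(M) {
  m <- ncol(M)
  out <- list()
  if (m < 2) return(out)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- M[, i]; b <- M[, j]
      if (any(a == 0 & b == 1) && any(a == 1 & b == 0) &&
          any(a == 1 & b == 1)) {
        out[[length(out) + 1L]] <- c(colnames(M)[i], colnames(M)[j])
      }
    }
  }
  out
}

# Haplotype diversity by exhaustive pair counting: probability that two
# samples drawn without replacement differ.
oracle_hd_pairs <- function(labels) {
  n <- length(labels)
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) if (labels[i] == labels[j]) same <- same + 1L
  }
  1 - same / choose(n, 2)
}

# Rho by the top-down route: mean root-to-tip variant count of the clade's
# tips minus the root-to-node count (the package computes it bottom-up).
oracle_rho_topdown <- function(tree, node) {
  tips <- bt_subtree_tips(tree, node)
  tips <- setdiff(tips, node)
  if (!length(tips)) return(0)
  root_to_tip <- vapply(tips, function(s) length(bt_path_variants(tree, s)),
                        numeric(1))
  mean(root_to_tip) - length(bt_path_variants(tree, node))
}

# Random 0/1 matrix (frequently incompatible).
random_matrix <- function(n, m, p = 0.4) {
  M <- matrix(rbinom(n * m, 1L, p), nrow = n,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("v", sprintf("%02d", seq_len(m)))))
  M
}

# Compatible matrix via the generator (infinite sites => always compatible).
compatible_matrix <- function(n_tips, seed, model = "kingman") {
  p <- sim_params(n_tips = n_tips, tree_model = model, tmrca_years = 1500,
                  mu = 1.69e-9, L = 4e6, seed = seed)
  tree <- simulate_genealogy(p)
  tree <- drop_mutations(tree, p$mu, p$L, seed = seed + 1L)
  list(tree = tree, M = genotype_matrix(tree))
}

# Is `anc` an ancestor-or-self of `node`?
is_ancestor_or_self <- function(tree, anc, node) anc %in% bt_path(tree, node)

# Breadth-first (prior-blind) test plan used as the baseline strategy.
bf_plan <- function(tree, node) {
  out <- character(0)
  queue <- tree$children[[node]]
  while (length(queue)) {
    nd <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, sort(tree$edge_variants[[nd]]))
    queue <- c(queue, tree$children[[nd]])
  }
  out
}

# Sequential assay simulation: test variants one at a time following a
# strategy until the sample's haplotype is pinned down; returns assay count.
simulate_assays <- function(tree, truth_node, strategy = c("greedy", "bf"),
                            prior = NULL) {
  strategy <- match.arg(strategy)
  truth_path <- bt_path_variants(tree, truth_node)
  calls <- stats::setNames(integer(0), character(0))
  n_assays <- 0L
  repeat {
    node <- if (length(calls)) {
      suppressWarnings(call_haplotype(calls, tree))$node
    } else tree$root
    plan <- if (strategy == "greedy") {
      plan_tests(tree, calls, prior = prior)$plan
    } else {
      setdiff(bf_plan(tree, node), names(calls))
    }
    if (!length(plan)) break
    v <- plan[[1L]]
    calls[v] <- as.integer(v %in% truth_path)
    n_assays <- n_assays + 1L
    a <- suppressWarnings(call_haplotype(calls, tree))
    if (a$status == "terminal" && a$node == truth_node) break
    if (a$status == "inner_confirmed" && a$node == truth_node) break
  }
  n_assays
}
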