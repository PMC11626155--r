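## ---------------------------------------------------------------------------
## Synthetic genealogies with known truth
## ---------------------------------------------------------------------------

#' Simulation parameters
#'
#' Defines the study conditions the generator emulates: a paternal genealogy
#' with a Crown-like recent expansion (default TMRCA 1,500 years and a
#' star-burst coalescent profile), Poisson infinite-sites mutations at the
#' horse MSY rate, breed groups with line-breeding frequency skew, and
#' partial successive genotyping with missingness.
#'
#' @param n_tips number of sampled male lineages (tree tips).
#' @param tree_model `"star_burst"` (all coalescences compressed near the
#'   root, the Crown expansion profile), `"kingman"` (constant-size
#'   coalescent) or `"yule"` (pure-birth).
#' @param tmrca_years root age in years (default 1500).
#' @param mu substitution rate per site per year (default 1.69e-9, the horse
#'   MSY rate).
#' @param L effective callable length in sites (default 5e6, a synthetic
#'   stand-in: real callable lengths are assay-specific).
#' @param n_breeds number of breed groups.
#' @param line_breeding_alpha Dirichlet concentration of per-breed clade
#'   weights; small values concentrate each breed on few patrilines (line
#'   breeding), large values approach panmixia.
#' @param missing_rate i.i.d. probability an entry is left untested.
#' @param genotyping_error_rate probability a tested entry is flipped.
#' @param seed mandatory integer seed; the whole bundle is a pure function of
#'   these parameters.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_tips = 100L, tree_model = "star_burst",
                       tmrca_years = 1500, mu = 1.69e-9, L = 5e6,
                       n_breeds = 5L, line_breeding_alpha = 0.3,
                       missing_rate = 0.3, genotyping_error_rate = 0,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  tree_model <- match.arg(tree_model, c("star_burst", "kingman", "yule"))
  stopifnot(n_tips >= 2L, tmrca_years > 0, mu > 0, L > 0, n_breeds >= 1L,
            line_breeding_alpha > 0,
            missing_rate >= 0, missing_rate < 1,
            genotyping_error_rate >= 0, genotyping_error_rate < 1)
  structure(list(n_tips = as.integer(n_tips), tree_model = tree_model,
                 tmrca_years = tmrca_years, mu = mu, L = L,
                 n_breeds = as.integer(n_breeds),
                 line_breeding_alpha = line_breeding_alpha,
                 missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Convert an ape phylo (rooted, binary) to a backbone_tree; internal nodes
# are named N0, N1, ... in deterministic preorder, tips keep their labels.
ape_to_backbone <- function(phy) {
  ntip <- length(phy$tip.label)
  labels <- c(phy$tip.label, paste0(".i", seq_len(phy$Nnode)))
  parent <- stats::setNames(rep(NA_character_, length(labels)), labels)
  children <- stats::setNames(rep(list(character(0)), length(labels)), labels)
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
  # deterministic preorder renaming of internals
  root <- labels[is.na(parent)]
  pre <- character(0)
  stack <- root
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    pre <- c(pre, cur)
    stack <- c(children[[cur]], stack)
  }
  ints <- pre[startsWith(pre, ".i")]
  new <- stats::setNames(paste0("N", seq_along(ints) - 1L), ints)
  ren <- function(x) {
    i <- x %in% names(new)
    x[i] <- new[x[i]]
    x
  }
  parent2 <- stats::setNames(ren(unname(parent)), ren(labels))
  children2 <- stats::setNames(lapply(children, ren), ren(names(children)))
  el2 <- if (!is.null(edge_length)) {
    stats::setNames(unname(edge_length), ren(names(edge_length)))
  } else NULL
  backbone_tree(parent2, children2, edge_length = el2)
}

# Node ages (years above the tips) for an ultrametric backbone tree.
bt_node_ages <- function(tree) {
  ages <- stats::setNames(numeric(length(bt_nodes(tree))), bt_nodes(tree))
  # depth from root, then age = max_depth - depth
  depth <- stats::setNames(numeric(length(bt_nodes(tree))), bt_nodes(tree))
  for (nd in bt_preorder(tree)) {
    if (is.na(tree$parent[[nd]])) next
    depth[nd] <- depth[tree$parent[[nd]]] + tree$edge_length[nd]
  }
  max_d <- max(depth[bt_tips(tree)])
  max_d - depth
}

#' Simulate a rooted genealogy
#'
#' Produces a rooted binary ultrametric tree with root age exactly
#' `tmrca_years`. `"kingman"` draws a standard coalescent topology,
#' `"yule"` a pure-birth tree (both rescaled to the target depth);
#' `"star_burst"` keeps a coalescent topology but compresses every
#' coalescence into the oldest 5% of the time depth, mimicking a rapid
#' founder expansion in which tip lineages are nearly independent.
#'
#' @param p a `sim_params` (only `n_tips`, `tree_model`, `tmrca_years`,
#'   `seed` are used).
#' @return a `backbone_tree` with `edge_length` in years; tips are named
#'   `t1..tn`, internal nodes `N0..` in preorder.
#' @export
simulate_genealogy <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  n <- p$n_tips
  phy <- switch(p$tree_model,
    kingman = ape::rcoal(n, tip.label = paste0("t", seq_len(n))),
    star_burst = ape::rcoal(n, tip.label = paste0("t", seq_len(n))),
    yule = {
      ph <- ape::rphylo(n, birth = 1, death = 0)
      ph$tip.label <- paste0("t", seq_len(n))
      ph
    })
  tree <- ape_to_backbone(phy)
  ages <- bt_node_ages(tree)
  if (p$tree_model == "star_burst") {
    ints <- setdiff(bt_nodes(tree), bt_tips(tree))
    r <- rank(ages[ints], ties.method = "first")
    ages[ints] <- p$tmrca_years * (0.95 + 0.05 * r / length(ints))
    ages[bt_tips(tree)] <- 0
  } else {
    root_age <- ages[[tree$root]]
    ages <- ages * (p$tmrca_years / root_age)
  }
  el <- tree$edge_length
  for (nd in setdiff(bt_nodes(tree), tree$root)) {
    el[nd] <- ages[[tree$parent[[nd]]]] - ages[[nd]]
  }
  tree$edge_length <- el
  tree
}

#' Drop Poisson infinite-sites mutations on a genealogy
#'
#' Each edge receives `Poisson(mu * L * t_edge)` fresh variants (ids
#' `"v<edge>_<k>"`), placed on that edge; the variant panel is rebuilt with
#' abstract 0/1 allele coding. Under infinite sites every variant arises
#' once, so the resulting genotype matrix is always perfect-phylogeny
#' compatible.
#'
#' @param tree a `backbone_tree` with `edge_length` in years.
#' @param mu substitution rate per site per year.
#' @param L callable length in sites.
#' @param seed integer seed.
#' @return the tree with `edge_variants` and `panel` filled.
#' @export
drop_mutations <- function(tree, mu, L, seed) {
  set.seed(seed)
  nodes <- setdiff(bt_preorder(tree), tree$root)
  t_edge <- vapply(nodes, function(nd) tree$edge_length[[nd]], numeric(1))
  k <- stats::rpois(length(nodes), mu * L * t_edge)
  ev <- tree$edge_variants
  rows <- list()
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    if (k[i] > 0L) {
      ids <- sprintf("v%s_%d", nd, seq_len(k[i]))
      ev[[nd]] <- ids
      rows[[nd]] <- data.frame(id = ids, marker_class = "SNP",
                               ancestral = "0", derived = "1", edge = nd,
                               placed = TRUE, stringsAsFactors = FALSE)
    } else {
      ev[[nd]] <- character(0)
    }
  }
  panel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), marker_class = character(0),
               ancestral = character(0), derived = character(0),
               edge = character(0), placed = logical(0),
               stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  tree$edge_variants <- ev
  tree$panel <- panel
  tree
}

#' Complete genotype matrix of a mutated genealogy
#'
#' @param tree a `backbone_tree` whose edges carry variants.
#' @return integer 0/1 matrix, tips x panel variants (panel order); a tip is
#'   derived exactly for the variants on its root path.
#' @export
genotype_matrix <- function(tree) {
  tips <- bt_tips(tree)
  ids <- tree$panel$id
  M <- matrix(0L, nrow = length(tips), ncol = length(ids),
              dimnames = list(tips, ids))
  for (s in tips) M[s, bt_path_variants(tree, s)] <- 1L
  M
}

#' True (identifiable) generating node of each tip
#'
#' Under partial mutation input a tip whose terminal edges carry no variant
#' is genotypically indistinguishable from its ancestor: the identifiable
#' truth is the deepest ancestor-or-self of the tip reached through
#' variant-carrying edges only. A fully genotyped, error-free caller recovers
#' exactly this node.
#'
#' @param tree a `backbone_tree` with edge variants.
#' @return named character vector, tip -> true node.
#' @export
true_nodes <- function(tree) {
  tips <- bt_tips(tree)
  vapply(tips, function(s) {
    cur <- s
    while (!is.na(tree$parent[[cur]]) &&
           length(tree$edge_variants[[cur]]) == 0L) {
      cur <- tree$parent[[cur]]
    }
    cur
  }, character(1))
}

#' Allocate tips to breeds with line-breeding skew
#'
#' Each breed draws Dirichlet(`alpha`) weights over the root-child clades
#' (the deep patrilines); each tip then joins a breed with probability
#' proportional to that breed's weight on the tip's clade. Small `alpha`
#' concentrates every breed on few patrilines (line breeding: skewed spectra,
#' low within-breed diversity); large `alpha` approaches random allocation.
#'
#' @param tree a `backbone_tree`.
#' @param n_breeds number of breeds.
#' @param alpha Dirichlet concentration.
#' @param seed integer seed.
#' @return list: `grouping` (tip -> breed), `clade_of` (tip -> root-child
#'   clade), `weights` (breed x clade Dirichlet draws), `spectra` (breed x
#'   clade tip counts).
#' @export
assign_breeds <- function(tree, n_breeds, alpha, seed) {
  set.seed(seed)
  clades <- tree$children[[tree$root]]
  clade_of <- stats::setNames(rep(NA_character_, length(bt_tips(tree))),
                              bt_tips(tree))
  for (cl in clades) {
    clade_of[bt_subtree_tips(tree, cl)] <- cl
  }
  K <- length(clades)
  W <- matrix(stats::rgamma(n_breeds * K, shape = alpha), nrow = n_breeds,
              dimnames = list(sprintf("breed%02d", seq_len(n_breeds)), clades))
  zero <- rowSums(W) == 0          # numeric underflow guard at tiny alpha
  W[zero, ] <- W[zero, , drop = FALSE] + 1e-300
  for (b in seq_len(n_breeds)) {
    if (sum(W[b, ]) == 0) W[b, sample.int(K, 1L)] <- 1
    W[b, ] <- W[b, ] / sum(W[b, ])
  }
  tips <- bt_tips(tree)
  breeds <- vapply(tips, function(s) {
    p <- W[, clade_of[[s]]]
    if (sum(p) == 0) p <- rep(1, n_breeds)
    rownames(W)[sample.int(n_breeds, 1L, prob = p)]
  }, character(1))
  spectra <- table(factor(breeds, levels = rownames(W)),
                   factor(clade_of[tips], levels = clades))
  list(grouping = breeds, clade_of = clade_of, weights = W,
       spectra = unclass(spectra))
}

#' Mask a complete genotype matrix
#'
#' Entries are hidden i.i.d. with `missing_rate`; surviving entries are
#' flipped with `error_rate` (the generator's stand-in for assay error and
#' recurrent mutation). Positions changed are recorded in attributes
#' `"masked"` and `"flipped"`.
#'
#' @param M complete 0/1 matrix.
#' @param missing_rate,error_rate rates in `[0, 1)`.
#' @param seed integer seed.
#' @return matrix with `NA` at masked positions.
#' @export
mask_panel <- function(M, missing_rate, error_rate, seed) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1)
  set.seed(seed)
  out <- M
  mask <- matrix(stats::runif(length(M)) < missing_rate, nrow = nrow(M))
  out[mask] <- NA_integer_
  flip <- matrix(stats::runif(length(M)) < error_rate, nrow = nrow(M)) & !mask
  out[flip] <- 1L - out[flip]
  attr(out, "masked") <- which(mask)
  attr(out, "flipped") <- which(flip)
  out
}

#' Simulate a full truth bundle
#'
#' Runs genealogy simulation, mutation dropping, breed allocation and panel
#' masking with per-stage sub-seeds derived from `p$seed`, and optionally
#' writes the bundle as plain-text files (`tree.nwk`, `panel.csv`,
#' `genotypes_complete.csv`, `genotypes_masked.csv`, `breeds.tsv`,
#' `truth.json`, `params.yaml`).
#'
#' @param p a `sim_params`.
#' @param dir optional output directory (created if needed).
#' @return list of class `truth_bundle`: `params`, `tree`, `panel`,
#'   `complete`, `masked`, `grouping`, `clade_of`, `spectra`, `true_node`,
#'   and `files` (written paths, when `dir` given).
#' @export
simulate_bundle <- function(p, dir = NULL) {
  stopifnot(inherits(p, "sim_params"))
  tree <- simulate_genealogy(p)
  tree <- drop_mutations(tree, p$mu, p$L, seed = p$seed + 1L)
  complete <- genotype_matrix(tree)
  br <- assign_breeds(tree, p$n_breeds, p$line_breeding_alpha,
                      seed = p$seed + 2L)
  masked <- mask_panel(complete, p$missing_rate, p$genotyping_error_rate,
                       seed = p$seed + 3L)
  bundle <- structure(
    list(params = p, tree = tree, panel = tree$panel, complete = complete,
         masked = masked, grouping = br$grouping, clade_of = br$clade_of,
         spectra = br$spectra, true_node = true_nodes(tree), files = NULL),
    class = "truth_bundle")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(dir, x)
    writeLines(serialize_backbone(tree, branch_lengths = TRUE), f("tree.nwk"))
    utils::write.csv(tree$panel[, c("id", "marker_class", "ancestral",
                                    "derived", "edge")],
                     f("panel.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(complete), f("genotypes_complete.csv"))
    utils::write.csv(as.data.frame(masked), f("genotypes_masked.csv"))
    utils::write.table(
      data.frame(sample = names(br$grouping), breed = unname(br$grouping)),
      f("breeds.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(true_node = as.list(true_nodes(tree)),
           clade_of = as.list(br$clade_of)),
      f("truth.json"), auto_unbox = TRUE)
    yaml::write_yaml(unclass(p), f("params.yaml"))
    bundle$files <- vapply(c("tree.nwk", "panel.csv",
                             "genotypes_complete.csv",
                             "genotypes_masked.csv", "breeds.tsv",
                             "truth.json", "params.yaml"), f, character(1))
  }
  bundle
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf(
    "truth_bundle: %d tips, %d variants, %d breeds (model %s, TMRCA %g y)\n",
    x$params$n_tips, nrow(x$panel), x$params$n_breeds, x$params$tree_model,
    x$params$tmrca_years))
  invisible(x)
}
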