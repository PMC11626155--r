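test_that("variant panel parsing validates ids, states and placement", {
  p <- toy_panel()
  expect_equal(nrow(p), 7L)
  expect_true(all(p$placed))
  expect_equal(p$edge[p$id == "rAX"], "daC")

  expect_warning(out <- parse_variant_panel(
    data.frame(id = character(0), marker_class = character(0),
               ancestral = character(0), derived = character(0),
               edge = character(0))), "empty")
  expect_equal(nrow(out), 0L)

  dup <- data.frame(id = c("rW", "rW"), marker_class = "SNP",
                    ancestral = "A", derived = "G", edge = c("x", "y"))
  expect_error(parse_variant_panel(dup), "rW")

  bad <- data.frame(id = "q1", marker_class = "SNP",
                    ancestral = "A", derived = "G|A", edge = "x")
  expect_error(parse_variant_panel(bad), "ancestral")

  # microsatellites may have multi-allele derived sets
  ms <- parse_variant_panel(data.frame(
    id = "fBVB", marker_class = "microsatellite",
    ancestral = "14", derived = "15|16", edge = "x"))
  expect_equal(ms$derived, "15|16")

  expect_warning(up <- parse_variant_panel(
    data.frame(id = "vU", marker_class = "SNP", ancestral = "A",
               derived = "G", edge = "")), "unplaced")
  expect_false(up$placed)
})

test_that("labelled Newick parses into the expected structure", {
  tree <- toy_tree()
  expect_equal(tree$root, "root")
  expect_setequal(bt_tips(tree), c("aA1a", "T1a", "T1b", "NCx"))
  expect_equal(tree$parent[["T1a"]], "T1")
  expect_equal(tree$edge_variants[["daC"]], "rAX")
  expect_equal(bt_path(tree, "T1b"), c("root", "daC", "T1", "T1b"))
  expect_setequal(bt_path_variants(tree, "T1b"), c("rAX", "vT", "vT1b"))

  expect_error(parse_backbone("((A,B),(C)D)root;", NULL), "labelled")
  expect_error(parse_backbone("((A1)A,(A2)A)root;", NULL), "duplicate")
  bad_panel <- parse_variant_panel(data.frame(
    id = "vz", marker_class = "SNP", ancestral = "A", derived = "G",
    edge = "nowhere"))
  expect_error(parse_backbone("((A1)A)root;", bad_panel), "nowhere")
})

test_that("serialize/parse round trip is the identity, cross-checked by ape", {
  for (seed in 1:5) {
    p <- sim_params(n_tips = 12, tree_model = "kingman", seed = seed)
    tree <- drop_mutations(simulate_genealogy(p), p$mu, p$L, seed + 100L)
    nwk <- serialize_backbone(tree)
    back <- parse_backbone(nwk, tree$panel)
    expect_identical(back$parent, tree$parent)
    expect_identical(back$children, tree$children)
    expect_identical(back$edge_variants, tree$edge_variants)
    expect_identical(serialize_backbone(back), nwk)
    # independent reader agrees on the taxon and label sets
    phy <- ape::read.tree(text = nwk)
    expect_setequal(phy$tip.label, bt_tips(tree))
    expect_setequal(c(phy$tip.label, phy$node.label), bt_nodes(tree))
  }
})

test_that("perfect-phylogeny builder reconstructs root-to-leaf paths", {
  # single informative variant
  M1 <- matrix(c(0L, 1L), nrow = 2,
               dimnames = list(c("s1", "s2"), "v1"))
  t1 <- build_tree_from_matrix(M1)
  expect_setequal(bt_tips(t1), c("s1", "s2"))
  expect_equal(bt_path_variants(t1, "s2"), "v1")
  expect_length(bt_path_variants(t1, "s1"), 0L)

  # nested chain: root -> {v1} -> {v2}
  M2 <- cbind(v1 = c(1L, 1L, 0L), v2 = c(1L, 0L, 0L))
  rownames(M2) <- c("s1", "s2", "s3")
  t2 <- build_tree_from_matrix(M2)
  expect_equal(sort(bt_path_variants(t2, "s1")), c("v1", "v2"))
  expect_equal(bt_path_variants(t2, "s2"), "v1")
  expect_length(bt_path_variants(t2, "s3"), 0L)
  expect_equal(t2$parent[["s3"]], "N0")     # at the root

  # duplicate columns collapse onto one edge
  M3 <- cbind(va = c(1L, 1L, 0L), vb = c(1L, 1L, 0L), vc = c(1L, 0L, 0L))
  rownames(M3) <- c("s1", "s2", "s3")
  t3 <- build_tree_from_matrix(M3)
  ev <- t3$edge_variants[[t3$panel$edge[t3$panel$id == "va"]]]
  expect_setequal(ev, c("va", "vb"))
})

test_that("builder agrees with the exhaustive compatibility oracle", {
  set.seed(20240901)
  n_compat <- 0L
  for (rep in 1:200) {
    if (rep %% 2 == 0) {
      M <- compatible_matrix(8, seed = 5000 + rep)$M
      if (ncol(M) > 40) M <- M[, 1:40, drop = FALSE]
    } else {
      M <- random_matrix(7, 6)
    }
    bad <- oracle_incompatible_pairs(M)
    res <- tryCatch(build_tree_from_matrix(M), error = function(e) e)
    if (length(bad) == 0L) {
      expect_s3_class(res, "backbone_tree")
      n_compat <- n_compat + 1L
      # infinite-sites property: derived set == path variants, per sample
      for (s in rownames(M)) {
        expect_setequal(bt_path_variants(res, s),
                        colnames(M)[M[s, ] == 1L])
      }
    } else {
      expect_s3_class(res, "error")
      expect_match(conditionMessage(res), "incompatible")
    }
  }
  expect_gt(n_compat, 50L)   # both branches genuinely exercised
})

test_that("drop_recurrent removes the most conflicted column and recovers", {
  M <- compatible_matrix(8, seed = 77)$M[, 1:10, drop = FALSE]
  # inject one recurrent column clashing with several others
  bad <- as.integer(rowSums(M[, 1:3, drop = FALSE]) == 1L)
  M2 <- cbind(M, vZrec = bad)
  if (length(oracle_incompatible_pairs(M2))) {
    expect_error(build_tree_from_matrix(M2), "incompatible")
    expect_warning(t2 <- build_tree_from_matrix(M2, drop_recurrent = TRUE),
                   "dropped")
    expect_true("vZrec" %in% attr(t2, "dropped_variants") ||
                  length(attr(t2, "dropped_variants")) > 0)
    # result is a valid perfect phylogeny of the surviving columns
    kept <- setdiff(colnames(M2), attr(t2, "dropped_variants"))
    for (s in rownames(M2)) {
      expect_setequal(bt_path_variants(t2, s),
                      kept[M2[s, kept] == 1L])
    }
  } else {
    succeed("injected column happened to be compatible")
  }
})

test_that("sHG condensation maps whole subtrees and rejects nesting", {
  tree <- toy_tree()
  shg <- condense_shg(tree, data.frame(node = c("Ao", "T1"),
                                       shg = c("sHG_A", "sHG_T")))
  expect_equal(shg$map[["aA1a"]], "sHG_A")
  expect_equal(shg$map[["T1a"]], "sHG_T")
  expect_equal(shg$map[["T1b"]], "sHG_T")
  expect_equal(shg$n_shg, 2L)
  expect_setequal(shg$unassigned, c("NCx"))

  expect_error(condense_shg(tree, data.frame(node = c("daC", "T1"),
                                             shg = c("a", "b"))),
               "contains")
  expect_error(condense_shg(tree, data.frame(node = "ghost", shg = "x")),
               "ghost")
})

test_that("structural report counts terminals, inner nodes and junctions", {
  tree <- toy_tree()
  rep0 <- validate_backbone(tree)
  expect_equal(rep0$crown_terminal, 3L)          # aA1a, T1a, T1b
  expect_equal(rep0$crown_inner, 3L)             # daC, Ao, T1
  expect_equal(rep0$noncrown_terminal, 1L)       # NCx
  expect_equal(rep0$noncrown_inner, 1L)          # NC (root excluded)
  expect_equal(rep0$junction_nodes, "NCx")

  # minimal 3-node tree
  tmin <- parse_backbone("(A,B)r;", NULL)
  rmin <- validate_backbone(tmin)
  expect_equal(rmin$noncrown_terminal, 2L)
  expect_equal(rmin$noncrown_inner, 0L)

  # generator bookkeeping oracle
  p <- sim_params(n_tips = 25, tree_model = "kingman", seed = 9)
  tg <- drop_mutations(simulate_genealogy(p), p$mu, p$L, 10)
  tg$crown_root <- tg$root
  rg <- validate_backbone(tg)
  expect_equal(rg$crown_terminal, 25L)
  # binary rooted: n-1 internal nodes, root excluded from the inner count
  expect_equal(rg$crown_inner, 23L)
  # JSON round trip
  tf <- tempfile(fileext = ".json")
  validate_backbone(tree, file = tf)
  js <- jsonlite::read_json(tf)
  expect_equal(js$crown_terminal, 3L)
})
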