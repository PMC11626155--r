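test_that("hierarchical descent handles skip-ahead, inner and root calls", {
  tree <- toy_tree()

  # successive skip-ahead series: Crown variant then deep terminal variant;
  # the untested intermediate (rW is tested here, qW-style gaps below) are
  # bracketed as derived
  a <- call_haplotype(c(rAX = 1, rY = 1), tree, "arab")
  expect_equal(a$node, "aA1a")
  expect_equal(a$status, "terminal")
  expect_equal(a$label, "aA1a")
  expect_setequal(a$tested_path, c("rAX", "rY"))

  # path tested-derived, all child edges tested-ancestral -> "*", confirmed
  b <- call_haplotype(c(rAX = 1, vT = 1, vT1a = 0, vT1b = 0), tree)
  expect_equal(b$label, "T1*")
  expect_equal(b$status, "inner_confirmed")

  # child edges untested -> unresolved, same "*" display label
  c1 <- call_haplotype(c(rAX = 1, vT = 1), tree)
  expect_equal(c1$label, "T1*")
  expect_equal(c1$status, "inner_unresolved")

  # fully ancestral sample sits at the root
  r <- call_haplotype(c(rAX = 0, vNC = 0), tree)
  expect_equal(r$node, "root")
  expect_equal(r$status, "inner_confirmed")
  expect_equal(r$label, "root*")

  # all-missing -> no-call error
  expect_error(call_haplotype(c(rAX = NA, vT = NA), tree),
               class = "msy_no_call")

  # a tested-ancestral edge blocks descent through it
  d <- call_haplotype(c(rAX = 1, vT = 0, rW = 1, rY = 1), tree)
  expect_equal(d$node, "aA1a")

  # unknown variant id rejected
  expect_error(call_haplotype(c(zz = 1), tree), "outside the panel")
})

test_that("off-path derived variants: one is tolerated, ties and pairs error", {
  tree <- toy_tree()
  # support 3 (rAX,vT,vT1a) vs off-path 1 (rW): keep stronger path, warn
  expect_warning(a <- call_haplotype(c(rAX = 1, vT = 1, vT1a = 1, rW = 1),
                                     tree),
                 "conflict")
  expect_equal(a$node, "T1a")
  expect_equal(a$conflicts, "rW")

  # equal support between sibling paths is irresolvable
  expect_error(call_haplotype(c(rAX = 1, vT = 1, rW = 1), tree),
               class = "msy_ambiguous_call")

  # tied support between disjoint paths -> ambiguous
  expect_error(call_haplotype(c(rAX = 1, rW = 1, rY = 1, vT = 1, vT1a = 1),
                              tree),
               class = "msy_ambiguous_call")

  # two off-path derived variants (even on different branches) -> ambiguous
  expect_error(call_haplotype(c(rAX = 1, rW = 1, rY = 1, vT = 1, vNC = 1),
                              tree),
               class = "msy_ambiguous_call")
})

test_that("batch calling isolates failures and is order-independent", {
  tree <- toy_tree()
  g <- list(s1 = c(rAX = 1, rY = 1),
            s2 = c(rAX = 1, vT = 1, vT1a = 1, vT1b = 0),
            s3 = c(rAX = NA, vT = NA),
            s4 = c(rAX = 0, vNC = 1))
  asn <- batch_call(g, tree)
  expect_s3_class(asn, "ht_assignments")
  expect_equal(nrow(asn), 4L)
  expect_equal(asn$node[asn$sample == "s1"], "aA1a")
  expect_false(asn$ok[asn$sample == "s3"])
  expect_equal(asn$status[asn$sample == "s3"], "no_call")
  expect_equal(asn$node[asn$sample == "s4"], "NC")

  # individual calls agree with the batch
  a1 <- call_haplotype(g$s1, tree, "s1")
  expect_equal(asn$label[asn$sample == "s1"], a1$label)

  # permuted input -> identical output set
  perm <- batch_call(g[c(3, 1, 4, 2)], tree)
  expect_equal(perm[order(perm$sample), ], asn[order(asn$sample), ],
               ignore_attr = TRUE)
})

test_that("matrix input works and '*' labelling matches status", {
  tree <- toy_tree()
  M <- rbind(x1 = c(rAX = 1, rW = NA, rY = 1, vT = NA, vT1a = NA,
                    vT1b = NA, vNC = NA),
             x2 = c(rAX = 1, rW = 0, rY = NA, vT = 0, vT1a = NA,
                    vT1b = NA, vNC = NA))
  asn <- batch_call(M, tree)
  expect_equal(asn$node, c("aA1a", "daC"))
  expect_equal(asn$label, c("aA1a", "daC*"))
  expect_identical(grepl("\\*$", asn$label), asn$status != "terminal")
})

test_that("frequency-aware planning orders assays by subtree prior mass", {
  tree <- toy_tree()
  pl <- plan_tests(tree, prior = c(aA1a = 0.6, T1a = 0.2, T1b = 0.2))
  expect_equal(pl$node, "root")
  expect_equal(pl$plan[1], "rAX")                    # mass-1 subtree first
  expect_lt(which(pl$plan == "rW"), which(pl$plan == "vT"))

  # concentrated prior -> plan is exactly the path to that HT
  pl2 <- plan_tests(tree, prior = c(aA1a = 1))
  expect_equal(pl2$plan, c("rAX", "rW", "rY"))

  # terminal reached -> empty plan
  pl3 <- plan_tests(tree, current = c(rAX = 1, rW = 1, rY = 1),
                    prior = c(aA1a = 1))
  expect_length(pl3$plan, 0L)

  # tested variants never reappear in a plan
  pl4 <- plan_tests(tree, current = c(rAX = 1))
  expect_false("rAX" %in% pl4$plan)
  expect_error(plan_tests(tree, prior = c(aA1a = -1)), ">= 0")
})

test_that("greedy planning needs no more assays than breadth-first search", {
  p <- sim_params(n_tips = 15, tree_model = "kingman", seed = 31)
  tree <- drop_mutations(simulate_genealogy(p), p$mu, p$L, 32)
  tips <- bt_tips(tree)
  set.seed(33)
  # skewed prior, as produced by line breeding
  w <- rgamma(length(tips), shape = 0.3)
  prior <- setNames(w / sum(w), tips)
  truth <- sample(tips, 1000, replace = TRUE, prob = prior)
  truth_nodes <- true_nodes(tree)[truth]
  greedy <- vapply(truth_nodes, simulate_assays, numeric(1), tree = tree,
                   strategy = "greedy", prior = prior)
  bf <- vapply(truth_nodes, simulate_assays, numeric(1), tree = tree,
               strategy = "bf")
  expect_lte(mean(greedy), mean(bf))
})

test_that("imputation fills the path, respects tested states, idempotent", {
  tree <- toy_tree()
  a <- call_haplotype(c(rAX = 1, rY = 1), tree)
  v <- impute_alleles(a, tree, calls = c(rAX = 1, rY = 1))
  expect_equal(unname(v[c("rAX", "rW", "rY")]), c(1L, 1L, 1L))  # rW imputed
  expect_equal(unname(v[c("vT", "vT1a", "vT1b", "vNC")]), rep(0L, 4))
  expect_equal(names(v), toy_panel()$id)          # panel order

  # fully genotyped input is returned unchanged (idempotence)
  full <- setNames(as.integer(toy_panel()$id %in% c("rAX", "rW", "rY")),
                   toy_panel()$id)
  af <- call_haplotype(full, tree)
  expect_equal(unname(impute_alleles(af, tree, calls = full)),
               unname(full), ignore_attr = TRUE)

  # conflicts are retained as 1 and flagged, never silently zeroed
  cc <- c(rAX = 1, vT = 1, vT1a = 1, rW = 1)
  expect_warning(ac <- call_haplotype(cc, tree))
  vc <- impute_alleles(ac, tree, calls = cc)
  expect_equal(unname(vc["rW"]), 1L)
  expect_equal(attr(vc, "conflict_variants"), "rW")

  # exhaustive node sweep: impute(node) equals the node's indicator vector
  for (nd in bt_nodes(tree)) {
    ind <- setNames(as.integer(toy_panel()$id %in%
                                 bt_path_variants(tree, nd)),
                    toy_panel()$id)
    expect_equal(unname(impute_alleles(nd, tree)), unname(ind),
                 ignore_attr = TRUE)
  }
})

test_that("encode -> batch_call is the identity on a synthetic cohort", {
  p <- sim_params(n_tips = 40, tree_model = "star_burst", seed = 51)
  bundle <- simulate_bundle(p)
  asn <- batch_call(bundle$complete, bundle$tree)
  expect_true(all(asn$ok))
  M <- encode_matrix(asn, bundle$tree, genotypes = bundle$complete)
  expect_equal(dim(M), dim(bundle$complete))
  back <- batch_call(M, bundle$tree)
  expect_equal(back$node, asn$node)
  expect_equal(back$label, asn$label)

  # sibling terminals differ exactly at their sibling-edge variant columns
  tr <- toy_tree()
  asn2 <- batch_call(list(u1 = c(rAX = 1, vT = 1, vT1a = 1),
                          u2 = c(rAX = 1, vT = 1, vT1b = 1)), tr)
  M2 <- encode_matrix(asn2, tr)
  expect_setequal(colnames(M2)[M2["u1", ] != M2["u2", ]], c("vT1a", "vT1b"))

  # empty assignment list -> header-only table
  M0 <- encode_matrix(asn2[0, ], tr)
  expect_equal(nrow(M0), 0L)
  expect_equal(colnames(M0), toy_panel()$id)
})

test_that("with missingness and no error, calls stay on the true ancestral path", {
  p <- sim_params(n_tips = 100, tree_model = "star_burst", seed = 61,
                  missing_rate = 0.4)
  bundle <- simulate_bundle(p)
  truth <- bundle$true_node
  n_checked <- 0L
  for (rep in 1:20) {
    mk <- mask_panel(bundle$complete, 0.4, 0, seed = 6100 + rep)
    asn <- batch_call(mk, bundle$tree)
    ok <- asn$ok
    for (i in which(ok)) {
      s <- asn$sample[i]
      expect_true(is_ancestor_or_self(bundle$tree, asn$node[i], truth[[s]]))
      # path consistency: every tested-derived variant on path or in conflicts
      tested_der <- colnames(mk)[!is.na(mk[s, ]) & mk[s, ] == 1L]
      onpath <- bt_path_variants(bundle$tree, asn$node[i])
      confl <- strsplit(asn$conflicts[i], ";", fixed = TRUE)[[1]]
      expect_true(all(tested_der %in% c(onpath, confl)))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 1500L)
})
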