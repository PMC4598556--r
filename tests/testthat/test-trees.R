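test_that("newick and nexus files parse to the same tree and round-trip", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", nwk)
  tr <- read_tree(nwk, quiet = TRUE)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)

  nex <- tempfile(fileext = ".nex")
  write_tree(tr, nex, format = "nexus")
  tr_nex <- read_tree(nex, quiet = TRUE)
  expect_equal(sort(tr_nex$tip.label), sort(tr$tip.label))
  expect_equal(ape::cophenetic.phylo(tr_nex)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr))

  # round-trip through the writer preserves all pairwise tip distances
  out <- tempfile(fileext = ".nwk")
  write_tree(tr, out)
  tr2 <- read_tree(out, quiet = TRUE)
  expect_equal(ape::cophenetic.phylo(tr2)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr))
})

test_that("malformed trees are rejected with informative errors", {
  f1 <- tempfile(); writeLines("((A:1,B):1,C:2);", f1)
  expect_error(read_tree(f1, quiet = TRUE), "missing branch length")
  f2 <- tempfile(); writeLines("((A:1,A:1):1,C:2);", f2)
  expect_error(read_tree(f2, quiet = TRUE), "duplicate tip labels.*A")
})

test_that("stem and crown ages follow the backward-time convention", {
  tr <- tree3()
  ab <- stem_age(tr, c("A", "B"))
  expect_equal(ab$stem_age, 2)
  expect_equal(ab$crown_age, 1)
  cc <- stem_age(tr, "C")
  expect_equal(cc$stem_age, 2)
  expect_true(is.na(cc$crown_age))
  expect_error(stem_age(tr, c("A", "C")), "monophyletic.*B")
})

test_that("stem age equals crown age plus stem branch length on random trees", {
  tr <- rand_tree(50, depth = 200, seed = 11)
  depths <- ape::node.depth.edgelength(tr)
  D <- max(depths[1:50])
  internal <- 51 + seq_len(tr$Nnode)[-1]  # skip the root
  for (nd in sample(internal, 10)) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    rec <- stem_age(tr, tips)
    stem_branch <- tr$edge.length[tr$edge[, 2] == nd]
    expect_equal(rec$stem_age, rec$crown_age + stem_branch, tolerance = 1e-9)
    expect_equal(rec$crown_age, D - depths[nd], tolerance = 1e-9)
    expect_gte(rec$stem_age, rec$crown_age)
  }
})

test_that("pruning to exemplars keeps one tip per clade and all distances", {
  tr6 <- tree6()
  map <- data.frame(tip_label = c("A", "B", "C", "D", "E", "F"),
                    clade_id = c("o1", "o1", "o2", "o2", "o3", "o3"))
  pr <- prune_to_exemplars(tr6, map)
  expect_equal(sort(pr$tip.label), c("o1", "o2", "o3"))
  # exemplar is the lexicographically first member (A, C, E): distances in
  # the pruned tree equal the corresponding distances in the full tree
  full <- ape::cophenetic.phylo(tr6)
  sub <- ape::cophenetic.phylo(pr)
  expect_equal(sub[c("o1", "o2", "o3"), c("o1", "o2", "o3")],
               `dimnames<-`(full[c("A", "C", "E"), c("A", "C", "E")],
                            list(c("o1", "o2", "o3"), c("o1", "o2", "o3"))))

  # all-singleton map is a relabeled copy
  map1 <- data.frame(tip_label = tr6$tip.label,
                     clade_id = paste0("c", tr6$tip.label))
  pr1 <- prune_to_exemplars(tr6, map1)
  expect_equal(ape::Ntip(pr1), 6)
  expect_equal(unname(ape::cophenetic.phylo(pr1)[paste0("c", tr6$tip.label),
                                                 paste0("c", tr6$tip.label)]),
               unname(ape::cophenetic.phylo(tr6)))

  # overlapping clades are an error
  bad <- rbind(map, data.frame(tip_label = "A", clade_id = "o9"))
  expect_error(prune_to_exemplars(tr6, bad), "overlapping")
})

test_that("pruning preserves the induced distance matrix on random trees", {
  set.seed(21)
  for (rep in 1:5) {
    tr <- rand_tree(24)
    grp <- sort(rep(paste0("g", 1:8), 3))
    map <- data.frame(tip_label = tr$tip.label, clade_id = grp)
    pr <- prune_to_exemplars(tr, map)
    ex <- vapply(split(map$tip_label, map$clade_id),
                 function(x) sort(x)[1], character(1))
    full <- ape::cophenetic.phylo(tr)[ex, ex]
    dimnames(full) <- list(names(ex), names(ex))
    expect_equal(ape::cophenetic.phylo(pr)[names(ex), names(ex)], full,
                 tolerance = 1e-12)
  }
})

test_that("vcv_matrix gives shared root-to-MRCA path lengths", {
  C <- vcv_matrix(tree3())
  expect_equal(unname(C[, ]), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  # star tree (zero-length interior): T * identity
  star <- ape::read.tree(text = "((A:2,B:2):0,C:2);")
  expect_equal(unname(vcv_matrix(star)[, ]), diag(2, 3))

  # brute-force per-pair MRCA oracle on a random 20-tip tree
  tr <- rand_tree(20, seed = 7)
  expect_equal(vcv_matrix(tr)[tr$tip.label, tr$tip.label],
               bf_vcv(tr), tolerance = 1e-12)
})

test_that("vcv_matrix rejects polytomies unless asked to resolve them", {
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  expect_error(vcv_matrix(poly), "polytomies")
  expect_message(C <- vcv_matrix(poly, resolve_polytomies = TRUE),
                 "resolving")
  expect_equal(dim(C), c(4, 4))
})

test_that("lambda transform scales off-diagonals only and checks bounds", {
  C <- vcv_matrix(tree3())
  expect_equal(unname(apply_lambda(C, 0)[, ]), diag(2, 3))
  expect_equal(unname(apply_lambda(C, 1)[, ]), unname(C[, ]))
  expect_equal(unname(apply_lambda(C, 0.5)[, ]),
               rbind(c(2, 0.5, 0), c(0.5, 2, 0), c(0, 0, 2)))
  expect_error(apply_lambda(C, -0.1), "lambda")
  expect_error(apply_lambda(C, 1.1), "lambda")
})

test_that("covariances are symmetric PSD with equal diagonals on ultrametric trees", {
  set.seed(5)
  for (rep in 1:10) {
    tr <- rand_tree(sample(5:40, 1))
    C <- vcv_matrix(tr)
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_true(all(diff(range(diag(C))) <= 1e-9))
    for (lam in c(0, 0.3, 1)) {
      ev <- eigen(apply_lambda(C, lam), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-9)
    }
  }
})
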