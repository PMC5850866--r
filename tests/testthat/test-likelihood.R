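test_that("alignment intake validates frame, stops and names", {
  expect_error(codon_alignment(c(a = "AAAT", b = "AAAT")), "divisible by 3")
  expect_error(codon_alignment(c(a = "AAATAA", b = "AAAAAA")), "stop codon")
  expect_error(codon_alignment(c("AAA", "AAA")), "names")
  aln <- codon_alignment(c(a = "AAAGGG", b = "AAACCC"))
  expect_identical(dim(aln), c(2L, 2L))
  # missing data: codons containing gaps are NA at FASTA intake
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "AAA---", ">b", "AAACCC"), tmp)
  aln2 <- read_codon_alignment(tmp)
  expect_true(is.na(aln2["a", 2]))
  expect_false(is.na(aln2["b", 2]))
})

test_that("pruning equals exhaustive summation over internal states", {
  m <- build_yn98(2, 0.4, gc_parameterization(0.3))
  # two taxa, stationary root
  sc2 <- two_taxon_scene(m)
  aln2 <- random_alignment(sc2, 5, seed = 3)
  expect_equal(total_log_likelihood(sc2, aln2), brute_force_loglik(sc2, aln2),
               tolerance = 1e-10)
  # three taxa, nonstationary root (61^2 assignments per site)
  sc3 <- three_taxon_scene(m, root = gc_parameterization(0.8))
  aln3 <- random_alignment(sc3, 5, seed = 4)
  expect_equal(total_log_likelihood(sc3, aln3), brute_force_loglik(sc3, aln3),
               tolerance = 1e-10)
  # with missing data
  aln3[2, 3] <- NA
  expect_equal(total_log_likelihood(sc3, aln3), brute_force_loglik(sc3, aln3),
               tolerance = 1e-10)
})

test_that("two-taxon stationary likelihood collapses to the path-length form", {
  m <- build_yn98(2, 0.4, gc_parameterization(0.3))
  sc <- two_taxon_scene(m, t1 = 0.2, t2 = 0.3)
  aln <- random_alignment(sc, 10, seed = 5)
  P <- transition_matrix(m, 0.5)  # reversibility: depends only on t1 + t2
  manual <- sum(log(m$pi[aln[1, ]] * P[cbind(aln[1, ], aln[2, ])]))
  expect_equal(total_log_likelihood(sc, aln), manual, tolerance = 1e-10)
})

test_that("degenerate cases: zero branches, identical states, empty alignment", {
  m <- build_yn98(2, 0.3, gc_parameterization(0.6))
  tree <- ape::read.tree(text = "(a:0,b:0);")
  root <- gc_parameterization(0.8)
  sc <- phylo_scene(tree, m, root = root)
  aln <- codon_alignment(c(a = "AAA", b = "AAA"))
  R <- codon_frequencies(root)
  expect_equal(site_log_likelihood(sc, aln), unname(log(R["AAA"])),
               tolerance = 1e-9)
  expect_identical(total_log_likelihood(sc, aln[, integer(0)]), 0)
})

test_that("duplicated columns double their contribution (site independence)", {
  m <- build_yn98(2, 0.3, gc_parameterization(0.6))
  sc <- three_taxon_scene(m, root = gc_parameterization(0.2))
  aln1 <- random_alignment(sc, 7, seed = 9)
  aln2 <- aln1[, c(seq_len(7), 3)]
  class(aln2) <- class(aln1)
  attr(aln2, "code") <- attr(aln1, "code")
  expect_equal(total_log_likelihood(sc, aln2),
               total_log_likelihood(sc, aln1) + site_log_likelihood(sc, aln1)[3],
               tolerance = 1e-10)
})

test_that("root placement: invariant for stationary reversible scenes, not otherwise", {
  m <- build_yn98(2, 0.4, gc_parameterization(0.35))
  t1 <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.05,d:0.3):0.1);")
  # reroot along the internal branch: shift length between the two root children
  t2 <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.05,d:0.3):0.2);")
  sc1 <- phylo_scene(t1, m, root = "stationary")
  aln <- random_alignment(sc1, 30, seed = 12)
  sc2 <- phylo_scene(t2, m, root = "stationary")
  expect_equal(total_log_likelihood(sc1, aln), total_log_likelihood(sc2, aln),
               tolerance = 1e-9)
  # nonstationary: the same move changes the likelihood
  r <- gc_parameterization(0.8)
  ns1 <- phylo_scene(t1, m, root = r)
  ns2 <- phylo_scene(t2, m, root = r)
  expect_gt(abs(total_log_likelihood(ns1, aln) - total_log_likelihood(ns2, aln)),
            1e-4)
})

test_that("likelihood at t = 0 equals the contracted tree", {
  m <- build_yn98(2, 0.3, gc_parameterization(0.5))
  big <- ape::read.tree(text = "((a:0.2,b:0.3):0,c:0.25);")
  small <- ape::read.tree(text = "(a:0.2,b:0.3,c:0.25);")
  r <- gc_parameterization(0.7)
  sc_big <- phylo_scene(big, m, root = r)
  sc_small <- phylo_scene(small, m, root = r)
  aln <- random_alignment(sc_small, 20, seed = 13)
  expect_equal(total_log_likelihood(sc_big, aln),
               total_log_likelihood(sc_small, aln), tolerance = 1e-9)
})

test_that("scene construction validates inputs", {
  m <- build_yn98(2, 0.3, gc_parameterization(0.5))
  tree <- fixture_tree()
  sc <- phylo_scene(tree, m, root = gc_parameterization(0.4))
  aln <- codon_alignment(c(human = "AAA", chimp = "AAA", macaque = "AAA",
                           mouse = "AAA", rat = "AAA", wolf = "AAA"))
  expect_error(total_log_likelihood(sc, aln), "dog")
  badtree <- tree
  badtree$edge.length[1] <- -0.1
  expect_error(phylo_scene(badtree, m), ">= 0")
  expect_error(phylo_scene(tree, list(m, m)), "partition")
})

test_that("branch-heterogeneous scenes use the right model on each branch", {
  fast <- build_yn98(2, 1, gc_parameterization(0.5))
  slow <- fast
  slow$Q <- fast$Q * 0.2
  slow$eig$values <- fast$eig$values * 0.2
  tree <- ape::read.tree(text = "(a:0.5,b:0.5);")
  # model halved on branch b is the same as shortening branch b
  sc_het <- phylo_scene(tree, list(fa = fast, sl = slow),
                        root = gc_parameterization(0.5),
                        partition = c("fa", "sl"))
  sc_short <- phylo_scene(ape::read.tree(text = "(a:0.5,b:0.1);"), fast,
                          root = gc_parameterization(0.5))
  aln <- random_alignment(sc_short, 25, seed = 21)
  expect_equal(total_log_likelihood(sc_het, aln),
               total_log_likelihood(sc_short, aln), tolerance = 1e-9)
})
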