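test_that("endpoint-conditioned counts have the right short-branch limits", {
  m <- uniform_model()
  # no time, no events
  expect_lt(conditional_expected_count(m, "synonymous", 1e-8, "AAA", "AAA"), 1e-7)
  expect_lt(conditional_expected_count(m, "nonsynonymous", 1e-8, "AAA", "AAA"), 1e-7)
  # endpoints one synonymous step apart: exactly that one jump
  expect_equal(conditional_expected_count(m, "synonymous", 1e-6, "AAA", "AAG"),
               1, tolerance = 1e-4)
  expect_lt(conditional_expected_count(m, "nonsynonymous", 1e-6, "AAA", "AAG"), 1e-4)
  # unreachable endpoint at t = 0
  expect_error(conditional_expected_count(m, "synonymous", 0, "AAA", "AAG"),
               "unreachable")
})

test_that("ability expectation tends to the instantaneous ability as t -> 0", {
  m <- uniform_model()
  m0 <- neutral_counterpart(m)
  t <- 1e-7
  for (s in c("AAA", "ATG", "GGG")) {
    got <- conditional_expected_ability(m, m0, "synonymous", t, s, s) / t
    expect_equal(got, instantaneous_ability(m0, s, "synonymous"),
                 tolerance = 1e-5)
  }
})

test_that("spectral integrals match uniformization to 1e-8 relative error", {
  m <- uniform_model(kappa = 2, omega = 0.3)
  m0 <- neutral_counterpart(m)
  mats <- list(
    syn = codonmap:::label_rate_matrix(m, "synonymous"),
    nonsyn = codonmap:::label_rate_matrix(m, "nonsynonymous"),
    ab_syn = diag(codonmap:::ability_vector(m0, "synonymous")),
    ab_nonsyn = diag(codonmap:::ability_vector(m0, "nonsynonymous"))
  )
  for (t in c(0.05, 0.5, 2)) {
    for (C in mats) {
      spec <- codonmap:::branch_integral(m, C, t)
      unif <- unif_branch_integral(m, C, t)
      expect_lt(max(abs(spec - unif)) / max(abs(unif)), 1e-8)
    }
    # and the transition matrix itself
    expect_lt(max(abs(transition_matrix(m, t) - unif_transition(m, t))), 1e-9)
  }
})

test_that("conditioned counts and dwell integrals match Gillespie paths", {
  set.seed(4242)
  m <- uniform_model(kappa = 2, omega = 0.3)
  m0 <- neutral_counterpart(m)
  t <- 0.5
  x0 <- "AAA"
  paths <- sim_path_ensemble(m, m$code$index[x0], t, 40000, reward_model = m0)
  # compare on every endpoint observed at least 200 times
  ends <- as.integer(names(which(table(paths$end) >= 200)))
  expect_gte(length(ends), 2)
  for (y in ends) {
    sub <- paths[paths$end == y, ]
    n <- nrow(sub)
    for (q in list(list(est = sub$n_syn, lab = "synonymous", kind = "count"),
                   list(est = sub$n_nonsyn, lab = "nonsynonymous", kind = "count"),
                   list(est = sub$int_syn, lab = "synonymous", kind = "ability"),
                   list(est = sub$int_nonsyn, lab = "nonsynonymous", kind = "ability"))) {
      exact <- if (q$kind == "count") {
        conditional_expected_count(m, q$lab, t, x0, y)
      } else {
        conditional_expected_ability(m, m0, q$lab, t, x0, y)
      }
      # floor the spread: in small bins every accepted path can hold the
      # same jump count (sample sd 0) while the exact value includes rare
      # longer paths, so the raw plug-in SE collapses
      se <- max(stats::sd(q$est), 0.15) / sqrt(n)
      expect_lt(abs(mean(q$est) - exact), 3 * se)
    }
  }
})

test_that("total-rate identity: labeled counts sum to t at stationarity", {
  m <- build_yn98(2.5, 0.4, gc_parameterization(0.3))
  for (t in c(0.1, 0.7, 2)) {
    Ms <- codonmap:::branch_integral(m, codonmap:::label_rate_matrix(m, "synonymous"), t)
    Mn <- codonmap:::branch_integral(m, codonmap:::label_rate_matrix(m, "nonsynonymous"), t)
    # sum over both labels and endpoint pairs weighted by pi_x (joint form)
    expect_equal(sum(m$pi * rowSums(Ms + Mn)), t, tolerance = 1e-9)
    # total reward 1 on the normalized model: integrated ability is t
    m0 <- neutral_counterpart(m)
    A <- codonmap:::branch_integral(
      m0, diag(codonmap:::ability_vector(m0, "synonymous") +
               codonmap:::ability_vector(m0, "nonsynonymous")), t)
    expect_equal(sum(m0$pi * rowSums(A)), t, tolerance = 1e-9)
  }
})

test_that("joint endpoint posteriors are consistent and match brute force", {
  m <- build_yn98(2, 0.4, gc_parameterization(0.35))
  # observed endpoints on a single-branch two-leaf tree: all mass on them
  sc2 <- two_taxon_scene(m, t1 = 1e-9, t2 = 0.3, root = gc_parameterization(0.6))
  aln2 <- codon_alignment(c(a = "AAA", b = "ACC"))
  jp <- joint_endpoint_posteriors(sc2, aln2, "b")
  expect_equal(sum(jp[, , 1]), 1, tolerance = 1e-12)
  # parent end is pinned by the (near) zero-length branch to leaf a
  expect_equal(unname(jp["AAA", "ACC", 1]), 1, tolerance = 1e-5)

  # three-taxon case against exhaustive enumeration
  sc3 <- three_taxon_scene(m, root = gc_parameterization(0.7))
  aln3 <- random_alignment(sc3, 4, seed = 31)
  tree <- sc3$tree
  e <- codonmap:::resolve_branch(tree, "a")
  jp3 <- joint_endpoint_posteriors(sc3, aln3, "a")
  # brute force: P(parent state u, leaf state fixed | data)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    transition_matrix(m, tree$edge.length[k]))
  R <- sc3$root
  for (s in seq_len(ncol(aln3))) {
    col <- unclass(aln3)[, s]
    post <- matrix(0, 61, 61)
    for (root_state in 1:61) {
      for (u in 1:61) {
        # root -> internal (u) -> leaves a, b; root -> c
        p <- R[root_state] * P[[1]][root_state, u] *
          P[[2]][u, col[1]] * P[[3]][u, col[2]] * P[[4]][root_state, col[3]]
        post[u, col[1]] <- post[u, col[1]] + p
      }
    }
    post <- post / sum(post)
    expect_equal(jp3[, , s], post, tolerance = 1e-9, ignore_attr = TRUE)
    # marginal over the child end equals the parent-node posterior
    expect_equal(rowSums(jp3[, , s]), rowSums(post), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("branch mapping satisfies conservation and the neutral closed form", {
  # at neutrality, counts and abilities coincide in expectation: dN ~ dS ~ t/3
  mneu <- build_yn98(2, 1, rep(0.25, 4))
  sc <- two_taxon_scene(mneu, t1 = 0.2, t2 = 0.3)
  sim <- simulate_alignment(sc, 2000, seed = 77)
  bd <- branch_dnds(sc, sim$alignment)
  expect_equal(bd$dN, bd$length / 3, tolerance = 0.08)
  expect_equal(bd$dS, bd$length / 3, tolerance = 0.08)
  expect_equal(bd$dnds, rep(1, 2), tolerance = 0.08)

  # conservation: labeled counts sum to the total expected substitution
  # count (the count integral over the union of both label sets)
  m <- build_yn98(2, 0.3, gc_parameterization(0.6))
  sc2 <- two_taxon_scene(m, root = gc_parameterization(0.8))
  sim2 <- simulate_alignment(sc2, 300, seed = 78)
  bd2 <- branch_dnds(sc2, sim2$alignment)
  pr <- codonmap:::prune_partials(sc2, sim2$alignment)
  out <- codonmap:::outside_partials(sc2, pr)
  Qall <- m$Q
  diag(Qall) <- 0
  for (i in 1:2) {
    t_e <- bd2$length[i]
    X <- codonmap:::branch_integral(m, Qall, t_e)
    v <- sc2$tree$edge[i, 2]
    Z <- colSums(out$Fdir[[i]] * (pr$P[[i]] %*% pr$L[[v]]))
    tot <- sum(pr$weights *
               colSums(out$Fdir[[i]] * (X %*% pr$L[[v]])) / Z)
    expect_equal(bd2$E_N_syn[i] + bd2$E_N_nonsyn[i], tot, tolerance = 1e-10)
  }
})

test_that("mapping expectations track simulated ground-truth counts", {
  m <- build_yn98(2, 0.3, gc_parameterization(0.25))
  sc <- phylo_scene(fixture_tree(), m, root = gc_parameterization(0.7))
  reps <- 8
  diffs_syn <- diffs_non <- matrix(0, reps, nrow(fixture_tree()$edge))
  for (r in seq_len(reps)) {
    sim <- simulate_alignment(sc, 400, seed = 500 + r)
    bd <- branch_dnds(sc, sim$alignment)
    diffs_syn[r, ] <- bd$E_N_syn - sim$counts$n_syn
    diffs_non[r, ] <- bd$E_N_nonsyn - sim$counts$n_nonsyn
  }
  # per-branch bias across replicates is within Monte-Carlo error
  for (e in seq_len(ncol(diffs_syn))) {
    expect_lt(abs(mean(diffs_syn[, e])), 3 * stats::sd(diffs_syn[, e]) / sqrt(reps) + 1)
    expect_lt(abs(mean(diffs_non[, e])), 3 * stats::sd(diffs_non[, e]) / sqrt(reps) + 1)
  }
})

test_that("aggregation sums branch rates; refinement leaves it unchanged", {
  m <- build_yn98(2, 0.5, gc_parameterization(0.5))
  sc <- three_taxon_scene(m, root = gc_parameterization(0.4))
  sim <- simulate_alignment(sc, 200, seed = 91)
  bd <- branch_dnds(sc, sim$alignment)
  agg <- aggregate_dnds(bd)
  expect_equal(agg$dN, sum(bd$dN))
  expect_equal(agg$dS, sum(bd$dS))
  expect_equal(agg$dnds, sum(bd$dN) / sum(bd$dS))
  one <- aggregate_dnds(bd, "a")
  expect_equal(one$dN, bd$dN[bd$branch == "a"])
  expect_error(aggregate_dnds(bd, "zebra"), "unknown branch")
  expect_error(aggregate_dnds(bd[integer(0), ]), "empty")

  # splitting a branch with a degree-2 node preserves the aggregate
  t_split <- ape::read.tree(text = "((a:0.08):0.07,b:0.25,c:0.3);")
  sc_split <- phylo_scene(t_split, m, root = gc_parameterization(0.4))
  t_flat <- ape::read.tree(text = "(a:0.15,b:0.25,c:0.3);")
  sc_flat <- phylo_scene(t_flat, m, root = gc_parameterization(0.4))
  aln <- random_alignment(sc_flat, 150, seed = 92)
  bd_split <- branch_dnds(sc_split, aln)
  bd_flat <- branch_dnds(sc_flat, aln)
  agg_a_split <- aggregate_dnds(bd_split, c("a", "node5"))
  agg_a_flat <- aggregate_dnds(bd_flat, "a")
  expect_equal(agg_a_split$dN, agg_a_flat$dN, tolerance = 1e-5)
  expect_equal(agg_a_split$dS, agg_a_flat$dS, tolerance = 1e-5)
})

test_that("mean-ratio aggregation is available as an alternative", {
  df <- structure(data.frame(branch = c("x", "y"), length = c(0.1, 0.2),
                             E_N_syn = 1, E_N_nonsyn = 1, E_A0_syn = 1,
                             E_A0_nonsyn = 1, dN = c(0.1, 0.3),
                             dS = c(0.1, 0.1), dnds = c(1, 3)),
                  class = c("branch_dnds", "data.frame"))
  expect_equal(aggregate_dnds(df)$dnds, 0.4 / 0.2)
  expect_equal(aggregate_dnds(df, method = "mean_ratio")$dnds, 2)
})
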