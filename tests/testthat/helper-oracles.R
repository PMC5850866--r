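# Independent oracles used across the suite. These deliberately avoid the
# spectral code paths of the package: likelihoods by exhaustive summation
# over internal-state assignments, branch integrals by uniformization
# (truncated Poisson series), endpoint-conditioned moments by direct
# Gillespie path simulation binned by endpoint.

# exhaustive likelihood: sum over all assignments of states to internal
# nodes (feasible for <= 2 internal nodes, i.e. <= 3-taxon rooted trees)
brute_force_site_lik <- function(scene, column) {
  tree <- scene$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nstate <- length(scene$root)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(scene$models[[scene$group[e]]], tree$edge.length[e]))
  internal <- (ntip + 1L):nnode
  grids <- do.call(expand.grid, rep(list(seq_len(nstate)), length(internal)))
  states <- integer(nnode)
  states[seq_len(ntip)] <- column[tree$tip.label]
  total <- 0
  root <- ntip + 1L
  for (g in seq_len(nrow(grids))) {
    states[internal] <- as.integer(grids[g, ])
    p <- scene$root[states[root]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- states[tree$edge[e, 1]]; b <- states[tree$edge[e, 2]]
      if (!is.na(b)) p <- p * P[[e]][a, b]
      else p <- p * 1  # missing leaf marginalized
    }
    total <- total + p
  }
  total
}

brute_force_loglik <- function(scene, aln) {
  sum(vapply(seq_len(ncol(aln)), function(s) {
    col <- unclass(aln)[, s]
    names(col) <- rownames(aln)
    log(brute_force_site_lik(scene, col))
  }, numeric(1)))
}

# uniformization: I(C) = (1/mu) sum_{n>=0} Pois(n+1; mu t) S_n,
# S_n = sum_{k=0}^{n} R^k C R^{n-k}, R = I + Q/mu, truncated when the
# remaining Poisson tail mass drops below `tol`
unif_branch_integral <- function(model, C, t, tol = 1e-12) {
  Q <- model$Q
  n <- nrow(Q)
  mu <- max(-diag(Q))
  R <- diag(n) + Q / mu
  nmax <- 10
  while (stats::ppois(nmax, mu * t, lower.tail = FALSE) > tol) nmax <- nmax + 10
  S <- C
  Rn <- diag(n)
  acc <- stats::dpois(1, mu * t) * S
  for (k in seq_len(nmax)) {
    Rn <- Rn %*% R
    S <- R %*% S + C %*% Rn
    acc <- acc + stats::dpois(k + 1, mu * t) * S
  }
  acc / mu
}

unif_transition <- function(model, t, tol = 1e-14) {
  Q <- model$Q
  n <- nrow(Q)
  mu <- max(-diag(Q))
  R <- diag(n) + Q / mu
  nmax <- 10
  while (stats::ppois(nmax, mu * t, lower.tail = FALSE) > tol) nmax <- nmax + 10
  acc <- stats::dpois(0, mu * t) * diag(n)
  Rn <- diag(n)
  for (k in seq_len(nmax)) {
    Rn <- Rn %*% R
    acc <- acc + stats::dpois(k, mu * t) * Rn
  }
  acc
}

# Gillespie paths from a fixed start, keeping per-path event counts and
# per-path time-integrated neutral abilities; endpoints are recorded so
# conditional moments can be estimated by binning (equivalent to rejection
# sampling against each endpoint simultaneously)
sim_path_ensemble <- function(model, x0, t, n, reward_model = model) {
  Q <- model$Q
  nstate <- nrow(Q)
  cls <- model$code$class
  exit <- -diag(Q)
  a_syn <- rowSums(reward_model$Q * (cls == 1L))
  a_non <- rowSums(reward_model$Q * (cls == 2L))
  states <- rep(as.integer(x0), n)
  nsyn <- integer(n); nnon <- integer(n)
  isyn <- numeric(n); inon <- numeric(n)
  time_left <- rep(t, n)
  active <- seq_len(n)
  while (length(active)) {
    r <- exit[states[active]]
    dt <- stats::rexp(length(active), pmax(r, 1e-300))
    dt[r <= 0] <- Inf
    stay <- pmin(dt, time_left[active])
    isyn[active] <- isyn[active] + a_syn[states[active]] * stay
    inon[active] <- inon[active] + a_non[states[active]] * stay
    jump <- dt < time_left[active]
    time_left[active] <- time_left[active] - dt
    jumping <- active[jump]
    for (i in jumping) {
      s <- states[i]
      p <- Q[s, ]; p[s] <- 0
      ns <- sample.int(nstate, 1L, prob = p)
      if (cls[s, ns] == 1L) nsyn[i] <- nsyn[i] + 1L else nnon[i] <- nnon[i] + 1L
      states[i] <- ns
    }
    active <- jumping
  }
  data.frame(end = states, n_syn = nsyn, n_nonsyn = nnon,
             int_syn = isyn, int_nonsyn = inon)
}

# shared small fixtures
uniform_model <- function(kappa = 2, omega = 0.3) {
  build_yn98(kappa, omega, rep(0.25, 4))
}

two_taxon_scene <- function(model = uniform_model(), t1 = 0.2, t2 = 0.3,
                            root = "stationary") {
  tree <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t1, t2))
  phylo_scene(tree, model, root = root)
}

three_taxon_scene <- function(model = uniform_model(),
                              root = "stationary") {
  tree <- ape::read.tree(text = "((a:0.15,b:0.25):0.1,c:0.3);")
  phylo_scene(tree, model, root = root)
}

random_alignment <- function(scene, nsites, seed) {
  simulate_alignment(scene, nsites, seed = seed)$alignment
}
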