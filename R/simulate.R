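#' Six-taxon mammalian fixture tree
#'
#' The rooted tree used by the simulation study: primates
#' ((human, chimp), macaque), rodents (mouse, rat) and dog joined at the
#' root. Branch lengths are configurable; the defaults are 0.1 expected
#' substitutions per codon on every branch with 0.05 on the short
#' human-chimp ancestral branch.
#'
#' @param branch_length Length of every branch except the human-chimp stem.
#' @param primate_internal Length of the human-chimp ancestral branch.
#' @return An `ape::phylo` rooted tree (trifurcating root).
#' @export
fixture_tree <- function(branch_length = 0.1, primate_internal = 0.05) {
  nwk <- sprintf(
    "(((human:%1$g,chimp:%1$g):%2$g,macaque:%1$g):%1$g,(mouse:%1$g,rat:%1$g):%1$g,dog:%1$g);",
    branch_length, primate_internal)
  ape::read.tree(text = nwk)
}

#' Sample a root codon sequence
#'
#' @param root Length-61 codon distribution (e.g. a scene's `$root`).
#' @param n Number of codon sites.
#' @return Integer vector of codon indices.
#' @export
sample_root <- function(root, n) {
  stopifnot(n >= 1)
  sample.int(length(root), n, replace = TRUE, prob = root)
}

#' Evolve a codon sequence along one branch (exact Gillespie paths)
#'
#' Each site evolves independently: exponential holding times at rate
#' `-Q[s, s]`, jump targets proportional to the off-diagonal rates. Every
#' jump is classified as synonymous or nonsynonymous and counted, giving
#' ground-truth event counts for validating the mapping estimators.
#'
#' @param states Integer vector of codon indices (current sequence).
#' @param model A `codon_model`.
#' @param t Branch length, >= 0.
#' @return List: `states` (sequence at the end of the branch), `n_syn`,
#'   `n_nonsyn` (total event counts over sites), `dwell_syn`, `dwell_nonsyn`
#'   (time-integrated synonymous/nonsynonymous ability of the realized path
#'   under `model`, summed over sites).
#' @export
evolve_branch <- function(states, model, t) {
  stopifnot(t >= 0)
  Q <- model$Q
  nstate <- nrow(Q)
  cls <- model$code$class
  exit <- -diag(Q)
  a_syn <- rowSums(Q * (cls == 1L))
  a_non <- rowSums(Q * (cls == 2L))
  n_syn <- 0L; n_nonsyn <- 0L
  dwell_syn <- 0; dwell_nonsyn <- 0
  if (t == 0 || length(states) == 0L) {
    return(list(states = states, n_syn = 0L, n_nonsyn = 0L,
                dwell_syn = 0, dwell_nonsyn = 0))
  }
  time_left <- rep(t, length(states))
  active <- seq_along(states)
  while (length(active)) {
    r <- exit[states[active]]
    dt <- stats::rexp(length(active), pmax(r, 1e-300))
    dt[r <= 0] <- Inf
    stay <- pmin(dt, time_left[active])
    dwell_syn <- dwell_syn + sum(a_syn[states[active]] * stay)
    dwell_nonsyn <- dwell_nonsyn + sum(a_non[states[active]] * stay)
    jump <- dt < time_left[active]
    time_left[active] <- time_left[active] - dt
    jumping <- active[jump]
    for (i in jumping) {
      s <- states[i]
      p <- Q[s, ]
      p[s] <- 0
      ns <- sample.int(nstate, 1L, prob = p)
      if (cls[s, ns] == 1L) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      states[i] <- ns
    }
    active <- jumping
  }
  list(states = states, n_syn = n_syn, n_nonsyn = n_nonsyn,
       dwell_syn = dwell_syn, dwell_nonsyn = dwell_nonsyn)
}

#' Simulate a codon alignment along a tree
#'
#' Draws a root sequence from the scene's root distribution and evolves it
#' in preorder along every branch under that branch's model, recording the
#' true per-branch synonymous and nonsynonymous event counts and the
#' realized time-integrated abilities (the ground truth against which the
#' stochastic-mapping expectations can be validated).
#'
#' @param scene A [phylo_scene()]. Nonstationary scenes (root distribution
#'   different from the model equilibrium) and branch-heterogeneous model
#'   maps are both supported.
#' @param nsites Number of codon sites.
#' @param seed Optional integer seed for exact replay.
#' @return Object of class `simulation_record`: list with `alignment` (a
#'   [codon_alignment()] over the tips), `ancestral` (node x site integer
#'   matrix of all sequences), `counts` (data.frame per branch: child,
#'   length, n_syn, n_nonsyn, dwell_syn, dwell_nonsyn), and `scene`.
#' @export
simulate_alignment <- function(scene, nsites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- scene$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nnode, nsites)
  seqs[root_node(tree), ] <- sample_root(scene$root, nsites)
  po <- ape::reorder.phylo(tree, "postorder")
  eidx <- rev(match(paste(po$edge[, 1], po$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2])))
  nedge <- nrow(tree$edge)
  counts <- data.frame(
    branch = branch_labels(tree),
    length = tree$edge.length,
    n_syn = integer(nedge), n_nonsyn = integer(nedge),
    dwell_syn = numeric(nedge), dwell_nonsyn = numeric(nedge)
  )
  for (e in eidx) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    ev <- evolve_branch(seqs[parent, ], scene$models[[scene$group[e]]],
                        tree$edge.length[e])
    seqs[child, ] <- ev$states
    counts$n_syn[e] <- ev$n_syn
    counts$n_nonsyn[e] <- ev$n_nonsyn
    counts$dwell_syn[e] <- ev$dwell_syn
    counts$dwell_nonsyn[e] <- ev$dwell_nonsyn
  }
  code <- scene$models[[1]]$code
  tipmat <- matrix(code$codons[seqs[seq_len(ntip), , drop = FALSE]],
                   nrow = ntip, dimnames = list(tree$tip.label, NULL))
  structure(
    list(alignment = codon_alignment(tipmat, code), ancestral = seqs,
         counts = counts, scene = scene),
    class = "simulation_record"
  )
}

#' Branch labels of a rooted tree
#'
#' Branches are identified by their child node: the tip label, the node
#' label if present, or `"node<N>"` (ape node number) for unlabeled
#' internal nodes. Labels are in `tree$edge` row order, the order used by
#' every per-branch table in the package.
#'
#' @param tree Rooted `phylo` tree.
#' @return Character vector, one label per edge.
#' @export
branch_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- tree$edge[, 2]
  lab <- character(length(ch))
  tip <- ch <= ntip
  lab[tip] <- tree$tip.label[ch[tip]]
  if (!is.null(tree$node.label) && any(nzchar(tree$node.label))) {
    nl <- tree$node.label[ch[!tip] - ntip]
    lab[!tip] <- ifelse(nzchar(nl), nl, paste0("node", ch[!tip]))
  } else {
    lab[!tip] <- paste0("node", ch[!tip])
  }
  lab
}

#' Scene grid for the stationary-vs-nonstationary bias study
#'
#' Enumerates simulation scenes over a grid of root G+C (`theta_root`),
#' equilibrium G+C (`theta_eq`) and selection strength (`omega`), with a
#' deterministic per-scene seed derived from a master seed so any cell can
#' be replayed in isolation. The full study grid spans theta values 0.1 to
#' 0.9 in steps of 0.1 and omega in {0.1, 0.9, 1, 1.1}.
#'
#' @param theta_root,theta_eq Vectors of G+C proportions.
#' @param omega Vector of omega values.
#' @param kappa Transition/transversion ratio used for all scenes.
#' @param tree Rooted tree (default [fixture_tree()]).
#' @param nsites Codon sites per replicate.
#' @param replicates Replicates per grid cell.
#' @param seed Master seed.
#' @return data.frame with one row per (cell, replicate): theta_root,
#'   theta_eq, omega, replicate, nsites, scene_seed.
#' @export
grid_scenes <- function(theta_root = seq(0.1, 0.9, by = 0.1),
                        theta_eq = seq(0.1, 0.9, by = 0.1),
                        omega = c(0.1, 0.9, 1, 1.1),
                        kappa = 2,
                        tree = fixture_tree(),
                        nsites = 1000, replicates = 10, seed = 1) {
  stopifnot(length(theta_root) > 0, length(theta_eq) > 0, length(omega) > 0)
  g <- expand.grid(replicate = seq_len(replicates), omega = omega,
                   theta_eq = theta_eq, theta_root = theta_root,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("theta_root", "theta_eq", "omega", "replicate")]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  g$scene_seed <- sample.int(2147483646L, nrow(g))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  g$nsites <- nsites
  g$kappa <- kappa
  attr(g, "tree") <- tree
  g
}

#' Build the scene for one grid row
#'
#' @param row One row of the data.frame from [grid_scenes()].
#' @param tree Rooted tree.
#' @return A [phylo_scene()] with a homogeneous YN98+F1X4 model at
#'   equilibrium G+C `theta_eq` and root composition at `theta_root`.
#' @export
scene_from_grid_row <- function(row, tree = fixture_tree()) {
  model <- build_yn98(row$kappa, row$omega, gc_parameterization(row$theta_eq))
  phylo_scene(tree, model, root = gc_parameterization(row$theta_root))
}
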