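# Closed-form branch integral I(C) = \int_0^t exp(Qs) C exp(Q(t-s)) ds
# through the cached spectral decomposition Q = A diag(lambda) A^{-1}:
#   I(C) = A [ (A^{-1} C A) * J ] A^{-1},
#   J_ij = (e^{lambda_i t} - e^{lambda_j t}) / (lambda_i - lambda_j),
# with the confluent limit t e^{lambda_i t} when eigenvalues coincide
# (gap below 1e-9). Entry (x, y) is the joint expectation
# E[functional ; X_t = y | X_0 = x]; dividing by P_xy(t) conditions on the
# endpoint.
branch_integral <- function(model, C, t) {
  e <- model$eig
  lam <- e$values
  elt <- exp(lam * t)
  d <- outer(lam, lam, "-")
  J <- (outer(elt, elt, "-")) / d
  conf <- abs(d) < 1e-9
  J[conf] <- (t * elt)[row(J)[conf]]
  G <- (e$inv %*% C %*% e$vectors) * J
  M <- e$vectors %*% G %*% e$inv
  M[M < 0 & M > -1e-12] <- 0
  M
}

label_rate_matrix <- function(model, label) {
  cls <- if (label == "synonymous") 1L else 2L
  model$Q * (model$code$class == cls)
}

#' Endpoint-conditioned expected number of labeled substitutions
#'
#' Expected number of synonymous (or nonsynonymous) substitution events on
#' a branch of length `t`, given the codon states at both ends, under the
#' model's substitution process. Computed exactly from the spectral closed
#' form of the path integral, not by sampling scenarios.
#'
#' @param model A `codon_model`.
#' @param label `"synonymous"` or `"nonsynonymous"`.
#' @param t Branch length >= 0.
#' @param x,y Start and end codons (strings or indices).
#' @return Expected count (scalar).
#' @export
conditional_expected_count <- function(model, label, t, x, y) {
  ixy <- resolve_pair(model, x, y)
  P <- transition_matrix(model, t)
  if (P[ixy[1], ixy[2]] <= 0) {
    stop("endpoint pair is unreachable: P_xy(t) = 0")
  }
  M <- branch_integral(model, label_rate_matrix(model, label), t)
  M[ixy[1], ixy[2]] / P[ixy[1], ixy[2]]
}

#' Endpoint-conditioned expected time-integrated ability
#'
#' Expected value of the time integral, along the branch, of the
#' instantaneous ability of `model0` (typically the neutral counterpart of
#' the branch model) to perform labeled substitutions from the current
#' state, conditional on the branch endpoints. The path law is that of
#' `model`; `model0` only supplies the per-state reward. This is the
#' reward-weighted sum of conditional dwell times.
#'
#' @param model Branch model defining the path law.
#' @param model0 Model defining the ability reward (default: the neutral
#'   counterpart of `model`).
#' @param label `"synonymous"` or `"nonsynonymous"`.
#' @param t Branch length >= 0.
#' @param x,y Start and end codons.
#' @return Expected integrated ability (units: expected substitutions).
#' @export
conditional_expected_ability <- function(model, model0 = neutral_counterpart(model),
                                         label, t, x, y) {
  ixy <- resolve_pair(model, x, y)
  P <- transition_matrix(model, t)
  if (P[ixy[1], ixy[2]] <= 0) {
    stop("endpoint pair is unreachable: P_xy(t) = 0")
  }
  M <- branch_integral(model, diag(ability_vector(model0, label)), t)
  M[ixy[1], ixy[2]] / P[ixy[1], ixy[2]]
}

resolve_pair <- function(model, x, y) {
  code <- model$code
  ix <- if (is.character(x)) code$index[x] else as.integer(x)
  iy <- if (is.character(y)) code$index[y] else as.integer(y)
  if (is.na(ix) || is.na(iy)) stop("x and y must be sense codons")
  c(ix, iy)
}

# Downward ("outside") pass: for each edge e = (u, v), the vector
# Fdir[[e]](x) is proportional to P(data outside the subtree of v, state x
# at u); multiplied by P_xy(t_e) and the inside partial L_v(y) it gives the
# joint endpoint posterior of the branch. Per-pattern scale factors from
# the pruning pass cancel within a branch because every mapped quantity is
# normalized by the branch evidence Z_e computed from the same vectors.
outside_partials <- function(scene, pr) {
  tree <- scene$tree
  nstate <- length(scene$root)
  npat <- ncol(pr$patterns)
  nnode <- length(tree$tip.label) + tree$Nnode
  Fout <- vector("list", nnode)
  Fout[[root_node(tree)]] <- matrix(scene$root, nstate, npat)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  Fdir <- vector("list", nrow(tree$edge))
  # preorder = reverse postorder over edges
  for (e in rev(pr$eidx_postorder)) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    Fd <- Fout[[u]]
    for (sib in children[[as.character(u)]]) {
      if (sib == e) next
      Fd <- Fd * (pr$P[[sib]] %*% pr$L[[tree$edge[sib, 2]]])
    }
    # renormalize per pattern for numerical stability (cancels in Z_e)
    cs <- colSums(Fd)
    cs[cs <= 0] <- 1
    Fd <- Fd / rep(cs, each = nstate)
    Fdir[[e]] <- Fd
    Fout[[v]] <- crossprod(pr$P[[e]], Fd)
  }
  list(Fdir = Fdir, Fout = Fout)
}

#' Joint posterior distribution of branch endpoint states
#'
#' For each alignment column, the a posteriori probability, given all data
#' and the scene's (possibly nonstationary, nonhomogeneous) model, of each
#' (state at the parent end, state at the child end) pair of a branch.
#'
#' @param scene A [phylo_scene()].
#' @param aln A [codon_alignment()].
#' @param branch Branch identifier: child-node label (see
#'   [branch_labels()]) or edge index into `scene$tree$edge`.
#' @return A 3-d array `(61, 61, n_sites)`; each site slice sums to 1.
#' @export
joint_endpoint_posteriors <- function(scene, aln, branch) {
  e <- resolve_branch(scene$tree, branch)
  pr <- prune_partials(scene, aln)
  out <- outside_partials(scene, pr)
  v <- scene$tree$edge[e, 2]
  Fd <- out$Fdir[[e]]
  Lv <- pr$L[[v]]
  P <- pr$P[[e]]
  nstate <- nrow(P)
  nsites <- ncol(aln)
  res <- array(0, c(nstate, nstate, nsites),
               dimnames = list(scene$models[[1]]$code$codons,
                               scene$models[[1]]$code$codons, NULL))
  for (s in seq_len(nsites)) {
    k <- pr$map[s]
    Jp <- (Fd[, k] * P) * rep(Lv[, k], each = nstate)
    res[, , s] <- Jp / sum(Jp)
  }
  res
}

resolve_branch <- function(tree, branch) {
  if (is.numeric(branch)) {
    e <- as.integer(branch)
    if (e < 1 || e > nrow(tree$edge)) stop("branch index out of range")
    return(e)
  }
  labs <- branch_labels(tree)
  e <- match(branch, labs)
  if (is.na(e)) stop("unknown branch: ", branch)
  e
}

#' Branch-wise dN, dS and dN/dS by stochastic mapping
#'
#' For every branch, computes the posterior expected numbers of synonymous
#' and nonsynonymous substitution events and the posterior expected mean
#' neutral abilities along the branch (the "(non)synonymous site"
#' normalizer, from the neutral counterpart M0 of the branch model, i.e.
#' omega set to 1), integrating over all substitution scenarios weighted
#' by their probability given the data. The rates are then
#'
#'   dN = E(N_nonsyn) / (3 * E(A0_nonsyn)),
#'   dS = E(N_syn) / (3 * E(A0_syn)),
#'
#' where `E(A0_L)` is the branch-mean neutral ability summed over sites
#' (expected number of L-site equivalents) and the factor 3 converts the
#' per-codon rate normalization to the conventional per-nucleotide one.
#'
#' @param scene A fitted or user-specified [phylo_scene()].
#' @param aln A [codon_alignment()].
#' @param branches Branches to map (labels or indices); default all.
#' @param renormalize_m0 Re-normalize the neutral model to unit equilibrium
#'   rate (default TRUE; FALSE reuses the branch model's scale).
#' @param ability_model Optional `codon_model` (or list, one per scene
#'   model group) overriding the neutral counterpart as the ability model.
#' @param per_site If TRUE, also return per-site expected counts.
#' @return Object of class `branch_dnds` (a data.frame): one row per
#'   branch with columns `branch`, `length`, `E_N_syn`, `E_N_nonsyn`,
#'   `E_A0_syn`, `E_A0_nonsyn`, `dN`, `dS`, `dnds`. `dnds` is `NA` (with a
#'   warning flag attribute) where `dS` is 0. When `per_site = TRUE` the
#'   per-site count matrices are attached as attribute `"per_site"`.
#' @export
branch_dnds <- function(scene, aln, branches = NULL, renormalize_m0 = TRUE,
                        ability_model = NULL, per_site = FALSE) {
  tree <- scene$tree
  edges <- if (is.null(branches)) seq_len(nrow(tree$edge))
           else vapply(branches, resolve_branch, 0L, tree = tree)
  pr <- prune_partials(scene, aln)
  out <- outside_partials(scene, pr)
  w <- pr$weights
  map <- pr$map

  m0s <- lapply(seq_along(scene$models), function(g) {
    if (is.null(ability_model)) {
      neutral_counterpart(scene$models[[g]], renormalize = renormalize_m0)
    } else if (inherits(ability_model, "codon_model")) {
      ability_model
    } else ability_model[[g]]
  })

  nb <- length(edges)
  res <- data.frame(branch = branch_labels(tree)[edges],
                    length = tree$edge.length[edges],
                    E_N_syn = numeric(nb), E_N_nonsyn = numeric(nb),
                    E_A0_syn = numeric(nb), E_A0_nonsyn = numeric(nb),
                    dN = numeric(nb), dS = numeric(nb), dnds = numeric(nb))
  persite <- if (per_site) vector("list", nb) else NULL

  for (i in seq_along(edges)) {
    e <- edges[i]
    v <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    M <- scene$models[[scene$group[e]]]
    M0 <- m0s[[scene$group[e]]]
    Fd <- out$Fdir[[e]]
    Lv <- pr$L[[v]]
    P <- pr$P[[e]]

    quants <- list(
      N_syn = branch_integral(M, label_rate_matrix(M, "synonymous"), t_e),
      N_nonsyn = branch_integral(M, label_rate_matrix(M, "nonsynonymous"), t_e),
      A0_syn = branch_integral(M, diag(ability_vector(M0, "synonymous")), t_e),
      A0_nonsyn = branch_integral(M, diag(ability_vector(M0, "nonsynonymous")), t_e)
    )
    Z <- colSums(Fd * (P %*% Lv))
    vals <- lapply(quants, function(X) colSums(Fd * (X %*% Lv)) / Z)
    tot <- vapply(vals, function(vv) sum(w * vv), numeric(1))

    res$E_N_syn[i] <- tot[["N_syn"]]
    res$E_N_nonsyn[i] <- tot[["N_nonsyn"]]
    # abilities are reported as branch means (integral / t): the expected
    # number of synonymous / nonsynonymous site-equivalents
    if (t_e > 0) {
      res$E_A0_syn[i] <- tot[["A0_syn"]] / t_e
      res$E_A0_nonsyn[i] <- tot[["A0_nonsyn"]] / t_e
    } else {
      res$E_A0_syn[i] <- res$E_A0_nonsyn[i] <- NA_real_
    }
    if (per_site) {
      persite[[i]] <- vapply(vals, function(vv) vv[map],
                             numeric(length(map)))
    }
  }
  res$dN <- res$E_N_nonsyn / (3 * res$E_A0_nonsyn)
  res$dS <- res$E_N_syn / (3 * res$E_A0_syn)
  res$dnds <- ifelse(is.finite(res$dS) & res$dS > 0, res$dN / res$dS, NA_real_)
  if (any(!is.na(res$dS) & res$dS == 0)) {
    attr(res, "undefined_ratio") <- res$branch[!is.na(res$dS) & res$dS == 0]
  }
  if (per_site) attr(res, "per_site") <- stats::setNames(persite, res$branch)
  class(res) <- c("branch_dnds", "data.frame")
  res
}

#' Aggregate mapped rates over a set of branches
#'
#' Clade-level dN and dS are the sums of the branch values, and the
#' clade-level ratio is the ratio of the sums (default). An average of the
#' per-branch ratios is available as an alternative.
#'
#' @param results A `branch_dnds` table.
#' @param branches Branch labels to aggregate (default: all rows).
#' @param method `"sum"` (ratio of summed dN and dS) or `"mean_ratio"`.
#' @return List: `dN`, `dS`, `dnds`.
#' @export
aggregate_dnds <- function(results, branches = NULL, method = c("sum", "mean_ratio")) {
  method <- match.arg(method)
  r <- if (is.null(branches)) results else {
    i <- match(branches, results$branch)
    if (anyNA(i)) stop("unknown branch: ",
                       paste(branches[is.na(i)], collapse = ", "))
    results[i, ]
  }
  if (nrow(r) == 0L) stop("empty branch set")
  dN <- sum(r$dN); dS <- sum(r$dS)
  ratio <- if (method == "sum") {
    if (dS > 0) dN / dS else NA_real_
  } else {
    mean(r$dnds)
  }
  list(dN = dN, dS = dS, dnds = ratio)
}
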