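#' Codon alignment container
#'
#' Stores an in-frame codon alignment as an integer matrix (taxa x codon
#' sites) over the sense-codon indexing of the genetic code, with `NA` for
#' missing data (gaps or ambiguous codons). Sequences containing in-frame
#' stop codons are rejected.
#'
#' @param seqs Named character vector of aligned DNA sequences (equal
#'   length, divisible by 3), or a taxa x sites matrix of codon strings.
#' @param code A [genetic_code()].
#' @return Object of class `codon_alignment`: integer matrix with taxa as
#'   rownames.
#' @export
codon_alignment <- function(seqs, code = std_genetic_code()) {
  if (is.matrix(seqs)) {
    codmat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("sequences must have unique names")
    }
    seqs <- toupper(gsub("\\s", "", seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
    if (lens[1] %% 3L != 0L) {
      stop("alignment length ", lens[1], " is not divisible by 3; ",
           "supply an in-frame codon alignment")
    }
    nsite <- lens[1] %/% 3L
    codmat <- t(vapply(seqs, function(s) {
      substring(s, seq(1, lens[1], by = 3), seq(3, lens[1], by = 3))
    }, character(nsite)))
    if (nsite == 1L) codmat <- matrix(codmat, ncol = 1, dimnames = list(names(seqs), NULL))
  }
  idx <- matrix(code$index[codmat], nrow = nrow(codmat),
                dimnames = list(rownames(codmat), NULL))
  # distinguish stops (hard error) from gaps/ambiguity (missing data)
  unknown <- is.na(idx) & !is.na(codmat)
  if (any(unknown)) {
    bad <- unique(codmat[unknown])
    stops <- intersect(bad, code$stop_codons)
    if (length(stops)) {
      stop("in-frame stop codon(s) in alignment: ", paste(stops, collapse = ", "))
    }
  }
  structure(idx, class = "codon_alignment", code = code)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x), "sequences x", ncol(x), "codon sites;",
      sum(is.na(x)), "missing cells\n")
  invisible(x)
}

#' Phylogenetic scene: tree, branch models, root distribution
#'
#' Binds a rooted tree to a (possibly branch-heterogeneous) set of codon
#' models and a root composition, defining a nonstationary nonhomogeneous
#' substitution process. Branches are identified by their child node; the
#' root placement given in the tree is respected and never changed, since
#' the nonstationary likelihood depends on it.
#'
#' @param tree An [ape::read.tree()] `phylo` object, rooted, with branch
#'   lengths in expected substitutions per codon.
#' @param models A single `codon_model` (homogeneous) or a named list of
#'   models (one per branch group).
#' @param root Root codon distribution: `"stationary"` (equilibrium of the
#'   root-adjacent group's model), a [freq_param()], a length-4 nucleotide
#'   distribution, or a length-61 codon distribution.
#' @param partition For heterogeneous models: either an integer/character
#'   vector of length `nrow(tree$edge)` giving the model (name or index)
#'   of each edge, or a named list of tip-label vectors -- each branch
#'   whose entire descendant tip set falls inside one group's tip set is
#'   assigned to that group.
#' @return Object of class `phylo_scene`.
#' @export
phylo_scene <- function(tree, models, root = "stationary", partition = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (inherits(models, "codon_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "codon_model")))
  nedge <- nrow(tree$edge)
  if (is.null(partition)) {
    if (length(models) != 1L) stop("multiple models require a partition")
    group <- rep(1L, nedge)
  } else if (is.list(partition)) {
    group <- assign_clade_partition(tree, partition, names(models))
  } else {
    if (length(partition) != nedge) stop("partition must cover every edge")
    group <- if (is.character(partition)) match(partition, names(models))
             else as.integer(partition)
    if (anyNA(group) || any(group < 1L) || any(group > length(models))) {
      stop("partition refers to unknown model groups")
    }
  }
  root_group <- group[tree$edge[, 1] == root_node(tree)][1]
  root_dist <- resolve_root(root, models[[root_group]])
  structure(
    list(tree = tree, models = models, group = group, root = root_dist,
         root_spec = root),
    class = "phylo_scene"
  )
}

root_node <- function(tree) length(tree$tip.label) + 1L

resolve_root <- function(root, model) {
  if (identical(root, "stationary")) return(model$pi)
  if (inherits(root, "freq_param") || length(root) == 4L) {
    return(codon_frequencies(root, model$code))
  }
  r <- as.numeric(root)
  if (length(r) != length(model$code$codons)) stop("invalid root distribution")
  if (any(r < 0)) stop("root distribution must be >= 0")
  r / sum(r)
}

# map a named list of tip sets to an edge->group assignment: an edge belongs
# to a group when all tips below it are in the group's tip set
assign_clade_partition <- function(tree, partition, model_names) {
  if (is.null(names(partition)) || is.null(model_names)) {
    stop("clade partitions and models must both be named")
  }
  tipsets <- lapply(partition, function(tips) {
    i <- match(tips, tree$tip.label)
    if (anyNA(i)) stop("unknown tip in partition: ",
                       paste(tips[is.na(i)], collapse = ", "))
    i
  })
  below <- tips_below(tree)
  group <- integer(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    tb <- below[[tree$edge[e, 2]]]
    hits <- which(vapply(tipsets, function(ts) all(tb %in% ts), TRUE))
    if (length(hits) == 0L) stop("edge above node ", tree$edge[e, 2],
                                 " matches no partition group")
    group[e] <- hits[1]
  }
  match(names(partition)[group], model_names)
}

tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# transition matrices for every edge, in tree$edge row order
edge_matrices <- function(scene) {
  lapply(seq_len(nrow(scene$tree$edge)), function(e) {
    transition_matrix(scene$models[[scene$group[e]]],
                      scene$tree$edge.length[e])
  })
}

# compress alignment columns into unique patterns
compress_patterns <- function(aln) {
  key <- apply(unclass(aln), 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(patterns = unclass(aln)[, u, drop = FALSE],
       weights = as.vector(table(key)[key[u]]),
       map = match(key, key[u]))
}

# Felsenstein pruning: conditional likelihoods L[[node]] (61 x npat) of the
# data below each node, with per-pattern log scaling factors accumulated to
# avoid underflow. Returns everything needed by both the likelihood and the
# mapping posteriors.
prune_partials <- function(scene, aln, P = edge_matrices(scene)) {
  tree <- scene$tree
  code <- scene$models[[1]]$code
  nstate <- length(code$codons)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  if (!all(tree$tip.label %in% rownames(aln))) {
    stop("alignment is missing sequences for tips: ",
         paste(setdiff(tree$tip.label, rownames(aln)), collapse = ", "))
  }
  cp <- compress_patterns(aln)
  pat <- cp$patterns
  npat <- ncol(pat)

  L <- vector("list", nnode)
  logscale <- numeric(npat)
  for (i in seq_len(ntip)) {
    M <- matrix(0, nstate, npat)
    s <- pat[tree$tip.label[i], ]
    obs <- !is.na(s)
    M[cbind(s[obs], which(obs))] <- 1
    M[, !obs] <- 1
    L[[i]] <- M
  }
  po <- ape::reorder.phylo(tree, "postorder")
  eidx <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(po$edge))) {
    e <- eidx[k]
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    up <- P[[e]] %*% L[[child]]
    # per-pattern rescaling so deep trees cannot underflow; the per-branch
    # mapping posteriors normalize within a branch, so scales cancel there
    cs <- colSums(up)
    cs[cs <= 0] <- 1
    up <- up / rep(cs, each = nstate)
    logscale <- logscale + log(cs)
    L[[parent]] <- if (is.null(L[[parent]])) up else L[[parent]] * up
  }
  rootL <- L[[root_node(tree)]]
  lik <- as.vector(scene$root %*% rootL)
  list(L = L, P = P, patterns = pat, weights = cp$weights, map = cp$map,
       pattern_lik = lik, pattern_loglik = log(lik) + logscale,
       eidx_postorder = eidx)
}

#' Per-site log-likelihood under a scene
#'
#' Felsenstein pruning over the 61 sense-codon states, summing the root
#' conditional likelihoods against the scene's root distribution (which
#' need not be the model equilibrium: nonstationary scenes are supported,
#' as are different models on different branches). Missing leaf states
#' contribute a vector of ones.
#'
#' @param scene A [phylo_scene()].
#' @param aln A [codon_alignment()].
#' @return Numeric vector: log-likelihood of each alignment column.
#' @export
site_log_likelihood <- function(scene, aln) {
  pr <- prune_partials(scene, aln)
  pr$pattern_loglik[pr$map]
}

#' Total log-likelihood of an alignment under a scene
#'
#' Sites are independent: the total is the sum of per-site
#' log-likelihoods. An empty alignment has log-likelihood 0.
#'
#' @inheritParams site_log_likelihood
#' @return Scalar log-likelihood.
#' @export
total_log_likelihood <- function(scene, aln) {
  if (ncol(aln) == 0L) return(0)
  pr <- prune_partials(scene, aln)
  sum(pr$weights * pr$pattern_loglik)
}
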