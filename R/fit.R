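# additive log-ratio transform for frequency vectors (last entry reference)
alr <- function(p) log(p[-length(p)] / p[length(p)])
alr_inv <- function(z) {
  e <- exp(c(z, 0))
  e / sum(e)
}

# flatten a 1x4 or 3x4 frequency matrix to its free parameters and back
freqs_to_par <- function(fp) as.vector(t(apply(fp$freqs, 1, alr)))
par_to_freqs <- function(z, scheme) {
  if (scheme == "F1X4") {
    freq_param(alr_inv(z), "F1X4")
  } else {
    freq_param(t(vapply(1:3, function(i) alr_inv(z[(3 * i - 2):(3 * i)]),
                        numeric(4))), "F3X4")
  }
}

#' Maximum-likelihood fit of a codon-model template
#'
#' Fits branch lengths, kappa, omega, equilibrium frequency parameters
#' and (for nonstationary templates) root frequency parameters by
#' box-constrained quasi-Newton optimization (L-BFGS-B) on transformed
#' parameters: log scale for branch lengths, kappa and omega,
#' additive-log-ratio for frequencies. Three templates are available:
#'
#' * `"stationary"`: homogeneous model, root composition constrained to
#'   the model equilibrium.
#' * `"nonstationary"`: homogeneous model with a free root composition.
#' * `"nonhomogeneous"`: nonstationary with one model (kappa, omega,
#'   equilibrium frequencies) per branch group of `partition`.
#'
#' Multiple starts (default 3: a data-informed start, a neutral start, and
#' a jittered start) mitigate local optima; the best final likelihood wins.
#'
#' @param aln A [codon_alignment()].
#' @param tree Rooted `phylo` tree (topology fixed; branch lengths used as
#'   starting values when positive).
#' @param template One of `"stationary"`, `"nonstationary"`,
#'   `"nonhomogeneous"`.
#' @param scheme Frequency parameterization, `"F1X4"` (3 free parameters
#'   per composition) or `"F3X4"` (9).
#' @param partition For `"nonhomogeneous"`: named list of tip-label
#'   vectors defining the branch groups (see [phylo_scene()]).
#' @param control List of optimizer settings: `n_starts` (default 3),
#'   `maxit` (default 500), `factr` (L-BFGS-B tolerance, default
#'   corresponds to about 1e-6 absolute on the log-likelihood),
#'   `branch_bounds` (default `c(1e-6, 20)`), `init` (optional named list
#'   overriding starting `kappa`, `omega`, `branch_length`), `jitter_sd`
#'   (default 0.3, on the transformed scale).
#' @return Object of class `codonmap_fit`: list with `logLik`, `scene`
#'   (fitted [phylo_scene()]), `par` (named fitted parameter list),
#'   `np` (number of free parameters), `template`, `scheme`,
#'   `convergence` (0 = converged), `message`, `starts` (per-start
#'   likelihoods).
#' @export
fit_ml <- function(aln, tree,
                   template = c("stationary", "nonstationary", "nonhomogeneous"),
                   scheme = c("F1X4", "F3X4"),
                   partition = NULL, control = list()) {
  template <- match.arg(template)
  scheme <- match.arg(scheme)
  ctl <- utils::modifyList(list(n_starts = 3, maxit = 500,
                                factr = 1e-6 / .Machine$double.eps,
                                branch_bounds = c(1e-6, 20),
                                init = list(), jitter_sd = 0.3), control)
  if (template == "nonhomogeneous" && is.null(partition)) {
    stop("nonhomogeneous template requires a partition")
  }
  code <- attr(aln, "code")
  if (is.null(code)) code <- std_genetic_code()
  nedge <- nrow(tree$edge)
  ngroup <- if (template == "nonhomogeneous") length(partition) else 1L
  nf <- if (scheme == "F1X4") 3L else 9L

  # resolve the edge -> group map once (constant across evaluations)
  group <- if (ngroup == 1L) rep(1L, nedge) else {
    dummy <- lapply(seq_len(ngroup), function(i)
      build_yn98(2, 1, gc_parameterization(0.5), code))
    names(dummy) <- names(partition)
    phylo_scene(tree_with_lengths(tree, rep(0.1, nedge)), dummy,
                root = gc_parameterization(0.5), partition = partition)$group
  }

  # parameter layout: [log blen] [per group: log kappa, log omega, alr freqs]
  # [alr root freqs if nonstationary]
  idx_blen <- seq_len(nedge)
  per_group <- 2L + nf
  idx_group <- lapply(seq_len(ngroup), function(g)
    nedge + (g - 1L) * per_group + seq_len(per_group))
  np <- nedge + ngroup * per_group
  has_root <- template != "stationary"
  idx_root <- if (has_root) np + seq_len(nf) else integer(0)
  np <- np + length(idx_root)

  unpack <- function(theta) {
    bl <- exp(theta[idx_blen])
    models <- lapply(seq_len(ngroup), function(g) {
      th <- theta[idx_group[[g]]]
      build_yn98(exp(th[1]), exp(th[2]),
                 par_to_freqs(th[-(1:2)], scheme), code)
    })
    if (ngroup > 1L) names(models) <- names(partition)
    root <- if (has_root) {
      codon_frequencies(par_to_freqs(theta[idx_root], scheme), code)
    } else "stationary"
    tr <- tree_with_lengths(tree, bl)
    structure(list(tree = tr, models = models, group = group,
                   root = if (has_root) root else models[[group_at_root(tr, group)]]$pi,
                   root_spec = if (has_root) "free" else "stationary"),
              class = "phylo_scene")
  }

  negll <- function(theta) {
    sc <- unpack(theta)
    ll <- tryCatch(total_log_likelihood(sc, aln), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # data-informed defaults: empirical nucleotide composition of the alignment
  emp <- empirical_nuc_freqs(aln, code, scheme)
  init <- ctl$init
  bl0 <- tree$edge.length
  if (is.null(bl0) || any(!is.finite(bl0)) || any(bl0 <= 0)) bl0 <- rep(0.1, nedge)
  if (!is.null(init$branch_length)) bl0 <- rep(init$branch_length, nedge)
  bl0 <- pmin(pmax(bl0, ctl$branch_bounds[1] * 2), ctl$branch_bounds[2] / 2)
  k0 <- if (is.null(init$kappa)) 2 else init$kappa
  w0 <- if (is.null(init$omega)) 0.3 else init$omega
  gpar <- function(k, w, fz) c(log(k), log(w), fz)
  femp <- freqs_to_par(emp)
  funi <- rep(0, nf)
  start1 <- c(log(bl0), rep(gpar(k0, w0, femp), ngroup),
              if (has_root) femp)
  start2 <- c(log(bl0), rep(gpar(1, 1, funi), ngroup),
              if (has_root) funi)
  starts <- list(start1, start2)
  while (length(starts) < ctl$n_starts) {
    starts[[length(starts) + 1L]] <-
      start1 + stats::rnorm(np, sd = ctl$jitter_sd)
  }
  starts <- starts[seq_len(max(1L, ctl$n_starts))]

  lower <- rep(-30, np); upper <- rep(30, np)
  lower[idx_blen] <- log(ctl$branch_bounds[1])
  upper[idx_blen] <- log(ctl$branch_bounds[2])
  for (g in seq_len(ngroup)) {
    lower[idx_group[[g]][1:2]] <- log(c(1e-3, 1e-4))
    upper[idx_group[[g]][1:2]] <- log(c(100, 100))
  }

  best <- NULL
  start_ll <- numeric(0)
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    opt <- stats::optim(s, negll, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctl$maxit, factr = ctl$factr))
    start_ll <- c(start_ll, -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  scene <- unpack(best$par)
  theta <- best$par
  par <- list(
    branch_lengths = stats::setNames(scene$tree$edge.length,
                                     branch_labels(scene$tree)),
    kappa = vapply(scene$models, `[[`, numeric(1), "kappa"),
    omega = vapply(scene$models, `[[`, numeric(1), "omega"),
    equilibrium = lapply(scene$models, function(m) m$freq_param),
    root = scene$root
  )
  structure(
    list(logLik = -best$value, scene = scene, par = par, np = np,
         template = template, scheme = scheme, partition = partition,
         convergence = best$convergence, message = best$message,
         starts = start_ll, theta = theta),
    class = "codonmap_fit"
  )
}

group_at_root <- function(tree, group) {
  group[tree$edge[, 1] == root_node(tree)][1]
}

tree_with_lengths <- function(tree, bl) {
  tree$edge.length <- bl
  tree
}

empirical_nuc_freqs <- function(aln, code, scheme) {
  counts <- matrix(0, 3, 4)
  tab <- tabulate(unclass(aln)[!is.na(aln)], nbins = length(code$codons))
  for (p in 1:3) {
    for (b in 1:4) counts[p, b] <- sum(tab[code$codon_nuc[, p] == b])
  }
  counts <- counts + 1  # flatten so no frequency starts at 0
  f <- counts / rowSums(counts)
  if (scheme == "F1X4") {
    freq_param(colSums(counts) / sum(counts), "F1X4")
  } else {
    freq_param(f, "F3X4")
  }
}

#' @export
print.codonmap_fit <- function(x, ...) {
  cat("codonmap_fit:", x$template, "template (", x$scheme, "), ",
      x$np, " free parameters\n", sep = "")
  cat("  log-likelihood:", format(x$logLik, digits = 10),
      if (x$convergence != 0) " (optimizer did not report convergence)", "\n")
  cat("  kappa:", signif(x$par$kappa, 4), " omega:", signif(x$par$omega, 4), "\n")
  invisible(x)
}

#' @export
logLik.codonmap_fit <- function(object, ...) {
  structure(object$logLik, df = object$np, class = "logLik")
}

#' Likelihood-ratio test between nested fits
#'
#' The statistic is twice the log-likelihood difference, referred to a
#' chi-squared distribution whose degrees of freedom equal the difference
#' in free-parameter counts between the two templates (computed from the
#' templates themselves, never hard-coded). A slightly negative statistic
#' (within `tolerance`) is clipped to zero; a larger negative statistic
#' indicates the models were not fitted or nested correctly and is an
#' error.
#'
#' @param ll0,ll1 Log-likelihoods of the null (smaller) and alternative
#'   (larger) model, or two `codonmap_fit` objects.
#' @param df Degrees of freedom; computed from the fits when both
#'   arguments are fits.
#' @param tolerance Slack for a negative statistic (default 1e-6).
#' @return List: `statistic`, `df`, `p.value`.
#' @export
likelihood_ratio_test <- function(ll0, ll1, df = NULL, tolerance = 1e-6) {
  if (inherits(ll0, "codonmap_fit") && inherits(ll1, "codonmap_fit")) {
    if (is.null(df)) df <- ll1$np - ll0$np
    ll0 <- ll0$logLik
    ll1 <- ll1$logLik
  }
  if (is.null(df) || df < 1) stop("df must be >= 1")
  stat <- 2 * (ll1 - ll0)
  if (stat < -tolerance) {
    stop("alternative log-likelihood is below the null beyond tolerance; ",
         "models are not correctly fitted or nested")
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR control over a batch of p-values
#'
#' Standard step-up procedure. The default FDR level is 1%.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param fdr Target false discovery rate (default 0.01).
#' @return List: `adjusted` (BH-adjusted p-values), `significant` (logical
#'   flags, monotone in the p-values).
#' @export
benjamini_hochberg <- function(pvalues, fdr = 0.01) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, significant = adj <= fdr)
}
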