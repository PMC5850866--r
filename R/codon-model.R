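#' Build a YN98 (Yang-Nielsen 1998) codon model
#'
#' Instantaneous rates between sense codons differing at exactly one
#' position are proportional to the target codon's equilibrium frequency,
#' multiplied by `kappa` for transitions and by `omega` for nonsynonymous
#' changes; multiple-hit changes have rate zero. The generator is
#' normalized so that the expected substitution rate at equilibrium is one
#' substitution per codon per unit time, and its spectral decomposition
#' (via the reversibility symmetrization, which guarantees a real
#' spectrum) is cached for transition probabilities and mapping integrals.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs Equilibrium composition: a [freq_param()], a length-4
#'   nucleotide distribution (F1X4), or a length-61 codon distribution.
#' @param code A [genetic_code()].
#' @return Object of class `codon_model`: list with `Q` (61 x 61
#'   normalized generator), `pi` (equilibrium distribution), `scale` (the
#'   raw equilibrium rate divided out), `kappa`, `omega`, `freq_param`,
#'   and `eig` (list `values`, `vectors` A, `inv` A^-1 with Q = A diag A^-1).
#' @examples
#' m <- build_yn98(kappa = 2, omega = 0.3, freqs = gc_parameterization(0.6))
#' -sum(m$pi * diag(m$Q))  # 1: one substitution per codon per unit time
#' @export
build_yn98 <- function(kappa, omega, freqs, code = std_genetic_code()) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  fp <- NULL
  if (inherits(freqs, "freq_param")) {
    fp <- freqs
    pi0 <- codon_frequencies(fp, code)
  } else if (length(freqs) == 4L) {
    fp <- freq_param(freqs, "F1X4")
    pi0 <- codon_frequencies(fp, code)
  } else if (length(freqs) == length(code$codons)) {
    pi0 <- as.numeric(freqs)
    if (any(pi0 < 0)) stop("codon frequencies must be >= 0")
    pi0 <- pi0 / sum(pi0)
  } else {
    stop("freqs must be a freq_param, 4 nucleotide frequencies, or 61 codon frequencies")
  }
  # floor zero-frequency states so the chain stays irreducible on all 61 codons
  pi0 <- pmax(pi0, 1e-12)
  pi0 <- pi0 / sum(pi0)

  n <- length(code$codons)
  W <- matrix(0, n, n, dimnames = list(code$codons, code$codons))
  single <- code$class == 1L | code$class == 2L
  W[single] <- 1
  W[code$is_transition] <- W[code$is_transition] * kappa
  nonsyn <- code$class == 2L
  W[nonsyn] <- W[nonsyn] * omega
  Q <- W * rep(pi0, each = n)          # q_xy = w_xy * pi_y
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi0 * diag(Q))
  if (scale <= 0) stop("degenerate model: zero total rate at equilibrium")
  Q <- Q / scale

  eig <- spectral_decompose(Q, pi0)
  structure(
    list(Q = Q, pi = stats::setNames(pi0, code$codons), scale = scale,
         kappa = kappa, omega = omega, freq_param = fp, code = code,
         eig = eig),
    class = "codon_model"
  )
}

# Eigendecomposition of a reversible generator through the symmetrized form
# B = D^{1/2} Q D^{-1/2} (D = diag(pi)), so the spectrum is real and the
# decomposition numerically stable. Returns A, A^{-1}, values with
# Q = A diag(values) A^{-1}.
spectral_decompose <- function(Q, pi) {
  s <- sqrt(pi)
  B <- Q * (s / rep(s, each = length(s)))   # B_xy = s_x q_xy / s_y
  B <- (B + t(B)) / 2                        # kill roundoff asymmetry
  e <- eigen(B, symmetric = TRUE)
  A <- e$vectors / s                         # rows scaled by 1/s_x
  Ainv <- t(e$vectors) * rep(s, each = length(s))
  list(values = e$values, vectors = A, inv = Ainv)
}

#' Neutral counterpart M0 of a YN98 model
#'
#' The neutral model used to normalize mapped substitution counts: same
#' kappa and equilibrium composition, omega set to 1. By default M0 is
#' re-normalized to one expected substitution per codon per unit time at
#' its own equilibrium; set `renormalize = FALSE` to reuse the parent
#' model's scale instead.
#'
#' @param model A `codon_model` from [build_yn98()].
#' @param renormalize Re-normalize M0 to unit equilibrium rate (default).
#' @return A `codon_model` with `omega = 1`.
#' @export
neutral_counterpart <- function(model, renormalize = TRUE) {
  stopifnot(inherits(model, "codon_model"))
  m0 <- build_yn98(model$kappa, 1, model$pi, model$code)
  if (!renormalize) {
    # undo m0's own normalization, apply the parent scale
    f <- m0$scale / model$scale
    m0$Q <- m0$Q * f
    m0$eig$values <- m0$eig$values * f
    m0$scale <- model$scale
  }
  m0
}

#' Transition probability matrix exp(Qt)
#'
#' @param model A `codon_model`.
#' @param t Branch length (expected substitutions per codon at
#'   equilibrium), >= 0.
#' @return 61 x 61 stochastic matrix; tiny negative entries from roundoff
#'   are clipped to 0 and rows renormalized.
#' @export
transition_matrix <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length t must be a single number >= 0")
  }
  if (t == 0) {
    n <- nrow(model$Q)
    return(diag(n))
  }
  e <- model$eig
  P <- e$vectors %*% (exp(e$values * t) * e$inv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Instantaneous ability of a model to perform labeled substitutions
#'
#' The ability of model `M'` for label L from state s is the summed rate of
#' all substitutions starting at s that belong to L (synonymous or
#' nonsynonymous). Its expectation along a branch, under the neutral
#' counterpart, is the denominator of the mapped dN and dS.
#'
#' @param model A `codon_model`.
#' @param state Codon string, or NULL to return the ability of every state.
#' @param label `"synonymous"` or `"nonsynonymous"`.
#' @return Rate (scalar, or named length-61 vector when `state` is NULL).
#' @export
instantaneous_ability <- function(model, state = NULL,
                                  label = c("synonymous", "nonsynonymous")) {
  label <- match.arg(label)
  a <- ability_vector(model, label)
  if (is.null(state)) return(a)
  i <- model$code$index[state]
  if (is.na(i)) stop("not a sense codon: ", state)
  a[[i]]
}

ability_vector <- function(model, label) {
  cls <- if (label == "synonymous") 1L else 2L
  mask <- model$code$class == cls
  stats::setNames(rowSums(model$Q * mask), model$code$codons)
}
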