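#' Heterogeneous-dynamics simulation scene
#'
#' The mixed scenario of the simulation study: base composition is
#' stationary from the root through the primate clade (the primate-branch
#' model's equilibrium G+C equals the root's `theta_root`), while the
#' branches leading to dog and to the rodents evolve toward a different
#' equilibrium `theta_eq`.
#'
#' @param theta_root G+C of the root composition and of the primate-branch
#'   equilibrium.
#' @param theta_eq G+C equilibrium on the dog and rodent branches.
#' @param omega,kappa YN98 parameters shared by both groups.
#' @param tree Rooted tree with a primate clade of tips
#'   `c("human", "chimp", "macaque")` (default [fixture_tree()]).
#' @return A [phylo_scene()] with two model groups, `primates` and `rest`.
#' @export
heterogeneous_scene <- function(theta_root, theta_eq, omega, kappa = 2,
                                tree = fixture_tree()) {
  models <- list(
    primates = build_yn98(kappa, omega, gc_parameterization(theta_root)),
    rest = build_yn98(kappa, omega, gc_parameterization(theta_eq))
  )
  phylo_scene(tree, models, root = gc_parameterization(theta_root),
              partition = list(primates = c("human", "chimp", "macaque"),
                               rest = tree$tip.label))
}

#' Simulate-fit-map over a grid of nonstationary conditions
#'
#' The bias-study driver: for every grid cell (theta_root, theta_eq,
#' omega) and replicate it simulates an alignment, fits the requested
#' templates by maximum likelihood, and (optionally) runs stochastic
#' mapping under each fitted scene, aggregating dN and dS over the whole
#' tree. Comparing the stationary and nonstationary columns reproduces
#' the stationary-fit bias (overestimated omega when G+C decreases toward
#' the equilibrium, underestimated when it increases) and its correction
#' by the nonstationary fit.
#'
#' @param grid A data.frame from [grid_scenes()] (one row per cell and
#'   replicate, with per-row `scene_seed`).
#' @param tree Rooted tree used for simulation and fitting.
#' @param templates Templates to fit (subset of `"stationary"`,
#'   `"nonstationary"`).
#' @param map Run stochastic mapping under each fit (default TRUE).
#' @param scenario `"homogeneous"` (one model on all branches) or
#'   `"heterogeneous"` (the mixed scenario of [heterogeneous_scene()]; the
#'   nonstationary template is then fitted as nonhomogeneous with a
#'   primates/rest partition, and mapped dN/dS is aggregated over the
#'   primate branches only).
#' @param fit_control Passed to [fit_ml()].
#' @param progress Print one line per completed replicate.
#' @return data.frame with one row per (cell, replicate, template):
#'   grid coordinates, `template`, `logLik`, `np`, `omega_hat`,
#'   `kappa_hat`, `dN`, `dS`, `dnds` (tree- or clade-aggregated), and the
#'   alignment's realized `gc` and `gc3`.
#' @export
bias_study <- function(grid, tree = fixture_tree(),
                       templates = c("stationary", "nonstationary"),
                       map = TRUE,
                       scenario = c("homogeneous", "heterogeneous"),
                       fit_control = list(), progress = FALSE) {
  scenario <- match.arg(scenario)
  templates <- match.arg(templates, several.ok = TRUE)
  rows <- list()
  primate_tips <- c("human", "chimp", "macaque")
  for (r in seq_len(nrow(grid))) {
    row <- grid[r, ]
    scene <- if (scenario == "homogeneous") {
      scene_from_grid_row(row, tree)
    } else {
      heterogeneous_scene(row$theta_root, row$theta_eq, row$omega,
                          row$kappa, tree)
    }
    sim <- simulate_alignment(scene, row$nsites, seed = row$scene_seed)
    gc <- gc_content(sim$alignment)
    gc3 <- gc_content(sim$alignment, 3)
    for (tmpl in templates) {
      fit_tmpl <- tmpl
      partition <- NULL
      if (scenario == "heterogeneous" && tmpl == "nonstationary") {
        fit_tmpl <- "nonhomogeneous"
        partition <- list(primates = primate_tips, rest = tree$tip.label)
      }
      fit <- fit_ml(sim$alignment, tree, fit_tmpl, partition = partition,
                    control = fit_control)
      agg <- list(dN = NA_real_, dS = NA_real_, dnds = NA_real_)
      if (map) {
        bd <- branch_dnds(fit$scene, sim$alignment)
        agg <- if (scenario == "heterogeneous") {
          aggregate_dnds(bd, clade_branches(tree, primate_tips))
        } else {
          aggregate_dnds(bd)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        theta_root = row$theta_root, theta_eq = row$theta_eq,
        omega = row$omega, replicate = row$replicate,
        template = tmpl, logLik = fit$logLik, np = fit$np,
        omega_hat = unname(fit$par$omega[1]),
        kappa_hat = unname(fit$par$kappa[1]),
        dN = agg$dN, dS = agg$dS, dnds = agg$dnds,
        gc = gc, gc3 = gc3
      )
      if (progress) {
        message(sprintf("cell(%g,%g,w=%g) rep %d %s: ll=%.2f omega_hat=%.3f",
                        row$theta_root, row$theta_eq, row$omega,
                        row$replicate, tmpl, fit$logLik, fit$par$omega[1]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Branches whose descendant tips lie within a tip set
#'
#' Convenience for clade-level aggregation: returns the labels of every
#' branch (including the clade's stem) whose entire descendant tip set is
#' contained in `tips`.
#'
#' @param tree Rooted `phylo` tree.
#' @param tips Character vector of tip labels.
#' @return Character vector of branch labels (see [branch_labels()]).
#' @export
clade_branches <- function(tree, tips) {
  below <- tips_below(tree)
  keep <- vapply(seq_len(nrow(tree$edge)), function(e)
    all(tree$tip.label[below[[tree$edge[e, 2]]]] %in% tips), TRUE)
  branch_labels(tree)[keep]
}

#' Summarize a bias study per grid cell and template
#'
#' @param results Output of [bias_study()].
#' @return data.frame: per (theta_root, theta_eq, omega, template) the
#'   mean and sd over replicates of `omega_hat`, `dN`, `dS`, `dnds`, plus
#'   the replicate count. When both templates are present, columns
#'   `ratio_dN`, `ratio_dS`, `ratio_dnds` give stationary/nonstationary
#'   ratios of the cell means (the shape of the study's ratio tables).
#' @export
bias_summary <- function(results) {
  key <- interaction(results$theta_root, results$theta_eq, results$omega,
                     results$template, drop = TRUE)
  agg <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(theta_root = d$theta_root[1], theta_eq = d$theta_eq[1],
               omega = d$omega[1], template = d$template[1],
               n = nrow(d),
               omega_hat_mean = mean(d$omega_hat), omega_hat_sd = stats::sd(d$omega_hat),
               dN_mean = mean(d$dN), dN_sd = stats::sd(d$dN),
               dS_mean = mean(d$dS), dS_sd = stats::sd(d$dS),
               dnds_mean = mean(d$dnds), dnds_sd = stats::sd(d$dnds))
  }))
  rownames(agg) <- NULL
  if (all(c("stationary", "nonstationary") %in% agg$template)) {
    st <- agg[agg$template == "stationary", ]
    ns <- agg[agg$template == "nonstationary", ]
    m <- merge(st, ns, by = c("theta_root", "theta_eq", "omega"),
               suffixes = c("_st", "_ns"))
    m$ratio_dN <- m$dN_mean_st / m$dN_mean_ns
    m$ratio_dS <- m$dS_mean_st / m$dS_mean_ns
    m$ratio_dnds <- m$dnds_mean_st / m$dnds_mean_ns
    attr(agg, "ratios") <- m[, c("theta_root", "theta_eq", "omega",
                                 "ratio_dN", "ratio_dS", "ratio_dnds")]
  }
  agg
}
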