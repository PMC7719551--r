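# Synthetic data: ultrametric trees and paired-sex CIELAB color evolution
# with known ground truth, under male-driven ("Darwinian"), female-driven
# ("Wallacean"), and shared-null scenarios.

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule tree conditioned on the number of tips (via [ape::rphylo()]),
#' rescaled so the root-to-tip depth equals `root_age`. Branch lengths are
#' in Myr.
#'
#' @param n_tips number of tips (at least 3).
#' @param birth_rate speciation rate per Myr (shape parameter only; the
#'   tree is rescaled to `root_age` afterwards).
#' @param root_age tree depth in Myr (default 100, the approximate age of
#'   the European butterfly radiation the simulator emulates).
#' @param seed optional seed.
#' @return a `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, root_age = 100,
                          seed = NULL) {
  if (n_tips < 3) stop("`n_tips` must be at least 3.")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (root_age / depth)
  tr
}

#' Scenario parameters for the color simulator
#'
#' Defines the generating process of [simulate_colors()]: on every branch
#' both sexes receive a shared Brownian increment (SD `sigma_shared *
#' sqrt(branch length)` per axis) plus an independent sex-specific
#' Brownian increment (SD `sigma_sex * sqrt(length)`). Under `drive =
#' "male"` (the Darwinian scenario) a set of clades covering about
#' `driven_clade_fraction` of the tips additionally pushes the male color
#' by `drive_strength * length` along one fixed random unit direction per
#' clade — sustained directional selection toward a new color; `drive =
#' "female"` is the mirrored Wallacean scenario, `drive = "none"` the
#' shared null. A fraction `mono_fraction` of species is exactly
#' monochromatic: their sex-specific components are dropped so both sexes
#' equal the shared trajectory.
#'
#' @param n_tips number of species.
#' @param birth_rate,root_age tree parameters (see [simulate_tree()]).
#' @param sigma_shared shared BM step SD, Lab units per sqrt(Myr).
#' @param sigma_sex sex-specific BM step SD, same units.
#' @param drive `"none"`, `"male"`, or `"female"`.
#' @param drive_strength directional displacement, Lab units per Myr,
#'   applied to the driven sex inside driven clades.
#' @param driven_clade_fraction target fraction of tips inside driven
#'   clades.
#' @param mono_fraction fraction of species forced exactly monochromatic.
#' @param root_color ancestral CIELAB color at the root.
#' @param seed optional seed, stored with the parameters.
#' @return a list of class `scenario_params`.
#' @export
scenario_params <- function(n_tips = 150, birth_rate = 0.1, root_age = 100,
                            sigma_shared = 3, sigma_sex = 1,
                            drive = c("none", "male", "female"),
                            drive_strength = 2,
                            driven_clade_fraction = 0.3,
                            mono_fraction = 0.15,
                            root_color = c(L = 50, a = 0, b = 0),
                            seed = NULL) {
  drive <- match.arg(drive)
  stopifnot(n_tips >= 3, birth_rate > 0, root_age > 0,
            sigma_shared >= 0, sigma_sex >= 0, drive_strength >= 0,
            driven_clade_fraction >= 0, driven_clade_fraction <= 1,
            mono_fraction >= 0, mono_fraction <= 1,
            length(root_color) == 3)
  structure(list(n_tips = n_tips, birth_rate = birth_rate,
                 root_age = root_age, sigma_shared = sigma_shared,
                 sigma_sex = sigma_sex, drive = drive,
                 drive_strength = drive_strength,
                 driven_clade_fraction = driven_clade_fraction,
                 mono_fraction = mono_fraction, root_color = root_color,
                 seed = seed),
            class = "scenario_params")
}

# tips descending from each node, as a list over all nodes
#' @noRd
.clade_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  out <- vector("list", ntot)
  for (i in seq_len(ntip)) out[[i]] <- i
  # postorder: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge)))
    out[[po$edge[k, 1]]] <- c(out[[po$edge[k, 1]]], out[[po$edge[k, 2]]])
  out
}

#' Simulate paired-sex color evolution on a tree
#'
#' Runs the generating process described in [scenario_params()] along
#' `tree` and returns both the observable data (a centroid table in the
#' same format the analysis pipeline consumes, clipped to the CIELAB
#' gamut box on output only) and the full ground truth: per-branch shared
#' and sex-specific increments, the driven clades and their directions,
#' and the monochromatic species. Branch order and identifiers match
#' [build_design_matrix()].
#'
#' @param tree a rooted ultrametric `phylo` (e.g. [simulate_tree()]).
#' @param params a [scenario_params()] object.
#' @return a list of class `synthetic_dataset`: `tree`, `centroids`,
#'   `tip_states` (unclipped per-sex tip matrices), `increments` (shared,
#'   male, female; branches x 3), `driven_clades`, `mono_species`,
#'   `params`.
#' @export
simulate_colors <- function(tree, params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  tree <- ape::reorder.phylo(.check_tree(tree), "cladewise")
  if (params$drive != "none" && params$drive_strength == 0)
    warning("drive is ", params$drive, " but drive_strength is 0; ",
            "the scenario reduces to the shared null.")
  if (!is.null(params$seed)) set.seed(params$seed)
  ntip <- ape::Ntip(tree)
  ne <- nrow(tree$edge)
  len <- tree$edge.length
  lab <- .node_labels(tree)

  draw <- function(sigma) matrix(stats::rnorm(ne * 3, 0, rep(sigma * sqrt(len), 3)),
                                 ne, 3, dimnames = list(lab[tree$edge[, 2]],
                                                        c("L", "a", "b")))
  shared <- draw(params$sigma_shared)
  # one stream for the driven sex, one for the other; which sex is which
  # is decided only after all random draws, so Darwinian and Wallacean
  # runs with the same seed are exact mirrors of each other
  inc_driven <- draw(params$sigma_sex)
  inc_other <- draw(params$sigma_sex)

  driven_clades <- list()
  if (params$drive != "none" && params$driven_clade_fraction > 0) {
    clades <- .clade_tips(tree)
    sizes <- lengths(clades)
    cand <- which(seq_along(clades) > ntip &
                    sizes >= max(3, ceiling(0.02 * ntip)) &
                    sizes <= floor(0.25 * ntip))
    cand <- cand[cand != ntip + 1L]           # never the root
    cand <- sample(cand)
    covered <- integer(0)
    target <- params$driven_clade_fraction * ntip
    for (nd in cand) {
      if (length(covered) >= target) break
      if (any(clades[[nd]] %in% covered)) next
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      in_clade <- c(clades[[nd]], .clade_nodes(tree, nd))
      on_branch <- tree$edge[, 2] %in% in_clade
      inc_driven[on_branch, ] <- inc_driven[on_branch, , drop = FALSE] +
        params$drive_strength * len[on_branch] %o% u
      driven_clades[[length(driven_clades) + 1L]] <-
        list(node = nd, tips = lab[clades[[nd]]], direction = u)
      covered <- c(covered, clades[[nd]])
    }
  }

  mono <- sort(sample(ntip, round(params$mono_fraction * ntip)))

  m_inc <- if (params$drive == "female") inc_other else inc_driven
  f_inc <- if (params$drive == "female") inc_driven else inc_other

  # accumulate states from the root (cladewise: parents precede children)
  acc <- function(inc) {
    S <- matrix(0, ntip + tree$Nnode, 3,
                dimnames = list(lab, c("L", "a", "b")))
    S[ntip + 1L, ] <- params$root_color
    for (k in seq_len(ne))
      S[tree$edge[k, 2], ] <- S[tree$edge[k, 1], ] + inc[k, ]
    S
  }
  S_shared <- acc(shared)
  S_m <- acc(shared + m_inc)
  S_f <- acc(shared + f_inc)

  tip_m <- S_m[seq_len(ntip), , drop = FALSE]
  tip_f <- S_f[seq_len(ntip), , drop = FALSE]
  tip_m[mono, ] <- S_shared[mono, , drop = FALSE]
  tip_f[mono, ] <- S_shared[mono, , drop = FALSE]

  clip <- function(m) cbind(L = .clamp(m[, 1], 0, 100),
                            a = .clamp(m[, 2], -127.999, 127.999),
                            b = .clamp(m[, 3], -127.999, 127.999))
  centroids <- rbind(
    data.frame(species_id = tree$tip.label, sex = "male", clip(tip_m)),
    data.frame(species_id = tree$tip.label, sex = "female", clip(tip_f)))
  rownames(centroids) <- NULL

  structure(list(tree = tree, centroids = centroids,
                 tip_states = list(male = tip_m, female = tip_f),
                 increments = list(shared = shared, male = m_inc,
                                   female = f_inc),
                 driven_clades = driven_clades,
                 mono_species = tree$tip.label[mono],
                 params = params),
            class = "synthetic_dataset")
}

# internal nodes descending from nd (nd included)
#' @noRd
.clade_nodes <- function(tree, nd) {
  kids <- tree$edge[tree$edge[, 1] == nd, 2]
  kids <- kids[kids > ape::Ntip(tree)]
  c(nd, unlist(lapply(kids, .clade_nodes, tree = tree)))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dichromatism dataset:",
      ape::Ntip(x$tree), "species, scenario drive =", x$params$drive, "\n")
  cat("  driven clades:", length(x$driven_clades),
      " monochromatic species:", length(x$mono_species), "\n")
  d <- species_dichromatism(x$centroids)
  cat(sprintf("  tip dichromatism ||D||: median %.2f (max %.2f)\n",
              stats::median(d$D_mag), max(d$D_mag)))
  invisible(x)
}

#' Write the ground truth of a synthetic dataset
#'
#' CSV of per-branch true increments (shared, male, female, one row per
#' branch) alongside the Newick tree and centroid CSV that the analysis
#' pipeline consumes.
#'
#' @param dataset a [simulate_colors()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, "tree.nwk")
  cp <- file.path(dir, "centroids.csv")
  gp <- file.path(dir, "ground_truth.csv")
  ape::write.tree(dataset$tree, tp)
  write_centroids(dataset$centroids, cp)
  inc <- dataset$increments
  gt <- data.frame(branch_id = rownames(inc$shared),
                   shared_L = inc$shared[, 1], shared_a = inc$shared[, 2],
                   shared_b = inc$shared[, 3],
                   male_L = inc$male[, 1], male_a = inc$male[, 2],
                   male_b = inc$male[, 3],
                   female_L = inc$female[, 1], female_a = inc$female[, 2],
                   female_b = inc$female[, 3], row.names = NULL)
  utils::write.csv(gt, gp, row.names = FALSE)
  invisible(c(tree = tp, centroids = cp, ground_truth = gp))
}
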