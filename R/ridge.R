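# Phylogenetic ridge regression: tip traits regressed on root-to-tip
# branch-length paths, one slope (rate) per branch, ancestral states by
# accumulation from the root.

#' Root-to-node path design matrix
#'
#' Builds the design matrix of a rate-additive model on a phylogeny:
#' entry (i, b) is the length of branch b if b lies on the root-to-node-i
#' path and 0 otherwise, so each row sums to that node's distance from the
#' root. Branches are ordered as the rows of `tree$edge` after cladewise
#' reordering (the canonical order used throughout the package), and each
#' branch is identified by its child node (tip label, or "N<number>" for
#' internal nodes).
#'
#' @param tree a rooted `phylo` with strictly positive branch lengths.
#' @param nodes `"tips"` (default) for a tips x branches matrix, `"all"`
#'   for every node (tips first, then internal nodes, root row all zero).
#' @return a numeric matrix; rownames are node labels, colnames the child
#'   labels identifying each branch.
#' @export
build_design_matrix <- function(tree, nodes = c("tips", "all")) {
  nodes <- match.arg(nodes)
  tree <- .check_tree(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  ne <- nrow(tree$edge)
  lab <- .node_labels(tree)
  P <- matrix(0, ntot, ne, dimnames = list(lab, lab[tree$edge[, 2]]))
  # cladewise order guarantees a parent's row is complete before its children
  for (k in seq_len(ne)) {
    P[tree$edge[k, 2], ] <- P[tree$edge[k, 1], ]
    P[tree$edge[k, 2], k] <- tree$edge.length[k]
  }
  if (nodes == "tips") P[seq_len(ntip), , drop = FALSE] else P
}

# Precompute everything about the tree that the ridge solution reuses:
# the centered design and its SVD. Centering profiles out the unpenalized
# intercept (the root state).
#' @noRd
.ridge_prep <- function(tree) {
  tree <- ape::reorder.phylo(.check_tree(tree), "cladewise")
  X_all <- build_design_matrix(tree, "all")
  ntip <- ape::Ntip(tree)
  X <- X_all[seq_len(ntip), , drop = FALSE]
  xbar <- colMeans(X)
  sv <- svd(sweep(X, 2, xbar))
  list(tree = tree, ntip = ntip, X_all = X_all, xbar = xbar,
       u = sv$u, d = sv$d, v = sv$v,
       n = nrow(X), p = ncol(X), labels = .node_labels(tree))
}

# Closed-form ridge solution for one penalty, all trait axes at once.
# minimize ||y - mu - X beta||^2 + lambda ||beta||^2 with mu unpenalized.
#' @noRd
.ridge_solve <- function(prep, Y, lambda) {
  ybar <- colMeans(Y)
  uty <- crossprod(prep$u, sweep(Y, 2, ybar))
  if (lambda == 0) {
    dtol <- max(prep$d) * 1e-10
    if (prep$p > prep$n - 1 || min(prep$d) < dtol)
      stop("the unpenalized system is singular (more branch rates than ",
           "tips); use a penalty > 0.")
  }
  beta <- prep$v %*% (uty * (prep$d / (prep$d^2 + lambda)))
  root <- ybar - as.vector(crossprod(beta, prep$xbar))
  node_states <- sweep(prep$X_all %*% beta, 2, root, "+")
  dimnames(beta) <- list(colnames(prep$X_all), colnames(Y))
  dimnames(node_states) <- list(prep$labels, colnames(Y))
  list(root_state = stats::setNames(root, colnames(Y)),
       branch_rates = beta, node_states = node_states, penalty = lambda)
}

# Exact leave-one-out cross-validated squared error of the ridge smoother,
# summed over trait axes, via the e/(1-h) shortcut.
#' @noRd
.ridge_loocv <- function(prep, Y, lambda, .cache = NULL) {
  if (is.null(.cache)) .cache <- .ridge_cv_cache(prep, Y)
  w <- prep$d^2 / (prep$d^2 + lambda)
  resid <- .cache$Yc - prep$u %*% (.cache$uty * w)
  h <- 1 / prep$n + drop(.cache$u2 %*% w)
  h <- pmin(h, 1 - 1e-12)
  sum((resid / (1 - h))^2)
}

#' @noRd
.ridge_cv_cache <- function(prep, Y) {
  Yc <- sweep(Y, 2, colMeans(Y))
  list(Yc = Yc, uty = crossprod(prep$u, Yc), u2 = prep$u^2)
}

#' @noRd
.select_penalty <- function(prep, Y) {
  lambda <- .select_penalty_joint(prep, list(Y))
  if (!is.finite(lambda) || lambda <= 0)
    stop("penalty selection failed: cross-validation returned a ",
         "non-positive penalty.")
  lambda
}

# Joint selection over several trait matrices (e.g. the two sexes):
# one penalty minimizing the summed LOOCV error, so shrinkage — which
# scales rate magnitudes directly — is identical across the fits being
# compared.
#' @noRd
.select_penalty_joint <- function(prep, Ys) {
  caches <- lapply(Ys, .ridge_cv_cache, prep = prep)
  cv_sum <- function(l) sum(vapply(caches, function(cc)
    .ridge_loocv(prep, NULL, l, cc), numeric(1)))
  d2 <- prep$d^2
  base <- stats::median(d2[d2 > max(d2) * 1e-12])
  grid <- base * 10^seq(-6, 6, by = 0.25)
  cv <- vapply(grid, cv_sum, numeric(1))
  i0 <- which.min(cv)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(function(ll) cv_sum(exp(ll)),
                         lower = log(lo), upper = log(hi), tol = 1e-4)
  exp(opt$minimum)
}

#' Select the ridge penalty by leave-one-out cross-validation
#'
#' Chooses the penalty that minimizes the exact leave-one-out
#' cross-validated squared prediction error of the tip values, summed over
#' trait axes (one shared penalty across axes, which share a perceptual
#' unit). The search is a log-spaced grid scaled to the design's spectrum,
#' refined locally by golden-section search; the result is deterministic.
#'
#' @inheritParams fit_rrphylo
#' @return the selected penalty (a positive scalar).
#' @export
select_penalty <- function(tree, tip_traits) {
  prep <- .ridge_prep(tree)
  .select_penalty(prep, .align_traits(prep, tip_traits))
}

#' @noRd
.align_traits <- function(prep, tip_traits) {
  Y <- as.matrix(tip_traits)
  if (is.null(rownames(Y)))
    stop("`tip_traits` must have rownames matching the tree's tip labels.")
  if (!setequal(rownames(Y), prep$tree$tip.label) ||
      nrow(Y) != prep$ntip)
    stop("`tip_traits` rownames must match the tree's tip labels exactly.")
  Y[prep$tree$tip.label, , drop = FALSE]
}

#' Phylogenetic ridge regression of tip traits
#'
#' Fits, per trait axis, branch rates `beta` minimizing
#' `||y - mu - X beta||^2 + lambda ||beta||^2`, where `X` is the
#' root-to-tip path design matrix ([build_design_matrix()]) and the root
#' state `mu` is estimated alongside the rates but left unpenalized.
#' Ancestral states at every node follow by accumulating rate x branch
#' length from the root, so `state(child) = state(parent) + rate * length`
#' holds exactly on every branch and the tip states reproduce the fitted
#' tip values. The penalty shrinks the variance of the evolutionary rates,
#' which is what makes a rate per branch identifiable. With 3-D CIELAB
#' traits the per-branch slope is a 3-vector: the local rate and direction
#' of color evolution, in Lab units per Myr.
#'
#' @param tree a rooted `phylo`, branch lengths in Myr, at least 3 tips.
#' @param tip_traits numeric matrix (tips x axes, typically L, a, b) with
#'   rownames matching `tree$tip.label`; traits are not standardized.
#' @param penalty optional nonnegative ridge penalty; if `NULL` (default)
#'   it is chosen by [select_penalty()].
#' @return an object of class `ridge_fit`: `root_state`, `branch_rates`
#'   (branches x axes, rownames = child node labels), `node_states` (all
#'   nodes x axes), `penalty`, and the (cladewise-reordered) `tree`.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' y <- matrix(c(1, 2, 4), 3, 1, dimnames = list(c("A", "B", "C"), "L"))
#' fit_rrphylo(tree, y, penalty = 1)
#' @export
fit_rrphylo <- function(tree, tip_traits, penalty = NULL) {
  prep <- .ridge_prep(tree)
  if (prep$ntip < 3) stop("need at least 3 tips.")
  Y <- .align_traits(prep, tip_traits)
  if (is.null(penalty)) penalty <- .select_penalty(prep, Y)
  if (!is.finite(penalty) || penalty < 0)
    stop("`penalty` must be a nonnegative scalar.")
  sol <- .ridge_solve(prep, Y, penalty)
  structure(c(sol, list(tree = prep$tree)), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("Phylogenetic ridge regression fit\n")
  cat("  tips:", ape::Ntip(x$tree), " branches:", nrow(x$branch_rates),
      " axes:", ncol(x$branch_rates), "\n")
  cat("  penalty:", signif(x$penalty, 4), "\n")
  cat("  root state:", paste(signif(x$root_state, 4), collapse = ", "), "\n")
  cat("  mean rate magnitude:",
      signif(mean(.norm_rows(x$branch_rates)), 4), "per Myr\n")
  invisible(x)
}

#' Write a ridge fit to CSV files
#'
#' @param fit a [fit_rrphylo()] result.
#' @param states_path CSV of node states (node_id, one column per axis).
#' @param rates_path CSV of branch rates (branch_id, parent, child,
#'   length, one rate column per axis).
#' @return invisibly, the two paths.
#' @export
write_ridge_fit <- function(fit, states_path, rates_path) {
  states <- data.frame(node_id = rownames(fit$node_states),
                       fit$node_states, row.names = NULL)
  lab <- .node_labels(fit$tree)
  rates <- data.frame(branch_id = rownames(fit$branch_rates),
                      parent = lab[fit$tree$edge[, 1]],
                      child = lab[fit$tree$edge[, 2]],
                      length = fit$tree$edge.length,
                      fit$branch_rates, row.names = NULL)
  names(rates)[-(1:4)] <- paste0("rate_", colnames(fit$branch_rates))
  utils::write.csv(states, states_path, row.names = FALSE)
  utils::write.csv(rates, rates_path, row.names = FALSE)
  invisible(c(states_path, rates_path))
}
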