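# Dichromatism dynamics: combine the two sexes' ridge fits into rate
# ratios, the rate-ratio ~ dichromatism regression, and sex-specific
# effective rates of dichromatism change.

#' Per-branch male and female rate vectors with ancestral dichromatism
#'
#' Pairs the two sexes' per-branch rate vectors (`m` and `f`, in Lab units
#' per Myr) and attaches the ancestral dichromatism vector at each
#' branch's parent node, `D = c_m - c_f` evaluated on the reconstructed
#' ancestral centroids (the state preceding the change along the branch).
#'
#' @param fit_male,fit_female [fit_rrphylo()] results for the two sexes on
#'   the same tree.
#' @return a data frame of class `branch_sex_rates`, one row per branch:
#'   identifiers (`branch_id`, `parent`, `child`, `length`, `is_tip`),
#'   rate vectors (`m_L`...`f_b`) and magnitudes (`m_mag`, `f_mag`), and
#'   the ancestral dichromatism (`D_L`, `D_a`, `D_b`, `anc_D_mag`).
#' @export
branch_sex_rates <- function(fit_male, fit_female) {
  if (!inherits(fit_male, "ridge_fit") || !inherits(fit_female, "ridge_fit"))
    stop("both arguments must be ridge_fit objects.")
  if (!identical(fit_male$tree$edge, fit_female$tree$edge) ||
      !identical(fit_male$tree$tip.label, fit_female$tree$tip.label))
    stop("the two fits must come from the same tree.")
  tree <- fit_male$tree
  lab <- .node_labels(tree)
  M <- fit_male$branch_rates
  F_ <- fit_female$branch_rates
  Danc <- fit_male$node_states[tree$edge[, 1], , drop = FALSE] -
    fit_female$node_states[tree$edge[, 1], , drop = FALSE]
  out <- data.frame(
    branch_id = lab[tree$edge[, 2]],
    parent = lab[tree$edge[, 1]],
    child = lab[tree$edge[, 2]],
    length = tree$edge.length,
    is_tip = tree$edge[, 2] <= ape::Ntip(tree),
    m_L = M[, 1], m_a = M[, 2], m_b = M[, 3],
    f_L = F_[, 1], f_a = F_[, 2], f_b = F_[, 3],
    m_mag = .norm_rows(M), f_mag = .norm_rows(F_),
    D_L = Danc[, 1], D_a = Danc[, 2], D_b = Danc[, 3],
    anc_D_mag = .norm_rows(Danc),
    row.names = NULL)
  class(out) <- c("branch_sex_rates", class(out))
  out
}

#' Effective rates of dichromatism change by scalar projection
#'
#' Projects each branch's rate vectors onto the unit ancestral
#' dichromatism direction `D_hat` (female-to-male): `s_m = m . D_hat`,
#' `s_f = -f . D_hat`, and the net effective rate `s = s_m + s_f =
#' (m - f) . D_hat`. Positive values increase dichromatism; to first order
#' `s` equals the change in `||D||` along the branch per unit time, and
#' change shared by both sexes (m = f) leaves dichromatism untouched.
#' Where the ancestral dichromatism is essentially zero (`anc_D_mag <
#' eps`) the projection direction is undefined: those branches get
#' `s_m = s_f = s = 0` and are flagged `degenerate`, to be excluded from
#' contribution regressions.
#'
#' @param rates a [branch_sex_rates()] table.
#' @param eps degeneracy threshold on `anc_D_mag` (default 1e-9).
#' @return the input with columns `s_m`, `s_f`, `s`, `degenerate`
#'   appended; class `contribution_table`.
#' @export
project_contributions <- function(rates, eps = 1e-9) {
  M <- as.matrix(rates[, c("m_L", "m_a", "m_b")])
  F_ <- as.matrix(rates[, c("f_L", "f_a", "f_b")])
  D <- as.matrix(rates[, c("D_L", "D_a", "D_b")])
  deg <- rates$anc_D_mag < eps
  Dhat <- D / ifelse(deg, 1, rates$anc_D_mag)
  rates$s_m <- ifelse(deg, 0, rowSums(M * Dhat))
  rates$s_f <- ifelse(deg, 0, -rowSums(F_ * Dhat))
  rates$s <- rates$s_m + rates$s_f
  rates$degenerate <- deg
  class(rates) <- unique(c("contribution_table", class(rates)))
  rates
}

#' Ratio of mean male to mean female evolutionary rate
#'
#' `mean(||m||) / mean(||f||)` over branches: values above 1 mean male
#' color evolves faster on average.
#'
#' @param rates a [branch_sex_rates()] (or [project_contributions()])
#'   table.
#' @return a scalar.
#' @export
sex_rate_ratio <- function(rates) {
  if (nrow(rates) < 1) stop("need at least one branch.")
  fbar <- mean(rates$f_mag)
  if (fbar == 0)
    stop("all female rates are zero; the rate ratio is undefined.")
  mean(rates$m_mag) / fbar
}

#' Regression of the log male/female rate ratio on ancestral dichromatism
#'
#' Fits `log(||m|| / ||f||) ~ anc_D_mag` by ordinary least squares. The
#' log makes the ratio linear and sex-symmetric, and the slope is exactly
#' the sex-by-dichromatism interaction of the stacked model
#' `log(rate) ~ dichromatism * sex`, since log(a) - log(b) = log(a/b).
#' A positive slope means rates grow more male-biased where dichromatism
#' is high. Branches where either rate magnitude falls below `min_rate`
#' are excluded (log of zero); the excluded count is reported.
#'
#' @param rates a [branch_sex_rates()] table.
#' @param min_rate exclusion threshold on rate magnitudes (default 1e-12).
#' @return a list of class `ratio_dichromatism_fit`: `slope`, `intercept`,
#'   `model` (the `lm`), `n`, `n_excluded`.
#' @export
ratio_vs_dichromatism <- function(rates, min_rate = 1e-12) {
  keep <- rates$m_mag > min_rate & rates$f_mag > min_rate
  if (sum(keep) < 3)
    stop("fewer than 3 branches with usable (nonzero) rates.")
  d <- data.frame(log_ratio = log(rates$m_mag[keep] / rates$f_mag[keep]),
                  anc_D_mag = rates$anc_D_mag[keep])
  fit <- stats::lm(log_ratio ~ anc_D_mag, data = d)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 model = fit, n = sum(keep), n_excluded = sum(!keep)),
            class = "ratio_dichromatism_fit")
}

#' @export
print.ratio_dichromatism_fit <- function(x, ...) {
  cat(sprintf(
    "log(male rate / female rate) ~ ancestral ||D||: slope = %.4f, intercept = %.4f (n = %d, excluded = %d)\n",
    x$slope, x$intercept, x$n, x$n_excluded))
  invisible(x)
}

#' Male and female contribution slopes
#'
#' Ordinary least-squares slopes of `s_m ~ s` and `s_f ~ s` (with
#' intercepts) over non-degenerate branches. Because `s = s_m + s_f` row
#' by row, the two slopes sum to exactly 1; equal male and female
#' contributions give 0.5 each, and a male slope above 0.5 means changes
#' in dichromatism are predominantly male-driven.
#'
#' @param table a [project_contributions()] table.
#' @return named numeric vector `c(male = ..., female = ...)`.
#' @export
contribution_slopes <- function(table) {
  if (!all(c("s_m", "s_f", "s") %in% names(table)))
    stop("`table` must come from project_contributions().")
  t2 <- table[!table$degenerate, , drop = FALSE]
  if (nrow(t2) < 3 ||
      stats::var(t2$s) <= (1e-10 * max(1, abs(t2$s)))^2)
    stop("the contribution regression is degenerate: fewer than 3 ",
         "non-degenerate branches or no variance in s (e.g. ",
         "monochromatic-everywhere data).")
  c(male = stats::cov(t2$s_m, t2$s) / stats::var(t2$s),
    female = stats::cov(t2$s_f, t2$s) / stats::var(t2$s))
}

#' Full dichromatism decomposition for one centroid table
#'
#' Runs the whole modelling stage: fits the phylogenetic ridge regression
#' to the male and the female centroids independently, with one
#' cross-validated penalty shared across the three CIELAB axes and both
#' sexes (shrinkage scales rate magnitudes, so comparing the sexes
#' requires identical shrinkage), builds the per-branch table of rate
#' vectors and ancestral
#' dichromatism, projects out the effective rates `s_m`, `s_f`, `s`, and
#' summarizes them as the mean rate ratio, the log-ratio ~ dichromatism
#' regression, and the contribution slopes.
#'
#' @param tree a rooted `phylo`, branch lengths in Myr; tip labels must
#'   match `centroids$species_id`.
#' @param centroids data frame with columns `species_id`, `sex`, `L`, `a`,
#'   `b` (one row per species and sex).
#' @param penalty optional fixed ridge penalty used for both sexes;
#'   default `NULL` selects one shared penalty by cross-validation over
#'   both sexes jointly.
#' @param tips_only if `TRUE`, the summary statistics (ratio, regressions)
#'   use terminal branches only; the branch table always holds all
#'   branches.
#' @param eps degeneracy threshold passed to [project_contributions()].
#' @return a list of class `dichromatism_decomposition`: `fit_male`,
#'   `fit_female`, `branches` (the contribution table), `rate_ratio`,
#'   `ratio_model`, `slopes`, `penalty` (per sex), `tips_only`.
#' @export
decompose_dichromatism <- function(tree, centroids, penalty = NULL,
                                   tips_only = FALSE, eps = 1e-9) {
  prep <- .ridge_prep(tree)
  cm <- .centroid_matrices(centroids)
  if (!setequal(rownames(cm$male), prep$tree$tip.label))
    stop("centroid species must match the tree's tip labels exactly.")
  M <- .align_traits(prep, cm$male)
  F_ <- .align_traits(prep, cm$female)
  # one penalty for both sexes: shrinkage scales rate magnitudes, so the
  # sex comparison requires identical shrinkage
  if (is.null(penalty)) penalty <- .select_penalty_joint(prep, list(M, F_))
  fit_m <- .fit_with_prep(prep, M, penalty)
  fit_f <- .fit_with_prep(prep, F_, penalty)
  ctab <- project_contributions(branch_sex_rates(fit_m, fit_f), eps = eps)
  sel <- if (tips_only) ctab[ctab$is_tip, , drop = FALSE] else ctab
  structure(list(fit_male = fit_m, fit_female = fit_f, branches = ctab,
                 rate_ratio = sex_rate_ratio(sel),
                 ratio_model = ratio_vs_dichromatism(sel),
                 slopes = contribution_slopes(sel),
                 penalty = c(male = fit_m$penalty, female = fit_f$penalty),
                 tips_only = tips_only),
            class = "dichromatism_decomposition")
}

#' @noRd
.fit_with_prep <- function(prep, Y, penalty = NULL) {
  Y <- .align_traits(prep, Y)
  if (is.null(penalty)) penalty <- .select_penalty(prep, Y)
  structure(c(.ridge_solve(prep, Y, penalty), list(tree = prep$tree)),
            class = "ridge_fit")
}

#' @export
print.dichromatism_decomposition <- function(x, ...) {
  cat("Dichromatism decomposition",
      if (x$tips_only) "(terminal branches)" else "(all branches)", "\n")
  cat(sprintf("  rate ratio ||m||/||f||: %.3f\n", x$rate_ratio))
  cat(sprintf("  log-ratio ~ dichromatism slope: %.4f\n", x$ratio_model$slope))
  cat(sprintf("  contribution slopes: male %.3f, female %.3f\n",
              x$slopes["male"], x$slopes["female"]))
  cat(sprintf("  ridge penalties: male %.3g, female %.3g\n",
              x$penalty["male"], x$penalty["female"]))
  invisible(x)
}

# Fast summary-statistics path used by the permutation machinery: same
# computations as decompose_dichromatism() but no data frames or lm().
#' @noRd
.decompose_stats <- function(prep, M, F_, tips_only = FALSE,
                             penalty = NULL, eps = 1e-9) {
  lam <- penalty %||% .select_penalty_joint(prep, list(M, F_))
  sm <- .ridge_solve(prep, M, lam)
  sf <- .ridge_solve(prep, F_, lam)
  edge <- prep$tree$edge
  Mv <- sm$branch_rates; Fv <- sf$branch_rates
  Danc <- sm$node_states[edge[, 1], , drop = FALSE] -
    sf$node_states[edge[, 1], , drop = FALSE]
  aD <- .norm_rows(Danc)
  m_mag <- .norm_rows(Mv); f_mag <- .norm_rows(Fv)
  sel <- if (tips_only) edge[, 2] <= prep$ntip else rep(TRUE, nrow(edge))
  ratio <- mean(m_mag[sel]) / mean(f_mag[sel])
  keep <- sel & m_mag > 1e-12 & f_mag > 1e-12
  lr <- log(m_mag[keep] / f_mag[keep])
  ratio_slope <- stats::cov(aD[keep], lr) / stats::var(aD[keep])
  deg <- aD < eps
  Dhat <- Danc / ifelse(deg, 1, aD)
  s_m <- ifelse(deg, 0, rowSums(Mv * Dhat))
  s_f <- ifelse(deg, 0, -rowSums(Fv * Dhat))
  s <- s_m + s_f
  ok <- sel & !deg
  vs <- stats::var(s[ok])
  c(rate_ratio = ratio,
    ratio_dichromatism_slope = ratio_slope,
    male_contribution_slope = stats::cov(s_m[ok], s[ok]) / vs,
    female_contribution_slope = stats::cov(s_f[ok], s[ok]) / vs)
}
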