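# Significance testing by sex-label permutation: refit the entire
# pipeline on datasets with the sexes randomly swapped within species.

#' Randomly swap sex labels within species
#'
#' Each species independently has its male and female rows exchanged with
#' probability 0.5. The phylogeny and the pair of colors present in each
#' species are untouched, so the permutation destroys any sex-specific
#' signal while preserving phylogenetic structure and the colors present
#' in each clade.
#'
#' @param centroids centroid table (`species_id`, `sex`, `L`, `a`, `b`);
#'   each species must have exactly one male and one female row.
#' @param seed optional integer seed.
#' @return a centroid table of the same shape with labels permuted.
#' @export
permute_sexes <- function(centroids, seed = NULL) {
  centroids <- .check_centroids(centroids)
  if (!is.null(seed)) set.seed(seed)
  sp <- sort(unique(centroids$species_id))
  swap <- sp[stats::runif(length(sp)) < 0.5]
  flip <- centroids$species_id %in% swap
  centroids$sex[flip] <- ifelse(centroids$sex[flip] == "male",
                                "female", "male")
  centroids
}

#' Two-tailed permutation p-value
#'
#' `p = (1 + #{|null - center| >= |observed - center|}) / (R + 1)`: the
#' null draws are re-centered at the statistic's theoretical null value
#' (0 for slopes measured as departures from zero, 0.5 for contribution
#' slopes, 0 for log rate ratios) and compared with the observed departure
#' in absolute value. The add-one rule counts the observed dataset as one
#' of the permutations, so p is never 0.
#'
#' @param observed observed statistic (scalar).
#' @param null_values numeric vector of the statistic on permuted data.
#' @param center the statistic's theoretical value under the null
#'   (default 0).
#' @return a p-value in (0, 1\].
#' @export
permutation_pvalue <- function(observed, null_values, center = 0) {
  if (!length(null_values)) stop("`null_values` must be non-empty.")
  if (!is.finite(observed)) stop("`observed` must be finite.")
  R <- length(null_values)
  (1 + sum(abs(null_values - center) >= abs(observed - center))) / (R + 1)
}

#' Sex-swap permutation study of the dichromatism statistics
#'
#' Recomputes the requested statistics on `R` datasets with sex labels
#' randomly swapped within species ([permute_sexes()]), refitting both
#' sexes' ridge regressions from scratch on every permuted dataset
#' (penalties re-selected by cross-validation each time, so the null
#' pipeline mirrors the observed pipeline end to end). Two-tailed
#' p-values follow [permutation_pvalue()] with the natural null centers:
#' the rate ratio is compared on the log scale about log(1) = 0,
#' regression slopes about 0, contribution slopes about 0.5. Replicate
#' seeds are drawn once from `seed`, so individual replicates are
#' reproducible.
#'
#' @param tree a rooted `phylo` matching the centroid table.
#' @param centroids centroid table (`species_id`, `sex`, `L`, `a`, `b`).
#' @param statistics which statistics to track; any subset of
#'   `"rate_ratio"`, `"ratio_dichromatism_slope"`,
#'   `"male_contribution_slope"`, `"female_contribution_slope"`.
#' @param R number of permutations (default 1000).
#' @param seed optional master seed.
#' @param tips_only restrict the summary statistics to terminal branches.
#' @param penalty optional fixed ridge penalty (both sexes, all
#'   replicates); default re-selects per dataset.
#' @return a list of class `permutation_study`; one element per statistic
#'   with fields `statistic`, `observed`, `null_values` (length `R`),
#'   `center`, `p_two_tailed`.
#' @export
run_permutation_study <- function(tree, centroids,
                                  statistics = c("rate_ratio",
                                                 "ratio_dichromatism_slope",
                                                 "male_contribution_slope",
                                                 "female_contribution_slope"),
                                  R = 1000, seed = NULL, tips_only = FALSE,
                                  penalty = NULL) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (R < 1) stop("`R` must be at least 1.")
  prep <- .ridge_prep(tree)
  cm <- .centroid_matrices(centroids)
  if (!setequal(rownames(cm$male), prep$tree$tip.label))
    stop("centroid species must match the tree's tip labels exactly.")
  cm$male <- .align_traits(prep, cm$male)
  cm$female <- .align_traits(prep, cm$female)
  observed <- .decompose_stats(prep, cm$male, cm$female,
                               tips_only = tips_only, penalty = penalty)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)
  nsp <- nrow(cm$male)
  null <- matrix(NA_real_, R, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    sw <- stats::runif(nsp) < 0.5
    Mp <- cm$male; Fp <- cm$female
    Mp[sw, ] <- cm$female[sw, ]
    Fp[sw, ] <- cm$male[sw, ]
    null[r, ] <- tryCatch(
      .decompose_stats(prep, Mp, Fp, tips_only = tips_only,
                       penalty = penalty),
      error = function(e) stop("permutation replicate ", r, " failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  centers <- c(rate_ratio = 0, ratio_dichromatism_slope = 0,
               male_contribution_slope = 0.5,
               female_contribution_slope = 0.5)
  out <- lapply(statistics, function(st) {
    obs <- observed[[st]]
    nv <- null[, st]
    if (st == "rate_ratio") {
      p <- permutation_pvalue(log(obs), log(nv), center = 0)
    } else {
      p <- permutation_pvalue(obs, nv, center = centers[[st]])
    }
    list(statistic = st, observed = unname(obs), null_values = unname(nv),
         center = if (st == "rate_ratio") 1 else unname(centers[[st]]),
         p_two_tailed = p)
  })
  names(out) <- statistics
  structure(out, class = "permutation_study", R = R)
}

#' @export
print.permutation_study <- function(x, ...) {
  cat("Sex-swap permutation study (R =", attr(x, "R"), ")\n")
  for (el in x) {
    q <- stats::quantile(el$null_values, c(0.025, 0.5, 0.975))
    cat(sprintf("  %-26s obs = %8.4f  null median = %8.4f [%.4f, %.4f]  p = %.4g\n",
                el$statistic, el$observed, q[2], q[1], q[3],
                el$p_two_tailed))
  }
  invisible(x)
}
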