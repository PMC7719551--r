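# End-to-end orchestration: colors -> per-sex ridge fits -> dichromatism
# dynamics -> permutation test -> phylogenetic signal, with logging and a
# reproducibility report.

#' Read / write a centroid table
#'
#' The interchange format of the package: a CSV with columns
#' `species_id`, `sex` ("male"/"female"), `L`, `a`, `b`, one row per
#' species and sex.
#'
#' @param path file path.
#' @return `read_centroids()` returns a validated data frame.
#' @export
read_centroids <- function(path) {
  .check_centroids(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_centroids
#' @param centroids a centroid table.
#' @export
write_centroids <- function(centroids, path) {
  utils::write.csv(.check_centroids(centroids), path, row.names = FALSE)
  invisible(path)
}

#' Run the full dichromatism analysis
#'
#' Sequences every stage on one centroid table: the dichromatism
#' decomposition (per-sex ridge fits, rate ratio, log-ratio ~
#' dichromatism regression, contribution slopes), the sex-swap
#' permutation test, and Pagel's lambda for per-species dichromatism.
#' All intermediates are written to `out_dir` (branch table, node states
#' and branch rates per sex, permutation nulls, summary JSON) together
#' with a `run.log`. Stage seeds are derived deterministically from the
#' master seed (two sub-seeds drawn up front, one for the permutation
#' study and one for the bootstrap), so a rerun with the same
#' configuration reproduces the summary JSON byte for byte.
#'
#' @param config a list, or the path to a YAML file, with fields:
#'   `tree` (Newick path or `phylo`), `centroids` (CSV path or data
#'   frame), `out_dir` (required), and optionally `surface` (label echoed
#'   to outputs, default `"dorsal"`), `R_perm` (default 1000), `R_boot`
#'   (default 1000), `seed` (default 1), `tips_only` (default `FALSE`),
#'   `penalty` (default `NULL`, cross-validated).
#' @return invisibly, a list of class `run_report` with the summary
#'   statistics, configuration echo, package version, per-stage timings,
#'   and output paths.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  cfg <- list(surface = config$surface %||% "dorsal",
              R_perm = config$R_perm %||% 1000,
              R_boot = config$R_boot %||% 1000,
              seed = config$seed %||% 1,
              tips_only = isTRUE(config$tips_only),
              penalty = config$penalty)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf("stage ", name, " started")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs retained in ", out_dir, ")", call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    logf("stage ", name, sprintf(" done in %.2f s", el))
    attr(res, "elapsed") <- el
    res
  }

  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2)

  inputs <- stage("load", {
    tree <- if (inherits(config$tree, "phylo")) config$tree
            else ape::read.tree(config$tree)
    centroids <- if (is.data.frame(config$centroids)) config$centroids
                 else read_centroids(config$centroids)
    list(tree = tree, centroids = .check_centroids(centroids))
  })

  dec <- stage("decompose", {
    d <- decompose_dichromatism(inputs$tree, inputs$centroids,
                                penalty = cfg$penalty,
                                tips_only = cfg$tips_only)
    utils::write.csv(d$branches[, c("branch_id", "parent", "child",
                                    "length", "is_tip", "m_mag", "f_mag",
                                    "anc_D_mag", "s_m", "s_f", "s",
                                    "degenerate")],
                     file.path(out_dir, "branches.csv"), row.names = FALSE)
    write_ridge_fit(d$fit_male,
                    file.path(out_dir, "node_states_male.csv"),
                    file.path(out_dir, "branch_rates_male.csv"))
    write_ridge_fit(d$fit_female,
                    file.path(out_dir, "node_states_female.csv"),
                    file.path(out_dir, "branch_rates_female.csv"))
    d
  })

  perm <- stage("permutation", {
    ps <- run_permutation_study(inputs$tree, inputs$centroids,
                                R = cfg$R_perm, seed = sub_seeds[1],
                                tips_only = cfg$tips_only,
                                penalty = cfg$penalty)
    nulls <- as.data.frame(lapply(ps, `[[`, "null_values"))
    utils::write.csv(nulls, file.path(out_dir, "permutation_nulls.csv"),
                     row.names = FALSE)
    ps
  })

  lam <- stage("signal", {
    d <- species_dichromatism(inputs$centroids)
    pagel_lambda(inputs$tree,
                 stats::setNames(d$D_mag, d$species_id),
                 R_boot = cfg$R_boot, seed = sub_seeds[2])
  })

  summary <- list(
    surface = cfg$surface,
    rate_ratio = dec$rate_ratio,
    ratio_dichromatism_slope = dec$ratio_model$slope,
    ratio_dichromatism_intercept = dec$ratio_model$intercept,
    male_contribution_slope = unname(dec$slopes["male"]),
    female_contribution_slope = unname(dec$slopes["female"]),
    penalty = as.list(dec$penalty),
    p_values = lapply(perm, `[[`, "p_two_tailed"),
    pagel_lambda = list(estimate = lam$lambda, ci_low = lam$ci[1],
                        ci_high = lam$ci[2], R_boot = lam$R_boot),
    config = c(list(out_dir = out_dir), cfg),
    version = as.character(utils::packageVersion("dichroma")))
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("report written to ", file.path(out_dir, "report.json"))

  report <- c(summary,
              list(timings = c(load = attr(inputs, "elapsed"),
                               decompose = attr(dec, "elapsed"),
                               permutation = attr(perm, "elapsed"),
                               signal = attr(lam, "elapsed")),
                   decomposition = dec, permutation = perm, lambda = lam,
                   out_dir = out_dir))
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("dichroma run report (", x$surface, ")\n", sep = "")
  cat(sprintf("  rate ratio ||m||/||f||: %.3f (p = %.4g)\n", x$rate_ratio,
              x$p_values$rate_ratio %||% NA))
  cat(sprintf("  log-ratio ~ dichromatism slope: %.4f (p = %.4g)\n",
              x$ratio_dichromatism_slope,
              x$p_values$ratio_dichromatism_slope %||% NA))
  cat(sprintf("  contribution slopes: male %.3f / female %.3f (p = %.4g)\n",
              x$male_contribution_slope, x$female_contribution_slope,
              x$p_values$male_contribution_slope %||% NA))
  cat(sprintf("  Pagel's lambda: %.3f [%.3f, %.3f]\n",
              x$pagel_lambda$estimate, x$pagel_lambda$ci_low,
              x$pagel_lambda$ci_high))
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
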