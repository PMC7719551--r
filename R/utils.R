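# shared validation helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.check_tree <- function(tree, call = sys.call(-1)) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be an object of class \"phylo\" (see ape::read.tree).")
  if (!ape::is.rooted(tree))
    stop("`tree` must be rooted.")
  if (is.null(tree$edge.length))
    stop("`tree` must have branch lengths (in Myr).")
  if (anyDuplicated(tree$tip.label))
    stop("tip labels must be unique.")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0))
    stop("all branch lengths must be strictly positive; a zero-length ",
         "branch has an unidentifiable rate. Collapse zero-length ",
         "branches (e.g. ape::di2multi) before fitting.")
  invisible(tree)
}

# label nodes: tips by tip label, internal nodes as "N<number>"
#' @noRd
.node_labels <- function(tree) {
  c(tree$tip.label, paste0("N", ape::Ntip(tree) + seq_len(tree$Nnode)))
}

# A centroid table has one male and one female row per species.
#' @noRd
.check_centroids <- function(centroids) {
  centroids <- as.data.frame(centroids)
  need <- c("species_id", "sex", "L", "a", "b")
  miss <- setdiff(need, names(centroids))
  if (length(miss))
    stop("centroid table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(centroids$sex %in% c("male", "female")))
    stop("`sex` must be \"male\" or \"female\".")
  tab <- table(centroids$species_id, centroids$sex)
  bad <- rownames(tab)[tab[, "male"] != 1 | tab[, "female"] != 1]
  if (length(bad))
    stop("each species needs exactly one male and one female row; offending ",
         "species: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  if (any(!is.finite(as.matrix(centroids[, c("L", "a", "b")]))))
    stop("centroid coordinates must be finite.")
  centroids
}

# split a centroid table into per-sex matrices with species rownames
#' @noRd
.centroid_matrices <- function(centroids) {
  centroids <- .check_centroids(centroids)
  out <- lapply(c("male", "female"), function(s) {
    d <- centroids[centroids$sex == s, , drop = FALSE]
    m <- as.matrix(d[, c("L", "a", "b")])
    rownames(m) <- d$species_id
    m[sort(rownames(m)), , drop = FALSE]
  })
  names(out) <- c("male", "female")
  out
}

#' @noRd
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
.norm_rows <- function(m) sqrt(rowSums(m^2))
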