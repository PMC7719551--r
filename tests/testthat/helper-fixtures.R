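# Fixtures are built in code: small trees, Brownian traits, and centroid
# tables with controllable sex structure.

tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

balanced_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# Brownian tip traits simulated by direct traversal (independent of the
# package's own generator), optionally with one branch given a jump.
bm_tips <- function(tree, sigma = 1, seed = 1, jump_branch = NA,
                    jump = 0) {
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  inc <- stats::rnorm(nrow(tree$edge), 0, sigma * sqrt(tree$edge.length))
  if (!is.na(jump_branch)) inc[jump_branch] <- inc[jump_branch] + jump
  s <- numeric(ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge)))
    s[tree$edge[k, 2]] <- s[tree$edge[k, 1]] + inc[k]
  stats::setNames(s[seq_len(ntip)], tree$tip.label)
}

# centroid table: shared Brownian color plus i.i.d. per-tip sex
# deviations (within-species sex labels exchangeable by construction)
exchangeable_centroids <- function(tree, sd_sex = 4, seed = 1) {
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  shared <- cbind(L = 50 + bm_tips(tree, 3, seed),
                  a = bm_tips(tree, 3, seed + 1),
                  b = bm_tips(tree, 3, seed + 2))
  mk <- function(sex) data.frame(
    species_id = tree$tip.label, sex = sex,
    shared + matrix(stats::rnorm(ntip * 3, 0, sd_sex), ntip, 3,
                    dimnames = list(NULL, c("L", "a", "b"))))
  rbind(mk("male"), mk("female"))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
}

# apply a 3-D rotation to the color coordinates of a centroid table
rotate_centroids <- function(centroids, R) {
  centroids[, c("L", "a", "b")] <-
    as.matrix(centroids[, c("L", "a", "b")]) %*% R
  centroids
}

swap_sex_labels <- function(centroids) {
  centroids$sex <- ifelse(centroids$sex == "male", "female", "male")
  centroids
}
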