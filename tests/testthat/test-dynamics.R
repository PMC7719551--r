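# helper: hand-built branch table with known geometry
fake_rates <- function(M, F_, D) {
  n <- nrow(M)
  data.frame(branch_id = paste0("b", seq_len(n)), parent = "N",
             child = paste0("b", seq_len(n)), length = 1, is_tip = TRUE,
             m_L = M[, 1], m_a = M[, 2], m_b = M[, 3],
             f_L = F_[, 1], f_a = F_[, 2], f_b = F_[, 3],
             m_mag = sqrt(rowSums(M^2)), f_mag = sqrt(rowSums(F_^2)),
             D_L = D[, 1], D_a = D[, 2], D_b = D[, 3],
             anc_D_mag = sqrt(rowSums(D^2)))
}

test_that("branch tables pair the sexes' rates with parent-node dichromatism", {
  tree <- balanced_tree()
  set.seed(1)
  mk <- function(seed) {
    set.seed(seed)
    matrix(rnorm(12, 50, 10), 4, 3,
           dimnames = list(tree$tip.label, c("L", "a", "b")))
  }
  fm <- fit_rrphylo(tree, mk(2), penalty = 1)
  ff <- fit_rrphylo(tree, mk(3), penalty = 1)
  tab <- branch_sex_rates(fm, ff)
  expect_equal(nrow(tab), nrow(tree$edge))
  expect_equal(sum(tab$is_tip), 4)
  # ancestral D is male minus female state at the branch's parent node
  k <- 3
  par <- tab$parent[k]
  expect_equal(unname(unlist(tab[k, c("D_L", "D_a", "D_b")])),
               unname(fm$node_states[par, ] - ff$node_states[par, ]))
  expect_equal(tab$m_mag, unname(sqrt(rowSums(fm$branch_rates^2))))
  # different trees are rejected
  y3 <- mk(2)[1:3, ]
  rownames(y3) <- c("A", "B", "C")
  other <- fit_rrphylo(tiny_tree(), y3, penalty = 1)
  expect_error(branch_sex_rates(fm, other), "same tree")
})

test_that("scalar projections decompose dichromatism change", {
  Dhat <- c(1, 0, 0)
  tab <- fake_rates(M = rbind(2 * Dhat, c(1, 1, 0), c(0.5, -2, 1)),
                    F_ = rbind(c(0, 0, 0), c(1, 1, 0), c(-0.5, 0, 2)),
                    D = rbind(Dhat, Dhat, Dhat))
  ct <- project_contributions(tab)
  expect_equal(ct$s_m[1], 2)
  expect_equal(ct$s_f[1], 0)
  expect_equal(ct$s[1], 2)
  # shared change (m = f) cannot alter dichromatism to first order
  expect_equal(ct$s[2], 0)
  expect_equal(ct$s, ct$s_m + ct$s_f, tolerance = 1e-10)
  # degenerate D: flagged and zeroed
  deg <- fake_rates(M = matrix(1, 1, 3), F_ = matrix(0, 1, 3),
                    D = matrix(0, 1, 3))
  cd <- project_contributions(deg)
  expect_true(cd$degenerate)
  expect_equal(cd$s, 0)
})

test_that("s equals the first-order change in ||D|| for small steps", {
  set.seed(2)
  errs <- sapply(c(1, 0.1, 0.01, 0.001), function(h) {
    mx <- 0
    for (i in 1:20) {
      cm <- runif(3, -20, 20); cf <- runif(3, -20, 20)
      m <- rnorm(3); f <- rnorm(3)
      D0 <- cm - cf
      tab <- fake_rates(M = matrix(m, 1), F_ = matrix(f, 1),
                        D = matrix(D0, 1))
      s <- project_contributions(tab)$s
      dD <- (sqrt(sum((cm + m * h - cf - f * h)^2)) - sqrt(sum(D0^2))) / h
      mx <- max(mx, abs(s - dD) / max(abs(s), 1e-12))
    }
    mx
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 0.01)
})

test_that("rate ratio behaves under identity, scaling, and degeneracy", {
  set.seed(3)
  M <- matrix(rnorm(30), 10, 3)
  D <- matrix(rnorm(30), 10, 3)
  expect_equal(sex_rate_ratio(fake_rates(M, M, D)), 1)
  expect_equal(sex_rate_ratio(fake_rates(2 * M, M, D)), 2)
  expect_error(sex_rate_ratio(fake_rates(M, 0 * M, D)), "undefined")
})

test_that("the log-ratio slope equals the stacked interaction coefficient", {
  set.seed(4)
  tr <- simulate_tree(60, seed = 41)
  sim <- simulate_colors(tr, scenario_params(n_tips = 60, drive = "male",
                                             seed = 42))
  dec <- decompose_dichromatism(sim$tree, sim$centroids)
  tab <- dec$branches
  keep <- tab$m_mag > 1e-12 & tab$f_mag > 1e-12
  stacked <- data.frame(
    log_rate = c(log(tab$m_mag[keep]), log(tab$f_mag[keep])),
    dich = rep(tab$anc_D_mag[keep], 2),
    sex = rep(c(1, 0), each = sum(keep)))
  inter <- unname(coef(lm(log_rate ~ dich * sex, stacked))["dich:sex"])
  expect_equal(dec$ratio_model$slope, inter, tolerance = 1e-10)
  # constant ratio across branches -> slope 0
  M <- matrix(rnorm(30), 10, 3)
  flat <- ratio_vs_dichromatism(fake_rates(2 * M, M,
                                           matrix(rnorm(30), 10, 3)))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_error(ratio_vs_dichromatism(fake_rates(M[1:2, ], M[1:2, ],
                                                M[1:2, ])), "fewer than 3")
})

test_that("contribution slopes sum to one and fail loudly when degenerate", {
  set.seed(5)
  D <- matrix(rnorm(60), 20, 3)
  Dhat <- D / sqrt(rowSums(D^2))
  s_target <- rnorm(20)
  M <- 0.5 * s_target * Dhat          # s_m = 0.5 * s
  F_ <- -0.5 * s_target * Dhat        # s_f = 0.5 * s
  sl <- contribution_slopes(project_contributions(fake_rates(M, F_, D)))
  expect_equal(unname(sl), c(0.5, 0.5), tolerance = 1e-10)
  # slopes always sum to 1
  r <- project_contributions(fake_rates(matrix(rnorm(60), 20, 3),
                                        matrix(rnorm(60), 20, 3), D))
  expect_equal(sum(contribution_slopes(r)), 1, tolerance = 1e-10)
  # no variance in s
  flat <- project_contributions(fake_rates(Dhat, 0 * Dhat, D))
  expect_error(contribution_slopes(flat), "degenerate")
  # monochromatic-everywhere data: decomposition refuses to summarize
  tree <- simulate_tree(20, seed = 51)
  mono <- simulate_colors(tree, scenario_params(
    n_tips = 20, sigma_sex = 0, drive = "none", mono_fraction = 0,
    seed = 52))
  expect_error(decompose_dichromatism(mono$tree, mono$centroids,
                                      penalty = 1), "degenerate")
})

test_that("the decomposition is invariant under rotations and mirrors sex swaps", {
  tr <- simulate_tree(40, seed = 61)
  sim <- simulate_colors(tr, scenario_params(n_tips = 40, drive = "male",
                                             seed = 62))
  dec <- decompose_dichromatism(sim$tree, sim$centroids, penalty = 5)
  # common rotation of all colors: pure geometry, s unchanged
  rot <- rotate_centroids(sim$centroids, random_rotation(63))
  dec_rot <- decompose_dichromatism(sim$tree, rot, penalty = 5)
  expect_equal(dec_rot$branches$s, dec$branches$s, tolerance = 1e-8)
  expect_equal(dec_rot$rate_ratio, dec$rate_ratio, tolerance = 1e-8)
  expect_equal(dec_rot$slopes, dec$slopes, tolerance = 1e-8)
  # relabeling the sexes inverts the ratio and exchanges the slopes
  dec_sw <- decompose_dichromatism(sim$tree, swap_sex_labels(sim$centroids),
                                   penalty = 5)
  expect_equal(dec_sw$rate_ratio, 1 / dec$rate_ratio, tolerance = 1e-10)
  expect_equal(unname(dec_sw$slopes["male"]), unname(dec$slopes["female"]),
               tolerance = 1e-10)
  expect_equal(dec_sw$ratio_model$slope, -dec$ratio_model$slope,
               tolerance = 1e-10)
  expect_equal(dec_sw$branches$s, dec$branches$s, tolerance = 1e-10)
})
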