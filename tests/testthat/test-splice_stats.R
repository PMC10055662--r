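test_that("Beta-Binomial MLE recovers mu and phi from simulated cells", {
  sim <- simulate_cells(500, 2, 6, seed = 3)
  fit <- fit_betabinom(sim$E, sim$G)
  expect_lt(abs(fit$mu - 0.25), 0.05)
  expect_lt(abs(fit$phi - 1 / 9), 0.05)
  expect_true(fit$converged)

  # no inter-cell variation: phi collapses to 0
  G <- rep(200L, 50)
  E <- rep(100L, 50)
  f0 <- fit_betabinom(E, G)
  expect_lt(f0$phi, 0.02)
  expect_lt(abs(f0$mu - 0.5), 0.01)

  # bimodal all-or-none cells: phi near 1
  G <- rep(100L, 60)
  E <- rep(c(0L, 100L), 30)
  f1 <- fit_betabinom(E, G)
  expect_gt(f1$phi, 0.9)

  # degenerate all-zero data: boundary fit flagged
  fb <- fit_betabinom(rep(0L, 20), rep(10L, 20))
  expect_true(fb$boundary)

  expect_error(fit_betabinom(c(1, 2), c(3, 4)), "informative cells")
})

test_that("phi equals the Beta variance identity for the fitted law", {
  sim <- simulate_cells(300, 5, 5, seed = 9)
  fit <- fit_betabinom(sim$E, sim$G)
  a <- fit$alpha; b <- fit$beta
  var_beta <- a * b / ((a + b)^2 * (a + b + 1))
  expect_equal(fit$phi, var_beta / (fit$mu * (1 - fit$mu)), tolerance = 1e-10)
})

test_that("likelihood estimation adjusts for coverage where moments do not", {
  # heterogeneous coverage: half the cells shallow (G=10), half deep
  set.seed(21)
  reps <- 30
  bias_mle <- bias_mom <- numeric(reps)
  for (r in seq_len(reps)) {
    psi <- rbeta(300, 5, 5)  # phi truth = 1/11
    G <- rep(c(10L, 100L), 150)
    E <- rbinom(300, G, psi)
    bias_mle[r] <- fit_betabinom(E, G)$phi - 1 / 11
    bias_mom[r] <- fit_psi_moments(E, G)$phi - 1 / 11
  }
  expect_gt(mean(bias_mom), 0.02)              # moments inflate phi
  expect_lt(abs(mean(bias_mle)), 0.02)         # likelihood stays unbiased
  expect_lt(abs(mean(bias_mle)), mean(bias_mom))
})

test_that("phi recovery improves with the number of cells", {
  set.seed(31)
  rmse <- function(n, reps = 15) {
    sqrt(mean(vapply(seq_len(reps), function(r) {
      sim <- simulate_cells(n, 2, 6, seed = 1000 + 37 * r + n)
      (fit_betabinom(sim$E, sim$G)$phi - 1 / 9)^2
    }, numeric(1))))
  }
  expect_lt(rmse(600), rmse(60))
})

test_that("exon selection applies strict cell and inclusive G thresholds", {
  counts <- data.frame(
    cell = paste0("c", 1:62), gene_id = "g",
    exon = rep(1:2, each = 31),
    E = 5L, G = c(rep(10L, 30), 5L, rep(10L, 31)),
    stringsAsFactors = FALSE)
  # exon 1 has G >= 10 in exactly 30 cells: excluded ("over 30" strict);
  # exon 2 reaches 31 cells: kept
  sel <- select_exons(counts, min_G = 10, min_cells = 30)
  expect_equal(sel$exon, 2L)

  # post-fit filter: extreme mean or wide phi CI excluded
  tab <- data.frame(gene_id = "g", exon = 1:3,
                    mu = c(0.95, 0.5, 0.5), phi = 0.1,
                    phi_lo = c(0.0, 0.05, 0.05),
                    phi_hi = c(0.1, 0.30, 0.20))
  kept <- filter_phi_estimates(tab)
  expect_equal(kept$exon, 3L)
})

test_that("bootstrap phi intervals behave at the degenerate extremes", {
  # constant psi: the interval hugs zero
  G <- rep(100L, 80)
  E <- rbinom(80, G, 0.5)
  est <- estimate_phi(E, G, n_boot = 50, seed = 2)
  expect_lt(est$phi_ci[2], 0.05)
  # n_boot = 0: point estimate only, flagged
  est0 <- estimate_phi(E, G, n_boot = 0)
  expect_true(est0$unreliable)
  expect_true(all(is.na(est0$mu_ci)))
})

test_that("GLRT is null on duplicated data and sensitive to swapped shapes", {
  sim <- simulate_cells(150, 3, 3, seed = 5)
  same <- glrt_diff_splice(sim$E, sim$G, sim$E, sim$G)
  expect_lt(same$lrt, 1e-4)
  expect_gt(same$p_value, 0.99)

  s1 <- simulate_cells(100, 8, 2, seed = 6)
  s2 <- simulate_cells(100, 2, 8, seed = 7)
  diff <- glrt_diff_splice(s1$E, s1$G, s2$E, s2$G)
  expect_lt(diff$p_value, 1e-10)
  expect_gt(diff$delta_mu, 0.5)
  expect_gte(diff$lrt, 0)
})

test_that("Wasserstein distances match closed forms", {
  expect_equal(w1_quantile(function(q) qbeta(q, 2, 5),
                           function(q) qbeta(q, 2, 5)), 0)
  # Beta(1,1) vs a point mass at 0: mean of Uniform(0,1)
  expect_equal(w1_quantile(function(q) qbeta(q, 1, 1), function(q) 0 * q),
               0.5, tolerance = 1e-3)
  # masses at 0 and 1: maximal distance on [0,1]
  expect_equal(w1_quantile(function(q) 0 * q, function(q) 0 * q + 1), 1)

  sim1 <- simulate_cells(200, 6, 2, seed = 8)
  sim2 <- simulate_cells(200, 2, 6, seed = 9)
  ws <- wasserstein_psi(sim1$E, sim1$G, sim2$E, sim2$G, n_boot = 30, seed = 1)
  expect_gt(ws$w1, 0.3)
  expect_true(ws$ci[1] <= ws$w1 && ws$w1 <= ws$ci[2])
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  q <- fdr_bh(c(0.001, 0.01, 0.2, 0.9))
  expect_true(all(diff(q[order(c(0.001, 0.01, 0.2, 0.9))]) >= 0))
})

test_that("diff_splice tests candidate exons with FDR control", {
  set.seed(55)
  cells1 <- paste0("a", 1:60)
  cells2 <- paste0("b", 1:60)
  mk <- function(cells, alpha, beta, exon) {
    psi <- rbeta(length(cells), alpha, beta)
    G <- 10L + rpois(length(cells), 10)
    data.frame(cell = cells, gene_id = "g", exon = exon,
               E = rbinom(length(cells), G, psi), G = G,
               stringsAsFactors = FALSE)
  }
  counts <- rbind(mk(cells1, 8, 2, 1), mk(cells2, 2, 8, 1),
                  mk(cells1, 3, 3, 2), mk(cells2, 3, 3, 2))
  groups <- data.frame(cell = c(cells1, cells2),
                       group = rep(c("g1", "g2"), each = 60))
  res <- diff_splice(counts, groups, min_G = 10, min_cells = 30)
  expect_equal(nrow(res), 2L)
  expect_lt(res$q_value[res$exon == 1], 0.05)
  expect_gt(res$q_value[res$exon == 2], 0.05)
  expect_gt(res$wasserstein[res$exon == 1],
            res$wasserstein[res$exon == 2])
})
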