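## Beta-Binomial model of percent-spliced-in.
##
## For a given exon, the inclusion count in cell c is E_c ~ Binomial(G_c,
## psi_c) with psi_c ~ Beta(alpha, beta) across cells. The Beta mean mu =
## alpha/(alpha+beta) is the bulk-level percent-spliced-in; the
## dispersion phi = var(psi)/[mu(1-mu)] = 1/(alpha+beta+1) in [0,1]
## separates intra-cell heterogeneity (low phi: isoforms co-expressed
## within cells) from inter-cell heterogeneity (high phi: bimodal,
## cell-exclusive usage). Likelihood-based estimation adjusts for unequal
## per-cell coverage G_c, which naive moments on E_c/G_c does not.

#' Beta-Binomial log-likelihood
#' @param E,G inclusion and informative counts per cell.
#' @param alpha,beta Beta shape parameters.
#' @return Total log-likelihood.
#' @keywords internal
betabinom_loglik <- function(E, G, alpha, beta) {
  sum(lchoose(G, E) + lbeta(E + alpha, G - E + beta) - lbeta(alpha, beta))
}

#' Fit the Beta-Binomial model to one exon
#'
#' Maximum likelihood in the (logit mu, log(alpha+beta)) parameterisation
#' over cells with `G > 0`. Degenerate data (all `E == 0` or all
#' `E == G`) yield a flagged boundary fit.
#'
#' @param E,G numeric vectors of inclusion and informative counts.
#' @param min_cells minimum informative cells required (default 5).
#' @return List of class `betabinom_fit`: `alpha`, `beta`, `mu`, `phi`,
#'   `loglik`, `converged`, `boundary`, `n_cells`.
#' @examples
#' set.seed(1)
#' psi <- rbeta(300, 2, 6)
#' G <- 10 + rpois(300, 10)
#' E <- rbinom(300, G, psi)
#' fit <- fit_betabinom(E, G)
#' c(mu = fit$mu, phi = fit$phi)  # truth: 0.25, 1/9
#' @export
fit_betabinom <- function(E, G, min_cells = 5L) {
  keep <- !is.na(E) & !is.na(G) & G > 0
  E <- E[keep]; G <- G[keep]
  n <- length(E)
  if (n < min_cells) stop("need at least ", min_cells, " informative cells")
  if (all(E == 0) || all(E == G)) {
    eps <- 1 / (sum(G) + 2)
    mu <- if (all(E == 0)) eps else 1 - eps
    s <- 1e4
    fit <- list(alpha = mu * s, beta = (1 - mu) * s, mu = mu,
                phi = 1 / (s + 1),
                loglik = betabinom_loglik(E, G, mu * s, (1 - mu) * s),
                converged = FALSE, boundary = TRUE, n_cells = n)
    class(fit) <- "betabinom_fit"
    return(fit)
  }
  psi <- E / G
  mu0 <- min(max(mean(psi), 1e-3), 1 - 1e-3)
  v0 <- var(psi)
  phi0 <- min(max(v0 / (mu0 * (1 - mu0)), 0.01), 0.95)
  s0 <- 1 / phi0 - 1
  nll <- function(th) {
    mu <- 1 / (1 + exp(-th[1]))
    s <- exp(th[2])
    a <- mu * s; b <- (1 - mu) * s
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e10)
    -betabinom_loglik(E, G, a, b)
  }
  th0 <- c(log(mu0 / (1 - mu0)), log(s0))
  opt <- optim(th0, nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  mu <- 1 / (1 + exp(-opt$par[1]))
  s <- exp(opt$par[2])
  boundary <- mu < 1e-5 || mu > 1 - 1e-5 || s > 1e6 || s < 1e-6
  fit <- list(alpha = mu * s, beta = (1 - mu) * s, mu = mu, phi = 1 / (s + 1),
              loglik = -opt$value, converged = opt$convergence == 0,
              boundary = boundary, n_cells = n)
  class(fit) <- "betabinom_fit"
  fit
}

#' Method-of-moments psi/phi baseline (no coverage adjustment)
#'
#' Treats the per-cell ratios `E/G` as direct observations of psi. Kept
#' as a comparison baseline: with heterogeneous coverage the binomial
#' sampling noise in `E/G` inflates the apparent inter-cell variance, so
#' this estimator is biased upward in phi.
#'
#' @param E,G counts per cell.
#' @return List with `mu`, `phi`.
#' @export
fit_psi_moments <- function(E, G) {
  keep <- !is.na(E) & !is.na(G) & G > 0
  psi <- E[keep] / G[keep]
  mu <- mean(psi)
  phi <- if (mu <= 0 || mu >= 1) 0 else var(psi) / (mu * (1 - mu))
  list(mu = mu, phi = min(max(phi, 0), 1))
}

#' Coverage filter for candidate exons
#'
#' Retains (gene, exon) pairs with `G >= min_G` in strictly more than
#' `min_cells` cells.
#'
#' @param counts data.frame from [build_count_matrices()].
#' @param min_G per-cell informative-count threshold (inclusive,
#'   default 10).
#' @param min_cells cell-count threshold (strict, default 30).
#' @return data.frame with `gene_id`, `exon`, `n_cells`.
#' @export
select_exons <- function(counts, min_G = 10L, min_cells = 30L) {
  ok <- counts$G >= min_G
  key <- interaction(counts$gene_id, counts$exon, drop = TRUE)
  n <- tapply(ok, key, sum)
  first <- !duplicated(key)
  out <- data.frame(gene_id = counts$gene_id[first],
                    exon = counts$exon[first],
                    n_cells = as.integer(n[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  out[out$n_cells > min_cells, , drop = FALSE]
}

#' Post-estimation filter on mean and dispersion confidence
#'
#' Keeps exons with `mu_lo < mu_hat < mu_hi` and a phi confidence
#' interval narrower than `max_ci_width`.
#'
#' @param phi_table data.frame from [estimate_phi_table()].
#' @param mu_lo,mu_hi bounds on the estimated mean (default 0.1, 0.9).
#' @param max_ci_width maximum phi CI width (default 0.2).
#' @return Filtered data.frame.
#' @export
filter_phi_estimates <- function(phi_table, mu_lo = 0.1, mu_hi = 0.9,
                                 max_ci_width = 0.2) {
  w <- phi_table$phi_hi - phi_table$phi_lo
  phi_table[phi_table$mu > mu_lo & phi_table$mu < mu_hi &
              !is.na(w) & w < max_ci_width, , drop = FALSE]
}

#' Estimate mu and phi with bootstrap confidence intervals
#'
#' Point estimates from [fit_betabinom()] on all cells; percentile
#' intervals from `n_boot` refits on cells resampled with replacement.
#'
#' @param E,G counts per cell.
#' @param n_boot bootstrap replicates (default 200; 0 for point
#'   estimates only).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return List: `mu`, `phi`, `mu_ci`, `phi_ci`, `n_cells`, `unreliable`
#'   (TRUE when more than 20% of bootstrap fits failed to converge).
#' @export
estimate_phi <- function(E, G, n_boot = 200L, seed = 1L, conf = 0.95) {
  fit <- fit_betabinom(E, G)
  out <- list(mu = fit$mu, phi = fit$phi,
              mu_ci = c(NA_real_, NA_real_), phi_ci = c(NA_real_, NA_real_),
              n_cells = fit$n_cells, unreliable = n_boot == 0)
  if (n_boot > 0) {
    keep <- !is.na(E) & !is.na(G) & G > 0
    E <- E[keep]; G <- G[keep]
    n <- length(E)
    set.seed(seed)
    bm <- bp <- rep(NA_real_, n_boot)
    bad <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(fit_betabinom(E[idx], G[idx]), error = function(e) NULL)
      if (is.null(fb)) { bad <- bad + 1L; next }
      if (!fb$converged && !fb$boundary) bad <- bad + 1L
      bm[b] <- fb$mu; bp[b] <- fb$phi
    }
    a <- (1 - conf) / 2
    out$mu_ci <- unname(quantile(bm, c(a, 1 - a), na.rm = TRUE))
    out$phi_ci <- unname(quantile(bp, c(a, 1 - a), na.rm = TRUE))
    out$unreliable <- bad > 0.2 * n_boot
  }
  out
}

#' Per-exon mu/phi table for all candidate exons
#'
#' @param counts data.frame from [build_count_matrices()].
#' @param min_G,min_cells coverage filter (see [select_exons()]).
#' @param n_boot,seed bootstrap settings (see [estimate_phi()]).
#' @return data.frame with one row per candidate exon: `gene_id`, `exon`,
#'   `n_cells`, `mu`, `phi`, `mu_lo`, `mu_hi`, `phi_lo`, `phi_hi`,
#'   `unreliable`.
#' @export
estimate_phi_table <- function(counts, min_G = 10L, min_cells = 30L,
                               n_boot = 200L, seed = 1L) {
  cand <- select_exons(counts, min_G, min_cells)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    sel <- counts$gene_id == cand$gene_id[i] & counts$exon == cand$exon[i] &
      counts$G >= min_G
    est <- estimate_phi(counts$E[sel], counts$G[sel], n_boot = n_boot,
                        seed = seed + i)
    data.frame(gene_id = cand$gene_id[i], exon = cand$exon[i],
               n_cells = est$n_cells, mu = est$mu, phi = est$phi,
               mu_lo = est$mu_ci[1], mu_hi = est$mu_ci[2],
               phi_lo = est$phi_ci[1], phi_hi = est$phi_ci[2],
               unreliable = est$unreliable, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), exon = integer(0),
                      n_cells = integer(0), mu = numeric(0), phi = numeric(0),
                      mu_lo = numeric(0), mu_hi = numeric(0),
                      phi_lo = numeric(0), phi_hi = numeric(0),
                      unreliable = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Generalized likelihood ratio test for differential splicing
#'
#' Tests H0: both cell groups share the same Beta(alpha, beta) law for
#' their cell-specific percent-spliced-in, against separate laws. The
#' statistic `2 [ll(g1) + ll(g2) - ll(pooled)]` is referred to a
#' chi-square with 2 degrees of freedom. Because both shape parameters
#' are tested, the procedure is sensitive to changes in dispersion as
#' well as in mean; the observed difference is decomposed into
#' `delta_mu` and `delta_phi` for interpretation.
#'
#' @param E1,G1 counts for group 1.
#' @param E2,G2 counts for group 2.
#' @return List: `lrt`, `p_value`, `delta_mu`, `delta_phi`, `fit1`,
#'   `fit2`, `fit0`, `flagged` (boundary fit in either group).
#' @export
glrt_diff_splice <- function(E1, G1, E2, G2) {
  fit1 <- fit_betabinom(E1, G1)
  fit2 <- fit_betabinom(E2, G2)
  fit0 <- fit_betabinom(c(E1, E2), c(G1, G2))
  lrt <- max(0, 2 * (fit1$loglik + fit2$loglik - fit0$loglik))
  list(lrt = lrt,
       p_value = stats::pchisq(lrt, df = 2, lower.tail = FALSE),
       delta_mu = fit1$mu - fit2$mu,
       delta_phi = fit1$phi - fit2$phi,
       fit1 = fit1, fit2 = fit2, fit0 = fit0,
       flagged = fit1$boundary || fit2$boundary)
}

#' W1 distance between two distributions given by quantile functions
#'
#' Evaluates `mean(|Q1(q) - Q2(q)|)` on a midpoint quantile grid, the
#' standard quantile-coupling form of the 1-Wasserstein distance.
#'
#' @param qf1,qf2 vectorised quantile functions on (0, 1).
#' @param n_grid grid size (default 1000).
#' @return Numeric distance.
#' @export
w1_quantile <- function(qf1, qf2, n_grid = 1000L) {
  q <- (seq_len(n_grid) - 0.5) / n_grid
  mean(abs(qf1(q) - qf2(q)))
}

#' Wasserstein distance between two fitted psi distributions
#'
#' W1 between the fitted Beta laws of two groups, with a percentile
#' bootstrap interval over cell resampling.
#'
#' @param E1,G1,E2,G2 counts per group.
#' @param n_boot bootstrap replicates (default 200; 0 disables the CI).
#' @param seed RNG seed.
#' @param n_grid quantile grid size.
#' @return List: `w1`, `ci` (lo, hi or NA).
#' @export
wasserstein_psi <- function(E1, G1, E2, G2, n_boot = 200L, seed = 1L,
                            n_grid = 1000L) {
  f1 <- fit_betabinom(E1, G1)
  f2 <- fit_betabinom(E2, G2)
  w <- w1_quantile(function(q) qbeta(q, f1$alpha, f1$beta),
                   function(q) qbeta(q, f2$alpha, f2$beta), n_grid)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    n1 <- length(E1); n2 <- length(E2)
    bw <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      i1 <- sample.int(n1, n1, replace = TRUE)
      i2 <- sample.int(n2, n2, replace = TRUE)
      fb <- tryCatch({
        g1 <- fit_betabinom(E1[i1], G1[i1])
        g2 <- fit_betabinom(E2[i2], G2[i2])
        w1_quantile(function(q) qbeta(q, g1$alpha, g1$beta),
                    function(q) qbeta(q, g2$alpha, g2$beta), n_grid)
      }, error = function(e) NA_real_)
      bw[b] <- fb
    }
    ci <- unname(quantile(bw, c(0.025, 0.975), na.rm = TRUE))
  }
  list(w1 = w, ci = ci)
}

#' Benjamini-Hochberg q-values
#' @param p numeric vector of p-values.
#' @return Monotone step-up q-values.
#' @export
fdr_bh <- function(p) {
  p.adjust(p, method = "BH")
}

#' Differential splicing between two cell groups, all candidate exons
#'
#' @param counts data.frame from [build_count_matrices()].
#' @param cell_groups data.frame with `cell` and `group` columns (exactly
#'   two groups).
#' @param min_G,min_cells coverage filter applied within each group
#'   (see [select_exons()]).
#' @param n_boot bootstrap replicates for the Wasserstein CI (default 0,
#'   point estimate only).
#' @param seed RNG seed.
#' @return data.frame with one row per tested exon: `gene_id`, `exon`,
#'   `lrt`, `p_value`, `q_value`, `wasserstein`, `w_lo`, `w_hi`,
#'   `delta_mu`, `delta_phi`, `flagged`.
#' @export
diff_splice <- function(counts, cell_groups, min_G = 10L, min_cells = 30L,
                        n_boot = 0L, seed = 1L) {
  groups <- sort(unique(cell_groups$group))
  if (length(groups) != 2) stop("exactly two cell groups are required")
  counts$group <- cell_groups$group[match(counts$cell, cell_groups$cell)]
  c1 <- counts[counts$group == groups[1], , drop = FALSE]
  c2 <- counts[counts$group == groups[2], , drop = FALSE]
  cand1 <- select_exons(c1, min_G, min_cells)
  cand2 <- select_exons(c2, min_G, min_cells)
  cand <- merge(cand1[, c("gene_id", "exon")], cand2[, c("gene_id", "exon")])
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    s1 <- c1$gene_id == cand$gene_id[i] & c1$exon == cand$exon[i] &
      c1$G >= min_G
    s2 <- c2$gene_id == cand$gene_id[i] & c2$exon == cand$exon[i] &
      c2$G >= min_G
    gl <- glrt_diff_splice(c1$E[s1], c1$G[s1], c2$E[s2], c2$G[s2])
    ws <- wasserstein_psi(c1$E[s1], c1$G[s1], c2$E[s2], c2$G[s2],
                          n_boot = n_boot, seed = seed + i)
    data.frame(gene_id = cand$gene_id[i], exon = cand$exon[i],
               lrt = gl$lrt, p_value = gl$p_value,
               wasserstein = ws$w1, w_lo = ws$ci[1], w_hi = ws$ci[2],
               delta_mu = gl$delta_mu, delta_phi = gl$delta_phi,
               flagged = gl$flagged, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), exon = integer(0),
                      lrt = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), wasserstein = numeric(0),
                      w_lo = numeric(0), w_hi = numeric(0),
                      delta_mu = numeric(0), delta_phi = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- fdr_bh(out$p_value)
  out[order(out$p_value), c("gene_id", "exon", "lrt", "p_value", "q_value",
                            "wasserstein", "w_lo", "w_hi", "delta_mu",
                            "delta_phi", "flagged")]
}
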