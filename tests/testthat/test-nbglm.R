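test_that("size factors are median-of-ratios with median-1 rescaling", {
  m <- mk_counts(c(10, 20, 30, 60, 5, 10), c("g1", "g2", "g3"), c("s1", "s2"))
  f <- size_factors(m)
  expect_equal(unname(f[2] / f[1]), 2)             # scale equivariance
  ident <- cbind(m[, 1], m[, 1]); dimnames(ident) <- dimnames(m)
  expect_equal(unname(size_factors(ident)), c(1, 1))

  # independent median-of-ratios oracle on a random NB matrix
  set.seed(6)
  r <- matrix(rnbinom(500, mu = 100, size = 10), 50, 10,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  oracle <- {
    pos <- apply(r, 1, function(x) all(x > 0))
    ref <- exp(rowMeans(log(r[pos, ])))
    raw <- apply(r[pos, ], 2, function(col) median(col / ref))
    raw / median(raw)
  }
  expect_equal(size_factors(r), oracle, tolerance = 1e-12)

  # fallback: no all-positive gene, but every gene positive in 9/10 samples
  r2 <- r + 1L
  r2[cbind(1:50, rep(1:10, length.out = 50))] <- 0L
  expect_error(size_factors(r2, fallback = FALSE), "fallback is disabled")
  f2 <- size_factors(r2)
  expect_true(all(f2 > 0))
  expect_equal(unname(median(f2)), 1)
})

test_that("saturated one-factor NB fits recover size-factor-weighted group means", {
  set.seed(9)
  grp <- factor(rep(c("a", "b"), each = 4))
  sf <- c(1, 1.2, 0.8, 1, 1.5, 0.7, 1, 1.1)
  y <- rnbinom(8, mu = 100 * sf, size = 20)
  # with dispersion fixed at 0 the saturated one-factor score equations have
  # the closed-form solution mu_i = s_i * sum(y_g)/sum(s_g) per group
  fit <- fit_nb_glm(y, grp, offset = log(sf), dispersion = 0)
  mu <- fit$fitted
  for (g in c("a", "b")) {
    expect_equal(unname(mu[grp == g] / sf[grp == g]),
                 rep(sum(y[grp == g]) / sum(sf[grp == g]), 4),
                 tolerance = 1e-8)
  }
  # all-equal counts with zero offsets: fitted means are the group means
  y2 <- rep(c(7, 12), each = 4)
  fit2 <- fit_nb_glm(y2, grp)
  expect_equal(unname(fit2$fitted), rep(c(7, 12), each = 4), tolerance = 1e-6)
})

test_that("NB fit agrees with MASS::glm.nb as an independent route", {
  set.seed(14)
  grp <- factor(rep(c("a", "b", "c"), each = 6))
  y <- rnbinom(18, mu = rep(c(50, 120, 80), each = 6), size = 8)
  fit <- fit_nb_glm(y, grp)
  ref <- MASS::glm.nb(y ~ grp)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-3)
  # estimation routes differ (Cox-Reid vs ML) but should land in the same
  # neighbourhood
  expect_equal(fit$dispersion, 1 / ref$theta, tolerance = 0.5)
  expect_true(fit$converged)
})

test_that("Poisson-generated counts yield near-zero dispersion estimates", {
  set.seed(15)
  grp <- factor(rep(c("a", "b"), each = 4))
  hits <- 0
  for (i in 1:200) {
    y <- rpois(8, 100)
    fit <- fit_nb_glm(y, grp)
    if (fit$dispersion < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("LRT equals the direct likelihood-evaluation oracle on a toy model", {
  # two tissues, 2 reps each, fixed dispersion, zero offsets: the saturated
  # one-factor fit has group-mean fitted values, so both likelihoods are
  # hand-computable with dnbinom
  y <- c(4, 8, 30, 22)
  grp <- factor(c("t1", "t1", "t2", "t2"))
  alpha <- 0.1
  full <- fit_nb_glm(y, grp, dispersion = alpha)
  red <- fit_nb_glm(y, matrix(1, 4, 1), dispersion = alpha)
  lt <- lrt_test(full, red, df = 1)
  ll_full <- sum(dnbinom(y, size = 1 / alpha, mu = rep(c(6, 26), each = 2), log = TRUE))
  ll_red <- sum(dnbinom(y, size = 1 / alpha, mu = rep(mean(y), 4), log = TRUE))
  expect_equal(lt$stat, 2 * (ll_full - ll_red), tolerance = 1e-8)
  expect_equal(lt$p_value, pchisq(2 * (ll_full - ll_red), 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical models give stat 0, p 1; df must be positive
  expect_equal(lrt_test(full, full, 1), list(stat = 0, p_value = 1))
  expect_error(lrt_test(full, red, 0), "df")
})

test_that("two-group DE is null on equal groups and exchangeable within groups", {
  cfg <- atlas_sim_config(n_genes = 60, tissues = c("control", "stress"),
                          frac_enriched = 0, frac_stable = 0, seed = 17)
  sim <- simulate_atlas(cfg)
  sim$samples$condition <- sim$samples$tissue
  de <- de_two_group(sim$counts, sim$samples, c("control", "stress"))
  expect_true(all(c("gene_id", "log2_fold_change", "p_value", "q_value", "is_deg")
                  %in% colnames(de)))
  expect_true(all(de$is_deg == (de$q_value <= 0.05 & abs(de$log2_fold_change) >= 1),
                  na.rm = TRUE))

  # permuting sample order within groups changes nothing
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)
  sam2 <- sim$samples[perm, ]
  de2 <- de_two_group(sim$counts, sam2, c("control", "stress"))
  expect_equal(de2$p_value, de$p_value, tolerance = 1e-9)
  expect_equal(de2$log2_fold_change, de$log2_fold_change, tolerance = 1e-9)

  # antisymmetry under contrast reversal
  de3 <- de_two_group(sim$counts, sim$samples, c("stress", "control"))
  expect_equal(de3$log2_fold_change, -de$log2_fold_change, tolerance = 1e-9)
  expect_equal(de3$p_value, de$p_value, tolerance = 1e-9)

  # identical normalized counts in both groups (equal library sizes, each
  # gene constant across samples): lfc exactly 0 and never a DEG
  set.seed(18)
  m3 <- matrix(rep(as.integer(sample(20:200, 30)), each = 8), 30, 8,
               byrow = TRUE,
               dimnames = list(paste0("h", 1:30), sim$samples$sample_id))
  de4 <- de_two_group(m3, sim$samples, c("control", "stress"))
  expect_equal(de4$log2_fold_change, rep(0, nrow(de4)))
  expect_false(any(de4$is_deg))

  expect_error(de_two_group(sim$counts, sim$samples[c(1, 5:8), ],
                            c("control", "stress")), "fewer than 2")
})

test_that("DEG overlap counts match set algebra", {
  mk_de <- function(genes, deg, lfc) {
    structure(data.frame(gene_id = genes, log2_fold_change = lfc,
                         is_deg = deg, stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  genes <- paste0("g", 1:20)
  set.seed(19)
  for (i in 1:20) {
    d1 <- mk_de(genes, runif(20) < 0.4, rnorm(20))
    d2 <- mk_de(genes, runif(20) < 0.4, rnorm(20))
    ov <- overlap_degs(d1, d2)
    up1 <- genes[d1$is_deg & d1$log2_fold_change > 0]
    up2 <- genes[d2$is_deg & d2$log2_fold_change > 0]
    dn1 <- genes[d1$is_deg & d1$log2_fold_change < 0]
    dn2 <- genes[d2$is_deg & d2$log2_fold_change < 0]
    expect_equal(ov$up_shared, length(intersect(up1, up2)))
    expect_equal(ov$up_only_1, length(setdiff(up1, up2)))
    expect_equal(ov$down_only_2, length(setdiff(dn2, dn1)))
    expect_equal(ov$down_shared, length(intersect(dn1, dn2)))
  }
  # identical and disjoint edge cases
  d <- mk_de(genes, rep(TRUE, 20), rep(2, 20))
  ov <- overlap_degs(d, d)
  expect_equal(ov$up_shared, 20)
  expect_equal(ov$up_only_1 + ov$up_only_2 + ov$down_shared, 0)
  expect_error(overlap_degs(d, mk_de(paste0("h", 1:20), rep(TRUE, 20), rep(1, 20))),
               "different gene universes")
})
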