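test_that("condition proportions are pooled counts over the pooled total", {
  counts <- mk_counts(c(30, 30, 10, 10,
                        10, 10, 5, 5,
                        5, 5, 2, 3,
                        5, 5, 3, 2),
                      c("q_a", "q_b", "q_c", "q_d"),
                      c("control_rep1", "control_rep2", "stress_rep1", "stress_rep2"))
  samples <- mk_samples(c("control", "stress"), n_rep = 2)
  q <- list(A = "q_a", B = "q_b", C = "q_c", D = "q_d")
  p <- condition_proportions(q, counts, samples, "control")
  expect_equal(unclass(p)[1:4], c(A = 0.6, B = 0.2, C = 0.1, D = 0.1))
  expect_equal(attr(p, "pooled_total"), 100)
  # property: equals counts/total and sums to 1, random draws
  set.seed(11)
  for (i in 1:25) {
    m <- mk_counts(sample(0:50, 16, replace = TRUE), rownames(counts),
                   colnames(counts))
    m[, 1] <- m[, 1] + 1L   # keep pooled totals positive
    p <- condition_proportions(q, m, samples, "control")
    pooled <- rowSums(m[, 1:2])
    expect_equal(as.numeric(p), as.numeric(pooled / sum(pooled)), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  zero <- counts; zero[, 3:4] <- 0L
  expect_error(condition_proportions(q, zero, samples, "stress"), "zero")
})

test_that("allelic bias classes respect the 0.25 / 0.5 boundaries", {
  expect_equal(allelic_bias(c(A = .25, B = .25, C = .25, D = .25)),
               list(bias = 0, dominance_class = "balanced"))
  b <- allelic_bias(c(A = .6, B = .2, C = .1, D = .1))
  expect_equal(b$bias, 0.5)
  expect_equal(b$dominance_class, "mild")        # 0.5 is inclusive to mild
  expect_equal(allelic_bias(c(A = .8, B = .1, C = .05, D = .05))$dominance_class,
               "strong")
  expect_equal(allelic_bias(c(A = .4, B = .15, C = .3, D = .15))$dominance_class,
               "mild")                           # bias exactly 0.25 -> mild
})

test_that("chi-square contrast equals the hand formula and drops dead columns", {
  flat <- contrast_chi_square(c(10, 10, 10, 10), c(10, 10, 10, 10))
  expect_equal(flat$stat, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$df, 3L)

  swap <- contrast_chi_square(c(100, 0, 0, 0), c(0, 100, 0, 0))
  expect_equal(swap$stat, 200)   # 2x2 reduced table
  expect_equal(swap$df, 1L)
  expect_lt(swap$p_value, 1e-40)

  # independent oracle: sum((O-E)^2/E) and the chi-square survival function
  oracle <- function(x, y) {
    tab <- rbind(x, y); tab <- tab[, colSums(tab) > 0, drop = FALSE]
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    s <- sum((tab - E)^2 / E)
    c(s, 1 - pchisq(s, ncol(tab) - 1))
  }
  got <- contrast_chi_square(c(30, 20, 10, 40), c(10, 20, 30, 40))
  want <- oracle(c(30, 20, 10, 40), c(10, 20, 30, 40))
  expect_equal(got$stat, want[1], tolerance = 1e-10)
  expect_equal(got$p_value, want[2], tolerance = 1e-10)

  # cross-check against stats::chisq.test on random non-degenerate tables
  set.seed(3)
  for (i in 1:50) {
    x <- sample(1:60, 4); y <- sample(1:60, 4)
    got <- contrast_chi_square(x, y)
    ref <- suppressWarnings(chisq.test(rbind(x, y), correct = FALSE))
    expect_equal(got$stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
  }

  # degenerate: one shared live column -> undefined p, flagged
  deg <- contrast_chi_square(c(5, 0, 0, 0), c(9, 0, 0, 0))
  expect_true(is.na(deg$p_value))
  expect_error(contrast_chi_square(c(0, 0, 0, 0), c(1, 1, 1, 1)), "positive")
})

test_that("BH adjustment handles the textbook cases and NA reinsertion", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  q <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.02)))  # NA not counted as a test
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  q20 <- bh_adjust(stats::runif(20))
  expect_true(all(q20 >= 0 & q20 <= 1))
})

test_that("rank switching and delta follow the max-proportion definition", {
  p0 <- c(A = .4, B = .3, C = .2, D = .1)
  same <- rank_and_delta(p0, p0)
  expect_false(same$rank_switch)
  expect_equal(same$delta, 0)
  expect_equal(same$effect_class, "none")

  sw <- rank_and_delta(c(A = .40, B = .30, C = .20, D = .10),
                       c(A = .25, B = .55, C = .10, D = .10))
  expect_true(sw$rank_switch)
  expect_equal(sw$delta, 0.15)
  expect_equal(sw$effect_class, "moderate")

  tie <- rank_and_delta(c(A = .3, B = .3, C = .2, D = .2), p0)
  expect_equal(tie$top_control, "A")   # alphabetical tie-break
  expect_true(tie$tie_control)

  big <- rank_and_delta(c(A = .30, B = .25, C = .25, D = .20),
                        c(A = .10, B = .60, C = .15, D = .15))
  expect_equal(big$effect_class, "pronounced")
})

test_that("ASE statistics are invariant under haplotype relabeling and condition swap", {
  cfg <- quartet_sim_config(n_quartets = 30, seed = 9)
  sim <- simulate_quartets(cfg)
  q <- select_quartets(sim$orthogroups)
  res <- run_ase(q, sim$counts, sim$samples, c("control", "stress"))

  # permute the haplotype columns of the quartet table (relabeling A-D)
  perm <- c("C", "A", "D", "B")
  qp <- q; qp[, c("A", "B", "C", "D")] <- q[, perm]
  resp <- run_ase(qp, sim$counts, sim$samples, c("control", "stress"))
  expect_equal(resp$table$bias_control, res$table$bias_control, tolerance = 1e-12)
  expect_equal(resp$table$p_value, res$table$p_value, tolerance = 1e-12)
  expect_equal(resp$table$delta, res$table$delta, tolerance = 1e-12)
  # the new A slot holds the old C gene, so proportions follow the genes
  expect_equal(resp$table$pA_control, res$table$pC_control, tolerance = 1e-12)

  # swapping condition labels preserves chi2, p, switch flag and delta
  sw_samples <- sim$samples
  sw_samples$condition <- ifelse(sw_samples$condition == "control", "stress", "control")
  res_sw <- run_ase(q, sim$counts, sw_samples, c("control", "stress"))
  expect_equal(res_sw$table$chi2_stat, res$table$chi2_stat, tolerance = 1e-12)
  expect_equal(res_sw$table$p_value, res$table$p_value, tolerance = 1e-12)
  expect_equal(res_sw$table$rank_switch, res$table$rank_switch)
  expect_equal(res_sw$table$delta, res$table$delta, tolerance = 1e-12)
})

test_that("run_ase summary counts are internally consistent and reruns are identical", {
  cfg <- quartet_sim_config(n_quartets = 60, seed = 13)
  sim <- simulate_quartets(cfg)
  q <- select_quartets(sim$orthogroups)
  r1 <- run_ase(q, sim$counts, sim$samples, c("control", "stress"))
  r2 <- run_ase(q, sim$counts, sim$samples, c("control", "stress"))
  expect_identical(r1$table, r2$table)
  s <- r1$summary
  expect_equal(s$control_balanced + s$control_mild + s$control_strong, s$n_quartets)
  expect_equal(s$n_rank_switch, sum(r1$table$rank_switch))
  expect_gte(s$n_delta_ge_10, s$n_delta_ge_20)
  expect_true(all(r1$table$q_value >= r1$table$p_value, na.rm = TRUE))
  # bias CDF covers both conditions over the analysed quartets
  expect_equal(nrow(r1$bias_cdf), 2L * s$n_quartets)
  expect_equal(max(r1$bias_cdf$cdf), 1)
  # empty input warns and returns empty tables
  expect_warning(r0 <- run_ase(q[0, ], sim$counts, sim$samples,
                               c("control", "stress"), filter = FALSE),
                 "no quartets")
  expect_equal(nrow(r0$table), 0L)
})
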