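# independent enumeration oracle for the exact Mann-Whitney p value:
# U computed by direct pairwise comparison (wins + half-ties), null
# distribution by enumerating every assignment of pooled values to x
mw_oracle_p <- function(x, y) {
  u_stat <- function(xx, yy)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  pooled <- c(x, y)
  nx <- length(x)
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(ix)
    u_stat(pooled[ix], pooled[-ix]))
  tol <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + tol), mean(u_all >= u_obs - tol)))
}

test_that("the normality gate routes distributions correctly", {
  gauss <- vapply(1:20, function(s) {
    set.seed(s); as.character(normality_gate(rnorm(50), rnorm(50)))
  }, character(1))
  expect_gte(mean(gauss == "parametric"), 0.9)
  heavy <- vapply(1:20, function(s) {
    set.seed(s); as.character(normality_gate(rlnorm(20, 0, 1)))
  }, character(1))
  expect_gte(mean(heavy == "nonparametric"), 0.8)
  expect_warning(g <- normality_gate(rep(1, 10)), "degenerate")
  expect_identical(as.character(g), "nonparametric")
  expect_warning(g2 <- normality_gate(c(1, 2)), "n < 3")
  expect_identical(as.character(g2), "nonparametric")
})

test_that("Welch t matches hand computation", {
  r <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(unname(unlist(r$df)), 4, tolerance = 1e-9)
  # identical samples: t = 0, p = 1
  x <- c(1.2, 3.4, 5.6, 2.1)
  r2 <- welch_t(x, x)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  # large separation with tiny variance
  set.seed(1)
  a <- rnorm(6, 0, 0.01)
  r3 <- welch_t(a, a + 10)
  expect_lt(r3$p, 1e-4)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("exact Mann-Whitney equals the enumeration oracle", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)  # 2/20 assignments as extreme
  expect_identical(r$method, "mann_whitney_exact")
  # perfectly interleaved symmetric groups: U = nx*ny/2, p = 1
  r2 <- mann_whitney(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(r2$statistic, 8)
  expect_equal(r2$p, 1)
  # randomized fixtures incl. ties, all group sizes with nx+ny <= 10
  set.seed(99)
  for (nx in 2:5) for (ny in 2:(10 - nx)) {
    x <- sample(1:6, nx, replace = TRUE)
    y <- sample(1:6, ny, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p, mw_oracle_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("nx=%d ny=%d", nx, ny))
  }
  # agrees with wilcox.test exact p in the tie-free case
  set.seed(3)
  x <- rnorm(5); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(11)
  x <- rnorm(6); y <- rnorm(7, 1)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(exp(x), exp(y))$p)
  m <- matrix(rnorm(21), 7, 3)
  expect_equal(friedman(m)$p, friedman(exp(m))$p)
  # Welch t is invariant under common location/scale changes
  r1 <- welch_t(x, y); r2 <- welch_t(3 * x - 5, 3 * y - 5)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches a hand sums-of-squares oracle", {
  m <- matrix(c(10, 12, 15,
                11, 14, 17,
                9, 11, 16), nrow = 3, byrow = TRUE)
  # second-path oracle: direct partition of the sums of squares
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_period <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - outer(rowMeans(m), colMeans(m), "+") + grand)^2)
  f_oracle <- (ss_period / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  r <- rm_anova(m)
  expect_equal(r$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(unname(unlist(r$df)), c(2, 4))
  expect_equal(r$p, stats::pf(f_oracle, 2, 4, lower.tail = FALSE),
               tolerance = 1e-9)
  # degenerate: identical period means, pure subject effect -> F = 0
  m0 <- matrix(rep(c(5, 7, 9), times = 3), nrow = 3)
  r0 <- rm_anova(m0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "complete|missing")
})

test_that("Friedman matches the direct rank formula", {
  # 4 subjects, 3 periods, strictly increasing within every subject:
  # column rank sums 4, 8, 12 -> chi2 = 12/(4*3*4)*(16+64+144) - 3*4*4 = 8
  m <- matrix(c(1, 2, 3,
                2, 5, 9,
                1.5, 2.5, 3.5,
                10, 20, 30), nrow = 4, byrow = TRUE)
  r <- friedman(m)
  expect_equal(r$statistic, 8, tolerance = 1e-9)
  expect_equal(unname(unlist(r$df)), 2)
  # all columns identical: degenerate, chi2 = 0
  m2 <- matrix(rep(c(3, 1, 2, 5), 3), nrow = 4)
  r2 <- friedman(m2)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  expect_true(isTRUE(r2$degenerate))
  expect_error(friedman(matrix(1:4, 2)), "3 periods")
})

test_that("gated dispatchers record the branch they chose", {
  set.seed(21)
  x <- rnorm(10); y <- rnorm(10, 2)
  r <- compare_groups(x, y)
  expect_identical(r$gate, "parametric")
  expect_identical(r$method, "welch_t")
  # heavy outliers at the study group sizes force the rank branch
  r2 <- compare_groups(c(1, 1.2, 0.9, 1.1, 60, 1.05, 0.98),
                       c(2, 2.1, 1.9, 40, 2.05))
  expect_identical(r2$gate, "nonparametric")
  expect_identical(r2$method, "mann_whitney_exact")
  m <- matrix(rnorm(28), 7, 4)
  r3 <- within_group_trend(m)
  expect_true(r3$method %in% c("rm_anova", "friedman"))
})

test_that("expression normalization divides by the animal's GAPDH", {
  rec <- data.frame(
    animal = rep(c("A1", "A2", "C1", "C2"), each = 2),
    group = rep(c("af", "af", "control", "control"), each = 2),
    gene = rep(c("GAPDH", "Hcn4"), 4),
    raw_level = c(10, 14.2, 8, 11.44, 12, 16.2, 9, 12.24))
  res <- relative_expression(rec)
  expect_equal(res$records$normalized,
               c(1.42, 1.43, 1.35, 1.36), tolerance = 1e-9)
  # raw_gene == raw_GAPDH -> normalized exactly 1
  rec1 <- data.frame(animal = c("A1", "A1"), group = "af",
                     gene = c("GAPDH", "Hcn1"), raw_level = c(7, 7))
  expect_equal(relative_expression(rec1)$records$normalized, 1)
  # zero GAPDH excludes the animal with a warning, others survive
  rec$raw_level[rec$animal == "A2" & rec$gene == "GAPDH"] <- 0
  expect_warning(res2 <- relative_expression(rec), "A2")
  expect_identical(res2$excluded, "A2")
  expect_false("A2" %in% res2$records$animal)
  expect_true(all(c("A1", "C1", "C2") %in% res2$records$animal))
})

test_that("simulated expression recovers the programmed group means", {
  raw <- simulate_expression(n_af = 7, n_control = 5, seed = 12)
  res <- relative_expression(raw)
  tgt <- ratafib:::expression_defaults()
  for (g in tgt$gene) {
    s_af <- res$summary[res$summary$gene == g & res$summary$group == "af", ]
    s_ct <- res$summary[res$summary$gene == g & res$summary$group == "control", ]
    mu_af <- tgt$af_mean[tgt$gene == g]
    mu_ct <- tgt$ctrl_mean[tgt$gene == g]
    expect_lt(abs(s_af$mean - mu_af), 2 * tgt$af_sem[tgt$gene == g],
              label = paste(g, "af mean"))
    expect_lt(abs(s_ct$mean - mu_ct), 2 * tgt$ctrl_sem[tgt$gene == g],
              label = paste(g, "control mean"))
    expect_s3_class(res$tests[[g]], "test_result")
  }
})
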