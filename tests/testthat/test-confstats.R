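test_that("welch's t matches the hand-evaluated formulas", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  res <- welch_t(a, b)
  # oracle: the Welch statistic and Welch-Satterthwaite df evaluated directly
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$statistic, -1.549, tolerance = 1e-3)
  expect_equal(res$df, 2.941, tolerance = 1e-3)
  expect_equal(res$p.value,
               2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("welch's t limit behaviour: identical groups and huge separation", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  apart <- welch_t(a, a + 1000)
  expect_lt(apart$p.value, 1e-6)
  expect_error(welch_t(a, 1), ">= 2")
  expect_error(welch_t(c(2, 2, 2), c(5, 5)), "zero variance")
})

test_that("welch's t reduces to student's t for equal sizes and variances", {
  set.seed(7)
  a <- rnorm(20); b <- a[sample(20)] + 0.5  # same variance, shifted
  w <- welch_t(a, b)
  st <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(st$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(st$parameter), tolerance = 1e-9)
})

test_that("pearson correlation endpoints and t-based p-value", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_cor(x, 2 * x)$estimate, 1)
  expect_equal(pearson_cor(x, -x + 4)$estimate, -1)
  set.seed(3)
  y <- x + rnorm(5)
  res <- pearson_cor(x, y)
  r <- cor(x, y)
  t_hand <- r * sqrt((5 - 2) / (1 - r^2))
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$p.value, 2 * pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-9)
  # affine invariance
  expect_equal(pearson_cor(3 * x - 2, 0.5 * y + 7)$estimate, res$estimate,
               tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 5)), "constant")
  expect_error(pearson_cor(x[1:2], y[1:2]), "3")
})

test_that("random pairs show near-zero correlation at large n", {
  set.seed(101)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(pearson_cor(x, y)$estimate), 0.1)
})

test_that("spearman handles monotone transforms and reversal", {
  x <- c(0.2, 1.1, 2.5, 3.1, 4.8, 6)
  expect_equal(spearman_cor(x, exp(x))$estimate, 1)
  expect_equal(spearman_cor(x, rev(x))$estimate, -1)
  set.seed(4)
  y <- x + rnorm(6, sd = 2)
  res <- spearman_cor(x, y)
  # monotone-transform invariance
  expect_equal(spearman_cor(exp(x), y^3 - 100 * y)$estimate,
               spearman_cor(x, abs(y)^3 * sign(y) - 100 * y)$estimate,
               tolerance = 1e-12)
  expect_true(res$estimate >= -1 && res$estimate <= 1)
})

test_that("tied blocks are handled by mid-ranks", {
  x <- c(1, 1, 2, 2, 3, 5)
  y <- c(2, 1, 4, 4, 6, 9)
  res <- spearman_cor(x, y)
  # brute-force mid-rank oracle: assign average ranks explicitly
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rho_hand <- cor(midrank(x), midrank(y))
  expect_equal(res$estimate, rho_hand, tolerance = 1e-12)
  t_hand <- rho_hand * sqrt((6 - 2) / (1 - rho_hand^2))
  expect_equal(res$p.value, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against the library implementation of rho
  expect_equal(res$estimate, unname(cor(x, y, method = "spearman")),
               tolerance = 1e-12)
})

test_that("confidence categories follow the three-band thresholds", {
  expect_equal(as.character(score_categories(c(99, 97, 90))),
               c("high", "medium", "low"))
  # band edges: >= 98.5 is high, exactly 96.0 is medium, just below is low
  expect_equal(as.character(score_categories(c(98.5, 96.0, 95.999))),
               c("high", "medium", "low"))
})

test_that("confidence vs flexibility recovers the planted negative link", {
  # B_i = 8 pi^2 sigma_i^2 and pLDDT decreasing in sigma_i by construction
  n <- 150
  sigma <- seq(0.05, 0.9, length.out = n)
  ens <- make_ensemble(n_residues = n, n_members = 2, sigma = sigma,
                       include_predicted = TRUE, seed = 67)
  plddt <- extract_profile(ens$structures$pred, "plddt")
  bfac_s <- ens$structures$m1
  rep <- confidence_vs_flexibility(plddt, extract_profile(bfac_s, "bfactor"))
  expect_lt(rep$spearman$estimate, 0)
  expect_lt(rep$spearman$p.value, 0.05)
  expect_equal(nrow(rep$data), n)
  expect_true(all(levels(rep$data$category) == c("high", "medium", "low")))
  g <- glance(rep)
  expect_equal(g$spearman_rho, rep$spearman$estimate)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})

test_that("PAE reduction correlates with B-factors when supplied", {
  n <- 60
  sigma <- seq(0.1, 0.8, length.out = n)
  ens <- make_ensemble(n_residues = n, n_members = 2, sigma = sigma,
                       include_predicted = TRUE, seed = 71)
  plddt <- extract_profile(ens$structures$pred, "plddt")
  bfac <- extract_profile(ens$structures$m1, "bfactor")
  # PAE rows scale with sigma, plus noise
  set.seed(72)
  pae <- outer(sigma * 10, rep(1, n)) + matrix(runif(n * n), n, n)
  rep <- confidence_vs_flexibility(plddt, bfac, pae = pae, pae_reduce = "row")
  expect_gt(rep$pearson_pae$estimate, 0.8)
  expect_lt(rep$pearson_pae$p.value, 1e-6)
  # reductions differ but all are means of the matrix
  rep_sym <- confidence_vs_flexibility(plddt, bfac, pae = pae, pae_reduce = "sym")
  expect_equal(rep_sym$data$pae, (rowMeans(pae) + colMeans(pae)) / 2)
  expect_error(confidence_vs_flexibility(plddt, bfac, pae = pae[1:5, 1:5]),
               "size")
})

test_that("degenerate confidence inputs are rejected", {
  ens <- make_ensemble(n_residues = 20, n_members = 2, sigma = 0.3,
                       include_predicted = TRUE, seed = 73)
  plddt <- extract_profile(ens$structures$pred, "plddt")
  bfac <- extract_profile(ens$structures$m1, "bfactor")
  # constant sigma means constant pLDDT -> correlation undefined
  expect_error(confidence_vs_flexibility(plddt, bfac), "constant")
})
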