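# overlap metrics, volumes and the statistical toolbox

test_that("voxel DICE equals brute-force set arithmetic on all tiny masks", {
  # every pair of subsets of a 3-voxel universe
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
  for (i in seq_len(nrow(subsets))) {
    for (j in seq_len(nrow(subsets))) {
      a <- array(unlist(subsets[i, ]), c(3, 1, 1))
      b <- array(unlist(subsets[j, ]), c(3, 1, 1))
      ia <- which(a); ib <- which(b)
      expected <- if (length(ia) + length(ib) == 0) 1
                  else 2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
      got <- if (length(ia) + length(ib) == 0)
        suppressWarnings(voxel_dice(a, b)) else voxel_dice(a, b)
      expect_equal(got, expected)
    }
  }
  expect_warning(voxel_dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
                 "empty")
})

test_that("compartment volumes count voxels and are additive", {
  lab <- array(0L, c(10, 10, 10))
  lab[seq_len(1000)] <- 2L
  cv <- compartment_volumes(label_map(lab, 1))
  expect_equal(cv$cavity_ml, 1)
  expect_equal(cv$scar_ml, 0)
  expect_equal(cv$scar_fraction, 0)
  lab[1:100] <- 1L
  lab[101:150] <- 3L
  cv2 <- compartment_volumes(label_map(lab, 1))
  expect_equal(cv2$wall_ml, 0.15)
  expect_equal(cv2$scar_ml, 0.05)
  expect_equal(cv2$scar_fraction, 1 / 3)
  expect_equal(cv2$cavity_ml + cv2$wall_ml, 1)
})

test_that("paired ratio test matches the closed-form t statistic", {
  x_in <- c(10, 12, 9, 11, 13)
  x_ex <- c(8.1, 10.4, 7.6, 9.8, 10.9)
  res <- paired_ratio_test(x_in, x_ex)
  lr <- log(x_ex / x_in)
  t_manual <- mean(lr) / (sd(lr) / sqrt(5))
  p_manual <- 2 * pt(-abs(t_manual), df = 4)
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p, p_manual, tolerance = 1e-10)
  expect_equal(res$mean_ratio, exp(mean(lr)), tolerance = 1e-12)
  expect_warning(eq <- paired_ratio_test(x_in, x_in), "zero variance")
  expect_equal(eq$mean_ratio, 1)
})

test_that("one-way ANOVA matches the closed form and handles constants", {
  g <- rep(c("a", "b", "c"), each = 7)
  set.seed(3)
  y <- rnorm(21) + rep(c(0, 1, 3), each = 7)
  res <- anova_tukey(y, g)
  # closed-form F
  gm <- mean(y)
  ssb <- 7 * sum((tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - ave(y, g))^2)
  f_manual <- (ssb / 2) / (ssw / 18)
  expect_equal(res$F, f_manual, tolerance = 1e-10)
  expect_equal(res$df, c(2, 18))
  expect_true(is.matrix(res$tukey) && nrow(res$tukey) == 3)
  const <- anova_tukey(rep(5, 21), g)
  expect_equal(const$F, 0)
  expect_equal(const$p, 1)
})

test_that("regression matches ordinary least squares", {
  x <- c(1, 2, 3, 4, 5)
  y <- 2 * x
  res <- regression(x, y)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  # textbook five-point set
  x2 <- c(1.2, 2.3, 3.1, 4.8, 5.6)
  y2 <- c(1.1, 2.9, 2.8, 5.2, 5.0)
  res2 <- regression(x2, y2)
  b <- cov(x2, y2) / var(x2)
  a <- mean(y2) - b * mean(x2)
  expect_equal(res2$slope, b, tolerance = 1e-10)
  expect_equal(res2$intercept, a, tolerance = 1e-10)
  expect_equal(res2$r_squared, cor(x2, y2)^2, tolerance = 1e-10)
  resc <- regression(x, rep(3, 5))
  expect_equal(resc$slope, 0)
  expect_equal(resc$r_squared, 0)
})

test_that("Shapiro-Wilk wrapper rejects tiny and non-normal samples", {
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  set.seed(5)
  bimodal <- c(rnorm(40, -4, 0.3), rnorm(40, 4, 0.3))
  expect_lt(shapiro_wilk(bimodal)$p, 0.01)
  normal <- rnorm(50)
  res <- shapiro_wilk(normal)
  expect_true(res$W > 0 && res$W <= 1)
})

test_that("thickness change is zero between identical meshes and binned by tau", {
  lm <- sphere_shell(20, 30, 1)
  mor <- lv_morphometry(lm)
  tc <- thickness_change_by_bin(mor$endo, mor$endo)
  expect_equal(tc$mean_pct[tc$bin == "healthy"], 0)
  expect_equal(tc$n[tc$bin == "healthy"], nrow(mor$endo$vertices))
  expect_equal(sum(tc$n), nrow(mor$endo$vertices))
})
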