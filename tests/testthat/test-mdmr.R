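test_that("Gower centering matches hand algebra and the Gram identity", {
  G <- gower_center(matrix(c(0, 2, 2, 0), 2))
  expect_equal(G, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  expect_equal(sum(diag(G)), 4 / 2)  # (1/n) sum_{i<j} d^2

  expect_equal(gower_center(matrix(0, 4, 4)), matrix(0, 4, 4), ignore_attr = TRUE)

  set.seed(31)
  for (i in 1:10) {
    X <- matrix(rnorm(8 * 3), 8)
    D <- as.matrix(dist(X))
    Xc <- scale(X, scale = FALSE)
    expect_equal(gower_center(D), tcrossprod(Xc), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sum(diag(gower_center(D))),
                 sum(D[lower.tri(D)]^2) / nrow(D), tolerance = 1e-9)
  }
})

test_that("explained and residual sums of squares decompose the total", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(10:25, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dat <- data.frame(a = rnorm(n), b = factor(sample(letters[1:3], n, TRUE)))
    fit <- mdmr(D ~ a + b, data = dat, n_perm = 0)
    expect_equal(fit$SS_expl + fit$SS_res, fit$SS_T, tolerance = 1e-9)
    expect_true(all(fit$aov_table$pseudo_R2 >= -1e-12 &
                      fit$aov_table$pseudo_R2 <= 1 + 1e-12))
  }
})

test_that("pseudo-F on a Euclidean 1-D matrix equals the classical one-way F", {
  set.seed(33)
  for (i in 1:10) {
    y <- rnorm(30, mean = rep(c(0, 0.8), each = 15))
    g <- rep(c(0, 1), each = 15)
    fit <- bivariate_mdmr(as.matrix(dist(y)), g, n_perm = 0)
    expect_equal(fit$aov_table$pseudo_F[1],
                 anova(lm(y ~ g))$`F value`[1], tolerance = 1e-9)
  }
})

test_that("a continuous covariate reproduces the linear-regression R2", {
  set.seed(34)
  y <- rnorm(40)
  x <- y + rnorm(40, 0, 2)
  fit <- bivariate_mdmr(as.matrix(dist(y)), x, n_perm = 0)
  expect_equal(fit$aov_table$pseudo_R2[1], summary(lm(y ~ x))$r.squared,
               tolerance = 1e-9)
})

test_that("an intercept-only design explains nothing", {
  set.seed(35)
  D <- as.matrix(dist(rnorm(12)))
  fit <- mdmr(D ~ 1, data = data.frame(row = 1:12), n_perm = 0)
  expect_equal(fit$aov_table$pseudo_R2[fit$aov_table$term == "Total"], 0,
               tolerance = 1e-12)
})

test_that("proportion explained is pseudo-R2 over total pseudo-R2", {
  set.seed(36)
  n <- 30
  D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dat <- data.frame(a = rnorm(n), b = rnorm(n), g = rbinom(n, 1, 0.5))
  fit <- mdmr(D ~ a + b + g, data = dat, n_perm = 99)
  tab <- fit$aov_table
  total_r2 <- tab$pseudo_R2[tab$term == "Total"]
  expect_equal(tab$proportion_explained[tab$term != "Total"],
               tab$pseudo_R2[tab$term != "Total"] / total_r2, tolerance = 1e-9)
  expect_equal(tab$proportion_explained[tab$term == "Total"], 1)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("sampled permutation p matches full enumeration at small n", {
  set.seed(37)
  n <- 6
  y <- rnorm(n)
  D <- as.matrix(dist(y))
  x <- c(0, 0, 0, 1, 1, 1)
  G <- gower_center(D)
  # exact null: all n! relabelings of the distance matrix
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  f_of <- function(pi_b) {
    Gp <- G[pi_b, pi_b]
    xc <- x - mean(x)
    ss <- drop(xc %*% Gp %*% xc) / sum(xc^2)
    (ss / 1) / ((sum(diag(Gp)) - ss) / (n - 2))
  }
  f_obs <- f_of(1:n)
  p_exact <- mean(apply(perms, 1, f_of) >= f_obs - 1e-12)
  fit <- bivariate_mdmr(D, x, n_perm = 1999, seed = 99)
  p_sampled <- fit$aov_table$p_value[fit$aov_table$term == "Total"]
  expect_lt(abs(p_sampled - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 1999) + 2 / 1999)
})

test_that("permutation inference is reproducible and warns on tiny n_perm", {
  set.seed(38)
  D <- as.matrix(dist(rnorm(15)))
  dat <- data.frame(x = rnorm(15))
  f1 <- mdmr(D ~ x, data = dat, n_perm = 199, seed = 7)
  f2 <- mdmr(D ~ x, data = dat, n_perm = 199, seed = 7)
  expect_identical(f1$aov_table, f2$aov_table)
  expect_warning(mdmr(D ~ x, data = dat, n_perm = 19, seed = 1), "coarse")
})

test_that("rank-deficient designs fail naming the collinear terms", {
  set.seed(39)
  D <- as.matrix(dist(rnorm(20)))
  dat <- data.frame(a = rnorm(20))
  dat$b <- 2 * dat$a
  expect_error(mdmr(D ~ a + b, data = dat, n_perm = 0), "collinear.*b")
})

test_that("rows with missing covariates are dropped listwise", {
  set.seed(40)
  y <- rnorm(20)
  D <- as.matrix(dist(y))
  dat <- data.frame(x = y + rnorm(20, 0, 0.5))
  dat$x[c(3, 17)] <- NA
  fit <- mdmr(D ~ x, data = dat, n_perm = 0)
  expect_identical(fit$n_dropped, 2L)
  expect_identical(fit$n, 18L)
  keep <- !is.na(dat$x)
  ref <- bivariate_mdmr(D[keep, keep], dat$x[keep], n_perm = 0)
  expect_equal(fit$aov_table$pseudo_F, ref$aov_table$pseudo_F, tolerance = 1e-12)
})

test_that("total statistics agree with an independent PERMANOVA implementation", {
  skip_if_not_installed("vegan")
  set.seed(42)
  n <- 40
  dat <- data.frame(a = rnorm(n), g = factor(sample(c("u", "v"), n, TRUE)))
  y <- dat$a * 0.7 + (dat$g == "v") * 1.2 + rnorm(n)
  D <- as.matrix(dist(cbind(y, rnorm(n))))
  fit <- mdmr(D ~ a + g, data = dat, n_perm = 0)
  ref <- vegan::adonis2(as.dist(D) ~ a + g, data = dat, permutations = 2,
                        by = NULL)
  expect_equal(fit$aov_table$pseudo_F[fit$aov_table$term == "Total"],
               ref$F[1], tolerance = 1e-9)
  expect_equal(fit$aov_table$pseudo_R2[fit$aov_table$term == "Total"],
               ref$R2[1], tolerance = 1e-9)
})

test_that("null covariates give approximately uniform p-values", {
  set.seed(43)
  pvals <- replicate(60, {
    ds <- null_dataset(n = 15, len = 60)
    fit <- bivariate_mdmr(ds$D, ds$x, n_perm = 99, seed = sample.int(1e6, 1))
    fit$aov_table$p_value[fit$aov_table$term == "Total"]
  })
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})
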