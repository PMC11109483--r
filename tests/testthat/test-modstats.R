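fit_fixture <- function(values_by_group) {
  # values_by_group: named list bait -> matrix (proteins x replicates)
  groups <- names(values_by_group)
  nreps <- vapply(values_by_group, ncol, integer(1))
  ids <- unlist(lapply(seq_along(groups), function(i) {
    paste0(groups[i], "_R", seq_len(nreps[i]))
  }))
  d <- sample_design(c(ids, "ctl1", "ctl2"),
                     c(rep(groups, nreps), "bead_control", "bead_control"),
                     c(unlist(lapply(nreps, seq_len)), 1, 2))
  v <- do.call(cbind, values_by_group)
  v <- cbind(v, matrix(0, nrow(v), 2))
  colnames(v) <- c(ids, "ctl1", "ctl2")
  rownames(v) <- paste0("P", seq_len(nrow(v)))
  m <- intensity_matrix(v, matrix(FALSE, nrow(v), ncol(v),
                                  dimnames = dimnames(v)), scale = "log2")
  list(matrix = m, design = d)
}

test_that("fit_groups reproduces hand-computed means and pooled variance", {
  fx <- fit_fixture(list(K48_Ub3 = matrix(c(1, 2, 3), 1),
                         K63_Ub3 = matrix(c(4, 5, 6), 1)))
  fit <- fit_groups(fx$matrix, fx$design, groups = c("K48_Ub3", "K63_Ub3"))
  expect_equal(unname(fit$means[1, ]), c(2, 5))
  expect_equal(unname(fit$s2), 1)  # RSS = 2 + 2, df = 4
  expect_equal(fit$df, 4L)
  # constant data has zero variance
  fx2 <- fit_fixture(list(K48_Ub3 = matrix(c(7, 7, 7), 1),
                          K63_Ub3 = matrix(c(7, 7, 7), 1)))
  expect_equal(unname(fit_groups(fx2$matrix, fx2$design,
                                 c("K48_Ub3", "K63_Ub3"))$s2), 0)
  # single group: mean over all its samples, df = n - 1
  fit1 <- fit_groups(fx$matrix, fx$design, groups = "K48_Ub3")
  expect_equal(unname(fit1$means[1, 1]), 2)
  expect_equal(fit1$df, 2L)
  expect_error(fit_groups(fx$matrix,
                          fx$design[fx$design$sample_id != "K48_Ub3_R1", ],
                          groups = "K48_Ub3"),
               NA)
})

test_that("variance-prior estimation recovers a known scaled-F generator", {
  # s2 ~ s02 * (chi2_d / d) / (chi2_d0 / d0) with d0 = 4, s02 = 1, d = 21
  set.seed(20)
  n <- 1e4; d0 <- 4; s02 <- 1; d <- 21
  sigma2 <- s02 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  prior <- estimate_variance_prior(s2, d)
  expect_lt(abs(prior$d0 - d0) / d0, 0.2)
  expect_lt(abs(prior$s02 - s02) / s02, 0.1)
})

test_that("variance-prior estimation agrees with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(21)
  n <- 5000
  sigma2 <- 0.5 * 6 / rchisq(n, 6)
  s2 <- sigma2 * rchisq(n, 10) / 10
  prior <- estimate_variance_prior(s2, 10)
  sq <- limma::squeezeVar(s2, df = 10)
  expect_equal(prior$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(prior$s02, sq$var.prior, tolerance = 0.05)
  ours <- moderate_variance(s2, 10, prior)
  expect_equal(ours, sq$var.post, tolerance = 0.05)
})

test_that("degenerate variance inputs fall back safely", {
  expect_warning(p <- estimate_variance_prior(rep(1, 5), 4), "fewer than 10")
  expect_identical(p$d0, Inf)
  # identical variances carry no excess spread: d0 = Inf
  pid <- estimate_variance_prior(rep(2, 100), 10)
  expect_identical(pid$d0, Inf)
  # pure chi-squared sampling noise: essentially no moderation left
  set.seed(22)
  s2 <- rchisq(2000, 12) / 12
  p2 <- estimate_variance_prior(s2, 12)
  expect_gt(p2$d0, 100)
  expect_equal(p2$s02, 1, tolerance = 0.05)
  # zero variances shrink to a positive moderated variance
  s3 <- c(rep(0, 5), rexp(100) + 0.5)
  p3 <- estimate_variance_prior(s3, 8)
  expect_true(all(moderate_variance(s3, 8, p3) > 0))
})

test_that("moderated t reduces to the classical pooled t at d0 = 0", {
  fx <- fit_fixture(list(K48_Ub3 = matrix(c(1, 2, 3), 1),
                         K63_Ub3 = matrix(c(4, 5, 6), 1)))
  fit <- fit_groups(fx$matrix, fx$design, c("K48_Ub3", "K63_Ub3"))
  prior0 <- variance_prior(d0 = 1e-12, s02 = 1)
  res <- moderated_t(fit, prior0, "K48_Ub3", "K63_Ub3")
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  # exact classical value: t = -3 / sqrt(2/3), p = 2 * pt(-sqrt(13.5), 4)
  expect_equal(res$statistic, -sqrt(13.5), tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-sqrt(13.5), 4), tolerance = 1e-9)
  expect_equal(res$p, 0.0214, tolerance = 5e-3)
  ct <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-6)
  expect_equal(res$p, ct$p.value, tolerance = 1e-6)
  # random fixtures: d0 -> 0 equals classical pooled t
  set.seed(30)
  for (i in 1:5) {
    a <- rnorm(4, 25, 1); b <- rnorm(4, 26, 1)
    fxr <- fit_fixture(list(K48_Ub3 = matrix(a, 1), K63_Ub3 = matrix(b, 1)))
    fr <- fit_groups(fxr$matrix, fxr$design, c("K48_Ub3", "K63_Ub3"))
    rr <- moderated_t(fr, prior0, "K48_Ub3", "K63_Ub3")
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(rr$statistic, unname(tt$statistic), tolerance = 1e-6)
    expect_equal(rr$p, tt$p.value, tolerance = 1e-6)
  }
})

test_that("moderated t limits and guards behave", {
  fx <- fit_fixture(list(K48_Ub3 = matrix(c(1, 2, 3), 1),
                         K63_Ub3 = matrix(c(4, 5, 6), 1)))
  fit <- fit_groups(fx$matrix, fx$design, c("K48_Ub3", "K63_Ub3"))
  # d0 = Inf: statistic uses the prior variance alone
  pri <- variance_prior(Inf, 2)
  res <- moderated_t(fit, pri, "K48_Ub3", "K63_Ub3")
  expect_equal(res$statistic, -3 / sqrt(2 * (1 / 3 + 1 / 3)), tolerance = 1e-9)
  expect_equal(res$df, 1e6)
  # zero fold change gives t = 0, p = 1
  fx0 <- fit_fixture(list(K48_Ub3 = matrix(c(1, 2, 3), 1),
                          K63_Ub3 = matrix(c(3, 2, 1), 1)))
  fit0 <- fit_groups(fx0$matrix, fx0$design, c("K48_Ub3", "K63_Ub3"))
  res0 <- moderated_t(fit0, variance_prior(4, 1), "K48_Ub3", "K63_Ub3")
  expect_equal(res0$logFC, 0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(moderated_t(fit, pri, "K48_Ub3", "K48_Ub3"), "differ")
})

test_that("moderated F matches classical ANOVA at d0 = 0 and t^2 at K = 2", {
  set.seed(31)
  prior0 <- variance_prior(1e-12, 1)
  for (i in 1:5) {
    vals <- list(K48_Ub3 = matrix(rnorm(4, 25), 1),
                 K63_Ub3 = matrix(rnorm(4, 25.5), 1),
                 Br_Ub3 = matrix(rnorm(4, 26), 1))
    fx <- fit_fixture(vals)
    fit <- fit_groups(fx$matrix, fx$design, names(vals))
    res <- moderated_F(fit, prior0, names(vals))
    y <- unlist(vals)
    g <- factor(rep(names(vals), each = 4))
    af <- anova(aov(y ~ g))
    expect_equal(res$statistic, af$`F value`[1], tolerance = 1e-6)
    expect_equal(res$p, af$`Pr(>F)`[1], tolerance = 1e-6)
  }
  # K = 2: F equals t^2 under the same prior
  fx2 <- fit_fixture(list(K48_Ub3 = matrix(rnorm(4, 25), 1),
                          K63_Ub3 = matrix(rnorm(4, 26), 1)))
  fit2 <- fit_groups(fx2$matrix, fx2$design, c("K48_Ub3", "K63_Ub3"))
  pri <- variance_prior(3, 0.8)
  expect_equal(moderated_F(fit2, pri, c("K48_Ub3", "K63_Ub3"))$statistic,
               moderated_t(fit2, pri, "K48_Ub3", "K63_Ub3")$statistic^2,
               tolerance = 1e-9)
  # equal group means: F = 0, p = 1
  fxe <- fit_fixture(list(K48_Ub3 = matrix(c(1, 2, 3), 1),
                          K63_Ub3 = matrix(c(2, 2, 2), 1)))
  fite <- fit_groups(fxe$matrix, fxe$design, c("K48_Ub3", "K63_Ub3"))
  rese <- moderated_F(fite, variance_prior(4, 1), c("K48_Ub3", "K63_Ub3"))
  expect_equal(rese$statistic, 0)
  expect_equal(rese$p, 1)
  expect_error(moderated_F(fite, pri, "K48_Ub3"), ">= 2 groups")
})

test_that("moderated variances shrink toward the prior", {
  set.seed(32)
  s2 <- rexp(200)
  pri <- variance_prior(5, 1)
  s2t <- moderate_variance(s2, 10, pri)
  expect_true(all(abs(s2t - 1) <= abs(s2 - 1) + 1e-12))
  expect_true(all(s2t >= pmin(s2, 1) - 1e-12 & s2t <= pmax(s2, 1) + 1e-12))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (i in 1:5) {
    p <- runif(50)
    adj <- bh_adjust(p)
    expect_equal(adj, stepup_bh(p))
    expect_true(all(adj >= p - 1e-12))
    expect_equal(order(adj[order(p)]), seq_along(p))  # rank preserved
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})
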