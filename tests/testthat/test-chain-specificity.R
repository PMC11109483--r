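sim_small <- function(seed = 7, n = 600, ...) {
  simulate_interactome(sim_config(n_proteins = n, seed = seed, ...))
}

test_that("prefilter retains every planted K48-specific interactor", {
  sim <- sim_small(seed = 7)
  pre <- preprocess_matrix(sim$matrix, sim$records, sim$design,
                           seed = 7, impute = FALSE)
  pf <- prefilter_ub_enriched(pre$filtered_linear, pre$design, seed = 7)
  planted <- sim$truth$labels$protein_id[
    sim$truth$labels$class == "K48_specific"]
  planted <- intersect(planted, protein_ids(pre$filtered_linear))
  expect_true(all(planted %in% pf$retained))
  # pass-2 matrix is restricted to the retained set and fully imputed
  expect_setequal(protein_ids(pf$matrix), pf$retained)
  expect_false(any(pf$matrix$missing))
})

test_that("background proteins pass the prefilter at a small controlled rate", {
  hits <- 0; total <- 0
  for (s in c(101, 202)) {
    sim <- sim_small(seed = s, n = 800)
    pre <- preprocess_matrix(sim$matrix, sim$records, sim$design,
                             seed = s, impute = FALSE)
    pf <- prefilter_ub_enriched(pre$filtered_linear, pre$design, seed = s)
    bg <- sim$truth$labels$protein_id[sim$truth$labels$class == "background"]
    bg <- intersect(bg, protein_ids(pre$filtered_linear))
    hits <- hits + sum(bg %in% pf$retained)
    total <- total + length(bg)
  }
  # six BH-corrected any-of contrasts at alpha = 0.05: the per-protein false
  # retention rate must stay well below the union bound of 6 * 0.05
  expect_lt(hits / total, 0.10)
})

test_that("a matrix identical to the control yields an empty prefilter set", {
  d <- full_design(n_rep = 4)
  v <- matrix(2^25, 20, nrow(d),
              dimnames = list(sprintf("P%02d", 1:20), d$sample_id))
  v <- v * matrix(2^rnorm(length(v), 0, 0.05), nrow(v))  # tiny jitter
  m <- intensity_matrix(v, matrix(FALSE, nrow(v), ncol(v),
                                  dimnames = dimnames(v)), scale = "linear")
  expect_warning(pf <- prefilter_ub_enriched(m, d, seed = 3), "no proteins")
  expect_length(pf$retained, 0)
})

test_that("the cross-bait moderated F recovers planted differential classes", {
  sim <- sim_small(seed = 13, n = 800)
  pre <- preprocess_matrix(sim$matrix, sim$records, sim$design,
                           seed = 13, impute = FALSE)
  pf <- prefilter_ub_enriched(pre$filtered_linear, pre$design, seed = 13)
  ft <- significant_across_baits(pf$matrix, pre$design)
  lab <- sim$truth$labels
  differential <- lab$protein_id[lab$class %in%
    c("K48_specific", "K63_specific", "length_dependent_K48",
      "length_dependent_K63", "branch_specific", "branch_excluded")]
  differential <- intersect(differential, pf$retained)
  expect_gte(mean(differential %in% ft$ids), 0.9)
  # a constant-profile matrix yields nothing
  d <- full_design(n_rep = 4)
  v <- matrix(rep(rnorm(15, 25, 2), nrow(d)), 15, nrow(d),
              dimnames = list(sprintf("P%02d", 1:15), d$sample_id))
  v <- v + matrix(rnorm(length(v), 0, 0.3), nrow(v))
  m <- intensity_matrix(v, matrix(FALSE, nrow(v), ncol(v),
                                  dimnames = dimnames(v)), scale = "log2")
  ft0 <- significant_across_baits(m, d)
  expect_lte(length(ft0$ids), 1L)
})

test_that("null simulations keep the F-significant fraction BH-controlled", {
  sim <- simulate_interactome(sim_config(n_proteins = 1000,
                                         class_prop = c(background = 1),
                                         mnar = FALSE, seed = 23))
  m <- impute_downshift(log2_median_normalize(sim$matrix), seed = 23)
  ft <- significant_across_baits(m, sim$design)
  expect_lte(length(ft$ids) / 1000, 0.05)
})

test_that("clustering separates planted profile archetypes perfectly", {
  # two archetypes with opposite bait preference, well separated
  d <- full_design(n_rep = 4)
  set.seed(41)
  base <- matrix(rnorm(60 * nrow(d), 25, 0.3), 60, nrow(d),
                 dimnames = list(sprintf("P%02d", 1:60), d$sample_id))
  k48_cols <- d$sample_id[grepl("^K48", d$bait)]
  k63_cols <- d$sample_id[grepl("^K63", d$bait)]
  base[1:30, k48_cols] <- base[1:30, k48_cols] + 4
  base[31:60, k63_cols] <- base[31:60, k63_cols] + 4
  m <- intensity_matrix(base, matrix(FALSE, 60, nrow(d),
                                     dimnames = dimnames(base)),
                        scale = "log2")
  cl <- cluster_profiles(m, k = 2)
  truth <- rep(1:2, each = 30)
  expect_equal(adjusted_rand(cl, truth), 1.0)
  # z-scored rows have mean 0 and sd 1
  z <- t(scale(t(base)))
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
  # duplicate rows always co-cluster
  dup <- base
  dup[2, ] <- dup[1, ]
  md <- intensity_matrix(dup, matrix(FALSE, 60, nrow(d),
                                     dimnames = dimnames(dup)),
                         scale = "log2")
  cld <- cluster_profiles(md, k = 5)
  expect_equal(cld[["P01"]], cld[["P02"]])
  expect_error(cluster_profiles(m, k = 100), "exceeds")
  const <- base
  const[3, ] <- 25
  mc <- intensity_matrix(const, matrix(FALSE, 60, nrow(d),
                                       dimnames = dimnames(const)),
                         scale = "log2")
  expect_warning(cluster_profiles(mc, k = 2), "constant row")
})

test_that("interactome correlation reproduces hand-computed Spearman values", {
  prof <- function(x) matrix(x, ncol = 1,
                             dimnames = list(paste0("P", seq_along(x)), "b"))
  expect_equal(interactome_correlation(prof(1:5), prof(1:5))[1, 1], 1)
  expect_equal(interactome_correlation(prof(1:5), prof(5:1))[1, 1], -1)
  # hand rank computation: d = (-1, 1, -1, 1, 0), sum d^2 = 4,
  # rho = 1 - 6*4 / (5 * 24) = 0.8
  expect_equal(interactome_correlation(prof(1:5),
                                       prof(c(2, 1, 4, 3, 5)))[1, 1], 0.8)
  expect_error(interactome_correlation(prof(1:2), prof(1:2)), ">= 3")
})

test_that("linkage classification applies the significance and sign rule", {
  cr <- fake_contrast(c("A", "B", "C"), logFC = c(2, -1.5, 0.8),
                      adj_p = c(0.001, 0.01, 0.2),
                      comparison = "K48_Ub3_vs_K63_Ub3")
  calls <- classify_linkage(cr)
  expect_equal(calls$call[calls$protein_id == "A"], "linkage_K48")
  expect_equal(calls$call[calls$protein_id == "B"], "linkage_K63")
  expect_false("C" %in% calls$protein_id)  # not significant -> unclassified
})

test_that("length classification enforces per-linkage thresholds across datasets", {
  # K48: significant in one dataset and logFC > 0.5 in both -> called
  k48 <- list(
    CAA = fake_contrast("A", 1.2, 0.01),
    NEM = fake_contrast("A", 0.8, 0.30)
  )
  calls <- classify_length(list(K48 = k48))
  expect_equal(calls$call, "length_Ub3_K48")
  # inconsistent direction -> unclassified
  k48b <- list(CAA = fake_contrast("A", 0.6, 0.01),
               NEM = fake_contrast("A", -0.2, 0.30))
  expect_equal(nrow(classify_length(list(K48 = k48b))), 0L)
  # 0.4 clears the K63 zero threshold but not the K48 0.5 threshold
  both <- list(K48 = list(CAA = fake_contrast("A", 0.4, 0.01)),
               K63 = list(CAA = fake_contrast("A", 0.4, 0.01)))
  calls2 <- classify_length(both)
  expect_equal(calls2$call, "length_Ub3_K63")
  # mirrored Ub2 preference
  ub2 <- list(K48 = list(CAA = fake_contrast("A", -1.0, 0.01)))
  expect_equal(classify_length(ub2)$call, "length_Ub2_preferring")
})

test_that("branch classification distinguishes plain, strict and homotypic", {
  mk <- function(l48_3, p48_3, l63_3, p63_3, l48_2 = 1, p48_2 = 0.01,
                 l63_2 = 1, p63_2 = 0.01) {
    list(vs_K48_Ub3 = fake_contrast("A", l48_3, p48_3),
         vs_K63_Ub3 = fake_contrast("A", l63_3, p63_3),
         vs_K48_Ub2 = fake_contrast("A", l48_2, p48_2),
         vs_K63_Ub2 = fake_contrast("A", l63_2, p63_2))
  }
  # all four significant-positive in both datasets -> strict
  res <- classify_branch(list(CAA = mk(2, 0.001, 2, 0.001),
                              NEM = mk(2, 0.001, 2, 0.001)))
  expect_equal(res$call, "branch_specific_strict")
  # only Ub3 pair passes in one dataset -> plain branch_specific
  res2 <- classify_branch(list(CAA = mk(2, 0.001, 2, 0.001,
                                        l48_2 = 0.5, p48_2 = 0.5),
                               NEM = mk(0.5, 0.5, 0.5, 0.5)))
  expect_equal(res2$call, "branch_specific")
  # one of the two Ub3 contrasts not significant -> unclassified
  res3 <- classify_branch(list(CAA = mk(2, 0.001, 0.3, 0.4)))
  expect_equal(nrow(res3), 0L)
  # reverse direction on both Ub3 contrasts -> homotypic_preferring
  res4 <- classify_branch(list(CAA = mk(-2, 0.001, -1.5, 0.002)))
  expect_equal(res4$call, "homotypic_preferring")
  expect_error(classify_branch(list(CAA = list(
    vs_K48_Ub3 = fake_contrast("A", 1, 0.01)))), "vs_K63_Ub3")
})

test_that("classification rules match a brute-force evaluator on random tables", {
  set.seed(51)
  for (rep_i in 1:20) {
    ids <- paste0("P", 1:8)
    ds_names <- c("d1", "d2")
    tabs <- lapply(ds_names, function(ds) {
      fake_contrast(ids, logFC = round(rnorm(8, 0, 1.2), 2),
                    adj_p = round(runif(8), 3),
                    comparison = "K48_Ub3_vs_K63_Ub3")
    })
    names(tabs) <- ds_names
    calls <- classify_linkage(tabs)
    for (id in ids) {
      lfc <- vapply(tabs, function(tt) tt$logFC[tt$protein_id == id],
                    numeric(1))
      ap <- vapply(tabs, function(tt) tt$adj_p[tt$protein_id == id],
                   numeric(1))
      expected <- if (any(ap < 0.05 & lfc > 0) && all(lfc > 0)) "linkage_K48"
                  else if (any(ap < 0.05 & lfc < 0) && all(lfc < 0)) "linkage_K63"
                  else NA_character_
      got <- calls$call[calls$protein_id == id]
      if (is.na(expected)) expect_length(got, 0)
      else expect_equal(got, expected)
    }
  }
})

test_that("end-to-end specificity recovery meets sensitivity and FDP targets", {
  cfg <- list(seed = 99, simulate = list(ds1 = list(n_proteins = 1000),
                                         ds2 = list(n_proteins = 1000)))
  rep_ <- run_all(cfg)
  sc <- rep_$scores
  expect_true(all(sc$per_class$sensitivity >= 0.8))
  expect_lte(sc$fdp, 0.1)
})
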