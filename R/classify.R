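#' Two-pass prefilter for ubiquitin-enriched proteins
#'
#' Pass 1 normalizes and imputes the full valid-value-filtered matrix, runs a
#' moderated t test of every ubiquitin bait against the bead-only control, and
#' retains proteins with `adj_p < alpha` and `logFC > lfc` in at least one
#' contrast — i.e. significantly enriched on some Ub chain over empty beads.
#' Pass 2 then subsets the *pre-normalization* matrix to the retained proteins
#' and re-normalizes and re-imputes it (with a fresh seed substream), so the
#' downstream statistics are computed on a matrix whose normalization and
#' imputation reflect only the Ub-enriched population.
#'
#' @param filtered_linear linear-scale `intensity_matrix` after flag /
#'   dropout / valid-value filtering (the `filtered_linear` element of
#'   [preprocess_matrix()])
#' @param design the `sample_design` (one dataset)
#' @param alpha BH-adjusted significance threshold (default 0.05)
#' @param lfc log2 fold-change threshold (default 0: enrichment over control)
#' @param width,shift downshift-imputation parameters
#' @param seed RNG seed; pass 1 and pass 2 imputations use distinct
#'   substreams
#' @return `list(retained, matrix, pass1_contrasts, prior)`: the retained
#'   protein ids, the re-processed pass-2 matrix, the per-bait pass-1
#'   contrast tables, and the pass-1 variance prior
#' @export
prefilter_ub_enriched <- function(filtered_linear, design, alpha = 0.05,
                                  lfc = 0, width = 0.3, shift = 1.8,
                                  seed = 1) {
  stopifnot(inherits(filtered_linear, "intensity_matrix"))
  design <- design[design$sample_id %in% sample_ids(filtered_linear), ,
                   drop = FALSE]
  if (!"bead_control" %in% design$bait) {
    stop("no bead_control group in design", call. = FALSE)
  }
  m1 <- impute_downshift(log2_median_normalize(filtered_linear),
                         width, shift, seed = substream_seed(seed, 11L))
  fit <- fit_groups(m1, design)
  prior <- estimate_variance_prior(fit$s2, fit$df)
  ub_baits <- setdiff(colnames(fit$means), "bead_control")
  contrasts <- lapply(ub_baits, function(b) {
    moderated_t(fit, prior, b, "bead_control")
  })
  names(contrasts) <- ub_baits
  hit <- Reduce(`|`, lapply(contrasts, function(cr) {
    cr$adj_p < alpha & cr$logFC > lfc
  }))
  retained <- protein_ids(filtered_linear)[hit]
  if (!length(retained)) {
    warning("prefilter retained no proteins", call. = FALSE)
    return(list(retained = character(),
                matrix = NULL, pass1_contrasts = contrasts, prior = prior))
  }
  m2 <- impute_downshift(log2_median_normalize(filtered_linear[retained, ]),
                         width, shift, seed = substream_seed(seed, 12L))
  list(retained = retained, matrix = m2,
       pass1_contrasts = contrasts, prior = prior)
}

#' Proteins differentially enriched across bait groups
#'
#' Moderated F test across all ubiquitin bait groups (the bead-only control
#' is excluded), BH adjustment, threshold `alpha`.
#'
#' @param matrix the prefiltered, processed (pass-2) `intensity_matrix`
#' @param design the `sample_design`
#' @param alpha BH-adjusted significance threshold
#' @param exclude groups excluded from the F comparison
#' @return `list(ids, result, fit, prior)`: significant protein ids, the
#'   F-test `contrast_result`, the `group_fit` and the `variance_prior`
#' @export
significant_across_baits <- function(matrix, design, alpha = 0.05,
                                     exclude = "bead_control") {
  stopifnot(inherits(matrix, "intensity_matrix"))
  design <- design[design$sample_id %in% sample_ids(matrix), , drop = FALSE]
  groups <- setdiff(unique(design$bait), exclude)
  if (length(groups) < 2L) {
    stop("need >= 2 bait groups for the cross-bait F test", call. = FALSE)
  }
  fit <- fit_groups(matrix, design)
  prior <- estimate_variance_prior(fit$s2, fit$df)
  res <- moderated_F(fit, prior, groups)
  list(ids = res$protein_id[res$adj_p < alpha], result = res,
       fit = fit, prior = prior)
}

#' Per-bait group-effect profiles
#'
#' Fitted group means from a [fit_groups()] object, optionally z-scored per
#' protein across baits — the per-pulldown model values used for interactome
#' correlation and heatmap-style exports.
#'
#' @param fit a `group_fit`
#' @param groups bait groups to include (default all except bead_control)
#' @param z_score z-score each protein's profile across baits
#' @return numeric matrix, protein x bait
#' @export
group_profiles <- function(fit, groups = NULL, z_score = TRUE) {
  stopifnot(inherits(fit, "group_fit"))
  if (is.null(groups)) groups <- setdiff(colnames(fit$means), "bead_control")
  mu <- fit$means[, groups, drop = FALSE]
  if (z_score) {
    mu <- t(scale(t(mu)))
    mu <- mu[, groups, drop = FALSE]
  }
  mu
}

#' Hierarchical clustering of enrichment profiles
#'
#' Rows are z-scored across samples (mean 0, sd 1), then clustered by
#' Euclidean distance with complete-linkage agglomeration and the tree cut at
#' `k` clusters. Constant rows cannot be z-scored and are dropped with a
#' warning.
#'
#' @param matrix processed `intensity_matrix` (or plain numeric matrix)
#' @param proteins proteins to cluster (default all rows)
#' @param k number of clusters
#' @return named integer vector of cluster assignments; the `hclust` tree is
#'   attached as attribute `tree`
#' @export
cluster_profiles <- function(matrix, proteins = NULL, k) {
  v <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant row(s) dropped before z-scoring",
                    sum(sds == 0)), call. = FALSE)
    v <- v[sds > 0, , drop = FALSE]
  }
  if (k > nrow(v)) {
    stop(sprintf("k = %d exceeds the number of clusterable proteins (%d)",
                 k, nrow(v)), call. = FALSE)
  }
  z <- t(scale(t(v)))
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
  cl <- stats::cutree(tree, k = k)
  attr(cl, "tree") <- tree
  cl
}

#' Spearman correlation of bait interactomes between two profile sets
#'
#' For every bait pair, the Spearman rank correlation of the per-bait
#' group-effect values (see [group_profiles()]) over the common significant
#' proteins.
#'
#' @param profilesA,profilesB protein x bait matrices (e.g. from
#'   [group_profiles()] of two datasets)
#' @param proteins proteins to correlate over; default the row-name
#'   intersection
#' @return bait(A) x bait(B) matrix of Spearman rho
#' @export
interactome_correlation <- function(profilesA, profilesB, proteins = NULL) {
  if (is.null(proteins)) {
    proteins <- intersect(rownames(profilesA), rownames(profilesB))
  }
  if (length(proteins) < 3L) {
    stop("need >= 3 common proteins for correlation", call. = FALSE)
  }
  a <- profilesA[proteins, , drop = FALSE]
  b <- profilesB[proteins, , drop = FALSE]
  stats::cor(a, b, method = "spearman")
}

# ---- specificity classification -------------------------------------------

specificity_calls <- function(protein_id, call, support, dataset) {
  d <- data.frame(protein_id = protein_id, call = call, support = support,
                  dataset = dataset, stringsAsFactors = FALSE)
  class(d) <- c("specificity_calls", "data.frame")
  d
}

#' @export
print.specificity_calls <- function(x, ...) {
  cat("specificity_calls:\n")
  print(table(x$call))
  invisible(x)
}

# Normalize `results` to a named list of contrast_result tables by dataset.
as_dataset_list <- function(results, what) {
  if (inherits(results, "contrast_result")) return(list(dataset1 = results))
  if (!is.list(results) || !length(results)) {
    stop(sprintf("missing required contrast: %s", what), call. = FALSE)
  }
  results
}

# Row lookup of one protein in one contrast table; NULL when absent.
lookup <- function(cr, id) {
  i <- match(id, cr$protein_id)
  if (is.na(i)) return(NULL)
  cr[i, ]
}

support_string <- function(rows) {
  paste(vapply(rows, function(r) {
    sprintf("%s[%s]:logFC=%.2f,adj_p=%.3g", r$comparison, r$dataset,
            r$logFC, r$adj_p)
  }, character(1)), collapse = "; ")
}

#' Classify chain-linkage preference (K48 vs K63)
#'
#' From the K48 Ub3 versus K63 Ub3 moderated t contrast: `linkage_K48` iff
#' `adj_p < alpha` and `logFC > 0`, `linkage_K63` for the opposite sign. With
#' several datasets a call requires significance in at least one dataset and
#' a consistent fold-change direction in every dataset where the protein was
#' quantified.
#'
#' @param results a `contrast_result` for K48_Ub3 vs K63_Ub3, or a named list
#'   of them by dataset
#' @param alpha significance threshold
#' @return a `specificity_calls` table (unclassified proteins omitted)
#' @export
classify_linkage <- function(results, alpha = 0.05) {
  results <- as_dataset_list(results, "K48_Ub3_vs_K63_Ub3")
  ids <- unique(unlist(lapply(results, `[[`, "protein_id")))
  out <- lapply(ids, function(id) {
    rows <- list()
    sig_pos <- sig_neg <- FALSE
    pos_all <- neg_all <- TRUE
    for (ds in names(results)) {
      r <- lookup(results[[ds]], id)
      if (is.null(r)) next
      r$dataset <- ds
      rows[[length(rows) + 1L]] <- r
      if (r$adj_p < alpha && r$logFC > 0) sig_pos <- TRUE
      if (r$adj_p < alpha && r$logFC < 0) sig_neg <- TRUE
      pos_all <- pos_all && r$logFC > 0
      neg_all <- neg_all && r$logFC < 0
    }
    call <- if (sig_pos && pos_all) "linkage_K48"
            else if (sig_neg && neg_all) "linkage_K63"
            else NA_character_
    if (is.na(call)) return(NULL)
    specificity_calls(id, call, support_string(rows),
                      paste(names(results), collapse = ","))
  })
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(specificity_calls(character(), character(),
                                          character(), character()))))
}

#' Classify chain-length preference (Ub3 vs Ub2)
#'
#' For each linkage, from its Ub3 versus Ub2 moderated t contrast: a protein
#' is called Ub3-preferring iff `adj_p < alpha` in at least one dataset AND
#' the log2 fold change exceeds the linkage threshold in every dataset where
#' it was quantified (`> 0.5` for K48, `> 0` — sign consistency — for K63);
#' mirrored with `< -0.5` / `< 0` for Ub2 preference
#' (`length_Ub2_preferring`).
#'
#' @param results nested list: `results[[linkage]][[dataset]]` is the
#'   `contrast_result` of Ub3 vs Ub2 for that linkage; linkage names `"K48"`
#'   and/or `"K63"`
#' @param alpha significance threshold
#' @param lfc_threshold named per-linkage fold-change thresholds
#' @return a `specificity_calls` table
#' @export
classify_length <- function(results, alpha = 0.05,
                            lfc_threshold = c(K48 = 0.5, K63 = 0)) {
  if (!is.list(results) || !length(results)) {
    stop("missing required contrast: Ub3_vs_Ub2 per linkage", call. = FALSE)
  }
  out <- list()
  for (lk in names(results)) {
    if (!lk %in% names(lfc_threshold)) {
      stop(sprintf("missing required contrast threshold for linkage '%s'", lk),
           call. = FALSE)
    }
    thr <- lfc_threshold[[lk]]
    by_ds <- as_dataset_list(results[[lk]], sprintf("%s Ub3_vs_Ub2", lk))
    ids <- unique(unlist(lapply(by_ds, `[[`, "protein_id")))
    for (id in ids) {
      rows <- list()
      sig <- FALSE
      up_all <- down_all <- TRUE
      for (ds in names(by_ds)) {
        r <- lookup(by_ds[[ds]], id)
        if (is.null(r)) next
        r$dataset <- ds
        rows[[length(rows) + 1L]] <- r
        if (r$adj_p < alpha) sig <- TRUE
        up_all <- up_all && r$logFC > thr
        down_all <- down_all && r$logFC < -thr
      }
      call <- if (sig && up_all) paste0("length_Ub3_", lk)
              else if (sig && down_all) "length_Ub2_preferring"
              else NA_character_
      if (is.na(call)) next
      out[[length(out) + 1L]] <-
        specificity_calls(id, call, support_string(rows),
                          paste(names(by_ds), collapse = ","))
    }
  }
  do.call(rbind, c(out, list(specificity_calls(character(), character(),
                                               character(), character()))))
}

#' Classify branched-chain specificity
#'
#' From the branched-Ub3-versus-homotypic moderated t contrasts:
#' `branch_specific` iff, within at least one dataset, Br Ub3 versus both
#' homotypic Ub3 chains (K48 Ub3 and K63 Ub3) has `adj_p < alpha` and
#' `logFC > 0`; `branch_specific_strict` iff all four Br-versus-homotypic
#' contrasts (Ub2 and Ub3 of both linkages) pass in every dataset provided;
#' `homotypic_preferring` iff both Ub3 contrasts pass in the reverse
#' direction. Strict calls are reported as `branch_specific_strict` (they
#' subsume the plain call).
#'
#' @param results nested list: `results[[dataset]]` is a named list of
#'   `contrast_result` tables with elements `vs_K48_Ub3`, `vs_K63_Ub3` and
#'   optionally `vs_K48_Ub2`, `vs_K63_Ub2` (each Br_Ub3 minus the named
#'   group)
#' @param alpha significance threshold
#' @return a `specificity_calls` table
#' @export
classify_branch <- function(results, alpha = 0.05) {
  if (!is.list(results) || !length(results)) {
    stop("missing required contrast: Br_Ub3 vs homotypic", call. = FALSE)
  }
  if (inherits(results[[1]], "contrast_result")) {
    results <- list(dataset1 = results)  # single-dataset convenience
  }
  for (ds in names(results)) {
    need <- c("vs_K48_Ub3", "vs_K63_Ub3")
    miss <- setdiff(need, names(results[[ds]]))
    if (length(miss)) {
      stop(sprintf("missing contrast %s in dataset '%s'",
                   paste(miss, collapse = ", "), ds), call. = FALSE)
    }
  }
  ids <- unique(unlist(lapply(results, function(x)
    lapply(x, `[[`, "protein_id"))))
  strict_names <- c("vs_K48_Ub3", "vs_K63_Ub3", "vs_K48_Ub2", "vs_K63_Ub2")
  out <- list()
  for (id in ids) {
    rows <- list()
    any_branch <- any_homo <- FALSE
    strict_all <- TRUE
    strict_possible <- TRUE
    for (ds in names(results)) {
      tabs <- results[[ds]]
      get <- function(nm) if (nm %in% names(tabs)) lookup(tabs[[nm]], id)
                          else NULL
      r48 <- get("vs_K48_Ub3"); r63 <- get("vs_K63_Ub3")
      for (r in Filter(Negate(is.null), list(r48, r63))) {
        r$dataset <- ds
        rows[[length(rows) + 1L]] <- r
      }
      ok_pos <- function(r) !is.null(r) && r$adj_p < alpha && r$logFC > 0
      ok_neg <- function(r) !is.null(r) && r$adj_p < alpha && r$logFC < 0
      if (ok_pos(r48) && ok_pos(r63)) any_branch <- TRUE
      if (ok_neg(r48) && ok_neg(r63)) any_homo <- TRUE
      strict_here <- all(strict_names %in% names(tabs))
      if (strict_here) {
        strict_all <- strict_all &&
          all(vapply(strict_names, function(nm) ok_pos(get(nm)), logical(1)))
      } else {
        strict_possible <- FALSE
      }
    }
    call <- if (strict_possible && strict_all) "branch_specific_strict"
            else if (any_branch) "branch_specific"
            else if (any_homo) "homotypic_preferring"
            else NA_character_
    if (is.na(call)) next
    out[[length(out) + 1L]] <-
      specificity_calls(id, call, support_string(rows),
                        paste(names(results), collapse = ","))
  }
  do.call(rbind, c(out, list(specificity_calls(character(), character(),
                                               character(), character()))))
}
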