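#' Analyse one pulldown dataset
#'
#' The per-dataset stage chain: preprocessing (flag / dropout / valid-value
#' filtering), the two-pass Ub-enrichment prefilter against the bead-only
#' control, the cross-bait moderated F test, and the pairwise moderated t
#' contrasts that the specificity classifiers consume (linkage, length and
#' branch comparisons, as available from the design's baits).
#'
#' @param matrix linear-scale `intensity_matrix`
#' @param records aligned `protein_records`
#' @param design `sample_design` (one dataset)
#' @param alpha BH-adjusted significance threshold
#' @param min_fraction,min_valid,width,shift preprocessing parameters
#' @param seed RNG seed (imputation substreams derive from it)
#' @return list with `prefilter`, `ftest`, `fit`, `prior`, `contrasts`
#'   (named list of `contrast_result`), `counts` (stage-by-stage protein
#'   counts) and `design`
#' @export
analyze_dataset <- function(matrix, records, design, alpha = 0.05,
                            min_fraction = 0.5, min_valid = 3,
                            width = 0.3, shift = 1.8, seed = 1) {
  pre <- preprocess_matrix(matrix, records, design,
                           min_fraction = min_fraction,
                           min_valid = min_valid,
                           width = width, shift = shift,
                           seed = seed, impute = FALSE)
  pf <- prefilter_ub_enriched(pre$filtered_linear, pre$design,
                              alpha = alpha, width = width, shift = shift,
                              seed = seed)
  counts <- c(input = nrow(matrix)[1],
              after_flag_filter = nrow(matrix)[1] - pre$n_flagged,
              after_valid_filter = nrow(pre$filtered_linear)[1],
              prefiltered = length(pf$retained))
  if (!length(pf$retained)) {
    return(list(prefilter = pf, ftest = NULL, fit = NULL, prior = NULL,
                contrasts = list(), counts = counts, design = pre$design))
  }
  ft <- significant_across_baits(pf$matrix, pre$design, alpha = alpha)
  counts["f_significant"] <- length(ft$ids)

  baits <- colnames(ft$fit$means)
  pairs <- list(
    linkage = c("K48_Ub3", "K63_Ub3"),
    length_K48 = c("K48_Ub3", "K48_Ub2"),
    length_K63 = c("K63_Ub3", "K63_Ub2"),
    branch_vs_K48_Ub3 = c("Br_Ub3", "K48_Ub3"),
    branch_vs_K63_Ub3 = c("Br_Ub3", "K63_Ub3"),
    branch_vs_K48_Ub2 = c("Br_Ub3", "K48_Ub2"),
    branch_vs_K63_Ub2 = c("Br_Ub3", "K63_Ub2")
  )
  contrasts <- list()
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (all(p %in% baits)) {
      contrasts[[nm]] <- moderated_t(ft$fit, ft$prior, p[1], p[2])
    }
  }
  list(prefilter = pf, ftest = ft, fit = ft$fit, prior = ft$prior,
       contrasts = contrasts, counts = counts, design = pre$design)
}

#' Classify chain specificity across one or more analysed datasets
#'
#' Assembles the per-dataset pairwise contrasts from [analyze_dataset()]
#' results into the inputs of [classify_linkage()], [classify_length()] and
#' [classify_branch()] and runs all three.
#'
#' @param analyses named list of [analyze_dataset()] results (names are
#'   dataset labels)
#' @param alpha significance threshold
#' @return list with `linkage`, `length`, `branch` (`specificity_calls`
#'   tables) and `all` (their row-bind)
#' @export
classify_specificity <- function(analyses, alpha = 0.05) {
  grab <- function(nm) {
    out <- lapply(analyses, function(a) a$contrasts[[nm]])
    out[!vapply(out, is.null, logical(1))]
  }
  calls_linkage <- calls_length <- calls_branch <- NULL
  lk <- grab("linkage")
  if (length(lk)) calls_linkage <- classify_linkage(lk, alpha = alpha)
  len <- list()
  for (side in c("K48", "K63")) {
    tabs <- grab(paste0("length_", side))
    if (length(tabs)) len[[side]] <- tabs
  }
  if (length(len)) calls_length <- classify_length(len, alpha = alpha)
  br <- lapply(analyses, function(a) {
    tabs <- a$contrasts[grepl("^branch_vs_", names(a$contrasts))]
    names(tabs) <- sub("^branch_", "", names(tabs))
    tabs
  })
  br <- br[vapply(br, function(x)
    all(c("vs_K48_Ub3", "vs_K63_Ub3") %in% names(x)), logical(1))]
  if (length(br)) calls_branch <- classify_branch(br, alpha = alpha)
  all_calls <- do.call(rbind, Filter(Negate(is.null),
                                     list(calls_linkage, calls_length,
                                          calls_branch)))
  list(linkage = calls_linkage, length = calls_length,
       branch = calls_branch, all = all_calls)
}

#' Expected specificity calls implied by planted truth
#'
#' Derives, mechanically from the planted per-bait effect matrix, which
#' specificity calls are true for each protein: a linkage call is true when
#' the planted K48 Ub3 effect exceeds the K63 Ub3 effect (and vice versa), a
#' length call when the planted Ub3-minus-Ub2 difference clears the same
#' fold-change threshold the classifier uses, and a branch call when the
#' branched-chain effect exceeds (or falls below) both homotypic Ub3
#' effects. Only proteins that are genuinely Ub-enriched over the control
#' (some positive bait effect net of the control effect) are eligible.
#'
#' @param truth the `truth` element of [simulate_interactome()]
#' @param lfc_threshold per-linkage length thresholds (as in
#'   [classify_length()])
#' @return data frame: `protein_id`, `class`, and logical columns
#'   `true_<call>` for each call type
#' @export
expected_calls <- function(truth, lfc_threshold = c(K48 = 0.5, K63 = 0)) {
  d <- truth$delta
  enriched <- apply(d[, setdiff(colnames(d), "bead_control"), drop = FALSE],
                    1L, max) - d[, "bead_control"] > 0
  has <- function(b) b %in% colnames(d)
  col <- function(b) if (has(b)) d[, b] else rep(0, nrow(d))
  out <- data.frame(
    protein_id = rownames(d),
    class = truth$labels$class[match(rownames(d), truth$labels$protein_id)],
    stringsAsFactors = FALSE
  )
  out$true_linkage_K48 <- enriched & col("K48_Ub3") > col("K63_Ub3")
  out$true_linkage_K63 <- enriched & col("K63_Ub3") > col("K48_Ub3")
  out$true_length_Ub3_K48 <- enriched &
    (col("K48_Ub3") - col("K48_Ub2")) > lfc_threshold[["K48"]]
  out$true_length_Ub3_K63 <- enriched &
    (col("K63_Ub3") - col("K63_Ub2")) > lfc_threshold[["K63"]]
  out$true_length_Ub2_preferring <- enriched &
    ((col("K48_Ub2") - col("K48_Ub3")) > lfc_threshold[["K48"]] |
     (col("K63_Ub2") - col("K63_Ub3")) > lfc_threshold[["K63"]])
  out$true_branch_specific <- enriched &
    col("Br_Ub3") > col("K48_Ub3") & col("Br_Ub3") > col("K63_Ub3")
  out$true_homotypic_preferring <- enriched &
    col("Br_Ub3") < col("K48_Ub3") & col("Br_Ub3") < col("K63_Ub3")
  out
}

#' Score specificity calls against planted truth
#'
#' @param calls a `specificity_calls` table (e.g. `classify_specificity()$all`)
#' @param truth the `truth` element of [simulate_interactome()] (or a list of
#'   them from several datasets sharing the planted design, in which case the
#'   first is used — planted classes are identical across datasets)
#' @return list with `per_class` (data frame: class, expected call, n
#'   planted, n recovered, sensitivity), `fdp` (false-discovery proportion
#'   over all calls), `n_calls`, `calls` (the calls annotated with
#'   `correct`)
#' @export
score_calls <- function(calls, truth) {
  if (!is.null(truth$labels)) truth <- truth else truth <- truth[[1]]
  exp_calls <- expected_calls(truth)
  call_to_truth <- c(
    linkage_K48 = "true_linkage_K48",
    linkage_K63 = "true_linkage_K63",
    length_Ub3_K48 = "true_length_Ub3_K48",
    length_Ub3_K63 = "true_length_Ub3_K63",
    length_Ub2_preferring = "true_length_Ub2_preferring",
    branch_specific = "true_branch_specific",
    branch_specific_strict = "true_branch_specific",
    homotypic_preferring = "true_homotypic_preferring"
  )
  calls$correct <- vapply(seq_len(nrow(calls)), function(i) {
    tcol <- call_to_truth[[calls$call[i]]]
    j <- match(calls$protein_id[i], exp_calls$protein_id)
    !is.na(j) && isTRUE(exp_calls[[tcol]][j])
  }, logical(1))
  fdp <- if (nrow(calls)) mean(!calls$correct) else 0

  class_map <- list(
    K48_specific = "linkage_K48",
    K63_specific = "linkage_K63",
    length_dependent_K48 = "length_Ub3_K48",
    length_dependent_K63 = "length_Ub3_K63",
    branch_specific = c("branch_specific", "branch_specific_strict"),
    branch_excluded = "homotypic_preferring"
  )
  per_class <- do.call(rbind, lapply(names(class_map), function(cl) {
    planted <- exp_calls$protein_id[exp_calls$class == cl]
    hit <- vapply(planted, function(id) {
      any(calls$protein_id == id & calls$call %in% class_map[[cl]])
    }, logical(1))
    data.frame(class = cl,
               expected_call = paste(class_map[[cl]], collapse = "|"),
               n_planted = length(planted),
               n_recovered = sum(hit),
               sensitivity = if (length(planted)) mean(hit) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_class = per_class, fdp = fdp, n_calls = nrow(calls),
       calls = calls)
}
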