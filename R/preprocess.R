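#' Remove reverse / contaminant / site-only protein rows
#'
#' Search-engine artefact rows are excluded before any statistic is computed.
#'
#' @param matrix an `intensity_matrix`
#' @param records the aligned `protein_records`
#' @return `list(matrix, records, n_removed)`
#' @export
drop_flagged <- function(matrix, records) {
  stopifnot(inherits(matrix, "intensity_matrix"),
            identical(protein_ids(matrix), records$protein_id))
  bad <- records$reverse | records$contaminant | records$site_only
  if (all(bad)) {
    warning("all rows flagged; returning an empty matrix", call. = FALSE)
  }
  list(matrix = matrix[!bad, ],
       records = records[!bad, , drop = FALSE],
       n_removed = sum(bad))
}

#' Detect dropout samples by detection count
#'
#' A sample is flagged as a dropout when its number of present (quantified)
#' values falls below `min_fraction` times the median present-count of the
#' samples in its dataset. Flagged samples must be removed before statistics.
#'
#' @param matrix an `intensity_matrix`
#' @param design the `sample_design`
#' @param min_fraction detection-fraction threshold (default 0.5)
#' @return character vector of flagged sample ids (possibly empty)
#' @export
detect_dropout_samples <- function(matrix, design, min_fraction = 0.5) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  design <- design[design$sample_id %in% sample_ids(matrix), , drop = FALSE]
  present <- colSums(!matrix$missing)
  flagged <- character()
  for (ds in unique(design$dataset)) {
    ids <- design$sample_id[design$dataset == ds]
    med <- stats::median(present[ids])
    flagged <- c(flagged, ids[present[ids] < min_fraction * med])
  }
  if (length(flagged)) {
    keep <- design[!design$sample_id %in% flagged, , drop = FALSE]
    sizes <- table(keep$dataset, keep$bait)
    low <- which(sizes < 2L & table(design$dataset, design$bait) > 0,
                 arr.ind = TRUE)
    if (nrow(low)) {
      stop(sprintf(
        "removing dropout sample(s) leaves group(s) with < 2 samples: %s",
        paste(unique(colnames(sizes)[low[, 2L]]), collapse = ", ")),
        call. = FALSE)
    }
  }
  flagged
}

#' Filter proteins by minimum valid values per bait group
#'
#' A protein is retained iff it has at least `min_valid` present values within
#' at least one bait group (the bead-only control counts as a group). This
#' keeps bait-exclusive binders — the interactors of interest — while removing
#' proteins too sparsely quantified for any group comparison.
#'
#' @param matrix an `intensity_matrix`
#' @param design the `sample_design`
#' @param min_valid minimum present values within a group (default 3)
#' @return the filtered `intensity_matrix`
#' @export
filter_min_valid <- function(matrix, design, min_valid = 3) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  design <- design[design$sample_id %in% sample_ids(matrix), , drop = FALSE]
  groups <- split(design$sample_id, paste(design$dataset, design$bait))
  too_small <- vapply(groups, length, integer(1)) < min_valid
  if (all(too_small)) {
    stop(sprintf("min_valid = %d exceeds every group size", min_valid),
         call. = FALSE)
  }
  keep <- Reduce(`|`, lapply(groups[!too_small], function(ids) {
    rowSums(!matrix$missing[, ids, drop = FALSE]) >= min_valid
  }))
  matrix[keep, ]
}

#' Log2 transform and median-normalize
#'
#' Moves the matrix to the log2 scale and shifts each sample's present values
#' so every per-sample median equals the grand median of per-sample medians.
#' The mask is unchanged; any constant anchor would yield identical downstream
#' statistics since group-mean differences are shift-invariant.
#'
#' @param matrix an `intensity_matrix` (linear or already log2)
#' @return a normalized log2-scale `intensity_matrix`
#' @export
log2_median_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  m <- transform_scale(matrix, "log2")
  present <- colSums(!m$missing)
  if (any(present == 0)) {
    stop(sprintf("sample(s) with no present values: %s (drop them first)",
                 paste(sample_ids(m)[present == 0], collapse = ", ")),
         call. = FALSE)
  }
  med <- apply(m$values, 2L, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  v <- sweep(m$values, 2L, med - target)
  intensity_matrix(v, m$missing, scale = "log2")
}

#' Impute missing values from a downshifted normal distribution
#'
#' For each sample with present-value mean `m_s` and standard deviation
#' `sd_s`, every missing cell is drawn independently from
#' `Normal(m_s - shift * sd_s, (width * sd_s)^2)` — the standard left-censored
#' "downshift" imputation that places imputed values in the low-intensity tail
#' where undetected proteins are expected. Present cells are never altered.
#' Which cells were imputed is recorded in the returned matrix's `imputed`
#' attribute.
#'
#' @param matrix a normalized log2-scale `intensity_matrix`
#' @param width imputation sd as a fraction of the sample sd (default 0.3)
#' @param shift downshift in sample-sd units (default 1.8)
#' @param seed RNG seed
#' @return a complete `intensity_matrix` (empty mask) with attribute
#'   `imputed`: logical matrix of the cells that were drawn
#' @export
impute_downshift <- function(matrix, width = 0.3, shift = 1.8, seed = 1) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (matrix$scale != "log2") {
    stop("impute_downshift expects a log2-scale matrix", call. = FALSE)
  }
  present <- colSums(!matrix$missing)
  if (any(present < 2)) {
    stop(sprintf("sample(s) with < 2 present values: %s",
                 paste(sample_ids(matrix)[present < 2], collapse = ", ")),
         call. = FALSE)
  }
  v <- matrix$values
  imputed <- matrix$missing
  if (any(imputed)) {
    v <- with_seed(seed, {
      for (j in seq_len(ncol(v))) {
        miss_j <- imputed[, j]
        if (!any(miss_j)) next
        x <- v[!miss_j, j]
        m_s <- mean(x)
        sd_s <- stats::sd(x)
        v[miss_j, j] <- stats::rnorm(sum(miss_j),
                                     m_s - shift * sd_s, width * sd_s)
      }
      v
    })
  }
  out <- intensity_matrix(v, matrix(FALSE, nrow(v), ncol(v),
                                    dimnames = dimnames(v)),
                          scale = "log2")
  attr(out, "imputed") <- imputed
  out
}

#' Run the full preprocessing chain
#'
#' Fixed order: flag filtering, dropout-sample removal, valid-value filtering,
#' log2 median normalization, downshift imputation. Re-running with the same
#' seed reproduces the output bit for bit. Set `impute = FALSE` to stop after
#' normalization (used by the two-pass prefilter, which needs the
#' pre-normalization matrix as well).
#'
#' @param matrix linear-scale `intensity_matrix`
#' @param records aligned `protein_records`
#' @param design `sample_design`
#' @param min_fraction dropout-sample detection threshold
#' @param min_valid valid-value threshold per group
#' @param width,shift downshift imputation parameters
#' @param seed RNG seed for imputation
#' @param impute run the imputation step
#' @return `list(matrix, records, design, filtered_linear, dropout_samples,
#'   n_flagged)` where `filtered_linear` is the valid-value-filtered matrix
#'   still on the linear scale (input to the second prefilter pass)
#' @export
preprocess_matrix <- function(matrix, records, design,
                              min_fraction = 0.5, min_valid = 3,
                              width = 0.3, shift = 1.8, seed = 1,
                              impute = TRUE) {
  fl <- drop_flagged(matrix, records)
  dropouts <- detect_dropout_samples(fl$matrix, design, min_fraction)
  m <- fl$matrix
  design_kept <- design
  if (length(dropouts)) {
    keep <- setdiff(sample_ids(m), dropouts)
    m <- m[, keep]
    design_kept <- design[!design$sample_id %in% dropouts, , drop = FALSE]
  }
  m <- filter_min_valid(m, design_kept, min_valid)
  recs <- fl$records[fl$records$protein_id %in% protein_ids(m), , drop = FALSE]
  filtered_linear <- m
  m <- log2_median_normalize(m)
  if (impute) m <- impute_downshift(m, width, shift, seed)
  list(matrix = m, records = recs, design = design_kept,
       filtered_linear = filtered_linear,
       dropout_samples = dropouts, n_flagged = fl$n_removed)
}
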