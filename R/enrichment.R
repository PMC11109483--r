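#' Fisher exact enrichment of expected ubiquitin binders
#'
#' Tests whether the proportion of expected UbBPs among the `n_in` proteins
#' of a filtered set exceeds the proportion in the remainder of the dataset.
#' The 2x2 table uses disjoint categories — filtered vs not-filtered — so
#' each protein is counted once:
#' `[[k_in, n_in - k_in], [k_all - k_in, (n_all - n_in) - (k_all - k_in)]]`.
#'
#' @param k_in expected UbBPs in the filtered set
#' @param n_in size of the filtered set
#' @param k_all expected UbBPs in the whole dataset
#' @param n_all size of the whole dataset
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#' @return list with `odds_ratio`, `p`, and the 2x2 `table`
#' @export
fisher_ubbp_enrichment <- function(k_in, n_in, k_all, n_all,
                                   alternative = "two.sided") {
  counts <- c(k_in = k_in, n_in = n_in, k_all = k_all, n_all = n_all)
  if (any(counts < 0) || k_in > n_in || n_in > n_all || k_in > k_all ||
      k_all > n_all || (k_all - k_in) > (n_all - n_in)) {
    stop("inconsistent counts for the 2x2 enrichment table", call. = FALSE)
  }
  tab <- matrix(c(k_in, n_in - k_in,
                  k_all - k_in, (n_all - n_in) - (k_all - k_in)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("filtered", "rest"),
                                c("expected_ubbp", "other")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Enrichment factor of a proportion over a reference proportion
#'
#' `(k_in / n_in) / (k_ref / n_ref)` — e.g. the expected-UbBP fraction in a
#' prefiltered list relative to its fraction in a reference proteome.
#'
#' @param k_in,n_in hits and size in the set of interest
#' @param k_ref,n_ref hits and size in the reference
#' @return the ratio of proportions
#' @export
enrichment_factor <- function(k_in, n_in, k_ref, n_ref) {
  if (n_in <= 0 || n_ref <= 0) stop("set sizes must be > 0", call. = FALSE)
  if (k_ref == 0) {
    stop("k_ref = 0: enrichment factor undefined", call. = FALSE)
  }
  (k_in / n_in) / (k_ref / n_ref)
}

#' Overlap cardinalities of identifier sets
#'
#' For every non-empty membership pattern over the input sets, the number of
#' identifiers showing exactly that pattern (the Venn-region counts).
#'
#' @param ... two or more character vectors, preferably named
#' @return data frame with one indicator column per set and a `count` column
#' @export
overlap_counts <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]])) sets <- sets[[1L]]
  if (length(sets) < 2L) stop("need >= 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(universe, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  patterns$count <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(row) all(row == p)))
  })
  rownames(patterns) <- NULL
  patterns
}
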