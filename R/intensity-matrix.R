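#' Protein-by-sample intensity matrix with explicit missingness
#'
#' The central quantitative container: one row per protein isoform, one column
#' per pulldown sample, holding iBAQ-style intensities together with a logical
#' mask that marks cells not quantified in the experiment. Values are stored
#' on either the linear or the log2 scale; the `scale` tag records which, and
#' all statistics refuse to read masked cells.
#'
#' @param values numeric matrix with rownames = protein isoform ids and
#'   colnames = sample ids. `NA` cells are taken as missing.
#' @param missing logical matrix of the same dimension; `TRUE` marks a missing
#'   (not-quantified) cell. Defaults to `is.na(values)`.
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, missing = is.na(values),
                             scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("`values` must carry protein ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop("`values` must carry sample ids as colnames", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop(sprintf("duplicate protein_id: '%s'", dup), call. = FALSE)
  }
  if (!is.matrix(missing) || !is.logical(missing) ||
      !identical(dim(missing), dim(values))) {
    stop("`missing` must be a logical matrix matching `values`", call. = FALSE)
  }
  values[missing] <- NA_real_
  present <- values[!missing]
  if (anyNA(present)) {
    stop("present cells must not be NA", call. = FALSE)
  }
  if (scale == "linear" && any(present <= 0)) {
    stop("linear-scale intensities must be > 0 on present cells", call. = FALSE)
  }
  structure(
    list(values = values, missing = missing, scale = scale),
    class = "intensity_matrix"
  )
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Protein ids of an intensity matrix
#' @param x an `intensity_matrix`
#' @return character vector of isoform ids
#' @export
protein_ids <- function(x) rownames(x$values)

#' Sample ids of an intensity matrix
#' @param x an `intensity_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "intensity_matrix: %d proteins x %d samples (%s scale), %d/%d cells missing (%.1f%%)\n",
    nrow(x$values), ncol(x$values), x$scale,
    sum(x$missing), length(x$missing), 100 * mean(x$missing)
  ))
  invisible(x)
}

#' Subset an intensity matrix by protein and/or sample
#'
#' @param x an `intensity_matrix`
#' @param i protein selector (ids, indices or logical)
#' @param j sample selector
#' @param ... ignored
#' @param drop ignored; the result is always an `intensity_matrix`
#' @export
`[.intensity_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  intensity_matrix(x$values[i, j, drop = FALSE],
                   x$missing[i, j, drop = FALSE],
                   scale = x$scale)
}

#' Move an intensity matrix between linear and log2 scale
#'
#' The transform is a bijection on present cells and leaves the missingness
#' mask untouched.
#'
#' @param x an `intensity_matrix`
#' @param to `"log2"` or `"linear"`
#' @return an `intensity_matrix` on the requested scale
#' @export
transform_scale <- function(x, to = c("log2", "linear")) {
  to <- match.arg(to)
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale == to) return(x)
  v <- x$values
  if (to == "log2") v <- log2(v) else v <- 2^v
  intensity_matrix(v, x$missing, scale = to)
}

#' Sample design for a pulldown experiment
#'
#' Maps each sample to its bait group, replicate number and dataset label, and
#' identifies the bead-only negative control. Each dataset must contain
#' exactly one `bead_control` group; bait groups entering variance estimation
#' need at least two samples.
#'
#' @param sample_id character vector of sample ids
#' @param bait character vector of bait group labels
#' @param replicate integer replicate index (>= 1)
#' @param dataset dataset label (e.g. `"CAA"`, `"NEM"`); default one dataset
#' @param extra_baits additional bait labels to accept beyond the built-in set
#' @return a `sample_design` data frame
#' @export
sample_design <- function(sample_id, bait, replicate,
                          dataset = "dataset1", extra_baits = character()) {
  known <- c(known_baits(), extra_baits)
  d <- data.frame(
    sample_id = as.character(sample_id),
    bait = as.character(bait),
    replicate = as.integer(replicate),
    dataset = as.character(dataset),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  bad <- setdiff(unique(d$bait), known)
  if (length(bad)) {
    stop(sprintf("unknown bait label(s): %s (declare via `extra_baits`)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(d$replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  for (ds in unique(d$dataset)) {
    if (!any(d$bait[d$dataset == ds] == "bead_control")) {
      stop(sprintf("no control group: dataset '%s' lacks a bead_control", ds),
           call. = FALSE)
    }
  }
  sizes <- table(d$dataset, d$bait)
  singletons <- which(sizes == 1L, arr.ind = TRUE)
  if (nrow(singletons)) {
    grps <- colnames(sizes)[singletons[, 2L]]
    warning(sprintf(
      "bait group(s) with a single sample excluded from variance estimation: %s",
      paste(unique(grps), collapse = ", ")), call. = FALSE)
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Recognised bait group labels
#' @return character vector of built-in bait labels
#' @export
known_baits <- function() {
  c("bead_control", "mono_Ub",
    "K48_Ub2", "K48_Ub3", "K48_Ub4",
    "K63_Ub2", "K63_Ub3", "K63_Ub4",
    "Br_Ub3")
}

#' Samples belonging to one bait group
#' @param design a `sample_design`
#' @param bait bait label
#' @param dataset optional dataset restriction
#' @return character vector of sample ids
#' @export
samples_of <- function(design, bait, dataset = NULL) {
  keep <- design$bait == bait
  if (!is.null(dataset)) keep <- keep & design$dataset == dataset
  design$sample_id[keep]
}

#' Protein record table
#'
#' One row per protein isoform: identifier, gene symbol, isoform suffix,
#' search-engine flags (reverse / contaminant / site-only) and, once
#' annotated, expected ubiquitin-binding-protein status and UBD names.
#'
#' @param protein_id isoform identifiers
#' @param gene gene symbols (default derived from the id before any
#'   underscore-number isoform suffix)
#' @param reverse,contaminant,site_only logical flags
#' @return a `protein_records` data frame
#' @export
protein_records <- function(protein_id, gene = NULL,
                            reverse = FALSE, contaminant = FALSE,
                            site_only = FALSE) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id)) {
    dup <- protein_id[duplicated(protein_id)][1L]
    stop(sprintf("duplicate protein_id: '%s'", dup), call. = FALSE)
  }
  if (is.null(gene)) gene <- sub("_[0-9]+$", "", protein_id)
  iso <- ifelse(grepl("_[0-9]+$", protein_id),
                sub("^.*_([0-9]+)$", "\\1", protein_id), NA_character_)
  d <- data.frame(
    protein_id = protein_id,
    gene = as.character(gene),
    isoform = iso,
    reverse = rep_len(as.logical(reverse), length(protein_id)),
    contaminant = rep_len(as.logical(contaminant), length(protein_id)),
    site_only = rep_len(as.logical(site_only), length(protein_id)),
    is_expected_ubbp = NA,
    ubd_names = NA_character_,
    stringsAsFactors = FALSE
  )
  class(d) <- c("protein_records", "data.frame")
  d
}

#' Annotation set of expected ubiquitin-binding proteins
#'
#' Identifiers are deduplicated and matched case-insensitively (lookups are
#' case-normalized), mirroring how GO/UBD gene lists are matched against
#' search-engine gene symbols.
#'
#' @param id character identifiers (gene symbols)
#' @param source per-identifier source tag (GO term, UBD database, literature)
#' @return an `annotation_set` data frame
#' @export
annotation_set <- function(id, source = "unspecified") {
  id <- as.character(id)
  source <- rep_len(as.character(source), length(id))
  key <- toupper(trimws(id))
  keep <- !duplicated(key) & nzchar(key)
  n_dup <- sum(duplicated(key[nzchar(key)]))
  if (n_dup > 0) {
    message(sprintf("annotation_set: %d duplicate identifier(s) removed", n_dup))
  }
  d <- data.frame(id = id[keep], source = source[keep], key = key[keep],
                  stringsAsFactors = FALSE)
  class(d) <- c("annotation_set", "data.frame")
  d
}

#' Annotate protein records with expected-UbBP membership
#'
#' Matching is case-normalized and tried against both the full isoform id and
#' the gene symbol, so `"rad23b"` in the list annotates records `RAD23B` and
#' `RAD23B_2`.
#'
#' @param records a `protein_records` table
#' @param annotation an `annotation_set`
#' @return the records with `is_expected_ubbp` and `ubd_names` filled in
#' @export
annotate_records <- function(records, annotation) {
  stopifnot(inherits(records, "protein_records"),
            inherits(annotation, "annotation_set"))
  key_id <- toupper(trimws(records$protein_id))
  key_gene <- toupper(trimws(records$gene))
  hit <- key_id %in% annotation$key | key_gene %in% annotation$key
  records$is_expected_ubbp <- hit
  src <- vapply(seq_along(hit), function(i) {
    if (!hit[i]) return(NA_character_)
    m <- annotation$key == key_id[i] | annotation$key == key_gene[i]
    paste(unique(annotation$source[m]), collapse = ";")
  }, character(1))
  records$ubd_names <- src
  records
}
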