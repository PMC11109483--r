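#' Read a MaxQuant-style protein-group quantification table
#'
#' Expects a tab-separated file with one row per protein isoform, per-sample
#' intensity columns identified by a common prefix (default `"iBAQ "`), and
#' optional flag columns marking reverse-database hits, contaminants and
#' site-only identifications (`"+"` convention). Zero and empty intensity
#' cells are treated as missing: an iBAQ of zero means the protein was not
#' quantified in that sample.
#'
#' @param path file path
#' @param intensity_prefix prefix identifying intensity columns; the sample id
#'   is the column name with the prefix stripped
#' @param id_col column holding the protein isoform identifier
#' @param gene_col optional column holding gene symbols
#' @param flag_cols named list mapping `reverse`, `contaminant`, `site_only`
#'   to column names; absent columns are silently skipped
#' @return `list(matrix = intensity_matrix, records = protein_records)`
#' @export
read_protein_table <- function(path,
                               intensity_prefix = "iBAQ ",
                               id_col = "Protein IDs",
                               gene_col = "Gene names",
                               flag_cols = list(
                                 reverse = "Reverse",
                                 contaminant = "Potential contaminant",
                                 site_only = "Only identified by site")) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  int_cols <- grep(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                    intensity_prefix)),
                   names(tab), value = TRUE)
  if (!length(int_cols)) {
    stop(sprintf("format error: no intensity columns with prefix '%s' in %s",
                 intensity_prefix, path), call. = FALSE)
  }
  if (!id_col %in% names(tab)) {
    stop(sprintf("format error: id column '%s' not found", id_col),
         call. = FALSE)
  }
  ids <- tab[[id_col]]
  vals <- vapply(int_cols, function(cn) {
    v <- tab[[cn]]
    v[v == "" | is.na(v)] <- "0"
    as.numeric(v)
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, sub(paste0("^", gsub(
                   "([][{}()+*^$|\\\\?.])", "\\\\\\1", intensity_prefix)),
                   "", int_cols)))
  miss <- vals == 0 | is.na(vals)
  gene <- if (!is.null(gene_col) && gene_col %in% names(tab)) {
    tab[[gene_col]]
  } else NULL
  flag <- function(which) {
    cn <- flag_cols[[which]]
    if (is.null(cn) || !cn %in% names(tab)) return(rep(FALSE, nrow(tab)))
    tab[[cn]] == "+"
  }
  records <- protein_records(ids, gene = gene,
                             reverse = flag("reverse"),
                             contaminant = flag("contaminant"),
                             site_only = flag("site_only"))
  list(matrix = intensity_matrix(vals, miss, scale = "linear"),
       records = records)
}

#' Write a protein table readable by [read_protein_table()]
#'
#' Missing cells are written as `0` (the MaxQuant convention) and flags as
#' `"+"`, so write followed by read is the identity on values, mask and
#' records.
#'
#' @param matrix an `intensity_matrix` on the linear scale
#' @param records the matching `protein_records`
#' @param path output path
#' @param intensity_prefix prefix for intensity column names
#' @return `path`, invisibly
#' @export
write_protein_table <- function(matrix, records, path,
                                intensity_prefix = "iBAQ ") {
  stopifnot(inherits(matrix, "intensity_matrix"),
            identical(protein_ids(matrix), records$protein_id))
  if (matrix$scale != "linear") {
    stop("write_protein_table expects a linear-scale matrix", call. = FALSE)
  }
  v <- matrix$values
  v[matrix$missing] <- 0
  out <- data.frame(
    `Protein IDs` = records$protein_id,
    `Gene names` = records$gene,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(v))) {
    out[[paste0(intensity_prefix, colnames(v)[j])]] <- v[, j]
  }
  out[["Reverse"]] <- ifelse(records$reverse, "+", "")
  out[["Potential contaminant"]] <- ifelse(records$contaminant, "+", "")
  out[["Only identified by site"]] <- ifelse(records$site_only, "+", "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-design table
#'
#' Tab-separated with columns `sample_id`, `bait`, `replicate`, `dataset`.
#' The design is validated: unknown baits are rejected unless declared,
#' every dataset needs a bead-only control, and (if a matrix is supplied)
#' every design sample must exist in the matrix.
#'
#' @param path file path
#' @param matrix optional `intensity_matrix` to validate sample ids against
#' @param extra_baits additional bait labels to accept
#' @return a `sample_design`
#' @export
read_design <- function(path, matrix = NULL, extra_baits = character()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "bait", "replicate", "dataset")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("design table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  d <- sample_design(tab$sample_id, tab$bait, tab$replicate, tab$dataset,
                     extra_baits = extra_baits)
  if (!is.null(matrix)) {
    absent <- setdiff(d$sample_id, sample_ids(matrix))
    if (length(absent)) {
      stop(sprintf("design sample(s) absent from matrix: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  d
}

#' Write a sample-design table
#' @param design a `sample_design`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation list of expected ubiquitin binders
#'
#' One identifier per line, or two tab-separated columns
#' `(identifier, source)`. Lines starting with `#` are ignored.
#'
#' @param path file path
#' @return an `annotation_set`
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    stop(sprintf("annotation file '%s' is empty", path), call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  id <- vapply(parts, `[[`, character(1), 1L)
  src <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else
    "unspecified", character(1))
  annotation_set(id, src)
}

#' Write a contrast-result table
#' @param result a `contrast_result` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_contrast <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
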