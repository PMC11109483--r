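#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates preprocess, the two-pass Ub-enrichment prefilter, the
#' moderated statistics, specificity classification and annotation
#' enrichment over one or more datasets, and writes a structured set of
#' tab-separated result tables plus a human-readable summary. The
#' configuration is a YAML file or an equivalent nested list with either a
#' `simulate` block (named per-dataset [sim_config()] argument lists) or an
#' `inputs` block (named per-dataset `protein_table` / `design` paths),
#' optionally an `annotation` path, a `thresholds` block
#' (`alpha`, `min_valid`, `min_fraction`, `width`, `shift`), a `clusters`
#' count, a `seed` and an `out_dir`. Identical configuration and seed
#' reproduce byte-identical outputs.
#'
#' @param config path to a YAML file, or a nested list
#' @param out_dir output directory (overrides the config entry); `NULL`
#'   writes nothing
#' @param seed overrides the config seed
#' @return the report bundle, invisibly: per-dataset analyses, calls,
#'   scores (when simulated truth is available), enrichment and the summary
#'   lines
#' @export
run_all <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: '%s'", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  seed <- if (!is.null(seed)) seed else config$seed
  if (is.null(seed)) stop("config field missing: seed", call. = FALSE)
  out_dir <- if (!is.null(out_dir)) out_dir else config$out_dir
  thr <- config$thresholds
  alpha <- thr$alpha %||% 0.05
  min_valid <- thr$min_valid %||% 3
  min_fraction <- thr$min_fraction %||% 0.5
  width <- thr$width %||% 0.3
  shift <- thr$shift %||% 1.8

  datasets <- list()
  truths <- list()
  if (!is.null(config$simulate)) {
    for (i in seq_along(config$simulate)) {
      nm <- names(config$simulate)[i] %||% paste0("sim", i)
      args <- config$simulate[[i]]
      args$dataset <- nm
      args$seed <- substream_seed(seed, 100L + i)
      cfg <- do.call(sim_config, args)
      sim <- simulate_interactome(cfg)
      datasets[[nm]] <- sim[c("matrix", "records", "design")]
      truths[[nm]] <- sim$truth
    }
  } else if (!is.null(config$inputs)) {
    for (nm in names(config$inputs)) {
      inp <- config$inputs[[nm]]
      for (field in c("protein_table", "design")) {
        if (is.null(inp[[field]])) {
          stop(sprintf("config field missing: inputs$%s$%s", nm, field),
               call. = FALSE)
        }
        if (!file.exists(inp[[field]])) {
          stop(sprintf("config field inputs$%s$%s: file not found '%s'",
                       nm, field, inp[[field]]), call. = FALSE)
        }
      }
      pt <- read_protein_table(inp$protein_table)
      datasets[[nm]] <- list(matrix = pt$matrix, records = pt$records,
                             design = read_design(inp$design, pt$matrix))
    }
  } else {
    stop("config field missing: either `simulate` or `inputs`", call. = FALSE)
  }

  annotation <- NULL
  if (!is.null(config$annotation)) {
    annotation <- read_annotation(config$annotation)
  }

  analyses <- list()
  for (i in seq_along(datasets)) {
    nm <- names(datasets)[i]
    d <- datasets[[nm]]
    analyses[[nm]] <- analyze_dataset(d$matrix, d$records, d$design,
                                      alpha = alpha,
                                      min_fraction = min_fraction,
                                      min_valid = min_valid,
                                      width = width, shift = shift,
                                      seed = substream_seed(seed, 200L + i))
  }

  calls <- classify_specificity(analyses, alpha = alpha)

  clusters <- NULL
  k <- config$clusters
  if (!is.null(k)) {
    clusters <- lapply(analyses, function(a) {
      if (is.null(a$ftest) || length(a$ftest$ids) < k) return(NULL)
      cluster_profiles(a$prefilter$matrix, a$ftest$ids, k = k)
    })
  }

  enrichment <- NULL
  if (!is.null(annotation)) {
    enrichment <- lapply(names(analyses), function(nm) {
      a <- analyses[[nm]]
      recs <- annotate_records(
        protein_records(protein_ids(datasets[[nm]]$matrix)), annotation)
      all_ids <- recs$protein_id
      pre_ids <- a$prefilter$retained
      k_all <- sum(recs$is_expected_ubbp)
      k_in <- sum(recs$is_expected_ubbp[recs$protein_id %in% pre_ids])
      fe <- fisher_ubbp_enrichment(k_in, length(pre_ids), k_all,
                                   length(all_ids))
      data.frame(dataset = nm, k_in = k_in, n_in = length(pre_ids),
                 k_all = k_all, n_all = length(all_ids),
                 odds_ratio = fe$odds_ratio, p = fe$p,
                 stringsAsFactors = FALSE)
    })
    enrichment <- do.call(rbind, enrichment)
  }

  scores <- NULL
  if (length(truths)) scores <- score_calls(calls$all, truths[[1]])

  summary_lines <- c(
    "ubinteract run summary",
    sprintf("seed: %s", format(seed)),
    sprintf("alpha: %g; min_valid: %g; min_fraction: %g; downshift: width=%g shift=%g",
            alpha, min_valid, min_fraction, width, shift),
    unlist(lapply(names(analyses), function(nm) {
      a <- analyses[[nm]]
      c(sprintf("[%s] stage counts: %s", nm,
                paste(sprintf("%s=%d", names(a$counts), a$counts),
                      collapse = ", ")),
        if (length(a$contrasts)) {
          sprintf("[%s] significant (adj_p < %g) per contrast: %s", nm, alpha,
                  paste(vapply(names(a$contrasts), function(cn) {
                    sprintf("%s=%d", cn,
                            sum(a$contrasts[[cn]]$adj_p < alpha))
                  }, character(1)), collapse = ", "))
        })
    })),
    sprintf("calls: %s",
            if (!is.null(calls$all) && nrow(calls$all)) {
              paste(sprintf("%s=%d", names(table(calls$all$call)),
                            as.integer(table(calls$all$call))),
                    collapse = ", ")
            } else "none"),
    if (!is.null(enrichment)) {
      sprintf("expected-UbBP enrichment: %s",
              paste(sprintf("%s OR=%.2f p=%.3g", enrichment$dataset,
                            enrichment$odds_ratio, enrichment$p),
                    collapse = "; "))
    },
    if (!is.null(scores)) {
      c(sprintf("truth recovery: %d calls, FDP=%.3f", scores$n_calls,
                scores$fdp),
        sprintf("  %s: sensitivity=%.3f (%d/%d)", scores$per_class$class,
                scores$per_class$sensitivity, scores$per_class$n_recovered,
                scores$per_class$n_planted))
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(analyses)) {
      a <- analyses[[nm]]
      for (cn in names(a$contrasts)) {
        write_contrast(a$contrasts[[cn]],
                       file.path(out_dir, sprintf("%s_contrast_%s.tsv",
                                                  nm, cn)))
      }
      if (!is.null(a$ftest)) {
        write_contrast(a$ftest$result,
                       file.path(out_dir, sprintf("%s_ftest.tsv", nm)))
      }
      utils::write.table(
        data.frame(protein_id = a$prefilter$retained),
        file.path(out_dir, sprintf("%s_prefiltered.tsv", nm)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(calls$all)) {
      utils::write.table(as.data.frame(calls$all),
                         file.path(out_dir, "specificity_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }

  invisible(list(analyses = analyses, calls = calls, clusters = clusters,
                 enrichment = enrichment, scores = scores,
                 summary = summary_lines, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
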