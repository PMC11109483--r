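#' Fit per-protein group means and pooled residual variance
#'
#' One-way layout per protein: group means for each bait and the residual
#' variance pooled across all groups, `s_g^2 = RSS_g / d_g` with
#' `d_g = N_g - K_g`. This single pooled variance feeds both the moderated t
#' (any pair of groups) and the moderated F (all groups), maximizing residual
#' degrees of freedom.
#'
#' @param matrix a complete (imputed) log2-scale `intensity_matrix`
#' @param design the `sample_design`
#' @param groups bait groups to fit; default all groups in the design that
#'   have at least 2 samples present in the matrix
#' @return a `group_fit` object: `means` (protein x group), `s2`, `df`
#'   (residual df, scalar per protein), `n` (per-group sizes)
#' @export
fit_groups <- function(matrix, design, groups = NULL) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (any(matrix$missing)) {
    stop("fit_groups requires a complete (imputed) matrix", call. = FALSE)
  }
  design <- design[design$sample_id %in% sample_ids(matrix), , drop = FALSE]
  if (length(unique(design$dataset)) > 1L) {
    stop("fit_groups pools variance within one dataset; subset the design first",
         call. = FALSE)
  }
  if (is.null(groups)) groups <- unique(design$bait)
  sizes <- vapply(groups, function(g) sum(design$bait == g), integer(1))
  if (any(sizes < 2L)) {
    stop(sprintf("group(s) with < 2 samples: %s",
                 paste(groups[sizes < 2L], collapse = ", ")), call. = FALSE)
  }
  v <- matrix$values
  means <- vapply(groups, function(g) {
    rowMeans(v[, samples_of(design, g), drop = FALSE])
  }, numeric(nrow(v)))
  means <- matrix(means, nrow = nrow(v),
                  dimnames = list(rownames(v), groups))
  rss <- rowSums(matrix(vapply(groups, function(g) {
    cols <- samples_of(design, g)
    rowSums((v[, cols, drop = FALSE] - means[, g])^2)
  }, numeric(nrow(v))), nrow = nrow(v)))
  d <- sum(sizes) - length(groups)
  structure(
    list(means = means, s2 = rss / d, df = d,
         n = stats::setNames(sizes, groups)),
    class = "group_fit"
  )
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("group_fit: %d proteins, %d groups (%s), residual df = %d\n",
              nrow(x$means), ncol(x$means),
              paste(colnames(x$means), collapse = ", "), x$df))
  invisible(x)
}

# Invert the trigamma function by Newton iteration on 1/x, which is close to
# linear in trigamma; monotone and quadratically convergent.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    t <- trigamma(x)
    delta <- t * (1 - t / y) / psigamma(x, 2L)
    x <- x + delta
    if (abs(delta) < 1e-10 * x) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Hierarchical model: true variances follow a scaled inverse-chi-squared
#' prior with `d0` degrees of freedom and scale `s0^2`, so the observed
#' `s_g^2` are marginally `s0^2 * F(d_g, d0)` distributed. Moment matching on
#' `log s_g^2`: after the digamma/log correction for finite `d_g`, the excess
#' variance of the corrected log variances over `trigamma(d_g/2)` estimates
#' `trigamma(d0/2)`, solved for `d0` by monotone (Newton) inversion; `s0^2`
#' then follows from the corrected mean. Zero or non-finite sample variances
#' are excluded from estimation but still shrink toward the prior.
#'
#' @param s2 per-protein sample variances
#' @param df residual degrees of freedom (scalar or per-protein, >= 1)
#' @return a `variance_prior`: list with `d0` (possibly `Inf`) and `s02`
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(ok) < 10) {
    warning("fewer than 10 usable variances; falling back to d0 = Inf",
            call. = FALSE)
    if (!any(ok)) return(variance_prior(Inf, 1))
    z <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
    return(variance_prior(Inf, exp(mean(z))))
  }
  s2u <- s2[ok]; dfu <- df[ok]
  e <- log(s2u) - digamma(dfu / 2) + log(dfu / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1) - mean(trigamma(dfu / 2))
  if (evar <= 0) {
    return(variance_prior(Inf, exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  variance_prior(d0, s02)
}

#' Construct a variance prior
#' @param d0 prior degrees of freedom, in (0, Inf]
#' @param s02 prior variance, > 0
#' @return a `variance_prior` object
#' @export
variance_prior <- function(d0, s02) {
  if (!(d0 > 0)) stop("d0 must be > 0", call. = FALSE)
  if (!(s02 > 0) || !is.finite(s02)) stop("s02 must be > 0", call. = FALSE)
  structure(list(d0 = d0, s02 = s02), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance_prior: d0 = %s, s0^2 = %.4g\n",
              format(x$d0, digits = 4), x$s02))
  invisible(x)
}

#' Posterior (moderated) variances
#'
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`; always between the sample
#' variance and the prior variance, and strictly positive whenever `s0^2 > 0`.
#'
#' @param s2 sample variances
#' @param df residual degrees of freedom
#' @param prior a `variance_prior`
#' @return numeric vector of moderated variances
#' @export
moderate_variance <- function(s2, df, prior) {
  if (is.infinite(prior$d0)) {
    rep_len(prior$s02, length(s2))
  } else if (prior$d0 == 0) {
    s2
  } else {
    (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
  }
}

# Effective df for the moderated statistic; Inf prior df capped so pt/pf
# stay numerically ordinary.
moderated_df <- function(df, d0) min(df + d0, 1e6)

contrast_result <- function(protein_id, comparison, logFC, statistic, df,
                            p, df1 = NA_real_) {
  d <- data.frame(protein_id = protein_id, comparison = comparison,
                  logFC = logFC, statistic = statistic,
                  df1 = df1, df = df, p = p,
                  adj_p = bh_adjust(p), stringsAsFactors = FALSE)
  class(d) <- c("contrast_result", "data.frame")
  d
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result '%s': %d proteins, %d with adj_p < 0.05\n",
              x$comparison[1], nrow(x), sum(x$adj_p < 0.05)))
  NextMethod()
}

#' Moderated two-sample t test between two bait groups
#'
#' `logFC = mean_A - mean_B`, `t = logFC / (s_tilde * sqrt(1/n_A + 1/n_B))`
#' with the moderated variance, on `d_g + d0` degrees of freedom (capped at
#' 1e6 when `d0 = Inf`); two-sided p and Benjamini-Hochberg adjustment across
#' proteins.
#'
#' @param fit a `group_fit`
#' @param prior a `variance_prior`
#' @param groupA,groupB bait labels present in the fit
#' @return a `contrast_result` data frame, one row per protein
#' @export
moderated_t <- function(fit, prior, groupA, groupB) {
  stopifnot(inherits(fit, "group_fit"), inherits(prior, "variance_prior"))
  if (identical(groupA, groupB)) {
    stop("groupA and groupB must differ", call. = FALSE)
  }
  for (g in c(groupA, groupB)) {
    if (!g %in% colnames(fit$means)) {
      stop(sprintf("group '%s' not in fit", g), call. = FALSE)
    }
  }
  logFC <- fit$means[, groupA] - fit$means[, groupB]
  s2t <- moderate_variance(fit$s2, fit$df, prior)
  se <- sqrt(s2t * (1 / fit$n[[groupA]] + 1 / fit$n[[groupB]]))
  tstat <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0, sign(logFC) * Inf))
  dft <- moderated_df(fit$df, prior$d0)
  p <- 2 * stats::pt(-abs(tstat), dft)
  contrast_result(rownames(fit$means),
                  sprintf("%s_vs_%s", groupA, groupB),
                  logFC, tstat, dft, p)
}

#' Moderated one-way F test across bait groups
#'
#' Between-group mean square over the moderated variance, on
#' `(K - 1, d_g + d0)` degrees of freedom with an upper-tail p. With two
#' groups the statistic equals the squared moderated t.
#'
#' @param fit a `group_fit`
#' @param prior a `variance_prior`
#' @param groups bait labels to compare; default every group in the fit
#' @return a `contrast_result`; `logFC` holds the largest minus smallest
#'   group mean (the enrichment span)
#' @export
moderated_F <- function(fit, prior, groups = colnames(fit$means)) {
  stopifnot(inherits(fit, "group_fit"), inherits(prior, "variance_prior"))
  groups <- unique(groups)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  miss <- setdiff(groups, colnames(fit$means))
  if (length(miss)) {
    stop(sprintf("group(s) not in fit: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  mu <- fit$means[, groups, drop = FALSE]
  n <- fit$n[groups]
  N <- sum(n)
  grand <- as.vector(mu %*% n) / N
  msb <- rowSums(sweep((mu - grand)^2, 2L, n, `*`)) / (length(groups) - 1)
  s2t <- moderate_variance(fit$s2, fit$df, prior)
  Fstat <- ifelse(s2t > 0, msb / s2t, ifelse(msb == 0, 0, Inf))
  df1 <- length(groups) - 1
  df2 <- moderated_df(fit$df, prior$d0)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  span <- apply(mu, 1L, max) - apply(mu, 1L, min)
  contrast_result(rownames(mu),
                  sprintf("F_%s", paste(groups, collapse = ".")),
                  span, Fstat, df2, p, df1 = df1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment with running-minimum enforcement, capped at 1;
#' preserves the rank order of the input p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return vector of adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
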