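# Small programmatic fixtures and independent oracles shared across tests.

# A tiny linear-scale matrix with named rows/columns and optional mask.
tiny_matrix <- function(values, missing = NULL) {
  if (is.null(missing)) missing <- matrix(FALSE, nrow(values), ncol(values))
  dimnames(missing) <- dimnames(values)
  intensity_matrix(values, missing, scale = "linear")
}

# Quadruplicate design over the full default bait panel.
full_design <- function(n_rep = 4, dataset = "d1") {
  baits <- c("bead_control", "mono_Ub", "K48_Ub2", "K48_Ub3",
             "K63_Ub2", "K63_Ub3", "Br_Ub3")
  sample_design(
    sample_id = as.vector(t(outer(baits, seq_len(n_rep), paste, sep = "_R"))),
    bait = rep(baits, each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(baits)),
    dataset = dataset
  )
}

# Two-group design for simple moderated-t fixtures.
two_group_design <- function(nA = 3, nB = 3) {
  sample_design(
    sample_id = c(paste0("a", seq_len(nA)), paste0("b", seq_len(nB)),
                  paste0("ctl", 1:2)),
    bait = c(rep("K48_Ub3", nA), rep("K63_Ub3", nB), rep("bead_control", 2)),
    replicate = c(seq_len(nA), seq_len(nB), 1:2),
    dataset = "d1"
  )
}

# Independent exhaustive hypergeometric oracle for the two-sided Fisher p:
# enumerate every table with the observed margins and sum the probabilities
# of outcomes no more likely than the observed one.
enum_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# Adjusted Rand index between two labelings (independent of any package).
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  maxi <- (b + c_) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# Brute-force BH step-up, written independently of stats::p.adjust.
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# A small contrast_result-like table for classifier rule tests.
fake_contrast <- function(ids, logFC, adj_p, comparison = "X_vs_Y") {
  d <- data.frame(protein_id = ids, comparison = comparison, logFC = logFC,
                  statistic = NA_real_, df1 = NA_real_, df = NA_real_,
                  p = adj_p, adj_p = adj_p, stringsAsFactors = FALSE)
  class(d) <- c("contrast_result", "data.frame")
  d
}
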