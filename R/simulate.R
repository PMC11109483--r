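#' Simulation configuration for a synthetic pulldown interactome
#'
#' Describes the generative model used by [simulate_interactome()]: planted
#' interactor classes with per-bait log2 effect sizes, a log-normal baseline
#' abundance, replicate noise, and intensity-dependent (left-censored)
#' missingness. Defaults emulate a quadruplicate pulldown with a bead-only
#' control and six ubiquitin-chain baits, with effect sizes large enough to
#' give clearly separated enrichment profiles at n = 4. The Ub-enriched
#' fraction is dominated by pan-Ub binders, as in real pulldowns (where
#' bait interactomes correlate strongly); this matters because the general
#' binders are what anchors per-sample median normalization of the
#' prefiltered matrix — a mix dominated by bait-exclusive classes would make
#' the sample medians bait-dependent and bias every cross-bait contrast.
#'
#' Planted classes and their per-bait log2 shifts (defaults):
#' \describe{
#'   \item{background}{0 everywhere.}
#'   \item{bead_binder}{`delta_bead` on the control and every bait (sticks to
#'     the resin, so shows no Ub enrichment over the control).}
#'   \item{pan_ub}{`delta_pref` on every Ub bait.}
#'   \item{K48_specific / K63_specific}{`delta_pref` on the baits of their
#'     linkage, `delta_br_cross` on the branched chain (which contains one
#'     cognate linkage), `delta_minor` on the other homotypic linkage and on
#'     mono-Ub (weak cross-binding).}
#'   \item{length_dependent_K48 / length_dependent_K63}{`delta_pref` on Ub2
#'     of their linkage plus `delta_length` extra on Ub3, with the same
#'     cross-binding profile as the linkage-specific classes.}
#'   \item{branch_specific}{`delta_pref` on the branched chain,
#'     `delta_minor` on the homotypic chains and mono-Ub.}
#'   \item{branch_excluded}{`delta_pref` on the homotypic chains,
#'     `delta_minor` on the branched chain and mono-Ub.}
#' }
#'
#' @param n_proteins number of protein isoforms
#' @param class_prop named numeric vector of class proportions (must sum to 1)
#' @param baits bait groups simulated (must include `bead_control`)
#' @param n_rep replicates per bait group
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution
#' @param sigma_rep replicate noise sd (log2 units)
#' @param delta_pref effect size on a class's preferred bait(s), log2 units
#' @param delta_length extra Ub3-over-Ub2 effect for length-dependent classes
#' @param delta_minor weak cross-binding effect: the branch classes' effect on
#'   their non-preferred chains, and the linkage/length classes' effect on the
#'   other homotypic linkage and mono-Ub
#' @param delta_br_cross linkage/length classes' effect on the branched chain,
#'   which carries one linkage of their cognate type
#' @param delta_bead bead-binder effect on control and baits
#' @param mnar_gamma,mnar_beta logistic missingness midpoint (log2 intensity)
#'   and slope; `mnar = FALSE` disables dropout entirely
#' @param mnar logical, apply intensity-dependent dropout
#' @param dataset dataset label written into the design
#' @param seed RNG seed; the whole simulation is reproducible from it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_proteins = 2000,
                       class_prop = c(background = 0.70,
                                      bead_binder = 0.05,
                                      pan_ub = 0.13,
                                      K48_specific = 0.02,
                                      K63_specific = 0.02,
                                      length_dependent_K48 = 0.02,
                                      length_dependent_K63 = 0.02,
                                      branch_specific = 0.02,
                                      branch_excluded = 0.02),
                       baits = c("bead_control", "mono_Ub",
                                 "K48_Ub2", "K48_Ub3",
                                 "K63_Ub2", "K63_Ub3", "Br_Ub3"),
                       n_rep = 4,
                       baseline_mean = 25, baseline_sd = 2,
                       sigma_rep = 0.4,
                       delta_pref = 3, delta_length = 1.5,
                       delta_minor = 1, delta_br_cross = 2,
                       delta_bead = 2,
                       mnar_gamma = 22, mnar_beta = 1,
                       mnar = TRUE,
                       dataset = "sim", seed = 1) {
  if (abs(sum(class_prop) - 1) > 1e-8) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (any(class_prop < 0)) stop("class proportions must be >= 0", call. = FALSE)
  if (baseline_sd <= 0 || sigma_rep <= 0) {
    stop("all sds must be > 0", call. = FALSE)
  }
  if (!"bead_control" %in% baits) {
    stop("`baits` must include bead_control", call. = FALSE)
  }
  structure(
    list(n_proteins = as.integer(n_proteins), class_prop = class_prop,
         baits = baits, n_rep = as.integer(n_rep),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         sigma_rep = sigma_rep,
         delta_pref = delta_pref, delta_length = delta_length,
         delta_minor = delta_minor, delta_br_cross = delta_br_cross,
         delta_bead = delta_bead,
         mnar_gamma = mnar_gamma, mnar_beta = mnar_beta, mnar = mnar,
         dataset = dataset, seed = seed),
    class = "sim_config"
  )
}

# Per-bait log2 effect sizes for one planted class.
class_delta <- function(class, baits, cfg) {
  d <- stats::setNames(numeric(length(baits)), baits)
  ub <- setdiff(baits, "bead_control")
  k48 <- grep("^K48_", baits, value = TRUE)
  k63 <- grep("^K63_", baits, value = TRUE)
  homotypic <- c(k48, k63)
  mono <- intersect("mono_Ub", baits)
  br <- intersect("Br_Ub3", baits)
  # Linkage/length classes still bind the branched chain (it carries one
  # linkage of their cognate type) and cross-bind weakly elsewhere; a zero
  # profile off the preferred bait would be biologically unrealistic and
  # would also make the prefiltered population bait-asymmetric, which the
  # median-normalization step assumes away.
  cross <- function(pref_linkage, other_linkage) {
    d[other_linkage] <<- cfg$delta_minor
    d[mono] <<- cfg$delta_minor
    d[br] <<- cfg$delta_br_cross
  }
  switch(class,
    background = NULL,
    bead_binder = { d[baits] <- cfg$delta_bead },
    pan_ub = { d[ub] <- cfg$delta_pref },
    K48_specific = { cross(k48, k63); d[k48] <- cfg$delta_pref },
    K63_specific = { cross(k63, k48); d[k63] <- cfg$delta_pref },
    length_dependent_K48 = {
      cross(k48, k63)
      d[k48] <- cfg$delta_pref
      d[grep("^K48_Ub[34]$", baits, value = TRUE)] <-
        cfg$delta_pref + cfg$delta_length
    },
    length_dependent_K63 = {
      cross(k63, k48)
      d[k63] <- cfg$delta_pref
      d[grep("^K63_Ub[34]$", baits, value = TRUE)] <-
        cfg$delta_pref + cfg$delta_length
    },
    branch_specific = {
      d[br] <- cfg$delta_pref
      d[homotypic] <- cfg$delta_minor
      d[mono] <- cfg$delta_minor
    },
    branch_excluded = {
      d[homotypic] <- cfg$delta_pref
      d[br] <- cfg$delta_minor
      d[mono] <- cfg$delta_minor
    },
    stop(sprintf("unknown planted class '%s'", class), call. = FALSE)
  )
  d
}

# Deterministic class counts from proportions: cumulative rounding so counts
# sum exactly to n and a 0.7 proportion of 2000 gives exactly 1400.
class_counts <- function(prop, n) {
  cum <- round(cumsum(prop) * n)
  stats::setNames(diff(c(0, cum)), names(prop))
}

#' Simulate a pulldown interactome with planted interactor classes
#'
#' Generates log2 intensities `x = b_g + delta_gk + eps` with
#' `eps ~ Normal(0, sigma_rep^2)`, exponentiates to the linear iBAQ-like
#' scale, and (optionally) applies intensity-dependent dropout via
#' [apply_mnar_dropout()]. The planted truth (class labels, baselines and the
#' full per-bait effect matrix) is returned alongside, so the generator is
#' its own oracle for recovery tests.
#'
#' @param config a [sim_config()]
#' @return `list(matrix, design, records, truth)` where `truth` is a list
#'   with `labels` (data frame: protein_id, class, baseline) and `delta`
#'   (protein x bait matrix of planted log2 effects)
#' @export
simulate_interactome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  counts <- class_counts(cfg$class_prop, cfg$n_proteins)
  classes <- rep(names(counts), counts)
  n <- length(classes)
  ids <- sprintf("P%0*d", nchar(as.character(n)), seq_len(n))

  delta <- matrix(0, n, length(cfg$baits),
                  dimnames = list(ids, cfg$baits))
  for (cl in unique(classes)) {
    if (cl == "background") next
    delta[classes == cl, ] <- matrix(class_delta(cl, cfg$baits, cfg),
                                     sum(classes == cl), length(cfg$baits),
                                     byrow = TRUE)
  }

  sample_id <- as.vector(t(outer(cfg$baits, seq_len(cfg$n_rep),
                                 function(b, r) paste0(b, "_R", r))))
  bait_of <- rep(cfg$baits, each = cfg$n_rep)

  log2_mat <- with_seed(cfg$seed, {
    b <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    eps <- matrix(stats::rnorm(n * length(sample_id), 0, cfg$sigma_rep),
                  n, length(sample_id))
    m <- b + delta[, bait_of, drop = FALSE] + eps
    dimnames(m) <- list(ids, sample_id)
    attr(m, "baseline") <- b
    m
  })
  baseline <- attr(log2_mat, "baseline")
  attr(log2_mat, "baseline") <- NULL

  mat <- intensity_matrix(log2_mat, matrix(FALSE, n, length(sample_id),
                                           dimnames = dimnames(log2_mat)),
                          scale = "log2")
  if (cfg$mnar) {
    mat <- apply_mnar_dropout(mat, cfg$mnar_gamma, cfg$mnar_beta,
                              seed = substream_seed(cfg$seed, 1L))
  }
  mat <- transform_scale(mat, "linear")

  design <- sample_design(sample_id, bait_of,
                          replicate = rep(seq_len(cfg$n_rep),
                                          times = length(cfg$baits)),
                          dataset = cfg$dataset)
  records <- protein_records(ids)
  truth <- list(
    labels = data.frame(protein_id = ids, class = classes,
                        baseline = baseline, stringsAsFactors = FALSE),
    delta = delta
  )
  list(matrix = mat, design = design, records = records, truth = truth)
}

#' Apply intensity-dependent (left-censored) dropout
#'
#' Each present cell with log2 intensity `x` is masked independently with
#' probability `1 / (1 + exp(beta * (x - gamma)))` — a decreasing function of
#' intensity, emulating the detection-limit censoring that downshift
#' imputation assumes.
#'
#' @param matrix an `intensity_matrix` on the log2 scale
#' @param gamma logistic midpoint (log2 intensity with 50% dropout)
#' @param beta logistic slope, must be >= 0
#' @param seed RNG seed
#' @return the matrix with additional cells masked
#' @export
apply_mnar_dropout <- function(matrix, gamma, beta, seed) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (matrix$scale != "log2") {
    stop("apply_mnar_dropout expects a log2-scale matrix", call. = FALSE)
  }
  if (beta < 0) {
    stop("`beta` must be >= 0 (dropout probability must decrease with intensity)",
         call. = FALSE)
  }
  p_drop <- 1 / (1 + exp(beta * (matrix$values - gamma)))
  p_drop[matrix$missing] <- 0
  drop <- with_seed(seed, {
    matrix(stats::runif(length(p_drop)) < p_drop, nrow(p_drop), ncol(p_drop))
  })
  miss <- matrix$missing | drop
  intensity_matrix(matrix$values, miss, scale = "log2")
}

#' One SPR sensorgram
#'
#' @param cycle injection cycle id
#' @param conc analyte concentration (uM)
#' @param time uniform time grid (s)
#' @param response response (RU) per time point
#' @param assoc_window,dissoc_window `c(t0, t1)` association / dissociation
#'   windows within the grid
#' @return a `sensorgram` object
#' @export
sensorgram <- function(cycle, conc, time, response, assoc_window,
                       dissoc_window = NULL) {
  stop_if_not_scalar_number(conc, "conc", positive = TRUE)
  if (length(time) != length(response)) {
    stop("time and response lengths differ", call. = FALSE)
  }
  rng <- range(time)
  chk <- function(w, name) {
    if (is.null(w)) return(NULL)
    if (length(w) != 2L || w[1] < rng[1] - 1e-9 || w[2] > rng[2] + 1e-9 ||
        w[1] >= w[2]) {
      stop(sprintf("%s must be an increasing pair within the time grid", name),
           call. = FALSE)
    }
    w
  }
  structure(list(cycle = cycle, conc = conc, time = time, response = response,
                 assoc_window = chk(assoc_window, "assoc_window"),
                 dissoc_window = chk(dissoc_window, "dissoc_window")),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("sensorgram: cycle %s, C = %g uM, %d points over %g s\n",
              format(x$cycle), x$conc, length(x$time), diff(range(x$time))))
  invisible(x)
}

#' Simulate 1:1-binding multicycle sensorgrams
#'
#' Association follows `R(t) = Req(C) * (1 - exp(-(kon*C + koff) * t))` with
#' `Req(C) = C * Rmax / (C + KD)` and `KD = koff/kon`; dissociation decays as
#' `R_end * exp(-koff * t)`. Gaussian noise is added per point.
#'
#' @param kon association rate (1/(uM s)), > 0
#' @param koff dissociation rate (1/s), > 0
#' @param Rmax maximal response (RU), > 0
#' @param concentrations strictly increasing analyte concentrations (uM)
#' @param t_assoc,t_dissoc association / dissociation durations (s)
#' @param noise_sd additive Gaussian noise sd (RU)
#' @param seed RNG seed
#' @param dt time step (s)
#' @return list of `sensorgram` objects, one per concentration
#' @export
simulate_sensorgram <- function(kon, koff, Rmax, concentrations,
                                t_assoc = 60, t_dissoc = 60,
                                noise_sd = 0, seed = 1, dt = 0.5) {
  stop_if_not_scalar_number(kon, "kon", positive = TRUE)
  stop_if_not_scalar_number(koff, "koff", positive = TRUE)
  stop_if_not_scalar_number(Rmax, "Rmax", positive = TRUE)
  if (any(diff(concentrations) <= 0) || any(concentrations <= 0)) {
    stop("concentrations must be strictly increasing and > 0", call. = FALSE)
  }
  kd <- koff / kon
  with_seed(seed, {
    lapply(seq_along(concentrations), function(i) {
      C <- concentrations[i]
      req <- C * Rmax / (C + kd)
      kobs <- kon * C + koff
      t_a <- seq(0, t_assoc, by = dt)
      r_a <- req * (1 - exp(-kobs * t_a))
      r_end <- r_a[length(r_a)]
      t_d <- seq(dt, t_dissoc, by = dt)
      r_d <- r_end * exp(-koff * t_d)
      time <- c(t_a, t_assoc + t_d)
      resp <- c(r_a, r_d)
      if (noise_sd > 0) resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
      sensorgram(cycle = i, conc = C, time = time, response = resp,
                 assoc_window = c(0, max(t_a)),
                 dissoc_window = c(max(t_a), max(time)))
    })
  })
}

#' One steady-state concentration series
#'
#' @param replicate replicate id
#' @param conc strictly increasing analyte concentrations (uM)
#' @param req equilibrium responses (RU)
#' @return a `steady_state_series` object
#' @export
steady_state_series <- function(replicate, conc, req) {
  if (any(conc <= 0)) stop("all concentrations must be > 0", call. = FALSE)
  if (any(diff(conc) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (length(conc) != length(req) || any(!is.finite(req))) {
    stop("req must be finite and match conc in length", call. = FALSE)
  }
  structure(list(replicate = replicate, conc = conc, req = req),
            class = "steady_state_series")
}

#' Default SPR concentration grid
#'
#' Two-fold dilution steps from 250 uM down 13 points (to about 0.061 uM),
#' mirroring a multicycle injection range of 60 nM to 250 uM.
#'
#' @param top highest concentration (uM)
#' @param n number of points
#' @return increasing numeric vector of concentrations (uM)
#' @export
spr_concentration_grid <- function(top = 250, n = 13) {
  sort(top / 2^(seq_len(n) - 1))
}

#' Simulate replicate steady-state equilibrium series
#'
#' `Req_i = C_i * Rmax / (C_i + KD) + Normal(0, noise_sd^2)`, `n_rep`
#' replicate series, reproducible from the seed.
#'
#' @param KD dissociation constant (uM), > 0
#' @param Rmax maximal response (RU), > 0
#' @param concentrations strictly increasing concentrations (uM)
#' @param noise_sd additive noise sd (RU)
#' @param n_rep number of replicate series
#' @param seed RNG seed
#' @return list of `steady_state_series`
#' @export
simulate_steady_state <- function(KD, Rmax,
                                  concentrations = spr_concentration_grid(),
                                  noise_sd = 0, n_rep = 3, seed = 1) {
  stop_if_not_scalar_number(KD, "KD", positive = TRUE)
  stop_if_not_scalar_number(Rmax, "Rmax", positive = TRUE)
  mu <- concentrations * Rmax / (concentrations + KD)
  with_seed(seed, {
    lapply(seq_len(n_rep), function(r) {
      req <- mu
      if (noise_sd > 0) req <- req + stats::rnorm(length(mu), 0, noise_sd)
      steady_state_series(r, concentrations, req)
    })
  })
}
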