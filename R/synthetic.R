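#' Specification of one synthetic species
#'
#' Describes a known ground-truth life history from which an age-classified
#' model (and, pooled, a stage-classified model) is built. Mortality regimes
#' map onto the classic survivorship types: `"TYPE_I"` — increasing
#' (Gompertz) hazard `mu(x) = a exp(b x)`, senescent, Keyfitz `H < 1`;
#' `"TYPE_II"` — constant hazard, `H = 1`; `"TYPE_III"` — decreasing hazard
#' `mu(x) = a / (1 + b x)`, `H > 1`.
#'
#' @param regime `"TYPE_I"`, `"TYPE_II"` or `"TYPE_III"`.
#' @param hazard Named numeric parameters: `a`, `b` (Type I/III) or `mu`
#'   (Type II). Defaults: Type I `a = 0.05, b = 0.20`; Type II `mu = 0.20`;
#'   Type III `a = 0.60, b = 0.50`.
#' @param fertility `"iteroparous"` (constant rate over `[alpha, omega]`)
#'   or `"semelparous"` (single reproductive age; placed at the last age so
#'   the pooled life cycle remains irreducible).
#' @param alpha First reproductive age (default 3).
#' @param omega Last reproductive age (default `n_ages - 1`).
#' @param rate Per-capita recruits per reproductive age (default 1).
#' @param clonal_fraction Fraction of reproduction routed through the clonal
#'   matrix `C` (default 0).
#' @param n_ages Number of age classes of the underlying age model.
#' @param n_stages Number of stage classes after pooling (`NULL` = keep the
#'   age model).
#' @param seed_bank Prepend a seed-bank stage? Default `FALSE`.
#' @param species_id Identifier.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(regime = c("TYPE_I", "TYPE_II", "TYPE_III"),
                           hazard = NULL,
                           fertility = c("iteroparous", "semelparous"),
                           alpha = 3L, omega = NULL, rate = 1,
                           clonal_fraction = 0, n_ages = 40L,
                           n_stages = NULL, seed_bank = FALSE,
                           species_id = "synthetic") {
  regime <- match.arg(regime)
  fertility <- match.arg(fertility)
  if (is.null(hazard)) {
    hazard <- switch(regime,
                     TYPE_I = c(a = 0.05, b = 0.20),
                     TYPE_II = c(mu = 0.20),
                     TYPE_III = c(a = 0.60, b = 0.50))
  }
  if (is.null(omega)) omega <- n_ages - 1L
  stopifnot(clonal_fraction >= 0, clonal_fraction <= 1,
            alpha >= 0, omega >= alpha, omega <= n_ages - 1L)
  structure(
    list(regime = regime, hazard = hazard, fertility = fertility,
         alpha = as.integer(alpha), omega = as.integer(omega), rate = rate,
         clonal_fraction = clonal_fraction, n_ages = as.integer(n_ages),
         n_stages = n_stages, seed_bank = isTRUE(seed_bank),
         species_id = species_id),
    class = "synthetic_spec"
  )
}

#' Hazard function of a synthetic spec
#' @param spec A [synthetic_spec()].
#' @return A vectorized function of age.
#' @export
hazard_fn <- function(spec) {
  h <- spec$hazard
  switch(spec$regime,
         TYPE_I = function(x) h[["a"]] * exp(h[["b"]] * x),
         TYPE_II = function(x) rep(h[["mu"]], length(x)),
         TYPE_III = function(x) h[["a"]] / (1 + h[["b"]] * x))
}

#' Build an age-classified (Leslie) MPM from a synthetic spec
#'
#' Age-class survival is `p_x = exp(-mu(x))` on the subdiagonal; per-capita
#' fertility sits in the top active row over the reproductive window
#' (a single age for semelparous specs), split between `F` and `C` by
#' `clonal_fraction`. An optional seed-bank stage is prepended with stasis
#' 0.2 and germination 0.5 into the first age class; half of the sexual
#' recruits are routed through the bank.
#'
#' @param spec A [synthetic_spec()].
#' @param meta A [species_meta()] attached to the model.
#' @return An [mpm()] object.
#' @export
make_age_mpm <- function(spec, meta = species_meta()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  na <- spec$n_ages
  mu <- hazard_fn(spec)
  haz <- mu(0:(na - 2))
  if (any(!is.finite(haz)) || any(haz <= 0)) {
    stop("hazard yields survival probabilities outside (0, 1)",
         call. = FALSE)
  }
  px <- exp(-haz)  # may underflow to 0 in a steep Gompertz tail
  U <- matrix(0, na, na)
  U[cbind(2:na, 1:(na - 1))] <- px
  fert <- numeric(na)
  if (spec$fertility == "semelparous") {
    fert[spec$omega + 1L] <- spec$rate
  } else {
    fert[(spec$alpha:spec$omega) + 1L] <- spec$rate
  }
  Fm <- matrix(0, na, na)
  Cm <- matrix(0, na, na)
  Fm[1, ] <- fert * (1 - spec$clonal_fraction)
  Cm[1, ] <- fert * spec$clonal_fraction
  stages <- data.frame(label = paste0("age_", seq_len(na) - 1L),
                       order_index = seq_len(na) - 1L,
                       is_seed_bank = FALSE)
  if (spec$seed_bank) {
    n <- na + 1L
    U2 <- matrix(0, n, n)
    U2[2:n, 2:n] <- U
    U2[1, 1] <- 0.2          # bank stasis
    U2[2, 1] <- 0.5          # germination into the first age class
    F2 <- matrix(0, n, n)
    C2 <- matrix(0, n, n)
    F2[1, 2:n] <- Fm[1, ] / 2    # half the sexual recruits enter the bank
    F2[2, 2:n] <- Fm[1, ] / 2
    C2[2, 2:n] <- Cm[1, ]        # ramets establish directly
    stages <- rbind(
      data.frame(label = "seed_bank", order_index = 0L, is_seed_bank = TRUE),
      within(stages, order_index <- order_index + 1L)
    )
    U <- U2; Fm <- F2; Cm <- C2
  }
  mpm(U = U, F = Fm, C = Cm, stages = stages,
      species_id = spec$species_id, meta = meta)
}

# stable age weights lambda^-x * lx for pooling; NULL when degenerate
stable_age_weights <- function(m) {
  act <- which(m$stages$is_active)
  lam <- tryCatch(dominant_eigen(m)$lam, error = function(e) NA_real_)
  if (!is.finite(lam) || lam <= 0) return(NULL)
  # survivorship along the age chain
  n <- length(act)
  lx <- numeric(n)
  lx[1] <- 1
  for (k in seq_len(n - 1)) {
    lx[k + 1] <- lx[k] * sum(m$U[act, act[k]])
  }
  w <- lam^(-(seq_len(n) - 1)) * lx
  if (!all(is.finite(w)) || sum(w) <= 0) return(NULL)
  w
}

#' Pool an age-classified model into a stage-classified one
#'
#' Contiguous age classes are pooled into `n_stages` bins (a seed-bank
#' stage, if present, is kept as its own stage). Transition rates are
#' within-bin weighted averages of the age rates, with weights given by the
#' stationary age composition (`lambda^-x l_x`; uniform weights when the
#' growth rate is degenerate, e.g. for periodic semelparous chains). Column
#' sums of `U` are preserved as the weighted averages of the pooled
#' columns, so per-capita survival is conserved at the population level.
#'
#' @param m An age-classified [mpm()] from [make_age_mpm()].
#' @param n_stages Number of active stage bins (less than the number of age
#'   classes).
#' @return A stage-classified [mpm()].
#' @export
aggregate_to_stages <- function(m, n_stages) {
  stopifnot(inherits(m, "mpm"))
  act <- which(m$stages$is_active)
  bank <- which(m$stages$is_seed_bank)
  na <- length(act)
  n_stages <- as.integer(n_stages)
  if (n_stages > na) stop("n_stages must not exceed the number of age ",
                          "classes", call. = FALSE)
  if (n_stages == na) return(m)
  # contiguous bins over active ages
  bin <- cut(seq_len(na), breaks = n_stages, labels = FALSE)
  if (any(tabulate(bin, n_stages) == 0)) {
    stop("empty stage bin", call. = FALSE)
  }
  w <- stable_age_weights(m)
  if (is.null(w)) w <- rep(1, na)
  nb <- length(bank)
  ntot <- n_stages + nb
  U <- matrix(0, ntot, ntot)
  Fm <- matrix(0, ntot, ntot)
  Cm <- matrix(0, ntot, ntot)
  dest <- integer(m$n)              # old index -> new index
  dest[act] <- nb + bin
  if (nb) dest[bank] <- seq_len(nb)
  for (J in seq_len(n_stages)) {
    js <- act[bin == J]
    wj <- w[bin == J]
    s <- sum(wj)
    # uniform fallback when the stationary weights underflow within a bin
    wj <- if (is.finite(s) && s > 0) wj / s else rep(1 / length(wj),
                                                     length(wj))
    for (k in seq_along(js)) {
      j <- js[k]
      for (i in seq_len(m$n)) {
        if (m$U[i, j] != 0) U[dest[i], nb + J] <-
            U[dest[i], nb + J] + wj[k] * m$U[i, j]
        if (m$F[i, j] != 0) Fm[dest[i], nb + J] <-
            Fm[dest[i], nb + J] + wj[k] * m$F[i, j]
        if (m$C[i, j] != 0) Cm[dest[i], nb + J] <-
            Cm[dest[i], nb + J] + wj[k] * m$C[i, j]
      }
    }
  }
  # seed-bank columns copy over unchanged
  for (j in bank) {
    for (i in seq_len(m$n)) {
      if (m$U[i, j] != 0) U[dest[i], dest[j]] <- U[dest[i], dest[j]] +
          m$U[i, j]
      if (m$F[i, j] != 0) Fm[dest[i], dest[j]] <- Fm[dest[i], dest[j]] +
          m$F[i, j]
    }
  }
  stages <- data.frame(
    label = c(if (nb) "seed_bank", paste0("stage_", seq_len(n_stages))),
    order_index = seq_len(ntot) - 1L,
    is_seed_bank = c(rep(TRUE, nb), rep(FALSE, n_stages))
  )
  mpm(U = U, F = Fm, C = Cm, stages = stages,
      species_id = m$species_id, meta = m$meta)
}

#' Add retrogression (shrinkage) to a stage-classified model
#'
#' Published plant MPMs typically contain some probability of shrinking
#' back to a less developed stage. Pooled age models have none, so the
#' generator re-routes a fraction of each stage's stasis into the previous
#' active stage. Column sums of `U` (stage survival) are preserved exactly.
#'
#' @param m A stage-classified [mpm()].
#' @param fraction Fraction of each stage's stasis moved one stage back.
#' @return The perturbed [mpm()].
#' @export
add_shrinkage <- function(m, fraction = 0.05) {
  stopifnot(inherits(m, "mpm"), fraction >= 0, fraction < 1)
  act <- which(m$stages$is_active)
  U <- m$U
  for (k in seq_along(act)[-1]) {
    j <- act[k]
    prev <- act[k - 1]
    moved <- U[j, j] * fraction
    U[j, j] <- U[j, j] - moved
    U[prev, j] <- U[prev, j] + moved
  }
  mpm(U = U, F = m$F, C = m$C, stages = m$stages,
      species_id = m$species_id, meta = m$meta)
}

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips Number of tips (>= 4).
#' @param seed Integer seed.
#' @param tip_labels Optional character vector of tip labels.
#' @return An ultrametric `ape::phylo` tree with positive branch lengths.
#' @export
make_yule_tree <- function(n_tips, seed = 1L, tip_labels = NULL) {
  stopifnot(n_tips >= 4)
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_tips)
    tr$tip.label <- tip_labels
  } else {
    tr$tip.label <- sprintf("sp_%03d", seq_len(n_tips))
  }
  tr
}

#' Simulate correlated traits under Brownian motion on a tree
#'
#' Draws a matrix-normal sample: tip values `X = L_C Z L_S'` where `L_C` is
#' the Cholesky factor of the tree's shared-branch-length covariance, `Z`
#' iid standard normal, and `L_S` the Cholesky factor of the among-trait
#' evolutionary covariance. Root state is zero.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param cov Positive-definite trait covariance matrix.
#' @param seed Integer seed.
#' @return Tips x traits numeric matrix with tip-label row names.
#' @export
simulate_bm_traits <- function(tree, cov, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  cov <- as.matrix(cov)
  Ls <- tryCatch(chol(cov), error = function(e)
    stop("trait covariance is not positive definite", call. = FALSE))
  Cmat <- ape::vcv(tree)
  # eigen square root: the tree covariance is PSD but can be singular
  # (zero-length branches)
  ec <- eigen(Cmat, symmetric = TRUE)
  Lc <- ec$vectors %*% diag(sqrt(pmax(ec$values, 0)), nrow(Cmat))
  set.seed(seed)
  Z <- matrix(stats::rnorm(nrow(Cmat) * ncol(cov)), nrow(Cmat), ncol(cov))
  X <- Lc %*% Z %*% Ls
  rownames(X) <- rownames(Cmat)
  colnames(X) <- colnames(cov)
  X
}

#' Scenario configuration for a synthetic collection
#'
#' @param n_only_sexual,n_sexual_but_clonal,n_sexual_and_clonal Species
#'   counts per reproduction mode. The defaults echo the proportions of a
#'   large comparative plant dataset (124 / 35 / 22).
#' @param regimes Mortality regimes cycled across species.
#' @param n_ages,n_stages Age classes of the underlying models and stage
#'   count after pooling.
#' @param seed_bank_fraction Fraction of species given a seed-bank stage.
#' @param planted_failures Character vector naming deliberate
#'   filter-failure cases to append, any of `"annual"`, `"no_repro"`,
#'   `"survival_ge_1"`, `"short_study"`, `"tree_form"`, `"two_stage"`.
#' @param seed Integer master seed.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_only_sexual = 124L,
                               n_sexual_but_clonal = 35L,
                               n_sexual_and_clonal = 22L,
                               regimes = c("TYPE_I", "TYPE_II", "TYPE_III"),
                               n_ages = 60L, n_stages = 30L,
                               seed_bank_fraction = 0.3,
                               planted_failures = character(0),
                               seed = 1L) {
  structure(
    list(counts = c(ONLY_SEXUAL = as.integer(n_only_sexual),
                    ONLY_SEXUAL_BUT_CLONAL = as.integer(n_sexual_but_clonal),
                    SEXUAL_AND_CLONAL = as.integer(n_sexual_and_clonal)),
         regimes = regimes, n_ages = as.integer(n_ages),
         n_stages = as.integer(n_stages),
         seed_bank_fraction = seed_bank_fraction,
         planted_failures = planted_failures, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

# one planted filter-failure model; all are otherwise-valid 3-stage models
# whose U alone is irreducible (retrogression arcs), so each trips exactly
# its targeted criterion
planted_failure_mpm <- function(kind, species_id) {
  U <- matrix(c(0.1, 0.4, 0,
                0.05, 0.2, 0.5,
                0, 0.1, 0.6), 3, 3)
  Fm <- matrix(0, 3, 3)
  Fm[1, 3] <- 2
  meta <- species_meta()
  m <- switch(kind,
    annual = mpm(U, Fm, species_id = species_id,
                 meta = species_meta(growth_form = "annual")),
    no_repro = mpm(U, species_id = species_id, meta = meta),
    survival_ge_1 = {
      U2 <- U
      U2[3, 3] <- 1.0
      mpm(U2, Fm, species_id = species_id, meta = meta)
    },
    short_study = mpm(U, Fm, species_id = species_id,
                      meta = species_meta(study_years = 1L,
                                          n_annual_matrices = 1L)),
    tree_form = mpm(U, Fm, species_id = species_id,
                    meta = species_meta(growth_form = "tree")),
    two_stage = mpm(matrix(c(0.1, 0.4, 0, 0.5), 2, 2),
                    matrix(c(0, 0, 1.5, 0), 2, 2),
                    species_id = species_id, meta = meta),
    stop("unknown planted failure kind: ", kind, call. = FALSE)
  )
  m
}

#' Generate a full synthetic study collection with ground truth
#'
#' Builds a species collection of stage-classified MPMs spanning the three
#' mortality regimes and three reproduction modes, a matching Yule tree,
#' and a ground-truth table recording each species' regime, the expected
#' side of Keyfitz entropy relative to 1, its reproduction mode, and any
#' deliberately planted filter failure. Regeneration under the same seed is
#' bit-identical.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list: `collection` (list of [mpm()]), `tree` (`ape::phylo`),
#'   `truth` (data frame `species_id`, `regime`, `mode`, `expected_H_side`,
#'   `planted_failure`).
#' @export
make_collection <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  counts <- scenario$counts
  n_good <- sum(counts)
  fails <- scenario$planted_failures
  total <- n_good + length(fails)
  if (total == 0) {
    return(list(collection = list(), tree = NULL,
                truth = data.frame(species_id = character(0),
                                   regime = character(0),
                                   mode = character(0),
                                   expected_H_side = character(0),
                                   planted_failure = character(0))))
  }
  set.seed(scenario$seed)
  ids <- sprintf("sp_%04d", seq_len(total))
  collection <- vector("list", total)
  truth <- data.frame(species_id = ids, regime = NA_character_,
                      mode = NA_character_, expected_H_side = NA_character_,
                      planted_failure = NA_character_,
                      stringsAsFactors = FALSE)
  modes <- rep(names(counts), counts)
  k <- 0L
  for (s in seq_len(n_good)) {
    k <- k + 1L
    mode <- modes[s]
    regime <- scenario$regimes[((s - 1L) %% length(scenario$regimes)) + 1L]
    hz <- switch(regime,
      TYPE_I = c(a = stats::runif(1, 0.03, 0.08),
                 b = stats::runif(1, 0.15, 0.25)),
      TYPE_II = c(mu = stats::runif(1, 0.15, 0.30)),
      TYPE_III = c(a = stats::runif(1, 0.5, 0.8),
                   b = stats::runif(1, 0.4, 0.7)))
    clonal_fraction <- if (mode == "SEXUAL_AND_CLONAL") {
      stats::runif(1, 0.2, 0.5)
    } else 0
    sb <- stats::runif(1) < scenario$seed_bank_fraction
    # age span matched to the regime: stop once the cohort is effectively
    # extinct (cumulative hazard > -log(1e-6)), so tail survival never
    # underflows and the pooled life cycle stays irreducible
    mu_fn <- hazard_fn(structure(list(regime = regime, hazard = hz),
                                 class = "synthetic_spec"))
    cumh <- cumsum(mu_fn(0:(scenario$n_ages - 1)))
    hit <- which(cumh > -log(1e-6))
    n_ages_i <- max(12L, min(scenario$n_ages,
                             if (length(hit)) hit[1] else scenario$n_ages))
    n_stages_i <- min(scenario$n_stages, n_ages_i %/% 2L)
    spec <- synthetic_spec(
      regime = regime, hazard = hz, fertility = "iteroparous",
      alpha = sample(2:5, 1), rate = stats::runif(1, 0.5, 2),
      clonal_fraction = clonal_fraction, n_ages = n_ages_i,
      seed_bank = sb, species_id = ids[k]
    )
    meta <- species_meta(
      growth_form = sample(c("epiphyte", "herbaceous_perennial",
                             "succulent", "shrub"), 1,
                           prob = c(0.1, 0.6, 0.1, 0.2)),
      study_years = sample(3:15, 1),
      n_annual_matrices = sample(2:10, 1),
      clonal_per_knowledge = mode != "ONLY_SEXUAL"
    )
    m_age <- make_age_mpm(spec, meta)
    m_stage <- aggregate_to_stages(m_age, n_stages_i)
    collection[[k]] <- add_shrinkage(m_stage,
                                     fraction = stats::runif(1, 0.02, 0.08))
    truth$regime[k] <- regime
    truth$mode[k] <- mode
    truth$expected_H_side[k] <- switch(regime, TYPE_I = "below",
                                       TYPE_II = "near", TYPE_III = "above")
  }
  for (f in fails) {
    k <- k + 1L
    collection[[k]] <- planted_failure_mpm(f, ids[k])
    truth$planted_failure[k] <- f
  }
  tree <- if (total >= 4) {
    make_yule_tree(total, seed = scenario$seed + 1L, tip_labels = ids)
  } else NULL
  list(collection = collection, tree = tree, truth = truth)
}
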