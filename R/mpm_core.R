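#' Construct a matrix population model (MPM)
#'
#' An MPM describes the annual dynamics of a stage-structured plant
#' population through three component matrices: `U` (survival, growth,
#' shrinkage: probabilities per year), `F` (per-capita sexual recruits per
#' year) and `C` (per-capita clonal recruits, i.e. new ramets, per year).
#' The full projection matrix is `A = U + F + C`. Matrices follow the
#' standard demographic orientation: entry `[i, j]` is the flow from stage
#' `j` (column) to stage `i` (row).
#'
#' @param U,F,C Square numeric matrices of equal dimension. `F` and `C`
#'   default to zero matrices.
#' @param stages A data frame describing the life-cycle stages, with columns
#'   `label` (character), `order_index` (integer, 0 = least developed, a
#'   permutation of `0:(n-1)`) and `is_seed_bank` (logical). Defaults to `n`
#'   active stages in matrix order.
#' @param species_id Character identifier for the species.
#' @param meta A [species_meta()] list.
#'
#' @return An object of class `mpm`: a list with elements `species_id`, `n`,
#'   `stages`, `U`, `F`, `C` and `meta`. The `stages` data frame gains a
#'   derived logical column `is_active` (`!is_seed_bank`).
#' @seealso [validate_mpm()], [dominant_eigen()], [species_meta()]
#' @export
mpm <- function(U, F = NULL, C = NULL, stages = NULL,
                species_id = "unnamed", meta = species_meta()) {
  U <- as.matrix(U)
  n <- nrow(U)
  if (ncol(U) != n) {
    stop("U must be square, got ", n, "x", ncol(U), call. = FALSE)
  }
  zero <- matrix(0, n, n)
  if (is.null(F)) F <- zero
  if (is.null(C)) C <- zero
  F <- as.matrix(F)
  C <- as.matrix(C)
  for (nm in c("F", "C")) {
    M <- get(nm)
    if (!all(dim(M) == c(n, n))) {
      stop(nm, " must match the dimension of U (", n, "x", n, ")",
           call. = FALSE)
    }
  }
  if (is.null(stages)) {
    stages <- data.frame(
      label = paste0("stage_", seq_len(n)),
      order_index = seq_len(n) - 1L,
      is_seed_bank = FALSE
    )
  }
  stages <- as.data.frame(stages)
  req <- c("label", "order_index", "is_seed_bank")
  if (!all(req %in% names(stages))) {
    stop("stages must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(stages) != n) {
    stop("stages has ", nrow(stages), " rows but matrices are ", n, "x", n,
         call. = FALSE)
  }
  if (!setequal(stages$order_index, seq_len(n) - 1L)) {
    stop("stages$order_index must be a permutation of 0:(n-1)", call. = FALSE)
  }
  stages$is_active <- !stages$is_seed_bank
  dimnames(U) <- dimnames(F) <- dimnames(C) <-
    list(stages$label, stages$label)
  structure(
    list(species_id = species_id, n = n, stages = stages,
         U = U, F = F, C = C, meta = meta),
    class = "mpm"
  )
}

#' Species-level study metadata
#'
#' Metadata attached to an MPM used by the study-selection filter:
#' growth form, study effort, experimental treatment, projection time-step,
#' and external botanical knowledge of clonality (a stand-in for a clonality
#' trait database lookup).
#'
#' @param growth_form One of `"epiphyte"`, `"herbaceous_perennial"`,
#'   `"succulent"`, `"shrub"`, `"tree"`, `"palm"`, `"annual"`, `"alga"`,
#'   `"other"`.
#' @param study_years Integer, duration of the field study in years.
#' @param n_annual_matrices Integer, number of annual transition matrices
#'   behind the model.
#' @param treatment `"unmanipulated"` or `"manipulated"`.
#' @param annual_timestep Logical, `TRUE` when the projection interval is one
#'   year.
#' @param clonal_per_knowledge Logical, `TRUE` when external botanical
#'   knowledge says the species can reproduce clonally.
#' @param gps Optional numeric `c(lat, lon)`.
#' @return A list of class `species_meta`.
#' @export
species_meta <- function(growth_form = "herbaceous_perennial",
                         study_years = 3L,
                         n_annual_matrices = 2L,
                         treatment = "unmanipulated",
                         annual_timestep = TRUE,
                         clonal_per_knowledge = FALSE,
                         gps = NULL) {
  growth_form <- match.arg(growth_form, c(
    "epiphyte", "herbaceous_perennial", "succulent", "shrub",
    "tree", "palm", "annual", "alga", "other"
  ))
  treatment <- match.arg(treatment, c("unmanipulated", "manipulated"))
  stopifnot(study_years >= 0, n_annual_matrices >= 0)
  structure(
    list(growth_form = growth_form,
         study_years = as.integer(study_years),
         n_annual_matrices = as.integer(n_annual_matrices),
         treatment = treatment,
         annual_timestep = isTRUE(annual_timestep),
         clonal_per_knowledge = isTRUE(clonal_per_knowledge),
         gps = gps),
    class = "species_meta"
  )
}

#' @export
print.mpm <- function(x, ...) {
  cat("<mpm> ", x$species_id, ": ", x$n, " stages (",
      sum(x$stages$is_seed_bank), " seed bank), growth form ",
      x$meta$growth_form, "\n", sep = "")
  cat("  sum(F) =", signif(sum(x$F), 4), " sum(C) =", signif(sum(x$C), 4),
      "\n")
  invisible(x)
}

#' Full projection matrix of an MPM
#'
#' @param m An [mpm()] object.
#' @return The matrix `A = U + F + C`.
#' @export
mpm_A <- function(m) m$U + m$F + m$C

# boolean reachability: is the directed graph of M strongly connected?
strongly_connected <- function(M) {
  g <- igraph::graph_from_adjacency_matrix(
    (M > 0) + 0, mode = "directed"
  )
  igraph::is_connected(g, mode = "strong")
}

# primitivity via the index-of-primitivity bound: a nonnegative irreducible
# n x n matrix is primitive iff A^((n-1)n + 1) > 0 entrywise (Wielandt)
is_primitive <- function(M) {
  B <- (M > 0) + 0
  n <- nrow(M)
  k <- (n - 1L) * n + 1L
  P <- diag(n)
  Q <- B
  # boolean fast exponentiation
  while (k > 0) {
    if (k %% 2 == 1) P <- ((P %*% Q) > 0) + 0
    Q <- ((Q %*% Q) > 0) + 0
    k <- k %/% 2
  }
  all(P > 0)
}

#' Structural validation of an MPM
#'
#' Runs the structural checks that a comparative demographic analysis
#' imposes on a published projection matrix before life-history traits are
#' derived from it: non-negativity, irreducibility and primitivity of
#' `A = U + F + C`, a minimum stage count, and stage-specific survival
#' (column sums of `U`) strictly below one.
#'
#' Irreducibility is decided by strong connectivity of the directed
#' life-cycle graph of `A`; primitivity by positivity of the boolean
#' adjacency raised to Wielandt's index-of-primitivity bound
#' `(n-1) * n + 1`. Both are evaluated on `A` rather than `U`, because
#' reproduction arcs are part of the life cycle.
#'
#' @param m An [mpm()] object.
#' @param min_dim Minimum stage count: models with `n <= min_dim` fail the
#'   `dim_gt_min` check (default 2, i.e. require at least 3 stages).
#' @return A data frame of class `validation_report` with one row per check
#'   (`nonnegative`, `irreducible`, `primitive`, `dim_gt_min`,
#'   `survival_lt_1`), columns `check`, `passed`, `reason`.
#' @export
validate_mpm <- function(m, min_dim = 2L) {
  stopifnot(inherits(m, "mpm"))
  A <- mpm_A(m)
  checks <- list()
  finite_ok <- all(is.finite(m$U)) && all(is.finite(m$F)) &&
    all(is.finite(m$C))
  nonneg <- finite_ok && all(m$U >= 0) && all(m$F >= 0) && all(m$C >= 0)
  checks$nonnegative <- list(
    passed = nonneg,
    reason = if (nonneg) "" else "negative or non-finite entries in U, F or C"
  )
  irr <- nonneg && strongly_connected(A)
  checks$irreducible <- list(
    passed = irr,
    reason = if (irr) "" else "life-cycle graph of A is not strongly connected"
  )
  prim <- irr && is_primitive(A)
  checks$primitive <- list(
    passed = prim,
    reason = if (prim) "" else "A is not primitive"
  )
  dim_ok <- m$n > min_dim
  checks$dim_gt_min <- list(
    passed = dim_ok,
    reason = if (dim_ok) "" else
      sprintf("n = %d but more than %d stages required", m$n, min_dim)
  )
  cs <- colSums(m$U)
  surv_ok <- nonneg && all(cs < 1)
  checks$survival_lt_1 <- list(
    passed = surv_ok,
    reason = if (surv_ok) "" else
      sprintf("stage survival >= 1 in column(s) %s",
              paste(which(cs >= 1), collapse = ","))
  )
  out <- data.frame(
    check = names(checks),
    passed = vapply(checks, `[[`, logical(1), "passed"),
    reason = vapply(checks, `[[`, character(1), "reason"),
    row.names = NULL
  )
  class(out) <- c("validation_report", class(out))
  out
}

#' Dominant eigen-structure of an MPM
#'
#' @param m An [mpm()] object (or a bare square matrix).
#' @return A list of class `eigen_summary` with `lam` (dominant eigenvalue,
#'   the asymptotic population growth rate), `w` (stable stage distribution,
#'   right eigenvector scaled to sum to 1) and `v` (reproductive values, left
#'   eigenvector scaled so `sum(v * w) = 1`).
#' @export
dominant_eigen <- function(m) {
  A <- if (inherits(m, "mpm")) mpm_A(m) else as.matrix(m)
  if (all(A == 0)) {
    stop("degenerate spectrum: projection matrix is identically zero",
         call. = FALSE)
  }
  er <- eigen(A)
  # Perron root: among max-modulus eigenvalues pick the real non-negative one
  # (periodic matrices tie the spectral radius with rotated copies)
  mods <- Mod(er$values)
  cand <- which(mods >= max(mods) * (1 - 1e-9))
  i <- cand[which.max(Re(er$values[cand]))]
  lam <- er$values[i]
  if (abs(Im(lam)) > 1e-8 * max(1, Mod(lam))) {
    stop("degenerate spectrum: dominant eigenvalue is complex", call. = FALSE)
  }
  lam <- Re(lam)
  w <- Re(er$vectors[, i])
  if (sum(w) < 0) w <- -w
  w <- w / sum(w)
  el <- eigen(t(A))
  modsl <- Mod(el$values)
  candl <- which(modsl >= max(modsl) * (1 - 1e-9))
  j <- candl[which.max(Re(el$values[candl]))]
  v <- Re(el$vectors[, j])
  if (sum(v) < 0) v <- -v
  vw <- sum(v * w)
  if (abs(vw) > 1e-12) v <- v / vw
  structure(list(lam = lam, w = w, v = v), class = "eigen_summary")
}

#' Fundamental matrix of the survival component
#'
#' `N = (I - U)^{-1}`; entry `[i, j]` is the expected number of years an
#' individual starting in stage `j` spends in stage `i` before death.
#'
#' @param U Square survival matrix with spectral radius < 1.
#' @return The fundamental matrix `N`.
#' @export
fundamental_matrix <- function(U) {
  U <- if (inherits(U, "mpm")) U$U else as.matrix(U)
  rho <- max(Mod(eigen(U, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12) {
    stop("spectral radius of U is ", signif(rho, 6),
         " >= 1: immortal life cycle, fundamental matrix undefined",
         call. = FALSE)
  }
  N <- solve(diag(nrow(U)) - U)
  # clamp tiny negative round-off
  N[N < 0 & N > -1e-12] <- 0
  N
}

#' Mean life expectancy from an MPM
#'
#' Expected number of years lived by an individual recruited into the
#' population, computed as the column sums of the fundamental matrix
#' weighted by the starting stage distribution `c0`.
#'
#' @param m An [mpm()] object.
#' @param c0 Starting distribution over stages: non-negative, sums to 1,
#'   zero on seed-bank stages (life is counted from active establishment).
#'   Defaults to [recruit_distribution()] of `m`.
#' @return Mean life expectancy in years (positive scalar).
#' @export
mean_life_expectancy <- function(m, c0 = NULL) {
  stopifnot(inherits(m, "mpm"))
  if (is.null(c0)) c0 <- recruit_distribution(m)
  check_c0(m, c0)
  N <- fundamental_matrix(m$U)
  eta <- as.numeric(colSums(N) %*% c0)
  stopifnot(eta > 0)
  eta
}

check_c0 <- function(m, c0) {
  if (length(c0) != m$n) {
    stop("c0 must have length ", m$n, call. = FALSE)
  }
  if (any(c0 < 0) || abs(sum(c0) - 1) > 1e-8) {
    stop("c0 must be a probability distribution over stages", call. = FALSE)
  }
  if (any(c0[m$stages$is_seed_bank] > 0)) {
    stop("c0 places mass on seed-bank stages; life is counted from active ",
         "establishment", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generation time
#'
#' `T = log(R0) / log(lambda)` where `R0` is the net reproductive rate, the
#' dominant eigenvalue of `(F + C) N` (or `F N` when clonal recruits are
#' excluded), and `lambda` the population growth rate: the number of years
#' for the population to be fully replaced by new recruits.
#'
#' @param m An [mpm()] object.
#' @param include_clonal Count clonal recruits in `R0`? Default `TRUE`.
#' @return Generation time in years, or `NA_real_` when `lambda` is within
#'   `1e-10` of 1 (generation time undefined; eligible for imputation
#'   downstream).
#' @export
generation_time <- function(m, include_clonal = TRUE) {
  stopifnot(inherits(m, "mpm"))
  R <- m$F + if (include_clonal) m$C else 0
  if (sum(R) == 0) {
    stop("no reproduction recorded (sum(F) and sum(C) are zero): ",
         "generation time undefined", call. = FALSE)
  }
  N <- fundamental_matrix(m$U)
  R0 <- max(Mod(eigen(R %*% N, only.values = TRUE)$values))
  if (!is.finite(R0) || R0 <= 0) {
    stop("net reproductive rate R0 is not finite and positive", call. = FALSE)
  }
  lam <- dominant_eigen(m)$lam
  if (abs(lam - 1) < 1e-10) {
    return(NA_real_)
  }
  log(R0) / log(lam)
}

#' Stable-stage-weighted vital rates
#'
#' Mean per-capita survival (`sigma`), sexual reproduction (`phi`), growth
#' (`gamma`, probability of transitioning to a more developed stage) and
#' shrinkage (`rho`, to a less developed stage), averaged across active
#' (non-seed-bank) stages with weights from the stable stage distribution
#' `w` renormalized over active stages. Growth/shrinkage direction is
#' defined by `stages$order_index`; survival, growth and shrinkage count
#' only flows into active stages, so for each active column
#' `growth + shrinkage + stasis = survival` exactly.
#'
#' @param m An [mpm()] object.
#' @return A named list `sigma`, `phi`, `gamma`, `rho`.
#' @export
ssd_weighted_rates <- function(m) {
  stopifnot(inherits(m, "mpm"))
  act <- m$stages$is_active
  if (!any(act)) {
    stop("all stages are seed banks: weighted rates undefined", call. = FALSE)
  }
  w <- dominant_eigen(m)$w
  wa <- w[act]
  if (sum(wa) <= 0) {
    stop("stable stage distribution has no mass on active stages",
         call. = FALSE)
  }
  wa <- wa / sum(wa)
  ord <- m$stages$order_index
  jact <- which(act)
  per <- vapply(jact, function(j) {
    rows <- which(act)
    u <- m$U[rows, j]
    surv <- sum(u)
    gro <- sum(u[ord[rows] > ord[j]])
    shr <- sum(u[ord[rows] < ord[j]])
    rep_ <- sum(m$F[, j])
    c(surv, rep_, gro, shr)
  }, numeric(4))
  res <- as.numeric(per %*% wa)
  list(sigma = res[1], phi = res[2], gamma = res[3], rho = res[4])
}
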