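#' Stage distribution of newly established recruits
#'
#' The cohort that age-from-stage life tables follow starts at active
#' establishment: the per-stage production of recruits at the stable stage
#' distribution, `(F + C) w`, with seed-bank entries zeroed (residence in
#' the bank is left-truncated) and renormalized.
#'
#' @param m An [mpm()] object.
#' @param include_clonal Count clonal recruits? Default `TRUE`.
#' @return A probability vector `c0` over stages, zero on seed banks.
#' @export
recruit_distribution <- function(m, include_clonal = TRUE) {
  stopifnot(inherits(m, "mpm"))
  ev <- dominant_eigen(m)
  R <- m$F + if (include_clonal) m$C else 0
  c0 <- as.numeric(R %*% ev$w)
  c0[m$stages$is_seed_bank] <- 0
  s <- sum(c0)
  if (s <= 0) {
    stop("all recruits land in seed-bank stages (or no reproduction): ",
         "no actively established cohort", call. = FALSE)
  }
  c0 / s
}

#' Age-specific trajectories from a stage-based model
#'
#' Projects a recruit cohort `c0` through the survival matrix `U` and reads
#' off the age schedules: survivorship `lx` (probability of being alive and
#' in an active stage at age `x`; seed-bank rows are excluded from the
#' count), per-capita sexual reproduction `mx` and clonal reproduction `cx`.
#'
#' @param m An [mpm()] object.
#' @param c0 Starting distribution (defaults to [recruit_distribution()]).
#' @param max_age Hard cap on the projected age range.
#' @param lx_min Stop once survivorship falls below this floor.
#' @return An object of class `age_trajectories`: list with `ages` (0-based
#'   integer vector), `lx`, `mx`, `cx`, the cohort stage-structure matrix
#'   `structure` (stages x ages, unnormalized), and `trunc = NULL`
#'   (untruncated).
#' @export
age_trajectories <- function(m, c0 = NULL, max_age = 1000L, lx_min = 1e-9) {
  stopifnot(inherits(m, "mpm"))
  if (is.null(c0)) c0 <- recruit_distribution(m)
  check_c0(m, c0)
  act <- m$stages$is_active
  nx <- c0
  lx <- sum(nx[act])
  if (lx <= 0) stop("degenerate cohort: no active mass at age 0",
                    call. = FALSE)
  L <- M <- Cx <- numeric(0)
  S <- matrix(NA_real_, m$n, 0)
  for (x in 0:max_age) {
    l <- sum(nx[act])
    if (l < lx_min) break
    L <- c(L, l)
    M <- c(M, sum(m$F %*% nx) / l)
    Cx <- c(Cx, sum(m$C %*% nx) / l)
    S <- cbind(S, nx)
    nx <- as.numeric(m$U %*% nx)
  }
  if (length(L) < 2) {
    stop("degenerate cohort: survivorship underflows before age 1",
         call. = FALSE)
  }
  structure(
    list(ages = seq_along(L) - 1L, lx = L / L[1], mx = M, cx = Cx,
         structure = S, trunc = NULL),
    class = "age_trajectories"
  )
}

#' @export
print.age_trajectories <- function(x, ...) {
  cat("<age_trajectories> ages 0..", max(x$ages), sep = "")
  if (!is.null(x$trunc)) {
    cat(" | truncated at QSD90 age ", x$trunc$qsd90_age,
        ", lx99 age ", x$trunc$lx99_age,
        ", eligible = ", x$trunc$eligible, sep = "")
  }
  cat("\n")
  invisible(x)
}

# quasi-stationary distribution: dominant right eigenvector of U restricted
# to active stages; NULL when the spectrum is degenerate (e.g. nilpotent U)
qsd_of <- function(m) {
  act <- m$stages$is_active
  Ua <- m$U[act, act, drop = FALSE]
  ev <- eigen(Ua)
  i <- which.max(Mod(ev$values))
  if (Mod(ev$values[i]) < 1e-12) return(NULL)
  q <- Re(ev$vectors[, i])
  if (sum(q) < 0) q <- -q
  if (any(q < -1e-8)) return(NULL)
  q[q < 0] <- 0
  q / sum(q)
}

#' Right-truncate age trajectories at quasi-stationary convergence
#'
#' Stage-based models carry a stasis loop in the most developed stage, so
#' age trajectories develop artefactual mortality and fertility plateaus
#' once the cohort structure converges. Trajectories are therefore cut at
#' the first age where the normalized active-stage cohort structure is
#' within `qsd_threshold` (Keyfitz's Delta, half the L1 distance) of the
#' quasi-stationary distribution (dominant right eigenvector of the
#' active-stage block of `U`). A species is flagged `eligible` when 99% of
#' the cohort has died (`lx < lx_threshold`) before that convergence age.
#'
#' @param t An untruncated [age_trajectories()] object.
#' @param m The [mpm()] the trajectories came from.
#' @param qsd_threshold Convergence tolerance on Keyfitz's Delta
#'   (default 0.10, i.e. 90% convergence).
#' @param lx_threshold Survivorship level defining cohort extinction
#'   (default 0.01, i.e. 99% dead).
#' @return An `age_trajectories` object cut at the convergence age, with
#'   `trunc` set to a list (`seed_bank_removed`, `qsd90_age`, `lx99_age`,
#'   `eligible`).
#' @export
qsd_truncate <- function(t, m, qsd_threshold = 0.10, lx_threshold = 0.01) {
  stopifnot(inherits(t, "age_trajectories"), inherits(m, "mpm"))
  act <- m$stages$is_active
  q <- qsd_of(m)
  n_ages <- length(t$ages)
  if (is.null(q)) {
    # degenerate QSD (e.g. strictly progressive life cycle): the cohort
    # never converges to a stationary structure, no plateau artefact arises
    qsd90_age <- t$ages[n_ages]
  } else {
    Sa <- t$structure[act, , drop = FALSE]
    tot <- colSums(Sa)
    delta <- vapply(seq_len(n_ages), function(k) {
      if (tot[k] <= 0) return(Inf)
      0.5 * sum(abs(Sa[, k] / tot[k] - q))
    }, numeric(1))
    hit <- which(delta <= qsd_threshold)
    qsd90_age <- if (length(hit)) t$ages[hit[1]] else t$ages[n_ages]
  }
  below <- which(t$lx < lx_threshold)
  lx99_age <- if (length(below)) t$ages[below[1]] else Inf
  keep <- t$ages <= qsd90_age
  out <- t
  out$ages <- t$ages[keep]
  out$lx <- t$lx[keep]
  out$mx <- t$mx[keep]
  out$cx <- t$cx[keep]
  out$structure <- t$structure[, keep, drop = FALSE]
  out$trunc <- list(
    seed_bank_removed = any(m$stages$is_seed_bank),
    qsd90_age = as.integer(qsd90_age),
    lx99_age = if (is.finite(lx99_age)) as.integer(lx99_age) else NA_integer_,
    eligible = is.finite(lx99_age) && lx99_age <= qsd90_age
  )
  out
}

#' Keyfitz life-table entropy
#'
#' `H = -integral(log(lx) * lx dx) / integral(lx dx)` by trapezoidal
#' quadrature, a dimensionless measure of heterogeneity in age at death.
#' `H < 1` indicates mortality increasing with age (senescence, Type I
#' survivorship), `H = 1` constant mortality (Type II), `H > 1` mortality
#' declining with age (escape from senescence, Type III).
#'
#' @param lx Survivorship curve: positive, non-increasing, `lx[1] = 1`.
#' @param ages Age grid matching `lx` (default `0, 1, 2, ...`); may be a
#'   fine non-integer grid for continuous curves.
#' @return Keyfitz entropy `H` (positive scalar).
#' @export
keyfitz_entropy <- function(lx, ages = seq_along(lx) - 1) {
  if (length(lx) != length(ages)) {
    stop("lx and ages must have equal length", call. = FALSE)
  }
  if (abs(lx[1] - 1) > 1e-8) stop("lx must start at 1", call. = FALSE)
  if (any(diff(lx) > 1e-12)) {
    stop("lx must be non-increasing", call. = FALSE)
  }
  # a steep hazard can underflow the tail to exactly 0; l log l -> 0 there,
  # so the trailing zeros contribute nothing and are dropped
  if (any(lx == 0)) {
    keep <- lx > 0
    lx <- lx[keep]
    ages <- ages[keep]
  }
  if (any(lx <= 0)) stop("lx must be strictly positive", call. = FALSE)
  if (length(lx) < 2) {
    stop("need at least two ages to integrate", call. = FALSE)
  }
  num <- -pracma::trapz(ages, log(lx) * lx)
  den <- pracma::trapz(ages, lx)
  num / den
}

#' Demetrius entropy of the reproductive schedule
#'
#' Shannon entropy of the population-growth-discounted age distribution of
#' reproduction: `p_x` proportional to `lambda^{-x} * lx * r_x` with
#' `r_x = mx` (plus `cx` when clonal recruits are included), renormalized to
#' sum to 1 over the (truncated) age range, and `S = -sum(p * log(p))`.
#' `S = 0` is strict semelparity (all reproduction at one age); larger `S`
#' means a more iteroparous, spread-out schedule.
#'
#' @param lx,mx,cx Age schedules on a common integer grid starting at age 0.
#' @param lam Population growth rate `lambda` (> 0).
#' @param include_clonal Add `cx` to the reproductive schedule? Default
#'   `TRUE`.
#' @return Demetrius entropy `S` in nats, or `NA_real_` when no reproduction
#'   occurs in the window.
#' @export
demetrius_entropy <- function(lx, mx, cx = NULL, lam = 1,
                              include_clonal = TRUE) {
  stopifnot(lam > 0, length(mx) == length(lx))
  if (is.null(cx)) cx <- numeric(length(mx))
  stopifnot(length(cx) == length(lx))
  r <- mx + if (include_clonal) cx else 0
  x <- seq_along(lx) - 1
  p <- lam^(-x) * lx * r
  s <- sum(p)
  if (s <= 0) return(NA_real_)
  p <- p[p > 0] / s
  -sum(p * log(p)) + 0  # + 0 normalizes the signed zero of a single atom
}

#' First and last reproduction and the reproductive span
#'
#' `L_alpha` is the first age with per-capita reproduction above `eps` in
#' the truncated window, `L_omega` the last. The span `L_alpha_omega` has
#' two variants used in different parts of comparative analyses:
#' `"mature"` (default) is mature life expectancy `eta_e - L_alpha`;
#' `"window"` is the window between reproductive events, `L_omega - L_alpha`.
#'
#' @param t A truncated [age_trajectories()] object.
#' @param eta_e Mean life expectancy (needed for the `"mature"` variant).
#' @param variant `"mature"` or `"window"`.
#' @param include_clonal Count clonal reproduction (first/last event whether
#'   clonal or sexual)? Default `TRUE`.
#' @param eps Threshold below which reproduction counts as zero.
#' @return A list `L_alpha`, `L_omega`, `L_alpha_omega`; all `NA` when no
#'   reproduction occurs in the window.
#' @export
reproductive_span <- function(t, eta_e = NULL,
                              variant = c("mature", "window"),
                              include_clonal = TRUE, eps = 1e-7) {
  variant <- match.arg(variant)
  stopifnot(inherits(t, "age_trajectories"))
  r <- t$mx + if (include_clonal) t$cx else 0
  on <- which(r > eps)
  if (!length(on)) {
    return(list(L_alpha = NA_real_, L_omega = NA_real_,
                L_alpha_omega = NA_real_))
  }
  La <- t$ages[on[1]]
  Lo <- t$ages[on[length(on)]]
  span <- if (variant == "window") {
    Lo - La
  } else {
    if (is.null(eta_e)) {
      stop("variant 'mature' needs eta_e (mean life expectancy)",
           call. = FALSE)
    }
    eta_e - La
  }
  list(L_alpha = as.numeric(La), L_omega = as.numeric(Lo),
       L_alpha_omega = as.numeric(span))
}

#' Survivorship curve from a hazard function
#'
#' Builds `l(x) = exp(-integral_0^x mu(t) dt)` on a grid by trapezoidal
#' accumulation of the hazard. Convenience used for analytic checks of
#' entropy behaviour (Type I: increasing hazard; Type II: constant;
#' Type III: decreasing).
#'
#' @param mu Vectorized hazard function of age.
#' @param ages Increasing age grid starting at 0.
#' @return Survivorship values on `ages`, starting at 1.
#' @export
survivorship_from_hazard <- function(mu, ages) {
  stopifnot(ages[1] == 0, all(diff(ages) > 0))
  h <- mu(ages)
  cumhaz <- pracma::cumtrapz(ages, h)
  exp(-as.numeric(cumhaz))
}
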