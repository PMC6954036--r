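#' Derive the life-history trait vector of one species
#'
#' Composes the matrix-algebra and life-table machinery into the eight
#' traits used for multivariate life-history analysis, plus Keyfitz entropy:
#' generation time `T`, mean life expectancy `eta_e`, stable-stage-weighted
#' survival `sigma`, mature life expectancy `L_am` (span from first
#' reproduction), Demetrius entropy `S`, weighted sexual reproduction `phi`,
#' weighted growth `gamma` and shrinkage `rho`, and Keyfitz entropy `H`
#' computed on the truncated survivorship. A failure in any component (e.g.
#' no reproduction inside the truncated window) yields a missing value for
#' the affected traits rather than an error.
#'
#' @param m A retained [mpm()].
#' @param t Optional pre-computed truncated [age_trajectories()]; computed
#'   (and QSD-truncated) from `m` when `NULL`.
#' @param include_clonal Count clonal recruits in generation time, the
#'   reproductive schedule and the recruit distribution? Default `TRUE`.
#' @param span_variant Variant of the reproductive span, see
#'   [reproductive_span()].
#' @return A one-row data frame with columns `species_id`, `T`, `eta_e`,
#'   `sigma`, `L_am`, `S`, `phi`, `gamma`, `rho`, `H`, `mode`, `eligible`.
#' @export
derive_traits <- function(m, t = NULL, include_clonal = TRUE,
                          span_variant = "mature") {
  stopifnot(inherits(m, "mpm"))
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  ev <- try(dominant_eigen(m), silent = TRUE)
  lam <- if (inherits(ev, "try-error")) NA_real_ else ev$lam
  if (is.null(t)) {
    t <- tryCatch({
      traj <- age_trajectories(m, recruit_distribution(m, include_clonal))
      qsd_truncate(traj, m)
    }, error = function(e) NULL)
  }
  Tg <- try_na(generation_time(m, include_clonal))
  eta <- try_na(mean_life_expectancy(m,
                                     recruit_distribution(m, include_clonal)))
  rates <- tryCatch(ssd_weighted_rates(m), error = function(e)
    list(sigma = NA_real_, phi = NA_real_, gamma = NA_real_, rho = NA_real_))
  S <- H <- L_am <- NA_real_
  eligible <- FALSE
  if (!is.null(t)) {
    eligible <- isTRUE(t$trunc$eligible)
    if (length(t$lx) >= 2) H <- try_na(keyfitz_entropy(t$lx, t$ages))
    if (!is.na(lam)) {
      S <- try_na(demetrius_entropy(t$lx, t$mx, t$cx, lam, include_clonal))
    }
    sp <- tryCatch(
      reproductive_span(t, eta_e = eta, variant = span_variant,
                        include_clonal = include_clonal),
      error = function(e) list(L_alpha_omega = NA_real_))
    L_am <- sp$L_alpha_omega
  }
  mode <- tryCatch(classify_reproduction_mode(m),
                   error = function(e) NA_character_)
  data.frame(
    species_id = m$species_id,
    T = Tg, eta_e = eta, sigma = rates$sigma, L_am = L_am, S = S,
    phi = rates$phi, gamma = rates$gamma, rho = rates$rho, H = H,
    mode = mode, eligible = eligible,
    stringsAsFactors = FALSE
  )
}

#' Trait columns entering the multivariate analysis
#' @keywords internal
pca_trait_names <- function() {
  c("T", "eta_e", "sigma", "L_am", "S", "phi", "gamma", "rho")
}

#' Assemble the analysis-ready trait matrix
#'
#' Applies the standard pre-processing to the species-by-trait table:
#' natural-log transform of each trait (traits that can legitimately be 0
#' are shifted by `eps` = half the smallest positive observed value before
#' logging; negatives become missing), per-trait masking of values outside
#' the given percentile range of the log-transformed distribution, and
#' standardization of each column to mean 0, variance 1 over the remaining
#' values. Keyfitz entropy `H` is carried untransformed as the downstream
#' response variable, not a PCA input.
#'
#' @param traits Data frame as returned by rbind-ing [derive_traits()] rows.
#' @param pcts Lower/upper percentile bounds for outlier masking
#'   (default `c(2.5, 97.5)`).
#' @param bounds Optional traits x 2 matrix of fixed log-scale masking
#'   bounds (as stored in `$outlier_bounds`); when supplied, the percentile
#'   estimation is skipped and these bounds are applied, which makes
#'   masking idempotent under re-application.
#' @return An object of class `trait_matrix`: list with `X` (species x 8
#'   standardized matrix, `NA` where missing or masked), `mask` (logical
#'   matrix, `TRUE` = unavailable), `center`, `scale`, `eps` (per-column log
#'   shifts), `species_id`, `H`, `mode`, and `transforms` flags.
#' @export
build_trait_matrix <- function(traits, pcts = c(2.5, 97.5), bounds = NULL) {
  stopifnot(is.data.frame(traits), nrow(traits) >= 3)
  cols <- pca_trait_names()
  stopifnot(all(cols %in% names(traits)))
  X <- as.matrix(traits[, cols])
  rownames(X) <- traits$species_id
  eps <- numeric(length(cols))
  names(eps) <- cols
  # log transform; zero-capable traits get a half-minimum shift
  for (j in seq_along(cols)) {
    x <- X[, j]
    pos <- x[!is.na(x) & x > 0]
    has_zero <- any(!is.na(x) & x == 0)
    if (has_zero) {
      if (!length(pos)) {
        stop("trait '", cols[j], "' has no positive values to anchor the ",
             "log shift", call. = FALSE)
      }
      eps[j] <- min(pos) / 2
    }
    x[!is.na(x) & x < 0] <- NA
    x[!is.na(x) & x == 0 & eps[j] == 0] <- NA
    X[, j] <- log(x + eps[j])
  }
  # percentile outlier mask on the logged values
  if (is.null(bounds)) {
    bounds <- matrix(c(-Inf, Inf), length(cols), 2, byrow = TRUE,
                     dimnames = list(cols, c("lo", "hi")))
    for (j in seq_along(cols)) {
      obs <- X[!is.na(X[, j]), j]
      if (length(obs) >= 3) {
        bounds[j, ] <- stats::quantile(obs, pcts / 100, names = FALSE)
      }
    }
  }
  for (j in seq_along(cols)) {
    x <- X[, j]
    X[!is.na(x) & (x < bounds[cols[j], 1] | x > bounds[cols[j], 2]), j] <- NA
  }
  # standardize
  center <- colMeans(X, na.rm = TRUE)
  scale_ <- apply(X, 2, stats::sd, na.rm = TRUE)
  for (j in seq_along(cols)) {
    if (all(is.na(X[, j]))) {
      stop("trait '", cols[j], "' is entirely missing after masking",
           call. = FALSE)
    }
    if (!is.finite(scale_[j]) || scale_[j] == 0) {
      stop("trait '", cols[j], "' has zero variance: cannot standardize",
           call. = FALSE)
    }
    X[, j] <- (X[, j] - center[j]) / scale_[j]
  }
  structure(
    list(X = X, mask = is.na(X), center = center, scale = scale_, eps = eps,
         outlier_bounds = bounds,
         species_id = traits$species_id, H = traits$H, mode = traits$mode,
         transforms = list(logged = TRUE, standardized = TRUE,
                           outliers_masked = TRUE, imputed = FALSE)),
    class = "trait_matrix"
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("<trait_matrix> ", nrow(x$X), " species x ", ncol(x$X), " traits; ",
      sum(x$mask), " missing/masked values (",
      round(100 * mean(x$mask), 1), "%)",
      if (isTRUE(x$transforms$imputed)) "; imputed" else "", "\n", sep = "")
  invisible(x)
}
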