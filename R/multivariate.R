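#' Chained-equation imputation with predictive mean matching
#'
#' Completes a [build_trait_matrix()] object by multivariate imputation by
#' chained equations: missing entries are initialized at column means, then
#' for `n_iter` sweeps each incomplete column is regressed (ordinary least
#' squares) on all other columns using its observed rows, and each missing
#' value is replaced by a donor draw — an observed value of that column whose
#' fitted prediction is among the `donors` closest to the missing row's
#' prediction (predictive mean matching). A single completed dataset is
#' produced; the result is deterministic under a fixed `seed`.
#'
#' @param tm A `trait_matrix`.
#' @param n_iter Number of chained-equation sweeps (default 10).
#' @param donors Donor-pool size for predictive mean matching (default 5).
#' @param seed Integer seed controlling donor draws.
#' @return The completed `trait_matrix` (no `NA` in `X`; `mask` still
#'   records which entries were imputed; `transforms$imputed = TRUE`).
#' @export
impute_missing <- function(tm, n_iter = 10L, donors = 5L, seed = 1L) {
  stopifnot(inherits(tm, "trait_matrix"))
  X <- tm$X
  miss <- is.na(X)
  if (!any(miss)) return(tm)
  p <- ncol(X)
  n_obs <- colSums(!miss)
  frac_miss <- colMeans(miss)
  if (any(frac_miss > 0.5)) {
    stop("column(s) ", paste(colnames(X)[frac_miss > 0.5], collapse = ", "),
         " have more than 50% missing values", call. = FALSE)
  }
  if (any(n_obs < p + 2)) {
    stop("column(s) ", paste(colnames(X)[n_obs < p + 2], collapse = ", "),
         " have too few observed values to regress on the others",
         call. = FALSE)
  }
  set.seed(seed)
  # initialize at column means of observed values
  for (j in seq_len(p)) {
    X[miss[, j], j] <- mean(X[!miss[, j], j])
  }
  for (it in seq_len(n_iter)) {
    for (j in which(colSums(miss) > 0)) {
      obs <- !miss[, j]
      fit <- stats::lm.fit(cbind(1, X[obs, -j, drop = FALSE]), X[obs, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred_all <- as.numeric(cbind(1, X[, -j, drop = FALSE]) %*% beta)
      pred_obs <- pred_all[obs]
      y_obs <- X[obs, j]
      for (i in which(miss[, j])) {
        d <- abs(pred_obs - pred_all[i])
        pool <- order(d)[seq_len(min(donors, length(d)))]
        X[i, j] <- y_obs[pool[sample.int(length(pool), 1L)]]
      }
    }
  }
  tm$X <- X
  tm$transforms$imputed <- TRUE
  tm
}

#' Phylogenetically corrected principal component analysis
#'
#' PCA on the evolutionary (Brownian-motion) covariance of the traits:
#' with tree covariance `Cmat` (shared branch lengths), the GLS ancestral
#' mean is `a = (1' Cmat^-1 1)^-1 1' Cmat^-1 X`, the evolutionary covariance
#' `R = (X - 1a)' Cmat^-1 (X - 1a) / (N - 1)`, and the loadings are the
#' eigenvectors of `R`. Scores are the GLS-centred data projected on the
#' loadings. On a star phylogeny with equal branch lengths this reduces to
#' ordinary covariance PCA.
#'
#' @param tm A complete `trait_matrix` (no missing values in `X`), or a bare
#'   numeric matrix with species row names.
#' @param tree An `ape::phylo` tree whose tip labels match the matrix rows
#'   one-to-one (extra tips are dropped).
#' @return A list of class `pca_result`: `loadings` (traits x axes),
#'   `scores` (species x axes), `eigenvalues`, `pct_var`, `retained`
#'   (Kaiser-criterion axis indices), `anc_mean`.
#' @export
phylo_pca <- function(tm, tree) {
  X <- if (inherits(tm, "trait_matrix")) tm$X else as.matrix(tm)
  if (anyNA(X)) {
    stop("trait matrix has missing values; run impute_missing() first",
         call. = FALSE)
  }
  stopifnot(inherits(tree, "phylo"))
  ids <- rownames(X)
  if (is.null(ids)) stop("trait matrix must have species row names",
                         call. = FALSE)
  missing_tips <- setdiff(ids, tree$tip.label)
  if (length(missing_tips)) {
    stop("species absent from the tree: ",
         paste(utils::head(missing_tips, 5), collapse = ", "), call. = FALSE)
  }
  if (length(tree$tip.label) > length(ids)) {
    tree <- ape::keep.tip(tree, ids)
  }
  Cmat <- ape::vcv(tree)[ids, ids]
  ch <- tryCatch(chol(Cmat), error = function(e)
    stop("phylogenetic covariance is not positive definite", call. = FALSE))
  Cinv <- chol2inv(ch)
  one <- rep(1, nrow(X))
  a <- as.numeric((t(one) %*% Cinv %*% X) / sum(Cinv))
  Xc <- sweep(X, 2, a)
  R <- t(Xc) %*% Cinv %*% Xc / (nrow(X) - 1)
  R <- (R + t(R)) / 2
  ee <- eigen(R, symmetric = TRUE)
  loadings <- ee$vectors
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(ncol(X))))
  scores <- Xc %*% loadings
  ev <- ee$values
  out <- structure(
    list(loadings = loadings, scores = scores, eigenvalues = ev,
         pct_var = 100 * ev / sum(ev), anc_mean = a,
         retained = integer(0)),
    class = "pca_result"
  )
  out$retained <- retain_axes_kaiser(out)
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " species, ",
      ncol(x$loadings), " axes; retained (Kaiser): ",
      paste(x$retained, collapse = ", "), "\n", sep = "")
  cat("  % variance:", paste(sprintf("%.2f", x$pct_var), collapse = " "),
      "\n")
  invisible(x)
}

#' Kaiser criterion for axis retention
#'
#' For a PCA of standardized traits, retain the axes whose eigenvalue is
#' strictly greater than 1 (i.e. that explain more than one trait's worth of
#' variance), in decreasing eigenvalue order.
#'
#' @param p A `pca_result`.
#' @return Integer vector of retained axis indices (possibly empty, with a
#'   warning).
#' @export
retain_axes_kaiser <- function(p) {
  idx <- which(p$eigenvalues > 1)
  if (!length(idx)) {
    warning("no eigenvalue exceeds 1: no axis retained by the Kaiser rule")
  }
  idx[order(p$eigenvalues[idx], decreasing = TRUE)]
}

coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], SE = s[, 2],
             t = s[, 3], P = s[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Predict Keyfitz entropy from PCA scores
#'
#' Fits the two-way model `H ~ PC1 + PC2 + PC1:PC2` by least squares, for
#' all species and (optionally) within a reproduction-mode subset, returning
#' the per-term estimate, standard error, t statistic and two-sided P value.
#'
#' @param H Numeric response vector (Keyfitz entropy per species).
#' @param scores Species x 2 matrix of retained PCA scores (columns PC1,
#'   PC2).
#' @param subset Optional logical vector selecting a species subset.
#' @param min_n Minimum subset size (default 10).
#' @return A data frame of class `regression_result` with columns `term`,
#'   `estimate`, `SE`, `t`, `P`.
#' @export
regress_entropy_on_scores <- function(H, scores, subset = NULL, min_n = 10L) {
  scores <- as.matrix(scores)
  stopifnot(length(H) == nrow(scores), ncol(scores) >= 2)
  if (!is.null(subset)) {
    H <- H[subset]
    scores <- scores[subset, , drop = FALSE]
  }
  keep <- !is.na(H)
  H <- H[keep]
  scores <- scores[keep, , drop = FALSE]
  if (length(H) < min_n) {
    stop("need at least ", min_n, " species, got ", length(H), call. = FALSE)
  }
  d <- data.frame(H = H, PC1 = scores[, 1], PC2 = scores[, 2])
  if (stats::sd(d$PC1) == 0 || stats::sd(d$PC2) == 0) {
    stop("constant score column: model is rank deficient", call. = FALSE)
  }
  fit <- stats::lm(H ~ PC1 * PC2, data = d)
  if (fit$rank < 4) stop("model is rank deficient", call. = FALSE)
  out <- coef_table(fit)
  class(out) <- c("regression_result", class(out))
  out
}

#' Clonality-covariate models for Keyfitz entropy
#'
#' Three companion models asking whether the ability to reproduce clonally
#' shifts the entropy-versus-strategy relationship: (A)
#' `H ~ PC1 + PC2 + clonal + PC1:clonal + PC2:clonal`; (B)
#' `H ~ PC1 * clonal`; (C) `H ~ PC2 * clonal`.
#'
#' @param H Numeric response vector.
#' @param scores Species x 2 score matrix.
#' @param clonal Logical vector (known clonality per species).
#' @return Named list (`A`, `B`, `C`) of `regression_result` tables.
#' @export
clonality_covariate_models <- function(H, scores, clonal) {
  scores <- as.matrix(scores)
  stopifnot(length(H) == nrow(scores), length(clonal) == length(H))
  keep <- !is.na(H) & !is.na(clonal)
  d <- data.frame(H = H[keep], PC1 = scores[keep, 1], PC2 = scores[keep, 2],
                  clonal = as.logical(clonal[keep]))
  if (length(unique(d$clonal)) < 2) {
    stop("clonality vector has a single class", call. = FALSE)
  }
  fits <- list(
    A = stats::lm(H ~ PC1 + PC2 + clonal + PC1:clonal + PC2:clonal, data = d),
    B = stats::lm(H ~ PC1 * clonal, data = d),
    C = stats::lm(H ~ PC2 * clonal, data = d)
  )
  lapply(fits, function(f) {
    out <- coef_table(f)
    class(out) <- c("regression_result", class(out))
    out
  })
}

#' One-sample t-tests of group mean entropy against 1
#'
#' For each reproduction mode, tests whether the group mean Keyfitz entropy
#' differs from the threshold value 1 separating senescence (`H < 1`) from
#' escape from senescence (`H > 1`).
#'
#' @param H Numeric entropy values.
#' @param mode Grouping vector (reproduction modes).
#' @param mu Null value (default 1).
#' @return Data frame with one row per group: `mode`, `n`, `mean`, `SE`,
#'   `df`, `t`, `P`.
#' @export
group_entropy_tests <- function(H, mode, mu = 1) {
  keep <- !is.na(H) & !is.na(mode)
  H <- H[keep]
  mode <- mode[keep]
  groups <- unique(mode)
  rows <- lapply(groups, function(g) {
    x <- H[mode == g]
    if (length(x) < 2) {
      stop("group '", g, "' has fewer than 2 observations", call. = FALSE)
    }
    n <- length(x)
    se <- stats::sd(x) / sqrt(n)
    dev <- mean(x) - mu
    # a constant group sitting exactly on the null has no evidence against it
    tstat <- if (se > 0) dev / se else if (dev == 0) 0 else Inf * sign(dev)
    pval <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), n - 1) else 0
    data.frame(mode = g, n = n, mean = mean(x), SE = se,
               df = n - 1, t = tstat, P = pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# compact letter display: groups not significantly different share a letter;
# letters are the maximal cliques of the non-significance graph, ordered by
# group mean
letters_from_nonsig <- function(groups, nonsig_pairs, means) {
  g <- igraph::make_empty_graph(n = length(groups), directed = FALSE)
  igraph::V(g)$name <- groups
  if (nrow(nonsig_pairs)) {
    g <- igraph::add_edges(g, t(as.matrix(nonsig_pairs)))
  }
  cl <- igraph::max_cliques(g)
  # order cliques by the mean of their best group so letters read a..z along
  # the trait gradient
  cl <- cl[order(vapply(cl, function(v) min(means[v]), numeric(1)))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cl)) {
    members <- igraph::V(g)$name[cl[[k]]]
    out[members] <- paste0(out[members], letters[k])
  }
  out
}

#' Tukey HSD comparison of a trait across reproduction modes
#'
#' One-way ANOVA followed by Tukey's honest significant difference test on
#' all pairwise mode contrasts, with a compact letter display at the given
#' significance level (groups sharing a letter do not differ).
#'
#' @param values Numeric trait values.
#' @param modes Grouping vector with at least two groups of size >= 2.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list: `pairs` (data frame `contrast`, `diff`, `lwr`, `upr`,
#'   `P_adj`) and `letters` (named character vector per group).
#' @export
tukey_by_mode <- function(values, modes, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(modes)
  values <- values[keep]
  modes <- factor(modes[keep])
  sizes <- table(modes)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  }
  fit <- stats::aov(values ~ modes)
  tk <- stats::TukeyHSD(fit)$modes
  pairs <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      P_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  groups <- levels(modes)
  idx <- do.call(rbind, strsplit(pairs$contrast, "-", fixed = TRUE))
  nonsig <- pairs$P_adj > alpha
  nonsig_pairs <- cbind(match(idx[nonsig, 1], groups),
                        match(idx[nonsig, 2], groups))
  nonsig_pairs <- matrix(nonsig_pairs, ncol = 2)
  means <- tapply(values, modes, mean)
  list(pairs = pairs,
       letters = letters_from_nonsig(groups, nonsig_pairs, means))
}
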