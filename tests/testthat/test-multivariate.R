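# build a small trait_matrix-like object directly
tm_from_matrix <- function(X) {
  structure(list(X = X, mask = is.na(X), species_id = rownames(X)),
            class = "trait_matrix")
}

test_that("imputation is a no-op on complete data and PMM draws donors", {
  set.seed(51)
  n <- 1500
  x <- rnorm(n)
  X <- cbind(a = x, b = 2 * x + rnorm(n, sd = 0.01),
             c = -x + rnorm(n, sd = 0.01))
  rownames(X) <- sprintf("s%04d", 1:n)

  tm <- tm_from_matrix(X)
  expect_identical(impute_missing(tm, seed = 3)$X, X)

  # mask 10% of b; truth retained for comparison
  Xm <- X
  miss_idx <- sample(n, n %/% 10)
  Xm[miss_idx, "b"] <- NA
  tm2 <- impute_missing(tm_from_matrix(Xm), n_iter = 10, donors = 1,
                        seed = 3)
  imputed <- tm2$X[miss_idx, "b"]
  expect_gte(mean(abs(imputed - X[miss_idx, "b"]) < 3 * 0.01), 0.9)
  # PMM property: every imputed value equals some observed value
  observed <- X[-miss_idx, "b"]
  expect_true(all(imputed %in% observed))

  # determinism under the seed
  tm3 <- impute_missing(tm_from_matrix(Xm), n_iter = 10, donors = 1,
                        seed = 3)
  expect_identical(tm2$X, tm3$X)

  # too much missingness
  Xbad <- X
  Xbad[seq_len(0.6 * n), "b"] <- NA
  expect_error(impute_missing(tm_from_matrix(Xbad)), "50%")
})

test_that("phylo PCA on a star tree equals ordinary covariance PCA", {
  set.seed(52)
  n <- 40
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("s%02d", 1:n)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(tr$tip.label, paste0("t", 1:5)))
  p <- phylo_pca(X, tr)
  ref <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(p$eigenvalues, ref$values, tolerance = 1e-8)
  for (k in 1:5) {
    expect_equal(abs(sum(p$loadings[, k] * ref$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  # eigenvalue sum equals the trace of the evolutionary covariance
  expect_equal(sum(p$eigenvalues), sum(diag(stats::cov(X))),
               tolerance = 1e-8)
  # percentages sum to 100
  expect_equal(sum(p$pct_var), 100, tolerance = 1e-6)
})

test_that("phylo PCA matches the phytools reference implementation", {
  tr <- make_yule_tree(24, seed = 5)
  cv <- diag(4); cv[1, 2] <- cv[2, 1] <- 0.6
  X <- simulate_bm_traits(tr, cv, seed = 9)
  colnames(X) <- paste0("t", 1:4)
  p1 <- phylo_pca(X, tr)
  p2 <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(p1$eigenvalues, unname(diag(p2$Eval)), tolerance = 1e-10)
  expect_equal(abs(unname(diag(crossprod(p1$loadings,
                                         unclass(p2$Evec))))),
               rep(1, 4), tolerance = 1e-8)
})

test_that("BM-simulated two-factor traits recover the leading subspace", {
  # principal angle between estimated and true leading 2-dim subspaces
  principal_angle <- function(A, B) {
    qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
    s <- svd(crossprod(qa, qb))$d
    acos(min(1, min(s))) * 180 / pi
  }
  B <- cbind(c(2, 2, 1.5, 0, 0, 0), c(0, 0, 0, 1.8, 1.8, 1.2))
  cov_true <- B %*% t(B) + diag(0.05, 6)
  true_sub <- eigen(cov_true, symmetric = TRUE)$vectors[, 1:2]
  angles <- sapply(1:20, function(r) {
    tr <- make_yule_tree(64, seed = 100 + r)
    X <- simulate_bm_traits(tr, cov_true, seed = 200 + r)
    colnames(X) <- paste0("t", 1:6)
    p <- phylo_pca(X, tr)
    principal_angle(p$loadings[, 1:2], true_sub)
  })
  expect_true(all(angles < 15))

  # sign flips of loading columns leave reconstruction unchanged
  tr <- make_yule_tree(32, seed = 1)
  X <- simulate_bm_traits(tr, cov_true, seed = 2)
  colnames(X) <- paste0("t", 1:6)
  p <- phylo_pca(X, tr)
  Xc <- sweep(p$scores %*% t(p$loadings), 2, -p$anc_mean)
  L2 <- p$loadings; L2[, 1] <- -L2[, 1]
  S2 <- p$scores;  S2[, 1] <- -S2[, 1]
  Xc2 <- sweep(S2 %*% t(L2), 2, -p$anc_mean)
  expect_equal(Xc, Xc2, tolerance = 1e-12)
})

test_that("Kaiser retention uses the strict eigenvalue > 1 rule", {
  p <- structure(list(eigenvalues = c(1.5, 1.2, 0.8, 0.3)),
                 class = "pca_result")
  expect_equal(retain_axes_kaiser(p), c(1L, 2L))
  p$eigenvalues <- c(0.9, 0.5)
  expect_warning(ret <- retain_axes_kaiser(p), "no axis")
  expect_length(ret, 0)
  p$eigenvalues <- c(1.2, 1.0, 0.8)
  expect_equal(retain_axes_kaiser(p), 1L)
})

test_that("entropy regression recovers exact and noisy coefficients", {
  set.seed(53)
  n <- 80
  sc <- cbind(PC1 = rnorm(n), PC2 = rnorm(n))

  # exact linear construction
  H <- 1 + 0.1 * sc[, 1]
  res <- suppressWarnings(regress_entropy_on_scores(H, sc))
  expect_equal(res$estimate[res$term == "PC1"], 0.1, tolerance = 1e-10)
  expect_equal(res$estimate[res$term == "PC2"], 0, tolerance = 1e-10)
  expect_equal(res$estimate[res$term == "PC1:PC2"], 0, tolerance = 1e-10)

  # orthogonal design: coefficients equal closed-form simple regressions
  sc_o <- cbind(PC1 = rep(c(-1, 1), 20), PC2 = rep(c(-1, -1, 1, 1), 10))
  Ho <- 1 + 0.3 * sc_o[, 1] - 0.2 * sc_o[, 2]
  ro <- suppressWarnings(regress_entropy_on_scores(Ho, sc_o))
  b1 <- sum((sc_o[, 1] - mean(sc_o[, 1])) * (Ho - mean(Ho))) /
    sum((sc_o[, 1] - mean(sc_o[, 1]))^2)
  expect_equal(ro$estimate[ro$term == "PC1"], b1, tolerance = 1e-10)

  # coverage: estimates within 2 SE of truth in >= 95% of replicates
  hits <- replicate(100, {
    Hr <- 1 + 0.15 * sc[, 1] - 0.25 * sc[, 2] + rnorm(n, sd = 0.2)
    r <- regress_entropy_on_scores(Hr, sc)
    ok1 <- abs(r$estimate[r$term == "PC1"] - 0.15) <
      2 * r$SE[r$term == "PC1"]
    ok2 <- abs(r$estimate[r$term == "PC2"] + 0.25) <
      2 * r$SE[r$term == "PC2"]
    c(ok1, ok2)
  })
  # nominal per-coefficient coverage of a 2 SE interval is ~95%
  expect_gte(mean(hits), 0.90)

  # constant score column
  expect_error(
    regress_entropy_on_scores(H, cbind(PC1 = rep(1, n), PC2 = sc[, 2])),
    "constant|rank")
})

test_that("clonality covariate models mirror the three model shapes", {
  set.seed(54)
  n <- 90
  sc <- cbind(PC1 = rnorm(n), PC2 = rnorm(n))
  clonal <- rep(c(TRUE, FALSE), length.out = n)

  # null: clonality coefficient within 2 SE of zero
  H0 <- 1 + 0.1 * sc[, 1] + rnorm(n, sd = 0.1)
  mA <- clonality_covariate_models(H0, sc, clonal)$A
  cl_row <- grepl("^clonal", mA$term)
  expect_true(abs(mA$estimate[cl_row][1]) < 2 * mA$SE[cl_row][1])

  # model B recovers both terms of an exact-plus-noise construction
  Hb <- 1 + 0.05 * sc[, 1] + 0.2 * clonal + rnorm(n, sd = 0.05)
  mB <- clonality_covariate_models(Hb, sc, clonal)$B
  expect_lt(abs(mB$estimate[mB$term == "PC1"] - 0.05),
            2 * mB$SE[mB$term == "PC1"])
  expect_lt(abs(mB$estimate[mB$term == "clonalTRUE"] - 0.2),
            2 * mB$SE[mB$term == "clonalTRUE"])

  # schema: exact term names per configured model
  expect_setequal(mB$term,
                  c("(Intercept)", "PC1", "clonalTRUE", "PC1:clonalTRUE"))
  mC <- clonality_covariate_models(Hb, sc, clonal)$C
  expect_setequal(mC$term,
                  c("(Intercept)", "PC2", "clonalTRUE", "PC2:clonalTRUE"))

  expect_error(clonality_covariate_models(H0, sc, rep(TRUE, n)),
               "single class")
})

test_that("group entropy tests against the H = 1 threshold", {
  g <- group_entropy_tests(c(0.5, 0.7), rep("x", 2))
  expect_equal(g$mean, 0.6)
  expect_equal(g$SE, 0.1, tolerance = 1e-10)
  expect_equal(g$t, -4, tolerance = 1e-10)
  expect_equal(g$df, 1)

  g1 <- group_entropy_tests(rep(1, 5), rep("y", 5))
  expect_equal(g1$t, 0)
  expect_equal(g1$P, 1)

  expect_error(group_entropy_tests(c(0.5), "z"), "fewer than 2")
})

test_that("tukey letters separate shifted groups and join null groups", {
  set.seed(55)
  shares_letter <- function(lt) {
    any(sapply(strsplit(lt[1], "")[[1]], function(ch)
      all(grepl(ch, lt, fixed = TRUE))))
  }
  # null: three groups from one distribution share a letter >= 90%
  joint <- replicate(60, {
    v <- rnorm(45)
    m <- rep(c("g1", "g2", "g3"), each = 15)
    shares_letter(tukey_by_mode(v, m)$letters)
  })
  expect_gte(mean(joint), 0.9)

  # one group shifted +5 SD gets its own letter
  sep <- replicate(10, {
    v <- c(rnorm(30), rnorm(15, mean = 5))
    m <- rep(c("g1", "g2", "g3"), each = 15)
    lt <- tukey_by_mode(v, m)$letters
    !grepl(lt[["g3"]], paste0(lt[["g1"]], lt[["g2"]]))
  })
  expect_gte(mean(sep), 0.9)

  # two identical groups: difference estimate 0
  v2 <- rep(c(1, 2, 3), 2)
  m2 <- rep(c("a", "b"), each = 3)
  tk <- tukey_by_mode(v2, m2)
  expect_equal(tk$pairs$diff, 0)

  expect_error(tukey_by_mode(1:3, c("a", "a", "b")), "at least 2")
})
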