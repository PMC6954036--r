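# independent individual-based cohort oracle: project a finite cohort by
# multinomial sampling of stage transitions; estimates of lx, mx and mean
# lifetime are compared with the matrix-algebra path. batch means give
# Monte-Carlo standard errors.

sim_cohort_once <- function(m, c0, n_ind, max_age) {
  act <- m$stages$is_active
  counts <- as.numeric(stats::rmultinom(1, n_ind, c0))
  lx <- numeric(max_age + 1)
  mx <- rep(NA_real_, max_age + 1)
  person_years <- 0
  for (x in 0:max_age) {
    alive <- sum(counts[act])
    lx[x + 1] <- alive / n_ind
    if (alive > 0) {
      mx[x + 1] <- sum(m$F %*% counts) / alive
    }
    person_years <- person_years + alive
    if (sum(counts) == 0) break
    nxt <- numeric(m$n)
    for (j in which(counts > 0)) {
      pj <- m$U[, j]
      probs <- c(pj, max(0, 1 - sum(pj)))
      draw <- as.numeric(stats::rmultinom(1, counts[j], probs))
      nxt <- nxt + draw[seq_len(m$n)]
    }
    counts <- nxt
  }
  list(lx = lx, mx = mx, eta = person_years / n_ind)
}

# B batches of n_ind/B individuals; returns per-age means and SEs
sim_cohort <- function(m, c0, n_ind = 1e5, B = 20, max_age = 60,
                       seed = 1) {
  set.seed(seed)
  nb <- n_ind %/% B
  runs <- lapply(seq_len(B), function(b) sim_cohort_once(m, c0, nb, max_age))
  lx_mat <- sapply(runs, `[[`, "lx")
  mx_mat <- sapply(runs, `[[`, "mx")
  eta <- sapply(runs, `[[`, "eta")
  list(
    lx = rowMeans(lx_mat),
    lx_se = apply(lx_mat, 1, stats::sd) / sqrt(B),
    mx = rowMeans(mx_mat, na.rm = TRUE),
    mx_se = apply(mx_mat, 1, stats::sd, na.rm = TRUE) / sqrt(B),
    mx_n = rowSums(!is.na(mx_mat)),
    eta = mean(eta),
    eta_se = stats::sd(eta) / sqrt(B)
  )
}
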