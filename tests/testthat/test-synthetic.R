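test_that("age-classified models encode the hazard on the subdiagonal", {
  spec <- synthetic_spec("TYPE_II", hazard = c(mu = 0.2), n_ages = 12)
  m <- make_age_mpm(spec)
  sub <- m$U[cbind(2:12, 1:11)]
  expect_equal(sub, rep(exp(-0.2), 11))
  expect_equal(sum(m$U) - sum(sub), 0)   # nothing off the subdiagonal

  # semelparous: exactly one nonzero fertility column
  sp_sem <- synthetic_spec("TYPE_II", fertility = "semelparous",
                           n_ages = 10, rate = 3)
  msem <- make_age_mpm(sp_sem)
  expect_equal(sum(colSums(msem$F) > 0), 1)
  expect_equal(msem$F[1, 10], 3)

  # a non-positive hazard cannot give survival in (0, 1)
  bad <- synthetic_spec("TYPE_II", hazard = c(mu = -0.1), n_ages = 5)
  expect_error(make_age_mpm(bad), "outside")
})

test_that("clonal fraction splits fertility between F and C", {
  sp <- synthetic_spec("TYPE_II", clonal_fraction = 0.4, alpha = 2,
                       n_ages = 10, rate = 1)
  m <- make_age_mpm(sp)
  expect_equal(sum(m$C) / (sum(m$F) + sum(m$C)), 0.4, tolerance = 1e-12)
})

test_that("seed-bank stage is prepended with stasis and germination", {
  sp <- synthetic_spec("TYPE_II", n_ages = 8, seed_bank = TRUE)
  m <- make_age_mpm(sp)
  expect_equal(m$n, 9)
  expect_true(m$stages$is_seed_bank[1])
  expect_equal(m$U[1, 1], 0.2)
  expect_equal(m$U[2, 1], 0.5)
  expect_lt(sum(m$U[, 1]), 1)
  # sexual recruits split between the bank and direct establishment
  expect_true(sum(m$F[1, ]) > 0 && sum(m$F[2, ]) > 0)
})

test_that("stage aggregation preserves structure-weighted rates", {
  sp <- synthetic_spec("TYPE_II", hazard = c(mu = 0.15), alpha = 3,
                       n_ages = 60, rate = 0.8)
  m_age <- make_age_mpm(sp)

  # identity pooling
  expect_identical(aggregate_to_stages(m_age, 60), m_age)

  # lambda within 5% after pooling 60 ages into 5 stages
  lam_age <- dominant_eigen(m_age)$lam
  for (ns in c(5, 10, 20)) {
    m_st <- aggregate_to_stages(m_age, ns)
    lam_st <- dominant_eigen(m_st)$lam
    expect_lt(abs(lam_st - lam_age) / lam_age, 0.05)
  }

  # weighted column sums and total reproductive output are conserved
  w <- mpmsen:::stable_age_weights(m_age)
  m5 <- aggregate_to_stages(m_age, 5)
  bin <- cut(seq_len(60), breaks = 5, labels = FALSE)
  W <- tapply(w, bin, sum)
  # population-level reproductive output: sum_x w_x f_x = sum_J W_J f_J
  expect_equal(sum(W * m5$F[1, ]), sum(w * m_age$F[1, ]), tolerance = 1e-10)
  # per-bin weighted column sums of U
  cs_age <- colSums(m_age$U)
  cs_st <- colSums(m5$U)
  for (J in 1:5) {
    expect_equal(cs_st[[J]],
                 sum(w[bin == J] * cs_age[bin == J]) / sum(w[bin == J]),
                 tolerance = 1e-6)
  }
})

test_that("add_shrinkage moves stasis backward, conserving survival", {
  sp <- synthetic_spec("TYPE_II", n_ages = 30)
  m <- aggregate_to_stages(make_age_mpm(sp), 10)
  ms <- add_shrinkage(m, 0.1)
  expect_equal(colSums(ms$U), colSums(m$U), tolerance = 1e-12)
  r <- ssd_weighted_rates(ms)
  expect_gt(r$rho, 0)
})

test_that("yule trees and BM traits are reproducible and well-formed", {
  tr <- make_yule_tree(16, seed = 4)
  expect_equal(ape::Ntip(tr), 16)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(all(tr$edge.length >= 0))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(make_yule_tree(16, seed = 4)))

  # star tree + BM: law of large numbers across many tips
  star <- ape::stree(1000, type = "star")
  star$edge.length <- rep(1, 1000)
  star$tip.label <- sprintf("t%04d", 1:1000)
  cv <- matrix(c(1, 0.5, 0.5, 2), 2, 2)
  X <- simulate_bm_traits(star, cv, seed = 6)
  expect_lt(max(abs(stats::cov(X) - cv)), 0.2)
  expect_identical(X, simulate_bm_traits(star, cv, seed = 6))

  # zero-length branches: every tip equals the root state
  star0 <- star
  star0$edge.length <- rep(0, 1000)
  X0 <- simulate_bm_traits(star0, diag(2) * 1e-12, seed = 6)
  expect_lt(max(abs(X0)), 1e-4)

  expect_error(simulate_bm_traits(star, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("collections carry labeled ground truth and planted failures", {
  sc <- synthetic_scenario(n_only_sexual = 6, n_sexual_but_clonal = 3,
                           n_sexual_and_clonal = 3,
                           planted_failures = c("annual", "no_repro",
                                                "survival_ge_1"),
                           seed = 11)
  gen <- make_collection(sc)
  expect_length(gen$collection, 15)
  expect_equal(sum(gen$truth$mode == "ONLY_SEXUAL", na.rm = TRUE), 6)
  expect_equal(sum(!is.na(gen$truth$planted_failure)), 3)
  expect_equal(ape::Ntip(gen$tree), 15)

  # filter excludes exactly the planted failures
  rep_ <- apply_selection_criteria(gen$collection)
  excl <- rep_$table$species_id[!rep_$table$passed]
  expect_setequal(excl,
                  gen$truth$species_id[!is.na(gen$truth$planted_failure)])

  # modes are recovered by classification
  retained_ids <- vapply(rep_$retained, function(m) m$species_id,
                         character(1))
  modes <- vapply(rep_$retained, classify_reproduction_mode, character(1))
  expect_equal(modes,
               gen$truth$mode[match(retained_ids, gen$truth$species_id)])

  # bit-identical regeneration under the same seed
  gen2 <- make_collection(sc)
  expect_identical(gen$collection, gen2$collection)
  expect_identical(ape::write.tree(gen$tree), ape::write.tree(gen2$tree))

  # empty scenario
  empty <- make_collection(synthetic_scenario(0, 0, 0))
  expect_length(empty$collection, 0)
})

test_that("planted failure kinds each trip their targeted criterion", {
  kinds <- c(annual = 4L, no_repro = 9L, survival_ge_1 = 8L,
             short_study = 2L, tree_form = 5L, two_stage = 7L)
  models <- lapply(names(kinds), function(k)
    mpmsen:::planted_failure_mpm(k, k))
  tab <- apply_selection_criteria(models)$table
  expect_equal(tab$criterion, unname(kinds[tab$species_id]))
})

test_that("small seeded collections put H on the planted side of 1", {
  sc <- synthetic_scenario(n_only_sexual = 9, n_sexual_but_clonal = 0,
                           n_sexual_and_clonal = 0, seed = 21)
  gen <- make_collection(sc)
  for (k in seq_along(gen$collection)) {
    m <- gen$collection[[k]]
    tt <- qsd_truncate(age_trajectories(m), m)
    H <- keyfitz_entropy(tt$lx, tt$ages)
    side <- gen$truth$expected_H_side[k]
    if (side == "below") expect_lt(H, 1)
    if (side == "above") expect_gt(H, 1)
    if (side == "near") expect_lt(abs(H - 1), 0.15)
  }
})
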