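#' Run the comparative senescence pipeline end to end
#'
#' Orchestrates the full analysis: structural validation and study
#' selection, reproduction-mode classification, age-from-stage trajectories
#' with quasi-stationary truncation (species whose cohort does not reach
#' 99% mortality before structural convergence are dropped), trait
#' derivation, trait-matrix assembly (log transform, percentile outlier
#' masking, standardization), chained-equation imputation, phylogenetically
#' corrected PCA with Kaiser axis retention, entropy-on-scores regressions
#' (overall and per mode), clonality-covariate models, one-sample group
#' tests of mean entropy against 1, and Tukey comparisons of each trait
#' across modes.
#'
#' @param collection List of [mpm()] objects.
#' @param tree An `ape::phylo` covering the species (extra tips allowed).
#' @param cfg A [selection_config()].
#' @param seed Master seed; stage-local seeds are derived from it.
#' @param include_clonal Count clonal recruits in derived traits.
#' @param span_variant Reproductive-span variant, see [reproductive_span()].
#' @param out_dir Optional directory; when given, CSV artifacts
#'   (`filter_report.csv`, `traits.csv`, `mask.csv`, `pca_loadings.csv`,
#'   `pca_scores.csv`, `regression.csv`, `group_tests.csv`, `tukey.csv`)
#'   are written there.
#' @param verbose Log per-stage counts to `stderr`.
#' @return A list with elements `filter`, `traits`, `trait_matrix`,
#'   `pca`, `regressions`, `clonality_models`, `group_tests`, `tukey`.
#' @export
run_pipeline <- function(collection, tree, cfg = selection_config(),
                         seed = 1L, include_clonal = TRUE,
                         span_variant = "mature", out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[mpmsen] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  filt <- stage("filter", apply_selection_criteria(collection, cfg))
  say("filter: ", length(collection), " candidates -> ",
      length(filt$retained), " species retained")

  traits_rows <- stage("traits", lapply(filt$retained, function(m) {
    derive_traits(m, include_clonal = include_clonal,
                  span_variant = span_variant)
  }))
  traits <- do.call(rbind, traits_rows)
  eligible <- traits[traits$eligible & !is.na(traits$H), , drop = FALSE]
  say("truncation eligibility: ", nrow(eligible), " of ", nrow(traits),
      " species kept")
  if (nrow(eligible) < 3) {
    stop("pipeline stage 'traits' failed: fewer than 3 eligible species",
         call. = FALSE)
  }

  tm <- stage("trait_matrix", build_trait_matrix(eligible))
  tm <- stage("impute", impute_missing(tm, seed = seed + 1L))

  pca <- stage("pca", phylo_pca(tm, tree))
  say("pca: retained axes ", paste(pca$retained, collapse = ", "),
      " (", paste(sprintf("%.1f%%", pca$pct_var[pca$retained]),
                  collapse = " + "), ")")
  if (length(pca$retained) < 2) {
    stop("pipeline stage 'pca' failed: fewer than 2 axes retained",
         call. = FALSE)
  }
  sc <- pca$scores[, pca$retained[1:2], drop = FALSE]
  colnames(sc) <- c("PC1", "PC2")

  H <- eligible$H
  mode <- eligible$mode
  regressions <- list(
    all = stage("regress", regress_entropy_on_scores(H, sc))
  )
  for (g in unique(mode)) {
    sub <- mode == g
    regressions[[g]] <- tryCatch(
      regress_entropy_on_scores(H, sc, subset = sub),
      error = function(e) NULL
    )
  }
  clonal <- mode != "ONLY_SEXUAL"
  clonality_models <- tryCatch(
    clonality_covariate_models(H, sc, clonal),
    error = function(e) NULL
  )
  group_tests <- stage("group_tests", group_entropy_tests(H, mode))
  tukey <- list()
  for (tr in c(pca_trait_names(), "H")) {
    tukey[[tr]] <- tryCatch(tukey_by_mode(eligible[[tr]], mode),
                            error = function(e) NULL)
  }

  res <- list(filter = filt, traits = traits, eligible = eligible,
              trait_matrix = tm, pca = pca, regressions = regressions,
              clonality_models = clonality_models,
              group_tests = group_tests, tukey = tukey)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(x, f) utils::write.csv(
      x, file.path(out_dir, f), row.names = FALSE)
    wcsv(filt$table, "filter_report.csv")
    wcsv(traits, "traits.csv")
    utils::write.csv(tm$mask, file.path(out_dir, "mask.csv"))
    utils::write.csv(pca$loadings, file.path(out_dir, "pca_loadings.csv"))
    utils::write.csv(pca$scores, file.path(out_dir, "pca_scores.csv"))
    reg_all <- do.call(rbind, lapply(names(regressions), function(nm) {
      r <- regressions[[nm]]
      if (is.null(r)) return(NULL)
      cbind(model = nm, r)
    }))
    wcsv(reg_all, "regression.csv")
    wcsv(group_tests, "group_tests.csv")
    tuk_all <- do.call(rbind, lapply(names(tukey), function(nm) {
      t <- tukey[[nm]]
      if (is.null(t)) return(NULL)
      cbind(trait = nm, t$pairs)
    }))
    wcsv(tuk_all, "tukey.csv")
    say("artifacts written to ", out_dir)
  }
  res
}
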