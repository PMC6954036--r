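#' Configuration for the study-selection filter
#'
#' @param min_years Minimum study duration in years (default 3).
#' @param min_matrices Minimum number of annual transition matrices
#'   (default 2).
#' @param allowed_growth_forms Growth forms retained by the filter.
#' @param min_dim Models must have more than this many stages (default 2).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(min_years = 3L, min_matrices = 2L,
                             allowed_growth_forms = c(
                               "epiphyte", "herbaceous_perennial",
                               "succulent", "shrub"),
                             min_dim = 2L) {
  structure(
    list(min_years = as.integer(min_years),
         min_matrices = as.integer(min_matrices),
         allowed_growth_forms = allowed_growth_forms,
         min_dim = as.integer(min_dim)),
    class = "selection_config"
  )
}

#' Element-wise average of replicate MPMs for one species
#'
#' Models from contiguous annual transitions or multiple populations of the
#' same study are combined by element-by-element arithmetic means of `U`,
#' `F` and `C`. Metadata are merged: `study_years` takes the maximum,
#' `n_annual_matrices` the total.
#'
#' @param models A list of [mpm()] objects sharing stage structure.
#' @return A single averaged [mpm()].
#' @export
average_mpms <- function(models) {
  stopifnot(length(models) >= 1, all(vapply(models, inherits, logical(1),
                                            "mpm")))
  ref <- models[[1]]
  for (m in models[-1]) {
    if (m$n != ref$n ||
        !identical(m$stages$label, ref$stages$label) ||
        !identical(m$stages$order_index, ref$stages$order_index) ||
        !identical(m$stages$is_seed_bank, ref$stages$is_seed_bank)) {
      stop("cannot average MPMs with different dimension or stage structure",
           call. = FALSE)
    }
  }
  avg <- function(get) Reduce(`+`, lapply(models, get)) / length(models)
  meta <- ref$meta
  meta$study_years <- max(vapply(models, function(m) m$meta$study_years,
                                 integer(1)))
  meta$n_annual_matrices <- sum(vapply(models, function(m)
    m$meta$n_annual_matrices, integer(1)))
  mpm(U = avg(function(m) m$U), F = avg(function(m) m$F),
      C = avg(function(m) m$C), stages = ref$stages,
      species_id = ref$species_id, meta = meta)
}

#' Classify the reproduction mode of a retained MPM
#'
#' Retained models fall in one of three classes: `"SEXUAL_AND_CLONAL"`
#' (both sexual and clonal rates quantified, `sum(F) > 0` and
#' `sum(C) > 0`); `"ONLY_SEXUAL_BUT_CLONAL"` (`sum(C) = 0` but external
#' botanical knowledge says the species is clonal — the study simply did
#' not quantify it); `"ONLY_SEXUAL"` (`sum(C) = 0` and the species is not
#' known to be clonal).
#'
#' @param m A retained [mpm()] with `sum(F) > 0`.
#' @return One of the three mode strings.
#' @export
classify_reproduction_mode <- function(m) {
  stopifnot(inherits(m, "mpm"))
  sF <- sum(m$F)
  sC <- sum(m$C)
  if (sF <= 0) {
    stop("sum(F) = 0: model should have been excluded before classification",
         call. = FALSE)
  }
  if (sC > 0) return("SEXUAL_AND_CLONAL")
  if (isTRUE(m$meta$clonal_per_knowledge)) return("ONLY_SEXUAL_BUT_CLONAL")
  "ONLY_SEXUAL"
}

# first failing criterion for one species model, or NULL if it passes all
first_failure <- function(m, cfg) {
  rep_struct <- validate_mpm(m, min_dim = cfg$min_dim)
  g <- function(chk) rep_struct$passed[rep_struct$check == chk]
  if (!g("nonnegative") || !g("irreducible") || !g("primitive")) {
    return(list(criterion = 1L,
                reason = "not a non-negative, irreducible, primitive model"))
  }
  if (m$meta$study_years < cfg$min_years ||
      m$meta$n_annual_matrices < cfg$min_matrices) {
    return(list(criterion = 2L, reason = sprintf(
      "study: %d years / %d annual matrices (need >= %d / >= %d)",
      m$meta$study_years, m$meta$n_annual_matrices,
      cfg$min_years, cfg$min_matrices)))
  }
  if (m$meta$treatment != "unmanipulated") {
    return(list(criterion = 3L, reason = "manipulated conditions"))
  }
  if (!m$meta$annual_timestep || m$meta$growth_form == "annual") {
    return(list(criterion = 4L,
                reason = "non-annual time step or annual species"))
  }
  if (!(m$meta$growth_form %in% cfg$allowed_growth_forms)) {
    return(list(criterion = 5L, reason = sprintf(
      "growth form '%s' not in the retained set", m$meta$growth_form)))
  }
  if (!g("dim_gt_min")) {
    return(list(criterion = 7L, reason = sprintf(
      "dimension %d <= %d", m$n, cfg$min_dim)))
  }
  if (!g("survival_lt_1")) {
    return(list(criterion = 8L, reason = "a stage survival column sum >= 1"))
  }
  sF <- sum(m$F); sC <- sum(m$C)
  if (sF == 0 && sC == 0) {
    return(list(criterion = 9L, reason = "no reproduction recorded"))
  }
  if (sF == 0 && sC > 0) {
    return(list(criterion = 9L,
                reason = "exclusively clonal reproduction recorded"))
  }
  NULL
}

#' Apply the study-selection criteria to a collection
#'
#' Screens each species model against the selection criteria used to build
#' a comparable cross-species dataset: structural validity (non-negative,
#' irreducible, primitive), study effort, unmanipulated field conditions,
#' annual time step and non-annual growth form, retained growth forms,
#' dimension, survival below one, and presence of sexual reproduction.
#' When several candidate models remain for one species, [pick_best_study()]
#' keeps one (criterion 11). Each excluded model carries its first failing
#' criterion id.
#'
#' @param collection List of [mpm()] objects (one candidate model per entry;
#'   replicate matrices should already be averaged with [average_mpms()]).
#' @param cfg A [selection_config()].
#' @return A list of class `filter_report`: `table` (data frame with
#'   `species_id`, `passed`, `criterion`, `reason`) and `retained` (list of
#'   retained [mpm()] objects, one per species).
#' @export
apply_selection_criteria <- function(collection, cfg = selection_config()) {
  stopifnot(all(vapply(collection, inherits, logical(1), "mpm")))
  rows <- lapply(collection, function(m) {
    f <- first_failure(m, cfg)
    data.frame(
      species_id = m$species_id,
      passed = is.null(f),
      criterion = if (is.null(f)) NA_integer_ else f$criterion,
      reason = if (is.null(f)) "" else f$reason
    )
  })
  tab <- do.call(rbind, rows)
  passing <- collection[tab$passed]
  # criterion 11: one model per species
  ids <- vapply(passing, function(m) m$species_id, character(1))
  retained <- lapply(unique(ids), function(id) {
    pick_best_study(passing[ids == id])
  })
  structure(list(table = tab, retained = retained), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", nrow(x$table), " candidate models, ",
      length(x$retained), " species retained\n", sep = "")
  if (any(!x$table$passed)) {
    excl <- table(x$table$criterion[!x$table$passed])
    cat("  exclusions by criterion:",
        paste(names(excl), excl, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Pick the preferred study among candidates for one species
#'
#' When several studies cover a species, the one with greater replication
#' is preferred, lexicographically: explicit quantification of clonality
#' (`sum(C) > 0` when the species is known to be clonal), then study
#' duration, then number of annual matrices, then stage count; remaining
#' ties keep the first candidate in input order.
#'
#' @param candidates Non-empty list of [mpm()] objects for one species.
#' @return The preferred [mpm()].
#' @export
pick_best_study <- function(candidates) {
  if (!length(candidates)) stop("no candidate models", call. = FALSE)
  key <- vapply(candidates, function(m) {
    clonal_quant <- as.numeric(sum(m$C) > 0 &&
                                 isTRUE(m$meta$clonal_per_knowledge))
    c(clonal_quant, m$meta$study_years, m$meta$n_annual_matrices, m$n)
  }, numeric(4))
  best <- 1L
  for (i in seq_along(candidates)[-1]) {
    d <- key[, i] - key[, best]
    nz <- which(d != 0)
    if (length(nz) && d[nz[1]] > 0) best <- i
  }
  candidates[[best]]
}
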