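#' Read a collection of MPMs from JSON
#'
#' The collection file is a JSON array of species records, each with
#' `species_id`, `stages` (list of `{label, order_index, is_seed_bank}`),
#' row-major nested arrays `matU`, `matF`, `matC` (entry `[i][j]` = flow
#' from stage `j` to stage `i`), and the [species_meta()] fields. Structural
#' validation happens on read; errors name the offending record.
#'
#' @param path Path to the JSON collection file.
#' @return A list of [mpm()] objects.
#' @export
read_collection <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(seq_along(recs), function(k) {
    r <- recs[[k]]
    to_mat <- function(x, nm) {
      rows <- lapply(x, function(row) as.numeric(unlist(row)))
      lens <- lengths(rows)
      if (length(unique(lens)) != 1 || lens[1] != length(rows)) {
        stop("record ", k, " (", r$species_id %||% "?", "): ", nm,
             " is not square", call. = FALSE)
      }
      do.call(rbind, rows)
    }
    stages <- do.call(rbind, lapply(r$stages, function(s) {
      data.frame(label = s$label, order_index = as.integer(s$order_index),
                 is_seed_bank = isTRUE(s$is_seed_bank))
    }))
    meta <- tryCatch(
      species_meta(
        growth_form = r$meta$growth_form %||% "other",
        study_years = r$meta$study_years %||% 0L,
        n_annual_matrices = r$meta$n_annual_matrices %||% 0L,
        treatment = r$meta$treatment %||% "unmanipulated",
        annual_timestep = r$meta$annual_timestep %||% TRUE,
        clonal_per_knowledge = r$meta$clonal_per_knowledge %||% FALSE,
        gps = if (!is.null(r$meta$gps)) as.numeric(unlist(r$meta$gps))
      ),
      error = function(e) stop("record ", k, " (", r$species_id %||% "?",
                               "): ", conditionMessage(e), call. = FALSE)
    )
    tryCatch(
      mpm(U = to_mat(r$matU, "matU"), F = to_mat(r$matF, "matF"),
          C = to_mat(r$matC, "matC"), stages = stages,
          species_id = r$species_id, meta = meta),
      error = function(e) stop("record ", k, " (", r$species_id %||% "?",
                               "): ", conditionMessage(e), call. = FALSE)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a collection of MPMs to JSON
#'
#' @param collection List of [mpm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collection <- function(collection, path) {
  recs <- lapply(collection, function(m) {
    list(
      species_id = m$species_id,
      stages = lapply(seq_len(m$n), function(i) list(
        label = m$stages$label[i],
        order_index = m$stages$order_index[i],
        is_seed_bank = m$stages$is_seed_bank[i]
      )),
      matU = apply(unname(m$U), 1, as.list, simplify = FALSE),
      matF = apply(unname(m$F), 1, as.list, simplify = FALSE),
      matC = apply(unname(m$C), 1, as.list, simplify = FALSE),
      meta = list(
        growth_form = m$meta$growth_form,
        study_years = m$meta$study_years,
        n_annual_matrices = m$meta$n_annual_matrices,
        treatment = m$meta$treatment,
        annual_timestep = m$meta$annual_timestep,
        clonal_per_knowledge = m$meta$clonal_per_knowledge,
        gps = m$meta$gps
      )
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree with branch lengths and labelled tips.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; Brownian-motion covariance undefined",
         call. = FALSE)
  }
  if (any(is.na(tr$tip.label)) || any(tr$tip.label == "")) {
    stop("tree has unlabeled tips", call. = FALSE)
  }
  tr
}
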