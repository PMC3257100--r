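#' Score one complex with the weighted-network docking score
#'
#' The score is Sn = -(S x <knn_w>): the negated product of the
#' whole-network strength and the network mean of the weighted average
#' nearest-neighbours degree. Both factors correlate negatively with ligand
#' RMSD, and their product needs no system-size-dependent coefficient, so a
#' more native-like (better packed) decoy gets a more negative score and
#' ranks ahead.
#'
#' @inheritParams build_network
#' @param decoy_id Identifier recorded in the output; defaults to the
#'   structure's source id.
#' @return A one-row tibble: `decoy_id`, `sn_score`, `strength`,
#'   `knn_w_mean`, `n_residues`.
#' @examples
#' make_complex(12, 6, separation = 4, seed = 1) |> score_structure()
#' @export
score_structure <- function(structure, energy_table = mj_contact_energies(),
                            cutoff = 6.5, covalent_weight = NULL,
                            decoy_id = NULL) {
  net <- build_network(structure, energy_table = energy_table,
                       cutoff = cutoff, covalent_weight = covalent_weight)
  s <- network_strength(net)
  knnw <- knn_weighted_mean(net)
  tibble(decoy_id = decoy_id %||% source_id(structure),
         sn_score = -(s * knnw),
         strength = s,
         knn_w_mean = knnw,
         n_residues = nrow(structure))
}

#' Score a set of decoy structures
#'
#' @param decoys Character vector of PDB paths, or a (preferably named) list
#'   of `wrn_structure` objects.
#' @inheritParams score_structure
#' @param quiet Passed to [read_structure()] for paths.
#' @return A tibble with one row per decoy, as in [score_structure()];
#'   unreadable files are skipped with a warning (an error if all fail).
#' @export
score_decoys <- function(decoys, energy_table = mj_contact_energies(),
                         cutoff = 6.5, covalent_weight = NULL, quiet = TRUE) {
  if (is.character(decoys))
    decoys <- setNames(as.list(decoys),
                       sub("\\.(pdb|ent)(\\.gz)?$", "", basename(decoys),
                           ignore.case = TRUE))
  if (!length(decoys)) abort("no decoys to score")
  ids <- names(decoys) %||% as.character(seq_along(decoys))
  rows <- purrr::imap(decoys, function(d, id) {
    tryCatch({
      s <- if (inherits(d, "wrn_structure")) d else read_structure(d, quiet = quiet)
      score_structure(s, energy_table = energy_table, cutoff = cutoff,
                      covalent_weight = covalent_weight, decoy_id = id)
    }, error = function(e) {
      warn(sprintf("skipping decoy '%s': %s", id, conditionMessage(e)))
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) abort("all decoys failed to score")
  out
}

#' Rank scored decoys
#'
#' Sorts ascending by score (most negative first), breaking ties by
#' `decoy_id` so the ranking is deterministic, and assigns ranks 1..M.
#'
#' @param scored Tibble from [score_decoys()] (columns `decoy_id`,
#'   `sn_score`; other columns pass through).
#' @return The tibble sorted with a `rank` column.
#' @export
rank_decoys <- function(scored) {
  stopifnot(all(c("decoy_id", "sn_score") %in% names(scored)))
  if (anyDuplicated(scored$decoy_id))
    abort("duplicate decoy_id values")
  scored |>
    dplyr::arrange(.data$sn_score, .data$decoy_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}
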