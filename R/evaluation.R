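#' Ligand RMSD of a decoy against the native complex
#'
#' Superimposes the decoy's receptor backbone onto the native receptor by
#' least squares (optimal proper rotation + translation), applies the fitted
#' transform to the decoy's ligand, and returns the RMSD over the matched
#' ligand backbone atoms (N, C, CA, O). Residues are matched native-decoy
#' by chain ID and parse-order index when the per-chain residue counts
#' agree, otherwise by author residue number; only backbone atoms present
#' on both sides contribute.
#'
#' @param native,decoy `wrn_structure` objects of the same complex.
#' @param receptor_chains,ligand_chains Character vectors of chain IDs.
#' @return Ligand RMSD in Angstrom.
#' @examples
#' nat <- make_complex(12, 6, separation = 4, seed = 1)
#' dec <- transform_structure(nat, translation = c(5, 0, 0), chains = "B")
#' ligand_rmsd(nat, dec, receptor_chains = "A", ligand_chains = "B")  # 5
#' @export
ligand_rmsd <- function(native, decoy, receptor_chains, ligand_chains) {
  stopifnot(inherits(native, "wrn_structure"), inherits(decoy, "wrn_structure"))
  chains <- c(receptor_chains, ligand_chains)
  missing_nat <- setdiff(chains, unique(native$chain))
  missing_dec <- setdiff(chains, unique(decoy$chain))
  if (length(missing_nat) || length(missing_dec))
    abort(sprintf("chain(s) not found: %s",
                  paste(union(missing_nat, missing_dec), collapse = ", ")),
          class = "wrndock_config_error")

  pairs <- .match_backbone(native, decoy, chains)
  rec <- pairs[pairs$chain %in% receptor_chains, , drop = FALSE]
  lig <- pairs[pairs$chain %in% ligand_chains, , drop = FALSE]
  if (nrow(rec) < 3)
    abort("fewer than 3 matched receptor backbone atoms; superposition underdetermined")
  if (!nrow(lig)) abort("no matched ligand backbone atoms")

  fit <- kabsch(as.matrix(rec[, c("xd", "yd", "zd")]),
                as.matrix(rec[, c("xn", "yn", "zn")]))
  lig_d <- sweep(as.matrix(lig[, c("xd", "yd", "zd")]) %*% t(fit$rotation),
                 2, fit$translation, "+")
  lig_n <- as.matrix(lig[, c("xn", "yn", "zn")])
  sqrt(mean(rowSums((lig_d - lig_n)^2)))
}

## pair backbone atoms of the two models over the given chains
.match_backbone <- function(native, decoy, chains) {
  bn <- dplyr::filter(structure_backbone(native), .data$chain %in% chains)
  bd <- dplyr::filter(structure_backbone(decoy), .data$chain %in% chains)
  counts_equal <- all(purrr::map_lgl(chains, function(ch)
    sum(native$chain == ch) == sum(decoy$chain == ch)))
  if (counts_equal) {
    key_n <- bn
    key_d <- bd
  } else {
    ## fall back to author numbering where parse order cannot be trusted
    num_n <- native[, c("chain", "seq_index", "resno", "insert")]
    num_d <- decoy[, c("chain", "seq_index", "resno", "insert")]
    key_n <- dplyr::inner_join(bn, num_n, by = c("chain", "seq_index")) |>
      dplyr::mutate(seq_index = paste(.data$resno, .data$insert))
    key_d <- dplyr::inner_join(bd, num_d, by = c("chain", "seq_index")) |>
      dplyr::mutate(seq_index = paste(.data$resno, .data$insert))
  }
  out <- dplyr::inner_join(key_n, key_d, by = c("chain", "seq_index", "atom"),
                           suffix = c("n", "d"))
  if (!nrow(out)) abort("no residue correspondence between native and decoy")
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' `sum ||R p_i + t - q_i||^2`, with the reflection case removed by
#' correcting the sign of the smallest singular direction.
#'
#' @param moving,fixed n x 3 coordinate matrices, rows paired.
#' @return List with `rotation` (3x3, det = +1), `translation` (length 3)
#'   and `rmsd` of the fit.
#' @export
kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3, ncol(fixed) == 3)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  p <- sweep(moving, 2, cm); q <- sweep(fixed, 2, cf)
  s <- svd(t(p) %*% q)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cf - drop(r %*% cm)
  fitted <- sweep(moving %*% t(r), 2, t, "+")
  list(rotation = r, translation = t,
       rmsd = sqrt(mean(rowSums((fitted - fixed)^2))))
}

#' Call a decoy a hit
#'
#' A near-native structure (hit) has ligand RMSD at or below the threshold;
#' the boundary is inclusive, so exactly 4.0 Angstrom is a hit.
#'
#' @param l_rmsd Ligand RMSD(s), Angstrom.
#' @param threshold Hit threshold, default 4.0 Angstrom.
#' @return Logical vector.
#' @export
call_hit <- function(l_rmsd, threshold = 4.0) {
  stopifnot(all(l_rmsd >= 0), threshold > 0)
  l_rmsd <= threshold
}

#' Score, rank and measure a full decoy set against its native
#'
#' Runs the whole per-system pipeline: scores every decoy, computes its
#' ligand RMSD against the native, calls hits and ranks by score.
#'
#' @inheritParams score_decoys
#' @inheritParams ligand_rmsd
#' @param hit_threshold Hit-calling threshold in Angstrom.
#' @return Ranked per-decoy tibble with columns `decoy_id`, `sn_score`,
#'   `strength`, `knn_w_mean`, `n_residues`, `l_rmsd`, `is_hit`, `rank`.
#' @export
evaluate_decoys <- function(native, decoys, receptor_chains, ligand_chains,
                            energy_table = mj_contact_energies(), cutoff = 6.5,
                            covalent_weight = NULL, hit_threshold = 4.0,
                            quiet = TRUE) {
  if (is.character(decoys))
    decoys <- setNames(lapply(decoys, read_structure, quiet = quiet),
                       sub("\\.(pdb|ent)(\\.gz)?$", "", basename(decoys),
                           ignore.case = TRUE))
  if (is.null(names(decoys)))
    names(decoys) <- as.character(seq_along(decoys))
  score_decoys(decoys, energy_table = energy_table, cutoff = cutoff,
               covalent_weight = covalent_weight, quiet = quiet) |>
    dplyr::mutate(l_rmsd = purrr::map_dbl(decoys[.data$decoy_id], ligand_rmsd,
                                          native = native,
                                          receptor_chains = receptor_chains,
                                          ligand_chains = ligand_chains),
                  is_hit = call_hit(.data$l_rmsd, hit_threshold)) |>
    rank_decoys()
}

#' Per-system ranking indicators
#'
#' The four standard indicators of a docking scoring function on one
#' system: the correlation between score and ligand RMSD over all decoys,
#' the ligand RMSD of the rank-1 decoy, the rank of the first hit, and the
#' number of hits among the top 10 scores.
#'
#' @param ranked Ranked per-decoy tibble (from [evaluate_decoys()], or any
#'   tibble with `rank`, `sn_score`, `l_rmsd`, `is_hit`).
#' @param system_id Label for the system.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `system_id`, `n_decoys`, `n_hits`, `pearson_r`,
#'   `rmsd_rank1`, `rank1_gt10` (flag: rank-1 RMSD above 10 Angstrom, a
#'   first-rank structure usually excluded from RMSD comparisons),
#'   `first_hit_rank` (NA when the set has no hit), `hits_top10`.
#' @export
evaluate_system <- function(ranked, system_id = "system",
                            cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  req <- c("rank", "sn_score", "l_rmsd", "is_hit")
  stopifnot(all(req %in% names(ranked)))
  ranked <- dplyr::arrange(ranked, .data$rank)
  r <- if (stats::sd(ranked$sn_score) == 0 || stats::sd(ranked$l_rmsd) == 0) {
    warn("zero variance in score or RMSD; correlation undefined")
    NA_real_
  } else cor(ranked$sn_score, ranked$l_rmsd, method = cor_method)
  hit_ranks <- ranked$rank[ranked$is_hit]
  tibble(system_id = system_id,
         n_decoys = nrow(ranked),
         n_hits = sum(ranked$is_hit),
         pearson_r = r,
         rmsd_rank1 = ranked$l_rmsd[1],
         rank1_gt10 = ranked$l_rmsd[1] > 10,
         first_hit_rank = if (length(hit_ranks)) min(hit_ranks) else NA_integer_,
         hits_top10 = sum(hit_ranks <= 10))
}

#' Success-rate curve over systems
#'
#' A system is a success under NP when at least one hit sits within the top
#' NP ranked decoys; the curve gives the fraction of successful systems at
#' each NP = 1..max_np, and is nondecreasing in NP by construction.
#'
#' @param evaluations Tibble of per-system rows (needs `first_hit_rank`,
#'   NA meaning the system has no hit), e.g. rows from [evaluate_system()].
#' @param max_np Largest NP; default the largest decoy count present.
#' @return Tibble `np`, `success_rate` (fraction in 0..1).
#' @export
success_rate_curve <- function(evaluations, max_np = NULL) {
  stopifnot("first_hit_rank" %in% names(evaluations), nrow(evaluations) >= 1)
  max_np <- max_np %||% max(evaluations$n_decoys)
  fh <- evaluations$first_hit_rank
  fh[is.na(fh)] <- Inf
  tibble(np = seq_len(max_np),
         success_rate = purrr::map_dbl(seq_len(max_np),
                                       function(np) mean(fh <= np)))
}

#' Random-ranking baseline success-rate curve
#'
#' Re-ranks each system's decoys uniformly at random `n_permutations` times
#' (default 100) and averages the resulting success-rate curves; the
#' reference any informative scoring function must beat. Converges to the
#' hypergeometric expectation [expected_random_success()] as permutations
#' grow.
#'
#' @param evaluations Tibble with per-system `n_decoys` and `n_hits`.
#' @param max_np Largest NP; default the largest decoy count.
#' @param n_permutations Number of random rankings per system.
#' @param seed Integer seed for reproducibility.
#' @return Tibble `np`, `success_rate`.
#' @export
random_baseline_curve <- function(evaluations, max_np = NULL,
                                  n_permutations = 100, seed = 1L) {
  stopifnot(all(c("n_decoys", "n_hits") %in% names(evaluations)),
            n_permutations >= 1)
  max_np <- max_np %||% max(evaluations$n_decoys)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ## first-hit rank of one random ranking: minimum of h positions drawn
  ## without replacement from 1..M (Inf when the system has no hit)
  fh <- matrix(Inf, nrow(evaluations), n_permutations)
  for (s in seq_len(nrow(evaluations))) {
    m <- evaluations$n_decoys[s]; h <- evaluations$n_hits[s]
    if (h > 0)
      fh[s, ] <- replicate(n_permutations, min(sample.int(m, h)))
  }
  rate <- purrr::map_dbl(seq_len(max_np), function(np) mean(fh <= np))
  tibble(np = seq_len(max_np), success_rate = rate)
}

#' Closed-form expected random success rate
#'
#' For one system with `n_hits` hits among `n_decoys` decoys, the
#' probability that a uniformly random ranking places at least one hit in
#' the top `np`: `1 - choose(M - h, np) / choose(M, np)`.
#'
#' @param n_decoys,n_hits System composition.
#' @param np Number of top predictions considered.
#' @return Probability in 0..1 (vectorised over `np`).
#' @export
expected_random_success <- function(n_decoys, n_hits, np) {
  np <- pmin(np, n_decoys)
  1 - exp(lchoose(n_decoys - n_hits, np) - lchoose(n_decoys, np))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
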