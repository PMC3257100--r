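#' Generate a synthetic polypeptide chain
#'
#' Builds a single chain with plausible backbone spacing (consecutive CA
#' about 3.8 Angstrom apart) and explicitly placed side-chain centres, for
#' testing the network and scoring machinery without real structures.
#' Residue types are drawn uniformly from the 20 standard amino acids;
#' everything is deterministic per seed. Geometries: `"extended"` (straight
#' strand, centres alternating sides, no non-local contacts under the
#' default cutoff), `"helix"` (ideal-helix CA trace, centres radially
#' outward) and `"coil"` (seeded random walk).
#'
#' @param n Number of residues.
#' @param geometry One of `"extended"`, `"helix"`, `"coil"`.
#' @param seed Integer seed.
#' @param chain Chain identifier.
#' @param origin Numeric length-3 offset applied to the whole chain.
#' @param source_id Label; defaults to a descriptive tag.
#' @return A [new_structure()] tibble.
#' @examples
#' make_polypeptide(6, "helix", seed = 7)
#' @export
make_polypeptide <- function(n, geometry = c("extended", "helix", "coil"),
                             seed = 1L, chain = "A", origin = c(0, 0, 0),
                             source_id = NULL) {
  stopifnot(n >= 1)
  geometry <- match.arg(geometry)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- seq_len(n) - 1L
  ca <- switch(geometry,
    extended = cbind(3.8 * i, 0, 0),
    helix = {
      th <- i * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    },
    coil = {
      ## random walk with bounded turning angle, step 3.8 A
      pos <- matrix(0, n, 3)
      dir <- c(1, 0, 0)
      for (k in seq_len(n - 1L)[n > 1]) {
        dir <- dir + rnorm(3, sd = 0.45)
        dir <- dir / sqrt(sum(dir^2))
        pos[k + 1L, ] <- pos[k, ] + 3.8 * dir
      }
      pos
    })
  side <- switch(geometry,
    extended = cbind(0, 1.5 * (-1)^i, 0),
    helix = {
      th <- i * 100 * pi / 180
      cbind(1.7 * cos(th), 1.7 * sin(th), 0)
    },
    coil = {
      u <- matrix(rnorm(3 * n), n, 3)
      1.5 * u / sqrt(rowSums(u^2))
    })
  resname <- sample(.AA3, n, replace = TRUE)
  center <- ca + side
  center[resname == "GLY", ] <- ca[resname == "GLY", ]
  ## PDB coordinate precision, so serialisation round-trips exactly
  ca <- round(sweep(ca, 2, origin, "+"), 3)
  center <- round(sweep(center, 2, origin, "+"), 3)

  nodes <- tibble(chain = chain, seq_index = i, resno = i + 1L, insert = "",
                  resname = resname,
                  x = center[, 1], y = center[, 2], z = center[, 3])
  ## synthetic backbone: fixed local offsets from CA
  off <- list(N = c(-1.0, 0.9, 0.0), CA = c(0, 0, 0),
              C = c(1.0, 0.9, 0.0), O = c(1.2, 1.4, 1.0))
  backbone <- purrr::imap(off, function(o, nm)
    tibble(chain = chain, seq_index = i, atom = nm,
           x = ca[, 1] + o[1], y = ca[, 2] + o[2], z = ca[, 3] + o[3])) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$seq_index)
  new_structure(nodes, backbone,
                source_id = source_id %||%
                  sprintf("synthetic_%s_n%d_seed%d", geometry, n, seed))
}

#' Generate a synthetic two-chain complex
#'
#' Receptor chain A and ligand chain B, each a [make_polypeptide()], with
#' the ligand offset along z so that the smallest receptor-ligand
#' side-chain-centre distance is controlled by `separation`: below the
#' network cutoff the chains touch, above it they are contact-free.
#'
#' @param n_receptor,n_ligand Residues per chain.
#' @param separation Inter-chain gap in Angstrom.
#' @param geometry Chain geometry, as in [make_polypeptide()].
#' @param seed Integer seed (ligand uses `seed + 1`).
#' @return A [new_structure()] tibble with chains A (receptor) and B
#'   (ligand).
#' @export
make_complex <- function(n_receptor, n_ligand, separation = 4,
                         geometry = "extended", seed = 1L) {
  stopifnot(separation >= 0)
  rec <- make_polypeptide(n_receptor, geometry, seed = seed, chain = "A")
  lig <- make_polypeptide(n_ligand, geometry, seed = seed + 1L, chain = "B",
                          origin = c(0, 0, separation))
  nodes <- dplyr::bind_rows(as_tibble(rec), as_tibble(lig))
  backbone <- dplyr::bind_rows(structure_backbone(rec), structure_backbone(lig))
  new_structure(nodes, backbone,
                source_id = sprintf("synthetic_complex_%d_%d_seed%d",
                                    n_receptor, n_ligand, seed))
}

#' Random proper rotation matrix
#'
#' Drawn from the Haar measure via QR decomposition; uses the current RNG
#' state.
#'
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a decoy set with exactly known ligand RMSDs
#'
#' Each decoy is the native with its ligand chain(s) rigidly translated
#' along a random direction by the target distance, so the true ligand
#' RMSD equals the target to machine precision (a uniform displacement of
#' every ligand atom). Optionally the whole decoy is then given a random
#' rigid transform, which the receptor superposition of [ligand_rmsd()]
#' must remove.
#'
#' @param native A two-or-more-chain `wrn_structure`.
#' @param rmsd_targets Nonnegative numeric vector, one target per decoy.
#' @param ligand_chains Chain IDs to displace.
#' @param seed Integer seed.
#' @param scramble_frame Also apply a random rigid transform to the whole
#'   decoy (default TRUE).
#' @return List with `structures` (named list of `wrn_structure`) and
#'   `manifest` (tibble `decoy_id`, `true_l_rmsd`).
#' @export
make_decoy_set <- function(native, rmsd_targets, ligand_chains = "B",
                           seed = 1L, scramble_frame = TRUE) {
  stopifnot(inherits(native, "wrn_structure"))
  if (any(rmsd_targets < 0)) abort("rmsd targets must be nonnegative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sprintf("decoy_%04d", seq_along(rmsd_targets))
  structures <- purrr::map2(rmsd_targets, ids, function(t, id) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    d <- transform_structure(native, translation = t * u, chains = ligand_chains)
    if (scramble_frame)
      d <- transform_structure(d, rotation = random_rotation(),
                               translation = runif(3, -20, 20))
    attr(d, "source_id") <- id
    d
  })
  names(structures) <- ids
  list(structures = structures,
       manifest = tibble(decoy_id = ids, true_l_rmsd = as.numeric(rmsd_targets)))
}

#' Write a decoy set (and manifest) to a directory
#'
#' @param decoy_set Result of [make_decoy_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decoy_set <- function(decoy_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(decoy_set$structures, function(s, id)
    write_pdb(s, file.path(dir, paste0(id, ".pdb"))))
  readr::write_tsv(decoy_set$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Generate a seeded synthetic docking benchmark
#'
#' A set of independent synthetic systems, each a native complex plus a
#' decoy set whose true ligand RMSDs are drawn uniformly on (0, max_rmsd),
#' with max_rmsd itself varying across systems so hit fractions differ.
#' Intended for end-to-end evaluation of scoring, ranking and success-rate
#' machinery against manifest ground truth.
#'
#' @param n_systems Number of systems.
#' @param n_decoys Decoys per system.
#' @param n_receptor,n_ligand Chain sizes of each native.
#' @param seed Integer seed.
#' @return Tibble with one row per system: `system_id`, and list-columns
#'   `native`, `decoys` (named list of structures), `manifest`.
#' @export
make_benchmark <- function(n_systems = 10, n_decoys = 100,
                           n_receptor = 30, n_ligand = 15, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sys_seeds <- sample.int(1e6, n_systems)
  max_rmsd <- runif(n_systems, 10, 30)
  rows <- purrr::map(seq_len(n_systems), function(s) {
    native <- make_complex(n_receptor, n_ligand, separation = 4,
                           geometry = "extended", seed = sys_seeds[s])
    targets <- runif(n_decoys, 0, max_rmsd[s])
    ds <- make_decoy_set(native, targets, ligand_chains = "B",
                         seed = sys_seeds[s] + 1L)
    tibble(system_id = sprintf("sys%02d", s),
           native = list(native),
           decoys = list(ds$structures),
           manifest = list(ds$manifest))
  })
  dplyr::bind_rows(rows)
}
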