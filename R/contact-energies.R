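#' Residue contact-energy weight tables
#'
#' A contact-energy table assigns every unordered pair of the 20 standard
#' amino-acid types a strictly positive link weight: the magnitude of the
#' statistical inter-residue contact energy for that pair. Because all
#' entries of the underlying energy set are negative, their absolute values
#' are used, so a more favourable residue-residue contact carries a larger
#' weight. Peptide-bonded neighbours get a fixed weight (`covalent_weight`,
#' default 2.55, the magnitude of the average collapse energy of the same
#' energy set) regardless of distance.
#'
#' @param weights A symmetric 20x20 numeric matrix of positive weights with
#'   three-letter amino-acid dimnames, or a single positive number for a
#'   uniform table.
#' @param covalent_weight Positive weight applied to sequence-adjacent
#'   residues of the same chain. Default 2.55.
#' @return An object of class `contact_energy_table`: a list with the weight
#'   matrix (`weights`) and `covalent_weight`.
#' @seealso [mj_contact_energies()], [read_energy_table()], [lookup_weight()]
#' @examples
#' tab <- contact_energy_table(1.0)   # uniform weights
#' lookup_weight(tab, "ALA", "GLY")
#' @export
contact_energy_table <- function(weights, covalent_weight = 2.55) {
  if (is.numeric(weights) && length(weights) == 1L) {
    if (weights <= 0) abort("uniform weight must be positive")
    weights <- matrix(weights, 20, 20, dimnames = list(.AA3, .AA3))
  }
  if (!is.matrix(weights) || !identical(dim(weights), c(20L, 20L)))
    abort("`weights` must be a 20x20 numeric matrix")
  rn <- normalize_resname(rownames(weights))
  cn <- normalize_resname(colnames(weights))
  if (anyNA(rn) || anyNA(cn) || anyDuplicated(rn) || anyDuplicated(cn))
    abort("weight matrix dimnames must name the 20 standard amino acids")
  dimnames(weights) <- list(rn, cn)
  weights <- weights[.AA3, .AA3]
  if (!isSymmetric(unname(weights), tol = 0))
    abort("weight matrix must be exactly symmetric")
  if (any(weights <= 0)) abort("all pair weights must be strictly positive")
  if (!is.numeric(covalent_weight) || length(covalent_weight) != 1L ||
      covalent_weight <= 0)
    abort("`covalent_weight` must be a single positive number")
  structure(list(weights = weights, covalent_weight = covalent_weight),
            class = "contact_energy_table")
}

#' Miyazawa-Jernigan contact-energy weights
#'
#' The default link-weight table: magnitudes of the Miyazawa-Jernigan (1996)
#' inter-residue contact energies e_ij (the all-negative upper-triangle set
#' of their Table 3), shipped as a plain-text file in `inst/extdata`. The
#' covalent weight defaults to 2.55, the magnitude of the same work's
#' average collapse energy.
#'
#' @param covalent_weight Weight for peptide-bonded neighbours.
#' @return A [contact_energy_table()].
#' @references Miyazawa S, Jernigan RL (1996). Residue-residue potentials
#'   with a favorable contact pair term and an unfavorable high packing
#'   density term, for simulation and threading. J Mol Biol 256(3):623-644.
#' @examples
#' tab <- mj_contact_energies()
#' lookup_weight(tab, "PHE", "PHE")   # 7.26
#' @export
mj_contact_energies <- function(covalent_weight = 2.55) {
  path <- system.file("extdata", "mj1996_eij.txt", package = "wrndock",
                      mustWork = TRUE)
  read_energy_table(path, covalent_weight = covalent_weight)
}

#' Read a contact-energy table from a plain-text file
#'
#' The format is a header line of 20 three-letter amino-acid codes followed
#' by a whitespace-delimited 20x20 matrix; lines starting with `#` are
#' comments. Only the magnitudes of the values are used as weights, so a
#' table of negative contact energies and a table of their absolute values
#' load identically.
#'
#' @param path File path.
#' @inheritParams contact_energy_table
#' @return A [contact_energy_table()].
#' @export
read_energy_table <- function(path, covalent_weight = 2.55) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) != 21L)
    abort(sprintf("expected 1 header + 20 matrix rows, got %d non-comment lines",
                  length(lines)))
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(hdr) != 20L || any(lengths(vals) != 20L))
    abort("energy table must be a 20-token header and a 20x20 matrix")
  m <- abs(do.call(rbind, vals))
  dimnames(m) <- list(hdr, hdr)
  contact_energy_table(m, covalent_weight = covalent_weight)
}

#' Write a contact-energy table to its plain-text format
#'
#' Inverse of [read_energy_table()]: round-tripping reproduces every entry.
#'
#' @param table A [contact_energy_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path) {
  stopifnot(inherits(table, "contact_energy_table"))
  w <- table$weights
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# residue contact-energy weights; covalent weight %.6g",
                     table$covalent_weight), con)
  writeLines(paste(colnames(w), collapse = " "), con)
  for (i in seq_len(nrow(w)))
    writeLines(paste(format(w[i, ], digits = 15, trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Look up the link weight for a residue-type pair
#'
#' Symmetric in its arguments. Residue names are normalised with
#' [normalize_resname()] first; an unmappable name is an error, so callers
#' that prefer to drop such residues must filter beforehand.
#'
#' @param table A [contact_energy_table()].
#' @param res_a,res_b Residue names (one- or three-letter, aliases allowed).
#' @return Positive numeric weight(s); vectorised over pairs.
#' @export
lookup_weight <- function(table, res_a, res_b) {
  stopifnot(inherits(table, "contact_energy_table"))
  a <- normalize_resname(res_a)
  b <- normalize_resname(res_b)
  bad <- c(res_a[is.na(a)], res_b[is.na(b)])
  if (length(bad))
    abort(sprintf("unmappable residue type(s): %s",
                  paste(unique(bad), collapse = ", ")),
          class = "wrndock_unmappable_residue")
  table$weights[cbind(a, b)]
}

#' @export
print.contact_energy_table <- function(x, ...) {
  cat("<contact_energy_table>\n")
  cat(sprintf("  20 amino-acid types, 210 pair weights in [%.3g, %.3g]\n",
              min(x$weights), max(x$weights)))
  cat(sprintf("  covalent weight: %.6g\n", x$covalent_weight))
  invisible(x)
}

#' @describeIn contact_energy_table weights as a long tibble (res_a, res_b,
#'   weight), one row per unordered pair.
#' @param x A `contact_energy_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.contact_energy_table <- function(x, ...) {
  idx <- which(upper.tri(x$weights, diag = TRUE), arr.ind = TRUE)
  tibble(res_a = rownames(x$weights)[idx[, 1]],
         res_b = colnames(x$weights)[idx[, 2]],
         weight = x$weights[idx])
}
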