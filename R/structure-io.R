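#' Construct a residue-level structure model
#'
#' A `wrn_structure` is a tibble with one row per residue: `chain`,
#' `seq_index` (0-based position in parse order within the chain), `resno`
#' and `insert` (author numbering, kept for residue matching), `resname`
#' (standard three-letter code) and the side-chain geometric centre
#' (`x`, `y`, `z`, in Angstrom). Backbone coordinates (atoms N, CA, C, O,
#' any subset) travel alongside as a long tibble in the `backbone`
#' attribute; `source_id` labels the origin (file stem or generator tag).
#'
#' @param nodes Tibble with columns chain, seq_index, resno, insert,
#'   resname, x, y, z.
#' @param backbone Tibble with columns chain, seq_index, atom, x, y, z.
#' @param source_id Single character label.
#' @return A `wrn_structure` tibble.
#' @export
new_structure <- function(nodes, backbone = NULL, source_id = "structure") {
  nodes <- as_tibble(nodes)
  req <- c("chain", "seq_index", "resno", "insert", "resname", "x", "y", "z")
  if (!all(req %in% names(nodes)))
    abort(paste("nodes must have columns:", paste(req, collapse = ", ")))
  if (!nrow(nodes)) abort("structure has no residues", class = "wrndock_empty_structure")
  if (!all(is.finite(as.matrix(nodes[c("x", "y", "z")]))))
    abort("all side-chain centres must be finite")
  bad <- nodes |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(ok = identical(as.integer(.data$seq_index),
                                    seq(0L, dplyr::n() - 1L)), .groups = "drop")
  if (!all(bad$ok))
    abort("seq_index must run 0..n-1 consecutively within each chain")
  if (is.null(backbone))
    backbone <- tibble(chain = character(), seq_index = integer(),
                       atom = character(), x = double(), y = double(), z = double())
  structure(nodes,
            backbone = as_tibble(backbone),
            source_id = source_id,
            class = c("wrn_structure", class(tibble())))
}

#' @rdname new_structure
#' @param x A `wrn_structure`.
#' @export
structure_backbone <- function(x) attr(x, "backbone")

#' @rdname new_structure
#' @export
source_id <- function(x) attr(x, "source_id") %||% "structure"

.WATER <- c("HOH", "WAT", "DOD", "SOL", "H2O")
.BACKBONE <- c("N", "CA", "C", "O")

#' Parse a PDB file into a residue-level structure
#'
#' Reads standard PDB records through bio3d and coarse-grains each standard
#' (or alias-mapped, see [normalize_resname()]) amino-acid residue to its
#' side-chain geometric centre. Waters, hetero ligands, hydrogens and
#' unmappable residues are excluded; their counts are reported unless
#' `quiet = TRUE`. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered). Of a multi-MODEL
#' file only one model is read (`model`, default the first).
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string with
#'   newlines or a character vector of records).
#' @param model 1-based MODEL index for multi-model files.
#' @param source_id Label for the structure; defaults to the file stem.
#' @param quiet Suppress the skipped-record message.
#' @return A [new_structure()] tibble.
#' @examples
#' pdb <- make_polypeptide(5, seed = 1)
#' s <- read_structure(write_pdb(pdb))
#' nrow(s)  # 5
#' @export
read_structure <- function(pdb, model = 1L, source_id = NULL, quiet = FALSE) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(source_id))
      source_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(pdb), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    if (is.null(source_id)) source_id <- "structure"
  }
  lines <- .select_model(lines, model)
  .check_coord_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb_obj <- NULL
  utils::capture.output(
    pdb_obj <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE,
                                                verbose = FALSE)))
  atoms <- pdb_obj$atom |>
    as_tibble() |>
    dplyr::filter(.data$type %in% c("ATOM", "HETATM"))
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$insert[is.na(atoms$insert)] <- ""

  n_water <- sum(atoms$resid %in% .WATER)
  atoms <- dplyr::filter(atoms, !.data$resid %in% .WATER)
  atoms$resname <- normalize_resname(atoms$resid)
  n_unmapped <- length(unique(paste(atoms$chain, atoms$resno, atoms$insert)[is.na(atoms$resname)]))
  atoms <- dplyr::filter(atoms, !is.na(.data$resname))
  is_h <- (!is.na(atoms$elesy) & atoms$elesy %in% c("H", "D")) |
    (is.na(atoms$elesy) & grepl("^[0-9]*[HD]", atoms$elety))
  atoms <- atoms[!is_h, , drop = FALSE]
  if (!nrow(atoms))
    abort("no parseable protein residues", class = "wrndock_empty_structure")

  ## altLoc: within each residue keep, per atom name, the highest-occupancy
  ## conformer; ties go to the first record encountered
  atoms <- atoms |>
    dplyr::mutate(.ord = dplyr::row_number(),
                  occ = dplyr::coalesce(.data$o, 1)) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)

  res <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resname) |>
    dplyr::summarise(first_ord = min(.data$.ord),
                     atoms = list(tibble(atom = elety, x = x, y = y, z = z)),
                     .groups = "drop") |>
    dplyr::arrange(.data$first_ord)

  centers <- purrr::map2(res$atoms, res$resname, sidechain_center)
  dropped <- purrr::map_lgl(centers, is.null)
  if (any(dropped) && !quiet)
    inform(sprintf("dropped %d residue(s) with no side-chain atoms and no CA",
                   sum(dropped)))
  res <- res[!dropped, , drop = FALSE]
  centers <- centers[!dropped]
  if (!nrow(res))
    abort("no parseable protein residues", class = "wrndock_empty_structure")

  cen <- do.call(rbind, centers)
  nodes <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(seq_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(x = cen[, 1], y = cen[, 2], z = cen[, 3]) |>
    dplyr::select("chain", "seq_index", "resno", "insert", "resname",
                  "x", "y", "z")

  backbone <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(seq_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("chain", "seq_index", "atoms") |>
    tidyr::unnest("atoms") |>
    dplyr::filter(.data$atom %in% .BACKBONE)

  if (!quiet && (n_water || n_unmapped))
    inform(sprintf("skipped %d water atom(s) and %d unmappable residue(s)",
                   n_water, n_unmapped))
  new_structure(nodes, backbone, source_id = source_id)
}

.select_model <- function(lines, model) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    if (model > 1L) abort("file has a single model; `model` out of range")
    return(lines)
  }
  if (model > length(starts)) abort(sprintf("model %d not present", model))
  ends <- grep("^ENDMDL", lines)
  end <- ends[ends > starts[model]][1]
  if (is.na(end)) end <- length(lines) + 1L
  lines[(starts[model] + 1L):(end - 1L)]
}

.check_coord_lines <- function(lines) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    f <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(f))))
      abort(sprintf("malformed coordinate fields on line %d: %s", i, lines[i]),
            class = "wrndock_parse_error")
  }
  invisible(lines)
}

#' Side-chain geometric centre of one residue
#'
#' Unweighted mean of the side-chain heavy-atom coordinates (every atom
#' except backbone N, CA, C, O and the terminal OXT; hydrogens are assumed
#' already removed). Glycine, and any residue whose side-chain heavy atoms
#' are all missing, falls back to the CA coordinate.
#'
#' @param atoms Tibble with columns atom, x, y, z for one residue.
#' @param resname Standard three-letter code.
#' @return Numeric length-3 centre, or `NULL` if the residue has neither
#'   side-chain atoms nor a CA (caller drops it).
#' @export
sidechain_center <- function(atoms, resname) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  side <- !(atoms$atom %in% c(.BACKBONE, "OXT"))
  if (resname != "GLY" && any(side))
    return(colMeans(xyz[side, , drop = FALSE]))
  ca <- which(atoms$atom == "CA")
  if (length(ca)) return(xyz[ca[1], ])
  if (any(side)) return(colMeans(xyz[side, , drop = FALSE]))  # GLY oddity
  NULL
}

#' Serialise a structure to PDB text
#'
#' Backbone atoms are written as-is; the side-chain centre is written as a
#' single CB pseudo-atom (omitted for glycine, whose centre is its CA), so
#' that [read_structure()] round-trips node count, order and coordinates.
#'
#' @param structure A `wrn_structure`.
#' @param path Optional output file; when `NULL` the text is returned.
#' @param remarks Character vector written as REMARK records.
#' @return `path` if written, else the PDB text as one string.
#' @export
write_pdb <- function(structure, path = NULL, remarks = character()) {
  stopifnot(inherits(structure, "wrn_structure"))
  bb <- structure_backbone(structure)
  out <- character()
  if (length(remarks)) out <- sprintf("REMARK   9 %s", remarks)
  serial <- 0L
  fmt <- function(serial, name, resname, chain, resno, x, y, z, ele) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resname, chain, resno, x, y, z, 1, 0, ele)
  }
  for (ch in unique(structure$chain)) {
    rows <- which(structure$chain == ch)
    for (r in rows) {
      nd <- structure[r, ]
      rb <- bb[bb$chain == ch & bb$seq_index == nd$seq_index, , drop = FALSE]
      rb <- rb[match(intersect(.BACKBONE, rb$atom), rb$atom), , drop = FALSE]
      for (k in seq_len(nrow(rb))) {
        serial <- serial + 1L
        out <- c(out, fmt(serial, rb$atom[k], nd$resname, ch, nd$resno,
                          rb$x[k], rb$y[k], rb$z[k],
                          substr(rb$atom[k], 1, 1)))
      }
      if (nd$resname != "GLY") {
        serial <- serial + 1L
        out <- c(out, fmt(serial, "CB", nd$resname, ch, nd$resno,
                          nd$x, nd$y, nd$z, "C"))
      }
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  if (is.null(path)) return(paste(out, collapse = "\n"))
  writeLines(out, path)
  invisible(path)
}

#' Apply a rigid-body transform to a structure
#'
#' Maps every side-chain centre and backbone atom through
#' `x' = R x + t`.
#'
#' @param structure A `wrn_structure`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric length-3 translation (Angstrom).
#' @param chains Optional chain IDs; when given, only those chains move.
#' @return The transformed `wrn_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0), chains = NULL) {
  stopifnot(inherits(structure, "wrn_structure"))
  sel_n <- if (is.null(chains)) rep(TRUE, nrow(structure)) else structure$chain %in% chains
  bb <- structure_backbone(structure)
  sel_b <- if (is.null(chains)) rep(TRUE, nrow(bb)) else bb$chain %in% chains
  tx <- function(m) sweep(m %*% t(rotation), 2, translation, "+")
  nodes <- as_tibble(structure)
  if (any(sel_n))
    nodes[sel_n, c("x", "y", "z")] <-
      as.data.frame(tx(as.matrix(nodes[sel_n, c("x", "y", "z")])))
  if (any(sel_b))
    bb[sel_b, c("x", "y", "z")] <-
      as.data.frame(tx(as.matrix(bb[sel_b, c("x", "y", "z")])))
  new_structure(nodes, bb, source_id = source_id(structure))
}

#' @export
print.wrn_structure <- function(x, ...) {
  ch <- table(x$chain)
  cat(sprintf("<wrn_structure> %s: %d residues in %d chain(s) [%s]\n",
              source_id(x), nrow(x), length(ch),
              paste(sprintf("%s:%d", names(ch), ch), collapse = ", ")))
  NextMethod()
}
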