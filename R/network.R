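#' Build the weighted residue contact network of a structure
#'
#' Residues are nodes at their side-chain geometric centres. The unweighted
#' adjacency links two distinct residues whenever their centre distance is
#' strictly below the cutoff (default 6.5 Angstrom). The weighted adjacency
#' assigns each such contact the magnitude of the pair's contact energy,
#' except that sequence-adjacent residues of the same chain always carry the
#' fixed covalent weight (default 2.55) irrespective of distance — the
#' covalent weight replaces, never adds to, a contact weight. Cross-chain
#' pairs are never covalent; the diagonal is zero.
#'
#' @param structure A [new_structure()] tibble (the whole complex: receptor
#'   and ligand chains together).
#' @param energy_table A [contact_energy_table()]; default the
#'   Miyazawa-Jernigan weights of [mj_contact_energies()].
#' @param cutoff Contact distance cutoff in Angstrom (default 6.5; strict
#'   `<`, so a pair at exactly the cutoff is not a contact).
#' @param covalent_weight Overrides the table's covalent weight if given.
#' @param degree_from How the node degree k_i used by the neighbour-degree
#'   averages is defined: `"weighted_support"` (default) counts the nonzero
#'   entries of the weighted adjacency, so peptide-bonded neighbours always
#'   count even beyond the cutoff; `"contact"` counts cutoff contacts only.
#' @return A `wrn_network`: list with `nodes` (the structure tibble),
#'   `adj` (0/1 contact matrix), `wadj` (weighted adjacency), `degree`,
#'   `strength` (row sums of `wadj`), and the parameters used.
#' @examples
#' net <- make_polypeptide(8, seed = 1) |> build_network()
#' network_strength(net)
#' knn_weighted_mean(net)
#' @export
build_network <- function(structure, energy_table = mj_contact_energies(),
                          cutoff = 6.5, covalent_weight = NULL,
                          degree_from = c("weighted_support", "contact")) {
  stopifnot(inherits(structure, "wrn_structure"), cutoff > 0)
  degree_from <- match.arg(degree_from)
  cw <- covalent_weight %||% energy_table$covalent_weight
  n <- nrow(structure)
  d <- as.matrix(dist(as.matrix(structure[, c("x", "y", "z")])))
  adj <- (d < cutoff) * 1
  diag(adj) <- 0

  w <- energy_table$weights[cbind(rep(structure$resname, each = n),
                                  rep(structure$resname, times = n))]
  wadj <- adj * matrix(w, n, n)

  ## peptide bond: consecutive parse-order residues of the same chain
  if (n > 1) {
    i <- seq_len(n - 1L)
    cov <- which(structure$chain[i] == structure$chain[i + 1L])
    wadj[cbind(cov, cov + 1L)] <- cw
    wadj[cbind(cov + 1L, cov)] <- cw
  }
  dimnames(adj) <- dimnames(wadj) <- NULL

  degree <- switch(degree_from,
                   weighted_support = rowSums(wadj > 0),
                   contact = rowSums(adj))
  net <- list(nodes = as_tibble(structure), adj = adj, wadj = wadj,
              degree = as.integer(degree), strength = rowSums(wadj),
              cutoff = cutoff, covalent_weight = cw,
              degree_from = degree_from,
              source_id = source_id(structure))
  class(net) <- "wrn_network"
  net
}

#' Whole-network strength
#'
#' The sum of all link weights, each link counted once: half the sum of the
#' node strengths. Larger strength corresponds to a more stably packed
#' (more and stronger contacts) structure.
#'
#' @param net A `wrn_network`.
#' @return Nonnegative scalar.
#' @export
network_strength <- function(net) {
  stopifnot(inherits(net, "wrn_network"))
  sum(net$strength) / 2
}

#' Weighted average nearest-neighbours degree of one node
#'
#' For node i with strength S_i, the weight-normalised mean degree of its
#' neighbours: (1/S_i) * sum_j wadj_ij * k_j. An isolated node (S_i = 0)
#' returns 0 by convention.
#'
#' @param net A `wrn_network`.
#' @param i Node index (1-based).
#' @return Nonnegative scalar.
#' @export
knn_weighted_node <- function(net, i) {
  stopifnot(inherits(net, "wrn_network"), i >= 1, i <= length(net$degree))
  s <- net$strength[i]
  if (s == 0) return(0)
  sum(net$wadj[i, ] * net$degree) / s
}

#' Unweighted average nearest-neighbours degree of one node
#'
#' (1/k_i) * sum over neighbours j of k_j, neighbours taken from the
#' support of the weighted adjacency; 0 when k_i = 0.
#'
#' @inheritParams knn_weighted_node
#' @return Nonnegative scalar.
#' @export
knn_unweighted_node <- function(net, i) {
  stopifnot(inherits(net, "wrn_network"), i >= 1, i <= length(net$degree))
  k <- net$degree[i]
  if (k == 0) return(0)
  sum((net$wadj[i, ] > 0) * net$degree) / k
}

#' Network mean of the weighted average nearest-neighbours degree
#'
#' The plain mean of [knn_weighted_node()] over all N nodes (isolated nodes
#' contribute 0). This global quantity reflects how the complex's residues
#' of different connectivity are wired together; for natively packed
#' protein complexes it sits near 6.
#'
#' @param net A `wrn_network`.
#' @return Nonnegative scalar.
#' @export
knn_weighted_mean <- function(net) {
  stopifnot(inherits(net, "wrn_network"))
  n <- length(net$degree)
  if (n == 0) abort("mean undefined for an empty network")
  mean(.knn_w_all(net))
}

.knn_w_all <- function(net) {
  num <- drop(net$wadj %*% net$degree)
  ifelse(net$strength > 0, num / net$strength, 0)
}

.knn_all <- function(net) {
  num <- drop((net$wadj > 0) %*% net$degree)
  ifelse(net$degree > 0, num / net$degree, 0)
}

#' Per-node network metrics
#'
#' @param net A `wrn_network`.
#' @return A tibble with one row per residue: chain, seq_index, resname,
#'   degree k_i, strength S_i, knn (unweighted average nearest-neighbours
#'   degree) and knn_w (weighted version).
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "wrn_network"))
  dplyr::bind_cols(net$nodes[, c("chain", "seq_index", "resname")],
                   tibble(degree = net$degree, strength = net$strength,
                          knn = .knn_all(net), knn_w = .knn_w_all(net)))
}

#' @describeIn build_network edge list as a tibble: `node_a`, `node_b`
#'   (1-based indices, a < b), `chain_a`, `chain_b`, `weight` and `type`
#'   (`"covalent"` or `"contact"`).
#' @param x A `wrn_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wrn_network <- function(x, ...) {
  idx <- which(upper.tri(x$wadj) & x$wadj > 0, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same_chain <- x$nodes$chain[i] == x$nodes$chain[j]
  covalent <- same_chain & (j - i == 1L) &
    purrr::map2_lgl(i, j, function(a, b)
      x$nodes$seq_index[b] - x$nodes$seq_index[a] == 1L)
  tibble(node_a = i, node_b = j,
         chain_a = x$nodes$chain[i], chain_b = x$nodes$chain[j],
         weight = x$wadj[idx],
         type = ifelse(covalent, "covalent", "contact")) |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

#' @describeIn build_network one-row network summary: node and edge counts,
#'   whole-network strength S and the mean weighted nearest-neighbours
#'   degree.
#' @exportS3Method generics::glance
glance.wrn_network <- function(x, ...) {
  tibble(n_nodes = length(x$degree),
         n_edges = sum(x$wadj > 0) / 2,
         n_contacts = sum(x$adj) / 2,
         strength = network_strength(x),
         knn_w_mean = knn_weighted_mean(x))
}

#' Write a network edge list as TSV
#'
#' @param net A `wrn_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  readr::write_tsv(tidy(net), path)
  invisible(path)
}

#' @export
print.wrn_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<wrn_network> %s: %d nodes, %d edges (%d contacts), cutoff %.2f A\n",
              x$source_id, g$n_nodes, g$n_edges, g$n_contacts, x$cutoff))
  cat(sprintf("  strength S = %.4g, <knn_w> = %.4g\n", g$strength, g$knn_w_mean))
  invisible(x)
}
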