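# Independent brute-force implementations used as oracles. Everything here
# is deliberately naive (explicit double loops, no matrix algebra) and
# kept separate from the package code paths it checks.

# all network quantities from scratch, given a structure tibble
naive_network <- function(structure, table = mj_contact_energies(),
                          cutoff = 6.5, cw = table$covalent_weight) {
  n <- nrow(structure)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  adj <- matrix(0, n, n)
  wadj <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < cutoff) adj[i, j] <- 1
    covalent <- structure$chain[i] == structure$chain[j] &&
      abs(structure$seq_index[i] - structure$seq_index[j]) == 1L
    if (covalent) {
      wadj[i, j] <- cw
    } else if (adj[i, j] == 1) {
      wadj[i, j] <- table$weights[structure$resname[i], structure$resname[j]]
    }
  }
  k <- integer(n)
  s_i <- numeric(n)
  for (i in seq_len(n)) {
    k[i] <- sum(wadj[i, ] > 0)
    s_i[i] <- sum(wadj[i, ])
  }
  knn <- knn_w <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] > 0) {
      acc <- 0
      for (j in seq_len(n)) if (wadj[i, j] > 0) acc <- acc + k[j]
      knn[i] <- acc / k[i]
    }
    if (s_i[i] > 0) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + wadj[i, j] * k[j]
      knn_w[i] <- acc / s_i[i]
    }
  }
  s_total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) s_total <- s_total + wadj[i, j]
  list(adj = adj, wadj = wadj, degree = k, strength = s_i,
       knn = knn, knn_w = knn_w, S = s_total, knn_w_mean = mean(knn_w))
}

# per-system indicators by direct enumeration over a ranked decoy table
naive_indicators <- function(ranked) {
  ranked <- ranked[order(ranked$rank), ]
  first_hit <- NA_integer_
  hits10 <- 0L
  for (r in seq_len(nrow(ranked))) {
    if (ranked$is_hit[r]) {
      if (is.na(first_hit)) first_hit <- ranked$rank[r]
      if (ranked$rank[r] <= 10) hits10 <- hits10 + 1L
    }
  }
  list(pearson_r = cor(ranked$sn_score, ranked$l_rmsd),
       rmsd_rank1 = ranked$l_rmsd[1],
       first_hit_rank = first_hit,
       hits_top10 = hits10,
       n_hits = sum(ranked$is_hit))
}

# success-rate curve by direct counting
naive_success_curve <- function(first_hit_ranks, max_np) {
  vapply(seq_len(max_np), function(np) {
    ok <- 0
    for (fh in first_hit_ranks)
      if (!is.na(fh) && fh <= np) ok <- ok + 1
    ok / length(first_hit_ranks)
  }, numeric(1))
}

# quick bare structure from explicit centres (no backbone atoms)
centres_structure <- function(centers, resnames, chains = "A") {
  n <- nrow(centers)
  chains <- rep_len(chains, n)
  nodes <- tibble::tibble(
    chain = chains,
    resname = resnames,
    x = centers[, 1], y = centers[, 2], z = centers[, 3])
  nodes <- dplyr::group_by(nodes, chain)
  nodes <- dplyr::mutate(nodes, seq_index = dplyr::row_number() - 1L,
                         resno = seq_index + 1L, insert = "")
  nodes <- dplyr::ungroup(nodes)
  new_structure(nodes[, c("chain", "seq_index", "resno", "insert",
                          "resname", "x", "y", "z")])
}

# the hand-worked three-residue chain: centres too far apart for contacts,
# so the network holds exactly the two peptide links
three_residue_chain <- function() {
  centres_structure(rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0)),
                    c("ALA", "TRP", "SER"))
}
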