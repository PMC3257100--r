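test_that("ligand RMSD honours the superposition contract", {
  nat <- make_complex(12, 6, separation = 4, seed = 1)
  # identity
  expect_equal(ligand_rmsd(nat, nat, "A", "B"), 0, tolerance = 1e-9)
  # a rigid motion of the whole decoy is removed by the receptor fit
  set.seed(3)
  moved <- transform_structure(nat, random_rotation(), runif(3, -50, 50))
  expect_lt(ligand_rmsd(nat, moved, "A", "B"), 1e-6)
  # translating only the ligand by d gives exactly d
  for (d in c(0.5, 4, 17.3)) {
    dec <- transform_structure(nat, translation = c(d, 0, 0), chains = "B")
    expect_equal(ligand_rmsd(nat, dec, "A", "B"), d, tolerance = 1e-6)
  }
  # invariance under a rigid motion of the native as well
  dec <- transform_structure(nat, translation = c(5, 0, 0), chains = "B")
  nat2 <- transform_structure(nat, random_rotation(), runif(3, -50, 50))
  expect_equal(ligand_rmsd(nat2, dec, "A", "B"), 5, tolerance = 1e-6)
})

test_that("the least-squares fit agrees with an established reference", {
  set.seed(11)
  q <- matrix(rnorm(30), 10, 3)
  p <- sweep(q %*% t(random_rotation()), 2, c(4, -2, 9), "+") +
    matrix(rnorm(30, sd = 0.1), 10, 3)
  fit <- kabsch(p, q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(q)), mobile = as.vector(t(p))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - q)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("hit calling is inclusive at the threshold", {
  expect_true(call_hit(4.0))
  expect_false(call_hit(4.0001))
  expect_true(call_hit(0))
  expect_identical(call_hit(c(1, 4, 4.5), threshold = 4), c(TRUE, TRUE, FALSE))
  expect_error(call_hit(-1))
})

test_that("underdetermined or mismatched inputs error out", {
  nat <- make_complex(12, 6, separation = 4, seed = 1)
  expect_error(ligand_rmsd(nat, nat, "A", "Q"), class = "wrndock_config_error")
  tiny <- make_complex(2, 2, separation = 4, seed = 1)
  # strip the receptor backbone below 3 atoms
  bb <- structure_backbone(tiny)
  keep <- !(bb$chain == "A" & !(bb$atom == "CA" & bb$seq_index == 0))
  tiny2 <- new_structure(tibble::as_tibble(tiny), bb[keep, ],
                         source_id = "tiny2")
  expect_error(ligand_rmsd(tiny2, tiny2, "A", "B"), "underdetermined")
})

test_that("per-system indicators match direct enumeration", {
  set.seed(21)
  for (rep in 1:5) {
    m <- sample(15:50, 1)
    ranked <- tibble::tibble(
      decoy_id = sprintf("d%03d", 1:m),
      sn_score = sort(rnorm(m) * 100),
      l_rmsd = runif(m, 0, 15)) |>
      dplyr::mutate(is_hit = call_hit(l_rmsd), rank = dplyr::row_number())
    ev <- evaluate_system(ranked, system_id = "rnd")
    ref <- naive_indicators(ranked)
    expect_equal(ev$pearson_r, ref$pearson_r)
    expect_equal(ev$rmsd_rank1, ref$rmsd_rank1)
    expect_equal(ev$first_hit_rank, ref$first_hit_rank)
    expect_equal(ev$hits_top10, ref$hits_top10)
    expect_equal(ev$n_hits, ref$n_hits)
    expect_lte(ev$hits_top10, min(10, ev$n_hits))
    expect_identical(is.na(ev$first_hit_rank), ev$n_hits == 0)
  }
})

test_that("indicator edge cases behave as documented", {
  ranked <- tibble::tibble(decoy_id = letters[1:5], sn_score = c(1, 2, 3, 4, 5),
                           l_rmsd = c(1, 2, 3, 4, 5),
                           is_hit = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                           rank = 1:5)
  ev <- evaluate_system(ranked)
  expect_equal(ev$pearson_r, 1)   # scores equal to RMSD: perfect correlation
  expect_equal(ev$hits_top10, 4)
  expect_false(ev$rank1_gt10)
  flat <- dplyr::mutate(ranked, sn_score = -1)
  expect_warning(ev2 <- evaluate_system(flat), "zero variance")
  expect_true(is.na(ev2$pearson_r))
})

test_that("success-rate curves count successful systems per NP", {
  evs <- tibble::tibble(first_hit_rank = c(1, 5, 12, NA),
                        n_decoys = rep(20L, 4), n_hits = c(3, 2, 1, 0))
  curve <- success_rate_curve(evs, max_np = 20)
  expect_equal(curve$success_rate[10], 0.5)
  expect_equal(curve$success_rate,
               naive_success_curve(evs$first_hit_rank, 20))
  expect_true(all(diff(curve$success_rate) >= 0))
  # at NP = set size the curve equals the fraction of systems with any hit
  expect_equal(curve$success_rate[20], mean(evs$n_hits >= 1))
  all1 <- tibble::tibble(first_hit_rank = c(1, 1), n_decoys = c(5L, 5L))
  expect_true(all(success_rate_curve(all1, 5)$success_rate == 1))
  none <- tibble::tibble(first_hit_rank = c(NA, NA), n_decoys = c(5L, 5L))
  expect_true(all(success_rate_curve(none, 5)$success_rate == 0))
})

test_that("the random baseline matches its closed-form expectation", {
  # degenerate compositions are exact
  all_hits <- tibble::tibble(n_decoys = 8L, n_hits = 8L)
  expect_true(all(random_baseline_curve(all_hits, 8, 10, seed = 1)$success_rate == 1))
  no_hits <- tibble::tibble(n_decoys = 8L, n_hits = 0L)
  expect_true(all(random_baseline_curve(no_hits, 8, 10, seed = 1)$success_rate == 0))
  # one hit among M: P(success at np) = np / M; check within 3 SE
  m <- 20L
  evs <- tibble::tibble(n_decoys = m, n_hits = 1L)
  nperm <- 1000
  curve <- random_baseline_curve(evs, m, n_permutations = nperm, seed = 42)
  for (np in c(1, 5, 10, 19)) {
    p <- expected_random_success(m, 1L, np)
    expect_equal(p, np / m)   # hypergeometric closed form
    se <- sqrt(p * (1 - p) / nperm)
    expect_lt(abs(curve$success_rate[np] - p), 3 * se + 1e-12)
  }
  # the baseline is reproducible per seed
  expect_identical(random_baseline_curve(evs, m, 50, seed = 7),
                   random_baseline_curve(evs, m, 50, seed = 7))
})

test_that("residue matching falls back to author numbering on length mismatch", {
  nat <- make_complex(10, 5, separation = 4, seed = 13)
  # drop the first receptor residue from the decoy (parse order shifts)
  dec0 <- tibble::as_tibble(nat)[-1, ]
  dec0$seq_index[dec0$chain == "A"] <- seq_len(sum(dec0$chain == "A")) - 1L
  bb <- structure_backbone(nat)
  bb <- bb[!(bb$chain == "A" & bb$seq_index == 0), ]
  bb$seq_index[bb$chain == "A"] <- bb$seq_index[bb$chain == "A"] - 1L
  dec <- new_structure(dec0, bb, source_id = "truncated")
  expect_equal(ligand_rmsd(nat, dec, "A", "B"), 0, tolerance = 1e-9)
})
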