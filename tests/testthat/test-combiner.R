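noisy_copy <- function(s, sd) {
  ca_structure(s$ca_coords + matrix(rnorm(3 * length(s), sd = sd),
                                    length(s), 3),
               sequence = s$sequence, residue_index = s$residue_index,
               target_id = s$target_id)
}

test_that("combination member selection honours rank, GDT, RMSD and cap rules", {
  s <- make_native(40, seed = 1)
  set.seed(2)
  n <- 70
  models <- c(list(ref = s),
              setNames(lapply(1:n, function(k) noisy_copy(s, 0.8)),
                       sprintf("m%02d", 1:n)))
  pool <- model_pool(models)
  rk <- new_ranking(names(models), seq(1, 0.01, length.out = n + 1))
  # ref ranks first; every other model is very similar (GDT >> 0.7)
  sel <- select_combination_set("ref", pool, rk)
  expect_lte(length(sel), 20L)                      # maximum 20 members
  expect_equal(sel, rk$model_id[2:21])              # rank order kept

  # a model at rank 61 is excluded even if nearly identical
  rk2 <- new_ranking(names(models), -seq_along(models))
  sel2 <- select_combination_set("ref", pool, rk2, top_n = 60)
  expect_false(rk2$model_id[61] %in% sel2)

  # dissimilar models fail both the GDT and RMSD gates
  far <- setNames(lapply(1:5, function(k) noisy_copy(s, 15)), paste0("far", 1:5))
  pool3 <- model_pool(c(list(ref = s), far))
  rk3 <- new_ranking(names(pool3$models), c(1, rep(0.5, 5)))
  expect_equal(length(select_combination_set("ref", pool3, rk3)), 0L)

  # near models qualify through the GDT > 0.7 gate at rank 10
  near <- noisy_copy(s, 0.5)
  expect_gt(gdt_ts(near, s), 0.7)
})

test_that("raising the GDT gate never enlarges the member set", {
  s <- make_native(40, seed = 3)
  set.seed(4)
  models <- c(list(ref = s),
              setNames(lapply(1:12, function(k)
                noisy_copy(s, runif(1, 0.3, 12))), sprintf("m%02d", 1:12)))
  pool <- model_pool(models)
  rk <- new_ranking(names(models), seq(1, 0, length.out = 13))
  sets <- lapply(c(0.3, 0.5, 0.7, 0.9), function(g)
    select_combination_set("ref", pool, rk, gdt_min = g, rmsd_max = 0))
  for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("consensus combination averages superposed members", {
  s <- make_native(30, seed = 5)
  # identical members: candidate equals the reference
  cand <- consensus_combine(s, list(s, s, s))
  expect_equal(cand$ca_coords, s$ca_coords, tolerance = 1e-9)

  # members symmetric about the reference: displacements cancel
  set.seed(6)
  delta <- matrix(rnorm(90, sd = 0.2), 30, 3)
  up <- ca_structure(s$ca_coords + delta, residue_index = s$residue_index)
  dn <- ca_structure(s$ca_coords - delta, residue_index = s$residue_index)
  cand2 <- consensus_combine(s, list(up, dn))
  expect_equal(cand2$ca_coords, s$ca_coords, tolerance = 0.05)

  expect_warning(same <- consensus_combine(s, list()), "no members")
  expect_equal(same$ca_coords, s$ca_coords)
})

test_that("consensus combination matches an independent superpose-and-average", {
  s <- make_native(30, seed = 7)
  set.seed(8)
  members <- lapply(1:5, function(k) {
    m <- noisy_copy(s, 1.5)
    ca_structure(random_rigid(m$ca_coords), residue_index = m$residue_index)
  })
  cand <- consensus_combine(s, members)
  acc <- s$ca_coords
  for (m in members)
    acc <- acc + oracle_superpose(m$ca_coords, s$ca_coords)$fit
  expect_equal(cand$ca_coords, acc / 6, tolerance = 1e-5)
})

test_that("the acceptance gate compares candidate and reference at 0.9", {
  s <- make_native(40, seed = 9)
  expect_equal(as.character(accept_candidate(s, s)), "accepted")
  expect_equal(as.character(accept_candidate(s, s, threshold = 0)),
               "accepted")

  # candidate constructed so its GDT-TS falls below the 0.9 gate
  set.seed(10)
  worse <- noisy_copy(s, 3)
  v <- accept_candidate(worse, s)
  expect_lt(attr(v, "gdt_ts"), 0.9)
  expect_equal(as.character(v), "rejected")
})

test_that("splice_regions replaces the region and keeps the rest bit-for-bit", {
  s <- make_native(40, seed = 11)
  out <- splice_regions(s, s, c(10, 20))
  expect_equal(out$ca_coords, s$ca_coords, tolerance = 1e-6)

  # donor identical outside a rigid motion: junctions stay bonded
  set.seed(12)
  donor <- ca_structure(random_rigid(s$ca_coords),
                        sequence = s$sequence,
                        residue_index = s$residue_index)
  spl <- splice_regions(s, donor, c(15, 25))
  keep_rows <- which(s$residue_index < 15 | s$residue_index > 25)
  expect_identical(spl$ca_coords[keep_rows, ], s$ca_coords[keep_rows, ])
  g <- attr(spl, "geometry")
  expect_s3_class(g, "geometry_report")
  expect_equal(nrow(g$breaks), 0L)

  expect_error(splice_regions(s, donor, c(1, 40)), "whole")
})

test_that("combination_plan wires selection, averaging and the gate", {
  s <- make_native(35, seed = 13)
  set.seed(14)
  models <- c(list(ref = s),
              setNames(lapply(1:6, function(k) noisy_copy(s, 0.8)),
                       paste0("m", 1:6)))
  pool <- model_pool(models)
  rk <- new_ranking(names(models), seq(1, 0.4, length.out = 7))
  plan <- combination_plan("ref", pool, rk, preset = "human")
  expect_s3_class(plan, "combination_plan")
  expect_equal(plan$acceptance, "accepted")
  expect_gte(plan$candidate_gdt, 0.9)
  expect_false("ref" %in% plan$member_ids)

  # the server preset uses the GDT > 0.6 rule without a rank window
  plan2 <- combination_plan("ref", pool, rk, preset = "server")
  expect_equal(sort(plan2$member_ids), sort(plan$member_ids))
})

test_that("averaging symmetric decoy pools moves the candidate toward truth", {
  wins <- 0L
  for (seed in 1:10) {
    s <- make_native(40, seed = 100 + seed)
    set.seed(seed)
    members <- lapply(1:8, function(k) noisy_copy(s, 2))
    ref <- members[[1]]
    cand <- consensus_combine(ref, members[-1])
    cand_rmsd <- rmsd_after_superposition(cand, s)
    member_rmsd <- mean(vapply(members, rmsd_after_superposition, numeric(1),
                               reference = s))
    if (cand_rmsd < member_rmsd) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
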