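test_that("neighbor ranking equals brute-force recomputation on a fixture database", {
  fit <- fit1(); w <- world1()
  qs <- standardize_smiles(w$queries$smiles[c(1, 8)],
                           ids = c("qa", "qb"))
  for (q in qs) {
    prof <- compute_profile(q)
    for (scheme in c("APfp", "MQN", "Sfp", "Ffp1", "Ffp4")) {
      nb <- rank_neighbors(prof, fit$db, scheme, st = fit$scaling)
      hits <- collect_targets(nb, fit$db, n_targets = 20, scheme = scheme)
      oracle <- brute_force_hits(prof, fit$db, scheme, fit$scaling)
      expect_equal(hits$target_id, oracle$target_id, info = scheme)
      expect_equal(hits$nn_distance, oracle$nn_distance, info = scheme)
      expect_equal(hits$nn_compound_id, oracle$nn_compound_id, info = scheme)
    }
  }
})

test_that("a database member retrieves itself at distance zero in every scheme", {
  fit <- fit1()
  member <- fit$db$members[[fit$db$targets$target_id[3]]]
  q <- standardize_smiles(member$canonical_smiles[2], ids = "self")[[1]]
  prof <- compute_profile(q)
  for (scheme in ppb_schemes()) {
    nb <- rank_neighbors(prof, fit$db, scheme, st = fit$scaling)
    expect_equal(nb$distance[1], 0, info = scheme)
    hits <- collect_targets(nb, fit$db, scheme = scheme)
    own <- hits[hits$target_id == fit$db$targets$target_id[3], ]
    expect_equal(own$nn_distance, 0, info = scheme)
    expect_true(own$identical_flag)
  }
})

test_that("target collection caps at n_targets and honors the first-seen rule", {
  fit <- fit1()
  q <- compute_profile(standardize_smiles(world1()$queries$smiles[1],
                                          ids = "q")[[1]])
  nb <- rank_neighbors(q, fit$db, "ECfp4")
  expect_equal(nrow(collect_targets(nb, fit$db, n_targets = 20)),
               nrow(fit$db$targets))               # fewer targets than the cap
  one <- collect_targets(nb, fit$db, n_targets = 1)
  expect_equal(nrow(one), 1)
  ## the single collected target must own the overall nearest neighbor
  expect_true(one$target_id %in%
                fit$db$comp2targets[[nb$canonical_smiles[1]]])
  ## a target's hit distance is the minimum over its members
  hits <- collect_targets(nb, fit$db, n_targets = 20)
  for (k in seq_len(nrow(hits))) {
    mem <- fit$db$members[[hits$target_id[k]]]$canonical_smiles
    expect_equal(hits$nn_distance[k],
                 min(nb$distance[nb$canonical_smiles %in% mem]))
  }
})

test_that("hit lists are stable under database record shuffling", {
  w <- world1()
  recs <- filter_activities(w$activities)
  db1 <- build_target_groups(recs, ionize = FALSE)
  set.seed(4)
  db2 <- build_target_groups(recs[sample(nrow(recs)), ], ionize = FALSE)
  q <- compute_profile(standardize_smiles(w$queries$smiles[5], ids = "q",
                                          ionize = FALSE)[[1]])
  for (scheme in c("APfp", "ECfp4")) {
    h1 <- collect_targets(rank_neighbors(q, db1, scheme), db1, scheme = scheme)
    h2 <- collect_targets(rank_neighbors(q, db2, scheme), db2, scheme = scheme)
    expect_equal(h1$target_id, h2$target_id)
    expect_equal(h1$nn_compound_id, h2$nn_compound_id)
  }
})

test_that("consensus merging sorts by votes, then p-sum, then best p", {
  mk <- function(scheme, targets, p) {
    data.frame(rank = seq_along(targets), target_id = targets,
               target_name = targets, scheme = scheme,
               nn_distance = 1, nn_compound_id = "c", p = p,
               identical_flag = FALSE, high_confidence = FALSE,
               stringsAsFactors = FALSE)
  }
  hits <- list(
    A = mk("A", c("t1", "t2", "t3"), c(0.5, 0.001, 0.5)),
    B = mk("B", c("t1", "t2"), c(0.5, 0.5)),
    C = mk("C", c("t1", "t4"), c(0.5, 1e-6)))
  rep <- merge_consensus(hits)
  ## t1 has 3 votes, beats t2 (2 votes) despite worse p values
  expect_equal(rep$consensus$target_id[1:2], c("t1", "t2"))
  expect_equal(rep$consensus$votes[1:2], c(3L, 2L))
  ## among single-vote targets, smaller p-sum first
  singles <- rep$consensus[rep$consensus$votes == 1, ]
  expect_equal(singles$target_id, c("t4", "t3"))
  ## combined view drops single-scheme targets
  expect_setequal(rep$combined$target_id, c("t1", "t2"))
  ## min_votes filters the consensus list itself
  expect_setequal(merge_consensus(hits, min_votes = 2)$consensus$target_id,
                  c("t1", "t2"))
  ## ranking is a total order
  expect_equal(rep$consensus$rank, seq_len(nrow(rep$consensus)))
  ## missing p-values count as 1.0 in the sum
  hna <- list(A = mk("A", "t1", NA_real_), B = mk("B", "t1", 0.2))
  expect_equal(merge_consensus(hna)$consensus$p_sum, 1.2)
})

test_that("prediction is deterministic end to end", {
  fit <- fit1(); w <- world1()
  r1 <- predict(fit, w$queries$smiles[2], ids = "q")
  r2 <- predict(fit, w$queries$smiles[2], ids = "q")
  expect_identical(r1, r2)
  expect_equal(length(r1$per_scheme), 10)
  expect_true(all(vapply(r1$per_scheme, nrow, 0L) <= 20))
})

test_that("planted analogs recover their true target in the combined list", {
  fit <- fit1(); w <- world1()
  reps <- predict(fit, w$queries$smiles, ids = w$queries$query_id)
  for (i in seq_along(reps)) {
    expect_true(w$queries$target_id[i] %in% reps[[i]]$combined$target_id,
                info = w$queries$query_id[i])
    expect_true(topk_success(reps[[i]], w$queries$target_id[i], k = 5))
  }
  ## the planted signal is strong: most queries rank their target first
  rank1 <- vapply(seq_along(reps), function(i)
    reps[[i]]$consensus$target_id[1] == w$queries$target_id[i], TRUE)
  expect_gte(mean(rank1), 0.8)
})

test_that("prediction without calibration warns and yields p-free hits", {
  fit <- fit1()
  expect_warning(
    r <- predict_targets(world1()$queries$smiles[1], fit$db, calib = NULL,
                         st = fit$scaling, ids = "q"),
    "no p-values")
  expect_true(all(is.na(r$per_scheme$APfp$p)))
  expect_error(rank_neighbors(compute_profile(panel_mols()$aspirin),
                              fit$db, "Ffp1", st = NULL),
               class = "ppb_validation_error")
})
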