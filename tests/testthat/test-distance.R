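test_that("city-block distance matches its definition and rejects mismatches", {
  expect_equal(cbd(c(0, 0, 0), c(1, 2, 4)), 7)
  expect_equal(cbd(1:5, 1:5), 0)
  a <- compute_apfp(panel_mols()$hexane)
  x <- compute_xfp(panel_mols()$hexane)
  expect_error(cbd(a, x), class = "ppb_validation_error")
  expect_error(cbd(1:3, 1:4), class = "ppb_validation_error")
})

test_that("city-block distance satisfies the metric axioms", {
  set.seed(42)
  n <- 1e4; k <- 16
  A <- matrix(sample(0:30, n * k, TRUE), n)
  B <- matrix(sample(0:30, n * k, TRUE), n)
  C <- matrix(sample(0:30, n * k, TRUE), n)
  dab <- rowSums(abs(A - B)); dba <- rowSums(abs(B - A))
  dac <- rowSums(abs(A - C)); dcb <- rowSums(abs(C - B))
  expect_identical(dab, dba)                       # symmetry
  expect_true(all(dab >= 0))
  expect_true(all(rowSums(abs(A - A)) == 0))       # identity
  expect_true(all(dab <= dac + dcb))               # triangle inequality
  ## spot-check the vectorized oracle against cbd() itself
  for (i in sample(n, 25))
    expect_equal(cbd(A[i, ], B[i, ]), dab[i])
})

test_that("distance mode picks the most frequent value, ties to the smaller", {
  expect_equal(distance_mode(c(3, 3, 5)), 3)
  expect_equal(distance_mode(c(2, 2, 4, 4)), 2)
  expect_error(distance_mode(numeric(0)), class = "ppb_validation_error")
  ## planted unique mode in a large sample
  set.seed(7)
  samp <- c(rpois(1e5, 40), rep(17, 12000))
  expect_equal(distance_mode(samp), 17)
})

test_that("scale factors are anchored to the pharmacophore fingerprint mode", {
  ## planted distance samples with known modes: Xfp 40, MQN 10
  d <- list(Xfp = c(rep(40, 50), 1:30), MQN = c(rep(10, 50), 1:30),
            APfp = c(rep(20, 50), 1:15))
  st <- scaling_from_distances(d)
  expect_equal(st$scale_factor[st$scheme == "Xfp"], 1)
  expect_equal(st$scale_factor[st$scheme == "MQN"], 4)
  expect_equal(st$scale_factor[st$scheme == "APfp"], 2)
  expect_error(scaling_from_distances(list(Xfp = rep(0, 10))),
               class = "ppb_degenerate_calibration")
  expect_error(scaling_from_distances(list(MQN = rep(3, 10))),
               class = "ppb_validation_error")    # reference scheme missing
})

test_that("scaling calibration is seeded, deterministic and anchored", {
  pm <- fit1()$db$profiles
  s1 <- calibrate_scaling(pm, n_pairs = 5000, seed = 11)
  s2 <- calibrate_scaling(pm, n_pairs = 5000, seed = 11)
  expect_equal(s1, s2)
  expect_equal(s1$scale_factor[s1$scheme == "Xfp"], 1)
  expect_true(all(s1$scale_factor > 0))
  ## an all-identical molecule set has zero modal distance
  same <- standardize_smiles(rep("c1ccccc1", 3), ids = c("a", "b", "c"),
                             ionize = FALSE)
  expect_error(calibrate_scaling(same, n_pairs = 100, seed = 1),
               class = "ppb_degenerate_calibration")
})

test_that("after scaling, every scheme's modal distance aligns with the reference", {
  pm <- fit1()$db$profiles
  st <- calibrate_scaling(pm, n_pairs = 5000, seed = 11)
  set.seed(11)
  n <- nrow(pm$Xfp)
  i <- sample.int(n, 5000, replace = TRUE)
  j <- sample.int(n - 1, 5000, replace = TRUE); j <- ifelse(j >= i, j + 1, j)
  mode_x <- st$mode_distance[st$scheme == "Xfp"]
  for (s in ppb_base_schemes()) {
    f <- st$scale_factor[st$scheme == s]
    d <- rowSums(abs(pm[[s]][i, ] - pm[[s]][j, ]))
    expect_lte(abs(distance_mode(f * d) - mode_x), max(1, f), label = s)
  }
})

test_that("fused distance equals the scaled concatenation view", {
  p <- panel_mols()
  pa <- compute_profile(p$aspirin); pb <- compute_profile(p$caffeine)
  ## planted samples giving a spread of positive factors
  st <- scaling_from_distances(list(
    Xfp = rep(1, 5), MQN = c(rep(2, 5), 1), APfp = c(rep(5, 5), 1),
    SMIfp = c(rep(4, 5), 1), Sfp = c(rep(3, 5), 1), ECfp4 = c(rep(7, 5), 1)))
  for (ffp in ppb_fused_schemes()) {
    comps <- ffp_components(ffp)
    weighted <- fused_distance(pa, pb, ffp, st)
    fvec_a <- unlist(lapply(comps, function(s)
      st$scale_factor[st$scheme == s] * as.numeric(pa[[s]])))
    fvec_b <- unlist(lapply(comps, function(s)
      st$scale_factor[st$scheme == s] * as.numeric(pb[[s]])))
    expect_equal(weighted, sum(abs(fvec_a - fvec_b)), tolerance = 1e-9)
    expect_equal(fused_distance(pa, pa, ffp, st), 0)
  }
  ## unit factors reduce fusion to a plain sum of component distances
  unit <- scaling_from_distances(lapply(
    structure(ppb_base_schemes(), names = ppb_base_schemes()),
    function(s) rep(1, 5)))
  expect_equal(fused_distance(pa, pb, "Ffp1", unit),
               cbd(pa$Xfp, pb$Xfp) + cbd(pa$SMIfp, pb$SMIfp) +
                 cbd(pa$Sfp, pb$Sfp))
  expect_error(fused_distance(pa, pb, "Ffp9", unit),
               class = "ppb_validation_error")
})

test_that("fused fingerprint definitions are the four fixed winners", {
  expect_identical(ffp_components("Ffp1"), c("Xfp", "SMIfp", "Sfp"))
  expect_identical(ffp_components("Ffp2"), c("Xfp", "MQN", "SMIfp"))
  expect_identical(ffp_components("Ffp3"), c("Xfp", "SMIfp", "Sfp", "ECfp4"))
  expect_identical(ffp_components("Ffp4"),
                   c("Xfp", "MQN", "SMIfp", "Sfp", "ECfp4"))
})

test_that("scaling tables survive a JSON round-trip", {
  st <- calibrate_scaling(fit1()$db$profiles, n_pairs = 2000, seed = 5)
  path <- tempfile(fileext = ".json")
  save_scaling(st, path)
  st2 <- load_scaling(path)
  expect_equal(st$scheme, st2$scheme)
  expect_equal(st$scale_factor, st2$scale_factor)
  expect_equal(attr(st, "sample_size"), attr(st2, "sample_size"))
})
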