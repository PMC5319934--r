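test_that("recovery metrics implement the fraction and hit-rate formulas", {
  rep <- fake_report(c("A", "C", "D"))
  m <- evaluate_recovery(rep, known = c("A", "B"))
  cons <- m[m$list == "consensus" & m$stratum == "all", ]
  expect_equal(cons$fraction_known_found, 0.5)      # 1 of 2 known found
  expect_equal(cons$hit_rate, 1 / 3)                # 1 of 3 predicted known
  expect_equal(cons$n_predicted, 3)

  sup <- evaluate_recovery(fake_report(c("A", "B", "X")), known = c("A", "B"))
  expect_equal(sup[sup$list == "consensus" & sup$stratum == "all",
                   "fraction_known_found"], 1)

  none <- evaluate_recovery(fake_report(character(0)), known = "A")
  row <- none[none$list == "consensus" & none$stratum == "all", ]
  expect_equal(row$fraction_known_found, 0)
  expect_equal(row$hit_rate, 0)

  expect_error(evaluate_recovery(rep, character(0)),
               class = "ppb_validation_error")
})

test_that("p-stratified metrics partition each list at 0.01", {
  rep <- fake_report(c("A", "B", "C"), best_p = c(0.001, 0.5, 0.009))
  m <- evaluate_recovery(rep, known = c("A", "B"))
  hi <- m[m$list == "consensus" & m$stratum == "p<=0.01", ]
  lo <- m[m$list == "consensus" & m$stratum == "p>0.01", ]
  expect_equal(hi$n_predicted, 2)                   # A and C
  expect_equal(hi$n_found, 1)                       # A
  expect_equal(lo$n_predicted, 1)                   # B
  expect_equal(lo$n_found, 1)
})

test_that("top-k success inspects exactly the first k consensus targets", {
  rep <- fake_report(c("x1", "x2", "x3", "x4", "K", "x6"))
  expect_true(topk_success(rep, "K", k = 5))        # rank 5 counts
  rep2 <- fake_report(c("x1", "x2", "x3", "x4", "x5", "K"))
  expect_false(topk_success(rep2, "K", k = 5))      # rank 6 does not
  expect_true(topk_success(rep2, "K", k = 100))     # k beyond list length
})

test_that("overlap statistics are row-normalized and uniqueness complements them", {
  same <- list(A = c("t1", "t2"), B = c("t1", "t2"))
  os <- overlap_stats(same)
  expect_true(all(os$overlap == 1))
  expect_true(all(os$unique_fraction == 0))

  disj <- list(A = c("t1", "t2"), B = c("t3", "t4"))
  od <- overlap_stats(disj)
  expect_equal(unname(od$overlap["A", "B"]), 0)
  expect_true(all(od$unique_fraction == 1))

  ## row normalization makes the matrix asymmetric
  asym <- list(A = c("t1", "t2", "t3", "t4"), B = c("t1"))
  oa <- overlap_stats(asym)
  expect_equal(unname(oa$overlap["A", "B"]), 0.25)
  expect_equal(unname(oa$overlap["B", "A"]), 1)

  expect_warning(oe <- overlap_stats(list(A = character(0), B = "t1")),
                 "empty")
  expect_equal(unname(oe$overlap["A", "B"]), 0)
  expect_error(overlap_stats(list(A = "t1")), class = "ppb_validation_error")
})

test_that("ROC AUC matches explicit curve integration and behaves at the extremes", {
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE)), 1)
  ## interleaved actives/decoys: 1 of 4 active-decoy pairs correctly ordered
  expect_equal(roc_auc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE)), 0.25)
  ## ties get the midrank correction
  expect_equal(roc_auc(c(1, 1), c(TRUE, FALSE)), 0.5)

  ## oracle: trapezoidal integration of the empirical ROC curve
  set.seed(8)
  sc <- c(rnorm(40, 1), rnorm(60, 0))
  lab <- rep(c(TRUE, FALSE), c(40, 60))
  ths <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
  tpr <- vapply(ths, function(t) mean(sc[lab] >= t), 0)
  fpr <- vapply(ths, function(t) mean(sc[!lab] >= t), 0)
  auc_int <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  expect_equal(roc_auc(sc, lab), auc_int, tolerance = 1e-12)

  ## random labels concentrate around 0.5
  set.seed(9)
  expect_equal(roc_auc(rnorm(2e4), sample(c(TRUE, FALSE), 2e4, TRUE)), 0.5,
               tolerance = 0.02)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "ppb_validation_error")
})

test_that("enrichment factor is recall over the screened fraction", {
  ## top 1% all active, 50% actives overall -> EF = 2
  lab <- rep(c(TRUE, FALSE), each = 100)
  sc <- c(rep(10, 2), rep(0, 98), rep(-1, 100))     # 2 actives lead the list
  lab2 <- c(rep(TRUE, 2), rep(c(TRUE, FALSE), c(98, 100)))
  expect_equal(enrichment_factor(sc, lab2, frac = 0.01), (2 / 100) / 0.01)
  ## ceiling: every top-slot active with rare actives
  sc2 <- c(rep(1, 2), rep(0, 198))
  lab3 <- c(TRUE, TRUE, rep(FALSE, 198))
  expect_equal(enrichment_factor(sc2, lab3, frac = 0.01), 100)   # = 1/frac
  expect_lte(enrichment_factor(sc2, lab3, frac = 0.01), 1 / 0.01)
  expect_error(enrichment_factor(1:5, rep(FALSE, 5)),
               class = "ppb_validation_error")
})

test_that("metrics are invariant to input permutation", {
  set.seed(10)
  sc <- rnorm(500); lab <- sample(c(TRUE, FALSE), 500, TRUE)
  perm <- sample(500)
  expect_equal(roc_auc(sc, lab), roc_auc(sc[perm], lab[perm]))
  expect_equal(enrichment_factor(sc, lab, 0.05),
               enrichment_factor(sc[perm], lab[perm], 0.05))
})

test_that("the leave-out benchmark removes drugs and aggregates recovery", {
  fit <- fit1(); w <- world1()
  drugs <- data.frame(drug_id = w$queries$query_id[1:6],
                      smiles = w$queries$smiles[1:6],
                      stringsAsFactors = FALSE)
  drugs$known_targets <- as.list(w$queries$target_id[1:6])
  bm <- benchmark_run(fit$db, fit$calib, fit$scaling, drugs)
  expect_equal(nrow(bm$topk), 6)
  expect_true(all(bm$summary$mean_fraction_known_found >= 0 &
                    bm$summary$mean_fraction_known_found <= 1))
  comb <- bm$summary$mean_fraction_known_found[bm$summary$list == "combined"]
  singles <- bm$summary$mean_fraction_known_found[
    bm$summary$list %in% ppb_base_schemes()]
  expect_gte(comb, max(singles))        # consensus dominates on the planted world

  ## leave-out enforcement: a member drug with removal disabled raises
  member <- fit$db$members[[fit$db$targets$target_id[1]]]
  mdrug <- data.frame(drug_id = "m", smiles = member$canonical_smiles[1],
                      stringsAsFactors = FALSE)
  mdrug$known_targets <- list(fit$db$targets$target_id[1])
  expect_error(benchmark_run(fit$db, fit$calib, fit$scaling, mdrug,
                             remove_self = FALSE),
               class = "ppb_validation_error")
  ## with removal enabled the same drug runs
  bm2 <- benchmark_run(fit$db, fit$calib, fit$scaling, mdrug)
  expect_equal(nrow(bm2$per_drug[bm2$per_drug$stratum == "all", ]) > 0, TRUE)

  ## deterministic
  bm3 <- benchmark_run(fit$db, fit$calib, fit$scaling, drugs[1:2, ])
  bm4 <- benchmark_run(fit$db, fit$calib, fit$scaling, drugs[1:2, ])
  expect_identical(bm3$per_drug, bm4$per_drug)
})
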