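## Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

## small panel of hand-analyzable molecules (neutral, ionize off)
panel_mols <- function() cached("panel", {
  standardize_smiles(c(
    methane = "C", ethane = "CC", hexane = "CCCCCC", octane = "CCCCCCCC",
    ethanol = "CCO", acetic = "CC(=O)O", benzene = "c1ccccc1",
    benzene_kekule = "C1=CC=CC=C1", cyclopropane = "C1CC1",
    naphthalene = "c1ccc2ccccc2c1", acetaminophen = "CC(=O)Nc1ccc(O)cc1",
    chloroethane = "CCl", aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C"
  ), ionize = FALSE)
})

## the standard synthetic world and a predictor fitted on it
world1 <- function() cached("world1", generate_fixture(seed = 1))

fit1 <- function() cached("fit1", {
  w <- world1()
  suppressWarnings(ppb_fit(w$activities, w$background,
                           scaling_pairs = 2e4, calib_n_max = 2e4, seed = 7))
})

## an activity table of simple distinct structures for database tests
simple_actives <- function(n, target_id = "T1", prefix = "C") {
  smis <- paste0("CCCCO", strrep("C", seq_len(n) - 1))   # homologous alcohols
  data.frame(compound_id = sprintf("%s%02d", prefix, seq_len(n)),
             smiles = smis, target_id = target_id,
             target_name = target_id, target_type = "SINGLE PROTEIN",
             organism = "Homo sapiens", activity_type = "IC50",
             value = 100, unit = "nM", stringsAsFactors = FALSE)
}

## Independent brute-force re-implementation of the per-scheme search:
## all pairwise distances by explicit summation, per-target minima, re-sort.
brute_force_hits <- function(query_profile, db, scheme, st, n_targets = 20) {
  comps <- if (scheme %in% ppb_base_schemes()) scheme else ffp_components(scheme)
  w <- vapply(comps, function(s) {
    if (scheme %in% ppb_base_schemes()) 1
    else st$scale_factor[match(s, st$scheme)]
  }, 0)
  nd <- vapply(seq_len(nrow(db$compounds)), function(k) {
    tot <- 0
    for (ci in seq_along(comps)) {
      s <- comps[ci]
      a <- as.numeric(query_profile[[s]])
      b <- as.numeric(db$profiles[[s]][k, ])
      tot <- tot + w[ci] * sum(abs(a - b))
    }
    tot
  }, 0)
  rows <- list()
  for (tid in db$targets$target_id) {
    mem <- db$members[[tid]]
    kk <- match(mem$canonical_smiles, db$compounds$canonical_smiles)
    dmin <- min(nd[kk])
    cand <- kk[nd[kk] == dmin]
    nn <- cand[order(db$compounds$compound_id[cand])][1]
    rows[[tid]] <- data.frame(target_id = tid, nn_distance = dmin,
                              nn_compound_id = db$compounds$compound_id[nn],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$nn_distance, out$nn_compound_id, out$target_id), ]
  out <- utils::head(out, n_targets)
  rownames(out) <- NULL
  out
}

## minimal hand-built prediction report for metric tests
fake_report <- function(consensus_targets, votes = NULL, best_p = NULL,
                        per_scheme = list()) {
  n <- length(consensus_targets)
  votes <- votes %||% rep(2L, n)
  cons <- data.frame(target_id = consensus_targets,
                     target_name = consensus_targets,
                     votes = votes, p_sum = rep(0.5, n),
                     best_p = best_p %||% rep(0.5, n),
                     any_identical = rep(FALSE, n),
                     schemes = rep("", n), rank = seq_len(n),
                     stringsAsFactors = FALSE)
  structure(list(query_id = "fake", canonical_smiles = "C",
                 per_scheme = per_scheme, consensus = cons,
                 combined = cons[cons$votes >= 2, , drop = FALSE],
                 options = list()), class = "ppb_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
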