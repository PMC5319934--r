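## Validation machinery: target-recovery metrics for prediction reports and
## actives-vs-decoys enrichment metrics for distance-ranked screens.

#' Target-recovery metrics for one prediction report
#'
#' For each per-fingerprint hit list, the full consensus list and the
#' combined (votes >= 2) list, computes the number of predicted targets,
#' the fraction of the known targets found
#' (`|known intersect predicted| / |known|`) and the hit rate
#' (`|known intersect predicted| / |predicted|`, 0 when nothing is
#' predicted). Each list is additionally stratified at p <= 0.01 versus
#' p > 0.01 (per-scheme lists by their hit p-value, consensus lists by
#' their best p-value).
#'
#' @param report a `ppb_report`.
#' @param known non-empty character vector of known target ids.
#' @return data frame with columns `list`, `stratum`, `n_predicted`,
#'   `n_found`, `fraction_known_found`, `hit_rate`.
#' @export
evaluate_recovery <- function(report, known) {
  if (!length(known))
    stop_ppb("the known-target set must be non-empty", "ppb_validation_error")
  known <- unique(as.character(known))
  lists <- c(
    lapply(report$per_scheme, function(h)
      list(targets = h$target_id, p = ifelse(is.na(h$p), 1.0, h$p))),
    list(consensus = list(targets = report$consensus$target_id,
                          p = report$consensus$best_p),
         combined = list(targets = report$combined$target_id,
                         p = report$combined$best_p)))
  rows <- list()
  for (nm in names(lists)) {
    tg <- lists[[nm]]$targets; pp <- lists[[nm]]$p
    strata <- list(all = rep(TRUE, length(tg)),
                   `p<=0.01` = pp <= 0.01, `p>0.01` = pp > 0.01)
    for (sn in names(strata)) {
      t_s <- unique(tg[strata[[sn]]])
      found <- length(intersect(t_s, known))
      rows[[length(rows) + 1L]] <- data.frame(
        list = nm, stratum = sn, n_predicted = length(t_s), n_found = found,
        fraction_known_found = found / length(known),
        hit_rate = if (length(t_s)) found / length(t_s) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-k success of a prediction report
#'
#' TRUE iff any of the first `k` consensus-ranked targets is a known
#' target.
#' @inheritParams evaluate_recovery
#' @param k depth of the consensus list to inspect (default 5).
#' @export
topk_success <- function(report, known, k = 5) {
  top <- utils::head(report$consensus$target_id, k)
  length(intersect(top, as.character(known))) > 0
}

#' Pairwise overlap and uniqueness of per-fingerprint target sets
#'
#' `overlap[i, j] = |T_i intersect T_j| / |T_i|` (row-normalized, hence not
#' symmetric) and `unique[i] = |T_i \\ union of the others| / |T_i|`. Empty
#' sets give 0 entries with a warning.
#'
#' @param per_scheme_targets named list (>= 2 schemes) of target-id vectors.
#' @return list with `overlap` matrix and `unique_fraction` vector.
#' @export
overlap_stats <- function(per_scheme_targets) {
  if (length(per_scheme_targets) < 2)
    stop_ppb("overlap statistics need at least two schemes", "ppb_validation_error")
  sets <- lapply(per_scheme_targets, function(x) unique(as.character(x)))
  if (any(lengths(sets) == 0))
    warning("empty target set(s); their overlap and uniqueness are reported as 0",
            call. = FALSE)
  ns <- names(sets)
  ov <- matrix(0, length(sets), length(sets), dimnames = list(ns, ns))
  for (i in ns) for (j in ns)
    ov[i, j] <- if (length(sets[[i]]))
      length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]]) else 0
  uq <- vapply(ns, function(i) {
    if (!length(sets[[i]])) return(0)
    others <- unique(unlist(sets[setdiff(ns, i)]))
    length(setdiff(sets[[i]], others)) / length(sets[[i]])
  }, 0)
  list(overlap = ov, unique_fraction = uq)
}

#' ROC AUC of an actives-vs-decoys score ranking
#'
#' Rank-statistic (Mann-Whitney) formulation with midrank tie correction;
#' higher scores must indicate more likely actives (negate distances before
#' calling).
#' @param scores numeric scores.
#' @param is_active logical labels (both classes required).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, is_active) {
  is_active <- as.logical(is_active)
  nA <- sum(is_active); nB <- sum(!is_active)
  if (nA == 0 || nB == 0)
    stop_ppb("both actives and decoys are required", "ppb_validation_error")
  r <- rank(scores)
  (sum(r[is_active]) - nA * (nA + 1) / 2) / (nA * nB)
}

#' Enrichment factor at a screened fraction
#'
#' Fold-concentration of actives in the top `frac` of the score-ranked
#' list relative to random screening:
#' `(actives in top / total actives) / frac`, with the top set of size
#' `round(frac * N)` (at least 1). Score ties are broken deterministically
#' by list position.
#' @inheritParams roc_auc
#' @param frac screened fraction (default 0.01).
#' @return non-negative enrichment factor (at most `1/frac`).
#' @export
enrichment_factor <- function(scores, is_active, frac = 0.01) {
  is_active <- as.logical(is_active)
  nA <- sum(is_active)
  if (nA == 0 || all(is_active))
    stop_ppb("both actives and decoys are required", "ppb_validation_error")
  n_top <- max(1L, round(frac * length(scores)))
  top <- order(-scores, seq_along(scores))[seq_len(n_top)]
  (sum(is_active[top]) / nA) / frac
}

#' Leave-out benchmark over an annotated drug set
#'
#' Runs the full prediction pipeline for each annotated drug after removing
#' the drug's own structure from the reference database (the leave-out rule
#' is enforced: predicting a drug still present in the database raises an
#' error unless it was removed). Reports per-drug recovery metrics, their
#' unweighted means per list, and the top-k success rate.
#'
#' @param db a `ppb_refdb`.
#' @param calib a `ppb_calibration`.
#' @param st a `ppb_scaling` table.
#' @param drugs data frame with `drug_id`, `smiles` and `known_targets`
#'   (list-column, or `;`-separated string), e.g. from
#'   [known_target_annotations()].
#' @param n_targets,schemes,min_votes search options (see [predict_targets()]).
#' @param k consensus depth for the top-k success rate (default 5).
#' @param remove_self remove each drug from the database before querying
#'   (default TRUE; FALSE raises an error if the drug is present).
#' @param ionize standardization flag.
#' @param out_dir optional directory for TSV/JSON result files.
#' @return list with `per_drug` (long data frame of per-drug metrics),
#'   `summary` (mean metrics per list), `topk` (per-drug successes) and
#'   `topk_rate`.
#' @export
benchmark_run <- function(db, calib, st, drugs, n_targets = 20,
                          schemes = ppb_schemes(), min_votes = 1, k = 5,
                          remove_self = TRUE, ionize = TRUE, out_dir = NULL) {
  known_list <- drugs$known_targets
  if (is.character(known_list)) known_list <- strsplit(known_list, ";", fixed = TRUE)
  per_drug <- list(); successes <- logical(nrow(drugs))
  for (d in seq_len(nrow(drugs))) {
    mol <- standardize_smiles(drugs$smiles[d], ids = drugs$drug_id[d],
                              ionize = ionize)[[1]]
    db_d <- db
    if (mol$canonical_smiles %in% db$compounds$canonical_smiles) {
      if (!remove_self)
        stop_ppb(sprintf(
          "drug '%s' is present in the reference database and removal is disabled",
          drugs$drug_id[d]), "ppb_validation_error")
      db_d <- remove_compounds(db, mol$canonical_smiles)
    }
    rep <- predict_targets(drugs$smiles[d], db_d, calib = calib, st = st,
                           n_targets = n_targets, schemes = schemes,
                           min_votes = min_votes, ionize = ionize,
                           ids = drugs$drug_id[d])
    met <- evaluate_recovery(rep, known_list[[d]])
    met$drug_id <- drugs$drug_id[d]
    per_drug[[d]] <- met
    successes[d] <- topk_success(rep, known_list[[d]], k = k)
  }
  per_drug <- do.call(rbind, per_drug)
  all_rows <- per_drug[per_drug$stratum == "all", , drop = FALSE]
  summ <- do.call(rbind, lapply(split(all_rows, all_rows$list), function(g)
    data.frame(list = g$list[1], n_drugs = nrow(g),
               mean_n_predicted = mean(g$n_predicted),
               mean_fraction_known_found = mean(g$fraction_known_found),
               mean_hit_rate = mean(g$hit_rate), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  out <- list(per_drug = per_drug, summary = summ,
              topk = data.frame(drug_id = drugs$drug_id, success = successes,
                                stringsAsFactors = FALSE),
              topk_rate = mean(successes), k = k)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(per_drug, file.path(out_dir, "per_drug_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(out_dir, "summary_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(topk_rate = out$topk_rate, k = k,
                              summary = summ),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
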