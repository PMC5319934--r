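## The search engine: per-fingerprint nearest-neighbor ranking, first-seen
## target collection, p-value annotation, and consensus-vote merging.

#' Rank all database compounds by distance to a query
#'
#' City-block distance in the requested fingerprint space (scaled weighted
#' sum of component distances for fused schemes), ascending; ties are
#' broken by lexicographic compound id for determinism.
#'
#' @param query a `ppb_profile` (or `ppb_mol`).
#' @param db a `ppb_refdb` with profiles.
#' @param scheme one of the ten scheme names.
#' @param st scaling table (required for fused schemes).
#' @return data frame `rank`, `compound_id`, `canonical_smiles`, `distance`.
#' @export
rank_neighbors <- function(query, db, scheme, st = NULL) {
  if (inherits(query, "ppb_mol")) query <- compute_profile(query)
  if (n_compounds(db) == 0)
    stop_ppb("reference database has no compounds", "ppb_validation_error")
  comps <- if (scheme %in% ppb_base_schemes()) scheme
           else ffp_components(scheme)
  if (!scheme %in% ppb_base_schemes() && is.null(st))
    stop_ppb("fused schemes require a scaling table", "ppb_validation_error")
  d <- numeric(n_compounds(db))
  for (s in comps) {
    w <- if (scheme %in% ppb_base_schemes()) 1 else scale_factor(st, s)
    M <- db$profiles[[s]]
    q <- as.integer(query[[s]])
    d <- d + w * as.numeric(abs(M - matrix(q, nrow(M), ncol(M), byrow = TRUE)) %*%
                              rep(1, ncol(M)))
  }
  ord <- order(d, db$compounds$compound_id, method = "radix")
  data.frame(rank = seq_along(ord),
             compound_id = db$compounds$compound_id[ord],
             canonical_smiles = db$compounds$canonical_smiles[ord],
             distance = d[ord], stringsAsFactors = FALSE)
}

#' Collect the nearest targets from a neighbor ranking
#'
#' Scans the ranked neighbor list and records each target the first time
#' one of its members is encountered — that member is the target's nearest
#' neighbor to the query, so the hit distance is the minimum over the
#' group. Collection stops after `n_targets` distinct targets (default 20)
#' or when the list is exhausted. The hit p-value is computed from the
#' nearest-member distance under the target's calibrated null; hits at
#' p <= 0.01 carry a high-confidence flag, and hits at distance 0 an
#' identical-structure flag.
#'
#' @param neighbors output of [rank_neighbors()].
#' @param db a `ppb_refdb`.
#' @param n_targets maximum number of targets to collect (default 20).
#' @param calib optional `ppb_calibration` for p-values.
#' @param scheme scheme the neighbor list was ranked in.
#' @return data frame of target hits.
#' @export
collect_targets <- function(neighbors, db, n_targets = 20, calib = NULL,
                            scheme = NULL) {
  hits <- list()
  seen <- character(0)
  for (k in seq_len(nrow(neighbors))) {
    tids <- db$comp2targets[[neighbors$canonical_smiles[k]]]
    for (tid in setdiff(tids, seen)) {
      if (length(seen) >= n_targets) break
      seen <- c(seen, tid)
      dist <- neighbors$distance[k]
      entry <- if (!is.null(scheme)) calibration_entry(calib, tid, scheme)
      p <- if (is.null(entry)) NA_real_ else p_value(entry, dist)
      hits[[length(hits) + 1L]] <- data.frame(
        rank = length(seen), target_id = tid,
        target_name = db$targets$target_name[match(tid, db$targets$target_id)],
        scheme = scheme %||% NA_character_,
        nn_distance = dist, nn_compound_id = neighbors$compound_id[k],
        p = p, identical_flag = dist == 0,
        high_confidence = !is.na(p) && p <= 0.01,
        stringsAsFactors = FALSE)
    }
    if (length(seen) >= n_targets) break
  }
  if (!length(hits))
    return(data.frame(rank = integer(), target_id = character(),
                      target_name = character(), scheme = character(),
                      nn_distance = numeric(), nn_compound_id = character(),
                      p = numeric(), identical_flag = logical(),
                      high_confidence = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Merge per-fingerprint target lists into a consensus ranking
#'
#' Targets are ranked by the number of fingerprint spaces that retrieved
#' them (votes, descending), then by the sum of their p-values over the
#' voting schemes (ascending; a missing p-value contributes 1.0), then by
#' the best single p-value, then by target id. The `combined` view is the
#' consensus restricted to targets voted by at least two fingerprints.
#'
#' @param per_scheme_hits named list (scheme -> hit data frame from
#'   [collect_targets()]).
#' @param min_votes drop consensus targets with fewer votes (default 1 =
#'   keep all).
#' @return a `ppb_report` with elements `per_scheme`, `consensus`,
#'   `combined`.
#' @export
merge_consensus <- function(per_scheme_hits, min_votes = 1) {
  if (!length(per_scheme_hits))
    stop_ppb("at least one per-scheme hit list is required", "ppb_validation_error")
  all_hits <- do.call(rbind, c(per_scheme_hits, list(stringsAsFactors = FALSE)))
  cons <- if (is.null(all_hits) || nrow(all_hits) == 0) {
    data.frame(target_id = character(), target_name = character(),
               votes = integer(), p_sum = numeric(), best_p = numeric(),
               any_identical = logical(), schemes = character(),
               rank = integer(), stringsAsFactors = FALSE)
  } else {
    p_eff <- ifelse(is.na(all_hits$p), 1.0, all_hits$p)
    agg <- split(seq_len(nrow(all_hits)), all_hits$target_id)
    rows <- lapply(names(agg), function(tid) {
      ii <- agg[[tid]]
      data.frame(target_id = tid, target_name = all_hits$target_name[ii[1]],
                 votes = length(unique(all_hits$scheme[ii])),
                 p_sum = sum(p_eff[ii]), best_p = min(p_eff[ii]),
                 any_identical = any(all_hits$identical_flag[ii]),
                 schemes = paste(sort(unique(all_hits$scheme[ii])),
                                 collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    ord <- order(-out$votes, out$p_sum, out$best_p, out$target_id,
                 method = "radix")
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  }
  structure(list(query_id = NA_character_, canonical_smiles = NA_character_,
                 per_scheme = per_scheme_hits,
                 consensus = cons[cons$votes >= min_votes, , drop = FALSE],
                 combined = cons[cons$votes >= 2, , drop = FALSE],
                 options = list(min_votes = min_votes)),
            class = "ppb_report")
}

#' @export
print.ppb_report <- function(x, n = 10, ...) {
  cat(sprintf("<target prediction> query %s (%s)\n  %d fingerprint spaces, %d consensus targets (%d voted by >= 2)\n",
              x$query_id, x$canonical_smiles, length(x$per_scheme),
              nrow(x$consensus), nrow(x$combined)))
  if (nrow(x$consensus)) {
    cat("  top consensus targets (votes desc, p-sum asc):\n")
    print(utils::head(x$consensus[c("rank", "target_id", "target_name",
                                    "votes", "p_sum", "best_p",
                                    "any_identical")], n),
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Predict the targets of a query molecule
#'
#' The full search pipeline: standardize the query, compute its six base
#' fingerprints, rank all database compounds in each requested fingerprint
#' space (six base + four fused by default), collect up to `n_targets`
#' nearest targets per space with null p-values, and merge the lists into
#' a consensus-vote ranking. Deterministic: two runs give identical
#' reports.
#'
#' @param smiles query SMILES (one or more).
#' @param db a `ppb_refdb`.
#' @param calib optional `ppb_calibration`; without it hits carry no
#'   p-values (a warning is emitted).
#' @param st scaling table; required when fused schemes are searched.
#' @param n_targets targets collected per fingerprint space (default 20).
#' @param schemes fingerprint spaces to search (default all ten).
#' @param min_votes consensus vote filter passed to [merge_consensus()].
#' @param ionize standardization flag (default TRUE, as for the database).
#' @param ids optional query identifiers.
#' @return a `ppb_report` for a single query, else a named list of reports.
#' @export
predict_targets <- function(smiles, db, calib = NULL, st = NULL,
                            n_targets = 20, schemes = ppb_schemes(),
                            min_votes = 1, ionize = TRUE, ids = NULL) {
  mols <- standardize_smiles(smiles, ids = ids, ionize = ionize)
  if (is.null(calib))
    warning("no calibration set supplied; hits will carry no p-values",
            call. = FALSE)
  reports <- lapply(mols, function(mol) {
    prof <- compute_profile(mol)
    hits <- lapply(schemes, function(s) {
      nb <- rank_neighbors(prof, db, s, st = st)
      collect_targets(nb, db, n_targets = n_targets, calib = calib, scheme = s)
    })
    names(hits) <- schemes
    rep <- merge_consensus(hits, min_votes = min_votes)
    rep$query_id <- mol$id
    rep$canonical_smiles <- mol$canonical_smiles
    rep$options <- list(n_targets = n_targets, schemes = schemes,
                        min_votes = min_votes, ionize = ionize)
    rep
  })
  if (length(reports) == 1) reports[[1]] else reports
}

#' Serialize a prediction report to JSON
#' @param report a `ppb_report`.
#' @param path output file.
#' @export
save_report <- function(report, path) {
  jsonlite::write_json(
    list(query_id = report$query_id,
         canonical_smiles = report$canonical_smiles,
         options = report$options, per_scheme = report$per_scheme,
         consensus = report$consensus, combined = report$combined),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
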