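## Reference database: target groups of deduplicated active compounds built
## from a ChEMBL-style activity table.
##
## Retention rules: a record is bioactive if its potency-type value
## (IC50, EC50, GI50, Ki, KD or Potency) is <= 10 uM after unit conversion,
## or its percent inhibition is strictly > 50%. Within each target,
## structures are deduplicated by canonical non-stereo SMILES, and only
## targets with at least `min_size` (default 10) distinct actives are kept.

.activity_fields <- c("compound_id", "smiles", "target_id", "target_name",
                      "target_type", "organism", "activity_type", "value",
                      "unit")
.mandatory_fields <- c("compound_id", "smiles", "target_id", "activity_type",
                       "value", "unit")
.potency_types <- c("IC50", "EC50", "GI50", "Ki", "KD", "Potency")

#' Load a ChEMBL-style activity table
#'
#' Reads a TSV/CSV activity table into normalized activity records. Column
#' names can be remapped through `dialect`, a named character vector from
#' standard field names (`compound_id`, `smiles`, `target_id`,
#' `target_name`, `target_type`, `organism`, `activity_type`, `value`,
#' `unit`) to the file's column names. Rows with an unparseable value or a
#' missing SMILES are dropped and counted in a message.
#'
#' @param path path to the table (`.csv` is read comma-separated, anything
#'   else tab-separated).
#' @param dialect optional named character vector remapping column names.
#' @return data frame of activity records with normalized `activity_type`
#'   (`IC50`, `EC50`, `GI50`, `Ki`, `KD`, `Potency`, `PercentInhibition`
#'   or `other`).
#' @export
load_activity_table <- function(path, dialect = NULL) {
  if (!file.exists(path))
    stop_ppb(sprintf("activity table not found: %s", path), "ppb_validation_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (std in names(dialect)) {
    if (!dialect[[std]] %in% names(df))
      stop_ppb(sprintf("dialect maps '%s' to missing column '%s'",
                       std, dialect[[std]]), "ppb_schema_error")
    names(df)[names(df) == dialect[[std]]] <- std
  }
  missing <- setdiff(.mandatory_fields, names(df))
  if (length(missing))
    stop_ppb(sprintf("activity table lacks mandatory column(s): %s",
                     paste(missing, collapse = ", ")), "ppb_schema_error")
  for (opt in setdiff(.activity_fields, names(df)))
    df[[opt]] <- if (opt == "target_name") df$target_id else ""
  df <- df[.activity_fields]

  n0 <- nrow(df)
  df$value <- suppressWarnings(as.numeric(df$value))
  df$smiles <- as.character(df$smiles)
  keep <- is.finite(df$value) & !is.na(df$smiles) & nzchar(trimws(df$smiles))
  if (any(!keep))
    message(sprintf("dropped %d of %d rows (unparseable value or missing SMILES)",
                    sum(!keep), n0))
  df <- df[keep, , drop = FALSE]
  df$activity_type <- normalize_activity_type(df$activity_type)
  rownames(df) <- NULL
  df
}

normalize_activity_type <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  out <- rep("other", length(x))
  out[key == "IC50"] <- "IC50"
  out[key == "EC50"] <- "EC50"
  out[key == "GI50"] <- "GI50"
  out[key == "KI"] <- "Ki"
  out[key == "KD"] <- "KD"
  out[key == "POTENCY"] <- "Potency"
  out[key %in% c("PERCENTINHIBITION", "INHIBITION", "PCTINHIBITION")] <-
    "PercentInhibition"
  out
}

## molar units convertible to micromolar
.unit_to_uM <- c(pM = 1e-6, nM = 1e-3, uM = 1, mM = 1e3, M = 1e6)

unit_in_uM <- function(value, unit) {
  u <- gsub("µ|μ", "u", trimws(unit))    # micro sign -> 'u'
  key <- match(u, names(.unit_to_uM))
  value * .unit_to_uM[key]
}

#' Apply the bioactivity retention filter
#'
#' Keeps a record iff its activity type is a potency measurement (IC50,
#' EC50, GI50, Ki, KD, Potency) with value at most 10 uM after unit
#' conversion (pM/nM/uM/mM/M accepted), or a percent inhibition strictly
#' greater than 50. Records with unconvertible units are dropped with a
#' warning. Idempotent.
#'
#' @param records activity records from [load_activity_table()].
#' @param potency_cutoff_uM potency threshold in micromolar (default 10).
#' @param inhibition_cutoff percent-inhibition threshold (default 50, strict).
#' @return the retained records.
#' @export
filter_activities <- function(records, potency_cutoff_uM = 10,
                              inhibition_cutoff = 50) {
  pot <- records$activity_type %in% .potency_types
  val_uM <- unit_in_uM(records$value, records$unit)
  bad_unit <- pot & is.na(val_uM)
  if (any(bad_unit))
    warning(sprintf("dropped %d record(s) with unconvertible unit(s): %s",
                    sum(bad_unit),
                    paste(unique(records$unit[bad_unit]), collapse = ", ")),
            call. = FALSE)
  keep_pot <- pot & !is.na(val_uM) & val_uM <= potency_cutoff_uM
  inh <- records$activity_type == "PercentInhibition" &
    trimws(records$unit) %in% c("%", "")
  keep_inh <- inh & records$value > inhibition_cutoff
  out <- records[keep_pot | keep_inh, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the reference database of target groups
#'
#' Standardizes every structure, deduplicates within each target by
#' canonical SMILES, drops targets with fewer than `min_size` distinct
#' actives, and precomputes the six base fingerprints for every surviving
#' compound. A compound active on several targets appears in each group but
#' carries a single profile.
#'
#' @param records activity-filtered records (see [filter_activities()]).
#' @param min_size minimum number of distinct actives per target (default 10).
#' @param ionize apply pH 7.4 protonation during standardization.
#' @param source label stored in the database provenance.
#' @return a `ppb_refdb` object.
#' @export
build_target_groups <- function(records, min_size = 10, ionize = TRUE,
                                source = "activity-table") {
  usmi <- unique(records$smiles)
  canon <- rep(NA_character_, length(usmi))
  ok <- logical(length(usmi))
  mols <- tryCatch({
    m <- standardize_smiles(usmi, ids = sprintf("U%d", seq_along(usmi)),
                            ionize = ionize)
    ok[] <- TRUE
    m
  }, ppb_parse_error = function(e) NULL)
  if (is.null(mols)) {                     # salvage parseable structures
    mols_list <- list()
    for (k in seq_along(usmi)) {
      m <- tryCatch(standardize_smiles(usmi[k], ids = sprintf("U%d", k),
                                       ionize = ionize)[[1]],
                    ppb_parse_error = function(e) NULL)
      if (!is.null(m)) { ok[k] <- TRUE; mols_list[[length(mols_list) + 1L]] <- m }
    }
    if (sum(!ok))
      warning(sprintf("dropped %d structure(s) that failed to parse", sum(!ok)),
              call. = FALSE)
    mols <- structure(mols_list, class = "ppb_molset")
  }
  canon[ok] <- vapply(mols, function(m) m$canonical_smiles, "")
  records$canonical_smiles <- canon[match(records$smiles, usmi)]
  records <- records[!is.na(records$canonical_smiles), , drop = FALSE]

  ## per-target deduplication and size filter
  split_idx <- split(seq_len(nrow(records)), records$target_id)
  groups <- list(); meta <- list()
  for (tid in names(split_idx)) {
    rows <- records[split_idx[[tid]], , drop = FALSE]
    rows <- rows[!duplicated(rows$canonical_smiles), , drop = FALSE]
    if (nrow(rows) < min_size) next
    groups[[tid]] <- data.frame(compound_id = rows$compound_id,
                                canonical_smiles = rows$canonical_smiles,
                                stringsAsFactors = FALSE)
    meta[[tid]] <- data.frame(target_id = tid,
                              target_name = rows$target_name[1],
                              target_type = rows$target_type[1],
                              organism = rows$organism[1],
                              n_members = nrow(rows),
                              stringsAsFactors = FALSE)
  }
  if (!length(groups))
    warning("no target group survived the size filter; database is empty",
            call. = FALSE)
  targets <- if (length(meta)) do.call(rbind, meta) else
    data.frame(target_id = character(), target_name = character(),
               target_type = character(), organism = character(),
               n_members = integer(), stringsAsFactors = FALSE)
  rownames(targets) <- NULL

  member_smiles <- unique(unlist(lapply(groups, `[[`, "canonical_smiles")))
  prof <- NULL; compounds <- NULL
  if (length(member_smiles)) {
    keep_mols <- mols[match(member_smiles,
                            vapply(mols, function(m) m$canonical_smiles, ""))]
    prof <- profile_matrices(keep_mols)
    first_id <- do.call(rbind, groups)
    first_id <- first_id[!duplicated(first_id$canonical_smiles), ]
    compounds <- data.frame(
      canonical_smiles = member_smiles,
      compound_id = first_id$compound_id[match(member_smiles,
                                               first_id$canonical_smiles)],
      stringsAsFactors = FALSE)
  }
  new_refdb(targets, groups, compounds, prof,
            provenance = list(source = source, min_size = min_size,
                              ionize = ionize,
                              built = format(Sys.time(), tz = "UTC"),
                              format_version = "1"))
}

new_refdb <- function(targets, members, compounds, profiles, provenance) {
  c2t <- list()
  for (tid in names(members))
    for (cs in members[[tid]]$canonical_smiles)
      c2t[[cs]] <- c(c2t[[cs]], tid)
  structure(list(targets = targets, members = members, compounds = compounds,
                 profiles = profiles, comp2targets = c2t,
                 provenance = provenance),
            class = "ppb_refdb")
}

#' @export
print.ppb_refdb <- function(x, ...) {
  cat(sprintf(
    "<reference database> %d target groups, %d unique compounds (source: %s)\n",
    nrow(x$targets), if (is.null(x$compounds)) 0L else nrow(x$compounds),
    x$provenance$source))
  if (nrow(x$targets)) print(utils::head(x$targets, 8), row.names = FALSE)
  invisible(x)
}

n_compounds <- function(db) if (is.null(db$compounds)) 0L else nrow(db$compounds)

#' Save / load a reference database
#'
#' The database is written as a directory: `groups.json` (targets, members,
#' provenance), `profiles.tsv` (one row per compound, fingerprint blocks
#' with scheme headers) and `checksums.json` (MD5 sums plus format
#' version). `load_database()` verifies the checksums and format version
#' and reconstructs the object losslessly.
#'
#' @param db a `ppb_refdb`.
#' @param path directory to create/read.
#' @return `save_database` returns `path` invisibly; `load_database`
#'   returns a `ppb_refdb`.
#' @export
save_database <- function(db, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  gj <- file.path(path, "groups.json")
  pt <- file.path(path, "profiles.tsv")
  jsonlite::write_json(
    list(format_version = db$provenance$format_version %||% "1",
         provenance = db$provenance, targets = db$targets,
         members = db$members),
    gj, auto_unbox = TRUE, digits = NA)
  prof_df <- data.frame(canonical_smiles = db$compounds$canonical_smiles,
                        compound_id = db$compounds$compound_id,
                        stringsAsFactors = FALSE, check.names = FALSE)
  for (s in ppb_base_schemes()) {
    m <- db$profiles[[s]]
    colnames(m) <- sprintf("%s.%d", s, seq_len(ncol(m)))
    prof_df <- cbind(prof_df, as.data.frame(m, check.names = FALSE),
                     stringsAsFactors = FALSE)
  }
  utils::write.table(prof_df, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  md5 <- unname(tools::md5sum(c(gj, pt)))
  jsonlite::write_json(
    list(format_version = db$provenance$format_version %||% "1",
         md5 = list(groups.json = md5[1], profiles.tsv = md5[2])),
    file.path(path, "checksums.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  gj <- file.path(path, "groups.json")
  pt <- file.path(path, "profiles.tsv")
  ck <- file.path(path, "checksums.json")
  for (f in c(gj, pt, ck)) if (!file.exists(f))
    stop_ppb(sprintf("database file missing: %s", f), "ppb_integrity_error")
  sums <- jsonlite::read_json(ck, simplifyVector = TRUE)
  if (!identical(as.character(sums$format_version), "1"))
    stop_ppb(sprintf("database format version mismatch: file has '%s', reader supports '1'",
                     sums$format_version), "ppb_version_error")
  actual <- unname(tools::md5sum(c(gj, pt)))
  expected <- c(sums$md5[["groups.json"]], sums$md5[["profiles.tsv"]])
  if (!identical(actual, as.character(expected)))
    stop_ppb("database integrity check failed (checksum mismatch; truncated or modified files)",
             "ppb_integrity_error")

  g <- jsonlite::read_json(gj, simplifyVector = TRUE)
  targets <- as.data.frame(g$targets, stringsAsFactors = FALSE)
  targets$n_members <- as.integer(targets$n_members)
  members <- lapply(g$members, function(m)
    data.frame(compound_id = as.character(m$compound_id),
               canonical_smiles = as.character(m$canonical_smiles),
               stringsAsFactors = FALSE))

  pd <- utils::read.table(pt, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  compounds <- data.frame(canonical_smiles = pd$canonical_smiles,
                          compound_id = as.character(pd$compound_id),
                          stringsAsFactors = FALSE)
  profiles <- lapply(ppb_base_schemes(), function(s) {
    cols <- grep(sprintf("^%s\\.", s), names(pd))
    m <- as.matrix(pd[cols])
    dimnames(m) <- list(pd$canonical_smiles, NULL)
    storage.mode(m) <- "integer"
    m
  })
  names(profiles) <- ppb_base_schemes()
  prov <- g$provenance
  prov$min_size <- as.integer(prov$min_size)
  new_refdb(targets, members, compounds,
            structure(profiles, class = "ppb_profilemat"), prov)
}

#' Remove compounds from a database
#'
#' Drops the given canonical structures from every target group (used for
#' leave-out benchmarking); groups left empty are removed.
#' @param db a `ppb_refdb`.
#' @param canonical_smiles structures to remove.
#' @export
remove_compounds <- function(db, canonical_smiles) {
  members <- lapply(db$members, function(m)
    m[!m$canonical_smiles %in% canonical_smiles, , drop = FALSE])
  members <- members[vapply(members, nrow, 0L) > 0]
  targets <- db$targets[db$targets$target_id %in% names(members), , drop = FALSE]
  targets$n_members <- vapply(members[targets$target_id], nrow, 0L)
  keep <- !db$compounds$canonical_smiles %in% canonical_smiles
  compounds <- db$compounds[keep, , drop = FALSE]
  profiles <- lapply(db$profiles, function(m) m[keep, , drop = FALSE])
  new_refdb(targets, members, compounds,
            structure(profiles, class = "ppb_profilemat"), db$provenance)
}

#' Annotate drugs with known targets by exact structure match
#'
#' Matches each drug's canonical non-stereo SMILES against the database's
#' group members and returns, per drug, the targets on which it is an
#' annotated active. Drugs with no known target, or with more than
#' `max_targets` known targets, are excluded (promiscuity cap).
#'
#' @param smiles drug SMILES.
#' @param ids drug identifiers.
#' @param db a `ppb_refdb`.
#' @param max_targets promiscuity cap (default 20).
#' @param ionize match under the same standardization as the database.
#' @return data frame with `drug_id`, `smiles`, `canonical_smiles` and a
#'   list-column `known_targets`.
#' @export
known_target_annotations <- function(smiles, ids = NULL, db, max_targets = 20,
                                     ionize = TRUE) {
  mols <- standardize_smiles(smiles, ids = ids, ionize = ionize)
  canon <- vapply(mols, function(m) m$canonical_smiles, "")
  known <- lapply(canon, function(cs) db$comp2targets[[cs]] %||% character(0))
  n <- lengths(known)
  keep <- n >= 1 & n <= max_targets
  out <- data.frame(drug_id = names(mols), smiles = unname(smiles),
                    canonical_smiles = unname(canon),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$known_targets <- unname(known[keep])
  rownames(out) <- NULL
  out
}
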