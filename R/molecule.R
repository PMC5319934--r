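## Structure standardization and molecular perception.
##
## All chemistry perception goes through OpenBabel (via ChemmineOB/ChemmineR):
## canonical SMILES, optional rule-based protonation at pH 7.4, SDF atom/bond
## blocks (with explicit hydrogens for H counting), aromatic ring perception,
## and the two hashed fingerprints (FP2 substructure paths, ECFP4 circular).

#' Standardize SMILES into molecule objects
#'
#' Parses one or more SMILES strings, strips stereochemistry, optionally
#' applies rule-based protonation at pH 7.4 (carboxylic/sulfonic/phosphonic
#' acids and tetrazoles deprotonated, aliphatic amines/amidines/guanidines
#' protonated, per the OpenBabel pH transform table), and produces the
#' toolkit-canonical non-stereo SMILES together with a parsed heavy-atom
#' graph used by all fingerprint computations.
#'
#' Stereo descriptors (`@`, `/`, `\`) are removed textually before
#' canonicalization, so canonicalization is idempotent: re-standardizing a
#' canonical SMILES returns it unchanged.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional character vector of molecule identifiers; defaults to
#'   `names(smiles)` or `M1..Mn`.
#' @param ionize logical; apply the pH 7.4 protonation rules (default TRUE).
#' @param quiet logical; suppress the standardization log message.
#' @return A `ppb_molset`: a list of `ppb_mol` objects, each carrying
#'   `id`, `source_smiles`, `canonical_smiles` and the perceived structure.
#' @examples
#' \donttest{
#' mols <- standardize_smiles(c(asp = "CC(=O)Oc1ccccc1C(=O)O"))
#' mols[[1]]$canonical_smiles
#' }
#' @export
standardize_smiles <- function(smiles, ids = NULL, ionize = TRUE, quiet = TRUE) {
  if (!is.character(smiles) || length(smiles) == 0)
    stop_ppb("'smiles' must be a non-empty character vector", "ppb_validation_error")
  if (anyNA(smiles) || any(!nzchar(trimws(smiles))))
    stop_ppb("empty or missing SMILES string in input", "ppb_validation_error")
  ids <- ids %||% names(smiles) %||% sprintf("M%d", seq_along(smiles))
  if (length(ids) != length(smiles))
    stop_ppb("'ids' must match 'smiles' in length", "ppb_validation_error")
  if (anyDuplicated(ids))
    stop_ppb("molecule ids must be unique", "ppb_validation_error")
  if (!quiet && ionize)
    message("applying pH 7.4 protonation rules: deprotonate carboxylic/",
            "sulfonic/phosphonic acids and tetrazoles; protonate aliphatic ",
            "amines, amidines and guanidines")

  src <- unname(smiles)
  canonical <- ob_canonical(strip_stereo(src), ionize = ionize)

  ## parse each distinct canonical structure once
  ucan <- unique(canonical)
  structs <- parse_structures(ucan)
  mols <- lapply(seq_along(src), function(k) {
    m <- structs[[match(canonical[k], ucan)]]
    m$id <- ids[k]
    m$source_smiles <- src[k]
    m
  })
  names(mols) <- ids
  structure(mols, class = "ppb_molset")
}

## Remove stereo descriptors from SMILES text. '@' marks tetrahedral centers,
## '/' and '\' cis/trans bonds; none of the three has any other meaning in
## SMILES, so textual removal is safe.
strip_stereo <- function(smiles) {
  gsub("@", "", gsub("[/\\\\]", "", smiles), fixed = TRUE)
}

## Batch canonicalization through OpenBabel. A parse failure truncates the
## batch output, so missing molecules are retried one by one to name the
## offending input precisely.
ob_canonical <- function(smiles, ionize = TRUE) {
  qid <- sprintf("q%d", seq_along(smiles))
  out <- ob_convert_smi(smiles, qid, "CAN", ionize = ionize)
  missing <- setdiff(qid, names(out))
  if (length(missing)) {
    for (q in missing) {
      one <- ob_convert_smi(smiles[match(q, qid)], q, "CAN", ionize = ionize)
      if (!length(one))
        stop_ppb(sprintf("unparseable SMILES: '%s'", smiles[match(q, qid)]),
                 "ppb_parse_error")
      out[q] <- one
    }
  }
  unname(out[qid])
}

ob_convert_smi <- function(smiles, qid, to, ionize = FALSE, add_h = FALSE) {
  opts <- data.frame(names = character(), args = character())
  if (ionize) opts <- rbind(opts, data.frame(names = "p", args = "7.4"))
  if (add_h)  opts <- rbind(opts, data.frame(names = "h", args = ""))
  input <- paste0(paste(smiles, qid, sep = "\t"), "\n", collapse = "")
  txt <- ChemmineOB::convertFormat("SMI", to, input, options = opts)
  if (to == "CAN") {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- vapply(parts, `[`, "", 1)
    out[is.na(out)] <- ""
    names(out) <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
    out
  } else txt
}

ob_sdfset <- function(smiles, qid, ionize = FALSE, add_h = FALSE) {
  txt <- ob_convert_smi(smiles, qid, "SDF", ionize = ionize, add_h = add_h)
  suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(txt, "\n", fixed = TRUE)[[1]])))
}

## V2000 old-style charge codes -> formal charges.
.sdf_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

## Parse canonical SMILES into heavy-atom graph structures. One SDF
## conversion per batch (explicit hydrogens: H counts, charges, bonds);
## aromaticity comes from the lowercase atoms of the canonical SMILES
## itself, cross-checked against the SDF element sequence.
parse_structures <- function(canonical) {
  qid <- sprintf("s%d", seq_along(canonical))
  sdf_h <- ob_sdfset(canonical, qid, add_h = TRUE)
  if (length(sdf_h) != length(canonical))
    stop_ppb("structure perception failed for part of the input", "ppb_parse_error")
  fps <- ob_hashed_fps(canonical)
  lapply(seq_along(canonical), function(k) {
    build_mol(canonical[k], sdf_h[[k]],
              sfp = fps$sfp[k, ], ecfp4 = fps$ecfp4[k, ])
  })
}

## per-atom (element, aromatic) in SMILES writing order: bracket atoms and
## the organic subset; aromatic atoms are written lowercase
smiles_atoms <- function(smiles) {
  tokens <- regmatches(smiles, gregexpr(
    "\\[[0-9]*[A-Za-z][a-z]?[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnops]",
    smiles))[[1]]
  elem <- character(length(tokens)); arom <- logical(length(tokens))
  for (k in seq_along(tokens)) {
    t <- tokens[k]
    if (startsWith(t, "[")) {
      ## the hydrogen count ('H' after a one-letter symbol) is uppercase and
      ## thus never captured by the optional lowercase second letter
      sym <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", t)
      arom[k] <- substr(sym, 1, 1) %in% letters
      elem[k] <- paste0(toupper(substr(sym, 1, 1)),
                        substring(sym, 2))
    } else {
      arom[k] <- t %in% c("b", "c", "n", "o", "p", "s")
      elem[k] <- paste0(toupper(substr(t, 1, 1)), substring(t, 2))
    }
  }
  list(element = elem, aromatic = arom)
}

## FP2 (1024-bit Daylight-type path fingerprint) and ECFP4 (4096 bits,
## OR-folded to 1024), computed straight from SMILES.
ob_hashed_fps <- function(smiles) {
  input <- paste0(paste(smiles, sprintf("f%d", seq_along(smiles))), "\n",
                  collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  fp2 <- ChemmineOB::fingerprint_OB(mols, "FP2")
  ec <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  if (is.null(dim(fp2))) fp2 <- matrix(fp2, nrow = 1)
  if (is.null(dim(ec))) ec <- matrix(ec, nrow = 1)
  if (nrow(fp2) != length(smiles) || nrow(ec) != length(smiles))
    stop_ppb("fingerprint computation failed for part of the input",
             "ppb_parse_error")
  folded <- ec[, 1:1024, drop = FALSE] | ec[, 1025:2048, drop = FALSE] |
    ec[, 2049:3072, drop = FALSE] | ec[, 3073:4096, drop = FALSE]
  list(sfp = matrix(as.integer(fp2 > 0), nrow = nrow(fp2)),
       ecfp4 = matrix(as.integer(folded), nrow = nrow(folded)))
}

build_mol <- function(canonical, sdf_h, sfp, ecfp4) {
  sa0 <- smiles_atoms(canonical)
  if (sum(toupper(sa0$element) != "H") == 0)      # no heavy atom at all
    return(structure(list(
      id = NA_character_, source_smiles = NA_character_,
      canonical_smiles = canonical, elements = character(0),
      charge = integer(0), nH = integer(0), aromatic = logical(0),
      bonds = matrix(integer(0), ncol = 3,
                     dimnames = list(NULL, c("from", "to", "order"))),
      dmat = matrix(numeric(0), 0, 0),
      sfp = as.integer(sfp), ecfp4 = as.integer(ecfp4)
    ), class = "ppb_mol"))
  ab <- ChemmineR::atomblock(sdf_h)
  elem <- sub("_\\d+$", "", rownames(ab))
  chg_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- unname(.sdf_charge[as.character(chg_code)])
  charge[is.na(charge)] <- 0
  bb <- tryCatch(ChemmineR::bondblock(sdf_h), error = function(e) NULL)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
  } else cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))

  heavy <- which(elem != "H")
  nH <- vapply(heavy, function(i) {
    nb <- c(bonds[bonds[, "from"] == i, "to"], bonds[bonds[, "to"] == i, "from"])
    sum(elem[nb] == "H")
  }, 0L)
  remap <- match(seq_along(elem), heavy)          # old index -> heavy index
  hb <- bonds[elem[bonds[, "from"]] != "H" & elem[bonds[, "to"]] != "H", ,
              drop = FALSE]
  hb[, "from"] <- remap[hb[, "from"]]
  hb[, "to"] <- remap[hb[, "to"]]

  n <- length(heavy)
  sa <- smiles_atoms(canonical)
  keep_sa <- toupper(sa$element) != "H"           # bracket hydrogens
  sa <- list(element = sa$element[keep_sa], aromatic = sa$aromatic[keep_sa])
  if (length(sa$element) != n ||
      !all(toupper(sa$element) == toupper(elem[heavy])))
    stop_ppb(sprintf("atom-order mismatch while perceiving '%s'", canonical),
             "ppb_parse_error")
  aromatic <- sa$aromatic

  dmat <- if (n > 1 && nrow(hb) > 0) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(hb[, c("from", "to"), drop = FALSE])))
    igraph::distances(g)
  } else if (n > 0) {
    d <- matrix(Inf, n, n); diag(d) <- 0; d
  } else matrix(numeric(0), 0, 0)

  structure(list(
    id = NA_character_, source_smiles = NA_character_,
    canonical_smiles = canonical,
    elements = elem[heavy], charge = charge[heavy], nH = nH,
    aromatic = aromatic, bonds = hb, dmat = dmat,
    sfp = as.integer(sfp), ecfp4 = as.integer(ecfp4)
  ), class = "ppb_mol")
}

## Hydrogen-bond perception (documented rule set): acceptors are N or O
## atoms without positive formal charge; donors are N or O atoms bearing at
## least one hydrogen. Acceptor site multiplicity: O contributes two lone
## pairs (plus one per unit of negative charge), N one.
mol_hba <- function(mol) mol$elements %in% c("N", "O") & mol$charge <= 0
mol_hbd <- function(mol) mol$elements %in% c("N", "O") & mol$nH > 0

#' @export
print.ppb_mol <- function(x, ...) {
  cat(sprintf("<molecule %s> %s\n  %d heavy atoms, %d bonds\n",
              x$id, x$canonical_smiles, length(x$elements), nrow(x$bonds)))
  invisible(x)
}

#' @export
print.ppb_molset <- function(x, ...) {
  cat(sprintf("<molecule set> %d molecules\n", length(x)))
  for (m in utils::head(x, 6))
    cat(sprintf("  %s  %s\n", m$id, m$canonical_smiles))
  if (length(x) > 6) cat(sprintf("  ... and %d more\n", length(x) - 6))
  invisible(x)
}

#' @export
`[.ppb_molset` <- function(x, i) structure(unclass(x)[i], class = "ppb_molset")
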