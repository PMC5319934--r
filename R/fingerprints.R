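## The six base fingerprints.
##
## APfp   21-D  atom-pair shape fingerprint: counts of heavy-atom pairs per
##              topological distance 1..21 (longer distances clamped to 21).
## Xfp    55-D  category atom-pair pharmacophore fingerprint: five channels
##              (any-any, HBA-HBA, HBD-HBD, HBA-HBD, aromatic-aromatic),
##              each 11 distance bins (1..10, >=11 clamped).
## MQN    42-D  molecular quantum numbers: atom, bond, polarity and ring
##              feature counts.
## SMIfp  34-D  character counts of the canonical SMILES over a fixed
##              34-symbol alphabet.
## Sfp  1024-D  binary Daylight-type substructure fingerprint (hashed linear
##              fragments up to 7 atoms).
## ECfp4 1024-D binary extended-connectivity circular fingerprint, bond
##              diameter 4, folded to 1024 bits.

.ppb_base_dims <- c(APfp = 21L, Xfp = 55L, MQN = 42L, SMIfp = 34L,
                    Sfp = 1024L, ECfp4 = 1024L)

#' Fingerprint scheme names
#'
#' `ppb_base_schemes()` returns the six base fingerprint names;
#' `ppb_fused_schemes()` the four fused fingerprints; `ppb_schemes()` all ten.
#' @return character vector of scheme names.
#' @export
ppb_base_schemes <- function() names(.ppb_base_dims)

#' @rdname ppb_base_schemes
#' @export
ppb_fused_schemes <- function() names(.ppb_ffp_components)

#' @rdname ppb_base_schemes
#' @export
ppb_schemes <- function() c(ppb_base_schemes(), ppb_fused_schemes())

new_fp <- function(values, scheme) {
  k <- .ppb_base_dims[[scheme]]
  values <- as.integer(values)
  stopifnot(length(values) == k, !anyNA(values), all(values >= 0))
  if (scheme %in% c("Sfp", "ECfp4")) stopifnot(all(values <= 1L))
  structure(values, scheme = scheme, class = "ppb_fp")
}

#' @export
print.ppb_fp <- function(x, ...) {
  cat(sprintf("<%s fingerprint> %d-D, %d non-zero\n",
              attr(x, "scheme"), length(x), sum(x > 0)))
  invisible(x)
}

check_mol <- function(mol) {
  if (!inherits(mol, "ppb_mol"))
    stop_ppb("expected a 'ppb_mol' (see standardize_smiles)", "ppb_validation_error")
  if (length(mol$elements) == 0)
    stop_ppb(sprintf("molecule '%s' has no heavy atoms", mol$id),
             "ppb_validation_error")
  invisible(mol)
}

## Histogram of clamped topological distances for a set of atom pairs.
pair_distance_counts <- function(dmat, sel_i, sel_j, nbins) {
  if (length(sel_i) == 0 || length(sel_j) == 0 || nrow(dmat) < 2)
    return(integer(nbins))
  n <- nrow(dmat)
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  keep <- matrix(FALSE, n, n)
  keep[sel_i, sel_j] <- TRUE
  keep[sel_j, sel_i] <- TRUE            # unordered pairs
  dd <- dmat[ut][keep[ut]]
  dd <- pmin(ifelse(is.finite(dd), dd, nbins), nbins)
  tabulate(dd[dd >= 1], nbins)
}

#' Compute the 21-D atom-pair shape fingerprint
#'
#' Bin d holds the number of unordered heavy-atom pairs at shortest
#' topological path length d; distances beyond 21 (including pairs in
#' disconnected fragments) are counted in bin 21 so the total pair count is
#' preserved.
#' @param mol a `ppb_mol`.
#' @return a 21-D integer `ppb_fp`.
#' @export
compute_apfp <- function(mol) {
  check_mol(mol)
  n <- length(mol$elements)
  new_fp(pair_distance_counts(mol$dmat, seq_len(n), seq_len(n), 21L), "APfp")
}

#' Compute the 55-D category atom-pair pharmacophore fingerprint
#'
#' Five channels of 11 topological-distance bins each (distances 1..10,
#' longer clamped into bin 11): all heavy-atom pairs, acceptor-acceptor,
#' donor-donor, acceptor-donor and aromatic-aromatic pairs. Acceptors are
#' N/O atoms without positive charge, donors N/O atoms bearing hydrogen.
#' @inheritParams compute_apfp
#' @return a 55-D integer `ppb_fp`.
#' @export
compute_xfp <- function(mol) {
  check_mol(mol)
  n <- length(mol$elements)
  all_i <- seq_len(n)
  hba <- which(mol_hba(mol)); hbd <- which(mol_hbd(mol))
  arom <- which(mol$aromatic)
  ch <- list(
    pair_distance_counts(mol$dmat, all_i, all_i, 11L),
    pair_distance_counts(mol$dmat, hba, hba, 11L),
    pair_distance_counts(mol$dmat, hbd, hbd, 11L),
    xfp_cross_counts(mol$dmat, hba, hbd, 11L),
    pair_distance_counts(mol$dmat, arom, arom, 11L)
  )
  new_fp(unlist(ch), "Xfp")
}

## Unordered pairs {i,j} where one atom is in A and the other in B (atoms in
## both categories never pair with themselves).
xfp_cross_counts <- function(dmat, A, B, nbins) {
  counts <- integer(nbins)
  n <- nrow(dmat)
  if (length(A) == 0 || length(B) == 0 || n < 2) return(counts)
  inA <- seq_len(n) %in% A; inB <- seq_len(n) %in% B
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  sel <- (inA[ut[, 1]] & inB[ut[, 2]]) | (inB[ut[, 1]] & inA[ut[, 2]])
  dd <- dmat[ut][sel]
  dd <- pmin(ifelse(is.finite(dd), dd, nbins), nbins)
  tabulate(dd[dd >= 1], nbins)
}

#' Compute the 34-D SMILES character-count fingerprint
#'
#' Counts occurrences of a fixed 34-symbol alphabet in the canonical SMILES:
#' the organic elements (upper and lower case where aromatic forms exist),
#' Cl/Br/I/B/H, brackets, parentheses, bond symbols, charges, the dot, the
#' percent sign and the digits 1-9. Two-character element tokens (Cl, Br)
#' are consumed before single characters.
#' @inheritParams compute_apfp
#' @return a 34-D integer `ppb_fp`.
#' @export
compute_smifp <- function(mol) {
  if (!inherits(mol, "ppb_mol"))
    stop_ppb("expected a 'ppb_mol'", "ppb_validation_error")
  new_fp(smifp_counts(mol$canonical_smiles), "SMIfp")
}

.smifp_alphabet <- c("C", "c", "N", "n", "O", "o", "S", "s", "P", "F",
                     "Cl", "Br", "I", "B", "H", "(", ")", "[", "]", "=",
                     "#", "+", "-", ".", "%", "1", "2", "3", "4", "5",
                     "6", "7", "8", "9")

smifp_counts <- function(smiles) {
  counts <- integer(length(.smifp_alphabet))
  names(counts) <- .smifp_alphabet
  chars <- strsplit(smiles, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    two <- if (i < length(chars)) paste0(chars[i], chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      counts[two] <- counts[two] + 1L
      i <- i + 2L
    } else {
      if (chars[i] %in% .smifp_alphabet)
        counts[chars[i]] <- counts[chars[i]] + 1L
      i <- i + 1L
    }
  }
  unname(counts)
}

#' Compute the 42-D molecular quantum numbers
#'
#' Counts of element types (C, F, Cl, Br, I, S, P), acyclic/cyclic N and O,
#' heavy atoms, acyclic/cyclic single/double/triple bonds, rotatable bonds,
#' hydrogen-bond acceptor sites and atoms, donor sites and atoms, formal
#' charges, acyclic mono-/di-/tri-/tetravalent and cyclic di-/tri-/
#' tetravalent nodes, smallest-set-of-smallest-rings counts by ring size
#' (3..9, >=10), and ring-fusion atoms and bonds.
#' @inheritParams compute_apfp
#' @return a 42-D integer `ppb_fp`.
#' @export
compute_mqn <- function(mol) {
  check_mol(mol)
  el <- mol$elements
  n <- length(el)
  bonds <- mol$bonds
  deg <- tabulate(c(bonds[, "from"], bonds[, "to"]), n)

  ## cyclic bonds = edges on some cycle (non-bridges); cyclic atoms =
  ## endpoints of cyclic bonds
  cyc_bond <- cyclic_bonds(n, bonds)
  cyc_atom <- logical(n)
  cyc_atom[c(bonds[cyc_bond, "from"], bonds[cyc_bond, "to"])] <- TRUE

  ord <- bonds[, "order"]
  acy <- !cyc_bond

  ## rotatable: acyclic single bonds between two non-terminal heavy atoms,
  ## excluding amide C-N bonds
  rbc <- 0L
  if (nrow(bonds)) {
    cand <- which(acy & ord == 1L & deg[bonds[, "from"]] > 1L &
                    deg[bonds[, "to"]] > 1L)
    rbc <- sum(vapply(cand, function(b) !is_amide_bond(mol, bonds[b, ]), TRUE))
  }

  hba <- mol_hba(mol); hbd <- mol_hbd(mol)
  hbam <- sum(ifelse(el == "O", 2L + pmax(0L, -mol$charge), 1L)[hba])
  hbdm <- sum(mol$nH[hbd])

  sr <- sssr_rings(n, bonds)
  ring_sizes <- vapply(sr, length, 0L)
  ring_atom_count <- tabulate(as.integer(unlist(sr)), n)
  ring_bond_count <- integer(nrow(bonds))
  for (r in sr) {
    eidx <- ring_edge_indices(r, bonds)
    ring_bond_count[eidx] <- ring_bond_count[eidx] + 1L
  }

  vals <- c(
    sum(el == "C"), sum(el == "F"), sum(el == "Cl"), sum(el == "Br"),
    sum(el == "I"), sum(el == "S"), sum(el == "P"),
    sum(el == "N" & !cyc_atom), sum(el == "N" & cyc_atom),
    sum(el == "O" & !cyc_atom), sum(el == "O" & cyc_atom),
    n,
    sum(acy & ord == 1L), sum(acy & ord == 2L), sum(acy & ord == 3L),
    sum(cyc_bond & ord == 1L), sum(cyc_bond & ord == 2L),
    sum(cyc_bond & ord == 3L),
    rbc,
    hbam, sum(hba), hbdm, sum(hbd),
    sum(mol$charge < 0), sum(mol$charge > 0),
    sum(!cyc_atom & deg == 1L), sum(!cyc_atom & deg == 2L),
    sum(!cyc_atom & deg == 3L), sum(!cyc_atom & deg == 4L),
    sum(cyc_atom & deg == 2L), sum(cyc_atom & deg == 3L),
    sum(cyc_atom & deg == 4L),
    sum(ring_sizes == 3L), sum(ring_sizes == 4L), sum(ring_sizes == 5L),
    sum(ring_sizes == 6L), sum(ring_sizes == 7L), sum(ring_sizes == 8L),
    sum(ring_sizes == 9L), sum(ring_sizes >= 10L),
    sum(ring_atom_count >= 2L), sum(ring_bond_count >= 2L)
  )
  new_fp(vals, "MQN")
}

.mqn_names <- c("c", "f", "cl", "br", "i", "s", "p", "an", "cn", "ao", "co",
                "hac", "asb", "adb", "atb", "csb", "cdb", "ctb", "rbc",
                "hbam", "hba", "hbdm", "hbd", "neg", "pos", "asv", "adv",
                "atv", "aqv", "cdv", "ctv", "cqv", "r3", "r4", "r5", "r6",
                "r7", "r8", "r9", "rg10", "afr", "bfr")

is_amide_bond <- function(mol, bond) {
  for (ij in list(c(bond[["from"]], bond[["to"]]),
                  c(bond[["to"]], bond[["from"]]))) {
    if (mol$elements[ij[1]] == "N" && mol$elements[ij[2]] == "C") {
      b <- mol$bonds
      nb <- b[(b[, "from"] == ij[2] | b[, "to"] == ij[2]) & b[, "order"] == 2L, ,
              drop = FALSE]
      other <- ifelse(nb[, "from"] == ij[2], nb[, "to"], nb[, "from"])
      if (any(mol$elements[other] == "O")) return(TRUE)
    }
  }
  FALSE
}

#' Compute the 1024-bit substructure path fingerprint
#'
#' Daylight-type hashed fingerprint of linear and branched fragments up to
#' seven atoms (OpenBabel FP2).
#' @inheritParams compute_apfp
#' @return a 1024-D binary `ppb_fp`.
#' @export
compute_sfp <- function(mol) {
  check_mol(mol)
  new_fp(mol$sfp, "Sfp")
}

#' Compute the 1024-bit extended-connectivity circular fingerprint
#'
#' Circular atom-environment fingerprint with bond diameter 4 (radius 2),
#' folded from 4096 to 1024 bits by OR.
#' @inheritParams compute_apfp
#' @return a 1024-D binary `ppb_fp`.
#' @export
compute_ecfp4 <- function(mol) {
  check_mol(mol)
  new_fp(mol$ecfp4, "ECfp4")
}

#' Compute all six base fingerprints of a molecule
#'
#' Fused fingerprints are never materialized as vectors; their distances are
#' derived on demand from the base fingerprints (see [fused_distance()]).
#' @inheritParams compute_apfp
#' @return a `ppb_profile`: named list of six `ppb_fp` vectors plus the
#'   molecule id.
#' @export
compute_profile <- function(mol) {
  check_mol(mol)
  structure(list(molecule_id = mol$id,
                 APfp = compute_apfp(mol), Xfp = compute_xfp(mol),
                 MQN = compute_mqn(mol), SMIfp = compute_smifp(mol),
                 Sfp = compute_sfp(mol), ECfp4 = compute_ecfp4(mol)),
            class = "ppb_profile")
}

#' @export
print.ppb_profile <- function(x, ...) {
  cat(sprintf("<fingerprint profile> %s\n", x$molecule_id))
  for (s in ppb_base_schemes())
    cat(sprintf("  %-6s %4d-D, %4d non-zero\n", s, length(x[[s]]), sum(x[[s]] > 0)))
  invisible(x)
}

#' Fingerprint profiles as per-scheme matrices
#'
#' Stacks the base-fingerprint profiles of a molecule set into one integer
#' matrix per scheme (rows = molecules, named by canonical SMILES), the
#' layout used for batch distance computation.
#' @param mols a `ppb_molset`.
#' @return named list of six integer matrices, class `ppb_profilemat`.
#' @export
profile_matrices <- function(mols) {
  if (inherits(mols, "ppb_mol")) mols <- structure(list(mols), class = "ppb_molset")
  profs <- lapply(mols, compute_profile)
  out <- lapply(ppb_base_schemes(), function(s) {
    m <- do.call(rbind, lapply(profs, function(p) as.integer(p[[s]])))
    rownames(m) <- vapply(mols, function(x) x$canonical_smiles, "")
    m
  })
  names(out) <- ppb_base_schemes()
  structure(out, class = "ppb_profilemat")
}
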