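## City-block distance, mode-matched scaling, and the fused fingerprints.
##
## All similarity in this package is the city-block (Manhattan) distance
## CBD(A, B) = sum_j |A_j - B_j|. Because typical random-pair distances
## differ by orders of magnitude between fingerprint schemes, fusion scales
## each component scheme so that the mode of its random-pair distance
## distribution matches that of the 55-D pharmacophore fingerprint (Xfp);
## the fused distance is then the sum of scaled component distances, which
## equals the CBD of the scaled concatenated vectors.

.ppb_ffp_components <- list(
  Ffp1 = c("Xfp", "SMIfp", "Sfp"),
  Ffp2 = c("Xfp", "MQN", "SMIfp"),
  Ffp3 = c("Xfp", "SMIfp", "Sfp", "ECfp4"),
  Ffp4 = c("Xfp", "MQN", "SMIfp", "Sfp", "ECfp4")
)

#' Component schemes of a fused fingerprint
#' @param name one of `"Ffp1".."Ffp4"`.
#' @return character vector of base scheme names.
#' @export
ffp_components <- function(name) {
  if (!name %in% names(.ppb_ffp_components))
    stop_ppb(sprintf("unknown fused fingerprint '%s'", name),
             "ppb_validation_error")
  .ppb_ffp_components[[name]]
}

#' City-block distance between two fingerprint vectors
#'
#' @param a,b numeric vectors of equal length; if both carry a scheme
#'   attribute (as `ppb_fp` objects do) the schemes must agree.
#' @return the non-negative sum of absolute coordinate differences.
#' @export
cbd <- function(a, b) {
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    stop_ppb(sprintf("fingerprint scheme mismatch: %s vs %s", sa, sb),
             "ppb_validation_error")
  if (length(a) != length(b))
    stop_ppb("fingerprint dimension mismatch", "ppb_validation_error")
  sum(abs(as.numeric(a) - as.numeric(b)))
}

#' Mode of a distance sample
#'
#' The most frequent value after rounding to unit-width integer bins; ties
#' are broken toward the smaller value.
#' @param samples non-empty numeric vector of distances.
#' @return the modal distance (a single number).
#' @export
distance_mode <- function(samples) {
  if (length(samples) == 0 || anyNA(samples))
    stop_ppb("empty or missing distance sample", "ppb_validation_error")
  r <- round(samples)
  tt <- table(r)                     # levels ascend numerically
  as.numeric(names(tt))[which.max(tt)]   # first maximum = smallest value
}

#' Calibrate mode-matching scale factors
#'
#' Samples random molecule pairs, computes the city-block distance
#' distribution in each base fingerprint space, and records the modal
#' distance. Each scheme's scale factor is mode(Xfp)/mode(scheme), anchoring
#' all schemes to the pharmacophore fingerprint; Xfp's factor is exactly 1.
#'
#' @param molecules a `ppb_molset` (>= 2 molecules) or a `ppb_profilemat`.
#' @param n_pairs number of random pairs to sample (default 1e5).
#' @param seed RNG seed; calibration is fully reproducible.
#' @return a `ppb_scaling` data frame with columns `scheme`,
#'   `mode_distance`, `scale_factor`, and attributes `sample_size`, `seed`.
#' @export
calibrate_scaling <- function(molecules, n_pairs = 1e5, seed = 1L) {
  pm <- if (inherits(molecules, "ppb_profilemat")) molecules
        else profile_matrices(molecules)
  n <- nrow(pm$Xfp)
  if (n < 2)
    stop_ppb("scaling calibration needs at least 2 molecules", "ppb_validation_error")
  if (n_pairs < 1)
    stop_ppb("n_pairs must be >= 1", "ppb_validation_error")
  idx <- with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)     # j != i, uniform over ordered pairs
    cbind(i, j)
  })
  dists <- lapply(pm[ppb_base_schemes()], function(m)
    pairwise_cbd(m, idx[, 1], idx[, 2]))
  scaling_from_distances(dists, sample_size = n_pairs, seed = seed)
}

## row-wise CBD between M[i, ] and M[j, ], chunked to bound memory
pairwise_cbd <- function(M, i, j, chunk = 5000L) {
  out <- numeric(length(i))
  for (s in seq(1L, length(i), by = chunk)) {
    e <- min(s + chunk - 1L, length(i))
    out[s:e] <- rowSums(abs(M[i[s:e], , drop = FALSE] - M[j[s:e], , drop = FALSE]))
  }
  out
}

#' Build a scaling table from per-scheme distance samples
#'
#' The deterministic core of [calibrate_scaling()], exposed so that scale
#' factors can be derived from any pre-computed distance distributions.
#' @param distances named list (one entry per base scheme, `Xfp` mandatory)
#'   of numeric distance samples.
#' @param sample_size,seed provenance recorded as attributes.
#' @return a `ppb_scaling` table.
#' @export
scaling_from_distances <- function(distances, sample_size = NA_integer_,
                                   seed = NA_integer_) {
  if (!"Xfp" %in% names(distances))
    stop_ppb("distance samples must include the reference scheme Xfp",
             "ppb_validation_error")
  modes <- vapply(distances, distance_mode, 0)
  if (any(modes <= 0))
    stop_ppb(sprintf(
      "degenerate calibration: zero modal distance for %s (molecule sample too uniform)",
      paste(names(modes)[modes <= 0], collapse = ", ")),
      "ppb_degenerate_calibration")
  st <- data.frame(scheme = names(distances), mode_distance = unname(modes),
                   scale_factor = unname(modes[["Xfp"]] / modes),
                   stringsAsFactors = FALSE)
  structure(st, class = c("ppb_scaling", "data.frame"),
            reference_scheme = "Xfp", sample_size = sample_size, seed = seed)
}

scale_factor <- function(st, scheme) {
  if (is.null(st)) return(1)
  st$scale_factor[match(scheme, st$scheme)]
}

#' @export
print.ppb_scaling <- function(x, ...) {
  cat(sprintf("<scaling table> reference %s, %s random pairs\n",
              attr(x, "reference_scheme"),
              format(attr(x, "sample_size"), big.mark = ",")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fused city-block distance between two profiles
#'
#' Sum over the fused fingerprint's component schemes of
#' `scale_factor(scheme) * cbd(a, b)`; by linearity this equals the
#' city-block distance of the scaled concatenated vectors.
#' @param pa,pb `ppb_profile` objects.
#' @param ffp fused fingerprint name (`"Ffp1".."Ffp4"`) or the result of
#'   [ffp_components()].
#' @param st a `ppb_scaling` table from [calibrate_scaling()].
#' @return non-negative fused distance.
#' @export
fused_distance <- function(pa, pb, ffp, st) {
  comps <- if (is.character(ffp) && length(ffp) == 1) ffp_components(ffp)
           else if (is.character(ffp) && all(ffp %in% ppb_base_schemes())) ffp
           else stop_ppb("'ffp' must be a fused fingerprint name or a vector of base schemes",
                         "ppb_validation_error")
  sum(vapply(comps, function(s) scale_factor(st, s) * cbd(pa[[s]], pb[[s]]), 0))
}

#' Distance between two profiles in any of the ten fingerprint spaces
#'
#' Base schemes use the raw (unscaled) integer city-block distance —
#' scaling a single scheme by a constant does not change its
#' nearest-neighbor ranking — while fused schemes use [fused_distance()].
#' @inheritParams fused_distance
#' @param scheme one of the ten scheme names.
#' @export
scheme_distance <- function(pa, pb, scheme, st = NULL) {
  if (scheme %in% ppb_base_schemes()) cbd(pa[[scheme]], pb[[scheme]])
  else if (scheme %in% ppb_fused_schemes()) {
    if (is.null(st))
      stop_ppb("fused distances require a scaling table", "ppb_validation_error")
    fused_distance(pa, pb, scheme, st)
  } else stop_ppb(sprintf("unknown scheme '%s'", scheme), "ppb_validation_error")
}

#' Serialize / restore a scaling table
#' @param st a `ppb_scaling` table.
#' @param path JSON file path.
#' @export
save_scaling <- function(st, path) {
  jsonlite::write_json(
    list(reference_scheme = attr(st, "reference_scheme"),
         sample_size = attr(st, "sample_size"), seed = attr(st, "seed"),
         table = st),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_scaling
#' @export
load_scaling <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(x$table, stringsAsFactors = FALSE),
            class = c("ppb_scaling", "data.frame"),
            reference_scheme = x$reference_scheme,
            sample_size = x$sample_size, seed = x$seed)
}
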