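## Negative-binomial p-value calibration.
##
## For each (target group, fingerprint space) pair, the distribution of
## city-block distances between group members and random background
## molecules is an overdispersed discrete distribution; it is fitted with a
## negative binomial by maximum likelihood. The p-value of an observed
## query-to-group distance d is then P(D <= round(d)) under the fitted
## null: the probability that a random molecule comes at least as close to
## the group as the query did. The p-value is comparable only within its
## own (target, fingerprint space) pair; ranking uses it solely through
## per-target sums and thresholds.

#' Sample background distances for one target group
#'
#' Distances between the members of a target group and a set of background
#' molecules, in the requested fingerprint space. All member-background
#' pairs are used when there are at most `n_max`; otherwise `n_max` pairs
#' are sampled uniformly without replacement (seeded). Fused (scaled)
#' distances are rounded to the nearest integer so that the sample stays
#' discrete for negative-binomial fitting.
#'
#' @param db a `ppb_refdb`.
#' @param target_id group to sample for.
#' @param background a `ppb_molset` or `ppb_profilemat` of background
#'   molecules.
#' @param scheme one of the ten fingerprint schemes.
#' @param st scaling table (required for fused schemes).
#' @param n_max maximum number of pairs (default 1e6).
#' @param seed RNG seed.
#' @return integer vector of distances.
#' @export
sample_background_distances <- function(db, target_id, background, scheme,
                                        st = NULL, n_max = 1e6, seed = 1L) {
  m <- db$members[[target_id]]
  if (is.null(m) || nrow(m) == 0)
    stop_ppb(sprintf("unknown or empty target group '%s'", target_id),
             "ppb_validation_error")
  bp <- if (inherits(background, "ppb_profilemat")) background
        else profile_matrices(background)
  if (nrow(bp$Xfp) == 0)
    stop_ppb("background molecule set is empty", "ppb_validation_error")
  gidx <- match(m$canonical_smiles, rownames(db$profiles$Xfp))
  cross_scheme_distances(db$profiles, gidx, bp, scheme, st, n_max, seed)
}

cross_scheme_distances <- function(gprof, gidx, bprof, scheme, st, n_max, seed) {
  ng <- length(gidx); nb <- nrow(bprof$Xfp)
  total <- as.numeric(ng) * nb
  pair <- if (total <= n_max) 0:(total - 1)
          else with_seed(seed, sample(total, n_max)) - 1
  gi <- gidx[(pair %% ng) + 1]
  bi <- (pair %/% ng) + 1
  comps <- if (scheme %in% ppb_base_schemes()) scheme else ffp_components(scheme)
  d <- numeric(length(gi))
  for (s in comps) {
    w <- if (scheme %in% ppb_base_schemes()) 1 else scale_factor(st, s)
    d <- d + w * pairwise_cbd_cross(gprof[[s]], gi, bprof[[s]], bi)
  }
  as.integer(round(d))
}

pairwise_cbd_cross <- function(A, i, B, j, chunk = 5000L) {
  out <- numeric(length(i))
  for (s in seq(1L, length(i), by = chunk)) {
    e <- min(s + chunk - 1L, length(i))
    out[s:e] <- rowSums(abs(A[i[s:e], , drop = FALSE] - B[j[s:e], , drop = FALSE]))
  }
  out
}

#' Fit a negative binomial by maximum likelihood
#'
#' Maximizes the negative-binomial log-likelihood over (log size, logit
#' prob), initialized at the method-of-moments estimate, with convergence
#' tolerance 1e-8 on the objective. Requires at least 100 samples and
#' overdispersion (variance > mean); underdispersed or constant samples
#' raise a degenerate-fit error (callers fall back to a Poisson fit, see
#' [calibrate_database()]).
#'
#' @param samples non-negative integer sample.
#' @return a `ppb_nbparams` list: `size_r`, `prob_p`, `n_samples`,
#'   `fit_loglik`, `status = "nb"`.
#' @export
fit_negative_binomial <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 100)
    stop_ppb("negative-binomial fit needs at least 100 samples",
             "ppb_validation_error")
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop_ppb("samples must be non-negative integers", "ppb_validation_error")
  m <- mean(x); v <- stats::var(x)
  if (v <= m)
    stop_ppb(sprintf(
      "degenerate fit: sample variance (%.3f) <= mean (%.3f); negative-binomial MLE diverges, fall back to a Poisson fit",
      v, m), "ppb_degenerate_fit")

  ## method of moments: m = r(1-p)/p, v = r(1-p)/p^2
  p0 <- m / v
  r0 <- m^2 / (v - m)
  nll <- function(par) {
    r <- exp(par[1]); p <- stats::plogis(par[2])
    -sum(stats::dnbinom(x, size = r, prob = p, log = TRUE))
  }
  fit <- stats::optim(c(log(r0), stats::qlogis(p0)), nll, method = "BFGS",
                      control = list(reltol = 1e-8, maxit = 500))
  structure(list(size_r = exp(fit$par[1]), prob_p = stats::plogis(fit$par[2]),
                 n_samples = length(x), fit_loglik = -fit$value,
                 status = "nb"),
            class = "ppb_nbparams")
}

fit_poisson <- function(samples) {
  x <- as.numeric(samples)
  structure(list(lambda = mean(x), n_samples = length(x),
                 fit_loglik = sum(stats::dpois(x, mean(x), log = TRUE)),
                 status = "poisson"),
            class = "ppb_nbparams")
}

#' @export
print.ppb_nbparams <- function(x, ...) {
  if (x$status == "nb")
    cat(sprintf("<null fit> NB(size = %.4g, prob = %.4g), n = %d, logLik = %.2f\n",
                x$size_r, x$prob_p, x$n_samples, x$fit_loglik))
  else if (x$status == "poisson")
    cat(sprintf("<null fit> Poisson(lambda = %.4g) [underdispersed fallback], n = %d\n",
                x$lambda, x$n_samples))
  else cat("<null fit> failed (no usable distribution)\n")
  invisible(x)
}

#' Null p-value of an observed distance
#'
#' `P(D <= round(distance))` under the fitted null distribution: the
#' probability that a random background molecule lies at least as close to
#' the target group as the query does. A valid CDF on the integers:
#' non-decreasing in the distance, with limits 0 and 1.
#'
#' @param params a `ppb_nbparams` fit.
#' @param distance non-negative distance(s).
#' @return p-value(s) in \[0, 1\] (`NA` for a failed fit).
#' @export
p_value <- function(params, distance) {
  if (any(distance < 0))
    stop_ppb("distance must be non-negative", "ppb_validation_error")
  d <- round(distance)
  switch(params$status,
         nb = stats::pnbinom(d, size = params$size_r, prob = params$prob_p),
         poisson = stats::ppois(d, params$lambda),
         rep(NA_real_, length(d)))
}

#' Calibrate null distributions for a whole database
#'
#' Fits one null distribution per (target group, fingerprint scheme):
#' negative binomial when the background distance sample is overdispersed,
#' Poisson as a flagged fallback otherwise, and a recorded failure (null
#' entry, excluded from p-value ranking) for constant samples. Entry-level
#' errors never abort the whole calibration. Deterministic under a fixed
#' seed and background.
#'
#' @param db a `ppb_refdb`.
#' @param background background molecules: SMILES vector, `ppb_molset` or
#'   `ppb_profilemat`.
#' @param st scaling table (needed for fused schemes).
#' @param schemes schemes to calibrate (default all ten).
#' @param n_max maximum background pairs per entry (default 1e6).
#' @param seed RNG seed.
#' @param ionize standardization flag for a SMILES background.
#' @return a `ppb_calibration` object.
#' @export
calibrate_database <- function(db, background, st = NULL,
                               schemes = ppb_schemes(), n_max = 1e6,
                               seed = 1L, ionize = TRUE) {
  if (is.character(background))
    background <- standardize_smiles(background, ids = sprintf("BG%d", seq_along(background)),
                                     ionize = ionize)
  bp <- if (inherits(background, "ppb_profilemat")) background
        else profile_matrices(background)
  overlap <- intersect(rownames(bp$Xfp), db$compounds$canonical_smiles)
  if (length(overlap))
    warning(sprintf("%d background molecule(s) also occur in the database",
                    length(overlap)), call. = FALSE)
  if (any(schemes %in% ppb_fused_schemes()) && is.null(st))
    stop_ppb("fused schemes require a scaling table", "ppb_validation_error")

  tids <- db$targets$target_id
  grid <- expand.grid(target_id = tids, scheme = schemes,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  entries <- vector("list", nrow(grid))
  names(entries) <- paste(grid$target_id, grid$scheme, sep = "::")
  for (k in seq_len(nrow(grid))) {
    dists <- sample_background_distances(db, grid$target_id[k], bp,
                                         grid$scheme[k], st = st,
                                         n_max = n_max, seed = seeds[k])
    entries[[k]] <- tryCatch(
      fit_negative_binomial(dists),
      ppb_degenerate_fit = function(e)
        if (stats::var(dists) > 0) fit_poisson(dists)
        else structure(list(n_samples = length(dists), status = "failed"),
                       class = "ppb_nbparams"),
      ppb_validation_error = function(e)
        structure(list(n_samples = length(dists), status = "failed"),
                  class = "ppb_nbparams"))
  }
  structure(list(entries = entries, schemes = schemes, seed = seed,
                 n_max = n_max,
                 background = sprintf("%d molecules", nrow(bp$Xfp))),
            class = "ppb_calibration")
}

calibration_entry <- function(calib, target_id, scheme) {
  if (is.null(calib)) return(NULL)
  calib$entries[[paste(target_id, scheme, sep = "::")]]
}

#' @export
print.ppb_calibration <- function(x, ...) {
  status <- vapply(x$entries, `[[`, "", "status")
  cat(sprintf("<calibration set> %d entries (%d NB, %d Poisson fallback, %d failed)\n  background: %s, seed %d\n",
              length(status), sum(status == "nb"), sum(status == "poisson"),
              sum(status == "failed"), x$background, x$seed))
  invisible(x)
}

#' Serialize / restore a calibration set
#' @param calib a `ppb_calibration`.
#' @param path JSON file path.
#' @export
save_calibration <- function(calib, path) {
  rows <- lapply(names(calib$entries), function(nm) {
    e <- calib$entries[[nm]]
    ts <- strsplit(nm, "::", fixed = TRUE)[[1]]
    list(target_id = ts[1], scheme = ts[2], status = e$status,
         size_r = e$size_r %||% NA, prob_p = e$prob_p %||% NA,
         lambda = e$lambda %||% NA, n_samples = e$n_samples,
         fit_loglik = e$fit_loglik %||% NA)
  })
  jsonlite::write_json(
    list(schemes = calib$schemes, seed = calib$seed, n_max = calib$n_max,
         background = calib$background, entries = rows),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- list()
  for (e in x$entries) {
    p <- list(status = e$status, n_samples = e$n_samples)
    if (identical(e$status, "nb"))
      p <- c(p, list(size_r = e$size_r, prob_p = e$prob_p,
                     fit_loglik = e$fit_loglik))
    if (identical(e$status, "poisson"))
      p <- c(p, list(lambda = e$lambda, fit_loglik = e$fit_loglik))
    entries[[paste(e$target_id, e$scheme, sep = "::")]] <-
      structure(p, class = "ppb_nbparams")
  }
  structure(list(entries = entries, schemes = unlist(x$schemes),
                 seed = x$seed, n_max = x$n_max, background = x$background),
            class = "ppb_calibration")
}
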