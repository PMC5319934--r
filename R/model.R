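## The fitted predictor object: reference database + scaling table + null
## calibration bundled as one classed model with the usual S3 verbs.

#' Fit a multi-fingerprint target predictor
#'
#' One call from an activity table to a ready-to-query predictor: applies
#' the bioactivity retention filter, builds the reference database of
#' target groups, calibrates the mode-matching scale factors on random
#' compound pairs from the database, and fits the negative-binomial null
#' distributions of query-to-group distances against the background set.
#'
#' @param activities activity records (data frame) or a path passed to
#'   [load_activity_table()].
#' @param background background molecules for null calibration: SMILES
#'   vector or `ppb_molset`.
#' @param min_size minimum distinct actives per retained target (default 10).
#' @param schemes fingerprint spaces to calibrate and search (default all
#'   ten).
#' @param scaling_pairs random pairs for scale-factor calibration.
#' @param calib_n_max maximum background pairs per null fit.
#' @param seed master RNG seed for both calibrations.
#' @param ionize apply pH 7.4 protonation throughout.
#' @param dialect column remapping for a table path.
#' @return an object of class `ppb`: list with `db`, `scaling`, `calib`,
#'   `schemes`, `options`, `call`.
#' @seealso [predict.ppb()], [coef.ppb()], [simulate.ppb()], [plot.ppb()]
#' @export
ppb_fit <- function(activities, background, min_size = 10,
                    schemes = ppb_schemes(), scaling_pairs = 1e5,
                    calib_n_max = 1e6, seed = 1L, ionize = TRUE,
                    dialect = NULL) {
  cl <- match.call()
  if (is.character(activities) && length(activities) == 1)
    activities <- load_activity_table(activities, dialect = dialect)
  records <- filter_activities(activities)
  db <- build_target_groups(records, min_size = min_size, ionize = ionize)
  if (nrow(db$targets) == 0)
    stop_ppb("no target group survived the retention filter", "ppb_validation_error")
  seeds <- derive_seeds(seed, 2L)
  st <- calibrate_scaling(db$profiles, n_pairs = scaling_pairs, seed = seeds[1])
  calib <- calibrate_database(db, background, st = st, schemes = schemes,
                              n_max = calib_n_max, seed = seeds[2],
                              ionize = ionize)
  structure(list(db = db, scaling = st, calib = calib, schemes = schemes,
                 options = list(min_size = min_size, seed = seed,
                                scaling_pairs = scaling_pairs,
                                calib_n_max = calib_n_max, ionize = ionize),
                 call = cl),
            class = "ppb")
}

#' @export
print.ppb <- function(x, ...) {
  status <- vapply(x$calib$entries, `[[`, "", "status")
  cat(sprintf(
    "Multi-fingerprint target predictor\n  %d target groups, %d unique compounds, %d fingerprint spaces\n  null fits: %d NB, %d Poisson fallback, %d failed\n",
    nrow(x$db$targets), n_compounds(x$db), length(x$schemes),
    sum(status == "nb"), sum(status == "poisson"), sum(status == "failed")))
  invisible(x)
}

#' @export
summary.ppb <- function(object, ...) {
  status <- vapply(object$calib$entries, `[[`, "", "status")
  structure(list(targets = object$db$targets, scaling = object$scaling,
                 fit_status = table(status), schemes = object$schemes,
                 n_compounds = n_compounds(object$db),
                 options = object$options),
            class = "summary.ppb")
}

#' @export
print.summary.ppb <- function(x, ...) {
  cat(sprintf("Target groups (%d, min size %d):\n", nrow(x$targets),
              x$options$min_size))
  print(x$targets, row.names = FALSE)
  cat(sprintf("\nUnique compounds: %d\n\n", x$n_compounds))
  print(x$scaling)
  cat("\nNull-distribution fits:\n")
  print(x$fit_status)
  invisible(x)
}

#' Predict targets with a fitted predictor
#'
#' @param object a fitted `ppb` model.
#' @param newdata query SMILES (one or more).
#' @param ... options passed to [predict_targets()] (`n_targets`,
#'   `min_votes`, `schemes`, `ids`).
#' @return a `ppb_report`, or a list of reports for several queries.
#' @export
predict.ppb <- function(object, newdata, ...) {
  predict_targets(newdata, object$db, calib = object$calib,
                  st = object$scaling, ionize = object$options$ionize, ...)
}

#' Fitted null parameters and scale factors
#'
#' @param object a fitted `ppb` model.
#' @param ... unused.
#' @return data frame of per-(target, scheme) null parameters, with the
#'   scaling table in attribute `"scaling"`.
#' @export
coef.ppb <- function(object, ...) {
  nm <- names(object$calib$entries)
  ts <- do.call(rbind, strsplit(nm, "::", fixed = TRUE))
  out <- data.frame(
    target_id = ts[, 1], scheme = ts[, 2],
    status = vapply(object$calib$entries, `[[`, "", "status"),
    size_r = vapply(object$calib$entries, function(e) e$size_r %||% NA_real_, 0),
    prob_p = vapply(object$calib$entries, function(e) e$prob_p %||% NA_real_, 0),
    lambda = vapply(object$calib$entries, function(e) e$lambda %||% NA_real_, 0),
    n_samples = vapply(object$calib$entries, function(e) as.integer(e$n_samples), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scaling") <- object$scaling
  out
}

#' Simulate from a fitted null distribution
#'
#' Draws random query-to-group distances from the calibrated null of one
#' (target, fingerprint space) pair.
#' @param object a fitted `ppb` model.
#' @param nsim number of draws.
#' @param seed RNG seed.
#' @param target_id,scheme which null to simulate from (defaults: first
#'   target, first scheme).
#' @param ... unused.
#' @export
simulate.ppb <- function(object, nsim = 1, seed = 1L,
                         target_id = object$db$targets$target_id[1],
                         scheme = object$schemes[1], ...) {
  e <- calibration_entry(object$calib, target_id, scheme)
  if (is.null(e) || e$status == "failed")
    stop_ppb(sprintf("no usable null fit for (%s, %s)", target_id, scheme),
             "ppb_validation_error")
  with_seed(seed, switch(e$status,
                         nb = stats::rnbinom(nsim, size = e$size_r, prob = e$prob_p),
                         poisson = stats::rpois(nsim, e$lambda)))
}

#' Plot a fitted null distribution
#'
#' Probability mass of the calibrated null for one (target, fingerprint
#' space) pair, with an optional observed query distance marked.
#' @param x a fitted `ppb` model.
#' @param target_id,scheme which null to plot.
#' @param observed optional observed distance drawn as a vertical line.
#' @param ... passed to [graphics::plot()].
#' @method plot ppb
#' @export
plot.ppb <- function(x, target_id = x$db$targets$target_id[1],
                     scheme = x$schemes[1], observed = NULL, ...) {
  e <- calibration_entry(x$calib, target_id, scheme)
  if (is.null(e) || e$status == "failed")
    stop_ppb(sprintf("no usable null fit for (%s, %s)", target_id, scheme),
             "ppb_validation_error")
  mu <- switch(e$status, nb = e$size_r * (1 - e$prob_p) / e$prob_p,
               poisson = e$lambda)
  sd <- switch(e$status, nb = sqrt(e$size_r * (1 - e$prob_p)) / e$prob_p,
               poisson = sqrt(e$lambda))
  d <- max(0, floor(mu - 4 * sd)):ceiling(mu + 4 * sd)
  pmf <- switch(e$status,
                nb = stats::dnbinom(d, size = e$size_r, prob = e$prob_p),
                poisson = stats::dpois(d, e$lambda))
  graphics::plot(d, pmf, type = "h", xlab = "city-block distance",
                 ylab = "null probability",
                 main = sprintf("%s / %s null (%s)", target_id, scheme, e$status),
                 ...)
  if (!is.null(observed)) graphics::abline(v = observed, col = 2, lty = 2)
  invisible(x)
}
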