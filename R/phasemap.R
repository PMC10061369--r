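#' Fit an SVM phase boundary in composition space
#'
#' Fits a soft-margin support-vector machine (linear or 2nd-degree
#' polynomial kernel) separating mixed from aggregate-containing droplets,
#' on standardised features, with class-weighted hinge loss for imbalanced
#' screens. The aggregation probability surface is a sigmoid (Platt)
#' calibration fitted by logistic regression of the training labels on the
#' SVM decision values, so the phase boundary is exactly the p = 0.5
#' contour. Features the flow programme holds fixed — relative spread below
#' \code{constant_cv}, i.e. varying only through measurement noise — are
#' dropped from the fit and remembered at their mean: a noise-only axis
#' carries no composition information but can correlate with residual
#' calibration error and tilt the boundary.
#'
#' @param points data frame of compositions; all numeric columns are used
#'   as features (typically precipitant, protein, additive concentrations).
#' @param labels droplet calls: \code{"mixed"}/\code{"aggregated"}, or 0/1
#'   (1 = aggregated).
#' @param kernel \code{"linear"} or \code{"poly2"}.
#' @param cost soft-margin regularisation strength C in standardised
#'   feature space.
#' @param precipitant name of the precipitant feature (the solubility axis).
#' @param min_per_class minimum droplets required in each class.
#' @param class_weights use inverse-prevalence class weights (default TRUE).
#' @param constant_cv features with \code{sd < constant_cv * |mean|} are
#'   treated as held fixed (default 0.05).
#' @return object of class \code{phase_model}.
#' @export
fit_phase_model <- function(points, labels, kernel = c("linear", "poly2"),
                            cost = 1, precipitant = "PEG",
                            min_per_class = 50L, class_weights = TRUE,
                            constant_cv = 0.05) {
  kernel <- match.arg(kernel)
  y <- canonical_labels(labels)
  for (cls in c("mixed", "aggregated"))
    if (sum(y == cls) == 0L)
      stop_dropsol(sprintf("no '%s' droplets in the training set", cls),
                   "dropsol_fit_error")
  if (min(table(y)) < min_per_class)
    stop_dropsol(sprintf("need >= %d droplets per class (have %s)",
                         min_per_class,
                         paste(table(y), collapse = "/")),
                 "dropsol_fit_error")
  x <- as.matrix(points[vapply(points, is.numeric, logical(1))])
  sds <- apply(x, 2L, sd)
  fixed <- sds < 1e-10 | sds < constant_cv * abs(colMeans(x))
  fixed_values <- colMeans(x[, fixed, drop = FALSE])
  x <- x[, !fixed, drop = FALSE]
  if (!ncol(x))
    stop_dropsol("all features are constant", "dropsol_fit_error")
  center <- colMeans(x); scale <- apply(x, 2L, sd)
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  cw <- if (class_weights) {
    tb <- table(y); setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
  } else NULL
  fit <- if (kernel == "linear")
    e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE,
               class.weights = cw)
  else
    e1071::svm(xs, y, kernel = "polynomial", degree = 2L, gamma = 1,
               coef0 = 1, cost = cost, scale = FALSE, class.weights = cw)
  dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")[, 1L]
  platt <- suppressWarnings(
    coef(glm((y == "aggregated") ~ dv, family = binomial())))
  structure(list(fit = fit, kernel = kernel, cost = cost,
                 platt = unname(platt),
                 center = center, scale = scale,
                 features = colnames(x),
                 fixed_features = fixed_values,
                 precipitant = precipitant,
                 ranges = apply(x, 2L, range),
                 counts = table(y),
                 class_weights = class_weights, constant_cv = constant_cv,
                 training = list(points = points, labels = y)),
            class = "phase_model")
}

canonical_labels <- function(labels) {
  if (is.numeric(labels))
    labels <- ifelse(labels > 0, "aggregated", "mixed")
  factor(as.character(labels), levels = c("mixed", "aggregated"))
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("phase_model (%s kernel): %s features [%s]; %d mixed / %d aggregated\n",
              x$kernel, length(x$features), paste(x$features, collapse = ", "),
              x$counts[["mixed"]], x$counts[["aggregated"]]))
  invisible(x)
}

# decision values on raw-unit compositions
decision_values <- function(model, newdata) {
  x <- matrix(NA_real_, nrow(newdata), length(model$features),
              dimnames = list(NULL, model$features))
  for (f in model$features) {
    if (!f %in% names(newdata))
      stop_dropsol(sprintf("query lacks feature '%s'", f),
                   "dropsol_query_error")
    x[, f] <- newdata[[f]]
  }
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  attr(predict(model$fit, xs, decision.values = TRUE),
       "decision.values")[, 1L]
}

#' Aggregation probability at queried compositions
#'
#' @param model a [fit_phase_model()] result.
#' @param newdata data frame with the model's feature columns, in the raw
#'   units the model was trained on.
#' @return probabilities in \code{[0, 1]}; attribute \code{"extrapolated"}
#'   flags queries outside the training range of any feature.
#' @export
aggregation_probability <- function(model, newdata) {
  dv <- decision_values(model, newdata)
  p <- plogis(model$platt[1L] + model$platt[2L] * dv)
  extra <- rep(FALSE, nrow(newdata))
  for (f in model$features)
    extra <- extra | newdata[[f]] < model$ranges[1L, f] |
      newdata[[f]] > model$ranges[2L, f]
  attr(p, "extrapolated") <- extra
  p
}

# refit with the same hyperparameters on resampled training rows
refit_phase_model <- function(model, idx) {
  fit_phase_model(model$training$points[idx, , drop = FALSE],
                  model$training$labels[idx],
                  kernel = model$kernel, cost = model$cost,
                  precipitant = model$precipitant, min_per_class = 1L,
                  class_weights = model$class_weights,
                  constant_cv = model$constant_cv)
}

# query row at given precipitant values with other features fixed
query_frame <- function(model, precipitant_values, protein_conc = NULL,
                        additives = NULL) {
  n <- length(precipitant_values)
  q <- data.frame(x = precipitant_values)
  names(q) <- model$precipitant
  for (f in setdiff(model$features, model$precipitant)) {
    v <- if (!is.null(additives) && f %in% names(additives)) additives[[f]]
    else if (!is.null(protein_conc) && f == "protein") protein_conc
    else 0
    q[[f]] <- rep(v, n)
  }
  q
}

# precipitant value where p crosses 0.5, by bisection; NA if unbracketed
find_crossing <- function(model, lo, hi, protein_conc, additives,
                          tol = 0.01) {
  pf <- function(x) aggregation_probability(
    model, query_frame(model, x, protein_conc, additives))
  p_ends <- pf(c(lo, hi))
  if (p_ends[1L] >= 0.5) return(structure(NA_real_, side = "below"))
  if (p_ends[2L] < 0.5) return(structure(NA_real_, side = "above"))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pf(mid) < 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Relative solubility with bootstrap uncertainty
#'
#' The relative solubility at a stated protein concentration is the
#' precipitant concentration at which the aggregation probability crosses
#' 0.5 along the precipitant axis (bisection to 0.01 w/v \%). Its standard
#' deviation — the thickness of the phase boundary — is the standard
#' deviation of that crossing over \code{B} bootstrap resamples of the
#' training droplets, each refitted with the same hyperparameters.
#'
#' @param model a [fit_phase_model()] whose features include the
#'   precipitant.
#' @param protein_conc protein concentration (mg/mL) at which the boundary
#'   is read; required if protein is a model feature.
#' @param additives named list/vector of additive concentrations at which
#'   to read the boundary (features not named default to 0).
#' @param B bootstrap resamples (default 200).
#' @param seed integer seed for the bootstrap.
#' @param window droplets within \code{protein_conc * (1 +/- window)} must
#'   exist when protein is a feature.
#' @param tol bisection tolerance (w/v \%).
#' @param on_unbracketed \code{"error"} (default) or \code{"censor"}: what
#'   to do when p never crosses 0.5 inside the data range — a screen whose
#'   solubility exceeds the sampled precipitant range (side \code{"above"})
#'   or lies below it (side \code{"below"}).
#' @return object of class \code{solubility_result}: \code{value} (w/v \%),
#'   \code{sd}, \code{band} (value +/- sd), \code{n_droplets}, \code{B},
#'   \code{censored} (NA or side).
#' @export
relative_solubility <- function(model, protein_conc = NULL, additives = NULL,
                                B = 200L, seed = 1L, window = 0.2,
                                tol = 0.01,
                                on_unbracketed = c("error", "censor")) {
  on_unbracketed <- match.arg(on_unbracketed)
  if (!model$precipitant %in% model$features)
    stop_dropsol("precipitant is not a free feature of this model",
                 "dropsol_query_error")
  if ("protein" %in% model$features) {
    if (is.null(protein_conc))
      stop_dropsol("protein_conc required (protein is a model feature)",
                   "dropsol_query_error")
    pr <- model$training$points$protein
    if (!any(pr >= protein_conc * (1 - window) &
             pr <= protein_conc * (1 + window)))
      stop_dropsol(sprintf(
        "no droplets within %.0f%% of protein = %g mg/mL", 100 * window,
        protein_conc), "dropsol_query_error")
  }
  lo <- model$ranges[1L, model$precipitant]
  hi <- model$ranges[2L, model$precipitant]
  value <- find_crossing(model, lo, hi, protein_conc, additives, tol)
  if (is.na(value)) {
    side <- attr(value, "side")
    if (on_unbracketed == "error")
      stop_dropsol(sprintf(
        "the boundary could not be determined: p never crosses 0.5 (%s data range)",
        ifelse(side == "above", "above", "below")),
        "dropsol_unbracketed_error", side = side)
    return(structure(list(protein_conc = protein_conc, value = NA_real_,
                          sd = NA_real_, band = c(NA_real_, NA_real_),
                          n_droplets = nrow(model$training$points),
                          B = 0L, censored = side,
                          precipitant = model$precipitant),
                     class = "solubility_result"))
  }
  n <- nrow(model$training$points)
  set.seed(seed)
  boots <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bm <- tryCatch(refit_phase_model(model, idx), error = function(e) NULL)
    if (is.null(bm)) next
    blo <- bm$ranges[1L, model$precipitant]
    bhi <- bm$ranges[2L, model$precipitant]
    boots[b] <- find_crossing(bm, blo, bhi, protein_conc, additives, tol)
  }
  boots <- boots[!is.na(boots)]
  sdv <- if (length(boots) >= 2L) sd(boots) else NA_real_
  structure(list(protein_conc = protein_conc, value = as.numeric(value),
                 sd = sdv, band = c(value - sdv, value + sdv),
                 n_droplets = n, B = B, n_boot_ok = length(boots),
                 censored = NA_character_,
                 precipitant = model$precipitant),
            class = "solubility_result")
}

#' @export
print.solubility_result <- function(x, ...) {
  if (!is.na(x$censored)) {
    cat(sprintf(
      "relative solubility: not bracketed (%s the sampled %s range), n = %d\n",
      ifelse(x$censored == "above", "above", "below"), x$precipitant,
      x$n_droplets))
  } else {
    cat(sprintf("relative solubility: %.2f +/- %.2f w/v%% %s (n = %d, B = %d)\n",
                x$value, x$sd, x$precipitant, x$n_droplets, x$B))
  }
  invisible(x)
}

#' Aggregation-probability solubility curve along the precipitant axis
#'
#' @inheritParams relative_solubility
#' @param grid precipitant values to evaluate.
#' @return data frame \code{precipitant}, \code{p} (raw probability) and
#'   \code{p_smooth} (isotonic-regression smoothed, guaranteed
#'   nondecreasing); attribute \code{"monotone"} says whether the raw curve
#'   was already nondecreasing.
#' @export
solubility_curve <- function(model, grid, protein_conc = NULL,
                             additives = NULL) {
  p <- as.numeric(aggregation_probability(
    model, query_frame(model, grid, protein_conc, additives)))
  mono <- !is.unsorted(p)
  ps <- if (mono) p else isoreg(grid, p)$yf
  structure(data.frame(precipitant = grid, p = p, p_smooth = ps),
            monotone = mono)
}

#' Raw-unit weight vector of a linear-kernel phase model
#'
#' @param model a linear-kernel [fit_phase_model()].
#' @return named numeric: boundary-normal weights per feature in raw
#'   concentration units, plus attribute \code{"intercept"}; the decision
#'   boundary is \code{sum(w * x) + intercept = 0}.
#' @export
linear_weights <- function(model) {
  if (model$kernel != "linear")
    stop_dropsol("linear_weights needs a linear-kernel model",
                 "dropsol_query_error")
  w_std <- drop(t(model$fit$coefs) %*% model$fit$SV)
  w_raw <- w_std / model$scale
  intercept <- -model$fit$rho - sum(w_std * model$center / model$scale)
  structure(setNames(w_raw, model$features), intercept = intercept)
}

#' Held-out log-likelihood comparison of the two kernels
#'
#' Splits the data once, fits both kernels on the training part, and
#' evaluates the Bernoulli log-likelihood of the held-out calls under each
#' Platt-calibrated probability surface. Used to decide when the curved
#' (poly2) boundary is warranted.
#'
#' @inheritParams fit_phase_model
#' @param prop training fraction.
#' @param seed split seed.
#' @param margin poly2 is selected only if it beats linear by this much
#'   (total held-out log-likelihood).
#' @return list: \code{loglik} (named, per kernel), \code{kernel} (the
#'   selection).
#' @export
compare_kernels <- function(points, labels, prop = 0.7, seed = 1L, cost = 1,
                            precipitant = "PEG", margin = 2,
                            min_per_class = 50L) {
  y <- canonical_labels(labels)
  set.seed(seed)
  n <- nrow(points)
  tr <- sample.int(n, round(prop * n))
  ll <- c(linear = NA_real_, poly2 = NA_real_)
  eps <- 1e-9
  for (k in names(ll)) {
    m <- fit_phase_model(points[tr, , drop = FALSE], y[tr], kernel = k,
                         cost = cost, precipitant = precipitant,
                         min_per_class = min_per_class)
    p <- pmin(pmax(aggregation_probability(
      m, points[-tr, , drop = FALSE]), eps), 1 - eps)
    yy <- y[-tr] == "aggregated"
    ll[k] <- sum(log(ifelse(yy, p, 1 - p)))
  }
  list(loglik = ll,
       kernel = if (ll["poly2"] > ll["linear"] + margin) "poly2" else "linear")
}
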