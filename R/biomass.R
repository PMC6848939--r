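#' Fit a single-leaf weight-to-area model
#'
#' Relates single-leaf weight (g) to single-leaf area (mm2) from a
#' reference sample of leaves measured destructively. Three model kinds
#' are supported:
#'
#' * `"density"` (default): the leaf density `rho = W / Area` (g/mm2),
#'   estimated as the mean per-sample ratio; area = weight / rho.
#' * `"mlp"`: a small fully connected network with one hidden layer
#'   (default width 8, logistic activations, linear output), fitted
#'   full-batch on standardized data.
#' * `"polynomial"`: least-squares polynomial of `degree`.
#'
#' The fitted map must be strictly increasing over the observed weight
#' range — that is what makes the inversion in [weight_from_area()]
#' well-posed — and the fit is rejected otherwise.
#'
#' @param samples Data frame with columns `weight_g` and `area_mm2`
#'   (one row per reference leaf; a `species` column is carried along
#'   if present).
#' @param kind `"density"`, `"mlp"` or `"polynomial"`.
#' @param degree Polynomial degree (kind `"polynomial"`), default 2.
#' @param hidden Hidden width (kind `"mlp"`), default 8.
#' @param decay Weight decay for the network, default 1e-4.
#' @param maxit Optimizer iterations for the network, default 2000.
#' @param seed RNG seed for the network's random initialization,
#'   default 42.
#' @return An object of class `weight_area_model`.
#' @export
fit_weight_area_model <- function(samples,
                                  kind = c("density", "mlp", "polynomial"),
                                  degree = 2L, hidden = 8L, decay = 1e-4,
                                  maxit = 2000L, seed = 42L) {
  kind <- match.arg(kind)
  stopifnot(all(c("weight_g", "area_mm2") %in% names(samples)))
  w <- as.numeric(samples$weight_g)
  a <- as.numeric(samples$area_mm2)
  if (any(w <= 0) || any(a <= 0)) {
    stop("weights and areas must be positive", call. = FALSE)
  }
  n <- length(w)
  min_n <- c(density = 1L, polynomial = 2L, mlp = 4L)[kind]
  if (n < min_n) {
    stop(sprintf("kind '%s' needs at least %d samples", kind, min_n),
         call. = FALSE)
  }
  pars <- switch(
    kind,
    density = list(rho = mean(w / a)),
    polynomial = {
      if (n < degree + 1L) {
        stop("under-determined polynomial: need degree + 1 samples",
             call. = FALSE)
      }
      fit <- stats::lm(a ~ stats::poly(w, degree, raw = TRUE))
      list(coef = unname(stats::coef(fit)), degree = degree)
    },
    mlp = {
      ow <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(ow)) assign(".Random.seed", ow,
                                       envir = globalenv()))
      set.seed(seed)
      mw <- mean(w); sw <- stats::sd(w)
      ma <- mean(a); sa <- stats::sd(a)
      net <- nnet::nnet(x = matrix((w - mw) / sw), y = (a - ma) / sa,
                        size = hidden, linout = TRUE, decay = decay,
                        maxit = maxit, trace = FALSE)
      h <- hidden
      W1 <- matrix(net$wts[seq_len(2L * h)], nrow = h, byrow = TRUE)
      W2 <- net$wts[2L * h + seq_len(h + 1L)]
      list(W1 = W1, W2 = W2, hidden = h,
           mw = mw, sw = sw, ma = ma, sa = sa)
    }
  )
  model <- structure(
    list(kind = kind, pars = pars,
         weight_range = range(w), area_range = range(a),
         n = n, train_rmse = NA_real_),
    class = "weight_area_model"
  )
  # monotonicity over the observed weight range (widened when the
  # sample collapses to a point, e.g. a single reference leaf)
  wr <- model$weight_range
  if (diff(wr) <= 0) wr <- wr * c(0.5, 1.5)
  grid <- seq(wr[1], wr[2], length.out = 201)
  fx <- predict_area(model, grid)
  if (any(diff(fx) <= 0)) {
    stop(paste("fitted model is not strictly increasing over the",
               "observed weight range; use a simpler kind",
               "(e.g. 'density')"), call. = FALSE)
  }
  model$train_rmse <- sqrt(mean((predict_area(model, w) - a)^2))
  model$area_range <- range(fx)
  model
}

# Forward evaluation: predicted single-leaf area for single-leaf weight.
predict_area <- function(model, w) {
  p <- model$pars
  switch(model$kind,
         density = w / p$rho,
         polynomial = {
           X <- outer(w, 0:p$degree, "^")
           as.numeric(X %*% p$coef)
         },
         mlp = {
           x <- (w - p$mw) / p$sw
           Z <- 1 / (1 + exp(-(p$W1[, 1] %o% rep(1, length(x)) +
                                 p$W1[, 2] %o% x)))
           y <- p$W2[1] + as.numeric(p$W2[-1] %*% Z)
           y * p$sa + p$ma
         })
}

#' @export
print.weight_area_model <- function(x, ...) {
  cat(sprintf("<weight_area_model> kind = %s, n = %d, train RMSE %.3g mm^2\n",
              x$kind, x$n, x$train_rmse))
  if (x$kind == "density") {
    cat(sprintf("  rho = %.6g g/mm^2\n", x$pars$rho))
  }
  cat(sprintf("  weight range %.3g-%.3g g -> area %.4g-%.4g mm^2\n",
              x$weight_range[1], x$weight_range[2],
              x$area_range[1], x$area_range[2]))
  invisible(x)
}

#' Predict single-leaf area from plug harvest weight
#'
#' The manual protocol weighs all leaves of a plug together and counts
#' them, so the model is fed the mean single-leaf weight
#' `Wleaves / Nleaves` and returns the predicted single-leaf area.
#'
#' @param model A [fit_weight_area_model()] fit.
#' @param Wleaves Total leaf weight of the plug, g (vectorized).
#' @param Nleaves Number of leaves collected for the plug (>= 1).
#' @return Predicted single-leaf area, mm2.
#' @export
area_from_weight <- function(model, Wleaves, Nleaves = 1) {
  stopifnot(inherits(model, "weight_area_model"), all(Nleaves >= 1))
  w <- Wleaves / Nleaves
  lo <- model$weight_range[1] / 3
  hi <- model$weight_range[2] * 3
  if (any(w < lo | w > hi)) {
    warning("mean leaf weight outside 3x the training range: extrapolating",
            call. = FALSE)
  }
  predict_area(model, w)
}

#' Invert the model: leaf weight from measured area
#'
#' Numerically inverts the (strictly increasing) weight-to-area map by
#' bracketed root finding, recovering the single-leaf weight whose
#' predicted area equals the vision-measured area. For the density
#' model this is exactly `weight = rho * area`.
#'
#' @param model A [fit_weight_area_model()] fit.
#' @param AVM Vision-measured leaf area, mm2 (vectorized).
#' @return Predicted single-leaf weight, g.
#' @export
weight_from_area <- function(model, AVM) {
  stopifnot(inherits(model, "weight_area_model"))
  if (model$kind == "density") {
    out <- model$pars$rho * AVM
    out_of_train <- AVM < model$area_range[1] | AVM > model$area_range[2]
    if (any(out_of_train)) {
      warning("area outside the training output range: extrapolating",
              call. = FALSE)
    }
    return(out)
  }
  lo <- model$weight_range[1] / 3
  hi <- model$weight_range[2] * 3
  flo <- predict_area(model, lo)
  fhi <- predict_area(model, hi)
  vapply(AVM, function(a) {
    if (a < flo || a > fhi) {
      stop(sprintf(paste("area %.4g mm^2 outside the attainable range",
                         "[%.4g, %.4g]"), a, flo, fhi), call. = FALSE)
    }
    if (a < model$area_range[1] || a > model$area_range[2]) {
      warning("area outside the training output range: extrapolating",
              call. = FALSE)
    }
    stats::uniroot(function(w) predict_area(model, w) - a,
                   lower = lo, upper = hi,
                   tol = 1e-12 * max(a, 1))$root
  }, numeric(1))
}

#' Polynomial growth-curve fit over days
#'
#' Manual measurements exist only at a few harvest days; trait values
#' at the unmeasured days are interpolated by a least-squares
#' polynomial in the day index.
#'
#' @param series Data frame with columns `das` and `value`.
#' @param degree Polynomial degree; needs at least `degree + 1` points.
#' @param predict_das Days at which to evaluate the fit (default: the
#'   input days).
#' @return Object of class `growth_curve`: `coef`, `fitted` tibble
#'   (`das`, `value`, `fitted`, `residual`), `predicted` tibble
#'   (`das`, `value`).
#' @export
fit_growth_curve <- function(series, degree = 2L, predict_das = NULL) {
  stopifnot(all(c("das", "value") %in% names(series)))
  x <- as.numeric(series$das); y <- as.numeric(series$value)
  if (length(x) < degree + 1L) {
    stop("under-determined: need at least degree + 1 points", call. = FALSE)
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  cf <- unname(stats::coef(fit))
  evalp <- function(z) as.numeric(outer(z, 0:degree, "^") %*% cf)
  if (is.null(predict_das)) predict_das <- x
  structure(
    list(coef = cf, degree = degree,
         fitted = tibble::tibble(das = x, value = y, fitted = evalp(x),
                                 residual = y - evalp(x)),
         predicted = tibble::tibble(das = predict_das,
                                    value = evalp(predict_das))),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> degree %d, RMSE %.4g over %d days\n",
              x$degree, sqrt(mean(x$fitted$residual^2)), nrow(x$fitted)))
  invisible(x)
}

#' Leaf reference samples and model serialization
#'
#' Reference leaves are stored as CSV with columns `species`,
#' `weight_g`, `area_mm2`; fitted models as JSON carrying the kind, the
#' parameters and the training ranges.
#'
#' @param path File path.
#' @param model A `weight_area_model`.
#' @return `read_leaf_samples()` returns a tibble; `read_weight_area_model()`
#'   a `weight_area_model`; writers return `path` invisibly.
#' @export
read_leaf_samples <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_leaf_samples
#' @export
write_weight_area_model <- function(model, path) {
  stopifnot(inherits(model, "weight_area_model"))
  obj <- unclass(model)
  if (model$kind == "mlp") obj$pars$W1 <- as.data.frame(obj$pars$W1)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_leaf_samples
#' @export
read_weight_area_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "mlp") {
    obj$pars$W1 <- as.matrix(obj$pars$W1)
    dimnames(obj$pars$W1) <- NULL
  }
  obj$weight_range <- as.numeric(obj$weight_range)
  obj$area_range <- as.numeric(obj$area_range)
  structure(obj, class = "weight_area_model")
}

#' Broom-style accessors for weight-area models
#'
#' `tidy()` returns one row per parameter; `glance()` a one-row model
#' summary.
#'
#' @param x A `weight_area_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy weight_area_model
#' @export
tidy.weight_area_model <- function(x, ...) {
  p <- x$pars
  switch(x$kind,
         density = tibble::tibble(term = "rho", estimate = p$rho),
         polynomial = tibble::tibble(
           term = paste0("w^", 0:p$degree), estimate = p$coef),
         mlp = tibble::tibble(
           term = c(paste0("hidden", seq_len(p$hidden), "_bias"),
                    paste0("hidden", seq_len(p$hidden), "_w"),
                    "out_bias", paste0("out_w", seq_len(p$hidden))),
           estimate = c(p$W1[, 1], p$W1[, 2], p$W2)))
}

#' @rdname tidy.weight_area_model
#' @method glance weight_area_model
#' @export
glance.weight_area_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$n, train_rmse = x$train_rmse,
                 weight_min = x$weight_range[1],
                 weight_max = x$weight_range[2])
}
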