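# Maximum-entropy presence-background suitability model.
#
# The model is the Gibbs distribution over background cells
#   q_w(x) = exp(w . f(x)) / Z(w),   Z(w) = sum_background exp(w . f(x)),
# fitted by minimizing the convex penalized objective
#   J(w) = -(1/m) sum_presences w . f(x)
#          + ln sum_background exp(w . f(x)) - ln B
#          + sum_j beta_j |w_j|,
# whose smooth part has gradient E_q[f] - mean_presence[f]. Optimization
# is a monotone proximal-gradient descent: gradient step on the smooth
# part with backtracking line search, soft-thresholding for the L1 term.
# The fit is deterministic given its inputs.

#' Build a Maxent feature set from a variable table
#'
#' Variables are first scaled to [0, 1] using min/max over the BACKGROUND
#' table (scaling constants must come from the background so that presence
#' and background rows receive identical transforms). Feature classes:
#' linear (scaled value z), quadratic (z^2), product (pairwise z_i * z_j),
#' and forward hinge max(0, (z - k)/(1 - k)) at a fixed grid of knots k.
#'
#' @param background data.frame of background variable values (columns =
#'   variables); defines the scaling.
#' @param vars Character vector of variable names to use.
#' @param classes Feature classes, subset of
#'   `c("linear", "quadratic", "product", "hinge")`.
#' @param n_knots Number of evenly spaced hinge knots per variable over
#'   [0, 1) (default 20).
#' @return List of class `feature_set`: `vars`, `classes`, `scaling`
#'   (data.frame var, min, max), `defs` (data.frame var, class, knot),
#'   `n_knots`. Variables constant over the background are dropped with a
#'   warning.
#' @export
build_features <- function(background, vars,
                           classes = c("linear", "quadratic", "hinge"),
                           n_knots = 20) {
  stopifnot(all(vars %in% names(background)))
  classes <- match.arg(classes, c("linear", "quadratic", "product", "hinge"),
                       several.ok = TRUE)
  mins <- vapply(vars, function(v) min(background[[v]]), numeric(1))
  maxs <- vapply(vars, function(v) max(background[[v]]), numeric(1))
  const <- maxs - mins == 0
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(vars[const], collapse = ", "))
    vars <- vars[!const]; mins <- mins[!const]; maxs <- maxs[!const]
  }
  if (length(vars) == 0) stop("no non-constant variables left")
  defs <- list()
  for (v in vars) {
    if ("linear" %in% classes)
      defs[[length(defs) + 1]] <- data.frame(var = v, class = "linear", knot = NA_real_)
    if ("quadratic" %in% classes)
      defs[[length(defs) + 1]] <- data.frame(var = v, class = "quadratic", knot = NA_real_)
    if ("hinge" %in% classes) {
      knots <- (seq_len(n_knots) - 1) / n_knots
      defs[[length(defs) + 1]] <- data.frame(var = v, class = "hinge", knot = knots)
    }
  }
  if ("product" %in% classes && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2)
    for (k in seq_len(ncol(cmb)))
      defs[[length(defs) + 1]] <- data.frame(
        var = paste(cmb[1, k], cmb[2, k], sep = "*"),
        class = "product", knot = NA_real_)
  }
  structure(list(vars = vars, classes = classes,
                 scaling = data.frame(var = vars, min = mins, max = maxs),
                 defs = do.call(rbind, defs), n_knots = n_knots),
            class = "feature_set")
}

#' Evaluate a feature set on a variable table
#'
#' @param fs A [build_features()] feature set.
#' @param values data.frame with the feature set's variables as columns.
#' @return Numeric matrix, one column per feature. Scaled features lie in
#'   [0, 1] on the background the set was built from; rows outside the
#'   background range extrapolate linearly (no clamping).
#' @export
feature_matrix <- function(fs, values) {
  z <- sapply(fs$vars, function(v) {
    s <- fs$scaling[fs$scaling$var == v, ]
    (values[[v]] - s$min) / (s$max - s$min)
  })
  z <- matrix(z, ncol = length(fs$vars),
              dimnames = list(NULL, fs$vars))
  cols <- vector("list", nrow(fs$defs))
  for (i in seq_len(nrow(fs$defs))) {
    d <- fs$defs[i, ]
    cols[[i]] <- switch(d$class,
      linear = z[, d$var],
      quadratic = z[, d$var]^2,
      hinge = pmax(0, (z[, d$var] - d$knot) / (1 - d$knot)),
      product = {
        vv <- strsplit(d$var, "*", fixed = TRUE)[[1]]
        z[, vv[1]] * z[, vv[2]]
      })
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste0(fs$defs$var, ":", fs$defs$class,
                        ifelse(is.na(fs$defs$knot), "",
                               paste0("@", format(fs$defs$knot))))
  X
}

# log-sum-exp with overflow guard
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a maximum-entropy presence-background model
#'
#' @param X_pres Presence feature matrix (m x J), from [feature_matrix()].
#' @param X_bg Background feature matrix (B x J), same feature set.
#' @param fs The [build_features()] feature set (stored in the model).
#' @param lambda Overall regularization multiplier; per-feature weights
#'   are `beta_j = lambda * sd_j(background) / sqrt(m)`.
#' @param beta Optional explicit per-feature L1 weights (overrides
#'   `lambda`).
#' @param max_iter Maximum proximal-gradient iterations.
#' @param tol Convergence: stop when the objective improves by less than
#'   `tol` (default 1e-8).
#' @return Object of class `maxent_model`: coefficients `w`, `lnZ` over
#'   the background, entropy `H` of the fitted background distribution,
#'   `beta`, sizes `m` and `B`, objective trace, convergence flag.
#' @export
fit_maxent <- function(X_pres, X_bg, fs = NULL, lambda = 1.0, beta = NULL,
                       max_iter = 1000, tol = 1e-8) {
  m <- nrow(X_pres); B <- nrow(X_bg); J <- ncol(X_bg)
  stopifnot(m >= 2, B >= m, ncol(X_pres) == J)
  if (is.null(beta)) {
    s <- apply(X_bg, 2, stats::sd)
    beta <- lambda * s / sqrt(m)
  }
  stopifnot(length(beta) == J, all(beta >= 0))
  fbar <- colMeans(X_pres)
  smooth_obj <- function(w) {
    lse(drop(X_bg %*% w)) - log(B) - sum(w * fbar)
  }
  grad <- function(w) {
    eta <- drop(X_bg %*% w)
    q <- exp(eta - lse(eta))
    drop(crossprod(X_bg, q)) - fbar
  }
  w <- rep(0, J)
  f_w <- smooth_obj(w)
  obj <- f_w + sum(beta * abs(w))
  trace <- obj
  L <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    repeat {
      w_new <- sign(w - g / L) * pmax(0, abs(w - g / L) - beta / L)
      dw <- w_new - w
      f_new <- smooth_obj(w_new)
      if (f_new <= f_w + sum(g * dw) + L / 2 * sum(dw^2) + 1e-12) break
      L <- L * 2
      if (L > 1e12) break
    }
    obj_new <- f_new + sum(beta * abs(w_new))
    if (obj_new > obj + 1e-12) break  # monotone safeguard
    improve <- obj - obj_new
    w <- w_new; f_w <- f_new; obj <- obj_new
    trace <- c(trace, obj)
    L <- max(L / 1.5, 1e-4)
    if (improve < tol) { converged <- TRUE; break }
  }
  # declare convergence also when the L1 subgradient optimality (KKT)
  # residual is essentially zero, even if the iteration cap was reached
  if (!converged) {
    g <- grad(w)
    res <- max(abs(ifelse(w != 0, g + beta * sign(w),
                          pmax(0, abs(g) - beta))))
    if (res < 1e-3) converged <- TRUE
  }
  eta <- drop(X_bg %*% w)
  lnZ <- lse(eta)
  q <- exp(eta - lnZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(list(w = stats::setNames(w, colnames(X_bg)), features = fs,
                 lnZ = lnZ, H = H, beta = beta, m = m, B = B,
                 objective = obj, trace = trace, converged = converged,
                 iterations = length(trace) - 1),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d features (%d nonzero), m = %d presences, B = %d background\n",
              length(x$w), sum(x$w != 0), x$m, x$B))
  cat(sprintf("  objective %.6f after %d iterations (converged: %s); H = %.4f\n",
              x$objective, x$iterations, x$converged, x$H))
  invisible(x)
}

#' Predict raw relative occurrence rates
#'
#' `raw(x) = exp(w . f(x)) / Z` with Z the model's background partition
#' function; with `renormalize = TRUE` values are rescaled to sum to 1
#' over the supplied rows (the convention used for AICc over a prediction
#' extent).
#'
#' @param model A [fit_maxent()] model.
#' @param X Feature matrix from [feature_matrix()] with the model's
#'   feature set.
#' @param renormalize Rescale to sum to 1 over the rows of `X`.
#' @return Numeric vector of raw rates.
#' @export
predict_raw <- function(model, X, renormalize = FALSE) {
  stopifnot(ncol(X) == length(model$w))
  eta <- drop(X %*% model$w)
  raw <- exp(eta - model$lnZ)
  if (renormalize) raw <- raw / sum(raw)
  raw
}

#' Predict cloglog suitability
#'
#' `cloglog(x) = 1 - exp(-exp(H) * raw(x))` with H the entropy of the
#' fitted background distribution; values lie in [0, 1] and are strictly
#' monotone in raw. A model with all-zero coefficients gives the constant
#' 1 - exp(-1).
#'
#' @inheritParams predict_raw
#' @return Numeric vector of suitabilities in [0, 1].
#' @export
predict_cloglog <- function(model, X) {
  raw <- predict_raw(model, X)
  pmin(1, 1 - exp(-exp(model$H) * raw))
}

#' Predict a suitability surface over a stack
#'
#' @param model A [fit_maxent()] model (must carry its feature set).
#' @param stack A [climate_stack()].
#' @param transform `"cloglog"` (default) or `"raw"`. Raw surfaces are
#'   renormalized to sum to 1 over the valid cells of the stack.
#' @return Numeric matrix aligned to the stack, NA on masked cells.
#' @export
predict_stack <- function(model, stack, transform = c("cloglog", "raw")) {
  transform <- match.arg(transform)
  if (is.null(model$features)) stop("model carries no feature set")
  idx <- which(stack$mask)
  vals <- as.data.frame(lapply(stack$layers, function(m) m[idx]))
  X <- feature_matrix(model$features, vals)
  out <- matrix(NA_real_, stack$nrow, stack$ncol)
  out[idx] <- if (transform == "cloglog") predict_cloglog(model, X)
              else predict_raw(model, X, renormalize = TRUE)
  out
}
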