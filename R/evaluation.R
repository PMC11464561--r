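# Train/test partitioning, discrimination metrics and AICc model ranking.

#' Partition occurrences into train and test sets
#'
#' Four schemes: `random` is a seeded 50/50 split (odd point goes to
#' train); `elevation` trains on points strictly above the median
#' elevation; `longitude` and `latitude` train on the side at or below the
#' median coordinate. Points exactly at the median therefore go to train
#' for the coordinate schemes and to test for the elevation scheme.
#'
#' @param points An [occurrence_set()] with >= 4 points.
#' @param scheme One of `"random"`, `"elevation"`, `"longitude"`,
#'   `"latitude"`.
#' @param seed Integer seed (random scheme only).
#' @return List of class `partition`: `scheme`, `train`, `test`,
#'   `split_stat` (median for the three median schemes, NA for random),
#'   `seed`.
#' @export
partition <- function(points, scheme = c("random", "elevation",
                                         "longitude", "latitude"),
                      seed = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(points)
  if (n < 4) stop("need at least 4 points to partition")
  split_stat <- NA_real_
  if (scheme == "random") {
    if (is.null(seed)) stop("random scheme requires a seed")
    n_train <- ceiling(n / 2)
    idx <- with_seed(seed, sample.int(n, n_train))
    in_train <- seq_len(n) %in% idx
  } else if (scheme == "elevation") {
    if (is.null(points$elev) || anyNA(points$elev))
      stop("elevation scheme requires an elevation attribute on all points")
    split_stat <- stats::median(points$elev)
    in_train <- points$elev > split_stat
  } else {
    v <- if (scheme == "longitude") points$lon else points$lat
    split_stat <- stats::median(v)
    in_train <- v <= split_stat
  }
  train <- points[in_train, , drop = FALSE]
  test <- points[!in_train, , drop = FALSE]
  class(train) <- class(points); class(test) <- class(points)
  structure(list(scheme = scheme, train = train, test = test,
                 split_stat = split_stat, seed = seed),
            class = "partition")
}

#' Area under the ROC curve (presence vs background)
#'
#' Mann-Whitney formulation: the probability that a random presence scores
#' above a random background point, ties counted 1/2. Computed from ranks.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); B <- length(background_scores)
  if (m == 0 || B == 0) stop("empty score set")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * B)
}

#' Maximum-TSS threshold
#'
#' Sweeps every distinct observed score as a candidate threshold t with
#' prediction rule score >= t -> presence; TSS(t) = sensitivity +
#' specificity - 1. Returns the maximizing threshold; ties are broken
#' toward the smallest t (the widest predicted-presence extent).
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return List of class `tss_threshold`: `threshold`, `tss`,
#'   `sensitivity`, `specificity`.
#' @export
tss_threshold <- function(presence_scores, background_scores) {
  m <- length(presence_scores); B <- length(background_scores)
  if (m == 0 || B == 0) stop("empty score set")
  cand <- sort(unique(c(presence_scores, background_scores)))
  # vectorized sweep via cumulative counts of scores >= t
  sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(background_scores < t), numeric(1))
  tss <- sens + spec - 1
  # ties (up to float noise in sens + spec - 1) break to the smallest t
  best <- which(tss >= max(tss) - 1e-9)[1]
  structure(list(threshold = cand[best], tss = tss[best],
                 sensitivity = sens[best], specificity = spec[best]),
            class = "tss_threshold")
}

#' Sample-size-corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2K + 2K(K+1)/(n - K - 1)`. Undefined (NA) when
#' `n <= K + 1`.
#'
#' @param lnL Presence log-likelihood (sum over occurrences of the log of
#'   the extent-normalized raw prediction).
#' @param K Number of nonzero model coefficients.
#' @param n Number of occurrences.
#' @return AICc (NA when not rankable).
#' @export
aicc <- function(lnL, K, n) {
  ifelse(n - K - 1 > 0,
         -2 * lnL + 2 * K + 2 * K * (K + 1) / (n - K - 1),
         NA_real_)
}

# All non-empty subsets of the candidate variables, ordered by size then
# lexicographically; names like "MAT+MAP+P_cold".
variable_subsets <- function(vars = c("MAT", "MAP", "P_cold", "P_warm")) {
  subs <- unlist(lapply(seq_along(vars),
                        function(k) utils::combn(vars, k, simplify = FALSE)),
                 recursive = FALSE)
  stats::setNames(subs, vapply(subs, paste, character(1), collapse = "+"))
}

#' Fit one variable-subset model on a presence/background table pair
#'
#' Convenience wrapper: builds features (scaling from the background),
#' evaluates both matrices and fits.
#'
#' @param pres_tab,bg_tab data.frames of variable values at presences and
#'   background points.
#' @param vars Variables to include.
#' @param settings List: `classes`, `n_knots`, `lambda`, `max_iter`
#'   (defaults: linear+quadratic+hinge, 20 knots, lambda 1, 1000).
#' @return A [fit_maxent()] model.
#' @export
fit_subset_model <- function(pres_tab, bg_tab, vars, settings = list()) {
  st <- utils::modifyList(
    list(classes = c("linear", "quadratic", "hinge"), n_knots = 20,
         lambda = 1.0, max_iter = 1000), settings)
  fs <- build_features(bg_tab, vars, classes = st$classes,
                       n_knots = st$n_knots)
  X_bg <- feature_matrix(fs, bg_tab)
  X_pr <- feature_matrix(fs, pres_tab)
  fit_maxent(X_pr, X_bg, fs = fs, lambda = st$lambda,
             max_iter = st$max_iter)
}

#' Rank all variable-subset models by AICc
#'
#' For every non-empty subset of the candidate variables: fit on the
#' training presences, score train/test AUC against the shared background;
#' refit on ALL occurrences and compute the presence log-likelihood under
#' the extent-normalized raw prediction, K (nonzero coefficients), AICc
#' and delta-AICc. One shared background sample is used for every model so
#' the comparison is free of sampling noise.
#'
#' @param stack A [climate_stack()] (the prediction extent for AICc).
#' @param occurrences All occurrences (post-thinning), an
#'   [occurrence_set()].
#' @param part A [partition()] of those occurrences.
#' @param background A [sample_background()] result.
#' @param vars Candidate variables (default MAT, MAP, P_cold, P_warm).
#' @param settings Passed to [fit_subset_model()].
#' @param compute_auc Set FALSE to skip the train-split fits and report
#'   AICc only (faster for ranking studies).
#' @return data.frame sorted by AICc: model, auc_train, auc_test, lnL, K,
#'   n, aicc, delta_aicc, converged. Attribute `models` carries the
#'   full-data fitted models.
#' @export
rank_models <- function(stack, occurrences, part, background,
                        vars = c("MAT", "MAP", "P_cold", "P_warm"),
                        settings = list(), compute_auc = TRUE) {
  subs <- variable_subsets(vars)
  bg_tab <- background$points
  ex_all <- extract_at_points(stack, occurrences)
  if (!all(ex_all$valid))
    warning(sum(!ex_all$valid), " occurrence(s) on invalid cells dropped")
  all_tab <- ex_all[ex_all$valid, , drop = FALSE]
  idx <- which(stack$mask)
  extent_tab <- as.data.frame(lapply(stack$layers, function(m) m[idx]))
  if (compute_auc) {
    tr_tab <- extract_at_points(stack, part$train)
    te_tab <- extract_at_points(stack, part$test)
    tr_tab <- tr_tab[tr_tab$valid, , drop = FALSE]
    te_tab <- te_tab[te_tab$valid, , drop = FALSE]
  }
  n <- nrow(all_tab)
  rows <- vector("list", length(subs))
  models <- vector("list", length(subs))
  names(models) <- names(subs)
  for (nm in names(subs)) {
    v <- subs[[nm]]
    auc_tr <- auc_te <- NA_real_
    ok <- TRUE
    res <- tryCatch({
      if (compute_auc) {
        m_tr <- fit_subset_model(tr_tab, bg_tab, v, settings)
        fs <- m_tr$features
        sc_bg <- predict_raw(m_tr, feature_matrix(fs, bg_tab))
        auc_tr <- auc(predict_raw(m_tr, feature_matrix(fs, tr_tab)), sc_bg)
        auc_te <- auc(predict_raw(m_tr, feature_matrix(fs, te_tab)), sc_bg)
      }
      m_full <- fit_subset_model(all_tab, bg_tab, v, settings)
      fs <- m_full$features
      z_ext <- sum(predict_raw(m_full, feature_matrix(fs, extent_tab)))
      raw_occ <- predict_raw(m_full, feature_matrix(fs, all_tab)) / z_ext
      lnL <- sum(log(raw_occ))
      K <- sum(m_full$w != 0)
      models[[nm]] <- m_full
      list(lnL = lnL, K = K, converged = m_full$converged)
    }, error = function(e) { ok <<- FALSE; NULL })
    rows[[nm]] <- if (ok) {
      data.frame(model = nm, auc_train = auc_tr, auc_test = auc_te,
                 lnL = res$lnL, K = res$K, n = n,
                 aicc = aicc(res$lnL, res$K, n),
                 delta_aicc = NA_real_, converged = res$converged)
    } else {
      data.frame(model = nm, auc_train = NA_real_, auc_test = NA_real_,
                 lnL = NA_real_, K = NA_integer_, n = n, aicc = NA_real_,
                 delta_aicc = NA_real_, converged = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rankable <- tab$converged & !is.na(tab$aicc)
  if (any(rankable))
    tab$delta_aicc[rankable] <- tab$aicc[rankable] - min(tab$aicc[rankable])
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  attr(tab, "models") <- models
  tab
}
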