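# Exact D-optimal design construction on small coded candidate grids,
# saturated response-surface fitting on replicated responses, test-point
# validation at a stated confidence, and multi-response optimum
# selection. Grids here are tiny (a handful of runs), so subset search is
# exhaustive: exactness beats speed.

#' Coded experimental factor
#'
#' @param name factor name used in model formulas (e.g. `"x1"`).
#' @param coded_levels distinct coded levels, in the order they map to
#'   the physical levels.
#' @param labels physical meaning of each level (e.g. `"30 um"`).
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, coded_levels, labels = NULL) {
  if (anyDuplicated(coded_levels)) {
    stop("coded levels must be distinct", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(coded_levels)) {
    stop("labels must align with coded levels", call. = FALSE)
  }
  structure(list(name = name, coded_levels = coded_levels, labels = labels),
            class = "factor_spec")
}

#' Full-factorial candidate grid over coded factors
#'
#' Expands all combinations of the coded levels; the first factor varies
#' fastest, so a 3x2 grid lists the three levels of the first factor
#' within each level of the second.
#'
#' @param factors list of [factor_spec()] objects.
#' @return data.frame of coded candidate points, one column per factor.
#' @export
build_candidates <- function(factors) {
  stopifnot(length(factors) >= 1,
            all(vapply(factors, inherits, logical(1), "factor_spec")))
  levels <- lapply(factors, `[[`, "coded_levels")
  names(levels) <- vapply(factors, `[[`, character(1), "name")
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  attr(grid, "factors") <- factors
  grid
}

#' The default saturated two-factor response-surface model
#'
#' Five terms — intercept, both linear effects, the quadratic of the
#' three-level factor and the two-factor interaction — which saturate a
#' five-run design (one parameter per run).
#'
#' @param x1 name of the three-level factor.
#' @param x2 name of the two-level factor.
#' @return A model formula.
#' @export
saturated_model <- function(x1 = "x1", x2 = "x2") {
  stats::as.formula(
    sprintf("~ %s + %s + I(%s^2) + %s:%s", x1, x2, x1, x1, x2)
  )
}

# Expanded model matrix of a coded point set under a model formula.
expand_model <- function(model, points) {
  stats::model.matrix(model, data = as.data.frame(points))
}

#' Exact D-optimal subset of a candidate grid
#'
#' Enumerates every k-subset of the candidate points and returns the one
#' maximizing det(X'X) of the expanded model matrix. Ties are broken in
#' favour of the lowest lexicographic run indices. Intended for the small
#' grids of screening designs, where enumeration is exact and cheap.
#'
#' @param candidates data.frame of coded candidate points (rows = runs).
#' @param model model formula over the factor columns; defaults to the
#'   two-factor [saturated_model()].
#' @param k number of runs to select; must be at least the number of
#'   model terms and at most the number of candidates.
#' @return An object of class `doe_design`: `runs` (selected coded
#'   points), `indices`, `excluded` (the left-out candidate points),
#'   `model`, `X` (expanded matrix of the selected runs), `det`
#'   (det(X'X) attained).
#' @export
d_optimal_subset <- function(candidates, model = saturated_model(), k) {
  candidates <- as.data.frame(candidates)
  n <- nrow(candidates)
  Xall <- expand_model(model, candidates)
  p <- ncol(Xall)
  if (k < p) stop("k = ", k, " is below the ", p, " model terms; the fit ",
                  "would be singular", call. = FALSE)
  if (k > n) stop("k exceeds the number of candidates", call. = FALSE)
  combos <- utils::combn(n, k)
  best_det <- -Inf
  best_idx <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    d <- det(crossprod(Xall[idx, , drop = FALSE]))
    # strict improvement keeps the first (lexicographically lowest) subset
    if (is.null(best_idx) || d > best_det + 1e-9 * max(1, abs(best_det))) {
      best_det <- d
      best_idx <- idx
    }
  }
  if (!is.finite(best_det) || best_det <= 0) {
    stop("every candidate subset is singular under this model",
         call. = FALSE)
  }
  structure(
    list(runs = candidates[best_idx, , drop = FALSE],
         indices = best_idx,
         excluded = candidates[-best_idx, , drop = FALSE],
         model = model,
         X = Xall[best_idx, , drop = FALSE],
         det = best_det,
         candidates = candidates),
    class = "doe_design"
  )
}

# Coerce replicate responses to a runs x replicates matrix.
as_response_matrix <- function(responses, n_runs) {
  m <- as.matrix(responses)
  if (nrow(m) != n_runs) {
    stop("responses must have one row per design run", call. = FALSE)
  }
  if (ncol(m) < 2) {
    stop("need >= 2 replicates per run for a pooled variance", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Fit a response-surface model on replicated run responses
#'
#' Ordinary least squares of the per-run replicate means on the expanded
#' model matrix, with the replicate-pooled within-run variance as the
#' error estimate (degrees of freedom sum of (n_i - 1)). On a saturated
#' design the fit reproduces the run means exactly.
#'
#' @param design a `doe_design` from [d_optimal_subset()].
#' @param responses numeric matrix or data.frame, rows aligned with
#'   `design$runs`, columns = replicates.
#' @return An object of class `doe_fit`: term `coefficients`, the pooled
#'   variance `sigma2` and its `df`, replicate count per run `n_rep`,
#'   `fitted` means and `residuals`.
#' @export
fit_model <- function(design, responses) {
  stopifnot(inherits(design, "doe_design"))
  Y <- as_response_matrix(responses, nrow(design$runs))
  X <- design$X
  if (qr(X)$rank < ncol(X)) {
    stop("expanded design matrix is rank deficient", call. = FALSE)
  }
  means <- unname(rowMeans(Y))
  beta <- drop(solve(crossprod(X), crossprod(X, means)))
  names(beta) <- colnames(X)
  vars <- apply(Y, 1, stats::var)
  n_i <- rep(ncol(Y), nrow(Y))
  df <- sum(n_i - 1)
  sigma2 <- sum((n_i - 1) * vars) / df
  fitted <- unname(drop(X %*% beta))
  structure(
    list(coefficients = beta, sigma2 = sigma2, df = df,
         n_rep = ncol(Y), fitted = fitted, residuals = means - fitted,
         design = design),
    class = "doe_fit"
  )
}

#' Predicted response at new coded points
#'
#' @param object a `doe_fit`.
#' @param newdata data.frame of coded points.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.doe_fit <- function(object, newdata, ...) {
  X0 <- expand_model(object$design$model, newdata)
  drop(X0 %*% object$coefficients)
}

#' Validate a fitted surface at a held-out test point
#'
#' Compares the observed replicate mean at the test point with the model
#' prediction. The standard error of the difference combines the
#' prediction variance of the coefficient estimate (run means carry
#' variance sigma^2 / m) with the variance of the observed test mean;
#' sigma^2 is pooled over the design-run and test-point replicates. The
#' model is validated when the observed mean falls inside the
#' (1 - alpha) interval around the prediction.
#'
#' @param fit a `doe_fit`.
#' @param point one-row data.frame of coded coordinates of the test
#'   point.
#' @param observed numeric vector of replicate responses observed at the
#'   point (length >= 2).
#' @param alpha significance level (default 0.10 for a 90% interval).
#' @return List with `validated` (logical), `predicted`,
#'   `observed_mean`, `interval` (bounds around the prediction),
#'   `se_difference` and `df`.
#' @export
validate_test_point <- function(fit, point, observed, alpha = 0.10) {
  stopifnot(inherits(fit, "doe_fit"), length(observed) >= 2)
  x0 <- drop(expand_model(fit$design$model, point))
  pred <- sum(x0 * fit$coefficients)
  obs_mean <- mean(observed)
  m0 <- length(observed)
  # pool test-point replicate scatter into the variance estimate
  df <- fit$df + (m0 - 1)
  sigma2 <- (fit$sigma2 * fit$df + stats::var(observed) * (m0 - 1)) / df
  XtXinv <- solve(crossprod(fit$design$X))
  leverage <- drop(t(x0) %*% XtXinv %*% x0)
  var_diff <- sigma2 * (leverage / fit$n_rep + 1 / m0)
  se <- sqrt(var_diff)
  if (se == 0) {
    # degenerate: no scatter at all; validated only on exact agreement
    ok <- isTRUE(all.equal(pred, obs_mean))
    return(list(validated = ok, predicted = pred, observed_mean = obs_mean,
                interval = c(pred, pred), se_difference = 0, df = df))
  }
  tcrit <- stats::qt(1 - alpha / 2, df)
  interval <- pred + c(-1, 1) * tcrit * se
  list(validated = obs_mean >= interval[1] && obs_mean <= interval[2],
       predicted = pred, observed_mean = obs_mean, interval = interval,
       se_difference = se, df = df)
}

#' Select the operating point optimizing several fitted responses
#'
#' Evaluates every fitted surface on the candidate grid. If a single
#' point simultaneously attains the optimum of every response (under its
#' stated direction) it is returned as the dominant optimum; otherwise
#' the Pareto-efficient set is returned with per-response ranks.
#'
#' @param fits named list of `doe_fit` objects sharing the factor space.
#' @param objectives named character vector mapping each response in
#'   `fits` to `"maximize"` or `"minimize"`.
#' @param candidates data.frame of coded grid points to evaluate; default
#'   the candidate grid stored in the first fit's design.
#' @return List with `optimum` (one-row data.frame or `NULL`), `pareto`
#'   (data.frame of non-dominated points), and `evaluation` (predictions
#'   and per-response ranks at every grid point).
#' @export
select_optimum <- function(fits, objectives, candidates = NULL) {
  if (length(objectives) == 0) stop("no objectives given", call. = FALSE)
  stopifnot(all(names(objectives) %in% names(fits)),
            all(objectives %in% c("maximize", "minimize")))
  if (is.null(candidates)) candidates <- fits[[1]]$design$candidates
  candidates <- as.data.frame(candidates)
  preds <- sapply(names(objectives), function(r) {
    predict(fits[[r]], candidates)
  })
  preds <- matrix(preds, nrow = nrow(candidates),
                  dimnames = list(NULL, names(objectives)))
  # orient every column so that larger is better
  oriented <- preds
  for (r in names(objectives)) {
    if (objectives[[r]] == "minimize") oriented[, r] <- -oriented[, r]
  }
  ranks <- apply(-oriented, 2, rank, ties.method = "min")
  best_sets <- lapply(seq_len(ncol(oriented)), function(j) {
    which(oriented[, j] >= max(oriented[, j]) - 1e-12 * abs(max(oriented[, j])))
  })
  common <- Reduce(intersect, best_sets)
  evaluation <- cbind(candidates, as.data.frame(preds),
                      stats::setNames(as.data.frame(ranks),
                                      paste0("rank_", colnames(ranks))))
  dominated <- vapply(seq_len(nrow(oriented)), function(i) {
    any(vapply(seq_len(nrow(oriented)), function(j) {
      j != i && all(oriented[j, ] >= oriented[i, ]) &&
        any(oriented[j, ] > oriented[i, ])
    }, logical(1)))
  }, logical(1))
  list(
    optimum = if (length(common)) candidates[common[1], , drop = FALSE],
    pareto = candidates[!dominated, , drop = FALSE],
    evaluation = evaluation
  )
}
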