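#' Orthonormal polynomial contrasts for an ordered predictor
#'
#' Returns the degree-1..k-1 polynomial contrast matrix over equally
#' spaced scores 0..k-1. Columns are mutually orthonormal and each is
#' orthogonal to the constant vector, so the encoded design separates the
#' linear trend of an ordinal predictor from its curvature without
#' collinearity. For k = 3 the columns are proportional to (-1, 0, 1) and
#' (1, -2, 1); for k = 2 the single column is proportional to (-1, 1).
#'
#' @param k number of levels (>= 2).
#' @return A k x (k-1) matrix; row i encodes level i-1.
#' @export
#' @examples
#' round(orthogonal_contrasts(3), 4)
orthogonal_contrasts <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop_fatal("orthogonal contrasts need k >= 2 levels")
  }
  k <- as.integer(k)
  x <- seq_len(k) - 1
  V <- outer(x, 0:(k - 1), `^`)       # Vandermonde in the raw polynomials
  Q <- qr.Q(qr(V))[, -1, drop = FALSE]
  sgn <- sign(Q[k, ])                  # orient each degree increasing at the top level
  sgn[sgn == 0] <- 1
  Q <- sweep(Q, 2, sgn, `*`)
  dimnames(Q) <- list(paste0("level", x),
                      c(".L", ".Q", if (k > 3) paste0(".", 3:(k - 1)))[seq_len(k - 1)])
  Q
}

#' Describe a model variant's design
#'
#' The three model variants differ only in which predictors enter:
#' * `full` -- 18 body-system ordinals + 30 comorbidity flags
#'   (48 predictor variables, 2*18 + 30 = 66 design columns);
#' * `comorbidity` -- the 30 flags (30 variables, 30 columns);
#' * `body_system` -- the 18 ordinals (18 variables, 36 columns).
#'
#' @param variant `"full"`, `"comorbidity"` or `"body_system"`.
#' @param registry Elixhauser category registry.
#' @return List with `variant`, `n_variables`, `n_columns` and the design
#'   `columns` names in their fixed order.
#' @export
design_info <- function(variant = c("full", "comorbidity", "body_system"),
                        registry = elix_registry()) {
  variant <- match.arg(variant)
  bs <- as.vector(t(outer(sprintf("bs%02d", seq_len(N_BODY_SYSTEMS)),
                          c(".L", ".Q"), paste0)))
  cols <- switch(variant,
                 full = c(bs, registry),
                 comorbidity = registry,
                 body_system = bs)
  n_var <- switch(variant,
                  full = N_BODY_SYSTEMS + length(registry),
                  comorbidity = length(registry),
                  body_system = N_BODY_SYSTEMS)
  list(variant = variant, n_variables = n_var,
       n_columns = length(cols), columns = cols)
}

#' Encode severity features as an orthogonal-contrast design matrix
#'
#' Each 3-level body-system ordinal contributes its linear and quadratic
#' contrast values; each binary comorbidity flag contributes the 2-level
#' contrast value (-1/sqrt(2) absent, +1/sqrt(2) present). Column order is
#' fixed by the variant and the registry so coefficient vectors are
#' positionally stable.
#'
#' @param features a [build_features()] result (or a compatible list with
#'   `body` and `elix` matrices).
#' @param variant model variant, see [design_info()].
#' @return Numeric matrix, one row per encounter, without an intercept
#'   column.
#' @export
encode_design <- function(features,
                          variant = c("full", "comorbidity", "body_system")) {
  variant <- match.arg(variant)
  registry <- features$registry %||% colnames(features$elix)
  info <- design_info(variant, registry = registry)
  n <- nrow(features$body %||% features$elix)
  C3 <- orthogonal_contrasts(3)
  C2 <- orthogonal_contrasts(2)
  parts <- list()
  if (variant %in% c("full", "body_system")) {
    L <- features$body
    if (is.null(L) || any(!L %in% 0:2)) {
      stop_fatal("body-system levels must be a matrix over {0,1,2}")
    }
    Xb <- matrix(0, n, 2L * N_BODY_SYSTEMS)
    Xb[, seq(1, 2L * N_BODY_SYSTEMS, by = 2)] <-
      matrix(C3[L + 1L, 1], n, N_BODY_SYSTEMS)
    Xb[, seq(2, 2L * N_BODY_SYSTEMS, by = 2)] <-
      matrix(C3[L + 1L, 2], n, N_BODY_SYSTEMS)
    parts$body <- Xb
  }
  if (variant %in% c("full", "comorbidity")) {
    F1 <- features$elix
    if (is.null(F1) || any(!F1 %in% 0:1)) {
      stop_fatal("comorbidity flags must be a matrix over {0,1}")
    }
    parts$elix <- matrix(C2[F1 + 1L, 1], n, ncol(F1))
  }
  X <- do.call(cbind, unname(parts))
  dimnames(X) <- list(rownames(features$body %||% features$elix),
                      info$columns)
  X
}

#' Fit a severity model by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of the binary high-severity
#' outcome on an orthogonal-contrast design. The fit iterates weighted
#' least squares until the relative deviance change drops below `tol`
#' (default 1e-8) or `maxit` iterations. An optional ridge penalty
#' (`ridge` > 0, not applied to the intercept) is the documented escape
#' hatch for quasi-separated data: without it, a diverging non-convergent
#' fit is reported as an error advising the ridge option rather than
#' returned silently.
#'
#' @param design numeric design matrix (no intercept column), e.g. from
#'   [encode_design()].
#' @param y binary outcome vector (0/1), e.g. from [binarize_outcome()].
#' @param variant,phase metadata recorded on the fit.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @param ridge L2 penalty on non-intercept coefficients (default 0,
#'   i.e. plain maximum likelihood).
#' @param version_label provenance label from the reference maps.
#' @return An object of class `severity_model` with the intercept,
#'   coefficient vector, standard errors, deviance diagnostics and
#'   convergence information.
#' @export
fit_severity_model <- function(design, y,
                               variant = c("full", "comorbidity",
                                           "body_system"),
                               phase = c("discharge", "admission"),
                               maxit = 100L, tol = 1e-8, ridge = 0,
                               version_label = "unversioned") {
  variant <- match.arg(variant)
  phase <- match.arg(phase)
  cn <- colnames(design) %||% character()
  non_bs <- cn[!grepl("^bs[0-9]{2}\\.", cn)]
  registry <- if (variant == "body_system" || !length(non_bs)) {
    elix_registry()
  } else {
    non_bs
  }
  info <- design_info(variant, registry = registry)
  # a zero-column design is the intercept-only model (useful as a
  # closed-form reference: intercept = logit of the outcome proportion)
  if (ncol(design) > 0 && ncol(design) != info$n_columns) {
    stop_fatal("design has ", ncol(design), " columns; variant '", variant,
               "' expects ", info$n_columns)
  }
  eng <- fit_logistic(design, y, maxit = maxit, tol = tol, ridge = ridge)
  structure(
    c(list(variant = variant, phase = phase, link = "logit",
           contrast = "orthonormal polynomial"),
      eng,
      list(registry = registry, version_label = version_label)),
    class = "severity_model")
}

#' Logistic maximum-likelihood fit by IRLS
#'
#' The width-agnostic fitting engine behind [fit_severity_model()]:
#' iteratively reweighted least squares for a binomial GLM with logit
#' link, an intercept always included, optional ridge penalty on the
#' non-intercept coefficients, and explicit convergence/separation
#' diagnostics. Exposed separately so the estimator can be checked
#' against independent references on arbitrary designs.
#'
#' @inheritParams fit_severity_model
#' @return List with `intercept`, `coefficients`, `se_intercept`, `se`,
#'   `deviance`, `null_deviance`, `n`, `iterations`, `converged`,
#'   `ridge`, `tol`.
#' @export
fit_logistic <- function(design, y, maxit = 100L, tol = 1e-8, ridge = 0) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_fatal("outcome must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop_fatal("outcome has a single class; cannot fit a classifier")
  }
  if (!all(is.finite(design))) stop_fatal("design matrix must be finite")
  X <- cbind(`(Intercept)` = 1, design)
  p <- ncol(X)
  n <- nrow(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  dev <- function(mu) -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  d_old <- dev(pmin(pmax(mu, 1e-15), 1 - 1e-15))
  converged <- FALSE
  it <- 0L
  A <- NULL
  while (it < maxit) {
    it <- it + 1L
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w)
    if (ridge > 0) {
      diag(A)[-1] <- diag(A)[-1] + ridge
    }
    beta_new <- tryCatch(drop(solve(A, crossprod(X, w * z))),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      stop_fatal("weighted least-squares step is singular; the design is ",
                 "rank deficient (a predictor may be constant in the ",
                 "training data)")
    }
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    d_new <- dev(pmin(pmax(mu, 1e-15), 1 - 1e-15)) +
      if (ridge > 0) ridge * sum(beta[-1]^2) else 0
    if (abs(d_new - d_old) / (abs(d_new) + 0.1) < tol) {
      converged <- TRUE
      d_old <- d_new
      break
    }
    d_old <- d_new
  }
  # runaway coefficients with no deviance plateau mean the likelihood is
  # maximized at infinity (quasi-separation); a plateaued fit with a few
  # saturated cells is returned as-is, matching standard GLM behaviour
  if (!converged && ridge == 0 && max(abs(beta)) > 15) {
    stop_fatal("fit did not converge and coefficients diverged: the data ",
               "look quasi-separated; refit with a small ridge penalty ",
               "(e.g. ridge = 1e-4)")
  }
  se <- sqrt(diag(solve(A)))
  p0 <- mean(y)
  null_dev <- -2 * sum(y * log(p0) + (1 - y) * log1p(-p0))
  list(intercept = unname(beta[1]),
       coefficients = stats::setNames(beta[-1], colnames(design)),
       se_intercept = unname(se[1]),
       se = stats::setNames(se[-1], colnames(design)),
       deviance = d_old, null_deviance = null_dev,
       n = n, iterations = it, converged = converged,
       ridge = ridge, tol = tol)
}

#' @export
print.severity_model <- function(x, ...) {
  cat("<severity_model> variant=", x$variant, ", phase=", x$phase,
      ", link=", x$link, "\n  n=", x$n, ", deviance=",
      format(x$deviance, digits = 6), " (null ",
      format(x$null_deviance, digits = 6), "), iterations=", x$iterations,
      if (!x$converged) " [NOT CONVERGED]", "\n  intercept=",
      format(x$intercept, digits = 4), ", ", length(x$coefficients),
      " coefficients\n", sep = "")
  invisible(x)
}

#' Predict the probability of high severity
#'
#' Applies the inverse-logit of the fitted linear predictor to new
#' features. These probabilities are the severity scores: computed from
#' all diagnoses they are the J_Score, from admission-selected diagnoses
#' the J_Score_POA.
#'
#' @param model a `severity_model`.
#' @param features a `severity_features` object (encoded internally) or an
#'   already-encoded design matrix with matching columns.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
predict_probability <- function(model, features) {
  X <- if (inherits(features, "severity_features")) {
    encode_design(features, model$variant)
  } else {
    features
  }
  if (ncol(X) != length(model$coefficients)) {
    stop_fatal("feature encoding has ", ncol(X), " columns but the '",
               model$variant, "' model expects ",
               length(model$coefficients),
               " (variant mismatch between model and features)")
  }
  stats::plogis(model$intercept + drop(X %*% model$coefficients))
}

#' Serialize and restore a fitted severity model
#'
#' Models round-trip through a versioned JSON document carrying the
#' variant, phase, contrast specification, registry order, coefficients,
#' fit diagnostics and the reference-map version label.
#'
#' @param model a `severity_model`.
#' @param path JSON file path.
#' @return `write_model`: `path`, invisibly. `read_model`: the restored
#'   `severity_model`.
#' @export
write_model <- function(model, path) {
  doc <- unclass(model)
  # named vectors serialize as JSON objects so coefficient names survive
  doc$coefficients <- as.list(doc$coefficients)
  doc$se <- as.list(doc$se)
  doc$format <- "jscore-model/1"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path), error = function(e) NULL)
  if (!identical(doc$format, "jscore-model/1")) {
    stop_fatal(path, " is not a serialized severity model")
  }
  doc$format <- NULL
  doc$coefficients <- unlist(doc$coefficients)
  doc$se <- unlist(doc$se)
  doc$registry <- unlist(doc$registry)
  structure(doc, class = "severity_model")
}
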