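## Multivariate linear LAI model: LAI = (sum_w t_w * g_w + j) / delta,
## where delta is the planting row spacing. Ships the published
## three-descriptor model and fits new ones by stepwise least squares.

#' Construct a linear LAI model
#'
#' @param coefficients Named numeric vector of descriptor coefficients
#'   `t_w` (names are the descriptor columns expected in feature tables).
#' @param intercept Model intercept `j`.
#' @param row_spacing Planting row spacing `delta` in metres (> 0); the
#'   affine predictor is divided by it.
#' @param fit Optional list of fit diagnostics (kept as-is).
#' @return An `lai_model` object.
#' @export
lai_model <- function(coefficients, intercept, row_spacing, fit = NULL) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop_validation("coefficients must be a named vector of descriptors")
  if (!is.numeric(row_spacing) || length(row_spacing) != 1 || row_spacing <= 0)
    stop_validation("row_spacing must be a single positive length in metres")
  structure(list(coefficients = coefficients, intercept = unname(intercept),
                 row_spacing = unname(row_spacing), fit = fit),
            class = "lai_model")
}

#' @export
print.lai_model <- function(x, ...) {
  cat("lai_model: LAI = (", paste(sprintf("%+.5f*%s", x$coefficients,
                                          names(x$coefficients)), collapse = " "),
      sprintf(" %+.5f ) / %.2f\n", x$intercept, x$row_spacing))
  if (!is.null(x$fit$r_squared))
    cat(sprintf("  fit: R^2 %.4f, residual sd %.4f, n %d\n",
                x$fit$r_squared, x$fit$sigma, x$fit$n))
  invisible(x)
}

#' The published three-descriptor cotton LAI model
#'
#' LAI = (1.37618 g + 0.66738 d_t - 0.02035 h_e - 0.51087) / 0.76, where
#' `g` is the density-grid occupancy ratio, `d_t` the maximum canopy
#' diameter (m) and `h_e` the estimated plant height (m). Note the 0.76 m
#' divisor differs from the 0.60 m planting row spacing of the source trial;
#' the discrepancy is inherited as published.
#'
#' @return An `lai_model`.
#' @export
published_lai_model <- function() {
  lai_model(c(g = 1.37618, d_t = 0.66738, h_e = -0.02035),
            intercept = -0.51087, row_spacing = 0.76)
}

#' Predict LAI from canopy descriptors
#'
#' @param model An `lai_model`.
#' @param features Data frame containing every descriptor column named in
#'   the model.
#' @return Numeric vector of LAI predictions. Negative predictions are legal
#'   output of the affine model and are returned as-is with a warning.
#' @export
predict_lai <- function(model, features) {
  stopifnot(inherits(model, "lai_model"))
  miss <- setdiff(names(model$coefficients), names(features))
  if (length(miss))
    stop_validation("feature table missing descriptor column(s): %s",
                    paste(miss, collapse = ", "))
  X <- as.matrix(features[names(model$coefficients)])
  if (!is.numeric(X) || anyNA(X))
    stop_validation("descriptor columns must be numeric and complete")
  lai <- drop(X %*% model$coefficients + model$intercept) / model$row_spacing
  if (any(lai < 0))
    warning(sprintf("%d negative LAI prediction(s) returned unclipped",
                    sum(lai < 0)))
  unname(lai)
}

#' Fit a linear LAI model by stepwise least squares
#'
#' Regresses `LAI * delta` on the candidate descriptors with an intercept,
#' selecting descriptors by bidirectional stepwise search. The default
#' penalty is BIC (`k = log(n)`); AIC and a p-value entry/stay mode are
#' available. Coefficients are returned on the row-spacing-normalized scale,
#' so predictions divide by `delta`.
#'
#' @param features Data frame with a measured `lai` column and the candidate
#'   descriptor columns; at least 10 complete rows.
#' @param candidates Character vector of candidate descriptor columns
#'   (default: every numeric column except `lai` and id columns).
#' @param row_spacing Row spacing `delta` in metres (default 0.76, the
#'   published model's divisor; pass 0.60 for the trial's agronomic spacing).
#' @param criterion `"BIC"` (default), `"AIC"`, `"pvalue"`, or `"none"`
#'   (no selection: ordinary least squares on all candidates).
#' @param alpha_enter,alpha_stay Entry/stay thresholds for the p-value mode.
#' @return An `lai_model` with `$fit` diagnostics (selected descriptors,
#'   R^2, residual sd, coefficient table, n).
#' @export
fit_lai_stepwise <- function(features, candidates = NULL, row_spacing = 0.76,
                             criterion = c("BIC", "AIC", "pvalue", "none"),
                             alpha_enter = 0.05, alpha_stay = 0.10) {
  criterion <- match.arg(criterion)
  if (!"lai" %in% names(features))
    stop_validation("feature table must contain a measured 'lai' column")
  if (is.null(candidates)) {
    candidates <- setdiff(names(features)[vapply(features, is.numeric, TRUE)],
                          c("lai", "quadrat_id", "plot_id"))
  }
  miss <- setdiff(candidates, names(features))
  if (length(miss))
    stop_validation("candidate descriptor(s) not in table: %s",
                    paste(miss, collapse = ", "))
  dat <- features[c("lai", candidates)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10)
    stop_validation("stepwise fitting needs >= 10 complete rows, got %d", n)
  X <- as.matrix(dat[candidates])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop_numeric("rank-deficient design: collinear descriptor(s) among %s",
                 paste(candidates, collapse = ", "))
  dat$.y <- dat$lai * row_spacing
  full_fml <- reformulate(candidates, response = ".y")
  selected <- switch(criterion,
    BIC = ,
    AIC = {
      k <- if (criterion == "BIC") log(n) else 2
      fit0 <- lm(.y ~ 1, data = dat)
      sel <- step(fit0, scope = list(lower = ~1, upper = full_fml),
                  direction = "both", k = k, trace = 0)
      setdiff(attr(terms(sel), "term.labels"), character(0))
    },
    pvalue = stepwise_pvalue(dat, candidates, alpha_enter, alpha_stay),
    none = candidates)
  fml <- if (length(selected)) reformulate(selected, response = ".y")
         else .y ~ 1
  fit <- lm(fml, data = dat)
  s <- summary(fit)
  coefs <- coef(fit)
  lai_model(coefficients = if (length(selected)) coefs[selected] else
              setNames(numeric(0), character(0)),
            intercept = coefs[["(Intercept)"]],
            row_spacing = row_spacing,
            fit = list(selected = selected, criterion = criterion,
                       r_squared = s$r.squared, sigma = s$sigma, n = n,
                       coefficients = s$coefficients,
                       candidates = candidates))
}

# Bidirectional p-value stepwise on the working response .y.
stepwise_pvalue <- function(dat, candidates, alpha_enter, alpha_stay) {
  selected <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        f <- lm(reformulate(c(selected, v), response = ".y"), data = dat)
        summary(f)$coefficients[v, "Pr(>|t|)"]
      }, 0)
      if (min(pvals) < alpha_enter) {
        selected <- c(selected, names(which.min(pvals)))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      f <- lm(reformulate(selected, response = ".y"), data = dat)
      pv <- summary(f)$coefficients[selected, "Pr(>|t|)", drop = TRUE]
      if (max(pv) > alpha_stay) {
        selected <- setdiff(selected, names(which.max(pv)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected
}

#' Serialize an LAI model to JSON (and back)
#'
#' @param model An `lai_model`.
#' @param path File path.
#' @return `read_lai_model()` returns the `lai_model`; `write_lai_model()`
#'   returns `path` invisibly.
#' @export
write_lai_model <- function(model, path) {
  stopifnot(inherits(model, "lai_model"))
  obj <- list(descriptors = names(model$coefficients),
              coefficients = unname(model$coefficients),
              intercept = model$intercept,
              row_spacing = model$row_spacing,
              fit = model$fit[c("selected", "criterion", "r_squared",
                                "sigma", "n")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lai_model
#' @export
read_lai_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lai_model(setNames(as.numeric(obj$coefficients), obj$descriptors),
            intercept = obj$intercept, row_spacing = obj$row_spacing,
            fit = obj$fit)
}
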