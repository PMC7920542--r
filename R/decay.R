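#' Fit the exponential distance-decay model of connectivity
#'
#' Fits \eqn{y = \alpha e^{-d/\lambda}} by nonlinear least squares on
#' linear-scale weights, where \eqn{\lambda} (mm) is the length constant in
#' the cable-theory convention and \eqn{\alpha} the scaling coefficient.
#' Initialization uses \eqn{\alpha_0 = \max(y)}, \eqn{\lambda_0 =
#' \mathrm{range}(d)/3}, with jittered restarts on failure; the confidence
#' interval for \eqn{\lambda} is the asymptotic interval from the QR
#' decomposition of the Jacobian. \eqn{r^2} is computed as 1 - SSE/SST on
#' the linear response.
#'
#' @param y Numeric vector of linear-scale weights (e.g. `10^Fpt`).
#' @param d Numeric vector of fiber tract lengths (mm), same length.
#' @param restarts Number of jittered restarts attempted on failure.
#' @param subset Label recorded in the result.
#' @return A `decay_fit`: list with `lambda_mm`, `alpha`, `r2`,
#'   `ci95_lambda`, `ci95_alpha`, `n_pairs`, `subset`.
#' @export
fit_exponential <- function(y, d, restarts = 5, subset = "all") {
  keep <- is.finite(y) & is.finite(d)
  y <- y[keep]; d <- d[keep]
  if (length(y) < 3L) stop("need at least 3 defined pairs")
  if (any(d <= 0)) stop("tract lengths must be positive")
  starts <- list(c(alpha = max(y), lambda = diff(range(d)) / 3))
  fit <- NULL
  last_err <- NULL
  for (k in seq_len(restarts + 1L)) {
    st <- starts[[1L]]
    if (k > 1L) {  # deterministic jitter ladder, no RNG involved
      st <- st * c(1.5^(k - 1L), 0.6^(k - 1L))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ alpha * exp(-d / lambda),
                        start = list(alpha = st[["alpha"]], lambda = st[["lambda"]]),
                        lower = c(1e-12, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("exponential fit failed to converge after restarts: ",
         conditionMessage(last_err))
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tq <- stats::qt(0.975, df = length(y) - 2L)
  pred <- co[["alpha"]] * exp(-d / co[["lambda"]])
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(lambda_mm = unname(co[["lambda"]]),
                 alpha = unname(co[["alpha"]]),
                 r2 = 1 - sse / sst,
                 ci95_lambda = unname(co[["lambda"]] + c(-1, 1) * tq * se[["lambda"]]),
                 ci95_alpha = unname(co[["alpha"]] + c(-1, 1) * tq * se[["alpha"]]),
                 sse = sse, n_pairs = length(y), subset = subset),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit [%s]: lambda = %.2f mm [%.2f, %.2f], alpha = %.3g, r2 = %.3f, n = %d\n",
              x$subset, x$lambda_mm, x$ci95_lambda[1], x$ci95_lambda[2],
              x$alpha, x$r2, x$n_pairs))
  invisible(x)
}

# Registry of candidate decay models. Each entry: formula in (y, d),
# start function, and parameter count.
decay_candidates <- function() {
  list(
    exponential = list(
      formula = y ~ alpha * exp(-d / lambda),
      start = function(y, d) list(alpha = max(y), lambda = diff(range(d)) / 3),
      lower = c(1e-12, 1e-3), n_params = 2),
    gaussian = list(
      formula = y ~ alpha * exp(-(d / lambda)^2),
      start = function(y, d) list(alpha = max(y), lambda = diff(range(d)) / 2),
      lower = c(1e-12, 1e-3), n_params = 2),
    power = list(
      formula = y ~ alpha * d^(-beta),
      start = function(y, d) list(alpha = max(y) * min(d), beta = 1),
      lower = c(1e-12, 1e-3), n_params = 2),
    exponential_offset = list(
      formula = y ~ alpha * exp(-d / lambda) + c0,
      start = function(y, d) list(alpha = max(y), lambda = diff(range(d)) / 3,
                                  c0 = min(y)),
      lower = c(1e-12, 1e-3, -Inf), n_params = 3))
}

#' Compare candidate distance-decay models by information criteria
#'
#' Least-squares fits of a registry of functional forms (at minimum the
#' exponential and Gaussian decays), ranked by corrected AIC. Information
#' criteria use the Gaussian-error log-likelihood implied by the residual
#' sum of squares; the parameter count includes the error variance.
#'
#' @param y Linear-scale weights.
#' @param d Tract lengths (mm).
#' @param candidates Character vector naming models from the registry, or a
#'   named list of custom entries with fields `formula`, `start`, `lower`,
#'   `n_params`.
#' @return A `model_comparison` data frame with columns `model`, `n_params`,
#'   `sse`, `r2`, `aic`, `aicc`, `bic`, `converged`, sorted by `aicc`.
#' @export
fit_candidates <- function(y, d, candidates = c("exponential", "gaussian")) {
  keep <- is.finite(y) & is.finite(d)
  y <- y[keep]; d <- d[keep]
  n <- length(y)
  reg <- decay_candidates()
  if (is.character(candidates)) {
    unknown <- setdiff(candidates, names(reg))
    if (length(unknown)) stop("unknown candidate model(s): ",
                              paste(unknown, collapse = ", "))
    cand <- reg[candidates]
  } else {
    cand <- candidates
  }
  if (!all(c("exponential", "gaussian") %in% names(cand))) {
    stop("candidate set must include exponential and gaussian forms")
  }
  sst <- sum((y - mean(y))^2)
  rows <- lapply(names(cand), function(nm) {
    cd <- cand[[nm]]
    fit <- tryCatch(
      minpack.lm::nlsLM(cd$formula, data = data.frame(y = y, d = d),
                        start = cd$start(y, d), lower = cd$lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(model = nm, n_params = cd$n_params, sse = NA_real_,
                        r2 = NA_real_, aic = NA_real_, aicc = NA_real_,
                        bic = NA_real_, converged = FALSE))
    }
    sse <- sum(stats::residuals(fit)^2)
    k <- cd$n_params + 1L  # + error variance
    ll <- -n / 2 * (log(2 * pi) + log(sse / n) + 1)
    aic <- -2 * ll + 2 * k
    aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
    bic <- -2 * ll + k * log(n)
    data.frame(model = nm, n_params = cd$n_params, sse = sse,
               r2 = 1 - sse / sst, aic = aic, aicc = aicc, bic = bic,
               converged = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Distance-decay fit restricted to a hemispheric subset
#'
#' @param F A symmetric `connectome_matrix` on the `log10_fractional` scale
#'   (weights are converted to linear scale as `10^F` before fitting) or
#'   `fractional` scale (used as is).
#' @param lengths A `tract_lengths`.
#' @param atlas A `parcel_atlas` resolving hemispheres.
#' @param subset `"all"`, `"left"`, `"right"` or `"callosal"`.
#' @return A `decay_fit`.
#' @export
subset_fit <- function(F, lengths, atlas,
                       subset = c("all", "left", "right", "callosal")) {
  subset <- match.arg(subset)
  mask <- pair_subset_mask(atlas, subset) & upper.tri(F$values)
  keep <- F$defined & lengths$defined & mask
  if (!any(keep)) stop("empty subset: ", subset)
  w <- F$values[keep]
  y <- if (F$scale == "log10_fractional") 10^w else w
  fit_exponential(y, lengths$lengths[keep], subset = subset)
}

#' Scalar head-motion index from a displacement time series
#'
#' Integrates RMS displacement over the scan duration by the trapezoidal
#' rule.
#'
#' @param displacement Non-negative displacement series.
#' @param dt Sampling interval (scalar) or explicit time vector `t`.
#' @param t Optional time vector overriding `dt`.
#' @return Scalar integral (displacement x time units).
#' @export
motion_index <- function(displacement, dt = 1, t = NULL) {
  if (length(displacement) == 0L) stop("empty displacement series")
  if (any(displacement < 0)) stop("displacement must be non-negative")
  if (length(displacement) == 1L) return(displacement * dt)
  if (is.null(t)) t <- seq(0, by = dt, length.out = length(displacement))
  pracma::trapz(t, displacement)
}

#' Relation between per-subject length constants and motion
#'
#' Pearson correlation of per-subject decay length constants with the
#' subjects' motion indices, with a Fisher-z 95\% CI (variance 1/(n-3)).
#'
#' @param lambdas Per-subject length constants.
#' @param motion Per-subject motion indices.
#' @return List with `r`, `r2`, `ci95`, `n`.
#' @export
motion_lambda_relation <- function(lambdas, motion) {
  if (length(lambdas) != length(motion)) stop("length mismatch")
  keep <- is.finite(lambdas) & is.finite(motion)
  lambdas <- lambdas[keep]; motion <- motion[keep]
  n <- length(lambdas)
  if (n < 4L) stop("need at least 4 subjects")
  if (stats::sd(lambdas) == 0 || stats::sd(motion) == 0) {
    stop("zero variance in lambdas or motion")
  }
  r <- stats::cor(lambdas, motion)
  ci <- fisher_ci(r, n)
  list(r = r, r2 = r^2, ci95 = ci, n = n)
}

# Fisher-z interval for a Pearson correlation.
fisher_ci <- function(r, n, conf = 0.95) {
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(z + c(-1, 1) * q * se)
}

#' Per-subject length constants from a subject stack
#'
#' Applies the per-subject normalization chain, converts to linear weights
#' and fits the exponential decay for each subject over non-zero defined
#' pairs.
#'
#' @param stack A `subject_stack`.
#' @param lengths A `tract_lengths`.
#' @return Numeric vector of per-subject `lambda_mm`.
#' @export
per_subject_lambda <- function(stack, lengths) {
  vapply(seq_len(stack$n_subjects), function(s) {
    f <- fpt_chain(connectome_matrix(stack$counts[s, , ], scale = "raw_counts"))
    keep <- f$defined & lengths$defined & upper.tri(f$values)
    fit_exponential(10^f$values[keep], lengths$lengths[keep],
                    subset = "all")$lambda_mm
  }, numeric(1))
}
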