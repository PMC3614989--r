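# Spline bases, the mixed-model fitting contract (binomial-logit and
# Gaussian with a random fishing-set intercept), small-sample AICc ranking
# with Akaike weights, and response-scale prediction grids.
#
# Fitting engines: lme4 (maximum likelihood; Laplace approximation for the
# binomial family) when a random set intercept is requested, and ordinary
# glm/lm otherwise. All models compared in one ranking are fitted by ML to
# the same observations so their AICc values are commensurable.

#' Cubic regression-spline basis
#'
#' Natural cubic spline basis of dimension `df` (intercept excluded) with
#' interior knots at quantiles of the observed values. The knot set is
#' carried in the attributes (`knots`, `Boundary.knots`) so the same basis
#' can be re-evaluated on a prediction grid.
#'
#' @param values Numeric vector with at least `df` distinct values.
#' @param df Basis dimension, an integer `>= 2`.
#' @param knots,boundary_knots Optional knot sets for re-evaluation; taken
#'   from a previous basis' attributes.
#' @return `df`-column basis matrix with knot attributes.
#' @export
spline_basis <- function(values, df, knots = NULL, boundary_knots = NULL) {
  stopifnot(is.numeric(values), df >= 2, df == round(df))
  if (!is.null(knots)) {
    return(splines::ns(values, knots = knots,
                       Boundary.knots = boundary_knots))
  }
  if (length(unique(values[!is.na(values)])) < 2) {
    stop("spline input is constant", call. = FALSE)
  }
  if (length(unique(values[!is.na(values)])) < df) {
    stop("need at least df distinct values", call. = FALSE)
  }
  splines::ns(values, df = df)
}

#' Candidate model specification
#'
#' Describes one candidate in the reproductive-parameter model sets: a
#' response, an error family, additive fixed terms (cubic splines of given
#' df, linear terms, or factors) and an optional random fishing-set
#' intercept.
#'
#' @param response Name of the response column. Binomial responses must be
#'   0/1.
#' @param family `"binomial_logit"` or `"gaussian_identity"`.
#' @param terms Named list: names are covariate columns, values are an
#'   integer spline df (`>= 2`), `"linear"` or `"factor"`. Empty list for an
#'   intercept-only model.
#' @param random_set Name of the clustering column for a random intercept
#'   (default `"set_id"`), or `NULL` for none.
#' @param label Optional display label; autogenerated otherwise.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("pof01", "binomial_logit",
#'            terms = list(fork_length_cm = "linear", month = 5))
model_spec <- function(response,
                       family = c("binomial_logit", "gaussian_identity"),
                       terms = list(), random_set = "set_id", label = NULL) {
  family <- match.arg(family)
  for (v in terms) {
    ok <- (is.numeric(v) && v >= 2) || identical(v, "linear") ||
      identical(v, "factor")
    if (!ok) stop("each term must be a spline df >= 2, \"linear\" or ",
                  "\"factor\"", call. = FALSE)
  }
  term_str <- function(nm, v) {
    if (is.numeric(v)) sprintf("s(%s, df = %d)", nm, as.integer(v))
    else if (v == "factor") sprintf("factor(%s)", nm)
    else nm
  }
  rhs <- if (length(terms)) {
    paste(mapply(term_str, names(terms), terms), collapse = " + ")
  } else "1"
  if (is.null(label)) {
    label <- paste0(response, " ~ ", rhs,
                    if (!is.null(random_set)) paste0(" + (1 | ", random_set, ")"))
  }
  structure(list(response = response, family = family, terms = terms,
                 random_set = random_set, label = label),
            class = "model_spec")
}

spec_formula <- function(spec) {
  term_str <- function(nm, v) {
    if (is.numeric(v)) {
      sprintf("splines::ns(%s, df = %d)", nm, as.integer(v))
    } else if (v == "factor") sprintf("factor(%s)", nm) else nm
  }
  rhs <- if (length(spec$terms)) {
    paste(mapply(term_str, names(spec$terms), spec$terms), collapse = " + ")
  } else "1"
  if (!is.null(spec$random_set)) {
    rhs <- paste0(rhs, " + (1 | ", spec$random_set, ")")
  }
  as.formula(paste(spec$response, "~", rhs))
}

#' Fit a candidate model by maximum likelihood
#'
#' Gaussian models with a random set intercept are fitted with
#' [lme4::lmer()] (ML, not REML, so that likelihoods are comparable across
#' fixed-effect structures); binomial-logit models with a random intercept
#' use [lme4::glmer()] (Laplace approximation). Without a random term the
#' fit degenerates to ordinary `lm()`/`glm()`. The parameter count `k` is
#' the fitted degrees of freedom: fixed coefficients, plus one variance
#' component per random term, plus the residual variance for Gaussian
#' models.
#'
#' @param spec A [model_spec()].
#' @param data Data frame holding the response and covariates; rows with
#'   missing values in any used column are dropped (count recorded).
#' @return A `pf_fit` object: `spec`, `fit` (the engine object), `loglik`,
#'   `k`, `n`, `aicc`, `coefficients`, `random_sd`, `converged`.
#' @export
fit_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  used <- c(spec$response, names(spec$terms), spec$random_set)
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("data lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dat <- as_tibble(data)[used]
  n_dropped <- sum(!stats::complete.cases(dat))
  dat <- dat[stats::complete.cases(dat), ]
  if (spec$family == "binomial_logit" &&
      !all(dat[[spec$response]] %in% c(0, 1))) {
    stop("binomial responses must be coded 0/1", call. = FALSE)
  }
  fml <- spec_formula(spec)
  msgs <- character()
  fit <- withCallingHandlers({
    if (is.null(spec$random_set)) {
      if (spec$family == "binomial_logit") {
        glm(fml, data = dat, family = binomial())
      } else {
        lm(fml, data = dat)
      }
    } else if (spec$family == "binomial_logit") {
      lme4::glmer(fml, data = dat, family = binomial())
    } else {
      lme4::lmer(fml, data = dat, REML = FALSE)
    }
  }, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  ll <- logLik(fit)
  k <- attr(ll, "df")
  # lm reports df = p + 1 (residual variance); glm binomial reports p.
  n <- nobs(fit)
  random_sd <- if (inherits(fit, "merMod")) {
    vc <- lme4::VarCorr(fit)
    unname(sqrt(vc[[spec$random_set]][1, 1]))
  } else 0
  coefs <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  covar_info <- lapply(seq_along(spec$terms), function(i) {
    nm <- names(spec$terms)[i]
    if (identical(spec$terms[[i]], "factor")) {
      unique(as.character(dat[[nm]]))
    } else {
      range(dat[[nm]])
    }
  })
  names(covar_info) <- names(spec$terms)
  structure(list(
    spec = spec, fit = fit, loglik = as.numeric(ll), k = k, n = n,
    aicc = aicc(as.numeric(ll), k, n), coefficients = coefs,
    random_sd = random_sd, n_dropped = n_dropped, covar_info = covar_info,
    converged = !any(grepl("converge|Hessian|singular", msgs)),
    messages = msgs), class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(x$spec$label, "\n")
  cat(sprintf("  logLik %.3f  k %d  n %d  AICc %.3f  random SD %.3f\n",
              x$loglik, x$k, x$n, x$aicc, x$random_sd))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`; requires
#' `n - k - 1 > 0` and converges to AIC as `n` grows.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (fixed coefficients + variance
#'   components + residual variance where applicable).
#' @param n Number of observations.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-100, 3, 50) # 206 + 24/46
aicc <- function(loglik, k, n) {
  if (any(n - k - 1 <= 0)) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate fits by AICc with Akaike weights
#'
#' `delta_aicc` is each model's AICc above the minimum;
#' `akaike_weight_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`.
#' Models with weight `>= 0.01` are flagged `supported`; models with
#' `delta_aicc < 2` are flagged `equivalent` (describing the data about as
#' well as the best model). All fits must be on the same observations.
#'
#' @param fits List of `pf_fit` objects for a common response.
#' @return Tibble sorted by AICc: `model`, `family`, `k`, `n`, `loglik`,
#'   `aicc`, `delta_aicc`, `akaike_weight`, `supported`, `equivalent`,
#'   `converged`.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "pf_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "pf_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) {
    stop("fits use different observation counts; AICc not comparable",
         call. = FALSE)
  }
  out <- tibble(
    model = vapply(fits, function(f) f$spec$label, character(1)),
    family = vapply(fits, function(f) f$spec$family, character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    n = ns,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  out$delta_aicc <- out$aicc - min(out$aicc)
  w <- exp(-out$delta_aicc / 2)
  out$akaike_weight <- w / sum(w)
  out$supported <- out$akaike_weight >= 0.01
  out$equivalent <- out$delta_aicc < 2
  arrange(out, .data$aicc)
}

#' Predict from a fitted candidate model on the response scale
#'
#' Fixed-effects prediction with the random intercept at its population
#' mean (zero); the inverse logit is applied for binomial fits. Grid points
#' outside the training range of any numeric covariate are flagged as
#' extrapolation.
#'
#' @param object A `pf_fit`.
#' @param newdata Covariate tibble (prediction grid).
#' @param ... Unused.
#' @return Numeric predictions with an `extrapolated` logical attribute.
#' @export
predict.pf_fit <- function(object, newdata, ...) {
  fit <- object$fit
  pred <- if (inherits(fit, "merMod")) {
    p <- predict(fit, newdata = newdata, re.form = NA)
    if (object$spec$family == "binomial_logit") plogis(p) else p
  } else {
    as.numeric(predict(fit, newdata = newdata, type = "response"))
  }
  extrap <- rep(FALSE, nrow(newdata))
  for (nm in names(object$spec$terms)) {
    info <- object$covar_info[[nm]]
    if (identical(object$spec$terms[[nm]], "factor")) {
      if (!all(as.character(newdata[[nm]]) %in% info)) {
        stop("unseen factor level in ", nm, call. = FALSE)
      }
    } else {
      extrap <- extrap | newdata[[nm]] < info[1] | newdata[[nm]] > info[2]
    }
  }
  attr(pred, "extrapolated") <- extrap
  pred
}
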