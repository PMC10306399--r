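## Dose-response model suite (constant-variance normal errors), following
## the EPA BMDS parameterizations:
##   linear: a + b*c
##   poly2:  a + b*c + d*c^2
##   power:  a + b*c^p,                        p in [1, 18]
##   exp3:   a * exp(s*(b*c)^p),               a > 0, b > 0, p in [1, 18]
##   exp5:   a * (e - (e - 1)*exp(-(b*c)^p)),  a > 0, b > 0, e > 0
## All models are fitted on the scaled concentration u = c / max(c), which
## makes the fit exactly equivariant under rescaling of the concentration
## axis; parameters are reported back on the original scale.

.bmcModels <- c("power", "exp3", "exp5", "linear", "poly2")

.meanFun <- function(model, pars, conc) {
  p <- as.list(pars)
  switch(model,
    linear = p$a + p$b * conc,
    poly2 = p$a + p$b * conc + p$d * conc^2,
    power = p$a + p$b * conc^p$p,
    exp3 = p$a * exp(p$sign * (p$b * conc)^p$p),
    exp5 = p$a * (p$e - (p$e - 1) * exp(-(p$b * conc)^p$p)),
    stopf("unknown model '%s'", model))
}

#' Predicted mean response of a fitted dose-response model
#' @param fit a fit from [fitDoseResponse()].
#' @param conc concentrations (uM).
#' @return predicted log2 expression.
#' @export
predictDR <- function(fit, conc) .meanFun(fit$model, fit$pars, conc)

## least squares of y on columns of X; returns list(coef, sse)
.lsq <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

## -- per-model fitting on scaled concentration u ---------------------------

.fitLinearFamily <- function(u, y, degree) {
  X <- stats::poly(u, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  ls <- .lsq(X, y)
  pars <- if (degree == 1) c(a = unname(ls$coef[1]), b = unname(ls$coef[2]))
  else c(a = unname(ls$coef[1]), b = unname(ls$coef[2]),
         d = unname(ls$coef[3]))
  list(pars = pars, sse = ls$sse, converged = all(is.finite(ls$coef)))
}

.fitPower <- function(u, y) {
  sseFor <- function(pw) .lsq(cbind(1, u^pw), y)$sse
  opt <- optimize(sseFor, c(1, 18), tol = 1e-7)
  cand <- rbind(c(1, sseFor(1)), c(opt$minimum, opt$objective))
  best <- cand[which.min(cand[, 2]), ]
  ls <- .lsq(cbind(1, u^best[1]), y)
  list(pars = c(a = unname(ls$coef[1]), b = unname(ls$coef[2]),
                p = unname(best[1])),
       sse = ls$sse, converged = all(is.finite(ls$coef)))
}

## deterministic starting points (log b, p) on the scaled axis
.nlStarts <- matrix(c(log(0.5), 1, log(1), 1, log(2), 1, log(5), 1,
                      log(1), 2), ncol = 2, byrow = TRUE)

.fitExp3 <- function(u, y) {
  best <- list(sse = Inf)
  for (s in c(1, -1)) {
    obj <- function(th) {
      g <- exp(s * (exp(th[1]) * u)^th[2])
      if (any(!is.finite(g))) return(1e30)
      a <- sum(y * g) / sum(g * g)
      if (!is.finite(a) || a <= 0) return(1e30)
      sum((y - a * g)^2)
    }
    for (i in seq_len(nrow(.nlStarts))) {
      op <- tryCatch(nlminb(.nlStarts[i, ], obj,
                            lower = c(log(1e-4), 1), upper = c(log(1e4), 18)),
                     error = function(e) NULL)
      if (is.null(op) || !is.finite(op$objective)) next
      if (op$objective < best$sse - 1e-12) {
        th <- op$par
        g <- exp(s * (exp(th[1]) * u)^th[2])
        a <- sum(y * g) / sum(g * g)
        best <- list(sse = op$objective,
                     pars = c(a = a, b = exp(th[1]), p = th[2], sign = s))
      }
    }
  }
  if (!is.finite(best$sse)) return(list(converged = FALSE))
  c(best, list(converged = TRUE))
}

.fitExp5 <- function(u, y) {
  best <- list(sse = Inf)
  obj <- function(th) {
    w <- exp(-(exp(th[1]) * u)^th[2])
    ls <- tryCatch(.lsq(cbind(1, w), y), error = function(e) NULL)
    if (is.null(ls) || any(!is.finite(ls$coef))) return(1e30)
    a <- sum(ls$coef) # beta0 + beta1 = f(inf contribution at w->? ) = a
    e <- ls$coef[1] / a
    if (!is.finite(a) || a <= 0 || !is.finite(e) || e <= 0) return(1e30)
    ls$sse
  }
  for (i in seq_len(nrow(.nlStarts))) {
    op <- tryCatch(nlminb(.nlStarts[i, ], obj,
                          lower = c(log(1e-4), 1), upper = c(log(1e4), 18)),
                   error = function(e) NULL)
    if (is.null(op) || !is.finite(op$objective)) next
    if (op$objective < best$sse - 1e-12) {
      th <- op$par
      w <- exp(-(exp(th[1]) * u)^th[2])
      ls <- .lsq(cbind(1, w), y)
      a <- sum(ls$coef)
      best <- list(sse = op$objective,
                   pars = c(a = unname(a), b = exp(th[1]),
                            e = unname(ls$coef[1] / a), p = th[2]))
    }
  }
  if (!is.finite(best$sse)) return(list(converged = FALSE))
  c(best, list(converged = TRUE))
}

## back-transform scaled-axis parameters to the original concentration scale
.unscalePars <- function(model, pars, top) {
  switch(model,
         linear = { pars["b"] <- pars["b"] / top; pars },
         poly2 = { pars["b"] <- pars["b"] / top
                   pars["d"] <- pars["d"] / top^2; pars },
         power = { pars["b"] <- pars["b"] / top^pars["p"]; pars },
         exp3 = , exp5 = { pars["b"] <- pars["b"] / top; pars })
}

.nParMean <- c(linear = 2, poly2 = 3, power = 3, exp3 = 3, exp5 = 4)

#' Fit one dose-response model by maximum likelihood
#'
#' Constant-variance normal errors; the variance MLE is SSE/n. The
#' goodness-of-fit p-value is the likelihood ratio of the fit against the
#' saturated per-group-means model, referred to a chi-square with
#' (number of groups - number of mean parameters) degrees of freedom.
#' Nonlinear models are optimized from 5 deterministic starting points
#' with the scale/asymptote parameters profiled out in closed form.
#'
#' @param model one of `"power"`, `"exp3"`, `"exp5"`, `"linear"`, `"poly2"`.
#' @param conc per-sample concentrations (uM), including controls at 0.
#' @param values per-sample log2 expression values.
#' @return list of class `"drcFit"`: `model`, `pars` (original scale),
#'   `sse`, `sigma`, `loglik`, `aic`, `npar`, `gofP`, `converged`, plus the
#'   data (`conc`, `values`, `topConc`). Non-convergent fits have
#'   `converged = FALSE` and no fabricated values.
#' @export
fitDoseResponse <- function(model, conc, values) {
  model <- match.arg(model, .bmcModels)
  n <- length(values)
  stopifnot(length(conc) == n)
  groups <- unique(conc)
  if (length(groups) < .nParMean[[model]] + 1)
    stopf("model '%s' needs at least %d distinct concentrations", model,
          .nParMean[[model]] + 1)
  top <- max(conc)
  u <- conc / top
  raw <- switch(model,
                linear = .fitLinearFamily(u, values, 1),
                poly2 = .fitLinearFamily(u, values, 2),
                power = .fitPower(u, values),
                exp3 = .fitExp3(u, values),
                exp5 = .fitExp5(u, values))
  fail <- list(model = model, converged = FALSE, conc = conc,
               values = values, topConc = top)
  if (!isTRUE(raw$converged)) return(structure(fail, class = "drcFit"))
  pars <- .unscalePars(model, raw$pars, top)
  sse <- raw$sse
  sigma2 <- max(sse / n, 1e-16) # sigma floored at 1e-8
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- .nParMean[[model]]
  gm <- vapply(split(values, conc), mean, numeric(1))
  sseSat <- sum((values - gm[as.character(conc)])^2)
  df <- length(groups) - k
  gofP <- if (df <= 0) 1
  else if (sseSat <= 1e-300) { if (sse <= 1e-12) 1 else 0 }
  else pchisq(n * log(max(sse, 1e-300) / sseSat), df, lower.tail = FALSE)
  structure(list(model = model, pars = pars, sse = sse,
                 sigma = sqrt(sigma2), loglik = loglik,
                 aic = 2 * (k + 1) - 2 * loglik, npar = k, gofP = gofP,
                 converged = TRUE, conc = conc, values = values,
                 topConc = top),
            class = "drcFit")
}

#' Fit the full model suite
#' @inheritParams fitDoseResponse
#' @param models models to fit (default: the full suite).
#' @return named list of `"drcFit"` objects.
#' @export
fitAllModels <- function(conc, values, models = .bmcModels) {
  setNames(lapply(models, function(m)
    tryCatch(fitDoseResponse(m, conc, values),
             error = function(e) structure(
               list(model = m, converged = FALSE), class = "drcFit"))),
    models)
}

#' Select the best-fitting model
#'
#' Within the nested linear/poly2 pair, poly2 replaces linear only when the
#' nested chi-square test (twice the log-likelihood difference against
#' chi-square with 1 df) has p below `alphaNested`. The pair's winner then
#' competes with the power and exponential models by lowest AIC; exact AIC
#' ties go to the model with fewer parameters, then to model-suite order
#' (power, exp3, exp5, linear, poly2).
#'
#' @param fits named list from [fitAllModels()].
#' @param alphaNested nested-test level (default 0.05).
#' @return the selected `"drcFit"`, or `NULL` when no model converged.
#' @export
selectBestModel <- function(fits, alphaNested = 0.05) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) return(NULL)
  drop <- character()
  if (all(c("linear", "poly2") %in% names(conv))) {
    lr <- 2 * (conv$poly2$loglik - conv$linear$loglik)
    pNested <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    drop <- if (pNested < alphaNested) "linear" else "poly2"
  }
  cand <- conv[setdiff(names(conv), drop)]
  aic <- vapply(cand, `[[`, numeric(1), "aic")
  npar <- vapply(cand, `[[`, numeric(1), "npar")
  ord <- order(aic, npar, match(names(cand), .bmcModels))
  cand[[ord[1]]]
}
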