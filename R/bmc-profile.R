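## Transformed parameter vectors for constrained (profile) optimization,
## on the scaled concentration axis u = c / topConc.
.thetaFromPars <- function(model, pars, top) {
  switch(model,
         linear = c(pars[["a"]], pars[["b"]] * top),
         poly2 = c(pars[["a"]], pars[["b"]] * top, pars[["d"]] * top^2),
         power = c(pars[["a"]], pars[["b"]] * top^pars[["p"]], pars[["p"]]),
         exp3 = c(log(pars[["a"]]), log(pars[["b"]] * top), pars[["p"]]),
         exp5 = c(log(pars[["a"]]), log(pars[["b"]] * top),
                  log(pars[["e"]]), pars[["p"]]))
}

.thetaBounds <- function(model) {
  switch(model,
         linear = list(lower = c(-Inf, -Inf), upper = c(Inf, Inf)),
         poly2 = list(lower = rep(-Inf, 3), upper = rep(Inf, 3)),
         power = list(lower = c(-Inf, -Inf, 1), upper = c(Inf, Inf, 18)),
         exp3 = list(lower = c(-20, log(1e-4), 1),
                     upper = c(20, log(1e4), 18)),
         exp5 = list(lower = c(-20, log(1e-4), -20, 1),
                     upper = c(20, log(1e4), 20, 18)))
}

## Constrained-likelihood profiler for one fit: returns
## function(uX, thetaStart) -> list(loglik, theta), where sigma is tied to
## the benchmark-response constraint sigma = dev(uX) / bmrFactor and the
## mean parameters are re-optimized under it. Model-specialized closures
## keep the objective cheap inside the optimizer.
.makeProfiler <- function(fit, bmrFactor) {
  u <- fit$conc / fit$topConc
  y <- fit$values
  n <- length(y)
  s <- if (fit$model == "exp3") fit$pars[["sign"]] else 1
  env <- new.env(parent = emptyenv())
  env$uX <- 1
  halfLog2pi <- n / 2 * log(2 * pi)
  mkNegll <- switch(fit$model,
    linear = function() function(th) {
      mu <- th[1] + th[2] * u
      sig <- max(abs(th[2] * env$uX) / bmrFactor, 1e-8)
      halfLog2pi + n * log(sig) + sum((y - mu)^2) / (2 * sig^2)
    },
    poly2 = function() function(th) {
      mu <- th[1] + th[2] * u + th[3] * u * u
      sig <- max(abs(th[2] * env$uX + th[3] * env$uX^2) / bmrFactor, 1e-8)
      halfLog2pi + n * log(sig) + sum((y - mu)^2) / (2 * sig^2)
    },
    power = function() function(th) {
      mu <- th[1] + th[2] * u^th[3]
      sig <- max(abs(th[2]) * env$uX^th[3] / bmrFactor, 1e-8)
      halfLog2pi + n * log(sig) + sum((y - mu)^2) / (2 * sig^2)
    },
    exp3 = function() function(th) {
      a <- exp(th[1]); b <- exp(th[2]); p <- th[3]
      mu <- a * exp(s * (b * u)^p)
      if (any(!is.finite(mu))) return(1e30)
      sig <- max(a * abs(exp(s * (b * env$uX)^p) - 1) / bmrFactor, 1e-8)
      halfLog2pi + n * log(sig) + sum((y - mu)^2) / (2 * sig^2)
    },
    exp5 = function() function(th) {
      a <- exp(th[1]); b <- exp(th[2]); e <- exp(th[3]); p <- th[4]
      w <- exp(-(b * u)^p)
      mu <- a * (e - (e - 1) * w)
      if (any(!is.finite(mu))) return(1e30)
      sig <- max(a * abs(e - 1) * (1 - exp(-(b * env$uX)^p)) / bmrFactor,
                 1e-8)
      halfLog2pi + n * log(sig) + sum((y - mu)^2) / (2 * sig^2)
    })
  negll <- mkNegll()
  bounds <- .thetaBounds(fit$model)
  function(uX, thetaStart) {
    env$uX <- uX
    op <- tryCatch(nlminb(thetaStart, negll, lower = bounds$lower,
                          upper = bounds$upper,
                          control = list(iter.max = 60, eval.max = 150)),
                   error = function(e) NULL)
    if (is.null(op) || !is.finite(op$objective))
      return(list(loglik = -Inf, theta = thetaStart))
    list(loglik = -op$objective, theta = op$par)
  }
}

## |f(u) - f(0)| on the scaled axis
.devFun <- function(fit) {
  pars <- fit$pars
  switch(fit$model,
    linear = function(u) abs(pars[["b"]] * fit$topConc * u),
    poly2 = function(u) abs(pars[["b"]] * fit$topConc * u +
                              pars[["d"]] * fit$topConc^2 * u^2),
    power = function(u) abs(pars[["b"]]) * (fit$topConc * u)^pars[["p"]],
    exp3 = function(u) pars[["a"]] *
      abs(exp(pars[["sign"]] * (pars[["b"]] * fit$topConc * u)^pars[["p"]]) - 1),
    exp5 = function(u) pars[["a"]] * abs(pars[["e"]] - 1) *
      (1 - exp(-(pars[["b"]] * fit$topConc * u)^pars[["p"]])))
}

## first concentration (scaled) where dev crosses bmr, on a log grid with
## bisection refinement; NA when the curve never deviates by bmr in bracket
.bmcCrossing <- function(fit, bmr, uLo, uHi, relTol = 1e-8) {
  dev <- .devFun(fit)
  grid <- exp(seq(log(uLo), log(uHi), length.out = 240))
  dv <- dev(grid)
  hit <- which(dv >= bmr)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(grid[1])
  lo <- grid[i - 1]; hi <- grid[i]
  while ((hi - lo) / hi > relTol) {
    mid <- sqrt(lo * hi)
    if (dev(mid) >= bmr) hi <- mid else lo <- mid
  }
  hi
}

## root search for a profile bound: walk geometrically from the BMC until
## the profile log-likelihood falls below the threshold, then bisect
.profileBound <- function(profiler, uBmc, thresh, thetaHat, uLimit,
                          upward) {
  step <- if (upward) 1.6 else 1 / 1.6
  x <- uBmc
  theta <- thetaHat
  for (i in 1:60) {
    xNext <- x * step
    limitHit <- if (upward) xNext >= uLimit else xNext <= uLimit
    if (limitHit) xNext <- uLimit
    pr <- profiler(xNext, theta)
    theta <- pr$theta
    if (pr$loglik < thresh) { # bracket found: root in (x, xNext)
      lo <- min(x, xNext); hi <- max(x, xNext)
      for (j in 1:20) {
        pm <- profiler(mid <- sqrt(lo * hi), theta)
        theta <- pm$theta
        inside <- pm$loglik >= thresh
        if (upward) { if (inside) lo <- mid else hi <- mid }
        else { if (inside) hi <- mid else lo <- mid }
        if ((hi - lo) / hi < 5e-4) break
      }
      return(if (upward) lo else hi)
    }
    x <- xNext
    if (limitHit) return(uLimit) # still inside the CI at the bracket edge
  }
  uLimit
}

#' Benchmark concentration with profile-likelihood confidence bounds
#'
#' The BMC is the concentration at which the fitted curve deviates from
#' its control response by `bmrFactor` times the estimated residual SD
#' (the constant-variance MLE), located by bisection on a log grid within
#' `[1e-6 x lowest positive concentration, 10 x top concentration]`.
#' BMCL/BMCU are the extreme concentrations whose constrained
#' log-likelihood (with sigma tied to the benchmark-response constraint
#' and the mean parameters re-optimized) stays within
#' `qchisq(ciLevel, 1) / 2` of the maximum.
#'
#' @param fit a converged `"drcFit"` from [fitDoseResponse()].
#' @param bmrFactor benchmark response in residual SDs (default 1).
#' @param ciLevel profile confidence level (default 0.95).
#' @return list with `bmc`, `bmcl`, `bmcu` (uM; all `NA` when the curve
#'   never reaches the benchmark response within the search bracket).
#' @export
profileBmc <- function(fit, bmrFactor = 1, ciLevel = 0.95) {
  if (!isTRUE(fit$converged)) stopf("profileBmc needs a converged fit")
  sigma <- max(fit$sigma, 1e-8)
  bmr <- bmrFactor * sigma
  top <- fit$topConc
  minPos <- min(fit$conc[fit$conc > 0])
  uLo <- 1e-6 * minPos / top
  uHi <- 10
  uBmc <- .bmcCrossing(fit, bmr, uLo, uHi)
  if (is.na(uBmc)) return(list(bmc = NA_real_, bmcl = NA_real_,
                               bmcu = NA_real_))
  profiler <- .makeProfiler(fit, bmrFactor)
  thetaHat <- .thetaFromPars(fit$model, fit$pars, top)
  llAtBmc <- profiler(uBmc, thetaHat)
  llMax <- max(fit$loglik, llAtBmc$loglik)
  thresh <- llMax - qchisq(ciLevel, df = 1) / 2
  bmcl <- .profileBound(profiler, uBmc, thresh, llAtBmc$theta,
                        uLimit = uLo, upward = FALSE)
  bmcu <- .profileBound(profiler, uBmc, thresh, llAtBmc$theta,
                        uLimit = uHi, upward = TRUE)
  list(bmc = uBmc * top, bmcl = min(bmcl, uBmc) * top,
       bmcu = max(bmcu, uBmc) * top)
}
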