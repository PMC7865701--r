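#' Firth-penalized Cox proportional-hazards regression
#'
#' Fits the Cox model by maximising the Firth-penalized partial
#' log-likelihood `l*(beta) = l(beta) + 0.5 * log det I(beta)`, where `l` is
#' the Breslow partial log-likelihood and `I` the observed information. The
#' penalty keeps the estimate finite under monotone likelihood (e.g. all
#' events in one arm), where the ordinary maximum partial-likelihood
#' estimate diverges — the situation that arises routinely in small
#' mutation-defined patient subgroups. Per-covariate p-values come from the
#' penalized likelihood-ratio test (the covariate profiled at zero), and
#' [confint()] gives profile-penalized-likelihood intervals.
#'
#' @param formula A model formula with a [survival::Surv()] response and no
#'   intercept term (the Cox model has none; any intercept is dropped).
#' @param data A `data.frame` holding the variables.
#' @param maxit Maximum Newton iterations.
#' @param tol Convergence tolerance on the maximum absolute modified score.
#' @param penalized Set `FALSE` for the ordinary (unpenalized) fit, used
#'   only for diagnostics and large-sample comparisons.
#' @return An object of class `firth_coxph` with components `coefficients`,
#'   `hazard_ratio` (`exp(coefficients)`), `var` (inverse information at
#'   the estimate), `se`, `p_value` (penalized LRT), `loglik`
#'   (penalized log-likelihood at `c(0, estimate)`), `iter`, `converged`,
#'   `n`, `n_events`.
#' @examples
#' d <- data.frame(time = c(4, 3, 1, 1, 2, 2, 3),
#'                 status = c(1, 1, 1, 0, 1, 1, 0),
#'                 x = c(0, 2, 1, 1, 1, 0, 0))
#' fit <- firth_coxph(survival::Surv(time, status) ~ x, d)
#' coef(fit)
#' @export
firth_coxph <- function(formula, data, maxit = 100L, tol = 1e-6,
                        penalized = TRUE) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("response must be a survival::Surv object")
  if (attr(y, "type") != "right") stop("only right-censored survival supported")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- firth_cox_engine(X, time = y[, 1], event = y[, 2],
                          maxit = maxit, tol = tol, penalized = penalized)
  # penalized LRT per covariate: refit with that coefficient profiled at 0
  p <- ncol(X)
  pv <- rep(NA_real_, p)
  for (r in seq_len(p)) {
    restr <- firth_cox_engine(X, y[, 1], y[, 2], maxit = maxit, tol = tol,
                              penalized = penalized,
                              fixed_idx = r, fixed_val = 0)
    lrt <- 2 * (fit$loglik_hat - restr$loglik_hat)
    pv[r] <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  }
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 hazard_ratio = stats::setNames(exp(fit$beta), colnames(X)),
                 var = fit$var, se = stats::setNames(sqrt(diag(fit$var)),
                                                     colnames(X)),
                 p_value = stats::setNames(pv, colnames(X)),
                 loglik = c(null = fit$loglik_null, model = fit$loglik_hat),
                 iter = fit$iter, converged = fit$converged,
                 n = nrow(X), n_events = sum(y[, 2]),
                 penalized = penalized,
                 X = X, time = y[, 1], event = y[, 2],
                 terms = attr(mf, "terms"),
                 maxit = maxit, tol = tol, call = cl),
            class = "firth_coxph")
}

# Newton-type maximisation of the (optionally Firth-penalized) Breslow
# partial log-likelihood, with step-halving and optional profiling of one
# coefficient at a fixed value. X must be a numeric matrix without an
# intercept column.
firth_cox_engine <- function(X, time, event, maxit = 100L, tol = 1e-6,
                             penalized = TRUE, fixed_idx = integer(),
                             fixed_val = numeric()) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1L) stop("at least one covariate is required")
  if (sum(event) < 1L) stop("at least one event is required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (qr(X)$rank < p)
    stop("collinear covariate columns: rank ", qr(X)$rank, " < ", p)

  free <- setdiff(seq_len(p), fixed_idx)
  beta <- rep(0, p)
  beta[fixed_idx] <- fixed_val

  state <- cox_loglik_parts(X, time, event, beta, penalized)
  ll0_at_zero <- {
    s0 <- cox_loglik_parts(X, time, event,
                           replace(rep(0, p), fixed_idx, fixed_val),
                           penalized)
    s0$lstar
  }
  converged <- FALSE
  iter <- 0L
  if (length(free) > 0L) {
    for (iter in seq_len(maxit)) {
      Uf <- state$Ustar[free]
      If <- state$I[free, free, drop = FALSE]
      if (max(abs(Uf)) < tol) { converged <- TRUE; break }
      step <- tryCatch(solve(If, Uf), error = function(e) NULL)
      if (is.null(step)) stop("information matrix is singular")
      # cap the step to keep exp(eta) in range on wild starts
      cap <- 5
      if (max(abs(step)) > cap) step <- step * cap / max(abs(step))
      ok <- FALSE
      for (h in 0:20) {
        cand <- beta
        cand[free] <- beta[free] + step / 2^h
        cand_state <- cox_loglik_parts(X, time, event, cand, penalized)
        if (is.finite(cand_state$lstar) &&
            cand_state$lstar >= state$lstar - 1e-10) {
          beta <- cand; state <- cand_state; ok <- TRUE; break
        }
      }
      if (!ok) break  # no ascent step found; report non-convergence
    }
    if (!converged && max(abs(state$Ustar[free])) < tol) converged <- TRUE
  } else {
    converged <- TRUE
  }
  var_hat <- tryCatch(solve(state$I), error = function(e)
    matrix(NA_real_, p, p))
  list(beta = beta, var = var_hat, loglik_hat = state$lstar,
       loglik_null = ll0_at_zero, iter = iter, converged = converged)
}

# Breslow partial log-likelihood, score, information, and (optionally) the
# Firth-modified score and penalized log-likelihood at beta.
cox_loglik_parts <- function(X, time, event, beta, penalized = TRUE) {
  p <- ncol(X)
  n <- nrow(X)
  ord <- order(time, decreasing = TRUE)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]
  es <- event[ord]
  eta <- drop(Xs %*% beta)
  off <- max(eta)
  w <- exp(eta - off)

  cs0 <- cumsum(w)
  cs1 <- apply(Xs * w, 2, cumsum)
  if (n == 1L) cs1 <- matrix(cs1, 1L, p)
  # second moments: p*(p+1)/2 columns (upper triangle), expanded on use
  ut <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  cs2 <- apply(Xs[, ut[, 1], drop = FALSE] * Xs[, ut[, 2], drop = FALSE] * w,
               2, cumsum)
  if (n == 1L) cs2 <- matrix(cs2, 1L, nrow(ut))
  need_third <- penalized
  if (need_third) {
    trip <- expand.grid(r = seq_len(p), k = seq_len(nrow(ut)))
    cs3 <- apply(Xs[, trip$r, drop = FALSE] *
                   Xs[, ut[trip$k, 1], drop = FALSE] *
                   Xs[, ut[trip$k, 2], drop = FALSE] * w, 2, cumsum)
    if (n == 1L) cs3 <- matrix(cs3, 1L, nrow(trip))
  }
  expand_sym <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(ut[, 1], ut[, 2])] <- v
    M[cbind(ut[, 2], ut[, 1])] <- v
    M
  }

  ev_times <- unique(ts[es == 1])
  ll <- 0
  U <- rep(0, p)
  I <- matrix(0, p, p)
  dI <- if (need_third) replicate(p, matrix(0, p, p), simplify = FALSE) else NULL
  for (t_k in ev_times) {
    at_risk <- sum(ts >= t_k)        # sorted descending: prefix of length m
    ev_idx <- which(ts == t_k & es == 1)
    d <- length(ev_idx)
    S0 <- unname(cs0[at_risk])
    m1 <- cs1[at_risk, ] / S0
    S2n <- expand_sym(cs2[at_risk, ]) / S0
    V <- S2n - tcrossprod(m1)
    ll <- ll + sum(eta[ev_idx]) - d * (log(S0) + off)
    U <- U + colSums(Xs[ev_idx, , drop = FALSE]) - d * m1
    I <- I + d * V
    if (need_third) {
      for (r in seq_len(p)) {
        M3r <- expand_sym(cs3[at_risk, trip$r == r]) / S0
        dm1 <- S2n[, r] - m1 * m1[r]
        dV <- M3r - m1[r] * S2n - tcrossprod(dm1, m1) - tcrossprod(m1, dm1)
        dI[[r]] <- dI[[r]] + d * dV
      }
    }
  }
  if (penalized) {
    ldet <- determinant(I, logarithm = TRUE)
    if (ldet$sign <= 0) return(list(lstar = -Inf, Ustar = U, I = I))
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) return(list(lstar = -Inf, Ustar = U, I = I))
    Ustar <- U + 0.5 * vapply(seq_len(p),
                              function(r) sum(Iinv * t(dI[[r]])), numeric(1))
    list(lstar = unname(ll + 0.5 * as.numeric(ldet$modulus)),
         Ustar = unname(Ustar), I = I)
  } else {
    list(lstar = unname(ll), Ustar = unname(U), I = I)
  }
}

#' @export
print.firth_coxph <- function(x, digits = 4, ...) {
  cat(if (x$penalized) "Firth-penalized" else "Unpenalized",
      "Cox proportional-hazards fit\n")
  cat("n =", x$n, ", events =", x$n_events,
      if (!x$converged) " [NOT CONVERGED]", "\n")
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratio,
                    se = x$se, p = x$p_value)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.firth_coxph <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  tab <- data.frame(coef = object$coefficients,
                    HR = object$hazard_ratio,
                    se = object$se,
                    HR_lower = exp(ci[, 1]), HR_upper = exp(ci[, 2]),
                    p = object$p_value)
  out <- list(table = tab, loglik = object$loglik, n = object$n,
              n_events = object$n_events, converged = object$converged,
              iter = object$iter, penalized = object$penalized,
              level = level)
  class(out) <- "summary.firth_coxph"
  out
}

#' @export
print.summary.firth_coxph <- function(x, digits = 4, ...) {
  cat(if (x$penalized) "Firth-penalized" else "Unpenalized",
      "Cox model: n =", x$n, ", events =", x$n_events, "\n")
  cat("penalized log-likelihood:", format(x$loglik[["model"]], digits = 7),
      "(null:", format(x$loglik[["null"]], digits = 7), ")\n")
  cat("converged:", x$converged, "in", x$iter, "iterations\n\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.firth_coxph <- function(object, ...) object$coefficients

#' @export
vcov.firth_coxph <- function(object, ...) object$var

#' @export
logLik.firth_coxph <- function(object, ...) {
  structure(object$loglik[["model"]], df = length(object$coefficients),
            class = "logLik")
}

#' Profile-penalized-likelihood confidence intervals
#'
#' Endpoints are the coefficient values at which twice the drop in the
#' profile penalized log-likelihood equals the chi-square quantile — the
#' interval whose test inversion is the penalized LRT.
#'
#' @param object A `firth_coxph` fit.
#' @param parm Covariate names or indices (default: all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix with lower/upper columns on the coefficient scale.
#' @export
confint.firth_coxph <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- object$coefficients
  idx <- if (is.null(parm)) seq_along(cf)
         else if (is.character(parm)) match(parm, names(cf)) else parm
  crit <- stats::qchisq(level, df = 1)
  ll_hat <- object$loglik[["model"]]
  out <- matrix(NA_real_, length(idx), 2,
                dimnames = list(names(cf)[idx],
                                paste0(c((1 - level) / 2,
                                         1 - (1 - level) / 2) * 100, " %")))
  for (j in seq_along(idx)) {
    r <- idx[j]
    prof <- function(b) {
      restr <- firth_cox_engine(object$X, object$time, object$event,
                                maxit = object$maxit, tol = object$tol,
                                penalized = object$penalized,
                                fixed_idx = r, fixed_val = b)
      2 * (ll_hat - restr$loglik_hat) - crit
    }
    out[j, 1] <- profile_root(prof, cf[r], direction = -1)
    out[j, 2] <- profile_root(prof, cf[r], direction = +1)
  }
  out
}

# Root of the profile deviance crossing, bracketing outward from the MLE.
profile_root <- function(f, at, direction, step0 = 0.5, max_expand = 30L) {
  lo <- at
  step <- step0
  for (k in seq_len(max_expand)) {
    hi <- at + direction * step
    if (f(hi) > 0)
      return(stats::uniroot(f, sort(c(lo, hi)), tol = 1e-5)$root)
    lo <- hi
    step <- step * 2
  }
  direction * Inf  # profile never crossed: open-ended interval
}

#' @export
predict.firth_coxph <- function(object, newdata = NULL,
                                type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else {
    tt <- stats::delete.response(object$terms)
    mm <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  lp <- drop(X %*% object$coefficients)
  if (type == "lp") lp else exp(lp)
}

#' Penalized likelihood-ratio test of a single coefficient
#'
#' Tests `H0: beta[covariate] = value` by refitting with the coefficient
#' profiled at `value` and comparing penalized log-likelihoods.
#'
#' @param object A `firth_coxph` fit.
#' @param covariate Covariate name or index.
#' @param value Null value of the coefficient (default 0).
#' @return A list with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
firth_lrt <- function(object, covariate, value = 0) {
  cf <- object$coefficients
  r <- if (is.character(covariate)) match(covariate, names(cf)) else covariate
  if (is.na(r)) stop("unknown covariate: ", covariate)
  restr <- firth_cox_engine(object$X, object$time, object$event,
                            maxit = object$maxit, tol = object$tol,
                            penalized = object$penalized,
                            fixed_idx = r, fixed_val = value)
  stat <- max(2 * (object$loglik[["model"]] - restr$loglik_hat), 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
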