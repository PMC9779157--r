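# Maximum-likelihood calibration of the decision model.

#' Fit the escape-decision model by maximum likelihood
#'
#' Maximizes the discrete-time survival likelihood of a decision panel over
#' the constant and the requested covariate coefficients. The hazard is the
#' natural-response-corrected probit `C + (1 - C) * pnorm(eta)`; `C` is
#' plugged in from the control group (or supplied), following the standard
#' control-group treatment of the natural response rate, and the noise scale
#' is normalized to 1.
#'
#' Optimization is damped Newton with analytic gradient and Hessian,
#' line-searched so the objective decreases monotonically, stopping when the
#' gradient norm drops below `gtol`. The plain probit likelihood is fitted
#' from an all-zero start (it is globally concave); the corrected
#' likelihood (`C > 0`) is not concave, so it starts from the plain-probit
#' solution with the constant shifted to the corrected response scale. The
#' fit is deterministic given the data and options. Standard errors come from the
#' inverse observed information. Covariates with two-sided significance
#' above `alpha` are flagged; with `screen = TRUE` they are dropped in one
#' pass and the model refit, mirroring the published screening that removed
#' education.
#'
#' @param data Survey panel data frame (see [simulate_survey()] /
#'   [read_survey()]). Control rows (`is_control == 1`) are used only for
#'   the natural-response estimate.
#' @param covariates Character vector of covariate columns to enter;
#'   defaults to the seven personal attributes plus the three situational
#'   factors, intersected with the columns present.
#' @param natural `"control"` (estimate C from control rows; 0 when there
#'   are none) or a number in [0, 1).
#' @param censored Include censored respondents (see [decision_loglik()]).
#' @param screen Drop covariates with significance above `alpha` in one
#'   pass and refit.
#' @param alpha Screening significance level (default 0.05).
#' @param init Optional numeric vector of starting values (const first, then
#'   covariates in order).
#' @param gtol Gradient-norm convergence tolerance.
#' @param maxit Iteration cap for the quasi-Newton stage.
#' @return Object of class `decision_fit` with components `coefficients`
#'   (named vector), `se`, `z`, `sig`, `ci` (two-column matrix), `vcov`,
#'   `loglik`, `iterations`, `converged`, `pearson` (statistic, df),
#'   `natural` (rate, se, counts, source), `excluded` (screened-out
#'   covariates), `flagged` (non-significant but retained), `n`, `n_subjects`,
#'   and `coef_set` (the fitted [coef_set()]).
#' @export
fit_decision_model <- function(data, covariates = NULL,
                               natural = "control", censored = TRUE,
                               screen = FALSE, alpha = 0.05, init = NULL,
                               gtol = 1e-8, maxit = 500L) {
  ctrl <- data[data$is_control == 1L, , drop = FALSE]
  dat <- data[data$is_control != 1L, , drop = FALSE]
  if (!nrow(dat)) stop("no non-control rows to fit", call. = FALSE)
  check_panel(dat)
  if (!censored) {
    esc <- unique(dat$id[dat$response == 1L])
    dat <- dat[dat$id %in% esc, , drop = FALSE]
  }

  if (is.null(covariates))
    covariates <- intersect(c(prt_fields(), "rcs", "dfd", "rnc"), names(dat))
  miss <- setdiff(covariates, names(dat))
  if (length(miss))
    stop("covariate column(s) absent from data: ",
         paste(miss, collapse = ", "), call. = FALSE)

  if (identical(natural, "control")) {
    if (nrow(ctrl)) {
      nr <- natural_response(nrow(ctrl), sum(ctrl$response))
      nat_src <- "control group"
    } else {
      nr <- list(rate = 0, se = NA_real_, subjects = 0L, responses = 0L)
      nat_src <- "none (C = 0)"
    }
  } else {
    if (!is.numeric(natural) || natural < 0 || natural >= 1)
      stop("natural must be 'control' or a rate in [0, 1)", call. = FALSE)
    nr <- list(rate = natural, se = NA_real_, subjects = NA_integer_,
               responses = NA_integer_)
    nat_src <- "supplied"
  }

  fit1 <- probit_panel_fit(dat, covariates, nr$rate, init, gtol, maxit)
  flagged <- names(which(fit1$sig[covariates] > alpha))
  excluded <- character(0)
  if (screen && length(flagged)) {
    excluded <- flagged
    keep <- setdiff(covariates, excluded)
    fit1 <- probit_panel_fit(dat, keep, nr$rate, NULL, gtol, maxit)
    covariates <- keep
    flagged <- names(which(fit1$sig[covariates] > alpha))
  }

  cs <- coef_set(const = fit1$coefficients[["const"]],
                 attr = fit1$coefficients[intersect(covariates,
                                                    prt_fields())],
                 context = {
                   cc <- c(rcs = 0, dfd = 0, rnc = 0)
                   for (f in intersect(covariates, names(cc)))
                     cc[f] <- fit1$coefficients[[f]]
                   cc
                 },
                 natural_rate = nr$rate)

  structure(c(fit1,
              list(natural = c(nr, list(source = nat_src)),
                   excluded = excluded, flagged = flagged,
                   covariates = covariates, coef_set = cs,
                   censored = censored, alpha = alpha)),
            class = "decision_fit")
}

# Core maximization of the row-factorized panel likelihood: damped Newton
# with analytic gradient and Hessian. The plain probit likelihood (C = 0)
# is globally concave; the corrected likelihood (C > 0) is not, so it is
# started from the plain-probit solution with the constant shifted to match
# the observed response rate, and every Newton step is line-searched so the
# objective decreases monotonically.
probit_panel_fit <- function(dat, covariates, C, init, gtol, maxit) {
  X <- cbind(const = 1, as.matrix(dat[covariates]))
  storage.mode(X) <- "double"
  y <- as.numeric(dat$response)
  sdev <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sdev == 0))
    stop("non-identifiable (constant) covariate(s): ",
         paste(covariates[sdev == 0], collapse = ", "), call. = FALSE)

  parts <- function(b) {
    eta <- drop(X %*% b)
    phi <- stats::dnorm(eta)
    p <- C + (1 - C) * stats::pnorm(eta)
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    list(eta = eta, phi = phi, p = p)
  }
  negll_of <- function(pp) -sum(y * log(pp$p) + (1 - y) * log1p(-pp$p))
  neggr_of <- function(pp) {
    w <- (1 - C) * pp$phi * (y - pp$p) / (pp$p * (1 - pp$p))
    -drop(crossprod(X, w))
  }
  neghess_of <- function(pp) {
    a <- (1 - C) * pp$phi
    u <- y - pp$p
    v <- 1 / (pp$p * (1 - pp$p))
    dw <- -pp$eta * a * u * v - a^2 * v - a^2 * u * (1 - 2 * pp$p) * v^2
    -crossprod(X, X * dw)
  }

  b <- if (is.null(init)) {
    if (C > 0) {
      b0 <- probit_panel_fit(dat, covariates, 0, NULL, 1e-6,
                             maxit)$coefficients
      adj <- max((mean(y) - C) / (1 - C), 1e-3)
      b0[1] <- b0[1] + stats::qnorm(adj) - stats::qnorm(mean(y))
      b0
    } else numeric(ncol(X))
  } else as.numeric(init)
  if (length(b) != ncol(X))
    stop("init must have length ", ncol(X), call. = FALSE)

  pp <- parts(b)
  f <- negll_of(pp)
  iters <- 0L
  converged <- FALSE
  H <- neghess_of(pp)
  while (iters < maxit) {
    g <- neggr_of(pp)
    H <- neghess_of(pp)
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    # fall back to a scaled gradient step if the Hessian is unusable or
    # does not give a descent direction
    if (is.null(step) || sum(step * g) <= 0)
      step <- g / max(sqrt(sum(g^2)), 1)
    s <- 1
    repeat {
      bn <- b - s * step
      ppn <- parts(bn)
      fn <- negll_of(ppn)
      if (is.finite(fn) && fn <= f + 1e-12) break
      s <- s / 2
      if (s < 1e-10) break
    }
    if (!is.finite(fn) || fn > f + 1e-12) break
    if (abs(f - fn) < 1e-14 * (abs(f) + 1) && max(abs(g)) < sqrt(gtol)) {
      b <- bn; pp <- ppn; f <- fn
      converged <- TRUE
      break
    }
    b <- bn; pp <- ppn; f <- fn
    iters <- iters + 1L
  }
  if (!converged) converged <- max(abs(neggr_of(pp))) < gtol

  H <- neghess_of(pp)
  vc <- tryCatch(solve(H), error = function(e)
    stop("singular information matrix; model not identified",
         call. = FALSE))
  nm <- c("const", covariates)
  names(b) <- nm
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc), 0))
  z <- b / se
  sig <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(lower = b - stats::qnorm(0.975) * se,
              upper = b + stats::qnorm(0.975) * se)

  pearson <- sum((y - pp$p)^2 / (pp$p * (1 - pp$p)))

  list(coefficients = b, se = se, z = z, sig = sig, ci = ci, vcov = vc,
       loglik = -f, iterations = iters,
       converged = converged,
       pearson = list(statistic = pearson, df = length(y) - length(b)),
       n = length(y), n_subjects = length(unique(dat$id)),
       gradient_norm = max(abs(neggr_of(pp))))
}

#' @export
print.decision_fit <- function(x, ...) {
  cat("Pre-evacuation decision model fit\n")
  cat(sprintf("  %d respondent-period rows, %d respondents; logLik %.3f\n",
              x$n, x$n_subjects, x$loglik))
  cat(sprintf("  converged: %s (%d iterations, |grad| %.2e)\n",
              if (x$converged) "yes" else "NO", x$iterations,
              x$gradient_norm))
  print(round(summary(x)$table, 4))
  if (length(x$excluded))
    cat("  excluded (screened out):",
        paste(x$excluded, collapse = ", "), "\n")
  if (length(x$flagged))
    cat("  flagged non-significant:",
        paste(x$flagged, collapse = ", "), "\n")
  if (!is.na(x$natural$rate))
    cat(sprintf("  natural response rate: %.4f (%s)\n", x$natural$rate,
                x$natural$source))
  invisible(x)
}

#' @export
summary.decision_fit <- function(object, ...) {
  tab <- cbind(B = object$coefficients, `S.E.` = object$se, Z = object$z,
               `Sig.` = object$sig, object$ci)
  structure(list(table = tab, pearson = object$pearson,
                 natural = object$natural, loglik = object$loglik,
                 iterations = object$iterations,
                 converged = object$converged),
            class = "summary.decision_fit")
}

#' @export
print.summary.decision_fit <- function(x, ...) {
  print(round(x$table, 4))
  cat(sprintf("Pearson-type fit statistic %.2f on %d df\n",
              x$pearson$statistic, x$pearson$df))
  invisible(x)
}

#' @export
coef.decision_fit <- function(object, ...) object$coefficients

#' @export
vcov.decision_fit <- function(object, ...) object$vcov

#' @export
logLik.decision_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Export a fit report
#'
#' Writes the estimates table (B, S.E., Z, Sig., 95% CI), the covariance of
#' the estimates, the convergence block, the Pearson-type fit statistic and
#' the natural-response block as a JSON document, and optionally a plain
#' text rendering.
#'
#' @param fit A [fit_decision_model()] result.
#' @param path Output path for the JSON report.
#' @param text_path Optional path for a human-readable text report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, text_path = NULL) {
  stopifnot(inherits(fit, "decision_fit"))
  est <- data.frame(term = names(fit$coefficients),
                    B = unname(fit$coefficients), SE = unname(fit$se),
                    Z = unname(fit$z), Sig = unname(fit$sig),
                    ci_lower = unname(fit$ci[, "lower"]),
                    ci_upper = unname(fit$ci[, "upper"]))
  obj <- list(schema = "preevac-fit/1",
              estimates = est,
              covariance = as.data.frame(fit$vcov),
              convergence = list(iterations = fit$iterations,
                                 converged = fit$converged,
                                 gradient_norm = fit$gradient_norm,
                                 loglik = fit$loglik),
              fit_test = fit$pearson,
              natural_response = fit$natural,
              excluded = fit$excluded, flagged = fit$flagged,
              n = fit$n, n_subjects = fit$n_subjects)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(text_path)) {
    con <- file(text_path, "w", encoding = "UTF-8")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(fit)
    cat("\nCovariance of estimates:\n")
    print(signif(fit$vcov, 4))
  }
  invisible(path)
}
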