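# The decision core: latent linear predictor, per-period probit hazard,
# staged-response probabilities, first-passage distribution and likelihood.

#' Latent linear predictor of the escape decision
#'
#' The deterministic part of the difference between subjective and objective
#' risk utility, evaluated at the escape-selection threshold: the constant
#' plus the coded personal attributes weighted by their coefficients plus
#' the three standardized situational factors weighted by theirs.
#' Attributes absent from the coefficient set (e.g. education after
#' screening) are omitted.
#'
#' @param ped Data frame (or named list) of coded attributes, one row per
#'   pedestrian.
#' @param ctx Data frame (or named list) with unit-interval `rcs`, `dfd`,
#'   `rnc`; recycled against `ped`.
#' @param coefs A [coef_set()].
#' @return Numeric vector of linear predictors.
#' @examples
#' linear_predictor(list(age = 2, gen = 0, edu = 2, time = 1, group = 1,
#'                       zone = 1, mode = 6),
#'                  list(rcs = 0.25, dfd = 0.25, rnc = 0.25),
#'                  default_coefs())
#' @export
linear_predictor <- function(ped, ctx, coefs) {
  coefs <- as_coef_set(coefs)
  ped <- as.data.frame(ped)
  ctx <- as.data.frame(ctx)
  n <- max(nrow(ped), nrow(ctx))
  lp <- rep(coefs$const, n)
  for (f in names(coefs$attr)) {
    v <- ped[[f]]
    if (is.null(v) || anyNA(v))
      stop("pedestrian record lacks coded attribute '", f,
           "' required by the coefficient set", call. = FALSE)
    lp <- lp + coefs$attr[[f]] * rep_len(v, n)
  }
  for (f in c("rcs", "dfd", "rnc")) {
    v <- ctx[[f]]
    if (is.null(v) || anyNA(v))
      stop("risk context lacks '", f, "'", call. = FALSE)
    lp <- lp + coefs$context[[f]] * rep_len(v, n)
  }
  lp
}

#' Per-period escape hazard
#'
#' Probability that a waiting pedestrian decides to escape in the current
#' decision period: the probit probability of the latent risk difference
#' exceeding the escape-selection threshold, floored by the natural-response
#' rate C through Abbott's correction,
#' \deqn{p = C + (1 - C)\,\Phi(\eta/\sigma).}
#' With `C = 0` and `sigma = 1` this is the plain probit choice probability.
#'
#' @param lp Linear predictor(s) from [linear_predictor()].
#' @param coefs A [coef_set()] (only `sigma` and `natural_rate` are used).
#' @return Hazard probabilities in `(C, 1)`.
#' @export
hazard_prob <- function(lp, coefs) {
  coefs <- as_coef_set(coefs)
  coefs$natural_rate +
    (1 - coefs$natural_rate) * stats::pnorm(lp / coefs$sigma)
}

#' Staged-response probabilities
#'
#' The staged (cumulative, shared-slope) form of the model: with ordered
#' intercepts \eqn{\tau_1 \le \dots \le \tau_K} and linear predictor
#' \eqn{\eta} (excluding the constant), the probability of responding at or
#' below stage k is \eqn{\Phi(\tau_k + \eta)}, following the probit
#' convention `PROBIT(p) = intercept + Bx`. The K+1 category probabilities
#' are the successive differences; they are nonnegative whenever the
#' intercepts are ordered and always sum to 1.
#'
#' @param lp Linear predictor(s) excluding the constant.
#' @param thresholds Ordered intercepts, or a [coef_set()] whose
#'   `thresholds` field is used.
#' @return Matrix (length(lp) x K+1) of stage probabilities, columns
#'   `stage1` (lowest response intensity) to `stageK+1`.
#' @export
stage_probabilities <- function(lp, thresholds) {
  if (inherits(thresholds, "coef_set")) thresholds <- thresholds$thresholds
  if (!length(thresholds))
    stop("no staged-response intercepts supplied", call. = FALSE)
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending", call. = FALSE)
  cum <- vapply(thresholds, function(tau) stats::pnorm(tau + lp),
                numeric(length(lp)))
  cum <- matrix(cum, nrow = length(lp))
  pr <- cbind(cum, 1) - cbind(0, cum)
  colnames(pr) <- paste0("stage", seq_len(ncol(pr)))
  pr
}

#' First-passage distribution over decision periods
#'
#' Decisions in successive periods are conditionally independent given the
#' hazards, so the probability that the first escape happens in period t is
#' the hazard at t times the survival through all earlier periods,
#' \deqn{P(t) = p_t \prod_{n<t} (1 - p_n),}
#' and the probability of never escaping within the horizon (the censor
#' mass) is \eqn{\prod_{n \le T} (1 - p_n)}. The masses sum to 1 exactly.
#'
#' @param hazards Numeric vector of per-period hazards in [0, 1].
#' @return List with `prob` (length-T escape-period probabilities) and
#'   `censor` (remaining mass).
#' @examples
#' first_passage(c(0.1, 0.2, 0.3))
#' @export
first_passage <- function(hazards) {
  if (any(!is.finite(hazards)) || any(hazards < 0) || any(hazards > 1))
    stop("hazards must lie in [0, 1]", call. = FALSE)
  surv <- cumprod(1 - hazards)
  prob <- hazards * c(1, surv[-length(surv)])
  if (!length(hazards)) prob <- numeric(0)
  list(prob = prob,
       censor = if (length(hazards)) surv[length(surv)] else 1)
}

#' Discrete-time survival log-likelihood of a decision panel
#'
#' Each respondent contributes the log first-passage probability of the
#' observed escape period; a respondent who never escapes within the
#' observed horizon contributes the log censor mass (standard discrete-time
#' survival practice, switchable off with `censored = FALSE`, which then
#' counts observed escapes only). Because escape is absorbing, the panel
#' likelihood factorizes into independent Bernoulli terms over
#' respondent-period rows.
#'
#' A zero-probability observation (hazard exactly 0 at an observed escape,
#' or exactly 1 at an observed wait) yields `-Inf` with a diagnostic
#' attribute rather than an error.
#'
#' @param data Survey data frame (see [simulate_survey()]); control rows are
#'   ignored.
#' @param coefs A [coef_set()].
#' @param censored Include censored respondents' survival contributions.
#' @return Log-likelihood (scalar); attribute `n_bad` counts
#'   zero-probability rows when the value is `-Inf`.
#' @export
decision_loglik <- function(data, coefs, censored = TRUE) {
  coefs <- as_coef_set(coefs)
  dat <- data[data$is_control %in% c(0L, NA), , drop = FALSE]
  check_panel(dat)
  if (!censored) {
    esc <- unique(dat$id[dat$response == 1L])
    dat <- dat[dat$id %in% esc, , drop = FALSE]
  }
  lp <- linear_predictor(dat[prt_fields()],
                         dat[c("rcs", "dfd", "rnc")], coefs)
  p <- hazard_prob(lp, coefs)
  y <- dat$response
  term <- ifelse(y == 1L, log(p), log1p(-p))
  ll <- sum(term)
  if (!is.finite(ll)) {
    n_bad <- sum(!is.finite(term))
    warning(n_bad, " observation(s) have probability zero under the model",
            call. = FALSE)
    attr(ll, "n_bad") <- n_bad
  }
  ll
}

# panel sanity: at most one escape per respondent and only in the last
# observed period
check_panel <- function(dat) {
  need <- c("id", "period", "response")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(dat$response %ni% c(0L, 1L)))
    stop("response must be 0/1", call. = FALSE)
  esc <- dat[dat$response == 1L, , drop = FALSE]
  if (anyDuplicated(esc$id))
    stop("a respondent escapes more than once", call. = FALSE)
  last <- tapply(dat$period, dat$id, max)
  bad <- esc$period != last[as.character(esc$id)]
  if (any(bad))
    stop("escape recorded before the final observed period for id(s): ",
         paste(utils::head(esc$id[bad], 5L), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Natural-response rate from a control group
#'
#' The baseline probability of responding absent the modelled stimulus,
#' estimated as the control-group response proportion with its binomial
#' standard error.
#'
#' @param subjects Number of control subjects (> 0).
#' @param responses Number of control responses (0..subjects).
#' @return List with `rate`, `se`, `subjects`, `responses`.
#' @examples
#' natural_response(2973, 589)
#' @export
natural_response <- function(subjects, responses) {
  if (!is.numeric(subjects) || length(subjects) != 1L || subjects <= 0)
    stop("subjects must be a positive count", call. = FALSE)
  if (!is.numeric(responses) || length(responses) != 1L ||
      responses < 0 || responses > subjects)
    stop("responses must lie in 0..subjects", call. = FALSE)
  rate <- responses / subjects
  list(rate = rate,
       se = sqrt(rate * (1 - rate) / subjects),
       subjects = subjects, responses = responses)
}
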