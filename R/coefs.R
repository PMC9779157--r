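# Coefficient sets for the escape-selection threshold model.

#' Coefficient set of the escape-selection threshold model
#'
#' Bundles every estimable quantity of the decision model: the constant of
#' the latent risk-difference equation, the ordered intercepts of the staged
#' (cumulative) response model, the personal-attribute coefficients, the
#' coefficients of the three standardized situational factors, the latent
#' noise scale, and the natural-response rate.
#'
#' Only the differences between subjective and objective utility
#' coefficients are identifiable, so the set carries those differences
#' directly. The noise scale `sigma` is not separately identifiable from the
#' coefficients in a probit and is fixed at 1 by convention; it is kept as a
#' field so rescaled models can be represented.
#'
#' @param const Constant term of the latent equation.
#' @param attr Named numeric vector of personal-attribute coefficients over
#'   a subset of `age, gen, edu, time, group, zone, mode`; attributes absent
#'   from the vector are excluded from the model.
#' @param context Named numeric vector with elements `rcs`, `dfd`, `rnc`.
#' @param thresholds Ordered numeric vector of staged-response intercepts
#'   (ascending).
#' @param sigma Positive latent noise scale (default 1).
#' @param natural_rate Baseline response probability in [0, 1) absent the
#'   modelled stimulus.
#' @return Object of class `coef_set`.
#' @seealso [default_coefs()] for the published calibration.
#' @export
coef_set <- function(const, attr, context = c(rcs = 1, dfd = 1, rnc = 1),
                     thresholds = numeric(0), sigma = 1, natural_rate = 0) {
  stopifnot(is.numeric(const), length(const) == 1L)
  if (length(attr)) {
    if (is.null(names(attr)) || any(!nzchar(names(attr))))
      stop("attr coefficients must be named", call. = FALSE)
    bad <- setdiff(names(attr), prt_fields())
    if (length(bad))
      stop("unknown attribute coefficient(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!all(c("rcs", "dfd", "rnc") %in% names(context)))
    stop("context coefficients must name rcs, dfd, rnc", call. = FALSE)
  if (length(thresholds) && is.unsorted(thresholds))
    stop("thresholds must be sorted ascending", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  if (natural_rate < 0 || natural_rate >= 1)
    stop("natural_rate must lie in [0, 1)", call. = FALSE)
  structure(list(const = unname(const),
                 attr = attr[intersect(prt_fields(), names(attr))],
                 context = context[c("rcs", "dfd", "rnc")],
                 thresholds = as.numeric(thresholds),
                 sigma = unname(sigma),
                 natural_rate = unname(natural_rate)),
            class = "coef_set")
}

as_coef_set <- function(x) {
  if (inherits(x, "coef_set")) return(x)
  if (is.list(x))
    return(coef_set(const = x$const, attr = unlist(x$attr),
                    context = unlist(x$context),
                    thresholds = as.numeric(x$thresholds %||% numeric(0)),
                    sigma = x$sigma %||% 1,
                    natural_rate = x$natural_rate %||% 0))
  stop("cannot interpret object as a coef_set", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published calibration of the decision model
#'
#' The coefficient set calibrated on the 4527-questionnaire survey: the
#' retained personal attributes (education was screened out as
#' non-significant), the two staged-response intercepts, and the
#' natural-response rate estimated from the 2973-subject control group.
#' The three situational-factor coefficients were not published; they
#' default to 1.0 on the standardized unit scales and every simulated
#' quantity is conditional on that choice.
#'
#' @param context Optional override of the situational-factor coefficients.
#' @return A [coef_set()].
#' @export
default_coefs <- function(context = c(rcs = 1, dfd = 1, rnc = 1)) {
  coef_set(const = -3.212,
           attr = c(age = -0.015, gen = 0.011, time = 0.004, group = 0.013,
                    zone = -0.013, mode = 0.002),
           context = context,
           thresholds = c(-3.212, -3.185),
           sigma = 1,
           natural_rate = 0.1981)
}

#' @export
print.coef_set <- function(x, ...) {
  cat("Escape-selection coefficient set\n")
  cat("  const:        ", format(x$const), "\n")
  if (length(x$attr))
    cat("  attributes:   ",
        paste(names(x$attr), format(unname(x$attr)), sep = "=",
              collapse = ", "), "\n")
  cat("  context:      ",
      paste(names(x$context), format(unname(x$context)), sep = "=",
            collapse = ", "), "\n")
  if (length(x$thresholds))
    cat("  thresholds:   ", paste(format(x$thresholds), collapse = ", "),
        "\n")
  cat("  sigma:        ", format(x$sigma), "\n")
  cat("  natural rate: ", format(x$natural_rate), "\n")
  invisible(x)
}

#' Serialize a coefficient set to / from JSON
#'
#' The JSON document carries a `schema` version tag and explicit field
#' names, so coefficient files remain readable across package versions.
#'
#' @param coefs A [coef_set()].
#' @param path File path.
#' @return `write_coefs` returns `path` invisibly; `read_coefs` returns the
#'   [coef_set()].
#' @export
write_coefs <- function(coefs, path) {
  coefs <- as_coef_set(coefs)
  obj <- list(schema = "preevac-coefs/1",
              const = coefs$const,
              attr = as.list(coefs$attr),
              context = as.list(coefs$context),
              thresholds = coefs$thresholds,
              sigma = coefs$sigma,
              natural_rate = coefs$natural_rate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefs
#' @export
read_coefs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "preevac-coefs/1"))
    stop("unrecognized coefficient schema in ", path, call. = FALSE)
  coef_set(const = obj$const, attr = unlist(obj$attr),
           context = unlist(obj$context),
           thresholds = as.numeric(obj$thresholds %||% numeric(0)),
           sigma = obj$sigma, natural_rate = obj$natural_rate)
}
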