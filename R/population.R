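# Pedestrian attributes and their ordinal/categorical codings, plus a
# synthetic questionnaire-population generator.

#' Attribute coding tables
#'
#' The seven personal risk-tolerance (PRT) attributes are recorded on fixed
#' category scales: age in five grades, gender as a male indicator, education
#' in three grades, familiarity time with the area in four grades, group size
#' in four grades, residence-distance zone in five grades, and travel mode as
#' a seven-way categorical code entered numerically.
#'
#' @return A named list; each element is a named integer vector mapping the
#'   category label to its numeric code.
#' @examples
#' attribute_codings()$gen
#' @export
attribute_codings <- function() {
  list(
    age   = c("<18" = 1L, "18-30" = 2L, "31-45" = 3L, "46-60" = 4L, ">60" = 5L),
    gen   = c("Male" = 1L, "Female" = 0L),
    edu   = c("High school and below" = 1L, "College" = 2L,
              "Graduate and above" = 3L),
    time  = c("Less than 2 years" = 1L, "2-5 years" = 2L, "5-10 years" = 3L,
              "10 years above" = 4L),
    group = c("1 ped" = 1L, "2 ped" = 2L, "3 ped" = 3L, "3 ped and above" = 4L),
    # five named distance bands; coded 1..5 so each band has its own grade
    zone  = c("<2 km" = 1L, "2-5 km" = 2L, "5-10 km" = 3L, "10-30 km" = 4L,
              "30 km above" = 5L),
    mode  = c("Car" = 1L, "Subway" = 2L, "Tricycle" = 3L,
              "Conventional bus" = 4L, "Bicycle" = 5L, "walk" = 6L,
              "taxi" = 7L)
  )
}

#' Valid numeric ranges of the coded attributes
#'
#' @return Named list of sorted integer vectors, the admissible codes per
#'   attribute field.
#' @export
attribute_levels <- function() {
  lapply(attribute_codings(), function(x) sort(unname(x)))
}

prt_fields <- function() c("age", "gen", "edu", "time", "group", "zone", "mode")

check_codes <- function(rec, fields = prt_fields()) {
  lv <- attribute_levels()
  for (f in fields) {
    v <- rec[[f]]
    if (is.null(v) || anyNA(v))
      stop("missing value for attribute '", f, "'", call. = FALSE)
    bad <- !(v %in% lv[[f]])
    if (any(bad))
      stop("attribute '", f, "' has out-of-range code(s): ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Encode a labelled questionnaire record to numeric codes
#'
#' Matches each raw label against the fixed category table
#' ([attribute_codings()]) and returns the numeric coding. Matching is
#' case-insensitive and tolerant of surrounding whitespace; an unknown label
#' is an error naming the field, never a silent guess or an imputation.
#'
#' @param raw Named list or one-row data frame with labelled values for
#'   `age`, `gen`, `edu`, `time`, `group`, `zone`, `mode`.
#' @return Named integer vector of codes over the seven attribute fields.
#' @examples
#' encode_record(list(age = "18-30", gen = "Female", edu = "College",
#'                    time = "2-5 years", group = "2 ped", zone = "<2 km",
#'                    mode = "walk"))
#' @export
encode_record <- function(raw) {
  cod <- attribute_codings()
  out <- integer(length(prt_fields()))
  names(out) <- prt_fields()
  for (f in prt_fields()) {
    lab <- raw[[f]]
    if (is.null(lab) || length(lab) != 1L || is.na(lab))
      stop("missing label for attribute '", f, "'", call. = FALSE)
    key <- tolower(trimws(as.character(lab)))
    hit <- match(key, tolower(names(cod[[f]])))
    if (is.na(hit))
      stop("unknown category '", lab, "' for attribute '", f, "'",
           call. = FALSE)
    out[[f]] <- unname(cod[[f]][hit])
  }
  out
}

#' Decode numeric attribute codes back to their category labels
#'
#' Inverse of [encode_record()] on every defined category.
#'
#' @param codes Named integer vector or list with the seven attribute fields.
#' @return Named character vector of labels.
#' @export
decode_record <- function(codes) {
  cod <- attribute_codings()
  out <- character(length(prt_fields()))
  names(out) <- prt_fields()
  for (f in prt_fields()) {
    v <- codes[[f]]
    hit <- match(v, unname(cod[[f]]))
    if (is.na(hit))
      stop("code ", v, " is not valid for attribute '", f, "'", call. = FALSE)
    out[[f]] <- names(cod[[f]])[hit]
  }
  out
}

#' Category-probability specification for a synthetic population
#'
#' @param n Population size (>= 1).
#' @param probs Named list of per-attribute probability vectors, each of the
#'   attribute's category count, in code order (for `gen`, over codes 0 then
#'   1). Omitted attributes default to uniform.
#' @return Object of class `attribute_dist`.
#' @export
attribute_dist <- function(n, probs = list()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("population size n must be >= 1", call. = FALSE)
  lv <- attribute_levels()
  unknown <- setdiff(names(probs), names(lv))
  if (length(unknown))
    stop("unknown attribute(s) in probs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  full <- lapply(names(lv), function(f) {
    k <- length(lv[[f]])
    p <- probs[[f]]
    if (is.null(p)) p <- rep(1 / k, k)
    if (length(p) != k)
      stop("probability vector for '", f, "' must have length ", k,
           call. = FALSE)
    if (any(!is.finite(p)) || any(p < 0))
      stop("probability vector for '", f, "' has negative or non-finite mass",
           call. = FALSE)
    s <- sum(p)
    if (abs(s - 1) > 1e-12)
      stop("probability vector for '", f, "' sums to ", format(s),
           ", not 1", call. = FALSE)
    p
  })
  names(full) <- names(lv)
  structure(list(n = as.integer(n), probs = full), class = "attribute_dist")
}

#' Draw a synthetic pedestrian population
#'
#' Attributes are drawn independently per pedestrian from the stated category
#' probabilities; the same seed always reproduces the same table.
#'
#' @param dist An [attribute_dist()] specification.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Data frame with columns `id` and the seven coded attributes.
#' @export
sample_population <- function(dist, seed = NULL) {
  stopifnot(inherits(dist, "attribute_dist"))
  if (!is.null(seed)) set.seed(seed)
  lv <- attribute_levels()
  out <- data.frame(id = seq_len(dist$n))
  for (f in names(lv))
    out[[f]] <- sample(lv[[f]], dist$n, replace = TRUE, prob = dist$probs[[f]])
  out
}

#' Simulate questionnaire responses from the decision model
#'
#' Generates the kind of record table the calibration stage consumes: for
#' each pedestrian, per-period standardized risk context levels are drawn,
#' the per-period escape hazard is evaluated from the supplied coefficient
#' set, and a Bernoulli escape decision is drawn each period until escape or
#' the horizon. Escape is absorbing, so each pedestrian contributes one row
#' per period observed and at most one row with `response = 1` (the final
#' one). Optional control-group respondents answer with probability equal to
#' the coefficient set's natural-response rate alone, independent of the
#' modelled stimulus.
#'
#' @param pop Population data frame from [sample_population()].
#' @param coefs A [coef_set()].
#' @param periods Number of decision periods offered per respondent.
#' @param context One of `"varying"` (levels redrawn each period, the
#'   default), `"fixed"` (one level triple per respondent, held over
#'   periods), or a data frame with columns `rcs`, `dfd`, `rnc` of one row
#'   (shared) or `nrow(pop)` rows.
#' @param n_control Number of extra control-group respondents (single
#'   period, hazard equal to the natural-response rate).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Data frame with columns `id`, `period`, `age` ... `mode`, `rcs`,
#'   `dfd`, `rnc`, `response`, `is_control`.
#' @export
simulate_survey <- function(pop, coefs, periods = 6L, context = "varying",
                            n_control = 0L, seed = NULL) {
  stopifnot(is.data.frame(pop), nrow(pop) >= 1L)
  coefs <- as_coef_set(coefs)
  check_codes(pop)
  if (!is.null(seed)) set.seed(seed)
  periods <- as.integer(periods)
  if (periods < 1L) stop("periods must be >= 1", call. = FALSE)
  n <- nrow(pop)
  scales <- risk_scales()

  draw_ctx <- function(m) {
    data.frame(rcs = sample(scales, m, replace = TRUE),
               dfd = sample(scales, m, replace = TRUE),
               rnc = sample(scales, m, replace = TRUE))
  }
  fixed_ctx <- NULL
  if (is.data.frame(context)) {
    if (!all(c("rcs", "dfd", "rnc") %in% names(context)))
      stop("context data frame needs columns rcs, dfd, rnc", call. = FALSE)
    fixed_ctx <- context[rep_len(seq_len(nrow(context)), n), , drop = FALSE]
  } else if (identical(context, "fixed")) {
    fixed_ctx <- draw_ctx(n)
  } else if (!identical(context, "varying")) {
    stop("context must be 'varying', 'fixed', or a data frame", call. = FALSE)
  }

  rows <- vector("list", periods)
  alive <- rep(TRUE, n)
  for (t in seq_len(periods)) {
    idx <- which(alive)
    if (!length(idx)) break
    ctx <- if (is.null(fixed_ctx)) draw_ctx(length(idx)) else
      fixed_ctx[idx, , drop = FALSE]
    lp <- linear_predictor(pop[idx, , drop = FALSE], ctx, coefs)
    p <- hazard_prob(lp, coefs)
    y <- as.integer(stats::runif(length(idx)) < p)
    rows[[t]] <- data.frame(id = pop$id[idx], period = t,
                            pop[idx, prt_fields(), drop = FALSE],
                            ctx, response = y, is_control = 0L,
                            row.names = NULL)
    alive[idx[y == 1L]] <- FALSE
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  n_control <- as.integer(n_control)
  if (n_control > 0L) {
    y <- as.integer(stats::runif(n_control) < coefs$natural_rate)
    ctrl <- data.frame(id = max(pop$id) + seq_len(n_control), period = 1L,
                       age = NA_integer_, gen = NA_integer_,
                       edu = NA_integer_, time = NA_integer_,
                       group = NA_integer_, zone = NA_integer_,
                       mode = NA_integer_,
                       rcs = NA_real_, dfd = NA_real_, rnc = NA_real_,
                       response = y, is_control = 1L)
    out <- rbind(out, ctrl)
  }
  out <- out[order(out$id, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

survey_columns <- function() {
  c("id", "period", prt_fields(), "rcs", "dfd", "rnc", "response",
    "is_control")
}

#' Read / write survey record tables
#'
#' Delimited text with one row per respondent-period and the fixed header
#' `id, period, age, gen, edu, time, group, zone, mode, rcs, dfd, rnc,
#' response, is_control` (UTF-8). Control rows may carry empty attribute
#' fields.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @return `read_survey` returns the validated data frame; `write_survey`
#'   returns `path` invisibly.
#' @export
read_survey <- function(path, sep = ",") {
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- setdiff(survey_columns(), names(dat))
  if (length(need))
    stop("survey file ", path, " is missing column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  live <- dat$is_control == 0L
  if (any(live)) check_codes(dat[live, , drop = FALSE])
  if (any(dat$response[live] %ni% c(0L, 1L)))
    stop("response must be 0/1", call. = FALSE)
  dat
}

`%ni%` <- function(x, table) !(x %in% table)

#' @rdname read_survey
#' @param dat Survey data frame.
#' @export
write_survey <- function(dat, path, sep = ",") {
  utils::write.table(dat[, survey_columns(), drop = FALSE], path,
                     sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
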