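# Reproducible-run plumbing: structured configs, seed substreams,
# provenance records, and the generate / fit / simulate entry points that
# the command-line wrapper binds to.

#' Derive a named seed substream
#'
#' All randomness in a run flows from one top-level seed; each stage draws
#' its own substream seed by hashing the stage name together with the
#' top-level seed, so stages stay decoupled when one of them changes its
#' number of draws.
#'
#' @param seed Top-level integer seed.
#' @param name Substream name (e.g. "population", "survey", "simulation").
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  # arithmetic in doubles: intermediate values stay below 2^53, result
  # below 2^31
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(name))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

resolve_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else list()
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  cfg
}

provenance <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  list(config = cfg,
       config_md5 = unname(tools::md5sum(tmp)),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("preevac")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

load_coefs_cfg <- function(cfg) {
  if (!is.null(cfg$coeffs_file)) read_coefs(cfg$coeffs_file)
  else if (!is.null(cfg$coeffs)) as_coef_set(cfg$coeffs)
  else default_coefs()
}

#' Generate a synthetic survey from a config
#'
#' Resolves the configuration (file plus overrides), draws a population and
#' its decision panel, and writes the record CSV next to a metadata JSON
#' carrying the resolved config, its hash and the seed. With the same
#' config and seed the output files are byte-identical across runs.
#'
#' Config fields: `n` (respondents), `periods`, `n_control`, `context`
#' (`"varying"`/`"fixed"`), `probs` (per-attribute category probabilities),
#' `coeffs`/`coeffs_file`, `seed`, `out`.
#'
#' @param config Path to a JSON config file, or `NULL`.
#' @param ... Named overrides of config fields (flags win over the file).
#' @return Invisibly, the output CSV path.
#' @export
cli_generate <- function(config = NULL, ...) {
  cfg <- resolve_config(config, list(...))
  cfg$n <- cfg$n %||% 4527L
  cfg$periods <- cfg$periods %||% 6L
  cfg$n_control <- cfg$n_control %||% 0L
  cfg$context <- cfg$context %||% "varying"
  cfg$seed <- cfg$seed %||% 1L
  if (is.null(cfg$out)) stop("config field 'out' is required", call. = FALSE)
  coefs <- load_coefs_cfg(cfg)
  dist <- attribute_dist(cfg$n, cfg$probs %||% list())
  pop <- sample_population(dist, seed = substream_seed(cfg$seed, "population"))
  dat <- simulate_survey(pop, coefs, periods = cfg$periods,
                         context = cfg$context, n_control = cfg$n_control,
                         seed = substream_seed(cfg$seed, "survey"))
  write_survey(dat, cfg$out)
  meta <- provenance(cfg)
  meta$rows <- nrow(dat)
  meta$respondents <- length(unique(dat$id))
  jsonlite::write_json(meta, paste0(cfg$out, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out)
}

#' Fit the decision model from a config
#'
#' Reads a record CSV, fits the model and writes the JSON report (estimates
#' with B / S.E. / Z / Sig. / CI, covariance of the estimates, convergence
#' block, Pearson-type fit statistic, natural-response block) plus a text
#' rendering.
#'
#' Config fields: `input` (CSV), `out` (report JSON path), `covariates`,
#' `screen`, `alpha`, `natural`, `censored`.
#'
#' @inheritParams cli_generate
#' @return Invisibly, the fitted `decision_fit`.
#' @export
cli_fit <- function(config = NULL, ...) {
  cfg <- resolve_config(config, list(...))
  if (is.null(cfg$input) || is.null(cfg$out))
    stop("config fields 'input' and 'out' are required", call. = FALSE)
  dat <- read_survey(cfg$input)
  fit <- fit_decision_model(dat,
                            covariates = cfg$covariates,
                            natural = cfg$natural %||% "control",
                            censored = cfg$censored %||% TRUE,
                            screen = cfg$screen %||% FALSE,
                            alpha = cfg$alpha %||% 0.05)
  write_fit_report(fit, cfg$out,
                   text_path = sub("\\.json$", ".txt", cfg$out))
  meta <- provenance(cfg)
  jsonlite::write_json(meta, paste0(cfg$out, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Run the fire-scene simulation from a config
#'
#' Builds (or loads) the scene, runs the time-stepped simulation and writes
#' the per-agent event CSV and a summary JSON with per-reporting-interval
#' escape counts; bit-reproducible under the seed.
#'
#' Config fields: `n` (agents), `layout` (scene JSON path; default scene
#' when absent), `fire_level`, `dt`, `horizon`, `reporting_interval`,
#' `window` (summary window, seconds), `coeffs`/`coeffs_file`, `seed`,
#' `out` (event CSV path).
#'
#' @inheritParams cli_generate
#' @return Invisibly, the `sim_result`.
#' @export
cli_simulate <- function(config = NULL, ...) {
  cfg <- resolve_config(config, list(...))
  cfg$seed <- cfg$seed %||% 1L
  if (is.null(cfg$n) || cfg$n < 1)
    stop("config field 'n' (positive agent count) is required",
         call. = FALSE)
  if (is.null(cfg$out)) stop("config field 'out' is required", call. = FALSE)
  scene <- if (!is.null(cfg$layout)) read_scene(cfg$layout)
           else default_scene(fire_level = cfg$fire_level %||% 4L)
  sc <- sim_config(n_agents = cfg$n,
                   demand_split = cfg$demand_split %||%
                     c(0.143, 0.286, 0.571),
                   dt = cfg$dt %||% 1,
                   horizon = cfg$horizon %||% 300L,
                   seed = substream_seed(cfg$seed, "simulation"),
                   reporting_interval = cfg$reporting_interval %||% 36,
                   coefs = load_coefs_cfg(cfg),
                   awareness_delay = cfg$awareness_delay %||% FALSE,
                   continuous = cfg$continuous %||% FALSE,
                   invert_rcs = cfg$invert_rcs %||% FALSE)
  res <- run_simulation(scene, sc)
  utils::write.table(res$events, cfg$out, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  summ <- summarize_events(res, window = cfg$window %||% 20)
  out <- list(summary = summ[c("fraction_within", "response_fraction", "n")],
              window = cfg$window %||% 20,
              interval_counts = summ$interval_counts,
              intervals = res$intervals,
              placement = res$placement,
              provenance = provenance(cfg))
  jsonlite::write_json(out, paste0(cfg$out, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
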