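# Time-stepped pre-evacuation simulation: agents wait in their halls and
# each decision period draw an escape decision from the probit hazard.

#' Simulation configuration
#'
#' @param n_agents Number of agents (>= number of origins with positive
#'   demand).
#' @param demand_split Proportions of demand per origin zone, summing to 1.
#'   The default is the three-origin demand distribution 14.3% / 28.6% /
#'   57.1%.
#' @param dt Seconds per decision period (default 1).
#' @param horizon Number of decision periods (default 300).
#' @param seed Integer seed for the whole run.
#' @param reporting_interval Seconds between reported occupancy snapshots
#'   (default 36).
#' @param coefs A [coef_set()] (default [default_coefs()]).
#' @param dist Optional [attribute_dist()] for the agents' attributes;
#'   default uniform categories.
#' @param radius Neighbourhood radius in metres for the crowd-reaction
#'   factor.
#' @param awareness_delay If `TRUE`, agents evaluate their context only
#'   once the smoke front has reached their zone; before that their hazard
#'   is 0.
#' @param natural_mode How the natural-response rate enters the simulated
#'   hazard: `"first_period"` (default) applies the spontaneous-response
#'   floor in the first decision period only, since it represents the
#'   fraction responding immediately upon perceiving the event;
#'   `"every_period"` applies it in every period; `"none"` drops it.
#' @param continuous Use continuous (unquantized) situational factors.
#' @param invert_rcs Invert the fire-level ordering when standardizing the
#'   event strength (see the vignette).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_agents, demand_split = c(0.143, 0.286, 0.571),
                       dt = 1, horizon = 300L, seed = 1L,
                       reporting_interval = 36, coefs = default_coefs(),
                       dist = NULL, radius = 10, awareness_delay = FALSE,
                       continuous = FALSE, invert_rcs = FALSE,
                       natural_mode = c("first_period", "every_period",
                                        "none")) {
  natural_mode <- match.arg(natural_mode)
  if (abs(sum(demand_split) - 1) > 1e-9)
    stop("demand_split must sum to 1", call. = FALSE)
  if (any(demand_split < 0)) stop("demand_split must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  horizon <- as.integer(horizon)
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  if (n_agents < sum(demand_split > 0))
    stop("n_agents is smaller than the number of origins with positive ",
         "demand", call. = FALSE)
  structure(list(n_agents = as.integer(n_agents),
                 demand_split = demand_split, dt = dt, horizon = horizon,
                 seed = as.integer(seed),
                 reporting_interval = reporting_interval,
                 coefs = as_coef_set(coefs), dist = dist, radius = radius,
                 awareness_delay = isTRUE(awareness_delay),
                 continuous = isTRUE(continuous),
                 invert_rcs = isTRUE(invert_rcs),
                 natural_mode = natural_mode),
            class = "sim_config")
}

#' Largest-remainder apportionment
#'
#' Splits `n` units across categories proportionally to `split`, giving
#' each category its integer floor and distributing the remaining units by
#' descending fractional remainder (ties broken by category order).
#'
#' @param n Total count.
#' @param split Nonnegative proportions summing to 1.
#' @return Integer vector of counts summing to `n`.
#' @examples
#' largest_remainder(1000, c(0.143, 0.286, 0.571))
#' @export
largest_remainder <- function(n, split) {
  exact <- n * split
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Place agents in the scene
#'
#' Allocates agents to origin zones by largest-remainder apportionment of
#' the demand split and scatters them uniformly inside their zone
#' rectangles; attributes are drawn from the configured category
#' distributions. Identical seeds give identical placements.
#'
#' @param scene An `evac_scene`.
#' @param config A [sim_config()].
#' @return Object of class `sim_state`: agent table (id, zone, x, y, coded
#'   attributes, status, escape period), clock and period counters.
#' @export
place_agents <- function(scene, config) {
  stopifnot(inherits(scene, "evac_scene"), inherits(config, "sim_config"))
  origins <- scene$zones$id
  if (length(config$demand_split) != length(origins))
    stop("demand_split length must equal the number of origin zones",
         call. = FALSE)
  set.seed(config$seed)
  counts <- largest_remainder(config$n_agents, config$demand_split)
  zone <- rep(origins, counts)
  n <- length(zone)
  idx <- match(zone, scene$zones$id)
  x <- stats::runif(n, scene$zones$xmin[idx], scene$zones$xmax[idx])
  y <- stats::runif(n, scene$zones$ymin[idx], scene$zones$ymax[idx])
  dist <- config$dist %||% attribute_dist(n)
  if (dist$n != n) dist$n <- n
  pop <- sample_population(dist)
  agents <- data.frame(id = seq_len(n), zone = zone, x = x, y = y,
                       pop[prt_fields()], status = "wait",
                       escape_period = NA_integer_,
                       stringsAsFactors = FALSE)
  structure(list(agents = agents, clock = 0, period = 0L,
                 counts = counts), class = "sim_state")
}

# squared distances from each waiting agent to every agent
zone_smoke_reached <- function(scene, zone_ids, radius_now) {
  z <- scene$zones[match(zone_ids, scene$zones$id), , drop = FALSE]
  dx <- pmax(z$xmin - scene$fire$source[1], 0,
             scene$fire$source[1] - z$xmax)
  dy <- pmax(z$ymin - scene$fire$source[2], 0,
             scene$fire$source[2] - z$ymax)
  sqrt(dx^2 + dy^2) <= radius_now
}

#' Advance the simulation by one decision period
#'
#' For every waiting agent the situational context is recomputed (event
#' strength, distance from the fire, fraction of neighbours already
#' reacting), the hazard is evaluated through the coefficient set, and a
#' Bernoulli escape decision is drawn. Escape is absorbing. The clock
#' advances by `dt`.
#'
#' @param state A `sim_state`.
#' @param scene The `evac_scene`.
#' @param config The [sim_config()].
#' @param coefs Optional coefficient override (e.g. to force degenerate
#'   hazards in checks); defaults to `config$coefs`.
#' @return The updated `sim_state`.
#' @export
sim_step <- function(state, scene, config, coefs = NULL) {
  coefs <- as_coef_set(coefs %||% config$coefs)
  ag <- state$agents
  period <- state$period + 1L
  mode <- config$natural_mode %||% "first_period"
  if (mode == "none" || (mode == "first_period" && period > 1L))
    coefs$natural_rate <- 0
  clock <- state$clock + config$dt
  wait <- which(ag$status == "wait")
  if (length(wait)) {
    reacted <- ag$status == "escaped"
    lvl <- scene$fire$level
    if (config$invert_rcs) lvl <- 5L - lvl
    rcs <- standardize_level(lvl)
    dx <- ag$x[wait] - scene$fire$source[1]
    dy <- ag$y[wait] - scene$fire$source[2]
    d <- sqrt(dx^2 + dy^2)
    # fraction of reacting neighbours within the configured radius
    f <- vapply(wait, function(i) {
      dd <- (ag$x - ag$x[i])^2 + (ag$y - ag$y[i])^2
      near <- dd <= config$radius^2 & ag$id != ag$id[i]
      if (any(near)) mean(reacted[near]) else 0
    }, numeric(1))
    if (config$continuous) {
      ctx <- data.frame(rcs = rcs, dfd = pmax(0, 1 - d / 80), rnc = f)
    } else {
      ctx <- data.frame(rcs = rcs,
                        dfd = standardize_level(dfd_level(d)),
                        rnc = standardize_level(rnc_level(f)))
    }
    lp <- linear_predictor(ag[wait, prt_fields(), drop = FALSE], ctx, coefs)
    p <- hazard_prob(lp, coefs)
    if (config$awareness_delay) {
      aware <- zone_smoke_reached(scene, ag$zone[wait],
                                  smoke_radius(state$clock, scene))
      p[!aware] <- 0
    }
    esc <- stats::runif(length(wait)) < p
    ag$status[wait[esc]] <- "escaped"
    ag$escape_period[wait[esc]] <- period
  }
  structure(list(agents = ag, clock = clock, period = period,
                 counts = state$counts), class = "sim_state")
}

#' Run the pre-evacuation simulation
#'
#' Places the agents, then advances the decision clock for the configured
#' horizon, recording each agent's escape period (or censoring). The run is
#' deterministic under the configuration seed.
#'
#' @param scene An `evac_scene`.
#' @param config A [sim_config()].
#' @return List of class `sim_result`: `events` (per-agent table with zone,
#'   position, attributes, escape period and time), `intervals`
#'   (cumulative escaped / waiting counts at each reporting interval),
#'   `config` and `placement` (per-origin counts).
#' @export
run_simulation <- function(scene, config) {
  state <- place_agents(scene, config)
  report_at <- unique(c(seq(0, config$horizon * config$dt,
                            by = config$reporting_interval),
                        config$horizon * config$dt))
  snaps <- list()
  take_snap <- function(state) {
    data.frame(time = state$clock,
               escaped = sum(state$agents$status == "escaped"),
               waiting = sum(state$agents$status == "wait"))
  }
  snaps[[1]] <- take_snap(state)
  for (t in seq_len(config$horizon)) {
    state <- sim_step(state, scene, config)
    if (any(abs(report_at - state$clock) < config$dt / 2) ||
        t == config$horizon)
      snaps[[length(snaps) + 1L]] <- take_snap(state)
  }
  ag <- state$agents
  events <- data.frame(id = ag$id, zone = ag$zone, x = ag$x, y = ag$y,
                       ag[prt_fields()],
                       escape_period = ag$escape_period,
                       escape_time = ag$escape_period * config$dt)
  structure(list(events = events,
                 intervals = unique(do.call(rbind, snaps)),
                 config = config, placement = state$counts),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  n <- nrow(x$events)
  esc <- sum(!is.na(x$events$escape_period))
  cat(sprintf("Pre-evacuation simulation: %d agents, %d periods of %.3g s\n",
              n, x$config$horizon, x$config$dt))
  cat(sprintf("  escaped within horizon: %d (%.1f%%); censored: %d\n",
              esc, 100 * esc / n, n - esc))
  invisible(x)
}

#' Summarize an event table
#'
#' @param events Event table from [run_simulation()] (or the `sim_result`
#'   itself).
#' @param window Observation window in seconds (> 0).
#' @param dt Seconds per period (taken from the result when one is given).
#' @param interval Reporting interval for the per-interval counts.
#' @return List with `fraction_within` (fraction escaped within the
#'   window), `response_fraction` (overall fraction escaped within the
#'   horizon), `n`, and `interval_counts` (escapes per reporting
#'   interval).
#' @export
summarize_events <- function(events, window, dt = 1, interval = 36) {
  if (inherits(events, "sim_result")) {
    dt <- events$config$dt
    interval <- events$config$reporting_interval
    events <- events$events
  }
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (!nrow(events)) stop("empty event table", call. = FALSE)
  times <- events$escape_period * dt
  n <- nrow(events)
  breaks <- seq(0, max(c(times, interval), na.rm = TRUE) + interval,
                by = interval)
  counts <- table(cut(times[!is.na(times)], breaks, right = TRUE))
  list(fraction_within = sum(!is.na(times) & times <= window) / n,
       response_fraction = sum(!is.na(times)) / n,
       n = n,
       interval_counts = data.frame(interval_end = breaks[-1],
                                    escapes = as.integer(counts)))
}
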