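test_that("the default scene matches the documented layout", {
  sc <- default_scene()
  expect_equal(nrow(sc$zones), 3)
  expect_equal(length(sc$exits), 2)
  expect_equal(sc$fire$zone, 3L)
  z3 <- sc$zones[sc$zones$id == 3, ]
  expect_true(sc$fire$source[1] >= z3$xmin && sc$fire$source[1] <= z3$xmax)
  expect_equal(sc$smoke_speed, 0.3)
})

test_that("scene validation rejects degenerate layouts", {
  zones <- data.frame(id = 1:2, xmin = c(0, 10), xmax = c(10, 10),
                      ymin = 0, ymax = 10)
  expect_error(build_scene(zones, exits = 3, edges = rbind(c(1, 3), c(2, 3)),
                           fire = list(source = c(5, 5), zone = 1,
                                       level = 4)),
               "zero or negative area")

  overlap <- data.frame(id = 1:2, xmin = c(0, 5), xmax = c(10, 15),
                        ymin = 0, ymax = 10)
  expect_error(build_scene(overlap, exits = 3,
                           edges = rbind(c(1, 3), c(2, 3)),
                           fire = list(source = c(5, 5), zone = 1,
                                       level = 4)),
               "overlap")

  ok <- data.frame(id = 1:2, xmin = c(0, 10), xmax = c(10, 20),
                   ymin = 0, ymax = 10)
  expect_error(build_scene(ok, exits = 3, edges = rbind(c(1, 3)),
                           fire = list(source = c(5, 5), zone = 1,
                                       level = 4)),
               "not connected")
  expect_error(build_scene(ok, exits = 3, edges = rbind(c(1, 3), c(2, 3)),
                           fire = list(source = c(15, 5), zone = 1,
                                       level = 4)),
               "outside its declared zone")
})

test_that("agents are apportioned by largest remainder and placed reproducibly", {
  expect_identical(largest_remainder(1000, c(0.143, 0.286, 0.571)),
                   c(143L, 286L, 571L))
  expect_identical(largest_remainder(10, c(1, 0, 0)), c(10L, 0L, 0L))
  expect_identical(sum(largest_remainder(97, c(0.21, 0.33, 0.46))), 97L)

  sc <- default_scene()
  cfg <- sim_config(n_agents = 1000, seed = 55)
  st <- place_agents(sc, cfg)
  expect_identical(st$counts, c(143L, 286L, 571L))
  expect_identical(as.integer(table(st$agents$zone)), st$counts)
  # every agent inside its zone rectangle
  z <- sc$zones[match(st$agents$zone, sc$zones$id), ]
  expect_true(all(st$agents$x >= z$xmin & st$agents$x <= z$xmax))
  expect_true(all(st$agents$y >= z$ymin & st$agents$y <= z$ymax))

  st2 <- place_agents(sc, cfg)
  expect_identical(st$agents, st2$agents)

  cfg1 <- sim_config(n_agents = 50, demand_split = c(1, 0, 0), seed = 9)
  expect_true(all(place_agents(sc, cfg1)$agents$zone == 1))
  expect_error(sim_config(n_agents = 1, demand_split = c(0.5, 0.3, 0.2)),
               "smaller than")
})

test_that("the smoke front grows linearly and monotonically", {
  sc <- default_scene()
  expect_equal(smoke_radius(0, sc), 0)
  expect_equal(smoke_radius(120, sc), 36)
  t <- seq(0, 400, by = 7)
  expect_true(all(diff(smoke_radius(t, sc)) >= 0))
  expect_error(smoke_radius(-3, sc), ">= 0")
})

test_that("stepping honours forced degenerate hazards and conservation", {
  sc <- default_scene()
  cfg <- sim_config(n_agents = 120, horizon = 5, seed = 77,
                    natural_mode = "none")
  st <- place_agents(sc, cfg)

  never <- coef_set(const = -Inf, attr = numeric(0),
                    context = c(rcs = 0, dfd = 0, rnc = 0))
  st0 <- sim_step(st, sc, cfg, coefs = never)
  expect_true(all(st0$agents$status == "wait"))
  expect_equal(st0$clock, st$clock + cfg$dt)

  always <- coef_set(const = Inf, attr = numeric(0),
                     context = c(rcs = 0, dfd = 0, rnc = 0))
  st1 <- sim_step(st, sc, cfg, coefs = always)
  expect_true(all(st1$agents$status == "escaped"))
  expect_true(all(st1$agents$escape_period == 1L))

  # escape is absorbing: a further forced-never step changes nothing
  st2 <- sim_step(st1, sc, cfg, coefs = never)
  expect_identical(st2$agents$status, st1$agents$status)

  # conservation at every step
  expect_equal(sum(st1$agents$status == "escaped") +
                 sum(st1$agents$status == "wait"), 120)
})

test_that("hazard decreases with distance from the fire, all else equal", {
  sc <- default_scene()
  # identical agents pinned near and far from the source, dfd weight > 0
  cfg <- sim_config(n_agents = 2, demand_split = c(0.5, 0, 0.5), seed = 1,
                    natural_mode = "none")
  cs <- coef_set(const = -2, attr = numeric(0),
                 context = c(rcs = 0, dfd = 1.5, rnc = 0))
  near <- context_at(sc$fire$source + c(-5, 0), sc)
  far <- context_at(c(5, 30), sc)
  expect_gt(hazard_prob(linear_predictor(homogeneous_pop(1), near, cs), cs),
            hazard_prob(linear_predictor(homogeneous_pop(1), far, cs), cs))
})

test_that("runs are seed-deterministic and the response curve is monotone", {
  sc <- default_scene()
  cfg <- sim_config(n_agents = 300, horizon = 80, seed = 101)
  r1 <- run_simulation(sc, cfg)
  r2 <- run_simulation(sc, cfg)
  expect_identical(r1$events, r2$events)
  expect_true(all(diff(r1$intervals$escaped) >= 0))
  expect_equal(r1$intervals$escaped + r1$intervals$waiting,
               rep(300, nrow(r1$intervals)))

  # zero horizon: everyone censored
  r0 <- run_simulation(sc, sim_config(n_agents = 50, horizon = 0, seed = 5))
  expect_true(all(is.na(r0$events$escape_period)))
})

test_that("fire-zone agents escape stochastically earlier than far-zone agents", {
  sc <- default_scene()
  cfg <- sim_config(n_agents = 600, horizon = 150, seed = 7,
                    natural_mode = "none")
  r <- run_simulation(sc, cfg)
  ev <- r$events
  t3 <- ev$escape_period[ev$zone == 3]
  t1 <- ev$escape_period[ev$zone == 1]
  # censored agents rank last
  t3[is.na(t3)] <- cfg$horizon + 1L
  t1[is.na(t1)] <- cfg$horizon + 1L
  w <- wilcox.test(t3, t1, alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 1e-3)
})

test_that("raising the event strength never slows early escape in expectation", {
  sc_weak <- default_scene(fire_level = 4)   # scale 0.25
  sc_strong <- default_scene(fire_level = 1) # scale 1.00
  frac <- function(sc) {
    r <- run_simulation(sc, sim_config(n_agents = 400, horizon = 30,
                                       seed = 13, natural_mode = "none"))
    summarize_events(r, window = 30)$fraction_within
  }
  expect_gte(frac(sc_strong), frac(sc_weak))
})

test_that("summaries count escapes within the window exactly", {
  ev <- data.frame(id = 1:5, escape_period = c(1, 2, NA, 40, 3))
  s <- summarize_events(ev, window = 20, dt = 1, interval = 36)
  expect_equal(s$fraction_within, 3 / 5)
  expect_equal(s$response_fraction, 4 / 5)
  s2 <- summarize_events(ev, window = 50, dt = 1)
  expect_equal(s2$fraction_within, 4 / 5)
  expect_error(summarize_events(ev[0, ], window = 10), "empty")
  expect_error(summarize_events(ev, window = 0), "> 0")

  all1 <- data.frame(id = 1:4, escape_period = 1)
  expect_equal(summarize_events(all1, window = 1, dt = 1)$fraction_within, 1)
  none <- data.frame(id = 1:4, escape_period = NA_integer_)
  expect_equal(summarize_events(none, window = 10, dt = 1)$fraction_within, 0)
})

test_that("scene layouts round-trip through JSON", {
  sc <- default_scene()
  f <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, f)
  back <- read_scene(f)
  expect_equal(back$zones, sc$zones, ignore_attr = TRUE)
  expect_equal(back$fire, sc$fire)
  expect_equal(back$smoke_speed, sc$smoke_speed)
})
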