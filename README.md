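# preevac

Discrete-time survival modelling of **pre-evacuation decision timing** —
the interval between the first cue of an emergency (alarm, smoke,
shouting) and the moment a person commits to escape. That interval often
dominates the required safe egress time (RSET) in crowded buildings, yet
most evacuation tools treat it as an externally assigned delay. `preevac`
is for safety engineers and researchers who want to *model* it: estimate
what drives the decision from survey panels, and simulate crowds of
heterogeneous agents making it in a fire scene.

## The model

In each decision period $t$, waiting pedestrian $i$ escapes when the
difference between subjective and objective risk utility exceeds a
personal escape-selection threshold. With standard-normal latent noise
this yields a per-period probit hazard, floored by a natural-response
rate $C$ (Abbott's correction):

$$
p_{it} = C + (1 - C)\,\Phi\!\Big(\beta_0 + \textstyle\sum_j \beta_j x_{ij}
 + c_{\mathrm{rcs}}\mathrm{RCS}_{it} + c_{\mathrm{dfd}}\mathrm{DFD}_{it}
 + c_{\mathrm{rnc}}\mathrm{RNC}_{it}\Big)
$$

where the $x_{ij}$ are coded personal attributes (age grade, gender,
education, familiarity, group size, residence-distance zone, travel
mode), and RCS / DFD / RNC are the event strength, the distance from
danger and the neighbourhood-crowd reaction, each standardized to
$\{1.00, 0.75, 0.50, 0.25\}$ on a four-level grading. The first escape
period then follows the first-passage law
$P_i(t) = p_{it}\prod_{n<t}(1-p_{in})$, whose likelihood the package
maximizes (damped Newton, analytic derivatives, observed-information
standard errors). A control group identifies $C$ as a simple proportion
with binomial standard error.

The package covers:

* attribute coding and a synthetic questionnaire generator
  (`encode_record`, `sample_population`, `simulate_survey`);
* the decision core (`linear_predictor`, `hazard_prob`,
  `stage_probabilities`, `first_passage`, `decision_loglik`,
  `fit_decision_model`, `natural_response`);
* risk standardization from scene geometry (`standardize_level`,
  `dfd_level`, `rnc_level`, `context_at`);
* an agent-based fire-scene simulator with a 0.3 m/s smoke front
  (`default_scene`, `build_scene`, `place_agents`, `run_simulation`,
  `summarize_events`);
* config-driven reproducible runs (`cli_generate`, `cli_fit`,
  `cli_simulate`) and a thin command-line wrapper in `inst/cli/preevac`.

## Worked example

Generate a synthetic survey the size of the study that calibrated the
published coefficients (4527 respondents plus a 2973-subject control
group), fit the model, and run the three-hall fire simulation:

```r
library(preevac)

pop <- sample_population(attribute_dist(4527),
                         seed = substream_seed(2026, "population"))
dat <- simulate_survey(pop, default_coefs(), periods = 6, n_control = 2973,
                       seed = substream_seed(2026, "survey"))
fit <- fit_decision_model(dat)
fit
#> Pre-evacuation decision model fit
#>   13795 respondent-period rows, 4527 respondents; logLik -8091.956
#>   converged: yes (5 iterations, |grad| 2.15e-09)
#>             B   S.E.        Z   Sig.   lower   upper
#> const -3.1157 0.2009 -15.5120 0.0000 -3.5094 -2.7221
#> age   -0.0029 0.0177  -0.1656 0.8684 -0.0377  0.0318
#> gen    0.0066 0.0508   0.1306 0.8961 -0.0930  0.1063
#> edu   -0.0010 0.0313  -0.0311 0.9752 -0.0623  0.0604
#> time  -0.0189 0.0228  -0.8293 0.4070 -0.0637  0.0258
#> group -0.0054 0.0227  -0.2380 0.8119 -0.0499  0.0391
#> zone  -0.0076 0.0180  -0.4220 0.6730 -0.0428  0.0276
#> mode   0.0113 0.0128   0.8798 0.3790 -0.0138  0.0363
#> rcs    1.0218 0.1040   9.8249 0.0000  0.8179  1.2256
#> dfd    0.9265 0.1002   9.2505 0.0000  0.7302  1.1228
#> rnc    0.9613 0.1005   9.5695 0.0000  0.7644  1.1582
#>   flagged non-significant: age, gen, edu, time, group, zone, mode
#>   natural response rate: 0.1937 (control group)
```

Reading the output: the situational factors (rcs, dfd, rnc — generated
with true weights 1.0) are recovered near 1 and dominate the decision;
the attribute effects are tiny by construction (the published
coefficients are of order 0.01), so at 4527 respondents they sit inside
their confidence intervals and are flagged non-significant — estimating
them precisely takes far larger samples, which is what the acceptance
study does. The control group gives the natural-response rate, the
fraction who respond spontaneously regardless of the stimulus.

```r
res <- run_simulation(default_scene(),
                      sim_config(n_agents = 1000, seed = 2026))
res
#> Pre-evacuation simulation: 1000 agents, 300 periods of 1 s
#>   escaped within horizon: 1000 (100.0%); censored: 0
summarize_events(res, window = 20)$fraction_within
#> [1] 0.718
```

Agents near the Zone 3 fire see DFD saturate and escape first; the
neighbourhood-reaction factor then feeds back as escapes accumulate.

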