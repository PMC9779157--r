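# Shared fixtures and independent oracles, built in code at test time.

# a labelled raw record covering typical categories
raw_record <- function() {
  list(age = "18-30", gen = "Female", edu = "College", time = "2-5 years",
       group = "2 ped", zone = "<2 km", mode = "walk")
}

# coefficient set with no covariate effects: hazard is Phi(const)
flat_coefs <- function(const = 0, natural_rate = 0) {
  coef_set(const = const, attr = numeric(0),
           context = c(rcs = 0, dfd = 0, rnc = 0),
           natural_rate = natural_rate)
}

# standard normal CDF by numerical integration of the density -- an oracle
# independent of pnorm and of the package
cdf_oracle <- function(x) {
  vapply(x, function(z)
    0.5 + stats::integrate(function(u) exp(-u^2 / 2) / sqrt(2 * pi),
                           0, z, rel.tol = 1e-12)$value,
    numeric(1))
}

# exhaustive outcome-tree enumeration of the first-passage distribution:
# walk all 2^T decision paths, accumulate the probability of each first
# escape period
enumerate_first_passage <- function(hazards) {
  T <- length(hazards)
  prob <- numeric(T)
  censor <- 0
  for (code in 0:(2^T - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(T)]
    pr <- prod(ifelse(bits == 1L, hazards, 1 - hazards))
    first <- match(1L, bits)
    if (is.na(first)) censor <- censor + pr else prob[first] <- prob[first] + pr
  }
  list(prob = prob, censor = censor)
}

# a small homogeneous population: identical attribute codes for everyone
homogeneous_pop <- function(n) {
  data.frame(id = seq_len(n), age = 2L, gen = 1L, edu = 1L, time = 1L,
             group = 1L, zone = 1L, mode = 1L)
}
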