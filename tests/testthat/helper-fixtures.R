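# shared fixtures: a representative truth, the default sampling grid, and
# small generators used across test files

truth_params <- function() churchill_params(1.82, 14, 0.018, 0.002)

default_grid <- function() c(0, 24, seq(84, 624, by = 60))

noise_free_series <- function(params = truth_params(), times = default_grid(),
                              ...) {
  count_series(times, exp(ln_abundance(params, times)), ...)
}

# random valid parameter draws for property-style tests
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    churchill_params(K1 = exp(runif(1, log(0.5), log(5))),
                     K2 = exp(runif(1, log(4), log(30))),
                     lambda1 = exp(runif(1, log(0.005), log(0.1))),
                     lambda2 = exp(runif(1, log(5e-4), log(0.02))))
  })
}

# balanced two-factor response table (no treatment effects unless given)
response_table <- function(seed, reps = 3, sd = 0.002, mu = 0.02,
                           inoculums = c("A", "B", "control"),
                           vitamins = c("replete", "deficient"),
                           shift = NULL) {
  set.seed(seed)
  d <- expand.grid(inoculum = inoculums, vitamin = vitamins,
                   replicate = seq_len(reps), stringsAsFactors = FALSE)
  d$host <- "H1"
  d$growth <- rnorm(nrow(d), mu, sd)
  d$max_abundance <- rnorm(nrow(d), 8, sd)
  d$decline <- rnorm(nrow(d), 0.002, sd / 10)
  d$fit_converged <- TRUE
  if (!is.null(shift)) {
    for (i in seq_len(nrow(shift))) {
      hit <- d$inoculum == shift$inoculum[i] & d$vitamin == shift$vitamin[i]
      d[[shift$response[i]]][hit] <- d[[shift$response[i]]][hit] +
        shift$delta[i]
    }
  }
  d
}
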