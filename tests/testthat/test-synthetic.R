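test_that("default design enumerates the full factorial", {
  spec <- default_design(seed = 1)
  cells <- design_cells(spec)
  expect_equal(nrow(cells), 36L)
  expect_equal(nrow(unique(cells)), 36L)
  expect_equal(length(spec$hosts), 3L)
  expect_equal(length(spec$inoculums), 6L)
  expect_equal(length(spec$vitamins), 2L)
  expect_false(anyDuplicated(c(spec$hosts, spec$inoculums, spec$vitamins)) > 0)
  expect_equal(nrow(cells) * spec$replicates, 108L)  # experimental units
  # default truth: modeled initial density within 1-10 cells/uL
  y0 <- ln_abundance(spec$base_params, 0)
  expect_gte(y0, log(1)); expect_lte(y0, log(10))
  # and a peak in the 200-400 h window
  expect_gte(peak_time(spec$base_params), 200)
  expect_lte(peak_time(spec$base_params), 400)
})

test_that("scenario invariants are enforced", {
  expect_error(default_design(seed = 1, replicates = 0),
               class = "churchill_configuration")
  expect_error(scenario_spec("h", "i", "v", schedule = c(24, 48)),
               class = "churchill_configuration")
  expect_error(noise_model(-0.1), class = "churchill_configuration")
  expect_error(scenario_spec("h", "i", "v",
                             effects = data.frame(host = NA, inoculum = NA,
                                                  vitamin = NA, param = "lambda1",
                                                  multiplier = -1)),
               class = "churchill_configuration")
})

test_that("simulated series honour the noise contract", {
  p <- truth_params()
  tt <- default_grid()
  # zero CV: counts exactly exp(model)
  s0 <- simulate_timeseries(p, tt, noise_model(0, 0), seed = 5)
  expect_equal(s0$counts, exp(ln_abundance(p, tt)))
  # determinism
  s1 <- simulate_timeseries(p, tt, noise_model(0.05, 0), seed = 5)
  s2 <- simulate_timeseries(p, tt, noise_model(0.05, 0), seed = 5)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(
    s1$counts, simulate_timeseries(p, tt, noise_model(0.05, 0), seed = 6)$counts))
  # Monte-Carlo check of the configured CV at a fixed timepoint
  draws <- vapply(1:1000, function(i) {
    simulate_timeseries(p, c(0, 100, 200), noise_model(0.05, 0), seed = i)$counts[2]
  }, 0)
  expect_gt(sd(draws) / mean(draws), 0.04)
  expect_lt(sd(draws) / mean(draws), 0.06)
})

test_that("experiment tables have the exact factorial shape", {
  spec <- default_design(seed = 42)
  tab <- simulate_experiment(spec)
  expect_equal(nrow(tab), 36L * 3L * 12L)
  expect_identical(names(tab), c("host", "inoculum", "vitamin", "replicate",
                                 "time_h", "count_per_uL"))
  expect_true(all(tab$count_per_uL > 0))
  # reproducible from the master seed
  expect_identical(tab, simulate_experiment(spec))
  expect_error(simulate_experiment(default_design()),
               class = "churchill_configuration")
})

test_that("zero jitter and zero noise make replicates identical", {
  spec <- default_design(seed = 8, noise = noise_model(0, 0))
  tab <- simulate_experiment(spec)
  one_cell <- tab[tab$host == spec$hosts[1] & tab$inoculum == "control" &
                    tab$vitamin == "replete", ]
  wide <- split(one_cell$count_per_uL, one_cell$replicate)
  expect_equal(wide[["1"]], wide[["2"]])
  expect_equal(wide[["1"]], wide[["3"]])
  expect_equal(wide[["1"]], exp(ln_abundance(spec$base_params, spec$schedule)))
})

test_that("replicate sub-streams are independent of design edits", {
  spec3 <- default_design(seed = 9, replicates = 3)
  spec2 <- default_design(seed = 9, replicates = 2)
  t3 <- simulate_experiment(spec3)
  t2 <- simulate_experiment(spec2)
  keep <- t3$replicate %in% c("1", "2")
  expect_equal(t3[keep, ], t2, ignore_attr = TRUE)
  expect_equal(t3$count_per_uL[keep], t2$count_per_uL)
  # dropping a host leaves the remaining hosts' draws untouched
  specS <- scenario_spec(hosts = spec3$hosts[-1], inoculums = spec3$inoculums,
                         vitamins = spec3$vitamins, seed = 9)
  tS <- simulate_experiment(specS)
  sub <- t3[t3$host %in% spec3$hosts[-1], ]
  expect_equal(sort(sub$count_per_uL), sort(tS$count_per_uL))
})

test_that("planted multiplicative effects reach the right cell's truth", {
  ef <- data.frame(host = "Chaetoceros sp. KBDT32", inoculum = "Alteromonas 2024",
                   vitamin = "deficient", param = "lambda1", multiplier = 0.6)
  spec <- default_design(seed = 10, effects = ef)
  hit <- cell_params(spec, "Chaetoceros sp. KBDT32", "Alteromonas 2024",
                     "deficient")
  miss <- cell_params(spec, "Chaetoceros sp. KBDT32", "Alteromonas 2024",
                      "replete")
  expect_equal(hit[["lambda1"]], spec$base_params[["lambda1"]] * 0.6)
  expect_equal(unclass(miss), unclass(spec$base_params))
})

test_that("generator and fitter round-trip exactly with zero noise", {
  spec <- default_design(seed = 12, noise = noise_model(0, 0), replicates = 1)
  tab <- simulate_experiment(spec)
  ser <- count_table_series(tab)
  for (s in ser[c(1, 10, 25)]) {
    fit <- churchill_fit(s)
    expect_lt(max(abs(coef(fit) - unclass(spec$base_params)) /
                    unclass(spec$base_params)), 1e-6)
  }
})
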