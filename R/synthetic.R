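#' Observation-noise model for simulated experiments
#'
#' Two multiplicative lognormal noise sources: a per-observation count
#' noise (mean-one lognormal with the given coefficient of variation,
#' emulating flow-cytometric counting error) and a per-replicate jitter
#' applied to the cell's true curve parameters (biological variation
#' between replicate bottles).
#'
#' @param count_cv coefficient of variation of the count noise (default
#'   0.05).
#' @param param_cv coefficient of variation of the replicate-level
#'   parameter jitter (default 0.05).
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(count_cv = 0.05, param_cv = 0.05) {
  if (!is.finite(count_cv) || count_cv < 0 ||
      !is.finite(param_cv) || param_cv < 0) {
    stop_churchill("configuration", "noise CVs must be finite and >= 0")
  }
  structure(list(count_cv = count_cv, param_cv = param_cv),
            class = "noise_model")
}

# sdlog of a mean-one lognormal with coefficient of variation cv
cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

rlnorm_mean1 <- function(n, cv) {
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# stable 31-bit string hash, so each design cell / replicate gets its own
# reproducible RNG sub-stream and adding a cell never perturbs the others
label_seed <- function(master, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Describe a synthetic factorial growth experiment
#'
#' @param hosts,inoculums,vitamins character vectors of design levels.
#' @param replicates replicates per design cell (>= 1).
#' @param schedule sampling times in hours; strictly increasing, starting
#'   at 0.
#' @param base_params the true [churchill_params()] shared by all cells
#'   before planted effects and replicate jitter.
#' @param effects optional planted treatment effects: a data frame with
#'   columns `host`, `inoculum`, `vitamin` (use `NA` for "any"), `param`
#'   (one of `K1`, `K2`, `lambda1`, `lambda2`) and `multiplier` (> 0);
#'   every matching row multiplies that parameter in the cell's truth.
#' @param noise a [noise_model()].
#' @param seed master seed; mandatory before simulation.
#' @return A list of class `"scenario_spec"`.
#' @seealso [default_design()], [simulate_experiment()]
#' @export
scenario_spec <- function(hosts, inoculums, vitamins, replicates = 3L,
                          schedule = c(0, 24, seq(84, 624, by = 60)),
                          base_params = churchill_params(1.82, 14, 0.018, 0.002),
                          effects = NULL, noise = noise_model(), seed = NA) {
  if (replicates < 1L) stop_churchill("configuration", "replicates must be >= 1")
  if (schedule[1] != 0 || any(diff(schedule) <= 0)) {
    stop_churchill("configuration",
                   "schedule must start at 0 and be strictly increasing")
  }
  base_params <- churchill_params(base_params[["K1"]], base_params[["K2"]],
                                  base_params[["lambda1"]],
                                  base_params[["lambda2"]])
  if (!is.null(effects)) {
    need <- c("host", "inoculum", "vitamin", "param", "multiplier")
    if (!all(need %in% names(effects))) {
      stop_churchill("configuration", "effects needs columns: %s",
                     paste(need, collapse = ", "))
    }
    if (any(!effects$param %in% names(base_params))) {
      stop_churchill("configuration", "unknown parameter in effects")
    }
    if (any(!is.finite(effects$multiplier) | effects$multiplier <= 0)) {
      stop_churchill("configuration", "effect multipliers must be > 0")
    }
  }
  structure(list(hosts = as.character(hosts),
                 inoculums = as.character(inoculums),
                 vitamins = as.character(vitamins),
                 replicates = as.integer(replicates),
                 schedule = as.numeric(schedule),
                 base_params = base_params, effects = effects,
                 noise = noise, seed = seed),
            class = "scenario_spec")
}

#' The default factorial design
#'
#' The study layout emulated by the generator: 3 diatom hosts
#' (Chaetoceros sp. KBDT20, Chaetoceros sp. KBDT32, Amphiprora sp.
#' KBDT35) crossed with 6 inoculation states (5 bacterial strains of
#' Alteromonas/Marinobacter plus a no-inoculum control) and 2 vitamin
#' levels — 36 combinations — with 3 replicate bottles each, sampled at
#' 0 h, 24 h and then every 60 h to 624 h (26 days).  Default true
#' parameters give an initial modeled density of 5 cells per microlitre
#' and a peak near 212 h at about 3.8e3 cells per microlitre.
#'
#' @inheritParams scenario_spec
#' @param ... overrides passed on to [scenario_spec()].
#' @return A [scenario_spec()].
#' @examples
#' d <- default_design(seed = 1)
#' nrow(design_cells(d))  # 36
#' @export
default_design <- function(seed = NA, ...) {
  scenario_spec(hosts = c("Chaetoceros sp. KBDT20", "Chaetoceros sp. KBDT32",
                          "Amphiprora sp. KBDT35"),
                inoculums = c("Alteromonas 2016", "Alteromonas 2024",
                              "Alteromonas scs5", "Marinobacter scs77",
                              "Marinobacter scs85", "control"),
                vitamins = c("replete", "deficient"),
                seed = seed, ...)
}

#' Enumerate the design cells of a scenario
#'
#' @param spec a [scenario_spec()].
#' @return A data frame with one row per host x inoculum x vitamin
#'   combination.
#' @export
design_cells <- function(spec) {
  expand.grid(host = spec$hosts, inoculum = spec$inoculums,
              vitamin = spec$vitamins, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic experiment: %d hosts x %d inoculation states",
                     " x %d vitamin levels x %d replicates\n"),
              length(x$hosts), length(x$inoculums), length(x$vitamins),
              x$replicates))
  cat(sprintf("  %d sampling times over %g-%g h; count CV %g, param CV %g\n",
              length(x$schedule), min(x$schedule), max(x$schedule),
              x$noise$count_cv, x$noise$param_cv))
  cat(sprintf("  planted effects: %d; master seed: %s\n",
              if (is.null(x$effects)) 0L else nrow(x$effects),
              if (is.na(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

# true parameters of one design cell after planted multiplicative effects
cell_params <- function(spec, host, inoculum, vitamin) {
  p <- unclass(spec$base_params)
  ef <- spec$effects
  if (!is.null(ef) && nrow(ef)) {
    hit <- (is.na(ef$host) | ef$host == host) &
      (is.na(ef$inoculum) | ef$inoculum == inoculum) &
      (is.na(ef$vitamin) | ef$vitamin == vitamin)
    for (i in which(hit)) p[[ef$param[i]]] <- p[[ef$param[i]]] * ef$multiplier[i]
  }
  churchill_params(p[["K1"]], p[["K2"]], p[["lambda1"]], p[["lambda2"]])
}

#' Simulate one replicate's count series
#'
#' Counts are the Churchill-Usagi curve exponentiated back to the count
#' scale, times mean-one multiplicative lognormal noise:
#' `count_i = exp(ln_abundance(params, t_i)) * eps_i`.  Deterministic
#' given `seed`; the global RNG state is left untouched.
#'
#' @param params true [churchill_params()].
#' @param schedule sampling times (hours).
#' @param noise a [noise_model()]; only `count_cv` is used here.
#' @param seed integer seed for this series.
#' @param ... metadata passed to [count_series()].
#' @return A [count_series()].
#' @export
simulate_timeseries <- function(params, schedule, noise = noise_model(),
                                seed, ...) {
  if (!inherits(noise, "noise_model")) {
    stop_churchill("configuration", "noise must be a noise_model()")
  }
  y <- ln_abundance(params, schedule)
  eps <- with_local_seed(seed, rlnorm_mean1(length(schedule), noise$count_cv))
  count_series(schedule, exp(y) * eps, ...)
}

#' Simulate a full factorial experiment
#'
#' One row per (design cell, replicate, timepoint).  Each replicate's
#' true parameters are the cell's parameters jittered by a mean-one
#' lognormal factor (`param_cv`), drawn in a replicate-specific RNG
#' sub-stream derived by stable hashing of the labels — so results are
#' reproducible from the master seed, and adding or renaming one cell or
#' replicate never changes another's values.
#'
#' @param spec a [scenario_spec()] with a non-`NA` master seed.
#' @return A tidy data frame with columns `host`, `inoculum`, `vitamin`,
#'   `replicate`, `time_h`, `count_per_uL`; convert to series with
#'   [count_table_series()].
#' @examples
#' spec <- default_design(seed = 42)
#' tab <- simulate_experiment(spec)
#' nrow(tab)  # 36 cells x 3 replicates x 12 timepoints = 1296
#' @export
simulate_experiment <- function(spec) {
  if (!inherits(spec, "scenario_spec")) {
    stop_churchill("configuration", "spec must be a scenario_spec()")
  }
  if (is.na(spec$seed)) {
    stop_churchill("configuration", "a master seed is required to simulate")
  }
  cells <- design_cells(spec)
  out <- vector("list", nrow(cells) * spec$replicates)
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    p_cell <- cell_params(spec, cells$host[i], cells$inoculum[i],
                          cells$vitamin[i])
    for (r in seq_len(spec$replicates)) {
      lab <- paste(cells$host[i], cells$inoculum[i], cells$vitamin[i], r,
                   sep = "|")
      rep_seed <- label_seed(spec$seed, lab)
      s <- with_local_seed(rep_seed, {
        jit <- rlnorm_mean1(4L, spec$noise$param_cv)
        p_rep <- churchill_params(p_cell[["K1"]] * jit[1],
                                  p_cell[["K2"]] * jit[2],
                                  p_cell[["lambda1"]] * jit[3],
                                  p_cell[["lambda2"]] * jit[4])
        eps <- rlnorm_mean1(length(spec$schedule), spec$noise$count_cv)
        exp(ln_abundance(p_rep, spec$schedule)) * eps
      })
      k <- k + 1L
      out[[k]] <- data.frame(host = cells$host[i],
                             inoculum = cells$inoculum[i],
                             vitamin = cells$vitamin[i],
                             replicate = as.character(r),
                             time_h = spec$schedule, count_per_uL = s,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Split a tidy count table into replicate series
#'
#' @param table a data frame with the count-table schema (`host`,
#'   `inoculum`, `vitamin`, `replicate`, `time_h`, `count_per_uL`).
#' @return A list of [count_series()], one per unique
#'   (host, inoculum, vitamin, replicate), timepoints sorted ascending.
#' @export
count_table_series <- function(table) {
  validate_count_table(table)
  key <- interaction(table$host, table$inoculum, table$vitamin,
                     table$replicate, drop = TRUE, lex.order = TRUE)
  lapply(split(table, key), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    count_series(d$time_h, d$count_per_uL, host = d$host[1],
                 inoculum = d$inoculum[1], vitamin = d$vitamin[1],
                 replicate = d$replicate[1])
  })
}
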