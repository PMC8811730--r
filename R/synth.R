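# Synthetic fermentation generator. An archetype is a planted phenotype: a
# growth rate plus a full vector of biomass-specific rates. Experiments are
# simulated by integrating dc1/dt = mu * c1, dcD/dt = rD * c1 with
# piecewise-constant (optionally cross-faded) archetype rates, then sampling
# and applying multiplicative lognormal measurement noise. Ground-truth rate
# vectors are emitted alongside so every downstream stage can be scored.

#' Construct a phenotype archetype
#'
#' @param name Archetype name.
#' @param mu Specific growth rate (1/h).
#' @param rates Named vector of biomass-specific rates (mmol/g/h) by
#'   registry abbreviation; consumption negative. Unnamed compounds are 0.
#' @param registry Compound registry.
#' @return An `archetype` object with a complete rate vector over all
#'   non-biomass registry dimensions.
#' @export
archetype <- function(name, mu, rates, registry = default_registry()) {
  abbrevs <- registry$abbreviation[registry$role != "biomass"]
  full <- stats::setNames(rep(0, length(abbrevs)), abbrevs)
  unknown <- setdiff(names(rates), abbrevs)
  if (length(unknown)) stop("unknown compound(s) in archetype: ",
                            paste(unknown, collapse = ", "))
  full[names(rates)] <- rates
  structure(list(name = name, mu = mu, rates = full), class = "archetype")
}

# (mu, r_*) named vector view of an archetype, matching rate_matrix columns
archetype_vector <- function(a) {
  c(mu = a$mu, stats::setNames(a$rates, paste0("r_", names(a$rates))))
}

#' Matrix of archetype phenotype vectors
#'
#' @param archetypes List of [archetype()] objects.
#' @return Matrix with one row per archetype, columns `mu`, `r_<abbrev>`.
#' @export
archetype_matrix <- function(archetypes) {
  out <- t(vapply(archetypes, archetype_vector,
                  archetype_vector(archetypes[[1]])))
  rownames(out) <- vapply(archetypes, function(a) a$name, character(1))
  out
}

# Scale a relative product slate so the archetype lands exactly on the ATP
# line q_ATP = (1000 / Y) * mu + q_m, then solve the substrate uptake from
# exact carbon closure (products + CO2 + biomass carbon). `glc_frac` routes
# that carbon fraction through glucose instead of glycerol.
closed_archetype <- function(name, mu, slate, Y = 10, q_m = 2.5,
                             glc_frac = 0, registry = default_registry()) {
  stopifnot(all(names(slate) %in% registry$abbreviation))
  s_atp <- stats::setNames(registry$atp_stoich, registry$abbreviation)
  atp_unit <- sum(ifelse(is.na(s_atp[names(slate)]), 0,
                         s_atp[names(slate)]) * slate)
  if (atp_unit <= 0) stop("slate yields no ATP; cannot place it on the line")
  q_target <- (1000 / Y) * mu + q_m
  prod <- slate * q_target / atp_unit
  nC <- stats::setNames(registry$n_carbons, registry$abbreviation)
  bm <- registry[registry$role == "biomass", ]
  get0 <- function(a) if (a %in% names(prod)) prod[[a]] else 0
  co2 <- get0("EtOH") + get0("AcAc") + 2 * get0("BuOH") + 2 * get0("BuAc") -
    get0("FoAc")
  c_total <- bm$n_carbons * mu * 1000 / bm$molar_mass +
    sum(nC[names(prod)] * prod) + co2
  rates <- prod
  rates["Gly"] <- -(1 - glc_frac) * c_total / nC[["Gly"]]
  if (glc_frac > 0) rates["Glc"] <- -glc_frac * c_total / nC[["Glc"]]
  archetype(name, mu, rates, registry)
}

#' Default library of planted phenotype archetypes
#'
#' Five carbon-closed clostridium-like archetypes spanning solventogenic,
#' acidogenic, 1,3-propanediol-producing, ethanol-producing and
#' near-dormant behavior. Product slates are scaled so that every archetype
#' lies exactly on the ATP line `q_ATP = (1000 / Y) * mu + q_m`, and the
#' substrate uptake (glycerol, plus glucose for the co-fermenting
#' archetype) is solved from exact carbon closure, so the full pipeline
#' should return ~100 % carbon recovery and recover `(Y, q_m)` from the
#' cluster centroids.
#'
#' @param Y Planted ATP-specific biomass yield (g/mol).
#' @param q_m Planted maintenance coefficient (mmol/g/h).
#' @param registry Compound registry.
#' @return List of five [archetype()] objects.
#' @export
default_archetypes <- function(Y = 10, q_m = 2.5,
                               registry = default_registry()) {
  list(
    closed_archetype("butanol_solventogenic", mu = 0.10,
                     c(BuOH = 1, BuAc = 0.15, AcAc = 0.1, PDO = 0.3,
                       EtOH = 0.1), Y, q_m, registry = registry),
    closed_archetype("acidogenic", mu = 0.20,
                     c(AcAc = 1, BuAc = 0.8, FoAc = 0.3, PDO = 0.4),
                     Y, q_m, registry = registry),
    closed_archetype("pdo_coferm", mu = 0.12,
                     c(PDO = 1, AcAc = 0.5, BuAc = 0.2),
                     Y, q_m, glc_frac = 0.4, registry = registry),
    closed_archetype("ethanologenic", mu = 0.15,
                     c(EtOH = 1, PDO = 0.5, AcAc = 0.3, LaAc = 0.2),
                     Y, q_m, registry = registry),
    closed_archetype("dormant", mu = 0.02,
                     c(AcAc = 0.3, BuAc = 0.2, PDO = 0.1, LaAc = 0.1,
                       OBuAc = 0.1), Y, q_m, registry = registry)
  )
}

#' Simulation configuration for one synthetic experiment
#'
#' @param experiment_id Identifier.
#' @param schedule Data frame with columns `start`, `end` (h) and
#'   `archetype` (index into `archetypes`); intervals must be contiguous
#'   and non-overlapping.
#' @param archetypes List of [archetype()] objects.
#' @param init Named initial concentrations (`BM` g/L, others mmol/L).
#' @param sample_times Strictly increasing sampling times within the
#'   schedule span.
#' @param noise_sigma Lognormal sigma of the multiplicative measurement
#'   noise (scalar, or named per compound).
#' @param tags Named character vector of condition tags.
#' @param cumulative Compounds to report as cumulative consumed amount
#'   (fed-batch convention) instead of concentration.
#' @param blend_h Cross-fade duration at archetype switches (h; 0 = sharp).
#' @export
simulation_config <- function(experiment_id, schedule, archetypes, init,
                              sample_times, noise_sigma = 0.02,
                              tags = character(0), cumulative = character(0),
                              blend_h = 0) {
  stopifnot(is.data.frame(schedule),
            all(c("start", "end", "archetype") %in% names(schedule)),
            all(noise_sigma >= 0), blend_h >= 0, init[["BM"]] > 0)
  schedule <- schedule[order(schedule$start), , drop = FALSE]
  if (any(schedule$end <= schedule$start) ||
      (nrow(schedule) > 1 &&
       any(abs(schedule$start[-1] - schedule$end[-nrow(schedule)]) > 1e-9))) {
    stop("schedule intervals must be contiguous and non-overlapping")
  }
  if (is.unsorted(sample_times, strictly = TRUE)) {
    stop("sample_times must be strictly increasing")
  }
  structure(list(experiment_id = experiment_id, schedule = schedule,
                 archetypes = archetypes, init = init,
                 sample_times = sample_times, noise_sigma = noise_sigma,
                 tags = tags, cumulative = cumulative, blend_h = blend_h),
            class = "simulation_config")
}

# active (mu, rates) at time t, cross-faded over blend_h around switches
scheduled_rates <- function(config, t) {
  sch <- config$schedule
  i <- findInterval(t, sch$start, rightmost.closed = TRUE)
  i <- max(1, min(i, nrow(sch)))
  a <- config$archetypes[[sch$archetype[i]]]
  mu <- a$mu; r <- a$rates
  if (config$blend_h > 0 && i > 1) {
    dt <- t - sch$start[i]
    if (dt < config$blend_h) {
      prev <- config$archetypes[[sch$archetype[i - 1]]]
      w <- dt / config$blend_h
      mu <- w * mu + (1 - w) * prev$mu
      r <- w * r + (1 - w) * prev$rates
    }
  }
  list(mu = mu, rates = r, archetype = sch$archetype[i])
}

#' Simulate one cultivation experiment
#'
#' Integrates `dc1/dt = mu * c1`, `dcD/dt = rD * c1` with fourth-order
#' Runge-Kutta (step <= 0.01 h) under the scheduled archetype rates,
#' samples at the configured times and applies seeded multiplicative
#' lognormal noise. If any concentration would go negative (substrate
#' exhaustion) all rates are set to zero from that moment on (logged).
#'
#' @param config A [simulation_config()].
#' @param registry Compound registry.
#' @param seed Integer seed for the measurement noise.
#' @return List with `experiment` (a [cultivation_experiment()]) and
#'   `truth` (data frame of the planted `mu`, `r_<abbrev>` and archetype
#'   index at every sampling time).
#' @export
simulate_experiment <- function(config, registry = default_registry(),
                                seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  abbrevs <- registry$abbreviation[registry$role != "biomass"]
  state <- stats::setNames(rep(0, 1 + length(abbrevs)), c("BM", abbrevs))
  state[names(config$init)] <- config$init
  t0 <- config$schedule$start[1]
  t_end <- config$schedule$end[nrow(config$schedule)]
  stopifnot(min(config$sample_times) >= t0,
            max(config$sample_times) <= t_end)
  dt <- 0.01
  times <- seq(t0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  exhausted <- FALSE

  deriv <- function(t, s) {
    act <- scheduled_rates(config, t)
    c(act$mu * s[["BM"]], act$rates * s[["BM"]])
  }
  snap_t <- config$sample_times
  snapshots <- matrix(NA_real_, length(snap_t), length(state),
                      dimnames = list(NULL, names(state)))
  truth <- matrix(NA_real_, length(snap_t), 1 + length(abbrevs),
                  dimnames = list(NULL, c("mu", paste0("r_", abbrevs))))
  truth_arch <- integer(length(snap_t))

  record <- function(ti, s, i) {
    snapshots[i, ] <<- s
    if (exhausted) {
      truth[i, ] <<- 0
      truth_arch[i] <<- NA_integer_
    } else {
      act <- scheduled_rates(config, ti)
      truth[i, ] <<- c(act$mu, act$rates)
      truth_arch[i] <<- act$archetype
    }
  }
  next_snap <- 1L
  while (next_snap <= length(snap_t) && snap_t[next_snap] <= times[1] + 1e-12) {
    record(snap_t[next_snap], state, next_snap)
    next_snap <- next_snap + 1L
  }
  for (i in seq_len(length(times) - 1)) {
    t <- times[i]; h <- times[i + 1] - times[i]
    if (!exhausted) {
      k1 <- deriv(t, state)
      k2 <- deriv(t + h / 2, state + h / 2 * k1)
      k3 <- deriv(t + h / 2, state + h / 2 * k2)
      k4 <- deriv(t + h, state + h * k3)
      new_state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(new_state < 0)) {
        exhausted <- TRUE
        message("experiment ", config$experiment_id, ": substrate exhausted at t ~ ",
                format(round(t, 2)), " h; rates set to 0")
        new_state <- pmax(new_state, 0)
      }
      state <- new_state
    }
    while (next_snap <= length(snap_t) && snap_t[next_snap] <= times[i + 1] + 1e-12) {
      record(snap_t[next_snap], state, next_snap)
      next_snap <- next_snap + 1L
    }
  }

  # measurement: cumulative columns report initial - current (consumed)
  measured <- snapshots
  for (a in intersect(config$cumulative, abbrevs)) {
    init_a <- if (a %in% names(config$init)) config$init[[a]] else 0
    measured[, a] <- pmax(init_a - snapshots[, a], 0)
  }
  sigma <- config$noise_sigma
  if (length(sigma) == 1) {
    sigma <- stats::setNames(rep(sigma, ncol(measured)), colnames(measured))
  }
  noisy <- withr_seed(seed, {
    out <- measured
    for (cc in colnames(measured)) {
      s <- if (cc %in% names(sigma)) sigma[[cc]] else 0
      if (s > 0) out[, cc] <- out[, cc] * exp(stats::rnorm(nrow(out), 0, s))
    }
    out
  })
  for (a in intersect(config$cumulative, abbrevs)) {
    noisy[, a] <- cummax(noisy[, a])  # keep the consumed amount monotone
  }
  samples <- data.frame(time_h = snap_t, noisy, check.names = FALSE)
  exp_obj <- cultivation_experiment(config$experiment_id, samples,
                                    tags = config$tags,
                                    cumulative = config$cumulative)
  truth_df <- data.frame(experiment_id = config$experiment_id,
                         time_h = snap_t, archetype = truth_arch, truth,
                         check.names = FALSE, stringsAsFactors = FALSE)
  list(experiment = exp_obj, truth = truth_df)
}

#' Generate a multi-experiment synthetic dataset with planted phenotypes
#'
#' Draws experiments with varied durations, sampling densities (4-15
#' samples), initial concentrations and archetype schedules (a fraction of
#' experiments switches archetype mid-run), attaches condition tags
#' correlated with the planted archetypes (the first archetype is planted
#' only under `BES = yes`, so conditionality screening has a known
#' positive), and emits ground-truth labels and rates per sampling point.
#' A small fraction of glycerol columns is reported as cumulative consumed
#' amount, emulating fed-batch logging.
#'
#' @param n_experiments Number of experiments.
#' @param archetypes Archetype library (>= 2).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param noise_sigma Multiplicative lognormal measurement noise sigma.
#' @param p_switch Probability that an experiment switches archetype.
#' @param p_cumulative Probability that glycerol is logged cumulatively.
#' @param registry Compound registry.
#' @return List with `experiments` (list of [cultivation_experiment()]),
#'   `truth` (per sampling point) and `archetypes`.
#' @export
generate_dataset <- function(n_experiments, archetypes = default_archetypes(),
                             seed = 7, noise_sigma = 0.02, p_switch = 0.3,
                             p_cumulative = 0.1,
                             registry = default_registry()) {
  stopifnot(length(archetypes) >= 2 || n_experiments == 0)
  if (n_experiments == 0) {
    return(list(experiments = list(), truth = NULL, archetypes = archetypes))
  }
  n_arch <- length(archetypes)
  withr_seed(seed, {
    configs <- lapply(seq_len(n_experiments), function(i) {
      dur <- stats::runif(1, 10, 24)
      n_samp <- sample(4:15, 1)
      st <- seq(0, dur, length.out = n_samp)
      if (n_samp > 2) {
        jit <- stats::runif(n_samp - 2, -0.2, 0.2) * dur / n_samp
        st[2:(n_samp - 1)] <- sort(st[2:(n_samp - 1)] + jit)
      }
      switches <- stats::runif(1) < p_switch
      if (switches) {
        arch_pair <- sample(n_arch, 2)
        t_sw <- stats::runif(1, 0.4, 0.6) * dur
        sch <- data.frame(start = c(0, t_sw), end = c(t_sw, dur),
                          archetype = arch_pair)
      } else {
        sch <- data.frame(start = 0, end = dur, archetype = sample(n_arch, 1))
      }
      uses_first <- 1 %in% sch$archetype
      bes <- if (uses_first) "yes" else {
        if (stats::runif(1) < 0.15) "yes" else "no"
      }
      # the first archetype is planted only under BES
      if (bes == "no" && uses_first) bes <- "yes"
      tags <- c(vessel = sample(c("serum_bottle", "bioreactor"), 1),
                BES = bes,
                FeSO4_mgL = as.character(sample(c(10, 100), 1)))
      # Biebl-type medium: glycerol sized to be substantially depleted over
      # the batch; glucose only for schedules containing the co-fermenting
      # archetype (media are designed per experiment)
      glc_used <- any(vapply(sch$archetype, function(ai)
        archetypes[[ai]]$rates[["Glc"]] < 0, logical(1)))
      init <- c(BM = stats::runif(1, 0.1, 0.4),
                Gly = stats::runif(1, 300, 600),
                Glc = if (glc_used) stats::runif(1, 100, 250) else 0)
      cumulative <- if (stats::runif(1) < p_cumulative) "Gly" else character(0)
      simulation_config(
        experiment_id = sprintf("synth%03d", i), schedule = sch,
        archetypes = archetypes, init = init, sample_times = st,
        noise_sigma = noise_sigma, tags = tags, cumulative = cumulative)
    })
    seeds <- sample.int(.Machine$integer.max, n_experiments)
    sims <- suppressMessages(
      lapply(seq_along(configs), function(i)
        simulate_experiment(configs[[i]], registry, seed = seeds[i])))
    list(experiments = lapply(sims, `[[`, "experiment"),
         truth = do.call(rbind, lapply(sims, `[[`, "truth")),
         archetypes = archetypes)
  })
}
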