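# Synthetic crossing experiments with the statistical structure the
# analysis assumes: F2 cohorts from selfed interspecies F1s (with
# seed-stage viability selection), per-plant backcross seed counts with
# binomial abortion at genotype-determined rates, seed-scoring noise, F1
# selfing series, and RIL panels built by single-seed descent.

#' Configuration of a synthetic crossing experiment
#'
#' All simulators draw from R's generator seeded once with `seed`;
#' identical configurations reproduce identical data sets. Set
#' `seed = NULL` inside a pipeline that has already seeded the stream
#' (as [simulate_f2_experiment()] does internally).
#'
#' @param model a [bdm_model()] (default: 1 maternal x 3 paternal loci).
#' @param n_plants number of plants in a simulated panel.
#' @param seeds_per_plant mean of the truncated-Poisson seeds-per-plant
#'   distribution, or the exact count when `fixed_seeds = TRUE`. The
#'   default of 25 seeds is a plausible per-plant scoring effort for a
#'   crucifer silique-based assay.
#' @param fixed_seeds score exactly `seeds_per_plant` seeds per plant
#'   instead of drawing a truncated Poisson count.
#' @param epsilon seed mis-scoring probability (each seed's
#'   aborted/normal call flips independently with this probability), in
#'   `[0, 0.5)`.
#' @param seed integer random seed, or `NULL` to continue the current
#'   stream.
#' @param conditioned sample F2 genotypes from the survivor-conditioned
#'   distribution (default `TRUE`; the plants of a real panel are
#'   necessarily survivors).
#' @param overdispersion intra-plant correlation of seed fates in
#'   `[0, 1)`; 0 (the default) gives pure binomial counts, positive
#'   values a beta-binomial with that correlation.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(model = bdm_model(1, 3), n_plants = 250,
                       seeds_per_plant = 25, fixed_seeds = FALSE,
                       epsilon = 0.01, seed = NULL, conditioned = TRUE,
                       overdispersion = 0) {
  if (!inherits(model, "bdm_model")) .cfg_err("model must be a bdm_model")
  if (!is.numeric(n_plants) || length(n_plants) != 1L || n_plants < 1 ||
      n_plants != trunc(n_plants))
    .cfg_err("n_plants must be a single integer >= 1")
  if (!is.numeric(seeds_per_plant) || length(seeds_per_plant) != 1L ||
      seeds_per_plant < 1)
    .cfg_err("seeds_per_plant must be >= 1")
  if (isTRUE(fixed_seeds) && seeds_per_plant != trunc(seeds_per_plant))
    .cfg_err("fixed seeds_per_plant must be an integer")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 ||
      epsilon >= 0.5)
    .cfg_err("epsilon must lie in [0, 0.5)")
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L ||
                         seed != trunc(seed)))
    .cfg_err("seed must be a single integer or NULL")
  if (!is.numeric(overdispersion) || length(overdispersion) != 1L ||
      overdispersion < 0 || overdispersion >= 1)
    .cfg_err("overdispersion must lie in [0, 1)")
  structure(list(model = model, n_plants = as.integer(n_plants),
                 seeds_per_plant = seeds_per_plant,
                 fixed_seeds = isTRUE(fixed_seeds), epsilon = epsilon,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 conditioned = isTRUE(conditioned),
                 overdispersion = overdispersion),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  for (ln in format(x)) cat(ln, "\n")
  invisible(x)
}

#' @export
format.sim_config <- function(x, ...) {
  c(sprintf("model: %d maternal x %d paternal loci", x$model$n_maternal,
            x$model$n_paternal),
    sprintf("n_plants: %d", x$n_plants),
    sprintf("seeds_per_plant: %s%g", if (x$fixed_seeds) "fixed "
            else "truncated Poisson, mean ", x$seeds_per_plant),
    sprintf("epsilon: %g", x$epsilon),
    sprintf("seed: %s", if (is.null(x$seed)) "none (current stream)"
            else as.character(x$seed)),
    sprintf("conditioned: %s", x$conditioned),
    sprintf("overdispersion: %g", x$overdispersion))
}

.check_config <- function(config) {
  if (!inherits(config, "sim_config"))
    .cfg_err("config must be a sim_config object")
  invisible(config)
}

.maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  invisible(NULL)
}

.strip_seed <- function(config) {
  config$seed <- NULL
  config
}

# truncated-at-1 Poisson (or fixed) seeds-per-plant counts
.draw_seed_counts <- function(n, config) {
  if (config$fixed_seeds) return(rep.int(as.integer(config$seeds_per_plant), n))
  k <- stats::rpois(n, config$seeds_per_plant)
  while (any(k == 0L)) k[k == 0L] <- stats::rpois(sum(k == 0L),
                                                  config$seeds_per_plant)
  k
}

# observed abortion probability after pushing rate q through the
# mis-scoring channel
.noisy_rate <- function(q, epsilon) q * (1 - epsilon) + (1 - q) * epsilon

#' Simulate an F2 cohort
#'
#' Draws `n_plants` ordered genotypes from the exact genotype distribution
#' of the selfed interspecies F1 — survivor-conditioned by default, since
#' real F2 plants grew from seeds that escaped the lethal class. Sampling
#' is a single categorical draw from the exact rational distribution; no
#' rejection loop is involved.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `plant_id` and `genotype` (genotype
#'   strings, see [parse_genotype()]).
#' @examples
#' cohort <- simulate_f2_cohort(sim_config(n_plants = 5, seed = 1))
#' @export
simulate_f2_cohort <- function(config) {
  .check_config(config)
  .maybe_seed(config)
  dist <- .self_offspring_dist(f1_genotype(config$model), config$model,
                               conditioned = config$conditioned)
  idx <- sample.int(length(dist$genotype), config$n_plants, replace = TRUE,
                    prob = as.numeric(dist$freq))
  data.frame(plant_id = sprintf("F2_%04d", seq_len(config$n_plants)),
             genotype = dist$genotype[idx], stringsAsFactors = FALSE)
}

# predicted donor abortion rates for a vector of genotype strings,
# computed once per distinct genotype
.donor_rates <- function(genotypes, model, tester = selfer_genotype(model)) {
  uniq <- unique(genotypes)
  q <- vapply(uniq, function(s)
    as.numeric(pollen_lethal_fraction(parse_genotype(s, model), tester,
                                      model)),
    numeric(1))
  unname(q[match(genotypes, uniq)])
}

#' Simulate a backcross panel
#'
#' For each plant of a cohort, draws the number of seeds scored from the
#' seeds-per-plant distribution and the number aborted from a binomial
#' (or beta-binomial, if `overdispersion > 0`) at the plant's predicted
#' abortion rate pushed through the mis-scoring channel
#' `q' = q(1-epsilon) + (1-q)epsilon`. The predicted rate is
#' [pollen_lethal_fraction()] of the plant's genotype on the tester.
#'
#' @param cohort a `data.frame` with a `genotype` column of genotype
#'   strings (as returned by [simulate_f2_cohort()] or
#'   [simulate_ril_panel()]).
#' @param config a [sim_config()].
#' @param tester seed-parent tester [genotype()]; defaults to the pure
#'   selfer.
#' @return A [plant_records()] table with one row per cohort plant.
#' @export
simulate_backcross_panel <- function(cohort, config,
                                     tester = selfer_genotype(config$model)) {
  .check_config(config)
  if (!is.data.frame(cohort) || !"genotype" %in% names(cohort))
    .data_err("cohort must be a data.frame with a genotype column")
  .maybe_seed(config)
  q <- .donor_rates(cohort$genotype, config$model, tester)
  q_eff <- .noisy_rate(q, config$epsilon)
  n <- nrow(cohort)
  n_seeds <- .draw_seed_counts(n, config)
  p <- q_eff
  if (config$overdispersion > 0) {
    rho <- config$overdispersion
    s <- (1 - rho) / rho
    inner <- q_eff > 0 & q_eff < 1
    p[inner] <- stats::rbeta(sum(inner), q_eff[inner] * s,
                             (1 - q_eff[inner]) * s)
  }
  n_aborted <- stats::rbinom(n, n_seeds, p)
  ids <- if ("plant_id" %in% names(cohort)) cohort$plant_id
         else sprintf("plant_%04d", seq_len(n))
  plant_records(ids, n_seeds, n_aborted)
}

#' Simulate the F2 experiment end to end
#'
#' Seeds the generator once from `config$seed`, draws the F2 cohort and
#' then the backcross panel from the same stream.
#'
#' @inheritParams simulate_backcross_panel
#' @return A list with `cohort` and `records`.
#' @export
simulate_f2_experiment <- function(config,
                                   tester = selfer_genotype(config$model)) {
  .check_config(config)
  .maybe_seed(config)
  inner <- .strip_seed(config)
  cohort <- simulate_f2_cohort(inner)
  records <- simulate_backcross_panel(cohort, inner, tester)
  list(cohort = cohort, records = records)
}

#' Simulate seed scoring on selfed F1 plants
#'
#' Each seed of each selfed F1 mother is independently lethal with
#' probability [f1_self_abortion_rate()] of the model, flipped through
#' the mis-scoring channel. The default design mirrors a small F1
#' selfing series: 7 mother plants totalling 207 scored seeds.
#'
#' @param config a [sim_config()].
#' @param n_mothers number of selfed F1 plants.
#' @param seeds_per_mother integer vector of seeds scored per mother
#'   (recycled to `n_mothers`), or `NULL` for the default design of 207
#'   seeds split over 7 plants.
#' @return A [plant_records()] table, one row per mother.
#' @examples
#' rec <- simulate_f1_selfing(sim_config(seed = 1))
#' sum(rec$n_aborted) / sum(rec$n_seeds)  # close to 1/16
#' @export
simulate_f1_selfing <- function(config, n_mothers = 7,
                                seeds_per_mother = NULL) {
  .check_config(config)
  if (!is.numeric(n_mothers) || length(n_mothers) != 1L || n_mothers < 1 ||
      n_mothers != trunc(n_mothers))
    .cfg_err("n_mothers must be a single integer >= 1")
  if (is.null(seeds_per_mother)) {
    if (n_mothers == 7) seeds_per_mother <- c(30, 30, 30, 30, 29, 29, 29)
    else seeds_per_mother <- rep.int(round(config$seeds_per_plant), n_mothers)
  }
  seeds_per_mother <- rep_len(as.integer(seeds_per_mother), n_mothers)
  if (any(seeds_per_mother < 1))
    .cfg_err("seeds_per_mother must be >= 1")
  .maybe_seed(config)
  rate <- .noisy_rate(as.numeric(f1_self_abortion_rate(config$model)),
                      config$epsilon)
  n_aborted <- stats::rbinom(n_mothers, seeds_per_mother, rate)
  plant_records(sprintf("F1self_%02d", seq_len(n_mothers)),
                seeds_per_mother, n_aborted)
}

#' Simulate a RIL panel by single-seed descent
#'
#' Each line starts at the interspecies F1 and advances one selfing
#' generation at a time; at every generation the line's next genotype is
#' drawn from the survivor distribution of its self-cross, so
#' incompatible allele combinations are purged exactly as in RIL
#' construction. Terminal genotypes pair with
#' [simulate_backcross_panel()] to emulate scoring the RILs as pollen
#' donors on the selfer tester.
#'
#' @param config a [sim_config()].
#' @param n_generations selfing generations (>= 1; 6 is a typical RIL
#'   depth).
#' @param n_lines number of independent lines (defaults to
#'   `config$n_plants`).
#' @return A `data.frame` with columns `plant_id` and `genotype`.
#' @examples
#' ril <- simulate_ril_panel(sim_config(n_plants = 20, seed = 1))
#' @export
simulate_ril_panel <- function(config, n_generations = 6,
                               n_lines = config$n_plants) {
  .check_config(config)
  if (!is.numeric(n_generations) || length(n_generations) != 1L ||
      n_generations < 1 || n_generations != trunc(n_generations))
    .cfg_err("n_generations must be a single integer >= 1")
  if (!is.numeric(n_lines) || length(n_lines) != 1L || n_lines < 1 ||
      n_lines != trunc(n_lines))
    .cfg_err("n_lines must be a single integer >= 1")
  .maybe_seed(config)
  model <- config$model
  cache <- new.env(parent = emptyenv())
  offspring_dist <- function(key) {
    d <- cache[[key]]
    if (is.null(d)) {
      out <- .self_offspring_dist(parse_genotype(key, model), model,
                                  conditioned = TRUE)
      d <- list(genotype = out$genotype, prob = as.numeric(out$freq))
      cache[[key]] <- d
    }
    d
  }
  lines <- rep.int(format_genotype(f1_genotype(model), model), n_lines)
  for (g in seq_len(n_generations)) {
    for (key in unique(lines)) {
      ix <- which(lines == key)
      d <- offspring_dist(key)
      lines[ix] <- d$genotype[sample.int(length(d$genotype), length(ix),
                                         replace = TRUE, prob = d$prob)]
    }
  }
  data.frame(plant_id = sprintf("RIL_%04d", seq_len(n_lines)),
             genotype = lines, stringsAsFactors = FALSE)
}
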