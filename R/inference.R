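# Confronting observed per-plant seed-abortion counts with candidate
# locus-number models: class assignment, chi-square goodness of fit,
# model selection, the 2% binarisation used upstream of QTL mapping, and
# Wilson intervals for abortion proportions.

#' Per-plant seed-abortion records
#'
#' Builds and validates the table of observed per-plant seed counts: one
#' row per plant with the number of seeds scored and the number of seeds
#' aborted. This is the data shape produced by scoring the seeds of each
#' backcross (seed parent x F2 pollen donor).
#'
#' @param plant_id plant identifiers (coerced to character; must be
#'   unique).
#' @param n_seeds number of seeds scored per plant (>= 1).
#' @param n_aborted number of aborted seeds per plant
#'   (0 <= n_aborted <= n_seeds).
#' @return A `data.frame` with columns `plant_id`, `n_seeds`, `n_aborted`
#'   and `observed_rate`.
#' @examples
#' plant_records(c("p1", "p2"), c(30, 28), c(0, 14))
#' @export
plant_records <- function(plant_id, n_seeds, n_aborted) {
  df <- data.frame(plant_id = as.character(plant_id),
                   n_seeds = as.numeric(n_seeds),
                   n_aborted = as.numeric(n_aborted),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$n_seeds) | is.na(df$n_aborted) |
                 df$n_seeds < 1 | df$n_seeds != trunc(df$n_seeds) |
                 df$n_aborted < 0 | df$n_aborted != trunc(df$n_aborted) |
                 df$n_aborted > df$n_seeds)
  if (length(bad))
    .data_err(sprintf(
      "invalid plant record(s) at row(s) %s: need integer n_seeds >= 1 and 0 <= n_aborted <= n_seeds",
      paste(bad, collapse = ", ")))
  if (anyDuplicated(df$plant_id))
    .data_err("plant_id values must be unique")
  df$observed_rate <- df$n_aborted / df$n_seeds
  df
}

.check_records <- function(records) {
  need <- c("plant_id", "n_seeds", "n_aborted")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    .data_err("records must be a data.frame with columns plant_id, n_seeds, n_aborted")
  plant_records(records$plant_id, records$n_seeds, records$n_aborted)
}

#' Read and write per-plant seed tables
#'
#' Tab-separated text with a header row `plant_id  n_seeds  n_aborted`;
#' lines starting with `#` are comments (used for provenance headers).
#'
#' @param path file path.
#' @param records a [plant_records()] table.
#' @param header_lines optional character vector written as `#` comment
#'   lines before the table.
#' @return `read_plant_table()` returns a validated [plant_records()]
#'   table; `write_plant_table()` returns `path` invisibly.
#' @export
read_plant_table <- function(path) {
  if (!file.exists(path)) .data_err(sprintf("no such file: %s", path))
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) .data_err(sprintf("cannot parse %s: %s", path,
                                          conditionMessage(e))))
  if (nrow(df) == 0L) .data_err(sprintf("empty plant table: %s", path))
  .check_records(df)
}

#' @rdname read_plant_table
#' @export
write_plant_table <- function(records, path, header_lines = character(0)) {
  records <- .check_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(records[c("plant_id", "n_seeds", "n_aborted")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign plants to abortion-rate classes
#'
#' Maximum-binomial-likelihood assignment of each plant to one of the
#' model's abortion-rate classes. A scoring-noise rate `epsilon` (the
#' probability a seed's aborted/normal call is flipped) moves each class
#' rate `c` to the effective rate `c(1-epsilon) + (1-c)epsilon`, so the
#' boundary classes 0 and 1 retain nonzero likelihood for imperfectly
#' scored plants. Ties break toward the smaller class.
#'
#' @param n_aborted,n_seeds integer vectors of per-plant counts.
#' @param classes candidate class rates (numeric or [rat()] vector), e.g.
#'   `as.numeric(f2_class_distribution(model)$class)`.
#' @param epsilon seed mis-scoring probability, in `[0, 0.5)`.
#' @return Numeric vector of assigned class rates (one per plant).
#' @examples
#' assign_class(c(0, 15, 4), c(30, 30, 24), c(0, 1/8, 1/4, 1/2, 1))
#' @export
assign_class <- function(n_aborted, n_seeds, classes, epsilon = 0.01) {
  if (!length(classes)) .cfg_err("classes must be non-empty")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 ||
      epsilon >= 0.5)
    .cfg_err("epsilon must lie in [0, 0.5)")
  cls <- sort(as.numeric(classes))
  eff <- cls * (1 - epsilon) + (1 - cls) * epsilon
  ll <- vapply(eff, function(p)
    stats::dbinom(n_aborted, n_seeds, p, log = TRUE),
    numeric(length(n_aborted)))
  ll <- matrix(ll, nrow = length(n_aborted))
  cls[max.col(ll, ties.method = "first")]
}

#' Expected class counts under a model
#'
#' @param dist a [f2_class_distribution()].
#' @param n_plants number of plants in the panel (>= 1).
#' @return Named numeric vector of expected counts (exact rationals
#'   rendered as floats), summing to `n_plants`.
#' @examples
#' expected_counts(f2_class_distribution(bdm_model(1, 3)), 240)
#' @export
expected_counts <- function(dist, n_plants) {
  if (!inherits(dist, "class_distribution"))
    .cfg_err("dist must be a class_distribution")
  if (!is.numeric(n_plants) || length(n_plants) != 1L || n_plants < 1 ||
      n_plants != trunc(n_plants))
    .cfg_err("n_plants must be a single integer >= 1")
  e <- as.numeric(rat(n_plants) * dist$freq)
  names(e) <- format(dist$class)
  e
}

#' Expected assigned-class counts given the scoring design
#'
#' When plants are assigned to abortion-rate classes from a finite number
#' of scored seeds, adjacent classes bleed into each other: a true-1/8
#' plant with 30 seeds is read as 1/4 whenever 6 or more seeds abort,
#' which happens about 17% of the time. The correct multinomial null for
#' a goodness-of-fit test on *assigned* classes is therefore the
#' theoretical class distribution pushed through this known binomial
#' read-out channel. For each plant with `s` scored seeds,
#' `P(assigned = c) = sum_t f(t) * P(assign(K, s) = c)` with
#' `K ~ Binomial(s, t(1-eps) + (1-t)eps)`; expected counts sum these over
#' the panel's actual seed numbers.
#'
#' @param dist a [f2_class_distribution()].
#' @param n_seeds integer vector of seeds scored per plant.
#' @param epsilon the mis-scoring rate used in [assign_class()].
#' @return Named numeric vector of expected assigned-class counts,
#'   summing to `length(n_seeds)`.
#' @seealso [chisq_gof()], which uses these counts when given the panel's
#'   seed numbers.
#' @export
expected_assigned_counts <- function(dist, n_seeds, epsilon = 0.01) {
  if (!inherits(dist, "class_distribution"))
    .cfg_err("dist must be a class_distribution")
  if (!length(n_seeds) || any(n_seeds < 1) || any(n_seeds != trunc(n_seeds)))
    .data_err("n_seeds must be integers >= 1")
  cls <- as.numeric(dist$class)
  f <- as.numeric(dist$freq)
  eff <- cls * (1 - epsilon) + (1 - cls) * epsilon
  expected <- numeric(length(cls))
  for (s in unique(n_seeds)) {
    n_s <- sum(n_seeds == s)
    amap <- assign_class(0:s, rep.int(s, s + 1L), cls, epsilon)
    # P(assigned = c | true class t, s seeds), classes x true-classes
    p_assign <- vapply(eff, function(p) {
      dk <- stats::dbinom(0:s, s, p)
      vapply(cls, function(cc) sum(dk[amap == cc]), numeric(1))
    }, numeric(length(cls)))
    expected <- expected + n_s * as.vector(p_assign %*% f)
  }
  names(expected) <- format(dist$class)
  expected
}

#' Chi-square goodness of fit of class counts to a model
#'
#' Pearson chi-square of observed class counts against the expected
#' counts of an abortion-rate class distribution. Adjacent classes (in
#' ascending rate order) are pooled until every pooled expected count is
#' at least `pooling_min` (the usual small-expected-count practice); the
#' pooling map is reported so the test is auditable. Degrees of freedom
#' are the number of pooled classes minus 1.
#'
#' By default the expected counts are the raw theoretical frequencies
#' times the panel size ([expected_counts()]). When the observed counts
#' came from likelihood-based class assignment of finite seed counts
#' (as in [compare_models()]), pass the panel's `n_seeds` so the null
#' accounts for assignment error ([expected_assigned_counts()]);
#' without that correction the test rejects a true model far too often
#' at realistic seed numbers.
#'
#' @param observed numeric vector of observed class counts, aligned with
#'   `dist$class` (ascending class order).
#' @param dist a [f2_class_distribution()].
#' @param pooling_min minimum pooled expected count (default 5).
#' @param n_seeds optional integer vector of seeds scored per plant; when
#'   supplied, expected counts are corrected for class-assignment error.
#' @param epsilon mis-scoring rate used by the assignment (only with
#'   `n_seeds`).
#' @return An object of class `"gof_result"` with the observed, expected
#'   and pooled counts, the pooling map, `statistic`, `df` and `p.value`.
#' @examples
#' d <- f2_class_distribution(bdm_model(1, 3))
#' chisq_gof(c(150, 34, 40, 22, 4), d)
#' @export
chisq_gof <- function(observed, dist, pooling_min = 5, n_seeds = NULL,
                      epsilon = 0.01) {
  if (!inherits(dist, "class_distribution"))
    .cfg_err("dist must be a class_distribution")
  if (length(observed) != length(dist$class))
    .data_err(sprintf("observed must have one count per class (%d)",
                      length(dist$class)))
  if (any(observed < 0) || any(observed != trunc(observed)))
    .data_err("observed counts must be non-negative integers")
  n <- sum(observed)
  if (n < 1) .data_err("observed counts sum to zero")
  if (is.null(n_seeds)) {
    expected <- expected_counts(dist, n)
  } else {
    if (length(n_seeds) != n)
      .data_err("n_seeds must have one entry per counted plant")
    expected <- expected_assigned_counts(dist, n_seeds, epsilon)
  }

  groups <- list()
  cur <- integer(0)
  acc <- 0
  for (i in seq_along(expected)) {
    cur <- c(cur, i)
    acc <- acc + expected[i]
    if (acc >= pooling_min) {
      groups[[length(groups) + 1L]] <- cur
      cur <- integer(0)
      acc <- 0
    }
  }
  if (length(cur)) {
    if (!length(groups)) groups <- list(cur)
    else groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
  }
  if (length(groups) < 2L)
    .stat_err("fewer than 2 classes after pooling: goodness of fit undefined")

  pooled_obs <- vapply(groups, function(ix) sum(observed[ix]), numeric(1))
  pooled_exp <- vapply(groups, function(ix) sum(expected[ix]), numeric(1))
  labels <- vapply(groups, function(ix)
    paste(names(expected)[ix], collapse = "+"), character(1))
  names(pooled_obs) <- names(pooled_exp) <- labels
  statistic <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
  df <- length(groups) - 1L
  structure(
    list(observed = stats::setNames(observed, names(expected)),
         expected = expected,
         pooled_observed = pooled_obs, pooled_expected = pooled_exp,
         pooling = stats::setNames(groups, labels),
         statistic = statistic, df = df,
         p.value = stats::pchisq(statistic, df, lower.tail = FALSE),
         n_plants = n,
         model = sprintf("%dm x %dp", dist$model$n_maternal,
                         dist$model$n_paternal)),
    class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit to the %s model\n", x$model))
  print(data.frame(class = names(x$pooled_observed),
                   observed = x$pooled_observed,
                   expected = round(x$pooled_expected, 2)),
        row.names = FALSE)
  cat(sprintf("X-squared = %.4g, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p.value))
  invisible(x)
}

#' Compare locus-number models on a backcross panel
#'
#' For each candidate incompatibility model, assigns every plant to that
#' model's abortion-rate classes ([assign_class()]), tests the class
#' counts against the model's theoretical F2 distribution
#' ([chisq_gof()]), and ranks candidates. The selected model is the one
#' with the highest goodness-of-fit p-value; candidates with p below
#' `alpha` are flagged as rejected (the non-rejection criterion used when
#' the observed panel was compared with the 2- and 3-paternal-locus
#' predictions).
#'
#' @param records a [plant_records()] table.
#' @param candidate_models list of at least two [bdm_model()]s.
#' @param epsilon seed mis-scoring rate used in class assignment.
#' @param pooling_min minimum pooled expected count for the chi-square.
#' @param alpha rejection level (default 0.05).
#' @param conditioned use the survivor-conditioned F2 distribution.
#' @return An object of class `"model_comparison"`: list with `table`
#'   (one row per candidate: statistic, df, p_value, rejected, selected)
#'   and `fits` (the underlying [chisq_gof()] results).
#' @examples
#' m3 <- bdm_model(1, 3)
#' cfg <- sim_config(model = m3, n_plants = 100, seed = 1)
#' panel <- simulate_backcross_panel(simulate_f2_cohort(cfg), cfg)
#' compare_models(panel, list(bdm_model(1, 2), m3))
#' @export
compare_models <- function(records, candidate_models, epsilon = 0.01,
                           pooling_min = 5, alpha = 0.05,
                           conditioned = TRUE) {
  records <- .check_records(records)
  if (!is.list(candidate_models) || length(candidate_models) < 2L ||
      !all(vapply(candidate_models, inherits, logical(1), "bdm_model")))
    .cfg_err("candidate_models must be a list of at least two bdm_model objects")
  fits <- vector("list", length(candidate_models))
  rows <- vector("list", length(candidate_models))
  for (k in seq_along(candidate_models)) {
    mod <- candidate_models[[k]]
    dist <- f2_class_distribution(mod, conditioned = conditioned)
    cls <- as.numeric(dist$class)
    assigned <- assign_class(records$n_aborted, records$n_seeds, cls,
                             epsilon = epsilon)
    observed <- vapply(cls, function(cc) sum(assigned == cc), numeric(1))
    fits[[k]] <- chisq_gof(observed, dist, pooling_min = pooling_min,
                           n_seeds = records$n_seeds, epsilon = epsilon)
    rows[[k]] <- data.frame(
      model = fits[[k]]$model,
      n_maternal = mod$n_maternal, n_paternal = mod$n_paternal,
      statistic = fits[[k]]$statistic, df = fits[[k]]$df,
      p_value = fits[[k]]$p.value,
      rejected = fits[[k]]$p.value <= alpha,
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  table$selected <- seq_len(nrow(table)) == which.max(table$p_value)
  names(fits) <- table$model
  structure(list(table = table[order(-table$p_value), ], fits = fits,
                 alpha = alpha, n_plants = nrow(records)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("locus-number model comparison on %d plants (alpha = %g)\n",
              x$n_plants, x$alpha))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Binarise per-plant abortion rates
#'
#' Converts each plant's observed abortion rate into the binary trait
#' used for QTL mapping: 1 for plants with a rate strictly greater than
#' `threshold` (default 2%), 0 otherwise. The returned vector carries a
#' `"histogram"` attribute: the log10-transformed rate histogram on which
#' such a threshold is judged (a bimodal distribution separating
#' non-triggering from triggering plants), with zero rates mapped to a
#' floor bin below the smallest positive rate.
#'
#' @param records a [plant_records()] table.
#' @param threshold rate threshold in (0, 1); the comparison is strict.
#' @param n_bins number of histogram bins.
#' @return Integer vector of 0/1 trait values named by `plant_id`, with
#'   attribute `"histogram"` (a [graphics::hist()] object on the log10
#'   rate scale, not plotted).
#' @examples
#' rec <- plant_records(paste0("p", 1:3), c(50, 50, 50), c(0, 1, 25))
#' binarize_abortion(rec)  # 0 1 1 at the default 2% threshold
#' @export
binarize_abortion <- function(records, threshold = 0.02) {
  records <- .check_records(records)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 ||
      threshold >= 1)
    .cfg_err("threshold must lie strictly between 0 and 1")
  trait <- as.integer(records$observed_rate > threshold)
  names(trait) <- records$plant_id
  r <- records$observed_rate
  floor_val <- if (any(r > 0)) min(r[r > 0]) / 10 else 1e-4
  lr <- log10(pmax(r, floor_val))
  attr(trait, "histogram") <- graphics::hist(lr, plot = FALSE)
  trait
}

#' Wilson score interval for a binomial proportion
#'
#' Confidence interval for a seed-abortion proportion. The Wilson score
#' interval behaves sensibly at the boundaries (0 of n, n of n), unlike
#' the Wald interval, which matters because most plants in these panels
#' abort no seeds at all.
#'
#' @param n_aborted,n_seeds counts (vectors are recycled).
#' @param level confidence level (default 0.95).
#' @return A `data.frame` with columns `estimate`, `lower`, `upper`.
#' @examples
#' binomial_ci(5, 100)          # about [0.022, 0.112]
#' binomial_ci(c(0, 100), 100)  # boundary cases
#' @export
binomial_ci <- function(n_aborted, n_seeds, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    .cfg_err("level must lie strictly between 0 and 1")
  n <- max(length(n_aborted), length(n_seeds))
  k <- rep_len(n_aborted, n)
  m <- rep_len(n_seeds, n)
  if (any(m < 1) || any(k < 0) || any(k > m))
    .data_err("need n_seeds >= 1 and 0 <= n_aborted <= n_seeds")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / m
  denom <- 1 + z^2 / m
  centre <- (p + z^2 / (2 * m)) / denom
  half <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / denom
  data.frame(estimate = p,
             lower = pmax(0, centre - half),
             upper = pmin(1, centre + half))
}
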