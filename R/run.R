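# File-emitting entry points tying the stages into the full workflow:
# predict (exact model outputs), simulate (synthetic panels), fit (model
# comparison on a plant table) and recover (replicated model-recovery
# study). A thin command-line dispatcher over these functions ships in
# inst/cli/bdmseed.R. All outputs are tab-separated text with '#'
# provenance headers; headers carry the package version, the
# configuration echo, the seed and input checksums, but no timestamps, so
# a fixed-seed rerun is byte-identical.

.provenance <- function(config_lines = character(0), seed = NULL,
                        inputs = character(0)) {
  h <- c(sprintf("bdmseed %s",
                 as.character(utils::packageVersion("bdmseed"))))
  if (!is.null(seed)) h <- c(h, sprintf("seed: %s", seed))
  h <- c(h, config_lines)
  for (f in inputs)
    h <- c(h, sprintf("input: %s md5=%s", basename(f),
                      unname(tools::md5sum(f))))
  h
}

.write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write exact distributions to delimited text
#'
#' Serialisers for the exact objects of the cross engine and the
#' predictor: genotype string (or class rate), exact numerator and
#' denominator, and the float rendering, as tab-separated text with `#`
#' provenance comment lines.
#'
#' @param x the object to write.
#' @param path output file path.
#' @param header_lines extra comment lines (e.g. a configuration echo).
#' @return `path`, invisibly.
#' @export
write_class_distribution <- function(x, path, header_lines = character(0)) {
  if (!inherits(x, "class_distribution"))
    .cfg_err("x must be a class_distribution")
  .write_tsv(as.data.frame(x), path, c(.provenance(header_lines),
                                       sprintf("tester: %s", x$tester)))
}

#' @rdname write_class_distribution
#' @export
write_cross_outcome <- function(x, path, header_lines = character(0)) {
  if (!inherits(x, "cross_outcome")) .cfg_err("x must be a cross_outcome")
  hdr <- c(.provenance(header_lines),
           sprintf("cross: %s x %s", x$maternal, x$paternal),
           sprintf("abortion_rate: %s (%.10g)", format(x$abortion_rate),
                   as.numeric(x$abortion_rate)))
  .write_tsv(as.data.frame(x), path, hdr)
}

#' @rdname write_class_distribution
#' @export
write_generation_state <- function(x, path, header_lines = character(0)) {
  if (!inherits(x, "generation_state"))
    .cfg_err("x must be a generation_state")
  .write_tsv(as.data.frame(x), path,
             c(.provenance(header_lines),
               sprintf("generation: %d", x$generation)))
}

#' Run the exact-prediction stage
#'
#' Writes the theoretical F2 abortion-rate class distribution, the
#' F1-selfing abortion rate, and (optionally) single-cross outcome tables
#' for a model, to `out_dir`.
#'
#' @param model a [bdm_model()].
#' @param out_dir output directory (created if missing).
#' @param crosses optional character vector of crosses to tabulate, each
#'   `"<maternal> x <paternal>"` in genotype-string form, e.g.
#'   `"RR|aabbcc x rr|AABBCC"`.
#' @param conditioned survivor-condition the F2 distribution.
#' @return Invisibly, the vector of files written.
#' @export
run_predict <- function(model = bdm_model(1, 3), out_dir,
                        crosses = character(0), conditioned = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sprintf("model: %d maternal x %d paternal loci", model$n_maternal,
                 model$n_paternal)
  files <- character(0)

  f <- file.path(out_dir, "f2_class_distribution.tsv")
  write_class_distribution(f2_class_distribution(model, conditioned), f, cfg)
  files <- c(files, f)

  f <- file.path(out_dir, "f1_self_abortion.tsv")
  rate <- f1_self_abortion_rate(model)
  .write_tsv(data.frame(quantity = "f1_self_abortion_rate",
                        num = rat_num(rate), den = rat_den(rate),
                        value = as.numeric(rate),
                        percent = 100 * as.numeric(rate)),
             f, .provenance(cfg))
  files <- c(files, f)

  for (i in seq_along(crosses)) {
    parts <- strsplit(crosses[i], "x", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      .cfg_err(sprintf("malformed cross spec '%s': expected '<mat> x <pat>'",
                       crosses[i]))
    mat <- parse_genotype(trimws(parts[1]), model)
    pat <- parse_genotype(trimws(parts[2]), model)
    f <- file.path(out_dir, sprintf("cross_%02d.tsv", i))
    write_cross_outcome(cross(mat, pat, model), f, cfg)
    files <- c(files, f)
  }
  invisible(files)
}

#' Run a synthetic crossing experiment
#'
#' Simulates the requested design and writes the cohort genotypes and the
#' per-plant seed table (directly consumable by [run_fit()]).
#'
#' @param config a [sim_config()]; its `seed` governs all draws.
#' @param out_dir output directory.
#' @param design `"f2_backcross"` (cohort + backcross panel),
#'   `"f1_selfing"` or `"ril"` (single-seed-descent panel + backcross
#'   scoring).
#' @param n_generations RIL depth when `design = "ril"`.
#' @return Invisibly, the vector of files written.
#' @export
run_simulate <- function(config, out_dir, design = c("f2_backcross",
                                                     "f1_selfing", "ril"),
                         n_generations = 6) {
  .check_config(config)
  design <- match.arg(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance(c(sprintf("design: %s", design), format(config)),
                     seed = config$seed)
  files <- character(0)
  .maybe_seed(config)
  inner <- .strip_seed(config)
  if (design == "f1_selfing") {
    records <- simulate_f1_selfing(inner)
  } else {
    cohort <- if (design == "f2_backcross") simulate_f2_cohort(inner)
              else simulate_ril_panel(inner, n_generations = n_generations)
    records <- simulate_backcross_panel(cohort, inner)
    f <- file.path(out_dir, "cohort_genotypes.tsv")
    .write_tsv(cohort, f, hdr)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "plant_records.tsv")
  write_plant_table(records, f, hdr)
  invisible(c(files, f))
}

#' Fit locus-number models to a plant table
#'
#' Reads a per-plant seed table, compares candidate incompatibility
#' models by chi-square goodness of fit, and writes the comparison table,
#' the per-model pooled observed/expected counts, and the binarised trait
#' vector (ready for downstream QTL tools).
#'
#' @param input path to a plant table (see [read_plant_table()]), or a
#'   [plant_records()] data.frame.
#' @param out_dir output directory.
#' @param candidate_models list of [bdm_model()]s; defaults to the
#'   2-paternal and 3-paternal candidates with one maternal locus.
#' @param epsilon,pooling_min,alpha passed to [compare_models()].
#' @param threshold binarisation threshold for the trait vector.
#' @return The [compare_models()] result, invisibly.
#' @export
run_fit <- function(input, out_dir,
                    candidate_models = list(bdm_model(1, 2), bdm_model(1, 3)),
                    epsilon = 0.01, pooling_min = 5, alpha = 0.05,
                    threshold = 0.02) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(input)) {
    records <- read_plant_table(input)
    inputs <- input
  } else {
    records <- .check_records(input)
    inputs <- character(0)
  }
  cfg <- sprintf("fit: epsilon=%g pooling_min=%g alpha=%g threshold=%g",
                 epsilon, pooling_min, alpha, threshold)
  hdr <- .provenance(cfg, inputs = inputs)
  cmp <- compare_models(records, candidate_models, epsilon = epsilon,
                        pooling_min = pooling_min, alpha = alpha)
  .write_tsv(cmp$table, file.path(out_dir, "model_comparison.tsv"), hdr)
  for (nm in names(cmp$fits)) {
    fit <- cmp$fits[[nm]]
    .write_tsv(data.frame(class = names(fit$pooled_observed),
                          observed = fit$pooled_observed,
                          expected = fit$pooled_expected),
               file.path(out_dir, sprintf("gof_%s.tsv",
                                          gsub("[^0-9a-z]+", "_", nm))),
               c(hdr, sprintf("model: %s", nm),
                 sprintf("statistic: %.10g df: %d p: %.10g", fit$statistic,
                         fit$df, fit$p.value)))
  }
  trait <- binarize_abortion(records, threshold = threshold)
  .write_tsv(data.frame(plant_id = names(trait), trait = as.integer(trait)),
             file.path(out_dir, "binary_trait.tsv"), hdr)
  invisible(cmp)
}

#' Replicated model-recovery study
#'
#' Simulates `n_reps` independent panels under the configured model and
#' fits the candidate models to each; reports how often each candidate is
#' selected and how often it is rejected at `alpha`. This is the check
#' that the inference stage recovers the generating locus number from
#' panels of realistic size.
#'
#' @param config a [sim_config()] describing the generating model and
#'   panel design; `config$seed` seeds the whole study.
#' @param n_reps number of replicate panels.
#' @param out_dir optional output directory for the summary table.
#' @param candidate_models,epsilon,pooling_min,alpha as in [run_fit()].
#' @return A list with `summary` (one row per candidate: times selected,
#'   times rejected) and `p_values` (an `n_reps` x candidates matrix).
#' @export
run_recover <- function(config, n_reps = 100, out_dir = NULL,
                        candidate_models = list(bdm_model(1, 2),
                                                bdm_model(1, 3)),
                        epsilon = 0.01, pooling_min = 5, alpha = 0.05) {
  .check_config(config)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1)
    .cfg_err("n_reps must be a single integer >= 1")
  .maybe_seed(config)
  inner <- .strip_seed(config)
  labels <- vapply(candidate_models, function(m)
    sprintf("%dm x %dp", m$n_maternal, m$n_paternal), character(1))
  pvals <- matrix(NA_real_, n_reps, length(candidate_models),
                  dimnames = list(NULL, labels))
  selected <- character(n_reps)
  for (r in seq_len(n_reps)) {
    panel <- simulate_backcross_panel(simulate_f2_cohort(inner), inner)
    cmp <- compare_models(panel, candidate_models, epsilon = epsilon,
                          pooling_min = pooling_min, alpha = alpha)
    pvals[r, cmp$table$model] <- cmp$table$p_value
    selected[r] <- cmp$table$model[cmp$table$selected]
  }
  summary <- data.frame(
    model = labels,
    n_selected = vapply(labels, function(l) sum(selected == l), numeric(1)),
    n_rejected = colSums(pvals <= alpha),
    n_reps = n_reps, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(summary, file.path(out_dir, "recovery_summary.tsv"),
               .provenance(c(sprintf("n_reps: %d", n_reps), format(config)),
                           seed = config$seed))
  }
  list(summary = summary, p_values = pvals)
}
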