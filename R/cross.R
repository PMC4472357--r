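# Exact offspring distributions under seed-stage viability selection.
#
# All gametes of a genotype are equiprobable (free recombination), so a
# cross is enumerated by counting ordered gamete pairs with integers and
# dividing once at the end; every frequency is an exact rational.

# genotype matrix row layout used for distributions: first n_loci columns
# are the maternally inherited alleles, next n_loci the paternally
# inherited ones (1 = incompatible allele)
.geno_row <- function(g) c(g["maternal", ], g["paternal", ])

.row_to_genotype <- function(row, model) {
  L <- model$n_loci
  genotype(row[seq_len(L)], row[L + seq_len(L)], model)
}

.row_key <- function(rows, model) {
  apply(rows, 1L, function(r) format_genotype(.row_to_genotype(r, model), model))
}

# all ordered offspring of maternal x paternal with integer pair counts
.pair_enumeration <- function(maternal, paternal, model) {
  gm <- enumerate_gametes(maternal, model)$haplotypes
  gp <- enumerate_gametes(paternal, model)$haplotypes
  nm <- nrow(gm)
  np <- nrow(gp)
  i <- rep(seq_len(nm), times = np)
  j <- rep(seq_len(np), each = nm)
  lethal <- .lethal_maternal(gm, model)[i] & .lethal_paternal(gp, model)[j]
  rows <- cbind(gm[i, , drop = FALSE], gp[j, , drop = FALSE])
  list(rows = rows, lethal = lethal, total = nm * np)
}

# aggregate duplicated offspring rows; returns rows, counts
.aggregate_rows <- function(rows) {
  L2 <- ncol(rows)
  code <- as.vector(rows %*% 2^(seq_len(L2) - 1))
  tab <- table(code)
  first <- match(as.numeric(names(tab)), code)
  list(rows = rows[first, , drop = FALSE], count = as.vector(tab))
}

#' Cross two genotypes under the lethality model
#'
#' Enumerates the product of the two parental gamete distributions,
#' applies the seed-lethality rule ([seed_fate()]) to every ordered gamete
#' pair, and returns the exact abortion rate (the lethal probability mass)
#' together with the distribution of *surviving* offspring genotypes,
#' renormalised to sum to 1. Offspring genotypes are ordered (maternal vs
#' paternal allele tracked) because their own fate as parents is
#' parent-of-origin dependent.
#'
#' If every seed dies (`abortion_rate == 1`, as in the selfer x outcrosser
#' direction of the species cross) the survivor map is empty and the
#' outcome carries `complete_abortion = TRUE`, so downstream code cannot
#' silently draw offspring from it.
#'
#' @param maternal seed-parent [genotype()].
#' @param paternal pollen-parent [genotype()].
#' @param g a [genotype()] (for `self_cross`).
#' @param model a [bdm_model()].
#' @return An object of class `"cross_outcome"`: list with `abortion_rate`
#'   (a [rat()] scalar), `survivors` (list of `genotype` strings, `geno`
#'   allele matrix and `freq` [rat()] vector summing to 1),
#'   `complete_abortion`, and the parental genotype strings.
#' @examples
#' m <- bdm_model(1, 3)
#' cross(selfer_genotype(m), outcrosser_genotype(m), m)  # 100% abortion
#' cross(outcrosser_genotype(m), selfer_genotype(m), m)  # viable F1s
#' self_cross(f1_genotype(m), m)$abortion_rate           # 1/16
#' @export
cross <- function(maternal, paternal, model) {
  .check_genotype(maternal, model)
  .check_genotype(paternal, model)
  enum <- .pair_enumeration(maternal, paternal, model)
  n_lethal <- sum(enum$lethal)
  abortion <- rat(n_lethal, enum$total)
  if (n_lethal == enum$total) {
    survivors <- list(genotype = character(0),
                      geno = enum$rows[0, , drop = FALSE],
                      freq = rat(numeric(0), numeric(0)))
    complete <- TRUE
  } else {
    agg <- .aggregate_rows(enum$rows[!enum$lethal, , drop = FALSE])
    survivors <- list(genotype = .row_key(agg$rows, model),
                      geno = agg$rows,
                      freq = rat(agg$count, enum$total - n_lethal))
    complete <- FALSE
  }
  structure(
    list(abortion_rate = abortion, survivors = survivors,
         complete_abortion = complete,
         maternal = format_genotype(maternal, model),
         paternal = format_genotype(paternal, model),
         model = model),
    class = "cross_outcome")
}

#' @rdname cross
#' @export
self_cross <- function(g, model) cross(g, g, model)

#' @export
print.cross_outcome <- function(x, ...) {
  cat(sprintf("cross %s (seed parent) x %s (pollen donor)\n",
              x$maternal, x$paternal))
  cat(sprintf("abortion rate: %s (%.4g)\n", format(x$abortion_rate),
              as.numeric(x$abortion_rate)))
  if (x$complete_abortion) {
    cat("complete abortion: no surviving offspring\n")
  } else {
    cat(sprintf("%d surviving ordered genotypes\n",
                length(x$survivors$genotype)))
  }
  invisible(x)
}

#' @export
#' @rdname cross
#' @param x a `cross_outcome`.
#' @param unordered collapse parent-of-origin (so `Rr` and `rR` pool into
#'   one class) before tabulating. The ordered view is the primitive one —
#'   fates downstream depend on allele origin — but unordered counts are
#'   what a codominant-marker genotyping assay observes.
#' @param ... unused.
as.data.frame.cross_outcome <- function(x, unordered = FALSE, ...) {
  keys <- x$survivors$genotype
  freq <- x$survivors$freq
  if (unordered && length(keys)) {
    L <- x$model$n_loci
    rows <- x$survivors$geno
    # per locus, sort the two alleles so origin no longer distinguishes
    lo <- pmin(rows[, seq_len(L), drop = FALSE],
               rows[, L + seq_len(L), drop = FALSE])
    hi <- pmax(rows[, seq_len(L), drop = FALSE],
               rows[, L + seq_len(L), drop = FALSE])
    ukeys <- .row_key(cbind(hi, lo), x$model)  # upper-case allele first
    agg <- .sum_by_key(ukeys, freq)
    keys <- agg$keys
    freq <- agg$freq
  }
  data.frame(genotype = keys,
             freq_num = rat_num(freq),
             freq_den = rat_den(freq),
             freq = as.numeric(freq),
             stringsAsFactors = FALSE)
}

# offspring distribution of a self, optionally without removing lethal
# seeds (the unconditioned distribution); memoisable by genotype key
.self_offspring_dist <- function(g, model, conditioned = TRUE) {
  if (conditioned) {
    out <- self_cross(g, model)
    if (out$complete_abortion)
      stop("selfing this genotype leaves no viable seed; it cannot occur ",
           "among survivors of the model")
    list(genotype = out$survivors$genotype, geno = out$survivors$geno,
         freq = out$survivors$freq)
  } else {
    enum <- .pair_enumeration(g, g, model)
    agg <- .aggregate_rows(enum$rows)
    list(genotype = .row_key(agg$rows, model), geno = agg$rows,
         freq = rat(agg$count, enum$total))
  }
}

#' Population state of a selfing programme
#'
#' A `generation_state` is an exact probability distribution over ordered
#' genotypes describing a population (or the ensemble of single-seed
#' descent lines) at a given selfing generation.
#'
#' @param genotypes character vector of genotype strings (see
#'   [parse_genotype()]).
#' @param freq a [rat()] vector of frequencies summing to exactly 1 (or an
#'   integer-valued numeric vector of weights, which is normalised).
#' @param model a [bdm_model()].
#' @param generation integer generation index (0 = founding generation).
#' @return An object of class `"generation_state"`.
#' @examples
#' m <- bdm_model(1, 3)
#' generation_state("rR|AaBbCc", rat(1), m)  # an F1 founder population
#' @export
generation_state <- function(genotypes, freq, model, generation = 0L) {
  if (!inherits(freq, "rat")) freq <- rat(freq) / rat(sum(freq))
  if (length(genotypes) != length(freq))
    .cfg_err("genotypes and freq must have equal length")
  if (sum(freq) != rat(1))
    .cfg_err("generation-state frequencies must sum to exactly 1")
  geno <- do.call(rbind, lapply(genotypes, function(s)
    .geno_row(parse_genotype(s, model))))
  structure(list(genotype = genotypes, geno = geno, freq = freq,
                 generation = as.integer(generation), model = model),
            class = "generation_state")
}

#' @export
print.generation_state <- function(x, ...) {
  cat(sprintf("generation %d: %d ordered genotypes\n", x$generation,
              length(x$genotype)))
  df <- as.data.frame(x)
  print(utils::head(df[order(-df$freq), ], 10), row.names = FALSE)
  if (nrow(df) > 10) cat(sprintf("... %d more\n", nrow(df) - 10))
  invisible(x)
}

#' @export
as.data.frame.generation_state <- function(x, ...) {
  data.frame(genotype = x$genotype,
             freq_num = rat_num(x$freq), freq_den = rat_den(x$freq),
             freq = as.numeric(x$freq), stringsAsFactors = FALSE)
}

# sum rational contributions sharing a key
.sum_by_key <- function(keys, contrib) {
  idx <- split(seq_along(keys), keys)
  num <- numeric(length(idx))
  den <- numeric(length(idx))
  for (k in seq_along(idx)) {
    s <- sum(contrib[idx[[k]]])
    num[k] <- rat_num(s)
    den[k] <- rat_den(s)
  }
  list(keys = names(idx), freq = rat(num, den))
}

#' Advance single-seed descent by one selfing generation
#'
#' Each line selfs; seed-stage viability selection removes the lethal
#' genotype class, and the line's next state is the survivor distribution
#' of its self-cross. The population state is the exact mixture of these
#' per-genotype survivor distributions weighted by the current
#' frequencies. With `select = FALSE` the lethality rule is switched off
#' (a modelling control: plain Mendelian single-seed descent), which is
#' useful for quantifying how much selection purges the incompatible
#' allele combinations.
#'
#' @param state a [generation_state()].
#' @param model a [bdm_model()].
#' @param select apply seed-stage viability selection (default `TRUE`).
#' @return The [generation_state()] one selfing generation later.
#' @seealso [ril_panel_distribution()] for the full multi-generation run.
#' @export
advance_ssd <- function(state, model, select = TRUE) {
  cache <- new.env(parent = emptyenv())
  .advance_ssd_cached(state, model, select, cache)
}

.advance_ssd_cached <- function(state, model, select, cache) {
  all_keys <- character(0)
  all_num <- numeric(0)
  all_den <- numeric(0)
  geno_map <- new.env(parent = emptyenv())
  for (i in seq_along(state$genotype)) {
    key <- state$genotype[i]
    dist <- cache[[key]]
    if (is.null(dist)) {
      g <- .row_to_genotype(state$geno[i, ], model)
      dist <- .self_offspring_dist(g, model, conditioned = select)
      cache[[key]] <- dist
    }
    contrib <- state$freq[i] * dist$freq
    all_keys <- c(all_keys, dist$genotype)
    all_num <- c(all_num, rat_num(contrib))
    all_den <- c(all_den, rat_den(contrib))
    for (j in seq_along(dist$genotype))
      if (is.null(geno_map[[dist$genotype[j]]]))
        geno_map[[dist$genotype[j]]] <- dist$geno[j, ]
  }
  agg <- .sum_by_key(all_keys, rat(all_num, all_den))
  geno <- do.call(rbind, lapply(agg$keys, function(k) geno_map[[k]]))
  structure(list(genotype = agg$keys, geno = geno, freq = agg$freq,
                 generation = state$generation + 1L, model = model),
            class = "generation_state")
}

#' Exact genotype distribution of a RIL panel
#'
#' Starting from the interspecies F1 (outcrosser seed parent x selfer
#' pollen donor), propagates a recombinant-inbred-line panel by
#' single-seed descent for `n_generations` selfing generations, applying
#' seed-stage viability selection in every generation (unless
#' `select = FALSE`). Also reports the exact fraction of lines whose
#' terminal genotype would trigger a nonzero seed-abortion rate when used
#' as pollen donor on the selfer tester — the quantity that shrinks over
#' generations as incompatibility alleles are purged.
#'
#' @param model a [bdm_model()].
#' @param n_generations number of selfing generations (>= 0).
#' @param select apply viability selection each generation.
#' @param tester seed-parent tester genotype; defaults to
#'   [selfer_genotype()].
#' @return An object of class `"ril_distribution"`: list with `state` (the
#'   terminal [generation_state()]), `trigger_fraction` (a [rat()]
#'   scalar), and `class_distribution` (exact distribution of lines over
#'   donor abortion-rate classes, as in [f2_class_distribution()]).
#' @examples
#' m <- bdm_model(1, 3)
#' ril_panel_distribution(m, n_generations = 2)
#' @export
ril_panel_distribution <- function(model, n_generations, select = TRUE,
                                   tester = selfer_genotype(model)) {
  if (!is.numeric(n_generations) || length(n_generations) != 1L ||
      n_generations != trunc(n_generations) || n_generations < 0)
    .cfg_err("n_generations must be a single integer >= 0")
  state <- generation_state(format_genotype(f1_genotype(model), model),
                            rat(1), model, generation = 0L)
  cache <- new.env(parent = emptyenv())
  for (g in seq_len(n_generations))
    state <- .advance_ssd_cached(state, model, select, cache)
  q <- .state_donor_classes(state, model, tester)
  trigger <- sum(state$freq[as.numeric(q$class_of_line) > 0])
  if (length(trigger) == 0L) trigger <- rat(0)
  structure(list(state = state, trigger_fraction = trigger,
                 class_distribution = q$dist, n_generations = n_generations,
                 select = select),
            class = "ril_distribution")
}

# donor abortion-rate class of every genotype in a state, plus the
# aggregated exact class distribution
.state_donor_classes <- function(state, model, tester) {
  n <- length(state$genotype)
  cls_num <- numeric(n)
  cls_den <- numeric(n)
  for (i in seq_len(n)) {
    g <- .row_to_genotype(state$geno[i, ], model)
    q <- pollen_lethal_fraction(g, tester, model)
    cls_num[i] <- rat_num(q)
    cls_den[i] <- rat_den(q)
  }
  class_of_line <- rat(cls_num, cls_den)
  key <- paste0(cls_num, "/", cls_den)
  agg <- .sum_by_key(key, state$freq)
  o <- order(as.numeric(class_of_line)[match(agg$keys, key)])
  cls <- class_of_line[match(agg$keys, key)][o]
  list(class_of_line = class_of_line,
       dist = .new_class_distribution(cls, agg$freq[o], model,
                                      conditioned = NA,
                                      tester = format_genotype(tester, model)))
}

#' @export
print.ril_distribution <- function(x, ...) {
  cat(sprintf("RIL panel after %d single-seed-descent generations (%s)\n",
              x$n_generations,
              if (x$select) "with viability selection" else "no selection"))
  cat(sprintf("fraction of abortion-triggering lines: %s (%.4g)\n",
              format(x$trigger_fraction), as.numeric(x$trigger_fraction)))
  print(x$class_distribution)
  invisible(x)
}
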