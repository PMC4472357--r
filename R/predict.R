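# Predicted seed-abortion rates of pollen donors and the theoretical
# distribution of an F2 backcross panel over abortion-rate classes.

#' Predicted abortion rate of a pollen donor on a tester
#'
#' The probability that a random seed of the cross `tester` (seed parent)
#' x `donor` (pollen parent) is lethal. Because lethality is a
#' conjunction of a condition on the maternal gamete and a condition on
#' the paternal gamete, this equals the fraction of tester gametes
#' carrying the full maternal incompatible complement times the fraction
#' of donor pollen carrying the full paternal incompatible complement;
#' for the standard tester (homozygous for the maternal allele, as the
#' pure selfer is) it reduces to the donor's pollen fraction alone.
#'
#' @param donor pollen-parent [genotype()].
#' @param tester seed-parent [genotype()]; defaults to
#'   [selfer_genotype()], matching a backcross of the donor onto the
#'   selfing species.
#' @param model a [bdm_model()].
#' @return A [rat()] scalar in `[0, 1]`.
#' @examples
#' m <- bdm_model(1, 3)
#' pollen_lethal_fraction(parse_genotype("rr|AaBbCc", m), model = m)  # 1/8
#' pollen_lethal_fraction(parse_genotype("rr|AABBCC", m), model = m)  # 1
#' @export
pollen_lethal_fraction <- function(donor, tester = selfer_genotype(model),
                                   model) {
  .check_genotype(donor, model)
  .check_genotype(tester, model)
  gm <- enumerate_gametes(tester, model)$haplotypes
  gp <- enumerate_gametes(donor, model)$haplotypes
  rat(sum(.lethal_maternal(gm, model)) * sum(.lethal_paternal(gp, model)),
      nrow(gm) * nrow(gp))
}

#' Abortion rate of the selfed interspecies F1
#'
#' The lethal seed mass when the F1 hybrid (heterozygous at every locus)
#' is selfed: the probability that a seed inherits the maternal
#' incompatible allele through the egg at every maternal locus and the
#' paternal incompatible allele through the pollen at every paternal
#' locus, i.e. `(1/2)^(n_maternal + n_paternal)`. Computed by full gamete
#' enumeration, not from the closed form.
#'
#' @param model a [bdm_model()].
#' @return A [rat()] scalar, e.g. 1/16 for the 1 maternal x 3 paternal
#'   model (6.25%, to be compared with observed F1-selfing abortion).
#' @examples
#' as.numeric(f1_self_abortion_rate(bdm_model(1, 3)))  # 0.0625
#' @export
f1_self_abortion_rate <- function(model) {
  self_cross(f1_genotype(model), model)$abortion_rate
}

.new_class_distribution <- function(classes, freq, model, conditioned,
                                    tester) {
  structure(list(class = classes, freq = freq, model = model,
                 conditioned = conditioned, tester = tester),
            class = "class_distribution")
}

#' Theoretical distribution of F2 plants over abortion-rate classes
#'
#' The headline model prediction: the exact distribution of the
#' seed-abortion rate an F2 plant triggers when used as pollen donor on
#' the selfer tester. The F2 panel is formed by selfing the interspecies
#' F1; by default the distribution is conditioned on seed survival
#' (`conditioned = TRUE`), because plants that can be grown and
#' backcrossed are necessarily survivors of the F2 seed-abortion episode.
#' Conditioning matters: for the 1x3 model the 100%-abortion class has
#' frequency 1/120 among survivors but 1/64 unconditioned.
#'
#' The realisable classes are the products over paternal loci of 0, 1/2
#' or 1: `{0, 1/8, 1/4, 1/2, 1}` for three paternal loci and
#' `{0, 1/4, 1/2, 1}` for two.
#'
#' @param model a [bdm_model()].
#' @param conditioned condition the F2 panel on seed survival (default
#'   `TRUE`).
#' @param tester seed-parent tester [genotype()]; defaults to the pure
#'   selfer.
#' @return An object of class `"class_distribution"`: list with `class`
#'   (a [rat()] vector of abortion-rate classes, ascending) and `freq`
#'   (a [rat()] vector summing to exactly 1).
#' @examples
#' f2_class_distribution(bdm_model(1, 3))
#' f2_class_distribution(bdm_model(1, 2))
#' @export
f2_class_distribution <- function(model, conditioned = TRUE,
                                  tester = selfer_genotype(model)) {
  key <- paste(.model_key(model), conditioned,
               format_genotype(tester, model))
  cached <- .bdmseed_cache[[key]]
  if (!is.null(cached)) return(cached)
  f2 <- .self_offspring_dist(f1_genotype(model), model,
                             conditioned = conditioned)
  n <- length(f2$genotype)
  q_num <- numeric(n)
  q_den <- numeric(n)
  for (i in seq_len(n)) {
    g <- .row_to_genotype(f2$geno[i, ], model)
    q <- pollen_lethal_fraction(g, tester, model)
    q_num[i] <- rat_num(q)
    q_den[i] <- rat_den(q)
  }
  q_key <- paste0(q_num, "/", q_den)
  agg <- .sum_by_key(q_key, f2$freq)
  q_all <- rat(q_num, q_den)
  cls <- q_all[match(agg$keys, q_key)]
  o <- order(as.numeric(cls))
  out <- .new_class_distribution(cls[o], agg$freq[o], model, conditioned,
                                 format_genotype(tester, model))
  .bdmseed_cache[[key]] <- out
  out
}

# per-session memo for exact distributions (they are pure functions of the
# model, and model-fitting loops request them repeatedly)
.bdmseed_cache <- new.env(parent = emptyenv())

#' @export
print.class_distribution <- function(x, ...) {
  cat(sprintf("abortion-rate class distribution (%d maternal x %d paternal loci",
              x$model$n_maternal, x$model$n_paternal))
  if (isTRUE(x$conditioned)) cat(", survivor-conditioned")
  if (isFALSE(x$conditioned)) cat(", unconditioned")
  cat(")\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.class_distribution <- function(x, ...) {
  data.frame(class_rate_fraction = format(x$class),
             class_rate_percent = 100 * as.numeric(x$class),
             frequency_fraction = format(x$freq),
             frequency_float = as.numeric(x$freq),
             stringsAsFactors = FALSE)
}

#' @export
plot.class_distribution <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("Theoretical F2 abortion-rate classes (%dm x %dp)",
                    x$model$n_maternal, x$model$n_paternal)
  graphics::barplot(as.numeric(x$freq),
                    names.arg = paste0(100 * as.numeric(x$class), "%"),
                    xlab = "seed-abortion rate triggered on the tester",
                    ylab = "frequency of plants", main = main, ...)
  invisible(x)
}
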