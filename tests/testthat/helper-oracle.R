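# Independent brute-force oracles, written against raw 0/1 allele vectors
# only (no package internals), so they can cross-check the cross engine
# and the predictor.

# A raw genotype for the oracles: list(m = <maternal alleles>,
# p = <paternal alleles>), 0/1, 1 = incompatible allele.

# Enumerate all 4^L ordered gamete pairs of seed parent `gm` x pollen
# parent `gp` (each parent transmits, per locus, its maternal or paternal
# copy with probability 1/2). Returns the lethal pair count, the total,
# and a table of surviving ordered offspring keyed by allele vectors.
oracle_cross <- function(gm, gp, is_maternal) {
  L <- length(is_maternal)
  sel <- as.matrix(expand.grid(rep(list(1:2), 2 * L)))
  lethal <- 0L
  surv <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(sel))) {
    mg <- ifelse(sel[r, 1:L] == 1L, gm$m, gm$p)
    pg <- ifelse(sel[r, L + 1:L] == 1L, gp$m, gp$p)
    if (all(mg[is_maternal] == 1) && all(pg[!is_maternal] == 1)) {
      lethal <- lethal + 1L
    } else {
      key <- paste(c(mg, pg), collapse = "")
      surv[[key]] <- (if (is.null(surv[[key]])) 0L else surv[[key]]) + 1L
    }
  }
  counts <- unlist(as.list(surv))
  list(lethal = lethal, total = nrow(sel), survivors = counts)
}

# Independent derivation of the theoretical F2 abortion-rate class
# distribution for 1 maternal x p paternal loci (selfer tester): the F1
# is heterozygous at every locus, so its gametes are all 2^L binary
# vectors; enumerate all ordered F2 gamete-pair origins, drop the lethal
# combination, and classify each survivor by the fraction of its pollen
# carrying the full paternal complement.
oracle_f2_classes <- function(n_maternal, n_paternal,
                              conditioned = TRUE) {
  L <- n_maternal + n_paternal
  is_mat <- c(rep(TRUE, n_maternal), rep(FALSE, n_paternal))
  haps <- as.matrix(expand.grid(rep(list(0:1), L)))
  acc <- new.env(parent = emptyenv())
  kept <- 0L
  for (i in seq_len(nrow(haps))) for (j in seq_len(nrow(haps))) {
    mg <- haps[i, ]
    pg <- haps[j, ]
    if (conditioned && all(mg[is_mat] == 1) && all(pg[!is_mat] == 1)) next
    kept <- kept + 1L
    # donor pollen: per paternal locus, P(incompatible allele) = mean of
    # the two copies; the full complement needs all simultaneously
    q <- prod((mg[!is_mat] + pg[!is_mat]) / 2)
    key <- format(q, digits = 15)
    acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) + 1L
  }
  counts <- unlist(as.list(acc))
  cls <- as.numeric(names(counts))
  o <- order(cls)
  list(class = cls[o], count = unname(counts[o]), total = kept)
}

# closed-form per-locus single-seed-descent fixation probability of an
# allele starting heterozygous, after g generations, no selection
oracle_ssd_fixation <- function(g) rat(2^g - 1, 2^(g + 1))

# direct maximum-binomial-likelihood class assignment (tie -> smaller)
oracle_assign <- function(k, n, classes, epsilon) {
  eff <- classes * (1 - epsilon) + (1 - classes) * epsilon
  lik <- vapply(eff, function(p) dbinom(k, n, p), numeric(1))
  classes[which.max(lik)]  # which.max takes the first (smallest class) on ties
}

# random raw genotype + matching package genotype under a model
random_genotype <- function(model) {
  m <- sample(0:1, model$n_loci, replace = TRUE)
  p <- sample(0:1, model$n_loci, replace = TRUE)
  list(raw = list(m = m, p = p), pkg = genotype(m, p, model))
}

# package survivor table keyed like the oracle's
pkg_survivor_counts <- function(outcome) {
  list(keys = apply(outcome$survivors$geno, 1, paste, collapse = ""),
       freq = outcome$survivors$freq)
}
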