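#' Define a multilocus incompatibility model
#'
#' A Bateson-Dobzhansky-Muller (BDM) seed-lethality model for a cross
#' between a selfing species and an outcrossing species. The model has
#' `n_maternal` maternal-incompatibility loci and `n_paternal`
#' paternal-incompatibility loci, all unlinked. A seed dies if and only if
#' its maternally inherited gamete carries the incompatible allele at
#' *every* maternal locus and its paternally inherited gamete carries the
#' incompatible allele at *every* paternal locus (see [seed_fate()]). The
#' incompatible allele is the selfer-origin allele at maternal loci (the
#' "R" allele of the selfer) and the outcrosser-origin allele at paternal
#' loci (the "A", "B", "C" alleles of the outcrosser); the lethality rule
#' itself is fixed, only the locus counts vary.
#'
#' Locus labels are single letters, maternal loci first. String renderings
#' of genotypes use the upper-case letter for the incompatible allele and
#' the lower-case letter for the compatible one.
#'
#' @param n_maternal number of maternal-incompatibility loci (>= 1).
#' @param n_paternal number of paternal-incompatibility loci (>= 1).
#' @param labels optional character vector of single-letter locus labels,
#'   maternal loci first; defaults to `R`, `S`, ... for maternal loci and
#'   `A`, `B`, `C`, ... for paternal loci.
#' @return An object of class `"bdm_model"` with components `n_maternal`,
#'   `n_paternal`, `n_loci`, `labels` and the logical vector `is_maternal`.
#' @examples
#' bdm_model(1, 3)   # one maternal locus R, three paternal loci A, B, C
#' bdm_model(1, 2)
#' @export
bdm_model <- function(n_maternal = 1, n_paternal = 3, labels = NULL) {
  if (!is.numeric(n_maternal) || length(n_maternal) != 1L ||
      n_maternal != trunc(n_maternal) || n_maternal < 1)
    .cfg_err("n_maternal must be a single integer >= 1")
  if (!is.numeric(n_paternal) || length(n_paternal) != 1L ||
      n_paternal != trunc(n_paternal) || n_paternal < 1)
    .cfg_err("n_paternal must be a single integer >= 1")
  n_maternal <- as.integer(n_maternal)
  n_paternal <- as.integer(n_paternal)
  n_loci <- n_maternal + n_paternal
  if (n_loci > 8L)
    .cfg_err("at most 8 loci are supported (exact enumeration model)")
  if (is.null(labels))
    labels <- c(c("R", "S", "T", "U", "V")[seq_len(n_maternal)],
                LETTERS[seq_len(n_paternal)])
  labels <- as.character(labels)
  if (length(labels) != n_loci || any(nchar(labels) != 1L) ||
      any(labels != toupper(labels)) || anyDuplicated(labels))
    .cfg_err("labels must be distinct single upper-case letters, one per locus")
  structure(
    list(n_maternal = n_maternal, n_paternal = n_paternal, n_loci = n_loci,
         labels = labels,
         is_maternal = c(rep(TRUE, n_maternal), rep(FALSE, n_paternal))),
    class = "bdm_model")
}

#' @export
print.bdm_model <- function(x, ...) {
  cat(sprintf("BDM seed-lethality model: %d maternal (%s) x %d paternal (%s) loci\n",
              x$n_maternal, paste(x$labels[x$is_maternal], collapse = ","),
              x$n_paternal, paste(x$labels[!x$is_maternal], collapse = ",")))
  cat(sprintf("lethal seed: maternal gamete %s + paternal gamete %s\n",
              paste(x$labels[x$is_maternal], collapse = ""),
              paste(x$labels[!x$is_maternal], collapse = "")))
  invisible(x)
}

# model signature used for internal caches
.model_key <- function(model) {
  paste0(model$n_maternal, "m", model$n_paternal, "p:",
         paste(model$labels, collapse = ""))
}

#' Construct an ordered diploid genotype
#'
#' A genotype records, for every locus of the model, the maternally and the
#' paternally inherited allele, coded 1 for the incompatible allele and 0
#' for the compatible one. The parental origin of each allele is kept
#' because seed fate is parent-of-origin dependent: the same unordered
#' genotype can behave differently as seed parent and as pollen donor.
#'
#' @param maternal,paternal 0/1 vectors of length `model$n_loci`: the
#'   alleles inherited from the seed parent and from the pollen parent
#'   (1 = incompatible allele).
#' @param model a [bdm_model()].
#' @return An object of class `"bdm_genotype"`: an integer matrix with rows
#'   `maternal` and `paternal` and one column per locus.
#' @seealso [parse_genotype()] for the string form, [selfer_genotype()],
#'   [outcrosser_genotype()], [f1_genotype()] for the standard genotypes.
#' @examples
#' m <- bdm_model(1, 3)
#' genotype(c(1, 0, 0, 0), c(0, 1, 1, 1), m)  # Ra|aAbBcC-type hybrid
#' @export
genotype <- function(maternal, paternal, model) {
  if (length(maternal) != model$n_loci || length(paternal) != model$n_loci)
    .cfg_err(sprintf("genotype must have %d loci to match the model",
                     model$n_loci))
  if (!all(c(maternal, paternal) %in% c(0, 1)))
    .cfg_err("alleles must be coded 0 (compatible) or 1 (incompatible)")
  g <- rbind(maternal = as.integer(maternal), paternal = as.integer(paternal))
  colnames(g) <- model$labels
  class(g) <- c("bdm_genotype", class(g))
  g
}

#' Parse a genotype string
#'
#' Genotype strings use a maternal-block `|` paternal-block dialect, e.g.
#' `"Rr|AaBbCc"` under the default 1x3 model: the first block covers the
#' maternal-incompatibility loci, the second the paternal-incompatibility
#' loci. Within each locus the maternally inherited allele is written
#' first, and the upper-case letter denotes the incompatible allele (so
#' `"Rr"` is maternal R, paternal r, while `"rR"` is the reverse).
#' Whitespace is ignored.
#'
#' @param x a genotype string such as `"Rr|AaBbCc"`.
#' @param model a [bdm_model()].
#' @return A [genotype()] object.
#' @examples
#' m <- bdm_model(1, 3)
#' parse_genotype("Rr|AaBbCc", m)
#' format(parse_genotype(" rR | aA Bb cC ", m))
#' @export
parse_genotype <- function(x, model) {
  if (!is.character(x) || length(x) != 1L)
    .data_err("genotype must be a single string")
  s <- gsub("[[:space:]]", "", x)
  blocks <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (length(blocks) != 2L)
    .data_err(sprintf("malformed genotype string '%s': expected one '|'", x))
  widths <- c(2L * model$n_maternal, 2L * model$n_paternal)
  if (any(nchar(blocks) != widths))
    .data_err(sprintf(
      "malformed genotype string '%s': blocks must have %d and %d letters",
      x, widths[1], widths[2]))
  chars <- strsplit(paste0(blocks, collapse = ""), "")[[1]]
  mat_chr <- chars[seq(1, length(chars), by = 2)]
  pat_chr <- chars[seq(2, length(chars), by = 2)]
  for (i in seq_len(model$n_loci)) {
    lab <- model$labels[i]
    ok <- c(lab, tolower(lab))
    if (!(mat_chr[i] %in% ok) || !(pat_chr[i] %in% ok))
      .data_err(sprintf(
        "malformed genotype string '%s': locus %d must use letter '%s'",
        x, i, lab))
  }
  genotype(as.integer(mat_chr == model$labels),
           as.integer(pat_chr == model$labels), model)
}

#' Render a genotype as a string
#'
#' Inverse of [parse_genotype()]: upper case marks the incompatible allele,
#' the maternally inherited allele is written first within each locus, and
#' `|` separates the maternal-locus block from the paternal-locus block.
#'
#' @param g a [genotype()].
#' @param model the [bdm_model()] the genotype belongs to.
#' @return A single string, e.g. `"rR|AaBbCc"`.
#' @export
format_genotype <- function(g, model) {
  .check_genotype(g, model)
  chr <- function(bit, lab) ifelse(bit == 1L, lab, tolower(lab))
  per_locus <- paste0(chr(g["maternal", ], model$labels),
                      chr(g["paternal", ], model$labels))
  paste0(paste(per_locus[model$is_maternal], collapse = ""), "|",
         paste(per_locus[!model$is_maternal], collapse = ""))
}

#' @export
print.bdm_genotype <- function(x, ...) {
  cat("ordered genotype (1 = incompatible allele):\n")
  print(unclass(x))
  invisible(x)
}

.check_genotype <- function(g, model) {
  if (!inherits(g, "bdm_genotype") || ncol(g) != model$n_loci)
    .cfg_err(sprintf("genotype does not match the %d-locus model", model$n_loci))
  invisible(g)
}

.check_haplotype <- function(h, model) {
  if (length(h) != model$n_loci || !all(h %in% c(0, 1)))
    .cfg_err(sprintf("haplotype must be a 0/1 vector of length %d",
                     model$n_loci))
  invisible(h)
}

#' Standard genotypes of the crossing scheme
#'
#' `selfer_genotype()` is the pure selfing species: homozygous for the
#' incompatible allele at every maternal locus (`RR`) and for the
#' compatible allele at every paternal locus (`aabbcc`).
#' `outcrosser_genotype()` is the pure outcrossing species: `rr|AABBCC`.
#' `f1_genotype()` is the viable interspecies F1, produced by the
#' outcrosser as seed parent pollinated by the selfer (the only direction
#' the barrier lets through); it is heterozygous at every locus, with the
#' maternally inherited allele coming from the outcrosser.
#'
#' @param model a [bdm_model()].
#' @return A [genotype()].
#' @examples
#' m <- bdm_model(1, 3)
#' format_genotype(selfer_genotype(m), m)      # "RR|aabbcc"
#' format_genotype(outcrosser_genotype(m), m)  # "rr|AABBCC"
#' format_genotype(f1_genotype(m), m)          # "rR|AaBbCc"
#' @export
selfer_genotype <- function(model) {
  h <- as.integer(model$is_maternal)
  genotype(h, h, model)
}

#' @rdname selfer_genotype
#' @export
outcrosser_genotype <- function(model) {
  h <- as.integer(!model$is_maternal)
  genotype(h, h, model)
}

#' @rdname selfer_genotype
#' @export
f1_genotype <- function(model) {
  genotype(as.integer(!model$is_maternal), as.integer(model$is_maternal),
           model)
}

#' Enumerate the gametes of a genotype
#'
#' Mendelian segregation with free recombination among all loci: each
#' heterozygous locus transmits either allele with probability 1/2,
#' independently across loci, so a genotype heterozygous at `h` loci
#' produces `2^h` equiprobable gametes. Probabilities are exact rationals.
#'
#' @param g a [genotype()].
#' @param model a [bdm_model()].
#' @return An object of class `"gamete_distribution"`: a list with
#'   `haplotypes` (0/1 matrix, one row per gamete, 1 = incompatible allele)
#'   and `prob` (a [rat()] vector summing to exactly 1).
#' @examples
#' m <- bdm_model(1, 3)
#' enumerate_gametes(f1_genotype(m), m)          # 16 gametes, each 1/16
#' enumerate_gametes(selfer_genotype(m), m)      # a single gamete
#' @export
enumerate_gametes <- function(g, model) {
  .check_genotype(g, model)
  choices <- lapply(seq_len(model$n_loci), function(i) unique(g[, i]))
  hap <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  dimnames(hap) <- list(NULL, model$labels)
  structure(
    list(haplotypes = hap, prob = rep(rat(1, nrow(hap)), nrow(hap))),
    class = "gamete_distribution")
}

#' @export
print.gamete_distribution <- function(x, ...) {
  cat(sprintf("%d equiprobable gametes (probability %s each)\n",
              nrow(x$haplotypes), format(x$prob[1])))
  print(x$haplotypes)
  invisible(x)
}

#' Fate of a seed from an ordered gamete pair
#'
#' The BDM lethality rule: a seed is lethal if and only if its maternally
#' inherited gamete carries the incompatible (selfer-origin) allele at
#' every maternal-incompatibility locus *and* its paternally inherited
#' gamete carries the incompatible (outcrosser-origin) allele at every
#' paternal-incompatibility locus. The rule is parent-of-origin aware:
#' swapping the two gametes can change the fate, which is what makes the
#' species barrier non-reciprocal.
#'
#' @param maternal_gamete,paternal_gamete 0/1 haplotype vectors of length
#'   `model$n_loci` (1 = incompatible allele), as rows of
#'   [enumerate_gametes()] output.
#' @param model a [bdm_model()].
#' @return `"lethal"` or `"viable"`.
#' @examples
#' m <- bdm_model(1, 3)
#' seed_fate(c(1, 0, 0, 0), c(0, 1, 1, 1), m)  # R egg + ABC pollen: lethal
#' seed_fate(c(0, 1, 1, 1), c(1, 0, 0, 0), m)  # reciprocal pair: viable
#' @export
seed_fate <- function(maternal_gamete, paternal_gamete, model) {
  .check_haplotype(maternal_gamete, model)
  .check_haplotype(paternal_gamete, model)
  lethal <- all(maternal_gamete[model$is_maternal] == 1) &&
    all(paternal_gamete[!model$is_maternal] == 1)
  if (lethal) "lethal" else "viable"
}

# vectorised lethality over gamete matrices (rows = gametes); used by the
# cross engine
.lethal_maternal <- function(hap, model) {
  rowSums(hap[, model$is_maternal, drop = FALSE]) == model$n_maternal
}

.lethal_paternal <- function(hap, model) {
  rowSums(hap[, !model$is_maternal, drop = FALSE]) == model$n_paternal
}
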