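#' Chromosome pairing models for a duplex tetraploid
#'
#' The five classical single-locus models of chromosome pairing in a
#' tetraploid that is duplex at a marker locus (genotype AAaa, i.e. two
#' alleles from each of the two subgenomes, G and N). Each model fixes the
#' expected ratio of the three gamete classes AA : Aa : aa produced by the
#' F1 hybrid.
#'
#' The models and their exact gametic ratios are:
#' \describe{
#'   \item{\code{homolog-disomic}}{Homolog-homolog pairing (autosyndesis),
#'     disomic inheritance: 0 AA : 1 Aa : 0 aa. Every gamete carries one
#'     allele from each subgenome ("fixed heterozygosity").}
#'   \item{\code{homeolog-disomic}}{Homolog-homeolog pairing (allosyndesis),
#'     disomic: 1 AA : 2 Aa : 1 aa.}
#'   \item{\code{random-chromosome}}{Random chromosome (random bivalent)
#'     assortment: 1 AA : 4 Aa : 1 aa.}
#'   \item{\code{random-chromatid}}{Random chromatid assortment (double
#'     reduction permitted): 3 AA : 8 Aa : 3 aa.}
#'   \item{\code{max-equational}}{Maximal equational segregation:
#'     2 AA : 5 Aa : 2 aa.}
#' }
#'
#' @param model Model name, one of the five names above (partial matching
#'   is not performed; the name must be given in full).
#' @return For `pairing_model()`, an object of class `"pairing_model"`: a
#'   list with elements `name`, `label`, `inheritance`, `ratio` (integer
#'   numerators for AA/Aa/aa) and `den` (their sum).
#' @examples
#' pairing_model("random-chromosome")
#' gamete_ratios("random-chromatid")
#' @export
pairing_model <- function(model) {
  spec <- .pairing_model_specs[[match_pairing_model(model)]]
  structure(spec, class = "pairing_model")
}

# Exact integer gametic ratios (AA, Aa, aa) per model.
.pairing_model_specs <- list(
  "homolog-disomic" = list(
    name = "homolog-disomic",
    label = "Homolog-homolog (autosyndesis)",
    inheritance = "disomic",
    ratio = c(AA = 0L, Aa = 1L, aa = 0L), den = 1L),
  "homeolog-disomic" = list(
    name = "homeolog-disomic",
    label = "Homolog-homeolog (allosyndesis)",
    inheritance = "disomic",
    ratio = c(AA = 1L, Aa = 2L, aa = 1L), den = 4L),
  "random-chromosome" = list(
    name = "random-chromosome",
    label = "Random chromosome assortment",
    inheritance = "disomic or tetrasomic",
    ratio = c(AA = 1L, Aa = 4L, aa = 1L), den = 6L),
  "random-chromatid" = list(
    name = "random-chromatid",
    label = "Random chromatid assortment",
    inheritance = "tetrasomic",
    ratio = c(AA = 3L, Aa = 8L, aa = 3L), den = 14L),
  "max-equational" = list(
    name = "max-equational",
    label = "Maximal equational segregation",
    inheritance = "tetrasomic",
    ratio = c(AA = 2L, Aa = 5L, aa = 2L), den = 9L)
)

#' @rdname pairing_model
#' @export
pairing_model_names <- function() names(.pairing_model_specs)

match_pairing_model <- function(model) {
  if (inherits(model, "pairing_model")) return(model$name)
  if (!is.character(model) || length(model) != 1L ||
      !model %in% names(.pairing_model_specs)) {
    stop("unknown pairing model ", deparse(model), "; must be one of: ",
         paste(names(.pairing_model_specs), collapse = ", "), call. = FALSE)
  }
  model
}

#' @export
print.pairing_model <- function(x, ...) {
  cat(x$label, " [", x$name, "], ", x$inheritance, " inheritance\n", sep = "")
  cat("  gametic ratio ", paste(x$ratio, collapse = ":"),
      " (AA:Aa:aa) / ", x$den, "\n", sep = "")
  invisible(x)
}

#' @rdname pairing_model
#' @return For `gamete_ratios()`, a named numeric vector of gamete-class
#'   probabilities `c(AA=, Aa=, aa=)` summing to 1, with the exact integer
#'   ratio attached as attributes `num` and `den`.
#' @export
gamete_ratios <- function(model) {
  m <- pairing_model(model)
  gamete_dist(m$ratio, m$den)
}

gamete_dist <- function(num, den) {
  stopifnot(sum(num) == den)
  structure(as.numeric(num) / den, names = c("AA", "Aa", "aa"),
            num = as.integer(num), den = as.integer(den))
}

check_gamete_dist <- function(g) {
  if (length(g) != 3L || any(g < 0) || abs(sum(g) - 1) > 1e-12)
    stop("gamete-class distribution must be 3 nonnegative frequencies summing to 1",
         call. = FALSE)
  invisible(g)
}

#' Progeny genotype frequencies from gamete-class distributions
#'
#' Convolves maternal and paternal gamete-class distributions (AA = 2, Aa =
#' 1, aa = 0 doses of the A allele) into the five zygotic dosage classes
#' AAAA, AAAa, AAaa, Aaaa, aaaa. A selfed (F2) design passes the same
#' distribution on both sides; a backcross to a quadruple-recessive tester
#' passes `c(0, 0, 1)` on the paternal side.
#'
#' @param gametes_maternal,gametes_paternal Numeric length-3 gamete-class
#'   distributions (AA, Aa, aa) summing to 1. `gametes_paternal` defaults to
#'   the maternal distribution (selfing).
#' @return Named numeric vector of length 5 (`AAAA`, `AAAa`, `AAaa`,
#'   `Aaaa`, `aaaa`) summing to 1.
#' @examples
#' g <- gamete_ratios("random-chromosome")
#' progeny_genotype_frequencies(g)               # selfed: (1,8,18,8,1)/36
#' progeny_genotype_frequencies(g, c(0, 0, 1))   # backcross: (0,0,1,4,1)/6
#' @export
progeny_genotype_frequencies <- function(gametes_maternal,
                                         gametes_paternal = gametes_maternal) {
  check_gamete_dist(gametes_maternal)
  check_gamete_dist(gametes_paternal)
  dose <- c(2L, 1L, 0L)
  f <- numeric(5L)                      # index = dose + 1
  for (i in 1:3) for (j in 1:3) {
    d <- dose[i] + dose[j]
    f[d + 1L] <- f[d + 1L] + gametes_maternal[i] * gametes_paternal[j]
  }
  stats::setNames(rev(f), c("AAAA", "AAAa", "AAaa", "Aaaa", "aaaa"))
}

#' Expected apparent heterozygosity of a progeny class
#'
#' Apparent heterozygosity is the proportion of progeny displaying a marker
#' band from each parent, regardless of allele dosage: any individual with
#' at least one A and one a allele (doses 1-3) scores as heterozygous.
#' Under a selfed (F2) design both quadruple-homozygote classes (AAAA and
#' aaaa) are excluded; under a backcross to the recessive tester only aaaa
#' is reachable.
#'
#' @param genotypes Named numeric length-5 genotype distribution as
#'   returned by [progeny_genotype_frequencies()], or a pairing-model name,
#'   in which case the distribution for `design` is derived first.
#' @param design `"self"` (F2) or `"backcross"` (to the aaaa tester).
#' @return Expected proportion of apparently heterozygous progeny.
#' @examples
#' expected_apparent_heterozygosity("random-chromosome", "self")       # 34/36
#' expected_apparent_heterozygosity("max-equational", "backcross")     # 7/9
#' @export
expected_apparent_heterozygosity <- function(genotypes, design = c("self", "backcross")) {
  design <- match.arg(design)
  if (is.character(genotypes) && length(genotypes) == 1L) {
    g <- gamete_ratios(genotypes)
    genotypes <- if (design == "self") progeny_genotype_frequencies(g)
                 else progeny_genotype_frequencies(g, c(0, 0, 1))
  }
  if (length(genotypes) != 5L || any(genotypes < 0) ||
      abs(sum(genotypes) - 1) > 1e-12)
    stop("genotype distribution must be 5 nonnegative frequencies summing to 1",
         call. = FALSE)
  if (design == "self") 1 - genotypes[[1L]] - genotypes[[5L]]
  else 1 - genotypes[[5L]]
}

#' Enumeration oracles for random chromosome and random chromatid assortment
#'
#' Independent brute-force derivations of the gametic ratios that the named
#' pairing models assert. `enumerate_random_chromosome()` enumerates the 3
#' partitions of the four chromosomes \{G1, G2, N1, N2\} into two bivalents,
#' each bivalent contributing one chromosome per gamete with equal
#' probability. `enumerate_random_chromatid()` enumerates unordered pairs
#' drawn from the 8 chromatids (two sister chromatids per chromosome; four
#' carry A, four carry a); retaining sister pairs permits double reduction.
#'
#' @param partitions Which bivalent partitions to enumerate: `"all"` (the
#'   random-chromosome model), `"homolog"` (G1-G2 and N1-N2 only; strictly
#'   homologous pairing) or `"homeolog"` (the two cross-subgenome
#'   partitions; homeolog-disomic pairing).
#' @param sister_pairs Allow gametes made of two sister chromatids of the
#'   same chromosome (double reduction). With `FALSE` the enumeration
#'   collapses to the random-chromosome ratio.
#' @return Gamete-class distribution `c(AA=, Aa=, aa=)` with exact integer
#'   ratio in attributes `num`/`den`.
#' @examples
#' enumerate_random_chromosome()                  # 1:4:1
#' enumerate_random_chromatid()                   # 3:8:3
#' enumerate_random_chromatid(sister_pairs = FALSE)  # 1:4:1
#' @export
enumerate_random_chromosome <- function(partitions = c("all", "homolog", "homeolog")) {
  partitions <- match.arg(partitions)
  chrom <- c("G1", "G2", "N1", "N2")   # G carries A, N carries a
  # all 3 perfect matchings of 4 chromosomes into two bivalents
  matchings <- list(
    list(c("G1", "G2"), c("N1", "N2")),  # homologous
    list(c("G1", "N1"), c("G2", "N2")),  # homeologous
    list(c("G1", "N2"), c("G2", "N1")))  # homeologous
  keep <- switch(partitions, all = 1:3, homolog = 1L, homeolog = 2:3)
  counts <- c(AA = 0L, Aa = 0L, aa = 0L)
  for (m in matchings[keep]) {
    for (i in 1:2) for (j in 1:2) {      # one chromosome from each bivalent
      gam <- c(m[[1L]][i], m[[2L]][j])
      a_dose <- sum(substr(gam, 1L, 1L) == "G")
      counts[3L - a_dose] <- counts[3L - a_dose] + 1L
    }
  }
  reduce_gamete_counts(counts)
}

reduce_gamete_counts <- function(counts) {
  d <- sum(counts)
  g <- Reduce(gcd3, c(counts[counts > 0L], d))
  gamete_dist(counts %/% g, d %/% g)
}

#' @rdname enumerate_random_chromosome
#' @export
enumerate_random_chromatid <- function(sister_pairs = TRUE) {
  chromatids <- rep(c("G1", "G2", "N1", "N2"), each = 2L)
  idx <- utils::combn(8L, 2L)
  counts <- c(AA = 0L, Aa = 0L, aa = 0L)
  for (k in seq_len(ncol(idx))) {
    pair <- chromatids[idx[, k]]
    if (!sister_pairs && pair[1L] == pair[2L]) next
    a_dose <- sum(substr(pair, 1L, 1L) == "G")
    counts[3L - a_dose] <- counts[3L - a_dose] + 1L
  }
  reduce_gamete_counts(counts)
}

gcd3 <- function(a, b) if (b == 0L) a else gcd3(b, a %% b)

#' Summary table of the five pairing models
#'
#' One row per pairing model: gametic ratio, F2 and backcross genotype
#' frequencies, and expected apparent heterozygosity under both designs.
#'
#' @param digits Number of decimal places for the heterozygosity columns.
#' @return A data frame with columns `model`, `inheritance`,
#'   `gametic_ratio`, `f2_genotypes`, `bc1_genotypes`, `het_f2`, `het_bc1`.
#' @export
pairing_model_table <- function(digits = 2L) {
  rows <- lapply(pairing_model_names(), function(nm) {
    m <- pairing_model(nm)
    g <- gamete_ratios(nm)
    f2 <- progeny_genotype_frequencies(g)
    bc <- progeny_genotype_frequencies(g, c(0, 0, 1))
    den2 <- m$den^2
    f2n <- as.integer(round(f2 * den2))
    bcn <- as.integer(round(bc * m$den))
    data.frame(
      model = nm, inheritance = m$inheritance,
      gametic_ratio = paste(m$ratio, collapse = ":"),
      f2_genotypes = paste(f2n, collapse = ":"),
      bc1_genotypes = paste(bcn[3:5], collapse = ":"),
      het_f2 = round(expected_apparent_heterozygosity(f2, "self"), digits),
      het_bc1 = round(expected_apparent_heterozygosity(bc, "backcross"), digits),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
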