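# Tetraploid genotypes are character vectors (or n x 4 matrices) of allele
# tags: subgenome letter ("G" or "N") followed by founder copy index, e.g.
# c("G1", "G2", "N1", "N2") for the duplex F1. Tags are preserved through
# simulated meioses so double-reduction and homeolog-derived gametes remain
# identifiable.

#' The duplex F1 allotetraploid genotype
#'
#' @return Character vector `c("G1", "G2", "N1", "N2")`.
#' @export
founder_duplex <- function() c("G1", "G2", "N1", "N2")

#' The quadruple-recessive tester genotype
#'
#' @return Character vector `c("N1", "N2", "N1", "N2")` (the
#'   neoautotetraploid recurrent parent carries only N-subgenome alleles).
#' @export
founder_tester <- function() c("N1", "N2", "N1", "N2")

subgenome_of <- function(tags) substr(tags, 1L, 1L)

#' Simulate gametes of a tetraploid parent
#'
#' For a parent with two alleles from each subgenome (the duplex case),
#' gamete classes GN, GG and NN are drawn from the preferential-pairing
#' model frequencies: GN at [wu_gn_frequency()]`(p, alpha)` and GG/NN at
#' equal shares of the remainder. Within the GG (or NN) class, the
#' double-reduction share [wu_dr_frequency()] is realised as sister-allele
#' pairs (e.g. G1G1), the rest as the two distinct homeolog-derived copies
#' (G1G2); within the GN class the four tag combinations are uniform. For
#' parents with an unbalanced subgenome composition (3+1 or 4+0, which
#' arise in selfed lineages after homeologous segregation) gametes are two
#' distinct chromosomes drawn uniformly (random chromosome assortment).
#'
#' @param parent Character vector of 4 allele tags.
#' @param p Preferential pairing factor in \eqn{[0, 2/3]}.
#' @param alpha Double reduction rate.
#' @param n Number of gametes.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x 2` character matrix of allele tags.
#' @examples
#' g <- simulate_gametes(founder_duplex(), p = 0.54, n = 10, seed = 1)
#' @export
simulate_gametes <- function(parent, p, alpha = 0, n, seed = NULL) {
  check_wu_params(p, alpha)
  stopifnot(length(parent) == 4L)
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(matrix(character(0), 0L, 2L))
  sub <- subgenome_of(parent)
  g_slots <- parent[sub == "G"]
  n_slots <- parent[sub == "N"]
  if (length(g_slots) != 2L || length(n_slots) != 2L) {
    # unbalanced composition: random chromosome assortment over the 4 slots
    pick <- replicate(n, sample.int(4L, 2L))
    return(cbind(parent[pick[1L, ]], parent[pick[2L, ]]))
  }
  f_gn <- wu_gn_frequency(p, alpha)
  f_dr <- wu_dr_frequency(p, alpha)
  cls <- sample.int(3L, n, replace = TRUE,
                    prob = c(f_gn, (1 - f_gn) / 2, (1 - f_gn) / 2))
  out <- matrix(NA_character_, n, 2L)
  i_gn <- which(cls == 1L)
  if (length(i_gn))
    out[i_gn, ] <- cbind(sample(g_slots, length(i_gn), replace = TRUE),
                         sample(n_slots, length(i_gn), replace = TRUE))
  for (k in 2:3) {
    idx <- which(cls == k)
    if (!length(idx)) next
    slots <- if (k == 2L) g_slots else n_slots
    # within-class split: sister pairs carry the double-reduction share
    pr_sister <- if (1 - f_gn > 0) (f_dr / 2) / ((1 - f_gn) / 2) else 0
    sister <- stats::runif(length(idx)) < pr_sister
    same <- sample(slots, length(idx), replace = TRUE)
    out[idx, ] <- cbind(ifelse(sister, same, slots[1L]),
                        ifelse(sister, same, slots[2L]))
  }
  out
}

#' Simulate a cross between two tetraploid parents
#'
#' Offspring are formed from independent gamete draws from each parent
#' under the same pairing parameters. The quadruple-recessive tester
#' (all-N) always contributes NN gametes.
#'
#' @param maternal,paternal Parent genotypes (length-4 tag vectors).
#' @param p,alpha Pairing parameters, as in [simulate_gametes()].
#' @param n_offspring Number of offspring.
#' @param seed Optional integer seed.
#' @return An `n_offspring x 4` character matrix of allele tags
#'   (maternal-gamete alleles in columns 1-2).
#' @examples
#' off <- simulate_cross(founder_duplex(), founder_tester(),
#'                       p = 0.54, n_offspring = 48, seed = 1)
#' @export
simulate_cross <- function(maternal, paternal, p, alpha = 0, n_offspring,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm <- simulate_gametes(maternal, p, alpha, n_offspring)
  gp <- simulate_gametes(paternal, p, alpha, n_offspring)
  cbind(gm, gp)
}

#' Design of a selfed-lineage (S-line) experiment
#'
#' Describes the crossing design the simulator reproduces: independent
#' family lines founded by duplex F1 individuals, advanced by single-seed
#' descent selfing, split into maternal lines (subfamilies) at the
#' penultimate generation, with a fixed number of measured individuals per
#' maternal line in the final generation.
#'
#' @param generations_of_selfing Number of selfing generations (founders
#'   are generation "S1"; the default 3 yields measured "S4" progeny).
#' @param n_families Number of independent family lines (default 48).
#' @param maternal_lines_per_family Subfamilies split off at the
#'   penultimate generation (default 2).
#' @param individuals_per_maternal_line Measured final-generation
#'   individuals per maternal line (default 3).
#' @param n_loci Number of independently segregating marker loci
#'   (default 13, one per linkage group).
#' @param cross_direction Label recording the maternal progenitor of the
#'   founding cross (`"G"` or `"N"`); carried through to output labels.
#' @return A list of class `"lineage_design"`.
#' @export
lineage_design <- function(generations_of_selfing = 3L,
                           n_families = 48L,
                           maternal_lines_per_family = 2L,
                           individuals_per_maternal_line = 3L,
                           n_loci = 13L,
                           cross_direction = c("G", "N")) {
  cross_direction <- match.arg(cross_direction)
  d <- list(generations_of_selfing = as.integer(generations_of_selfing),
            n_families = as.integer(n_families),
            maternal_lines_per_family = as.integer(maternal_lines_per_family),
            individuals_per_maternal_line = as.integer(individuals_per_maternal_line),
            n_loci = as.integer(n_loci),
            cross_direction = cross_direction)
  if (any(unlist(d[1:5]) < 0) || any(unlist(d[2:5]) < 1))
    stop("design counts must be positive (generations may be 0)", call. = FALSE)
  structure(d, class = "lineage_design")
}

self_once <- function(geno_row, p, alpha, n_offspring = 1L) {
  simulate_cross(geno_row, geno_row, p, alpha, n_offspring)
}

#' Simulate selfed lineages under the crossing design
#'
#' Founds `n_families` duplex F1 family lines and advances each by
#' single-seed-descent selfing for the designed number of generations; at
#' the penultimate generation each line is split into maternal lines, and
#' in the final generation each maternal line contributes the designed
#' number of measured individuals. All loci segregate independently under
#' the same pairing parameters.
#'
#' @param design A [lineage_design()].
#' @param p,alpha Pairing parameters.
#' @param seed Optional integer seed.
#' @return A long data frame with one row per individual per locus:
#'   columns `generation` (e.g. `"S4"`), `family`, `maternal_line`,
#'   `individual`, `locus`, `a1`-`a4` (allele tags), `g_dose` (number of
#'   G-subgenome alleles, 0-4) and `het` (both subgenomes present).
#'   Earlier generations are included with `maternal_line = NA`.
#' @examples
#' d <- lineage_design(generations_of_selfing = 2, n_families = 4, n_loci = 2)
#' sim <- simulate_lineages(d, p = 0.5, seed = 1)
#' @export
simulate_lineages <- function(design, p, alpha = 0, seed = NULL) {
  stopifnot(inherits(design, "lineage_design"))
  if (!is.null(seed)) set.seed(seed)
  G <- design$generations_of_selfing
  nf <- design$n_families
  nl <- design$n_loci
  gen_label <- function(g) paste0("S", g + 1L)

  # current population: list over loci of (individual x 4) tag matrices,
  # plus bookkeeping of family/maternal ids per individual row
  pop <- replicate(nl, matrix(rep(founder_duplex(), each = nf), nf, 4L),
                   simplify = FALSE)
  fam <- seq_len(nf)
  mat <- rep(NA_integer_, nf)
  rows <- list(pop_to_rows(pop, gen_label(0L), fam, mat, design))

  if (G >= 1L) for (g in seq_len(G)) {
    last <- g == G
    penult <- g == G - 1L && G >= 2L
    n_off <- if (last && G >= 2L) design$individuals_per_maternal_line
             else if (penult) design$maternal_lines_per_family
             else if (last) design$maternal_lines_per_family *
                            design$individuals_per_maternal_line
             else 1L
    new_pop <- replicate(nl, vector("list", length(fam)), simplify = FALSE)
    for (i in seq_along(fam)) {
      for (l in seq_len(nl))
        new_pop[[l]][[i]] <- self_once(pop[[l]][i, ], p, alpha, n_off)
    }
    pop <- lapply(new_pop, function(x) do.call(rbind, x))
    fam <- rep(fam, each = n_off)
    mat <- if (penult) stats::ave(fam, fam, FUN = seq_along)
           else rep(mat, each = n_off)
    rows[[length(rows) + 1L]] <- pop_to_rows(pop, gen_label(g), fam, mat, design)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pop_to_rows <- function(pop, gen, fam, mat, design) {
  n <- length(fam)
  do.call(rbind, lapply(seq_along(pop), function(l) {
    m <- pop[[l]]
    gd <- rowSums(matrix(subgenome_of(m) == "G", n, 4L))
    data.frame(generation = gen,
               family = paste0(design$cross_direction, fam),
               maternal_line = ifelse(is.na(mat), NA_character_,
                                      letters[mat]),
               individual = seq_len(n),
               locus = paste0("L", l),
               a1 = m[, 1L], a2 = m[, 2L], a3 = m[, 3L], a4 = m[, 4L],
               g_dose = gd, het = gd > 0L & gd < 4L,
               stringsAsFactors = FALSE)
  }))
}

#' Collapse tagged genotypes to marker calls
#'
#' Scores each individual at each locus as heterozygous (at least one
#' allele from each subgenome: a band from each parent) or as a band loss
#' (all four alleles from one subgenome, i.e. a quadruple homozygote), and
#' aggregates counts per locus.
#'
#' @param genotypes Either an `n x 4` character tag matrix (one locus) or
#'   a long data frame with columns `locus` and `a1`-`a4` (or `g_dose`) as
#'   produced by [simulate_lineages()].
#' @param marker_id Marker label used when `genotypes` is a matrix.
#' @param class_label Progeny class label for the output panel rows.
#' @return A `"marker_panel"` data frame with one row per locus:
#'   `n_scored`, `n_het`, `n_loss` (plus `n_loss_G` = all-N individuals
#'   and `n_loss_N` = all-G individuals).
#' @examples
#' off <- simulate_cross(founder_duplex(), founder_tester(),
#'                       p = 0.5, n_offspring = 100, seed = 2)
#' collapse_to_marker_calls(off)
#' @export
collapse_to_marker_calls <- function(genotypes, marker_id = "M1",
                                     class_label = "SIM") {
  if (is.matrix(genotypes)) {
    gd <- rowSums(matrix(subgenome_of(genotypes) == "G",
                         nrow(genotypes), 4L))
    df <- data.frame(locus = marker_id, g_dose = gd,
                     stringsAsFactors = FALSE)
  } else {
    df <- genotypes
    if (!"g_dose" %in% names(df))
      df$g_dose <- rowSums(subgenome_of(as.matrix(df[, c("a1", "a2", "a3", "a4")])) == "G")
  }
  agg <- lapply(split(df$g_dose, df$locus), function(gd) {
    data.frame(n_scored = length(gd),
               n_het = sum(gd > 0L & gd < 4L),
               n_loss = sum(gd == 0L | gd == 4L),
               n_loss_G = sum(gd == 0L),
               n_loss_N = sum(gd == 4L))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(marker_id = names(agg), arm_label = NA_character_,
                    class = class_label, out,
                    n_loss_excl = out$n_loss,
                    stringsAsFactors = FALSE, row.names = NULL)
  as_marker_panel(out)
}

#' Simulate a backcross marker panel
#'
#' Convenience wrapper: for each marker, crosses the duplex F1 to the
#' quadruple-recessive tester and collapses the offspring to
#' heterozygous/loss counts. Loss of the dominant-parent band occurs
#' exactly when the F1 transmits an NN gamete.
#'
#' @param n_progeny Scored progeny per marker.
#' @param n_markers Number of independent markers.
#' @param p,alpha Pairing parameters.
#' @param seed Optional integer seed.
#' @return A `"marker_panel"` data frame with `n_markers` rows of class
#'   `"BC1N"`.
#' @export
simulate_bc1_panel <- function(n_progeny, n_markers = 1L, p, alpha = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_markers), function(m) {
    off <- simulate_cross(founder_duplex(), founder_tester(), p, alpha,
                          n_progeny)
    collapse_to_marker_calls(off, marker_id = paste0("M", m),
                             class_label = "BC1N")
  })
  as_marker_panel(do.call(rbind, rows))
}

#' Phenotype model for simulated progeny
#'
#' Trait values are generated as
#' `mu + additive_effect * (G dose summed over loci) + dominance_effect *
#' (number of heterozygous loci) + family deviate + maternal deviate +
#' residual`, with deviates drawn independently from zero-mean normal
#' distributions at the stated variances. With strictly homologous pairing
#' every locus is permanently heterozygous and the genetic terms are
#' constant, so the genetic variance contribution is zero.
#'
#' @param mu Baseline trait value.
#' @param additive_effect Trait increment per G-subgenome allele.
#' @param dominance_effect Increment when a locus carries alleles from
#'   both subgenomes.
#' @param var_family,var_maternal,var_residual Variance components
#'   (\eqn{\ge 0}) for family, maternal-line-within-family, and residual
#'   deviates.
#' @param trait Trait name used in output.
#' @return A list of class `"phenotype_model"`.
#' @export
phenotype_model <- function(mu = 0, additive_effect = 0, dominance_effect = 0,
                            var_family = 0, var_maternal = 0,
                            var_residual = 1, trait = "trait") {
  if (var_family < 0 || var_maternal < 0 || var_residual < 0)
    stop("variance components must be nonnegative", call. = FALSE)
  structure(list(mu = mu, additive_effect = additive_effect,
                 dominance_effect = dominance_effect,
                 var_family = var_family, var_maternal = var_maternal,
                 var_residual = var_residual, trait = trait),
            class = "phenotype_model")
}

#' Simulate phenotypes for a genotyped population
#'
#' @param genotypes Long genotype data frame (one row per individual per
#'   locus) with columns `family`, `maternal_line`, `individual`,
#'   `g_dose`, `het` — typically one generation of
#'   [simulate_lineages()] output.
#' @param model A [phenotype_model()].
#' @param class_label Progeny class label for the records.
#' @param seed Optional integer seed.
#' @return A data frame with one row per individual: `class_label`,
#'   `family`, `maternal_line`, `individual` and the trait column.
#' @examples
#' d <- lineage_design(generations_of_selfing = 2, n_families = 6, n_loci = 3)
#' g <- simulate_lineages(d, p = 0.5, seed = 3)
#' s4 <- g[g$generation == "S3", ]
#' simulate_phenotypes(s4, phenotype_model(additive_effect = 0.5), seed = 4)
#' @export
simulate_phenotypes <- function(genotypes, model, class_label = "SIM",
                                seed = NULL) {
  stopifnot(inherits(model, "phenotype_model"))
  if (!is.null(seed)) set.seed(seed)
  ml <- genotypes$maternal_line
  ml <- ifelse(is.na(ml), "0", as.character(ml))   # pre-split generations
  key <- interaction(genotypes$family, ml, genotypes$individual, drop = TRUE)
  agg <- data.frame(
    family = tapply(genotypes$family, key, `[`, 1L),
    maternal_line = tapply(ml, key, `[`, 1L),
    individual = tapply(genotypes$individual, key, `[`, 1L),
    dose = as.numeric(tapply(genotypes$g_dose, key, sum)),
    n_het = as.numeric(tapply(genotypes$het, key, sum)),
    stringsAsFactors = FALSE)
  fam_ids <- unique(agg$family)
  b_fam <- stats::setNames(stats::rnorm(length(fam_ids), 0,
                                        sqrt(model$var_family)), fam_ids)
  mat_key <- paste(agg$family, agg$maternal_line)
  mat_ids <- unique(mat_key)
  b_mat <- stats::setNames(stats::rnorm(length(mat_ids), 0,
                                        sqrt(model$var_maternal)), mat_ids)
  value <- model$mu + model$additive_effect * agg$dose +
    model$dominance_effect * agg$n_het +
    b_fam[agg$family] + b_mat[mat_key] +
    stats::rnorm(nrow(agg), 0, sqrt(model$var_residual))
  out <- data.frame(class_label = class_label,
                    family = agg$family,
                    maternal_line = agg$maternal_line,
                    individual = agg$individual,
                    value = as.numeric(value),
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "value"] <- model$trait
  rownames(out) <- NULL
  out
}

#' Simulate a diploid heritability study
#'
#' Generates trait values for the four classes of a classical diploid
#' cross (P1, P2, F1, F2) at `n_loci` unlinked biallelic loci with
#' additive effect `a` and dominance `d` per locus: P1 is fixed for the
#' high allele, P2 for the low allele, F1 uniformly heterozygous and F2
#' doses binomial(2, 1/2). Only the F2 segregates, so the parental and F1
#' variances estimate the environmental variance.
#'
#' @param n_per_class Individuals per class.
#' @param n_loci Number of loci.
#' @param a Additive effect (half the homozygote difference per locus).
#' @param d Dominance effect per locus.
#' @param var_e Environmental (residual) variance.
#' @param seed Optional integer seed.
#' @return Data frame with columns `class_label` (`"P1"`, `"P2"`, `"F1"`,
#'   `"F2"`) and `trait`.
#' @export
simulate_diploid_f2 <- function(n_per_class = 300L, n_loci = 5L, a = 1,
                                d = 0, var_e = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_class <- function(cl, doses) {
    g <- matrix(doses, n_per_class, n_loci)
    geno <- a * (g - 1) + d * (g == 1L)
    data.frame(class_label = cl,
               trait = rowSums(geno) + stats::rnorm(n_per_class, 0, sqrt(var_e)),
               stringsAsFactors = FALSE)
  }
  f2_doses <- stats::rbinom(n_per_class * n_loci, 2L, 0.5)
  rbind(one_class("P1", 2L), one_class("P2", 0L), one_class("F1", 1L),
        one_class("F2", f2_doses))
}
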