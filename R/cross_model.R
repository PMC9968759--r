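# Deterministic enumeration of gamete and offspring genotype distributions
# for a single cross: germline cutting, maternal deposition, viability
# selection, expected drive inheritance and egg-to-adult viability.

#' Specify a cross
#'
#' @param mother,father [genotype()] objects; `mother` must be female and
#'   `father` male.
#' @return An object of class `"cross_spec"`.
#' @export
cross_spec <- function(mother, father) {
  stopifnot(inherits(mother, "drive_genotype"),
            inherits(father, "drive_genotype"))
  if (mother$sex != "female") stop("`mother` must be female", call. = FALSE)
  if (father$sex != "male") stop("`father` must be male", call. = FALSE)
  structure(list(mother = mother, father = father), class = "cross_spec")
}

# Per-allele transmission distribution over c(wt, r1, r2), conditional on
# whether germline cutting is active in this parent.  Conditional on a cut
# (prob c_germline), repair goes to r1 with p_hdr_functional (only when the
# rescue element can template HDR), back to wt with p_hdr_wt, else to r2.
.transmit_allele <- function(allele, cutting, params, arch) {
  p <- c(wt = 0, r1 = 0, r2 = 0)
  if (!cutting || allele != "wt") {
    p[allele] <- 1
    return(p)
  }
  cg <- params$c_germline
  p_r1 <- if (arch$rescue_is_hdr_template) params$p_hdr_functional else 0
  p["wt"] <- (1 - cg) + cg * params$p_hdr_wt
  p["r1"] <- cg * p_r1
  p["r2"] <- cg * (1 - p_r1 - params$p_hdr_wt)
  p
}

.mendel_half <- function(copies) {
  switch(copies + 1L,
         c(`0` = 1),
         c(`0` = 0.5, `1` = 0.5),
         c(`1` = 1))
}

#' Gamete distribution of a parent's germline
#'
#' Drive and Cas9 alleles segregate Mendelianly and independently of each
#' other and of the target.  Each transmitted wild-type target allele is,
#' in a parent carrying at least one drive and one Cas9 allele, modified
#' with probability `c_germline`; conditional on modification it becomes a
#' functional recoded `"r1"` allele with probability `p_hdr_functional`
#' (only if the architecture allows the rescue element to template HDR),
#' remains wild type with probability `p_hdr_wt`, and otherwise becomes a
#' disrupted `"r2"` allele.  Non-wild-type alleles transmit unchanged, as
#' do all alleles of parents lacking drive or Cas9.
#'
#' @param parent A [genotype()].
#' @param params A [rate_params()].
#' @param arch A [drive_architecture()].
#' @return A data frame with columns `drive` (0/1), `cas9` (0/1), `target`
#'   (allele code) and `prob`, containing only rows with positive
#'   probability; probabilities sum to 1.
#' @export
germline_gametes <- function(parent, params, arch) {
  stopifnot(inherits(parent, "drive_genotype"),
            inherits(params, "rate_params"),
            inherits(arch, "drive_architecture"))
  cutting <- parent$drive >= 1L && parent$cas9 >= 1L
  t1 <- .transmit_allele(parent$targets[1], cutting, params, arch)
  t2 <- .transmit_allele(parent$targets[2], cutting, params, arch)
  tprob <- 0.5 * t1 + 0.5 * t2
  dp <- .mendel_half(parent$drive)
  cp <- .mendel_half(parent$cas9)
  out <- expand.grid(drive = as.integer(names(dp)),
                     cas9 = as.integer(names(cp)),
                     target = names(tprob),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$prob <- rep(dp, times = length(cp) * length(tprob)) *
    rep(rep(cp, each = length(dp)), times = length(tprob)) *
    rep(tprob, each = length(dp) * length(cp))
  out <- out[out$prob > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical key for an unordered target allele pair.
.pair_sort <- function(a, b) {
  swap <- .allele_rank[a] > .allele_rank[b]
  t1 <- ifelse(swap, b, a)
  t2 <- ifelse(swap, a, b)
  list(t1 = t1, t2 = t2)
}

# Unite two gamete distributions into a diploid genotype distribution.
# Returns data.frame(drive, cas9, t1, t2, prob) with canonical pair order,
# aggregated over equivalent rows.
.unite_gametes <- function(gm, gf) {
  im <- rep(seq_len(nrow(gm)), times = nrow(gf))
  jf <- rep(seq_len(nrow(gf)), each = nrow(gm))
  pair <- .pair_sort(gm$target[im], gf$target[jf])
  out <- data.frame(drive = gm$drive[im] + gf$drive[jf],
                    cas9 = gm$cas9[im] + gf$cas9[jf],
                    t1 = pair$t1, t2 = pair$t2,
                    prob = gm$prob[im] * gf$prob[jf],
                    stringsAsFactors = FALSE)
  .aggregate_genotypes(out)
}

.aggregate_genotypes <- function(df) {
  key <- paste(df$drive, df$cas9, df$t1, df$t2, sep = "|")
  p <- rowsum(df$prob, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- df[first, c("drive", "cas9", "t1", "t2"), drop = FALSE]
  out$prob <- as.vector(p[match(key[first], rownames(p)), 1])
  out <- out[out$prob > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Outcome distribution for a target pair under embryo cutting at per-allele
# rate ce: each wild-type allele independently becomes r2.
.deposition_outcomes <- function(t1, t2, ce) {
  cut1 <- if (t1 == "wt") c(FALSE, TRUE) else FALSE
  cut2 <- if (t2 == "wt") c(FALSE, TRUE) else FALSE
  out <- expand.grid(c1 = cut1, c2 = cut2, KEEP.OUT.ATTRS = FALSE)
  out$prob <- ifelse(out$c1, ce, if (t1 == "wt") 1 - ce else 1) *
    ifelse(out$c2, ce, if (t2 == "wt") 1 - ce else 1)
  a <- ifelse(out$c1, "r2", t1)
  b <- ifelse(out$c2, "r2", t2)
  pair <- .pair_sort(a, b)
  data.frame(t1 = pair$t1, t2 = pair$t2, prob = out$prob,
             stringsAsFactors = FALSE)
}

#' Apply maternal Cas9/gRNA deposition to an offspring distribution
#'
#' If the mother carries at least one drive and one Cas9 allele, each
#' wild-type target allele of every offspring genotype (maternally and
#' paternally inherited alike) is independently converted to a disrupted
#' `"r2"` allele with probability `c_embryo`.  Otherwise the distribution
#' is returned unchanged.  Total probability mass is preserved.
#'
#' @param offspring A data frame with columns `drive`, `cas9`, `t1`, `t2`,
#'   `prob` (as produced internally by [offspring_distribution()]).
#' @param mother The mother's [genotype()].
#' @param params A [rate_params()].
#' @return A data frame of the same shape.
#' @export
apply_maternal_deposition <- function(offspring, mother, params) {
  stopifnot(is.data.frame(offspring), inherits(mother, "drive_genotype"),
            inherits(params, "rate_params"))
  ce <- params$c_embryo
  if (mother$drive < 1L || mother$cas9 < 1L || ce == 0) return(offspring)
  pieces <- lapply(seq_len(nrow(offspring)), function(i) {
    dep <- .deposition_outcomes(offspring$t1[i], offspring$t2[i], ce)
    data.frame(drive = offspring$drive[i], cas9 = offspring$cas9[i],
               t1 = dep$t1, t2 = dep$t2,
               prob = offspring$prob[i] * dep$prob,
               stringsAsFactors = FALSE)
  })
  .aggregate_genotypes(do.call(rbind, pieces))
}

# Post-embryonic survival weight of an offspring genotype row: viability
# under the dosage rule, somatic-expression removal for drive+Cas9 carriers
# of a haplolethal target, and the per-drive-copy fitness coefficient.
.survival_weight <- function(df, params, arch) {
  dose <- .allele_dose[df$t1] + .allele_dose[df$t2] +
    if (arch$rescue_functional) df$drive else 0
  viable <- as.numeric(dose >= arch$required_dosage)
  somatic <- ifelse(arch$required_dosage == 2L &
                      df$drive >= 1L & df$cas9 >= 1L,
                    1 - params$somatic_cut_rate, 1)
  viable * somatic * params$drive_fitness^df$drive
}

#' Offspring genotype distribution and viability of a cross
#'
#' Composes [germline_gametes()] for both parents, unites haplotypes into
#' diploid genotypes, applies [apply_maternal_deposition()], then selection:
#' non-viable dosages are removed, drive + Cas9 carriers of a haplolethal
#' target are additionally removed with probability `somatic_cut_rate`
#' (leaky somatic expression), and each genotype is weighted by
#' `drive_fitness^drive_copies`.
#'
#' @param cross A [cross_spec()].
#' @param params A [rate_params()].
#' @param arch A [drive_architecture()].
#' @return An object of class `"offspring_distribution"`: a list with
#'   * `pre_selection`, `post_selection`: data frames (`drive`, `cas9`,
#'     `t1`, `t2`, `prob`); `pre_selection` is the genotype distribution at
#'     the egg stage (after maternal deposition) and sums to 1;
#'     `post_selection` sums to 1 among survivors and has zero rows when
#'     nothing survives;
#'   * `relative_viability`: survival probability relative to an unaffected
#'     egg;
#'   * `absolute_viability`: `baseline_viability * relative_viability`;
#'   * `inheritance_rate`: probability a surviving offspring carries DsRed
#'     (>= 1 drive copy); `NA` with `inheritance_defined = FALSE` when no
#'     offspring survive;
#'   * `cas9_transmission_rate`: probability a surviving offspring carries
#'     EGFP (>= 1 Cas9 copy).
#' @export
#' @examples
#' # male TADE suppression drive heterozygote x wild-type female
#' arch <- drive_architecture("tade_suppression")
#' par <- rate_params(c_germline = 0.10, baseline_viability = 0.83)
#' cr <- cross_spec(genotype(0, 0, sex = "female"),
#'                  genotype(1, 1, sex = "male"))
#' offspring_distribution(cr, par, arch)$absolute_viability  # 0.747
offspring_distribution <- function(cross, params, arch) {
  stopifnot(inherits(cross, "cross_spec"),
            inherits(params, "rate_params"),
            inherits(arch, "drive_architecture"))
  k <- .cross_kernel(cross$mother, cross$father, params, arch)
  g <- .sim_tables()$geno
  as_df <- function(p) {
    keep <- p > 0
    out <- data.frame(drive = g$drive[keep], cas9 = g$cas9[keep],
                      t1 = g$t1[keep], t2 = g$t2[keep], prob = p[keep],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  rel <- k$relative_viability
  post <- as_df(if (rel > 0) k$sel / rel else k$sel)
  structure(
    list(pre_selection = as_df(k$pre),
         post_selection = post,
         relative_viability = rel,
         absolute_viability = k$absolute_viability,
         inheritance_rate = k$inheritance_rate,
         cas9_transmission_rate = k$cas9_transmission_rate,
         inheritance_defined = rel > 0),
    class = "offspring_distribution")
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat("<offspring_distribution>\n")
  cat(sprintf("  relative viability:  %.4f\n", x$relative_viability))
  cat(sprintf("  absolute viability:  %.4f\n", x$absolute_viability))
  if (x$inheritance_defined) {
    cat(sprintf("  drive inheritance:   %.4f\n", x$inheritance_rate))
  } else {
    cat("  drive inheritance:   undefined (no survivors)\n")
  }
  cat(sprintf("  genotypes pre/post:  %d / %d\n",
              nrow(x$pre_selection), nrow(x$post_selection)))
  invisible(x)
}

#' Tabular cross-prediction report
#'
#' Flattens an [offspring_distribution()] into one row per genotype with
#' pre- and post-selection probabilities and dominant markers.
#'
#' @param od An `"offspring_distribution"`.
#' @return A data frame with columns `drive`, `cas9`, `target_1`,
#'   `target_2`, `pre_prob`, `post_prob`, `markers`.
#' @export
cross_prediction_table <- function(od) {
  stopifnot(inherits(od, "offspring_distribution"))
  pre <- od$pre_selection
  key <- paste(pre$drive, pre$cas9, pre$t1, pre$t2, sep = "|")
  post <- od$post_selection
  pkey <- paste(post$drive, post$cas9, post$t1, post$t2, sep = "|")
  post_prob <- post$prob[match(key, pkey)]
  post_prob[is.na(post_prob)] <- 0
  markers <- paste0(ifelse(pre$drive >= 1L, "DsRed", ""),
                    ifelse(pre$drive >= 1L & pre$cas9 >= 1L, "+", ""),
                    ifelse(pre$cas9 >= 1L, "EGFP", ""))
  markers[markers == ""] <- "none"
  data.frame(drive = pre$drive, cas9 = pre$cas9,
             target_1 = pre$t1, target_2 = pre$t2,
             pre_prob = pre$prob, post_prob = post_prob,
             markers = markers, stringsAsFactors = FALSE)
}

#' Confidence bound on the kill rate from a zero-survivor cross
#'
#' When a cross yields 0 surviving adults among `n_eggs` eggs, the exact
#' binomial (Clopper-Pearson) one-sided bound at the given confidence level
#' puts the per-egg survival probability at most `1 - alpha^(1/n)` (with
#' `alpha = 1 - confidence`), i.e. the per-egg kill probability at least
#' `alpha^(1/n)`.  Used to turn "no surviving offspring" observations into
#' statements like ">= 95% killing".
#'
#' @param n_eggs Number of eggs observed (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return The lower confidence bound on the per-egg kill probability, with
#'   attribute `"survival_upper"` giving the matching upper bound on
#'   survival.
#' @export
#' @examples
#' zero_survivor_bound(59)   # kill rate >= 0.9505
zero_survivor_bound <- function(n_eggs, confidence = 0.95) {
  n_eggs <- as.integer(n_eggs)
  if (is.na(n_eggs) || n_eggs < 1L)
    stop("`n_eggs` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("`confidence` must lie strictly in (0, 1)", call. = FALSE)
  alpha <- 1 - confidence
  kill_lower <- alpha^(1 / n_eggs)
  structure(kill_lower, survival_upper = 1 - kill_lower)
}
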