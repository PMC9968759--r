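# Core allele, genotype and viability/fertility model for distant-site
# CRISPR toxin-antidote drives (TADE modification, TADE suppression, TARE).

#' Target-gene allele states
#'
#' A diploid target-gene allele is in one of three states, following the
#' standard gene-drive nomenclature for resistance alleles:
#'
#' * `"wt"`  -- wild type: functional and cleavable by Cas9/gRNA.
#' * `"r1"`  -- functional resistance allele: a cleavage-repair product that
#'   preserves gene function (here via homology-directed repair using the
#'   drive's recoded rescue element as template); functional, not cleavable.
#' * `"r2"`  -- nonfunctional (disrupted) resistance allele: end-joining
#'   repair product destroying gene function; nonfunctional, not cleavable.
#'
#' Dosage contributions are wt = 1, r1 = 1, r2 = 0.
#'
#' @return Character vector of the three valid allele codes.
#' @export
target_allele_states <- function() c("wt", "r1", "r2")

# dosage contribution per allele state
.allele_dose <- c(wt = 1, r1 = 1, r2 = 0)
# canonical ordering used when storing an unordered allele pair
.allele_rank <- c(wt = 1L, r1 = 2L, r2 = 3L)

.check_alleles <- function(targets) {
  if (length(targets) != 2L || !all(targets %in% target_allele_states()))
    stop("`targets` must be two allele codes from ",
         paste(target_allele_states(), collapse = "/"), call. = FALSE)
  targets[order(.allele_rank[targets])]
}

#' Describe a toxin-antidote drive architecture
#'
#' Captures which toxin-antidote system is modeled and its viability and
#' fertility rules.  TADE systems target a haplolethal gene (two functional
#' doses required for survival); TARE targets a haplosufficient gene (one
#' dose suffices).  A TADE suppression drive is additionally inserted inside
#' a haplosufficient-but-essential female fertility gene, so drive
#' homozygous females are sterile.
#'
#' @param system One of `"tade_modification"`, `"tade_suppression"`,
#'   `"tare"`.
#' @param rescue_functional Does a drive allele contribute one functional
#'   dose of the target gene (i.e., does its recoded rescue element work)?
#'   All distant-site rescue elements assessed experimentally failed, so the
#'   default is `FALSE`.
#' @param rescue_is_hdr_template Can the (minimally recoded) rescue element
#'   serve as a template for homology-directed repair of a cut target
#'   allele, producing functional `"r1"` resistance alleles?
#' @param n_cut_sites Number of gRNA cut sites in the target gene
#'   (integer >= 1).  Enters only the embryo-resistance estimator; the cross
#'   model operates at per-allele level.
#' @param drive_disrupts_fertility_gene Is the drive inserted inside a
#'   haplosufficient female-fertility gene?  Only allowed (and default
#'   `TRUE`) for the suppression system.
#'
#' @return An object of class `"drive_architecture"`, a list with fields
#'   `system`, `required_dosage` (2 for TADE, 1 for TARE),
#'   `rescue_functional`, `rescue_is_hdr_template`, `n_cut_sites`,
#'   `drive_disrupts_fertility_gene`.
#' @export
#' @examples
#' drive_architecture("tade_suppression")
#' drive_architecture("tare", rescue_functional = TRUE)
drive_architecture <- function(system = c("tade_modification",
                                          "tade_suppression", "tare"),
                               rescue_functional = FALSE,
                               rescue_is_hdr_template = FALSE,
                               n_cut_sites = 2L,
                               drive_disrupts_fertility_gene =
                                 (system == "tade_suppression")) {
  system <- match.arg(system)
  drive_disrupts_fertility_gene <- isTRUE(drive_disrupts_fertility_gene)
  n_cut_sites <- as.integer(n_cut_sites)
  if (is.na(n_cut_sites) || n_cut_sites < 1L)
    stop("`n_cut_sites` must be an integer >= 1", call. = FALSE)
  if (drive_disrupts_fertility_gene && system != "tade_suppression")
    stop("only the suppression system places the drive in a fertility gene",
         call. = FALSE)
  structure(
    list(system = system,
         required_dosage = if (system == "tare") 1L else 2L,
         rescue_functional = isTRUE(rescue_functional),
         rescue_is_hdr_template = isTRUE(rescue_is_hdr_template),
         n_cut_sites = n_cut_sites,
         drive_disrupts_fertility_gene = drive_disrupts_fertility_gene),
    class = "drive_architecture")
}

#' @export
print.drive_architecture <- function(x, ...) {
  cat("<drive_architecture> ", x$system,
      " (required dosage ", x$required_dosage, ")\n", sep = "")
  cat("  rescue functional: ", x$rescue_functional,
      "; HDR template: ", x$rescue_is_hdr_template,
      "; cut sites: ", x$n_cut_sites, "\n", sep = "")
  if (x$drive_disrupts_fertility_gene)
    cat("  drive disrupts a haplosufficient female-fertility gene\n")
  invisible(x)
}

#' Rate parameters of the drive model
#'
#' @param c_germline Probability, per transmitted target allele, of
#'   cleavage-derived modification in the parental germline.  Cutting
#'   occurs only in parents carrying at least one drive and one Cas9 allele.
#' @param c_embryo Probability, per wild-type target allele of the zygote,
#'   of cleavage by maternally deposited Cas9/gRNA.  Active only when the
#'   mother carries at least one drive and one Cas9 allele.  Both the
#'   maternally and paternally inherited wild-type alleles are exposed.
#' @param p_hdr_functional Probability that a germline-cut allele is
#'   repaired to a functional recoded `"r1"` allele using the drive's rescue
#'   element as template (meaningful only when the architecture has
#'   `rescue_is_hdr_template = TRUE`).
#' @param p_hdr_wt Probability that a germline cut is seamlessly repaired to
#'   wild type using the homolog as template.  Confounded with a lower
#'   `c_germline`; only the product is identifiable.  Defaults to 0.
#' @param baseline_viability Egg-to-adult survival of an unaffected egg
#'   (v0).  The control value from w1118 x w1118 crosses is 0.83.
#' @param somatic_cut_rate Probability that leaky somatic Cas9 activity
#'   removes a drive + Cas9 carrier with a haplolethal target
#'   post-embryonically.
#' @param drive_fitness Multiplicative viability/fecundity coefficient per
#'   drive copy (1 = no fitness cost).
#'
#' @return An object of class `"rate_params"`.
#' @export
rate_params <- function(c_germline = 0, c_embryo = 0,
                        p_hdr_functional = 0, p_hdr_wt = 0,
                        baseline_viability = 0.83,
                        somatic_cut_rate = 0, drive_fitness = 1) {
  p <- list(c_germline = c_germline, c_embryo = c_embryo,
            p_hdr_functional = p_hdr_functional, p_hdr_wt = p_hdr_wt,
            baseline_viability = baseline_viability,
            somatic_cut_rate = somatic_cut_rate,
            drive_fitness = drive_fitness)
  for (nm in setdiff(names(p), "drive_fitness")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a single probability in [0, 1]",
           call. = FALSE)
  }
  if (!is.numeric(p$drive_fitness) || p$drive_fitness < 0)
    stop("`drive_fitness` must be a nonnegative number", call. = FALSE)
  if (p$p_hdr_functional + p$p_hdr_wt > 1 + 1e-12)
    stop("p_hdr_functional + p_hdr_wt must be <= 1", call. = FALSE)
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Construct a diploid genotype
#'
#' A genotype at the three unlinked loci of a split toxin-antidote drive:
#' the drive insertion (DsRed-marked), the supporting Cas9 allele
#' (EGFP-marked), and the diploid autosomal target gene.  Sex is carried
#' solely to gate maternal deposition and female fertility; no locus is
#' sex linked.
#'
#' @param drive Drive copy number (0, 1, 2).
#' @param cas9 Cas9 copy number (0, 1, 2).
#' @param targets Character vector of two target allele codes (see
#'   [target_allele_states()]); stored in canonical order.
#' @param sex `"female"` or `"male"`.
#' @return An object of class `"drive_genotype"`.
#' @export
#' @examples
#' genotype(1, 1, c("wt", "wt"), "female")
genotype <- function(drive = 0L, cas9 = 0L, targets = c("wt", "wt"),
                     sex = c("female", "male")) {
  sex <- match.arg(sex)
  drive <- as.integer(drive); cas9 <- as.integer(cas9)
  if (is.na(drive) || drive < 0L || drive > 2L)
    stop("`drive` copy number must be 0, 1 or 2", call. = FALSE)
  if (is.na(cas9) || cas9 < 0L || cas9 > 2L)
    stop("`cas9` copy number must be 0, 1 or 2", call. = FALSE)
  targets <- .check_alleles(targets)
  structure(list(drive = drive, cas9 = cas9, targets = targets, sex = sex),
            class = "drive_genotype")
}

#' @export
print.drive_genotype <- function(x, ...) {
  cat(sprintf("<genotype> drive=%d cas9=%d target={%s,%s} %s\n",
              x$drive, x$cas9, x$targets[1], x$targets[2], x$sex))
  invisible(x)
}

#' Functional dosage of the target gene
#'
#' Number of functional target-gene doses available to a genotype: the
#' count of functional target alleles (wt or r1) plus, if the
#' architecture's rescue element works, one dose per drive copy.  No upper
#' cap is applied: drive homozygotes with functional rescue contribute two
#' doses and incur no over-expression penalty.
#'
#' @param genotype A [genotype()].
#' @param arch A [drive_architecture()].
#' @return Integer dosage.
#' @export
functional_dosage <- function(genotype, arch) {
  stopifnot(inherits(genotype, "drive_genotype"),
            inherits(arch, "drive_architecture"))
  d <- sum(.allele_dose[genotype$targets])
  if (arch$rescue_functional) d <- d + genotype$drive
  as.integer(d)
}

#' Egg viability of a genotype under the dosage rule
#'
#' A genotype is viable iff its [functional_dosage()] meets the
#' architecture's required dosage: two doses for a haplolethal TADE target
#' (a single disrupted allele is lethal absent a rescuing drive allele),
#' one dose for a haplosufficient TARE target.
#'
#' @inheritParams functional_dosage
#' @return Logical.
#' @export
is_viable <- function(genotype, arch) {
  functional_dosage(genotype, arch) >= arch$required_dosage
}

#' Female fertility under a suppression architecture
#'
#' When the drive sits inside a haplosufficient female-fertility gene
#' (TADE suppression), drive homozygous females are sterile: both fertility
#' gene copies are disrupted by the insertions.  Heterozygotes retain one
#' intact copy and are fertile.  Other architectures never sterilize.
#'
#' @inheritParams functional_dosage
#' @return Logical.
#' @export
is_fertile_female <- function(genotype, arch) {
  stopifnot(inherits(genotype, "drive_genotype"),
            inherits(arch, "drive_architecture"))
  if (genotype$sex != "female")
    stop("is_fertile_female() requires a female genotype", call. = FALSE)
  if (arch$drive_disrupts_fertility_gene) genotype$drive < 2L else TRUE
}

#' Dominant fluorescence markers of a genotype
#'
#' DsRed marks the drive allele and EGFP marks the supporting Cas9 allele;
#' both are dominant, so one copy suffices for the phenotype.
#'
#' @param genotype A [genotype()].
#' @return Character vector, a subset of `c("DsRed", "EGFP")`.
#' @export
phenotype_markers <- function(genotype) {
  stopifnot(inherits(genotype, "drive_genotype"))
  c(if (genotype$drive >= 1L) "DsRed", if (genotype$cas9 >= 1L) "EGFP")
}
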