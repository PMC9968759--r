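# Shared fixtures and independent oracles used across test files.

geno_key <- function(drive, cas9, t1, t2) {
  swap <- c(wt = 1, r1 = 2, r2 = 3)[t1] > c(wt = 1, r1 = 2, r2 = 3)[t2]
  paste(drive, cas9, ifelse(swap, t2, t1), ifelse(swap, t1, t2), sep = "|")
}

od_prob <- function(od, which = c("post", "pre")) {
  which <- match.arg(which)
  df <- if (which == "post") od$post_selection else od$pre_selection
  stats::setNames(df$prob, geno_key(df$drive, df$cas9, df$t1, df$t2))
}

# Monte-Carlo offspring sampler: an independent, direct-simulation route
# through the same biology (per-allele Bernoulli draws), used as an oracle
# for the deterministic enumeration.
mc_offspring <- function(n, mother, father, params, arch) {
  sample_gamete <- function(parent) {
    drive <- stats::rbinom(n, 1, parent$drive / 2)
    cas9 <- stats::rbinom(n, 1, parent$cas9 / 2)
    allele <- parent$targets[sample.int(2, n, replace = TRUE)]
    if (parent$drive >= 1 && parent$cas9 >= 1) {
      is_wt <- allele == "wt"
      cut <- is_wt & stats::rbinom(n, 1, params$c_germline) == 1
      u <- stats::runif(n)
      p1 <- if (arch$rescue_is_hdr_template) params$p_hdr_functional else 0
      allele[cut & u < p1] <- "r1"
      allele[cut & u >= p1 & u < p1 + params$p_hdr_wt] <- "wt"
      allele[cut & u >= p1 + params$p_hdr_wt] <- "r2"
    }
    list(drive = drive, cas9 = cas9, allele = allele)
  }
  gm <- sample_gamete(mother)
  gf <- sample_gamete(father)
  drive <- gm$drive + gf$drive
  cas9 <- gm$cas9 + gf$cas9
  a1 <- gm$allele
  a2 <- gf$allele
  if (mother$drive >= 1 && mother$cas9 >= 1 && params$c_embryo > 0) {
    cut1 <- a1 == "wt" & stats::rbinom(n, 1, params$c_embryo) == 1
    cut2 <- a2 == "wt" & stats::rbinom(n, 1, params$c_embryo) == 1
    a1[cut1] <- "r2"
    a2[cut2] <- "r2"
  }
  dose <- (a1 != "r2") + (a2 != "r2") +
    if (arch$rescue_functional) drive else 0
  alive <- dose >= arch$required_dosage
  somatic <- arch$required_dosage == 2 & drive >= 1 & cas9 >= 1
  alive[somatic] <- alive[somatic] &
    stats::rbinom(sum(somatic), 1, 1 - params$somatic_cut_rate) == 1
  if (params$drive_fitness < 1)
    alive <- alive & stats::rbinom(n, 1, params$drive_fitness^drive) == 1
  list(pre = geno_key(drive, cas9, a1, a2),
       post = geno_key(drive, cas9, a1, a2)[alive])
}

wt_female <- genotype(0, 0, sex = "female")
wt_male <- genotype(0, 0, sex = "male")
drive_het_female <- genotype(1, 1, sex = "female")
drive_het_male <- genotype(1, 1, sex = "male")
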