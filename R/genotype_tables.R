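# Internal static index tables over the finite genotype space.
#
# Haplotypes: drive 0/1 x cas9 0/1 x target allele {wt, r1, r2} -> 12,
# laid out with drive varying fastest, then cas9, then allele.
# Genotypes: drive 0..2 x cas9 0..2 x unordered target pair (6) -> 54.
# Precomputed once per session: the 144 -> 54 gamete-union index, and a
# triplet representation of the maternal-deposition transition (source
# genotype, destination genotype, coefficient kind), so that the embryo
# cutting step is a single scatter-add for any per-allele rate.

.sim_env <- new.env(parent = emptyenv())

.sim_tables <- function() {
  if (!is.null(.sim_env$tab)) return(.sim_env$tab)
  alleles <- target_allele_states()
  hap <- expand.grid(drive = 0:1, cas9 = 0:1, allele = alleles,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- data.frame(a1 = c("wt", "wt", "wt", "r1", "r1", "r2"),
                      a2 = c("wt", "r1", "r2", "r1", "r2", "r2"),
                      stringsAsFactors = FALSE)
  geno <- expand.grid(drive = 0:2, cas9 = 0:2, pair = seq_len(nrow(pairs)),
                      KEEP.OUT.ATTRS = FALSE)
  geno$t1 <- pairs$a1[geno$pair]
  geno$t2 <- pairs$a2[geno$pair]
  geno$key <- paste(geno$drive, geno$cas9, geno$t1, geno$t2, sep = "|")
  geno$dose <- .allele_dose[geno$t1] + .allele_dose[geno$t2]
  geno$n_wt <- (geno$t1 == "wt") + (geno$t2 == "wt")
  pair_index <- function(a, b) {
    s <- .pair_sort(a, b)
    match(paste(s$t1, s$t2), paste(pairs$a1, pairs$a2))
  }
  geno_index <- function(dr, cs, a, b)
    match(paste(dr, cs, pair_index(a, b)),
          paste(geno$drive, geno$cas9, geno$pair))
  # gamete-union index: offspring genotype for (maternal hap i, paternal
  # hap j), i varying fastest to match as.vector(outer(m, f))
  i <- rep(seq_len(nrow(hap)), times = nrow(hap))
  j <- rep(seq_len(nrow(hap)), each = nrow(hap))
  union_idx <- geno_index(hap$drive[i] + hap$drive[j],
                          hap$cas9[i] + hap$cas9[j],
                          hap$allele[i], hap$allele[j])
  # deposition triplets; coefficient kinds:
  # 1 identity, 2 (1-ce), 3 ce, 4 (1-ce)^2, 5 2ce(1-ce), 6 ce^2
  src <- integer(0); dst <- integer(0); kind <- integer(0)
  one_cut <- function(t1, t2) {
    # replace the single wt allele by r2
    a <- ifelse(t1 == "wt", "r2", t1)
    b <- ifelse(t1 == "wt", t2, "r2")
    list(a = a, b = b)
  }
  for (r in seq_len(nrow(geno))) {
    k <- geno$n_wt[r]
    if (k == 0L) {
      src <- c(src, r); dst <- c(dst, r); kind <- c(kind, 1L)
    } else if (k == 1L) {
      oc <- one_cut(geno$t1[r], geno$t2[r])
      src <- c(src, r, r)
      dst <- c(dst, r, geno_index(geno$drive[r], geno$cas9[r], oc$a, oc$b))
      kind <- c(kind, 2L, 3L)
    } else {
      src <- c(src, r, r, r)
      dst <- c(dst, r,
               geno_index(geno$drive[r], geno$cas9[r], "wt", "r2"),
               geno_index(geno$drive[r], geno$cas9[r], "r2", "r2"))
      kind <- c(kind, 4L, 5L, 6L)
    }
  }
  # dense 54 x 144 union matrix: U %*% as.vector(outer(m, f)) accumulates
  # the diploid genotype distribution in one multiply
  U <- matrix(0, nrow(geno), length(union_idx))
  U[cbind(union_idx, seq_along(union_idx))] <- 1
  # deposition transition as a quadratic in the per-allele rate ce:
  # t(D(ce)) = A0 + A1 * ce + A2 * ce^2 (column j = source genotype)
  A0 <- A1 <- A2 <- matrix(0, nrow(geno), nrow(geno))
  basis <- list(`1` = c(1, 0, 0),    # 1
                `2` = c(1, -1, 0),   # 1 - ce
                `3` = c(0, 1, 0),    # ce
                `4` = c(1, -2, 1),   # (1 - ce)^2
                `5` = c(0, 2, -2),   # 2 ce (1 - ce)
                `6` = c(0, 0, 1))    # ce^2
  for (t in seq_along(src)) {
    b <- basis[[kind[t]]]
    A0[dst[t], src[t]] <- A0[dst[t], src[t]] + b[1]
    A1[dst[t], src[t]] <- A1[dst[t], src[t]] + b[2]
    A2[dst[t], src[t]] <- A2[dst[t], src[t]] + b[3]
  }
  .sim_env$tab <- list(hap = hap, geno = geno, pairs = pairs,
                       union_idx = union_idx, geno_index = geno_index,
                       dep_src = src, dep_dst = dst, dep_kind = kind,
                       U = U, dep_A0 = A0, dep_A1 = A1, dep_A2 = A2)
  .sim_env$tab
}

# 12-vector of gamete haplotype probabilities for one parent.
.gamete_vec <- function(parent, params, arch) {
  cutting <- parent$drive >= 1L && parent$cas9 >= 1L
  tprob <- 0.5 * .transmit_allele(parent$targets[1], cutting, params, arch) +
    0.5 * .transmit_allele(parent$targets[2], cutting, params, arch)
  dprob <- c(`0` = 0, `1` = 0)
  dprob[names(.mendel_half(parent$drive))] <- .mendel_half(parent$drive)
  cprob <- c(`0` = 0, `1` = 0)
  cprob[names(.mendel_half(parent$cas9))] <- .mendel_half(parent$cas9)
  kronecker(unname(tprob), kronecker(unname(cprob), unname(dprob)))
}

# Apply embryo cutting at per-allele rate ce to a 54-vector of genotype
# probabilities (precomputed quadratic-in-ce transition).
.depose_vec <- function(off, ce) {
  tab <- .sim_tables()
  as.vector((tab$dep_A0 + ce * tab$dep_A1 + ce * ce * tab$dep_A2) %*% off)
}

# Per-genotype survival weight over the 54-genotype table (viability under
# the dosage rule, somatic removal, drive-fitness coefficient).
.survival_vec <- function(params, arch) {
  g <- .sim_tables()$geno
  dose <- g$dose + if (arch$rescue_functional) g$drive else 0
  viable <- as.numeric(dose >= arch$required_dosage)
  somatic <- ifelse(arch$required_dosage == 2L & g$drive >= 1L &
                      g$cas9 >= 1L,
                    1 - params$somatic_cut_rate, 1)
  viable * somatic * params$drive_fitness^g$drive
}

# Full cross kernel on the indexed genotype space.  Returns the
# pre-selection 54-vector (after deposition), the selected (unnormalized)
# 54-vector and the summary rates.
.cross_kernel <- function(mother, father, params, arch) {
  tab <- .sim_tables()
  m <- .gamete_vec(mother, params, arch)
  f <- .gamete_vec(father, params, arch)
  pre <- as.vector(tab$U %*% as.vector(outer(m, f)))
  if (mother$drive >= 1L && mother$cas9 >= 1L && params$c_embryo > 0)
    pre <- .depose_vec(pre, params$c_embryo)
  w <- .survival_vec(params, arch)
  sel <- pre * w
  rel <- sum(sel)
  g <- tab$geno
  list(pre = pre, sel = sel, relative_viability = rel,
       absolute_viability = params$baseline_viability * rel,
       inheritance_rate = if (rel > 0)
         sum(sel[g$drive >= 1L]) / rel else NA_real_,
       cas9_transmission_rate = if (rel > 0)
         sum(sel[g$cas9 >= 1L]) / rel else NA_real_)
}
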