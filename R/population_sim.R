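# Discrete-generation forward simulation of toxin-antidote drive allele
# dynamics in a panmictic population: deterministic recursion on genotype
# frequencies, Wright-Fisher-style multinomial resampling in stochastic
# mode, and introduction-threshold search by bisection.

# Static genotype/haplotype index tables and the cross kernel live in
# genotype_tables.R and are shared with the single-cross model.

# 54 x 12 matrix of gamete distributions, one row per genotype, under the
# given parameters (germline cutting included; identical for both sexes).
.gamete_matrix <- function(params, arch) {
  tab <- .sim_tables()
  g <- tab$geno
  G <- matrix(0, nrow(g), nrow(tab$hap))
  for (r in seq_len(nrow(g))) {
    gt <- genotype(g$drive[r], g$cas9[r], c(g$t1[r], g$t2[r]), "female")
    G[r, ] <- .gamete_vec(gt, params, arch)
  }
  G
}

# Per-genotype selection weight (viability, somatic removal, drive fitness)
# and female fertility indicator.
.sim_weights <- function(params, arch) {
  g <- .sim_tables()$geno
  fertile <- if (arch$drive_disrupts_fertility_gene) g$drive < 2L
             else rep(TRUE, nrow(g))
  list(survival = .survival_vec(params, arch), fertile = fertile)
}

#' Construct a population state
#'
#' Genotype frequencies are pooled across sexes (1:1 sex ratio; genotype
#' distributions are identical between sexes at birth since no locus is
#' sex linked).
#'
#' @param frequencies Numeric vector of genotype frequencies, named by
#'   genotype key `"drive|cas9|t1|t2"`, or a data frame with columns
#'   `drive`, `cas9`, `t1`, `t2`, `freq`.  Missing genotypes get frequency
#'   0; frequencies are normalized to sum to 1.
#' @param generation Generation counter (>= 0).
#' @param population_size Census size for stochastic multinomial
#'   resampling, or `Inf` for the deterministic (infinite-population)
#'   recursion.
#' @return An object of class `"population_state"` with fields `freq`
#'   (length-54 named vector), `generation`, `population_size`, `extinct`.
#' @export
population_state <- function(frequencies, generation = 0L,
                             population_size = Inf) {
  tab <- .sim_tables()
  f <- numeric(nrow(tab$geno))
  names(f) <- tab$geno$key
  if (is.data.frame(frequencies)) {
    idx <- tab$geno_index(frequencies$drive, frequencies$cas9,
                          frequencies$t1, frequencies$t2)
    if (anyNA(idx)) stop("invalid genotype in `frequencies`", call. = FALSE)
    f[idx] <- f[idx] + frequencies$freq
  } else {
    idx <- match(names(frequencies), names(f))
    if (anyNA(idx))
      stop("unknown genotype key(s): ",
           paste(names(frequencies)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    f[idx] <- frequencies
  }
  if (any(f < 0)) stop("frequencies must be nonnegative", call. = FALSE)
  s <- sum(f)
  if (s <= 0) stop("frequencies must have positive total", call. = FALSE)
  structure(list(freq = f / s, generation = as.integer(generation),
                 population_size = population_size, extinct = FALSE),
            class = "population_state")
}

#' Initial population for a drive release
#'
#' A fraction `release` of individuals are drive-carrying releases (by
#' default homozygous for both the drive and the supporting Cas9 allele,
#' with wild-type target alleles); the remainder are fully wild type.
#'
#' @param release Release frequency in \[0, 1\].
#' @param release_genotype A [genotype()] describing released individuals.
#' @param background_genotype A [genotype()] describing the resident
#'   population (default fully wild type).  Fixing Cas9 in the background
#'   (`genotype(0, 2)`) emulates a complete, non-split drive in which the
#'   toxin element never dissociates from the drive.
#' @param population_size See [population_state()].
#' @return A `"population_state"`.
#' @export
initial_population <- function(release,
                               release_genotype = genotype(2, 2),
                               background_genotype = genotype(0, 0),
                               population_size = Inf) {
  if (!is.numeric(release) || release < 0 || release > 1)
    stop("`release` must lie in [0, 1]", call. = FALSE)
  rg <- release_genotype
  bg <- background_genotype
  df <- data.frame(drive = c(rg$drive, bg$drive),
                   cas9 = c(rg$cas9, bg$cas9),
                   t1 = c(rg$targets[1], bg$targets[1]),
                   t2 = c(rg$targets[2], bg$targets[2]),
                   freq = c(release, 1 - release),
                   stringsAsFactors = FALSE)
  population_state(df, 0L, population_size)
}

#' Advance a population by one generation
#'
#' One nonoverlapping generation: (1) sterile females (see
#' [is_fertile_female()]) contribute no gametes; (2) per-genotype germline
#' gamete pools via [germline_gametes()]; (3) random union of maternal and
#' paternal gametes, with maternal deposition applied conditionally on the
#' mother's genotype (mothers are paired with the paternal pool before
#' deposition, partitioned by whether they deposit Cas9/gRNA -- deposition
#' depends on the mother only through that indicator, so the partition is
#' exact); (4) viability, somatic-expression and drive-fitness selection;
#' (5) renormalization, followed in stochastic mode by multinomial
#' resampling to `population_size`.
#'
#' @param state A [population_state()].
#' @param params A [rate_params()].
#' @param arch A [drive_architecture()].
#' @param cache Optional precomputed model matrices from an internal call;
#'   users can ignore this argument.
#' @return The next `"population_state"`; if no viable offspring can be
#'   produced the returned state has `extinct = TRUE` and zero
#'   frequencies.
#' @export
step_population <- function(state, params, arch, cache = NULL) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "rate_params"),
            inherits(arch, "drive_architecture"))
  if (state$extinct) return(state)
  if (is.null(cache)) cache <- .sim_cache(params, arch)
  rep_out <- .reproduce(state$freq, params, arch, cache)
  if (is.null(rep_out) || rep_out$total <= 0)
    return(.extinct_state(state))
  newf <- rep_out$selected / rep_out$total
  if (is.finite(state$population_size)) {
    counts <- stats::rmultinom(1, size = state$population_size, prob = newf)
    newf <- as.vector(counts) / state$population_size
  }
  structure(list(freq = stats::setNames(newf, names(state$freq)),
                 generation = state$generation + 1L,
                 population_size = state$population_size,
                 extinct = FALSE),
            class = "population_state")
}

# Steps (1)-(4) of a generation on a frequency vector: fertility-gated
# maternal gamete pools (partitioned by the deposition indicator, which is
# the only feature of the mother the embryo-cutting step depends on),
# random union with the paternal pool, maternal deposition, and
# viability/somatic/fitness selection.  Returns NULL when no fertile
# mothers exist.
.reproduce <- function(f, params, arch, cache) {
  tab <- .sim_tables()
  wts <- cache$weights
  fertile_mass <- sum(f * wts$fertile)
  if (fertile_mass <= 0 || sum(f) <= 0) return(NULL)
  mother_w <- f * wts$fertile / fertile_mass
  father_w <- f / sum(f)
  deposits <- tab$geno$drive >= 1L & tab$geno$cas9 >= 1L
  paternal_pool <- as.vector(crossprod(cache$G, father_w))
  offspring <- numeric(length(f))
  for (dep in c(FALSE, TRUE)) {
    w_cls <- mother_w[deposits == dep]
    if (sum(w_cls) <= 0) next
    maternal_pool <- as.vector(crossprod(cache$G[deposits == dep, ,
                                                 drop = FALSE], w_cls))
    joint <- outer(maternal_pool, paternal_pool)
    off <- numeric(length(f))
    acc <- rowsum(as.vector(joint), tab$union_idx)
    off[as.integer(rownames(acc))] <- acc[, 1]
    if (dep && params$c_embryo > 0)
      off <- .depose_vec(off, params$c_embryo)
    offspring <- offspring + off
  }
  sel <- offspring * wts$survival
  list(selected = sel, total = sum(sel), fertile_mass = fertile_mass)
}

.extinct_state <- function(state) {
  structure(list(freq = state$freq * 0,
                 generation = state$generation + 1L,
                 population_size = state$population_size,
                 extinct = TRUE),
            class = "population_state")
}

.sim_cache <- function(params, arch) {
  list(G = .gamete_matrix(params, arch),
       weights = .sim_weights(params, arch))
}

# Allele frequencies and summary statistics of a state.  Genetic load is
# prospective: one minus the product of the fraction of fertile females and
# the mean relative survival of the offspring this state would produce.
.state_summary <- function(state, params, arch, cache) {
  g <- .sim_tables()$geno
  f <- state$freq
  allele_freq <- function(code)
    sum(f * ((g$t1 == code) + (g$t2 == code))) / 2
  fertile_frac <- sum(f * cache$weights$fertile)
  if (state$extinct) {
    load <- 1
  } else {
    rep_out <- .reproduce(f, params, arch, cache)
    load <- if (is.null(rep_out)) 1 else
      1 - min(1, rep_out$total) * rep_out$fertile_mass
  }
  data.frame(generation = state$generation,
             drive_freq = sum(f * g$drive) / 2,
             cas9_freq = sum(f * g$cas9) / 2,
             wt_freq = allele_freq("wt"),
             r1_freq = allele_freq("r1"),
             r2_freq = allele_freq("r2"),
             fertile_female_fraction = fertile_frac,
             genetic_load = load,
             extinct = state$extinct)
}

#' Simulate a drive-release trajectory
#'
#' Iterates [step_population()] from an [initial_population()] and records
#' per-generation allele frequencies, the fraction of fertile females, and
#' genetic load (one minus the product of mean relative offspring survival
#' and the fertile-female fraction).
#'
#' @param initial_release Release frequency of drive individuals in
#'   \[0, 1\].
#' @param generations Number of generations to simulate.
#' @param params A [rate_params()].
#' @param arch A [drive_architecture()].
#' @param mode `"deterministic"` (infinite population) or `"stochastic"`
#'   (multinomial resampling to `population_size`).
#' @param population_size Census size for stochastic mode.
#' @param seed Integer seed for stochastic mode (ignored otherwise);
#'   trajectories are reproducible under a fixed seed.
#' @param release_genotype Genotype of released individuals (default:
#'   homozygous for drive and Cas9).
#' @param background_genotype Genotype of the resident population (see
#'   [initial_population()]).
#' @return An object of class `"drive_trajectory"`: list with `summary`
#'   (data frame, one row per generation from 0), `final_state` and
#'   `extinct`.
#' @export
run_trajectory <- function(initial_release, generations, params, arch,
                           mode = c("deterministic", "stochastic"),
                           population_size = 10000, seed = NULL,
                           release_genotype = genotype(2, 2),
                           background_genotype = genotype(0, 0)) {
  mode <- match.arg(mode)
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 0L)
    stop("`generations` must be a nonnegative integer", call. = FALSE)
  if (mode == "stochastic") {
    if (!is.null(seed)) set.seed(as.integer(seed))
  } else {
    population_size <- Inf
  }
  state <- initial_population(initial_release, release_genotype,
                              background_genotype, population_size)
  cache <- .sim_cache(params, arch)
  rows <- vector("list", generations + 1L)
  rows[[1]] <- .state_summary(state, params, arch, cache)
  for (gen in seq_len(generations)) {
    state <- step_population(state, params, arch, cache)
    rows[[gen + 1L]] <- .state_summary(state, params, arch, cache)
    if (state$extinct) {
      rows <- rows[seq_len(gen + 1L)]
      break
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 final_state = state,
                 extinct = state$extinct),
            class = "drive_trajectory")
}

#' @export
print.drive_trajectory <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  cat("<drive_trajectory> ", nrow(s) - 1, " generation(s)",
      if (x$extinct) " [EXTINCT]", "\n", sep = "")
  cat(sprintf("  final drive freq %.4f, load %.4f, fertile females %.4f\n",
              last$drive_freq, last$genetic_load,
              last$fertile_female_fraction))
  invisible(x)
}

#' Find the introduction threshold of a drive
#'
#' Bisection on the release frequency for the boundary between eventual
#' drive spread and loss in the deterministic recursion.  A release
#' spreads when the drive allele frequency at the horizon exceeds its
#' initial value or the population goes extinct under suppression.
#' Because a drive with fitness costs settles at an internal equilibrium
#' below very high release frequencies (so a release above the
#' equilibrium "fails" this criterion while the drive persists), the
#' upper bracket is found by scanning release frequencies downward for
#' the largest probe that spreads.  Returns 0 when every
#' positive release spreads (an unconfined drive) and `NA` when no release
#' below 1 spreads (a failed drive).
#'
#' @param params A [rate_params()].
#' @param arch A [drive_architecture()].
#' @param generations Simulation horizon per probe.
#' @param tol Bisection tolerance on the release frequency.
#' @param release_genotype Genotype of released individuals.
#' @param background_genotype Genotype of the resident population (see
#'   [initial_population()]).
#' @return The threshold release frequency, 0, or `NA_real_` (no release
#'   spreads).  The attribute `"separated"` is `FALSE` if the horizon was
#'   too short to separate outcomes at neighboring probes.
#' @export
find_introduction_threshold <- function(params, arch, generations = 100,
                                        tol = 0.005,
                                        release_genotype = genotype(2, 2),
                                        background_genotype =
                                          genotype(0, 0)) {
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  spreads <- function(r) {
    tr <- run_trajectory(r, generations, params, arch,
                         mode = "deterministic",
                         release_genotype = release_genotype,
                         background_genotype = background_genotype)
    if (tr$extinct) return(TRUE)
    d <- tr$summary$drive_freq
    d[length(d)] > d[1] + 1e-12
  }
  lo <- tol / 2
  if (spreads(lo)) return(structure(0, separated = TRUE))
  hi <- NA_real_
  for (probe in c(0.99, 0.95, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3)) {
    if (spreads(probe)) {
      hi <- probe
      break
    }
  }
  if (is.na(hi)) return(structure(NA_real_, separated = TRUE))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spreads(mid)) hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, separated = TRUE)
}
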