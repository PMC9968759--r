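test_that("germline gametes: no cutting without drive or Cas9", {
  arch <- drive_architecture("tade_suppression")
  par <- rate_params(c_germline = 0.4)
  for (parent in list(genotype(0, 0), genotype(1, 0), genotype(0, 2))) {
    g <- germline_gametes(parent, par, arch)
    expect_equal(sum(g$prob), 1, tolerance = 1e-12)
    expect_identical(unique(g$target), "wt")
  }
})

test_that("germline gametes: full cutting with full HDR yields only r1", {
  arch <- drive_architecture("tade_modification",
                             rescue_is_hdr_template = TRUE)
  par <- rate_params(c_germline = 1, p_hdr_functional = 1)
  g <- germline_gametes(genotype(1, 1), par, arch)
  expect_identical(unique(g$target), "r1")
  # without the HDR-template architecture flag the same mass goes to r2
  arch2 <- drive_architecture("tade_modification")
  g2 <- germline_gametes(genotype(1, 1), par, arch2)
  expect_identical(unique(g2$target), "r2")
})

test_that("germline gametes match the 2x2x2 outcome tree at c_g = 0.1", {
  arch <- drive_architecture("tade_suppression")
  par <- rate_params(c_germline = 0.1)
  g <- germline_gametes(genotype(1, 1), par, arch)
  p <- function(d, c, t) sum(g$prob[g$drive == d & g$cas9 == c &
                                      g$target == t])
  # drive, cas9 and target outcomes are jointly independent
  for (d in 0:1) for (c in 0:1) {
    expect_equal(p(d, c, "r2"), 0.5 * 0.5 * 0.1, tolerance = 1e-12)
    expect_equal(p(d, c, "wt"), 0.5 * 0.5 * 0.9, tolerance = 1e-12)
  }
  expect_equal(sum(g$prob[g$target == "r2"]), 0.1, tolerance = 1e-12)
  expect_equal(sum(g$prob[g$drive == 1]), 0.5, tolerance = 1e-12)
})

test_that("maternal deposition exposes both wild-type alleles", {
  par <- rate_params(c_embryo = 0.02)
  off <- data.frame(drive = 0L, cas9 = 0L, t1 = "wt", t2 = "wt", prob = 1,
                    stringsAsFactors = FALSE)
  out <- apply_maternal_deposition(off, genotype(1, 1, sex = "female"), par)
  p <- stats::setNames(out$prob, paste(out$t1, out$t2))
  # oracle: exhaustive 4-outcome enumeration of two independent Bernoullis
  expect_equal(unname(p["wt wt"]), 0.9604, tolerance = 1e-12)
  expect_equal(unname(p["wt r2"]), 0.0392, tolerance = 1e-12)
  expect_equal(unname(p["r2 r2"]), 0.0004, tolerance = 1e-12)
  expect_equal(sum(out$prob), 1, tolerance = 1e-12)
  # mothers without Cas9 deposit nothing
  out2 <- apply_maternal_deposition(off, genotype(1, 0, sex = "female"),
                                    par)
  expect_identical(out2, off)
  # complete deposition disrupts every wild-type allele
  out3 <- apply_maternal_deposition(off, genotype(1, 1, sex = "female"),
                                    rate_params(c_embryo = 1))
  expect_identical(out3$t1, "r2")
  expect_identical(out3$t2, "r2")
})

test_that("suppression-drive cross viabilities match the printed pair", {
  arch <- drive_architecture("tade_suppression")
  par <- rate_params(c_germline = 0.10, c_embryo = 0.02,
                     baseline_viability = 0.83)
  male <- offspring_distribution(cross_spec(wt_female, drive_het_male),
                                 par, arch)
  expect_equal(male$absolute_viability, 0.83 * 0.90, tolerance = 1e-12)
  expect_equal(male$inheritance_rate, 0.5, tolerance = 1e-12)
  female <- offspring_distribution(cross_spec(drive_het_female, wt_male),
                                   par, arch)
  expect_equal(female$absolute_viability, 0.83 * 0.90 * 0.98^2,
               tolerance = 1e-12)
  expect_equal(female$inheritance_rate, 0.5, tolerance = 1e-12)
})

test_that("all rates zero gives the Mendelian limit", {
  arch <- drive_architecture("tade_suppression")
  par <- rate_params(baseline_viability = 0.83)
  od <- offspring_distribution(cross_spec(drive_het_female, wt_male),
                               par, arch)
  expect_equal(od$absolute_viability, 0.83, tolerance = 1e-12)
  expect_equal(od$inheritance_rate, 0.5, tolerance = 1e-12)
})

test_that("idealized functional TADE biases inheritance to 100%", {
  arch <- drive_architecture("tade_modification", rescue_functional = TRUE)
  par <- rate_params(c_germline = 1)
  od <- offspring_distribution(cross_spec(wt_female, drive_het_male),
                               par, arch)
  # only drive carriers obtain the rescuing second dose
  expect_equal(od$relative_viability, 0.5, tolerance = 1e-12)
  expect_equal(od$inheritance_rate, 1.0, tolerance = 1e-12)
})

test_that("full HDR to r1 restores full viability of male drive crosses", {
  arch <- drive_architecture("tade_modification",
                             rescue_is_hdr_template = TRUE)
  for (cg in c(0.2, 0.7, 1)) {
    par <- rate_params(c_germline = cg, p_hdr_functional = 1)
    od <- offspring_distribution(cross_spec(wt_female, drive_het_male),
                                 par, arch)
    expect_equal(od$relative_viability, 1, tolerance = 1e-12)
  }
})

test_that("zero-survivor crosses flag inheritance as undefined", {
  arch <- drive_architecture("tade_modification")
  par <- rate_params(c_germline = 1)  # every transmitted allele disrupted
  od <- offspring_distribution(cross_spec(wt_female, drive_het_male),
                               par, arch)
  expect_equal(od$relative_viability, 0)
  expect_false(od$inheritance_defined)
  expect_true(is.na(od$inheritance_rate))
  expect_identical(nrow(od$post_selection), 0L)
})

test_that("distributions normalize over a random parameter grid", {
  set.seed(42)
  systems <- c("tade_modification", "tade_suppression", "tare")
  parents <- list(genotype(1, 1), genotype(2, 2), genotype(1, 0),
                  genotype(2, 1, c("wt", "r2")))
  for (i in 1:25) {
    arch <- drive_architecture(sample(systems, 1),
                               rescue_functional = runif(1) < 0.5,
                               rescue_is_hdr_template = runif(1) < 0.5)
    hdr <- runif(2) / 2
    par <- rate_params(c_germline = runif(1), c_embryo = runif(1),
                       p_hdr_functional = hdr[1], p_hdr_wt = hdr[2],
                       somatic_cut_rate = runif(1),
                       baseline_viability = runif(1))
    mo <- parents[[sample.int(4, 1)]]
    fa <- parents[[sample.int(4, 1)]]
    mo$sex <- "female"; fa$sex <- "male"
    od <- offspring_distribution(cross_spec(mo, fa), par, arch)
    expect_equal(sum(od$pre_selection$prob), 1, tolerance = 1e-12)
    if (od$inheritance_defined)
      expect_equal(sum(od$post_selection$prob), 1, tolerance = 1e-12)
    g <- germline_gametes(mo, par, arch)
    expect_equal(sum(g$prob), 1, tolerance = 1e-12)
  }
})

test_that("viability is non-increasing in cut rates for failed rescue", {
  arch <- drive_architecture("tade_suppression")
  grid <- seq(0, 1, by = 0.2)
  prev <- NULL
  for (cg in grid) {
    v <- offspring_distribution(
      cross_spec(drive_het_female, wt_male),
      rate_params(c_germline = cg, c_embryo = 0.3), arch
    )$relative_viability
    if (!is.null(prev)) expect_lte(v, prev + 1e-12)
    prev <- v
  }
  prev <- NULL
  for (ce in grid) {
    v <- offspring_distribution(
      cross_spec(drive_het_female, wt_male),
      rate_params(c_germline = 0.3, c_embryo = ce), arch
    )$relative_viability
    if (!is.null(prev)) expect_lte(v, prev + 1e-12)
    prev <- v
  }
})

test_that("parent-role symmetry holds up to maternal deposition", {
  arch <- drive_architecture("tade_suppression")
  par_nodep <- rate_params(c_germline = 0.3, c_embryo = 0)
  a <- offspring_distribution(cross_spec(drive_het_female, wt_male),
                              par_nodep, arch)
  b <- offspring_distribution(cross_spec(wt_female, drive_het_male),
                              par_nodep, arch)
  expect_equal(od_prob(a), od_prob(b)[names(od_prob(a))], tolerance = 1e-12)
  # with deposition active they differ
  par_dep <- rate_params(c_germline = 0.3, c_embryo = 0.2)
  a2 <- offspring_distribution(cross_spec(drive_het_female, wt_male),
                               par_dep, arch)
  b2 <- offspring_distribution(cross_spec(wt_female, drive_het_male),
                               par_dep, arch)
  expect_false(isTRUE(all.equal(a2$relative_viability,
                                b2$relative_viability)))
})

test_that("Monte-Carlo sampling reproduces the enumeration within 3 SE", {
  set.seed(7)
  n <- 1e5
  cases <- list(
    list(arch = drive_architecture("tade_suppression"),
         par = rate_params(c_germline = 0.10, c_embryo = 0.02),
         mother = drive_het_female, father = wt_male),
    list(arch = drive_architecture("tare", rescue_functional = TRUE),
         par = rate_params(c_germline = 0.9, c_embryo = 0.6,
                           somatic_cut_rate = 0),
         mother = genotype(1, 1, sex = "female"),
         father = genotype(1, 0, sex = "male")),
    list(arch = drive_architecture("tade_modification",
                                   rescue_is_hdr_template = TRUE,
                                   rescue_functional = FALSE),
         par = rate_params(c_germline = 0.8, p_hdr_functional = 0.6,
                           p_hdr_wt = 0.1, c_embryo = 0.2),
         mother = drive_het_female, father = drive_het_male))
  for (cs in cases) {
    od <- offspring_distribution(cross_spec(cs$mother, cs$father),
                                 cs$par, cs$arch)
    mc <- mc_offspring(n, cs$mother, cs$father, cs$par, cs$arch)
    pre_hat <- table(mc$pre) / n
    for (k in names(od_prob(od, "pre"))) {
      p <- od_prob(od, "pre")[[k]]
      phat <- if (k %in% names(pre_hat)) pre_hat[[k]] else 0
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(phat - p), max(3 * se, 1e-4))
    }
    # post-selection genotype frequencies among survivors
    m <- length(mc$post)
    post_hat <- table(mc$post) / m
    for (k in names(od_prob(od, "post"))) {
      p <- od_prob(od, "post")[[k]]
      phat <- if (k %in% names(post_hat)) post_hat[[k]] else 0
      se <- sqrt(p * (1 - p) / m)
      expect_lt(abs(phat - p), max(3 * se, 1e-4))
    }
    # survival rate itself
    p <- od$relative_viability
    expect_lt(abs(m / n - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("cross prediction table carries probabilities and markers", {
  arch <- drive_architecture("tade_suppression")
  par <- rate_params(c_germline = 0.10, baseline_viability = 0.83)
  od <- offspring_distribution(cross_spec(wt_female, drive_het_male),
                               par, arch)
  tab <- cross_prediction_table(od)
  expect_equal(sum(tab$pre_prob), 1, tolerance = 1e-12)
  expect_equal(sum(tab$post_prob), 1, tolerance = 1e-12)
  expect_true(all(tab$markers[tab$drive >= 1 & tab$cas9 >= 1] ==
                    "DsRed+EGFP"))
  expect_true(all(tab$markers[tab$drive == 0 & tab$cas9 == 0] == "none"))
})

test_that("zero-survivor bound inverts the exact binomial", {
  # oracle: P(0 survivors | kill rate k) = k^n; bisection on k^n = alpha
  bisect_bound <- function(n, conf) {
    f <- function(k) k^n - (1 - conf)
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (n in c(1, 10, 59, 500)) {
    b <- zero_survivor_bound(n, 0.95)
    expect_equal(as.numeric(b), bisect_bound(n, 0.95), tolerance = 1e-9)
  }
  b59 <- zero_survivor_bound(59, 0.95)
  expect_equal(attr(b59, "survival_upper"), 0.0495, tolerance = 1e-3)
  expect_equal(as.numeric(zero_survivor_bound(1, 0.95)), 0.05,
               tolerance = 1e-12)
  # more eggs -> tighter bound toward 1
  expect_gt(zero_survivor_bound(500), zero_survivor_bound(59))
})
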