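# Generator of vial-structured cross count datasets with known ground
# truth, emulating the statistical structure of the fly experiments:
# binomial egg-to-adult survival with vial-level (batch) effects on the
# logit scale.

#' Describe a synthetic vial-count study design
#'
#' @param cross_specs Named list mapping `cross_id` to [cross_spec()].
#' @param vials_per_cross Number of vials (batches) per cross (>= 1).
#' @param egg_distribution Per-vial egg-count distribution: a list with
#'   `type` one of `"fixed"`, `"poisson"`, `"negative_binomial"`, plus `n`
#'   (fixed), `mean` (poisson), or `mean` and `dispersion` (size parameter,
#'   negative binomial).  Default: Poisson with mean 50, loosely matching
#'   multi-day egg-lay protocols.
#' @param batch_sd Standard deviation of the per-vial logit-scale viability
#'   perturbation (>= 0); mirrors a binomial GLMM's random intercept.
#' @param seed Integer seed; generation is fully reproducible given the
#'   seed.
#' @return An object of class `"generation_design"`.
#' @export
generation_design <- function(cross_specs, vials_per_cross = 20,
                              egg_distribution = list(type = "poisson",
                                                      mean = 50),
                              batch_sd = 0, seed = 1L) {
  if (!is.list(cross_specs) || length(cross_specs) == 0 ||
      is.null(names(cross_specs)) || any(names(cross_specs) == ""))
    stop("`cross_specs` must be a non-empty named list", call. = FALSE)
  for (cs in cross_specs)
    if (!inherits(cs, "cross_spec"))
      stop("all elements of `cross_specs` must be cross_spec objects",
           call. = FALSE)
  vials_per_cross <- as.integer(vials_per_cross)
  if (is.na(vials_per_cross) || vials_per_cross < 1L)
    stop("`vials_per_cross` must be >= 1", call. = FALSE)
  if (!is.list(egg_distribution) ||
      !egg_distribution$type %in% c("fixed", "poisson",
                                    "negative_binomial"))
    stop("`egg_distribution$type` must be fixed, poisson or ",
         "negative_binomial", call. = FALSE)
  mean_ok <- switch(egg_distribution$type,
                    fixed = isTRUE(egg_distribution$n >= 1),
                    poisson = isTRUE(egg_distribution$mean > 0),
                    negative_binomial = isTRUE(egg_distribution$mean > 0) &&
                      isTRUE(egg_distribution$dispersion > 0))
  if (!mean_ok)
    stop("egg_distribution parameters must be positive", call. = FALSE)
  if (!is.numeric(batch_sd) || batch_sd < 0)
    stop("`batch_sd` must be >= 0", call. = FALSE)
  structure(list(cross_specs = cross_specs,
                 vials_per_cross = vials_per_cross,
                 egg_distribution = egg_distribution,
                 batch_sd = batch_sd,
                 seed = as.integer(seed)),
            class = "generation_design")
}

.draw_eggs <- function(dist, n) {
  switch(dist$type,
         fixed = rep(as.integer(dist$n), n),
         poisson = stats::rpois(n, dist$mean),
         negative_binomial = stats::rnbinom(n, size = dist$dispersion,
                                            mu = dist$mean))
}

# Which parent carries the drive allele, for the CSV sex column.
.drive_parent_sex <- function(cs) {
  if (cs$mother$drive >= 1L) "female"
  else if (cs$father$drive >= 1L) "male"
  else "none"
}

#' Generate a synthetic vial-count dataset
#'
#' For each vial: eggs are drawn from the design's egg distribution; the
#' cross's absolute viability and marker transmission rates come from
#' [offspring_distribution()]; viability is perturbed on the logit scale
#' by `Normal(0, batch_sd)` (the batch effect); `adults` is binomial in
#' eggs, and `dsred_adults` / `egfp_adults` are binomial in adults at the
#' drive and Cas9 transmission rates.
#'
#' @param design A [generation_design()].
#' @param params A [rate_params()] (the ground truth).
#' @param arch A [drive_architecture()].
#' @return A vial-count data frame with columns `cross_id`, `vial_id`,
#'   `drive_parent_sex`, `eggs`, `adults`, `dsred_adults`, `egfp_adults`,
#'   carrying the design, parameters and architecture as attribute
#'   `"ground_truth"`.
#' @export
generate_dataset <- function(design, params, arch) {
  stopifnot(inherits(design, "generation_design"),
            inherits(params, "rate_params"),
            inherits(arch, "drive_architecture"))
  set.seed(design$seed)
  rows <- list()
  for (id in names(design$cross_specs)) {
    cs <- design$cross_specs[[id]]
    od <- offspring_distribution(cs, params, arch)
    nv <- design$vials_per_cross
    eggs <- .draw_eggs(design$egg_distribution, nv)
    v <- od$absolute_viability
    if (design$batch_sd > 0 && v > 0 && v < 1) {
      pert <- stats::rnorm(nv, 0, design$batch_sd)
      pvial <- stats::plogis(stats::qlogis(v) + pert)
    } else {
      pvial <- rep(v, nv)
    }
    adults <- stats::rbinom(nv, eggs, pvial)
    if (od$inheritance_defined) {
      dsred <- stats::rbinom(nv, adults, od$inheritance_rate)
      egfp <- stats::rbinom(nv, adults, od$cas9_transmission_rate)
    } else {
      dsred <- egfp <- integer(nv)
    }
    rows[[id]] <- data.frame(cross_id = id,
                             vial_id = paste0(id, "_v", seq_len(nv)),
                             drive_parent_sex = .drive_parent_sex(cs),
                             eggs = eggs, adults = adults,
                             dsred_adults = dsred, egfp_adults = egfp,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(
    params = unclass(params),
    architecture = unclass(arch),
    seed = design$seed,
    vials_per_cross = design$vials_per_cross,
    egg_distribution = design$egg_distribution,
    batch_sd = design$batch_sd)
  out
}
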