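## Synthetic-herd generator: pedigree, breeding values by gene dropping, and
## lactation records under the repeatability animal model
##   y = Xb + Za + Wpe + e
## with methane phenotypes produced indirectly from the simulated milk traits
## (mirroring how the phenotype is defined), so every stage of the analysis
## is testable against known truth.

## symmetric PSD square root (chol is not defined for singular blocks)
.mat_sqrt <- function(M) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

.default_trait_cor <- function() {
  tr <- c("milk", "fat", "protein", "lactose", "other_solids")
  R <- diag(5)
  dimnames(R) <- list(tr, tr)
  set_ <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_("milk", "fat", 0.50); set_("milk", "protein", 0.85)
  set_("milk", "lactose", 0.95); set_("milk", "other_solids", 0.30)
  set_("fat", "protein", 0.60); set_("fat", "lactose", 0.45)
  set_("fat", "other_solids", 0.30)
  set_("protein", "lactose", 0.80); set_("protein", "other_solids", 0.30)
  set_("lactose", "other_solids", 0.30)
  R
}

#' Simulation configuration for a synthetic dairy herd
#'
#' The defaults emulate the study population: a paternal half-sib structure
#' of sires each with 10 recorded daughters (the `"study"` preset gives
#' ~17,470 cows, the `"small"` preset 2,000), 28 herds, 12 year levels, 4
#' calving seasons, parities 1--6 with ~2.18 records per cow, lactation
#' length ~N(310, 35) truncated to [200, 400] days, and milk-trait means and
#' dispersions on the published summary scale (milk 11,221 +/- 2,353 kg etc.).
#' Milk variance components are calibrated so that the derived MPE1 methane
#' phenotype (an affine image of milk yield) carries exactly the published
#' MPE1 additive / permanent-environment / residual components; the same
#' variance fractions and a common correlation structure are applied to the
#' other yield traits.  Dry matter is generated as fat + protein + lactose
#' plus an independent positive "other solids" component so the record
#' invariants hold by construction.
#'
#' @param preset `"small"` (200 sires, tests) or `"study"` (1,747 sires).
#' @param seed integer seed; `NULL` uses the caller's RNG state.
#' @param n_sires,daughters_per_sire,n_generations pedigree design; founders
#'   are sires and dams, each later generation is produced by random mating
#'   (no selfing).
#' @param records_per_cow fixed number of records per cow, or `NULL` for a
#'   truncated-geometric number of parities on 1..`max_parity` with mean
#'   `mean_records`.
#' @param mean_records target mean records per cow (default 2.176 =
#'   38,011 / 17,468).
#' @param max_parity maximum parity (default 6).
#' @param n_herds,n_years,n_seasons numbers of fixed-effect levels.
#' @param lactation_mean,lactation_sd,lactation_range lactation-length model.
#' @param trait_means,trait_sds means and total SDs of the latent yield
#'   traits (kg/lactation).
#' @param milk_components `c(sigma2_a, sigma2_pe, sigma2_e)` for milk yield;
#'   the default is the published MPE1 component set divided by 2.73^2.
#' @param genetic_cor,pe_cor,residual_cor 5x5 correlation matrices across the
#'   latent traits (unit diagonal, positive semidefinite).
#' @param fixed_sd_frac SD of each fixed-effect level distribution, as a
#'   fraction of the trait SD, for herd/year/season/parity.
#' @param lactation_slope_frac covariate effect: slope such that one SD of
#'   lactation length moves the trait by this fraction of its SD.
#' @param methane_noise_sd optional g/lactation SD of independent noise added
#'   to the methane columns (default 0: methane is a deterministic function
#'   of the milk traits, which forces unit correlations with them).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(preset = c("small", "study"), seed = NULL,
                       n_sires = NULL, daughters_per_sire = 10,
                       n_generations = 1, records_per_cow = NULL,
                       mean_records = 2.176, max_parity = 6,
                       n_herds = 28, n_years = 12, n_seasons = 4,
                       lactation_mean = 310, lactation_sd = 35,
                       lactation_range = c(200, 400),
                       trait_means = c(milk = 11221, fat = 428,
                                       protein = 375, lactose = 546,
                                       other_solids = 82),
                       trait_sds = c(milk = 2353, fat = 92, protein = 74,
                                     lactose = 114, other_solids = 20),
                       milk_components = c(6771940, 3371540, 12418000) /
                         2.73^2,
                       genetic_cor = NULL, pe_cor = NULL,
                       residual_cor = NULL,
                       fixed_sd_frac = c(herd = 0.25, year = 0.15,
                                         season = 0.05, parity = 0.20),
                       lactation_slope_frac = 0.2,
                       methane_noise_sd = 0) {
  preset <- match.arg(preset)
  if (is.null(n_sires)) n_sires <- if (preset == "study") 1747 else 200
  stopifnot(n_sires >= 1, daughters_per_sire >= 1, n_generations >= 1,
            max_parity >= 1, n_herds >= 1, n_years >= 1, n_seasons >= 1,
            all(milk_components >= 0), methane_noise_sd >= 0)
  if (is.null(genetic_cor)) genetic_cor <- .default_trait_cor()
  if (is.null(pe_cor)) pe_cor <- genetic_cor
  if (is.null(residual_cor)) residual_cor <- genetic_cor
  for (R in list(genetic_cor, pe_cor, residual_cor)) {
    stopifnot(nrow(R) == 5, ncol(R) == 5, all(abs(diag(R) - 1) < 1e-12))
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("trait correlation matrix is not positive semidefinite")
  }
  ## variance fractions and total-variance scale, calibrated on milk
  fr <- milk_components / sum(milk_components)
  comp_scale <- sum(milk_components) / trait_sds["milk"]^2
  comp_sum <- comp_scale * trait_sds^2
  comp_sum["milk"] <- sum(milk_components)  # exact, not via rounding
  sigma2 <- rbind(a = fr[1] * comp_sum, pe = fr[2] * comp_sum,
                  e = fr[3] * comp_sum)
  sigma2[, "milk"] <- milk_components

  ## truncated-geometric parity count with the target mean
  if (is.null(records_per_cow) && max_parity > 1) {
    mean_records <- min(max(mean_records, 1 + 1e-6), max_parity - 1e-6)
    f <- function(pp) {
      w <- (1 - pp)^(0:(max_parity - 1)) * pp
      sum((1:max_parity) * w / sum(w)) - mean_records
    }
    geom_p <- stats::uniroot(f, c(1e-6, 1 - 1e-6))$root
  } else geom_p <- NA_real_

  structure(list(
    preset = preset, seed = seed, n_sires = n_sires,
    daughters_per_sire = daughters_per_sire, n_generations = n_generations,
    records_per_cow = records_per_cow, mean_records = mean_records,
    max_parity = max_parity, geom_p = geom_p,
    n_herds = n_herds, n_years = n_years, n_seasons = n_seasons,
    lactation_mean = lactation_mean, lactation_sd = lactation_sd,
    lactation_range = lactation_range,
    trait_means = trait_means, trait_sds = trait_sds,
    sigma2 = sigma2, genetic_cor = genetic_cor, pe_cor = pe_cor,
    residual_cor = residual_cor, fixed_sd_frac = fixed_sd_frac,
    lactation_slope_frac = lactation_slope_frac,
    methane_noise_sd = methane_noise_sd), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic herd configuration (", x$preset, " preset): ",
      x$n_sires, " sires x ", x$daughters_per_sire,
      " daughters, ", x$n_generations, " generation(s)\n", sep = "")
  invisible(x)
}

#' Simulate a pedigree
#'
#' Founder sires and dams, then `n_generations` of offspring by random
#' mating (no selfing).  Each generation has `n_sires * daughters_per_sire`
#' offspring; in intermediate generations half the offspring are male, the
#' final generation is all female.  The recorded-cow set (the final
#' generation's females) is attached as attribute `"cows"`.
#'
#' @param cfg a [sim_config].
#' @return A [pedigree] with attribute `"cows"`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_off <- cfg$n_sires * cfg$daughters_per_sire
  sires <- sprintf("S%04d", seq_len(cfg$n_sires))
  dams0 <- sprintf("D%05d", seq_len(n_off))
  rows <- data.frame(animal = c(sires, dams0), sire = NA_character_,
                     dam = NA_character_, stringsAsFactors = FALSE)
  males <- sires
  females <- dams0
  for (g in seq_len(cfg$n_generations)) {
    if (!length(males) || !length(females))
      stop("infeasible mating constraints: no ",
           if (!length(males)) "males" else "females", " in generation ", g)
    last <- g == cfg$n_generations
    ids <- sprintf("G%d_%05d", g, seq_len(n_off))
    sire_of <- rep(sample(males), length.out = n_off)
    dam_of <- sample(females, n_off, replace = length(females) < n_off)
    rows <- rbind(rows, data.frame(animal = ids, sire = sire_of,
                                   dam = dam_of, stringsAsFactors = FALSE))
    if (last) {
      cows <- ids
    } else {
      sex <- rep(c(TRUE, FALSE), length.out = n_off)
      males <- ids[sex]
      females <- ids[!sex]
    }
  }
  ped <- pedigree(rows)
  attr(ped, "cows") <- cows
  ped
}

#' Simulate breeding values by gene dropping
#'
#' Founders are drawn from `N(0, G)`; each non-founder is the mean of its
#' parents' values plus a Mendelian-sampling deviation with covariance
#' `k_i G`, where `k_i = 1/2 - (F_s + F_d)/4` with both parents known,
#' `3/4 - F_p/4` with one, and 1 with none.  The population covariance of
#' the result converges to `A (x) G`.
#'
#' @param ped a [pedigree].
#' @param G genetic covariance matrix (any dimension; positive
#'   semidefinite) or a single variance.
#' @return Matrix of effects, one row per animal (pedigree order).
#' @export
simulate_breeding_values <- function(ped, G) {
  stopifnot(is(ped, "pedigree"))
  if (length(G) == 1) G <- matrix(G, 1, 1)
  t <- ncol(G)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("G is not positive semidefinite")
  Gh <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  n <- nrow(ped)
  ml <- ml_inbreeding(ped$si, ped$di)
  Zm <- matrix(stats::rnorm(n * t), n, t) %*% Gh  # N(0, G) rows
  a <- matrix(0, n, t, dimnames = list(ped$animal, colnames(G)))
  for (i in seq_len(n)) {
    s <- ped$si[i]; d <- ped$di[i]
    par <- numeric(t)
    if (s > 0L) par <- par + 0.5 * a[s, ]
    if (d > 0L) par <- par + 0.5 * a[d, ]
    a[i, ] <- par + sqrt(ml$d[i]) * Zm[i, ]
  }
  a
}

#' Simulate lactation records for a synthetic herd
#'
#' Runs the repeatability animal model generatively: fixed-effect values are
#' drawn once per herd/year/season/parity level, breeding values come from
#' [simulate_breeding_values()] jointly across the latent yield traits,
#' permanent-environment effects are one draw per cow, residuals one per
#' record.  Dry matter is the sum of fat, protein, lactose and the latent
#' other-solids trait.  Methane columns (`ecm`, `cpc`, `mpe1`--`mpe3`) are
#' produced indirectly from the simulated milk traits by
#' [predict_methane()], plus optional independent noise
#' (`cfg$methane_noise_sd`).
#'
#' @param ped a [pedigree] (typically from [simulate_pedigree()]).
#' @param cfg a [sim_config].
#' @param cows character vector of recorded cows; defaults to
#'   `attr(ped, "cows")`.
#' @return A list of class `synthetic_herd`: `pedigree`, `records` (one row
#'   per cow-parity), and `truth` (true breeding values,
#'   permanent-environment effects, per-record fixed-effect contributions,
#'   level effects and the configuration) for oracle checks.
#' @export
simulate_records <- function(ped, cfg, cows = NULL) {
  stopifnot(is(ped, "pedigree"), is(cfg, "sim_config"))
  if (is.null(cows)) cows <- attr(ped, "cows")
  if (is.null(cows)) cows <- ped$animal[ped$gen == max(ped$gen)]
  stopifnot(all(cows %in% ped$animal))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 500000L)

  tr <- names(cfg$trait_means)
  t5 <- length(tr)
  n_cows <- length(cows)
  mkcov <- function(v, R) {
    s <- sqrt(v)
    (s %o% s) * R
  }
  Ga <- mkcov(cfg$sigma2["a", ], cfg$genetic_cor)
  Gpe <- mkcov(cfg$sigma2["pe", ], cfg$pe_cor)
  Re <- mkcov(cfg$sigma2["e", ], cfg$residual_cor)
  dimnames(Ga) <- dimnames(Gpe) <- dimnames(Re) <- list(tr, tr)

  bv <- simulate_breeding_values(ped, Ga)
  pe <- matrix(stats::rnorm(n_cows * t5), n_cows, t5) %*% .mat_sqrt(Gpe)
  rownames(pe) <- cows; colnames(pe) <- tr

  ## records per cow
  k <- if (!is.null(cfg$records_per_cow)) {
    rep(as.integer(cfg$records_per_cow), n_cows)
  } else if (cfg$max_parity == 1) {
    rep(1L, n_cows)
  } else {
    w <- (1 - cfg$geom_p)^(0:(cfg$max_parity - 1)) * cfg$geom_p
    sample(seq_len(cfg$max_parity), n_cows, replace = TRUE, prob = w / sum(w))
  }
  n_rec <- sum(k)

  ## fixed-effect level values, one draw per level per trait
  lv <- function(nlev, tag) {
    m <- matrix(stats::rnorm(nlev * t5), nlev, t5) *
      rep(cfg$fixed_sd_frac[tag] * cfg$trait_sds, each = nlev)
    colnames(m) <- tr
    m
  }
  herd_eff <- lv(cfg$n_herds, "herd")
  year_eff <- lv(cfg$n_years, "year")
  season_eff <- lv(cfg$n_seasons, "season")
  parity_eff <- lv(cfg$max_parity, "parity")
  ll_slope <- cfg$lactation_slope_frac * cfg$trait_sds / cfg$lactation_sd

  cow_rec <- rep(cows, k)
  parity <- unlist(lapply(k, seq_len))
  herd <- rep(sample.int(cfg$n_herds, n_cows, replace = TRUE), k)
  base_year <- rep(sample.int(cfg$n_years, n_cows, replace = TRUE), k)
  year <- (base_year + parity - 2L) %% cfg$n_years + 1L
  season <- sample.int(cfg$n_seasons, n_rec, replace = TRUE)
  ll <- round(stats::rnorm(n_rec, cfg$lactation_mean, cfg$lactation_sd))
  ll <- pmin(pmax(ll, cfg$lactation_range[1]), cfg$lactation_range[2])

  fixed_part <- herd_eff[herd, , drop = FALSE] +
    year_eff[year, , drop = FALSE] +
    season_eff[season, , drop = FALSE] +
    parity_eff[parity, , drop = FALSE] +
    (ll - cfg$lactation_mean) %o% ll_slope
  e <- matrix(stats::rnorm(n_rec * t5), n_rec, t5) %*% .mat_sqrt(Re)
  ridx <- match(cow_rec, ped$animal)
  cidx <- match(cow_rec, cows)
  Yl <- rep(cfg$trait_means, each = n_rec) + fixed_part +
    bv[ridx, , drop = FALSE] + pe[cidx, , drop = FALSE] + e
  colnames(Yl) <- tr

  rec <- data.frame(cow = cow_rec,
                    parity = factor(parity, levels = seq_len(cfg$max_parity)),
                    herd = factor(herd, levels = seq_len(cfg$n_herds)),
                    year = factor(year, levels = seq_len(cfg$n_years)),
                    season = factor(season, levels = seq_len(cfg$n_seasons)),
                    lactation_length = as.numeric(ll),
                    stringsAsFactors = FALSE)
  rec$milk <- Yl[, "milk"]
  rec$fat <- Yl[, "fat"]
  rec$protein <- Yl[, "protein"]
  rec$lactose <- Yl[, "lactose"]
  rec$dry_matter <- Yl[, "fat"] + Yl[, "protein"] + Yl[, "lactose"] +
    Yl[, "other_solids"]
  ## guard rails for the record invariants (violations are essentially
  ## impossible at the default scales; clamping keeps the table valid)
  clamped <- sum(rec$milk <= rec$dry_matter)
  rec$milk <- pmax(rec$milk, rec$dry_matter * 1.001)
  for (v in c("fat", "protein", "lactose")) rec[[v]] <- pmax(rec[[v]], 0.1)

  rec <- predict_methane(rec)
  if (cfg$methane_noise_sd > 0) {
    for (v in c("mpe1", "mpe2", "mpe3"))
      rec[[v]] <- rec[[v]] + stats::rnorm(n_rec, 0, cfg$methane_noise_sd)
  }

  structure(list(
    pedigree = ped, records = rec,
    truth = list(bv = bv, pe = pe, fixed_part = fixed_part,
                 herd_eff = herd_eff, year_eff = year_eff,
                 season_eff = season_eff, parity_eff = parity_eff,
                 ll_slope = ll_slope, Ga = Ga, Gpe = Gpe, Re = Re,
                 config = cfg, n_clamped = clamped)),
    class = "synthetic_herd")
}

#' Simulate a complete synthetic herd
#'
#' Convenience wrapper: [simulate_pedigree()] then [simulate_records()].
#'
#' @param cfg a [sim_config].
#' @return A `synthetic_herd` (see [simulate_records()]).
#' @export
simulate_herd <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  simulate_records(ped, cfg)
}

#' @export
print.synthetic_herd <- function(x, ...) {
  cat("Synthetic herd:", nrow(x$records), "records on",
      length(unique(x$records$cow)), "cows;",
      nrow(x$pedigree), "animals in pedigree\n")
  invisible(x)
}
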