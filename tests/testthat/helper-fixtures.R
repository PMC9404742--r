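# Shared fixtures and independent oracles built in code.

trio_ped <- function() {
  pedigree(data.frame(animal = c("A", "B", "C"),
                      sire = c(NA, NA, "A"),
                      dam = c(NA, NA, "B")))
}

# full-sib mating: C, D full sibs from A x B; E their offspring (F_E = 0.25)
fullsib_ped <- function() {
  pedigree(data.frame(animal = c("A", "B", "C", "D", "E"),
                      sire = c("0", "0", "A", "A", "C"),
                      dam = c("0", "0", "B", "B", "D")))
}

# random valid pedigree: animals numbered so parents precede offspring
random_ped <- function(n, seed, p_known = 0.7) {
  set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2) {
      if (runif(1) < p_known) sire[i] <- paste0("a", sample.int(i - 1, 1))
      if (runif(1) < p_known) dam[i] <- paste0("a", sample.int(i - 1, 1))
    }
  }
  pedigree(data.frame(animal = paste0("a", seq_len(n)), sire = sire,
                      dam = dam))
}

# Independent oracle for the relationship matrix: memoised recursive kinship
# phi(i, j); a_ij = 2 phi(i, j), a_ii = 1 + F_i = 2 phi(i, i) ... with
# phi(i, i) = (1 + phi(s_i, d_i)) / 2.  Independent of the tabular fill.
oracle_nrm <- function(ped) {
  n <- nrow(ped)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      (1 + phi(ped$si[i], ped$di[i])) / 2
    } else {
      # recurse on the younger (later) animal
      if (i < j) { tmp <- i; i <- j; j <- tmp }
      0.5 * (phi(ped$si[i], j) + phi(ped$di[i], j))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) A[i, j] <- A[j, i] <- 2 * phi(i, j)
    A[i, i] <- 2 * phi(i, i)  # = 1 + F_i
  }
  A
}

# small synthetic herd for model tests
tiny_herd <- function(seed = 11, n_sires = 30, daughters = 5,
                      records = 2, ...) {
  cfg <- sim_config(n_sires = n_sires, daughters_per_sire = daughters,
                    seed = seed, records_per_cow = records,
                    n_herds = 3, n_years = 3, n_seasons = 2, ...)
  simulate_herd(cfg)
}

# intercept-only recovery configuration used by the parameter-recovery checks
recovery_cfg <- function(seed, n_sires = 200, daughters = 10) {
  sim_config(preset = "small", seed = seed, n_sires = n_sires,
             daughters_per_sire = daughters, records_per_cow = 2,
             n_herds = 1, n_years = 1, n_seasons = 1,
             fixed_sd_frac = c(herd = 0, year = 0, season = 0, parity = 0),
             lactation_slope_frac = 0)
}

published_components <- list(
  mpe1 = c(6771940, 3371540, 12418000),
  mpe2 = c(10345900, 6870700, 25606200),
  mpe3 = c(12898700, 8566120, 31924400)
)
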