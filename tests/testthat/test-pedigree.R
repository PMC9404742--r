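test_that("read_pedigree parses, sorts and validates a CSV pedigree", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "C,A,B", "B,0,0", "A,0,0"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$animal[3], "C")          # child last
  expect_setequal(ped$animal[1:2], c("A", "B"))
  expect_equal(ped$gen, c(0L, 0L, 1L))

  # order invariance of the sorted structure
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "A,0,0", "B,0,0", "C,A,B"), f2)
  ped2 <- read_pedigree(f2)
  expect_equal(build_nrm(ped)[ped2$animal, ped2$animal], build_nrm(ped2),
               ignore_attr = TRUE)

  # parents referenced but never listed become founders
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "C,A,B"), f3)
  expect_equal(nrow(read_pedigree(f3)), 3)
})

test_that("pedigree rejects self-parents, duplicates and cycles", {
  expect_error(pedigree(data.frame(animal = "A", sire = "A", dam = NA)),
               "cycle")
  expect_error(pedigree(data.frame(animal = c("A", "A"), sire = NA,
                                   dam = NA)), "duplicate")
  # two-animal parent cycle: error must name an animal on the cycle
  expect_error(pedigree(data.frame(animal = c("A", "B"), sire = c("B", "A"),
                                   dam = NA)), "cycle.*'(A|B)'")
})

test_that("prune_generations keeps ancestors within g parent-links", {
  chain <- pedigree(data.frame(animal = paste0("x", 1:8),
                               sire = c(NA, paste0("x", 1:7)), dam = NA))
  expect_equal(nrow(prune_generations(chain, "x8", 6)), 7)
  p0 <- prune_generations(chain, "x8", 0)
  expect_equal(p0$animal, "x8")
  expect_true(all(is.na(p0$sire)))

  trio <- trio_ped()
  expect_equal(nrow(prune_generations(trio, "C", 1)), 3)
  expect_error(prune_generations(trio, character(0), 2), "empty focal")
  expect_error(prune_generations(trio, "nope", 2), "not in pedigree")

  # g >= depth is the identity
  for (s in 1:3) {
    ped <- random_ped(12, seed = 40 + s)
    pr <- prune_generations(ped, ped$animal, g = 12)
    expect_identical(build_nrm(pr), build_nrm(ped))
  }
})

test_that("build_nrm reproduces hand-computed relationships", {
  founders <- pedigree(data.frame(animal = letters[1:4], sire = NA, dam = NA))
  expect_equal(unname(build_nrm(founders))[1:4, 1:4], diag(4))

  A <- build_nrm(trio_ped())
  expect_equal(A["C", "A"], 0.5)
  expect_equal(A["C", "B"], 0.5)
  expect_equal(A["C", "C"], 1)

  A2 <- build_nrm(fullsib_ped())
  expect_equal(A2["C", "D"], 0.5)
  expect_equal(A2["E", "E"], 1.25)      # F_E = 0.25 from full-sib mating
  expect_equal(unname(inbreeding(fullsib_ped())["E"]), 0.25)
})

test_that("build_nrm matches the recursive-kinship oracle on random pedigrees", {
  for (s in 1:8) {
    ped <- random_ped(sample(4:12, 1), seed = 100 + s)
    expect_lt(max(abs(build_nrm(ped) - oracle_nrm(ped))), 1e-12)
  }
})

test_that("A is positive semidefinite on generated pedigrees", {
  for (s in 1:5) {
    ped <- random_ped(20, seed = 200 + s)
    ev <- eigen(build_nrm(ped), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("build_nrm_inverse inverts A, including with inbreeding", {
  for (ped in list(trio_ped(), fullsib_ped(), random_ped(60, seed = 7))) {
    A <- build_nrm(ped)
    Ai <- as.matrix(build_nrm_inverse(ped))
    expect_lt(max(abs(A %*% Ai - diag(nrow(ped)))), 1e-10)
    expect_equal(attr(build_nrm_inverse(ped), "logdet_A"),
                 as.numeric(determinant(A)$modulus))
  }
  # larger pedigree from the generator (multi-generation, 500+ animals)
  cfg <- sim_config(n_sires = 15, daughters_per_sire = 15,
                    n_generations = 2, seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_gte(nrow(ped), 400)
  A <- build_nrm(ped)
  Ai <- as.matrix(build_nrm_inverse(ped))
  expect_lt(max(abs(A %*% Ai - diag(nrow(ped)))), 1e-8)
})
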