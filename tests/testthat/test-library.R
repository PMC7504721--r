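test_that("load_library validates rows and reports rejections", {
  lib <- load_library(data.frame(
    id = c("C1", "C2", "C3"),
    sublibrary = c("2D-FL", "PPI", "2D-FL"),
    mw = c(150, 0, 250)
  ))
  expect_equal(nrow(lib), 2)
  expect_equal(lib$mw[lib$id == "C1"], 150)
  rej <- attr(lib, "rejected")
  expect_equal(rej$id, "C2")
  expect_match(rej$reason, "non-positive molecular weight")

  expect_error(
    load_library(data.frame(id = c("A", "A"), sublibrary = "NPB", mw = 100)),
    "duplicate"
  )
  expect_error(load_library(data.frame(id = "A", mw = 100)), "sublibrary")
})

test_that("synthetic library reproduces the five-subset composition", {
  lib <- synthetic_library(2000, seed = 1)
  counts <- table(lib$sublibrary)
  expect_equal(
    as.integer(counts[c("2D-FL", "3D-FL", "NPB", "SPI", "PPI")]),
    c(250, 250, 250, 250, 1000)
  )
  expect_equal(nrow(lib), 2000)
  expect_true(all(lib$mw > 0))
})

test_that("rule of three uses inclusive boundaries and isolates criteria", {
  res <- rule_of_three(data.frame(
    mw = c(300, 301, 150), hbd = c(3, 0, 4), clogp = c(3.0, 0, 1)
  ))
  expect_equal(res$ro3_compliant, c(TRUE, FALSE, FALSE))
  # failing criterion is the right one
  expect_false(res$ro3_mw[2])
  expect_true(res$ro3_hbd[2] && res$ro3_clogp[2])
  expect_false(res$ro3_hbd[3])
  expect_true(res$ro3_mw[3] && res$ro3_clogp[3])
})

test_that("missing descriptors are indeterminate, never silently compliant", {
  res <- rule_of_three(data.frame(mw = 150, hbd = NA_real_, clogp = 1))
  expect_true(res$ro3_indeterminate)
  expect_true(is.na(res$ro3_compliant))
  # a definite failure dominates a missing descriptor
  res2 <- rule_of_three(data.frame(mw = 500, hbd = NA_real_, clogp = 1))
  expect_false(res2$ro3_compliant)
})

test_that("rule of three is monotone: worsening never restores compliance", {
  base <- expand.grid(mw = c(200, 300, 350), hbd = c(0, 3, 5),
                      clogp = c(-1, 3, 4))
  res <- rule_of_three(base)
  for (i in seq_len(nrow(base))) {
    worse <- base[i, ] + c(50, 1, 0.5)
    res_w <- rule_of_three(worse)
    if (!res$ro3_compliant[i]) expect_false(res_w$ro3_compliant)
  }
})

test_that("ligand efficiency matches its closed form and scaling laws", {
  expect_equal(ligand_efficiency(1, 10), 0)
  # frozen oracle: -(0.0019872 * 298.15) * ln(4.8e-4) / 17
  expect_equal(ligand_efficiency(480e-6, 17), 0.2663292, tolerance = 1e-6)
  expect_equal(ligand_efficiency(1e-4, 10), 2 * ligand_efficiency(1e-4, 20))
  # strictly decreasing in KD
  kds <- 10^seq(-7, -2, length.out = 12)
  le <- ligand_efficiency(kds, 15)
  expect_true(all(diff(le) < 0))
  expect_error(ligand_efficiency(0, 10), "positive")
  expect_error(ligand_efficiency(1e-4, 0), "at least 1")
})

test_that("tanimoto follows the set-overlap definition", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(1:5, 1:5), 1)
  expect_equal(tanimoto(1:3, 4:6), 0)
  expect_equal(tanimoto(numeric(0), numeric(0)), 0)
})

test_that("tanimoto matrix is symmetric, bounded and unit-diagonal", {
  set.seed(42)
  fps <- lapply(1:6, function(i) sample(1:40, sample(5:15, 1)))
  names(fps) <- paste0("c", 1:6)
  m <- tanimoto_matrix(fingerprints = fps)
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(diag(m)), rep(1, 6))
})

test_that("atom-pair backend agrees with ChemmineR's Tanimoto", {
  skip_if_not_installed("ChemmineR")
  smiles <- c(a = "CCCCCO", b = "CCCCCCCCN", c = "c1ccccc1CCO", d = "CCCCCO")
  m <- tanimoto_matrix(data.frame(id = names(smiles), smiles = smiles))
  expect_equal(m["a", "d"], 1) # identical structures
  apset <- ChemmineR::sdf2ap(ChemmineR::smiles2sdf(smiles))
  expect_equal(m["a", "b"], ChemmineR::cmp.similarity(apset[[1]], apset[[2]]),
               tolerance = 1e-12)
  expect_equal(m["b", "c"], ChemmineR::cmp.similarity(apset[[2]], apset[[3]]),
               tolerance = 1e-12)
})

test_that("unparsable SMILES are excluded and reported, matrix built on rest", {
  skip_if_not_installed("ChemmineR")
  m <- suppressWarnings(tanimoto_matrix(data.frame(
    id = c("ok1", "bad", "ok2"),
    smiles = c("CCO", "not_a_smiles((", "CCN")
  )))
  expect_setequal(rownames(m), c("ok1", "ok2"))
  expect_true("bad" %in% attr(m, "excluded"))
})

test_that("single-linkage clustering matches the field examples", {
  # two compounds at T = 0.83 (distance 0.17) cluster at cut 0.5
  sim <- matrix(c(1, 0.83, 0.83, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(cluster_single_linkage(sim, 0.5)$cluster, c(1L, 1L))

  # all-zero similarity: singletons below cut 1
  sim0 <- diag(4)
  rownames(sim0) <- colnames(sim0) <- letters[1:4]
  expect_equal(cluster_single_linkage(sim0, 0.9)$cluster, 1:4)

  # three points, distances 0.1 / 0.2 / 0.9, cut 0.3: chain of all three
  # via the minimum-link rule (0.1 and 0.2 both below the cut)
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.2, 0.9, 0.2, 0), 3)
  sim3 <- 1 - d
  rownames(sim3) <- colnames(sim3) <- c("x", "y", "z")
  got <- cluster_single_linkage(sim3, 0.3)$cluster
  oracle <- brute_force_single_linkage(d, 0.3)
  expect_true(same_partition(got, oracle))
  expect_equal(got, c(1L, 1L, 1L))

  expect_error(cluster_single_linkage(matrix(numeric(0), 0, 0), 0.5), "empty")
})

test_that("single linkage equals brute-force agglomeration on random instances", {
  set.seed(7)
  for (trial in 1:20) {
    n <- sample(3:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    sim <- 1 - d
    rownames(sim) <- colnames(sim) <- paste0("m", seq_len(n))
    cut <- runif(1, 0.05, 0.95)
    got <- cluster_single_linkage(sim, cut)$cluster
    oracle <- brute_force_single_linkage(d, cut)
    expect_true(same_partition(got, oracle))
  }
})
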