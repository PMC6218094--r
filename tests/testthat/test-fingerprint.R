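# On-bit sets computed independently with the reference MACCS implementation
# (RDKit 2024.09, MACCSkeys.GenMACCSKeys) for molecules where the SMARTS
# dictionaries agree bit-for-bit; frozen here as the oracle.
RDKIT_MACCS <- list(
  "C" = c(160L),
  "CCO" = c(82L, 109L, 114L, 139L, 153L, 155L, 157L, 160L, 164L),
  "CC=O" = c(154L, 160L, 164L),
  "OC(=O)C(=O)C" = c(72L, 123L, 136L, 139L, 146L, 152L, 154L, 157L, 159L,
                     160L, 164L)
)

test_that("MACCS keys reproduce the reference implementation's on-bits", {
  keys <- maccs_keys(names(RDKIT_MACCS))
  expect_equal(dim(keys), c(4, 166))
  for (smi in names(RDKIT_MACCS)) {
    expect_equal(which(keys[smi, ] == 1), RDKIT_MACCS[[smi]],
                 ignore_attr = TRUE, label = smi)
  }
  # the ethanol/acetaldehyde contrast: shared and differing oxygen keys
  shared <- intersect(RDKIT_MACCS[["CCO"]], RDKIT_MACCS[["CC=O"]])
  expect_true(all(keys["CCO", shared] == 1 & keys["CC=O", shared] == 1))
  only_etoh <- setdiff(RDKIT_MACCS[["CCO"]], RDKIT_MACCS[["CC=O"]])
  expect_true(all(keys["CC=O", only_etoh] == 0))
  # determinism
  expect_identical(maccs_keys("CCO"), maccs_keys("CCO"))
  # unparseable SMILES are rejected with the offending string
  expect_error(maccs_keys("not(a)smiles["), "not\\(a\\)smiles")
})

test_that("reaction fingerprints concatenate substrate then product blocks", {
  k <- maccs_keys(c("CC=O", "CCO"))
  fp <- concat_fingerprints(k[1, ], k[2, ], pair_id = "ald__etoh")
  expect_equal(dim(fp), c(1, 332))
  expect_true(all(fp %in% 0:1))
  # brute-force index check against manual concatenation
  expect_equal(unname(fp[1, 1:166]), unname(k[1, ]))
  expect_equal(unname(fp[1, 167:332]), unname(k[2, ]))
  # substrate = product mirrors the halves; zero in, zero out
  same <- concat_fingerprints(k[2, ], k[2, ])
  expect_equal(unname(same[1, 1:166]), unname(same[1, 167:332]))
  zero <- concat_fingerprints(rep(0L, 166), rep(0L, 166))
  expect_true(all(zero == 0))
  expect_error(concat_fingerprints(rep(0L, 165), rep(0L, 166)), "166")

  comp <- simulate_compound_set()
  pairs <- toy_pairs(comp)
  rf <- reaction_fingerprints(pairs, comp)
  expect_equal(dim(rf), c(nrow(pairs), 332))
  expect_equal(rownames(rf), pairs$pair_id)
  # a missing structure is reported by id
  expect_error(
    reaction_fingerprints(
      tibble::tibble(pair_id = "x", substrate_id = "C01", product_id = "ZZZ"),
      comp),
    "ZZZ")
})

test_that("fingerprint Lasso recovers planted structure and its limits", {
  # exactly-linear target over 10 bits, no regularization
  set.seed(5)
  x10 <- matrix(stats::rbinom(600, 1, 0.5), 60, 10)
  w10 <- seq(0.01, 0.1, length.out = 10)
  y10 <- as.numeric(x10 %*% w10) + 0.2
  m0 <- fit_fingerprint_model(x10, y10, lambda = 0)
  expect_equal(unname(coef(m0)), w10, tolerance = 1e-6)

  # heavy regularization shrinks everything to the intercept = mean
  mb <- fit_fingerprint_model(x10, y10, lambda = 10)
  expect_equal(sum(coef(mb) != 0), 0)
  expect_equal(unique(predict(mb, x10)), mean(y10), tolerance = 1e-10)

  # sparse ground truth over the full 332-bit design
  set.seed(42)
  planted <- c(5L, 50L, 170L, 250L, 300L)
  x <- matrix(stats::rbinom(100 * 332, 1, 0.3), 100, 332)
  w <- numeric(332); w[planted] <- c(0.08, -0.06, 0.05, 0.07, -0.09)
  y <- as.numeric(x %*% w) + 0.1 + stats::rnorm(100, 0, 0.005)
  m <- fit_fingerprint_model(x, y, lambda = 0.002, seed = 1)
  expect_gte(sum(abs(coef(m)[planted]) > 0.01), 4)
  expect_equal(sum(abs(coef(m)[-planted]) > 0.01), 0)
  expect_error(fit_fingerprint_model(x, y, lambda = -1), "lambda")
})

test_that("fingerprint model is order-invariant and improves with data", {
  set.seed(9)
  planted <- c(10L, 80L, 200L, 310L)
  w <- numeric(332); w[planted] <- c(0.06, -0.05, 0.08, -0.07)
  gen <- function(n) {
    x <- matrix(stats::rbinom(n * 332, 1, 0.3), n, 332)
    list(x = x, y = as.numeric(x %*% w) + 0.05 + stats::rnorm(n, 0, 0.01))
  }
  test_set <- gen(200)

  # row-order invariance (same rows, shuffled)
  tr <- gen(50)
  m1 <- fit_fingerprint_model(tr$x, tr$y, seed = 1)
  perm <- sample(50)
  m2 <- fit_fingerprint_model(tr$x[perm, ], tr$y[perm], seed = 1)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-8)
  expect_equal(m1$lambda, m2$lambda)

  # held-out MAE decreases monotonically with training size
  maes <- vapply(c(30, 100, 300), function(n) {
    d <- gen(n)
    m <- fit_fingerprint_model(d$x, d$y, seed = 1)
    evaluate_predictions(predict(m, test_set$x), test_set$y)$mae
  }, numeric(1))
  expect_true(all(diff(maes) < 0))
})
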