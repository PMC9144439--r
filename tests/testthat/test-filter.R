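test_that("MAF threshold is a strict 5% boundary", {
  # 100 accessions: MAF 0.04 and 0.06 markers, plus one at exactly 0.05
  vals <- cbind(
    c(rep(1, 4), rep(0, 96)),
    c(rep(1, 6), rep(0, 94)),
    c(rep(1, 5), rep(0, 95))
  )
  G <- toy_genotypes(vals)
  out <- filter_markers(G, maf_min = 0.05, max_missing = 0.5)
  expect_equal(out$genotypes$map$id, "mk002")
  expect_equal(out$report$n_input, 3)
  expect_equal(out$report$n_failed_maf, 2)
  expect_equal(out$report$n_retained, 1)
})

test_that("missingness threshold is a strict 50% boundary", {
  vals <- cbind(
    c(rep(NA, 5), rep(0, 3), rep(1, 2)),   # 50% missing: removed
    c(rep(NA, 4), rep(0, 3), rep(1, 3))    # 40% missing: kept
  )
  G <- toy_genotypes(vals)
  out <- filter_markers(G)
  expect_equal(out$genotypes$map$id, "mk002")
  expect_equal(out$report$n_failed_missing, 1)
})

test_that("monomorphic and fully missing markers are removed; filtering is idempotent", {
  set.seed(3)
  vals <- cbind(
    rep(0, 30), rep(1, 30), rep(NA_real_, 30),
    rbinom(30, 1, 0.5), rbinom(30, 1, 0.4)
  )
  G <- toy_genotypes(vals)
  once <- filter_markers(G)
  expect_false(any(c("mk001", "mk002", "mk003") %in% once$genotypes$map$id))
  twice <- filter_markers(once$genotypes)
  expect_identical(twice$genotypes$values, once$genotypes$values)
  expect_equal(twice$report$n_retained, twice$report$n_input)

  mono <- toy_genotypes(matrix(0, 10, 3))
  expect_equal(filter_markers(mono)$report$n_retained, 0)
  expect_error(filter_markers(toy_genotypes(matrix(numeric(0), 0, 2))),
               "zero accessions")
})

test_that("proportional subsampling follows largest-remainder quotas", {
  set.seed(1)
  G <- toy_genotypes(matrix(rbinom(10 * 400, 1, 0.5), nrow = 10),
                     chrom = rep(c("Chr01", "Chr02"), c(100, 300)))
  Gs <- subsample_markers(G, 40, seed = 7)
  quotas <- table(factor(Gs$map$chrom, levels = c("Chr01", "Chr02")))
  expect_equal(as.vector(quotas), c(10, 30))

  G3 <- toy_genotypes(matrix(rbinom(5 * 9, 1, 0.5), nrow = 5),
                      chrom = rep(c("c1", "c2", "c3"), each = 3))
  for (s in 1:5) {
    q <- table(factor(subsample_markers(G3, 4, seed = s)$map$chrom,
                      levels = c("c1", "c2", "c3")))
    expect_equal(sum(q), 4)
    expect_true(all(q >= 1 & q <= 2))
  }

  # identity at full target, error above it
  expect_identical(subsample_markers(G, 400, seed = 1)$values, G$values)
  expect_error(subsample_markers(G, 401), "target_n")

  # quotas are deterministic; only the within-chromosome draw varies
  a <- subsample_markers(G, 40, seed = 1)
  b <- subsample_markers(G, 40, seed = 2)
  expect_equal(as.vector(table(a$map$chrom)), as.vector(table(b$map$chrom)))
  expect_false(identical(a$map$id, b$map$id))
  expect_identical(subsample_markers(G, 40, seed = 1)$map$id, a$map$id)
  # column order is preserved
  expect_true(!is.unsorted(match(a$map$id, G$map$id)))
})

test_that("encoding imputes with the reference mean and centers on it", {
  vals <- rbind(c(0, 1), c(1, 0), c(0, 0), c(NA, 1))
  G <- toy_genotypes(vals)
  enc <- genotype_encoder(G)
  # marker 1 mean over non-missing = 1/3; the NA becomes 1/3 pre-centering
  E <- encode_genotypes(enc, G)
  expect_equal(E[4, 1], 0, tolerance = 1e-12)
  expect_true(!anyNA(E))
  # imputation by the centering constant leaves column means exactly zero
  expect_equal(unname(colMeans(E)), c(0, 0), tolerance = 1e-12)

  # no missing values: encoding is exactly column centering
  G2 <- toy_genotypes(rbind(c(0, 1), c(1, 0), c(1, 1)))
  E2 <- encode_genotypes(genotype_encoder(G2), G2)
  expect_equal(E2, sweep(G2$values, 2, colMeans(G2$values)),
               ignore_attr = TRUE)
})

test_that("test accessions are encoded on the training scale", {
  set.seed(4)
  vals <- matrix(rbinom(10 * 6, 1, 0.5), nrow = 10)
  vals[9, ] <- vals[1, ]  # test accession identical to a training accession
  G <- toy_genotypes(vals)
  train <- accessions(G)[1:8]
  test <- accessions(G)[9:10]
  enc <- genotype_encoder(G, train)
  Etr <- encode_genotypes(enc, G, train)
  Ete <- encode_genotypes(enc, G, test)
  expect_equal(unname(Ete[1, ]), unname(Etr[1, ]))
  expect_error(genotype_encoder(toy_genotypes(matrix(NA_real_, 4, 1))),
               "zero non-missing")
})
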