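test_that("HapMap calls are coded 0/1/2 with the major allele as reference", {
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap_fixture(path,
    calls_by_marker = list(
      c("AA", "AT", "TT", "AA"),   # A major (5 A vs 3 T)
      c("AA", "AT", "TT", "TT"),   # T major (5 T vs 3 A)
      c("GG", "GG", "GG", "GG"),   # monomorphic
      c("R",  "AA", "GG", "AG")),  # IUPAC single-letter het R = AG
    chrom = c("1", "1", "2", "2"), pos = c(100, 200, 50, 80))
  g <- read_hapmap(path)
  expect_equal(unname(g$values[, "mk1"]), c(0, 1, 2, 0))
  expect_equal(unname(g$values[, "mk2"]), c(2, 1, 0, 0))
  expect_equal(unname(g$values[, "mk3"]), c(0, 0, 0, 0))
  expect_true(g$monomorphic[["mk3"]])
  expect_false(any(g$monomorphic[c("mk1", "mk2")]))
  # mk4: alleles A(4) G(4) tie -> alphabetical major A; R=AG het
  expect_equal(unname(g$values[, "mk4"]), c(1, 0, 2, 1))
  # column mean equals 2 x minor allele frequency from raw calls
  expect_equal(mean(g$values[, "mk1"]), 2 * 3 / 8)
})

test_that("HapMap parser drops multi-allelic markers, imputes missing calls, sorts map", {
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap_fixture(path,
    calls_by_marker = list(
      c("AA", "CC", "GG", "AA"),           # 3 alleles -> dropped
      c("TT", "NN", "TT", "CT"),           # one missing -> mode-imputed (TT)
      c("AA", "AT", "AA", "AA")),
    chrom = c("1", "10", "2"), pos = c(1, 5, 9))
  expect_warning(g <- read_hapmap(path), ">2 alleles")
  expect_equal(ncol(g$values), 2L)
  expect_equal(unname(g$values[, "mk2"]), c(0, 0, 0, 1))
  expect_equal(g$n_imputed, 1L)
  # natural chromosome ordering: 2 before 10
  expect_equal(g$marker_map$chrom, c("2", "10"))
})

test_that("HapMap rejects malformed headers", {
  path <- withr::local_tempfile()
  writeLines(c("a\tb\tc", "1\t2\t3"), path)
  expect_error(read_hapmap(path), "malformed")
})

test_that("numeric genotype round-trips bit-exactly and handles orientation", {
  g <- geno_matrix(matrix(c(0, 1, 2, 0), 2, 2), c("i1", "i2"),
                   data.frame(id = c("m1", "m2"), chrom = "1", pos = 1:2))
  gpath <- withr::local_tempfile(); mpath <- withr::local_tempfile()
  write_numeric(g, gpath, mpath)
  g2 <- read_numeric(gpath, mpath)
  expect_identical(g2$values, g$values)
  expect_identical(g2$marker_map, g$marker_map)
  # markers-in-rows input equals individuals-in-rows of its transpose
  tpath <- withr::local_tempfile()
  tdf <- data.frame(id = colnames(g$values), t(g$values), check.names = FALSE)
  utils::write.table(tdf, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  g3 <- read_numeric(tpath, mpath, orientation = "markers-rows")
  expect_identical(g3$values, g$values)
})

test_that("numeric reader imputes declared missing codes and rejects bad values", {
  gpath <- withr::local_tempfile()
  writeLines(c("taxa\tm1\tm2", "i1\t0\t2", "i2\tNA\t2", "i3\t0\t2"), gpath)
  g <- read_numeric(gpath)
  expect_equal(g$n_imputed, 1L)
  expect_equal(unname(g$values[, "m1"]), c(0, 0, 0))
  bad <- withr::local_tempfile()
  writeLines(c("taxa\tm1", "i1\t3"), bad)
  expect_error(read_numeric(bad), "outside")
})

test_that("phenotype reader aligns ids to genotype order and drops strays", {
  g <- tiny_geno(4, 3, seed = 2)
  ppath <- withr::local_tempfile()
  # shuffled order + one id absent from the genotype
  writeLines(c("taxa\tenvA\tenvB",
               "ind0003\t3\t30", "ind0001\t1\t10", "stranger\t9\t90",
               "ind0004\t4\t40", "ind0002\t2\t20"), ppath)
  expect_warning(ph <- read_phenotype(ppath, g), "dropped")
  expect_equal(ph$individual_ids, g$individual_ids)
  expect_equal(unname(ph$values[, "envA"]), c(1, 2, 3, 4))
  expect_equal(ph$env_names, c("envA", "envB"))
  nop <- withr::local_tempfile()
  writeLines(c("taxa\tenvA", "nobody\t1"), nop)
  expect_error(read_phenotype(nop, g), "overlap")
})

test_that("synthetic genotypes are seed-deterministic with even chromosome split", {
  a <- generate_synthetic_genotypes(100, 500, seed = 1)
  b <- generate_synthetic_genotypes(100, 500, seed = 1)
  expect_identical(a$values, b$values)
  g <- generate_synthetic_genotypes(20, 10, n_chrom = 2, seed = 3)
  expect_equal(as.integer(table(g$marker_map$chrom)), c(5L, 5L))
  expect_error(generate_synthetic_genotypes(10, 10, maf_low = 0.6),
               "maf")
})

test_that("synthetic allele frequencies match their binomial expectation", {
  # at p = 0.5 the grand mean genotype is 1 with SE sqrt(0.5/(n m))
  g <- generate_synthetic_genotypes(2000, 20, maf_low = 0.5, maf_high = 0.5,
                                    seed = 7)
  expect_lt(abs(mean(g$values) - 1), 3 * sqrt(0.5 / (2000 * 20)))
  # empirical per-marker frequencies converge to the drawn p at n = 5000
  n <- 5000; m <- 30
  g2 <- generate_synthetic_genotypes(n, m, n_chrom = 3, maf_low = 0.1,
                                     maf_high = 0.4, seed = 11)
  set.seed(11); p <- runif(m, 0.1, 0.4)  # the generator's documented draw
  phat <- colMeans(g2$values) / 2        # marker order preserves draw order
  se <- sqrt(p * (1 - p) / (2 * n))
  expect_true(all(abs(phat - p) < 3.5 * se))
})
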