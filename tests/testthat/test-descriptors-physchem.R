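test_that("property tables load from AAindex flat files and TSV", {
  pt <- loadPropertyTable(ffExtdata("synthetic_aaindex.txt"),
                          standardize = FALSE)
  expect_s4_class(pt, "PropertyTable")
  expect_identical(pt@accession, "SYNH000001")
  raw <- readLines(ffExtdata("synthetic_aaindex.txt"))
  row1 <- as.numeric(strsplit(trimws(raw[grep("^I ", raw) + 1]), "\\s+")[[1]])
  expect_identical(unname(pt@values["ALA"]), row1[1])
  expect_identical(unname(pt@values["ILE"]), row1[10])

  pt2 <- loadPropertyTable(ffExtdata("synthetic_properties.tsv"),
                           accession = "PTIO830101")
  expect_true(all(featureforge:::AA3 %in% names(pt2@values)))
  expect_true(pt2@standardized)
  expect_lt(abs(mean(pt2@values[featureforge:::AA3])), 1e-12)
  expect_lt(abs(sd(pt2@values[featureforge:::AA3]) - 1), 1e-12)

  ## missing canonical residue is a format error
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("code\tvalue", "ALA\t1.0"), bad)
  expect_error(loadPropertyTable(bad), "missing canonical")

  ## degenerate constant scale still validates
  const <- tempfile(fileext = ".tsv")
  writeLines(c("code\tvalue",
               paste(featureforge:::AA3, "1.0", sep = "\t")), const)
  expect_s4_class(loadPropertyTable(const), "PropertyTable")
})

test_that("non-canonical residues resolve per policy", {
  pt <- loadPropertyTable(ffExtdata("synthetic_properties.tsv"),
                          accession = "KARS160108",
                          ncaaPath = ffExtdata("synthetic_properties_nc.tsv"))
  ## HYP has its own extension entry, distinct from PRO
  expect_false(isTRUE(all.equal(pt@values[["HYP"]], pt@values[["PRO"]])))
  chain <- testChain(n = 12, seed = 61)
  chain <- substituteResidue(chain, 5, "HYP")
  strict <- chainPropertyValues(chain, pt, ncaaPolicy = "strict")
  expect_identical(strict[5], unname(pt@values["HYP"]))
  ## a scale without the MSE entry: fallback inherits MET, strict is NA
  pt2 <- loadPropertyTable(ffExtdata("synthetic_properties.tsv"),
                           accession = "MUNV940103")
  chain2 <- substituteResidue(chain, 5, "MSE")
  expect_identical(chainPropertyValues(chain2, pt2, "fallback")[5],
                   unname(pt2@values["MET"]))
  expect_true(is.na(chainPropertyValues(chain2, pt2, "strict")[5]))
})

test_that("the periodicity descriptor matches term-by-term re-evaluation", {
  for (i in 1:100) {
    set.seed(1000 + i)
    T <- runif(1, 1.5, 15); nT <- sample(2:9, 1); A <- sample(c(0.5, 1, 2, 3), 1)
    n <- round((T * nT - 1) / 2)
    if (n < 1) next
    H <- rnorm(2 * n + 1)
    expect_equal(periodicDescriptorValue(H, T, nT, A),
                 directPeriodic(H, T, nT, A), tolerance = 1e-12)
  }
})

test_that("periodicity descriptor limiting cases are exact", {
  T <- 3.6; nT <- 5; A <- 1
  n <- round((T * nT - 1) / 2)
  expect_identical(periodicDescriptorValue(numeric(2 * n + 1), T, nT, A), 0)
  ## single central residue: cos term 1, sin term 0, f(0) = 1
  H <- numeric(2 * n + 1); H[n + 1] <- -2.7
  expect_equal(periodicDescriptorValue(H, T, nT, A), 2.7, tolerance = 1e-12)
  expect_error(periodicDescriptorValue(numeric(1), 1.2, 1, 1), "too small")
})

test_that("a pure cosine peaks at its own period over the scan grid", {
  T0 <- 3.6; nT <- 5; A <- 0.5
  grid <- seq(2.4, 6.0, by = 0.1)
  vals <- vapply(grid, function(T) {
    n <- round((T * nT - 1) / 2)
    H <- cos(2 * pi * (-n:n) / T0)
    periodicDescriptorValue(H, T, nT, A)
  }, 0)
  expect_equal(grid[which.max(vals)], T0, tolerance = 0.051)
})

test_that("the periodic descriptor is 1-homogeneous and phase-invariant", {
  T <- 3.6; nT <- 5; A <- 1
  n <- round((T * nT - 1) / 2)
  set.seed(17)
  H <- rnorm(2 * n + 1)
  expect_equal(periodicDescriptorValue(-3.5 * H, T, nT, A),
               3.5 * periodicDescriptorValue(H, T, nT, A), tolerance = 1e-12)
  ## shifting the phase of a pure sinusoid leaves the magnitude unchanged.
  ## Exactly so (machine precision) when the window spans whole periods
  ## and no decay reweights the lattice (the discrete double-frequency
  ## cross-term vanishes); approximately so once the Gaussian decay is on.
  Tc <- 3; nTc <- 5                       # 2n+1 = 15 = 5 whole periods
  nc <- round((Tc * nTc - 1) / 2)
  base0 <- periodicDescriptorValue(cos(2 * pi * (-nc:nc) / Tc), Tc, nTc, 0)
  base <- periodicDescriptorValue(cos(2 * pi * (-n:n) / T), T, nT, A)
  for (ph in c(0.3, 1.1, 2.9)) {
    shifted0 <- periodicDescriptorValue(cos(2 * pi * (-nc:nc) / Tc + ph),
                                        Tc, nTc, 0)
    expect_equal(shifted0, base0, tolerance = 1e-9)
    shifted <- periodicDescriptorValue(cos(2 * pi * (-n:n) / T + ph),
                                       T, nT, A)
    expect_lt(abs(shifted - base) / base, 0.1)
  }
})

test_that("window descriptors match the direct-sum oracle", {
  pt <- loadPropertyTable(ffExtdata("synthetic_properties.tsv"),
                          accession = "MUNV940103")
  chain <- testChain(n = 40, seed = 71)
  spec <- windowDescriptorSpec("MUNV940103", left = -5, right = 6, power = 1)
  got <- evaluateWindowDescriptor(chain, spec, pt)
  H <- chainPropertyValues(chain, pt)
  for (p in seq_len(40))
    expect_equal(got[p], directWindow(H, p, -5, 6, A = 1), tolerance = 1e-12)
  ## power enters after the sum
  spec3 <- windowDescriptorSpec("MUNV940103", -5, 6, power = 3)
  got3 <- evaluateWindowDescriptor(chain, spec3, pt)
  expect_equal(got3, got^3, tolerance = 1e-12)
})

test_that("window descriptor boundary and linearity contracts hold", {
  const <- propertyTable(structure(rep(1, 20), names = featureforge:::AA3),
                         standardize = FALSE)
  chain <- testChain(n = 20, seed = 72)
  ## unweighted five-residue window sums to 5 in the interior
  spec <- windowDescriptorSpec("c", -2, 2, A = 0, power = 1)
  v <- evaluateWindowDescriptor(chain, spec, const)
  expect_equal(v[3:18], rep(5, 16))
  expect_equal(v[1], 3)                     # two offsets fall off-chain
  ## a window entirely left of the chain start gives 0
  specL <- windowDescriptorSpec("c", -10, -3, A = 0, power = 1)
  expect_equal(evaluateWindowDescriptor(chain, specL, const)[1], 0)
  ## with A = 0, power = 1 the descriptor is linear in the table
  pt1 <- genPropertyTable(seed = 81, standardize = FALSE)
  pt2 <- genPropertyTable(seed = 82, standardize = FALSE)
  ptSum <- propertyTable(pt1@values + pt2@values[names(pt1@values)],
                         standardize = FALSE)
  s <- windowDescriptorSpec("c", -3, 4, A = 0, power = 1)
  expect_equal(evaluateWindowDescriptor(chain, s, ptSum),
               evaluateWindowDescriptor(chain, s, pt1) +
                 evaluateWindowDescriptor(chain, s, pt2), tolerance = 1e-12)
})

test_that("one-hot and terminal features follow their contracts", {
  chain <- testChain(n = 12, seed = 91)
  chain <- substituteResidue(chain, 6, "MSE")
  X <- categoricalFeatures(chain)
  ## exactly one identity bit per residue
  idCols <- grep("^is_", colnames(X))
  expect_true(all(rowSums(X[, idCols]) == 1))
  expect_identical(unname(X[6, "is_MSE"]), 1)
  expect_identical(unname(X[6, "is_MET"]), 0)
  ## N-terminal proximity: first three residues only
  expect_identical(unname(X[, "End_N_3"]),
                   as.numeric(seq_len(12) <= 3))
  expect_identical(unname(X[3, "End_N_3"]), 1)
  expect_identical(unname(X[4, "End_N_3"]), 0)
  ## unknown code: all-zero identity row
  chain2 <- testChain(n = 12, seed = 92)
  chain2@seq3[2] <- "QQQ"
  X2 <- categoricalFeatures(chain2)
  expect_identical(sum(X2[2, idCols]), 0)
  ## optional C-terminal column
  X3 <- categoricalFeatures(chain, endC = TRUE)
  expect_identical(unname(X3[, "End_C_3"]),
                   as.numeric(seq_len(12) > 9))
})

test_that("disorder scores clamp, power and propagate gaps", {
  sc <- data.frame(position = c(1, 2, 4), score = c(0, 0.5, 1))
  v <- disorderDescriptor(sc, n = 5, power = 3)
  expect_equal(v[1:2], c(0, 0.125))
  expect_equal(v[4], 1)
  expect_true(all(is.na(v[c(3, 5)])))
  expect_warning(disorderDescriptor(
    data.frame(position = 1, score = 1.2), n = 2), "clamped")
  f <- tempfile(fileext = ".tsv")
  write.table(sc, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(disorderDescriptor(f, n = 5, power = 1)[2], 0.5)
})

test_that("canonical chains are unaffected by non-canonical support", {
  pt <- loadPropertyTable(ffExtdata("synthetic_properties.tsv"),
                          accession = "KARS160108",
                          ncaaPath = ffExtdata("synthetic_properties_nc.tsv"))
  ptNoNc <- loadPropertyTable(ffExtdata("synthetic_properties.tsv"),
                              accession = "KARS160108")
  chain <- testChain(n = 25, seed = 93)   # fully canonical
  spec <- periodicDescriptorSpec("KARS160108", T = 3.6, nT = 5, A = 1)
  expect_identical(evaluatePeriodicDescriptor(chain, spec, pt),
                   evaluatePeriodicDescriptor(chain, spec, ptNoNc))
  wspec <- windowDescriptorSpec("KARS160108", -5, 5, power = 2)
  expect_identical(evaluateWindowDescriptor(chain, wspec, pt),
                   evaluateWindowDescriptor(chain, wspec, ptNoNc))
})

test_that("periodic evaluation over a chain matches windowed recomputation", {
  pt <- loadPropertyTable(ffExtdata("synthetic_properties.tsv"),
                          accession = "MIYS990102")
  chain <- testChain(n = 30, seed = 94)
  spec <- periodicDescriptorSpec("MIYS990102", T = 3.6, nT = 5, A = 1,
                                 power = 2)
  got <- evaluatePeriodicDescriptor(chain, spec, pt)
  H <- chainPropertyValues(chain, pt)
  n <- round((spec$T * spec$nT - 1) / 2)
  for (p in c(1, 5, 15, 30)) {
    win <- vapply(p + (-n:n), function(q)
      if (q >= 1 && q <= 30) H[q] else 0, 0)
    expect_equal(got[p], directPeriodic(win, spec$T, spec$nT, spec$A)^2,
                 tolerance = 1e-12)
  }
})
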