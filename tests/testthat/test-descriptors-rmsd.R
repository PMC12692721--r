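test_that("the t statistic matches direct arithmetic on synthetic statistics", {
  ## hand-built accumulator state: key observed 4 times with known moments
  alph <- loadAlphabets()["Full5"]
  stats <- featureforge:::emptyPBStats(alph)
  stats@globalN <- 1e6
  stats@globalMean <- rep(5, 16)
  stats@globalM2 <- rep(2 * (1e6 - 1), 16)    # global variance 2
  key <- patternKey("AAAAA", alph$Full5)
  assign(key, list(n = 4, mean = rep(3, 16), m2 = rep(3, 16)),  # var 1
         envir = stats@keyStats[["Full5"]])
  t <- tStatistic(stats, "Full5", key, 1)
  expect_equal(t, 2 / sqrt(0.25 + 2e-6), tolerance = 1e-12)
  expect_equal(t, directTStat(5, 3, 1, 4, 2, 1e6), tolerance = 1e-12)
  ## zero numerator
  assign(key, list(n = 4, mean = rep(5, 16), m2 = rep(3, 16)),
         envir = stats@keyStats[["Full5"]])
  expect_equal(tStatistic(stats, "Full5", key, 1), 0)
  ## single occurrence: undefined
  assign(key, list(n = 1, mean = rep(3, 16), m2 = rep(0, 16)),
         envir = stats@keyStats[["Full5"]])
  expect_true(is.na(tStatistic(stats, "Full5", key, 1)))
  ## constant sample with zero global-variance share: clamped
  stats@globalM2 <- rep(0, 16)
  assign(key, list(n = 4, mean = rep(3, 16), m2 = rep(0, 16)),
         envir = stats@keyStats[["Full5"]])
  expect_equal(abs(tStatistic(stats, "Full5", key, 1)), 38)
})

test_that("the large-corpus limit folds into the two-term form", {
  ## with N >> N_occ the corpus-variance term vanishes:
  ## t ~ (mu - mu_seq) * sqrt(N_occ) / sd_seq
  for (i in 1:100) {
    set.seed(i)
    mu <- runif(1, 2, 6); muSeq <- runif(1, 1, 5)
    varSeq <- runif(1, 0.2, 3); nOcc <- sample(2:50, 1)
    varG <- runif(1, 0.5, 4)
    full6 <- directTStat(mu, muSeq, varSeq, nOcc, varG, 1e6 * nOcc)
    full10 <- directTStat(mu, muSeq, varSeq, nOcc, varG, 1e10 * nOcc)
    folded <- (mu - muSeq) * sqrt(nOcc) / sqrt(varSeq)
    ## the folding error shrinks as the corpus grows ...
    expect_lte(abs(full10 - folded), abs(full6 - folded))
    ## ... and is below 1e-6 once the corpus dwarfs the key count
    expect_lt(abs(full10 - folded), 1e-6)
  }
})

test_that("the probability transform is the standard normal CDF", {
  expect_equal(tToProbability(0), 0.5)
  expect_equal(tToProbability(38), 1.0)
  expect_equal(tToProbability(-38), 0.0, tolerance = 1e-12)
  expect_equal(tToProbability(1.959964), 0.975, tolerance = 1e-4)
  ## monotone
  ts <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(tToProbability(ts)) > 0))
})

test_that("block-string probabilities match brute-force counting", {
  ## toy corpus: three keys with hand-countable assigned strings
  alph <- loadAlphabets()["Full5"]
  chains <- list(
    genChain(list(c("helix", 9)), seed = 1, seq1 = rep("A", 9)),
    genChain(list(c("helix", 9)), seed = 2, seq1 = rep("G", 9)),
    genChain(list(c("strand", 9)), seed = 3, seq1 = rep("G", 9)))
  stats <- accumulatePBStats(chains, alph)
  keyA <- patternKey("AAAAA", alph$Full5)
  keyG <- patternKey("GGGGG", alph$Full5)
  ## brute-force: recount strings directly from the chains
  pb <- proteinBlockSet()
  countStrings <- function(chain) {
    lets <- assignPBLetters(fragmentRmsdVectors(chain, pb))
    out <- character(0)
    for (p in 3:7) {
      win <- lets[(p - 2):(p + 2)]
      if (!anyNA(win)) out <- c(out, paste(win, collapse = ""))
    }
    out
  }
  sA <- countStrings(chains[[1]])
  sG <- c(countStrings(chains[[2]]), countStrings(chains[[3]]))
  vocab <- unique(c(sA, sG))
  V <- length(vocab)
  for (q in vocab) {
    expect_equal(pbSequenceProbability(stats, "Full5", keyA, q),
                 (sum(sA == q) + 1) / (length(sA) + V), tolerance = 1e-12)
    expect_equal(pbSequenceProbability(stats, "Full5", keyG, q),
                 (sum(sG == q) + 1) / (length(sG) + V), tolerance = 1e-12)
  }
  ## unseen key: uniform prior
  keyU <- patternKey("WWWWW", alph$Full5)
  expect_equal(pbSequenceProbability(stats, "Full5", keyU, "mmmmm"), 1 / V)
  ## degenerate corpus: all-helix key is near-certain 'mmmmm'
  pA <- pbSequenceProbability(stats, "Full5", keyA, "mmmmm")
  expect_equal(pA, (length(sA) + 1) / (length(sA) + V))
  ## shorter query matches the centred substring
  p3 <- pbSequenceProbability(stats, "Full5", keyA, "mmm")
  expect_gte(p3, pA)
})

test_that("descriptor matrix evaluation matches the per-position oracle", {
  alphabets <- loadAlphabets()["Full5"]
  stats <- testStats(nChains = 3, alphabets = alphabets)
  chain <- testChain(n = 30, seed = 99, noiseSd = 10)
  specs <- list(
    rmsdDescriptorSpec("Full5", "m", offset = 0, power = 1),
    rmsdDescriptorSpec("Full5", "m", offset = 5, power = 1),
    rmsdDescriptorSpec("Full5", "d", offset = -4, power = 2),
    rmsdDescriptorSpec("Full5", "mmmmm", offset = 0, power = 1),
    rmsdDescriptorSpec("Full5", "ddfmm", offset = 2, power = 2))
  M <- evaluateRmsdDescriptors(chain, specs, stats, alphabets)
  expect_identical(dim(M), c(30L, 5L))
  keys <- featureforge:::chainPatternKeys(chain@seq1, alphabets$Full5)
  for (ci in seq_along(specs)) {
    s <- specs[[ci]]
    for (p in seq_len(30)) {
      q <- p + s$offset
      want <- if (q < 1 || q > 30 || is.na(keys[q])) NA_real_ else {
        base <- if (s$kind == "t_stat")
          tToProbability(tStatistic(stats, "Full5", keys[q], s$pb))
        else pbSequenceProbability(stats, "Full5", keys[q], s$pb)
        if (is.na(base)) NA_real_ else base^s$power
      }
      expect_equal(unname(M[p, ci]), want, tolerance = 1e-12)
    }
  }
  ## power = 2 column equals the square of the power = 1 column
  s1 <- list(rmsdDescriptorSpec("Full5", "mmmmm", 0, 1),
             rmsdDescriptorSpec("Full5", "mmmmm", 0, 2))
  M2 <- evaluateRmsdDescriptors(chain, s1, stats, alphabets)
  expect_equal(unname(M2[, 2]), unname(M2[, 1])^2, tolerance = 1e-12)
  ## permuting specs permutes columns identically
  M3 <- evaluateRmsdDescriptors(chain, rev(specs), stats, alphabets)
  expect_equal(unname(M3), unname(M[, 5:1]), tolerance = 0)
  ## unknown alphabet is a config error
  expect_error(evaluateRmsdDescriptors(
    chain, list(rmsdDescriptorSpec("nope", "m")), stats, alphabets),
    "absent")
})

test_that("increasing the key mean strictly decreases the descriptor", {
  probs <- vapply(seq(2, 4, by = 0.5), function(muSeq)
    tToProbability(directTStat(5, muSeq, 1, 10, 2, 1e5)), 0)
  expect_true(all(diff(probs) < 0))
})

test_that("offset-induced missingness matches window geometry exactly", {
  alphabets <- loadAlphabets()["Full5"]
  stats <- testStats(nChains = 2, alphabets = alphabets)
  chain <- testChain(n = 25, seed = 7, noiseSd = 10)
  off <- 3
  M <- evaluateRmsdDescriptors(
    chain, list(rmsdDescriptorSpec("Full5", "m", offset = off)), stats,
    alphabets)
  ## defined iff p + off lies in [3, n-2] (key window) -- fully resolved chain
  expected <- (seq_len(25) + off) >= 3 & (seq_len(25) + off) <= 23
  ## ...provided the key was seen at least twice in the training corpus
  keys <- featureforge:::chainPatternKeys(chain@seq1, alphabets$Full5)
  seen <- vapply(seq_len(25), function(p) {
    q <- p + off
    if (q < 1 || q > 25 || is.na(keys[q])) return(FALSE)
    ks <- pbKeyStats(stats, "Full5", keys[q])
    !is.null(ks) && ks$n >= 2
  }, TRUE)
  expect_identical(!is.na(M[, 1]), expected & seen)
})
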