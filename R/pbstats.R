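## Streaming accumulation of per-key and global RMSD statistics, and of
## assigned protein-block strings per key.

emptyPBStats <- function(alphabets, blockLabels = PB_LETTERS) {
  nm <- names(alphabets)
  new("PBStats",
      blockLabels = blockLabels,
      alphabetNames = nm,
      fragmentLengths = structure(
        vapply(alphabets, function(a) a@fragmentLength, 0L), names = nm),
      globalN = 0,
      globalMean = numeric(16),
      globalM2 = numeric(16),
      keyStats = structure(lapply(nm, function(.) new.env(parent = emptyenv())),
                           names = nm),
      pbStrings = structure(lapply(nm, function(.) new.env(parent = emptyenv())),
                            names = nm),
      stringVocab = structure(lapply(nm, function(.) new.env(parent = emptyenv())),
                              names = nm),
      alphabetN = structure(numeric(length(nm)), names = nm))
}

## one Welford update of (n, mean, m2) with a 16-vector x
welfordUpdate <- function(state, x) {
  n <- state$n + 1
  delta <- x - state$mean
  mean <- state$mean + delta / n
  m2 <- state$m2 + delta * (x - mean)
  list(n = n, mean = mean, m2 = m2)
}

#' Accumulate protein-block RMSD statistics over a chain corpus
#'
#' Single pass over all chains. For every position with a defined
#' pentapeptide RMSD profile, updates (a) the global per-block streaming
#' mean/variance, and, for each reduced alphabet whose key window is
#' defined at that position, (b) the key-conditional per-block statistics
#' and (c) the count of the assigned block-letter string over the key
#' window (used by PB-string probability descriptors). Mean and variance
#' use Welford's numerically stable one-pass recurrence; variances are
#' unbiased (divisor n-1) and undefined for single-occurrence keys.
#'
#' @param chains list of [ProteinChain-class] with backbone coordinates.
#' @param alphabets named list of [ReducedAlphabet-class].
#' @param pbset a [ProteinBlockSet-class].
#' @return A [PBStats-class].
#' @export
accumulatePBStats <- function(chains, alphabets, pbset = proteinBlockSet()) {
  if (methods::is(chains, "ProteinChain")) chains <- list(chains)
  stats <- emptyPBStats(alphabets, pbset@labels)
  gN <- 0; gMean <- numeric(16); gM2 <- numeric(16)
  aN <- stats@alphabetN
  for (chain in chains) {
    rv <- fragmentRmsdVectors(chain, pbset)
    pbLetters <- assignPBLetters(rv)
    keys <- lapply(alphabets, function(a) chainPatternKeys(chain@seq1, a))
    defined <- which(!apply(rv, 1, anyNA))
    for (p in defined) {
      x <- unname(rv[p, ])
      gN <- gN + 1
      delta <- x - gMean
      gMean <- gMean + delta / gN
      gM2 <- gM2 + delta * (x - gMean)
      for (a in names(alphabets)) {
        key <- keys[[a]][p]
        if (is.na(key)) next
        env <- stats@keyStats[[a]]
        st <- if (exists(key, envir = env, inherits = FALSE))
          get(key, envir = env, inherits = FALSE)
        else list(n = 0, mean = numeric(16), m2 = numeric(16))
        assign(key, welfordUpdate(st, x), envir = env)
        aN[[a]] <- aN[[a]] + 1
        ## assigned PB string over the key window
        L <- alphabets[[a]]@fragmentLength
        h <- (L - 1L) %/% 2L
        win <- (p - h):(p + h)
        if (min(win) >= 1 && max(win) <= length(pbLetters)) {
          lets <- pbLetters[win]
          if (!anyNA(lets)) {
            s <- paste(lets, collapse = "")
            senv <- stats@pbStrings[[a]]
            cnt <- if (exists(key, envir = senv, inherits = FALSE))
              get(key, envir = senv, inherits = FALSE) else integer(0)
            cnt[s] <- (if (s %in% names(cnt)) cnt[[s]] else 0L) + 1L
            assign(key, cnt, envir = senv)
            assign(s, TRUE, envir = stats@stringVocab[[a]])
          }
        }
      }
    }
  }
  if (gN == 0) warning("no defined fragments: empty statistics")
  stats@globalN <- gN
  stats@globalMean <- gMean
  stats@globalM2 <- gM2
  stats@alphabetN <- aN
  stats
}

#' @rdname accumulatePBStats
#' @param stats a [PBStats-class].
#' @export
pbGlobalMean <- function(stats) {
  structure(stats@globalMean, names = stats@blockLabels)
}

#' @rdname accumulatePBStats
#' @export
pbGlobalVar <- function(stats) {
  v <- if (stats@globalN > 1) stats@globalM2 / (stats@globalN - 1)
       else rep(NA_real_, 16)
  structure(v, names = stats@blockLabels)
}

#' @rdname accumulatePBStats
#' @param alphabet alphabet name.
#' @param key pattern key string.
#' @export
pbKeyStats <- function(stats, alphabet, key) {
  env <- stats@keyStats[[alphabet]]
  if (is.null(env)) stop("alphabet not accumulated: ", alphabet)
  if (!exists(key, envir = env, inherits = FALSE)) return(NULL)
  st <- get(key, envir = env, inherits = FALSE)
  list(n = st$n,
       mean = structure(st$mean, names = stats@blockLabels),
       var = if (st$n > 1) structure(st$m2 / (st$n - 1),
                                     names = stats@blockLabels)
             else structure(rep(NA_real_, 16), names = stats@blockLabels))
}

#' @rdname accumulatePBStats
#' @export
pbStatsKeys <- function(stats, alphabet) ls(stats@keyStats[[alphabet]])

#' Serialize / restore accumulated statistics
#'
#' Writes the accumulator to a portable JSON file (header with alphabet
#' names, block labels and totals; per-key records) and reads it back.
#'
#' @param stats a [PBStats-class].
#' @param path output file.
#' @export
writePBStats <- function(stats, path) {
  keyed <- lapply(stats@alphabetNames, function(a) {
    keys <- ls(stats@keyStats[[a]])
    lapply(structure(keys, names = keys), function(k) {
      st <- get(k, envir = stats@keyStats[[a]], inherits = FALSE)
      strings <- if (exists(k, envir = stats@pbStrings[[a]], inherits = FALSE))
        as.list(get(k, envir = stats@pbStrings[[a]], inherits = FALSE))
      else list()
      list(n = st$n, mean = st$mean, m2 = st$m2, strings = strings)
    })
  })
  names(keyed) <- stats@alphabetNames
  obj <- list(block_labels = stats@blockLabels,
              alphabets = stats@alphabetNames,
              fragment_lengths = as.list(stats@fragmentLengths),
              global_n = stats@globalN, global_mean = stats@globalMean,
              global_m2 = stats@globalM2,
              alphabet_n = as.list(stats@alphabetN), keys = keyed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePBStats
#' @export
readPBStats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nm <- unlist(obj$alphabets)
  stats <- new("PBStats",
               blockLabels = unlist(obj$block_labels),
               alphabetNames = nm,
               fragmentLengths = structure(
                 as.integer(unlist(obj$fragment_lengths)), names = nm),
               globalN = obj$global_n,
               globalMean = as.numeric(unlist(obj$global_mean)),
               globalM2 = as.numeric(unlist(obj$global_m2)),
               keyStats = structure(
                 lapply(nm, function(.) new.env(parent = emptyenv())),
                 names = nm),
               pbStrings = structure(
                 lapply(nm, function(.) new.env(parent = emptyenv())),
                 names = nm),
               stringVocab = structure(
                 lapply(nm, function(.) new.env(parent = emptyenv())),
                 names = nm),
               alphabetN = structure(as.numeric(unlist(obj$alphabet_n)),
                                     names = nm))
  for (a in nm) {
    for (k in names(obj$keys[[a]])) {
      rec <- obj$keys[[a]][[k]]
      assign(k, list(n = rec$n, mean = as.numeric(unlist(rec$mean)),
                     m2 = as.numeric(unlist(rec$m2))),
             envir = stats@keyStats[[a]])
      if (length(rec$strings)) {
        cnt <- structure(as.integer(unlist(rec$strings)),
                         names = names(rec$strings))
        assign(k, cnt, envir = stats@pbStrings[[a]])
        for (s in names(cnt)) assign(s, TRUE, envir = stats@stringVocab[[a]])
      }
    }
  }
  stats
}
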