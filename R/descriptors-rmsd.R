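## RMSD-statistic descriptors: Welch-style t statistics per (key, block),
## probability transforms, and protein-block string probabilities.

T_CLAMP <- 38   # |t| beyond which the normal CDF saturates in double precision

#' RMSD descriptor specification
#'
#' A parameterized recipe producing one feature column from accumulated
#' protein-block RMSD statistics. Single-letter `pb` entries denote
#' t-statistic descriptors for that block; multi-letter entries denote
#' block-string probability descriptors.
#'
#' @param alphabet reduced-alphabet name (must be present in the stats).
#' @param pb one block letter (a..p) or a block-letter string.
#' @param offset displacement in residues from the central position at
#'   which the descriptor is evaluated.
#' @param power positive integer applied after the probability transform.
#' @param kind `"t_stat"` or `"pb_seq_prob"`; inferred from `nchar(pb)`
#'   by default.
#' @return an object of class `RmsdDescriptorSpec`.
#' @export
rmsdDescriptorSpec <- function(alphabet, pb, offset = 0L, power = 1L,
                               kind = if (nchar(pb) > 1L) "pb_seq_prob"
                                      else "t_stat") {
  stopifnot(power >= 1, nchar(pb) >= 1)
  pb <- tolower(pb)
  if (!all(strsplit(pb, "")[[1]] %in% PB_LETTERS))
    stop("pb must use block letters a..p")
  kind <- match.arg(kind, c("t_stat", "pb_seq_prob"))
  structure(list(alphabet = alphabet, pb = pb, offset = as.integer(offset),
                 power = as.integer(power), kind = kind),
            class = "RmsdDescriptorSpec")
}

#' @export
print.RmsdDescriptorSpec <- function(x, ...) {
  cat(sprintf("RmsdDescriptorSpec[%s]: %s / '%s', offset %+d, power %d\n",
              x$kind, x$alphabet, x$pb, x$offset, x$power))
  invisible(x)
}

#' Welch-style t statistic of a pattern key against the corpus
#'
#' Compares the key-conditional mean RMSD to block `j` with the corpus
#' mean: `t = (mu_j - mu_j(key)) / s_j(key)` where
#' `s_j(key) = sqrt(var_j(key)/N_occ + var_j/N)`. Positive values mean the
#' key's fragments lie closer to the block than the corpus average.
#'
#' Keys observed fewer than twice have no defined variance and return NA
#' (imputed downstream); a zero standard error returns the clamped value
#' +/-38, where the normal CDF already saturates.
#'
#' @param stats a [PBStats-class].
#' @param alphabet alphabet name.
#' @param key pattern key string.
#' @param j block index (1..16) or block letter.
#' @return dimensionless t (NA when undefined).
#' @export
tStatistic <- function(stats, alphabet, key, j) {
  if (is.character(j)) j <- match(j, stats@blockLabels)
  ks <- pbKeyStats(stats, alphabet, key)
  if (is.null(ks) || ks$n < 2) return(NA_real_)
  gv <- pbGlobalVar(stats)
  num <- stats@globalMean[j] - ks$mean[[j]]
  s2 <- ks$var[[j]] / ks$n + gv[[j]] / stats@globalN
  if (s2 <= 0) return(sign(num) * T_CLAMP)
  unname(num / sqrt(s2))
}

#' Probability transform of a t statistic
#'
#' Standard normal CDF: the probability that fragments with this key are
#' closer to the block than the corpus average. Monotone increasing in t.
#'
#' @param t numeric (vectorized).
#' @return values in \[0, 1\].
#' @export
tToProbability <- function(t) stats::pnorm(t)

#' Probability of a protein-block string for a pattern key
#'
#' Laplace-smoothed frequency of the assigned block-letter string over the
#' key window: `(count + 1) / (N + V)` where `N` is the number of counted
#' windows for the key and `V` the number of distinct block strings
#' observed for the alphabet. A query shorter than the window matches the
#' centred substring of the counted strings. Unseen keys return the
#' uniform prior `1/V`.
#'
#' @param stats a [PBStats-class].
#' @param alphabet alphabet name.
#' @param key pattern key string.
#' @param pbString block-letter string (length at most the key window).
#' @return probability in (0, 1).
#' @export
pbSequenceProbability <- function(stats, alphabet, key, pbString) {
  pbString <- tolower(pbString)
  L <- stats@fragmentLengths[[alphabet]]
  m <- nchar(pbString)
  if (m > L) stop("pbString longer than the alphabet key window")
  V <- length(ls(stats@stringVocab[[alphabet]]))
  if (V == 0) stop("no block strings accumulated for alphabet ", alphabet)
  senv <- stats@pbStrings[[alphabet]]
  if (!exists(key, envir = senv, inherits = FALSE)) return(1 / V)
  cnt <- get(key, envir = senv, inherits = FALSE)
  if (m == L) {
    hit <- if (pbString %in% names(cnt)) cnt[[pbString]] else 0L
  } else {
    start <- (L - m) %/% 2L + 1L
    sub <- substr(names(cnt), start, start + m - 1L)
    hit <- sum(cnt[sub == pbString])
  }
  n <- sum(cnt)
  (hit + 1) / (n + V)
}

#' Evaluate RMSD descriptor columns over a chain
#'
#' For each position `p` and spec, the underlying quantity is computed at
#' position `p + offset`: the pattern key under the spec's alphabet, then
#' either the normal-CDF-transformed t statistic of the spec's block
#' (single letter) or the block-string probability (multi-letter), raised
#' to the spec's power. Out-of-range positions and undefined statistics
#' yield NA (imputed after standardization).
#'
#' @param chain a [ProteinChain-class].
#' @param specs list of [rmsdDescriptorSpec()] objects.
#' @param stats a [PBStats-class].
#' @param alphabets named list of compiled [ReducedAlphabet-class] used to
#'   key the chain (must include every spec's alphabet).
#' @return numeric matrix, one column per spec in spec order.
#' @export
evaluateRmsdDescriptors <- function(chain, specs, stats, alphabets) {
  n <- chainLength(chain)
  used <- unique(vapply(specs, function(s) s$alphabet, ""))
  missingA <- setdiff(used, stats@alphabetNames)
  if (length(missingA))
    stop("alphabet(s) absent from stats: ", paste(missingA, collapse = ", "))
  keyCache <- lapply(structure(used, names = used), function(a)
    chainPatternKeys(chain@seq1, alphabets[[a]]))
  out <- matrix(NA_real_, nrow = n, ncol = length(specs))
  colnames(out) <- vapply(specs, function(s)
    sprintf("%s_%s_%s_o%+d_p%d", s$kind, s$alphabet, s$pb, s$offset, s$power), "")
  for (ci in seq_along(specs)) {
    s <- specs[[ci]]
    keys <- keyCache[[s$alphabet]]
    cache <- new.env(parent = emptyenv())
    for (p in seq_len(n)) {
      q <- p + s$offset
      if (q < 1 || q > n) next
      key <- keys[q]
      if (is.na(key)) next
      val <- if (exists(key, envir = cache, inherits = FALSE))
        get(key, envir = cache, inherits = FALSE)
      else {
        v <- if (s$kind == "t_stat")
          tToProbability(tStatistic(stats, s$alphabet, key,
                                    match(s$pb, stats@blockLabels)))
        else pbSequenceProbability(stats, s$alphabet, key, s$pb)
        assign(key, v, envir = cache)
        v
      }
      out[p, ci] <- if (is.na(val)) NA_real_ else val ^ s$power
    }
  }
  out
}
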