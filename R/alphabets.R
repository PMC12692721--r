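## Position-dependent reduced alphabets and pattern keys.

WILDCARD_CLASS <- "*"

## build one position's letter -> class-id map from a grouping spec
compilePositionMap <- function(groups, wildcard, where) {
  if (identical(groups, "full"))
    groups <- as.list(AA1)
  letters1 <- unlist(groups)
  if (anyDuplicated(letters1))
    stop("alphabet config error at position ", where,
         ": letter in more than one group (",
         paste(unique(letters1[duplicated(letters1)]), collapse = ","), ")")
  map <- character(0)
  for (g in seq_along(groups)) {
    grp <- toupper(unlist(groups[[g]]))
    map[grp] <- paste0("c", g)
  }
  missing <- setdiff(AA1, names(map))
  if (length(missing)) {
    if (!wildcard)
      stop("alphabet config error at position ", where,
           ": letters not covered and wildcard disabled (",
           paste(missing, collapse = ","), ")")
    map[missing] <- WILDCARD_CLASS
  }
  if (wildcard) map["X"] <- WILDCARD_CLASS
  map
}

#' Compile a reduced alphabet from a config list
#'
#' The config mirrors one entry of `alphabets.yaml`: `name`,
#' `fragment_length`, and either `all_positions` (one grouping applied at
#' every position, or the string `"full"` for the identity alphabet) or
#' `positions` (one grouping per fragment position). Groups within a
#' position must be disjoint; letters left uncovered fall into a single
#' wildcard class when `wildcard: true`, otherwise compilation fails.
#'
#' @param spec named list as read from YAML.
#' @return A [ReducedAlphabet-class] with O(1) per-position lookup.
#' @export
compileAlphabet <- function(spec) {
  L <- as.integer(spec$fragment_length)
  if (is.na(L) || L < 1 || L %% 2 == 0)
    stop("alphabet config error: fragment_length must be a positive odd integer")
  wildcard <- isTRUE(spec$wildcard)
  if (!is.null(spec$all_positions)) {
    m <- compilePositionMap(spec$all_positions, wildcard, "all")
    maps <- rep(list(m), L)
  } else if (!is.null(spec$positions)) {
    if (length(spec$positions) != L)
      stop("alphabet config error: positions length != fragment_length")
    maps <- lapply(seq_len(L), function(i)
      compilePositionMap(spec$positions[[i]], wildcard, i))
  } else stop("alphabet config error: need all_positions or positions")
  new("ReducedAlphabet", name = as.character(spec$name), fragmentLength = L,
      classMaps = maps, wildcard = wildcard,
      unverified = isTRUE(spec$unverified))
}

#' Load a reduced-alphabet catalog from YAML
#'
#' @param path YAML file with a top-level `alphabets:` list; defaults to
#'   the shipped catalog (Full3/5/7/11 plus example groupings).
#' @return named list of [ReducedAlphabet-class] objects.
#' @export
loadAlphabets <- function(path = ffExtdata("alphabets.yaml")) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg$alphabets, compileAlphabet)
  names(out) <- vapply(out, function(a) a@name, "")
  out
}

#' Pattern key of a sequence fragment under a reduced alphabet
#'
#' Deterministic key: concatenation of the per-position class identifiers
#' of the fragment's letters. Two fragments share a key iff they are
#' equivalent under the alphabet. Non-canonical letters must already be
#' mapped to canonical one-letter codes; 'X' maps to the wildcard class
#' when the alphabet enables one, otherwise it is an error.
#'
#' @param fragment one-letter string of length `fragmentLength`, or a
#'   character vector of single letters.
#' @param alphabet a [ReducedAlphabet-class].
#' @return single key string.
#' @export
patternKey <- function(fragment, alphabet) {
  letters1 <- if (length(fragment) == 1L && nchar(fragment) > 1L)
    strsplit(fragment, "")[[1]] else fragment
  L <- alphabet@fragmentLength
  if (length(letters1) != L)
    stop("fragment length ", length(letters1), " != alphabet length ", L)
  cls <- character(L)
  for (i in seq_len(L)) {
    v <- alphabet@classMaps[[i]][letters1[i]]
    if (is.na(v))
      stop("letter '", letters1[i], "' outside alphabet '", alphabet@name,
           "' at position ", i, " and no wildcard class")
    cls[i] <- v
  }
  paste(cls, collapse = "|")
}

## vectorized keys for every position of a chain; NA at positions whose
## window leaves the chain
chainPatternKeys <- function(seq1, alphabet) {
  n <- length(seq1)
  L <- alphabet@fragmentLength
  h <- (L - 1L) %/% 2L
  out <- rep(NA_character_, n)
  if (n < L) return(out)
  classes <- lapply(alphabet@classMaps, function(m) unname(m[seq1]))
  for (p in (h + 1L):(n - h)) {
    cls <- vapply(seq_len(L), function(i) classes[[i]][p - h - 1L + i], "")
    out[p] <- if (anyNA(cls)) NA_character_ else paste(cls, collapse = "|")
  }
  out
}

#' Count distinct pattern keys of an alphabet (combinatorial)
#'
#' The number of distinct keys an alphabet can produce equals the product
#' over positions of the number of distinct classes at that position
#' (wildcard class included only when enabled).
#'
#' @param alphabet a [ReducedAlphabet-class].
#' @return numeric count (may exceed integer range).
#' @export
countPatternKeys <- function(alphabet) {
  prod(vapply(alphabet@classMaps,
              function(m) length(unique(unname(m))), 0))
}
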