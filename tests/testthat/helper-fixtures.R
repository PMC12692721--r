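## Programmatic plain-text fixtures: minimal PDB and DSSP writers used to
## exercise the file parsers without any stored binary data.

## write chain backbone as PDB ATOM/HETATM records (N, CA, C only)
writePdbFixture <- function(path, chain, chainId = "A",
                            dropAtoms = list(), hetero = character(0)) {
  lines <- c("HEADER    SYNTHETIC FIXTURE")
  serial <- 0
  bb <- chainBackbone(chain)
  for (i in seq_len(chainLength(chain))) {
    for (a in 1:3) {
      nm <- c("N", "CA", "C")[a]
      if (!is.null(dropAtoms[[as.character(i)]]) &&
          nm %in% dropAtoms[[as.character(i)]]) next
      serial <- serial + 1
      rec <- if (chain@seq3[i] %in% hetero) "HETATM" else "ATOM  "
      lines <- c(lines, sprintf(
        "%s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        rec, serial, paste0(" ", nm), chain@seq3[i], chainId, i,
        bb[i, a, 1], bb[i, a, 2], bb[i, a, 3],
        substr(nm, 1, 1)))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

## write a classic DSSP-style residue table for one chain
writeDsspFixture <- function(path, resno, aa, ss, chainId = "A") {
  lines <- c(
    "==== Secondary Structure Definition (fixture) ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    vapply(seq_along(resno), function(i)
      sprintf("%5d%5d %s %s  %s", i, resno[i], chainId, aa[i], ss[i]), ""))
  writeLines(lines, path)
  path
}

## small multi-segment chain used by several descriptor tests
testChain <- function(n = 30, seed = 11, noiseSd = 0) {
  stopifnot(n >= 10)
  h <- max(4, n %/% 3)
  s <- max(3, n %/% 4)
  c1 <- max(1, (n - h - s) %/% 2)
  c2 <- n - h - s - c1
  genChain(list(c("coil", c1), c("helix", h), c("strand", s),
                c("coil", max(c2, 1))), noiseSd = noiseSd, seed = seed)
}

## tiny corpus + Full5 alphabet stats used by RMSD descriptor tests
testStats <- function(nChains = 4, seed = 5,
                      alphabets = loadAlphabets()["Full5"]) {
  chains <- lapply(seq_len(nChains), function(i)
    testChain(seed = seed + i, noiseSd = 10))
  accumulatePBStats(chains, alphabets)
}
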