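## Reading structures, DSSP label files and sequences; label mapping and
## dataset filtering.

#' Default non-canonical residue mapping table
#'
#' Three-letter code to canonical one-letter code (plus the canonical
#' three-letter counterpart), for the frequently occurring non-canonical
#' amino acids shipped with the package. Users may extend or replace it.
#'
#' @param path TSV with columns code, one_letter, counterpart.
#' @return data.frame.
#' @export
ncaaTable <- function(path = ffExtdata("ncaa_map.tsv")) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

## three-letter -> one-letter with ncAA support; unknown -> 'X'
threeToOne <- function(codes, ncaa = ncaaTable()) {
  out <- unname(AA3TO1[codes])
  hit <- match(codes, ncaa$code)
  out[is.na(out) & !is.na(hit)] <- ncaa$one_letter[hit[is.na(out) & !is.na(hit)]]
  out[is.na(out)] <- "X"
  out
}

#' Parse a protein structure file into a ProteinChain
#'
#' Reads a PDB or mmCIF file through bio3d, selects one chain, and extracts
#' per-residue three-letter codes (non-canonical codes verbatim), one-letter
#' codes via the non-canonical mapping table ('X' when unmapped), and
#' backbone N/CA/C coordinates. Residues missing any of the three backbone
#' atoms are marked unresolved and carry the mask label. For multi-model
#' (NMR) files only the first model is read.
#'
#' @param path structure file (.pdb or .cif).
#' @param chain chain identifier; default: first chain in the file.
#' @param ncaa non-canonical mapping table from [ncaaTable()].
#' @return A [ProteinChain-class].
#' @export
parseStructure <- function(path, chain = NULL, ncaa = ncaaTable()) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  iscif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (iscif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("structure parse error: ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain & !is.na(at$resno), , drop = FALSE]
  if (!nrow(at)) stop("empty chain or chain not found: ", chain)
  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert)
         else ""
  rid <- paste(at$resno, ins, sep = "_")
  resIdx <- match(unique(rid), rid)
  n <- length(resIdx)
  seq3 <- at$resid[resIdx]
  resno <- at$resno[resIdx]
  bb <- array(NA_real_, dim = c(n, 3, 3))
  for (k in seq_len(n)) {
    rows <- at[rid == rid[resIdx[k]], , drop = FALSE]
    for (a in 1:3) {
      nm <- c("N", "CA", "C")[a]
      hit <- which(rows$elety == nm)
      if (length(hit))
        bb[k, a, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
    }
  }
  resolved <- apply(is.finite(bb), 1, all)
  proteinChain(seq1 = threeToOne(seq3, ncaa), seq3 = seq3,
               backbone = bb, resolved = resolved, chainId = chain,
               resno = resno)
}

#' Parse a DSSP (v4 text output) file
#'
#' Extracts per-residue eight-state labels for one chain from classic DSSP
#' text output. Blank (or '-') structure codes map to C (the standard
#' loop/irregular convention); chain-break records ('!') are skipped.
#'
#' @param path DSSP output file.
#' @param chain chain identifier.
#' @return data.frame with columns `resno`, `aa`, `label8`.
#' @export
parseDssp <- function(path, chain) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("malformed DSSP file: residue table header not found")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]; aa <- aa[keep]
  ch <- substr(body, 12, 12)
  sel <- ch == chain
  if (!any(sel)) stop("chain not found in DSSP file: ", chain)
  body <- body[sel]; aa <- aa[sel]
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  if (anyNA(resno)) stop("malformed DSSP record: unparsable residue number")
  ss <- substr(body, 17, 17)
  ss[ss %in% c(" ", "-", "~", "")] <- "C"
  ## DSSP v4 may report polyproline-II as 'P'; fold into coil
  ss[ss == "P"] <- "C"
  bad <- !ss %in% LABELS8
  if (any(bad)) stop("malformed DSSP record: unknown structure code ",
                     paste(unique(ss[bad]), collapse = ","))
  data.frame(resno = resno, aa = aa, label8 = ss, stringsAsFactors = FALSE)
}

#' Attach DSSP labels to a chain
#'
#' Reconciles labels with the chain by author residue number. Residues
#' present in the sequence but absent from the DSSP records keep the mask
#' label (unresolved structure).
#'
#' @param chain a [ProteinChain-class].
#' @param dssp data.frame from [parseDssp()].
#' @return the chain with `labels8` filled in.
#' @export
attachDssp <- function(chain, dssp) {
  lab <- rep(MASK_LABEL, chainLength(chain))
  hit <- match(chain@resno, dssp$resno)
  lab[!is.na(hit)] <- dssp$label8[hit[!is.na(hit)]]
  chain@labels8 <- lab
  chain@resolved <- chain@resolved & lab != MASK_LABEL
  chain@labels8[!chain@resolved] <- MASK_LABEL
  validObject(chain)
  chain
}

#' Map eight-state labels to three states
#'
#' H, G, I -> H; E, B -> E; T, S, C -> C; the mask label propagates.
#'
#' @param label8 character vector of eight-state labels.
#' @return character vector over `c("H", "E", "C", MASK_LABEL)`.
#' @export
map8to3 <- function(label8) {
  m <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
         T = "C", S = "C", C = "C")
  m[MASK_LABEL] <- MASK_LABEL
  out <- m[label8]
  if (anyNA(out)) stop("unknown eight-state label: ",
                       paste(unique(label8[is.na(out)]), collapse = ","))
  unname(out)
}

#' Dataset filtering criteria
#'
#' Defaults are the quality thresholds used for non-redundant X-ray
#' training-set compilation: resolution at most 3.0 Angstrom, length
#' between 40 and 10,000 residues, R-factor at most 0.3, X-ray entries
#' only. Any predicate can be disabled by setting it to `NULL`.
#'
#' @param resolutionMax,lengthMin,lengthMax,rFactorMax numeric or NULL.
#' @param methods character vector of allowed methods, or NULL.
#' @return list of active criteria.
#' @export
chainFilterCriteria <- function(resolutionMax = 3.0, lengthMin = 40,
                                lengthMax = 10000, rFactorMax = 0.3,
                                methods = "xray") {
  out <- list(resolutionMax = resolutionMax, lengthMin = lengthMin,
              lengthMax = lengthMax, rFactorMax = rFactorMax,
              methods = methods)
  out[!vapply(out, is.null, TRUE)]
}

#' Filter chain metadata
#'
#' Keeps rows satisfying all active predicates; row order preserved. With
#' `criteria = NULL` (or an empty list) the input is returned unchanged.
#'
#' @param meta data.frame with columns pdb_id, chain_id, resolution,
#'   r_factor, length, method (and optionally identity_cluster).
#' @param criteria from [chainFilterCriteria()].
#' @return filtered data.frame.
#' @export
filterChains <- function(meta, criteria = chainFilterCriteria()) {
  if (is.null(criteria) || !length(criteria)) return(meta)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(criteria$resolutionMax))
    keep <- keep & meta$resolution <= criteria$resolutionMax
  if (!is.null(criteria$lengthMin)) keep <- keep & meta$length >= criteria$lengthMin
  if (!is.null(criteria$lengthMax)) keep <- keep & meta$length <= criteria$lengthMax
  if (!is.null(criteria$rFactorMax)) keep <- keep & meta$r_factor <= criteria$rFactorMax
  if (!is.null(criteria$methods)) keep <- keep & meta$method %in% criteria$methods
  meta[keep, , drop = FALSE]
}

#' Write chains to FASTA
#'
#' @param chains list of [ProteinChain-class] (or a single chain).
#' @param path output file.
#' @export
writeChainsFasta <- function(chains, path) {
  if (methods::is(chains, "ProteinChain")) chains <- list(chains)
  seqs <- Biostrings::AAStringSet(vapply(chains, chainSeq, ""))
  names(seqs) <- vapply(chains, function(x) x@chainId, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  structure(as.character(s), names = names(s))
}

#' Write per-residue labels to TSV
#'
#' Columns: chain_id, position (1-based), label8, label3.
#'
#' @param chain a [ProteinChain-class].
#' @param path output file.
#' @export
writeLabelsTsv <- function(chain, path) {
  df <- data.frame(chain_id = chain@chainId,
                   position = seq_len(chainLength(chain)),
                   label8 = chain@labels8,
                   label3 = map8to3(chain@labels8))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
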