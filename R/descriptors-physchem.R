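## Physicochemical descriptors: property-scale loading (AAindex flat file /
## TSV, non-canonical extensions), periodicity descriptors, windowed sums,
## one-hot and terminal features, external disorder scores.

AAINDEX_I_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

parseAAindexFlat <- function(lines, accession = NULL) {
  hidx <- grep("^H ", lines)
  if (!length(hidx)) stop("property table format error: no AAindex 'H' record")
  accs <- trimws(sub("^H ", "", lines[hidx]))
  pick <- if (is.null(accession)) 1L else match(accession, accs)
  if (is.na(pick)) stop("accession not found in AAindex file: ", accession)
  iidx <- grep("^I ", lines)
  iidx <- iidx[iidx > hidx[pick]][1]
  if (is.na(iidx)) stop("property table format error: no 'I' record")
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[c(iidx + 1, iidx + 2)]), "\\s+"))))
  if (length(vals) != 20 || anyNA(vals))
    stop("property table format error: expected 20 numeric values")
  ## first value row: A R N D C Q E G H I; second: L K M F P S T W Y V
  v <- numeric(20)
  names(v) <- AAINDEX_I_ORDER
  v[AAINDEX_I_ORDER[1:10]] <- vals[1:10]
  v[AAINDEX_I_ORDER[11:20]] <- vals[11:20]
  structure(unname(v), names = unname(AA3[names(v)]))
}

#' Load a physicochemical property table
#'
#' Reads one scale from either an AAindex flat file (`H`/`D`/`I` records)
#' or a TSV with columns `code`/`value` (optionally `accession`). All 20
#' canonical residues are mandatory. Non-canonical residue values may be
#' merged from an extension TSV (`code`, `accession`, `value`); under
#' `ncaaPolicy = "fallback"`, codes without an extension entry inherit
#' their canonical counterpart's value at lookup time, under `"strict"`
#' they stay missing.
#'
#' Canonical values are z-standardized across the 20 residues by default
#' (AAindex scales carry heterogeneous units); extension values are scaled
#' with the same canonical location/scale. Use `standardize = FALSE` for
#' raw values.
#'
#' @param path property file.
#' @param accession scale to extract (multi-entry files); also the label.
#' @param ncaaPath optional extension TSV.
#' @param ncaaPolicy `"fallback"` or `"strict"`.
#' @param standardize z-scale across the canonical residues.
#' @param source provenance tag.
#' @return A [PropertyTable-class].
#' @export
loadPropertyTable <- function(path, accession = NULL, ncaaPath = NULL,
                              ncaaPolicy = c("fallback", "strict"),
                              standardize = TRUE, source = "user") {
  ncaaPolicy <- match.arg(ncaaPolicy)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (any(grepl("^H ", lines))) {
    vals <- parseAAindexFlat(lines, accession)
    if (is.null(accession))
      accession <- trimws(sub("^H ", "", lines[grep("^H ", lines)[1]]))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    if ("accession" %in% names(tab)) {
      if (is.null(accession)) accession <- tab$accession[1]
      tab <- tab[tab$accession == accession, , drop = FALSE]
    } else if (is.null(accession)) accession <- "USER000001"
    if (!nrow(tab)) stop("accession not found: ", accession)
    vals <- structure(tab$value, names = toupper(tab$code))
  }
  if (!all(AA3 %in% names(vals)))
    stop("property table format error: missing canonical residues ",
         paste(setdiff(AA3, names(vals)), collapse = ","))
  if (!is.null(ncaaPath)) {
    ext <- utils::read.table(ncaaPath, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    ext <- ext[ext$accession == accession, , drop = FALSE]
    if (nrow(ext)) {
      extv <- structure(ext$value, names = toupper(ext$code))
      vals <- c(vals[setdiff(names(vals), names(extv))], extv)
    }
  }
  if (standardize) {
    mu <- mean(vals[AA3]); sd0 <- stats::sd(vals[AA3])
    if (sd0 > 0) vals <- (vals - mu) / sd0 else vals <- vals - mu
  }
  pt <- new("PropertyTable", accession = accession, values = vals,
            source = source, standardized = standardize)
  attr(pt, "ncaaPolicy") <- ncaaPolicy
  pt
}

#' Build a PropertyTable from named values
#'
#' @param values numeric named by three-letter code; all 20 canonical
#'   codes required.
#' @param accession,source labels.
#' @param standardize z-scale across the canonical residues.
#' @return A [PropertyTable-class].
#' @export
propertyTable <- function(values, accession = "USER000001",
                          source = "user", standardize = TRUE) {
  if (standardize) {
    mu <- mean(values[AA3]); sd0 <- stats::sd(values[AA3])
    if (is.finite(sd0) && sd0 > 0) values <- (values - mu) / sd0
    else values <- values - mu
  }
  new("PropertyTable", accession = accession, values = values,
      source = source, standardized = standardize)
}

#' Per-residue property values of a chain
#'
#' Looks up each residue's three-letter code. Non-canonical codes missing
#' from the table inherit their canonical counterpart's value under the
#' fallback policy, or return NA under the strict policy; unknown codes
#' yield NA either way.
#'
#' @param chain a [ProteinChain-class].
#' @param table a [PropertyTable-class].
#' @param ncaaPolicy `"fallback"` or `"strict"`.
#' @param ncaa mapping table from [ncaaTable()] (for counterpart lookup).
#' @return numeric vector, NA where no value applies.
#' @export
chainPropertyValues <- function(chain, table,
                                ncaaPolicy = c("fallback", "strict"),
                                ncaa = ncaaTable()) {
  ncaaPolicy <- match.arg(ncaaPolicy)
  v <- unname(table@values[chain@seq3])
  if (ncaaPolicy == "fallback" && anyNA(v)) {
    miss <- which(is.na(v))
    cp <- ncaa$counterpart[match(chain@seq3[miss], ncaa$code)]
    v[miss] <- unname(table@values[cp])
  }
  v
}

## half-window from period and period count: 2n+1 = T * n_T
periodicHalfWindow <- function(T, nT) {
  n <- round((T * nT - 1) / 2)
  if (n < 1) stop("periodic descriptor config error: window too small (T*nT <= 2)")
  as.integer(n)
}

#' Periodicity descriptor of a property signal
#'
#' Magnitude of the decayed Fourier component at period `T` over a window
#' of `2n+1` residues (with `2n+1 = T * nT`, `n = round((T*nT - 1)/2)`):
#' `F = sqrt((sum_k H_k cos(2*pi*k/T) f(k))^2 + (sum_k H_k sin(...) f(k))^2)`
#' with `k = -n..n` and the Gaussian-like decay `f(k) = exp(-A (k/n)^2)`
#' (so the window edge is attenuated by `exp(-A)` for every `T`, `nT`).
#' The alternative normalization `f(k) = exp(-A (k/(T*nT))^2)` is available
#' via `decayNorm = "TnT"`.
#'
#' @param H numeric window of length `2n+1` (values `H_{-n}..H_n`).
#' @param T period in residues.
#' @param nT number of periods in the window.
#' @param A decay strength (dimensionless).
#' @param decayNorm `"half"` (default) or `"TnT"`.
#' @return non-negative scalar.
#' @export
periodicDescriptorValue <- function(H, T, nT, A, decayNorm = c("half", "TnT")) {
  decayNorm <- match.arg(decayNorm)
  n <- periodicHalfWindow(T, nT)
  if (length(H) != 2 * n + 1)
    stop("window length ", length(H), " != 2n+1 = ", 2 * n + 1)
  k <- -n:n
  denom <- if (decayNorm == "half") n else T * nT
  f <- exp(-A * (k / denom)^2)
  w <- 2 * pi * k / T
  a <- sum(H * cos(w) * f)
  b <- sum(H * sin(w) * f)
  sqrt(a * a + b * b)
}

#' Periodic descriptor specification and chain-wide evaluation
#'
#' @param accession property scale name.
#' @param T period in residues (scan range 1.2-15.0 in the screening
#'   protocol).
#' @param nT integer number of periods (2-9).
#' @param A decay strength (0.5, 1, 2, 3 in the default scan).
#' @param power positive integer applied to the descriptor value.
#' @return an object of class `PeriodicDescriptorSpec`.
#' @export
periodicDescriptorSpec <- function(accession, T, nT, A = 1, power = 1L) {
  stopifnot(T > 0, nT >= 1, A >= 0, power >= 1)
  structure(list(accession = accession, T = T, nT = as.integer(nT), A = A,
                 power = as.integer(power)),
            class = "PeriodicDescriptorSpec")
}

#' @export
print.PeriodicDescriptorSpec <- function(x, ...) {
  cat(sprintf("PeriodicDescriptorSpec: %s, T=%.2f, nT=%d, A=%g, power=%d\n",
              x$accession, x$T, x$nT, x$A, x$power))
  invisible(x)
}

#' @rdname periodicDescriptorSpec
#' @param chain a [ProteinChain-class].
#' @param spec a `PeriodicDescriptorSpec`.
#' @param table the matching [PropertyTable-class].
#' @param ... passed to [chainPropertyValues()].
#' @return numeric vector, one value per residue.
#' @export
evaluatePeriodicDescriptor <- function(chain, spec, table, ...) {
  H <- chainPropertyValues(chain, table, ...)
  H[is.na(H)] <- 0
  n <- periodicHalfWindow(spec$T, spec$nT)
  N <- length(H)
  Hpad <- c(numeric(n), H, numeric(n))   # out-of-chain positions contribute 0
  vapply(seq_len(N), function(p) {
    periodicDescriptorValue(Hpad[p:(p + 2 * n)], spec$T, spec$nT,
                            spec$A)^spec$power
  }, 0)
}

#' Windowed (non-periodic) descriptor specification and evaluation
#'
#' Decayed sum of a property over a fixed window of offsets from the
#' target residue:
#' `D(p) = (sum_{k=left..right} H(p+k) exp(-A (k/m)^2))^power` with
#' `m = max(|left|, |right|)`; offsets falling outside the chain
#' contribute 0. The window need not contain the target position itself.
#'
#' @param accession property scale name.
#' @param left,right window offsets (left <= right), residues.
#' @param A decay strength.
#' @param power positive integer.
#' @return an object of class `WindowDescriptorSpec`.
#' @export
windowDescriptorSpec <- function(accession, left, right, A = 1, power = 1L) {
  stopifnot(left <= right, A >= 0, power >= 1)
  structure(list(accession = accession, left = as.integer(left),
                 right = as.integer(right), A = A, power = as.integer(power)),
            class = "WindowDescriptorSpec")
}

#' @export
print.WindowDescriptorSpec <- function(x, ...) {
  cat(sprintf("WindowDescriptorSpec: %s, window [%d, %d], A=%g, power=%d\n",
              x$accession, x$left, x$right, x$A, x$power))
  invisible(x)
}

#' @rdname windowDescriptorSpec
#' @param chain a [ProteinChain-class].
#' @param spec a `WindowDescriptorSpec`.
#' @param table the matching [PropertyTable-class].
#' @param ... passed to [chainPropertyValues()].
#' @return numeric vector, one value per residue.
#' @export
evaluateWindowDescriptor <- function(chain, spec, table, ...) {
  H <- chainPropertyValues(chain, table, ...)
  H[is.na(H)] <- 0
  N <- length(H)
  k <- spec$left:spec$right
  m <- max(abs(spec$left), abs(spec$right))
  f <- if (m == 0) rep(1, length(k)) else exp(-spec$A * (k / m)^2)
  vapply(seq_len(N), function(p) {
    idx <- p + k
    ok <- idx >= 1 & idx <= N
    sum(H[idx[ok]] * f[ok])^spec$power
  }, 0)
}

#' One-hot identity and terminal-proximity features
#'
#' One identity bit per canonical residue plus one per configured
#' non-canonical code (selenomethionine sets its own bit, not the
#' methionine bit); unknown codes give an all-zero identity row. The
#' `End_N_3` column is 1 for the first `nEnd` residues of the chain (a
#' binary feature; raising it to a power is a no-op). A symmetric
#' C-terminal column is available but off by default.
#'
#' @param chain a [ProteinChain-class].
#' @param ncaaCodes three-letter codes to one-hot encode beyond the
#'   canonical 20; defaults to the shipped mapping table's codes.
#' @param nEnd terminal window (residues).
#' @param endC also emit the C-terminal column.
#' @return numeric matrix with named columns.
#' @export
categoricalFeatures <- function(chain, ncaaCodes = ncaaTable()$code,
                                nEnd = 3L, endC = FALSE) {
  n <- chainLength(chain)
  vocab <- c(AA3, ncaaCodes)
  X <- matrix(0, nrow = n, ncol = length(vocab),
              dimnames = list(NULL, paste0("is_", vocab)))
  hit <- match(chain@seq3, vocab)
  ok <- !is.na(hit)
  X[cbind(which(ok), hit[ok])] <- 1
  endN <- as.numeric(seq_len(n) <= nEnd)
  out <- cbind(X, End_N_3 = endN)
  if (endC) out <- cbind(out, End_C_3 = as.numeric(seq_len(n) > n - nEnd))
  out
}

#' Per-residue disorder-score descriptor
#'
#' Ingests externally computed per-residue disorder scores (TSV with
#' columns `position`, `score` in \[0, 1\]) and raises them to a power.
#' Scores outside \[0, 1\] are clamped with a warning; positions absent
#' from the file are NA.
#'
#' @param scores path to a TSV, or a data.frame with `position`, `score`.
#' @param n chain length.
#' @param power positive integer.
#' @return numeric vector of length `n` with NA at missing positions.
#' @export
disorderDescriptor <- function(scores, n, power = 1L) {
  if (is.character(scores))
    scores <- utils::read.table(scores, header = TRUE, sep = "\t",
                                comment.char = "#")
  out <- rep(NA_real_, n)
  s <- scores$score
  if (any(s < 0 | s > 1, na.rm = TRUE)) {
    warning("disorder scores outside [0, 1] clamped")
    s <- pmin(pmax(s, 0), 1)
  }
  keep <- scores$position >= 1 & scores$position <= n
  out[scores$position[keep]] <- s[keep]
  out^power
}
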