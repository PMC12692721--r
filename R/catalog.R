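## Descriptor catalogs: YAML files mirroring the published top-descriptor
## tables, parsed into spec objects.

#' Load a descriptor catalog
#'
#' Reads a YAML catalog with sections `rmsd`, `periodic`,
#' `physchem_window` and `other` into lists of descriptor spec objects.
#' The shipped catalog carries the published top-ranked recipes; window
#' descriptors default to decay strength `A = 1` (the printed tables list
#' no decay column).
#'
#' @param path YAML catalog; defaults to the shipped file.
#' @return list with elements `rmsd`, `periodic`, `window`, `other`.
#' @export
loadDescriptorCatalog <- function(path = ffExtdata("descriptor_catalog.yaml")) {
  cfg <- yaml::read_yaml(path)
  list(
    rmsd = lapply(cfg$rmsd, function(e)
      rmsdDescriptorSpec(alphabet = e$alphabet, pb = e$pb,
                         offset = e$offset, power = e$power)),
    periodic = lapply(cfg$periodic, function(e)
      periodicDescriptorSpec(accession = e$accession, T = e$T, nT = e$n_T,
                             A = if (is.null(e$A)) 1 else e$A,
                             power = e$power)),
    window = lapply(cfg$physchem_window, function(e)
      windowDescriptorSpec(accession = e$accession, left = e$left,
                           right = e$right,
                           A = if (is.null(e$A)) 1 else e$A,
                           power = e$power)),
    other = cfg$other)
}

#' Assemble a feature matrix for one chain
#'
#' Evaluates RMSD-statistic, periodic and window descriptor specs plus
#' optional categorical and disorder columns for a chain, and stacks them
#' into a [FeatureMatrix-class] (raw values; standardize and impute with
#' [standardizeFeatures()] before model fitting).
#'
#' @param chain a [ProteinChain-class].
#' @param stats a [PBStats-class] (required when `rmsdSpecs` given).
#' @param alphabets compiled alphabets for the RMSD specs.
#' @param rmsdSpecs,periodicSpecs,windowSpecs descriptor spec lists.
#' @param tables named list of [PropertyTable-class] keyed by accession.
#' @param categorical include one-hot/terminal features.
#' @param disorder optional disorder score vector or file.
#' @param ... passed to [chainPropertyValues()].
#' @return A [FeatureMatrix-class] with per-residue labels from the chain.
#' @export
buildChainFeatures <- function(chain, stats = NULL, alphabets = NULL,
                               rmsdSpecs = list(), periodicSpecs = list(),
                               windowSpecs = list(), tables = list(),
                               categorical = FALSE, disorder = NULL, ...) {
  blocks <- list()
  meta <- list()
  if (length(rmsdSpecs)) {
    m <- evaluateRmsdDescriptors(chain, rmsdSpecs, stats, alphabets)
    blocks <- c(blocks, list(m))
    meta <- c(meta, list(data.frame(name = colnames(m), family = "rmsd")))
  }
  getTable <- function(acc) {
    if (!acc %in% names(tables))
      stop("no property table supplied for accession ", acc)
    tables[[acc]]
  }
  for (s in periodicSpecs) {
    v <- evaluatePeriodicDescriptor(chain, s, getTable(s$accession), ...)
    nm <- sprintf("per_%s_T%.1f_n%d_A%g_p%d", s$accession, s$T, s$nT, s$A,
                  s$power)
    blocks <- c(blocks, list(matrix(v, ncol = 1, dimnames = list(NULL, nm))))
    meta <- c(meta, list(data.frame(name = nm, family = "periodic")))
  }
  for (s in windowSpecs) {
    v <- evaluateWindowDescriptor(chain, s, getTable(s$accession), ...)
    nm <- sprintf("win_%s_%d_%d_A%g_p%d", s$accession, s$left, s$right,
                  s$A, s$power)
    blocks <- c(blocks, list(matrix(v, ncol = 1, dimnames = list(NULL, nm))))
    meta <- c(meta, list(data.frame(name = nm, family = "window")))
  }
  if (categorical) {
    m <- categoricalFeatures(chain)
    blocks <- c(blocks, list(m))
    meta <- c(meta, list(data.frame(name = colnames(m),
                                    family = "categorical")))
  }
  if (!is.null(disorder)) {
    v <- if (is.character(disorder))
      disorderDescriptor(disorder, chainLength(chain))
    else disorder
    blocks <- c(blocks, list(matrix(v, ncol = 1,
                                    dimnames = list(NULL, "disorder"))))
    meta <- c(meta, list(data.frame(name = "disorder", family = "disorder")))
  }
  if (!length(blocks)) stop("no descriptors requested")
  X <- do.call(cbind, blocks)
  labs <- chainLabels(chain)
  featureMatrix(X, y = ifelse(labs == MASK_LABEL, NA, labs),
                mask = labs != MASK_LABEL,
                columnMeta = do.call(rbind, meta))
}
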