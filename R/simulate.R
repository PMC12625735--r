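#' Build a simulation configuration
#'
#' Defaults emulate the study design the package targets: two diet groups
#' (normal chow vs 60\% kcal high-fat) with 12 mice each, every mouse
#' contributing an ileal and a colonic microbial community plus liver
#' transcriptome, serum/liver metabolome and metabolic phenotypes.
#' Cross-kingdom coupling is planted through shared latent factors;
#' \code{loadingA > loadingB} makes compartment A (ileum) couple more
#' strongly to the host layers than compartment B (colon).
#'
#' @param nPerGroup samples per diet group.
#' @param nMicrobesA,nMicrobesB genus counts in the two compartments
#'   (shared genus namespace).
#' @param nGenes,nMetabSerum,nMetabLiver,nPhenotypes host feature counts.
#' @param nFactors number of latent factors; each feature loads on exactly
#'   one factor (round-robin within layer), so factors define disjoint
#'   coupled blocks — with \code{nFactors = 2} the gene layer carries two
#'   planted modules.
#' @param loadingA,loadingB,loadingHost absolute factor loadings of
#'   compartment A microbes, compartment B microbes, and host features.
#' @param dietEffectSD scale of diet-effect magnitudes (latent SD units).
#' @param sequencingDepth total microbial counts per sample.
#' @param noiseSD residual latent noise SD.
#' @param seed RNG seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nPerGroup = 6, seed = 42)
#' cfg
#' @export
simulationConfig <- function(nPerGroup = 12, nMicrobesA = 40, nMicrobesB = 40,
                             nGenes = 80, nMetabSerum = 20, nMetabLiver = 20,
                             nPhenotypes = 5, nFactors = 2,
                             loadingA = 0.8, loadingB = 0.3, loadingHost = 0.8,
                             dietEffectSD = 2, sequencingDepth = 20000,
                             noiseSD = 0.5, seed = 1) {
  new("SimulationConfig",
      nPerGroup = as.integer(nPerGroup),
      nMicrobesA = as.integer(nMicrobesA), nMicrobesB = as.integer(nMicrobesB),
      nGenes = as.integer(nGenes), nMetabSerum = as.integer(nMetabSerum),
      nMetabLiver = as.integer(nMetabLiver),
      nPhenotypes = as.integer(nPhenotypes), nFactors = as.integer(nFactors),
      loadingA = as.numeric(loadingA), loadingB = as.numeric(loadingB),
      loadingHost = as.numeric(loadingHost),
      dietEffectSD = as.numeric(dietEffectSD),
      sequencingDepth = as.integer(sequencingDepth),
      noiseSD = as.numeric(noiseSD), seed = as.integer(seed))
}

#' Canonical node id: layer-qualified feature id
#'
#' @param layer layer name.
#' @param feature feature id within the layer.
#' @return character vector \code{"layer:feature"}.
#' @export
nodeId <- function(layer, feature) paste(layer, feature, sep = ":")

# Latent values for one layer: baseline + diet effect + loading * factor + noise.
# Diet-effect sign is sign(loading) * factor diet direction, so every
# same-factor pair's fold-change sign product equals its correlation sign.
.simulateLayerLatent <- function(prefix, ids, loadingAbs, factorOf, z, diet01,
                                 factorDietDir, dietEffectSD, noiseSD,
                                 baselineSD = 1) {
  n <- length(ids)
  ns <- length(diet01)
  signL <- sample(c(-1, 1), n, replace = TRUE)
  loading <- signL * loadingAbs
  baseline <- rnorm(n, 0, baselineSD)
  effMag <- abs(rnorm(n, 0, dietEffectSD))
  effSign <- ifelse(loading == 0, sample(c(-1, 1), n, replace = TRUE),
                    sign(loading)) * factorDietDir[factorOf]
  lat <- matrix(baseline, n, ns) +
    outer(effSign * effMag, diet01) +
    loading * z[factorOf, , drop = FALSE] +
    matrix(rnorm(n * ns, 0, noiseSD), n, ns)
  rownames(lat) <- ids
  list(latent = lat, loading = loading, factorOf = factorOf,
       effectSign = effSign, nodes = nodeId(prefix, ids))
}

.latentToCounts <- function(latent, depth) {
  counts <- apply(latent, 2, function(col) {
    p <- exp(col - max(col))
    as.integer(rmultinom(1, depth, p / sum(p)))
  })
  dimnames(counts) <- dimnames(latent)
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a paired-compartment multi-omics dataset with planted truth
#'
#' Draws per-sample latent factors \code{z ~ N(0, 1)}; every feature's
#' latent value is \code{baseline + dietEffect * 1[HFD] + loading * z +
#' noise}, with each feature tied to one factor. Microbial latents are
#' softmax-normalized per sample and counts drawn multinomially at
#' \code{sequencingDepth}; genes and metabolites are exponentiated
#' (log-normal); phenotypes stay linear. Diet-effect signs follow
#' \code{sign(loading)} times a per-factor diet direction, so for every
#' coupled pair the product of fold-change signs equals the expected
#' correlation sign (planted coherence; PUC near zero on truth).
#'
#' The single RNG stream is seeded once from \code{config@seed} and
#' consumed in a fixed documented order (factors, then layers in the
#' order microbes_A, microbes_B, genes, metab_serum, metab_liver,
#' phenotypes, then multinomial draws), so a given config is bit-
#' reproducible.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{dataset}
#'   (\linkS4class{MultiOmicsDataset}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' sim <- generateDataset(simulationConfig(nPerGroup = 6, seed = 7))
#' sim$dataset
#' head(coupledPairs(sim$truth))
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  n <- config@nPerGroup
  ns <- 2L * n
  sampleIds <- sprintf("S%02d", seq_len(ns))
  diet <- rep(c("NC", "HFD"), each = n)
  diet01 <- as.numeric(diet == "HFD")

  z <- matrix(rnorm(config@nFactors * ns), config@nFactors, ns)
  factorDietDir <- sample(c(-1, 1), config@nFactors, replace = TRUE)

  rr <- function(k) ((seq_len(k) - 1L) %% config@nFactors) + 1L
  gid <- function(pre, k) sprintf("%s%03d", pre, seq_len(k))

  layers <- list(
    microbes_A = list(pre = "g", k = config@nMicrobesA, load = config@loadingA),
    microbes_B = list(pre = "g", k = config@nMicrobesB, load = config@loadingB),
    genes      = list(pre = "gene", k = config@nGenes, load = config@loadingHost),
    metab_serum = list(pre = "sm", k = config@nMetabSerum, load = config@loadingHost),
    metab_liver = list(pre = "lm", k = config@nMetabLiver, load = config@loadingHost),
    phenotypes = list(pre = "ph", k = config@nPhenotypes, load = config@loadingHost)
  )

  sims <- lapply(names(layers), function(nm) {
    ly <- layers[[nm]]
    .simulateLayerLatent(nm, gid(ly$pre, ly$k), ly$load, rr(ly$k), z, diet01,
                         factorDietDir, config@dietEffectSD, config@noiseSD)
  })
  names(sims) <- names(layers)

  mats <- list(
    microbes_A = .latentToCounts(sims$microbes_A$latent, config@sequencingDepth),
    microbes_B = .latentToCounts(sims$microbes_B$latent, config@sequencingDepth),
    genes = exp(sims$genes$latent) * 100,
    metab_serum = exp(sims$metab_serum$latent) * 1000,
    metab_liver = exp(sims$metab_liver$latent) * 1000,
    phenotypes = 20 + 2 * sims$phenotypes$latent
  )
  for (nm in names(mats)) colnames(mats[[nm]]) <- sampleIds

  info <- data.frame(
    layer = names(layers),
    kind = c("microbe", "microbe", "gene", "metabolite", "metabolite",
             "phenotype"),
    compartment = c("ileum", "colon", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  dataset <- new("MultiOmicsDataset", layers = mats, layerInfo = info,
                 sampleData = data.frame(sample_id = sampleIds, diet = diet,
                                         stringsAsFactors = FALSE))

  loadingsDf <- do.call(rbind, lapply(sims, function(s)
    data.frame(node = s$nodes, factor = s$factorOf, loading = s$loading,
               stringsAsFactors = FALSE)))
  rownames(loadingsDf) <- NULL
  effSign <- unlist(lapply(sims, function(s)
    stats::setNames(s$effectSign, s$nodes)))
  names(effSign) <- sub("^[^.]*\\.", "", names(effSign))

  hostLayers <- c("genes", "metab_serum", "metab_liver", "phenotypes")
  pairs <- do.call(rbind, lapply(c("microbes_A", "microbes_B"), function(mA) {
    sm <- sims[[mA]]
    keep <- sm$loading != 0
    do.call(rbind, lapply(hostLayers, function(h) {
      sh <- sims[[h]]
      hkeep <- sh$loading != 0
      idx <- expand.grid(i = which(keep), j = which(hkeep))
      idx <- idx[sm$factorOf[idx$i] == sh$factorOf[idx$j], , drop = FALSE]
      if (!nrow(idx)) return(NULL)
      data.frame(microbe = sm$nodes[idx$i], host = sh$nodes[idx$j],
                 sign = sign(sm$loading[idx$i]) * sign(sh$loading[idx$j]),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(pairs))
    pairs <- data.frame(microbe = character(), host = character(),
                        sign = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  truth <- new("SyntheticTruth", coupledPairs = pairs,
               dietEffectSign = effSign, factorLoadings = loadingsDf)
  list(dataset = dataset, truth = truth)
}

#' Write a dataset (and optional truth) to a directory of TSVs
#'
#' One feature table per layer (first column \code{feature_id}, then one
#' column per sample), a \code{metadata.tsv} (sample_id, diet) and, when
#' truth is given, \code{truth_coupled_pairs.tsv} (microbe, host, sign).
#' Round-trips losslessly through [readFeatureTable()] /
#' [readSampleMetadata()].
#'
#' @param dataset a \linkS4class{MultiOmicsDataset}.
#' @param directory output directory (created if needed).
#' @param truth optional \linkS4class{SyntheticTruth}.
#' @return invisibly, the vector of files written.
#' @export
writeDataset <- function(dataset, directory, truth = NULL) {
  stopifnot(is(dataset, "MultiOmicsDataset"))
  if (!is.character(directory) || length(directory) != 1L || !nzchar(directory))
    stop("'directory' must be a non-empty path")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory '", directory, "'")
  files <- character()
  for (nm in layerNames(dataset)) {
    f <- file.path(directory, paste0(nm, ".tsv"))
    writeFeatureTable(assayLayer(dataset, nm), f)
    files <- c(files, f)
  }
  f <- file.path(directory, "metadata.tsv")
  utils::write.table(sampleData(dataset), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  if (!is.null(truth)) {
    stopifnot(is(truth, "SyntheticTruth"))
    f <- file.path(directory, "truth_coupled_pairs.tsv")
    utils::write.table(coupledPairs(truth), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
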