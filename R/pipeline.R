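#' Run the full transkingdom analysis pipeline
#'
#' Orchestrates every stage in the order of the underlying study:
#' microbial normalization and differential screening (per-layer
#' HFD-vs-NC tests, diet x segment two-way ANOVA on the shared genus
#' namespace, Shannon diversity, compartment-specific genera), network
#' construction, the two-compartment topology report, dense-subnetwork
#' detection with compartment-to-subnetwork closeness, and optional
#' over-representation analysis against a caller-supplied GMT file.
#' Writes all result tables, the GraphML network, a JSON report and a
#' run log recording every setting actually used. Idempotent for fixed
#' inputs and seed.
#'
#' Config keys (YAML or list): \code{data_dir} (required; a directory
#' from [writeDataset()]), \code{out_dir}, \code{seed} (default 1),
#' \code{diff_test} (mw/welch), \code{diff_fdr}, \code{pseudocount},
#' \code{network_method} (spearman/pearson), \code{network_fdr},
#' \code{require_coherence}, \code{exclude_cross_compartment},
#' \code{top_fraction}, \code{subnet_layer}, \code{subnet_k},
#' \code{subnet_min_size}, \code{gmt_file} (optional).
#'
#' @param config named list (see [validatePipelineConfig()]) or a path
#'   to a YAML file.
#' @param outDir overrides \code{config$out_dir}.
#' @return invisibly, a list with the in-memory results: diff, anova,
#'   shannon, specific, network, topology, subnetworks,
#'   subnetworkCloseness, enrichment, files.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  else config <- validatePipelineConfig(config)
  if (!is.null(outDir)) config$out_dir <- outDir
  if (is.null(config$out_dir)) stop("config needs out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dataset <- stage("read", readDataset(config$data_dir))
  set.seed(config$seed)
  info <- layerInfo(dataset)
  microLayers <- info$layer[info$kind == "microbe"]

  # differential screening, per layer
  diff <- stage("differential",
                screenLayers(dataset, method = config$diff_test,
                             fdr = config$diff_fdr,
                             pseudocount = config$pseudocount))
  for (nm in names(diff)) {
    f <- file.path(od, paste0("diff_", nm, ".tsv"))
    utils::write.table(diff[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }

  # diet x segment ANOVA, Shannon and presence screen on the microbial
  # compartments (needs the shared genus namespace)
  anova <- NULL; shannon <- NULL; specific <- NULL
  if (length(microLayers) == 2L) {
    tA <- assayLayer(dataset, microLayers[1])
    tB <- assayLayer(dataset, microLayers[2])
    if (setequal(rownames(tA), rownames(tB))) {
      tB <- tB[rownames(tA), , drop = FALSE]
      comb <- cbind(tA, tB)
      colnames(comb) <- c(paste0(colnames(tA), ".A"),
                          paste0(colnames(tB), ".B"))
      diet2 <- rep(as.character(dietLabels(dataset)), 2L)
      seg2 <- rep(microLayers, each = ncol(tA))
      anova <- stage("anova",
                     twoWayAnova(clrTransform(comb, config$pseudocount),
                                 diet2, seg2, fdr = config$diff_fdr))
      f <- file.path(od, "anova_diet_by_segment.tsv")
      utils::write.table(anova, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
      specific <- stage("presence", compartmentSpecificFeatures(tA, tB))
    }
    shannon <- stage("diversity", data.frame(
      sample_id = rep(sampleData(dataset)$sample_id, 2L),
      compartment = rep(microLayers, each = ncol(tA)),
      shannon = c(shannonDiversity(tA), shannonDiversity(tB)),
      stringsAsFactors = FALSE
    ))
    f <- file.path(od, "shannon.tsv")
    utils::write.table(shannon, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }

  # network
  network <- stage("network",
                   buildNetwork(dataset, diff, fdr = config$network_fdr,
                                method = config$network_method,
                                requireCoherence = config$require_coherence,
                                excludeCrossCompartment =
                                  config$exclude_cross_compartment,
                                pseudocount = config$pseudocount))
  files <- c(files, stage("export", exportNetwork(network, od)))

  # topology
  topology <- stage("topology",
                    compartmentReport(network, microbeLayers = microLayers,
                                      topFraction = config$top_fraction))
  f <- file.path(od, "topology_report.json")
  jsonlite::write_json(reportToList(topology), f, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  files <- c(files, f)

  # subnetworks
  subs <- list(); subClose <- list()
  subs <- tryCatch(
    stage("subnetworks",
          detectDenseSubnetworks(network, layer = config$subnet_layer,
                                 k = config$subnet_k,
                                 minSize = config$subnet_min_size,
                                 seed = config$seed)),
    error = function(e) { warning(conditionMessage(e)); list() })
  if (length(subs)) {
    memDf <- do.call(rbind, lapply(subs, function(s)
      data.frame(node = members(s), subnetwork_id = s@id,
                 stringsAsFactors = FALSE)))
    f <- file.path(od, "subnetworks.tsv")
    utils::write.table(memDf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    for (s in subs) {
      for (ml in microLayers) {
        ms <- layerNodes(network, ml)
        key <- paste0(ml, "->subnet", s@id)
        subClose[[key]] <- if (length(ms))
          subnetworkCloseness(network, ms, s)
        else list(lengths = numeric(), mean = NA_real_, n_unreachable = 0L,
                  n_pairs = 0L)
      }
    }
  }

  # enrichment (optional)
  enr <- NULL
  if (!is.null(config$gmt_file) && length(subs)) {
    universe <- sub("^[^:]*:", "", layerNodes(network, config$subnet_layer))
    coll <- stage("enrichment", readGmt(config$gmt_file, universe = universe))
    enr <- lapply(subs, function(s)
      ora(sub("^[^:]*:", "", members(s)), coll, fdr = config$diff_fdr))
    names(enr) <- paste0("subnet", vapply(subs, function(s) s@id, integer(1)))
    for (nm in names(enr)) {
      f <- file.path(od, paste0("enrichment_", nm, ".tsv"))
      utils::write.table(enr[[nm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }

  # run log: every setting actually used, defaults included
  log <- list(
    package_version = as.character(utils::packageVersion("tknet")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[order(names(config))]
  )
  f <- file.path(od, "run_log.json")
  jsonlite::write_json(log, f, auto_unbox = TRUE, null = "null")
  files <- c(files, f)

  invisible(list(dataset = dataset, diff = diff, anova = anova,
                 shannon = shannon, specific = specific, network = network,
                 topology = topology, subnetworks = subs,
                 subnetworkCloseness = subClose, enrichment = enr,
                 files = files))
}
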