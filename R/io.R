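#' Read a feature table TSV
#'
#' Expected layout: header row of sample ids, first column feature ids,
#' numeric cells. Duplicate feature ids and non-numeric cells are
#' rejected with a message naming the offender; sample order is
#' preserved.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames = feature ids, colnames = sample ids.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs a feature-id column plus >= 1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write a feature table TSV
#'
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFeatureTable <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV (sample_id, diet)
#'
#' @param path TSV path with at least columns \code{sample_id} and
#'   \code{diet} (NC/HFD).
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "diet") %in% names(df)))
    stop("metadata needs columns sample_id and diet")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$diet %in% c("NC", "HFD")))
    stop("diet values must be NC or HFD")
  df
}

#' Read a dataset back from a directory written by [writeDataset()]
#'
#' @param directory directory holding one TSV per layer plus
#'   \code{metadata.tsv}.
#' @param layerInfo data.frame (layer, kind, compartment); defaults to
#'   the generator's six-layer convention for the files present.
#' @return a \linkS4class{MultiOmicsDataset}.
#' @export
readDataset <- function(directory, layerInfo = NULL) {
  meta <- readSampleMetadata(file.path(directory, "metadata.tsv"))
  default <- data.frame(
    layer = c("microbes_A", "microbes_B", "genes", "metab_serum",
              "metab_liver", "phenotypes"),
    kind = c("microbe", "microbe", "gene", "metabolite", "metabolite",
             "phenotype"),
    compartment = c("ileum", "colon", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  if (is.null(layerInfo)) layerInfo <- default
  present <- layerInfo$layer[file.exists(
    file.path(directory, paste0(layerInfo$layer, ".tsv")))]
  if (!length(present)) stop("no layer TSVs found in ", directory)
  layers <- lapply(present, function(nm) {
    m <- readFeatureTable(file.path(directory, paste0(nm, ".tsv")))
    m <- m[, meta$sample_id, drop = FALSE]
    if (layerInfo$kind[layerInfo$layer == nm] == "microbe")
      storage.mode(m) <- "integer"
    m
  })
  names(layers) <- present
  new("MultiOmicsDataset", layers = layers,
      layerInfo = layerInfo[layerInfo$layer %in% present, , drop = FALSE],
      sampleData = meta)
}

#' Export a network as GraphML plus plain TSV tables
#'
#' Writes \code{network.graphml} (node attributes: layer, kind,
#' compartment, lfc, q; edge attributes: r_NC, r_HFD, combined_p, q,
#' sign, coherent), \code{edges.tsv} and \code{nodes.tsv}.
#'
#' @param network a \linkS4class{TranskingdomNetwork}.
#' @param directory output directory (created if needed).
#' @return invisibly, the files written.
#' @export
exportNetwork <- function(network, directory) {
  stopifnot(is(network, "TranskingdomNetwork"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  g <- asIgraph(network)
  # GraphML has no native logical type via igraph's writer; coerce
  if (igraph::ecount(g) && "coherent" %in% igraph::edge_attr_names(g))
    igraph::E(g)$coherent <- as.integer(igraph::E(g)$coherent)
  # subnormal doubles (possible for extreme combined p) break GraphML
  # readers; floor them at the smallest normal double for export
  if (igraph::ecount(g)) {
    for (at in igraph::edge_attr_names(g)) {
      v <- igraph::edge_attr(g, at)
      if (is.numeric(v))
        igraph::edge_attr(g, at) <- sign(v) * pmax(abs(v), 2.3e-308) *
          (v != 0)
    }
  }
  gml <- file.path(directory, "network.graphml")
  igraph::write_graph(g, gml, format = "graphml")
  etsv <- file.path(directory, "edges.tsv")
  utils::write.table(edgeTable(network), etsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ntsv <- file.path(directory, "nodes.tsv")
  utils::write.table(nodeTable(network), ntsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gml, etsv, ntsv))
}

.knownConfigKeys <- c(
  "data_dir", "out_dir", "seed",
  "diff_test", "diff_fdr", "pseudocount",
  "network_method", "network_fdr", "require_coherence",
  "exclude_cross_compartment",
  "top_fraction", "subnet_layer", "subnet_k", "subnet_min_size",
  "gmt_file"
)

#' Read and validate a pipeline configuration (YAML)
#'
#' Strict key validation: unknown keys are errors (typo'd thresholds
#' must not pass silently). See [runPipeline()] for the keys and their
#' defaults.
#'
#' @param path YAML file.
#' @return named list of validated settings.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .knownConfigKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg named list of settings (as from YAML).
#' @export
validatePipelineConfig <- function(cfg) {
  defaults <- list(
    seed = 1L, diff_test = "mw", diff_fdr = 0.05, pseudocount = 0.5,
    network_method = "spearman", network_fdr = 0.05,
    require_coherence = TRUE, exclude_cross_compartment = TRUE,
    top_fraction = 0.20, subnet_layer = "genes", subnet_k = 2L,
    subnet_min_size = 10L, gmt_file = NULL
  )
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  for (k in c("diff_fdr", "network_fdr"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1)
      stop(k, " must lie in (0, 1)")
  if (!cfg$diff_test %in% c("mw", "welch")) stop("diff_test must be mw or welch")
  if (!cfg$network_method %in% c("spearman", "pearson"))
    stop("network_method must be spearman or pearson")
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  if (is.null(cfg$data_dir)) stop("config needs data_dir")
  if (!dir.exists(cfg$data_dir)) stop("data_dir does not exist: ", cfg$data_dir)
  if (!is.null(cfg$gmt_file) && !file.exists(cfg$gmt_file))
    stop("gmt_file does not exist: ", cfg$gmt_file)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
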