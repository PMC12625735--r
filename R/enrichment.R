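#' Assemble a gene-set collection against a universe
#'
#' Sets are intersected with the universe; empty results are kept (they
#' simply can never enrich). The defensible background here is the genes
#' that entered network construction, not the genome.
#'
#' @param sets named list of character vectors (gene ids).
#' @param universe character vector of background gene ids.
#' @return list of class \code{GeneSetCollection}: \code{sets} (filtered),
#'   \code{universe}.
#' @export
geneSetCollection <- function(sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(as.character(universe))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  filtered <- lapply(sets, function(s) intersect(unique(as.character(s)),
                                                 universe))
  structure(list(sets = filtered, universe = universe),
            class = "GeneSetCollection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set: the overlap with the hit list, the upper-tail
#' hypergeometric p-value \code{P[X >= overlap]} (population = universe,
#' successes = set, draws = hits), BH-adjusted q across sets, and fold
#' enrichment \code{(overlap / nHits) / (setSize / nUniverse)}. Stands in
#' for GO analysis with caller-supplied sets; no database access.
#'
#' @param hits character vector of hit genes (e.g. a dense subnetwork's
#'   members); ids outside the universe are dropped with a warning.
#' @param collection a \code{GeneSetCollection} from
#'   [geneSetCollection()] or [readGmt()].
#' @param fdr FDR threshold for the pass flag.
#' @return data.frame: set, set_size, overlap, p, q, fold, pass; sorted
#'   by p.
#' @export
ora <- function(hits, collection, fdr = 0.05) {
  if (!inherits(collection, "GeneSetCollection"))
    stop("'collection' must be a GeneSetCollection")
  uni <- collection$universe
  hits <- unique(as.character(hits))
  out <- setdiff(hits, uni)
  if (length(out)) {
    warning(length(out), " hit(s) outside the universe dropped")
    hits <- intersect(hits, uni)
  }
  if (!length(hits)) stop("no hits remain inside the universe")
  N <- length(uni); nH <- length(hits)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    K <- length(s)
    ov <- length(intersect(hits, s))
    p <- if (K == 0) 1 else
      stats::phyper(ov - 1, K, N - K, nH, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = ov, p = p,
               fold = if (K > 0) (ov / nH) / (K / N) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$pass <- res$q < fdr
  res[order(res$p, res$set), c("set", "set_size", "overlap", "p", "q",
                               "fold", "pass")]
}

#' Read gene sets in GMT format
#'
#' Standard tab-delimited format: set name, description, then member
#' gene ids, one set per line.
#'
#' @param path GMT file path.
#' @param universe background gene ids; defaults to the union of all
#'   sets in the file.
#' @return a \code{GeneSetCollection}.
#' @export
readGmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed GMT line(s): ",
                        paste(utils::head(bad, 3), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  if (is.null(universe)) universe <- unique(unlist(sets))
  geneSetCollection(sets, universe)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to
#'   "na").
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
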