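#' Centered log-ratio transformation
#'
#' Compositional normalization for count tables: per sample,
#' \code{x -> ln(x + pseudocount) - mean_features ln(x + pseudocount)}.
#' Every sample column of the result sums to zero.
#'
#' @param counts non-negative features x samples matrix.
#' @param pseudocount positive offset added before the log (default 0.5).
#' @return matrix of the same shape with attribute \code{pseudocount};
#'   columns sum to zero.
#' @examples
#' m <- matrix(c(1, 10, 100), 3, 1, dimnames = list(letters[1:3], "s1"))
#' clrTransform(m, pseudocount = 1e-12)
#' @export
clrTransform <- function(counts, pseudocount = 0.5) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("'pseudocount' must be a single positive number")
  lg <- log(counts + pseudocount)
  out <- sweep(lg, 2L, colMeans(lg), "-")
  attr(out, "pseudocount") <- pseudocount
  out
}

# BH step-up that tolerates NAs (adjusts over the non-missing family).
.bh <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Per-feature two-way ANOVA (diet x gut segment)
#'
#' Screens for taxa whose diet response differs between compartments:
#' for each feature, a linear model \code{value ~ diet * segment} is fit
#' and type-II F tests extracted for the diet, segment and interaction
#' terms (type II tolerates mild unbalance and coincides with type I/III
#' on balanced designs). Interaction p-values are BH-adjusted across
#' features; \code{pass} flags interaction q below \code{fdr}.
#'
#' @param values features x samples matrix (typically CLR-normalized
#'   microbial abundances with samples = animal x segment).
#' @param dietLabels,segmentLabels factors/character of length
#'   \code{ncol(values)}; each of the four cells needs >= 2 samples.
#' @param fdr FDR threshold for the interaction screen (default 0.05).
#' @return data.frame, one row per feature: F and p for diet, segment and
#'   diet:segment, interaction q and pass flag. Features with zero
#'   residual variance get missing p-values and are flagged
#'   \code{degenerate}.
#' @export
twoWayAnova <- function(values, dietLabels, segmentLabels, fdr = 0.05) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  diet <- factor(dietLabels)
  seg <- factor(segmentLabels)
  if (length(diet) != ncol(values) || length(seg) != ncol(values))
    stop("label length must equal ncol(values)")
  if (nlevels(diet) != 2L || nlevels(seg) != 2L)
    stop("design must be 2 x 2 (two diets, two segments)")
  cells <- table(diet, seg)
  if (any(cells < 2L))
    stop("every diet x segment cell needs >= 2 samples; got min ", min(cells))

  one <- function(y) {
    if (stats::var(y) == 0)
      return(c(NA, NA, NA, NA, NA, NA, degenerate = 1))
    fit <- stats::lm(y ~ diet * seg)
    if (stats::sigma(fit) < .Machine$double.eps^0.5 * max(1, stats::sd(y)))
      return(c(NA, NA, NA, NA, NA, NA, degenerate = 1))
    a <- car::Anova(fit, type = 2)
    c(a["diet", "F value"], a["diet", "Pr(>F)"],
      a["seg", "F value"], a["seg", "Pr(>F)"],
      a["diet:seg", "F value"], a["diet:seg", "Pr(>F)"],
      degenerate = 0)
  }
  res <- t(apply(values, 1L, one))
  out <- data.frame(
    feature = rownames(values),
    F_diet = res[, 1], p_diet = res[, 2],
    F_segment = res[, 3], p_segment = res[, 4],
    F_interaction = res[, 5], p_interaction = res[, 6],
    degenerate = res[, 7] == 1,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$q_interaction <- .bh(out$p_interaction)
  out$pass <- !is.na(out$q_interaction) & out$q_interaction < fdr
  out
}

#' Two-group differential statistics (HFD vs NC) per feature
#'
#' The per-node screen feeding network construction: Mann-Whitney U by
#' default (robust on skewed omics scales) or Welch's t, BH-adjusted
#' across features. The fold change is \code{log2((mean_HFD + pc) /
#' (mean_NC + pc))} when the layer is non-negative (counts/intensities,
#' pseudocount \code{pc}), and the plain mean difference for layers that
#' can be negative (CLR values, phenotypes); only its sign enters the
#' coherence filter downstream.
#'
#' @param values features x samples matrix.
#' @param dietLabels factor/character with levels NC and HFD, length
#'   \code{ncol(values)}; each group needs >= 3 samples.
#' @param method "mw" (Mann-Whitney, default) or "welch".
#' @param pseudocount offset for the fold-change ratio on non-negative
#'   layers.
#' @param fdr FDR threshold for the pass flag.
#' @return data.frame: feature, group means, lfc, stat, p, q, sign
#'   (-1/0/+1), pass. Constant features get missing p and sign 0.
#' @export
twoGroupDifferential <- function(values, dietLabels, method = c("mw", "welch"),
                                 pseudocount = 0.5, fdr = 0.05) {
  method <- match.arg(method)
  if (!is.matrix(values)) stop("'values' must be a matrix")
  diet <- factor(dietLabels, levels = c("NC", "HFD"))
  if (any(is.na(diet))) stop("dietLabels must be NC or HFD")
  if (length(diet) != ncol(values)) stop("label length must equal ncol(values)")
  if (any(table(diet) < 3L)) stop("each diet group needs >= 3 samples")
  iNC <- diet == "NC"
  iHF <- diet == "HFD"
  nonneg <- all(values >= 0)

  one <- function(y) {
    a <- y[iNC]; b <- y[iHF]
    if (stats::var(y) == 0) return(c(mean(a), mean(b), NA, NA))
    ht <- if (method == "mw")
      suppressWarnings(stats::wilcox.test(b, a, exact = FALSE, correct = TRUE))
    else stats::t.test(b, a, var.equal = FALSE)
    c(mean(a), mean(b), unname(ht$statistic), ht$p.value)
  }
  res <- t(apply(values, 1L, one))
  meanNC <- res[, 1]; meanHFD <- res[, 2]
  lfc <- if (nonneg) log2((meanHFD + pseudocount) / (meanNC + pseudocount))
         else meanHFD - meanNC
  lfc[is.na(res[, 4])] <- 0
  out <- data.frame(
    feature = rownames(values), mean_NC = meanNC, mean_HFD = meanHFD,
    lfc = lfc, stat = res[, 3], p = res[, 4],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$q <- .bh(out$p)
  out$sign <- sign(out$lfc)
  out$sign[is.na(out$p)] <- 0
  out$pass <- !is.na(out$q) & out$q < fdr
  out
}

#' Compartment-specific genera by presence screening
#'
#' A genus is "specific to A" when present (count > 0) in at least
#' \code{prevalenceMin} of A samples and in at most \code{maxOther} of B
#' samples (defaults: >= 50\% of one compartment, absent from the other),
#' and vice versa. Both tables must cover the same genus namespace.
#'
#' @param tableA,tableB count matrices with identical rowname sets
#'   (genus ids), samples in columns.
#' @param prevalenceMin minimum presence fraction in the home compartment.
#' @param maxOther maximum presence fraction tolerated in the other
#'   compartment (default 0 = strict absence).
#' @return list with character vectors \code{A} and \code{B} (disjoint).
#' @export
compartmentSpecificFeatures <- function(tableA, tableB, prevalenceMin = 0.5,
                                        maxOther = 0) {
  if (!setequal(rownames(tableA), rownames(tableB)))
    stop("tableA and tableB must share the same genus namespace (rownames)")
  tableB <- tableB[rownames(tableA), , drop = FALSE]
  prevA <- rowMeans(tableA > 0)
  prevB <- rowMeans(tableB > 0)
  list(A = rownames(tableA)[prevA >= prevalenceMin & prevB <= maxOther],
       B = rownames(tableA)[prevB >= prevalenceMin & prevA <= maxOther])
}

#' Shannon alpha diversity per sample
#'
#' \code{H = -sum p_i ln p_i} over features with positive counts, where
#' p are within-sample relative abundances (natural log).
#'
#' @param counts non-negative features x samples matrix; every sample
#'   needs at least one positive count.
#' @return named numeric vector, one value per sample.
#' @examples
#' m <- matrix(c(5, 5, 5, 5), 4, 1, dimnames = list(NULL, "s1"))
#' shannonDiversity(m)  # ln 4
#' @export
shannonDiversity <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  cs <- colSums(counts)
  if (any(cs == 0)) stop("all-zero sample column(s): ",
                         paste(which(cs == 0), collapse = ", "))
  h <- vegan::diversity(t(counts), index = "shannon")
  stats::setNames(as.numeric(h), colnames(counts))
}
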