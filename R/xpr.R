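#' Cluster-level expression matrix with metadata
#'
#' Wraps a clusters x genes matrix of published cluster-level expression
#' values (whatever aggregation statistic the source dataset provides is
#' consumed as-is) together with per-cluster metadata.
#'
#' @param expr numeric matrix, rows = clusters, columns = genes, with
#'   dimnames.
#' @param meta data frame with at least a `cluster` column matching
#'   `rownames(expr)`; an `annotation` column carries the source's
#'   population names, `dataset` its origin.
#' @export
cluster_matrix <- function(expr, meta = NULL) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (is.null(rownames(expr))) {
    if (nrow(expr) > 0) stop("expr must have cluster row names")
    rownames(expr) <- character(0)
  }
  if (is.null(meta))
    meta <- data.frame(cluster = rownames(expr),
                       annotation = rownames(expr),
                       dataset = "unknown", stringsAsFactors = FALSE)
  stopifnot(is.data.frame(meta), "cluster" %in% names(meta),
            nrow(meta) == nrow(expr))
  if (nrow(expr) > 0)
    stopifnot(identical(as.character(meta$cluster), rownames(expr)))
  if (is.null(meta$annotation)) meta$annotation <- meta$cluster
  structure(list(expr = expr, meta = meta), class = "cluster_matrix")
}

#' @export
print.cluster_matrix <- function(x, ...) {
  cat(sprintf("cluster_matrix: %d clusters x %d genes\n",
              nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' Canonical marker rulebook for major brain cell classes
#'
#' The default mapping of cell classes to canonical marker genes:
#' astrocytes (Aldh1l1), ependymal including choroid plexus epithelium
#' (Ttr, Foxj1, Aqp1), vascular endothelial (Pecam1), mural (Pdgfrb,
#' Acta2), fibroblasts (Dcn, Col1a1, Pdgfra), OPCs (Sox10, Pdgfra, Olig2),
#' oligodendrocytes (Olig2, Sox10, Mog), immune i.e. microglia and
#' macrophages (Aif1), neuroblasts (Sox4), and the neuron subclasses
#' excitatory (Slc17a7, Slc17a6), inhibitory (Gad1, Gad2) and cholinergic
#' (Chat).  Monoaminergic/peptidergic/mixed neurons ("other neurons") are a
#' remainder category handled by explicit overrides, not by marker scoring.
#'
#' @return named list mapping class name to a data frame (`gene`,
#'   `direction`); the deterministic tie-break priority is attached as
#'   attribute `"priority"`.
#' @export
default_marker_rulebook <- function() {
  hi <- function(...) data.frame(gene = c(...), direction = "high",
                                 stringsAsFactors = FALSE)
  rb <- list(
    cholinergic = hi("Chat"),
    inhibitory = hi("Gad1", "Gad2"),
    excitatory = hi("Slc17a7", "Slc17a6"),
    astrocytes = hi("Aldh1l1"),
    ependymal = hi("Ttr", "Foxj1", "Aqp1"),
    endothelial = hi("Pecam1"),
    mural = hi("Pdgfrb", "Acta2"),
    fibroblasts = hi("Dcn", "Col1a1", "Pdgfra"),
    OPC = hi("Sox10", "Pdgfra", "Olig2"),
    oligodendrocyte = hi("Olig2", "Sox10", "Mog"),
    immune = hi("Aif1"),
    neuroblasts = hi("Sox4")
  )
  attr(rb, "priority") <- c("cholinergic", "inhibitory", "excitatory",
                            sort(setdiff(names(rb), c("cholinergic",
                                                      "inhibitory",
                                                      "excitatory"))))
  rb
}

#' Remove excluded populations from a cluster matrix
#'
#' Matches exclusion names against the `annotation` metadata column (exact
#' match).  Names that resolve to no cluster produce a warning and are
#' reported, never silently dropped.
#'
#' @param cm a [cluster_matrix()].
#' @param exclude character vector of population names to remove.
#' @return filtered `cluster_matrix`; attributes `"n_removed"` (named
#'   counts per exclusion), `"unresolved"` (names matching nothing) and
#'   `"empty"` (`TRUE` when no cluster survives).
#' @export
filter_populations <- function(cm, exclude = character(0)) {
  stopifnot(inherits(cm, "cluster_matrix"))
  ann <- cm$meta$annotation
  n_removed <- stats::setNames(integer(length(exclude)), exclude)
  drop <- rep(FALSE, nrow(cm$expr))
  unresolved <- character(0)
  for (e in exclude) {
    hit <- ann == e
    n_removed[e] <- sum(hit)
    if (!any(hit)) unresolved <- c(unresolved, e)
    drop <- drop | hit
  }
  if (length(unresolved))
    warning("exclusions matched no cluster: ",
            paste(unresolved, collapse = ", "))
  out <- cluster_matrix(cm$expr[!drop, , drop = FALSE],
                        cm$meta[!drop, , drop = FALSE])
  attr(out, "n_removed") <- n_removed
  attr(out, "unresolved") <- unresolved
  attr(out, "empty") <- nrow(out$expr) == 0
  out
}

#' Assign clusters to major cell classes by canonical markers
#'
#' Each cluster is scored per class as the mean expression of the class's
#' "high" markers minus the mean of its "low" markers (on the matrix's own
#' expression scale) and assigned the argmax class.  Exact ties break by
#' the declared priority order; clusters whose top-two score gap is below
#' `ambiguity_tol` are flagged ambiguous.  Clusters with zero expression of
#' every marker gene are labelled `"unassigned"`.  Missing rulebook genes
#' are reported in attribute `"missing_genes"`.  Manual reassignment is an
#' explicit `overrides` named vector (cluster -> class), never heuristic.
#'
#' @param cm a [cluster_matrix()].
#' @param rulebook marker rulebook (see [default_marker_rulebook()]); list
#'   entries may be character vectors (all "high") or data frames with
#'   `gene`/`direction`.
#' @param priority class order for tie-breaks (defaults to the rulebook's).
#' @param ambiguity_tol score-gap threshold below which a cluster is
#'   flagged ambiguous.
#' @param overrides optional named character vector of manual class
#'   assignments by cluster name.
#' @return data frame: `cluster`, `class`, `score`, `ambiguous`.
#' @export
assign_classes <- function(cm, rulebook = default_marker_rulebook(),
                           priority = NULL, ambiguity_tol = 1e-8,
                           overrides = NULL) {
  stopifnot(inherits(cm, "cluster_matrix"))
  if (is.null(priority)) priority <- attr(rulebook, "priority")
  if (is.null(priority)) priority <- names(rulebook)
  priority <- c(priority, setdiff(names(rulebook), priority))
  genes <- colnames(cm$expr)
  missing_genes <- character(0)
  scores <- matrix(NA_real_, nrow(cm$expr), length(rulebook),
                   dimnames = list(rownames(cm$expr), names(rulebook)))
  all_marker_genes <- character(0)
  for (cl in names(rulebook)) {
    mk <- rulebook[[cl]]
    if (!is.data.frame(mk))
      mk <- data.frame(gene = mk, direction = "high",
                       stringsAsFactors = FALSE)
    if (!any(mk$direction == "high"))
      stop(sprintf("class '%s' has no 'high' marker", cl))
    present <- mk$gene %in% genes
    missing_genes <- c(missing_genes, mk$gene[!present])
    mk <- mk[present, , drop = FALSE]
    all_marker_genes <- c(all_marker_genes, mk$gene)
    if (nrow(mk) == 0) next
    hi <- mk$gene[mk$direction == "high"]
    lo <- mk$gene[mk$direction == "low"]
    s <- if (length(hi)) rowMeans(cm$expr[, hi, drop = FALSE]) else 0
    if (length(lo)) s <- s - rowMeans(cm$expr[, lo, drop = FALSE])
    scores[, cl] <- s
  }
  all_marker_genes <- unique(all_marker_genes)
  ord <- match(colnames(scores), priority)
  out <- data.frame(cluster = rownames(cm$expr),
                    class = NA_character_, score = NA_real_,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]
    if (all(is.na(s)) ||
        all(abs(cm$expr[i, all_marker_genes]) < .Machine$double.eps)) {
      out$class[i] <- "unassigned"
      next
    }
    top <- max(s, na.rm = TRUE)
    cand <- which(!is.na(s) & s == top)
    pick <- cand[which.min(ord[cand])]
    out$class[i] <- colnames(scores)[pick]
    out$score[i] <- top
    second <- suppressWarnings(max(s[-pick], na.rm = TRUE))
    if (is.finite(second) && (top - second) < ambiguity_tol)
      out$ambiguous[i] <- TRUE
  }
  if (!is.null(overrides)) {
    hit <- match(names(overrides), out$cluster)
    if (anyNA(hit)) stop("override names unknown cluster")
    out$class[hit] <- unname(overrides)
  }
  attr(out, "missing_genes") <- unique(missing_genes)
  if (length(missing_genes))
    warning("rulebook genes absent from matrix: ",
            paste(unique(missing_genes), collapse = ", "))
  out
}

#' Per-class summary of a query gene
#'
#' Unweighted mean over member clusters (each subpopulation counts once),
#' SEM over clusters (missing for singletons), and rank by mean
#' (1 = highest; ties broken by first occurrence so ranks are a
#' permutation).
#'
#' @param cm a [cluster_matrix()].
#' @param labels class labels per cluster (vector, or the data frame from
#'   [assign_classes()]).
#' @param gene query gene name (must be present).
#' @return data frame: `class_name`, `n_populations`, `mean`, `sem`,
#'   `rank`.
#' @export
class_summary <- function(cm, labels, gene) {
  stopifnot(inherits(cm, "cluster_matrix"))
  if (!gene %in% colnames(cm$expr))
    stop(sprintf("gene '%s' absent from matrix", gene))
  if (is.data.frame(labels)) labels <- labels$class
  stopifnot(length(labels) == nrow(cm$expr))
  v <- cm$expr[, gene]
  sp <- split(v, labels)
  out <- data.frame(
    class_name = names(sp),
    n_populations = vapply(sp, length, 0L),
    mean = vapply(sp, mean, 0),
    sem = vapply(sp, function(x)
      if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out$rank <- rank(-out$mean, ties.method = "first")
  out[order(out$rank), ]
}

#' Rank concordance of class summaries across datasets
#'
#' Spearman rank correlation of per-class mean expression between every
#' pair of datasets over their shared classes, plus the per-class spread of
#' ranks (max - min across datasets, after re-ranking within the shared
#' set).
#'
#' @param summaries named list (>= 2) of [class_summary()] data frames.
#' @return list with `pairs` (data frame: `dataset1`, `dataset2`,
#'   `n_shared`, `spearman`) and `rank_spread` (per shared class).
#' @export
# Spearman correlation of two rank vectors; the closed form for tie-free
# ranks, so identical rankings give exactly 1 and reversals exactly -1
spearman_rho <- function(r1, r2) {
  n <- length(r1)
  if (anyDuplicated(r1) || anyDuplicated(r2))
    return(stats::cor(r1, r2, method = "spearman"))
  1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
}

rank_consistency <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 2,
            !is.null(names(summaries)))
  shared <- Reduce(intersect, lapply(summaries, function(s) s$class_name))
  if (length(shared) < 3)
    stop("need at least three shared classes across datasets")
  rk <- vapply(summaries, function(s) {
    m <- s$mean[match(shared, s$class_name)]
    rank(-m, ties.method = "average")
  }, numeric(length(shared)))
  rownames(rk) <- shared
  nm <- names(summaries)
  pr <- utils::combn(length(summaries), 2)
  pairs <- data.frame(
    dataset1 = nm[pr[1, ]], dataset2 = nm[pr[2, ]],
    n_shared = length(shared),
    spearman = apply(pr, 2, function(ix) spearman_rho(rk[, ix[1]],
                                                      rk[, ix[2]])),
    stringsAsFactors = FALSE)
  list(pairs = pairs,
       rank_spread = apply(rk, 1, function(r) max(r) - min(r)))
}
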