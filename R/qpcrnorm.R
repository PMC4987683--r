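#' Single-EB qPCR expression panel
#'
#' A genes x EBs matrix of raw CT cycle values with per-EB metadata.
#' Failed reactions are encoded as `NA` (never as the cycle ceiling);
#' present CT values must lie in `(0, 30]` (30 amplification cycles).
#'
#' @param ct numeric matrix, rows = genes (rownames required), columns =
#'   EBs (colnames required); `NA` marks missing reactions.
#' @param metadata data.frame with one row per EB: columns `eb_id`,
#'   `harvest_h`, `group`, and optionally `radius_um`, `devA_h`.
#' @return An object of class `"expression_panel"`.
#' @export
expression_panel <- function(ct, metadata) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' needs gene rownames and EB colnames", call. = FALSE)
  if (anyDuplicated(rownames(ct)))
    stop("duplicate gene names", call. = FALSE)
  if (ncol(ct) == 0L) stop("empty cohort", call. = FALSE)
  vals <- ct[!is.na(ct)]
  if (length(vals) && (any(vals <= 0) || any(vals > 30)))
    stop("CT values must lie in (0, 30]; encode failures as NA",
         call. = FALSE)
  metadata <- as.data.frame(metadata)
  if (!all(c("eb_id", "harvest_h", "group") %in% names(metadata)))
    stop("metadata needs columns eb_id, harvest_h, group", call. = FALSE)
  if (nrow(metadata) != ncol(ct) ||
      !all(as.character(metadata$eb_id) == colnames(ct)))
    stop("metadata rows must match 'ct' columns (same EB ids, same order)",
         call. = FALSE)
  structure(list(ct = ct, metadata = metadata), class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("Expression panel: %d genes x %d EBs, %.1f%% missing, groups: %s\n",
              nrow(x$ct), ncol(x$ct), 100 * mean(is.na(x$ct)),
              paste(unique(as.character(x$metadata$group)), collapse = ", ")))
  invisible(x)
}

complete_candidate_rows <- function(panel, candidates) {
  sub <- panel$ct[candidates, , drop = FALSE]
  keep <- colSums(is.na(sub)) == 0L
  sub[, keep, drop = FALSE]
}

#' geNorm stability (M value) of candidate reference genes
#'
#' For each candidate j, `M_j` is the mean over all other candidates k of
#' the standard deviation across EBs of the pairwise difference
#' `CT_j - CT_k` (the log-ratio of expression). Genes whose expression
#' tracks total cell content move in parallel, so stable candidates have
#' low M. Following the iterative geNorm scheme, [select_normalizers()]
#' repeatedly drops the least stable candidate until two remain.
#'
#' @param panel an [expression_panel()].
#' @param candidates character vector of >= 3 candidate gene names.
#' @return data.frame with columns `gene`, `M`, sorted ascending (most
#'   stable first; ties keep candidate order).
#' @export
genorm_stability <- function(panel, candidates) {
  if (length(candidates) < 3L)
    stop("need at least 3 candidate genes", call. = FALSE)
  if (!all(candidates %in% rownames(panel$ct)))
    stop("unknown candidate gene(s)", call. = FALSE)
  sub <- complete_candidate_rows(panel, candidates)
  if (ncol(sub) < 3L)
    stop("need at least 3 EBs with complete candidate data", call. = FALSE)
  M <- vapply(seq_along(candidates), function(j) {
    others <- setdiff(seq_along(candidates), j)
    mean(vapply(others,
                function(k) stats::sd(sub[j, ] - sub[k, ]), numeric(1)))
  }, numeric(1))
  out <- data.frame(gene = candidates, M = M)
  out[order(out$M), , drop = FALSE]
}

# geNorm final pair: iteratively drop the highest-M candidate.
genorm_top_pair <- function(panel, candidates) {
  current <- candidates
  while (length(current) > 2L) {
    st <- genorm_stability(panel, current)
    current <- setdiff(current, st$gene[nrow(st)])
  }
  current
}

#' NormFinder-style stability of candidate reference genes
#'
#' Model-based stability combining the estimated inter-group bias and the
#' intra-group variance of each candidate's CT values: for candidate i,
#' \deqn{\rho_i = \mathrm{mean}_g \sqrt{d_{ig}^2 + \sigma_{ig}^2}}
#' where `d_ig` is the deviation of the group-g mean from the candidate's
#' grand mean and `sigma_ig^2` its within-group variance. A candidate
#' with identical CT in every EB has stability 0. With a single group the
#' measure reduces to the within-group SD, so the ranking equals the
#' intra-group variance ranking.
#'
#' @param panel an [expression_panel()].
#' @param candidates candidate gene names.
#' @param groups optional group labels per EB; defaults to the panel
#'   metadata `group` column. Each group must hold >= 2 EBs.
#' @return data.frame with columns `gene`, `stability`, sorted ascending.
#' @export
normfinder_stability <- function(panel, candidates, groups = NULL) {
  if (!all(candidates %in% rownames(panel$ct)))
    stop("unknown candidate gene(s)", call. = FALSE)
  sub <- complete_candidate_rows(panel, candidates)
  if (is.null(groups)) groups <- panel$metadata$group
  groups <- as.character(groups)[match(colnames(sub), colnames(panel$ct))]
  tab <- table(groups)
  if (any(tab < 2L))
    stop("every group needs at least 2 EBs with complete candidate data",
         call. = FALSE)
  stab <- vapply(seq_along(candidates), function(i) {
    x <- sub[i, ]
    grand <- mean(x)
    per_group <- vapply(names(tab), function(g) {
      xs <- x[groups == g]
      d <- mean(xs) - grand
      v <- stats::var(xs)
      sqrt(d^2 + v)
    }, numeric(1))
    mean(per_group)
  }, numeric(1))
  out <- data.frame(gene = candidates, stability = stab)
  out[order(out$stability), , drop = FALSE]
}

#' Select the housekeeping normalizer pair
#'
#' Returns the two most stable candidates when the geNorm iterative
#' ranking and the NormFinder-style ranking agree on the same pair (as a
#' set). When they disagree there is no defensible automatic choice, so
#' a condition of class `"ebclock_normalizer_disagreement"` is raised
#' carrying both rankings for inspection.
#'
#' @inheritParams genorm_stability
#' @param groups optional group labels for the NormFinder component.
#' @return Character vector of two gene names (geNorm order).
#' @export
select_normalizers <- function(panel, candidates, groups = NULL) {
  gpair <- genorm_top_pair(panel, candidates)
  nf <- normfinder_stability(panel, candidates, groups)
  npair <- nf$gene[1:2]
  if (!setequal(gpair, npair)) {
    cond <- structure(
      class = c("ebclock_normalizer_disagreement", "error", "condition"),
      list(message = paste0(
        "geNorm and NormFinder disagree on the normalizer pair: geNorm -> {",
        paste(gpair, collapse = ", "), "}, NormFinder -> {",
        paste(npair, collapse = ", "), "}"),
        call = sys.call(-1),
        genorm = genorm_stability(panel, candidates), normfinder = nf))
    stop(cond)
  }
  gpair
}

#' Normalize a CT panel to -ddCt units
#'
#' `dCt = CT_gene - mean(CT of the two normalizers)` compensates for
#' differences in cell number between EBs; `-ddCt = -(dCt - median dCt
#' over the reference group)` shifts each gene so the reference
#' (control) group median is exactly 0. Higher -ddCt means higher
#' expression; one unit is one cycle, i.e. a two-fold change. EBs in
#' which both normalizers failed are dropped (with a message); when one
#' normalizer is missing the other is used alone.
#'
#' @param panel an [expression_panel()].
#' @param normalizers character vector of two housekeeping gene names.
#' @param reference_group group label of the control group (default
#'   `"control"`).
#' @return An object of class `"normalized_panel"`: list with `neg_ddct`
#'   (genes x EBs matrix, normalizer genes excluded), `metadata`,
#'   `normalizer_genes`, `reference_group`, `dropped_ebs`.
#' @export
normalize_neg_ddct <- function(panel, normalizers,
                               reference_group = "control") {
  stopifnot(length(normalizers) == 2L)
  if (!all(normalizers %in% rownames(panel$ct)))
    stop("normalizer gene(s) not in panel", call. = FALSE)
  if (!reference_group %in% panel$metadata$group)
    stop("reference group not present in metadata", call. = FALSE)
  norm_ct <- colMeans(panel$ct[normalizers, , drop = FALSE], na.rm = TRUE)
  dropped <- colnames(panel$ct)[is.na(norm_ct)]
  if (length(dropped))
    message("dropping EB(s) with no usable normalizer value: ",
            paste(dropped, collapse = ", "))
  keep <- !is.na(norm_ct)
  genes <- setdiff(rownames(panel$ct), normalizers)
  dct <- sweep(panel$ct[genes, keep, drop = FALSE], 2, norm_ct[keep], "-")
  meta <- panel$metadata[keep, , drop = FALSE]
  ref <- meta$group == reference_group
  ref_med <- apply(dct[, ref, drop = FALSE], 1, stats::median, na.rm = TRUE)
  neg_ddct <- -sweep(dct, 1, ref_med, "-")
  structure(list(neg_ddct = neg_ddct, metadata = meta,
                 normalizer_genes = normalizers,
                 reference_group = reference_group,
                 dropped_ebs = dropped),
            class = "normalized_panel")
}

#' @export
print.normalized_panel <- function(x, ...) {
  cat(sprintf(
    "Normalized panel: %d genes x %d EBs (-ddCt, normalizers %s, reference '%s')\n",
    nrow(x$neg_ddct), ncol(x$neg_ddct),
    paste(x$normalizer_genes, collapse = " + "), x$reference_group))
  invisible(x)
}

#' Nearest-neighbor imputation of missing matrix entries
#'
#' Fills each missing cell (gene g, EB e) with the value of g in the EB
#' nearest to e, where distance is the root mean squared difference over
#' the genes observed in both EBs (so EBs with different missingness
#' patterns are comparable). Observed cells are never changed. Intended
#' for the -ddCt matrix ahead of clustering or PCA; trend analyses
#' should use observed values only.
#'
#' @param mat numeric matrix (genes x EBs) with `NA` for missing values.
#' @return Matrix of the same shape with missing cells filled.
#' @export
impute_nn <- function(mat) {
  mat <- as.matrix(mat)
  if (any(rowSums(!is.na(mat)) == 0L))
    stop("gene(s) with no observed value cannot be imputed", call. = FALSE)
  if (any(colSums(!is.na(mat)) == 0L))
    stop("EB(s) with no observed value cannot be imputed", call. = FALSE)
  if (!anyNA(mat)) return(mat)
  out <- mat
  n <- ncol(mat)
  for (e in which(colSums(is.na(mat)) > 0L)) {
    miss_genes <- which(is.na(mat[, e]))
    d <- vapply(seq_len(n), function(o) {
      if (o == e) return(Inf)
      shared <- !is.na(mat[, e]) & !is.na(mat[, o])
      if (!any(shared)) return(Inf)
      sqrt(mean((mat[shared, e] - mat[shared, o])^2))
    }, numeric(1))
    for (g in miss_genes) {
      cand <- which(is.finite(d) & !is.na(mat[g, ]))
      if (!length(cand))
        stop("no neighbor observes gene '", rownames(mat)[g],
             "' for EB '", colnames(mat)[e], "'", call. = FALSE)
      out[g, e] <- mat[g, cand[which.min(d[cand])]]
    }
  }
  out
}

#' Hierarchical clustering on Pearson correlation
#'
#' Agglomerative average-linkage clustering with distance
#' `d = 1 - r` (Pearson correlation between profiles). With the profiles
#' in a fixed input order the merge sequence and leaf order are
#' deterministic.
#'
#' @param mat numeric matrix.
#' @param axis `"rows"` to cluster row profiles (genes), `"cols"` for
#'   column profiles (EBs).
#' @return An `hclust` object (leaf order in `$order`).
#' @export
cluster_corr <- function(mat, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  mat <- as.matrix(mat)
  if (axis == "rows") mat <- t(mat)
  if (ncol(mat) < 2L) stop("need at least 2 profiles", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("constant profile(s): Pearson correlation undefined for ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(mat))
  stats::hclust(d, method = "average")
}

#' Fold range of a gene across EBs
#'
#' The expression ratio between the highest- and lowest-expressing EB:
#' `2^(max - min)` on the -ddCt (log2) scale. A gene spanning 12 cycles
#' varies 4096-fold.
#'
#' @param gene_values numeric -ddCt values (>= 2 observed).
#' @return Fold change (>= 1).
#' @export
fold_range <- function(gene_values) {
  v <- gene_values[!is.na(gene_values)]
  if (length(v) < 2L) stop("need at least 2 observed values", call. = FALSE)
  2^(max(v) - min(v))
}
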