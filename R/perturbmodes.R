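#' Per-gene expression shift of a perturbation group
#'
#' For every gene, the difference between the group's median -ddCt and
#' the control group's median, with an advisory significance flag from a
#' two-group Wilcoxon rank-sum test, Benjamini--Hochberg corrected across
#' genes at 0.05. Swapping `group` and `control` negates the deltas.
#'
#' @param normalized a `"normalized_panel"` from [normalize_neg_ddct()].
#' @param group perturbation group label.
#' @param control control group label.
#' @return data.frame with columns `gene`, `group`, `delta`, `p_value`,
#'   `p_adj`, `significant`.
#' @export
group_shift <- function(normalized, group, control = "control") {
  meta <- normalized$metadata
  in_g <- meta$group == group
  in_c <- meta$group == control
  if (sum(in_g) < 3L || sum(in_c) < 3L)
    stop("both groups need at least 3 EBs", call. = FALSE)
  mat <- normalized$neg_ddct
  res <- lapply(rownames(mat), function(g) {
    xg <- mat[g, in_g]; xc <- mat[g, in_c]
    xg <- xg[!is.na(xg)]; xc <- xc[!is.na(xc)]
    p <- if (length(xg) >= 2L && length(xc) >= 2L)
      suppressWarnings(stats::wilcox.test(xg, xc)$p.value) else NA_real_
    data.frame(gene = g, group = group,
               delta = stats::median(xg) - stats::median(xc), p_value = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' PCA of EBs in expression space
#'
#' Principal component analysis of the EB x gene -ddCt matrix after
#' nearest-neighbor imputation of missing cells and gene-wise centering,
#' with percent explained variance per component. Used to visualize the
#' gradual directional effect of perturbation duration on expression
#' state.
#'
#' @param normalized a `"normalized_panel"`.
#' @param n_pc number of components to return (default all).
#' @return List with `scores` (EB x PC matrix), `percent_var` (per
#'   returned PC), `groups` (per-EB labels), `rotation` (gene loadings).
#' @export
pca_groups <- function(normalized, n_pc = NULL) {
  mat <- normalized$neg_ddct
  if (nrow(mat) < 2L || ncol(mat) < 3L)
    stop("need at least 2 genes and 3 EBs", call. = FALSE)
  mat <- impute_nn(mat)
  x <- t(mat)                          # EBs as observations
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) stop("rank-0 matrix", call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(n_pc)) n_pc <- length(pc$sdev)
  n_pc <- min(n_pc, length(pc$sdev))
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       percent_var = pct[seq_len(n_pc)],
       groups = normalized$metadata$group,
       rotation = pc$rotation[, seq_len(n_pc), drop = FALSE])
}

group_median <- function(v, idx) stats::median(v[idx], na.rm = TRUE)

#' Classify Wnt3-dependency modes under CHIR perturbation
#'
#' CHIR activates canonical Wnt signaling downstream of the Wnt3 ligand
#' while simultaneously lowering Wnt3 transcription, so it dissociates
#' canonical-pathway targets from Wnt3 levels. For each gene correlated
#' with Wnt3 on control EBs, the classifier asks how the gene behaves
#' under CHIR relative to the control-EB trend line of gene vs Wnt3:
#'
#' * `canonical_regulation` — the gene's expression moves off the trend
#'   (up for activation, like Lmo2 or Brachyury, despite Wnt3 dropping).
#' * `trend_continuation` — expression moves along the control trend to
#'   the new (lower) Wnt3 level, as for Otx2: regulation via a
#'   non-canonical route, or simply expedited developmental progression.
#' * `decoupled_parallel` — expression does not move although Wnt3 does
#'   (Mixl1): the correlation reflects a parallel mechanism.
#' * `indirect_long_term_only` — only the long (24--72 h) treatment
#'   changes expression while short pulses do not, pointing to indirect,
#'   slow-acting effects.
#' * `not_correlated` — |Pearson r| with Wnt3 on control EBs below
#'   `r_min`.
#'
#' Operationally, per gene: (1) Pearson r vs Wnt3 on control EBs;
#' (2) control trend line of gene vs Wnt3, fitted as the standardized
#' major axis (slope `sign(r) * sd(gene)/sd(Wnt3)`) because both axes are
#' measured with noise and an ordinary regression of gene on Wnt3 would
#' attenuate the slope and make trend-following genes look off-trend;
#' (3) per group,
#' `shift_z` = (group median - control median) / control SD and
#' `residual_z` = median trend residual / control residual SD; (4) the
#' ordered rules: no group with |shift_z| > k -> decoupled_parallel;
#' shifted only in the long group -> indirect_long_term_only; otherwise
#' off-trend (any shifted group with |residual_z| > k) ->
#' canonical_regulation, else trend_continuation. All statistics are
#' invariant to gene-wise affine rescaling of -ddCt.
#'
#' @param normalized a `"normalized_panel"` covering a control group and
#'   CHIR perturbation groups.
#' @param wnt3_gene name of the Wnt3 row (default `"Wnt3"`).
#' @param control control group label.
#' @param long_group label of the long CHIR treatment group.
#' @param short_groups labels of the short CHIR pulse groups; with none
#'   present the long-only mode is unresolvable and the classifier says
#'   so rather than guessing.
#' @param r_min correlation gate for `not_correlated` (default 0.5).
#' @param k z-score threshold for "moved"/"off-trend" (default 2).
#' @return data.frame (one row per gene, Wnt3 excluded): `gene`,
#'   `r_wnt3`, `trend_slope`, `trend_intercept`, `shift_z_*` and
#'   `residual_z_*` per group, `mode`, and `direction`
#'   (`"activation"`/`"repression"` for canonical calls).
#' @export
classify_dependency_modes <- function(normalized, wnt3_gene = "Wnt3",
                                      control = "control",
                                      long_group = "chir_long",
                                      short_groups = c("chir_short_early",
                                                       "chir_short_late"),
                                      r_min = 0.5, k = 2) {
  mat <- normalized$neg_ddct
  meta <- normalized$metadata
  if (!wnt3_gene %in% rownames(mat))
    stop("Wnt3 gene '", wnt3_gene, "' not in panel", call. = FALSE)
  in_ctrl <- meta$group == control
  if (sum(in_ctrl) < 5L)
    stop("control group needs at least 5 EBs", call. = FALSE)
  groups_present <- intersect(c(short_groups, long_group),
                              unique(meta$group))
  short_present <- intersect(short_groups, groups_present)
  if (!long_group %in% groups_present)
    stop("long CHIR group '", long_group, "' absent", call. = FALSE)
  if (length(short_present) == 0L)
    message("no short CHIR group present: indirect_long_term_only ",
            "cannot be distinguished from the other modes")
  wnt3 <- mat[wnt3_gene, ]
  genes <- setdiff(rownames(mat), wnt3_gene)

  rows <- lapply(genes, function(g) {
    y <- mat[g, ]
    ok_ctrl <- in_ctrl & !is.na(y) & !is.na(wnt3)
    r <- stats::cor(y[ok_ctrl], wnt3[ok_ctrl])
    ctrl_sd <- stats::sd(y[ok_ctrl])
    # standardized major axis: symmetric in the two noisy variables
    slope <- sign(r) * ctrl_sd / stats::sd(wnt3[ok_ctrl])
    intercept <- mean(y[ok_ctrl]) - slope * mean(wnt3[ok_ctrl])
    resid_ctrl_sd <- stats::sd(y[ok_ctrl] -
                                 (intercept + slope * wnt3[ok_ctrl]))
    ctrl_med <- stats::median(y[ok_ctrl])
    zs <- lapply(groups_present, function(grp) {
      idx <- meta$group == grp & !is.na(y) & !is.na(wnt3)
      shift_z <- (group_median(y, idx) - ctrl_med) / ctrl_sd
      resid <- y[idx] - (intercept + slope * wnt3[idx])
      residual_z <- stats::median(resid) / resid_ctrl_sd
      c(shift_z = shift_z, residual_z = residual_z)
    })
    names(zs) <- groups_present
    shift_z <- vapply(zs, `[[`, numeric(1), "shift_z")
    residual_z <- vapply(zs, `[[`, numeric(1), "residual_z")

    direction <- NA_character_
    if (is.na(r) || abs(r) < r_min) {
      mode <- "not_correlated"
    } else {
      moved <- abs(shift_z) > k
      if (!any(moved)) {
        mode <- "decoupled_parallel"
      } else if (length(short_present) > 0L &&
                 moved[long_group] && !any(moved[short_present])) {
        mode <- "indirect_long_term_only"
      } else {
        off_trend <- abs(residual_z) > k
        if (any(off_trend & moved)) {
          mode <- "canonical_regulation"
          direction <- if (stats::median(residual_z[off_trend & moved]) > 0)
            "activation" else "repression"
        } else {
          mode <- "trend_continuation"
        }
      }
    }
    row <- data.frame(gene = g, r_wnt3 = r, trend_slope = unname(slope),
                      trend_intercept = unname(intercept))
    for (grp in groups_present) {
      row[[paste0("shift_z_", grp)]] <- unname(shift_z[grp])
      row[[paste0("residual_z_", grp)]] <- unname(residual_z[grp])
    }
    row$mode <- mode
    row$direction <- direction
    row
  })
  do.call(rbind, rows)
}
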