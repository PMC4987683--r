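#' Specification of one synthetic gene
#'
#' Describes how a gene's expression (in -ddCt units, log2 scale) depends
#' on developmental age and on perturbation group:
#' `-ddCt = intercept + slope_devA * DevA + shift(group) + noise`.
#' Housekeeping genes must have zero slope and small noise.
#'
#' @param name gene name.
#' @param intercept expression at DevA = 0, -ddCt units.
#' @param slope_devA trend along the clock, -ddCt units per hour.
#' @param noise_sd biological + technical noise SD, -ddCt units (>= 0).
#' @param perturbation_shifts named list/vector of additive group shifts
#'   (-ddCt units), e.g. `c(chir_long = -4)`; unlisted groups shift 0.
#' @param housekeeping logical: stable reference gene (forces
#'   `slope_devA = 0`).
#' @param wnt3_mode designed Wnt3-dependency mode label, one of `"none"`,
#'   `"canonical_regulation"`, `"trend_continuation"`,
#'   `"decoupled_parallel"`, `"indirect_long_term_only"`; ground truth
#'   for classifier validation.
#' @return An object of class `"gene_spec"`.
#' @export
gene_spec <- function(name, intercept = 0, slope_devA = 0, noise_sd = 0.3,
                      perturbation_shifts = NULL, housekeeping = FALSE,
                      wnt3_mode = c("none", "canonical_regulation",
                                    "trend_continuation",
                                    "decoupled_parallel",
                                    "indirect_long_term_only")) {
  wnt3_mode <- match.arg(wnt3_mode)
  stopifnot(is.character(name), length(name) == 1L, noise_sd >= 0)
  if (housekeeping && slope_devA != 0)
    stop("housekeeping genes must have slope_devA = 0", call. = FALSE)
  shifts <- unlist(perturbation_shifts)
  if (!is.null(shifts) && is.null(names(shifts)))
    stop("perturbation_shifts must be named by group", call. = FALSE)
  structure(list(name = name, intercept = intercept,
                 slope_devA = slope_devA, noise_sd = noise_sd,
                 perturbation_shifts = shifts, housekeeping = housekeeping,
                 wnt3_mode = wnt3_mode),
            class = "gene_spec")
}

spec_shift <- function(spec, group) {
  s <- spec$perturbation_shifts
  if (is.null(s) || !(group %in% names(s))) 0 else unname(s[[group]])
}

#' Generate a synthetic single-EB CT panel
#'
#' Builds a genes x EBs CT matrix whose expression structure is linear in
#' developmental age plus group shifts and noise. Each EB gets a loading
#' offset (cell-number proxy) shared by all its genes; two or more
#' designated housekeeping genes track that offset with small noise, so
#' -ddCt normalization against them removes it. Target genes are emitted
#' as `CT = loading + base_gene - signal`, inverting the -ddCt transform.
#'
#' The returned truth record stores, per gene, the signal minus its
#' noise-free control-group median — exactly what [normalize_neg_ddct()]
#' recovers when all noise terms are zero.
#'
#' @param devA_per_eb developmental age of each EB, hours.
#' @param gene_specs list of [gene_spec()] objects (>= 2 must be
#'   housekeeping).
#' @param groups character vector of group labels per EB (default all
#'   `"control"`).
#' @param harvest_h,radius_um optional per-EB metadata.
#' @param missing_rate probability that any single reaction fails
#'   (emitted as `NA`).
#' @param loading_mean,loading_sd per-EB loading offset distribution
#'   (CT cycles).
#' @param hk_noise_sd technical noise of housekeeping reactions, cycles.
#' @param reference_group label of the control group used for centering.
#' @param seed optional RNG seed.
#' @return List with `panel` (an [expression_panel()]) and `truth` (list
#'   with `neg_ddct` matrix, `devA`, `groups`, `modes`, `hk_genes`).
#' @export
gen_expression_panel <- function(devA_per_eb, gene_specs,
                                 groups = NULL, harvest_h = NULL,
                                 radius_um = NULL, missing_rate = 0,
                                 loading_mean = 13, loading_sd = 0.8,
                                 hk_noise_sd = 0.05,
                                 reference_group = "control",
                                 seed = NULL) {
  n <- length(devA_per_eb)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(groups)) groups <- rep("control", n)
  stopifnot(length(groups) == n)
  if (!reference_group %in% groups)
    stop("no EB belongs to the reference group", call. = FALSE)
  names_ <- vapply(gene_specs, function(s) s$name, character(1))
  if (anyDuplicated(names_)) stop("duplicate gene names", call. = FALSE)
  hk <- vapply(gene_specs, function(s) s$housekeeping, logical(1))
  if (sum(hk) < 2L)
    stop("need at least two housekeeping gene specs", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  loading <- stats::rnorm(n, loading_mean, loading_sd)
  eb_id <- sprintf("eb%03d", seq_len(n))
  ct <- matrix(NA_real_, nrow = length(gene_specs), ncol = n,
               dimnames = list(names_, eb_id))
  truth_sig <- matrix(NA_real_, nrow = length(gene_specs), ncol = n,
                      dimnames = list(names_, eb_id))
  hk_offsets <- seq(0, by = 0.7, length.out = sum(hk))
  i_hk <- 0L
  ctrl <- groups == reference_group
  for (i in seq_along(gene_specs)) {
    sp <- gene_specs[[i]]
    if (sp$housekeeping) {
      i_hk <- i_hk + 1L
      ct[i, ] <- loading + hk_offsets[i_hk] +
        stats::rnorm(n, sd = max(sp$noise_sd, hk_noise_sd))
      next
    }
    shift <- vapply(as.character(groups), function(g) spec_shift(sp, g),
                    numeric(1))
    clean <- sp$intercept + sp$slope_devA * devA_per_eb + shift
    signal <- clean + stats::rnorm(n, sd = sp$noise_sd)
    base_g <- 4      # gene-specific assay offset; cancels in -ddCt
    ct[i, ] <- loading + base_g - signal
    truth_sig[i, ] <- signal - stats::median(clean[ctrl])
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(ct)) < missing_rate, nrow = nrow(ct))
    ct[drop] <- NA_real_
  }
  out_of_range <- !is.na(ct) & (ct <= 0 | ct > 30)
  if (any(out_of_range)) {
    warning("clipping ", sum(out_of_range), " CT value(s) into (0, 30]")
    ct[out_of_range] <- pmin(pmax(ct[out_of_range], 0.1), 30)
  }
  meta <- data.frame(
    eb_id = eb_id,
    harvest_h = if (is.null(harvest_h)) NA_real_ else harvest_h,
    group = as.character(groups),
    radius_um = if (is.null(radius_um)) NA_real_ else radius_um,
    devA_h = devA_per_eb)
  list(panel = expression_panel(ct, meta),
       truth = list(neg_ddct = truth_sig[!hk, , drop = FALSE],
                    devA = devA_per_eb, groups = as.character(groups),
                    modes = stats::setNames(
                      vapply(gene_specs, function(s) s$wnt3_mode,
                             character(1)), names_)[!hk],
                    hk_genes = names_[hk]))
}

#' Default synthetic gene panel
#'
#' A compact panel emulating the structure of the profiled gene set: two
#' stable housekeeping genes (Rock2, Ywhaz), a Wnt3 signaling gene that
#' declines along the clock and is down-regulated by CHIR, primitive
#' streak genes declining with DevA, later mesoderm genes rising with
#' DevA, Bmp4 rising, plus a flat high-noise gene with no clock trend.
#' Shifts under the CHIR and Bmp4 presets follow the designed dependency
#' modes of the exemplar genes.
#'
#' @return List of [gene_spec()] objects.
#' @export
default_gene_panel <- function() {
  wnt3_shifts <- c(chir_long = -4, chir_short_late = -2.5,
                   chir_short_early = -2)
  list(
    gene_spec("Rock2", housekeeping = TRUE, noise_sd = 0.05),
    gene_spec("Ywhaz", housekeeping = TRUE, noise_sd = 0.05),
    gene_spec("Wnt3", intercept = 3, slope_devA = -0.2, noise_sd = 0.3,
              perturbation_shifts = wnt3_shifts),
    gene_spec("T", intercept = 4, slope_devA = -0.3, noise_sd = 0.3,
              perturbation_shifts = c(chir_long = 5, chir_short_late = 4,
                                      chir_short_early = 3.5, bmp4 = -2),
              wnt3_mode = "canonical_regulation"),
    gene_spec("Lmo2", intercept = 2, slope_devA = -0.3, noise_sd = 0.3,
              perturbation_shifts = c(chir_long = 5, chir_short_late = 4,
                                      chir_short_early = 3.5),
              wnt3_mode = "canonical_regulation"),
    gene_spec("Otx2", intercept = 3.5, slope_devA = -0.3, noise_sd = 0.3,
              perturbation_shifts = c(chir_long = -6, chir_short_late = -3.75,
                                      chir_short_early = -3, bmp4 = -2),
              wnt3_mode = "trend_continuation"),
    gene_spec("Mixl1", intercept = 3, slope_devA = -0.3, noise_sd = 0.3,
              wnt3_mode = "decoupled_parallel"),
    gene_spec("Eomes", intercept = 3, slope_devA = -0.25, noise_sd = 0.35,
              perturbation_shifts = c(chir_long = -3, bmp4 = -2)),
    gene_spec("Gata6", intercept = -2, slope_devA = 0.2, noise_sd = 0.35,
              perturbation_shifts = c(chir_long = -3),
              wnt3_mode = "indirect_long_term_only"),
    gene_spec("Mef2c", intercept = -2, slope_devA = 0.2, noise_sd = 0.35),
    gene_spec("Bmp4", intercept = -1, slope_devA = 0.25, noise_sd = 0.35),
    gene_spec("Klf4", intercept = 0, slope_devA = 0, noise_sd = 1,
              wnt3_mode = "none"))
}

#' Gene specs for dependency-mode recovery experiments
#'
#' Builds `n_per_mode` genes for each of the four Wnt3-dependency modes
#' plus uncorrelated controls, with effect sizes of at least three
#' control SDs, alongside the Wnt3 spec and two housekeeping genes.
#' All correlated genes share the clock trend direction with Wnt3
#' (slope -0.3 vs Wnt3's -0.2 per hour of DevA), so on control EBs their
#' correlation with Wnt3 is strong and the control trend line has slope
#' 1.5; the per-mode CHIR shifts are sized relative to that line.
#'
#' @param n_per_mode genes per mode.
#' @param noise_sd per-gene noise, -ddCt units.
#' @return List of [gene_spec()] objects.
#' @export
mode_gene_specs <- function(n_per_mode = 20, noise_sd = 0.3) {
  wnt3_shifts <- c(chir_long = -4, chir_short_late = -2.5,
                   chir_short_early = -2)
  trend_ratio <- -0.3 / -0.2     # control trend slope of gene vs Wnt3
  specs <- list(
    gene_spec("Rock2", housekeeping = TRUE, noise_sd = 0.05),
    gene_spec("Ywhaz", housekeeping = TRUE, noise_sd = 0.05),
    gene_spec("Wnt3", intercept = 3, slope_devA = -0.2, noise_sd = noise_sd,
              perturbation_shifts = wnt3_shifts))
  add <- function(specs, name, shifts, mode)
    c(specs, list(gene_spec(name, intercept = 3, slope_devA = -0.3,
                            noise_sd = noise_sd,
                            perturbation_shifts = shifts, wnt3_mode = mode)))
  for (i in seq_len(n_per_mode)) {
    specs <- add(specs, sprintf("canon%02d", i),
                 c(chir_long = 5, chir_short_late = 4,
                   chir_short_early = 3.5), "canonical_regulation")
    specs <- add(specs, sprintf("trend%02d", i),
                 trend_ratio * wnt3_shifts, "trend_continuation")
    specs <- add(specs, sprintf("decoup%02d", i), NULL,
                 "decoupled_parallel")
    specs <- add(specs, sprintf("indir%02d", i), c(chir_long = -5),
                 "indirect_long_term_only")
    specs <- c(specs, list(
      gene_spec(sprintf("uncor%02d", i), intercept = 0, slope_devA = 0,
                noise_sd = 1, wnt3_mode = "none")))
  }
  specs
}
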