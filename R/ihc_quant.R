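# Quantification formulas for pathology readouts: H-score, pooled field
# density, PD-L1 combined positive score, regional ratios, and the
# spatial immune-phenotype call.

#' H-score from stain-intensity percentages
#'
#' 1 x weak% + 2 x medium% + 3 x strong%, range [0, 300].
#'
#' @param weak_pct,medium_pct,strong_pct percentages in [0,100] summing
#'   to at most 100 (vectorized).
#' @return numeric H-score(s).
#' @export
h_score <- function(weak_pct, medium_pct, strong_pct) {
  v <- cbind(weak_pct, medium_pct, strong_pct)
  if (any(v < 0) || any(v > 100)) stop("validation error: percentages outside [0,100]")
  if (any(rowSums(v) > 100 + 1e-9))
    stop("validation error: stain percentages sum to more than 100")
  drop(v %*% c(1, 2, 3))
}

#' Pooled positive-cell density over fields
#'
#' Sum of counts divided by sum of areas (a single fraction of sums),
#' not the mean of per-field ratios.
#'
#' @param counts positive-cell counts per field (length 5 by
#'   convention).
#' @param areas_mm2 field areas in mm^2, same length.
#' @return cells/mm^2.
#' @export
cell_density <- function(counts, areas_mm2) {
  if (length(counts) != length(areas_mm2)) stop("counts/areas length mismatch")
  if (any(counts < 0)) stop("validation error: negative count")
  if (any(areas_mm2 <= 0) || sum(areas_mm2) == 0)
    stop("validation error: field areas must be positive")
  sum(counts) / sum(areas_mm2)
}

#' PD-L1 combined positive score
#'
#' 100 x (PD-L1-positive tumor cells + lymphocytes + macrophages) /
#' viable tumor cells, capped at 100 per the standard clinical
#' convention.
#'
#' @param positive_cells PD-L1-positive cell count.
#' @param viable_tumor_cells viable tumor cell count (>= 1).
#' @return list(cps, cps_ge_5) — the score and the CPS >= 5 flag.
#' @export
cps <- function(positive_cells, viable_tumor_cells) {
  if (any(viable_tumor_cells < 1))
    stop("validation error: viable tumor cells must be >= 1")
  if (any(positive_cells < 0)) stop("validation error: negative count")
  score <- pmin(100, 100 * positive_cells / viable_tumor_cells)
  list(cps = score, cps_ge_5 = score >= 5)
}

#' Core-of-tumor / invasive-margin density ratio
#'
#' Cases where either regional density is below `min_density` (default
#' 5 cells/mm^2) are excluded (returned as NA) to avoid abnormal
#' oversize/undersize ratios.
#'
#' @param density_ct,density_im regional densities (cells/mm^2).
#' @param min_density exclusion threshold.
#' @return ratio, or NA when excluded.
#' @export
ct_im_ratio <- function(density_ct, density_im, min_density = 5) {
  if (any(c(density_ct, density_im) < 0)) stop("validation error: negative density")
  ifelse(density_ct >= min_density & density_im >= min_density,
         density_ct / density_im, NA_real_)
}

#' Spatial immune phenotype from regional CD8 densities
#'
#' inflamed: CD8 density in the tumor core at or above `t_high`;
#' excluded: core below `t_high` but invasive margin at or above
#' `t_high`; desert: both compartments below.  (Equivalently: borderline
#' cores in [t_low, t_high) fall to excluded when the margin is rich,
#' else desert — the partition is total and deterministic.)
#'
#' @param cd8_ct,cd8_im CD8 densities (cells/mm^2), vectorized.
#' @param t_high,t_low thresholds (cells/mm^2), t_low <= t_high; the
#'   defaults are configuration values, not published cutoffs.
#' @return character vector in {"inflamed", "excluded", "desert"}.
#' @export
classify_phenotype <- function(cd8_ct, cd8_im, t_high = 50, t_low = 10) {
  if (t_low > t_high) stop("t_low must be <= t_high")
  if (any(c(cd8_ct, cd8_im) < 0)) stop("validation error: negative density")
  ifelse(cd8_ct >= t_high, "inflamed",
         ifelse(cd8_im >= t_high, "excluded", "desert"))
}

#' M1/M2 macrophage density ratio
#'
#' Greater than 1 means an M1-skewed (anti-tumor) milieu.  When both
#' densities are zero the ratio is defined as 1 with a warning; M1 > 0
#' with M2 = 0 gives Inf.
#'
#' @param m1_density,m2_density densities (cells/mm^2).
#' @return ratio(s).
#' @export
m1_m2_ratio <- function(m1_density, m2_density) {
  if (any(c(m1_density, m2_density) < 0)) stop("validation error: negative density")
  both_zero <- m1_density == 0 & m2_density == 0
  if (any(both_zero)) warning("both densities zero; ratio defined as 1")
  ifelse(both_zero, 1, m1_density / m2_density)
}
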