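# FISH census arithmetic: relative densities from probe/DAPI counts and
# percent contributions of a probe-defined group.

#' Relative density of a probe-hybridized population
#'
#' The product of the probe-positive fraction of DAPI-stained objects on the
#' filter sections and the DAPI-stained direct cell count; any
#' filtration-volume/filter-area calibration is assumed already folded into
#' `dapi_cells_per_ml`.
#'
#' @param fraction_of_dapi probe-positive fraction of DAPI objects, in
#'   `[0, 1]`.
#' @param dapi_cells_per_ml DAPI direct count (cells/mL, >= 0).
#' @return cells/mL.
#' @examples
#' relative_density(0.05, 1e6)  # 5e4 cells/mL
#' @export
relative_density <- function(fraction_of_dapi, dapi_cells_per_ml) {
  stopifnot(all(fraction_of_dapi >= 0), all(fraction_of_dapi <= 1),
            all(dapi_cells_per_ml >= 0))
  fraction_of_dapi * dapi_cells_per_ml
}

#' Percent contribution of a probe population to a group
#'
#' `100 * probe_density / group_density`. Values above 100 are reported
#' as-is with a warning (counting noise between probes can make a subgroup
#' count exceed its group).
#'
#' @param probe_density cells/mL of the specific probe population.
#' @param group_density cells/mL of the encompassing group (> 0).
#' @return percent.
#' @examples
#' percent_of_group(5e4, 2e5)  # 25
#' @export
percent_of_group <- function(probe_density, group_density) {
  if (any(group_density <= 0)) stop("group density must be positive")
  p <- 100 * probe_density / group_density
  if (any(p > 100))
    warning("probe density exceeds group density (> 100%); counting noise")
  p
}

#' Process a FISH count table
#'
#' @param counts data.frame with columns `sample_id`, `depth_m`, `probe_id`,
#'   `fraction_of_dapi`, `dapi_cells_per_ml`, and optionally
#'   `group_probe_id` naming the encompassing group probe measured in the
#'   same sample/depth (for percent contributions).
#' @return the input with `density_cells_per_ml` and, where a group probe is
#'   given, `percent_of_group` columns added.
#' @export
fish_census <- function(counts) {
  need <- c("sample_id", "depth_m", "probe_id", "fraction_of_dapi",
            "dapi_cells_per_ml")
  if (!all(need %in% names(counts)))
    stop("missing column(s): ", paste(setdiff(need, names(counts)),
                                      collapse = ", "))
  counts$density_cells_per_ml <- relative_density(
    counts$fraction_of_dapi, counts$dapi_cells_per_ml)
  if ("group_probe_id" %in% names(counts)) {
    counts$percent_of_group <- NA_real_
    for (i in seq_len(nrow(counts))) {
      gp <- counts$group_probe_id[i]
      if (is.na(gp) || !nzchar(gp)) next
      g <- counts[counts$sample_id == counts$sample_id[i] &
                    counts$depth_m == counts$depth_m[i] &
                    counts$probe_id == gp, , drop = FALSE]
      if (nrow(g) != 1)
        stop("group probe '", gp, "' not uniquely measured for sample ",
             counts$sample_id[i], " at ", counts$depth_m[i], " m")
      counts$percent_of_group[i] <- percent_of_group(
        counts$density_cells_per_ml[i], g$density_cells_per_ml)
    }
  }
  counts
}
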