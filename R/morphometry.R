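#' Bifurcation angle between the aorta and a branch
#'
#' Computes the angle between the branch vector and the aortic vector, each
#' spanning an arc distance `d_branch` along its centerline: the branch vector
#' runs from the first branch-centerline point forward; the aortic vector runs
#' from the aortic-centerline point closest to the branch origin towards the
#' descending aorta (the aortic centerline must be ordered inlet to DA).
#' `d_branch` conventionally equals the branch diameter; the default is the
#' maximum diameter of the first extracted branch section when `sections` is
#' supplied.
#'
#' @param cl_ao Aortic [centerline()], ordered inlet to descending aorta.
#' @param cl_branch Branch [centerline()], ordered origin to tip.
#' @param d_branch Arc distance (mm) defining both vectors; required unless
#'   `sections` is given.
#' @param sections Optional `cross_sections` of the branch; its first
#'   station's `dmax_cm` (converted to mm) is used as `d_branch`.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bifurcation_angle <- function(cl_ao, cl_branch, d_branch = NULL, sections = NULL) {
  if (is.null(d_branch)) {
    if (is.null(sections) || nrow(sections) < 1) {
      abort("Provide `d_branch` or branch `sections`.")
    }
    d_branch <- sections$dmax_cm[1] * 10
  }
  if (d_branch <= 0) abort("`d_branch` must be positive.")
  if (d_branch > cl_length(cl_branch)) {
    abort(sprintf("Centerline '%s' (%.1f mm) is shorter than d_branch = %.1f mm.",
                  cl_label(cl_branch), cl_length(cl_branch), d_branch))
  }
  o <- cl_point_at(cl_branch, 0)
  v_branch <- cl_point_at(cl_branch, d_branch) - o

  ao <- cl_points(cl_ao)
  d2 <- rowSums(sweep(ao, 2, o)^2)
  s0 <- cl_ao$s_mm[which.min(d2)]
  if (s0 + d_branch > cl_length(cl_ao)) {
    abort(sprintf("Centerline '%s' too short beyond the branch origin for d_branch = %.1f mm.",
                  cl_label(cl_ao), d_branch))
  }
  v_ao <- cl_point_at(cl_ao, s0 + d_branch) - cl_point_at(cl_ao, s0)

  cosang <- sum(v_branch * v_ao) / (sqrt(sum(v_branch^2)) * sqrt(sum(v_ao^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Summarise branch morphometry
#'
#' Packages per-branch cross-section statistics with the bifurcation angle and
#' tortuosity into one row: arithmetic means of the per-section maximum
#' diameter and area, plus the section count.
#'
#' @param sections A `cross_sections` tibble from [extract_sections()].
#' @param theta Bifurcation angle (degrees), passed through.
#' @param tort Tortuosity, passed through.
#' @param label Branch label.
#' @return A one-row `morpho_summary` tibble: `label`, `avg_dmax_cm`,
#'   `avg_area_cm2`, `theta_deg`, `tortuosity`, `n_sections`.
#' @export
summarize_branch <- function(sections, theta = NA_real_, tort = NA_real_,
                             label = "LSA") {
  if (nrow(sections) < 1) abort("At least one cross-section is required.")
  if (!is.na(theta) && (theta < 0 || theta > 180)) abort("`theta` must be in [0, 180].")
  out <- tibble(label = label,
                avg_dmax_cm = mean(sections$dmax_cm),
                avg_area_cm2 = mean(sections$area_cm2),
                theta_deg = theta,
                tortuosity = tort,
                n_sections = nrow(sections))
  class(out) <- c("morpho_summary", class(out))
  out
}

#' Percent reduction between two diameters (or areas)
#'
#' `100 * (1 - post/pre)`: the percent reduction of a lumen measure after
#' treatment relative to baseline.
#'
#' @param pre,post Pre- and post-treatment values (same units).
#' @return Percent reduction.
#' @export
percent_reduction <- function(pre, post) {
  if (any(pre <= 0)) abort("`pre` must be positive.")
  100 * (1 - post / pre)
}

#' Ground-truth morphometry from a generated vessel
#'
#' Builds `morpho_summary` rows for every branch from the generator's exact
#' parametric dimensions (nominal diameters and centerlines) instead of mesh
#' measurements. For an SBSG vessel the LSA average reflects the narrowed
#' origin over the summarised range.
#'
#' @param vessel A `synthetic_vessel`.
#' @param range_mm Arc range (from the vessel wall) summarised per branch.
#' @return Named list of `morpho_summary` tibbles, one per branch.
#' @export
truth_morpho <- function(vessel, range_mm = 30) {
  spec <- vessel$spec
  r_in <- spec$inlet_diameter / 2
  out <- list()
  for (i in seq_len(nrow(spec$branches))) {
    b <- spec$branches[i, ]
    d_nom <- b$diameter_mm
    s <- seq(0, range_mm, by = 1)
    d_prof <- rep(d_nom, length(s))
    if (spec$configuration == "SBSG" && b$label == "LSA" && spec$lsa_narrowing > 0) {
      narrow_end <- .lsa_narrow_extra
      taper_end <- narrow_end + .lsa_narrow_taper
      d_n <- d_nom * (1 - spec$lsa_narrowing)
      d_prof <- ifelse(s <= narrow_end, d_n,
                       ifelse(s <= taper_end,
                              d_n + (d_nom - d_n) * (s - narrow_end) / .lsa_narrow_taper,
                              d_nom))
    }
    sections <- tibble(station_mm = s,
                       area_cm2 = pi * (d_prof / 2)^2 / 100,
                       dmax_cm = d_prof / 10)
    key <- paste0("AO_", b$label)
    tort <- unname(vessel$truth_tortuosity[key])
    out[[b$label]] <- summarize_branch(sections,
                                       theta = unname(vessel$truth_angles[b$label]),
                                       tort = tort, label = b$label)
  }
  out
}
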