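#' Study configuration
#'
#' Assembles and validates the full set of knobs for an end-to-end study run.
#' Unknown arguments are rejected (strict schema). Defaults mirror the solver
#' settings of the reference protocol: 0.85 s cycles, 0.004 s time step,
#' convergence at 0.06% cycle-to-cycle variation.
#'
#' @param configurations Subset of `c("PRE", "SBSG", "HYBRID")`.
#' @param lsa_narrowing SBSG origin diameter reduction fraction.
#' @param p_systolic_mmHg,p_diastolic_mmHg Calibration pressure targets.
#' @param gamma Proximal resistance fraction `Rp/(Rp+Rd)`.
#' @param period_s,dt_s Cycle duration and solver time step (s).
#' @param stroke_volume_mL Inflow stroke volume per cycle.
#' @param tawss_threshold,osi_threshold Exposure thresholds (Pa, -).
#' @param mesh_resolution Surface grid spacing (mm).
#' @param max_cycles,convergence Cycle cap and periodic criterion.
#' @param section_spacing_mm LSA cross-section station spacing.
#' @param wss_n_steps Time samples per cycle for the synthetic WSS field.
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created on demand) or `NULL` to skip
#'   writing.
#' @return A validated `study_config` list.
#' @export
study_config <- function(configurations = c("PRE", "SBSG", "HYBRID"),
                         lsa_narrowing = 0.124,
                         p_systolic_mmHg = 120, p_diastolic_mmHg = 80,
                         gamma = 0.09, period_s = 0.85, dt_s = 0.004,
                         stroke_volume_mL = 70,
                         tawss_threshold = 0.4, osi_threshold = 0.25,
                         mesh_resolution = 1.8, max_cycles = 60,
                         convergence = 6e-4, section_spacing_mm = 2,
                         wss_n_steps = 32, seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  known <- names(formals(study_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort(paste("Unknown config key(s):", paste(extra, collapse = ", ")))
  }
  missing <- setdiff(known, names(cfg))
  defaults <- formals(study_config)
  for (m in missing) cfg[[m]] <- eval(defaults[[m]])
  if (!all(cfg$configurations %in% c("PRE", "SBSG", "HYBRID"))) {
    abort("`configurations` must be a subset of PRE, SBSG, HYBRID.")
  }
  if (!"PRE" %in% cfg$configurations) abort("`configurations` must include PRE.")
  if (cfg$p_systolic_mmHg <= cfg$p_diastolic_mmHg || cfg$p_diastolic_mmHg <= 0) {
    abort("Require p_systolic_mmHg > p_diastolic_mmHg > 0.")
  }
  if (cfg$dt_s >= cfg$period_s) abort("`dt_s` must be smaller than `period_s`.")
  if (cfg$tawss_threshold <= 0 || cfg$osi_threshold <= 0) {
    abort("Thresholds must be positive.")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg[known], class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys match the [study_config()] arguments;
#'   unknown keys are rejected.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg)
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL  # hash the scientific configuration, not the destination
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(cfg, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

study_specs <- function(cfg) {
  specs <- list()
  for (nm in cfg$configurations) {
    specs[[nm]] <- aorta_spec(
      configuration = nm,
      lsa_narrowing = if (nm == "SBSG") cfg$lsa_narrowing else 0,
      mesh_resolution = cfg$mesh_resolution,
      seed = cfg$seed
    )
  }
  specs
}

#' Run the full comparison study
#'
#' End-to-end pipeline: generate the configured synthetic aortas; measure LSA
#' morphometry (computed centerlines, cross-sections, bifurcation angle,
#' tortuosity) for PRE and SBSG; calibrate a global Windkessel to the pressure
#' targets and distribute it over the baseline outlet areas; solve the 0D
#' network per configuration and compare LSA flow and arch-to-LSA pressure
#' drop; synthesise WSS fields per configuration and report TAWSS/OSI/ECAP
#' exposure statistics. Deterministic for a fixed seed. When
#' `config$out_dir` is set, JSON reports (morphometry, RCR table, comparison,
#' exposure, manifest), per-branch section CSVs, the inflow CSV and STL
#' surfaces are written there.
#'
#' @param config A [study_config()].
#' @return A `study_report` list: `morphometry`, `rcr_table`, `comparison`,
#'   `exposure`, `manifest` (all tibbles/lists of tibbles).
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config")) config <- validate_study_config(config)
  cfg <- config
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    inform(sprintf("[%s] ...", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  specs <- study_specs(cfg)
  vessels <- stage("generate", lapply(specs, make_aorta))
  inflow <- make_waveform(period = cfg$period_s,
                          stroke_volume_mL = cfg$stroke_volume_mL)

  morpho <- stage("morpho", {
    out <- list()
    for (nm in intersect(cfg$configurations, c("PRE", "SBSG"))) {
      out[[nm]] <- measure_lsa_morphometry(vessels[[nm]],
                                           spacing = cfg$section_spacing_mm)
    }
    out
  })
  morpho_tbl <- bind_rows(lapply(names(morpho), function(nm) {
    mutate(morpho[[nm]]$summary, configuration = nm, .before = 1)
  }))

  targets <- pressure_targets(cfg$p_systolic_mmHg, cfg$p_diastolic_mmHg)
  rcr <- stage("calibrate", {
    global <- calibrate_rcr(inflow, targets, gamma = cfg$gamma, dt = cfg$dt_s,
                            converge_tol = cfg$convergence)
    areas <- outlet_areas(vessels[["PRE"]]) |> rename(area = "area_m2")
    list(global = global,
         table = distribute_rcr(global, areas[, c("outlet", "area")]))
  })

  comparison <- NULL
  if (length(cfg$configurations) > 1) {
    comparison <- stage("compare", {
      compare_configurations(specs, inflow, targets, gamma = cfg$gamma,
                             vessels = vessels, dt = cfg$dt_s,
                             converge_tol = cfg$convergence)
    })
  }

  exposure <- stage("indicators", {
    bind_rows(lapply(cfg$configurations, function(nm) {
      field <- make_wss_field(vessels[[nm]]$surface,
                              base_magnitude = default_wss_magnitude,
                              oscillation = default_wss_oscillation,
                              period = cfg$period_s, n_steps = cfg$wss_n_steps,
                              seed = cfg$seed)
      maps <- indicator_maps(field)
      mutate(exposure_report(maps, cfg$tawss_threshold, cfg$osi_threshold),
             configuration = nm, .before = 1)
    }))
  })

  manifest <- list(package = "pauhemo",
                   version = as.character(utils::packageVersion("pauhemo")),
                   seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   configurations = cfg$configurations)

  report <- structure(list(morphometry = morpho_tbl, morpho_detail = morpho,
                           rcr_table = rcr$table, rcr_global = rcr$global,
                           comparison = comparison, exposure = exposure,
                           inflow = inflow, vessels = vessels,
                           manifest = manifest),
                      class = "study_report")
  if (!is.null(cfg$out_dir)) stage("report", write_study_report(report, cfg))
  report
}

# spatial defaults for the synthetic WSS field: lower magnitudes and stronger
# oscillation towards the distal arch / proximal descending aorta, emulating
# the low-TAWSS, high-OSI pockets seen after arch interventions
default_wss_magnitude <- function(v) {
  z <- (v[, 3] - min(v[, 3])) / max(1e-9, diff(range(v[, 3])))
  x <- (v[, 1] - min(v[, 1])) / max(1e-9, diff(range(v[, 1])))
  0.15 + 2.3 * (0.2 + 0.8 * x) * (1 - 0.7 * z)
}

default_wss_oscillation <- function(v) {
  z <- (v[, 3] - min(v[, 3])) / max(1e-9, diff(range(v[, 3])))
  pmin(1, pmax(0, 0.2 + 0.8 * z^1.5))
}

#' Measure LSA morphometry from a vessel mesh
#'
#' Computes the aortic and LSA centerlines by centroid marching, extracts
#' LSA cross-sections from just outside the ostium over the proximal segment,
#' and assembles the bifurcation angle (branch-diameter vector convention)
#' and inlet-to-LSA-tip tortuosity.
#'
#' @param vessel A `synthetic_vessel` with an LSA branch.
#' @param spacing Section spacing (mm).
#' @param range_mm Proximal LSA length to section, measured from the ostium.
#' @return List with `sections` (a `cross_sections` tibble), `summary`
#'   (a `morpho_summary` row), `cl_ao`, `cl_lsa`.
#' @export
measure_lsa_morphometry <- function(vessel, spacing = 2, range_mm = 25) {
  if (!"LSA" %in% names(vessel$truth_centerlines)) abort("Vessel has no LSA branch.")
  tr_ao <- vessel$truth_centerlines$AO
  r_in <- vessel$spec$inlet_diameter / 2
  seed_ao <- cl_point_at(tr_ao, 2)
  target_ao <- cl_point_at(tr_ao, cl_length(tr_ao) - 2)
  dir0 <- cl_tangent_at(tr_ao, 2)
  cl_ao <- compute_centerline(vessel$surface, seed_ao, target_ao, step = 2,
                              initial_direction = dir0, label = "AO",
                              r_hint = r_in)

  tr_lsa <- vessel$truth_centerlines$LSA
  # the wall exit distance along an oblique branch axis is r_in/sin(theta)
  th <- vessel$spec$branches$angle_deg[vessel$spec$branches$label == "LSA"] * pi / 180
  s_wall <- r_in / max(sin(th), 0.35)
  s_seed <- min(s_wall + 4, cl_length(tr_lsa) / 2)
  seed_lsa <- cl_point_at(tr_lsa, s_seed)
  target_lsa <- cl_point_at(tr_lsa, cl_length(tr_lsa) - 4)
  dir_lsa <- cl_tangent_at(tr_lsa, s_seed)
  r_lsa <- vessel$spec$branches$diameter_mm[vessel$spec$branches$label == "LSA"] / 2
  if (vessel$spec$configuration == "SBSG") r_lsa <- r_lsa * (1 - vessel$spec$lsa_narrowing)
  cl_lsa <- compute_centerline(vessel$surface, seed_lsa, target_lsa, step = 1.5,
                               initial_direction = dir_lsa, label = "LSA",
                               r_hint = r_lsa)

  s_end <- min(range_mm, cl_length(cl_lsa) - 1)
  sections <- extract_sections(vessel$surface, cl_lsa, s_start = 0,
                               s_end = s_end, spacing = spacing)
  # cuts straddling the ostium produce merged polygons spanning the junction;
  # drop leading stations whose diameter is far above the branch profile
  med_dmax <- stats::median(sections$dmax_cm)
  while (nrow(sections) > 1 && sections$dmax_cm[1] > 1.3 * med_dmax) {
    sections <- sections[-1, ]
  }
  theta <- bifurcation_angle(cl_ao, cl_lsa, sections = sections)
  # inlet -> LSA tip path for tortuosity
  ao_pts <- cl_points(cl_ao)
  o <- cl_point_at(cl_lsa, 0)
  i0 <- which.min(rowSums(sweep(ao_pts, 2, o)^2))
  path <- rbind(ao_pts[seq_len(i0), , drop = FALSE], cl_points(cl_lsa))
  tort <- tortuosity(centerline(path, "AO_LSA"))
  summary <- summarize_branch(sections, theta = theta, tort = tort, label = "LSA")
  list(sections = sections, summary = summary, cl_ao = cl_ao, cl_lsa = cl_lsa)
}

#' Measure one branch's bifurcation angle from the mesh
#'
#' Marches the aortic and branch centerlines and applies the branch-diameter
#' vector convention of [bifurcation_angle()]. The branch march is seeded one
#' step beyond the wall exit distance `r_in/sin(theta)` of the oblique ostium.
#'
#' @param vessel A `synthetic_vessel`.
#' @param label Branch label.
#' @param cl_ao Optional precomputed aortic centerline (reused across
#'   branches).
#' @return Angle in degrees.
#' @export
measure_branch_angle <- function(vessel, label, cl_ao = NULL) {
  br <- vessel$spec$branches
  if (!label %in% br$label) abort(sprintf("No branch '%s' in this vessel.", label))
  r_in <- vessel$spec$inlet_diameter / 2
  tr_ao <- vessel$truth_centerlines$AO
  if (is.null(cl_ao)) {
    cl_ao <- compute_centerline(vessel$surface, cl_point_at(tr_ao, 2),
                                cl_point_at(tr_ao, cl_length(tr_ao) - 2),
                                step = 1.5, initial_direction = cl_tangent_at(tr_ao, 2),
                                label = "AO", r_hint = r_in, smooth_window = 7)
  }
  i <- which(br$label == label)
  trb <- vessel$truth_centerlines[[label]]
  th <- br$angle_deg[i] * pi / 180
  s_w <- r_in / max(sin(th), 0.35) + 4
  clb <- compute_centerline(vessel$surface, cl_point_at(trb, s_w),
                            cl_point_at(trb, cl_length(trb) - 4), step = 1.5,
                            initial_direction = cl_tangent_at(trb, s_w),
                            label = label, r_hint = br$diameter_mm[i] / 2)
  bifurcation_angle(cl_ao, clb, d_branch = br$diameter_mm[i])
}

write_study_report <- function(report, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, name) {
    jsonlite::write_json(x, file.path(cfg$out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  wj(report$morphometry, "morphometry.json")
  wj(report$rcr_table, "rcr_table.json")
  if (!is.null(report$comparison)) {
    wj(as_tibble(report$comparison), "comparison.json")
  }
  wj(report$exposure, "exposure.json")
  wj(report$manifest, "manifest.json")
  write_waveform_csv(report$inflow, file.path(cfg$out_dir, "inflow.csv"))
  for (nm in names(report$morpho_detail)) {
    write_sections_csv(report$morpho_detail[[nm]]$sections,
                       file.path(cfg$out_dir, sprintf("lsa_sections_%s.csv", nm)))
  }
  for (nm in names(report$vessels)) {
    write_stl(report$vessels[[nm]]$surface,
              file.path(cfg$out_dir, sprintf("aorta_%s.stl", nm)), name = nm)
  }
  invisible(cfg$out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n\nMorphometry (LSA):\n")
  print(x$morphometry)
  if (!is.null(x$comparison)) {
    cat("\nConfiguration comparison:\n")
    print(as_tibble(x$comparison))
  }
  cat("\nExposure:\n")
  print(x$exposure)
  invisible(x)
}
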