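#' Parametric thoracic-aorta specification
#'
#' Describes a synthetic thoracic aorta — ascending segment, arch (a circular
#' torus segment), tapered descending segment and up to three supra-aortic
#' branches — in one of three treatment configurations:
#'
#' * `"PRE"` — untreated baseline, optionally with a saccular PAU bulge;
#' * `"SBSG"` — single-branched stent graft: the LSA lumen is narrowed at its
#'   origin by the fraction `lsa_narrowing` (diameter reduction);
#' * `"HYBRID"` — TEVAR with LSA-origin coverage plus a carotid-subclavian
#'   bypass conduit (default diameter 8 mm) from the LCCA to the LSA at least
#'   2 cm distal to the covered origin.
#'
#' All lengths are millimetres. Branch `position_deg` is the arc position on
#' the arch (degrees from the ascending end, strictly increasing);
#' `angle_deg` is the angle between the branch axis and the local aortic
#' centerline tangent (towards the descending aorta); `length_mm` is measured
#' from the aortic centerline. With `arch_sweep_deg = 0` the main vessel is a
#' straight tube and `position_deg` is interpreted as millimetres along it
#' (useful for analytic validation, where chord and tangent coincide).
#'
#' @param configuration One of `"PRE"`, `"SBSG"`, `"HYBRID"`.
#' @param arch_radius Arch centerline radius (mm).
#' @param inlet_diameter Aortic lumen diameter (mm).
#' @param descending_taper Ratio of distal to proximal descending diameter.
#' @param ascending_length,descending_length Straight extension lengths (mm).
#' @param branches Tibble with columns `label`, `position_deg`, `diameter_mm`,
#'   `angle_deg`, `length_mm`.
#' @param lsa_narrowing Proximal LSA diameter reduction fraction (SBSG only).
#' @param bypass_diameter Bypass conduit diameter (mm, HYBRID only).
#' @param pau_bulge Optional `list(position_deg =, depth_mm =)` saccular bulge.
#' @param mesh_resolution Target mesh edge length / grid spacing (mm).
#' @param arch_sweep_deg Arch sweep (180 = full hemi-arch; 0 = straight tube).
#' @param straight_length Main-vessel length when `arch_sweep_deg = 0`.
#' @param seed Integer seed (grid jitter).
#' @return An `aorta_spec` object.
#' @export
aorta_spec <- function(configuration = c("PRE", "SBSG", "HYBRID"),
                       arch_radius = 30, inlet_diameter = 26,
                       descending_taper = 0.9,
                       ascending_length = 30, descending_length = 70,
                       branches = default_branches(),
                       lsa_narrowing = 0, bypass_diameter = 8,
                       pau_bulge = NULL, mesh_resolution = 1.6,
                       arch_sweep_deg = 180, straight_length = 120,
                       seed = 1L) {
  configuration <- match.arg(configuration)
  branches <- as_tibble(branches)
  need <- c("label", "position_deg", "diameter_mm", "angle_deg", "length_mm")
  if (!all(need %in% names(branches))) {
    abort(paste("`branches` needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(branches) > 0) {
    if (any(diff(branches$position_deg) <= 0)) {
      abort("Branch arc positions must be strictly increasing.")
    }
    if (any(branches$diameter_mm >= inlet_diameter)) {
      abort("Branch diameters must be smaller than the inlet diameter.")
    }
    if (!all(branches$label %in% c("BCA", "LCCA", "LSA"))) {
      abort("Branch labels must be among BCA, LCCA, LSA.")
    }
  }
  if (descending_taper <= 0 || descending_taper > 1) {
    abort("`descending_taper` must be in (0, 1].")
  }
  if (lsa_narrowing < 0 || lsa_narrowing >= 1) abort("`lsa_narrowing` must be in [0, 1).")
  if (lsa_narrowing > 0 && configuration != "SBSG") {
    abort("`lsa_narrowing` applies only to the SBSG configuration.")
  }
  if (configuration == "SBSG" && !"LSA" %in% branches$label) {
    abort("SBSG configuration requires an LSA branch.")
  }
  if (configuration == "HYBRID" && !all(c("LCCA", "LSA") %in% branches$label)) {
    abort("HYBRID configuration requires LCCA and LSA branches.")
  }
  if (bypass_diameter <= 0) abort("`bypass_diameter` must be positive.")
  if (!is.null(pau_bulge) &&
      (is.null(pau_bulge$position_deg) || is.null(pau_bulge$depth_mm))) {
    abort("`pau_bulge` must be list(position_deg =, depth_mm =).")
  }
  structure(list(
    configuration = configuration, arch_radius = arch_radius,
    inlet_diameter = inlet_diameter, descending_taper = descending_taper,
    ascending_length = ascending_length, descending_length = descending_length,
    branches = branches, lsa_narrowing = lsa_narrowing,
    bypass_diameter = bypass_diameter, pau_bulge = pau_bulge,
    mesh_resolution = mesh_resolution, arch_sweep_deg = arch_sweep_deg,
    straight_length = straight_length, seed = as.integer(seed)
  ), class = "aorta_spec")
}

#' @rdname aorta_spec
#' @export
default_branches <- function() {
  tibble(label = c("BCA", "LCCA", "LSA"),
         position_deg = c(55, 85, 112),
         diameter_mm = c(13, 9, 11.5),
         angle_deg = c(75, 82, 87),
         length_mm = c(45, 45, 50))
}

#' @export
print.aorta_spec <- function(x, ...) {
  cat(sprintf("<aorta_spec: %s, arch R %g mm, inlet D %g mm, %d branches>\n",
              x$configuration, x$arch_radius, x$inlet_diameter, nrow(x$branches)))
  invisible(x)
}

# geometric constants for treatment features (mm)
.lsa_narrow_extra <- 15   # narrowed length beyond the aortic radius
.lsa_narrow_taper <- 4    # transition length back to nominal diameter
.lcca_attach_extra <- 15  # bypass take-off beyond the aortic radius on the LCCA
.lsa_bypass_extra <- 20   # bypass landing beyond the aortic radius on the LSA
.bypass_bulge_mm <- 12    # out-of-plane offset of the bypass conduit apex

# exact parametric description shared by the mesher, the ground-truth
# centerlines and the lumped-network skeleton
aorta_frame <- function(spec) {
  r_in <- spec$inlet_diameter / 2
  if (spec$arch_sweep_deg > 0) {
    Ra <- spec$arch_radius
    sweep_rad <- spec$arch_sweep_deg * pi / 180
    arc_len <- Ra * sweep_rad
    main_len <- spec$ascending_length + arc_len + spec$descending_length
    point_at <- function(s) {
      if (s <= spec$ascending_length) {
        c(Ra, 0, s - spec$ascending_length)
      } else if (s <= spec$ascending_length + arc_len) {
        phi <- (s - spec$ascending_length) / Ra
        c(Ra * cos(phi), 0, Ra * sin(phi))
      } else {
        # descending continues along the arc end tangent (-sin, 0, cos)
        u <- s - spec$ascending_length - arc_len
        end <- c(Ra * cos(sweep_rad), 0, Ra * sin(sweep_rad))
        end + u * c(-sin(sweep_rad), 0, cos(sweep_rad))
      }
    }
    branch_pos <- function(position_deg) spec$ascending_length + Ra * position_deg * pi / 180
    tangent_at <- function(s) {
      if (s <= spec$ascending_length) c(0, 0, 1)
      else if (s <= spec$ascending_length + arc_len) {
        phi <- (s - spec$ascending_length) / Ra
        c(-sin(phi), 0, cos(phi))
      } else c(cos(sweep_rad + pi / 2), 0, sin(sweep_rad + pi / 2))
    }
    normal_at <- function(s) {
      if (s <= spec$ascending_length) c(1, 0, 0)
      else if (s <= spec$ascending_length + arc_len) {
        phi <- (s - spec$ascending_length) / Ra
        c(cos(phi), 0, sin(phi))
      } else {
        tg <- tangent_at(s)
        unit3(pracma_cross(c(0, 1, 0), tg))
      }
    }
  } else {
    main_len <- spec$straight_length
    point_at <- function(s) c(s, 0, 0)
    tangent_at <- function(s) c(1, 0, 0)
    normal_at <- function(s) c(0, 0, 1)
    branch_pos <- function(position_deg) position_deg  # interpreted as mm
  }
  desc_start <- main_len - spec$descending_length
  radius_at <- function(s) {
    if (spec$arch_sweep_deg > 0 && s > desc_start) {
      frac <- (s - desc_start) / spec$descending_length
      r_in * (1 + frac * (spec$descending_taper - 1))
    } else r_in
  }
  br <- spec$branches
  binfo <- NULL
  if (nrow(br) > 0) {
    binfo <- lapply(seq_len(nrow(br)), function(i) {
      s_b <- branch_pos(br$position_deg[i])
      tg <- tangent_at(s_b)
      nr <- normal_at(s_b)
      th <- br$angle_deg[i] * pi / 180
      list(label = br$label[i], s_main = s_b,
           origin = point_at(s_b),
           dir = unit3(cos(th) * tg + sin(th) * nr),
           radius = br$diameter_mm[i] / 2,
           length = br$length_mm[i])
    })
    names(binfo) <- br$label
  }
  list(r_in = r_in, main_len = main_len, point_at = point_at,
       tangent_at = tangent_at, normal_at = normal_at, radius_at = radius_at,
       branches = binfo)
}

# quadratic Bezier polyline for the HYBRID bypass conduit
bypass_curve <- function(frame, n = 41) {
  lcca <- frame$branches[["LCCA"]]
  lsa <- frame$branches[["LSA"]]
  p1 <- lcca$origin + (frame$r_in + .lcca_attach_extra) * lcca$dir
  p2 <- lsa$origin + (frame$r_in + .lsa_bypass_extra) * lsa$dir
  ctrl <- (p1 + p2) / 2 + c(0, .bypass_bulge_mm, 0)
  t <- seq(0, 1, length.out = n)
  pts <- outer((1 - t)^2, p1) + outer(2 * t * (1 - t), ctrl) + outer(t^2, p2)
  pts
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

check_branch_collisions <- function(spec, frame) {
  b <- frame$branches
  if (length(b) < 2) return(invisible(TRUE))
  for (i in seq_len(length(b) - 1)) {
    for (j in (i + 1):length(b)) {
      gap <- abs(b[[j]]$s_main - b[[i]]$s_main)
      if (gap < b[[i]]$radius + b[[j]]$radius + 2) {
        abort(sprintf(
          "Branches %s and %s collide: arc separation %.1f mm < %.1f mm required.",
          b[[i]]$label, b[[j]]$label, gap, b[[i]]$radius + b[[j]]$radius + 2))
      }
    }
  }
  invisible(TRUE)
}

# implicit solid (negative inside) for the configured aorta
aorta_implicit <- function(spec, frame) {
  r_in <- frame$r_in
  prims <- list()
  add <- function(f) prims[[length(prims) + 1]] <<- f

  if (spec$arch_sweep_deg > 0) {
    Ra <- spec$arch_radius
    sweep_rad <- spec$arch_sweep_deg * pi / 180
    a0 <- frame$point_at(0)
    a1 <- frame$point_at(spec$ascending_length)
    add(function(p) sdf_capsule(p, a0, a1, r_in))
    add(function(p) sdf_arc_tube(p, c(0, 0, 0), c(1, 0, 0), c(0, 0, 1),
                                 Ra, 0, sweep_rad, r_in))
    d0 <- frame$point_at(frame$main_len - spec$descending_length)
    d1 <- frame$point_at(frame$main_len)
    add(function(p) sdf_round_cone(p, d0, d1, r_in, r_in * spec$descending_taper))
  } else {
    d1 <- frame$point_at(frame$main_len)
    add(function(p) sdf_capsule(p, frame$point_at(0), d1, r_in))
  }

  for (b in frame$branches) {
    tip <- b$origin + b$length * b$dir
    if (spec$configuration == "HYBRID" && b$label == "LSA") {
      start <- b$origin + (r_in + .lsa_bypass_extra) * b$dir
      local({
        start <- start; tip <- tip; rb <- b$radius
        add(function(p) sdf_capsule(p, start, tip, rb))
      })
    } else if (spec$configuration == "SBSG" && b$label == "LSA" &&
               spec$lsa_narrowing > 0) {
      local({
        rn <- b$radius * (1 - spec$lsa_narrowing)
        s1 <- r_in + .lsa_narrow_extra
        s2 <- s1 + .lsa_narrow_taper
        o <- b$origin; rb <- b$radius; tip <- tip
        p1 <- o + s1 * b$dir; p2 <- o + min(s2, b$length) * b$dir
        add(function(p) sdf_capsule(p, o, p1, rn))
        add(function(p) sdf_round_cone(p, p1, p2, rn, rb))
        add(function(p) sdf_capsule(p, p2, tip, rb))
      })
    } else {
      local({
        o <- b$origin; tip <- tip; rb <- b$radius
        add(function(p) sdf_capsule(p, o, tip, rb))
      })
    }
  }
  if (spec$configuration == "HYBRID") {
    bp <- bypass_curve(frame)
    rb <- spec$bypass_diameter / 2
    add(function(p) sdf_polyline_tube(p, bp, rb))
  }
  if (!is.null(spec$pau_bulge)) {
    s_b <- if (spec$arch_sweep_deg > 0) {
      spec$ascending_length + spec$arch_radius * spec$pau_bulge$position_deg * pi / 180
    } else spec$pau_bulge$position_deg
    ctr <- frame$point_at(s_b) + frame$normal_at(s_b) * frame$radius_at(s_b)
    depth <- spec$pau_bulge$depth_mm
    add(function(p) sdf_sphere(p, ctr, depth))
  }
  function(p) {
    d <- prims[[1]](p)
    for (f in prims[-1]) d <- pmin(d, f(p))
    d
  }
}

# node/segment skeleton of the configured vasculature for the 0D network
aorta_skeleton <- function(spec, frame = aorta_frame(spec)) {
  r_in <- frame$r_in
  d_in <- 2 * r_in
  b <- frame$branches
  segs <- list()
  seg <- function(from, to, label, length_mm, diameter_mm) {
    segs[[length(segs) + 1]] <<- tibble(from = from, to = to, label = label,
                                        length_mm = length_mm,
                                        diameter_mm = diameter_mm)
  }
  s_prev <- 0; n_prev <- "inlet"
  for (lbl in names(b)) {
    jn <- paste0("j_", lbl)
    seg(n_prev, jn, paste0("aorta_to_", lbl), b[[lbl]]$s_main - s_prev, d_in)
    s_prev <- b[[lbl]]$s_main; n_prev <- jn
  }
  d_desc <- d_in * (1 + spec$descending_taper) / 2
  seg(n_prev, "t_DA", "aorta_descending", frame$main_len - s_prev,
      if (spec$arch_sweep_deg > 0) d_desc else d_in)

  for (lbl in names(b)) {
    bb <- b[[lbl]]
    jn <- paste0("j_", lbl)
    tn <- paste0("t_", lbl)
    if (spec$configuration == "HYBRID" && lbl == "LSA") {
      next  # origin covered; handled with the bypass below
    } else if (spec$configuration == "SBSG" && lbl == "LSA" && spec$lsa_narrowing > 0) {
      s1 <- r_in + .lsa_narrow_extra + .lsa_narrow_taper / 2
      seg(jn, "n_LSA_origin", "LSA_origin", s1, bb$radius * 2 * (1 - spec$lsa_narrowing))
      seg("n_LSA_origin", tn, "LSA_distal", bb$length - s1, bb$radius * 2)
    } else {
      seg(jn, tn, lbl, bb$length, bb$radius * 2)
    }
  }
  if (spec$configuration == "HYBRID") {
    lcca <- b[["LCCA"]]; lsa <- b[["LSA"]]
    s_att <- r_in + .lcca_attach_extra
    seg("j_LCCA", "n_LCCA_mid", "LCCA_proximal", s_att, lcca$radius * 2)
    seg("n_LCCA_mid", "t_LCCA", "LCCA_distal", lcca$length - s_att, lcca$radius * 2)
    bp_len <- polyline_length(bypass_curve(frame))
    seg("n_LCCA_mid", "n_LSA_bypass", "bypass", bp_len, spec$bypass_diameter)
    s_bp <- r_in + .lsa_bypass_extra
    seg("n_LSA_bypass", "t_LSA", "LSA_distal", lsa$length - s_bp, lsa$radius * 2)
  }
  out <- bind_rows(segs)
  # LCCA segment was emitted in branch loop; drop the duplicate nominal LCCA
  # segment for HYBRID (replaced by proximal/distal split)
  if (spec$configuration == "HYBRID") out <- out[out$label != "LCCA", ]
  out
}

#' Generate a synthetic aortic surface with ground truth
#'
#' Builds the implicit union of the configured vessel primitives and
#' polygonises it by marching tetrahedra at the spec's `mesh_resolution`,
#' returning a closed, manifold, outward-oriented triangulation together with
#' exact parametric ground truth: centerlines, branch angles, tortuosity,
#' outlet areas and the lumped-network skeleton.
#'
#' @param spec An [aorta_spec()].
#' @return A `synthetic_vessel`: list with elements `surface`
#'   ([tri_surface()]), `spec`, `truth_centerlines` (named [centerline()]
#'   list: `AO`, one per branch, and `AO_<branch>` inlet-to-branch-tip paths),
#'   `truth_angles` (degrees), `truth_tortuosity`, `outlet_areas` (m^2) and
#'   `skeleton` (segment tibble).
#' @export
make_aorta <- function(spec) {
  if (!inherits(spec, "aorta_spec")) abort("`spec` must be an aorta_spec.")
  frame <- aorta_frame(spec)
  check_branch_collisions(spec, frame)
  f <- aorta_implicit(spec, frame)

  # sample the exact centerlines
  s_main <- seq(0, frame$main_len, by = 1)
  ao_pts <- t(vapply(s_main, frame$point_at, numeric(3)))
  cls <- list(AO = centerline(ao_pts, "AO"))
  angles <- list(); torts <- list(AO = tortuosity(cls$AO))
  for (b in frame$branches) {
    s0 <- if (spec$configuration == "HYBRID" && b$label == "LSA") {
      frame$r_in + .lsa_bypass_extra
    } else 0
    sb <- seq(s0, b$length, by = 1)
    pts <- matrix(b$origin, length(sb), 3, byrow = TRUE) + outer(sb, b$dir)
    cls[[b$label]] <- centerline(pts, b$label)
    angles[[b$label]] <- spec$branches$angle_deg[spec$branches$label == b$label]
    # inlet -> branch tip path for tortuosity ground truth
    ao_part <- ao_pts[s_main <= b$s_main, , drop = FALSE]
    path <- rbind(ao_part, pts[-1, , drop = FALSE])
    key <- paste0("AO_", b$label)
    cls[[key]] <- centerline(path, key)
    torts[[key]] <- tortuosity(cls[[key]])
  }

  areas <- list()
  for (b in frame$branches) areas[[b$label]] <- pi * mm_to_m(b$radius)^2
  r_out <- frame$radius_at(frame$main_len)
  areas[["DA"]] <- pi * mm_to_m(r_out)^2

  # polygonisation grid with seeded sub-cell jitter
  h <- spec$mesh_resolution
  all_pts <- do.call(rbind, lapply(cls, cl_points))
  if (spec$configuration == "HYBRID") all_pts <- rbind(all_pts, bypass_curve(frame))
  rmax <- max(frame$r_in, vapply(frame$branches, function(b) b$radius, numeric(1)))
  if (!is.null(spec$pau_bulge)) rmax <- max(rmax, spec$pau_bulge$depth_mm)
  pad <- rmax + 4 * h
  jit <- local({ set.seed(spec$seed); stats::runif(3, -0.3, 0.3) * h })
  lo <- apply(all_pts, 2, min) - pad + jit
  hi <- apply(all_pts, 2, max) + pad + jit
  xs <- seq(lo[1], hi[1], by = h)
  ys <- seq(lo[2], hi[2], by = h)
  zs <- seq(lo[3], hi[3], by = h)
  surface <- marching_tets(f, xs, ys, zs)

  structure(list(
    surface = surface, spec = spec,
    truth_centerlines = cls,
    truth_angles = unlist(angles),
    truth_tortuosity = unlist(torts),
    outlet_areas = unlist(areas),
    skeleton = aorta_skeleton(spec, frame),
    frame = frame
  ), class = "synthetic_vessel")
}

#' @export
print.synthetic_vessel <- function(x, ...) {
  cat(sprintf("<synthetic_vessel: %s, %d vertices, %d faces, outlets: %s>\n",
              x$spec$configuration, nrow(x$surface$vertices),
              nrow(x$surface$faces), paste(names(x$outlet_areas), collapse = ", ")))
  invisible(x)
}

#' @method glance synthetic_vessel
#' @export
glance.synthetic_vessel <- function(x, ...) {
  dplyr::bind_cols(tibble(configuration = x$spec$configuration),
                   glance(x$surface))
}

#' Outlet areas of a synthetic vessel as a tibble
#'
#' @param vessel A `synthetic_vessel`.
#' @return Tibble with columns `outlet`, `area_m2`, `area_cm2`.
#' @export
outlet_areas <- function(vessel) {
  tibble(outlet = names(vessel$outlet_areas),
         area_m2 = unname(vessel$outlet_areas),
         area_cm2 = unname(vessel$outlet_areas) * 1e4)
}
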