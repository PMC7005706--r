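# Post-hoc adsorption analysis: ring-orientation classification,
# lock-and-key (LAK) registry detection, vacuum/water comparison
# tables, and on-surface mobility.
#
# The orientation and LAK thresholds operationalize classifications
# usually made visually from structure imagery; they are interpretive
# and exposed as arguments.

#' Default analysis thresholds
#' @return List: `flat_tilt` (deg), `stand_tilt` (deg), `contact_height`
#'   (A), `detach_height` (A), `registry_tol` (A, lateral),
#'   `planarity_tol` (A, rms out-of-plane).
#' @export
analysis_thresholds <- function() {
  list(flat_tilt = 20, stand_tilt = 60, contact_height = 4.5,
       detach_height = 6, registry_tol = 0.8, planarity_tol = 0.3)
}

#' Classify the orientation of a ring over the surface
#'
#' Tilt is the angle between the ring-plane normal (least-squares plane)
#' and the surface normal (+z), folded to [0, 90] degrees.  Classes:
#' `"detached"` (centroid higher than the detach threshold),
#' `"flat-on"` (tilt at most `flat_tilt` with the centroid in contact),
#' `"stand-up"` (tilt at least `stand_tilt` with the lowest ring atom
#' in contact), otherwise `"intermediate"`.  A ring whose atoms deviate
#' from planarity beyond tolerance is reported `"intermediate"` with a
#' warning.
#'
#' @param ring_coords 5 x 3 or 6 x 3 matrix of ring-atom coordinates.
#' @param top_z z of the top slab layer (or a slab `molsys`).
#' @param thresholds See [analysis_thresholds()].
#' @return List: `class`, `tilt` (deg), `height` (centroid above top
#'   layer, A), `min_height`, `centroid`.
#' @export
ring_orientation <- function(ring_coords, top_z = 0,
                             thresholds = analysis_thresholds()) {
  ring_coords <- as.matrix(ring_coords)
  if (!nrow(ring_coords) %in% c(5L, 6L))
    stop("ring must have 5 or 6 atoms", call. = FALSE)
  if (inherits(top_z, "molsys")) top_z <- top_z$slab$top_z
  centroid <- colMeans(ring_coords)
  cen <- sweep(ring_coords, 2, centroid)
  sv <- svd(cen)
  normal <- sv$v[, 3]
  planarity <- sqrt(mean((cen %*% normal)^2))
  tilt <- acos(min(1, abs(normal[3]))) * 180 / pi
  height <- centroid[3] - top_z
  min_height <- min(ring_coords[, 3]) - top_z
  cls <- if (height > thresholds$detach_height) {
    "detached"
  } else if (planarity > thresholds$planarity_tol) {
    warning("ring deviates from planarity; classified intermediate",
            call. = FALSE)
    "intermediate"
  } else if (tilt <= thresholds$flat_tilt &&
             height <= thresholds$contact_height) {
    "flat-on"
  } else if (tilt >= thresholds$stand_tilt &&
             min_height <= thresholds$contact_height) {
    "stand-up"
  } else "intermediate"
  list(class = cls, tilt = tilt, height = height, min_height = min_height,
       centroid = centroid)
}

#' @keywords internal
.ring_indices <- function(system) {
  out <- list()
  pep <- which(system$atoms$group == "peptide")
  for (rid in unique(system$atoms$resid[pep])) {
    sel <- pep[system$atoms$resid[pep] == rid]
    rn <- system$atoms$resname[sel[1]]
    if (is.na(match(rn, names(.three_to_one)))) next
    tmpl <- .residue_table[[.three_to_one[rn]]]
    if (!length(tmpl$ring)) next
    idx <- sel[match(tmpl$ring, system$atoms$name[sel])]
    out[[length(out) + 1L]] <- list(resid = rid, resname = rn,
                                    size = length(idx), idx = idx)
  }
  out
}

#' Detect lock-and-key (LAK) ring-surface registry
#'
#' A ring is LAK-locked when it lies flat on the surface with its
#' centroid laterally within the registry tolerance of a top-layer
#' metal atom -- the geometry in which the ring encloses a surface atom
#' while its members line up with the subsurface (second/third layer)
#' lattice sites.  The report lists every Phe/Pro ring with its
#' orientation class, registry class beneath the centroid, the
#' per-ring-atom site classes, height and tilt.  The LAK criterion is
#' an operationalization of a visual classification; the thresholds are
#' interpretive.
#'
#' @param system Peptide-on-slab `molsys` (slab metadata required).
#' @param thresholds See [analysis_thresholds()].
#' @return Data frame of class `lak_report`: columns `resid`, `resname`,
#'   `ring_size`, `orientation`, `tilt`, `height`, `centroid_site`,
#'   `centroid_site_dist`, `lak`; attribute `"atom_sites"` holds the
#'   per-ring-atom site classes.
#' @export
detect_lak <- function(system, thresholds = analysis_thresholds()) {
  rings <- .ring_indices(system)
  reg <- surface_registry(system)
  meta <- system$slab
  rows <- list(); atom_sites <- list()
  for (r in rings) {
    orient <- ring_orientation(system$coords[r$idx, , drop = FALSE],
                               meta$top_z, thresholds)
    ctr <- orient$centroid[1:2]
    site <- classify_site(reg, ctr)
    sdist <- attr(site, "distance")
    lak <- orient$class == "flat-on" && site[1] == "top" &&
      sdist[1] <= thresholds$registry_tol
    persite <- classify_site(reg, system$coords[r$idx, 1:2, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      resid = r$resid, resname = r$resname, ring_size = r$size,
      orientation = orient$class, tilt = orient$tilt,
      height = orient$height, centroid_site = site[1],
      centroid_site_dist = sdist[1], lak = lak)
    atom_sites[[length(atom_sites) + 1L]] <- as.character(persite)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resid = integer(0), resname = character(0),
               ring_size = integer(0), orientation = character(0),
               tilt = numeric(0), height = numeric(0),
               centroid_site = character(0),
               centroid_site_dist = numeric(0), lak = logical(0))
  attr(out, "atom_sites") <- atom_sites
  class(out) <- c("lak_report", class(out))
  out
}

#' Percent difference
#'
#' `100 * (a - b) / b`, the convention used for vacuum/water
#' adsorption-energy contrasts (the reference is the second argument).
#' @param a,b Numeric.
#' @export
percent_difference <- function(a, b) 100 * (a - b) / b

#' Time-averaged binding energy over a trajectory window
#'
#' Re-evaluates the peptide-surface interaction energy over the final
#' fraction of a trajectory (default: the production half) and averages.
#'
#' @param traj `md_trajectory` of a peptide-on-slab (optionally
#'   solvated) system.
#' @param params `ff_params`.
#' @param window Final fraction of frames to average (default 0.5).
#' @return Mean peptide-surface interaction energy, kcal/mol.
#' @export
trajectory_binding_energy <- function(traj, params = default_forcefield(),
                                      window = 0.5) {
  nf <- length(traj$frames)
  use <- seq.int(max(1L, ceiling(nf * (1 - window))), nf)
  sys <- traj$final_system
  vals <- vapply(use, function(f) {
    sys$coords <- traj$frames[[f]]
    total_energy(sys, params)$e_surface
  }, numeric(1))
  mean(vals)
}

#' Vacuum/water adsorption-energy comparison table
#'
#' Builds the standard two-environment comparison: one row per
#' configuration with its vacuum and water adsorption energies, plus
#' pairwise percent differences between configurations in each
#' environment (`100 * (E_a - E_b) / E_b`, reference stated per row).
#' Inputs may be plain numbers (e.g. published table values) or
#' trajectories, which are averaged with
#' [trajectory_binding_energy()].
#'
#' @param vacuum,water Named numeric vectors of adsorption energies
#'   (kcal/mol), or named lists of `md_trajectory` objects.
#' @param params `ff_params` (used only when trajectories are given).
#' @return List with `energies` (data frame: configuration, vacuum,
#'   water, percent_change_water_vs_vacuum) and `contrasts` (data
#'   frame: environment, a, b, percent_difference, reference).
#' @examples
#' environment_comparison(
#'   vacuum = c(`S7-1` = -250.06, `S7-2` = -252.84),
#'   water = c(`S7-1` = -235.23, `S7-2` = -210.26))
#' @export
environment_comparison <- function(vacuum, water,
                                   params = default_forcefield()) {
  as_energies <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, trajectory_binding_energy, numeric(1), params = params)
  }
  ev <- as_energies(vacuum); ew <- as_energies(water)
  if (is.null(names(ev)) || is.null(names(ew)) ||
      !identical(sort(names(ev)), sort(names(ew))))
    stop("vacuum and water inputs must carry matching configuration names",
         call. = FALSE)
  ew <- ew[names(ev)]
  energies <- data.frame(
    configuration = names(ev), vacuum = as.numeric(ev),
    water = as.numeric(ew),
    percent_change_water_vs_vacuum = percent_difference(as.numeric(ew),
                                                        as.numeric(ev)))
  contrasts <- list()
  nms <- names(ev)
  if (length(nms) >= 2) {
    for (env in c("vacuum", "water")) {
      e <- if (env == "vacuum") ev else ew
      for (i in seq_along(nms)) for (j in seq_along(nms)) {
        if (i == j) next
        contrasts[[length(contrasts) + 1L]] <- data.frame(
          environment = env, a = nms[i], b = nms[j],
          percent_difference = percent_difference(e[i], e[j]),
          reference = nms[j])
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame(environment = character(0), a = character(0),
               b = character(0), percent_difference = numeric(0),
               reference = character(0))
  rownames(contrasts) <- NULL
  list(energies = energies, contrasts = contrasts)
}

#' Lateral mobility of an adsorbed peptide
#'
#' In-plane displacement of the peptide center of mass from the first
#' frame, with frame-to-frame increments minimum-image corrected so a
#' trajectory whose coordinates were wrapped into the cell is unwrapped
#' before accumulation.
#'
#' @param traj `md_trajectory`.
#' @param slab Slab `molsys` (for the cell); defaults to the
#'   trajectory's own system.
#' @return List: `displacement` (per-frame, A), `max`, `mean`, `series`
#'   (data frame with per-frame lateral COM).
#' @export
mobility <- function(traj, slab = NULL) {
  sys <- traj$system
  cell <- if (!is.null(slab)) slab$cell else sys$cell
  pep <- sys$atoms$group == "peptide"
  if (!any(pep)) stop("trajectory has no peptide atoms", call. = FALSE)
  m <- sys$atoms$mass[pep]
  com <- t(vapply(traj$frames, function(fr)
    colSums(fr[pep, 1:2, drop = FALSE] * m) / sum(m), numeric(2)))
  unwrapped <- com
  if (!is.null(cell) && nrow(com) > 1) {
    Minv <- solve(cell)
    for (f in 2:nrow(com)) {
      d <- com[f, ] - com[f - 1, ]
      fr <- Minv %*% d
      d <- d - cell %*% round(fr)
      unwrapped[f, ] <- unwrapped[f - 1, ] + d
    }
  }
  disp <- sqrt(rowSums(sweep(unwrapped, 2, unwrapped[1, ])^2))
  list(displacement = disp, max = max(disp), mean = mean(disp),
       series = data.frame(frame = seq_len(nrow(com)),
                           x = unwrapped[, 1], y = unwrapped[, 2],
                           displacement = disp))
}
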