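# FCC(111) slab generation and surface-site bookkeeping.
#
# Conventions: surface normal +z, top layer at z = 0, adsorbate above.
# In-plane primitive vectors a1 = d(1,0), a2 = d(1/2, sqrt(3)/2) with
# d = a/sqrt(2) (nearest-neighbour distance); interlayer spacing
# a/sqrt(3); ABC stacking with lateral shift (a1+a2)/3 per layer going
# down.  The slab is periodic in-plane and rigid (fixed) by default.

#' Build an FCC slab exposing the (111) facet
#'
#' @param element Chemical symbol of the metal (default `"Au"`).
#' @param a Cubic lattice constant in Angstrom (Au: 4.08).
#' @param miller Miller index; only `c(1, 1, 1)` is supported.
#' @param n_layers Number of atomic layers (default 6).
#' @param repeats Length-2 integer vector: in-plane repeats of the
#'   primitive surface cell.  The default 13 x 13 gives a 37.5 A cell,
#'   large enough that even a fully extended 7-mer (about 25 A) cannot
#'   reach its own periodic image at the 12 A nonbonded cutoff; smaller
#'   adsorbates can use smaller slabs.
#' @param fixed Freeze all slab atoms (default TRUE; the substrate is
#'   treated as rigid).
#' @return A `molsys` whose `slab` element records `element`, `a`,
#'   `n_layers`, `repeats`, `d` (in-plane nn distance), `spacing`
#'   (interlayer distance), `top_z`, and `layer` (per-atom layer index,
#'   1 = top).
#' @examples
#' slab <- build_fcc_slab("Au", a = 4.08, n_layers = 6, repeats = c(4, 4))
#' slab$slab$spacing # 4.08 / sqrt(3)
#' @export
build_fcc_slab <- function(element = "Au", a = 4.08, miller = c(1, 1, 1),
                           n_layers = 6, repeats = c(13, 13), fixed = TRUE) {
  stopifnot(a > 0, n_layers >= 1)
  if (length(miller) != 3 || !all(miller == c(1, 1, 1)))
    stop("only the (111) facet is supported; (100)/(110) are excluded ",
         "because the peptides studied show no adsorption preference there",
         call. = FALSE)
  d <- a / sqrt(2)
  h <- a / sqrt(3)
  a1 <- d * c(1, 0)
  a2 <- d * c(0.5, sqrt(3) / 2)
  shift <- (a1 + a2) / 3

  n1 <- repeats[1]; n2 <- repeats[2]
  ij <- expand.grid(i = 0:(n1 - 1), j = 0:(n2 - 1))
  coords <- list(); layer <- integer(0)
  for (k in seq_len(n_layers)) {
    off <- ((k - 1) %% 3) * shift
    xy <- cbind(ij$i * a1[1] + ij$j * a2[1] + off[1],
                ij$i * a1[2] + ij$j * a2[2] + off[2])
    coords[[k]] <- cbind(xy, -(k - 1) * h)
    layer <- c(layer, rep(k, nrow(xy)))
  }
  xyz <- do.call(rbind, coords)
  n <- nrow(xyz)
  type <- toupper(element)
  if (!type %in% .lj_types$type)
    stop("no LJ parameters for metal element: ", element, call. = FALSE)
  atoms <- data.frame(
    name = element, element = element, resid = 1L, resname = type,
    type = type, charge = 0, mass = if (type == "AU") 196.967 else 100,
    group = "surface", fixed = fixed, stringsAsFactors = FALSE
  )[rep(1, n), ]
  rownames(atoms) <- NULL
  cell <- cbind(n1 * a1, n2 * a2)
  slab_meta <- list(element = element, a = a, miller = c(1, 1, 1),
                    n_layers = n_layers, repeats = c(n1, n2), d = d,
                    spacing = h, top_z = 0, layer = layer,
                    a1 = a1, a2 = a2, shift = shift)
  molecular_system(atoms, xyz, empty_topology(), cell = cell,
                   slab = slab_meta)
}

#' Surface-site registry of an FCC(111) slab
#'
#' Maps lateral positions to the three site classes of the (111)
#' surface: `"top"` (above a first-layer atom), `"hcp"` (above a
#' second-layer atom) and `"fcc"` (above a third-layer atom).  The map
#' is periodic under the surface lattice vectors.
#'
#' @param slab A slab from [build_fcc_slab()] with at least 3 layers.
#' @return Object of class `surface_registry` with a `classify(xy)`
#'   function and the sublattice offsets.
#' @export
surface_registry <- function(slab) {
  meta <- slab$slab
  if (is.null(meta)) stop("not a slab system", call. = FALSE)
  if (meta$n_layers < 3)
    stop("surface registry requires at least 3 layers", call. = FALSE)
  offsets <- rbind(top = c(0, 0), hcp = meta$shift, fcc = 2 * meta$shift)
  structure(list(a1 = meta$a1, a2 = meta$a2, offsets = offsets,
                 cell = slab$cell),
            class = "surface_registry")
}

#' Classify a lateral position against the (111) site registry
#'
#' @param registry A `surface_registry` (or a slab, from which one is
#'   built).
#' @param xy Numeric length-2 lateral position, or an n x 2 matrix.
#' @return Character vector of site classes (`"top"`, `"hcp"`, `"fcc"`),
#'   chosen as the nearest sublattice point; attribute `"distance"`
#'   carries the lateral distance to that point.
#' @export
classify_site <- function(registry, xy) {
  if (inherits(registry, "molsys")) registry <- surface_registry(registry)
  stopifnot(inherits(registry, "surface_registry"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  M <- cbind(registry$a1, registry$a2)
  Minv <- solve(M)
  cls <- character(nrow(xy)); dmin <- numeric(nrow(xy))
  for (r in seq_len(nrow(xy))) {
    dd <- vapply(seq_len(3), function(s) {
      v <- xy[r, ] - registry$offsets[s, ]
      f <- Minv %*% v
      best <- Inf
      for (s1 in -1:1) for (s2 in -1:1) {
        w <- v - M %*% (round(f) + c(s1, s2))
        best <- min(best, sqrt(sum(w^2)))
      }
      best
    }, numeric(1))
    k <- which.min(dd)
    cls[r] <- rownames(registry$offsets)[k]
    dmin[r] <- dd[k]
  }
  structure(cls, distance = dmin)
}
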