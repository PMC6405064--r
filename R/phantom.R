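## Synthetic shell phantoms and the physics model used to scan them.
##
## The phantom emulates a trochospiral chambered shell: a sequence of hollow
## calcite spheres whose radii grow geometrically, wound around a coiling
## axis, with later chamber cavities opening into earlier walls (apertures)
## and optional radial pores through the walls. Density is pure calcite
## (2.71 g/cm^3) on the wall and 0 elsewhere; the generating geometry gives
## an exact wall-thickness ground truth away from chamber junctions.

CALCITE_DENSITY <- 2.71  # g/cm^3, ceiling of the density scale

## Two-term photoelectric + scatter attenuation model, mu = rho*(a*E^-3 + b).
## The absolute scale is arbitrary (the CCN is scale-free); the constants are
## chosen so calcite at mid-spectrum attenuates appreciably over the ~100 um
## field of view of a desk-scale phantom, which makes beam hardening visible.
MU_PHOTOELECTRIC_A <- 120   # keV^3 um^-1 cm^3/g
MU_COMPTON_B <- 0.003       # um^-1 cm^3/g
# aluminum pre-filter constants (lower effective Z than calcite)
MU_AL_A <- 30
MU_AL_B <- 0.0025
AL_DENSITY <- 2.70          # g/cm^3

#' Linear X-ray attenuation coefficient of a material voxel
#'
#' Two-term model `mu = density * (a * E^-3 + b)`: a photoelectric term
#' falling steeply with photon energy plus a flat scatter term. Strictly
#' decreasing in energy and linear in density, which is all the beam
#' hardening mechanism requires.
#'
#' @param density mass density, g/cm^3 (0 = air/vacuum).
#' @param energy photon energy, keV; must lie in (5, 80].
#' @param a,b model constants (package defaults documented above).
#' @return linear attenuation, 1/um (same shape as the broadcast inputs).
#' @export
attenuation_coefficient <- function(density, energy,
                                    a = MU_PHOTOELECTRIC_A, b = MU_COMPTON_B) {
  if (any(energy <= 5 | energy > 80)) {
    stop("energy out of range (5, 80] keV", call. = FALSE)
  }
  if (any(density < 0)) stop("negative density", call. = FALSE)
  density * (a * energy^-3 + b)
}

#' Polychromatic X-ray beam spectrum
#'
#' Kramers-law bremsstrahlung weights on a discrete energy grid below the
#' tube voltage, optionally hardened by an aluminum pre-filter
#' (Beer-Lambert transmission of the filter thickness). `gain_drift` is the
#' per-scan multiplicative detector/source factor applied to detected
#' intensities and to the grayscale digitization.
#'
#' @param n_bins number of energy bins (<= 16).
#' @param e_min,kvp spectrum support, keV; `kvp` is the tube voltage (80 kV).
#' @param filter_mm_al aluminum filter thickness, mm (scanner default 0.2).
#' @param gain_drift positive per-scan gain factor.
#' @return a `beam_spectrum` list: `energies` (keV), `weights` (sum 1),
#'   `gain_drift`.
#' @export
beam_spectrum <- function(n_bins = 12, e_min = 10, kvp = 80,
                          filter_mm_al = 0.2, gain_drift = 1) {
  stopifnot(n_bins >= 1, n_bins <= 16, e_min > 5, kvp <= 80, e_min < kvp,
            gain_drift > 0)
  e <- seq(e_min, kvp - 1e-9, length.out = n_bins + 1)
  e <- (e[-1] + e[-length(e)]) / 2          # bin centres, all < kvp
  w <- (kvp - e) / e                        # Kramers' law
  if (filter_mm_al > 0) {
    mu_al <- attenuation_coefficient(AL_DENSITY, e, a = MU_AL_A, b = MU_AL_B)
    w <- w * exp(-mu_al * filter_mm_al * 1000)   # mm -> um
  }
  structure(list(energies = e, weights = w / sum(w), gain_drift = gain_drift),
            class = "beam_spectrum")
}

#' Monochromatic beam (single energy bin)
#'
#' @param energy photon energy, keV.
#' @param gain_drift per-scan gain factor.
#' @return a `beam_spectrum`.
#' @export
monochromatic_spectrum <- function(energy = 40, gain_drift = 1) {
  stopifnot(energy > 5, energy <= 80, gain_drift > 0)
  structure(list(energies = energy, weights = 1, gain_drift = gain_drift),
            class = "beam_spectrum")
}

#' Geometry parameters for a shell phantom
#'
#' Defaults state the package's reference phantom: a 128^3 grid at
#' 0.8 um/voxel with a 4 um calcite wall, matching the scanner metadata the
#' pipeline emulates (0.8 um/pixel resolution, ~4 um shell walls).
#'
#' @param n_chambers number of chambers (>= 1).
#' @param r0 radius of the first chamber, um.
#' @param growth_factor geometric chamber growth per step.
#' @param wall wall thickness, um (must be >= 2 voxels).
#' @param pore_radius pore radius, um.
#' @param pore_density pores per um^2 of chamber surface (0 = none).
#' @param voxel_size voxel edge, um.
#' @param dims grid dimensions (length-3).
#' @param turn_deg azimuthal advance per chamber, degrees (3 chambers/whorl).
#' @param rise fractional rise of the coiling axis per chamber (trochospire).
#' @return a `shell_geometry` list.
#' @export
shell_geometry <- function(n_chambers = 4, r0 = 9.6, growth_factor = 1.2,
                           wall = 4, pore_radius = 1.2, pore_density = 0,
                           voxel_size = 0.8, dims = c(128, 128, 128),
                           turn_deg = 120, rise = 0.35) {
  stopifnot(n_chambers >= 1, r0 > 0, growth_factor > 0, wall > 0,
            voxel_size > 0, length(dims) == 3)
  structure(list(n_chambers = n_chambers, r0 = r0,
                 growth_factor = growth_factor, wall = wall,
                 pore_radius = pore_radius, pore_density = pore_density,
                 voxel_size = voxel_size, dims = as.integer(dims),
                 turn_deg = turn_deg, rise = rise),
            class = "shell_geometry")
}

# chamber centres (um, relative to the phantom centre) and radii
.chamber_layout <- function(g) {
  k <- seq_len(g$n_chambers) - 1
  r <- g$r0 * g$growth_factor^k
  theta <- k * g$turn_deg * pi / 180
  # radial offset keeps successive chambers overlapping so apertures open
  off <- ifelse(k == 0, 0, 0.75 * r)
  z <- cumsum(c(0, (g$rise * r)[-length(r)]))
  cx <- off * cos(theta)
  cy <- off * sin(theta)
  cz <- z - mean(z)
  list(centres = cbind(cx, cy, cz), radii = r)
}

#' Generate a trochospiral shell phantom
#'
#' Builds the density volume (g/cm^3), the binary shell mask and the exact
#' wall-thickness ground truth from the generating geometry. Later chambers
#' carve their cavities through earlier walls; pores (if requested) are
#' radial cylinders through the wall, placed reproducibly from `seed`.
#' Thickness truth equals the nominal wall thickness on wall voxels; at
#' chamber junctions the generating value is retained (documented
#' approximation).
#'
#' @param geometry a [shell_geometry()].
#' @param seed integer seed for pore placement.
#' @param centre phantom centre in the grid, voxel coordinates (default grid
#'   centre).
#' @return a `shell_phantom` list: `density` (3-D array, g/cm^3),
#'   `mask` (logical array), `thickness_truth` (um, 0 off the wall),
#'   `voxel_size`, `geometry`.
#' @export
make_shell_phantom <- function(geometry = shell_geometry(), seed = 1,
                               centre = NULL) {
  g <- geometry
  if (g$wall < 2 * g$voxel_size) {
    stop("wall thickness ", g$wall, " um is below 2 voxels (",
         2 * g$voxel_size, " um): unmeasurable at this resolution",
         call. = FALSE)
  }
  dims <- g$dims
  if (is.null(centre)) centre <- (dims + 1) / 2
  lay <- .chamber_layout(g)
  # voxel-centre coordinates in um relative to the phantom centre
  xs <- (seq_len(dims[1]) - centre[1]) * g$voxel_size
  ys <- (seq_len(dims[2]) - centre[2]) * g$voxel_size
  zs <- (seq_len(dims[3]) - centre[3]) * g$voxel_size
  nvox <- prod(dims)
  in_outer <- FALSE
  in_cavity <- FALSE
  X <- rep(xs, times = dims[2] * dims[3])
  Y <- rep(rep(ys, each = dims[1]), times = dims[3])
  Z <- rep(zs, each = dims[1] * dims[2])
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  pore_cut <- FALSE
  for (k in seq_len(g$n_chambers)) {
    ctr <- lay$centres[k, ]
    r <- lay$radii[k]
    d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
    in_outer <- in_outer | (d2 <= r^2)
    in_cavity <- in_cavity | (d2 <= (r - g$wall)^2)
    if (g$pore_density > 0) {
      n_pores <- max(0L, round(g$pore_density * 4 * pi * r^2))
      if (n_pores > 0) {
        u <- matrix(rnorm(3 * n_pores), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        dx <- X - ctr[1]; dy <- Y - ctr[2]; dz <- Z - ctr[3]
        for (p in seq_len(n_pores)) {
          proj <- dx * u[p, 1] + dy * u[p, 2] + dz * u[p, 3]
          perp2 <- d2 - proj^2
          pore_cut <- pore_cut |
            (perp2 <= g$pore_radius^2 & proj > 0 & proj <= r + g$voxel_size)
        }
      }
    }
  }
  mask <- in_outer & !in_cavity & !pore_cut
  mask <- array(mask, dim = dims)
  density <- array(0, dim = dims)
  density[mask] <- CALCITE_DENSITY
  thickness <- array(0, dim = dims)
  thickness[mask] <- g$wall
  structure(list(density = density, mask = mask, thickness_truth = thickness,
                 voxel_size = g$voxel_size, geometry = g, seed = seed),
            class = "shell_phantom")
}

#' Assemble a scan scene from phantoms plus references
#'
#' Places one or more phantoms side by side along x (the stacking direction
#' that produces beam hardening when several specimens are mounted
#' together), adds a solid standard-calcite block and labels an air
#' reference region. The returned labels follow the package convention:
#' 0 unknown, 1 air reference, 2 standard calcite.
#'
#' @param phantoms list of `shell_phantom` objects (identical grids assumed
#'   for their extents; each is cropped to its bounding box).
#' @param dims scene grid dimensions.
#' @param voxel_size um/voxel.
#' @param standard logical; include the standard-calcite block.
#' @param standard_density density of the standard block, g/cm^3.
#' @return a `scan_scene` list: `density`, `labels`, `voxel_size`,
#'   `specimen_masks` (list of logical arrays, scene grid).
#' @export
assemble_scene <- function(phantoms, dims = c(128, 128, 32), voxel_size = 0.8,
                           standard = TRUE, standard_density = CALCITE_DENSITY) {
  if (length(phantoms) == 0) stop("empty scene", call. = FALSE)
  dims <- as.integer(dims)
  density <- array(0, dim = dims)
  labels <- array(0L, dim = dims)
  masks <- vector("list", length(phantoms))
  np <- length(phantoms)
  # specimen centres spread along x through the scene centre
  xc <- round(dims[1] * (seq_len(np) - 0.5) / np)
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    bb <- which(ph$mask, arr.ind = TRUE)
    if (nrow(bb) == 0) stop("phantom ", i, " is empty", call. = FALSE)
    lo <- apply(bb, 2, min); hi <- apply(bb, 2, max)
    sub_d <- ph$density[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub_m <- ph$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sz <- dim(sub_d)
    org <- c(xc[i] - sz[1] %/% 2,
             (dims[2] - sz[2]) %/% 2 + 1,
             (dims[3] - sz[3]) %/% 2 + 1)
    if (any(org < 1) || any(org + sz - 1 > dims)) {
      stop("phantom ", i, " does not fit in the scene field of view",
           call. = FALSE)
    }
    ix <- org[1]:(org[1] + sz[1] - 1)
    iy <- org[2]:(org[2] + sz[2] - 1)
    iz <- org[3]:(org[3] + sz[3] - 1)
    density[ix, iy, iz] <- pmax(density[ix, iy, iz], sub_d)
    m <- array(FALSE, dim = dims)
    m[ix, iy, iz] <- sub_m
    masks[[i]] <- m
  }
  if (standard) {
    # solid block near the y-edge of the field, clear of the specimens
    bx <- max(2, dims[1] %/% 2 - 7):(dims[1] %/% 2 + 7)
    by <- max(2, dims[2] - 13):(dims[2] - 2)
    bz <- max(1, dims[3] %/% 2 - 3):min(dims[3], dims[3] %/% 2 + 3)
    density[bx, by, bz] <- standard_density
    labels[bx, by, bz] <- 2L
  }
  # air reference: front-corner box guaranteed empty
  ax <- 2:min(12, dims[1]); ay <- 2:min(12, dims[2]); az <- 1:dims[3]
  if (any(density[ax, ay, az] > 0)) {
    stop("air reference region is occupied; enlarge the scene")
  }
  labels[ax, ay, az] <- 1L
  structure(list(density = density, labels = labels, voxel_size = voxel_size,
                 specimen_masks = masks),
            class = "scan_scene")
}

#' Parameters for the synthetic isotope dataset generator
#'
#' Defaults state the emulated world: three treatment groups with the study
#' sample sizes (A = 14, B = 20, C = 15), genotype composition of the typed
#' specimens (Ia/Ib/IIa = 15/8/11 of 34, one untyped), genotype-specific
#' linear d13C-weight structure with slopes near the field's reported
#' values, a common d18O level, log-normal shell weights spanning ~1-8 ug,
#' residual noise at the instrument + vital-effect scale (~0.2 permil), and
#' null treatment effects (the study detected none).
#'
#' @param n_groups named sample sizes for groups A/B/C.
#' @param type_probs genotype mixing proportions among typed specimens.
#' @param untyped_frac fraction of B/C records left untyped (failed
#'   sequencing).
#' @param intercepts,slopes named per-genotype intercept (permil) and slope
#'   (permil/ug) of d13C vs weight.
#' @param d18o_mean,d18o_sd d18O level and spread, permil.
#' @param weight_meanlog,weight_sdlog log-normal weight parameters (ug).
#' @param group_effect_d13c,group_effect_d18o named per-group additive
#'   offsets, permil (default all 0).
#' @param noise_sd_d13c residual d13C noise sd, permil.
#' @param seed integer seed.
#' @return an `isotope_sim_params` list.
#' @export
isotope_sim_params <- function(
    n_groups = c(A = 14, B = 20, C = 15),
    type_probs = c(Ia = 15, Ib = 8, IIa = 11) / 34,
    untyped_frac = 1 / 35,
    intercepts = c(Ia = -0.75, Ib = -0.71, IIa = -0.54),
    slopes = c(Ia = 0.085, Ib = 0.05, IIa = 0.128),
    d18o_mean = -1.85, d18o_sd = 0.32,
    weight_meanlog = log(2.8), weight_sdlog = 0.5,
    group_effect_d13c = c(A = 0, B = 0, C = 0),
    group_effect_d18o = c(A = 0, B = 0, C = 0),
    noise_sd_d13c = 0.2,
    seed = 1) {
  stopifnot(all(n_groups >= 2), noise_sd_d13c >= 0, d18o_sd >= 0,
            abs(sum(type_probs) - 1) < 1e-8)
  if (!all(names(slopes) %in% c("Ia", "Ib", "IIa")) ||
      !all(names(intercepts) %in% c("Ia", "Ib", "IIa"))) {
    stop("unknown genotype label in slopes/intercepts", call. = FALSE)
  }
  structure(as.list(environment()), class = "isotope_sim_params")
}

#' Simulate an individual-level isotope dataset
#'
#' Weights are log-normal; `d13c = intercept(type) + slope(type) * weight +
#' group effect + N(0, sd)`; `d18o = mean + group effect + N(0, sd)`.
#' Group-A specimens (and a fraction of B/C) are reported untyped but keep
#' their latent genotype for the mean structure. Deterministic given
#' `params$seed`.
#'
#' @param params an [isotope_sim_params()].
#' @return an `isotope_table` data frame (same shape as
#'   [load_isotope_table()]).
#' @export
make_isotope_dataset <- function(params = isotope_sim_params()) {
  p <- params
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(p$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  groups <- rep(names(p$n_groups), times = p$n_groups)
  n <- length(groups)
  latent <- sample(names(p$type_probs), n, replace = TRUE, prob = p$type_probs)
  shown <- latent
  shown[groups == "A"] <- "untyped"
  bc <- which(groups != "A")
  n_unt <- round(p$untyped_frac * length(bc))
  if (n_unt > 0) shown[sample(bc, n_unt)] <- "untyped"
  w <- rlnorm(n, p$weight_meanlog, p$weight_sdlog)
  d13c <- p$intercepts[latent] + p$slopes[latent] * w +
    p$group_effect_d13c[groups] + rnorm(n, 0, p$noise_sd_d13c)
  d18o <- p$d18o_mean + p$group_effect_d18o[groups] + rnorm(n, 0, p$d18o_sd)
  ids <- unlist(lapply(p$n_groups, function(k) sprintf("S%02d", seq_len(k))))
  out <- data.frame(
    group = factor(groups, levels = c("A", "B", "C")),
    specimen_id = ids,
    genetic_type = factor(shown, levels = c("Ia", "Ib", "IIa", "untyped")),
    d13c = as.numeric(d13c), d18o = as.numeric(d18o), weight = w,
    stringsAsFactors = FALSE
  )
  class(out) <- c("isotope_table", class(out))
  out
}
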