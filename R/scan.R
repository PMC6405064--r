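## Polychromatic parallel-beam scan simulation and filtered back projection.
##
## Geometry is 2-D parallel-beam per slice (the z axis of the scene is the
## rotation axis). Because the attenuation model is linear in density,
## each slice's density is forward-projected once; the polychromatic
## detector signal is then assembled per energy bin from the same density
## line integrals:
##   I = gain * sum_E w(E) * exp(-mu_coef(E) * P)      P = density path, um
## The stored sinogram is the flat-field-corrected log attenuation
## -log(I / I0) with I0 the same scan's unattenuated (air-ray) intensity,
## so the per-scan gain cancels inside the sinogram; the gain re-enters in
## the grayscale digitization of the reconstruction, which is where
## scan-to-scan drift shows up in real data.

#' Simulate a tomographic scan of a scene
#'
#' @param scene a [assemble_scene()] result (or any list with `density`
#'   array and `voxel_size`).
#' @param spectrum a [beam_spectrum()] / [monochromatic_spectrum()].
#' @param n_angles projection count over 360 degrees (>= 16).
#' @param photons if finite, Poisson counting noise with this many photons
#'   per unattenuated ray; `Inf` (default) disables noise.
#' @param seed seed for the Poisson noise.
#' @param step ray-marching step, voxels.
#' @return a `sinogram` list: `values` (detector x angle x slice array of
#'   log-attenuations), `angles` (radians), `voxel_size`, `spectrum`.
#' @export
simulate_scan <- function(scene, spectrum = beam_spectrum(), n_angles = 360,
                          photons = Inf, seed = 1, step = 0.5) {
  if (is.null(scene$density) || all(dim(scene$density) == 0)) {
    stop("empty scene", call. = FALSE)
  }
  stopifnot(n_angles >= 16)
  dims <- dim(scene$density)
  n <- dims[1]
  if (dims[2] != n) stop("scene slices must be square")
  nz <- if (length(dims) == 3) dims[3] else 1L
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  mu_coef <- attenuation_coefficient(1, spectrum$energies)  # per unit density
  w <- spectrum$weights
  sino <- array(0, dim = c(n, n_angles, nz))
  use_noise <- is.finite(photons)
  if (use_noise) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    })
  }
  for (z in seq_len(nz)) {
    slice <- if (length(dims) == 3) scene$density[, , z] else scene$density
    P <- forward_project_cpp(slice, angles, step = step) * scene$voxel_size
    I <- 0
    for (k in seq_along(mu_coef)) I <- I + w[k] * exp(-mu_coef[k] * P)
    I <- spectrum$gain_drift * I
    I0 <- spectrum$gain_drift
    if (use_noise) {
      counts <- matrix(rpois(length(I), photons * I), nrow = nrow(I))
      I <- counts / photons
      if (any(I <= 0)) {
        stop("nonpositive detected intensity (photon starvation); ",
             "increase `photons`", call. = FALSE)
      }
    }
    sino[, , z] <- -log(I / I0)
  }
  if (any(!is.finite(sino))) stop("non-finite sinogram values", call. = FALSE)
  structure(list(values = sino, angles = angles, voxel_size = scene$voxel_size,
                 spectrum = spectrum),
            class = "sinogram")
}

# Ram-Lak spatial-domain kernel (Kak & Slaney), applied by FFT convolution.
.ramp_filter <- function(proj) {
  n <- nrow(proj)
  m <- 2^ceiling(log2(2 * n))
  k <- c(0:(m / 2), (-m / 2 + 1):-1)
  h <- numeric(m)
  h[k == 0] <- 1 / 4
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2)
  H <- Re(fft(h))
  padded <- rbind(proj, matrix(0, m - n, ncol(proj)))
  filt <- Re(mvfft(mvfft(padded) * H, inverse = TRUE)) / m
  filt[seq_len(n), , drop = FALSE]
}

#' Filtered back projection reconstruction
#'
#' Slice-wise parallel-beam FBP with a Ram-Lak ramp filter. Returns
#' effective linear attenuation per um on the scene grid.
#'
#' @param sinogram a [simulate_scan()] result.
#' @return an `attenuation_volume` (see [attenuation_volume()]) whose values
#'   are effective mu (1/um).
#' @export
reconstruct_fbp <- function(sinogram) {
  v <- sinogram$values
  if (length(dim(v)) == 2) v <- array(v, dim = c(dim(v), 1))
  if (length(sinogram$angles) < 16) stop("need >= 16 angles", call. = FALSE)
  if (dim(v)[2] != length(sinogram$angles)) {
    stop("detector/angle layout inconsistent with angle list", call. = FALSE)
  }
  n <- dim(v)[1]
  nz <- dim(v)[3]
  out <- array(0, dim = c(n, n, nz))
  for (z in seq_len(nz)) {
    filt <- .ramp_filter(v[, , z])
    out[, , z] <- backproject_cpp(filt, sinogram$angles)
  }
  # backprojection is in per-detector-sample units; convert to mu per um
  out <- out / sinogram$voxel_size
  attenuation_volume(out, voxel_size = sinogram$voxel_size)
}

#' Digitize a reconstructed volume to 16-bit grayscale
#'
#' Emulates the scanner's grayscale chain: `gray = gain * (scale * mu +
#' offset)`, clamped to the 16-bit range and rounded. The per-scan gain is
#' exactly the drift that the standard-calcite normalization is designed to
#' cancel.
#'
#' @param volume an `attenuation_volume` of mu values (1/um).
#' @param gain per-scan gain factor (use the spectrum's `gain_drift`).
#' @param scale,offset digitization constants (defaults put calcite near
#'   30000 and air near 2000 gray levels).
#' @return an `attenuation_volume` of grayscale values.
#' @export
digitize_volume <- function(volume, gain = 1, scale = 1.4e6, offset = 2000) {
  g <- gain * (scale * volume$values + offset)
  g <- pmin(pmax(round(g), 0), 65535)
  attenuation_volume(g, voxel_size = volume$voxel_size,
                     region_labels = volume$region_labels)
}
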