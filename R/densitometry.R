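## CCN densitometry: per-scan calibration against standard calcite and air,
## the CT-number and CCN mappings, shell segmentation, per-specimen
## summaries and color slice export.
##
## Label convention for `region_labels`: 0 = unknown, 1 = air reference,
## 2 = standard calcite.

LABEL_AIR <- 1L
LABEL_CALCITE <- 2L

#' Attenuation volume container
#'
#' A reconstructed 3-D grid of grayscale or attenuation values with its
#' voxel size and (optionally) labeled reference regions.
#'
#' @param values numeric 3-D array (a matrix is promoted to one slice).
#' @param voxel_size voxel edge length, um.
#' @param region_labels optional integer array of the same shape
#'   (0 unknown, 1 air, 2 standard calcite).
#' @return an `attenuation_volume` list.
#' @export
attenuation_volume <- function(values, voxel_size, region_labels = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1))
  stopifnot(length(dim(values)) == 3, voxel_size > 0)
  if (any(!is.finite(values))) stop("non-finite volume values", call. = FALSE)
  if (!is.null(region_labels)) {
    stopifnot(identical(dim(region_labels), dim(values)))
  }
  structure(list(values = values, voxel_size = voxel_size,
                 region_labels = region_labels),
            class = "attenuation_volume")
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("attenuation_volume %dx%dx%d @ %.3g um/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$values), max(x$values)))
  invisible(x)
}

#' Clinical CT number (Hounsfield units)
#'
#' `k * (mu_m - mu_w) / mu_w`: water maps to 0 HU and vacuum/air (mu = 0)
#' to -k HU.
#'
#' @param mu_m attenuation of the object.
#' @param mu_w attenuation of water (> 0).
#' @param k scale constant, conventionally 1000.
#' @return CT number, HU.
#' @export
ct_number <- function(mu_m, mu_w, k = 1000) {
  if (any(mu_w <= 0)) stop("mu_w must be positive", call. = FALSE)
  k * (mu_m - mu_w) / mu_w
}

#' Calcite CT number (CCN)
#'
#' `1000 * (mu_sample - mu_air) / (mu_calcite - mu_air)`: the per-scan air
#' level maps to 0 and the standard-calcite level (pure calcite, density
#' 2.71 g/cm^3) to 1000. Values are not clipped: noisy voxels may fall
#' below 0 or above 1000, and clipping would bias paired comparisons.
#' Because the mapping is affine in the grayscale, any per-scan gain/offset
#' applied alike to sample and calibration cancels exactly.
#'
#' @param mu_sample attenuation/grayscale value(s) of the object.
#' @param cal a [scan_calibration()] (or list with `mu_air`, `mu_calcite`).
#' @return CCN value(s).
#' @export
ccn <- function(mu_sample, cal) {
  if (!(cal$mu_calcite > cal$mu_air)) {
    stop("degenerate calibration: mu_calcite must exceed mu_air",
         call. = FALSE)
  }
  1000 * (mu_sample - cal$mu_air) / (cal$mu_calcite - cal$mu_air)
}

#' Scan calibration object
#'
#' @param mu_air,mu_calcite mean grayscale of the air and standard-calcite
#'   reference regions.
#' @param n_air,n_calcite voxel counts the means were taken over.
#' @return a `scan_calibration` list.
#' @export
scan_calibration <- function(mu_air, mu_calcite, n_air = NA_integer_,
                             n_calcite = NA_integer_) {
  if (!(mu_calcite > mu_air)) {
    stop("degenerate calibration: mu_calcite must exceed mu_air",
         call. = FALSE)
  }
  structure(list(mu_air = mu_air, mu_calcite = mu_calcite,
                 n_air = n_air, n_calcite = n_calcite),
            class = "scan_calibration")
}

# one-voxel 6-neighbourhood erosion of a logical array
.erode1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) {
    out <- out & shift(mask, ax, 1) & shift(mask, ax, -1)
  }
  out
}

# Otsu threshold on a numeric vector restricted to a range
.otsu <- function(x, range = NULL, n_bins = 256) {
  if (!is.null(range)) x <- x[x >= range[1] & x <= range[2]]
  if (length(x) < 2 || diff(range(x)) == 0) {
    stop("degenerate histogram for Otsu thresholding", call. = FALSE)
  }
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

#' Calibrate a scan against its reference regions
#'
#' Computes the air and standard-calcite reference means after a one-voxel
#' morphological erosion of each region (partial-volume rims bias the
#' reference level). If the volume carries no region labels, the function
#' attempts auto-detection: the standard is the brightest large connected
#' component above the Otsu threshold and air is the histogram's dominant
#' low mode.
#'
#' @param volume an [attenuation_volume()].
#' @param min_voxels minimum region size after erosion.
#' @return a [scan_calibration()].
#' @export
calibrate_scan <- function(volume, min_voxels = 100) {
  v <- volume$values
  lab <- volume$region_labels
  if (!is.null(lab) && any(lab == LABEL_AIR) && any(lab == LABEL_CALCITE)) {
    air_m <- .erode1(lab == LABEL_AIR)
    cal_m <- .erode1(lab == LABEL_CALCITE)
  } else {
    thr <- .otsu(as.vector(v))
    bright <- v > thr
    labc <- array(label_components_cpp(as.integer(bright), dim(v)), dim(v))
    sizes <- tabulate(labc[labc > 0])
    cand <- which(sizes >= min_voxels)
    if (length(cand) == 0) {
      stop("calibration failure: no bright component large enough for a ",
           "standard-calcite reference", call. = FALSE)
    }
    means <- vapply(cand, function(k) {
      m <- .erode1(labc == k)
      if (sum(m) < min_voxels) return(NA_real_)
      mean(v[m])
    }, numeric(1))
    if (all(is.na(means))) {
      stop("calibration failure: candidate regions vanish under erosion",
           call. = FALSE)
    }
    best <- cand[which.max(means)]
    cal_m <- .erode1(labc == best)
    air_m <- .erode1(v <= thr & labc == 0)
    # auto-detection sanity: the bright/dark split must be a real contrast,
    # not a noise histogram cut
    if (sum(cal_m) >= 1 && sum(air_m) >= 1) {
      sep <- mean(v[cal_m]) - mean(v[air_m])
      spread <- sd(v[cal_m]) + sd(v[air_m])
      if (!is.finite(sep) || sep < 3 * spread) {
        stop("calibration failure: no credible standard-calcite/air contrast ",
             "detected", call. = FALSE)
      }
    }
  }
  n_air <- sum(air_m); n_cal <- sum(cal_m)
  if (n_air < min_voxels || n_cal < min_voxels) {
    stop(sprintf(
      "calibration failure: reference region too small after erosion (air %d, calcite %d, need %d)",
      n_air, n_cal, min_voxels), call. = FALSE)
  }
  mu_air <- mean(v[air_m]); mu_cal <- mean(v[cal_m])
  scan_calibration(mu_air, mu_cal, n_air, n_cal)
}

#' Map a calibrated volume to the CCN scale
#'
#' @param volume an [attenuation_volume()].
#' @param cal a [scan_calibration()]; computed with [calibrate_scan()] when
#'   omitted.
#' @return an `attenuation_volume` of CCN values (labels carried through).
#' @export
ccn_volume <- function(volume, cal = calibrate_scan(volume)) {
  attenuation_volume(ccn(volume$values, cal), voxel_size = volume$voxel_size,
                     region_labels = volume$region_labels)
}

#' Segment the shell from a CCN volume
#'
#' Otsu threshold on the CCN histogram restricted to `[0, 1200]`, then
#' 26-connected components of at least `min_component` voxels, excluding
#' any labeled standard-calcite region. Pores are left open (no hole
#' filling).
#'
#' @param ccn_vol an `attenuation_volume` on the CCN scale.
#' @param min_component minimum surviving component size, voxels.
#' @param threshold optional fixed CCN threshold overriding Otsu.
#' @param min_auto_threshold an automatically chosen threshold below this
#'   CCN level means the volume holds no calcite-bright structure (an
#'   all-air scan): segmentation error.
#' @return logical mask array.
#' @export
segment_shell <- function(ccn_vol, min_component = 1000, threshold = NULL,
                          min_auto_threshold = 100) {
  v <- ccn_vol$values
  if (is.null(threshold)) {
    threshold <- .otsu(as.vector(v), range = c(0, 1200))
    if (threshold < min_auto_threshold) {
      stop("segmentation failure: no calcite-bright class in the CCN ",
           "histogram (auto threshold ", round(threshold, 1), ")",
           call. = FALSE)
    }
  }
  mask <- v > threshold
  if (!is.null(ccn_vol$region_labels)) {
    mask[ccn_vol$region_labels == LABEL_CALCITE] <- FALSE
  }
  labc <- array(label_components_cpp(as.integer(mask), dim(v)), dim(v))
  if (max(labc) == 0) stop("segmentation failure: nothing above threshold",
                           call. = FALSE)
  sizes <- tabulate(labc[labc > 0])
  keep <- which(sizes >= min_component)
  if (length(keep) == 0) {
    stop("segmentation failure: no component of >= ", min_component,
         " voxels", call. = FALSE)
  }
  array(labc %in% keep, dim = dim(v))
}

#' Per-specimen density summary over a shell mask
#'
#' @param ccn_vol an `attenuation_volume` on the CCN scale.
#' @param mask logical shell mask.
#' @param breaks histogram break count (over `[0, 1200]`).
#' @return a `specimen_density_summary` list: `mean_ccn`, `ccn_histogram`
#'   (counts + breaks), `shell_voxel_count`, `shell_volume` (um^3).
#' @export
specimen_summary <- function(ccn_vol, mask, breaks = 50) {
  if (!any(mask)) stop("empty shell mask", call. = FALSE)
  x <- ccn_vol$values[mask]
  br <- seq(0, 1200, length.out = breaks + 1)
  counts <- tabulate(findInterval(pmin(pmax(x, 0), 1200), br,
                                  rightmost.closed = TRUE), breaks)
  structure(list(
    mean_ccn = mean(x),
    ccn_histogram = list(breaks = br, counts = counts),
    shell_voxel_count = sum(mask),
    shell_volume = sum(mask) * ccn_vol$voxel_size^3
  ), class = "specimen_density_summary")
}

## Documented density palette: monotone black-purple-red-yellow-white ramp
## over CCN 0..1000 in 256 steps. Monotone in luminance, hence invertible by
## nearest-color lookup.
ccn_palette <- function(n = 256) {
  colorRampPalette(c("black", "#4B0082", "red", "yellow", "white"))(n)
}

#' Export color-mapped CCN slices
#'
#' Writes one binary PPM image per slice along the chosen axis, mapping
#' CCN 0 to the palette bottom and 1000 to its top (values outside are
#' clamped), plus a JSON sidecar recording the palette so images can be
#' decoded back to CCN bins.
#'
#' @param ccn_vol an `attenuation_volume` on the CCN scale.
#' @param axis slicing axis: `"x"`, `"y"` or `"z"`.
#' @param out_dir output directory (created if needed).
#' @param ccn_range CCN range mapped across the palette.
#' @return character vector of image paths, invisibly.
#' @export
density_slices <- function(ccn_vol, axis = "z", out_dir, ccn_range = c(0, 1000)) {
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("invalid axis: ", axis, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pal <- ccn_palette()
  rgb_tab <- col2rgb(pal)                      # 3 x 256
  nlev <- length(pal)
  v <- ccn_vol$values
  nslice <- dim(v)[ax]
  paths <- character(nslice)
  for (s in seq_len(nslice)) {
    sl <- switch(ax, v[s, , ], v[, s, ], v[, , s])
    idx <- 1 + floor((nlev - 1e-9) *
      pmin(pmax((sl - ccn_range[1]) / diff(ccn_range), 0), 1 - 1e-12))
    rgb <- array(0L, dim = c(dim(sl), 3))
    for (ch in 1:3) rgb[, , ch] <- rgb_tab[ch, idx]
    paths[s] <- file.path(out_dir, sprintf("slice_%s_%04d.ppm", axis, s))
    write_ppm(rgb, paths[s])
  }
  meta <- list(axis = axis, ccn_range = ccn_range, palette = pal,
               mapping = "linear, clamped; index = floor(255 * (ccn - lo)/(hi - lo))")
  jsonlite::write_json(meta, file.path(out_dir, "palette.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Decode palette colors back to CCN bin centres
#'
#' Inverse of the [density_slices()] color mapping by nearest palette entry.
#'
#' @param rgb integer matrix/array with last dimension 3 (0-255).
#' @param ccn_range range used at encoding time.
#' @return numeric CCN values (bin centres).
#' @export
decode_palette <- function(rgb, ccn_range = c(0, 1000)) {
  pal <- ccn_palette()
  rgb_tab <- t(col2rgb(pal))                   # 256 x 3
  m <- matrix(rgb, ncol = 3)
  idx <- apply(m, 1, function(px) {
    which.min(colSums((t(rgb_tab) - px)^2))
  })
  lo <- ccn_range[1]; hi <- ccn_range[2]
  lo + (idx - 0.5) / length(pal) * (hi - lo)
}
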