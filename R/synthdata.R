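#' Specification for a multi-modal brain phantom
#'
#' Defines the geometry, class mixture and corruption model of a synthetic
#' follow-up-like brain scan. The phantom emulates the statistical structure
#' of post-treatment glioblastoma MRI: a nested lesion (FLAIR-hyperintense
#' envelope, enhancing shell, optional non-enhancing necrotic core),
#' possible fragmentation of subregions into disconnected components, a
#' resection cavity labeled background, multiplicative low-frequency bias
#' and additive noise. Necrotic cores are rare: by default a phantom
#' contains one with probability 47/311, matching the prevalence of
#' non-enhancing regions in follow-up cohorts.
#'
#' @param shape integer vector of 3 voxel counts, each >= 8.
#' @param spacing_mm positive voxel spacing (mm) along each axis.
#' @param n_lesions non-negative number of lesions.
#' @param nenr_prevalence probability in \[0,1\] that the phantom contains a
#'   non-enhancing necrotic core (NENR).
#' @param fragmentation probability in \[0,1\] that the enhancing shell is
#'   split into disconnected components.
#' @param cavity carve a background-labeled resection cavity next to the
#'   lesion (TRUE for follow-up-like scans).
#' @param bias_amplitude non-negative strength of the multiplicative
#'   low-frequency intensity field (0 = none).
#' @param noise_sigma non-negative additive Gaussian noise s.d. per modality.
#' @param seed integer RNG seed; identical specs give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L),
                         spacing_mm = c(1, 1, 1),
                         n_lesions = 1L,
                         nenr_prevalence = 47 / 311,
                         fragmentation = 0.3,
                         cavity = TRUE,
                         bias_amplitude = 0,
                         noise_sigma = 0.04,
                         seed = 1L) {
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 8)) {
    stop_validation("'shape' must be 3 integers, each >= 8", field = "shape")
  }
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop_validation("'spacing_mm' must be 3 positive reals", field = "spacing_mm")
  }
  check_scalar_num(n_lesions, "n_lesions", min = 0)
  check_scalar_num(nenr_prevalence, "nenr_prevalence", min = 0, max = 1)
  check_scalar_num(fragmentation, "fragmentation", min = 0, max = 1)
  if (!is.logical(cavity) || length(cavity) != 1L || is.na(cavity)) {
    stop_validation("'cavity' must be TRUE or FALSE", field = "cavity")
  }
  check_scalar_num(bias_amplitude, "bias_amplitude", min = 0)
  check_scalar_num(noise_sigma, "noise_sigma", min = 0)
  check_scalar_num(seed, "seed")
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 n_lesions = as.integer(n_lesions),
                 nenr_prevalence = nenr_prevalence,
                 fragmentation = fragmentation, cavity = cavity,
                 bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Multi-modal volume container
#'
#' A 4-channel 3D intensity field with channel order T1, T1+Gd, T2, FLAIR.
#'
#' @param data numeric array of dim `c(4, X, Y, Z)` with finite values.
#' @param spacing_mm positive voxel spacing (mm).
#' @param affine optional 4x4 voxel-to-world matrix (RAS); defaults to a
#'   diagonal scaling by `spacing_mm`.
#' @return An object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(data, spacing_mm = c(1, 1, 1), affine = NULL) {
  d <- dim(data)
  if (is.null(d) || length(d) != 4L || d[1L] != 4L) {
    stop_validation("'data' must be a 4 x X x Y x Z array", field = "data")
  }
  if (!all(is.finite(data))) {
    stop_validation("all intensities must be finite", field = "data")
  }
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop_validation("'spacing_mm' must be 3 positive reals", field = "spacing_mm")
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 affine = affine),
            class = "multimodal_volume")
}

#' Integer label map container
#'
#' Per-voxel class in \{0 background, 1 FHR, 2 ER, 3 NENR\}.
#'
#' @param labels integer 3D array with values in \{0,1,2,3\}.
#' @return An object of class `label_map` carrying the fixed class names.
#' @export
label_map <- function(labels) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3L) {
    stop_validation("'labels' must be a 3D array", field = "labels")
  }
  if (!all(labels %in% 0:3)) {
    stop_validation("label values must lie in {0,1,2,3}", field = "labels")
  }
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 class_names = c(`0` = "background", `1` = "FHR",
                                 `2` = "ER", `3` = "NENR")),
            class = "label_map")
}

#' @export
class_names_glioseg <- function() {
  c(`0` = "background", `1` = "FHR", `2` = "ER", `3` = "NENR")
}

# Per-tissue mean intensities, one row per modality (t1, t1gd, t2, flair).
# The table encodes the clinical contrast logic: the enhancing shell is
# bright on T1+Gd, the FLAIR-hyperintense envelope bright on T2/FLAIR, the
# necrotic core dark on T1+Gd; the cavity is CSF-like on every channel.
.phantom_contrast <- function() {
  rbind(air    = c(0.02, 0.02, 0.02, 0.02),
        brain  = c(0.45, 0.45, 0.40, 0.35),
        fhr    = c(0.35, 0.35, 0.80, 0.85),
        er     = c(0.40, 0.95, 0.55, 0.55),
        nenr   = c(0.25, 0.10, 0.75, 0.60),
        cavity = c(0.10, 0.10, 0.95, 0.15))
}

.ellipsoid_mask <- function(shape, center, semi) {
  x <- (seq_len(shape[1L]) - center[1L]) / semi[1L]
  y <- (seq_len(shape[2L]) - center[2L]) / semi[2L]
  z <- (seq_len(shape[3L]) - center[3L]) / semi[3L]
  q <- outer(outer(x^2, y^2, "+"), z^2, "+")
  q <= 1
}

# Quadratic form of an axis-aligned ellipsoid; nested thresholds of the same
# form guarantee strictly nested (morphologically contained) subregions.
.ellipsoid_q <- function(shape, center, semi) {
  x <- (seq_len(shape[1L]) - center[1L]) / semi[1L]
  y <- (seq_len(shape[2L]) - center[2L]) / semi[2L]
  z <- (seq_len(shape[3L]) - center[3L]) / semi[3L]
  outer(outer(x^2, y^2, "+"), z^2, "+")
}

#' Generate a multi-modal brain phantom with ground-truth labels
#'
#' Builds an ellipsoidal head, places nested lesion subregions
#' (NENR core inside ER shell inside FHR envelope), optionally fragments the
#' enhancing shell, carves a resection cavity, fills per-tissue contrasts on
#' the four modality channels, and applies bias/noise corruption.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([multimodal_volume]) and `labels`
#'   ([label_map]).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  shp <- spec$shape
  labels <- array(0L, dim = shp)
  tissue <- array(1L, dim = shp)  # rows of .phantom_contrast(): 1 = air
  head_center <- (shp + 1) / 2
  head_semi <- 0.46 * shp
  head <- .ellipsoid_mask(shp, head_center, head_semi)
  tissue[head] <- 2L  # brain

  has_nenr <- spec$n_lesions > 0 && stats::runif(1) < spec$nenr_prevalence
  fragment <- spec$n_lesions > 0 && stats::runif(1) < spec$fragmentation

  # Nested thresholds of a shared quadratic form guarantee morphological
  # containment (NENR inside the ER shell inside the FHR envelope). The
  # normalized bands (0.30 / 0.65 / 1.0) keep each shell thicker than one
  # diagonal voxel step for lesions of the default size, so 26-neighbors
  # of a core voxel stay within the enclosing shell.
  for (i in seq_len(spec$n_lesions)) {
    center <- round(head_center + stats::runif(3, -0.15, 0.15) * shp)
    a_f <- stats::runif(3, 0.16, 0.21) * shp
    q1 <- .ellipsoid_q(shp, center, a_f)
    # second overlapping ellipsoid keeps the envelope connected but lumpy
    off <- stats::runif(3, -0.4, 0.4) * a_f
    q2 <- .ellipsoid_q(shp, center + off, a_f * stats::runif(3, 0.5, 0.8))
    fhr <- (q1 <= 1 | q2 <= 1) & head
    labels[fhr] <- 1L
    labels[q1 <= 0.65^2] <- 2L
    if (i == 1L && has_nenr) {
      labels[q1 <= 0.30^2] <- 3L
    }
    q_m <- NULL
    if (i == 1L && fragment) {
      # tumor subregions in follow-up scans are often not contiguous:
      # add a detached satellite (its own small ER core inside a small
      # FHR halo) so the ER subregion has >= 2 connected components
      dir <- head_center - center
      if (sqrt(sum(dir^2)) < 2) dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      c2 <- round(center + dir * 1.6 * max(a_f))
      a_m <- 0.55 * a_f
      q_m <- .ellipsoid_q(shp, c2, a_m)
      sat <- (q_m <= 1) & head
      labels[sat & labels == 0L] <- 1L
      labels[sat & (q_m <= 0.45^2)] <- 2L
    }
    if (i == 1L && spec$cavity) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cav_semi <- 0.45 * a_f
      cav_center <- center + dir * (a_f + 0.55 * cav_semi)
      cav <- .ellipsoid_mask(shp, cav_center, cav_semi) & head
      # the cavity sits tangent to the lesion: it only claims voxels
      # outside the envelope, so subregion nesting is untouched
      cav <- cav & (q1 > 1) & (labels == 0L)
      if (!is.null(q_m)) cav <- cav & (q_m > 1)
      tissue[cav] <- 6L
      labels[cav] <- 0L
    }
  }
  tissue[labels == 1L] <- 3L
  tissue[labels == 2L] <- 4L
  tissue[labels == 3L] <- 5L

  contrast <- .phantom_contrast()
  nvox <- prod(shp)
  data <- array(0, dim = c(4L, shp))
  for (ch in 1:4) {
    base <- contrast[as.integer(tissue), ch]
    data[ch, , , ] <- base
  }
  vol <- multimodal_volume(data, spacing_mm = spec$spacing_mm)
  if (spec$bias_amplitude > 0) {
    vol <- apply_bias_field(vol, spec$bias_amplitude,
                            length_scale_mm = 0.8 * max(shp * spec$spacing_mm),
                            seed = stats::runif(1, 0, .Machine$integer.max))
  }
  if (spec$noise_sigma > 0) {
    noise <- array(stats::rnorm(4 * nvox, sd = spec$noise_sigma),
                   dim = c(4L, shp))
    vol$data <- vol$data + noise
  }
  list(volume = vol, labels = label_map(labels))
}

#' Apply a smooth multiplicative bias field
#'
#' Multiplies every channel by a shared positive low-frequency field with
#' unit mean, emulating scanner intensity inhomogeneity. The field is the
#' exponential of a sum of low-order separable cosine modes, normalized to
#' unit mean; `amplitude` is the peak log-intensity deviation (0.3 means
#' the field spans roughly -26/+35 percent at its extremes).
#'
#' @param vol a [multimodal_volume].
#' @param amplitude non-negative field strength; 0 returns `vol` unchanged.
#' @param length_scale_mm smallest spatial wavelength retained (mm).
#' @param seed integer RNG seed for the mode coefficients.
#' @return A bias-modulated [multimodal_volume].
#' @export
apply_bias_field <- function(vol, amplitude, length_scale_mm = 80, seed = 1L) {
  if (!inherits(vol, "multimodal_volume")) {
    stop_validation("'vol' must be a multimodal_volume", field = "vol")
  }
  check_scalar_num(amplitude, "amplitude", min = 0)
  if (amplitude == 0) return(vol)
  shp <- dim(vol$data)[-1L]
  extent <- shp * vol$spacing_mm
  n_max <- pmax(1L, pmin(4L, as.integer(ceiling(extent / length_scale_mm))))
  with_seed(seed, {
    g <- array(0, dim = shp)
    ax_coord <- lapply(1:3, function(a) (seq_len(shp[a]) - 0.5) / shp[a])
    for (nx in 0:n_max[1]) for (ny in 0:n_max[2]) for (nz in 0:n_max[3]) {
      if (nx + ny + nz == 0 || nx + ny + nz > max(n_max)) next
      coef <- stats::rnorm(1)
      phx <- stats::runif(1, 0, pi); phy <- stats::runif(1, 0, pi)
      phz <- stats::runif(1, 0, pi)
      mode <- outer(outer(cos(pi * nx * ax_coord[[1]] + phx),
                          cos(pi * ny * ax_coord[[2]] + phy), "*"),
                    cos(pi * nz * ax_coord[[3]] + phz), "*")
      g <- g + coef * mode
    }
    g <- g - mean(g)
    g <- g / max(max(abs(g)), .Machine$double.eps)
    field <- exp(amplitude * g)
    field <- field / mean(field)
    out <- vol
    for (ch in 1:4) out$data[ch, , , ] <- out$data[ch, , , ] * field
    out
  })
}

#' Add independent Gaussian noise to every voxel of every channel
#'
#' @param vol a [multimodal_volume].
#' @param sigma non-negative noise standard deviation; 0 is the identity.
#' @param seed integer RNG seed.
#' @return A noise-corrupted [multimodal_volume].
#' @export
add_noise <- function(vol, sigma, seed = 1L) {
  if (!inherits(vol, "multimodal_volume")) {
    stop_validation("'vol' must be a multimodal_volume", field = "vol")
  }
  check_scalar_num(sigma, "sigma", min = 0)
  if (sigma == 0) return(vol)
  with_seed(seed, {
    out <- vol
    out$data <- out$data + array(stats::rnorm(length(vol$data), sd = sigma),
                                 dim = dim(vol$data))
    out
  })
}
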