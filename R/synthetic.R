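# Seeded synthetic H&E-like patch generator.
#
# Forward model: nucleus centers from a Poisson process at a
# class-specific density; a hematoxylin-like concentration high inside
# nuclei; a diffuse eosin-like concentration representing
# cytoplasm/stroma, suppressed inside nuclei (nuclei displace cytoplasm);
# Gaussian concentration noise clipped at zero; Beer-Lambert rendering
# I = background * 10^(-W c) quantized to 8 bits.

#' Parameters of the synthetic patch generator
#'
#' Defaults emulate the visual statistics relevant downstream: two (or
#' eight) classes that differ only in nucleus density and size, rendered
#' through a two-stain Beer-Lambert color model with the standard H&E
#' absorption directions.
#'
#' @param image_size side length in pixels.
#' @param n_classes 2 (benign/malignant) or 8 (subtypes).
#' @param nuclei_density_per_class nuclei per 10^4 px^2, one rate per
#'   class, strictly positive and distinct. Defaults: 40 vs 110 for two
#'   classes (malignant tissue is more nucleus-dense), an increasing
#'   ladder 30..170 for eight.
#' @param nucleus_radius_range `(min, max)` nucleus radius in px.
#' @param stain_matrix 3 x 2 nonnegative matrix with unit-norm columns
#'   (hematoxylin-like, eosin-like).
#' @param nucleus_concentration hematoxylin concentration inside nuclei.
#' @param stroma_concentration diffuse eosin concentration outside nuclei.
#' @param nucleus_stroma_fraction fraction of `stroma_concentration`
#'   remaining inside nuclei.
#' @param concentration_noise_sd sd of additive concentration noise.
#' @param background_intensity 8-bit background (unstained) intensity.
#' @param seed integer seed (per-image seeds are derived from it).
#' @return a `synth_params` list.
#' @export
synth_params <- function(image_size = 224L,
                         n_classes = 2L,
                         nuclei_density_per_class = NULL,
                         nucleus_radius_range = c(3, 6),
                         stain_matrix = default_stain_matrix(),
                         nucleus_concentration = 1.0,
                         stroma_concentration = 0.3,
                         nucleus_stroma_fraction = 0.15,
                         concentration_noise_sd = 0.02,
                         background_intensity = 255L,
                         seed = 0L) {
  if (is.null(nuclei_density_per_class)) {
    nuclei_density_per_class <- if (n_classes == 2) c(40, 110)
      else seq(30, 170, length.out = n_classes)
  }
  stopifnot(length(nuclei_density_per_class) == n_classes,
            all(nuclei_density_per_class >= 0),
            !anyDuplicated(nuclei_density_per_class),
            length(nucleus_radius_range) == 2,
            all(dim(stain_matrix) == c(3, 2)), all(stain_matrix >= 0))
  stopifnot(max(abs(sqrt(colSums(stain_matrix^2)) - 1)) < 1e-6)
  structure(list(image_size = as.integer(image_size), n_classes = as.integer(n_classes),
                 nuclei_density_per_class = nuclei_density_per_class,
                 nucleus_radius_range = nucleus_radius_range,
                 stain_matrix = stain_matrix,
                 nucleus_concentration = nucleus_concentration,
                 stroma_concentration = stroma_concentration,
                 nucleus_stroma_fraction = nucleus_stroma_fraction,
                 concentration_noise_sd = concentration_noise_sd,
                 background_intensity = as.integer(background_intensity),
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Class labels used in the generated directory tree: benign/malignant for
# two classes; the eight BreakHis subtypes (nested under their tumor
# class) for eight.
synth_class_labels <- function(n_classes) {
  if (n_classes == 2) c("benign", "malignant")
  else if (n_classes == 8) ALL_SUBTYPES
  else stopf("n_classes must be 2 or 8, got %d", n_classes)
}

#' Generate one synthetic H&E-like patch
#'
#' @param params a [synth_params()] object.
#' @param class_index 1-based class index in `1..n_classes`.
#' @param seed integer seed; the same `(params, class_index, seed)` always
#'   yields a pixel-identical image.
#' @return list with `image` (`H x W x 3`, values in `[0, 255]`),
#'   `centers` (n x 2 matrix of nucleus centers), `radii`, and
#'   `concentrations` (`H x W x 2` ground-truth stain concentrations).
#' @export
generate_patch <- function(params, class_index, seed = 0L) {
  stopifnot(inherits(params, "synth_params"))
  if (class_index < 1 || class_index > params$n_classes)
    stopf("class_index %d out of range 1..%d", class_index, params$n_classes)
  s <- params$image_size
  with_seed(seed, {
    lambda <- params$nuclei_density_per_class[class_index] * s * s / 1e4
    n_nuclei <- rpois(1, lambda)
    centers <- cbind(runif(n_nuclei, 0.5, s + 0.5), runif(n_nuclei, 0.5, s + 0.5))
    radii <- runif(n_nuclei, params$nucleus_radius_range[1], params$nucleus_radius_range[2])
    nucleus_mask <- matrix(FALSE, s, s)
    for (i in seq_len(n_nuclei)) {
      r <- radii[i]
      h0 <- max(1L, floor(centers[i, 1] - r)); h1 <- min(s, ceiling(centers[i, 1] + r))
      w0 <- max(1L, floor(centers[i, 2] - r)); w1 <- min(s, ceiling(centers[i, 2] + r))
      if (h0 > h1 || w0 > w1) next
      hh <- h0:h1; ww <- w0:w1
      d2 <- outer((hh - centers[i, 1])^2, (ww - centers[i, 2])^2, "+")
      nucleus_mask[hh, ww] <- nucleus_mask[hh, ww] | (d2 <= r^2)
    }
    c_h <- ifelse(nucleus_mask, params$nucleus_concentration, 0)
    c_e <- ifelse(nucleus_mask,
                  params$stroma_concentration * params$nucleus_stroma_fraction,
                  params$stroma_concentration)
    if (params$concentration_noise_sd > 0) {
      c_h <- c_h + matrix(rnorm(s * s, 0, params$concentration_noise_sd), s, s)
      c_e <- c_e + matrix(rnorm(s * s, 0, params$concentration_noise_sd), s, s)
    }
    c_h <- pmax(c_h, 0); c_e <- pmax(c_e, 0)
    conc <- array(c(c_h, c_e), c(s, s, 2))
    od <- array(t(params$stain_matrix %*% rbind(as.vector(c_h), as.vector(c_e))),
                c(s, s, 3))
    image <- pmin(pmax(round(params$background_intensity * 10^(-od)), 0), 255)
    list(image = image, centers = centers, radii = radii, concentrations = conc)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes a BreakHis-style directory tree under `out_dir` (tumor class /
#' subtype when eight classes / pseudo-magnification directories cycling
#' through 40x, 100x, 200x, 400x) with `per_class` PNG patches per class,
#' and returns the matching manifest (equal to re-scanning the tree).
#'
#' @param params a [synth_params()] object.
#' @param per_class images per class.
#' @param out_dir output directory.
#' @return a `dataset_manifest`; the per-image nucleus counts are attached
#'   as `attr(, "n_nuclei")` in manifest record order.
#' @export
generate_dataset <- function(params, per_class, out_dir) {
  stopifnot(per_class >= 1)
  labels <- synth_class_labels(params$n_classes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  paths <- character(0); n_nuclei <- integer(0)
  for (ci in seq_along(labels)) {
    cls <- labels[ci]
    subdir <- if (params$n_classes == 8) file.path(subtype_to_class(cls), cls) else cls
    for (i in seq_len(per_class)) {
      mag <- MAGNIFICATIONS[((i - 1) %% 4) + 1]
      img_seed <- (params$seed * 1009L + ci * 131071L + i * 7919L) %% .Machine$integer.max
      patch <- generate_patch(params, ci, seed = img_seed)
      rel <- file.path(subdir, sprintf("%dx", mag), sprintf("%s_%04d.png", cls, i))
      write_patch(patch$image, file.path(out_dir, rel))
      paths <- c(paths, rel)
      n_nuclei <- c(n_nuclei, nrow(patch$centers))
    }
  }
  ord <- order(paths, method = "radix")
  manifest <- scan_dataset(out_dir, layout = "breakhis")
  attr(manifest, "n_nuclei") <- n_nuclei[ord]
  manifest$provenance <- sprintf("generate_dataset(n_classes=%d, per_class=%d, seed=%d)",
                                 params$n_classes, per_class, params$seed)
  manifest
}
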