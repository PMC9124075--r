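# Exact rotation/flip augmentation. Histopathology patches are
# rotation-invariant, so right-angle rotations and mirror flips expand the
# training set without changing labels; all five operations are pure pixel
# permutations (no interpolation).

AUGMENT_OPS <- c("rot90", "rot180", "rot270", "hflip", "vflip")

#' Apply an exact rotation/flip to an RGB patch
#'
#' `rot90`/`rot270` rotate clockwise/counter-clockwise by 90 degrees
#' (output dimensions swap), `rot180` rotates by 180 degrees, `hflip`
#' mirrors left-right, `vflip` mirrors top-bottom. All are exact pixel
#' permutations.
#'
#' @param image numeric array `H x W x 3`.
#' @param op one of `"rot90"`, `"rot180"`, `"rot270"`, `"hflip"`, `"vflip"`.
#' @return transformed array (`W x H x 3` for `rot90`/`rot270`).
#' @export
augment_image <- function(image, op = AUGMENT_OPS) {
  op <- match.arg(op)
  d <- dim(image)
  switch(op,
    rot90  = aperm(image[rev(seq_len(d[1])), , , drop = FALSE], c(2, 1, 3)),
    rot270 = aperm(image[, rev(seq_len(d[2])), , drop = FALSE], c(2, 1, 3)),
    rot180 = image[rev(seq_len(d[1])), rev(seq_len(d[2])), , drop = FALSE],
    hflip  = image[, rev(seq_len(d[2])), , drop = FALSE],
    vflip  = image[rev(seq_len(d[1])), , , drop = FALSE])
}

#' Expand the training split by augmentation
#'
#' Applies each operation in `ops` to every `split == "train"` record,
#' writing the augmented images under `out_dir` (mirroring each source's
#' relative directory structure) and appending matching records with
#' identical labels. Validation and test records are never augmented — a
#' leakage guard recorded per record in the `op`/`source` provenance
#' columns (`op` is `NA` for originals).
#'
#' @param manifest a `dataset_manifest` with split assignments.
#' @param ops character vector of [augment_image()] operations.
#' @param out_dir directory for augmented images.
#' @return a `dataset_manifest` containing the original records plus
#'   `length(ops)` augmented records per training record.
#' @export
expand_training_set <- function(manifest, ops = AUGMENT_OPS, out_dir) {
  stopifnot(all(ops %in% AUGMENT_OPS))
  r <- manifest$records
  if (!any(r$split == "train")) stopf("manifest has no training split to augment")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  if (is.null(r$op)) r$op <- NA_character_
  if (is.null(r$source)) r$source <- NA_character_
  train_idx <- which(r$split == "train")
  new_rows <- vector("list", length(train_idx) * length(ops))
  k <- 0
  for (i in train_idx) {
    img <- read_patch(r$path[i])
    stem <- sub("\\.[A-Za-z]+$", "", basename(r$path[i]))
    for (op in ops) {
      out <- file.path(out_dir, sprintf("%s_%06d_%s.png", stem, i, op))
      write_patch(augment_image(img, op), out)
      row <- r[i, , drop = FALSE]
      row$path <- out
      row$op <- op
      row$source <- r$path[i]
      k <- k + 1
      new_rows[[k]] <- row
    }
  }
  out_rec <- rbind(r, do.call(rbind, new_rows))
  rownames(out_rec) <- NULL
  new_manifest(out_rec, seed = manifest$seed,
               provenance = sprintf("%s | augment(%s)", manifest$provenance,
                                    paste(ops, collapse = ",")))
}
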