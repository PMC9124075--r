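# Dataset manifests: scanning class-labelled image trees (BreakHis layout),
# subset sampling, and stratified train/val/test splitting.

BENIGN_SUBTYPES <- c("adenosis", "fibroadenoma", "tubular_adenoma", "phyllodes_tumor")
MALIGNANT_SUBTYPES <- c("ductal", "lobular", "mucinous", "papillary")
ALL_SUBTYPES <- c(BENIGN_SUBTYPES, MALIGNANT_SUBTYPES)
MAGNIFICATIONS <- c(40L, 100L, 200L, 400L)

subtype_to_class <- function(subtype) {
  ifelse(subtype %in% BENIGN_SUBTYPES, "benign",
         ifelse(subtype %in% MALIGNANT_SUBTYPES, "malignant", NA_character_))
}

new_manifest <- function(records, seed = NA_integer_, provenance = "") {
  stopifnot(is.data.frame(records))
  need <- c("path", "tumor_class", "subtype", "magnification", "split")
  missing_cols <- setdiff(need, names(records))
  for (m in missing_cols) records[[m]] <- if (m == "magnification") NA_integer_ else NA_character_
  if (anyDuplicated(records$path)) stopf("manifest contains duplicate paths")
  structure(list(records = records, seed = as.integer(seed), provenance = provenance),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  r <- x$records
  cat(sprintf("<dataset_manifest> %d records\n", nrow(r)))
  if (nrow(r)) {
    cat("  tumor_class:", paste(sprintf("%s=%d", names(table(r$tumor_class)),
                                        table(r$tumor_class)), collapse = " "), "\n")
    if (any(!is.na(r$subtype)))
      cat("  subtypes:", length(unique(stats::na.omit(r$subtype))), "\n")
    cat("  splits:", paste(sprintf("%s=%d", names(table(r$split)), table(r$split)),
                           collapse = " "), "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of records in a manifest
#' @param manifest a `dataset_manifest`.
#' @return integer record count.
#' @export
manifest_size <- function(manifest) nrow(manifest$records)

#' Scan a class-labelled image directory tree into a manifest
#'
#' Walks `root_dir` recursively and builds one record per image file
#' (PNG/JPEG). With `layout = "breakhis"` the directory components between
#' the root and the file are interpreted as tumor class
#' (`benign`/`malignant`), subtype (one of the eight BreakHis subtypes) and
#' magnification (`40x`, `100x`, `200x`, `400x`), in any nesting order;
#' components that parse as none of these leave the corresponding fields
#' unknown (`NA`) with a warning. With `layout = "flat_by_class"` the
#' immediate subdirectory name is the class label (either a tumor class or
#' a subtype, from which the tumor class is derived).
#'
#' Records are ordered lexicographically (byte order) by path, so the scan
#' is byte-identical across runs and platforms.
#'
#' @param root_dir directory to scan.
#' @param layout `"breakhis"` or `"flat_by_class"`.
#' @return a `dataset_manifest` with all records `split = "unassigned"`.
#' @export
scan_dataset <- function(root_dir, layout = c("breakhis", "flat_by_class")) {
  layout <- match.arg(layout)
  if (!dir.exists(root_dir)) stopf("dataset root does not exist: %s", root_dir)
  files <- list.files(root_dir, pattern = "\\.(png|jpe?g)$", recursive = TRUE,
                      ignore.case = TRUE, full.names = FALSE)
  files <- sort(files, method = "radix")
  n <- length(files)
  rec <- data.frame(path = file.path(root_dir, files),
                    tumor_class = rep(NA_character_, n),
                    subtype = rep(NA_character_, n),
                    magnification = rep(NA_integer_, n),
                    split = rep("unassigned", n),
                    stringsAsFactors = FALSE)
  unparsed <- character(0)
  for (i in seq_len(n)) {
    comps <- strsplit(files[i], "/", fixed = TRUE)[[1]]
    dirs <- comps[-length(comps)]
    if (layout == "flat_by_class") dirs <- dirs[seq_len(min(1, length(dirs)))]
    for (d in dirs) {
      dl <- tolower(d)
      if (dl %in% c("benign", "malignant")) {
        rec$tumor_class[i] <- dl
      } else if (dl %in% ALL_SUBTYPES) {
        rec$subtype[i] <- dl
        if (is.na(rec$tumor_class[i])) rec$tumor_class[i] <- subtype_to_class(dl)
      } else if (grepl("^[0-9]+x$", dl)) {
        mag <- as.integer(sub("x$", "", dl))
        if (mag %in% MAGNIFICATIONS) rec$magnification[i] <- mag
        else unparsed <- c(unparsed, d)
      } else {
        unparsed <- c(unparsed, d)
      }
    }
  }
  if (length(unparsed))
    warnf("unparseable directory component(s) kept with unknown fields: %s",
          paste(unique(unparsed), collapse = ", "))
  new_manifest(rec, provenance = sprintf("scan_dataset(%s, layout=%s)", root_dir, layout))
}

#' Sample a fixed-size per-class subset
#'
#' Uniform sampling without replacement, reproducible from `seed`:
#' `task = "binary"` draws `per_class` records per tumor class (benign and
#' malignant); `task = "multiclass"` draws `per_class` per subtype (eight
#' classes). The defaults elsewhere in the package follow the standard
#' protocol of 2000 per tumor class and 400 per subtype.
#'
#' @param manifest a `dataset_manifest`.
#' @param task `"binary"` or `"multiclass"`.
#' @param per_class records to draw per class.
#' @param seed integer seed for the draw.
#' @return a `dataset_manifest` with `2 * per_class` (binary) or
#'   `8 * per_class` (multiclass) records, ordered by path.
#' @export
sample_subset <- function(manifest, task = c("binary", "multiclass"), per_class, seed = 0L) {
  task <- match.arg(task)
  r <- manifest$records
  label <- if (task == "binary") r$tumor_class else r$subtype
  if (anyNA(label)) stopf("manifest has records with unknown %s labels",
                          if (task == "binary") "tumor_class" else "subtype")
  keep <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(label))) {
      idx <- which(label == cl)
      if (length(idx) < per_class)
        stopf("class '%s' has only %d records; %d requested", cl, length(idx), per_class)
      keep <- c(keep, if (length(idx) == per_class) idx else sample(idx, per_class))
    }
  })
  out <- r[sort(keep), , drop = FALSE]
  out <- out[order(out$path, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  new_manifest(out, seed = seed,
               provenance = sprintf("sample_subset(task=%s, per_class=%d, seed=%d)",
                                    task, per_class, seed))
}

# Largest-remainder apportionment of n into parts proportional to ratios.
apportion <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign stratified train/validation/test splits
#'
#' Every record is assigned to exactly one of train/val/test. Assignment is
#' stratified by class label — the subtype when every record has one,
#' otherwise the tumor class — and per-class counts follow the requested
#' ratios under largest-remainder rounding, so the canonical 7:1:2 split of
#' 4000 records yields exactly 2800/400/800. Reproducible from `seed`.
#'
#' @param manifest a `dataset_manifest`.
#' @param ratios numeric length-3 vector `(train, val, test)` summing to 1.
#' @param seed integer seed for the shuffle within each stratum.
#' @return the manifest with `split` populated.
#' @export
make_splits <- function(manifest, ratios = c(0.7, 0.1, 0.2), seed = 0L) {
  stopifnot(length(ratios) == 3)
  if (abs(sum(ratios) - 1) > 1e-9) stopf("split ratios must sum to 1")
  r <- manifest$records
  if (!nrow(r)) stopf("cannot split an empty manifest")
  strata <- if (!anyNA(r$subtype)) r$subtype else r$tumor_class
  if (anyNA(strata)) stopf("manifest has records with unknown class labels")
  split <- rep(NA_character_, nrow(r))
  with_seed(seed, {
    for (cl in sort(unique(strata))) {
      idx <- which(strata == cl)
      counts <- apportion(length(idx), ratios)
      if (any(counts == 0 & ratios > 0))
        stopf("class '%s' has too few records (%d) for a %s split",
              cl, length(idx), paste(ratios, collapse = ":"))
      shuffled <- if (length(idx) > 1) sample(idx) else idx
      split[shuffled] <- rep(c("train", "val", "test"), times = counts)
    }
  })
  r$split <- split
  new_manifest(r, seed = seed,
               provenance = sprintf("%s | make_splits(%s, seed=%d)", manifest$provenance,
                                    paste(ratios, collapse = ":"), seed))
}

#' Write a manifest to CSV
#' @param manifest a `dataset_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(manifest$records, path, row.names = FALSE)
  invisible(path)
}

#' Read a manifest from CSV
#' @param path CSV path written by [write_manifest()].
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(path = "character", tumor_class = "character",
                                 subtype = "character", split = "character"))
  rec$magnification <- as.integer(rec$magnification)
  new_manifest(rec, provenance = sprintf("read_manifest(%s)", path))
}

#' Subset a manifest to one split
#' @param manifest a `dataset_manifest`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return a `dataset_manifest` restricted to the split.
#' @export
manifest_split <- function(manifest, split) {
  out <- manifest$records[manifest$records$split == split, , drop = FALSE]
  rownames(out) <- NULL
  new_manifest(out, seed = manifest$seed,
               provenance = sprintf("%s | split=%s", manifest$provenance, split))
}
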