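# Shared fixtures and independent oracles, all built in code at test time.

ns <- asNamespace("mfscnet")

# Brute-force pair-enumeration AUC: the tie-corrected Mann-Whitney count
# over all positive/negative pairs, written as the explicit double loop.
auc_pair_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  wins <- 0
  for (a in sp) for (b in sn) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(sp) * length(sn))
}

# Largest-remainder apportionment, re-derived independently.
apportion_oracle <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  left <- n - sum(base)
  ord <- order(exact - base, decreasing = TRUE)
  if (left > 0) base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  base
}

# A small on-disk synthetic dataset, generated once per test run.
local_synth_dataset <- local({
  cache <- new.env()
  function(n_classes = 2L, per_class = 6L, image_size = 32L, seed = 11L) {
    key <- paste(n_classes, per_class, image_size, seed, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("mfscnet_fix_", key))
      unlink(dir, recursive = TRUE)
      params <- synth_params(image_size = image_size, n_classes = n_classes, seed = seed)
      cache[[key]] <- list(manifest = generate_dataset(params, per_class, dir),
                           params = params, dir = dir)
    }
    cache[[key]]
  }
})

# In-memory manifest of fake records (no files), for split/sampling tests.
fake_manifest <- function(per_class, classes = c("benign", "malignant")) {
  rec <- do.call(rbind, lapply(classes, function(cl) {
    subtype <- if (cl %in% c("benign", "malignant")) NA_character_ else cl
    data.frame(path = sprintf("%s/img_%05d.png", cl, seq_len(per_class)),
               tumor_class = if (cl %in% c("benign", "malignant")) cl
                             else ns$subtype_to_class(cl),
               subtype = subtype, magnification = NA_integer_,
               split = "unassigned", stringsAsFactors = FALSE)
  }))
  ns$new_manifest(rec)
}

seeded_image <- function(h = 8, w = 8, seed = 5) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

tiny_arch <- function(variant = "A", num_classes = 2L)
  architecture_spec(variant, num_classes = num_classes, growth_rate = 4L,
                    block_config = c(1L, 1L, 1L, 1L), se_reduction = 4L,
                    input_size = 32L, num_init_features = 8L)
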