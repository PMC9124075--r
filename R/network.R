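# The MFSCNet architecture family: a DenseNet121-style backbone with
# optimized squeeze-and-excitation (SE) blocks at configurable insertion
# points.
#
#   baseline  - plain DenseNet121 (stem, four dense blocks, three
#               transitions, final BN-ReLU, global average pool, linear
#               classifier)
#   variant C - one SE block after each dense block output
#               (channels 256, 512, 1024, 1024 at the defaults)
#   variant B - one SE block after each transition output (128, 256, 512)
#   variant A - SE blocks at all seven positions (union of B and C)
#
# The SE parameter overhead is therefore additive by construction:
# params(A) - params(baseline) =
#   [params(B) - params(baseline)] + [params(C) - params(baseline)],
# and is independent of the class count, for every configuration.

#' Declare an MFSCNet architecture variant
#'
#' @param variant `"baseline"`, `"A"`, `"B"` or `"C"` (see package docs:
#'   A = SE after every dense block and transition, B = after transitions
#'   only, C = after dense blocks only).
#' @param num_classes number of output classes.
#' @param growth_rate channels appended per dense-block layer (k).
#' @param block_config layer counts of the four dense blocks.
#' @param compression transition-layer channel compression in (0, 1].
#' @param se_reduction SE bottleneck reduction ratio r.
#' @param se_squeeze `"optimized"` (per-channel global mean, local-pooled
#'   max and spatial variance; 3C squeeze vector) or `"plain"` (global
#'   mean only; C squeeze vector).
#' @param head_width optional width of an extra fully connected + ReLU
#'   layer between the pooled features and the classifier (`NULL` for the
#'   native direct classifier).
#' @param input_size expected input side length in pixels.
#' @param num_init_features stem convolution output channels.
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(variant = c("baseline", "A", "B", "C"),
                              num_classes = 2L,
                              growth_rate = 32L,
                              block_config = c(6L, 12L, 24L, 16L),
                              compression = 0.5,
                              se_reduction = 16L,
                              se_squeeze = c("optimized", "plain"),
                              head_width = NULL,
                              input_size = 224L,
                              num_init_features = 64L) {
  variant <- match.arg(variant)
  se_squeeze <- match.arg(se_squeeze)
  stopifnot(length(block_config) == 4, all(block_config >= 0),
            compression > 0, compression <= 1, se_reduction >= 1,
            num_classes >= 2)
  structure(list(variant = variant, num_classes = as.integer(num_classes),
                 growth_rate = as.integer(growth_rate),
                 block_config = as.integer(block_config),
                 compression = compression,
                 se_reduction = as.integer(se_reduction),
                 se_squeeze = se_squeeze,
                 head_width = if (is.null(head_width)) NULL else as.integer(head_width),
                 input_size = as.integer(input_size),
                 num_init_features = as.integer(num_init_features)),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> variant %s, %d classes, k=%d, blocks (%s), r=%d, %s squeeze\n",
              x$variant, x$num_classes, x$growth_rate,
              paste(x$block_config, collapse = ","), x$se_reduction, x$se_squeeze))
  invisible(x)
}

#' Serialize / read an architecture spec as JSON
#' @param spec an `architecture_spec`.
#' @param path JSON file path.
#' @return `path` invisibly (write); an `architecture_spec` (read).
#' @export
write_architecture_spec <- function(spec, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_architecture_spec
#' @export
read_architecture_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  architecture_spec(variant = x$variant, num_classes = x$num_classes,
                    growth_rate = x$growth_rate, block_config = x$block_config,
                    compression = x$compression, se_reduction = x$se_reduction,
                    se_squeeze = x$se_squeeze, head_width = x$head_width,
                    input_size = x$input_size, num_init_features = x$num_init_features)
}

#' Build a network from an architecture spec
#'
#' Constructs the module tree with seeded He-normal initialization. The
#' stem is a 7x7 stride-2 convolution to `num_init_features` channels,
#' BN-ReLU, and a 3x3 stride-2 max pool (padding 1); dense blocks and
#' transitions follow `block_config`/`compression`; SE blocks are inserted
#' according to the variant; the head is final BN-ReLU, global average
#' pooling, an optional `head_width` FC+ReLU, and the class-score linear
#' layer.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed for weight initialization.
#' @return a `network_model`: list with `modules` (module tree), `spec`,
#'   and `parameter_count`.
#' @export
build_network <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "architecture_spec"))
  k <- spec$growth_rate
  optimized <- spec$se_squeeze == "optimized"
  se_after_blocks <- spec$variant %in% c("A", "C")
  se_after_transitions <- spec$variant %in% c("A", "B")
  modules <- with_seed(seed, {
    layers <- list(layer_conv(3L, spec$num_init_features, 7L, stride = 2L, pad = 3L),
                   layer_bn(spec$num_init_features), layer_relu(),
                   layer_maxpool(3L, 2L, 1L))
    ch <- spec$num_init_features
    for (b in seq_len(4L)) {
      blk <- dense_block_module(ch, spec$block_config[b], k)
      ch <- blk$out_ch
      layers <- c(layers, list(blk))
      if (se_after_blocks)
        layers <- c(layers, list(layer_se(ch, spec$se_reduction, optimized)))
      if (b < 4L) {
        tr <- transition_module(ch, spec$compression)
        ch <- tr$out_ch
        layers <- c(layers, list(tr))
        if (se_after_transitions)
          layers <- c(layers, list(layer_se(ch, spec$se_reduction, optimized)))
      }
    }
    layers <- c(layers, list(layer_bn(ch), layer_relu(), layer_gap()))
    if (!is.null(spec$head_width)) {
      layers <- c(layers, list(layer_fc(ch, spec$head_width), layer_relu()))
      ch <- spec$head_width
    }
    layers <- c(layers, list(layer_fc(ch, spec$num_classes)))
    layer_seq(layers, name = "network")
  })
  model <- structure(list(modules = modules, spec = spec, seed = as.integer(seed),
                          classes = NULL),
                     class = "network_model")
  model$parameter_count <- count_parameters(model)
  model
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> variant %s, %d classes, %s trainable parameters\n",
              x$spec$variant, x$spec$num_classes,
              format(x$parameter_count, big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable array: convolution kernels,
#' fully connected weights, biases, and BN scale/shift (running statistics
#' are buffers, not parameters). Accepts a built `network_model` or any
#' internal module/layer.
#'
#' @param model a `network_model` or module.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  mod <- if (inherits(model, "network_model")) model$modules else model
  sum(vapply(flatten_params(mod), length, numeric(1)))
}

#' Forward pass: class scores for a batch of images
#'
#' @param model a `network_model`.
#' @param images list of `H x W x 3` arrays with values in `[0, 1]`, or a
#'   single such array.
#' @param training logical; use batch statistics (and update running
#'   statistics) in BN layers.
#' @return matrix `N x num_classes` of unnormalized class scores.
#' @export
network_forward <- function(model, images, training = FALSE) {
  if (is.array(images)) images <- list(images)
  f <- fm_from_images(images)
  net_forward(model$modules, f, training = training)$out$x
}

#' Softmax over class scores
#' @param scores matrix `N x K` of unnormalized scores.
#' @return matrix of row-wise softmax probabilities.
#' @export
softmax <- function(scores) {
  z <- exp(scores - apply(scores, 1, max))
  z / rowSums(z)
}

#' Remove all SE blocks from a model
#'
#' Structural surgery: drops every SE module from the tree, leaving the
#' shared backbone weights untouched. Stripping variant A/B/C yields a
#' model whose forward pass equals the baseline's with identical weights.
#'
#' @param model a `network_model`.
#' @return the model without SE blocks.
#' @export
strip_se_blocks <- function(model) {
  drop_se <- function(mod) {
    if (!is.null(mod$children)) {
      kept <- Filter(function(ch) ch$type != "se", mod$children)
      mod$children <- lapply(kept, drop_se)
    }
    mod
  }
  model$modules <- drop_se(model$modules)
  model$spec$variant <- "baseline"
  model$parameter_count <- count_parameters(model)
  model
}

# --- functional single-map operations -----------------------------------
# These expose the same kernels used inside build_network on a single
# H x W x C feature map (an array), for direct inspection and testing.

#' Run a dense block on a feature map
#'
#' Each of `n_layers` layers computes BN-ReLU-1x1 conv (4k channels)-
#' BN-ReLU-3x3 conv (k channels) on the concatenation of the block input
#' and all previous layer outputs; the output is the full concatenation,
#' with `C_in + n_layers * k` channels and unchanged spatial size.
#'
#' @param x feature map, `H x W x C` array.
#' @param n_layers number of layers in the block.
#' @param k growth rate.
#' @param seed seed for the block's (random) weights.
#' @return `H x W x (C + n_layers * k)` array.
#' @export
dense_block_forward <- function(x, n_layers, k, seed = 1L) {
  blk <- with_seed(seed, dense_block_module(dim(x)[3], n_layers, k))
  fm_to_array(net_forward(blk, fm_from_array(x), training = FALSE)$out)
}

#' Run a transition layer on a feature map
#'
#' BN-ReLU, 1x1 convolution to `floor(C * compression)` channels, then
#' 2x2 stride-2 average pooling (spatial dimensions halve, flooring odd
#' sizes).
#'
#' @param x feature map, `H x W x C` array.
#' @param compression channel compression fraction in (0, 1].
#' @param seed seed for the transition's weights.
#' @return pooled array with `floor(C * compression)` channels.
#' @export
transition_forward <- function(x, compression = 0.5, seed = 1L) {
  tr <- with_seed(seed, transition_module(dim(x)[3], compression))
  fm_to_array(net_forward(tr, fm_from_array(x), training = FALSE)$out)
}

#' Squeeze statistics of a feature map
#'
#' The optimized squeeze descriptor: per channel, the global spatial mean,
#' the maximum of the 2x2-average-pooled (stride 2) map, and the
#' population spatial variance (divisor `H * W`). With
#' `optimized = FALSE`, only the global mean (the plain SE squeeze).
#'
#' @param x feature map, `H x W x C` array.
#' @param optimized logical; return the three-statistic descriptor.
#' @return `C x 3` matrix (columns `global_mean`, `local_max`, `variance`)
#'   or a length-C vector of means.
#' @export
squeeze_statistics <- function(x, optimized = TRUE) {
  stopifnot(length(dim(x)) == 3)
  C <- dim(x)[3]
  se <- layer_se(C, r = max(1L, C), optimized = optimized, zero_init = TRUE)
  cache <- net_forward(se, fm_from_array(x), training = FALSE)$cache
  if (!optimized) return(as.numeric(cache$S))
  S <- cache$S
  out <- cbind(global_mean = S[1, seq_len(C)],
               local_max = S[1, C + seq_len(C)],
               variance = S[1, 2 * C + seq_len(C)])
  rownames(out) <- NULL
  out
}

#' Create a standalone SE block
#'
#' @param channels number of feature-map channels C.
#' @param r bottleneck reduction ratio (clamped to keep C/r >= 1, with a
#'   warning).
#' @param optimized use the three-statistic squeeze (3C input) rather than
#'   the mean-only squeeze (C input).
#' @param seed seed for the two FC layers' weights.
#' @param zero_init zero all weights (every gate becomes 0.5).
#' @return an SE block usable with [se_gate()] and [apply_se_block()].
#' @export
se_block <- function(channels, r = 16L, optimized = TRUE, seed = 1L, zero_init = FALSE) {
  with_seed(seed, layer_se(channels, r, optimized, zero_init = zero_init))
}

#' Excitation gates from squeeze statistics
#'
#' `gates = sigmoid(FC2(ReLU(FC1(stats))))`, with FC1 mapping the (3C or
#' C)-dimensional squeeze descriptor to the C/r bottleneck and FC2 back to
#' C; both layers carry biases. Gates are strictly inside (0, 1).
#'
#' @param stats a `C x 3` matrix from [squeeze_statistics()] (or a
#'   length-C mean vector for a plain block).
#' @param block an [se_block()] with matching channel count and squeeze.
#' @return numeric vector of C gates in (0, 1).
#' @export
se_gate <- function(stats, block) {
  stopifnot(block$type == "se")
  S <- if (is.matrix(stats)) matrix(as.vector(stats), 1) else matrix(stats, 1)
  stopifnot(ncol(S) == nrow(block$params$W1))
  z1 <- S %*% block$params$W1 + matrix(block$params$b1, 1)
  a1 <- z1 * (z1 > 0)
  z2 <- a1 %*% block$params$W2 + matrix(block$params$b2, 1)
  as.numeric(1 / (1 + exp(-z2)))
}

#' Apply an SE block to a feature map
#'
#' Rescales every channel by its excitation gate:
#' `out[h, w, c] = x[h, w, c] * gate[c]`. Shape is preserved.
#'
#' @param x feature map, `H x W x C` array.
#' @param block an [se_block()] built for C channels.
#' @return gated `H x W x C` array.
#' @export
apply_se_block <- function(x, block) {
  stopifnot(block$type == "se")
  if (dim(x)[3] != block$ch)
    stopf("SE block built for %d channels; feature map has %d", block$ch, dim(x)[3])
  fm_to_array(net_forward(block, fm_from_array(x), training = FALSE)$out)
}
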