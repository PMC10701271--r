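#' Dose-prediction model configuration
#'
#' Architecture of the 3D dose-prediction networks. Both variants are
#' encoder-decoder UNets whose filter count starts at `base_filters` and
#' doubles after each 2x2x2 max pooling, peaking at
#' `base_filters * 2^depth` in the bottleneck. `unet` runs a single
#' encoder over the structure channels (optionally with CT appended);
#' `attunet` runs separate structure and CT encoders fused at the
#' bottleneck by multi-head cross attention (Query from structure
#' features, Key/Value from CT features).
#'
#' @param variant `"unet"` or `"attunet"`.
#' @param depth number of pooling levels.
#' @param base_filters first-level filter count.
#' @param n_heads,head_dim attention heads and per-head feature dimension
#'   (attunet only); the attention embedding width is their product.
#' @param scale_attention divide attention scores by `sqrt(head_dim)`
#'   (numerically stable default; set `FALSE` for raw dot products).
#' @param include_ct for `unet`, append the CT channel to the input
#'   (default `FALSE`: structures only).
#' @param attn_residual add the structure bottleneck features back onto
#'   the attention output before decoding.
#' @return A `model_config` list, with derived `bottleneck_filters` and
#'   `embed_dim`.
#' @export
model_config <- function(variant = c("unet", "attunet"), depth = 4,
                         base_filters = 32, n_heads = 8, head_dim = 64,
                         scale_attention = TRUE, include_ct = FALSE,
                         attn_residual = TRUE) {
  variant <- match.arg(variant)
  stopifnot(depth >= 1, base_filters >= 1, n_heads >= 1, head_dim >= 1)
  structure(list(variant = variant, depth = depth,
                 base_filters = base_filters,
                 bottleneck_filters = base_filters * 2^depth,
                 n_heads = n_heads, head_dim = head_dim,
                 embed_dim = n_heads * head_dim,
                 conv_kernel = c(3, 3, 3), pool = c(2, 2, 2),
                 scale_attention = scale_attention,
                 include_ct = include_ct, attn_residual = attn_residual),
            class = "model_config")
}

#' Full-resolution model preset
#'
#' Depth 4, 32 base filters (bottleneck 512), 8 attention heads of 64
#' dimensions — the configuration matched to 224 x 224 x 32 inputs.
#' Intended for GPU-class hardware; see [model_config_desk()] for the
#' CPU-scale default.
#'
#' @param variant `"unet"` or `"attunet"`.
#' @return A `model_config`.
#' @export
model_config_full <- function(variant = c("unet", "attunet")) {
  model_config(match.arg(variant), depth = 4, base_filters = 32,
               n_heads = 8, head_dim = 64)
}

#' Desk-scale model preset
#'
#' Depth 3, 16 base filters (bottleneck 128), 4 attention heads of 32
#' dimensions, sized for CPU experimentation on 96 x 96 x 32 grids.
#'
#' @param variant `"unet"` or `"attunet"`.
#' @return A `model_config`.
#' @export
model_config_desk <- function(variant = c("unet", "attunet")) {
  model_config(match.arg(variant), depth = 3, base_filters = 16,
               n_heads = 4, head_dim = 32)
}

conv_block <- function(cin, cout) {
  list(nn_conv3d(cin, cout), nn_batchnorm(cout), nn_relu(),
       nn_conv3d(cout, cout), nn_batchnorm(cout), nn_relu())
}

#' Build a dose-prediction model
#'
#' Instantiates the network of a [model_config()] with Kaiming-initialized
#' weights. The decoder mirrors the encoder with 2x nearest-neighbour
#' upsampling and skip connections (from the structure encoder for
#' `attunet`); a pointwise convolution produces the single dose channel at
#' input resolution.
#'
#' @param config a [model_config()].
#' @param struct_channels number of structure input channels (1 for the
#'   integer-label encoding).
#' @param seed RNG seed for weight initialization.
#' @return A `dose_model` environment.
#' @export
build_model <- function(config, struct_channels = 1L, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$depth
  F0 <- config$base_filters
  md <- new.env(parent = emptyenv())
  md$config <- config
  md$struct_channels <- struct_channels
  lv_filters <- F0 * 2^(seq_len(L) - 1)
  mk_encoder <- function(cin1) {
    enc <- vector("list", L)
    pool <- vector("list", L)
    for (l in seq_len(L)) {
      cin <- if (l == 1) cin1 else lv_filters[l - 1]
      enc[[l]] <- conv_block(cin, lv_filters[l])
      pool[[l]] <- nn_maxpool()
    }
    list(enc = enc, pool = pool)
  }
  cb <- config$bottleneck_filters
  if (config$variant == "unet") {
    cin1 <- struct_channels + as.integer(config$include_ct)
    e <- mk_encoder(cin1)
    md$enc_s <- e$enc; md$pool_s <- e$pool
    md$bott_s <- conv_block(lv_filters[L], cb)
  } else {
    e <- mk_encoder(struct_channels)
    md$enc_s <- e$enc; md$pool_s <- e$pool
    md$bott_s <- conv_block(lv_filters[L], cb)
    ec <- mk_encoder(1L)
    md$enc_c <- ec$enc; md$pool_c <- ec$pool
    md$bott_c <- conv_block(lv_filters[L], cb)
    md$mha <- nn_mha(cb, cb, config$n_heads, config$head_dim, cb,
                     scale = config$scale_attention)
  }
  md$up <- vector("list", L)
  md$dec <- vector("list", L)
  for (l in seq_len(L)) {
    md$up[[l]] <- nn_upsample()
    c_below <- if (l == L) cb else lv_filters[l + 1]
    md$dec[[l]] <- conv_block(c_below + lv_filters[l], lv_filters[l])
  }
  md$head <- nn_conv3d(F0, 1L, ksize = 1L)
  layers <- c(unlist(md$enc_s, recursive = FALSE),
              md$bott_s, unlist(md$dec, recursive = FALSE),
              list(md$head))
  if (config$variant == "attunet")
    layers <- c(layers, unlist(md$enc_c, recursive = FALSE), md$bott_c,
                list(md$mha))
  md$layers <- Filter(function(ly) length(ly$params) > 0, layers)
  class(md) <- "dose_model"
  md
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf(
    "<dose_model> %s, depth %d, filters %d..%d, %s parameters\n",
    x$config$variant, x$config$depth, x$config$base_filters,
    x$config$bottleneck_filters, format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `dose_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(ly)
    sum(vapply(ly$params, length, numeric(1))), numeric(1)))
}

split_input_channels <- function(md, x) {
  nc <- dim(x)[4]
  sc <- md$struct_channels
  if (md$config$variant == "unet") {
    xs <- if (md$config$include_ct) x
    else x[, , , seq_len(sc), drop = FALSE]
    list(xs = xs, xc = NULL)
  } else {
    list(xs = x[, , , seq_len(sc), drop = FALSE],
         xc = x[, , , nc, drop = FALSE])
  }
}

model_forward <- function(md, x, train = TRUE) {
  d <- dim(x)
  L <- md$config$depth
  if (any(d[1:3] %% 2^L != 0))
    stop(sprintf(
      "input spatial shape %s is not divisible by 2^depth = %d",
      paste(d[1:3], collapse = "x"), 2^L))
  sp <- split_input_channels(md, x)
  skips <- vector("list", L)
  h <- sp$xs
  for (l in seq_len(L)) {
    h <- seq_forward(md$enc_s[[l]], h, train)
    skips[[l]] <- h
    h <- md$pool_s[[l]]$forward(h, train)
  }
  h <- seq_forward(md$bott_s, h, train)
  if (md$config$variant == "attunet") {
    hc <- sp$xc
    for (l in seq_len(L)) {
      hc <- seq_forward(md$enc_c[[l]], hc, train)
      hc <- md$pool_c[[l]]$forward(hc, train)
    }
    hc <- seq_forward(md$bott_c, hc, train)
    fused <- md$mha$forward(h, hc, train)
    h <- if (md$config$attn_residual) fused + h else fused
  }
  md$cat_c1 <- integer(L)
  for (l in rev(seq_len(L))) {
    h <- md$up[[l]]$forward(h, train)
    md$cat_c1[l] <- dim(h)[4]
    h <- array(c(h, skips[[l]]), c(dim(h)[1:3], dim(h)[4] +
                                     dim(skips[[l]])[4]))
    h <- seq_forward(md$dec[[l]], h, train)
  }
  md$head$forward(h, train)
}

model_backward <- function(md, dy) {
  L <- md$config$depth
  dy <- md$head$backward(dy)
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    dy <- seq_backward(md$dec[[l]], dy)
    c1 <- md$cat_c1[l]
    d_up <- dy[, , , seq_len(c1), drop = FALSE]
    dskips[[l]] <- dy[, , , -seq_len(c1), drop = FALSE]
    dy <- md$up[[l]]$backward(d_up)
  }
  if (md$config$variant == "attunet") {
    gr <- md$mha$backward(dy)
    ds <- gr$ds
    if (md$config$attn_residual) ds <- ds + dy
    dc <- seq_backward(md$bott_c, gr$dct)
    for (l in rev(seq_len(L))) {
      dc <- md$pool_c[[l]]$backward(dc)
      dc <- seq_backward(md$enc_c[[l]], dc)
    }
    dy <- ds
  }
  dy <- seq_backward(md$bott_s, dy)
  for (l in rev(seq_len(L))) {
    dy <- md$pool_s[[l]]$backward(dy)
    dy <- dy + dskips[[l]]
    dy <- seq_backward(md$enc_s[[l]], dy)
  }
  invisible(dy)
}

#' Fuse structure and CT feature blocks with multi-head attention
#'
#' Treats every spatial position as one token; the Query comes from the
#' structure features and the Key/Value from the CT features. Scores are
#' softmax-normalized dot products (scaled by `1/sqrt(head_dim)` unless
#' disabled); heads are concatenated and linearly projected. Exposed as a
#' stand-alone operation so the fusion arithmetic can be exercised (and
#' checked by hand) outside a full model.
#'
#' @param struct_feats,ct_feats arrays `(X, Y, Z, C)` sharing spatial
#'   shape.
#' @param n_heads,head_dim attention geometry.
#' @param weights optional named list `Wq, Wk, Wv, Wo, bo` of projection
#'   matrices; random Kaiming draws otherwise.
#' @param scale divide scores by `sqrt(head_dim)`.
#' @return Array `(X, Y, Z, ncol(Wo))`.
#' @export
attention_fuse <- function(struct_feats, ct_feats, n_heads, head_dim,
                           weights = NULL, scale = TRUE) {
  cq <- dim(struct_feats)[4]
  ckv <- dim(ct_feats)[4]
  c_out <- if (!is.null(weights)) ncol(weights$Wo) else cq
  ly <- nn_mha(cq, ckv, n_heads, head_dim, c_out, scale = scale)
  if (!is.null(weights)) {
    for (nm in intersect(names(weights), names(ly$params)))
      ly$params[[nm]] <- weights[[nm]]
  }
  ly$forward(struct_feats, ct_feats, train = FALSE)
}

#' Training configuration
#'
#' Mean-squared-error objective, Adam optimizer, plateau learning-rate
#' decay and early stopping on the validation loss.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size cases per gradient step (default 2).
#' @param max_epochs training ceiling (default 1000).
#' @param plateau_factor divide the learning rate by this on plateau.
#' @param plateau_patience epochs without validation improvement before
#'   decaying the learning rate.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 100).
#' @param val_fraction fraction of the dataset held out for validation
#'   (default 0.2; with one training case, validation falls back to the
#'   training loss).
#' @param seed RNG seed for the split and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 2,
                         max_epochs = 1000, plateau_factor = 10,
                         plateau_patience = 50,
                         early_stop_patience = 100, val_fraction = 0.2,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1,
            early_stop_patience < max_epochs)
  structure(list(loss = "mse", learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 early_stop_patience = early_stop_patience,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

case_target <- function(tc) {
  if (is.null(tc$target)) stop("tensor case has no dose target")
  array(tc$target, c(dim(tc$target), 1L))
}

#' Train a dose-prediction model
#'
#' Deterministic given the seed: the validation split, shuffling and all
#' weight updates derive from `cfg$seed`. Returns the per-epoch training
#' and validation losses; training stops early when the validation loss
#' has not improved for `early_stop_patience` epochs, and the learning
#' rate decays by `plateau_factor` on shorter plateaus.
#'
#' @param model a `dose_model` from [build_model()].
#' @param dataset list of `tensor_case`s with targets.
#' @param cfg a [train_config()].
#' @return List with `model` (trained, same environment) and `history`
#'   (data.frame: epoch, train_loss, val_loss, lr).
#' @export
train_model <- function(model, dataset, cfg = train_config()) {
  if (length(dataset) == 0L) stop("dataset is empty")
  set.seed(cfg$seed)
  n <- length(dataset)
  n_val <- floor(cfg$val_fraction * n)
  perm <- sample(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  if (length(tr_idx) == 0L) tr_idx <- perm
  state <- adam_state(model$layers)
  lr <- cfg$learning_rate
  t_step <- 0L
  best_val <- Inf
  wait <- 0L
  plateau_wait <- 0L
  hist <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- if (length(tr_idx) > 1) sample(tr_idx) else tr_idx
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      zero_grads(model$layers)
      bl <- 0
      for (ci in batch) {
        tc <- dataset[[ci]]
        pred <- model_forward(model, tc$inputs, train = TRUE)
        resid <- pred - case_target(tc)
        bl <- bl + mean(resid^2)
        model_backward(model, 2 * resid /
                         (length(resid) * length(batch)))
      }
      t_step <- t_step + 1L
      state <- adam_step(model$layers, state, lr, t_step)
      ep_loss <- ep_loss + bl
    }
    train_loss <- ep_loss / length(tr_idx)
    val_loss <- if (length(val_idx) > 0) {
      mean(vapply(val_idx, function(ci) {
        tc <- dataset[[ci]]
        pred <- model_forward(model, tc$inputs, train = FALSE)
        mean((pred - case_target(tc))^2)
      }, numeric(1)))
    } else train_loss
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss, lr = lr)
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      wait <- 0L
      plateau_wait <- 0L
    } else {
      wait <- wait + 1L
      plateau_wait <- plateau_wait + 1L
      if (plateau_wait >= cfg$plateau_patience) {
        lr <- lr / cfg$plateau_factor
        plateau_wait <- 0L
        dl_log("epoch %d: validation plateau, learning rate -> %g",
               epoch, lr)
      }
      if (wait >= cfg$early_stop_patience) {
        dl_log("early stop at epoch %d (no improvement for %d epochs)",
               epoch, cfg$early_stop_patience)
        break
      }
    }
  }
  list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null,
                                                            logical(1))]))
}

#' Predict a physical dose distribution for one case
#'
#' Runs the forward pass in evaluation mode, converts the normalized
#' output back to Gy, clamps negative values to zero (logged), and
#' restores the window to the case's CT coordinates.
#'
#' @param model a trained `dose_model`.
#' @param tc a `tensor_case` (with `meta`).
#' @return A `voxel_grid` of dose in Gy on the CT geometry.
#' @export
predict_dose <- function(model, tc) {
  y <- model_forward(model, tc$inputs, train = FALSE)
  dose <- denormalize_dose(y[, , , 1, drop = TRUE], tc$meta$norm)
  n_neg <- sum(dose < 0)
  if (n_neg > 0) {
    dl_log("clamping %d negative dose voxel(s) to zero", n_neg)
    dose <- pmax(dose, 0)
  }
  uncrop_to_ct(dose, tc$meta)
}

#' Extract model weights for serialization
#'
#' @param model a `dose_model`.
#' @return List of per-layer parameter lists (use with [set_weights()]).
#' @export
get_weights <- function(model) lapply(model$layers, function(ly) ly$params)

#' Restore weights extracted with [get_weights()]
#'
#' @param model a `dose_model` with identical architecture.
#' @param weights list from [get_weights()].
#' @return The model, invisibly.
#' @export
set_weights <- function(model, weights) {
  stopifnot(length(weights) == length(model$layers))
  for (i in seq_along(weights)) {
    stopifnot(identical(lapply(model$layers[[i]]$params, dim),
                        lapply(weights[[i]], dim)))
    model$layers[[i]]$params <- weights[[i]]
  }
  invisible(model)
}
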