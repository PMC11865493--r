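#' Residual U-Net configuration
#'
#' Contracting and expansive paths of `depth` blocks. Each contracting
#' block is two 3 x 3 convolutions with ReLU followed by 2 x 2 max pooling
#' (stride 2); each expansive block is a 2 x 2 nearest-neighbour upsampling,
#' concatenation with the skip-connected contracting feature map, and two
#' 3 x 3 convolutions with ReLU. A final 1 x 1 convolution maps back to one
#' channel and is added to the network input (residual head), so the model
#' learns a correction to the input image.
#'
#' @param depth number of down/up blocks (>= 1, default 3).
#' @param base_filters channels of the first block (doubled at each depth).
#' @param residual_output add the input to the final layer's output.
#' @return An object of class `network_config`.
#' @export
network_config <- function(depth = 3L, base_filters = 32L,
                           residual_output = TRUE) {
  if (depth < 1) stop("depth must be >= 1")
  if (base_filters < 1) stop("base_filters must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 residual_output = isTRUE(residual_output)),
            class = "network_config")
}

conv_spec <- function(cin, cout, k) list(cin = cin, cout = cout, k = k)

layer_plan <- function(cfg) {
  plan <- list()
  ch <- function(k) cfg$base_filters * 2L^(k - 1L)
  cin <- 1L
  for (k in seq_len(cfg$depth)) {
    plan[[paste0("enc", k, "_c1")]] <- conv_spec(cin, ch(k), 3L)
    plan[[paste0("enc", k, "_c2")]] <- conv_spec(ch(k), ch(k), 3L)
    cin <- ch(k)
  }
  cb <- cfg$base_filters * 2L^cfg$depth
  plan[["bott_c1"]] <- conv_spec(cin, cb, 3L)
  plan[["bott_c2"]] <- conv_spec(cb, cb, 3L)
  up_ch <- cb
  for (k in rev(seq_len(cfg$depth))) {
    plan[[paste0("dec", k, "_c1")]] <- conv_spec(up_ch + ch(k), ch(k), 3L)
    plan[[paste0("dec", k, "_c2")]] <- conv_spec(ch(k), ch(k), 3L)
    up_ch <- ch(k)
  }
  plan[["out"]] <- conv_spec(cfg$base_filters, 1L, 1L)
  plan
}

#' Build a residual U-Net model
#'
#' Convolution weights use He initialization; the final 1 x 1 convolution
#' is zero-initialized so an untrained model is exactly the identity on its
#' input (the residual correction starts at zero), which keeps early
#' training stable.
#'
#' @param config a [network_config()].
#' @param seed integer seed for the weight draw (NULL uses the current RNG
#'   stream).
#' @return An object of class `unet_model`.
#' @export
build_network <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  plan <- layer_plan(config)
  params <- with_seed(seed, {
    p <- list()
    for (nm in names(plan)) {
      sp <- plan[[nm]]
      fan_in <- sp$cin * sp$k^2
      if (nm == "out") {
        p[[paste0(nm, ".W")]] <- matrix(0, sp$cout, fan_in)
      } else {
        p[[paste0(nm, ".W")]] <- matrix(rnorm(sp$cout * fan_in,
                                              sd = sqrt(2 / fan_in)),
                                        sp$cout, fan_in)
      }
      p[[paste0(nm, ".b")]] <- numeric(sp$cout)
    }
    p
  })
  structure(list(config = config, params = params, plan = plan),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat("Residual U-Net: depth", x$config$depth, "- base filters",
      x$config$base_filters, "-", count_params(x), "parameters\n")
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `unet_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# lift a matrix (one image) or H x W x B array (batch) to (H, W, B, 1)
as_hwb1 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L, 1L))
  else array(x, dim = c(dim(x), 1L))
}

unet_forward <- function(model, x, keep = FALSE) {
  p <- model$params
  cfg <- model$config
  a0 <- as_hwb1(x)
  h <- dim(a0)[1]; w <- dim(a0)[2]; nb <- dim(a0)[3]
  if (h %% 2L^cfg$depth || w %% 2L^cfg$depth)
    stop("spatial dims must be multiples of ", 2L^cfg$depth)
  cache <- if (keep) list(a0 = a0) else NULL
  conv_relu <- function(inp, nm) {
    z <- .conv3_fwd_cpp(inp, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
    a <- z * (z > 0)
    dim(a) <- dim(z)
    if (keep) cache[[nm]] <<- list(inp = inp, mask = z > 0)
    a
  }
  cur <- a0
  skips <- vector("list", cfg$depth)
  for (k in seq_len(cfg$depth)) {
    cur <- conv_relu(cur, paste0("enc", k, "_c1"))
    cur <- conv_relu(cur, paste0("enc", k, "_c2"))
    skips[[k]] <- cur
    mp <- .maxpool_fwd_cpp(cur)
    if (keep) cache[[paste0("pool", k)]] <- list(idx = mp$idx,
                                                 h = dim(cur)[1],
                                                 w = dim(cur)[2])
    cur <- mp$out
  }
  cur <- conv_relu(cur, "bott_c1")
  cur <- conv_relu(cur, "bott_c2")
  for (k in rev(seq_len(cfg$depth))) {
    up <- .upsample_fwd_cpp(cur)
    # channels are the last dim, so concatenation is a plain c()
    cat_ <- array(c(up, skips[[k]]),
                  dim = c(dim(up)[1], dim(up)[2], nb,
                          dim(up)[4] + dim(skips[[k]])[4]))
    if (keep) cache[[paste0("cat", k)]] <- list(up_ch = dim(up)[4])
    cur <- conv_relu(cat_, paste0("dec", k, "_c1"))
    cur <- conv_relu(cur, paste0("dec", k, "_c2"))
  }
  out <- .conv1_fwd_cpp(cur, p[["out.W"]], p[["out.b"]])
  if (keep) cache[["out"]] <- list(inp = cur)
  y <- if (cfg$residual_output) out + a0 else out
  y <- if (nb == 1L) matrix(y, h, w) else array(y, dim = c(h, w, nb))
  list(y = y, cache = cache)
}

unet_backward <- function(model, cache, g_y) {
  p <- model$params
  cfg <- model$config
  grads <- list()
  g <- as_hwb1(g_y)
  back_conv <- function(g, nm) {
    cc <- cache[[nm]]
    g <- g * cc$mask
    dim(g) <- dim(cc$mask)
    res <- .conv3_bwd_cpp(cc$inp, p[[paste0(nm, ".W")]], g)
    grads[[paste0(nm, ".W")]] <<- res$gW
    grads[[paste0(nm, ".b")]] <<- res$gb
    res$gx
  }
  # final 1x1 conv; the residual path needs no extra work for weight grads
  res <- .conv1_bwd_cpp(cache[["out"]]$inp, p[["out.W"]], g)
  grads[["out.W"]] <- res$gW
  grads[["out.b"]] <- res$gb
  g <- res$gx
  g_skip <- vector("list", cfg$depth)
  for (k in seq_len(cfg$depth)) {
    g <- back_conv(g, paste0("dec", k, "_c2"))
    g <- back_conv(g, paste0("dec", k, "_c1"))
    up_ch <- cache[[paste0("cat", k)]]$up_ch
    d <- dim(g)
    g_up <- g[, , , seq_len(up_ch), drop = FALSE]
    g_skip[[k]] <- g[, , , (up_ch + 1):d[4], drop = FALSE]
    g <- .upsample_bwd_cpp(g_up)
  }
  g <- back_conv(g, "bott_c2")
  g <- back_conv(g, "bott_c1")
  for (k in rev(seq_len(cfg$depth))) {
    pl <- cache[[paste0("pool", k)]]
    g <- .maxpool_bwd_cpp(g, pl$idx, pl$h, pl$w)
    g <- g + g_skip[[k]]
    g <- back_conv(g, paste0("enc", k, "_c2"))
    g <- back_conv(g, paste0("enc", k, "_c1"))
  }
  grads
}

#' Apply a model to one image patch or plane
#'
#' Low-level forward pass on an image whose dimensions are multiples of
#' `2^depth`; see [predict_image()] for arbitrary sizes.
#'
#' @param model a `unet_model`.
#' @param x numeric matrix.
#' @return Restored matrix of the same shape.
#' @export
unet_apply <- function(model, x) {
  unet_forward(model, x, keep = FALSE)$y
}

#' Restore an image or plane stack with a trained model
#'
#' Each plane is percentile-normalized (the same normalization used for
#' training inputs), reflect-padded to spatial multiples of `2^depth`,
#' passed through the network and cropped back. Multi-plane inputs
#' (2D+time or z-stacks as `H x W x P` arrays) are restored plane by
#' plane; a plane whose normalization is degenerate is skipped with a
#' warning and returned as all-NA.
#'
#' @param model a `unet_model`.
#' @param image numeric matrix or `H x W x P` array.
#' @param norm a [normalization_params()].
#' @return Restoration with the same shape as the input, on the normalized
#'   intensity scale.
#' @export
predict_image <- function(model, image, norm = normalization_params()) {
  stopifnot(inherits(model, "unet_model"))
  if (is.array(image) && length(dim(image)) == 3) {
    planes <- lapply(seq_len(dim(image)[3]), function(k) {
      tryCatch(predict_image(model, image[, , k], norm),
               error = function(e) {
                 warning("plane ", k, " skipped: ", conditionMessage(e))
                 matrix(NA_real_, dim(image)[1], dim(image)[2])
               })
    })
    return(array(unlist(planes), dim = dim(image)))
  }
  check_image(image)
  x <- percentile_normalize(image, norm)
  mult <- 2L^model$config$depth
  h <- nrow(x); w <- ncol(x)
  ph <- (mult - h %% mult) %% mult
  pw <- (mult - w %% mult) %% mult
  xp <- if (ph || pw) pad_reflect(x, 0, ph, 0, pw) else x
  yp <- unet_apply(model, xp)
  yp[seq_len(h), seq_len(w), drop = FALSE]
}
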