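#' Avatar network architecture specification
#'
#' The dual-branch architecture: the 400-sample touch window passes through
#' three 1D convolution layers (kernel size 4, ReLU) and a size-4 max pooling
#' before flattening; the 500-bin sliding spectrum passes through fully
#' connected 400-ReLU and 300-ReLU layers; the concatenated branches pass
#' through fully connected 400-ReLU and 200-ReLU trunk layers and terminate
#' in a softmax layer with one node per material, sorted smooth/soft to
#' rough. Optimized by stochastic gradient descent with momentum 0.9 and
#' learning-rate decay 1e-6.
#'
#' Two loss modes: `"histogram"` fits the softmax output to the human rank
#' decision histogram with mean-square error (the avatar system);
#' `"categorical"` uses cross-entropy against one-hot labels (the
#' conventional classifier baseline).
#'
#' @param n_out Output nodes = number of materials (default 42).
#' @param touch_len,slide_len Input widths (defaults 400 and 500).
#' @param conv_channels Channels per convolution layer (default 8; the layer
#'   count and kernel size are fixed at 3 and 4).
#' @param kernel Convolution kernel size (default 4).
#' @param pool Max-pooling size (default 4).
#' @param slide_units Fully connected widths of the spectrum branch.
#' @param trunk_units Fully connected widths of the combined trunk.
#' @param loss `"histogram"` or `"categorical"`.
#' @param learning_rate,momentum,decay SGD hyperparameters; decay follows the
#'   `lr_t = lr / (1 + decay * t)` schedule with t the update count. The
#'   learning-rate default depends on the loss mode: 20 for histogram-MSE
#'   (whose gradients through the softmax are roughly three orders of
#'   magnitude smaller) and 0.05 for cross-entropy.
#' @param epochs,batch_size Training schedule defaults (40 epochs, batch 16;
#'   small batches matter for the histogram loss, whose gradients through a
#'   diffuse softmax are weak enough that large-batch averaging can stall
#'   boundary-ranked materials on a plateau).
#' @return A `avatar_spec` list.
#' @export
#' @examples
#' avatar_spec(n_out = 6)
avatar_spec <- function(n_out = 42, touch_len = 400, slide_len = 500,
                        conv_channels = 8, kernel = 4, pool = 4,
                        slide_units = c(400, 300), trunk_units = c(400, 200),
                        loss = c("histogram", "categorical"),
                        learning_rate = NULL, momentum = 0.9, decay = 1e-6,
                        epochs = 40, batch_size = 16) {
  loss <- rlang::arg_match(loss)
  learning_rate <- learning_rate %||% if (loss == "histogram") 20 else 0.05
  check_count(n_out, "n_out")
  check_count(conv_channels, "conv_channels")
  conv_len <- touch_len - 3 * (kernel - 1)
  if (conv_len < pool) abort_invalid("touch input too short for conv stack")
  structure(
    list(
      n_out = as.integer(n_out), touch_len = as.integer(touch_len),
      slide_len = as.integer(slide_len),
      conv_channels = as.integer(conv_channels), kernel = as.integer(kernel),
      pool = as.integer(pool), slide_units = as.integer(slide_units),
      trunk_units = as.integer(trunk_units), loss = loss,
      learning_rate = learning_rate, momentum = momentum, decay = decay,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      conv_len = as.integer(conv_len),
      pooled_len = as.integer(conv_len %/% pool),
      flat_len = as.integer((conv_len %/% pool) * conv_channels)
    ),
    class = "avatar_spec"
  )
}

#' @export
print.avatar_spec <- function(x, ...) {
  cat("<avatar_spec>\n")
  cat(sprintf(
    "  touch %d -> conv(3 x k%d, %dch) -> pool%d -> %d | slide %d -> %s\n",
    x$touch_len, x$kernel, x$conv_channels, x$pool, x$flat_len,
    x$slide_len, paste(x$slide_units, collapse = " -> ")
  ))
  cat(sprintf(
    "  trunk %s -> %d softmax | %s loss | SGD lr %g, momentum %g, decay %g\n",
    paste(x$trunk_units, collapse = " -> "), x$n_out, x$loss,
    x$learning_rate, x$momentum, x$decay
  ))
  invisible(x)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Initialize an avatar network
#'
#' He-normal seeded weight initialization for every layer of the spec.
#'
#' @param spec An [avatar_spec()].
#' @param seed Integer seed; the same seed reproduces the weights exactly.
#' @return An `avatar_net` object (weights + spec).
#' @export
avatar_net <- function(spec = avatar_spec(), seed = 1) {
  if (!inherits(spec, "avatar_spec")) abort_invalid("`spec` must be an avatar_spec")
  k <- spec$kernel; ch <- spec$conv_channels
  withr::with_seed(derive_seed(seed, "net-init"), {
    w <- list(
      conv1 = he_init(k, ch, k), b_conv1 = numeric(ch),
      conv2 = he_init(k * ch, ch, k * ch), b_conv2 = numeric(ch),
      conv3 = he_init(k * ch, ch, k * ch), b_conv3 = numeric(ch),
      slide1 = he_init(spec$slide_len, spec$slide_units[1], spec$slide_len),
      b_slide1 = numeric(spec$slide_units[1]),
      slide2 = he_init(spec$slide_units[1], spec$slide_units[2], spec$slide_units[1]),
      b_slide2 = numeric(spec$slide_units[2]),
      trunk1 = he_init(spec$flat_len + spec$slide_units[2], spec$trunk_units[1],
        spec$flat_len + spec$slide_units[2]),
      b_trunk1 = numeric(spec$trunk_units[1]),
      trunk2 = he_init(spec$trunk_units[1], spec$trunk_units[2], spec$trunk_units[1]),
      b_trunk2 = numeric(spec$trunk_units[2]),
      out = he_init(spec$trunk_units[2], spec$n_out, spec$trunk_units[2]),
      b_out = numeric(spec$n_out)
    )
  })
  structure(list(spec = spec, weights = w, seed = seed), class = "avatar_net")
}

#' @export
print.avatar_net <- function(x, ...) {
  np <- sum(purrr::map_int(x$weights, length))
  cat(sprintf("<avatar_net> %d parameters, seed %s\n", np, format(x$seed)))
  print(x$spec)
  invisible(x)
}

# ---- conv primitives (valid padding, stride 1) -------------------------------
# activations are 3D arrays dim (batch, length, channels); im2col (compiled
# gather) turns the convolution into one BLAS matmul. The scalar kernels
# conv1d_fwd/conv1d_bwd in src/ are kept as independent references for the
# test suite.

.idx_cache <- new.env(parent = emptyenv())

im2col_index <- function(b, l, ch, k) {
  key <- paste(b, l, ch, k, sep = "-")
  cached <- .idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  lo <- l - k + 1
  # column j = (c-1)*k + u maps to input position l+u-1, channel c
  u <- rep(seq_len(k), times = ch)
  cc <- rep(seq_len(ch), each = k)
  base <- rep(seq_len(lo), each = b) # output position, batch fastest
  rows <- rep(seq_len(b), times = lo)
  # linear index into a: row + b*(pos-1) + b*l*(c-1)
  pos <- outer(base, u - 1, "+") # (b*lo) x (k*ch) positions
  idx <- as.vector(rows + b * (pos - 1) + b * l * rep(cc - 1, each = length(rows)))
  out <- list(idx = idx, nr = b * lo, nc = k * ch)
  .idx_cache[[key]] <- out
  out
}

im2col <- function(a, k) {
  im2col_cpp(a, k)
}

# pure-R gather used as an independent reference in the tests
im2col_ref <- function(a, k) {
  d <- dim(a)
  ix <- im2col_index(d[1], d[2], d[3], k)
  x <- a[ix$idx]
  dim(x) <- c(ix$nr, ix$nc)
  x
}

conv_forward <- function(a, w, bias) {
  d <- dim(a); b <- d[1]; l <- d[2]
  k <- nrow(w) / d[3]; ch_out <- ncol(w)
  lo <- l - k + 1
  x2 <- im2col(a, k)
  y <- x2 %*% w
  y <- sweep(y, 2, bias, "+")
  list(out = array(y, c(b, lo, ch_out)), x2 = x2)
}

conv_backward <- function(dy, x2, w, a_dim) {
  b <- a_dim[1]; l <- a_dim[2]; ch_in <- a_dim[3]
  k <- nrow(w) / ch_in
  lo <- l - k + 1
  ch_out <- dim(dy)[3]
  dy2 <- matrix(dy, b * lo, ch_out)
  dw <- crossprod(x2, dy2)
  db <- colSums(dy2)
  # input gradient = full convolution of dy with the flipped kernel:
  # zero-pad dy by k-1 on both sides and run the same im2col matmul
  dyp <- array(0, c(b, lo + 2 * (k - 1), ch_out))
  dyp[, k:(k + lo - 1), ] <- dy
  wf <- matrix(0, k * ch_out, ch_in)
  for (ci in seq_len(ch_in)) {
    # wf[(o-1)*k + u, ci] = w[(ci-1)*k + (k + 1 - u), o]
    wf[, ci] <- as.vector(w[(ci - 1) * k + (k:1), , drop = FALSE])
  }
  da <- im2col(dyp, k) %*% wf
  dim(da) <- a_dim
  list(da = da, dw = dw, db = db)
}

maxpool_forward_ref <- function(a, p) {
  d <- dim(a); b <- d[1]; l <- d[2]; ch <- d[3]
  lw <- l %/% p
  a4 <- array(a[, seq_len(lw * p), , drop = FALSE], c(b, p, lw, ch))
  out <- a4[, 1, , , drop = FALSE]
  arg <- array(1L, c(b, 1, lw, ch))
  for (v in 2:p) {
    sl <- a4[, v, , , drop = FALSE]
    better <- sl > out
    out[better] <- sl[better]
    arg[better] <- v
  }
  list(out = array(out, c(b, lw, ch)), arg = array(arg, c(b, lw, ch)),
    in_dim = d, p = p)
}

maxpool_backward_ref <- function(dy, pool) {
  p_ <- dim(pool$arg)
  b <- p_[1]; lw <- p_[2]; ch <- p_[3]
  p <- pool$p
  da4 <- array(0, c(b, p, lw, ch))
  # scatter gradient to the argmax tap
  idx <- cbind(
    rep(seq_len(b), times = lw * ch),
    as.vector(pool$arg),
    rep(rep(seq_len(lw), each = b), times = ch),
    rep(seq_len(ch), each = b * lw)
  )
  da4[idx] <- as.vector(dy)
  da <- array(0, pool$in_dim)
  da[, seq_len(p * lw), ] <- array(da4, c(b, p * lw, ch))
  da
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# full forward pass; returns activations needed for backprop
net_forward <- function(net, touch, slide) {
  w <- net$weights; sp <- net$spec
  b <- nrow(touch)
  a0 <- array(touch, c(b, sp$touch_len, 1L))
  c1 <- conv_forward(a0, w$conv1, w$b_conv1); r1 <- relu(c1$out)
  c2 <- conv_forward(r1, w$conv2, w$b_conv2); r2 <- relu(c2$out)
  c3 <- conv_forward(r2, w$conv3, w$b_conv3); r3 <- relu(c3$out)
  pl <- maxpool1d_fwd(r3, sp$pool)
  flat <- matrix(pl$out, b, sp$flat_len)
  s1 <- sweep(slide %*% w$slide1, 2, w$b_slide1, "+"); rs1 <- relu(s1)
  s2 <- sweep(rs1 %*% w$slide2, 2, w$b_slide2, "+"); rs2 <- relu(s2)
  comb <- cbind(flat, rs2)
  t1 <- sweep(comb %*% w$trunk1, 2, w$b_trunk1, "+"); rt1 <- relu(t1)
  t2 <- sweep(rt1 %*% w$trunk2, 2, w$b_trunk2, "+"); rt2 <- relu(t2)
  z <- sweep(rt2 %*% w$out, 2, w$b_out, "+")
  p <- softmax_rows(z)
  list(
    p = p, z = z, rt2 = rt2, rt1 = rt1, comb = comb, rs2 = rs2, rs1 = rs1,
    slide = slide, flat = flat, pl = pl, r1 = r1, r2 = r2, r3 = r3,
    c1 = c1, c2 = c2, c3 = c3, a0 = a0, b = b
  )
}

# gradient of the loss w.r.t. pre-softmax logits
loss_grad_logits <- function(p, targets, loss) {
  if (loss == "categorical") {
    (p - targets) / nrow(p)
  } else {
    g <- 2 * (p - targets) / ncol(p) / nrow(p) # d mean-square / dp
    p * (g - rowSums(g * p)) # softmax jacobian
  }
}

loss_value <- function(p, targets, loss) {
  if (loss == "categorical") {
    -mean(rowSums(targets * log(pmax(p, 1e-12))))
  } else {
    mean((p - targets)^2)
  }
}

net_backward <- function(net, fwd, dz) {
  w <- net$weights; sp <- net$spec
  g <- list()
  g$out <- crossprod(fwd$rt2, dz); g$b_out <- colSums(dz)
  dt2 <- dz %*% t(w$out); dt2[fwd$rt2 <= 0] <- 0
  g$trunk2 <- crossprod(fwd$rt1, dt2); g$b_trunk2 <- colSums(dt2)
  dt1 <- dt2 %*% t(w$trunk2); dt1[fwd$rt1 <= 0] <- 0
  g$trunk1 <- crossprod(fwd$comb, dt1); g$b_trunk1 <- colSums(dt1)
  dcomb <- dt1 %*% t(w$trunk1)
  dflat <- dcomb[, seq_len(sp$flat_len), drop = FALSE]
  ds2 <- dcomb[, sp$flat_len + seq_len(sp$slide_units[2]), drop = FALSE]
  ds2[fwd$rs2 <= 0] <- 0
  g$slide2 <- crossprod(fwd$rs1, ds2); g$b_slide2 <- colSums(ds2)
  ds1 <- ds2 %*% t(w$slide2); ds1[fwd$rs1 <= 0] <- 0
  g$slide1 <- crossprod(fwd$slide, ds1); g$b_slide1 <- colSums(ds1)
  dpool <- array(dflat, c(fwd$b, sp$pooled_len, sp$conv_channels))
  dr3 <- maxpool1d_bwd(dpool, fwd$pl$arg, dim(fwd$r3)[2], sp$pool)
  dr3[fwd$r3 <= 0] <- 0
  bk3 <- conv_backward(dr3, fwd$c3$x2, w$conv3, dim(fwd$r2))
  g$conv3 <- bk3$dw; g$b_conv3 <- bk3$db
  dr2 <- bk3$da; dr2[fwd$r2 <= 0] <- 0
  bk2 <- conv_backward(dr2, fwd$c2$x2, w$conv2, dim(fwd$r1))
  g$conv2 <- bk2$dw; g$b_conv2 <- bk2$db
  dr1 <- bk2$da; dr1[fwd$r1 <= 0] <- 0
  bk1 <- conv_backward(dr1, fwd$c1$x2, w$conv1, dim(fwd$a0))
  g$conv1 <- bk1$dw; g$b_conv1 <- bk1$db
  g
}

#' Train an avatar network
#'
#' Stochastic gradient descent with momentum 0.9 and learning-rate decay
#' 1e-6 per update. In histogram mode the mean-square error between the
#' softmax output and the target rank histogram is minimized; in categorical
#' mode the cross-entropy against one-hot labels. Training is deterministic
#' given the seed (single-threaded BLAS assumed).
#'
#' @param net An [avatar_net()] (or an `avatar_fit` to continue training).
#' @param touch n x 400 matrix of touch windows.
#' @param slide n x 500 matrix of sliding spectra.
#' @param targets n x n_out matrix of row-normalized target histograms
#'   (one-hot rows in categorical mode; a one-hot row is also a valid
#'   degenerate histogram).
#' @param epochs,batch_size,learning_rate Override the spec defaults.
#' @param seed Seed for batch shuffling.
#' @param validation Optional list with `touch`, `slide`, `targets` to track
#'   a held-out loss per epoch.
#' @param verbose Print the loss every 10 epochs.
#' @return An `avatar_fit` object: trained weights, spec, and a `history`
#'   tibble (epoch, loss, val_loss).
#' @export
fit_avatar <- function(net, touch, slide, targets,
                       epochs = NULL, batch_size = NULL, learning_rate = NULL,
                       seed = 1, validation = NULL, verbose = FALSE) {
  if (inherits(net, "avatar_fit")) net <- structure(net[c("spec", "weights", "seed")], class = "avatar_net")
  if (!inherits(net, "avatar_net")) abort_invalid("`net` must be an avatar_net")
  sp <- net$spec
  touch <- as.matrix(touch); slide <- as.matrix(slide); targets <- as.matrix(targets)
  n <- nrow(touch)
  if (nrow(slide) != n || nrow(targets) != n) {
    abort_invalid("touch, slide and targets must have the same number of rows")
  }
  if (ncol(targets) != sp$n_out) {
    abort_invalid("targets width must equal the number of output nodes")
  }
  if (any(targets < -1e-9) || any(abs(rowSums(targets) - 1) > 1e-6)) {
    abort_invalid("target rows must be normalized histograms (sum to 1)")
  }
  if (sp$loss == "categorical" && any(apply(targets, 1, max) < 1 - 1e-9)) {
    abort_invalid("categorical mode requires one-hot target rows")
  }
  epochs <- epochs %||% sp$epochs
  batch_size <- batch_size %||% sp$batch_size
  lr0 <- learning_rate %||% sp$learning_rate
  # standardize the touch input scale (volts are small); the spectrum is
  # already max-normalized to [0, 1]. The factor is stored for prediction.
  touch_scale <- sd(touch)
  if (!is.finite(touch_scale) || touch_scale <= 0) touch_scale <- 1
  touch <- touch / touch_scale
  if (!is.null(validation)) validation$touch <- validation$touch / touch_scale
  w <- net$weights
  vel <- purrr::map(w, function(x) x * 0)
  step <- 0
  hist_rows <- vector("list", epochs)
  withr::with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        ix <- ord[s:min(s + batch_size - 1, n)]
        fwd <- net_forward(net, touch[ix, , drop = FALSE], slide[ix, , drop = FALSE])
        tg <- targets[ix, , drop = FALSE]
        ep_loss <- ep_loss + loss_value(fwd$p, tg, sp$loss) * length(ix)
        dz <- loss_grad_logits(fwd$p, tg, sp$loss)
        g <- net_backward(net, fwd, dz)
        lr <- lr0 / (1 + sp$decay * step)
        for (nm in names(w)) {
          vel[[nm]] <- sp$momentum * vel[[nm]] - lr * g[[nm]]
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
        net$weights <- w
        step <- step + 1
      }
      val <- NA_real_
      if (!is.null(validation)) {
        vp <- net_forward(net, validation$touch, validation$slide)$p
        val <- loss_value(vp, validation$targets, sp$loss)
      }
      hist_rows[[ep]] <- tibble::tibble(
        epoch = ep, loss = ep_loss / n, val_loss = val
      )
      if (verbose && ep %% 10 == 0) {
        message(sprintf("epoch %d  loss %.3e", ep, ep_loss / n))
      }
    }
  })
  structure(
    list(
      spec = sp, weights = w, seed = net$seed, touch_scale = touch_scale,
      history = dplyr::bind_rows(hist_rows)
    ),
    class = c("avatar_fit", "avatar_net")
  )
}

#' Predict activation distributions
#'
#' Forward pass of the network: each row of the result is the softmax
#' activation over the rank-sorted output nodes, a probability distribution
#' interpreted as the avatar's tactile decision distribution.
#'
#' @param object An `avatar_net` or `avatar_fit`.
#' @param touch n x 400 matrix (or length-400 vector) of touch windows.
#' @param slide n x 500 matrix (or length-500 vector) of sliding spectra.
#' @param ... Unused.
#' @return An n x n_out matrix of probabilities; rows sum to 1.
#' @export
predict.avatar_net <- function(object, touch, slide, ...) {
  if (is.null(dim(touch))) touch <- matrix(touch, 1)
  if (is.null(dim(slide))) slide <- matrix(slide, 1)
  if (ncol(touch) != object$spec$touch_len || ncol(slide) != object$spec$slide_len) {
    abort_invalid("input widths do not match the network spec")
  }
  scale <- object$touch_scale %||% 1
  net_forward(object, as.matrix(touch) / scale, as.matrix(slide))$p
}

#' @export
print.avatar_fit <- function(x, ...) {
  cat(sprintf(
    "<avatar_fit> %s loss | %d epochs | final loss %.3e\n",
    x$spec$loss, nrow(x$history), utils::tail(x$history$loss, 1)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of an avatar fit
#'
#' @param x An `avatar_fit`.
#' @param ... Unused.
#' @return The history tibble (epoch, loss, val_loss).
#' @method tidy avatar_fit
#' @export
tidy.avatar_fit <- function(x, ...) x$history

#' One-row summary of an avatar fit
#'
#' @param x An `avatar_fit`.
#' @param ... Unused.
#' @return A tibble with loss mode, epochs, initial/final training loss.
#' @method glance avatar_fit
#' @export
glance.avatar_fit <- function(x, ...) {
  tibble::tibble(
    loss_mode = x$spec$loss,
    epochs = nrow(x$history),
    initial_loss = x$history$loss[1],
    final_loss = utils::tail(x$history$loss, 1),
    n_parameters = sum(purrr::map_int(x$weights, length))
  )
}

#' Stratified train/validation split over trials
#'
#' Splits recording indices into train and held-out sets with the given
#' proportion within every material, so both sets cover all materials.
#'
#' @param material_id Integer vector, one entry per recording.
#' @param prop Training proportion (default 0.8).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(material_id, prop = 0.8, seed = 1) {
  check_number(prop, "prop", min = 0, strict = TRUE)
  if (prop >= 1) abort_invalid("`prop` must be < 1")
  withr::with_seed(derive_seed(seed, "split"), {
    idx <- purrr::map(split(seq_along(material_id), material_id), function(ix) {
      n_tr <- max(1L, floor(length(ix) * prop))
      tr <- sample(ix, n_tr)
      list(train = tr, test = setdiff(ix, tr))
    })
  })
  list(
    train = sort(unlist(purrr::map(idx, "train"), use.names = FALSE)),
    test = sort(unlist(purrr::map(idx, "test"), use.names = FALSE))
  )
}

#' Build target histogram rows for a corpus
#'
#' Aligns a participant's per-material decision histograms with the corpus
#' recordings: row i is the histogram of the material of recording i. In
#' categorical mode the histogram is collapsed to a one-hot row at its
#' rounded mean rank (the conventional label).
#'
#' @param material_id Integer vector of recording materials.
#' @param histograms Tibble from [decision_histograms()].
#' @param mode `"histogram"` or `"categorical"`.
#' @return An n x n_out matrix of target rows.
#' @export
histogram_targets <- function(material_id, histograms,
                              mode = c("histogram", "categorical")) {
  mode <- rlang::arg_match(mode)
  hm <- histogram_matrix(histograms)
  miss <- setdiff(unique(material_id), as.integer(rownames(hm)))
  if (length(miss) > 0) {
    abort_invalid(sprintf("no histogram for material(s) %s", toString(miss)))
  }
  tg <- hm[as.character(material_id), , drop = FALSE]
  if (mode == "categorical") {
    ranks <- seq_len(ncol(tg))
    lab <- apply(tg, 1, function(p) round_half_away(sum(ranks * p)))
    tg <- matrix(0, nrow(tg), ncol(tg))
    tg[cbind(seq_len(nrow(tg)), lab)] <- 1
  }
  unname(tg)
}

#' Mean activation entropy
#'
#' Shannon entropy (nats) of each activation row, averaged; used to contrast
#' the sharp decisions of the categorical baseline with the spread decisions
#' of the histogram-trained avatar.
#'
#' @param p Matrix of activation distributions (rows sum to 1).
#' @return Mean entropy in nats.
#' @export
activation_entropy <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1)
  mean(-rowSums(p * log(pmax(p, 1e-12))))
}
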