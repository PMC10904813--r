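# Small neural models for dimensionality reduction, written directly in
# matrix algebra (full-batch Adam). Desk-scale stand-ins for the large
# pretrained backbones used with real radiographs; both are configurable.

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (k in names(params)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

patch_indices <- function(size, patch) {
  H <- size[1]; W <- size[2]
  stopifnot(H %% patch == 0, W %% patch == 0)
  idx <- list()
  for (pj in seq_len(W / patch)) {
    for (pi in seq_len(H / patch)) {
      rowsel <- (pi - 1) * patch + seq_len(patch)
      colsel <- (pj - 1) * patch + seq_len(patch)
      # images are stored column-major as H x W matrices
      idx[[length(idx) + 1L]] <- as.vector(outer(rowsel, (colsel - 1) * H, "+"))
    }
  }
  idx
}

#' Autoencoder architecture and training settings
#'
#' The encoder is a single convolutional layer with kernel = stride =
#' `patch` (a patchwise linear map to `latent_dim` channels), producing a
#' spatial bottleneck feature map of `n_patches x latent_dim`; the decoder
#' linearly reconstructs each patch from its bottleneck vector. For drift
#' detection the bottleneck map is mean-pooled over spatial positions to a
#' single `latent_dim` vector per image.
#'
#' @param latent_dim bottleneck channels (>= 2).
#' @param patch patch (kernel/stride) size in pixels; must divide H and W.
#' @param epochs full-batch training epochs.
#' @param lr Adam learning rate.
#' @param seed integer seed for weight initialization.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(latent_dim = 32L, patch = 8L, epochs = 60L,
                         lr = 0.01, seed = 1L) {
  stopifnot(latent_dim >= 2)
  structure(list(latent_dim = as.integer(latent_dim), patch = as.integer(patch),
                 epochs = as.integer(epochs), lr = lr, seed = as.integer(seed)),
            class = "encoder_spec")
}

#' Train the autoencoder (TAE) on a pool of images
#'
#' @param images `n x (H*W)` pixel matrix (see [images_as_matrix()]). The
#'   training pool must be disjoint from all evaluation pools.
#' @param spec an [encoder_spec()].
#' @param size image size `(H, W)`.
#' @param holdout_frac fraction of images held out to report a reconstruction
#'   loss; also used for the non-convergence check.
#' @return an `encoder_model` with weights, patch geometry, and a training
#'   log (`loss` per epoch, `holdout_loss`, `baseline_loss` of the untrained
#'   model, `converged` flag).
#' @export
train_autoencoder <- function(images, spec, size, holdout_frac = 0.1) {
  stopifnot(inherits(spec, "encoder_spec"))
  n <- nrow(images)
  if (n < 4) stop("need at least 4 training images", call. = FALSE)
  idx <- patch_indices(size, spec$patch)
  pd <- spec$patch^2
  np <- length(idx)

  hold <- with_stream(derive_seed(spec$seed, "ae-holdout"),
                      sample.int(n, max(1, floor(holdout_frac * n))))
  train <- setdiff(seq_len(n), hold)

  to_patches <- function(X) {
    # (n * np) x pd matrix of flattened patches
    do.call(rbind, lapply(idx, function(ix) X[, ix, drop = FALSE]))
  }
  Ptr <- to_patches(images[train, , drop = FALSE])
  Pho <- to_patches(images[hold, , drop = FALSE])
  mu <- colMeans(Ptr)
  Ptr <- sweep(Ptr, 2, mu)
  Pho <- sweep(Pho, 2, mu)

  params <- with_stream(derive_seed(spec$seed, "ae-init"), list(
    W = matrix(stats::rnorm(pd * spec$latent_dim, 0, 0.1), pd, spec$latent_dim),
    D = matrix(stats::rnorm(spec$latent_dim * pd, 0, 0.1), spec$latent_dim, pd)
  ))
  recon_loss <- function(P, par) {
    R <- (P %*% par$W) %*% par$D
    mean((R - P)^2)
  }
  baseline <- recon_loss(Pho, params)

  st <- adam_state(params)
  losses <- numeric(spec$epochs)
  N <- nrow(Ptr)
  for (e in seq_len(spec$epochs)) {
    Z <- Ptr %*% params$W
    R <- Z %*% params$D
    E <- R - Ptr
    losses[e] <- mean(E^2)
    G <- 2 * E / (N * pd)
    grads <- list(W = crossprod(Ptr, G %*% t(params$D)), D = crossprod(Z, G))
    upd <- adam_step(params, grads, st, spec$lr)
    params <- upd$params
    st <- upd$state
  }
  holdout <- recon_loss(Pho, params)
  converged <- losses[spec$epochs] < losses[1]
  if (!converged) {
    message("autoencoder training loss did not improve; model returned anyway")
  }
  structure(list(W = params$W, D = params$D, mu = mu, patch = spec$patch,
                 size = size, latent_dim = spec$latent_dim,
                 log = list(loss = losses, holdout_loss = holdout,
                            baseline_loss = baseline, converged = converged),
                 spec = spec),
            class = "encoder_model")
}

#' Encode images with a trained autoencoder
#'
#' Each image's patchwise bottleneck map is mean-pooled over spatial
#' positions to one `latent_dim` vector (the TAE representation).
#'
#' @param model an `encoder_model`.
#' @param images `n x (H*W)` pixel matrix matching the training size.
#' @param pool if `FALSE`, return the unpooled bottleneck maps as an
#'   `n_patches`-long list of `n x latent_dim` matrices.
#' @return an `n x latent_dim` feature matrix (tag `tae`), rows named by the
#'   image rownames.
#' @export
encode_images <- function(model, images, pool = TRUE) {
  stopifnot(inherits(model, "encoder_model"))
  if (ncol(images) != prod(model$size)) {
    stop("image size does not match the encoder's training size", call. = FALSE)
  }
  idx <- patch_indices(model$size, model$patch)
  pd <- model$patch^2
  maps <- vector("list", length(idx))
  for (p in seq_along(idx)) {
    musub <- model$mu
    maps[[p]] <- sweep(images[, idx[[p]], drop = FALSE], 2, musub) %*% model$W
  }
  if (!pool) return(maps)
  out <- Reduce(`+`, maps) / length(maps)
  rownames(out) <- rownames(images)
  attr(out, "tag") <- "tae"
  out
}

#' Classifier architecture and training settings
#'
#' A small dense network (one tanh hidden layer, or plain multi-label
#' logistic regression when `hidden_dim = 0`) with per-label sigmoid outputs,
#' trained with full-batch Adam on binary cross-entropy and early-stopped on
#' a patient-disjoint validation split.
#'
#' @param n_labels number of output labels.
#' @param hidden_dim hidden units (0 for a linear model).
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_frac fraction of patients assigned to the validation split.
#' @param seed integer seed.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(n_labels = 14L, hidden_dim = 24L, epochs = 150L,
                            lr = 0.02, patience = 20L, val_frac = 0.2,
                            seed = 1L) {
  structure(list(n_labels = as.integer(n_labels), hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

split_by_patient <- function(patient_ids, val_frac, seed) {
  # deterministic hash split at the patient level: no patient overlap
  upat <- unique(patient_ids)
  h <- vapply(upat, function(p) derive_seed(seed, "valsplit", p) %% 1000L,
              integer(1))
  val_pat <- upat[h < round(val_frac * 1000)]
  patient_ids %in% val_pat
}

#' Train the multi-label classifier
#'
#' @param records cohort records (one row per image row) providing
#'   `patient_id` and the label columns; row order must match `images`.
#' @param images `n x (H*W)` pixel matrix.
#' @param spec a [classifier_spec()].
#' @return a `classifier_model` with weights, input standardization stats, a
#'   training log, and `flagged_labels` (labels with a single class in the
#'   training split; their heads are trained but unreliable).
#' @export
train_classifier <- function(records, images, spec) {
  stopifnot(inherits(spec, "classifier_spec"), nrow(records) == nrow(images))
  lcols <- label_cols(spec$n_labels)
  stopifnot(all(lcols %in% names(records)))
  Y <- as.matrix(records[, lcols])
  storage.mode(Y) <- "double"

  is_val <- split_by_patient(records$patient_id, spec$val_frac, spec$seed)
  mu <- colMeans(images[!is_val, , drop = FALSE])
  sdv <- apply(images[!is_val, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  std <- function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xtr <- std(images[!is_val, , drop = FALSE]); Ytr <- Y[!is_val, , drop = FALSE]
  Xva <- std(images[is_val, , drop = FALSE]); Yva <- Y[is_val, , drop = FALSE]

  flagged <- lcols[colSums(Ytr) == 0 | colSums(Ytr) == nrow(Ytr)]
  if (length(flagged) > 0) {
    message("single-class label(s) in training data: ",
            paste(flagged, collapse = ", "))
  }

  d <- ncol(images); L <- spec$n_labels; Hd <- spec$hidden_dim
  params <- with_stream(derive_seed(spec$seed, "clf-init"), {
    if (Hd > 0) {
      list(W1 = matrix(stats::rnorm(d * Hd, 0, sqrt(1 / d)), d, Hd),
           b1 = rep(0, Hd),
           W2 = matrix(stats::rnorm(Hd * L, 0, sqrt(1 / Hd)), Hd, L),
           b2 = rep(0, L))
    } else {
      list(W2 = matrix(stats::rnorm(d * L, 0, sqrt(1 / d)), d, L),
           b2 = rep(0, L))
    }
  })
  forward <- function(X, par) {
    if (Hd > 0) {
      H1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
      list(H = H1, P = stats::plogis(sweep(H1 %*% par$W2, 2, par$b2, "+")))
    } else {
      list(H = X, P = stats::plogis(sweep(X %*% par$W2, 2, par$b2, "+")))
    }
  }
  bce <- function(P, Y) {
    eps <- 1e-12
    -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
  }

  st <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0)
  wait <- 0
  tr_loss <- va_loss <- numeric(0)
  n <- nrow(Xtr)
  for (e in seq_len(spec$epochs)) {
    fw <- forward(Xtr, params)
    tr_loss[e] <- bce(fw$P, Ytr)
    dlog <- (fw$P - Ytr) / (n * L)
    grads <- list(W2 = crossprod(fw$H, dlog), b2 = colSums(dlog))
    if (Hd > 0) {
      dH <- (dlog %*% t(params$W2)) * (1 - fw$H^2)
      grads$W1 <- crossprod(Xtr, dH)
      grads$b1 <- colSums(dH)
    }
    upd <- adam_step(params, grads, st, spec$lr)
    params <- upd$params; st <- upd$state
    va_loss[e] <- if (nrow(Xva) > 0) bce(forward(Xva, params)$P, Yva) else tr_loss[e]
    if (va_loss[e] < best$loss - 1e-7) {
      best <- list(loss = va_loss[e], params = params, epoch = e)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= spec$patience) break
    }
  }
  structure(list(params = best$params, mu = mu, sd = sdv,
                 hidden_dim = Hd, n_labels = L,
                 flagged_labels = flagged,
                 log = list(train_loss = tr_loss, val_loss = va_loss,
                            best_epoch = best$epoch),
                 spec = spec),
            class = "classifier_model")
}

#' Classifier-output (BBSD) representation of a set of images
#'
#' Reduces each image to the vector of predicted per-label probabilities.
#' Consumes images only; no gold labels enter this computation.
#'
#' @param model a `classifier_model`.
#' @param images `n x (H*W)` pixel matrix.
#' @return an `n x n_labels` matrix of probabilities in `[0, 1]` (tag
#'   `bbsd`), rows named by the image rownames.
#' @export
reduce_bbsd <- function(model, images) {
  stopifnot(inherits(model, "classifier_model"))
  X <- sweep(sweep(images, 2, model$mu), 2, model$sd, "/")
  par <- model$params
  if (model$hidden_dim > 0) {
    H1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
    P <- stats::plogis(sweep(H1 %*% par$W2, 2, par$b2, "+"))
  } else {
    P <- stats::plogis(sweep(X %*% par$W2, 2, par$b2, "+"))
  }
  rownames(P) <- rownames(images)
  colnames(P) <- label_cols(model$n_labels)
  attr(P, "tag") <- "bbsd"
  P
}

#' Combine TAE and BBSD features into one representation
#'
#' Each block is z-scored per dimension with statistics estimated on the
#' source rows only (applied identically to all rows), then the blocks are
#' concatenated. Zero-variance dimensions are mapped to zero.
#'
#' @param tae TAE feature matrix.
#' @param bbsd BBSD feature matrix, row-aligned with `tae`.
#' @param source_ids rownames of the source sample used to fit the
#'   normalization statistics (default: all rows).
#' @return an `n x (latent_dim + n_labels)` matrix (tag `tae+bbsd`).
#' @export
reduce_combined <- function(tae, bbsd, source_ids = rownames(tae)) {
  if (is.null(rownames(tae)) || is.null(rownames(bbsd)) ||
      !identical(rownames(tae), rownames(bbsd))) {
    stop("tae and bbsd feature matrices must share identical record ids",
         call. = FALSE)
  }
  zblock <- function(M) {
    src <- M[source_ids, , drop = FALSE]
    mu <- colMeans(src)
    sdv <- apply(src, 2, stats::sd)
    Z <- sweep(M, 2, mu)
    zero <- sdv == 0 | is.na(sdv)
    sdv[zero] <- 1
    Z <- sweep(Z, 2, sdv, "/")
    Z[, zero] <- 0
    Z
  }
  out <- cbind(zblock(tae), zblock(bbsd))
  rownames(out) <- rownames(tae)
  attr(out, "tag") <- "tae+bbsd"
  out
}
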