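#' Loss weights for cGAN training
#'
#' Adversarial binary cross-entropy weighted 1, with L1 and L2
#' reconstruction losses weighted 1000 and 100, and label smoothing
#' applied to the discriminator's real-label targets.
#'
#' @param adversarial,l1,l2 Non-negative loss weights.
#' @param label_smoothing Smoothing `eps` (real targets become `1 - eps`).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(adversarial = 1, l1 = 1000, l2 = 100,
                         label_smoothing = 0.1) {
  stopifnot(adversarial >= 0, l1 >= 0, l2 >= 0,
            label_smoothing >= 0, label_smoothing < 0.5)
  structure(list(adversarial = adversarial, l1 = l1, l2 = l2,
                 label_smoothing = label_smoothing),
            class = "loss_weights")
}

#' Training configuration
#'
#' Adam with a learning rate of 1e-4 for the generator and 1e-5 for the
#' discriminator, beta1 = 0.5, beta2 = 0.999, weight decay 1e-4, batch
#' size 1; `epochs_main` epochs of plain training followed by
#' `epochs_select` additional epochs during which the checkpoint with the
#' lowest validation reconstruction loss is selected.
#'
#' @param lr_generator,lr_discriminator Learning rates.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 weight decay added to the gradients.
#' @param batch_size Batch size (the training loop is defined for 1).
#' @param epochs_main,epochs_select Epoch budget.
#' @param seed Seed fanned out to weight init, data order, and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_generator = 1e-4, lr_discriminator = 1e-5,
                         beta1 = 0.5, beta2 = 0.999, weight_decay = 1e-4,
                         batch_size = 1, epochs_main = 150,
                         epochs_select = 10, seed = 1L) {
  stopifnot(lr_generator > 0, lr_discriminator > 0, epochs_main >= 1,
            epochs_select >= 1, batch_size == 1)
  structure(list(lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator, beta1 = beta1,
                 beta2 = beta2, weight_decay = weight_decay,
                 batch_size = batch_size, epochs_main = epochs_main,
                 epochs_select = epochs_select, seed = as.integer(seed)),
            class = "train_config")
}

bce_mean <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_grad <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  (-target / p + (1 - target) / (1 - p)) / length(p)
}

#' Generator loss with components
#'
#' `BCE(D(x, G(x)), 1) * w_adv + w_l1 mean|G(x) - y| + w_l2 mean((G(x) - y)^2)`.
#'
#' @param synthetic,target Normalized RF matrices.
#' @param disc_map Discriminator probability map on the synthetic pair.
#' @param weights A [loss_weights()].
#' @return List with `total`, `adv`, `l1`, `l2`.
#' @export
generator_loss <- function(synthetic, target, disc_map,
                           weights = loss_weights()) {
  if (!identical(dim(synthetic), dim(target))) stop("shape mismatch")
  if (any(!is.finite(synthetic)) || any(!is.finite(target)))
    stop("non-finite inputs to generator_loss")
  delta <- synthetic - target
  adv <- bce_mean(disc_map, 1)
  l1 <- mean(abs(delta)); l2 <- mean(delta^2)
  list(total = weights$adversarial * adv + weights$l1 * l1 +
         weights$l2 * l2,
       adv = adv, l1 = l1, l2 = l2)
}

#' Discriminator loss with label smoothing
#'
#' `BCE(map_real, 1 - eps) + BCE(map_fake, 0)`, each averaged over
#' patches.
#'
#' @param map_real,map_fake Discriminator probability maps.
#' @param label_smoothing Smoothing applied to the real labels only.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(map_real, map_fake, label_smoothing = 0.1) {
  bce_mean(map_real, 1 - label_smoothing) + bce_mean(map_fake, 0)
}

recon_loss <- function(synthetic, target, weights) {
  delta <- synthetic - target
  weights$l1 * mean(abs(delta)) + weights$l2 * mean(delta^2)
}

#' Train a conditional GAN translator
#'
#' Alternating discriminator/generator Adam updates at batch size 1. After
#' `epochs_main` epochs, training continues for `epochs_select` epochs
#' during which the parameter snapshot with the lowest validation
#' reconstruction loss (weighted L1 + L2) is kept as the selected
#' checkpoint. Deterministic given `config$seed`.
#'
#' @param train_pairs,val_pairs Lists of `list(bmode =, rf =)` with
#'   normalized `[0, 1]` matrices; the split must be at lesion level
#'   (callers are responsible for grouping planes of one lesion together).
#' @param gen_spec A [generator_spec()].
#' @param disc_spec A [discriminator_spec()] (same geometry).
#' @param weights A [loss_weights()].
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `trained_translator`: `generator`,
#'   `discriminator`, `gen_spec`, `log` (per-epoch data.frame),
#'   `selected_epoch`, `weights`, `config`.
#' @export
train_cgan <- function(train_pairs, val_pairs, gen_spec, disc_spec,
                       weights = loss_weights(), config = train_config(),
                       verbose = FALSE) {
  if (length(train_pairs) == 0) stop("empty training dataset")
  if (length(val_pairs) == 0) stop("empty validation dataset")
  set.seed(config$seed)
  G <- build_generator(gen_spec)
  D <- build_discriminator(disc_spec)
  optG <- adam_state(config$lr_generator, config$beta1, config$beta2,
                     config$weight_decay)
  optD <- adam_state(config$lr_discriminator, config$beta1, config$beta2,
                     config$weight_decay)
  n_epochs <- config$epochs_main + config$epochs_select
  log <- data.frame(epoch = integer(0), g_total = numeric(0),
                    g_adv = numeric(0), g_l1 = numeric(0),
                    g_l2 = numeric(0), d_loss = numeric(0),
                    val_recon = numeric(0), val_l1 = numeric(0))
  eps <- weights$label_smoothing
  best_val <- Inf; best_snap <- NULL; selected_epoch <- NA_integer_
  for (epoch in seq_len(n_epochs)) {
    ord <- sample.int(length(train_pairs))
    acc <- c(g_total = 0, g_adv = 0, g_l1 = 0, g_l2 = 0, d_loss = 0)
    for (ix in ord) {
      bm <- train_pairs[[ix]]$bmode
      rf <- train_pairs[[ix]]$rf
      fake <- G$forward(bm, training = TRUE)
      # --- discriminator update ---
      map_real <- D$forward(bm, rf, training = TRUE)
      D$backward(bce_grad(map_real, 1 - eps))
      map_fake <- D$forward(bm, fake, training = TRUE)
      D$backward(bce_grad(map_fake, 0))
      d_loss <- discriminator_loss(map_real, map_fake, eps)
      if (!is.finite(d_loss))
        stop("discriminator loss diverged (NaN) at epoch ", epoch)
      adam_step(D$params, optD)
      # --- generator update (through the updated discriminator) ---
      map_fake2 <- D$forward(bm, fake, training = TRUE)
      gl <- generator_loss(fake, rf, map_fake2, weights)
      if (!is.finite(gl$total))
        stop("generator loss diverged (NaN) at epoch ", epoch)
      dmap <- weights$adversarial * bce_grad(map_fake2, 1)
      dfake <- D$backward(dmap)$drf
      zero_grads(D$params)   # discard D gradients from the G pass
      n <- length(fake)
      delta <- fake - rf
      dfake <- dfake + weights$l1 * sign(delta) / n +
        weights$l2 * 2 * delta / n
      G$backward(dfake)
      adam_step(G$params, optG)
      acc <- acc + c(gl$total, gl$adv, gl$l1, gl$l2, d_loss)
    }
    acc <- acc / length(train_pairs)
    val <- vapply(val_pairs, function(p) {
      syn <- G$forward(p$bmode, training = FALSE)
      c(recon_loss(syn, p$rf, weights), mean(abs(syn - p$rf)))
    }, numeric(2))
    val_recon <- mean(val[1, ]); val_l1 <- mean(val[2, ])
    log <- rbind(log, data.frame(epoch = epoch, g_total = acc[1],
                                 g_adv = acc[2], g_l1 = acc[3],
                                 g_l2 = acc[4], d_loss = acc[5],
                                 val_recon = val_recon, val_l1 = val_l1))
    if (epoch > config$epochs_main && val_recon < best_val) {
      best_val <- val_recon
      best_snap <- snapshot_params(G$params)
      selected_epoch <- epoch
    }
    if (verbose)
      message(sprintf(
        "epoch %3d  G %.3f (adv %.3f l1 %.4f l2 %.5f)  D %.3f  val %.4f",
        epoch, acc[1], acc[2], acc[3], acc[4], acc[5], val_recon))
  }
  if (!is.null(best_snap)) restore_params(G$params, best_snap)
  rownames(log) <- NULL
  structure(list(generator = G, discriminator = D, gen_spec = gen_spec,
                 log = log, selected_epoch = selected_epoch,
                 weights = weights, config = config),
            class = "trained_translator")
}

#' @export
print.trained_translator <- function(x, ...) {
  cat(sprintf("<trained_translator> %s, %d epochs, selected epoch %d (val recon %.4f)\n",
              x$gen_spec$variant, nrow(x$log), x$selected_epoch,
              min(x$log$val_recon[x$log$epoch > x$config$epochs_main])))
  invisible(x)
}

#' Synthesize normalized RF from a normalized B-mode image
#'
#' Deterministic forward pass in inference mode; the output shares the
#' input shape and lies in `[0, 1]` (sigmoid head). Denormalize with
#' [minmax_denormalize()] and the training-set parameters to obtain RF in
#' linear units.
#'
#' @param translator A [train_cgan()] result (or any `rf_generator`).
#' @param bmode Normalized B-mode matrix in `[0, 1]`.
#' @return Normalized synthetic RF matrix.
#' @export
synthesize_rf <- function(translator, bmode) {
  G <- if (inherits(translator, "trained_translator"))
    translator$generator else translator
  spec <- G$spec
  if (!all(dim(bmode) == c(spec$rows, spec$cols)))
    stop(sprintf("bmode must be %d x %d for this model",
                 spec$rows, spec$cols))
  if (min(bmode) < -1e-9 || max(bmode) > 1 + 1e-9)
    stop("bmode must be normalized to [0, 1]")
  G$forward(bmode, training = FALSE)
}
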