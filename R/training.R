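#' Training configuration
#'
#' Defaults are the published hyperparameter set: learning rate 0.0002, Adam
#' momentum 0.5, reconstruction weight `lambda1 = 100`, adversarial weight
#' `lambda2 = 1`, exponential learning-rate decay 0.99 per epoch, batch size
#' 1, 10 epochs, dropout 0.5, loss logged every 100 iterations, model saved
#' every 500 iterations.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param adam_beta1 Adam first-moment coefficient (the "momentum" 0.5).
#' @param adam_beta2 Adam second-moment coefficient.
#' @param lambda1 Weight of the generator reconstruction (L1) loss.
#' @param lambda2 Weight of the adversarial loss.
#' @param exponential_decay Learning-rate multiplier applied once per epoch.
#' @param batch_size Items per update (the method trains at 1).
#' @param epochs Passes over the dataset.
#' @param dropout Generator dropout rate.
#' @param loss_log_every Record losses every this many iterations.
#' @param checkpoint_every Write a checkpoint every this many iterations.
#' @param seed Master seed for initialization and data order.
#' @param reconstruction_only If `TRUE`, the generator minimizes the pure L1
#'   objective (no adversarial feedback term) and its image path receives the
#'   intact original slice instead of the whitened one.
#' @return A `training_config`.
#' @export
training_config <- function(learning_rate = 2e-4, adam_beta1 = 0.5,
                            adam_beta2 = 0.999, lambda1 = 100, lambda2 = 1,
                            exponential_decay = 0.99, batch_size = 1L,
                            epochs = 10L, dropout = 0.5,
                            loss_log_every = 100L, checkpoint_every = 500L,
                            seed = 1L, reconstruction_only = FALSE) {
  num_fields <- list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                     adam_beta2 = adam_beta2, lambda1 = lambda1,
                     lambda2 = lambda2, exponential_decay = exponential_decay,
                     batch_size = batch_size, epochs = epochs,
                     loss_log_every = loss_log_every,
                     checkpoint_every = checkpoint_every)
  for (nm in names(num_fields))
    if (!is.numeric(num_fields[[nm]]) || length(num_fields[[nm]]) != 1 ||
        !is.finite(num_fields[[nm]]) || num_fields[[nm]] <= 0)
      ct_error("config_error", sprintf("invalid value for field '%s'", nm))
  if (dropout < 0 || dropout >= 1)
    ct_error("config_error", "invalid value for field 'dropout'")
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, lambda1 = lambda1, lambda2 = lambda2,
                 exponential_decay = exponential_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 loss_log_every = as.integer(loss_log_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed), reconstruction_only = isTRUE(reconstruction_only)),
            class = "training_config")
}

#' Combined adversarial objective
#'
#' `lambda1 * gen_loss + lambda2 * disc_loss`, the weighted sum the min-max
#' game optimizes.
#'
#' @param gen_loss,disc_loss Scalar losses.
#' @param config A [training_config()] providing the weights.
#' @return Scalar.
#' @export
total_loss <- function(gen_loss, disc_loss, config = training_config()) {
  if (!is.finite(gen_loss) || !is.finite(disc_loss))
    ct_error("invalid_input", "losses must be finite")
  config$lambda1 * gen_loss + config$lambda2 * disc_loss
}

# standardize one training pair: returns normalized real, whitened input and
# the statistics used
prep_item <- function(slice, mask, reconstruction_only = FALSE) {
  nr <- normalize_slice(slice)
  am <- make_attention_map(slice, mask)
  wn <- (am$pixels - nr$source_mean) / nr$source_sd
  list(real = nr$pixels, whitened = wn,
       image_in = if (reconstruction_only) nr$pixels else wn,
       mean = nr$source_mean, sd = nr$source_sd, mask = am$mask$pixels)
}

#' Train the adversarial inpainting model
#'
#' Alternates one discriminator update (ascending the patch log loss) and one
#' generator update (descending `lambda1 * L1` plus a non-saturating
#' adversarial term) per item, with Adam, per-epoch exponential
#' learning-rate decay, periodic loss logging and checkpointing. Fully
#' deterministic given the configuration seed in single-threaded BLAS.
#'
#' @param dataset List of `list(slice, mask)` pairs (as produced by
#'   [generate_dataset()]).
#' @param gen_config A [generator_config()].
#' @param disc_config A [discriminator_config()]; defaults to the canonical
#'   geometry at the generator's input size.
#' @param train_config A [training_config()].
#' @param checkpoint_dir Directory for periodic checkpoints (none written
#'   when `NULL`).
#' @param verbose Print a progress line at each loss record.
#' @return List with `generator`, `discriminator`, `losses` (data frame of
#'   iteration, generator_loss, discriminator_loss, total_loss),
#'   `checkpoints` (paths written).
#' @export
train <- function(dataset, gen_config, disc_config = NULL,
                  train_config = training_config(), checkpoint_dir = NULL,
                  verbose = FALSE) {
  if (length(dataset) == 0) ct_error("empty_dataset", "dataset is empty")
  if (!inherits(gen_config, "generator_config"))
    err_config("gen_config must be a generator_config")
  if (is.null(disc_config))
    disc_config <- if (gen_config$input_size >= 512L)
      discriminator_config(gen_config$input_size)
    else toy_discriminator_config(gen_config$input_size)
  if (disc_config$input_size != gen_config$input_size)
    err_config("generator and discriminator input sizes differ")
  tc <- train_config
  gen_config$dropout_rate <- tc$dropout
  gen <- build_generator(gen_config, seed = tc$seed + 1L)
  disc <- build_discriminator(disc_config, seed = tc$seed + 2L)
  n <- length(dataset)
  iters <- tc$epochs * n
  records <- vector("list", iters %/% tc$loss_log_every + 1L)
  nrec <- 0L
  checkpoints <- character()
  eps <- 1e-7
  t <- 0L
  with_seed(tc$seed + 3L, {
    lr <- tc$learning_rate
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      for (idx in ord) {
        t <- t + 1L
        item <- dataset[[idx]]
        it <- prep_item(item$slice %||% item[[1]], item$mask %||% item[[2]],
                        tc$reconstruction_only)
        npix <- length(it$real)
        fake <- generator_forward(gen, it$image_in, it$whitened,
                                  training = TRUE)
        # --- discriminator step: minimize the negated patch log loss
        zero_grads(disc$layers)
        inp_real <- cbind(as.vector(it$real), as.vector(it$whitened))
        inp_fake <- cbind(as.vector(fake), as.vector(it$whitened))
        outR <- disc_fwd(disc, inp_real, training = TRUE)
        mR <- outR$map
        nm <- length(mR)
        rC <- pmin(pmax(mR, eps), 1 - eps)
        dR <- -1 / (nm * rC) * (mR > eps & mR < 1 - eps)
        disc_bwd(disc, dR)
        outF <- disc_fwd(disc, inp_fake, training = TRUE)
        mF <- outF$map
        fC <- pmin(pmax(mF, eps), 1 - eps)
        dF <- 1 / (nm * (1 - fC)) * (mF > eps & mF < 1 - eps)
        disc_bwd(disc, dF)
        loss_d <- mean(log(rC)) + mean(log(1 - fC))
        adam_step(disc$layers, lr, tc$adam_beta1, tc$adam_beta2, 1e-8, t)
        # --- generator step: lambda1 * L1 + lambda2 * (-mean log D(fake))
        zero_grads(gen$layers)
        loss_l1 <- mean(abs(fake - it$real))
        dfake <- sign(fake - it$real) / npix * tc$lambda1
        if (!tc$reconstruction_only) {
          outG <- disc_fwd(disc, inp_fake, training = TRUE)
          mG <- pmin(pmax(outG$map, eps), 1 - eps)
          dmapG <- -1 / (nm * mG) * (outG$map > eps) * tc$lambda2
          dxin <- disc_bwd(disc, dmapG)
          dfake <- dfake + matrix(dxin[, 1], nrow(fake), ncol(fake))
        }
        generator_backward(gen, dfake)
        adam_step(gen$layers, lr, tc$adam_beta1, tc$adam_beta2, 1e-8, t)
        if (!is.finite(loss_l1) || !is.finite(loss_d))
          ct_error("diverged_training",
                   sprintf("non-finite loss at iteration %d", t))
        if (t %% tc$loss_log_every == 0L) {
          nrec <- nrec + 1L
          records[[nrec]] <- data.frame(
            iteration = t, generator_loss = loss_l1,
            discriminator_loss = loss_d,
            total_loss = tc$lambda1 * loss_l1 + tc$lambda2 * loss_d)
          if (verbose)
            message(sprintf("iter %d: G %.4f D %.4f", t, loss_l1, loss_d))
        }
        if (t %% tc$checkpoint_every == 0L && !is.null(checkpoint_dir)) {
          if (!dir.exists(checkpoint_dir))
            dir.create(checkpoint_dir, recursive = TRUE)
          path <- file.path(checkpoint_dir, sprintf("checkpoint_%06d.rds", t))
          save_checkpoint(gen, disc, path)
          checkpoints <- c(checkpoints, path)
        }
      }
      lr <- lr * tc$exponential_decay
    }
  })
  list(generator = gen, discriminator = disc,
       losses = do.call(rbind, records[seq_len(nrec)]) %||%
         data.frame(iteration = integer(), generator_loss = numeric(),
                    discriminator_loss = numeric(), total_loss = numeric()),
       checkpoints = checkpoints, train_config = tc)
}

#' Save generator (and optionally discriminator) parameters
#'
#' @param generator A `generator_state`.
#' @param discriminator Optional `discriminator_state`.
#' @param path Destination file (RDS).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(generator, discriminator = NULL, path) {
  obj <- list(gen_config = generator$config,
              gen_params = layers_dump(generator$layers),
              disc_config = if (!is.null(discriminator))
                discriminator$config,
              disc_params = if (!is.null(discriminator))
                layers_dump(discriminator$layers))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return List with `generator` and (possibly `NULL`) `discriminator`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    ct_error("corrupt_file", sprintf("checkpoint not found: %s", path))
  obj <- readRDS(path)
  gen <- build_generator(obj$gen_config, seed = 0L)
  layers_restore(gen$layers, obj$gen_params)
  disc <- NULL
  if (!is.null(obj$disc_config)) {
    disc <- build_discriminator(obj$disc_config, seed = 0L)
    layers_restore(disc$layers, obj$disc_params)
  }
  list(generator = gen, discriminator = disc)
}

#' Synthesize a slice from a whitened input
#'
#' Standardizes the whitened slice with its own statistics, runs the
#' generator in evaluation mode (deterministic), inverts the
#' standardization and clamps to the raw range `[0, 4096]`.
#'
#' @param gen_state A trained `generator_state`.
#' @param whitened An [make_attention_map()] result (or matrix) whose tumor
#'   regions are set to the white value.
#' @return A [ct_slice()] with the whitened regions filled in.
#' @export
synthesize <- function(gen_state, whitened) {
  px <- as_pixel_matrix(whitened)
  size <- gen_state$config$input_size
  if (nrow(px) != size || ncol(px) != size)
    err_shape(sprintf("input is %dx%d but the generator expects %dx%d",
                      nrow(px), ncol(px), size, size))
  m <- mean(px)
  s <- sqrt(mean((px - m)^2))
  if (s == 0) ct_error("degenerate_image", "constant whitened input")
  wn <- (px - m) / s
  out <- generator_forward(gen_state, wn, wn, training = FALSE)
  raw <- out * s + m
  raw[raw < 0] <- 0
  raw[raw > RAW_MAX] <- RAW_MAX
  ct_slice(raw)
}
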