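# Patch classifier: a compact convolutional network trained on chopped
# patches. The network is authored in the package (src/cnn.cpp); all
# randomness — weight initialisation, shuffling, the validation split and
# dropout masks — is drawn from R's RNG so a seed fixes the whole fit.

#' Training configuration for the patch classifier
#'
#' Defaults follow the reference training regime: batch size 32, Adam at
#' its conventional default learning rate (1e-3), a 20% validation split
#' and 30 epochs. The architecture is a LeNet-class network — two 3x3
#' convolution blocks (ReLU + 2x2 max-pool) with `filters` feature maps,
#' a `dense_units` fully connected layer with dropout, and a 2-way
#' softmax — and is a configuration choice, not hard-coded.
#'
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 32).
#' @param validation_fraction Held-out fraction, stratified by class
#'   (default 0.2).
#' @param learning_rate Adam step size (default 1e-3, the framework
#'   convention for "default").
#' @param filters Length-2 integer vector: feature maps of the two
#'   convolution blocks (default `c(32, 64)`).
#' @param dense_units Width of the fully connected layer (default 128).
#' @param dropout Dropout probability on the dense layer (default 0.5).
#' @param decision_threshold Probability threshold for calling a patch
#'   greenery (default 0.5).
#' @param class_weights `NULL` (off, the default), `"balanced"`, or a
#'   length-2 numeric `c(other, greenery)` of loss weights.
#' @param seed Integer seed for the whole fit.
#' @return A `cpm_config` list.
#' @export
cpm_config <- function(epochs = 30L, batch_size = 32L,
                       validation_fraction = 0.2, learning_rate = 1e-3,
                       filters = c(32L, 64L), dense_units = 128L,
                       dropout = 0.5, decision_threshold = 0.5,
                       class_weights = NULL, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop("decision_threshold must lie in (0, 1)")
  if (length(filters) != 2L || any(filters < 1L))
    stop("filters must be two positive counts")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 learning_rate = learning_rate,
                 optimizer = "adam",
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 decision_threshold = decision_threshold,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "cpm_config")
}

# Feature dimensions implied by the patch size.
.cpm_dims <- function(patch_px, filters, dense_units) {
  S <- patch_px
  if (S < 12L) stop("patch_px must be at least 12 for two conv/pool blocks")
  ho1 <- S - 2L; hp1 <- ho1 %/% 2L
  ho2 <- hp1 - 2L; hp2 <- ho2 %/% 2L
  list(flat = hp2 * hp2 * filters[2], hp2 = hp2)
}

.cpm_init_params <- function(patch_px, filters, dense_units) {
  he <- function(nout, nin) matrix(rnorm(nout * nin, sd = sqrt(2 / nin)),
                                   nout, nin)
  flat <- .cpm_dims(patch_px, filters, dense_units)$flat
  list(W1 = he(filters[1], 27L),            b1 = numeric(filters[1]),
       W2 = he(filters[2], 9L * filters[1]), b2 = numeric(filters[2]),
       W3 = he(dense_units, flat),           b3 = numeric(dense_units),
       W4 = he(2L, dense_units),             b4 = numeric(2L))
}

#' Fit the chopped-picture patch classifier
#'
#' Trains the convolutional patch classifier on a chopped patch set with
#' minibatch Adam and a seeded, class-stratified validation split.
#'
#' @param patchset A `cpm_patchset` from [build_patchset()] containing
#'   both classes.
#' @param config A [cpm_config()].
#' @return An object of class `cpm` with components `params` (weights),
#'   `patch_px`, `config`, `history` (per-epoch data.frame with columns
#'   `epoch, loss, accuracy, val_loss, val_accuracy`), `n_train`,
#'   `n_val`, and `class_counts`. Methods: [predict.cpm()],
#'   `print`, `summary`, `coef` (the weight list) and `plot` (training
#'   curves).
#' @examples
#' \donttest{
#' # a tiny colour-separable problem learns within a few epochs
#' set.seed(1)
#' n <- 60
#' px <- vapply(seq_len(n), function(i) {
#'   col <- if (i <= n / 2) c(0.1, 0.6, 0.1) else c(0.5, 0.5, 0.5)
#'   as.vector(array(rep(col, each = 32 * 32), c(32, 32, 3)))
#' }, numeric(3 * 32 * 32))
#' ps <- greenview:::.new_patchset(px, rep(c(TRUE, FALSE), each = n / 2),
#'   data.frame(image_id = "x", x = 0, y = 0)[rep(1, n), ], 32L)
#' fit <- cpm_train(ps, cpm_config(epochs = 3, filters = c(4, 8),
#'                                 dense_units = 16, seed = 1))
#' fit$history$accuracy
#' }
#' @export
cpm_train <- function(patchset, config = cpm_config()) {
  if (!inherits(patchset, "cpm_patchset")) stop("patchset must be a cpm_patchset")
  n <- length(patchset$label)
  if (n == 0L) stop("empty patchset")
  if (length(unique(patchset$label)) < 2L)
    stop("patchset contains a single class; need both greenery and other")
  p <- patchset$patch_px
  set.seed(config$seed)

  # stratified validation split
  idx_pos <- which(patchset$label)
  idx_neg <- which(!patchset$label)
  val_idx <- c(sample(idx_pos, max(1L, floor(length(idx_pos) *
                                             config$validation_fraction))),
               sample(idx_neg, max(1L, floor(length(idx_neg) *
                                             config$validation_fraction))))
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) < 2L) stop("too few patches to train")

  Xtr <- patchset$pixels[, train_idx, drop = FALSE]
  ytr <- as.integer(patchset$label[train_idx])
  Xva <- patchset$pixels[, val_idx, drop = FALSE]
  yva <- as.integer(patchset$label[val_idx])

  w_class <- c(1, 1)
  if (identical(config$class_weights, "balanced")) {
    w_class <- length(ytr) / (2 * c(sum(ytr == 0L), sum(ytr == 1L)))
  } else if (is.numeric(config$class_weights)) {
    w_class <- config$class_weights
  }
  use_w <- !all(w_class == 1)

  params <- .cpm_init_params(p, config$filters, config$dense_units)
  adam_m <- lapply(params, function(x) x * 0)
  adam_v <- lapply(params, function(x) x * 0)
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  keep <- 1 - config$dropout
  d <- config$dense_units

  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                     accuracy = NA_real_, val_loss = NA_real_,
                     val_accuracy = NA_real_)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(ytr))
    starts <- seq(1L, length(ord), by = config$batch_size)
    ep_loss <- 0; ep_correct <- 0L
    for (s0 in starts) {
      bi <- ord[s0:min(s0 + config$batch_size - 1L, length(ord))]
      nb <- length(bi)
      dropmask <- if (config$dropout > 0)
        matrix(rbinom(d * nb, 1L, keep) / keep, d, nb)
      else matrix(0, 0L, 0L)
      wb <- if (use_w) w_class[ytr[bi] + 1L] else numeric(0)
      res <- cnn_batch_cpp(params, Xtr[, bi, drop = FALSE], ytr[bi],
                           dropmask, wb, p, TRUE)
      ep_loss <- ep_loss + res$loss * nb
      ep_correct <- ep_correct + res$correct
      t_step <- t_step + 1L
      g <- res$grads
      for (nm in names(params)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^t_step)
        vhat <- adam_v[[nm]] / (1 - b2^t_step)
        params[[nm]] <- params[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    val <- .cpm_eval(params, Xva, yva, p)
    hist$loss[epoch] <- ep_loss / length(ytr)
    hist$accuracy[epoch] <- ep_correct / length(ytr)
    hist$val_loss[epoch] <- val$loss
    hist$val_accuracy[epoch] <- val$accuracy
  }

  structure(list(params = params, patch_px = p, config = config,
                 history = hist,
                 n_train = length(ytr), n_val = length(yva),
                 class_counts = c(greenery = sum(patchset$label),
                                  other = sum(!patchset$label))),
            class = "cpm")
}

# loss/accuracy of fixed weights on a labelled set, in memory-bounded chunks
.cpm_eval <- function(params, X, y, patch_px, chunk = 256L) {
  n <- length(y)
  loss <- 0; correct <- 0L
  for (s0 in seq(1L, n, by = chunk)) {
    ii <- s0:min(s0 + chunk - 1L, n)
    res <- cnn_batch_cpp(params, X[, ii, drop = FALSE], y[ii],
                         matrix(0, 0L, 0L), numeric(0), patch_px, FALSE)
    loss <- loss + res$loss * length(ii)
    correct <- correct + res$correct
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Greenery probabilities for patches
#'
#' @param object A fitted `cpm` model.
#' @param newdata A `cpm_patchset`, a `(3*patch_px^2) x N` pixel matrix,
#'   or a single `patch_px x patch_px x 3` array.
#' @param type `"prob"` (default) for greenery probabilities in
#'   `[0, 1]`, `"class"` for logical calls at the model's decision
#'   threshold.
#' @param batch_size Inference chunk size; results are independent of it.
#' @param ... Unused.
#' @return Numeric (or logical) vector, one value per patch, in input
#'   order.
#' @export
predict.cpm <- function(object, newdata, type = c("prob", "class"),
                        batch_size = 256L, ...) {
  type <- match.arg(type)
  p <- object$patch_px
  X <- if (inherits(newdata, "cpm_patchset")) newdata$pixels
       else if (is.array(newdata) && length(dim(newdata)) == 3L)
         matrix(as.vector(newdata), ncol = 1L)
       else as.matrix(newdata)
  if (nrow(X) != 3L * p * p)
    stop(sprintf("patches must be %dx%d RGB (%d values per patch), got %d",
                 p, p, 3L * p * p, nrow(X)))
  n <- ncol(X)
  if (n == 0L) return(if (type == "prob") numeric(0) else logical(0))
  probs <- numeric(n)
  for (s0 in seq(1L, n, by = batch_size)) {
    ii <- s0:min(s0 + batch_size - 1L, n)
    probs[ii] <- cnn_probs_cpp(object$params, X[, ii, drop = FALSE], p)[2L, ]
  }
  if (type == "prob") probs else probs > object$config$decision_threshold
}

#' @export
print.cpm <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("Chopped-picture patch classifier (CNN)\n")
  cat(sprintf("  patches: %d train / %d validation (%d greenery, %d other)\n",
              x$n_train, x$n_val, x$class_counts["greenery"],
              x$class_counts["other"]))
  cat(sprintf("  architecture: conv %d/%d (3x3) + dense %d, dropout %.2f\n",
              x$config$filters[1], x$config$filters[2], x$config$dense_units,
              x$config$dropout))
  cat(sprintf("  after %d epochs: accuracy %.3f, validation accuracy %.3f\n",
              h$epoch, h$accuracy, h$val_accuracy))
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  structure(list(model = object), class = "summary.cpm")
}

#' @export
print.summary.cpm <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  optimizer: %s (lr %g), batch size %d, seed %d\n",
              m$config$optimizer, m$config$learning_rate,
              m$config$batch_size, m$config$seed))
  cat(sprintf("  decision threshold: %.2f\n", m$config$decision_threshold))
  cat("\nTraining history (last 5 epochs):\n")
  print(tail(m$history, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) object$params

#' Training curves of a fitted patch classifier
#'
#' Two panels: accuracy and loss per epoch, training and validation.
#'
#' @param x A fitted `cpm`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cpm <- function(x, ...) {
  h <- x$history
  old <- par(mfrow = c(1, 2))
  on.exit(par(old))
  matplot(h$epoch, cbind(h$accuracy, h$val_accuracy), type = "l", lty = 1,
          col = c("black", "forestgreen"), xlab = "epoch",
          ylab = "accuracy", ...)
  legend("bottomright", c("training", "validation"), lty = 1,
         col = c("black", "forestgreen"), bty = "n")
  matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l", lty = 1,
          col = c("black", "forestgreen"), xlab = "epoch", ylab = "loss", ...)
  invisible(x)
}

#' Save / load a fitted patch classifier
#'
#' The model is written as an RDS file plus a JSON sidecar
#' (`<path>.json`) echoing the patch size, threshold, configuration and
#' final metrics for auditability. A reloaded model reproduces
#' predictions exactly.
#'
#' @param model A fitted `cpm`.
#' @param path Destination RDS path.
#' @return `save_cpm` returns `path` invisibly; `load_cpm` the model.
#' @export
save_cpm <- function(model, path) {
  if (!inherits(model, "cpm")) stop("model must be a cpm fit")
  saveRDS(model, path)
  h <- model$history[nrow(model$history), ]
  jsonlite::write_json(
    list(patch_px = model$patch_px,
         decision_threshold = model$config$decision_threshold,
         config = model$config[c("epochs", "batch_size",
                                 "validation_fraction", "learning_rate",
                                 "optimizer", "filters", "dense_units",
                                 "dropout", "seed")],
         final = list(accuracy = h$accuracy, val_accuracy = h$val_accuracy,
                      loss = h$loss, val_loss = h$val_loss)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cpm
#' @export
load_cpm <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cpm")) stop("not a saved cpm model: ", path)
  model
}
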