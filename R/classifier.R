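#' Network and training configuration
#'
#' A single-hidden-layer feed-forward classifier: 58 inputs, a 10-unit tanh
#' hidden stage, 3-way softmax output trained by full-batch Adam on the
#' cross-entropy, with patience-based early stopping against the validation
#' partition and restoration of the best-validation-epoch weights.
#'
#' @param input_dim,hidden_units,output_dim Architecture (58, 10, 3).
#' @param max_epochs Upper bound on training epochs (default 1000).
#' @param patience Consecutive epochs without a new best validation loss
#'   tolerated before stopping (default 6).
#' @param split_fractions Train/validation/test fractions, summing to 1
#'   (default 0.70 / 0.15 / 0.15).
#' @param seed Integer seed for splitting and weight initialization.
#' @param learning_rate,weight_decay Adam step size (default 0.02) and L2
#'   penalty (default 1e-4).
#' @param stratified Preserve class proportions per partition (default
#'   `FALSE`, plain random assignment).
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_dim = 58, hidden_units = 10, output_dim = 3,
                           max_epochs = 1000, patience = 6,
                           split_fractions = c(0.70, 0.15, 0.15), seed = 1,
                           learning_rate = 0.02, weight_decay = 1e-4,
                           stratified = FALSE) {
  if (any(c(input_dim, hidden_units, output_dim) < 1))
    stop_renotex("all dimensions must be positive",
                 class = "renotex_config_error")
  if (abs(sum(split_fractions) - 1) > 1e-9 || length(split_fractions) != 3)
    stop_renotex("split_fractions must be three numbers summing to 1",
                 class = "renotex_config_error")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 output_dim = as.integer(output_dim),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 split_fractions = split_fractions, seed = as.integer(seed),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 stratified = isTRUE(stratified)),
            class = "network_config")
}

#' Assign records to train / validation / test partitions
#'
#' Seeded random assignment with sizes `n_train = round(0.70 n)`,
#' `n_val = round(0.15 n)` (half away from zero), remainder test. In
#' stratified mode the same rule is applied within each class, so partition
#' class proportions track the cohort within one record.
#'
#' @param tab A `feature_table` (or anything with an `id` column).
#' @param cfg A [network_config()].
#' @return Character vector of `"train"`, `"val"`, `"test"`, named by id.
#' @export
split_data <- function(tab, cfg = network_config()) {
  n <- nrow(tab)
  if (n == 0) stop_renotex("cannot split an empty table",
                           class = "renotex_config_error")
  fr <- cfg$split_fractions
  assign_one <- function(m) {
    n_tr <- round_half_up(fr[1] * m)
    n_va <- round_half_up(fr[2] * m)
    n_te <- m - n_tr - n_va
    sample(rep(c("train", "val", "test"), c(n_tr, n_va, n_te)))
  }
  withr::with_seed(cfg$seed, {
    if (cfg$stratified) {
      out <- character(n)
      for (cls in unique(tab$label)) {
        idx <- which(tab$label == cls)
        out[idx] <- assign_one(length(idx))
      }
    } else {
      out <- assign_one(n)
    }
    out
  }) -> part
  for (p in c("train", "val", "test"))
    if (fr[match(p, c("train", "val", "test"))] > 0 && !any(part == p))
      warning(sprintf("partition '%s' is empty at n = %d", p, n))
  stats::setNames(part, tab$id)
}

fit_scaler <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

# Map to [-1, 1] by training min/max; zero-range features map to 0 and
# out-of-range inputs are clipped, so unseen extremes stay finite.
apply_scaler <- function(scaler, x) {
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  z <- sweep(sweep(x, 2, scaler$min), 2, rng, "/") * 2 - 1
  z[, scaler$max == scaler$min] <- 0
  clip01(z, -1, 1)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(w, x) {
  h <- tanh(sweep(x %*% w$w1, 2, w$b1, "+"))
  list(h = h, p = softmax_rows(sweep(h %*% w$w2, 2, w$b2, "+")))
}

cross_entropy <- function(p, y_onehot) {
  -mean(log(pmax(rowSums(p * y_onehot), 1e-12)))
}

#' Train the feed-forward classifier
#'
#' Full-batch Adam on the softmax cross-entropy over min-max-scaled inputs
#' (scaler fitted on the training partition only). Training stops at
#' `max_epochs` or once `patience` consecutive epochs fail to improve the
#' best validation loss; the returned weights are those of the best
#' validation epoch. With an empty validation partition the training loss
#' takes its place.
#'
#' @param tab A `feature_table`.
#' @param split Output of [split_data()] (computed from `cfg` if omitted).
#' @param cfg A [network_config()].
#' @return Object of class `trained_network`: weights, scaler, per-epoch
#'   `history` (train/val loss), `best_epoch`, `config`, `split`.
#' @export
train_network <- function(tab, split = NULL, cfg = network_config()) {
  if (is.null(split)) split <- split_data(tab, cfg)
  fm <- feature_matrix(tab)
  if (ncol(fm$x) != cfg$input_dim)
    stop_renotex("feature matrix has %d columns, network expects %d",
                 ncol(fm$x), cfg$input_dim, class = "renotex_schema_error")
  tr <- which(split[tab$id] == "train")
  va <- which(split[tab$id] == "val")
  if (length(unique(fm$y[tr])) < 2)
    stop_renotex("training partition must contain at least two classes",
                 class = "renotex_config_error")
  onehot <- function(y) {
    m <- matrix(0, length(y), length(CLASS_LEVELS))
    m[cbind(seq_along(y), as.integer(y))] <- 1
    m
  }
  scaler <- fit_scaler(fm$x[tr, , drop = FALSE])
  xtr <- unname(apply_scaler(scaler, fm$x[tr, , drop = FALSE]))
  ytr <- onehot(fm$y[tr])
  have_val <- length(va) > 0
  if (have_val) {
    xva <- unname(apply_scaler(scaler, fm$x[va, , drop = FALSE]))
    yva <- onehot(fm$y[va])
  }

  d <- cfg$input_dim; h <- cfg$hidden_units; k <- cfg$output_dim
  w <- withr::with_seed(cfg$seed, list(
    w1 = matrix(stats::rnorm(d * h, sd = 1 / sqrt(d)), d, h),
    b1 = numeric(h),
    w2 = matrix(stats::rnorm(h * k, sd = 1 / sqrt(h)), h, k),
    b2 = numeric(k)))
  mom <- lapply(w, function(p) p * 0)
  vel <- lapply(w, function(p) p * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  ntr <- length(tr)

  hist_train <- numeric(0); hist_val <- numeric(0)
  best <- list(loss = Inf, epoch = 0L, w = w)
  fails <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- mlp_forward(w, xtr)
    dz2 <- (fw$p - ytr) / ntr
    grad <- list(
      w1 = NULL, b1 = NULL,
      w2 = crossprod(fw$h, dz2) + cfg$weight_decay * w$w2,
      b2 = colSums(dz2))
    dh <- (dz2 %*% t(w$w2)) * (1 - fw$h^2)
    grad$w1 <- crossprod(xtr, dh) + cfg$weight_decay * w$w1
    grad$b1 <- colSums(dh)
    for (nm in names(w)) {
      mom[[nm]] <- b1m * mom[[nm]] + (1 - b1m) * grad[[nm]]
      vel[[nm]] <- b2m * vel[[nm]] + (1 - b2m) * grad[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1m^epoch)
      vhat <- vel[[nm]] / (1 - b2m^epoch)
      w[[nm]] <- w[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    tr_loss <- cross_entropy(mlp_forward(w, xtr)$p, ytr)
    va_loss <- if (have_val) cross_entropy(mlp_forward(w, xva)$p, yva) else tr_loss
    hist_train[epoch] <- tr_loss
    hist_val[epoch] <- va_loss
    if (va_loss < best$loss) {
      best <- list(loss = va_loss, epoch = epoch, w = w)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= cfg$patience) break
    }
  }

  structure(list(weights = best$w, scaler = scaler,
                 history = data.frame(epoch = seq_along(hist_train),
                                      train_loss = hist_train,
                                      val_loss = hist_val),
                 best_epoch = best$epoch, config = cfg, split = split,
                 class_levels = CLASS_LEVELS),
            class = "trained_network")
}

#' Class-probability predictions
#'
#' @param net A [train_network()] result.
#' @param x Numeric matrix (n x 58) or a `feature_table`.
#' @return Matrix of per-class probabilities, rows summing to 1, columns in
#'   canonical class order.
#' @export
predict_proba <- function(net, x) {
  stopifnot(inherits(net, "trained_network"))
  if (inherits(x, "feature_table")) x <- feature_matrix(x)$x
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$config$input_dim)
    stop_renotex("input has %d columns, network expects %d",
                 ncol(x), net$config$input_dim, class = "renotex_schema_error")
  p <- mlp_forward(net$weights, apply_scaler(net$scaler, x))$p
  colnames(p) <- net$class_levels
  p
}

#' Hard class predictions
#'
#' @inheritParams predict_proba
#' @return Factor over the canonical class levels.
#' @export
predict_class <- function(net, x) {
  p <- predict_proba(net, x)
  factor(net$class_levels[max.col(p, ties.method = "first")],
         levels = net$class_levels)
}

#' Serialize / restore a trained network as JSON
#'
#' Weights, scaler, configuration, split, and training history travel in a
#' single human-readable JSON container.
#'
#' @param net A `trained_network`.
#' @param path Destination file.
#' @return `path` invisibly (save); the restored network (load).
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "trained_network"))
  payload <- list(
    weights = lapply(net$weights, function(m)
      if (is.matrix(m)) list(dim = dim(m), data = as.vector(m))
      else list(dim = NULL, data = as.vector(m))),
    scaler = net$scaler,
    history = as.list(net$history),
    best_epoch = net$best_epoch,
    config = unclass(net$config),
    split = as.list(net$split),
    class_levels = net$class_levels)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  w <- lapply(p$weights, function(el) {
    data <- as.numeric(unlist(el$data))
    dim <- as.integer(unlist(el$dim))
    if (length(dim) == 2) matrix(data, dim[1], dim[2]) else data
  })
  cfg_args <- p$config[names(p$config) %in% names(formals(network_config))]
  cfg_args <- lapply(cfg_args, unlist)
  cfg <- do.call(network_config, cfg_args)
  structure(list(weights = w,
                 scaler = lapply(p$scaler, function(v) as.numeric(unlist(v))),
                 history = as.data.frame(lapply(p$history,
                                                function(v) unlist(v))),
                 best_epoch = unlist(p$best_epoch), config = cfg,
                 split = unlist(p$split),
                 class_levels = unlist(p$class_levels)),
            class = "trained_network")
}
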