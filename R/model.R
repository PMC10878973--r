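# The learnable head: a three-layer perceptron mapping baseline features to
# mixture weights on the K-simplex, trained by mini-batch SGD on the
# interval-censored mixture loss. Because the Weibull atoms are frozen, the
# per-record atom survival terms are precomputed once and training reduces to
# cheap dense matrix algebra.

#' Training configuration
#'
#' @param learning_rate SGD step size (> 0). Default 3e-3 for the tabular
#'   (metadata) path, selected by validation-loss grid search on simulated
#'   cohorts.
#' @param momentum Classical momentum coefficient. Default 0.9.
#' @param epochs Number of passes over the training data. Default 300.
#' @param batch_size Mini-batch size. Default 32.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param gamma Weight on the event-likelihood loss term (see
#'   [loss_config()]). Default 1.
#' @param validation_fraction Fraction of participants held out for
#'   validation loss tracking, in `[0, 1)`. Default 0 (train on everything).
#' @param hidden Two hidden-layer widths of the MLP. Default `c(32, 16)`,
#'   sized for the 12-covariate tabular path; image-feature inputs warrant
#'   wider layers.
#' @param weight_decay L2 penalty coefficient on the weight matrices
#'   (biases excluded). Default 1e-3.
#' @param prob_floor Probability clamp inside logarithms.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 3e-3, momentum = 0.9, epochs = 300L,
                         batch_size = 32L, seed = 42L, gamma = 1,
                         validation_fraction = 0, hidden = c(32L, 16L),
                         weight_decay = 1e-3, prob_floor = 1e-12) {
  abort_if(learning_rate <= 0, "`learning_rate` must be > 0")
  abort_if(epochs < 1, "`epochs` must be >= 1")
  abort_if(momentum < 0 || momentum >= 1, "`momentum` must be in [0, 1)")
  abort_if(validation_fraction < 0 || validation_fraction >= 1,
           "`validation_fraction` must be in [0, 1)")
  abort_if(length(hidden) != 2L || any(hidden < 1),
           "`hidden` must give two positive layer widths")
  abort_if(weight_decay < 0, "`weight_decay` must be non-negative")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), gamma = gamma,
                 validation_fraction = validation_fraction,
                 hidden = as.integer(hidden), weight_decay = weight_decay,
                 prob_floor = prob_floor),
            class = "train_config")
}

# He-initialized hidden layers; the output layer starts at zero so an
# untrained network emits uniform mixture weights 1/K.
mlp_init <- function(input_dim, hidden, K, seed) {
  set.seed(seed)
  h1 <- hidden[1L]; h2 <- hidden[2L]
  list(
    W1 = matrix(stats::rnorm(input_dim * h1, 0, sqrt(2 / input_dim)),
                input_dim, h1),
    b1 = numeric(h1),
    W2 = matrix(stats::rnorm(h1 * h2, 0, sqrt(2 / h1)), h1, h2),
    b2 = numeric(h2),
    W3 = matrix(0, h2, K),
    b3 = numeric(K)
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

mlp_forward <- function(params, X, keep_cache = FALSE) {
  Z1 <- sweep(X %*% params$W1, 2L, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% params$W2, 2L, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  logits <- sweep(A2 %*% params$W3, 2L, params$b3, `+`)
  phi <- softmax_rows(logits)
  if (keep_cache) list(phi = phi, X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2)
  else phi
}

# Backprop from dL/dlogits; returns gradients matching params' shapes.
mlp_backward <- function(params, cache, dlogits) {
  dW3 <- t(cache$A2) %*% dlogits
  db3 <- colSums(dlogits)
  dA2 <- dlogits %*% t(params$W3)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- t(cache$A1) %*% dZ2
  db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- t(cache$X) %*% dZ1
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# dL/dphi for a batch, given precomputed per-record atom survival terms
# A = S_atoms(t) and B = 1 - S_atoms(t'), both n x K.
loss_grad_phi <- function(phi, A, B, event, gamma, floor) {
  S <- pmin(pmax(rowSums(phi * A), floor), 1)
  g <- -A / S
  if (gamma > 0) {
    Fp <- pmin(pmax(rowSums(phi * B), floor), 1)
    g <- g - gamma * event * (B / Fp)
  }
  g
}

batch_loss <- function(phi, A, B, event, gamma, floor) {
  S <- pmin(pmax(rowSums(phi * A), floor), 1)
  total <- -sum(log(S))
  if (gamma > 0 && any(event == 1)) {
    Fp <- pmin(pmax(rowSums(phi * B), floor), 1)
    total <- total - gamma * sum(event * log(Fp))
  }
  total
}

#' Fit the mixture-weight network on interval-censored records
#'
#' Samples (and freezes) the Weibull atoms from `prior`, then trains the
#' three-layer MLP to minimize the interval-censored mixture loss (see
#' [mixture_loss()]) by mini-batch stochastic gradient descent with momentum.
#' Fully reproducible: the same records, prior and config give identical
#' fits.
#'
#' @param records Survival-records data.frame carrying feature columns
#'   `f0..f{d-1}` plus `t`, `t_prime`, `event`. At least two records; a
#'   warning is raised (and training proceeds on the censored term alone)
#'   when no events are present.
#' @param prior An [atom_prior()].
#' @param config A [train_config()].
#' @param encoder Optional `feature_encoder` stored alongside the model so a
#'   saved bundle can encode raw covariates.
#' @return A `dr_model` with the atom set, network parameters, per-epoch
#'   training log, and config.
#' @export
fit_progression_model <- function(records, prior = atom_prior(),
                                  config = train_config(), encoder = NULL) {
  abort_if(nrow(records) < 2L, "need at least two records to fit")
  X <- record_features(records)
  if (!any(records$event == 1L)) {
    warning("no event records: the loss degenerates to its censored term",
            call. = FALSE)
  }
  atoms <- sample_atoms(prior)
  K <- length(atoms$alpha)
  gamma <- config$gamma
  floor <- config$prob_floor

  # frozen per-record atom terms
  A_all <- t(atom_survival(atoms, records$t))
  B_all <- 1 - t(atom_survival(atoms, records$t_prime))
  e_all <- as.numeric(records$event)

  # participant-level validation split
  val_idx <- integer(0)
  if (config$validation_fraction > 0) {
    set.seed(config$seed + 1L)
    ids <- unique(records$participant_id)
    n_val <- max(1L, round(length(ids) * config$validation_fraction))
    val_ids <- sample(ids, n_val)
    val_idx <- which(records$participant_id %in% val_ids)
  }
  tr_idx <- setdiff(seq_len(nrow(records)), val_idx)
  abort_if(length(tr_idx) < 2L, "validation split leaves too few records")

  params <- mlp_init(ncol(X), config$hidden, K, config$seed)
  velocity <- lapply(params, function(p) p * 0)
  set.seed(config$seed + 2L)

  n_tr <- length(tr_idx)
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- tr_idx[sample.int(n_tr)]
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (s in starts) {
      b <- perm[s:min(s + config$batch_size - 1L, n_tr)]
      cache <- mlp_forward(params, X[b, , drop = FALSE], keep_cache = TRUE)
      g_phi <- loss_grad_phi(cache$phi, A_all[b, , drop = FALSE],
                             B_all[b, , drop = FALSE], e_all[b], gamma, floor)
      # softmax Jacobian, then mean over the batch
      dlogits <- cache$phi * (g_phi - rowSums(cache$phi * g_phi)) / length(b)
      grads <- mlp_backward(params, cache, dlogits)
      for (nm in names(params)) {
        g <- grads[[nm]]
        if (config$weight_decay > 0 && is.matrix(params[[nm]])) {
          g <- g + config$weight_decay * params[[nm]]
        }
        velocity[[nm]] <- config$momentum * velocity[[nm]] -
          config$learning_rate * g
        params[[nm]] <- params[[nm]] + velocity[[nm]]
      }
    }
    phi_tr <- mlp_forward(params, X[tr_idx, , drop = FALSE])
    train_loss <- batch_loss(phi_tr, A_all[tr_idx, , drop = FALSE],
                             B_all[tr_idx, , drop = FALSE], e_all[tr_idx],
                             gamma, floor)
    abort_if(!is.finite(train_loss),
             sprintf("training loss became non-finite at epoch %d", epoch))
    val_loss <- NA_real_
    if (length(val_idx) > 0) {
      phi_val <- mlp_forward(params, X[val_idx, , drop = FALSE])
      val_loss <- batch_loss(phi_val, A_all[val_idx, , drop = FALSE],
                             B_all[val_idx, , drop = FALSE], e_all[val_idx],
                             gamma, floor)
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                    val_loss = val_loss)
  }

  structure(list(atoms = atoms, params = params, hidden = config$hidden,
                 input_dim = ncol(X), config = config, encoder = encoder,
                 training_log = do.call(rbind, log_rows)),
            class = "dr_model")
}

check_model <- function(model) {
  abort_if(!inherits(model, "dr_model"),
           "`model` must come from fit_progression_model()")
  invisible(model)
}

as_feature_matrix <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  abort_if(ncol(X) != model$input_dim,
           sprintf("feature dimension mismatch: model expects %d, got %d",
                   model$input_dim, ncol(X)))
  X
}

#' Mixture weights for new subjects
#'
#' @param model A fitted `dr_model`.
#' @param x Feature vector of length `d`, or an `n x d` matrix.
#' @return `n x K` matrix of simplex rows.
#' @export
predict_weights <- function(model, x) {
  check_model(model)
  mlp_forward(model$params, as_feature_matrix(model, x))
}

#' Predicted time to progression per subject
#'
#' The mode-of-density predicted time for each row of `X`; used as the risk
#' score throughout (smaller predicted time = higher risk).
#'
#' @param model A fitted `dr_model`.
#' @param X `n x d` feature matrix (or a single feature vector).
#' @param grid Evaluation grid, see [time_grid()].
#' @return Numeric vector of years, one per row.
#' @export
predict_time_batch <- function(model, X, grid = time_grid()) {
  check_model(model)
  phi <- predict_weights(model, X)
  predict_time(model$atoms, phi, grid)
}

#' Per-subject survival curve closure
#'
#' @param model A fitted `dr_model`.
#' @param X `n x d` feature matrix.
#' @return A function `f(times)` returning the `n x length(times)` matrix of
#'   survival probabilities, suitable for [brier_score()].
#' @export
survival_curves <- function(model, X) {
  check_model(model)
  phi <- predict_weights(model, X)
  atoms <- model$atoms
  function(times) mixture_survival(atoms, phi, times)
}

#' @export
predict.dr_model <- function(object, newdata,
                             type = c("time", "weights", "survival"),
                             grid = time_grid(), times = NULL, ...) {
  type <- match.arg(type)
  switch(type,
         time = predict_time_batch(object, newdata, grid),
         weights = predict_weights(object, newdata),
         survival = {
           abort_if(is.null(times), "`times` required for type = \"survival\"")
           survival_curves(object, newdata)(times)
         })
}

#' Append an upstream model's score as an extra feature
#'
#' Builds the combined-model input: the upstream predicted time-to-event
#' (e.g. the fundus score) is z-scored and appended as one extra column, so
#' the combined model sees `d + 1` features.
#'
#' @param X `n x d` feature matrix.
#' @param upstream_scores Numeric vector of length `n` (predicted times).
#' @param center,scale Standardization statistics; when `NULL` (training
#'   time) they are computed from `upstream_scores` and attached to the
#'   result as attributes `score_center` / `score_scale` for reuse on
#'   held-out data.
#' @return `n x (d+1)` matrix; the new column is named `f{d}`.
#' @export
make_combined_features <- function(X, upstream_scores, center = NULL,
                                   scale = NULL) {
  X <- as.matrix(X)
  abort_if(nrow(X) != length(upstream_scores),
           "`upstream_scores` length must match rows of `X`")
  if (is.null(center)) center <- mean(upstream_scores)
  if (is.null(scale)) {
    scale <- stats::sd(upstream_scores)
    if (is.na(scale) || scale < 1e-12) scale <- 1
  }
  extra <- (upstream_scores - center) / scale
  out <- cbind(X, extra)
  colnames(out) <- paste0("f", seq_len(ncol(out)) - 1L)
  attr(out, "score_center") <- center
  attr(out, "score_scale") <- scale
  out
}

#' Grid search over training configurations
#'
#' Fits one model per candidate config and returns the one with the lowest
#' final validation loss (ties go to the earliest config in grid order).
#' Configs with `validation_fraction = 0` are given 0.2.
#'
#' @param records Survival records (as for [fit_progression_model()]).
#' @param prior An [atom_prior()].
#' @param configs Non-empty list of [train_config()] objects.
#' @return List with `best_config`, `best_model`, and a `trials` data.frame
#'   logging every candidate's validation loss.
#' @export
grid_search_configs <- function(records, prior, configs) {
  abort_if(length(configs) == 0, "`configs` must be non-empty")
  trials <- vector("list", length(configs))
  models <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    if (cfg$validation_fraction == 0) cfg$validation_fraction <- 0.2
    fit <- fit_progression_model(records, prior, cfg)
    vl <- utils::tail(fit$training_log$val_loss, 1L)
    trials[[i]] <- data.frame(trial = i, learning_rate = cfg$learning_rate,
                              epochs = cfg$epochs, gamma = cfg$gamma,
                              val_loss = vl)
    models[[i]] <- fit
  }
  trials <- do.call(rbind, trials)
  best <- which.min(trials$val_loss)  # which.min takes the first on ties
  list(best_config = configs[[best]], best_model = models[[best]],
       trials = trials)
}

# ---- model bundle -----------------------------------------------------------

#' Save a fitted model bundle
#'
#' Writes `atoms.json`, `network.json` (full-precision weights),
#' `train_config.yaml`, `training_log.csv`, and `encoder.json` when an
#' encoder is attached, into `dir`.
#'
#' @param model A fitted `dr_model`.
#' @param dir Output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  check_model(model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atoms_to_json(model$atoms, file.path(dir, "atoms.json"))
  net <- list(input_dim = model$input_dim, hidden = model$hidden,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = length(p), data = as.numeric(p))
              }))
  jsonlite::write_json(net, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(model$config), file.path(dir, "train_config.yaml"))
  utils::write.csv(model$training_log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  if (!is.null(model$encoder)) {
    jsonlite::write_json(unclass(model$encoder),
                         file.path(dir, "encoder.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a fitted model bundle
#' @param dir Directory written by [save_model()].
#' @return A `dr_model`.
#' @export
load_model <- function(dir) {
  atoms <- atoms_from_json(file.path(dir, "atoms.json"))
  net <- jsonlite::read_json(file.path(dir, "network.json"),
                             simplifyVector = TRUE)
  params <- lapply(net$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  cfg <- yaml::read_yaml(file.path(dir, "train_config.yaml"))
  config <- do.call(train_config, cfg[setdiff(names(cfg), NULL)])
  log <- utils::read.csv(file.path(dir, "training_log.csv"))
  encoder <- NULL
  enc_path <- file.path(dir, "encoder.json")
  if (file.exists(enc_path)) {
    raw <- jsonlite::read_json(enc_path, simplifyVector = TRUE)
    encoder <- structure(list(fields = raw$fields,
                              stats = lapply(raw$stats, as.list)),
                         class = "feature_encoder")
  }
  structure(list(atoms = atoms, params = params,
                 hidden = as.integer(net$hidden),
                 input_dim = as.integer(net$input_dim), config = config,
                 encoder = encoder, training_log = log),
            class = "dr_model")
}
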