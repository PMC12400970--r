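#' Configure the compact convolutional classifier
#'
#' Architecture of the EEGNet family: a temporal convolution (`F1` kernels
#' of length `temporal_kernel_len`, same padding), a depthwise spatial
#' convolution spanning the full channel axis (`D` spatial filters per
#' temporal filter, collapsing the channel dimension), a pointwise
#' convolution to `F2` maps, then `n_blocks - 1` separable blocks
#' (depthwise temporal + pointwise convolution); every block is batch
#' normalized, ELU-activated, average-pooled along time and regularized by
#' channel-wise dropout; a dense layer maps the flattened features to one
#' logit per class.
#'
#' @param n_classes Number of classes K (>= 2).
#' @param n_channels,n_samples Input geometry (default 61 x 251).
#' @param F1 Temporal filter count.
#' @param temporal_kernel_len Temporal kernel length in samples (default
#'   64, about a quarter second at 250 Hz).
#' @param D Depth multiplier (spatial filters per temporal filter).
#' @param F2 Pointwise filter count.
#' @param n_blocks Total convolutional blocks (2 or 3).
#' @param pool_sizes Per-block average-pool lengths (length `n_blocks`).
#'   Pooled lengths use floor division.
#' @param sep_kernel_len Depthwise temporal kernel length of the separable
#'   blocks (recycled to `n_blocks - 1`).
#' @param dropout_rate Channel-wise dropout probability in `[0, 1)`.
#' @param seed Seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_classes, n_channels = 61, n_samples = 251,
                         F1 = 8, temporal_kernel_len = 64, D = 2, F2 = 16,
                         n_blocks = 2, pool_sizes = c(4, 8),
                         sep_kernel_len = 16, dropout_rate = 0.25,
                         seed = 1) {
  stopifnot(n_classes >= 2, n_channels >= 1, n_samples >= 1, F1 >= 1,
            D >= 1, F2 >= 1, n_blocks %in% c(2, 3),
            length(pool_sizes) == n_blocks,
            dropout_rate >= 0, dropout_rate < 1)
  sep_kernel_len <- rep_len(sep_kernel_len, n_blocks - 1L)
  tl <- n_samples
  for (p in pool_sizes) {
    tl <- tl %/% p
    if (tl < 1)
      stop("pooled temporal length falls below 1; reduce pool_sizes",
           call. = FALSE)
  }
  structure(
    list(n_classes = as.integer(n_classes),
         n_channels = as.integer(n_channels),
         n_samples = as.integer(n_samples), F1 = as.integer(F1),
         temporal_kernel_len = as.integer(temporal_kernel_len),
         D = as.integer(D), F2 = as.integer(F2),
         n_blocks = as.integer(n_blocks),
         pool_sizes = as.integer(pool_sizes),
         sep_kernel_len = as.integer(sep_kernel_len),
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Configure classifier training
#'
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled weight decay on convolution/dense weights.
#' @param patience Early-stopping patience in epochs (must be below
#'   `max_epochs`); the best-validation-epoch weights are restored.
#' @param validation_fraction Fraction carved from the training pool when a
#'   validation set is not supplied explicitly.
#' @param spatial_max_norm,dense_max_norm Max-norm constraints on the rows
#'   of the depthwise-spatial and dense layers (`Inf` disables).
#' @param seed Seed for shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_epochs = 50, batch_size = 64,
                         learning_rate = 1e-3, weight_decay = 0,
                         patience = 5, validation_fraction = 0.15,
                         spatial_max_norm = 1, dense_max_norm = 0.25,
                         seed = 1) {
  stopifnot(max_epochs >= 1, patience < max_epochs, batch_size >= 1,
            learning_rate > 0, validation_fraction > 0,
            validation_fraction < 1, spatial_max_norm > 0,
            dense_max_norm > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 spatial_max_norm = spatial_max_norm,
                 dense_max_norm = dense_max_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

# pooled temporal lengths after each block (floor division)
pooled_lengths <- function(config) {
  out <- integer(config$n_blocks)
  tl <- config$n_samples
  for (b in seq_len(config$n_blocks)) {
    tl <- tl %/% config$pool_sizes[b]
    out[b] <- tl
  }
  out
}

glorot <- function(nr, nc, fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Build an untrained classifier
#'
#' Initializes all parameters from the config seed (Glorot-uniform
#' convolution/dense weights, unit batch-norm scale) and zeroed running
#' batch-norm statistics.
#'
#' @param config A [model_config()].
#' @return An object of class `classifier_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  C <- config$n_channels; F1 <- config$F1; D <- config$D; F2 <- config$F2
  L <- config$temporal_kernel_len
  tlast <- pooled_lengths(config)[config$n_blocks]
  n_sep <- config$n_blocks - 1L
  w <- with_seed(derive_seed(config$seed, "init"), {
    sep <- lapply(seq_len(n_sep), function(b) {
      L2 <- config$sep_kernel_len[b]
      list(Wdt = glorot(F2, L2, L2, L2),
           Wpw = glorot(F2, F2, F2, F2),
           g = rep(1, F2), b = rep(0, F2))
    })
    list(Wt = glorot(F1, L, L, F1),
         Wdw = glorot(F1 * D, C, C, D),
         Wpw1 = glorot(F2, F1 * D, F1 * D, F2),
         g1 = rep(1, F2), b1 = rep(0, F2),
         sep = sep,
         Wd = glorot(config$n_classes, F2 * tlast, F2 * tlast,
                     config$n_classes),
         bd = rep(0, config$n_classes))
  })
  bn_state <- list(
    bn1 = list(mu = rep(0, F2), var = rep(1, F2)),
    bnsep = lapply(seq_len(n_sep), function(b)
      list(mu = rep(0, F2), var = rep(1, F2))))
  structure(list(config = config, weights = w, bn_state = bn_state,
                 label_map = NULL, history = NULL, trained = FALSE),
            class = "classifier_model")
}

#' Trainable parameter count of a classifier
#' @param model A `classifier_model`.
#' @export
param_count <- function(model) {
  leaves <- rapply(model$weights, length, how = "unlist")
  sum(leaves)
}

#' @export
print.classifier_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<classifier_model> %d ch x %d samples -> %d classes | F1=%d D=%d F2=%d blocks=%d | %s, %d parameters\n",
    cfg$n_channels, cfg$n_samples, cfg$n_classes, cfg$F1, cfg$D, cfg$F2,
    cfg$n_blocks, if (x$trained) "trained" else "untrained",
    param_count(x)))
  invisible(x)
}

# --- nested-list parameter utilities ---------------------------------------
nested_map <- function(x, f) {
  if (is.list(x)) lapply(x, nested_map, f = f) else f(x)
}
nested_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- nested_map2(x[[i]], y[[i]], f)
    out
  } else f(x, y)
}
nested_map3 <- function(x, y, z, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x))
      out[[i]] <- nested_map3(x[[i]], y[[i]], z[[i]], f)
    out
  } else f(x, y, z)
}

epochs_to_cube <- function(epochs, config) {
  d <- dim(epochs$data)
  if (d[2] != config$n_channels || d[3] != config$n_samples)
    stop("epoch geometry ", d[2], " x ", d[3],
         " does not match the model config ", config$n_channels, " x ",
         config$n_samples, call. = FALSE)
  aperm(epochs$data, c(3, 2, 1))
}

make_label_map <- function(labels) {
  sort(unique(as.character(labels)))
}

labels_to_index <- function(labels, label_map) {
  idx <- match(as.character(labels), label_map)
  if (anyNA(idx))
    stop("labels outside the model's label map: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  as.integer(idx - 1L)
}

#' Class weights for class-weighted cross-entropy
#'
#' `w_k = N / (K * N_k)`, so that `sum_k N_k w_k = N` exactly.
#'
#' @param y Integer 0-based class indices.
#' @param k Number of classes.
#' @export
class_weights <- function(y, k) {
  nk <- tabulate(y + 1L, nbins = k)
  if (any(nk == 0L))
    stop("empty class in the training data", call. = FALSE)
  length(y) / (k * nk)
}

drop_masks <- function(config, B) {
  r <- config$dropout_rate
  lapply(seq_len(config$n_blocks), function(b) {
    if (r == 0) matrix(1, config$F2, B)
    else matrix((stats::runif(config$F2 * B) >= r) / (1 - r),
                config$F2, B)
  })
}

max_norm_constrain <- function(w, dense_norm = 0.25, dw_norm = 1) {
  if (is.finite(dw_norm)) {
    rn <- sqrt(rowSums(w$Wdw^2))
    w$Wdw <- w$Wdw * pmin(1, dw_norm / pmax(rn, 1e-12))
  }
  if (is.finite(dense_norm)) {
    rn <- sqrt(rowSums(w$Wd^2))
    w$Wd <- w$Wd * pmin(1, dense_norm / pmax(rn, 1e-12))
  }
  w
}

infer_batched <- function(cube, model, chunk = 512L, want_features = FALSE) {
  N <- dim(cube)[3]
  logits <- NULL; feats <- NULL
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    out <- nn_infer(cube[, , idx, drop = FALSE], model$weights,
                    model$config, model$bn_state, 1e-5, want_features)
    logits <- cbind(logits, out$logits)
    if (want_features) {
      if (is.null(feats)) {
        dfeat <- dim(out$features)
        feats <- array(0, c(dfeat[1], dfeat[2], N))
      }
      feats[, , idx] <- out$features
    }
  }
  list(logits = logits, features = feats)
}

weighted_ce <- function(logits, y, cw) {
  zm <- apply(logits, 2, max)
  lse <- log(colSums(exp(sweep(logits, 2, zm, "-")))) + zm
  ll <- logits[cbind(y + 1L, seq_along(y))] - lse
  -sum(cw[y + 1L] * ll) / sum(cw[y + 1L])
}

#' Train the classifier
#'
#' Minimizes class-weighted cross-entropy (`w_k = N/(K N_k)`) with Adam and
#' decoupled weight decay, early-stopping when the validation loss fails to
#' improve for `patience` epochs and restoring the best-epoch weights.
#' Deterministic given the config and training seeds.
#'
#' @param model A [build_model()] result.
#' @param train,val `epoch_set` objects; `val` may be `NULL`, in which case
#'   a stratified `validation_fraction` is carved from `train`.
#' @param tc A [train_config()].
#' @param label_field Metadata column holding the class labels.
#' @return The trained `classifier_model` with `label_map` and a
#'   per-epoch `history` tibble.
#' @export
train_classifier <- function(model, train, val = NULL,
                             tc = train_config(), label_field) {
  if (is.null(val)) {
    sp <- split_validation(train, tc$validation_fraction, label_field,
                           seed = tc$seed)
    train <- sp$train; val <- sp$val
  }
  label_map <- make_label_map(train$metadata[[label_field]])
  if (length(label_map) != model$config$n_classes)
    stop("found ", length(label_map), " classes but the model expects ",
         model$config$n_classes, call. = FALSE)
  y_tr <- labels_to_index(train$metadata[[label_field]], label_map)
  y_va <- labels_to_index(val$metadata[[label_field]], label_map)
  cw <- class_weights(y_tr, model$config$n_classes)
  Xtr <- epochs_to_cube(train, model$config)
  Xva <- epochs_to_cube(val, model$config)
  N <- length(y_tr)
  B <- min(tc$batch_size, N)

  adam_m <- nested_map(model$weights, function(x) x * 0)
  adam_v <- adam_m
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  decay_leaf <- function(name) name %in% c("Wt", "Wdw", "Wpw1", "Wdt",
                                           "Wpw", "Wd")
  best <- list(loss = Inf, weights = model$weights,
               bn_state = model$bn_state, epoch = 0L)
  wait <- 0L
  hist <- vector("list", tc$max_epochs)

  with_seed(derive_seed(tc$seed, "train"), {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(N)
      tl <- 0; nb <- 0L
      for (start in seq(1L, N, by = B)) {
        idx <- ord[start:min(start + B - 1L, N)]
        masks <- drop_masks(model$config, length(idx))
        out <- nn_train_batch(Xtr[, , idx, drop = FALSE], y_tr[idx],
                              model$weights, model$config, cw, masks, 1e-5)
        step <- step + 1L
        lr <- tc$learning_rate
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        adam_m <- nested_map2(adam_m, out$grads, function(m, g)
          beta1 * m + (1 - beta1) * g)
        adam_v <- nested_map2(adam_v, out$grads, function(v, g)
          beta2 * v + (1 - beta2) * g^2)
        upd <- nested_map2(adam_m, adam_v, function(m, g)
          lr * (m / bc1) / (sqrt(g / bc2) + eps))
        model$weights <- apply_update(model$weights, upd,
                                      tc$weight_decay * lr)
        model$weights <- max_norm_constrain(model$weights,
                                            tc$dense_max_norm,
                                            tc$spatial_max_norm)
        # running batch-norm statistics (momentum 0.1)
        model$bn_state$bn1$mu <- 0.9 * model$bn_state$bn1$mu +
          0.1 * out$bn1$mu
        model$bn_state$bn1$var <- 0.9 * model$bn_state$bn1$var +
          0.1 * out$bn1$var
        for (bix in seq_along(model$bn_state$bnsep)) {
          model$bn_state$bnsep[[bix]]$mu <-
            0.9 * model$bn_state$bnsep[[bix]]$mu + 0.1 * out$bnsep[[bix]]$mu
          model$bn_state$bnsep[[bix]]$var <-
            0.9 * model$bn_state$bnsep[[bix]]$var +
            0.1 * out$bnsep[[bix]]$var
        }
        tl <- tl + out$loss; nb <- nb + 1L
      }
      va <- infer_batched(Xva, model)
      val_loss <- weighted_ce(va$logits, y_va, cw)
      val_acc <- mean(max.col(t(va$logits), ties.method = "first") - 1L ==
                        y_va)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tl / nb, val_loss = val_loss,
        val_acc = val_acc)
      if (is.finite(val_loss) && val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, weights = model$weights,
                     bn_state = model$bn_state, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
  })
  model$weights <- best$weights
  model$bn_state <- best$bn_state
  model$label_map <- label_map
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

apply_update <- function(w, upd, wd_lr) {
  rec <- function(x, u, nm) {
    if (is.list(x)) {
      for (i in seq_along(x))
        x[[i]] <- rec(x[[i]], u[[i]],
                      if (!is.null(names(x))) names(x)[i] else "")
      x
    } else {
      x <- x - u
      if (wd_lr > 0 && nm %in% c("Wt", "Wdw", "Wpw1", "Wdt", "Wpw", "Wd"))
        x <- x - wd_lr * x
      x
    }
  }
  rec(w, upd, "")
}

#' Predict class labels and logits
#'
#' Argmax over logits with ties broken toward the lowest output index;
#' order-equivariant over trials.
#'
#' @param object A trained `classifier_model`.
#' @param epochs An `epoch_set` matching the model geometry.
#' @param ... Unused.
#' @return A list with `labels` (character) and `logits` (trials x classes
#'   matrix with class column names).
#' @export
predict.classifier_model <- function(object, epochs, ...) {
  out <- infer_batched(epochs_to_cube(epochs, object$config), object)
  logits <- t(out$logits)
  lm <- object$label_map
  if (is.null(lm)) lm <- as.character(seq_len(object$config$n_classes))
  colnames(logits) <- lm
  idx <- max.col(logits, ties.method = "first")
  list(labels = lm[idx], logits = logits)
}

#' Stratified pooled train/holdout split
#'
#' Splits trials into disjoint, exhaustive train and holdout sets,
#' stratified by subject x class so every stratum contributes
#' proportionally (within +-1 trial of `train_fraction`).
#'
#' @param epochs An `epoch_set`.
#' @param label_field Metadata column holding class labels.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Seed.
#' @return A list with `train` and `holdout` epoch sets.
#' @export
pooled_split <- function(epochs, label_field, train_fraction = 0.8,
                         seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  md <- epochs$metadata
  strata <- paste(md$participant_id, md[[label_field]], sep = "\r")
  tr_idx <- with_seed(derive_seed(seed, "pooled_split"), {
    unlist(lapply(split(seq_len(nrow(md)), strata), function(idx) {
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(0L, min(length(idx), n_tr))
      if (n_tr == 0L) return(integer(0))
      sample(idx, n_tr)
    }))
  })
  list(train = epochs[sort(tr_idx)],
       holdout = epochs[setdiff(seq_len(nrow(md)), tr_idx)])
}

#' Carve a stratified validation set from a training pool
#'
#' @param epochs An `epoch_set`.
#' @param fraction Validation fraction.
#' @param label_field Metadata column with class labels.
#' @param seed Seed.
#' @return A list with `train` and `val` epoch sets.
#' @export
split_validation <- function(epochs, fraction = 0.15, label_field,
                             seed = 1) {
  sp <- pooled_split(epochs, label_field, train_fraction = 1 - fraction,
                     seed = derive_seed(seed, "val_split"))
  list(train = sp$train, val = sp$holdout)
}

#' Per-subject k-fold evaluation of a trained model
#'
#' For each subject, partitions that subject's holdout trials into `k`
#' folds (sizes differing by at most one) and reports the mean over folds
#' of the trained model's fold accuracy. No refitting takes place; a
#' single pooled model is scored. Subjects with fewer than `k` trials are
#' skipped with a warning.
#'
#' @param model A trained `classifier_model`.
#' @param holdout An `epoch_set`.
#' @param label_field Metadata column with the true labels.
#' @param k Fold count (default 5; `k = 1` gives plain per-subject holdout
#'   accuracy).
#' @param seed Seed for the fold assignment.
#' @return A list with `per_subject` (tibble: participant_id, accuracy,
#'   n_trials) and `per_fold` (tibble: participant_id, fold, accuracy, n).
#' @export
evaluate_per_subject_cv <- function(model, holdout, label_field, k = 5,
                                    seed = 1) {
  pred <- predict(model, holdout)
  correct <- pred$labels == as.character(holdout$metadata[[label_field]])
  md <- holdout$metadata
  per_subject <- list(); per_fold <- list()
  for (pid in sort(unique(md$participant_id))) {
    idx <- which(md$participant_id == pid)
    if (length(idx) < k) {
      warning("subject ", pid, " has fewer than ", k,
              " holdout trials; skipped")
      next
    }
    ord <- with_seed(derive_seed(seed, paste0("cvfold_s", pid)),
                     sample(idx))
    fold_of <- rep_len(seq_len(k), length(ord))
    accs <- vapply(seq_len(k), function(f)
      mean(correct[ord[fold_of == f]]), numeric(1))
    fold_n <- tabulate(fold_of, k)
    per_fold[[length(per_fold) + 1L]] <- tibble::tibble(
      participant_id = pid, fold = seq_len(k), accuracy = accs,
      n = fold_n)
    per_subject[[length(per_subject) + 1L]] <- tibble::tibble(
      participant_id = pid, accuracy = mean(accs),
      n_trials = length(idx))
  }
  list(per_subject = dplyr::bind_rows(per_subject),
       per_fold = dplyr::bind_rows(per_fold))
}

#' Seeded random hyperparameter search with successive halving
#'
#' Samples `budget` configurations uniformly from the supplied space,
#' trains each for a small epoch budget, keeps the best half on interim
#' validation accuracy, doubles the epoch budget, and repeats until one
#' configuration remains. The full trial log is retained.
#'
#' @param space Named list of candidate value vectors; names must be
#'   arguments of [model_config()] (e.g. `F1`, `D`, `F2`, `dropout_rate`,
#'   `temporal_kernel_len`) or [train_config()] (e.g. `learning_rate`,
#'   `batch_size`, `weight_decay`).
#' @param train,val `epoch_set` objects.
#' @param label_field Metadata column with class labels.
#' @param n_classes Class count for the sampled model configs.
#' @param budget Number of sampled configurations (>= 1).
#' @param seed Seed controlling the whole search trajectory.
#' @param initial_epochs Epoch budget of the first rung.
#' @param eta Halving factor.
#' @return A list with `model_config`, `train_config` (the winner) and
#'   `log` (tibble of every evaluation).
#' @export
hyperparameter_search <- function(space, train, val, label_field,
                                  n_classes, budget, seed = 1,
                                  initial_epochs = 2, eta = 2) {
  if (length(space) == 0L) stop("empty search space", call. = FALSE)
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  mc_args <- names(formals(model_config))
  tc_args <- names(formals(train_config))
  bad <- setdiff(names(space), c(mc_args, tc_args))
  if (length(bad))
    stop("unknown search-space entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  nch <- n_channels(train); nsa <- n_samples(train)

  draws <- with_seed(derive_seed(seed, "hp_search"), {
    lapply(seq_len(budget), function(i)
      lapply(space, function(v) v[[sample.int(length(v), 1L)]]))
  })
  alive <- seq_len(budget)
  epochs_budget <- initial_epochs
  log <- list()
  scores <- rep(NA_real_, budget)
  rung <- 0L
  repeat {
    rung <- rung + 1L
    for (i in alive) {
      pars <- draws[[i]]
      mc <- do.call(model_config, c(
        list(n_classes = n_classes, n_channels = nch, n_samples = nsa,
             seed = derive_seed(seed, paste0("hp_model", i))),
        pars[intersect(names(pars), mc_args)]))
      tcp <- pars[intersect(names(pars), tc_args)]
      tcp$max_epochs <- epochs_budget
      tcp$patience <- max(1L, epochs_budget - 1L)
      tcp$seed <- derive_seed(seed, paste0("hp_train", i))
      tc <- do.call(train_config, tcp)
      fitted <- train_classifier(build_model(mc), train, val, tc,
                                 label_field)
      acc <- utils::tail(fitted$history$val_acc, 1)
      if (!is.finite(acc)) acc <- 0
      scores[i] <- acc
      log[[length(log) + 1L]] <- tibble::tibble(
        trial = i, rung = rung, epochs = epochs_budget, val_acc = acc,
        params = as.character(jsonlite::toJSON(pars, auto_unbox = TRUE)))
    }
    if (length(alive) <= 1L) break
    keep_n <- ceiling(length(alive) / eta)
    alive <- alive[order(-scores[alive])][seq_len(keep_n)]
    epochs_budget <- epochs_budget * eta
  }
  best <- alive[1L]
  pars <- draws[[best]]
  mc <- do.call(model_config, c(
    list(n_classes = n_classes, n_channels = nch, n_samples = nsa,
         seed = derive_seed(seed, paste0("hp_model", best))),
    pars[intersect(names(pars), mc_args)]))
  tcp <- pars[intersect(names(pars), tc_args)]
  tc <- do.call(train_config, tcp)
  list(model_config = mc, train_config = tc,
       log = dplyr::bind_rows(log))
}
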