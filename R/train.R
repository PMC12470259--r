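# Adam / binary-cross-entropy training engine with early stopping and
# reduce-on-plateau learning-rate decay. When inter-slice attention is
# active, each batch is a set of slice indices from one subject and the
# encoder-decoder pass of every slice the batch touches (centres plus
# their volume neighbours) is computed once and shared between the losses
# that need it; gradients flow through the neighbour slices as well, so
# the gradient is exact, not an approximation.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam at learning rate 0.001,
#' batch size 4, up to 200 epochs of binary cross-entropy, early stopping
#' on validation loss (patience 20) and reduce-on-plateau learning-rate
#' decay (factor 0.5, patience 10, floor 1e-5).
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Slices per optimization step.
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping.
#' @param lr_factor,lr_patience,min_lr Reduce-on-plateau schedule.
#' @param balance_sampling Train on all slices with non-empty masks plus an
#'   equal number of empty-mask slices per subject (seeded draw); `FALSE`
#'   uses every slice.
#' @param seed Seed controlling sampling and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 4L,
                         max_epochs = 200L, early_stop_patience = 20L,
                         lr_factor = 0.5, lr_patience = 10L, min_lr = 1e-5,
                         balance_sampling = TRUE, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be at least 1", call. = FALSE)
  if (max_epochs < 1L) stop("max_epochs must be at least 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 min_lr = min_lr, balance_sampling = isTRUE(balance_sampling),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))`. A prediction of 0.5
#' everywhere scores `log(2)` regardless of the truth.
#'
#' @param pred Probability map in (0,1).
#' @param truth Binary mask, same size.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, truth) {
  pd <- dim(pred)[1:2]; td <- dim(truth)[1:2]
  if (!identical(pd, td)) {
    stop(sprintf("prediction %s and truth %s differ in size",
                 paste(pd, collapse = "x"), paste(td, collapse = "x")),
         call. = FALSE)
  }
  p <- as.vector(unclass(pred)); y <- as.vector(unclass(truth))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(wts) {
  list(m = lapply(wts, function(w) array(0, dim(w) %||% length(w))),
       v = lapply(wts, function(w) array(0, dim(w) %||% length(w))),
       t = 0L)
}

adam_step <- function(wts, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(wts)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    wts[[nm]] <- wts[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(wts = wts, state = state)
}

add_grads <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

## ---- one optimization step on a batch of slice centres ---------------------

# vol: subject_volume; centres: slice indices whose losses enter the batch
train_step <- function(wts, cfg, vol, centres) {
  S <- length(vol$slices)
  if (cfg$isa_enabled) {
    needed <- sort(unique(unlist(lapply(centres, function(i) {
      j <- c(i - 1L, i, i + 1L)
      j[j >= 1L & j <= S]
    }))))
  } else {
    needed <- centres
  }
  cores <- lapply(needed, function(j) {
    core_forward(vol$slices[[j]], wts, cfg, train = TRUE)
  })
  names(cores) <- as.character(needed)
  gF <- setNames(vector("list", length(needed)), as.character(needed))
  grads <- list()
  loss <- 0
  nb <- length(centres)
  for (i in centres) {
    Fc <- cores[[as.character(i)]]$out
    y <- vol$masks[[i]]
    if (cfg$isa_enabled) {
      jp <- if (i - 1L >= 1L) i - 1L else NA_integer_
      jn <- if (i + 1L <= S) i + 1L else NA_integer_
      Fp <- if (!is.na(jp)) cores[[as.character(jp)]]$out
            else if (cfg$isa_boundary_policy == "replicate") Fc
            else array(0, dim(Fc))
      Fn <- if (!is.na(jn)) cores[[as.character(jn)]]$out
            else if (cfg$isa_boundary_policy == "replicate") Fc
            else array(0, dim(Fc))
      isa <- isa_forward(Fp, Fc, Fn, wts[["isa.W"]], wts[["isa.b"]],
                         train = TRUE)
      feat <- isa$out
    } else {
      feat <- Fc
    }
    hf <- head_forward(feat, wts)
    p <- hf$p[, , 1]
    loss <- loss + bce_loss(p, y)
    gz <- (p - y) / length(p) / nb
    dim(gz) <- c(dim(gz), 1L)
    hb <- conv2d_bwd(feat, wts[["head.W"]], gz)
    grads <- add_grads(grads, list(head.W = hb$gW, head.b = hb$gb))
    if (cfg$isa_enabled) {
      ib <- isa_backward(hb$gx, isa$cache, wts[["isa.W"]])
      grads <- add_grads(grads, list(isa.W = ib$gW, isa.b = ib$gb))
      key <- as.character(i)
      gF[[key]] <- (gF[[key]] %||% 0) + ib$g_curr
      if (!is.na(jp)) {
        gF[[as.character(jp)]] <- (gF[[as.character(jp)]] %||% 0) + ib$g_prev
      } else if (cfg$isa_boundary_policy == "replicate") {
        gF[[key]] <- gF[[key]] + ib$g_prev
      }
      if (!is.na(jn)) {
        gF[[as.character(jn)]] <- (gF[[as.character(jn)]] %||% 0) + ib$g_next
      } else if (cfg$isa_boundary_policy == "replicate") {
        gF[[key]] <- gF[[key]] + ib$g_next
      }
    } else {
      key <- as.character(i)
      gF[[key]] <- (gF[[key]] %||% 0) + hb$gx
    }
  }
  for (key in names(gF)) {
    if (is.null(gF[[key]])) next
    grads <- add_grads(grads,
                       core_backward(gF[[key]], cores[[key]]$cache, wts, cfg))
  }
  list(loss = loss / nb, grads = grads)
}

## ---- slice sampling and batching -------------------------------------------

eligible_slices <- function(vol, balance) {
  nonempty <- which(vapply(vol$masks, function(m) any(m > 0), logical(1)))
  if (!balance) return(seq_along(vol$slices))
  empty <- setdiff(seq_along(vol$slices), nonempty)
  take <- min(length(empty), length(nonempty))
  sort(c(nonempty, if (take > 0L) sample(empty, take)))
}

make_batches <- function(sets, batch_size) {
  batches <- list()
  for (s in seq_along(sets)) {
    idx <- sets[[s]]
    while (length(idx) > 0L) {
      k <- min(batch_size, length(idx))
      batches[[length(batches) + 1L]] <- list(subject = s,
                                              centres = idx[seq_len(k)])
      idx <- idx[-seq_len(k)]
    }
  }
  batches
}

## ---- validation pass -------------------------------------------------------

validation_pass <- function(wts, cfg, vols) {
  model <- structure(list(config = cfg, weights = wts),
                     class = "attunet_model")
  loss <- 0; n <- 0L
  counts <- list()
  for (vol in vols) {
    preds <- forward_subject(vol, model)
    for (i in seq_along(preds)) {
      loss <- loss + bce_loss(preds[[i]], vol$masks[[i]])
      n <- n + 1L
      counts[[length(counts) + 1L]] <-
        confusion_counts(binarize(preds[[i]]), vol$masks[[i]])
    }
  }
  rep <- aggregate_metrics(counts, "micro")
  list(loss = loss / n, dice = rep$dice, iou = rep$iou)
}

## ---- training loop ---------------------------------------------------------

#' Train a model
#'
#' Full training protocol: Adam on binary cross-entropy, per-epoch
#' validation, best-validation-loss checkpointing, early stopping and
#' plateau learning-rate decay. Training and validation subjects must be
#' disjoint — sharing a subject would leak near-identical neighbouring
#' slices across the split, and is rejected before training starts.
#'
#' @param model_config A [unet_config()] (input size must match the data).
#' @param train_set,val_set Lists of [subject_volume()]s.
#' @param tc A [train_config()].
#' @return List of class `attunet_fit`: `model` (weights of the best
#'   validation epoch), `log` (`attunet_train_log` tibble with per-epoch
#'   train/validation loss and validation Dice/IoU, and attributes
#'   `best_epoch`, `stop_reason`).
#' @export
train <- function(model_config, train_set, val_set, tc = train_config()) {
  if (length(train_set) == 0L || length(val_set) == 0L) {
    stop("train and validation sets must be non-empty", call. = FALSE)
  }
  tr_ids <- vapply(train_set, `[[`, character(1), "subject_id")
  va_ids <- vapply(val_set, `[[`, character(1), "subject_id")
  leak <- intersect(tr_ids, va_ids)
  if (length(leak) > 0L) {
    stop("subject(s) present in both train and validation sets: ",
         paste(leak, collapse = ", "), call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tc$seed)

  model <- build_model(model_config)
  wts <- model$weights
  state <- adam_init(wts)
  lr <- tc$learning_rate

  sets <- lapply(train_set, eligible_slices, balance = tc$balance_sampling)
  best_loss <- Inf; best_wts <- wts; best_epoch <- 0L
  plateau <- 0L
  log <- NULL
  stop_reason <- "max_epochs"

  for (epoch in seq_len(tc$max_epochs)) {
    batches <- make_batches(sets, tc$batch_size)
    batches <- batches[sample(length(batches))]
    ep_loss <- 0
    for (b in batches) {
      st <- train_step(wts, model_config, train_set[[b$subject]], b$centres)
      upd <- adam_step(wts, st$grads, state, lr)
      wts <- upd$wts; state <- upd$state
      ep_loss <- ep_loss + st$loss * length(b$centres)
    }
    ep_loss <- ep_loss / sum(lengths(lapply(batches, `[[`, "centres")))
    val <- validation_pass(wts, model_config, val_set)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_loss = val$loss, val_dice = val$dice,
                                 val_iou = val$iou, lr = lr))
    if (val$loss < best_loss) {
      best_loss <- val$loss; best_wts <- wts; best_epoch <- epoch
      plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau >= tc$lr_patience) {
        lr <- max(lr * tc$lr_factor, tc$min_lr)
        plateau <- 0L
      }
      if (epoch - best_epoch > tc$early_stop_patience) {
        stop_reason <- "early_stop"
        break
      }
    }
  }
  log <- tibble::as_tibble(log)
  attr(log, "best_epoch") <- best_epoch
  attr(log, "stop_reason") <- stop_reason
  class(log) <- c("attunet_train_log", class(log))
  model$weights <- best_wts
  structure(list(model = model, log = log), class = "attunet_fit")
}

#' @export
print.attunet_fit <- function(x, ...) {
  cat(sprintf("<attunet_fit> %d epochs (%s), best epoch %d, val dice %.4f\n",
              nrow(x$log), attr(x$log, "stop_reason"),
              attr(x$log, "best_epoch"),
              x$log$val_dice[attr(x$log, "best_epoch")]))
  invisible(x)
}

#' Overfit a single batch (convergence smoke test)
#'
#' Runs repeated Adam steps on one fixed batch of slices. A correct
#' forward/backward implementation drives the training loss towards zero.
#'
#' @param model_config A [unet_config()].
#' @param slices,masks Lists of HxW image and binary mask matrices.
#' @param steps Number of Adam steps.
#' @param learning_rate Adam learning rate.
#' @return Numeric vector of the loss at every step.
#' @export
overfit_one_batch <- function(model_config, slices, masks, steps = 200L,
                              learning_rate = 0.001) {
  vol <- subject_volume("overfit", slices, masks)
  model <- build_model(model_config)
  wts <- model$weights
  state <- adam_init(wts)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    st <- train_step(wts, model_config, vol, seq_along(slices))
    upd <- adam_step(wts, st$grads, state, learning_rate)
    wts <- upd$wts; state <- upd$state
    losses[s] <- st$loss
  }
  losses
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a model on held-out subjects
#'
#' Pads every slice to the model's input size, runs inference per subject
#' (with inter-slice fusion if enabled), crops predictions back to the
#' original slice size, binarizes at the threshold, and aggregates
#' confusion counts. The primary report averages per-subject micro metrics
#' across subjects (matching the paired-by-subject statistics); the
#' per-subject table is attached as attribute `per_subject`.
#'
#' @param model An `attunet_model` (or `attunet_fit`).
#' @param test_set List of [subject_volume()]s.
#' @param threshold Binarization threshold.
#' @param mode Within-subject aggregation: `"micro"` (default) or
#'   `"per_slice_mean"`.
#' @return One-row `metric_report` tibble with attribute `per_subject`.
#' @export
evaluate <- function(model, test_set, threshold = 0.5, mode = "micro") {
  if (inherits(model, "attunet_fit")) model <- model$model
  cfg <- model$config
  target <- c(cfg$input_height, cfg$input_width)
  per <- lapply(test_set, function(vol) {
    padded <- subject_volume(vol$subject_id,
                             lapply(vol$slices, pad_to_canvas, target = target),
                             lapply(vol$masks, pad_to_canvas, target = target))
    preds <- forward_subject(padded, model)
    counts <- lapply(seq_along(preds), function(i) {
      pr <- crop_back(copy_pad_meta(binarize(preds[[i]], threshold),
                                    padded$slices[[i]]))
      confusion_counts(pr, vol$masks[[i]])
    })
    rep <- aggregate_metrics(counts, mode)
    rep$subject_id <- vol$subject_id
    rep
  })
  per_tab <- do.call(rbind, per)
  cols <- c("accuracy", "precision", "recall", "f1", "dice", "iou")
  report <- tibble::as_tibble(lapply(setNames(cols, cols),
                                     function(cl) mean(per_tab[[cl]])))
  report$aggregation <- paste0("per_subject_mean(", mode, ")")
  report$n_slices <- sum(per_tab$n_slices)
  report$n_subjects <- nrow(per_tab)
  class(report) <- c("metric_report", class(report))
  attr(report, "per_subject") <- per_tab
  report
}

## ---- ablation harness ------------------------------------------------------

#' Run the four-way ablation
#'
#' Trains the plain U-Net, U-Net + spatial attention, U-Net + inter-slice
#' attention and the full dual-attention variant with shared seeds and
#' identical data order, evaluates each on the test subjects, and pairs the
#' full variant against every baseline with per-subject paired t-tests on
#' Dice and IoU.
#'
#' @param dataset A `phantom_dataset` (or list with `volumes` and
#'   `manifest`).
#' @param tc A [train_config()].
#' @param base_channels,input_size,depth Architecture of the variants;
#'   default width 8, five levels, at the dataset's slice size.
#' @param n_val Training subjects held out for early stopping.
#' @return List: `metrics` (4-row tibble, one per variant), `tests`
#'   (paired-test tibble, dual vs each baseline on dice and iou), `fits`
#'   (the four `attunet_fit` objects).
#' @export
run_ablation <- function(dataset, tc = train_config(),
                         base_channels = 8L, input_size = NULL,
                         depth = 5L, n_val = 2L) {
  split <- dataset_split(dataset, n_val = n_val, seed = tc$seed)
  if (is.null(input_size)) {
    input_size <- dim(split$train[[1]]$slices[[1]])
  }
  variants <- ablation_variants(input_height = input_size[1],
                                input_width = input_size[2],
                                base_channels = base_channels,
                                depth = depth, seed = tc$seed)
  fits <- lapply(variants, function(cfg) {
    train(cfg, split$train, split$val, tc)
  })
  reports <- lapply(fits, evaluate, test_set = split$test)
  metrics <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    tibble::tibble(model = nm, precision = r$precision, recall = r$recall,
                   f1 = r$f1, dice = r$dice, iou = r$iou)
  }))
  dual_sub <- attr(reports$dual, "per_subject")
  tests <- do.call(rbind, lapply(c("unet", "unet_sa", "unet_isa"),
                                 function(nm) {
    base_sub <- attr(reports[[nm]], "per_subject")
    do.call(rbind, lapply(c("dice", "iou"), function(metric) {
      tt <- paired_t_test(dual_sub[[metric]], base_sub[[metric]])
      tt$comparison <- paste0("dual_vs_", nm)
      tt$metric <- metric
      tt
    }))
  }))
  list(metrics = metrics, tests = tests, fits = fits)
}

#' Split a phantom dataset into train / validation / test volumes
#'
#' Test subjects come from the manifest's subject-level split; `n_val`
#' training subjects (seeded draw) are held out for early stopping.
#'
#' @param dataset A `phantom_dataset`.
#' @param n_val Number of validation subjects taken from the training split.
#' @param seed Seed for the validation draw.
#' @return List of volume lists: `train`, `val`, `test`.
#' @export
dataset_split <- function(dataset, n_val = 2L, seed = 1L) {
  man <- dataset$manifest
  tr_ids <- unique(man$subject_id[man$split == "train"])
  te_ids <- unique(man$subject_id[man$split == "test"])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  va_ids <- if (n_val > 0L) sample(tr_ids, n_val) else character()
  list(train = dataset$volumes[setdiff(tr_ids, va_ids)],
       val = dataset$volumes[va_ids],
       test = dataset$volumes[te_ids])
}
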