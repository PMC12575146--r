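#' Corrupt a trajectory for masked-language-model training
#'
#' Each eligible position (any non-special content token) is
#' independently replaced by the `MASK` token with probability
#' `mask_rate` (reference 15%) or swapped for a uniformly random other
#' content token with probability `swap_rate` (reference 2%); the two
#' corruptions are disjoint. Targets record the original token id at
#' every corrupted position and `NA` elsewhere.
#'
#' @param traj An encoded trajectory (see [encode_trajectory()]).
#' @param vocab The [build_vocabulary()] used for encoding.
#' @param seed Optional seed making the corruption reproducible.
#' @param mask_rate,swap_rate Corruption probabilities in `[0, 1]` with
#'   `mask_rate + swap_rate <= 1`.
#' @return A list of class `masked_batch`: corrupted `token_ids`,
#'   untouched `modality_ids`/`delay_ids`/`positions`, integer `targets`
#'   (`NA` at unperturbed positions) and `corruption` (`"mask"`,
#'   `"swap"` or `"none"` per position).
#' @export
corrupt_sequence <- function(traj, vocab, seed = NULL, mask_rate = 0.15,
                             swap_rate = 0.02) {
  if (mask_rate < 0 || swap_rate < 0 || mask_rate + swap_rate > 1) {
    stop_input("need mask_rate, swap_rate >= 0 with mask_rate + swap_rate <= 1")
  }
  with_seed(seed, {
    ids <- traj$token_ids
    specials <- special_tokens()
    eligible <- !(ids %in% specials)
    u <- stats::runif(length(ids))
    do_mask <- eligible & u < mask_rate
    do_swap <- eligible & u >= mask_rate & u < mask_rate + swap_rate
    targets <- rep(NA_integer_, length(ids))
    targets[do_mask | do_swap] <- ids[do_mask | do_swap]
    corrupted <- ids
    corrupted[do_mask] <- specials[["MASK"]]
    content <- content_token_ids(vocab)
    for (j in which(do_swap)) {
      pool <- content[content != ids[j]]
      corrupted[j] <- if (length(pool)) pool[sample.int(length(pool), 1)]
                      else ids[j]
    }
    traj$token_ids <- corrupted
    traj$targets <- targets
    traj$corruption <- ifelse(do_mask, "mask", ifelse(do_swap, "swap", "none"))
    class(traj) <- c("masked_batch", class(traj))
    traj
  })
}

# Forward + loss + gradients for one packed, corrupted minibatch.
# Targets at swapped positions are kept or dropped via swap_in_loss.
mlm_batch_pass <- function(params, cfg, corrupted, swap_in_loss = TRUE,
                           compute_grads = TRUE) {
  batch <- pack_batch(corrupted)
  tmask <- unlist(lapply(corrupted, function(tr) {
    keep <- !is.na(tr$targets)
    if (!swap_in_loss) keep <- keep & tr$corruption != "swap"
    keep
  }))
  targets <- unlist(lapply(corrupted, `[[`, "targets"))[tmask]
  if (length(targets) == 0L) {
    return(list(loss = NA_real_, n_targets = 0L))
  }
  X <- embed_tabular(params, batch)
  fwd <- encoder_forward(params, cfg, X, batch$seqs)
  Ht <- fwd$H[tmask, , drop = FALSE]
  logits <- addb(Ht %*% params$mlm_W, params$mlm_b)
  P <- softmax_rows(logits)
  n <- length(targets)
  picked <- P[cbind(seq_len(n), targets)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  out <- list(loss = loss, n_targets = n,
              pred = max.col(logits, ties.method = "first"),
              targets = targets, tmask = tmask)
  if (compute_grads) {
    dlogits <- P
    dlogits[cbind(seq_len(n), targets)] <-
      dlogits[cbind(seq_len(n), targets)] - 1
    dlogits <- dlogits / n
    grads <- list(mlm_W = crossprod(Ht, dlogits),
                  mlm_b = colSums(dlogits))
    dH <- matrix(0, nrow(fwd$H), ncol(fwd$H))
    dH[tmask, ] <- tcrossprod(dlogits, params$mlm_W)
    bwd <- encoder_backward(params, cfg, fwd, batch$seqs, dH)
    grads <- acc_grads(grads, bwd$grads)
    grads <- acc_grads(grads, embed_tabular_backward(params, batch, bwd$dX))
    out$grads <- grads
  }
  out
}

#' Pretrain the tabular trajectory encoder with a masked language model
#'
#' Randomly initializes token/modality/delay/position embeddings and the
#' encoder, splits the trajectories 90/10 into training and validation
#' sets, and minimizes cross-entropy at corrupted positions only with
#' Adam. Training is deterministic given `config$seed`.
#'
#' @param trajectories List of encoded trajectories.
#' @param vocab The [build_vocabulary()] used for encoding.
#' @param config An [encoder_config()].
#' @param mask_rate,swap_rate Corruption rates (defaults 0.15 / 0.02).
#' @param swap_in_loss Should swapped positions contribute prediction
#'   targets (default `TRUE`)?
#' @param val_fraction Validation share of the 90/10 split.
#' @param verbose Print per-epoch losses.
#' @return An object of class `mlm_model` carrying the learned
#'   parameters, the config, vocabulary, and train/validation loss
#'   histories.
#' @export
train_mlm <- function(trajectories, vocab, config, mask_rate = 0.15,
                      swap_rate = 0.02, swap_in_loss = TRUE,
                      val_fraction = 0.10, verbose = FALSE) {
  if (length(trajectories) < 1L) stop_input("need at least one trajectory")
  with_seed(config$seed, {
    V <- length(vocab$token_ids)
    H <- config$hidden
    params <- c(
      list(emb_tok = rmat(V, H),
           emb_mod = rmat(length(vocab$modality_ids), H),
           emb_del = rmat(length(vocab$delay_ids), H),
           emb_pos = rmat(config$max_len, H)),
      init_encoder_layers(config),
      list(mlm_W = rmat(H, V), mlm_b = numeric(V))
    )
    n <- length(trajectories)
    n_val <- floor(val_fraction * n)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer()
    train_idx <- setdiff(perm, val_idx)
    state <- adam_init(params)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    val_seed <- sample.int(.Machine$integer.max - 1L, 1)

    eval_val <- function(params) {
      if (length(val_idx) == 0L) return(NA_real_)
      corrupted <- mapply(function(tr, s) {
        corrupt_sequence(tr, vocab, seed = s, mask_rate = mask_rate,
                         swap_rate = swap_rate)
      }, trajectories[val_idx], val_seed + seq_along(val_idx),
      SIMPLIFY = FALSE)
      mlm_batch_pass(params, config, corrupted, swap_in_loss,
                     compute_grads = FALSE)$loss
    }

    val0 <- eval_val(params)
    for (epoch in seq_len(config$epochs)) {
      order_ <- sample(train_idx)
      batches <- split(order_, ceiling(seq_along(order_) / config$batch_size))
      epoch_loss <- 0
      n_batches <- 0L
      for (bi in batches) {
        corrupted <- lapply(trajectories[bi], function(tr) {
          corrupt_sequence(tr, vocab, seed = NULL, mask_rate = mask_rate,
                           swap_rate = swap_rate)
        })
        pass <- mlm_batch_pass(params, config, corrupted, swap_in_loss)
        if (pass$n_targets == 0L) next
        if (!is.finite(pass$loss)) {
          stop_input("MLM training diverged (non-finite loss) at epoch %d",
                     epoch)
        }
        st <- adam_step(params, pass$grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
        epoch_loss <- epoch_loss + pass$loss
        n_batches <- n_batches + 1L
      }
      vl <- eval_val(params)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epoch_loss / max(1, n_batches),
                                  val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        epoch_loss / max(1, n_batches), vl))
      }
    }
    structure(
      list(params = params, config = config, vocab = vocab,
           history = history, val_loss_initial = val0,
           val_seed = val_seed, train_idx = train_idx, val_idx = val_idx,
           mask_rate = mask_rate, swap_rate = swap_rate),
      class = "mlm_model"
    )
  })
}

#' @export
print.mlm_model <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  cat(sprintf("<mlm_model: %d layers, hidden %d, vocab %d; final train loss %.4f, val loss %.4f>\n",
              x$config$n_layers, x$config$hidden,
              length(x$vocab$token_ids),
              if (nrow(last)) last$train_loss else NA,
              if (nrow(last)) last$val_loss else NA))
  invisible(x)
}

#' Token embedding table of a pretrained model
#' @param model An `mlm_model`.
#' @return Numeric matrix (vocabulary x hidden) with token names as row
#'   names.
#' @export
token_embeddings <- function(model) {
  E <- model$params$emb_tok
  rownames(E) <- names(model$vocab$token_ids)
  E
}

#' Masked-token prediction precision
#'
#' Corrupts held-out trajectories with a fixed seed and reports the top-1
#' accuracy of the model at masked positions only (swapped positions are
#' noise, not part of the metric).
#'
#' @param model A trained `mlm_model`.
#' @param trajectories Encoded trajectories compatible with the model's
#'   vocabulary.
#' @param seed Masking seed (fixed so the metric is stable).
#' @return Fraction of correctly predicted masked tokens.
#' @export
mlm_precision <- function(model, trajectories, seed = 1L) {
  corrupted <- mapply(function(tr, s) {
    corrupt_sequence(tr, model$vocab, seed = s, mask_rate = model$mask_rate,
                     swap_rate = model$swap_rate)
  }, trajectories, seed + seq_along(trajectories) - 1L, SIMPLIFY = FALSE)
  masked <- unlist(lapply(corrupted, function(tr) tr$corruption == "mask"))
  pass <- mlm_batch_pass(model$params, model$config, corrupted,
                         swap_in_loss = TRUE, compute_grads = FALSE)
  if (pass$n_targets == 0L || !any(masked)) {
    stop_input("no masked positions; cannot compute precision")
  }
  keep <- masked[pass$tmask]
  mean(pass$pred[keep] == pass$targets[keep])
}

#' Shuffle content tokens within a trajectory
#'
#' Baseline transformation destroying sequential structure: all positions
#' after `CLS` are permuted uniformly, moving each token jointly with its
#' modality (a token keeps its feature type). The delay layer stays at
#' the original positions -- it describes visit timing, not token
#' identity.
#'
#' @param traj An encoded trajectory.
#' @param seed Optional permutation seed.
#' @return The shuffled trajectory.
#' @export
shuffle_tokens_within_sequence <- function(traj, seed = NULL) {
  with_seed(seed, {
    n <- length(traj$token_ids)
    if (n <= 2L) return(traj)
    idx <- 2:n
    perm <- sample(idx)
    traj$token_ids[idx] <- traj$token_ids[perm]
    traj$modality_ids[idx] <- traj$modality_ids[perm]
    if (!is.null(traj$tokens)) traj$tokens[idx] <- traj$tokens[perm]
    if (!is.null(traj$modalities)) {
      traj$modalities[idx] <- traj$modalities[perm]
    }
    traj
  })
}

#' Ensemble token embeddings across pretraining runs
#'
#' Standardizes each run's embedding table per dimension (zero mean, unit
#' variance across the vocabulary) and averages the standardized tables
#' elementwise -- the multi-seed ensembling used to stabilize token
#' embeddings (reference: five seeds).
#'
#' @param tables List (length >= 2) of equally sized embedding matrices,
#'   or of `mlm_model`s.
#' @return The ensembled embedding matrix.
#' @export
ensemble_token_embeddings <- function(tables) {
  if (length(tables) < 2L) stop_input("need at least two embedding tables")
  tables <- lapply(tables, function(x) {
    if (inherits(x, "mlm_model")) token_embeddings(x) else x
  })
  dims <- vapply(tables, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_input("embedding tables differ in shape")
  }
  std <- lapply(tables, function(E) {
    mu <- colMeans(E)
    sdv <- apply(E, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    t((t(E) - mu) / sdv)
  })
  Reduce(`+`, std) / length(std)
}

#' Pretrain with several seeds and ensemble the embeddings
#'
#' Runs [train_mlm()] once per seed and returns the models together with
#' the standardized-mean embedding table.
#'
#' @param trajectories,vocab,config As in [train_mlm()].
#' @param seeds Integer vector of masking/initialization seeds
#'   (reference: five).
#' @param ... Passed to [train_mlm()].
#' @return List with `models` and `embeddings`.
#' @export
pretrain_ensemble <- function(trajectories, vocab, config, seeds = 1:5, ...) {
  models <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    train_mlm(trajectories, vocab, cfg, ...)
  })
  list(models = models,
       embeddings = ensemble_token_embeddings(models))
}
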