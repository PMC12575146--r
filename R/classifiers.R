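#' Class-balanced batch indices
#'
#' Builds one epoch of minibatches in which every batch contains exactly
#' `batch_size / 2` positives and negatives: the majority class is
#' chunked without replacement from a random permutation (topped up by
#' resampling only when the final chunk is short), the minority class is
#' sampled with replacement. With perfectly balanced input both classes
#' are chunked without replacement, so each example appears once per
#' epoch.
#'
#' @param labels Logical (or 0/1) vector; both classes must be present.
#' @param batch_size Even batch size.
#' @param seed Optional seed.
#' @return List of integer index vectors, one per batch.
#' @export
balanced_batches <- function(labels, batch_size, seed = NULL) {
  labels <- as.logical(labels)
  if (batch_size %% 2 != 0) stop_input("batch_size must be even")
  pos <- which(labels)
  neg <- which(!labels)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_input("both classes must be present")
  }
  half <- batch_size / 2
  with_seed(seed, {
    if (length(pos) >= length(neg)) {
      major <- pos; minor <- neg
    } else {
      major <- neg; minor <- pos
    }
    equal <- length(pos) == length(neg)
    major <- sample(major)
    if (equal) minor <- sample(minor)
    n_batches <- max(1L, ceiling(length(major) / half))
    lapply(seq_len(n_batches), function(b) {
      lo <- (b - 1) * half + 1
      hi <- min(b * half, length(major))
      maj <- major[lo:hi]
      if (length(maj) < half) {
        maj <- c(maj, sample(major, half - length(maj), replace = TRUE))
      }
      mnr <- if (equal) {
        minor[lo:hi]
      } else {
        minor[sample.int(length(minor), half, replace = TRUE)]
      }
      sample(c(maj, mnr))
    })
  })
}

#' Fine-tuning configuration
#'
#' Reference settings for fine-tuning the tabular classifier: Adam,
#' learning rate 1e-4, batch size 16, 5 epochs.
#'
#' @param learning_rate,batch_size,epochs Optimizer settings.
#' @param seed Integer seed.
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(learning_rate = 1e-4, batch_size = 16,
                            epochs = 5, seed = 1) {
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, seed = as.integer(seed)),
            class = "finetune_config")
}

#' Text classifier configuration
#'
#' Architecture and training settings of the report-sequence
#' transformer. The hidden size defaults to 768 so report vectors from
#' the reference 768-dimensional token embedder flow through unchanged;
#' training defaults are the reference settings (Adam, learning rate
#' 5e-4, batch size 32, 99 epochs). Layer/head counts are package
#' defaults.
#'
#' @inheritParams encoder_config
#' @return An `encoder_config`.
#' @export
text_config <- function(n_layers = 2, n_heads = 12, hidden = 768,
                        intermediate = 512, max_len = 512,
                        learning_rate = 5e-4, batch_size = 32, epochs = 99,
                        seed = 1) {
  encoder_config(n_layers = n_layers, n_heads = n_heads, hidden = hidden,
                 intermediate = intermediate, max_len = max_len,
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, seed = seed)
}

# --- Tabular classifier ------------------------------------------------

tabular_forward_cls <- function(params, cfg, trajectories) {
  batch <- pack_batch(trajectories)
  X <- embed_tabular(params, batch)
  fwd <- encoder_forward(params, cfg, X, batch$seqs)
  Hc <- fwd$H[batch$cls_rows, , drop = FALSE]
  list(batch = batch, fwd = fwd, Hc = Hc,
       logit = drop(Hc %*% params$cls_w) + params$cls_b)
}

#' Fine-tune the pretrained tabular encoder into a classifier
#'
#' Initializes the encoder and embedding layers from a pretrained
#' masked-language model (or freshly when `pretrained` is `NULL`, for
#' from-scratch baselines), replaces the token-prediction head with a
#' single feed-forward layer and sigmoid over the `CLS` representation,
#' and minimizes binary cross-entropy on class-balanced batches.
#'
#' @param pretrained An `mlm_model`, or `NULL` for random initialization
#'   (requires `vocab` and `encoder_cfg`).
#' @param trajectories Encoded, labelled trajectories.
#' @param config A [finetune_config()].
#' @param vocab,encoder_cfg Used only when `pretrained` is `NULL`.
#' @return An object of class `tabular_classifier`.
#' @export
finetune_tabular <- function(pretrained, trajectories,
                             config = finetune_config(), vocab = NULL,
                             encoder_cfg = NULL) {
  if (!is.null(pretrained)) {
    vocab <- pretrained$vocab
    encoder_cfg <- pretrained$config
  } else if (is.null(vocab) || is.null(encoder_cfg)) {
    stop_input("random initialization requires vocab and encoder_cfg")
  }
  vmax <- max(unlist(lapply(trajectories, `[[`, "token_ids")))
  if (vmax > length(vocab$token_ids)) {
    stop_input("trajectories contain token ids outside the model vocabulary")
  }
  labels <- vapply(trajectories, function(tr) isTRUE(tr$label), logical(1))
  with_seed(config$seed, {
    if (!is.null(pretrained)) {
      params <- pretrained$params
      params$mlm_W <- NULL
      params$mlm_b <- NULL
    } else {
      V <- length(vocab$token_ids)
      H <- encoder_cfg$hidden
      params <- c(
        list(emb_tok = rmat(V, H),
             emb_mod = rmat(length(vocab$modality_ids), H),
             emb_del = rmat(length(vocab$delay_ids), H),
             emb_pos = rmat(encoder_cfg$max_len, H)),
        init_encoder_layers(encoder_cfg)
      )
    }
    params$cls_w <- stats::rnorm(encoder_cfg$hidden, 0, 0.02)
    params$cls_b <- 0
    state <- adam_init(params)
    history <- numeric()
    for (epoch in seq_len(config$epochs)) {
      batches <- balanced_batches(labels, config$batch_size)
      epoch_loss <- 0
      for (bi in batches) {
        fc <- tabular_forward_cls(params, encoder_cfg, trajectories[bi])
        y <- labels[bi]
        p <- sigmoid(fc$logit)
        loss <- -mean(y * log(pmax(p, 1e-12)) +
                        (1 - y) * log(pmax(1 - p, 1e-12)))
        dz <- (p - y) / length(y)
        grads <- list(cls_w = drop(crossprod(fc$Hc, dz)), cls_b = sum(dz))
        dH <- matrix(0, nrow(fc$fwd$H), ncol(fc$fwd$H))
        dH[fc$batch$cls_rows, ] <- outer(dz, params$cls_w)
        bwd <- encoder_backward(params, encoder_cfg, fc$fwd,
                                fc$batch$seqs, dH)
        grads <- acc_grads(grads, bwd$grads)
        grads <- acc_grads(grads,
                           embed_tabular_backward(params, fc$batch, bwd$dX))
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
        epoch_loss <- epoch_loss + loss
      }
      history <- c(history, epoch_loss / length(batches))
    }
    structure(
      list(params = params, config = encoder_cfg, vocab = vocab,
           finetune = config, history = history,
           pretrained = !is.null(pretrained)),
      class = "tabular_classifier"
    )
  })
}

#' CLS representations and pre-sigmoid logits of the tabular classifier
#' @param model A `tabular_classifier`.
#' @param trajectories Encoded trajectories.
#' @param chunk Forward-pass chunk size.
#' @return List with `representation` (n x hidden matrix) and `logit`.
#' @export
tabular_representations <- function(model, trajectories, chunk = 64L) {
  idx <- split(seq_along(trajectories),
               ceiling(seq_along(trajectories) / chunk))
  H <- NULL; z <- numeric()
  for (bi in idx) {
    fc <- tabular_forward_cls(model$params, model$config, trajectories[bi])
    H <- rbind(H, fc$Hc)
    z <- c(z, fc$logit)
  }
  list(representation = H, logit = z)
}

#' Predicted event probabilities
#'
#' Deterministic forward pass; results are invariant to how patients are
#' batched.
#'
#' @param model A trained classifier (`tabular_classifier`,
#'   `text_classifier` or `fusion_model`).
#' @param newdata Encoded trajectories (tabular or text), or for a fusion
#'   model a list with elements `tabular` and `text`.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, newdata, ...) UseMethod("predict_proba")

#' @export
predict_proba.tabular_classifier <- function(model, newdata, ...) {
  sigmoid(tabular_representations(model, newdata)$logit)
}

# --- Text classifier ---------------------------------------------------

pack_text_batch <- function(ttrajs, delay_ids) {
  n_rep <- vapply(ttrajs, function(t) nrow(t$vectors), integer(1))
  lens <- 2L * n_rep + 1L
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  N <- sum(lens)
  role <- integer(N)    # 1 cls, 2 report, 3 sep
  del <- integer(N)
  pos <- integer(N)
  rep_rows <- integer(sum(n_rep))
  Rstack <- do.call(rbind, lapply(ttrajs, `[[`, "vectors"))
  k <- 0L
  for (i in seq_along(ttrajs)) {
    rows <- starts[i]:ends[i]
    role[rows[1]] <- 1L
    del[rows[1]] <- delay_ids[["W0"]]
    d_ids <- unname(delay_ids[ttrajs[[i]]$delays])
    for (j in seq_len(n_rep[i])) {
      r_row <- rows[1] + 2L * j - 1L
      s_row <- r_row + 1L
      role[r_row] <- 2L
      role[s_row] <- 3L
      del[r_row] <- d_ids[j]
      del[s_row] <- d_ids[j]
      k <- k + 1L
      rep_rows[k] <- r_row
    }
    pos[rows] <- seq_along(rows) - 1L
  }
  list(Rstack = Rstack, role = role, del = del, pos = pos,
       seqs = mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE),
       cls_rows = starts, rep_rows = rep_rows,
       sep_rows = which(role == 3L), N = N)
}

text_input_forward <- function(params, batch) {
  H <- ncol(params$proj_W)
  X <- matrix(0, batch$N, H)
  X[batch$cls_rows, ] <- matrix(params$cls_vec, length(batch$cls_rows), H,
                                byrow = TRUE)
  X[batch$sep_rows, ] <- matrix(params$sep_vec, length(batch$sep_rows), H,
                                byrow = TRUE)
  Xrep <- addb(batch$Rstack %*% params$proj_W, params$proj_b)
  X[batch$rep_rows, ] <- Xrep
  X + params$emb_del[batch$del, , drop = FALSE] +
    params$emb_pos[batch$pos + 1L, , drop = FALSE]
}

text_input_backward <- function(params, batch, dX) {
  g <- list()
  dXrep <- dX[batch$rep_rows, , drop = FALSE]
  g$proj_W <- crossprod(batch$Rstack, dXrep)
  g$proj_b <- colSums(dXrep)
  g$cls_vec <- colSums(dX[batch$cls_rows, , drop = FALSE])
  g$sep_vec <- colSums(dX[batch$sep_rows, , drop = FALSE])
  g$emb_del <- params$emb_del * 0
  rs <- rowsum(dX, group = batch$del)
  g$emb_del[as.integer(rownames(rs)), ] <- rs
  g$emb_pos <- params$emb_pos * 0
  rs <- rowsum(dX, group = batch$pos + 1L)
  g$emb_pos[as.integer(rownames(rs)), ] <- rs
  g
}

text_forward_cls <- function(params, cfg, ttrajs, delay_ids) {
  batch <- pack_text_batch(ttrajs, delay_ids)
  X <- text_input_forward(params, batch)
  fwd <- encoder_forward(params, cfg, X, batch$seqs)
  Hc <- fwd$H[batch$cls_rows, , drop = FALSE]
  list(batch = batch, fwd = fwd, Hc = Hc,
       logit = drop(Hc %*% params$cls_w) + params$cls_b)
}

#' Train the report-sequence (text) classifier
#'
#' A transformer over chronologically ordered pooled report vectors:
#' reports pass through a learned input projection, learned `CLS`/`SEP`
#' vectors delimit the sequence, delay and position embeddings are added,
#' and the `CLS` representation feeds a single feed-forward layer with
#' sigmoid. Trained with binary cross-entropy on class-balanced batches.
#'
#' @param text_trajectories List of [build_text_trajectory()] results
#'   with labels.
#' @param config A [text_config()].
#' @return An object of class `text_classifier`.
#' @export
train_text_classifier <- function(text_trajectories, config = text_config()) {
  dims <- unique(vapply(text_trajectories, `[[`, numeric(1), "dim"))
  if (length(dims) != 1L) {
    stop_input("text trajectories have inconsistent embedding dimensions")
  }
  d_text <- dims
  labels <- vapply(text_trajectories, function(t) isTRUE(t$label), logical(1))
  delay_ids <- stats::setNames(seq_along(delay_bucket_levels()),
                               delay_bucket_levels())
  with_seed(config$seed, {
    H <- config$hidden
    params <- c(
      list(proj_W = rmat(d_text, H), proj_b = numeric(H),
           cls_vec = stats::rnorm(H, 0, 0.02),
           sep_vec = stats::rnorm(H, 0, 0.02),
           emb_del = rmat(length(delay_ids), H),
           emb_pos = rmat(config$max_len, H)),
      init_encoder_layers(config),
      list(cls_w = stats::rnorm(H, 0, 0.02), cls_b = 0)
    )
    state <- adam_init(params)
    history <- numeric()
    for (epoch in seq_len(config$epochs)) {
      batches <- balanced_batches(labels, config$batch_size)
      epoch_loss <- 0
      for (bi in batches) {
        fc <- text_forward_cls(params, config, text_trajectories[bi],
                               delay_ids)
        y <- labels[bi]
        p <- sigmoid(fc$logit)
        loss <- -mean(y * log(pmax(p, 1e-12)) +
                        (1 - y) * log(pmax(1 - p, 1e-12)))
        dz <- (p - y) / length(y)
        grads <- list(cls_w = drop(crossprod(fc$Hc, dz)), cls_b = sum(dz))
        dH <- matrix(0, nrow(fc$fwd$H), ncol(fc$fwd$H))
        dH[fc$batch$cls_rows, ] <- outer(dz, params$cls_w)
        bwd <- encoder_backward(params, config, fc$fwd, fc$batch$seqs, dH)
        grads <- acc_grads(grads, bwd$grads)
        grads <- acc_grads(grads,
                           text_input_backward(params, fc$batch, bwd$dX))
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
        epoch_loss <- epoch_loss + loss
      }
      history <- c(history, epoch_loss / length(batches))
    }
    structure(
      list(params = params, config = config, d_text = d_text,
           delay_ids = delay_ids, history = history),
      class = "text_classifier"
    )
  })
}

#' CLS representations and pre-sigmoid logits of the text classifier
#' @param model A `text_classifier`.
#' @param text_trajectories List of report trajectories.
#' @param chunk Forward-pass chunk size.
#' @return List with `representation` and `logit`.
#' @export
text_representations <- function(model, text_trajectories, chunk = 64L) {
  idx <- split(seq_along(text_trajectories),
               ceiling(seq_along(text_trajectories) / chunk))
  H <- NULL; z <- numeric()
  for (bi in idx) {
    fc <- text_forward_cls(model$params, model$config,
                           text_trajectories[bi], model$delay_ids)
    H <- rbind(H, fc$Hc)
    z <- c(z, fc$logit)
  }
  list(representation = H, logit = z)
}

#' @export
predict_proba.text_classifier <- function(model, newdata, ...) {
  sigmoid(text_representations(model, newdata)$logit)
}

# --- Cross-attention fusion -------------------------------------------

#' Fusion configuration
#'
#' Reference dimensions: the tabular representation ("logits" entering
#' the fusion) has dimension `d_model` = 144 and the text representation
#' enters a linear projection with input dimension 768 to match it.
#' Training defaults: Adam, learning rate 1e-3, batch size 64, 6 epochs.
#'
#' @param d_model Tabular representation dimension.
#' @param text_dim Text representation (projection input) dimension.
#' @param n_heads Attention heads of the fusion module (default 1).
#' @param freeze_submodels Must be `TRUE`: only the projection, the
#'   cross-attention block and the head are trained.
#' @param mode `"representation"` (query/key/value are the CLS
#'   pre-sigmoid representations) or `"scalar"` (the scalar logits,
#'   combined by a trained logistic stack).
#' @param learning_rate,batch_size,epochs,seed Training settings.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(d_model = 144, text_dim = 768, n_heads = 1,
                          freeze_submodels = TRUE, mode = "representation",
                          learning_rate = 1e-3, batch_size = 64, epochs = 6,
                          seed = 1) {
  mode <- match.arg(mode, c("representation", "scalar"))
  structure(list(d_model = d_model, text_dim = text_dim, n_heads = n_heads,
                 freeze_submodels = freeze_submodels, mode = mode,
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, seed = as.integer(seed)),
            class = "fusion_config")
}

# Fusion forward on precomputed representations. In representation mode
# the projected text representation is the query and the tabular
# representation the single key/value; with one key the attention output
# is the value itself, and the residual connection from the query makes
# the fused representation depend on both modalities:
# fused = Q + Attn(Q, K, V) -> feed-forward + sigmoid.
fusion_forward <- function(params, cfg, Ttab, Ttext, tab_logit, text_logit) {
  if (cfg$mode == "scalar") {
    z <- params$a_text * text_logit + params$a_tab * tab_logit + params$a_0
    return(list(logit = z))
  }
  Q <- addb(Ttext %*% params$fq_W, params$fq_b)
  Z0 <- Q + Ttab
  list(logit = drop(Z0 %*% params$head_w) + params$head_b, Q = Q, Z0 = Z0)
}

#' Fuse tabular and text classifiers by cross-attention
#'
#' Trains the multimodal meta-model: both submodels are frozen, their
#' CLS pre-sigmoid representations are computed once, and only the text
#' projection, the cross-attention block (text as query, tabular as key
#' and value) and a fresh feed-forward + sigmoid head are trained, with
#' binary cross-entropy on class-balanced batches.
#'
#' @param tab_model A `tabular_classifier`.
#' @param text_model A `text_classifier`.
#' @param trajectories Encoded tabular trajectories (training set).
#' @param text_trajectories Matching report trajectories (same patients,
#'   same order).
#' @param config A [fusion_config()]; `d_model` and `text_dim` are taken
#'   from the submodels.
#' @return An object of class `fusion_model`.
#' @export
cross_attention_fuse <- function(tab_model, text_model, trajectories,
                                 text_trajectories,
                                 config = fusion_config()) {
  if (!isTRUE(config$freeze_submodels)) {
    stop_input("only frozen-submodel fusion is supported (freeze_submodels = TRUE)")
  }
  if (length(trajectories) != length(text_trajectories)) {
    stop_input("tabular and text trajectories must pair up one-to-one")
  }
  labels <- vapply(trajectories, function(tr) isTRUE(tr$label), logical(1))
  rt <- tabular_representations(tab_model, trajectories)
  rx <- text_representations(text_model, text_trajectories)
  cfg <- config
  cfg$d_model <- ncol(rt$representation)
  cfg$text_dim <- ncol(rx$representation)
  # per-dimension standardization of both frozen representations,
  # stored with the model: the two encoders produce activations on very
  # different scales and the fusion block needs commensurate inputs
  scaler <- function(M) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    sdv[sdv < 1e-8] <- 1
    list(mu = mu, sd = sdv)
  }
  sc_tab <- scaler(rt$representation)
  sc_text <- scaler(rx$representation)
  apply_scaler <- function(M, sc) t((t(M) - sc$mu) / sc$sd)
  rt$representation <- apply_scaler(rt$representation, sc_tab)
  rx$representation <- apply_scaler(rx$representation, sc_text)
  with_seed(cfg$seed, {
    if (cfg$mode == "scalar") {
      params <- list(a_text = 0.0, a_tab = 0.0, a_0 = 0.0)
    } else {
      # Warm start: express the frozen submodel heads in the
      # standardized bases and initialize the head along the tabular
      # head direction with the projection mapping the text logit onto
      # it, so the fused block begins close to a logistic stack of the
      # two submodels and training refines it with the full
      # representations. Small noise breaks symmetry.
      w_tab <- tab_model$params$cls_w * sc_tab$sd
      w_text <- text_model$params$cls_w * sc_text$sd
      w_tab <- w_tab / max(sqrt(sum(w_tab^2)), 1e-8)
      w_text <- w_text / max(sqrt(sum(w_text^2)), 1e-8)
      params <- list(fq_W = outer(w_text, w_tab) +
                       rmat(cfg$text_dim, cfg$d_model,
                            sd = 0.1 / sqrt(cfg$text_dim)),
                     fq_b = numeric(cfg$d_model),
                     head_w = w_tab, head_b = 0)
    }
    state <- adam_init(params)
    history <- numeric()
    for (epoch in seq_len(cfg$epochs)) {
      batches <- balanced_batches(labels, cfg$batch_size)
      epoch_loss <- 0
      for (bi in batches) {
        Ttab <- rt$representation[bi, , drop = FALSE]
        Ttext <- rx$representation[bi, , drop = FALSE]
        ff <- fusion_forward(params, cfg, Ttab, Ttext,
                             rt$logit[bi], rx$logit[bi])
        y <- labels[bi]
        p <- sigmoid(ff$logit)
        loss <- -mean(y * log(pmax(p, 1e-12)) +
                        (1 - y) * log(pmax(1 - p, 1e-12)))
        dz <- (p - y) / length(y)
        if (cfg$mode == "scalar") {
          grads <- list(a_text = sum(dz * rx$logit[bi]),
                        a_tab = sum(dz * rt$logit[bi]),
                        a_0 = sum(dz))
        } else {
          grads <- list(head_w = drop(crossprod(ff$Z0, dz)),
                        head_b = sum(dz))
          dQ <- outer(dz, params$head_w)
          grads$fq_W <- crossprod(Ttext, dQ)
          grads$fq_b <- colSums(dQ)
        }
        st <- adam_step(params, grads, state, cfg$learning_rate)
        params <- st$params
        state <- st$state
        epoch_loss <- epoch_loss + loss
      }
      history <- c(history, epoch_loss / length(batches))
    }
    structure(
      list(params = params, config = cfg, tab_model = tab_model,
           text_model = text_model, history = history,
           scalers = list(tab = sc_tab, text = sc_text)),
      class = "fusion_model"
    )
  })
}

#' @export
predict_proba.fusion_model <- function(model, newdata, ...) {
  if (!is.list(newdata) || is.null(newdata$tabular) || is.null(newdata$text)) {
    stop_input("fusion prediction needs newdata = list(tabular = ..., text = ...)")
  }
  rt <- tabular_representations(model$tab_model, newdata$tabular)
  rx <- text_representations(model$text_model, newdata$text)
  apply_scaler <- function(M, sc) t((t(M) - sc$mu) / sc$sd)
  ff <- fusion_forward(model$params, model$config,
                       apply_scaler(rt$representation, model$scalers$tab),
                       apply_scaler(rx$representation, model$scalers$text),
                       rt$logit, rx$logit)
  sigmoid(ff$logit)
}

#' Hash of a model's parameter tensors
#'
#' Cheap content digest used to verify that frozen submodels are
#' bit-unchanged by fusion training.
#'
#' @param model Any model object with a `params` list.
#' @return Character digest.
#' @export
params_digest <- function(model) {
  vals <- unlist(model$params, use.names = FALSE)
  paste(format(sum(vals), digits = 17),
        format(sum(vals^2), digits = 17),
        format(sum(vals * seq_along(vals)), digits = 17),
        sep = "|")
}
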