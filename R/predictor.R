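#' Presentation-classifier configuration
#'
#' Architecture and training hyperparameters of the peptide-MHC
#' presentation classifier: a one-dimensional multi-kernel convolutional
#' branch over the encoded, padded peptide (kernel sizes 1, 3, 5 and 7,
#' each globally max-pooled) concatenated with a small scalar-feature
#' branch (-log10 binding rank, hydrophobicity, peptide length), followed
#' by a dense stack and a single sigmoid output. The defaults are the
#' published settings of the method: learning rate 1e-5, weight decay
#' 1e-6, dropout 0.1, batch size 50, dense layers of 2000 and 256 units,
#' 10-fold cross-validation. Epochs are governed by early stopping on a
#' held-in validation slice since no epoch count is published.
#'
#' @param kernel_sizes convolution kernel sizes (each must not exceed the
#'   hotspot length).
#' @param filters_per_kernel convolution filters per kernel size.
#' @param dense_units widths of the dense stack.
#' @param scalar_units width of the scalar-branch layer.
#' @param dropout dropout probability in the dense stack.
#' @param learning_rate,weight_decay Adam step size and decoupled weight
#'   decay.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param folds cross-validation folds.
#' @param seed integer seed for initialization, shuffling, dropout and
#'   fold assignment.
#' @param pos_weight optional loss weight for the positive class (e.g. the
#'   negative:positive ratio) to counter class imbalance; `NULL` for
#'   unweighted binary cross-entropy.
#' @param patience early-stopping patience in epochs.
#' @param val_fraction fraction of the training split held in for early
#'   stopping.
#' @return a `PresentationModelConfig` list.
#' @export
presentation_model_config <- function(kernel_sizes = c(1L, 3L, 5L, 7L),
                                      filters_per_kernel = 64L,
                                      dense_units = c(2000L, 256L),
                                      scalar_units = 16L,
                                      dropout = 0.1,
                                      learning_rate = 1e-5,
                                      weight_decay = 1e-6,
                                      batch_size = 50L,
                                      epochs = 100L,
                                      folds = 10L,
                                      seed = 1L,
                                      pos_weight = NULL,
                                      patience = 5L,
                                      val_fraction = 0.1) {
  stopifnot(all(kernel_sizes >= 1L), filters_per_kernel >= 1L,
            length(dense_units) >= 1L, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1L, epochs >= 1L, folds >= 2L)
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 filters_per_kernel = as.integer(filters_per_kernel),
                 dense_units = as.integer(dense_units),
                 scalar_units = as.integer(scalar_units),
                 dropout = dropout, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed), pos_weight = pos_weight,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, loss = "binary_cross_entropy"),
            class = "PresentationModelConfig")
}

N_SCALAR_FEATURES <- 3L  # -log10 rank, hydrophobicity, relative length

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

#' Build an initialized presentation model
#'
#' Instantiates the architecture with seeded parameter initialization. The
#' concatenation layer has width
#' `filters_per_kernel * length(kernel_sizes) + scalar_units`.
#'
#' @param config a [presentation_model_config()].
#' @param fcfg a [feature_config()].
#' @return a `PresentationModel` (parameters + configs), untrained.
#' @export
build_model <- function(config, fcfg) {
  if (any(config$kernel_sizes > fcfg$hotspot_length))
    stop("kernel size exceeds hotspot length ", fcfg$hotspot_length)
  D <- ncol(encoder_matrix(fcfg))
  with_seed(config$seed, {
    params <- list()
    for (k in config$kernel_sizes) {
      params[[paste0("Wconv", k)]] <- glorot(k * D, config$filters_per_kernel)
      params[[paste0("bconv", k)]] <- numeric(config$filters_per_kernel)
    }
    params$Wscalar <- glorot(N_SCALAR_FEATURES, config$scalar_units)
    params$bscalar <- numeric(config$scalar_units)
    widths <- c(config$filters_per_kernel * length(config$kernel_sizes) +
                  config$scalar_units, config$dense_units)
    for (i in seq_along(config$dense_units)) {
      params[[paste0("Wdense", i)]] <- glorot(widths[i], widths[i + 1L])
      params[[paste0("bdense", i)]] <- numeric(widths[i + 1L])
    }
    params$Wout <- glorot(widths[length(widths)], 1L)
    params$bout <- 0
    structure(list(params = params, config = config, feature_config = fcfg,
                   input_dim = D, trained = FALSE),
              class = "PresentationModel")
  })
}

#' @export
print.PresentationModel <- function(x, ...) {
  npar <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("PresentationModel: kernels [%s] x %d filters, dense [%s], %d parameters%s\n",
              paste(x$config$kernel_sizes, collapse = ","),
              x$config$filters_per_kernel,
              paste(x$config$dense_units, collapse = ","), npar,
              if (x$trained) "" else " (untrained)"))
  invisible(x)
}

# im2col: precompute, per kernel size, the unfolded window matrix of the
# whole dataset. Row layout: sample-major, position-fastest.
unfold_windows <- function(X, kernel_sizes) {
  n <- dim(X)[1L]; P <- dim(X)[2L]; D <- dim(X)[3L]
  out <- list()
  for (k in kernel_sizes) {
    Pk <- P - k + 1L
    Z <- matrix(0, n * Pk, k * D)
    for (p in seq_len(Pk)) {
      rows <- (seq_len(n) - 1L) * Pk + p
      Z[rows, ] <- matrix(X[, p:(p + k - 1L), , drop = FALSE], n, k * D)
    }
    out[[as.character(k)]] <- Z
  }
  out
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over sample indices `idx` of a precomputed feature set.
# Returns scores and (when `keep = TRUE`) the cache needed for backprop.
nn_forward <- function(params, cfg, Z_list, S, idx, drop_masks = NULL,
                       keep = FALSE) {
  nb <- length(idx)
  cache <- list(M = list(), A = list(), argmax = list(), rows = list())
  pooled <- vector("list", length(cfg$kernel_sizes))
  for (ki in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[ki]
    Z <- Z_list[[as.character(k)]]
    Pk <- nrow(Z) / nrow(S)
    rows <- rep((idx - 1L) * Pk, each = Pk) + rep(seq_len(Pk), nb)
    A <- relu(sweep(Z[rows, , drop = FALSE] %*% params[[paste0("Wconv", k)]],
                    2L, params[[paste0("bconv", k)]], `+`))
    Fn <- ncol(A)
    AM <- array(A, c(Pk, nb, Fn))
    best <- matrix(AM[1L, , ], nb, Fn)
    argm <- matrix(1L, nb, Fn)
    if (Pk > 1L) for (p in 2:Pk) {
      cur <- matrix(AM[p, , ], nb, Fn)
      upd <- cur > best
      argm[upd] <- p
      best[upd] <- cur[upd]
    }
    pooled[[ki]] <- best
    if (keep) {
      cache$A[[ki]] <- A; cache$argmax[[ki]] <- argm; cache$rows[[ki]] <- rows
      cache$Pk[[ki]] <- Pk
    }
  }
  Sb <- S[idx, , drop = FALSE]
  Hs <- relu(sweep(Sb %*% params$Wscalar, 2L, params$bscalar, `+`))
  H <- cbind(do.call(cbind, pooled), Hs)
  if (keep) { cache$H0 <- H; cache$Hs <- Hs; cache$Sb <- Sb }
  Hd <- list()
  for (i in seq_along(cfg$dense_units)) {
    H <- relu(sweep(H %*% params[[paste0("Wdense", i)]], 2L,
                    params[[paste0("bdense", i)]], `+`))
    if (!is.null(drop_masks)) H <- H * drop_masks[[i]]
    Hd[[i]] <- H
  }
  z <- drop(H %*% params$Wout) + params$bout
  p <- sigmoid(z)
  if (keep) { cache$Hd <- Hd; cache$p <- p }
  if (keep) list(p = p, cache = cache) else p
}

nn_backward <- function(params, cfg, Z_list, S, idx, y, cache, drop_masks,
                        pos_weight) {
  nb <- length(idx)
  w <- if (is.null(pos_weight)) rep(1, nb) else ifelse(y == 1, pos_weight, 1)
  dz <- w * (cache$p - y) / nb
  grads <- list()
  H_last <- cache$Hd[[length(cache$Hd)]]
  grads$Wout <- crossprod(H_last, dz)
  grads$bout <- sum(dz)
  dH <- matrix(dz, ncol = 1L) %*% t(params$Wout)
  for (i in rev(seq_along(cfg$dense_units))) {
    Hi <- cache$Hd[[i]]
    dH <- dH * drop_masks[[i]] * (Hi > 0)
    Hin <- if (i == 1L) cache$H0 else cache$Hd[[i - 1L]]
    grads[[paste0("Wdense", i)]] <- crossprod(Hin, dH)
    grads[[paste0("bdense", i)]] <- colSums(dH)
    dH <- dH %*% t(params[[paste0("Wdense", i)]])
  }
  # split the concatenation gradient
  Fn <- cfg$filters_per_kernel
  off <- 0L
  for (ki in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[ki]
    dM <- dH[, (off + 1L):(off + Fn), drop = FALSE]
    off <- off + Fn
    Pk <- cache$Pk[[ki]]
    A <- cache$A[[ki]]; argm <- cache$argmax[[ki]]
    dA <- matrix(0, nb * Pk, Fn)
    rsel <- (rep(seq_len(nb), times = Fn) - 1L) * Pk + as.vector(argm)
    csel <- rep(seq_len(Fn), each = nb)
    sel <- cbind(rsel, csel)
    dA[sel] <- as.vector(dM) * (A[sel] > 0)
    Zb <- Z_list[[as.character(k)]][cache$rows[[ki]], , drop = FALSE]
    grads[[paste0("Wconv", k)]] <- crossprod(Zb, dA)
    grads[[paste0("bconv", k)]] <- colSums(dA)
  }
  dHs <- dH[, (off + 1L):(off + cfg$scalar_units), drop = FALSE] * (cache$Hs > 0)
  grads$Wscalar <- crossprod(cache$Sb, dHs)
  grads$bscalar <- colSums(dHs)
  grads
}

bce_loss <- function(p, y, pos_weight = NULL) {
  eps <- 1e-12
  w <- if (is.null(pos_weight)) rep(1, length(y)) else ifelse(y == 1, pos_weight, 1)
  -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

# Scalar features of a candidate table: -log10 rank (missing ranks imputed),
# hydrophobicity, and length relative to the hotspot.
scalar_features <- function(peptides, rank_percent, fcfg, impute_rank = 50) {
  rank_percent[is.na(rank_percent)] <- impute_rank
  cbind(rank_transform(rank_percent, fcfg$rank_floor),
        vapply(peptides, hydrophobicity,
               numeric(1L), hydrophobic_set = fcfg$hydrophobic_set,
               pad_symbol = fcfg$pad_symbol, USE.NAMES = FALSE),
        nchar(peptides) / fcfg$hotspot_length)
}

#' Train the presentation model on a labeled peptide table
#'
#' Minimizes (optionally class-weighted) binary cross-entropy with Adam and
#' decoupled weight decay, stopping early when the loss on a held-in
#' validation slice stops improving. Fully deterministic for a fixed
#' config seed.
#'
#' @param data data.frame with `peptide`, `rank_percent`, `label` (0/1).
#' @param config a [presentation_model_config()].
#' @param fcfg a [feature_config()].
#' @param verbose print per-epoch losses.
#' @return a trained `PresentationModel`.
#' @export
fit_presentation_model <- function(data, config, fcfg, verbose = FALSE) {
  if (length(unique(data$label)) < 2L)
    stop("training data must contain both labels")
  if (any(nchar(data$peptide) > fcfg$hotspot_length))
    stop("peptide longer than hotspot length ", fcfg$hotspot_length,
         "; no core-extraction policy is defined")
  model <- build_model(config, fcfg)
  X <- encode_batch(data$peptide, fcfg)
  S <- scalar_features(data$peptide, data$rank_percent, fcfg)
  y <- as.numeric(data$label)
  n <- length(y)
  Z_list <- unfold_windows(X, config$kernel_sizes)

  with_seed(config$seed + 1L, {
    # held-in validation slice, stratified by label
    val <- unlist(lapply(split(seq_len(n), y), function(ix) {
      nv <- max(1L, round(length(ix) * config$val_fraction))
      sample(ix, nv)
    }), use.names = FALSE)
    tr <- setdiff(seq_len(n), val)

    params <- model$params
    mom <- lapply(params, function(p) p * 0)
    vel <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    best_val <- Inf; best_params <- params; stall <- 0L
    dense_n <- length(config$dense_units)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr)
      for (b in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[b:min(b + config$batch_size - 1L, length(ord))]
        masks <- lapply(seq_len(dense_n), function(i) {
          u <- config$dense_units[i]
          if (config$dropout > 0)
            matrix(rbinom(length(idx) * u, 1L, 1 - config$dropout) /
                     (1 - config$dropout), length(idx), u)
          else matrix(1, length(idx), u)
        })
        fw <- nn_forward(params, config, Z_list, S, idx, drop_masks = masks,
                         keep = TRUE)
        grads <- nn_backward(params, config, Z_list, S, idx, y[idx],
                             fw$cache, masks, config$pos_weight)
        step <- step + 1L
        for (nm in names(grads)) {
          g <- grads[[nm]]
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          upd <- config$learning_rate * mhat / (sqrt(vhat) + eps)
          if (startsWith(nm, "W"))
            upd <- upd + config$learning_rate * config$weight_decay * params[[nm]]
          params[[nm]] <- params[[nm]] - upd
        }
      }
      p_val <- nn_forward(params, config, Z_list, S, val)
      val_loss <- bce_loss(p_val, y[val], config$pos_weight)
      if (verbose)
        message(sprintf("epoch %d: val loss %.5f", epoch, val_loss))
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_params <- params; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    model$params <- best_params
    model$trained <- TRUE
    model
  })
}

#' Score candidate peptides with a presentation model
#'
#' @param model a `PresentationModel`.
#' @param candidates data.frame with at least `peptide`; `rank_percent` is
#'   used when present, with missing ranks imputed at `impute_rank`.
#' @param impute_rank percentile rank substituted for missing ranks
#'   (default 50, an uninformative mid-scale value).
#' @return `candidates` with a `score` column in `[0, 1]`; row order
#'   preserved.
#' @export
predict_presentation <- function(model, candidates, impute_rank = 50) {
  if (!nrow(candidates)) {
    candidates$score <- numeric(0L)
    return(candidates)
  }
  fcfg <- model$feature_config
  if (any(nchar(candidates$peptide) > fcfg$hotspot_length))
    stop("peptide longer than hotspot length ", fcfg$hotspot_length,
         "; no core-extraction policy is defined")
  rank <- if ("rank_percent" %in% names(candidates)) candidates$rank_percent
          else rep(NA_real_, nrow(candidates))
  X <- encode_batch(candidates$peptide, fcfg)
  S <- scalar_features(candidates$peptide, rank, fcfg, impute_rank)
  Z_list <- unfold_windows(X, model$config$kernel_sizes)
  candidates$score <- as.numeric(
    nn_forward(model$params, model$config, Z_list, S, seq_len(nrow(candidates))))
  candidates
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with midrank tie handling:
#' equal to the probability that a random positive outscores a random
#' negative, counting ties as one half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: the sum over positives, in
#' decreasing-score order, of precision at each positive's rank, divided
#' by the number of positives. Ties are broken by original index for
#' determinism.
#'
#' @inheritParams roc_auc
#' @return average precision in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  if (n1 == 0L) stop("pr_auc requires positives")
  ord <- order(-scores, seq_along(scores))
  ys <- y[ord]
  prec <- cumsum(ys) / seq_along(ys)
  sum(prec[ys == 1L]) / n1
}

#' Generate length-matched decoy peptides from a source proteome
#'
#' Draws negative examples as substrings of the source proteome, sampled
#' uniformly over all eligible start positions, with the decoy length
#' multiset equal to exactly `ratio` copies of the positives' length
#' multiset. No decoy may equal any positive; draws colliding with the
#' positive set are retried a bounded number of times.
#'
#' @param positives character vector of positive peptides.
#' @param source_proteome named character vector of protein sequences.
#' @param ratio decoys per positive (r in the 1:r imbalance).
#' @param seed integer seed.
#' @param max_retries resampling rounds before giving up.
#' @return character vector of `ratio * length(positives)` decoys.
#' @export
generate_decoys <- function(positives, source_proteome, ratio, seed,
                            max_retries = 100L) {
  if (ratio == 0L) return(character(0L))
  stopifnot(ratio >= 0L, length(positives) >= 1L)
  posset <- unique(positives)
  with_seed(seed, {
    out <- character(0L)
    for (len in sort(unique(nchar(positives)))) {
      need <- ratio * sum(nchar(positives) == len)
      n_starts <- pmax(0L, nchar(source_proteome) - len + 1L)
      total <- sum(n_starts)
      if (total < 1L)
        stop("source proteome has no windows of length ", len)
      cum <- cumsum(n_starts)
      got <- character(0L)
      for (try in seq_len(max_retries)) {
        draw <- sample.int(total, need - length(got), replace = TRUE)
        rec <- findInterval(draw - 1L, cum) + 1L
        start <- draw - c(0L, cum)[rec]
        pep <- substr(rep(source_proteome[rec], 1L), start, start + len - 1L)
        pep <- unname(pep[!pep %in% posset])
        got <- c(got, pep)
        if (length(got) >= need) { got <- got[seq_len(need)]; break }
      }
      if (length(got) < need)
        stop("could not generate ", need - length(got),
             " decoy(s) of length ", len, " disjoint from the positives")
      out <- c(out, got)
    }
    out
  })
}

#' Stratified k-fold cross-validation of the presentation model
#'
#' Folds are stratified jointly by label and allele. Each fold's model is
#' trained only on its training split; ROC-AUC and PR-AUC are computed on
#' the held-out split and pooled over all held-out predictions.
#'
#' @param dataset data.frame with `peptide`, `allele`, `rank_percent`,
#'   `label`.
#' @param config a [presentation_model_config()] (`folds` >= 2).
#' @param fcfg a [feature_config()].
#' @param verbose print per-fold metrics.
#' @return list with `models` (one per fold) and `report` (a `CvReport`:
#'   per-fold and pooled ROC/PR AUC, fold assignments, seed, config
#'   fingerprint).
#' @export
train_cv <- function(dataset, config, fcfg, verbose = FALSE) {
  if (length(unique(dataset$label)) < 2L)
    stop("cross-validation requires both labels")
  n <- nrow(dataset)
  folds <- config$folds
  assign <- integer(n)
  with_seed(config$seed, {
    groups <- split(seq_len(n), paste(dataset$label, dataset$allele))
    for (ix in groups) {
      assign[sample(ix)] <- rep(seq_len(folds), length.out = length(ix))
    }
  })
  scores <- numeric(n)
  per_fold <- list()
  models <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(assign == f); tr <- which(assign != f)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    model <- fit_presentation_model(dataset[tr, , drop = FALSE], cfg_f, fcfg)
    pred <- predict_presentation(model, dataset[te, , drop = FALSE])
    scores[te] <- pred$score
    fold_roc <- if (length(unique(dataset$label[te])) == 2L)
      roc_auc(dataset$label[te], pred$score) else NA_real_
    fold_pr <- if (any(dataset$label[te] == 1L))
      pr_auc(dataset$label[te], pred$score) else NA_real_
    per_fold[[f]] <- data.frame(fold = f, n = length(te),
                                roc_auc = fold_roc, pr_auc = fold_pr)
    models[[f]] <- model
    if (verbose)
      message(sprintf("fold %d/%d: ROC-AUC %.4f PR-AUC %.4f", f, folds,
                      fold_roc, fold_pr))
  }
  report <- structure(list(
    per_fold = do.call(rbind, per_fold),
    pooled_roc_auc = roc_auc(dataset$label, scores),
    pooled_pr_auc = pr_auc(dataset$label, scores),
    fold_assignments = assign,
    pooled_scores = scores,
    seed = config$seed,
    config_fingerprint = as.character(jsonlite::toJSON(
      config[setdiff(names(config), "pos_weight")], auto_unbox = TRUE))),
    class = "CvReport")
  list(models = models, report = report)
}

#' @export
print.CvReport <- function(x, ...) {
  cat(sprintf("CvReport: %d folds, pooled ROC-AUC %.4f, pooled PR-AUC %.4f\n",
              nrow(x$per_fold), x$pooled_roc_auc, x$pooled_pr_auc))
  invisible(x)
}

#' Filter scored candidates into called binders
#'
#' A candidate is kept iff its score passes `score_threshold` and its rank
#' is missing or passes `rank_threshold`. Counts are reported separately
#' for MHC class I and II.
#'
#' @param scored data.frame with `score`, `mhc_class` and optionally
#'   `rank_percent`.
#' @param score_threshold minimum presentation score.
#' @param rank_threshold maximum percentile binding rank.
#' @return list with `candidates` (kept rows) and `counts` (named vector,
#'   classes I and II).
#' @export
call_binders <- function(scored, score_threshold = 0.5, rank_threshold = 2) {
  rank <- if ("rank_percent" %in% names(scored)) scored$rank_percent
          else rep(NA_real_, nrow(scored))
  keep <- scored$score >= score_threshold & (is.na(rank) | rank <= rank_threshold)
  kept <- scored[keep, , drop = FALSE]
  counts <- c(I = sum(kept$mhc_class == "I"), II = sum(kept$mhc_class == "II"))
  list(candidates = kept, counts = counts)
}
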