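## Convolutional-recurrent promoter model: one-hot DNA -> valid-mode
## convolution (ReLU) -> non-overlapping max-pooling -> bidirectional
## LSTM -> max-over-time readout -> dense (ReLU) -> 3 linear outputs,
## trained by summed per-output mean squared error with Adam. Implemented
## directly on base R matrix algebra with hand-derived gradients
## (verified against numerical derivatives in the test suite); single
## threaded and bit-reproducible under a fixed seed.

#' One-hot encode a DNA sequence
#'
#' A/C/G/T map to unit columns (rows in A, C, G, T order); N maps to an
#' all-0.25 column. Case-insensitive; any other character errors.
#'
#' @param seq DNA string.
#' @return 4 x nchar(seq) numeric matrix.
#' @export
one_hot_encode <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) {
    stop(sprintf("invalid character '%s' in sequence",
                 chars[which(is.na(codes))[1]]))
  }
  cols <- cbind(diag(4), rep(0.25, 4))
  m <- cols[, codes, drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Promoter model configuration
#'
#' Desk-scale defaults: 32 filters of width 13, max-pool 6, 16
#' recurrent units per direction, dense width 32, 3 outputs, Adam with
#' a cosine-decayed learning rate (to 10% of the base rate;
#' `lr_schedule = "constant"` disables the decay) and optional
#' decoupled weight decay on the weight matrices.
#'
#' @param ... overrides of any default field; unknown names error.
#' @return list of class "cnn_config".
#' @export
cnn_config <- function(...) {
  cfg <- list(
    n_filters = 32L, filter_width = 13L, pool_width = 6L,
    recurrent_units = 16L, dense_units = 32L, n_outputs = 3L,
    epochs = 15L, learning_rate = 2e-3, batch_size = 32L,
    lr_schedule = "cosine", weight_decay = 0, p_cap = 20, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown cnn_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "cnn_config")
}

#' Build regression labels from a rhythmicity scan
#'
#' The three continuous targets per (gene, genotype): relative
#' amplitude, `-log10(pvalue)` capped at `p_cap` (a perfect fit would
#' otherwise give an infinite target), and R-squared.
#'
#' @param rhythm data.frame from [rhythm_scan()].
#' @param p_cap cap on the -log10 p label (default 20).
#' @return numeric matrix n x 3 (rel_amp, neglog10_p, R2) with rownames
#'   "gene|genotype".
#' @export
rhythm_labels <- function(rhythm, p_cap = 20) {
  p <- pmin(-log10(pmax(rhythm$pvalue, 1e-300)), p_cap)
  m <- cbind(rel_amp = ifelse(is.na(rhythm$rel_amp), 0, rhythm$rel_amp),
             neglog10_p = p, R2 = rhythm$R2)
  rownames(m) <- paste(rhythm$gene_id, rhythm$genotype_id, sep = "|")
  m
}

## --- internal tensor plumbing -------------------------------------

## flatten a sequence to the column-major one-hot vector used by the
## sliding-window im2col construction
.seq_flat <- function(seq) as.vector(one_hot_encode(seq))

## im2col row template: row p covers one-hot entries of positions
## p..p+fw-1 (valid mode)
.im2col_template <- function(L, fw) {
  P <- L - fw + 1L
  outer(seq(0L, by = 4L, length.out = P), seq_len(4L * fw), "+")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.init_params <- function(cfg) {
  fw <- cfg$filter_width; F <- cfg$n_filters
  H <- cfg$recurrent_units; D <- cfg$dense_units; K <- cfg$n_outputs
  gl <- function(nr, nc, scale) {
    matrix(rnorm(nr * nc, 0, scale), nr, nc)
  }
  lstm <- function() list(
    Wx = gl(F, 4 * H, 1 / sqrt(F)),
    Wh = gl(H, 4 * H, 1 / sqrt(H)),
    ## forget-gate bias 1 keeps the cell memory alive at init
    b = c(rep(0, H), rep(1, H), rep(0, 2 * H))
  )
  list(
    Wc = gl(4 * fw, F, sqrt(2 / (4 * fw))), bc = rep(0, F),
    fwd = lstm(), bwd = lstm(),
    W1 = gl(2 * H, D, sqrt(2 / (2 * H))), b1 = rep(0, D),
    W2 = gl(D, K, sqrt(1 / D)), b2 = rep(0, K)
  )
}

## Batch im2col template: one index gather for a whole batch of
## flattened one-hot sequences laid out column-wise.
.batch_template <- function(tmpl, B, L) {
  P <- nrow(tmpl)
  off <- rep((seq_len(B) - 1L) * (4L * L), each = P)
  tmpl[rep(seq_len(P), times = B), , drop = FALSE] + off
}

## Forward pass for a batch. xflat: 4L x B matrix of flattened one-hot
## sequences. btmpl: optional cached .batch_template for this batch
## size. Returns prediction and (optionally) the backward caches.
.cnn_forward <- function(params, xflat, tmpl, cfg, keep_cache = FALSE,
                         btmpl = NULL) {
  B <- ncol(xflat)
  P <- nrow(tmpl)
  L <- nrow(xflat) %/% 4L
  F <- cfg$n_filters; H <- cfg$recurrent_units
  q <- cfg$pool_width
  T_ <- P %/% q
  ## conv: single gather builds all im2col blocks (seq-major rows);
  ## a trailing 1s column folds the filter bias into the product
  if (is.null(btmpl)) btmpl <- .batch_template(tmpl, B, L)
  Xc <- cbind(matrix(xflat[btmpl], B * P), 1)
  conv_pre <- Xc %*% rbind(params$Wc, params$bc)
  conv <- pmax(conv_pre, 0)
  ## pool: group conv rows (position fastest, then sequence, then
  ## filter in column-major order) into q-blocks; columns of cw are
  ## then indexed (t, b, f)
  usable <- q * T_
  if (usable == P) {
    keep_rows <- seq_len(B * P)
    cw <- conv
  } else {
    keep_rows <- as.vector(outer(seq_len(usable),
                                 (seq_len(B) - 1) * P, "+"))
    cw <- conv[keep_rows, , drop = FALSE]
  }
  dim(cw) <- c(q, length(cw) %/% q)
  amax <- max.col(t(cw), ties.method = "first")
  ncw <- ncol(cw)
  pooled_flat <- cw[cbind(amax, seq_len(ncw))]   # length T*B*F, (t,b,f)
  ## stack pooled inputs as one (T*B) x F matrix, timestep-major, so
  ## the per-direction input projections batch into a single product
  ord_tb <- as.vector(outer(seq(0, by = T_, length.out = B),
                            seq_len(T_), "+"))   # (b,t) -> t-major
  Pmat <- matrix(0, T_ * B, F)
  for (f in seq_len(F)) {
    Pmat[, f] <- pooled_flat[(f - 1) * T_ * B + ord_tb]
  }
  ## bidirectional LSTM with max-over-time readout (per-unit maximum
  ## of the hidden state across steps; picks up localized motif hits
  ## without diluting them over the sequence). The input projection
  ## for all timesteps is one matrix product.
  run_lstm <- function(pp, reverse = FALSE) {
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
    Hs <- vector("list", T_); Cs <- vector("list", T_)
    G <- if (keep_cache) vector("list", T_) else NULL
    hmax <- matrix(-Inf, B, H); amax_t <- matrix(0L, B, H)
    XW <- Pmat %*% pp$Wx
    bmat <- matrix(pp$b, B, 4 * H, byrow = TRUE)
    i3 <- 1:(3 * H); i4 <- (3 * H + 1):(4 * H)
    for (t in ord) {
      rows <- ((t - 1L) * B + 1L):(t * B)
      z <- XW[rows, , drop = FALSE] + (h %*% pp$Wh + bmat)
      z[, i3] <- .sigmoid(z[, i3])
      z[, i4] <- tanh(z[, i4])
      i <- z[, 1:H, drop = FALSE]
      f <- z[, (H + 1):(2 * H), drop = FALSE]
      o <- z[, (2 * H + 1):(3 * H), drop = FALSE]
      cc <- f * cc + i * z[, i4, drop = FALSE]
      h <- o * tanh(cc)
      Hs[[t]] <- h; Cs[[t]] <- cc
      if (keep_cache) G[[t]] <- z
      upd <- h > hmax
      hmax[upd] <- h[upd]
      amax_t[upd] <- t
    }
    list(Hs = Hs, Cs = Cs, G = G, hmax = hmax, amax_t = amax_t)
  }
  lf <- run_lstm(params$fwd, FALSE)
  lb <- run_lstm(params$bwd, TRUE)
  u <- cbind(lf$hmax, lb$hmax)                   # B x 2H
  d_pre <- sweep(u %*% params$W1, 2, params$b1, "+")
  d <- pmax(d_pre, 0)
  yhat <- sweep(d %*% params$W2, 2, params$b2, "+")
  if (!keep_cache) return(list(yhat = yhat))
  list(yhat = yhat, Xc = Xc, conv_pre = conv_pre, amax = amax,
       keep_rows = keep_rows, Pmat = Pmat, lf = lf, lb = lb,
       u = u, d = d, T_ = T_, P = P, B = B, q = q, usable = usable)
}

## Loss and gradients for a batch (summed-MSE over outputs, mean over
## batch).
.cnn_forward_backward <- function(params, xflat, y, tmpl, cfg,
                                  btmpl = NULL) {
  fw <- .cnn_forward(params, xflat, tmpl, cfg, keep_cache = TRUE,
                     btmpl = btmpl)
  B <- fw$B; F <- cfg$n_filters; H <- cfg$recurrent_units
  T_ <- fw$T_
  err <- fw$yhat - y
  loss <- sum(err^2) / B
  dy <- 2 * err / B
  gW2 <- crossprod(fw$d, dy); gb2 <- colSums(dy)
  dd <- dy %*% t(params$W2)
  dd[fw$d <= 0] <- 0
  gW1 <- crossprod(fw$u, dd); gb1 <- colSums(dd)
  du <- dd %*% t(params$W1)
  dPmat <- matrix(0, T_ * B, F)

  back_lstm <- function(pp, cache, du_dir, reverse = FALSE) {
    gWh <- matrix(0, H, 4 * H)
    dZ <- matrix(0, T_ * B, 4 * H)
    dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
    ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
    for (t in rev(ord)) {
      prev_t <- if (reverse) {
        if (t == T_) 0L else t + 1L
      } else t - 1L
      h_prev <- if (prev_t == 0L) matrix(0, B, H) else cache$Hs[[prev_t]]
      c_prev <- if (prev_t == 0L) matrix(0, B, H) else cache$Cs[[prev_t]]
      gt <- cache$G[[t]]
      i <- gt[, 1:H, drop = FALSE]
      f <- gt[, (H + 1):(2 * H), drop = FALSE]
      o <- gt[, (2 * H + 1):(3 * H), drop = FALSE]
      g <- gt[, (3 * H + 1):(4 * H), drop = FALSE]
      tc <- tanh(cache$Cs[[t]])
      dh <- du_dir * (cache$amax_t == t) + dh_next
      dc <- dh * o * (1 - tc^2) + dc_next
      dz <- cbind(
        dc * g * i * (1 - i),
        dc * c_prev * f * (1 - f),
        dh * tc * o * (1 - o),
        dc * i * (1 - g^2)
      )
      dZ[((t - 1L) * B + 1L):(t * B), ] <- dz
      gWh <- gWh + crossprod(h_prev, dz)
      dh_next <- dz %*% t(pp$Wh)
      dc_next <- dc * f
    }
    ## batched input-side gradients
    dPmat <<- dPmat + dZ %*% t(pp$Wx)
    list(Wx = crossprod(Pmat, dZ), Wh = gWh, b = colSums(dZ))
  }
  Pmat <- fw$Pmat
  gf <- back_lstm(params$fwd, fw$lf, du[, 1:H, drop = FALSE], FALSE)
  gb_ <- back_lstm(params$bwd, fw$lb,
                   du[, (H + 1):(2 * H), drop = FALSE], TRUE)

  ## pool backward: route dP to the argmax rows of conv. The flattened
  ## (t, b, f) order equals the pooled column order, and each pooled
  ## cell maps to a distinct (conv row, filter) pair, so the scatter is
  ## a single indexed assignment.
  dconv <- matrix(0, B * fw$P, F)
  ncw <- T_ * B * F
  col_id <- seq_len(ncw)
  blk <- (col_id - 1L) %% (T_ * B)        # (t, b) block within a filter
  filt <- (col_id - 1L) %/% (T_ * B) + 1L
  row_in_cv <- blk * fw$q + fw$amax        # row index in cv (1-based)
  conv_row <- fw$keep_rows[row_in_cv]
  ## dPmat rows are timestep-major with batch fastest; reorder to the
  ## (t, b, f) flat order of the pooled columns
  perm <- as.vector(outer((seq_len(T_) - 1L) * B, seq_len(B), "+"))
  dvals <- as.vector(dPmat[perm, , drop = FALSE])
  idx <- cbind(conv_row, filt)
  dconv[idx] <- dvals * (fw$conv_pre[idx] > 0)
  gWcb <- crossprod(fw$Xc, dconv)   # last row is the bias gradient
  nr <- nrow(gWcb)
  gWc <- gWcb[-nr, , drop = FALSE]
  gbc <- gWcb[nr, ]

  list(loss = loss,
       grads = list(Wc = gWc, bc = gbc, fwd = gf, bwd = gb_,
                    W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

.flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

.unflatten_params <- function(vec, ref) {
  out <- ref; k <- 0L
  assign_rec <- function(x) {
    if (is.list(x)) return(lapply(x, assign_rec))
    n <- length(x)
    v <- vec[(k + 1):(k + n)]
    k <<- k + n
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  assign_rec(ref)
}

#' Train the promoter model
#'
#' Trains the convolution / max-pool / bidirectional-LSTM / dense
#' network on promoter sequences with three continuous rhythmicity
#' labels, minimizing the sum over outputs of mean squared error with
#' Adam. The train/validation split is by genotype so no genotype's
#' alleles straddle the split. Labels are standardized internally with
#' training-set statistics; reported losses are on the standardized
#' scale, while predictions are returned on the original scale.
#'
#' @param sequences named character vector of promoter sequences
#'   (all the same length).
#' @param labels numeric matrix n x 3, rows aligned with `sequences`.
#' @param genotypes character vector, genotype of each sequence.
#' @param val_genotypes genotypes held out for validation (default: the
#'   last genotype in sorted order).
#' @param config a [cnn_config()].
#' @return object of class "promoter_model": params, config, history
#'   (per-epoch train/val loss), label statistics, split.
#' @export
train_promoter_model <- function(sequences, labels, genotypes,
                                 val_genotypes = NULL,
                                 config = cnn_config()) {
  n <- length(sequences)
  labels <- as.matrix(labels)
  if (nrow(labels) != n || length(genotypes) != n) {
    stop("sequences, labels and genotypes must align")
  }
  if (!all(is.finite(labels))) stop("labels must be finite")
  gset <- sort(unique(genotypes))
  if (length(gset) < 2) stop("need >= 2 genotypes to split")
  if (is.null(val_genotypes)) val_genotypes <- gset[length(gset)]
  val <- genotypes %in% val_genotypes
  if (!any(val) || all(val)) stop("split leaves an empty partition")

  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("sequences must share one length")
  set.seed(config$seed)
  tmpl <- .im2col_template(L, config$filter_width)
  xflat <- vapply(sequences, .seq_flat, numeric(4 * L))

  mu <- colMeans(labels[!val, , drop = FALSE])
  sdv <- pmax(apply(labels[!val, , drop = FALSE], 2, sd), 1e-8)
  ystd <- sweep(sweep(labels, 2, mu), 2, sdv, "/")

  params <- .init_params(config)
  flat <- .flatten_params(params)
  m_adam <- numeric(length(flat)); v_adam <- numeric(length(flat))
  ## decoupled weight decay applies to weight matrices, not biases
  wd_mask <- unlist(rapply(params, function(x) {
    rep(if (is.matrix(x)) 1 else 0, length(x))
  }, how = "list"), use.names = FALSE)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tr_idx <- which(!val); va_idx <- which(val)
  ## cache the batched im2col index template per batch size
  btmpl_cache <- new.env(parent = emptyenv())
  get_btmpl <- function(b) {
    key <- as.character(b)
    if (is.null(btmpl_cache[[key]])) {
      btmpl_cache[[key]] <- .batch_template(tmpl, b, L)
    }
    btmpl_cache[[key]]
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  eval_loss <- function(idx) {
    tot <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      out <- .cnn_forward(params, xflat[, chunk, drop = FALSE], tmpl,
                          config, btmpl = get_btmpl(length(chunk)))
      tot <- tot + sum((out$yhat - ystd[chunk, , drop = FALSE])^2)
    }
    tot / length(idx)
  }
  for (ep in seq_len(config$epochs)) {
    ## cosine decay to 10% of the base rate over the run; "constant"
    ## keeps the base rate throughout
    lr_ep <- if (identical(config$lr_schedule, "cosine") &&
                 config$epochs > 1) {
      lr0 <- config$learning_rate
      0.1 * lr0 + 0.45 * lr0 *
        (1 + cos(pi * (ep - 1) / (config$epochs - 1)))
    } else {
      config$learning_rate
    }
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      fb <- .cnn_forward_backward(params, xflat[, bt, drop = FALSE],
                                  ystd[bt, , drop = FALSE], tmpl, config,
                                  btmpl = get_btmpl(length(bt)))
      ep_loss <- ep_loss + fb$loss * length(bt)
      g <- .flatten_params(fb$grads)
      step <- step + 1L
      m_adam <- b1 * m_adam + (1 - b1) * g
      v_adam <- b2 * v_adam + (1 - b2) * g^2
      mh <- m_adam / (1 - b1^step)
      vh <- v_adam / (1 - b2^step)
      flat <- .flatten_params(params)
      flat <- flat - lr_ep *
        (mh / (sqrt(vh) + eps) + config$weight_decay * wd_mask * flat)
      params <- .unflatten_params(flat, params)
    }
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / length(tr_idx),
      val_loss = eval_loss(va_idx)))
  }
  structure(list(params = params, config = config, history = history,
                 label_mu = mu, label_sd = sdv, seq_len = L,
                 train_ids = names(sequences)[tr_idx],
                 val_ids = names(sequences)[va_idx]),
            class = "promoter_model")
}

#' @exportS3Method base::print
print.promoter_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "Promoter model: %d filters x %d bp, %d LSTM units/dir; %d epochs (train loss %.3f, val loss %.3f)\n",
    x$config$n_filters, x$config$filter_width, x$config$recurrent_units,
    h$epoch, h$train_loss, h$val_loss))
  invisible(x)
}

#' Predict rhythmicity labels from promoter sequence
#'
#' @param object trained "promoter_model".
#' @param sequences character vector of sequences of the trained
#'   length.
#' @param ... unused.
#' @return numeric matrix n x 3 on the original label scale.
#' @export
predict.promoter_model <- function(object, sequences, ...) {
  L <- unique(nchar(sequences))
  if (length(L) != 1 || L != object$seq_len) {
    stop("sequences must have the trained length")
  }
  cfg <- object$config
  tmpl <- .im2col_template(L, cfg$filter_width)
  xflat <- vapply(sequences, .seq_flat, numeric(4 * L))
  out <- matrix(0, length(sequences), cfg$n_outputs)
  idx <- seq_along(sequences)
  for (chunk in split(idx, ceiling(idx / cfg$batch_size))) {
    fwd <- .cnn_forward(object$params, xflat[, chunk, drop = FALSE],
                        tmpl, cfg)
    out[chunk, ] <- fwd$yhat
  }
  out <- sweep(sweep(out, 2, object$label_sd, "*"), 2, object$label_mu,
               "+")
  colnames(out) <- names(object$label_mu)
  rownames(out) <- names(sequences)
  out
}

#' Convert trained convolutional filters to sequence motifs
#'
#' Scans the sequences with each filter, collects the filter-width
#' subsequences wherever the activation reaches
#' `activation_fraction` times that filter's maximum activation, and
#' builds a position frequency matrix with pseudocount 1. Filters with
#' fewer than `min_sites` activating sites are dropped.
#'
#' @param model trained "promoter_model".
#' @param sequences character vector (>= 100 sequences) of the trained
#'   length.
#' @param activation_fraction threshold as a fraction of the per-filter
#'   maximum (default 0.5).
#' @param min_sites minimum activating sites to keep a filter
#'   (default 10).
#' @return named list of [new_motif_pfm()] motifs ("filter<k>").
#' @export
filters_to_motifs <- function(model, sequences,
                              activation_fraction = 0.5,
                              min_sites = 10) {
  if (!inherits(model, "promoter_model")) stop("model must be trained")
  if (length(sequences) < 100) stop("need >= 100 sequences")
  cfg <- model$config
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("sequences must share one length")
  fw <- cfg$filter_width
  tmpl <- .im2col_template(L, fw)
  P <- nrow(tmpl)
  F <- cfg$n_filters
  seqs_up <- toupper(sequences)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  codes <- lapply(seqs_up, function(s) {
    unname(base_idx[strsplit(s, "")[[1]]])  # NA for ambiguous bases
  })
  ## per-sequence activation maps (positions x filters)
  act <- vector("list", length(sequences))
  for (s in seq_along(seqs_up)) {
    x <- .seq_flat(seqs_up[s])
    a <- sweep(matrix(x[tmpl], P) %*% model$params$Wc, 2,
               model$params$bc, "+")
    act[[s]] <- pmax(a, 0)
  }
  fmax <- Reduce(pmax, lapply(act, function(a) apply(a, 2, max)))
  motifs <- list()
  for (f in seq_len(F)) {
    if (fmax[f] <= 0) next
    thr <- activation_fraction * fmax[f]
    counts <- matrix(0, 4, fw)
    n_sites <- 0L
    for (s in seq_along(seqs_up)) {
      pos <- which(act[[s]][, f] >= thr)
      for (p in pos) {
        ki <- codes[[s]][p:(p + fw - 1L)]
        ok <- which(!is.na(ki))
        counts[cbind(ki[ok], ok)] <- counts[cbind(ki[ok], ok)] + 1
        n_sites <- n_sites + 1L
      }
    }
    if (n_sites < min_sites) next
    pfm <- sweep(counts + 1, 2, colSums(counts + 1), "/")
    motifs[[sprintf("filter%d", f)]] <-
      new_motif_pfm(pfm, name = sprintf("filter%d", f),
                    n_sites = n_sites)
  }
  motifs
}

.iupac_pfm <- function(s) {
  map <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(s), "")[[1]]
  if (!all(chars %in% names(map))) stop("invalid IUPAC string")
  m <- vapply(chars, function(ch) {
    col <- rep(0, 4); names(col) <- c("A", "C", "G", "T")
    col[map[[ch]]] <- 1 / length(map[[ch]])
    col
  }, numeric(4))
  m
}

.revcomp_pfm <- function(m) m[4:1, ncol(m):1, drop = FALSE]

#' Similarity between a learned motif and a reference
#'
#' Maximum, over all ungapped offsets (overlap at least 5 columns) and
#' both strands, of the mean per-column Pearson correlation between the
#' two position probability matrices. Columns with zero variance (e.g.
#' uniform background positions) contribute a correlation of 0.
#'
#' @param pfm a "motif_pfm" (or bare 4 x W column-stochastic matrix).
#' @param reference a "motif_pfm", a 4 x W matrix, or an IUPAC string.
#' @return score in [-1, 1].
#' @export
motif_match_score <- function(pfm, reference) {
  getm <- function(x) {
    if (inherits(x, "motif_pfm")) return(x$pfm)
    if (is.character(x)) return(.iupac_pfm(x))
    as.matrix(x)
  }
  a <- getm(pfm); b <- getm(reference)
  if (min(ncol(a), ncol(b)) < 5) stop("overlap of >= 5 columns impossible")
  col_cor <- function(u, v) {
    if (sd(u) == 0 || sd(v) == 0) return(0)
    suppressWarnings(stats::cor(u, v))
  }
  score_pair <- function(a, b) {
    wa <- ncol(a); wb <- ncol(b)
    best <- -Inf
    for (off in (-(wb - 5)):(wa - 5)) {
      ia <- max(1, off + 1); ib <- max(1, 1 - off)
      len <- min(wa - ia + 1, wb - ib + 1)
      if (len < 5) next
      cs <- vapply(seq_len(len) - 1L, function(j) {
        col_cor(a[, ia + j], b[, ib + j])
      }, numeric(1))
      best <- max(best, mean(cs))
    }
    best
  }
  max(score_pair(a, b), score_pair(a, .revcomp_pfm(b)))
}
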