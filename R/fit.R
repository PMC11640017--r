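#' Hyperparameter configuration for a survival network
#'
#' Holds the architecture and optimisation settings of one of the four
#' model families:
#' `"deepsurv"` (Cox partial likelihood with a network risk score),
#' `"deephit"` (discrete PMF with likelihood/ranking mixture),
#' `"logistic_hazard"` (discrete conditional-hazard Bernoulli model,
#' Nnet-survival), and `"cox_time"` (time-dependent score with sampled risk
#' sets). `alpha` and `sigma` are only meaningful for `"deephit"`.
#'
#' With `strict = TRUE` every field must lie in the published tuning
#' ranges/sets (batch size, epochs, dropout, nodes, alpha and sigma
#' categorical; layers 2–5; learning rate in \[1e-4, 0.1\]) — the regime
#' enforced when sampling from [default_search_space()]. Without it, any
#' positive values are accepted so that quick desk-scale runs (small epoch
#' counts, tiny networks) remain expressible.
#'
#' @param family model family, see above.
#' @param n_layers hidden layers.
#' @param n_nodes hidden-layer width.
#' @param dropout dropout rate on hidden activations.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param alpha DeepHit likelihood/ranking trade-off in \[0, 1\].
#' @param sigma DeepHit ranking-kernel width.
#' @param n_intervals discrete output grid size; observed durations are
#'   coarsened onto at most this many quantile-based intervals (the monthly
#'   grid remains the data-level truth).
#' @param n_control_samples sampled controls per event (cox_time).
#' @param validation_fraction fraction of patients held out for early
#'   stopping (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed controlling initialisation, batching, dropout
#'   and control sampling.
#' @param strict enforce the published tuning sets (see above).
#' @return object of class `hazard_model_config`.
#' @export
hazard_model_config <- function(family = c("deepsurv", "deephit",
                                           "logistic_hazard", "cox_time"),
                                n_layers = 2, n_nodes = 32, dropout = 0.1,
                                batch_size = 256, epochs = 100,
                                learning_rate = 0.01, alpha = 0.5,
                                sigma = 1.0, n_intervals = 50,
                                n_control_samples = 4,
                                validation_fraction = 0.1, patience = 10,
                                seed = 1, strict = FALSE) {
  family <- match.arg(family)
  if (strict) {
    sp <- default_search_space()
    ok <- n_layers %in% seq(sp$n_layers[1], sp$n_layers[2]) &&
      n_nodes %in% sp$n_nodes && dropout %in% sp$dropout &&
      batch_size %in% sp$batch_size && epochs %in% sp$epochs &&
      alpha %in% sp$alpha && sigma %in% sp$sigma &&
      learning_rate >= sp$learning_rate[1] &&
      learning_rate <= sp$learning_rate[2]
    if (!ok) stop("configuration outside the published tuning space",
                  call. = FALSE)
  }
  stopifnot(n_layers >= 1, n_nodes >= 1, batch_size >= 1, epochs >= 1,
            learning_rate > 0, learning_rate <= 1,
            dropout >= 0, dropout < 1, sigma > 0, n_intervals >= 1,
            n_control_samples >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  structure(list(family = family, n_layers = as.integer(n_layers),
                 n_nodes = as.integer(n_nodes), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, alpha = alpha, sigma = sigma,
                 n_intervals = as.integer(n_intervals),
                 n_control_samples = as.integer(n_control_samples),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "hazard_model_config")
}

# quantile-based coarsening of integer durations onto <= K intervals;
# returns ascending cut upper-bounds (months) covering max(durations)
duration_cuts <- function(durations, K) {
  qs <- stats::quantile(durations, probs = seq_len(K) / K, type = 1)
  cuts <- sort(unique(as.numeric(qs)))
  cuts[length(cuts)] <- max(durations)
  cuts
}

duration_to_interval <- function(durations, cuts) {
  idx <- findInterval(durations, cuts, left.open = TRUE) + 1L
  pmin(idx, length(cuts))
}

#' Fit a survival network
#'
#' Trains the configured family on an encoded dataset by mini-batch Adam on
#' the family's loss. Discrete families (logistic hazard, DeepHit) predict
#' on a quantile-coarsened interval grid; `deepsurv` additionally estimates
#' the Breslow baseline cumulative hazard on the training data, and
#' `cox_time` a Breslow-type baseline with time-dependent scores. Training
#' is deterministic given `config$seed`. A patient-level validation split
#' drives early stopping when `validation_fraction > 0`.
#'
#' @param dataset an `encoded_dataset` (standardised).
#' @param config a [hazard_model_config()].
#' @return object of class `hazard_model` with the network, interval grid,
#'   feature names, standardisation parameters, baselines where relevant,
#'   and a per-epoch training log.
#' @export
fit <- function(dataset, config) {
  stopifnot(inherits(dataset, "encoded_dataset"),
            inherits(config, "hazard_model_config"))
  X <- dataset$features
  n <- nrow(X)
  if (n == 0L) stop("dataset is empty", call. = FALSE)
  durations <- dataset$durations
  events <- dataset$events
  cuts <- duration_cuts(durations, config$n_intervals)
  K <- length(cuts)
  intervals <- duration_to_interval(durations, cuts)
  fam <- config$family
  t_scale <- max(durations)

  n_out <- switch(fam, deepsurv = 1L, cox_time = 1L,
                  logistic_hazard = K, deephit = K + 1L)
  n_in <- ncol(X) + (fam == "cox_time")

  with_seed(derive_seed(config$seed, 11L), {
    net <- mlp_init(n_in, n_out, config$n_layers, config$n_nodes,
                    derive_seed(config$seed, 12L))
    opt <- adam_init(net)

    # patient-level validation split for early stopping
    val_rows <- integer(0)
    if (config$validation_fraction > 0 && n >= 20) {
      pats <- unique(dataset$patient_id)
      n_val <- max(1L, floor(length(pats) * config$validation_fraction))
      vp <- sample(pats, n_val)
      val_rows <- which(dataset$patient_id %in% vp)
      if (length(val_rows) == n) val_rows <- integer(0)
    }
    train_rows <- setdiff(seq_len(n), val_rows)

    batch_loss_grad <- function(net, rows, training = TRUE, batch_seed = NULL) {
      Xi <- X[rows, , drop = FALSE]
      di <- intervals[rows]; dm <- durations[rows]; ei <- events[rows]
      nb <- length(rows)
      if (fam == "logistic_hazard") {
        fw <- mlp_forward(net, Xi, config$dropout, training)
        h <- plogis(fw$out)
        M <- outer(di, seq_len(K), ">=")
        Y <- matrix(0, nb, K); Y[cbind(seq_len(nb), di)] <- ei
        eps <- 1e-7
        hc <- pmin(pmax(h, eps), 1 - eps)
        loss <- -sum(M * (Y * log(hc) + (1 - Y) * log(1 - hc))) / nb
        dOut <- (h - Y) * M / nb
        list(loss = loss, fw = fw, dOut = dOut)
      } else if (fam == "deephit") {
        fw <- mlp_forward(net, Xi, config$dropout, training)
        z <- fw$out
        z <- z - apply(z, 1, max)
        P <- exp(z); P <- P / rowSums(P)
        Fm <- t(apply(P[, seq_len(K), drop = FALSE], 1, cumsum))
        if (K == 1L) Fm <- matrix(Fm, ncol = 1L)
        eps <- 1e-7
        # likelihood part: P(A) with A = {d} (event) or {d+1..K+1} (censored)
        inA <- matrix(0, nb, K + 1L)
        for (r in seq_len(nb)) {
          if (ei[r] == 1) inA[r, di[r]] <- 1
          else if (di[r] < K + 1L) inA[r, (di[r] + 1L):(K + 1L)] <- 1
        }
        PA <- pmax(rowSums(P * inA), eps)
        loss_like <- mean(-log(PA))
        dZ_like <- (P - P * inA / PA) / nb
        loss_rank <- 0
        dZ_rank <- matrix(0, nb, K + 1L)
        if (config$alpha < 1) {
          G <- matrix(0, nb, K)   # dL_rank/dF[r, k] accumulator (unscaled)
          terms_n <- 0L; terms_sum <- 0
          for (r in which(ei == 1)) {
            j <- which(di > di[r])
            if (!length(j)) next
            tr <- exp(-(Fm[r, di[r]] - Fm[j, di[r]]) / config$sigma)
            terms_sum <- terms_sum + sum(tr)
            terms_n <- terms_n + length(j)
            G[r, di[r]] <- G[r, di[r]] - sum(tr) / config$sigma
            G[cbind(j, di[r])] <- G[cbind(j, di[r])] + tr / config$sigma
          }
          if (terms_n > 0L) {
            loss_rank <- terms_sum / terms_n
            G <- G / terms_n
            # chain rule through F (cumsum of softmax over first K bins)
            a <- t(apply(G[, K:1, drop = FALSE], 1, cumsum))[, K:1, drop = FALSE]
            cc <- rowSums(G * Fm)
            dZ_rank[, seq_len(K)] <- P[, seq_len(K), drop = FALSE] * (a - cc)
            dZ_rank[, K + 1L] <- P[, K + 1L] * (-cc)
          }
        }
        loss <- config$alpha * loss_like + (1 - config$alpha) * loss_rank
        dOut <- config$alpha * dZ_like + (1 - config$alpha) * dZ_rank
        list(loss = loss, fw = fw, dOut = dOut)
      } else if (fam == "deepsurv") {
        fw <- mlp_forward(net, Xi, config$dropout, training)
        g <- drop(fw$out)
        loss <- if (sum(ei) == 0) 0 else
          suppressWarnings(loss_deepsurv(g, dm, ei))
        dOut <- matrix(grad_deepsurv(g, dm, ei), ncol = 1L)
        list(loss = loss, fw = fw, dOut = dOut)
      } else { # cox_time
        evs <- which(ei == 1)
        if (!length(evs)) {
          return(list(loss = 0, fw = NULL, dOut = NULL, skip = TRUE))
        }
        if (!is.null(batch_seed)) set.seed(batch_seed)
        case_pos <- integer(0); group <- integer(0)
        in_rows <- integer(0); in_time <- numeric(0)
        gidx <- 0L
        for (e in evs) {
          pool <- which(dm >= dm[e]); pool <- pool[pool != e]
          if (!length(pool)) next
          ctrl <- if (length(pool) <= config$n_control_samples) pool else {
            pool[sample.int(length(pool), config$n_control_samples)]
          }
          gidx <- gidx + 1L
          members <- c(e, ctrl)
          in_rows <- c(in_rows, members)
          in_time <- c(in_time, rep(dm[e] / t_scale, length(members)))
          group <- c(group, rep(gidx, length(members)))
          case_pos <- c(case_pos, length(in_rows) - length(members) + 1L)
        }
        if (gidx == 0L) {
          return(list(loss = 0, fw = NULL, dOut = NULL, skip = TRUE))
        }
        Xin <- cbind(Xi[in_rows, , drop = FALSE], t = in_time)
        fw <- mlp_forward(net, Xin, config$dropout, training)
        g <- drop(fw$out)
        loss <- 0
        dOut <- numeric(length(g))
        for (k in seq_len(gidx)) {
          m <- which(group == k)
          gm <- g[m]
          w <- exp(gm - max(gm)); w <- w / sum(w)
          loss <- loss + (logsumexp(gm) - gm[1])
          dOut[m] <- w / gidx
          dOut[m[1]] <- dOut[m[1]] - 1 / gidx
        }
        list(loss = loss / gidx, fw = fw, dOut = matrix(dOut, ncol = 1L))
      }
    }

    eval_loss <- function(net, rows, seed_off) {
      out <- batch_loss_grad(net, rows, training = FALSE,
                             batch_seed = derive_seed(config$seed, seed_off))
      out$loss
    }

    log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
    best_net <- net; best_val <- Inf; stall <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(train_rows)
      nb <- ceiling(length(ord) / config$batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1L) * config$batch_size + 1L):
                      min(b * config$batch_size, length(ord))]
        res <- batch_loss_grad(net, rows, training = TRUE,
                               batch_seed = derive_seed(config$seed, ep, b))
        if (isTRUE(res$skip)) next
        if (!is.finite(res$loss)) {
          stop("non-finite training loss (family = ", fam, ", epoch ", ep,
               "); consider a lower learning rate", call. = FALSE)
        }
        grads <- mlp_backward(net, res$fw, res$dOut)
        st <- adam_step(net, grads, opt, config$learning_rate)
        net <- st$net; opt <- st$state
        ep_loss <- ep_loss + res$loss; ep_n <- ep_n + 1L
      }
      tr_loss <- if (ep_n) ep_loss / ep_n else NA_real_
      vl <- NA_real_
      if (length(val_rows)) {
        vl <- eval_loss(net, val_rows, 999L)
        if (is.finite(vl) && vl < best_val - 1e-9) {
          best_val <- vl; best_net <- net; stall <- 0L
        } else {
          stall <- stall + 1L
        }
      } else {
        best_net <- net
      }
      log_epoch <- c(log_epoch, ep); log_train <- c(log_train, tr_loss)
      log_val <- c(log_val, vl)
      if (length(val_rows) && stall >= config$patience) break
    }
    net <- best_net

    model <- structure(list(
      family = fam, net = net, cuts = cuts, t_scale = t_scale,
      feature_names = dataset$feature_names,
      standardization = dataset$standardization,
      config = config,
      training_log = data.frame(epoch = log_epoch, train_loss = log_train,
                                val_loss = log_val)
    ), class = "hazard_model")

    train_X <- X[train_rows, , drop = FALSE]
    if (fam == "deepsurv") {
      g <- drop(mlp_forward(net, train_X)$out)
      model$breslow <- breslow_baseline(g, durations[train_rows],
                                        events[train_rows])
    }
    if (fam == "cox_time") {
      model$coxtime_base <- coxtime_baseline(net, train_X,
                                             durations[train_rows],
                                             events[train_rows], cuts,
                                             t_scale,
                                             derive_seed(config$seed, 77L))
    }
    model
  })
}

# Breslow estimator of the baseline cumulative hazard at distinct event
# times: dH0(t_k) = d_k / sum_{T_j >= t_k} exp(g_j).
breslow_baseline <- function(scores, durations, events) {
  et <- sort(unique(durations[events == 1]))
  if (!length(et)) return(list(times = numeric(0), cumhaz = numeric(0)))
  dH <- vapply(et, function(tk) {
    sum(events == 1 & durations == tk) *
      exp(-logsumexp(scores[durations >= tk]))
  }, numeric(1))
  list(times = et, cumhaz = cumsum(dH))
}

# Breslow-type baseline for a time-dependent score, estimated on the
# coarsened grid with a capped random subsample of each risk set.
coxtime_baseline <- function(net, X, durations, events, cuts, t_scale,
                             seed, max_risk = 512L) {
  with_seed(seed, {
    dH <- numeric(length(cuts))
    lo <- c(0, cuts[-length(cuts)])
    for (k in seq_along(cuts)) {
      d_k <- sum(events == 1 & durations > lo[k] & durations <= cuts[k])
      risk <- which(durations > lo[k])
      if (!length(risk) || d_k == 0) { dH[k] <- 0; next }
      sub <- if (length(risk) > max_risk) sample(risk, max_risk) else risk
      Xin <- cbind(X[sub, , drop = FALSE], t = cuts[k] / t_scale)
      g <- drop(mlp_forward(net, Xin)$out)
      denom <- length(risk) * mean(exp(g))
      dH[k] <- d_k / denom
    }
    list(times = cuts, dhaz = dH)
  })
}

#' Predict survival curves from a fitted model
#'
#' Maps covariate vectors through the fitted network to survival curves on
#' the model's interval grid:
#' logistic hazard \eqn{S(t) = \prod_{s \le t} (1 - h_s)};
#' DeepHit \eqn{S(t) = 1 - \sum_{s \le t} f_s};
#' deepsurv \eqn{S(t) = \exp(-H_0(t) e^{g(x)})};
#' cox_time \eqn{S(t) = \exp(-\sum_{t_k \le t} \Delta H_0(t_k)
#'   e^{g(t_k, x)})}.
#'
#' @param model a `hazard_model`.
#' @param x an `extended_covariates` object, a named numeric vector, or a
#'   matrix with one row per subject; feature names must match the model's
#'   feature space.
#' @param standardized set `TRUE` when `x` is already on the model's
#'   standardised training scale; otherwise the model's stored
#'   standardisation is applied.
#' @return a [survival_curve] (single subject) or a list of them.
#' @export
predict_survival <- function(model, x, standardized = FALSE) {
  stopifnot(inherits(model, "hazard_model"))
  single <- FALSE
  if (inherits(x, "extended_covariates")) { x <- x$values }
  if (is.null(dim(x))) { x <- matrix(x, nrow = 1,
                                     dimnames = list(NULL, names(x)))
    single <- TRUE }
  if (ncol(x) != length(model$feature_names)) {
    stop("feature dimension mismatch: model expects ",
         length(model$feature_names), " features, got ", ncol(x),
         call. = FALSE)
  }
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), model$feature_names)) {
      stop("feature names do not match the model's feature space",
           call. = FALSE)
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  if (!standardized && !is.null(model$standardization)) {
    st <- model$standardization
    x <- sweep(sweep(x, 2, st$center), 2, st$scale, "/")
  }
  K <- length(model$cuts)
  n <- nrow(x)
  fam <- model$family
  S <- if (fam == "logistic_hazard") {
    h <- plogis(mlp_forward(model$net, x)$out)
    t(apply(1 - h, 1, cumprod))
  } else if (fam == "deephit") {
    z <- mlp_forward(model$net, x)$out
    z <- z - apply(z, 1, max)
    P <- exp(z); P <- P / rowSums(P)
    Fm <- t(apply(P[, seq_len(K), drop = FALSE], 1, cumsum))
    pmin(pmax(1 - Fm, 0), 1)
  } else if (fam == "deepsurv") {
    g <- drop(mlp_forward(model$net, x)$out)
    bl <- model$breslow
    H0 <- c(0, bl$cumhaz)[findInterval(model$cuts, bl$times) + 1L]
    exp(-outer(exp(g), H0))
  } else { # cox_time
    base <- model$coxtime_base
    Hm <- matrix(0, n, K)
    for (k in seq_len(K)) {
      Xin <- cbind(x, t = model$cuts[k] / model$t_scale)
      g <- drop(mlp_forward(model$net, Xin)$out)
      Hm[, k] <- base$dhaz[k] * exp(g)
    }
    exp(-t(apply(Hm, 1, cumsum)))
  }
  if (K == 1L) S <- matrix(S, ncol = 1L)
  # enforce monotone non-increasing curves against numerical jitter
  S <- t(apply(S, 1, function(s) pmin(cummin(pmax(pmin(s, 1), 0)), 1)))
  if (K == 1L) S <- matrix(S, ncol = 1L)
  curves <- lapply(seq_len(n), function(i) survival_curve(model$cuts, S[i, ]))
  if (single) curves[[1]] else curves
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("<hazard_model>", x$family, "|", length(x$feature_names), "features |",
      length(x$cuts), "intervals |", nrow(x$training_log), "epochs\n")
  invisible(x)
}

#' Save / load a fitted model as text
#'
#' Writes the network weights and metadata as JSON plus, for the Cox-based
#' families, the baseline hazard table as CSV.
#'
#' @param model a `hazard_model`.
#' @param dir checkpoint directory.
#' @return `save_model()` the directory invisibly; `load_model()` a
#'   `hazard_model`.
#' @export
save_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(family = model$family, cuts = model$cuts,
               t_scale = model$t_scale,
               feature_names = model$feature_names,
               standardization = model$standardization,
               config = unclass(model$config),
               W = lapply(model$net$W, function(w) list(dim = dim(w),
                                                       val = as.numeric(w))),
               b = model$net$b, dims = model$net$dims)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(model$breslow)) {
    utils::write.csv(data.frame(time = model$breslow$times,
                                cumhaz = model$breslow$cumhaz),
                     file.path(dir, "baseline_hazard.csv"), row.names = FALSE)
  }
  if (!is.null(model$coxtime_base)) {
    utils::write.csv(data.frame(time = model$coxtime_base$times,
                                dhaz = model$coxtime_base$dhaz),
                     file.path(dir, "baseline_hazard.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  net <- list(W = lapply(meta$W$dim, function(d) NULL), b = NULL)
  W <- vector("list", length(meta$b))
  for (l in seq_along(W)) {
    W[[l]] <- matrix(meta$W$val[[l]], meta$W$dim[[l]][1], meta$W$dim[[l]][2])
  }
  cfg <- do.call(hazard_model_config, meta$config[
    intersect(names(meta$config), names(formals(hazard_model_config)))])
  model <- structure(list(
    family = meta$family, net = list(W = W, b = meta$b, dims = meta$dims),
    cuts = meta$cuts, t_scale = meta$t_scale,
    feature_names = meta$feature_names,
    standardization = meta$standardization, config = cfg,
    training_log = data.frame()), class = "hazard_model")
  bh <- file.path(dir, "baseline_hazard.csv")
  if (file.exists(bh)) {
    tab <- utils::read.csv(bh)
    if (meta$family == "deepsurv") {
      model$breslow <- list(times = tab$time, cumhaz = tab$cumhaz)
    } else {
      model$coxtime_base <- list(times = tab$time, dhaz = tab$dhaz)
    }
  }
  model
}
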