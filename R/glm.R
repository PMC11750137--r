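predictor_names <- function() {
  c("CE_ipsi", "CE_contra", "CX_ipsi", "CX_contra",
    "SE_ipsi", "SE_contra", "SX_ipsi", "SX_contra", "Rew", "Unrew")
}

#' Binary behavioral predictor series on the frame grid
#'
#' Builds the ten one-hot event series used as GLM features: center
#' entry/exit, side entry/exit (each split by choice direction relative
#' to the recording hemisphere) plus reward and unrewarded outcome. Each
#' event occupies exactly the frame containing its timestamp; Rew/Unrew
#' fire once per trial, by default at the first-lick frame -- the moment
#' the outcome is revealed at the spout (falling back to side entry when
#' no lick time is logged). `outcome_at = "SE"` places them at the
#' side-entry frame instead, but note that then `SE_ipsi + SE_contra =
#' Rew + Unrew` on every frame, an exact collinearity that leaves the
#' individual kernels of that quartet unidentifiable (the ridge penalty
#' picks one representative among the equivalent solutions). Events
#' falling off the frame grid are dropped with a warning.
#'
#' @param session A `session_table` on the same clock as the signal.
#' @param sig A `demod_signal` defining the frame grid.
#' @param hemisphere Recording hemisphere; same-side choices are ipsi.
#' @param outcome_at `"FL"` (default) or `"SE"`.
#' @return A `predictor_set`: list with `mat` (frames x 10 binary
#'   matrix), `period`, and `trial_frames` (data.frame of each trial's
#'   CE and SX frames, used for trial windowing).
#' @export
build_predictors <- function(session, sig, hemisphere = c("left", "right"),
                             outcome_at = c("FL", "SE")) {
  hemisphere <- match.arg(hemisphere)
  outcome_at <- match.arg(outcome_at)
  stopifnot(inherits(sig, "demod_signal"))
  nf <- length(sig$values)
  mat <- matrix(0, nf, 10, dimnames = list(NULL, predictor_names()))
  dir <- ifelse(session$choice == hemisphere, "ipsi", "contra")
  dropped <- 0L
  put <- function(mat, times, cols) {
    k <- nearest_frame(times, sig$period)
    ok <- !is.na(k) & k >= 1 & k <= nf
    dropped <<- dropped + sum(!ok & !is.na(times))
    mat[cbind(k[ok], match(cols[ok], predictor_names()))] <- 1
    mat
  }
  for (ev in c("CE", "CX", "SE", "SX"))
    mat <- put(mat, session[[paste0("t_", ev)]], paste0(ev, "_", dir))
  t_out <- session[[paste0("t_", outcome_at)]]
  t_out[is.na(t_out)] <- session$t_SE[is.na(t_out)]  # FL absent: fall back
  mat <- put(mat, t_out, ifelse(session$rewarded, "Rew", "Unrew"))
  if (dropped > 0)
    warning(dropped, " event(s) off the frame grid were dropped")
  structure(list(mat = mat, period = sig$period,
                 trial_frames = data.frame(
                   trial = session$trial,
                   k_CE = nearest_frame(session$t_CE, sig$period),
                   k_SX = nearest_frame(session$t_SX, sig$period))),
            class = "predictor_set")
}

#' Time-shifted GLM design matrix
#'
#' Expands each predictor into `2T + 1` lagged copies (shifts of -T..+T
#' frames, T = 20 by default, 54 ms each), so the fitted coefficients
#' form a 41-lag kernel per predictor. Only frames from shortly before
#' center entry to shortly after side-port exit are modeled: each trial
#' contributes the frames `[CE - margin, SX + margin]` (margin = T frames
#' by default, covering every kernel's support), the inter-trial interval
#' is excluded, and frames shared by consecutive trial windows are
#' included twice -- once in each trial's group -- so that grouped
#' cross-validation splits never starve an event of its flanks.
#'
#' The design column for predictor f at lag l holds, in the row for frame
#' i, the value of f at frame i - l; a kernel weight at positive lag l
#' therefore describes the signal l frames *after* the event.
#'
#' @param pred A `predictor_set` from [build_predictors()].
#' @param response A `demod_signal` on the same frame grid.
#' @param T Number of shifts each way (default 20).
#' @param margin Extra frames kept around each trial (default `T`).
#' @return A `glm_design`: list with `X` (rows x 10(2T+1)), `y`,
#'   `groups` (trial id per row), `frames` (source frame per row), `T`,
#'   `lags`, and `pred_names`.
#' @export
build_design <- function(pred, response, T = 20, margin = T) {
  stopifnot(inherits(pred, "predictor_set"))
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  y_all <- if (inherits(response, "demod_signal")) response$values
           else as.numeric(response)
  nf <- nrow(pred$mat)
  if (length(y_all) != nf)
    stop("response and predictors are on different frame grids",
         call. = FALSE)
  tf <- pred$trial_frames
  wins <- lapply(seq_len(nrow(tf)), function(i) {
    seq(max(1L, tf$k_CE[i] - margin), min(nf, tf$k_SX[i] + margin))
  })
  rows <- unlist(wins)
  groups <- rep(tf$trial, lengths(wins))
  lags <- -T:T
  p_names <- colnames(pred$mat)
  X <- matrix(0, length(rows), length(p_names) * length(lags))
  colnames(X) <- paste0(rep(p_names, each = length(lags)), "_lag",
                        rep(lags, length(p_names)))
  col <- 0L
  for (f in seq_along(p_names)) {
    v <- pred$mat[, f]
    for (l in lags) {
      col <- col + 1L
      src <- rows - l
      ok <- src >= 1 & src <= nf
      X[ok, col] <- v[src[ok]]
    }
  }
  structure(list(X = X, y = y_all[rows], groups = groups, frames = rows,
                 T = T, lags = lags, pred_names = p_names),
            class = "glm_design")
}

#' Stack per-session designs
#'
#' Row-binds designs from several sessions, relabeling trial groups to
#' stay unique across sessions.
#'
#' @param designs List of `glm_design` objects with identical columns.
#' @return A single `glm_design`.
#' @export
stack_designs <- function(designs) {
  stopifnot(length(designs) >= 1)
  g <- unlist(lapply(seq_along(designs), function(i)
    paste0("s", i, "_", designs[[i]]$groups)))
  structure(list(X = do.call(rbind, lapply(designs, `[[`, "X")),
                 y = unlist(lapply(designs, `[[`, "y")),
                 groups = g,
                 frames = unlist(lapply(designs, `[[`, "frames")),
                 T = designs[[1]]$T, lags = designs[[1]]$lags,
                 pred_names = designs[[1]]$pred_names),
            class = "glm_design")
}

# Solve the ridge system from precomputed crossproducts.
# A = X1'X1 and b = X1'y where X1 = cbind(1, X); the intercept (column 1)
# is unpenalized. Returns the coefficient vector (intercept first).
ridge_solve <- function(A, b, alpha) {
  p <- nrow(A)
  Ap <- A + diag(c(0, rep(alpha, p - 1)))
  beta <- tryCatch(solve(Ap, b), error = function(e) NULL)
  if (is.null(beta)) {
    warning("singular system; using a pseudo-inverse solution")
    sv <- svd(Ap)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  }
  drop(beta)
}

mse_from_cross <- function(beta, A, b, yty, n) {
  drop(yty - 2 * crossprod(beta, b) + crossprod(beta, A %*% beta)) / n
}

#' Fit the kernel ridge GLM
#'
#' Minimizes `||y - X beta||^2 + alpha * ||beta||^2` (intercept included
#' and unpenalized) by a closed-form normal-equations solve; `alpha = 0`
#' gives ordinary least squares. Neither the response (already z-scored)
#' nor the predictors are standardized: `alpha` is interpreted on the
#' raw design scale.
#'
#' @param design A `glm_design`.
#' @param alpha Ridge penalty (default 1).
#' @return A `glm_fit`: list with `kernels` (lags x predictors matrix of
#'   coefficients), `intercept`, `coef` (full vector), `alpha`, `mse`,
#'   `r2`, `lags`, `lag_s` (lag axis in seconds), `T`, `pred_names`.
#' @export
fit_ridge <- function(design, alpha = 1) {
  stopifnot(inherits(design, "glm_design"))
  n <- nrow(design$X); p <- ncol(design$X)
  if (n < p)
    warning("fewer rows than columns; the fit is under-determined")
  X1 <- cbind(`(Intercept)` = 1, design$X)
  A <- crossprod(X1)
  b <- drop(crossprod(X1, design$y))
  beta <- ridge_solve(A, b, alpha)
  yty <- sum(design$y^2)
  mse <- mse_from_cross(beta, A, b, yty, n)
  r2 <- 1 - mse / stats::var(design$y) / ((n - 1) / n)
  K <- matrix(beta[-1], nrow = length(design$lags),
              dimnames = list(design$lags, design$pred_names))
  structure(list(kernels = K, intercept = beta[1], coef = beta,
                 alpha = alpha, mse = mse, r2 = r2,
                 lags = design$lags,
                 lag_s = design$lags * 0.054,
                 T = design$T, pred_names = design$pred_names),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d predictors x %d lags, alpha = %g, train MSE = %.4f, R2 = %.3f\n",
              ncol(x$kernels), nrow(x$kernels), x$alpha, x$mse, x$r2))
  invisible(x)
}

split_groups <- function(groups, test_frac) {
  ug <- unique(groups)
  test_g <- sample(ug, size = max(1, round(test_frac * length(ug))))
  list(test = groups %in% test_g, train = !(groups %in% test_g))
}

#' Grouped shuffle-split cross-validation of the ridge GLM
#'
#' Repeats an 80/20 train/test split `n_folds` times, shuffling whole
#' trials (groups) so that no trial's rows ever straddle train and test
#' (duplicated boundary frames belong to their own trial's group). Each
#' fold refits the ridge solution on the training rows and evaluates MSE
#' and R-squared on both partitions.
#'
#' @param design A `glm_design`.
#' @param alpha Ridge penalty.
#' @param n_folds Number of shuffle splits (default 10).
#' @param test_frac Fraction of trials held out per fold (default 0.2).
#' @param seed Integer seed; fold assignment is deterministic under it.
#' @return Data.frame with one row per fold: `fold`, `train_mse`,
#'   `test_mse`, `train_r2`, `test_r2`; attribute `sd_test_mse`.
#' @export
cross_validate <- function(design, alpha = 1, n_folds = 10,
                           test_frac = 0.2, seed = 1) {
  stopifnot(inherits(design, "glm_design"))
  ug <- unique(design$groups)
  if (length(ug) < n_folds)
    stop("need at least ", n_folds, " trial groups", call. = FALSE)
  set.seed(seed)
  X1 <- cbind(1, design$X)
  res <- lapply(seq_len(n_folds), function(k) {
    sp <- split_groups(design$groups, test_frac)
    Xtr <- X1[sp$train, , drop = FALSE]; ytr <- design$y[sp$train]
    Xte <- X1[sp$test, , drop = FALSE]; yte <- design$y[sp$test]
    A <- crossprod(Xtr); b <- drop(crossprod(Xtr, ytr))
    beta <- ridge_solve(A, b, alpha)
    tr_mse <- mse_from_cross(beta, A, b, sum(ytr^2), length(ytr))
    pe <- yte - drop(Xte %*% beta)
    te_mse <- mean(pe^2)
    data.frame(fold = k, train_mse = tr_mse, test_mse = te_mse,
               train_r2 = 1 - tr_mse / mean((ytr - mean(ytr))^2),
               test_r2 = 1 - te_mse / mean((yte - mean(yte))^2))
  })
  out <- do.call(rbind, res)
  attr(out, "sd_test_mse") <- stats::sd(out$test_mse)
  out
}

#' Reconstruct the signal from fitted kernels
#'
#' Convolves each predictor's event series with its fitted kernel and
#' sums across predictors (plus the intercept), producing the model's
#' predicted signal on the full frame grid.
#'
#' @param fit A `glm_fit`.
#' @param pred The `predictor_set` the fit's columns refer to.
#' @return Numeric series on the frame grid.
#' @export
reconstruct <- function(fit, pred) {
  stopifnot(inherits(fit, "glm_fit"), inherits(pred, "predictor_set"))
  nf <- nrow(pred$mat)
  yhat <- rep(fit$intercept, nf)
  for (f in seq_along(fit$pred_names)) {
    v <- pred$mat[, fit$pred_names[f]]
    for (j in seq_along(fit$lags)) {
      l <- fit$lags[j]
      k <- fit$kernels[j, f]
      if (k == 0) next
      src <- seq_len(nf) - l
      ok <- src >= 1 & src <= nf
      yhat[ok] <- yhat[ok] + k * v[src[ok]]
    }
  }
  yhat
}

#' Omission-model variants
#'
#' Column maps defining the ten models of the omission analysis. Each
#' variant is expressed as a 0/1 matrix mapping full-model design columns
#' onto variant columns: dropped predictors map nowhere, and `-Direction`
#' collapses each ipsi/contra pair into a single direction-free series
#' (their lagged columns sum), preserving event timing.
#'
#' @param T Number of shifts each way (default 20).
#' @return Named list of column-map matrices (410 x p_variant at T=20).
#' @export
omission_variants <- function(T = 20) {
  L <- 2 * T + 1
  pn <- predictor_names()
  base <- c("CE", "CX", "SE", "SX")
  keep_map <- function(keep) {          # plain column selection
    idx <- which(rep(pn, each = L) %in% keep)
    M <- matrix(0, length(pn) * L, length(idx))
    M[cbind(idx, seq_along(idx))] <- 1
    M
  }
  collapse_map <- function(collapse, keep_extra) {
    # collapsed predictors (ipsi+contra summed) first, then extras
    out_names <- c(collapse, keep_extra)
    M <- matrix(0, length(pn) * L, length(out_names) * L)
    for (j in seq_along(out_names)) {
      nm <- out_names[j]
      srcs <- if (nm %in% collapse) paste0(nm, c("_ipsi", "_contra")) else nm
      for (s in srcs) {
        f <- match(s, pn)
        M[cbind((f - 1) * L + seq_len(L), (j - 1) * L + seq_len(L))] <- 1
      }
    }
    M
  }
  list(
    Full = keep_map(pn),
    `-Rew` = keep_map(setdiff(pn, c("Rew", "Unrew"))),
    `-Direction` = collapse_map(base, c("Rew", "Unrew")),
    `-Direction&Rew` = collapse_map(base, character(0)),
    `-CE/CX` = keep_map(pn[!grepl("^C", pn)]),
    `-CE` = keep_map(pn[!grepl("^CE", pn)]),
    `-CX` = keep_map(pn[!grepl("^CX", pn)]),
    `-SE/SX` = keep_map(pn[!grepl("^S[EX]", pn)]),
    `-SE` = keep_map(pn[!grepl("^SE", pn)]),
    `-SX` = keep_map(pn[!grepl("^SX", pn)]))
}

#' Variable-omission analysis
#'
#' Refits the ridge GLM for each omission variant under a shared grouped
#' shuffle-split scheme (5 folds by default) and tabulates train/test
#' MSE per fold -- the box-plot-ready comparison of which behavioral
#' variables the signal reconstruction needs. All variants within a fold
#' reuse the fold's crossproducts, so every variant sees exactly the
#' same train/test trials.
#'
#' @param design A full-model `glm_design` (410 columns at T = 20).
#' @param variants Character vector of variant names (see
#'   [omission_variants()]), or `"all"`.
#' @param alpha Ridge penalty (default 1).
#' @param n_folds Number of shuffle splits (default 5).
#' @param test_frac Held-out trial fraction per fold.
#' @param seed Integer seed.
#' @return Data.frame with columns `variant`, `fold`, `n_cols`,
#'   `train_mse`, `test_mse`.
#' @export
omission_analysis <- function(design, variants = "all", alpha = 1,
                              n_folds = 5, test_frac = 0.2, seed = 1) {
  stopifnot(inherits(design, "glm_design"))
  maps <- omission_variants(design$T)
  if (!identical(variants, "all")) {
    bad <- setdiff(variants, names(maps))
    if (length(bad))
      stop("unknown variant(s): ", paste(bad, collapse = ", "), call. = FALSE)
    maps <- maps[variants]
  }
  set.seed(seed)
  X1 <- cbind(1, design$X)
  out <- list()
  for (k in seq_len(n_folds)) {
    sp <- split_groups(design$groups, test_frac)
    Xtr <- X1[sp$train, , drop = FALSE]; ytr <- design$y[sp$train]
    Xte <- X1[sp$test, , drop = FALSE]; yte <- design$y[sp$test]
    A <- crossprod(Xtr); b <- drop(crossprod(Xtr, ytr))
    yty <- sum(ytr^2)
    for (vn in names(maps)) {
      M1 <- rbind(0, cbind(0, maps[[vn]]))   # pass the intercept through
      M1[1, 1] <- 1
      Av <- crossprod(M1, A %*% M1)
      bv <- drop(crossprod(M1, b))
      beta_v <- ridge_solve(Av, bv, alpha)
      tr_mse <- mse_from_cross(beta_v, Av, bv, yty, length(ytr))
      beta_full <- drop(M1 %*% beta_v)
      te_mse <- mean((yte - drop(Xte %*% beta_full))^2)
      out[[length(out) + 1]] <-
        data.frame(variant = vn, fold = k, n_cols = ncol(maps[[vn]]),
                   train_mse = tr_mse, test_mse = te_mse,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$variant <- factor(res$variant, levels = names(maps))
  res
}
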