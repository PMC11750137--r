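# A small design built directly from a matrix, for solver-level tests.
fake_design <- function(X, y, groups = seq_len(nrow(X))) {
  structure(list(X = X, y = y, groups = groups,
                 frames = seq_len(nrow(X)), T = 0, lags = 0,
                 pred_names = colnames(X)),
            class = "glm_design")
}

test_that("predictor series are one-hot with correct direction labels", {
  sig <- make_signal(rep(0, 400))
  s <- make_session("left", TRUE)
  pr <- build_predictors(s, sig, hemisphere = "left")
  expect_identical(sum(pr$mat), 5)   # CE, CX, SE, SX ipsi + Rew
  expect_identical(unname(colSums(pr$mat)[c("CE_ipsi", "CX_ipsi", "SE_ipsi",
                                            "SX_ipsi", "Rew")]),
                   rep(1, 5))
  # hemisphere flip swaps ipsi/contra columns exactly
  pr_r <- build_predictors(s, sig, hemisphere = "right")
  expect_identical(pr$mat[, "CE_ipsi"], pr_r$mat[, "CE_contra"])
  expect_identical(sum(pr_r$mat[, grepl("ipsi", colnames(pr_r$mat))]), 0)
  # unrewarded trial fires Unrew instead
  s2 <- make_session("right", FALSE)
  pr2 <- build_predictors(s2, sig, hemisphere = "left")
  expect_identical(unname(colSums(pr2$mat)[c("SE_contra", "Unrew")]), c(1, 1))
})

test_that("design matrix has the N x F(2T+1) structure with trial windows", {
  sig <- make_signal(rnorm(400))
  s <- make_session(c("left", "right"), c(TRUE, FALSE))
  for (col in c("t_CE", "t_CX", "t_SE", "t_FL", "t_SX"))
    s[[col]] <- s[[col]] + 2        # keep margins clear of the grid edge
  pr <- build_predictors(s, sig)
  de <- build_design(pr, sig, T = 20)
  expect_identical(ncol(de$X), 410L)           # 10 predictors x 41 lags
  # trial windows: [CE - 20, SX + 20] frames, trials 4 s apart -> overlap
  tf <- pr$trial_frames
  w1 <- (tf$k_CE[1] - 20):(tf$k_SX[1] + 20)
  w2 <- (tf$k_CE[2] - 20):(tf$k_SX[2] + 20)
  expect_identical(nrow(de$X), length(w1) + length(w2))
  overlap <- intersect(w1, w2)
  expect_gt(length(overlap), 0)                # boundary frames duplicated
  expect_identical(sum(de$frames %in% overlap), 2L * length(overlap))
  # each event contributes a 41-long diagonal stripe in its column block
  ce_cols <- grepl("^CE_ipsi_", colnames(de$X))
  expect_identical(sum(de$X[de$groups == 1, ce_cols]), 41)
  expect_error(build_design(pr, sig, margin = -1), "margin")
  # all-zero predictors give an all-zero design
  pr0 <- pr; pr0$mat[] <- 0
  expect_identical(sum(build_design(pr0, sig)$X), 0)
})

test_that("ridge at alpha = 0 equals the least-squares oracle", {
  set.seed(5)
  X <- matrix(rnorm(500), 50, 10, dimnames = list(NULL, paste0("p", 1:10)))
  beta_true <- rnorm(10)
  y <- drop(X %*% beta_true) + rnorm(50, 0, 0.1)
  fit <- fit_ridge(fake_design(X, y), alpha = 0)
  oracle <- lm.fit(cbind(1, X), y)$coefficients
  expect_lt(max(abs(fit$coef - oracle)), 1e-8)
  # alpha = 1 equals the sqrt(alpha)-augmented least-squares system
  fit1 <- fit_ridge(fake_design(X, y), alpha = 1)
  Xa <- rbind(cbind(1, X), cbind(0, diag(10)))
  ya <- c(y, rep(0, 10))
  aug <- lm.fit(Xa, ya)$coefficients
  expect_lt(max(abs(fit1$coef - aug)), 1e-8)
  # heavy shrinkage sends penalized coefficients toward zero
  fitH <- fit_ridge(fake_design(X, y), alpha = 1e8)
  expect_lt(max(abs(fitH$coef[-1])), 1e-4)
})

test_that("training MSE is non-decreasing in the ridge penalty", {
  set.seed(6)
  X <- matrix(rnorm(2000), 100, 20)
  colnames(X) <- paste0("p", 1:20)
  y <- drop(X %*% rnorm(20)) + rnorm(100)
  d <- fake_design(X, y)
  mses <- vapply(c(0, 0.1, 1, 10, 100), function(a) fit_ridge(d, a)$mse, 0)
  expect_true(all(diff(mses) >= -1e-10))
})

test_that("noise-free kernels are recovered through the design machinery", {
  spec <- truth_spec(task = task_config(0.9, 0.1, n_trials = 80))
  co <- generate_cohort(spec, 1, 1, photometry = "none")
  s <- co$sessions[[1]]
  nf <- ceiling((max(s$t_SX) + 2) / 0.054)
  sig <- make_signal(numeric(nf))
  pr <- build_predictors(s, sig, hemisphere = "left")
  Kt <- truth_kernel_matrix(spec)
  fit0 <- structure(list(kernels = Kt, intercept = 0.3,
                         lags = -20:20, pred_names = colnames(Kt)),
                    class = "glm_fit")
  y <- reconstruct(fit0, pr)
  de <- build_design(pr, make_signal(y))
  fit <- fit_ridge(de, alpha = 0)
  cors <- vapply(colnames(Kt), function(nm)
    cor(fit$kernels[, nm], Kt[, nm]), 0)
  expect_true(all(cors > 0.999))
  expect_equal(unname(fit$intercept), 0.3, tolerance = 1e-6)
})

test_that("reconstruction is the impulse response and matches X beta", {
  sig <- make_signal(rnorm(300))
  s <- make_session("left", TRUE)
  for (col in c("t_CE", "t_CX", "t_SE", "t_FL", "t_SX"))
    s[[col]] <- s[[col]] + 2
  pr <- build_predictors(s, sig)
  K <- matrix(0, 41, 10, dimnames = list(-20:20, colnames(pr$mat)))
  K[, "CE_ipsi"] <- cos(seq(-1.5, 1.5, length.out = 41))   # no zero entries
  fit0 <- structure(list(kernels = K, intercept = 0, lags = -20:20,
                         pred_names = colnames(pr$mat)), class = "glm_fit")
  yhat <- reconstruct(fit0, pr)
  k_ce <- which(pr$mat[, "CE_ipsi"] == 1)
  expect_equal(yhat[k_ce + (-20:20)], unname(K[, "CE_ipsi"]),
               tolerance = 1e-12)
  expect_identical(sum(yhat != 0), 41L)
  # row-for-row identity with the design-matrix product
  de <- build_design(pr, sig)
  fit <- suppressWarnings(fit_ridge(de, alpha = 1))
  yh_full <- reconstruct(fit, pr)
  expect_equal(unname(yh_full[de$frames]),
               unname(drop(cbind(1, de$X) %*% fit$coef)), tolerance = 1e-10)
})

test_that("grouped shuffle splits keep whole trials together", {
  sig <- make_signal(rnorm(4000))
  s <- make_session(sample(c("left", "right"), 40, TRUE),
                    sample(c(TRUE, FALSE), 40, TRUE))
  pr <- build_predictors(s, sig)
  de <- build_design(pr, sig)
  set.seed(1)
  for (i in 1:5) {
    sp <- probswitch:::split_groups(de$groups, 0.2)
    expect_identical(sp$train, !sp$test)
    expect_length(intersect(unique(de$groups[sp$train]),
                            unique(de$groups[sp$test])), 0)
  }
  cv1 <- cross_validate(de, n_folds = 5, seed = 3)
  cv2 <- cross_validate(de, n_folds = 5, seed = 3)
  expect_identical(cv1, cv2)
})

test_that("cross-validation separates signal from overfitting", {
  spec <- truth_spec(task = task_config(0.9, 0.1, n_trials = 150))
  co <- generate_cohort(spec, 1, 1, photometry = "none")
  s <- co$sessions[[1]]
  nf <- ceiling((max(s$t_SX) + 2) / 0.054)
  pr <- build_predictors(s, make_signal(numeric(nf)))
  Kt <- truth_kernel_matrix(spec)
  fit0 <- structure(list(kernels = Kt, intercept = 0, lags = -20:20,
                         pred_names = colnames(Kt)), class = "glm_fit")
  y_sig <- reconstruct(fit0, pr)
  # noise-free kernel response: test R-squared near 1 (unpenalized fit)
  cv_sig <- cross_validate(build_design(pr, make_signal(y_sig)),
                           alpha = 0, n_folds = 5, seed = 2)
  expect_gt(min(cv_sig$test_r2), 0.98)
  # pure-noise response: train fits better than test, test R2 near 0
  set.seed(7)
  cv_noise <- cross_validate(build_design(pr, make_signal(rnorm(nf))),
                             n_folds = 5, seed = 2)
  expect_gt(mean(cv_noise$train_r2), mean(cv_noise$test_r2))
  expect_lt(abs(mean(cv_noise$test_r2)), 0.25)
})

test_that("omission variants have the documented column counts", {
  maps <- omission_variants(T = 20)
  expect_identical(names(maps),
                   c("Full", "-Rew", "-Direction", "-Direction&Rew",
                     "-CE/CX", "-CE", "-CX", "-SE/SX", "-SE", "-SX"))
  nc <- vapply(maps, ncol, 0L)
  expect_identical(unname(nc["Full"]), 410L)
  expect_identical(unname(nc["-Direction"]), 246L)    # (4 + 2) x 41
  expect_identical(unname(nc["-Rew"]), 328L)          # 8 x 41
  expect_identical(unname(nc["-Direction&Rew"]), 164L)
  expect_identical(unname(nc["-CE/CX"]), 246L)
  expect_identical(unname(nc["-CE"]), 328L)
  # -Direction sums each ipsi/contra pair, preserving timing
  M <- maps[["-Direction"]]
  expect_true(all(colSums(M) %in% c(1, 2)))
  # 4 collapsed pairs (2 sources each) + Rew/Unrew passthrough, 41 lags
  expect_identical(sum(M), (4 * 2 + 2) * 41)
})

test_that("omitting informative variables raises test error", {
  # direction-dominant truth: only CE kernels differ strongly by side
  kern <- default_kernels()
  spec <- truth_spec(task = task_config(0.9, 0.1, n_trials = 250),
                     kernels = kern,
                     noise = list(ar = 0.8, sd = 0.25))
  co <- generate_cohort(spec, 1, 1, photometry = "all")
  sig <- demodulate(co$photometry[[1]]$raw, 167, detrend_raw = TRUE)
  pr <- build_predictors(co$sessions[[1]], sig)
  de <- build_design(pr, sig)
  om <- omission_analysis(de, n_folds = 5, seed = 4)
  med <- tapply(om$test_mse, om$variant, median)
  expect_true(all(med[names(med) != "Full"] >= med["Full"] - 1e-3))
  expect_gt(med["-Direction"], med["Full"])
  expect_gt(med["-Rew"], med["Full"])
  expect_error(omission_analysis(de, variants = "nope"), "unknown")
  # a variable absent from the truth is free to omit
  kern0 <- default_kernels()
  for (nm in c("Rew", "Unrew")) kern0[[nm]]$amp <- 0
  spec0 <- truth_spec(task = task_config(0.9, 0.1, n_trials = 250),
                      kernels = kern0, noise = list(ar = 0.8, sd = 0.25))
  co0 <- generate_cohort(spec0, 1, 1, photometry = "all")
  sig0 <- demodulate(co0$photometry[[1]]$raw, 167, detrend_raw = TRUE)
  de0 <- build_design(build_predictors(co0$sessions[[1]], sig0), sig0)
  om0 <- omission_analysis(de0, variants = c("Full", "-Rew"),
                           n_folds = 5, seed = 4)
  med0 <- tapply(om0$test_mse, om0$variant, median)
  expect_equal(unname(med0["-Rew"] / med0["Full"]), 1, tolerance = 0.02)
})
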