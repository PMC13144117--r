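# Internal model fits shared by the selection and evaluation modules.
# All three learners take the genomes x families matrix X (double), return
# named per-family weights/importances plus whatever the caller needs to
# score new genomes.

# L2-penalised logistic regression minimised by L-BFGS with a hard iteration
# cap. Objective: 0.5*||w||^2 + C * sum_i log(1 + exp(-margin_i)); the
# intercept is unpenalised. Reaching the cap keeps the current coefficients
# and raises a warning rather than failing.
fit_lr_ridge <- function(X, y01, max_iter = 300L, C = 1, start = NULL) {
  storage.mode(X) <- "double"
  p <- ncol(X)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!identical(cache$par, par)) {
      cache$par <- par
      cache$val <- lr_obj_grad_cpp(X, y01, par, C)
    }
    cache$val
  }
  fn <- function(par) evaluate(par)$value
  gr <- function(par) evaluate(par)$grad
  par0 <- start %||% rep(0, p + 1L)
  opt <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  if (opt$convergence == 1L) {
    warning(sprintf("logistic regression reached the %d-iteration cap; coefficients retained",
                    max_iter), call. = FALSE)
  }
  w <- opt$par[seq_len(p)]
  names(w) <- colnames(X)
  list(weights = w, intercept = opt$par[p + 1L],
       converged = opt$convergence == 0L, par = opt$par)
}

predict_lr_score <- function(fit, X) {
  plogis(drop(X %*% fit$weights) + fit$intercept)
}

# Linear SVM trained by SGD on the hinge loss with L2 penalty. The visiting
# order over epochs is drawn from the given seed, making the fit fully
# reproducible. y must be a factor; the second level is mapped to +1.
fit_svm_sgd <- function(X, y, alpha = 1e-2, epochs = 80L, seed = 1L) {
  storage.mode(X) <- "double"
  n <- nrow(X)
  ypm1 <- ifelse(y == levels(y)[2L], 1, -1)
  ord <- withr::with_seed(seed, {
    unlist(lapply(seq_len(epochs), function(e) sample.int(n)), use.names = FALSE)
  }) - 1L
  # tail-average the second half of the updates
  res <- sgd_hinge_cpp(X, ypm1, alpha, as.integer(ord),
                       as.integer(length(ord) %/% 2L))
  w <- res$weights
  names(w) <- colnames(X)
  list(weights = w, intercept = res$intercept)
}

predict_svm_score <- function(fit, X) {
  drop(X %*% fit$weights) + fit$intercept
}

# Random forest with Gini impurity importance; single-threaded and seeded so
# runs are reproducible. probability = TRUE gives class-probability trees,
# used by the evaluation module for ROC scores.
fit_rf <- function(X, y, num_trees = 100L, seed = 1L, probability = FALSE) {
  ranger::ranger(x = X, y = y, num.trees = num_trees,
                 importance = "impurity", seed = seed, num.threads = 1L,
                 probability = probability)
}

predict_rf_score <- function(fit, X, positive) {
  pr <- stats::predict(fit, data = X, num.threads = 1L)$predictions
  pr[, positive]
}
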