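#' Random train/validation/test split
#'
#' Seeded row-level partition of a feature series into disjoint, exhaustive
#' subsets.
#'
#' @param series Data.frame with one row per window (e.g. columns `time_s`,
#'   `feature`, `ref`).
#' @param fractions Length-3 numeric summing to 1; default `c(0.70, 0.15,
#'   0.15)` for train/validation/test.
#' @param seed Integer seed.
#' @return List with data.frames `train`, `val`, `test`.
#' @export
split_data <- function(series, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  n <- nrow(series)
  if (n < 20) stop("need at least 20 rows to split")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must have length 3 and sum to 1")
  counts <- diff(c(0L, round(cumsum(fractions) * n)))
  idx <- with_seed(seed, sample.int(n))
  grp <- rep(1:3, times = counts)
  list(train = series[sort(idx[grp == 1]), , drop = FALSE],
       val = series[sort(idx[grp == 2]), , drop = FALSE],
       test = series[sort(idx[grp == 3]), , drop = FALSE])
}

# Two-hidden-layer (9, 18) backpropagation regressor: tanh hidden units,
# linear output, full-batch Adam, early stopping on the validation split.
mlp_fit <- function(x, y, xval = NULL, yval = NULL, hidden = c(9, 18),
                    seed = 1L, max_iter = 3000, lr = 0.01, patience = 12L) {
  mx <- mean(x); sx <- max(sd(x), 1e-8)
  my <- mean(y); sy <- max(sd(y), 1e-8)
  xs <- matrix((x - mx) / sx, ncol = 1)
  ys <- matrix((y - my) / sy, ncol = 1)
  have_val <- !is.null(xval) && length(xval) >= 2
  if (have_val) {
    xv <- matrix((xval - mx) / sx, ncol = 1)
    yv <- matrix((yval - my) / sy, ncol = 1)
  }
  sizes <- c(1, hidden, 1)
  init <- with_seed(seed, lapply(seq_len(length(sizes) - 1), function(l) {
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(1 / sizes[l])),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  }))
  theta <- init
  mstate <- lapply(theta, function(p) list(W = p$W * 0, b = p$b * 0))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; epsn <- 1e-8

  forward <- function(th, X) {
    a1 <- tanh(sweep(X %*% th[[1]]$W, 2, th[[1]]$b, "+"))
    a2 <- tanh(sweep(a1 %*% th[[2]]$W, 2, th[[2]]$b, "+"))
    out <- sweep(a2 %*% th[[3]]$W, 2, th[[3]]$b, "+")
    list(a1 = a1, a2 = a2, out = out)
  }

  best <- theta
  best_err <- Inf
  bad <- 0L
  n <- nrow(xs)
  for (it in seq_len(max_iter)) {
    f <- forward(theta, xs)
    d3 <- 2 * (f$out - ys) / n                     # dL/d out
    g3W <- t(f$a2) %*% d3
    g3b <- colSums(d3)
    d2 <- (d3 %*% t(theta[[3]]$W)) * (1 - f$a2^2)
    g2W <- t(f$a1) %*% d2
    g2b <- colSums(d2)
    d1 <- (d2 %*% t(theta[[2]]$W)) * (1 - f$a1^2)
    g1W <- t(xs) %*% d1
    g1b <- colSums(d1)
    grads <- list(list(W = g1W, b = g1b), list(W = g2W, b = g2b),
                  list(W = g3W, b = g3b))
    for (l in 1:3) {
      for (nm in c("W", "b")) {
        g <- grads[[l]][[nm]]
        mstate[[l]][[nm]] <- b1 * mstate[[l]][[nm]] + (1 - b1) * g
        vstate[[l]][[nm]] <- b2 * vstate[[l]][[nm]] + (1 - b2) * g^2
        mh <- mstate[[l]][[nm]] / (1 - b1^it)
        vh <- vstate[[l]][[nm]] / (1 - b2^it)
        theta[[l]][[nm]] <- theta[[l]][[nm]] - lr * mh / (sqrt(vh) + epsn)
      }
    }
    if (it %% 25 == 0) {
      err <- if (have_val) mean((forward(theta, xv)$out - yv)^2)
             else mean((forward(theta, xs)$out - ys)^2)
      if (err < best_err - 1e-7) {
        best_err <- err
        best <- theta
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  }
  structure(list(theta = best, mx = mx, sx = sx, my = my, sy = sy,
                 hidden = hidden),
            class = "doa_mlp")
}

mlp_predict <- function(fit, x) {
  xs <- matrix((x - fit$mx) / fit$sx, ncol = 1)
  th <- fit$theta
  a1 <- tanh(sweep(xs %*% th[[1]]$W, 2, th[[1]]$b, "+"))
  a2 <- tanh(sweep(a1 %*% th[[2]]$W, 2, th[[2]]$b, "+"))
  out <- sweep(a2 %*% th[[3]]$W, 2, th[[3]]$b, "+")
  as.numeric(out) * fit$sy + fit$my
}

#' Fit a DoA regression model
#'
#' Regresses the window feature (e.g. Sample Entropy) onto the 0-100
#' reference index with one of three model families:
#' \describe{
#'   \item{`rf`}{Random Forest, 1,000 trees by default.}
#'   \item{`svm`}{Support vector regression with a Gaussian RBF kernel
#'     (inverse width `gamma` defaulting to 1/feature-variance, cost 1).}
#'   \item{`ann`}{Backpropagation network with a 1-9-18-1 topology (tanh
#'     hidden layers of 9 and 18 units, linear output), trained with
#'     validation-based early stopping.}
#' }
#' All stochastic elements are seeded; the same data and seed give identical
#' predictions.
#'
#' @param train Data.frame with columns `feature` and `ref` (>= 10 rows).
#' @param family `"rf"`, `"svm"` or `"ann"`.
#' @param hyperparams Named list of family-specific overrides: `ntree` (rf),
#'   `gamma`/`cost` (svm), `hidden`/`max_iter`/`lr` (ann).
#' @param seed Integer seed.
#' @param val Optional validation data.frame (same columns) for the ANN's
#'   early stopping.
#' @param feature_name Label recorded in the model metadata.
#' @return An object of class `doa_model`.
#' @export
fit_doa_model <- function(train, family = c("rf", "svm", "ann"),
                          hyperparams = list(), seed = 1L, val = NULL,
                          feature_name = "sampen") {
  family <- match.arg(family)
  if (nrow(train) < 10) stop("need at least 10 training rows")
  x <- train$feature
  y <- train$ref
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("training data contains non-finite values; drop NaN rows upstream")
  if (sd(y) == 0) {
    # degenerate target: every family reduces to the constant predictor
    fit <- structure(list(constant = y[1]), class = "doa_const")
    return(structure(list(family = family, fit = fit,
                          feature_name = feature_name,
                          hyperparams = hyperparams, seed = as.integer(seed),
                          train_fingerprint = sprintf("n%d_f%.10g_r%.10g",
                                                      length(x), sum(x),
                                                      sum(y))),
                     class = "doa_model"))
  }
  fit <- switch(family,
    rf = {
      ntree <- hyperparams$ntree %||% 1000L
      # large terminal nodes smooth the univariate conditional mean
      nodesize <- hyperparams$nodesize %||% 50L
      with_seed(seed,
        randomForest::randomForest(x = matrix(x, ncol = 1), y = y,
                                   ntree = ntree, nodesize = nodesize))
    },
    svm = {
      gamma <- hyperparams$gamma %||% (1 / max(var(x), 1e-8))
      cost <- hyperparams$cost %||% 1
      with_seed(seed,
        e1071::svm(x = matrix(x, ncol = 1), y = y, type = "eps-regression",
                   kernel = "radial", gamma = gamma, cost = cost,
                   scale = FALSE))
    },
    ann = {
      mlp_fit(x, y,
              xval = val$feature, yval = val$ref,
              hidden = hyperparams$hidden %||% c(9, 18),
              seed = seed,
              max_iter = hyperparams$max_iter %||% 3000,
              lr = hyperparams$lr %||% 0.01)
    })
  structure(list(family = family, fit = fit, feature_name = feature_name,
                 hyperparams = hyperparams, seed = as.integer(seed),
                 train_fingerprint = sprintf("n%d_f%.10g_r%.10g",
                                             length(x), sum(x), sum(y))),
            class = "doa_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.doa_model <- function(x, ...) {
  cat(sprintf("<doa_model> family=%s feature=%s (%s)\n",
              x$family, x$feature_name, x$train_fingerprint))
  invisible(x)
}

#' Predict the DoA index from window features
#'
#' @param object A fitted [fit_doa_model()] object.
#' @param newdata Numeric vector of feature values, or a data.frame with a
#'   `feature` column.
#' @param ... Unused.
#' @return Numeric vector of index predictions, clipped to \[0, 100\].
#' @export
predict.doa_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    if (!"feature" %in% names(newdata))
      stop("newdata must contain a 'feature' column")
    newdata$feature
  } else as.numeric(newdata)
  if (length(x) == 0) return(numeric(0))
  if (inherits(object$fit, "doa_const"))
    return(pmin(pmax(rep(object$fit$constant, length(x)), 0), 100))
  p <- switch(object$family,
    rf = as.numeric(predict(object$fit, matrix(x, ncol = 1))),
    svm = as.numeric(predict(object$fit, matrix(x, ncol = 1))),
    ann = mlp_predict(object$fit, x))
  pmin(pmax(p, 0), 100)
}
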