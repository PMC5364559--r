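# Binary kernel SVM: dual problem solved by sequential minimal optimization
# (src/smo.cpp), with Platt sigmoid probability calibration.

#' Kernel specification
#'
#' The four kernels: linear `x'z`, polynomial `(gamma x'z + r)^degree`,
#' radial basis `exp(-gamma ||x - z||^2)` and sigmoid
#' `tanh(gamma x'z + r)`. Parameters irrelevant to the chosen kind are
#' ignored. `gamma = NULL` resolves to `1 / n_features` at training time.
#'
#' @param kind one of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param gamma positive scale parameter (polynomial, rbf, sigmoid).
#' @param coef0 offset r (polynomial, sigmoid).
#' @param degree positive integer degree (polynomial).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial", "sigmoid"),
                        gamma = NULL, coef0 = 0, degree = 3L) {
  kind <- match.arg(kind)
  if (!is.null(gamma)) stopifnot(gamma > 0)
  degree <- as.integer(degree)
  stopifnot(degree >= 1L)
  spec <- switch(kind,
                 linear = list(kind = kind),
                 polynomial = list(kind = kind, gamma = gamma, coef0 = coef0,
                                   degree = degree),
                 rbf = list(kind = kind, gamma = gamma),
                 sigmoid = list(kind = kind, gamma = gamma, coef0 = coef0))
  structure(spec, class = "kernel_spec")
}

kernel_kind_code <- function(kind) {
  match(kind, c("linear", "polynomial", "rbf", "sigmoid")) - 1L
}

#' Kernel Gram matrix
#'
#' @param X,Z numeric matrices with matching column counts.
#' @param kernel a [kernel_spec()] with `gamma` resolved (non-NULL where
#'   required).
#' @return The `nrow(X) x nrow(Z)` kernel matrix.
#' @export
kernel_matrix <- function(X, Z, kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  gamma <- kernel$gamma %||% (1 / ncol(X))  # %||% binds tighter than /
  kernel_matrix_cpp(as.matrix(X), as.matrix(Z),
                    kernel_kind_code(kernel$kind), gamma,
                    kernel$coef0 %||% 0, kernel$degree %||% 3L)
}

# Platt (1999) sigmoid fit P(y=1|f) = 1/(1+exp(A f + B)), by the robust
# Newton iteration of Lin, Lin & Weng (2007).
platt_fit <- function(f, y, max_iter = 200L) {
  prior1 <- sum(y > 0)
  prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  eps <- 1e-10
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + eps
    h22 <- sum(d2) + eps
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      nA <- A + step * dA
      nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) {
        A <- nA; B <- nB; fv <- nf
        break
      }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B, converged = FALSE))
    }
  }
  list(A = A, B = B, converged = TRUE)
}

platt_prob <- function(f, platt) {
  z <- platt$A * f + platt$B
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Train a binary kernel SVM
#'
#' Solves the dual problem
#' `max sum(alpha) - 1/2 sum alpha_i alpha_j y_i y_j K(x_i, x_j)` subject to
#' `0 <= alpha_i <= c` and `sum(alpha_i y_i) = 0` by sequential minimal
#' optimization, and (optionally) fits a Platt sigmoid on the training
#' decision values so predictions carry a probability of the positive
#' class. Training is deterministic; `seed` is accepted for interface
#' stability and seeds any future stochastic component.
#'
#' @param features a [feature_matrix()] (rows = sequences).
#' @param labels +1 / -1 per row; both classes must be present.
#' @param kernel a [kernel_spec()].
#' @param cost regularization parameter c > 0 (default 1).
#' @param probability fit the probability calibration (default TRUE).
#' @param seed integer seed.
#' @param tol KKT violation tolerance of the SMO solver.
#' @param max_sweeps SMO sweep cap.
#' @return An `svm_model`: kernel (with resolved gamma), cost, support
#'   vectors with their `alpha` and labels, intercept `rho`, Platt
#'   coefficients, and the feature fingerprint the model will insist on at
#'   prediction time.
#' @export
train_svm <- function(features, labels, kernel = kernel_spec("rbf"),
                      cost = 1, probability = TRUE, seed = 1L,
                      tol = 1e-3, max_sweeps = 2000L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!all(is.finite(X))) stop("non-finite feature values")
  if (!(cost > 0)) stop("cost must be positive")
  if (is.null(kernel$gamma) && kernel$kind != "linear") {
    # scale-aware default gamma = 1 / (d * Var(X)) (libsvm/sklearn "scale"):
    # descriptor vectors are normalized, so their entries live on scale ~1/d
    # and the naive 1/d would flatten the RBF kernel to a constant.
    v <- mean((X - mean(X))^2)
    kernel$gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }

  K <- kernel_matrix(X, X, kernel)
  fit <- smo_train_cpp(K, y, cost, tol, as.integer(max_sweeps))
  if (!fit$converged) {
    warning("SMO did not reach the KKT tolerance within ", max_sweeps,
            " sweeps")
  }
  alpha <- fit$alpha
  sv <- which(alpha > 0)
  model <- structure(list(
    kernel = kernel, cost = cost,
    alpha = alpha[sv], sv_labels = y[sv],
    sv = X[sv, , drop = FALSE], rho = fit$rho,
    platt = NULL,
    n_features = ncol(X), feature_names = colnames(X),
    fingerprint = fm_fingerprint(features),
    scheme = attr(features, "scheme"),
    version = "protclass-svm-1", seed = as.integer(seed)),
    class = "svm_model")
  if (probability) {
    f <- decision_values(model, features)
    model$platt <- platt_fit(f, y)
  }
  model
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("svm_model: %s kernel, cost %g, %d support vectors, %s features (%s)\n",
              x$kernel$kind, x$cost, length(x$alpha),
              x$n_features, x$scheme %||% "unknown scheme"))
  invisible(x)
}

check_fingerprint <- function(model, features) {
  fp <- fm_fingerprint(features)
  if (is.null(fp) || !identical(fp, model$fingerprint)) {
    stop(sprintf(paste0("feature fingerprint mismatch: model was trained on ",
                        "'%s', supplied features are '%s'"),
                 model$fingerprint, fp %||% "<unfingerprinted>"))
  }
  if (ncol(features) != model$n_features) stop("feature dimension mismatch")
}

#' Pre-sign SVM decision values
#'
#' `f(x) = sum_i y_i alpha_i K(x, x_i) + rho` over the stored support
#' vectors.
#'
#' @param model an `svm_model`.
#' @param features a [feature_matrix()] whose fingerprint matches the
#'   model's.
#' @return Numeric vector, one value per row.
#' @export
decision_values <- function(model, features) {
  stopifnot(inherits(model, "svm_model"))
  check_fingerprint(model, features)
  K <- kernel_matrix(as.matrix(features), model$sv, model$kernel)
  drop(K %*% (model$alpha * model$sv_labels)) + model$rho
}

#' Predict class labels and resistance probabilities
#'
#' Label is the sign of the decision value (ties at exactly 0 predict +1,
#' with a message); probability is the Platt-calibrated chance of class +1
#' (`NA` when the model was trained without calibration). Discrepancies
#' between the sign rule and the 0.5 probability threshold are counted and
#' reported, never silently reconciled.
#'
#' @param object an `svm_model`.
#' @param features a matching [feature_matrix()].
#' @param ... unused.
#' @return A data frame with columns `label` (+1/-1), `probability` and
#'   `decision_value`.
#' @export
predict.svm_model <- function(object, features, ...) {
  f <- decision_values(object, features)
  ties <- sum(f == 0)
  if (ties > 0) message(ties, " decision value(s) exactly 0: predicted +1")
  label <- ifelse(f >= 0, 1L, -1L)
  prob <- if (!is.null(object$platt)) platt_prob(f, object$platt) else
    rep(NA_real_, length(f))
  if (!is.null(object$platt)) {
    mismatch <- sum((prob >= 0.5) != (label == 1L))
    if (mismatch > 0) {
      message(mismatch, " prediction(s) where calibrated probability and ",
              "decision sign disagree; label follows the sign")
    }
  }
  data.frame(id = rownames(features) %||% seq_along(f), label = label,
             probability = prob, decision_value = f,
             stringsAsFactors = FALSE)
}

# --- persistence: JSON with hex-float doubles (bit-exact round trip) -------

num_enc <- function(x) sprintf("%a", x)
num_dec <- function(s) vapply(s, function(z) as.numeric(z), numeric(1),
                              USE.NAMES = FALSE)

#' Save a trained model to a versioned text file
#'
#' JSON, with all doubles encoded as C99 hex-float literals so that reloaded
#' models reproduce decision values bit-exactly.
#'
#' @param model an `svm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  obj <- list(
    version = model$version,
    kernel = model$kernel[!vapply(model$kernel, is.null, logical(1))],
    cost = num_enc(model$cost),
    alpha = num_enc(model$alpha),
    sv_labels = as.integer(model$sv_labels),
    sv = list(dim = dim(model$sv), data = num_enc(as.vector(model$sv))),
    rho = num_enc(model$rho),
    platt = if (!is.null(model$platt))
      list(A = num_enc(model$platt$A), B = num_enc(model$platt$B)),
    n_features = model$n_features,
    feature_names = model$feature_names,
    fingerprint = model$fingerprint,
    scheme = model$scheme,
    seed = model$seed)
  obj$kernel$kind <- model$kernel$kind
  if (!is.null(obj$kernel$gamma)) obj$kernel$gamma <- num_enc(obj$kernel$gamma)
  if (!is.null(obj$kernel$coef0)) obj$kernel$coef0 <- num_enc(obj$kernel$coef0)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a model written by [save_model()]
#'
#' @param path path to the model file.
#' @return An `svm_model`. Files written by a different format version are
#'   refused.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "protclass-svm-1")) {
    stop("unsupported model file version: ",
         obj$version %||% "<missing>", " (this build reads protclass-svm-1)")
  }
  kern <- obj$kernel
  spec <- kernel_spec(kern$kind,
                      gamma = if (!is.null(kern$gamma)) num_dec(kern$gamma),
                      coef0 = if (!is.null(kern$coef0)) num_dec(kern$coef0)
                              else 0,
                      degree = kern$degree %||% 3L)
  sv <- matrix(num_dec(obj$sv$data), nrow = obj$sv$dim[1L],
               ncol = obj$sv$dim[2L])
  colnames(sv) <- obj$feature_names
  structure(list(
    kernel = spec, cost = num_dec(obj$cost),
    alpha = num_dec(obj$alpha), sv_labels = as.numeric(obj$sv_labels),
    sv = sv, rho = num_dec(obj$rho),
    platt = if (!is.null(obj$platt))
      list(A = num_dec(obj$platt$A), B = num_dec(obj$platt$B)),
    n_features = obj$n_features, feature_names = obj$feature_names,
    fingerprint = obj$fingerprint, scheme = obj$scheme,
    version = obj$version, seed = obj$seed),
    class = "svm_model")
}
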