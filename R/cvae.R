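# Conditional variational autoencoder on feature vectors, trained by
# minibatch SGD with hand-written backpropagation.
#
# Model: the class label is one-hot concatenated to the input of both the
# encoder and the decoder. The encoder (two ReLU hidden layers) outputs a
# diagonal Gaussian q(z | x, c) via a mean and a log-variance head; the
# sampled latent z = mu + sigma * eps (reparameterization) feeds the
# decoder (mirrored hidden layers), whose output parameterizes a
# unit-variance Gaussian likelihood on the standardized features, so the
# reconstruction term is squared error / 2. Training minimizes
#   reconstruction + KL(q(z|x,c) || N(0, I))
# with a single Monte-Carlo sample per step; at inference the noise is
# pinned to 0 and classification evaluates the objective under every
# candidate class, taking the argmin (conditional-likelihood decision
# rule, ties to the lowest class index).

#' CVAEModel: conditional variational autoencoder state
#'
#' @slot par named list of weight matrices and bias vectors (encoder
#'   `W1,b1,W2,b2,Wm,bm,Wv,bv`; decoder `V1,c1,V2,c2,Vo,co`).
#' @slot inputDim feature dimension.
#' @slot K number of classes (>= 2).
#' @slot latentDim latent dimension (< inputDim).
#' @slot hidden encoder hidden layer sizes (decoder mirrors them).
#' @slot trained logical.
#' @slot history data.frame of per-epoch mean losses (epoch, loss, recon,
#'   kl), empty before training.
#' @slot config training configuration actually used.
#' @aliases CVAEModel
#' @exportClass CVAEModel
setClass("CVAEModel", representation(
  par = "list", inputDim = "integer", K = "integer",
  latentDim = "integer", hidden = "integer", trained = "logical",
  history = "data.frame", config = "list"
))

setValidity("CVAEModel", function(object) {
  if (object@latentDim >= object@inputDim)
    return("latent dimension must be smaller than the input dimension")
  if (object@K < 2L) return("need at least 2 classes")
  TRUE
})

setMethod("show", "CVAEModel", function(object) {
  cat(sprintf(
    "CVAEModel: %d features, %d classes, latent %d, hidden (%s)%s\n",
    object@inputDim, object@K, object@latentDim,
    paste(object@hidden, collapse = ", "),
    if (object@trained) sprintf(" [trained, %d epochs]",
                                nrow(object@history)) else " [untrained]"))
})

#' Initialize an untrained CVAE
#'
#' @param inputDim feature dimension.
#' @param K number of classes (>= 2).
#' @param latentDim latent dimension, strictly smaller than `inputDim`
#'   (default 8).
#' @param hidden two encoder hidden sizes (default `c(64, 32)`); the
#'   decoder mirrors them.
#' @param seed weight initialization seed.
#' @return an untrained [CVAEModel-class].
#' @export
newCVAE <- function(inputDim, K, latentDim = 8L, hidden = c(64L, 32L),
                    seed = 1L) {
  inputDim <- as.integer(inputDim); K <- as.integer(K)
  latentDim <- as.integer(latentDim); hidden <- as.integer(hidden)
  stopifnot(length(hidden) == 2L)
  d <- inputDim; L <- latentDim
  par <- withr::with_seed(as.integer(seed), {
    he <- function(out, inn) matrix(rnorm(out * inn, 0, sqrt(2 / inn)),
                                    out, inn)
    sm <- function(out, inn) matrix(rnorm(out * inn, 0, sqrt(1 / inn)),
                                    out, inn)
    list(
      W1 = he(hidden[1], d + K), b1 = rep(0, hidden[1]),
      W2 = he(hidden[2], hidden[1]), b2 = rep(0, hidden[2]),
      Wm = sm(L, hidden[2]), bm = rep(0, L),
      Wv = sm(L, hidden[2]), bv = rep(0, L),
      V1 = he(hidden[2], L + K), c1 = rep(0, hidden[2]),
      V2 = he(hidden[1], hidden[2]), c2 = rep(0, hidden[1]),
      Vo = sm(d, hidden[1]), co = rep(0, d)
    )
  })
  new("CVAEModel", par = par, inputDim = inputDim, K = K,
      latentDim = latentDim, hidden = hidden, trained = FALSE,
      history = data.frame(), config = list(seed = as.integer(seed)))
}

oneHot <- function(y, K) {
  C <- matrix(0, K, length(y))
  C[cbind(as.integer(y), seq_along(y))] <- 1
  C
}

# forward pass; columns are samples. eps NULL => zeros (inference).
# dropout masks are sampled from the current RNG stream when p > 0.
cvaeForward <- function(par, X, C, eps = NULL, dropout = 0) {
  b <- ncol(X)
  L <- nrow(par$Wm)
  if (is.null(eps)) eps <- matrix(0, L, b)
  keep <- 1 - dropout
  mask <- function(nr) {
    if (dropout > 0)
      matrix(rbinom(nr * b, 1, keep), nr, b) / keep
    else 1
  }
  a0 <- rbind(X, C)
  z1 <- par$W1 %*% a0 + par$b1
  h1 <- relu(z1); m1 <- mask(nrow(h1)); h1d <- h1 * m1
  z2 <- par$W2 %*% h1d + par$b2
  h2 <- relu(z2); m2 <- mask(nrow(h2)); h2d <- h2 * m2
  mu <- par$Wm %*% h2d + par$bm
  lv <- pmin(pmax(par$Wv %*% h2d + par$bv, -15), 15)  # overflow guard
  sdv <- exp(lv / 2)
  z <- mu + sdv * eps
  g0 <- rbind(z, C)
  y1 <- par$V1 %*% g0 + par$c1
  u1 <- relu(y1); n1 <- mask(nrow(u1)); u1d <- u1 * n1
  y2 <- par$V2 %*% u1d + par$c2
  u2 <- relu(y2); n2 <- mask(nrow(u2)); u2d <- u2 * n2
  xhat <- par$Vo %*% u2d + par$co
  recon <- 0.5 * colSums((X - xhat)^2)
  kl <- 0.5 * colSums(mu^2 + exp(lv) - 1 - lv)
  list(a0 = a0, z1 = z1, h1d = h1d, m1 = m1, z2 = z2, h2d = h2d, m2 = m2,
       mu = mu, lv = lv, sdv = sdv, eps = eps, z = z, g0 = g0, y1 = y1,
       u1d = u1d, n1 = n1, y2 = y2, u2d = u2d, n2 = n2, xhat = xhat,
       recon = recon, kl = kl, loss = mean(recon + kl))
}

# gradients of the batch-mean loss wrt all parameters
cvaeBackward <- function(par, X, C, fw) {
  b <- ncol(X)
  L <- nrow(par$Wm)
  G <- (fw$xhat - X) / b
  dVo <- G %*% t(fw$u2d); dco <- rowSums(G)
  du2 <- (t(par$Vo) %*% G) * fw$n2
  dy2 <- du2 * (fw$y2 > 0)
  dV2 <- dy2 %*% t(fw$u1d); dc2 <- rowSums(dy2)
  du1 <- (t(par$V2) %*% dy2) * fw$n1
  dy1 <- du1 * (fw$y1 > 0)
  dV1 <- dy1 %*% t(fw$g0); dc1 <- rowSums(dy1)
  dz <- (t(par$V1) %*% dy1)[seq_len(L), , drop = FALSE]
  dmu <- dz + fw$mu / b
  dlv <- dz * fw$eps * fw$sdv * 0.5 + 0.5 * (exp(fw$lv) - 1) / b
  dWm <- dmu %*% t(fw$h2d); dbm <- rowSums(dmu)
  dWv <- dlv %*% t(fw$h2d); dbv <- rowSums(dlv)
  dh2 <- (t(par$Wm) %*% dmu + t(par$Wv) %*% dlv) * fw$m2
  dz2 <- dh2 * (fw$z2 > 0)
  dW2 <- dz2 %*% t(fw$h1d); db2 <- rowSums(dz2)
  dh1 <- (t(par$W2) %*% dz2) * fw$m1
  dz1 <- dh1 * (fw$z1 > 0)
  dW1 <- dz1 %*% t(fw$a0); db1 <- rowSums(dz1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wm = dWm, bm = dbm,
       Wv = dWv, bv = dbv, V1 = dV1, c1 = dc1, V2 = dV2, c2 = dc2,
       Vo = dVo, co = dco)
}

checkClassArg <- function(y, K) {
  y <- as.integer(y)
  if (any(y < 1L) || any(y > K)) stop("class labels out of range 1..", K)
  y
}

#' Encode a feature vector to its approximate posterior
#'
#' Runs the encoder with the class one-hot concatenated to `x` and returns
#' the Gaussian posterior parameters. The variance is parameterized via
#' log-variance, so it is strictly positive by construction.
#'
#' @param model a [CVAEModel-class].
#' @param x numeric feature vector of length `inputDim`.
#' @param class class label in `1..K`.
#' @return list with `mu` and `sigma2` (both length `latentDim`).
#' @export
encodeCVAE <- function(model, x, class) {
  class <- checkClassArg(class, model@K)
  stopifnot(length(x) == model@inputDim, all(is.finite(x)))
  fw <- cvaeForward(model@par, matrix(x, ncol = 1),
                    oneHot(class, model@K))
  list(mu = as.numeric(fw$mu), sigma2 = as.numeric(exp(fw$lv)))
}

#' Reparameterized latent sample
#'
#' `z = mu + sqrt(sigma2) * noise` elementwise.
#'
#' @param mu mean vector.
#' @param sigma2 strictly positive variance vector.
#' @param noise standard-normal draw of the same length.
#' @return latent sample `z`.
#' @export
#' @examples
#' reparameterize(c(1, 2), c(1, 4), c(0, 0))  # equals mu
reparameterize <- function(mu, sigma2, noise) {
  if (any(sigma2 <= 0)) stop("variance must be strictly positive")
  mu + sqrt(sigma2) * noise
}

#' KL divergence of a diagonal Gaussian from the standard-normal prior
#'
#' Closed form `0.5 * sum(mu^2 + sigma2 - 1 - log(sigma2))`; nonnegative,
#' and zero exactly when `mu = 0, sigma2 = 1`.
#'
#' @param mu mean vector.
#' @param sigma2 strictly positive variance vector.
#' @return nonnegative scalar.
#' @export
#' @examples
#' klGaussian(0, 1)   # 0
#' klGaussian(1, 1)   # 0.5
klGaussian <- function(mu, sigma2) {
  if (any(sigma2 <= 0)) stop("variance must be strictly positive")
  0.5 * sum(mu^2 + sigma2 - 1 - log(sigma2))
}

#' Single-sample CVAE objective for one (x, class) pair
#'
#' Evaluates the training objective with the supplied noise draw: the
#' unit-variance Gaussian reconstruction term `0.5 * ||x - xhat||^2` plus
#' the KL term, which matches [klGaussian()] on the encoder output
#' exactly. `total = reconstruction + kl`.
#'
#' @param model a [CVAEModel-class].
#' @param x feature vector.
#' @param class class label in `1..K`.
#' @param noise standard-normal vector of length `latentDim` (default 0,
#'   the inference setting).
#' @return list `(reconstruction, kl, total)`.
#' @export
cvaeLoss <- function(model, x, class, noise = NULL) {
  class <- checkClassArg(class, model@K)
  if (is.null(noise)) noise <- rep(0, model@latentDim)
  fw <- cvaeForward(model@par, matrix(x, ncol = 1),
                    oneHot(class, model@K),
                    eps = matrix(noise, ncol = 1))
  list(reconstruction = as.numeric(fw$recon), kl = as.numeric(fw$kl),
       total = as.numeric(fw$recon + fw$kl))
}

#' Train a CVAE by minibatch SGD
#'
#' Minimizes the conditional objective (reconstruction + KL) with one
#' reparameterized Monte-Carlo sample per step, inverted dropout on the
#' hidden layers, and global gradient-norm clipping (at 5) for stability.
#' Fully reproducible given `seed`. Defaults follow the study settings:
#' learning rate 0.01, 50 epochs, batch size 5, dropout 0.5.
#'
#' @param model an untrained (or previously trained) [CVAEModel-class].
#' @param X numeric feature matrix, rows = samples (standardized features
#'   are assumed; see [fitFeatureScaler()]).
#' @param y integer class labels in `1..K`.
#' @param lr learning rate (default 0.01).
#' @param epochs number of epochs (default 50).
#' @param batchSize minibatch size (default 5).
#' @param dropout hidden-layer dropout probability (default 0.5).
#' @param seed training seed (shuffling, noise, dropout).
#' @return the trained model; `model@history` holds one row per epoch
#'   with the mean total / reconstruction / KL loss.
#' @export
trainCVAE <- function(model, X, y, lr = 0.01, epochs = 50L,
                      batchSize = 5L, dropout = 0.5, seed = 1L) {
  if (is.null(dim(X)) || nrow(X) == 0) stop("empty training data")
  y <- checkClassArg(y, model@K)
  stopifnot(ncol(X) == model@inputDim, length(y) == nrow(X))
  par <- model@par
  n <- nrow(X)
  L <- model@latentDim
  hist <- matrix(0, epochs, 3)
  # reconstruction gradients grow with the feature dimension (the loss sums
  # over dimensions), so the clip threshold scales with it
  clip <- max(5, 0.25 * model@inputDim)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epLoss <- epRec <- epKL <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        Xb <- t(X[idx, , drop = FALSE])
        Cb <- oneHot(y[idx], model@K)
        eps <- matrix(rnorm(L * length(idx)), L, length(idx))
        fw <- cvaeForward(par, Xb, Cb, eps, dropout)
        gr <- cvaeBackward(par, Xb, Cb, fw)
        gn <- sqrt(sum(vapply(gr, function(g) sum(g^2), numeric(1))))
        sc <- if (gn > clip) clip / gn else 1
        for (nm in names(par)) par[[nm]] <- par[[nm]] - lr * sc * gr[[nm]]
        epLoss <- epLoss + fw$loss
        epRec <- epRec + mean(fw$recon)
        epKL <- epKL + mean(fw$kl)
        nb <- nb + 1L
      }
      hist[ep, ] <- c(epLoss, epRec, epKL) / nb
    }
  })
  model@par <- par
  model@trained <- TRUE
  model@history <- data.frame(epoch = seq_len(epochs), loss = hist[, 1],
                              recon = hist[, 2], kl = hist[, 3])
  model@config <- list(lr = lr, epochs = as.integer(epochs),
                       batchSize = as.integer(batchSize),
                       dropout = dropout, seed = as.integer(seed))
  model
}

# deterministic per-class objective scores; rows = samples, cols = classes
cvaeScores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xt <- t(X)
  n <- ncol(Xt)
  scores <- matrix(0, n, model@K)
  for (c in seq_len(model@K)) {
    Cb <- oneHot(rep(c, n), model@K)
    fw <- cvaeForward(model@par, Xt, Cb)  # noise 0, no dropout
    scores[, c] <- fw$recon + fw$kl
  }
  scores
}

decideClass <- function(scores) max.col(-scores, ties.method = "first")

#' Classify feature vectors with a trained CVAE
#'
#' Evaluates the conditional objective for every candidate class with the
#' latent noise pinned to 0 (deterministic) and returns the argmin class;
#' exact ties resolve to the lowest class index. Lower score = better fit
#' under that class condition.
#'
#' @param model a trained [CVAEModel-class].
#' @param X feature matrix (rows = samples) or a single vector.
#' @return list with `labels` (integer vector) and `scores` (n x K matrix
#'   of per-class objective values).
#' @export
classifyCVAE <- function(model, X) {
  if (!model@trained) stop("model has not been trained")
  scores <- cvaeScores(model, X)
  list(labels = decideClass(scores), scores = scores)
}
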