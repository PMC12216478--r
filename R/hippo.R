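# Hippopotamus optimization: a population metaheuristic with three phases
# per iteration. Phase 1 (social/exploration): the first half of the herd
# moves toward the leader (males) and relative to the mean of a random
# subgroup (females/calves, with a time-decay branch). Phase 2 (defense):
# the second half reacts to a randomly placed predator with Levy-flight
# jumps scaled by the inverse distance. Phase 3 (escape/exploitation):
# every individual takes a step inside bounds that shrink as 1/iteration.
# All proposals are clamped to the box and accepted only on strict fitness
# improvement, so the best-so-far trajectory is non-increasing.

#' Heavy-tailed Levy-flight step
#'
#' Mantegna's stable-ratio construction: `u / |v|^(1/beta)` with
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and `sigma_u` chosen so the step
#' follows a symmetric alpha-stable law with exponent `beta`.
#'
#' @param n number of components.
#' @param beta stability exponent in (1, 2] (default 1.5).
#' @return numeric vector of `n` heavy-tailed steps.
#' @export
levyStep <- function(n, beta = 1.5) {
  stopifnot(beta > 1, beta <= 2)
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  rnorm(n, 0, sigma) / abs(rnorm(n))^(1 / beta)
}

clampBox <- function(x, lower, upper) pmin(pmax(x, lower), upper)

evalFitness <- function(f, x, who) {
  v <- f(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("fitness function returned a non-finite value for individual ",
         who)
  v
}

# Eq-11-style random coefficient vector: one of five scenarios chosen
# uniformly per update
randomV <- function(n, C1, C2) {
  th1 <- runif(1); th2 <- runif(1)
  switch(sample.int(5L, 1L),
         C2 * runif(n) + th1 * runif(n),
         2 * runif(n) - 1,
         runif(n),
         C1 * runif(n) + th2 * runif(n),
         runif(n))
}

#' Minimize a function with hippopotamus optimization
#'
#' Bound-constrained population minimizer. Per iteration the decay scalar
#' is `T = exp(-t / maxIter)` (so `T` starts near 1 and falls to `e^-1`),
#' proposals outside the box are clamped, and every acceptance requires a
#' strict fitness improvement, making the best-so-far trajectory monotone
#' non-increasing. Fully deterministic under `seed`.
#'
#' @param f objective function mapping a numeric vector to a finite
#'   scalar; minimized.
#' @param lower,upper numeric bound vectors (equal length, `lower <
#'   upper`).
#' @param M population size (>= 2, default 20).
#' @param maxIter iteration budget (default 50).
#' @param C1,C2 social constants in `[1, 2]` (defaults 1.5).
#' @param levyExponent stability exponent for the defense-phase Levy
#'   flight (default 1.5).
#' @param bcdg ranges for the four defense-phase coefficients, drawn
#'   uniformly per update: a list with elements `b`, `c`, `d`, `g`, each
#'   `c(min, max)`.
#' @param seed integer seed.
#' @param init optional matrix of initial positions (rows used to seed
#'   the first individuals; remaining ones drawn uniformly in the box).
#' @param callback optional function called per iteration with the trace
#'   row.
#' @return list with `best` (position), `bestFit`, `history` (data.frame
#'   iteration / bestFit / meanFit) and `evaluations`.
#' @export
#' @examples
#' res <- hippoOptimize(function(x) sum(x^2), c(-5, -5), c(5, 5),
#'                      M = 10, maxIter = 20, seed = 1)
#' res$bestFit
hippoOptimize <- function(f, lower, upper, M = 20L, maxIter = 50L,
                          C1 = 1.5, C2 = 1.5, levyExponent = 1.5,
                          bcdg = list(b = c(2, 4), c = c(1, 1.5),
                                      d = c(2, 3), g = c(-1, 1)),
                          seed = 1L, init = NULL, callback = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(lower >= upper))
    stop("invalid bounds: need lower < upper elementwise")
  if (M < 2L) stop("population size must be at least 2")
  if (maxIter < 1L) stop("need at least one iteration")
  if (C1 < 1 || C1 > 2 || C2 < 1 || C2 > 2)
    stop("C1 and C2 must lie in [1, 2]")
  N <- length(lower)
  nEval <- 0L
  fit1 <- function(x, who) {
    nEval <<- nEval + 1L
    evalFitness(f, x, who)
  }
  withSeedIf(seed, {
    pos <- matrix(runif(M * N), M, N)
    pos <- sweep(sweep(pos, 2, upper - lower, "*"), 2, lower, "+")
    if (!is.null(init)) {
      init <- matrix(init, ncol = N)
      take <- min(nrow(init), M)
      pos[seq_len(take), ] <- clampBox(init[seq_len(take), , drop = FALSE],
                                       matrix(lower, take, N, byrow = TRUE),
                                       matrix(upper, take, N, byrow = TRUE))
    }
    fit <- vapply(seq_len(M), function(i) fit1(pos[i, ], i), numeric(1))
    half <- ceiling(M / 2)
    hist <- matrix(0, maxIter, 3)
    for (t in seq_len(maxIter)) {
      Tdec <- exp(-t / maxIter)
      # ---- phase 1: social behaviour (first half) ----
      for (i in seq_len(half)) {
        bestIdx <- which.min(fit)
        leader <- pos[bestIdx, ]
        prop <- pos[i, ] + runif(N) * (leader - C1 * pos[i, ])
        prop <- clampBox(prop, lower, upper)
        fp <- fit1(prop, i)
        if (fp < fit[i]) { pos[i, ] <- prop; fit[i] <- fp }
        # female/calf update against the mean of a random subgroup
        bestIdx <- which.min(fit)
        leader <- pos[bestIdx, ]
        sub <- sample.int(M, sample.int(M, 1L))
        RGm <- colMeans(pos[sub, , drop = FALSE])
        prop <- if (Tdec > 0.6) {
          pos[i, ] + randomV(N, C1, C2) * (leader - C2 * RGm)
        } else if (runif(1) > 0.5) {
          pos[i, ] + randomV(N, C1, C2) * (RGm - leader)
        } else {
          lower + runif(N) * (upper - lower)
        }
        prop <- clampBox(prop, lower, upper)
        fp <- fit1(prop, i)
        if (fp < fit[i]) { pos[i, ] <- prop; fit[i] <- fp }
      }
      # ---- phase 2: defense against a predator (second half) ----
      if (half < M) for (i in (half + 1L):M) {
        P <- lower + runif(N) * (upper - lower)
        fP <- fit1(P, i)
        Dist <- abs(P - pos[i, ])
        b <- runif(1, bcdg$b[1], bcdg$b[2])
        cc <- runif(1, bcdg$c[1], bcdg$c[2])
        d <- runif(1, bcdg$d[1], bcdg$d[2])
        g <- runif(1, bcdg$g[1], bcdg$g[2])
        fac <- b / (cc - d * cos(2 * pi * g))
        lev <- levyStep(N, levyExponent)
        prop <- if (fP < fit[i]) {
          lev * P + fac / pmax(Dist, 1e-10)
        } else {
          lev * P + fac / (2 * Dist + runif(1))
        }
        prop <- clampBox(prop, lower, upper)
        fp <- fit1(prop, i)
        if (fp < fit[i]) { pos[i, ] <- prop; fit[i] <- fp }
      }
      # ---- phase 3: escape to nearby water (everyone) ----
      Uloc <- upper / t; Lloc <- lower / t
      for (i in seq_len(M)) {
        alpha <- switch(sample.int(3L, 1L),
                        2 * runif(N) - 1, runif(N), rnorm(N))
        prop <- pos[i, ] + runif(1) * (Lloc + alpha * (Uloc - Lloc))
        prop <- clampBox(prop, lower, upper)
        fp <- fit1(prop, i)
        if (fp < fit[i]) { pos[i, ] <- prop; fit[i] <- fp }
      }
      hist[t, ] <- c(t, min(fit), mean(fit))
      if (!is.null(callback)) callback(hist[t, ])
    }
  })
  bestIdx <- which.min(fit)
  history <- data.frame(iteration = hist[, 1], bestFit = hist[, 2],
                        meanFit = hist[, 3])
  list(best = pos[bestIdx, ], bestFit = fit[bestIdx], history = history,
       evaluations = nEval)
}

#' Negative (macro) precision fitness for classifier tuning
#'
#' Returns `-precision` so that maximizing precision fits the minimizer
#' contract of [hippoOptimize()]. Binary problems use the positive-class
#' precision `TP / (TP + FP)`; multiclass problems use the unweighted
#' macro precision. A class with no positive predictions contributes 0
#' (documented zero-denominator convention).
#'
#' @param yTrue,yPred integer labels in `1..K`.
#' @param K number of classes (default `max` of the labels).
#' @param positive optional positive class index; when given, the binary
#'   one-vs-rest precision of that class is used instead of the macro
#'   precision.
#' @return scalar in `[-1, 0]` to minimize.
#' @export
#' @examples
#' precisionFitness(c(1, 1, 2), c(1, 1, 2))  # -1
precisionFitness <- function(yTrue, yPred, K = max(yTrue, yPred),
                             positive = NULL) {
  if (length(yTrue) != length(yPred)) stop("labels must align")
  cm <- confusionMatrix(yTrue, yPred, K)
  prec <- function(c) {
    b <- binarizeClass(cm, c)
    if (b["TP"] + b["FP"] > 0) unname(b["TP"] / (b["TP"] + b["FP"])) else 0
  }
  if (!is.null(positive)) return(-prec(positive))
  -mean(vapply(seq_len(K), prec, numeric(1)))
}
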