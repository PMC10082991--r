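# Shared numeric kernels: activations, softmax, Adam over nested parameter
# lists, gradient clipping. Parameters live in plain nested lists of numeric
# matrices/vectors so optimizer state can mirror their structure.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax and log-softmax, max-shifted for stability.
.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.logSoftmax <- function(z) {
  z <- z - apply(z, 1L, max)
  z - log(rowSums(exp(z)))
}

.zerosLike <- function(p) {
  if (is.list(p)) lapply(p, .zerosLike)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

.paramsAdd <- function(a, b) {
  if (is.list(a)) Map(.paramsAdd, a, b) else a + b
}

.paramsScale <- function(a, s) {
  if (is.list(a)) lapply(a, .paramsScale, s = s) else a * s
}

.sumSquares <- function(p) {
  if (is.list(p)) sum(vapply(p, .sumSquares, 0)) else sum(p * p)
}

.globalNorm <- function(grads) sqrt(.sumSquares(grads))

.clipGrads <- function(grads, maxNorm) {
  if (is.null(maxNorm) || !is.finite(maxNorm)) return(grads)
  nrm <- .globalNorm(grads)
  if (nrm > maxNorm) .paramsScale(grads, maxNorm / nrm) else grads
}

#' Adam optimizer over nested parameter lists
#'
#' @param params nested list of numeric arrays.
#' @return \code{adamInit}: optimizer state; \code{adamStep}: list with
#'   updated \code{params} and \code{opt}.
#' @keywords internal
adamInit <- function(params) {
  list(m = .zerosLike(params), v = .zerosLike(params), t = 0L)
}

#' @rdname adamInit
#' @param grads gradient structure parallel to \code{params}.
#' @param opt state from \code{adamInit}.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @keywords internal
adamStep <- function(params, grads, opt, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  t <- opt$t + 1L
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(rec, p, g, m, v)
      list(p = lapply(r, `[[`, "p"),
           m = lapply(r, `[[`, "m"),
           v = lapply(r, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = t))
}

# Seed scoping: set the RNG locally when a seed is given, restoring the
# caller's stream afterwards so seeded calls do not disturb ambient state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
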