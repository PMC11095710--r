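# Two-state Mk machinery.
#
# States are 0 (single-chromosome) and 1 (fragmented). The rate matrix is
#   Q = [ -q01  q01 ]
#       [  q10 -q10 ]
# and the transition probabilities P(t) = expm(Qt) have the closed form
# used in .mk_pmat(), so no general matrix exponential is needed.

# P(t) as a 2x2 matrix, rows = from-state, cols = to-state
.mk_pmat <- function(q01, q10, t) {
  s <- q01 + q10
  if (s == 0 || t == 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c((q10 + q01 * e) / s, q10 * (1 - e) / s,
           q01 * (1 - e) / s, (q01 + q10 * e) / s),
         2, 2, dimnames = list(c("0", "1"), c("0", "1")))
}

.mk_root_prior <- function(q01, q10, root_prior) {
  if (root_prior == "flat") return(c(0.5, 0.5))
  s <- q01 + q10
  if (s == 0) return(c(0.5, 0.5))
  c(q10, q01) / s
}

# pruning pass: per-node scaled partial likelihoods and log scaling factors
.mk_partials <- function(tree, x, q01, q10) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  L <- matrix(0, n_node, 2)
  L[cbind(seq_len(n_tip), x + 1L)] <- 1
  L[(n_tip + 1):n_node, ] <- 1
  logscale <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge; elen <- po$edge.length
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    P <- .mk_pmat(q01, q10, elen[i])
    L[p, ] <- L[p, ] * as.vector(P %*% L[ch, ])
    if (ch > n_tip) {           # rescale after folding an internal child
      m <- max(L[p, ])
      if (m > 0 && m < 1e-100) { L[p, ] <- L[p, ] / m; logscale <- logscale + log(m) }
    }
  }
  list(L = L, logscale = logscale, postorder = po)
}

#' Log-likelihood of a two-state Mk model
#'
#' Felsenstein pruning with exact 2x2 transition probabilities.
#'
#' @param tree Dated `"phylo"` tree.
#' @param trait Named 0/1 vector over the tips.
#' @param q01,q10 Transition rates per Mya (>= 0).
#' @param root_prior `"flat"` (0.5, 0.5) or `"stationary"`.
#' @return The log-likelihood (finite for valid inputs).
#' @export
mk_loglik <- function(tree, trait, q01, q10, root_prior = "flat") {
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  x <- match_trait(tree, trait)
  pr <- .mk_partials(tree, x, q01, q10)
  root <- length(tree$tip.label) + 1L
  prior <- .mk_root_prior(q01, q10, root_prior)
  lik <- sum(prior * pr$L[root, ])
  ll <- log(lik) + pr$logscale
  if (is.nan(ll)) stop("internal error: NaN log-likelihood")
  ll
}

#' Fit a two-state Mk model by maximum likelihood
#'
#' Model classes: `"ER"` (q01 = q10, one free rate), `"ARD"` (two free
#' rates), `"USR"` (irreversible, q10 = 0, one free rate). Optimization is
#' on the log-rate scale from several deterministic starting points; the
#' free-parameter count `k` is 1 (ER), 2 (ARD) and 1 (USR). Setting
#' `compat_k = TRUE` reports the USR information criteria with `k = 2`
#' (counting the structurally fixed rate), a convention some published
#' analyses use.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"`, `"ARD"` or `"USR"`.
#' @param compat_k Report USR criteria with `k = 2`.
#' @return An object of class `"mk_fit"`: rates, `logL`, `k`, `n`, `AIC`,
#'   `AICc`.
#' @export
fit_mk <- function(tree, trait, model = c("ER", "ARD", "USR"),
                   root_prior = "flat", compat_k = FALSE) {
  model <- match.arg(model)
  x <- match_trait(tree, trait)
  n <- length(tree$tip.label)
  lo <- log(1e-9); hi <- log(1e3)
  if (model %in% c("ER", "USR")) {
    f <- function(lq) {
      q <- exp(lq)
      -mk_loglik(tree, trait,
                 q01 = q, q10 = if (model == "ER") q else 0,
                 root_prior = root_prior)
    }
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-10)
    # polish around the optimum from a few deterministic brackets
    for (st in c(-4, -2, 0, 2)) {
      o2 <- stats::optimize(f, c(opt$minimum + st - 1, opt$minimum + st + 1),
                            tol = 1e-10)
      if (o2$objective < opt$objective) opt <- o2
    }
    q <- exp(opt$minimum)
    rates <- if (model == "ER") c(q01 = q, q10 = q) else c(q01 = q, q10 = 0)
    logL <- -opt$objective
    k <- 1L
  } else {
    f <- function(lq) -mk_loglik(tree, trait, exp(lq[1]), exp(lq[2]),
                                 root_prior = root_prior)
    starts <- list(c(-3, -3), c(-1, -1), c(-3, -6), c(-6, -3), c(0, 0))
    best <- NULL
    for (st in starts) {
      o <- try(stats::optim(st, f, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(factr = 1e4)), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("optimizer failed to converge from all starts")
    rates <- c(q01 = exp(best$par[1]), q10 = exp(best$par[2]))
    logL <- -best$value
    k <- 2L
  }
  k_used <- if (model == "USR" && compat_k) 2L else k
  aic <- aic_from_loglik(logL, k_used)
  structure(list(model = model, q01 = unname(rates["q01"]),
                 q10 = unname(rates["q10"]), logL = logL,
                 k = k_used, n = n, AIC = aic,
                 AICc = aicc_from_aic(aic, k_used, n),
                 root_prior = root_prior),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk %s fit: q01 = %.6g, q10 = %.6g\n", x$model, x$q01, x$q10))
  cat(sprintf("  logL = %.4f, k = %d, n = %d, AIC = %.4f, AICc = %.4f\n",
              x$logL, x$k, x$n, x$AIC, x$AICc))
  invisible(x)
}

#' Information criteria helpers
#'
#' `AIC = 2k - 2 logL`; `AICc = AIC + 2k(k+1)/(n-k-1)` with `n` the number
#' of tips; `aic_weights` normalizes `exp(-dAICc/2)` over a model set.
#'
#' @param logL Log-likelihood.
#' @param k Free-parameter count.
#' @param n Sample size (tips).
#' @param aic AIC value.
#' @param ic Vector of information-criterion values (lower is better).
#' @export
aic_from_loglik <- function(logL, k) 2 * k - 2 * logL

#' @rdname aic_from_loglik
#' @export
aicc_from_aic <- function(aic, k, n) {
  if (any(n - k - 1 <= 0)) stop("AICc undefined: n - k - 1 <= 0")
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aic_from_loglik
#' @export
aic_weights <- function(ic) {
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and compare a set of Mk models
#'
#' Fits each model class, ranks by AICc and reports Akaike weights over the
#' declared set.
#'
#' @inheritParams fit_mk
#' @param models Character vector of model classes.
#' @return A `data.frame` (one row per model) with rates, `logL`, `k`,
#'   `AIC`, `AICc` and `weight`, plus attribute `"fits"` holding the
#'   individual `mk_fit` objects.
#' @export
fit_mk_set <- function(tree, trait, models = c("ER", "ARD", "USR"),
                       root_prior = "flat", compat_k = FALSE) {
  fits <- lapply(models, function(m)
    fit_mk(tree, trait, m, root_prior = root_prior, compat_k = compat_k))
  tab <- data.frame(
    model = models,
    q01 = vapply(fits, `[[`, numeric(1), "q01"),
    q10 = vapply(fits, `[[`, numeric(1), "q10"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    k = vapply(fits, `[[`, integer(1), "k"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"))
  tab$weight <- aic_weights(tab$AICc)
  attr(tab, "fits") <- stats::setNames(fits, models)
  tab
}
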