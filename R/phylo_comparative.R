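# Phylogenetic signal (Pagel's lambda, Blomberg's K), comparative model
# fitting (BM / OU / EB / white noise) with AICc selection, maximum
# likelihood ancestral reconstruction of a continuous trait, and the
# TE-load / genome-size correlations.
#
# All Gaussian fits profile the root state z0 and the rate sigma^2
# analytically (GLS); only the shape parameter (lambda, alpha or a) is
# optimised numerically, deterministically, over a fixed bracket.

#' Pair a timetree with a continuous tip trait
#'
#' @param tree a `timetree`, an `ape` phylo, or a Newick string.
#' @param trait named numeric vector; names must cover all tip labels.
#' @return object of class `trait_tree`: list with `tree` (phylo), `trait`
#'   (ordered as the tip labels), `vcv` (phylogenetic covariance: shared
#'   path lengths), `height`, `n`.
#' @export
trait_tree <- function(tree, trait) {
  tt <- if (inherits(tree, "timetree")) tree
        else if (inherits(tree, "phylo")) timetree_from_phylo(tree)
        else read_newick_timetree(tree)
  tips <- tt$tree$tip.label
  if (!all(tips %in% names(trait)))
    stop("trait missing for tips: ",
         paste(setdiff(tips, names(trait)), collapse = ", "))
  z <- trait[tips]
  C <- ape::vcv.phylo(tt$tree)
  structure(list(tree = tt$tree, trait = z, vcv = C,
                 height = tt$height, n = length(tips),
                 timetree = tt), class = "trait_tree")
}

#' Pearson correlation with a two-sided t test
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# Profiled Gaussian likelihood on covariance structure M (V = sigma2 * M):
# z0 = (1' M^-1 z) / (1' M^-1 1), sigma2 = (z - z0)' M^-1 (z - z0) / n.
.gls_profile <- function(M, z) {
  n <- length(z)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  L1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  Lz <- backsolve(ch, z, transpose = TRUE)
  z0 <- sum(L1 * Lz) / sum(L1 * L1)
  r <- backsolve(ch, z - z0, transpose = TRUE)
  sigma2 <- sum(r * r) / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  logdet <- 2 * sum(log(diag(ch)))
  logL <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(z0 = z0, sigma2 = sigma2, logL = logL)
}

.lambda_cov <- function(C, lambda) {
  M <- C * lambda
  diag(M) <- diag(C)
  M
}

#' Pagel's lambda by maximum likelihood
#'
#' The off-diagonal phylogenetic covariances are scaled by `lambda`, which
#' is optimised over `[0, lambda_max]` where
#' `lambda_max = height / tallest internal node height` (so the rescaled
#' covariance stays valid; on trees with short deep branches the estimate
#' can exceed 1). The p-value is a likelihood-ratio test against
#' `lambda = 0` on one degree of freedom.
#'
#' @param tt a [trait_tree()].
#' @return list of class `signal_result`: `statistic = "lambda"`,
#'   `estimate`, `lambda_max`, `logL`, `logL0`, `p_value`, `degenerate`
#'   (TRUE on a star tree, where the likelihood is flat in lambda).
#' @export
pagel_lambda <- function(tt) {
  stopifnot(inherits(tt, "trait_tree"), tt$n >= 4)
  C <- tt$vcv
  z <- tt$trait
  off <- C[row(C) != col(C)]
  t_max <- if (length(off)) max(off) else 0
  if (t_max <= 1e-12 * tt$height) {
    g <- .gls_profile(.lambda_cov(C, 0), z)
    return(structure(list(statistic = "lambda", estimate = 0,
                          lambda_max = Inf, logL = g$logL, logL0 = g$logL,
                          p_value = 1, degenerate = TRUE),
                     class = "signal_result"))
  }
  lambda_max <- tt$height / t_max
  nll <- function(lam) {
    g <- .gls_profile(.lambda_cov(C, lam), z)
    if (is.null(g)) return(1e10)
    -g$logL
  }
  opt <- stats::optimize(nll, c(0, lambda_max), tol = 1e-8)
  cand <- rbind(c(opt$minimum, opt$objective),
                c(0, nll(0)), c(lambda_max, nll(lambda_max)))
  best <- cand[which.min(cand[, 2]), ]
  logL <- -best[2]
  logL0 <- -nll(0)
  p <- stats::pchisq(2 * max(0, logL - logL0), df = 1, lower.tail = FALSE)
  structure(list(statistic = "lambda", estimate = unname(best[1]),
                 lambda_max = lambda_max, logL = logL, logL0 = logL0,
                 p_value = p, degenerate = FALSE),
            class = "signal_result")
}

#' Blomberg's K with a permutation test
#'
#' `K = (MSE0 / MSE) observed / (MSE0 / MSE) expected under BM`, where the
#' mean is the phylogenetically corrected `a = (1' C^-1 z) / (1' C^-1 1)`,
#' `MSE0 = sum((z - a)^2) / (n - 1)`, `MSE = (z - a)' C^-1 (z - a)/(n - 1)`
#' and the BM expectation of the ratio is
#' `(tr(C) - n / (1' C^-1 1)) / (n - 1)`. The p-value is the fraction of
#' tip permutations whose `MSE0 / MSE` is at least the observed one.
#'
#' @param tt a [trait_tree()].
#' @param n_perm number of permutations (0 skips the test).
#' @param seed optional seed for the permutation generator.
#' @return list of class `signal_result` with `estimate` (K), `p_value`
#'   (`NA` when `n_perm = 0`), `n_permutations`.
#' @export
blomberg_k <- function(tt, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(tt, "trait_tree"), tt$n >= 4)
  C <- tt$vcv
  z <- tt$trait
  n <- tt$n
  Cinv <- solve(C)
  ones <- rep(1, n)
  denom1 <- drop(ones %*% Cinv %*% ones)
  expected <- (sum(diag(C)) - n / denom1) / (n - 1)
  ratio <- function(zz) {
    a <- drop(ones %*% Cinv %*% zz) / denom1
    mse0 <- sum((zz - a)^2) / (n - 1)
    mse <- drop(t(zz - a) %*% Cinv %*% (zz - a)) / (n - 1)
    mse0 / mse
  }
  obs <- ratio(z)
  K <- obs / expected
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) ratio(sample(z)), numeric(1))
    p <- mean(perm >= obs)
  }
  structure(list(statistic = "K", estimate = K, p_value = p,
                 n_permutations = n_perm), class = "signal_result")
}

# Covariance structure (up to sigma2) for each comparative model.
.model_cov <- function(C, height, model, par = NULL) {
  switch(model,
    BM = C,
    WN = diag(nrow(C)),
    EB = {
      a <- par
      if (abs(a) < 1e-15) C else expm1(a * C) / a
    },
    OU = {
      alpha <- par
      D <- height - C   # time since the MRCA of each pair
      exp(-2 * alpha * D) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
    },
    stop("unknown model: ", model))
}

#' AICc from a log-likelihood
#' @param logL log-likelihood.
#' @param k number of parameters.
#' @param n number of observations.
#' @return small-sample corrected AIC.
#' @export
aicc <- function(logL, k, n) {
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a comparative model of continuous trait evolution
#'
#' Maximum likelihood fits of Brownian motion (BM), a stationary
#' Ornstein-Uhlenbeck process (OU), Early-Burst (EB: the Brownian rate
#' decays as `exp(a t)` with `a <= 0`), and white noise (WN). `sigma2` and
#' the root state `z0` are profiled analytically; `alpha` (OU) or `a` (EB)
#' is optimised over a fixed bracket split into five segments, which makes
#' the fit deterministic. Parameter counts are 2 (BM, WN) or 3 (OU, EB).
#'
#' @param tt a [trait_tree()].
#' @param model one of `"BM"`, `"OU"`, `"EB"`, `"WN"`.
#' @return list of class `model_fit` with `model`, `sigma2`, `z0`, `alpha`
#'   or `a` where applicable, `logL`, `k_params`, `n`, `AICc`.
#' @export
fit_continuous <- function(tt, model = c("BM", "OU", "EB", "WN")) {
  model <- match.arg(model)
  stopifnot(inherits(tt, "trait_tree"))
  C <- tt$vcv
  z <- tt$trait
  n <- tt$n
  h <- tt$height
  par <- NULL
  if (model %in% c("BM", "WN")) {
    g <- .gls_profile(.model_cov(C, h, model), z)
    if (is.null(g)) stop(model, " fit failed: singular covariance")
    k <- 2L
  } else {
    if (model == "EB") {
      lo <- -10 / h; hi <- -1e-8
      transf <- identity
    } else {
      lo <- log(1e-6 / h); hi <- log(50 / h)
      transf <- exp
    }
    nll <- function(x) {
      g <- .gls_profile(.model_cov(C, h, model, transf(x)), z)
      if (is.null(g)) return(1e10)
      -g$logL
    }
    cuts <- seq(lo, hi, length.out = 6)
    best <- NULL
    for (s in seq_len(5)) {
      o <- stats::optimize(nll, c(cuts[s], cuts[s + 1]), tol = 1e-8)
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    for (edge in c(lo, hi)) {
      v <- nll(edge)
      if (v < best$objective) best <- list(minimum = edge, objective = v)
    }
    if (!is.finite(best$objective) || best$objective >= 1e10)
      stop(model, " fit did not converge (singular covariance throughout)")
    par <- transf(best$minimum)
    g <- .gls_profile(.model_cov(C, h, model, par), z)
    k <- 3L
  }
  out <- list(model = model, sigma2 = g$sigma2, z0 = g$z0, logL = g$logL,
              k_params = k, n = n, AICc = aicc(g$logL, k, n))
  if (model == "OU") out$alpha <- par
  if (model == "EB") out$a <- par
  structure(out, class = "model_fit")
}

#' Rescale a tree's branch lengths under the Early-Burst transform
#'
#' A branch segment running from time `t1` to `t2` after the root maps to
#' `(exp(a t2) - exp(a t1)) / a`; BM on the rescaled tree equals EB on the
#' original.
#'
#' @param tree an `ape` phylo.
#' @param a EB exponent (a <= 0; `a = 0` returns the tree unchanged).
#' @return the rescaled phylo.
#' @export
eb_rescale_tree <- function(tree, a) {
  if (abs(a) < 1e-12) return(tree)
  depth <- ape::node.depth.edgelength(tree)
  t1 <- depth[tree$edge[, 1]]
  t2 <- depth[tree$edge[, 2]]
  tree$edge.length <- (exp(a * t2) - exp(a * t1)) / a
  tree
}

#' Maximum likelihood ancestral states for a continuous trait
#'
#' Under BM the joint ML ancestral states solve a sparse linear system
#' (each internal node is the branch-length-weighted average of its
#' neighbours); an EB fit is handled by rescaling the branches with
#' [eb_rescale_tree()] first. Each branch is labelled `expansion` when the
#' child value exceeds the parent value, `reduction` when below, and
#' `no_change` on exact ties.
#'
#' @param tt a [trait_tree()].
#' @param fit a [fit_continuous()] result of model `"BM"` or `"EB"`
#'   (default: a fresh BM fit).
#' @return list of class `ancestral_states`: `node_states` (named by node
#'   number), `branches` (data.frame `parent`, `child`, `child_label`,
#'   `parent_value`, `child_value`, `direction`), `model`.
#' @export
ancestral_ml <- function(tt, fit = fit_continuous(tt, "BM")) {
  stopifnot(inherits(tt, "trait_tree"))
  if (!fit$model %in% c("BM", "EB"))
    stop("ancestral reconstruction supports BM or EB fits")
  tree <- if (fit$model == "EB") eb_rescale_tree(tt$tree, fit$a) else tt$tree
  z <- tt$trait
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  eps <- 1e-12 * max(1, sum(tree$edge.length))
  w <- 1 / pmax(tree$edge.length, eps)
  A <- matrix(0, nnode, nnode)
  b <- numeric(nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - ntip
    ch <- tree$edge[e, 2]
    A[p, p] <- A[p, p] + w[e]
    if (ch > ntip) {
      cc <- ch - ntip
      A[cc, cc] <- A[cc, cc] + w[e]
      A[p, cc] <- A[p, cc] - w[e]
      A[cc, p] <- A[cc, p] - w[e]
    } else {
      b[p] <- b[p] + w[e] * z[tree$tip.label[ch]]
    }
  }
  x <- solve(A, b)
  node_states <- stats::setNames(x, ntip + seq_len(nnode))
  val_of <- function(node) {
    if (node <= ntip) unname(z[tree$tip.label[node]])
    else unname(node_states[as.character(node)])
  }
  pv <- vapply(tt$tree$edge[, 1], val_of, numeric(1))
  cv <- vapply(tt$tree$edge[, 2], val_of, numeric(1))
  branches <- data.frame(
    parent = tt$tree$edge[, 1], child = tt$tree$edge[, 2],
    child_label = ifelse(tt$tree$edge[, 2] <= ntip,
                         tt$tree$tip.label[tt$tree$edge[, 2]],
                         as.character(tt$tree$edge[, 2])),
    parent_value = pv, child_value = cv,
    direction = {
      tol <- 1e-8 * (1 + max(abs(c(pv, cv))))
      ifelse(cv - pv > tol, "expansion",
             ifelse(pv - cv > tol, "reduction", "no_change"))
    },
    stringsAsFactors = FALSE)
  structure(list(node_states = node_states, branches = branches,
                 model = fit$model), class = "ancestral_states")
}
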