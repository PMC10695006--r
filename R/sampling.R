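# Latent-space generation strategies: prior sampling, repeated
# reconstruction of one cage, lerp/slerp interpolation, and Bayesian
# optimisation of a negative-log-likelihood acquisition inside the
# training-latent bounding box.

#' Sample latent vectors from the standard-normal prior
#'
#' @param n number of vectors (>= 1).
#' @param latent_dim latent dimensionality.
#' @param rng_seed optional seed.
#' @return `n x latent_dim` matrix of i.i.d. N(0, 1) draws.
#' @export
sample_prior <- function(n, latent_dim, rng_seed = NULL) {
  stopifnot(n >= 1, latent_dim >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  matrix(stats::rnorm(n * latent_dim), n, latent_dim)
}

#' Repeated stochastic reconstruction of a single cage
#'
#' Encodes the record once, draws `n_samples` latent samples from its
#' posterior and greedily decodes each. Decoded cages are tallied and
#' sorted by frequency, with the mean Euclidean distance of their latent
#' samples from the posterior mean.
#'
#' @param model a trained `poc_vae`.
#' @param record a single-row `cage_records`.
#' @param n_samples number of reconstructions.
#' @param rng_seed seed.
#' @param clamp_log_variance optional fixed log-variance overriding the
#'   posterior's (e.g. a very negative value for the zero-noise limit).
#' @return data.frame with `bb1_id`, `bb2_smiles`, `reaction_id`, `count`,
#'   `mean_latent_distance`, sorted by decreasing count.
#' @export
reconstruct_repeated <- function(model, record, n_samples = 1000L,
                                 rng_seed = 1L,
                                 clamp_log_variance = NULL) {
  stopifnot(nrow(record) == 1L)
  post <- encode(model, record)
  if (!is.null(clamp_log_variance)) {
    post$log_variance[] <- clamp_log_variance
  }
  mu <- post$mean[rep(1L, n_samples), , drop = FALSE]
  lv <- post$log_variance[rep(1L, n_samples), , drop = FALSE]
  z <- reparameterize(list(mean = mu, log_variance = lv), rng_seed)
  dec <- decode_bb2(model, z, mode = "greedy")
  cats <- decode_bb1_reaction(model, z)
  dist <- sqrt(rowSums(sweep(z, 2L, post$mean[1L, ], "-")^2))
  key <- paste(cats$bb1_id, dec$smiles, cats$reaction_id, sep = "|")
  agg <- split(seq_len(n_samples), key)
  out <- do.call(rbind, lapply(agg, function(ii) {
    data.frame(bb1_id = cats$bb1_id[ii[1]],
               bb2_smiles = dec$smiles[ii[1]],
               reaction_id = cats$reaction_id[ii[1]],
               count = length(ii),
               mean_latent_distance = mean(dist[ii]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linear interpolation between two latent vectors
#'
#' @param z0,z1 latent vectors.
#' @param steps number of path points (>= 2), endpoints included.
#' @return an `interp_path`: list with `points` (steps x dim), `t`.
#' @export
lerp <- function(z0, z1, steps) {
  stopifnot(steps >= 2, length(z0) == length(z1))
  tt <- seq(0, 1, length.out = steps)
  pts <- outer(1 - tt, z0) + outer(tt, z1)
  structure(list(points = pts, t = tt, method = "lerp"),
            class = "interp_path")
}

#' Spherical linear interpolation between two latent vectors
#'
#' `sin((1 - t) * Omega) / sin(Omega) * z0 + sin(t * Omega) / sin(Omega) *
#' z1` with `Omega` the angle between the endpoints; falls back to [lerp()]
#' for (anti-)parallel endpoints.
#'
#' @param z0,z1 nonzero latent vectors.
#' @param steps number of path points (>= 2).
#' @param tol angle below which the linear fallback is used.
#' @return an `interp_path`.
#' @export
slerp <- function(z0, z1, steps, tol = 1e-7) {
  stopifnot(steps >= 2, length(z0) == length(z1))
  n0 <- sqrt(sum(z0^2)); n1 <- sqrt(sum(z1^2))
  if (n0 == 0 || n1 == 0) stop("slerp endpoints must be nonzero")
  cosw <- sum(z0 * z1) / (n0 * n1)
  omega <- acos(pmin(pmax(cosw, -1), 1))
  if (omega < tol || abs(pi - omega) < tol) {
    p <- lerp(z0, z1, steps)
    p$method <- "slerp"
    return(p)
  }
  tt <- seq(0, 1, length.out = steps)
  c0 <- sin((1 - tt) * omega) / sin(omega)
  c1 <- sin(tt * omega) / sin(omega)
  pts <- outer(c0, z0) + outer(c1, z1)
  structure(list(points = pts, t = tt, method = "slerp"),
            class = "interp_path")
}

#' Acquisition configuration for latent Bayesian optimisation
#'
#' @param target desired label value; 0 selects shape-persistent
#'   (non-collapsed) cages.
#' @param omega exploration weight on the standard-normal regulariser.
#' @param bounds 2 x latent matrix (rows: min, max), typically from
#'   [latent_bounds()].
#' @return an `acq_config` list.
#' @export
acq_config <- function(target = 0, omega = 0.1, bounds = NULL) {
  stopifnot(target %in% c(0, 1), omega >= 0)
  if (!is.null(bounds)) {
    stopifnot(is.matrix(bounds), nrow(bounds) == 2L,
              all(is.finite(bounds)), all(bounds[2, ] >= bounds[1, ]))
  }
  structure(list(target = target, omega = omega, bounds = bounds),
            class = "acq_config")
}

#' Per-dimension latent bounding box of a record set
#'
#' Minimum and maximum of the posterior means over the given records,
#' the box-constraint used during Bayesian optimisation.
#'
#' @param model a `poc_vae`; @param records `cage_records`.
#' @return 2 x latent matrix (rows: min, max).
#' @export
latent_bounds <- function(model, records) {
  mu <- encode(model, records)$mean
  rbind(min = apply(mu, 2L, min), max = apply(mu, 2L, max))
}

#' Acquisition function for shape-persistent cage search
#'
#' `-log p(y = target | z) + omega * ||z||^2 / 2`; the regulariser is the
#' negative log standard-normal density with its constant dropped. The
#' probability is clamped to `[1e-6, 1 - 1e-6]` so the value is finite
#' everywhere. Minimised during optimisation.
#'
#' @param z a latent vector (or matrix of row vectors).
#' @param predictor function mapping a latent matrix to `P(collapse | z)`;
#'   typically `function(z) predict_persistence(model, z)`.
#' @param config an [acq_config()].
#' @return numeric vector of acquisition values.
#' @export
acquisition <- function(z, predictor, config = acq_config()) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  p_collapse <- predictor(z)
  p_target <- if (config$target == 0) 1 - p_collapse else p_collapse
  p_target <- pmin(pmax(p_target, 1e-6), 1 - 1e-6)
  -log(p_target) + config$omega * rowSums(z^2) / 2
}

# squared-exponential GP regression with median-heuristic lengthscale
.gp_fit <- function(X, y) {
  d2 <- as.matrix(stats::dist(X))^2
  ell2 <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(ell2) || ell2 <= 0) ell2 <- 1
  sf2 <- stats::var(y); if (!is.finite(sf2) || sf2 <= 0) sf2 <- 1
  K <- sf2 * exp(-d2 / (2 * ell2)) + diag(1e-6 * sf2 + 1e-10, nrow(X))
  mu0 <- mean(y)
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, y - mu0, transpose = TRUE))
  list(X = X, y = y, ell2 = ell2, sf2 = sf2, L = L, alpha = alpha,
       mu0 = mu0)
}

.gp_predict <- function(gp, Xs) {
  d2 <- outer(rowSums(Xs^2), rowSums(gp$X^2), "+") -
    2 * Xs %*% t(gp$X)
  Ks <- gp$sf2 * exp(-pmax(d2, 0) / (2 * gp$ell2))
  mu <- gp$mu0 + as.vector(Ks %*% gp$alpha)
  v <- backsolve(gp$L, t(Ks), transpose = TRUE)
  s2 <- pmax(gp$sf2 - colSums(v^2), 1e-12)
  list(mean = mu, sd = sqrt(s2))
}

# expected improvement for minimisation
.gp_ei <- function(gp, Xs, f_best) {
  pr <- .gp_predict(gp, Xs)
  u <- (f_best - pr$mean) / pr$sd
  (f_best - pr$mean) * stats::pnorm(u) + pr$sd * stats::dnorm(u)
}

#' Box-constrained Bayesian optimisation of a latent objective
#'
#' Gaussian-process surrogate (squared-exponential kernel, median
#' lengthscale) with expected-improvement proposals: a Latin-hypercube
#' design seeds the surrogate, each iteration maximises EI over a random
#' candidate cloud refined by L-BFGS-B inside the box, and the incumbent
#' is finally polished by a bounded local descent on the objective itself
#' (counted among the evaluations). All evaluated points lie inside the
#' box.
#'
#' @param fn objective to minimise; takes a latent row-matrix, returns a
#'   numeric vector.
#' @param bounds 2 x d matrix (rows: min, max) with `min < max` per
#'   dimension.
#' @param n_iterations number of surrogate-guided evaluations.
#' @param rng_seed seed.
#' @param n_init size of the initial Latin-hypercube design.
#' @param n_candidates size of the EI candidate cloud per iteration.
#' @param refine polish the incumbent with box-constrained local descent.
#' @return list with `best_x`, `best_value`, and all evaluated `X`, `values`
#'   ranked by increasing objective value.
#' @export
bayes_optimize <- function(fn, bounds, n_iterations = 50L, rng_seed = 1L,
                           n_init = NULL, n_candidates = 256L,
                           refine = TRUE) {
  stopifnot(is.matrix(bounds), nrow(bounds) == 2L)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  if (any(hi <= lo)) stop("degenerate bounds: min == max on a dimension")
  d <- length(lo)
  set.seed(rng_seed)
  if (is.null(n_init)) n_init <- max(5L, 2L * d)
  X <- sweep(sweep(lhs::randomLHS(n_init, d), 2L, hi - lo, "*"),
             2L, lo, "+")
  y <- as.vector(fn(X))
  for (it in seq_len(n_iterations)) {
    gp <- .gp_fit(X, y)
    f_best <- min(y)
    cand <- sweep(sweep(matrix(stats::runif(n_candidates * d),
                               n_candidates, d), 2L, hi - lo, "*"),
                  2L, lo, "+")
    ei <- .gp_ei(gp, cand, f_best)
    x0 <- cand[which.max(ei), ]
    opt <- stats::optim(x0, function(x) {
      -.gp_ei(gp, matrix(x, 1L), f_best)
    }, method = "L-BFGS-B", lower = lo, upper = hi,
    control = list(maxit = 30L))
    xn <- pmin(pmax(opt$par, lo), hi)
    X <- rbind(X, xn)
    y <- c(y, as.vector(fn(matrix(xn, 1L))))
  }
  if (refine) {
    x0 <- X[which.min(y), ]
    opt <- stats::optim(x0, function(x) as.vector(fn(matrix(x, 1L))),
                        method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = 100L))
    xr <- pmin(pmax(opt$par, lo), hi)
    X <- rbind(X, xr)
    y <- c(y, as.vector(fn(matrix(xr, 1L))))
  }
  ord <- order(y)
  rownames(X) <- NULL
  list(best_x = X[ord[1], ], best_value = y[ord[1]],
       X = X[ord, , drop = FALSE], values = y[ord])
}

#' Conditional cage generation by latent Bayesian optimisation
#'
#' Minimises the [acquisition()] for shape-persistent cages inside the
#' training-latent box and decodes every evaluated latent point, ranked by
#' acquisition value.
#'
#' @param model a trained `poc_vae`.
#' @param config an [acq_config()] with non-NULL `bounds`.
#' @param n_iterations surrogate-guided evaluations.
#' @param rng_seed seed.
#' @return data.frame of decoded candidates with `p_collapse` and
#'   `acquisition`, best first.
#' @export
optimize_generate <- function(model, config, n_iterations = 50L,
                              rng_seed = 1L) {
  stopifnot(inherits(config, "acq_config"), !is.null(config$bounds))
  fn <- function(z) {
    acquisition(z, function(zz) predict_persistence(model, zz), config)
  }
  bo <- bayes_optimize(fn, config$bounds, n_iterations = n_iterations,
                       rng_seed = rng_seed)
  dec <- decode_bb2(model, bo$X, mode = "greedy")
  cats <- decode_bb1_reaction(model, bo$X)
  data.frame(bb1_id = cats$bb1_id,
             bb2_smiles = dec$smiles,
             reaction_id = cats$reaction_id,
             p_collapse = predict_persistence(model, bo$X),
             acquisition = bo$values,
             source_strategy = "optimize",
             stringsAsFactors = FALSE)
}

#' Conditional cage generation along a slerp path
#'
#' Interpolates spherically between the posterior means of two cages,
#' decodes every path point, and keeps candidates whose predicted
#' probability of shape persistence (`1 - p_collapse`) reaches the
#' threshold. The start record itself must meet the threshold (only
#' checked for attainable thresholds, i.e. `threshold <= 1`).
#'
#' @param start_record,end_record single-row `cage_records`.
#' @param model a trained `poc_vae`.
#' @param threshold shape-persistence probability cutoff (default 0.8).
#' @param steps number of path points.
#' @return data.frame of retained candidates (`t`, decoded components,
#'   `p_persist`); attribute `path` carries all decoded points.
#' @export
interpolation_generate <- function(start_record, end_record, model,
                                   threshold = 0.8, steps = 10L) {
  z0 <- encode(model, start_record)$mean[1L, ]
  z1 <- encode(model, end_record)$mean[1L, ]
  p_start <- 1 - predict_persistence(model, matrix(z0, 1L))
  if (threshold <= 1 && p_start < threshold) {
    stop(sprintf(
      "start record fails the persistence threshold (%.3f < %.3f)",
      p_start, threshold))
  }
  path <- slerp(z0, z1, steps)
  dec <- decode_bb2(model, path$points, mode = "greedy")
  cats <- decode_bb1_reaction(model, path$points)
  p_persist <- 1 - predict_persistence(model, path$points)
  all_pts <- data.frame(t = path$t,
                        bb1_id = cats$bb1_id,
                        bb2_smiles = dec$smiles,
                        reaction_id = cats$reaction_id,
                        p_persist = p_persist,
                        source_strategy = "interpolate",
                        stringsAsFactors = FALSE)
  out <- all_pts[all_pts$p_persist >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "path") <- all_pts
  out
}
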