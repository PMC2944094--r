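#' Fit the Besag-York-Mollie spatial model by MCMC
#'
#' The BYM convolution model for area relative risks:
#' \eqn{O_i \sim Poisson(E_i RR_i)}, \eqn{\log RR_i = \mu + u_i + v_i},
#' with \eqn{u} an intrinsic conditional autoregressive (ICAR) spatially
#' structured effect on the adjacency graph, \eqn{v_i \sim N(0,
#' \tau_v^{-1})} unstructured, a flat prior on \eqn{\mu} and gamma
#' hyperpriors on the precisions. Smooths risk toward the local
#' (neighbourhood) mean, in contrast to the global-mean shrinkage of
#' \code{\link{ebPoissonGamma}}.
#'
#' Sampling is Metropolis-within-Gibbs: random-walk Metropolis for
#' \eqn{\mu}, each \eqn{u_i} and each \eqn{v_i} against the Poisson
#' likelihood, with conjugate Gibbs draws for \eqn{\tau_u} (from the ICAR
#' pairwise-difference quadratic form, with rank correction for the number
#' of connected components) and \eqn{\tau_v}. Structured effects are updated
#' in conditionally independent blocks given by a greedy graph colouring, so
#' each block is vectorised without breaking detailed balance, and \eqn{u}
#' is recentred to sum to zero within each connected component after every
#' sweep (for a single component the removed mean is absorbed into
#' \eqn{\mu}, leaving the fitted risks untouched). Isolated areas have
#' \eqn{u_i \equiv 0}. Random-walk scales adapt during burn-in toward
#' 30-50\% acceptance and are frozen afterwards. Areas with \eqn{E_i \le 0}
#' are excluded from the fit and reported as missing.
#'
#' @param O Per-area observed counts (or, for the Gaussian test harness,
#'   observations \eqn{y_i}).
#' @param E Per-area expected counts.
#' @param adjacency An \code{\link{buildAdjacency}} adjacency object over
#'   the same areas, in order.
#' @param n_iter,n_burn,thin Total sweeps, burn-in sweeps discarded, and
#'   thinning of the retained chain. Defaults 11000/1000/5 give 2000
#'   retained samples.
#' @param priors List with elements \code{tau_u} and \code{tau_v}, each
#'   \code{c(shape, rate)} of the gamma hyperprior. The default
#'   Gamma(0.5, 0.0005) is the conventional weakly-informative choice for
#'   log-relative-risk precisions.
#' @param seed Integer seed (mandatory): identical seed and inputs give
#'   bitwise-identical chains.
#' @param family \code{"poisson"} for the BYM model; \code{"normal"} swaps
#'   in a Gaussian likelihood \eqn{y_i \sim N(\mu + u_i + v_i,
#'   1/prec_i)} so the sampler can be validated against closed-form
#'   posterior moments (test harness).
#' @param obs_prec Per-area observation precisions (normal family only).
#' @param fix_tau Optional \code{c(tau_u, tau_v)} to hold the precisions
#'   fixed instead of Gibbs sampling them.
#' @return An object of class \code{bym_fit}: retained samples
#'   (\code{rr} matrix, \code{mu}, \code{tau_u}, \code{tau_v}), posterior
#'   mean RR per area, Monte-Carlo standard errors (batch means),
#'   acceptance rates, and bookkeeping.
#' @references Model: the convolution prior of Besag, York and Mollie for
#'   disease mapping.
#' @export
bymFit <- function(O, E, adjacency, n_iter = 11000, n_burn = 1000,
                   thin = 5, priors = list(tau_u = c(0.5, 0.0005),
                                           tau_v = c(0.5, 0.0005)),
                   seed, family = c("poisson", "normal"),
                   obs_prec = NULL, fix_tau = NULL) {
  family <- match.arg(family)
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory for reproducible chains", call. = FALSE)
  stopifnot(inherits(adjacency, "adjacency"),
            length(O) == length(adjacency$area_id),
            length(E) == length(O))
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn", call. = FALSE)
  if (any(vapply(priors, function(p) any(p <= 0), TRUE)))
    stop("non-positive prior parameters", call. = FALSE)
  set.seed(as.integer(seed))

  full_n <- length(O)
  ok <- if (family == "poisson") is.finite(E) & E > 0 else rep(TRUE, full_n)
  if (any(!ok))
    warning("areas with non-positive expected counts excluded from the ",
            "BYM fit: ", paste(adjacency$area_id[!ok], collapse = ", "),
            call. = FALSE)
  idx_map <- which(ok)
  n <- length(idx_map)
  o <- as.numeric(O[ok]); e <- as.numeric(E[ok])
  prec <- if (family == "normal") {
    if (is.null(obs_prec)) stop("obs_prec required for the normal family",
                                call. = FALSE)
    as.numeric(obs_prec[ok])
  } else NULL

  # adjacency restricted to the included areas
  nb <- lapply(adjacency$neighbours[ok], function(js)
    match(js[js %in% idx_map], idx_map))
  deg <- vapply(nb, length, integer(1))
  g <- .adj_igraph(structure(list(area_id = as.character(seq_len(n)),
                                  neighbours = nb), class = "adjacency"))
  comp <- igraph::components(g)$membership
  island <- deg == 0L
  if (any(island))
    warning("areas with no neighbours get u = 0 (no spatial smoothing): ",
            paste(adjacency$area_id[idx_map][island], collapse = ", "),
            call. = FALSE)
  single_comp <- length(unique(comp[!island])) == 1L && !any(island)
  col <- as.integer(igraph::greedy_vertex_coloring(g))
  col_groups <- split(seq_len(n)[!island], col[!island])
  Wm <- matrix(0, n, n)
  for (i in seq_len(n)) if (length(nb[[i]])) Wm[i, nb[[i]]] <- 1
  edges <- which(upper.tri(Wm) & Wm == 1, arr.ind = TRUE)
  icar_rank <- sum(!island) - length(unique(comp[!island]))

  loglik_eta <- if (family == "poisson") {
    function(eta, i) o[i] * eta - e[i] * exp(eta)
  } else {
    function(eta, i) -prec[i] / 2 * (o[i] - eta)^2
  }

  # state
  mu <- if (family == "poisson") log(max(sum(o), 0.5) / sum(e))
        else mean(o)
  u <- numeric(n); v <- numeric(n)
  tau_u <- if (!is.null(fix_tau)) fix_tau[1] else 10
  tau_v <- if (!is.null(fix_tau)) fix_tau[2] else 10

  s_mu <- 0.1; s_u <- 0.5; s_v <- 0.5
  acc <- c(mu = 0, u = 0, v = 0); prop <- c(mu = 0, u = 0, v = 0)
  acc_win <- c(mu = 0, u = 0, v = 0); prop_win <- c(mu = 0, u = 0, v = 0)

  n_keep <- floor((n_iter - n_burn) / thin)
  rr_s <- matrix(NA_real_, n_keep, n)
  mu_s <- numeric(n_keep); tu_s <- numeric(n_keep); tv_s <- numeric(n_keep)
  keep_at <- n_burn + thin * seq_len(n_keep)
  k <- 0L
  all_i <- seq_len(n)

  for (it in seq_len(n_iter)) {
    # mu: scalar random walk
    mu_p <- mu + s_mu * stats::rnorm(1)
    dlp <- sum(loglik_eta(mu_p + u + v, all_i)) -
      sum(loglik_eta(mu + u + v, all_i))
    prop["mu"] <- prop["mu"] + 1; prop_win["mu"] <- prop_win["mu"] + 1
    if (log(stats::runif(1)) < dlp) {
      mu <- mu_p
      acc["mu"] <- acc["mu"] + 1; acc_win["mu"] <- acc_win["mu"] + 1
    }

    # u: vectorised random walk within conditionally independent colour
    # blocks; ICAR full conditional u_i ~ N(mean of neighbours, 1/(tau_u d_i))
    for (grp in col_groups) {
      su <- as.vector(Wm[grp, , drop = FALSE] %*% u)
      u_p <- u[grp] + s_u * stats::rnorm(length(grp))
      dll <- loglik_eta(mu + u_p + v[grp], grp) -
        loglik_eta(mu + u[grp] + v[grp], grp)
      dpr <- -tau_u / 2 * (deg[grp] * (u_p^2 - u[grp]^2) -
                             2 * su * (u_p - u[grp]))
      take <- log(stats::runif(length(grp))) < dll + dpr
      u[grp[take]] <- u_p[take]
      prop["u"] <- prop["u"] + length(grp)
      prop_win["u"] <- prop_win["u"] + length(grp)
      acc["u"] <- acc["u"] + sum(take)
      acc_win["u"] <- acc_win["u"] + sum(take)
    }

    # v: all conditionally independent, one vectorised block
    v_p <- v + s_v * stats::rnorm(n)
    dlp_v <- loglik_eta(mu + u + v_p, all_i) -
      loglik_eta(mu + u + v, all_i) - tau_v / 2 * (v_p^2 - v^2)
    take <- log(stats::runif(n)) < dlp_v
    v[take] <- v_p[take]
    prop["v"] <- prop["v"] + n; prop_win["v"] <- prop_win["v"] + n
    acc["v"] <- acc["v"] + sum(take); acc_win["v"] <- acc_win["v"] + sum(take)

    # recentre u (sum-to-zero per component); single component: absorb
    # the shift into mu so fitted risks are unchanged
    if (single_comp) {
      ubar <- mean(u)
      mu <- mu + ubar
      u <- u - ubar
    } else if (any(!island)) {
      for (cc in unique(comp[!island])) {
        sel <- !island & comp == cc
        u[sel] <- u[sel] - mean(u[sel])
      }
    }

    # conjugate Gibbs draws for the precisions
    if (is.null(fix_tau)) {
      if (nrow(edges)) {
        q_u <- sum((u[edges[, 1]] - u[edges[, 2]])^2)
        tau_u <- stats::rgamma(1, priors$tau_u[1] + icar_rank / 2,
                               priors$tau_u[2] + q_u / 2)
      }
      tau_v <- stats::rgamma(1, priors$tau_v[1] + n / 2,
                             priors$tau_v[2] + sum(v^2) / 2)
    }

    # adapt proposal scales during burn-in only
    if (it <= n_burn && it %% 100 == 0) {
      r <- acc_win / pmax(prop_win, 1)
      adj <- function(s, rate) {
        if (rate < 0.3) s * 0.7 else if (rate > 0.5) s * 1.4 else s
      }
      s_mu <- adj(s_mu, r["mu"]); s_u <- adj(s_u, r["u"])
      s_v <- adj(s_v, r["v"])
      acc_win[] <- 0; prop_win[] <- 0
    }

    if (k < n_keep && it == keep_at[k + 1L]) {
      k <- k + 1L
      rr_s[k, ] <- exp(mu + u + v)
      mu_s[k] <- mu; tu_s[k] <- tau_u; tv_s[k] <- tau_v
    }
  }

  # expand to the full area set (NA for excluded areas)
  rr_full <- matrix(NA_real_, n_keep, full_n)
  rr_full[, idx_map] <- rr_s
  colnames(rr_full) <- adjacency$area_id
  pm <- colMeans(rr_full)
  mcse <- apply(rr_full, 2, .batch_mcse)
  structure(list(samples = list(rr = rr_full, mu = mu_s, tau_u = tu_s,
                                tau_v = tv_s),
                 posterior_mean_rr = pm, mcse = mcse,
                 acceptance = acc / pmax(prop, 1),
                 area_id = adjacency$area_id, included = ok,
                 n_iter = n_iter, n_burn = n_burn, thin = thin,
                 seed = as.integer(seed), family = family),
            class = "bym_fit")
}

.batch_mcse <- function(x, n_batch = 20) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  m <- floor(length(x) / n_batch)
  if (m < 2) return(stats::sd(x) / sqrt(length(x)))
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], m))
  stats::sd(bm) / sqrt(n_batch)
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf(
    "BYM fit: %d areas (%d excluded), %d retained samples (%d sweeps, burn %d, thin %d), seed %d\n",
    length(x$area_id), sum(!x$included), nrow(x$samples$rr), x$n_iter,
    x$n_burn, x$thin, x$seed))
  cat(sprintf("  acceptance: mu %.2f, u %.2f, v %.2f; posterior mean RR in [%.3f, %.3f]\n",
              x$acceptance["mu"], x$acceptance["u"], x$acceptance["v"],
              min(x$posterior_mean_rr, na.rm = TRUE),
              max(x$posterior_mean_rr, na.rm = TRUE)))
  invisible(x)
}

#' Posterior exceedance probabilities
#'
#' The posterior probability of an excess risk, \eqn{Pr(RR_i > threshold |
#' data)}, estimated as the fraction of retained MCMC samples above the
#' threshold.
#'
#' @param fit A \code{\link{bymFit}} result, or a samples matrix (retained
#'   draws in rows, areas in columns).
#' @param threshold Risk threshold, default 1.
#' @return Named numeric vector of exceedance probabilities in [0, 1]
#'   (\code{NA} for excluded areas).
#' @export
exceedanceProb <- function(fit, threshold = 1) {
  s <- if (inherits(fit, "bym_fit")) fit$samples$rr else as.matrix(fit)
  if (nrow(s) < 100)
    stop("need at least 100 retained samples", call. = FALSE)
  colMeans(s > threshold)
}

#' Classify areas by posterior risk
#'
#' The decision rule for exceedance maps: an area is \code{elevated} when
#' its posterior mean relative risk exceeds 1 and the exceedance
#' probability exceeds \code{hi} (so an excess risk is asserted with
#' confidence \code{hi}); \code{lowered} when the posterior mean is below 1
#' and the exceedance probability is below \code{lo}; otherwise
#' \code{uncertain}.
#'
#' @param rr_mean Posterior mean relative risks.
#' @param exceedance Exceedance probabilities in [0, 1].
#' @param hi,lo Classification cut-points, default 0.8 / 0.2.
#' @return Factor with levels \code{elevated}, \code{lowered},
#'   \code{uncertain} (\code{NA} where inputs are missing).
#' @examples
#' classifyRisk(c(1.4, 0.7, 1.4), c(0.92, 0.10, 0.50))
#' @export
classifyRisk <- function(rr_mean, exceedance, hi = 0.8, lo = 0.2) {
  stopifnot(length(rr_mean) == length(exceedance))
  bad <- is.finite(exceedance) & (exceedance < 0 | exceedance > 1)
  if (any(bad)) stop("exceedance probabilities must lie in [0, 1]",
                     call. = FALSE)
  out <- rep("uncertain", length(rr_mean))
  out[rr_mean > 1 & exceedance > hi] <- "elevated"
  out[rr_mean < 1 & exceedance < lo] <- "lowered"
  out[!is.finite(rr_mean) | !is.finite(exceedance)] <- NA
  factor(out, levels = c("elevated", "lowered", "uncertain"))
}

#' Smoothed risk field: raw, EB and full-Bayes estimates per area
#'
#' Convenience wrapper running the whole mapping pipeline: raw ratios
#' \eqn{O_i/E_i}, empirical-Bayes Poisson-gamma shrinkage toward the global
#' mean, the BYM full-Bayes fit toward the local mean, exceedance
#' probabilities and the elevated/lowered/uncertain classification. Areas
#' with zero expected count are reported as missing, not as zero risk.
#'
#' @param O,E Per-area observed and expected counts.
#' @param adjacency Adjacency over the same areas.
#' @param seed Seed for the MCMC (mandatory).
#' @param hi,lo Classification cut-points.
#' @param ... Further arguments to \code{\link{bymFit}}.
#' @return A data frame of class \code{smoothed_risk_field} with columns
#'   \code{area_id, observed, expected, raw_rr, eb_rr, fb_rr, exceedance,
#'   classification}; the \code{bym_fit} and \code{eb_fit} objects are
#'   attached as attributes.
#' @export
smoothedRiskField <- function(O, E, adjacency, seed, hi = 0.8, lo = 0.2,
                              ...) {
  eb <- ebPoissonGamma(O, E)
  fb <- bymFit(O, E, adjacency, seed = seed, ...)
  ex <- exceedanceProb(fb)
  out <- data.frame(area_id = adjacency$area_id, observed = O,
                    expected = E, raw_rr = eb$raw_rr, eb_rr = eb$eb_rr,
                    fb_rr = unname(fb$posterior_mean_rr),
                    exceedance = unname(ex),
                    classification = classifyRisk(fb$posterior_mean_rr, ex,
                                                  hi, lo))
  attr(out, "eb_fit") <- eb
  attr(out, "bym_fit") <- fb
  class(out) <- c("smoothed_risk_field", "data.frame")
  out
}
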