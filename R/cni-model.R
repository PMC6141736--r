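#' CNI category probabilities
#'
#' Action probabilities implied by the CNI processing tree for the four
#' norm-by-consequences cells. With probability `C` the response is driven by
#' consequences (act iff benefits exceed costs); otherwise, with probability
#' `N`, it is driven by the moral norm (act iff the norm is prescriptive);
#' otherwise a general inaction preference applies (inaction with
#' probability `I`). Cells are always ordered
#' (proscriptive/benefits>costs, proscriptive/benefits<costs,
#'  prescriptive/benefits>costs, prescriptive/benefits<costs).
#'
#' @param C,N,I parameters in \[0, 1\]; may be equal-length vectors.
#' @return For scalar input a named length-4 vector of action probabilities;
#'   for vector input an n-by-4 matrix (rows = parameter sets).
#' @examples
#' cni_probabilities(0.2, 0.3, 0.6)
#' @export
cni_probabilities <- function(C, N, I) {
  stopifnot_prob(C, "C"); stopifnot_prob(N, "N"); stopifnot_prob(I, "I")
  base <- (1 - C) * (1 - N) * (1 - I)   # neither C nor N drives, still acts
  norm <- (1 - C) * N                   # norm drives
  p <- cbind(pro_bgc = C + base,
             pro_bsc = base,
             pre_bgc = C + norm + base,
             pre_bsc = norm + base)
  if (length(C) == 1L && length(N) == 1L && length(I) == 1L) p[1, ] else p
}

#' Moment inversion of cell proportions to CNI parameters
#'
#' Solves the tree equations algebraically: `C = p1 - p2`,
#' `N = (p3 - p1) / (1 - C)`, `I = 1 - p2 / ((1 - C)(1 - N))`, with the cell
#' proportions in the package's canonical order. Used as an analytic oracle
#' and as an initializer for [cni_fit()]. Results are clipped to \[0, 1\];
#' out-of-range or undefined solutions (division by a vanishing margin when
#' `C` or `N` is near 1) are flagged via the `"flagged"` attribute.
#'
#' @param p numeric length-4 vector of action proportions.
#' @param tol margins below `tol` are treated as zero (undefined solution).
#' @return Named vector `c(C=, N=, I=)` with attribute `flagged` (logical).
#' @examples
#' cni_invert(cni_probabilities(0.2, 0.3, 0.6))
#' @export
cni_invert <- function(p, tol = 1e-8) {
  stopifnot(length(p) == 4L)
  stopifnot_prob(p, "p")
  flagged <- FALSE
  C <- p[[1]] - p[[2]]
  if (C < 0 || C > 1) { flagged <- TRUE; C <- min(max(C, 0), 1) }
  if (1 - C < tol) {
    N <- NA_real_; I <- NA_real_; flagged <- TRUE
  } else {
    N <- (p[[3]] - p[[1]]) / (1 - C)
    if (is.na(N) || N < 0 || N > 1) { flagged <- TRUE; N <- min(max(N, 0), 1) }
    if (1 - N < tol) {
      I <- NA_real_; flagged <- TRUE
    } else {
      I <- 1 - p[[2]] / ((1 - C) * (1 - N))
      if (I < 0 || I > 1) { flagged <- TRUE; I <- min(max(I, 0), 1) }
    }
  }
  structure(c(C = unname(C), N = unname(N), I = unname(I)), flagged = flagged)
}

#' Aggregate a response dataset into CNI count tables
#'
#' Pools action/inaction counts over participants within group for each of
#' the four norm-by-consequences cells — the sufficient statistic for the
#' aggregate product-binomial CNI likelihood. With a complete dataset each
#' cell total equals 6 times the group size. Counts use available responses
#' only, so incomplete participants simply contribute fewer trials.
#'
#' @param data a `cni_data` object.
#' @param group optional named vector (names = participant ids) of group
#'   labels, or the name of a column of the participant table; `NULL` pools
#'   everyone into one group `"all"`.
#' @return data.frame of class `cni_counts` with columns `group`, `cell`,
#'   `norm`, `consequences`, `n_action`, `n_inaction` (4 rows per group).
#' @export
cni_counts <- function(data, group = NULL) {
  stopifnot(inherits(data, "cni_data"))
  r <- data$responses
  if (is.null(group)) {
    g <- rep("all", nrow(r))
  } else if (is.character(group) && length(group) == 1L &&
             group %in% names(data$participants)) {
    gv <- data$participants[[group]]
    names(gv) <- data$participants$participant_id
    g <- as.character(gv[r$participant_id])
  } else {
    if (is.null(names(group)))
      mc_stop("'group' must be named by participant_id or name a participant column")
    g <- as.character(group[r$participant_id])
  }
  if (anyNA(g)) mc_stop("some participants have no group assignment")
  groups <- unique(g)
  out <- do.call(rbind, lapply(groups, function(gg) {
    sub <- r[g == gg, ]
    if (nrow(sub) == 0L) mc_stop(sprintf("empty group '%s'", gg))
    act <- tapply(sub$response, factor(sub$cell, levels = 1:4), sum, default = 0L)
    tot <- tapply(sub$response, factor(sub$cell, levels = 1:4), length, default = 0L)
    data.frame(group = gg, cell = 1:4,
               norm = .cni_cells$norm, consequences = .cni_cells$consequences,
               n_action = as.integer(act), n_inaction = as.integer(tot - act),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cni_counts", "data.frame")
  out
}

#' Construct a CNI count table directly
#'
#' @param n_action,n_inaction integer vectors, 4 entries per group, in the
#'   canonical cell order.
#' @param group group labels (length 4 per group); default a single group.
#' @return A `cni_counts` data.frame.
#' @export
as_cni_counts <- function(n_action, n_inaction, group = NULL) {
  n <- length(n_action)
  if (n %% 4L != 0L || length(n_inaction) != n)
    mc_stop("n_action and n_inaction must have 4 entries per group")
  if (is.null(group)) {
    if (n == 4L) group <- rep("all", 4L)
    else group <- rep(paste0("g", seq_len(n / 4L)), each = 4L)
  }
  if (any(n_action < 0) || any(n_inaction < 0))
    mc_stop("counts must be non-negative")
  out <- data.frame(group = as.character(group), cell = rep(1:4, n / 4L),
                    norm = rep(.cni_cells$norm, n / 4L),
                    consequences = rep(.cni_cells$consequences, n / 4L),
                    n_action = as.integer(round(n_action)),
                    n_inaction = as.integer(round(n_inaction)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cni_counts", "data.frame")
  out
}

# ---- likelihood machinery ---------------------------------------------------

# Free-parameter layout. `fixed` is a named numeric vector (applies to all
# groups); `equal` names parameters constrained equal across groups. Returns
# an index matrix idx[G, 3] (0 = fixed) and the fixed-value matrix.
.cni_layout <- function(G, fixed, equal) {
  pars <- c("C", "N", "I")
  idx <- matrix(0L, G, 3, dimnames = list(NULL, pars))
  val <- matrix(NA_real_, G, 3, dimnames = list(NULL, pars))
  k <- 0L
  for (j in seq_along(pars)) {
    pn <- pars[j]
    if (pn %in% names(fixed)) {
      v <- fixed[[pn]]
      if (v < 0 || v > 1) mc_stop(sprintf("fixed value for %s outside [0, 1]", pn))
      val[, j] <- v
    } else if (G == 1L || pn %in% equal) {
      k <- k + 1L
      idx[, j] <- k
    } else {
      idx[, j] <- k + seq_len(G)
      k <- k + G
    }
  }
  list(idx = idx, val = val, n_free = k)
}

.cni_expand <- function(theta, layout) {
  p <- layout$val
  sel <- layout$idx > 0L
  p[sel] <- theta[layout$idx[sel]]
  p
}

# counts as matrices: na[G,4], ni[G,4]
.cni_negll <- function(theta, layout, na, ni, eps = 1e-12) {
  par <- .cni_expand(theta, layout)
  p <- cni_probabilities(par[, 1], par[, 2], par[, 3])
  if (is.null(dim(p))) p <- matrix(p, 1)
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(na * log(p) + ni * log(1 - p))
}

# analytic gradient of the negative log-likelihood in free-parameter space
.cni_negll_grad <- function(theta, layout, na, ni, eps = 1e-12) {
  par <- .cni_expand(theta, layout)
  G <- nrow(par)
  g <- numeric(length(theta))
  for (gi in seq_len(G)) {
    C <- par[gi, 1]; N <- par[gi, 2]; I <- par[gi, 3]
    p <- cni_probabilities(C, N, I)
    p <- pmin(pmax(p, eps), 1 - eps)
    # dp/d(C, N, I) per cell, canonical order
    dC <- c(1 - (1 - N) * (1 - I), -(1 - N) * (1 - I),
            1 - N - (1 - N) * (1 - I), -N - (1 - N) * (1 - I))
    dN <- c(-(1 - C) * (1 - I), -(1 - C) * (1 - I), (1 - C) * I, (1 - C) * I)
    dI <- c(-(1 - C) * (1 - N), -(1 - C) * (1 - N),
            -(1 - C) * (1 - N), -(1 - C) * (1 - N))
    dldp <- na[gi, ] / p - ni[gi, ] / (1 - p)
    contr <- c(sum(dldp * dC), sum(dldp * dN), sum(dldp * dI))
    for (j in 1:3) {
      k <- layout$idx[gi, j]
      if (k > 0L) g[k] <- g[k] - contr[j]
    }
  }
  g
}

.cni_saturated_ll <- function(na, ni) {
  n <- na + ni
  xlx <- function(x, d) ifelse(x == 0, 0, x * log(x / d))
  sum(xlx(na, n) + xlx(ni, n))
}

#' Fit the CNI model by maximum likelihood
#'
#' Maximizes the product-binomial log-likelihood of pooled action/inaction
#' counts over the free parameters in \[0, 1\], using bounded quasi-Newton
#' (`L-BFGS-B`) with an analytic gradient, a moment-inversion start and
#' random restarts. Goodness of fit is the likelihood-ratio statistic
#' `G2 = 2 * sum(observed * log(observed / expected))` over all
#' `8 * n_groups` cells (with `0 * log(0) == 0`), on
#' `4 * n_groups - n_free_parameters` degrees of freedom. 95% confidence
#' intervals are Wald intervals from the observed information at the MLE.
#'
#' @param data a `cni_counts` table (or a `cni_data` object, aggregated via
#'   [cni_counts()]).
#' @param group passed to [cni_counts()] when `data` is a `cni_data`.
#' @param fixed named numeric vector fixing parameters at constants in all
#'   groups, e.g. `c(I = 0.5)`.
#' @param equal character vector of parameters constrained equal across
#'   groups, e.g. `"I"`.
#' @param n_starts number of additional uniform random starts (default 10).
#' @param control passed to [stats::optim()]; the default convergence
#'   tolerance is `factr = 10` (about 2e-15 relative on the log-likelihood).
#' @return An object of class `cni_fit` with components `coefficients`
#'   (groups-by-parameters matrix), `se`, `ci` (3-d array), `logLik`, `G2`,
#'   `df`, `p.value`, `boundary`, `counts`, `fixed`, `equal`.
#' @examples
#' counts <- as_cni_counts(round(1000 * cni_probabilities(0.2, 0.3, 0.6)),
#'                         round(1000 * (1 - cni_probabilities(0.2, 0.3, 0.6))))
#' fit <- cni_fit(counts)
#' coef(fit)
#' @export
cni_fit <- function(data, group = NULL, fixed = NULL, equal = character(0),
                    n_starts = 10, control = list()) {
  counts <- if (inherits(data, "cni_data")) cni_counts(data, group) else data
  if (!inherits(counts, "cni_counts")) {
    if (is.data.frame(counts) &&
        all(c("group", "cell", "n_action", "n_inaction") %in% names(counts))) {
      class(counts) <- c("cni_counts", "data.frame")
    } else mc_stop("'data' must be a cni_counts table or a cni_data object")
  }
  fixed <- if (is.null(fixed)) numeric(0) else unlist(fixed)
  if (length(fixed) && !all(names(fixed) %in% c("C", "N", "I")))
    mc_stop("names of 'fixed' must be among C, N, I")
  if (!all(equal %in% c("C", "N", "I")))
    mc_stop("'equal' must name parameters among C, N, I")

  groups <- unique(counts$group)
  G <- length(groups)
  na <- ni <- matrix(0, G, 4)
  for (gi in seq_len(G)) {
    sub <- counts[counts$group == groups[gi], ]
    sub <- sub[order(sub$cell), ]
    if (!identical(sub$cell, 1:4) && !identical(as.integer(sub$cell), 1:4))
      mc_stop(sprintf("group '%s' must have exactly one row per cell", groups[gi]))
    na[gi, ] <- sub$n_action
    ni[gi, ] <- sub$n_inaction
  }
  if (any(na + ni <= 0)) mc_stop("every cell needs a positive total count for fitting")

  layout <- .cni_layout(G, fixed, equal)
  if (layout$n_free == 0L) {
    theta <- numeric(0)
    ll <- -.cni_negll(theta, layout, na, ni)
    conv <- TRUE
  } else {
    # moment-inversion start (per group, averaged onto shared slots)
    prop <- na / (na + ni)
    inv <- t(apply(prop, 1, function(p) {
      v <- suppressWarnings(cni_invert(p))
      v[!is.finite(v)] <- 0.5
      pmin(pmax(v, 0.02), 0.98)
    }))
    start0 <- numeric(layout$n_free)
    cnt <- numeric(layout$n_free)
    for (gi in seq_len(G)) for (j in 1:3) {
      k <- layout$idx[gi, j]
      if (k > 0L) { start0[k] <- start0[k] + inv[gi, j]; cnt[k] <- cnt[k] + 1 }
    }
    start0 <- start0 / cnt
    starts <- c(list(start0, rep(0.5, layout$n_free)),
                lapply(seq_len(n_starts),
                       function(i) stats::runif(layout$n_free, 0.02, 0.98)))
    ctrl <- utils::modifyList(list(factr = 10, maxit = 500), control)
    best <- best_conv <- NULL
    for (s in starts) {
      o <- try(stats::optim(s, .cni_negll, gr = .cni_negll_grad,
                            layout = layout, na = na, ni = ni,
                            method = "L-BFGS-B", lower = 0, upper = 1,
                            control = ctrl), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value - 1e-12) best <- o
      if (o$convergence == 0 &&
          (is.null(best_conv) || o$value < best_conv$value - 1e-12)) best_conv <- o
    }
    if (is.null(best))
      mc_stop("CNI fit failed to converge from every start", class = "moralcni_convergence_error")
    # a cleanly converged start within tolerance of the overall best wins;
    # the line search can end abnormally at machine-precision tolerances
    if (!is.null(best_conv) && best_conv$value <= best$value + 1e-8) best <- best_conv
    conv <- best$convergence == 0
    if (!conv)
      warning("CNI fit: optimizer reported non-convergence at the best start")
    theta <- best$par
    ll <- -best$value
  }

  par <- .cni_expand(theta, layout)
  dimnames(par) <- list(groups, c("C", "N", "I"))
  boundary <- layout$idx > 0L & (par < 1e-4 | par > 1 - 1e-4)

  G2 <- max(0, 2 * (.cni_saturated_ll(na, ni) - ll))
  df <- 4L * G - layout$n_free
  p.value <- if (df > 0) stats::pchisq(G2, df, lower.tail = FALSE) else NA_real_

  se_par <- ci <- NULL
  se_theta <- rep(NA_real_, layout$n_free)
  vc <- NULL
  if (layout$n_free > 0L) {
    H <- try(stats::optimHess(theta, .cni_negll, gr = .cni_negll_grad,
                              layout = layout, na = na, ni = ni), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc <- try(solve(H), silent = TRUE)
      if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
          all(diag(vc) >= 0)) {
        se_theta <- sqrt(diag(vc))
      } else vc <- NULL
    }
  }
  se_par <- matrix(NA_real_, G, 3, dimnames = dimnames(par))
  sel <- layout$idx > 0L
  se_par[sel] <- se_theta[layout$idx[sel]]
  if (any(boundary)) se_par[boundary] <- NA_real_  # Wald invalid at the boundary
  z <- stats::qnorm(0.975)
  ci <- array(NA_real_, c(G, 3, 2),
              dimnames = list(groups, c("C", "N", "I"), c("lower", "upper")))
  ci[, , 1] <- pmax(par - z * se_par, 0)
  ci[, , 2] <- pmin(par + z * se_par, 1)

  structure(list(coefficients = par, se = se_par, ci = ci,
                 logLik = ll, G2 = G2, df = df, p.value = p.value,
                 boundary = boundary, counts = counts, groups = groups,
                 fixed = fixed, equal = equal, layout = layout,
                 theta = theta, vcov = vc, na = na, ni = ni,
                 converged = conv),
            class = "cni_fit")
}
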