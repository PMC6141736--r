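# Independent oracles for the CNI likelihood machinery. These never call the
# package's fitting path: probabilities come from explicit enumeration of the
# processing-tree branches, and maximization is an exhaustive grid search.

# Enumerate the three tree branches for one cell and sum the action paths.
oracle_probs <- function(C, N, I) {
  p <- numeric(4)
  k <- 0
  for (norm in c("proscriptive", "prescriptive")) {
    for (benefits in c("greater", "smaller")) {
      k <- k + 1
      act <- 0
      act <- act + C * (benefits == "greater")            # consequences drive
      act <- act + (1 - C) * N * (norm == "prescriptive") # norms drive
      act <- act + (1 - C) * (1 - N) * (1 - I)            # residual action
      p[k] <- act
    }
  }
  p
}

# Shared 101^3 grid (step 0.01) with per-cell log-probabilities precomputed.
oracle_grid <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- seq(0, 1, by = 0.01)
    eg <- expand.grid(C = g, N = g, I = g)  # C varies fastest, then N, then I
    base <- (1 - eg$C) * (1 - eg$N) * (1 - eg$I)
    P <- cbind(eg$C + base, base,
               eg$C + (1 - eg$C) * eg$N + base, (1 - eg$C) * eg$N + base)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    cache <<- list(g = g, C = eg$C, N = eg$N, I = eg$I,
                   Lp = log(P), Lq = log1p(-P))
    cache
  }
})

oracle_sat_ll <- function(na, ni) {
  n <- na + ni
  xlx <- function(x, d) ifelse(x == 0, 0, x * log(x / d))
  sum(xlx(na, n) + xlx(ni, n))
}

# log-likelihood over the whole grid, as a 101x101x101 array indexed (C, N, I)
oracle_ll_array <- function(na, ni) {
  og <- oracle_grid()
  ll <- as.vector(og$Lp %*% na + og$Lq %*% ni)
  array(ll, dim = c(101, 101, 101))
}

oracle_fit <- function(na, ni) {
  og <- oracle_grid()
  arr <- oracle_ll_array(na, ni)
  i <- which.max(arr)
  list(par = c(C = og$C[i], N = og$N[i], I = og$I[i]),
       ll = arr[i],
       G2 = 2 * (oracle_sat_ll(na, ni) - arr[i]))
}

# max log-likelihood with one parameter held at a grid value
oracle_ll_fixed <- function(arr, parameter, value) {
  i <- which.min(abs(seq(0, 1, by = 0.01) - value))
  switch(parameter,
         C = max(arr[i, , ]), N = max(arr[, i, ]), I = max(arr[, , i]))
}

# profile of the per-group max over one parameter's grid axis
oracle_profile <- function(arr, parameter) {
  switch(parameter,
         C = apply(arr, 1, max), N = apply(arr, 2, max), I = apply(arr, 3, max))
}

# two-group fit with one parameter constrained equal across groups
oracle_ll_equal <- function(arrA, arrB, parameter) {
  max(oracle_profile(arrA, parameter) + oracle_profile(arrB, parameter))
}
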