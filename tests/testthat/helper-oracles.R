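# Independent oracles used to check the package's optimizers. Both are
# deliberately naive: exhaustive basis enumeration for linear programs and
# exhaustive grid search for max-min driving force profiles.

# maximize obj'x s.t. A x = b, lb <= x <= ub, by enumerating all basic
# solutions (choose m basic columns, pin the rest at either bound)
enumerate_lp_optimum <- function(obj, A, b, lb, ub, tol = 1e-9) {
  A <- as.matrix(A)
  n <- length(obj); m <- nrow(A)
  best <- -Inf
  nb_patterns <- function(k) {
    if (k == 0L) return(matrix(logical(0), nrow = 1))
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  }
  for (basic in utils::combn(n, m, simplify = FALSE)) {
    AB <- A[, basic, drop = FALSE]
    if (abs(det(AB)) < tol) next
    nonbasic <- setdiff(seq_len(n), basic)
    pats <- nb_patterns(length(nonbasic))
    for (r in seq_len(nrow(pats))) {
      xN <- ifelse(pats[r, ], ub[nonbasic], lb[nonbasic])
      rhs <- b - if (length(nonbasic)) A[, nonbasic, drop = FALSE] %*% xN else 0
      xB <- solve(AB, rhs)
      if (any(xB < lb[basic] - 1e-7) || any(xB > ub[basic] + 1e-7)) next
      x <- numeric(n); x[basic] <- xB; x[nonbasic] <- xN
      val <- sum(obj * x)
      if (val > best) best <- val
    }
  }
  best
}

# brute-force MDF for a linear chain m0 -> m1 -> m2 -> m3 with the two end
# concentrations fixed and two free intermediates, on a log-concentration
# grid (default 0.01 log-units over the 1 uM - 10 mM range)
brute_mdf_chain <- function(thermo, lnc_fixed_first, lnc_fixed_last,
                            lo = log(1e-6), hi = log(1e-2), step = 0.01,
                            RT = 8.314e-3 * 298.15) {
  stopifnot(nrow(thermo) == 3L)
  g <- seq(lo, hi, by = step * log(10))
  dg <- thermo$drg0_prime
  df1 <- -dg[1] - RT * (g - lnc_fixed_first)            # over m1
  df3 <- -dg[3] - RT * (lnc_fixed_last - g)             # over m2
  # df2 over (m1, m2): -dg2 - RT (m2 - m1)
  df2 <- -dg[2] - RT * outer(-g, g, `+`)                # [i=m1, j=m2]
  worst <- pmin(df2, matrix(df1, nrow = length(g), ncol = length(g)),
                matrix(df3, nrow = length(g), ncol = length(g), byrow = TRUE))
  max(worst)
}
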