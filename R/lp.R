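#' Solve a small dense linear program
#'
#' Maximizes (or minimizes) \code{obj \%*\% x} subject to \code{A \%*\% x == b}
#' and \code{lb <= x <= ub}, using a deterministic two-phase full-tableau
#' simplex. The solver is intentionally self-contained and single-threaded so
#' that repeated runs on the same problem return bit-identical solutions; the
#' problems solved in this package (core-scale flux balance models and
#' max-min driving force programs in log-concentration space) have at most a
#' few hundred variables, for which a dense tableau is entirely adequate.
#'
#' @param obj numeric objective vector (length n).
#' @param A constraint matrix (m x n); equality constraints \code{A x = b}.
#' @param b right-hand side (length m).
#' @param lb,ub finite variable bounds, elementwise \code{lb <= ub}.
#' @param maximize if \code{TRUE} (default) maximize, else minimize.
#' @param tol numeric pivot tolerance.
#' @param max_iter iteration cap across both phases.
#' @return list with elements \code{status} ("optimal" or "infeasible"),
#'   \code{objective} (optimal value, \code{NA} if infeasible) and \code{x}
#'   (optimal point, \code{NA} if infeasible).
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  n <- length(obj)
  stopifnot(ncol(A) == n, nrow(A) == length(b),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp() requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    stop("lower bound exceeds upper bound for variable ",
         which(lb > ub + 1e-12)[1])

  infeasible <- list(status = "infeasible", objective = NA_real_,
                     x = rep(NA_real_, n))

  ## presolve: substitute variables fixed by their bounds
  fixed <- (ub - lb) <= tol
  x_full <- lb
  free <- which(!fixed)
  if (any(fixed)) {
    b <- b - A[, fixed, drop = FALSE] %*% lb[fixed]
    b <- as.numeric(b)
  }
  nf <- length(free)
  if (nf == 0L) {
    if (all(abs(b) <= 1e-7)) {
      return(list(status = "optimal",
                  objective = sum(obj * x_full), x = x_full))
    }
    return(infeasible)
  }
  Af <- A[, free, drop = FALSE]
  lbf <- lb[free]; ubf <- ub[free]
  ## shift to y = x - lb, 0 <= y <= u
  u <- ubf - lbf
  b1 <- b - as.numeric(Af %*% lbf)
  cf <- obj[free] * (if (maximize) -1 else 1)  # internal convention: minimize

  m1 <- nrow(Af)
  ## drop all-zero equality rows (after substitution)
  rs <- rowSums(abs(Af))
  zero_rows <- rs <= tol
  if (any(zero_rows)) {
    if (any(abs(b1[zero_rows]) > 1e-7)) return(infeasible)
    Af <- Af[!zero_rows, , drop = FALSE]
    b1 <- b1[!zero_rows]
    m1 <- nrow(Af)
  }

  ## standard form rows: [Af] y = b1 ; y_i + s_i = u_i
  ## columns: y (nf), slacks s (nf), artificials (m1)
  sgn <- ifelse(b1 < 0, -1, 1)
  m <- m1 + nf
  ncols <- 2L * nf + m1
  T0 <- matrix(0, m, ncols + 1L)
  if (m1 > 0L) {
    T0[seq_len(m1), seq_len(nf)] <- Af * sgn
    T0[cbind(seq_len(m1), 2L * nf + seq_len(m1))] <- 1
    T0[seq_len(m1), ncols + 1L] <- b1 * sgn
  }
  ub_rows <- m1 + seq_len(nf)
  T0[cbind(ub_rows, seq_len(nf))] <- 1
  T0[cbind(ub_rows, nf + seq_len(nf))] <- 1
  T0[ub_rows, ncols + 1L] <- u

  basis <- c(2L * nf + seq_len(m1), nf + seq_len(nf))
  art_cols <- if (m1 > 0L) 2L * nf + seq_len(m1) else integer(0)

  run_simplex <- function(T, basis, cost, allowed, max_iter, tol) {
    ## cost: length ncols vector (minimization); returns updated state
    m <- nrow(T); ncols <- ncol(T) - 1L
    ## reduced cost row
    z <- cost
    rhs_obj <- 0
    bc <- cost[basis]
    if (any(bc != 0)) {
      z <- cost - as.numeric(bc %*% T[, seq_len(ncols), drop = FALSE])
      rhs_obj <- -sum(bc * T[, ncols + 1L])
    }
    it <- 0L
    bland_after <- 4000L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        stop("simplex iteration limit reached (", max_iter, ")")
      cand <- which(allowed & z < -1e-9)
      if (length(cand) == 0L) break
      j <- if (it > bland_after) cand[1L] else cand[which.min(z[cand])]
      col <- T[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L)
        stop("unbounded linear program (missing bound?)")
      ratios <- T[pos, ncols + 1L] / col[pos]
      rmin <- min(ratios)
      prow <- pos[which(ratios <= rmin + 1e-12)]
      ## tie-break: prefer leaving artificials, then lowest basis index
      if (length(prow) > 1L) {
        ia <- prow[basis[prow] %in% art_cols]
        prow <- if (length(ia) > 0L) ia[1L] else prow[which.min(basis[prow])]
      } else prow <- prow[1L]
      piv <- T[prow, j]
      T[prow, ] <- T[prow, ] / piv
      fac <- T[, j]
      fac[prow] <- 0
      T <- T - outer(fac, T[prow, ])
      zfac <- z[j]
      rhs_obj <- rhs_obj - zfac * T[prow, ncols + 1L]
      z <- z - zfac * T[prow, seq_len(ncols)]
      z[j] <- 0
      basis[prow] <- j
    }
    list(T = T, basis = basis, obj = -rhs_obj)
  }

  ncols_all <- ncols
  ## phase 1: minimize sum of artificials
  if (m1 > 0L) {
    cost1 <- c(rep(0, 2L * nf), rep(1, m1))
    allowed1 <- rep(TRUE, ncols_all)
    ph1 <- run_simplex(T0, basis, cost1, allowed1, max_iter, tol)
    scale1 <- max(1, max(abs(b1)))
    if (ph1$obj > 1e-7 * scale1) return(infeasible)
    T0 <- ph1$T; basis <- ph1$basis
    ## drive remaining basic artificials out where possible
    for (r in which(basis %in% art_cols)) {
      row <- T0[r, seq_len(2L * nf)]
      j <- which(abs(row) > 1e-7)[1]
      if (!is.na(j)) {
        piv <- T0[r, j]
        T0[r, ] <- T0[r, ] / piv
        fac <- T0[, j]; fac[r] <- 0
        T0 <- T0 - outer(fac, T0[r, ])
        basis[r] <- j
      }
      ## if no pivot available the row is redundant and stays at zero level
    }
  }
  allowed2 <- c(rep(TRUE, 2L * nf), rep(FALSE, m1))
  cost2 <- c(cf, rep(0, nf + m1))
  ph2 <- run_simplex(T0, basis, cost2, allowed2, max_iter, tol)

  ## polish: re-solve the basic system from the original data to remove
  ## the roundoff accumulated across tableau updates
  y <- rep(0, nf)
  basis <- ph2$basis
  M <- matrix(0, m, length(basis))
  rhs <- c(b1 * sgn, u)
  for (k in seq_along(basis)) {
    j <- basis[k]
    if (j <= nf) {                      # structural y_j
      if (m1 > 0L) M[seq_len(m1), k] <- Af[, j] * sgn
      M[m1 + j, k] <- 1
    } else if (j <= 2L * nf) {          # slack s_j
      M[m1 + (j - nf), k] <- 1
    } else {                            # residual artificial (zero level)
      M[j - 2L * nf, k] <- 1
    }
  }
  z <- tryCatch(qr.solve(M, rhs, tol = 1e-12), error = function(e) NULL)
  if (is.null(z)) {
    inb <- basis <= nf
    y[basis[inb]] <- ph2$T[which(inb), ncols_all + 1L]
  } else {
    inb <- basis <= nf
    y[basis[inb]] <- z[inb]
  }
  x_full[free] <- pmin(pmax(lbf + y, lbf), ubf)
  objective <- sum(obj * x_full)
  list(status = "optimal", objective = objective, x = x_full)
}
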