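# Bounded linear-programming layer used by every flux-balance solve.
#
# Problems have the form
#   maximize  obj' v
#   subject to  row_lower <= A v <= row_upper   (equality when the two agree)
#               lb <= v <= ub
# which covers both the individual-growth and the coupled-pair programs:
# intracellular mass-balance rows are equalities at zero, extracellular rows
# are ranged by the environment bounds, and fluxes are boxed.
#
# boot::simplex() works on standard-form problems (x >= 0, non-negative
# right-hand sides), so variables are shifted by their lower bounds, upper
# bounds become inequality rows, and rows are flipped as needed.

# Substitute for infinite bounds; an optimum pressing against it is reported
# as "unbounded" rather than trusted.
.LP_BIG <- 1e7

#' @keywords internal
lp_solve <- function(obj, A, row_lower, row_upper, lb, ub,
                     n_iter = NULL, eps = 1e-10) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(row_lower) == m, length(row_upper) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) stop("lp_solve: lower bound exceeds upper bound")
  if (any(row_lower > row_upper + 1e-12)) {
    stop("lp_solve: row lower bound exceeds row upper bound")
  }

  capped_lo <- !is.finite(lb)
  capped_hi <- !is.finite(ub)
  lb2 <- ifelse(capped_lo, -.LP_BIG, lb)
  ub2 <- ifelse(capped_hi, .LP_BIG, ub)

  # shift x = v - lb2 so x >= 0
  shift <- as.numeric(A %*% lb2)
  rl <- row_lower - shift
  ru <- row_upper - shift
  ubx <- ub2 - lb2

  A1 <- NULL; b1 <- NULL   # <=
  A2 <- NULL; b2 <- NULL   # >=
  A3 <- NULL; b3 <- NULL   # ==
  add <- function(side, row, rhs) {
    if (abs(rhs) < 1e-11) rhs <- 0
    if (all(row == 0)) {
      # vacuous row: only check it is not plainly inconsistent
      bad <- (side == "le" && rhs < 0) || (side == "ge" && rhs > 0) ||
        (side == "eq" && rhs != 0)
      if (bad) stop("lp_solve: inconsistent constant constraint row")
      return(invisible())
    }
    if (side == "le") {
      if (rhs >= 0) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
      else          { A2 <<- rbind(A2, -row); b2 <<- c(b2, -rhs) }
    } else if (side == "ge") {
      if (rhs > 0) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
      else         { A1 <<- rbind(A1, -row); b1 <<- c(b1, -rhs) }
    } else {
      if (rhs >= 0) { A3 <<- rbind(A3, row); b3 <<- c(b3, rhs) }
      else          { A3 <<- rbind(A3, -row); b3 <<- c(b3, -rhs) }
    }
  }

  # Equalities are emitted as <= pairs: boot::simplex's phase 1 mishandles
  # zero right-hand-side rows that need artificial variables (they never
  # pivot), while <= rows start from feasible slacks. Rows that genuinely
  # need artificials (positive-rhs >=, e.g. the partner floor) always have a
  # positive phase-1 objective and are handled correctly.
  for (i in seq_len(m)) {
    if (isTRUE(all.equal(row_lower[i], row_upper[i], tolerance = 1e-12))) {
      add("le", A[i, ], ru[i])
      add("ge", A[i, ], rl[i])
    } else {
      if (is.finite(ru[i])) add("le", A[i, ], ru[i])
      if (is.finite(rl[i])) add("ge", A[i, ], rl[i])
    }
  }
  # box upper bounds as rows (all finite after capping)
  for (j in seq_len(n)) {
    row <- numeric(n); row[j] <- 1
    add("le", row, ubx[j])
  }

  mtot <- length(b1) + length(b2) + length(b3)
  if (is.null(n_iter)) n_iter <- 50L * (n + mtot)
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = TRUE,
                       n.iter = n_iter, eps = eps)
  if (res$solved == -1) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  if (res$solved != 1) stop("lp_solve: simplex iteration limit reached")

  x <- as.numeric(res$soln)[seq_len(n)]
  v <- x + lb2
  # pressing an artificial cap means the true problem is unbounded there
  hit_cap <- (capped_hi & v > .LP_BIG * 0.999) | (capped_lo & v < -.LP_BIG * 0.999)
  if (any(hit_cap & obj != 0)) {
    return(list(status = "unbounded", objective = Inf, x = v))
  }
  list(status = "optimal",
       objective = as.numeric(res$value) + sum(obj * lb2),
       x = v)
}
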