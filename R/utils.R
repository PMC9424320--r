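#' @keywords internal
"_PACKAGE"

## Numeric tolerance used when comparing stoichiometries and LP results.
STOICH_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' Optimizes `obj' x` subject to `Aeq x = beq` and `lb <= x <= ub` with a
#' dense two-phase simplex using Bland's anti-cycling rule. Problems are
#' shifted to the non-negative orthant (`y = x - lb`); finite upper bounds
#' become slack rows. The dense tableau is entirely adequate for the model
#' sizes this package solves (tens of reactions).
#'
#' @param obj numeric objective vector.
#' @param Aeq,beq equality constraints (`Aeq` may have zero rows).
#' @param lb,ub bounds; `ub` may contain `Inf`.
#' @param maximize logical, maximize instead of minimize.
#' @return list with `x` (solution on the original scale), `value` and
#'   `status` (`"optimal"`, `"infeasible"` or `"unbounded"`).
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n, all(lb <= ub))
  if (is.null(Aeq)) Aeq <- matrix(0, 0, n)
  Aeq <- as.matrix(Aeq)
  if (is.null(beq)) beq <- numeric(0)
  failed <- function(status) list(x = rep(NA_real_, n), value = NA_real_,
                                  status = status)

  ## shift to y = x - lb >= 0; add slack rows for finite upper bounds
  beq2 <- beq - as.numeric(Aeq %*% lb)
  finite_ub <- which(is.finite(ub))
  n_s <- length(finite_ub)
  A_full <- rbind(
    cbind(Aeq, matrix(0, nrow(Aeq), n_s)),
    cbind(diag(n)[finite_ub, , drop = FALSE], diag(n_s)))
  b_full <- c(beq2, ub[finite_ub] - lb[finite_ub])

  sense <- if (maximize) -1 else 1
  res <- simplex_two_phase(sense * c(obj, rep(0, n_s)), A_full, b_full)
  if (res$status != "optimal") return(failed(res$status))
  x <- res$x[seq_len(n)] + lb
  list(x = x, value = sum(obj * x), status = "optimal")
}

## Two-phase primal simplex for min c'z, A z = b, z >= 0 (dense tableau,
## Bland's rule: entering = lowest eligible index, leaving ties broken by
## lowest basis index, which guarantees termination on degenerate problems).
simplex_two_phase <- function(cost, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0) {
    ## no constraints: minimum over z >= 0 is at the origin unless some cost
    ## is negative
    if (any(cost < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = rep(0, n)))
  }
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  ## phase 1: artificial basis
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  p1 <- simplex_iterate(Tab, basis, c(rep(0, n), rep(1, m)), active = n + m,
                        tol = tol)
  Tab <- p1$Tab; basis <- p1$basis
  rhs_col <- ncol(Tab)
  if (sum(Tab[basis > n, rhs_col]) > 1e-7) return(list(status = "infeasible"))

  ## pivot lingering zero-level artificials onto structural columns
  for (i in which(basis > n)) {
    piv <- which(abs(Tab[i, seq_len(n)]) > tol)[1]
    if (is.na(piv)) next  # redundant row; the artificial stays at zero
    Tab[i, ] <- Tab[i, ] / Tab[i, piv]
    for (k in setdiff(seq_len(m), i)) {
      Tab[k, ] <- Tab[k, ] - Tab[k, piv] * Tab[i, ]
    }
    basis[i] <- piv
  }

  ## phase 2: original costs, artificials barred from entering
  p2 <- simplex_iterate(Tab, basis, c(cost, rep(0, m)), active = n, tol = tol)
  if (p2$status == "unbounded") return(list(status = "unbounded"))
  x <- rep(0, n)
  keep <- p2$basis <= n
  x[p2$basis[keep]] <- p2$Tab[keep, rhs_col]
  list(status = "optimal", x = x)
}

simplex_iterate <- function(Tab, basis, cost, active, tol = 1e-9,
                            maxit = 100000L) {
  m <- nrow(Tab); rhs_col <- ncol(Tab)
  for (it in seq_len(maxit)) {
    reduced <- cost[seq_len(active)] -
      as.numeric(cost[basis] %*% Tab[, seq_len(active), drop = FALSE])
    enter <- which(reduced < -tol)[1]
    if (is.na(enter)) {
      return(list(Tab = Tab, basis = basis, status = "optimal"))
    }
    col <- Tab[, enter]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded"))
    ratios <- Tab[pos, rhs_col] / col[pos]
    cand <- pos[ratios <= min(ratios) + tol]
    leave <- cand[which.min(basis[cand])]
    Tab[leave, ] <- Tab[leave, ] / Tab[leave, enter]
    others <- setdiff(seq_len(m), leave)
    Tab[others, ] <- Tab[others, ] -
      outer(Tab[others, enter], Tab[leave, ])
    basis[leave] <- enter
  }
  stop("simplex iteration limit reached")
}

## 32-bit FNV-1a hash over a character string; returns a double in [0, 2^32).
## Exact 32-bit arithmetic is kept by splitting the multiplication, since R
## doubles lose integer exactness past 2^53.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- mul32(bitwXor_dbl(h, b), 16777619)
  }
  h
}

mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

bitwXor_dbl <- function(a, b) {
  ## bitwXor works on 32-bit signed ints; map via the two 16-bit halves
  al <- a %% 65536; ah <- (a - al) / 65536
  bl <- b %% 65536; bh <- (b - bl) / 65536
  bitwXor(ah, bh) * 65536 + bitwXor(al, bl)
}

## Deterministic decimal rendering with up to 6 significant digits, used for
## stoichiometries so that write -> read -> write round-trips byte-stably.
format_stoich <- function(x) {
  vapply(x, function(v) {
    s <- format(signif(v, 6), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
    s
  }, character(1))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## InChIKey layout: 14 uppercase letters, dash, 10 letters, dash, 1 letter.
is_inchikey <- function(x) {
  grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

inchikey_block1 <- function(x) substr(x, 1L, 14L)
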