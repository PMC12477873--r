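#' Bounded-variable linear programming by two-phase revised simplex
#'
#' Solves `max/min c'x  s.t.  A x = b,  lb <= x <= ub` and returns, besides
#' the optimum, the dual vector `y` of the equality rows from the final
#' basis (`y = B^-T c_B`), i.e. `y_i = dZ/db_i` for the maximization form.
#' These exact basic duals are what the steady-state shadow-price analysis
#' consumes; an interior-point solver's smoothed duals would not do.
#'
#' The implementation is a dense two-phase revised simplex with bounded
#' variables. The basis inverse is maintained explicitly and updated by
#' elementary row operations at each pivot (product form), with periodic
#' refactorization for numerical stability. Entering variables are chosen
#' by the Dantzig rule with an automatic switch to Bland's rule to escape
#' cycling under degeneracy; the ratio test supports bound flips. Intended
#' for the model sizes this package generates (hundreds of rows/columns),
#' not for industrial LPs.
#'
#' @param A Constraint matrix (rows are equalities), dense or `Matrix`.
#' @param b Right-hand side vector.
#' @param c_obj Objective coefficients.
#' @param lb,ub Variable bounds (may be -Inf/Inf).
#' @param sense `"max"` (default) or `"min"`.
#' @param maxit Iteration cap.
#' @param tol Pivot/feasibility tolerance.
#' @param engine `"cpp"` (default, compiled) or `"r"` (pure-R reference
#'   implementation of the same algorithm; the two are cross-checked in
#'   the test suite).
#' @return List with `status` ("optimal", "infeasible", "unbounded" or
#'   "maxit"), `objective`, primal solution `x`, equality-row duals `y`
#'   (named by rownames of `A` when present), and iteration count `niter`.
#' @export
solve_lp <- function(A, b, c_obj, lb, ub, sense = c("max", "min"),
                     maxit = NULL, tol = 1e-9, engine = c("cpp", "r")) {
  sense <- match.arg(sense)
  engine <- match.arg(engine)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(c_obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stopf("lb > ub in LP")
  if (sense == "min") {
    res <- solve_lp(A, b, -c_obj, lb, ub, sense = "max", maxit = maxit,
                    tol = tol, engine = engine)
    res$objective <- -res$objective
    res$y <- -res$y
    return(res)
  }
  if (is.null(maxit)) maxit <- max(2000L, 60L * (m + n))
  row_names <- rownames(A)
  if (engine == "cpp") {
    out <- .simplex_bounded_cpp(A, b, c_obj, lb, ub, as.integer(maxit), tol)
    status <- c("optimal", "infeasible", "unbounded", "maxit")[out$status + 1L]
    if (status != "optimal") {
      return(list(status = status,
                  objective = if (status == "unbounded") Inf else NA_real_,
                  x = rep(NA_real_, n), y = rep(NA_real_, m),
                  niter = out$niter))
    }
    y <- as.numeric(out$y)
    names(y) <- row_names
    return(list(status = "optimal", objective = out$objective,
                x = as.numeric(out$x), y = y, niter = out$niter))
  }

  # --- augmented problem: structural vars then m artificials -------------
  x0 <- numeric(n)
  stat <- integer(n + m) # 1 at-lb, 2 at-ub, 3 free-at-0, 0 basic
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) { x0[j] <- lb[j]; stat[j] <- 1L }
    else if (is.finite(ub[j])) { x0[j] <- ub[j]; stat[j] <- 2L }
    else { x0[j] <- 0; stat[j] <- 3L }
  }
  resid <- as.numeric(b - A %*% x0)
  sgn <- ifelse(resid >= 0, 1, -1)
  Aaug <- cbind(A, diag(sgn, nrow = m))
  lbA <- c(lb, rep(0, m))
  ubA <- c(ub, rep(Inf, m))
  basis <- n + seq_len(m)
  stat[basis] <- 0L
  xval <- c(x0, abs(resid))

  bland_after <- 3L * (n + m)
  refactor_every <- 100L
  niter <- 0L
  enterable <- rep(TRUE, n + m)
  dtol <- 1e-7

  refactor <- function(basis) {
    Bi <- tryCatch(solve(Aaug[, basis, drop = FALSE]), error = function(e) NULL)
    if (is.null(Bi)) stopf("singular basis encountered in LP")
    Bi
  }

  run_phase <- function(cc, basis, stat, xval, Binv = NULL) {
    degenerate_streak <- 0L
    if (is.null(Binv)) Binv <- refactor(basis)
    since_refactor <- 0L
    repeat {
      if (niter >= maxit) {
        return(list(status = "maxit", basis = basis, stat = stat, xval = xval,
                    Binv = Binv))
      }
      niter <<- niter + 1L
      if (since_refactor >= refactor_every) {
        Binv <- refactor(basis)
        since_refactor <- 0L
        nb0 <- which(stat != 0L)
        xval[basis] <- as.numeric(
          Binv %*% (b - Aaug[, nb0, drop = FALSE] %*% xval[nb0]))
      }
      nb <- which(stat != 0L)
      y <- as.numeric(crossprod(Binv, cc[basis]))
      d_full <- cc - as.numeric(crossprod(Aaug, y))
      d <- d_full[nb]

      up_ok <- (stat[nb] == 1L | stat[nb] == 3L) & d > dtol
      dn_ok <- (stat[nb] == 2L | stat[nb] == 3L) & d < -dtol
      cand <- which((up_ok | dn_ok) & enterable[nb])
      if (length(cand) == 0L) {
        return(list(status = "optimal", basis = basis, stat = stat,
                    xval = xval, y = y, Binv = Binv))
      }
      use_bland <- niter > bland_after || degenerate_streak > (n + m)
      pick <- if (use_bland) cand[which.min(nb[cand])] else cand[which.max(abs(d[cand]))]
      e <- nb[pick]
      sigma <- if (up_ok[pick]) 1 else -1

      w <- as.numeric(Binv %*% Aaug[, e])
      sw <- sigma * w
      tmax_basic <- rep(Inf, m)
      dec <- sw > tol # basic value decreases toward its lower bound
      inc <- sw < -tol
      tmax_basic[dec] <- (xval[basis[dec]] - lbA[basis[dec]]) / sw[dec]
      tmax_basic[inc] <- (ubA[basis[inc]] - xval[basis[inc]]) / (-sw[inc])
      tmax_basic[tmax_basic < 0] <- 0
      t_flip <- ubA[e] - lbA[e] # Inf for free/one-sided vars
      tstar <- min(tmax_basic, t_flip)
      if (!is.finite(tstar)) {
        return(list(status = "unbounded", basis = basis, stat = stat,
                    xval = xval, Binv = Binv))
      }
      degenerate_streak <- if (tstar < tol) degenerate_streak + 1L else 0L

      if (is.finite(t_flip) && t_flip <= min(tmax_basic)) {
        # bound flip: entering variable runs to its opposite bound
        xval[e] <- if (sigma > 0) ubA[e] else lbA[e]
        stat[e] <- if (sigma > 0) 2L else 1L
        xval[basis] <- xval[basis] - tstar * sw
      } else {
        rel <- tol * (1 + abs(tstar))
        hit <- which(tmax_basic <= tstar + rel)
        r <- if (use_bland) hit[which.min(basis[hit])] else hit[which.max(abs(sw[hit]))]
        if (abs(w[r]) < 1e-9) { # unsafe pivot: refactor and retry
          Binv <- refactor(basis)
          since_refactor <- 0L
          next
        }
        lv <- basis[r]
        xval[e] <- xval[e] + sigma * tstar
        xval[basis] <- xval[basis] - tstar * sw
        stat[lv] <- if (sw[r] > 0) 1L else 2L
        xval[lv] <- if (sw[r] > 0) lbA[lv] else ubA[lv]
        basis[r] <- e
        stat[e] <- 0L
        # product-form update of the basis inverse
        pivrow <- Binv[r, ] / w[r]
        Binv <- Binv - tcrossprod(w, pivrow)
        Binv[r, ] <- pivrow
        since_refactor <- since_refactor + 1L
      }
    }
  }

  # --- phase 1: drive artificials to zero --------------------------------
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, basis, stat, xval,
                   Binv = diag(sgn, nrow = m)) # artificial basis inverts itself
  if (ph1$status == "maxit") {
    return(list(status = "maxit", objective = NA_real_, x = rep(NA_real_, n),
                y = rep(NA_real_, m), niter = niter))
  }
  basis <- ph1$basis; stat <- ph1$stat; xval <- ph1$xval; Binv <- ph1$Binv
  art <- n + seq_len(m)
  if (sum(xval[art]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m), niter = niter))
  }
  # pivot residual artificials out of the basis where possible
  in_basis_art <- which(basis > n)
  if (length(in_basis_art)) {
    for (r in in_basis_art) {
      cand_cols <- which(stat[seq_len(n)] != 0L)
      if (length(cand_cols) == 0L) next
      row_r <- as.numeric(Binv[r, , drop = FALSE] %*% Aaug[, cand_cols, drop = FALSE])
      k <- which(abs(row_r) > 1e-7)
      if (length(k)) {
        enter <- cand_cols[k[1]]
        stat[basis[r]] <- 1L
        xval[basis[r]] <- 0
        basis[r] <- enter
        stat[enter] <- 0L
        Binv <- refactor(basis)
      }
    }
  }
  ubA[art] <- 0
  enterable[art] <- FALSE # artificials may not re-enter in phase 2

  # --- phase 2 -----------------------------------------------------------
  c2 <- c(c_obj, rep(0, m))
  ph2 <- run_phase(c2, basis, stat, xval, Binv = Binv)
  if (ph2$status == "maxit") {
    return(list(status = "maxit", objective = NA_real_, x = rep(NA_real_, n),
                y = rep(NA_real_, m), niter = niter))
  }
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = Inf, x = rep(NA_real_, n),
                y = rep(NA_real_, m), niter = niter))
  }
  x <- ph2$xval[seq_len(n)]
  y <- ph2$y
  names(y) <- row_names
  list(status = "optimal", objective = sum(c_obj * x), x = x, y = y,
       niter = niter)
}
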