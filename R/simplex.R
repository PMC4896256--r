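# Dense two-phase primal simplex with Bland's anti-cycling rule, for the
# small LPs this package solves (tens of variables). Standard form is built
# internally: structural variables x >= 0, slack variables for <= / >= rows,
# artificial variables for = and >= rows. Degenerate bases (ubiquitous in
# flux polytopes, where many bounds sit at 0) are handled by Bland's rule.
#
# maximize c'x  s.t.  Aeq x = beq,  Ale x <= ble,  Age x >= bge,  x >= 0
dense_simplex <- function(c_obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                          Age = NULL, bge = NULL, maximize = TRUE,
                          tol = 1e-9) {
  n <- length(c_obj)
  rows <- list(); rhs <- numeric(0); type <- character(0)
  add_rows <- function(A, b, tp) {
    if (is.null(A)) return()
    A <- matrix(A, ncol = n)
    for (i in seq_len(nrow(A))) {
      a <- A[i, ]; bi <- b[i]; tpi <- tp
      if (bi < 0) {  # normalize to non-negative rhs, flipping <= and >=
        a <- -a; bi <- -bi
        tpi <- switch(tp, le = "ge", ge = "le", eq = "eq")
      }
      rows[[length(rows) + 1]] <<- a
      rhs[length(rhs) + 1] <<- bi
      type[length(type) + 1] <<- tpi
    }
  }
  add_rows(Ale, ble, "le")
  add_rows(Age, bge, "ge")
  add_rows(Aeq, beq, "eq")
  m <- length(rows)
  A <- do.call(rbind, rows)

  n_slack <- sum(type != "eq")
  n_art <- sum(type != "le")
  ncol_tab <- n + n_slack + n_art
  Tab <- matrix(0, m, ncol_tab)
  Tab[, seq_len(n)] <- A
  basis <- integer(m)
  s_idx <- n; a_idx <- n + n_slack
  for (i in seq_len(m)) {
    if (type[i] != "eq") {
      s_idx <- s_idx + 1L
      Tab[i, s_idx] <- if (type[i] == "le") 1 else -1
      if (type[i] == "le") basis[i] <- s_idx
    }
    if (type[i] != "le") {
      a_idx <- a_idx + 1L
      Tab[i, a_idx] <- 1
      basis[i] <- a_idx
    }
  }
  b <- rhs
  art_cols <- seq.int(n + n_slack + 1L, length.out = n_art)

  pivot <- function(r, col) {
    piv <- Tab[r, col]
    Tab[r, ] <<- Tab[r, ] / piv
    b[r] <<- b[r] / piv
    for (i in seq_len(m)) {
      if (i != r && abs(Tab[i, col]) > 0) {
        f <- Tab[i, col]
        Tab[i, ] <<- Tab[i, ] - f * Tab[r, ]
        b[i] <<- b[i] - f * b[r]
      }
    }
    basis[r] <<- col
  }

  # minimize obj_min over the current tableau (Bland's rule)
  run_simplex <- function(obj_min, allowed) {
    repeat {
      # reduced costs: z_j - c_j with c_B from obj_min
      cb <- obj_min[basis]
      red <- obj_min - as.numeric(crossprod(Tab, cb))
      cand <- which(allowed & red < -tol)
      if (!length(cand)) return(TRUE)
      col <- cand[1]  # Bland: smallest index
      ratio <- ifelse(Tab[, col] > tol, b / Tab[, col], Inf)
      if (all(!is.finite(ratio))) return(FALSE)  # unbounded
      r <- which(ratio == min(ratio))
      r <- r[which.min(basis[r])]  # Bland on the leaving variable
      pivot(r, col)
    }
  }

  allowed <- rep(TRUE, ncol_tab)
  if (n_art > 0) {
    obj1 <- numeric(ncol_tab); obj1[art_cols] <- 1
    run_simplex(obj1, allowed)
    if (sum(obj1[basis] * b) > 1e-7)
      return(list(status = "infeasible", x = rep(NA_real_, n),
                  objective = NA_real_))
    # pivot residual artificials out of the basis where possible
    for (r in which(basis %in% art_cols)) {
      col <- which(abs(Tab[r, seq_len(n + n_slack)]) > tol)[1]
      if (!is.na(col)) pivot(r, col)
    }
    allowed[art_cols] <- FALSE
  }
  obj2 <- numeric(ncol_tab)
  obj2[seq_len(n)] <- if (maximize) -c_obj else c_obj
  if (!run_simplex(obj2, allowed))
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = NA_real_))
  x <- numeric(ncol_tab)
  x[basis] <- b
  list(status = "optimal", x = x[seq_len(n)],
       objective = sum(c_obj * x[seq_len(n)]))
}
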