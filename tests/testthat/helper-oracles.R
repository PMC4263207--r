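# Independent oracles, deliberately implemented with different algorithms
# than the package: exact rational rank via fraction-free (Bareiss)
# elimination, LP optima via exhaustive vertex enumeration, and QP optima
# via brute-force grid search.

# exact rank of an integer matrix; Bareiss divisions are exact, so entries
# stay integral (doubles hold them exactly at these sizes)
bareissRank <- function(M) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  m <- nrow(M); n <- ncol(M)
  r <- 0L; prev <- 1
  for (col in seq_len(n)) {
    if (r == m) break
    rows <- (r + 1L):m
    p <- rows[which(M[rows, col] != 0)[1L]]
    if (is.na(p)) next
    if (p != r + 1L) M[c(r + 1L, p), ] <- M[c(p, r + 1L), ]
    r <- r + 1L
    if (r < m) {
      for (i in (r + 1L):m)
        M[i, ] <- (M[i, ] * M[r, col] - M[i, col] * M[r, ]) / prev
    }
    prev <- M[r, col]
  }
  r
}

# LP oracle: enumerate candidate vertices of {Aeq v = beq, l <= v <= u} by
# activating every subset of d = n - rank(Aeq) variable bounds, solving the
# square-ish system, and keeping feasible points.
vertexOptimumLP <- function(obj, Aeq, beq, lower, upper, maximize = TRUE,
                            tol = 1e-7) {
  Aeq <- as.matrix(Aeq)
  n <- ncol(Aeq)
  d <- n - qr(Aeq)$rank
  best <- NULL
  consider <- function(v) {
    if (any(v < lower - tol) || any(v > upper + tol)) return()
    if (max(abs(Aeq %*% v - beq)) > tol) return()
    val <- sum(obj * v)
    if (is.null(best) || (maximize && val > best) || (!maximize && val < best))
      best <<- val
  }
  if (d == 0L) {
    consider(qr.solve(Aeq, beq))
    return(best)
  }
  sides <- as.matrix(expand.grid(rep(list(c(1L, 2L)), d)))
  for (idx in asplit(utils::combn(n, d), 2L)) {
    for (s in seq_len(nrow(sides))) {
      bvals <- ifelse(sides[s, ] == 1L, lower[idx], upper[idx])
      E <- matrix(0, d, n); E[cbind(seq_len(d), idx)] <- 1
      A2 <- rbind(Aeq, E); b2 <- c(beq, bvals)
      if (qr(A2)$rank < n) next
      v <- tryCatch(qr.solve(A2, b2), error = function(e) NULL)
      if (is.null(v)) next
      if (max(abs(A2 %*% v - b2)) > tol) next
      consider(v)
    }
  }
  best
}

# brute-force grid oracle for the branched measurement fit:
# min w1 (E1 - t1)^2 + w2 (E2 - t2)^2 s.t. E1 + E2 = total
gridFitBranch <- function(t1, t2, w1 = 1, w2 = 1, total = 10, step = 1e-3) {
  e1 <- seq(0, total, by = step)
  obj <- w1 * (e1 - t1)^2 + w2 * ((total - e1) - t2)^2
  e1[which.min(obj)]
}
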