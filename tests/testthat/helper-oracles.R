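# Independent brute-force oracles, kept deliberately naive and separate from
# the implementations they check.

# Rank-based AUC: probability that a random error trial carries a higher
# uncertainty rating than a random correct trial, ties counted 1/2.
oracle_rank_auc <- function(u, correct) {
  correct <- as.logical(correct)
  ue <- u[!correct]
  uc <- u[correct]
  cmp <- outer(ue, uc, ">") + 0.5 * outer(ue, uc, "==")
  mean(cmp)
}

# Threshold-sweep ROC + trapezoid, written independently of type2_roc().
oracle_sweep_auc <- function(u, correct) {
  correct <- as.logical(correct)
  ks <- sort(unique(u), decreasing = TRUE)
  hit <- vapply(ks, function(k) mean(u[!correct] >= k), numeric(1))
  fa <- vapply(ks, function(k) mean(u[correct] >= k), numeric(1))
  fa <- c(0, fa, 1); hit <- c(0, hit, 1)
  sum(diff(fa) * (hit[-length(hit)] + hit[-1]) / 2)
}

# O(n^2) Goodman-Kruskal gamma over all pairs.
oracle_gamma <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / (conc + disc)
}

# Cronbach alpha evaluated directly from its definition.
oracle_alpha <- function(mat) {
  k <- ncol(mat)
  item_var <- numeric(k)
  for (j in seq_len(k)) item_var[j] <- var(mat[, j])
  k / (k - 1) * (1 - sum(item_var) / var(rowSums(mat)))
}

# Exhaustive 4x4 Sudoku completion count over all 4^k digit assignments of
# the empty cells (no backtracking; pure enumeration). Only usable for a
# handful of empties.
oracle_sudoku_count <- function(grid) {
  stopifnot(is.matrix(grid))
  empties <- which(grid == 0)
  k <- length(empties)
  stopifnot(k <= 6)
  box_of <- function(r, c) 2 * ((r - 1) %/% 2) + ((c - 1) %/% 2) + 1
  valid <- function(g) {
    for (r in 1:4) if (anyDuplicated(g[r, ])) return(FALSE)
    for (c in 1:4) if (anyDuplicated(g[, c])) return(FALSE)
    for (b in 1:4) {
      cells <- g[outer(1:4, 1:4, box_of) == b]
      if (anyDuplicated(cells)) return(FALSE)
    }
    TRUE
  }
  n <- 0
  for (code in seq_len(4^k) - 1) {
    g <- grid
    rest <- code
    for (e in empties) {
      g[e] <- rest %% 4 + 1
      rest <- rest %/% 4
    }
    if (valid(g)) n <- n + 1
  }
  n
}

# Recursive minimum-inference-count to fill a target cell, independent of
# the package's breadth-first search. One inference = one cell filled by a
# naked or hidden single. Returns Inf if the rules never reach the target.
oracle_target_steps <- function(grid, target) {
  box_of <- function(r, c) 2 * ((r - 1) %/% 2) + ((c - 1) %/% 2) + 1
  boxes <- outer(1:4, 1:4, box_of)
  cand_of <- function(g, r, c) {
    used <- c(g[r, ], g[, c], g[boxes == boxes[r, c]])
    setdiff(1:4, used[used > 0])
  }
  deducible <- function(g) {
    out <- list()
    emp <- which(g == 0)
    cand <- list()
    for (e in emp) {
      r <- (e - 1) %% 4 + 1; c <- (e - 1) %/% 4 + 1
      cand[[as.character(e)]] <- cand_of(g, r, c)
      if (length(cand[[as.character(e)]]) == 1) {
        out[[length(out) + 1]] <- c(e, cand[[as.character(e)]])
      }
    }
    units <- c(lapply(1:4, function(r) which(row(g) == r)),
               lapply(1:4, function(c) which(col(g) == c)),
               lapply(1:4, function(b) which(boxes == b)))
    found <- vapply(out, `[`, numeric(1), 1)
    for (u in units) {
      ue <- intersect(u, emp)
      for (d in 1:4) {
        places <- ue[vapply(ue, function(e) d %in% cand[[as.character(e)]],
                            logical(1))]
        if (length(places) == 1 && !(places %in% found)) {
          out[[length(out) + 1]] <- c(places, d)
          found <- c(found, places)
        }
      }
    }
    out
  }
  ti <- (target[2] - 1) * 4 + target[1]
  memo <- new.env()
  rec <- function(g) {
    key <- paste(g, collapse = "")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    memo[[key]] <- Inf # cycle guard (not reachable, but safe)
    ded <- deducible(g)
    if (!length(ded)) return(Inf)
    if (any(vapply(ded, `[`, numeric(1), 1) == ti)) {
      memo[[key]] <- 1
      return(1)
    }
    best <- Inf
    for (mv in ded) {
      g2 <- g
      g2[mv[1]] <- mv[2]
      best <- min(best, 1 + rec(g2))
    }
    memo[[key]] <- best
    best
  }
  rec(grid)
}

# Pseudoinverse OLS, an independent linear-algebra path to the GLM betas.
oracle_pinv_beta <- function(y, X) {
  Xi <- cbind(1, X)
  s <- svd(Xi)
  as.numeric(s$v %*% diag(1 / s$d, length(s$d)) %*% t(s$u) %*% y)
}

# A session-shaped trial tibble built directly (not via the simulator).
make_trial_tab <- function(n = 8, u1 = rep(1:4, length.out = n),
                           correct1 = rep(c(1, 0), length.out = n),
                           correct2 = correct1, u2 = pmax(u1 - 1, 1),
                           condition = rep("task", n), level = rep(5L, n),
                           rt1 = 0.5 + 0.25 * u1, rt2 = 0.5 + 0.25 * u2) {
  tibble::tibble(
    participant = 1L, session = 1L, task = "sudoku", run = 1L,
    trial = seq_len(n), condition = condition, level = level,
    choice1 = 1L, correct1 = correct1, conf1 = 5L - u1, u1 = u1, rt1 = rt1,
    choice2 = 1L, correct2 = correct2, conf2 = 5L - u2, u2 = u2, rt2 = rt2,
    delta_u = u1 - u2
  )
}
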