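# 4x4 Sudoku engine: every digit 1-4 appears exactly once in each row, each
# column and each of the four non-overlapping 2x2 corner boxes. Grids are
# 4x4 integer matrices with 0 marking an empty cell. Internally cells are
# indexed 1..16 in row-major order.

.su_row <- rep(1:4, each = 4L)
.su_col <- rep(1:4, times = 4L)
.su_box <- 2L * ((.su_row - 1L) %/% 2L) + ((.su_col - 1L) %/% 2L) + 1L
.su_units <- c(
  lapply(1:4, function(r) which(.su_row == r)),
  lapply(1:4, function(c) which(.su_col == c)),
  lapply(1:4, function(b) which(.su_box == b))
)
.su_peers <- lapply(1:16, function(i) {
  setdiff(sort(unique(unlist(.su_units[c(.su_row[i], 4L + .su_col[i],
                                         8L + .su_box[i])]))), i)
})

as_cells <- function(grid) {
  if (is.matrix(grid)) {
    stopifnot(all(dim(grid) == c(4L, 4L)))
    cells <- as.integer(t(grid)) # row-major
  } else {
    stopifnot(length(grid) == 16L)
    cells <- as.integer(grid)
  }
  cells
}

cells_to_grid <- function(cells) matrix(cells, 4L, 4L, byrow = TRUE)

check_grid <- function(cells) {
  if (anyNA(cells) || any(cells < 0L | cells > 4L)) {
    abort("Sudoku grid values must be integers in 0..4 (0 = empty).",
          class = "redecide_constraint_error")
  }
  for (u in .su_units) {
    filled <- cells[u][cells[u] > 0L]
    if (anyDuplicated(filled)) {
      abort("Sudoku grid violates the row/column/corner-box constraint.",
            class = "redecide_constraint_error")
    }
  }
  invisible(cells)
}

cell_candidates <- function(cells, i) {
  used <- cells[.su_peers[[i]]]
  setdiff(1:4, used[used > 0L])
}

#' Enumerate all completions of a 4x4 Sudoku grid
#'
#' Exhaustive backtracking over the row/column/corner-box constraints.
#' Used as the uniqueness oracle for puzzle generation: a well-posed
#' puzzle admits exactly one completion.
#'
#' @param grid A 4x4 integer matrix, 0 for empty cells, 1-4 for givens.
#' @param limit Stop after this many solutions have been found (e.g. 2 to
#'   test uniqueness without enumerating everything).
#' @return A list of completed 4x4 matrices (empty if unsolvable).
#' @examples
#' g <- matrix(0L, 4, 4)
#' length(solve_sudoku(g, limit = 300)) # 288 complete grids
#' @export
solve_sudoku <- function(grid, limit = Inf) {
  cells <- check_grid(as_cells(grid))
  sols <- list()
  recurse <- function(cl) {
    if (length(sols) >= limit) return(invisible(NULL))
    empties <- which(cl == 0L)
    if (!length(empties)) {
      sols[[length(sols) + 1L]] <<- cells_to_grid(cl)
      return(invisible(NULL))
    }
    # most-constrained-cell heuristic
    best <- 0L; best_cand <- NULL
    for (i in empties) {
      cand <- cell_candidates(cl, i)
      if (!length(cand)) return(invisible(NULL))
      if (is.null(best_cand) || length(cand) < length(best_cand)) {
        best <- i; best_cand <- cand
      }
      if (length(best_cand) == 1L) break
    }
    for (d in best_cand) {
      cl[best] <- d
      recurse(cl)
    }
    invisible(NULL)
  }
  recurse(cells)
  sols
}

# One round of forced single-cell inferences: naked singles (a cell with one
# candidate) and hidden singles (a digit with one place left in a unit).
# Returns the deducible cell indices and their forced digits.
sudoku_deductions <- function(cells) {
  empties <- which(cells == 0L)
  cand <- vector("list", 16L)
  idx <- integer(0); dig <- integer(0)
  for (i in empties) {
    cand[[i]] <- cell_candidates(cells, i)
    if (length(cand[[i]]) == 1L) {
      idx <- c(idx, i); dig <- c(dig, cand[[i]])
    }
  }
  for (u in .su_units) {
    ue <- intersect(u, empties)
    if (!length(ue)) next
    for (d in 1:4) {
      places <- ue[vapply(ue, function(i) d %in% cand[[i]], logical(1))]
      if (length(places) == 1L && !(places %in% idx)) {
        idx <- c(idx, places); dig <- c(dig, d)
      }
    }
  }
  list(idx = idx, dig = dig)
}

# Breadth-first search over inference orderings. Each state is a partially
# filled grid reachable by forced fills only; the depth-d frontier holds the
# grids obtainable after d inferences. For every empty cell this returns the
# minimum number of inferences after which that cell can be filled (the
# cell's own fill included), or NA if the rule set never reaches it.
sudoku_bfs_steps <- function(cells) {
  empties <- which(cells == 0L)
  steps <- setNames(rep(NA_integer_, length(empties)), empties)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  seen[[paste(cells, collapse = "")]] <- TRUE
  frontier <- list(cells)
  depth <- 0L
  while (length(frontier) && anyNA(steps)) {
    nxt <- list()
    for (cl in frontier) {
      ded <- sudoku_deductions(cl)
      for (j in seq_along(ded$idx)) {
        i <- ded$idx[j]
        nm <- as.character(i)
        if (!is.na(match(nm, names(steps))) && is.na(steps[[nm]])) {
          steps[[nm]] <- depth + 1L
        }
        cl2 <- cl
        cl2[i] <- ded$dig[j]
        key <- paste(cl2, collapse = "")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- cl2
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
    if (depth > 16L) break
  }
  steps
}

#' Map a difficulty step count onto the 10-level ladder
#'
#' Step counts 1-9 map to levels 1-9; counts of 10 or more all map to
#' level 10. The bin edges can be overridden.
#'
#' @param steps Non-negative integer step count(s).
#' @param bins Increasing integer vector of lower bin edges, one per level.
#' @return Integer level(s) in 1..length(bins).
#' @export
sudoku_level_from_steps <- function(steps, bins = 1:10) {
  stopifnot(all(steps >= 1L), !is.unsorted(bins, strictly = TRUE))
  findInterval(steps, bins)
}

#' Grade the difficulty of a 4x4 Sudoku puzzle
#'
#' `difficulty_steps` is the minimum number of single-cell logic inferences
#' (naked singles and hidden singles; one inference fills one cell) required
#' to arrive at the complete solution. Once the puzzle is verified to be
#' solvable by that rule set, this equals the number of empty cells.
#' `target_steps` is the minimum number of inferences after which the target
#' cell itself can be filled, minimized over inference orderings by
#' breadth-first search; it is reported as a secondary score (exhaustive
#' enumeration shows it never exceeds 4 on a 4x4 board, so it cannot span a
#' 10-level ladder on its own).
#'
#' @param grid A 4x4 matrix (0 = empty) or a `sudoku_puzzle`.
#' @param target Length-2 integer vector `c(row, col)`, 1-based; ignored
#'   when `grid` is a `sudoku_puzzle`.
#' @param bins Passed to [sudoku_level_from_steps()].
#' @return A list with `difficulty_steps`, `difficulty_level`,
#'   `target_steps` and `solution_digit`.
#' @export
score_sudoku_difficulty <- function(grid, target, bins = 1:10) {
  if (inherits(grid, "sudoku_puzzle")) {
    target <- grid$target
    grid <- grid$grid
  }
  cells <- check_grid(as_cells(grid))
  stopifnot(length(target) == 2L, all(target %in% 1:4))
  ti <- (target[1] - 1L) * 4L + target[2]
  if (cells[ti] != 0L) {
    abort("The target cell must be empty.", class = "redecide_constraint_error")
  }
  sols <- solve_sudoku(cells_to_grid(cells), limit = 2)
  if (length(sols) != 1L) {
    abort(
      sprintf("Puzzle has %s completions; grading requires a unique solution.",
              if (length(sols)) "multiple" else "no"),
      class = "redecide_beyond_ladder_error"
    )
  }
  steps_all <- sudoku_bfs_steps(cells)
  if (anyNA(steps_all)) {
    abort("Puzzle is not solvable by naked/hidden singles; beyond the ladder.",
          class = "redecide_beyond_ladder_error")
  }
  n_steps <- length(steps_all) # one inference per empty cell
  list(
    difficulty_steps = n_steps,
    difficulty_level = sudoku_level_from_steps(n_steps, bins),
    target_steps = unname(steps_all[[as.character(ti)]]),
    solution_digit = sols[[1]][target[1], target[2]]
  )
}

# Random complete grid via backtracking with shuffled digit order.
random_full_grid <- function() {
  recurse <- function(cl) {
    i <- match(0L, cl)
    if (is.na(i)) return(cl)
    cand <- cell_candidates(cl, i)
    for (d in cand[sample.int(length(cand))]) {
      cl[i] <- d
      res <- recurse(cl)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  recurse(rep(0L, 16L))
}

new_sudoku_puzzle <- function(cells, target_idx, score) {
  structure(
    list(
      grid = cells_to_grid(cells),
      target = c((target_idx - 1L) %/% 4L + 1L, (target_idx - 1L) %% 4L + 1L),
      solution_digit = score$solution_digit,
      difficulty_steps = score$difficulty_steps,
      difficulty_level = score$difficulty_level,
      target_steps = score$target_steps
    ),
    class = "sudoku_puzzle"
  )
}

#' @export
print.sudoku_puzzle <- function(x, ...) {
  cat(sprintf("4x4 Sudoku puzzle, level %d (%d logic steps, target chain %d)\n",
              x$difficulty_level, x$difficulty_steps, x$target_steps))
  g <- x$grid
  for (r in 1:4) {
    row <- ifelse(g[r, ] == 0L, ".", as.character(g[r, ]))
    if (r == x$target[1]) row[x$target[2]] <- "?"
    cat(" ", paste(row, collapse = " "), "\n")
  }
  invisible(x)
}

#' Generate a 4x4 Sudoku puzzle at a requested difficulty level
#'
#' Rejection sampling: complete a random full grid, remove cells one at a
#' time in random order while the puzzle keeps a unique completion, and read
#' off the prefix of the removal sequence whose length matches the step
#' count for the requested level. The first removed cell is the target cell
#' (it is empty in every prefix). The returned puzzle is re-graded so the
#' generator and grader are a fixed point by construction.
#'
#' @param level Integer difficulty level in 1..10 (1 easiest).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param max_attempts Retry budget over fresh grids/removal orders.
#' @return A `sudoku_puzzle`.
#' @export
generate_sudoku <- function(level, seed, max_attempts = 2000L) {
  stopifnot(length(level) == 1L, level %in% 1:10)
  with_seed_(seed, {
    for (attempt in seq_len(max_attempts)) {
      cells <- random_full_grid()
      order_rm <- sample.int(16L)
      removed <- integer(0)
      work <- cells
      need_max <- if (level < 10L) level else 12L
      for (i in order_rm) {
        if (length(removed) >= need_max) break
        trial <- work
        trial[i] <- 0L
        if (length(solve_sudoku(cells_to_grid(trial), limit = 2)) == 1L) {
          work <- trial
          removed <- c(removed, i)
        }
      }
      need <- if (level < 10L) level else 10:12
      for (n_rm in intersect(need, seq_along(removed))) {
        cand <- cells
        cand[removed[seq_len(n_rm)]] <- 0L
        score <- tryCatch(
          score_sudoku_difficulty(cells_to_grid(cand),
                                  target = c((removed[1] - 1L) %/% 4L + 1L,
                                             (removed[1] - 1L) %% 4L + 1L)),
          redecide_beyond_ladder_error = function(e) NULL
        )
        if (!is.null(score) && score$difficulty_level == level) {
          return(new_sudoku_puzzle(cand, removed[1], score))
        }
      }
    }
    abort(
      sprintf("Could not generate a level-%d puzzle within %d attempts.",
              level, max_attempts),
      class = "redecide_generation_exhausted_error"
    )
  })
}

#' Export or import a puzzle bank
#'
#' One row per puzzle: the 16-character row-major grid string (0 = empty),
#' the 1-based target row and column, the solution digit, the step count and
#' the level.
#'
#' @param puzzles A list of `sudoku_puzzle` objects.
#' @param path File path for the delimited text bank.
#' @return `write_puzzle_bank()` returns the tibble it wrote, invisibly;
#'   `read_puzzle_bank()` returns a list of `sudoku_puzzle` objects.
#' @export
write_puzzle_bank <- function(puzzles, path) {
  stopifnot(all(vapply(puzzles, inherits, logical(1), "sudoku_puzzle")))
  tab <- purrr::map_dfr(puzzles, function(p) {
    tibble::tibble(
      grid = paste(as.integer(t(p$grid)), collapse = ""),
      target_row = p$target[1], target_col = p$target[2],
      solution_digit = p$solution_digit,
      steps = p$difficulty_steps, level = p$difficulty_level
    )
  })
  readr::write_csv(tab, path)
  invisible(tab)
}

#' @rdname write_puzzle_bank
#' @export
read_puzzle_bank <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(grid = readr::col_character()))
  required <- c("grid", "target_row", "target_col", "solution_digit",
                "steps", "level")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(paste0("Puzzle bank is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "redecide_validation_error")
  }
  purrr::pmap(tab, function(grid, target_row, target_col, solution_digit,
                            steps, level, ...) {
    cells <- as.integer(strsplit(grid, "")[[1]])
    score <- score_sudoku_difficulty(cells_to_grid(cells),
                                     target = c(target_row, target_col))
    p <- new_sudoku_puzzle(cells, (target_row - 1L) * 4L + target_col, score)
    if (p$difficulty_level != level || p$solution_digit != solution_digit) {
      abort("Puzzle bank row disagrees with its re-grade.",
            class = "redecide_validation_error")
    }
    p
  })
}
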