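# ---- signed permutations ----------------------------------------------------

.check_signed_perm <- function(p, arg = "perm") {
  if (!is.numeric(p) || length(p) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric vector of signed integers", arg))
  if (any(p != trunc(p)) || any(p == 0))
    stop(sprintf("`%s` must contain non-zero integers (unsigned permutations are not supported)", arg))
  a <- sort(abs(as.integer(p)))
  if (!identical(a, seq_along(p)))
    stop(sprintf("`%s` is not a signed permutation: absolute values must be 1..n each exactly once", arg))
  as.integer(p)
}

#' Apply a signed reversal to a permutation
#'
#' Reverses the segment between positions `i` and `j` (1-based, inclusive)
#' and flips the sign of every element inside it. This is the elementary
#' move modelling a paracentric chromosomal inversion on a signed block
#' arrangement.
#'
#' @param perm Integer vector, a signed permutation (absolute values are
#'   `1..n`, each once; signs encode block orientation).
#' @param i,j Segment bounds, `1 <= i <= j <= length(perm)`.
#' @return The permutation after the reversal.
#' @examples
#' apply_reversal(c(1, 2, 3, 4, 5), 3, 3)
#' apply_reversal(c(1, 2, -3, 4, 5), 2, 4)
#' @export
apply_reversal <- function(perm, i, j) {
  p <- .check_signed_perm(perm)
  n <- length(p)
  if (!(is.numeric(i) && is.numeric(j) && length(i) == 1L && length(j) == 1L &&
        i >= 1 && j >= i && j <= n))
    stop(sprintf("reversal bounds out of range: need 1 <= i <= j <= %d, got (%s, %s)", n, i, j))
  p[i:j] <- -rev(p[i:j])
  p
}

#' Count breakpoints of a signed permutation
#'
#' With framing elements 0 and n+1 added, a breakpoint is an adjacent pair
#' (x, y) with `y != x + 1` in the signed extension. The identity has zero
#' breakpoints; each reversal can remove at most two, giving the classical
#' lower bound `d >= b / 2` on reversal distance.
#'
#' @param perm A signed permutation.
#' @return Integer breakpoint count.
#' @export
breakpoint_count <- function(perm) {
  p <- .check_signed_perm(perm)
  ext <- c(0L, p, length(p) + 1L)
  sum(ext[-1] != ext[-length(ext)] + 1L)
}

# Compose target^{-1} o source: the permutation whose sorting to identity is
# equivalent to transforming `source` into `target`.
.relative_perm <- function(source, target) {
  s <- .check_signed_perm(source, "source")
  t <- .check_signed_perm(target, "target")
  if (length(s) != length(t))
    stop("source and target must have the same length")
  tinv <- integer(length(t))
  tinv[abs(t)] <- sign(t) * seq_along(t)
  as.integer(sign(s) * tinv[abs(s)])
}

# ---- breakpoint graph -------------------------------------------------------

# Unsigned doubling of a signed permutation, framed by 0 and 2n+1.
# Element k of p occupies positions 2k and 2k+1 (1-based) of the result.
.double_perm <- function(p) {
  n <- length(p)
  u <- integer(2L * n + 2L)
  u[1L] <- 0L
  pos <- 2L * seq_len(n)
  u[pos] <- ifelse(p > 0, 2L * p - 1L, -2L * p)
  u[pos + 1L] <- ifelse(p > 0, 2L * p, -2L * p - 1L)
  u[2L * n + 2L] <- 2L * n + 1L
  u
}

# Breakpoint-graph cycle decomposition of a signed permutation.
# Returns cycle count and, for each nontrivial cycle, its gray edges as
# 0-indexed position pairs plus an orientation flag.
.breakpoint_graph <- function(p) {
  u <- .double_perm(p)
  n <- length(p)
  m <- length(u)
  pos_of_value <- integer(m)
  pos_of_value[u + 1L] <- seq_len(m)           # 1-based position of each value

  # black partner of 1-based position i: junction pairs (1,2), (3,4), ...
  black_partner <- function(i) if (i %% 2L == 0L) i - 1L else i + 1L
  # gray partner of value v: v xor 1 pairs (0,1), (2,3), ...
  gray_partner_value <- function(v) bitwXor(v, 1L)

  visited <- logical(m)
  cycles <- list()
  n_cycles <- 0L
  for (start in seq_len(m)) {
    if (visited[start]) next
    n_cycles <- n_cycles + 1L
    edges <- NULL
    i <- start
    repeat {
      visited[i] <- TRUE
      j <- black_partner(i)
      visited[j] <- TRUE
      vj <- u[j]
      k <- pos_of_value[gray_partner_value(vj) + 1L]   # follow gray edge
      edges <- rbind(edges, c(j - 1L, k - 1L))         # 0-indexed positions
      i <- k
      if (i == start) break
    }
    if (nrow(edges) > 1L) {                            # nontrivial cycle
      span <- t(apply(edges, 1L, sort))
      cycles[[length(cycles) + 1L]] <- list(
        gray = span,
        oriented = any((span[, 1L] + span[, 2L]) %% 2L == 0L)
      )
    }
  }
  list(n = n, n_cycles = n_cycles, cycles = cycles)
}

# Group nontrivial cycles into components by interleaving gray edges.
.bg_components <- function(bg) {
  k <- length(bg$cycles)
  if (k == 0L) return(list())
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (k > 1L) {
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      ga <- bg$cycles[[a]]$gray; gb <- bg$cycles[[b]]$gray
      hit <- FALSE
      for (ia in seq_len(nrow(ga))) {
        i1 <- ga[ia, 1L]; j1 <- ga[ia, 2L]
        ov <- (gb[, 1L] < i1 & i1 < gb[, 2L] & gb[, 2L] < j1) |
              (i1 < gb[, 1L] & gb[, 1L] < j1 & j1 < gb[, 2L])
        if (any(ov)) { hit <- TRUE; break }
      }
      if (hit) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <- rb }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  lapply(split(seq_len(k), roots), function(idx) {
    grays <- do.call(rbind, lapply(bg$cycles[idx], `[[`, "gray"))
    list(
      positions = sort(unique(as.vector(grays))),
      oriented = any(vapply(bg$cycles[idx], `[[`, logical(1), "oriented"))
    )
  })
}

# Hurdle set among unoriented components, by the circular non-separation
# rule: a hurdle is an unoriented component U such that the vertices of all
# other unoriented components fall into a single circular gap between
# consecutive vertices of U.
.hurdle_flags <- function(unor_pos) {
  m <- length(unor_pos)
  vapply(seq_len(m), function(i) {
    others <- unlist(unor_pos[-i], use.names = FALSE)
    if (length(others) == 0L) return(TRUE)
    u <- unor_pos[[i]]
    gap <- findInterval(others, u)
    gap[gap == length(u)] <- 0L       # after-last wraps onto before-first
    length(unique(gap)) == 1L
  }, logical(1))
}

.hurdle_analysis <- function(components) {
  unor <- Filter(function(cmp) !cmp$oriented, components)
  if (length(unor) == 0L) return(list(h = 0L, f = 0L))
  pos <- lapply(unor, `[[`, "positions")
  flags <- .hurdle_flags(pos)
  h <- sum(flags)
  f <- 0L
  if (h %% 2L == 1L && length(pos) > 1L) {
    # a hurdle is "super" if deleting it promotes a non-hurdle to a hurdle
    super <- vapply(which(flags), function(i) {
      rest <- pos[-i]
      newflags <- .hurdle_flags(rest)
      any(newflags & !flags[-i])
    }, logical(1))
    if (all(super) && length(super) == h) f <- 1L
  }
  list(h = as.integer(h), f = f)
}

#' Exact signed reversal distance
#'
#' Computes the minimum number of reversals (inversions) transforming one
#' signed permutation into another, by breakpoint-graph cycle decomposition
#' with hurdle and fortress corrections: `d = (n + 1) - c + h + f`. This is
#' the exact distance, not the cycle lower bound, so the value is a true
#' minimum even on permutations with unoriented components.
#'
#' @param source,target Signed permutations over the same element set.
#' @return Integer minimum reversal count; symmetric in its arguments.
#' @examples
#' reversal_distance(1:5, c(1, -4, 3, -2, 5))  # 2
#' @export
reversal_distance <- function(source, target = seq_along(source)) {
  p <- .relative_perm(source, target)
  n <- length(p)
  bg <- .breakpoint_graph(p)
  comps <- .bg_components(bg)
  hp <- .hurdle_analysis(comps)
  as.integer(n + 1L - bg$n_cycles + hp$h + hp$f)
}

#' Enumerate all minimal reversal scenarios
#'
#' Lists every ordered sequence of exactly `d = reversal_distance(source,
#' target)` reversals in which each step decreases the remaining distance by
#' one and whose application transforms `source` into `target`. Scenarios
#' are generated in lexicographic order of their step index pairs.
#'
#' The set of minimal scenarios is reported in full (up to `max_count`);
#' when the data cannot order the events, as for two nested inversions
#' where either may have occurred first, both orders appear and the solver
#' never picks one.
#'
#' @param source,target Signed permutations over the same element set.
#' @param max_count Cap on the number of scenarios returned; if exceeded the
#'   result carries attribute `truncated = TRUE` instead of erroring.
#' @param dedupe_unordered If `TRUE`, scenarios equal as unordered step sets
#'   are collapsed to one representative (default `FALSE`: order matters).
#' @return List of scenarios; each scenario is an integer matrix with
#'   columns `i`, `j`, one row per reversal, in order of application.
#' @examples
#' enumerate_minimal_scenarios(1:5, c(1, -4, 3, -2, 5))
#' @export
enumerate_minimal_scenarios <- function(source, target = seq_along(source),
                                        max_count = 1000L,
                                        dedupe_unordered = FALSE) {
  if (!(is.numeric(max_count) && length(max_count) == 1L && max_count >= 1))
    stop("`max_count` must be a single number >= 1")
  s <- .check_signed_perm(source, "source")
  t <- .check_signed_perm(target, "target")
  d <- reversal_distance(s, t)
  n <- length(s)
  out <- list()
  truncated <- FALSE

  recurse <- function(cur, dist_left, steps) {
    if (truncated) return()
    if (dist_left == 0L) {
      if (length(out) >= max_count) { truncated <<- TRUE; return() }
      m <- if (length(steps)) matrix(unlist(steps), ncol = 2L, byrow = TRUE,
                                     dimnames = list(NULL, c("i", "j")))
           else matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
      out[[length(out) + 1L]] <<- m
      return()
    }
    for (i in seq_len(n)) for (j in i:n) {
      nxt <- cur
      nxt[i:j] <- -rev(nxt[i:j])
      if (reversal_distance(nxt, t) == dist_left - 1L) {
        recurse(nxt, dist_left - 1L, c(steps, list(c(i, j))))
        if (truncated) return()
      }
    }
  }
  recurse(s, d, list())

  if (dedupe_unordered && length(out) > 1L) {
    key <- vapply(out, function(m) {
      rows <- apply(m, 1L, paste, collapse = ",")
      paste(sort(rows), collapse = ";")
    }, character(1))
    out <- out[!duplicated(key)]
  }
  attr(out, "distance") <- d
  attr(out, "truncated") <- truncated
  out
}

# ---- BFS oracle -------------------------------------------------------------

# Rank a matrix of signed permutations (columns) to 1-based state indices
# in 1..n! * 2^n: Lehmer rank of |p| times 2^n plus sign bits.
.encode_perms <- function(P) {
  n <- nrow(P)
  m <- ncol(P)
  signbits <- as.integer(crossprod(2^(seq_len(n) - 1L), P < 0))
  A <- abs(P)
  rank <- numeric(m)
  fact <- factorial(n - seq_len(n))
  for (i in seq_len(max(n - 1L, 1L))) {
    if (i >= n) break
    smaller <- integer(m)
    for (j in (i + 1L):n) smaller <- smaller + (A[j, ] < A[i, ])
    rank <- rank + smaller * fact[i]
  }
  as.integer(rank * 2^n + signbits + 1)
}

# All reversal distances from the identity for size n, by vectorized BFS
# over the full reversal graph. Cached per n within the session.
.bfs_env <- new.env(parent = emptyenv())

.bfs_distance_table <- function(n) {
  key <- as.character(n)
  if (!is.null(.bfs_env[[key]])) return(.bfs_env[[key]])
  n_states <- factorial(n) * 2^n
  if (n_states > 2^31 - 1) stop("state space too large for BFS oracle")
  dist <- rep(-1L, n_states)
  frontier <- matrix(seq_len(n), ncol = 1L)
  dist[.encode_perms(frontier)] <- 0L
  level <- 0L
  revs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  while (ncol(frontier) > 0L) {
    level <- level + 1L
    nxt <- vector("list", nrow(revs))
    for (r in seq_len(nrow(revs))) {
      i <- revs[r, 1L]; j <- revs[r, 2L]
      Q <- frontier
      Q[i:j, ] <- -Q[j:i, , drop = FALSE]
      ids <- .encode_perms(Q)
      new <- dist[ids] == -1L
      if (any(new)) {
        ids_new <- ids[new]
        keep <- !duplicated(ids_new)
        dist[ids_new[keep]] <- level
        nxt[[r]] <- Q[, new, drop = FALSE][, keep, drop = FALSE]
      }
    }
    nxt <- Filter(Negate(is.null), nxt)
    if (length(nxt) == 0L) break
    frontier <- do.call(cbind, nxt)
    ids <- .encode_perms(frontier)
    frontier <- frontier[, !duplicated(ids), drop = FALSE]
    # columns first reached by an earlier reversal at this same level
    frontier <- frontier[, dist[.encode_perms(frontier)] == level, drop = FALSE]
  }
  .bfs_env[[key]] <- dist
  dist
}

#' Brute-force reversal distance by breadth-first search
#'
#' Independent oracle for [reversal_distance()]: exhaustive BFS over the
#' reversal graph, exact by construction and sharing no code with the
#' breakpoint-graph path. Restricted to `n <= 8` (the state space is
#' `n! * 2^n`).
#'
#' @param source,target Signed permutations with `length <= 8`.
#' @return Integer exact distance.
#' @export
bfs_distance_oracle <- function(source, target = seq_along(source)) {
  p <- .relative_perm(source, target)
  n <- length(p)
  if (n > 8L) stop("bfs_distance_oracle is restricted to n <= 8")
  dist <- .bfs_distance_table(n)
  dist[.encode_perms(matrix(p, ncol = 1L))]
}

# ---- plain-text permutation I/O --------------------------------------------

#' Read signed permutations from a plain-text arrangement file
#'
#' Format: a `>name` header line followed by one line of space-separated
#' signed integers per genome (the conventional input style of genome
#' rearrangement tools).
#'
#' @param path File path.
#' @return Named list of signed integer vectors.
#' @export
read_signed_permutations <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  cur_name <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur_name <- trimws(substring(ln, 2L))
    } else {
      if (is.null(cur_name)) stop("permutation data before any '>' header")
      toks <- strsplit(ln, "[[:space:]]+")[[1]]
      # tolerate unicode minus as printed in some sources
      toks <- gsub("−", "-", toks)
      vals <- suppressWarnings(as.integer(toks))
      if (anyNA(vals)) stop(sprintf("cannot parse permutation line for '%s'", cur_name))
      out[[cur_name]] <- .check_signed_perm(vals, cur_name)
      cur_name <- NULL
    }
  }
  out
}

#' Write signed permutations in the plain-text arrangement format
#'
#' @param perms Named list of signed permutations.
#' @param path File path.
#' @export
write_signed_permutations <- function(perms, path) {
  stopifnot(is.list(perms), !is.null(names(perms)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(perms)) {
    writeLines(paste0(">", nm), con)
    writeLines(paste(perms[[nm]], collapse = " "), con)
  }
  invisible(path)
}
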