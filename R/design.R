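#' Generate a balanced incomplete block design for best-worst scaling tasks
#'
#' Builds questionnaire versions of object-case best-worst scaling (MaxDiff)
#' choice tasks in which each task shows a subset of `set_size` items out of
#' `n_items`. Within every version each item appears exactly
#' `r = n_tasks * set_size / n_items` times (this must be an integer); the
#' search then minimises, lexicographically, the variance of pairwise item
#' co-occurrence counts and the imbalance of display positions, using
#' random-restart pairwise-swap hill climbing. A version whose pair
#' co-occurrence counts are all equal to
#' `lambda = r * (set_size - 1) / (n_items - 1)` is a strict balanced
#' incomplete block design (BIBD); for the study configuration of 16 items,
#' 6 per task and 16 tasks, `r = 6` and `lambda = 2`. The search reports the
#' achieved minimum, which may exceed the BIBD optimum when the hill climb
#' does not find a perfect design.
#'
#' Versions are produced by independent searches (they share items, not
#' tasks). Results are deterministic for a fixed `seed`.
#'
#' @param n_items Number of items (attributes) in the study; 16 for the
#'   OxCAP-MH.
#' @param set_size Number of items shown per choice task (6).
#' @param n_tasks Number of tasks per questionnaire version (16).
#' @param n_versions Number of questionnaire versions (blocks, 3).
#' @param n_iterations Random restarts of the swap search per version.
#' @param seed Integer seed governing the whole search.
#' @return An object of class `bws_design`: a list with `n_items`,
#'   `set_size`, `n_tasks`, `n_versions`, `versions` (list of
#'   `n_tasks` x `set_size` integer matrices of 1-based item ids; columns are
#'   display positions), `pair_ss` (achieved sum of squared pair counts per
#'   version), `min_pair_ss` (integer lower bound), `r`, `seed`,
#'   `n_iterations`.
#' @seealso [validate_design()], [write_design()]
#' @export
#' @examples
#' d <- generate_design(16, 6, 16, n_versions = 1, n_iterations = 20, seed = 7)
#' validate_design(d)
generate_design <- function(n_items, set_size, n_tasks, n_versions = 1L,
                            n_iterations = 1000L, seed = 1L) {
  n_items <- as.integer(n_items); set_size <- as.integer(set_size)
  n_tasks <- as.integer(n_tasks); n_versions <- as.integer(n_versions)
  n_iterations <- as.integer(n_iterations)
  if (set_size > n_items)
    stop("`set_size` (", set_size, ") must not exceed `n_items` (",
         n_items, ")")
  if (set_size < 2L) stop("`set_size` must be at least 2")
  if ((n_tasks * set_size) %% n_items != 0L)
    stop("n_tasks * set_size (", n_tasks * set_size,
         ") must be divisible by n_items (", n_items,
         ") so that each item can appear equally often")
  if (n_iterations < 1L) stop("`n_iterations` must be at least 1")
  if (n_versions < 1L) stop("`n_versions` must be at least 1")

  set.seed(seed)
  versions <- vector("list", n_versions)
  pair_ss <- numeric(n_versions)
  min_pair_ss <- NA_real_
  for (v in seq_len(n_versions)) {
    res <- cpp_search_version(n_items, set_size, n_tasks, n_iterations,
                              inner_budget = 5000L, stall_limit = 800L)
    tasks <- balance_positions(res$tasks, n_items)
    dimnames(tasks) <- list(task = seq_len(n_tasks),
                            position = seq_len(set_size))
    versions[[v]] <- tasks
    pair_ss[v] <- res$pair_ss
    min_pair_ss <- res$min_pair_ss
  }
  structure(
    list(n_items = n_items, set_size = set_size, n_tasks = n_tasks,
         n_versions = n_versions, versions = versions, pair_ss = pair_ss,
         min_pair_ss = min_pair_ss,
         r = (n_tasks * set_size) %/% n_items,
         seed = seed, n_iterations = n_iterations),
    class = "bws_design")
}

# Greedy within-task position swaps minimising the variance of item-by-
# position display counts. Swapping two positions of the same task leaves
# item and pair balance untouched, so this is the lowest-priority objective.
balance_positions <- function(tasks, n_items, sweeps = 8L) {
  k <- ncol(tasks)
  counts <- matrix(0L, n_items, k)
  for (p in seq_len(k)) {
    tab <- tabulate(tasks[, p], nbins = n_items)
    counts[, p] <- counts[, p] + tab
  }
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    for (t in seq_len(nrow(tasks))) {
      for (p1 in seq_len(k - 1L)) {
        for (p2 in seq.int(p1 + 1L, k)) {
          a <- tasks[t, p1]; b <- tasks[t, p2]
          delta <- 2 * (counts[a, p2] - counts[a, p1] + 1) +
                   2 * (counts[b, p1] - counts[b, p2] + 1)
          if (delta < 0) {
            counts[a, p1] <- counts[a, p1] - 1L
            counts[a, p2] <- counts[a, p2] + 1L
            counts[b, p2] <- counts[b, p2] - 1L
            counts[b, p1] <- counts[b, p1] + 1L
            tasks[t, p1] <- b; tasks[t, p2] <- a
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  tasks
}

#' Validate a best-worst scaling design and report its balance
#'
#' Counts, per questionnaire version, how often each item is shown, how often
#' each unordered item pair co-occurs in a task, and how often each item
#' lands in each display position. A version is flagged as a strict BIBD when
#' both its item frequencies and its pair co-occurrences are constant.
#'
#' @param design A [`bws_design`][generate_design()] object.
#' @return An object of class `bws_balance`: list with `item_frequencies`
#'   (`n_items` x `n_versions`), `pair_cooccurrence`
#'   (`n_items` x `n_items` x `n_versions` array, zero diagonal),
#'   `positional_frequencies` (`n_items` x `set_size` x `n_versions`),
#'   `is_bibd` (logical per version), `r` and `lambda` (per-version common
#'   frequency and pair count, `NA` when not constant).
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "bws_design"))
  v <- design$n_items; k <- design$set_size
  nv <- design$n_versions
  freq <- matrix(0L, v, nv, dimnames = list(item = seq_len(v),
                                            version = seq_len(nv)))
  pairs <- array(0L, c(v, v, nv),
                 dimnames = list(item = seq_len(v), item = seq_len(v),
                                 version = seq_len(nv)))
  pos <- array(0L, c(v, k, nv),
               dimnames = list(item = seq_len(v), position = seq_len(k),
                               version = seq_len(nv)))
  is_bibd <- logical(nv)
  r_out <- lambda_out <- rep(NA_real_, nv)
  for (b in seq_len(nv)) {
    tasks <- design$versions[[b]]
    for (t in seq_len(nrow(tasks))) {
      row <- tasks[t, ]
      if (anyDuplicated(row))
        stop("version ", b, ", task ", t, " contains a duplicated item (",
             paste(row[duplicated(row)], collapse = ", "), ")")
      if (any(row < 1L | row > v))
        stop("version ", b, ", task ", t, " references items outside 1..",
             v)
    }
    X <- matrix(0L, nrow(tasks), v)
    X[cbind(rep(seq_len(nrow(tasks)), k), as.vector(tasks))] <- 1L
    freq[, b] <- colSums(X)
    P <- crossprod(X)
    diag(P) <- 0L
    pairs[, , b] <- P
    for (p in seq_len(k))
      pos[, p, b] <- tabulate(tasks[, p], nbins = v)
    upper <- P[upper.tri(P)]
    freq_const <- length(unique(freq[, b])) == 1L
    pair_const <- length(unique(upper)) == 1L
    is_bibd[b] <- freq_const && pair_const
    if (freq_const) r_out[b] <- freq[1L, b]
    if (pair_const) lambda_out[b] <- upper[1L]
  }
  structure(
    list(item_frequencies = freq, pair_cooccurrence = pairs,
         positional_frequencies = pos, is_bibd = is_bibd,
         r = r_out, lambda = lambda_out,
         n_items = v, set_size = k, n_tasks = design$n_tasks),
    class = "bws_balance")
}

#' @export
print.bws_design <- function(x, ...) {
  cat("Best-worst scaling design:", x$n_versions, "version(s) of", x$n_tasks,
      "tasks,", x$set_size, "of", x$n_items, "items per task\n")
  cat("Item frequency per version: r =", x$r, "\n")
  cat("Pair co-occurrence sum of squares:", paste(x$pair_ss, collapse = ", "),
      "(lower bound", x$min_pair_ss, ")\n")
  invisible(x)
}

#' @export
print.bws_balance <- function(x, ...) {
  cat("Design balance report (", ncol(x$item_frequencies), " version(s))\n",
      sep = "")
  for (b in seq_along(x$is_bibd)) {
    up <- x$pair_cooccurrence[, , b][upper.tri(diag(x$n_items))]
    cat("  version ", b, ": item frequencies ",
        paste(range(x$item_frequencies[, b]), collapse = "-"),
        ", pair co-occurrence ", paste(range(up), collapse = "-"),
        if (x$is_bibd[b]) " [strict BIBD]" else "", "\n", sep = "")
  }
  invisible(x)
}
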